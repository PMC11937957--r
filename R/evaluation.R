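#' Call edges from fitted precision matrices
#'
#' An off-diagonal entry is declared an edge when its absolute value exceeds
#' `edge_threshold`. The shared-relationship network is composed from the
#' subtype networks by the configured rule; the default is the union, so an
#' edge present in any subtype network is reported as shared-candidate (the
#' intersection rule is also available).
#'
#' @param params a [mixture_params()].
#' @param edge_threshold positive threshold on the precision scale.
#' @param rule `"union"` or `"intersection"` for the shared network.
#' @return Object of class `network_set`: `subtype_adjacency` (list of K
#'   logical matrices), `overall_adjacency`, `shared_adjacency`, `rule`.
#' @export
call_edges <- function(params, edge_threshold, rule = c("union", "intersection")) {
  rule <- match.arg(rule)
  if (edge_threshold <= 0) stop("edge_threshold must be positive")
  adj <- function(Om) {
    A <- abs(Om) > edge_threshold
    diag(A) <- FALSE
    A
  }
  sub <- lapply(params$precisions, adj)
  shared <- Reduce(if (rule == "union") `|` else `&`, sub)
  structure(list(subtype_adjacency = sub,
                 overall_adjacency = adj(params$overall_precision),
                 shared_adjacency = shared, rule = rule),
            class = "network_set")
}

#' Edge-level confusion metrics
#'
#' Standard confusion metrics over unordered gene pairs (upper triangle,
#' diagonal excluded). When the truth has no edges the TPR (and recall) is
#' undefined and reported as `NA`; an F1 with zero denominator is reported
#' as 0.
#'
#' @param est,truth logical adjacency matrices of the same shape (or objects
#'   coercible by `as.matrix`).
#' @param pair_mask optional logical matrix restricting which unordered pairs
#'   enter the counts.
#' @return Named list: `TP`, `FP`, `FN`, `TN`, `FPR`, `TPR`, `precision`,
#'   `recall`, `F1`.
#' @export
confusion_metrics <- function(est, truth, pair_mask = NULL) {
  est <- as.matrix(est); truth <- as.matrix(truth)
  if (!identical(dim(est), dim(truth)))
    stop("estimate and truth adjacency shapes differ")
  keep <- upper.tri(est)
  if (!is.null(pair_mask)) keep <- keep & pair_mask
  e <- est[keep]; t_ <- truth[keep]
  TP <- sum(e & t_); FP <- sum(e & !t_)
  FN <- sum(!e & t_); TN <- sum(!e & !t_)
  TPR <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  FPR <- if (FP + TN > 0) FP / (FP + TN) else NA_real_
  prec <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
  F1 <- if (is.na(prec) || is.na(TPR) || prec + TPR == 0) {
    if (isTRUE(TP + FP + FN == 0)) NA_real_ else 0
  } else 2 * prec * TPR / (prec + TPR)
  list(TP = TP, FP = FP, FN = FN, TN = TN, FPR = FPR, TPR = TPR,
       precision = prec, recall = TPR, F1 = F1)
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same samples,
#' computed from the pair-counting contingency table. Equals 1 exactly when
#' the partitions coincide up to relabeling; its expectation under random
#' labeling is 0.
#'
#' @param labels_a,labels_b vectors of equal length (any label type).
#' @return A single number `<= 1`.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors must have equal length")
  tab <- table(labels_a, labels_b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  a <- sum(choose2(rowSums(tab)))
  b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(labels_a))
  expected <- a * b / n2
  mx <- (a + b) / 2
  if (mx == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (mx - expected)
}

# Logical matrix of unordered pairs lying within the same diagonal 10x10
# block, restricted to blocks flagged (or not flagged) public.
.block_pair_mask <- function(p, public, want_public) {
  B <- p %/% 10L
  mask <- matrix(FALSE, p, p)
  for (b in seq_len(B)) {
    if (public[b] == want_public) {
      idx <- ((b - 1L) * 10L + 1L):(b * 10L)
      mask[idx, idx] <- TRUE
    }
  }
  diag(mask) <- FALSE
  mask
}

#' Public vs non-public block metrics and overall-network performance
#'
#' Restricts [confusion_metrics()] to gene pairs lying within public blocks
#' and, separately, within non-public blocks (pairs within the same diagonal
#' 10 x 10 block slot), reported per subtype and pooled. Also scores the
#' overall network against the true shared-edge set (edges present in every
#' true subtype network), where the model is expected to show high recall and
#' more modest precision.
#'
#' @param networks a [call_edges()] network set.
#' @param truth a [make_precision_set()] ground truth.
#' @return List: `per_subtype` (data.frame of public/non-public F1 etc. per
#'   subtype), `public`, `nonpublic` (pooled metrics), `overall` (recall and
#'   precision of the overall network for true shared edges).
#' @export
blockwise_metrics <- function(networks, truth) {
  p <- truth$p
  K <- length(networks$subtype_adjacency)
  pub_mask <- .block_pair_mask(p, truth$public_block_mask, TRUE)
  non_mask <- .block_pair_mask(p, truth$public_block_mask, FALSE)
  rows <- list()
  agg <- function(mask) {
    cnt <- c(TP = 0, FP = 0, FN = 0, TN = 0)
    for (k in seq_len(K)) {
      mk <- confusion_metrics(networks$subtype_adjacency[[k]],
                              truth$true_edges[[k]], mask)
      cnt <- cnt + c(mk$TP, mk$FP, mk$FN, mk$TN)
    }
    TPR <- if (cnt["TP"] + cnt["FN"] > 0)
      cnt[["TP"]] / (cnt[["TP"]] + cnt[["FN"]]) else NA_real_
    prec <- if (cnt["TP"] + cnt["FP"] > 0)
      cnt[["TP"]] / (cnt[["TP"]] + cnt[["FP"]]) else NA_real_
    F1 <- if (is.na(prec) || is.na(TPR) || prec + TPR == 0) 0
      else 2 * prec * TPR / (prec + TPR)
    list(TPR = TPR, precision = prec, F1 = F1)
  }
  for (k in seq_len(K)) {
    pm <- confusion_metrics(networks$subtype_adjacency[[k]],
                            truth$true_edges[[k]], pub_mask)
    nm <- confusion_metrics(networks$subtype_adjacency[[k]],
                            truth$true_edges[[k]], non_mask)
    rows[[k]] <- data.frame(subtype = k,
                            public_TPR = pm$TPR, public_F1 = pm$F1,
                            nonpublic_TPR = nm$TPR, nonpublic_F1 = nm$F1)
  }
  shared_truth <- Reduce(`&`, truth$true_edges)
  ov <- confusion_metrics(networks$overall_adjacency, shared_truth)
  list(per_subtype = do.call(rbind, rows),
       public = agg(pub_mask), nonpublic = agg(non_mask),
       overall = list(recall = ov$recall, precision = ov$precision,
                      F1 = ov$F1))
}

#' Score a fit against simulation ground truth
#'
#' Convenience wrapper: edge-level FPR/TPR/F1 per subtype network averaged
#' over subtypes, plus the clustering ARI.
#'
#' @param fit an [ajgm_fit()] result.
#' @param truth a [make_precision_set()] ground truth.
#' @param labels true generating labels aligned with the fitted data rows.
#' @return Named list `FPR`, `TPR`, `F1` (subtype means) and `ARI`.
#' @export
score_fit <- function(fit, truth, labels) {
  K <- length(fit$networks$subtype_adjacency)
  # Match fitted clusters to generating subtypes by majority vote so the
  # network comparison is label-permutation proof; fall back to the identity
  # if the vote is not a bijection.
  map <- vapply(seq_len(K), function(k) {
    in_k <- labels[fit$hard_labels == k]
    if (length(in_k) == 0L) return(NA_integer_)
    as.integer(names(which.max(table(in_k))))
  }, integer(1))
  if (anyNA(map) || anyDuplicated(map)) map <- seq_len(K)
  ms <- lapply(seq_len(K), function(k)
    confusion_metrics(fit$networks$subtype_adjacency[[k]],
                      truth$true_edges[[map[k]]]))
  list(FPR = mean(vapply(ms, `[[`, numeric(1), "FPR")),
       TPR = mean(vapply(ms, `[[`, numeric(1), "TPR")),
       F1 = mean(vapply(ms, `[[`, numeric(1), "F1")),
       ARI = adjusted_rand_index(fit$hard_labels, labels))
}
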