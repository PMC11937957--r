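#' Expression data container
#'
#' Bundles an n x p log-scale expression matrix (samples in rows, genes in
#' columns) with sample/gene labels and a logical mask recording which entries
#' were exact zeros in the raw data. The mask drives dropout imputation during
#' fitting: log-transforming raw counts maps 0 to 0 again, so the mask is the
#' only record of which zeros are candidate dropouts.
#'
#' @param values numeric n x p matrix, no missing values, n >= 2 and p >= 2.
#' @param sample_ids optional character vector of n sample labels.
#' @param gene_ids optional character vector of p gene labels.
#' @param zero_mask optional logical n x p matrix; `TRUE` marks entries that
#'   were exactly zero in the raw data. Defaults to all `FALSE`.
#' @return An object of class `ajgm_data` with fields `values`, `sample_ids`,
#'   `gene_ids`, `zero_mask`.
#' @export
ajgm_data <- function(values, sample_ids = NULL, gene_ids = NULL,
                      zero_mask = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values); p <- ncol(values)
  if (n < 2L || p < 2L)
    stop("expression matrix must have at least 2 samples and 2 genes")
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression matrix contains missing or non-finite values")
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  if (is.null(gene_ids))   gene_ids <- paste0("g", seq_len(p))
  if (length(sample_ids) != n) stop("sample_ids length must equal nrow(values)")
  if (length(gene_ids) != p)   stop("gene_ids length must equal ncol(values)")
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  if (is.null(zero_mask)) {
    zero_mask <- matrix(FALSE, n, p)
  } else {
    zero_mask <- as.matrix(zero_mask)
    if (!is.logical(zero_mask) || !identical(dim(zero_mask), dim(values)))
      stop("zero_mask must be a logical matrix with the same shape as values")
  }
  dimnames(values) <- list(sample_ids, gene_ids)
  structure(list(values = values, sample_ids = as.character(sample_ids),
                 gene_ids = as.character(gene_ids), zero_mask = zero_mask),
            class = "ajgm_data")
}

#' @export
print.ajgm_data <- function(x, ...) {
  cat(sprintf("<ajgm_data> %d samples x %d genes, %.1f%% masked zeros\n",
              nrow(x$values), ncol(x$values), 100 * mean(x$zero_mask)))
  invisible(x)
}

#' Overall-sample container
#'
#' The m x p matrix X' from which the overall (shared) network is estimated.
#' See [make_overall()] for the two constructions when no dedicated overall
#' samples exist.
#'
#' @param values numeric m x p matrix, m >= 2.
#' @param source one of `"provided"`, `"identity_of_X"`, `"sampled"`.
#' @return Object of class `overall_samples`.
#' @export
overall_samples <- function(values,
                            source = c("provided", "identity_of_X", "sampled")) {
  source <- match.arg(source)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 2L) stop("overall samples need m >= 2")
  if (anyNA(values)) stop("overall samples contain missing values")
  structure(list(values = values, source = source), class = "overall_samples")
}

#' Mixture-model parameters
#'
#' Holds the full parameter set of the model: subtype proportions pi_k, subtype
#' means mu_k and precisions Omega_k (k = 1..K), plus the overall mean mu_X and
#' precision Omega_X fitted to the pooled samples.
#'
#' @param proportions length-K simplex vector of subtype proportions.
#' @param means K x p matrix of subtype means (rows are subtypes).
#' @param precisions list of K symmetric positive-definite p x p matrices.
#' @param overall_mean length-p mean of the overall samples.
#' @param overall_precision symmetric positive-definite p x p matrix.
#' @return Object of class `mixture_params`.
#' @export
mixture_params <- function(proportions, means, precisions, overall_mean,
                           overall_precision) {
  proportions <- as.numeric(proportions)
  means <- rbind(means)  # 1 x p stays a matrix for K = 1
  K <- length(proportions)
  if (abs(sum(proportions) - 1) > 1e-12)
    stop("proportions must sum to 1 (within 1e-12)")
  if (any(proportions <= 0)) stop("all proportions must be positive")
  if (!is.list(precisions) || length(precisions) != K)
    stop("precisions must be a list of K matrices")
  if (nrow(means) != K) stop("means must be a K x p matrix")
  p <- ncol(means)
  for (Om in c(precisions, list(overall_precision))) {
    if (!is.matrix(Om) || nrow(Om) != p || ncol(Om) != p)
      stop("precision matrices must be p x p")
    if (max(abs(Om - t(Om))) > 1e-10) stop("precision matrix not symmetric")
    ev <- min(eigen(Om, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 0) stop("precision matrix not positive definite")
  }
  if (length(overall_mean) != p) stop("overall_mean must have length p")
  structure(list(proportions = proportions, means = means,
                 precisions = precisions,
                 overall_mean = as.numeric(overall_mean),
                 overall_precision = overall_precision),
            class = "mixture_params")
}

#' Penalty configuration
#'
#' Tuning parameters of the adaptive fused penalty. `lambda1` controls network
#' sparsity, `lambda2` the similarity between adjacent subtype networks and
#' `lambda3` (> lambda2) the pull of the last subtype network towards the
#' overall network. `gamma` is the adaptive-weight exponent: weights are
#' 1/|difference|^gamma, clamped between `1/weight_floor^gamma` issues via the
#' floor and `weight_cap`. `tre` is the similarity threshold deciding whether
#' all subtypes agree on an entry (in which case the full `lambda3` applies to
#' the overall-fusion term; otherwise it is downgraded to `lambda2`).
#'
#' @param lambda1,lambda2,lambda3 non-negative penalty strengths,
#'   `lambda3 > lambda2`.
#' @param gamma non-negative adaptive-weight exponent (default 1).
#' @param tre non-negative similarity threshold (default 0.01, on the
#'   precision-entry scale).
#' @param weight_floor,weight_cap clamping constants for the adaptive weights.
#' @param edge_threshold absolute precision value above which an off-diagonal
#'   entry is called an edge. The default 0.1 is about two null standard
#'   deviations of a precision entry at sample sizes in the low hundreds;
#'   entries below it are indistinguishable from estimation noise even when
#'   numerically nonzero (the overall network in particular carries small
#'   nonzero entries induced by between-subtype mean variance in the pooled
#'   samples, which a near-zero threshold would misread as edges).
#' @return Object of class `penalty_config`.
#' @export
penalty_config <- function(lambda1 = 1, lambda2 = 0.25, lambda3 = 0.5,
                           gamma = 1, tre = 0.01,
                           weight_floor = 1e-6, weight_cap = 1e4,
                           edge_threshold = 0.1) {
  if (lambda1 < 0 || lambda2 < 0) stop("lambda1 and lambda2 must be >= 0")
  if (lambda3 <= lambda2) stop("lambda3 must be strictly greater than lambda2")
  if (gamma < 0) stop("gamma must be >= 0")
  if (tre < 0) stop("tre must be >= 0")
  if (weight_floor <= 0 || weight_cap <= weight_floor)
    stop("need 0 < weight_floor < weight_cap")
  if (edge_threshold <= 0) stop("edge_threshold must be positive")
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
                 gamma = gamma, tre = tre, weight_floor = weight_floor,
                 weight_cap = weight_cap, edge_threshold = edge_threshold),
            class = "penalty_config")
}

#' Posterior responsibilities
#'
#' Validates an n x K matrix of posterior subtype-membership probabilities
#' (each row a simplex vector).
#'
#' @param posterior n x K numeric matrix.
#' @return Object of class `responsibilities` (the validated matrix).
#' @export
responsibilities <- function(posterior) {
  posterior <- as.matrix(posterior)
  if (any(posterior < -1e-12) || any(posterior > 1 + 1e-12))
    stop("responsibilities must lie in [0, 1]")
  if (max(abs(rowSums(posterior) - 1)) > 1e-10)
    stop("responsibility rows must sum to 1 (within 1e-10)")
  structure(posterior, class = c("responsibilities", "matrix", "array"))
}

# log N(x | mu, Omega^{-1}) for all rows of X, parameterized by the precision.
# chol(Omega) = R (upper) with Omega = R'R, so the quadratic form is the
# squared norm of R (x - mu) and logdet(Omega) = 2 sum(log(diag(R))).
.ldens_prec <- function(X, mu, Omega, R = NULL) {
  X <- rbind(X)
  p <- ncol(X)
  if (is.null(R)) R <- chol(Omega)
  D <- sweep(X, 2L, mu)
  q <- rowSums((D %*% t(R))^2)
  -0.5 * p * log(2 * pi) + sum(log(diag(R))) - 0.5 * q
}

# n x K matrix of per-component log pi_k + log N(x_l | mu_k, Omega_k^{-1})
.component_logdens <- function(X, params) {
  K <- length(params$proportions)
  out <- matrix(0, nrow(X), K)
  for (k in seq_len(K)) {
    out[, k] <- log(params$proportions[k]) +
      .ldens_prec(X, params$means[k, ], params$precisions[[k]])
  }
  out
}

.logsumexp_rows <- function(M) {
  mx <- apply(M, 1L, max)
  bad <- !is.finite(mx)
  out <- mx + log(rowSums(exp(M - mx)))
  out[bad] <- -Inf
  out
}

#' Log-density of the Gaussian mixture
#'
#' Evaluates log p(x) = log sum_k pi_k N(x | mu_k, Omega_k^{-1}) in log space
#' (log-sum-exp), so that components with densities as small as exp(-700)
#' neither underflow nor overflow.
#'
#' @param x length-p numeric vector.
#' @param params a [mixture_params()] object.
#' @return The log mixture density, a single number.
#' @export
mixture_log_density <- function(x, params) {
  x <- as.numeric(x)
  if (length(x) != ncol(params$means))
    stop("x has length ", length(x), " but the model has p = ",
         ncol(params$means), " genes")
  ld <- .component_logdens(matrix(x, nrow = 1L), params)
  as.numeric(.logsumexp_rows(ld))
}

#' Adaptive fusion weight for one entry pair
#'
#' w = 1 / max(|theta_a - theta_b|, weight_floor)^gamma, capped at
#' `weight_cap`: pairs of precision entries that already agree get a large
#' weight (their difference is penalized hard, pushing them to fuse exactly),
#' while clearly different pairs are left alone. Vectorized over its first two
#' arguments.
#'
#' @param theta_a,theta_b precision-matrix entries (numeric, recycled).
#' @param gamma non-negative exponent.
#' @param cfg a [penalty_config()] (supplies floor and cap).
#' @return Numeric weight(s) in `(0, weight_cap]`.
#' @export
adaptive_weight <- function(theta_a, theta_b, gamma, cfg) {
  d <- pmax(abs(theta_a - theta_b), cfg$weight_floor)
  pmin(1 / d^gamma, cfg$weight_cap)
}

#' Consensus multiplier for the overall-fusion term
#'
#' Returns 1 when all adjacent subtype differences for an entry are below the
#' similarity threshold `tre` (the subtypes agree, so the full `lambda3`
#' applies to the difference from the overall network), and `lambda2/lambda3`
#' otherwise (disagreeing subtypes are only pulled with strength `lambda2`).
#' With a single subtype the agreement condition is vacuous and 1 is returned.
#'
#' @param theta_row numeric vector of the K subtype values for one (i, j).
#' @param cfg a [penalty_config()].
#' @return A single number, 1 or `lambda2/lambda3`.
#' @export
consensus_multiplier <- function(theta_row, cfg) {
  K <- length(theta_row)
  if (K < 2L) return(1)
  if (all(abs(diff(theta_row)) < cfg$tre)) 1 else cfg$lambda2 / cfg$lambda3
}

#' Adaptive weight set
#'
#' Container for the fusion weights used by the penalty: `subtype_fusion` is a
#' list of K-1 symmetric p x p matrices of weights on adjacent subtype
#' differences, `overall_fusion` the p x p weights on the last-subtype vs
#' overall differences, and `consensus` the p x p matrix of consensus
#' multipliers (values 1 or lambda2/lambda3).
#'
#' @param subtype_fusion list of K-1 p x p matrices (empty list for K = 1).
#' @param overall_fusion p x p matrix.
#' @param consensus p x p matrix.
#' @return Object of class `adaptive_weights`.
#' @export
adaptive_weights <- function(subtype_fusion, overall_fusion, consensus) {
  structure(list(subtype_fusion = subtype_fusion,
                 overall_fusion = overall_fusion,
                 consensus = consensus),
            class = "adaptive_weights")
}

#' Unit weights (no adaptivity)
#'
#' All fusion weights 1 and all consensus multipliers 1; used for the first
#' EM iteration, before any precision estimate exists to adapt to.
#'
#' @param K number of subtypes.
#' @param p number of genes.
#' @return An [adaptive_weights()] object.
#' @export
unit_weights <- function(K, p) {
  one <- matrix(1, p, p)
  adaptive_weights(
    subtype_fusion = rep(list(one), max(K - 1L, 0L)),
    overall_fusion = one,
    consensus = one)
}

#' Adaptive fused penalty value
#'
#' Evaluates the penalty
#' \deqn{P(\Theta) = \lambda_1 (\sum_{i \ne j} \sum_k |\theta_{ij}^{(k)}| +
#'   \sum_{i \ne j} |\theta_{ij}^{(X)}|)
#'   + \lambda_2 \sum_{i \ne j} \sum_{k<K} w_{ij}^{(k,k+1)}
#'     |\theta_{ij}^{(k)} - \theta_{ij}^{(k+1)}|
#'   + \lambda_3 \sum_{i \ne j} f_{ij} w_{ij}^{(K,X)}
#'     |\theta_{ij}^{(K)} - \theta_{ij}^{(X)}|}
#' where sums run over ordered pairs i != j (each unordered pair counted
#' twice); diagonal entries are never penalized.
#'
#' @param params a [mixture_params()].
#' @param cfg a [penalty_config()].
#' @param weights an [adaptive_weights()] consistent with K.
#' @return The penalty value, a non-negative number.
#' @export
penalty_value <- function(params, cfg, weights) {
  K <- length(params$proportions)
  p <- ncol(params$means)
  off <- !diag(TRUE, p)
  l1 <- sum(vapply(params$precisions,
                   function(Om) sum(abs(Om[off])), numeric(1))) +
    sum(abs(params$overall_precision[off]))
  fus <- 0
  if (K >= 2L) {
    for (k in seq_len(K - 1L)) {
      d <- params$precisions[[k]] - params$precisions[[k + 1L]]
      fus <- fus + sum((weights$subtype_fusion[[k]] * abs(d))[off])
    }
  }
  dX <- params$precisions[[K]] - params$overall_precision
  ov <- sum((weights$consensus * weights$overall_fusion * abs(dX))[off])
  cfg$lambda1 * l1 + cfg$lambda2 * fus + cfg$lambda3 * ov
}

#' Penalized log-likelihood
#'
#' The objective of the model: the observed-data mixture log-likelihood of X,
#' plus the Gaussian log-likelihood of the overall samples X', minus the
#' adaptive fused penalty.
#'
#' @param X an [ajgm_data()] object.
#' @param Xp an [overall_samples()] object.
#' @param params a [mixture_params()].
#' @param cfg a [penalty_config()].
#' @param weights an [adaptive_weights()].
#' @return A single number (deterministic in its inputs).
#' @export
penalized_loglik <- function(X, Xp, params, cfg, weights) {
  if (ncol(X$values) != ncol(params$means))
    stop("dimension mismatch between data and parameters")
  ll_mix <- sum(.logsumexp_rows(.component_logdens(X$values, params)))
  ll_ov <- sum(.ldens_prec(Xp$values, params$overall_mean,
                           params$overall_precision))
  ll_mix + ll_ov - penalty_value(params, cfg, weights)
}

#' Unpenalized log-likelihood
#'
#' Mixture log-likelihood of X plus Gaussian log-likelihood of X' at the given
#' parameters; the quantity entering the BIC.
#'
#' @inheritParams penalized_loglik
#' @return A single number.
#' @export
loglik <- function(X, Xp, params) {
  sum(.logsumexp_rows(.component_logdens(X$values, params))) +
    sum(.ldens_prec(Xp$values, params$overall_mean, params$overall_precision))
}
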