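#' Simulation configuration
#'
#' Settings for the modular block-structured generator: precision matrices are
#' block diagonal with 10 x 10 modules; each diagonal block slot is "public"
#' (identical across all subtypes) with probability `public_prob`, otherwise
#' each subtype gets an independently drawn module. Subtype means are offset
#' multiples of the all-ones vector, `mu_k = k * mean_separation * 1`.
#'
#' @param p number of genes, a multiple of 10.
#' @param K number of subtypes.
#' @param nk samples per subtype.
#' @param public_prob probability a block slot is public (default 0.3).
#' @param mean_separation spacing between consecutive subtype means
#'   (default 2, in log-expression units).
#' @param seed integer seed.
#' @return Object of class `sim_config`.
#' @export
simulation_config <- function(p = 100L, K = 3L, nk = 300L, public_prob = 0.3,
                              mean_separation = 2, seed = 1L) {
  if (p %% 10L != 0L) stop("p must be a multiple of 10")
  if (public_prob < 0 || public_prob > 1) stop("public_prob must be in [0,1]")
  if (K < 1L || nk < 2L) stop("need K >= 1 and nk >= 2")
  structure(list(p = as.integer(p), K = as.integer(K), nk = as.integer(nk),
                 public_prob = public_prob, mean_separation = mean_separation,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Build a 10 x 10 precision module
#'
#' The four module archetypes: `Md` (dense: every off-diagonal pair connected
#' with value 0.2), `Mc` (circle: the 10-cycle, value 0.25), `Ms` (star: node 1
#' is a hub connected to all others, value 0.25) and `M0` (no edges). All have
#' unit diagonal and are positive definite as-is.
#'
#' @param kind one of `"Md"`, `"Mc"`, `"Ms"`, `"M0"`.
#' @return A symmetric 10 x 10 matrix.
#' @export
make_module <- function(kind = c("Md", "Mc", "Ms", "M0")) {
  kind <- match.arg(kind)
  M <- diag(10)
  if (kind == "Md") {
    M[] <- 0.2
    diag(M) <- 1
  } else if (kind == "Mc") {
    for (i in 1:9) M[i, i + 1L] <- M[i + 1L, i] <- 0.25
    M[1L, 10L] <- M[10L, 1L] <- 0.25
  } else if (kind == "Ms") {
    M[1L, 2:10] <- M[2:10, 1L] <- 0.25
  }
  M
}

#' Generate the ground-truth precision matrices
#'
#' Each of the p/10 diagonal block slots is public with probability
#' `public_prob`; public slots receive one module drawn uniformly from
#' {Md, Mc, Ms}, shared bit-identically by all K precision matrices;
#' non-public slots receive an independent module per subtype drawn from
#' {Md, Mc, Ms, M0}. Off-block entries are zero. Should a matrix's smallest
#' eigenvalue fall below 0.1, the diagonal is shifted up just enough to reach
#' it (with the module values above no shift is ever needed).
#'
#' @param cfg a [simulation_config()].
#' @return Object of class `sim_truth`: `precisions` (list of K), `means`
#'   (K x p), `public_block_mask` (logical, one per block slot),
#'   `true_edges` (list of K logical adjacency matrices), `module_types`
#'   (B x K character matrix of the drawn module kinds).
#' @export
make_precision_set <- function(cfg) {
  p <- cfg$p; K <- cfg$K
  B <- p %/% 10L
  public <- stats::runif(B) < cfg$public_prob
  kinds <- matrix("", B, K)
  precisions <- rep(list(diag(p)), K)
  for (b in seq_len(B)) {
    idx <- ((b - 1L) * 10L + 1L):(b * 10L)
    if (public[b]) {
      kinds[b, ] <- sample(c("Md", "Mc", "Ms"), 1L)
      M <- make_module(kinds[b, 1L])
      for (k in seq_len(K)) precisions[[k]][idx, idx] <- M
    } else {
      for (k in seq_len(K)) {
        kinds[b, k] <- sample(c("Md", "Mc", "Ms", "M0"), 1L)
        precisions[[k]][idx, idx] <- make_module(kinds[b, k])
      }
    }
  }
  for (k in seq_len(K)) {
    ev <- min(eigen(precisions[[k]], symmetric = TRUE,
                    only.values = TRUE)$values)
    if (ev < 0.1) precisions[[k]] <- precisions[[k]] + (0.1 - ev) * diag(p)
  }
  means <- outer(seq_len(K) * cfg$mean_separation, rep(1, p))
  true_edges <- lapply(precisions, function(Om) {
    A <- abs(Om) > 1e-12
    diag(A) <- FALSE
    A
  })
  structure(list(precisions = precisions, means = means,
                 public_block_mask = public, true_edges = true_edges,
                 module_types = kinds, p = p, K = K),
            class = "sim_truth")
}

#' Draw an expression dataset from the ground truth
#'
#' nk samples per subtype from N(mu_k, Omega_k^{-1}); rows are shuffled and
#' the generating labels retained.
#'
#' @param truth a [make_precision_set()] result.
#' @param cfg the matching [simulation_config()].
#' @return List with `data` (an [ajgm_data()]) and `labels` (integer vector of
#'   generating subtypes, aligned with the shuffled rows).
#' @export
sample_dataset <- function(truth, cfg) {
  p <- truth$p; K <- truth$K; nk <- cfg$nk
  X <- matrix(0, K * nk, p)
  labels <- rep(seq_len(K), each = nk)
  for (k in seq_len(K)) {
    R <- chol(truth$precisions[[k]])
    Zr <- matrix(stats::rnorm(nk * p), p, nk)
    # x = mu + R^{-1} z has precision R'R = Omega_k
    X[labels == k, ] <- t(backsolve(R, Zr) + truth$means[k, ])
  }
  ord <- sample.int(K * nk)
  list(data = ajgm_data(X[ord, , drop = FALSE]), labels = labels[ord])
}

#' Apply dropout-style zero inflation
#'
#' Each entry is independently set to exact zero with probability
#' `exp(-alpha * x)` (method `"exp"`) or `1 - beta * x` (method `"linear"`),
#' clamped to [0, 1]; both probabilities decrease with the expression value,
#' mimicking the preferential dropout of lowly expressed genes. The zero mask
#' records the new zeros (on top of any existing mask).
#'
#' @param X an [ajgm_data()].
#' @param method `"exp"` or `"linear"`.
#' @param param the positive rate parameter (alpha or beta).
#' @return A new [ajgm_data()] with zeros written and the mask updated.
#' @export
zero_inflate <- function(X, method = c("exp", "linear"), param) {
  method <- match.arg(method)
  if (param <= 0) stop("param must be positive")
  V <- X$values
  pr <- if (method == "exp") exp(-param * V) else 1 - param * V
  pr <- pmin(pmax(pr, 0), 1)
  hit <- matrix(stats::runif(length(V)) < pr, nrow(V))
  V[hit] <- 0
  ajgm_data(V, X$sample_ids, X$gene_ids, X$zero_mask | hit)
}

#' Generate a complete simulated benchmark dataset
#'
#' Convenience wrapper running [make_precision_set()] and [sample_dataset()]
#' (and optionally [zero_inflate()]) under the configured seed.
#'
#' @param cfg a [simulation_config()].
#' @param zero_method optional `"exp"` or `"linear"` to add zero inflation.
#' @param zero_param rate parameter for zero inflation.
#' @return List with `data`, `labels`, `truth`, and (when zero-inflated)
#'   `data_clean`, the pre-inflation dataset.
#' @export
simulate_ajgm_data <- function(cfg, zero_method = NULL, zero_param = NULL) {
  .with_local_seed(cfg$seed, {
    truth <- make_precision_set(cfg)
    ds <- sample_dataset(truth, cfg)
    out <- list(data = ds$data, labels = ds$labels, truth = truth)
    if (!is.null(zero_method)) {
      out$data_clean <- ds$data
      out$data <- zero_inflate(ds$data, zero_method, zero_param)
    }
    out
  })
}

#' Calibrate the exponential dropout rate to a target zero fraction
#'
#' Solves for alpha such that the expected fraction of zeroed entries under
#' `p = exp(-alpha x)` matches `target` on the given data, by bisection on the
#' monotone map alpha -> mean(exp(-alpha x)).
#'
#' @param X an [ajgm_data()].
#' @param target desired zero fraction in (0, 1).
#' @return The calibrated alpha.
#' @export
calibrate_dropout <- function(X, target = 0.3) {
  stopifnot(target > 0, target < 1)
  f <- function(a) mean(pmin(pmax(exp(-a * X$values), 0), 1)) - target
  stats::uniroot(f, c(1e-6, 50), extendInt = "downX")$root
}
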