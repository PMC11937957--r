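# Run expr with a locally-seeded RNG stream, restoring the caller's stream.
.with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' E-step: posterior subtype responsibilities
#'
#' Computes, in log space, the posterior probability that each sample belongs
#' to each subtype given the current parameters. Samples whose density
#' underflows in every component are assigned uniform responsibilities with a
#' warning.
#'
#' @param X an [ajgm_data()].
#' @param params a [mixture_params()].
#' @return A [responsibilities()] matrix (n x K).
#' @export
e_step <- function(X, params) {
  ld <- .component_logdens(X$values, params)
  lse <- .logsumexp_rows(ld)
  bad <- !is.finite(lse)
  Z <- exp(ld - ifelse(bad, 0, lse))
  if (any(bad)) {
    warning(sum(bad), " sample(s) underflowed in every component; ",
            "assigned uniform responsibilities")
    Z[bad, ] <- 1 / ncol(Z)
  }
  Z <- Z / rowSums(Z)
  responsibilities(Z)
}

#' M-step: closed-form moment updates
#'
#' Given responsibilities, computes the subtype proportions, the
#' responsibility-weighted means and scatter matrices, and the overall-sample
#' mean and scatter:
#' mu_k = sum_l Z_lk x_l / sum_l Z_lk, pi_k = (1/n) sum_l Z_lk,
#' S_k = sum_l Z_lk (x_l - mu_k)(x_l - mu_k)' / sum_l Z_lk, with the overall
#' block using the plain mean and covariance of X'.
#'
#' @param X an [ajgm_data()].
#' @param Xp an [overall_samples()].
#' @param Z a [responsibilities()] matrix.
#' @return List with `proportions`, `means` (K x p), `overall_mean`, and
#'   `stats` (a [weighted_stats()] with K+1 entries, overall last).
#' @export
m_step_moments <- function(X, Xp, Z) {
  V <- X$values
  n <- nrow(V); p <- ncol(V); K <- ncol(Z)
  nk <- colSums(Z)
  if (any(nk < 2))
    stop("a mixture component has effective size < 2; consider a smaller K")
  means <- matrix(0, K, p)
  scatter <- vector("list", K + 1L)
  for (k in seq_len(K)) {
    means[k, ] <- colSums(Z[, k] * V) / nk[k]
    Vc <- sweep(V, 2L, means[k, ])
    S <- crossprod(Vc, Z[, k] * Vc) / nk[k]
    scatter[[k]] <- (S + t(S)) / 2
  }
  m <- nrow(Xp$values)
  overall_mean <- colMeans(Xp$values)
  Xc <- sweep(Xp$values, 2L, overall_mean)
  SX <- crossprod(Xc) / m
  scatter[[K + 1L]] <- (SX + t(SX)) / 2
  list(proportions = nk / n, means = means, overall_mean = overall_mean,
       stats = weighted_stats(scatter, c(nk, m)))
}

#' Refresh the adaptive weights from current precision estimates
#'
#' Entrywise evaluation of the fusion weights w = 1/|difference|^gamma
#' (clamped) for every adjacent subtype pair and for the last subtype vs the
#' overall network, plus the consensus multipliers f (1 where all adjacent
#' subtype differences fall below `tre`, lambda2/lambda3 elsewhere).
#'
#' @param params a [mixture_params()].
#' @param cfg a [penalty_config()].
#' @return An [adaptive_weights()] object.
#' @export
refresh_weights <- function(params, cfg) {
  K <- length(params$proportions)
  p <- ncol(params$means)
  sub <- list()
  if (K >= 2L)
    sub <- lapply(seq_len(K - 1L), function(k)
      adaptive_weight(params$precisions[[k]], params$precisions[[k + 1L]],
                      cfg$gamma, cfg))
  ov <- adaptive_weight(params$precisions[[K]], params$overall_precision,
                        cfg$gamma, cfg)
  if (K >= 2L) {
    agree <- Reduce(`&`, lapply(seq_len(K - 1L), function(k)
      abs(params$precisions[[k]] - params$precisions[[k + 1L]]) < cfg$tre))
    f <- ifelse(agree, 1, cfg$lambda2 / cfg$lambda3)
  } else {
    f <- matrix(1, p, p)
  }
  adaptive_weights(subtype_fusion = sub, overall_fusion = ov, consensus = f)
}

#' Impute masked zeros by conditional Gaussian sampling
#'
#' For each sample, the subtype is taken as the argmax of its responsibilities;
#' entries flagged in the zero mask are replaced by a draw from the conditional
#' Gaussian of those coordinates given the observed (unmasked) coordinates
#' under N(mu_k, Omega_k^{-1}). With a precision parameterization the
#' conditional is direct: x_A | x_B ~ N(mu_A - Omega_AA^{-1} Omega_AB
#' (x_B - mu_B), Omega_AA^{-1}). Unmasked entries are never touched.
#'
#' @param X an [ajgm_data()] with a zero mask.
#' @param Z a [responsibilities()] matrix.
#' @param params a [mixture_params()].
#' @param rng_seed optional integer; if given, draws are made from a local RNG
#'   stream seeded with it (reproducible and side-effect free). If `NULL`, the
#'   current RNG stream is used.
#' @return A new [ajgm_data()] differing from `X` only at masked positions.
#' @export
impute_zeros <- function(X, Z, params, rng_seed = NULL) {
  .with_local_seed(rng_seed, {
    V <- X$values
    mask <- X$zero_mask
    rows <- which(rowSums(mask) > 0)
    hard <- max.col(Z, ties.method = "first")
    for (l in rows) {
      k <- hard[l]
      mu <- params$means[k, ]
      Om <- params$precisions[[k]]
      A <- which(mask[l, ])
      B <- which(!mask[l, ])
      if (length(B) == 0L) {
        warning("sample ", l, " has all entries masked; drawing from the ",
                "full subtype marginal")
        R <- chol(Om)
        V[l, ] <- mu + backsolve(R, stats::rnorm(length(mu)))
      } else {
        OmAA <- Om[A, A, drop = FALSE]
        shift <- solve(OmAA, Om[A, B, drop = FALSE] %*% (V[l, B] - mu[B]))
        R <- chol(OmAA)
        V[l, A] <- mu[A] - as.numeric(shift) +
          backsolve(R, stats::rnorm(length(A)))
      }
    }
    ajgm_data(V, X$sample_ids, X$gene_ids, mask)
  })
}

#' Construct overall samples from the expression data
#'
#' Two constructions when no dedicated overall samples exist: `identity`
#' reuses X itself as X' (m = n), which keeps all information and is the
#' recommended default; `sampled` fits a single multivariate Gaussian to X
#' (mean and covariance, the latter ridged by 1e-6 I for stability) and draws
#' m synthetic rows from it.
#'
#' @param X an [ajgm_data()].
#' @param mode `"identity"` or `"sampled"`.
#' @param m number of rows to draw in `sampled` mode (>= 2).
#' @param rng_seed optional integer seed for `sampled` mode (local stream).
#' @return An [overall_samples()] object.
#' @export
make_overall <- function(X, mode = c("identity", "sampled"), m = NULL,
                         rng_seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "identity")
    return(overall_samples(X$values, "identity_of_X"))
  if (is.null(m) || m < 2) stop("sampled mode requires m >= 2")
  .with_local_seed(rng_seed, {
    mu <- colMeans(X$values)
    S <- stats::cov(X$values) + 1e-6 * diag(ncol(X$values))
    R <- chol(S)
    Zr <- matrix(stats::rnorm(m * ncol(X$values)), m)
    overall_samples(sweep(Zr %*% R, 2L, mu, `+`), "sampled")
  })
}

#' Fit the adaptive joint graphical model
#'
#' Runs the full EM algorithm: k-means initialization of the means and
#' proportions (precisions start at the identity), then iterates E-step,
#' optional dropout imputation, closed-form moment updates, adaptive-weight
#' refresh, and the ADMM precision update, until the penalized log-likelihood
#' stabilizes. The subtype chain order for the fusion penalty is fixed at
#' initialization by sorting the k-means clusters by the norm of their center
#' and is frozen thereafter, so the objective is well defined across
#' iterations.
#'
#' The first EM iteration is a pilot pass with unit fusion weights (the
#' identity initialization carries no difference information to adapt to);
#' the adaptive weights are then computed once from the pilot precision
#' estimates. Under the default `"pilot"` schedule they stay frozen from then
#' on, so the penalized objective is a fixed function and every recorded step
#' is an exact EM ascent: the objective trace (recorded from the first
#' post-pilot iteration) is non-decreasing whenever imputation is off. The
#' `"refresh"` schedule instead recomputes the weights from the previous
#' iterate at every iteration; the objective then moves between iterations
#' and the trace need not be monotone. With imputation on, the objective is
#' stochastic, so convergence is declared on the parameter trace instead (max
#' relative change of mu, pi and all precisions below `param_tol` for 3
#' consecutive iterations).
#'
#' @param X an [ajgm_data()].
#' @param K number of subtypes (1 <= K <= n).
#' @param Xp optional [overall_samples()]; by default built via
#'   [make_overall()] with `overall_mode`.
#' @param cfg a [penalty_config()].
#' @param admm an [admm_config()].
#' @param max_iter maximum EM iterations.
#' @param tol relative tolerance on the penalized log-likelihood.
#' @param impute impute masked zeros each iteration?
#' @param seed integer seed covering k-means restarts, imputation draws and
#'   `sampled`-mode overall construction.
#' @param overall_mode passed to [make_overall()] when `Xp` is `NULL`.
#' @param m overall sample count for `overall_mode = "sampled"`.
#' @param weight_schedule `"pilot"` (default) computes the adaptive weights
#'   once from the pilot iteration's estimates and freezes them (one-step
#'   adaptive estimator; fixed objective, monotone EM); `"refresh"`
#'   recomputes them from the previous iterate at every EM iteration.
#' @param param_tol parameter-trace tolerance used when `impute = TRUE`.
#' @param nstart k-means restarts.
#' @return An object of class `ajgm_fit`: `params`, `responsibilities`,
#'   `hard_labels`, `objective_trace`, `converged`, `n_iter`, `networks`
#'   (a [call_edges()] network set), plus the configuration used.
#' @export
ajgm_fit <- function(X, K, Xp = NULL, cfg = penalty_config(),
                     admm = admm_config(), max_iter = 100L, tol = 1e-4,
                     impute = FALSE, seed = 1L,
                     overall_mode = c("identity", "sampled"), m = NULL,
                     weight_schedule = c("pilot", "refresh"),
                     param_tol = 1e-3, nstart = 10L) {
  overall_mode <- match.arg(overall_mode)
  weight_schedule <- match.arg(weight_schedule)
  n <- nrow(X$values); p <- ncol(X$values)
  if (K < 1L) stop("K must be >= 1")
  if (K > n) stop("K cannot exceed the number of samples")
  .with_local_seed(seed, {
    if (is.null(Xp)) Xp <- make_overall(X, overall_mode, m)
    if (ncol(Xp$values) != p)
      stop("overall samples must have the same genes as X")

    km <- stats::kmeans(X$values, centers = K, nstart = nstart)
    ord <- order(sqrt(rowSums(km$centers^2)))   # fixes the fusion chain order
    centers <- km$centers[ord, , drop = FALSE]
    sizes <- km$size[ord]
    params <- mixture_params(
      proportions = sizes / n,
      means = centers,
      precisions = rep(list(diag(p)), K),
      overall_mean = colMeans(Xp$values),
      overall_precision = diag(p))

    X_work <- X
    Xp_work <- Xp
    identity_overall <- Xp$source == "identity_of_X"
    trace <- numeric(0)
    warm <- NULL
    weights <- unit_weights(K, p)
    converged <- FALSE
    small_steps <- 0L
    it <- 0L
    # The ADMM objective drops the 1/2 of the Gaussian log-likelihood;
    # doubling the lambdas makes its argmin the exact M-step of the
    # penalized log-likelihood.
    cfg2 <- cfg
    cfg2$lambda1 <- 2 * cfg$lambda1
    cfg2$lambda2 <- 2 * cfg$lambda2
    cfg2$lambda3 <- 2 * cfg$lambda3
    for (it in seq_len(max_iter)) {
      Z <- e_step(X_work, params)
      if (impute && any(X$zero_mask)) {
        X_work <- impute_zeros(X, Z, params)
        if (identity_overall)
          Xp_work <- overall_samples(X_work$values, "identity_of_X")
        Z <- e_step(X_work, params)
      }
      mom <- m_step_moments(X_work, Xp_work, Z)
      if (it == 2L || (it > 2L && weight_schedule == "refresh"))
        weights <- refresh_weights(params, cfg)
      sol <- update_precisions(mom$stats, cfg2, weights, admm, warm = warm)
      warm <- sol$warm
      prev <- params
      params <- mixture_params(
        proportions = mom$proportions,
        means = mom$means,
        precisions = sol$precisions[seq_len(K)],
        overall_mean = mom$overall_mean,
        overall_precision = sol$precisions[[K + 1L]])
      # The pilot (unit-weight) iteration is not part of the recorded trace:
      # from iteration 2 on the objective is evaluated under the adaptive
      # weights actually in force.
      if (it >= 2L)
        trace <- c(trace, penalized_loglik(X_work, Xp_work, params, cfg,
                                           weights))
      if (impute) {
        dpar <- max(
          abs(params$proportions - prev$proportions),
          abs(params$means - prev$means) / (1 + abs(prev$means)),
          max(vapply(seq_len(K), function(k)
            max(abs(params$precisions[[k]] - prev$precisions[[k]])) /
              (1 + max(abs(prev$precisions[[k]]))), numeric(1))),
          max(abs(params$overall_precision - prev$overall_precision)) /
            (1 + max(abs(prev$overall_precision))))
        small_steps <- if (dpar < param_tol) small_steps + 1L else 0L
        if (small_steps >= 3L) { converged <- TRUE; break }
      } else if (length(trace) >= 2L) {
        nt <- length(trace)
        rel <- abs(trace[nt] - trace[nt - 1L]) / (abs(trace[nt - 1L]) + 1e-10)
        if (rel < tol) { converged <- TRUE; break }
      }
    }

    Zfin <- e_step(X_work, params)
    structure(list(params = params,
                   responsibilities = Zfin,
                   hard_labels = max.col(Zfin, ties.method = "first"),
                   objective_trace = trace,
                   converged = converged,
                   n_iter = it,
                   networks = call_edges(params, cfg$edge_threshold),
                   weights = weights,
                   cfg = cfg, admm = admm, seed = seed,
                   imputed_data = if (impute) X_work else NULL),
              class = "ajgm_fit")
  })
}

#' @export
print.ajgm_fit <- function(x, ...) {
  K <- length(x$params$proportions)
  cat(sprintf("<ajgm_fit> K = %d, %s after %d EM iteration(s)\n", K,
              if (x$converged) "converged" else "stopped", x$n_iter))
  cat("  cluster sizes:", paste(tabulate(x$hard_labels, K), collapse = ", "),
      "\n")
  cat("  edges per subtype network:",
      paste(vapply(x$networks$subtype_adjacency,
                   function(A) sum(A[upper.tri(A)]), numeric(1)),
            collapse = ", "), "\n")
  cat("  overall network edges:",
      sum(x$networks$overall_adjacency[upper.tri(x$networks$overall_adjacency)]),
      "\n")
  invisible(x)
}
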