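# Independent oracles used by the tests. These deliberately take different
# algorithmic routes from the package code: a smoothed-objective quasi-Newton
# solve with epsilon-continuation for the penalized precision problem, a
# nested grid search for the chain prox, and direct (non-log) density
# summation for the mixture likelihood.

# Smoothed |x|: sqrt(x^2 + eps^2), with derivative x / sqrt(x^2 + eps^2).
oracle_precisions <- function(stats, cfg, weights,
                              eps_seq = c(1e-2, 1e-4, 1e-6, 1e-8)) {
  L <- length(stats$scatter)
  K <- L - 1L
  p <- nrow(stats$scatter[[1L]])
  iu <- which(upper.tri(diag(p)))
  nv <- p * (p + 1) / 2
  vech_idx <- which(upper.tri(diag(p), diag = TRUE))

  to_mats <- function(par) {
    lapply(seq_len(L), function(c) {
      M <- matrix(0, p, p)
      M[vech_idx] <- par[((c - 1) * nv + 1):(c * nv)]
      M <- M + t(M)
      diag(M) <- diag(M) / 2
      M
    })
  }
  link_w <- function(k) {
    if (k < K) cfg$lambda2 * weights$subtype_fusion[[k]]
    else cfg$lambda3 * weights$consensus * weights$overall_fusion
  }

  make_f <- function(eps) function(par) {
    mats <- to_mats(par)
    tot <- 0
    for (c in seq_len(L)) {
      R <- tryCatch(chol(mats[[c]]), error = function(e) NULL)
      if (is.null(R)) return(1e12)
      tot <- tot + stats$sizes[c] *
        (sum(stats$scatter[[c]] * mats[[c]]) - 2 * sum(log(diag(R))))
    }
    s <- function(x) sqrt(x^2 + eps^2)
    for (c in seq_len(L))
      tot <- tot + cfg$lambda1 * 2 * sum(s(mats[[c]][iu]))
    for (k in seq_len(L - 1L)) {
      d <- mats[[k]] - mats[[k + 1L]]
      tot <- tot + 2 * sum((link_w(k) * s(d))[iu])
    }
    tot
  }
  # Gradient in vech space: one parameter per unordered (i, j). For the
  # symmetric smooth part df/dtheta_ij = 2 G[i,j] off-diagonal and G[i,i] on
  # the diagonal; the penalty (which itself counts each unordered pair twice)
  # contributes 2 lambda ds(.) per off-diagonal parameter and nothing on the
  # diagonal.
  offd <- vech_idx %in% iu
  make_g <- function(eps) function(par) {
    mats <- to_mats(par)
    ds <- function(x) x / sqrt(x^2 + eps^2)
    pen <- vector("list", L)
    for (c in seq_len(L)) pen[[c]] <- 2 * cfg$lambda1 * ds(mats[[c]])
    for (k in seq_len(L - 1L)) {
      d <- 2 * link_w(k) * ds(mats[[k]] - mats[[k + 1L]])
      pen[[k]] <- pen[[k]] + d
      pen[[k + 1L]] <- pen[[k + 1L]] - d
    }
    unlist(lapply(seq_len(L), function(c) {
      G <- stats$sizes[c] * (stats$scatter[[c]] - solve(mats[[c]]))
      v <- G[vech_idx]
      v[offd] <- 2 * v[offd] + pen[[c]][vech_idx][offd]
      v
    }))
  }

  par <- unlist(lapply(stats$scatter, function(S) {
    M <- diag(1 / pmax(diag(S), 1e-8), p)
    M[vech_idx]
  }))
  for (eps in eps_seq) {
    res <- stats::nlminb(par, make_f(eps), make_g(eps),
                         control = list(iter.max = 5000, eval.max = 10000,
                                        rel.tol = 1e-14))
    par <- res$par
  }
  to_mats(par)
}

# Exhaustive nested grid search for the chain prox objective. The grid is
# refined around the incumbent; the objective is convex, so the continuous
# minimizer always stays within the zoom window.
grid_prox_oracle <- function(v, lam1, fw, rho, levels = 9L, pts = NULL) {
  L <- length(v)
  if (is.null(pts)) pts <- c(41L, 41L, 25L, 15L, 11L)[min(L, 5L)]
  obj <- function(zmat) {
    q <- rho / 2 * colSums((zmat - v)^2) + lam1 * colSums(abs(zmat))
    if (L > 1L)
      q <- q + colSums(fw * abs(zmat[-1L, , drop = FALSE] -
                                  zmat[-L, , drop = FALSE]))
    q
  }
  lo <- rep(min(0, v) - 0.05, L)
  hi <- rep(max(0, v) + 0.05, L)
  best <- (lo + hi) / 2
  for (lev in seq_len(levels)) {
    grids <- lapply(seq_len(L), function(c) seq(lo[c], hi[c], length.out = pts))
    Zg <- t(as.matrix(do.call(expand.grid, grids)))
    o <- obj(Zg)
    best <- Zg[, which.min(o)]
    span <- (hi - lo) / (pts - 1)
    lo <- best - 2 * span
    hi <- best + 2 * span
  }
  best
}

# Direct (non-log) mixture density evaluation via covariance matrices.
brute_mixture_density <- function(x, params) {
  K <- length(params$proportions)
  p <- length(x)
  tot <- 0
  for (k in seq_len(K)) {
    Sig <- solve(params$precisions[[k]])
    d <- x - params$means[k, ]
    tot <- tot + params$proportions[k] *
      (2 * pi)^(-p / 2) * det(Sig)^(-1 / 2) *
      exp(-0.5 * sum(d * solve(Sig, d)))
  }
  log(tot)
}

# Random symmetric positive-definite matrix with unit-scale diagonal.
random_spd <- function(p) {
  A <- matrix(stats::rnorm(p * p), p)
  S <- crossprod(A) / p + diag(p) * 0.5
  (S + t(S)) / 2
}

# Random small weighted_stats fixture for solver tests.
random_stats <- function(K, p, n_lo = 20, n_hi = 60) {
  scatter <- replicate(K + 1L, random_spd(p), simplify = FALSE)
  sizes <- stats::runif(K + 1L, n_lo, n_hi)
  weighted_stats(scatter, sizes)
}

# Random adaptive weights in [0.2, 2] with consensus in {1, lambda2/lambda3}.
random_weights <- function(K, p, cfg) {
  rw <- function() {
    W <- matrix(stats::runif(p * p, 0.2, 2), p)
    (W + t(W)) / 2
  }
  cons <- matrix(sample(c(1, cfg$lambda2 / cfg$lambda3), p * p, TRUE), p)
  cons <- (cons + t(cons)) / 2
  cons[] <- ifelse(cons > (1 + cfg$lambda2 / cfg$lambda3) / 2, 1,
                   cfg$lambda2 / cfg$lambda3)
  adaptive_weights(
    subtype_fusion = replicate(max(K - 1L, 0L), rw(), simplify = FALSE),
    overall_fusion = rw(),
    consensus = cons)
}
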