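#' ADMM solver configuration
#'
#' @param rho positive augmented-Lagrangian parameter (default 1; the solver
#'   internally normalizes the objective by the total effective sample size, so
#'   rho = 1 is well scaled across problem sizes).
#' @param max_iter maximum number of ADMM iterations.
#' @param tol_primal,tol_dual relative stopping tolerances on the primal and
#'   dual residual norms.
#' @return Object of class `admm_config`.
#' @export
admm_config <- function(rho = 1, max_iter = 500L, tol_primal = 1e-5,
                        tol_dual = 1e-5) {
  stopifnot(rho > 0, max_iter > 0, tol_primal > 0, tol_dual > 0)
  structure(list(rho = rho, max_iter = as.integer(max_iter),
                 tol_primal = tol_primal, tol_dual = tol_dual),
            class = "admm_config")
}

#' Responsibility-weighted sample statistics
#'
#' The sufficient statistics of the M-step: the K responsibility-weighted
#' scatter (covariance) matrices, the overall-sample covariance, and the
#' effective sample sizes (n_k = sum of responsibilities for subtype k; m for
#' the overall block).
#'
#' @param scatter list of K+1 symmetric p x p matrices, overall last.
#' @param sizes numeric vector of K+1 positive effective sizes.
#' @return Object of class `weighted_stats`.
#' @export
weighted_stats <- function(scatter, sizes) {
  stopifnot(is.list(scatter), length(scatter) == length(sizes),
            all(sizes > 0))
  for (S in scatter)
    if (max(abs(S - t(S))) > 1e-8) stop("scatter matrix not symmetric")
  structure(list(scatter = scatter, sizes = as.numeric(sizes)),
            class = "weighted_stats")
}

# Sign patterns for the exact chain prox, memoized by chain length. Each of
# the 3^(L-1) patterns fixes the sign (-1, 0, +1) of every adjacent difference;
# zeros merge neighbours into groups. The optimum of the chain fused lasso is
# the stationary point of one of these patterns, so evaluating the true
# objective at every pattern's stationary candidate and taking the minimum is
# exact.
.ajgm_env <- new.env(parent = emptyenv())

.chain_patterns <- function(L) {
  key <- as.character(L)
  if (!is.null(.ajgm_env[[key]])) return(.ajgm_env[[key]])
  if (L > 8L)
    stop("fused chain prox supports at most 8 matrices in the chain (K <= 7)")
  signs <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), L - 1L)))
  pats <- lapply(seq_len(nrow(signs)), function(r) {
    s <- signs[r, ]
    grp <- cumsum(c(1, s != 0))
    G <- max(grp)
    Agg <- matrix(0, G, L)
    Agg[cbind(grp, seq_len(L))] <- 1
    bnd <- which(s != 0)
    list(grp = grp, sizes = tabulate(grp, nbins = G), Agg = Agg,
         bnd = bnd, bnd_sign = s[bnd],
         bnd_left = grp[bnd], bnd_right = grp[bnd + 1L])
  })
  .ajgm_env[[key]] <- pats
  pats
}

# Exact prox for many entries at once. V is L x M (each column one (i,j)
# entry's chain of values), FW is (L-1) x M of absolute fusion weights.
# Minimizes, per column, (rho/2) sum (z - v)^2 + lam1 sum |z| +
# sum_c FW[c] |z_c - z_{c+1}|. The fused part is solved first (pattern
# enumeration), then each coordinate is soft-thresholded by lam1/rho, which is
# exact for the chain topology.
.fused_chain_prox_mat <- function(V, lam1, FW, rho) {
  L <- nrow(V); M <- ncol(V)
  a <- lam1 / rho
  if (L == 1L) return(sign(V) * pmax(abs(V) - a, 0))
  T_ <- FW / rho
  if (!is.matrix(T_)) T_ <- matrix(T_, L - 1L, M)
  pats <- .chain_patterns(L)
  best_obj <- rep(Inf, M)
  best_Z <- V
  for (pt in pats) {
    SV <- pt$Agg %*% V                       # G x M group sums
    C <- matrix(0, nrow(SV), M)
    for (b in seq_along(pt$bnd)) {
      tb <- pt$bnd_sign[b] * T_[pt$bnd[b], ]
      C[pt$bnd_left[b], ] <- C[pt$bnd_left[b], ] + tb
      C[pt$bnd_right[b], ] <- C[pt$bnd_right[b], ] - tb
    }
    U <- (SV - C) / pt$sizes
    Z <- U[pt$grp, , drop = FALSE]           # L x M candidate
    R <- Z - V
    obj <- 0.5 * colSums(R * R) +
      colSums(T_ * abs(Z[-1L, , drop = FALSE] - Z[-L, , drop = FALSE]))
    upd <- obj < best_obj
    if (any(upd)) {
      best_Z[, upd] <- Z[, upd]
      best_obj[upd] <- obj[upd]
    }
  }
  sign(best_Z) * pmax(abs(best_Z) - a, 0)
}

#' Entrywise proximal operator of the chain fused penalty
#'
#' For one matrix entry (i, j), solves exactly
#' \deqn{\mathrm{argmin}_z \; (\rho/2) \sum_c (z_c - v_c)^2
#'   + \lambda_1 \sum_c |z_c| + \sum_c t_c |z_c - z_{c+1}|}
#' over the chain of K+1 values (subtype 1..K, then overall). The fused part is
#' solved by exact sign-pattern enumeration over the chain, after which
#' soft-thresholding by `lam1 / rho` gives the joint solution (the chain graph
#' admits this two-stage decomposition).
#'
#' @param values numeric vector of the K+1 chain values.
#' @param lam1 non-negative L1 penalty.
#' @param fusion_weights numeric vector of K absolute fusion weights
#'   (`lambda2 * w` for adjacent subtype links, `lambda3 * f * w` for the last
#'   link to the overall network).
#' @param rho positive quadratic coefficient.
#' @return Numeric vector of the same length as `values`.
#' @export
fused_chain_prox <- function(values, lam1, fusion_weights, rho) {
  L <- length(values)
  if (L >= 2L && length(fusion_weights) != L - 1L)
    stop("need exactly length(values) - 1 fusion weights")
  as.numeric(.fused_chain_prox_mat(matrix(values, ncol = 1L), lam1,
                                   matrix(fusion_weights, ncol = 1L), rho))
}

#' Penalized precision objective
#'
#' The criterion minimized by [update_precisions()]:
#' \deqn{\sum_k n_k (\mathrm{tr}(S_k \Omega_k) - \log\det \Omega_k)
#'   + m (\mathrm{tr}(S_X \Omega_X) - \log\det \Omega_X) + P(\Theta)}
#' with P the adaptive fused penalty restricted to the precision matrices.
#'
#' @param precisions list of K+1 precision matrices, overall last.
#' @param stats a [weighted_stats()].
#' @param cfg a [penalty_config()].
#' @param weights an [adaptive_weights()].
#' @return A single number.
#' @export
precision_objective <- function(precisions, stats, cfg, weights) {
  L <- length(precisions)
  sm <- 0
  for (c in seq_len(L)) {
    Om <- precisions[[c]]
    ld <- determinant(Om, logarithm = TRUE)
    if (ld$sign <= 0) return(Inf)
    sm <- sm + stats$sizes[c] *
      (sum(stats$scatter[[c]] * Om) - as.numeric(ld$modulus))
  }
  K <- L - 1L
  p <- nrow(precisions[[1L]])
  off <- !diag(TRUE, p)
  l1 <- sum(vapply(precisions, function(Om) sum(abs(Om[off])), numeric(1)))
  fus <- 0
  if (K >= 2L) {
    for (k in seq_len(K - 1L)) {
      d <- precisions[[k]] - precisions[[k + 1L]]
      fus <- fus + sum((weights$subtype_fusion[[k]] * abs(d))[off])
    }
  }
  dX <- precisions[[K]] - precisions[[L]]
  ov <- sum((weights$consensus * weights$overall_fusion * abs(dX))[off])
  sm + cfg$lambda1 * l1 + cfg$lambda2 * fus + cfg$lambda3 * ov
}

#' M-step precision update by ADMM
#'
#' Jointly minimizes [precision_objective()] over the K subtype precision
#' matrices and the overall precision, using consensus ADMM: each matrix gets a
#' sparse copy Z and a scaled dual U; the Omega-subproblem is solved in closed
#' form by eigendecomposition (which keeps every iterate positive definite),
#' and the Z-subproblem decouples over matrix entries into the exact chain
#' prox of [fused_chain_prox()]. Diagonal entries bypass all penalties.
#'
#' @param stats a [weighted_stats()] with K+1 scatter matrices (overall last).
#' @param cfg a [penalty_config()].
#' @param weights an [adaptive_weights()] for K subtypes.
#' @param admm an [admm_config()].
#' @param warm optional warm start, the `warm` element of a previous result.
#' @return A list of class `admm_result`: `precisions` (K+1 symmetric positive
#'   definite matrices with exact zeros from the sparse copies), `converged`,
#'   `iterations`, `objective`, and `warm` for restarts.
#' @export
update_precisions <- function(stats, cfg, weights, admm = admm_config(),
                              warm = NULL) {
  L <- length(stats$scatter)
  K <- L - 1L
  p <- nrow(stats$scatter[[1L]])
  if (cfg$lambda1 == 0) {
    for (S in stats$scatter) {
      ev <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
      if (ev < 1e-10)
        stop("singular scatter matrix with lambda1 = 0; set lambda1 > 0")
    }
  }
  # Normalize by the total effective size so entries and rho are O(1)
  # regardless of n; the minimizer is unchanged.
  N <- sum(stats$sizes)
  w_n <- stats$sizes / N
  lam1 <- cfg$lambda1 / N
  rho <- admm$rho
  iu <- which(upper.tri(matrix(0, p, p)))
  M <- length(iu)
  FW <- matrix(0, max(L - 1L, 1L), M)
  if (K >= 2L)
    for (k in seq_len(K - 1L))
      FW[k, ] <- cfg$lambda2 * weights$subtype_fusion[[k]][iu] / N
  FW[L - 1L, ] <- cfg$lambda3 *
    (weights$consensus * weights$overall_fusion)[iu] / N

  Omega <- vector("list", L)
  if (is.null(warm)) {
    Z <- lapply(stats$scatter, function(S) diag(1 / pmax(diag(S), 1e-8), p))
    U <- rep(list(matrix(0, p, p)), L)
  } else {
    Z <- warm$Z
    U <- warm$U
  }

  converged <- FALSE
  it <- 0L
  for (it in seq_len(admm$max_iter)) {
    Vmat <- matrix(0, L, M)
    for (c in seq_len(L)) {
      A <- rho * (Z[[c]] - U[[c]]) - w_n[c] * stats$scatter[[c]]
      A <- (A + t(A)) / 2
      ee <- eigen(A, symmetric = TRUE)
      om <- (ee$values + sqrt(ee$values^2 + 4 * rho * w_n[c])) / (2 * rho)
      Omega[[c]] <- ee$vectors %*% (om * t(ee$vectors))
      Omega[[c]] <- (Omega[[c]] + t(Omega[[c]])) / 2
      Vmat[c, ] <- (Omega[[c]] + U[[c]])[iu]
    }
    Znew_ut <- .fused_chain_prox_mat(Vmat, lam1, FW, rho)
    r2 <- 0; s2 <- 0; nO <- 0; nZ <- 0; nU <- 0
    for (c in seq_len(L)) {
      Zc <- matrix(0, p, p)
      Zc[iu] <- Znew_ut[c, ]
      Zc <- Zc + t(Zc)
      diag(Zc) <- diag(Omega[[c]]) + diag(U[[c]])
      s2 <- s2 + sum((Zc - Z[[c]])^2)
      Z[[c]] <- Zc
      U[[c]] <- U[[c]] + Omega[[c]] - Zc
      r2 <- r2 + sum((Omega[[c]] - Zc)^2)
      nO <- nO + sum(Omega[[c]]^2); nZ <- nZ + sum(Zc^2); nU <- nU + sum(U[[c]]^2)
    }
    if (sqrt(r2) <= admm$tol_primal * max(1, sqrt(nO), sqrt(nZ)) &&
        rho * sqrt(s2) <= admm$tol_dual * max(1, rho * sqrt(nU))) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("ADMM reached max_iter = ", admm$max_iter,
            " without meeting tolerances; returning current iterate")

  precisions <- vector("list", L)
  for (c in seq_len(L)) {
    P <- (Z[[c]] + t(Z[[c]])) / 2
    ev <- min(eigen(P, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 1e-10) diag(P) <- diag(P) + (1e-10 - ev) + 1e-12
    precisions[[c]] <- P
  }
  structure(list(precisions = precisions, converged = converged,
                 iterations = it,
                 objective = precision_objective(precisions, stats, cfg,
                                                weights),
                 warm = list(Z = Z, U = U)),
            class = "admm_result")
}
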