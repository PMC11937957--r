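#' BIC of a fitted model
#'
#' BIC = -2 * (unpenalized log-likelihood at the fitted parameters)
#' + log(n + m) * df, where the degrees of freedom count, for every unordered
#' gene pair, the number of *distinct* nonzero values among the K+1 fitted
#' precision entries (entries fused to equality by the penalty are counted
#' once), plus (K+1) * p allowances for diagonals/means and K-1 free mixture
#' proportions. Lower is better.
#'
#' @param fit an [ajgm_fit()] result.
#' @param X the [ajgm_data()] it was fitted to.
#' @param Xp the [overall_samples()] used.
#' @return A single number.
#' @export
ajgm_bic <- function(fit, X, Xp) {
  params <- fit$params
  K <- length(params$proportions)
  p <- ncol(params$means)
  ll <- loglik(X, Xp, params)
  mats <- c(params$precisions, list(params$overall_precision))
  iu <- upper.tri(mats[[1L]])
  vals <- vapply(mats, function(Om) Om[iu], numeric(sum(iu)))
  df_edges <- sum(apply(vals, 1L, function(v) {
    v <- v[abs(v) > 1e-12]
    length(unique(signif(v, 10)))
  }))
  df <- df_edges + (K + 1L) * p + (K - 1L)
  -2 * ll + log(nrow(X$values) + nrow(Xp$values)) * df
}

#' Selection grid
#'
#' Grids for the iterative subtype-count / penalty search. Every
#' (lambda2, lambda3) combination explored must satisfy lambda3 > lambda2;
#' offending pairs are skipped.
#'
#' @param K_grid integer candidates for the number of subtypes.
#' @param lambda1_grid,lambda2_grid,lambda3_grid,gamma_grid,tre_grid numeric
#'   candidate values (a length-1 grid pins the parameter).
#' @param max_rounds maximum alternations between the K search and the
#'   penalty search.
#' @return Object of class `selection_grid`.
#' @export
selection_grid <- function(K_grid = 1:4, lambda1_grid = NULL,
                           lambda2_grid = NULL, lambda3_grid = NULL,
                           gamma_grid = NULL, tre_grid = NULL,
                           max_rounds = 3L) {
  if (length(K_grid) == 0L) stop("K_grid must be non-empty")
  structure(list(K_grid = sort(unique(as.integer(K_grid))),
                 lambda1_grid = lambda1_grid, lambda2_grid = lambda2_grid,
                 lambda3_grid = lambda3_grid, gamma_grid = gamma_grid,
                 tre_grid = tre_grid, max_rounds = as.integer(max_rounds)),
            class = "selection_grid")
}

#' Iterative BIC model search
#'
#' Alternates (a) choosing K by BIC over `K_grid` with the penalty parameters
#' held fixed, and (b) one coordinate-descent sweep over the supplied penalty
#' grids with K held fixed, until K is unchanged between rounds or
#' `max_rounds` is reached. Ties are broken toward smaller K, then toward
#' smaller parameter values (parsimony). Fits that fail for a candidate are
#' dropped with a warning; if every candidate K fails, an error is raised.
#'
#' @param X an [ajgm_data()].
#' @param grid a [selection_grid()].
#' @param base_cfg starting [penalty_config()].
#' @param admm an [admm_config()].
#' @param rng_seed seed forwarded to every fit.
#' @param ... further arguments to [ajgm_fit()] (e.g. `max_iter`, `impute`).
#' @return List: `best_K`, `best_cfg`, `fit` (the winning [ajgm_fit()]),
#'   `bic_table` (data.frame of every evaluated configuration).
#' @export
select_model <- function(X, grid, base_cfg = penalty_config(),
                         admm = admm_config(), rng_seed = 1L, ...) {
  Xp <- make_overall(X, "identity")
  cfg <- base_cfg
  records <- list()
  fit_one <- function(K, cfg) {
    tryCatch({
      f <- ajgm_fit(X, K, Xp = Xp, cfg = cfg, admm = admm, seed = rng_seed,
                    ...)
      list(fit = f, bic = ajgm_bic(f, X, Xp))
    }, error = function(e) {
      warning("fit failed for K = ", K, ": ", conditionMessage(e))
      NULL
    })
  }
  best_K <- NA_integer_
  best <- NULL
  for (round in seq_len(grid$max_rounds)) {
    # (a) K search at the current penalty configuration
    K_best <- NA_integer_; K_bic <- Inf; K_fit <- NULL
    for (K in grid$K_grid) {
      r <- fit_one(K, cfg)
      if (is.null(r)) next
      records[[length(records) + 1L]] <-
        data.frame(round = round, K = K, lambda1 = cfg$lambda1,
                   lambda2 = cfg$lambda2, lambda3 = cfg$lambda3,
                   gamma = cfg$gamma, tre = cfg$tre, bic = r$bic)
      if (r$bic < K_bic - 1e-9) { K_bic <- r$bic; K_best <- K; K_fit <- r$fit }
    }
    if (is.na(K_best)) stop("model selection failed for every candidate K")
    best <- list(fit = K_fit, bic = K_bic)
    # (b) one coordinate-descent sweep over the penalty grids at fixed K
    sweep_par <- function(name, grid_vals, cfg, best) {
      if (is.null(grid_vals)) return(list(cfg = cfg, best = best))
      for (v in sort(grid_vals)) {
        cand <- cfg
        cand[[name]] <- v
        if (cand$lambda3 <= cand$lambda2) next
        if (abs(cand[[name]] - cfg[[name]]) < 1e-12) next
        r <- fit_one(K_best, cand)
        if (is.null(r)) next
        records[[length(records) + 1L]] <<-
          data.frame(round = round, K = K_best, lambda1 = cand$lambda1,
                     lambda2 = cand$lambda2, lambda3 = cand$lambda3,
                     gamma = cand$gamma, tre = cand$tre, bic = r$bic)
        if (r$bic < best$bic - 1e-9) {
          best <- r
          cfg <- cand
        }
      }
      list(cfg = cfg, best = best)
    }
    for (nm in c("lambda1", "lambda2", "lambda3", "gamma", "tre")) {
      res <- sweep_par(nm, grid[[paste0(nm, "_grid")]], cfg, best)
      cfg <- res$cfg
      best <- res$best
    }
    if (!is.na(best_K) && best_K == K_best) { best_K <- K_best; break }
    best_K <- K_best
  }
  list(best_K = best_K, best_cfg = cfg, fit = best$fit,
       bic_table = do.call(rbind, records))
}
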