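# Small in-code fixtures shared across test files.

# Random valid mixture parameters.
toy_params <- function(K = 2L, p = 3L, seed = 1L) {
  withr::with_seed(seed, {
    mixture_params(
      proportions = {
        w <- stats::runif(K) + 0.2
        w / sum(w)
      },
      means = matrix(stats::rnorm(K * p), K, p),
      precisions = replicate(K, random_spd(p), simplify = FALSE),
      overall_mean = stats::rnorm(p),
      overall_precision = random_spd(p))
  })
}

# Two well-separated Gaussian clusters (identity covariance).
two_cluster_data <- function(n_per = 50L, p = 5L, sep = 5, seed = 1L) {
  withr::with_seed(seed, {
    X <- rbind(matrix(stats::rnorm(n_per * p), n_per, p),
               matrix(stats::rnorm(n_per * p, mean = sep), n_per, p))
    ord <- sample.int(2L * n_per)
    list(data = ajgm_data(X[ord, ]),
         labels = rep(1:2, each = n_per)[ord])
  })
}

# Small random expression fixture with no structure.
random_data <- function(n = 30L, p = 4L, seed = 1L) {
  withr::with_seed(seed, ajgm_data(matrix(stats::rnorm(n * p), n, p)))
}
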