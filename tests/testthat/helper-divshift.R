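# Shared fixture builders (all data generated in code).

# Minimal hand-built observation table with full factor coverage.
toy_table <- function(n = 12, seed = 1) {
  set.seed(seed)
  data.frame(
    species_id = sprintf("sp%02d", rep(seq_len(ceiling(n / 2)), length.out = n)),
    class_id = rep(c("A", "B"), length.out = n),
    position = rep(c("centroid", "leading", "trailing"), length.out = n),
    shift_velocity_signed = rlnorm(n),
    isotherm_velocity_signed = rlnorm(n),
    genetic_diversity = rep(rlnorm(ceiling(n / 2), log(0.006), 0.5),
                            length.out = n),
    log_n_periods = rnorm(n, log(5), 0.3),
    grain_size = rep(c("small", "moderate", "large", "very_large"),
                     length.out = n),
    data_type = rep(c("occurrence", "abundance"), length.out = n),
    sampling_design = rep(c("balanced", "raw", "resurvey"), length.out = n),
    log_study_extent = rnorm(n, log(1000), 1),
    latitude = rnorm(n, 45, 10),
    stringsAsFactors = FALSE)
}

# Small preprocessed synthetic dataset for model-level tests.
small_prep <- function(seed = 5, n_species = 300, ...) {
  cfg <- simulation_config(seed = seed, n_species = n_species, ...)
  preprocess_table(generate_dataset(cfg))
}

# Independent brute-force marginal log-likelihood: dense Simpson-rule
# integration of the weighted Gamma likelihood over the class random
# intercept, written without reference to the package internals.
bruteforce_loglik <- function(design, weights, beta, class_sd, shape) {
  w <- weights * length(weights) / sum(weights)
  eta <- drop(design$X %*% beta)
  lim <- 10 * class_sd + 3
  u <- seq(-lim, lim, length.out = 20001)
  h <- u[2] - u[1]
  simp <- c(1, rep(c(4, 2), length.out = length(u) - 2), 1) * h / 3
  total <- 0
  for (cl in levels(design$group)) {
    i <- design$group == cl
    lf <- vapply(u, function(uu) {
      sum(w[i] * stats::dgamma(design$y[i], shape = shape,
                               scale = exp(eta[i] + uu) / shape,
                               log = TRUE)) +
        stats::dnorm(uu, 0, class_sd, log = TRUE)
    }, 0)
    m <- max(lf)
    total <- total + m + log(sum(simp * exp(lf - m)))
  }
  total
}
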