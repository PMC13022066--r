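#' Generate a synthetic range-shift observation table
#'
#' Draws a table with the statistical structure the downstream analysis
#' assumes. Species-level quantities (taxonomic class, nucleotide
#' diversity) are drawn once per species and broadcast to all of that
#' species' rows; per-row quantities (range position, isotherm velocity,
#' methodological covariates) are drawn independently per observation,
#' since the original studies differ per estimate. The absolute shift
#' velocity is Gamma with shape `nu` and mean `exp(eta)`, where `eta`
#' combines the true coefficients applied to sample-standardised GD and
#' |VIS|, the position/method covariates, the class random intercept,
#' and (optionally) a planted latitude effect. Signs are then assigned
#' so that exactly `round(n * discordant_fraction)` rows shift against
#' the isotherm direction.
#'
#' @param config A [simulation_config()].
#' @param seed Optional integer overriding `config$seed`.
#' @return A `data.frame` (one row per range-shift estimate) with the
#'   observation-table columns; the generating truth (linear predictor,
#'   class intercepts, coefficients, standardisation) is attached as
#'   `attr(, "truth")`.
#' @export
generate_dataset <- function(config, seed = NULL) {
  stopifnot(inherits(config, "divshift_config"))
  set.seed(if (is.null(seed)) config$seed else as.integer(seed))

  n_sp <- config$n_species
  sp_class <- sample.int(config$n_classes, n_sp, replace = TRUE,
                         prob = config$class_probs)
  gd_sp <- stats::rlnorm(n_sp, config$gd_distribution$meanlog,
                         config$gd_distribution$sdlog)
  u_class <- stats::rnorm(config$n_classes, 0, config$class_sd)

  m <- config$obs_per_species$mean
  if (m <= 1) stop("mean observations per species must exceed 1")
  if (!identical(config$obs_per_species$dist, "geometric"))
    stop("unsupported obs_per_species distribution: ",
         config$obs_per_species$dist)
  n_obs <- 1L + stats::rgeom(n_sp, prob = 1 / m)

  idx <- rep.int(seq_len(n_sp), n_obs)
  n <- length(idx)
  if (n == 0L) stop("empty species set")

  position <- sample(c("centroid", "leading", "trailing"), n,
                     replace = TRUE, prob = config$position_probs)
  vis_abs <- stats::rlnorm(n, config$vis_distribution$meanlog,
                           config$vis_distribution$sdlog)
  vis_sign <- ifelse(stats::runif(n) < config$poleward_prob, 1, -1)

  mcs <- config$method_covariate_specs
  lnp <- stats::rnorm(n, mcs$log_n_periods$mean, mcs$log_n_periods$sd)
  lnp <- pmin(pmax(lnp, mcs$log_n_periods$min), mcs$log_n_periods$max)
  grain <- sample(grain_levels, n, replace = TRUE, prob = mcs$grain_probs)
  dty <- sample(c("occurrence", "abundance"), n, replace = TRUE,
                prob = mcs$data_type_probs)
  sdes <- sample(c("balanced", "raw", "resurvey"), n, replace = TRUE,
                 prob = mcs$sampling_design_probs)
  lsae <- stats::rnorm(n, mcs$log_study_extent$mean, mcs$log_study_extent$sd)

  lat <- config$latitude$mean + config$latitude$vis_coef * (vis_abs - mean(vis_abs)) +
    stats::rnorm(n, 0, config$latitude$sd)

  gd <- gd_sp[idx]
  gd_z <- as.numeric(scale(gd))
  vis_z <- as.numeric(scale(vis_abs))
  lat_z <- as.numeric(scale(lat))

  tab <- data.frame(species_id = sprintf("sp%04d", idx),
                    class_id = sprintf("class%d", sp_class[idx]),
                    position = position,
                    gd_z = gd_z, vis_z = vis_z,
                    log_n_periods = lnp,
                    grain_size = grain,
                    data_type = dty,
                    sampling_design = sdes,
                    log_study_extent = lsae,
                    stringsAsFactors = FALSE)
  beta <- structure(numeric(length(coef_names())), names = coef_names())
  beta[names(config$true_coefficients)] <- config$true_coefficients
  eta <- drop(fixed_matrix(tab, formula_spec()) %*% beta) +
    u_class[sp_class[idx]] + config$latitude$effect * lat_z

  shift_abs <- stats::rgamma(n, shape = config$gamma_shape,
                             scale = exp(eta) / config$gamma_shape)

  n_disc <- round(n * config$discordant_fraction)
  discordant <- logical(n)
  if (n_disc > 0) discordant[sample.int(n, n_disc)] <- TRUE
  shift_sign <- ifelse(discordant, -vis_sign, vis_sign)

  out <- data.frame(species_id = tab$species_id,
                    class_id = tab$class_id,
                    position = position,
                    shift_velocity_signed = shift_abs * shift_sign,
                    isotherm_velocity_signed = vis_abs * vis_sign,
                    genetic_diversity = gd,
                    log_n_periods = lnp,
                    grain_size = grain,
                    data_type = dty,
                    sampling_design = sdes,
                    log_study_extent = lsae,
                    latitude = lat,
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- list(
    eta = eta,
    class_intercepts = structure(u_class,
                                 names = sprintf("class%d", seq_len(config$n_classes))),
    coefficients = beta,
    gamma_shape = config$gamma_shape,
    scaling = data.frame(covariate = c("gd", "vis"),
                         mean = c(mean(gd), mean(vis_abs)),
                         sd = c(stats::sd(gd), stats::sd(vis_abs))),
    discordant = discordant)
  out
}

#' Ground-truth marginal effect of genetic diversity
#'
#' Link-scale slope of the absolute shift velocity in GD z-units at a
#' given range position and standardised |VIS|, computed from the
#' generating coefficients: the GD main effect plus its position
#' deviation, plus (interaction plus its position deviation) times
#' |VIS|. Deviations are zero at the centroid reference.
#'
#' @param config A [simulation_config()].
#' @param position One of `"centroid"`, `"leading"`, `"trailing"`.
#' @param vis Standardised |VIS| value (z units).
#' @return The true link-scale GD slope.
#' @export
true_marginal_effect <- function(config, position, vis) {
  stopifnot(inherits(config, "divshift_config"))
  beta <- structure(numeric(length(coef_names())), names = coef_names())
  beta[names(config$true_coefficients)] <- config$true_coefficients
  marginal_gd_effect(beta, position, vis)
}
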