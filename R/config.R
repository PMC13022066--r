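#' Coefficient vocabulary of the range-shift model
#'
#' Names of the fixed-effect coefficients of the full model: intercept,
#' main effects of genetic diversity (GD, z-scored), absolute isotherm
#' velocity (|VIS|, z-scored) and range position (centroid as reference),
#' all two-way and the three-way interactions among them, and the five
#' methodological covariates (log number of temporal periods, log study
#' area extent, spatial grain score 1-4, data type, sampling design).
#'
#' @param positions Character vector of non-reference range positions to
#'   include (default `c("leading", "trailing")`).
#' @param position_terms If `FALSE`, all position-related terms are
#'   dropped (used by the per-position sensitivity models).
#' @return Character vector of coefficient names, in design-matrix order.
#' @export
coef_names <- function(positions = c("leading", "trailing"),
                       position_terms = TRUE) {
  nm <- c("intercept", "gd", "vis")
  if (position_terms && length(positions)) {
    nm <- c(nm, paste0("pos_", positions))
  }
  nm <- c(nm, "gd_vis")
  if (position_terms && length(positions)) {
    nm <- c(nm,
            paste0("gd_pos_", positions),
            paste0("vis_pos_", positions),
            paste0("gd_vis_pos_", positions))
  }
  c(nm, "log_n_periods", "log_study_extent", "grain_score",
    "dty_abundance", "sdes_raw", "sdes_resurvey")
}

#' Default true coefficients for the synthetic-data generator
#'
#' Link-scale (log km/yr) effects used to build the linear predictor of
#' the generator. The centroid GD x |VIS| interaction defaults to -0.086
#' so that recovery tests target an effect of realistic magnitude;
#' methodological covariates carry the largest effects, mirroring the
#' dominant role of methodology in observed range-shift variability.
#'
#' @return Named numeric vector over [coef_names()].
#' @export
default_true_coefficients <- function() {
  c(intercept        = -0.70,
    gd               =  0.10,
    vis              =  0.25,
    pos_leading      =  0.15,
    pos_trailing     = -0.35,
    gd_vis           = -0.086,
    gd_pos_leading   =  0.05,
    gd_pos_trailing  = -0.05,
    vis_pos_leading  =  0.10,
    vis_pos_trailing =  0.05,
    gd_vis_pos_leading  = -0.03,
    gd_vis_pos_trailing = -0.08,
    log_n_periods    = -0.30,
    log_study_extent =  0.15,
    grain_score      =  0.25,
    dty_abundance    = -0.40,
    sdes_raw         =  0.50,
    sdes_resurvey    = -0.30)
}

#' Configuration for the synthetic observation-table generator
#'
#' Describes a study population with the structure of a merged
#' range-shift x genetic-diversity table: species nested in taxonomic
#' classes, repeated range-shift observations per species at three range
#' positions (heavily imbalanced, as in the real data), Gamma-distributed
#' positive shift velocities whose log-mean is a linear function of
#' standardised genetic diversity, standardised absolute isotherm
#' velocity, range position, their interactions, and five methodological
#' covariates, plus a class-level random intercept.
#'
#' @param n_species Number of species.
#' @param n_classes Number of taxonomic classes (default 7).
#' @param position_probs Probabilities of (centroid, leading, trailing)
#'   positions per observation; default proportional to the observed
#'   2298/2082/295 imbalance.
#' @param obs_per_species List describing the per-species observation
#'   count distribution; currently `list(dist = "geometric", mean = m)`
#'   giving `1 + Geom(1/m)` counts with mean `m`.
#' @param class_probs Probabilities of class membership per species;
#'   default mirrors the observed class imbalance (recycled/renormalised
#'   to `n_classes`).
#' @param true_coefficients Named link-scale coefficient vector; see
#'   [default_true_coefficients()]. Names must belong to [coef_names()].
#' @param class_sd Standard deviation of the class random intercept
#'   (log scale).
#' @param gamma_shape Gamma shape `nu` of the response; the conditional
#'   variance of the absolute shift velocity is `mu^2 / nu`.
#' @param gd_distribution Lognormal parameters for species-level
#'   nucleotide diversity (`meanlog`, `sdlog`); default spans the
#'   typical 0.001-0.02 range.
#' @param vis_distribution Lognormal parameters for absolute isotherm
#'   velocity in km/yr.
#' @param poleward_prob Probability that an isotherm shifts poleward
#'   (positive sign).
#' @param discordant_fraction Fraction of rows whose species shift sign
#'   is set opposite to the isotherm sign (direction-discordant rows,
#'   removed later by the concordance filter).
#' @param method_covariate_specs Distributions/level frequencies of the
#'   five methodological covariates.
#' @param latitude List with `mean`, `sd`, `vis_coef` (association of
#'   latitude with |VIS|, default 0) and `effect` (direct link-scale
#'   effect of z-scored latitude on the log-mean, default 0; used to
#'   plant signal for residual-sensitivity tests).
#' @param seed Integer seed; every random draw of the generator flows
#'   from it.
#' @return An object of class `divshift_config`.
#' @export
simulation_config <- function(n_species = 1888,
                              n_classes = 7,
                              position_probs = c(centroid = 2298,
                                                 leading = 2082,
                                                 trailing = 295) / 4675,
                              obs_per_species = list(dist = "geometric",
                                                     mean = 4673 / 1888),
                              class_probs = NULL,
                              true_coefficients = default_true_coefficients(),
                              class_sd = 0.15,
                              gamma_shape = 2,
                              gd_distribution = list(meanlog = log(0.006),
                                                     sdlog = 0.7),
                              vis_distribution = list(meanlog = log(1.5),
                                                      sdlog = 0.7),
                              poleward_prob = 4673 / 4809,
                              discordant_fraction = 136 / 4809,
                              method_covariate_specs = list(
                                log_n_periods = list(mean = log(4.9), sd = 0.5,
                                                     min = log(2), max = log(61)),
                                grain_probs = c(small = 0.3, moderate = 0.4,
                                                large = 0.2, very_large = 0.1),
                                data_type_probs = c(occurrence = 0.7,
                                                    abundance = 0.3),
                                sampling_design_probs = c(balanced = 0.4,
                                                          raw = 0.4,
                                                          resurvey = 0.2),
                                log_study_extent = list(mean = log(1238),
                                                        sd = 1.2)),
                              latitude = list(mean = 45, sd = 12,
                                              vis_coef = 0, effect = 0),
                              seed = 1L) {
  if (n_species < 1) stop("n_species must be a positive integer")
  if (n_classes < 1) stop("n_classes must be a positive integer")
  if (gamma_shape <= 0) stop("gamma_shape must be positive")
  if (class_sd < 0) stop("class_sd must be non-negative")
  if (discordant_fraction < 0 || discordant_fraction >= 1)
    stop("discordant_fraction must lie in [0, 1)")
  if (length(position_probs) != 3L)
    stop("position_probs must have three entries (centroid, leading, trailing)")
  if (abs(sum(position_probs) - 1) > 1e-8)
    stop("position_probs must sum to 1")
  if (is.null(names(position_probs)))
    names(position_probs) <- c("centroid", "leading", "trailing")
  bad <- setdiff(names(true_coefficients), coef_names())
  if (length(bad))
    stop("unknown coefficient name(s): ", paste(bad, collapse = ", "))
  if (is.null(class_probs)) {
    # observed species counts per class in the merged data, largest first
    base <- c(1002, 342, 154, 134, 150, 60, 46)
    class_probs <- rep_len(base, n_classes)
  }
  class_probs <- class_probs / sum(class_probs)
  cfg <- list(n_species = as.integer(n_species),
              n_classes = as.integer(n_classes),
              position_probs = position_probs,
              obs_per_species = obs_per_species,
              class_probs = class_probs,
              true_coefficients = true_coefficients,
              class_sd = class_sd,
              gamma_shape = gamma_shape,
              gd_distribution = gd_distribution,
              vis_distribution = vis_distribution,
              poleward_prob = poleward_prob,
              discordant_fraction = discordant_fraction,
              method_covariate_specs = method_covariate_specs,
              latitude = latitude,
              seed = as.integer(seed))
  class(cfg) <- "divshift_config"
  cfg
}

#' @export
print.divshift_config <- function(x, ...) {
  cat("Synthetic range-shift study configuration\n")
  cat(sprintf("  species: %d in %d classes; mean obs/species: %.2f\n",
              x$n_species, x$n_classes, x$obs_per_species$mean))
  cat(sprintf("  position probs (C/L/T): %.3f / %.3f / %.3f\n",
              x$position_probs[1], x$position_probs[2], x$position_probs[3]))
  cat(sprintf("  class SD: %.3f; Gamma shape: %.2f; discordant fraction: %.4f\n",
              x$class_sd, x$gamma_shape, x$discordant_fraction))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Read a simulation configuration from YAML or JSON
#'
#' Scalar fields override the defaults of [simulation_config()]; the
#' `true_coefficients` entry, if present, is merged into the default
#' coefficient vector.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `divshift_config` object.
#' @export
read_simulation_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- raw[intersect(names(raw), names(formals(simulation_config)))]
  if (!is.null(args$true_coefficients)) {
    tc <- default_true_coefficients()
    ov <- unlist(args$true_coefficients)
    tc[names(ov)] <- ov
    args$true_coefficients <- tc
  }
  if (!is.null(args$position_probs))
    args$position_probs <- unlist(args$position_probs)
  do.call(simulation_config, args)
}
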