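#' Marginal effect of genetic diversity at a position and |VIS|
#'
#' Link-scale slope of the absolute shift velocity in GD z-units:
#' the GD main effect plus its position deviation, plus the GD x |VIS|
#' interaction (plus its position deviation) times standardised |VIS|.
#' Deviations are zero at the centroid reference.
#'
#' @param coefficients Named coefficient vector (vocabulary of
#'   [coef_names()]).
#' @param position `"centroid"`, `"leading"` or `"trailing"`.
#' @param vis_z Standardised |VIS| (z units); may be a vector.
#' @return Link-scale GD slope(s).
#' @export
marginal_gd_effect <- function(coefficients, position, vis_z) {
  if (!position %in% c("centroid", "leading", "trailing"))
    stop("unknown position: ", position)
  cf <- function(nm) if (nm %in% names(coefficients)) coefficients[[nm]] else 0
  a1 <- cf("gd")
  a3 <- cf("gd_vis")
  if (position != "centroid") {
    a1 <- a1 + cf(paste0("gd_pos_", position))
    a3 <- a3 + cf(paste0("gd_vis_pos_", position))
  }
  a1 + a3 * vis_z
}

#' Bootstrap marginal-effect curve of genetic diversity
#'
#' Evaluates the GD slope at each climate-velocity grid point on every
#' retained bootstrap draw, and summarises per grid point with the
#' ensemble mean, 2.5%/97.5% percentile bands and a significance flag
#' (pointwise 95% interval excluding zero).
#'
#' @param ensemble A `divshift_boot` (or a draws matrix with named
#'   columns).
#' @param position Range position of the curve.
#' @param vis_grid Climate-velocity grid in raw km/yr.
#' @param scaling Scaling table from preprocessing (converts the grid
#'   to z units).
#' @return An object of class `divshift_curve`: a `data.frame` with
#'   columns `vis`, `vis_z`, `slope`, `lower`, `upper`, `significant`,
#'   plus `position` and `scaling` attributes.
#' @export
effect_curve <- function(ensemble, position, vis_grid, scaling) {
  if (length(vis_grid) == 0L) stop("empty velocity grid")
  if (missing(scaling) || is.null(scaling)) stop("scaling missing")
  if (!position %in% c("centroid", "leading", "trailing"))
    stop("unknown position: ", position)
  draws <- if (inherits(ensemble, "divshift_boot")) ensemble$draws else ensemble
  vz <- scale_to_z(scaling, vis_grid, "vis")
  cf <- function(nm) if (nm %in% colnames(draws)) draws[, nm] else 0
  a1 <- cf("gd")
  a3 <- cf("gd_vis")
  if (position != "centroid") {
    a1 <- a1 + cf(paste0("gd_pos_", position))
    a3 <- a3 + cf(paste0("gd_vis_pos_", position))
  }
  S <- outer(a3, vz) + a1                      # draws x grid
  if (nrow(draws) >= 2L) {
    qs <- apply(S, 2L, stats::quantile, probs = c(0.025, 0.975),
                type = 7, names = FALSE)
    lower <- qs[1, ]; upper <- qs[2, ]
  } else {
    lower <- upper <- drop(S)
  }
  out <- data.frame(vis = vis_grid, vis_z = vz,
                    slope = colMeans(S),
                    lower = lower, upper = upper,
                    significant = lower > 0 | upper < 0)
  attr(out, "position") <- position
  attr(out, "scaling") <- scaling
  class(out) <- c("divshift_curve", "data.frame")
  out
}

#' Contiguous significance bands of an effect curve
#'
#' Maximal runs of grid points where the pointwise 95% interval excludes
#' zero, split where the sign of the mean slope changes, reported as
#' climate-velocity ranges in raw km/yr.
#'
#' @param curve A `divshift_curve`.
#' @return A `data.frame` with columns `vis_lo`, `vis_hi`, `sign`
#'   (`"positive"`/`"negative"`); zero rows when nowhere significant.
#' @export
significance_bands <- function(curve) {
  sig <- curve$significant
  sgn <- ifelse(curve$slope > 0, 1L, -1L)
  id <- cumsum(c(TRUE, diff(sig) != 0 | (diff(sgn) != 0 & sig[-1])))
  out <- data.frame(vis_lo = numeric(0), vis_hi = numeric(0),
                    sign = character(0))
  for (g in unique(id)) {
    i <- which(id == g)
    if (!sig[i[1]]) next
    out <- rbind(out, data.frame(vis_lo = min(curve$vis[i]),
                                 vis_hi = max(curve$vis[i]),
                                 sign = if (sgn[i[1]] > 0) "positive" else "negative"))
  }
  out
}

#' Representative methodological covariates for predictions
#'
#' Default covariate combination at which response-scale predictions
#' are made: occurrence-based observations, balanced sampling, moderate
#' spatial grain, a study-area extent of 1238 km2 and 4.9 temporal
#' periods (average values in the source range-shift database). The
#' extent and period counts are log-transformed before use.
#'
#' @param data_type,sampling_design,grain,study_area_extent,n_periods
#'   Overrides for individual attributes.
#' @return Named list of representative covariates.
#' @export
representative_covariates <- function(data_type = "occurrence",
                                      sampling_design = "balanced",
                                      grain = "moderate",
                                      study_area_extent = 1238,
                                      n_periods = 4.9) {
  list(data_type = data_type, sampling_design = sampling_design,
       grain = grain, study_area_extent = study_area_extent,
       n_periods = n_periods)
}

#' Predicted range-shift velocity at given GD and |VIS|
#'
#' Response-scale prediction `exp(eta)` (km/yr) with the class random
#' intercept at its population mean (zero), for raw-unit genetic
#' diversity and climate velocity and a representative combination of
#' methodological covariates.
#'
#' @param coefficients Named coefficient vector.
#' @param position Range position.
#' @param gd Nucleotide diversity, raw units; may be a vector.
#' @param vis Climate velocity, raw km/yr; may be a vector.
#' @param rep Representative covariates, see
#'   [representative_covariates()].
#' @param scaling Scaling table from preprocessing.
#' @return Predicted velocities in km/yr.
#' @export
predict_response <- function(coefficients, position, gd, vis,
                             rep = representative_covariates(), scaling) {
  if (missing(scaling) || is.null(scaling)) stop("scaling missing")
  if (!position %in% c("centroid", "leading", "trailing"))
    stop("unknown position: ", position)
  cf <- function(nm) if (nm %in% names(coefficients)) coefficients[[nm]] else 0
  g <- scale_to_z(scaling, gd, "gd")
  v <- scale_to_z(scaling, vis, "vis")
  eta <- cf("intercept") + cf("gd") * g + cf("vis") * v + cf("gd_vis") * g * v
  if (position != "centroid") {
    eta <- eta + cf(paste0("pos_", position)) +
      cf(paste0("gd_pos_", position)) * g +
      cf(paste0("vis_pos_", position)) * v +
      cf(paste0("gd_vis_pos_", position)) * g * v
  }
  eta <- eta + cf("log_n_periods") * log(rep$n_periods) +
    cf("log_study_extent") * log(rep$study_area_extent) +
    cf("grain_score") * match(rep$grain, grain_levels) +
    cf("dty_abundance") * (rep$data_type == "abundance") +
    cf("sdes_raw") * (rep$sampling_design == "raw") +
    cf("sdes_resurvey") * (rep$sampling_design == "resurvey")
  exp(eta)
}
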