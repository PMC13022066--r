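#' Keep only direction-concordant range shifts
#'
#' Restricts the table to observations whose range-shift direction
#' matches the local isotherm-shift direction (both poleward or both
#' equatorward); movements against the isotherm are unlikely to reflect
#' climate tracking. Rows with a zero shift or isotherm velocity have
#' undefined concordance and are dropped with a logged count (the Gamma
#' response cannot be zero in any case).
#'
#' @param table Observation table with signed `shift_velocity_signed`
#'   and `isotherm_velocity_signed` columns.
#' @return The filtered table; counts are recorded in
#'   `attr(, "filter")` as `n_input`, `n_discordant`, `n_zero`, `n_kept`.
#' @export
directional_filter <- function(table) {
  if (is.null(table$shift_velocity_signed) ||
      is.null(table$isotherm_velocity_signed))
    stop("table lacks signed shift / isotherm velocity columns")
  s <- sign(table$shift_velocity_signed)
  v <- sign(table$isotherm_velocity_signed)
  zero <- s == 0 | v == 0
  keep <- !zero & s == v
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter") <- list(n_input = nrow(table),
                              n_discordant = sum(!zero & s != v),
                              n_zero = sum(zero),
                              n_kept = nrow(out))
  out
}

#' Remove taxonomic classes with few species
#'
#' Classes represented by fewer than `min_species` distinct species are
#' removed entirely, to avoid taxonomic imbalance dominating the class
#' random intercept. A class with exactly `min_species` species is kept.
#'
#' @param table Observation table with `class_id` and `species_id`.
#' @param min_species Minimum number of distinct species per class
#'   (default 10).
#' @return The filtered table; removed class identifiers are recorded in
#'   `attr(, "removed_classes")`.
#' @export
filter_rare_classes <- function(table, min_species = 10L) {
  if (is.null(table$class_id) || is.null(table$species_id))
    stop("table lacks class_id / species_id columns")
  n_sp <- tapply(table$species_id, table$class_id,
                 function(s) length(unique(s)))
  drop_cls <- names(n_sp)[n_sp < min_species]
  out <- table[!(table$class_id %in% drop_cls), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed_classes") <- drop_cls
  out
}

#' Standardise model covariates to z-scores
#'
#' Adds z-scored genetic diversity (`gd_z`) and absolute isotherm
#' velocity (`vis_z`) columns, using the sample mean and sd (denominator
#' n - 1) of the table as given. |VIS| is taken as the absolute value of
#' the signed isotherm velocity before scaling. The scaling parameters
#' are returned so prediction grids in raw units can be mapped to the
#' model scale and back.
#'
#' @param table Observation table.
#' @return List with `table` (augmented) and `scaling` (a `data.frame`
#'   with columns `covariate`, `mean`, `sd`).
#' @export
standardize_covariates <- function(table) {
  gd <- table$genetic_diversity
  vis <- abs(table$isotherm_velocity_signed)
  sc <- data.frame(covariate = c("gd", "vis"),
                   mean = c(mean(gd), mean(vis)),
                   sd = c(stats::sd(gd), stats::sd(vis)))
  if (any(!is.finite(sc$sd)) || any(sc$sd <= 0))
    stop("zero-variance covariate; cannot standardise")
  table$gd_z <- (gd - sc$mean[1]) / sc$sd[1]
  table$vis_z <- (vis - sc$mean[2]) / sc$sd[2]
  list(table = table, scaling = sc)
}

#' Map raw covariate values to z-scores and back
#'
#' @param scaling Scaling table from [standardize_covariates()].
#' @param x Values to transform.
#' @param covariate `"gd"` or `"vis"`.
#' @return Transformed values.
#' @export
scale_to_z <- function(scaling, x, covariate = "vis") {
  i <- match(covariate, scaling$covariate)
  (x - scaling$mean[i]) / scaling$sd[i]
}

#' @rdname scale_to_z
#' @export
z_to_scale <- function(scaling, x, covariate = "vis") {
  i <- match(covariate, scaling$covariate)
  x * scaling$sd[i] + scaling$mean[i]
}

#' Position-balancing observation weights
#'
#' Computes the weight of each observation as
#' `W = 1 / N_obs(species, position) x 1 / N_sp(position) x 1/3`,
#' where `N_obs` is the number of observations of the focal species at
#' the focal range position, `N_sp` the number of species observed at
#' that position, and 1/3 the equal contribution of each of the three
#' range positions. Weights therefore sum to exactly 1/3 within each
#' position present, and to 1 when all three positions are present.
#' Counts are taken from the table as given (in the bootstrap, from the
#' resampled table).
#'
#' @param table Observation table with `species_id` and `position`.
#' @return A `data.frame` with columns `weight`, `n_obs_sp_pos`,
#'   `n_sp_pos`, aligned with the rows of `table`.
#' @export
compute_weights <- function(table) {
  if (nrow(table) == 0L) stop("empty table")
  key <- paste(table$species_id, table$position, sep = "\r")
  n_obs <- table(key)[key]
  sp_per_pos <- tapply(table$species_id, table$position,
                       function(s) length(unique(s)))
  n_sp <- sp_per_pos[as.character(table$position)]
  data.frame(weight = 1 / (as.numeric(n_obs) * as.numeric(n_sp) * 3),
             n_obs_sp_pos = as.integer(n_obs),
             n_sp_pos = as.integer(n_sp))
}

#' Preprocess a raw merged observation table
#'
#' Applies, in order: optional exclusion of named outlier species, the
#' directional concordance filter, rare-class removal, covariate
#' standardisation (computed once, after all filters, and held fixed
#' thereafter, including inside the bootstrap), and the
#' position-balancing weights.
#'
#' @param table Raw observation table.
#' @param min_species Minimum distinct species per class (default 10).
#' @param exclude_species Character vector of species identifiers to
#'   drop before filtering (e.g. known continental-scale outliers).
#' @return List of class `divshift_prep` with `table` (augmented with
#'   `gd_z`, `vis_z`, `weight`), `scaling`, `weights` and `report`.
#' @export
preprocess_table <- function(table, min_species = 10L,
                             exclude_species = NULL) {
  n0 <- nrow(table)
  if (!is.null(exclude_species))
    table <- table[!(table$species_id %in% exclude_species), , drop = FALSE]
  n_excl <- nrow(table)
  tab <- directional_filter(table)
  filt <- attr(tab, "filter")
  tab2 <- filter_rare_classes(tab, min_species)
  removed <- attr(tab2, "removed_classes")
  std <- standardize_covariates(tab2)
  w <- compute_weights(std$table)
  std$table$weight <- w$weight
  report <- list(n_input_rows = n0,
                 n_after_exclusions = n_excl,
                 n_after_directional_filter = filt$n_kept,
                 n_discordant_dropped = filt$n_discordant,
                 n_zero_velocity_dropped = filt$n_zero,
                 n_after_class_filter = nrow(tab2),
                 removed_classes = removed,
                 scaling = std$scaling)
  out <- list(table = std$table, scaling = std$scaling,
              weights = w, report = report)
  class(out) <- "divshift_prep"
  out
}

#' @export
print.divshift_prep <- function(x, ...) {
  r <- x$report
  cat("Preprocessed range-shift table\n")
  cat(sprintf("  rows: %d input -> %d concordant -> %d after class filter\n",
              r$n_input_rows, r$n_after_directional_filter,
              r$n_after_class_filter))
  cat(sprintf("  dropped: %d discordant, %d zero-velocity; classes removed: %s\n",
              r$n_discordant_dropped, r$n_zero_velocity_dropped,
              if (length(r$removed_classes))
                paste(r$removed_classes, collapse = ", ") else "none"))
  cat(sprintf("  weight sum: %.6f over %d position(s)\n",
              sum(x$table$weight), length(unique(x$table$position))))
  invisible(x)
}
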