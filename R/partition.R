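#' Hierarchical partitioning of marginal R-squared
#'
#' Decomposes the full-model marginal R-squared (lognormal method)
#' across predictor groups by fitting the GLMM for every subset of the
#' groups (intercept and class random intercept always included; the
#' empty subset has R2 = 0 by definition) and averaging incremental
#' contributions over hierarchy levels (the classic hierarchical
#' partitioning / Shapley decomposition). For each group: `unique` is
#' the loss of R2 when the group is removed from the full model;
#' `individual` is the level-averaged incremental contribution (the
#' independent contribution, which sums to the full-model R2 across
#' groups); `average_share = individual - unique`. Subsets may contain
#' an interaction group without its main effects, as required for the
#' averaging to be defined over all subsets. Performed on single fits,
#' without bootstrap.
#'
#' @param table Preprocessed observation table (with `gd_z`, `vis_z`).
#' @param spec A [formula_spec()].
#' @param groups Named list mapping group names to design columns
#'   (default [term_groups()]).
#' @param weights Observation weights; recomputed from the table when
#'   `NULL`.
#' @param control Fitter control.
#' @return An object of class `divshift_partition`: a `data.frame` with
#'   columns `group`, `unique`, `average_share`, `individual`,
#'   `individual_percent`; the full-model R2 and the per-subset R2
#'   table are attached as attributes `r2_full` and `subsets`.
#' @export
hierarchical_partition <- function(table, spec = formula_spec(),
                                   groups = term_groups(spec$positions),
                                   weights = NULL,
                                   control = glmm_control()) {
  K <- length(groups)
  if (K > 12L) stop("more than 12 groups; 2^K subset fits intractable")
  design <- build_design(table, spec)
  if (is.null(weights)) weights <- compute_weights(table)$weight
  if (length(bad <- setdiff(unlist(groups), colnames(design$X))))
    stop("group columns not in design: ", paste(bad, collapse = ", "))

  n_sub <- 2L^K
  r2 <- rep(NA_real_, n_sub)
  failed <- logical(n_sub)
  full_fit <- fit_glmm(design, weights, control = control)
  # subset s (0-based mask): bit j set => group j included
  masks <- 0:(n_sub - 1L)
  has <- function(mask, j) bitwAnd(mask, bitwShiftL(1L, j - 1L)) != 0L
  for (s in masks) {
    if (s == 0L) { r2[1L] <- 0; next }   # intercept + random only
    cols <- c("intercept", unlist(groups[vapply(seq_len(K), has, TRUE, mask = s)]))
    sub <- design
    sub$X <- design$X[, cols, drop = FALSE]
    st <- c(full_fit$coefficients[cols],
            log(max(full_fit$class_sd, 1e-6)), log(full_fit$gamma_shape))
    fit <- try(fit_glmm(sub, weights, control = control, start = st),
               silent = TRUE)
    if (inherits(fit, "try-error") || !fit$converged) {
      # one retry from a perturbed least-squares start
      b0 <- stats::lm.wfit(sub$X, log(sub$y), weights)$coefficients
      b0[is.na(b0)] <- 0
      st <- c(b0 + stats::rnorm(length(b0), 0, 0.05), log(0.2), log(1))
      fit <- try(fit_glmm(sub, weights, control = control, start = st),
                 silent = TRUE)
    }
    if (inherits(fit, "try-error") || !fit$converged) {
      failed[s + 1L] <- TRUE
    } else {
      r2[s + 1L] <- marginal_r2_lognormal(fit, sub)
    }
  }
  # impute any failed subset by the average of its one-group neighbours
  if (any(failed)) {
    for (s in masks[failed]) {
      nb <- vapply(seq_len(K), function(j) bitwXor(s, bitwShiftL(1L, j - 1L)), 0L)
      r2[s + 1L] <- mean(r2[nb + 1L], na.rm = TRUE)
    }
  }

  lev <- vapply(masks, function(s) sum(bitwAnd(s, bitwShiftL(1L, 0:(K - 1L))) != 0L), 0L)
  lw <- exp(lfactorial(0:(K - 1L)) + lfactorial(K - 1L - (0:(K - 1L))) - lfactorial(K))
  individual <- unique_c <- numeric(K)
  full_mask <- n_sub - 1L
  for (j in seq_len(K)) {
    bit <- bitwShiftL(1L, j - 1L)
    without <- masks[bitwAnd(masks, bit) == 0L]
    inc <- r2[bitwOr(without, bit) + 1L] - r2[without + 1L]
    individual[j] <- sum(lw[lev[without + 1L] + 1L] * inc)
    unique_c[j] <- r2[full_mask + 1L] - r2[bitwXor(full_mask, bit) + 1L]
  }
  r2_full <- r2[full_mask + 1L]
  out <- data.frame(group = names(groups),
                    unique = unique_c,
                    average_share = individual - unique_c,
                    individual = individual,
                    individual_percent = 100 * individual / r2_full,
                    row.names = NULL)
  attr(out, "r2_full") <- r2_full
  attr(out, "subsets") <- data.frame(mask = masks, size = lev, r2 = r2,
                                     imputed = failed)
  class(out) <- c("divshift_partition", "data.frame")
  out
}

#' Aggregate a variable's contribution across its interaction groups
#'
#' Total percentage of explained variance attributable to a variable:
#' the individual contribution of its main-effect group plus those of
#' every interaction group containing it; the interaction part is also
#' reported alone. Group membership is read from the `":"`-separated
#' group names.
#'
#' @param partition A `divshift_partition` (or any `data.frame` with
#'   `group` and `individual_percent` columns).
#' @param variable One of the main-effect group names (e.g. `"GD"`,
#'   `"VIS"`, `"POS"`).
#' @return Named numeric vector `c(total, interaction)`, in percent.
#' @export
aggregate_variable_contribution <- function(partition, variable) {
  parts <- strsplit(partition$group, ":", fixed = TRUE)
  if (!variable %in% unlist(parts)) stop("unknown variable: ", variable)
  contains <- vapply(parts, function(p) variable %in% p, TRUE)
  main <- vapply(parts, function(p) identical(p, variable), TRUE)
  inter <- contains & !main
  c(total = sum(partition$individual_percent[contains]),
    interaction = sum(partition$individual_percent[inter]))
}

#' Residual covariate test (latitude sensitivity)
#'
#' Fits a baseline GLMM on the requested term groups, takes link-scale
#' residuals (log response minus fitted linear predictor, conditional
#' on the class intercepts), and regresses them on the probe covariates
#' with a linear model. Reports the residual-model R-squared alongside
#' the baseline marginal R-squared. Used in both directions: does
#' latitude explain what the model misses, and does the model explain
#' what a latitude-only model misses.
#'
#' @param table Preprocessed observation table (with `gd_z`, `vis_z`,
#'   `latitude`).
#' @param baseline Character vector of term-group names (from
#'   [term_groups()]) and/or the keyword `"latitude"` defining the
#'   baseline GLMM fixed effects.
#' @param probe Character vector of probe terms (group names and/or
#'   `"latitude"`) for the residual regression.
#' @param spec A [formula_spec()].
#' @param weights Observation weights; recomputed when `NULL`.
#' @param control Fitter control.
#' @return List with `baseline_terms`, `probe_terms`,
#'   `r2_residual_model` (R2 of the residual regression), `baseline_r2`
#'   (marginal R2 of the baseline GLMM), and the residual `lm` fit.
#' @export
residual_covariate_test <- function(table, baseline, probe,
                                    spec = formula_spec(),
                                    weights = NULL,
                                    control = glmm_control()) {
  if (length(intersect(baseline, probe)))
    stop("baseline and probe terms must be disjoint")
  groups <- term_groups(spec$positions)
  lat_z <- as.numeric(scale(table$latitude))
  cols_for <- function(terms) {
    unlist(lapply(terms, function(t) {
      if (t == "latitude") "latitude" else groups[[t]] %||%
        stop("unknown term: ", t)
    }))
  }
  base_cols <- cols_for(baseline)
  design <- build_design(table, spec,
                         extra = if ("latitude" %in% base_cols)
                           list(latitude = lat_z) else NULL)
  keep <- c("intercept", base_cols)
  design$X <- design$X[, keep, drop = FALSE]
  if (is.null(weights)) weights <- compute_weights(table)$weight
  fit <- fit_glmm(design, weights, control = control)
  if (!fit$converged) stop("baseline model did not converge")
  resid <- log(design$y) - fit$fitted_eta

  probe_cols <- cols_for(probe)
  full_X <- build_design(table, spec, extra = list(latitude = lat_z))$X
  pd <- as.data.frame(full_X[, probe_cols, drop = FALSE])
  lmfit <- stats::lm(resid ~ ., data = pd)
  list(baseline_terms = baseline,
       probe_terms = probe,
       r2_residual_model = summary(lmfit)$r.squared,
       baseline_r2 = marginal_r2_lognormal(fit, design),
       residual_fit = lmfit)
}
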