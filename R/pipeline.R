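#' Configuration of a full pipeline run
#'
#' Exactly one of `input` (a CSV path) or `simulation` (a
#' [simulation_config()]) must be given.
#'
#' @param input Path to an observation-table CSV.
#' @param simulation A `divshift_config` for synthetic input.
#' @param seed Master seed (mandatory) governing the bootstrap and any
#'   synthetic generation.
#' @param B,keep Bootstrap iterations and retained fits.
#' @param min_species Rare-class threshold.
#' @param exclude_species Optional species exclusion list.
#' @param vis_grid_n Number of climate-velocity grid points for the
#'   effect curves (grid spans the observed |VIS| range).
#' @param gd_low,gd_high Nucleotide-diversity cut-points used for the
#'   low/high prediction scenarios.
#' @param representative Representative methodological covariates, see
#'   [representative_covariates()].
#' @param partition Run the hierarchical variance partitioning (256
#'   subset fits)?
#' @param residual_tests Run the latitude residual-sensitivity tests?
#' @param control Fitter control.
#' @return An object of class `divshift_run_config`.
#' @export
run_config <- function(input = NULL, simulation = NULL, seed,
                       B = 12000L, keep = 10000L,
                       min_species = 10L, exclude_species = NULL,
                       vis_grid_n = 100L,
                       gd_low = 0.003, gd_high = 0.015,
                       representative = representative_covariates(),
                       partition = TRUE, residual_tests = TRUE,
                       control = glmm_control()) {
  if (is.null(input) == is.null(simulation))
    stop("exactly one of input / simulation must be supplied")
  if (missing(seed)) stop("seed is mandatory")
  cfg <- list(input = input, simulation = simulation,
              seed = as.integer(seed), B = as.integer(B),
              keep = if (is.null(keep)) NULL else as.integer(keep),
              min_species = as.integer(min_species),
              exclude_species = exclude_species,
              vis_grid_n = as.integer(vis_grid_n),
              gd_low = gd_low, gd_high = gd_high,
              representative = representative,
              partition = partition, residual_tests = residual_tests,
              control = control)
  class(cfg) <- "divshift_run_config"
  cfg
}

#' Read a pipeline run configuration from YAML
#'
#' Top-level keys map to [run_config()] arguments; a `simulation` block
#' is passed through [simulation_config()] field-by-field.
#'
#' @param path Path to a YAML file.
#' @return A `divshift_run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$simulation)) {
    args <- raw$simulation[intersect(names(raw$simulation),
                                     names(formals(simulation_config)))]
    if (!is.null(args$true_coefficients)) {
      tc <- default_true_coefficients()
      ov <- unlist(args$true_coefficients)
      tc[names(ov)] <- ov
      args$true_coefficients <- tc
    }
    raw$simulation <- do.call(simulation_config, args)
  }
  do.call(run_config, raw[intersect(names(raw), names(formals(run_config)))])
}

#' Run the full range-shift / genetic-diversity analysis
#'
#' Executes every stage in order: input (read or simulate), preprocess
#' (concordance filter, rare-class removal, standardisation, weights),
#' collinearity diagnostics, full GLMM fit, bootstrap, marginal-effect
#' curves with significance bands for every position present,
#' representative predictions at low/high genetic diversity,
#' hierarchical variance partitioning, latitude residual tests, and
#' per-position sensitivity fits. Deterministic given the master seed.
#'
#' @param config A [run_config()].
#' @param progress Print stage progress to stderr.
#' @return A list of class `divshift_bundle` with elements `report`,
#'   `vif`, `fit`, `ensemble`, `summary`, `curves`, `bands`,
#'   `predictions`, `partition`, `residual_tests`,
#'   `per_position_fits`, `provenance`.
#' @export
run_full_analysis <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "divshift_run_config"))
  say <- function(...) if (progress) message(sprintf(...))
  t0 <- Sys.time()

  say("stage: input")
  raw <- if (!is.null(config$input)) {
    read_observation_table(config$input)
  } else {
    generate_dataset(config$simulation, seed = config$seed)
  }

  say("stage: preprocess")
  prep <- preprocess_table(raw, min_species = config$min_species,
                           exclude_species = config$exclude_species)
  tab <- prep$table
  positions <- intersect(c("leading", "trailing"), unique(tab$position))
  spec <- formula_spec(positions = positions)

  say("stage: collinearity")
  design <- build_design(tab, spec)
  vif <- variance_inflation(design)

  say("stage: full fit")
  fit <- fit_glmm(design, tab$weight, control = config$control)

  say("stage: bootstrap (B = %d)", config$B)
  ens <- bootstrap_fit(tab, spec, B = config$B, keep = config$keep,
                       seed = config$seed, control = config$control)
  summ <- summarize_ensemble(ens)

  say("stage: effect curves")
  vis_abs <- abs(tab$isotherm_velocity_signed)
  grid <- seq(min(vis_abs), max(vis_abs), length.out = config$vis_grid_n)
  pos_all <- c("centroid", positions)
  curves <- lapply(pos_all, function(p)
    effect_curve(ens, p, grid, prep$scaling))
  names(curves) <- pos_all
  bands <- lapply(curves, significance_bands)

  preds <- do.call(rbind, lapply(pos_all, function(p) {
    data.frame(position = p,
               gd = c(config$gd_low, config$gd_high),
               vis = stats::median(vis_abs),
               predicted = predict_response(colMeans(ens$draws), p,
                                            c(config$gd_low, config$gd_high),
                                            stats::median(vis_abs),
                                            config$representative,
                                            prep$scaling))
  }))

  part <- NULL
  if (isTRUE(config$partition)) {
    say("stage: variance partitioning")
    part <- hierarchical_partition(tab, spec, weights = tab$weight,
                                   control = config$control)
  }

  res_tests <- NULL
  if (isTRUE(config$residual_tests)) {
    say("stage: residual tests")
    all_groups <- names(term_groups(positions))
    res_tests <- list(
      latitude_on_baseline_residuals =
        residual_covariate_test(tab, baseline = all_groups,
                                probe = "latitude", spec = spec,
                                weights = tab$weight,
                                control = config$control)[1:4],
      model_on_latitude_residuals =
        residual_covariate_test(tab, baseline = c("latitude", "Methods"),
                                probe = setdiff(all_groups, "Methods"),
                                spec = spec, weights = tab$weight,
                                control = config$control)[1:4])
  }

  say("stage: per-position sensitivity fits")
  pp <- per_position_models(tab, control = config$control)

  bundle <- list(report = prep$report,
                 scaling = prep$scaling,
                 vif = vif,
                 fit = fit,
                 marginal_r2 = marginal_r2_lognormal(fit, design),
                 ensemble = ens,
                 summary = summ,
                 curves = curves,
                 bands = bands,
                 predictions = preds,
                 partition = part,
                 residual_tests = res_tests,
                 per_position_fits = pp,
                 provenance = list(seed = config$seed,
                                   B = config$B, keep = config$keep,
                                   package_version =
                                     as.character(utils::packageVersion("divshift")),
                                   r_version = R.version.string,
                                   elapsed_s = as.numeric(difftime(Sys.time(),
                                                                   t0, units = "secs"))))
  class(bundle) <- "divshift_bundle"
  bundle
}

#' @export
print.divshift_bundle <- function(x, ...) {
  cat("Range-shift x genetic-diversity analysis bundle\n")
  cat(sprintf("  n = %d observations, marginal R2 = %.3f, mean bootstrap R2 = %.3f\n",
              x$fit$n_obs, x$marginal_r2, mean(x$ensemble$r2)))
  gv <- x$summary[x$summary$coefficient == "gd_vis", ]
  if (nrow(gv))
    cat(sprintf("  GD x |VIS| (centroid): %.3f [%.3f, %.3f]%s\n",
                gv$mean, gv$lower, gv$upper,
                if (gv$significant) " *" else ""))
  invisible(x)
}

#' Per-position sensitivity models
#'
#' Subsets the data by range position and fits one independent GLMM per
#' position, with every position term (main effect and the two- and
#' three-way interactions involving position) removed and weights
#' recomputed within the subset.
#'
#' @param table Preprocessed observation table.
#' @param control Fitter control.
#' @return Named list of `divshift_glmm` fits, one per position present.
#' @export
per_position_models <- function(table, control = glmm_control()) {
  spec0 <- formula_spec(position_terms = FALSE)
  pos <- intersect(c("centroid", "leading", "trailing"),
                   unique(table$position))
  out <- lapply(pos, function(p) {
    sub <- table[table$position == p, , drop = FALSE]
    if (nrow(sub) == 0L) stop("empty position subset: ", p)
    sub$class_id <- factor(as.character(sub$class_id))
    d <- build_design(sub, spec0)
    fit_glmm(d, compute_weights(sub)$weight, control = control)
  })
  names(out) <- pos
  out
}

#' Write a report bundle to disk
#'
#' Serialises the bundle's tables as CSV and its scalar metadata as
#' JSON under `dir`: `summary.csv`, `curve_<position>.csv`,
#' `bands_<position>.csv`, `partition.csv`, `predictions.csv`,
#' `vif.csv`, `draws.csv`, `report.json`, `provenance.json`.
#'
#' @param bundle A `divshift_bundle`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, f) utils::write.csv(df, file.path(dir, f),
                                           row.names = FALSE)
  wcsv(bundle$summary, "summary.csv")
  wcsv(data.frame(term = names(bundle$vif), vif = bundle$vif), "vif.csv")
  wcsv(bundle$predictions, "predictions.csv")
  wcsv(as.data.frame(bundle$ensemble$draws), "draws.csv")
  for (p in names(bundle$curves)) {
    wcsv(as.data.frame(bundle$curves[[p]]), sprintf("curve_%s.csv", p))
    wcsv(bundle$bands[[p]], sprintf("bands_%s.csv", p))
  }
  if (!is.null(bundle$partition))
    wcsv(as.data.frame(bundle$partition), "partition.csv")
  jsonlite::write_json(bundle$report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  jsonlite::write_json(c(bundle$provenance,
                         list(marginal_r2 = bundle$marginal_r2)),
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(bundle$residual_tests))
    jsonlite::write_json(bundle$residual_tests,
                         file.path(dir, "residual_tests.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
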