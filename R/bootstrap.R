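#' Bootstrap the weighted Gamma GLMM
#'
#' Nonparametric bootstrap of the full model: each iteration resamples
#' `n` observations with replacement, recomputes the position-balancing
#' weights from the resampled counts, and refits the GLMM (warm-started
#' at the full-data estimates). Iterations whose fit fails, does not
#' converge, or is singular are discarded; among the converging fits a
#' seeded uniform random subset of size `keep` is retained. Iteration
#' seeds are spawned deterministically from the master seed, so results
#' do not depend on execution order.
#'
#' @param table Preprocessed observation table (with `gd_z`, `vis_z`);
#'   standardisation is held fixed across iterations so coefficients
#'   stay comparable in z-units.
#' @param spec A [formula_spec()].
#' @param B Number of bootstrap iterations (default 12000).
#' @param keep Number of converging fits to retain (default 10000);
#'   `NULL` retains all converging fits.
#' @param seed Master seed.
#' @param control Fitter control, see [glmm_control()]. Refits default
#'   to a slightly looser optimiser tolerance than single fits; the
#'   resulting perturbation of the draws is orders of magnitude below
#'   their Monte Carlo spread.
#' @param progress Print a dot every 100 iterations.
#' @return An object of class `divshift_boot`: `draws` (retained
#'   iterations x coefficients), `r2` (per-draw marginal R-squared),
#'   `shape`, `class_sd` (per-draw), `n_attempted`, `n_converged`,
#'   `n_retained`, `seed`.
#' @export
bootstrap_fit <- function(table, spec = formula_spec(), B = 12000L,
                          keep = 10000L, seed = 1L,
                          control = glmm_control(rel_tol = 1e-8),
                          progress = FALSE) {
  if (B < 1) stop("B must be positive")
  if (!is.null(keep) && keep > B) stop("keep must not exceed B")
  n <- nrow(table)
  design <- build_design(table, spec)
  full <- fit_glmm(design, compute_weights(table)$weight, control = control)

  set.seed(as.integer(seed))
  iter_seeds <- sample.int(.Machine$integer.max - 1L, B)
  keep_seed <- sample.int(.Machine$integer.max - 1L, 1L)

  p <- length(full$coefficients)
  draws <- matrix(NA_real_, B, p, dimnames = list(NULL, names(full$coefficients)))
  r2 <- shape <- csd <- rep(NA_real_, B)
  ok <- logical(B)
  # every design term is row-local, so resampled designs are row subsets
  sp_pos <- paste(table$species_id, table$position, sep = "\r")
  pos <- as.character(table$position)
  for (b in seq_len(B)) {
    set.seed(iter_seeds[b])
    idx <- sample.int(n, n, replace = TRUE)
    db <- design
    db$X <- design$X[idx, , drop = FALSE]
    db$y <- design$y[idx]
    db$group <- design$group[idx]
    fit <- try(fit_glmm(db, fast_weights(sp_pos[idx], pos[idx]),
                        control = control, start = full),
               silent = TRUE)
    if (!inherits(fit, "try-error") && fit$converged && !fit$singular) {
      ok[b] <- TRUE
      draws[b, ] <- fit$coefficients
      r2[b] <- marginal_r2_lognormal(fit, db)
      shape[b] <- fit$gamma_shape
      csd[b] <- fit$class_sd
    }
    if (progress && b %% 100L == 0L) cat(".")
  }
  if (progress) cat("\n")
  n_conv <- sum(ok)
  if (is.null(keep)) keep <- n_conv
  if (n_conv < keep)
    stop(sprintf("only %d of %d bootstrap fits converged (< keep = %d)",
                 n_conv, B, keep))
  set.seed(keep_seed)
  retained <- sort(sample(which(ok), keep))
  out <- list(draws = draws[retained, , drop = FALSE],
              r2 = r2[retained],
              shape = shape[retained],
              class_sd = csd[retained],
              retained = retained,
              converged = which(ok),
              n_attempted = B,
              n_converged = n_conv,
              n_retained = keep,
              seed = as.integer(seed),
              full_fit = full,
              spec = spec)
  class(out) <- "divshift_boot"
  out
}

#' @export
print.divshift_boot <- function(x, ...) {
  cat(sprintf("Bootstrap ensemble: %d retained of %d converged (of %d attempted)\n",
              x$n_retained, x$n_converged, x$n_attempted))
  print(utils::head(summarize_ensemble(x), 8))
  invisible(x)
}

#' Two-sided bootstrap significance
#'
#' `p = 2 * min(P(draw > 0), P(draw < 0))`, clipped below at
#' `1 / n_draws` (an empirical p of exactly zero is unreportable).
#'
#' @param draws Numeric vector of bootstrap draws.
#' @return The two-sided bootstrap p-value.
#' @export
bootstrap_significance <- function(draws) {
  draws <- draws[!is.na(draws)]
  if (length(draws) < 1L) stop("empty draw vector")
  p <- 2 * min(mean(draws > 0), mean(draws < 0))
  max(p, 1 / length(draws))
}

#' Summarise a bootstrap ensemble
#'
#' Per coefficient: bootstrap mean, 2.5% and 97.5% percentile interval
#' (type-7 quantiles), two-sided bootstrap p-value, and a significance
#' flag (the 95% interval excludes zero).
#'
#' @param ensemble A `divshift_boot`, or a draws matrix.
#' @return A `data.frame` with one row per coefficient.
#' @export
summarize_ensemble <- function(ensemble) {
  draws <- if (inherits(ensemble, "divshift_boot")) ensemble$draws else ensemble
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1)
  if (nrow(draws) < 2L) stop("need at least two retained draws")
  qs <- apply(draws, 2L, stats::quantile, probs = c(0.025, 0.975),
              type = 7, names = FALSE)
  data.frame(coefficient = colnames(draws) %||% paste0("V", seq_len(ncol(draws))),
             mean = colMeans(draws),
             lower = qs[1, ],
             upper = qs[2, ],
             p = apply(draws, 2L, bootstrap_significance),
             significant = qs[1, ] > 0 | qs[2, ] < 0,
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Position-balancing weights from species-position keys and positions
# (same arithmetic as compute_weights, minimising per-iteration cost).
fast_weights <- function(sp_pos, pos) {
  ku <- match(sp_pos, unique(sp_pos))
  n_obs <- tabulate(ku)[ku]
  pu <- match(pos, unique(pos))
  # distinct species per position: count unique species-position keys
  first <- !duplicated(ku)
  n_sp <- tabulate(pu[first])[pu]
  1 / (n_obs * n_sp * 3)
}
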