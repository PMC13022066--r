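test_that("design matrix applies treatment coding at the references", {
  tab <- toy_table(12)
  tab$position <- rep("centroid", 12)
  tab$position[2] <- "leading"
  tab$data_type <- "occurrence"
  tab$sampling_design <- "balanced"
  tab$grain_size <- "small"
  tab$log_n_periods <- 0
  tab$log_study_extent <- 0
  std <- standardize_covariates(tab)
  d <- build_design(std$table, formula_spec())
  # a reference row with GD = |VIS| = 0 has zeros everywhere except the
  # intercept and the grain score
  i <- which(std$table$position == "centroid")[1]
  X <- d$X
  X[i, "gd"] <- X[i, "vis"] <- X[i, "gd_vis"] <- 0   # zero out covariates
  expect_equal(sum(X[i, ] != 0), 2)                  # intercept + grain 1
  expect_equal(unname(X[i, "intercept"]), 1)
  expect_equal(unname(X[i, "grain_score"]), 1)
  # a leading-edge row carries its deviations g, v, g*v
  g <- std$table$gd_z[2]; v <- std$table$vis_z[2]
  expect_equal(unname(d$X[2, "gd_pos_leading"]), g)
  expect_equal(unname(d$X[2, "vis_pos_leading"]), v)
  expect_equal(unname(d$X[2, "gd_vis_pos_leading"]), g * v)
  expect_equal(unname(d$X[2, "pos_leading"]), 1)
  expect_equal(unname(d$X[2, "gd_pos_trailing"]), 0)
})

test_that("full design has the expected number of columns", {
  prep <- small_prep(seed = 7, n_species = 120)
  d <- build_design(prep$table, formula_spec())
  # 1 intercept + 6 continuous + 2 position dummies + 6 position
  # interaction deviations + 1 data type + 2 sampling design = 18
  expect_equal(ncol(d$X), 18)
  expect_identical(colnames(d$X), coef_names())
  bad <- prep$table
  bad$position[1] <- "edge"
  expect_error(build_design(bad, formula_spec()), "unseen position")
  expect_error(build_design(toy_table(6), formula_spec()), "gd_z")
})

test_that("intercept-only Gamma fit recovers the weighted-mean closed form", {
  set.seed(71)
  y <- rgamma(40, 2, 1)
  w <- runif(40, 0.2, 3)
  d <- list(X = cbind(intercept = rep(1, 40)), y = y,
            group = factor(rep(1:2, 20)))
  class(d) <- "divshift_design"
  fit <- fit_glmm(d, w, random = FALSE)
  expect_equal(unname(fit$coefficients), log(weighted.mean(y, w)),
               tolerance = 1e-8)
})

test_that("quadrature marginal likelihood matches brute-force integration", {
  set.seed(72)
  cfg <- simulation_config(seed = 73, n_species = 8, n_classes = 2,
                           class_sd = 0.3)
  tab <- generate_dataset(cfg)
  prep <- preprocess_table(tab, min_species = 1)
  spec <- formula_spec(positions = intersect(c("leading", "trailing"),
                                             unique(prep$table$position)))
  d <- build_design(prep$table, spec)
  d$X <- d$X[, c("intercept", "gd", "vis")]
  w <- prep$table$weight
  fit <- fit_glmm(d, w)
  beta <- fit$coefficients
  oracle <- bruteforce_loglik(d, w, beta, 0.3, fit$gamma_shape)
  # default adaptive quadrature is essentially exact
  expect_equal(glmm_loglik(d, w, beta, 0.3, fit$gamma_shape), oracle,
               tolerance = 1e-6)
  # dense 50-node rule agrees with the brute-force integral too
  expect_equal(glmm_loglik(d, w, beta, 0.3, fit$gamma_shape, nagq = 50),
               oracle, tolerance = 1e-6)
  # the one-node Laplace approximation is close but not exact
  expect_equal(glmm_loglik(d, w, beta, 0.3, fit$gamma_shape, nagq = 1),
               oracle, tolerance = 5e-3)
})

test_that("estimates agree with an independent mixed-model implementation", {
  skip_if_not_installed("glmmTMB")
  prep <- small_prep(seed = 9, n_species = 150, n_classes = 4)
  d <- build_design(prep$table, formula_spec())
  w <- prep$table$weight
  fit <- fit_glmm(d, w)
  df <- as.data.frame(d$X[, -1])
  df$y <- d$y; df$cl <- d$group
  df$w <- w * length(w) / sum(w)
  form <- stats::reformulate(c(colnames(d$X)[-1], "(1|cl)"), response = "y")
  tm <- glmmTMB::glmmTMB(form, data = df, family = Gamma(link = "log"),
                         weights = w)
  expect_equal(unname(fit$coefficients),
               unname(glmmTMB::fixef(tm)$cond), tolerance = 1e-3)
  expect_equal(unname(fit$class_sd),
               unname(attr(glmmTMB::VarCorr(tm)$cond$cl, "stddev")),
               tolerance = 1e-2)
  expect_equal(fit$log_likelihood, as.numeric(stats::logLik(tm)),
               tolerance = 1e-3)
})

test_that("weights act as likelihood multipliers", {
  # scale invariance: c * w leaves coefficient estimates unchanged
  prep <- small_prep(seed = 10, n_species = 250, class_sd = 0.5)
  d <- build_design(prep$table, formula_spec())
  f1 <- fit_glmm(d, prep$table$weight)
  f2 <- fit_glmm(d, prep$table$weight * 7.3)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-4)
  # a weight of 2 is equivalent to duplicating the observation
  set.seed(74)
  n <- 60
  X <- cbind(intercept = 1, x = rnorm(n))
  y <- rgamma(n, 2, 1)
  g <- factor(rep(1:3, each = 20))
  d1 <- structure(list(X = X, y = y, group = g), class = "divshift_design")
  w1 <- c(rep(2, 10), rep(1, 50))
  idx <- c(1:10, 1:n)
  d2 <- structure(list(X = X[idx, ], y = y[idx], group = g[idx]),
                  class = "divshift_design")
  f1 <- fit_glmm(d1, w1)
  f2 <- fit_glmm(d2, rep(1, length(idx)))
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-4)
})

test_that("coefficients are recovered within their standard errors", {
  # equal weights: the inverse-Hessian variance is the sampling variance
  # (with unequal likelihood weights it understates it, which is why
  # inference in the pipeline is bootstrap-based)
  cfg <- simulation_config(seed = 75, n_species = 2020, class_sd = 0)
  tab <- generate_dataset(cfg)
  prep <- preprocess_table(tab)
  d <- build_design(prep$table, formula_spec())
  fit <- fit_glmm(d, rep(1, nrow(prep$table)), se = TRUE)
  truth <- attr(tab, "truth")$coefficients
  expect_true(fit$converged)
  expect_true(all(abs(fit$coefficients - truth) < 3.5 * fit$se))
})

test_that("rank-deficient designs are reported, not silently dropped", {
  prep <- small_prep(seed = 12, n_species = 80)
  d <- build_design(prep$table, formula_spec())
  d$X <- cbind(d$X, dup = d$X[, "gd"])
  expect_error(fit_glmm(d, prep$table$weight), "rank-deficient")
})

test_that("variance inflation factors match their definition", {
  set.seed(76)
  # orthogonal columns
  X <- cbind(intercept = 1, kronecker(diag(2), c(1, -1))[rep(1:4, 5), ])
  colnames(X) <- c("intercept", "u", "v")
  expect_equal(unname(variance_inflation(X)), c(1, 1))
  # duplicated column is infinite, not an error
  X2 <- cbind(intercept = 1, a = rnorm(20))
  X2 <- cbind(X2, b = X2[, "a"])
  expect_equal(unname(variance_inflation(X2)), c(Inf, Inf))
  # random design against the definitional regression
  X3 <- cbind(intercept = 1, matrix(rnorm(300), 60, 5,
                                    dimnames = list(NULL, paste0("x", 1:5))))
  X3[, "x2"] <- X3[, "x1"] + 0.4 * X3[, "x2"]
  v <- variance_inflation(X3)
  for (j in paste0("x", 1:5)) {
    r2 <- summary(lm(X3[, j] ~ X3[, setdiff(colnames(X3), c(j, "intercept"))]))$r.squared
    expect_equal(unname(v[j]), 1 / (1 - r2), tolerance = 1e-8)
  }
})

test_that("lognormal marginal R2 follows the stated formula", {
  expect_equal(lognormal_r2(0, 0.5, 4), 0)
  expect_equal(lognormal_r2(1, 0.5, 4), 1 / (1.5 + log(1.25)))
  # enormous shape: observation-level variance vanishes
  expect_equal(lognormal_r2(2, 0.5, 1e8), 2 / 2.5, tolerance = 1e-3)
  expect_error(lognormal_r2(1, 0, -2), "shape")
  # on a fitted model the fixed variance is the population variance of eta
  prep <- small_prep(seed = 13, n_species = 100)
  d <- build_design(prep$table, formula_spec())
  fit <- fit_glmm(d, prep$table$weight)
  eta <- drop(d$X %*% fit$coefficients)
  s2f <- mean((eta - mean(eta))^2)
  expect_equal(marginal_r2_lognormal(fit, d),
               s2f / (s2f + fit$class_variance + log1p(1 / fit$gamma_shape)))
})

test_that("Gauss-Hermite rule integrates known moments", {
  gh <- gauss_hermite(7)
  expect_equal(sum(gh$weights), sqrt(pi), tolerance = 1e-12)
  expect_equal(sum(gh$weights * gh$nodes^2), sqrt(pi) / 2, tolerance = 1e-12)
  expect_equal(gauss_hermite(1)$nodes, 0)
})
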