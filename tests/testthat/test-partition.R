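test_that("partitioning matches a brute-force Shapley oracle", {
  prep <- small_prep(seed = 22, n_species = 150)
  groups <- list(GD = "gd", VIS = "vis", "GD:VIS" = "gd_vis")
  part <- hierarchical_partition(prep$table, groups = groups,
                                 weights = prep$table$weight)
  sub <- attr(part, "subsets")
  r2 <- sub$r2
  # independent reimplementation of level-averaged incremental R2
  K <- 3
  for (j in seq_len(K)) {
    bit <- 2^(j - 1)
    incs <- c()
    for (k in 0:(K - 1)) {
      without <- sub$mask[bitwAnd(sub$mask, bit) == 0 & sub$size == k]
      level_incs <- r2[match(bitwOr(without, bit), sub$mask)] -
        r2[match(without, sub$mask)]
      incs <- c(incs, mean(level_incs))
    }
    expect_equal(part$individual[j], mean(incs), tolerance = 1e-10)
    expect_equal(part$unique[j],
                 r2[sub$mask == 7] - r2[sub$mask == 7 - bit],
                 tolerance = 1e-12)
  }
  expect_equal(sum(part$individual), attr(part, "r2_full"), tolerance = 1e-10)
  expect_equal(sum(part$individual_percent), 100, tolerance = 1e-8)
})

test_that("a single group owns the whole marginal R2", {
  prep <- small_prep(seed = 23, n_species = 120)
  part <- hierarchical_partition(prep$table, groups = list(GD = "gd"),
                                 weights = prep$table$weight)
  expect_equal(part$individual, attr(part, "r2_full"))
  expect_equal(part$average_share, 0)
})

test_that("orthogonal predictors share no variance in the linear limit", {
  # modest additive effects of two orthogonalised covariates on a common
  # noise floor: omitting one group barely perturbs the R2 denominator,
  # so shared contributions vanish
  cfg <- simulation_config(seed = 24, n_species = 1500, class_sd = 0,
                           true_coefficients = c(intercept = 0.3, gd = 0.15,
                                                 vis = 0.15))
  tab <- generate_dataset(cfg)
  prep <- preprocess_table(tab)
  # orthogonalise vis_z against gd_z so the two groups cannot overlap
  prep$table$vis_z <- residuals(lm(vis_z ~ gd_z, data = prep$table))
  prep$table$vis_z <- prep$table$vis_z / sd(prep$table$vis_z)
  part <- hierarchical_partition(prep$table,
                                 groups = list(GD = "gd", VIS = "vis"),
                                 weights = rep(1, nrow(prep$table)))
  expect_lt(max(abs(part$average_share)), 0.01)
  expect_equal(part$individual, part$unique, tolerance = 0.05)
})

test_that("group order does not affect the partition", {
  prep <- small_prep(seed = 25, n_species = 150)
  g1 <- list(GD = "gd", VIS = "vis", "GD:VIS" = "gd_vis")
  p1 <- hierarchical_partition(prep$table, groups = g1,
                               weights = prep$table$weight)
  p2 <- hierarchical_partition(prep$table, groups = rev(g1),
                               weights = prep$table$weight)
  m <- match(p1$group, p2$group)
  expect_equal(p1$individual, p2$individual[m], tolerance = 1e-8)
  expect_equal(p1$unique, p2$unique[m], tolerance = 1e-8)
})

test_that("variable contributions aggregate across interaction groups", {
  part <- data.frame(group = c("GD", "VIS", "POS", "GD:VIS", "GD:POS",
                               "VIS:POS", "GD:VIS:POS", "Methods"),
                     individual_percent = c(1.64, 2.50, 28.54, 4.33, 1.70,
                                            4.27, 2.28, 54.74))
  agg <- aggregate_variable_contribution(part, "GD")
  expect_equal(unname(agg["total"]), 9.95, tolerance = 1e-9)
  expect_equal(unname(agg["interaction"]), 8.31, tolerance = 1e-9)
  # with all interactions at zero the total is the main effect
  part0 <- part; part0$individual_percent[4:7] <- 0
  expect_equal(unname(aggregate_variable_contribution(part0, "GD")["total"]),
               1.64)
  # hand-built arithmetic for another variable
  agg2 <- aggregate_variable_contribution(part, "VIS")
  expect_equal(unname(agg2["total"]), 2.50 + 4.33 + 4.27 + 2.28)
  expect_error(aggregate_variable_contribution(part, "CLASS"), "unknown")
})

test_that("residual tests detect planted latitude signal and not noise", {
  # null regime: latitude plays no role in the generative model
  cfg0 <- simulation_config(seed = 26, n_species = 2020)
  prep0 <- preprocess_table(generate_dataset(cfg0))
  rt0 <- residual_covariate_test(prep0$table,
                                 baseline = names(term_groups()),
                                 probe = "latitude",
                                 weights = prep0$table$weight)
  expect_lt(rt0$r2_residual_model, 0.01)
  # planted regime: latitude directly drives the log-mean
  lat <- list(mean = 45, sd = 12, vis_coef = 0, effect = 0.4)
  cfg1 <- simulation_config(seed = 27, n_species = 2020, latitude = lat)
  prep1 <- preprocess_table(generate_dataset(cfg1))
  rt1 <- residual_covariate_test(prep1$table,
                                 baseline = names(term_groups()),
                                 probe = "latitude",
                                 weights = prep1$table$weight)
  expect_gt(rt1$r2_residual_model, 0.05)
  # reversed direction: model terms explain latitude-model residuals
  rt2 <- residual_covariate_test(prep1$table,
                                 baseline = c("latitude", "Methods"),
                                 probe = setdiff(names(term_groups()),
                                                 "Methods"),
                                 weights = prep1$table$weight)
  expect_gt(rt2$r2_residual_model, 0.02)
  expect_error(residual_covariate_test(prep1$table,
                                       baseline = c("GD", "latitude"),
                                       probe = c("latitude")),
               "disjoint")
})
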