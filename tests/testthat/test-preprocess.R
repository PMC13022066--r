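test_that("directional filter keeps concordant rows only", {
  tab <- toy_table(10)
  tab$shift_velocity_signed <- c(1, -1, 2, 0.5, -0.3, 1, 1, -2, 3, 0.1)
  tab$isotherm_velocity_signed <- c(0.5, 0.5, 1, 1, 1, -1, 2, -1, 1, 1)
  # discordant: rows 2, 5, 6; concordant: 1,3,4,7,8,9,10
  out <- directional_filter(tab)
  expect_equal(nrow(out), 7)
  expect_equal(attr(out, "filter")$n_discordant, 3)
  expect_true(all(sign(out$shift_velocity_signed) ==
                    sign(out$isotherm_velocity_signed)))
})

test_that("zero velocities are dropped with a logged count", {
  tab <- toy_table(6)
  tab$shift_velocity_signed <- c(1, 0, 1, -1, 1, 1)
  tab$isotherm_velocity_signed <- c(1, 1, 0, -1, 1, 1)
  out <- directional_filter(tab)
  expect_equal(attr(out, "filter")$n_zero, 2)
  expect_equal(nrow(out), 4)
  # idempotent
  out2 <- directional_filter(out)
  expect_equal(out2[names(tab)], out[names(tab)], ignore_attr = TRUE)
})

test_that("rare-class filter applies a strict less-than-10 boundary", {
  mk <- function(sizes) {
    do.call(rbind, lapply(seq_along(sizes), function(k) {
      data.frame(species_id = sprintf("c%d_sp%d", k, seq_len(sizes[k])),
                 class_id = sprintf("class%d", k),
                 x = 1)
    }))
  }
  tab <- mk(c(9, 10))
  out <- filter_rare_classes(tab)
  expect_false("class1" %in% out$class_id)   # 9 species: removed
  expect_true("class2" %in% out$class_id)    # 10 species: kept
  tab2 <- mk(c(5, 10, 50))
  out2 <- filter_rare_classes(tab2)
  expect_setequal(unique(out2$class_id), c("class2", "class3"))
  expect_equal(nrow(out2), 60)
  # identity when all classes are large enough, and idempotence
  out3 <- filter_rare_classes(out2)
  expect_equal(out3, out2, ignore_attr = TRUE)
})

test_that("standardisation yields exact z-scores and round-trips", {
  prep <- standardize_covariates(toy_table(30, seed = 3))
  expect_lt(abs(mean(prep$table$gd_z)), 1e-12)
  expect_lt(abs(sd(prep$table$gd_z) - 1), 1e-12)
  expect_lt(abs(mean(prep$table$vis_z)), 1e-12)
  expect_lt(abs(sd(prep$table$vis_z) - 1), 1e-12)
  expect_equal(as.numeric(scale(c(1, 2, 3))), c(-1, 0, 1))
  x <- c(0.4, 1.7, 6.2)
  expect_equal(z_to_scale(prep$scaling, scale_to_z(prep$scaling, x)), x,
               tolerance = 1e-12)
  bad <- toy_table(5)
  bad$genetic_diversity <- 0.005
  expect_error(standardize_covariates(bad), "zero-variance")
})

test_that("weights implement the position-balancing formula", {
  # one focal species with 4 observations among 500 species at a position
  tab <- data.frame(species_id = c(rep("focal", 4), sprintf("s%03d", 1:499)),
                    position = "centroid")
  w <- compute_weights(tab)
  expect_equal(w$weight[1], 1 / (4 * 500 * 3))
  expect_equal(w$n_obs_sp_pos[1], 4)
  expect_equal(w$n_sp_pos[1], 500)
  # single species, single observation, one position
  w1 <- compute_weights(data.frame(species_id = "a", position = "leading"))
  expect_equal(w1$weight, 1 / 3)
})

test_that("weights conserve total mass by position", {
  prep <- small_prep(seed = 6, n_species = 200)
  w <- prep$table$weight
  expect_equal(sum(w), 1, tolerance = 1e-12)
  for (p in unique(prep$table$position))
    expect_equal(sum(w[prep$table$position == p]), 1 / 3, tolerance = 1e-12)
  # all observations of a species at a position carry identical weight
  key <- paste(prep$table$species_id, prep$table$position)
  expect_true(all(tapply(w, key, function(x) diff(range(x))) == 0))
  # two-position table sums to 2/3
  two <- prep$table[prep$table$position != "trailing", ]
  expect_equal(sum(compute_weights(two)$weight), 2 / 3, tolerance = 1e-12)
})

test_that("preprocessing reports stage counts and honours exclusions", {
  cfg <- simulation_config(seed = 61, n_species = 250)
  tab <- generate_dataset(cfg)
  drop_sp <- unique(tab$species_id)[1:2]
  prep <- preprocess_table(tab, min_species = 1, exclude_species = drop_sp)
  r <- prep$report
  expect_false(any(drop_sp %in% prep$table$species_id))
  expect_true(r$n_input_rows >= r$n_after_exclusions)
  expect_true(r$n_after_exclusions >= r$n_after_directional_filter)
  expect_true(r$n_after_directional_filter >= r$n_after_class_filter)
  expect_true(all(prep$scaling$sd > 0))
})
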