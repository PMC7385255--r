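test_that("Bray-Curtis matches its definition on hand cases", {
  expect_equal(bray_curtis(c(3, 1, 2), c(3, 1, 2)), 0)
  expect_equal(bray_curtis(c(1, 0, 2), c(0, 4, 0)), 1)   # disjoint supports
  expect_equal(bray_curtis(c(1, 1, 0), c(0, 1, 1)), 0.5) # 2/4
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
})

test_that("distance matrix agrees with the pairwise formula", {
  m <- matrix(c(10, 0, 5,
                2, 8, 5,
                0, 0, 15), nrow = 3,
              dimnames = list(paste0("o", 1:3), c("a", "b", "c")))
  d <- bc_distance_matrix(m)
  # dual route: scalar formula vs the matrix implementation
  for (i in 1:3) for (j in 1:3) {
    expected <- if (i == j) 0 else bray_curtis(m[, i], m[, j])
    expect_equal(d[i, j], expected, tolerance = 1e-12)
  }
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 3))
  # duplicated sample has zero off-diagonal distance
  d2 <- bc_distance_matrix(cbind(m, a2 = m[, "a"]))
  expect_equal(d2["a", "a2"], 0)
})

test_that("Bray-Curtis on percent profiles ignores uniform count rescaling", {
  set.seed(7)
  m <- matrix(rpois(40, 5) + 1, nrow = 8)
  pct <- sweep(m, 2, colSums(m), "/") * 100
  m10 <- m * 10
  pct10 <- sweep(m10, 2, colSums(m10), "/") * 100
  expect_equal(bray_curtis(pct[, 1], pct[, 2]),
               bray_curtis(pct10[, 1], pct10[, 2]), tolerance = 1e-12)
})

test_that("reference trajectories exclude the reference and warn on gaps", {
  sim <- generate_dataset(simulation_design(seed = 13))
  tb <- rarefy_counts(sim$table, "min", seed = 13)
  traj <- reference_trajectory(tb, reference = c(2013, 1))
  # 24 non-reference dates per fraction
  expect_equal(unname(table(traj$fraction_rank)), rep(24L, 6),
               ignore_attr = TRUE)
  expect_true(all(traj$bc > 0 & traj$bc <= 1))
  expect_false(any(traj$year == 2013 & traj$month == 1))
  expect_error(reference_trajectory(tb, c(2020, 1)), "not sampled")

  # drop the reference sample of one fraction: that fraction is skipped
  drop <- !(tb$meta$year == 2013 & tb$meta$month == 1 &
              tb$meta$fraction_rank == 3)
  tb2 <- subset_count_table(tb, samples = drop)
  expect_warning(t2 <- reference_trajectory(tb2, c(2013, 1)), "rank 3")
  expect_false(3 %in% t2$fraction_rank)
})

test_that("auto-selected reference is the maximum-gamma month", {
  sim <- generate_dataset(simulation_design(seed = 14))
  tb <- rarefy_counts(sim$table, "min", seed = 14)
  ps <- partition_series(tb)
  best <- ps[which.max(ps$gamma), ]
  traj <- reference_trajectory(tb)
  expect_equal(attr(traj, "reference"), c(best$year, best$month))
})

test_that("warm/cold period compositions are closed at 100 percent", {
  sim <- generate_dataset(simulation_design(seed = 15))
  pre <- preprocess_pipeline(sim$table, seed = 15)
  pc <- period_composition(pre$groups)
  sums <- tapply(pc$mean_percent, paste(pc$period, pc$fraction_rank), sum)
  expect_equal(as.numeric(sums), rep(100, 12), tolerance = 1e-9)
  expect_setequal(unique(pc$period), c("warm", "cold"))

  # a single month per period reduces to that month's composition
  one <- subset_count_table(sim$table,
                            samples = sim$table$meta$month %in% c(1, 7) &
                              sim$table$meta$year == 2012)
  g1 <- aggregate_taxonomy(one, "genus")
  pc1 <- period_composition(g1)
  jan <- g1$abundance[, g1$meta$month == 1 & g1$meta$fraction_rank == 1]
  got <- pc1$mean_percent[pc1$period == "cold" & pc1$fraction_rank == 1]
  expect_equal(got, unname(jan), tolerance = 1e-12)
})

test_that("warm-period expectation shifts are recovered from counts", {
  # one group whose warm expectation doubles its cold expectation in one
  # fraction: the recovered warm/cold ratio should be near 2
  groups <- default_group_specs(amplitude_grows_with_size = FALSE)
  groups <- lapply(groups, function(g) { g$seasonal_amplitude[] <- 0; g })
  # target group: amplitude 1/3 in fraction 1 peaked mid-warm-period gives
  # (1 + 1/3)/(1 - 1/3) = 2 between its peak and trough
  groups[[1]]$seasonal_amplitude[1] <- 1 / 3
  groups[[1]]$peak_ordinal <- 196  # mid-July
  design <- simulation_design(groups = groups, dispersion = 1e6,
                              depth_range = c(20000L, 20000L), seed = 31)
  sim <- generate_dataset(design)
  tname <- groups[[1]]$name
  tr <- sim$truth[sim$truth$group == tname, ]
  meta <- sim$table$meta[match(tr$sample_id, sim$table$meta$sample_id), ]
  f1 <- meta$fraction_rank == 1
  peak <- tr$expected_proportion[f1 & meta$month == 7]
  trough <- tr$expected_proportion[f1 & meta$month == 1]
  truth_ratio <- mean(peak) / mean(trough)
  # the multiplicative modulation doubles the group before renormalization,
  # so the truth ratio sits between the renormalized floor and 2
  expect_gt(truth_ratio, 1.4)
  expect_lte(truth_ratio, 2 + 1e-9)
  # and the counts recover the truth-record ratio within sampling error
  g <- aggregate_taxonomy(sim$table, "genus")
  obs_ratio <- mean(g$abundance[tname, f1 & meta$month == 7]) /
    mean(g$abundance[tname, f1 & meta$month == 1])
  expect_equal(obs_ratio, truth_ratio, tolerance = 0.2)
})
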