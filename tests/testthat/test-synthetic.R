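test_that("day length obeys the sunrise-equation limiting cases", {
  # equatorial symmetry: 12 h on any date without refraction
  expect_equal(day_length(0, c(1, 100, 172, 300), refraction = FALSE),
               rep(12, 4), tolerance = 1e-9)
  # polar day clamps at 24 h
  expect_equal(day_length(80, 172), 24)
  # polar night clamps at 0 h
  expect_equal(day_length(80, 355), 0)
  # refraction lengthens the day
  expect_gt(day_length(41.67, 100, TRUE), day_length(41.67, 100, FALSE))
})

test_that("SST model reproduces the site climatology extremes", {
  t <- 1:365
  sst <- sst_model(t)
  expect_equal(max(sst), 24.1, tolerance = 1e-9)
  # the integer-ordinal minimum sits half a day off the continuous trough
  expect_equal(min(sst), 12.5, tolerance = 1e-4)
  expect_equal(which.max(sst), 227)
  # zero amplitude is constant
  expect_equal(sst_model(t, harmonic_params(18.3, 0, 0)), rep(18.3, 365))
})

test_that("environmental series are seeded and noise-free when asked", {
  design <- simulation_design(seed = 11)
  e1 <- generate_env_series(design)
  e2 <- generate_env_series(design)
  expect_identical(e1, e2)                 # same seed, identical tables
  e0 <- generate_env_series(design, noise_sd = 0)
  expect_equal(e0$sst_c, sst_model(e0$ordinal_date), tolerance = 1e-12)
  expect_equal(e0$day_length_h, day_length(41.67, e0$ordinal_date))
  expect_equal(nrow(e1), 25)
})

test_that("generate_dataset is deterministic and respects depths", {
  design <- simulation_design(seed = 5)
  s1 <- generate_dataset(design)
  s2 <- generate_dataset(design)
  expect_identical(s1$table$counts, s2$table$counts)
  s3 <- generate_dataset(simulation_design(seed = 6))
  expect_false(identical(s1$table$counts, s3$table$counts))
  depths <- colSums(s1$table$counts)
  expect_true(all(depths >= design$depth_range[1] &
                    depths <= design$depth_range[2]))
  expect_equal(ncol(s1$table$counts), 25 * 6)
  # truth record covers every sample and sums to 1 over groups
  agg <- tapply(s1$truth$expected_proportion, s1$truth$sample_id, sum)
  expect_equal(as.numeric(agg), rep(1, 150), tolerance = 1e-12)
})

test_that("zero-amplitude, low-dispersion-noise design recovers baselines", {
  # amplitudes all zero and near-multinomial sampling: observed group
  # proportions should match the baseline expectation within multinomial
  # standard error
  groups <- default_group_specs(amplitude_grows_with_size = FALSE)
  groups <- lapply(groups, function(g) {
    g$seasonal_amplitude[] <- 0
    g
  })
  design <- simulation_design(groups = groups, dispersion = 1e7,
                              depth_range = c(20000L, 20000L), seed = 21)
  sim <- generate_dataset(design)
  grp <- aggregate_taxonomy(sim$table, "genus")
  # per (sample, group): |obs% - exp%| within 5 multinomial SEs
  exp_prop <- matrix(sim$truth$expected_proportion,
                     nrow = length(design$groups),
                     dimnames = list(sim$truth$group[seq_along(design$groups)],
                                     unique(sim$truth$sample_id)))
  obs <- grp$abundance[rownames(exp_prop), colnames(exp_prop)] / 100
  se <- sqrt(exp_prop * (1 - exp_prop) / 20000)
  expect_true(all(abs(obs - exp_prop) <= 5 * se + 1e-6))
  # with zero amplitude the expected composition within a fraction is
  # month-invariant (columns 1 and 25 are the same fraction, 2 years apart)
  expect_equal(unname(exp_prop[, 1]), unname(exp_prop[, 25]),
               tolerance = 1e-12)
})

test_that("default group amplitudes are non-decreasing with fraction rank", {
  for (g in default_group_specs(amplitude_grows_with_size = TRUE)) {
    expect_false(is.unsorted(g$seasonal_amplitude))
    expect_true(all(g$seasonal_amplitude >= 0 & g$seasonal_amplitude <= 1))
  }
})

test_that("warm-cold compositional contrast grows with fraction size", {
  # simulation oracle: mean Bray-Curtis between warm and cold months,
  # per fraction, averaged over replicates, is non-decreasing in rank 1..5
  # when amplitude grows with size
  reps <- lapply(1:5, function(s) {
    sim <- generate_dataset(simulation_design(seed = 100 + s))
    tb <- sim$table
    meta <- tb$meta
    vapply(sort(unique(meta$fraction_rank)), function(fr) {
      warm <- which(meta$fraction_rank == fr & meta$month %in% 5:10)
      cold <- which(meta$fraction_rank == fr & meta$month %in% c(11:12, 1:4))
      pairs <- expand.grid(warm, cold)
      mean(mapply(function(i, j)
        bray_curtis(tb$counts[, i], tb$counts[, j]),
        pairs[[1]], pairs[[2]]))
    }, numeric(1))
  })
  avg <- Reduce(`+`, reps) / length(reps)
  expect_false(is.unsorted(avg[1:5]))
})
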