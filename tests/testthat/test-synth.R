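test_that("populations regenerate bit-identically from config and seed", {
  cfg <- synth_config(seed = 7, n_cells = 200)
  a <- generate_population(cfg)
  b <- generate_population(cfg)
  expect_identical(a$cells, b$cells)
  expect_identical(a$truth, b$truth)
  expect_identical(generate_profiles(a), generate_profiles(b))
  # a different seed changes the draw
  c2 <- generate_population(synth_config(seed = 8, n_cells = 200))
  expect_false(identical(a$cells$length_um, c2$cells$length_um))
  # generation does not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(generate_population(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("config validation catches inconsistent parameters", {
  expect_error(synth_config(seed = NULL), "seed")
  expect_error(synth_config(t_period = 200, seed = 1), "t_period")
  expect_error(synth_config(s_period = -1, seed = 1), "s_period")
  expect_error(synth_config(length_cv = -0.1, seed = 1), "CV")
})

test_that("class fractions match the age-distribution formula", {
  pop <- slow_population()
  cfg <- attr(pop, "config")
  n <- nrow(pop$cells)
  f_con_expected <- fraction_from_terminal_period(cfg$t_period, cfg$td)
  f_two_expected <- fraction_from_terminal_period(cfg$s_period, cfg$td)
  f_con <- mean(!is.na(pop$cells$constriction_diameter_um))
  f_two <- mean(pop$cells$n_nucleoids == 2)
  # binomial 4 sigma around the target fractions
  expect_lt(abs(f_con - f_con_expected),
            4 * sqrt(f_con_expected * (1 - f_con_expected) / n))
  expect_lt(abs(f_two - f_two_expected),
            4 * sqrt(f_two_expected * (1 - f_two_expected) / n))
})

test_that("population-mean DNA matches the closed form at both growth rates", {
  slow <- slow_population()
  fast <- fast_population()
  expect_equal(mean(slow$truth$equivalents),
               mean_genome_equivalents(122, 70, 40), tolerance = 0.05)
  expect_equal(mean(fast$truth$equivalents),
               mean_genome_equivalents(29, 53, 25), tolerance = 0.03)
})

test_that("reference population calibration round-trips", {
  ref <- generate_reference_population(1000, 100, peak_cv = 0.1,
                                       fraction_2c = 0.4, seed = 13)
  expect_equal(calibrate_fluorescence(ref), 100, tolerance = 0.03)
  # noise-free reference degenerates to two exact spikes
  spikes <- generate_reference_population(100, 100, peak_cv = 0,
                                          fraction_2c = 0.4, seed = 13)
  expect_setequal(unique(spikes), c(100, 200))
  # fully 1C reference is unimodal (mode estimation is noisier with a
  # single broad peak; 4% band)
  uni <- generate_reference_population(2000, 80, peak_cv = 0.1,
                                       fraction_2c = 0, seed = 14)
  expect_equal(calibrate_fluorescence(uni), 80, tolerance = 0.04)
})

test_that("a noise-free population exposes the calibration factor exactly", {
  cfg <- synth_config(seed = 5, n_cells = 50, fluor_cv = 0)
  pop <- generate_population(cfg)
  expect_equal(pop$cells$fluor_au / pop$truth$equivalents,
               rep(100, 50), tolerance = 1e-9)
})

test_that("profiles integrate to the cell's fluorescence and encode geometry", {
  pop <- fast_population()
  prof <- fast_profiles()
  cells <- pop$cells
  ids <- sample(cells$id, 100)
  for (i in ids) {
    df <- prof[prof$id == i, ]
    integral <- sum(diff(df$position_um) *
                      (head(df$fluor_au, -1) + tail(df$fluor_au, -1)) / 2)
    expect_equal(integral, cells$fluor_au[cells$id == i], tolerance = 0.01)
  }
  # one-nucleoid cells give unimodal profiles, two-nucleoid (well separated)
  # cells drop below the 20% threshold between pulses
  truth <- pop$truth
  sep_ids <- truth$id[truth$two_nucleoids &
                        truth$gap_um > 3 * attr(pop, "config")$profile_spacing_um]
  one_ids <- truth$id[!truth$two_nucleoids]
  m1 <- nucleoid_metrics(prof$position_um[prof$id == one_ids[1]],
                         prof$fluor_au[prof$id == one_ids[1]])
  expect_equal(m1$count, 1)
  spacing <- attr(pop, "config")$profile_spacing_um
  for (i in sep_ids[1:25]) {
    df <- prof[prof$id == i, ]
    m <- nucleoid_metrics(df$position_um, df$fluor_au)
    expect_equal(m$count, 2)
    # gap and centre-of-mass separation recovered to about a sample spacing
    expect_equal(m$gap_distance, truth$gap_um[truth$id == i],
                 tolerance = 2.5 * spacing / truth$gap_um[truth$id == i])
    expect_equal(m$com_distance, truth$com_separation_um[truth$id == i],
                 tolerance = 0.06)
  }
})

test_that("the analysis pipeline recovers the generator's ground truth", {
  pop <- fast_population()
  cfg <- attr(pop, "config")
  ref <- generate_reference_population(1500, cfg$au_per_equivalent,
                                       peak_cv = 0.1, fraction_2c = 0.4,
                                       seed = 77)
  report <- analyze_population(pop$cells, td = cfg$td, reference = ref,
                               profiles = fast_profiles())
  # periods within 10%
  t_est <- report$periods$duration_min[report$periods$period == "constriction"]
  s_est <- report$periods$duration_min[report$periods$period == "segregation"]
  expect_equal(t_est, cfg$t_period, tolerance = 0.10)
  expect_equal(s_est, cfg$s_period, tolerance = 0.10)
  # calibration factor within 3%, mean DNA within 5% of the closed form
  expect_equal(report$au_per_equivalent, cfg$au_per_equivalent,
               tolerance = 0.03)
  expect_equal(report$mean_equivalents,
               mean_genome_equivalents(cfg$td, cfg$c_period, cfg$d_period),
               tolerance = 0.05)
  # division asymmetry CV within 0.5 percentage points of the configured 4.9%
  expect_lt(abs(report$kl_cv - 100 * cfg$k_cv), 0.5)
})

test_that("the large/small DNA contrast is stronger at fast growth", {
  ref <- generate_reference_population(1500, 100, peak_cv = 0.1,
                                       fraction_2c = 0.4, seed = 77)
  fast_rep <- analyze_population(fast_population()$cells, td = 29,
                                 reference = ref)
  slow_rep <- analyze_population(slow_population()$cells, td = 122,
                                 reference = ref)
  fast_diff <- fast_rep$dna_comparison$percent_difference
  slow_diff <- slow_rep$dna_comparison$percent_difference
  expect_gt(fast_diff, 0)
  expect_gt(fast_diff, slow_diff)
  expect_lt(fast_rep$dna_comparison$p_value, 1e-4)
  # nucleoid separation is also more advanced in the large cells
  fast_prof_rep <- analyze_population(fast_population()$cells, td = 29,
                                      reference = ref,
                                      profiles = fast_profiles())
  expect_gt(fast_prof_rep$distance_comparison$percent_difference, 0)
})
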