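test_that("modal background subtraction recovers the clean signal", {
  # constant background plus a signal bump
  profile <- c(rep(50, 40), 50 + c(10, 80, 100, 80, 10), rep(50, 40))
  corrected <- subtract_background(profile)
  expect_equal(attr(corrected, "background"), 50)
  expect_equal(max(corrected), 100)
  expect_equal(sum(corrected > 0), 5)
  # all-background input comes back (almost) all zero
  flat <- subtract_background(rep(37, 100))
  expect_true(all(flat == 0))
  # image-style histogram with known mode 37: integrated signal recovered
  set.seed(11)
  img <- c(round(rnorm(5000, 37, 1.5)), 37 + rpois(300, 40))
  bg <- modal_value(img)
  expect_equal(bg, 37)
  corrected_img <- subtract_background(img, bg)
  true_signal <- sum(img[5001:5300] - 37)
  expect_equal(sum(corrected_img[5001:5300]), true_signal, tolerance = 0.01)
  expect_error(subtract_background(numeric()), "empty")
})

test_that("calibration finds the one-chromosome peak of a reference population", {
  ref <- generate_reference_population(1500, 100, peak_cv = 0.1,
                                       fraction_2c = 0.4, seed = 31)
  expect_equal(calibrate_fluorescence(ref), 100, tolerance = 0.03)
  # unimodal reference: its single mode
  uni <- generate_reference_population(800, 100, peak_cv = 0.08,
                                       fraction_2c = 0, seed = 32)
  expect_equal(calibrate_fluorescence(uni), 100, tolerance = 0.03)
  # applying the factor is plain division
  expect_equal(154 / calibrate_fluorescence(ref), 1.54, tolerance = 0.05)
  # degenerate references fail loudly
  expect_error(calibrate_fluorescence(numeric()), "calibration failure")
  expect_error(calibrate_fluorescence(rep(5, 100)), "calibration failure")
})

test_that("constriction classification uses the mean waist, strictly", {
  cells <- tibble::tibble(
    id = letters[1:5], length_um = c(3, 4, 5, 2, 6),
    constriction_diameter_um = c(0.3, 0.5, 0.7, NA, NA)
  )
  out <- classify_constriction(cells)
  expect_equal(attr(out, "mean_constriction_diameter"), 0.5)
  expect_equal(
    as.character(out$constriction_class),
    c("deeply_constricted", "constricted", "constricted", "none", "none")
  )
  # no constricting cells at all
  none <- classify_constriction(tibble::tibble(
    id = "a", length_um = 3, constriction_diameter_um = NA_real_
  ))
  expect_equal(as.character(none$constriction_class), "none")
})

test_that("splitting at the mean length sends ties to the large group", {
  cells <- tibble::tibble(id = 1:3, length_um = c(3, 4, 5))
  out <- split_by_mean_length(cells)
  expect_equal(as.character(out$size_group), c("small", "large", "large"))
  # degenerate: all equal lengths -> everything is 'large'
  same <- split_by_mean_length(tibble::tibble(id = 1:3, length_um = rep(4, 3)))
  expect_true(all(same$size_group == "large"))
  expect_error(split_by_mean_length(tibble::tibble(id = 1, length_um = 3)),
               "at least 2")
})

test_that("group comparison reproduces the published summary contrasts", {
  # slow growth, DNA per nucleoid: 0.36 +/- 0.03 (24) vs 0.38 +/- 0.03 (27)
  slow <- compare_groups_summary(0.36, 0.03, 24, 0.38, 0.03, 27)
  expect_equal(round(slow$percent_difference), 6)
  # fast growth, DNA per nucleoid: 0.62 +/- 0.08 (63) vs 0.75 +/- 0.12 (56)
  fast <- compare_groups_summary(0.62, 0.08, 63, 0.75, 0.12, 56)
  expect_equal(fast$t, 6.87, tolerance = 0.01)
  expect_lt(fast$p_value, 1e-8)
  # fast manual nucleoid distances: 0.74 vs 0.89 um is a 20% increase
  dist <- compare_groups_summary(0.74, 0.12, 63, 0.89, 0.14, 56)
  expect_equal(round(dist$percent_difference), 20)
})

test_that("summary-statistic Welch test matches t.test on moment-matched samples", {
  set.seed(21)
  cases <- list(
    c(0.36, 0.03, 24, 0.38, 0.03, 27),
    c(0.62, 0.08, 63, 0.75, 0.12, 56),
    c(1.26, 0.33, 25, 1.72, 0.21, 26)
  )
  for (cs in cases) {
    small <- moment_matched_sample(cs[3], cs[1], cs[2])
    large <- moment_matched_sample(cs[6], cs[4], cs[5])
    from_summary <- compare_groups_summary(cs[1], cs[2], cs[3],
                                           cs[4], cs[5], cs[6])
    from_raw <- compare_groups(small, large)
    expect_equal(from_raw$t, from_summary$t, tolerance = 1e-6)
    expect_equal(from_raw$df, from_summary$df, tolerance = 1e-6)
    expect_equal(from_raw$p_value, from_summary$p_value, tolerance = 1e-6)
    # pooled variant agrees with t.test(var.equal = TRUE) as well
    pooled_raw <- compare_groups(small, large, var_equal = TRUE)
    pooled_sum <- compare_groups_summary(cs[1], cs[2], cs[3],
                                         cs[4], cs[5], cs[6],
                                         var_equal = TRUE)
    expect_equal(pooled_raw$t, pooled_sum$t, tolerance = 1e-6)
  }
  # identical groups: no difference, p = 1
  x <- c(1, 2, 3, 4)
  same <- compare_groups(x, x)
  expect_equal(same$percent_difference, 0)
  expect_equal(same$p_value, 1)
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})

test_that("tidy and glance methods summarise a comparison", {
  cmp <- compare_groups_summary(0.62, 0.08, 63, 0.75, 0.12, 56)
  td <- tidy(cmp)
  expect_equal(td$group, c("small", "large"))
  expect_equal(td$n, c(63, 56))
  gl <- glance(cmp)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$method, "Welch")
})

test_that("nucleoid metrics measure two rectangular pulses exactly", {
  x <- seq(0, 4, by = 0.01)
  fl <- as.numeric(abs(x - 1) <= 0.5) + as.numeric(abs(x - 3) <= 0.5)
  m <- nucleoid_metrics(x, fl)
  expect_equal(m$count, 2)
  expect_equal(m$com_distance, 2.0, tolerance = 1e-6)
  expect_equal(m$gap_distance, 1.0, tolerance = 0.011)
  expect_equal(m$nucleoids$length_um, c(1, 1), tolerance = 0.011)
  # single pulse: one nucleoid, no distances
  single <- nucleoid_metrics(x, as.numeric(abs(x - 2) <= 0.5))
  expect_equal(single$count, 1)
  expect_true(is.na(single$gap_distance))
  expect_error(nucleoid_metrics(x, rep(0, length(x))), "signal")
})

test_that("collective profiles average resampled cells pointwise", {
  profiles <- dplyr::bind_rows(
    tibble::tibble(id = "a", position_um = seq(0, 2, by = 0.1),
                   fluor_au = 2, diameter_um = 0.6),
    tibble::tibble(id = "b", position_um = seq(0, 3.4, by = 0.2),
                   fluor_au = 4, diameter_um = 0.8)
  )
  cp <- collective_profile(profiles)
  expect_equal(nrow(cp), 100)
  expect_true(all(cp$mean_fluor_au == 3))
  expect_true(all(abs(cp$mean_diameter_um - 0.7) < 1e-9))
  # a single cell yields its own resampled profile
  one <- collective_profile(dplyr::filter(profiles, id == "a"))
  expect_true(all(one$mean_fluor_au == 2))
  # missing ids are named in the error
  expect_error(collective_profile(profiles, ids = c("a", "zz")), "zz")
})

test_that("profile maps are length-sorted with stable ties", {
  profiles <- dplyr::bind_rows(
    tibble::tibble(id = "c3", position_um = seq(0, 4, by = 0.5), fluor_au = 3),
    tibble::tibble(id = "c1", position_um = seq(0, 2, by = 0.5), fluor_au = 1),
    tibble::tibble(id = "c2", position_um = seq(0, 3, by = 0.5), fluor_au = 2),
    tibble::tibble(id = "c2b", position_um = seq(0, 3, by = 0.5), fluor_au = 9)
  )
  pm <- profile_map(profiles)
  expect_equal(attr(pm, "ids"), c("c1", "c2", "c2b", "c3"))
  # columns bottom-aligned, padded with NA above
  expect_equal(pm[1, ], c(1, 2, 9, 3))
  expect_true(is.na(pm[9, 1]) && !is.na(pm[9, 4]))
  # monotone top envelope: number of finite rows increases with length
  heights <- colSums(!is.na(pm))
  expect_true(all(diff(heights) >= 0))
})

test_that("K(L) asymmetry distribution and its CV", {
  # perfectly midcell divisions: CV 0
  mid <- tibble::tibble(id = 1:4, length_um = 4, division_position_um = 2)
  expect_equal(kl_distribution(mid)$cv, 0)
  # known K values {0.45, 0.55, 0.5, 0.5} (pooled with their complements)
  cells <- tibble::tibble(
    id = 1:4, length_um = 10,
    division_position_um = c(4.5, 5.5, 5, 5)
  )
  res <- kl_distribution(cells)
  expect_equal(res$cv, 100 * sd(c(0.45, 0.55, 0.5, 0.5,
                                  0.55, 0.45, 0.5, 0.5)) / 0.5,
               tolerance = 1e-9)
  expect_equal(round(res$cv, 1), 7.6)
  # division plane from the diameter-profile minimum
  prof <- tibble::tibble(
    id = rep("x", 41), position_um = seq(0, 4, by = 0.1),
    diameter_um = 0.8 - 0.3 * exp(-((seq(0, 4, by = 0.1) - 1.8) / 0.3)^2)
  )
  one <- tibble::tibble(id = "x", length_um = 4)
  res2 <- kl_distribution(one, profiles = prof)
  expect_equal(sort(res2$k), c(0.45, 0.55), tolerance = 1e-6)
})

test_that("terminal periods are estimated from class fractions", {
  cells <- tibble::tibble(
    id = seq_len(100), length_um = 3,
    constriction_diameter_um = c(rep(0.4, 9), rep(NA, 91)),
    n_nucleoids = c(rep(2L, 17), rep(1L, 83))
  )
  est <- estimate_periods(cells, td = 122)
  t_row <- est[est$period == "constriction", ]
  s_row <- est[est$period == "segregation", ]
  expect_equal(t_row$fraction, 0.09)
  expect_equal(round(t_row$duration_min), 15)
  expect_equal(s_row$fraction, 0.17)
  expect_equal(s_row$duration_min, 122 * log2(1.17), tolerance = 1e-9)
  # no information at all errors
  expect_error(estimate_periods(tibble::tibble(id = 1, length_um = 3), 122),
               "no constriction")
})
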