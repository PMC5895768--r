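#' Configuration for a synthetic steady-state population
#'
#' Collects every parameter of the generator: the growth condition, the
#' terminal periods, the newborn length and its variability, division
#' asymmetry, fluorescence calibration and noise, and the sampling of
#' axial profiles. Defaults are the slow-growth (succinate, Td = 122
#' min) condition; [synth_config_fast()] gives the fast-growth
#' (glucose + amino acids, Td = 29 min) preset.
#'
#' @param td,c_period,d_period Growth condition, minutes.
#' @param t_period Constriction period T, minutes (visible waist during
#'   the last T minutes of the cycle).
#' @param s_period Segregation period S, minutes (two separated
#'   nucleoids during the last S minutes).
#' @param lb_star Mean newborn length, micrometres.
#' @param delta_l Adder increment, micrometres (defaults to `lb_star`,
#'   the steady-state anchoring).
#' @param diameter_um Mean cell diameter, micrometres.
#' @param diameter_cv Fractional CV of cell diameter.
#' @param length_cv Fractional CV of newborn length (0.15 as observed).
#' @param k_cv Fractional CV of the K(L) division-asymmetry
#'   distribution (0.095 slow, 0.049 fast).
#' @param au_per_equivalent Integrated fluorescence of one chromosome
#'   equivalent, arbitrary units.
#' @param fluor_cv Fractional CV of multiplicative fluorescence
#'   measurement noise.
#' @param background_au Constant background added to profile samples.
#' @param nucleoid_fraction Fraction of the (half-)cell length occupied
#'   by a nucleoid in the profile model.
#' @param profile_spacing_um Axial sample spacing of generated
#'   profiles, micrometres.
#' @param n_cells Number of cells to generate.
#' @param seed Integer seed; mandatory, so every population is exactly
#'   regenerable.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(td = 122, c_period = 70, d_period = 40,
                         t_period = terminal_period_from_fraction(0.09, td),
                         s_period = terminal_period_from_fraction(0.17, td),
                         lb_star = 2.0, delta_l = lb_star,
                         diameter_um = 0.63, diameter_cv = 0.08,
                         length_cv = 0.15, k_cv = 0.095,
                         au_per_equivalent = 100, fluor_cv = 0.05,
                         background_au = 0, nucleoid_fraction = 0.45,
                         profile_spacing_um = 0.05,
                         n_cells = 2000L, seed = NULL) {
  if (is.null(seed)) abort("`seed` is mandatory for a synth_config.")
  cfg <- list(
    td = td, c_period = c_period, d_period = d_period,
    t_period = t_period, s_period = s_period,
    lb_star = lb_star, delta_l = delta_l,
    diameter_um = diameter_um, diameter_cv = diameter_cv,
    length_cv = length_cv, k_cv = k_cv,
    au_per_equivalent = au_per_equivalent, fluor_cv = fluor_cv,
    background_au = background_au, nucleoid_fraction = nucleoid_fraction,
    profile_spacing_um = profile_spacing_um,
    n_cells = as.integer(n_cells), seed = as.integer(seed)
  )
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

#' @rdname synth_config
#' @param ... Overrides passed on to [synth_config()].
#' @export
synth_config_fast <- function(seed, ...) {
  args <- modifyList(
    list(
      td = 29, c_period = 53, d_period = 25,
      t_period = terminal_period_from_fraction(0.26, 29),
      s_period = terminal_period_from_fraction(0.74, 29),
      lb_star = 2.6, diameter_um = 0.88, diameter_cv = 0.06,
      k_cv = 0.049, seed = seed
    ),
    list(...)
  )
  do.call(synth_config, args)
}

validate_synth_config <- function(cfg) {
  check_positive(cfg$td, "td")
  check_positive(cfg$c_period, "c_period")
  if (cfg$d_period < 0) abort("`d_period` must be non-negative.")
  if (cfg$t_period < 0 || cfg$t_period > cfg$td) {
    abort("`t_period` must lie in [0, td].")
  }
  if (cfg$s_period < 0 || cfg$s_period > cfg$td) {
    abort("`s_period` must lie in [0, td].")
  }
  check_positive(cfg$lb_star, "lb_star")
  check_positive(cfg$delta_l, "delta_l")
  cvs <- c(cfg$diameter_cv, cfg$length_cv, cfg$k_cv, cfg$fluor_cv)
  if (any(cvs < 0)) abort("all CVs must be non-negative.")
  if (cfg$n_cells < 1L) abort("`n_cells` must be positive.")
  invisible(cfg)
}

# lognormal draws with a given mean and fractional CV; cv = 0 degenerates
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sigma2 <- log(1 + cv^2)
  exp(rnorm(n, log(mean) - sigma2 / 2, sqrt(sigma2)))
}

# adder-consistent division schedule (ages of this cell's and the tracked
# descendants' divisions) for a cell born at length lb; descendants follow
# the adder map, halving the newborn deviation each generation
adder_schedule <- function(lb, delta_l, td, n_divisions) {
  ages <- numeric(n_divisions)
  t_acc <- 0
  for (j in seq_len(n_divisions)) {
    t_acc <- t_acc + division_time(lb, delta_l, td)
    ages[j] <- t_acc
    lb <- (lb + delta_l) / 2
  }
  ages
}

#' Generate a synthetic steady-state cell population
#'
#' Emulates a single fixed-and-stained snapshot of an exponentially
#' growing population. Ages are drawn from the steady-state age
#' distribution; each cell's newborn length is lognormal around
#' `lb_star`; lengths grow exponentially; cells in the last `t_period`
#' minutes of their cycle constrict, with the waist shrinking linearly
#' to zero; cells in the last `s_period` minutes carry two nucleoids
#' whose separation grows linearly towards L/2. DNA content follows the
#' multifork replication model conditioned on the cell's own
#' adder-consistent division schedule (initiation a fixed C+D before
#' each division it feeds), scaled to fluorescence by
#' `au_per_equivalent` with multiplicative lognormal noise.
#'
#' @param config A [synth_config()].
#' @return A list of class `synth_population` with tibbles `cells`
#'   (columns `id`, `length_um`, `diameter_um`,
#'   `constriction_diameter_um`, `fluor_au`, `n_nucleoids`,
#'   `division_position_um`) and `truth` (per-cell ground truth: age,
#'   division age, true equivalents, class labels, nucleoid geometry),
#'   plus the config as attribute `config`.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(config$seed)

  n <- config$n_cells
  age_frac <- sample_ages(n, config$td) / config$td
  lb <- rlnorm_mean_cv(n, config$lb_star, config$length_cv)
  tau <- division_time(lb, config$delta_l, config$td)
  age <- age_frac * tau
  length_um <- lb * 2^(age / config$td)
  diameter <- rlnorm_mean_cv(n, config$diameter_um, config$diameter_cv)

  # DNA from the per-cell adder-consistent schedule
  n_div <- ceiling((config$c_period + config$d_period) / config$td) + 2L
  equivalents <- vapply(seq_len(n), function(i) {
    sched <- adder_schedule(lb[i], config$delta_l, config$td, n_div)
    genome_equivalents(state_from_schedule(
      age[i], sched, config$c_period, config$d_period
    ))
  }, numeric(1))
  fluor <- equivalents * config$au_per_equivalent *
    rlnorm_mean_cv(n, 1, config$fluor_cv)

  # terminal classes from residual time to the cell's own division
  residual <- tau - age
  constricting <- residual < config$t_period
  constr_diam <- ifelse(constricting, diameter * residual / config$t_period,
                        NA_real_)
  two_nucleoids <- residual < config$s_period

  # division plane: K asymmetry for constricting cells, midcell otherwise
  k <- rep(0.5, n)
  if (any(constricting)) {
    k[constricting] <- rnorm(sum(constricting), 0.5, 0.5 * config$k_cv)
  }
  division_position <- ifelse(constricting, k * length_um, NA_real_)

  # nucleoid geometry: separation of intensity centres grows linearly
  # through the S window from 0 to half the cell length
  sep_frac <- pmax(0, 1 - residual / config$s_period)
  com_sep <- ifelse(two_nucleoids, sep_frac * length_um / 2, 0)
  nuc_center <- ifelse(constricting, k, 0.5) * length_um
  nuc_len <- config$nucleoid_fraction * length_um /
    ifelse(two_nucleoids, 2, 1)
  gap <- ifelse(two_nucleoids, com_sep - nuc_len, NA_real_)

  cells <- tibble::tibble(
    id = sprintf("cell%04d", seq_len(n)),
    length_um = length_um,
    diameter_um = diameter,
    constriction_diameter_um = constr_diam,
    fluor_au = fluor,
    n_nucleoids = ifelse(two_nucleoids, 2L, 1L),
    division_position_um = division_position
  )
  truth <- tibble::tibble(
    id = cells$id,
    age_min = age,
    division_age_min = tau,
    lb_um = lb,
    equivalents = equivalents,
    constricting = constricting,
    two_nucleoids = two_nucleoids,
    k = ifelse(constricting, k, NA_real_),
    nucleoid_center_um = nuc_center,
    com_separation_um = com_sep,
    nucleoid_length_um = nuc_len,
    gap_um = gap
  )
  structure(
    list(cells = cells, truth = truth),
    config = config,
    class = "synth_population"
  )
}

#' @export
print.synth_population <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf(
    "<synth_population> %d cells (Td = %g min, C = %g, D = %g, seed = %d)\n",
    nrow(x$cells), cfg$td, cfg$c_period, cfg$d_period, cfg$seed
  ))
  invisible(x)
}

#' Generate a two-peak calibration reference population
#'
#' Fluorescence values for a reference population of cells arrested
#' with one or two fully replicated chromosomes: a lognormal mixture
#' whose components have their modes at `au_per_equivalent` and twice
#' it.
#'
#' @param n Number of reference cells.
#' @param au_per_equivalent Fluorescence of one chromosome equivalent.
#' @param peak_cv Fractional CV of each mixture component.
#' @param fraction_2c Fraction of cells in the 2-chromosome component.
#' @param seed Integer seed.
#' @return Numeric vector of `n` fluorescence values.
#' @export
generate_reference_population <- function(n, au_per_equivalent,
                                          peak_cv = 0.1, fraction_2c = 0.4,
                                          seed) {
  if (fraction_2c < 0 || fraction_2c > 1) {
    abort("`fraction_2c` must lie in [0, 1].")
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  two <- runif(n) < fraction_2c
  mu <- au_per_equivalent * ifelse(two, 2, 1)
  if (peak_cv == 0) return(mu)
  sigma2 <- log(1 + peak_cv^2)
  # a lognormal with meanlog m has its mode at exp(m - sigma^2); shift m so
  # the component peak (not the mean) sits at the unit fluorescence
  exp(rnorm(n, log(mu) + sigma2, sqrt(sigma2)))
}

#' Generate axial fluorescence and diameter profiles
#'
#' Builds the per-cell 1-D profiles that the cytometry pipeline
#' consumes. The fluorescence profile is a sum of trapezoid-shaped
#' nucleoid pulses at the ground-truth positions, scaled so its
#' trapezoid integral equals the cell's integrated fluorescence
#' exactly; the diameter profile is the cell diameter with a smooth
#' constriction notch down to the waist diameter at the division plane.
#' An optional constant background is added to fluorescence samples.
#'
#' @param population A [generate_population()] result.
#' @return A long tibble with columns `id`, `position_um`, `fluor_au`,
#'   `diameter_um`.
#' @export
generate_profiles <- function(population) {
  stopifnot(inherits(population, "synth_population"))
  cfg <- attr(population, "config")
  cells <- population$cells
  truth <- population$truth

  one_cell <- function(i) {
    len <- cells$length_um[i]
    x <- seq(0, len, by = cfg$profile_spacing_um)
    if (tail(x, 1) < len) x <- c(x, len)
    ramp <- cfg$profile_spacing_um

    if (truth$two_nucleoids[i]) {
      nuc_len <- cfg$nucleoid_fraction * len / 2
      centers <- truth$nucleoid_center_um[i] +
        c(-1, 1) * truth$com_separation_um[i] / 2
      weights <- c(0.5, 0.5)
    } else {
      nuc_len <- cfg$nucleoid_fraction * len
      centers <- truth$nucleoid_center_um[i]
      weights <- 1
    }
    raw <- rep(0, length(x))
    for (j in seq_along(centers)) {
      pulse <- trapezoid_pulse(x, centers[j], nuc_len, ramp)
      # slight axial tilt so no two signal samples tie exactly; image-style
      # modal background estimation must never mistake a plateau for
      # background
      tilt <- 1 + 0.05 * (x - centers[j]) / nuc_len
      raw <- raw + weights[j] * pulse * tilt
    }
    integral <- trapz(x, raw)
    fl <- if (integral > 0) raw * cells$fluor_au[i] / integral else raw
    fl <- fl + cfg$background_au

    d <- rep(cells$diameter_um[i], length(x))
    if (!is.na(cells$constriction_diameter_um[i])) {
      depth <- cells$diameter_um[i] - cells$constriction_diameter_um[i]
      d <- d - depth * notch(x, cells$division_position_um[i],
                             half_width = len / 8)
    }
    tibble::tibble(id = cells$id[i], position_um = x, fluor_au = fl,
                   diameter_um = d)
  }

  purrr::map_dfr(seq_len(nrow(cells)), one_cell)
}

# unit-height flat-top pulse with linear ramps, clipped to >= 0 positions
trapezoid_pulse <- function(x, center, width, ramp) {
  a <- center - width / 2
  b <- center + width / 2
  y <- pmin(1, pmax(0, pmin((x - a) / ramp + 1, (b - x) / ramp + 1)))
  y
}

# smooth cosine notch of unit depth at `center`
notch <- function(x, center, half_width) {
  z <- abs(x - center) / half_width
  ifelse(z < 1, (1 + cos(pi * z))^2 / 4, 0)
}

trapz <- function(x, y) {
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}
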