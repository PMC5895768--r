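#' Per-cell multifork chromosome-replication state
#'
#' The chromosome is collapsed to one normalized replication coordinate
#' x in `[0, 1]` from origin to terminus (both bidirectional forks merged
#' into a single progress fraction); this is the standard
#' Cooper-Helmstetter reduction and preserves all DNA amounts. A state
#' is a count of independent, complete-backbone chromosomes plus an
#' ordered vector of active replication-round progress fractions, oldest
#' (farthest along) first. Every round runs synchronously on all origins
#' present at its initiation, so origins per chromosome double with each
#' nested round.
#'
#' @param n_chromosomes Count of complete chromosome backbones (>= 1).
#' @param round_progress Numeric vector of active-round progress
#'   fractions in `[0, 1)`, strictly decreasing (oldest round first).
#' @return An object of class `replication_state`.
#' @examples
#' replication_state()                      # one unreplicated chromosome
#' replication_state(1, c(0.75, 0.25))      # two nested rounds
#' @export
replication_state <- function(n_chromosomes = 1L, round_progress = numeric()) {
  n_chromosomes <- as.integer(n_chromosomes)
  if (is.na(n_chromosomes) || n_chromosomes < 1L) {
    abort("`n_chromosomes` must be a positive integer.")
  }
  round_progress <- as.numeric(round_progress)
  if (any(is.na(round_progress)) ||
      any(round_progress < 0 | round_progress >= 1)) {
    abort("`round_progress` values must lie in [0, 1).")
  }
  if (length(round_progress) > 1L && any(diff(round_progress) >= 0)) {
    abort("`round_progress` must be strictly decreasing (oldest round first).")
  }
  structure(
    list(n_chromosomes = n_chromosomes, round_progress = round_progress),
    class = "replication_state"
  )
}

#' @export
print.replication_state <- function(x, ...) {
  cat(sprintf(
    "<replication_state> %d chromosome(s), %d active round(s)%s; G = %.4f eq, %d origin(s)\n",
    x$n_chromosomes, length(x$round_progress),
    if (length(x$round_progress)) {
      paste0(" at ", paste(signif(x$round_progress, 4), collapse = ", "))
    } else "",
    genome_equivalents(x), origins_count(x)
  ))
  invisible(x)
}

#' Genome content of a replication state, in chromosome equivalents
#'
#' Exact piecewise integral of the local copy number over the
#' normalized chromosome coordinate: with active-round progress
#' fractions p, position x is covered by `k(x)` rounds (those with
#' progress >= x) and carries `2^k(x)` copies, so
#' `G = n_chromosomes * integral of 2^k(x) dx`. Genome content "in
#' minutes" is `C * G`.
#'
#' @param state A [replication_state()].
#' @return Genome equivalents (dimensionless, >= `n_chromosomes`).
#' @examples
#' genome_equivalents(replication_state(1, 0.5))          # 1.5
#' genome_equivalents(replication_state(1, c(0.75, 0.25)))  # 2.25
#' @export
genome_equivalents <- function(state) {
  stopifnot(inherits(state, "replication_state"))
  state$n_chromosomes * copy_number_integral(state$round_progress)
}

# integral of 2^(#rounds covering x) over x in [0,1]; p any order
copy_number_integral <- function(p) {
  m <- length(p)
  if (m == 0L) return(1)
  q <- sort(p)                       # ascending
  edges <- c(0, q, 1)
  counts <- m:0                      # [0,q1): m rounds, ..., [qm,1): 0
  sum(2^counts * diff(edges))
}

#' Number of replication origins in a state
#'
#' `n_chromosomes * 2^(number of active rounds)`: each nested round
#' doubles the origins per chromosome.
#'
#' @inheritParams genome_equivalents
#' @return Integer origin count.
#' @export
origins_count <- function(state) {
  stopifnot(inherits(state, "replication_state"))
  state$n_chromosomes * 2^length(state$round_progress)
}

#' Advance replication forks by a time interval
#'
#' Forks progress at rate 1/C. A round reaching progress 1 terminates:
#' it is removed and the chromosome count doubles, so genome content is
#' continuous across the termination. Terminations are processed
#' oldest-first; no initiations occur.
#'
#' @inheritParams genome_equivalents
#' @param dt Time interval, minutes (>= 0).
#' @param c_period Replication period C, minutes.
#' @return The advanced `replication_state`.
#' @export
advance <- function(state, dt, c_period) {
  stopifnot(inherits(state, "replication_state"))
  check_positive(c_period, "c_period")
  if (!is.numeric(dt) || length(dt) != 1L || is.na(dt) || dt < 0) {
    abort("`dt` must be a single non-negative number (minutes).")
  }
  p <- state$round_progress + dt / c_period
  done <- p >= 1
  replication_state(
    n_chromosomes = state$n_chromosomes * 2^sum(done),
    round_progress = p[!done]
  )
}

#' Initiate a new replication round on all origins
#'
#' Adds a round at progress 0, synchronously on every origin present;
#' origins double, genome content is unchanged at the instant of
#' initiation.
#'
#' @inheritParams genome_equivalents
#' @return The state with one more active round.
#' @export
initiate <- function(state) {
  stopifnot(inherits(state, "replication_state"))
  if (length(state$round_progress) && min(state$round_progress) <= 0) {
    abort("cannot initiate: a round at progress 0 is already present.")
  }
  replication_state(
    n_chromosomes = state$n_chromosomes,
    round_progress = c(state$round_progress, 0)
  )
}

#' Split a replication state at cell division
#'
#' Each daughter receives half the chromosome backbones with the same
#' nested round structure, so the daughters' genome contents sum to the
#' mother's (DNA conservation). Requires an even chromosome count: in
#' the Cooper-Helmstetter cycle the round feeding a division terminates
#' D minutes earlier, so a dividing cell always carries a doubled
#' backbone.
#'
#' @inheritParams genome_equivalents
#' @return The `replication_state` of one daughter.
#' @export
split_state <- function(state) {
  stopifnot(inherits(state, "replication_state"))
  if (state$n_chromosomes %% 2L != 0L) {
    abort(paste0(
      "cannot split a state with an odd chromosome count (",
      state$n_chromosomes, "); the round feeding this division has not terminated."
    ))
  }
  replication_state(
    n_chromosomes = state$n_chromosomes %/% 2L,
    round_progress = state$round_progress
  )
}

# Replication state of a cell at a given age under an arbitrary future
# division schedule. `division_ages` are the ages (relative to this
# cell's birth) at which the cell and then the tracked descendant line
# divide, ascending; each division at d is fed by a round initiated at
# d - (C+D) (possibly before birth, in an ancestor assumed to follow the
# same rule) and terminating at d - D. Rounds that terminated before
# birth are absorbed into the single newborn backbone.
state_from_schedule <- function(age, division_ages, c_period, d_period) {
  cd <- c_period + d_period
  division_ages <- division_ages[division_ages - cd <= age]
  # terminations count even when they fired before birth (d_j - D < 0, a
  # division arriving sooner than D after birth): the doubling happened in an
  # ancestor and the newborn inherits it on top of the steady one-per-
  # generation baseline, keeping genome content continuous in the schedule
  terminated <- sum(division_ages - d_period <= age)
  active <- division_ages[division_ages - d_period > age]
  progress <- (age - (active - cd)) / c_period
  progress <- progress[progress >= 0 & progress < 1]
  replication_state(
    n_chromosomes = 2^terminated,
    round_progress = sort(progress, decreasing = TRUE)
  )
}

#' Replication state of a steady-state cell of a given age
#'
#' Under the assumption that every cell has the same C+D period, a cell
#' of age `a` carries exactly the rounds initiated `C+D` minutes before
#' each division of itself and its descendant line, which at steady
#' state occur at ages `Td, 2 Td, ...`. Rounds initiated before birth
#' (when `C+D > Td`) are inherited from ancestors.
#'
#' @param cond A [growth_condition()].
#' @param age Cell age, minutes, in `[0, td]`.
#' @return A [replication_state()].
#' @examples
#' cond <- growth_condition(29, 53, 25)
#' steady_state_cell(cond, 0)   # newborn already carries two rounds
#' @export
steady_state_cell <- function(cond, age) {
  cond <- as_growth_condition(cond)
  if (!is.numeric(age) || length(age) != 1L || is.na(age) ||
      age < 0 || age > cond$td) {
    abort("`age` must lie in [0, td].")
  }
  k_max <- ceiling((age + cond$cd) / cond$td) + 1
  state_from_schedule(age, cond$td * seq_len(k_max), cond$c_period,
                      cond$d_period)
}

#' Population-mean genome equivalents from the single-cell model
#'
#' Averages [genome_equivalents()] of [steady_state_cell()] over the
#' steady-state age distribution, either by adaptive quadrature split at
#' the initiation/termination event ages (where per-age genome content
#' has kinks) or by Monte-Carlo sampling of ages. Serves as the
#' independent oracle for the closed form
#' [mean_genome_equivalents()].
#'
#' @inheritParams steady_state_cell
#' @param n Number of Monte-Carlo age samples (ignored for quadrature).
#' @param method `"quadrature"` (default) or `"montecarlo"`.
#' @param seed Optional seed for the Monte-Carlo draw.
#' @return Mean genome equivalents per cell.
#' @export
population_mean_genome <- function(cond, n = 1e5,
                                   method = c("quadrature", "montecarlo"),
                                   seed = NULL) {
  cond <- as_growth_condition(cond)
  method <- match.arg(method)
  g_of_age <- function(a) {
    vapply(a, function(ai) genome_equivalents(steady_state_cell(cond, ai)),
           numeric(1))
  }
  if (method == "montecarlo") {
    ages <- sample_ages(n, cond$td, seed = seed)
    return(mean(g_of_age(ages)))
  }
  integrate_over_ages(cond, g_of_age)
}

# integral of f(a) * phi(a) over [0, Td], split at replication event ages
integrate_over_ages <- function(cond, f, rel.tol = 1e-9, extra_breaks = NULL) {
  breaks <- event_ages(cond)
  if (!is.null(extra_breaks)) {
    extra_breaks <- extra_breaks[extra_breaks > 0 & extra_breaks < cond$td]
    breaks <- sort(unique(c(breaks, extra_breaks)))
  }
  total <- 0
  for (i in seq_len(length(breaks) - 1)) {
    total <- total + integrate(
      function(a) f(a) * age_density(a, cond$td),
      breaks[i], breaks[i + 1], rel.tol = rel.tol, subdivisions = 200L
    )$value
  }
  total
}

# ages in [0, Td] at which a steady-state cell gains or loses a round
event_ages <- function(cond) {
  k <- seq_len(ceiling((cond$td + cond$cd) / cond$td) + 1)
  ev <- c(k * cond$td - cond$cd, k * cond$td - cond$d_period)
  sort(unique(c(0, ev[ev > 0 & ev < cond$td], cond$td)))
}

#' Population-mean origin count
#'
#' Quadrature average of [origins_count()] over the steady-state age
#' distribution; analytically equal to `2^((C+D)/Td)`.
#'
#' @inheritParams steady_state_cell
#' @return Mean origins per cell.
#' @export
population_mean_origins <- function(cond) {
  cond <- as_growth_condition(cond)
  integrate_over_ages(cond, function(a) {
    vapply(a, function(ai) origins_count(steady_state_cell(cond, ai)),
           numeric(1))
  })
}

#' Rifampicin run-off DNA accumulation curve
#'
#' Simulates run-off synthesis after blocking all initiations at t = 0
#' in a steady-state population: active forks run to completion, no new
#' rounds start, and division is frozen so DNA is reported per original
#' cell. The population mean rises monotonically and plateaus exactly at
#' t = C, when the youngest forks (initiated just before the block)
#' terminate; the plateau equals the mean origin count at t = 0, since
#' every origin completes into one chromosome.
#'
#' @inheritParams steady_state_cell
#' @param timestep Output sampling interval, minutes. Fork dynamics are
#'   exact (event-driven per age); the timestep only controls where the
#'   curve is reported.
#' @param t_max Last reported time, minutes; defaults to 1.25 C.
#' @return A tibble of class `runoff_curve` with columns `time_min` and
#'   `mean_genome_equivalents`, and attributes `plateau_value`,
#'   `plateau_time` (first reported time within `1e-6` relative of the
#'   plateau) and `cond`.
#' @export
runoff_curve <- function(cond, timestep = 1, t_max = NULL) {
  cond <- as_growth_condition(cond)
  check_positive(timestep, "timestep")
  if (is.null(t_max)) t_max <- 1.25 * cond$c_period
  times <- unique(sort(c(seq(0, t_max, by = timestep), cond$c_period)))
  g_t <- vapply(times, function(t) {
    integrate_over_ages(cond, function(a) {
      vapply(a, function(ai) {
        genome_equivalents(advance(steady_state_cell(cond, ai), t,
                                   cond$c_period))
      }, numeric(1))
    }, extra_breaks = event_ages(cond) - t)
  }, numeric(1))
  plateau_value <- g_t[length(g_t)]
  reached <- times[g_t >= plateau_value * (1 - 1e-6)]
  out <- tibble::tibble(time_min = times, mean_genome_equivalents = g_t)
  structure(
    out,
    plateau_value = plateau_value,
    plateau_time = reached[1],
    cond = cond,
    class = c("runoff_curve", class(out))
  )
}

#' Summary of a run-off curve
#'
#' @param curve A [runoff_curve()].
#' @return A one-row tibble: plateau time (min), plateau value
#'   (genome equivalents), initial value, and plateau/initial ratio.
#' @export
runoff_summary <- function(curve) {
  stopifnot(inherits(curve, "runoff_curve"))
  g0 <- curve$mean_genome_equivalents[curve$time_min == 0]
  tibble::tibble(
    plateau_time_min = attr(curve, "plateau_time"),
    plateau_equivalents = attr(curve, "plateau_value"),
    initial_equivalents = g0,
    plateau_ratio = attr(curve, "plateau_value") / g0
  )
}
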