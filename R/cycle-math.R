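#' Growth condition: the scalar cell-cycle parameter set
#'
#' Bundles the doubling time `Td`, the chromosome replication period `C`
#' and the termination-to-division period `D` of one steady-state growth
#' condition, together with the derived `C+D` period and the birth-to-
#' initiation period `B = Td - (C+D)`. `B` may be negative: initiation of
#' the round feeding a division then occurred in an ancestor, the
#' signature of multifork replication.
#'
#' @param td Doubling time, minutes. Must be positive.
#' @param c_period Replication (C) period, minutes. Must be positive.
#' @param d_period Termination-to-division (D) period, minutes. Must be
#'   non-negative.
#'
#' @return An object of class `growth_condition`: a list with elements
#'   `td`, `c_period`, `d_period`, `cd` (= C+D) and `b` (= Td - (C+D)).
#' @examples
#' growth_condition(122, 70, 40)   # slow growth, succinate
#' growth_condition(29, 53, 25)    # fast growth, glucose + amino acids
#' @export
growth_condition <- function(td, c_period, d_period) {
  check_positive(td, "td")
  check_positive(c_period, "c_period")
  if (!is.numeric(d_period) || length(d_period) != 1L || is.na(d_period) ||
      d_period < 0) {
    abort("`d_period` must be a single non-negative number (minutes).")
  }
  structure(
    list(
      td = as.numeric(td),
      c_period = as.numeric(c_period),
      d_period = as.numeric(d_period),
      cd = as.numeric(c_period + d_period),
      b = as.numeric(td - c_period - d_period)
    ),
    class = "growth_condition"
  )
}

#' @export
print.growth_condition <- function(x, ...) {
  cat(sprintf(
    "<growth_condition> Td = %g min, C = %g min, D = %g min (C+D = %g, B = %g)\n",
    x$td, x$c_period, x$d_period, x$cd, x$b
  ))
  invisible(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number.", name))
  }
  invisible(x)
}

as_growth_condition <- function(cond) {
  if (inherits(cond, "growth_condition")) return(cond)
  if (is.list(cond) && all(c("td", "c_period", "d_period") %in% names(cond))) {
    return(growth_condition(cond$td, cond$c_period, cond$d_period))
  }
  abort("`cond` must be a growth_condition (see `growth_condition()`).")
}

#' Mean genome equivalents per cell in a steady-state population
#'
#' Cooper-Helmstetter closed form for the population-average DNA content
#' of an exponentially growing culture, in units of chromosome
#' equivalents:
#' \deqn{G_c = \frac{T_d}{C \ln 2}\left(2^{(C+D)/T_d} - 2^{D/T_d}\right)}
#' Valid only for steady-state growth, where the age distribution is
#' \eqn{\phi(a) = (2\ln 2/T_d)\,2^{-a/T_d}}.
#'
#' @inheritParams growth_condition
#' @return Mean genome equivalents per cell (dimensionless, > 1 whenever
#'   C > 0).
#' @examples
#' mean_genome_equivalents(122, 70, 40)  # ~1.54
#' mean_genome_equivalents(29, 53, 25)   # ~3.66
#' @seealso [solve_d_period()] for the inverse in D,
#'   [population_mean_genome()] for the single-cell-model oracle.
#' @export
mean_genome_equivalents <- function(td, c_period, d_period) {
  check_positive(td, "td")
  check_positive(c_period, "c_period")
  if (d_period < 0) abort("`d_period` must be non-negative.")
  td / (c_period * log(2)) *
    (2^((c_period + d_period) / td) - 2^(d_period / td))
}

#' Solve for the D period from mean genome equivalents
#'
#' Inverts [mean_genome_equivalents()] in `D` by bracketed bisection on
#' `[0, 3 Td]`. \eqn{G_c} is strictly increasing in D, so the solution is
#' unique when it exists.
#'
#' @inheritParams growth_condition
#' @param gc Observed mean genome equivalents per cell. Must be at least
#'   the D = 0 value `mean_genome_equivalents(td, c_period, 0)`;
#'   otherwise no non-negative D can produce it and an error is raised
#'   rather than clamping.
#' @param tol Convergence tolerance on D, minutes.
#' @return The D period in minutes.
#' @examples
#' solve_d_period(122, 70, mean_genome_equivalents(122, 70, 40))  # 40
#' @export
solve_d_period <- function(td, c_period, gc, tol = 1e-6) {
  check_positive(td, "td")
  check_positive(c_period, "c_period")
  g0 <- mean_genome_equivalents(td, c_period, 0)
  if (gc < g0) {
    abort(sprintf(
      "`gc` = %g is below the D = 0 minimum %g for Td = %g, C = %g; no feasible D.",
      gc, g0, td, c_period
    ))
  }
  lo <- 0
  hi <- 3 * td
  while (mean_genome_equivalents(td, c_period, hi) < gc) hi <- 2 * hi
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (mean_genome_equivalents(td, c_period, mid) < gc) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Terminal period from the fraction of cells in a terminal class
#'
#' In a steady-state population the fraction F of cells occupying the
#' last T minutes of the cycle satisfies \eqn{F = 2^{T/T_d} - 1}, a
#' direct consequence of the steady-state age distribution. Inverting
#' gives \eqn{T = T_d \log_2(1 + F)}. Used to estimate the constriction
#' period from the percentage of constricting cells and the nucleoid
#' segregation period from the percentage of two-nucleoid cells.
#'
#' @param f Fraction of the population in the class, in `[0, 1]`.
#' @param td Doubling time, minutes.
#' @return The duration of the terminal period, minutes, in `[0, Td]`.
#' @examples
#' terminal_period_from_fraction(0.09, 122)  # ~15.2 min constriction
#' terminal_period_from_fraction(0.74, 29)   # ~23.2 min segregation
#' @export
terminal_period_from_fraction <- function(f, td) {
  check_positive(td, "td")
  if (!is.numeric(f) || any(is.na(f)) || any(f < 0 | f > 1)) {
    abort("`f` must be a fraction in [0, 1].")
  }
  td * log2(1 + f)
}

#' Fraction of cells in a terminal class from its duration
#'
#' Inverse of [terminal_period_from_fraction()]:
#' \eqn{F = 2^{T/T_d} - 1}.
#'
#' @param t_period Terminal period, minutes, in `[0, Td]`.
#' @inheritParams terminal_period_from_fraction
#' @return Fraction in `[0, 1]`.
#' @export
fraction_from_terminal_period <- function(t_period, td) {
  check_positive(td, "td")
  if (!is.numeric(t_period) || any(is.na(t_period)) ||
      any(t_period < 0 | t_period > td)) {
    abort("`t_period` must lie in [0, td].")
  }
  2^(t_period / td) - 1
}

#' Newborn cell length from the population mean length
#'
#' Under exponential elongation at steady state,
#' \eqn{L_b = \langle L \rangle / (2 \ln 2)}, where
#' \eqn{\langle L \rangle} is the mean length of all cells.
#'
#' @param mean_length Population mean cell length, micrometres.
#' @return Mean newborn length, micrometres.
#' @examples
#' newborn_length_from_mean(2.78)  # ~2.0 um
#' @export
newborn_length_from_mean <- function(mean_length) {
  check_positive(mean_length, "mean_length")
  mean_length / (2 * log(2))
}

#' Steady-state cell-age distribution
#'
#' Density of cell age in an exponentially growing steady-state
#' population, \eqn{\phi(a) = (2\ln 2/T_d)\,2^{-a/T_d}} for
#' \eqn{0 \le a \le T_d}, zero outside. Newborns are twice as frequent
#' as dividing cells.
#'
#' @param age Cell age(s), minutes. Vectorized.
#' @param td Doubling time, minutes.
#' @return Probability density per minute (0 outside `[0, td]`).
#' @export
age_density <- function(age, td) {
  check_positive(td, "td")
  ifelse(age >= 0 & age <= td, (2 * log(2) / td) * 2^(-age / td), 0)
}

#' Sample cell ages from the steady-state age distribution
#'
#' Inverse-CDF sampling: the CDF is \eqn{F(a) = 2(1 - 2^{-a/T_d})}, so
#' \eqn{a = -T_d \log_2(1 - u/2)} for uniform u.
#'
#' @param n Number of ages to draw.
#' @param td Doubling time, minutes.
#' @param seed Optional integer seed; when supplied the draw is
#'   reproducible without touching the caller's RNG stream.
#' @return Numeric vector of `n` ages in `[0, td)`.
#' @export
sample_ages <- function(n, td, seed = NULL) {
  check_positive(td, "td")
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  u <- runif(n)
  -td * log2(1 - u / 2)
}

age_cdf <- function(age, td) {
  pmin(pmax(2 * (1 - 2^(-age / td)), 0), 1)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
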