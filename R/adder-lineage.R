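#' Generation time of an adder cell growing exponentially
#'
#' A cell born at length `Lb` elongates exponentially at the population
#' rate (length doubling time `Td`) and divides after adding the fixed
#' increment `dL`, so its generation time is
#' \eqn{\tau = T_d \log_2((L_b + \Delta L)/L_b)}. Large newborns divide
#' younger than small ones (`tau < Td` iff `Lb > dL`), the origin of
#' size homeostasis under the adder rule.
#'
#' @param lb Birth length, micrometres.
#' @param dl Adder increment, micrometres.
#' @param td Doubling time, minutes.
#' @return Generation time, minutes.
#' @examples
#' division_time(2.0, 2.0, 122)  # 122: a steady-state cell doubles
#' division_time(2.3, 2.0, 122)  # ~110: a large sibling divides earlier
#' @export
division_time <- function(lb, dl, td) {
  check_positive(td, "td")
  if (!is.numeric(lb) || !is.numeric(dl) || any(lb <= 0) || any(dl <= 0)) {
    abort("`lb` and `dl` must be positive lengths (micrometres).")
  }
  td * log2((lb + dl) / lb)
}

#' Construct sibling lineages born from one asymmetric division
#'
#' An average cell divides asymmetrically at time 0 into a large
#' (`Lb (1 + asym_sd)`) and a small (`Lb (1 - asym_sd)`) newborn. Each
#' branch then grows exponentially, adds the fixed increment `dl` before
#' dividing, and is followed through one daughter of each subsequent
#' symmetric division. The newborn-length deviation from steady state
#' halves at every division, so both branches converge geometrically
#' back to `Lb`.
#'
#' @param lb_star Steady-state newborn length, micrometres (the figure
#'   construction anchors `lb_star = dl`).
#' @param dl Adder increment, micrometres.
#' @param cond A [growth_condition()].
#' @param asym_sd Fractional birth-size deviation of the first siblings,
#'   in `[0, 0.5)` (e.g. 0.15 for a 15% CV of newborn lengths).
#' @param n_cycles Number of cycles to follow per branch (>= 1).
#' @return A tibble of class `lineage_pair`, one row per (branch,
#'   cycle): `branch` ("large"/"small"), `cycle`, `birth_time`, `lb`,
#'   `ld`, `tau` and `div_time` (absolute, minutes). Attributes store
#'   the construction parameters.
#' @examples
#' cond <- growth_condition(122, 70, 40)
#' construct_sibling_lineages(2, 2, cond, asym_sd = 0.15, n_cycles = 4)
#' @export
construct_sibling_lineages <- function(lb_star, dl, cond, asym_sd,
                                       n_cycles = 4L) {
  check_positive(lb_star, "lb_star")
  check_positive(dl, "dl")
  cond <- as_growth_condition(cond)
  if (!is.numeric(asym_sd) || length(asym_sd) != 1L || is.na(asym_sd) ||
      asym_sd < 0 || asym_sd >= 0.5) {
    abort("`asym_sd` must lie in [0, 0.5).")
  }
  if (n_cycles < 1) abort("`n_cycles` must be at least 1.")

  branch_tbl <- function(branch, sign) {
    lb <- lb_star * (1 + sign * asym_sd)
    rows <- vector("list", n_cycles)
    birth <- 0
    for (i in seq_len(n_cycles)) {
      tau <- division_time(lb, dl, cond$td)
      rows[[i]] <- tibble::tibble(
        branch = branch, cycle = i, birth_time = birth,
        lb = lb, ld = lb + dl, tau = tau, div_time = birth + tau
      )
      birth <- birth + tau
      lb <- (lb + dl) / 2
    }
    dplyr::bind_rows(rows)
  }

  out <- dplyr::bind_rows(branch_tbl("large", +1), branch_tbl("small", -1))
  structure(
    out,
    lb_star = lb_star, dl = dl, asym_sd = asym_sd, cond = cond,
    class = c("lineage_pair", class(out))
  )
}

lineage_attrs <- function(pair) {
  stopifnot(inherits(pair, "lineage_pair"))
  list(
    lb_star = attr(pair, "lb_star"), dl = attr(pair, "dl"),
    asym_sd = attr(pair, "asym_sd"), cond = attr(pair, "cond")
  )
}

# carry lineage_pair class and attributes through a transformation
restitch_pair <- function(out, pair) {
  for (a in c("lb_star", "dl", "asym_sd", "cond")) {
    attr(out, a) <- attr(pair, a)
  }
  class(out) <- unique(c("lineage_pair", class(out)))
  out
}

#' Schedule replication initiations along sibling lineages
#'
#' Each division at absolute time `t_div` is fed by one initiation at
#' `t_div - (C+D)`. If that instant precedes the dividing cell's birth,
#' the event is assigned to the ancestor alive then: a tracked earlier
#' cycle, or (for times before the founding asymmetric division at
#' t = 0) the pre-asymmetry ancestor line, assumed to have been at
#' steady state with newborn length `lb_star`. `li` is the length of the
#' host cell at the initiation instant and `generation_offset` counts
#' how many generations before the division the initiation occurred
#' (0 = same cell, 1 = mother, ...).
#'
#' @param pair A [construct_sibling_lineages()] result.
#' @return The lineage pair with added columns `init_time`,
#'   `host_cycle`, `generation_offset`, `li` and `out_of_window`
#'   (`TRUE` when the initiation precedes the reconstructed steady
#'   ancestor window of 5 generations; `li` is still reported from the
#'   steady ancestor line).
#' @export
schedule_initiations <- function(pair) {
  par <- lineage_attrs(pair)
  cond <- par$cond

  one_branch <- function(df) {
    init_time <- df$div_time - cond$cd
    host_cycle <- integer(nrow(df))
    li <- numeric(nrow(df))
    for (i in seq_along(init_time)) {
      t0 <- init_time[i]
      if (t0 >= 0) {
        j <- max(which(df$birth_time <= t0 + 1e-9))
        host_cycle[i] <- df$cycle[j]
        li[i] <- df$lb[j] * 2^((t0 - df$birth_time[j]) / cond$td)
      } else {
        # steady pre-asymmetry ancestor line: generation -k alive on
        # [-(k+1) Td, -k Td), newborn length lb_star
        k <- ceiling(-t0 / cond$td) - 1   # 0 = mother of the siblings
        host_cycle[i] <- -k
        li[i] <- par$lb_star * 2^((t0 + (k + 1) * cond$td) / cond$td)
      }
    }
    df$init_time <- init_time
    df$host_cycle <- host_cycle
    df$generation_offset <- df$cycle - host_cycle
    df$li <- li
    df$out_of_window <- init_time < -5 * cond$td
    df
  }

  out <- pair |>
    dplyr::group_by(.data$branch) |>
    dplyr::group_modify(~ one_branch(.x)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$branch, .data$cycle)
  restitch_pair(out, pair)
}

#' Genome content along sibling lineages
#'
#' Evolves a [replication_state()] along each branch: the newborn state
#' at t = 0 is the steady-state newborn (the founding division is
#' assumed to split a steady-state mother), rounds initiated before
#' birth follow the steady schedule, post-birth initiations occur at the
#' times scheduled by [schedule_initiations()], terminations are exact,
#' and the state splits symmetrically at each division.
#'
#' @param pair A lineage pair; initiations are scheduled automatically
#'   if not already present.
#' @return The pair with columns `g_birth`, `g_division` (chromosome
#'   equivalents) and `g_birth_min`, `g_division_min` (the same content
#'   expressed in minutes, i.e. multiplied by C).
#' @export
genome_trajectory <- function(pair) {
  if (!"init_time" %in% names(pair)) pair <- schedule_initiations(pair)
  par <- lineage_attrs(pair)
  cond <- par$cond

  one_branch <- function(df) {
    state <- steady_state_cell(cond, 0)
    n <- nrow(df)
    g_birth <- g_div <- numeric(n)
    # initiations feeding divisions beyond the constructed window can still
    # fall inside it (C+D may span several generations): extend the division
    # schedule along the adder map far enough to cover the window
    div_times <- df$div_time
    lb_next <- df$ld[n] / 2
    t_next <- df$div_time[n]
    while (t_next - cond$cd < df$div_time[n]) {
      t_next <- t_next + division_time(lb_next, par$dl, cond$td)
      div_times <- c(div_times, t_next)
      lb_next <- (lb_next + par$dl) / 2
    }
    all_inits <- div_times - cond$cd
    # post-birth initiation events, one per division they feed
    inits <- all_inits[all_inits >= 0 & all_inits <= df$div_time[n]]
    # sanity: divisions with pre-birth initiations must be covered by the
    # rounds the steady newborn already carries
    n_prebirth <- sum(all_inits < 0)
    if (n_prebirth > length(state$round_progress)) {
      abort(paste(
        "more pre-birth initiations than rounds in the steady newborn state;",
        "the asymmetry is too large for the steady-ancestor assumption."
      ))
    }
    now <- 0
    for (i in seq_len(n)) {
      g_birth[i] <- genome_equivalents(state)
      pending <- sort(inits[inits > now - 1e-9 & inits < df$div_time[i] - 1e-9])
      for (t_init in pending) {
        state <- advance(state, t_init - now, cond$c_period)
        state <- initiate(state)
        now <- t_init
      }
      state <- advance(state, df$div_time[i] - now, cond$c_period)
      now <- df$div_time[i]
      g_div[i] <- genome_equivalents(state)
      state <- split_state(state)
    }
    df$g_birth <- g_birth
    df$g_division <- g_div
    df
  }

  out <- pair |>
    dplyr::group_by(.data$branch) |>
    dplyr::group_modify(~ one_branch(.x)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$branch, .data$cycle) |>
    dplyr::mutate(
      g_birth_min = .data$g_birth * cond$c_period,
      g_division_min = .data$g_division * cond$c_period
    )
  restitch_pair(out, pair)
}

#' Cycles needed for an adder lineage to return to steady state
#'
#' The adder map halves the newborn-length deviation at every division,
#' so a fractional deviation `dev0` falls below `tol` after the smallest
#' n with \eqn{dev_0 / 2^n < tol}.
#'
#' @param dev0 Initial fractional deviation (>= 0), e.g. 0.15 for a
#'   sibling born 1 SD (15%) from the mean.
#' @param tol Convergence criterion as a fraction, e.g. 0.01.
#' @return Integer number of cycles (0 when already within tolerance).
#' @examples
#' convergence_cycles(0.15, 0.01)  # 4 cycles, "about four"
#' @export
convergence_cycles <- function(dev0, tol) {
  if (!is.numeric(dev0) || dev0 < 0) abort("`dev0` must be non-negative.")
  check_positive(tol, "tol")
  if (dev0 < tol) return(0L)
  as.integer(ceiling(log2(dev0 / tol) + 1e-12))
}
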