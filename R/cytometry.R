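#' Modal value of a sample
#'
#' Location of the highest peak of a Silverman-bandwidth kernel density
#' estimate. For heavily tied (discrete) data the most frequent value is
#' returned instead, which matches the modal grey value of an image
#' histogram.
#'
#' @param x Numeric vector (>= 10 values for a meaningful mode).
#' @return The modal value.
#' @export
modal_value <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) abort("cannot estimate a mode from an empty sample.")
  tab <- table(x)
  if (max(tab) > length(x) / 10) {
    # discrete-looking data: plain majority value
    return(as.numeric(names(tab)[which.max(tab)]))
  }
  d <- density(x, bw = "nrd0")
  d$x[which.max(d$y)]
}

#' Subtract a modal background from fluorescence values
#'
#' The modal value of the input (or an externally estimated background,
#' e.g. the mode of the whole image) is taken as background and
#' subtracted; negative residuals are clamped to zero.
#'
#' @param x Numeric vector of fluorescence values (profile samples or
#'   pixel values).
#' @param background Background level to subtract; estimated with
#'   [modal_value()] from `x` itself when `NULL`.
#' @return Corrected values, same length as `x`, with attribute
#'   `background` recording the level subtracted.
#' @export
subtract_background <- function(x, background = NULL) {
  if (length(x) == 0L) abort("`x` is empty; nothing to background-correct.")
  if (is.null(background)) {
    if (length(x) < 10L) {
      abort("at least 10 samples are needed to estimate a modal background.")
    }
    background <- modal_value(x)
  }
  structure(pmax(x - background, 0), background = background)
}

#' Calibrate fluorescence against a reference population
#'
#' The reference is a population whose left (lowest-fluorescence) peak
#' corresponds to exactly one chromosome equivalent -- cells arrested
#' with one or two fully replicated chromosomes, giving a 1C/2C
#' two-peak distribution. The calibration factor is the location of the
#' leftmost substantial local maximum (height >= 10% of the global
#' maximum) of a Silverman-bandwidth kernel density estimate; dividing a
#' cell's integrated fluorescence by it yields chromosome equivalents.
#'
#' @param reference Numeric vector of integrated fluorescence per
#'   reference cell, arbitrary units.
#' @return Arbitrary units per chromosome equivalent.
#' @examples
#' set.seed(1)
#' ref <- c(100 * exp(rnorm(300, 0, 0.1)), 200 * exp(rnorm(200, 0, 0.1)))
#' calibrate_fluorescence(ref)  # ~100
#' @export
calibrate_fluorescence <- function(reference) {
  reference <- reference[!is.na(reference)]
  if (length(reference) < 10L) {
    abort("calibration failure: need at least 10 reference cells.")
  }
  if (sd(reference) == 0) {
    abort("calibration failure: reference distribution is degenerate (flat).")
  }
  d <- density(reference, bw = "nrd0")
  y <- d$y
  is_max <- which(diff(sign(diff(y))) == -2) + 1L
  is_max <- is_max[y[is_max] >= 0.1 * max(y)]
  if (length(is_max) == 0L) {
    # strictly monotone-free degenerate KDE; fall back to the global mode
    is_max <- which.max(y)
  }
  d$x[min(is_max)]
}

#' Classify cells by constriction depth
#'
#' Constricting cells are those with a measured constriction diameter;
#' deeply-constricted cells are the constricting cells whose waist is
#' strictly narrower than the mean constriction diameter of all
#' constricting cells. Deeply-constricted cells are about to divide and
#' serve as proxies for pairs of prospective daughter cells.
#'
#' @param cells A data frame of per-cell measurements with columns
#'   `length_um` and `constriction_diameter_um` (`NA` for
#'   non-constricting cells).
#' @return The input as a tibble with an added factor column
#'   `constriction_class` (levels `none`, `constricted`,
#'   `deeply_constricted`) and attribute `mean_constriction_diameter`.
#' @export
classify_constriction <- function(cells) {
  cells <- tibble::as_tibble(cells)
  if (!"constriction_diameter_um" %in% names(cells)) {
    abort("`cells` must have a `constriction_diameter_um` column (NA = none).")
  }
  cd <- cells$constriction_diameter_um
  mean_cd <- if (any(!is.na(cd))) mean(cd, na.rm = TRUE) else NA_real_
  cls <- dplyr::case_when(
    is.na(cd) ~ "none",
    cd < mean_cd ~ "deeply_constricted",
    TRUE ~ "constricted"
  )
  cells$constriction_class <- factor(
    cls, levels = c("none", "constricted", "deeply_constricted")
  )
  attr(cells, "mean_constriction_diameter") <- mean_cd
  cells
}

#' Split cells at the mean length of the group
#'
#' Cells shorter than the mean length go to the `small` group, cells at
#' or above it to the `large` group (documented tie rule). Applied to
#' deeply-constricted cells this separates prospective small and large
#' daughter pairs.
#'
#' @param cells A data frame with a `length_um` column (>= 2 rows).
#' @return The input as a tibble with an added factor column
#'   `size_group` (levels `small`, `large`) and attribute
#'   `split_length`.
#' @export
split_by_mean_length <- function(cells) {
  cells <- tibble::as_tibble(cells)
  if (nrow(cells) < 2L) abort("need at least 2 cells to split by mean length.")
  m <- mean(cells$length_um)
  cells$size_group <- factor(
    ifelse(cells$length_um < m, "small", "large"),
    levels = c("small", "large")
  )
  attr(cells, "split_length") <- m
  cells
}

#' Compare a small and a large group of measurements
#'
#' Two-sample two-tailed t test with group summaries and the percent
#' difference `100 (large - small)/small`. Welch's unequal-variance test
#' is the default; Student's pooled test is available with
#' `var_equal = TRUE`.
#'
#' @param small,large Numeric vectors of per-cell values (>= 2 each).
#' @param var_equal Use the pooled-variance Student test instead of
#'   Welch.
#' @return An object of class `group_comparison`; see
#'   [tidy.group_comparison()] and [glance.group_comparison()].
#' @export
compare_groups <- function(small, large, var_equal = FALSE) {
  small <- small[!is.na(small)]
  large <- large[!is.na(large)]
  if (length(small) < 2L || length(large) < 2L) {
    abort("each group needs at least 2 values for a t test.")
  }
  ht <- stats::t.test(large, small, var.equal = var_equal)
  new_group_comparison(
    mean_small = mean(small), sd_small = sd(small), n_small = length(small),
    mean_large = mean(large), sd_large = sd(large), n_large = length(large),
    t = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value, var_equal = var_equal
  )
}

#' Compare groups from summary statistics
#'
#' Welch (or pooled Student) two-tailed t test computed directly from
#' group means, standard deviations and counts, as needed when only
#' published summaries are available. The Welch statistic is
#' \eqn{t = (m_L - m_S)/\sqrt{s_S^2/n_S + s_L^2/n_L}} with
#' Welch-Satterthwaite degrees of freedom.
#'
#' @param mean_small,sd_small,n_small Summary of the small group.
#' @param mean_large,sd_large,n_large Summary of the large group.
#' @param var_equal Use the pooled-variance Student test.
#' @return An object of class `group_comparison`.
#' @examples
#' # DNA per nucleoid (AU) in small vs large prospective daughters,
#' # fast growth: 0.62 +/- 0.08 (n = 63) vs 0.75 +/- 0.12 (n = 56)
#' compare_groups_summary(0.62, 0.08, 63, 0.75, 0.12, 56)
#' @export
compare_groups_summary <- function(mean_small, sd_small, n_small,
                                   mean_large, sd_large, n_large,
                                   var_equal = FALSE) {
  if (n_small < 2L || n_large < 2L) {
    abort("each group needs at least 2 values for a t test.")
  }
  vs <- sd_small^2 / n_small
  vl <- sd_large^2 / n_large
  if (var_equal) {
    sp2 <- ((n_small - 1) * sd_small^2 + (n_large - 1) * sd_large^2) /
      (n_small + n_large - 2)
    se <- sqrt(sp2 * (1 / n_small + 1 / n_large))
    df <- n_small + n_large - 2
  } else {
    se <- sqrt(vs + vl)
    df <- (vs + vl)^2 / (vs^2 / (n_small - 1) + vl^2 / (n_large - 1))
  }
  t <- (mean_large - mean_small) / se
  new_group_comparison(
    mean_small = mean_small, sd_small = sd_small, n_small = n_small,
    mean_large = mean_large, sd_large = sd_large, n_large = n_large,
    t = t, df = df, p_value = 2 * pt(-abs(t), df), var_equal = var_equal
  )
}

new_group_comparison <- function(...) {
  x <- list(...)
  x$percent_difference <- 100 * (x$mean_large - x$mean_small) / x$mean_small
  structure(x, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<group_comparison> small %.4g +/- %.3g (n=%d) vs large %.4g +/- %.3g",
      " (n=%d)\n  difference %+.3g%%, %s t = %.3g, df = %.4g,",
      " two-tail p = %.3g\n"
    ),
    x$mean_small, x$sd_small, x$n_small, x$mean_large, x$sd_large, x$n_large,
    x$percent_difference, if (x$var_equal) "Student" else "Welch",
    x$t, x$df, x$p_value
  ))
  invisible(x)
}

#' Tidy a group comparison
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return A two-row tibble, one per group, with mean, sd and n.
#' @export
tidy.group_comparison <- function(x, ...) {
  tibble::tibble(
    group = c("small", "large"),
    mean = c(x$mean_small, x$mean_large),
    sd = c(x$sd_small, x$sd_large),
    n = c(x$n_small, x$n_large)
  )
}

#' One-row summary of a group comparison
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return A one-row tibble with the percent difference, t statistic,
#'   degrees of freedom and two-tail p value.
#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(
    percent_difference = x$percent_difference,
    statistic = x$t, df = x$df, p_value = x$p_value,
    method = if (x$var_equal) "Student" else "Welch"
  )
}

#' Nucleoid metrics from an axial fluorescence profile
#'
#' Nucleoids are maximal runs of profile samples above a threshold
#' fraction of the profile maximum (after background subtraction); two
#' nucleoids count as separated when the inter-run minimum drops below
#' the threshold, mirroring the manual rule that residual fluorescence
#' between nucleoids means they have not segregated. For two nucleoids
#' both distance conventions are reported: `gap_distance` between
#' proximal edges (the manual, edge-to-edge measure) and `com_distance`
#' between intensity centres of mass.
#'
#' @param position_um Axial sample positions, micrometres from one pole.
#' @param fluor Background-subtracted fluorescence samples, same length.
#' @param threshold Segmentation threshold as a fraction of the profile
#'   maximum (default 0.2).
#' @return A list of class `nucleoid_measure`: `count`, a `nucleoids`
#'   tibble (start/end/length/center/com/integrated fluorescence per
#'   nucleoid) and, when `count == 2`, `gap_distance` and
#'   `com_distance` in micrometres (`NA` otherwise).
#' @export
nucleoid_metrics <- function(position_um, fluor, threshold = 0.2) {
  if (length(position_um) != length(fluor) || length(fluor) < 10L) {
    abort("`position_um` and `fluor` must be equal-length (>= 10 samples).")
  }
  if (max(fluor) <= 0) abort("no above-threshold signal in the profile.")
  above <- fluor > threshold * max(fluor)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  nuc <- purrr::map_dfr(runs, function(j) {
    idx <- starts[j]:ends[j]
    w <- fluor[idx]
    dx <- if (length(idx) > 1) mean(diff(position_um[idx])) else 1
    tibble::tibble(
      start_um = position_um[starts[j]],
      end_um = position_um[ends[j]],
      length_um = position_um[ends[j]] - position_um[starts[j]],
      center_um = (position_um[starts[j]] + position_um[ends[j]]) / 2,
      com_um = sum(position_um[idx] * w) / sum(w),
      fluor_au = sum(w) * dx
    )
  })
  out <- list(count = nrow(nuc), nucleoids = nuc,
              gap_distance = NA_real_, com_distance = NA_real_)
  if (nrow(nuc) == 2L) {
    out$gap_distance <- nuc$start_um[2] - nuc$end_um[1]
    out$com_distance <- nuc$com_um[2] - nuc$com_um[1]
  }
  structure(out, class = "nucleoid_measure")
}

#' @export
print.nucleoid_measure <- function(x, ...) {
  cat(sprintf("<nucleoid_measure> %d nucleoid(s)", x$count))
  if (x$count == 2L) {
    cat(sprintf("; gap %.3g um, centre-of-mass distance %.3g um",
                x$gap_distance, x$com_distance))
  }
  cat("\n")
  invisible(x)
}

#' Nucleoid metrics for every cell in a profile table
#'
#' @param profiles Long-format profile table with columns `id`,
#'   `position_um` and `fluor_au` (background-subtracted).
#' @param threshold Segmentation threshold, fraction of each profile's
#'   maximum.
#' @return A tibble with one row per cell: `id`, `n_nucleoids`,
#'   `gap_distance_um`, `com_distance_um`.
#' @export
nucleoid_metrics_all <- function(profiles, threshold = 0.2) {
  profiles |>
    dplyr::group_by(.data$id) |>
    dplyr::group_modify(function(df, key) {
      m <- nucleoid_metrics(df$position_um, df$fluor_au, threshold)
      tibble::tibble(
        n_nucleoids = m$count,
        gap_distance_um = m$gap_distance,
        com_distance_um = m$com_distance
      )
    }) |>
    dplyr::ungroup()
}

#' Collective profile of a set of cells
#'
#' Each per-cell axial profile is linearly resampled to 100 points on
#' the normalized cell length `[0, 1]`, then averaged pointwise across
#' cells, yielding one mean diameter and/or fluorescence profile for the
#' whole set.
#'
#' @param profiles Long-format table with columns `id`, `position_um`
#'   and one or both of `fluor_au`, `diameter_um`.
#' @param ids Optional cell ids that must all be present; an error lists
#'   any whose profiles are missing.
#' @param n_points Number of resampled points (default 100).
#' @return A tibble of class `collective_profile` with columns
#'   `position_frac` and `mean_fluor_au` / `mean_diameter_um` as
#'   available, plus attribute `n_cells`.
#' @export
collective_profile <- function(profiles, ids = NULL, n_points = 100L) {
  profiles <- tibble::as_tibble(profiles)
  if (!all(c("id", "position_um") %in% names(profiles))) {
    abort("`profiles` must have `id` and `position_um` columns.")
  }
  if (!is.null(ids)) {
    missing_ids <- setdiff(ids, unique(profiles$id))
    if (length(missing_ids)) {
      abort(paste0("profiles missing for cell id(s): ",
                   paste(missing_ids, collapse = ", ")))
    }
    profiles <- dplyr::filter(profiles, .data$id %in% ids)
  }
  if (nrow(profiles) == 0L) abort("no profiles to average.")
  grid <- seq(0, 1, length.out = n_points)
  value_cols <- intersect(c("fluor_au", "diameter_um"), names(profiles))
  resampled <- profiles |>
    dplyr::group_by(.data$id) |>
    dplyr::group_modify(function(df, key) {
      xf <- (df$position_um - min(df$position_um)) /
        (max(df$position_um) - min(df$position_um))
      out <- tibble::tibble(position_frac = grid)
      for (v in value_cols) {
        out[[v]] <- approx(xf, df[[v]], xout = grid, rule = 2)$y
      }
      out
    }) |>
    dplyr::ungroup()
  out <- resampled |>
    dplyr::group_by(.data$position_frac) |>
    dplyr::summarise(dplyr::across(
      dplyr::all_of(value_cols), mean,
      .names = "mean_{.col}"
    ), .groups = "drop")
  structure(
    out,
    n_cells = dplyr::n_distinct(profiles$id),
    class = c("collective_profile", class(out))
  )
}

#' Length-sorted map of per-cell profiles
#'
#' Reproduces the profile-map visualization: one column per cell,
#' ordered by ascending cell length (ties broken by id, stable), each
#' column holding the cell's axial profile bottom-aligned at the pole
#' and padded with `NA` above.
#'
#' @param profiles Long-format table with columns `id`, `position_um`
#'   and the value column.
#' @param value Which profile to map: `"fluor_au"` (default) or
#'   `"diameter_um"`.
#' @return A numeric matrix of class `profile_map` (rows = axial
#'   samples from the pole, columns = cells in length order) with
#'   attributes `ids`, `lengths_um` and `spacing_um`.
#' @export
profile_map <- function(profiles, value = c("fluor_au", "diameter_um")) {
  value <- match.arg(value)
  profiles <- tibble::as_tibble(profiles)
  per_cell <- profiles |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      length_um = max(.data$position_um) - min(.data$position_um),
      n = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::arrange(.data$length_um, .data$id)
  n_rows <- max(per_cell$n)
  mat <- matrix(NA_real_, nrow = n_rows, ncol = nrow(per_cell))
  spacing <- numeric(nrow(per_cell))
  for (j in seq_len(nrow(per_cell))) {
    df <- profiles[profiles$id == per_cell$id[j], ]
    df <- df[order(df$position_um), ]
    mat[seq_len(nrow(df)), j] <- df[[value]]
    spacing[j] <- if (nrow(df) > 1) mean(diff(df$position_um)) else NA_real_
  }
  structure(
    mat,
    ids = per_cell$id, lengths_um = per_cell$length_um,
    spacing_um = mean(spacing, na.rm = TRUE), value = value,
    class = c("profile_map", "matrix", "array")
  )
}

#' Division asymmetry: the K(L) distribution
#'
#' For each constricting cell the division plane splits the length L
#' into prospective daughters of relative size K and 1 - K; the CV of
#' the pooled symmetric sample (each cell contributing both K and
#' 1 - K) measures division asymmetry. The division-plane position is
#' taken from the `division_position_um` column when present, otherwise
#' from the minimum of the cell's diameter profile.
#'
#' @param cells Per-cell table of constricting cells with `id`,
#'   `length_um` and optionally `division_position_um`.
#' @param profiles Optional long-format profile table with
#'   `diameter_um`, used when `division_position_um` is absent.
#' @return A list of class `kl_result`: `k` (the pooled symmetric
#'   sample) and `cv` (percent).
#' @export
kl_distribution <- function(cells, profiles = NULL) {
  cells <- tibble::as_tibble(cells)
  if ("division_position_um" %in% names(cells)) {
    pos <- cells$division_position_um
    len <- cells$length_um
  } else {
    if (is.null(profiles)) {
      abort(paste(
        "need either a `division_position_um` column or diameter",
        "profiles to locate the division plane."
      ))
    }
    waist <- profiles |>
      dplyr::filter(.data$id %in% cells$id) |>
      dplyr::group_by(.data$id) |>
      dplyr::summarise(
        division_position_um =
          .data$position_um[which.min(.data$diameter_um)] -
          min(.data$position_um),
        .groups = "drop"
      )
    joined <- dplyr::left_join(cells, waist, by = "id")
    pos <- joined$division_position_um
    len <- joined$length_um
  }
  keep <- !is.na(pos)
  k_one <- pos[keep] / len[keep]
  if (any(k_one <= 0 | k_one >= 1)) {
    abort("division positions must lie strictly inside the cell.")
  }
  k <- c(k_one, 1 - k_one)
  structure(
    list(k = k, cv = 100 * sd(k) / mean(k)),
    class = "kl_result"
  )
}

#' @export
print.kl_result <- function(x, ...) {
  cat(sprintf("<kl_result> %d K values, CV = %.2f%%\n",
              length(x$k), x$cv))
  invisible(x)
}

#' Estimate terminal cell-cycle periods from class fractions
#'
#' The constriction period T is estimated from the fraction of
#' constricting cells and the nucleoid segregation period S from the
#' fraction of two-nucleoid cells, both through the steady-state age
#' distribution ([terminal_period_from_fraction()]).
#'
#' @param cells Per-cell table; constriction is read from
#'   `constriction_class` (after [classify_constriction()]) or from
#'   `constriction_diameter_um`, the nucleoid count from an
#'   `n_nucleoids` column when present.
#' @param td Doubling time, minutes.
#' @return A tibble with one row per estimable period: `period`
#'   (`"constriction"` / `"segregation"`), `fraction`, `duration_min`.
#' @export
estimate_periods <- function(cells, td) {
  cells <- tibble::as_tibble(cells)
  rows <- list()
  if ("constriction_class" %in% names(cells)) {
    f_con <- mean(cells$constriction_class != "none")
  } else if ("constriction_diameter_um" %in% names(cells)) {
    f_con <- mean(!is.na(cells$constriction_diameter_um))
  } else {
    f_con <- NULL
  }
  if (!is.null(f_con)) {
    rows$constriction <- tibble::tibble(
      period = "constriction", fraction = f_con,
      duration_min = terminal_period_from_fraction(f_con, td)
    )
  }
  if ("n_nucleoids" %in% names(cells)) {
    f_two <- mean(cells$n_nucleoids >= 2)
    rows$segregation <- tibble::tibble(
      period = "segregation", fraction = f_two,
      duration_min = terminal_period_from_fraction(f_two, td)
    )
  }
  if (length(rows) == 0L) {
    abort("no constriction or nucleoid-count information in `cells`.")
  }
  dplyr::bind_rows(rows)
}
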