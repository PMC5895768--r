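#' Run the full image-cytometry analysis on a measurement table
#'
#' The measurement-table pipeline: classify constriction depth, estimate
#' the constriction (T) and segregation (S) periods from class
#' fractions, calibrate fluorescence against a reference population and
#' convert to chromosome equivalents, split the deeply-constricted
#' cells at their mean length and contrast DNA (and, when profiles are
#' available, nucleoid separation distances) between small and large
#' prospective daughters, and measure division asymmetry as the K(L)
#' CV.
#'
#' @param cells Per-cell measurement table: `id`, `length_um`,
#'   `diameter_um`, `constriction_diameter_um` (NA = non-constricting),
#'   `fluor_au`, optionally `n_nucleoids` and `division_position_um`.
#' @param td Doubling time of the culture, minutes.
#' @param reference Optional fluorescence vector of the calibration
#'   reference population (see [calibrate_fluorescence()]).
#' @param profiles Optional long-format profile table (`id`,
#'   `position_um`, `fluor_au`, `diameter_um`); enables nucleoid
#'   distance contrasts and profile-based division planes.
#' @param threshold Nucleoid segmentation threshold (fraction of
#'   profile maximum).
#' @return An object of class `cytometry_report`; see
#'   [tidy.cytometry_report()] and [glance.cytometry_report()].
#' @export
analyze_population <- function(cells, td, reference = NULL, profiles = NULL,
                               threshold = 0.2) {
  cells <- classify_constriction(cells)
  if (nrow(cells) == 0L) abort("`cells` is empty.")
  periods <- estimate_periods(cells, td)

  au_per_equivalent <- if (!is.null(reference)) {
    calibrate_fluorescence(reference)
  } else {
    NA_real_
  }
  equivalents <- if (!is.na(au_per_equivalent)) {
    cells$fluor_au / au_per_equivalent
  } else {
    rep(NA_real_, nrow(cells))
  }
  cells$equivalents <- equivalents

  deep <- dplyr::filter(cells,
                        .data$constriction_class == "deeply_constricted")
  dna_comparison <- NULL
  distance_comparison <- NULL
  deep_split <- NULL
  if (nrow(deep) >= 4L) {
    deep_split <- split_by_mean_length(deep)
    value <- if (!all(is.na(deep_split$equivalents))) {
      deep_split$equivalents
    } else {
      deep_split$fluor_au
    }
    dna_comparison <- compare_groups(
      value[deep_split$size_group == "small"],
      value[deep_split$size_group == "large"]
    )
    if (!is.null(profiles)) {
      two <- deep_split[
        !is.na(deep_split$n_nucleoids) & deep_split$n_nucleoids == 2L, ,
        drop = FALSE
      ]
      prof_sub <- dplyr::filter(profiles, .data$id %in% two$id)
      if (nrow(prof_sub)) {
        corrected <- prof_sub |>
          dplyr::group_by(.data$id) |>
          dplyr::mutate(fluor_au = as.numeric(
            subtract_background(.data$fluor_au)
          )) |>
          dplyr::ungroup()
        nm <- nucleoid_metrics_all(corrected, threshold = threshold)
        nm <- dplyr::inner_join(
          nm, two[, c("id", "size_group")], by = "id"
        )
        nm <- dplyr::filter(nm, .data$n_nucleoids == 2L)
        if (sum(nm$size_group == "small") >= 2 &&
            sum(nm$size_group == "large") >= 2) {
          distance_comparison <- compare_groups(
            nm$com_distance_um[nm$size_group == "small"],
            nm$com_distance_um[nm$size_group == "large"]
          )
        }
      }
    }
  }

  constricting <- dplyr::filter(cells, .data$constriction_class != "none")
  kl <- NULL
  if (nrow(constricting) >= 2L &&
      ("division_position_um" %in% names(constricting) || !is.null(profiles))) {
    has_pos <- "division_position_um" %in% names(constricting) &&
      any(!is.na(constricting$division_position_um))
    kl <- tryCatch(
      if (has_pos) kl_distribution(constricting)
      else kl_distribution(
        dplyr::select(constricting, -dplyr::any_of("division_position_um")),
        profiles = profiles
      ),
      error = function(e) NULL
    )
  }

  structure(
    list(
      n_cells = nrow(cells),
      fraction_constricted = mean(cells$constriction_class != "none"),
      fraction_deep = mean(cells$constriction_class == "deeply_constricted"),
      periods = periods,
      au_per_equivalent = au_per_equivalent,
      mean_equivalents = mean(equivalents),
      dna_comparison = dna_comparison,
      distance_comparison = distance_comparison,
      kl_cv = if (!is.null(kl)) kl$cv else NA_real_,
      td = td,
      cells = cells,
      deep = deep_split
    ),
    class = "cytometry_report"
  )
}

#' @export
print.cytometry_report <- function(x, ...) {
  cat(sprintf("<cytometry_report> %d cells, Td = %g min\n", x$n_cells, x$td))
  cat(sprintf("  constricted: %.1f%% (deeply: %.1f%%)\n",
              100 * x$fraction_constricted, 100 * x$fraction_deep))
  for (i in seq_len(nrow(x$periods))) {
    cat(sprintf("  %s period: %.1f min (fraction %.3f)\n",
                x$periods$period[i], x$periods$duration_min[i],
                x$periods$fraction[i]))
  }
  if (!is.na(x$au_per_equivalent)) {
    cat(sprintf("  calibration: %.4g AU/equivalent; mean DNA %.3f eq/cell\n",
                x$au_per_equivalent, x$mean_equivalents))
  }
  if (!is.na(x$kl_cv)) cat(sprintf("  K(L) CV: %.2f%%\n", x$kl_cv))
  if (!is.null(x$dna_comparison)) {
    cat("  DNA, small vs large deeply-constricted:\n    ")
    print(x$dna_comparison)
  }
  if (!is.null(x$distance_comparison)) {
    cat("  nucleoid centre-of-mass distance, small vs large:\n    ")
    print(x$distance_comparison)
  }
  invisible(x)
}

#' Tidy a cytometry report
#'
#' @param x A `cytometry_report`.
#' @param ... Unused.
#' @return A long tibble of (quantity, value) pairs covering fractions,
#'   periods, calibration, mean DNA, group contrasts and the K(L) CV.
#' @export
tidy.cytometry_report <- function(x, ...) {
  rows <- list(
    tibble::tibble(quantity = "n_cells", value = x$n_cells),
    tibble::tibble(quantity = "fraction_constricted",
                   value = x$fraction_constricted),
    tibble::tibble(quantity = "fraction_deeply_constricted",
                   value = x$fraction_deep),
    tibble::tibble(
      quantity = paste0(x$periods$period, "_period_min"),
      value = x$periods$duration_min
    ),
    tibble::tibble(quantity = "au_per_equivalent",
                   value = x$au_per_equivalent),
    tibble::tibble(quantity = "mean_equivalents",
                   value = x$mean_equivalents),
    tibble::tibble(quantity = "kl_cv_percent", value = x$kl_cv)
  )
  if (!is.null(x$dna_comparison)) {
    g <- glance(x$dna_comparison)
    rows <- c(rows, list(tibble::tibble(
      quantity = c("dna_percent_difference", "dna_t", "dna_p"),
      value = c(g$percent_difference, g$statistic, g$p_value)
    )))
  }
  if (!is.null(x$distance_comparison)) {
    g <- glance(x$distance_comparison)
    rows <- c(rows, list(tibble::tibble(
      quantity = c("distance_percent_difference", "distance_t", "distance_p"),
      value = c(g$percent_difference, g$statistic, g$p_value)
    )))
  }
  dplyr::bind_rows(rows)
}

#' One-row summary of a cytometry report
#'
#' @param x A `cytometry_report`.
#' @param ... Unused.
#' @return A one-row tibble with the headline quantities.
#' @export
glance.cytometry_report <- function(x, ...) {
  t_row <- x$periods[x$periods$period == "constriction", ]
  s_row <- x$periods[x$periods$period == "segregation", ]
  tibble::tibble(
    n_cells = x$n_cells,
    fraction_constricted = x$fraction_constricted,
    t_period_min = if (nrow(t_row)) t_row$duration_min else NA_real_,
    s_period_min = if (nrow(s_row)) s_row$duration_min else NA_real_,
    au_per_equivalent = x$au_per_equivalent,
    mean_equivalents = x$mean_equivalents,
    dna_percent_difference = if (!is.null(x$dna_comparison)) {
      x$dna_comparison$percent_difference
    } else NA_real_,
    kl_cv_percent = x$kl_cv
  )
}
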