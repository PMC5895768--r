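#' Plot sibling lineage growth curves
#'
#' Length trajectories of the large and small branches on a log length
#' axis, with division and initiation events marked, in the style of
#' the classical adder cell-cycle construction.
#'
#' @param object A lineage pair (see [construct_sibling_lineages()]),
#'   with initiations scheduled if they are to be shown.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lineage_pair <- function(object, ...) {
  cond <- attr(object, "cond")
  seg <- object |>
    dplyr::group_by(.data$branch, .data$cycle) |>
    dplyr::reframe(
      time = seq(.data$birth_time, .data$div_time, length.out = 25),
      length_um = .data$lb * 2^((time - .data$birth_time) / cond$td)
    )
  p <- ggplot2::ggplot(seg, ggplot2::aes(
    x = .data$time, y = .data$length_um,
    colour = .data$branch, group = interaction(.data$branch, .data$cycle)
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(
      data = object,
      ggplot2::aes(x = .data$div_time, y = .data$ld, colour = .data$branch),
      inherit.aes = FALSE
    ) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "time (min)", y = "cell length (µm, log scale)",
      colour = "sibling",
      title = "Adder sibling lineages after one asymmetric division"
    )
  if ("init_time" %in% names(object)) {
    p <- p + ggplot2::geom_point(
      data = object,
      ggplot2::aes(x = .data$init_time, y = .data$li),
      inherit.aes = FALSE, shape = 1, colour = "red"
    )
  }
  p
}

#' Plot a run-off DNA accumulation curve
#'
#' @param object A [runoff_curve()].
#' @param ... Unused.
#' @return A ggplot object with the plateau time (= C) marked.
#' @export
autoplot.runoff_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object), ggplot2::aes(
    x = .data$time_min, y = .data$mean_genome_equivalents
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = attr(object, "plateau_time"),
                        linetype = "dashed") +
    ggplot2::labs(
      x = "time after blocking initiation (min)",
      y = "mean DNA per original cell (genome equivalents)",
      title = "Run-off DNA synthesis"
    )
}

#' Plot a collective profile
#'
#' @param object A [collective_profile()].
#' @param ... Unused.
#' @return A ggplot object with one panel per measured channel.
#' @export
autoplot.collective_profile <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(-"position_frac", names_to = "channel",
                        values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$position_frac,
                                     y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ .data$channel, scales = "free_y") +
    ggplot2::labs(
      x = "normalized cell length", y = "mean signal",
      title = sprintf("Collective profile of %d cells",
                      attr(object, "n_cells"))
    )
}

#' Plot a length-sorted profile map
#'
#' One column per cell in ascending length order, bottom-aligned at the
#' pole, the classic demograph-style visualization of a population
#' snapshot.
#'
#' @param object A [profile_map()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.profile_map <- function(object, ...) {
  mat <- unclass(object)
  df <- tidyr::expand_grid(
    row = seq_len(nrow(mat)), cell = seq_len(ncol(mat))
  )
  df$value <- mat[cbind(df$row, df$cell)]
  df <- df[!is.na(df$value), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cell, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::labs(
      x = "cells, ascending length", y = "axial position (samples)",
      fill = attr(object, "value"),
      title = "Length-sorted profile map"
    )
}
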