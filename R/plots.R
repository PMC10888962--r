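# ggplot2 views of the main result types. Each returns a ggplot object.

#' Plot a strand-resolved enrichment landscape
#'
#' Enrichment ratio of each profiled spacer against its genome position,
#' one panel per matched strand, optionally with shaded region annotations.
#'
#' @param profile Output of [position_profile()].
#' @param regions Optional region tibble (see [default_regions()]).
#' @param log_y Use a log10 y axis (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_enrichment_profile <- function(profile, regions = NULL, log_y = TRUE) {
  stopifnot(all(c("position", "strand", "ratio") %in% names(profile)))
  p <- ggplot2::ggplot(profile,
                       ggplot2::aes(x = .data$position, y = .data$ratio))
  if (!is.null(regions)) {
    # finite shading bounds keep the optional log10 y scale warning-free
    pos <- profile$ratio[is.finite(profile$ratio) & profile$ratio > 0]
    ylo <- if (length(pos)) min(pos) / 10 else 0.01
    yhi <- if (length(pos)) max(pos) * 10 else 100
    p <- p + ggplot2::geom_rect(
      data = regions, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = ylo, ymax = yhi, fill = .data$region),
      alpha = 0.12
    )
  }
  p <- p +
    ggplot2::geom_point(size = 0.3, alpha = 0.5) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::facet_wrap(~strand, ncol = 1) +
    ggplot2::labs(x = "genome position (nt)", y = "enrichment ratio")
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot a strand coverage track
#'
#' Per-nucleotide coverage with plus-strand values drawn upward and
#' minus-strand values downward, as in strand-resolved acquisition maps.
#'
#' @param track A `coverage_track` (see [strand_coverage()]).
#' @param value `"rpm"` (if present) or `"count"`.
#' @return A ggplot object.
#' @export
plot_coverage_track <- function(track, value = NULL) {
  value <- value %||% if ("plus_rpm" %in% names(track)) "rpm" else "count"
  cols <- paste0(c("plus_", "minus_"), value)
  stopifnot(all(cols %in% names(track)))
  df <- tibble(
    position = rep(track$position, 2L),
    strand = rep(c("plus", "minus"), each = nrow(track)),
    value = c(track[[cols[1L]]], -track[[cols[2L]]])
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$value,
                                   colour = .data$strand)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::labs(x = "genome position (nt)",
                  y = if (value == "rpm") "RPM (minus strand down)"
                      else "coverage (minus strand down)")
}

#' Plot sorted-well growth curves
#'
#' OD600 time series per well, coloured by replicate, with the regrowth
#' threshold drawn.
#'
#' @param wells Long tibble `well_id`, `replicate`, `time_h`, `od600`.
#' @param od_threshold Threshold line (default 0.5).
#' @return A ggplot object.
#' @export
plot_growth_curves <- function(wells, od_threshold = 0.5) {
  stopifnot(all(c("well_id", "time_h", "od600") %in% names(wells)))
  p <- ggplot2::ggplot(wells, ggplot2::aes(x = .data$time_h, y = .data$od600,
                                           group = .data$well_id))
  if ("replicate" %in% names(wells)) {
    p <- p + ggplot2::aes(colour = factor(.data$replicate)) +
      ggplot2::labs(colour = "replicate")
  }
  p +
    ggplot2::geom_line(alpha = 0.4, linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = od_threshold, linetype = "dashed") +
    ggplot2::labs(x = "time after sorting (h)", y = "OD600")
}

#' Plot transcript coverage by timepoint
#'
#' Normalized (or raw) plus-strand transcript coverage along the genome,
#' one line per timepoint.
#'
#' @param tracks Long tibble from [simulate_rnaseq_coverage()] or
#'   [normalize_timepoints()].
#' @param value Column to draw; defaults to `norm_coverage` when present.
#' @param bin Bin width in nt for display smoothing (default 200).
#' @return A ggplot object.
#' @export
plot_expression_tracks <- function(tracks, value = NULL, bin = 200) {
  value <- value %||% intersect(c("norm_coverage", "coverage"),
                                names(tracks))[1L]
  stopifnot(!is.na(value), value %in% names(tracks))
  df <- tracks |>
    mutate(bin_start = (.data$position %/% bin) * bin) |>
    group_by(.data$timepoint, .data$bin_start) |>
    summarise(value = mean(.data[[value]]), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_start, y = .data$value,
                                   colour = factor(.data$timepoint))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "genome position (nt)", y = value,
                  colour = "min post-infection")
}
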