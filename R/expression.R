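#' Normalize transcript coverage across timepoints
#'
#' Scales each timepoint's strand-aware coverage track by
#' `reference_size / library_size` so that differences in total sequenced
#' reads per timepoint do not masquerade as expression changes. The
#' reference is the smallest library among the tracks (down-scaling only,
#' never extrapolating).
#'
#' @param tracks Long tibble with columns `timepoint`, `position`,
#'   `coverage` (raw read coverage on the transcribed strand).
#' @param library_sizes Optional tibble `timepoint`, `library_size`; when
#'   `NULL` the per-timepoint total coverage is used as library size.
#' @return `tracks` with added columns `library_size`, `scale` and
#'   `norm_coverage`.
#' @export
normalize_timepoints <- function(tracks, library_sizes = NULL) {
  stopifnot(is.data.frame(tracks),
            all(c("timepoint", "position", "coverage") %in% names(tracks)))
  if (any(tracks$coverage < 0)) abort("coverage must be non-negative")
  if (is.null(library_sizes)) {
    library_sizes <- tracks |>
      group_by(.data$timepoint) |>
      summarise(library_size = sum(.data$coverage), .groups = "drop")
  }
  stopifnot(all(c("timepoint", "library_size") %in% names(library_sizes)))
  if (any(library_sizes$library_size <= 0)) {
    abort("zero library size for a timepoint")
  }
  reference <- min(library_sizes$library_size)
  out <- left_join(tracks, library_sizes, by = "timepoint")
  if (any(is.na(out$library_size))) {
    abort("missing library size for some timepoint")
  }
  out$scale <- reference / out$library_size
  out$norm_coverage <- out$coverage * out$scale
  out
}

#' Mean target-transcript expression under each spacer
#'
#' For minus-strand spacers — whose crRNA is complementary to the
#' plus-strand transcript and therefore has an RNA target — computes the
#' mean normalized coverage of the transcribed strand over the spacer's
#' genome interval `[start, end)`. Plus-strand spacers have no transcript
#' target and are flagged.
#'
#' @param spacers Tibble with `start`, `end`, `strand` (library manifest
#'   rows).
#' @param track One timepoint's coverage: tibble with `position` and a
#'   coverage column. Positions absent from the track count as zero.
#' @param value Column to average: first of `norm_coverage` / `coverage`
#'   present by default.
#' @return `spacers` with added `expression` (`NA` for plus-strand spacers)
#'   and `target_status` (`"ok"` / `"no_target"`).
#' @export
target_expression <- function(spacers, track, value = NULL) {
  stopifnot(is.data.frame(spacers),
            all(c("start", "end", "strand") %in% names(spacers)))
  stopifnot(is.data.frame(track), "position" %in% names(track))
  value <- value %||% intersect(c("norm_coverage", "coverage"), names(track))[1L]
  if (is.na(value) || !value %in% names(track)) {
    abort("track has no coverage column")
  }
  Lmax <- max(c(spacers$end, track$position + 1L))
  cov <- numeric(Lmax)
  cov[track$position + 1L] <- track[[value]]
  csum <- cumsum(c(0, cov))
  expr <- (csum[spacers$end + 1L] - csum[spacers$start + 1L]) /
    (spacers$end - spacers$start)
  spacers$expression <- ifelse(spacers$strand == "minus", expr, NA_real_)
  spacers$target_status <- ifelse(spacers$strand == "minus", "ok", "no_target")
  spacers
}

#' Pearson product-moment correlation
#'
#' Computed from its definition (centered cross-moments), used to relate
#' target transcript expression to spacer enrichment.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`, each with non-zero
#'   variance.
#' @return The correlation coefficient in `[-1, 1]`.
#' @examples
#' pearson_r(c(1, 2, 3, 4), c(2, 1, 4, 3))  # 0.6
#' @export
pearson_r <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) abort("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) abort("need at least 3 complete observations")
  dx <- x - mean(x)
  dy <- y - mean(y)
  sxx <- sum(dx^2)
  syy <- sum(dy^2)
  if (sxx == 0 || syy == 0) abort("degenerate input: zero variance")
  r <- sum(dx * dy) / sqrt(sxx * syy)
  min(1, max(-1, r))
}

#' Expression-enrichment correlation for a screen
#'
#' Convenience wrapper pairing each profiled minus-strand spacer's
#' enrichment ratio with its mean target expression and returning the
#' Pearson correlation, optionally on log-transformed values.
#'
#' @param profile Output of [position_profile()] joined back to the library
#'   manifest, or any tibble with `spacer_sequence`, `ratio`.
#' @param spacers Library manifest with `sequence`, `start`, `end`, `strand`.
#' @param track Normalized coverage track for one timepoint.
#' @param log_transform Correlate `log10(x + pseudo)` values instead.
#' @param pseudo Offset used under `log_transform`.
#' @return A list with elements `data` (paired tibble), `r` and `n`.
#' @export
expression_enrichment_correlation <- function(profile, spacers, track,
                                              log_transform = FALSE,
                                              pseudo = 1e-3) {
  stopifnot(all(c("spacer_sequence", "ratio") %in% names(profile)))
  sp <- target_expression(spacers, track)
  paired <- dplyr::inner_join(
    profile[c("spacer_sequence", "ratio")],
    sp[sp$target_status == "ok", c("sequence", "expression")],
    by = c(spacer_sequence = "sequence")
  )
  paired <- paired[is.finite(paired$ratio) & is.finite(paired$expression), ]
  x <- paired$expression
  y <- paired$ratio
  if (log_transform) {
    x <- log10(x + pseudo)
    y <- log10(y + pseudo)
  }
  list(data = paired, r = pearson_r(x, y), n = nrow(paired))
}
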