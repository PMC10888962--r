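#' First time a growth curve crosses an OD threshold
#'
#' For each well, the first time its OD series crosses `od_threshold`,
#' linearly interpolated between the bracketing observations. A series that
#' starts at or above the threshold returns 0; a series that never crosses
#' returns `NA`.
#'
#' @param wells Long tibble with columns `well_id`, `time_h`, `od600`
#'   (optionally `replicate`).
#' @param od_threshold OD600 threshold (default 0.5).
#' @return A tibble with one row per well: `well_id` (and `replicate` if
#'   present), `t_cross` in hours (`NA` if never crossed).
#' @export
time_to_threshold <- function(wells, od_threshold = 0.5) {
  stopifnot(is.data.frame(wells),
            all(c("well_id", "time_h", "od600") %in% names(wells)))
  if (any(wells$od600 < 0, na.rm = TRUE)) abort("OD600 must be non-negative")
  keys <- intersect(c("well_id", "replicate"), names(wells))
  wells |>
    group_by(dplyr::across(dplyr::all_of(keys))) |>
    summarise(
      t_cross = cross_time(.data$time_h, .data$od600, od_threshold),
      .groups = "drop"
    )
}

cross_time <- function(time_h, od, threshold) {
  o <- order(time_h)
  time_h <- time_h[o]; od <- od[o]
  if (any(diff(time_h) <= 0)) abort("times within a well must be strictly increasing")
  if (length(od) == 0L) return(NA_real_)
  if (od[1L] >= threshold) return(0)
  above <- which(od >= threshold)
  if (length(above) == 0L) return(NA_real_)
  i <- above[1L]
  # linear interpolation between the bracketing samples
  time_h[i - 1L] + (threshold - od[i - 1L]) / (od[i] - od[i - 1L]) *
    (time_h[i] - time_h[i - 1L])
}

#' Fraction of sorted wells that regrow
#'
#' A sorted single-cell well "regrew" if its OD series crosses
#' `od_threshold` within the horizon. Returns per-replicate fractions with
#' their binomial standard deviation, plus the across-replicate mean +- SD
#' and the pooled estimate (both pooling conventions are reported).
#'
#' @param wells Long tibble with `well_id`, `replicate`, `time_h`, `od600`.
#' @param od_threshold OD600 threshold (default 0.5).
#' @param horizon_h Time horizon in hours; default is the last timepoint
#'   common to all wells.
#' @return A tibble with one row per replicate (`replicate`, `n_wells`,
#'   `n_regrew`, `fraction`, `binom_sd`); attributes `mean_fraction`,
#'   `sd_fraction`, `pooled_fraction`, `n_total`, `n_excluded`.
#' @export
regrowth_fraction <- function(wells, od_threshold = 0.5, horizon_h = NULL) {
  stopifnot(is.data.frame(wells),
            all(c("well_id", "replicate", "time_h", "od600") %in% names(wells)))
  if (nrow(wells) == 0L) abort("no wells")
  n_excluded <- 0L
  if (is.null(horizon_h)) {
    horizon_h <- wells |>
      group_by(.data$replicate, .data$well_id) |>
      summarise(tmax = max(.data$time_h), .groups = "drop")
    horizon_h <- min(horizon_h$tmax)
  }
  wells <- wells[wells$time_h <= horizon_h, , drop = FALSE]
  empty <- wells |>
    group_by(.data$replicate, .data$well_id) |>
    summarise(n_obs = sum(!is.na(.data$od600)), .groups = "drop")
  n_excluded <- sum(empty$n_obs == 0L)
  good <- empty[empty$n_obs > 0L, c("replicate", "well_id")]
  wells <- dplyr::semi_join(wells, good, by = c("replicate", "well_id"))
  tt <- time_to_threshold(wells, od_threshold)
  per_rep <- tt |>
    group_by(.data$replicate) |>
    summarise(
      n_wells = n(),
      n_regrew = sum(!is.na(.data$t_cross) & .data$t_cross <= horizon_h),
      .groups = "drop"
    ) |>
    mutate(fraction = .data$n_regrew / .data$n_wells,
           binom_sd = sqrt(.data$fraction * (1 - .data$fraction) / .data$n_wells))
  attr(per_rep, "mean_fraction") <- mean(per_rep$fraction)
  attr(per_rep, "sd_fraction") <- if (nrow(per_rep) >= 2L) sd(per_rep$fraction) else NA_real_
  attr(per_rep, "pooled_fraction") <- sum(per_rep$n_regrew) / sum(per_rep$n_wells)
  attr(per_rep, "n_total") <- sum(per_rep$n_wells)
  attr(per_rep, "n_excluded") <- n_excluded
  attr(per_rep, "horizon_h") <- horizon_h
  per_rep
}

#' Welch's unequal-variance two-sample t-test
#'
#' The unpaired t-test used for group comparisons of initial fluorescence:
#' Welch's statistic with Welch-Satterthwaite degrees of freedom and a
#' two-sided p-value, implemented from the formulas. If both groups have
#' zero variance, equal means give `t = 0, p = 1`; unequal means give
#' `p = 0` and the result is flagged degenerate.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @return An object of class `welch_t` with fields `mean_a`, `sd_a`,
#'   `n_a`, `mean_b`, `sd_b`, `n_b`, `statistic`, `df`, `p_value`,
#'   `degenerate`. Has [tidy()] and [glance()] methods.
#' @examples
#' welch_t(c(1, 2, 3, 4), c(2, 3, 4, 5))
#' @export
welch_t <- function(group_a, group_b) {
  a <- group_a[is.finite(group_a)]
  b <- group_b[is.finite(group_b)]
  if (length(a) < 2L || length(b) < 2L) abort("each group needs n >= 2")
  na <- length(a); nb <- length(b)
  ma <- mean(a); mb <- mean(b)
  va <- sum((a - ma)^2) / (na - 1)
  vb <- sum((b - mb)^2) / (nb - 1)
  degenerate <- FALSE
  if (va == 0 && vb == 0) {
    if (ma == mb) {
      t_stat <- 0; df <- na + nb - 2; p <- 1
    } else {
      t_stat <- sign(ma - mb) * Inf; df <- na + nb - 2; p <- 0
      degenerate <- TRUE
    }
  } else {
    se2 <- va / na + vb / nb
    t_stat <- (ma - mb) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- 2 * pt(-abs(t_stat), df)
  }
  structure(
    list(mean_a = ma, sd_a = sqrt(va), n_a = na,
         mean_b = mb, sd_b = sqrt(vb), n_b = nb,
         statistic = t_stat, df = df, p_value = p, degenerate = degenerate),
    class = "welch_t"
  )
}

#' @export
print.welch_t <- function(x, ...) {
  cat("Welch two-sample t-test\n")
  cat(sprintf("  group a: mean %.4g (sd %.4g, n %d)\n", x$mean_a, x$sd_a, x$n_a))
  cat(sprintf("  group b: mean %.4g (sd %.4g, n %d)\n", x$mean_b, x$sd_b, x$n_b))
  cat(sprintf("  t = %.4g, df = %.4g, p = %.4g%s\n", x$statistic, x$df,
              x$p_value, if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' @method tidy welch_t
#' @export
tidy.welch_t <- function(x, ...) {
  tibble(
    estimate = x$mean_a - x$mean_b,
    estimate_a = x$mean_a, estimate_b = x$mean_b,
    statistic = x$statistic, df = x$df, p.value = x$p_value,
    method = "Welch two-sample t-test", alternative = "two.sided"
  )
}

#' @method glance welch_t
#' @export
glance.welch_t <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p.value = x$p_value,
         n_a = x$n_a, n_b = x$n_b, degenerate = x$degenerate)
}

#' Escaper-phage fraction from paired plaque counts
#'
#' The fraction of plaque-forming units that escape CRISPR immunity: the
#' titer on a targeting host divided by the titer on a naive
#' (non-targeting) host. Vectorized over paired counts.
#'
#' @param pfu_targeting PFU counted on the spacer-matched (targeting) host.
#' @param pfu_naive PFU counted on the non-targeting host; must be > 0.
#' @return Numeric vector of escape fractions.
#' @examples
#' escape_fraction(90, 100)  # 0.9
#' @export
escape_fraction <- function(pfu_targeting, pfu_naive) {
  stopifnot(is.numeric(pfu_targeting), is.numeric(pfu_naive))
  if (any(pfu_naive <= 0, na.rm = TRUE) || any(is.na(pfu_naive))) {
    abort("no reference titer: pfu_naive must be > 0")
  }
  if (any(pfu_targeting < 0, na.rm = TRUE)) abort("PFU counts must be >= 0")
  pfu_targeting / pfu_naive
}
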