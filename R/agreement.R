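#' Bland-Altman agreement between two measurement methods
#'
#' For paired measurements the bias is the mean of the differences
#' (oriented A - B), the spread their sample standard deviation (n - 1),
#' and the 90% limits of agreement lie `k` standard deviations on either
#' side of the bias, with `k = 1.64` (the interval expected to contain
#' 90% of future paired differences).
#'
#' @param data A data frame holding the paired values.
#' @param a,b Columns of `data` with the two methods' values
#'   (tidy-selected; defaults `value_a` and `value_b`).
#' @param k Limits-of-agreement multiplier (default 1.64; use
#'   `loa_multiplier(0.90, exact = TRUE)` for the exact normal quantile).
#' @return An object of class `bland_altman` with fields `bias`, `sd`,
#'   `loa_low`, `loa_high`, `k`, `n`, `differences`, `means` and
#'   `orientation`.
#' @examples
#' df <- data.frame(value_a = c(10, 20, 10, 25), value_b = c(10, 15, 15, 15))
#' tidy(bland_altman(df))
#' @export
bland_altman <- function(data, a = "value_a", b = "value_b", k = 1.64) {
  stopifnot(is.data.frame(data), k > 0)
  va <- dplyr::pull(data, {{ a }})
  vb <- dplyr::pull(data, {{ b }})
  if (length(va) < 2) {
    stop("need at least 2 pairs to estimate the SD of differences",
         call. = FALSE)
  }
  d <- va - vb
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, sd = s,
                 loa_low = bias - k * s, loa_high = bias + k * s,
                 k = k, n = length(d), differences = d,
                 means = (va + vb) / 2, orientation = "a - b"),
            class = "bland_altman")
}

#' Limits-of-agreement multiplier for a given coverage
#'
#' @param coverage Two-sided coverage (default 0.90).
#' @param exact If `FALSE` (default), the conventional two-decimal
#'   constant (1.64 for 90%); if `TRUE`, the exact normal quantile.
#' @return The multiplier `k`.
#' @export
loa_multiplier <- function(coverage = 0.90, exact = FALSE) {
  z <- stats::qnorm((1 + coverage) / 2)
  if (exact) z else round(z, 2)
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> n = %d (%s): bias %.3f, SD %.3f, LoA [%.3f, %.3f] (k = %g)\n",
    x$n, x$orientation, x$bias, x$sd, x$loa_low, x$loa_high, x$k))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname bland_altman
#' @param x A `bland_altman` object.
#' @param ... Unused.
#' @method tidy bland_altman
#' @export
tidy.bland_altman <- function(x, ...) {
  tibble::tibble(bias = x$bias, sd = x$sd, loa_low = x$loa_low,
                 loa_high = x$loa_high, k = x$k, n = x$n)
}

#' @rdname bland_altman
#' @method glance bland_altman
#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(n = x$n, k = x$k,
                 outlier_rate_15db = outlier_rate(x$differences))
}

#' Per-frequency Bland-Altman analysis of a paired audiogram study
#'
#' Pairs each ear's thresholds across the two devices and runs
#' [bland_altman()] at every frequency.
#'
#' @param paired A long tibble as returned by [run_two_device_study()] or
#'   [read_paired_audiograms()]: columns `participant_id`, `ear`,
#'   `device` (two levels), `frequency_hz`, `threshold_hl`.
#' @param k Limits-of-agreement multiplier (default 1.64).
#' @return A tibble of class `agreement_by_freq`: one row per frequency
#'   with `frequency_hz`, `n`, `bias_db`, `sd_db`, `loa_low_db`,
#'   `loa_high_db`, and the per-ear differences in a `differences`
#'   list-column.
#' @export
agreement_by_frequency <- function(paired, k = 1.64) {
  devices <- sort(unique(paired$device))
  if (length(devices) != 2) {
    stop("paired data must contain exactly two devices, found: ",
         paste(devices, collapse = ", "), call. = FALSE)
  }
  wide <- tidyr::pivot_wider(
    dplyr::select(paired, "participant_id", "ear", "device",
                  "frequency_hz", "threshold_hl"),
    names_from = "device", values_from = "threshold_hl")
  if (anyNA(wide[[devices[1]]]) || anyNA(wide[[devices[2]]])) {
    stop("unpaired measurements: every (participant, ear, frequency) ",
         "must be measured on both devices", call. = FALSE)
  }
  out <- wide |>
    dplyr::group_by(.data$frequency_hz) |>
    dplyr::group_modify(function(g, key) {
      ba <- bland_altman(g, a = !!rlang::sym(devices[1]),
                         b = !!rlang::sym(devices[2]), k = k)
      tibble::tibble(n = ba$n, bias_db = ba$bias, sd_db = ba$sd,
                     loa_low_db = ba$loa_low, loa_high_db = ba$loa_high,
                     differences = list(ba$differences),
                     means = list(ba$means))
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$frequency_hz)
  class(out) <- c("agreement_by_freq", class(out))
  attr(out, "k") <- k
  attr(out, "orientation") <- paste(devices[1], "-", devices[2])
  out
}

#' Summarise agreement across frequencies
#'
#' Unweighted mean and sample SD over the per-frequency biases and limits
#' of agreement (the "average bias between frequencies" presentation),
#' plus a pooled analysis of all differences regardless of frequency.
#'
#' @param by_freq An `agreement_by_freq` tibble from
#'   [agreement_by_frequency()].
#' @return A one-row tibble: `mean_bias_db`, `sd_bias_db`,
#'   `mean_loa_low_db`, `sd_loa_low_db`, `mean_loa_high_db`,
#'   `sd_loa_high_db`, then pooled-difference versions (`pooled_bias_db`,
#'   `pooled_sd_db`, `pooled_loa_low_db`, `pooled_loa_high_db`) and
#'   `outlier_rate_15db`.
#' @export
summarize_agreement <- function(by_freq) {
  if (nrow(by_freq) < 2) {
    stop("need results at >= 2 frequencies to summarise", call. = FALSE)
  }
  k <- attr(by_freq, "k") %||% 1.64
  all_d <- unlist(by_freq$differences)
  pooled_bias <- mean(all_d)
  pooled_sd <- stats::sd(all_d)
  tibble::tibble(
    mean_bias_db = mean(by_freq$bias_db),
    sd_bias_db = stats::sd(by_freq$bias_db),
    mean_loa_low_db = mean(by_freq$loa_low_db),
    sd_loa_low_db = stats::sd(by_freq$loa_low_db),
    mean_loa_high_db = mean(by_freq$loa_high_db),
    sd_loa_high_db = stats::sd(by_freq$loa_high_db),
    pooled_bias_db = pooled_bias,
    pooled_sd_db = pooled_sd,
    pooled_loa_low_db = pooled_bias - k * pooled_sd,
    pooled_loa_high_db = pooled_bias + k * pooled_sd,
    outlier_rate_15db = outlier_rate(all_d)
  )
}

#' Fraction of large inter-device differences
#'
#' Differences at or beyond the cutoff (default 15 dB in absolute value)
#' are reported as an outlier rate; they are never removed from the
#' agreement analysis, to avoid biasing it.
#'
#' @param differences Numeric vector of paired differences (dB).
#' @param cutoff_db Absolute cutoff (default 15).
#' @return Fraction in `[0, 1]`.
#' @examples
#' outlier_rate(c(0, 15, -20, 5))  # 0.5
#' @export
outlier_rate <- function(differences, cutoff_db = 15) {
  if (length(differences) == 0) {
    stop("no differences supplied", call. = FALSE)
  }
  mean(abs(differences) >= cutoff_db)
}
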