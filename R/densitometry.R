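# Lane densitometry: ladder-based size calibration, intensity-weighted mean
# cDNA length, and the F_stop statistic
#   F_stop = I_GCSL / (I_readthrough + I_GCSL),
# where I_GCSL integrates the stall band and I_readthrough the intensity of
# LONGER extension products (molecules that passed the obstacle); shorter
# background stops are deliberately excluded from both.

# Local maxima of a smoothed trace above a fraction of the lane maximum,
# refined by parabolic interpolation through the three bins around each
# maximum (removes the half-bin quantization of the grid).
find_lane_peaks <- function(lane, min_frac = 0.05, smooth_bins = 3L) {
  y <- as.numeric(stats::filter(lane$intensity,
                                rep(1 / smooth_bins, smooth_bins),
                                sides = 2))
  y[is.na(y)] <- 0
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
                y[2:(n - 1)] >= y[3:n], FALSE)
  is_max <- is_max & y >= min_frac * max(y)
  idx <- which(is_max)
  dx <- attr(lane, "bin_width")
  vapply(idx, function(i) {
    denom <- y[i - 1] - 2 * y[i] + y[i + 1]
    shift <- if (denom < 0) 0.5 * (y[i - 1] - y[i + 1]) / denom else 0
    lane$mobility[i] + max(-0.5, min(0.5, shift)) * dx
  }, numeric(1))
}

#' Calibrate a mobility-to-length curve from a ladder lane
#'
#' Detects one peak per marker (local maxima above 5% of the lane maximum
#' after 3-bin moving-average smoothing) and builds a piecewise-linear
#' interpolant in (mobility, log10 length). Errors if the detected peak count
#' does not match the marker count or the peaks are not strictly ordered.
#'
#' @param ladder An `rt_lane_profile` from [render_ladder()] (or a measured
#'   ladder trace).
#' @param marker_sizes Marker lengths in nt, matching the ladder.
#' @return An object of class `rt_calibration`.
#' @export
#' @examples
#' model <- gel_model()
#' cal <- calibrate_ladder(render_ladder(model, c(100, 1000)), c(100, 1000))
#' predict_length(cal, mobility_of(model, 100)) # ~100
calibrate_ladder <- function(ladder, marker_sizes) {
  marker_sizes <- sort(unique(as.numeric(marker_sizes)), decreasing = TRUE)
  peaks <- find_lane_peaks(ladder)           # ascending mobility
  if (length(peaks) != length(marker_sizes)) {
    stop("detected ", length(peaks), " peaks for ", length(marker_sizes),
         " markers; calibration requires a one-to-one match", call. = FALSE)
  }
  if (any(diff(peaks) <= 0)) {
    stop("ladder peaks are not strictly ordered in mobility", call. = FALSE)
  }
  # ascending mobility corresponds to descending size
  structure(
    list(mobility = peaks, log10_length = log10(marker_sizes),
         length_range = range(marker_sizes)),
    class = "rt_calibration"
  )
}

#' Convert mobility to calibrated length
#'
#' Piecewise-linear interpolation in log10(length); `NA` outside the
#' calibrated mobility range.
#'
#' @param cal An `rt_calibration`.
#' @param mobility Numeric vector of mobilities.
#' @return Numeric vector of lengths in nt (`NA` outside range).
#' @export
predict_length <- function(cal, mobility) {
  stopifnot(inherits(cal, "rt_calibration"))
  rng <- range(cal$mobility)
  tol <- 1e-3 * diff(rng)       # numerical slack at the range boundaries
  mobility <- ifelse(mobility >= rng[1] - tol & mobility <= rng[2] + tol,
                     pmin(pmax(mobility, rng[1]), rng[2]), mobility)
  l10 <- stats::approx(cal$mobility, cal$log10_length, xout = mobility,
                       rule = 1)$y
  10^l10
}

#' Intensity-weighted mean cDNA length of a lane
#'
#' Calibrates every lane bin to a length and returns the intensity-weighted
#' mean over `window`, excluding everything below the window lower bound
#' (typically set just above the unextended-primer band).
#'
#' @param lane An `rt_lane_profile`.
#' @param cal An `rt_calibration`.
#' @param window Length range `c(lower, upper)` in nt; defaults to the full
#'   calibrated range.
#' @return Mean length in nt.
#' @export
lane_mean_length <- function(lane, cal, window = NULL) {
  stopifnot(inherits(cal, "rt_calibration"))
  len <- predict_length(cal, lane$mobility)
  if (is.null(window)) window <- cal$length_range
  keep <- !is.na(len) & len >= window[1] & len <= window[2]
  w <- lane$intensity[keep]
  if (sum(w) <= 1e-9 * sum(lane$intensity)) {
    stop("no intensity inside the requested window", call. = FALSE)
  }
  m <- stats::weighted.mean(len[keep], w)
  # a Gaussian band in mobility is log-normal in length, so the weighted
  # mean overshoots the band center by exp((ln10 * sigma / b)^2 / 2);
  # divide the known band-width factor back out
  sigma <- attr(lane, "band_sigma")
  slope <- attr(lane, "migration_slope")
  if (!is.null(sigma) && !is.null(slope)) {
    m <- m / exp((log(10) * sigma / slope)^2 / 2)
  }
  m
}

#' F_stop from lane densitometry
#'
#' Integrates the stall band `I_GCSL` over `[stall_len - tol, stall_len +
#' tol]` and the readthrough intensity `I_readthrough` over lengths greater
#' than `stall_len + tol`, and returns
#' `F_stop = I_GCSL / (I_readthrough + I_GCSL)`.
#'
#' By default `tol` adapts to the rendered band width: 3.5 standard
#' deviations of the Gaussian band at the stall length (`sd = stall_len *
#' ln(10) * band_sigma / migration_slope`), floored at 15 nt, so that the
#' window integrates essentially the whole stall band -- the analogue of
#' drawing a box around the band in densitometry software.
#'
#' @param lane An `rt_lane_profile`.
#' @param cal An `rt_calibration`.
#' @param stall_len Expected truncated-product length in nt.
#' @param tol Half-width of the stall integration window in nt, or `NULL`
#'   for the adaptive default.
#' @return A one-row tibble with `i_gcsl`, `i_readthrough`, `f_stop`, `tol`.
#' @export
#' @examples
#' model <- gel_model()
#' cal <- calibrate_ladder(render_ladder(model), c(25, 50, 100, 200, 500, 1000, 2000, 3000))
#' lane <- render_gel_lane(rep(c(378, 1883), c(860, 140)), model)
#' compute_fstop(lane, cal, 378)
compute_fstop <- function(lane, cal, stall_len, tol = NULL) {
  stopifnot(inherits(cal, "rt_calibration"))
  if (stall_len < cal$length_range[1] || stall_len > cal$length_range[2]) {
    stop("`stall_len` lies outside the calibrated range", call. = FALSE)
  }
  if (is.null(tol)) {
    sigma <- attr(lane, "band_sigma")
    slope <- attr(lane, "migration_slope")
    if (is.null(sigma) || is.null(slope)) {
      stop("`tol` must be given for lanes without band-width metadata",
           call. = FALSE)
    }
    tol <- max(15, 3.5 * stall_len * log(10) * sigma / slope)
  }
  len <- predict_length(cal, lane$mobility)
  dx <- attr(lane, "bin_width")
  in_stall <- !is.na(len) & abs(len - stall_len) <= tol
  longer <- !is.na(len) & len > stall_len + tol
  i_gcsl <- sum(lane$intensity[in_stall]) * dx
  i_rt <- sum(lane$intensity[longer]) * dx
  if (i_gcsl + i_rt <= 0) {
    stop("no intensity in either the stall or the readthrough window",
         call. = FALSE)
  }
  tibble::tibble(i_gcsl = i_gcsl, i_readthrough = i_rt,
                 f_stop = i_gcsl / (i_gcsl + i_rt), tol = tol)
}

#' Measure a simulated time course through the gel channel
#'
#' Renders one lane per (time point, replicate) tube -- applying a per-lane
#' mobility offset drawn from `Normal(0, lane_jitter_sd)` -- calibrates
#' against a rendered ladder, and returns the intensity-weighted mean length
#' per lane. The default window spans from just above the unextended-primer
#' band (`primer_len + 5`) to the top of the calibrated range.
#'
#' @param products An `rt_product_table` from [simulate_timecourse()].
#' @param spec The `rt_template` the products were simulated on.
#' @param model A [gel_model()].
#' @param marker_sizes Ladder marker lengths.
#' @param window Length window for the mean, or `NULL` for the default.
#' @return A tibble with columns `time_s`, `replicate`, `mean_length`.
#' @export
measure_gel_timecourse <- function(products, spec, model = gel_model(),
                                   marker_sizes = NULL,
                                   window = NULL) {
  stopifnot(inherits(spec, "rt_template"))
  if (is.null(marker_sizes)) marker_sizes <- default_markers(model)
  cal <- calibrate_ladder(render_ladder(model, marker_sizes), marker_sizes)
  if (is.null(window)) {
    window <- c(spec$primer_len + 5, cal$length_range[2])
  }
  products |>
    dplyr::group_by(.data$time_s, .data$replicate) |>
    dplyr::group_modify(function(df, key) {
      offset <- stats::rnorm(1, 0, model$lane_jitter_sd)
      lane <- render_gel_lane(df$product_len, model,
                              mobility_offset = offset)
      tibble::tibble(mean_length = lane_mean_length(lane, cal, window))
    }) |>
    dplyr::ungroup()
}
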