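# The inference core: cDNA lengths from alignments, length distributions and
# their peak maxima, replicate averaging, and ordinary-least-squares velocity
# estimation. The gel channel feeds intensity-weighted mean lengths into the
# fit; the nanopore channel feeds distribution peak maxima; both use the same
# regression.

# Reference-consumed span of one CIGAR string (M/D/N/=/X count).
cigar_ref_span <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    lens <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
    ops <- regmatches(cg, gregexpr("[MIDNSHP=X]", cg))[[1]]
    sum(lens[ops %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' cDNA length from SAM alignment records
#'
#' The cDNA length of a read is the reference-consumed span of its alignment
#' (alignment end - POS + 1, counting M/D/N/=/X CIGAR operations) -- a
#' native re-implementation of the custom length-extraction step of the
#' assay. Unmapped or CIGAR-less records are dropped with a message.
#'
#' @param alignments A tibble of SAM records (see [read_sam()]) with at
#'   least `flag`, `pos` and `cigar` columns.
#' @return The mapped subset of `alignments` with a `length` column added.
#' @export
#' @examples
#' cdna_length_from_alignment(
#'   tibble::tibble(flag = 0L, pos = 1550L, cigar = "378M"))$length # 378
cdna_length_from_alignment <- function(alignments) {
  stopifnot(is.data.frame(alignments))
  unmapped <- bitwAnd(alignments$flag, 4L) != 0L |
    is.na(alignments$cigar) | alignments$cigar == "*" |
    is.na(alignments$pos)
  if (any(unmapped)) {
    message("skipping ", sum(unmapped), " unmapped or CIGAR-less record(s)")
  }
  out <- alignments[!unmapped, , drop = FALSE]
  out$length <- cigar_ref_span(out$cigar)
  out
}

#' Histogram of cDNA lengths
#'
#' Fixed-origin binning from 0 with the given bin width; counts are
#' conserved.
#'
#' @param lengths Integer vector of cDNA lengths (>= 1).
#' @param bin_width Bin width in nt (default 25).
#' @return A tibble of class `rt_length_distribution` with `bin_start`,
#'   `bin_end`, `bin_mid`, `count` (empty bins included).
#' @export
#' @examples
#' length_distribution(c(100, 100, 200), bin_width = 50)
length_distribution <- function(lengths, bin_width = 25L) {
  stopifnot(bin_width >= 1)
  if (!length(lengths)) stop("`lengths` is empty", call. = FALSE)
  bin <- lengths %/% bin_width            # fixed origin at 0
  n_bins <- max(bin) + 1L
  counts <- tabulate(bin + 1L, nbins = n_bins)
  out <- tibble::tibble(
    bin_start = (seq_len(n_bins) - 1L) * bin_width,
    bin_end = seq_len(n_bins) * bin_width,
    bin_mid = (seq_len(n_bins) - 0.5) * bin_width,
    count = counts
  )
  class(out) <- c("rt_length_distribution", class(out))
  attr(out, "bin_width") <- bin_width
  attr(out, "n_reads") <- length(lengths)
  out
}

#' Peak maximum of a length distribution
#'
#' Center of the maximal-count bin; ties are broken toward the larger
#' length (the front of the advancing population).
#'
#' @param dist An `rt_length_distribution`.
#' @return Bin center in nt.
#' @export
peak_maximum <- function(dist) {
  if (!sum(dist$count)) stop("empty distribution", call. = FALSE)
  best <- which(dist$count == max(dist$count))
  dist$bin_mid[max(best)]
}

#' Average per-replicate length estimates at each time point
#'
#' Arithmetic mean and sample standard deviation per time point; for a
#' single replicate the sd is reported as 0 and flagged.
#'
#' @param per_replicate A tibble with columns `time_s` and `value` (one row
#'   per replicate measurement).
#' @return A tibble with `time_s`, `mean`, `sd`, `n_replicates`,
#'   `single_replicate`.
#' @export
#' @examples
#' average_replicates(tibble::tibble(time_s = 10, value = c(250, 260, 255)))
average_replicates <- function(per_replicate) {
  stopifnot(all(c("time_s", "value") %in% names(per_replicate)))
  per_replicate |>
    dplyr::group_by(.data$time_s) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = ifelse(dplyr::n() > 1L, stats::sd(.data$value), 0),
      n_replicates = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(single_replicate = .data$n_replicates == 1L)
}

#' Fit elongation velocity by ordinary least squares
#'
#' Regresses cDNA length on reaction time. The slope is the velocity in
#' nt/s; the intercept estimates the primer length. Points should come from
#' unsaturated time points only (see [saturation_by_time()]); the
#' higher-level estimators exclude time points where at least half the
#' population has reached full length, because the length ceiling flattens
#' the line.
#'
#' @param points A tibble with columns `time_s` and `length_nt`.
#' @param weights Optional per-point weights (e.g. inverse variances);
#'   `NULL` (default) for the unweighted fit.
#' @return An object of class `rt_velocity_fit` with elements `slope`,
#'   `slope_se`, `intercept`, `intercept_se`, `r2`, `n_points` and the
#'   underlying `lm` fit. Supports [generics::tidy()], [generics::glance()]
#'   and [ggplot2::autoplot()].
#' @export
#' @examples
#' fit_velocity(tibble::tibble(time_s = 0:2, length_nt = c(20, 45, 70)))
fit_velocity <- function(points, weights = NULL) {
  stopifnot(all(c("time_s", "length_nt") %in% names(points)))
  if (length(unique(points$time_s)) < 2L) {
    stop("at least two distinct time points are required", call. = FALSE)
  }
  fit <- stats::lm(length_nt ~ time_s, data = points, weights = weights)
  sm <- suppressWarnings(summary(fit))   # exact lines are legitimate input
  structure(
    list(slope = unname(stats::coef(fit)["time_s"]),
         slope_se = sm$coefficients["time_s", "Std. Error"],
         intercept = unname(stats::coef(fit)["(Intercept)"]),
         intercept_se = sm$coefficients["(Intercept)", "Std. Error"],
         r2 = sm$r.squared,
         n_points = nrow(points),
         fit = fit,
         points = tibble::as_tibble(points)),
    class = "rt_velocity_fit"
  )
}

#' @export
print.rt_velocity_fit <- function(x, ...) {
  cat("<rt_velocity_fit>\n")
  cat(sprintf("  velocity  : %.2f +/- %.2f nt/s\n", x$slope, x$slope_se))
  cat(sprintf("  intercept : %.1f +/- %.1f nt\n", x$intercept,
              x$intercept_se))
  cat(sprintf("  r^2       : %.4f   (n = %d points)\n", x$r2, x$n_points))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a velocity fit
#'
#' @param x An `rt_velocity_fit`.
#' @param ... Unused.
#' @return A tibble with one row per model term.
#' @export
tidy.rt_velocity_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("intercept_nt", "velocity_nt_per_s"),
    estimate = c(x$intercept, x$slope),
    std.error = c(x$intercept_se, x$slope_se),
    statistic = sm[, "t value"],
    p.value = sm[, "Pr(>|t|)"]
  )
}

#' Glance at a velocity fit
#'
#' @inheritParams tidy.rt_velocity_fit
#' @return A one-row tibble with `velocity`, `velocity_se`, `intercept`,
#'   `r.squared`, `sigma`, `nobs`.
#' @export
glance.rt_velocity_fit <- function(x, ...) {
  tibble::tibble(
    velocity = x$slope, velocity_se = x$slope_se,
    intercept = x$intercept, r.squared = x$r2,
    sigma = summary(x$fit)$sigma, nobs = x$n_points
  )
}

#' Estimate velocity from a simulated gel time course
#'
#' Runs the full gel channel: per-lane densitometry means (with per-lane
#' mobility jitter), exclusion of saturated time points (fraction of
#' run-off molecules >= `saturation_threshold`), replicate averaging, and
#' the OLS fit. With `per_replicate = TRUE` each replicate is fit
#' separately and a list of fits is returned (the single-cycle analysis
#' averages the three replicate slopes).
#'
#' @inheritParams measure_gel_timecourse
#' @param saturation_threshold Drop time points whose run-off fraction
#'   reaches this value (default 0.5).
#' @param per_replicate Fit each replicate separately?
#' @return An `rt_velocity_fit`, or a list of them when
#'   `per_replicate = TRUE`.
#' @export
estimate_velocity_gel <- function(products, spec, model = gel_model(),
                                  marker_sizes = NULL,
                                  window = NULL,
                                  saturation_threshold = 0.5,
                                  per_replicate = FALSE) {
  meas <- measure_gel_timecourse(products, spec, model, marker_sizes, window)
  sat <- saturation_by_time(products)
  keep_t <- sat$time_s[sat$fraction_full_length < saturation_threshold]
  meas <- dplyr::filter(meas, .data$time_s %in% keep_t)
  if (per_replicate) {
    meas |>
      dplyr::group_by(.data$replicate) |>
      dplyr::group_map(function(df, key) {
        fit_velocity(tibble::tibble(time_s = df$time_s,
                                    length_nt = df$mean_length))
      })
  } else {
    # fit on the replicate-level lane measurements: for a balanced design
    # the slope equals the fit through the time-point averages, but the
    # residual degrees of freedom (and hence the standard errors) are
    # estimated from every lane rather than from the averaged points
    fit_velocity(tibble::tibble(time_s = meas$time_s,
                                length_nt = meas$mean_length))
  }
}

#' Estimate velocity from per-time-point read length distributions
#'
#' The nanopore-channel estimator: bins the recovered cDNA lengths at each
#' time point, takes the distribution peak maximum, drops saturated time
#' points (fraction of full-length reads >= `saturation_threshold`), and
#' fits the peak positions against time.
#'
#' @param read_lengths A tibble with columns `time_s` and `length` (one row
#'   per read; see [cdna_length_from_alignment()]).
#' @param full_length Full-length product size in nt (see [full_length()]).
#' @param bin_width Histogram bin width in nt.
#' @param saturation_threshold Drop time points where the full-length read
#'   fraction reaches this value.
#' @param full_length_tol Reads within this many nt of `full_length` count
#'   as full length (terminal-indel jitter).
#' @return An `rt_velocity_fit`.
#' @export
estimate_velocity_reads <- function(read_lengths, full_length,
                                    bin_width = 25L,
                                    saturation_threshold = 0.5,
                                    full_length_tol = 2L) {
  stopifnot(all(c("time_s", "length") %in% names(read_lengths)))
  peaks <- read_lengths |>
    dplyr::group_by(.data$time_s) |>
    dplyr::summarise(
      peak = peak_maximum(length_distribution(.data$length, bin_width)),
      fraction_full = mean(.data$length >= full_length - full_length_tol),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$fraction_full < saturation_threshold)
  fit_velocity(tibble::tibble(time_s = peaks$time_s, length_nt = peaks$peak))
}
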