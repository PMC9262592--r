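# Denaturing-gel measurement channel. Electrophoretic mobility is linear in
# log10(fragment length) (standard denaturing-PAGE behavior); each molecule
# contributes a Gaussian band on the mobility axis and a lane is the sum of
# its bands, discretized on a fixed bin grid shared with the ladder lane.

#' Gel rendering model
#'
#' @param migration_intercept Mobility of a (hypothetical) 1-nt fragment, in
#'   arbitrary mobility units (`a` in `mobility = a - b * log10(length)`).
#' @param migration_slope Mobility decrease per decade of length (`b` > 0).
#' @param band_sigma Gaussian band width (sd) in mobility units.
#' @param profile_bins Number of bins of the discretized lane trace.
#' @param intensity_per_molecule Integrated band area contributed by one
#'   molecule (arbitrary units).
#' @param min_length,max_length Fragment lengths delimiting the rendered
#'   mobility axis.
#' @param lane_jitter_sd Standard deviation (mobility units) of a per-lane
#'   mobility offset emulating gel-to-gel migration variability; drawn once
#'   per lane by [measure_gel_timecourse()]. Set to 0 for an ideal gel.
#' @return An object of class `rt_gel_model`.
#' @export
gel_model <- function(migration_intercept = 100, migration_slope = 30,
                      band_sigma = 0.6, profile_bins = 1200L,
                      intensity_per_molecule = 1,
                      min_length = 10L, max_length = 3500L,
                      lane_jitter_sd = 0.2) {
  stopifnot(migration_slope > 0, band_sigma > 0, profile_bins >= 10L,
            intensity_per_molecule > 0, min_length >= 1L,
            max_length > min_length, lane_jitter_sd >= 0)
  structure(
    list(migration_intercept = migration_intercept,
         migration_slope = migration_slope, band_sigma = band_sigma,
         profile_bins = as.integer(profile_bins),
         intensity_per_molecule = intensity_per_molecule,
         min_length = as.integer(min_length),
         max_length = as.integer(max_length),
         lane_jitter_sd = lane_jitter_sd),
    class = "rt_gel_model"
  )
}

#' Electrophoretic mobility of a fragment length
#'
#' @param model An [gel_model()].
#' @param length Fragment length(s) in nt.
#' @return Mobility in arbitrary units.
#' @export
mobility_of <- function(model, length) {
  model$migration_intercept - model$migration_slope * log10(length)
}

gel_axis <- function(model) {
  lo <- mobility_of(model, model$max_length) - 3 * model$band_sigma
  hi <- mobility_of(model, model$min_length) + 3 * model$band_sigma
  centers <- seq(lo, hi, length.out = model$profile_bins)
  list(centers = centers, width = centers[2] - centers[1])
}

new_lane_profile <- function(mobility, intensity, label, model) {
  out <- tibble::tibble(mobility = mobility, intensity = intensity)
  class(out) <- c("rt_lane_profile", class(out))
  attr(out, "label") <- label
  attr(out, "bin_width") <- mobility[2] - mobility[1]
  attr(out, "band_sigma") <- model$band_sigma
  attr(out, "migration_slope") <- model$migration_slope
  out
}

#' Render a population of cDNA lengths as a gel lane trace
#'
#' Each molecule contributes a Gaussian band centered at its mobility; the
#' integrated lane intensity equals `length(lengths) * intensity_per_molecule`
#' (intensity conservation), up to the axis truncation of band tails.
#'
#' @param lengths Integer vector of product lengths (>= 1); one entry per
#'   molecule.
#' @param model A [gel_model()].
#' @param label Lane label.
#' @param mobility_offset Additive mobility shift applied to every band in
#'   this lane (per-lane migration jitter); default 0.
#' @return A tibble of class `rt_lane_profile` with columns `mobility` and
#'   `intensity`.
#' @export
#' @examples
#' lane <- render_gel_lane(rep(c(378, 1883), each = 100), gel_model())
render_gel_lane <- function(lengths, model = gel_model(), label = "lane",
                            mobility_offset = 0) {
  stopifnot(inherits(model, "rt_gel_model"))
  if (length(lengths) == 0L) {
    stop("`lengths` must contain at least one molecule", call. = FALSE)
  }
  if (any(lengths < 1)) stop("`lengths` must be >= 1", call. = FALSE)
  ax <- gel_axis(model)
  tab <- table(lengths)
  centers <- mobility_of(model, as.numeric(names(tab))) + mobility_offset
  counts <- as.numeric(tab)
  # bins x bands Gaussian evaluation, collapsed by band multiplicity
  dens <- vapply(seq_along(centers), function(i) {
    stats::dnorm(ax$centers, centers[i], model$band_sigma) * counts[i]
  }, numeric(length(ax$centers)))
  intensity <- if (is.matrix(dens)) rowSums(dens) else dens
  new_lane_profile(ax$centers, intensity * model$intensity_per_molecule,
                   label, model)
}

#' Render a size-ladder lane
#'
#' One unit-area band per marker; centers are strictly ordered in mobility
#' because mobility is strictly decreasing in length.
#'
#' @param model A [gel_model()].
#' @param marker_sizes At least two distinct marker lengths in nt.
#' @return An `rt_lane_profile` labeled `"ladder"`.
#' @export
render_ladder <- function(model = gel_model(),
                          marker_sizes = c(25, 50, 100, 200, 500, 1000, 2000, 3000)) {
  marker_sizes <- sort(unique(as.numeric(marker_sizes)))
  if (length(marker_sizes) < 2L) {
    stop("at least two distinct markers are required for calibration",
         call. = FALSE)
  }
  render_gel_lane(marker_sizes, model, label = "ladder")
}

#' Default ladder markers for a gel model
#'
#' The canonical marker set restricted to sizes the model's axis renders
#' without edge truncation.
#'
#' @param model A [gel_model()].
#' @return Numeric vector of at least two marker sizes.
#' @export
default_markers <- function(model) {
  m <- c(25, 50, 100, 200, 500, 1000, 2000, 3000)
  m <- m[m >= model$min_length & m <= model$max_length]
  if (length(m) < 2L) {
    stop("gel model range too narrow for the canonical ladder", call. = FALSE)
  }
  m
}

#' Integrated intensity of a lane
#'
#' Trapezoid-free Riemann sum `sum(intensity) * bin_width`; equals
#' molecules x intensity-per-molecule for bands away from the axis edges.
#'
#' @param lane An `rt_lane_profile`.
#' @return A single number.
#' @export
lane_total_intensity <- function(lane) {
  sum(lane$intensity) * attr(lane, "bin_width")
}
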