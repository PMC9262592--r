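# Per-position stop-site analysis from alignment termini. The "stop
# position" of a read is the template coordinate of the last incorporated
# nucleotide, i.e. the smallest reference coordinate covered by the
# alignment (synthesis runs toward coordinate 1). This is a native
# re-implementation of termination-event counting from aligned reads; no
# mutational-profiling event counting is attempted.

#' Count read termini and coverage along the template
#'
#' The terminus of a read is its 5'-most covered reference coordinate (its
#' POS); a read reaches every coordinate its reference span covers.
#' Records mapped to a different reference are rejected with a message.
#'
#' @param alignments A tibble of mapped records with columns `rname`, `pos`
#'   and either `length` (reference span) or `cigar` (spans are then
#'   computed via [cdna_length_from_alignment()]).
#' @param spec The `rt_template` the reads were aligned to.
#' @return A tibble of class `rt_stop_profile` with one row per template
#'   coordinate: `position`, `n_terminating`, `n_reaching`,
#'   `stop_frequency` (`NA` where nothing reaches). The total of
#'   `n_terminating` equals the number of accepted reads.
#' @export
#' @examples
#' aln <- tibble::tibble(rname = "toy", pos = c(1L, 5L), length = c(10L, 6L))
#' spec <- template_spec("toy", 30, 28, 5)
#' count_termini(aln, spec)
count_termini <- function(alignments, spec) {
  stopifnot(inherits(spec, "rt_template"), is.data.frame(alignments))
  if (!"length" %in% names(alignments)) {
    alignments <- cdna_length_from_alignment(alignments)
  }
  if ("rname" %in% names(alignments)) {
    foreign <- alignments$rname != spec$name
    if (any(foreign)) {
      message("rejecting ", sum(foreign),
              " read(s) mapped to an unknown reference")
      alignments <- alignments[!foreign, , drop = FALSE]
    }
  }
  L <- spec$length
  if (any(alignments$pos < 1L | alignments$pos + alignments$length - 1L > L)) {
    stop("alignment span exceeds the template", call. = FALSE)
  }
  n_term <- tabulate(alignments$pos, nbins = L)
  ends <- tabulate(alignments$pos + alignments$length, nbins = L + 1L)
  cov <- cumsum(n_term - ends[seq_len(L)])
  out <- tibble::tibble(
    position = seq_len(L),
    n_terminating = n_term,
    n_reaching = cov,
    stop_frequency = ifelse(cov > 0L, n_term / cov, NA_real_)
  )
  class(out) <- c("rt_stop_profile", class(out))
  attr(out, "template") <- spec$name
  attr(out, "n_reads") <- nrow(alignments)
  attr(out, "primer_window_start") <- primer_window_start(spec)
  out
}

# Pooled terminating counts: sum of n_terminating over position +/- window.
pooled_termini <- function(profile, window) {
  if (window == 0L) return(profile$n_terminating)
  kern <- rep(1, 2L * window + 1L)
  as.numeric(stats::filter(profile$n_terminating, kern, sides = 2,
                           circular = FALSE)) |>
    (\(x) ifelse(is.na(x), profile$n_terminating, x))()
}

#' Call the dominant stop site
#'
#' Ranks template coordinates by pooled stop frequency: termini within
#' `aggregate_window` nt are pooled onto each candidate (indel-bearing
#' alignments jitter endpoints by a nucleotide or two), frequencies are
#' computed against the coverage at the candidate, positions reached by
#' fewer than `min_reaching` reads are never called, and the full-length
#' (run-off) terminus at the template 5' end is excluded by default --
#' running off the template is not a stop. Ties break toward the 3'-most
#' (largest) coordinate.
#'
#' @param profile An `rt_stop_profile` from [count_termini()].
#' @param min_reaching Minimum coverage for a callable position.
#' @param exclude_full_length Exclude coordinates within
#'   `aggregate_window` of the template 5' end?
#' @param aggregate_window Half-width (nt) of the terminus pooling window.
#' @return A one-row tibble with `coordinate`, `stop_frequency` (pooled),
#'   `n_terminating` (pooled), `n_reaching` and `low_confidence` (`TRUE`
#'   when the called frequency does not stand out above the background
#'   median).
#' @export
call_dominant_stop <- function(profile, min_reaching = 50L,
                               exclude_full_length = TRUE,
                               aggregate_window = 2L) {
  stopifnot(inherits(profile, "rt_stop_profile"))
  w <- as.integer(aggregate_window)
  pooled <- pooled_termini(profile, w)
  n_term <- profile$n_terminating
  # candidates: positions carrying a local maximum of raw terminus counts
  # within the pooling window (endpoint jitter collapses onto these)
  local_max <- if (w > 0L) {
    run_max <- vapply(seq_along(n_term), function(c) {
      max(n_term[max(1L, c - w):min(length(n_term), c + w)])
    }, integer(1))
    n_term > 0L & n_term == run_max
  } else {
    n_term > 0L
  }
  freq <- ifelse(profile$n_reaching > 0,
                 pmin(pooled / profile$n_reaching, 1), NA_real_)
  eligible <- local_max & profile$n_reaching >= min_reaching &
    profile$position < attr(profile, "primer_window_start")
  if (exclude_full_length) {
    eligible <- eligible & profile$position > 1L + w
  }
  if (!any(eligible, na.rm = TRUE)) {
    stop("no coordinate passes the `min_reaching` threshold", call. = FALSE)
  }
  f <- ifelse(eligible & !is.na(freq), freq, -Inf)
  best <- max(which(f == max(f)))                 # tie toward 3'-most
  others <- eligible
  others[best] <- FALSE
  bg <- if (any(others)) stats::median(freq[others], na.rm = TRUE) else 0
  tibble::tibble(
    coordinate = profile$position[best],
    stop_frequency = freq[best],
    n_terminating = pooled[best],
    n_reaching = profile$n_reaching[best],
    low_confidence = freq[best] < max(0.01, 3 * bg) || pooled[best] < 20
  )
}

#' Read-count F_stop at a stall coordinate
#'
#' The read-based analogue of the densitometry statistic: the fraction of
#' obstacle-reaching reads that terminate at the stall,
#' `n_terminating(stall) / (n_terminating(stall) + reads extending past)`.
#' Since every read covering the stall either terminates there or extends
#' past it, the denominator is the coverage at the stall.
#'
#' @param profile An `rt_stop_profile`.
#' @param stall_coord Template coordinate of the stall.
#' @param window Pool termini within this many nt of the stall (for noisy
#'   alignments); default 0.
#' @return The stop fraction in `[0, 1]`.
#' @export
fstop_from_reads <- function(profile, stall_coord, window = 0L) {
  stopifnot(inherits(profile, "rt_stop_profile"))
  row <- which(profile$position == stall_coord)
  if (!length(row)) stop("`stall_coord` not on the template", call. = FALSE)
  reach <- profile$n_reaching[row]
  if (reach == 0L) stop("no read reaches the stall coordinate", call. = FALSE)
  pooled <- pooled_termini(profile, window)
  min(pooled[row] / reach, 1)
}

#' Truncated product length implied by a stop coordinate
#'
#' Delegates to [product_length()]: the band size a stop at `coordinate`
#' produces, for cross-checking the read-based stop call against the
#' densitometry stall band.
#'
#' @param spec An `rt_template`.
#' @param coordinate Stop coordinate (last incorporated nucleotide).
#' @return Product length in nt.
#' @export
#' @examples
#' truncation_length_at(gcsl_template(), 1550) # 378
truncation_length_at <- function(spec, coordinate) {
  product_length(spec, coordinate)
}
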