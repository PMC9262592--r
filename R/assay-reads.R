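# Nanopore-style read emission. Each surviving molecule yields one read
# covering template interval [p_last, primer_anchor] on the DNA-sense
# reference; reads are emitted cDNA-sense with the SAM reverse flag unset
# (the pipeline measures reference spans, not strands, which avoids
# double reverse-complement bookkeeping). Substitutions perturb bases only;
# deletions become D operations (reference-consuming) and insertions I
# operations, so the reference span stays anchored to the true product
# length except where a terminal indel is absorbed into the alignment ends,
# which jitters POS/span by a nucleotide or two -- the behavior long-read
# aligners show on noisy ends.

#' Sequencing error and library-dropout model
#'
#' Defaults are nanopore-like: substitution 0.05, insertion 0.03, deletion
#' 0.05 per base, and a per-nucleotide library-survival penalty
#' `exp(-length_dropout_coef * product_len)` reproducing the amplitude decay
#' of longer products in library construction.
#'
#' @param substitution_rate,insertion_rate,deletion_rate Per-base error
#'   probabilities in `[0, 1)`.
#' @param length_dropout_coef Per-nt survival penalty (>= 0).
#' @return An object of class `rt_read_error_model`.
#' @export
read_error_model <- function(substitution_rate = 0.05,
                             insertion_rate = 0.03,
                             deletion_rate = 0.05,
                             length_dropout_coef = 3e-4) {
  rates <- c(substitution_rate, insertion_rate, deletion_rate)
  if (any(rates < 0) || any(rates >= 1)) {
    stop("error rates must lie in [0, 1)", call. = FALSE)
  }
  stopifnot(length_dropout_coef >= 0)
  structure(
    list(substitution_rate = substitution_rate,
         insertion_rate = insertion_rate,
         deletion_rate = deletion_rate,
         length_dropout_coef = length_dropout_coef),
    class = "rt_read_error_model"
  )
}

#' Error-free model (identity channel)
#' @return An `rt_read_error_model` with all rates zero.
#' @export
perfect_reads <- function() {
  read_error_model(0, 0, 0, 0)
}

# Build a CIGAR from deletion/insertion positions within a 1..span reference
# walk. Terminal deletions are absorbed (leading ones shift POS, trailing
# ones shorten the span), as an aligner would clip them.
build_cigar <- function(span, del_pos, ins_pos) {
  del_pos <- sort(unique(del_pos))
  ins_pos <- sort(ins_pos)                 # gaps 0..span; repeats allowed
  # absorb leading deletions (1, 2, ... consecutive)
  lead <- 0L
  while (lead < length(del_pos) && del_pos[lead + 1L] == lead + 1L) {
    lead <- lead + 1L
  }
  # absorb trailing deletions (span, span-1, ... consecutive)
  trail <- 0L
  nd <- length(del_pos)
  while (trail < nd - lead && del_pos[nd - trail] == span - trail) {
    trail <- trail + 1L
  }
  lo <- lead + 1L
  hi <- span - trail
  if (lo > hi) {
    return(list(cigar = NA_character_, pos_shift = lead, ref_span = 0L,
                lo = lo, hi = hi, del_used = integer(0),
                ins_used = integer(0)))
  }
  del_pos <- del_pos[del_pos >= lo & del_pos <= hi]
  ins_pos <- ins_pos[ins_pos >= lo - 1L & ins_pos <= hi]
  # walk events in coordinate order; insertion at gap g sits after ref pos g
  ops <- character(0)
  lens <- integer(0)
  push <- function(op, len) {
    if (len <= 0L) return()
    n <- length(ops)
    if (n && ops[n] == op) {
      lens[n] <<- lens[n] + len
    } else {
      ops[n + 1L] <<- op
      lens[n + 1L] <<- len
    }
  }
  events <- rbind(
    if (length(del_pos)) cbind(pos = del_pos, type = 1L),
    if (length(ins_pos)) cbind(pos = ins_pos, type = 2L)
  )
  cur <- lo - 1L   # last reference position emitted
  if (!is.null(events)) {
    events <- events[order(events[, "pos"], events[, "type"]), , drop = FALSE]
    for (r in seq_len(nrow(events))) {
      p <- events[r, "pos"]
      if (events[r, "type"] == 1L) {        # deletion of ref pos p
        push("M", p - 1L - cur)
        push("D", 1L)
        cur <- p
      } else {                              # insertion after ref pos p
        push("M", p - cur)
        cur <- max(cur, p)
        push("I", 1L)
      }
    }
  }
  push("M", hi - cur)
  list(cigar = paste0(lens, ops, collapse = ""),
       pos_shift = lead, ref_span = hi - lo + 1L,
       lo = lo, hi = hi, del_used = del_pos, ins_used = ins_pos)
}

#' Emit nanopore-style reads and SAM alignment records
#'
#' Every simulated molecule survives library construction with probability
#' `exp(-length_dropout_coef * product_len)`; each surviving molecule yields
#' one read whose SAM record has `POS = p_last` and a CIGAR whose
#' reference-consumed length equals the product length, up to terminal-indel
#' jitter under nonzero error rates. Draws from the current RNG state.
#'
#' @param products An `rt_product_table` (or any tibble with `p_last` and
#'   `product_len` columns).
#' @param spec An `rt_template` carrying a sequence (see
#'   [add_template_sequence()]).
#' @param err A [read_error_model()].
#' @param with_seq If `FALSE`, skip base-level sequence construction and
#'   emit `*` SEQ/QUAL fields (faster; spans and CIGARs are unaffected).
#' @return A tibble of class `rt_read_set` with SAM-ready columns `qname`,
#'   `flag`, `rname`, `pos`, `mapq`, `cigar`, `seq`, `qual` plus the true
#'   `product_len`; the number of dropout-lost molecules is in
#'   `attr(, "n_dropped")`.
#' @export
#' @examples
#' set.seed(1)
#' spec <- add_template_sequence(build_wt_template())
#' prods <- simulate_timecourse(mrt_profile(), spec,
#'   timecourse_design(20, replicates = 1, molecules_per_reaction = 10))
#' emit_reads(prods, spec, perfect_reads())
emit_reads <- function(products, spec, err = read_error_model(),
                       with_seq = TRUE) {
  stopifnot(inherits(spec, "rt_template"), inherits(err, "rt_read_error_model"))
  if (is.null(spec$sequence)) {
    stop("`spec` carries no sequence; call add_template_sequence() or ",
         "supply a FASTA template", call. = FALSE)
  }
  n <- nrow(products)
  surv <- stats::runif(n) < exp(-err$length_dropout_coef * products$product_len)
  kept <- products[surv, , drop = FALSE]
  n_drop <- n - nrow(kept)
  tmpl_chars <- strsplit(spec$sequence, "", fixed = TRUE)[[1]]

  m <- nrow(kept)
  pos <- integer(m)
  cigar <- character(m)
  seqs <- character(m)
  keep <- logical(m)
  for (i in seq_len(m)) {
    span <- kept$product_len[i]
    p0 <- kept$p_last[i]
    ndel <- stats::rbinom(1, span, err$deletion_rate)
    nins <- stats::rbinom(1, span + 1L, err$insertion_rate)
    nsub <- stats::rbinom(1, span, err$substitution_rate)
    del_pos <- if (ndel) sample.int(span, ndel) else integer(0)
    ins_pos <- if (nins) sample.int(span + 1L, nins, replace = TRUE) - 1L else integer(0)
    sub_pos <- if (nsub) sample.int(span, nsub) else integer(0)
    bc <- build_cigar(span, del_pos, ins_pos)
    if (is.na(bc$cigar)) next                  # fully deleted (vanishingly rare)
    keep[i] <- TRUE
    pos[i] <- p0 + bc$pos_shift
    cigar[i] <- bc$cigar
    if (with_seq) {
      # build the read from exactly the events encoded in the CIGAR:
      # the aligned reference window is lo..hi (relative), internal
      # deletions drop bases, insertions add one base at their gap
      chars <- tmpl_chars[p0:(p0 + span - 1L)]
      if (length(sub_pos)) {
        chars[sub_pos] <- sample(c("A", "C", "G", "T"), length(sub_pos),
                                 replace = TRUE)
      }
      keep_base <- rep(FALSE, span)
      keep_base[bc$lo:bc$hi] <- TRUE
      if (length(bc$del_used)) keep_base[bc$del_used] <- FALSE
      kept_idx <- cumsum(keep_base)
      chars <- chars[keep_base]
      if (length(bc$ins_used)) {
        gap <- ifelse(bc$ins_used == 0L, 0L, kept_idx[pmax(bc$ins_used, 1L)])
        for (g in sort(gap, decreasing = TRUE)) {
          chars <- append(chars, sample(c("A", "C", "G", "T"), 1L),
                          after = g)
        }
      }
      seqs[i] <- paste(chars, collapse = "")
    }
  }
  kept <- kept[keep, , drop = FALSE]
  out <- tibble::tibble(
    qname = sprintf("read_%06d", seq_len(nrow(kept))),
    flag = 0L,
    rname = spec$name,
    pos = pos[keep],
    mapq = 60L,
    cigar = cigar[keep],
    seq = if (with_seq) seqs[keep] else "*",
    qual = if (with_seq) strrep("I", nchar(seqs[keep])) else "*",
    product_len = kept$product_len
  )
  # carry tube metadata through so channel estimators can group by time
  for (col in intersect(c("time_s", "replicate"), names(kept))) {
    out[[col]] <- kept[[col]]
  }
  class(out) <- c("rt_read_set", class(out))
  attr(out, "n_dropped") <- n_drop
  attr(out, "template") <- spec$name
  out
}

#' Write alignment records as a SAM file
#'
#' Emits a minimal valid SAM 1.6 file with `@HD`/`@SQ`/`@PG` header lines
#' for the template reference.
#'
#' @param reads An `rt_read_set` (or tibble with the SAM columns).
#' @param spec The `rt_template` the reads were aligned to.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, spec, path) {
  stopifnot(inherits(spec, "rt_template"))
  header <- c(
    "@HD\tVN:1.6\tSO:unknown",
    paste0("@SQ\tSN:", spec$name, "\tLN:", spec$length),
    "@PG\tID:rtvelocity\tPN:rtvelocity"
  )
  body <- paste(reads$qname, reads$flag, reads$rname, reads$pos, reads$mapq,
                reads$cigar, "*", 0L, 0L, reads$seq, reads$qual,
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write reads as FASTQ
#'
#' @inheritParams write_sam
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (any(reads$seq == "*")) {
    stop("reads were emitted without sequences (`with_seq = FALSE`)",
         call. = FALSE)
  }
  dna <- Biostrings::DNAStringSet(reads$seq)
  names(dna) <- reads$qname
  qual <- Biostrings::BStringSet(reads$qual)
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Write the template sequence as FASTA
#'
#' @param spec An `rt_template` with a sequence.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_template_fasta <- function(spec, path) {
  stopifnot(inherits(spec, "rt_template"))
  if (is.null(spec$sequence)) stop("`spec` carries no sequence", call. = FALSE)
  dna <- Biostrings::DNAStringSet(spec$sequence)
  names(dna) <- spec$name
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

#' Read a template sequence from FASTA into a template spec
#'
#' @param path FASTA path (first record used).
#' @param primer_anchor,primer_len Primer geometry to pair with the sequence.
#' @param obstacles Optional obstacle list.
#' @return An `rt_template` carrying the FASTA sequence.
#' @export
read_template_fasta <- function(path, primer_anchor, primer_len = 20L,
                                obstacles = list()) {
  dna <- Biostrings::readDNAStringSet(path)
  template_spec(name = sub("\\s.*$", "", names(dna)[1]),
                length = Biostrings::width(dna)[1],
                primer_anchor = primer_anchor, primer_len = primer_len,
                obstacles = obstacles,
                sequence = as.character(dna[[1]]))
}

#' Read SAM alignments into a tibble
#'
#' Parses through Rsamtools (SAM -> BAM -> scan), returning one row per
#' record with the fields the length and stop estimators need.
#'
#' @param path Path to a SAM file with a valid header.
#' @return A tibble with columns `qname`, `flag`, `rname`, `pos`, `mapq`,
#'   `cigar`.
#' @export
read_sam <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  res <- Rsamtools::scanBam(
    bam,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "mapq", "cigar")
    )
  )[[1]]
  tibble::tibble(
    qname = res$qname, flag = res$flag,
    rname = as.character(res$rname), pos = res$pos,
    mapq = res$mapq, cigar = res$cigar
  )
}
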