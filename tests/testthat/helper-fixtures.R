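# Shared miniature fixtures, built in code.

# 30-nt toy template: primer occupies [24, 28], first incorporation at 23.
toy_template <- function(obstacles = list()) {
  template_spec("toy", length = 30L, primer_anchor = 28L, primer_len = 5L,
                obstacles = obstacles)
}

# Mid-sized template for simulation tests (fast but non-trivial).
midi_template <- function(obstacles = list()) {
  template_spec("midi", length = 600L, primer_anchor = 520L, primer_len = 20L,
                obstacles = obstacles)
}

# Convert an emitted read set straight into the alignment-tibble form the
# stop/length estimators accept, skipping SAM round-trip I/O.
reads_as_alignments <- function(reads) {
  tibble::tibble(qname = reads$qname, flag = reads$flag,
                 rname = reads$rname, pos = reads$pos,
                 mapq = reads$mapq, cigar = reads$cigar)
}

expect_within <- function(object, expected, tol) {
  expect_lt(abs(object - expected), tol)
}

cigar_spans_for_test <- function(cigar) {
  rtvelocity:::cigar_ref_span(cigar)
}
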