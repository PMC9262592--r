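test_that("error-free reads round-trip product lengths exactly through SAM", {
  set.seed(41)
  spec <- add_template_sequence(build_wt_template())
  prods <- simulate_reaction(mrt_profile(25), spec, t = 40, n = 200L)
  reads <- emit_reads(prods, spec, perfect_reads())
  expect_identical(nrow(reads), nrow(prods))       # dropout_coef = 0
  expect_identical(attr(reads, "n_dropped"), 0L)
  expect_identical(reads$pos, prods$p_last)

  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(reads, spec, sam)
  aln <- cdna_length_from_alignment(read_sam(sam))
  expect_identical(nrow(aln), nrow(reads))
  expect_identical(aln$length, reads$product_len)
  expect_identical(aln$pos, prods$p_last)
})

test_that("emitted SAM agrees with an independent alignment parser", {
  skip_if_not_installed("GenomicAlignments")
  set.seed(42)
  spec <- add_template_sequence(midi_template())
  prods <- simulate_reaction(mrt_profile(25), spec, t = 12, n = 150L)
  reads <- emit_reads(prods, spec, read_error_model())
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(reads, spec, sam)
  bam <- Rsamtools::asBam(sam, withr::local_tempfile(),
                          indexDestination = FALSE)
  ga <- GenomicAlignments::readGAlignments(bam)
  expect_identical(length(ga), nrow(reads))
  # our CIGAR reference-span computation matches the reference parser
  ours <- cdna_length_from_alignment(read_sam(sam))
  expect_identical(ours$length, GenomicAlignments::width(ga))
})

test_that("a stalled molecule emits POS at the stall with the truncated span", {
  set.seed(43)
  spec <- add_template_sequence(gcsl_template(1))
  row <- tibble::tibble(p_last = 1550L,
                        product_len = product_length(spec, 1550L))
  read <- emit_reads(row, spec, perfect_reads())
  expect_identical(read$pos, 1550L)
  expect_identical(read$cigar, "378M")
  full <- emit_reads(tibble::tibble(p_last = 1L,
                                    product_len = product_length(spec, 1L)),
                     spec, perfect_reads())
  expect_identical(full$pos, 1L)
  expect_identical(full$cigar, paste0(full_length(spec), "M"))
})

test_that("indel errors leave recovered lengths within one percent at the median", {
  set.seed(44)
  spec <- add_template_sequence(build_wt_template())
  prods <- simulate_reaction(mrt_profile(25), spec, t = 40, n = 300L)
  reads <- emit_reads(prods, spec, read_error_model())
  recovered <- cigar_spans_for_test(reads$cigar)
  rel <- abs(recovered - reads$product_len) / reads$product_len
  expect_lt(stats::median(rel), 0.01)
  # read sequences are consistent with their CIGAR query lengths
  qlen <- vapply(reads$cigar, function(cg) {
    lens <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
    ops <- regmatches(cg, gregexpr("[MIDNSHP=X]", cg))[[1]]
    sum(lens[ops %in% c("M", "I", "S", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
  expect_identical(nchar(reads$seq), qlen)
})

test_that("length-dependent dropout thins long products preferentially", {
  set.seed(45)
  spec <- add_template_sequence(build_wt_template())
  prods <- tibble::tibble(p_last = rep(c(1L, 1500L), each = 1500L)) |>
    dplyr::mutate(product_len = product_length(spec, p_last))
  reads <- emit_reads(prods, spec,
                      read_error_model(0, 0, 0, length_dropout_coef = 1e-3))
  surv_long <- mean(reads$product_len == 1883L) /
    mean(prods$product_len == 1883L)
  n_long <- sum(reads$product_len == 1883L)
  n_short <- sum(reads$product_len == 384L)
  # survival odds follow exp(-coef * len): 1883 nt vs 384 nt
  expect_within(n_long / n_short, exp(-1e-3 * (1883 - 384)), 0.08)
})

test_that("FASTQ and template FASTA round-trip through Biostrings", {
  set.seed(46)
  spec <- add_template_sequence(midi_template())
  prods <- simulate_reaction(mrt_profile(25), spec, t = 8, n = 25L)
  reads <- emit_reads(prods, spec, perfect_reads())
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, fq)
  back <- Biostrings::readDNAStringSet(fq, format = "fastq")
  expect_identical(length(back), nrow(reads))
  expect_identical(as.character(back[[1]]), reads$seq[1])

  fa <- withr::local_tempfile(fileext = ".fasta")
  write_template_fasta(spec, fa)
  spec2 <- read_template_fasta(fa, primer_anchor = spec$primer_anchor,
                               primer_len = spec$primer_len)
  expect_identical(spec2$sequence, spec$sequence)
  expect_identical(spec2$length, spec$length)

  expect_error(emit_reads(prods, midi_template(), perfect_reads()),
               "no sequence")
})
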