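test_that("terminus counting places each read at its smallest covered coordinate", {
  spec <- gcsl_template(0.86)
  aln <- tibble::tibble(rname = spec$name,
                        pos = c(1550L, 1L),
                        length = c(378L, full_length(spec)))
  prof <- count_termini(aln, spec)
  expect_identical(prof$n_terminating[prof$position == 1550], 1L)
  expect_identical(prof$n_terminating[prof$position == 1], 1L)
  expect_identical(sum(prof$n_terminating), 2L)
  # a read reaches every coordinate it covers
  expect_identical(prof$n_reaching[prof$position == 1600], 2L)
  expect_identical(prof$n_reaching[prof$position == 1000], 1L)
})

test_that("terminus totals are conserved and foreign references rejected", {
  spec <- toy_template()
  set.seed(81)
  aln <- tibble::tibble(
    rname = c(rep("toy", 18), "other", "other"),
    pos = c(sample(1:20, 18, replace = TRUE), 1L, 2L),
    length = 3L
  )
  expect_message(prof <- count_termini(aln, spec), "rejecting 2")
  expect_identical(sum(prof$n_terminating), 18L)
  expect_identical(attr(prof, "n_reads"), 18L)
})

test_that("the dominant stop is called at the stall on simulated alignments", {
  spec <- add_template_sequence(gcsl_template(0.26))
  d <- timecourse_design(120, replicates = 1, molecules_per_reaction = 3000,
                         seed = 82)
  prods <- simulate_timecourse(mrt_profile(25), spec, d)
  set.seed(83)
  reads <- emit_reads(prods, spec, perfect_reads(), with_seq = FALSE)
  prof <- count_termini(
    tibble::tibble(rname = reads$rname, pos = reads$pos,
                   length = reads$product_len), spec)
  call <- call_dominant_stop(prof)
  expect_identical(call$coordinate, 1550L)
  expect_false(call$low_confidence)
  expect_identical(truncation_length_at(spec, call$coordinate), 378L)
})

test_that("equal-frequency obstacles tie toward the 3'-most coordinate", {
  spec <- template_spec("two", 2000, 1900, 20,
                        obstacles = list(obstacle(900, 0.5),
                                         obstacle(1550, 0.5)))
  # construct an exact tie by hand: one third of the reads reaching each
  # coordinate terminate there (60/180 at 1550, 40/120 at 900)
  aln <- tibble::tibble(
    rname = "two",
    pos = c(rep(1550L, 60), rep(900L, 40), rep(1L, 80)),
    length = c(rep(1900L - 1550L + 1L, 60), rep(1900L - 900L + 1L, 40),
               rep(1900L, 80))
  )
  prof <- count_termini(aln, spec)
  expect_equal(prof$stop_frequency[prof$position == 1550],
               prof$stop_frequency[prof$position == 900], tolerance = 1e-12)
  expect_identical(call_dominant_stop(prof)$coordinate, 1550L)
})

test_that("obstacle-free background stops give only a low-confidence call", {
  spec <- build_wt_template()
  bg <- enzyme_profile("bg_only", 25, p_background_stop_per_nt = 0.002)
  d <- timecourse_design(150, replicates = 1, molecules_per_reaction = 4000,
                         seed = 84)
  prods <- simulate_timecourse(bg, spec, d)
  prof <- count_termini(
    tibble::tibble(rname = spec$name, pos = prods$p_last,
                   length = prods$product_len), spec)
  call <- call_dominant_stop(prof)
  expect_true(call$low_confidence)
})

test_that("read-count F_stop matches the configured stop probability", {
  spec <- add_template_sequence(gcsl_template(0.26))
  d <- timecourse_design(150, replicates = 1, molecules_per_reaction = 4000,
                         seed = 86)
  prods <- simulate_timecourse(mrt_profile(25), spec, d)
  reads_tbl <- tibble::tibble(rname = spec$name, pos = prods$p_last,
                              length = prods$product_len)
  prof <- count_termini(reads_tbl, spec)
  f <- fstop_from_reads(prof, 1550L)
  expect_within(f, 0.26, 1.96 * sqrt(0.26 * 0.74 / 4000))

  # degenerate inputs
  all_stop <- count_termini(
    tibble::tibble(rname = spec$name, pos = rep(1550L, 10), length = 378L),
    spec)
  expect_equal(fstop_from_reads(all_stop, 1550L), 1)
  none_stop <- count_termini(
    tibble::tibble(rname = spec$name, pos = rep(1L, 10), length = 1927L),
    spec)
  expect_equal(fstop_from_reads(none_stop, 1550L), 0)
  expect_error(fstop_from_reads(none_stop, 2100L), "no read reaches")
})

test_that("noisy alignments still localize the stall within the pooling window", {
  spec <- add_template_sequence(gcsl_template(0.26))
  d <- timecourse_design(120, replicates = 1, molecules_per_reaction = 2500,
                         seed = 87)
  prods <- simulate_timecourse(mrt_profile(25), spec, d)
  set.seed(88)
  reads <- emit_reads(prods, spec, read_error_model(), with_seq = FALSE)
  prof <- count_termini(reads_as_alignments(reads), spec)
  call <- call_dominant_stop(prof)
  expect_lte(abs(call$coordinate - 1550L), 2L)
})

test_that("implied truncation lengths delegate to the template geometry", {
  gcsl <- gcsl_template()
  expect_identical(truncation_length_at(gcsl, 1550L), 378L)
  expect_identical(truncation_length_at(build_wt_template(), 1L), 1883L)
  expect_error(truncation_length_at(gcsl, 1927L), "primer window")
})
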