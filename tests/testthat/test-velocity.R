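test_that("reference-consumed span follows the CIGAR accounting rules", {
  aln <- tibble::tibble(
    flag = c(0L, 0L, 0L, 4L, 0L),
    pos = c(1550L, 1L, 10L, NA, 3L),
    cigar = c("378M", "1883M", "5M2I5M", "*", "4M2D3M1I2M")
  )
  expect_message(out <- cdna_length_from_alignment(aln), "skipping 1")
  expect_identical(out$length, c(378L, 1883L, 10L, 11L))
})

test_that("length histograms conserve counts on a fixed-origin grid", {
  d <- length_distribution(c(100, 100, 200), bin_width = 50)
  expect_identical(d$count[d$bin_start == 100], 2L)
  expect_identical(d$count[d$bin_start == 200], 1L)
  expect_identical(sum(d$count), 3L)
  expect_identical(attr(d, "n_reads"), 3L)
  single <- length_distribution(77, bin_width = 25)
  expect_identical(sum(single$count > 0), 1L)
  expect_error(length_distribution(integer(0)), "empty")
})

test_that("peak maximum takes the modal bin, ties toward longer products", {
  d <- length_distribution(c(100, 100, 200), bin_width = 50)
  expect_equal(peak_maximum(d), 125)
  tie <- length_distribution(c(100, 200), bin_width = 50)
  expect_equal(peak_maximum(tie), 225)
  # the modal bin of a Poisson-driven cohort contains mean + primer
  set.seed(51)
  lens <- 20 + stats::rpois(20000, 25 * 20)
  dd <- length_distribution(lens, bin_width = 25)
  peak <- peak_maximum(dd)
  expect_true(peak - 12.5 <= 520 && 520 < peak + 12.5)
})

test_that("replicate averaging reports mean, sd and the degenerate flag", {
  avg <- average_replicates(
    tibble::tibble(time_s = c(10, 10, 10, 20),
                   value = c(250, 260, 255, 400)))
  r10 <- avg[avg$time_s == 10, ]
  expect_equal(r10$mean, 255)
  expect_equal(r10$sd, 5)
  expect_false(r10$single_replicate)
  r20 <- avg[avg$time_s == 20, ]
  expect_equal(r20$sd, 0)
  expect_true(r20$single_replicate)
})

test_that("ordinary least squares reproduces exact lines and rejects singular designs", {
  fit <- fit_velocity(tibble::tibble(time_s = 0:2, length_nt = c(20, 45, 70)))
  expect_equal(fit$slope, 25, tolerance = 1e-12)
  expect_equal(fit$intercept, 20, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)

  fit2 <- fit_velocity(tibble::tibble(time_s = c(0, 1), length_nt = c(0, 1)))
  expect_equal(fit2$slope, 1, tolerance = 1e-12)
  expect_equal(fit2$intercept, 0, tolerance = 1e-12)

  expect_error(fit_velocity(tibble::tibble(time_s = c(5, 5),
                                           length_nt = c(1, 2))),
               "distinct time")
})

test_that("tidy and glance expose the fit in broom shape", {
  fit <- fit_velocity(tibble::tibble(time_s = c(0, 10, 20, 30),
                                     length_nt = c(21, 270, 521, 772)))
  td <- tidy(fit)
  expect_identical(td$term, c("intercept_nt", "velocity_nt_per_s"))
  expect_equal(td$estimate[2], fit$slope)
  gl <- glance(fit)
  expect_identical(names(gl),
                   c("velocity", "velocity_se", "intercept", "r.squared",
                     "sigma", "nobs"))
  expect_identical(gl$nobs, 4L)
})

test_that("regression on noiseless closed-form means recovers rate and primer exactly", {
  wt <- build_wt_template()
  k <- 25
  ts <- seq(10, 60, 10)
  pts <- tibble::tibble(
    time_s = ts,
    length_nt = vapply(ts, function(t) {
      theoretical_mean_length(mrt_profile(k), wt, t)
    }, numeric(1))
  )
  fit <- fit_velocity(pts)
  expect_equal(fit$slope, k, tolerance = 1e-6)
  expect_equal(fit$intercept, wt$primer_len, tolerance = 1e-4)
  expect_gt(fit$r2, 1 - 1e-10)
})

test_that("saturated time points are excluded from the gel-channel fit", {
  wt <- build_wt_template()
  d <- timecourse_design(c(20, 40, 60, 200), replicates = 1,
                         molecules_per_reaction = 400, seed = 61)
  prods <- simulate_timecourse(mrt_profile(25), wt, d)
  sat <- saturation_by_time(prods)
  expect_gt(sat$fraction_full_length[sat$time_s == 200], 0.99)
  set.seed(62)
  fit <- estimate_velocity_gel(prods, wt)
  expect_identical(fit$n_points, 3L)
  expect_false(200 %in% fit$points$time_s)
})

test_that("simulated gel time courses recover the configured rate within 2%", {
  wt <- build_wt_template()
  k <- 25
  slopes <- vapply(1:12, function(i) {
    d <- timecourse_design(seq(10, 60, 10), replicates = 1,
                           molecules_per_reaction = 1000, seed = 700 + i)
    prods <- simulate_timecourse(mrt_profile(k), wt, d)
    set.seed(800 + i)
    estimate_velocity_gel(prods, wt)$slope
  }, numeric(1))
  expect_within(mean(slopes), k, 0.02 * k)
  # constant-rate runs are near-perfectly linear almost always
  r2s <- vapply(1:12, function(i) {
    d <- timecourse_design(seq(10, 60, 10), replicates = 1,
                           molecules_per_reaction = 1000, seed = 900 + i)
    prods <- simulate_timecourse(mrt_profile(k), wt, d)
    set.seed(950 + i)
    estimate_velocity_gel(prods, wt)$r2
  }, numeric(1))
  expect_gte(sum(r2s > 0.98), 11)
})

test_that("peak-maximum and mean estimators agree for symmetric cohorts", {
  set.seed(71)
  lens <- round(stats::rnorm(20000, 800, 30))
  d <- length_distribution(lens, bin_width = 25)
  expect_within(peak_maximum(d), mean(lens), 25)
})
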