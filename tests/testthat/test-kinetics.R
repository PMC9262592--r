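test_that("zero reaction time leaves the primer unextended", {
  set.seed(1)
  out <- simulate_molecule(mrt_profile(), build_wt_template(), t = 0)
  expect_identical(out$p_last, primer_window_start(build_wt_template()))
  expect_identical(out$product_len, 20L)
  expect_identical(out$cause, "time_up")
})

test_that("an unobstructed molecule runs off the 5' end at long times", {
  wt <- build_wt_template()
  set.seed(2)
  out <- simulate_reaction(mrt_profile(), wt, t = 300, n = 50L)
  expect_true(all(out$cause == "ran_off_5prime_end"))
  expect_true(all(out$product_len == 1883L))
})

test_that("incorporation counts follow the Poisson stepping law", {
  wt <- build_wt_template()
  k <- 25; t <- 10; n <- 10000L
  set.seed(3)
  out <- simulate_reaction(mrt_profile(k), wt, t = t, n = n)
  steps <- primer_window_start(wt) - out$p_last
  mu <- k * t
  # mean and variance both equal kt; 3-sigma Monte Carlo bands
  expect_within(mean(steps), mu, 3 * sqrt(mu / n))
  expect_within(stats::var(steps), mu, 3 * mu * sqrt(2 / n))

  # chi-square goodness of fit against the Poisson pmf at small t
  set.seed(4)
  small <- simulate_reaction(mrt_profile(5), wt, t = 2, n = 10000L)
  s <- primer_window_start(wt) - small$p_last
  grid <- 0:25
  probs <- stats::dpois(grid, 10)
  obs <- tabulate(factor(pmin(s, 25L), levels = grid), nbins = length(grid))
  keep <- probs * length(s) >= 5
  gof <- stats::chisq.test(obs[keep], p = probs[keep] / sum(probs[keep]))
  expect_gt(gof$p.value, 0.001)
})

test_that("closed-form mean length matches its defining summation", {
  wt <- build_wt_template()
  expect_equal(theoretical_mean_length(mrt_profile(25), wt, 10), 270,
               tolerance = 1e-9)
  expect_equal(theoretical_mean_length(tgirt_profile(4.4), wt, 60), 284,
               tolerance = 1e-9)
  expect_equal(theoretical_mean_length(mrt_profile(25), wt, 1e4), 1883,
               tolerance = 1e-9)
  expect_error(theoretical_mean_length(ssiv_profile(), wt, 10),
               "background")
  expect_error(theoretical_mean_length(mrt_profile(), gcsl_template(), 10),
               "obstacle")
})

test_that("time-course populations are independent tubes with exact cardinality", {
  wt <- build_wt_template()
  d <- timecourse_design(c(10, 20), replicates = 2, molecules_per_reaction = 30,
                         seed = 9)
  tab <- simulate_timecourse(mrt_profile(), wt, d)
  expect_identical(nrow(tab), 2L * 2L * 30L)
  counts <- dplyr::count(tab, time_s, replicate)
  expect_true(all(counts$n == 30L))

  # empirical run-off fraction at 75 s matches the analytic Poisson tail
  d75 <- timecourse_design(75, replicates = 1, molecules_per_reaction = 4000,
                           seed = 10)
  tab75 <- simulate_timecourse(mrt_profile(25), wt, d75)
  frac <- mean(tab75$cause == "ran_off_5prime_end")
  p_exact <- stats::ppois(max_extension(wt) - 1L, 25 * 75,
                          lower.tail = FALSE)
  expect_within(frac, p_exact, 3 * sqrt(p_exact * (1 - p_exact) / 4000))
})

test_that("single-cycle trap makes every obstacle termination exact and final", {
  hard <- gcsl_template(p_stop = 1)
  d <- timecourse_design(120, replicates = 1, molecules_per_reaction = 2000,
                         mode = "single_cycle", seed = 11)
  tab <- simulate_timecourse(mrt_profile(25), hard, d)
  stopped <- tab[tab$cause == "obstacle", ]
  expect_gt(nrow(stopped), 1900)             # nearly all reach the stall
  expect_true(all(stopped$product_len == 378L))
  expect_true(all(stopped$p_last == 1550L))
})

test_that("obstacle termination frequency converges to the configured probability", {
  spec <- gcsl_template(p_stop = 0.26)
  d <- timecourse_design(150, replicates = 1, molecules_per_reaction = 10000,
                         seed = 12)
  tab <- simulate_timecourse(mrt_profile(25), spec, d)
  reached <- tab[tab$cause %in% c("obstacle", "ran_off_5prime_end"), ]
  frac <- mean(reached$cause == "obstacle")
  expect_within(frac, 0.26, 1.96 * sqrt(0.26 * 0.74 / nrow(reached)))
})

test_that("a distributive enzyme cannot finish under single-cycle conditions", {
  wt <- build_wt_template()
  d <- timecourse_design(120, replicates = 1, molecules_per_reaction = 500,
                         mode = "single_cycle", seed = 13)
  tab <- simulate_timecourse(ssiv_profile(), wt, d)
  expect_lt(mean(tab$cause == "ran_off_5prime_end"), 0.05)
  # but multiple-cycle rebinding rescues it
  d2 <- timecourse_design(300, replicates = 1, molecules_per_reaction = 500,
                          mode = "multiple_cycle", seed = 13)
  tab2 <- simulate_timecourse(ssiv_profile(), wt, d2)
  expect_gt(mean(tab2$cause == "ran_off_5prime_end"), 0.9)
  expect_gt(mean(tab2$n_rebinds), 1)
})

test_that("identical design and seed give identical product tables", {
  wt <- build_wt_template()
  d <- timecourse_design(c(10, 30), replicates = 2,
                         molecules_per_reaction = 100, seed = 77)
  a <- simulate_timecourse(mrt_profile(), wt, d)
  b <- simulate_timecourse(mrt_profile(), wt, d)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("extension is bounded and stochastically monotone in time", {
  wt <- build_wt_template()
  d <- timecourse_design(c(5, 15, 30, 50), replicates = 1,
                         molecules_per_reaction = 500, seed = 21)
  tab <- simulate_timecourse(mrt_profile(), wt, d)
  expect_true(all(tab$p_last >= 1L))
  expect_true(all(tab$product_len <= full_length(wt)))
  means <- tapply(tab$product_len, tab$time_s, mean)
  expect_true(all(diff(means) > 0))
})
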