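# Stochastic primer-extension kinetics. Elongation is a homogeneous Poisson
# stepping process (i.i.d. Exponential(step_rate) waiting times per
# incorporated nucleotide), punctuated by obstacle encounters (one Bernoulli
# readthrough draw per molecule per obstacle), per-nucleotide background
# dissociation, and -- under multiple-cycle reaction conditions -- rebinding
# after an Exponential(rebind_delay_rate) wait. The simulator advances whole
# segments at a time: within a segment the number of arrivals in the remaining
# time is Poisson, and when a target is reached the elapsed time is drawn as
# the corresponding uniform order statistic, which by the strong Markov
# property leaves the residual process a fresh Poisson process.

#' Define an enzyme stepping/rebinding profile
#'
#' @param name Profile name.
#' @param step_rate Mean stepping rate in nt/s (the velocity `k`).
#' @param p_background_stop_per_nt Probability that the enzyme dissociates
#'   after any given incorporation (per-nucleotide Bernoulli).
#' @param rebind_mode One of `"processive_single_pass"` (never rebinds),
#'   `"multiple_cycle"` (background-stopped primers are resumed after an
#'   exponential wait when the reaction is run under multiple-cycle
#'   conditions) or `"distributive_no_rescue"` (a distributive enzyme that
#'   needs repeated rebinding to finish a template; behaves like
#'   `multiple_cycle` for background stops but is non-functional under
#'   single-cycle conditions).
#' @param rebind_delay_rate Rate (1/s) of the exponential rebinding wait.
#' @param obstacle_overrides Optional named numeric vector replacing the
#'   per-encounter `p_stop` of template obstacles by obstacle label.
#' @param obstacle_rescue If `TRUE`, a molecule stopped at an obstacle may be
#'   rebound and redraw the readthrough Bernoulli under multiple-cycle
#'   conditions. Off by default: the persistent obstacle band seen under
#'   enzyme excess indicates re-initiated enzymes stop with the same
#'   probability, which one draw per molecule already captures.
#' @return An object of class `rt_enzyme_profile`.
#' @export
#' @examples
#' enzyme_profile("MRT", step_rate = 25)
enzyme_profile <- function(name, step_rate,
                           p_background_stop_per_nt = 0,
                           rebind_mode = c("processive_single_pass",
                                           "multiple_cycle",
                                           "distributive_no_rescue"),
                           rebind_delay_rate = 1,
                           obstacle_overrides = NULL,
                           obstacle_rescue = FALSE) {
  rebind_mode <- match.arg(rebind_mode)
  if (!is.numeric(step_rate) || step_rate <= 0) {
    stop("`step_rate` must be > 0", call. = FALSE)
  }
  if (p_background_stop_per_nt < 0 || p_background_stop_per_nt > 1) {
    stop("`p_background_stop_per_nt` must be in [0, 1]", call. = FALSE)
  }
  stopifnot(rebind_delay_rate > 0)
  structure(
    list(name = as.character(name), step_rate = as.numeric(step_rate),
         p_background_stop_per_nt = as.numeric(p_background_stop_per_nt),
         rebind_mode = rebind_mode,
         rebind_delay_rate = as.numeric(rebind_delay_rate),
         obstacle_overrides = obstacle_overrides,
         obstacle_rescue = isTRUE(obstacle_rescue)),
    class = "rt_enzyme_profile"
  )
}

#' @export
print.rt_enzyme_profile <- function(x, ...) {
  cat("<rt_enzyme_profile> ", x$name, "\n", sep = "")
  cat("  step rate     : ", x$step_rate, " nt/s\n", sep = "")
  cat("  background    : ", x$p_background_stop_per_nt, " /nt\n", sep = "")
  cat("  rebind mode   : ", x$rebind_mode,
      " (delay rate ", x$rebind_delay_rate, "/s)\n", sep = "")
  invisible(x)
}

#' Built-in enzyme profiles
#'
#' `mrt_profile()` is a fast, highly processive group II intron RT class
#' (default 25 nt/s, no background stops); `tgirt_profile()` the slower
#' thermostable group II intron RT class (default 4.4 nt/s); and
#' `ssiv_profile()` a distributive retroviral RT class with frequent
#' background stops (default 0.002/nt) that relies on multiple-cycle
#' rebinding. The retroviral step rate is not separately measurable by the
#' time-course assay (premature stops dominate), so the default 15 nt/s sits
#' in the range reported for retroviral RTs on homopolymer templates.
#'
#' @param step_rate Stepping rate override in nt/s.
#' @param ... Passed on to [enzyme_profile()].
#' @return An `rt_enzyme_profile`.
#' @export
mrt_profile <- function(step_rate = 25, ...) {
  enzyme_profile("MRT", step_rate = step_rate,
                 rebind_mode = "processive_single_pass", ...)
}

#' @rdname mrt_profile
#' @export
tgirt_profile <- function(step_rate = 4.4, ...) {
  enzyme_profile("TGIRT", step_rate = step_rate,
                 rebind_mode = "processive_single_pass", ...)
}

#' @rdname mrt_profile
#' @export
ssiv_profile <- function(step_rate = 15, ...) {
  enzyme_profile("SSIV", step_rate = step_rate,
                 p_background_stop_per_nt = 0.002,
                 rebind_mode = "distributive_no_rescue", ...)
}

#' Time-course experimental design
#'
#' Each (time point, replicate) pair is an independent reaction tube stopped
#' at that time; molecules are never observed twice.
#'
#' @param time_points Strictly increasing reaction times in seconds.
#' @param replicates Number of replicate tubes per time point.
#' @param molecules_per_reaction Number of primer-template molecules per tube.
#' @param mode `"multiple_cycle"` (enzyme excess, rebinding allowed) or
#'   `"single_cycle"` (trap added at initiation: any dissociation is final).
#' @param seed Integer master seed; all tube-level randomness derives from it.
#' @return An object of class `rt_timecourse_design`.
#' @export
timecourse_design <- function(time_points, replicates = 3L,
                              molecules_per_reaction = 2000L,
                              mode = c("multiple_cycle", "single_cycle"),
                              seed = 1L) {
  mode <- match.arg(mode)
  time_points <- as.numeric(time_points)
  if (length(time_points) < 1L || any(diff(time_points) <= 0)) {
    stop("`time_points` must be strictly increasing", call. = FALSE)
  }
  stopifnot(any(time_points >= 0), replicates >= 1L,
            molecules_per_reaction >= 1L)
  structure(
    list(time_points = time_points, replicates = as.integer(replicates),
         molecules_per_reaction = as.integer(molecules_per_reaction),
         mode = mode, seed = as.integer(seed)),
    class = "rt_timecourse_design"
  )
}

# Obstacles in encounter order (descending coordinate), with profile
# overrides applied, as a data frame of step distances and probabilities.
effective_obstacles <- function(profile, spec) {
  obs <- spec$obstacles
  if (!length(obs)) {
    return(data.frame(stall_coord = integer(), p_stop = numeric(),
                      d_steps = integer()))
  }
  coord <- vapply(obs, `[[`, integer(1), "stall_coord")
  p <- vapply(obs, `[[`, numeric(1), "p_stop")
  lab <- vapply(obs, `[[`, character(1), "label")
  ov <- profile$obstacle_overrides
  if (!is.null(ov)) {
    hit <- lab %in% names(ov)
    p[hit] <- as.numeric(ov[lab[hit]])
  }
  ord <- order(coord, decreasing = TRUE)
  data.frame(stall_coord = coord[ord], p_stop = p[ord],
             d_steps = primer_window_start(spec) - coord[ord])
}

# Vectorized cohort simulation under the current RNG state.
simulate_cohort <- function(profile, spec, t, mode, n) {
  pw <- primer_window_start(spec)
  max_steps <- pw - 1L
  k <- profile$step_rate
  pbg <- profile$p_background_stop_per_nt
  obs <- effective_obstacles(profile, spec)
  n_obs <- nrow(obs)
  rebind_ok <- mode == "multiple_cycle" &&
    profile$rebind_mode %in% c("multiple_cycle", "distributive_no_rescue")

  ext <- integer(n)
  t_rem <- rep(as.numeric(t), n)
  cause <- rep(NA_character_, n)
  n_reb <- integer(n)
  next_ob <- rep(1L, n)
  active <- rep(TRUE, n)

  while (any(active)) {
    i <- which(active)
    m <- length(i)
    to_end <- max_steps - ext[i]
    d_next <- rep(Inf, m)
    p_next <- rep(NA_real_, m)
    if (n_obs) {
      ok <- next_ob[i] <= n_obs
      d_next[ok] <- obs$d_steps[next_ob[i][ok]] - ext[i][ok]
      p_next[ok] <- obs$p_stop[next_ob[i][ok]]
    }
    to_bg <- if (pbg > 0) stats::rgeom(m, pbg) + 1 else rep(Inf, m)
    steps <- pmin(to_end, d_next, to_bg)
    event <- ifelse(steps == to_end, "end",
                    ifelse(steps == d_next, "obstacle", "background"))
    n_arr <- stats::rpois(m, k * t_rem[i])

    ran_out <- n_arr < steps
    idx <- i[ran_out]
    ext[idx] <- ext[idx] + n_arr[ran_out]
    cause[idx] <- "time_up"
    active[idx] <- FALSE

    j <- which(!ran_out)
    if (!length(j)) next
    ii <- i[j]
    s <- steps[j]
    # elapsed time of the s-th of n_arr uniform arrival times on (0, t_rem)
    t_used <- numeric(length(j))
    pos <- s > 0
    t_used[pos] <- t_rem[ii][pos] *
      stats::rbeta(sum(pos), s[pos], n_arr[j][pos] - s[pos] + 1)
    ext[ii] <- ext[ii] + s
    t_rem[ii] <- t_rem[ii] - t_used
    ev <- event[j]

    done <- ii[ev == "end"]
    cause[done] <- "ran_off_5prime_end"
    active[done] <- FALSE

    o <- which(ev == "obstacle")
    if (length(o)) {
      oi <- ii[o]
      stopped_draw <- stats::runif(length(o)) < p_next[j][o]
      passed <- oi[!stopped_draw]
      next_ob[passed] <- next_ob[passed] + 1L
      stopped <- oi[stopped_draw]
      if (length(stopped)) {
        if (profile$obstacle_rescue && rebind_ok) {
          t_rem[stopped] <- t_rem[stopped] -
            stats::rexp(length(stopped), profile$rebind_delay_rate)
          n_reb[stopped] <- n_reb[stopped] + 1L
          out <- stopped[t_rem[stopped] <= 0]
          cause[out] <- "obstacle"
          active[out] <- FALSE
          # survivors stay at the stall and redraw on the next sweep
        } else {
          cause[stopped] <- "obstacle"
          active[stopped] <- FALSE
        }
      }
    }

    b <- which(ev == "background")
    if (length(b)) {
      bi <- ii[b]
      if (rebind_ok) {
        t_rem[bi] <- t_rem[bi] -
          stats::rexp(length(bi), profile$rebind_delay_rate)
        n_reb[bi] <- n_reb[bi] + 1L
        out <- bi[t_rem[bi] <= 0]
        cause[out] <- "background"
        active[out] <- FALSE
      } else {
        cause[bi] <- "background"
        active[bi] <- FALSE
      }
    }
  }

  p_last <- pw - ext
  tibble::tibble(
    p_last = as.integer(p_last),
    product_len = spec$primer_anchor - as.integer(p_last) + 1L,
    cause = cause,
    n_rebinds = n_reb
  )
}

#' Simulate a single elongating molecule
#'
#' Draws one molecule's outcome after reaction time `t` from the current RNG
#' state. See [simulate_timecourse()] for whole experiments.
#'
#' @param profile An [enzyme_profile()].
#' @param spec An `rt_template`.
#' @param t Reaction time in seconds (>= 0).
#' @param mode `"multiple_cycle"` or `"single_cycle"`.
#' @return A one-row tibble with columns `p_last`, `product_len`, `cause`
#'   (`time_up`, `ran_off_5prime_end`, `obstacle` or `background`) and
#'   `n_rebinds`.
#' @export
#' @examples
#' set.seed(1)
#' simulate_molecule(mrt_profile(), build_wt_template(), t = 10)
simulate_molecule <- function(profile, spec, t,
                              mode = c("multiple_cycle", "single_cycle")) {
  simulate_reaction(profile, spec, t, mode, n = 1L)
}

#' Simulate one reaction tube of `n` molecules
#'
#' Vectorized single-tube counterpart of [simulate_timecourse()]; draws from
#' the current RNG state.
#'
#' @inheritParams simulate_molecule
#' @param n Number of molecules in the tube.
#' @return A tibble with one row per molecule (`p_last`, `product_len`,
#'   `cause`, `n_rebinds`).
#' @export
simulate_reaction <- function(profile, spec, t,
                              mode = c("multiple_cycle", "single_cycle"),
                              n = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(profile, "rt_enzyme_profile"),
            inherits(spec, "rt_template"), t >= 0, n >= 1L)
  simulate_cohort(profile, spec, t, mode, as.integer(n))
}

#' Simulate a primer-extension time course
#'
#' Runs one independent reaction tube per (time point, replicate) pair, each
#' containing `molecules_per_reaction` primer-template molecules, and stops
#' each tube at its design time. Deterministic given the design seed: every
#' tube draws from its own derived seed, so results do not depend on tube
#' order or on how many molecules other tubes contain.
#'
#' @inheritParams simulate_molecule
#' @param design A [timecourse_design()].
#' @return A tibble of class `rt_product_table` with columns `time_s`,
#'   `replicate`, `molecule`, `p_last`, `product_len`, `cause`, `n_rebinds`.
#' @export
#' @examples
#' design <- timecourse_design(c(10, 20), replicates = 1,
#'                             molecules_per_reaction = 50, seed = 1)
#' simulate_timecourse(mrt_profile(), build_wt_template(), design)
simulate_timecourse <- function(profile, spec, design) {
  stopifnot(inherits(profile, "rt_enzyme_profile"),
            inherits(spec, "rt_template"),
            inherits(design, "rt_timecourse_design"))
  tubes <- tidyr::expand_grid(time_s = design$time_points,
                              replicate = seq_len(design$replicates))
  out <- purrr::pmap(tubes, function(time_s, replicate) {
    idx <- which(tubes$time_s == time_s)[1] * 1000L + replicate
    set.seed(derive_seed(design$seed, idx))
    res <- simulate_cohort(profile, spec, time_s, design$mode,
                           design$molecules_per_reaction)
    res$time_s <- time_s
    res$replicate <- replicate
    res$molecule <- seq_len(nrow(res))
    res
  })
  out <- dplyr::bind_rows(out)
  out <- dplyr::select(out, "time_s", "replicate", "molecule", "p_last",
                       "product_len", "cause", "n_rebinds")
  class(out) <- c("rt_product_table", class(out))
  attr(out, "template") <- spec$name
  attr(out, "profile") <- profile$name
  attr(out, "mode") <- design$mode
  out
}

# Deterministic sub-seed derivation that stays inside 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %%
               2147483647)
}

#' Closed-form expected product length for an unobstructed profile
#'
#' For an obstacle-free template and a profile with zero background
#' dissociation, the number of incorporations by time `t` is
#' `min(Poisson(step_rate * t), max_extension)`, so the expected product
#' length is `primer_len + E[min(Poisson(kt), M)]`, evaluated by summing the
#' Poisson survival function. Used as the analytic oracle for the
#' simulation-based estimators.
#'
#' @inheritParams simulate_molecule
#' @return Expected product length in nucleotides (numeric).
#' @export
#' @examples
#' theoretical_mean_length(mrt_profile(), build_wt_template(), 10) # ~270
theoretical_mean_length <- function(profile, spec, t) {
  stopifnot(inherits(profile, "rt_enzyme_profile"),
            inherits(spec, "rt_template"))
  if (length(spec$obstacles) || profile$p_background_stop_per_nt > 0) {
    stop("closed form requires an obstacle-free template and zero ",
         "background dissociation", call. = FALSE)
  }
  m <- max_extension(spec)
  mu <- profile$step_rate * t
  # E[min(N, m)] = sum_{j=0}^{m-1} P(N > j)
  e_min <- sum(stats::ppois(0:(m - 1L), mu, lower.tail = FALSE))
  spec$primer_len + e_min
}

#' Fraction of molecules that ran off the template 5' end, per time point
#'
#' Used by the velocity estimators to drop saturated time points: once a
#' majority of molecules has hit the full-length ceiling, mean length no
#' longer grows linearly with time.
#'
#' @param products An `rt_product_table`.
#' @return A tibble with columns `time_s` and `fraction_full_length`.
#' @export
saturation_by_time <- function(products) {
  stopifnot(is.data.frame(products))
  products |>
    dplyr::group_by(.data$time_s) |>
    dplyr::summarise(
      fraction_full_length = mean(.data$cause == "ran_off_5prime_end"),
      .groups = "drop"
    )
}
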