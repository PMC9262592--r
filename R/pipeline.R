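# Supporting engineering: YAML run configuration, TSV interchange between
# stages, the end-to-end pipeline driver and deterministic fixture
# generation. TSV (tab-separated, header row) is the interchange format;
# SAM/FASTQ/FASTA appear only at the simulation boundary.

#' Assemble and validate a pipeline run configuration
#'
#' @param template An `rt_template`.
#' @param profile An `rt_enzyme_profile`.
#' @param design An `rt_timecourse_design`.
#' @param gel A [gel_model()].
#' @param error_model A [read_error_model()].
#' @param seed Integer master seed for every downstream stage.
#' @return An object of class `rt_run_config`.
#' @export
run_config <- function(template, profile, design, gel = gel_model(),
                       error_model = read_error_model(), seed = 1L) {
  stopifnot(inherits(template, "rt_template"),
            inherits(profile, "rt_enzyme_profile"),
            inherits(design, "rt_timecourse_design"),
            inherits(gel, "rt_gel_model"),
            inherits(error_model, "rt_read_error_model"))
  structure(
    list(template = template, profile = profile, design = design,
         gel = gel, error_model = error_model, seed = as.integer(seed)),
    class = "rt_run_config"
  )
}

#' Write / read a run configuration as YAML
#'
#' The template sequence, if present, is inlined. Reading re-validates every
#' component through its constructor, so schema violations (negative rates,
#' bad coordinates) fail before any compute.
#'
#' @param config An `rt_run_config`.
#' @param path YAML file path.
#' @return `path` invisibly; `read_run_config()` returns the config.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "rt_run_config"))
  tm <- config$template
  obj <- list(
    template = list(
      name = tm$name, length = tm$length, primer_anchor = tm$primer_anchor,
      primer_len = tm$primer_len,
      obstacles = lapply(tm$obstacles, function(ob) {
        list(stall_coord = ob$stall_coord, p_stop = ob$p_stop,
             label = ob$label)
      }),
      sequence = tm$sequence
    ),
    profile = unclass(config$profile),
    design = unclass(config$design),
    gel = unclass(config$gel),
    error_model = unclass(config$error_model),
    seed = config$seed
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  template <- template_spec(
    name = obj$template$name, length = obj$template$length,
    primer_anchor = obj$template$primer_anchor,
    primer_len = obj$template$primer_len,
    obstacles = lapply(obj$template$obstacles, function(ob) {
      obstacle(ob$stall_coord, ob$p_stop, ob$label)
    }),
    sequence = obj$template$sequence
  )
  profile <- enzyme_profile(
    name = obj$profile$name, step_rate = obj$profile$step_rate,
    p_background_stop_per_nt = obj$profile$p_background_stop_per_nt,
    rebind_mode = obj$profile$rebind_mode,
    rebind_delay_rate = obj$profile$rebind_delay_rate,
    obstacle_overrides = obj$profile$obstacle_overrides,
    obstacle_rescue = obj$profile$obstacle_rescue
  )
  design <- timecourse_design(
    time_points = obj$design$time_points,
    replicates = obj$design$replicates,
    molecules_per_reaction = obj$design$molecules_per_reaction,
    mode = obj$design$mode, seed = obj$design$seed
  )
  run_config(template, profile, design,
             gel = do.call(gel_model, obj$gel),
             error_model = do.call(read_error_model, obj$error_model),
             seed = obj$seed)
}

#' Run the simulation-and-estimation pipeline
#'
#' Executes the requested stages in dependency order, writes each stage's
#' table under `out_dir` as TSV (plus SAM/FASTA at the simulation
#' boundary), writes the resolved configuration next to the outputs, and
#' returns a run report. Deterministic given the config seed.
#'
#' Stages: `simulate` (product table), `gel` (per-lane mean lengths),
#' `lengths` (reads, SAM, recovered lengths), `velocity` (fits from
#' whichever channels ran), `stops` (termini profile + dominant stop +
#' read-count F_stop, requires `lengths`).
#'
#' @param config An `rt_run_config`.
#' @param stages Subset of `c("simulate", "gel", "lengths", "velocity",
#'   "stops")`.
#' @param out_dir Output directory (created if missing).
#' @return A list report: per-stage file paths, record counts, and the
#'   final `velocity`/`f_stop`/stop-call results where computed.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "gel", "lengths",
                                    "velocity", "stops"),
                         out_dir = tempfile("rtvk_run_")) {
  stopifnot(inherits(config, "rt_run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_run_config(config, file.path(out_dir, "config_resolved.yaml"))
  report <- list(out_dir = out_dir, stages = stages)

  needs_sim <- length(intersect(stages,
                                c("simulate", "gel", "lengths",
                                  "velocity", "stops"))) > 0
  if (!needs_sim) return(report)

  spec <- config$template
  products <- simulate_timecourse(config$profile, spec, config$design)
  if ("simulate" %in% stages) {
    p <- file.path(out_dir, "products.tsv")
    readr::write_tsv(tibble::as_tibble(products), p)
    report$products <- p
    report$n_molecules <- nrow(products)
  }

  gel_means <- NULL
  if ("gel" %in% stages || "velocity" %in% stages) {
    set.seed(derive_seed(config$seed, 101L))
    gel_means <- measure_gel_timecourse(products, spec, config$gel)
    p <- file.path(out_dir, "gel_mean_lengths.tsv")
    readr::write_tsv(gel_means, p)
    report$gel_mean_lengths <- p
  }

  read_lengths <- NULL
  if ("lengths" %in% stages || "stops" %in% stages) {
    if (is.null(spec$sequence)) {
      set.seed(derive_seed(config$seed, 201L))
      spec <- add_template_sequence(spec)
    }
    set.seed(derive_seed(config$seed, 202L))
    reads <- emit_reads(products, spec, config$error_model)
    sam_path <- file.path(out_dir, "reads.sam")
    write_sam(reads, spec, sam_path)
    write_template_fasta(spec, file.path(out_dir, "template.fasta"))
    aln <- cdna_length_from_alignment(read_sam(sam_path))
    report$reads_sam <- sam_path
    report$n_reads <- nrow(reads)
    lens <- tibble::tibble(qname = aln$qname, length = aln$length)
    p <- file.path(out_dir, "read_lengths.tsv")
    readr::write_tsv(lens, p)
    report$read_lengths <- p
    read_lengths <- lens
    report$alignments <- aln
  }

  if ("velocity" %in% stages) {
    set.seed(derive_seed(config$seed, 301L))
    fit <- estimate_velocity_gel(products, spec, config$gel)
    report$velocity <- glance(fit)
    readr::write_tsv(report$velocity,
                     file.path(out_dir, "velocity_fit.tsv"))
  }

  if ("stops" %in% stages) {
    profile <- count_termini(report$alignments, spec)
    p <- file.path(out_dir, "stop_profile.tsv")
    readr::write_tsv(tibble::as_tibble(profile), p)
    report$stop_profile <- p
    if (length(spec$obstacles)) {
      stall <- spec$obstacles[[1]]$stall_coord
      call <- call_dominant_stop(profile)
      report$dominant_stop <- call
      report$f_stop_reads <- fstop_from_reads(profile, stall)
      readr::write_tsv(call, file.path(out_dir, "dominant_stop.tsv"))
    }
  }
  report
}

#' Generate the bundled deterministic toy fixtures
#'
#' Writes a 300-nt toy template (YAML spec + FASTA), a 20-read SAM aligned
#' to it, and a two-lane gel TSV (a lane plus a ladder), all derived from
#' `seed` -- byte-identical across calls with the same seed.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @return Named character vector of the written paths, invisibly.
#' @export
generate_fixtures <- function(dir, seed = 42L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- template_spec("toy_template", length = 300L, primer_anchor = 280L,
                        primer_len = 20L,
                        obstacles = list(obstacle(150L, 0.5, "toy_stem")))
  set.seed(derive_seed(seed, 1L))
  spec <- add_template_sequence(spec)
  paths <- c(
    template_yaml = file.path(dir, "toy_template.yaml"),
    template_fasta = file.path(dir, "toy_template.fasta"),
    reads_sam = file.path(dir, "toy_reads.sam"),
    lanes_tsv = file.path(dir, "toy_lanes.tsv")
  )
  cfg <- run_config(spec, mrt_profile(), timecourse_design(10, 1, 20),
                    seed = seed)
  write_run_config(cfg, paths["template_yaml"])
  write_template_fasta(spec, paths["template_fasta"])

  set.seed(derive_seed(seed, 2L))
  prods <- simulate_cohort(mrt_profile(), spec, t = 30, "multiple_cycle", 20L)
  reads <- emit_reads(prods, spec, perfect_reads())
  write_sam(reads, spec, paths["reads_sam"])

  model <- gel_model(profile_bins = 400L, min_length = 10L,
                     max_length = 400L)
  lane <- render_gel_lane(prods$product_len, model, label = "t30")
  ladder <- render_ladder(model, c(25, 50, 100, 200))
  lanes <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(lane), lane = "t30"),
    dplyr::mutate(tibble::as_tibble(ladder), lane = "ladder")
  )
  readr::write_tsv(lanes, paths["lanes_tsv"])
  invisible(paths)
}
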