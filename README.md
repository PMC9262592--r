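# rtvelocity

Simulation and inference for reverse-transcriptase (RT) elongation kinetics on
long RNA templates.

Processive group II intron RTs (MarathonRT, TGIRT) copy kilobase RNAs as a
synchronized population at a constant speed, while retroviral enzymes stall at
template structure. The experimental readout behind those statements is a
primer-extension time course: reactions stopped every few seconds, product
lengths measured by denaturing-gel densitometry or by long-read sequencing of
the cDNA, and velocity obtained by linear regression of length on time.
rtvelocity packages that analysis end to end for method development and power
analysis: a stochastic model of an RT stepping along a template (with
structural obstacles, background dissociation, multiple-cycle rebinding, and
single-cycle trap conditions), generators for both measurement channels, and
the estimators that read them back out.

## The model and the estimators

* Stepping is a Poisson process at rate *k* (nt/s): incorporations by time *t*
  number `min(Poisson(kt), M)`, truncated at the template 5' end. A structural
  obstacle at stall coordinate *s* terminates each encountering molecule with
  per-encounter probability `p_stop`; the product of a blocked molecule is
  `primer_anchor − s + 1` nt (primer included).
* Gel channel: bands at mobility `a − b·log10(L)`, ladder calibration,
  intensity-weighted mean length per lane, per-lane migration jitter.
* Read channel: one SAM record per surviving molecule with `POS = p_last` and
  reference span equal to the product length; cDNA length is recovered as the
  alignment's reference-consumed span (CIGAR M/D/N/=/X).
* Velocity: OLS of length on time, `v = slope`, excluding time points where
  ≥50% of molecules have hit full length.
* Obstacle strength: `F_stop = I_GCSL / (I_readthrough + I_GCSL)`, the stall
  band's share of all intensity at the stall length and above, plus a
  read-count analogue (terminating / reaching reads at the stall).
* Stop localization: per-position terminus counting from alignments; the
  dominant stop maximizes pooled stop frequency (±2-nt endpoint jitter
  window), with the run-off terminus excluded.

## Worked example

Simulate the classic velocity experiment — a 2148-nt HOTAIR-like template,
time points every 5 s from 10–75 s, three replicate tubes of 2000 molecules,
an enzyme stepping at 25.1 nt/s — and recover the velocity through the gel
channel:

```r
library(rtvelocity)

wt <- build_wt_template()          # 2148 nt, primer anchored at 1883
design <- timecourse_design(seq(10, 75, 5), replicates = 3,
                            molecules_per_reaction = 2000, seed = 1)
products <- simulate_timecourse(mrt_profile(25.1), wt, design)
set.seed(1)                        # per-lane gel migration jitter
fit <- estimate_velocity_gel(products, wt)
fit
#> <rt_velocity_fit>
#>   velocity  : 25.15 +/- 0.13 nt/s
#>   intercept : 17.6 +/- 5.7 nt
#>   r^2       : 0.9990   (n = 39 points)
```

The fitted slope recovers the configured 25.1 nt/s within its standard error;
the intercept estimates the 20-nt primer; r² ≈ 0.999 reflects the constant
stepping rate. The 75-s time point was dropped automatically because most
molecules have already run off the 1883-nt full length there
(`saturation_by_time(products)` shows the fraction). `glance(fit)` and
`tidy(fit)` give the same numbers as tibbles, and `ggplot2::autoplot(fit)`
draws the regression.

Localize the stop induced by a GC-rich stem-loop inserted mid-template, from
error-free alignments of 5000 molecules:

```r
gcsl <- add_template_sequence(gcsl_template(p_stop = 0.26))
pg <- simulate_timecourse(mrt_profile(25), gcsl,
                          timecourse_design(120, 1, 5000, seed = 1))
set.seed(1)
reads <- emit_reads(pg, gcsl, perfect_reads(), with_seq = FALSE)
prof <- count_termini(
  tibble::tibble(rname = reads$rname, pos = reads$pos,
                 cigar = reads$cigar, flag = reads$flag), gcsl)
call_dominant_stop(prof)
#> # A tibble: 1 × 5
#>   coordinate stop_frequency n_terminating n_reaching low_confidence
#>        <int>          <dbl>         <dbl>      <int> <lgl>
#> 1       1550          0.257          1283       5000 FALSE
truncation_length_at(gcsl, 1550)
#> [1] 378
fstop_from_reads(prof, 1550)
#> [1] 0.2566
```

The dominant stop lands at template position 1550 — the base of the inserted
stem — implying a 378-nt truncated product, and the read-count stop fraction
recovers the configured per-encounter probability 0.26.

A thin command-line front end lives at `inst/cli/rtvk.R`
(`Rscript rtvk.R <stage> --config run.yaml --seed 1 --out outdir`; stages
`simulate | gel | lengths | velocity | stops | all | demo`).

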