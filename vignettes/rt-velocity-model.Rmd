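---
title: "Modeling reverse-transcriptase velocity and template sensitivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling reverse-transcriptase velocity and template sensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

rtvelocity simulates primer extension by a reverse transcriptase (RT) along a
long RNA template and implements the estimators used to characterize RT
behavior from two experimental readouts: densitometry of denaturing-gel time
courses, and length analysis of long-read (nanopore-style) sequencing of the
cDNA products. This vignette is the package's own account of the model, its
assumptions, the tunable parameters, and the design decisions behind the
numerical choices.

## The stepping model

A template is described by 1-based coordinates `1..length`; the DNA primer
anneals with its 5' end at `primer_anchor` and the RT extends it toward
coordinate 1 (the enzyme moves 3'→5' on the template). Because the label sits
on the primer, product lengths include the primer:

$$\mathrm{product\_length}(p_\mathrm{last}) = \mathrm{primer\_anchor} - p_\mathrm{last} + 1,$$

where $p_\mathrm{last}$ is the template coordinate of the last incorporated
nucleotide. A run-off (full-length) product therefore has length
`primer_anchor` exactly. The default wild-type geometry is a 2148-nt
HOTAIR-like lncRNA with a 20-nt primer anchored at 1883, so the full-length
cDNA is 1883 nt.

Elongation is a homogeneous Poisson process: waiting times between
incorporations are i.i.d. Exponential with rate `step_rate` ($k$, nt/s), so
the number of incorporations by time $t$ on an unobstructed template is
$\min(\mathrm{Poisson}(kt), M)$ with $M$ the distance to the template 5' end.
A constant rate across the template is the model's central assumption — it is
what the velocity assay tests (linearity of length versus time), and it is
what lets `theoretical_mean_length()` serve as a closed-form oracle:
$\mathbb{E}[\mathrm{len}] = \mathrm{primer\_len} + \sum_{j<M} P(N_t > j)$.
Sequence-dependent stepping rates are deliberately not modeled.

Three kinds of termination punctuate stepping:

* **Obstacles** (`obstacle()`): a stable structural element, such as a GC-rich
  stem-loop, registered at a stall coordinate — the last nucleotide a blocked
  molecule incorporates, i.e. the base of the stem. Each molecule draws one
  readthrough Bernoulli per obstacle with per-encounter probability `p_stop`;
  survivors continue at full speed (passing molecules are not slowed, matching
  the observed behavior of processive group II intron RTs). Obstacle
  terminations are final even under enzyme excess by default: a persistent
  stall band under multiple-cycle conditions indicates re-initiated enzymes
  stop with the same probability, which a single draw per molecule already
  captures. Setting `obstacle_rescue = TRUE` instead redraws on each rebind.
* **Background dissociation**: a per-nucleotide Bernoulli
  (`p_background_stop_per_nt`) modeling the frequent premature stops of
  distributive retroviral enzymes. A curated hotspot list is not used; the
  observed multitude of stops is represented by a rate (default 0.002/nt for
  the SSIV-class profile).
* **Run-off** at the template 5' end.

Under **multiple-cycle** reaction conditions (enzyme excess), a
background-stopped primer is picked up again after an
Exponential(`rebind_delay_rate`) wait. Under **single-cycle** conditions a
trap sequesters dissociated enzyme, so any termination is final; the trap
chemistry itself is out of scope — the trap is modeled as rebinding
probability zero from reaction start.

The simulator advances molecules segment-by-segment: within a segment the
arrival count over the remaining time is Poisson, and when a target (obstacle,
background stop, or template end) is reached, the elapsed time is drawn as the
corresponding uniform order statistic. By the strong Markov property the
residual process after such a stop is again a fresh Poisson process, so the
segmented simulation is exact, and it vectorizes across whole cohorts.

Built-in profiles: `mrt_profile()` (25 nt/s, processive, no background),
`tgirt_profile()` (4.4 nt/s, processive), `ssiv_profile()` (distributive,
0.002/nt background, relies on rebinding). The retroviral step rate is not
identifiable from the time-course assay (premature stops dominate before a
front forms), so its default of 15 nt/s is taken from the range reported for
retroviral RTs on homopolymer templates; it only controls how quickly that
profile reaches an obstacle.

## The gel channel

`render_gel_lane()` maps each product length $L$ to an electrophoretic
mobility $a - b\,\log_{10} L$ (standard denaturing-PAGE behavior; defaults
$a = 100$, $b = 30$ mobility units per decade) and adds a Gaussian band of
width `band_sigma` (default 0.6 units, chosen so 378-nt and 1883-nt bands are
cleanly separated). Integrated lane intensity equals molecules ×
`intensity_per_molecule` (conservation, tested). A ladder lane
(`render_ladder()`) with markers spanning 25–3000 nt calibrates mobility back
to length by piecewise-linear interpolation in $\log_{10}$-length
(`calibrate_ladder()`); peak centers are refined by parabolic interpolation
through the three bins around each maximum so calibration is not quantized to
the bin grid.

Two numerical points about the mean-length estimator
(`lane_mean_length()`):

* A Gaussian band in mobility is log-normal in length, so a raw
  intensity-weighted mean overshoots the band center by the factor
  $\exp((\ln 10 \cdot \sigma / b)^2/2)$ (about 0.1% at the defaults). The
  estimator divides this known band-width factor out, which makes it exactly
  unbiased for single-length cohorts.
* The window lower bound defaults to `primer_len + 5` so the unextended-primer
  band is excluded from the mean.

Replicate gel lanes in real experiments do not migrate identically. The gel
model therefore applies a per-lane mobility offset drawn from
Normal(0, `lane_jitter_sd`) (default 0.2 units, ≈1.5% length error per lane)
in `measure_gel_timecourse()`. This term is what gives simulated replicate
time courses error bars and slope spreads on the scale seen in practice; an
ideal noiseless gel would make recovery checks degenerate, with standard
errors dominated by sub-nucleotide binning artifacts. Set `lane_jitter_sd = 0`
for an ideal gel.

The `F_stop` statistic quantifies how much of the extending population an
obstacle terminates:

$$F_\mathrm{stop} = \frac{I_\mathrm{GCSL}}{I_\mathrm{readthrough} + I_\mathrm{GCSL}},$$

with $I_\mathrm{GCSL}$ the integrated intensity of the stall band and
$I_\mathrm{readthrough}$ the intensity at **longer** lengths only — shorter
background-stop products are deliberately excluded, so the statistic
conditions on molecules that reached the obstacle. The integration half-width
`tol` defaults to 3.5 band standard deviations at the stall length (floored at
15 nt): the window should integrate essentially the whole band, as when one
draws a box around a band in densitometry software. A fixed narrow window
would clip the band tails into the readthrough integral and bias the ratio
down; the adaptive default keeps the estimator's bias far below its sampling
noise at $n = 10^4$ molecules.

## The read channel

`emit_reads()` turns each simulated molecule into one nanopore-style read
covering template interval $[p_\mathrm{last}, \mathrm{primer\_anchor}]$, with
SAM `POS` $= p_\mathrm{last}$ and a CIGAR whose reference-consumed span equals
the product length. Reads are emitted cDNA-sense against the DNA-sense
reference with the reverse flag unset: the pipeline measures spans, not
strands, and this avoids double reverse-complement bookkeeping. Default error
rates are nanopore-like (substitution 0.05, insertion 0.03, deletion 0.05 per
base). Deletions become reference-consuming `D` operations and insertions `I`
operations, so interior errors do not change the span; indels at the alignment
ends are absorbed the way an aligner clips them, shifting `POS`/span by a
nucleotide or two. This terminal jitter is why the stop caller pools termini
over a ±2-nt window.

Library-construction bias against long molecules is modeled as survival
probability $\exp(-c \cdot L)$ with `length_dropout_coef` $c = 3\times10^{-4}$
per nt, reproducing the amplitude decay of later time points in long-read
length distributions. How much of the real amplitude decay is kinetic versus
library bias is not asserted; both knobs (kinetic background stops, dropout)
exist and default to the library-bias explanation for processive profiles.

When no template sequence is supplied, `add_template_sequence()` generates one
with a linear 5'→3' GC gradient (60%→40%), echoing the composition gradient of
the real template; it has no kinetic effect and only provides realistic read
content.

## Estimators

* `cdna_length_from_alignment()` — the cDNA length of a read is its
  reference-consumed span (M/D/N/=/X), a native re-implementation of the
  custom length-extraction step; aligned span rather than raw read length is
  used because insertions would otherwise inflate lengths by ~3%.
* `length_distribution()` / `peak_maximum()` — fixed-origin histograms
  (default 25-nt bins, the resolution is not critical) and the modal bin
  center, ties broken toward the longer length (the front of the advancing
  population). The peak maximum tracks the synchronized population front; the
  distribution mean would be dragged by stragglers and dropout.
* `fit_velocity()` — ordinary least squares of length on time; the slope is
  the velocity, the intercept estimates the primer length. The fit is
  unweighted by default (a weighted option exists). Time points where at
  least half the population has reached full length are excluded upstream
  (`saturation_by_time()`): the length ceiling flattens the line, and the
  usual experimental design (≤75 s for a 1883-nt product at ~25 nt/s) stays
  below this threshold, so the exclusion rule generalizes that design. The
  gel-channel wrapper fits the replicate-level lane measurements rather than
  per-time averages: for a balanced design the slope is identical, but the
  residual degrees of freedom — and hence the standard error — are estimated
  from every lane.
* `count_termini()` / `call_dominant_stop()` — a read's stop position is its
  smallest covered reference coordinate (the last incorporated nucleotide;
  synthesis runs toward coordinate 1). The off-by-one alternative (first
  blocked nucleotide) is a matter of bookkeeping on top of this profile.
  Candidates for the dominant stop are local maxima of the terminus counts;
  termini within ±2 nt are pooled onto them before frequency ranking;
  positions reached by fewer than `min_reaching = 50` reads are never called;
  the run-off terminus is excluded by default (running off the template is
  not a stop); ties break 3'-ward. A call is flagged `low_confidence` when
  its pooled frequency does not stand out over the background (under 3× the
  median candidate frequency, or fewer than 20 pooled termini) — a heuristic
  for the no-signal case, not a calibrated test.
* `fstop_from_reads()` — the read-count analogue of the densitometry
  statistic: terminating / reaching reads at the stall. Under length-biased
  dropout this estimator is inflated (short stall products survive library
  construction better than long readthrough products), which is precisely the
  clustering-bias argument for preferring densitometry; the package therefore
  treats the densitometry route as the primary `F_stop` estimator and the
  read-count route as the cross-check, to be used with dropout-free error
  models.

## The GC stem-loop construct

`gcsl_template()` reproduces the strongest challenge construct: a 44-nt
GC-rich stem-loop inserted after position 1512 of the wild-type template
(between two structural domains), with the stall at nucleotide 1550 — the base
of the stem — so a blocked molecule yields a 378-nt truncated product. The
printed construct coordinates fix the insert length: with the primer anchor at
1883 + 44 and a stall at 1550, only a 44-nt insert gives
$1927 - 1550 + 1 = 378$. The true insert and primer sequences are not public;
the 20-nt primer and the insert's internal layout are internally consistent
reconstructions flagged as configuration, not fact. The stem-loop's folding
stability (ΔG) is treated as metadata; no RNA thermodynamics is computed.

## Reproducibility and problem sizes

All randomness flows from explicit seeds: a `timecourse_design()` seed derives
one independent sub-seed per reaction tube, so results do not depend on tube
order or the sizes of other tubes. The bundled analyses use desk-scale sizes —
2000 molecules per reaction for gel time courses (14 time points × 3
replicates), 5000 reads per time point for the read channel, and $10^4$
molecules for `F_stop` recovery — chosen so parameter-recovery standard errors
sit well inside the tolerances being tested while a full analysis completes in
about a minute.

## What the simulations do and do not show

Passing recovery tests demonstrates that the estimators are unbiased and
correctly implemented under the model's assumptions: constant stepping rate,
memoryless dissociation and rebinding, one readthrough draw per obstacle,
log-linear gel mobility with Gaussian bands, and span-preserving interior
sequencing errors. Real data can violate each of these — sequence-dependent
pausing, non-exponential rebinding kinetics, gel smiling, basecaller-specific
error structure, and adapter artifacts are all absent from the generator — so
agreement here validates the analysis pipeline, not the biology. Limitations
worth restating: no nucleotide-level chemistry (fidelity, dNTP dependence), no
temperature effects, no mutational-profiling signal (termination events only),
and no image processing (lanes enter as 1-D traces).
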