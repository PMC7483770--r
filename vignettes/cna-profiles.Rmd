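---
title: "Probability profiles of copy number alterations: model, estimation and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probability profiles of copy number alterations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnaprofiler)
```

## The model

cnaprofiler treats the genomic signature of a disease population as a
*generator function*: a per-region probability of copy-number alteration,
Φ(r), defined over regions with hard boundaries. Each subject's profile is
modelled as an independent Bernoulli draw per region — region r of a random
subject is altered with probability Φ(r) and normal otherwise. Alterations
are binary (present/absent per call type); segment amplitudes beyond the
calling thresholds are deliberately ignored.

The inverse problem is the one of practical interest: given a cohort of
segmented, called profiles, estimate Φ. Two obstacles separate real data from
the clean model. First, subjects do not share region boundaries — each
arrives with its own segment starts and ends. Second, Φ is only identified up
to the regions the cohort itself defines.

### Partition into common regions

The package resolves the first obstacle with a breakpoint sweep. All
subjects' altered segments on a chromosome contribute a start breakpoint
(identifier 1) and an end breakpoint (identifier 0); the pooled breakpoints
are sorted and a counter sweeps across them, +1 at each start and −1 at each
end. Between any two adjacent distinct breakpoint positions the counter is
constant and equals the number of subjects altered there; each such interval
with a positive counter is a *common region of alteration* with that subject
count, `n_occurrences`. Every subject's alteration status is constant across
a common region by construction, so the cohort compresses losslessly into a
subjects × regions binary incidence matrix.

Numerical conventions that make this exact:

* Coordinates are 0-based half-open internally (`[start, end)`, the BED
  convention); SEG input, 1-based inclusive, is converted on read. Book-ended
  segments (one ending where another starts) are then disjoint by
  construction.
* At a shared locus, end breakpoints process before start breakpoints, so a
  book-ended pair contributes a boundary of zero width rather than a spurious
  overlap, and the two flanking regions stay separate.
* Remaining ties break by sample id; the output is invariant to input row
  order.
* Intervals where the counter is zero (no subject altered) are *not* emitted
  as regions; the estimated probability there is zero, and grid-alignment
  utilities (`phi_on_grid()`) fill those gaps with 0 explicitly.
* A counter that would go negative means unbalanced breakpoints and is raised
  as a contract violation with the offending position.

Each subject's overlapping same-call segments must be unioned first
(`merge_subject_segments()`, applied by default inside `cna_profile()`) —
otherwise a subject would be double-counted in regions its segments cover
twice, biasing the estimate. The simulator's output is book-ended but never
overlapping per subject, so the simulated pipeline may skip the merge
(`merge = FALSE`); counts are identical either way.

### Estimation and confidence bands

On the partitioned regions the estimator is the exact integer ratio

> Φ̂(r) = n_occurrences(r) / N_subjects,

where `N_subjects` is the *cohort roster size*, passed explicitly — not the
number of subjects with at least one alteration. Each region is treated as an
independent binomial experiment and receives a proportion confidence
interval; plotted along the genome these intervals form the signature's
confidence band.

The interval method is configurable:

* **Wilson score** (default): well behaved at Φ̂ = 0 and Φ̂ = 1, both of
  which occur routinely (a region altered in nobody or in everybody), and
  close to nominal coverage at moderate n. The package's acceptance checks
  verify 93–97% empirical coverage at Φ = 0.3, n = 200.
* **Wald**: provided for sensitivity analysis; collapses to zero width at the
  extremes.
* **Clopper–Pearson**: exact and conservative, via the beta quantile.

`confidence_level` defaults to 0.95.

### Comparing phenotypic groups

Two groups are comparable only on a shared region set, and nothing in the
data forces their partitions to coincide. `harmonize_profiles()` therefore
partitions the *pooled* segments of both groups once and estimates each
group's Φ̂ on those shared boundaries against its own cohort size. A region
altered in only one group appears in both profiles, with Φ̂ = 0 and an
interval at 0 successes in the other. (A per-group partition followed by
re-intersection would give the same boundaries; the pooled partition is the
direct construction.)

`compare_profiles()` flags a region as *differential* when the two confidence
bands do not overlap. This mirrors how group differences are read off the
plotted signatures, and two caveats are documented rather than "fixed": band
non-overlap at level 1−α is a conservative screen, not an α-level
two-proportion test, and no multiple-testing correction is applied across
regions. The package deliberately ships no significance machinery beyond
this rule.

The profile distance is the region-length-weighted mean absolute difference
of the two probability vectors, Σ|Φ̂ₐ−Φ̂ᵦ|·len / Σlen. Weighting by length
matters because the partition produces regions of very unequal sizes; an
unweighted mean would let many short regions dominate. The distance is a
pseudometric on [0, 1]: symmetric, zero for identical profiles, and
triangle-inequality-consistent (property-tested on random triples). Distinct
profiles over disjoint region supports can in principle coincide in
distance, hence pseudo.

### Subsampling robustness

`stratified_subsample()` draws n subjects without replacement while
maintaining the group proportions of the full cohort, with largest-remainder
rounding so the per-group quotas sum exactly to n (e.g. classes of 423 and 99
subjects at n = 200 give quotas 162 and 38). Re-fitting on subsamples of
increasing size shows the band width shrinking while the overall shape of the
signature is preserved — the package's band-monotonicity checks assert the
width ordering 50 > 100 > 200 at fixed Φ̂.

## The simulator

The simulator solves the direct problem so the inverse machinery can be
validated against a known truth. `sample_cohort()` draws a binary
subjects × regions matrix from a generator function over uniform fixed-size
regions (default 1 kb); `matrix_to_segments()` expands every altered cell
into one segment covering exactly its region. Contiguous altered cells are
emitted as separate book-ended segments rather than merged, mimicking how
per-region calls arrive with individual starts and ends in segmented data —
and exercising the partition's book-ended tie rule.

Seed discipline: one root seed deterministically spawns one uniform stream
per subject, and a cell is altered iff its uniform draw is below Φ(r).
Cohorts are therefore reproducible for a fixed seed and independent of
subject iteration order. The same uniforms drive the three-state
(gain/loss/normal) generator — gain when u < p_gain, loss when
p_gain ≤ u < p_gain + p_loss — so a three-state run with zero gain
probability is *identical* (not merely equal in distribution) to the
two-state run with the loss generator at the same seed, which the tests
assert exactly.

What the simulator does **not** emulate: variable region sizes, probe-level
noise, signal aliasing from highly altered neighbourhoods, correlation
between regions, tumour purity/ploidy effects, or segmentation error. Tests
passing on simulated data validate the partition/estimation machinery — that
the pipeline recovers exactly the matrix it was fed (the closure property,
checked for every seed) and that the estimator converges at the binomial
rate — not the upstream calling choices on real arrays.

## Error metrics and the convergence study

With Φ known, one simulated dataset's recovery error is measured two ways,
after aligning the estimate back to the generator grid with `phi_on_grid()`:

* `error_sq()`: ε = Σᵣ (Φ(r) − Φ̂(r))² / N_subjects. The cohort-size
  normalisation is applied per dataset; replicate averaging is done
  explicitly by `convergence_study()`. Since
  E[Σᵣ(Φ−Φ̂)²] = ΣᵣΦ(1−Φ)/n, mean ε decays like 1/n², and the raw squared
  deviation is reported alongside (`raw_sq_mean`) for closed-form
  comparisons.
* `error_pct()`: ε_p = Σᵣ (Φ(r) − Φ̂(r))² / Φ(r), summed over regions with
  Φ(r) > 0. Regions with Φ = 0 contribute 0/0 and are excluded; the (under
  the simulator impossible) case Φ = 0 with Φ̂ > 0 would contribute an
  infinite term and is instead counted in a `flagged` attribute. Scaled by
  n, ε_p behaves like a chi-square statistic across replicates, with
  E[n·ε_p] = Σᵣ(1−Φ(r)); the package remarks on but does not formally test
  this distributional shape.

`convergence_study()` runs the full pipeline — draw, expand, partition,
estimate, score — for each (generator, cohort size) cell and reports
mean ± sd over replicates. The package's own acceptance run uses the built-in
single-peak generator at n ∈ {100, 400, 1000} with 30 replicates, which keeps
the whole study under a couple of minutes on one core while giving Monte-Carlo
standard errors small enough to resolve both the strict decrease of mean ε
and its agreement with the closed form within 3 SEs. Four built-in generators
(`builtin_generators()`: peak, bimodal, flat, sparse) span qualitatively
different signature shapes; they are illustrative choices, not estimates from
any cohort.

## Filtering defaults and open choices

SEG calling thresholds are platform- and cohort-specific and the package
cannot know them; `filter_config()` defaults — at least 10 probes, |log2
segment mean| ≥ 0.2, closed comparisons so values exactly at a threshold are
called — are conventional SNP-array cut-offs and are *not* derived from any
dataset. Real-data profiles depend on them materially. Sex chromosomes are
dropped at calling time (the reader stays generic), restricting profiles to
the 22 autosomes.

## Known limitations

* Region boundaries are cohort-dependent: adding a subject can split or move
  common regions, so profiles from different cohorts are comparable only
  after harmonization on pooled segments (or, across published cohorts, via
  smoothing — out of scope here).
* The band-overlap rule is descriptive; no FDR control is offered.
* The estimator ignores alteration amplitude and within-region heterogeneity;
  a region is a Bernoulli outcome per subject.
* `N_subjects` must include alteration-free subjects to estimate absolute
  probabilities; SEG files alone cannot reveal them, so pass the roster size
  explicitly when it differs from the number of samples present.

```{r example}
# worked example: a five-subject cohort over five 1 kb regions
m <- rbind(S1 = c(0, 0, 0, 0, 1), S2 = c(0, 0, 0, 1, 1), S3 = c(0, 1, 1, 1, 0),
           S4 = c(0, 0, 0, 1, 1), S5 = c(0, 0, 1, 0, 1))
segs <- matrix_to_segments(simulated_cohort(m, region_size = 1000))
fit <- cna_profile(segs, n_subjects = 5, merge = FALSE)
fit$regions[, c("start", "end", "n_occurrences", "phat")]
```
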