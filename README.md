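# cnaprofiler

Somatic copy number alterations (SCNAs) — deletions and amplifications of
genomic fragments — are pervasive in cancer, but any single tumour mixes
disease-linked alterations with random passenger events. `cnaprofiler` is for
researchers who have a *cohort* of segmented copy-number profiles (SEG files
from SNP arrays or aCGH, segmented upstream by Circular Binary Segmentation)
and want the population-level picture: which regions of the genome are
recurrently altered, with what probability, and whether two phenotypic groups
differ.

The package models the disease's genomic signature as a **generator
function** Φ(r): the probability that region r is altered in a random subject
of the population, with each region a Bernoulli outcome per subject. From a
cohort it:

1. **Partitions** all subjects' altered segments on each chromosome into
   *common regions of alteration* with a breakpoint sweep: every segment
   start (+1) and end (−1) moves a counter, and each interval between
   adjacent distinct breakpoints with a positive counter is one common
   region whose count is the number of subjects altered there.
2. **Estimates** the signature on those regions,

   Φ̂(r) = n_occurrences(r) / N_subjects,

   an exact integer ratio, with a proportion confidence interval per region
   (Wilson score by default) forming a confidence band around the profile.
3. **Compares groups** on a shared (pooled) partition: regions whose bands do
   not overlap are flagged as differential, and a region-length-weighted L1
   distance summarises how far apart two signatures are.
4. **Validates itself by simulation**: cohorts drawn from a known generator
   function are pushed through the full pipeline and the recovery error
   ε = Σᵣ(Φ−Φ̂)²/N and its chi-square-like percentage variant are tracked as
   cohorts grow.

## Worked example

Five subjects over five 1 kb regions, as a binary status matrix (1 = region
altered in that subject):

```r
library(cnaprofiler)

m <- rbind(S1 = c(0, 0, 0, 0, 1), S2 = c(0, 0, 0, 1, 1), S3 = c(0, 1, 1, 1, 0),
           S4 = c(0, 0, 0, 1, 1), S5 = c(0, 0, 1, 0, 1))
segs <- matrix_to_segments(simulated_cohort(m, region_size = 1000))
fit  <- cna_profile(segs, n_subjects = 5, merge = FALSE)
fit
#> Probability-of-alteration profile
#>   5 subjects, 4 common regions (ALTERED), 95% wilson bands
#>   most frequently altered regions:
#>     1:4000-5000  ALTERED  phat=0.800 (0.376, 0.964)
#>     1:3000-4000  ALTERED  phat=0.600 (0.231, 0.882)
#>     1:2000-3000  ALTERED  phat=0.400 (0.118, 0.769)
#>     1:1000-2000  ALTERED  phat=0.200 (0.036, 0.624)
```

The ten per-region segments collapse into four common regions altered in
1, 2, 3 and 4 of the 5 subjects — probabilities 0.2, 0.4, 0.6, 0.8 — and the
never-altered first kilobase is a gap with Φ̂ = 0. The Wilson intervals in
parentheses are the confidence band; `coef(fit)`, `confint(fit)`,
`predict(fit, ...)` and `plot(fit)` expose the fitted signature, and
`simulate(fit, ...)` draws new cohorts from it.

How fast does the estimate converge to the truth? Simulating from a known
single-peak generator and re-estimating:

```r
convergence_study(builtin_generators()$peak, sizes = c(100, 400, 1000),
                  replicates = 30, seed = 20)[, 1:5]
#>   generator n_subjects replicates epsilon_mean   epsilon_sd
#> 1      peak        100         30 1.048000e-04 6.572010e-05
#> 2      peak        400         30 6.809375e-06 3.549655e-06
#> 3      peak       1000         30 1.096933e-06 5.925212e-07
```

Mean ε falls roughly 100-fold from n = 100 to n = 1000, the 1/n² decay the
binomial variance predicts.

Real cohorts enter through `read_seg()` + `filter_and_call()` (probe-count
and log2-ratio thresholds, gains/losses separate or combined), with
group comparison via `harmonize_profiles()`/`compare_profiles()`,
proportion-preserving `stratified_subsample()` for robustness checks, and
`run_pipeline()` (or the `inst/cli/cnaprofiler.R` script) to run SEG → regions
→ profiles → comparison → plots from one YAML/JSON config with a JSON run
manifest. `vignettes/cna-profiles.Rmd` documents the model, the numerical
conventions and the simulator's scope.

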