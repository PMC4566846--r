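---
title: "Models and methods behind magicpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind magicpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

`magicpop` models an eight-founder MAGIC (Multi-parent Advanced Generation
InterCross) population of maize recombinant inbred lines: it simulates the
funnel breeding design that produces such a population, reconstructs founder
mosaics from SNP-array genotypes with a hidden Markov model, maps QTL on the
reconstructed haplotype probabilities with a kinship-adjusted mixed model,
and estimates the mapping power of the design by simulation. This vignette
explains each model, its assumptions, the tunable parameters, and the design
choices made where more than one reasonable implementation existed.

## The breeding design and its analytic expectations

Eight inbred founders (labelled A-H) are crossed in a half-diallel to give
the 28 two-way hybrids. Two-way hybrids with no founder in common are
crossed (210 such crosses), and the results pooled into 70 four-way pools,
one per 4-founder subset. Each of the 35 funnels pairs a pool with its
complement so that the eight-way hybrid carries all eight genomes, and each
line is then advanced by single seed descent (SSD) to F6. A ninth parent
(CML91, label I) enters through a substitution rule: wherever the
B96 x HP301 two-way was needed and failed, the B73 x CML91 two-way replaced
it.

Three expectations follow analytically and anchor the test suite:

* **Founder contributions.** Without substitution each founder is expected
  to contribute 1/8 of the genome. With substitution, enumerating all 35
  complementary pool partitions in integer arithmetic
  (`expected_contributions()`) gives B73 = 1/7 (14.29%), CML91 = 1/56
  (1.79%), B96 = HP301 = 3/28 (10.71%) and 1/8 for the rest. The key fact
  is that B96 and HP301 share a pool in 3/7 of partitions, and within such a
  pool the failed component is picked for a given seed with probability 1/3.
* **Junctions.** On a genetic map of total length L Morgans, the expected
  number of founder switches per line is 4L: one full round of
  recombinations for each of the two intercross meioses and the first
  selfing, plus one more round contributed by the whole of SSD as
  heterozygosity halves geometrically. With L = 19.96 M this gives 79.84.
* **Heterozygosity.** The eight-way F1 is fully heterozygous and SSD halves
  heterozygosity each generation: F_k carries 0.5^(k-1), i.e. 3.125% at F6.

`design_expectations()` returns all three plus the count of distinct
recombinant inbred intercrosses, n(n-1)/2.

## The forward simulator

`simulate_funnel_population()` samples each line's pedigree independently:
the funnel fixes the pool pair, the contributing four-way component is drawn
uniformly from the pool's three components (the study pooled balanced seed
amounts, so uniform weights are the natural reading), and every meiosis is
simulated with a no-interference crossover process -- Poisson counts with
mean the chromosome's length in Morgans, positions uniform on the cM scale
and mapped to bp through the marker map. No interference keeps the simulator
consistent with the Haldane map function used to convert marker distances to
recombination fractions for the HMM.

The default synthetic map (`magic_map_synthetic()`) spans 10 chromosomes
with maize-like physical sizes (~2.06 Gb) and genetic lengths summing to
1,996 cM, at a constant cM/bp rate per chromosome (about 1 cM/Mb, the maize
genome-wide average). The default desk-scale panel is 5,000 markers; the
full-array scale of ~54,000 markers is supported but reserved for long runs.
Synthetic founder alleles are drawn independently with probability 1/2 per
founder and redrawn while monomorphic, emulating an array ascertained for
polymorphic markers. Genotyping noise is applied per call: a 1% chance of
flipping to a random different call and a 15% chance of a missing call,
matching the 85% mean call rate of the reference assay.

What the simulator does **not** emulate: founder pairs that are nearly
identical by state over long stretches (the real panel's pairwise
polymorphism ranges roughly 0.3-0.5 and contains IBS regions that confuse
reconstruction), array ascertainment bias toward particular founder splits,
residual founder heterozygosity (available via `het_rate` but off by
default so truth segments stay well defined), and any selection during
breeding. Synthetic founders are therefore *easier* to distinguish than the
real ones, and reconstruction accuracy and mapping power on simulated data
should be read as upper ends of what the same pipeline achieves on real
arrays.

## Founder-mosaic reconstruction

`magic_reconstruct()` fits a hidden Markov model per chromosome. Because
residual heterozygosity at F6 is small, the hidden states are the eight (or,
for lines whose funnel received CML91, nine) homozygous founder genotypes;
observed heterozygous calls are treated as emission noise.

* **Transitions.** Between adjacent markers at recombination fraction r, the
  probability that the founder state changes is R = r(4-r)/(1+2r), the
  two-locus non-identity probability for an eight-way cross advanced by
  selfing at the inbred limit; the test suite verifies this against an
  independently coded pedigree-plus-selfing Markov chain. The change mass is
  split equally over the alternative founders, which is exact under founder
  exchangeability. r comes from the Haldane inverse of the cM distance,
  with an optional multiplicative damping factor (default 1) and a floor/cap
  at [1e-12, 0.499].
* **Emissions.** Initialized from the founder calls: a homozygous call puts
  its mass on that symbol, a heterozygous founder call splits 0.5/0.5
  between the homozygous symbols, and a smoothing constant (default 0.01) is
  added everywhere before renormalizing, so a confident founder call emits
  its symbol with probability ~0.98. Missing observations are emitted
  uniformly by all states. The smoothing default makes the emission noise
  comparable to the simulated 1% genotyping error.
* **EM.** The M-step re-estimates each marker-by-state emission from
  posterior-weighted symbol counts pooled across lines (pooling keeps the
  estimates stable at desk-scale marker counts), re-applying the smoothing
  (disable with `smooth_updates = FALSE`). Iteration stops when the total
  log-likelihood moves by less than 1/1000 of its initial magnitude. The
  log-likelihood is monotone by construction and the fit aborts loudly if it
  ever decreases beyond numerical tolerance.
* **Numerics.** Scaled forward-backward with per-marker normalization; the
  log-likelihood is the sum of log scale factors, so 50k-marker chromosomes
  cannot underflow. All lines sharing a state space are propagated together
  as a matrix, which keeps the E-step a few seconds for 500 lines x 5,000
  markers.

**Junction counting and its resolution limit.** `count_junctions()` counts
changes of the maximum-posterior founder between consecutive *confidently
assigned* markers (maximum posterior at least `min_prob`, default 0.8);
markers straddling a crossover are naturally uncertain and are skipped
rather than suppressing the junction. Two effects bound what this can
recover at a given marker density. First, segments shorter than a few
marker spacings are invisible outright. Second, the transition prior prices
each junction at roughly 2 log(R/(G-1)) nats while each informative marker
inside a segment contributes only ~log(0.98/0.01) nats, so a segment needs
several informative markers to overcome the prior -- and the uniform
split of the change mass underweights the common pattern in selfing
pedigrees where the genome switches *back* to the other locally resident
haplotype (A-B-A). Both effects shrink as marker density grows; at the
desk-scale 5,000-marker default a material fraction of true junctions sits
below the evidence hurdle (the acceptance suite measures the recovery ratio
at that scale), while assignment accuracy is essentially unaffected because
the missed segments are short. Full-array densities recover nearly all
junctions.

## QTL mapping

`magic_scan()` regresses a trait on the eight founder-posterior columns at
each marker with a polygenic random effect whose covariance is sigma_g^2 K.
The kinship K is the marker-averaged inner product of posterior vectors
(`compute_kinship()`), computed LOCO by default -- each chromosome is
scanned with a kinship built from the other nine, so the scanned
chromosome's own QTL are not absorbed. CML91's column is removed first and
the remaining posteriors renormalized (`drop_ninth_founder()`): the ninth
founder segregates in ~1/56 of the genome, far too little for stable
coefficients.

The variance ratio is estimated once per chromosome under the null by REML
on the eigendecomposition of K and then fixed across markers
(EMMAX-style); each marker is tested by generalized least squares on the
rotated data, LOD = (n/2) log10(RSS0/RSS1). Because the posterior columns
sum to one, the marker model carries no separate intercept and founder
effects are reported centered at zero, which is what a founder-effect plot
wants. With K proportional to the identity the whole machinery collapses
exactly to ordinary least squares, a property the tests exploit.

Significance is calibrated by permuting the raw trait across lines
(`permutation_thresholds()`), re-running the full scan, and recording each
permutation's genome-wide maximum LOD: the 99th percentile of the maxima is
the strong threshold (genome-wide P < 0.01), the 37th percentile the
suggestive one (P < 0.63). Variance components are re-estimated per
permutation by default (`freeze_vc` skips this). Peaks above the suggestive
threshold are reported with -2 LOD support intervals; two local maxima are
distinct peaks only when separated by at least 50 consecutive
sub-suggestive markers (`call_peaks()`). Conditional scans add the largest
QTL's founder columns to both null and alternative models
(`covariate` argument), which empties its own peak while leaving unlinked
signal intact.

Association mapping (`impute_founder_snps()`, `association_scan()`)
transfers each line's posterior at the nearest array marker (ties leftward;
posteriors are effectively piecewise constant between informative markers,
so nearest-marker transfer is both simpler and testable against hand
computation) onto founder variant alleles, giving a continuous dosage in
[0, 2]; regression uses the continuous dosage, while the rounded haploid
0/1 companion is used only for LD profiles, mirroring the reference
analysis's use of rounding. The region-wide significance threshold is the
90th percentile of 500 permutation maxima.

## The power study

`simulate_phenotype()` draws a sample of lines, picks 20 QTL markers (two
per chromosome, shuffled so effect rank is independent of genome position),
draws an independent minor-allele founder set F of size 1-4 per QTL, and
condenses posteriors to a genotype f = 2 sum_{s in F} P(s) - 1 in [-1, 1].
QTL i carries effect 0.9^i; the genetic value is standardized to unit
variance and mixed with standard normal noise at heritability 0.4 or 0.7.
The realized fraction of variance each QTL explains is recorded per run and
drives the power-by-variance binning (2%-wide bins; the reference binning
was not published, so bins centered on the printed values are the natural
choice).

`stepwise_map()` is the mapping engine: scan all markers with the current
multi-marker founder regression, take the maximum-LOD marker, and test it
with a 7-df likelihood-ratio test (seven, because a marker's eight columns
add rank 7 over the intercept). A nominal per-marker cut at P <= 0.01
cannot terminate this loop -- the tested marker is the maximum over
thousands of correlated tests and its nominal P is essentially always below
0.01 under the null -- so the entry level is enforced genome-wide. The
default calibrates a per-sample-size entry threshold as the permutation
99th percentile of the null genome-wide maximum LRT
(`stepwise_entry_threshold()`); an analytic Sidak adjustment by the marker
count is available (`entry = "sidak"`) and is slightly more conservative
because it ignores inter-marker correlation. On null traits the default
rule selects a median of zero to one markers per genome, the behaviour a
1% genome-wide level implies.

The kinship random effect is off in the power study by default: lines are
drawn at random from a structure-free population, and pre-whitening with
the posterior kinship mostly absorbs the simulated QTL themselves (they are
the only genetic signal), deflating power across the board. The flag is
exposed for users who want the conservative variant.

Detection follows the +/- 5 Mb rule with greedy nearest-first one-to-one
matching between selected markers and simulated QTL (boundary inclusive),
preventing one selected marker from claiming two QTL or vice versa; power
is the detected fraction of the 20 QTL and FDR the unmatched fraction of
selections (zero when nothing is selected). `run_power_study()` averages
over runs and the four MAF settings per sample-size/heritability cell.

**Problem sizes.** The shipped analyses use a 5,000-marker panel, 500-529
simulated lines, 25 runs per MAF setting (100 per cell), 50 permutations
for the stepwise entry threshold, 200 replicates for the type-I
calibration, and 10,000 lines for the Monte-Carlo check of the expected
contributions. These are the package's desk-scale defaults; every size is a
function argument and scales up unchanged.

## Diversity and LD diagnostics

Marker QC keeps markers with call rate strictly above 0.8 that are
polymorphic among the lines. MAF is computed only at markers where every
founder is homozygous and non-missing, so the founder allele count is
unambiguous; with nine founders the founder MAF cannot reach 0.5. LD is the
squared Pearson correlation of additive dosages over pairwise-complete
lines (heterozygous calls contribute dosage 1). Decay curves bin all pairs
within 10 Mb into 100-kb distance bins per chromosome; the halving distance
is the first bin at which the mean falls to half the first bin's mean --
the first-bin baseline is the simplest definition consistent with reading
the halving point off a decay curve. Local profiles average each marker's
r^2 within +/-1 Mb and smooth mean and quartile series with a 100-marker
sliding window stepping one marker at a time (the step size was not pinned
down by the reference description; step 1 is the finest and subsumes
coarser choices). Pruning drops markers in r^2 > 0.4 with any retained
marker within 500 kb, greedily left to right, repeating until stable --
one pass is already stable, and idempotence is tested.

## Degenerate inputs and numerical guards

Constant traits scan to LOD 0 everywhere. Monomorphic or collinear marker
designs (including the covariate marker in a conditional scan) are detected
by comparing the residualized design's diagonal against the chromosome's
typical column norm and reported as LOD 0 with flagged coefficients. The
batched 7x7 Cholesky in the stepwise engine drops deficient pivots
(pseudo-inverse behaviour) so locally monomorphic founder columns cannot
inflate the test statistic. Mixed-model solves add a relative ridge of
1e-10 before Cholesky. All simulation entry points take explicit seeds;
pipeline stages derive per-stage seeds from one master seed
(`derive_seed()`), so every stage is independently reproducible.

## Known limitations

* Junction recovery at desk-scale marker density is incomplete, as
  discussed above; counts converge to the 4L expectation only at
  full-array densities.
* The simulator's founder panel is maximally informative; real-array IBS
  regions will lower reconstruction accuracy and mapping power relative to
  simulated results.
* The synthetic founder panel has no haplotype structure: each marker's
  founder alleles are drawn independently, so even perfectly linked markers
  have expected r^2 near 1/(G-1) unless their founder splits happen to
  align. Short-range LD on simulated panels therefore plateaus around 0.14
  rather than the much higher values real arrays show, and absolute halving
  distances come out larger than the 1-4 Mb seen on real data even though
  the decay *shape* (monotone decline to the 1/n background within the
  10 Mb window) is reproduced. Conclusions from simulated LD should be
  drawn from relative, not absolute, r^2.
* Crossover interference is not modelled; map functions other than Haldane
  (plus the raw linear mode) are not implemented.
* The association module assumes inbred founders (haploid allele transfer);
  heterozygous founder variant calls are carried as dosage 1 but phasing
  within a founder is out of scope.
* The stepwise engine is designed for the simulation study; real-trait
  multi-QTL model selection (refinement, drop-one tests, interval support
  for selected models) is deliberately not provided.
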