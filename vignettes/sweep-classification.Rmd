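---
title: "Classifying shared and divergent sweeps between sympatric population pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying shared and divergent sweeps between sympatric population pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Two sympatric populations that recently diverged inside a colonized
habitat (the motivating system is a pair of cichlid species inside a
volcanic crater lake, colonized from a large source lake) can differ at a
handful of loci under divergent selection while remaining nearly
identical elsewhere. `diverscan` asks, window by window along the
genome, whether phased genotypes from the two populations look *neutral*,
like a *shared* selective sweep (the beneficial allele rose in both), or
like a *divergent* sweep (beneficial in only one). The answer comes from
a supervised classifier trained on coalescent-realistic simulations of
the pair's own demographic history — the pairwise extension of the
simulation-trained sweep classifiers of the diploS/HIC family.

The package also carries the classical companions of such a scan:
windowed Hudson F~ST~ with loess smoothing, outgroup-polarized joint
site-frequency spectra, and neutral whole-genome "drift null"
simulations used to ask whether genome-wide differentiation needs
anything beyond drift and migration.

## The demographic model

All simulations share one history (`demographic_model()`): a source
population of diploid size `source_size`; a founder event
`colonization_time` generations ago into a colony of size
`founder_size`; a sympatric split `split_time` generations ago into two
daughters of sizes `daughter_sizes`; symmetric migration at
`migration_rate` per generation thereafter. Mutation and recombination
rates are per site per generation; the generation time (default 1.5
years) only converts to calendar units. Fitted parameters from an
external demographic inference are *inputs* here — the package does not
re-fit them.

## The simulation engine

The training data and the drift-null genomes come from a forward-in-time
Wright–Fisher engine (C++) with infinite-sites mutation on a continuous
locus and Poisson recombination. Selection is genic (haplotype fitness
`1 + s` per copy) and population-restricted: a shared sweep is beneficial
from the colonization onward in the colony and both daughters; a
divergent sweep is beneficial in exactly one daughter (fair coin, hidden
from the classifier) and strictly neutral in the other, including any
migrant copies. Sweeps start as a single de novo copy or at a standing
frequency `f0` drawn loguniform(1e-5, 1e-2) (at desk population sizes
most standing draws still round to one copy — at this scale the two
origins largely coincide, and origin is treated as a latent nuisance
within each class). A run is conditioned, by re-running the
post-colonization segment from a snapshot, on the selected allele
reaching frequency `f_end` (default 0.9 — an essentially completed
sweep) in its sweeping population(s) at sampling time; runs where the
allele is lost are abandoned early.

A trajectory-conditioned coalescent would be the other standard engine
for this design; the forward engine was chosen because it handles the
two-population, population-restricted fitness regime exactly, with one
code path for neutral, shared and divergent classes. Its contract is
behavioural and enforced by the test suite: neutral runs reproduce
Watterson's theta and Tajima's D at equilibrium, sweeps carve diversity
valleys centred on the selected site, and the SS-H12 sign separates
shared from divergent sweeps.

Burn-in is 4 source-population coalescent "units" (4 x 2N generations)
for training instances — leaving under 2% residual deficit in
heterozygosity, shared identically by all classes — and 10 units for the
neutral-calibration runs, where unbiasedness itself is under test.

## Desk scale versus paper scale

`paper_profile()` keeps the published training design: 1.05-Mb loci, 21
x 50-kb subwindows, per-locus mutation rate uniform(0.000668, 0.00668),
truncated-exponential recombination (mean 0.018375, max 0.055125),
selected site at uniform(0.4, 0.6) of the locus, s uniform(0.01, 0.1),
4,000 training and 2,000 test loci per class. Running that design needs
cluster-scale compute.

`desk_profile()` is the package's reduced study condition, sized to run
the whole pipeline in minutes while preserving the *dimensionless*
quantities that control what the classifier sees:

* locus 105 kb in 21 x 5-kb subwindows (same frame geometry);
* per-locus mutation draws rescaled so that per-site diversity is a
  realistic 1-3 per kb at desk population sizes and every 5-kb
  subwindow keeps the information content of a paper-scale 50-kb
  subwindow (roughly 10-60 SNPs; the draw range is uniform(0.06, 0.3)
  per locus per generation, a fivefold spread);
* selection rescaled to preserve the *population-scaled* strength and
  tempo of the published strong-sweep regime rather than the raw
  coefficient: at paper-scale effective sizes, s in [0.01, 0.1] means
  2Ns of several hundred to a few thousand and a sweep lasting a few
  percent of a coalescent unit. At desk daughter sizes (2N = 1000),
  keeping the raw range would give sweeps that last ~0.2 coalescent
  units — diversity regenerates *during* the sweep and the signature
  largely dissolves. The desk "strong-s regime" therefore draws
  s uniform(0.2, 0.4), giving 2Ns of 200-400 and sweep durations near
  0.05 coalescent units, the same dimensionless regime;
* recombination chosen to preserve the *sweep footprint to subwindow*
  ratio rather than the genome-average rho/theta: the expected footprint
  s / (r log 4Ns) spans about 4 subwindows, as it does at paper scale.
  Matching rho/theta instead would shrink footprints below one
  subwindow and make the desk problem unrepresentatively hard;
* a desk demographic model (`desk_model()`) with a founder bottleneck,
  a short colony phase, daughters about 0.1 coalescent units old and
  4Nm near 2 — window F~ST~ around 0.1-0.2, matching the more diverged
  crater-lake pairs; sweeps complete shortly before sampling under
  this clock.

What desk-scale success does *not* show: performance under weak
selection (s near 0.01), under the paper's much larger effective sizes,
or on real data with phasing error, unmodelled population structure or
reference bias. The desk profile demonstrates that the pipeline's
machinery — simulation, features, training, scan — is correct and
calibrated, not that the biological conclusions transfer.

## Summary statistics

Eleven statistics per subwindow, for populations A and B where
applicable: nucleotide diversity pi, Tajima's D, unnormalized Fay & Wu's
H (the normalized variant is behind a flag), Garud's H1, H12 and H2/H1,
the mean per-haplotype 1-HAF score, Hudson's F~ST~ as a ratio of
averages (never an average of ratios), D~XY~, G~min~ and SS-H12 — 18
feature rows in all. Conventions worth knowing:

* Undefined values (no segregating sites, no accessible bp) are `NaN`,
  never silent zeros.
* Haplotype-identity statistics (H1/H12/H2-H1, 1-HAF, G~min~, SS-H12)
  drop sites with more than 20% missing alleles and impute the rest to
  the population major allele for string construction only;
  frequency-based statistics always use observed counts.
* The 1-HAF window summary is the *mean* over haplotypes (sample-size
  comparable); some implementations sum.
* SS-H12 follows its published contract (positive = shared sweep,
  negative = divergent, near zero = neutral) via a documented surrogate:
  pooled-sample H12 signed +1 when the modal pooled haplotype class
  occurs in both populations at at least half its pooled frequency, -1
  otherwise. The simulation property suite validates the sign behaviour.
* Tie-breaks in haplotype-frequency ranking are lexicographic, for
  determinism.

## Feature matrices and normalization

A locus is summarized as an 18 x 21 matrix of statistics by subwindow,
each row divided by its sum across subwindows so only the spatial
profile remains. Rows containing negative values (the signed statistics)
are first shifted by their minimum — the behaviour of the diploS/HIC
feature vectors this design follows. Plain division would occasionally
divide by a near-zero signed sum and produce unbounded, sign-flipped
rows; the min-shift keeps every row a proper profile in [0, 1]. `NaN`
cells (masked-out subwindows) are imputed to the row mean and counted;
rows that are entirely undefined, or constant, fall back to uniform.
Windows needing more than 50% imputation are dropped before training.
Simulated loci are masked beforehand by a random locus-length slice of
the empirical accessibility mask (`mirror_mask()`), so simulated and
empirical features share the same missing-data geometry.

## The classifier

A small convolutional network over the 18 x 21 matrices, written in
base-R matrix operations: two 1-D convolutions along the subwindow axis
(kernel 3), a dense hidden layer with dropout, softmax over
{neutral, shared, divergent}; Adam, minibatches, early stopping on a
15% validation split with best-weights restoration, at most 100
epochs. Three networks are trained from different initialization seeds
and their posteriors averaged (a small deterministic ensemble; the
averaging recovers a few points of accuracy that any single
early-stopped member leaves behind). Inputs are standardized cell-wise on the training set (z-score,
clipped at 5 sigma) and the transform ships inside the serialized model,
which also carries the feature layout and class order and refuses
mismatched features. Because the selected site is drawn symmetrically
around the locus centre, every training matrix is also presented
reversed along the subwindow axis (flip augmentation).

Empirical prediction slides a 21-subwindow frame one subwindow at a
time and classifies the frame's central 5-kb window; frames whose
central subwindow has under 20% accessible sites are skipped. A window
is *asserted* to be under divergent selection only when its posterior
reaches 0.99, the support convention used for all headline fractions;
at that threshold the false-positive rate on fully neutral synthetic
genomes stays below 2%.

## Genome scans and the drift null

Windowed F~ST~ uses non-overlapping 10-kb windows and requires at least
2,000 valid (accessible, coverage-passing) sites; disqualified windows
are absent, not NaN. Loess smoothing (tricube weights, local linear
fit, span 0.01 at genome scale) is presentation-only and implemented
directly, cross-checked in the tests against `stats::loess`. The
unfolded 2D SFS downsamples each polarized site to 40 (or 30) alleles
per population without replacement, with the per-site random draw keyed
by (chromosome, position, population label, seed) so that swapping the
populations transposes the spectrum exactly. The drift-null experiment
simulates whole neutral genomes under the fitted model, recomputes
windowed F~ST~ with the empirical code path, and repeats the exercise
with past and present effective sizes exchanged between two models
(`ne_swap_experiment()`) to show which features of the F~ST~
distribution are attributable to drift alone.

## Numerical and design choices

* Coordinates are 0-based half-open everywhere inside the package;
  1-based only at the VCF boundary.
* Polarization requires at least 4 of 5 outgroup diploids fully called,
  outgroup monomorphism, and the outgroup allele present in the ingroup
  coding; failing sites stay unpolarized and are excluded from unfolded
  statistics.
* The coverage rule (>= 5x in >= 80% of individuals) is applied per
  population by default; whether to pool the panel is a config switch,
  since published descriptions leave the pooled case open.
* Watterson/Tajima constants use the panel haplotype count; per-site
  frequency terms use observed (non-missing) counts.
* Per-window pi is reported per accessible site (per-window totals are a
  config away); feature rows are scale-free after normalization either
  way.
* Training-set sizes, seeds and parameter draws are all derived from one
  master seed via a splitmix-style hash, so a training set is
  byte-identical across machines given (seed, config).

## Known limitations

* Small-population forward simulation is exact only up to O(1/N)
  discrete-generation effects; the calibration suite bounds these at
  well under the tolerances used.
* The synthetic outgroup is constructed (ancestral plus configurable
  noise), not simulated along a real outgroup branch; it exercises the
  polarization rule, not outgroup biology.
* The desk profile's standing-variation sweeps mostly collapse to
  single-copy starts (see above); soft-sweep-specific behaviour is only
  weakly probed at desk scale.
* No indels, no multi-allelic sites, no genotype error model; phasing is
  taken as given.
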