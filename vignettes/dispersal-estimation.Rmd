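---
title: "Estimating per-generation dispersal distance from georeferenced SNPs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating per-generation dispersal distance from georeferenced SNPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dispersr)
```

## The estimation problem

The mean per-generation dispersal distance sigma — defined here as the
root-mean-square displacement along one axis between a child and a randomly
chosen parent — controls how genetic variation is structured across space.
Under restricted dispersal, nearby individuals are more closely related than
distant ones (isolation by distance), and the strength of that decay carries
information about sigma. `dispersr` estimates sigma from two inputs that are
available even for non-model organisms: a matrix of unphased (or phased) SNP
genotypes and the geographic coordinates of the sampled individuals.

Two estimators are provided.

* **Rousset regression** (the classical baseline): the slope b of the least
  squares fit of the individual-pair differentiation statistic a-hat on
  ln(geographic distance) estimates the inverse of Wright's neighborhood size
  Nb = 4 pi D sigma^2, so with a known density D,
  sigma-hat = sqrt(1 / (4 pi D b)). When the fitted slope is non-positive the
  estimate is undefined and reported as such.
* **A pairwise convolutional network**: a feature extractor with weights
  shared across all n(n-1)/2 sample pairs summarizes each pair's stacked
  genotypes together with the pair's geographic distance; the per-pair
  features are stacked and a single linear unit maps them to sigma-hat. The
  network is trained on simulated data whose generating process mirrors the
  study system, which makes the method a simulation-based (likelihood-free)
  estimator.

## The pairwise network

Each pair contributes a block of 2 rows (4 when phased) by m SNPs, coded as
minor-allele counts and ordered by genomic position. The extractor applies
repeated blocks of convolution and average pooling: the convolution kernel
spans two adjacent SNPs across both members of the pair (stride 1, no
padding) and each pooling step averages ten positions (non-overlapping, with
the remainder truncated); these two constants are fixed in `model_spec()`.
The flattened convolution output is concatenated with the pair's Euclidean
distance (divided by `dist_scale`, by default the habitat or sample-cloud
width, so the distance feature is commensurate with the convolution output)
and passed through one fully connected layer of `pair_dense_units` rectified
linear units. The head stacks all pairs' feature vectors — in the canonical
lexicographic pair order, which fixes the otherwise arbitrary pair-row
ordering — and applies a single linear unit.

Hidden layers are rectified linear; the output is linear on the normalized
target scale. Targets are z-scores of log sigma over the training set
(predictions are back-transformed), which stabilizes the mean squared error
loss across the roughly 15-fold sigma range of the prior and guarantees
positive sigma estimates. Training uses Adam at learning rate 1e-4, mean
squared error loss, and early stopping on validation loss with the
best-validation checkpoint retained. The number of convolution blocks and
filter counts are configurable; the default (32 and 64 filters) reduces a
5,000-SNP input to a ~50-position per-pair map before the dense layer, while
the desk-scale study configuration (16 and 32 filters, 64 dense units)
matches the 200-SNP toy datasets.

Because the forward and backward passes are written in this package (R with
small compiled kernels for the convolution blocks), gradients are verified in
the test suite against central finite differences on toy models.

### Gradient gating (`k_extract`)

With n = 100 there are 4,950 pairs, and backpropagating through the shared
extractor for every pair dominates memory. `dispersr` implements the gating
strategy in which features are extracted from *all* pairs during the forward
pass — so the prediction is identical whatever the gating — but only a random
subset of `k_extract` pairs, resampled every batch, contributes gradients to
the extractor weights. The head's weights always receive gradients from all
pairs. The tests verify both halves of this contract: gating with the full
pair set reproduces ungated backpropagation, and gating never changes the
forward value.

## The spatial simulator

Training data come from a continuous-space individual-based forward model on
a square habitat of side W with non-overlapping generations. A single
interaction scale sigma_f governs three Gaussian kernels:

* **mate choice** — each mother samples a father with Gaussian weights
  truncated at 3 sigma_f (no candidate in range means no offspring that
  generation);
* **dispersal** — offspring are displaced from the mother by independent
  axial Gaussian draws with standard deviation sigma_f, reflected at the
  habitat boundary (displacements are recorded pre-reflection, which is what
  the kernel calibration test measures);
* **competition** — the expected number of offspring per mother follows a
  Beverton-Holt (discrete logistic) form
  lambda = 2 / (1 + D_local / K), where D_local is a truncated-Gaussian
  kernel density estimate, edge-corrected by the kernel mass inside the
  habitat. At D_local = K each mother expects one offspring, so the census
  fluctuates around K W^2.

The benchmark prior draws sigma_f uniformly on [0.2, 3]. The quantity the
estimators target is the effective sigma to a randomly chosen parent, which
absorbs both the mother-offspring and the mating kernel; displacement to the
mother has variance sigma_f^2 while displacement to the father adds the
mating kernel on top, giving a parent-averaged variance of
(3/2) sigma_f^2. `effective_sigma()` therefore multiplies sigma_f by
sqrt(3/2) by default; the factor is configurable because it is a convention
about the reported scale, not a fitted quantity.

Genomes are represented by their segregating sites (positions plus binary
haplotypes). Gametes recombine with Poisson(recomb_rate x genome_length)
crossovers at uniform base-pair positions and mutate at `mut_rate`. Initial
standing variation is seeded site-wise from the neutral site-frequency
spectrum (allele-frequency density proportional to 1/p, truncated to
[0.05, 0.95]) at linkage equilibrium — this matches a neutral coalescent
sample marginally per site while avoiding a coalescent-with-recombination
dependency; linkage and spatial structure then accumulate over the forward
generations.

### What the toy scale does and does not show

The desk-scale study conditions are a 15 x 15 habitat at carrying capacity
K = 5 (about 1,125 individuals), a 100 kb genome with recombination rate
1e-5 per bp (preserving the 1-Morgan total map length of the full-scale
benchmark genome of 1e8 bp at 1e-8), 20 generations of spatial reproduction,
and datasets of n = 10 individuals by m = 200 SNPs; 300 training simulations
are each sampled 10 times (3,000 training datasets) and 50 held-out
simulations form the test set. Twenty generations is a deliberate compromise:
the spatial correlation scale of relatedness grows like sigma_f sqrt(t), so
at the smallest sigma_f the structure is strongly local while at the largest
it approaches panmixia on this habitat — the contrast the estimators exploit
— but full isolation-by-distance *equilibrium* (which requires times of order
(W / sigma)^2 generations) is not reached. (Running the toy model longer does
not strengthen the signal: drift erodes the seeded variation about as fast as
spatial structure accumulates, so 20 generations is kept.)

Consequently absolute error levels here are not comparable to full-scale
results; what the toy study demonstrates is that the whole pipeline learns —
the network's held-out MRAE is well below both the no-information prior-mean
predictor and the Rousset baseline — not that it attains any particular
published accuracy. A sample of n = 10 individuals carries limited
information about sigma at any scale (the classical regression is near-random
at n = 10 even in full-scale studies), and at desk scale even an oracle
regression on hand-engineered summary statistics (sample homozygosity, mean
pairwise differentiation, the differentiation-on-log-distance slope) leaves
most of the natural-scale variance unexplained, with estimates compressed at
the top of the prior where the habitat no longer constrains dispersal. The
network's squared correlation with the truth should therefore be read as
moderate by construction of the toy conditions, while the relative-error
comparisons between methods are the informative surface. Equally, the
simulator omits demographic perturbations and habitat heterogeneity by
design, so passing tests say nothing about robustness to such
misspecification on real data.

## Rousset baseline conventions

The individual-pair statistic is the identity-probability analogue of
FST/(1 - FST): with per-individual minor-allele dose p_i at a locus, the
between-individual gene identity is Q_b = p_i p_j + (1 - p_i)(1 - p_j) and
the within-individual identity is 1 for homozygotes, 0 for heterozygotes;
a-hat(i, j) = (Q_w - Q_b(i, j)) / (1 - Q_w) with both quantities averaged
over loci (and Q_w also over individuals). Pairs at identical locations are
excluded from the ln-distance regression (ln 0 is undefined) and counted.
The density supplied to `sigma_from_slope()` is the true simulated density
in benchmark runs — the baseline's best case — and user-supplied for
empirical data.

## Numerical and design choices

* **Input centering.** Genotype codes are centered before entering the
  network (0/1/2 becomes -1/0/1; phased 0/1 becomes -0.5/0.5): zero-mean
  inputs condition the rectified-linear stack much better than raw counts,
  and the centered code doubles as a homozygosity indicator (|x| = 1 exactly
  for homozygotes).
* **Grouped validation.** The early-stopping validation split is made by
  simulation, not by dataset: sample draws from one simulation share the true
  sigma, and letting them straddle the split would leak simulation identity
  into checkpoint selection.
* **Batch size.** Within a fixed epoch budget, smaller batches buy more Adam
  steps at the fixed 1e-4 learning rate; the desk-scale study uses batches of
  8 datasets.
* **Minor-allele ties.** A site with minor-allele frequency exactly 0.5 codes
  the REF (index-smaller) allele as minor, making the coding deterministic.
* **SNP subsetting.** When more usable sites exist than requested, sites are
  taken evenly spaced by rank along the genome (deterministic, uniform
  linkage coverage), never at random.
* **Missing genotypes** are rejected, not imputed.
* **Projection.** Latitude/longitude are projected by a centroid-centered
  equirectangular projection on a 6371-km sphere; adequate at regional scale,
  and tested to preserve distance ratios within 1% for clusters under two
  degrees.
* **Sampling-scheme matching.** Empirical localities are matched greedily to
  the nearest unchosen simulated individual after aligning the two point
  clouds by centroid translation and widest-axis width matching; width
  matching is the minimal alignment given that no canonical mapping exists
  between empirical and simulated coordinates.
* **Seeding.** One master seed fans out to per-stage seeds through a fixed
  string hash (`simulate`, `train`, `sampling`, ...), so every pipeline stage
  is independently reproducible and all derived seeds stay within 32-bit
  range.
* **Extinction** during a simulation raises a typed condition; the driver
  retries with a derived seed a bounded number of times.
* **Degenerate inputs.** Zero pair distances are legal network inputs (the
  distance feature is simply 0); monomorphic sites are excluded at coding
  time, so convolution inputs are never all-constant by construction.

## Known limitations

* The desk-scale simulator is not a drop-in replacement for a full-scale
  forward-simulation study (as run with simulators such as SLiM): population
  sizes, genome lengths and run times are orders of magnitude smaller, and
  several life-cycle details (mate-search truncation, edge reflection,
  Beverton-Holt regulation) are this package's own choices among the options
  such models leave open.
* The network estimates sigma in the map units of its training simulations;
  interpreting empirical predictions requires the training habitat to be
  scaled to the empirical sampling area (the preprocessing tools rescale
  coordinates by cloud width for this reason).
* No uncertainty quantification is attached to sigma-hat; the benchmark
  reports population-level error metrics instead.
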