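---
title: "Models and methods behind minihic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind minihic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minihic)
```

`minihic` analyses the spatial organisation of small circular bacterial
chromosomes from Hi-C contact data: matrix construction and balancing,
restraint-based 3D model ensembles, chromosome interaction domain (CID)
detection, border feature statistics, and domain-level co-expression. This
vignette is the package's own account of the underlying models, the
tunable parameters, and the design choices made where the design was
genuinely open.

## The data model

A genome of length $G$ bp is divided into $n = \lceil G/w \rceil$ bins of
width $w$; the final partial bin is kept, so an 816,394 bp genome at 10 kb
has 82 bins and at 3 kb has 273 bins. Because the chromosome is circular,
genomic distance between bins is $d(i,j) = \min(|i-j|,\, n - |i-j|)$; the
wrap-around contacts between the two chromosomal arms form the secondary
anti-diagonal familiar from circular-genome Hi-C maps. Bin indices are
1-based in all R interfaces, while bp coordinates follow the BED
convention (0-based, half-open).

## Matrix construction and balancing

Read pairs are classified on the restriction digest before binning:
same-fragment pairs with outward or co-directional orientation are
self-ligation circles, same- or adjacent-fragment pairs with inward
orientation are dangling/re-ligation products, everything else is a valid
product. Only valid pairs are pooled into `contact_matrix` bins (counts
are conserved exactly).

Balancing uses iterative correction (ICE): the update
$m_{ij} \leftarrow m_{ij}\,T/(r_i\,r_j)$ (with $T$ the matrix total and
$r_i$ the bin totals) is applied to the whole matrix and repeated until
the maximum relative deviation of the bin totals is below $10^{-5}$. Bins
with zero total cannot be balanced and are auto-blacklisted with a
warning. After convergence the matrix is rescaled to mean 1 over usable
entries; the rescale does not affect the balance and makes magnitudes
comparable across libraries. An unfixed control library can additionally
zero cells (distance $\ge 2$) among a user-supplied list of affected bins
when the control signal there exceeds a high quantile (default 0.99) of
the control's off-diagonal values — the threshold is explicit
configuration because only the off-diagonal rule and the bin list are
standard.

The matrix modelling potential (MMP) score summarises how suitable a
balanced matrix is for 3D reconstruction. It combines matrix size, the
spectral weight of eigenvalues exceeding those of entry-shuffled matrices,
and the skewness/kurtosis of the z-scores of log-transformed entries,
through a logistic link with documented default weights. Shuffling
preserves the entry distribution and the size, so paired
structured-versus-shuffled comparisons isolate the eigenvector structure;
the weights are calibratable configuration, not a fitted model.

## Restraint-based 3D modelling

Each bin becomes a particle of radius $w \cdot s / 2$, with occupancy
scale $s = 0.0201$ nm/bp by default (100.5 nm at 10 kb). Contact
frequencies are z-scored on $\log_{10}$ of the positive entries.
Restraints:

* consecutive particles (circularly): harmonic restraint at the sum of
  their radii;
* pairs with $z$ above the upper cutoff (default $-0.2$): harmonic
  attraction whose equilibrium distance interpolates linearly in $z$
  between the proximal distance `maxdist` (250 nm, at the cutoff) and the
  sum of radii (at the maximum z-score) — monotone and bounded;
* pairs below the lower cutoff (default $-0.6$), including zero-contact
  pairs: one-sided lower-bound restraint at `maxdist`;
* pairs between the cutoffs: unrestrained.

All force constants default to 1 in consistent units. Models start from
uniform random positions in a ball and are relaxed by single-particle
Gaussian Metropolis moves under geometric cooling
($T_0 = 10^4$, factor 0.85, 40 temperatures, 5 sweeps each, move size
100 nm shrinking with $\sqrt{T/T_0}$), followed by 150 zero-temperature
quench sweeps. The schedule constants were set on closed-form checks (a
single attraction reaches its equilibrium distance within 1%; an
adjacency-only chain reaches the sums of radii) and a small recovery run,
and then left fixed. Each model derives its random stream from the master
seed plus the model index, so ensembles are bit-reproducible and
individual models are independent.

The `n_keep` lowest-penalty models (ties broken by model index) form the
reported ensemble. Pairwise model dissimilarity is coordinate RMSD after
optimal superposition **without reflection**, so mirror-image folds — which
contact data cannot distinguish — separate into distinct clusters;
`allow_reflection = TRUE` merges them. Average-linkage trees are cut at
the mean pairwise RMSD by default (a fixed `k` is available), and each
cluster's centroid is the member closest to the cluster mean.

Ensemble geometry per model: length is the largest inter-particle
distance, width twice the radius of gyration, and volume that of the
prolate ellipsoid with those axes, $\tfrac{4}{3}\pi (L/2)(W/2)^2$.
Medians are taken per quantity across models, so the median volume is not
the ellipsoid volume of the median length and width; this per-model-first
order is deliberate and should not be "corrected". The model contact map
records the fraction of models with particles closer than a cutoff
(default `maxdist`); its correlation with the input is computed against
$\log_{10}$ of the positive input entries because the restraints live in
log-frequency space and raw Pearson against a heavy-tailed power-law
matrix is dominated by a few near-diagonal cells.

## Domain detection

CIDs are detected on a binned map (3 kb by default) after a single ICE
iteration — enough to remove first-order visibility bias without iterating
the strong distance decay away. Counts within a band of the diagonal
(default 20 bins; the informative signal is near-diagonal) are modelled as
Poisson with expectation $\lambda_k\, A d^{b}$, where $A d^b$ is the
global power-law distance decay and $\lambda_k$ a per-domain intensity
multiplier; cells crossing a border keep $\lambda = 1$. Dynamic
programming returns the exact optimum of the penalised likelihood with a
BIC penalty `bic_multiplier * log(n_cells)` per domain (domains are at
least 3 bins, admitting 9 kb domains). The origin bin is treated as a
border, since coordinates on the circular genome start at the replication
origin.

One numerical choice matters: fitting $A d^b$ over *all* distances lets
the within-domain enrichment leak into the expectation (at small $d$ most
cells lie inside domains), which can absorb the entire domain signal. The
default `decay_fit = "beyond_band"` therefore fits the power law on
distances larger than the band — where no domain-scale structure lives —
and extrapolates inward; `"all"` remains available for maps without block
structure. Segmentation is invariant to positive rescaling of the matrix,
and increasing `bic_multiplier` can only remove borders.

Border confidence on the 1–10 scale is the number of penalty levels (10
geometrically spaced multipliers, up to 10 times the configured value) at
which the border persists in the optimal segmentation — a robustness
score, since sharper borders survive stronger penalties. Domain density is
the ratio of observed to expected within-domain counts, the expectation
being the genome-wide per-distance average, so the whole genome as one
domain has density exactly 1. Border alignment across replicates groups
borders within a tolerance (default 1 bin, circularly) and scores the
fraction matched in at least half of the segmentations; its null
randomises border positions keeping their number.

## Border features and permutation tests

Each border contributes two bins (last of the preceding domain, first of
the following one); a segmentation with 44 domains on a circular genome
has 88 border bins. The permutation null applies **one uniform random
circular rotation to the entire border set**, which preserves the number
and sizes of domains exactly — the minimal null consistent with
"shifted while conserving size and number". Empirical p-values are the
plain ratio of null values at least as extreme as the observed (no $+1$
correction; a `plus_one` estimator and an exhaustive enumeration over all
offsets are options). The border statistic is the mean over border bins by
default, with a sum mode, because the two are equivalent under the
rotation null up to a constant. Under track-independent nulls the p-value
distribution is approximately uniform, which the test suite checks by a
Kolmogorov–Smirnov sanity test at 200 simulated datasets.

## Co-expression

The tendency statistic counts, for each gene pair, sample pairs moving in
the same versus opposite directions, normalised by all sample pairs; ties
count to neither side but stay in the denominator, which keeps values in
$[-1,1]$ and penalises flat profiles. It equals exhaustive pair
enumeration exactly (a compiled implementation makes the $O(g^2 m^2)$
count practical) and is insensitive to large shifts in a few conditions,
unlike Pearson correlation, which is also provided. The statistic runs
over sample columns as given (e.g. 282 samples for 141 duplicated
conditions); an option averages replicates per condition first.

Genes are assigned to domains by their midpoint bin. Within- versus
between-domain comparisons report mean absolute co-expression with both
rank-sum and Welch t-tests. The border test uses gene pairs *spanning* a
border (one gene in each of the border's two bins) by default; pooling
all genes found anywhere in border bins is available but dilutes the
border signal with distant pairs. Distance-stratified curves bucket pairs
by circular genomic distance up to 30 kb and contrast same- versus
cross-domain pairs below 12 kb.

## The synthetic generator

The generator emulates the study system so that every stage is testable
without sequencing data: a circular ~816 kb genome, bins of 3–20 kb, genes
tiling both strands in runs (creating convergent and divergent junctions),
a smooth GC track around 0.40 and a restriction-site count track (default
rate 1/450 bp, configurable since published cutting-frequency figures for
4-cutters are not fully consistent). Contact counts are Poisson with
expectation $A\,d^{b}$ ($b = -1$ by default), multiplied by a
within-domain boost and by $1 + \epsilon$ on the anti-diagonal
($\epsilon = 0.3$, emulating the weaker second diagonal). Ground-truth 3D
structures are closed chains on an elongated ellipse (axis ratio 2) with
consecutive spacing equal to the sum of particle radii and the first and
opposite particles at the poles; maps derived from structures use contact
probability proportional to spatial distance$^{-2}$ (with $-3$ the
dynamic range leaves too few graded contacts above the upper cutoff for
stable recovery). Expression matrices share a per-condition latent factor
within each planted domain with loading $\sqrt{\rho}$, giving pairwise
within-domain correlation $\rho$, independent genes across domains, and
replicate samples sharing the condition factor.

What the generator does *not* emulate: restriction-site positions in real
sequence, copy-number and mappability artefacts beyond a supplied
blacklist, transcription-coupled contact structure, and non-Poisson
overdispersion. Passing recovery tests therefore demonstrates correctness
of the algorithms under the stated generative model, not performance on
any particular real library.

## Problem sizes and reproducibility

The test-suite and acceptance runs use the study-scale problem sizes the
methods target: 273-bin (3 kb) maps with borders every 15 kb at
depth 50 and boost 3 for segmentation recovery; an 82-particle structure
with 500 annealed models (best 250 kept) for structure recovery; 200
simulated datasets with 199 rotations each for permutation calibration;
and 300 genes over 141 duplicated conditions for co-expression coupling.
All stochastic steps derive from explicit seeds, and generators are
bit-reproducible given a seed.

A reproduction driver (`reproduce_cid_analysis()`,
`reproduce_model_analysis()`) runs the complete workflow on externally
supplied dense matrices, e.g. deposited raw 3 kb replicate matrices of a
real experiment, with the BIC multiplier exposed because the exact penalty
constant of the original segmentation implementation is not published.

## Known limitations

* The annealing objective is a sum of harmonic restraint penalties — no
  excluded volume or polymer physics beyond the restraints; ensembles are
  restraint-satisfaction ensembles, not thermodynamic ones.
* The MMP combination weights are heuristics on documented components; the
  score is comparative (same matrix family, different resolutions), not an
  absolute accuracy predictor.
* The segmentation is flat (no nesting) and assumes a single global decay
  exponent.
* The rotational-volume formula models radius changes as cylinder plus
  completing cone rather than a true frustum, matching the stated
  cylinder-plus-cone decomposition of the imaging protocol it mirrors.
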