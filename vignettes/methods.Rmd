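---
title: "Methods: local biclustering and variance partitioning for proteome-stoichiometry experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: local biclustering and variance partitioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stoichprot)
```

# The scientific setting

Marine picocyanobacteria such as *Synechococcus* adjust their elemental
composition (C:N:P) in response to nutrient supply and temperature, and the
biochemical traits behind that adjustment are visible in the proteome.
`stoichprot` implements the computational chain for a factorial chemostat
experiment: two nutrient regimes (N-stress, molar N:P input 1.7; P-stress,
N:P input 80) crossed with three temperatures (20, 24, 28 °C), five
replicate samplings each (30 samples). Three data streams meet here:

1. a DIA-MS protein-by-sample peak-area table,
2. a per-sample elemental table (particulate C/N/P, cell density, forward
   scatter), and
3. a protein-to-trait-group map (ribosomal, P-acquisition, heat shock, ...).

The package filters and normalizes the proteome, computes allocation
metrics (percent of total peak area, `%` of `PA_Total`), clusters proteins
by response pattern with a nonparametric Bayesian local biclustering model,
and partitions the variance of quotas, ratios and the whole proteome
between the two environmental factors.

# Proteome filtering, normalization and allocation

Proteins are retained when quantified by at least two representative
peptides and missing in at most two of the 30 samples; both filters report
the fraction of summed peak area they remove. Per-sample totals are then
equalized to the grand-mean total (total-sum normalization). The exact
cross-sample normalization used by commercial DIA software is generally not
published; total-sum is the transparent default here, it preserves
within-sample proportions, and every allocation metric downstream is
invariant to any positive per-sample rescaling applied beforehand.

Allocation of a protein set is its summed peak area over the summed peak
area of *all retained* proteins in that sample, times 100. Missing cells
count as zero in both sums — peak areas are summed without imputation, so
totals match what the instrument reported. The denominator is always the
retained set; if you need the allocation against a larger identification
universe, pass that table unfiltered.

`log_prop_diff()` expresses each sample as a proportional deviation from a
protein's mean log peak area. Natural log is used throughout; because the
same base appears in numerator and denominator the choice only rescales
the degenerate case of a row whose mean log abundance is near zero.

# The local biclustering model

Let `y[g, s]` be the standardized log abundance of protein `g` in sample
`s` (per-protein log, center, scale — the model clusters proteins by
*response pattern*, not by mean abundance). The generative structure is:

* Protein `g` is **invariant** with probability `1 − pi0` (its whole row
  follows the baseline `Normal(m0, baseline_sd²)`), otherwise it joins a
  bicluster by a Pólya urn with concentration `alpha_protein` (a
  zero-enriched Dirichlet-process partition).
* Each bicluster `k` carries its own **local partition of the samples**:
  each sample is inactive in `k` with probability `1 − pi0_sample`
  (baseline), otherwise it joins a subcluster by an urn with concentration
  `alpha_sample`.
* Within bicluster `k`, the values of protein `g` in subcluster `j` share a
  Normal likelihood whose mean and variance are integrated out under a
  conjugate Normal–Inverse-Gamma base `NIG(m0, k0, a0, b0)` — each
  (protein, subcluster) block has its own parameters, so proteins in a
  bicluster agree on *which samples behave alike*, not on the block means
  themselves.

The conjugacy is the load-bearing choice: block marginal likelihoods are
available in closed form (Student-t predictives), which makes the collapsed
Gibbs sampler exact and — crucially for testing — makes the full posterior
enumerable on tiny instances, so the sampler can be validated against brute
force rather than against itself.

Defaults: `pi0 = 0.01` (variation is the exception: most biological
processes involve a small subset of proteins), `pi0_sample = 0.5` (no
prior pull either way on a sample's participation), `alpha = 1` for both
urns, `m0 = 0, k0 = 0.1, a0 = 1, b0 = 1`, and baseline SD 1 — all matched
to the unit scale of standardized rows, all configurable. On planted data
where a large fraction of proteins is variant by construction, `pi0 = 0.5`
is the matching prior and is what the recovery experiments use.

## Sampling

One sweep updates every sample label within every bicluster, then every
protein membership. Protein updates use the zero-enriched urn weights
(invariant / existing bicluster / new bicluster); a new bicluster is
proposed together with one auxiliary sample partition drawn from the prior,
which leaves the exact posterior invariant (an auxiliary-variable update in
the style of Neal's algorithm 8). The default run length is 35 000 sweeps
with 5 000 burn-in.

Two mixing facts shaped the implementation. First, building a sample
subcluster one member at a time must pass through a singleton block, whose
diffuse Student-t predictive scores below the unit-Normal baseline for any
value within about one baseline SD of zero — so a sampler started from
uninformative sample partitions settles into sparse-activation modes even
when a fully partitioned representation has far higher posterior mass.
Second, if one bicluster's sample partition refines another's, the coarser
bicluster's proteins fit the finer partition and the urn's rich-get-richer
term merges them. The remedies are initialization-side and do not alter the
target distribution: sample partitions are updated *before* protein
memberships in each sweep, and the hierarchical initialization below also
initializes each bicluster's local sample partition.

## Initialization

The membership vector is initialized from average-linkage hierarchical
clustering (Euclidean distance on standardized rows), cut by default at
half the median pairwise distance; clusters of size one are declared
invariant. The height cut (rather than a fixed number of groups) matters:
with a fixed `k`, the noise floor — whose merge heights all sit close to
the median — absorbs most of the budget of groups before genuinely distinct
pattern clusters separate. Each initial bicluster's sample partition is
initialized by average-linkage clustering of the samples restricted to that
bicluster's proteins, with the number of subclusters chosen by the
Calinski–Harabasz index.

## Point estimate and uncertainty

The reported partition is the sampled partition minimizing the summed L1
distance `H` to all posterior samples, where `H` counts protein pairs on
which two partitions disagree about co-membership (the indicator is
literal: two invariant proteins count as co-clustered). The search is
restricted to visited partitions — what a finite trace supports — with ties
broken by the earliest minimizer. As an uncertainty diagnostic the package
reports every trace sample's distance to the selection, scaled by the
number of protein pairs `G(G−1)/2` so it is comparable across matrix sizes;
a concentrated posterior shows this distribution piled up near zero.

# Variance partitioning

Quotas are `Q_X = concentration × 10⁹ / cell density` (fmol per cell),
optionally normalized to the forward-scatter size proxy; ratios are molar
quotients per sample. Two-way ANOVA (sequential sums of squares on the
balanced design, via `stats::aov`) partitions each response into nutrient,
temperature, and an "other" pool defined as interaction plus residual —
the three-way split used when comparing the relative influence of the two
factors across many responses. PERMANOVA on the proteome delegates to
`vegan::adonis2` (sequential terms, nutrient entered first — immaterial on
a balanced design) with a seeded permutation stream. On the Euclidean
distance of a single centered variable the PERMANOVA R² values equal the
ANOVA fractions exactly, which the tests exploit as a consistency check.
Pairwise treatment comparisons use Welch's t-test with Benjamini–Hochberg
adjustment; the base test is a package choice, as figure-level reporting
conventions usually name only the correction.

# The synthetic-data generator

The generator defines the study conditions every test runs under.

**Proteome.** Log peak areas are Normal around planted block means
(log-normal abundances; peak areas are positive and span decades). The
planted biclusters follow four response archetypes tied to the design:
split by nutrient regime; split by temperature; split by regime with the
24 °C samples inactive; split by temperature under P-stress only with
N-stress samples inactive. The archetypes are deliberately pairwise
non-nested: if one archetype's partition refined another's, proteins
following the coarser pattern would fit the finer bicluster equally well
and the two planted clusters would not be identifiable by *any* method —
a property of the model, not of a particular sampler. Block means for a
`J`-subcluster archetype sit at `separation × (j − (J+1)/2)` in log units;
`separation = 2` (about a 7-fold span) is strong but realistic for
stress-responsive proteins, and the default within-block `noise_sd = 0.25`
corresponds to ~25% replicate CV. Defaults are `G = 200` proteins with
`K = 4` planted biclusters of 15 for fast tests; a `G = 1146` full-scale
mode mirrors the size of a deposited 30-sample dataset.

At a 2-unit separation, recovery (adjusted Rand index of the selected
partition against truth) exceeds 0.9 for every tested seed at the default
noise and degrades monotonically through `noise_sd = 0.5` and `1`. At
`noise_sd = 1` the standardized signal amplitude falls inside the baseline
bulk and the posterior itself prefers merged or sparse-activation
representations — low ARI there reflects the model's resolution limit, not
sampler failure.

**Elemental table.** Quotas, forward scatter and cell density are drawn
with additive factor effects on the log scale. The planted contrasts mirror
the treatment responses expected for this organism: a 3-fold higher P quota
under N- than P-stress, a ~12% C:N surplus under N-stress, cells largest at
28 °C and smallest at the 24 °C element-use optimum, C:P and N:P more than
doubling from N- to P-stress. The noise structure follows the measurement
chain: C and N come from the same filter and analyzer (3% element-specific
CV each, so C:N is precise), P from a separate assay (10%), plus a 5%
shared per-sample biomass factor that cancels in ratios. Under these
defaults the two-way ANOVA assigns ≈93%/95%/61% of C:P/N:P/C:N variance to
the nutrient factor and ≈2%/≈1%/≈14% to temperature, the regime a
well-replicated chemostat experiment of this design produces. Particulate
concentrations are back-computed from the drawn quotas and cell densities,
so the quota computation is exercised as a genuine inverse.

**What the generator does not emulate:** peptide-level spectra and
ionization efficiency, chromatographic drift, compositional coupling
between trait groups, chemostat transients, or structured (non-random)
missingness. Passing tests demonstrate correctness of the algorithms under
the planted model, not performance guarantees on any particular real
dataset — in real data the normalization totals, for instance, are
dominated by the stable majority of the proteome, which is why the default
planted configuration also keeps most proteins invariant.

# Numerical choices and degenerate inputs

* Block marginal likelihoods are computed from sufficient statistics with
  the within-block sum of squares floored at zero against cancellation;
  the empty block returns log-likelihood 0.
* Missing cells are skipped in every block likelihood (ignorable
  missingness — defensible because the missingness filter caps them at two
  per protein) and count as zero in peak-area sums.
* Rows with zero variance standardize to all-zero rather than dividing by
  zero; constant responses are rejected by the ANOVA with an explicit
  error, as is a sample with non-positive total peak area.
* All randomness flows through R's RNG (the C++ sampler uses R's uniform
  stream), so a single seed reproduces a run bit-for-bit; pipeline stage
  seeds derive deterministically from one global seed.
* Full-scale traces can be thinned (`thin = 10` keeps memory modest at
  `G = 1146`); the least-squares selection uses the pair-counts identity to
  cost each candidate in `O(G²)` instead of `O(T·G²)`.

# Problem sizes used by the tests

The enumeration-oracle comparisons run at 3–4 proteins × 2–3 samples with
30 000 sweeps, where the zero-enriched posterior is exhaustively
enumerable. Recovery experiments run at `G = 60`, `S = 30`, `K = 3` over
ten seeds and a three-point noise grid (300 sweeps each; the hierarchical
initialization puts the chain inside the dominant mode, which short chains
then confirm). The end-to-end pipeline check runs the full 35 000-sweep
default on the `G = 200` synthetic proteome. These sizes were chosen so the
whole suite exercises every code path, including the full run length, in
about a minute and a half of CPU time.

# Known limitations

* The sampler has no split–merge moves; escaping a merged mode at large
  `G` relies on the initialization. Partially-active archetypes with small
  protein sets can be absorbed into the invariant pool under `pi0 = 0.01`.
* Exact reproduction of results obtained with other NoB-LoC
  implementations additionally depends on their (often unpublished)
  likelihood hyperparameters, input transformation, and tie-breaking; the
  bicluster/invariant counts of a given deposited analysis should be
  treated as an approximate target.
* PERMANOVA p-values use free permutation of sample rows; restricted
  permutation schemes are not implemented.
* The elemental simulator draws independent samples; it does not model the
  day-to-day autocorrelation of repeated chemostat samplings.
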