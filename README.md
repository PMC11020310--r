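# stoichprot

Linking proteome allocation to elemental stoichiometry in factorial
chemostat experiments.

Marine *Synechococcus* adjusts its cellular C:N:P in response to nutrient
supply and temperature, and the adjustment is carried by protein-level
traits: nutrient-acquisition proteins, ribosomes, heat-shock chaperones,
photosynthetic machinery. `stoichprot` implements the analysis chain for a
2 nutrient-regime × 3 temperature × 5 replicate design (30 samples):

* **Proteome allocation** — peptide-count and missingness filtering of
  DIA-MS peak-area tables, total-sum normalization, and the allocation
  metric `%PA_Total = PA(protein set) / PA(all retained proteins) × 100`
  for proteins and trait groups.
* **Nonparametric Bayesian local biclustering** — a zero-enriched Pólya urn
  model in which a protein is invariant with probability `1 − π₀` or joins
  a bicluster of proteins sharing a *local partition of the samples*
  (samples may be inactive, or grouped into subclusters with block-wise
  Normal likelihoods under a conjugate Normal–Inverse-Gamma base).
  Inference is by collapsed Gibbs sampling in C++; the point estimate is
  the sampled partition ω minimizing the summed pairwise-disagreement
  distance `H(ω, ω′) = Σ_{g≤g′} |I(ω_g = ω_{g′}) − I(ω′_g = ω′_{g′})|`
  over the trace.
* **Variance partitioning** — two-way ANOVA of cell quotas
  (`Q_X = concentration × 10⁹ / cell density`, fmol/cell), molar ratios
  (C:P, N:P, C:N) and size-normalized quotas into nutrient, temperature,
  and other (interaction + residual); two-way PERMANOVA of the whole
  proteome via `vegan::adonis2`; Welch pairwise comparisons with
  Benjamini–Hochberg adjustment.
* **A synthetic-data generator** that plants known bicluster structure and
  factor effects, so every stage is testable against ground truth.

## Worked example

Simulate a 100-protein proteome with three planted biclusters, filter,
normalize, cluster, and partition the variance of the elemental ratios:

```r
library(stoichprot)
design <- make_design()                      # 2 regimes x 3 temperatures x 5
str    <- planted_structure(design, G = 100, K = 3, proteins_per_bicluster = 10)
sim    <- simulate_proteome(design, G = 100, structure = str, seed = 1)

mn <- normalize_samples(filter_by_missingness(filter_by_peptide_count(sim$matrix)))
trace <- run_mcmc(mn, prior_settings(pi0 = 0.5), n_iter = 300, burn_in = 100, seed = 1)
part  <- least_squares_partition(trace)
summarize_partition(part$omega, part$sample_partition)
#> $n_biclusters
#> [1] 3
#> $n_invariant
#> [1] 70
#> $sizes
#> [1] 10 10 10
#> $n_subclusters
#> [1] 2 3 2
adjusted_rand_index(part$omega, sim$truth$protein_membership)
#> [1] 1
mean(part$scaled_distance)
#> [1] 0.0135
```

All three planted biclusters are recovered exactly (ARI 1): one splits the
samples by nutrient regime (2 subclusters), one by temperature (3), one by
regime with the mid-temperature samples inactive. The scaled posterior
distance piled up near zero (mean 0.014) says the posterior concentrates
on that partition.

```r
elem <- element_ratios(cell_quotas(simulate_elemental(design, seed = 1)))
two_way_anova(elem$C_P, elem$nutrient_regime, elem$temperature)
#> Variance partition (fraction of total SS):
#>      A      B  other
#> 0.9238 0.0465 0.0296
```

Nutrient supply explains 92% of the C:P variance, temperature under 5% —
the hierarchy the generator plants (a 3-fold P-quota contrast between
regimes against small thermal effects).

The full pipeline (simulate → filter → allocate → bicluster → stats, with
a JSON manifest of every output file and its hash) is one call:

```r
man <- run_pipeline(pipeline_config(seed = 1, out_dir = "run1"))
make_report(man)
```

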