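#' Planted bicluster structure for synthetic proteomes
#'
#' Describes the ground truth used by [simulate_proteome()]: which proteins
#' belong to which bicluster (0 = invariant), how each bicluster locally
#' partitions the samples into subclusters (0 = inactive sample), and the
#' log-scale block means. By default the sample partitions follow the
#' factorial design: one bicluster splits samples by nutrient regime, one by
#' temperature, one by the full regime x temperature interaction, and one
#' splits by regime with the mid-temperature samples inactive — the response
#' archetypes expected in a nutrient/temperature stress experiment.
#'
#' @param design Sample design from [make_design()].
#' @param G Total number of proteins (structured + invariant).
#' @param K Number of planted biclusters (at most 4 distinct archetypes;
#'   patterns recycle beyond that).
#' @param proteins_per_bicluster Proteins planted in each bicluster.
#' @param separation Distance between adjacent subcluster block means, in
#'   absolute log units (a 2-unit separation is strong but realistic for
#'   stress-responsive proteins; see the methods vignette).
#' @param noise_sd Within-block standard deviation on the log scale.
#' @param baseline_mean,baseline_sd Log-scale mean and SD of invariant
#'   proteins and inactive samples.
#' @return An object of class `planted_structure` with fields
#'   `protein_membership` (length `G`, values 0..K), `sample_partitions`
#'   (K x S integer matrix, values 0..J_k), `block_means` (list of per-
#'   subcluster means per bicluster), `noise_sd`, `baseline_mean`,
#'   `baseline_sd`.
#' @export
planted_structure <- function(design = make_design(), G = 200, K = 4,
                              proteins_per_bicluster = 15,
                              separation = 2, noise_sd = 0.25,
                              baseline_mean = 0, baseline_sd = 1) {
  stopifnot(K >= 1, proteins_per_bicluster >= 2, noise_sd >= 0,
            G >= K * proteins_per_bicluster)
  S <- nrow(design)
  regime <- as.integer(design$nutrient_regime)
  temp <- as.integer(design$temperature)
  # archetypes are chosen pairwise non-nested: no partition refines another,
  # otherwise proteins following the coarser pattern also fit the finer
  # bicluster and the two planted clusters are not identifiable
  archetypes <- list(
    regime,                                   # nutrient response
    temp,                                     # temperature response
    ifelse(temp == 2L, 0L, regime),           # nutrient response, T_opt inactive
    ifelse(regime == 2L, temp, 0L)            # temperature response under P only
  )
  sp <- t(vapply(seq_len(K), function(k) {
    lab <- archetypes[[(k - 1L) %% length(archetypes) + 1L]]
    # relabel active subclusters contiguously 1..J_k
    act <- lab != 0L
    lab[act] <- as.integer(factor(lab[act]))
    as.integer(lab)
  }, integer(S)))
  block_means <- lapply(seq_len(K), function(k) {
    J <- max(sp[k, ])
    baseline_mean + separation * (seq_len(J) - (J + 1) / 2)
  })
  membership <- integer(G)
  membership[seq_len(K * proteins_per_bicluster)] <-
    rep(seq_len(K), each = proteins_per_bicluster)
  structure(list(protein_membership = membership,
                 sample_partitions = sp,
                 block_means = block_means,
                 noise_sd = noise_sd,
                 baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd),
            class = "planted_structure")
}

#' Simulate a proteome peak-area matrix with planted bicluster structure
#'
#' Log peak areas are drawn Normal(block mean, noise_sd^2) for protein g in
#' bicluster k and sample s in subcluster j of k; invariant proteins and
#' inactive samples are drawn Normal(baseline_mean, baseline_sd^2). Values
#' are exponentiated to positive peak areas (log-normal abundances).
#'
#' @param design Sample design from [make_design()].
#' @param G Number of proteins; must cover the planted structure.
#' @param structure A [planted_structure()].
#' @param seed Integer RNG seed; identical seeds give identical matrices.
#' @param missing_rate Fraction of cells set missing uniformly at random
#'   (default 0), to exercise the missingness filter.
#' @return List with `matrix` (a [pa_matrix]) and `truth` (the structure,
#'   unchanged, with the membership trimmed/padded to length `G`).
#' @export
simulate_proteome <- function(design, G, structure, seed,
                              missing_rate = 0) {
  stopifnot(inherits(structure, "planted_structure"),
            structure$noise_sd >= 0, structure$baseline_sd >= 0,
            missing_rate >= 0, missing_rate < 1)
  omega <- structure$protein_membership
  if (G < length(omega) && any(omega[-seq_len(G)] != 0))
    stop("G smaller than the planted structure")
  omega <- c(omega, integer(max(0, G - length(omega))))[seq_len(G)]
  S <- nrow(design)
  stopifnot(ncol(structure$sample_partitions) == S)
  set.seed(as.integer(seed))
  logv <- matrix(rnorm(G * S, structure$baseline_mean,
                       structure$baseline_sd), G, S)
  for (g in which(omega > 0)) {
    k <- omega[g]
    lab <- structure$sample_partitions[k, ]
    act <- lab > 0
    logv[g, act] <- rnorm(sum(act),
                          structure$block_means[[k]][lab[act]],
                          structure$noise_sd)
  }
  vals <- exp(logv)
  if (missing_rate > 0)
    vals[runif(G * S) < missing_rate] <- NA
  dimnames(vals) <- list(sprintf("P%04d", seq_len(G)), design$sample_id)
  truth <- structure
  truth$protein_membership <- omega
  list(matrix = pa_matrix(vals), truth = truth)
}

#' Write planted ground truth as a sidecar TSV
#'
#' @param truth A [planted_structure()] (as returned by
#'   [simulate_proteome()]).
#' @param path Output path; columns `protein_id`, `bicluster_id`
#'   (0 = invariant).
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  g <- length(truth$protein_membership)
  write.table(data.frame(protein_id = sprintf("P%04d", seq_len(g)),
                         bicluster_id = truth$protein_membership),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default factor effects for the elemental simulator
#'
#' Log-scale additive offsets per response and factor level, calibrated to
#' the treatment contrasts expected for nutrient/temperature-stressed
#' *Synechococcus*: the P quota about 3-fold higher under N- than P-stress,
#' a modest C-quota surplus under N-stress, cells largest at 28 C and
#' smallest at the 24 C element-use optimum.
#'
#' @details The per-response noise defaults reflect how the measurements
#' are made: C and N come from the same filter and elemental analyzer
#' (small, ~3% element-specific error each, so C:N is precise), P from a
#' separate digestion/colorimetric assay (~10%), and all three quotas share
#' a common per-sample biomass/counting factor (~5%) that cancels in the
#' molar ratios.
#'
#' @param qp_nstress_fold Fold-change of the P quota under N-stress relative
#'   to P-stress (default 3).
#' @return Named list, one element per response (`Q_C`, `Q_N`, `Q_P`,
#'   `FSC_H`, `cell_density`), each with `baseline` (natural units),
#'   log-offset vectors `nutrient` and `temperature`, and an
#'   element-specific log-scale `noise_sd`.
#' @export
elemental_effects <- function(qp_nstress_fold = 3) {
  list(
    Q_C = list(baseline = 30,    # fmol C per cell
               nutrient = c(N_stress = 0.07, P_stress = 0),
               temperature = c(`20` = 0, `24` = -0.05, `28` = 0.10),
               noise_sd = 0.03),
    Q_N = list(baseline = 5.5,   # fmol N per cell
               nutrient = c(N_stress = 0, P_stress = 0.05),
               temperature = c(`20` = 0, `24` = -0.03, `28` = 0.06),
               noise_sd = 0.03),
    Q_P = list(baseline = 0.2,   # fmol P per cell (P-stress baseline)
               nutrient = c(N_stress = log(qp_nstress_fold), P_stress = 0),
               temperature = c(`20` = 0.03, `24` = 0, `28` = 0),
               noise_sd = 0.10),
    FSC_H = list(baseline = 1000,  # arbitrary flow-cytometry units
                 nutrient = c(N_stress = 0, P_stress = 0),
                 temperature = c(`20` = 0, `24` = -0.05, `28` = 0.10),
                 noise_sd = 0.05),
    cell_density = list(baseline = 1e10,  # cells per litre
                        nutrient = c(N_stress = 0, P_stress = 0),
                        temperature = c(`20` = 0, `24` = 0, `28` = 0),
                        noise_sd = 0.05)
  )
}

#' Simulate a per-sample elemental table
#'
#' Draws cell quotas, forward scatter, and cell densities with additive
#' factor effects on the log scale plus log-normal noise, then back-computes
#' particulate concentrations (POC/PON/POP, umol per litre) so that
#' [cell_quotas()] recovers the planted quotas exactly.
#'
#' @param design Sample design from [make_design()].
#' @param effects Effect specification from [elemental_effects()].
#' @param noise_sd When `NULL` (default) each response uses its own
#'   `noise_sd` from `effects` plus the shared biomass factor; a numeric
#'   value overrides every element-specific SD and silences the shared
#'   factor (so `noise_sd = 0` is fully deterministic).
#' @param shared_noise_sd Log-scale SD of the per-sample biomass/counting
#'   factor common to the three quotas (default 0.05); cancels in ratios.
#' @param seed Integer RNG seed.
#' @return A `data.frame` elemental table: design columns plus `POC`, `PON`,
#'   `POP` (umol/L), `cell_density` (cells/L) and `FSC_H`.
#' @export
simulate_elemental <- function(design, effects = elemental_effects(),
                               noise_sd = NULL, shared_noise_sd = 0.05,
                               seed = 1) {
  stopifnot(is.null(noise_sd) || noise_sd >= 0, shared_noise_sd >= 0)
  for (nm in names(effects))
    if (effects[[nm]]$baseline <= 0)
      stop("negative or zero baseline for ", nm)
  set.seed(as.integer(seed))
  S <- nrow(design)
  draw <- function(eff, extra = 0) {
    mu <- log(eff$baseline) +
      eff$nutrient[as.character(design$nutrient_regime)] +
      eff$temperature[as.character(design$temperature)]
    sdv <- if (is.null(noise_sd)) eff$noise_sd else noise_sd
    exp(mu + rnorm(S, 0, sdv) + extra)
  }
  shared <- if (is.null(noise_sd) && shared_noise_sd > 0)
    rnorm(S, 0, shared_noise_sd) else 0
  qc <- draw(effects$Q_C, shared)
  qn <- draw(effects$Q_N, shared)
  qp <- draw(effects$Q_P, shared)
  fsc <- draw(effects$FSC_H); dens <- draw(effects$cell_density)
  out <- design
  out$POC <- qc * dens / 1e9
  out$PON <- qn * dens / 1e9
  out$POP <- qp * dens / 1e9
  out$cell_density <- dens
  out$FSC_H <- fsc
  out
}
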