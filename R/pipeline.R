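#' Pipeline configuration
#'
#' Assembles the declarative configuration consumed by [run_pipeline()].
#' The defaults encode the standard analysis parameter set: two-peptide
#' filter, at most two missing values per protein, total-sum
#' normalization, variant-protein prior probability `pi0 = 0.01`, and
#' 35000 Gibbs sweeps with 5000 burn-in; the synthetic input sizes default
#' to the fast test scale (G = 200, K = 4).
#'
#' @param seed Global integer seed; all stage seeds derive from it.
#' @param out_dir Output directory (created if needed).
#' @param synth List of [planted_structure()] / [simulate_proteome()]
#'   arguments (`G`, `K`, `proteins_per_bicluster`, `separation`,
#'   `noise_sd`, `missing_rate`) for synthetic input, or `NULL` when
#'   `input` paths are given.
#' @param input Optional list of file paths (`abundance`, `groups`,
#'   `elemental`) replacing the synthetic stage.
#' @param min_peptides,max_missing Filter thresholds.
#' @param mcmc List of sampler settings (`n_iter`, `burn_in`, `thin`,
#'   `pi0`, `pi0_sample`, `alpha_protein`, `alpha_sample`); set
#'   `mcmc$enabled = FALSE` to skip the biclustering stage.
#' @param n_perm PERMANOVA permutation count.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, out_dir = tempfile("stoichprot_run_"),
                            synth = list(), input = NULL,
                            min_peptides = 2, max_missing = 2,
                            mcmc = list(), n_perm = 999) {
  synth_def <- list(G = 200, K = 4, proteins_per_bicluster = 15,
                    separation = 2, noise_sd = 0.25, missing_rate = 0)
  mcmc_def <- list(enabled = TRUE, n_iter = 35000, burn_in = 5000,
                   thin = 1, pi0 = 0.01, pi0_sample = 0.5,
                   alpha_protein = 1, alpha_sample = 1)
  synth <- utils::modifyList(synth_def, synth)
  mcmc <- utils::modifyList(mcmc_def, mcmc)
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 synth = if (is.null(input)) synth else NULL,
                 input = input,
                 min_peptides = min_peptides, max_missing = max_missing,
                 normalize = "total_sum", mcmc = mcmc, n_perm = n_perm),
            class = "pipeline_config")
}

stage_seed <- function(seed, stage)
  as.integer((as.numeric(seed) * 13 + stage) %% 2147483647)

synthetic_group_map <- function(truth) {
  vocab <- c("P-acquisition", "ribosomal", "heat shock", "phycobilisome",
             "photic electron transport", "CO2 fixation", "cell structure",
             "oxidative stress", "cell motility", "biosynthesis",
             "N-acquisition", "metal transport")
  omega <- truth$protein_membership
  ids <- sprintf("P%04d", seq_along(omega))
  grp <- character(length(omega))
  grp[omega > 0] <- vocab[(omega[omega > 0] - 1) %% length(vocab) + 1]
  inv <- which(omega == 0)
  # spread most invariant proteins over the remaining vocabulary, leave the
  # tail unmapped so the "other" bucket is exercised
  n_map <- floor(0.8 * length(inv))
  if (n_map > 0)
    grp[inv[seq_len(n_map)]] <- vocab[(seq_len(n_map) - 1) %% length(vocab) + 1]
  data.frame(protein_id = ids[grp != ""], group = grp[grp != ""],
             stringsAsFactors = FALSE)
}

#' Run the full pipeline
#'
#' Executes, in order: data simulation (or ingestion), peptide-count and
#' missingness filtering, total-sum normalization, trait-group allocation,
#' local biclustering, and variance partitioning of quotas, ratios and the
#' proteome. Every output file is written under `config$out_dir` and
#' recorded, with its MD5 hash, in a JSON manifest.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly (also written to
#'   `<out_dir>/manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  files <- character(0)
  design <- make_design()
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    message("[stoichprot] ", msg)
    log_lines <<- c(log_lines, msg)
  }

  # --- stage 1: input -------------------------------------------------
  truth <- NULL
  if (!is.null(config$synth)) {
    sy <- config$synth
    say("simulate: G=%d, K=%d, separation=%.2f, noise_sd=%.2f",
        sy$G, sy$K, sy$separation, sy$noise_sd)
    str <- planted_structure(design, G = sy$G, K = sy$K,
                             proteins_per_bicluster = sy$proteins_per_bicluster,
                             separation = sy$separation,
                             noise_sd = sy$noise_sd)
    sim <- simulate_proteome(design, sy$G, str,
                             seed = stage_seed(config$seed, 1L),
                             missing_rate = sy$missing_rate)
    m <- sim$matrix; truth <- sim$truth
    groups <- synthetic_group_map(truth)
    elem <- simulate_elemental(design, seed = stage_seed(config$seed, 2L))
    files <- c(files, write_abundance_table(m, out("abundance_raw.tsv")),
               write_truth_table(truth, out("truth.tsv")))
  } else {
    say("ingest: %s", config$input$abundance)
    m <- read_abundance_table(config$input$abundance)
    groups <- read.delim(config$input$groups, stringsAsFactors = FALSE)
    elem <- read.delim(config$input$elemental, stringsAsFactors = FALSE)
    elem$nutrient_regime <- factor(elem$nutrient_regime)
    elem$temperature <- factor(elem$temperature)
  }
  write.table(groups, out("groups.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(elem, out("elemental.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  files <- c(files, out("groups.tsv"), out("elemental.tsv"))

  # --- stage 2: filter + normalize ------------------------------------
  g_before <- nrow(m$values)
  m1 <- filter_by_peptide_count(m, config$min_peptides)
  loss1 <- attr(m1, "pa_loss")
  m2 <- filter_by_missingness(m1, config$max_missing)
  loss2 <- attr(m2, "pa_loss")
  say("filter: %d -> %d -> %d proteins (PA loss %.4f%% + %.4f%%)",
      g_before, nrow(m1$values), nrow(m2$values),
      100 * loss1, 100 * loss2)
  mn <- normalize_samples(m2, config$normalize)
  files <- c(files,
             write_abundance_table(mn, out("abundance_filtered_normalized.tsv")))

  # --- stage 3: allocations -------------------------------------------
  alloc <- group_allocations(mn, groups)
  write.table(alloc, out("allocations.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  files <- c(files, out("allocations.tsv"))
  top_n <- min(100L, nrow(mn$values))
  top <- top_n_share(mn, design = if (!is.null(config$synth)) design else {
    idx <- match(colnames(mn$values), elem$sample_id); elem[idx, ]
  }, n = top_n)
  say("top-%d share: %.1f%% (SE %.2f)", top_n, top$mean, top$se)

  # --- stage 4: biclustering ------------------------------------------
  bicluster_summary <- NULL
  if (isTRUE(config$mcmc$enabled)) {
    mc <- config$mcmc
    pri <- prior_settings(pi0 = mc$pi0, pi0_sample = mc$pi0_sample,
                          alpha_protein = mc$alpha_protein,
                          alpha_sample = mc$alpha_sample)
    say("bicluster: %d iterations, %d burn-in, pi0=%.3g",
        mc$n_iter, mc$burn_in, mc$pi0)
    trace <- run_mcmc(mn, priors = pri, n_iter = mc$n_iter,
                      burn_in = mc$burn_in, thin = mc$thin,
                      seed = stage_seed(config$seed, 3L))
    ls <- least_squares_partition(trace)
    summ <- summarize_partition(ls$omega, ls$sample_partition)
    bicluster_summary <- list(
      n_biclusters = summ$n_biclusters,
      n_invariant = summ$n_invariant,
      sizes = as.integer(summ$sizes),
      scaled_distance_quantiles = as.list(round(
        stats::quantile(ls$scaled_distance, c(0.05, 0.5, 0.95)), 6)))
    if (!is.null(truth)) {
      keep_ids <- rownames(mn$values)
      tr_omega <- truth$protein_membership[match(keep_ids,
        sprintf("P%04d", seq_along(truth$protein_membership)))]
      bicluster_summary$ari_vs_truth <-
        adjusted_rand_index(ls$omega, tr_omega)
    }
    write.table(data.frame(protein_id = rownames(mn$values),
                           bicluster_id = ls$omega),
                out("bicluster_omega.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    if (!is.null(ls$sample_partition)) {
      sp <- as.data.frame(ls$sample_partition)
      names(sp) <- colnames(mn$values)
      write.table(cbind(bicluster = seq_len(nrow(sp)), sp),
                  out("bicluster_sample_partitions.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      files <- c(files, out("bicluster_sample_partitions.tsv"))
    }
    files <- c(files, out("bicluster_omega.tsv"))
    trace_summary <- list(n_iter = mc$n_iter, burn_in = mc$burn_in,
                          thin = mc$thin, seed = stage_seed(config$seed, 3L),
                          summary = bicluster_summary)
    jsonlite::write_json(trace_summary, out("trace_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, out("trace_summary.json"))
    say("bicluster result: %d biclusters, %d invariant",
        summ$n_biclusters, summ$n_invariant)
  }

  # --- stage 5: variance partitioning ---------------------------------
  elem <- element_ratios(cell_quotas(elem))
  responses <- c("Q_C", "Q_N", "Q_P", "FSC_H", "C_P", "N_P", "C_N")
  anova_fracs <- lapply(responses, function(r)
    as.list(round(two_way_anova(elem[[r]], elem$nutrient_regime,
                                elem$temperature)$fraction, 6)))
  names(anova_fracs) <- responses
  X <- t(mn$values)
  X[is.na(X)] <- 0
  idx <- match(rownames(X), elem$sample_id)
  perma <- permanova_two_way(X, elem$nutrient_regime[idx],
                             elem$temperature[idx],
                             n_perm = config$n_perm,
                             seed = stage_seed(config$seed, 4L))
  stats_out <- list(anova_fractions = anova_fracs,
                    permanova = list(
                      fraction = as.list(round(perma$fraction, 6)),
                      p_value = as.list(perma$p_value),
                      n_perm = config$n_perm))
  jsonlite::write_json(stats_out, out("stats.json"), auto_unbox = TRUE,
                       digits = NA)
  files <- c(files, out("stats.json"))
  say("anova nutrient fraction C:P = %.3f",
      anova_fracs$C_P$A)

  # --- manifest -------------------------------------------------------
  manifest <- list(
    package = "stoichprot",
    version = as.character(utils::packageVersion("stoichprot")),
    seed = config$seed,
    parameters = list(min_peptides = config$min_peptides,
                      max_missing = config$max_missing,
                      normalize = config$normalize,
                      pi0 = config$mcmc$pi0,
                      n_iter = config$mcmc$n_iter,
                      burn_in = config$mcmc$burn_in,
                      n_perm = config$n_perm),
    filters = list(n_input = g_before,
                   n_after_peptide_filter = nrow(m1$values),
                   n_retained = nrow(m2$values),
                   n_dropped_peptide = g_before - nrow(m1$values),
                   n_dropped_missing = nrow(m1$values) - nrow(m2$values),
                   pa_loss_peptide = loss1,
                   pa_loss_missing = loss2),
    top_share = list(n = top_n, mean = top$mean, se = top$se),
    bicluster = bicluster_summary,
    stats = stats_out,
    files = lapply(setNames(nm = basename(unique(files))), function(f)
      list(path = f, md5 = unname(tools::md5sum(out(f))))),
    log = log_lines
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Human-readable run report
#'
#' Renders the manifest of a [run_pipeline()] run as a text report with the
#' standard result tables: variance fractions per response, trait-group
#' allocations by treatment, bicluster/invariant counts, and the top-100
#' share. Sections for stages that did not run are omitted.
#'
#' @param manifest A manifest list from [run_pipeline()] or the path to a
#'   `manifest.json`.
#' @return Character vector of report lines, invisibly; also printed.
#' @export
make_report <- function(manifest) {
  if (is.character(manifest))
    manifest <- jsonlite::read_json(manifest, simplifyVector = FALSE)
  ln <- c("stoichprot run report",
          "=====================",
          sprintf("seed %s; %s proteins retained of %s",
                  manifest$seed, manifest$filters$n_retained,
                  manifest$filters$n_input))
  ln <- c(ln, "", "Variance fractions (nutrient / temperature / other):")
  for (r in names(manifest$stats$anova_fractions)) {
    fr <- manifest$stats$anova_fractions[[r]]
    ln <- c(ln, sprintf("  %-6s %5.1f%% / %5.1f%% / %5.1f%%", r,
                        100 * as.numeric(fr$A), 100 * as.numeric(fr$B),
                        100 * as.numeric(fr$other)))
  }
  pf <- manifest$stats$permanova$fraction
  ln <- c(ln, sprintf("  proteome (PERMANOVA) %5.1f%% / %5.1f%% / %5.1f%%",
                      100 * as.numeric(pf$A), 100 * as.numeric(pf$B),
                      100 * as.numeric(pf$other)))
  ln <- c(ln, "",
          sprintf("Top-%s proteins: %.1f%% of total peak area (SE %.2f)",
                  manifest$top_share$n,
                  as.numeric(manifest$top_share$mean),
                  as.numeric(manifest$top_share$se)))
  if (!is.null(manifest$bicluster)) {
    ln <- c(ln, "",
            sprintf("Biclustering: %s biclusters, %s invariant proteins",
                    manifest$bicluster$n_biclusters,
                    manifest$bicluster$n_invariant))
    if (!is.null(manifest$bicluster$ari_vs_truth))
      ln <- c(ln, sprintf("  adjusted Rand index vs planted truth: %.3f",
                          as.numeric(manifest$bicluster$ari_vs_truth)))
  }
  cat(paste(ln, collapse = "\n"), "\n")
  invisible(ln)
}

#' Deterministic reproduction chain for deposited tables
#'
#' Runs the deterministic analysis chain on user-supplied deposited tables:
#' an identification-level abundance table (proteins x samples with a
#' `peptide_count` column), a protein-to-trait-group map, and a per-sample
#' elemental table. Applies the two-peptide and two-missing filters,
#' computes filter losses, the retained protein count, ribosomal and
#' P-acquisition allocation ranges, the top-100 share, two-way ANOVA
#' fractions for C:P, N:P and C:N, and the proteome PERMANOVA.
#'
#' @param abundance_path,groups_path,elemental_path Paths to the three
#'   delimited tables (formats as written by [run_pipeline()]).
#' @param n_perm,seed PERMANOVA settings.
#' @return Named list of the headline statistics.
#' @export
reproduce_deposited <- function(abundance_path, groups_path, elemental_path,
                                n_perm = 9999, seed = 1) {
  m <- read_abundance_table(abundance_path)
  groups <- read.delim(groups_path, stringsAsFactors = FALSE)
  elem <- read.delim(elemental_path, stringsAsFactors = FALSE)
  m1 <- filter_by_peptide_count(m, 2)
  m2 <- filter_by_missingness(m1, 2)
  mn <- normalize_samples(m2)
  design <- elem[match(colnames(mn$values), elem$sample_id), ]
  alloc <- group_allocations(mn, groups)
  treat <- interaction(design$nutrient_regime, design$temperature)
  treat_means <- function(col) tapply(alloc[[col]], treat, mean)
  rib <- if ("ribosomal" %in% names(alloc)) treat_means("ribosomal") else NULL
  pacq <- if ("P-acquisition" %in% names(alloc))
    treat_means("P-acquisition") else NULL
  top <- top_n_share(mn, design, n = min(100L, nrow(mn$values)))
  elem <- element_ratios(cell_quotas(elem))
  an <- lapply(c(C_P = "C_P", N_P = "N_P", C_N = "C_N"), function(r)
    two_way_anova(elem[[r]], elem$nutrient_regime, elem$temperature)$fraction)
  X <- t(mn$values); X[is.na(X)] <- 0
  idx <- match(rownames(X), elem$sample_id)
  perma <- permanova_two_way(X, elem$nutrient_regime[idx],
                             elem$temperature[idx], n_perm = n_perm,
                             seed = seed)
  list(n_retained = nrow(m2$values),
       pa_loss_peptide_pct = 100 * attr(m1, "pa_loss"),
       pa_loss_missing_pct = 100 * attr(m2, "pa_loss"),
       ribosomal_range_pct = if (!is.null(rib)) range(rib) else NULL,
       p_acquisition_range_pct = if (!is.null(pacq)) range(pacq) else NULL,
       top100_share_pct = top$mean, top100_se = top$se,
       anova_nutrient_fraction = vapply(an, `[[`, numeric(1), "A"),
       permanova_nutrient_r2 = unname(perma$r2["A"]),
       permanova_temperature_r2 = unname(perma$r2["B"]))
}
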