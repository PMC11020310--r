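#' Prior settings for the local biclustering model
#'
#' The model allocates each protein either to the invariant pool (with
#' prior probability `1 - pi0`) or, via a Dirichlet-process urn with
#' concentration `alpha_protein`, to a bicluster; within each bicluster the
#' samples are likewise either inactive (probability `1 - pi0_sample`) or
#' allocated to subclusters by an urn with concentration `alpha_sample`.
#' Block likelihoods are Normal with a conjugate Normal-Inverse-Gamma base
#' `NIG(m0, k0, a0, b0)`; cells outside any block follow the baseline
#' `Normal(m0, baseline_sd^2)`.
#'
#' @param pi0 Prior probability that a protein is variant (default 0.01:
#'   most biological processes involve only a small subset of proteins).
#' @param pi0_sample Prior probability that a sample is active within a
#'   bicluster (default 0.5).
#' @param alpha_protein,alpha_sample Urn concentration parameters (> 0).
#' @param m0,k0,a0,b0 Normal-Inverse-Gamma base-measure hyperparameters.
#' @param baseline_sd Standard deviation of the baseline model.
#' @return A list of class `nobloc_priors`.
#' @export
prior_settings <- function(pi0 = 0.01, pi0_sample = 0.5,
                           alpha_protein = 1, alpha_sample = 1,
                           m0 = 0, k0 = 0.1, a0 = 1, b0 = 1,
                           baseline_sd = 1) {
  stopifnot(pi0 > 0, pi0 < 1, pi0_sample > 0, pi0_sample < 1,
            alpha_protein > 0, alpha_sample > 0,
            k0 > 0, a0 > 0, b0 > 0, baseline_sd > 0)
  structure(list(pi0 = pi0, pi0_sample = pi0_sample,
                 alpha_protein = alpha_protein, alpha_sample = alpha_sample,
                 m0 = m0, k0 = k0, a0 = a0, b0 = b0,
                 baseline_sd = baseline_sd),
            class = "nobloc_priors")
}

#' Marginal log-likelihood of a block of values
#'
#' Integrates the Normal likelihood over its mean and variance under the
#' conjugate Normal-Inverse-Gamma prior `NIG(m0, k0, a0, b0)`. The empty
#' block returns 0 (log of 1); `NA` values are skipped.
#'
#' @param values Numeric vector of observations sharing one block.
#' @param priors A [prior_settings()] object (only the base-measure fields
#'   are used).
#' @return The log marginal likelihood.
#' @export
block_marginal_loglik <- function(values, priors = prior_settings()) {
  stopifnot(inherits(priors, "nobloc_priors"))
  v <- values[!is.na(values)]
  if (length(v) && any(!is.finite(v))) stop("values must be finite")
  nig_marg_cpp(as.numeric(v), priors$m0, priors$k0, priors$a0, priors$b0)
}

#' Log-transform and row-standardize an abundance matrix
#'
#' The clustering model groups proteins by response pattern regardless of
#' mean abundance, so rows are log-transformed, centered, and scaled to
#' unit variance (ignoring missing cells). Rows with zero variance are
#' centered only.
#'
#' @param m A [pa_matrix] or a positive numeric matrix.
#' @return Numeric matrix of standardized log abundances (`NA` preserved).
#' @export
standardize_log_rows <- function(m) {
  v <- if (inherits(m, "pa_matrix")) m$values else as.matrix(m)
  if (any(v[!is.na(v)] <= 0)) stop("peak areas must be strictly positive")
  lv <- log(v)
  mu <- rowMeans(lv, na.rm = TRUE)
  sdv <- apply(lv, 1, sd, na.rm = TRUE)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  (lv - mu) / sdv
}

#' Initial partition from hierarchical clustering
#'
#' Cuts an average-linkage hierarchical clustering (Euclidean distance on
#' standardized rows) into `n_variant_sets` groups; singleton groups are
#' designated invariant (membership 0) under the default rule, and the
#' remaining groups become the initial biclusters, each starting with a
#' single subcluster containing all samples.
#'
#' @param data Numeric matrix of standardized log abundances (proteins in
#'   rows), e.g. from [standardize_log_rows()]. Missing cells are
#'   mean-imputed (row mean, i.e. 0 after standardization) for the distance
#'   computation only.
#' @param n_variant_sets Number of groups to cut the dendrogram into;
#'   `NULL` (default) cuts at height `h` instead.
#' @param h Cut height; defaults to half the median pairwise distance,
#'   which keeps tight response-pattern clusters together while shattering
#'   the noise floor into singletons (marked invariant).
#' @param invariant_rule `"singleton"` (default) marks singleton groups
#'   invariant; `"none"` keeps every group as a bicluster.
#' @param init_sample_partitions When `TRUE` (default), each bicluster's
#'   local sample partition is also initialized from an average-linkage
#'   clustering of the samples restricted to that bicluster's proteins,
#'   with the number of subclusters chosen by the Calinski-Harabasz index;
#'   when `FALSE`, every bicluster starts with a single subcluster holding
#'   all samples. Single-site Gibbs updates cross the energy barrier of
#'   creating a subcluster one sample at a time only slowly, so a
#'   data-informed start is the practical default (it does not change the
#'   posterior being sampled).
#' @return List with `omega` (integer membership vector, labels contiguous)
#'   and `sample_partition` (K x S integer matrix of initial subcluster
#'   labels).
#' @export
init_partition <- function(data, n_variant_sets = NULL,
                           invariant_rule = c("singleton", "none"),
                           init_sample_partitions = TRUE, h = NULL) {
  invariant_rule <- match.arg(invariant_rule)
  data <- as.matrix(data)
  G <- nrow(data)
  if (G < 2) stop("need at least two proteins")
  imp <- data
  if (anyNA(imp)) {
    mu <- rowMeans(imp, na.rm = TRUE)
    mu[!is.finite(mu)] <- 0
    idx <- which(is.na(imp), arr.ind = TRUE)
    imp[idx] <- mu[idx[, 1]]
  }
  dd <- dist(imp)
  tree <- hclust(dd, method = "average")
  cl <- if (!is.null(n_variant_sets)) {
    stopifnot(n_variant_sets >= 1, n_variant_sets <= G)
    cutree(tree, k = n_variant_sets)
  } else {
    if (is.null(h)) h <- 0.5 * stats::median(dd)
    cutree(tree, h = h)
  }
  sizes <- table(cl)
  omega <- as.integer(cl)
  if (invariant_rule == "singleton") {
    singleton <- as.integer(names(sizes)[sizes == 1])
    omega[omega %in% singleton] <- 0L
  }
  keep <- omega > 0
  omega[keep] <- as.integer(factor(omega[keep]))
  K <- if (any(keep)) max(omega) else 0L
  sp <- matrix(1L, nrow = K, ncol = ncol(data))
  if (init_sample_partitions && K > 0) {
    for (k in seq_len(K))
      sp[k, ] <- cluster_samples_ch(imp[omega == k, , drop = FALSE])
  }
  list(omega = omega, sample_partition = sp)
}

# average-linkage clustering of samples on the rows of `sub`, cut at the
# number of groups (1..min(8, S-1)) maximizing the Calinski-Harabasz index
cluster_samples_ch <- function(sub) {
  S <- ncol(sub)
  xs <- t(sub)
  hc <- hclust(dist(xs), method = "average")
  kmax <- min(8L, S - 1L)
  best_k <- 1L
  best_ch <- -Inf
  total_ss <- sum(scale(xs, scale = FALSE)^2)
  for (k in 2:kmax) {
    labs <- cutree(hc, k = k)
    within <- sum(vapply(split(seq_len(S), labs), function(idx)
      sum(scale(xs[idx, , drop = FALSE], scale = FALSE)^2), numeric(1)))
    between <- total_ss - within
    if (within <= 0) next
    ch <- (between / (k - 1)) / (within / (S - k))
    if (ch > best_ch) { best_ch <- ch; best_k <- k }
  }
  as.integer(cutree(hc, k = best_k))
}

#' Run the local biclustering Gibbs sampler
#'
#' One sweep resamples every protein's bicluster membership (invariant /
#' existing bicluster / new bicluster, by the zero-enriched urn with
#' collapsed Normal-NIG block likelihoods) and then every sample's
#' subcluster label within every bicluster. New biclusters are proposed
#' with an auxiliary sample partition drawn from the prior, so the chain
#' targets the exact posterior.
#'
#' @param data A [pa_matrix] of positive peak areas, or a numeric matrix.
#' @param priors A [prior_settings()] object.
#' @param n_iter Total sweeps (default 35000).
#' @param burn_in Discarded initial sweeps (default 5000).
#' @param thin Keep every `thin`-th post-burn-in sweep (default 1).
#' @param seed Integer RNG seed; fixed seeds give identical traces.
#' @param init Initial partition as returned by [init_partition()];
#'   `NULL` (default) initializes from hierarchical clustering with the
#'   default height cut and singleton-invariant rule.
#' @param transform `"standardize_log"` (default) applies
#'   [standardize_log_rows()]; `"none"` uses `data` as-is (it should then
#'   already be on a roughly standardized scale for the default priors).
#' @return An object of class `nobloc_trace`: list with `omega` (kept
#'   sweeps x proteins membership matrix), `sample_partitions` (list of
#'   K x S integer matrices), `loglik` (per-sweep data log-likelihood),
#'   and bookkeeping fields `n_iter`, `burn_in`, `thin`, `seed`,
#'   `protein_ids`, `sample_ids`.
#' @export
run_mcmc <- function(data, priors = prior_settings(), n_iter = 35000,
                     burn_in = 5000, thin = 1, seed = 1, init = NULL,
                     transform = c("standardize_log", "none")) {
  transform <- match.arg(transform)
  stopifnot(inherits(priors, "nobloc_priors"), n_iter > burn_in,
            burn_in >= 0, thin >= 1)
  raw <- if (inherits(data, "pa_matrix")) data$values else as.matrix(data)
  y <- if (transform == "standardize_log") standardize_log_rows(raw) else raw
  if (any(!is.finite(y[!is.na(y)]))) stop("non-finite data")
  set.seed(as.integer(seed))
  if (is.null(init)) init <- init_partition(y)
  stopifnot(length(init$omega) == nrow(y))
  res <- nobloc_mcmc_cpp(y, as.integer(init$omega),
                         init$sample_partition, unclass(priors),
                         as.integer(n_iter), as.integer(burn_in),
                         as.integer(thin))
  structure(list(omega = res$omega,
                 sample_partitions = res$sample_partitions,
                 loglik = as.numeric(res$loglik),
                 n_iter = n_iter, burn_in = burn_in, thin = thin,
                 seed = seed,
                 protein_ids = rownames(raw),
                 sample_ids = colnames(raw)),
            class = "nobloc_trace")
}

#' @export
print.nobloc_trace <- function(x, ...) {
  cat(sprintf(
    "nobloc_trace: %d kept sweeps (%d iterations, %d burn-in, thin %d)\n",
    nrow(x$omega), x$n_iter, x$burn_in, x$thin))
  invisible(x)
}

#' Posterior co-clustering probabilities
#'
#' Fraction of kept sweeps in which each pair of proteins shares a
#' membership label (invariant pairs count as co-clustered, matching the
#' literal indicator used by [partition_distance()]).
#'
#' @param trace An `nobloc_trace` from [run_mcmc()] or a membership matrix.
#' @return Symmetric G x G matrix of probabilities.
#' @export
coclustering_probability <- function(trace) {
  omega_mat <- if (inherits(trace, "nobloc_trace")) trace$omega else
    as.matrix(trace)
  G <- ncol(omega_mat)
  acc <- matrix(0, G, G)
  for (t in seq_len(nrow(omega_mat)))
    acc <- acc + coclustering_indicator(omega_mat[t, ])
  acc / nrow(omega_mat)
}
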