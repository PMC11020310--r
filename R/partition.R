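#' Pairwise co-clustering indicator matrix
#'
#' Entry (g, g') is 1 exactly when proteins g and g' carry the same
#' membership label. The indicator is literal: two invariant proteins
#' (label 0) count as co-clustered.
#'
#' @param omega Integer membership vector (0 = invariant).
#' @return Symmetric G x G 0/1 matrix with unit diagonal.
#' @export
coclustering_indicator <- function(omega) {
  outer(omega, omega, `==`) * 1L
}

#' L1 distance between two partitions
#'
#' Sums, over unordered protein pairs, the absolute difference between the
#' co-clustering indicators of the two partitions: the number of pairs on
#' which the partitions disagree about being clustered together.
#'
#' @param omega,omega_prime Integer membership vectors of equal length.
#' @return Non-negative integer distance.
#' @export
partition_distance <- function(omega, omega_prime) {
  if (length(omega) != length(omega_prime))
    stop("partitions have different lengths")
  d1 <- coclustering_indicator(omega)
  d2 <- coclustering_indicator(omega_prime)
  sum(abs(d1 - d2)) / 2
}

#' Least-squares posterior point partition
#'
#' Selects, among the partitions visited by the sampler, the one minimizing
#' the summed L1 distance [partition_distance()] to all posterior samples
#' (Dahl-style least-squares selection restricted to visited partitions;
#' ties broken by the earliest minimizer). Also returns the distance of
#' every trace sample to the selected partition, scaled by the number of
#' protein pairs, as an uncertainty diagnostic.
#'
#' @param trace An `nobloc_trace` from [run_mcmc()], or a plain integer
#'   matrix of sampled membership vectors (samples in rows).
#' @return List with `omega` (the selected membership vector), `index` (its
#'   position in the trace), `sample_partition` (the per-bicluster sample
#'   partition at that iteration, when available), and `scaled_distance`
#'   (per-sample H to the selection, divided by G(G-1)/2).
#' @export
least_squares_partition <- function(trace) {
  omega_mat <- if (inherits(trace, "nobloc_trace")) trace$omega else
    as.matrix(trace)
  if (is.null(dim(omega_mat)) || nrow(omega_mat) == 0)
    stop("empty trace")
  T_ <- nrow(omega_mat); G <- ncol(omega_mat)
  # pair co-clustering counts over the trace, then each candidate's summed
  # distance in O(G^2) rather than O(T G^2) per candidate
  counts <- matrix(0, G, G)
  for (t in seq_len(T_))
    counts <- counts + coclustering_indicator(omega_mat[t, ])
  cost <- numeric(T_)
  for (t in seq_len(T_)) {
    d <- coclustering_indicator(omega_mat[t, ])
    # pairs where d=1 disagree with (T - count) samples; d=0 with count
    cost[t] <- (sum(d * (T_ - counts)) + sum((1 - d) * counts)) / 2
  }
  idx <- which.min(cost)
  omega_ls <- omega_mat[idx, ]
  npair <- G * (G - 1) / 2
  scaled <- vapply(seq_len(T_), function(t)
    partition_distance(omega_mat[t, ], omega_ls) / npair, numeric(1))
  sp <- if (inherits(trace, "nobloc_trace")) trace$sample_partitions[[idx]]
        else NULL
  list(omega = omega_ls, index = idx, sample_partition = sp,
       scaled_distance = scaled)
}

#' Summarize a bicluster membership vector
#'
#' @param omega Integer membership vector (0 = invariant).
#' @param sample_partition Optional K x S matrix of per-bicluster sample
#'   subcluster labels (0 = inactive), as produced by [run_mcmc()].
#' @return List with `n_biclusters`, `n_invariant`, `sizes` (proteins per
#'   bicluster), and `n_subclusters` per bicluster when the sample
#'   partition is supplied.
#' @export
summarize_partition <- function(omega, sample_partition = NULL) {
  k <- sort(unique(omega[omega > 0]))
  sizes <- vapply(k, function(j) sum(omega == j), integer(1))
  out <- list(n_biclusters = length(k),
              n_invariant = sum(omega == 0),
              sizes = sizes)
  if (!is.null(sample_partition))
    out$n_subclusters <- apply(sample_partition, 1, max)
  out
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between a recovered membership vector and the
#' planted truth; 1 for identical partitions (up to relabeling), ~0 for
#' independent ones. Label 0 (invariant) is treated as an ordinary class.
#'
#' @param a,b Integer label vectors of equal length.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}
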