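# Independent oracles used across tests. These deliberately avoid the
# package's computational path: the marginal likelihood is evaluated by the
# sequential Student-t predictive (chain rule), and posteriors over
# partitions by exhaustive enumeration of zero-enriched labelings.

# all zero-enriched labelings of n items (0 = inactive/invariant; positive
# labels in first-appearance canonical order)
enum_labelings <- function(n) {
  out <- list()
  rec <- function(lab) {
    i <- length(lab) + 1
    if (i > n) { out[[length(out) + 1]] <<- lab; return(invisible()) }
    maxl <- if (length(lab)) max(lab) else 0
    for (l in 0:(maxl + 1)) rec(c(lab, l))
  }
  rec(integer(0))
  out
}

log_prior_ze <- function(lab, pi0, alpha) {
  nv <- sum(lab > 0); n0 <- sum(lab == 0)
  K <- if (nv) max(lab) else 0
  lp <- n0 * log(1 - pi0) + nv * log(pi0)
  if (K > 0) {
    sizes <- tabulate(lab[lab > 0])
    lp <- lp + K * log(alpha) + sum(lgamma(sizes)) -
      sum(log(alpha + seq_len(nv) - 1))
  }
  lp
}

# chain-rule marginal likelihood: product of Student-t posterior
# predictives, one observation at a time
chain_marg <- function(v, m0, k0, a0, b0) {
  ll <- 0
  m <- m0; k <- k0; a <- a0; b <- b0
  for (x in v) {
    scale <- sqrt(b * (k + 1) / (a * k))
    ll <- ll + dt((x - m) / scale, df = 2 * a, log = TRUE) - log(scale)
    b <- b + k * (x - m)^2 / (2 * (k + 1))
    m <- (k * m + x) / (k + 1)
    k <- k + 1
    a <- a + 1 / 2
  }
  ll
}

row_ll_oracle <- function(v, clab, pr) {
  ll <- 0
  for (s in seq_along(v)) if (clab[s] == 0)
    ll <- ll + dnorm(v[s], pr$m0, pr$baseline_sd, log = TRUE)
  for (j in seq_len(max(c(0, clab))))
    ll <- ll + chain_marg(v[clab == j], pr$m0, pr$k0, pr$a0, pr$b0)
  ll
}

# exact co-clustering probabilities by full enumeration over protein
# labelings, marginalizing each bicluster over all sample labelings
exact_coclustering <- function(y, pr) {
  G <- nrow(y); S <- ncol(y)
  omegas <- enum_labelings(G)
  clabs <- enum_labelings(S)
  clab_lp <- vapply(clabs, log_prior_ze, numeric(1),
                    pi0 = pr$pi0_sample, alpha = pr$alpha_sample)
  set_ll <- function(gs) {
    terms <- vapply(seq_along(clabs), function(i) {
      clab_lp[i] + sum(vapply(gs, function(g)
        row_ll_oracle(y[g, ], clabs[[i]], pr), numeric(1)))
    }, numeric(1))
    m <- max(terms); m + log(sum(exp(terms - m)))
  }
  lps <- vapply(omegas, function(om) {
    lp <- log_prior_ze(om, pr$pi0, pr$alpha_protein)
    for (g in which(om == 0))
      lp <- lp + sum(dnorm(y[g, ], pr$m0, pr$baseline_sd, log = TRUE))
    for (k in seq_len(max(c(0, om))))
      lp <- lp + set_ll(which(om == k))
    lp
  }, numeric(1))
  w <- exp(lps - max(lps)); w <- w / sum(w)
  P <- matrix(0, G, G)
  for (i in seq_along(omegas))
    P <- P + w[i] * coclustering_indicator(omegas[[i]])
  P
}

# random zero-enriched membership vector for property tests
random_partition <- function(G, max_k = 3) {
  sample(0:max_k, G, replace = TRUE)
}

# small planted simulation used by several tests
planted_sim <- function(seed, G = 60, K = 3, noise_sd = 0.25,
                        separation = 2,
                        ppb = min(15L, G %/% (K + 1L))) {
  design <- make_design()
  str <- planted_structure(design, G = G, K = K,
                           proteins_per_bicluster = ppb,
                           separation = separation, noise_sd = noise_sd)
  simulate_proteome(design, G, str, seed = seed)
}
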