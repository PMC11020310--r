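test_that("block marginal likelihood matches its conjugate closed form", {
  pr <- prior_settings(m0 = 0, k0 = 1, a0 = 1, b0 = 1)
  expect_equal(block_marginal_loglik(numeric(0), pr), 0)
  # single observation: Student-t posterior predictive
  for (x in c(-2, 0.3, 1.7)) {
    scale <- sqrt(1 * (1 + 1) / (1 * 1))
    expect_equal(block_marginal_loglik(x, pr),
                 dt(x / scale, df = 2, log = TRUE) - log(scale),
                 tolerance = 1e-12)
  }
  # longer blocks: sequential chain-rule predictive (independent path)
  pr2 <- prior_settings(m0 = 0.5, k0 = 0.3, a0 = 2, b0 = 1.5)
  set.seed(5)
  v <- rnorm(7)
  expect_equal(block_marginal_loglik(v, pr2),
               chain_marg(v, 0.5, 0.3, 2, 1.5), tolerance = 1e-10)
  # tight blocks beat dispersed blocks
  expect_gt(block_marginal_loglik(c(1, 1.01), pr),
            block_marginal_loglik(c(-3, 3), pr))
  # NA values are skipped
  expect_equal(block_marginal_loglik(c(v, NA), pr2),
               block_marginal_loglik(v, pr2))
  expect_error(prior_settings(k0 = -1))
})

test_that("hierarchical initialization separates blocks and flags singletons invariant", {
  set.seed(6)
  y <- rbind(matrix(rnorm(4 * 10, 5), 4, 10),
             matrix(rnorm(4 * 10, -5), 4, 10))
  ini <- init_partition(y, n_variant_sets = 2)
  expect_equal(ini$omega[1:4], rep(ini$omega[1], 4))
  expect_equal(ini$omega[5:8], rep(ini$omega[5], 4))
  expect_true(all(ini$omega > 0))
  # an outlier forced into a singleton becomes invariant
  y2 <- rbind(y, rnorm(10, 40))
  ini2 <- init_partition(y2, n_variant_sets = 3)
  expect_equal(ini2$omega[9], 0L)
  expect_equal(max(ini2$omega), 2L)
  expect_error(init_partition(y[1, , drop = FALSE]), "two proteins")
})

test_that("the sampler is reproducible under a fixed seed and respects thinning", {
  sim <- planted_sim(seed = 31, G = 20, K = 2, noise_sd = 0.25)
  pri <- prior_settings(pi0 = 0.5)
  a <- run_mcmc(sim$matrix, pri, n_iter = 80, burn_in = 20, seed = 42)
  b <- run_mcmc(sim$matrix, pri, n_iter = 80, burn_in = 20, seed = 42)
  expect_identical(a$omega, b$omega)
  expect_identical(a$loglik, b$loglik)
  expect_true(all(is.finite(a$loglik)))
  th <- run_mcmc(sim$matrix, pri, n_iter = 80, burn_in = 20, thin = 5,
                 seed = 42)
  expect_equal(nrow(th$omega), (80 - 20) / 5)
  expect_error(run_mcmc(sim$matrix, pri, n_iter = 10, burn_in = 20))
})

test_that("prior limits drive the partition to its degenerate states", {
  set.seed(7)
  y <- matrix(rnorm(8 * 6), 8, 6)
  # pi0 -> 0: every protein forced invariant
  tiny <- prior_settings(pi0 = 1e-12)
  tr <- run_mcmc(exp(y), tiny, n_iter = 30, burn_in = 20, seed = 1)
  expect_true(all(tr$omega == 0))
  # pi0 near 1 with vanishing concentration: one bicluster for coherent data
  block <- matrix(rep(c(2, 2, 2, -2, -2, -2), each = 8), 8, 6) +
    0.05 * matrix(rnorm(48), 8, 6)
  one <- prior_settings(pi0 = 1 - 1e-9, alpha_protein = 1e-9)
  tr2 <- run_mcmc(exp(block), one, n_iter = 40, burn_in = 30, seed = 2)
  expect_true(all(tr2$omega == 1))
  # pi0_sample -> 1 with a diffuse baseline keeps every sample active
  act <- prior_settings(pi0 = 1 - 1e-9, alpha_protein = 1e-9,
                        pi0_sample = 1 - 1e-9, baseline_sd = 50)
  tr3 <- run_mcmc(exp(block), act, n_iter = 40, burn_in = 30, seed = 3)
  sp <- tr3$sample_partitions[[length(tr3$sample_partitions)]]
  expect_true(all(sp > 0))
})

test_that("posterior co-clustering tracks the enumeration oracle on a toy instance", {
  pr <- prior_settings(pi0 = 0.4, pi0_sample = 0.5, alpha_protein = 1,
                       alpha_sample = 1, m0 = 0, k0 = 0.5, a0 = 2, b0 = 1)
  set.seed(42)
  y <- matrix(rnorm(6), 3, 2)
  y[1:2, 1] <- y[1:2, 1] + 2
  P_exact <- exact_coclustering(y, pr)
  tr <- run_mcmc(y, pr, n_iter = 8000, burn_in = 1000, seed = 7,
                 transform = "none",
                 init = list(omega = c(1L, 1L, 1L),
                             sample_partition = matrix(1L, 1, 2)))
  expect_lt(max(abs(P_exact - coclustering_probability(tr))), 0.1)
})

test_that("label permutation leaves summaries and likelihood unchanged", {
  sim <- planted_sim(seed = 33, G = 20, K = 2, noise_sd = 0.25)
  tr <- run_mcmc(sim$matrix, prior_settings(pi0 = 0.5), n_iter = 60,
                 burn_in = 30, seed = 9)
  om <- tr$omega[nrow(tr$omega), ]
  relab <- om
  K <- max(om)
  if (K >= 2) {
    perm <- c(K, seq_len(K - 1))
    relab[om > 0] <- perm[om[om > 0]]
    s1 <- summarize_partition(om); s2 <- summarize_partition(relab)
    expect_equal(s1$n_biclusters, s2$n_biclusters)
    expect_equal(s1$n_invariant, s2$n_invariant)
    expect_equal(sort(s1$sizes), sort(s2$sizes))
    expect_equal(partition_distance(om, relab), 0)
  }
})

test_that("row standardization prepares positive matrices for clustering", {
  sim <- planted_sim(seed = 34, G = 10, K = 2, noise_sd = 0.25)
  z <- standardize_log_rows(sim$matrix)
  expect_equal(unname(rowMeans(z)), rep(0, 10), tolerance = 1e-12)
  expect_equal(unname(apply(z, 1, sd)), rep(1, 10), tolerance = 1e-12)
  expect_error(standardize_log_rows(matrix(c(-1, 1, 2, 3), 2)), "positive")
})
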