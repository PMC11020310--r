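elem_fixture <- function(seed = 1, ...) {
  element_ratios(cell_quotas(simulate_elemental(make_design(), seed = seed,
                                                ...)))
}

test_that("cell quotas follow the unit conversion exactly", {
  tab <- data.frame(POC = 10, PON = 2, POP = 0.5,
                    cell_density = 1e9, FSC_H = 100)
  q <- cell_quotas(tab)
  expect_equal(q$Q_C, 10)   # 10 umol/L over 1e9 cells/L = 10 fmol/cell
  expect_equal(q$Q_N, 2)
  expect_equal(q$Q_P, 0.5)
  expect_equal(q$Q_C_FSC, 0.1)
  tab$cell_density <- 0
  expect_error(cell_quotas(tab), "cell_density")
})

test_that("element ratios are molar quotients with the expected homogeneity", {
  tab <- data.frame(Q_C = 106, Q_N = 16, Q_P = 1)
  r <- element_ratios(tab)
  expect_equal(r$C_P, 106)
  expect_equal(r$N_P, 16)
  expect_equal(r$C_N, 106 / 16)
  tab2 <- transform(tab, Q_P = 2 * Q_P)
  expect_equal(element_ratios(tab2)$C_P, r$C_P / 2)
  expect_error(element_ratios(transform(tab, Q_P = 0)), "denominator")
})

test_that("two-way ANOVA fractions match explicit textbook sums of squares", {
  e <- elem_fixture(seed = 3)
  y <- e$C_P; A <- e$nutrient_regime; B <- e$temperature
  vp <- two_way_anova(y, A, B)
  # independent oracle: direct group-mean computation on the balanced design
  gm <- mean(y)
  ss_a <- sum(tapply(y, A, function(v) length(v) * (mean(v) - gm)^2))
  ss_b <- sum(tapply(y, B, function(v) length(v) * (mean(v) - gm)^2))
  cell_means <- tapply(y, interaction(A, B), mean)
  ss_cells <- sum(5 * (cell_means - gm)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_tot <- sum((y - gm)^2)
  expect_equal(unname(vp$fraction["A"]), ss_a / ss_tot, tolerance = 1e-10)
  expect_equal(unname(vp$fraction["B"]), ss_b / ss_tot, tolerance = 1e-10)
  expect_equal(unname(vp$fraction["other"]),
               (ss_ab + (ss_tot - ss_cells)) / ss_tot, tolerance = 1e-10)
  expect_equal(unname(sum(vp$fraction[c("A", "B")]) + vp$fraction["other"]),
               1, tolerance = 1e-12)
  # affine invariance
  vp2 <- two_way_anova(3 * y - 17, A, B)
  expect_equal(vp$fraction, vp2$fraction, tolerance = 1e-10)
  expect_error(two_way_anova(rep(1, 30), A, B), "constant")
})

test_that("a pure factor-A signal yields fraction 1 for A", {
  d <- make_design()
  y <- ifelse(d$nutrient_regime == "N_stress", 10, 20)
  vp <- suppressWarnings(two_way_anova(y, d$nutrient_regime, d$temperature))
  expect_equal(unname(vp$fraction), c(1, 0, 0), tolerance = 1e-12)
})

test_that("Euclidean PERMANOVA on one centered variable reproduces ANOVA fractions", {
  e <- elem_fixture(seed = 4)
  y <- e$N_P
  vp <- two_way_anova(y, e$nutrient_regime, e$temperature)
  pm <- permanova_two_way(matrix(y - mean(y), ncol = 1),
                          e$nutrient_regime, e$temperature,
                          n_perm = 99, seed = 1)
  expect_equal(pm$fraction, vp$fraction, tolerance = 1e-9)
  # reproducible permutation p-values under a fixed seed
  pm2 <- permanova_two_way(matrix(y - mean(y), ncol = 1),
                           e$nutrient_regime, e$temperature,
                           n_perm = 99, seed = 1)
  expect_identical(pm$p_value, pm2$p_value)
})

test_that("PERMANOVA p-values are calibrated under the null", {
  d <- make_design()
  set.seed(20)
  pvals <- vapply(1:40, function(i) {
    X <- matrix(rnorm(30 * 5), 30, 5)
    permanova_two_way(X, d$nutrient_regime, d$temperature,
                      n_perm = 199, seed = i)$p_value[["A"]]
  }, numeric(1))
  # type-I error at alpha = 0.05 within a binomial 99% CI for n = 40
  expect_lte(sum(pvals < 0.05), 8)
})

test_that("BH adjustment reproduces the step-up computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 4)), rep(1, 4))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(21)
  p <- runif(20)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("pairwise Welch comparisons flag separated groups only", {
  set.seed(22)
  g <- rep(c("a", "b", "c"), each = 5)
  y_same <- rnorm(15)
  same <- pairwise_comparisons(y_same, g)
  expect_equal(nrow(same), 3)   # k(k-1)/2 rows
  expect_false(any(same$significant))
  y_sep <- y_same + ifelse(g == "c", 10, 0)
  sep <- pairwise_comparisons(y_sep, g)
  expect_true(all(sep$significant[sep$group2 == "c" | sep$group1 == "c"]))
  expect_error(pairwise_comparisons(1:3, c("a", "a", "b")),
               "two observations")
})
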