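#' Cellular element quotas
#'
#' Converts particulate element concentrations (umol per litre of culture)
#' and cell densities (cells per litre) to per-cell quotas in fmol/cell
#' (`Q_X = concentration * 1e9 / cell_density`), plus quotas normalized to
#' the forward-scatter cell-size proxy.
#'
#' @param table Elemental data frame with columns `POC`, `PON`, `POP`,
#'   `cell_density` and `FSC_H` (e.g. from [simulate_elemental()]).
#' @return The table with added columns `Q_C`, `Q_N`, `Q_P` (fmol/cell) and
#'   `Q_C_FSC`, `Q_N_FSC`, `Q_P_FSC`.
#' @export
cell_quotas <- function(table) {
  stopifnot(all(c("POC", "PON", "POP", "cell_density", "FSC_H") %in%
                  names(table)))
  if (any(table$cell_density <= 0))
    stop("cell_density must be > 0 for quota computation")
  table$Q_C <- table$POC * 1e9 / table$cell_density
  table$Q_N <- table$PON * 1e9 / table$cell_density
  table$Q_P <- table$POP * 1e9 / table$cell_density
  table$Q_C_FSC <- table$Q_C / table$FSC_H
  table$Q_N_FSC <- table$Q_N / table$FSC_H
  table$Q_P_FSC <- table$Q_P / table$FSC_H
  table
}

#' Molar element ratios per sample
#'
#' @param table Elemental table with quota columns (see [cell_quotas()]).
#' @return The table with added molar ratio columns `C_P`, `N_P`, `C_N`.
#' @export
element_ratios <- function(table) {
  stopifnot(all(c("Q_C", "Q_N", "Q_P") %in% names(table)))
  if (any(table$Q_P <= 0) || any(table$Q_N <= 0))
    stop("zero denominator in element ratios")
  table$C_P <- table$Q_C / table$Q_P
  table$N_P <- table$Q_N / table$Q_P
  table$C_N <- table$Q_C / table$Q_N
  table
}

#' Two-way ANOVA variance partition
#'
#' Fits `y ~ A * B` with sequential sums of squares and partitions the
#' total sum of squares into the two main factors and an "other" pool
#' (interaction plus residual), the three-way split used to compare the
#' relative influence of nutrient supply and temperature on each response.
#'
#' @param y Numeric response, one value per sample.
#' @param factorA,factorB Factors (coerced), same length as `y`; by
#'   convention A is the nutrient regime and B the temperature.
#' @return List of class `variance_partition` with `ss` (named sums of
#'   squares), `fraction` (named fractions of total SS for `A`, `B`,
#'   `other`), `anova_table` (the full sequential ANOVA with F tests), and
#'   `terms`.
#' @export
two_way_anova <- function(y, factorA, factorB) {
  factorA <- factor(factorA); factorB <- factor(factorB)
  stopifnot(length(y) == length(factorA), length(y) == length(factorB))
  if (anyNA(y)) stop("missing response values")
  if (var(y) == 0) stop("constant response: total sum of squares is zero")
  if (any(table(factorA, factorB) == 0))
    stop("empty design cell(s)")
  fit <- aov(y ~ factorA * factorB)
  tab <- anova(fit)
  ss <- tab[["Sum Sq"]]
  names(ss) <- rownames(tab)
  total <- sum(ss)
  fraction <- c(A = unname(ss["factorA"] / total),
                B = unname(ss["factorB"] / total),
                other = unname((ss["factorA:factorB"] + ss["Residuals"]) /
                                 total))
  structure(list(ss = ss, fraction = fraction, anova_table = tab,
                 terms = c(A = "factorA", B = "factorB")),
            class = "variance_partition")
}

#' @export
print.variance_partition <- function(x, ...) {
  cat("Variance partition (fraction of total SS):\n")
  print(round(x$fraction, 4))
  invisible(x)
}

#' Two-way PERMANOVA variance partition
#'
#' Partitions the total variation of a sample distance matrix among two
#' crossed factors and their interaction by sequential (Type I)
#' permutational multivariate ANOVA, with the first factor entered first.
#' Delegates the fit to [vegan::adonis2()], the standard implementation,
#' with a fixed permutation seed.
#'
#' @param X Numeric matrix or data frame, samples in rows, variables in
#'   columns (e.g. protein peak areas), or a `dist` object.
#' @param factorA,factorB Factors, one level per sample.
#' @param distance Distance metric passed to vegan (default
#'   `"euclidean"`); ignored when `X` is already a `dist`.
#' @param n_perm Number of permutations (default 9999).
#' @param seed Integer seed for the permutation stream.
#' @return List of class `variance_partition` with `fraction` (`A`, `B`,
#'   `other` = interaction + residual R2), `r2` (per-term R2 including the
#'   interaction), `pseudo_f`, `p_value`, `n_perm`, `seed`, and the
#'   underlying `adonis_table`.
#' @export
permanova_two_way <- function(X, factorA, factorB, distance = "euclidean",
                              n_perm = 9999, seed = 1) {
  factorA <- factor(factorA); factorB <- factor(factorB)
  stopifnot(n_perm >= 1)
  meta <- data.frame(A = factorA, B = factorB)
  set.seed(as.integer(seed))
  tab <- vegan::adonis2(X ~ A * B, data = meta, method = distance,
                        permutations = n_perm, by = "terms")
  r2 <- setNames(tab$R2, rownames(tab))
  fraction <- c(A = unname(r2["A"]),
                B = unname(r2["B"]),
                other = unname(r2["A:B"] + r2["Residual"]))
  structure(list(fraction = fraction,
                 r2 = r2[c("A", "B", "A:B")],
                 pseudo_f = setNames(tab$F, rownames(tab))[c("A", "B", "A:B")],
                 p_value = setNames(tab$`Pr(>F)`,
                                    rownames(tab))[c("A", "B", "A:B")],
                 n_perm = n_perm, seed = seed, adonis_table = tab),
            class = "variance_partition")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values
#' (delegates to [stats::p.adjust()]).
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Pairwise Welch tests with BH adjustment
#'
#' Tests every unordered pair of groups with Welch's unequal-variance
#' t-test and adjusts the p-values by Benjamini-Hochberg.
#'
#' @param y Numeric response.
#' @param groups Group labels, same length as `y`.
#' @param alpha Significance level for the `significant` flag
#'   (default 0.05).
#' @return Data frame with one row per group pair: `group1`, `group2`,
#'   `estimate` (mean difference), `p_value`, `p_adjusted`, `significant`.
#' @export
pairwise_comparisons <- function(y, groups, alpha = 0.05) {
  groups <- factor(groups)
  stopifnot(length(y) == length(groups))
  if (any(table(groups) < 2))
    stop("every group needs at least two observations")
  lev <- levels(groups)
  pairs <- combn(lev, 2)
  res <- apply(pairs, 2, function(pr) {
    a <- y[groups == pr[1]]; b <- y[groups == pr[2]]
    tt <- t.test(a, b, var.equal = FALSE)
    c(estimate = unname(mean(a) - mean(b)), p_value = tt$p.value)
  })
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    estimate = res["estimate", ],
                    p_value = res["p_value", ],
                    stringsAsFactors = FALSE)
  out$p_adjusted <- bh_adjust(out$p_value)
  out$significant <- out$p_adjusted < alpha
  out
}
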