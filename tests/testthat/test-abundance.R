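toy_matrix <- function() {
  v <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 3, byrow = TRUE,
              dimnames = list(c("P1", "P2", "P3"), c("s1", "s2")))
  pa_matrix(v, peptide_count = c(1L, 2L, 3L))
}

test_that("abundance tables round-trip through TSV with missing cells", {
  m <- toy_matrix()
  m$values[2, 1] <- NA
  path <- withr::local_tempfile(fileext = ".tsv")
  write_abundance_table(m, path)
  m2 <- read_abundance_table(path)
  expect_equal(m2$values, m$values)
  expect_equal(m2$peptide_count, m$peptide_count)
  expect_equal(sum(missing_mask(m2)), 1)
})

test_that("reader rejects duplicate accessions and non-numeric cells", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\ts1\ts2", "P1\t1\t2", "P1\t3\t4"), path)
  expect_error(read_abundance_table(path), "P1")
  writeLines(c("protein_id\ts1\ts2", "P1\t1\tabc", "P2\t3\t4"), path)
  expect_error(read_abundance_table(path), "abc")
  writeLines(c("protein_id\ts1\ts2", "P1\t1\t", "P2\t3\t4"), path)
  m <- read_abundance_table(path)
  expect_equal(sum(missing_mask(m)), 1)
})

test_that("peptide-count filter keeps >= min_peptides and reports PA loss", {
  m <- toy_matrix()
  f <- filter_by_peptide_count(m, 2)
  expect_equal(rownames(f$values), c("P2", "P3"))
  expect_equal(attr(f, "pa_loss"), (1 + 2) / sum(m$values))
  expect_equal(filter_by_peptide_count(m, 1)$values, m$values)
})

test_that("missingness filter drops proteins missing in > max_missing samples", {
  v <- matrix(runif(4 * 30, 1, 10), nrow = 4,
              dimnames = list(paste0("P", 1:4), paste0("s", 1:30)))
  v[1, 1:3] <- NA   # 3 missing: dropped
  v[2, 1:2] <- NA   # 2 missing: kept
  m <- pa_matrix(v)
  f <- filter_by_missingness(m, 2)
  expect_equal(rownames(f$values), c("P2", "P3", "P4"))
  complete <- pa_matrix(v[3:4, ])
  expect_equal(filter_by_missingness(complete, 2)$values, complete$values)
})

test_that("chained filters lose at most the sum of the individual losses", {
  set.seed(9)
  v <- matrix(runif(20 * 30, 1, 100), nrow = 20,
              dimnames = list(sprintf("P%02d", 1:20), paste0("s", 1:30)))
  v[3, 1:5] <- NA
  v[7, 1:3] <- NA
  m <- pa_matrix(v, peptide_count = sample(1:4, 20, replace = TRUE))
  m1 <- filter_by_peptide_count(m, 2)
  m2 <- filter_by_missingness(m1, 2)
  total_loss <- 1 - sum(m2$values, na.rm = TRUE) / sum(m$values, na.rm = TRUE)
  expect_lte(total_loss,
             attr(m1, "pa_loss") + attr(m2, "pa_loss") + 1e-12)
})

test_that("total-sum normalization equalizes totals and preserves proportions", {
  v <- matrix(c(4, 6, 10, 20), nrow = 2,
              dimnames = list(c("P1", "P2"), c("s1", "s2")))
  m <- normalize_samples(pa_matrix(v))
  expect_equal(unname(colSums(m$values)), c(20, 20))
  expect_equal(m$values["P1", "s1"] / m$values["P2", "s1"], 4 / 6)
  eq <- pa_matrix(matrix(c(1, 3, 2, 2), nrow = 2,
                         dimnames = list(c("P1", "P2"), c("s1", "s2"))))
  expect_equal(normalize_samples(eq)$values, eq$values)
  bad <- pa_matrix(matrix(c(0, 0, 1, 2), nrow = 2,
                          dimnames = list(c("P1", "P2"), c("s1", "s2"))))
  expect_error(normalize_samples(bad), "non-positive total")
})

test_that("percent of total peak area behaves like a proportion", {
  v <- matrix(c(1, 3, 2, 6), nrow = 2,
              dimnames = list(c("P1", "P2"), c("s1", "s2")))
  m <- pa_matrix(v)
  expect_equal(unname(percent_pa_total(m, c("P1", "P2"))), c(100, 100))
  expect_equal(unname(percent_pa_total(m, "P1")), c(25, 25))
  expect_error(percent_pa_total(m, "PX"), "unknown protein")
  # additivity over disjoint sets, and invariance to per-sample rescaling
  set.seed(1)
  v2 <- matrix(runif(8 * 4, 1, 10), nrow = 8,
               dimnames = list(paste0("P", 1:8), paste0("s", 1:4)))
  m2 <- pa_matrix(v2)
  s1 <- paste0("P", 1:3); s2 <- paste0("P", 4:6)
  expect_equal(percent_pa_total(m2, c(s1, s2)),
               percent_pa_total(m2, s1) + percent_pa_total(m2, s2))
  scaled <- pa_matrix(sweep(v2, 2, c(2, 0.5, 7, 1), `*`))
  expect_equal(percent_pa_total(normalize_samples(scaled), s1),
               percent_pa_total(normalize_samples(m2), s1))
})

test_that("trait-group allocations partition the proteome", {
  set.seed(2)
  v <- matrix(runif(6 * 3, 1, 10), nrow = 6,
              dimnames = list(paste0("P", 1:6), paste0("s", 1:3)))
  m <- pa_matrix(v)
  groups <- data.frame(protein_id = paste0("P", 1:4),
                       group = c("ribosomal", "ribosomal",
                                 "P-acquisition", "heat shock"))
  al <- group_allocations(m, groups)
  num <- al[, setdiff(names(al), "sample_id")]
  expect_equal(unname(rowSums(num)), rep(100, 3))
  expect_true("other" %in% names(al))
  expect_equal(al[["heat shock"]], unname(percent_pa_total(m, "P4")))
  dup <- rbind(groups, data.frame(protein_id = "P1", group = "heat shock"))
  expect_error(group_allocations(m, dup), "more than one group")
})

test_that("top-n share reaches 100% at n = G and recovers a planted share", {
  design <- make_design()
  set.seed(3)
  v <- matrix(runif(20 * 30, 0.9, 1.1), nrow = 20,
              dimnames = list(sprintf("P%02d", 1:20), design$sample_id))
  # plant 10 proteins jointly carrying 90% of the total in every sample
  for (s in 1:30) v[1:10, s] <- 9 * sum(v[11:20, s]) / 10
  m <- pa_matrix(v)
  all_share <- top_n_share(m, design, n = 20)
  expect_equal(all_share$mean, 100)
  expect_equal(all_share$se, 0)
  ten <- top_n_share(m, design, n = 10)
  expect_equal(ten$mean, 90, tolerance = 1e-10)
  expect_error(top_n_share(m, design, n = 21), "exceeds")
})

test_that("log proportional difference centers rows", {
  v <- matrix(exp(c(2, 2, 2, 1, 3, 2)), nrow = 2, byrow = TRUE,
              dimnames = list(c("P1", "P2"), c("s1", "s2", "s3")))
  m <- pa_matrix(v)
  d <- log_prop_diff(m)
  expect_equal(unname(d["P1", ]), c(0, 0, 0))
  expect_equal(unname(d["P2", ]), c(-0.5, 0.5, 0))
  expect_equal(unname(rowMeans(d)), c(0, 0))
  bad <- pa_matrix(matrix(c(0, 1, 1, 1), 2,
                          dimnames = list(c("a", "b"), c("s1", "s2"))))
  expect_error(log_prop_diff(bad), "positive")
})
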