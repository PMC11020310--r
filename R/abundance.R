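#' Protein-by-sample peak-area matrix
#'
#' Container for DIA-MS protein quantifications: a proteins x samples matrix
#' of summed peptide peak areas (arbitrary instrument units), with missing
#' quantifications stored as `NA` and a per-protein count of representative
#' peptides.
#'
#' @param values Numeric matrix, proteins in rows, samples in columns.
#'   Missing cells are `NA`; observed cells must be finite and non-negative.
#' @param peptide_count Integer vector, one entry per protein; defaults to 2
#'   for every protein when unknown.
#' @param protein_ids,sample_ids Character vectors of unique identifiers;
#'   default to the dimnames of `values`.
#' @return An object of class `pa_matrix`.
#' @export
pa_matrix <- function(values, peptide_count = NULL,
                      protein_ids = rownames(values),
                      sample_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(protein_ids))
    protein_ids <- paste0("protein_", seq_len(nrow(values)))
  if (is.null(sample_ids))
    sample_ids <- paste0("sample_", seq_len(ncol(values)))
  if (anyDuplicated(protein_ids))
    stop("duplicate protein ids: ",
         paste(unique(protein_ids[duplicated(protein_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids")
  stopifnot(length(protein_ids) == nrow(values),
            length(sample_ids) == ncol(values))
  obs <- values[!is.na(values)]
  if (length(obs) && (any(!is.finite(obs)) || any(obs < 0)))
    stop("observed peak areas must be finite and >= 0")
  if (is.null(peptide_count)) peptide_count <- rep(2L, nrow(values))
  peptide_count <- as.integer(peptide_count)
  stopifnot(length(peptide_count) == nrow(values))
  dimnames(values) <- list(protein_ids, sample_ids)
  structure(list(values = values, peptide_count = peptide_count),
            class = "pa_matrix")
}

#' @export
print.pa_matrix <- function(x, ...) {
  cat(sprintf("pa_matrix: %d proteins x %d samples (%d missing cells)\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.pa_matrix <- function(x) dim(x$values)

#' Logical mask of missing quantifications
#' @param m A [pa_matrix].
#' @return Logical matrix, `TRUE` where the peak area is missing.
#' @export
missing_mask <- function(m) is.na(m$values)

sentinel_na <- c("", "NA", "NaN", "n/a", "N/A", "missing")

#' Read a protein-by-sample peak-area table
#'
#' Reads a delimited text table with one row per protein. The first column
#' must hold unique protein accessions; an optional `peptide_count` column
#' gives the number of representative peptides (defaulting to 2 when
#' absent); all remaining columns are sample quantifications. Blank cells
#' and the usual NA sentinels become missing values.
#'
#' @param path Path to a TSV/CSV file.
#' @param sep Field separator (default tab).
#' @return A [pa_matrix].
#' @export
read_abundance_table <- function(path, sep = "\t") {
  stopifnot(file.exists(path))
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   na.strings = sentinel_na, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expected a protein id column plus sample columns")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate protein accession(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  df <- df[, -1, drop = FALSE]
  pep <- NULL
  pc <- which(tolower(names(df)) == "peptide_count")
  if (length(pc)) {
    pep <- as.integer(df[[pc[1]]])
    df <- df[, -pc, drop = FALSE]
  }
  vals <- vapply(df, function(col) {
    num <- suppressWarnings(as.numeric(col))
    bad <- !is.na(col) & is.na(num)
    if (any(bad))
      stop("non-numeric value(s) in abundance table: ",
           paste(unique(col[bad]), collapse = ", "))
    num
  }, numeric(nrow(df)))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(ids, names(df)))
  pa_matrix(vals, peptide_count = pep)
}

#' Write a peak-area matrix as TSV
#'
#' Inverse of [read_abundance_table()]: protein ids in the first column,
#' `peptide_count` second, samples after; missing cells written blank.
#'
#' @param m A [pa_matrix].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(m, path) {
  df <- data.frame(protein_id = rownames(m$values),
                   peptide_count = m$peptide_count,
                   m$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Keep proteins quantified by at least `min_peptides` peptides
#'
#' DIA identifications supported by a single peptide are unreliable; the
#' standard filter keeps proteins with two or more representative peptides.
#'
#' @param m A [pa_matrix].
#' @param min_peptides Minimum peptide count (default 2).
#' @return Filtered [pa_matrix] (protein order preserved), with attribute
#'   `"pa_loss"`: the fraction of total summed peak area removed.
#' @export
filter_by_peptide_count <- function(m, min_peptides = 2) {
  keep <- m$peptide_count >= min_peptides
  out <- pa_matrix(m$values[keep, , drop = FALSE],
                   peptide_count = m$peptide_count[keep])
  attr(out, "pa_loss") <- pa_loss_fraction(m$values, keep)
  out
}

#' Drop proteins missing in more than `max_missing` samples
#'
#' Proteins not detected across (nearly) the whole sample set cannot be
#' compared between treatments; the default keeps proteins with at most two
#' missing values over the sample set.
#'
#' @param m A [pa_matrix].
#' @param max_missing Maximum tolerated number of missing cells per protein
#'   (default 2).
#' @return Filtered [pa_matrix] with attribute `"pa_loss"` as in
#'   [filter_by_peptide_count()].
#' @export
filter_by_missingness <- function(m, max_missing = 2) {
  keep <- rowSums(is.na(m$values)) <= max_missing
  out <- pa_matrix(m$values[keep, , drop = FALSE],
                   peptide_count = m$peptide_count[keep])
  attr(out, "pa_loss") <- pa_loss_fraction(m$values, keep)
  out
}

pa_loss_fraction <- function(values, keep) {
  tot <- sum(values, na.rm = TRUE)
  if (tot == 0) return(0)
  sum(values[!keep, , drop = FALSE], na.rm = TRUE) / tot
}

#' Equalize per-sample totals
#'
#' Rescales every sample so that its total observed peak area equals the
#' grand mean of the per-sample totals, removing between-run loading and
#' instrument-response differences while leaving within-sample proportions
#' untouched.
#'
#' @param m A [pa_matrix].
#' @param method Normalization rule; `"total_sum"` (the default and
#'   currently only method) equalizes totals to the grand mean total.
#' @return Normalized [pa_matrix] with attribute `"normalization"`.
#' @export
normalize_samples <- function(m, method = c("total_sum")) {
  method <- match.arg(method)
  totals <- colSums(m$values, na.rm = TRUE)
  if (any(totals <= 0))
    stop("sample(s) with non-positive total peak area: ",
         paste(colnames(m$values)[totals <= 0], collapse = ", "))
  target <- mean(totals)
  out <- pa_matrix(sweep(m$values, 2, target / totals, `*`),
                   peptide_count = m$peptide_count)
  attr(out, "normalization") <- list(method = method, target_total = target)
  out
}

#' Percent of total peak area for a protein set
#'
#' The proteome allocation metric: for each sample, the summed peak area of
#' the query proteins divided by the summed peak area of all retained
#' proteins, times 100. Missing cells contribute zero to both sums.
#'
#' @param m A [pa_matrix] (already filtered/normalized).
#' @param protein_set Character vector of protein ids to aggregate.
#' @return Named numeric vector (one % value per sample), in \[0, 100\].
#' @export
percent_pa_total <- function(m, protein_set) {
  unknown <- setdiff(protein_set, rownames(m$values))
  if (length(unknown))
    stop("unknown protein id(s): ", paste(unknown, collapse = ", "))
  pa_total <- colSums(m$values, na.rm = TRUE)
  pa_set <- colSums(m$values[protein_set, , drop = FALSE], na.rm = TRUE)
  100 * pa_set / pa_total
}

#' Trait-group allocation table
#'
#' Sums [percent_pa_total()] over proteins within each trait group (e.g.
#' P-acquisition, ribosomal, heat shock), per sample. Retained proteins not
#' present in the map are reported under `"other"`.
#'
#' @param m A [pa_matrix].
#' @param groups Data frame with columns `protein_id` and `group`, mapping
#'   each protein to at most one trait group.
#' @return Data frame, samples in rows, one column per group (percent of
#'   total peak area); rows sum to 100 when every protein is mapped or
#'   falls into `"other"`.
#' @export
group_allocations <- function(m, groups) {
  stopifnot(all(c("protein_id", "group") %in% names(groups)))
  if (anyDuplicated(groups$protein_id))
    stop("protein(s) mapped to more than one group")
  groups <- groups[groups$protein_id %in% rownames(m$values), , drop = FALSE]
  lab <- setNames(as.character(groups$group), groups$protein_id)
  g <- lab[rownames(m$values)]
  g[is.na(g)] <- "other"
  out <- sapply(sort(unique(g)), function(gr)
    percent_pa_total(m, rownames(m$values)[g == gr]))
  out <- as.data.frame(out, check.names = FALSE)
  cbind(sample_id = colnames(m$values), out, row.names = NULL)
}

#' Share of the proteome held by the most abundant proteins
#'
#' Ranks proteins by mean peak area across all samples, sums the percent of
#' total peak area of the top `n` within each sample, averages within
#' treatment, and reports the mean and standard error across treatments.
#'
#' @param m A [pa_matrix].
#' @param design Sample design from [make_design()] (matched by sample id);
#'   treatments are `nutrient_regime` x `temperature` cells.
#' @param n Number of top proteins (default 100).
#' @return List with `mean` and `se` (percent of total peak area), plus the
#'   per-treatment shares in `per_treatment`.
#' @export
top_n_share <- function(m, design, n = 100) {
  if (n > nrow(m$values)) stop("n exceeds the number of proteins")
  mean_pa <- rowMeans(m$values, na.rm = TRUE)
  top <- rownames(m$values)[order(mean_pa, decreasing = TRUE)][seq_len(n)]
  share <- percent_pa_total(m, top)
  idx <- match(colnames(m$values), design$sample_id)
  stopifnot(!anyNA(idx))
  treat <- interaction(design$nutrient_regime[idx],
                       design$temperature[idx], drop = TRUE)
  per_treat <- tapply(share, treat, mean)
  se <- if (length(per_treat) > 1)
    sd(per_treat) / sqrt(length(per_treat)) else 0
  list(mean = mean(per_treat), se = se, per_treatment = per_treat)
}

#' Proportional difference from the mean log peak area
#'
#' For each protein, expresses every sample's log peak area as a
#' proportional deviation from that protein's mean log peak area across all
#' samples (missing cells ignored in the mean and returned as `NA`). This
#' mean-free representation is used to order and compare proteins by
#' response pattern rather than absolute abundance.
#'
#' @param m A [pa_matrix] with strictly positive observed values.
#' @return Numeric matrix of the same dimension as `m`.
#' @export
log_prop_diff <- function(m) {
  v <- m$values
  if (any(v[!is.na(v)] <= 0))
    stop("log_prop_diff requires strictly positive peak areas")
  lv <- log(v)
  mu <- rowMeans(lv, na.rm = TRUE)
  (lv - mu) / mu
}
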