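#' Multi-tissue expression matrix
#'
#' Bundles a genes x samples matrix of non-negative expression values
#' (e.g. TPM) with a sample -> tissue map. At least two distinct tissues are
#' required, since the Tau tissue-specificity index is undefined otherwise.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene IDs), samples
#'   in columns (colnames = sample IDs). All values must be `>= 0`.
#' @param tissues Character vector of tissue labels, one per sample, either
#'   named by sample ID or in column order.
#' @return An object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, tissues) {
  values <- as.matrix(values)
  if (any(values < 0, na.rm = TRUE)) stop("expression values must be non-negative")
  if (is.null(rownames(values))) stop("values must have gene IDs as rownames")
  if (is.null(colnames(values))) stop("values must have sample IDs as colnames")
  if (is.null(names(tissues))) {
    if (length(tissues) != ncol(values)) stop("one tissue label per sample required")
    names(tissues) <- colnames(values)
  }
  missing <- setdiff(colnames(values), names(tissues))
  if (length(missing) > 0L) {
    stop(sprintf("samples without a tissue label: %s", paste(missing, collapse = ", ")))
  }
  tissues <- as.character(tissues[colnames(values)])
  if (length(unique(tissues)) < 2L) stop("at least 2 distinct tissues required")
  structure(list(values = values, tissues = setNames(tissues, colnames(values))),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, %d tissues\n",
              nrow(x$values), ncol(x$values), length(unique(x$tissues))))
  invisible(x)
}

#' Read an expression matrix and sample->tissue map from TSV files
#'
#' @param expr_path TSV with a header row of sample IDs and gene IDs in the
#'   first column.
#' @param tissue_path Two-column TSV (sample, tissue), no header required; a
#'   header line `sample<TAB>tissue` is tolerated.
#' @return An `expr_matrix`.
#' @export
read_expression_tsv <- function(expr_path, tissue_path) {
  df <- read.table(expr_path, header = TRUE, sep = "\t", row.names = 1,
                   check.names = FALSE)
  tt <- read.table(tissue_path, header = FALSE, sep = "\t",
                   col.names = c("sample", "tissue"), colClasses = "character")
  if (nrow(tt) > 0 && identical(tolower(tt$sample[1]), "sample")) tt <- tt[-1, ]
  expression_matrix(as.matrix(df), setNames(tt$tissue, tt$sample))
}

#' Log-transform expression values with low-expression zeroing
#'
#' `y = log2(x + 1)`; transformed values below 1 are set to 0, so raw values
#' below 1 (log2 of at most 0.93) contribute nothing downstream. This is the
#' transform applied before Tau, tissue aggregation, z-scores, and the
#' regression target.
#'
#' @param raw Non-negative numeric vector or matrix.
#' @param zero_below Transformed values strictly below this are zeroed
#'   (default 1).
#' @return Transformed values, same shape as `raw`.
#' @export
log_transform <- function(raw, zero_below = 1) {
  if (any(raw < 0, na.rm = TRUE)) stop("expression values must be non-negative")
  y <- log2(raw + 1)
  y[y < zero_below] <- 0
  y
}

#' Per-tissue profile of a gene (median of log-transformed samples)
#'
#' Replicate samples of each tissue are aggregated as the median of their
#' log-transformed values.
#'
#' @param em An `expr_matrix`.
#' @param gene_id Gene ID present in `em`.
#' @return A list with `gene_id`, `tissue_values` (named numeric, sorted by
#'   tissue name), and `n_tissues`.
#' @export
aggregate_by_tissue <- function(em, gene_id) {
  if (!gene_id %in% rownames(em$values)) stop(sprintf("unknown gene: %s", gene_id))
  lg <- log_transform(em$values[gene_id, ])
  vals <- tapply(lg, em$tissues, median)
  vals <- vals[sort(names(vals))]
  list(gene_id = gene_id, tissue_values = vals, n_tissues = length(vals))
}

## all genes at once: genes x tissues matrix of per-tissue medians of log values
tissue_profile_matrix <- function(em) {
  lg <- log_transform(em$values)
  tissues <- sort(unique(em$tissues))
  out <- vapply(tissues, function(tt) {
    cols <- which(em$tissues == tt)
    apply(lg[, cols, drop = FALSE], 1, median)
  }, numeric(nrow(lg)))
  if (nrow(lg) == 1L) out <- matrix(out, nrow = 1, dimnames = list(rownames(lg), tissues))
  out
}

#' Tau tissue-specificity index
#'
#' `tau = sum_i (1 - x_i / max_j x_j) / (n - 1)` over `n >= 2` tissue values.
#' Tau is 1 for a gene expressed in exactly one tissue, 0 for a perfectly
#' uniform profile, lies in `[0, 1]` otherwise, and is invariant to positive
#' rescaling of the profile.
#'
#' @param tissue_values Non-negative numeric vector of per-tissue (log)
#'   expression, length >= 2.
#' @return Tau in `[0, 1]`, or `NA` for an all-zero profile (such genes are
#'   excluded from classification).
#' @export
compute_tau <- function(tissue_values) {
  x <- as.numeric(tissue_values)
  if (length(x) < 2L) stop("Tau requires at least 2 tissues")
  if (any(x < 0)) stop("tissue values must be non-negative")
  mx <- max(x)
  if (mx == 0) return(NA_real_)
  sum(1 - x / mx) / (length(x) - 1)
}

#' Classify tissue specificity for every gene
#'
#' Computes Tau on the per-tissue median log profile, the top tissue
#' (argmax, ties broken by lexicographic tissue name), and the
#' tissue-specific flag (`tau > tau_threshold`, strict). All-zero genes get
#' `tau = NA`, an `NA` top tissue, and are never tissue-specific.
#'
#' @param em An `expr_matrix`.
#' @param tau_threshold Strict lower bound for calling a gene
#'   tissue-specific (default 0.85).
#' @return A data.frame with columns `gene_id`, `tau`, `top_tissue`,
#'   `top_value`, `is_tissue_specific`.
#' @export
classify_genes <- function(em, tau_threshold = 0.85) {
  prof <- tissue_profile_matrix(em)
  tissues <- colnames(prof)
  tau <- apply(prof, 1, compute_tau)
  top_idx <- apply(prof, 1, which.max)  # ties: first = lexicographically smallest
  top_tissue <- tissues[top_idx]
  top_value <- prof[cbind(seq_len(nrow(prof)), top_idx)]
  all_zero <- is.na(tau)
  top_tissue[all_zero] <- NA_character_
  data.frame(
    gene_id = rownames(prof),
    tau = tau,
    top_tissue = top_tissue,
    top_value = ifelse(all_zero, 0, top_value),
    is_tissue_specific = !all_zero & tau > tau_threshold,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Expression-level tiers relative to the population
#'
#' A gene's pollen expression is `extremely_high` if more than 3 population
#' standard deviations above the mean of all genes' pollen values, `high` if
#' between 2 and 3, and `other` otherwise. With a degenerate population
#' (zero standard deviation) every gene is `other`.
#'
#' @param values Numeric vector of per-gene expression values (the genes to
#'   tier).
#' @param population Numeric vector defining mean/sd (defaults to `values`).
#' @return Character vector of tiers, same length as `values`.
#' @export
expression_tier <- function(values, population = values) {
  mu <- mean(population)
  sdev <- sqrt(mean((population - mu)^2))  # population sd
  if (sdev == 0) return(rep("other", length(values)))
  ifelse(values > mu + 3 * sdev, "extremely_high",
         ifelse(values > mu + 2 * sdev, "high", "other"))
}

#' Select pollen-specific foreground and non-pollen background gene sets
#'
#' Foreground: HRGP genes with `tau > tau_threshold` whose top tissue is
#' pollen. Background: HRGP genes whose aggregated pollen expression is 0
#' after the log transform ("not expressed in pollen"). The two sets are
#' disjoint by construction. HRGP IDs absent from the matrix are skipped
#' with a message.
#'
#' @param em An `expr_matrix`.
#' @param hrgp_ids Character vector of gene IDs to consider.
#' @param pollen_tissue Tissue label identifying pollen samples.
#' @param tau_threshold Passed to [classify_genes()].
#' @return A list with `pollen_specific`, `non_pollen` (character vectors),
#'   and `classification` (the [classify_genes()] table restricted to
#'   `hrgp_ids`, with a `pollen_value` column appended).
#' @export
select_gene_sets <- function(em, hrgp_ids, pollen_tissue = "pollen",
                             tau_threshold = 0.85) {
  present <- hrgp_ids %in% rownames(em$values)
  if (any(!present)) {
    message(sprintf("skipping %d HRGP id(s) absent from the matrix", sum(!present)))
  }
  ids <- hrgp_ids[present]
  if (length(ids) == 0L) stop("no HRGP ids present in the expression matrix")
  prof <- tissue_profile_matrix(em)
  if (!pollen_tissue %in% colnames(prof)) {
    stop(sprintf("no samples labelled '%s'", pollen_tissue))
  }
  cls <- classify_genes(em, tau_threshold)
  cls <- cls[match(ids, cls$gene_id), ]
  cls$pollen_value <- prof[ids, pollen_tissue]
  fg <- cls$gene_id[cls$is_tissue_specific & !is.na(cls$top_tissue) &
                      cls$top_tissue == pollen_tissue]
  bg <- cls$gene_id[cls$pollen_value == 0]
  bg <- setdiff(bg, fg)
  list(pollen_specific = fg, non_pollen = bg, classification = cls)
}

#' Per-gene z-scores of log expression across samples
#'
#' Standardizes each gene's log-transformed sample values to mean 0 and
#' population standard deviation 1 (rows with zero variance become all
#' zeros). This is the matrix behind tissue-expression heatmaps.
#'
#' @param em An `expr_matrix`.
#' @return Numeric matrix, genes x samples.
#' @export
zscore_matrix <- function(em) {
  lg <- log_transform(em$values)
  mu <- rowMeans(lg)
  sdev <- sqrt(rowMeans((lg - mu)^2))
  z <- (lg - mu) / ifelse(sdev == 0, 1, sdev)
  z[sdev == 0, ] <- 0
  z
}

#' Mean pollen log expression per gene (regression target)
#'
#' @param em An `expr_matrix`.
#' @param genes Gene IDs to report (must be present in `em`).
#' @param pollen_tissue Tissue label identifying pollen samples.
#' @return Named numeric vector: mean of log-transformed pollen-sample
#'   values per gene.
#' @export
build_target <- function(em, genes = rownames(em$values), pollen_tissue = "pollen") {
  cols <- which(em$tissues == pollen_tissue)
  if (length(cols) == 0L) stop(sprintf("no samples labelled '%s'", pollen_tissue))
  missing <- setdiff(genes, rownames(em$values))
  if (length(missing) > 0L) stop("genes absent from matrix: ", paste(missing, collapse = ", "))
  lg <- log_transform(em$values[genes, cols, drop = FALSE])
  setNames(rowMeans(lg), genes)
}
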