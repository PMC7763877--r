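## Log-odds score matrix (4 x w, base 2) for a motif against a background.
## A small floor keeps log2 finite for zero-probability cells.
score_matrix <- function(m, bg, floor_prob = 1e-4) {
  p <- pmax(m$probs, floor_prob)
  p <- sweep(p, 2, colSums(p), "/")
  log2(sweep(p, 1, bg, "/"))
}

#' Log-odds score of a motif against a single window
#'
#' `sum_j log2(p_j(base_j) / bg(base_j))` over the motif's columns. `N`
#' (or any non-ACGT character) contributes 0, i.e. scores as background.
#'
#' @param m A [motif()].
#' @param window String of length `motif_width(m)`.
#' @param bg Background model.
#' @return Numeric log-odds score (bits).
#' @export
score_window <- function(m, window, bg = background_model()) {
  codes <- encode_seq(window)
  if (length(codes) != motif_width(m)) {
    stop(sprintf("window length %d != motif width %d", length(codes), motif_width(m)))
  }
  sm <- score_matrix(m, bg)
  idx <- cbind(codes, seq_along(codes))
  sum(sm[idx[!is.na(codes), , drop = FALSE]])
}

#' Exact null distribution of motif scores (dynamic programming)
#'
#' Discretizes the per-column log-odds scores onto a shared integer grid and
#' convolves the per-column score distributions under an iid background,
#' yielding the exact p-value `P(S >= s)` for every achievable discretized
#' score — the standard construction behind FIMO-style scanning. The maximum
#' discretization error of a reported score is `w * granularity / 2`.
#'
#' @param m A [motif()].
#' @param bg Background model.
#' @param n_bins Number of grid points spanning the motif's score range
#'   (default 10000; granularity = range / n_bins).
#' @return A list with `pvalue` (survival function over the integer grid),
#'   `int_score` function mapping a window's integer column codes to a grid
#'   index, `offset`/`granularity` for score reconstruction, and
#'   `int_matrix` (4 x w integer column scores).
#' @export
score_pvalue_table <- function(m, bg = background_model(), n_bins = 10000L) {
  sm <- score_matrix(m, bg)
  w <- ncol(sm)
  col_min <- apply(sm, 2, min)
  col_max <- apply(sm, 2, max)
  rng <- sum(col_max) - sum(col_min)
  gran <- if (rng > 0) rng / n_bins else 1
  int_m <- round(sweep(sm, 2, col_min, "-") / gran)  # 4 x w, non-negative ints
  storage.mode(int_m) <- "integer"
  max_total <- sum(apply(int_m, 2, max))
  ## pmf over integer total score 0..max_total
  pmf <- numeric(max_total + 1L)
  pmf[1] <- 1
  for (j in seq_len(w)) {
    new <- numeric(max_total + 1L)
    for (b in 1:4) {
      s <- int_m[b, j]
      new[(1L + s):(max_total + 1L)] <- new[(1L + s):(max_total + 1L)] +
        pmf[1:(max_total + 1L - s)] * bg[b]
    }
    pmf <- new
  }
  surv <- rev(cumsum(rev(pmf)))
  surv <- pmin(surv, 1)
  list(
    pvalue = surv,                      # surv[k+1] = P(int score >= k)
    granularity = gran,
    offset = sum(col_min),
    int_matrix = int_m,
    width = w
  )
}

## p-value of an integer total score under a score_pvalue_table
lookup_pvalue <- function(tab, int_total) {
  k <- pmin(pmax(int_total, 0L), length(tab$pvalue) - 1L)
  tab$pvalue[k + 1L]
}

## integer + real window scores at every start position of an encoded sequence
window_scores <- function(codes, sm, int_m) {
  w <- ncol(sm)
  n <- length(codes) - w + 1L
  if (n < 1L) return(NULL)
  real <- numeric(n)
  intg <- integer(n)
  sm5 <- rbind_na0(sm)     # 5th row: 0 for N
  int5 <- rbind_na0(int_m) # N contributes the column minimum (index 0)
  codes5 <- ifelse(is.na(codes), 5L, codes)
  for (j in seq_len(w)) {
    idx <- codes5[j:(j + n - 1L)]
    real <- real + sm5[idx, j]
    intg <- intg + int5[idx, j]
  }
  list(real = real, int = intg)
}

rbind_na0 <- function(mat) rbind(mat, 0)

#' Scan sequences with a motif (FIMO-style)
#'
#' Scores every window on one or both strands, converts scores to exact
#' p-values via [score_pvalue_table()], and reports occurrences with
#' `pvalue < p_threshold`. Sequences shorter than the motif are skipped with
#' a warning.
#'
#' @param m A [motif()].
#' @param seqs Named character vector of promoter sequences.
#' @param bg Background model.
#' @param p_threshold Report windows with p-value strictly below this
#'   (default `1e-4`, the conventional scanning cutoff).
#' @param strands `"both"` (default) or `"forward"`.
#' @return A data.frame (class `occurrence_set`) with columns `gene_id`,
#'   `start` (0-based on the forward strand), `strand`, `score` (log2
#'   log-odds), `pvalue`, sorted by gene then p-value. Attribute
#'   `motif_name` records the motif.
#' @export
scan_motif <- function(m, seqs, bg = background_model(), p_threshold = 1e-4,
                       strands = c("both", "forward")) {
  strands <- match.arg(strands)
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%d", seq_along(seqs))
  sm <- score_matrix(m, bg)
  tab <- score_pvalue_table(m, bg)
  w <- ncol(sm)
  out <- vector("list", length(seqs))
  short <- character(0)
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    if (nchar(s) < w) {
      short <- c(short, names(seqs)[i])
      next
    }
    codes <- encode_seq(s)
    fw <- window_scores(codes, sm, tab$int_matrix)
    res <- data.frame(start = seq_along(fw$real) - 1L, strand = "+",
                      score = fw$real, pvalue = lookup_pvalue(tab, fw$int),
                      stringsAsFactors = FALSE)
    if (strands == "both") {
      rc_codes <- rev(5L - ifelse(is.na(codes), NA_integer_, codes))
      rc_codes[is.na(rc_codes)] <- NA_integer_
      rv <- window_scores(rc_codes, sm, tab$int_matrix)
      n_win <- length(rv$real)
      ## window k (1-based) on rc strand starts at forward position L - k - w + 1 (0-based)
      res_rc <- data.frame(start = nchar(s) - seq_len(n_win) - w + 1L, strand = "-",
                           score = rv$real, pvalue = lookup_pvalue(tab, rv$int),
                           stringsAsFactors = FALSE)
      res <- rbind(res, res_rc)
    }
    res <- res[res$pvalue < p_threshold, , drop = FALSE]
    if (nrow(res) > 0L) {
      res$gene_id <- names(seqs)[i]
      out[[i]] <- res
    }
  }
  if (length(short) > 0L) {
    warning(sprintf("%d sequence(s) shorter than the motif were skipped", length(short)))
  }
  occ <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(occ)) {
    occ <- data.frame(gene_id = character(0), start = integer(0),
                      strand = character(0), score = numeric(0), pvalue = numeric(0))
  } else {
    occ <- occ[, c("gene_id", "start", "strand", "score", "pvalue")]
    occ <- occ[order(occ$gene_id, occ$pvalue, occ$start), ]
    rownames(occ) <- NULL
  }
  attr(occ, "motif_name") <- m$name
  class(occ) <- c("occurrence_set", "data.frame")
  occ
}

#' Best occurrence per gene
#' @param occ An occurrence set from [scan_motif()].
#' @return One row per gene: the lowest-p-value occurrence.
#' @export
best_per_gene <- function(occ) {
  if (nrow(occ) == 0L) return(occ)
  occ[!duplicated(occ$gene_id), , drop = FALSE]  # already sorted by gene, pvalue
}

#' Foreground/background coverage statistics for a motif
#'
#' A gene is covered if it has at least one occurrence at the scan
#' threshold, counted once regardless of multiplicity. Percentages are
#' rounded to the nearest integer; the relative frequency is the unrounded
#' foreground coverage fraction divided by the background fraction
#' (`Inf` when no background gene is hit).
#'
#' @param motif_name Motif name for the report row.
#' @param fg_occ,bg_occ Occurrence sets on the foreground and background
#'   promoter sets.
#' @param fg_total,bg_total Number of genes in each set (must be positive).
#' @return A one-row data.frame: `motif_name`, `fg_hits`, `fg_total`,
#'   `fg_coverage_pct`, `bg_hits`, `bg_total`, `bg_coverage_pct`,
#'   `relative_frequency`.
#' @export
coverage_stats <- function(motif_name, fg_occ, bg_occ, fg_total, bg_total) {
  if (fg_total <= 0 || bg_total <= 0) stop("gene set totals must be positive")
  fg_hits <- length(unique(fg_occ$gene_id))
  bg_hits <- length(unique(bg_occ$gene_id))
  data.frame(
    motif_name = motif_name,
    fg_hits = fg_hits, fg_total = fg_total,
    fg_coverage_pct = round_half_up(100 * fg_hits / fg_total),
    bg_hits = bg_hits, bg_total = bg_total,
    bg_coverage_pct = round_half_up(100 * bg_hits / bg_total),
    relative_frequency = if (bg_hits == 0) Inf else
      (fg_hits / fg_total) / (bg_hits / bg_total),
    stringsAsFactors = FALSE
  )
}

## deterministic nearest-integer rounding (.5 always up), unlike round()'s
## round-half-even
round_half_up <- function(x) floor(x + 0.5)

#' Motif-scan feature matrix for regression
#'
#' Entry (gene, motif) = `-log10` of the best (lowest) occurrence p-value of
#' that motif on the gene's promoter, or 0 if the motif has no occurrence
#' below the scan threshold — absence is treated as uninformative.
#'
#' @param motifs List of [motif()] objects.
#' @param promoters Named character vector of promoter sequences.
#' @param bg Background model.
#' @param p_threshold Scan threshold (see [scan_motif()]).
#' @return Numeric matrix, genes x motifs (dimnames from inputs).
#' @export
feature_matrix <- function(motifs, promoters, bg = background_model(),
                           p_threshold = 1e-4) {
  out <- matrix(0, nrow = length(promoters), ncol = length(motifs),
                dimnames = list(names(promoters),
                                vapply(motifs, function(m) m$name, character(1))))
  for (m in motifs) {
    occ <- best_per_gene(scan_motif(m, promoters, bg, p_threshold))
    if (nrow(occ) > 0L) out[occ$gene_id, m$name] <- -log10(occ$pvalue)
  }
  out
}

#' Write an occurrence set as a 6-column TSV
#'
#' Columns: gene, start (0-based), end (half-open), strand, score, p-value.
#'
#' @param occ Occurrence set.
#' @param width Motif width (to compute `end`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occ, width, path) {
  df <- data.frame(gene = occ$gene_id, start = occ$start, end = occ$start + width,
                   strand = occ$strand,
                   score = sprintf("%.4f", occ$score),
                   pvalue = sprintf("%.3e", occ$pvalue))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
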