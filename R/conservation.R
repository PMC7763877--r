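#' Alignment parameters for promoter pairs
#'
#' Global (Needleman-Wunsch) alignment with affine gaps: a gap of length L
#' costs `gap_open + L * gap_extend`. Defaults follow the conventional
#' promoter-alignment setting of gap open 10 / extension 0.1, with
#' match +2 / mismatch -1 substitution scores.
#'
#' @param match,mismatch Substitution scores.
#' @param gap_open,gap_extend Gap penalties (non-negative).
#' @return List of class `align_params`.
#' @export
align_params <- function(match = 2, mismatch = -1, gap_open = 10, gap_extend = 0.1) {
  if (gap_open < 0 || gap_extend < 0) stop("gap penalties must be non-negative")
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "align_params")
}

#' Globally align two orthologous promoter sequences
#'
#' Needleman-Wunsch with affine gap penalties (via Biostrings), plus the
#' column maps needed to ask whether motif occurrences fall at the same
#' alignment position in both species.
#'
#' @param a,b Non-empty DNA sequences (species A = the scanned species,
#'   species B = the ortholog).
#' @param params An [align_params()].
#' @param gene_id Optional identifier carried on the result.
#' @return An `ortholog_pair`: list with `gene_id`, `seq_a`, `seq_b`,
#'   `aln_a`, `aln_b` (gapped strings of equal length), `score`, and
#'   `col_map_a`, `col_map_b` (strictly increasing maps from 1-based
#'   sequence position to alignment column).
#' @export
align_pair <- function(a, b, params = align_params(), gene_id = NA_character_) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) == 0L || nchar(b) == 0L) stop("cannot align an empty sequence")
  sub <- Biostrings::nucleotideSubstitutionMatrix(
    match = params$match, mismatch = params$mismatch, baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    substitutionMatrix = sub, gapOpening = params$gap_open,
    gapExtension = params$gap_extend, type = "global")
  aln_a <- as.character(Biostrings::alignedPattern(pa))
  aln_b <- as.character(Biostrings::alignedSubject(pa))
  structure(list(
    gene_id = gene_id, seq_a = a, seq_b = b,
    aln_a = aln_a, aln_b = aln_b,
    score = Biostrings::score(pa),
    col_map_a = which(strsplit(aln_a, "")[[1]] != "-"),
    col_map_b = which(strsplit(aln_b, "")[[1]] != "-")
  ), class = "ortholog_pair")
}

#' @export
print.ortholog_pair <- function(x, ...) {
  ident <- mean(strsplit(x$aln_a, "")[[1]] == strsplit(x$aln_b, "")[[1]])
  cat(sprintf("<ortholog_pair> %s: %d columns, score %.1f, identity %.1f%%\n",
              x$gene_id, nchar(x$aln_a), x$score, 100 * ident))
  invisible(x)
}

#' Is a motif occurrence conserved in the orthologous promoter?
#'
#' An occurrence on species A is conserved if the species-B promoter carries
#' an occurrence of the same motif (same scan settings) whose start maps to
#' the same alignment column, within a tolerance of `tol` columns that
#' absorbs alignment ambiguity around the site.
#'
#' @param occ One occurrence row (from [scan_motif()]) on `pair$seq_a`.
#' @param pair An [align_pair()] result.
#' @param m The scanned [motif()].
#' @param bg,p_threshold,strands Scan settings, applied identically to the
#'   ortholog.
#' @param tol Position tolerance in alignment columns (default 3).
#' @param b_occ Optional pre-computed occurrence set on `pair$seq_b` (to
#'   avoid rescanning when testing many occurrences of one gene).
#' @return Logical.
#' @export
is_conserved <- function(occ, pair, m, bg = background_model(),
                         p_threshold = 1e-4, strands = "both", tol = 3L,
                         b_occ = NULL) {
  if (occ$start < 0 || occ$start + motif_width(m) > nchar(pair$seq_a)) {
    stop("occurrence lies outside the species-A promoter")
  }
  if (is.null(b_occ)) {
    b_occ <- scan_motif(m, setNames(pair$seq_b, "b"), bg, p_threshold, strands)
  }
  if (nrow(b_occ) == 0L) return(FALSE)
  col_a <- pair$col_map_a[occ$start + 1L]
  cols_b <- pair$col_map_b[b_occ$start + 1L]
  any(abs(cols_b - col_a) <= tol)
}

#' Motif-level conservation call over the foreground gene set
#'
#' A motif is conserved if at least `min_frac` of the foreground genes
#' carrying it have at least one conserved occurrence. Genes without an
#' ortholog pair are excluded from the denominator.
#'
#' @param m A [motif()].
#' @param occs Occurrence set of `m` on the species-A foreground promoters.
#' @param pairs Named list of [align_pair()] results (names = gene IDs).
#' @param min_frac Minimum conserved-gene fraction (default 0.5).
#' @param bg,p_threshold,strands,tol Passed to [is_conserved()].
#' @return Logical, with attribute `detail`: data.frame (gene_id, conserved).
#' @export
motif_is_conserved <- function(m, occs, pairs, min_frac = 0.5,
                               bg = background_model(), p_threshold = 1e-4,
                               strands = "both", tol = 3L) {
  genes <- unique(occs$gene_id)
  genes_with_pair <- intersect(genes, names(pairs))
  skipped <- setdiff(genes, genes_with_pair)
  if (length(skipped) > 0L) {
    message(sprintf("motif %s: %d gene(s) without an ortholog excluded",
                    m$name, length(skipped)))
  }
  detail <- data.frame(gene_id = character(0), conserved = logical(0))
  if (length(genes_with_pair) > 0L) {
    conserved <- vapply(genes_with_pair, function(g) {
      pair <- pairs[[g]]
      b_occ <- scan_motif(m, setNames(pair$seq_b, g), bg, p_threshold, strands)
      g_occ <- occs[occs$gene_id == g, , drop = FALSE]
      any(vapply(seq_len(nrow(g_occ)), function(r) {
        is_conserved(g_occ[r, ], pair, m, bg, p_threshold, strands, tol, b_occ)
      }, logical(1)))
    }, logical(1))
    detail <- data.frame(gene_id = genes_with_pair, conserved = conserved,
                         row.names = NULL, stringsAsFactors = FALSE)
  }
  ok <- nrow(detail) > 0L && mean(detail$conserved) >= min_frac
  attr(ok, "detail") <- detail
  ok
}

## Brute-force optimal global alignment score with affine gaps, for tiny
## strings: enumerates all alignments recursively. Oracle for align_pair.
brute_force_align_score <- function(a, b, params = align_params()) {
  a <- strsplit(toupper(a), "")[[1]]
  b <- strsplit(toupper(b), "")[[1]]
  gap_cost <- function(len) if (len == 0) 0 else params$gap_open + len * params$gap_extend
  rec <- function(i, j, state) {
    ## state: 0 = diagonal, 1 = in gap of b (a consumed), 2 = in gap of a
    if (i > length(a) && j > length(b)) return(0)
    best <- -Inf
    if (i <= length(a) && j <= length(b)) {
      s <- if (a[i] == b[j]) params$match else params$mismatch
      best <- max(best, s + rec(i + 1, j + 1, 0))
    }
    if (i <= length(a)) {
      open <- if (state == 1) 0 else params$gap_open
      best <- max(best, -open - params$gap_extend + rec(i + 1, j, 1))
    }
    if (j <= length(b)) {
      open <- if (state == 2) 0 else params$gap_open
      best <- max(best, -open - params$gap_extend + rec(i, j + 1, 2))
    }
    best
  }
  rec(1, 1, 0)
}
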