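#' @importFrom stats cor median sd setNames phyper cor.test rnorm runif var predict
#' @importFrom utils head read.table write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Construct a motif object
#'
#' A motif is a position probability matrix over the DNA alphabet together
#' with a name, the (effective) number of sites it was built from, and a
#' provenance tag. Columns are motif positions; rows are A, C, G, T.
#'
#' @param name Motif name (unique within a collection).
#' @param probs 4 x L column-stochastic matrix (rows A,C,G,T). If `NULL`,
#'   derived from `counts` with a pseudocount of 0.25 per base.
#' @param counts Optional 4 x L non-negative count matrix.
#' @param nsites Number of sites behind the matrix (defaults to the column
#'   sum of `counts`, or 20).
#' @param source Provenance: `"discovered"`, `"known_db"`, or `"iupac"`.
#' @return An object of class `motif`.
#' @export
motif <- function(name, probs = NULL, counts = NULL, nsites = NULL,
                  source = c("discovered", "known_db", "iupac")) {
  source <- match.arg(source)
  if (is.null(probs)) {
    if (is.null(counts)) stop("either `probs` or `counts` must be given")
    counts <- as.matrix(counts)
    if (any(counts < 0)) stop("counts must be non-negative")
    probs <- sweep(counts + 0.25, 2, colSums(counts) + 1, "/")
  }
  probs <- as.matrix(probs)
  if (nrow(probs) != 4L) stop("probs must have 4 rows (A,C,G,T)")
  if (any(probs < 0)) stop("probs must be non-negative")
  cs <- colSums(probs)
  if (any(abs(cs - 1) > 1e-3)) {
    warning(sprintf("motif '%s': %d column(s) did not sum to 1; renormalized",
                    name, sum(abs(cs - 1) > 1e-3)))
  }
  probs <- sweep(probs, 2, cs, "/")
  rownames(probs) <- DNA_BASES
  if (is.null(nsites)) {
    nsites <- if (!is.null(counts)) max(1, round(mean(colSums(counts)))) else 20L
  }
  structure(
    list(name = name, probs = probs, counts = counts,
         nsites = as.integer(nsites), source = source),
    class = "motif"
  )
}

#' @export
print.motif <- function(x, ...) {
  cat(sprintf("<motif> %s  (%d columns, nsites=%d, source=%s)\n",
              x$name, ncol(x$probs), x$nsites, x$source))
  cat("consensus:", motif_consensus(x), "\n")
  invisible(x)
}

#' Motif width (number of columns)
#' @param m A `motif`.
#' @return Integer width.
#' @export
motif_width <- function(m) ncol(m$probs)

#' Majority-base consensus string of a motif
#' @param m A `motif`.
#' @return Character scalar over A,C,G,T.
#' @export
motif_consensus <- function(m) {
  paste(DNA_BASES[apply(m$probs, 2, which.max)], collapse = "")
}

#' Build a motif from an IUPAC consensus string
#'
#' Each degenerate symbol becomes a column uniform over its base set
#' (e.g. `R` -> 1/2 A, 1/2 G; `D` -> 1/3 each of A, G, T).
#'
#' @param consensus String over the IUPAC DNA alphabet.
#' @param name Motif name; defaults to the consensus itself.
#' @param nsites Effective site count recorded on the motif.
#' @return A `motif` with `source = "iupac"`.
#' @export
iupac_to_motif <- function(consensus, name = consensus, nsites = 20L) {
  chars <- strsplit(toupper(consensus), "")[[1]]
  if (length(chars) == 0L) stop("empty consensus")
  bad <- setdiff(chars, names(IUPAC_SETS))
  if (length(bad) > 0L) {
    stop(sprintf("illegal IUPAC character(s): %s", paste(unique(bad), collapse = ", ")))
  }
  probs <- vapply(chars, function(ch) {
    p <- setNames(numeric(4), DNA_BASES)
    p[IUPAC_SETS[[ch]]] <- 1 / length(IUPAC_SETS[[ch]])
    p
  }, numeric(4))
  motif(name, probs = probs, nsites = nsites, source = "iupac")
}

#' Reverse complement of a motif
#'
#' Columns are reversed and the A/T and C/G rows swapped, so the motif
#' describes the same sites read on the opposite strand. Involution:
#' `reverse_complement(reverse_complement(m))` equals `m`.
#'
#' @param m A `motif`.
#' @return A `motif`.
#' @export
reverse_complement <- function(m) {
  rc <- m$probs[c("T", "G", "C", "A"), rev(seq_len(ncol(m$probs))), drop = FALSE]
  rownames(rc) <- DNA_BASES
  out <- m
  out$probs <- rc
  if (!is.null(m$counts)) {
    cc <- m$counts[c(4, 3, 2, 1), rev(seq_len(ncol(m$counts))), drop = FALSE]
    rownames(cc) <- DNA_BASES
    out$counts <- cc
  }
  out
}

#' Background nucleotide model
#'
#' Order-0 base frequencies used for scanning, similarity, and information
#' content. All four frequencies must be positive.
#'
#' @param freqs Named numeric of length 4 (names A,C,G,T); normalized to sum 1.
#' @return Named numeric vector of class use, summing to 1.
#' @export
background_model <- function(freqs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  freqs <- freqs[DNA_BASES]
  if (any(is.na(freqs)) || any(freqs <= 0)) {
    stop("background frequencies must be positive and named A,C,G,T")
  }
  freqs / sum(freqs)
}

#' Estimate a 0-order background model from sequences
#'
#' @param seqs Character vector of DNA sequences (typically the background
#'   promoter set). Non-ACGT characters are ignored.
#' @param pseudocount Added per base to keep all frequencies positive.
#' @return A background model (named numeric, sums to 1).
#' @export
estimate_background <- function(seqs, pseudocount = 1) {
  tab <- table(factor(strsplit(paste(toupper(seqs), collapse = ""), "")[[1]],
                      levels = DNA_BASES))
  background_model(setNames(as.numeric(tab) + pseudocount, DNA_BASES))
}

#' Information content of a motif (bits)
#'
#' Sum over columns of the Kullback-Leibler divergence from the background:
#' `sum_j sum_b p_jb * log2(p_jb / bg_b)`. Non-negative for any background;
#' equals 2 bits per fully determined column under a uniform background.
#'
#' @param m A `motif`.
#' @param bg A background model (default uniform).
#' @return Numeric scalar, bits.
#' @export
information_content <- function(m, bg = background_model()) {
  p <- m$probs
  terms <- p * log2(sweep(p, 1, bg, "/"))
  sum(terms[p > 0])
}

## integer codes 1..4 for A,C,G,T; NA for anything else (N etc.)
encode_seq <- function(s) {
  match(strsplit(toupper(s), "")[[1]], DNA_BASES)
}

decode_seq <- function(codes) {
  paste(ifelse(is.na(codes), "N", DNA_BASES[codes]), collapse = "")
}

revcomp_string <- function(s) {
  chartr("ACGTacgt", "TGCAtgca", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}
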