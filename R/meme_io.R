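#' Read motifs from a MEME minimal format file
#'
#' Parses the "MEME version 4" minimal dialect: a version line, optional
#' `ALPHABET= ACGT`, optional `strands:` line, an optional
#' `Background letter frequencies` block, and one or more `MOTIF` blocks each
#' carrying a `letter-probability matrix:` header followed by one row per
#' motif column. Columns that do not sum to 1 are renormalized with a
#' warning; malformed lines raise an error that reports the line number.
#'
#' @param path Path to a MEME minimal text file.
#' @return A list with elements `motifs` (list of [motif()] objects, source
#'   `"known_db"`) and `background` (a background model; uniform if the file
#'   has none).
#' @seealso [write_meme()]
#' @export
read_meme <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^MEME version", lines))) {
    stop(sprintf("%s: not a MEME minimal file (no 'MEME version' line)", path))
  }
  bg <- background_model()
  motifs <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    line <- trimws(lines[i])
    if (grepl("^Background letter frequencies", line)) {
      i <- i + 1L
      while (i <= n && !nzchar(trimws(lines[i]))) i <- i + 1L
      toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(toks) < 8L) stop(sprintf("line %d: malformed background line", i))
      vals <- as.numeric(toks[seq(2, 8, by = 2)])
      names(vals) <- toks[seq(1, 7, by = 2)]
      bg <- background_model(vals)
      i <- i + 1L
    } else if (grepl("^MOTIF", line)) {
      toks <- strsplit(line, "\\s+")[[1]]
      if (length(toks) < 2L) stop(sprintf("line %d: MOTIF line without a name", i))
      name <- toks[2]
      i <- i + 1L
      while (i <= n && !grepl("^letter-probability matrix:", trimws(lines[i]))) {
        if (grepl("^MOTIF", trimws(lines[i]))) {
          stop(sprintf("line %d: MOTIF '%s' has no letter-probability matrix", i, name))
        }
        i <- i + 1L
      }
      if (i > n) stop(sprintf("motif '%s': missing letter-probability matrix", name))
      hdr <- trimws(lines[i])
      w <- as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", hdr))
      nsites <- if (grepl("nsites=", hdr)) {
        as.numeric(sub(".*nsites=\\s*([0-9.]+).*", "\\1", hdr))
      } else 20
      if (is.na(w)) stop(sprintf("line %d: matrix header lacks w=", i))
      rows <- matrix(0, nrow = w, ncol = 4)
      for (j in seq_len(w)) {
        i <- i + 1L
        if (i > n) stop(sprintf("line %d: motif '%s' matrix truncated", i, name))
        vals <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
        if (length(vals) != 4L || any(is.na(vals))) {
          stop(sprintf("line %d: expected 4 numeric probabilities", i))
        }
        rows[j, ] <- vals
      }
      motifs[[name]] <- motif(name, probs = t(rows),
                              nsites = max(1, round(nsites)), source = "known_db")
      i <- i + 1L
    } else {
      i <- i + 1L
    }
  }
  list(motifs = motifs, background = bg)
}

#' Write motifs to a MEME minimal format file
#'
#' @param motifs A list of [motif()] objects (or a single motif).
#' @param path Output file path.
#' @param background Background model written into the file header.
#' @return `path`, invisibly.
#' @seealso [read_meme()]
#' @export
write_meme <- function(motifs, path, background = background_model()) {
  if (inherits(motifs, "motif")) motifs <- list(motifs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    sprintf("A %.5f C %.5f G %.5f T %.5f",
            background["A"], background["C"], background["G"], background["T"]),
    ""), con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s", m$name), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                       ncol(m$probs), m$nsites), con)
    for (j in seq_len(ncol(m$probs))) {
      writeLines(sprintf(" %.6f %.6f %.6f %.6f",
                         m$probs[1, j], m$probs[2, j], m$probs[3, j], m$probs[4, j]), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Read sequences from a FASTA file as a named character vector
#' @param path FASTA file path.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' Write a named character vector of sequences to FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
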