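#' Specification of a synthetic study
#'
#' Describes the simulated inputs: foreground/background promoter counts
#' and length, tissues and replicate samples, planted motifs with their
#' target coverages and conservation status, ortholog mutation/indel rates,
#' and the RNG seed. Defaults mirror the study conditions the pipeline is
#' designed for: 13 pollen-specific foreground genes vs 132 non-pollen
#' background genes, 1 kb promoters, 11 tissues, and an ortholog point
#' mutation rate of 0.10.
#'
#' @param n_fg_genes,n_bg_genes Foreground / background gene counts.
#' @param promoter_len Promoter length in bp.
#' @param n_tissues Number of tissues (the first is "pollen").
#' @param samples_per_tissue Replicate RNA-seq samples per tissue.
#' @param planted_motifs List of planting instructions, each a list with
#'   `motif` (a [motif()]), `fg_coverage`, `bg_coverage` (fractions in
#'   `[0,1]`), and `conserved` (logical).
#' @param ortholog_mutation_rate Per-base substitution probability outside
#'   planted sites.
#' @param ortholog_indel_rate Per-base probability of starting a 1-5 bp
#'   insertion or deletion outside planted sites.
#' @param base_freqs Background base composition of the promoters
#'   (default uniform, which keeps analytic p-value checks exact).
#' @param seed RNG seed; every generator below derives its stream from it.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_fg_genes = 13L, n_bg_genes = 132L,
                           promoter_len = 1000L, n_tissues = 11L,
                           samples_per_tissue = 10L,
                           planted_motifs = list(),
                           ortholog_mutation_rate = 0.10,
                           ortholog_indel_rate = 0.002,
                           base_freqs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                           seed = 1L) {
  for (pm in planted_motifs) {
    stopifnot(inherits(pm$motif, "motif"),
              pm$fg_coverage >= 0, pm$fg_coverage <= 1,
              pm$bg_coverage >= 0, pm$bg_coverage <= 1,
              is.logical(pm$conserved))
  }
  if (ortholog_mutation_rate < 0 || ortholog_mutation_rate >= 1 ||
      ortholog_indel_rate < 0 || ortholog_indel_rate >= 1) {
    stop("mutation and indel rates must lie in [0, 1)")
  }
  structure(list(
    n_fg_genes = as.integer(n_fg_genes), n_bg_genes = as.integer(n_bg_genes),
    promoter_len = as.integer(promoter_len), n_tissues = as.integer(n_tissues),
    samples_per_tissue = as.integer(samples_per_tissue),
    planted_motifs = planted_motifs,
    ortholog_mutation_rate = ortholog_mutation_rate,
    ortholog_indel_rate = ortholog_indel_rate,
    base_freqs = background_model(base_freqs),
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

#' A random high-information motif for planting experiments
#'
#' Each column has one dominant base (probability `dominance`) with the
#' remainder spread evenly — the shape of a typical eukaryotic TF motif.
#'
#' @param width Motif width (6-16; default 12, a typical planted-site width
#'   at which near-consensus sites stay detectable at the 1e-4 scan
#'   threshold).
#' @param seed RNG seed.
#' @param dominance Probability of the consensus base per column
#'   (default 0.95, a sharp eukaryotic TF motif).
#' @param name Motif name.
#' @return A [motif()].
#' @export
random_motif <- function(width = 12L, seed = 1L, dominance = 0.95,
                         name = sprintf("planted_w%d_s%d", width, seed)) {
  with_isolated_rng(seed, {
    cons <- sample(1:4, width, replace = TRUE)
    probs <- matrix((1 - dominance) / 3, nrow = 4, ncol = width)
    probs[cbind(cons, seq_len(width))] <- dominance
    motif(name, probs = probs, source = "known_db")
  })
}

## sample a concrete site sequence from a motif's PWM
sample_site <- function(m) {
  paste(apply(m$probs, 2, function(p) sample(DNA_BASES, 1, prob = p)),
        collapse = "")
}

random_dna <- function(len, freqs) {
  paste(sample(DNA_BASES, len, replace = TRUE, prob = freqs), collapse = "")
}

#' Generate promoters with planted motif sites
#'
#' Background promoters are iid at `spec$base_freqs`. For every planted
#' motif, sites sampled from its PWM are inserted at uniform random,
#' non-overlapping positions (random strand) into exactly
#' `round(coverage * n)` genes of each set.
#'
#' @param spec A [synthetic_spec()].
#' @return List: `fg`, `bg` (named character vectors) and `truth`
#'   (data.frame: gene_id, motif_name, start 0-based, strand, site,
#'   conserved).
#' @export
gen_promoters <- function(spec) {
  with_isolated_rng(spec$seed * 13L + 1L, {
    fg_ids <- sprintf("FG%03d", seq_len(spec$n_fg_genes))
    bg_ids <- sprintf("BG%03d", seq_len(spec$n_bg_genes))
    seqs <- setNames(
      vapply(seq_len(spec$n_fg_genes + spec$n_bg_genes),
             function(i) random_dna(spec$promoter_len, spec$base_freqs),
             character(1)),
      c(fg_ids, bg_ids))
    occupied <- lapply(seqs, function(s) logical(nchar(s)))
    truth <- list()
    for (pm in spec$planted_motifs) {
      w <- motif_width(pm$motif)
      if (w > spec$promoter_len) stop("promoter too short for a planted site")
      targets <- c(
        if (spec$n_fg_genes > 0)
          sample(fg_ids, round(pm$fg_coverage * spec$n_fg_genes)),
        if (spec$n_bg_genes > 0)
          sample(bg_ids, round(pm$bg_coverage * spec$n_bg_genes)))
      for (g in targets) {
        placed <- FALSE
        for (try in 1:200) {
          start <- sample.int(spec$promoter_len - w + 1L, 1L)  # 1-based
          span <- start:(start + w - 1L)
          if (!any(occupied[[g]][span])) {
            site <- sample_site(pm$motif)
            strand <- sample(c("+", "-"), 1L)
            ins <- if (strand == "+") site else revcomp_string(site)
            seqs[[g]] <- paste0(substr(seqs[[g]], 1, start - 1L), ins,
                                substr(seqs[[g]], start + w, spec$promoter_len))
            occupied[[g]][span] <- TRUE
            truth[[length(truth) + 1L]] <- data.frame(
              gene_id = g, motif_name = pm$motif$name, start = start - 1L,
              strand = strand, site = site, conserved = pm$conserved,
              stringsAsFactors = FALSE)
            placed <- TRUE
            break
          }
        }
        if (!placed) stop("promoter too crowded to place all sites")
      }
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(gene_id = character(0), motif_name = character(0),
                 start = integer(0), strand = character(0),
                 site = character(0), conserved = logical(0))
    list(fg = seqs[fg_ids], bg = seqs[bg_ids], truth = truth)
  })
}

#' Generate orthologous promoters by neutral mutation
#'
#' Each promoter is copied with point substitutions at
#' `ortholog_mutation_rate` and 1-5 bp insertions/deletions at
#' `ortholog_indel_rate`, both applied only outside planted sites. Sites
#' planted with `conserved = TRUE` are copied intact; sites with
#' `conserved = FALSE` are replaced by random background sequence (the
#' site is ablated in the ortholog).
#'
#' @param promoters Named character vector (e.g. `gen_promoters()$fg`).
#' @param truth Truth table from [gen_promoters()].
#' @param spec The [synthetic_spec()].
#' @return Named character vector of ortholog sequences.
#' @export
gen_orthologs <- function(promoters, truth, spec) {
  with_isolated_rng(spec$seed * 13L + 2L, {
    out <- vapply(names(promoters), function(g) {
      chars <- strsplit(promoters[[g]], "")[[1]]
      n <- length(chars)
      protected <- logical(n)
      rows <- truth[truth$gene_id == g, , drop = FALSE]
      for (r in seq_len(nrow(rows))) {
        w <- nchar(rows$site[r])
        span <- (rows$start[r] + 1L):(rows$start[r] + w)
        protected[span] <- TRUE
        if (!rows$conserved[r]) {
          chars[span] <- strsplit(random_dna(w, spec$base_freqs), "")[[1]]
        }
      }
      pieces <- character(0)
      i <- 1L
      while (i <= n) {
        if (!protected[i] && runif(1) < spec$ortholog_indel_rate) {
          if (runif(1) < 0.5) {  # insertion before position i
            pieces <- c(pieces, random_dna(sample.int(5L, 1L), spec$base_freqs))
          } else {               # deletion, clamped at protected positions
            del <- sample.int(5L, 1L)
            j <- i
            while (j <= n && j < i + del && !protected[j]) j <- j + 1L
            i <- j
            next
          }
        }
        ch <- chars[i]
        if (!protected[i] && runif(1) < spec$ortholog_mutation_rate) {
          ch <- sample(setdiff(DNA_BASES, ch), 1L)
        }
        pieces <- c(pieces, ch)
        i <- i + 1L
      }
      paste(pieces, collapse = "")
    }, character(1))
    setNames(out, names(promoters))
  })
}

#' Generate a multi-tissue expression matrix
#'
#' Foreground genes get high pollen expression (log2 median well above the
#' tissue-specificity threshold; the remaining tissues are below the
#' zeroing cutoff), so their Tau is ~1 with pollen argmax. Background genes
#' get zero pollen expression and moderate expression in a random subset of
#' other tissues. If `pollen_target` is supplied (regression mode), the
#' pollen samples of each gene are drawn so the mean log2 value matches it.
#'
#' @param spec A [synthetic_spec()].
#' @param fg_ids,bg_ids Gene IDs for the two sets.
#' @param pollen_target Optional named numeric: desired mean pollen log2
#'   expression per gene (overrides the defaults for genes listed).
#' @param replicate_sd Lognormal replicate noise sd on the log2 scale.
#' @return An [expression_matrix()] with tissues `pollen`, `tissue02`, ...
#' @export
gen_expression <- function(spec, fg_ids, bg_ids, pollen_target = NULL,
                           replicate_sd = 0.25) {
  with_isolated_rng(spec$seed * 13L + 3L, {
    tissues <- c("pollen", sprintf("tissue%02d", 2:spec$n_tissues))
    samples <- paste0(rep(tissues, each = spec$samples_per_tissue), "_s",
                      rep(seq_len(spec$samples_per_tissue), times = length(tissues)))
    tissue_of <- setNames(rep(tissues, each = spec$samples_per_tissue), samples)
    genes <- c(fg_ids, bg_ids)
    vals <- matrix(0, nrow = length(genes), ncol = length(samples),
                   dimnames = list(genes, samples))
    pollen_cols <- which(tissue_of == "pollen")
    other_cols <- which(tissue_of != "pollen")
    for (g in fg_ids) {
      level <- if (!is.null(pollen_target) && g %in% names(pollen_target)) {
        pollen_target[[g]]
      } else runif(1, 6, 14)
      vals[g, pollen_cols] <- pmax(2^(level + rnorm(length(pollen_cols), 0, replicate_sd)) - 1, 0)
      vals[g, other_cols] <- runif(length(other_cols), 0, 0.8)  # zeroed by log transform
    }
    for (g in bg_ids) {
      vals[g, pollen_cols] <- runif(length(pollen_cols), 0, 0.9)  # zero in pollen
      if (!is.null(pollen_target) && g %in% names(pollen_target) &&
          pollen_target[[g]] >= 1) {
        vals[g, pollen_cols] <-
          pmax(2^(pollen_target[[g]] + rnorm(length(pollen_cols), 0, replicate_sd)) - 1, 0)
      }
      expressed <- sample(tissues[-1], sample(2:6, 1))
      for (tt in expressed) {
        cols <- which(tissue_of == tt)
        level <- runif(1, 2, 10)
        vals[g, cols] <- pmax(2^(level + rnorm(length(cols), 0, replicate_sd)) - 1, 0)
      }
    }
    expression_matrix(vals, tissue_of)
  })
}

#' Generate a known-TF motif database with TF pollen expression
#'
#' The database holds every planted motif, assigned to a pollen-expressed
#' TF (log2 expression >= 1), plus `n_decoys` random motifs of which half
#' get sub-threshold expression — so the expression gate and the match step
#' both have work to do.
#'
#' @param spec A [synthetic_spec()].
#' @param n_decoys Number of decoy motifs (default 50).
#' @return List: `motifs` (named list of [motif()]), `tf_expression`
#'   (named numeric, log2).
#' @export
gen_known_db <- function(spec, n_decoys = 50L) {
  with_isolated_rng(spec$seed * 13L + 4L, {
    motifs <- list()
    expr <- numeric(0)
    for (pm in spec$planted_motifs) {
      nm <- paste0("TF_", pm$motif$name)
      m <- pm$motif
      m$name <- nm
      m$source <- "known_db"
      motifs[[nm]] <- m
      expr[nm] <- runif(1, 1.5, 8)
    }
    for (i in seq_len(n_decoys)) {
      nm <- sprintf("TF_decoy%03d", i)
      width <- sample(6:16, 1)
      cons <- sample(1:4, width, replace = TRUE)
      probs <- matrix(0.05, nrow = 4, ncol = width)
      probs[cbind(cons, seq_len(width))] <- 0.85
      motifs[[nm]] <- motif(nm, probs = probs, source = "known_db")
      expr[nm] <- if (i %% 2 == 0) runif(1, 1, 8) else runif(1, 0, 0.9)
    }
    list(motifs = motifs, tf_expression = expr)
  })
}

#' Generate a regression study: features, weights, and a noisy target
#'
#' Emulates the motif-feature regression setting directly: sparse
#' `-log10 p`-style features (a motif hits a gene with probability
#' `coverage`; hit strengths are uniform on 4-8), a weighted linear signal
#' over the first `n_informative` motifs, and Gaussian noise scaled to a
#' requested population R-squared.
#'
#' @param n_genes,n_motifs Dimensions.
#' @param n_informative Number of nonzero-weight motifs.
#' @param r2 Target population R-squared (noise sd is set from the realized
#'   signal variance); `1` means noiseless.
#' @param coverage Per-motif hit probability.
#' @param seed RNG seed.
#' @return List: `features`, `target` (named), `weights`, `noise_sd`.
#' @export
gen_regression_data <- function(n_genes = 200L, n_motifs = 15L,
                                n_informative = 5L, r2 = 0.4,
                                coverage = 0.6, seed = 1L) {
  with_isolated_rng(seed, {
    genes <- sprintf("G%04d", seq_len(n_genes))
    motifs <- sprintf("m%02d", seq_len(n_motifs))
    X <- matrix(0, n_genes, n_motifs, dimnames = list(genes, motifs))
    hits <- matrix(runif(n_genes * n_motifs) < coverage, n_genes, n_motifs)
    X[hits] <- runif(sum(hits), 4, 8)
    w <- c(runif(n_informative, 0.5, 1.5), rep(0, n_motifs - n_informative))
    signal <- as.numeric(X %*% w)
    noise_sd <- if (r2 >= 1) 0 else sqrt(var(signal) * (1 - r2) / r2)
    y <- signal + rnorm(n_genes, 0, noise_sd)
    list(features = X, target = setNames(y, genes), weights = setNames(w, motifs),
         noise_sd = noise_sd)
  })
}
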