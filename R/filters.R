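#' Filter A configuration (relaxed filter)
#'
#' Pass a motif if it occurs in at least `min_fg_genes` foreground
#' (pollen-specific) promoters, at most `max_bg_genes` background
#' (non-pollen) promoters, and is conserved in the orthologous promoters.
#' Defaults correspond to >= 11 of 13 foreground and <= 30 of 132
#' background genes.
#'
#' @param min_fg_genes,max_bg_genes Occurrence bounds (inclusive).
#' @param require_conserved Require the conservation flag (default TRUE).
#' @return List of class `filter_a_config`.
#' @export
filter_a_config <- function(min_fg_genes = 11L, max_bg_genes = 30L,
                            require_conserved = TRUE) {
  structure(list(min_fg_genes = as.integer(min_fg_genes),
                 max_bg_genes = as.integer(max_bg_genes),
                 require_conserved = require_conserved),
            class = "filter_a_config")
}

#' Filter B configuration (rigorous filter)
#'
#' Pass a motif if it matches (similarity `p < similarity_p`) the binding
#' motif of a known TF expressed in pollen (log2 expression
#' >= `tf_expr_threshold`), meets the occurrence bounds, and is conserved.
#'
#' @param tf_expr_threshold Minimum TF log2 pollen expression (default 1).
#' @param similarity_p Known-motif similarity cutoff (default 0.001).
#' @param min_fg_genes,max_bg_genes Occurrence bounds (inclusive).
#' @param require_conserved Require the conservation flag (default TRUE).
#' @return List of class `filter_b_config`.
#' @export
filter_b_config <- function(tf_expr_threshold = 1.0, similarity_p = 0.001,
                            min_fg_genes = 10L, max_bg_genes = 30L,
                            require_conserved = TRUE) {
  structure(list(tf_expr_threshold = tf_expr_threshold,
                 similarity_p = similarity_p,
                 min_fg_genes = as.integer(min_fg_genes),
                 max_bg_genes = as.integer(max_bg_genes),
                 require_conserved = require_conserved),
            class = "filter_b_config")
}

empty_filter_report <- function() {
  data.frame(motif_name = character(0), fg_hits = integer(0),
             fg_total = integer(0), fg_coverage_pct = numeric(0),
             bg_hits = integer(0), bg_total = integer(0),
             bg_coverage_pct = numeric(0), relative_frequency = numeric(0),
             conserved = logical(0), best_known_match = character(0),
             best_known_pvalue = numeric(0), passed = logical(0))
}

## shared row builder: one FilterReport row per motif
filter_report_row <- function(cov, conserved, known_match = NA_character_,
                              known_p = NA_real_) {
  data.frame(motif_name = cov$motif_name,
             fg_hits = cov$fg_hits, fg_total = cov$fg_total,
             fg_coverage_pct = cov$fg_coverage_pct,
             bg_hits = cov$bg_hits, bg_total = cov$bg_total,
             bg_coverage_pct = cov$bg_coverage_pct,
             relative_frequency = cov$relative_frequency,
             conserved = conserved,
             best_known_match = known_match, best_known_pvalue = known_p,
             stringsAsFactors = FALSE)
}

#' Apply Filter A (occurrence + conservation)
#'
#' @param coverage data.frame of [coverage_stats()] rows (one per motif).
#' @param conserved Named logical: conservation call per motif.
#' @param cfg A [filter_a_config()].
#' @return data.frame of filter-report rows with a `passed` column, passing
#'   motifs first, ordered by descending foreground then ascending
#'   background hits.
#' @export
filter_a <- function(coverage, conserved, cfg = filter_a_config()) {
  if (nrow(coverage) == 0L) return(empty_filter_report())
  cons <- as.logical(conserved[coverage$motif_name])
  cons[is.na(cons)] <- FALSE
  rep <- do.call(rbind, lapply(seq_len(nrow(coverage)), function(i) {
    filter_report_row(coverage[i, ], cons[i])
  }))
  rep$passed <- rep$fg_hits >= cfg$min_fg_genes &
    rep$bg_hits <= cfg$max_bg_genes &
    (!cfg$require_conserved | rep$conserved)
  rep[order(-rep$passed, -rep$fg_hits, rep$bg_hits, rep$motif_name), ]
}

#' Apply Filter B (known pollen-expressed TF match + occurrence + conservation)
#'
#' Candidates must carry at least one known-motif match computed against the
#' expression-restricted database ([match_known()]); redundant passing
#' motifs are then collapsed with [remove_redundant()].
#'
#' @param coverage data.frame of [coverage_stats()] rows.
#' @param conserved Named logical per motif.
#' @param known_matches data.frame from [match_known()] (already restricted
#'   to pollen-expressed TFs and `p < similarity_p`).
#' @param motifs Named list of the candidate [motif()] objects (needed for
#'   redundancy removal).
#' @param cfg A [filter_b_config()].
#' @param bg,n_shuffle,seed Similarity settings for redundancy removal.
#' @return data.frame of filter-report rows with `passed`; passing rows
#'   exclude redundant motifs.
#' @export
filter_b <- function(coverage, conserved, known_matches, motifs,
                     cfg = filter_b_config(), bg = background_model(),
                     n_shuffle = 2000L, seed = 1L) {
  if (nrow(coverage) == 0L) return(empty_filter_report())
  cons <- as.logical(conserved[coverage$motif_name])
  cons[is.na(cons)] <- FALSE
  best_match <- vapply(coverage$motif_name, function(nm) {
    hits <- known_matches[known_matches$query_name == nm &
                            known_matches$pvalue < cfg$similarity_p, , drop = FALSE]
    if (nrow(hits) == 0L) NA_character_ else hits$target_name[which.min(hits$pvalue)]
  }, character(1))
  best_p <- vapply(coverage$motif_name, function(nm) {
    hits <- known_matches[known_matches$query_name == nm &
                            known_matches$pvalue < cfg$similarity_p, , drop = FALSE]
    if (nrow(hits) == 0L) NA_real_ else min(hits$pvalue)
  }, numeric(1))
  rep <- do.call(rbind, lapply(seq_len(nrow(coverage)), function(i) {
    filter_report_row(coverage[i, ], cons[i], best_match[i], best_p[i])
  }))
  rep$passed <- !is.na(rep$best_known_match) &
    rep$fg_hits >= cfg$min_fg_genes &
    rep$bg_hits <= cfg$max_bg_genes &
    (!cfg$require_conserved | rep$conserved)
  ## collapse redundant survivors
  surv <- rep$motif_name[rep$passed]
  if (length(surv) > 1L) {
    fg_counts <- setNames(rep$fg_hits, rep$motif_name)[surv]
    rr <- remove_redundant(motifs[surv], fg_counts, cfg$similarity_p,
                           bg = bg, n_shuffle = n_shuffle, seed = seed)
    kept <- vapply(rr$kept, function(m) m$name, character(1))
    rep$passed[rep$passed & !(rep$motif_name %in% kept)] <- FALSE
  }
  rep[order(-rep$passed, -rep$fg_hits, rep$bg_hits, rep$motif_name), ]
}

#' Union of Filter A and Filter B survivors
#'
#' Motifs passing either filter are combined; two survivors similar at
#' `p < p_threshold` count as the same motif and the higher-foreground
#' member is retained. Provenance flags record which filter(s) found each
#' motif.
#'
#' @param report_a,report_b Outputs of [filter_a()] / [filter_b()].
#' @param motifs Named list of candidate [motif()] objects.
#' @param p_threshold Similarity cutoff defining motif identity (0.001).
#' @param bg,n_shuffle,seed Similarity settings.
#' @return data.frame: `motif_name`, `fg_hits`, `bg_hits`, `from_a`,
#'   `from_b`, one row per distinct final motif.
#' @export
combine_filters <- function(report_a, report_b, motifs, p_threshold = 0.001,
                            bg = background_model(), n_shuffle = 2000L, seed = 1L) {
  a_pass <- report_a$motif_name[report_a$passed]
  b_pass <- report_b$motif_name[report_b$passed]
  all_names <- union(a_pass, b_pass)
  if (length(all_names) == 0L) {
    return(data.frame(motif_name = character(0), fg_hits = integer(0),
                      bg_hits = integer(0), from_a = logical(0), from_b = logical(0)))
  }
  stats <- rbind(report_a[, c("motif_name", "fg_hits", "bg_hits")],
                 report_b[, c("motif_name", "fg_hits", "bg_hits")])
  stats <- stats[!duplicated(stats$motif_name), ]
  fg_counts <- setNames(stats$fg_hits, stats$motif_name)[all_names]
  dedup <- if (length(all_names) > 1L) {
    remove_redundant(motifs[all_names], fg_counts, p_threshold,
                     bg = bg, n_shuffle = n_shuffle, seed = seed)
  } else list(kept = motifs[all_names],
              dropped = data.frame(motif = character(0), absorbed_by = character(0)))
  kept <- vapply(dedup$kept, function(m) m$name, character(1))
  ## a dropped motif transfers its provenance to its absorber
  provenance <- function(nm, pass_set) {
    if (nm %in% pass_set) return(TRUE)
    absorbed <- dedup$dropped$motif[dedup$dropped$absorbed_by == nm]
    any(absorbed %in% pass_set)
  }
  out <- data.frame(
    motif_name = kept,
    fg_hits = as.integer(fg_counts[kept]),
    bg_hits = as.integer(setNames(stats$bg_hits, stats$motif_name)[kept]),
    from_a = vapply(kept, provenance, logical(1), pass_set = a_pass),
    from_b = vapply(kept, provenance, logical(1), pass_set = b_pass),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out[order(-out$fg_hits, out$bg_hits, out$motif_name), ]
}
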