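#' Pipeline configuration
#'
#' Bundles every stage's settings for [run_pipeline()]. Inputs come from
#' the synthetic generator (a [synthetic_spec()]); each stage writes plain
#' files (FASTA / TSV / MEME / JSON) into the run directory so stages are
#' independently inspectable and a rerun with the same configuration
#' reproduces identical bytes.
#'
#' @param spec A [synthetic_spec()] describing the simulated inputs.
#' @param discovery A [discovery_config()].
#' @param scan_p Scan p-value threshold (default 1e-4).
#' @param similarity_p Motif-similarity cutoff (default 0.001).
#' @param n_shuffle Shuffle-null size for similarity p-values.
#' @param filter_a_cfg,filter_b_cfg Filter configurations. Defaults scale
#'   the canonical bounds (11/13 foreground, 30/132 background) to the
#'   spec's gene counts.
#' @param regression A [regression_config()].
#' @param conservation_tol,conservation_min_frac Conservation settings
#'   (see [is_conserved()], [motif_is_conserved()]).
#' @param n_decoys Decoy motifs in the synthetic known-TF database.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(spec = synthetic_spec(),
                            discovery = discovery_config(seed = spec$seed),
                            scan_p = 1e-4,
                            similarity_p = 0.001,
                            n_shuffle = 2000L,
                            filter_a_cfg = NULL,
                            filter_b_cfg = NULL,
                            regression = regression_config(seed = spec$seed),
                            conservation_tol = 3L,
                            conservation_min_frac = 0.5,
                            n_decoys = 50L) {
  if (is.null(filter_a_cfg)) {
    filter_a_cfg <- filter_a_config(
      min_fg_genes = ceiling(11 / 13 * spec$n_fg_genes),
      max_bg_genes = floor(30 / 132 * spec$n_bg_genes))
  }
  if (is.null(filter_b_cfg)) {
    filter_b_cfg <- filter_b_config(
      min_fg_genes = ceiling(10 / 13 * spec$n_fg_genes),
      max_bg_genes = floor(30 / 132 * spec$n_bg_genes))
  }
  structure(list(spec = spec, discovery = discovery, scan_p = scan_p,
                 similarity_p = similarity_p, n_shuffle = as.integer(n_shuffle),
                 filter_a_cfg = filter_a_cfg, filter_b_cfg = filter_b_cfg,
                 regression = regression,
                 conservation_tol = as.integer(conservation_tol),
                 conservation_min_frac = conservation_min_frac,
                 n_decoys = as.integer(n_decoys)),
            class = "pipeline_config")
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) {
    if (!all(df[[j]] == round(df[[j]]) | !is.finite(df[[j]]), na.rm = TRUE)) {
      df[[j]] <- sprintf("%.6g", df[[j]])
    }
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline on synthetic inputs
#'
#' Executes, in order: input simulation, tissue-specificity gene-set
#' selection, discriminative motif discovery, redundancy removal, promoter
#' scanning with coverage statistics, cross-species conservation, Filter A
#' and Filter B with their union, and the motif-to-expression regression.
#' Every stage writes its outputs under `out_dir`; `manifest.json` records
#' configuration, seed, and stage counts. Deterministic given the spec seed.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory (created; contents overwritten).
#' @return Invisibly, a list with all stage results (`gene_sets`,
#'   `discovered`, `coverage`, `conserved`, `report_a`, `report_b`,
#'   `final_motifs`, `regression`, `paths`).
#' @export
run_pipeline <- function(cfg, out_dir) {
  stage <- "setup"
  result <- tryCatch({
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    spec <- cfg$spec
    bgm <- spec$base_freqs

    stage <- "simulate"
    proms <- gen_promoters(spec)
    orthologs <- gen_orthologs(proms$fg, proms$truth, spec)
    em <- gen_expression(spec, names(proms$fg), names(proms$bg))
    db <- gen_known_db(spec, cfg$n_decoys)
    write_fasta(proms$fg, file.path(out_dir, "fg_promoters.fa"))
    write_fasta(proms$bg, file.path(out_dir, "bg_promoters.fa"))
    write_fasta(orthologs, file.path(out_dir, "orthologs.fa"))
    write_tsv(proms$truth, file.path(out_dir, "truth_sites.tsv"))
    write_meme(db$motifs, file.path(out_dir, "known_db.meme"), bgm)
    write_tsv(data.frame(tf = names(db$tf_expression),
                         log2_expression = sprintf("%.4f", db$tf_expression)),
              file.path(out_dir, "tf_expression.tsv"))

    stage <- "specificity"
    all_ids <- c(names(proms$fg), names(proms$bg))
    sets <- select_gene_sets(em, all_ids)
    writeLines(sets$pollen_specific, file.path(out_dir, "pollen_specific.txt"))
    writeLines(sets$non_pollen, file.path(out_dir, "non_pollen.txt"))
    fg_seqs <- c(proms$fg, proms$bg)[sets$pollen_specific]
    bg_seqs <- c(proms$fg, proms$bg)[sets$non_pollen]
    if (length(fg_seqs) == 0L) stop("empty foreground gene set")

    stage <- "discovery"
    disc <- discover_motifs(fg_seqs, bg_seqs, cfg$discovery, background = bgm)
    if (length(disc$motifs) == 0L) stop("discovery produced no motifs")
    write_tsv(disc$seeds, file.path(out_dir, "seed_stats.tsv"))
    ## low-confidence (low information content) motifs do not go forward
    motifs <- Filter(function(m) !isTRUE(attr(m, "low_confidence")), disc$motifs)
    write_meme(motifs, file.path(out_dir, "candidate_motifs.meme"), bgm)

    stage <- "scanning"
    occ_fg <- lapply(motifs, scan_motif, seqs = fg_seqs, bg = bgm,
                     p_threshold = cfg$scan_p)
    occ_bg <- lapply(motifs, scan_motif, seqs = bg_seqs, bg = bgm,
                     p_threshold = cfg$scan_p)
    cov <- if (length(motifs) > 0L) {
      do.call(rbind, lapply(names(motifs), function(nm) {
        coverage_stats(nm, occ_fg[[nm]], occ_bg[[nm]],
                       length(fg_seqs), length(bg_seqs))
      }))
    } else {
      data.frame(motif_name = character(0), fg_hits = integer(0),
                 fg_total = integer(0), fg_coverage_pct = numeric(0),
                 bg_hits = integer(0), bg_total = integer(0),
                 bg_coverage_pct = numeric(0), relative_frequency = numeric(0))
    }
    write_tsv(cov, file.path(out_dir, "coverage.tsv"))

    stage <- "conservation"
    pairs <- lapply(names(fg_seqs)[names(fg_seqs) %in% names(orthologs)],
                    function(g) align_pair(fg_seqs[[g]], orthologs[[g]], gene_id = g))
    names(pairs) <- vapply(pairs, function(p) p$gene_id, character(1))
    conserved <- vapply(names(motifs), function(nm) {
      suppressMessages(motif_is_conserved(
        motifs[[nm]], occ_fg[[nm]], pairs,
        min_frac = cfg$conservation_min_frac, bg = bgm,
        p_threshold = cfg$scan_p, tol = cfg$conservation_tol))
    }, logical(1))
    write_tsv(data.frame(motif_name = names(motifs), conserved = conserved),
              file.path(out_dir, "conservation.tsv"))

    stage <- "known_match"
    matches <- match_known(motifs, db$motifs, db$tf_expression,
                           p_threshold = cfg$similarity_p,
                           expr_threshold = cfg$filter_b_cfg$tf_expr_threshold,
                           bg = bgm, n_shuffle = cfg$n_shuffle, seed = spec$seed)
    write_tsv(matches, file.path(out_dir, "known_matches.tsv"))

    stage <- "filters"
    report_a <- filter_a(cov, conserved, cfg$filter_a_cfg)
    report_b <- filter_b(cov, conserved, matches, motifs, cfg$filter_b_cfg,
                         bg = bgm, n_shuffle = cfg$n_shuffle, seed = spec$seed)
    final <- combine_filters(report_a, report_b, motifs, cfg$similarity_p,
                             bg = bgm, n_shuffle = cfg$n_shuffle, seed = spec$seed)
    write_tsv(report_a, file.path(out_dir, "filter_a.tsv"))
    write_tsv(report_b, file.path(out_dir, "filter_b.tsv"))
    write_tsv(final, file.path(out_dir, "final_motifs.tsv"))

    stage <- "regression"
    regression <- NULL
    if (nrow(final) > 0L) {
      ## present genes in a seeded random order: the cross-validation folds
      ## are contiguous, and a class-sorted gene list would segregate all
      ## foreground genes into one fold
      all_seqs <- c(proms$fg, proms$bg)
      all_seqs <- with_isolated_rng(spec$seed * 13L + 5L,
                                    all_seqs[sample(length(all_seqs))])
      feats <- feature_matrix(motifs[final$motif_name], all_seqs, bgm, cfg$scan_p)
      target <- build_target(em, rownames(feats))
      regression <- fit_evaluate(feats, target, cfg$regression)
      write_tsv(regression$predictions, file.path(out_dir, "predictions.tsv"))
      write_tsv(data.frame(motif_name = names(regression$feature_importances),
                           importance = sprintf("%.6f", regression$feature_importances)),
                file.path(out_dir, "importances.tsv"))
    }

    stage <- "report"
    manifest <- list(
      seed = spec$seed,
      n_fg_genes = length(fg_seqs), n_bg_genes = length(bg_seqs),
      n_seeds_considered = nrow(disc$seeds),
      n_motifs_discovered = length(disc$motifs),
      n_motifs_confident = length(motifs),
      n_filter_a = sum(report_a$passed), n_filter_b = sum(report_b$passed),
      n_final = nrow(final),
      pearson_r = if (is.null(regression)) NA else round(regression$pearson_r, 6),
      scan_p = cfg$scan_p, similarity_p = cfg$similarity_p,
      n_shuffle = cfg$n_shuffle
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    res <- list(gene_sets = sets, discovered = disc, coverage = cov,
                conserved = conserved, report_a = report_a, report_b = report_b,
                final_motifs = final, regression = regression,
                truth = proms$truth, out_dir = out_dir)
    report_pipeline(out_dir)
    res
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  invisible(result)
}

#' Write a human-readable summary of a completed pipeline run
#'
#' Produces `report.md` in the run directory: gene-set sizes, the
#' coverage/conservation table of every candidate motif (sorted by
#' descending foreground coverage), filter outcomes with the union count,
#' and the regression summary.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @return Path of the report, invisibly.
#' @export
report_pipeline <- function(run_dir) {
  path <- function(f) file.path(run_dir, f)
  lines <- c("# Pipeline run summary", "")
  manifest <- jsonlite::read_json(path("manifest.json"))
  lines <- c(lines, sprintf("- seed: %s", manifest$seed),
             sprintf("- foreground genes: %s, background genes: %s",
                     manifest$n_fg_genes, manifest$n_bg_genes),
             sprintf("- motifs: %s discovered, %s confident candidates",
                     manifest$n_motifs_discovered, manifest$n_motifs_confident),
             sprintf("- Filter A passed: %s; Filter B passed: %s; union: %s",
                     manifest$n_filter_a, manifest$n_filter_b, manifest$n_final),
             "")
  if (file.exists(path("filter_a.tsv"))) {
    fa <- read.table(path("filter_a.tsv"), header = TRUE, sep = "\t")
    fa <- fa[order(-fa$fg_hits, fa$bg_hits, fa$motif_name), ]
    lines <- c(lines, "## Candidate motifs (coverage and filters)", "",
               "| motif | fg coverage | bg coverage | conserved | filter A | known match |",
               "|---|---|---|---|---|---|")
    for (i in seq_len(nrow(fa))) {
      lines <- c(lines, sprintf("| %s | %d%% (%d) | %d%% (%d) | %s | %s | %s |",
                                fa$motif_name[i], fa$fg_coverage_pct[i], fa$fg_hits[i],
                                fa$bg_coverage_pct[i], fa$bg_hits[i],
                                ifelse(fa$conserved[i], "yes", "no"),
                                ifelse(fa$passed[i], "pass", "fail"),
                                ifelse(is.na(fa$best_known_match[i]), "",
                                       fa$best_known_match[i])))
    }
    lines <- c(lines, "")
  }
  if (!is.null(manifest$pearson_r) && !is.na(manifest$pearson_r)) {
    lines <- c(lines, "## Regression", "",
               sprintf("Pooled out-of-fold Pearson r = %s", manifest$pearson_r), "")
  }
  writeLines(lines, path("report.md"))
  invisible(path("report.md"))
}
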