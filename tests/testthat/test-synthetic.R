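test_that("promoter generation honours coverages, positions, and the seed", {
  pl <- random_motif(seed = 2)
  spec <- synthetic_spec(planted_motifs = list(list(motif = pl, fg_coverage = 12 / 13,
                                                    bg_coverage = 10 / 132,
                                                    conserved = TRUE)),
                         seed = 5)
  pr <- gen_promoters(spec)
  expect_length(pr$fg, 13)
  expect_length(pr$bg, 132)
  expect_true(all(nchar(c(pr$fg, pr$bg)) == 1000))
  ## exact planted gene counts
  expect_equal(length(unique(grep("^FG", pr$truth$gene_id, value = TRUE))), 12)
  expect_equal(length(unique(grep("^BG", pr$truth$gene_id, value = TRUE))), 10)
  ## every truth row points at its site (allowing for PWM sampling, the
  ## planted string must sit at the recorded 0-based offset)
  for (i in seq_len(nrow(pr$truth))) {
    tr <- pr$truth[i, ]
    s <- c(pr$fg, pr$bg)[[tr$gene_id]]
    emb <- substr(s, tr$start + 1, tr$start + nchar(tr$site))
    expect_equal(emb, if (tr$strand == "+") tr$site else
      pollenmotif:::revcomp_string(tr$site))
  }
  ## byte-identical regeneration under the same seed
  pr2 <- gen_promoters(spec)
  expect_identical(pr, pr2)
})

test_that("plant-free sequences look like the background composition", {
  spec <- synthetic_spec(n_fg_genes = 30L, n_bg_genes = 5L, promoter_len = 500L,
                         seed = 19)
  pr <- gen_promoters(spec)
  counts <- table(factor(strsplit(paste(pr$fg, collapse = ""), "")[[1]],
                         levels = c("A", "C", "G", "T")))
  chi <- stats::chisq.test(counts, p = rep(0.25, 4))
  expect_gt(chi$p.value, 0.01)
})

test_that("generated expression reproduces the designed gene classes", {
  spec <- synthetic_spec(seed = 23)
  em <- gen_expression(spec, sprintf("FG%03d", 1:13), sprintf("BG%03d", 1:132))
  expect_equal(dim(em$values), c(145, 11 * 10))
  sets <- select_gene_sets(em, rownames(em$values))
  ## recall 1 on construction: all fg genes pollen-specific, all bg non-pollen
  expect_setequal(sets$pollen_specific, sprintf("FG%03d", 1:13))
  expect_setequal(sets$non_pollen, sprintf("BG%03d", 1:132))
  cls <- sets$classification
  expect_true(all(cls$tau[grepl("FG", cls$gene_id)] > 0.85))
  expect_true(all(cls$pollen_value[grepl("BG", cls$gene_id)] == 0))
  ## regression mode pins the mean pollen level
  tg <- setNames(c(8, 3), c("FG001", "FG002"))
  em2 <- gen_expression(spec, sprintf("FG%03d", 1:13), character(0),
                        pollen_target = tg, replicate_sd = 0.05)
  got <- build_target(em2, names(tg))
  expect_equal(unname(got), unname(tg), tolerance = 0.15)
})

test_that("the synthetic known-TF database wires the expression gate", {
  pl <- random_motif(seed = 31)
  spec <- synthetic_spec(planted_motifs = list(list(motif = pl, fg_coverage = 0.9,
                                                    bg_coverage = 0.05,
                                                    conserved = TRUE)),
                         seed = 37)
  db <- gen_known_db(spec, n_decoys = 20)
  expect_length(db$motifs, 21)
  planted_name <- paste0("TF_", pl$name)
  expect_true(planted_name %in% names(db$motifs))
  expect_gte(db$tf_expression[planted_name], 1)
  expect_true(any(db$tf_expression < 1))        # some decoys sub-threshold
  ## database round-trips through the MEME reader
  path <- tempfile(fileext = ".meme")
  write_meme(db$motifs, path)
  back <- read_meme(path)
  expect_length(back$motifs, 21)
  expect_lt(max(abs(back$motifs[[planted_name]]$probs - db$motifs[[planted_name]]$probs)),
            1e-6)
  ## a planted query matches its database entry
  res <- match_known(list(pl), db$motifs, db$tf_expression)
  expect_equal(res$target_name[1], planted_name)
})

test_that("ortholog generation respects rates and site conservation flags", {
  pl <- random_motif(seed = 41)
  spec <- synthetic_spec(n_fg_genes = 4L, n_bg_genes = 2L, promoter_len = 600L,
                         planted_motifs = list(list(motif = pl, fg_coverage = 1,
                                                    bg_coverage = 0, conserved = TRUE)),
                         ortholog_mutation_rate = 0.1, seed = 43)
  pr <- gen_promoters(spec)
  orth <- gen_orthologs(pr$fg, pr$truth, spec)
  ## conserved planted windows are copied intact
  for (i in seq_len(nrow(pr$truth))) {
    tr <- pr$truth[i, ]
    a_site <- substr(pr$fg[[tr$gene_id]], tr$start + 1, tr$start + 12)
    expect_true(grepl(a_site, orth[[tr$gene_id]], fixed = TRUE))
  }
  ## mutation rate 0 and indel rate 0 reproduce the input exactly
  spec0 <- synthetic_spec(n_fg_genes = 4L, n_bg_genes = 2L, promoter_len = 600L,
                          ortholog_mutation_rate = 0, ortholog_indel_rate = 0,
                          seed = 43)
  pr0 <- gen_promoters(spec0)
  expect_identical(gen_orthologs(pr0$fg, pr0$truth, spec0), pr0$fg)
  expect_error(synthetic_spec(ortholog_mutation_rate = 1.2), "rates")
})
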