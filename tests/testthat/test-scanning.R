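test_that("window log-odds scores match closed forms", {
  uni <- motif("u", probs = matrix(0.25, 4, 6), source = "iupac")
  expect_equal(score_window(uni, "ACGTAC"), 0)
  ## single-column A motif: floor-adjusted probability keeps this near 2 bits
  mA <- iupac_to_motif("A")
  expect_equal(score_window(mA, "A"), 2, tolerance = 2e-3)
  expect_error(score_window(mA, "AA"), "length")
  ## N columns contribute zero (score as background)
  m <- consensus_motif("ACGT")
  expect_equal(score_window(m, "NNNN"), 0)
  sm <- pollenmotif:::score_matrix(m, background_model())
  expect_equal(score_window(m, "ACGN"), sum(sm[cbind(1:3, 1:3)]))
})

test_that("consensus window maximizes the score over all windows", {
  m <- consensus_motif("ACGTTGC")
  bf <- brute_force_pvalues(m)
  cons_score <- score_window(m, "ACGTTGC")
  expect_equal(cons_score, max(bf$scores), tolerance = 1e-9)
})

test_that("exact DP p-values agree with brute-force enumeration (L <= 8)", {
  bg_sets <- list(background_model(),
                  background_model(c(A = 0.35, C = 0.15, G = 0.15, T = 0.35)))
  motifs <- list(consensus_motif("ACGTT"), iupac_to_motif("GADGAY"),
                 smooth_motif(7, seed = 4))
  for (bg in bg_sets) {
    for (m in motifs) {
      tab <- score_pvalue_table(m, bg)
      bf <- brute_force_pvalues(m, bg)
      grid <- as.matrix(expand.grid(rep(list(1:4), motif_width(m))))
      ints <- rowSums(matrix(tab$int_matrix[cbind(as.vector(grid),
                                                  rep(seq_len(motif_width(m)), each = nrow(grid)))],
                             nrow = nrow(grid)))
      dp_p <- pollenmotif:::lookup_pvalue(tab, ints)
      bf_p <- vapply(bf$scores, bf$pvalue, numeric(1))
      ## discretization bound: both the window score and the enumerated
      ## scores shift by up to w*granularity/2 each on the integer grid
      bound <- 2 * motif_width(m) * tab$granularity
      tol <- vapply(bf$scores, function(s) {
        sum(bf$probs[abs(bf$scores - s) <= bound + 1e-12])
      }, numeric(1))
      expect_true(all(abs(dp_p - bf_p) <= tol + 1e-12))
    }
  }
  ## for a motif without large tied score classes the agreement is tight
  m <- smooth_motif(7, seed = 4)
  tab <- score_pvalue_table(m)
  bf <- brute_force_pvalues(m)
  grid <- as.matrix(expand.grid(rep(list(1:4), 7)))
  ints <- rowSums(matrix(tab$int_matrix[cbind(as.vector(grid),
                                              rep(1:7, each = nrow(grid)))],
                         nrow = nrow(grid)))
  dp_p <- pollenmotif:::lookup_pvalue(tab, ints)
  bf_p <- vapply(bf$scores, bf$pvalue, numeric(1))
  expect_lt(max(abs(dp_p - bf_p)), 5e-3)
})

test_that("p-value table is monotone with p = 1 at the minimum score", {
  m <- smooth_motif(9, seed = 8)
  tab <- score_pvalue_table(m)
  expect_true(all(diff(tab$pvalue) <= 1e-15))
  expect_equal(tab$pvalue[1], 1)
})

test_that("scanning finds planted sites on both strands at the right offsets", {
  m <- consensus_motif("ACGTTGCATGCA")
  seqs <- c(g1 = rand_seq(300, 21), g2 = rand_seq(300, 22), g3 = rand_seq(300, 23))
  substr(seqs["g1"], 51, 62) <- "ACGTTGCATGCA"
  substr(seqs["g2"], 101, 112) <- pollenmotif:::revcomp_string("ACGTTGCATGCA")
  occ <- scan_motif(m, seqs)
  expect_true(any(occ$gene_id == "g1" & occ$start == 50 & occ$strand == "+"))
  expect_true(any(occ$gene_id == "g2" & occ$start == 100 & occ$strand == "-"))
  ## forward-only scan misses the minus-strand site
  occ_f <- scan_motif(m, seqs, strands = "forward")
  expect_false(any(occ_f$gene_id == "g2" & occ_f$start == 100))
  ## threshold 1 reports every window on both strands
  all_occ <- scan_motif(m, seqs["g3"], p_threshold = 1.000001)
  expect_equal(nrow(all_occ), 2 * (300 - 12 + 1))
  ## sequences shorter than the motif are skipped with a warning
  expect_warning(scan_motif(m, c(tiny = "ACGT", g3 = seqs[["g3"]])), "skipped")
})

test_that("empirical hit rate on iid background matches the nominal threshold", {
  ## a smooth motif has a dense score distribution, so the achievable
  ## p-value just below the threshold is ~ the threshold itself
  m <- smooth_motif(16, seed = 33)
  seqs <- setNames(vapply(1:100, function(i) rand_seq(1000, 4000 + i), character(1)),
                   sprintf("r%03d", 1:100))
  occ <- scan_motif(m, seqs, p_threshold = 1e-4)
  expected <- 2 * (1000 - 16 + 1) * 1e-4 * 100
  se <- sqrt(expected)
  expect_lt(abs(nrow(occ) - expected), 3 * se)
})

test_that("coverage statistics reproduce the nearest-integer rounding rule", {
  mk_occ <- function(genes) data.frame(gene_id = as.character(genes),
                                       start = rep(0L, length(genes)),
                                       strand = rep("+", length(genes)),
                                       score = rep(1, length(genes)),
                                       pvalue = rep(1e-5, length(genes)))
  cov <- coverage_stats("m", mk_occ(sprintf("f%d", 1:11)), mk_occ(sprintf("b%d", 1:25)),
                        13, 132)
  expect_equal(cov$fg_coverage_pct, 85)
  expect_equal(cov$bg_coverage_pct, 19)
  expect_equal(cov$relative_frequency, (11 / 13) / (25 / 132))
  ## multiplicity does not double-count genes
  cov2 <- coverage_stats("m", mk_occ(c("f1", "f1", "f2")), mk_occ(character(0)), 13, 132)
  expect_equal(cov2$fg_hits, 2)
  expect_equal(cov2$relative_frequency, Inf)
  expect_error(coverage_stats("m", mk_occ("f1"), mk_occ("b1"), 0, 132), "positive")
})

test_that("feature matrix holds -log10 best p with zero for no-hit genes", {
  m <- consensus_motif("ACGTTGCATGCA", name = "planted")
  seqs <- c(hit = rand_seq(300, 61), miss = rand_seq(300, 62))
  substr(seqs["hit"], 101, 112) <- "ACGTTGCATGCA"
  fm <- feature_matrix(list(m), seqs)
  expect_equal(dim(fm), c(2, 1))
  best <- min(scan_motif(m, seqs["hit"])$pvalue)
  expect_equal(fm["hit", "planted"], -log10(best))
  expect_equal(fm["miss", "planted"], 0)
})

test_that("occurrence TSV export uses 0-based half-open coordinates", {
  m <- consensus_motif("ACGTTGCATGCA")
  s <- c(g = rand_seq(200, 77))
  substr(s["g"], 51, 62) <- "ACGTTGCATGCA"
  occ <- scan_motif(m, s)
  path <- tempfile(fileext = ".tsv")
  write_occurrences(occ, motif_width(m), path)
  df <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(df$end - df$start, rep(12, nrow(df)))
  expect_true(any(df$start == 50 & df$end == 62))
})
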