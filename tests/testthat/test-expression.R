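test_that("log transform zeroes sub-threshold values on the log scale", {
  expect_equal(log_transform(0), 0)            # log2(1) = 0 < 1 -> zeroed
  expect_equal(log_transform(1), 1)            # log2(2) = 1, kept
  expect_equal(log_transform(0.9), 0)          # log2(1.9) ~ 0.93 < 1 -> zeroed
  expect_equal(log_transform(3), 2)
  expect_error(log_transform(-1), "non-negative")
})

test_that("Tau hits its limits exactly and matches hand arithmetic", {
  expect_equal(compute_tau(c(0, 0, 5, rep(0, 8))), 1)
  expect_equal(compute_tau(rep(4, 4)), 0)
  ## x_hat = (1, .5, .25, 0); sum(1 - x_hat) = 2.25; / 3 = 0.75
  expect_equal(compute_tau(c(8, 4, 2, 0)), 0.75)
  expect_true(is.na(compute_tau(c(0, 0, 0))))
  expect_error(compute_tau(5), "at least 2")
})

test_that("Tau is scale-invariant and monotone under background raising", {
  with_seed(101, {
    for (i in 1:20) {
      x <- runif(11, 0, 10)
      tau <- compute_tau(x)
      expect_true(tau >= 0 && tau <= 1)
      expect_equal(compute_tau(x * runif(1, 0.1, 50)), tau)
      ## raising a non-maximal tissue toward the max never increases Tau
      j <- which.min(x)
      x2 <- x
      x2[j] <- x2[j] + runif(1) * (max(x) - x2[j])
      expect_lte(compute_tau(x2), tau + 1e-12)
    }
  })
})

test_that("tissue aggregation takes the median of log-transformed replicates", {
  prof <- aggregate_by_tissue(tiny_expr(), "g_flat")
  expect_equal(prof$n_tissues, 3)
  ## leaf samples raw (61, 63): median(log2(62), log2(64)) by hand
  expect_equal(unname(prof$tissue_values["leaf"]),
               median(log2(c(61, 63) + 1)))
  expect_error(aggregate_by_tissue(tiny_expr(), "nope"), "unknown gene")
  ## three identical raw-3 samples -> log2(4) = 2
  em <- expression_matrix(
    matrix(c(3, 3, 3, 0, 0, 0), nrow = 1,
           dimnames = list("g", paste0("s", 1:6))),
    setNames(rep(c("a", "b"), each = 3), paste0("s", 1:6)))
  expect_equal(unname(aggregate_by_tissue(em, "g")$tissue_values["a"]), 2)
})

test_that("classification flags tissue-specific genes with a strict threshold", {
  cls <- classify_genes(tiny_expr())
  expect_true(cls$is_tissue_specific[cls$gene_id == "g_pollen"])
  expect_equal(cls$top_tissue[cls$gene_id == "g_pollen"], "pollen")
  expect_false(cls$is_tissue_specific[cls$gene_id == "g_flat"])
  expect_true(is.na(cls$tau[cls$gene_id == "g_zero"]))
  expect_false(cls$is_tissue_specific[cls$gene_id == "g_zero"])
})

test_that("gene-set selection yields disjoint pollen-specific and non-pollen sets", {
  em <- tiny_expr()
  sets <- select_gene_sets(em, rownames(em$values))
  expect_equal(sets$pollen_specific, "g_pollen")
  expect_true("g_root" %in% sets$non_pollen)
  expect_false("g_pollen" %in% sets$non_pollen)
  expect_length(intersect(sets$pollen_specific, sets$non_pollen), 0)
  ## flat gene is in neither set
  expect_false("g_flat" %in% c(sets$pollen_specific, sets$non_pollen))
  ## absent ids are skipped with a message
  expect_message(select_gene_sets(em, c(rownames(em$values), "ghost")),
                 "skipping 1")
})

test_that("expression tiers use population standard deviations from the mean", {
  pop <- c(rep(0, 50), rep(1, 50))   # mean 0.5, population sd 0.5
  expect_equal(expression_tier(0.5 + 3.5 * 0.5, pop), "extremely_high")
  expect_equal(expression_tier(0.5 + 2.5 * 0.5, pop), "high")
  expect_equal(expression_tier(0.5, pop), "other")
  expect_equal(expression_tier(c(1, 2), population = rep(7, 5)), c("other", "other"))
})

test_that("z-score matrix standardizes rows; constant rows become zeros", {
  em <- tiny_expr()
  z <- zscore_matrix(em)
  expect_equal(dim(z), dim(em$values))
  expect_equal(unname(rowMeans(z)), rep(0, 4), tolerance = 1e-12)
  nonconst <- apply(log_transform(em$values), 1, function(r) length(unique(r)) > 1)
  for (g in rownames(z)[nonconst]) {
    expect_equal(sqrt(mean((z[g, ] - mean(z[g, ]))^2)), 1, tolerance = 1e-12)
  }
  expect_equal(unname(z["g_zero", ]), rep(0, 6))
  ## row (0, 2) with population sd -> (-1, 1)
  em2 <- expression_matrix(matrix(c(0, 3), 1, dimnames = list("g", c("s1", "s2"))),
                           setNames(c("a", "b"), c("s1", "s2")))
  expect_equal(unname(zscore_matrix(em2)[1, ]), c(-1, 1))
})

test_that("expression TSV round-trips through the reader", {
  em <- tiny_expr()
  ef <- tempfile(fileext = ".tsv"); tf <- tempfile(fileext = ".tsv")
  write.table(data.frame(gene = rownames(em$values), em$values, check.names = FALSE),
              ef, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample = names(em$tissues), tissue = em$tissues),
              tf, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  em2 <- read_expression_tsv(ef, tf)
  expect_equal(em2$values, em$values)
  expect_equal(em2$tissues, em$tissues)
})

test_that("regression target is the mean pollen log expression", {
  em <- tiny_expr()
  tg <- build_target(em, c("g_pollen", "g_root"))
  expect_equal(unname(tg["g_pollen"]), mean(log2(c(500, 480) + 1)))
  expect_equal(unname(tg["g_root"]), 0)  # zero-in-pollen definition
  expect_error(build_target(em, "g_pollen", pollen_tissue = "petal"), "no samples")
})
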