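## Shared fixtures, built in code.

## deterministic random DNA
rand_seq <- function(len, seed) {
  with_seed(seed, paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""))
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

## tiny expression matrix: 3 tissues x 2 samples each, 4 genes
tiny_expr <- function() {
  samples <- c("p1", "p2", "r1", "r2", "l1", "l2")
  tissues <- setNames(c("pollen", "pollen", "root", "root", "leaf", "leaf"), samples)
  vals <- rbind(
    g_pollen = c(500, 480, 0.2, 0.1, 0.4, 0.3),   # pollen-specific
    g_root   = c(0.1, 0.3, 120, 130, 0.5, 0.2),   # root-specific, zero in pollen
    g_flat   = c(60, 64, 62, 58, 61, 63),         # uniform
    g_zero   = c(0, 0, 0, 0, 0, 0)                # silent
  )
  colnames(vals) <- samples
  expression_matrix(vals, tissues)
}

## a sharp toy motif from a consensus string
consensus_motif <- function(cons, name = cons, dominance = 0.95) {
  codes <- match(strsplit(cons, "")[[1]], c("A", "C", "G", "T"))
  probs <- matrix((1 - dominance) / 3, nrow = 4, ncol = length(codes))
  probs[cbind(codes, seq_along(codes))] <- dominance
  motif(name, probs = probs, source = "discovered")
}

## a smooth motif (random stochastic columns) for null-rate checks
smooth_motif <- function(width, seed, name = sprintf("smooth%d", seed)) {
  with_seed(seed, {
    probs <- matrix(runif(4 * width, 0.5, 1.5), nrow = 4)
    probs <- sweep(probs, 2, colSums(probs), "/")
    motif(name, probs = probs, source = "discovered")
  })
}

## brute-force motif-score p-values over all 4^L windows (oracle for the DP)
brute_force_pvalues <- function(m, bg = background_model()) {
  L <- motif_width(m)
  sm <- pollenmotif:::score_matrix(m, bg)
  grid <- as.matrix(expand.grid(rep(list(1:4), L)))
  scores <- rowSums(matrix(sm[cbind(as.vector(grid), rep(seq_len(L), each = nrow(grid)))],
                           nrow = nrow(grid)))
  wprob <- apply(grid, 1, function(cd) prod(bg[cd]))
  list(scores = scores, probs = wprob,
       pvalue = function(s) sum(wprob[scores >= s - 1e-9]))
}
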