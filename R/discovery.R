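#' Discovery configuration
#'
#' Settings for discriminative de novo motif discovery: k-mer seed
#' enumeration over lengths `min_len..max_len` (6-16 nt), followed by
#' ZOOPS (zero-or-one occurrence per sequence) EM refinement of the top
#' seeds per length.
#'
#' @param min_len,max_len Motif length range, within 6..16.
#' @param n_seeds Seed candidates retained per length (ranked by
#'   hypergeometric enrichment p-value; default 50).
#' @param n_refine Seeds per length refined by EM (default 5).
#' @param em_max_iter,em_tol EM stopping rule: stop when the log-likelihood
#'   gain drops below `em_tol` or after `em_max_iter` iterations.
#' @param min_ic_per_col Refined motifs with information content below this
#'   (bits per column, uniform background) are flagged low-confidence:
#'   ZOOPS EM run on a foreground without a shared motif converges to a
#'   smeared average of unrelated windows whose per-column information
#'   stays near 1 bit, while genuinely shared sites refine well above it
#'   (default 1.1, the gap between the two regimes in planted-vs-random
#'   calibration runs).
#' @param seed RNG seed propagated to stochastic steps.
#' @param strands `"both"` or `"forward"` for seed counting and EM.
#' @return A list of class `discovery_config`.
#' @export
discovery_config <- function(min_len = 6L, max_len = 16L, n_seeds = 50L,
                             n_refine = 5L, em_max_iter = 100L, em_tol = 1e-4,
                             min_ic_per_col = 1.1,
                             seed = 1L, strands = c("both", "forward")) {
  strands <- match.arg(strands)
  if (min_len < 6L || max_len > 16L || min_len > max_len) {
    stop("motif lengths must satisfy 6 <= min_len <= max_len <= 16")
  }
  structure(list(min_len = as.integer(min_len), max_len = as.integer(max_len),
                 n_seeds = as.integer(n_seeds), n_refine = as.integer(n_refine),
                 em_max_iter = as.integer(em_max_iter), em_tol = em_tol,
                 min_ic_per_col = min_ic_per_col,
                 seed = as.integer(seed), strands = strands),
            class = "discovery_config")
}

## set of distinct k-mers present in a sequence (ACGT only), optionally
## including the reverse-complement strand
kmer_set <- function(s, k, both_strands = TRUE) {
  grab <- function(x) {
    n <- nchar(x) - k + 1L
    if (n < 1L) return(character(0))
    km <- substring(x, 1:n, k:(n + k - 1L))
    km[!grepl("[^ACGT]", km)]
  }
  km <- grab(toupper(s))
  if (both_strands) km <- c(km, grab(revcomp_string(toupper(s))))
  unique(km)
}

#' Enumerate discriminative k-mer seeds
#'
#' Counts, for every k-mer present in the foreground, the number of
#' foreground and background genes containing it (on both strands), and
#' scores enrichment with the hypergeometric tail
#' `P(X >= fg_hits)` for drawing `n_fg` genes out of `n_fg + n_bg` with
#' `fg_hits + bg_hits` marked.
#'
#' @param fg,bg Named character vectors of promoter sequences.
#' @param k Seed length, 6..16 and at most the shortest sequence length.
#' @param both_strands Count k-mers on both strands (default TRUE).
#' @return data.frame sorted by ascending `enrichment_pvalue`: `kmer`,
#'   `fg_genes_with_hit`, `bg_genes_with_hit`, `enrichment_pvalue`.
#' @export
enumerate_seeds <- function(fg, bg, k, both_strands = TRUE) {
  if (k > min(nchar(c(fg, bg)))) stop("k exceeds the shortest sequence length")
  fg_sets <- lapply(fg, kmer_set, k = k, both_strands = both_strands)
  bg_sets <- lapply(bg, kmer_set, k = k, both_strands = both_strands)
  fg_tab <- table(unlist(fg_sets, use.names = FALSE))
  bg_tab <- table(unlist(bg_sets, use.names = FALSE))
  kmers <- names(fg_tab)
  fg_hits <- as.integer(fg_tab)
  bg_hits <- as.integer(bg_tab[kmers])
  bg_hits[is.na(bg_hits)] <- 0L
  n_fg <- length(fg); n_bg <- length(bg)
  ## P(X >= fg_hits), X ~ Hypergeom(marked = fg_hits + bg_hits, drawn = n_fg)
  p <- phyper(fg_hits - 1L, fg_hits + bg_hits,
              n_fg + n_bg - fg_hits - bg_hits, n_fg, lower.tail = FALSE)
  out <- data.frame(kmer = kmers, fg_genes_with_hit = fg_hits,
                    bg_genes_with_hit = bg_hits, enrichment_pvalue = p,
                    stringsAsFactors = FALSE)
  out <- out[order(out$enrichment_pvalue, -out$fg_genes_with_hit, out$kmer), ]
  rownames(out) <- NULL
  out
}

## Seed PWM from a k-mer: consensus base 0.7, others 0.1
seed_matrix <- function(kmer, match_prob = 0.7) {
  codes <- encode_seq(kmer)
  probs <- matrix((1 - match_prob) / 3, nrow = 4, ncol = length(codes))
  probs[cbind(codes, seq_along(codes))] <- match_prob
  rownames(probs) <- DNA_BASES
  probs
}

#' Refine a seed motif by ZOOPS expectation-maximization
#'
#' Fits the two-component ZOOPS model on the foreground: each sequence
#' carries at most one motif site at an unknown position/strand; elsewhere
#' the sequence follows the 0-order background. The E-step computes the
#' posterior over site positions (and the no-site alternative), the M-step
#' re-estimates the probability matrix from expected site counts under a
#' Dirichlet pseudocount of 0.25 per base, and the site prior by its
#' expected frequency. The reported objective (observed-data log-likelihood
#' up to the constant background term, plus the Dirichlet penalty) is
#' non-decreasing across iterations; iteration stops when its gain falls
#' below `em_tol`.
#'
#' @param seed_kmer Seed k-mer string (or a 4 x w probability matrix).
#' @param fg Named character vector of foreground sequences.
#' @param bg Background model.
#' @param cfg A [discovery_config()].
#' @param name Name for the refined motif.
#' @return A [motif()] (source `"discovered"`) with attributes
#'   `objective` (per-iteration trace of the EM objective), `site_prior`,
#'   and `converged`.
#' @export
em_refine <- function(seed_kmer, fg, bg = background_model(),
                      cfg = discovery_config(), name = NULL) {
  probs <- if (is.character(seed_kmer)) seed_matrix(seed_kmer) else as.matrix(seed_kmer)
  w <- ncol(probs)
  if (w < cfg$min_len || w > cfg$max_len) {
    stop(sprintf("seed width %d outside [%d, %d]", w, cfg$min_len, cfg$max_len))
  }
  if (is.null(name)) {
    name <- if (is.character(seed_kmer)) paste0("em_", seed_kmer) else "em_motif"
  }
  both <- cfg$strands == "both"
  alpha <- 0.25  # Dirichlet pseudocount per base
  ## encode all candidate windows once: per sequence, a (positions x w)
  ## integer matrix over codes 1..4 (5 = N) covering both strands
  win_list <- lapply(fg, function(s) {
    codes <- encode_seq(toupper(s))
    n <- length(codes) - w + 1L
    if (n < 1L) return(NULL)
    idx <- outer(seq_len(n), 0:(w - 1L), "+")
    fwm <- matrix(codes[idx], nrow = n)
    if (both) {
      rc <- rev(5L - codes)
      rcm <- matrix(rc[idx], nrow = n)
      rbind(fwm, rcm)
    } else fwm
  })
  win_list <- win_list[!vapply(win_list, is.null, logical(1))]
  if (length(win_list) == 0L) stop("no foreground sequence is as long as the seed")
  for (i in seq_along(win_list)) win_list[[i]][is.na(win_list[[i]])] <- 5L

  ## flatten windows of all sequences into one matrix for vectorized E/M steps
  W <- do.call(rbind, win_list)
  seq_id <- rep(seq_along(win_list), vapply(win_list, nrow, integer(1)))
  n_win <- vapply(win_list, nrow, numeric(1))
  n_seq <- length(win_list)

  log_bg5 <- c(log(bg), 0)
  lr_bg <- numeric(nrow(W))
  col_off <- (seq_len(w) - 1L) * 5L
  for (j in seq_len(w)) lr_bg <- lr_bg + log_bg5[W[, j]]

  prior <- 0.5   # P(sequence contains a site)
  objective <- numeric(0)
  converged <- FALSE
  exp_sites <- 0
  for (iter in seq_len(cfg$em_max_iter)) {
    log_p5 <- rbind(log(pmax(probs, 1e-10)), 0)
    lr <- -lr_bg
    for (j in seq_len(w)) lr <- lr + log_p5[W[, j] + col_off[j]]
    elr <- exp(lr)                       # bounded: lr <= w * log(4) + |min bg|
    A <- rowsum(elr, seq_id)[, 1]        # per-sequence sum of likelihood ratios
    denom_seq <- (1 - prior) + (prior / n_win) * A
    ll <- sum(log(denom_seq))
    z <- (prior / n_win[seq_id]) * elr / denom_seq[seq_id]
    exp_sites <- sum(z)
    objective <- c(objective, ll + alpha * sum(log(pmax(probs, 1e-10))))
    if (iter > 1L && (objective[iter] - objective[iter - 1L]) < cfg$em_tol) {
      converged <- TRUE
      break
    }
    ## M-step: expected base counts per column
    exp_counts <- matrix(0, nrow = 4, ncol = w)
    for (j in seq_len(w)) {
      cj <- W[, j]
      for (b in 1:4) exp_counts[b, j] <- sum(z[cj == b])
    }
    probs <- sweep(exp_counts + alpha, 2, colSums(exp_counts) + 4 * alpha, "/")
    prior <- min(max(exp_sites / n_seq, 1e-3), 1 - 1e-3)
  }
  out <- motif(name, probs = probs,
               nsites = max(1L, round(exp_sites)), source = "discovered")
  attr(out, "objective") <- objective
  attr(out, "site_prior") <- prior
  attr(out, "converged") <- converged
  if (!converged) warning(sprintf("EM for '%s' stopped at max_iter without converging", name))
  out
}

#' Discriminative motif discovery on foreground vs background promoters
#'
#' For each length in `min_len..max_len`, enumerates hypergeometrically
#' enriched k-mer seeds ([enumerate_seeds()]), refines the top `n_refine`
#' seeds by ZOOPS EM ([em_refine()]), and returns the refined motifs with
#' their seed statistics. Motifs whose information content falls below
#' `cfg$min_ic_per_col` bits per column carry a `low_confidence` attribute
#' (TRUE); downstream stages should exclude them. Deterministic given
#' `cfg$seed`.
#'
#' @param fg,bg Named character vectors of promoter sequences.
#' @param cfg A [discovery_config()].
#' @param background Background model (default estimated from `bg`).
#' @return A list with `motifs` (list of discovered [motif()]s, each with a
#'   `low_confidence` attribute) and `seeds` (data.frame of all retained
#'   seed candidates with a `length` column).
#' @export
discover_motifs <- function(fg, bg, cfg = discovery_config(),
                            background = NULL) {
  if (length(fg) == 0L || length(bg) == 0L) {
    stop("foreground and background sets must be non-empty")
  }
  if (is.null(background)) background <- estimate_background(bg)
  motifs <- list()
  seed_rows <- list()
  for (k in cfg$min_len:cfg$max_len) {
    seeds <- enumerate_seeds(fg, bg, k, both_strands = cfg$strands == "both")
    seeds <- head(seeds, cfg$n_seeds)
    if (nrow(seeds) == 0L) next
    seeds$length <- k
    seed_rows[[length(seed_rows) + 1L]] <- seeds
    top <- head(seeds, cfg$n_refine)
    for (i in seq_len(nrow(top))) {
      nm <- sprintf("disc_w%d_%s", k, top$kmer[i])
      m <- em_refine(top$kmer[i], fg, background, cfg, name = nm)
      attr(m, "low_confidence") <-
        information_content(m) / motif_width(m) < cfg$min_ic_per_col
      motifs[[nm]] <- m
    }
  }
  list(motifs = motifs,
       seeds = if (length(seed_rows)) do.call(rbind, seed_rows) else
         data.frame(kmer = character(0), fg_genes_with_hit = integer(0),
                    bg_genes_with_hit = integer(0),
                    enrichment_pvalue = numeric(0), length = integer(0)))
}
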