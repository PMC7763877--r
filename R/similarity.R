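## Standardize motif columns for Pearson-correlation distances.
## Returns list(z = 4 x L standardized columns (unit norm), const = logical)
standardize_cols <- function(probs) {
  mu <- colMeans(probs)
  cen <- sweep(probs, 2, mu, "-")
  ss <- sqrt(colSums(cen^2))
  const <- ss < 1e-12
  z <- sweep(cen, 2, ifelse(const, 1, ss), "/")
  list(z = z, const = const)
}

## 1 - Pearson correlation between every query column and every target column.
## Constant columns: distance 0 vs another constant column, 1 otherwise.
column_distance_matrix <- function(q, t) {
  zq <- standardize_cols(q)
  zt <- standardize_cols(t)
  D <- 1 - crossprod(zq$z, zt$z)       # cor = dot of unit-normalized columns
  D[zq$const, ] <- 1
  D[, zt$const] <- 1
  if (any(zq$const) && any(zt$const)) D[zq$const, zt$const] <- 0
  D
}

## distance of each column to a background column
column_bg_distance <- function(probs, bg) {
  as.numeric(column_distance_matrix(probs, matrix(bg, ncol = 1)))
}

## Best (minimal) total distance over all offsets with >= min_overlap aligned
## columns; unaligned columns of either motif are penalized by their distance
## to a background column.
best_offset_distance <- function(D, dbg_q, dbg_t, min_overlap) {
  lq <- nrow(D); lt <- ncol(D)
  sum_q <- sum(dbg_q); sum_t <- sum(dbg_t)
  best <- Inf; best_off <- NA_integer_
  for (off in (-(lt - min_overlap)):(lq - min_overlap)) {
    j1 <- max(1L, 1L - off); j2 <- min(lt, lq - off)
    if (j2 - j1 + 1L < min_overlap) next
    js <- j1:j2
    qs <- off + js
    d <- sum(D[cbind(qs, js)]) +
      (sum_q - sum(dbg_q[qs])) + (sum_t - sum(dbg_t[js]))
    if (d < best - 1e-12) { best <- d; best_off <- off }
  }
  list(distance = best, offset = best_off)
}

## Per-shuffle best distance, vectorized over the rows of perm_mat
## (n_shuffle x lt permutations of target columns).
null_best_distances <- function(D, dbg_q, dbg_t, min_overlap, perm_mat) {
  lq <- nrow(D); lt <- ncol(D)
  ns <- nrow(perm_mat)
  sum_q <- sum(dbg_q); sum_t <- sum(dbg_t)
  dbg_t_perm <- matrix(dbg_t[perm_mat], nrow = ns)   # per-shuffle bg penalties
  best <- rep(Inf, ns)
  for (off in (-(lt - min_overlap)):(lq - min_overlap)) {
    j1 <- max(1L, 1L - off); j2 <- min(lt, lq - off)
    k <- j2 - j1 + 1L
    if (k < min_overlap) next
    js <- j1:j2
    qs <- off + js
    ## linear indices into D for each shuffle: row qs[j], col perm[, js[j]]
    idx <- matrix(qs, nrow = ns, ncol = k, byrow = TRUE) +
      (perm_mat[, js, drop = FALSE] - 1L) * lq
    d <- rowSums(matrix(D[idx], nrow = ns)) +
      (sum_q - sum(dbg_q[qs])) +
      (sum_t - rowSums(dbg_t_perm[, js, drop = FALSE]))
    best <- pmin(best, d)
  }
  best
}

#' Compare two motifs (column-correlation distance with a shuffle null)
#'
#' Aligns the query to the target at every offset (both orientations)
#' requiring at least `min_overlap` overlapping columns; the distance at an
#' offset is the sum over aligned column pairs of `1 - Pearson correlation`
#' of their 4-vectors, plus the same distance against a background column
#' for every unaligned column of either motif. The p-value is Monte-Carlo:
#' the best distance is ranked against `n_shuffle` column-shuffled versions
#' of the target scored identically (seeded, so deterministic).
#'
#' @param query,target [motif()] objects.
#' @param bg Background model (penalty column for unaligned positions).
#' @param min_overlap Minimum aligned columns (default 4).
#' @param n_shuffle Null sample size (default 2000; the smallest achievable
#'   p is `1/(n_shuffle+1)`).
#' @param seed RNG seed for the shuffle null.
#' @return A one-row data.frame: `query_name`, `target_name`, `offset`
#'   (target column 1 relative to query column 1), `orientation` (+/-),
#'   `distance`, `pvalue`.
#' @export
compare_motifs <- function(query, target, bg = background_model(),
                           min_overlap = 4L, n_shuffle = 2000L, seed = 1L) {
  lq <- motif_width(query); lt <- motif_width(target)
  if (min(lq, lt) < min_overlap) {
    stop(sprintf("motifs narrower than min_overlap=%d cannot be compared", min_overlap))
  }
  tp <- target$probs
  tp_rc <- reverse_complement(target)$probs
  D_fw <- column_distance_matrix(query$probs, tp)
  D_rc <- column_distance_matrix(query$probs, tp_rc)
  dbg_q <- column_bg_distance(query$probs, bg)
  dbg_t <- column_bg_distance(tp, bg)
  dbg_t_rc <- column_bg_distance(tp_rc, bg)

  obs_fw <- best_offset_distance(D_fw, dbg_q, dbg_t, min_overlap)
  obs_rc <- best_offset_distance(D_rc, dbg_q, dbg_t_rc, min_overlap)
  if (obs_fw$distance <= obs_rc$distance) {
    obs <- obs_fw; orientation <- "+"
  } else {
    obs <- obs_rc; orientation <- "-"
  }

  ## Column-shuffle null: permuting target columns permutes the columns of
  ## D_fw directly. For the rc orientation, column j' of rc(shuffled t) is the
  ## complement of shuffled column lt+1-j', whose distances are the columns of
  ## D_comp = distances to complemented (un-reversed) target columns.
  D_comp <- D_rc[, rev(seq_len(lt)), drop = FALSE]
  dbg_t_comp <- dbg_t_rc[rev(seq_len(lt))]
  perm_mat <- with_isolated_rng(seed, {
    t(vapply(seq_len(n_shuffle), function(i) sample.int(lt), integer(lt)))
  })
  nb_fw <- null_best_distances(D_fw, dbg_q, dbg_t, min_overlap, perm_mat)
  nb_rc <- null_best_distances(D_comp, dbg_q, dbg_t_comp, min_overlap,
                               perm_mat[, rev(seq_len(lt)), drop = FALSE])
  null_best <- pmin(nb_fw, nb_rc)
  pvalue <- (1 + sum(null_best <= obs$distance + 1e-12)) / (n_shuffle + 1)

  data.frame(query_name = query$name, target_name = target$name,
             offset = obs$offset, orientation = orientation,
             distance = obs$distance, pvalue = pvalue,
             stringsAsFactors = FALSE)
}

## Run `expr` under a private RNG seed, leaving the caller's RNG untouched.
with_isolated_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Match query motifs against a known-TF motif database
#'
#' The database is first restricted to TFs whose pollen expression (log2)
#' meets `expr_threshold`; each query is then compared to every remaining
#' database motif and matches with `pvalue < p_threshold` are reported,
#' best first.
#'
#' @param queries List of [motif()] objects.
#' @param db List of [motif()] objects with names identifying TFs.
#' @param tf_expression Named numeric: log2 pollen expression per TF
#'   (names matching `db` motif names).
#' @param p_threshold Similarity cutoff (default 0.001).
#' @param expr_threshold Minimum TF log2 pollen expression (default 1).
#' @param bg,min_overlap,n_shuffle,seed Passed to [compare_motifs()].
#' @return data.frame of matches (possibly 0 rows): query_name,
#'   target_name, offset, orientation, distance, pvalue.
#' @export
match_known <- function(queries, db, tf_expression, p_threshold = 0.001,
                        expr_threshold = 1.0, bg = background_model(),
                        min_overlap = 4L, n_shuffle = 2000L, seed = 1L) {
  keep <- vapply(db, function(m) {
    e <- tf_expression[m$name]
    !is.na(e) && e >= expr_threshold
  }, logical(1))
  db <- db[keep]
  if (length(db) == 0L) {
    warning("no known motifs remain after the TF expression filter")
  }
  rows <- list()
  for (q in queries) {
    for (t in db) {
      cmp <- compare_motifs(q, t, bg, min_overlap, n_shuffle, seed)
      if (cmp$pvalue < p_threshold) rows[[length(rows) + 1L]] <- cmp
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query_name = character(0), target_name = character(0),
               offset = integer(0), orientation = character(0),
               distance = numeric(0), pvalue = numeric(0))
  out[order(out$query_name, out$pvalue), , drop = FALSE]
}

#' Remove redundant (mutually similar) motifs
#'
#' Among each pair of similar motifs (similarity `pvalue < p_threshold`) the
#' member occurring in fewer foreground genes is dropped. Motifs are
#' processed from most to least foreground coverage (ties broken by higher
#' information content, then name) and kept only if dissimilar to every
#' already-kept motif, so the result contains no similar pair and, on
#' conflict chains, retains the maximal set of dissimilar survivors.
#'
#' @param motifs List of [motif()] objects.
#' @param fg_counts Named integer: foreground genes covered per motif.
#' @param p_threshold Similarity cutoff (default 0.001).
#' @param bg,min_overlap,n_shuffle,seed Passed to [compare_motifs()].
#' @return List with `kept` (list of motifs) and `dropped`
#'   (data.frame: motif, absorbed_by).
#' @export
remove_redundant <- function(motifs, fg_counts, p_threshold = 0.001,
                             bg = background_model(), min_overlap = 4L,
                             n_shuffle = 2000L, seed = 1L) {
  if (length(motifs) <= 1L) {
    return(list(kept = motifs,
                dropped = data.frame(motif = character(0), absorbed_by = character(0))))
  }
  nm <- vapply(motifs, function(m) m$name, character(1))
  ic <- vapply(motifs, information_content, numeric(1), bg = bg)
  cnt <- fg_counts[nm]
  if (any(is.na(cnt))) stop("fg_counts missing for some motifs")
  ord <- order(-cnt, -ic, nm)
  kept <- list()
  dropped <- list()
  for (i in ord) {
    absorbed <- NA_character_
    for (k in kept) {
      cmp <- compare_motifs(motifs[[i]], k, bg, min_overlap, n_shuffle, seed)
      if (cmp$pvalue < p_threshold) { absorbed <- k$name; break }
    }
    if (is.na(absorbed)) {
      kept[[length(kept) + 1L]] <- motifs[[i]]
    } else {
      dropped[[length(dropped) + 1L]] <-
        data.frame(motif = nm[i], absorbed_by = absorbed, stringsAsFactors = FALSE)
    }
  }
  list(kept = kept,
       dropped = if (length(dropped)) do.call(rbind, dropped) else
         data.frame(motif = character(0), absorbed_by = character(0)))
}
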