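## Column-wise Jensen-Shannon divergence (base 2) between two frequency
## matrices of equal width; returns per-column JSD in [0, 1] bits.
jsd_columns <- function(P, Q) {
  M <- (P + Q) / 2
  kl <- function(X, Y) colSums(ifelse(X > 0, X * log2(X / Y), 0))
  0.5 * kl(P, M) + 0.5 * kl(Q, M)
}

## inner product of expected gapped-k-mer occurrence vectors of two
## motifs (single given strands). Features are k-mers with at most one
## internal gap of length <= max_gap; occurrences summed over all
## placements overlapping the motif, with uniform background flanks.
gapped_inner <- function(fa, fb, k, max_gap) {
  La <- ncol(fa); Lb <- ncol(fb)
  smax <- k + max_gap
  xr <- (2L - smax):(La + smax - 1L)   # extended column indices, A
  yr <- (2L - smax):(Lb + smax - 1L)
  colx <- function(f, L, x) if (x >= 1L && x <= L) f[, x] else rep(0.25, 4L)
  C <- matrix(0, length(xr), length(yr))
  for (ix in seq_along(xr)) for (iy in seq_along(yr))
    C[ix, iy] <- sum(colx(fa, La, xr[ix]) * colx(fb, Lb, yr[iy]))
  offx <- 1L - xr[1L]; offy <- 1L - yr[1L]
  configs <- list(0:(k - 1L))
  for (g in seq_len(max_gap)) for (t in seq_len(k - 1L))
    configs[[length(configs) + 1L]] <- c(0:(t - 1L), (t + g):(k + g - 1L))
  total <- 0
  for (D in configs) {
    s <- max(D) + 1L                 # span of this gapped window
    irange <- (2L - s):La            # window starts overlapping motif A
    jrange <- (2L - s):Lb
    for (i in irange) {
      v <- rep(1, length(jrange))
      for (d in D) v <- v * C[i + d + offx, jrange + d + offy]
      total <- total + sum(v)
    }
  }
  total
}

#' Gapped k-mer similarity between motifs
#'
#' Cosine similarity of the motifs' expected gapped-k-mer occurrence
#' vectors (k-mers with up to one internal gap), strand-symmetrised by
#' averaging each motif's forward and reverse-complement vectors.
#' Symmetric, bounded in \[0, 1\], equal to 1 for identical motifs (and
#' for a motif against its own reverse complement), and near 0 for
#' motifs with disjoint sharp consensus sequences. Computed in closed
#' form (the inner product of expected-count vectors factorises over
#' positions), so no k-mer enumeration is performed.
#'
#' @param ma,mb `Motif` objects.
#' @param k word length of the feature space (default 10).
#' @param max_gap maximum internal gap length (default 5).
#' @return similarity in \[0, 1\].
#' @export
gapped_kmer_similarity <- function(ma, mb, k = 10L, max_gap = 5L) {
  fa <- motif_freq(ma); fb <- motif_freq(mb)
  far <- motif_freq(motif_revcomp(ma))
  fbr <- motif_freq(motif_revcomp(mb))
  ab <- (gapped_inner(fa, fb, k, max_gap) + gapped_inner(fa, fbr, k, max_gap)) / 2
  aa <- (gapped_inner(fa, fa, k, max_gap) + gapped_inner(fa, far, k, max_gap)) / 2
  bb <- (gapped_inner(fb, fb, k, max_gap) + gapped_inner(fb, fbr, k, max_gap)) / 2
  min(1, ab / sqrt(aa * bb))
}

#' Align a monomer motif against a composite motif
#'
#' Exhaustive ungapped alignment over all offsets and both orientations,
#' maximising the summed column similarity (one minus the per-column
#' Jensen-Shannon divergence) over the aligned columns; minimum overlap
#' of 4 columns. Ties prefer the smaller absolute offset, then the
#' same-strand orientation.
#'
#' @param monomer,composite `Motif` objects.
#' @param min_overlap minimum aligned columns (default 4).
#' @return An object of class `MotifAlignment`: `offset` (composite
#'   column of monomer column 1, minus 1; can be negative),
#'   `orientation` (`"same"` or `"revcomp"`), `score`, `mono_cols`,
#'   `comp_cols` (paired aligned column indices, monomer indices in its
#'   oriented frame).
#' @export
align_motifs <- function(monomer, composite, min_overlap = 4L) {
  fc <- motif_freq(composite)
  Lc <- ncol(fc); Lm <- motif_length(monomer)
  best <- NULL
  for (ori in c("same", "revcomp")) {
    fm <- if (ori == "same") motif_freq(monomer)
          else motif_freq(motif_revcomp(monomer))
    for (s in (1L - Lm):(Lc - 1L)) {   # monomer col j -> composite col s + j
      j <- seq_len(Lm)
      ok <- s + j >= 1L & s + j <= Lc
      if (sum(ok) < min_overlap) next
      mono_cols <- j[ok]; comp_cols <- s + mono_cols
      score <- sum(1 - jsd_columns(fm[, mono_cols, drop = FALSE],
                                   fc[, comp_cols, drop = FALSE]))
      cand <- list(offset = s, orientation = ori, score = score,
                   mono_cols = mono_cols, comp_cols = comp_cols)
      if (is.null(best) || score > best$score + 1e-12 ||
          (abs(score - best$score) <= 1e-12 &&
           (abs(s) < abs(best$offset) ||
            (abs(s) == abs(best$offset) && ori == "same" &&
             best$orientation == "revcomp"))))
        best <- cand
    }
  }
  if (is.null(best)) stop("no alignment with overlap >= ", min_overlap)
  structure(best, class = "MotifAlignment")
}

## product-of-frequency scores of all L-mers against a frequency matrix
## section (code-ordered vector of length 4^L)
section_kmer_scores <- function(f) {
  v <- 1
  for (j in seq_len(ncol(f))) v <- rep(v, each = 4L) * f[, j]
  v
}

#' Divergence between a composite core and the monomer flanks
#'
#' Aligns both monomers to the composite motif, extracts the composite
#' columns covered by both monomer alignments (the composite overlap),
#' and quantifies how different the overlap is from the corresponding
#' monomer sections: (1) total Jensen-Shannon divergence (bits, summed
#' over overlap columns) against each monomer, calling the core distinct
#' when either total exceeds `jsd_threshold`; (2) the Jaccard index of
#' the high-affinity k-mer sets (k-mers of the overlap length scoring at
#' least `score_frac` of each section's maximum product-of-frequency
#' score), calling the core distinct when both Jaccard indexes fall
#' below `jaccard_threshold`. The Jaccard route is computed only when
#' the overlap is shorter than `max_jaccard_len` columns.
#'
#' @param composite,monoA,monoB `Motif` objects.
#' @param jsd_threshold bits (default 0.5).
#' @param jaccard_threshold default 0.5.
#' @param score_frac fraction of the maximum score (default 0.9).
#' @param max_jaccard_len overlap length bound for the k-mer route
#'   (default 13, exclusive).
#' @return An object of class `DivergenceReport`; `analysable` is FALSE
#'   (with a `reason`) when the monomer alignments do not overlap.
#' @export
core_flank_divergence <- function(composite, monoA, monoB,
                                  jsd_threshold = 0.5, jaccard_threshold = 0.5,
                                  score_frac = 0.9, max_jaccard_len = 13L) {
  alA <- tryCatch(align_motifs(monoA, composite), error = function(e) NULL)
  alB <- tryCatch(align_motifs(monoB, composite), error = function(e) NULL)
  fail <- function(reason) structure(list(analysable = FALSE, reason = reason),
                                     class = "DivergenceReport")
  if (is.null(alA) || is.null(alB)) return(fail("monomer alignment failed"))
  overlap <- intersect(alA$comp_cols, alB$comp_cols)
  if (!length(overlap)) return(fail("monomer alignments do not overlap"))
  fc <- motif_freq(composite)
  sect <- function(mono, al) {
    fm <- if (al$orientation == "same") motif_freq(mono)
          else motif_freq(motif_revcomp(mono))
    fm[, overlap - al$offset, drop = FALSE]
  }
  co <- fc[, overlap, drop = FALSE]
  tf1 <- sect(monoA, alA); tf2 <- sect(monoB, alB)
  jsd <- c(tf1 = sum(jsd_columns(co, tf1)), tf2 = sum(jsd_columns(co, tf2)))
  jac <- c(tf1 = NA_real_, tf2 = NA_real_)
  if (length(overlap) < max_jaccard_len) {
    top_set <- function(f) {
      sc <- section_kmer_scores(f)
      which(sc >= score_frac * max(sc))
    }
    sco <- top_set(co)
    for (nm in c("tf1", "tf2")) {
      s2 <- top_set(if (nm == "tf1") tf1 else tf2)
      jac[nm] <- length(intersect(sco, s2)) / length(union(sco, s2))
    }
  }
  structure(list(analysable = TRUE, overlap_cols = overlap,
                 overlap_length = length(overlap),
                 jsd_total_bits = jsd, jaccard = jac,
                 distinct_by_jsd = any(jsd > jsd_threshold),
                 distinct_by_jaccard = if (all(is.na(jac))) NA
                   else all(jac < jaccard_threshold, na.rm = FALSE),
                 alignments = list(A = alA, B = alB)),
            class = "DivergenceReport")
}

#' @export
print.DivergenceReport <- function(x, ...) {
  if (!x$analysable) {
    cat("DivergenceReport: not analysable (", x$reason, ")\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("DivergenceReport: overlap %d columns\n", x$overlap_length))
  cat(sprintf("  total JSD (bits): TF1 %.3f, TF2 %.3f -> distinct: %s\n",
              x$jsd_total_bits[["tf1"]], x$jsd_total_bits[["tf2"]],
              x$distinct_by_jsd))
  if (!all(is.na(x$jaccard)))
    cat(sprintf("  Jaccard: TF1 %.3f, TF2 %.3f -> distinct: %s\n",
                x$jaccard[["tf1"]], x$jaccard[["tf2"]], x$distinct_by_jaccard))
  invisible(x)
}

## best log-odds score of a motif over all full-fit windows and strands
## of a DNA string; targets shorter than the motif are padded with
## background (zero-scoring) positions so a best partial fit is scored
best_logodds_score <- function(lo, dna) {
  L <- ncol(lo)
  lut <- integer(128)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("C")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("T")] <- 4L
  b <- lut[utf8ToInt(dna)]
  pad <- max(0L, L - length(b))
  bp <- c(rep(5L, pad), b, rep(5L, pad))
  lo0 <- rbind(lo, 0)  # row 5 scores 0 for padding
  best <- -Inf
  for (str in 1:2) {
    m <- if (str == 1L) lo0 else rbind(lo[4:1, rev(seq_len(L)), drop = FALSE], 0)
    for (w in seq_len(length(bp) - L + 1L)) {
      s <- sum(m[cbind(bp[w:(w + L - 1L)], seq_len(L))])
      if (s > best) best <- s
    }
  }
  best
}

#' Consensus score differential of a monomer against a composite
#'
#' Compares the monomer motif's best log-odds score against its own
#' consensus sequence with its best score against the composite motif's
#' consensus. A large differential means the individual TF binds the
#' composite site poorly on its own.
#'
#' @param monomer,composite `Motif` objects.
#' @return named numeric: `score_own`, `score_on_composite`,
#'   `differential` (own minus composite).
#' @export
consensus_score_differential <- function(monomer, composite) {
  lo <- motif_logodds(monomer)
  own <- best_logodds_score(lo, motif_consensus(monomer))
  onc <- best_logodds_score(lo, motif_consensus(composite))
  c(score_own = own, score_on_composite = onc, differential = own - onc)
}

## exact minimum dominating set by branch and bound over a logical
## adjacency matrix (diagonal ignored)
exact_dominating_set <- function(adj) {
  n <- nrow(adj)
  closed <- adj | diag(TRUE, n)
  cover_sz <- rowSums(closed)
  best <- greedy_dominating_set(adj)
  search <- function(chosen, covered) {
    if (all(covered)) {
      if (length(chosen) < length(best)) best <<- chosen
      return(invisible())
    }
    if (length(chosen) + 1L >= length(best)) return(invisible())
    unc <- which(!covered)
    ## lower bound: each added vertex covers at most max(cover_sz) nodes
    if (length(chosen) + ceiling(length(unc) / max(cover_sz)) >= length(best))
      return(invisible())
    v <- unc[which.min(cover_sz[unc])]  # hardest-to-cover vertex
    cands <- which(closed[, v])
    cands <- cands[order(rowSums(closed[cands, !covered, drop = FALSE]),
                         decreasing = TRUE)]
    for (u in cands) search(c(chosen, u), covered | closed[u, ])
  }
  search(integer(0), rep(FALSE, n))
  sort(best)
}

greedy_dominating_set <- function(adj) {
  n <- nrow(adj)
  closed <- adj | diag(TRUE, n)
  covered <- rep(FALSE, n)
  chosen <- integer(0)
  while (!all(covered)) {
    gain <- rowSums(closed[, !covered, drop = FALSE])
    u <- which.max(gain)
    chosen <- c(chosen, u)
    covered <- covered | closed[u, ]
  }
  sort(chosen)
}

#' Minimum dominating set of a motif similarity network
#'
#' Connects two motifs when their similarity exceeds `threshold` and
#' finds a minimum set of representatives such that every motif is
#' either a representative or similar to one. Exact branch-and-bound
#' search is used up to `exact_limit` nodes; larger networks fall back
#' to the standard greedy set-cover approximation (the mode used is
#' reported).
#'
#' @param motifs list of `Motif` objects, or `NULL` when `similarity`
#'   is given directly.
#' @param similarity optional precomputed symmetric similarity matrix.
#' @param similarity_fn pairwise similarity function (default
#'   [gapped_kmer_similarity()]).
#' @param threshold edge threshold on the similarity (default 0.1, the
#'   scale of the gapped k-mer metric; supply a metric-appropriate value
#'   for other similarity functions).
#' @param exact_limit maximum network size for the exact solver.
#' @param ... passed on to `similarity_fn`.
#' @return list with `representatives` (indices), `names`, `mode`
#'   (`"exact"` or `"greedy"`), `adjacency`.
#' @export
dominating_set <- function(motifs = NULL, similarity = NULL,
                           similarity_fn = gapped_kmer_similarity,
                           threshold = 0.1, exact_limit = 25L, ...) {
  if (is.null(similarity)) {
    n <- length(motifs)
    similarity <- diag(1, n)
    if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n)
      similarity[i, j] <- similarity[j, i] <- similarity_fn(motifs[[i]], motifs[[j]], ...)
    rownames(similarity) <- colnames(similarity) <-
      vapply(motifs, function(m) m$name, character(1))
  }
  adj <- similarity > threshold
  diag(adj) <- FALSE
  mode <- if (nrow(adj) <= exact_limit) "exact" else "greedy"
  reps <- if (mode == "exact") exact_dominating_set(adj)
          else greedy_dominating_set(adj)
  ## validity: every non-member adjacent to >= 1 member
  covered <- apply(adj[, reps, drop = FALSE], 1L, any)
  covered[reps] <- TRUE
  stopifnot(all(covered))
  list(representatives = reps, names = rownames(adj)[reps], mode = mode,
       adjacency = adj)
}
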