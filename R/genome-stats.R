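#' Scan sequences with a motif
#'
#' Log-odds (natural log) scan of both strands against a background
#' base composition. The score threshold is chosen as the smallest
#' score that retains at least `target_matches` matches, but never
#' below the floor of `min_score`; when fewer matches reach the floor,
#' all floor-passing matches are returned with a warning.
#'
#' @param sequences named character vector of DNA sequences, or a
#'   [Biostrings::DNAStringSet].
#' @param m a `Motif`.
#' @param target_matches desired number of matches (default 300000).
#' @param min_score score floor in natural-log units (default 2).
#' @param background length-4 base composition; defaults to the
#'   composition of `sequences`.
#' @return An object of class `MatchSet`: `matches` is a `GRanges`
#'   (1-based closed) with `strand`, `score` and `motif` columns, plus
#'   `score_threshold`, `target_count` and `motif_name`.
#' @export
scan_motif <- function(sequences, m, target_matches = 300000L, min_score = 2,
                       background = NULL) {
  if (inherits(sequences, "DNAStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  if (length(sequences) == 0L) stop("empty sequence set")
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  if (is.null(background)) {
    cnt <- numeric(4L)
    for (s in sequences) cnt <- cnt + tabulate(seq_int_matrix(s), nbins = 4L)
    background <- cnt / sum(cnt)
  }
  lo_f <- motif_logodds(m, background = background)
  L <- ncol(lo_f)
  lo_r <- lo_f[4:1, rev(seq_len(L)), drop = FALSE]
  hits <- list()
  for (nm in names(sequences)) {
    x <- seq_int_matrix(sequences[nm])[1L, ]
    nw <- length(x) - L + 1L
    if (nw < 1L) next
    for (str in c("+", "-")) {
      lo <- if (str == "+") lo_f else lo_r
      sc <- numeric(nw)
      for (j in seq_len(L)) sc <- sc + lo[x[seq_len(nw) + j - 1L] + (j - 1L) * 4L]
      keep <- which(sc >= min_score)
      if (length(keep))
        hits[[length(hits) + 1L]] <- data.frame(
          seq = nm, start = keep, strand = str, score = sc[keep])
    }
  }
  if (!length(hits)) {
    df <- data.frame(seq = character(0), start = integer(0),
                     strand = character(0), score = numeric(0))
  } else df <- do.call(rbind, hits)
  threshold <- min_score
  if (nrow(df) > target_matches) {
    srt <- sort(df$score, decreasing = TRUE)
    threshold <- srt[target_matches]
    df <- df[df$score >= threshold, , drop = FALSE]
  } else if (nrow(df) < target_matches) {
    warning("only ", nrow(df), " matches reach the score floor of ", min_score)
  }
  gr <- GenomicRanges::GRanges(df$seq,
          IRanges::IRanges(start = df$start, width = L),
          strand = df$strand)
  S4Vectors::mcols(gr)$score <- df$score
  S4Vectors::mcols(gr)$motif <- rep(m$name, length(gr))
  structure(list(matches = gr, score_threshold = threshold,
                 target_count = target_matches, motif_name = m$name,
                 motif_length = L),
            class = "MatchSet")
}

#' @export
print.MatchSet <- function(x, ...) {
  cat(sprintf("MatchSet: %d matches of '%s' (threshold %.3f nats)\n",
              length(x$matches), x$motif_name, x$score_threshold))
  invisible(x)
}

#' Hypergeometric enrichment of motif matches in a region subset
#'
#' Tests whether regions of a subset carry a motif match more (or less)
#' often than the regions of the universe. `k` of the `n` subset
#' regions and `m` of the `N` universe regions contain at least one
#' match; the fold change is `log2((k/n)/(m/N))` and the one-sided
#' hypergeometric tail follows its sign (upper for enrichment, lower
#' for depletion, `p = 1` at exactly zero). The conventional call rule
#' is `p < 0.01` and `log2 FC > 0.75`.
#'
#' @param matchset a `MatchSet` (or a `GRanges` of matches).
#' @param subset,universe `GRanges` region sets; `subset` should be
#'   contained in `universe` (violations are reported).
#' @return An object of class `ContingencyResult` with `k`, `n`, `m`,
#'   `N`, `log2_fold_change`, `p_value`, `direction`, `enriched`.
#' @export
region_enrichment <- function(matchset, subset, universe) {
  gr <- if (inherits(matchset, "MatchSet")) matchset$matches else matchset
  N <- length(universe); n <- length(subset)
  if (N == 0L) stop("empty universe")
  outside <- sum(GenomicRanges::countOverlaps(subset, universe, type = "equal") == 0L)
  if (outside > 0L)
    warning(outside, " subset region(s) not present in the universe")
  k <- sum(GenomicRanges::countOverlaps(subset, gr) > 0L)
  mm <- sum(GenomicRanges::countOverlaps(universe, gr) > 0L)
  l2fc <- if (k == 0L || mm == 0L) {
    if (k == 0L && mm == 0L) 0 else log2((k / n) / (mm / N))
  } else log2((k / n) / (mm / N))
  if (l2fc > 0) {
    p <- stats::phyper(k - 1L, mm, N - mm, n, lower.tail = FALSE)
    direction <- "enrichment"
  } else if (l2fc < 0) {
    p <- stats::phyper(k, mm, N - mm, n, lower.tail = TRUE)
    direction <- "depletion"
  } else { p <- 1; direction <- "none" }
  structure(list(k = k, n = n, m = mm, N = N, log2_fold_change = l2fc,
                 p_value = p, direction = direction,
                 enriched = p < 0.01 && l2fc > 0.75),
            class = "ContingencyResult")
}

#' @export
print.ContingencyResult <- function(x, ...) {
  cat(sprintf("ContingencyResult: k=%d n=%d m=%d N=%d, log2FC=%.3f, p=%.3g (%s)\n",
              x$k, x$n, x$m, x$N, x$log2_fold_change, x$p_value, x$direction))
  invisible(x)
}

#' Artificial control motifs by half recombination
#'
#' For every split point that leaves both halves at least one-third of
#' the motif length (rounded down), three controls are formed:
#' right+left, left+revcomp(right) and revcomp(left)+right. Controls
#' that remain too similar to the original (similarity above
#' `exclude_above`) are excluded; duplicates arising from palindromic
#' symmetry are removed and counted.
#'
#' @param m a `Motif` (length >= 6; shorter motifs yield no valid split
#'   and an empty set with a warning).
#' @param similarity_fn similarity used for the exclusion filter
#'   (default [gapped_kmer_similarity()]).
#' @param exclude_above similarity cut-off (default 0.1).
#' @param ... passed to `similarity_fn`.
#' @return An object of class `ControlMotifSet`: `controls` (list of
#'   `Motif`), `provenance` (split point and recombination type per
#'   control), `excluded` (data.frame of excluded controls with their
#'   similarity), `n_duplicates`.
#' @export
make_control_motifs <- function(m, similarity_fn = gapped_kmer_similarity,
                                exclude_above = 0.1, ...) {
  L <- motif_length(m)
  min_part <- floor(L / 3)
  splits <- seq_len(L - 1L)
  splits <- splits[splits >= min_part & (L - splits) >= min_part]
  if (L < 6L || !length(splits)) {
    warning("motif too short for control generation")
    return(structure(list(controls = list(), provenance = NULL,
                          excluded = NULL, n_duplicates = 0L),
                     class = "ControlMotifSet"))
  }
  rc_cols <- function(cm) {
    out <- cm[4:1, rev(seq_len(ncol(cm))), drop = FALSE]
    rownames(out) <- DNA_BASES
    out
  }
  ctrls <- list(); prov <- list()
  for (s in splits) {
    left <- m$counts[, seq_len(s), drop = FALSE]
    right <- m$counts[, (s + 1L):L, drop = FALSE]
    pieces <- list(RL = cbind(right, left),
                   L_rcR = cbind(left, rc_cols(right)),
                   rcL_R = cbind(rc_cols(left), right))
    for (ty in names(pieces)) {
      ctrls[[length(ctrls) + 1L]] <- pieces[[ty]]
      prov[[length(prov) + 1L]] <- data.frame(split = s, type = ty)
    }
  }
  prov <- do.call(rbind, prov)
  key <- vapply(ctrls, function(cm) paste(signif(cm, 8), collapse = ","), character(1))
  dup <- duplicated(key)
  n_dup <- sum(dup)
  ctrls <- ctrls[!dup]; prov <- prov[!dup, , drop = FALSE]
  keep <- logical(length(ctrls)); sims <- numeric(length(ctrls))
  controls <- list(); kept_prov <- list(); excluded <- list()
  for (i in seq_along(ctrls)) {
    ctrl <- motif(ctrls[[i]],
                  name = sprintf("%s_ctrl_s%d_%s", m$name, prov$split[i], prov$type[i]),
                  motif_class = "control")
    sim <- similarity_fn(m, ctrl, ...)
    if (sim > exclude_above) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(name = ctrl$name, similarity = sim)
    } else {
      controls[[length(controls) + 1L]] <- ctrl
      kept_prov[[length(kept_prov) + 1L]] <-
        cbind(prov[i, , drop = FALSE], similarity = sim)
    }
  }
  structure(list(controls = controls,
                 provenance = if (length(kept_prov)) do.call(rbind, kept_prov) else NULL,
                 excluded = if (length(excluded)) do.call(rbind, excluded) else NULL,
                 n_duplicates = n_dup),
            class = "ControlMotifSet")
}

#' @export
print.ControlMotifSet <- function(x, ...) {
  cat(sprintf("ControlMotifSet: %d controls kept, %d excluded (similarity), %d duplicates removed\n",
              length(x$controls),
              if (is.null(x$excluded)) 0L else nrow(x$excluded),
              x$n_duplicates))
  invisible(x)
}

## one EM run of a 1-D two-component Gaussian mixture; returns NULL on
## degeneracy
em_gmm2 <- function(x, mu0, max_iter = 200L, tol = 1e-8) {
  n <- length(x)
  mu <- mu0
  sd_ <- rep(stats::sd(x), 2L)
  if (sd_[1L] == 0) return(NULL)
  w <- c(0.5, 0.5)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1L] * stats::dnorm(x, mu[1L], sd_[1L])
    d2 <- w[2L] * stats::dnorm(x, mu[2L], sd_[2L])
    tot <- d1 + d2
    if (any(tot == 0) || any(!is.finite(tot))) return(NULL)
    g <- d1 / tot
    n1 <- sum(g); n2 <- n - n1
    if (n1 < 1e-6 || n2 < 1e-6) return(NULL)
    mu <- c(sum(g * x) / n1, sum((1 - g) * x) / n2)
    sd_ <- sqrt(c(sum(g * (x - mu[1L])^2) / n1,
                  sum((1 - g) * (x - mu[2L])^2) / n2))
    if (any(sd_ < 1e-9)) return(NULL)
    w <- c(n1, n2) / n
    ll <- sum(log(tot))
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(w = w, mu = mu, sd = sd_, loglik = ll,
       bic = -2 * ll + 5 * log(n))
}

#' Conservation threshold from a two-component Gaussian mixture
#'
#' Fits ten randomly initialised two-component Gaussian mixtures to the
#' per-match average conservation scores, keeps the best model by BIC,
#' and returns the smallest score at which the posterior probability of
#' the higher-mean (constrained) component exceeds one half. Degenerate
#' fits (a collapsing component) fall back to the median with a flag.
#'
#' @param avg_scores numeric vector of per-match average scores (>= 20
#'   values).
#' @param n_init number of random initialisations (default 10).
#' @param seed RNG seed for the initialisations.
#' @return threshold (numeric scalar) with attributes `model` (the
#'   winning mixture parameters or `NULL`), `fallback` (logical) and
#'   `seed`.
#' @export
gmm_conservation_threshold <- function(avg_scores, n_init = 10L, seed = 1L) {
  x <- avg_scores[is.finite(avg_scores)]
  if (length(x) < 20L) stop("need at least 20 scores")
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  if (stats::sd(x) > 0) {
    for (i in seq_len(n_init)) {
      mu0 <- sort(sample(x, 2L))
      if (mu0[1L] == mu0[2L]) mu0 <- mu0 + c(-1, 1) * stats::sd(x) / 10
      fit <- em_gmm2(x, mu0)
      if (!is.null(fit) && (is.null(best) || fit$bic < best$bic)) best <- fit
    }
  }
  if (is.null(best)) {
    thr <- stats::median(x)
    attr(thr, "model") <- NULL
    attr(thr, "fallback") <- TRUE
    attr(thr, "seed") <- seed
    return(thr)
  }
  hi <- which.max(best$mu)
  xs <- sort(unique(x))
  post_hi <- function(v) {
    d1 <- best$w[1L] * stats::dnorm(v, best$mu[1L], best$sd[1L])
    d2 <- best$w[2L] * stats::dnorm(v, best$mu[2L], best$sd[2L])
    (if (hi == 1L) d1 else d2) / (d1 + d2)
  }
  above <- xs[post_hi(xs) > 0.5 & xs >= min(best$mu)]
  thr <- if (length(above)) min(above) else max(xs)
  attr(thr, "model") <- best
  attr(thr, "fallback") <- FALSE
  attr(thr, "seed") <- seed
  thr
}

## greedy selection of the top-n non-overlapping matches by descending
## score; returns the kept GRanges (with origin metadata preserved)
top_nonoverlapping <- function(gr, top_n) {
  ord <- order(S4Vectors::mcols(gr)$score, decreasing = TRUE)
  gr <- gr[ord]
  ov <- GenomicRanges::findOverlaps(gr, gr)
  ov <- ov[S4Vectors::queryHits(ov) < S4Vectors::subjectHits(ov)]
  blockers <- split(S4Vectors::queryHits(ov), S4Vectors::subjectHits(ov))
  kept <- logical(length(gr))
  n_kept <- 0L
  for (i in seq_along(gr)) {
    bl <- blockers[[as.character(i)]]
    if (!is.null(bl) && any(kept[bl])) next
    kept[i] <- TRUE
    n_kept <- n_kept + 1L
    if (n_kept >= top_n) break
  }
  gr[kept]
}

#' Conservation of motif matches versus recombined controls
#'
#' Pools the matches of the true motif and its artificial controls,
#' keeps the `top_n` non-overlapping matches with the highest affinity
#' score (after removing matches overlapping an exclusion region set),
#' derives the motif-specific conservation threshold by Gaussian
#' mixture from the true matches, and tests whether conserved matches
#' (average per-base score above the threshold) are enriched among the
#' true matches with a one-sided (upper tail) Fisher test. The fold
#' change is the conditional frequency ratio `(k/n) / ((m-k)/(N-n))`.
#'
#' @param true_matches `MatchSet` of the true motif.
#' @param control_matches `MatchSet` (or list of them) of the control
#'   motifs.
#' @param track a `ConservationTrack`.
#' @param top_n matches retained after merging (default 10000; fewer
#'   available matches proceed with a flag).
#' @param exclude optional `GRanges` of regions whose matches are
#'   removed (exons, repeats).
#' @param threshold optional precomputed conservation threshold;
#'   computed by [gmm_conservation_threshold()] when `NULL`.
#' @param gmm_seed seed for the threshold fit.
#' @return A `ContingencyResult` with extra fields `threshold`,
#'   `fold_change` (conditional ratio), `n_true`, `n_control`,
#'   `truncated` (TRUE when fewer than `top_n` matches were available).
#' @export
conserved_match_test <- function(true_matches, control_matches, track,
                                 top_n = 10000L, exclude = NULL,
                                 threshold = NULL, gmm_seed = 1L) {
  tg <- true_matches$matches
  S4Vectors::mcols(tg)$origin <- "true"
  if (inherits(control_matches, "MatchSet")) control_matches <- list(control_matches)
  cg <- do.call(c, lapply(control_matches, function(ms) {
    g <- ms$matches; S4Vectors::mcols(g)$origin <- "control"; g
  }))
  all_gr <- c(tg, cg)
  if (!is.null(exclude)) {
    drop <- GenomicRanges::countOverlaps(all_gr, exclude) > 0L
    all_gr <- all_gr[!drop]
  }
  truncated <- length(all_gr) < top_n
  if (truncated)
    warning("fewer than ", top_n, " merged matches; proceeding with all")
  sel <- top_nonoverlapping(all_gr, top_n)
  avg <- track_mean_score(track, sel)
  ok <- is.finite(avg)
  sel <- sel[ok]; avg <- avg[ok]
  is_true <- S4Vectors::mcols(sel)$origin == "true"
  if (is.null(threshold)) {
    true_scores <- avg[is_true]
    if (!is.null(track$mask)) {
      keep <- GenomicRanges::countOverlaps(sel[is_true], track$mask) > 0L
      if (sum(keep) >= 20L) true_scores <- avg[is_true][keep]
    }
    threshold <- gmm_conservation_threshold(true_scores, seed = gmm_seed)
  }
  conserved <- avg > as.numeric(threshold)
  N <- length(sel); n <- sum(is_true)
  k <- sum(conserved & is_true); m <- sum(conserved)
  tab <- matrix(c(k, n - k, m - k, N - n - (m - k)), nrow = 2L, byrow = TRUE)
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  fc <- if (m - k == 0L || N == n) {
    if (k > 0L) Inf else 0
  } else (k / n) / ((m - k) / (N - n))
  res <- structure(list(k = k, n = n, m = m, N = N,
                        log2_fold_change = log2(max(fc, .Machine$double.xmin)),
                        p_value = p, direction = "enrichment",
                        enriched = NA,
                        threshold = as.numeric(threshold),
                        fold_change = fc,
                        n_true = n, n_control = N - n,
                        truncated = truncated),
                   class = "ContingencyResult")
  res
}

#' Half-site conservation correlation of a composite motif
#'
#' Correlates per-base conservation scores between the positions of a
#' composite motif's matches, compares the inter-half correlations with
#' an empirical Gaussian null fitted to the correlations observed in
#' control-motif matches, applies Benjamini-Hochberg correction across
#' position pairs, and reports the minimum q of the inter-half block's
#' lower triangle. A small q means that conservation of one half-site
#' predicts conservation of the other.
#'
#' @param matches `MatchSet` of the composite motif.
#' @param control_matches `MatchSet` or list of them (the null source).
#' @param track a `ConservationTrack`.
#' @param half_split last column of the first half (1 <= split < motif
#'   length).
#' @param min_matches minimum usable matches (default 100).
#' @return list with `q` (minimum inter-half lower-triangle q-value),
#'   `significant` (q < 0.05), `correlations`, `p_values`, `q_values`
#'   (upper-triangular matrices), `null_mean`, `null_sd`, `n_used`.
#' @export
halfsite_correlation <- function(matches, control_matches, track, half_split,
                                 min_matches = 100L) {
  L <- matches$motif_length
  if (half_split < 1L || half_split >= L) stop("half_split must leave two non-empty halves")
  S <- track_score_matrix(track, matches$matches)
  S <- S[stats::complete.cases(S), , drop = FALSE]
  if (nrow(S) < min_matches) stop("need at least ", min_matches, " fully covered matches")
  if (inherits(control_matches, "MatchSet")) control_matches <- list(control_matches)
  null_r <- unlist(lapply(control_matches, function(ms) {
    Sc <- track_score_matrix(track, ms$matches)
    Sc <- Sc[stats::complete.cases(Sc), , drop = FALSE]
    if (nrow(Sc) < 10L) return(numeric(0))
    cm <- suppressWarnings(stats::cor(Sc))
    cm[upper.tri(cm)]
  }))
  null_r <- null_r[is.finite(null_r)]
  if (length(null_r) < 10L) stop("too few control correlations for the null")
  mu <- mean(null_r); sdv <- stats::sd(null_r)
  cm <- suppressWarnings(stats::cor(S))
  pm <- matrix(NA_real_, L, L)
  ut <- which(upper.tri(cm), arr.ind = TRUE)
  r <- cm[ut]
  p <- stats::pnorm((r - mu) / sdv, lower.tail = FALSE)
  p[!is.finite(r)] <- NA  # constant columns: pair skipped
  q <- rep(NA_real_, length(p))
  q[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], method = "BH")
  pmat <- qmat <- matrix(NA_real_, L, L)
  pmat[ut] <- p; qmat[ut] <- q
  ## inter-half block: rows i <= half_split, cols j > half_split; its
  ## lower triangle taken along the block diagonal
  block <- ut[, 1L] <= half_split & ut[, 2L] > half_split
  a <- ut[block, 1L]; b <- ut[block, 2L] - half_split
  lower <- b <= (half_split - a + 1L)
  qs <- q[block][lower]
  qmin <- if (all(is.na(qs))) NA_real_ else min(qs, na.rm = TRUE)
  list(q = qmin, significant = isTRUE(qmin < 0.05),
       correlations = cm, p_values = pmat, q_values = qmat,
       null_mean = mu, null_sd = sdv, n_used = nrow(S))
}

## enumerate A-B match pairs with gap in [0, max_gap); orientation is
## canonicalised with the A match on the left (strand pair flipped when
## the B match is leftmost)
match_pairs_by_gap <- function(grA, grB, max_gap = 30L) {
  ov <- GenomicRanges::findOverlaps(grA, grB,
          maxgap = max_gap - 1L, ignore.strand = TRUE)
  qa <- S4Vectors::queryHits(ov); qb <- S4Vectors::subjectHits(ov)
  sa <- GenomicRanges::start(grA)[qa]; ea <- GenomicRanges::end(grA)[qa]
  sb <- GenomicRanges::start(grB)[qb]; eb <- GenomicRanges::end(grB)[qb]
  stA <- as.character(GenomicRanges::strand(grA))[qa]
  stB <- as.character(GenomicRanges::strand(grB))[qb]
  a_left <- eb > ea & sb > sa
  b_left <- ea > eb & sa > sb
  gap <- ifelse(a_left, sb - ea - 1L, ifelse(b_left, sa - eb - 1L, -1L))
  keep <- gap >= 0L & gap < max_gap
  flip <- c(`+` = "-", `-` = "+")
  ori <- ifelse(a_left[keep],
                paste0(stA[keep], stB[keep]),
                paste0(flip[stA[keep]], flip[stB[keep]]))
  ori <- chartr("+-", "FR", ori)
  data.frame(ia = qa[keep], ib = qb[keep], gap = gap[keep], orientation = ori)
}

#' Conservation of monomer-match pairs by spacing and orientation
#'
#' Identifies genomic co-occurrences of two monomer motifs with gaps
#' below `max_gap`, counts per (gap, orientation) cell the pairs in
#' which both matches are conserved (average score above each motif's
#' threshold), and compares the counts with an empirical null built
#' from pairings of each true motif with the other motif's control
#' matches. One-sided empirical p-values are Benjamini-Hochberg
#' corrected (FDR threshold 0.01).
#'
#' @param matchesA,matchesB `MatchSet` objects of the two monomers.
#' @param track `ConservationTrack`.
#' @param thresholdA,thresholdB per-motif conservation thresholds.
#' @param controlsA,controlsB lists of control `MatchSet` objects.
#' @param max_gap exclusive gap bound (default 30).
#' @param fdr FDR threshold (default 0.01).
#' @return data.frame with one row per (gap, orientation) cell:
#'   observed conserved-pair count, null mean, `p`, `q`, `significant`.
#' @export
spacing_conservation <- function(matchesA, matchesB, track,
                                 thresholdA, thresholdB,
                                 controlsA = list(), controlsB = list(),
                                 max_gap = 30L, fdr = 0.01) {
  if (!length(matchesA$matches) || !length(matchesB$matches))
    stop("empty match sets")
  conserved_flags <- function(ms, thr) {
    avg <- track_mean_score(track, ms$matches)
    !is.na(avg) & avg > thr
  }
  cons_counts <- function(grA, consA, grB, consB) {
    prs <- match_pairs_by_gap(grA, grB, max_gap)
    both <- consA[prs$ia] & consB[prs$ib]
    tab <- matrix(0L, nrow = max_gap, ncol = 4L,
                  dimnames = list(0:(max_gap - 1L), c("FF", "FR", "RF", "RR")))
    if (any(both)) {
      agg <- table(prs$gap[both], prs$orientation[both])
      tab[cbind(as.character(rownames(agg)[row(agg)]),
                colnames(agg)[col(agg)])] <- as.integer(agg)
    }
    tab
  }
  consA <- conserved_flags(matchesA, thresholdA)
  consB <- conserved_flags(matchesB, thresholdB)
  obs <- cons_counts(matchesA$matches, consA, matchesB$matches, consB)
  null_tabs <- list()
  for (cb in controlsB) {
    cf <- conserved_flags(cb, thresholdB)
    null_tabs[[length(null_tabs) + 1L]] <-
      cons_counts(matchesA$matches, consA, cb$matches, cf)
  }
  for (ca in controlsA) {
    cf <- conserved_flags(ca, thresholdA)
    null_tabs[[length(null_tabs) + 1L]] <-
      cons_counts(ca$matches, cf, matchesB$matches, consB)
  }
  if (!length(null_tabs)) stop("no control match sets supplied for the null")
  null_arr <- simplify2array(null_tabs)
  null_mean <- apply(null_arr, c(1L, 2L), mean)
  ## one-sided tail under a Poisson null whose rate is estimated from
  ## the control pairings (counts are small; a rank-based empirical p
  ## cannot fall below 1/(n_controls + 1))
  p <- matrix(1, nrow = max_gap, ncol = 4L)
  for (g in seq_len(max_gap)) for (o in seq_len(4L)) {
    nv <- null_arr[g, o, ]
    lambda <- (sum(nv) + 0.5) / length(nv)
    p[g, o] <- stats::ppois(obs[g, o] - 1L, lambda, lower.tail = FALSE)
  }
  df <- data.frame(gap = rep(0:(max_gap - 1L), times = 4L),
                   orientation = rep(c("FF", "FR", "RF", "RR"), each = max_gap),
                   observed = as.vector(obs),
                   null_mean = as.vector(null_mean),
                   p = as.vector(p))
  df$q <- stats::p.adjust(df$p, method = "BH")
  df$significant <- df$q < fdr
  df
}
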