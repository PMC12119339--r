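#' Candidate composite 10-mers
#'
#' Compares the 10-mer relative affinities of a CAP-SELEX (TF pair)
#' library with the best of the two single-TF HT-SELEX libraries. A
#' 10-mer is a composite candidate when its CAP affinity ranks in the
#' top `rank_frac` of the observed CAP 10-mers and is at least
#' `ratio_min` times the higher of its two HT-SELEX affinities.
#' Percentile ranks are computed over 10-mers with non-zero CAP counts.
#'
#' @param aff_cap `AffinityTable` (k = 10) of the CAP-SELEX pool.
#' @param aff_ht1,aff_ht2 `AffinityTable` objects (k = 10) of the two
#'   single-TF pools.
#' @param rank_frac retain 10-mers ranked in this top fraction of the
#'   CAP table (default 0.5).
#' @param ratio_min minimum CAP/HT affinity ratio (default 1.5).
#' @return data.frame with `tenmer`, `ka_cap`, `ka_ht_best`, `ratio`,
#'   `rank_cap` (percentile in (0, 1]), sorted by `ka_cap` descending.
#' @export
composite_candidates <- function(aff_cap, aff_ht1, aff_ht2,
                                 rank_frac = 0.5, ratio_min = 1.5) {
  for (tb in list(aff_cap, aff_ht1, aff_ht2))
    if (tb$k != 10L) stop("all affinity tables must be 10-mer tables")
  obs <- aff_cap$observed
  if (is.null(obs)) stop("CAP affinity table lacks observed-count flags")
  idx <- which(obs)
  ka <- aff_cap$ka[idx]
  rk <- rank(-ka, ties.method = "min") / length(ka)
  ht_best <- pmax(aff_ht1$ka[idx], aff_ht2$ka[idx])
  keep <- rk <= rank_frac & ka >= ratio_min * ht_best
  out <- data.frame(tenmer = kmer_decode(idx[keep], 10L),
                    ka_cap = ka[keep], ka_ht_best = ht_best[keep],
                    ratio = ka[keep] / ht_best[keep], rank_cap = rk[keep])
  out[order(-out$ka_cap, out$tenmer), , drop = FALSE]
}

## all Hamming-distance-1 neighbours of a k-mer
hamming1_neighbours <- function(x) {
  k <- nchar(x)
  chars <- strsplit(x, "")[[1L]]
  out <- character(0)
  for (i in seq_len(k)) for (b in setdiff(DNA_BASES, chars[i])) {
    y <- chars; y[i] <- b
    out <- c(out, paste(y, collapse = ""))
  }
  out
}

#' Select seed 10-mers from composite candidates
#'
#' A candidate becomes a seed iff no other candidate within Hamming
#' distance one has a higher CAP affinity (equal affinities are resolved
#' in favour of the lexicographically smaller 10-mer). Several seeds can
#' emerge for one TF pair.
#'
#' @param candidates data.frame from [composite_candidates()].
#' @return character vector of seed 10-mers, ordered by CAP affinity.
#' @export
select_seeds <- function(candidates) {
  if (nrow(candidates) == 0L) stop("empty candidate list")
  ka <- stats::setNames(candidates$ka_cap, candidates$tenmer)
  is_seed <- vapply(candidates$tenmer, function(x) {
    nb <- hamming1_neighbours(x)
    nb <- nb[nb %in% names(ka)]
    if (!length(nb)) return(TRUE)
    all(ka[x] > ka[nb] | (ka[x] == ka[nb] & x < nb))
  }, logical(1))
  candidates$tenmer[is_seed]
}

## IUPAC seed class ------------------------------------------------------

iupac_seed <- function(symbols, multinomial_level = 1L) {
  if (nchar(symbols) < 4L) stop("seed too short")
  structure(list(symbols = symbols,
                 multinomial_level = as.integer(multinomial_level)),
            class = "IUPACSeed")
}

#' @export
print.IUPACSeed <- function(x, ...) {
  cat(sprintf("IUPACSeed: %s (multinomial = %d)\n", x$symbols,
              x$multinomial_level))
  invisible(x)
}

## 4 x L logical matrix of bases allowed by an IUPAC string
iupac_allowed <- function(symbols) {
  syms <- strsplit(symbols, "")[[1L]]
  out <- vapply(syms, function(s) DNA_BASES %in% IUPAC_SETS[[s]], logical(4))
  rownames(out) <- DNA_BASES
  out
}

## per-window mismatch counts of an IUPAC pattern over an integer read
## matrix; returns list(mm = n x nw matrix of mismatch counts, nw)
pattern_mismatches <- function(m, allowed) {
  L <- ncol(allowed)
  nw <- ncol(m) - L + 1L
  if (nw < 1L) stop("pattern longer than reads")
  mm <- matrix(0L, nrow = nrow(m), ncol = nw)
  for (j in seq_len(L)) {
    ok <- allowed[, j]
    for (w in seq_len(nw)) mm[, w] <- mm[, w] + !ok[m[, w + j - 1L]]
  }
  mm
}

## IUPAC symbol for a base-frequency vector, following the redundancy
## rule: consensus base if its frequency >= 0.5; otherwise N unless the
## 2nd/3rd (or 3rd/4th) frequency ratio exceeds 2, in which case the
## 2- (or 3-) base degeneracy code is used.
symbol_for_freq <- function(freq) {
  ord <- order(freq, decreasing = TRUE)
  f <- freq[ord]
  if (f[1L] >= 0.5) return(DNA_BASES[ord[1L]])
  if (f[3L] > 0 && f[2L] / f[3L] > 2) return(iupac_symbol(DNA_BASES[ord[1:2]]))
  if (f[4L] > 0 && f[3L] / f[4L] > 2) return(iupac_symbol(DNA_BASES[ord[1:3]]))
  if (f[3L] == 0 && f[2L] > 0) return(iupac_symbol(DNA_BASES[ord[1:2]]))
  "N"
}

## base-count profile around seed matches, from one mismatch pass per
## strand: `flank` gives counts at the 5' (offset 0) and 3' (offset
## L+1) flanking positions of exact matches; `internal` gives, per seed
## position i, the counts among windows matching everywhere but i
## (multinomial-1 window classes); `n_exact` is the exact match count.
seed_profile <- function(m, allowed) {
  L <- ncol(allowed)
  flank5 <- flank3 <- numeric(4L)
  internal <- matrix(0, nrow = 4L, ncol = L)
  n_exact <- 0L
  for (mat in list(m, int_revcomp(m))) {
    mm <- pattern_mismatches(mat, allowed)
    nw <- ncol(mm)
    exact <- which(mm == 0L, arr.ind = TRUE)
    n_exact <- n_exact + nrow(exact)
    if (nrow(exact)) {
      p5 <- exact[, 2L] - 1L
      ok <- p5 >= 1L
      if (any(ok))
        flank5 <- flank5 + tabulate(mat[cbind(exact[ok, 1L], p5[ok])], nbins = 4L)
      p3 <- exact[, 2L] + L
      ok <- p3 <= ncol(mat)
      if (any(ok))
        flank3 <- flank3 + tabulate(mat[cbind(exact[ok, 1L], p3[ok])], nbins = 4L)
    }
    for (i in seq_len(L)) {
      mi <- !allowed[, i][mat[, seq_len(nw) + i - 1L, drop = FALSE]]
      dim(mi) <- dim(mm)
      idx <- which(mm - mi == 0L, arr.ind = TRUE)
      if (nrow(idx))
        internal[, i] <- internal[, i] +
          tabulate(mat[cbind(idx[, 1L], idx[, 2L] + i - 1L)], nbins = 4L)
    }
  }
  list(flank5 = flank5, flank3 = flank3, internal = internal,
       n_exact = n_exact)
}

#' Refine a 10-mer seed into an IUPAC seed
#'
#' Extends the seed outward while the flanking position shows base
#' preference (ratio of the most to the least frequent base above 2
#' among seed-matching windows), then substitutes degeneracy codes at
#' positions where the most common base falls below frequency 0.5. If
#' the refined seed exceeds 10 bp the multinomial level is set to 2 so
#' that PWM counting tolerates one extra mismatch.
#'
#' @param pool the selected `ReadPool` used for counting.
#' @param seed a 10-mer (or longer) ACGT seed string.
#' @param min_matches minimum number of seed matches required (default
#'   50).
#' @param flank_ratio extension rule threshold (default 2).
#' @param max_extend maximum columns added per side (default 5).
#' @return An `IUPACSeed`.
#' @export
refine_seed <- function(pool, seed, min_matches = 50L, flank_ratio = 2,
                        max_extend = 5L) {
  m <- pool_matrix(pool)
  symbols <- strsplit(seed, "")[[1L]]
  prof <- seed_profile(m, iupac_allowed(paste(symbols, collapse = "")))
  if (prof$n_exact < min_matches)
    stop("seed too rare: fewer than ", min_matches, " matches")
  ## outward extension while a flank shows base preference
  for (step in seq_len(2L * max_extend)) {
    extended <- FALSE
    for (side in c("left", "right")) {
      fr <- if (side == "left") prof$flank5 else prof$flank3
      if (sum(fr) < min_matches) next
      f <- fr / sum(fr)
      ratio <- if (min(f) == 0) Inf else max(f) / min(f)
      if (!(ratio > flank_ratio)) next
      sym <- symbol_for_freq(f)
      if (sym == "N") next  # no base preference worth encoding: stop
      symbols <- if (side == "left") c(sym, symbols) else c(symbols, sym)
      prof <- seed_profile(m, iupac_allowed(paste(symbols, collapse = "")))
      extended <- TRUE
    }
    if (!extended || length(symbols) >= nchar(seed) + 2L * max_extend) break
  }
  ## internal degeneracy substitution from the multinomial-1 profile
  for (i in seq_along(symbols)) {
    fr <- prof$internal[, i]
    if (sum(fr) == 0) next
    f <- fr / sum(fr)
    if (max(f) < 0.5) symbols[i] <- symbol_for_freq(f)
  }
  iupac_seed(paste(symbols, collapse = ""),
             multinomial_level = if (length(symbols) > 10L) 2L else 1L)
}

## expected probability that a window matches an IUPAC pattern under a
## Markov background (DP over chain contexts)
markov_pattern_prob <- function(background, allowed) {
  o <- background$order
  L <- ncol(allowed)
  if (o == 0L)
    return(prod(colSums(background$trans[1L, ] * allowed)))
  if (L <= o) {  # sum expected frequencies over compatible L-mers
    p <- markov_p0_all(background, L)
    comp <- rep(TRUE, 4^L)
    cc <- seq_len(4^L) - 1L
    for (j in L:1) { comp <- comp & allowed[(cc %% 4L) + 1L, j]; cc <- cc %/% 4L }
    return(sum(p[comp]))
  }
  nctx <- 4^o
  v <- background$initial
  cc <- seq_len(nctx) - 1L
  for (j in o:1) { v <- v * allowed[(cc %% 4L) + 1L, j]; cc <- cc %/% 4L }
  shift <- ((seq_len(nctx) - 1L) %% 4^(o - 1L)) * 4L
  for (j in (o + 1L):L) {
    vn <- numeric(nctx)
    for (b in which(allowed[, j])) {
      w <- v * background$trans[, b]
      ctx_new <- shift + b  # drop the oldest base, append b
      agg <- rowsum(w, ctx_new)
      vn[as.integer(rownames(agg))] <- vn[as.integer(rownames(agg))] + agg[, 1L]
    }
    v <- vn
  }
  sum(v)
}

#' Multinomial position count matrix from a seed
#'
#' For each seed position i, counts the windows (both strands) that
#' match the seed at every other position, tallying the base observed at
#' position i; with multinomial level 2 one additional mismatch
#' elsewhere is tolerated. Because each column is estimated from its own
#' window class, column totals need not agree. When a background model
#' is supplied, the Markov-expected count of each column class is
#' subtracted (floored at zero) and a pseudocount of one is added.
#'
#' @param pool the selected `ReadPool`.
#' @param seed an `IUPACSeed` or ACGT/IUPAC string.
#' @param background optional `MarkovBackground` for background
#'   correction.
#' @param min_matches minimum seed matches (default 50).
#' @param name motif name.
#' @return A `Motif` with the seed and multinomial level recorded.
#' @export
multinomial_pcm <- function(pool, seed, background = NULL, min_matches = 50L,
                            name = NULL) {
  if (is.character(seed)) seed <- iupac_seed(seed, if (nchar(seed) > 10L) 2L else 1L)
  level <- seed$multinomial_level
  allowed <- iupac_allowed(seed$symbols)
  L <- ncol(allowed)
  m <- pool_matrix(pool)
  counts <- matrix(0, nrow = 4L, ncol = L, dimnames = list(DNA_BASES, NULL))
  total_windows <- 0L
  for (mat in list(m, int_revcomp(m))) {
    mm <- pattern_mismatches(mat, allowed)
    total_windows <- total_windows + length(mm)
    ## windows contribute to column i when mismatches outside i fit the level
    for (i in seq_len(L)) {
      mi <- !allowed[, i][mat[, seq_len(ncol(mm)) + i - 1L, drop = FALSE]]
      dim(mi) <- dim(mm)
      use <- (mm - mi) <= (level - 1L)
      idx <- which(use, arr.ind = TRUE)
      if (!nrow(idx)) next
      counts[, i] <- counts[, i] +
        tabulate(mat[cbind(idx[, 1L], idx[, 2L] + i - 1L)], nbins = 4L)
    }
  }
  n_exact <- sum(pattern_mismatches(m, allowed) == 0L) +
    sum(pattern_mismatches(int_revcomp(m), allowed) == 0L)
  if (n_exact < min_matches)
    stop("seed too rare: ", n_exact, " exact matches < ", min_matches)
  if (!is.null(background)) {
    for (i in seq_len(L)) for (b in seq_len(4L)) {
      cls <- allowed; cls[, i] <- seq_len(4L) == b
      expected <- total_windows * markov_pattern_prob(background, cls)
      counts[b, i] <- max(counts[b, i] - expected, 0)
    }
    counts <- counts + 1
  } else {
    zero_cols <- colSums(counts) == 0
    if (any(zero_cols)) {
      warning("zero matches for some column class; pseudocount column emitted")
      counts[, zero_cols] <- 1
    }
  }
  motif(counts, name = if (is.null(name)) seed$symbols else name,
        seed = seed$symbols, multinomial_level = level,
        motif_class = "composite")
}

#' End-to-end composite motif discovery for one TF pair
#'
#' Orchestrates candidate detection, seed selection, seed refinement and
#' multinomial PWM construction from a selected CAP-SELEX cycle and the
#' two single-TF affinity tables. Motifs are ranked primary, secondary,
#' ... by their (strand-combined) seed match counts. With monomer
#' consensus strings supplied, a motif whose consensus embeds both
#' monomer consensuses in order is reclassified `"spacing"`; otherwise
#' motifs are classified `"composite"`.
#'
#' @param cap_pool selected CAP-SELEX `ReadPool` (cycle 3 by default
#'   design).
#' @param aff_ht1,aff_ht2 single-TF `AffinityTable` objects (k = 10).
#' @param background cycle-0 `MarkovBackground`.
#' @param rank_frac,ratio_min candidate rules (see
#'   [composite_candidates()]).
#' @param min_matches seed floor for refinement/counting.
#' @param max_seeds cap on the number of seeds expanded to motifs.
#' @param monomer_consensus optional character vector of the two monomer
#'   consensus strings, used only for the class heuristic.
#' @return list of `Motif` objects (possibly empty), ordered primary
#'   first; each has attribute `n_seed_matches`.
#' @export
motif_from_pair <- function(cap_pool, aff_ht1, aff_ht2, background,
                            rank_frac = 0.5, ratio_min = 1.5,
                            min_matches = 50L, max_seeds = 3L,
                            monomer_consensus = NULL) {
  stats_cap <- count_kmers(cap_pool, 10L)
  aff_cap <- relative_affinity(stats_cap, background, r = cap_pool$cycle)
  cand <- composite_candidates(aff_cap, aff_ht1, aff_ht2,
                               rank_frac = rank_frac, ratio_min = ratio_min)
  if (nrow(cand) == 0L) return(list())
  seeds <- select_seeds(cand)
  ## a site enriches in both read orientations: drop the second of a
  ## reverse-complement seed pair
  kept <- character(0)
  for (s in seeds) if (!(revcomp(s) %in% kept)) kept <- c(kept, s)
  seeds <- utils::head(kept, max_seeds)
  motifs <- list()
  for (s in seeds) {
    refined <- tryCatch(refine_seed(cap_pool, s, min_matches = min_matches),
                        error = function(e) NULL)
    if (is.null(refined)) next
    mot <- tryCatch(
      multinomial_pcm(cap_pool, refined, background = background,
                      min_matches = min_matches, name = s),
      error = function(e) NULL)
    if (is.null(mot)) next
    allowed <- iupac_allowed(refined$symbols)
    m <- pool_matrix(cap_pool)
    nm <- sum(pattern_mismatches(m, allowed) == 0L) +
      sum(pattern_mismatches(int_revcomp(m), allowed) == 0L)
    if (!is.null(monomer_consensus) && length(monomer_consensus) == 2L) {
      cons <- motif_consensus(mot)
      embeds <- function(x) grepl(x, cons, fixed = TRUE) ||
        grepl(revcomp(x), cons, fixed = TRUE)
      if (embeds(monomer_consensus[1L]) && embeds(monomer_consensus[2L]))
        mot$motif_class <- "spacing"
    }
    attr(mot, "n_seed_matches") <- nm
    motifs[[length(motifs) + 1L]] <- mot
  }
  if (!length(motifs)) return(list())
  ord <- order(vapply(motifs, attr, numeric(1), "n_seed_matches"),
               decreasing = TRUE)
  motifs <- motifs[ord]
  ranks <- c("primary", "secondary", "tertiary")
  for (i in seq_along(motifs))
    motifs[[i]]$name <- sprintf("%s_%s", motifs[[i]]$name,
                                if (i <= 3L) ranks[i] else paste0("rank", i))
  motifs
}
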