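#' Exhaustive k-mer counting
#'
#' Counts every overlapping k-length window of every read. With
#' `both_strands = TRUE` each window additionally contributes its reverse
#' complement, so the count total doubles.
#'
#' @param pool a `ReadPool`.
#' @param k word length (1..12; larger tables are refused to bound
#'   memory).
#' @param both_strands also count each window's reverse complement.
#' @return An object of class `KmerStats` with elements `k`, `counts` (a
#'   dense integer vector indexed by k-mer code, in lexicographic A<C<G<T
#'   order), `total`, `n_reads`, `both_strands` and `cycle`.
#' @export
count_kmers <- function(pool, k, both_strands = FALSE) {
  stopifnot(inherits(pool, "ReadPool"))
  if (k <= 0) stop("k must be positive")
  if (k > 12) stop("k > 12 refused: table would need 4^", k, " cells")
  if (k > pool$read_length) stop("k exceeds read length")
  m <- pool_matrix(pool)
  codes <- kmer_code_matrix(m, k)
  counts <- tabulate(codes, nbins = 4^k)
  if (both_strands)
    counts <- counts + tabulate(kmer_code_matrix(int_revcomp(m), k), nbins = 4^k)
  structure(list(k = as.integer(k), counts = counts,
                 total = sum(counts), n_reads = nrow(m),
                 both_strands = both_strands, cycle = pool$cycle),
            class = "KmerStats")
}

#' @export
print.KmerStats <- function(x, ...) {
  cat(sprintf("KmerStats: k=%d, %d distinct k-mers, %d windows, cycle %d\n",
              x$k, sum(x$counts > 0), x$total, x$cycle))
  invisible(x)
}

#' Named counts of the observed k-mers
#'
#' @param stats a `KmerStats`.
#' @return named integer vector over k-mers with non-zero count.
#' @export
kmer_counts <- function(stats) {
  nz <- which(stats$counts > 0)
  stats::setNames(stats$counts[nz], kmer_decode(nz, stats$k))
}

#' Fit a Markov background model to an input library
#'
#' Maximum-likelihood transition frequencies of the given order with an
#' add-one pseudocount per (context, base) cell; the initial distribution
#' over order-mers is estimated from all order-length windows. Order 5 is
#' the default used to model SELEX cycle-0 pools.
#'
#' @param pool0 the cycle-0 `ReadPool`.
#' @param order Markov order (0 = i.i.d. base composition).
#' @return An object of class `MarkovBackground` with elements `order`,
#'   `initial` (probabilities over order-mers) and `trans` (4^order x 4
#'   conditional probability matrix).
#' @export
fit_markov_background <- function(pool0, order = 5L) {
  stopifnot(inherits(pool0, "ReadPool"))
  order <- as.integer(order)
  if (order < 0) stop("order must be >= 0")
  if (order >= pool0$read_length)
    stop("order must be smaller than the read length")
  m <- pool_matrix(pool0)
  nctx <- 4^order
  if (order == 0L) {
    initial <- 1
    base_counts <- tabulate(as.vector(m), nbins = 4L) + 1
    trans <- matrix(base_counts / sum(base_counts), nrow = 1L)
  } else {
    ctx_codes <- kmer_code_matrix(m, order)      # n x (L-order+1)
    initial_counts <- tabulate(ctx_codes, nbins = nctx) + 1
    initial <- initial_counts / sum(initial_counts)
    ## transition counts: context at window p, next base at p+order
    nw <- ncol(ctx_codes) - 1L
    tc <- matrix(1, nrow = nctx, ncol = 4L)  # add-one pseudocount
    for (p in seq_len(nw)) {
      nxt <- m[, p + order]
      idx <- (nxt - 1L) * nctx + ctx_codes[, p]
      add <- tabulate(idx, nbins = nctx * 4L)
      tc <- tc + matrix(add, nrow = nctx)
    }
    trans <- tc / rowSums(tc)
  }
  colnames(trans) <- DNA_BASES
  structure(list(order = order, initial = initial, trans = trans),
            class = "MarkovBackground")
}

#' @export
print.MarkovBackground <- function(x, ...) {
  cat(sprintf("MarkovBackground: order %d\n", x$order))
  invisible(x)
}

#' Expected k-mer frequency under a Markov background
#'
#' The chain probability of each k-mer: initial probability of its first
#' order-mer times the product of the transition probabilities.
#'
#' @param background a `MarkovBackground`.
#' @param kmers character vector of k-mers (equal length).
#' @return numeric vector of expected frequencies.
#' @export
expected_frequency <- function(background, kmers) {
  k <- unique(nchar(kmers))
  if (length(k) != 1L) stop("k-mers must share one length")
  p0 <- markov_p0_all(background, k)
  p0[kmer_encode(kmers)]
}

## expected frequencies of ALL k-mers (vector of length 4^k, code-indexed)
markov_p0_all <- function(background, k) {
  o <- background$order
  if (o == 0L) {
    p <- 1
    for (j in seq_len(k)) p <- rep(p, each = 4L) * background$trans[1L, ]
    return(p)
  }
  if (k <= o) {
    ## marginalise the initial order-mer distribution over trailing bases
    p <- background$initial
    grp <- (seq_along(p) - 1L) %/% 4^(o - k)
    return(as.vector(rowsum(p, grp)))
  }
  p <- background$initial
  nctx <- 4^o
  for (m in (o + 1L):k) {
    c0 <- seq_along(p) - 1L              # 0-based prefix codes
    ctx <- (c0 %% nctx) + 1L             # trailing order-mer of the prefix
    p <- rep(p, each = 4L) * as.vector(t(background$trans[ctx, , drop = FALSE]))
  }
  p
}

#' Relative affinity table from cycle counts and a Markov background
#'
#' Estimates each k-mer's relative affinity as
#' `((F_k^r / F_ref^r) / (P0(k) / P0(ref)))^(1/r)`, where `F^r` are
#' pseudocounted frequencies in the selected cycle `r`, `P0` is the
#' Markov-expected input frequency, and `ref` is the most abundant k-mer
#' in the selected pool (ties broken lexicographically). The reference
#' k-mer has relative affinity exactly one.
#'
#' @param stats_r `KmerStats` of a selected cycle (r >= 1).
#' @param background `MarkovBackground` fitted on cycle 0 of the same
#'   library design.
#' @param r number of selection cycles behind `stats_r`; defaults to its
#'   `cycle` field.
#' @param pseudocount added to every k-mer count so that unobserved
#'   k-mers get a finite small affinity.
#' @return An object of class `AffinityTable` with elements `k`, `ka`
#'   (code-indexed numeric vector), `ref_kmer` and `r`.
#' @export
relative_affinity <- function(stats_r, background, r = stats_r$cycle,
                              pseudocount = 0.5) {
  stopifnot(inherits(stats_r, "KmerStats"), inherits(background, "MarkovBackground"))
  if (is.null(r) || r < 1) stop("r must be >= 1")
  if (stats_r$total == 0) stop("empty k-mer statistics")
  f <- stats_r$counts + pseudocount
  f <- f / sum(f)
  ref <- which(stats_r$counts == max(stats_r$counts))[1L]  # lexicographic tie-break
  p0 <- markov_p0_all(background, stats_r$k)
  ka <- ((f / f[ref]) / (p0 / p0[ref]))^(1 / r)
  ka[ref] <- 1  # exact by construction; avoid float drift
  structure(list(k = stats_r$k, ka = ka,
                 ref_kmer = kmer_decode(ref, stats_r$k), r = as.integer(r),
                 observed = stats_r$counts > 0L),
            class = "AffinityTable")
}

#' @export
print.AffinityTable <- function(x, ...) {
  cat(sprintf("AffinityTable: k=%d, ref %s (K_a = 1), r = %d\n",
              x$k, x$ref_kmer, x$r))
  invisible(x)
}

#' Look up relative affinities
#'
#' @param table an `AffinityTable`.
#' @param kmers character vector of k-mers.
#' @return numeric vector of K_a values.
#' @export
affinity <- function(table, kmers) {
  if (any(nchar(kmers) != table$k)) stop("k-mer length mismatch")
  table$ka[kmer_encode(kmers)]
}

#' Hamming distance between equal-length k-mers
#'
#' @param a,b k-mer strings of equal length.
#' @return integer substitution count.
#' @export
hamming_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming distance needs equal lengths")
  sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
}

#' Huddinge distance between k-mers
#'
#' The minimum, over all relative ungapped offsets of `a` against `b`
#' (with `b` taken on either strand), of the number of mismatching
#' aligned positions plus the number of positions of the longer k-mer
#' left unaligned. Zero iff the k-mers are equal or reverse-complement
#' equal at full overlap.
#'
#' @param a,b k-mer strings (lengths may differ).
#' @return integer distance.
#' @export
huddinge_distance <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty k-mer")
  xa <- utf8ToInt(a); la <- length(xa)
  best <- Inf
  for (bs in c(b, revcomp(b))) {
    xb <- utf8ToInt(bs); lb <- length(xb)
    for (s in -(lb - 1L):(la - 1L)) {
      ia <- max(1L, s + 1L):min(la, s + lb)
      ib <- ia - s
      ov <- length(ia)
      d <- sum(xa[ia] != xb[ib]) + (max(la, lb) - ov)
      if (d < best) best <- d
    }
  }
  as.integer(best)
}

## all 8-mers (strings) at Huddinge distance exactly 1 from x
huddinge1_neighbours <- function(x) {
  k <- nchar(x)
  chars <- strsplit(x, "")[[1L]]
  cand <- character(0)
  for (i in seq_len(k)) for (b in setdiff(DNA_BASES, chars[i])) {
    y <- chars; y[i] <- b
    cand <- c(cand, paste(y, collapse = ""))
  }
  left <- substr(x, 2L, k); right <- substr(x, 1L, k - 1L)
  cand <- c(cand, paste0(left, DNA_BASES), paste0(DNA_BASES, right))
  cand <- unique(c(cand, revcomp(cand)))
  cand[vapply(cand, function(y) huddinge_distance(x, y) == 1L, logical(1))]
}

#' Locally maximal enriched 8-mers
#'
#' Returns the 8-mers whose fold enrichment (observed frequency over the
#' Markov-expected input frequency) strictly exceeds `min_fold` and the
#' enrichment of every 8-mer within Huddinge distance one. These local
#' maxima serve as characteristic 8-mers / motif seeds.
#'
#' @param stats_sel `KmerStats` with k = 8 from a selected cycle.
#' @param background `MarkovBackground` of the input library.
#' @param min_fold strict lower bound on fold enrichment (default 5).
#' @return data.frame with columns `kmer` and `enrichment`, sorted by
#'   enrichment, descending.
#' @export
local_maxima_8mers <- function(stats_sel, background, min_fold = 5) {
  stopifnot(stats_sel$k == 8L)
  freq <- stats_sel$counts / stats_sel$total
  p0 <- markov_p0_all(background, 8L)
  enr <- freq / p0
  cand <- which(enr > min_fold)
  if (!length(cand)) return(data.frame(kmer = character(0), enrichment = numeric(0)))
  cand <- cand[order(enr[cand], decreasing = TRUE)]
  kmers <- kmer_decode(cand, 8L)
  keep <- vapply(seq_along(cand), function(i) {
    nb <- huddinge1_neighbours(kmers[i])
    all(enr[cand[i]] > enr[kmer_encode(nb)])
  }, logical(1))
  data.frame(kmer = kmers[keep], enrichment = enr[cand[keep]],
             row.names = NULL)
}

#' Export a k-mer table
#'
#' Writes a tab-separated table of observed k-mers with counts,
#' frequencies and (optionally) relative affinities.
#'
#' @param stats a `KmerStats`.
#' @param path output file.
#' @param affinity_table optional matching `AffinityTable`.
#' @return `path`, invisibly.
#' @export
write_kmer_table <- function(stats, path, affinity_table = NULL) {
  nz <- which(stats$counts > 0)
  df <- data.frame(kmer = kmer_decode(nz, stats$k),
                   count = stats$counts[nz],
                   frequency = stats$counts[nz] / stats$total)
  if (!is.null(affinity_table)) df$K_a <- affinity_table$ka[nz]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
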