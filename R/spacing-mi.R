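#' Partition a characteristic 8-mer into its indexed 4-mer set
#'
#' An 8-mer and its reverse complement are partitioned into ten indexed
#' 4-mers: indices 1..5 are the forward windows at offsets 0..4; indices
#' 6..10 are the reverse-complement windows, index 6 being the reverse
#' complement of 4-mer number 5 and index 10 the reverse complement of
#' 4-mer number 1.
#'
#' @param eightmer an 8-character ACGT string.
#' @return An object of class `FourMerSet` with elements `source_8mer`
#'   and `fourmers` (length-10 character vector).
#' @export
build_4mer_sets <- function(eightmer) {
  if (nchar(eightmer) != 8L || grepl("[^ACGT]", eightmer))
    stop("need an 8-mer over ACGT")
  fwd <- vapply(1:5, function(j) substr(eightmer, j, j + 3L), character(1))
  fourmers <- c(fwd, revcomp(rev(fwd)))
  structure(list(source_8mer = eightmer, fourmers = fourmers),
            class = "FourMerSet")
}

#' Pair two 4-mer sets in the forward and inverse orientations
#'
#' In the forward orientation a 4-mer with index j in one set is paired
#' with the 4-mer of the other set that has the same index; in the
#' inverse orientation j is paired with 5 + j when j <= 5 and with j - 5
#' when j > 5. Any 4-mer present in both sets is excluded together with
#' every pair containing it, so that signal from the individual binding
#' sites cannot masquerade as an interaction.
#'
#' @param setA,setB `FourMerSet` objects.
#' @return list with data.frames `forward` and `inverse` (columns `ja`,
#'   `jb`, `a`, `b` for surviving pairs) and `excluded` (the shared
#'   4-mers).
#' @export
pair_4mer_sets <- function(setA, setB) {
  stopifnot(inherits(setA, "FourMerSet"), inherits(setB, "FourMerSet"))
  shared <- intersect(setA$fourmers, setB$fourmers)
  mk <- function(ja, jb) {
    df <- data.frame(ja = ja, jb = jb,
                     a = setA$fourmers[ja], b = setB$fourmers[jb])
    df[!(df$a %in% shared) & !(df$b %in% shared), , drop = FALSE]
  }
  j <- 1:10
  list(forward = mk(j, j),
       inverse = mk(j, ifelse(j <= 5L, j + 5L, j - 5L)),
       excluded = shared)
}

## 0/1 term-safe binary mutual information for 2x2 tables given
## n11 (matrix), n1 (row totals by pos1), n2 (col totals by pos2), n
binary_mi_matrix <- function(n11, n1, n2, n) {
  p11 <- n11 / n
  p1 <- matrix(n1 / n, nrow = length(n1), ncol = length(n2))
  p2 <- matrix(n2 / n, nrow = length(n1), ncol = length(n2), byrow = TRUE)
  p10 <- p1 - p11
  p01 <- p2 - p11
  p00 <- 1 - p1 - p2 + p11
  term <- function(p, qx, qy) {
    out <- p * log2(p / (qx * qy))
    out[p <= 0 | qx <= 0 | qy <= 0] <- 0
    out
  }
  mi <- term(p11, p1, p2) + term(p10, p1, 1 - p2) +
    term(p01, 1 - p1, p2) + term(p00, 1 - p1, 1 - p2)
  pmax(mi, 0)  # clip float negatives of order -1e-16
}

#' Positional mutual information between two 4-mer sets
#'
#' For every non-overlapping position pair (pos2 - pos1 >= 4) and both
#' pairings (forward, inverse), sums over the surviving 4-mer pairs the
#' mutual information between the presence of the first 4-mer at pos1
#' and the presence of the second at pos2 across the reads of a selected
#' CAP-SELEX pool. For 40-bp reads each pairing scores exactly 561
#' position pairs. Reads are scanned on the given strand only: the
#' opposite-strand arrangements are captured by the reverse-complement
#' 4-mers of indices 6..10.
#'
#' @param pool a selected-cycle `ReadPool` (read length >= 12).
#' @param setA,setB `FourMerSet` objects for the two TFs.
#' @return An object of class `MIMatrix`: `mi` is a list of two P x P
#'   matrices (`forward`, `inverse`; `NA` at overlapping cells) indexed
#'   by 0-based 4-mer start positions, plus `n_reads`, `read_length`,
#'   `excluded_4mers` and the pairings used.
#' @export
positional_mi <- function(pool, setA, setB) {
  stopifnot(inherits(pool, "ReadPool"))
  if (pool$read_length < 12L) stop("read length must be >= 12")
  n <- length(pool$reads)
  if (n < 100L) warning("fewer than 100 reads; MI estimates will be noisy")
  pairs <- pair_4mer_sets(setA, setB)
  if (nrow(pairs$forward) == 0L && nrow(pairs$inverse) == 0L)
    stop("no surviving 4-mer pairs after exclusion of shared 4-mers")
  m <- pool_matrix(pool)
  codes <- kmer_code_matrix(m, 4L)
  P <- ncol(codes)
  valid <- outer(seq_len(P), seq_len(P), function(i, j) j - i >= 4L)
  used <- unique(c(pairs$forward$a, pairs$forward$b,
                   pairs$inverse$a, pairs$inverse$b))
  ind <- lapply(stats::setNames(kmer_encode(used), used),
                function(cc) (codes == cc) * 1)
  margins <- lapply(ind, colSums)
  mi <- list()
  for (pr in c("forward", "inverse")) {
    df <- pairs[[pr]]
    acc <- matrix(0, P, P)
    for (i in seq_len(nrow(df))) {
      a <- df$a[i]; b <- df$b[i]
      n11 <- crossprod(ind[[a]], ind[[b]])
      acc <- acc + binary_mi_matrix(n11, margins[[a]], margins[[b]], n)
    }
    acc[!valid] <- NA_real_
    mi[[pr]] <- acc
  }
  structure(list(mi = mi, n_reads = n, read_length = pool$read_length,
                 n_cells = sum(valid), setA = setA, setB = setB,
                 excluded_4mers = pairs$excluded),
            class = "MIMatrix")
}

#' @export
print.MIMatrix <- function(x, ...) {
  cat(sprintf("MIMatrix: %d position pairs per pairing, %d reads of %d bp\n",
              x$n_cells, x$n_reads, x$read_length))
  cat(sprintf("  max MI: forward %.4f, inverse %.4f bits\n",
              max(x$mi$forward, na.rm = TRUE), max(x$mi$inverse, na.rm = TRUE)))
  invisible(x)
}

#' Long-format MI values
#'
#' @param mim an `MIMatrix`.
#' @return data.frame with 0-based `pos1`, `pos2`, `pairing`, `offset`
#'   (pos2 - pos1) and `mi`.
#' @export
mi_values <- function(mim) {
  out <- lapply(c("forward", "inverse"), function(pr) {
    mat <- mim$mi[[pr]]
    idx <- which(!is.na(mat), arr.ind = TRUE)
    data.frame(pos1 = idx[, 1L] - 1L, pos2 = idx[, 2L] - 1L,
               pairing = pr, offset = idx[, 2L] - idx[, 1L],
               mi = mat[idx])
  })
  do.call(rbind, out)
}

#' Call a spacing/orientation interaction from an MI matrix
#'
#' Within each pairing the position-pair MI values are ranked and the
#' top fraction (floor(top_frac x cells), 28 of 561 for 40-bp reads) is
#' selected. If cooperative binding imposes a preferred arrangement,
#' those top cells concentrate on few offsets; under the null they
#' scatter. The pair is called interacting when the top cells of either
#' pairing fall into fewer than `max_groups` distinct offsets. The
#' preferred arrangement is the modal (offset, pairing) group of the
#' concentrated pairing (ties broken by higher summed MI, then smaller
#' offset, then forward before inverse).
#'
#' @param mim an `MIMatrix`.
#' @param top_frac fraction of position pairs ranked as top signal.
#' @param max_groups strict upper bound ("fewer than 6") on the distinct
#'   arrangements the top cells may span in an interacting pair.
#' @return An object of class `InteractionCall`: `is_interacting`,
#'   `top_pairs` (per-pairing top cells), `groups` (distinct
#'   (offset, pairing) groups with cell counts), `n_groups` per pairing,
#'   and `preferred` (list with `offset`, `gap` = offset - 8, `pairing`).
#' @export
call_interaction <- function(mim, top_frac = 0.05, max_groups = 6L) {
  vals <- mi_values(mim)
  per_pairing <- split(vals, vals$pairing)
  n_top <- as.integer(floor(top_frac * mim$n_cells))
  top_list <- list(); n_groups <- c(forward = NA_integer_, inverse = NA_integer_)
  for (pr in names(per_pairing)) {
    df <- per_pairing[[pr]]
    df <- df[order(-df$mi, df$offset, df$pos1), , drop = FALSE]
    top <- df[seq_len(min(n_top, nrow(df))), , drop = FALSE]
    top_list[[pr]] <- top
    n_groups[pr] <- length(unique(top$offset))
  }
  passing <- names(which(n_groups < max_groups))
  is_interacting <- length(passing) > 0L
  top_pairs <- do.call(rbind, top_list)
  rownames(top_pairs) <- NULL
  grp <- stats::aggregate(mi ~ offset + pairing, data = top_pairs,
                          FUN = function(v) c(n = length(v), sum = sum(v)))
  groups <- data.frame(offset = grp$offset, pairing = grp$pairing,
                       n_cells = grp$mi[, "n"], sum_mi = grp$mi[, "sum"])
  cand <- if (is_interacting) groups[groups$pairing %in% passing, , drop = FALSE]
          else groups
  cand <- cand[order(-cand$n_cells, -cand$sum_mi, cand$offset,
                     match(cand$pairing, c("forward", "inverse"))), , drop = FALSE]
  preferred <- list(offset = cand$offset[1L], gap = cand$offset[1L] - 8L,
                    pairing = as.character(cand$pairing[1L]))
  structure(list(is_interacting = is_interacting, top_pairs = top_pairs,
                 groups = groups, n_groups = n_groups, n_top = n_top,
                 preferred = preferred),
            class = "InteractionCall")
}

#' @export
print.InteractionCall <- function(x, ...) {
  cat(sprintf("InteractionCall: %s (top %d cells; %d/%d distinct offsets fwd/inv)\n",
              if (x$is_interacting) "INTERACTING" else "not interacting",
              x$n_top, x$n_groups[["forward"]], x$n_groups[["inverse"]]))
  cat(sprintf("  preferred arrangement: offset %d (8-mer gap %d), %s pairing\n",
              x$preferred$offset, x$preferred$gap, x$preferred$pairing))
  invisible(x)
}

#' Average spacing profile over interacting pairs
#'
#' Averages the positional MI of the interacting calls by the gap
#' between the characteristic 8-mers (offset minus 8; negative gaps mean
#' overlapping 8-mers and are retained).
#'
#' @param calls list of `InteractionCall` objects.
#' @param mims list of the matching `MIMatrix` objects.
#' @return data.frame with `gap` and `mean_mi`, averaged first within
#'   and then across the interacting pairs.
#' @export
spacing_profile <- function(calls, mims) {
  stopifnot(length(calls) == length(mims))
  keep <- vapply(calls, function(cl) isTRUE(cl$is_interacting), logical(1))
  if (!any(keep)) stop("no interacting calls to profile")
  per_pair <- lapply(which(keep), function(i) {
    vals <- mi_values(mims[[i]])
    ag <- stats::aggregate(mi ~ offset, data = vals, FUN = mean)
    data.frame(gap = ag$offset - 8L, mi = ag$mi)
  })
  all_gaps <- sort(unique(unlist(lapply(per_pair, `[[`, "gap"))))
  prof <- vapply(all_gaps, function(g) {
    mean(unlist(lapply(per_pair, function(df) df$mi[df$gap == g])))
  }, numeric(1))
  data.frame(gap = all_gaps, mean_mi = prof)
}

#' Co-occurrence table of two 6-mers by gap and orientation
#'
#' Counts, per read, co-occurrences of two 6-mers (each matched on both
#' strands) by gap (0..max_gap-1 intervening bases) and strand
#' arrangement. Arrangements are canonicalised with the first 6-mer on
#' the left (`FF`, `FR`, `RF`, `RR`); a pair with the second 6-mer on
#' the left is recorded as the equivalent opposite-strand arrangement.
#' For palindromic 6-mers the forward orientation is recorded.
#'
#' @param pool a `ReadPool`.
#' @param sixmerA,sixmerB 6-character ACGT strings.
#' @param max_gap gaps 0..max_gap-1 are tabulated (default 30).
#' @return integer matrix `max_gap` x 4 (rows gaps, columns FF, FR, RF,
#'   RR).
#' @export
sixmer_spacing_table <- function(pool, sixmerA, sixmerB, max_gap = 30L) {
  stopifnot(nchar(sixmerA) == 6L, nchar(sixmerB) == 6L)
  m <- pool_matrix(pool)
  codes <- kmer_code_matrix(m, 6L)
  occ <- function(sm) {
    fwd <- which(codes == kmer_encode(sm), arr.ind = TRUE)
    rcs <- revcomp(sm)
    if (rcs == sm) {  # palindrome: forward only
      rev <- fwd[0, , drop = FALSE]
    } else rev <- which(codes == kmer_encode(rcs), arr.ind = TRUE)
    list(F = fwd, R = rev)
  }
  oa <- occ(sixmerA); ob <- occ(sixmerB)
  pal_a <- revcomp(sixmerA) == sixmerA
  pal_b <- revcomp(sixmerB) == sixmerB
  tab <- matrix(0L, nrow = max_gap, ncol = 4L,
                dimnames = list(0:(max_gap - 1L), c("FF", "FR", "RF", "RR")))
  flip <- c(F = "R", R = "F")
  for (sa in c("F", "R")) for (sb in c("F", "R")) {
    A <- oa[[sa]]; B <- ob[[sb]]
    if (!nrow(A) || !nrow(B)) next
    ## join occurrences by read
    common <- intersect(A[, 1L], B[, 1L])
    for (rd in common) {
      pa <- A[A[, 1L] == rd, 2L]
      pb <- B[B[, 1L] == rd, 2L]
      for (x in pa) for (y in pb) {
        if (y >= x + 6L) {            # A left of B
          gap <- y - (x + 6L)
          la <- sa; lb <- sb
        } else if (x >= y + 6L) {     # B left of A: flip strands
          gap <- x - (y + 6L)
          la <- flip[[sa]]; lb <- flip[[sb]]
        } else next                   # overlapping
        if (pal_a) la <- "F"          # palindromes recorded as forward
        if (pal_b) lb <- "F"
        ori <- paste0(la, lb)
        if (gap < max_gap) tab[gap + 1L, ori] <- tab[gap + 1L, ori] + 1L
      }
    }
  }
  tab
}
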