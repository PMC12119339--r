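## Shared fixtures and independent brute-force oracles.

## random ACGT strings
random_kmers <- function(n, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = ""),
    character(1))
}

## brute-force k-mer counting via substring enumeration
oracle_kmer_counts <- function(reads, k, both_strands = FALSE) {
  words <- unlist(lapply(reads, function(r) {
    w <- substring(r, seq_len(nchar(r) - k + 1L), seq_len(nchar(r) - k + 1L) + k - 1L)
    if (both_strands) c(w, revcomp(w)) else w
  }))
  table(words)
}

## brute-force Huddinge distance by explicit offset/strand enumeration
oracle_huddinge <- function(a, b) {
  la <- nchar(a); best <- Inf
  for (bs in c(b, revcomp(b))) {
    lb <- nchar(bs)
    for (s in -(lb - 1L):(la - 1L)) {
      xa <- strsplit(a, "")[[1L]]; xb <- strsplit(bs, "")[[1L]]
      mism <- 0L; overlap <- 0L
      for (i in seq_len(la)) {
        j <- i - s
        if (j >= 1L && j <= lb) {
          overlap <- overlap + 1L
          if (xa[i] != xb[j]) mism <- mism + 1L
        }
      }
      best <- min(best, mism + max(la, lb) - overlap)
    }
  }
  best
}

## brute-force minimum dominating set by subset enumeration
oracle_min_domset_size <- function(adj) {
  n <- nrow(adj)
  closed <- adj | diag(TRUE, n)
  for (size in 1:n) {
    combos <- utils::combn(n, size)
    for (ci in seq_len(ncol(combos))) {
      s <- combos[, ci]
      covered <- apply(closed[, s, drop = FALSE], 1L, any)
      if (all(covered)) return(size)
    }
  }
  n
}

## small deterministic pool: every read carries given left/right parts
## at a fixed layout inside random background
make_planted_pool <- function(n, len, inserts, positions, seed = 1) {
  set.seed(seed)
  reads <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
  for (j in seq_along(inserts)) {
    s <- positions[j]
    substr(reads, s, s + nchar(inserts[j]) - 1L) <- inserts[j]
  }
  read_pool_from_reads(reads, cycle = 3L)
}

## toy motif with exact column frequencies
freq_motif <- function(freqs, name = "toy", total = 100) {
  motif(freqs * total, name = name)
}

## deterministic consensus motif (0.97 consensus base)
sharp_motif <- function(consensus, name = consensus) {
  planted_motif(consensus, 0.97, name = name)
}

## write lines to a temp file and return the path
tmpfile_with <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

## build a synthetic conservation world: matches of a true motif sit on
## high-phyloP bases, control matches on background
synthetic_conservation <- function(n_true = 300, n_ctrl = 300, width = 8,
                                   sep = TRUE, seed = 42) {
  set.seed(seed)
  spacing <- 20L
  n <- n_true + n_ctrl
  len <- (n + 2L) * spacing
  starts <- seq_len(n) * spacing
  truth <- rep(c(TRUE, FALSE), c(n_true, n_ctrl))[sample(n)]
  base_score <- rnorm(len, 0, 0.5)
  for (i in seq_len(n)) {
    lift <- if (sep && truth[i]) rnorm(1, 3, 0.5) else rnorm(1, 0, 0.5)
    base_score[starts[i]:(starts[i] + width - 1L)] <- lift
  }
  track <- conservation_track(list(chrS = base_score))
  mk <- function(idx, nm) {
    gr <- GenomicRanges::GRanges("chrS", IRanges::IRanges(starts[idx], width = width),
                                 strand = "+")
    S4Vectors::mcols(gr)$score <- runif(length(idx), 2, 10)
    S4Vectors::mcols(gr)$motif <- nm
    structure(list(matches = gr, score_threshold = 2, target_count = length(idx),
                   motif_name = nm, motif_length = width), class = "MatchSet")
  }
  list(true = mk(which(truth), "true"), ctrl = mk(which(!truth), "ctrl"),
       track = track)
}

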