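#' Thermodynamic SELEX selection model
#'
#' Describes the binding landscape used by the simulator: one or two
#' position weight matrices, an optional cooperativity factor applied
#' when the two sites occur at a planted gap and strand arrangement, and
#' the saturation constant that sets the free-protein regime.
#'
#' Affinities follow the standard mononucleotide-independence energy
#' model: a window's affinity is the product of its column frequencies
#' normalised so that the consensus site has affinity one. A ligand's
#' affinity is the maximum over all single-site and paired-configuration
#' terms; the paired term at the planted arrangement (and its reverse
#' complement, since ligands are double-stranded) is
#' `cooperativity x a_A x a_B`. `cooperativity = 1` recovers independent
#' binding and `cooperativity = 0` forbids the paired configuration.
#'
#' @param motifA a `Motif` (the only motif for single-TF selections).
#' @param motifB optional second `Motif`.
#' @param cooperativity cooperativity factor omega (>= 0).
#' @param gap planted gap in bp between the end of the A site and the
#'   start of the B site.
#' @param orientation planted strand arrangement, one of `"ff"`, `"fr"`,
#'   `"rf"`, `"rr"` (A strand then B strand, A left of B).
#' @param rounds number of selection cycles.
#' @param K_ratio saturation constant in consensus-affinity units; the
#'   default `10 x max(1, cooperativity)` keeps selection approximately
#'   affinity-proportional (weak-binding regime).
#' @return An object of class `SelectionModel`.
#' @export
selection_model <- function(motifA, motifB = NULL, cooperativity = 1,
                            gap = 0L, orientation = c("ff", "fr", "rf", "rr"),
                            rounds = 3L, K_ratio = NULL) {
  stopifnot(inherits(motifA, "Motif"))
  orientation <- match.arg(orientation)
  if (cooperativity < 0) stop("cooperativity must be >= 0")
  if (is.null(K_ratio)) K_ratio <- 10 * max(1, cooperativity)
  structure(list(motifA = motifA, motifB = motifB,
                 cooperativity = cooperativity, gap = as.integer(gap),
                 orientation = orientation, rounds = as.integer(rounds),
                 K_ratio = K_ratio),
            class = "SelectionModel")
}

#' @export
print.SelectionModel <- function(x, ...) {
  cat(sprintf("SelectionModel: %s%s, omega = %g, rounds = %d, K = %g\n",
              x$motifA$name,
              if (!is.null(x$motifB))
                sprintf(" + %s (gap %d, %s)", x$motifB$name, x$gap, x$orientation)
              else "", x$cooperativity, x$rounds, x$K_ratio))
  invisible(x)
}

## log(f/fmax) scanning matrix of a motif
motif_log_relfreq <- function(mot) {
  f <- motif_freq(mot)
  log(pmax(f, 1e-12)) - rep(log(apply(f, 2L, max)), each = 4L)
}

## all per-read affinity components for a model; internal workhorse
## (compiled scanning kernel)
ligand_affinity_components <- function(m, model) {
  storage.mode(m) <- "integer"
  lwAf <- motif_log_relfreq(model$motifA)
  lwAr <- motif_log_relfreq(motif_revcomp(model$motifA))
  if (!is.null(model$motifB)) {
    lwBf <- motif_log_relfreq(model$motifB)
    lwBr <- motif_log_relfreq(motif_revcomp(model$motifB))
  } else lwBf <- lwBr <- matrix(numeric(0), nrow = 4L, ncol = 0L)
  orient <- match(model$orientation, c("ff", "fr", "rf", "rr")) - 1L
  res <- .cpp_affinity_components(m, lwAf, lwAr, lwBf, lwBr,
                                  as.integer(model$gap), orient)
  comp <- list(A = exp(res$logA))
  if (!is.null(model$motifB)) {
    comp$B <- exp(res$logB)
    comp$paired <- if (model$cooperativity > 0)
      model$cooperativity * exp(res$logPaired) else rep(0, nrow(m))
  }
  comp
}

#' Ligand affinities under a selection model
#'
#' @param reads character vector of equal-length reads, or a `ReadPool`.
#' @param model a `SelectionModel`.
#' @return numeric vector: each ligand's relative affinity (consensus
#'   single site = 1).
#' @export
ligand_affinities <- function(reads, model) {
  if (inherits(reads, "ReadPool")) reads <- reads$reads
  comp <- ligand_affinity_components(seq_int_matrix(reads), model)
  do.call(pmax, comp)
}

#' @rdname ligand_affinities
#' @param read a single read.
#' @export
ligand_affinity <- function(read, model) {
  ligand_affinities(read, model)
}

#' Simulate a random input library (cycle 0)
#'
#' I.i.d. reads from a uniform or Markov background.
#'
#' @param n_reads number of reads.
#' @param length read length in nt (default 40, the random-region length
#'   of the SELEX ligand design).
#' @param background `NULL` for uniform bases, or a `MarkovBackground`.
#' @param seed RNG seed (optional).
#' @return A `ReadPool` with cycle 0.
#' @export
simulate_library <- function(n_reads, length = 40L, background = NULL,
                             seed = NULL) {
  if (n_reads < 1) stop("n_reads must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  L <- as.integer(length)
  if (is.null(background)) {
    m <- matrix(1L + as.integer(4 * stats::runif(n_reads * L)), ncol = L)
    m[m > 4L] <- 4L  # guard the runif(., 1) edge case
  } else {
    o <- background$order
    m <- matrix(0L, nrow = n_reads, ncol = L)
    if (o == 0L) {
      m[] <- sample.int(4L, n_reads * L, replace = TRUE,
                        prob = background$trans[1L, ])
    } else {
      ctx <- sample.int(4^o, n_reads, replace = TRUE, prob = background$initial)
      ## decode the initial order-mer
      cc <- ctx - 1L
      for (j in o:1) { m[, j] <- (cc %% 4L) + 1L; cc <- cc %/% 4L }
      for (j in (o + 1L):L) {
        u <- stats::runif(n_reads)
        cum <- t(apply(background$trans[ctx, , drop = FALSE], 1L, cumsum))
        nxt <- 1L + (u > cum[, 1L]) + (u > cum[, 2L]) + (u > cum[, 3L])
        m[, j] <- nxt
        ctx <- ((ctx - 1L) %% 4^(o - 1L)) * 4L + (nxt - 1L) + 1L
      }
    }
  }
  read_pool_from_reads(int_to_seq(m), cycle = 0L, label = "simulated cycle 0")
}

#' Simulate rounds of thermodynamic SELEX selection
#'
#' Each round, ligand i enters the bound fraction with probability
#' proportional to its occupancy `a_i / (a_i + K_ratio)` at fixed free
#' protein activity; the proportionality constant (the capture
#' efficiency) is normalised so that the best ligand of the pool is
#' always captured, which keeps pool complexity at sequencing scale
#' while preserving the post- to pre-selection frequency-ratio relation
#' `F'_i/F'_j = (w_i/w_j) F_i/F_j`. The bound fraction is resampled
#' with replacement back to the original pool size (uniform PCR
#' amplification). All draws are seeded and reproducible.
#'
#' @param pool the cycle-0 `ReadPool`.
#' @param model a `SelectionModel`.
#' @param seed RNG seed (optional).
#' @param rounds number of rounds; defaults to `model$rounds`.
#' @param keep `"all"` materialises every cycle's pool; `"last"` only
#'   the final cycle (earlier entries are `NULL`), which saves time and
#'   memory for large libraries.
#' @return list with `pools` (list of `ReadPool`, cycles 1..r) and
#'   `truth` (list: per-round survivor counts, per-read affinities of
#'   the input library, the model, the seed).
#' @export
simulate_selection <- function(pool, model, seed = NULL, rounds = model$rounds,
                               keep = c("all", "last")) {
  stopifnot(inherits(pool, "ReadPool"), inherits(model, "SelectionModel"))
  keep <- match.arg(keep)
  if (!is.null(seed)) set.seed(seed)
  n <- length(pool$reads)
  m <- pool_matrix(pool)
  ## ligands never mutate: affinities are a property of the founder
  ## reads, so selection runs in index space on one affinity pass
  a0 <- do.call(pmax, ligand_affinity_components(m, model))
  w0 <- a0 / (a0 + model$K_ratio)
  idx <- seq_len(n)
  pools <- vector("list", rounds)
  survivors <- integer(rounds)
  for (r in seq_len(rounds)) {
    w <- w0[idx]
    sel <- which(stats::runif(n) < w / max(w))
    if (!length(sel))
      stop("selection extinction: no ligand bound in round ", r)
    survivors[r] <- length(sel)
    idx <- idx[sample(sel, n, replace = TRUE)]
    if (keep == "all" || r == rounds)
      pools[[r]] <- read_pool_from_reads(int_to_seq(m[idx, , drop = FALSE]),
                                         cycle = r,
                                         label = sprintf("simulated cycle %d", r))
  }
  list(pools = pools,
       truth = list(survivors = survivors, affinities = a0, model = model,
                    seed = seed, n_reads = n))
}

#' Planted k-mer affinity landscape of a motif
#'
#' The relative affinity of every k-mer taken as a complete binding
#' site: the maximum, over all placements of the motif fully inside the
#' k-mer (k >= motif length) and both strands, of the product of
#' `f/fmax` over the motif columns.
#'
#' @param mot the planted `Motif`.
#' @param k word length (>= motif length; memory is 4^k doubles,
#'   k <= 12).
#' @return numeric vector of length 4^k, indexed by k-mer code in
#'   lexicographic order, with consensus-containing k-mers at 1.
#' @export
planted_kmer_landscape <- function(mot, k) {
  if (k > 12) stop("k > 12 refused")
  f <- motif_freq(mot)
  relf <- sweep(f, 2L, apply(f, 2L, max), "/")
  Lm <- ncol(relf)
  if (k < Lm) stop("k must be >= the motif length")
  nk <- 4^k
  codes <- seq_len(nk) - 1
  digits <- lapply(seq_len(k), function(j) (codes %/% 4^(k - j)) %% 4 + 1)
  best <- rep(0, nk)
  for (s in 0:(k - Lm)) {  # motif column j sits at k-mer position s + j
    v <- rep(1, nk)
    for (j in seq_len(Lm)) v <- v * relf[, j][digits[[s + j]]]
    best <- pmax(best, v)
  }
  rc <- kmer_code_revcomp(seq_len(nk), k)
  pmax(best, best[rc])
}

#' Effective k-mer enrichment landscape of a selection model
#'
#' The noise-free expectation of the k-mer enrichment a selection
#' experiment produces on a given input library: each read's windows
#' are weighted by the read's selection weight over `r` rounds,
#' `(a / (a + K))^r`, and each k-mer's expected selected frequency is
#' divided by its input frequency. The r-th root expresses the result
#' on the relative-affinity scale. This is the ground truth the
#' relative-affinity estimator aims to recover from sequenced
#' (noisy, resampled) pools.
#'
#' @param pool0 the input `ReadPool` (cycle 0).
#' @param model a `SelectionModel`.
#' @param k word length (k <= 12).
#' @param r number of rounds (defaults to `model$rounds`).
#' @param both_strands count each window and its reverse complement.
#' @return numeric vector of length 4^k: the expected enrichment ratio
#'   `(F_exp(k)/F_0(k))^(1/r)`, normalised to its maximum; `NA` for
#'   k-mers absent from the input library.
#' @export
effective_kmer_landscape <- function(pool0, model, k, r = model$rounds,
                                     both_strands = TRUE) {
  if (k > 12) stop("k > 12 refused")
  m <- pool_matrix(pool0)
  a <- do.call(pmax, ligand_affinity_components(m, model))
  w <- (a / (a + model$K_ratio))^r
  nk <- 4^k
  f0 <- numeric(nk); fw <- numeric(nk)
  mats <- if (both_strands) list(m, int_revcomp(m)) else list(m)
  for (mat in mats) {
    codes <- kmer_code_matrix(mat, k)
    for (p in seq_len(ncol(codes))) {
      f0 <- f0 + tabulate(codes[, p], nbins = nk)
      agg <- rowsum(w, codes[, p])
      idx <- as.integer(rownames(agg))
      fw[idx] <- fw[idx] + agg[, 1L]
    }
  }
  out <- rep(NA_real_, nk)
  seen <- f0 > 0
  out[seen] <- (fw[seen] / f0[seen])^(1 / r)
  out / max(out, na.rm = TRUE)
}

#' Best binding configuration per read
#'
#' Reports, for each read, which term of the selection model dominates
#' its affinity: the A site, the B site, or the cooperative paired
#' configuration (with the affinity of each component).
#'
#' @param reads character vector or `ReadPool`.
#' @param model a `SelectionModel`.
#' @return data.frame with per-read `affinity`, `configuration`
#'   (`"A"`, `"B"` or `"paired"`) and the three component affinities.
#' @export
sim_best_configuration <- function(reads, model) {
  if (inherits(reads, "ReadPool")) reads <- reads$reads
  comp <- ligand_affinity_components(seq_int_matrix(reads), model)
  aff <- do.call(pmax, comp)
  cfg <- names(comp)[max.col(do.call(cbind, comp), ties.method = "first")]
  cfg[cfg == "A"] <- "A"; cfg[cfg == "B"] <- "B"
  out <- data.frame(affinity = aff, configuration = cfg)
  for (nm in names(comp)) out[[paste0("a_", nm)]] <- comp[[nm]]
  out
}

#' Example planted motifs for simulations
#'
#' Builds a count-matrix motif from a consensus string with a fixed
#' consensus-base frequency per column. Sharper columns (`consensus_freq`
#' near 1) emulate crisp composite cores; softer columns emulate typical
#' monomer motifs.
#'
#' @param consensus ACGT consensus string.
#' @param consensus_freq frequency of the consensus base per column
#'   (recycled along the motif, so a vector plants a core/flank
#'   profile).
#' @param name motif name.
#' @param total pseudo-observation total per column.
#' @return A `Motif`.
#' @export
planted_motif <- function(consensus, consensus_freq = 0.7,
                          name = consensus, total = 1000) {
  bases <- strsplit(consensus, "")[[1L]]
  if (any(!bases %in% DNA_BASES)) stop("consensus must be ACGT")
  cf <- rep_len(consensus_freq, length(bases))
  counts <- matrix(rep((1 - cf) / 3 * total, each = 4L), nrow = 4L,
                   dimnames = list(DNA_BASES, NULL))
  counts[cbind(match(bases, DNA_BASES), seq_along(bases))] <- cf * total
  motif(counts, name = name, motif_class = "monomer")
}

#' Default planted monomer motifs for the simulator
#'
#' Two 8-bp monomer motifs with a sharp 4-bp core (consensus frequency
#' 0.9) and soft 2-bp flanks on each side (consensus frequency 0.3),
#' emulating the information-content profile of typical monomeric TF
#' motifs; the 4-mer sets of the two consensus 8-mers share no 4-mer.
#'
#' @return named list with `A` and `B` (`Motif` objects) and the
#'   consensus 8-mers `a8`, `b8`.
#' @export
default_sim_motifs <- function() {
  prof <- c(0.3, 0.3, 0.9, 0.9, 0.9, 0.9, 0.3, 0.3)
  list(A = planted_motif("ACCGGAAG", prof, name = "simTF_A"),
       B = planted_motif("TGACTCAT", prof, name = "simTF_B"),
       a8 = "ACCGGAAG", b8 = "TGACTCAT")
}
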