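test_that("4-mer sets satisfy the indexing invariants for all inputs", {
  fs <- build_4mer_sets("AAAACCCC")
  expect_identical(fs$fourmers[1L], "AAAA")
  expect_identical(fs$fourmers[5L], "CCCC")
  expect_identical(fs$fourmers[6L], "GGGG")
  expect_identical(fs$fourmers[10L], "TTTT")

  ## property over random 8-mers: forward windows and revcomp mirror rule
  for (e in random_kmers(200, 8, seed = 11)) {
    fs <- build_4mer_sets(e)
    for (j in 1:5) {
      expect_identical(fs$fourmers[j], substr(e, j, j + 3L))
      expect_identical(fs$fourmers[5L + j], revcomp(fs$fourmers[6L - j]))
    }
  }
  ## palindromic 8-mer still satisfies both invariants
  fs <- build_4mer_sets("ACGTACGT")
  expect_identical(fs$fourmers[6L], revcomp(fs$fourmers[5L]))
  expect_error(build_4mer_sets("ACGT"), "8-mer")
})

test_that("pairing excludes shared 4-mers exactly as set intersection", {
  pa <- pair_4mer_sets(build_4mer_sets("AAAATTTT"), build_4mer_sets("CCCCGGGG"))
  expect_identical(nrow(pa$forward) + nrow(pa$inverse), 20L)
  expect_length(pa$excluded, 0L)

  same <- pair_4mer_sets(build_4mer_sets("ACGGATTA"), build_4mer_sets("ACGGATTA"))
  expect_identical(nrow(same$forward), 0L)
  expect_identical(nrow(same$inverse), 0L)

  ## inverse pairing index rule: j <-> 5 + j (j <= 5), j - 5 (j > 5)
  expect_identical(pa$inverse$jb, ifelse(pa$inverse$ja <= 5L,
                                         pa$inverse$ja + 5L, pa$inverse$ja - 5L))

  ## exclusion oracle on random 8-mer pairs
  set.seed(12)
  for (i in 1:25) {
    sA <- build_4mer_sets(random_kmers(1, 8))
    sB <- build_4mer_sets(random_kmers(1, 8))
    pr <- pair_4mer_sets(sA, sB)
    shared <- intersect(sA$fourmers, sB$fourmers)
    expect_setequal(pr$excluded, shared)
    expect_false(any(pr$forward$a %in% shared | pr$forward$b %in% shared))
    expect_false(any(pr$inverse$a %in% shared | pr$inverse$b %in% shared))
  }
})

test_that("positional MI scores 561 cells for 40-bp reads and detects dependence", {
  sA <- build_4mer_sets("ACCGGAAG"); sB <- build_4mer_sets("TGACTCAT")

  ## i.i.d. uniform pool: MI stays at sampling-noise level
  lib <- simulate_library(50000, 40, seed = 13)
  mm <- positional_mi(lib, sA, sB)
  expect_identical(mm$n_cells, 561L)
  expect_lt(max(unlist(mm$mi), na.rm = TRUE), 0.01)
  expect_true(all(unlist(mm$mi) >= 0, na.rm = TRUE))

  ## perfectly dependent events: 4-mer A at pos 3 always with B at pos 12
  ## (0-based), each in half the reads -> that pair's term is 1 bit
  set.seed(14)
  n <- 2000
  reads <- random_kmers(n, 40)
  ## scrub accidental occurrences of the planted words, then plant the
  ## arrangement in both ligand orientations (double-stranded pools)
  for (w in c("ACCG", "TGAC", "GTCA", "CGGT"))
    reads <- gsub(w, "AATT", reads, fixed = TRUE)
  half <- seq_len(n / 2)
  substr(reads[half], 4L, 7L) <- "ACCG"    # 0-based pos 3
  substr(reads[half], 13L, 16L) <- "TGAC"  # 0-based pos 12
  substr(reads[half], 25L, 28L) <- "GTCA"  # the same arrangement read
  substr(reads[half], 34L, 37L) <- "CGGT"  # on the opposite strand
  pool <- read_pool_from_reads(reads, cycle = 3)
  mm2 <- positional_mi(pool, sA, sB)
  got <- mm2$mi$forward[4L, 13L]  # 1-based matrix indices
  expect_gt(got, 0.95)  # ~1 bit minus scrub imperfections

  ## MI is symmetric under swapping which TF is A vs B (up to the
  ## junction 4-mers the planting itself creates)
  mm3 <- positional_mi(pool, sB, sA)
  expect_equal(max(unlist(mm2$mi), na.rm = TRUE),
               max(unlist(mm3$mi), na.rm = TRUE), tolerance = 0.01)
})

test_that("interaction calls concentrate on true arrangements and scatter on noise", {
  sA <- build_4mer_sets("ACCGGAAG"); sB <- build_4mer_sets("TGACTCAT")
  lib <- simulate_library(50000, 40, seed = 15)
  cl0 <- call_interaction(positional_mi(lib, sA, sB))
  expect_identical(cl0$n_top, 28L)
  expect_false(cl0$is_interacting)
  expect_true(all(cl0$n_groups >= 6L))

  ## constructed MIMatrix: all strong cells at one offset
  mmx <- positional_mi(read_pool_from_reads(random_kmers(500, 40, seed = 16),
                                            cycle = 3), sA, sB)
  for (p1 in 1:24) mmx$mi$forward[p1, p1 + 10L] <- 1 + p1 / 100
  clx <- call_interaction(mmx)
  expect_true(clx$is_interacting)
  expect_identical(clx$preferred$offset, 10L)
  expect_identical(clx$preferred$gap, 2L)
  expect_identical(clx$preferred$pairing, "forward")
})

test_that("spacing profile averages interacting pairs by 8-mer gap", {
  sA <- build_4mer_sets("ACCGGAAG"); sB <- build_4mer_sets("TGACTCAT")
  base <- positional_mi(read_pool_from_reads(random_kmers(500, 40, seed = 17),
                                             cycle = 3), sA, sB)
  mm <- base
  for (p1 in 1:24) mm$mi$forward[p1, p1 + 10L] <- 2
  cl <- call_interaction(mm)
  prof <- spacing_profile(list(cl), list(mm))
  expect_identical(prof$gap[which.max(prof$mean_mi)], 2L)

  cl0 <- call_interaction(base)
  expect_error(spacing_profile(list(cl0), list(base)), "no interacting")
})

test_that("6-mer spacing tables count co-occurrences by gap and arrangement", {
  ## planted: A then B on the same strand at gap 3 in every read
  pool <- make_planted_pool(200, 40, c("AAACCC", "GGGTTT"), c(5L, 14L), seed = 18)
  tab <- sixmer_spacing_table(pool, "AAACCC", "GGGTTT")
  expect_identical(dim(tab), c(30L, 4L))
  expect_gte(tab["3", "FF"], 200L)
  expect_identical(unname(which.max(rowSums(tab))), 4L)  # gap 3 row

  ## palindromic 6-mer against itself: only forward orientations recorded
  pool2 <- make_planted_pool(50, 40, c("ACGCGT", "ACGCGT"), c(3L, 20L), seed = 19)
  tab2 <- sixmer_spacing_table(pool2, "ACGCGT", "ACGCGT")
  expect_true(all(tab2[, c("FR", "RF", "RR")] == 0L))

  ## regex co-occurrence oracle on random reads
  pool3 <- read_pool_from_reads(random_kmers(300, 40, seed = 20))
  a6 <- "ACGTAC"; b6 <- "GGATCC"
  tab3 <- sixmer_spacing_table(pool3, a6, b6)
  oracle <- matrix(0L, 30, 4, dimnames = dimnames(tab3))
  occ <- function(r, w) {
    hits <- c()
    for (s in seq_len(nchar(r) - 5L))
      if (substr(r, s, s + 5L) == w) hits <- c(hits, s)
    hits
  }
  flip <- c(F = "R", R = "F")
  for (r in pool3$reads) {
    oa <- list(F = occ(r, a6), R = occ(r, revcomp(a6)))
    ob <- list(F = occ(r, b6), R = occ(r, revcomp(b6)))
    for (sa in c("F", "R")) for (sb in c("F", "R"))
      for (x in oa[[sa]]) for (y in ob[[sb]]) {
        if (y >= x + 6L) { g <- y - x - 6L; o <- paste0(sa, sb) }
        else if (x >= y + 6L) { g <- x - y - 6L; o <- paste0(flip[[sa]], flip[[sb]]) }
        else next
        if (g < 30L) oracle[g + 1L, o] <- oracle[g + 1L, o] + 1L
      }
  }
  expect_identical(unclass(tab3), unclass(oracle))
})
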