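## small synthetic genome with a planted motif match
toy_genome <- function(len = 10000, seed = 40) {
  set.seed(seed)
  setNames(paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = ""), "chrT")
}

test_that("motif scanning matches a per-window brute-force scorer", {
  g <- toy_genome()
  mot <- sharp_motif("ACGGATCC")
  ms <- scan_motif(g, mot, target_matches = 50, min_score = 2)
  expect_s3_class(ms, "MatchSet")
  expect_true(all(S4Vectors::mcols(ms$matches)$score >= ms$score_threshold))
  expect_true(all(GenomicRanges::width(ms$matches) == 8L))

  ## brute-force oracle with the same log-odds matrix
  lo <- motif_logodds(mot, background = rep(0.25, 4))
  x <- strsplit(g, "")[[1]]
  base_i <- match(x, c("A", "C", "G", "T"))
  lo_r <- lo[4:1, 8:1]
  oracle <- list()
  for (w in seq_len(length(x) - 7L)) {
    idx <- base_i[w:(w + 7L)]
    s_f <- sum(lo[cbind(idx, 1:8)]); s_r <- sum(lo_r[cbind(idx, 1:8)])
    if (s_f >= 2) oracle[[length(oracle) + 1L]] <- c(w, 1L, s_f)
    if (s_r >= 2) oracle[[length(oracle) + 1L]] <- c(w, 2L, s_r)
  }
  odf <- do.call(rbind, oracle)
  ms_all <- suppressWarnings(scan_motif(g, mot, target_matches = 100000,
                                        min_score = 2,
                                        background = rep(0.25, 4)))
  expect_identical(length(ms_all$matches), nrow(odf))
  got <- sort(GenomicRanges::start(ms_all$matches) * 10 +
                (GenomicRanges::strand(ms_all$matches) == "-"))
  want <- sort(odf[, 1] * 10 + (odf[, 2] == 2L))
  expect_identical(as.integer(got), as.integer(want))

  ## exact planted site found on both strands
  g2 <- g
  substr(g2, 101, 108) <- "ACGGATCC"
  ms2 <- scan_motif(g2, mot, target_matches = 5, min_score = 2,
                    background = rep(0.25, 4))
  expect_true(101 %in% GenomicRanges::start(ms2$matches))

  ## fallback: fewer floor-passing matches than requested
  expect_warning(
    scan_motif(setNames("ACGTACGTACGTACGT", "s"), mot, target_matches = 1000),
    "reach the score floor")
})

test_that("hypergeometric region enrichment matches exact enumeration", {
  ## match everywhere: log2FC 0, p 1
  gr <- GenomicRanges::GRanges("chrT", IRanges::IRanges(c(1, 50, 100, 150), width = 10))
  matches <- GenomicRanges::GRanges("chrT", IRanges::IRanges(c(2, 51, 101, 151), width = 5))
  S4Vectors::mcols(matches)$score <- 3
  res <- region_enrichment(matches, gr, gr)
  expect_equal(res$log2_fold_change, 0)
  expect_equal(res$p_value, 1)

  ## N=20, n=5, m=8, k=5 against full enumeration of the hypergeometric
  universe <- GenomicRanges::GRanges("chrT", IRanges::IRanges((0:19) * 100 + 1, width = 50))
  subset <- universe[1:5]
  hit_regions <- universe[c(1:5, 6:8)]  # m = 8, all 5 subset regions hit
  matches2 <- GenomicRanges::GRanges("chrT",
    IRanges::IRanges(GenomicRanges::start(hit_regions) + 5, width = 4))
  res2 <- region_enrichment(matches2, subset, universe)
  expect_identical(c(res2$k, res2$n, res2$m, res2$N), c(5L, 5L, 8L, 20L))
  ## exact upper tail: P(X >= 5) by enumeration over all C(20,5) draws
  p_exact <- sum(vapply(5:5, function(k)
    choose(8, k) * choose(12, 5 - k) / choose(20, 5), numeric(1)))
  expect_equal(res2$p_value, p_exact, tolerance = 1e-12)
  expect_identical(res2$direction, "enrichment")
})

test_that("control motifs follow the split/recombination/similarity rules", {
  mot <- freq_motif(prop.table(matrix(runif(40, 0.05, 1), 4), 2))  # L = 10
  cs <- make_control_motifs(mot, exclude_above = 1.01)  # keep everything
  ## L=10: split points 3..7, three recombinations each
  expect_identical(length(cs$controls) + cs$n_duplicates, 15L)
  expect_true(all(vapply(cs$controls, motif_length, numeric(1)) == 10))
  expect_true(all(cs$provenance$split >= 3 & cs$provenance$split <= 7))

  ## degenerate uniform motif: every control is the original; all excluded
  uni <- motif(matrix(10, 4, 9), name = "uni")
  cs2 <- make_control_motifs(uni, exclude_above = 0.1)
  expect_length(cs2$controls, 0L)

  ## too-short motif yields an empty set with a warning
  expect_warning(res <- make_control_motifs(sharp_motif("ACGT")), "too short")
  expect_length(res$controls, 0L)
})

test_that("GMM thresholds separate mixture components stably", {
  set.seed(41)
  x <- c(rnorm(1000, 0, 1), rnorm(1000, 5, 1))
  thr <- gmm_conservation_threshold(x, seed = 1)
  expect_gt(as.numeric(thr), 2.0)
  expect_lt(as.numeric(thr), 3.0)
  expect_false(attr(thr, "fallback"))

  ## stability across initialisation seeds
  thrs <- vapply(1:10, function(s)
    as.numeric(gmm_conservation_threshold(x, seed = s)), numeric(1))
  expect_lt(max(thrs) - min(thrs), 0.1)

  ## independent cross-check against mclust on the same data
  if (requireNamespace("mclust", quietly = TRUE)) {
    suppressMessages(library(mclust))  # Mclust needs its namespace attached
    fit <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
    mu <- fit$parameters$mean
    mid <- mean(range(mu))
    expect_lt(abs(as.numeric(thr) - mid), 0.6)
  }

  ## degenerate input falls back to the median with a flag
  same <- rep(1.5, 30)
  thr2 <- gmm_conservation_threshold(same)
  expect_true(attr(thr2, "fallback"))
  expect_equal(as.numeric(thr2), 1.5)
  expect_error(gmm_conservation_threshold(1:5), "at least 20")
})

test_that("conserved-match test separates planted conservation from controls", {
  w <- synthetic_conservation(sep = TRUE, seed = 43)
  res <- conserved_match_test(w$true, w$ctrl, w$track, top_n = 600)
  expect_lt(res$p_value, 1e-6)
  expect_gt(res$fold_change, 2)

  ## k = 0 edge: no conserved true matches
  w0 <- synthetic_conservation(sep = TRUE, seed = 44)
  res0 <- conserved_match_test(w0$true, w0$ctrl, w0$track, top_n = 600,
                               threshold = 1e9)
  expect_identical(res0$k, 0L)
  expect_equal(res0$fold_change, 0)
  expect_equal(res0$p_value, 1)
})

test_that("half-site conservation correlation detects shared state", {
  set.seed(45)
  n <- 400; width <- 8L; spacing <- 20L
  len <- (2 * n + 2) * spacing
  score <- rnorm(len, 0, 1)
  starts_true <- seq_len(n) * spacing
  starts_ctrl <- (n + seq_len(n)) * spacing
  ## per-match shared Bernoulli state lifts both halves together
  state <- rbinom(n, 1, 0.5)
  for (i in seq_len(n)) {
    lift <- state[i] * 3
    score[starts_true[i]:(starts_true[i] + width - 1L)] <-
      rnorm(width, lift, 0.8)
  }
  track <- conservation_track(list(chrH = score))
  mk <- function(starts, nm) {
    gr <- GenomicRanges::GRanges("chrH", IRanges::IRanges(starts, width = width),
                                 strand = "+")
    S4Vectors::mcols(gr)$score <- 5
    S4Vectors::mcols(gr)$motif <- nm
    structure(list(matches = gr, score_threshold = 2, target_count = length(starts),
                   motif_name = nm, motif_length = width), class = "MatchSet")
  }
  res <- halfsite_correlation(mk(starts_true, "t"), mk(starts_ctrl, "c"),
                              track, half_split = 4L)
  expect_lt(res$q, 0.05)
  expect_true(res$significant)

  ## split at the boundary is rejected
  expect_error(halfsite_correlation(mk(starts_true, "t"), mk(starts_ctrl, "c"),
                                    track, half_split = 0L), "halves")
  expect_error(halfsite_correlation(mk(starts_true, "t"), mk(starts_ctrl, "c"),
                                    track, half_split = 8L), "halves")
})

test_that("spacing conservation counts pairs per gap/orientation cell exactly", {
  set.seed(46)
  width <- 6L
  ## A matches at fixed anchors; B matches at gap 5 on the + strand
  nA <- 120
  startsA <- seq_len(nA) * 50L
  startsB <- startsA + width + 5L
  len <- max(startsB) + 100L
  score <- rnorm(len, 0, 0.3)
  conserved_sites <- seq_len(nA) <= 60  # first half conserved pairs
  for (i in seq_len(nA)) if (conserved_sites[i]) {
    score[startsA[i]:(startsA[i] + width - 1L)] <- 3
    score[startsB[i]:(startsB[i] + width - 1L)] <- 3
  }
  track <- conservation_track(list(chrP = score))
  mk <- function(starts, nm, strand = "+") {
    gr <- GenomicRanges::GRanges("chrP", IRanges::IRanges(starts, width = width),
                                 strand = strand)
    S4Vectors::mcols(gr)$score <- 5
    S4Vectors::mcols(gr)$motif <- nm
    structure(list(matches = gr, score_threshold = 2, target_count = length(starts),
                   motif_name = nm, motif_length = width), class = "MatchSet")
  }
  mA <- mk(startsA, "A"); mB <- mk(startsB, "B")
  ## controls: B-like matches at shuffled positions (not conserved-paired)
  set.seed(47)
  ctrls <- lapply(1:6, function(i) mk(sample(200:(len - 50), nA), sprintf("c%d", i)))
  res <- spacing_conservation(mA, mB, track, thresholdA = 1, thresholdB = 1,
                              controlsB = ctrls, max_gap = 30)
  cell <- res[res$gap == 5 & res$orientation == "FF", ]
  expect_identical(cell$observed, 60L)
  expect_true(cell$significant)
  expect_true(all(res$observed[res$gap != 5] == 0L))

  ## brute-force pair enumeration oracle on the same match sets
  prs <- coopselex:::match_pairs_by_gap(mA$matches, mB$matches, 30L)
  expect_identical(nrow(prs), as.integer(nA))
  expect_true(all(prs$gap == 5L & prs$orientation == "FF"))
})
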