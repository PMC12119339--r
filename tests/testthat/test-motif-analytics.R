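test_that("gapped k-mer similarity is a bounded strand-symmetric metric", {
  m1 <- sharp_motif("ACGGATCC")
  expect_equal(gapped_kmer_similarity(m1, m1, k = 6, max_gap = 3), 1)
  expect_equal(gapped_kmer_similarity(m1, motif_revcomp(m1), k = 6, max_gap = 3), 1)

  ## disjoint sharp consensi share almost nothing
  m2 <- sharp_motif("AAAAAAAA"); m3 <- sharp_motif("CCCCCCCC")
  expect_lt(gapped_kmer_similarity(m2, m3, k = 10, max_gap = 5), 0.01)

  ## symmetry and bounds over random motif pairs
  set.seed(30)
  for (i in 1:5) {
    a <- freq_motif(matrix(prop.table(matrix(runif(4 * 7), 4), 2), 4))
    b <- freq_motif(matrix(prop.table(matrix(runif(4 * 9), 4), 2), 4))
    s1 <- gapped_kmer_similarity(a, b, k = 5, max_gap = 2)
    s2 <- gapped_kmer_similarity(b, a, k = 5, max_gap = 2)
    expect_equal(s1, s2, tolerance = 1e-9)
    expect_gte(s1, 0); expect_lte(s1, 1)
  }
})

test_that("closed-form gapped similarity equals brute-force enumeration", {
  ## oracle: enumerate every gapped word and placement explicitly
  oracle_vec <- function(m, k, max_gap) {
    f <- motif_freq(m); L <- ncol(f)
    colx <- function(x) if (x >= 1 && x <= L) f[, x] else rep(0.25, 4)
    configs <- list(0:(k - 1))
    for (g in seq_len(max_gap)) for (t in seq_len(k - 1))
      configs[[length(configs) + 1]] <- c(0:(t - 1), (t + g):(k + g - 1))
    feats <- list()
    for (ci in seq_along(configs)) {
      D <- configs[[ci]]
      s <- max(D) + 1
      words <- expand.grid(rep(list(1:4), k))
      probs <- numeric(nrow(words))
      for (i in (2 - s):L) {
        pw <- rep(1, nrow(words))
        for (d in seq_along(D)) pw <- pw * colx(i + D[d])[words[[d]]]
        probs <- probs + pw
      }
      feats[[ci]] <- probs
    }
    unlist(feats)
  }
  set.seed(31)
  a <- freq_motif(matrix(prop.table(matrix(runif(4 * 5), 4), 2), 4))
  b <- freq_motif(matrix(prop.table(matrix(runif(4 * 6), 4), 2), 4))
  k <- 3; mg <- 2
  va <- (oracle_vec(a, k, mg) + oracle_vec(motif_revcomp(a), k, mg)) / 2
  vb <- (oracle_vec(b, k, mg) + oracle_vec(motif_revcomp(b), k, mg)) / 2
  want <- sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
  got <- gapped_kmer_similarity(a, b, k = k, max_gap = mg)
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("motif alignment recovers embeddings, orientation and the oracle optimum", {
  mono <- sharp_motif("ACGTGA")
  ## composite = uniform padding + monomer + padding
  pad <- matrix(25, 4, 3)
  comp <- motif(cbind(pad, mono$counts * 25 / 97 * 4, pad), name = "emb")
  al <- align_motifs(mono, comp)
  expect_identical(al$offset, 3L)
  expect_identical(al$orientation, "same")
  expect_identical(al$comp_cols, 4:9)

  ## revcomp-embedded monomer aligns in revcomp orientation
  rcc <- motif(cbind(pad, motif_revcomp(mono)$counts, pad), name = "embrc")
  alr <- align_motifs(mono, rcc)
  expect_identical(alr$orientation, "revcomp")
  expect_identical(alr$comp_cols, 4:9)

  ## exhaustive-offset oracle on random motif pairs
  set.seed(32)
  for (i in 1:5) {
    mo <- freq_motif(matrix(prop.table(matrix(runif(4 * 5), 4), 2), 4))
    co <- freq_motif(matrix(prop.table(matrix(runif(4 * 9), 4), 2), 4))
    al <- align_motifs(mo, co)
    best <- -Inf
    for (ori in c("same", "revcomp")) {
      fm <- if (ori == "same") motif_freq(mo) else motif_freq(motif_revcomp(mo))
      fc <- motif_freq(co)
      for (s in -4:8) {
        j <- which(s + 1:5 >= 1 & s + 1:5 <= 9)
        if (length(j) < 4) next
        sc <- sum(1 - coopselex:::jsd_columns(fm[, j, drop = FALSE],
                                              fc[, s + j, drop = FALSE]))
        best <- max(best, sc)
      }
    }
    expect_equal(al$score, best, tolerance = 1e-9)
  }
  expect_error(align_motifs(mono, sharp_motif("ACG")), "overlap")
})

test_that("core/flank divergence applies the JSD and Jaccard rules", {
  mono <- sharp_motif("ACGTGACC")
  pad <- matrix(25, 4, 2)
  comp <- motif(cbind(pad, mono$counts, pad), name = "comp")
  rep0 <- core_flank_divergence(comp, mono, mono)
  expect_true(rep0$analysable)
  expect_lt(max(rep0$jsd_total_bits), 0.05)   # identical sections
  expect_equal(unname(rep0$jaccard), c(1, 1), tolerance = 1e-12)
  expect_false(rep0$distinct_by_jsd)
  expect_false(rep0$distinct_by_jaccard)

  ## per-column JSD of (1,0,0,0) vs (0,1,0,0) is exactly 1 bit
  p <- matrix(c(1, 0, 0, 0), 4, 1); q <- matrix(c(0, 1, 0, 0), 4, 1)
  expect_equal(unname(coopselex:::jsd_columns(p, q)), 1)

  ## random sections: Jaccard equals brute-force 4^len enumeration
  set.seed(33)
  co <- prop.table(matrix(runif(4 * 6), 4), 2)
  tf <- prop.table(matrix(runif(4 * 6), 4), 2)
  top_oracle <- function(f) {
    words <- expand.grid(rep(list(1:4), 6))
    sc <- rep(1, nrow(words))
    code <- rep(1, nrow(words))
    for (j in 1:6) {
      sc <- sc * f[cbind(words[[j]], j)]
      code <- code + (words[[j]] - 1) * 4^(6 - j)
    }
    code[sc >= 0.9 * max(sc)]
  }
  s_co <- coopselex:::section_kmer_scores(co)
  expect_setequal(which(s_co >= 0.9 * max(s_co)), top_oracle(co))
  s_tf <- coopselex:::section_kmer_scores(tf)
  expect_setequal(which(s_tf >= 0.9 * max(s_tf)), top_oracle(tf))
})

test_that("consensus score differential is zero for embedded consensi", {
  mono <- sharp_motif("ACGTGA")
  pad <- matrix(25, 4, 3)
  comp <- motif(cbind(pad, mono$counts, pad), name = "c")
  d <- consensus_score_differential(mono, comp)
  expect_equal(unname(d["score_own"]), unname(d["score_on_composite"]))

  ## uniform monomer scores every sequence identically
  uni <- motif(matrix(25, 4, 5), name = "uniform")
  du <- consensus_score_differential(uni, comp)
  expect_equal(unname(du["differential"]), 0)

  ## two mismatches cost exactly the summed per-position penalties
  ## (two-column toy where both strand readings are equally penalised)
  toy <- planted_motif("AC", 0.97, name = "toy")
  lo2 <- motif_logodds(toy)
  comp2 <- planted_motif("TG", 0.97, name = "target")
  dm <- consensus_score_differential(toy, comp2)
  pen <- (lo2["A", 1] - lo2["T", 1]) + (lo2["C", 2] - lo2["G", 2])
  expect_equal(unname(dm["differential"]), unname(pen), tolerance = 1e-9)
})

test_that("dominating sets are minimum and valid", {
  ## edgeless network: every node is its own representative
  ds <- dominating_set(similarity = diag(1, 5))
  expect_identical(ds$representatives, 1:5)

  ## star network: the hub alone dominates
  sim <- diag(1, 6)
  sim[1, 2:6] <- sim[2:6, 1] <- 0.9
  ds2 <- dominating_set(similarity = sim, threshold = 0.5)
  expect_identical(ds2$representatives, 1L)

  ## exact solver equals brute-force minimum on random graphs <= 12 nodes
  set.seed(34)
  for (i in 1:12) {
    n <- sample(4:12, 1)
    adj <- matrix(runif(n * n) < 0.3, n, n)
    adj <- adj | t(adj); diag(adj) <- FALSE
    sim <- ifelse(adj, 1, 0); diag(sim) <- 1
    ds <- dominating_set(similarity = sim, threshold = 0.5)
    expect_identical(ds$mode, "exact")
    expect_identical(length(ds$representatives), oracle_min_domset_size(adj))
    ## validity
    closed <- adj | diag(TRUE, n)
    expect_true(all(apply(closed[, ds$representatives, drop = FALSE], 1, any)))
  }

  ## greedy mode engages above the exact limit and stays valid
  n <- 30
  set.seed(35)
  adj <- matrix(runif(n * n) < 0.15, n, n); adj <- adj | t(adj); diag(adj) <- FALSE
  sim <- ifelse(adj, 1, 0); diag(sim) <- 1
  dg <- dominating_set(similarity = sim, threshold = 0.5, exact_limit = 10)
  expect_identical(dg$mode, "greedy")
  closed <- adj | diag(TRUE, n)
  expect_true(all(apply(closed[, dg$representatives, drop = FALSE], 1, any)))
})

test_that("saturation fits recover exact models and extrapolate monotonely", {
  ## curve generated exactly from p = 2 sqrt(N): fit recovers A=2, B=0
  curve <- data.frame(N = c(100, 400, 900, 1600), clusters = 2 * sqrt(c(100, 400, 900, 1600)))
  fit <- sqrt_extrapolate(curve, 10000)
  expect_equal(fit$A, 2, tolerance = 1e-6)
  expect_equal(fit$B, 0, tolerance = 1e-6)
  expect_equal(fit$estimate_total_clusters, 200, tolerance = 1e-6)

  ## subsampled discovery curves rise and full-N extrapolation bounds the
  ## observed cluster count from above (concavity), over seeds
  for (s in 1:10) {
    set.seed(s)
    C <- 40
    pairs <- sample(c(seq_len(C), rep(NA, 460)), 500)  # 40 clusters, sparse hits
    cur <- discovery_curve(pairs, n_subsamples = 40, seed = s)
    expect_true(all(diff(cur$clusters) > -0.5))   # rising up to subsample noise
    expect_gt(cur$clusters[nrow(cur)], cur$clusters[1])
    fit <- sqrt_extrapolate(cur, 2 * length(pairs))
    expect_gte(fit$estimate_total_clusters + 1e-6, max(cur$clusters))
  }

  ## linear bound through two anchors
  cur2 <- data.frame(N = c(10, 100, 1000), clusters = c(5, 20, 40))
  lb <- linear_lower_bound(cur2, 4000, anchor = 100)
  expect_equal(lb, 40 + (40 - 20) / 900 * 3000)
  expect_error(sqrt_extrapolate(cur2, 500), "smaller")
})

test_that("ward cluster counts span the threshold grid", {
  set.seed(36)
  sim <- diag(1, 8)
  sim[1:4, 1:4] <- 0.9; sim[5:8, 5:8] <- 0.9; diag(sim) <- 1
  cc <- ward_cluster_counts(sim, thresholds = c(0.05, 0.5, 2))
  expect_identical(names(cc), c("threshold", "clusters"))
  expect_true(all(diff(cc$clusters) <= 0))  # higher cut, fewer clusters
  expect_identical(cc$clusters[1], 8)       # tiny cut: all singletons
  expect_lte(cc$clusters[3], 2)
})

test_that("screen bookkeeping helpers do the published arithmetic", {
  expect_equal(tf_pair_count(4), 6)
  expect_equal(tf_pair_count(4, include_self = TRUE), 10)
  expect_equal(interaction_rate(5, 100), 0.05)
  expect_equal(extrapolated_interactions(0.05, 1000), 50)
  cs <- motif_collection_summary()
  expect_identical(cs$total, cs$new + cs$prior)
})
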