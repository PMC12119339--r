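#' Discovery-saturation curve by subsampling
#'
#' Subsamples the tested TF pairs (without replacement) at a grid of
#' sample sizes and records the mean number of distinct motif clusters
#' discovered, averaged over repeated subsamples.
#'
#' @param pair_to_cluster vector mapping each tested TF pair to its
#'   motif cluster id (pairs that yielded no motif are `NA` and count as
#'   discovering nothing).
#' @param n_subsamples subsamples per grid point (default 300).
#' @param grid sample sizes; defaults to 15 points spanning the data.
#' @param seed RNG seed (optional).
#' @return data.frame with `N` (pairs sampled) and `clusters` (mean
#'   distinct clusters discovered).
#' @export
discovery_curve <- function(pair_to_cluster, n_subsamples = 300L,
                            grid = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  N <- length(pair_to_cluster)
  if (is.null(grid))
    grid <- unique(pmax(2L, round(seq(sqrt(N / 15), sqrt(N), length.out = 15L)^2)))
  if (length(grid) < 2L) stop("need at least 2 distinct curve points")
  cl <- as.vector(pair_to_cluster)
  means <- vapply(grid, function(ns) {
    mean(vapply(seq_len(n_subsamples), function(i) {
      s <- cl[sample.int(N, ns)]
      length(unique(s[!is.na(s)]))
    }, numeric(1)))
  }, numeric(1))
  data.frame(N = grid, clusters = means)
}

#' Square-root saturation model
#'
#' Fits `p = A * sqrt(N) + B` to a discovery curve by least squares and
#' extrapolates the total number of clusters at the full pair count.
#'
#' @param curve data.frame from [discovery_curve()].
#' @param N_total number of all possible TF pairs.
#' @return An object of class `SaturationFit`: `A`, `B`, `N_total`,
#'   `estimate_total_clusters`, `curve`.
#' @export
sqrt_extrapolate <- function(curve, N_total) {
  if (nrow(curve) < 2L) stop("need at least 2 curve points")
  if (N_total < max(curve$N)) stop("N_total smaller than the largest curve point")
  fit <- stats::lm(clusters ~ sqrt(N), data = curve)
  A <- unname(stats::coef(fit)[2L]); B <- unname(stats::coef(fit)[1L])
  structure(list(A = A, B = B, N_total = N_total,
                 estimate_total_clusters = saturation_estimate(A, B, N_total),
                 curve = curve),
            class = "SaturationFit")
}

#' @rdname sqrt_extrapolate
#' @param A,B coefficients of the square-root model.
#' @param N number of pairs at which to evaluate the model.
#' @export
saturation_estimate <- function(A, B, N) A * sqrt(N) + B

#' @export
print.SaturationFit <- function(x, ...) {
  cat(sprintf("SaturationFit: p = %.4g * sqrt(N) %+.4g\n", x$A, x$B))
  cat(sprintf("  extrapolated clusters at N = %s: %.1f\n",
              format(x$N_total, big.mark = ","), x$estimate_total_clusters))
  invisible(x)
}

#' Linear lower bound on the saturation curve
#'
#' Draws a line through two anchor points of the discovery curve (the
#' point nearest `anchor` pairs and the last point) and evaluates it at
#' the full pair count. Because the discovery curve is concave, the line
#' lies above it, making the implied discovered fraction a lower bound.
#'
#' @param curve data.frame from [discovery_curve()].
#' @param N_total number of all possible TF pairs.
#' @param anchor pair count of the first anchor (default 50000).
#' @return the linear extrapolation of the cluster count at `N_total`.
#' @export
linear_lower_bound <- function(curve, N_total, anchor = 50000) {
  if (nrow(curve) < 2L) stop("need at least 2 curve points")
  i1 <- which.min(abs(curve$N - anchor))
  i2 <- nrow(curve)
  if (i1 == i2) i1 <- i2 - 1L
  slope <- (curve$clusters[i2] - curve$clusters[i1]) /
    (curve$N[i2] - curve$N[i1])
  curve$clusters[i2] + slope * (N_total - curve$N[i2])
}

#' Cluster counts across a similarity-threshold grid
#'
#' Ward clustering of motifs at distance `1 - s`, reporting the number
#' of clusters at each threshold of a grid (default 0.98 to 1.02 by
#' 0.001, the region where cluster counts change quickly for gapped
#' k-mer similarities).
#'
#' @param similarity symmetric motif similarity matrix.
#' @param thresholds cut heights on the `1 - s` dendrogram scale.
#' @return data.frame with `threshold` and `clusters`.
#' @export
ward_cluster_counts <- function(similarity,
                                thresholds = seq(0.98, 1.02, by = 0.001)) {
  d <- stats::as.dist(1 - similarity)
  hc <- stats::hclust(d, method = "ward.D2")
  data.frame(threshold = thresholds,
             clusters = vapply(thresholds, function(h)
               max(stats::cutree(hc, h = h)), numeric(1)))
}

#' TF pair counts and screen-rate arithmetic
#'
#' Small helpers for the screen bookkeeping: the number of TF pairs
#' formable from `n_tf` factors (optionally counting self-pairs), the
#' specific interaction rate of a screen, and its genome-wide
#' extrapolation.
#'
#' @param n_tf number of transcription factors.
#' @param include_self count homotypic pairs.
#' @return `tf_pair_count`: the pair count.
#' @export
tf_pair_count <- function(n_tf, include_self = FALSE) {
  if (include_self) n_tf * (n_tf + 1) / 2 else n_tf * (n_tf - 1) / 2
}

#' @rdname tf_pair_count
#' @param n_interacting number of interacting pairs found.
#' @param n_tested number of pairs screened.
#' @return `interaction_rate`: fraction of tested pairs that interact.
#' @export
interaction_rate <- function(n_interacting, n_tested) n_interacting / n_tested

#' @rdname tf_pair_count
#' @param rate specific interaction rate (fraction).
#' @param n_pairs number of pairs to extrapolate over.
#' @return `extrapolated_interactions`: expected interacting pairs.
#' @export
extrapolated_interactions <- function(rate, n_pairs) rate * n_pairs

#' Motif collection bookkeeping
#'
#' Summarises a motif-collection category table (columns `set` --
#' `"new"` or `"prior"` -- `category` and `count`). The package ships
#' the published SELEX collection categories as
#' `system.file("extdata", "motif_collection_counts.tsv")`.
#'
#' @param path category table; defaults to the shipped table.
#' @return list with `new`, `prior`, `total` motif counts and the table.
#' @export
motif_collection_summary <- function(path = system.file(
    "extdata", "motif_collection_counts.tsv", package = "coopselex")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("set", "category", "count") %in% names(tab)))
  new <- sum(tab$count[tab$set == "new"])
  prior <- sum(tab$count[tab$set == "prior"])
  list(new = new, prior = prior, total = new + prior, table = tab)
}
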