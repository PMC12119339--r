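#' Genomic region sets and conservation tracks
#'
#' Region sets are plain [GenomicRanges::GRanges] objects. BED input is
#' 0-based half-open and converted to the 1-based closed GRanges
#' convention on load; writing converts back, so round-trips are exact.
#'
#' @param path BED3/BED4 file.
#' @return A `GRanges`; a fourth BED column, when present, becomes the
#'   `name` metadata column.
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !grepl("^(#|track|browser)", lines)
  idx <- which(keep)
  if (!length(idx)) stop("no intervals in ", path)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("malformed BED line ", idx[which(nf < 3L)[1L]], ": fewer than 3 fields")
  chrom <- vapply(fields, `[`, character(1), 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3L)))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad)) stop("malformed BED line ", idx[bad[1L]], ": non-numeric coordinates")
  bad <- which(start0 >= end0)
  if (length(bad))
    stop("malformed BED line ", idx[bad[1L]], ": start >= end")
  gr <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(start = start0 + 1L, end = end0))
  if (all(nf >= 4L))
    S4Vectors::mcols(gr)$name <- vapply(fields, `[`, character(1), 4L)
  gr
}

#' @rdname read_regions
#' @param gr a `GRanges`.
#' @export
write_regions <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  if (!is.null(S4Vectors::mcols(gr)$name)) df$name <- S4Vectors::mcols(gr)$name
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Per-base conservation tracks
#'
#' Loads a bedGraph of per-base (phyloP-like, signed) scores plus an
#' optional BED mask of constrained bases. Overlapping bedGraph intervals
#' are rejected with the offending line number. Scores are expanded to
#' per-base run-length vectors keyed by sequence id; positions without a
#' score are `NA`.
#'
#' @param scores_path bedGraph file of per-base scores.
#' @param mask_path optional BED file of constrained bases.
#' @param score_threshold metadata only: the constrained-base score
#'   convention associated with the mask (e.g. phyloP >= 2.27).
#' @return An object of class `ConservationTrack` with elements `score`
#'   (named list of [S4Vectors::Rle], 1-based), `mask` (`GRanges` or
#'   `NULL`) and `score_threshold`.
#' @export
read_conservation <- function(scores_path, mask_path = NULL,
                              score_threshold = NA_real_) {
  if (!file.exists(scores_path)) stop("file not found: ", scores_path)
  lines <- readLines(scores_path)
  keep <- nzchar(trimws(lines)) & !grepl("^(#|track|browser)", lines)
  idx <- which(keep)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4L))
    stop("malformed bedGraph line ", idx[which(nf < 4L)[1L]], ": fewer than 4 fields")
  chrom <- vapply(fields, `[`, character(1), 1L)
  start0 <- as.numeric(vapply(fields, `[`, character(1), 2L))
  end0 <- as.numeric(vapply(fields, `[`, character(1), 3L))
  val <- as.numeric(vapply(fields, `[`, character(1), 4L))
  bad <- which(is.na(start0) | is.na(end0) | is.na(val) | start0 >= end0)
  if (length(bad)) stop("malformed bedGraph line ", idx[bad[1L]])
  score <- list()
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    ord <- sel[order(start0[sel])]
    over <- which(start0[ord][-1L] < end0[ord][-length(ord)])
    if (length(over))
      stop("overlapping bedGraph intervals on ", ch, "; second interval at line ",
           idx[ord[over[1L] + 1L]])
    len <- max(end0[ord])
    v <- rep(NA_real_, len)
    for (i in ord) v[(start0[i] + 1L):end0[i]] <- val[i]
    score[[ch]] <- S4Vectors::Rle(v)
  }
  mask <- if (!is.null(mask_path)) read_regions(mask_path) else NULL
  structure(list(score = score, mask = mask, score_threshold = score_threshold),
            class = "ConservationTrack")
}

#' @rdname read_conservation
#' @param score_list named list of per-base numeric score vectors
#'   (1-based), one per sequence id.
#' @param mask optional `GRanges` of constrained bases.
#' @export
conservation_track <- function(score_list, mask = NULL, score_threshold = NA_real_) {
  structure(list(score = lapply(score_list, S4Vectors::Rle), mask = mask,
                 score_threshold = score_threshold),
            class = "ConservationTrack")
}

#' @export
print.ConservationTrack <- function(x, ...) {
  cat(sprintf("ConservationTrack: %d sequence(s), %s masked interval(s)\n",
              length(x$score),
              if (is.null(x$mask)) "no" else length(x$mask)))
  invisible(x)
}

#' Mean per-base score over intervals
#'
#' @param track a `ConservationTrack`.
#' @param gr a `GRanges` of intervals (1-based closed, as returned by the
#'   scanners).
#' @return numeric vector of per-interval means; `NA` where any base
#'   lacks a score or the sequence is absent from the track.
#' @export
track_mean_score <- function(track, gr) {
  chrom <- as.character(GenomicRanges::seqnames(gr))
  starts <- GenomicRanges::start(gr)
  ends <- GenomicRanges::end(gr)
  out <- rep(NA_real_, length(gr))
  for (ch in unique(chrom)) {
    v <- track$score[[ch]]
    if (is.null(v)) next
    i <- which(chrom == ch & ends <= length(v) & starts >= 1L)
    if (!length(i)) next
    out[i] <- IRanges::viewMeans(
      IRanges::Views(v, start = starts[i], end = ends[i]), na.rm = FALSE)
  }
  out
}

## per-base score matrix (n_intervals x width); intervals must share width
track_score_matrix <- function(track, gr) {
  w <- unique(GenomicRanges::width(gr))
  if (length(w) != 1L) stop("intervals must share a common width")
  chrom <- as.character(GenomicRanges::seqnames(gr))
  starts <- GenomicRanges::start(gr)
  out <- matrix(NA_real_, nrow = length(gr), ncol = w)
  for (i in seq_along(gr)) {
    v <- track$score[[chrom[i]]]
    if (is.null(v) || starts[i] + w - 1L > length(v)) next
    out[i, ] <- as.numeric(S4Vectors::window(v, starts[i], starts[i] + w - 1L))
  }
  out
}
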