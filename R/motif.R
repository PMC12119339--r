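#' Binding motifs as position count matrices
#'
#' A `Motif` wraps a 4 x L matrix of non-negative (possibly fractional,
#' e.g. background-corrected) base counts with rows A, C, G, T, plus
#' optional metadata: the IUPAC seed it was built from, the multinomial
#' level of the counting model, and a class label (`"monomer"`,
#' `"composite"`, `"spacing"` or `"control"`).
#'
#' @param counts 4 x L numeric matrix (rows A, C, G, T in that order, or
#'   named).
#' @param name motif name.
#' @param seed IUPAC seed string, or `NULL`.
#' @param multinomial_level 1, 2 or `NULL`.
#' @param motif_class one of `"monomer"`, `"composite"`, `"spacing"`,
#'   `"control"`, or `NULL`.
#' @return An object of class `Motif`.
#' @export
motif <- function(counts, name = "motif", seed = NULL,
                  multinomial_level = NULL, motif_class = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("count matrix must have 4 rows (A, C, G, T)")
  if (ncol(counts) < 1L) stop("motif must have at least one column")
  if (any(counts < 0)) stop("negative counts in motif")
  if (!is.null(rownames(counts))) {
    if (!setequal(rownames(counts), DNA_BASES))
      stop("count matrix rows must be labelled A, C, G, T")
    counts <- counts[DNA_BASES, , drop = FALSE]
  } else rownames(counts) <- DNA_BASES
  if (any(colSums(counts) <= 0)) stop("every motif column must have positive total count")
  if (!is.null(motif_class))
    motif_class <- match.arg(motif_class, c("monomer", "composite", "spacing", "control"))
  structure(list(counts = counts, name = name, seed = seed,
                 multinomial_level = multinomial_level,
                 motif_class = motif_class),
            class = "Motif")
}

#' @export
print.Motif <- function(x, ...) {
  cat(sprintf("Motif '%s' (%d bp%s%s): consensus %s\n", x$name,
              motif_length(x),
              if (!is.null(x$motif_class)) paste0(", ", x$motif_class) else "",
              if (!is.null(x$seed)) paste0(", seed ", x$seed) else "",
              motif_consensus(x)))
  print(round(x$counts, 2))
  invisible(x)
}

#' @rdname motif
#' @param m a `Motif`.
#' @export
motif_length <- function(m) ncol(m$counts)

#' Frequency view of a motif
#'
#' Per-column base frequencies (columns sum to one).
#'
#' @param m a `Motif`.
#' @param pseudocount added to every cell before normalisation.
#' @return 4 x L numeric matrix.
#' @export
motif_freq <- function(m, pseudocount = 0) {
  cm <- m$counts + pseudocount
  sweep(cm, 2L, colSums(cm), "/")
}

#' Log-odds view of a motif
#'
#' Natural-log odds of the (pseudocounted) base frequencies against a
#' background base composition; the scale used for genomic scanning.
#'
#' @param m a `Motif`.
#' @param background length-4 background base distribution (A, C, G, T).
#' @param pseudocount fraction of each column total added per cell.
#' @return 4 x L numeric matrix of natural-log odds.
#' @export
motif_logodds <- function(m, background = rep(0.25, 4), pseudocount = 0.01) {
  cm <- m$counts
  cm <- cm + pseudocount * rep(colSums(cm), each = 4L)
  f <- sweep(cm, 2L, colSums(cm), "/")
  log(f / background)
}

#' @rdname motif
#' @export
motif_consensus <- function(m) {
  paste(DNA_BASES[apply(m$counts, 2L, which.max)], collapse = "")
}

#' @rdname motif
#' @export
motif_revcomp <- function(m) {
  rc <- m$counts[4:1, rev(seq_len(ncol(m$counts))), drop = FALSE]
  rownames(rc) <- DNA_BASES
  motif(rc, name = paste0(m$name, "_rc"), seed = m$seed,
        multinomial_level = m$multinomial_level, motif_class = m$motif_class)
}

#' Read a position count matrix
#'
#' Accepts two dialects, auto-detected per line: a 4-row tab-separated
#' matrix (optionally with a leading A/C/G/T row label) and the
#' JASPAR-style bracket format `A [ 10 0 ... ]`. Comment/header lines
#' starting with `>` or `#` are skipped.
#'
#' @param path input file.
#' @param name motif name; defaults to the file name or the `>` header.
#' @return A `Motif`.
#' @export
read_count_matrix <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  header <- grep("^>", lines, value = TRUE)
  if (is.null(name))
    name <- if (length(header)) sub("^>\\s*", "", header[1L]) else basename(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^[>#]", lines)]
  if (length(lines) != 4L) stop("expected 4 data rows, found ", length(lines))
  rows <- vector("list", 4L)
  labels <- character(4L)
  for (i in seq_len(4L)) {
    ln <- trimws(lines[i])
    if (grepl("^[ACGT]\\s*\\[", ln)) {  # JASPAR bracket dialect
      labels[i] <- substr(ln, 1L, 1L)
      ln <- sub("^[ACGT]\\s*\\[", "", ln)
      ln <- sub("\\]\\s*$", "", ln)
    } else if (grepl("^[ACGT]([ \t:]|$)", ln)) {
      labels[i] <- substr(ln, 1L, 1L)
      ln <- sub("^[ACGT][ \t:]*", "", ln)
    }
    vals <- suppressWarnings(as.numeric(strsplit(trimws(ln), "[ \t,]+")[[1L]]))
    if (anyNA(vals)) stop("malformed count row ", i, " in ", path)
    rows[[i]] <- vals
  }
  lens <- lengths(rows)
  if (length(unique(lens)) != 1L)
    stop("row-length mismatch: rows have ", paste(lens, collapse = ", "), " columns")
  counts <- do.call(rbind, rows)
  rownames(counts) <- if (all(nzchar(labels))) labels else DNA_BASES
  motif(counts, name = name)
}

#' Write a position count matrix
#'
#' Writes the labelled 4-row tab-separated dialect with values at 6
#' significant digits; `read_count_matrix()` recovers the motif.
#'
#' @param m a `Motif`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(m, path) {
  stopifnot(inherits(m, "Motif"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", m$name), con)
  for (b in DNA_BASES)
    writeLines(paste(c(b, formatC(m$counts[b, ], digits = 6, format = "g")),
                     collapse = "\t"), con)
  invisible(path)
}
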