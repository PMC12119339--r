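#' SELEX read pools
#'
#' A `ReadPool` holds the equal-length DNA reads of one SELEX selection
#' cycle. Reads containing characters outside A/C/G/T, or whose length
#' differs from the modal read length, are dropped at construction and
#' tallied in the attached load report.
#'
#' @param reads character vector of DNA reads.
#' @param cycle non-negative integer selection cycle index (0 = input
#'   library).
#' @param label free-text label for the pool.
#' @return An object of class `ReadPool` with elements `reads`,
#'   `read_length`, `cycle`, `label` and `load_report` (counts of reads
#'   kept, dropped for alphabet, dropped for length).
#' @export
read_pool_from_reads <- function(reads, cycle = 0L, label = "") {
  if (length(reads) == 0L) stop("no reads supplied")
  if (cycle < 0) stop("cycle must be >= 0")
  reads <- toupper(reads)
  ok_alpha <- !grepl("[^ACGT]", reads)
  n_bad_alpha <- sum(!ok_alpha)
  reads <- reads[ok_alpha]
  if (length(reads) == 0L) stop("zero reads retained (all contained non-ACGT characters)")
  len <- nchar(reads)
  modal_len <- as.integer(names(which.max(table(len))))
  n_bad_len <- sum(len != modal_len)
  reads <- reads[len == modal_len]
  structure(list(
    reads = reads,
    read_length = modal_len,
    cycle = as.integer(cycle),
    label = label,
    load_report = c(kept = length(reads), dropped_alphabet = n_bad_alpha,
                    dropped_length = n_bad_len)
  ), class = "ReadPool")
}

#' Read a SELEX pool from disk
#'
#' Supported formats: FASTA, FASTQ (read via Biostrings) and plain text
#' with one read per line. Filtering rules are those of
#' [read_pool_from_reads()].
#'
#' @param path input file.
#' @param format one of `"txt"`, `"fasta"`, `"fastq"`; `"auto"` guesses
#'   from the file extension and first character.
#' @param cycle selection cycle the file holds.
#' @param label pool label; defaults to the file name.
#' @return A `ReadPool`.
#' @export
read_pool <- function(path, format = c("auto", "txt", "fasta", "fastq"),
                      cycle = 0L, label = basename(path)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("fa", "fasta", "fna")) "fasta"
      else if (ext %in% c("fq", "fastq")) "fastq"
      else {
        first <- substr(readLines(path, n = 1L), 1L, 1L)
        if (identical(first, ">")) "fasta" else if (identical(first, "@")) "fastq" else "txt"
      }
  }
  reads <- switch(format,
    txt = {
      lines <- readLines(path)
      lines[nzchar(lines)]
    },
    fasta = as.character(Biostrings::readDNAStringSet(path)),
    fastq = as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
  )
  names(reads) <- NULL
  read_pool_from_reads(reads, cycle = cycle, label = label)
}

#' Write a pool as plain one-read-per-line text
#'
#' @param pool a `ReadPool`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pool <- function(pool, path) {
  stopifnot(inherits(pool, "ReadPool"))
  writeLines(pool$reads, path)
  invisible(path)
}

#' @export
print.ReadPool <- function(x, ...) {
  cat(sprintf("ReadPool '%s': %d reads of %d bp, cycle %d\n",
              x$label, length(x$reads), x$read_length, x$cycle))
  rep <- x$load_report
  if (any(rep[-1L] > 0))
    cat(sprintf("  load report: %d dropped (alphabet), %d dropped (length)\n",
                rep[["dropped_alphabet"]], rep[["dropped_length"]]))
  invisible(x)
}

## cached integer encoding of a pool
pool_matrix <- function(pool) {
  seq_int_matrix(pool$reads)
}
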