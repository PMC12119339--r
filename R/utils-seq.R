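## Low-level DNA sequence utilities shared by all modules.
## Reads are held as plain character vectors over {A,C,G,T}; hot paths
## convert them once to an integer matrix (A=1, C=2, G=3, T=4).

DNA_BASES <- c("A", "C", "G", "T")

## IUPAC degeneracy code: symbol -> base set
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

## base set (sorted) -> IUPAC symbol
iupac_symbol <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  sym <- names(IUPAC_SETS)[vapply(IUPAC_SETS, function(s)
    paste(sort(s), collapse = "") == key, logical(1))]
  if (length(sym) != 1L) stop("no IUPAC symbol for base set: ", key)
  sym
}

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement for plain character DNA (IUPAC symbols
#' supported).
#'
#' @param x character vector of DNA strings.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

## Fast integer encoding: n x L matrix, A=1 C=2 G=3 T=4.
seq_int_matrix <- function(reads) {
  if (length(reads) == 0L) stop("no reads to encode")
  L <- nchar(reads[1L])
  codes <- utf8ToInt(paste(reads, collapse = ""))
  lut <- integer(128)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("C")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("T")] <- 4L
  m <- matrix(lut[codes], ncol = L, byrow = TRUE)
  if (any(m == 0L)) stop("non-ACGT character in reads")
  m
}

int_to_seq <- function(m) {
  do.call(paste0, lapply(seq_len(ncol(m)), function(j) DNA_BASES[m[, j]]))
}

## integer matrix -> reverse-complement integer matrix
int_revcomp <- function(m) {
  (5L - m)[, rev(seq_len(ncol(m))), drop = FALSE]
}

## k-mer integer codes (1-based, in 1..4^k) for every window start of an
## integer matrix; returns n x (L-k+1) matrix.
kmer_code_matrix <- function(m, k) {
  if (k > ncol(m)) stop("k exceeds read length")
  storage.mode(m) <- "integer"
  .cpp_kmer_codes(m, as.integer(k))
}

## decode integer codes (1..4^k) to k-mer strings
kmer_decode <- function(codes, k) {
  codes <- codes - 1
  chars <- matrix("", nrow = length(codes), ncol = k)
  for (j in k:1) {
    chars[, j] <- DNA_BASES[(codes %% 4) + 1]
    codes <- codes %/% 4
  }
  apply(chars, 1L, paste, collapse = "")
}

## encode k-mer strings to integer codes 1..4^k
kmer_encode <- function(kmers) {
  m <- seq_int_matrix(kmers)
  code <- 0
  for (j in seq_len(ncol(m))) code <- code * 4 + (m[, j] - 1L)
  code + 1
}

## code of the reverse complement of each code (k-mers)
kmer_code_revcomp <- function(codes, k) {
  codes <- codes - 1
  out <- 0
  for (j in seq_len(k)) {
    base <- codes %% 4  # iteration j extracts the base at position k-j+1
    out <- out + (3 - base) * 4^(k - j)  # its complement leads the revcomp
    codes <- codes %/% 4
  }
  out + 1
}
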