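#' @importFrom rlang %||% .data
#' @importFrom stats cor var sd predict rnorm rpois rbinom runif setNames
#' @importFrom utils head tail
NULL

RNA_ALPHABET <- c("A", "C", "G", "U")

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases, maps T to U, and validates that only A, C, G, U remain.
#' DNA input is therefore accepted transparently.
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector over \{A, C, G, U\}.
#' @examples
#' normalize_rna("attta")
#' @export
normalize_rna <- function(x) {
  if (!is.character(x)) stop("sequences must be character vectors", call. = FALSE)
  out <- chartr("T", "U", toupper(x))
  bad <- regexpr("[^ACGU]", out)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf(
      "invalid character '%s' at position %d of sequence %d",
      substr(out[i], bad[i], bad[i]), bad[i], i
    ), call. = FALSE)
  }
  out
}

#' Reverse complement of an RNA string (strict Watson-Crick)
#'
#' @param x Character vector over \{A, C, G, U\} (T accepted).
#' @return Reverse-complemented sequences.
#' @export
revcomp_rna <- function(x) {
  x <- normalize_rna(x)
  vapply(
    strsplit(chartr("ACGU", "UGCA", x), ""),
    function(ch) paste(rev(ch), collapse = ""),
    character(1)
  )
}

#' GC fraction of sequences
#'
#' @param x Character vector of nucleotide sequences.
#' @return Numeric vector in \[0, 1\]: (#G + #C) / length.
#' @export
gc_fraction <- function(x) {
  x <- normalize_rna(x)
  n <- nchar(x)
  gc <- nchar(gsub("[^GC]", "", x))
  ifelse(n == 0L, NA_real_, gc / n)
}

# Evaluate a polynomial sum(coefs[j] * x^(j-1)) at x.
polyval <- function(coefs, x) {
  out <- numeric(length(x))
  for (j in seq_along(coefs)) out <- out + coefs[j] * x^(j - 1)
  out
}

# The infinite periodic AUUUA pattern: P[i] = "A" iff i %% 4 == 0 else "U"
# (0-based i). Returns the substring P[g : g + len).
periodic_pattern <- function(g, len) {
  if (len <= 0L) return("")
  idx <- (g + seq_len(len) - 1L) %% 4L
  paste(ifelse(idx == 0L, "A", "U"), collapse = "")
}
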