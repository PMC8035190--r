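# Small sequence helpers shared across modules. All coordinates in the
# package are 0-based, half-open, on the top strand; nick positions are
# between-base offsets (a nick at k separates bases k-1 and k).

#' Reverse-complement nucleotide strings
#'
#' Vectorised over `x`; `N` is preserved.
#'
#' @param x Character vector of sequences over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", x))
}

#' Decode and encode Phred+33 quality strings
#'
#' @param qual A single quality string (Phred+33).
#' @return `phred_decode()` returns an integer vector of per-base scores;
#'   `phred_encode()` the inverse.
#' @export
phred_decode <- function(qual) {
  if (is.na(qual) || !nzchar(qual)) return(integer(0))
  utf8ToInt(qual) - 33L
}

#' @rdname phred_decode
#' @param q Integer vector of Phred scores.
#' @export
phred_encode <- function(q) {
  if (length(q) == 0) return("")
  intToUtf8(q + 33L)
}

#' Generate a random nucleotide sequence
#'
#' Draws uniformly over A/C/G/T using the current RNG state.
#'
#' @param n Length in bases.
#' @return A single string of length `n`.
#' @export
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# mean Phred per read, vectorised over quality strings
qual_stats <- function(qual) {
  qs <- lapply(qual, function(q) if (is.na(q) || !nzchar(q)) integer(0) else utf8ToInt(q) - 33L)
  tibble(
    mean_q = vapply(qs, function(v) if (length(v)) mean(v) else NA_real_, numeric(1)),
    min_q  = vapply(qs, function(v) if (length(v)) min(v) else NA_integer_, numeric(1))
  )
}

check_dna <- function(x, what = "sequence", allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    abort(sprintf("%s contains characters outside {A,C,G,T%s} (first offender: %s)",
                  what, if (allow_n) ",N" else "", x[which(bad)[1]]))
  }
  invisible(x)
}

# 0-based half-open substring
substr0 <- function(x, start, end) substr(x, start + 1L, end)

hamming <- function(a, b) {
  va <- utf8ToInt(a); vb <- utf8ToInt(b)
  if (length(va) != length(vb)) stop("hamming distance requires equal lengths")
  sum(va != vb)
}
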