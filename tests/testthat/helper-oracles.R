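# Independent oracles used by the alignment tests. Both are written without
# reference to the package's C++ implementation.

# Brute-force enumeration of every global alignment path, scoring affine gaps
# (a gap of length L costs gap_open + L * gap_extend). Exponential: only for
# tiny sequences.
oracle_enum_score <- function(q, r, match = 2, mismatch = -4,
                              gap_open = -8, gap_extend = -1) {
  n <- nchar(q); m <- nchar(r)
  qs <- strsplit(q, "")[[1]]; rs <- strsplit(r, "")[[1]]
  best <- -Inf
  rec <- function(i, j, last, acc) {
    if (i == n && j == m) {
      best <<- max(best, acc)
      return(invisible())
    }
    if (i < n && j < m) {
      s <- if (qs[i + 1] == rs[j + 1]) match else mismatch
      rec(i + 1, j + 1, "M", acc + s)
    }
    if (j < m) {
      cost <- gap_extend + if (last != "D") gap_open else 0
      rec(i, j + 1, "D", acc + cost)
    }
    if (i < n) {
      cost <- gap_extend + if (last != "I") gap_open else 0
      rec(i + 1, j, "I", acc + cost)
    }
  }
  rec(0L, 0L, "M", 0)
  best
}

# Plain-R Gotoh three-matrix DP, coded independently of src/align.cpp.
oracle_gotoh_score <- function(q, r, match = 2, mismatch = -4,
                               gap_open = -8, gap_extend = -1) {
  n <- nchar(q); m <- nchar(r)
  qs <- strsplit(q, "")[[1]]; rs <- strsplit(r, "")[[1]]
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); D <- matrix(NEG, n + 1, m + 1)
  I <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (j in seq_len(m)) D[1, j + 1] <- gap_open + j * gap_extend
  for (i in seq_len(n)) I[i + 1, 1] <- gap_open + i * gap_extend
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (qs[i] == rs[j]) match else mismatch
      M[i + 1, j + 1] <- s + max(M[i, j], D[i, j], I[i, j])
      D[i + 1, j + 1] <- max(M[i + 1, j] + gap_open + gap_extend,
                             D[i + 1, j] + gap_extend,
                             I[i + 1, j] + gap_open + gap_extend)
      I[i + 1, j + 1] <- max(M[i, j + 1] + gap_open + gap_extend,
                             D[i, j + 1] + gap_open + gap_extend,
                             I[i, j + 1] + gap_extend)
    }
  }
  max(M[n + 1, m + 1], D[n + 1, m + 1], I[n + 1, m + 1])
}

# all sequences of a given length over an alphabet
all_seqs <- function(len, alphabet = c("A", "C")) {
  if (len == 0) return(character(0))
  do.call(paste0, expand.grid(rep(list(alphabet), len), stringsAsFactors = FALSE))
}

# quick constructor for read tibbles
make_reads <- function(bases, qual = NULL, id_prefix = "r") {
  tibble::tibble(
    read_id = paste0(id_prefix, seq_along(bases)),
    bases = bases,
    qual = qual %||% strrep("I", nchar(bases)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
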