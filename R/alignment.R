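# Pairwise alignment engine: affine-gap global / fitting / local alignment of
# reads against short amplicon references, with deterministic tie-breaking
# (match/mismatch > deletion > insertion) and VCF-style left-normalized event
# extraction so that identical molecules always yield identical events.

#' Alignment scoring scheme
#'
#' Defaults favour one long contiguous indel over scattered gaps
#' (`gap_open` much larger than `gap_extend`), matching how contiguous
#' pegRNA-programmed deletions present in the data. A gap of length L scores
#' `gap_open + L * gap_extend`; `N` scores 0 against anything.
#'
#' @param match,mismatch,gap_open,gap_extend Integer scores.
#' @return A named list.
#' @export
scoring_scheme <- function(match = 2L, mismatch = -4L, gap_open = -8L, gap_extend = -1L) {
  list(match = as.integer(match), mismatch = as.integer(mismatch),
       gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend))
}

new_alignment <- function(raw, query, ref_len, mode, query_id, ref_name) {
  codes <- c("match", "mismatch", "deletion", "insertion")
  v <- raw$ops
  if (length(v)) {
    r <- rle(v)
    ops <- tibble(op = codes[r$values + 1L], length = r$lengths)
  } else {
    ops <- tibble(op = character(0), length = integer(0))
  }
  # attach inserted / consumed query segments per op
  qpos <- raw$query_start
  seqs <- character(nrow(ops))
  for (k in seq_len(nrow(ops))) {
    if (ops$op[k] %in% c("match", "mismatch", "insertion")) {
      seqs[k] <- substr0(query, qpos, qpos + ops$length[k])
      qpos <- qpos + ops$length[k]
    } else seqs[k] <- NA_character_
  }
  ops$seq <- seqs
  structure(list(query_id = query_id, ref_name = ref_name, mode = mode,
                 score = raw$score,
                 ref_start = raw$ref_start, ref_end = raw$ref_end,
                 query_start = raw$query_start, query_end = raw$query_end,
                 ops = ops, query = query, ref_len = ref_len),
            class = "pe_alignment")
}

#' Global, fitting and local pairwise alignment
#'
#' `align_global()` aligns both sequences end to end; with
#' `ref_free_ends = TRUE` it performs a fitting alignment (the read end to
#' end, reference ends free — the end-to-end read-alignment semantics used for
#' primer-anchored UDiTaS reads). `align_local()` returns the best local
#' alignment; the empty alignment (score 0) is allowed.
#'
#' @param query,ref Sequences over `{A,C,G,T,N}`; both non-empty.
#' @param scoring A [scoring_scheme()].
#' @param ref_free_ends Fitting mode flag (global only).
#' @param query_id,ref_name Optional labels carried into the result.
#' @return A `pe_alignment`: score, 0-based `ref_start`, and an `ops` tibble
#'   (`op` in match/mismatch/insertion/deletion, `length`, `seq`).
#' @export
align_global <- function(query, ref, scoring = scoring_scheme(),
                         ref_free_ends = FALSE, query_id = NA_character_,
                         ref_name = NA_character_) {
  check_dna(query, "query"); check_dna(ref, "ref")
  if (!nzchar(query) || !nzchar(ref)) abort("sequences must be non-empty")
  raw <- .align_cpp(query, ref, scoring$match, scoring$mismatch,
                    scoring$gap_open, scoring$gap_extend,
                    if (ref_free_ends) 1L else 0L)
  new_alignment(raw, query, nchar(ref), if (ref_free_ends) "glocal" else "global",
                query_id, ref_name)
}

#' @rdname align_global
#' @export
align_local <- function(query, ref, scoring = scoring_scheme(),
                        query_id = NA_character_, ref_name = NA_character_) {
  check_dna(query, "query"); check_dna(ref, "ref")
  if (!nzchar(query) || !nzchar(ref)) abort("sequences must be non-empty")
  raw <- .align_cpp(query, ref, scoring$match, scoring$mismatch,
                    scoring$gap_open, scoring$gap_extend, 2L)
  new_alignment(raw, query, nchar(ref), "local", query_id, ref_name)
}

#' @export
print.pe_alignment <- function(x, ...) {
  cat(sprintf("<pe_alignment %s> score %d, ref [%d,%d), query [%d,%d), %d op(s)\n",
              x$mode, x$score, x$ref_start, x$ref_end, x$query_start, x$query_end,
              nrow(x$ops)))
  invisible(x)
}

# fraction of alignment columns that are matches
alignment_identity <- function(aln) {
  tot <- sum(aln$ops$length)
  if (tot == 0) return(0)
  sum(aln$ops$length[aln$ops$op == "match"]) / tot
}

# matches over query-consuming columns: 1 - (per-base disagreement), blind to
# deletions, so programmed contiguous deletions still look "clean"
query_identity <- function(aln) {
  qcols <- aln$ops$op %in% c("match", "mismatch", "insertion")
  tot <- sum(aln$ops$length[qcols])
  if (tot == 0) return(0)
  sum(aln$ops$length[aln$ops$op == "match"]) / tot
}

# reference span covered by query bases (terminal deletion ops excluded)
covered_ref_span <- function(aln) {
  ops <- aln$ops
  if (nrow(ops) == 0) return(c(aln$ref_start, aln$ref_start))
  lead <- 0L
  k <- 1L
  while (k <= nrow(ops) && ops$op[k] == "deletion") { lead <- lead + ops$length[k]; k <- k + 1L }
  trail <- 0L
  k <- nrow(ops)
  while (k >= 1 && ops$op[k] == "deletion") { trail <- trail + ops$length[k]; k <- k - 1L }
  c(aln$ref_start + lead, aln$ref_end - trail)
}

# Reconstruct the query bases aligned to reference window [ws, we).
# Insertions strictly inside the window are included (they will break an
# exact-match comparison, as they should); boundary insertions are not.
# Returns list(covered = flag, segment = string).
aligned_query_segment <- function(aln, window) {
  ws <- window[1]; we <- window[2]
  span <- covered_ref_span(aln)
  if (span[1] > ws || span[2] < we)
    return(list(covered = FALSE, segment = NA_character_))
  rpos <- aln$ref_start
  parts <- character(0)
  for (k in seq_len(nrow(aln$ops))) {
    op <- aln$ops$op[k]; len <- aln$ops$length[k]
    if (op %in% c("match", "mismatch")) {
      lo <- max(rpos, ws); hi <- min(rpos + len, we)
      if (hi > lo) parts <- c(parts, substr(aln$ops$seq[k], lo - rpos + 1L, hi - rpos))
      rpos <- rpos + len
    } else if (op == "deletion") {
      rpos <- rpos + len
    } else { # insertion at between-base position rpos
      if (rpos > ws && rpos < we) parts <- c(parts, aln$ops$seq[k])
    }
    if (rpos >= we) break
  }
  list(covered = TRUE, segment = paste(parts, collapse = ""))
}

#' Extract left-normalized indel and substitution events
#'
#' Walks the alignment, emits one event per run (substitutions merged per
#' mismatch run), then shifts every indel to its leftmost equivalent placement
#' (VCF convention) and merges events that become adjacent, so that identical
#' molecules yield identical position-keyed events regardless of equivalent
#' DP gap placements.
#'
#' @param aln A `pe_alignment` (global or fitting mode).
#' @param ref The reference sequence the alignment was computed against.
#' @return Tibble with columns `kind` (`insertion`/`deletion`/`substitution`),
#'   `ref_pos` (0-based; between-base for insertions), `length`, `allele`.
#' @export
normalize_events <- function(aln, ref) {
  ops <- aln$ops
  ev <- list()
  rpos <- aln$ref_start
  lead <- TRUE
  n_ops <- nrow(ops)
  for (k in seq_len(n_ops)) {
    op <- ops$op[k]; len <- ops$length[k]
    terminal <- (lead && op == "deletion") || (k == n_ops && op == "deletion")
    if (op %in% c("match", "mismatch")) lead <- FALSE
    if (op == "insertion") lead <- FALSE
    if (op == "mismatch") {
      ev[[length(ev) + 1L]] <- list(kind = "substitution", ref_pos = rpos, length = len,
                                    allele = ops$seq[k])
      rpos <- rpos + len
    } else if (op == "deletion") {
      if (!terminal)
        ev[[length(ev) + 1L]] <- list(kind = "deletion", ref_pos = rpos, length = len,
                                      allele = substr0(ref, rpos, rpos + len))
      rpos <- rpos + len
    } else if (op == "insertion") {
      ev[[length(ev) + 1L]] <- list(kind = "insertion", ref_pos = rpos, length = len,
                                    allele = ops$seq[k])
    } else {
      rpos <- rpos + len
    }
  }
  if (!length(ev))
    return(tibble(kind = character(0), ref_pos = integer(0),
                  length = integer(0), allele = character(0)))
  # left-normalize indels; events act as anchors for one another
  span0 <- covered_ref_span(aln)[1]
  out <- list()
  for (e in ev) {
    bound <- span0
    if (length(out)) {
      prev <- out[[length(out)]]
      bound <- prev$ref_pos + if (prev$kind == "insertion") 0L else prev$length
    }
    if (e$kind == "deletion") {
      s <- e$ref_pos; L <- e$length
      while (s > bound && substr0(ref, s - 1L, s) == substr0(ref, s + L - 1L, s + L)) s <- s - 1L
      e$ref_pos <- s
      e$allele <- substr0(ref, s, s + L)
    } else if (e$kind == "insertion") {
      p <- e$ref_pos; a <- e$allele; L <- e$length
      while (p > bound && substr0(ref, p - 1L, p) == substr(a, L, L)) {
        a <- paste0(substr(a, L, L), substr(a, 1L, L - 1L))
        p <- p - 1L
      }
      e$ref_pos <- p; e$allele <- a
    }
    # merge with previous event if same kind and now adjacent/coincident
    if (length(out)) {
      prev <- out[[length(out)]]
      if (prev$kind == "deletion" && e$kind == "deletion" &&
          prev$ref_pos + prev$length == e$ref_pos) {
        prev$length <- prev$length + e$length
        prev$allele <- paste0(prev$allele, e$allele)
        out[[length(out)]] <- prev
        next
      }
      if (prev$kind == "insertion" && e$kind == "insertion" && prev$ref_pos == e$ref_pos) {
        prev$length <- prev$length + e$length
        prev$allele <- paste0(prev$allele, e$allele)
        out[[length(out)]] <- prev
        next
      }
      if (prev$kind == "substitution" && e$kind == "substitution" &&
          prev$ref_pos + prev$length == e$ref_pos) {
        prev$length <- prev$length + e$length
        prev$allele <- paste0(prev$allele, e$allele)
        out[[length(out)]] <- prev
        next
      }
    }
    out[[length(out) + 1L]] <- e
  }
  dplyr::bind_rows(lapply(out, as_tibble))
}

#' Apply events back to a reference
#'
#' Reconstructs the query implied by a set of events over `ref[from, to)`;
#' the inverse of [normalize_events()] on N-free global alignments, used for
#' round-trip checks.
#'
#' @param ref Reference sequence.
#' @param events Event tibble from [normalize_events()].
#' @param from,to Reference window to reconstruct (defaults to whole ref).
#' @return The reconstructed query string.
#' @export
apply_events <- function(ref, events, from = 0L, to = nchar(ref)) {
  events <- arrange(events, .data$ref_pos,
                    match(.data$kind, c("insertion", "deletion", "substitution")))
  pos <- from
  parts <- character(0)
  for (k in seq_len(nrow(events))) {
    e <- events[k, ]
    if (e$ref_pos > pos) parts <- c(parts, substr0(ref, pos, e$ref_pos))
    pos <- max(pos, e$ref_pos)
    if (e$kind == "insertion") {
      parts <- c(parts, e$allele)
    } else if (e$kind == "deletion") {
      pos <- pos + e$length
    } else {
      parts <- c(parts, e$allele)
      pos <- pos + e$length
    }
  }
  if (pos < to) parts <- c(parts, substr0(ref, pos, to))
  paste(parts, collapse = "")
}

#' Collapse neighbouring events into complex replacement blocks
#'
#' On random sequence, a replacement (delete one segment, insert another) has
#' no unique decomposition into elementary indel events: the optimal
#' alignment may thread short spurious matches through the replaced region.
#' Collapsing runs of events separated by at most `max_gap` matched bases
#' into one `replacement` block restores a decomposition-invariant
#' description: the block's reference span and its alternate-segment length
#' are the same whichever equivalent alignment produced the events.
#'
#' @param events Tibble from [normalize_events()].
#' @param ref The reference sequence.
#' @param max_gap Maximum matched-base run length absorbed into a block
#'   (default 25).
#' @return Event tibble where collapsed groups appear as
#'   `kind = "replacement"` rows (`length` = reference span, `allele` = the
#'   alternate segment); isolated events are returned unchanged.
#' @export
collapse_complex_events <- function(events, ref, max_gap = 25L) {
  if (nrow(events) < 2) return(events)
  events <- arrange(events, .data$ref_pos)
  ref_end <- function(k) {
    if (events$kind[k] == "insertion") events$ref_pos[k]
    else events$ref_pos[k] + events$length[k]
  }
  grp <- integer(nrow(events)); g <- 1L; grp[1] <- g
  for (k in 2:nrow(events)) {
    if (events$ref_pos[k] - ref_end(k - 1L) <= max_gap) grp[k] <- g
    else { g <- g + 1L; grp[k] <- g }
  }
  out <- list()
  for (gg in unique(grp)) {
    idx <- which(grp == gg)
    sub <- events[idx, , drop = FALSE]
    n_indel <- sum(sub$kind != "substitution")
    if (length(idx) == 1 || n_indel < 2) {
      out[[length(out) + 1L]] <- sub
      next
    }
    s <- min(sub$ref_pos)
    e <- max(vapply(seq_len(nrow(sub)), function(k)
      if (sub$kind[k] == "insertion") sub$ref_pos[k] else sub$ref_pos[k] + sub$length[k],
      numeric(1)))
    alt <- apply_events(ref, sub, from = s, to = e)
    out[[length(out) + 1L]] <-
      tibble(kind = "replacement", ref_pos = as.integer(s),
             length = as.integer(e - s), allele = alt)
  }
  bind_rows(out)
}

#' Split alignment for large-deletion breakpoints
#'
#' For reads that align poorly end to end, finds a prefix and a suffix that
#' align collinearly to disjoint reference windows (each segment at least
#' `min_segment` bases at `min_identity`), reporting the deleted interval with
#' microhomology assigned leftmost. Returns `NULL` when no qualifying split
#' exists.
#'
#' @param query Read sequence.
#' @param ref Reference sequence.
#' @param scoring A [scoring_scheme()].
#' @param min_segment Minimum aligned length per segment (default 25).
#' @param min_identity Minimum per-segment identity (default 0.95).
#' @return `list(left_end, right_start, size)` (0-based, half-open deleted
#'   interval) or `NULL`.
#' @export
split_align_breakpoints <- function(query, ref, scoring = scoring_scheme(),
                                    min_segment = 25L, min_identity = 0.95) {
  a1 <- align_local(query, ref, scoring)
  seg_len1 <- a1$query_end - a1$query_start
  if (seg_len1 < min_segment || alignment_identity(a1) < min_identity) return(NULL)
  qlen <- nchar(query)
  # try the unaligned query suffix to the right of segment 1, then the prefix
  right_q <- if (qlen - a1$query_end >= min_segment)
    substr0(query, a1$query_end, qlen) else NULL
  left_q <- if (a1$query_start >= min_segment)
    substr0(query, 0L, a1$query_start) else NULL
  if (!is.null(right_q) && a1$ref_end < nchar(ref)) {
    refR <- substr0(ref, a1$ref_end, nchar(ref))
    a2 <- align_local(right_q, refR, scoring)
    seg_len2 <- a2$query_end - a2$query_start
    if (seg_len2 >= min_segment && alignment_identity(a2) >= min_identity &&
        a2$query_start <= 5L) {
      left_end <- a1$ref_end
      right_start <- a1$ref_end + a2$ref_start
      return(normalize_deletion_interval(ref, left_end, right_start))
    }
  }
  if (!is.null(left_q) && a1$ref_start > 0) {
    refL <- substr0(ref, 0L, a1$ref_start)
    a2 <- align_local(left_q, refL, scoring)
    seg_len2 <- a2$query_end - a2$query_start
    if (seg_len2 >= min_segment && alignment_identity(a2) >= min_identity &&
        (a1$query_start - a2$query_end) <= 5L) {
      left_end <- a2$ref_end
      right_start <- a1$ref_start
      return(normalize_deletion_interval(ref, left_end, right_start))
    }
  }
  NULL
}

# shift a deleted interval [s, e) to its leftmost equivalent placement
normalize_deletion_interval <- function(ref, s, e) {
  if (e <= s) return(NULL)
  while (s > 0 && substr0(ref, s - 1L, s) == substr0(ref, e - 1L, e)) {
    s <- s - 1L; e <- e - 1L
  }
  list(left_end = s, right_start = e, size = e - s)
}

# does any equivalent (microhomology-shifted) placement of the deletion
# [s, e) cover both nick offsets?
deletion_spans_nicks <- function(ref, s, e, nicks) {
  d <- normalize_deletion_interval(ref, s, e)
  s <- d$left_end; e <- d$right_start
  kmax <- 0L
  while (e + kmax < nchar(ref) &&
         substr0(ref, s + kmax, s + kmax + 1L) == substr0(ref, e + kmax, e + kmax + 1L))
    kmax <- kmax + 1L
  lo <- max(0L, nicks[2] - e)
  hi <- min(kmax, nicks[1] - s)
  lo <= hi
}

#' Export alignments as SAM
#'
#' Minimal single-reference SAM text export with a configurable CIGAR dialect.
#'
#' @param alns List of `pe_alignment` objects.
#' @param ref_name,ref_len Reference name and length for the header.
#' @param path Output path.
#' @param dialect `"MID"` (mismatches as M) or `"X=ID"`.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alns, ref_name, ref_len, path, dialect = c("MID", "X=ID")) {
  dialect <- match.arg(dialect)
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", ref_name, ref_len))
  body <- vapply(alns, function(a) {
    cig <- to_cigar(a, dialect)
    sprintf("%s\t0\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t*\tAS:i:%d",
            a$query_id %||% "read", ref_name, a$ref_start + 1L, cig, a$query, a$score)
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

to_cigar <- function(aln, dialect = "MID") {
  map <- if (dialect == "MID")
    c(match = "M", mismatch = "M", insertion = "I", deletion = "D")
  else c(match = "=", mismatch = "X", insertion = "I", deletion = "D")
  codes <- map[aln$ops$op]
  # re-merge runs that map to the same letter (e.g. match+mismatch under MID)
  lens <- integer(0); lets <- character(0)
  for (k in seq_along(aln$ops$op)) {
    lt <- codes[k]; ln <- aln$ops$length[k]
    if (length(lets) && lets[length(lets)] == lt) {
      lens[length(lens)] <- lens[length(lens)] + ln
    } else {
      lets <- c(lets, lt); lens <- c(lens, ln)
    }
  }
  if (!length(lets)) return("*")
  paste0(paste0(lens, lets), collapse = "")
}
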