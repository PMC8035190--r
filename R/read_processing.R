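# FASTQ ingestion and read-level preprocessing. Reads travel as tibbles with
# columns read_id, bases, qual (Phred+33 string) plus optional mate, sample,
# umi, index columns, so every step chains with the pipe. Streams that a step
# routes away (unassigned, discarded, unmerged) are attached as attributes and
# always counted, never silently dropped.

#' Read and write FASTQ as a read tibble
#'
#' Phred+33 is assumed throughout; gzipped input is detected automatically.
#'
#' @param path FASTQ or FASTQ.gz path.
#' @param mate Optional mate label (`"R1"`/`"R2"`) recorded per read.
#' @return A tibble with columns `read_id`, `bases`, `qual`, `mate`.
#' @export
read_fastq <- function(path, mate = NA_character_) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble(read_id = sub("\\s.*$", "", names(x)),
         bases = unname(as.character(x)),
         qual = unname(as.character(S4Vectors::mcols(x)$qualities)),
         mate = mate)
}

#' @rdname read_fastq
#' @param reads A read tibble.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$bases)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' Demultiplex reads by index barcode
#'
#' A read is assigned to a sample iff exactly one barcode lies within Hamming
#' distance 1 of its index sequence (one mismatch allowed per barcode);
#' ambiguous or more distant indices stay unassigned.
#'
#' @param reads Read tibble carrying an `index` column (the index read), or
#'   pass `index` explicitly.
#' @param barcode_table Tibble/data.frame with columns `sample`, `barcode`
#'   (equal-length barcodes; pairwise Hamming distance >= 3 recommended).
#' @param index Optional character vector of index reads, one per row.
#' @return The read tibble with a `sample` column (`NA` = unassigned) and a
#'   `demux_counts` attribute (`assigned`, `unassigned`).
#' @export
demultiplex <- function(reads, barcode_table, index = NULL) {
  index <- index %||% reads$index
  if (is.null(index)) abort("demultiplex needs an 'index' column or argument")
  bcs <- toupper(barcode_table$barcode)
  bl <- unique(nchar(bcs))
  if (length(bl) != 1) abort("barcodes must share a single length")
  if (any(nchar(index) != bl))
    abort("index read length does not match barcode length")
  if (length(bcs) > 1) {
    dmin <- min(utils::combn(seq_along(bcs), 2, function(ij) hamming(bcs[ij[1]], bcs[ij[2]])))
    if (dmin < 3)
      warn(sprintf("minimum pairwise barcode distance is %d (< 3); demultiplexing may be ambiguous", dmin))
  }
  im <- matrix(utf8ToInt(paste(index, collapse = "")), ncol = bl, byrow = TRUE)
  d <- vapply(bcs, function(b) {
    bv <- utf8ToInt(b)
    rowSums(im != matrix(bv, nrow(im), bl, byrow = TRUE))
  }, numeric(nrow(im)))
  d <- matrix(d, nrow = nrow(im))
  hits <- rowSums(d <= 1)
  assigned <- hits == 1
  which_bc <- apply(d, 1, which.min)
  sample <- ifelse(assigned, barcode_table$sample[which_bc], NA_character_)
  out <- mutate(reads, sample = sample)
  attr(out, "demux_counts") <- c(assigned = sum(assigned), unassigned = sum(!assigned))
  out
}

#' Define a UMI extraction scheme
#'
#' @param source `"read_prefix"` (UMI is the first `length` bases of the read,
#'   removed from bases and qualities) or `"header"` (UMI is the final
#'   `:`-separated field of the read id; bases untouched).
#' @param length UMI length for the prefix scheme.
#' @return A list describing the scheme.
#' @export
umi_scheme <- function(source = c("read_prefix", "header"), length = 8L) {
  list(source = match.arg(source), length = as.integer(length))
}

#' Extract UMIs from reads
#'
#' Reads whose UMI contains `N` are routed to a discard stream (attached as
#' the `umi_discarded` attribute) and excluded from the result.
#'
#' @param reads Read tibble.
#' @param scheme A [umi_scheme()].
#' @return Read tibble with a `umi` column (prefix scheme: bases/qual trimmed).
#' @export
extract_umi <- function(reads, scheme = umi_scheme()) {
  if (scheme$source == "read_prefix") {
    L <- scheme$length
    if (any(nchar(reads$bases) < L)) abort("UMI scheme length exceeds a read length")
    umi <- substr(reads$bases, 1L, L)
    out <- mutate(reads, umi = umi,
                  bases = substr(.data$bases, L + 1L, nchar(.data$bases)),
                  qual = substr(.data$qual, L + 1L, nchar(.data$qual)))
  } else {
    out <- mutate(reads, umi = sub("^.*:", "", .data$read_id))
  }
  bad <- grepl("N", out$umi, fixed = TRUE)
  res <- out[!bad, , drop = FALSE]
  attr(res, "umi_discarded") <- out[bad, , drop = FALSE]
  res
}

#' Trim a 3' adapter
#'
#' Removes the longest read suffix matching a prefix of the adapter with at
#' most 10% mismatches and at least `min_overlap` bases; reads without a
#' qualifying match are left unchanged.
#'
#' @param reads Read tibble.
#' @param adapter Adapter sequence (5'->3' as it appears at the read 3' end).
#' @param min_overlap Minimum suffix/prefix overlap (default 3).
#' @param max_mismatch_frac Mismatch budget as a fraction of the overlap.
#' @return Read tibble with trimmed `bases`/`qual`.
#' @export
trim_adapter_3p <- function(reads, adapter, min_overlap = 3L, max_mismatch_frac = 0.1) {
  if (!nzchar(adapter)) abort("adapter must be non-empty")
  tr <- .trim3p_cpp(reads$bases, toupper(adapter), as.integer(min_overlap), max_mismatch_frac)
  keep_to <- nchar(reads$bases) - tr
  mutate(reads, bases = substr(.data$bases, 1L, keep_to),
         qual = substr(.data$qual, 1L, keep_to))
}

#' Merge paired-end reads by overlap
#'
#' Read 2 is reverse-complemented, the overlap maximizing matched bases is
#' chosen (ties toward the longer overlap), and in disagreeing overlap columns
#' the higher-quality base wins with the column quality set to the maximum of
#' the two. Pairs with no overlap meeting `min_overlap`/`max_mismatch_frac`
#' are routed to the `unmerged` attribute.
#'
#' @param r1,r2 Read tibbles, row-matched pairs.
#' @param min_overlap Minimum acceptable overlap (default 10).
#' @param max_mismatch_frac Maximum mismatch fraction in the overlap.
#' @return Tibble of merged reads (`read_id`, `bases`, `qual`, `overlap_len`)
#'   with an `unmerged` attribute holding the failed pairs' ids.
#' @export
merge_pairs <- function(r1, r2, min_overlap = 10L, max_mismatch_frac = 0.1) {
  stopifnot(nrow(r1) == nrow(r2))
  b2 <- revcomp(r2$bases)
  q2 <- stringi::stri_reverse(r2$qual)
  n <- nrow(r1)
  bases <- character(n); qual <- character(n); ov <- integer(n)
  for (k in seq_len(n)) {
    res <- .best_overlap_cpp(r1$bases[k], b2[k], as.integer(min_overlap), max_mismatch_frac)
    o <- res[1]
    ov[k] <- o
    if (o == 0) next
    la <- nchar(r1$bases[k])
    if (res[2] == 0) {
      bases[k] <- paste0(r1$bases[k], substr(b2[k], o + 1L, nchar(b2[k])))
      qa <- utf8ToInt(substr(r1$qual[k], la - o + 1L, la)) - 33L
      qb <- utf8ToInt(substr(q2[k], 1L, o)) - 33L
      qual[k] <- paste0(substr(r1$qual[k], 1L, la - o),
                        phred_encode(pmax(qa, qb)),
                        substr(q2[k], o + 1L, nchar(q2[k])))
    } else {
      a_ov <- utf8ToInt(substr(r1$bases[k], la - o + 1L, la))
      b_ov <- utf8ToInt(substr(b2[k], 1L, o))
      qa <- utf8ToInt(substr(r1$qual[k], la - o + 1L, la)) - 33L
      qb <- utf8ToInt(substr(q2[k], 1L, o)) - 33L
      take_b <- (a_ov != b_ov) & (qb > qa)
      cons <- ifelse(take_b, b_ov, a_ov)
      bases[k] <- paste0(substr(r1$bases[k], 1L, la - o), intToUtf8(cons),
                         substr(b2[k], o + 1L, nchar(b2[k])))
      qual[k] <- paste0(substr(r1$qual[k], 1L, la - o),
                        phred_encode(pmax(qa, qb)),
                        substr(q2[k], o + 1L, nchar(q2[k])))
    }
  }
  ok <- ov > 0
  out <- tibble(read_id = r1$read_id[ok], bases = bases[ok], qual = qual[ok],
                overlap_len = ov[ok])
  if ("umi" %in% names(r1)) out$umi <- r1$umi[ok]
  if ("sample" %in% names(r1)) out$sample <- r1$sample[ok]
  attr(out, "unmerged") <- tibble(read_id = r1$read_id[!ok])
  out
}

#' Quality-filter reads
#'
#' Keeps a read iff its mean Phred score is at least `min_mean` and its
#' minimum per-base score at least `min_base` (the removal condition is
#' "mean under 30 or any base under 24"). Empty reads are discarded.
#'
#' @param reads Read tibble.
#' @param min_mean,min_base Thresholds (defaults 30 and 24).
#' @return The kept reads, with a `qc_discarded` attribute holding the rest.
#' @export
quality_filter <- function(reads, min_mean = 30, min_base = 24) {
  qs <- qual_stats(reads$qual)
  keep <- !is.na(qs$mean_q) & qs$mean_q >= min_mean & qs$min_q >= min_base
  out <- reads[keep, , drop = FALSE]
  attr(out, "qc_discarded") <- reads[!keep, , drop = FALSE]
  out
}
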