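# UDiTaS-mode quantification. Reads sharing a UMI are collapsed to one family
# and the family's exemplar read is classified into exactly one category:
#
#   aav_integration > precise_edit > pegnick_deletion > small_indel_sub >
#   large_deletion > wild_type > unclassified
#
# AAV evidence wins because it is junction-based; a deletion that spans both
# nick positions at size < 100 bp is a pegRNA-nick deletion (takes precedence
# over small_indel_sub); sizes >= 100 bp are large deletions, recovered by
# split alignment when end-to-end alignment fails. Recurrent large deletions
# are tested against a control-derived background rate with a one-sided
# binomial tail and Benjamini-Hochberg adjustment at a 0.05 cut-off.

UDITAS_CATEGORIES <- c("wild_type", "precise_edit", "small_indel_sub",
                       "pegnick_deletion", "large_deletion", "aav_integration",
                       "unclassified")

#' Group reads into UMI families
#'
#' One family per distinct UMI string; no UMI error-correction is applied by
#' default (UMIs at Hamming distance 1 are distinct families).
#'
#' @param reads Read tibble with a `umi` column.
#' @return Tibble `umi`, `n_reads`, `reads` (list of per-family read tibbles),
#'   with attribute `no_umi` counting reads lacking a UMI.
#' @export
build_umi_families <- function(reads) {
  no_umi <- sum(is.na(reads$umi))
  ok <- reads[!is.na(reads$umi), , drop = FALSE]
  fams <- ok |> tidyr::nest(reads = -dplyr::all_of("umi")) |>
    mutate(n_reads = vapply(.data$reads, nrow, integer(1))) |>
    select("umi", "n_reads", "reads")
  attr(fams, "no_umi") <- no_umi
  fams
}

#' Select the exemplar read of a UMI family
#'
#' The most frequent member sequence; ties broken by highest summed quality,
#' then lexicographically smallest sequence — fully deterministic.
#'
#' @param family A per-family read tibble (one element of
#'   [build_umi_families()]'s `reads` column).
#' @return The exemplar row (one-row tibble).
#' @export
select_exemplar <- function(family) {
  n <- nrow(family)
  if (n == 0) abort("cannot select an exemplar from an empty family")
  if (n == 1 || length(unique(family$bases)) == 1)
    return(family[1, , drop = FALSE])
  cnt <- table(family$bases)
  top <- names(cnt)[cnt == max(cnt)]
  if (length(top) > 1) {
    sq <- vapply(top, function(b) {
      rows <- which(family$bases == b)
      sum(vapply(family$qual[rows], function(q) sum(utf8ToInt(q)) - 33 * nchar(q),
                 numeric(1)))
    }, numeric(1))
    top <- top[sq == max(sq)]
    top <- sort(top)[1] # lexicographic last resort
  }
  family[which(family$bases == top[1])[1], , drop = FALSE]
}

#' Classify a UMI-family exemplar
#'
#' Applies the category cascade described above. The exemplar must cover the
#' window between the pegRNA and nicking-sgRNA nick positions (a deletion gap
#' bridged by aligned flanks counts as covering); otherwise the family is
#' `unclassified`.
#'
#' @param bases Exemplar read sequence.
#' @param amplicon An [amplicon_spec()] (with `nick_sgrna_nick` set).
#' @param edit An [edit_spec()].
#' @param edited Matching [build_edited_allele()] result.
#' @param aav_ref AAV/plasmid reference sequence, or `NULL` to disable
#'   integration calling.
#' @param scoring A [scoring_scheme()].
#' @param family_size,exemplar_multiplicity Family context used to corroborate
#'   substitution-only calls: a substitution-only family is called
#'   `small_indel_sub` only when the exemplar sequence is carried by at least
#'   two members. A substitution observed in a single read is
#'   indistinguishable from a sequencing error — the reason UMI families are
#'   collapsed at all — so uncorroborated substitution-only families are
#'   conservatively called `wild_type` (indels at these quality levels are
#'   orders of magnitude rarer as errors and need no corroboration).
#' @param params List of thresholds: `small_max` (49), `pegnick_max` (99),
#'   `large_min` (100), `min_identity_global` (0.6), `min_local_score` (40),
#'   `locus_match_k` (15), `min_segment` (25).
#' @return `list(category, events, deletion)` where `deletion` is the
#'   normalized large/pegnick deletion interval or `NULL`.
#' @export
classify_family <- function(bases, amplicon, edit, edited, aav_ref = NULL,
                            scoring = scoring_scheme(), params = list(),
                            family_size = 1L, exemplar_multiplicity = 1L) {
  p <- utils::modifyList(list(small_max = 49L, pegnick_max = 99L, large_min = 100L,
                              min_identity_global = 0.6, min_clean_identity = 0.95,
                              min_local_score = 40L,
                              locus_match_k = 15L, min_segment = 25L,
                              adjacency_tol = 5L), params)
  nicks <- sort(c(amplicon$peg_nick, amplicon$nick_sgrna_nick))
  if (length(nicks) < 2) abort("UDiTaS classification needs both nick positions")
  # fast path: error-free primer-anchored fragments of either allele
  # (such reads cannot carry junction or indel evidence)
  L <- nchar(bases)
  if (identical(bases, substr(amplicon$sequence, 1L, L)) && L >= nicks[2]) {
    return(list(category = "wild_type",
                events = tibble(kind = character(0), ref_pos = integer(0),
                                length = integer(0), allele = character(0)),
                deletion = NULL))
  }
  if (identical(bases, substr(edited$sequence, 1L, L)) &&
      L >= nicks[2] + max(0L, edited$delta) &&
      !identical(substr(edited$sequence, 1L, L), substr(amplicon$sequence, 1L, L))) {
    return(list(category = "precise_edit", events = NULL, deletion = NULL))
  }
  aln <- align_global(bases, amplicon$sequence, scoring, ref_free_ends = TRUE)
  # per-base cleanliness: matches over query-consuming columns; programmed
  # contiguous deletions stay "clean", junction chimeras and misplaced gaps
  # do not
  qidy <- query_identity(aln)
  # (1) AAV integration: junction evidence beats everything else. Chimeric
  # reads cannot reach near-perfect locus identity, so the AAV screen runs on
  # every read that aligns imperfectly (the paper screens the unmapped
  # stream); filtered false-priming reads are flagged for removal.
  if (!is.null(aav_ref) && qidy < p$min_clean_identity) {
    hit <- detect_aav_integration(bases, aav_ref, amplicon,
                                  min_local_score = p$min_local_score,
                                  locus_match_k = p$locus_match_k,
                                  adjacency_tol = p$adjacency_tol,
                                  scoring = scoring, detail = TRUE)
    if (!is.null(hit)) {
      if (isTRUE(hit$false_priming))
        return(list(category = "false_priming", events = NULL, deletion = NULL))
      return(list(category = "aav_integration", events = NULL, deletion = NULL))
    }
  }
  events <- normalize_events(aln, amplicon$sequence)
  dels <- events[events$kind == "deletion", , drop = FALSE]
  # (5) large deletion: the affine-gap end-to-end alignment recovers most
  # contiguous deletions directly (one long gap beats scattered alternatives)
  if (nrow(dels) && any(dels$length >= p$large_min)) {
    d <- dels[which.max(dels$length), ]
    bp <- normalize_deletion_interval(amplicon$sequence, d$ref_pos, d$ref_pos + d$length)
    return(list(category = "large_deletion", events = events, deletion = bp))
  }
  # (3) deletion spanning both nicks (any equivalent placement) at size < 100
  if (nrow(dels)) {
    span_both <- vapply(seq_len(nrow(dels)), function(k)
      deletion_spans_nicks(amplicon$sequence, dels$ref_pos[k],
                           dels$ref_pos[k] + dels$length[k], nicks), logical(1))
    cand <- dels[span_both & dels$length <= p$pegnick_max, , drop = FALSE]
    if (nrow(cand)) {
      d <- cand[which.max(cand$length), ]
      return(list(category = "pegnick_deletion", events = events,
                  deletion = list(left_end = d$ref_pos,
                                  right_start = d$ref_pos + d$length,
                                  size = d$length)))
    }
  }
  if (qidy < p$min_clean_identity) {
    # breakpoints the end-to-end alignment could not place: split alignment
    bp <- split_align_breakpoints(bases, amplicon$sequence, scoring,
                                  min_segment = p$min_segment)
    if (!is.null(bp)) {
      cat_for <- classify_deletion_size(bp$size, bp, nicks, p, ref = amplicon$sequence)
      return(list(category = cat_for, events = events, deletion = bp))
    }
    if (qidy < p$min_identity_global)
      return(list(category = "unclassified", events = events, deletion = NULL))
  }
  # (2) precise edit (checked against the edited allele, which carries any
  # intended indel, so coverage is evaluated in edited coordinates)
  oc <- call_read_outcome(bases, amplicon, edit, edited, scoring, ref_free_ends = TRUE)
  if (oc$call == "precise_edit")
    return(list(category = "precise_edit", events = events, deletion = NULL))
  # (4) small indel (< 50 bp): direct molecular evidence; an insertion
  # shortens reference coverage, so this precedes the nick-window gate
  indels <- events[events$kind != "substitution", , drop = FALSE]
  if (nrow(indels) && any(indels$length <= p$small_max))
    return(list(category = "small_indel_sub", events = events, deletion = NULL))
  if (nrow(indels))  # only indels of 50-99 bp not spanning both nicks remain
    return(list(category = "unclassified", events = events, deletion = NULL))
  # WT / substitution calls require the read to observe the nick window
  span <- covered_ref_span(aln)
  if (span[1] > nicks[1] || span[2] < nicks[2])
    return(list(category = "unclassified", events = events, deletion = NULL))
  # corroborated substitution in the quantification window (partial edits
  # present as window substitutions; substitutions elsewhere in a single
  # read are treated as noise)
  subs <- events_in_window(events[events$kind == "substitution", , drop = FALSE],
                           edit$quant_window)
  if (nrow(subs)) {
    corroborated <- exemplar_multiplicity >= 2L
    if (corroborated)
      return(list(category = "small_indel_sub", events = events, deletion = NULL))
  }
  # (6) no molecular events: wild type
  list(category = "wild_type", events = events, deletion = NULL)
}

classify_deletion_size <- function(size, bp, nicks, p, ref = NULL) {
  if (size >= p$large_min) return("large_deletion")
  spans <- if (is.null(ref)) bp$left_end <= nicks[1] && bp$right_start >= nicks[2]
           else deletion_spans_nicks(ref, bp$left_end, bp$right_start, nicks)
  if (spans && size <= p$pegnick_max) return("pegnick_deletion")
  if (size <= p$small_max) return("small_indel_sub")
  "unclassified"
}

#' Detect AAV/plasmid integration in a read
#'
#' Calls an integration iff the read locally aligns to the AAV reference with
#' score at least `min_local_score` AND is not a false-priming artifact.
#' False priming: the AAV hit begins directly adjacent to the UDiTaS primer
#' footprint and the read contains no exact `locus_match_k`-mer from the
#' target locus outside the primer (reads initiated by the locus primer on
#' AAV template, carrying no genuine locus sequence).
#'
#' @param bases Read sequence.
#' @param aav_ref AAV/plasmid reference sequence.
#' @param amplicon An [amplicon_spec()] with `uditas_primer_interval` set.
#' @param min_local_score Minimum local alignment score (default 40).
#' @param locus_match_k Exact-match length certifying genuine locus sequence
#'   (default 15).
#' @param adjacency_tol Distance (bases) from the primer end within which an
#'   AAV hit counts as "directly adjacent" (default 5).
#' @param scoring A [scoring_scheme()].
#' @param detail Also report filtered false-priming hits (internal plumbing
#'   for the pipeline's false-priming accounting).
#' @return `list(score, query_start, aav_start)` for a call, else `NULL`;
#'   with `detail = TRUE` a filtered false-priming hit is returned with field
#'   `false_priming = TRUE` instead of `NULL`.
#' @export
detect_aav_integration <- function(bases, aav_ref, amplicon,
                                   min_local_score = 40L, locus_match_k = 15L,
                                   adjacency_tol = 5L, scoring = scoring_scheme(),
                                   detail = FALSE) {
  hit <- seeded_local(bases, aav_ref, scoring)
  if (is.null(hit) || hit$score < min_local_score) {
    hit_rc <- seeded_local(bases, revcomp(aav_ref), scoring)
    if (is.null(hit_rc) || hit_rc$score < min_local_score) return(NULL)
    hit <- hit_rc
  }
  pi <- amplicon$uditas_primer_interval
  primer_len <- if (is.null(pi)) 0L else (pi[2] - pi[1])
  adjacent <- hit$query_start <= primer_len + adjacency_tol
  if (adjacent && !has_locus_kmer(bases, amplicon, primer_len, locus_match_k)) {
    if (detail)
      return(list(score = hit$score, query_start = hit$query_start,
                  aav_start = hit$ref_start, false_priming = TRUE))
    return(NULL) # false priming
  }
  list(score = hit$score, query_start = hit$query_start,
       aav_start = hit$ref_start, false_priming = FALSE)
}

# Seeded local alignment: find shared 11-mers, then run the local DP in a
# reference window around the dominant seed diagonal. Reads sharing no seed
# with the reference cannot reach the report threshold and return NULL.
# Contiguous integration fragments sit on a single diagonal, so the windowed
# score equals the full-reference score except in pathological cases.
seeded_local <- function(query, ref, scoring, k = 11L, margin = 60L) {
  lq <- nchar(query); lr <- nchar(ref)
  if (lq < k || lr < k) return(NULL)
  qk <- substring(query, 1:(lq - k + 1L), k:lq)
  rk <- substring(ref, 1:(lr - k + 1L), k:lr)
  m <- match(qk, rk)
  hit <- which(!is.na(m))
  if (!length(hit)) return(NULL)
  diag <- m[hit] - hit  # 0-based ref offset of the read start per seed
  d <- as.integer(names(sort(table(diag), decreasing = TRUE))[1])
  w0 <- max(0L, d - margin)
  w1 <- min(lr, d + lq + margin)
  a <- align_local(query, substr0(ref, w0, w1), scoring)
  a$ref_start <- a$ref_start + w0
  a$ref_end <- a$ref_end + w0
  a
}

# does the read carry any exact k-mer from the locus outside the primer?
has_locus_kmer <- function(bases, amplicon, primer_len, k) {
  body <- substr(bases, primer_len + 1L, nchar(bases))
  if (nchar(body) < k) return(FALSE)
  locus <- substr(amplicon$sequence, primer_len + 1L, nchar(amplicon$sequence))
  if (nchar(locus) < k) return(FALSE)
  kmers <- substring(locus, 1:(nchar(locus) - k + 1L), k:nchar(locus))
  probes <- substring(body, 1:(nchar(body) - k + 1L), k:nchar(body))
  any(probes %in% kmers)
}

#' Classify every UMI family
#'
#' Selects exemplars and classifies them; identical exemplar sequences are
#' classified once. Classification is invariant to read order and UMI
#' relabelling.
#'
#' @param families Result of [build_umi_families()].
#' @inheritParams classify_family
#' @return `families` with columns `exemplar`, `category`, `deletion` added.
#' @export
classify_families <- function(families, amplicon, edit, edited, aav_ref = NULL,
                              scoring = scoring_scheme(), params = list()) {
  ex <- vapply(families$reads, function(f) select_exemplar(f)$bases, character(1))
  mult <- vapply(seq_along(ex), function(i) sum(families$reads[[i]]$bases == ex[i]),
                 integer(1))
  corro <- mult >= 2L
  key <- paste0(ifelse(corro, "c:", "u:"), ex)
  uq <- !duplicated(key)
  res <- vector("list", nrow(families))
  res[uq] <- lapply(which(uq), function(i)
    classify_family(ex[i], amplicon = amplicon, edit = edit, edited = edited,
                    aav_ref = aav_ref, scoring = scoring, params = params,
                    family_size = if (corro[i]) 1L else 2L,
                    exemplar_multiplicity = if (corro[i]) 2L else 1L))
  idx <- match(key, key[uq])
  res <- res[uq][idx]
  mutate(families, exemplar = ex,
         category = vapply(res, `[[`, character(1), "category"),
         deletion = lapply(res, `[[`, "deletion"))
}

#' Cluster large deletions by breakpoints
#'
#' Families whose normalized breakpoints coincide form one cluster
#' (microhomology-shifted but equivalent placements have already been
#' left-normalized and therefore coincide).
#'
#' @param families Classified families (from [classify_families()]).
#' @param categories Which categories contribute (default the two deletion
#'   categories).
#' @return Tibble `start`, `end`, `size`, `umi_count` (0-based half-open).
#' @export
cluster_deletions <- function(families,
                              categories = c("large_deletion", "pegnick_deletion")) {
  keep <- families$category %in% categories &
    !vapply(families$deletion, is.null, logical(1))
  if (!any(keep)) {
    return(tibble(start = integer(0), end = integer(0), size = integer(0),
                  umi_count = integer(0)))
  }
  dels <- families[keep, , drop = FALSE]
  tibble(start = vapply(dels$deletion, function(d) as.integer(d$left_end), integer(1)),
         end = vapply(dels$deletion, function(d) as.integer(d$right_start), integer(1))) |>
    count(.data$start, .data$end, name = "umi_count") |>
    mutate(size = .data$end - .data$start) |>
    select("start", "end", "size", "umi_count") |>
    arrange(.data$start, .data$end)
}

#' Estimate the background large-deletion rate from controls
#'
#' Pooled per-UMI probability of observing any large deletion in matched
#' control libraries, with a Jeffreys-style pseudo-count:
#' `(events + 0.5) / (total + 1)`.
#'
#' @param n_events Large-deletion UMIs across pooled controls.
#' @param n_total Total control UMIs.
#' @return A rate in (0, 1).
#' @export
estimate_background_rate <- function(n_events, n_total) {
  if (n_total <= 0) abort("control UMI total must be positive")
  (n_events + 0.5) / (n_total + 1)
}

#' Test deletion clusters for enrichment over background
#'
#' Per cluster, a one-sided binomial tail `P(X >= umi_count)` with
#' `n = total_umis` and `p = background_rate`, Benjamini-Hochberg adjusted
#' across clusters; significant iff the adjusted p-value is at most `alpha`.
#'
#' @param clusters Result of [cluster_deletions()].
#' @param total_umis Total UMIs in the sample.
#' @param background_rate Per-UMI background probability (see
#'   [estimate_background_rate()]).
#' @param alpha FDR cut-off (default 0.05).
#' @return `clusters` with `p_value`, `p_adjusted`, `significant` columns.
#' @export
deletion_significance <- function(clusters, total_umis, background_rate,
                                  alpha = 0.05) {
  if (total_umis == 0) abort("total_umis must be positive")
  p <- pbinom(clusters$umi_count - 1, total_umis, background_rate, lower.tail = FALSE)
  padj <- p.adjust(p, method = "BH")
  mutate(clusters, p_value = p, p_adjusted = padj,
         significant = padj <= alpha)
}

#' Summarise a UDiTaS run
#'
#' Per-category UMI counts and ratios (summing to 1 over all families,
#' integration UMIs included in the denominator), the AAV-integration UMI
#' fraction, and the significant deletion clusters.
#'
#' @param families Classified families.
#' @param clusters Optional result of [deletion_significance()].
#' @param sample Sample label.
#' @return One-row tibble of class `uditas_summary`; cluster table in the
#'   `clusters` attribute, per-category counts in `category_counts`.
#' @export
summarize_uditas <- function(families, clusters = NULL, sample = NA_character_) {
  n <- nrow(families)
  if (n == 0) abort("no UMI families to summarise")
  counts <- table(factor(families$category, levels = UDITAS_CATEGORIES))
  stopifnot(sum(counts) == n)
  ratios <- as.numeric(counts) / n
  out <- tibble(sample = sample, total_umis = n,
                !!!setNames(as.list(as.numeric(counts)), paste0("n_", UDITAS_CATEGORIES)),
                !!!setNames(as.list(ratios), paste0("ratio_", UDITAS_CATEGORIES)),
                aav_fraction = as.numeric(counts[["aav_integration"]]) / n)
  class(out) <- c("uditas_summary", class(out))
  attr(out, "clusters") <- clusters
  attr(out, "category_counts") <- counts
  out
}
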