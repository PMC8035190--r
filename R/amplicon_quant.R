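# Amplicon-mode quantification: per-read outcome calls against the unedited
# and edited alleles, the per-position indel catalog, triplicate-control
# background subtraction, and the per-sample summary.
#
# A precise call requires the read's quantification window to match the
# edited allele exactly — both the intended edit and the synonymous PAM
# modification present, and nothing else in the window. Sequencing errors in
# the window demote a read to substitution_other; calls are scoped to the
# window, with out-of-window events reported separately.

#' Call the editing outcome of one read
#'
#' Aligns the read to the unedited amplicon and to the edited allele, then
#' classifies: `precise_edit` iff the window sequence equals the edited
#' allele's window exactly; `wild_type` iff it equals the unedited amplicon's;
#' `indel` iff an insertion/deletion event touches the window; otherwise
#' `substitution_other`; `ambiguous` when the read does not cover the window.
#'
#' @param bases Read sequence (merged, filtered).
#' @param amplicon An [amplicon_spec()].
#' @param edit An [edit_spec()].
#' @param edited The matching [build_edited_allele()] result.
#' @param scoring A [scoring_scheme()].
#' @param ref_free_ends Use fitting alignment (partial-span reads).
#' @return One-row tibble: `call`, `events` (list of in-window events),
#'   `out_window_events` (list), `score`, `identity`.
#' @export
call_read_outcome <- function(bases, amplicon, edit, edited,
                              scoring = scoring_scheme(), ref_free_ends = FALSE) {
  qw <- edit$quant_window
  ew <- edited_window(edit)
  empty <- tibble(kind = character(0), ref_pos = integer(0),
                  length = integer(0), allele = character(0))
  # fast paths: exact full-length molecules dominate real libraries
  if (!ref_free_ends) {
    if (identical(bases, edited$sequence) && !identical(edited$sequence, amplicon$sequence)) {
      ev <- intended_events(amplicon, edit)
      return(tibble(call = "precise_edit", events = list(ev),
                    out_window_events = list(empty),
                    score = 2L * nchar(bases), identity = 1))
    }
    if (identical(bases, amplicon$sequence)) {
      return(tibble(call = "wild_type", events = list(empty),
                    out_window_events = list(empty),
                    score = 2L * nchar(bases), identity = 1))
    }
  }
  aln_un <- align_global(bases, amplicon$sequence, scoring, ref_free_ends = ref_free_ends)
  seg_un <- aligned_query_segment(aln_un, qw)
  aln_ed <- align_global(bases, edited$sequence, scoring, ref_free_ends = ref_free_ends)
  seg_ed <- aligned_query_segment(aln_ed, ew)
  events <- normalize_events(aln_un, amplicon$sequence)
  in_win <- events_in_window(events, qw)
  out_win <- events[!events_mask(events, qw), , drop = FALSE]
  if (!seg_un$covered && !seg_ed$covered) {
    return(tibble(call = "ambiguous", events = list(in_win),
                  out_window_events = list(out_win),
                  score = aln_un$score, identity = alignment_identity(aln_un)))
  }
  ed_window_seq <- substr0(edited$sequence, ew[1], ew[2])
  un_window_seq <- substr0(amplicon$sequence, qw[1], qw[2])
  call <- if (seg_ed$covered && identical(seg_ed$segment, ed_window_seq) &&
              !identical(ed_window_seq, un_window_seq)) {
    "precise_edit"
  } else if (seg_un$covered && identical(seg_un$segment, un_window_seq)) {
    "wild_type"
  } else if (!seg_un$covered) {
    "ambiguous"
  } else if (any(in_win$kind %in% c("insertion", "deletion"))) {
    "indel"
  } else {
    "substitution_other"
  }
  tibble(call = call, events = list(in_win), out_window_events = list(out_win),
         score = aln_un$score, identity = alignment_identity(aln_un))
}

# the events the intended edit itself produces against the unedited amplicon
intended_events <- function(amplicon, edit) {
  ev <- list()
  if (edit$type == "deletion") {
    ev[[1]] <- tibble(kind = "deletion", ref_pos = edit$ref_start,
                      length = edit$ref_end - edit$ref_start,
                      allele = substr0(amplicon$sequence, edit$ref_start, edit$ref_end))
  } else if (edit$type == "insertion") {
    ev[[1]] <- tibble(kind = "insertion", ref_pos = edit$ref_start,
                      length = nchar(edit$alt), allele = edit$alt)
  } else if (edit$type == "replacement") {
    ev[[1]] <- tibble(kind = "deletion", ref_pos = edit$ref_start,
                      length = edit$ref_end - edit$ref_start,
                      allele = substr0(amplicon$sequence, edit$ref_start, edit$ref_end))
    ev[[2]] <- tibble(kind = "insertion", ref_pos = edit$ref_start,
                      length = nchar(edit$alt), allele = edit$alt)
  } else {
    ev[[1]] <- tibble(kind = "substitution", ref_pos = edit$ref_start,
                      length = edit$ref_end - edit$ref_start, allele = edit$alt)
  }
  if (!is.null(edit$pam_mod)) {
    pm <- edit$pam_mod
    ev[[length(ev) + 1L]] <- tibble(kind = "substitution", ref_pos = pm$pos,
                                    length = 1L, allele = pm$alt)
  }
  arrange(bind_rows(ev), .data$ref_pos)
}

events_mask <- function(events, window) {
  if (nrow(events) == 0) return(logical(0))
  ws <- window[1]; we <- window[2]
  s <- events$ref_pos
  e <- ifelse(events$kind == "insertion", events$ref_pos, events$ref_pos + events$length)
  # insertion at between-base p touches the window iff ws < p < we
  ifelse(events$kind == "insertion", s > ws & s < we, s < we & e > ws)
}

events_in_window <- function(events, window) {
  events[events_mask(events, window), , drop = FALSE]
}

#' Call outcomes for a read tibble
#'
#' Vectorised wrapper around [call_read_outcome()]; identical read sequences
#' are classified once.
#'
#' @param reads Read tibble (columns `read_id`, `bases`, optionally `umi`).
#' @inheritParams call_read_outcome
#' @return `reads` with columns `call`, `events`, `out_window_events` added.
#' @export
call_read_outcomes <- function(reads, amplicon, edit, edited,
                               scoring = scoring_scheme(), ref_free_ends = FALSE) {
  uq <- unique(reads$bases)
  res <- lapply(uq, call_read_outcome, amplicon = amplicon, edit = edit,
                edited = edited, scoring = scoring, ref_free_ends = ref_free_ends)
  res <- bind_rows(res)
  idx <- match(reads$bases, uq)
  mutate(reads, call = res$call[idx], events = res$events[idx],
         out_window_events = res$out_window_events[idx])
}

#' Catalog indel and substitution events across reads
#'
#' One row per distinct event key `(kind, ref_pos, length, allele)` with the
#' number of supporting reads and its frequency over all passing reads —
#' the per-base text catalog used for background subtraction.
#'
#' @param outcomes Result of [call_read_outcomes()].
#' @param total Denominator; defaults to `nrow(outcomes)`.
#' @param amplicon_name Label recorded on the catalog (guards background
#'   subtraction against mixing amplicons).
#' @return Tibble `kind, ref_pos, length, allele, reads, freq` with attributes
#'   `total` and `amplicon_name`.
#' @export
catalog_indels <- function(outcomes, total = nrow(outcomes), amplicon_name = NA_character_) {
  all_ev <- bind_rows(c(outcomes$events, outcomes$out_window_events))
  if (nrow(all_ev) == 0) {
    tab <- tibble(kind = character(0), ref_pos = integer(0), length = integer(0),
                  allele = character(0), reads = integer(0), freq = numeric(0))
  } else {
    tab <- all_ev |>
      count(.data$kind, .data$ref_pos, .data$length, .data$allele, name = "reads") |>
      mutate(freq = .data$reads / total) |>
      arrange(.data$ref_pos, .data$kind)
  }
  attr(tab, "total") <- total
  attr(tab, "amplicon_name") <- amplicon_name
  tab
}

#' Subtract control background from an indel catalog
#'
#' Per event key, the mean frequency across the control catalogs (absent keys
#' count 0) is subtracted from the treatment frequency and floored at zero.
#' Keys absent from every control pass through unchanged; keys seen only in
#' controls are retained at net 0. Precise-edit counting is untouched — the
#' subtraction applies to the indel catalog only.
#'
#' @param treatment An indel catalog from [catalog_indels()].
#' @param controls List of control catalogs on the same amplicon.
#' @return The treatment catalog with columns `bg_freq` and `net_freq`, and
#'   attribute `background_subtracted = TRUE`.
#' @export
subtract_background <- function(treatment, controls) {
  if (!length(controls)) abort("at least one control catalog is required")
  amp <- attr(treatment, "amplicon_name")
  for (ct in controls) {
    camp <- attr(ct, "amplicon_name")
    if (!is.na(amp %||% NA) && !is.na(camp %||% NA) && !identical(amp, camp))
      abort(sprintf("control catalog is for amplicon '%s', treatment for '%s'", camp, amp))
  }
  nctl <- length(controls)
  key <- c("kind", "ref_pos", "length", "allele")
  pooled <- bind_rows(lapply(controls, function(ct) ct[, c(key, "freq")])) |>
    group_by(across(dplyr::all_of(key))) |>
    summarise(bg_freq = sum(.data$freq) / nctl, .groups = "drop")
  out <- dplyr::full_join(treatment, pooled, by = key) |>
    mutate(reads = dplyr::coalesce(.data$reads, 0L),
           freq = dplyr::coalesce(.data$freq, 0),
           bg_freq = dplyr::coalesce(.data$bg_freq, 0),
           net_freq = pmax(0, .data$freq - .data$bg_freq)) |>
    arrange(.data$ref_pos, .data$kind)
  attr(out, "total") <- attr(treatment, "total")
  attr(out, "amplicon_name") <- amp
  attr(out, "background_subtracted") <- TRUE
  out
}

#' Summarise amplicon-mode outcomes
#'
#' Category rates over all passing reads: the precise-editing fraction is
#' reads carrying the desired allele divided by all reads for the locus, the
#' indel rate is per-read (any indel in the window), plus raw and
#' background-subtracted indel mass where a subtracted catalog is supplied.
#'
#' @param outcomes Result of [call_read_outcomes()].
#' @param indel_table Optional [catalog_indels()] result to attach.
#' @param subtracted Optional [subtract_background()] result; its removed
#'   background mass yields `net_indel_rate`.
#' @param sample Sample label.
#' @return One-row tibble of class `amplicon_summary`.
#' @export
summarize_amplicon <- function(outcomes, indel_table = NULL, subtracted = NULL,
                               sample = NA_character_) {
  n <- nrow(outcomes)
  if (n == 0) abort("no passing reads to summarise")
  rate <- function(cl) sum(outcomes$call == cl) / n
  out <- tibble(sample = sample, n_reads = n,
                precise_rate = rate("precise_edit"),
                indel_rate = rate("indel"),
                wild_type_rate = rate("wild_type"),
                substitution_other_rate = rate("substitution_other"),
                ambiguous_rate = rate("ambiguous"))
  if (!is.null(subtracted)) {
    bg_mass <- sum(subtracted$freq - subtracted$net_freq)
    out$net_indel_rate <- max(0, out$indel_rate - bg_mass)
  }
  class(out) <- c("amplicon_summary", class(out))
  attr(out, "indel_table") <- indel_table
  attr(out, "subtracted_table") <- subtracted
  out
}
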