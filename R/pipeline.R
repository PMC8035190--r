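# Pipeline drivers tying the stages together in the two library modes, with
# per-stage read/UMI accounting (the run manifest) and TSV/JSON artifact
# output. Amplicon mode: merge -> quality filter -> (UMI collapse) -> align ->
# call -> catalog -> background subtraction -> summary. UDiTaS mode: UMI
# extraction -> family collapse -> exemplar classification -> false-priming
# removal -> deletion clustering -> BH significance -> summary.

#' Run the amplicon-mode pipeline
#'
#' @param amplicon An [amplicon_spec()].
#' @param edit An [edit_spec()].
#' @param r1,r2 Read tibbles (see [read_fastq()]), row-matched pairs.
#' @param controls Optional list of control read sets, each a
#'   `list(r1 =, r2 =)`, for triplicate background subtraction.
#' @param umi Optional [umi_scheme()]; when given, reads are collapsed to one
#'   exemplar per UMI family before outcome calling and all denominators are
#'   UMI counts.
#' @param scoring A [scoring_scheme()].
#' @param sample Sample label.
#' @param min_overlap,max_mismatch_frac Merge parameters.
#' @param min_mean,min_base Quality-filter thresholds.
#' @param out_dir Optional artifact directory (TSV catalog, JSON summary and
#'   manifest).
#' @return List of class `amplicon_run`: `summary`, `outcomes`, `indel_table`,
#'   `subtracted`, `manifest`.
#' @export
run_amplicon <- function(amplicon, edit, r1, r2, controls = NULL, umi = NULL,
                         scoring = scoring_scheme(), sample = "sample",
                         min_overlap = 10L, max_mismatch_frac = 0.1,
                         min_mean = 30, min_base = 24, out_dir = NULL) {
  if (nrow(r1) == 0) abort("empty input: no read pairs")
  edited <- build_edited_allele(amplicon, edit)
  manifest <- list(sample = sample, n_input_pairs = nrow(r1))
  if (!is.null(umi) && umi$source == "read_prefix") {
    r1 <- extract_umi(r1, umi)
    dropped <- attr(r1, "umi_discarded")
    manifest$n_umi_discarded <- if (is.null(dropped)) 0L else nrow(dropped)
    r2 <- r2[match(r1$read_id, r2$read_id), , drop = FALSE]
  }
  merged <- merge_pairs(r1, r2, min_overlap = min_overlap,
                        max_mismatch_frac = max_mismatch_frac)
  manifest$n_merged <- nrow(merged)
  manifest$n_unmerged <- nrow(attr(merged, "unmerged"))
  passed <- quality_filter(merged, min_mean = min_mean, min_base = min_base)
  manifest$n_pass_qc <- nrow(passed)
  manifest$n_fail_qc <- nrow(attr(passed, "qc_discarded"))
  if (nrow(passed) == 0) abort("no reads pass the quality filter")
  if (!is.null(umi)) {
    fams <- build_umi_families(passed)
    units <- bind_rows(lapply(fams$reads, select_exemplar))
    units$umi <- fams$umi
    manifest$n_umi_families <- nrow(fams)
  } else {
    units <- passed
  }
  outcomes <- call_read_outcomes(units, amplicon, edit, edited, scoring = scoring)
  manifest$n_units_called <- nrow(outcomes)
  stopifnot(manifest$n_input_pairs ==
              manifest$n_merged + manifest$n_unmerged + (manifest$n_umi_discarded %||% 0L))
  itab <- catalog_indels(outcomes, amplicon_name = amplicon$name)
  subtracted <- NULL
  if (!is.null(controls) && length(controls)) {
    ctabs <- lapply(controls, function(ct) {
      cr <- run_amplicon(amplicon, edit, ct$r1, ct$r2, controls = NULL, umi = umi,
                         scoring = scoring, sample = "control",
                         min_overlap = min_overlap,
                         max_mismatch_frac = max_mismatch_frac,
                         min_mean = min_mean, min_base = min_base)
      cr$indel_table
    })
    subtracted <- subtract_background(itab, ctabs)
  }
  summary <- summarize_amplicon(outcomes, indel_table = itab,
                                subtracted = subtracted, sample = sample)
  res <- structure(list(summary = summary, outcomes = outcomes,
                        indel_table = itab, subtracted = subtracted,
                        manifest = manifest),
                   class = "amplicon_run")
  if (!is.null(out_dir)) write_amplicon_artifacts(res, out_dir)
  res
}

write_amplicon_artifacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- res$subtracted %||% res$indel_table
  tab_out <- mutate(tab, pos_1based = .data$ref_pos + 1L)
  utils::write.table(tab_out, file.path(out_dir, "indel_catalog.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.list(res$summary), file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Run the UDiTaS-mode pipeline
#'
#' Operates on the primer-anchored read-2 stream. False-priming families are
#' removed before summarisation (and counted in the manifest); deletion
#' clusters are tested against the control-derived background rate with BH
#' adjustment at the 0.05 cut-off.
#'
#' @param amplicon An [amplicon_spec()] with both nicks and
#'   `uditas_primer_interval` set.
#' @param edit An [edit_spec()].
#' @param r2 Read-2 tibble (UMI in the header field, see [umi_scheme()]).
#' @param aav_ref AAV/plasmid reference sequence, or `NULL`.
#' @param umi A [umi_scheme()] (default header field).
#' @param background_rate Per-UMI large-deletion background probability; by
#'   default estimated from `control_deletions`/`control_total` via
#'   [estimate_background_rate()], or the no-event pooled estimate if no
#'   controls are supplied.
#' @param control_deletions,control_total Pooled control deletion-family and
#'   total-family counts.
#' @param scoring A [scoring_scheme()].
#' @param params Classification thresholds, see [classify_family()].
#' @param sample Sample label.
#' @param out_dir Optional artifact directory.
#' @return List of class `uditas_run`: `summary`, `families`, `clusters`,
#'   `manifest`.
#' @export
run_uditas <- function(amplicon, edit, r2, aav_ref = NULL,
                       umi = umi_scheme("header"), background_rate = NULL,
                       control_deletions = 0L, control_total = NULL,
                       scoring = scoring_scheme(), params = list(),
                       sample = "sample", out_dir = NULL) {
  if (nrow(r2) == 0) abort("empty input: no reads")
  edited <- build_edited_allele(amplicon, edit)
  manifest <- list(sample = sample, n_input_reads = nrow(r2))
  reads <- extract_umi(r2, umi)
  manifest$n_umi_discarded <- nrow(attr(reads, "umi_discarded"))
  fams <- build_umi_families(reads)
  manifest$n_reads_no_umi <- attr(fams, "no_umi")
  manifest$n_umi_families <- nrow(fams)
  n_reads_in_families <- sum(fams$n_reads)
  stopifnot(manifest$n_input_reads ==
              manifest$n_umi_discarded + manifest$n_reads_no_umi + n_reads_in_families)
  fams <- classify_families(fams, amplicon, edit, edited, aav_ref = aav_ref,
                            scoring = scoring, params = params)
  fp <- fams$category == "false_priming"
  manifest$n_false_priming_families <- sum(fp)
  fams <- fams[!fp, , drop = FALSE]
  manifest$n_families_analysed <- nrow(fams)
  if (nrow(fams) == 0) abort("no UMI families to analyse")
  clusters <- cluster_deletions(fams)
  if (is.null(background_rate)) {
    background_rate <- estimate_background_rate(
      control_deletions, control_total %||% nrow(fams))
  }
  clusters <- deletion_significance(clusters, total_umis = nrow(fams),
                                    background_rate = background_rate)
  summary <- summarize_uditas(fams, clusters = clusters, sample = sample)
  res <- structure(list(summary = summary, families = fams, clusters = clusters,
                        manifest = manifest),
                   class = "uditas_run")
  if (!is.null(out_dir)) write_uditas_artifacts(res, out_dir)
  res
}

write_uditas_artifacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fam_out <- tibble(umi = res$families$umi, size = res$families$n_reads,
                    category = res$families$category)
  utils::write.table(fam_out, file.path(out_dir, "umi_families.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cl <- res$clusters
  if (nrow(cl)) cl <- mutate(cl, start_1based = .data$start + 1L,
                             end_1based = .data$end)
  utils::write.table(cl, file.path(out_dir, "deletion_clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.list(res$summary), file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Assemble a plain-text report over one or more run summaries
#'
#' Per-sample category fractions, deletion-cluster table and run accounting,
#' rendered to a single document. Regeneration is idempotent.
#'
#' @param runs A list of `amplicon_run` / `uditas_run` objects.
#' @param path Optional output file.
#' @return Character vector of report lines, invisibly when `path` is given.
#' @export
generate_report <- function(runs, path = NULL) {
  if (!length(runs)) abort("at least one run is required")
  if (inherits(runs, c("amplicon_run", "uditas_run"))) runs <- list(runs)
  fmt <- function(x) sprintf("%.6f", x)
  lines <- c("# pequant run report", "")
  for (r in runs) {
    s <- r$summary
    lines <- c(lines, sprintf("## Sample: %s", s$sample[1]))
    if (inherits(r, "amplicon_run")) {
      lines <- c(lines,
                 sprintf("reads analysed: %d", s$n_reads),
                 sprintf("precise_edit: %s", fmt(s$precise_rate)),
                 sprintf("indel: %s", fmt(s$indel_rate)),
                 sprintf("wild_type: %s", fmt(s$wild_type_rate)),
                 sprintf("substitution_other: %s", fmt(s$substitution_other_rate)),
                 sprintf("ambiguous: %s", fmt(s$ambiguous_rate)))
      if ("net_indel_rate" %in% names(s))
        lines <- c(lines, sprintf("net_indel (background-subtracted): %s",
                                  fmt(s$net_indel_rate)))
    } else {
      lines <- c(lines, sprintf("UMI families: %d", s$total_umis))
      for (cat in UDITAS_CATEGORIES)
        lines <- c(lines, sprintf("%s: %s", cat, fmt(s[[paste0("ratio_", cat)]])))
      cl <- r$clusters
      if (!is.null(cl) && nrow(cl)) {
        lines <- c(lines, "deletion clusters (start, end, size, umis, p_adj, significant):")
        lines <- c(lines, sprintf("  %d\t%d\t%d\t%d\t%.3g\t%s", cl$start + 1L, cl$end,
                                  cl$size, cl$umi_count, cl$p_adjusted, cl$significant))
      }
    }
    lines <- c(lines, "")
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
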