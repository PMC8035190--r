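# Genomic coordinate model for a prime-editing target: the amplicon (or
# UDiTaS locus) reference, the guide nick positions, the intended edit, and
# construction of the edited-allele reference.
#
# Conventions: 0-based half-open intervals on the top strand; nicks are
# between-base offsets; reverse-strand guides carry top-strand coordinates
# plus an orientation flag and all classification happens on the top strand.

#' Describe a target amplicon or UDiTaS locus
#'
#' Bundles the reference sequence with the pegRNA and nicking-sgRNA nick
#' offsets, the PAM interval, and (for UDiTaS libraries) the footprint of the
#' locus-specific primer.
#'
#' @param name Text label for the locus.
#' @param sequence Uppercase reference sequence over `{A,C,G,T}`.
#' @param peg_nick 0-based between-base offset of the pegRNA-directed nick.
#' @param nick_sgrna_nick Offset of the PE3 nicking-sgRNA nick, or `NULL`.
#' @param peg_strand,nick_strand Orientation flags (`"+"` or `"-"`).
#' @param pam_interval Half-open interval `c(start, end)` of the protospacer
#'   adjacent motif, or `NULL`.
#' @param uditas_primer_interval Half-open interval of the locus-specific
#'   UDiTaS primer footprint, or `NULL`.
#' @return An object of class `amplicon_spec`.
#' @export
amplicon_spec <- function(name, sequence, peg_nick, nick_sgrna_nick = NULL,
                          peg_strand = "+", nick_strand = "-",
                          pam_interval = NULL, uditas_primer_interval = NULL) {
  check_dna(sequence, "amplicon sequence", allow_n = FALSE)
  len <- nchar(sequence)
  if (len < 1) abort("amplicon sequence must have length >= 1")
  chk_off <- function(x, what) {
    if (!is.null(x) && (x < 0 || x > len)) abort(sprintf("%s (%d) outside [0, %d]", what, x, len))
  }
  chk_off(peg_nick, "peg_nick")
  chk_off(nick_sgrna_nick, "nick_sgrna_nick")
  if (!is.null(nick_sgrna_nick) && identical(peg_nick, nick_sgrna_nick))
    abort("peg_nick and nick_sgrna_nick must differ")
  chk_iv <- function(iv, what) {
    if (is.null(iv)) return()
    if (length(iv) != 2 || iv[1] > iv[2] || iv[1] < 0 || iv[2] > len)
      abort(sprintf("%s must be half-open [start, end) within [0, %d]", what, len))
  }
  chk_iv(pam_interval, "pam_interval")
  chk_iv(uditas_primer_interval, "uditas_primer_interval")
  structure(list(name = name, sequence = sequence, length = len,
                 peg_nick = as.integer(peg_nick),
                 nick_sgrna_nick = if (is.null(nick_sgrna_nick)) NULL else as.integer(nick_sgrna_nick),
                 peg_strand = peg_strand, nick_strand = nick_strand,
                 pam_interval = if (is.null(pam_interval)) NULL else as.integer(pam_interval),
                 uditas_primer_interval = if (is.null(uditas_primer_interval)) NULL else as.integer(uditas_primer_interval)),
            class = "amplicon_spec")
}

#' @export
print.amplicon_spec <- function(x, ...) {
  cat(sprintf("<amplicon_spec> %s: %d bp; peg nick @%d; nicking sgRNA @%s\n",
              x$name, x$length, x$peg_nick,
              if (is.null(x$nick_sgrna_nick)) "-" else x$nick_sgrna_nick))
  invisible(x)
}

#' Describe an intended prime edit
#'
#' The intended sequence change written by the pegRNA, the optional synonymous
#' PAM modification installed alongside it, and the quantification window
#' within which a read must match the edited allele exactly to be called a
#' precise edit.
#'
#' @param type One of `"substitution"`, `"insertion"`, `"deletion"`,
#'   `"replacement"`.
#' @param ref_start,ref_end Half-open interval on the amplicon replaced by the
#'   edit (equal for a pure insertion).
#' @param alt Installed segment (empty string for a pure deletion).
#' @param pam_mod Optional `list(pos =, ref =, alt =)` single-base synonymous
#'   PAM change.
#' @param quant_window Half-open interval; must cover the edit and the PAM
#'   modification.
#' @return An object of class `edit_spec`.
#' @export
edit_spec <- function(type = c("substitution", "insertion", "deletion", "replacement"),
                      ref_start, ref_end, alt = "", pam_mod = NULL, quant_window) {
  type <- match.arg(type)
  check_dna(alt, "alt segment", allow_n = FALSE)
  ref_start <- as.integer(ref_start); ref_end <- as.integer(ref_end)
  if (ref_start > ref_end) abort("ref interval must satisfy start <= end")
  la <- nchar(alt); lr <- ref_end - ref_start
  if (type == "substitution" && la != lr)
    abort("substitution requires len(alt) == len(ref interval)")
  if (type == "deletion" && la != 0) abort("deletion requires empty alt segment")
  if (type == "insertion" && (lr != 0 || la == 0))
    abort("insertion requires an empty ref interval and non-empty alt")
  if (!is.null(pam_mod)) {
    if (!all(c("pos", "ref", "alt") %in% names(pam_mod)))
      abort("pam_mod must have fields pos, ref, alt")
    pam_mod$pos <- as.integer(pam_mod$pos)
  }
  if (length(quant_window) != 2 || quant_window[1] > quant_window[2])
    abort("quant_window must be half-open [start, end)")
  structure(list(type = type, ref_start = ref_start, ref_end = ref_end, alt = alt,
                 pam_mod = pam_mod, quant_window = as.integer(quant_window)),
            class = "edit_spec")
}

#' @export
print.edit_spec <- function(x, ...) {
  cat(sprintf("<edit_spec> %s [%d,%d) -> '%s'%s; window [%d,%d)\n",
              x$type, x$ref_start, x$ref_end,
              if (nchar(x$alt) > 12) paste0(substr(x$alt, 1, 12), "...") else x$alt,
              if (is.null(x$pam_mod)) "" else
                sprintf("; PAM %s>%s @%d", x$pam_mod$ref, x$pam_mod$alt, x$pam_mod$pos),
              x$quant_window[1], x$quant_window[2]))
  invisible(x)
}

#' Validate an edit specification against its amplicon
#'
#' Checks interval bounds, that the PAM-modification reference base matches
#' the amplicon, and that the quantification window covers both the edit and
#' the PAM position. Called by [build_edited_allele()] and the config parser.
#'
#' @param amplicon An [amplicon_spec()].
#' @param edit An [edit_spec()].
#' @return The edit, invisibly; errors describe the offending field.
#' @export
validate_edit <- function(amplicon, edit) {
  len <- amplicon$length
  if (edit$ref_start < 0 || edit$ref_end > len)
    abort(sprintf("edit ref interval [%d,%d) outside amplicon [0,%d)",
                  edit$ref_start, edit$ref_end, len))
  qw <- edit$quant_window
  if (qw[1] < 0 || qw[2] > len) abort("quant_window outside amplicon")
  if (qw[1] > edit$ref_start || qw[2] < edit$ref_end)
    abort("quant_window must cover the edit ref interval")
  pm <- edit$pam_mod
  if (!is.null(pm)) {
    if (pm$pos < 0 || pm$pos >= len) abort("pam_mod position outside amplicon")
    have <- substr0(amplicon$sequence, pm$pos, pm$pos + 1L)
    if (!identical(have, pm$ref))
      abort(sprintf("pam_mod ref base mismatch at position %d: amplicon has '%s', spec says '%s'",
                    pm$pos, have, pm$ref))
    if (pm$pos < qw[1] || pm$pos >= qw[2])
      abort("quant_window must cover the pam_mod position")
  }
  invisible(edit)
}

#' Construct the edited-allele reference
#'
#' Splices the intended edit (and the synonymous PAM modification) into the
#' amplicon sequence, returning the edited-allele sequence together with a
#' monotone coordinate map back to the original amplicon.
#'
#' @inheritParams validate_edit
#' @return An object of class `edited_allele` with fields `sequence`,
#'   `coordinate_map` (0-based original position per edited base, `NA` for
#'   inserted bases), and `delta` (net length change).
#' @export
build_edited_allele <- function(amplicon, edit) {
  validate_edit(amplicon, edit)
  s <- amplicon$sequence
  pre <- substr0(s, 0L, edit$ref_start)
  post <- substr0(s, edit$ref_end, amplicon$length)
  seq <- paste0(pre, edit$alt, post)
  map <- c(if (edit$ref_start > 0) 0:(edit$ref_start - 1L) else integer(0),
           rep(NA_integer_, nchar(edit$alt)),
           if (edit$ref_end < amplicon$length) edit$ref_end:(amplicon$length - 1L) else integer(0))
  pm <- edit$pam_mod
  if (!is.null(pm)) {
    epos <- map_to_edited(edit, pm$pos)
    if (is.na(epos)) abort("pam_mod position falls inside the replaced interval")
    substr(seq, epos + 1L, epos + 1L) <- pm$alt
  }
  structure(list(sequence = seq, coordinate_map = map,
                 delta = nchar(edit$alt) - (edit$ref_end - edit$ref_start)),
            class = "edited_allele")
}

# map an amplicon position to edited-allele coordinates (NA if deleted)
map_to_edited <- function(edit, pos) {
  delta <- nchar(edit$alt) - (edit$ref_end - edit$ref_start)
  if (pos < edit$ref_start) return(as.integer(pos))
  if (pos >= edit$ref_end) return(as.integer(pos + delta))
  NA_integer_
}

# the quantification window expressed in edited-allele coordinates;
# valid because the window is required to cover the ref interval
edited_window <- function(edit) {
  delta <- nchar(edit$alt) - (edit$ref_end - edit$ref_start)
  c(edit$quant_window[1], edit$quant_window[2] + delta)
}

#' Parse and serialize the edit-spec run configuration
#'
#' The configuration is JSON with an `amplicon` block (`name`, `sequence` or
#' `fasta_path`, nick offsets, intervals) and an `edit` block (`type`,
#' `ref_start`, `ref_end`, `alt`, optional `pam_mod`, `quant_window`), plus
#' free-form run `params`. All model invariants are validated on parse.
#'
#' @param text JSON text, or a path to a JSON file.
#' @return A list with elements `amplicon` ([amplicon_spec()]),
#'   `edit` ([edit_spec()]) and `params` (a list, possibly empty).
#' @export
parse_edit_config <- function(text) {
  if (length(text) == 1 && !grepl("[{]", text) && file.exists(text))
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  cfg <- jsonlite::fromJSON(text, simplifyVector = TRUE)
  a <- cfg$amplicon
  if (is.null(a)) abort("config missing required block: amplicon")
  seq <- a$sequence
  if (is.null(seq)) {
    if (is.null(a$fasta_path)) abort("amplicon block needs 'sequence' or 'fasta_path'")
    ss <- Biostrings::readDNAStringSet(a$fasta_path)
    seq <- as.character(ss[[1]])
  }
  need <- function(x, field) {
    if (is.null(x)) abort(sprintf("config missing required field: %s", field))
    x
  }
  amp <- amplicon_spec(
    name = need(a$name, "amplicon.name"), sequence = toupper(seq),
    peg_nick = need(a$peg_nick, "amplicon.peg_nick"),
    nick_sgrna_nick = a$nick_sgrna_nick,
    peg_strand = a$peg_strand %||% "+", nick_strand = a$nick_strand %||% "-",
    pam_interval = a$pam_interval, uditas_primer_interval = a$uditas_primer_interval)
  e <- need(cfg$edit, "edit")
  ed <- edit_spec(type = need(e$type, "edit.type"),
                  ref_start = need(e$ref_start, "edit.ref_start"),
                  ref_end = need(e$ref_end, "edit.ref_end"),
                  alt = e$alt %||% "",
                  pam_mod = if (is.null(e$pam_mod)) NULL else as.list(e$pam_mod),
                  quant_window = need(e$quant_window, "edit.quant_window"))
  validate_edit(amp, ed)
  list(amplicon = amp, edit = ed, params = cfg$params %||% list())
}

#' @rdname parse_edit_config
#' @param amplicon,edit,params Components to serialize.
#' @export
write_edit_config <- function(amplicon, edit, params = list()) {
  cfg <- list(
    amplicon = list(name = amplicon$name, sequence = amplicon$sequence,
                    peg_nick = amplicon$peg_nick,
                    nick_sgrna_nick = amplicon$nick_sgrna_nick,
                    peg_strand = amplicon$peg_strand, nick_strand = amplicon$nick_strand,
                    pam_interval = amplicon$pam_interval,
                    uditas_primer_interval = amplicon$uditas_primer_interval),
    edit = list(type = edit$type, ref_start = edit$ref_start, ref_end = edit$ref_end,
                alt = edit$alt, pam_mod = edit$pam_mod, quant_window = edit$quant_window),
    params = params)
  jsonlite::toJSON(cfg, auto_unbox = TRUE, null = "null", digits = NA, pretty = TRUE)
}
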