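# Ground-truth library simulator. Emulates the two library types the pipeline
# quantifies: (i) targeted amplicon libraries (optionally UMI-tagged by linear
# pre-amplification) sequenced as 150-bp paired-end reads spanning the whole
# amplicon, and (ii) UDiTaS libraries with read 2 anchored at the
# locus-specific primer and a Tn5-style random fragment end on the read-1
# side, including AAV-fragment insertion chimeras and false-priming reads.
#
# Synthetic loci are random sequences carrying the real designs' geometry
# (edit offsets, nick spacing, PAM, primer footprints) — no genomic sequence
# is fetched. Family sizes are geometric: the statistical consequence of
# linear pre-amplification plus exponential PCR that matters to the pipeline
# (dispersed family sizes, one UMI per molecule), not a mechanistic PCR model.

SIM_CATEGORIES <- c("wild_type", "precise_edit", "small_indel_sub",
                    "pegnick_deletion", "large_deletion", "aav_integration")

#' Simulation configuration
#'
#' @param amplicon An [amplicon_spec()].
#' @param edit An [edit_spec()].
#' @param mixture Named numeric vector of true outcome fractions over the
#'   categories `wild_type`, `precise_edit`, `small_indel_sub`,
#'   `pegnick_deletion`, `large_deletion`, `aav_integration`; must sum to 1.
#' @param n_molecules Number of original molecules.
#' @param umi Either `NULL` (no UMI) or a [umi_scheme()].
#' @param umi_length UMI length (default 12).
#' @param family_mean Mean of the geometric family-size model (default 4).
#' @param error_rate Per-base substitution error rate `e` in `[0, 0.05]`
#'   (default 0.001).
#' @param q20_fraction Fraction of reads carrying one base labelled Q20
#'   instead of the constant `Q = round(-10 log10 e)`, so that the quality
#'   filter is exercised without length-dependent selection (default 0.02).
#' @param read_length Read length (default 150, paired-end).
#' @param mode `"amplicon"` (fixed fragment ends) or `"uditas"` (fixed primer
#'   end, uniform Tn5 end).
#' @param aav_ref AAV/plasmid reference sequence (required when the mixture
#'   includes `aav_integration` or `false_priming_fraction > 0`).
#' @param false_priming_fraction Fraction of the final UDiTaS library that is
#'   false-priming reads (locus primer on AAV template, no locus sequence).
#' @param seed Integer seed; every downstream draw derives from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(amplicon, edit, mixture, n_molecules = 10000L,
                       umi = NULL, umi_length = 12L, family_mean = 4,
                       error_rate = 0.001, q20_fraction = 0.02,
                       read_length = 150L, mode = c("amplicon", "uditas"),
                       aav_ref = NULL, false_priming_fraction = 0, seed = 1L) {
  mode <- match.arg(mode)
  mix <- setNames(numeric(length(SIM_CATEGORIES)), SIM_CATEGORIES)
  if (is.null(names(mixture)) || !all(names(mixture) %in% SIM_CATEGORIES))
    abort(sprintf("mixture names must be among: %s", paste(SIM_CATEGORIES, collapse = ", ")))
  mix[names(mixture)] <- mixture
  if (abs(sum(mix) - 1) > 1e-9) abort("mixture must sum to 1")
  if (n_molecules < 1) abort("n_molecules must be >= 1")
  if (error_rate < 0 || error_rate > 0.05) abort("error_rate must lie in [0, 0.05]")
  if ((mix[["aav_integration"]] > 0 || false_priming_fraction > 0) && is.null(aav_ref))
    abort("aav_ref is required for AAV-integration or false-priming simulation")
  structure(list(amplicon = amplicon, edit = edit,
                 edited = build_edited_allele(amplicon, edit),
                 mixture = mix, n_molecules = as.integer(n_molecules),
                 umi = umi, umi_length = as.integer(umi_length),
                 family_mean = family_mean, error_rate = error_rate,
                 q20_fraction = q20_fraction, read_length = as.integer(read_length),
                 mode = mode, aav_ref = aav_ref,
                 false_priming_fraction = false_priming_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw labelled molecules from the outcome mixture
#'
#' Each molecule is drawn i.i.d. from the configured mixture; event molecules
#' are constructed by splicing: small indels (1-49 bp) and window
#' substitutions near the pegRNA nick, deletions spanning both nicks below
#' 100 bp, large deletions of 100 bp and above, and locus-AAV junction
#' chimeras. Deterministic under the config seed.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed override. The default is offset from the config
#'   seed so that molecule construction, reference construction and
#'   amplification draw from unrelated RNG streams (replaying one stream
#'   would correlate "random" insertions with reference sequence).
#' @return Tibble `molecule_id, category, sequence, event_kind, event_start,
#'   event_end, event_size` with a `realized_fractions` attribute.
#' @export
simulate_molecules <- function(config, seed = config$seed + 500009L) {
  set.seed(seed)
  amp <- config$amplicon; edit <- config$edit
  s <- amp$sequence; len <- amp$length
  nicks <- sort(c(amp$peg_nick, amp$nick_sgrna_nick %||% integer(0)))
  n <- config$n_molecules
  cats <- sample(SIM_CATEGORIES, n, replace = TRUE, prob = config$mixture)
  seqs <- character(n)
  ek <- rep(NA_character_, n); es <- rep(NA_integer_, n)
  ee <- rep(NA_integer_, n); esz <- rep(NA_integer_, n)
  primer_end <- if (!is.null(amp$uditas_primer_interval)) amp$uditas_primer_interval[2] else 0L
  for (i in seq_len(n)) {
    ci <- cats[i]
    if (ci == "wild_type") {
      seqs[i] <- s
    } else if (ci == "precise_edit") {
      seqs[i] <- config$edited$sequence
    } else if (ci == "small_indel_sub") {
      kind <- sample(c("deletion", "insertion", "substitution"), 1,
                     prob = c(0.4, 0.4, 0.2))
      if (kind == "substitution") {
        qw <- edit$quant_window
        pos <- sample(qw[1]:(qw[2] - 1L), 1)
        old <- substr0(s, pos, pos + 1L)
        new <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
        seqs[i] <- s
        substr(seqs[i], pos + 1L, pos + 1L) <- new
        ek[i] <- "substitution"; es[i] <- pos; ee[i] <- pos + 1L; esz[i] <- 1L
      } else if (kind == "deletion") {
        size <- sample(1:49, 1)
        start <- max(primer_end + 1L, amp$peg_nick - sample(0:5, 1))
        start <- min(start, len - size - 1L)
        seqs[i] <- paste0(substr0(s, 0L, start), substr0(s, start + size, len))
        ek[i] <- "deletion"; es[i] <- start; ee[i] <- start + size; esz[i] <- size
      } else {
        size <- sample(1:49, 1)
        ins <- random_dna(size)
        p <- amp$peg_nick
        seqs[i] <- paste0(substr0(s, 0L, p), ins, substr0(s, p, len))
        ek[i] <- "insertion"; es[i] <- p; ee[i] <- p; esz[i] <- size
      }
    } else if (ci == "pegnick_deletion") {
      if (length(nicks) < 2) abort("pegnick_deletion requires both nick positions")
      spacing <- nicks[2] - nicks[1]
      size <- sample(spacing:99, 1)
      start <- sample((nicks[2] - size):nicks[1], 1)
      seqs[i] <- paste0(substr0(s, 0L, start), substr0(s, start + size, len))
      ek[i] <- "deletion"; es[i] <- start; ee[i] <- start + size; esz[i] <- size
    } else if (ci == "large_deletion") {
      lo <- primer_end + 30L
      hi <- min(config$read_length - 30L, len - 131L)
      start <- sample(lo:hi, 1)
      max_size <- min(400L, len - start - 30L)
      size <- sample(100:max_size, 1)
      seqs[i] <- paste0(substr0(s, 0L, start), substr0(s, start + size, len))
      ek[i] <- "deletion"; es[i] <- start; ee[i] <- start + size; esz[i] <- size
    } else { # aav_integration: junction near the pegRNA nick, within read 2
      j_hi <- min(nicks[1] + 25L, config$read_length - 25L)
      j <- sample(max(primer_end + 25L, nicks[1] - 10L):j_hi, 1)
      amax <- nchar(config$aav_ref) - 401L
      a0 <- sample(0:amax, 1)
      frag <- substr0(config$aav_ref, a0, a0 + 400L)
      seqs[i] <- paste0(substr0(s, 0L, j), frag)
      ek[i] <- "aav_junction"; es[i] <- j; ee[i] <- j; esz[i] <- 400L
    }
  }
  out <- tibble(molecule_id = sprintf("M%06d", seq_len(n)), category = cats,
                sequence = seqs, event_kind = ek, event_start = es,
                event_end = ee, event_size = esz)
  attr(out, "realized_fractions") <-
    setNames(as.numeric(table(factor(cats, levels = SIM_CATEGORIES))) / n,
             SIM_CATEGORIES)
  out
}

#' Amplify molecules and emit sequenced read pairs
#'
#' Each molecule receives a distinct random UMI and a geometric family size
#' with the configured mean; each copy becomes one read pair with independent
#' per-base substitution errors at rate `e` and quality strings at constant
#' `Q = round(-10 log10 e)` with a `q20_fraction` of bases labelled Q20.
#' Amplicon mode reads the two fragment ends; UDiTaS mode anchors read 2 at
#' the primer and draws the read-1 (Tn5) end uniformly. False-priming reads
#' (primer + AAV, no locus) are injected at the configured library fraction.
#'
#' @param molecules Result of [simulate_molecules()].
#' @param config The same [sim_config()].
#' @param seed Optional seed override (offset from the config seed; see
#'   [simulate_molecules()]).
#' @return List with `r1`, `r2` (read tibbles), and `truth` (read-pair level:
#'   `read_id`, `molecule_id`, `category`, `umi`, `family_size`).
#' @export
amplify_and_sequence <- function(molecules, config, seed = config$seed + 1000003L) {
  set.seed(seed)
  n <- nrow(molecules)
  rl <- config$read_length
  mode <- config$mode
  umis <- vapply(seq_len(n), function(i) random_dna(config$umi_length), character(1))
  fam <- 1L + rgeom(n, prob = 1 / config$family_mean)
  mol_seq <- molecules$sequence
  mol_cat <- molecules$category
  mol_id <- molecules$molecule_id
  # false-priming molecules are extra library members (UDiTaS only)
  if (config$false_priming_fraction > 0 && mode == "uditas") {
    f <- config$false_priming_fraction
    n_fp <- round(f / (1 - f) * n)
    if (n_fp > 0) {
      pi <- config$amplicon$uditas_primer_interval
      if (is.null(pi)) abort("false priming requires uditas_primer_interval")
      primer <- substr0(config$amplicon$sequence, pi[1], pi[2])
      amax <- nchar(config$aav_ref) - 401L
      fp_seq <- vapply(seq_len(n_fp), function(i) {
        a0 <- sample(0:amax, 1)
        paste0(primer, substr0(config$aav_ref, a0, a0 + 400L))
      }, character(1))
      mol_seq <- c(mol_seq, fp_seq)
      mol_cat <- c(mol_cat, rep("false_priming", n_fp))
      mol_id <- c(mol_id, sprintf("FP%06d", seq_len(n_fp)))
      umis <- c(umis, vapply(seq_len(n_fp), function(i) random_dna(config$umi_length),
                             character(1)))
      fam <- c(fam, 1L + rgeom(n_fp, prob = 1 / config$family_mean))
    }
  }
  ncopies <- sum(fam)
  mol_of <- rep(seq_along(mol_seq), fam)
  copy_no <- sequence(fam)
  lens <- nchar(mol_seq)[mol_of]
  if (mode == "amplicon") {
    frag <- mol_seq[mol_of]
    b1 <- substr(frag, 1L, pmin(rl, lens))
    b2 <- revcomp(substr(frag, pmax(1L, lens - rl + 1L), lens))
    if (!is.null(config$umi) && config$umi$source == "read_prefix") {
      b1 <- paste0(umis[mol_of], substr(b1, 1L, rl - config$umi$length))
    }
    ids <- sprintf("%s:%d", mol_id[mol_of], copy_no)
  } else {
    # Tn5 fragment end; the 200 bp floor reflects library size selection
    tn5 <- floor(runif(ncopies, min = pmin(200L, lens), max = lens + 1L))
    tn5 <- pmin(tn5, lens)
    frag <- substr(mol_seq[mol_of], 1L, tn5)
    b2 <- substr(frag, 1L, pmin(rl, tn5))
    b1 <- revcomp(substr(frag, pmax(1L, tn5 - rl + 1L), tn5))
    ids <- sprintf("%s.%d:%s", mol_id[mol_of], copy_no, umis[mol_of])
  }
  b1 <- add_errors(b1, config$error_rate)
  b2 <- add_errors(b2, config$error_rate)
  q1 <- make_quals(nchar(b1), config$error_rate, config$q20_fraction)
  q2 <- make_quals(nchar(b2), config$error_rate, config$q20_fraction)
  r1 <- tibble(read_id = ids, bases = b1, qual = q1, mate = "R1")
  r2 <- tibble(read_id = ids, bases = b2, qual = q2, mate = "R2")
  truth <- tibble(read_id = ids, molecule_id = mol_id[mol_of],
                  category = mol_cat[mol_of], umi = umis[mol_of],
                  family_size = fam[mol_of])
  list(r1 = r1, r2 = r2, truth = truth)
}

# independent per-base substitution errors at rate e
add_errors <- function(bases, e) {
  if (e <= 0) return(bases)
  lens <- nchar(bases)
  k <- rbinom(length(bases), lens, e)
  hit <- which(k > 0)
  for (i in hit) {
    pos <- sample.int(lens[i], k[i])
    for (p in pos) {
      old <- substr(bases[i], p, p)
      substr(bases[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
    }
  }
  bases
}

# Constant high quality; a q20_frac fraction of reads carries one Q20-labelled
# base at a random position so the downstream mean/min quality filter has
# genuine work to do. The label is assigned per read, not per base: a
# per-base model would make the any-low-base discard probability grow with
# read length, selecting systematically for deletion alleles over insertion
# alleles and corrupting every length-changing outcome fraction downstream.
make_quals <- function(lens, e, q20_frac) {
  qhi <- if (e > 0) min(41L, as.integer(round(-10 * log10(e)))) else 40L
  hi_char <- intToUtf8(qhi + 33L)
  lo_char <- intToUtf8(20L + 33L)
  out <- vapply(lens, function(L) strrep(hi_char, L), character(1))
  if (q20_frac > 0) {
    hit <- which(runif(length(lens)) < q20_frac & lens > 0)
    pos <- vapply(lens[hit], sample.int, integer(1), size = 1L)
    for (k in seq_along(hit)) {
      i <- hit[k]
      substr(out[i], pos[k], pos[k]) <- lo_char
    }
  }
  out
}

#' Built-in fixture scenarios
#'
#' Constructs the synthetic locus, edit specification and simulation
#' configuration for a named scenario. Loci are random sequences with the
#' real designs' geometry: `serpina1_correction` (1-bp A-to-G correction plus
#' a 1-bp synonymous AGG-to-AAG PAM modification), `ctnnb1_s45f` (1-bp C-to-T
#' substitution), `ctnnb1_s45del` (3-bp TCC deletion), `ccr5_del` (32-bp
#' deletion, UMI-tagged library), and `uditas_aav` (UDiTaS library on a
#' 600-bp locus with large deletions, AAV-fragment insertions and false
#' priming).
#'
#' @param scenario Scenario name.
#' @param seed Integer seed controlling the synthetic locus and library.
#' @param n_molecules Override the scenario's molecule count.
#' @param ... Further [sim_config()] fields to override (e.g. `mixture`,
#'   `error_rate`, `false_priming_fraction`).
#' @return A [sim_config()].
#' @export
scenario_config <- function(scenario, seed = 1L, n_molecules = NULL, ...) {
  scenarios <- c("serpina1_correction", "ctnnb1_s45f", "ctnnb1_s45del",
                 "ccr5_del", "uditas_aav")
  if (!scenario %in% scenarios)
    abort(sprintf("unknown scenario '%s'; valid scenarios: %s",
                  scenario, paste(scenarios, collapse = ", ")))
  set.seed(seed)
  force_motif <- function(s, at, motif) {
    substr(s, at + 1L, at + nchar(motif)) <- motif
    s
  }
  if (scenario == "uditas_aav") {
    s <- random_dna(600)
    s <- force_motif(s, 93L, "AGG")   # PAM
    s <- force_motif(s, 99L, "A")     # target base
    amp <- amplicon_spec("uditas_locus_synthetic", s, peg_nick = 90L,
                         nick_sgrna_nick = 150L, pam_interval = c(93L, 96L),
                         uditas_primer_interval = c(0L, 20L))
    ed <- edit_spec("substitution", 99L, 100L, alt = "G",
                    pam_mod = list(pos = 94L, ref = substr(s, 95, 95), alt = flip_base(substr(s, 95, 95))),
                    quant_window = c(88L, 102L))
    args <- list(amplicon = amp, edit = ed,
                 mixture = c(wild_type = 0.95126, precise_edit = 0.0310,
                             small_indel_sub = 0.0060, pegnick_deletion = 0.0080,
                             large_deletion = 0.0036, aav_integration = 0.00014),
                 n_molecules = n_molecules %||% 10000L,
                 umi = umi_scheme("header", 12L), mode = "uditas",
                 aav_ref = random_dna(2000), false_priming_fraction = 0.05,
                 seed = seed)
  } else {
    s <- random_dna(220)
    s <- force_motif(s, 103L, "AGG")
    # plain amplicon libraries carry no molecular tag: one read pair per molecule
    base <- list(n_molecules = n_molecules %||% 10000L, mode = "amplicon",
                 family_mean = 1, seed = seed)
    if (scenario == "serpina1_correction") {
      s <- force_motif(s, 109L, "A")
      amp <- amplicon_spec("serpina1_synthetic", s, peg_nick = 100L,
                           nick_sgrna_nick = 160L, pam_interval = c(103L, 106L))
      ed <- edit_spec("substitution", 109L, 110L, alt = "G",
                      pam_mod = list(pos = 104L, ref = "G", alt = "A"),
                      quant_window = c(98L, 112L))
      args <- c(list(amplicon = amp, edit = ed,
                     mixture = c(wild_type = 0.906, precise_edit = 0.067,
                                 small_indel_sub = 0.027)), base)
    } else if (scenario == "ctnnb1_s45f") {
      s <- force_motif(s, 109L, "C")
      amp <- amplicon_spec("ctnnb1_s45f_synthetic", s, peg_nick = 100L,
                           nick_sgrna_nick = 160L, pam_interval = c(103L, 106L))
      ed <- edit_spec("substitution", 109L, 110L, alt = "T",
                      quant_window = c(98L, 114L))
      args <- c(list(amplicon = amp, edit = ed,
                     mixture = c(wild_type = 0.15, precise_edit = 0.80,
                                 small_indel_sub = 0.05)), base)
    } else if (scenario == "ctnnb1_s45del") {
      s <- force_motif(s, 106L, "TCC")
      amp <- amplicon_spec("ctnnb1_s45del_synthetic", s, peg_nick = 100L,
                           nick_sgrna_nick = 160L, pam_interval = c(103L, 106L))
      ed <- edit_spec("deletion", 106L, 109L, alt = "",
                      quant_window = c(98L, 114L))
      args <- c(list(amplicon = amp, edit = ed,
                     mixture = c(wild_type = 0.15, precise_edit = 0.80,
                                 small_indel_sub = 0.05)), base)
    } else { # ccr5_del
      amp <- amplicon_spec("ccr5_synthetic", s, peg_nick = 95L,
                           nick_sgrna_nick = 155L, pam_interval = c(103L, 106L))
      ed <- edit_spec("deletion", 95L, 127L, alt = "",
                      quant_window = c(92L, 130L))
      args <- c(list(amplicon = amp, edit = ed,
                     mixture = c(wild_type = 0.930, precise_edit = 0.060,
                                 small_indel_sub = 0.010),
                     umi = umi_scheme("read_prefix", 8L)), base)
      args$family_mean <- 4 # UMI-tagged library: dispersed family sizes
    }
  }
  args <- utils::modifyList(args, list(...))
  do.call(sim_config, args)
}

flip_base <- function(b) c(A = "G", G = "A", C = "T", T = "C")[[b]]

#' Generate a complete end-to-end fixture
#'
#' Runs [simulate_molecules()] and [amplify_and_sequence()] for a named
#' scenario; optionally writes FASTQ pairs, the truth table (TSV) and the
#' config (JSON) to a directory. Byte-identical under a fixed seed.
#'
#' @inheritParams scenario_config
#' @param dir Optional output directory.
#' @return List: `config`, `molecules`, `reads` (list `r1`, `r2`), `truth`.
#' @export
end_to_end_fixture <- function(scenario, seed = 1L, n_molecules = NULL, dir = NULL, ...) {
  config <- scenario_config(scenario, seed = seed, n_molecules = n_molecules, ...)
  molecules <- simulate_molecules(config)
  seqd <- amplify_and_sequence(molecules, config)
  out <- list(config = config, molecules = molecules,
              reads = list(r1 = seqd$r1, r2 = seqd$r2), truth = seqd$truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_fastq(seqd$r1, file.path(dir, paste0(scenario, "_R1.fastq")))
    write_fastq(seqd$r2, file.path(dir, paste0(scenario, "_R2.fastq")))
    utils::write.table(seqd$truth, file.path(dir, paste0(scenario, "_truth.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(write_edit_config(config$amplicon, config$edit,
                                 params = list(scenario = scenario, seed = seed)),
               file.path(dir, paste0(scenario, "_config.json")))
  }
  out
}
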