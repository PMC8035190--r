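---
title: "Quantifying prime-editing outcomes: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying prime-editing outcomes: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pequant)
```

# The measurement problem

A prime editor installs a pegRNA-templated change at a nick; in the PE3
configuration a second sgRNA nicks the opposite strand. The repair outcome at
a treated locus is a mixture: the intended allele, unedited molecules, small
indels and partial edits near the nicks, deletions between the two nick
sites, occasional large deletions, and — after AAV delivery — vector-fragment
capture at the break. `pequant` quantifies this mixture from two library
types: conventional targeted amplicons (precise-edit and indel rates) and
UDiTaS unidirectional libraries (UMI-resolved allele categories including
large deletions and AAV integrations).

Everything downstream rests on a small coordinate model: 0-based, half-open
intervals on the top strand; nick positions as between-base offsets (a nick
at $k$ separates bases $k-1$ and $k$); reverse-strand guides stored with
top-strand coordinates plus an orientation flag. The edited-allele reference
is constructed by splicing the intended change (and the synonymous PAM
modification) into the amplicon, with a monotone coordinate map back to the
original.

# Amplicon mode

The stage order is: paired-end merging, quality filtering, alignment, outcome
calling, indel cataloguing, control subtraction.

**Merging.** Read 2 is reverse-complemented and the overlap maximizing
matched bases is chosen (ties toward the longer overlap; defaults
`min_overlap = 10`, ≤ 10% mismatches — the merger's exact settings are not
prescribed by the protocol we emulate, so they are exposed in the API). In
disagreeing columns the higher-quality base wins and the column quality is
the maximum of the two.

**Quality filter.** A read is kept iff its mean Phred score is ≥ 30 *and*
its minimum per-base score is ≥ 24. The removal condition is stated as
"under 30 / under 24", so the boundary values 30 and 24 are kept — the filter
tests in `tests/testthat/` pin exactly this.

**Outcome calling.** A read is `precise_edit` iff its quantification-window
sequence equals the edited allele's window exactly: the intended edit *and*
the PAM modification present, and nothing else in the window. There is no
error tolerance — a sequencing error inside the window demotes the read to
`substitution_other` (or to `indel` when the intended edit is itself an
indel, since the intended deletion/insertion still registers as an event
against the unedited reference). This is deliberate: tolerating errors would
require a quality model the read-level "desired allele" definition does not
provide. The demoted fraction is predictable, $1-(1-e)^W$ per read for a
$W$-base window at error rate $e$, and the recovery tests carry exactly this
analytic allowance.

**The quantification window** is a config field, not a constant. The original
analysis does not state its extent, so each scenario uses a window spanning
from just upstream of the pegRNA nick through the edit and PAM positions
(10–40 bp) — the field's usual nick-centred choice. A tight window makes the
precise/wild-type calls robust to unrelated errors elsewhere in the read;
out-of-window events are reported separately rather than folded into the
call.

**Indel catalog and background subtraction.** Events are catalogued per key
(kind, position, length, allele) with read-fraction frequencies over all
passing reads; the catalog deliberately includes every event from every read
(including a deletion-type intended edit in precise reads) — summary-level
precise/indel rates come from read calls, the catalog is the per-position
reporting and subtraction table. Subtraction removes, per key, the *mean*
frequency across the control catalogs (absent keys count zero), floored at
zero. Keys are stricter than type+position alone so a control artifact at a
position cannot cancel a different event type there. Subtraction never
touches precise-edit counting.

**UMI-tagged amplicons** (linear pre-amplification with a UMI-bearing
primer): reads carry the UMI as an 8-bp read prefix, and passing reads are
collapsed to one exemplar per family before calling, making all denominators
molecule counts rather than read counts.

# The alignment engine

Amplicon references are a few hundred bases, so full dynamic programming
replaces seed-and-extend mapping. Three modes share one affine-gap core
(Gotoh three-state DP, implemented in C++): global, *fitting* (the read end
to end, reference ends free — the end-to-end semantics a short-read aligner
applies to a primer-anchored partial-span read), and local. Scoring defaults
(+2/−4, gap open −8, extend −1; a gap of length $L$ costs open + $L$·extend;
`N` scores 0 against anything) favour one long contiguous indel over
scattered gaps, matching how contiguous pegRNA-programmed deletions present.
Tie-breaking is fixed — diagonal over deletion over insertion — so alignments
are bit-reproducible across platforms; the test suite additionally checks
score equality against a brute-force path-enumeration oracle (all tiny pairs)
and an independently coded plain-R Gotoh oracle, plus
`Biostrings::pairwiseAlignment()` as an external cross-check.

**Event normalization.** Indels are shifted to their leftmost equivalent
placement (the VCF convention), with other events acting as anchors, and
adjacent same-kind events merged. Left-alignment is what makes position-keyed
background subtraction meaningful: treatment and control must key the same
molecular event identically.

**Complex replacements.** A replacement (delete one segment, insert another)
has no unique decomposition into elementary events on arbitrary sequence —
the optimal alignment may thread short spurious matches through the replaced
region. `collapse_complex_events()` merges runs of events separated by at
most 25 matched bases into one `replacement` block whose reference span and
alternate segment are decomposition-invariant.

**Split alignment.** Reads whose per-base identity (matches over
query-consuming columns) falls below 0.95 and whose end-to-end alignment did
not already place a clean gap are split: the best local segment is anchored,
the unaligned prefix or suffix (each ≥ 25 bp at ≥ 95% identity) is re-aligned
to the flanking reference, and collinear segment pairs yield a deleted
interval with microhomology assigned leftmost, so equivalent junction
placements coincide exactly. The per-base identity router matters: a fitting
alignment can produce mid-scoring spurious alignments for deletions of
several hundred bases, while the split reconstruction recovers the exact
breakpoints.

# UDiTaS mode

Only read 2 is anchored at the locus-specific primer; read 1 carries the Tn5
end. Classification therefore runs on the R2 stream (the UMI rides in the
read header, emulating its position in the index read). There is no mean/min
quality filter in this mode — the protocol we emulate applies that filter to
amplicon libraries only; UMI-family collapsing plays the corresponding
error-suppression role here.

Families are collapsed to an exemplar — the most frequent member sequence,
ties by highest summed quality, then lexicographically smallest — and each
exemplar is classified into exactly one category, with precedence:

1. **AAV integration**: local alignment to the AAV/plasmid reference scores
   ≥ 40 (both strands tried; an 11-mer seed restricts the DP to the matching
   diagonal window) *and* the read is not a false-priming artifact. False
   priming — the AAV hit begins directly adjacent to the primer footprint
   (≤ 5 bp) and the read contains no exact 15-mer of locus sequence beyond
   the primer — is removed from the library entirely (counted in the
   manifest), mirroring the original filter. Junction evidence outranks all
   other categories because it is physical, not inferential.
2. **Precise edit**, per the amplicon-mode definition (coverage evaluated in
   edited-allele coordinates).
3. **pegRNA–nick deletion**: a deletion spanning both nick positions at size
   ≤ 99 bp. "Spanning" is tested over *all* microhomology-equivalent
   placements of the deletion, not just the left-normalized one.
4. **Small indel/substitution**: any indel of 1–49 bp; or a substitution
   inside the quantification window (partial edits present exactly there)
   carried by ≥ 2 family members. A substitution seen in a single read is
   indistinguishable from a sequencing error — the reason UMIs are collapsed
   at all — so uncorroborated substitution-only families are conservatively
   called wild type; indel errors at these quality levels are orders of
   magnitude rarer and need no corroboration. The cost is that genuine
   partial edits in single-read families are folded into wild type; the
   benefit is that the small-indel/substitution category is not inflated by
   read noise.
5. **Large deletion**: ≥ 100 bp (a deletion of exactly 100 bp is large; the
   published size labels leave 100 itself ambiguous). Breakpoints come from
   the end-to-end alignment's own gap when it found one, otherwise from split
   alignment. Checked before the small-indel rule so a family with both a
   stray substitution and a 300-bp deletion is called by its deletion.
6. **Wild type**: no molecular events. Reads not observing the nick-to-nick
   window (and carrying no indel evidence) are `unclassified`, never
   silently dropped.

Category counts over families sum exactly to the analysed-UMI total;
integration UMIs are included in the denominator of every ratio.

**Recurrent-deletion significance.** Families with identical normalized
breakpoints form clusters. Each cluster is tested with a one-sided binomial
tail $P(X \ge k \mid n = \text{total UMIs}, p = p_0)$ against a background
rate $p_0$ estimated from matched controls as $(x + 0.5)/(n + 1)$ (a
Jeffreys-style pseudo-count; with no controls supplied the no-event estimate
is used), followed by Benjamini–Hochberg adjustment across clusters and a
0.05 cut-off. The null model is this package's construction — the original
analysis names only the BH adjustment and the cut-off — and a 200-replicate
Monte-Carlo test confirms the familywise false-positive proportion stays at
the nominal level under background-only simulation.

# The synthetic-data generator

The generator emulates the study conditions, not a sequencer. Loci are random
sequences carrying the real designs' geometry: 220-bp amplicons (so the
largest small insertion still leaves mergeable overlap at 150-bp reads),
nick spacing 60 bp (≥ 50 so near-nick small deletions cannot span both
nicks; < 99 so nick-to-nick deletions under 100 bp exist), forced AGG PAM
and edit bases, a 600-bp UDiTaS locus with a 20-bp primer footprint, and a
2-kb synthetic AAV/plasmid reference. Five scenarios mirror the published
designs: `serpina1_correction` (1-bp A→G plus AGG→AAG PAM change; truth
precise 6.7%, indel 2.7%), `ctnnb1_s45f` (C→T, tumour-level 80% precise),
`ctnnb1_s45del` (3-bp TCC deletion), `ccr5_del` (32-bp deletion, UMI-tagged),
and `uditas_aav` (UDiTaS mixture dominated by wild type with 3.1% precise and
an AAV-integration fraction of 0.014% of UMIs, plus 5% false priming).

Molecules are drawn i.i.d. from the mixture; each receives a distinct random
12-bp UMI and a geometric family size (mean 4 for tagged libraries — the
statistical consequence of linear pre-amplification plus exponential PCR
that matters to the pipeline, not a mechanistic PCR model; plain amplicon
scenarios sequence each molecule once). Reads are 150-bp pairs with
independent per-base substitution errors at $e = 0.001$ and constant
$Q = \text{round}(-10\log_{10} e)$ quality; 2% of reads carry one Q20-labelled
base so the quality filter has genuine work to do. The label is assigned per
read rather than per base: a per-base model would make the
any-low-base discard probability grow exponentially with allele length,
selecting for deletion alleles over insertion alleles before the pipeline's
first stage — a distortion no analysis could undo. UDiTaS fragments get a
uniform Tn5 end with a 200-bp floor reflecting library size selection, and
AAV junctions are placed near the pegRNA nick within read 2's span (the
pipeline classifies on the primer-anchored read). Everything is deterministic
under the config seed, with molecule construction, reference construction
and amplification drawing from deliberately unrelated RNG streams.

**What the generator does not model:** PCR chimeras and index hopping,
quality-by-cycle decay, indel sequencing errors, UMI collisions/errors beyond
what random tagging produces, real genomic sequence context (homopolymers,
repeats at the actual loci), and paired-end evidence in UDiTaS mode (R1 is
emitted but classification uses R2). Passing the recovery tests therefore
demonstrates correctness of the measurement machinery under a clean
generative model, not robustness to every artifact of real libraries.

# Validation scale and expectations

The test suite runs each scenario at $n = 10{,}000$ molecules and requires
every recovered category fraction to match the realized truth within three
binomial standard errors at the analysed-unit count, plus the analytic
demotion allowance described above where exact-window matching applies; the
comparison maps truth to call semantics (indel-kind small mutations to the
`indel` call, substitution-kind ones to `substitution_other`). Worked-example
constructs (the 32-bp CCR5-style deletion, the 47-bp reporter-restoring
deletion, the 39→18-bp reporter replacement, the EMX1-style 3-bp deletion and
6-bp insertion) must yield their designed event sizes exactly from error-free
reads. The false-priming filter is exercised at a deliberately elevated
sensitivity condition — AAV fraction 2%, 50% injected false-priming reads,
5,000 molecules — distinct from the study-condition defaults, requiring zero
surviving false-priming reads among integration calls and ≥ 95% recall of
true junction molecules. Alignment oracle equivalence is exhaustive over all
pairs up to length 4 (every alignment path enumerated) and sampled at lengths
5–8 against an independent plain-R implementation: full enumeration at
length 8 is combinatorially impossible (hundreds of thousands of paths per
pair across a quarter-million pairs), so exhaustiveness is spent where it is
affordable.

# Known limitations

* Precise calls are all-or-nothing within the window; there is no
  quality-aware error tolerance, so at high error rates the precise rate is
  an underestimate by the predictable demotion fraction.
* Singleton-family partial edits (substitution-only evidence in one read)
  are conservatively counted as wild type in UDiTaS mode.
* UDiTaS classification uses read 2 only; events visible exclusively on the
  Tn5-side mate (for example a junction beyond read 2's reach) are missed —
  the generator places junctions within read 2's span accordingly.
* Non-nick-spanning deletions of 50–99 bp fall outside every published
  category and are reported as `unclassified`.
* The deletion-significance null is a per-UMI binomial against a pooled
  control rate; it does not model breakpoint-specific artifact structure.
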