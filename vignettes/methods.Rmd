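---
title: "Methods: model, parameters and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: model, parameters and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bivalvID)
```

This vignette records the modelling decisions behind bivalvID: what the
package computes, which parameters it defaults to and why, and what is
deliberately out of scope. The worked example lives in the README; this
document is the reference for the knobs.

## The barcode model

The method identifies bivalves from a short (150 bp, primer-inclusive)
fragment of mitochondrial 16S rDNA, chosen so that it still amplifies from
the degraded DNA of processed seafood. Amplification uses a triplex assay of
seven family-specific primers:

```{r assay}
assay_primers(default_assay())
```

Three conventions follow from this model and are used consistently
throughout the package:

* **Product vs insert.** A *product* is the primer-inclusive amplicon; the
  fixture generator constructs templates whose product is exactly 150 bp.
  An *insert* is the primer-free interior — what survives primer trimming —
  and is what the reference database stores and the classifier compares.
  With the default primers the inserts are 103 bp (Mytilidae, via Rev1_Mu),
  106 bp (Pectinidae) and 111 bp (Ostreidae).
* **Coordinates.** Binding sites and amplicons are reported in 0-based
  half-open coordinates on the plus strand of the template as given.
* **Resolution groups.** Species whose inserts are byte-identical cannot be
  distinguished by this barcode. The database partitions species into
  equivalence classes under exact insert identity: singletons keep the
  species name, same-genus classes are labelled `"<Genus> spp."`,
  cross-genus classes join the sorted members with `/`, and every species
  with no amplifiable product falls into a single `"non-amplifiable"` group.

## In-silico PCR

`find_binding_sites()` and `predict_amplicons()` scan every window of the
template on both strands with IUPAC-aware matching: a template base matches a
primer base when it is a concrete `A`/`C`/`G`/`T` contained in the primer
base's IUPAC expansion; ambiguous template bases never match, so an `N` in
the template always counts as a mismatch.

* `max_mm = 2` — at most two mismatches per primer, a conventional tolerance
  for ~20-mer primers at stringent annealing.
* 3'-anchor of 3 bases — the three primer bases nearest the 3' end must
  match exactly, reflecting polymerase intolerance of 3'-terminal
  mismatches. For a forward primer the anchor is at the end of the pattern;
  for a reverse primer (scanned as its reverse complement) it is at the
  start.
* `length_window = c(80, 300)` — products outside this range are discarded;
  the real assay targets 150 bp and anything far outside would not survive
  the size-selection implicit in short-read amplicon sequencing.

Every forward site is paired with every compatible reverse site in both
orientations, so a template with two alternative reverse sites yields two
products. `tm_wallace()` (the Wallace rule, 2(A+T)+4(G+C)) and
`self_complement_score()` (longest ungapped self-complementary run) are
lightweight screening heuristics for primer quality, not thermodynamic
predictions.

## Read simulation

`simulate_sample()` draws per-component read-pair counts from a single
multinomial at the specified proportions, i.e. DNA proportion maps directly
to read proportion. Components whose species have no amplifiable product are
allocated pairs like any other component, but those pairs are not emitted —
that is the model of "no amplification", and it is why an off-target main
component simply vanishes from the output rather than appearing as noise.

Reads are R1 = the amplicon 5' prefix and R2 = the reverse complement of the
3' suffix, of length `min(151, amplicon length)` (300-cycle kit, 2 × 151).
The error model is substitution-only and i.i.d. per base (default rate
0.001) with a constant quality symbol `'I'`. The simulator deliberately does
**not** emulate: indels, position- or motif-dependent error profiles,
quality-score decay, chimera formation, PCR duplicates, or amplification
bias — a per-species efficiency multiplier exists as a knob but defaults to
uniform. Consequently, simulated percentages recover the mixing proportions
up to multinomial sampling error, unlike real runs where primer bias shifts
them by several points.

All randomness flows through a single integer seed via `withr::with_seed()`;
the same seed reproduces byte-identical FASTQ files.

## Analysis pipeline

`run_sample()` chains four stages, with every input read pair accounted for
in exactly one output or rejection category:

1. **Merge** (`merge_pairs()`): best-scoring ungapped overlap between R1 and
   the reverse complement of R2, requiring `min_overlap = 20` bases and at
   most `max_mismatch_frac = 0.1` mismatches in the overlap; ties resolve to
   the R1 base. Only non-negative offsets are considered — the amplicons are
   at most ~150 bp, so reads always run *into* each other and
   read-through-adapter geometries do not occur in this model.
2. **Trim** (`trim_primers()`): requires a forward-primer prefix and a
   reverse-primer reverse-complement suffix from the *same* family, each
   within `max_mm = 2`; the flipped orientation is tried before rejecting.
   Rejection reasons: `no-forward`, `no-reverse`, `family-conflict`.
3. **Dereplicate** (`dereplicate()`): exact-sequence clustering, ordered by
   count (descending) then sequence.
4. **Classify** (`classify()`): per-cluster identity against every reference
   insert, `identity = 1 - edit_distance / max(lengths)`, assignment at
   `min_identity = 0.97` — the conventional species-level amplicon
   threshold; for a ~105 bp insert it tolerates 3 edits, matching the
   fixture's minimum within-family divergence of 5. Equal-best hits collapse
   to their resolution-group label when they form one, else to
   `"<Genus> spp."` when congeneric, else `"ambiguous"`.

Reported percentages are `round(100 * assigned / passing, 2)`; a label
counts as *detected* at ≥ 1.0 % of reads passing the workflow, though the
full table always lists every label.

## Problem sizes and limitations

The packaged fixtures (up to 11 bivalve species plus one off-target record)
and the 50,000-pair study designs are the package's own choices: large
enough that 0.5 % components carry ~250 reads and binomial error is a few
hundredths of a percent, small enough that a full study runs in seconds on
one core. The classifier computes an all-pairs edit-distance matrix per
sample, which is appropriate for curated databases of tens to a few hundred
inserts, not for genome-scale references. The package makes no attempt to
model real sequencing-run metrics (cluster density, Q30, platform error
rates) and its simulated accuracy should not be read as a claim about
wet-lab performance, where amplification bias dominates the error budget.
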