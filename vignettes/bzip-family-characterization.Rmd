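---
title: "Characterizing a plant bZIP transcription factor family with bzipscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing a plant bZIP transcription factor family with bzipscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bzipscan)
```

## The biological model

Basic leucine zipper (bZIP) transcription factors carry a compact two-part
domain. A **basic region** of 16 residues binds DNA; its hallmark is an
invariant asparagine followed seven residues later by an arginine or lysine
(the N-x7-R/K motif), and bzipscan defines the basic region as the 16 residues
ending at that R/K (seven residues upstream of the Asn, then N-x7-R/K). A
short **hinge** connects it to the **leucine zipper**, a coiled-coil built
from heptad repeats. Positions within each heptad are labeled
`g a b c d e f` in sequence order: hydrophobic residues at `a` and `d`
(canonically Leu at `d`) form the dimer interface, while charged residues at
`g` and `e` form inter-helical salt bridges that bias which partners a given
zipper accepts.

`bzipscan` operationalizes the family-survey workflow around this model:

1. **Domain annotation** (`annotate_domain`): scan for N-x7-R/K anchors; for
   each, search a hinge window for the first canonical interface residue
   (L/I/V/F/M) that, taken as the `d` of heptad 1, yields a plausible zipper.
2. **DNA-binding specificity** (`match_group`): align a 30-column signature
   window over the basic region and hinge and match it against ten fixed
   group templates, reporting the group's putative binding element (G-box,
   C-box, ABRE, and so on).
3. **Dimerization properties** (`dimer_propensity` and the `*_per_heptad`
   statistics): interface residue frequencies, per-heptad Asn-at-`a` rates,
   and electrostatic typing of g↔e′ pairs.
4. **Gene structure** (`classify_intron_pattern`): splicing phases and
   positions of introns that interrupt the basic region or hinge.
5. **Duplication history** (`chain_collinear_anchors`,
   `classify_duplication`): tandem versus segmental duplication of homolog
   pairs via collinear anchor chaining over gene-order ranks.
6. **Expression filtering** (`expressed_genes`, `highly_expressed`,
   `differential_call`): FPKM thresholds and a fold-change rule.

## Annotation rules and their rationale

**Basic region and window geometry.** The signature window is 30 columns:
11 residues upstream of the invariant Asn, the nine N-x7-R/K residues
(columns 12–20), and the ten residues after the R/K anchor (columns 21–30).
Defining the basic region as 16 residues *ending at* the R/K anchor makes the
16-residue claim and this window geometry mutually consistent.

**Heptad registration.** The zipper anchor is interpreted as the `d` position
of heptad 1 (`g` starts four residues earlier); this anchor-at-`d` convention
follows the rice/Arabidopsis survey methodology, since position labels are
meaningless without a stated register. Tiling proceeds every seven residues
and stops at the sequence end, after nine heptads (the observed family
maximum), or when two consecutive heptads carry a non-canonical `d` (neither
is kept). After tiling, trailing heptads with non-canonical `d` are trimmed.
The trim is a deliberate extension of the stop rule: a zipper's terminal
heptad is only evidence of a zipper through its interface residue, and
without the trim a single downstream background heptad would inflate the
zipper length whenever the C-terminal tail happens to be five or more
residues long. A terminal partial heptad is kept only when it includes its
`d` position.

**Acceptance of an anchor.** A candidate anchor must lie 1–16 residues after
the basic region (wide enough for a ten-column hinge plus register slack) and
must yield at least two heptads with at least 50% canonical `d` residues.
The 50% tolerance reflects that only ~59% of `d` residues are Leu and ~15%
other aliphatics — an all-Leu rule would reject real zippers. Among multiple
basic-region hits, the most N-terminal hit that yields a valid zipper wins;
this is deterministic and matches single-domain biology. Candidates whose
heptad-1 `g` would fall inside the basic region are skipped so the hinge is
never negative. A failed search is a no-call value, not an error.

**Group templates and anchor-column tolerance.** The ten signature templates
are shipped as a plain-text resource (`inst/extdata/group_templates.tsv`) and
matched column by column: a group matches only if *every* fixed column
matches, the group with the most literally matched fixed columns wins, and
ties fall back to a fixed priority order (D > B > H > A > G/M/S > C > E > I >
J > F/K). Two templates contradict the N-x7-R/K anchor itself: group A fixes
K at the Asn column (12) and group J fixes I at the R/K column (20). Because
every window extracted from an annotation has N at 12 and R/K at 20 by
construction, those templates could never match under a literal rule. We
therefore *tolerate* the canonical anchor residue at exactly those columns —
without re-anchoring the window — and do not count a tolerated column toward
the match score. Not counting it matters: group J's only fixed column is the
tolerated one, so J scores 0 and never steals ties from F/K (whose single
fixed column is literal). A consequence worth knowing: any annotator-derived
window matches at least group J, so annotated proteins are never
"unclassified"; the unclassified label remains reachable for windows built
from other sources.

**Dimerization conventions.** The g↔e′ pair is evaluated as (`g` of heptad
*i*, `e` of heptad *i+1*) — the intra-sequence proxy for the inter-helical
pair of a parallel dimer; the offset is not stated in the survey literature
we follow, so it is configurable in spirit (the pairing is isolated in one
internal function). Glutamine is treated as *acidic-like* for pair typing
only (E↔Q is a repulsive acidic pair) but is excluded from the charged
tallies (K, R, D, E) at the `a` position; each convention follows its own
source sentence literally. Attractive pairs require a strict E/D acid, so
(K, Q) is "incomplete". The propensity labels use reporting thresholds —
homodimer-favoring needs ≥ 2 Asn at `a` and no repulsive pair,
heterodimer-favoring needs ≥ 1 repulsive pair or ≥ 2 charged `a` residues,
both conditions give "mixed" — and all raw counts are emitted so users can
re-threshold.

**Splicing phases.** Phase labels follow the survey convention: P0/P1/P2
means the splice falls after the 3rd/2nd/1st nucleotide of a codon. This is
the *inverse* of classical intron-phase naming, and is numerically identical
to the GFF3 phase of the CDS segment downstream of the intron — a property
the test suite verifies on every synthetic gene model. An intron after coding
nucleotide *c* belongs to a region `[s, e]` iff `s <= c <= e - 1`; a splice
at a region's right boundary belongs to the next region. Intra-domain means
basic+hinge; zipper introns are reported but not typed. Coding offsets are
computed in translation order, so strand is invisible to the phase logic.

**Duplication classification.** Collinear blocks are chains of homolog
anchors, strictly monotonic in gene-order rank on both chromosomes
(increasing or decreasing on the second — "same" or "inverted" orientation)
with per-step rank gaps bounded by `max_gap`. Defaults `min_anchors = 5`,
`max_gap = 25`, `tandem_max_gap = 1` mirror the MCScanX convention that
family surveys rely on. Chains are extracted greedily, longest first, each
anchor in at most one block; an O(n²) dynamic program suffices at gene-family
scale. Tandem (same chromosome, adjacent rank) takes precedence over
segmental so the tandem tally stays a separate count. Homology itself is an
input: the package classifies pairs, it does not discover them.

**Expression rules.** "Expressed" is FPKM ≥ 1, "highly expressed" FPKM ≥ 20,
tissue-preferential means the threshold is reached in the row-maximum tissue
(ties count for every argmax tissue). Row scaling is the usual heatmap
z-score with constant rows mapping to zero. The differential rule — fold
change ≥ 2 with a 0.01 pseudo-FPKM and an FPKM ≥ 1 floor on the higher
condition — is a package convention: the surveys we emulate do not state
their criterion, so the default is labeled as such and every threshold is a
parameter.

## The synthetic world

`sim_config()` fixes a "stated world" whose defaults are the published
family's conditions: 197 members mixed over the ten groups in the published
proportions (41 A, 1 B, 13 C, 32 D, 8 E, 10 F/K, 62 G/M/S, 2 H, 25 I, 2 J of
196 classified); zipper lengths uniform on 2–9 heptads; Asn-at-`a`
probabilities of 0.589 and 0.574 in heptads 2 and 5 and 0.11 elsewhere —
under the uniform length mix this makes the pooled Asn-at-`a` frequency
0.25, with 16% of non-Asn `a` residues charged; 59% Leu at `d` with the rest
split over I/V/M/F (0.15/0.12/0.08/0.06, a package choice — the generator
keeps all `d` residues canonical); interactive g↔e′ fractions of 0.4264 at
the first pair position decaying as 0.25, 0.15, 0.10, ... (the decay beyond
the first value is a package choice matching the reported "sharp decrease");
7 tandem pairs and 10 collinear blocks totaling 53 anchor pairs on 10
chromosomes; and an FPKM atlas with the 185/197 and 76/197 expressed
proportions, 21 root- and 23 leaf-preferential genes, and 20 up/20 down
drought genes at fold change 4 with log-normal noise (sd 0.25 on the log
scale, a choice representing moderate biological noise).

The generator is *clean by construction*: background residues are drawn by
rejection so that no spurious N-x7-R/K anchor, no accidental fixed-column
match for a non-planted template, and no spurious zipper anchor can arise;
`a`-position residues are drawn from a non-interface alphabet so the first
hydrophobic residue after the basic region is always the planted `d` of
heptad 1. For groups whose template letter contradicts an anchor column (A
and J), the generator plants the canonical anchor residue — exactly the case
the matcher's tolerance rule covers. Tissue-atlas baselines are capped below
the high-expression threshold so the planted preferential sets are the only
ones.

A green test on this world therefore establishes that the *rules* are
implemented exactly as stated — planted truth is recovered 100% at zero noise
and planted frequencies are recovered within binomial error — but it does not
establish robustness to real-proteome phenomena: degenerate or drifted
motifs, multi-domain proteins, hinge lengths outside 1–16, non-canonical
zipper interruptions, fragmented gene models, or noisy homology calls. Those
are the responsibility of the user's inputs, not of the synthetic suite.

## Numerical and degenerate-input choices

* `percentage()` rounds to one decimal, halves away from zero (survey
  reporting style), unlike base `round()`.
* `row_scale()` maps zero-variance rows to all zeros rather than NaN.
* `differential_call()` guards division with a 0.01 pseudo-FPKM.
* Empty inputs are values, not crashes: no-call annotations, empty block
  tables, empty group tables; but an empty FASTA, an empty expression
  matrix, or a CDS length not divisible by 3 are loud (error or
  warning+invalid flag).
* Chaining output is invariant to input pair order (anchors are canonically
  sorted before the DP; ties in chain extraction resolve deterministically).
* All generator randomness is seeded through `withr::with_seed`, restoring
  the caller's RNG state; two runs with the same configuration are
  byte-identical.

## Known limitations

* One domain per protein: the most N-terminal valid architecture wins, and
  proteins with two bZIP domains are reported by their first.
* The specificity matcher is exact-template matching, not a profile model;
  it asserts nothing about binding affinity.
* Group labels merged in the template table (F/K, G/M/S) stay merged;
  splitting them requires a phylogeny, which is out of scope.
* Duplication classification requires user-supplied homolog pairs and
  gene-order ranks; no Ka/Ks dating is attempted.
* Differential expression is a fold-change filter, not a statistical test
  with replicates.
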