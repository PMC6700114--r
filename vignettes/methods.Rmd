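---
title: "Designing motif cassettes and scoring methyltransferase activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing motif cassettes and scoring methyltransferase activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifcassette)
```

## The assay this package models

Bacterial methyltransferases (MTases) methylate a fixed base inside a
short recognition sequence. A methylome analysis of a strain yields a list
of motifs — possibly degenerate (IUPAC codes), possibly bipartite (two
half-sites separated by an N-spacer, the Type I signature) — each with its
modified position and modification type (m6A, m4C, m5C). To attribute each
motif to a gene, every candidate MTase is expressed individually on a
vector that carries a *motif cassette*: a synthetic segment containing
every methylome motif in known copy numbers. Pooled, linearised plasmids
are sequenced full-length; reads are sorted first by the cassette, then by
the MTase gene; and the per-gene read groups are scored for modification at
each motif's expected base. The package implements the design, the
scanning, the scoring, the read sorting, and a simulator that stands in for
the sequencer.

## Motif representation

A `methyl_motif` is a triple (IUPAC sequence, modified position, type),
validated so that the modified position's base set contains the methylated
base (A for m6A, C for m4C/m5C; the complementary base when the motif has
been reverse complemented, since the mark then sits on the other strand).
Classification follows a single rule: a motif is *spacer class* iff it has
an internal run of 2–10 N flanked by fully specified half-sites. The bounds
are inclusive; a run of 1 is ordinary degeneracy and a run of 11 or more is
rejected with a warning (no known Type I spacer is that long) and the motif
treated as simple.

Degenerate motifs denote Cartesian products of per-position base sets. This
makes set relations decidable position-wise (`relate_motifs()`), after an
ungapped sliding alignment that maximises the number of positions specified
in both motifs (ties to the smallest offset — a deterministic convention,
since informal motif comparisons do not specify one). `union_equals()`
decides whether motifs jointly cover a degenerate motif by enumeration,
which is how a "double motif" is recognised: SATC = GATC ∪ CATC, two
enzymes producing what the genome-level analysis sees as one motif.

## Cassette design

Copy rules: 12 instances per spacer-class motif, 10 per simple motif.
Bipartite motifs get more copies because each instance constrains only the
half-sites; the spacer contributes nothing. Degenerate motifs are
de-ambiguated under one of two modes (`distribute_L`, the default, keeps
the class copy number fixed and spreads it over variants; `per_variant_K`
gives every variant K copies). `distribute_L` is the default because the
copy rules above fix the per-motif total; `per_variant_K` is retained for
designs that need guaranteed per-variant counts.

Rendering decisions worth knowing:

* **Separator**: exactly one base between instances. The default policy
  fills separators and spacer Ns with seeded random bases, because
  synthesised DNA cannot contain N; `literal_n` keeps them as N for design
  review.
* **Adjacency**: no two consecutive instances may carry the same concrete
  (filled) sequence. Spacer fills are drawn before arrangement, so two
  instances of the same bipartite motif are almost surely distinct and the
  constraint binds mostly on simple-motif copies. Arrangement is retried
  random shuffling with a deterministic interleaving fallback; an
  infeasible multiset (one sequence holding more than half the slots)
  degrades to a warning, not an error.
* **Junction guard** (default on): the rendered cassette is rescanned for
  every design motif and compared against the *design-determined* site set
  — the variant-level matches lifted to cassette coordinates, computed with
  subject-N never matching a specified position so that nothing a filler
  could change is counted as designed. Any extra site is an artifact of a
  filler or junction; only the filler bases inside artifact sites are
  redrawn, repeatedly, until the scan is exact. Targeted repair matters:
  with ~30 junctions the expected number of chance artifacts per render
  exceeds one, so blindly re-rendering has a poor success probability,
  while each targeted redraw fixes its artifact with high probability. A
  determined artifact (one no filler can remove) stops with an error
  advising a different seed.

The whole design is a pure function of the motif list and the
`cassette_spec`, including its seed; identical specs give byte-identical
FASTA/GenBank output. GenBank features carry parent motif, variant, filled
sequence and modified position, and re-parsing recovers all coordinates.

## Scanning and detection

Site counting uses both strands and counts palindromic duplex loci once
(collapse can be disabled; disabling exactly doubles palindromic counts).
This convention is consistent with published genome-wide counts for both
palindromic and asymmetric motifs at these genome sizes; it is also the
convention under which a cassette's designed counts equal its scanned
counts. Overlapping matches all count; subject N never matches a specified
motif position. Coordinates are 1-based throughout, the R/Bioconductor
convention — reports and file formats (GFF3) are then coordinate-compatible
with the rest of the ecosystem without translation.

`detection_rate()` is the core statistic: the fraction of a motif's sites
whose expected modified base carries a call of compatible type with
modification QV ≥ `qv_min` (default 30, the conventional caller cut-off).
For a collapsed palindromic site, a qualifying call on either strand's
modified base counts the locus. Empty site lists yield a missing rate, not
zero — "no sites to detect" and "nothing detected" are different results.

## De novo motif refinement

`refine_motif()` reconstructs a recognition motif from calls alone. It is a
deliberate simplification of production modification-pipeline motif
finders, validated by parameter recovery rather than output matching:

1. collect the ±k context (default k = 10) of every qualifying call,
   reverse complementing minus-strand contexts so the modified base sits at
   a fixed index;
2. per position, assign the smallest IUPAC code covering ≥ `min_fraction`
   (default 0.9) of the base mass; background positions fall to N because
   no code below N covers 90% of near-uniform usage;
3. trim flanking N, then refine greedily.

The greedy step scores each candidate by the harmonic mean of site-level
precision (fraction of the candidate's genome-wide sites detected — also
the reported score) and call recall (fraction of qualifying calls explained
by the candidate's sites). Precision alone is not identifiable: any
extension of the true motif that happens to select a fully detected subset
of sites scores at least as high, so trimming would never fire. Recall
breaks the tie — extensions explain fewer calls. Trims that do not lower
the combined score are taken (prefer the simpler motif on ties), and
ambiguous positions beyond `max_degeneracy` (default 2) are collapsed to
their majority base when that costs nothing.

With ~10–100 sites in 50 kb this recovers planted motifs of length 4–7
reliably at high detection rates, and recovers composite motifs (joint
GATC+CATC calls give SATC). The genuine failure mode is informational, not
algorithmic: with very few sites and a missed detection, an extended motif
that excludes the missed site fits the data better than the truth, and no
scoring rule can tell them apart.

## Read sorting

"Mapping-based selection" is realised as Smith–Waterman local alignment
(Biostrings) with identity and coverage thresholds: a read is kept if the
cassette aligns at ≥ 0.85 identity over ≥ 0.8 of its length (either
orientation; kept reads are canonicalised to cassette-forward), then
assigned to the best-scoring gene reference at ≥ 0.85 identity over ≥ 0.9
of the gene, with reads whose top two gene scores differ by < 2% left
ambiguous rather than guessed. These thresholds are declared defaults — the
assay's published description names neither aligner nor cutoffs — chosen to
sit comfortably between the ~2–15% error of long reads and the < 90%
identity of distinct genes. The gene set should include the
negative-control insert so control reads form their own group. Raising a
threshold can only move reads to unassigned, never between genes.

## The simulator

The synthetic-data module emulates three instruments' worth of input:

* `simulate_sequence()` — i.i.d. bases at a chosen GC content.
* `simulate_plasmid()` — backbone + gene + cassette + backbone, linearised
  at position 1; `mask_motifs` regenerates backbones until neither they nor
  part junctions carry masked-motif sites, for experiments needing exact
  denominators.
* `simulate_reads()` — uniform start, truncated log-normal length, random
  strand, substitution/insertion/deletion errors split 60/20/20. The
  defaults describe generic fragment libraries; pooled-plasmid experiments
  should set the minimum read length above the plasmid length, since the
  assay sequences full-length linearised plasmids — with fragment-length
  reads, sorting "errors" mostly measure reads that truncate the gene.
* `simulate_calls()` — per site, a call at the modified base with
  probability `p_detect` (default 0.99, matching the near-complete
  detection rates typical of well-covered m6A/m4C motifs); collapsed
  palindromic loci emit correlated calls on both strands so the measured
  rate stays `p_detect`. True-call QVs are Normal(60, 20) *conditioned
  above the caller's reporting threshold* (30): `p_detect` is the
  probability of a reported, qualifying call, so measured detection rates
  match it at the default cut-off. False calls hit each A/C base per strand
  at `fp_rate` (default 1e-4) with QVs Normal(15, 5) truncated at zero,
  mostly below the cut-off as real false signals are. m5C motifs get a
  detection multiplier (default 0.5) reflecting the weaker single-molecule
  m5C signal — a qualitative stand-in, not a calibrated model.

Everything is a pure function of its seed; reruns are byte-identical.

What the simulator does **not** model: instrument-specific error profiles
(errors are uniform, not context-dependent), kinetic signal strength versus
coverage, per-molecule phasing, or chimeric reads. Tests passing on this
simulator therefore demonstrate the pipeline's logic and statistics —
copy-number exactness, detection-rate estimation, motif recovery, sorting
accuracy at a given error rate — not robustness to every artefact of real
single-molecule data.

## Problem sizes and numerical choices

The test suite and reproduction script run at desk scale: 50 kb simulated
sequences for motif recovery (giving 10–100 sites for motifs of length
4–7), 20 recovery replicates, 3 plasmids × 200 full-length reads at 2%
error for sorting, and 100 random motif/sequence pairs up to 10 kb for the
scanner-versus-brute-force equivalence check. Detection probabilities are
checked against binomial 99% confidence bounds, never for exact equality.
Ties in `relate_motifs()` alignment go to the smallest offset; ties among
equal-cardinality IUPAC codes in the profile step go to the higher covered
mass, then alphabetically. Degenerate inputs are handled explicitly: empty
site lists give missing rates, all-N motifs are rejected at construction,
and a cassette of a single repeated sequence arranges with a warning.

## Known limitations

* Genome-scale site counting loads each contig into memory; fine for
  bacterial genomes, not engineered for metagenomes.
* `refine_motif()` reports a single motif; a read group containing two
  active enzymes with unrelated motifs will yield whichever signal
  dominates, possibly degenerate.
* Read sorting is all-vs-all alignment, quadratic in pool size × read
  count; pools beyond a few thousand reads would want a minimiser-based
  prefilter.
* GenBank output implements the minimal LOCUS/FEATURES/ORIGIN subset needed
  for round-tripping cassette annotations, not the full format.
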