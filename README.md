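# motifcassette

Tools for coupling bacterial DNA methyltransferases (MTases) to the
methylation motifs they recognise.

## The problem

Single-molecule sequencing makes it easy to call a strain's *methylome* —
the set of methylation motifs (m6A, m4C, m5C) and their genome-wide
detection rates — but it does not say **which MTase gene produces which
motif**. A strain with a dozen motifs and twenty MTase genes leaves most of
the coupling to homology guesswork. One experimental solution: synthesise a
strain-specific **motif cassette** — a short DNA segment carrying every
methylome motif in known copy numbers — put it on an expression vector,
clone each MTase into that vector, pool the linearised plasmids, sequence
the pool, sort reads by MTase gene, and read each enzyme's specificity
directly off the cassette.

`motifcassette` implements the computational side of that workflow:

| step | functions |
|---|---|
| represent/expand IUPAC motifs | `motif()`, `classify_motif()`, `expand_motif()`, `variant_count()`, `reverse_complement_motif()`, `relate_motifs()`, `union_equals()` |
| design the cassette | `cassette_spec()`, `design_cassette()`, `write_cassette()` (GenBank + FASTA) |
| scan sequences for motif sites | `find_sites()`, `count_sites()` |
| score modification calls | `detection_rate()`, `summarize_motifs()`, `refine_motif()`, `assign_to_design()` |
| sort pooled long reads | `select_by_cassette()`, `group_by_gene()`, `sort_reads()`, `report_groups()` |
| simulate everything | `sim_config()`, `simulate_sequence()`, `simulate_plasmid()`, `simulate_reads()`, `simulate_calls()` |

### Design rules

A motif is classed **spacer** (bipartite: two specified half-sites separated
by a run of 2–10 `N`, typical for Type I enzymes) or **simple** (Type II /
III). A designed cassette carries **12 copies** of every spacer-class motif
and **10 copies** of every simple-class motif. Degenerate motifs are
de-ambiguated: with class copy number *L* and *V* concrete variants, either
*L* copies are spread over the variants (`distribute_L`, default: *L*
distinct random variants when *V* ≥ *L*, otherwise ⌊*L*/*V*⌋ of each plus
randomly chosen extras), or every variant gets exactly *K* copies
(`per_variant_K`). Instances are randomly ordered with **no two identical
neighbours**, separated by exactly one base, and a **junction guard**
rescans the rendered sequence and re-randomises filler bases until the scan
finds exactly the designed site counts — so detection-rate denominators
computed from the cassette are exact.

Site counting uses the both-strand convention with palindromic duplex loci
counted once. The **detection rate** of a motif is the fraction of its
sites whose expected modified base carries a modification call with
modification QV ≥ 30 (the conventional cut-off).

## Worked example

```r
library(motifcassette)

# a methylome with one bipartite and one simple motif
motifs <- list(motif("GAGNNNNNGAT", 2, "m6A"),
               motif("AACCA", 5, "m6A"))

cas <- design_cassette(motifs, cassette_spec(seed = 7))
cas
#> <motif_cassette> 203 bp, 22 instances of 2 motifs (seed 7)
#>   AACCA                 10 copies
#>   GAGNNNNNGAT           12 copies

# independent verification by scanning the rendered sequence
count_sites(cas$sequence, motifs)
#>         motif modified_position mod_type n_sites
#> 1 GAGNNNNNGAT                 2      m6A      12
#> 2       AACCA                 5      m6A      10

# simulate modification calls from an active MTase and summarise
calls <- simulate_calls(cas$sequence,
                        sim_config(active_motifs = motifs[1],
                                   p_detect = 1, fp_rate = 0), seed = 3)
summarize_motifs(cas$sequence, motifs, calls)
#>         motif modified_position mod_type fraction_detected  mean_qv n_sites n_detected
#> 1 GAGNNNNNGAT                 2      m6A                 1 58.59193      12         12
#> 2       AACCA                 5      m6A                 0       NA      10          0
```

The 12/10 site counts are the designed copy numbers; `fraction_detected`
is 1 for the motif whose enzyme was simulated as active and 0 for the
other, exactly as a per-MTase cassette experiment reads out.

A command-line front end (`exec/motifcassette`) exposes the same steps as
`design`, `scan`, `summarize`, `refine`, `sort` and `simulate` subcommands;
every run writes a `manifest.json` with the configuration, seed and input
checksums.

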