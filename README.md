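# bzipscan

Genome-wide characterization of plant **basic leucine zipper (bZIP)**
transcription factor families, for researchers running family surveys on a
proteome + annotation + expression matrix (the kind of analysis routinely
published for cotton, rice, Arabidopsis, soybean, ...).

A bZIP domain is a 16-residue DNA-binding **basic region** carrying the
invariant **N-x7-R/K** motif, a short **hinge**, and a **leucine zipper** of
2–9 heptad repeats whose positions are labeled `g a b c d e f` along the
sequence. Hydrophobic residues at `a`/`d` form the dimer interface; charged
residues at `g`/`e` form inter-helical **g↔e′ salt bridges** (`g` of heptad
*i* against `e` of heptad *i+1*) that are attractive (opposite charges) or
repulsive (like charges) and bias homo- versus heterodimerization. The
basic+hinge residue signature determines DNA-binding specificity toward
ACGT-core elements (A-box TACGTA, C-box GACGTC, G-box CACGTG, ABRE).

The package implements the full survey pipeline:

| stage | function(s) | output |
|---|---|---|
| domain annotation | `annotate_proteome()` | basic region, hinge, registered heptads |
| binding specificity | `classify_proteome()` | one of 10 signature groups + putative binding site |
| dimerization | `dimerize_proteome()`, `ge_pair_frequency_per_heptad()`, ... | a/d/e/g statistics, pair typing, propensity |
| gene structure | `classify_intron_pattern()`, `intron_phase()` | intra-domain intron types 1–4, phases P0/P1/P2 |
| duplications | `chain_collinear_anchors()`, `classify_duplication()` | tandem / segmental / dispersed |
| expression | `expressed_genes()`, `highly_expressed()`, `differential_call()` | FPKM ≥ 1 / ≥ 20 sets, drought calls |
| synthetic data | `sim_config()`, `generate_all()` | every pipeline input + planted ground truth |

Inputs are standard formats: protein FASTA, GFF3 gene models, two-column
homolog-pair TSV, FPKM matrix TSV. Everything is also reachable from one
front end, `run_pipeline()` / the `bzipscan` CLI script (`inst/exec/bzipscan`).

## Worked example

The synthetic generator plants a complete family with known truth, so the
whole pipeline can be exercised without downloads:

```r
library(bzipscan)

cfg <- sim_config(n_proteins = 197, seed = 1)   # the stated default world
sim <- generate_all(cfg)

ann <- annotate_proteome(sim$proteins)
ann[["bzip001"]]
#> <bzip_annotation> bzip001  basic 27-42 (N34, R/K42)  hinge 43-52  9 heptad(s), d: LLLLVVLLL
```

The basic region spans residues 27–42 with the invariant Asn at 34 and R/K at
42, a 10-residue hinge, and nine heptads whose `d` positions are mostly Leu.

```r
cls <- classify_proteome(ann, sim$proteins)
cls$counts
#>            A            B            C            D            E          F/K
#>           50            0           13           34            4           11
#>        G/M/S            H            I            J unclassified
#>           52            4           28            1            0

head(cls$calls[, c("protein_id", "group", "binding_site", "matched_positions")], 3)
#>   protein_id group                                            binding_site matched_positions
#> 1    bzip001 G/M/S                       G-box and/or G-box-like sequences                 5
#> 2    bzip002     A ABREs with the core ACGT or others containing GCGT/AAGT                 5
#> 3    bzip003     D                                          C-box sequence                15
```

Counts are a multinomial draw around the published group proportions;
`matched_positions` is the number of literally matched fixed template columns.

```r
blocks <- chain_collinear_anchors(sim$pairs, sim$layout)
table(classify_duplication(sim$pairs, blocks, sim$layout)$label)
#> dispersed segmental    tandem
#>        10        53         7
```

The planted duplication history — 7 tandem pairs, 53 collinear anchor pairs —
is recovered exactly.

```r
sets <- expressed_genes(sim$fpkm)          # FPKM >= 1
length(sets$any_tissue); percentage(length(sets$any_tissue), 197)
#> [1] 185
#> [1] 93.9
length(sets$all_tissues); percentage(length(sets$all_tissues), 197)
#> [1] 76
#> [1] 38.6

head(asn_frequency_per_heptad(ann), 5)
#>   heptad n_proteins n_asn  frequency
#> 1      1        197    12 0.06091371
#> 2      2        197   111 0.56345178
#> 3      3        172    16 0.09302326
#> 4      4        152    18 0.11842105
#> 5      5        119    66 0.55462185
```

185/197 genes (93.9%) are expressed in at least one tissue and 76 (38.6%) in
all tissues; the Asn-at-`a` frequency peaks in heptads 2 and 5 (~0.56 here,
planted at 0.589/0.574 — the gap is binomial noise at n ≈ 200), the signature
of homodimer-stabilizing a↔a′ Asn contacts.

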