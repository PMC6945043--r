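# gatafam

Comparative characterization of the MED / END-1 / END-3 GATA
transcription-factor families of *Caenorhabditis*.

In *C. elegans*, gut fate is specified by a cascade of transiently
expressed GATA factors, SKN-1 → MED-1,2 → END-1,3 → ELT-2,7. Across the
Elegans supergroup the three upstream families evolve under visibly
different constraints: END-1 is a unique, highly conserved ortholog in
nearly every genome; END-3 duplicates occasionally; the med genes amplify
extensively and diverge fastest. `gatafam` is an R package for the
analyses that characterize such a gene set from genome scaffolds:

* **Gene models** — TBLASTN-HSP-guided gene stitching with GT..AG splice
  search, an identity-based short-intron read-through judgment, splice-site
  validation, CDS assembly/translation, and intron-position comparison
  across orthologs in alignment coordinates.
* **Protein annotation** — C4 zinc-finger detection
  (`C-x(2,4)-C-x(15,19)-C-x(2)-C`) with X16/X17/X18 spacing classes,
  amino-terminal poly-serine (and Ser/Thr) domain detection, the ~25-residue
  Endodermal GATA Domain (EGD), and pseudogene classification (truncation,
  DBD stop/frameshift, missing finger cysteine, unresolved near-identical
  duplicates).
* **Promoter motifs** — 600-bp promoter extraction, IUPAC consensus
  scanning on both strands with overlap-aware counting, and Poisson
  enrichment: `lambda = (L - w + 1) * (p+ + p-)` under the promoter's own
  mononucleotide composition, `P = P(X >= k; lambda)`. Polypyrimidine
  (PPY/PPU) tract detection and per-family site summaries.
* **Codon bias** — serine codon tallies (TCT/TCC/TCA/TCG vs AGT/AGC) in
  protein intervals and Pearson chi-square goodness-of-fit against
  genome-wide background usage (TCN-vs-AGY, 1 df, or within-TCN, 3 df).
* **Synteny** — extent-based gap distances, the four linked-orientation
  classes, and single-linkage tandem-cluster detection (5 kbp med /
  10 kbp end-3 defaults).
* **Conservation** — alignment profiles (invariant columns, consensus),
  conserved blocks, contact-position conservation, and a neighbor-joining
  p-distance tree with a family clade-purity score.
* **Synthetic data** — a seeded generator that emits multi-species
  scaffolds, gene models, promoters with planted motif sites, biased
  poly-serine codons, lesioned pseudogenes, linkage/cluster layouts and
  true alignments, plus machine-readable truth tables; its defaults mirror
  the published summary statistics so default runs resemble the study
  regime.

## Worked example

```r
library(gatafam)

ds <- generate_dataset(family_spec(seed = 1))   # synthetic 20-species dataset
report <- run_characterize(ds)

head(report$counts[, c("species", "med.functional", "med.pseudogene",
                       "end1.functional", "end3.functional")], 5)
#>      species med.functional med.pseudogene end1.functional end3.functional
#> sp01    sp01              2              0               1               2
#> sp02    sp02              1              0               1               1
#> sp03    sp03              3              1               1               1
#> sp04    sp04              5              0               1               1
#> sp05    sp05              4              0               1               2

report$summaries[c("med.skn1_double", "end3.med_site"),
                 c("n_species_with_site", "mean_sites_per_gene_with_site",
                   "fraction_within_d_of_atg")]
#>                 n_species_with_site mean_sites_per_gene_with_site fraction_within_d_of_atg
#> med.skn1_double                  19                      3.631579                0.9855072
#> end3.med_site                    20                      2.700000                0.9444444

report$codon_bias$tcn_vs_agy
#> <codon_bias_result tcn_vs_agy> X-squared = 264.7, df = 1, p = 1.595e-59
report$tree_check$purity
#> [1] 1
```

The count matrix partitions every ingested gene into
functional / pseudogene / unresolved-duplicate per species and family.
The site summaries say that 19 of 20 species carry the double SKN-1 site
in their med promoter (≈ 3.6 sites per gene, almost all within 300 bp of
the ATG) and every species carries MED sites in its end3 promoter
(≈ 2.7 per gene within 200 bp) — the pattern expected if SKN-1 → med and
MED → end3 regulation is conserved. The chi-square report shows the
poly-serine TCN codon bias of the end proteins (here 98.8% TCN against a
75% background expectation), and a clade purity of 1 means the three
families separate cleanly on the p-distance tree of their DBDs.

`run_characterize(..., outdir = "out")` additionally writes the report
bundle (count matrix, enrichment and site tables, BED sites, synteny and
cluster tables, domain maps, codon-bias report, conservation profiles and
Newick tree) as plain-text files; `write_dataset(ds, dir)` /
`run_characterize(input_dir = dir)` round-trip the dataset through the
on-disk FASTA/GFF3/TSV formats.

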