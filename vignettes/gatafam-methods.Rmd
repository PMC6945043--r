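---
title: "Methods: comparative characterization of MED/END GATA-factor families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative characterization of MED/END GATA-factor families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gatafam)
```

# The problem

In *Caenorhabditis* endoderm specification, the maternal factor SKN-1
activates a cascade of transiently expressed GATA transcription factors —
MED → END-1,3 → ELT-2,7 — that commits the E blastomere to gut fate. The
MED, END-1 and END-3 families co-occur only within the Elegans supergroup
and evolve at markedly different rates: END-1 orthologs are unique per
genome and conserved along their whole length, END-3 orthologs duplicate
occasionally and diverge more, and the med genes amplify extensively while
their DNA-binding domains (DBDs) drift the most. `gatafam` packages the
comparative analyses that establish such a picture — gene-model curation
from TBLASTN hits, domain and zinc-finger classification, promoter motif
statistics, serine codon-bias testing, microsynteny, and alignment
conservation profiling — as tested, reusable functions, together with a
seeded synthetic-genome generator that plants every measured feature with
truth tables so the whole pipeline can be validated hermetically.

# Gene models

Internally, exons are `[start, end)` intervals in 0-based half-open
forward-scaffold coordinates, kept in transcription order; GFF3 I/O
converts to and from the 1-based inclusive convention at the boundary.
This makes window arithmetic, intergenic distances and promoter extraction
free of off-by-one ambiguity. A model whose summed exon length is not a
multiple of three cannot be translated in a single frame and is
automatically treated as a pseudogene candidate.

## HSP stitching

`stitch_hsps()` reconstructs a gene model from ungapped TBLASTN
high-scoring segment pairs (HSPs) on one scaffold and strand. For each
inter-HSP gap the donor position is searched within ±30 bp (configurable)
of the upstream HSP edge; frame consistency ties the acceptor to the donor
(total coding length between the HSP anchors must equal three times the
spanned query residues), so each gap reduces to a one-dimensional search
over GT..AG-bounded candidates. Candidates are scored by amino-acid
identity of the translated join against the reference protein, ties
preferring boundaries closest to the HSP edges. Two special rules:

* **Collinear merge.** When the genomic span between two HSPs codes
  straight through (query gap equals the genomic gap in codons) and the
  read-through translation is open, the exons are merged; when both a
  merge and a splice are possible, the higher-identity variant wins and
  ties keep the intron.
* **Short-intron read-through.** A chosen intron shorter than 50 bp whose
  length is a multiple of three and whose inclusion keeps the frame open
  is re-scored as coding; the higher-identity variant is kept, ties keep
  the intron. This operationalizes, as a reproducible rule, the
  case-by-case judgment of maximizing amino-acid-level homology that
  manual curation applies to sub-50-bp predicted introns.

The model is then extended to the in-frame ATG that best covers the
reference amino terminus (ties to the most upstream, stopping at the first
in-frame stop) and through the stop codon downstream. Gaps with no
GT..AG candidate in the window are reported as unresolved rather than
guessed. On noiseless synthetic HSPs the stitcher recovers 100% of exon
boundaries exactly (the acceptance suite requires ≥ 95% over 100 genes).

## Intron comparison

Intron positions are expressed as the 0-based index of the interrupted
codon (`floor(upstream_cds/3)`) plus the phase (`upstream_cds mod 3`).
Across orthologs, introns are grouped by the *alignment column* of the
residue following the splice together with the phase, which is invariant
to indels in the alignment; this reproduces the bookkeeping by which a
zinc-finger intron shared by every end gene (and Japonica-group med genes)
is recognized.

# Protein annotation

* **C4 zinc fingers** are matched by `C x{2,4} C x{15,19} C x{2} C` with
  lazy spacing (shortest consistent spacing at each start, left to right,
  non-overlapping). The bounds cover every reported variant — X16–X18
  inner spacings and both CXXC and the extended END-1-type CSNPNC amino
  gap — with one-residue margins, so detection does not presuppose the
  family. `classify_finger()` labels X18 (Elegans-group MED-like), X17
  (canonical GATA/END), X16, or other, and flags amino gaps > 2 as
  extended.
* **Poly-S / Poly-S/T.** The domain starts at the first serine run of
  length ≥ 3 beginning within the first 10 residues and extends while
  every trailing 10-residue window keeps the defining-residue fraction
  ≥ 0.5 (S only, or S+T for the MED-type region), then trims to a
  defining residue and shrinks until the whole interval satisfies the 0.5
  rule. The window rule is an explicit operationalization of
  "homopolymeric clusters" and all three constants are arguments.
* **EGD.** The Endodermal GATA Domain is taken as the 25 residues
  immediately upstream of the first finger cysteine, truncated (and
  flagged) at the protein start.
* **Pseudogene calls.** A gene is a pseudogene when its protein is shorter
  than 0.6× the family median (configurable; the qualitative criterion
  "truncated" needs a number), carries an in-frame stop or a frameshift
  within the DBD, or lacks an intact finger there. When the frame is
  broken, downstream translation is unreliable, so the call is attributed
  to the frameshift and the stop/finger rules are not double-reported.
  A ≥ 99% identical same-species peer of equal length marks both members
  of the pair `unresolved_duplicate` (assembly heterozygosity produces
  such "paralogs" that are really alleles); a lesion takes precedence over
  near-duplication. The 99% threshold separates alleles from recent
  paralogs in the synthetic tests and is configurable.

# Promoter motifs

Promoters are the 600 bp immediately 5′ of the ATG on the transcribed
strand (the window within which the known regulatory interactions of
these genes concentrate), truncated and flagged when the scaffold ends.
Scanning uses IUPAC consensus semantics via `Biostrings`: every start
offset is counted (the double SKN-1 site RTCATCAT is itself two
overlapping cores, so overlap-aware counting is required), both strands
by default, palindromic intervals reported once on the top strand, and an
`N` in the sequence never satisfies a non-`N` code. Site positions are
reported as bp upstream of the ATG (1 = the base 5′ of the A).

Enrichment uses the Poisson upper tail: with per-offset match probability
$p_s = \prod_j P(\text{base} \in \text{allowed}_j)$ under an i.i.d.
mononucleotide background, the null expectation over both strands is
$\lambda = (L - w + 1)(p_+ + p_-)$ and $P = P(X \ge k;\lambda)$. The
default background is the scanned promoter's own composition — the most
defensible choice when no genome-wide model is given — with uniform and
user-supplied compositions available. No multiple-testing correction is
applied by default, matching per-gene P ≤ 0.05 usage; Monte-Carlo
simulation confirms the Poisson tail within 3 standard errors for
k ∈ {1,2,3} at 10,000 replicates. Polypyrimidine (PPY) tracts are maximal
windows of length ≥ 12 with C+T fraction ≥ 0.9 (A+G windows are reported
as bottom-strand tracts); their strand bias is summarized from site
tables because at these thresholds pyrimidine-rich windows also arise
frequently by chance in AT-rich background.

# Serine codon bias

Serine is the only amino acid split across two codon blocks (TCN and
AGY). `tally_serine_codons()` counts the six serine codons inside a
protein-coordinate interval (by default the detected Poly-S domain), and
`chisq_codon_bias()` tests the tally against a background table with
Pearson goodness-of-fit: `tcn_vs_agy` (1 df) tests the TCN/AGY split
against the background TCN fraction, `within_tcn` (3 df) the four TCN
counts against TCN-internal proportions. Both are exposed because the
published significance statement does not pin down which comparison was
made; the default is the variant that reproduces the printed statistic
(≈ 177.8 on the printed 554/557 tally against a 75% background, upper-tail
p of order 10⁻⁴⁰). The shipped background (`celegans_genscript`) carries
the published genome-wide values — TCN 75% of serine codons, TCT/TCC 28%
and 18% within TCN — with the unpublished TCA/TCG remainder split evenly
(configurable). Expected cells below 1 set a warning flag without
suppressing the test.

# Synteny

Distances are measured between gene *extents* (outermost exon
boundaries), which are strand-neutral and match to-scale linkage
diagrams; ATG-to-ATG distances would shift values by roughly the gene
lengths. Orientation falls in four classes — `same_strand_ab`,
`same_strand_ba` (by transcription order), `convergent` (3′ ends facing),
`divergent` (5′ ends facing) — with overlapping extents an error.
Clustering is single-linkage chaining along a scaffold with the
thresholds the analyses quote: 5 kbp for med clusters, 10 kbp for end-3
pairs. A gene within 10 kbp of a scaffold end is flagged, since apparent
non-linkage there may be an assembly break.

# Conservation

`profile_alignment()` computes per-column majority residue, identity
fraction, gap fraction and an invariant flag. Gap handling is strict: a
column containing any gap is never invariant, while the identity-fraction
denominator excludes gaps so "conserved" is judged among residues
present. Conserved blocks are maximal runs of gap-free columns with
per-column identity ≥ 0.9 and length ≥ 5 (a per-column threshold implies
the run's mean also meets it, and keeps block boundaries well defined).
The threshold behind "generally conserved" contact positions is 0.8 by
default — the published figures mark such positions without stating a
number — and the contact-position lists themselves ship empty because
they must be transcribed from a structure annotation.

`pdistance_tree()` builds a neighbor-joining tree on p-distances
(pairwise gap deletion; complete deletion available) and scores clade
purity: the fraction of families whose members form a clade on the
unrooted tree. This is deliberately a property check, not phylogenetics —
likelihood trees and bootstrap supports are out of scope — but NJ is
exact on additive matrices, which the tests verify on 4- and 5-leaf
cases. Family-rate comparisons are made on DBD columns: the generator
conserves the poly-serine region in every family by construction, so
whole-protein invariant fractions would dilute the rate signal, whereas
the DBD carries it directly (mirroring invariant-residue counts ordered
END-1 > END-3 > MED).

# The synthetic generator

`generate_dataset(family_spec(seed))` emits scaffolds, gene models,
CDS/protein/promoter sequences, a motif-site listing, true per-family
alignments and truth tables. Its defaults *are* the study regime:

* 20 species, the first 5 forming a Japonica-like group; one end1 per
  species, end3 copies 1 + Poisson(1.0) (mean 2.0), med copies
  1 + Poisson(2.7) with two species amplified to 20–21 copies (overall
  mean ≈ 5.6, ≈ 3.7 excluding the two).
* Planted promoter sites on representative genes, with the *totals*
  allocated multinomially so the stated averages are exact by design:
  3.5 double-SKN-1 sites per med promoter (within 300 bp of the ATG),
  2.6 MED sites per end3 and 1.2 per end1 gene with sites (within 200 bp,
  ~55 bp ladder spacing), 1.5/1.6 degenerate SKN-1 sites per end1/end3
  gene with sites, 34 end1 PPY tracts with exactly 30 on the top strand,
  and a single-med species carrying six isolated RTCAT cores and no
  double site (realized by rejection sampling). Because AGTATAC is
  quasi-palindromic (followed by T it also matches one base over on the
  minus strand), planted MED sites are written with one flanking guard
  base so each scans as exactly one occurrence; scan-measured means
  therefore exceed planted means only by the small background expectation
  (≈ 0.06–0.13 sites per 600-bp promoter for the 7–8-mers).
* Protein families evolved from per-family ancestors by substitutions at
  rates med 0.25 > end3 0.12 > end1 0.05 per site, never touching the
  start methionine, finger cysteines, the poly-serine region, or the
  END-1 frozen blocks (including an invariant FGQYF). Japonica-group med
  proteins lose one inner-spacer residue (X18 → X17) and, like all end
  genes, carry the zinc-finger intron; Elegans-group med genes are
  intronless. Background residues (and substitution targets) are drawn
  from an alphabet without C, S or T so planted fingers and poly-serine
  domains are the only matches to their own patterns.
* Poly-serine codons are drawn with a 0.99 TCN bias split
  TCT/TCC/TCA/TCG = 0.50/0.22/0.18/0.10; the draws are recorded per gene
  so tallies can be checked exactly.
* Lesions (truncation, DBD stop, DBD frameshift, missing finger
  cysteine) hit non-representative copies at rate 0.16, mirroring the
  observed pseudogene fraction; one species carries a ≥ 99.5%-identical
  end1 pair on a small extra scaffold (both marked unresolved in truth).
* Linkage: 13/20 species carry end1 and end3 on one scaffold at uniform
  20–63 kbp separations (one fixed at 30 kbp), cycling through all four
  orientation classes; among species with ≥ 2 end3 genes, 70% place a
  second copy within 10 kbp; half of multi-med species carry a ≤ 5 kbp
  med pair; one species carries 9 med genes across exactly 23 kbp; one
  unlinked species has its end1 3 kbp from a scaffold end.

Two runs with one seed are byte-identical file for file. What the
generator does *not* emulate — indels (alignments are equal-length except
the known spacer deletion), realistic intergenic sequence, transposons,
assembly gaps, sequencing error, codon-usage structure outside the
poly-serine region — bounds what green tests mean: they validate the
measurement machinery against planted truth under the stated statistical
regime, not the biological accuracy of any annotation on real genomes.

# Numerical and design choices

* Problem sizes: 20-species datasets (~170 genes, ~130 scaffolds);
  100 genes for stitching accuracy; 100 random 600-mers for the
  scanner/oracle comparison; 10,000 Monte-Carlo promoters for Poisson
  calibration; 2,000 null replicates for the type-I error, drawn at the
  published tally size of 557 serine codons, where the exact rejection
  rate of the asymptotic test is 0.0502 (discreteness makes the exact
  rate oscillate with tally size, e.g. 0.053 at 600).
* Determinism: a single master seed drives the generator; the pipeline
  itself is RNG-free, so reruns are byte-identical.
* Degenerate inputs: empty FASTA files parse to empty sets; single-exon
  genes have no introns; summaries of empty site tables are errors rather
  than NaNs; spacing over genes with one site is reported `NA`; zero
  distances in NJ resolve deterministically in input order.
* The Supplemental-site-listing dialect is a configurable column-alias
  map (gene/species/motif/start/strand/site with common synonyms), since
  the authoritative file's exact column structure is not fixed by the
  publication.

# Limitations

The stitcher performs bounded exact search, not spliced alignment: HSPs
must be compatible and on one scaffold/strand, frameshift-tolerant joins
are out of scope, and unresolvable gaps are reported rather than forced.
Consensus scanning is not a PWM model; motif definitions are exact IUPAC
strings, and lexicon entries for Sp1/TATA/SL1 are placeholders to be
replaced with authoritative consensi. The chi-square codon-bias test is
asymptotic; for very small tallies the warning flag should be heeded.
The clade-purity tree is a sanity check on family separation and is not a
substitute for model-based phylogenetics.
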