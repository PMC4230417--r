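---
title: "A reference-anchored pan-genome workflow for a triplicated plant genome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reference-anchored pan-genome workflow for a triplicated plant genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pangenekit)
```

## The problem

Crop species such as *Brassica rapa* span extreme morphotypes — heading
cabbages, tuberizing turnips, rapid-cycling oil types — that are nevertheless
very close at the sequence level, on the order of 0.45 differences per 100 bp
between cultivated lines. When deep *de novo* assembly of every line is out of
reach, a practical alternative is reference-anchored comparison: map
assembly-based variant calls from each resequenced line onto the single
reference genome, reconstruct a pseudo-genome per line by applying the calls,
and compare gene content across the resulting trio. The species is a
mesopolyploid: a whole-genome triplication left three fractionated subgenomes
(LF, the least fractionated, through MF1 to MF2), so gene families commonly
have one, two or three surviving copies, and copy-number differences between
lines ("retained" and "lost" genes) are part of the biology of interest.

`pangenekit` implements that comparison end to end, and ships a simulator
that generates every input of the workflow together with ground-truth tables,
so the entire pipeline can be validated on data where the right answer is
known.

## The workflow

The pipeline mirrors the reference-anchored study design, in eight stages.

1. **Merge caller outputs** (`merge_caller_outputs()`). Assembly-based
   variant calling is run twice per genotype, with a bubble caller and a
   path-divergence caller. Two calls are *overlapping* when they lie on the
   same chromosome and either share a position or their assembled-contig
   intervals `[pos, pos + contig_length)` intersect; each group of
   transitively overlapping calls is collapsed to the single call with the
   longest assembled contig. The contig-interval rule is our operational
   reading of "close enough that one contig could cover another"; ties on
   contig length keep the bubble-caller record, then the leftmost call, then
   the lexicographically smaller alternative allele, purely for determinism.
2. **Quality filter** (`filter_variants()`). Calls whose contig 5′ flank maps
   with quality `Q < 30` are removed. The boundary is inclusive — a call at
   exactly `Q = 30` survives — because the filter is defined by the strict
   inequality.
3. **Pseudo-genome reconstruction** (`apply_variants()`). All remaining
   variants are applied to the reference. The function returns the
   reconstructed sequence together with a `coordinate_map`, a block-wise
   monotone liftover between reference and genotype coordinates
   (serialisable as a UCSC chain file). SNVs do not break alignment blocks;
   indels do. Positions inside deleted spans lift to `NA`; all other
   positions round-trip exactly. Calls are validated against the reference
   allele and overlapping calls are rejected rather than silently resolved —
   applying "all remaining variants" presumes a consistent set.
4. **Coding-effect annotation** (`annotate_effects()`). Each variant ×
   overlapping gene pair receives the most severe applicable category in the
   fixed order `EXON_DELETED > FRAME_SHIFT > STOP_GAINED > STOP_LOST >
   START_LOST > SPLICE_SITE_ACCEPTOR > SPLICE_SITE_DONOR > NONE`. Codon
   evaluation is strand-aware and works on the re-built mutant spliced CDS;
   splice sites are the first/last two intronic bases (GT/AG convention,
   the usual variant-annotator default, since the category names do not
   define extents). `count_affected_genes()` deduplicates to gene level.
5. **Region classification** (`classify_regions()`). Every variant is
   assigned one region by the precedence EXON > UTR > INTRON > INTERGENIC at
   its start position, where EXON means CDS-overlapping and UTRs are their
   own category. Counts and summed lengths are grouped by the containing
   gene's subgenome; intergenic variants take the nearest gene's subgenome.
   A variant's length is `max(len(ref), len(alt))`, so a SNP contributes
   1 bp. (Whether indel "length" should instead be the reference span alone
   is not decidable from the table definitions we follow; we flag the choice
   here.)
6. **Positional orthology** (`positional_orthologs()`). Protein similarity
   is Smith–Waterman local alignment with BLOSUM62, gap open 11 / extend 1
   (a gap of length *L* costs `11 + L`), computed by a small C++ kernel with
   a pluggable scorer interface. Two genes are positional orthologs when
   they are reciprocal best hits — each the other's unique best score, at or
   above a floor of 50 — *and* lie on same-named chromosomes. Score ties
   break uniqueness and therefore form no pair; that sacrifices a little
   recall for determinism.
7. **Pan-genome classification** (`classify_pangenes()`,
   `call_retained_lost()`). With three genomes there are three pairwise
   comparisons; a gene present in both of its comparisons (hence in all
   three genomes) is *common*, a gene in neither is *unique*, and everything
   else is *dispensable*. Against an outgroup proteome,
   `ortholog_copy_counts()` counts, for each outgroup gene, the genome genes
   whose unique best outgroup hit it is and whose score reaches
   `inclusion_ratio` (default 0.8) of the best such hit — a best-hit cluster
   rule standing in for full ortholog-group inference, which reproduces
   1:many copy counting on data with known family structure. An outgroup
   gene with counts `(x, y, z)` is *retained* for the genome with `x > y = z`
   and *lost* for the genome with `x < y = z`. We require the two other
   counts to be exactly equal: the defining examples are the 3-2-2 and 2-3-3
   patterns, and a trio like (1, 2, 3) singles out no genome, so it is
   called *neither* rather than guessing.
8. **Subgenome transfer** (`assign_by_coordinates()`,
   `transfer_assignments()`). Reference genes carry published LF/MF1/MF2
   labels; a re-annotated reference gene inherits a label by coordinate
   congruence (reciprocal overlap ≥ 50%; the overlap criterion for "same
   coordinates" is unstated upstream, so the familiar 50% reciprocal rule is
   our default), and a genotype gene takes the label of its reference RBH
   partner, or, failing that, of its nearest *labeled* up- and downstream
   neighbours when the two agree. Skipping unlabeled neighbours is our
   resolution of a rule that is otherwise undefined when the immediate
   neighbour has no label; chromosome-terminal genes with a single labeled
   side stay unassigned.

Annotation sets can additionally be compared with
`compare_annotations()`/`coverage_curve()`: a reference feature matches a new
feature when the intersection covers at least a fraction *f* of the
*reference* feature (the fraction is deliberately denominated on the
reference model only), and matches are booked as reciprocal, split (one
reference, several new) or join (several reference, one new). A feature that
participates in both a split and a join is counted as split — one category
per feature keeps the table a partition, at a small risk of divergence from
other implementations that may double-count such features.

## The simulator

`simulate_pangenome()` generates the full study design: a triplicated,
annotated reference; two derived genotypes; two noisy caller outputs per
genotype; two outgroup proteomes; and truth tables for every downstream
quantity.

**What it emulates.** Each chromosome carries one contiguous block per
subgenome. Gene families draw a copy class (1, 2 or 3 copies; default
probabilities 0.6/0.25/0.15) under a capacity constraint so that each
subgenome holds exactly `n_genes_per_subgenome` genes; copies land in
distinct subgenomes, preferring those with most free slots, and on distinct
chromosomes whenever the chromosome count allows — in the real triplication
the three blocks descending from one ancestral region lie on different
chromosomes, which is exactly the premise of the same-chromosome
positional-orthology constraint. (With fewer chromosomes than copies, a
lost gene's same-chromosome paralog can pass the positional filter in its
place, so study-scale runs use at least three chromosomes.) Genes have 1–3
exons, GT..AG introns of 60–120 bp, UTRs of 30–80 bp and CDSs of 50–90
codons, on either strand. Genotypes differ from the reference by SNPs
(default 0.0045/bp), short indels (4×10⁻⁴/bp, ≤10 bp), whole-gene losses
(probability 0.03/gene) and tandem duplications (0.02/gene). Callers miss a
variant with probability 0.05 (it is then reported by only one of the two),
assign a low (<30) flank quality with probability 0.02, and the
path-divergence caller assembles the longer contig at half of the shared
sites, exercising the longest-contig merge rule.

**Divergence bookkeeping.** `snp_rate` is the density of single-nucleotide
differences of each genotype *versus the reference*. The reference is one of
the three genomes of the trio, so reference–genotype comparisons are pairwise
comparisons at the advertised 0.45/100 bp; between the two derived genotypes
the expected density is roughly twice that, as in a star phylogeny. Short
indels add about 0.04 events/100 bp on top of the SNP density.

**What it deliberately does not emulate**, and what that means for the
tests: no read-level sequencing or k-mer assembly (caller outputs are
derived from the truth by subsampling and jitter, not by re-calling); no
recombination or population structure; no annotation errors — genotype gene
models are the reference models lifted through the true coordinate map plus
inserted duplicates, standing in for a re-annotation step that real data
would need. Passing tests therefore demonstrate the correctness of the
comparison machinery, not robustness to assembly artefacts or gene-model
misprediction.

**Constraints that keep the truth unambiguous.** Several placement rules
exist so that the recorded truth is exactly recoverable, and they are also
biologically motivated:

* Variant events are placed uniformly at random but rejected when their
  assembled-contig intervals could overlap another event's; this keeps the
  merge step lossless for true variants.
* Short indels never touch exons or splice dinucleotides — coding indels are
  under strong purifying selection — which also keeps lifted gene models
  exact.
* Coding SNPs are drawn stop-codon-safe and never hit the start or stop
  codon: fixed differences between viable inbred lines are strongly depleted
  for nonsense alleles, and gene presence/absence is modelled by explicit
  whole-gene loss events instead of pseudogenization.
* Paralog drift (3% of CDS positions per copy) and outgroup drift (4% and 7%
  of residues for the two outgroups) use a *fixed* number of changes rather
  than a per-base coin flip. On desk-scale proteins the Poisson variance of
  per-base drift would occasionally push a true family member below the
  0.8 inclusion ratio or a paralog inside the ortholog distance; the fixed
  count bounds the within-family score spread by construction while keeping
  paralogs several-fold more distant than orthologs. Family copies are
  additionally forced to distinct proteins, so best-hit relations are never
  tied.
* A tandem duplicate is the parent's sequence with 1–3 forced
  *nonsynonymous* changes, and the parent copy stays variant-free in that
  genotype, so the duplicate can never out-score the parent in RBH and
  dup/parent identities match the truth tables.

## Numerical and interface choices

* Coordinates are 1-based inclusive at every file interface (GFF3/VCF
  convention); variant alleles are stored un-anchored internally (an
  insertion has an empty reference allele) and left-anchored only in VCF.
* Caller metadata travel in the VCF INFO keys `CONTIGLEN`, `FLANKQ` and
  `CALLER`; files missing the first two are rejected.
* The liftover chain writes the reference as target and the genotype as
  query, both on the + strand.
* `Q = 30`, score floor 50, inclusion ratio 0.8 and the 50% reciprocal
  overlap are the package defaults and are all exposed as parameters.
* Genes whose reference CDS length is not a multiple of three trigger a
  model-validation warning and are skipped by the effect annotator.
* Determinism throughout: a `simulation_config(seed = )` reproduces every
  simulated byte; `run_pipeline()` reruns to identical checksums.

## Validation strategy and problem sizes

The test suite checks every operation against an independent oracle or the
simulator's truth: caller merging against a brute-force all-pairs overlap
search (1,000 randomized caller pairs of up to 200 calls), reconstruction
against right-to-left string editing plus exhaustive liftover round-trips
(50 genotypes of 50 kb at the default divergence), the alignment kernel
against `Biostrings::pairwiseAlignment` and RBH against exhaustive
all-vs-all scoring (50×50 proteomes with planted homologs), annotation
comparison against a quadratic interval oracle (100 random instances at
f ∈ {1, 0.75, 0.5, 0.25}), effect categories against a chromosome-level
retranslation oracle plus a reverse-complement symmetry property, and the
pan-genome stages against truth tables on ten noise-free simulations of
300 genes (exact agreement, including the 3-2-2 retained and 2-3-3 lost
patterns) and three noisy ones (≥95% agreement required). Simulated genomes
in the tests use 1–2 chromosomes of 40–180 kb with 15–300 genes — small
enough to iterate quickly, large enough that every copy-class, strand and
category combination occurs.

## Known limitations

* The RBH scorer is all-vs-all Smith–Waterman; fine for desk-scale
  proteomes (hundreds to a few thousand genes), not for full plant
  proteomes, where the pluggable scorer should be backed by an external
  search tool.
* Copy counting is a best-hit cluster rule, not full ortholog-group
  inference; it is validated against known family structure, not against
  curated ortholog databases.
* The retained/lost rule requires the two other genomes to agree exactly;
  patterns like (1, 2, 3) are reported as `neither`.
* Genotype gene models come from coordinate liftover (plus simulated
  duplicates); genes gained through means other than tandem duplication
  would require genuine re-annotation, which is out of scope.
* Heterozygous calls are not modelled — the lines compared are double
  haploid or inbred.
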