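---
title: "Methods: genotyping-by-sequencing analysis with gbskit"
author: "gbskit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotyping-by-sequencing analysis with gbskit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbskit)
```

## The problem and the model

Genotyping-by-sequencing (GBS) is a reduced-representation protocol:
a genome is digested with a restriction enzyme, barcoded adapters are
ligated to the fragment ends, and short single-end reads are sequenced from
the cut sites. Because only fragment ends are sequenced, a modest read
budget yields usable depth at a reproducible subset of loci, which allows
simultaneous SNP discovery and genotyping across many pooled samples.
`gbskit` implements the full desk-scale analysis chain:

1. **Enzyme assessment** by in silico digestion: for a candidate enzyme,
   how many fragments arise, and what fraction of the *internal* fragments
   (those bounded by cut sites at both ends — the only ones that can
   acquire adapters at both ends and amplify) falls inside a
   sequencing-friendly size window, by default 100–400 bp.
2. **Read processing**: demultiplexing by exact barcode with validation
   that the bases after the barcode match the enzyme's restriction remnant
   (for ApeKI `G^CWGC`, a read must continue with `C[AT]GC`), removal of
   the barcode (the remnant is genomic and is retained), clipping of
   common-adapter read-through on short fragments, and the length/N
   filters (reads shorter than 25 bases or containing `N` are discarded).
3. **Mapping** with a built-in substitution-only unique mapper (or import
   of externally produced SAM with a MAPQ threshold standing in for
   "unique location").
4. **Variant calling** from per-sample pileups with conservative
   genotype rules, followed by depth / missing-data / minor-allele
   frequency filters and an explicit heterozygote-correction stage.
5. **Annotation** of variants against GFF3 gene models into structural
   categories and coding effects.
6. **Diversity analysis**: pairwise informative-site counts, p-distances,
   neighbor-joining trees with majority-rule bootstrap consensus, and
   genotype-concordance and protocol-comparison statistics.

A seeded simulator generates data with the structural properties the
pipeline assumes, so every stage is testable end to end against known
truth without any external download.

## Key parameters

| Parameter | Default | Meaning |
|---|---|---|
| `size_range` | 100–400 bp | fragment-size window counted as sequencing-friendly |
| `min_length` | 25 | minimum processed read length (bases) |
| `min_adapter` | 5 | exact adapter bases required as clipping evidence after a remnant |
| `k` | 31 | seed k-mer length of the built-in mapper |
| `max_mismatch` | 2 | substitutions allowed by the built-in mapper |
| `min_mapq` | 20 | SAM-import threshold operationalising "unique location" |
| `min_depth` | 2 | reads per sample per site required for any genotype call |
| `het_min_reads`, `het_min_frac` | 2, 0.2 | evidence required for a heterozygous call |
| `max_missing` | 0.5 | maximum per-site missing fraction |
| `min_maf` | 0 | minimum minor allele frequency |
| `flank` | 5000 bp | upstream/downstream window in annotation (inclusive) |
| `splice_window` | 2 | intron bases at each junction classified SPLICE_SITE |
| `B` | 1000 | bootstrap replicates for the consensus tree |

The genotype rule is deliberately conservative for GBS depths: a site
needs two reads in a sample for any call; a heterozygote needs at least
two reads of *each* allele and a minor fraction of at least 0.2; a lone
stray read of a second allele — the typical signature of sequencing error
at depth 2–10 — is ignored and the majority allele is called homozygous,
with count ties broken toward the reference. Heterozygote correction
(replacing every heterozygous call with missing, then dropping sites left
monomorphic) reflects the empirical observation in selfing crops that a
large share of GBS heterozygote calls arises from reads of paralogous
loci rather than true heterozygosity.

Minor allele frequency is computed over the non-missing allele calls
(two per genotype); for multi-allelic sites it is defined as one minus
the major-allele frequency, which coincides with the minor-allele
frequency in the biallelic case.

## Selective-base complexity reduction

A common amplification primer may extend one or two bases past the
restriction remnant into the insert. Only fragments whose insert begins
with those bases — at either end, since adapter ligation is
orientation-agnostic — amplify. `selective_subset()` models the retained
set; `simulate_reads(..., selective =)` redistributes a fixed total read
budget over the retained fragments, so per-fragment depth rises by
roughly the inverse of the retained fraction (about 16/2 for one
dinucleotide checked at both ends). This is the mechanism by which
selective primers raise depth of coverage — and with it the number of
loci passing the two-read calling threshold — without more sequencing.

## What the simulator emulates, and what it does not

`sim_config()` defaults define the study conditions used throughout the
test suite:

* two 30 kb contigs with soybean-like GC (0.35) and ApeKI sites planted at
  uniform spacings of 130–240 bp, so internal fragments fall inside the
  100–400 bp window; the generator scrubs all chance recognition sites and
  verifies that digestion recovers exactly the planted sites;
* 8 barcoded samples (distinct 6-mers, hence prefix-free), ~200 SNPs and
  ~5% indels (1–5 bp) placed inside internal fragments away from
  remnants and selective-base positions and within reach of a read from at
  least one fragment end;
* fully homozygous samples by default (`het_fraction = 0`): the package
  targets selfing crops whose cultivars are essentially inbred lines, and
  heterozygous GBS calls in such material are dominated by paralogy
  artifacts, which the pipeline removes anyway; heterozygosity is
  configurable and exercised in unit tests;
* per-site alternate-allele frequency drawn from 0.2–0.8; sites drawn
  with no alternate carrier are redrawn so the truth set has a fixed
  number of polymorphic sites;
* 100 b single-end reads, Poisson per-fragment depth, each read starting
  at a random fragment end (which fixes its strand); fragments shorter
  than the read produce read-through into the distal remnant followed by
  the common adapter sequence, exercising the clipper on realistic bytes;
  uniform per-base substitution error.

Every pre-adapter base a simulated read carries is literal reference
sequence (templates run from one cut through the far cut-site instance),
so error-free reads map back exactly and adapter-clipped read-through
retains only reference-matching bases.

Depth bookkeeping: `mean_depth` is the Poisson mean per (sample,
fragment). Because each read picks a random end, a locus reachable from
only one fragment end sees about half the fragment's reads. Where a
property is stated at a per-locus depth (e.g. recovery at ~8 reads per
SNP locus), the simulation uses a per-fragment mean of twice that value.

Not modelled: PCR-duplicate structure and amplification bias beyond
uniform Poisson (a per-fragment weight hook exists), base-quality error
profiles, organellar contamination, methylation sensitivity of the
enzyme (in silico counts are maxima — real digests of methylated genomes
cut less), and paired-end layouts. Passing tests therefore demonstrate
algorithmic correctness under idealised sequencing, not robustness to
every artifact of real libraries.

## Numerical and algorithmic choices

* **Coordinates** are 0-based half-open internally; 1-based only in
  VCF/GFF3 text.
* **Digestion** scans the forward strand for possibly overlapping IUPAC
  matches (each degenerate match yields a cut — physical digestion can cut
  either overlapping site). All bundled enzymes are degenerate
  palindromes, so forward-only scanning is lossless; non-palindromic
  patterns are rejected outright. Matches spanning `N` do not fire.
* **Mapper seeding** uses k-mers at read offsets 0, k, 2k and the read
  end (canonical form, both strands), so a read carrying a variant inside
  one seed window is still recovered from another; every candidate is
  verified over the full read at `max_mismatch`, and only a single
  passing location yields an alignment. The mapper is ungapped:
  indel-carrying reads are left to the SAM-import path, and reads whose
  indel sits at a read edge can occasionally be placed with a shifted
  tail, producing spurious substitution calls confined to the indel's
  read-length neighbourhood — use an external gapped aligner when indels
  matter.
* **Neighbor joining** follows the classic Q-criterion agglomeration with
  deterministic tie-breaking by the smallest label pair; negative branch
  lengths are clamped to zero with the deficit moved to the sibling
  branch. p-distance is the default distance (the minimal defensible
  choice for genotype matrices); a heterozygote scores 0.5 against either
  homozygote, though the default pipeline removes heterozygotes first.
* **Bootstrap** resamples SNP sites with replacement; supports are the
  fraction of replicates containing each retained bipartition of the
  majority-rule consensus; the seed is mandatory.
* **Annotation** assigns one category per variant with the priority
  SPLICE > UTR > EXON > INTRON inside genes, nearest-gene strand-aware
  flanks (inclusive at exactly 5000 bp) outside, ties to the
  lexicographically smallest gene id. The splice window is two intron
  bases. For genes with several isoforms the longest-CDS isoform is used.
  Models whose CDS length is not a multiple of three (or whose first
  phase is nonzero) are flagged partial and excluded from codon effects.
  In summaries, the upstream/downstream flank classes are sub-labels of
  the intergenic fraction.
* **Degenerate inputs**: an empty sequence digests to nothing; a contig
  without internal fragments reports an in-range fraction of 0 with a
  warning; a sample pair sharing no genotyped site makes `p_distance()`
  fail loudly naming the pair; unsorted sites make `write_vcf()` fail
  rather than silently reorder.

## Problem sizes used in the checks

The test-suite simulations use 1–2 contigs of 6–30 kb, 2–8 samples,
10–200 variants and per-fragment depths of 3–16, which keeps the whole
suite to a few minutes on one CPU while leaving every property
(placement accuracy, truth recovery, selective-depth scaling,
bootstrap supports) statistically unambiguous at the asserted
thresholds. The digestion oracle comparisons run on contigs up to 50 kb
and the enzyme-ordering check on a 1 Mb contig.

## Known limitations

* The built-in mapper is a desk-scale stand-in: ungapped, exact-seeded
  and entirely in R. Real-genome workloads should map externally (BWA,
  minimap2) and enter through `import_sam()`.
* "Unique location" on import is operationalised as MAPQ ≥ 20, which is
  aligner-specific; the threshold is exposed.
* Imputation of missing genotypes is out of scope: `export_fastphase()`
  writes the input layout for the external fastPHASE program.
* The enzyme table covers the common GBS enzymes (ApeKI, PstI, MseI);
  other palindromic enzymes can be supplied via `--enzyme-file` /
  `read_enzyme_file()`. Two-enzyme protocols are not modelled.
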