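---
title: "Methods: recessive trio exome screening with trioscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recessive trio exome screening with trioscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trioscreen)
```

## The screening model

trioscreen implements the candidate-variant screen for a fully penetrant
autosomal-recessive monogenic disease observed in a small cohort: affected
offspring, their parents, and unaffected controls drawn from the same
population. Under that model the causal site must satisfy three exact
genotype constraints — every affected sample homozygous for the alternate
allele, every parent of an affected sample heterozygous (they are obligate
carriers; hemizygous calls are accepted as carrying), and no unaffected
control homozygous-alternate. Controls *may* be carriers: in a breed or
population where the allele segregates, heterozygous controls are expected,
and only homozygosity contradicts the model.

These constraints are embedded in a stepwise funnel rather than applied as
one opaque predicate, because the per-step survivor counts are themselves
the scientific record of the screen. The SNV branch orders the steps
total → coverage → gene-coding → exon-coding → segregation
(affected-homozygous and parent-heterozygous jointly) → control exclusion →
missense-only; the indel branch defers the exon restriction to the end and
splits the segregation requirement into carried-by-all, affected-homozygous
and parent-heterozygous steps. "Gene coding" means anywhere within a gene
span, introns included, and "exon coding" within an exon interval — the
two successive region classes are deliberately nested so their counts are
monotone.

Assumptions worth stating: full penetrance (one discordant affected
genotype eliminates a variant — there is no tolerance parameter);
bi-allelic reasoning (multi-allelic VCF records are split into one record
per alternate allele on read); and a single causal locus (no
compound-heterozygous, dominant or X-linked models).

## Parameters and their defaults

* `min_depth = 10` reads: the coverage rule. It is applied to affected and
  parent samples only (`depth_scope = "core"`) by default, because a
  low-coverage control cannot be allowed to discard a true candidate — a
  missing or thin control genotype simply fails to certify homozygosity.
  `depth_scope = "all"` extends the rule to controls for users who prefer
  the stricter reading. Missing `DP` always fails: depth is an evidentiary
  requirement, not an annotation.
* Missing genotypes fail the affected and parent requirements but do *not*
  trigger the control exclusion, for the same evidentiary reason.
* Triage thresholds (all closed at the boundary): SIFT ≤ 0.05 deleterious,
  PROVEAN ≤ −2.5 deleterious (the predictor's own published threshold),
  PolyPhen-2 ≥ 0.453 possibly damaging and ≥ 0.957 probably damaging (the
  standard HumDiv bands). The PolyPhen-2 and SIFT cuts are package
  defaults, declared rather than inferred, and are configurable through
  `triage_criteria()`.
* Fluorescence calling: `ntc_radius = 0.25` Rn units around the
  no-template-control centroid excludes failed wells; cluster separation
  in the simulator is 1 Rn unit, so the radius is a quarter of the
  inter-cluster distance. Published assay read-outs give no numeric
  threshold for this; the default is a declared design choice.
* Alignment scoring: BLOSUM62 with affine gap penalties 10 (open) and 0.5
  (per position), Clustal-like defaults. Percent identity divides the
  count of identical columns by the **total number of alignment columns,
  gap columns included**; published "homology" percentages rarely state
  their denominator, so `denominator = "shorter"` and `"anchor"` are
  exposed as alternatives. Domain ranges are configuration
  (`domain_identity()` takes a data frame), never hard-coded.

## What the synthetic cohort emulates — and what it does not

The generator exists so that every downstream stage is testable without
access to the original raw sequencing data. Its default design mirrors the
study shape this pipeline targets: 3 affected, 2 parents, 6 controls.
It emulates:

* a reference with protein-coding gene models whose CDS are clean ORFs
  (ATG start, no internal stop) split across exons on both strands;
* a planted causal variant that is always an exonic, missense-inducing SNV
  at a first or second codon position (the discovered-variant class), with
  genotypes forced to the recessive pattern and control carriers drawn
  with probability `carrier_freq_controls = 0.1`;
* background variants with allele frequencies uniform on
  `background_af_range = [0.05, 0.95]` and genotypes drawn independently
  per sample from Hardy–Weinberg proportions;
* per-call sequencing depth as negative binomial with
  `mean_depth = 30` and dispersion (NB size) `depth_dispersion = 8`. With
  these defaults about 1.5 % of calls fall below 10×, so the coverage
  filter does real work on background sites. At the causal site itself the
  affected and parent depths are drawn from the same distribution
  left-truncated at `causal_min_depth = 10`: the planted variant models a
  variant that *was discovered*, i.e. one sequenced at usable depth, and
  coverage dropout at the causal locus is a separate failure mode that the
  generator does not conflate with filter correctness;
* optional symmetric genotyping error: with probability
  `genotyping_error` a written call is replaced by a uniformly chosen
  different diploid genotype — the simplest corruption that exercises
  filter robustness;
* endpoint fluorescence wells at the canonical scatter geometry
  (homozygous-mutant high-FAM/low-VIC, heterozygous high/high, wild-type
  low/high, NTC at the origin) with isotropic Gaussian noise, floored at
  zero because an Rn ratio cannot be negative.

It deliberately does **not** emulate: read-level data (no FASTQ, mapping
or calling artifacts), linkage disequilibrium between background variants,
relatedness among controls (treated as unrelated founders, a choice the
source material does not constrain), strand- or allele-biased depth,
UTRs/non-coding exons (toy CDS coincide with exons), or multi-nucleotide
and structural variation. Passing tests on synthetic cohorts therefore
demonstrate the *logic* of the funnel — segregation arithmetic, region
classification, codon translation, count bookkeeping — not robustness to
the error modes of real exome data.

## Numerical and algorithmic choices

* **Coordinates** are 1-based inclusive everywhere (VCF and GFF3 native);
  no half-open interface is exposed.
* **Fisher exact test**: two-sided by the point-probability method (sum of
  hypergeometric probabilities not exceeding the observed table's, with
  the customary 10⁻⁷ relative slack for floating-point ties), delegated to
  `stats::fisher.test` and cross-checked in the test suite against an
  independent `lchoose`-based enumeration to 10⁻¹². A table with a zero
  margin is reported as `p = 1` with a `degenerate` flag rather than an
  error.
* **3-means seeding** for fluorescence calling is deterministic: seeds at
  (max FAM, min VIC), (max FAM, max VIC), (min FAM, max VIC), matching the
  scatter-plot geometry, so repeated calls on the same wells give
  identical genotypes. If fewer than three distinct points remain after
  NTC exclusion, the seeds themselves serve as centroids.
* **Alignment tie-break**: among co-optimal global alignments,
  `pairwiseAlignment`'s choice depends on argument order; trioscreen
  always aligns the lexicographically smaller sequence as the pattern and
  swaps back, making percent identity exactly symmetric.
* **Survivor ordering**: funnel survivors are reported in
  (chrom, pos, alt) order for reproducibility.
* **Stop-codon edge cases**: a stop-gained SNV is `nonsense`; a
  stop-lost change is reported as `missense` (the consequence vocabulary
  is deliberately small); a substitution disrupting the initiator codon is
  flagged `start_lost` and formatted `p.Met1?`.
* **Genotype vocabulary**: VCF-facing modules use
  hom_ref/het/hom_alt/hemi/missing; the assay-facing modules use
  wild/het/hom_mut, matching how genotyping tables are reported.

## Design decisions that were genuinely open

* The published funnel's coverage step precedes segregation and the
  source never states whether controls' depth was required; `depth_scope`
  makes both readings available and defaults to core-only (rationale
  above).
* The indel-branch step "mutated in all affected and parents" is read as
  "carries at least one alternate allele"; the subsequent
  homozygous/heterozygous refinements make any stricter reading
  redundant.
* The identity denominator question (gapped columns or not) is left
  configurable because a single published percentage cannot adjudicate
  it.
* Within-package disagreements in the source material about the mutated
  residue's numbering are resolved in favor of the text/table value
  (residue 527 for cDNA position 1579), which is also what
  `cdna_to_codon()` computes.

## Problem sizes in the shipped checks

The test suite and acceptance script size their simulations for
single-CPU runs: 50 seeded cohorts (11 samples × 501 variants) for
planted-variant recovery in the tests and 20 in the acceptance script;
100 random 30-variant cohorts for funnel monotonicity; 1,000 random 2×2
tables (margins ≤ 300) for the Fisher cross-check; 300-well plates over 5
seeds for caller accuracy; and exhaustive alignment enumeration up to
length 6 (a sampled sweep of such pairs) for the alignment core. Larger
fixtures are always generated by code at run time, never stored.

## Known limitations

Beyond the synthetic-data caveats above: the VCF reader targets the
GT/DP subset of VCF v4.2 (no breakends or symbolic alleles); consequence
annotation assumes one transcript per gene and non-overlapping genes, as
in the toy models; the funnel has no tolerance parameters for reduced
penetrance or phenocopies; `check_obligate_carriers` accepts
homozygous-mutant parents as carriers (degenerate but model-consistent);
and multiple sequence alignments are consumed pre-aligned — the package
never constructs an MSA.
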