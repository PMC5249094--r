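# trioscreen

Candidate-causal-variant discovery for rare autosomal-recessive Mendelian
disease in small cohort designs: an affected offspring with both parents
(obligate heterozygous carriers), additional unrelated affected samples, and
unaffected controls. The package grew out of the canine neuroaxonal
dystrophy (NAD) setting — a recessive neurodegenerative disease of Papillon
dogs ultimately attributed to a *PLA2G6* missense change — but every stage
is generic: it takes a multi-sample VCF, a pedigree, gene models and a
reference sequence, and returns an auditable trail from every called
variant down to a protein-level characterization of the surviving
candidate.

It is written for geneticists and bioinformaticians who have exome calls in
hand and want the downstream screen to be reproducible, testable and
explicit about its filtering rules, without re-running anyone's read
mapping or variant calling.

## What it computes

**Filtering funnel.** Variants are pushed through the classical recessive
exome funnel, each step reporting its surviving count. For SNVs:

1. total SNVs;
2. coverage: every affected and parent sample at depth ≥ 10×;
3. gene-coding: position within a gene span (introns included);
4. exon-coding: position within an exon;
5. segregation: all affected `1/1` **and** all parents `0/1` (or
   hemizygous);
6. control exclusion: no control `1/1`;
7. missense only (codons translated strand-aware under the standard
   genetic code).

The indel branch runs coverage, then carried-by-all-core, homozygosity in
affected, heterozygosity in parents and control exclusion, and applies the
exon restriction *last* — mirroring how the two branches of the published
funnel are ordered.

**Score triage.** Ingested PolyPhen-2 / PROVEAN / SIFT scores (the tools
are never invoked) are classified with closed thresholds — SIFT ≤ 0.05 and
PROVEAN ≤ −2.5 deleterious, PolyPhen-2 ≥ 0.453 / ≥ 0.957 possibly/probably
damaging — and a disease-homolog gene list can rescue unflagged variants
into the screening set.

**Genotype screening.** Endpoint FAM/VIC fluorescence wells are called by
nearest-centroid assignment (3-means with deterministic axis-extreme
seeding when no cluster model is given; NTC-like wells excluded),
tabulated per cohort, and tested for recessive genotype–phenotype
concordance with a two-sided Fisher exact test
(P of the 2×2 affected/unaffected × homozygous-mutant/not table).
Obligate-carrier genotypes are checked against the pedigree.

**Protein mapping.** HGVS `c.` substitutions are mapped to codons
(`codon = ⌈pos/3⌉`), applied to a CDS, and characterized by global pairwise
alignment (Needleman–Wunsch, BLOSUM62, affine gaps 10/0.5) with
whole-protein, per-domain and MSA-column conservation reports.

**Synthetic cohorts.** Because raw study reads are not redistributable, a
seeded generator builds a toy reference with clean ORFs, plants a
homozygous-recessive exonic missense variant plus Hardy–Weinberg background
variants, simulates negative-binomial sequencing depth and optional
genotyping error, and writes standard FASTA/GFF3/VCF/PED plus simulated
fluorescence wells — so the whole pipeline is exercised end-to-end with no
downloads.

## Worked example

```r
library(trioscreen)
sim <- simulate_cohort(cohort_design(seed = 42, n_background_variants = 500),
                       dir = tempfile("demo"))
vs  <- read_vcf(sim$vcf)
ped <- read_ped(sim$ped)
run_snv_funnel(vs, ped, sim$reference$genes, sim$reference)
#> <funnel_report>
#>                     step count
#>                    total   501
#>    coverage_ge_min_depth   464
#>              gene_coding    18
#>              exon_coding    10
#>  affected_hom_parent_het     1
#>      control_not_hom_alt     1
#>                 missense     1
```

501 simulated SNVs enter; 37 lose a core sample to the 10× rule; region
filters cut to the 10 exonic candidates; the recessive segregation pattern
leaves exactly one survivor — the planted causal variant (`sim$truth`
confirms it is `chr1:356 G>T`).

```r
scores <- candidate_score_table()
count_flagged(scores)
#> [1] 3
select_for_screening(scores, disease_gene_list = "PLA2G6")[, c("variant_id", "selection_reason")]
#>                    variant_id selection_reason
#> 1 ENSCAFG00000029271:c.130G>A          flagged
#> 2        PDGFB_CANFA:c.693C>A          flagged
#> 3            PLA2G6:c.1579G>A          flagged
#> 4            PLA2G6:c.1516G>A     disease_gene
```

Of the ten packaged candidates, three are flagged by at least one
predictor and a fourth is rescued because its gene is a known
disease-homolog candidate.

```r
cohort <- expand_genotype_counts(published_genotyping_counts())
test_recessive_concordance(cohort$calls, cohort$phenotypes)
#> <segregation_result> perfect=TRUE; discordant affected=0, unaffected=0; Fisher p=5.72e-09
cdna_to_codon(1579)
#>   codon_index offset
#> 1         527      1
```

All 4 affected dogs in the 256-sample screening cohort are homozygous
mutant and none of the 252 unaffected dogs is — perfect recessive
concordance, Fisher exact P = 5.7×10⁻⁹ — and the causal cDNA position 1579
falls on the first base of codon 527.

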