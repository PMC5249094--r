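#' Triage thresholds for ingested predictor scores
#'
#' Per-tool classification boundaries, all closed at the threshold:
#' SIFT <= `sift_deleterious_max` is deleterious (standard published cut
#' 0.05); PROVEAN <= `provean_deleterious_max` is deleterious (the tool's
#' own -2.5 threshold); PolyPhen-2 is classified by the two standard HumDiv
#' bands (`>= 0.453` possibly damaging, `>= 0.957` probably damaging).
#'
#' @param sift_deleterious_max SIFT deleterious boundary (probability).
#' @param provean_deleterious_max PROVEAN deleterious boundary (score).
#' @param polyphen2_possibly_min,polyphen2_probably_min PolyPhen-2 category
#'   boundaries (probabilities); `possibly < probably` required.
#' @return An object of class `triage_criteria`.
#' @export
triage_criteria <- function(sift_deleterious_max = 0.05,
                            provean_deleterious_max = -2.5,
                            polyphen2_possibly_min = 0.453,
                            polyphen2_probably_min = 0.957) {
  stopifnot(polyphen2_possibly_min < polyphen2_probably_min)
  structure(
    list(
      sift_deleterious_max = sift_deleterious_max,
      provean_deleterious_max = provean_deleterious_max,
      polyphen2_possibly_min = polyphen2_possibly_min,
      polyphen2_probably_min = polyphen2_probably_min
    ),
    class = "triage_criteria"
  )
}

validate_scores <- function(scores) {
  need <- c("variant_id", "gene", "polyphen2", "provean", "sift")
  missing <- setdiff(need, names(scores))
  if (length(missing)) stopf("score table lacks column '%s'", missing[1L])
  for (col in c("polyphen2", "sift")) {
    x <- scores[[col]]
    if (any(x < 0 | x > 1, na.rm = TRUE)) {
      stopf("%s scores must lie in [0, 1]", col)
    }
  }
  scores
}

#' Classify predictor scores into per-tool categories
#'
#' Adds per-tool class columns and the `any_flagged` indicator: a variant is
#' flagged when at least one tool calls it non-benign (PolyPhen-2 possibly
#' or probably damaging, PROVEAN deleterious, or SIFT deleterious).
#'
#' @param scores data.frame with columns `variant_id`, `gene`, `polyphen2`,
#'   `provean`, `sift`.
#' @param criteria a [triage_criteria()].
#' @return `scores` with added columns `polyphen2_class`
#'   (benign / possibly_damaging / probably_damaging), `provean_class`
#'   (neutral / deleterious), `sift_class` (tolerant / deleterious) and
#'   `any_flagged`.
#' @examples
#' classify_variants(candidate_score_table())
#' @export
classify_variants <- function(scores, criteria = triage_criteria()) {
  scores <- validate_scores(scores)
  scores$polyphen2_class <- ifelse(
    scores$polyphen2 >= criteria$polyphen2_probably_min, "probably_damaging",
    ifelse(scores$polyphen2 >= criteria$polyphen2_possibly_min,
      "possibly_damaging", "benign"
    )
  )
  scores$provean_class <- ifelse(
    scores$provean <= criteria$provean_deleterious_max, "deleterious", "neutral"
  )
  scores$sift_class <- ifelse(
    scores$sift <= criteria$sift_deleterious_max, "deleterious", "tolerant"
  )
  scores$any_flagged <- scores$polyphen2_class != "benign" |
    scores$provean_class == "deleterious" |
    scores$sift_class == "deleterious"
  scores
}

#' Count flagged variants in a score table
#' @inheritParams classify_variants
#' @return Number of rows with `any_flagged` true.
#' @export
count_flagged <- function(scores, criteria = triage_criteria()) {
  if (nrow(scores) == 0L) {
    return(0L)
  }
  sum(classify_variants(scores, criteria)$any_flagged)
}

#' Select variants to advance to genotype screening
#'
#' The screening set is the union of the flagged variants and any unflagged
#' variant whose gene appears in `disease_gene_list` (the disease-homolog
#' rescue: a known candidate gene for the homologous human disease earns a
#' genotyping assay regardless of its scores). Flagged variants come first,
#' each group ordered by `variant_id`.
#'
#' @inheritParams classify_variants
#' @param disease_gene_list character vector of gene symbols (may be
#'   empty).
#' @return data.frame of selected rows with a `selection_reason` column
#'   (`"flagged"` or `"disease_gene"`).
#' @export
select_for_screening <- function(scores, criteria = triage_criteria(),
                                 disease_gene_list = character()) {
  labelled <- classify_variants(scores, criteria)
  flagged <- labelled[labelled$any_flagged, , drop = FALSE]
  rescued <- labelled[
    !labelled$any_flagged & labelled$gene %in% disease_gene_list, ,
    drop = FALSE
  ]
  flagged <- flagged[order(flagged$variant_id), , drop = FALSE]
  rescued <- rescued[order(rescued$variant_id), , drop = FALSE]
  if (nrow(flagged)) flagged$selection_reason <- "flagged"
  if (nrow(rescued)) rescued$selection_reason <- "disease_gene"
  out <- rbind(flagged, rescued)
  rownames(out) <- NULL
  out
}

#' Read a predictor score table from TSV
#'
#' Expects a header with columns `variant_id`, `gene`, `polyphen2`,
#' `provean`, `sift`.
#'
#' @param path TSV path.
#' @return Validated data.frame.
#' @export
read_score_table <- function(path) {
  df <- utils::read.table(path,
    header = TRUE, sep = "\t",
    stringsAsFactors = FALSE
  )
  validate_scores(df)
}

#' Packaged candidate predictor-score table
#'
#' The ten missense candidates that survive the recessive exome funnel in
#' the canine neuroaxonal dystrophy screen, with their published
#' PolyPhen-2, PROVEAN and SIFT scores. Shipped as plain TSV in
#' `extdata/candidate_scores.tsv`.
#'
#' @return data.frame with columns `variant_id`, `gene`, `chrom`, `pos`,
#'   `cdna`, `protein`, `polyphen2`, `provean`, `sift`.
#' @export
candidate_score_table <- function() {
  path <- system.file("extdata", "candidate_scores.tsv",
    package = "trioscreen",
    mustWork = TRUE
  )
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Packaged published genotyping-assay counts
#'
#' Per-breed-group genotype counts from the large-scale allelic
#' discrimination screen of the canine neuroaxonal dystrophy candidate
#' variant (wild-type / heterozygous / homozygous-mutant tallies with
#' phenotype annotation). Shipped as plain TSV in
#' `extdata/genotyping_counts.tsv`.
#'
#' @return data.frame with columns `cohort`, `phenotype`, `n_tested`,
#'   `n_wild`, `n_het`, `n_hom_mut`.
#' @export
published_genotyping_counts <- function() {
  path <- system.file("extdata", "genotyping_counts.tsv",
    package = "trioscreen",
    mustWork = TRUE
  )
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Expand per-cohort genotype counts into per-sample calls
#'
#' Turns a counts table (as from [published_genotyping_counts()]) into the
#' per-sample calls, cohort labels and phenotypes that
#' [tabulate_genotypes()] and [test_recessive_concordance()] consume.
#'
#' @param counts data.frame with columns `cohort`, `phenotype`, `n_wild`,
#'   `n_het`, `n_hom_mut`.
#' @return List with named vectors `calls`, `labels`, `phenotypes`.
#' @export
expand_genotype_counts <- function(counts) {
  calls <- character()
  labels <- character()
  phenos <- character()
  ids <- character()
  k <- 0L
  for (i in seq_len(nrow(counts))) {
    g <- rep(
      c("wild", "het", "hom_mut"),
      c(counts$n_wild[i], counts$n_het[i], counts$n_hom_mut[i])
    )
    id <- sprintf("s%03d", k + seq_along(g))
    k <- k + length(g)
    calls <- c(calls, setNames(g, id))
    labels <- c(labels, setNames(rep(counts$cohort[i], length(g)), id))
    phenos <- c(phenos, setNames(rep(counts$phenotype[i], length(g)), id))
  }
  list(calls = calls, labels = labels, phenotypes = phenos)
}
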