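#' Filtering criteria for the recessive screen
#'
#' @param min_depth minimum per-sample read depth (default 10, the usual
#'   exome evidentiary cut); calls with missing depth fail.
#' @param depth_scope `"core"` applies the depth requirement to affected and
#'   parent samples only (a low-coverage control should not discard a true
#'   candidate); `"all"` additionally requires it of controls.
#' @return An object of class `filter_criteria`. The genotype requirements
#'   themselves are fixed by the recessive model: affected samples
#'   homozygous-alternate, parents heterozygous (or hemizygous), and no
#'   control homozygous-alternate.
#' @export
filter_criteria <- function(min_depth = 10L, depth_scope = c("core", "all")) {
  stopifnot(min_depth >= 0L)
  depth_scope <- match.arg(depth_scope)
  structure(
    list(min_depth = as.integer(min_depth), depth_scope = depth_scope),
    class = "filter_criteria"
  )
}

check_cohort_samples <- function(vs, ped) {
  roles <- ped_roles(ped)
  missing <- setdiff(unlist(roles), vs_samples(vs))
  if (length(missing)) {
    stopf("pedigree sample '%s' is absent from the VCF", missing[1L])
  }
  roles
}

#' Coverage filter
#'
#' A record survives iff every in-scope sample (affected and parents, plus
#' controls when `depth_scope = "all"`) has depth at least `min_depth`.
#' Missing depth fails the requirement.
#'
#' @param vs a [variant_set()].
#' @param ped a [pedigree()].
#' @param criteria a [filter_criteria()].
#' @return The surviving [variant_set()].
#' @export
depth_filter <- function(vs, ped, criteria = filter_criteria()) {
  roles <- check_cohort_samples(vs, ped)
  scope <- c(roles$affected, roles$parents)
  if (criteria$depth_scope == "all") scope <- c(scope, roles$controls)
  if (length(scope) == 0L || nrow(vs$sites) == 0L) {
    return(vs)
  }
  d <- vs$dp[, scope, drop = FALSE]
  ok <- rowSums(is.na(d) | d < criteria$min_depth) == 0L
  vs[ok]
}

#' Recessive segregation filter for SNVs
#'
#' A record survives iff (a) every affected sample is homozygous-alternate,
#' (b) every parent is heterozygous or hemizygous, and (c) no control is
#' homozygous-alternate. A missing genotype fails the requirement it is
#' evaluated under in (a) and (b); a missing control genotype does *not*
#' trigger the exclusion in (c), because an uncalled control cannot certify
#' homozygosity.
#'
#' @inheritParams depth_filter
#' @return The surviving [variant_set()].
#' @export
segregation_filter_snv <- function(vs, ped, criteria = filter_criteria()) {
  roles <- check_cohort_samples(vs, ped)
  if (nrow(vs$sites) == 0L) {
    return(vs)
  }
  ok <- affected_all_hom_alt(vs, roles$affected) &
    parents_all_het(vs, roles$parents) &
    controls_none_hom_alt(vs, roles$controls)
  vs[ok]
}

affected_all_hom_alt <- function(vs, affected) {
  if (length(affected) == 0L) {
    return(rep(TRUE, nrow(vs$sites)))
  }
  g <- vs$gt[, affected, drop = FALSE]
  rowSums(g != "hom_alt") == 0L
}

parents_all_het <- function(vs, parents) {
  if (length(parents) == 0L) {
    return(rep(TRUE, nrow(vs$sites)))
  }
  g <- vs$gt[, parents, drop = FALSE]
  rowSums(g != "het" & g != "hemi") == 0L
}

controls_none_hom_alt <- function(vs, controls) {
  if (length(controls) == 0L) {
    return(rep(TRUE, nrow(vs$sites)))
  }
  g <- vs$gt[, controls, drop = FALSE]
  rowSums(g == "hom_alt") == 0L
}

carried_by_all <- function(vs, samples) {
  if (length(samples) == 0L) {
    return(rep(TRUE, nrow(vs$sites)))
  }
  g <- vs$gt[, samples, drop = FALSE]
  carries <- g == "het" | g == "hom_alt" | g == "hemi"
  rowSums(!carries) == 0L
}

funnel_report <- function(steps, counts, survivors) {
  stopifnot(length(steps) == length(counts), all(diff(counts) <= 0))
  stopifnot(counts[length(counts)] == nrow(survivors$sites))
  structure(
    list(
      steps = data.frame(step = steps, count = as.integer(counts)),
      survivors = survivors
    ),
    class = "funnel_report"
  )
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("<funnel_report>\n")
  print(x$steps, row.names = FALSE)
  invisible(x)
}

SNV_FUNNEL_STEPS <- c(
  "total", "coverage_ge_min_depth", "gene_coding", "exon_coding",
  "affected_hom_parent_het", "control_not_hom_alt", "missense"
)

INDEL_FUNNEL_STEPS <- c(
  "total", "coverage_ge_min_depth", "carried_by_all_affected_and_parents",
  "affected_hom_alt", "parent_het", "control_not_hom_alt", "exon_coding"
)

in_gene_span <- function(vs, models) {
  vapply(seq_len(nrow(vs$sites)), function(i) {
    any(vapply(models, function(m) {
      m$chrom == vs$sites$chrom[i] &&
        vs$sites$pos[i] >= m$start && vs$sites$pos[i] <= m$end
    }, logical(1L)))
  }, logical(1L))
}

in_exon_interval <- function(vs, models) {
  vapply(seq_len(nrow(vs$sites)), function(i) {
    any(vapply(models, function(m) {
      m$chrom == vs$sites$chrom[i] &&
        any(vs$sites$pos[i] >= m$exons$start & vs$sites$pos[i] <= m$exons$end)
    }, logical(1L)))
  }, logical(1L))
}

#' Run the SNV filtering funnel
#'
#' Applies, in order: restriction to SNVs (total), the coverage filter, the
#' gene-span filter ("gene coding": anywhere within a gene, introns
#' included), the exon filter ("exon coding"), the combined
#' affected-homozygous / parent-heterozygous segregation requirement, the
#' control exclusion, and finally restriction to missense consequences.
#' Survivors are reported in (chrom, pos, alt) order.
#'
#' @param vs a [variant_set()].
#' @param ped a [pedigree()].
#' @param models list of [gene_model()].
#' @param reference a `toy_reference` or named [Biostrings::DNAStringSet].
#' @param criteria a [filter_criteria()].
#' @return A `funnel_report`: `$steps` (step name, surviving count) and
#'   `$survivors` (a [variant_set()]).
#' @export
run_snv_funnel <- function(vs, ped, models, reference,
                           criteria = filter_criteria()) {
  roles <- check_cohort_samples(vs, ped)
  cur <- vs[vs$sites$kind == "SNV"]
  counts <- integer(0)
  note <- function(n) counts <<- c(counts, n)
  note(nrow(cur$sites))

  cur <- depth_filter(cur, ped, criteria)
  note(nrow(cur$sites))

  cur <- cur[in_gene_span(cur, models)]
  note(nrow(cur$sites))

  cur <- cur[in_exon_interval(cur, models)]
  note(nrow(cur$sites))

  cur <- cur[
    affected_all_hom_alt(cur, roles$affected) &
      parents_all_het(cur, roles$parents)
  ]
  note(nrow(cur$sites))

  cur <- cur[controls_none_hom_alt(cur, roles$controls)]
  note(nrow(cur$sites))

  if (nrow(cur$sites) > 0L) {
    csq <- annotate_consequence(cur, models, reference)
    cur <- cur[csq$coding_effect == "missense"]
  }
  note(nrow(cur$sites))

  funnel_report(SNV_FUNNEL_STEPS, counts, cur[vs_order(cur)])
}

#' Run the indel filtering funnel
#'
#' Applies, in order: restriction to indels (total), the coverage filter,
#' the requirement that every affected and parent sample carries at least
#' one alternate allele, the affected homozygous-alternate requirement, the
#' parent heterozygous requirement, the control exclusion, and finally the
#' exon filter — the region restriction comes *last* in the indel branch,
#' unlike the SNV branch.
#'
#' @inheritParams run_snv_funnel
#' @return A `funnel_report`.
#' @export
run_indel_funnel <- function(vs, ped, models, criteria = filter_criteria()) {
  roles <- check_cohort_samples(vs, ped)
  cur <- vs[vs$sites$kind == "indel"]
  counts <- integer(0)
  note <- function(n) counts <<- c(counts, n)
  note(nrow(cur$sites))

  cur <- depth_filter(cur, ped, criteria)
  note(nrow(cur$sites))

  cur <- cur[carried_by_all(cur, c(roles$affected, roles$parents))]
  note(nrow(cur$sites))

  cur <- cur[affected_all_hom_alt(cur, roles$affected)]
  note(nrow(cur$sites))

  cur <- cur[parents_all_het(cur, roles$parents)]
  note(nrow(cur$sites))

  cur <- cur[controls_none_hom_alt(cur, roles$controls)]
  note(nrow(cur$sites))

  cur <- cur[in_exon_interval(cur, models)]
  note(nrow(cur$sites))

  funnel_report(INDEL_FUNNEL_STEPS, counts, cur[vs_order(cur)])
}

#' Write a funnel report as TSV
#' @param report a `funnel_report`.
#' @param path output path (step name TAB surviving count).
#' @return `path`, invisibly.
#' @export
write_funnel_report <- function(report, path) {
  utils::write.table(report$steps, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
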