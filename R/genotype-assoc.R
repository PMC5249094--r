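#' Cluster model for endpoint-fluorescence genotype calling
#'
#' @param centroids 3 x 2 numeric matrix with rownames `hom_mut`, `het`,
#'   `wild` and columns `fam_rn`, `vic_rn`.
#' @param ntc_radius wells closer than this to the no-template-control
#'   centroid are excluded from calling (Rn units).
#' @return An object of class `cluster_model`.
#' @export
cluster_model <- function(centroids, ntc_radius = 0.25) {
  stopifnot(
    is.matrix(centroids), nrow(centroids) == 3L, ncol(centroids) == 2L,
    setequal(rownames(centroids), c("hom_mut", "het", "wild")),
    ntc_radius > 0
  )
  if (anyDuplicated(centroids)) stopf("cluster centroids must be pairwise distinct")
  colnames(centroids) <- c("fam_rn", "vic_rn")
  structure(
    list(
      centroids = centroids[c("hom_mut", "het", "wild"), ],
      ntc_radius = ntc_radius
    ),
    class = "cluster_model"
  )
}

#' Call genotypes from endpoint-fluorescence wells
#'
#' Automates the visual scatter-plot read of an allelic discrimination
#' assay. NTC wells, and any well within `ntc_radius` of the NTC centroid
#' (the mean of the NTC wells, or the origin when none are present), are
#' excluded as no-amplification. The remaining wells are assigned to the
#' nearest cluster centroid. When no `model` is supplied, centroids are
#' fitted by 3-means seeded at the plot-geometry extremes: (max FAM, min
#' VIC) for homozygous-mutant, (max FAM, max VIC) for heterozygous and
#' (min FAM, max VIC) for wild-type — a deterministic seeding, so calls are
#' reproducible for identical input.
#'
#' @param wells data.frame with `sample_id`, `fam_rn`, `vic_rn`, `is_ntc`.
#' @param model optional [cluster_model()]; fitted from the wells when
#'   `NULL`.
#' @param ntc_radius exclusion radius used when fitting (ignored when
#'   `model` is supplied).
#' @return Named character vector sample -> genotype
#'   (`wild`/`het`/`hom_mut`); excluded wells are absent.
#' @export
call_genotypes <- function(wells, model = NULL, ntc_radius = 0.25) {
  stopifnot(all(c("sample_id", "fam_rn", "vic_rn", "is_ntc") %in% names(wells)))
  if (all(wells$is_ntc)) stopf("no non-NTC wells to call")
  ntc_centroid <- if (any(wells$is_ntc)) {
    c(mean(wells$fam_rn[wells$is_ntc]), mean(wells$vic_rn[wells$is_ntc]))
  } else {
    c(0, 0)
  }
  radius <- if (is.null(model)) ntc_radius else model$ntc_radius
  cand <- wells[!wells$is_ntc, , drop = FALSE]
  d_ntc <- sqrt((cand$fam_rn - ntc_centroid[1L])^2 +
    (cand$vic_rn - ntc_centroid[2L])^2)
  cand <- cand[d_ntc > radius, , drop = FALSE]
  if (nrow(cand) == 0L) stopf("all wells are NTC-like: nothing to call")
  xy <- cbind(cand$fam_rn, cand$vic_rn)
  if (is.null(model)) {
    seeds <- rbind(
      hom_mut = c(max(xy[, 1L]), min(xy[, 2L])),
      het = c(max(xy[, 1L]), max(xy[, 2L])),
      wild = c(min(xy[, 1L]), max(xy[, 2L]))
    )
    centroids <- seeds
    if (nrow(unique(xy)) >= 3L && !anyDuplicated(seeds)) {
      km <- suppressWarnings(stats::kmeans(xy, centers = seeds))
      centroids <- km$centers
      rownames(centroids) <- rownames(seeds)
    }
  } else {
    centroids <- model$centroids
  }
  d <- vapply(
    seq_len(nrow(centroids)),
    function(k) (xy[, 1L] - centroids[k, 1L])^2 + (xy[, 2L] - centroids[k, 2L])^2,
    numeric(nrow(cand))
  )
  if (nrow(cand) == 1L) d <- matrix(d, nrow = 1L)
  calls <- rownames(centroids)[max.col(-d, ties.method = "first")]
  setNames(calls, cand$sample_id)
}

#' Tabulate genotype calls by cohort (Table-3 shape)
#'
#' One row per cohort label (in order of first appearance) with columns
#' `n_tested`, `n_wild`, `n_het`, `n_hom_mut`, plus a totals row. Row sums
#' and column totals are validated on construction.
#'
#' @param calls named character vector sample -> genotype
#'   (`wild`/`het`/`hom_mut`).
#' @param cohort_labels named character vector sample -> cohort label;
#'   every called sample must be labeled.
#' @return data.frame of class `genotype_table`.
#' @export
tabulate_genotypes <- function(calls, cohort_labels) {
  unlabeled <- setdiff(names(calls), names(cohort_labels))
  if (length(unlabeled)) stopf("sample '%s' has no cohort label", unlabeled[1L])
  labels <- cohort_labels[names(calls)]
  lab_order <- unique(labels)
  rows <- lapply(lab_order, function(lab) {
    g <- calls[labels == lab]
    data.frame(
      cohort = lab, n_tested = length(g),
      n_wild = sum(g == "wild"), n_het = sum(g == "het"),
      n_hom_mut = sum(g == "hom_mut")
    )
  })
  tab <- do.call(rbind, rows)
  totals <- data.frame(
    cohort = "Total", n_tested = sum(tab$n_tested),
    n_wild = sum(tab$n_wild), n_het = sum(tab$n_het),
    n_hom_mut = sum(tab$n_hom_mut)
  )
  out <- rbind(tab, totals)
  rownames(out) <- NULL
  stopifnot(all(out$n_tested == out$n_wild + out$n_het + out$n_hom_mut))
  class(out) <- c("genotype_table", "data.frame")
  out
}

#' Test recessive genotype-phenotype concordance
#'
#' Under the recessive model a concordant cohort has every affected sample
#' homozygous-mutant and no unaffected sample homozygous-mutant. Reports
#' the two discordance counts and the two-sided Fisher exact probability of
#' the 2x2 table (affected vs unaffected) x (hom_mut vs not), computed by
#' the point-probability method. A degenerate table (any zero margin) is
#' reported with `fisher_p = 1` and `degenerate = TRUE`.
#'
#' @param calls named character vector sample -> genotype
#'   (`wild`/`het`/`hom_mut`).
#' @param phenotypes named character vector sample -> `"affected"` or
#'   `"unaffected"`; must cover every called sample.
#' @return List of class `segregation_result`: `perfect`,
#'   `n_discordant_affected`, `n_discordant_unaffected`, `fisher_p`,
#'   `degenerate`, `table` (the 2x2 table).
#' @export
test_recessive_concordance <- function(calls, phenotypes) {
  missing_ph <- setdiff(names(calls), names(phenotypes))
  if (length(missing_ph)) stopf("sample '%s' has no phenotype", missing_ph[1L])
  ph <- phenotypes[names(calls)]
  if (!all(ph %in% c("affected", "unaffected"))) {
    stopf("phenotypes must be 'affected' or 'unaffected'")
  }
  if (!any(ph == "affected") || !any(ph == "unaffected")) {
    stopf("need at least one affected and one unaffected sample")
  }
  hom <- calls == "hom_mut"
  tab <- matrix(
    c(
      sum(hom & ph == "affected"), sum(!hom & ph == "affected"),
      sum(hom & ph == "unaffected"), sum(!hom & ph == "unaffected")
    ),
    nrow = 2L, byrow = TRUE,
    dimnames = list(c("affected", "unaffected"), c("hom_mut", "not_hom_mut"))
  )
  res <- fisher_exact_2x2(tab)
  structure(
    list(
      perfect = tab["affected", "not_hom_mut"] == 0L &&
        tab["unaffected", "hom_mut"] == 0L,
      n_discordant_affected = unname(tab["affected", "not_hom_mut"]),
      n_discordant_unaffected = unname(tab["unaffected", "hom_mut"]),
      fisher_p = res$p, degenerate = res$degenerate, table = tab
    ),
    class = "segregation_result"
  )
}

#' @export
print.segregation_result <- function(x, ...) {
  cat(sprintf(
    "<segregation_result> perfect=%s; discordant affected=%d, unaffected=%d; Fisher p=%.3g%s\n",
    x$perfect, x$n_discordant_affected, x$n_discordant_unaffected,
    x$fisher_p, if (x$degenerate) " (degenerate table)" else ""
  ))
  invisible(x)
}

#' Two-sided Fisher exact probability of a 2x2 table
#'
#' Point-probability method (the sum over tables with the observed margins
#' whose hypergeometric probability does not exceed the observed table's).
#' Tables with a zero margin are degenerate: the probability is reported
#' as 1.
#'
#' @param tab 2x2 integer matrix.
#' @return List with `p` and `degenerate`.
#' @export
fisher_exact_2x2 <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == 2L), all(tab >= 0))
  degenerate <- any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)
  if (degenerate) {
    return(list(p = 1, degenerate = TRUE))
  }
  list(p = stats::fisher.test(tab)$p.value, degenerate = FALSE)
}

#' Check obligate-carrier genotypes against a pedigree
#'
#' Every parent of an affected sample is an obligate carrier under the
#' recessive model and must be heterozygous (or homozygous-mutant, the
#' degenerate carrier case). Returns the violations.
#'
#' @param calls named character vector sample -> genotype
#'   (`wild`/`het`/`hom_mut`).
#' @param ped a [pedigree()].
#' @return data.frame with columns `sample`, `child`, `genotype`; zero rows
#'   when all obligate carriers comply.
#' @export
check_obligate_carriers <- function(calls, ped) {
  df <- as.data.frame(ped)
  affected <- df$id[df$phenotype == "2"]
  out <- data.frame(
    sample = character(), child = character(), genotype = character()
  )
  for (child in affected) {
    for (p in c(df$sire[df$id == child], df$dam[df$id == child])) {
      if (p == "0" || !p %in% names(calls)) next
      g <- calls[[p]]
      if (!g %in% c("het", "hom_mut")) {
        out <- rbind(out, data.frame(sample = p, child = child, genotype = g))
      }
    }
  }
  rownames(out) <- NULL
  out
}
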