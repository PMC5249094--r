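#' Multi-sample variant set
#'
#' The central container for called variants: a site table plus parallel
#' genotype and depth matrices, one row per bi-allelic record and one column
#' per sample. Genotypes use the vocabulary `hom_ref`, `het`, `hom_alt`,
#' `hemi` (single-allele alternate call) and `missing`; depths are
#' non-negative integers with `NA` for missing DP.
#'
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param gt character matrix (sites x samples) over the genotype vocabulary.
#' @param dp integer matrix (sites x samples), `NA` allowed.
#' @return An object of class `variant_set`.
#' @export
variant_set <- function(sites, gt, dp) {
  stopifnot(
    is.data.frame(sites),
    all(c("chrom", "pos", "ref", "alt") %in% names(sites)),
    nrow(gt) == nrow(sites), nrow(dp) == nrow(sites),
    ncol(gt) == ncol(dp), !is.null(colnames(gt))
  )
  if (any(sites$pos < 1L)) stopf("variant pos must be >= 1")
  if (any(sites$ref == sites$alt)) stopf("ref and alt alleles must differ")
  bad <- !(gt %in% GT_LEVELS)
  if (any(bad)) stopf("unknown genotype code '%s'", gt[which(bad)[1L]])
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  sites$ref <- as.character(sites$ref)
  sites$alt <- as.character(sites$alt)
  sites$kind <- ifelse(nchar(sites$ref) == 1L & nchar(sites$alt) == 1L, "SNV", "indel")
  rownames(sites) <- NULL
  storage.mode(dp) <- "integer"
  if (any(dp < 0L, na.rm = TRUE)) stopf("depths must be non-negative")
  dimnames(gt) <- list(NULL, colnames(gt))
  dimnames(dp) <- list(NULL, colnames(gt))
  structure(list(sites = sites, gt = gt, dp = dp), class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf(
    "<variant_set> %d record(s) x %d sample(s) (%d SNV, %d indel)\n",
    nrow(x$sites), ncol(x$gt), sum(x$sites$kind == "SNV"),
    sum(x$sites$kind == "indel")
  ))
  if (nrow(x$sites)) print(utils::head(x$sites, 5L))
  invisible(x)
}

#' @export
length.variant_set <- function(x) nrow(x$sites)

#' Subset a variant set by record index
#' @param x a [variant_set()].
#' @param i record indices (integer or logical).
#' @param ... unused.
#' @return A `variant_set` with the selected records.
#' @export
`[.variant_set` <- function(x, i, ...) {
  variant_set(
    x$sites[i, c("chrom", "pos", "ref", "alt"), drop = FALSE],
    x$gt[i, , drop = FALSE],
    x$dp[i, , drop = FALSE]
  )
}

#' Sample names of a variant set
#' @param x a [variant_set()].
#' @return Character vector of sample ids.
#' @export
vs_samples <- function(x) colnames(x$gt)

# canonical (chrom, pos, alt) ordering used for all reported survivor sets
vs_order <- function(x) order(x$sites$chrom, x$sites$pos, x$sites$alt)

#' Pedigree with phenotype roles
#'
#' Builds a pedigree from 6-column PED-style data and partitions samples
#' into the three roles the recessive screen uses: `affected` (phenotype 2),
#' `parents` (unaffected samples with at least one affected child) and
#' `controls` (all remaining unaffected samples).
#'
#' @param df data.frame with columns `family`, `id`, `sire`, `dam`, `sex`,
#'   `phenotype` (1 = unaffected, 2 = affected; `0` in `sire`/`dam` means
#'   unknown).
#' @return An object of class `pedigree`: the table plus a `roles` attribute
#'   (list of `affected`, `parents`, `controls` id vectors).
#' @export
pedigree <- function(df) {
  need <- c("family", "id", "sire", "dam", "sex", "phenotype")
  stopifnot(all(need %in% names(df)))
  df <- df[, need]
  df[] <- lapply(df, as.character)
  if (anyDuplicated(df$id)) {
    stopf("duplicate sample id '%s' in pedigree", df$id[duplicated(df$id)][1L])
  }
  if (!all(df$phenotype %in% c("1", "2"))) {
    stopf(
      "unknown phenotype code '%s' (expected 1=unaffected, 2=affected)",
      setdiff(df$phenotype, c("1", "2"))[1L]
    )
  }
  self_parent <- df$id == df$sire | df$id == df$dam
  if (any(self_parent)) {
    stopf("sample '%s' is listed as its own parent", df$id[self_parent][1L])
  }
  known <- c("0", df$id)
  if (!all(df$sire %in% known)) {
    stopf("sire id '%s' does not resolve", setdiff(df$sire, known)[1L])
  }
  if (!all(df$dam %in% known)) {
    stopf("dam id '%s' does not resolve", setdiff(df$dam, known)[1L])
  }
  affected <- df$id[df$phenotype == "2"]
  parent_ids <- unique(c(df$sire[df$phenotype == "2"], df$dam[df$phenotype == "2"]))
  parent_ids <- setdiff(intersect(parent_ids, df$id), affected)
  controls <- setdiff(df$id[df$phenotype == "1"], parent_ids)
  structure(df,
    roles = list(affected = affected, parents = parent_ids, controls = controls),
    class = c("pedigree", "data.frame")
  )
}

#' Role partition of a pedigree
#' @param ped a [pedigree()].
#' @return List with `affected`, `parents` and `controls` sample ids.
#' @export
ped_roles <- function(ped) attr(ped, "roles")

#' Read a 6-column PED file
#'
#' Whitespace-delimited, no header: family, individual, sire, dam, sex,
#' phenotype (1 = unaffected, 2 = affected). Gzip input is accepted.
#'
#' @param path PED path.
#' @return A [pedigree()]; empty files yield an empty pedigree.
#' @export
read_ped <- function(path) {
  first <- tryCatch(readLines(path, n = 1L), error = function(e) character())
  if (length(first) == 0L) {
    return(pedigree(data.frame(
      family = character(), id = character(), sire = character(),
      dam = character(), sex = character(), phenotype = character()
    )))
  }
  df <- utils::read.table(path,
    header = FALSE, colClasses = "character",
    col.names = c("family", "id", "sire", "dam", "sex", "phenotype")
  )
  pedigree(df)
}

#' Write a pedigree as a PED file
#' @param ped a [pedigree()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path) {
  utils::write.table(as.data.frame(ped)[, c(
    "family", "id", "sire", "dam", "sex", "phenotype"
  )], path,
  sep = "\t", quote = FALSE,
  row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
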