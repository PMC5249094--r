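#' Read a multi-sample VCF into a variant set
#'
#' Parses a VCF v4.2 file (plain or gzip) carrying `GT` and `DP` FORMAT
#' fields. Phased (`|`) and unphased (`/`) genotype separators are both
#' accepted and phase is discarded; single-allele calls are recorded as
#' hemizygous. Multi-allelic sites are split into one bi-allelic record per
#' alternate allele, classifying each sample's genotype relative to that
#' allele (an allele of a different alternate counts as non-carried).
#' Records without a usable `DP` get a missing depth, which downstream
#' coverage filtering treats as failing.
#'
#' @param path VCF path.
#' @return A [variant_set()].
#' @export
read_vcf <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con)
  close(con)
  hdr_idx <- grep("^#CHROM\t", lines)
  if (length(hdr_idx) != 1L) {
    stopf("malformed VCF header in '%s': expected exactly one #CHROM line", path)
  }
  n_fields <- length(strsplit(lines[hdr_idx], "\t", fixed = TRUE)[[1L]])
  if (n_fields < 10L) {
    stopf("malformed VCF header at line %d: no sample columns", hdr_idx)
  }
  data_idx <- which(!grepl("^#", lines) & nzchar(lines))
  nf <- vapply(
    strsplit(lines[data_idx], "\t", fixed = TRUE), length,
    integer(1L)
  )
  bad <- data_idx[nf != n_fields]
  if (length(bad)) {
    stopf(
      "malformed VCF record at line %d: %d fields, header has %d",
      bad[1L], nf[which(data_idx == bad[1L])], n_fields
    )
  }

  v <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(v@gt)[-1L]
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n == 0L) {
    return(variant_set(
      data.frame(
        chrom = character(), pos = integer(), ref = character(),
        alt = character()
      ),
      matrix(character(), 0L, length(samples), dimnames = list(NULL, samples)),
      matrix(integer(), 0L, length(samples), dimnames = list(NULL, samples))
    ))
  }
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  dp_raw <- tryCatch(
    suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)),
    error = function(e) matrix(NA_real_, n, length(samples))
  )
  if (is.null(dim(gt_raw))) gt_raw <- matrix(gt_raw, nrow = n)
  if (is.null(dim(dp_raw))) dp_raw <- matrix(dp_raw, nrow = n)

  out_sites <- vector("list", n)
  out_gt <- vector("list", n)
  out_dp <- vector("list", n)
  for (i in seq_len(n)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]
    gt_i <- vapply(
      seq_along(alts),
      function(k) classify_gt_strings(gt_raw[i, ], k),
      character(length(samples))
    )
    if (length(samples) == 1L) gt_i <- matrix(gt_i, nrow = length(alts))
    else gt_i <- t(gt_i)
    out_sites[[i]] <- data.frame(
      chrom = unname(fix[i, "CHROM"]), pos = as.integer(fix[i, "POS"]),
      ref = unname(fix[i, "REF"]), alt = alts, row.names = NULL
    )
    out_gt[[i]] <- gt_i
    out_dp[[i]] <- matrix(rep(dp_raw[i, ], each = length(alts)),
      nrow = length(alts)
    )
  }
  sites <- do.call(rbind, out_sites)
  gt <- do.call(rbind, out_gt)
  dp <- do.call(rbind, out_dp)
  colnames(gt) <- samples
  dp_int <- suppressWarnings(matrix(as.integer(round(dp)),
    nrow = nrow(dp),
    dimnames = list(NULL, samples)
  ))
  variant_set(sites, gt, dp_int)
}

# Classify one row of raw GT strings relative to alternate allele index k.
classify_gt_strings <- function(gts, k) {
  vapply(gts, function(g) {
    if (is.na(g) || g == "." || g == "./." || g == ".|.") {
      return("missing")
    }
    alleles <- strsplit(g, "[/|]")[[1L]]
    if (any(alleles == ".")) {
      return("missing")
    }
    a <- suppressWarnings(as.integer(alleles))
    if (anyNA(a)) {
      return("missing")
    }
    n_alt <- sum(a == k)
    if (length(a) == 1L) {
      if (n_alt == 1L) "hemi" else "hom_ref"
    } else if (n_alt == length(a)) {
      "hom_alt"
    } else if (n_alt >= 1L) {
      "het"
    } else {
      "hom_ref"
    }
  }, character(1L), USE.NAMES = FALSE)
}

GT_TO_VCF <- c(
  hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
  hemi = "1", missing = "./."
)

#' Write a variant set as VCF v4.2
#'
#' Emits bi-allelic records with a `GT:DP` FORMAT column. Round-trips
#' losslessly through [read_vcf()].
#'
#' @param vs a [variant_set()].
#' @param path output path; a `.gz` suffix writes gzip.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vs, path) {
  samples <- vs_samples(vs)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=trioscreen",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", samples
    ), collapse = "\t")
  )
  body <- character(nrow(vs$sites))
  for (i in seq_len(nrow(vs$sites))) {
    dp <- vs$dp[i, ]
    calls <- paste(GT_TO_VCF[vs$gt[i, ]],
      ifelse(is.na(dp), ".", as.character(dp)),
      sep = ":"
    )
    body[i] <- paste(c(
      vs$sites$chrom[i], vs$sites$pos[i], ".", vs$sites$ref[i],
      vs$sites$alt[i], ".", "PASS", ".", "GT:DP", calls
    ), collapse = "\t")
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}
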