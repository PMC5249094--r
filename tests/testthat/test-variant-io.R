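write_lines_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".vcf", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

minimal_vcf <- function(records, samples = c("s1", "s2")) {
  c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", samples
    ), collapse = "\t"),
    records
  )
}

test_that("a minimal one-record VCF parses to the expected record", {
  path <- write_lines_tmp(minimal_vcf(
    "chr1\t42\t.\tG\tA\t.\tPASS\t.\tGT:DP\t0/1:12\t1/1:30"
  ))
  vs <- read_vcf(path)
  expect_equal(nrow(vs$sites), 1)
  expect_equal(vs$sites$pos, 42L)
  expect_equal(vs$sites$ref, "G")
  expect_equal(vs$sites$alt, "A")
  expect_equal(vs$sites$kind, "SNV")
  expect_equal(unname(vs$gt[1, ]), c("het", "hom_alt"))
  expect_equal(unname(vs$dp[1, ]), c(12L, 30L))
})

test_that("phase is discarded, hemizygous and missing calls are honored", {
  path <- write_lines_tmp(minimal_vcf(c(
    "chr1\t10\t.\tC\tT\t.\tPASS\t.\tGT:DP\t0|1:9\t1|1:22",
    "chr1\t20\t.\tA\tG\t.\tPASS\t.\tGT:DP\t1:15\t./.:7",
    "chr1\t30\t.\tT\tTA\t.\tPASS\t.\tGT:DP\t0/0:31\t0/1:8"
  )))
  vs <- read_vcf(path)
  expect_equal(unname(vs$gt[1, ]), c("het", "hom_alt"))
  expect_equal(unname(vs$gt[2, ]), c("hemi", "missing"))
  expect_equal(vs$sites$kind, c("SNV", "SNV", "indel"))
})

test_that("multi-allelic sites split into per-alternate bi-allelic records", {
  path <- write_lines_tmp(minimal_vcf(
    "chr1\t99\t.\tG\tA,T\t.\tPASS\t.\tGT:DP\t1/2:40\t0/2:18"
  ))
  vs <- read_vcf(path)
  expect_equal(nrow(vs$sites), 2)
  expect_equal(vs$sites$alt, c("A", "T"))
  expect_equal(unname(vs$gt[1, ]), c("het", "hom_ref")) # relative to A
  expect_equal(unname(vs$gt[2, ]), c("het", "het")) # relative to T
  expect_equal(unname(vs$dp[2, ]), c(40L, 18L))
})

test_that("absent DP becomes missing depth and fails the coverage filter", {
  path <- write_lines_tmp(minimal_vcf(
    "chr1\t7\t.\tA\tC\t.\tPASS\t.\tGT\t1/1\t0/1"
  ))
  vs <- read_vcf(path)
  expect_true(all(is.na(vs$dp)))
  ped <- pedigree(data.frame(
    family = "F", id = c("s1", "s2"), sire = "0", dam = "0",
    sex = "0", phenotype = c("2", "1")
  ))
  expect_equal(nrow(depth_filter(vs, ped)$sites), 0)
})

test_that("malformed records and headers are rejected with a line number", {
  path <- write_lines_tmp(minimal_vcf(
    c(
      "chr1\t10\t.\tC\tT\t.\tPASS\t.\tGT:DP\t0/1:9\t1/1:22",
      "chr1\t20\t.\tA\tG\t.\tPASS\t.\tGT:DP\t0/1:9"
    )
  ))
  expect_error(read_vcf(path), "line 6")
  path2 <- write_lines_tmp("##fileformat=VCFv4.2")
  expect_error(read_vcf(path2), "header")
})

test_that("write(read(f)) is stable under re-reading, including gzip", {
  sim <- simulate_cohort(cohort_design(seed = 20, n_background_variants = 25),
    dir = withr::local_tempdir()
  )
  vs <- read_vcf(sim$vcf)
  out <- withr::local_tempfile(fileext = ".vcf.gz")
  write_vcf(vs, out)
  back <- read_vcf(out)
  expect_equal(back$sites, vs$sites)
  expect_identical(back$gt, vs$gt)
  expect_identical(back$dp, vs$dp)
})

test_that("pedigree roles partition the published cohort design 3/2/6", {
  ped <- cohort_pedigree(cohort_design())
  roles <- ped_roles(ped)
  expect_length(roles$affected, 3)
  expect_length(roles$parents, 2)
  expect_length(roles$controls, 6)
  expect_length(intersect(roles$parents, roles$controls), 0)
  # file round trip preserves roles
  path <- withr::local_tempfile(fileext = ".ped")
  write_ped(ped, path)
  expect_equal(ped_roles(read_ped(path)), roles)
})

test_that("pedigree rejects malformed input and accepts the empty file", {
  expect_error(
    pedigree(data.frame(
      family = "F", id = c("a", "a"), sire = "0", dam = "0",
      sex = "0", phenotype = "1"
    )),
    "duplicate"
  )
  expect_error(
    pedigree(data.frame(
      family = "F", id = "a", sire = "a", dam = "0", sex = "0", phenotype = "2"
    )),
    "own parent"
  )
  expect_error(
    pedigree(data.frame(
      family = "F", id = "a", sire = "0", dam = "0", sex = "0", phenotype = "9"
    )),
    "phenotype"
  )
  empty <- withr::local_tempfile(fileext = ".ped")
  file.create(empty)
  expect_length(ped_roles(read_ped(empty))$affected, 0)
})

test_that("consequence annotation matches hand-computed codons on both strands", {
  ref <- make_known_reference()
  # plus gene: codon 2 GCA; position 14 is its first base
  plus1 <- annotate_consequence(single_snv("chr1", 14, "G", "A"), ref$genes, ref)
  expect_true(plus1$in_gene && plus1$in_exon)
  expect_equal(plus1$coding_effect, "missense")
  expect_equal(plus1$ref_aa, "A")
  expect_equal(plus1$alt_aa, "T")
  expect_equal(plus1$codon_index, 2L)
  # third codon position GCA -> GCG: synonymous
  plus2 <- annotate_consequence(single_snv("chr1", 16, "A", "G"), ref$genes, ref)
  expect_equal(plus2$coding_effect, "synonymous")
  # minus gene: genome 49 is the first base of codon 2 on the coding strand
  minus1 <- annotate_consequence(single_snv("chr1", 49, "C", "T"), ref$genes, ref)
  expect_equal(minus1$coding_effect, "missense")
  expect_equal(minus1$ref_aa, "A")
  expect_equal(minus1$alt_aa, "T")
  # intergenic SNV
  out <- annotate_consequence(single_snv("chr1", 2, "A", "C"), ref$genes, ref)
  expect_false(out$in_gene)
  expect_equal(out$coding_effect, "non_coding")
  # exonic indel
  ind <- variant_set(
    data.frame(chrom = "chr1", pos = 14, ref = "GC", alt = "G"),
    matrix("het", 1, 1, dimnames = list(NULL, "s1")),
    matrix(30L, 1, 1, dimnames = list(NULL, "s1"))
  )
  expect_equal(
    annotate_consequence(ind, ref$genes, ref)$coding_effect,
    "indel_exonic"
  )
  # reference mismatch
  expect_error(
    annotate_consequence(single_snv("chr1", 14, "T", "A"), ref$genes, ref),
    "mismatch"
  )
})

test_that("synonymous iff translated codons agree, over random codons and strands", {
  # independent hand-typed codon table as oracle, all 9 single-base changes
  # of 50 random codons (plus strand) and 20 codons (minus strand)
  set.seed(404)
  check_gene <- function(strand, n_codons_check) {
    codons <- c("ATG", sample(names(ORACLE_CODON)[ORACLE_CODON != "*"], 58, replace = TRUE), "TAA")
    mrna <- paste(codons, collapse = "")
    glen <- nchar(mrna)
    gstart <- 11L
    gseq <- if (strand == "+") mrna else oracle_revcomp(mrna)
    chrom <- paste0(
      strrep("A", gstart - 1L), gseq,
      strrep("A", 50L)
    )
    ref <- structure(
      list(
        chromosomes = Biostrings::DNAStringSet(c(chr1 = chrom)),
        genes = list(gene_model("g", "chr1", strand,
          exons = data.frame(start = gstart, end = gstart + glen - 1L)
        ))
      ),
      class = "toy_reference"
    )
    for (ci in sample(2:59, n_codons_check)) {
      for (off in 1:3) {
        cds_pos <- (ci - 1L) * 3L + off
        gpos <- cds_to_genome(ref$genes[[1]], cds_pos)
        gref <- substr(chrom, gpos, gpos)
        for (galt in setdiff(c("A", "C", "G", "T"), gref)) {
          csq <- annotate_consequence(
            single_snv("chr1", gpos, gref, galt), ref$genes, ref
          )
          ref_codon <- codons[ci]
          coding_alt <- if (strand == "+") galt else oracle_revcomp(galt)
          alt_codon <- ref_codon
          substr(alt_codon, off, off) <- coding_alt
          expected <- if (ORACLE_CODON[[ref_codon]] == ORACLE_CODON[[alt_codon]]) {
            "synonymous"
          } else if (ORACLE_CODON[[alt_codon]] == "*") {
            "nonsense"
          } else {
            "missense"
          }
          expect_equal(csq$coding_effect, expected)
          expect_equal(csq$ref_aa, unname(ORACLE_CODON[[ref_codon]]))
        }
      }
    }
  }
  check_gene("+", 17) # ~50 codons' worth of single-base changes
  check_gene("-", 7)
})

test_that("region hierarchy holds: exonic implies genic", {
  ref <- build_toy_reference(seed = 13, n_genes = 4, chrom_length = 80000)
  set.seed(1)
  pos <- sample.int(80000, 300)
  refbase <- substring(
    as.character(ref$chromosomes[[1]]), pos, pos
  )
  altbase <- vapply(refbase, function(r) setdiff(c("A", "C", "G", "T"), r)[1], "")
  vs <- variant_set(
    data.frame(chrom = "chr1", pos = pos, ref = refbase, alt = altbase),
    matrix("het", 300, 1, dimnames = list(NULL, "s1")),
    matrix(30L, 300, 1, dimnames = list(NULL, "s1"))
  )
  csq <- annotate_consequence(vs, ref$genes, ref)
  expect_true(all(!csq$in_exon | csq$in_gene))
  # purity: identical inputs give identical output
  expect_identical(csq, annotate_consequence(vs, ref$genes, ref))
})

test_that("virtual PCR finds the constructed amplicon and flags ambiguity", {
  fwd <- "TCCAGCTTCTCATCGCCATC"
  rev <- "CACCCCACAAAGGGCTTTCA"
  insert <- strrep("N", 10)
  tpl <- paste0(fwd, insert, oracle_revcomp(rev))
  amp <- virtual_pcr(tpl, fwd, rev)
  expect_true(amp$product)
  expect_equal(amp$length, nchar(fwd) + 10 + nchar(rev))
  expect_equal(amp$sequence, tpl)

  none <- virtual_pcr(strrep("ACGT", 30), fwd, rev)
  expect_false(none$product)

  # orientation matters: swapped primers give no product
  expect_false(virtual_pcr(tpl, rev, fwd)$product)

  two_fwd <- paste0(fwd, insert, fwd, insert, oracle_revcomp(rev))
  err <- tryCatch(virtual_pcr(two_fwd, fwd, rev), condition = identity)
  expect_s3_class(err, "trioscreen_pcr_ambiguity")
  expect_length(err$products, 2)
  # exhaustive-scan oracle: number of (fwd, rev) orderings in the template
  fwd_sites <- gregexpr(fwd, two_fwd, fixed = TRUE)[[1]]
  rev_sites <- gregexpr(oracle_revcomp(rev), two_fwd, fixed = TRUE)[[1]]
  n_pairs <- sum(outer(
    as.integer(fwd_sites) + nchar(fwd) - 1L, as.integer(rev_sites),
    function(fe, rs) rs > fe
  ))
  expect_equal(length(err$products), n_pairs)

  expect_error(virtual_pcr(tpl, "ACGTACGT", rev), "15 nt")
})
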