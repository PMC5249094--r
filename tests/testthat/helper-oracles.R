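# Independent oracles and fixture builders. Everything here is deliberately
# written without the package's own machinery (hand-typed codon table,
# enumeration instead of dynamic programming, lchoose instead of dhyper) so
# that dual-route checks stay honest.

# -- hand-typed standard genetic code ---------------------------------------
ORACLE_CODON <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

oracle_translate <- function(dna) {
  dna <- toupper(as.character(dna))
  stopifnot(nchar(dna) %% 3 == 0)
  codons <- substring(dna, seq(1, nchar(dna), 3), seq(3, nchar(dna), 3))
  paste(ORACLE_CODON[codons], collapse = "")
}

oracle_revcomp <- function(dna) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(toupper(as.character(dna)), "")[[1]]]), collapse = "")
}

# -- exhaustive global-alignment oracle (affine gaps) ------------------------
# Enumerates every monotone alignment of a and b; a gap run of length L
# costs open + ext * L, charged when the run starts plus ext per position.
oracle_align_score <- function(a, b, smat, open, ext) {
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  na <- length(ac)
  nb <- length(bc)
  best <- -Inf
  rec <- function(i, j, last, sc) {
    if (i > na && j > nb) {
      best <<- max(best, sc)
      return(invisible(NULL))
    }
    if (i <= na && j <= nb) rec(i + 1, j + 1, "m", sc + smat[ac[i], bc[j]])
    if (i <= na) rec(i + 1, j, "d", sc - ext - if (last == "d") 0 else open)
    if (j <= nb) rec(i, j + 1, "i", sc - ext - if (last == "i") 0 else open)
  }
  rec(1L, 1L, "", 0)
  best
}

toy_dna_matrix <- function(match = 1, mismatch = -1) {
  m <- matrix(mismatch, 4, 4, dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T")))
  diag(m) <- match
  m
}

# -- exhaustive hypergeometric enumeration for the 2x2 Fisher test -----------
# Probabilities from lchoose; two-sided p sums tables whose probability does
# not exceed the observed one (with the customary 1e-7 relative slack for
# floating ties).
oracle_fisher_two_sided <- function(tab) {
  a <- tab[1, 1]
  b <- tab[1, 2]
  c_ <- tab[2, 1]
  d <- tab[2, 2]
  r1 <- a + b
  r2 <- c_ + d
  c1 <- a + c_
  n <- r1 + r2
  lo <- max(0, c1 - r2)
  hi <- min(r1, c1)
  xs <- lo:hi
  logp <- lchoose(r1, xs) + lchoose(r2, c1 - xs) - lchoose(n, c1)
  p <- exp(logp)
  p_obs <- p[xs == a]
  sum(p[p <= p_obs * (1 + 1e-7)])
}

# -- fixture builders --------------------------------------------------------

# Hand-built two-gene annotation fixture with known codons:
#   geneP (+): CDS ATG GCA CCT TAA at 11..22
#   geneM (-): same mRNA, genomic revcomp at 41..52
make_known_reference <- function() {
  base <- rep("A", 100)
  plus_cds <- "ATGGCACCTTAA"
  minus_genomic <- oracle_revcomp(plus_cds)
  base[11:22] <- strsplit(plus_cds, "")[[1]]
  base[41:52] <- strsplit(minus_genomic, "")[[1]]
  chrom <- paste(base, collapse = "")
  ref <- structure(
    list(
      chromosomes = Biostrings::DNAStringSet(c(chr1 = chrom)),
      genes = list(
        gene_model("geneP", "chr1", "+", data.frame(start = 11, end = 22)),
        gene_model("geneM", "chr1", "-", data.frame(start = 41, end = 52))
      )
    ),
    class = "toy_reference"
  )
  ref
}

make_test_ped <- function(design = cohort_design()) cohort_pedigree(design)

# A one-sample variant set holding a single site (for annotation tests).
single_snv <- function(chrom, pos, ref, alt) {
  variant_set(
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt),
    matrix("het", 1, 1, dimnames = list(NULL, "s1")),
    matrix(30L, 1, 1, dimnames = list(NULL, "s1"))
  )
}

# Random multi-sample variant set over the default cohort's samples. When a
# toy_reference is given, SNV reference alleles are read from it so that
# consequence annotation never trips the reference-mismatch guard.
random_variant_set <- function(n, samples, p_indel = 0.2, p_missing = 0.05,
                               chrom = "chr1", max_pos = 1e5,
                               reference = NULL) {
  pos <- sort(sample.int(max_pos, n))
  is_indel <- runif(n) < p_indel
  ref <- ifelse(is_indel, "AT", sample(c("A", "C", "G", "T"), n, replace = TRUE))
  if (!is.null(reference)) {
    seq <- as.character(reference$chromosomes[[chrom]])
    ref[!is_indel] <- substring(seq, pos[!is_indel], pos[!is_indel])
  }
  alt <- character(n)
  for (i in seq_len(n)) {
    alt[i] <- if (is_indel[i]) "A" else sample(setdiff(c("A", "C", "G", "T"), ref[i]), 1)
  }
  gt <- matrix(
    sample(c("hom_ref", "het", "hom_alt", "hemi", "missing"),
      n * length(samples),
      replace = TRUE, prob = c(0.4, 0.25, 0.2, 0.05, 0.1)
    ),
    n, length(samples),
    dimnames = list(NULL, samples)
  )
  dp <- matrix(
    sample(c(NA_integer_, 0:60), n * length(samples), replace = TRUE),
    n, length(samples),
    dimnames = list(NULL, samples)
  )
  dp[runif(n * length(samples)) < p_missing] <- NA_integer_
  variant_set(data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt), gt, dp)
}

# Per-record brute-force re-check of the full SNV funnel predicate set.
oracle_snv_survivors <- function(vs, ped, models, reference, min_depth = 10) {
  roles <- ped_roles(ped)
  keep <- logical(nrow(vs$sites))
  for (i in seq_len(nrow(vs$sites))) {
    if (vs$sites$kind[i] != "SNV") next
    core <- c(roles$affected, roles$parents)
    dp <- vs$dp[i, core]
    if (any(is.na(dp)) || any(dp < min_depth)) next
    pos <- vs$sites$pos[i]
    in_gene <- any(vapply(models, function(m) {
      m$chrom == vs$sites$chrom[i] && pos >= m$start && pos <= m$end
    }, logical(1)))
    in_exon <- any(vapply(models, function(m) {
      m$chrom == vs$sites$chrom[i] && any(pos >= m$exons$start & pos <= m$exons$end)
    }, logical(1)))
    if (!in_gene || !in_exon) next
    csq <- annotate_consequence(vs[i], models, reference)
    if (!all(vs$gt[i, roles$affected] == "hom_alt")) next
    if (!all(vs$gt[i, roles$parents] %in% c("het", "hemi"))) next
    if (any(vs$gt[i, roles$controls] == "hom_alt")) next
    if (csq$coding_effect != "missense") next
    keep[i] <- TRUE
  }
  keep
}

oracle_indel_survivors <- function(vs, ped, models, min_depth = 10) {
  roles <- ped_roles(ped)
  keep <- logical(nrow(vs$sites))
  for (i in seq_len(nrow(vs$sites))) {
    if (vs$sites$kind[i] != "indel") next
    core <- c(roles$affected, roles$parents)
    dp <- vs$dp[i, core]
    if (any(is.na(dp)) || any(dp < min_depth)) next
    if (!all(vs$gt[i, core] %in% c("het", "hom_alt", "hemi"))) next
    if (!all(vs$gt[i, roles$affected] == "hom_alt")) next
    if (!all(vs$gt[i, roles$parents] %in% c("het", "hemi"))) next
    if (any(vs$gt[i, roles$controls] == "hom_alt")) next
    pos <- vs$sites$pos[i]
    in_exon <- any(vapply(models, function(m) {
      m$chrom == vs$sites$chrom[i] && any(pos >= m$exons$start & pos <= m$exons$end)
    }, logical(1)))
    if (!in_exon) next
    keep[i] <- TRUE
  }
  keep
}

site_key <- function(vs) {
  with(vs$sites, paste(chrom, pos, ref, alt, sep = ":"))
}
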