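#' Cohort design for the synthetic recessive study
#'
#' Bundles the knobs of the synthetic cohort generator. The defaults mirror
#' the screening design the pipeline targets: three affected offspring, the
#' two parents of the first one (obligate heterozygous carriers under the
#' recessive model) and six unrelated unaffected controls.
#'
#' @param n_affected number of affected samples.
#' @param n_parents number of obligate-carrier parents (0, 1 or 2; parents
#'   are attached to the first affected sample).
#' @param n_controls number of unaffected control samples.
#' @param carrier_freq_controls probability that a control carries one copy
#'   of the causal allele (controls are never homozygous-alternate).
#' @param n_background_variants number of Hardy-Weinberg background SNVs.
#' @param background_af_range allele-frequency interval for background
#'   variants.
#' @param mean_depth mean per-call sequencing depth (reads).
#' @param depth_dispersion negative-binomial size parameter of the depth
#'   model; smaller values give more overdispersed depth.
#' @param genotyping_error per-call probability of swapping a written
#'   genotype for a uniformly chosen different one.
#' @param causal_min_depth guaranteed minimum depth at the causal site for
#'   affected and parent samples (the planted variant emulates a variant
#'   that was actually sequenced at usable depth); background sites use the
#'   untruncated depth model.
#' @param seed integer seed; all generator randomness derives from it.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(n_affected = 3L, n_parents = 2L, n_controls = 6L,
                          carrier_freq_controls = 0.1,
                          n_background_variants = 500L,
                          background_af_range = c(0.05, 0.95),
                          mean_depth = 30, depth_dispersion = 8,
                          genotyping_error = 0, causal_min_depth = 10L,
                          seed = 1L) {
  stopifnot(
    n_affected >= 0L, n_parents >= 0L, n_parents <= 2L, n_controls >= 0L,
    carrier_freq_controls >= 0, carrier_freq_controls <= 1,
    n_background_variants >= 0L,
    length(background_af_range) == 2L,
    background_af_range[1L] >= 0, background_af_range[2L] <= 1,
    background_af_range[1L] <= background_af_range[2L],
    mean_depth > 0, depth_dispersion > 0,
    genotyping_error >= 0, genotyping_error <= 1
  )
  structure(
    list(
      n_affected = as.integer(n_affected), n_parents = as.integer(n_parents),
      n_controls = as.integer(n_controls),
      carrier_freq_controls = carrier_freq_controls,
      n_background_variants = as.integer(n_background_variants),
      background_af_range = background_af_range,
      mean_depth = mean_depth, depth_dispersion = depth_dispersion,
      genotyping_error = genotyping_error,
      causal_min_depth = as.integer(causal_min_depth),
      seed = as.integer(seed)
    ),
    class = "cohort_design"
  )
}

design_sample_ids <- function(design) {
  list(
    affected = if (design$n_affected) paste0("affected_", seq_len(design$n_affected)) else character(),
    parents = if (design$n_parents) paste0("parent_", seq_len(design$n_parents)) else character(),
    controls = if (design$n_controls) paste0("control_", seq_len(design$n_controls)) else character()
  )
}

#' Plant a recessive causal variant and background variants in a cohort
#'
#' Chooses an exonic, missense-inducing SNV at the first or second position
#' of a codon of a randomly chosen gene as the causal variant and assigns
#' genotypes under the strict recessive model: every affected sample is
#' homozygous-alternate, every parent heterozygous, and controls carry at
#' most one allele (heterozygous with probability `carrier_freq_controls`).
#' Background SNVs get allele frequencies drawn uniformly from
#' `background_af_range` and per-sample genotypes drawn independently from
#' Hardy-Weinberg proportions.
#'
#' @param reference a `toy_reference` from [build_toy_reference()]; must
#'   contain at least one gene.
#' @param design a [cohort_design()].
#' @return An object of class `truth_set`: `sites` (with a `causal` flag and
#'   background allele frequencies), `genotypes` (sites x samples matrix
#'   over the genotype vocabulary), `causal` (row index), `samples`,
#'   `design`.
#' @export
plant_cohort <- function(reference, design) {
  if (length(reference$genes) == 0L) {
    stopf("reference has no genes: no exonic position available for the causal variant")
  }
  ids <- design_sample_ids(design)
  samples <- unlist(ids, use.names = FALSE)
  with_seed(design$seed, {
    gene <- reference$genes[[sample(length(reference$genes), 1L)]]
    n_codons <- cds_length(gene) %/% 3L
    causal <- NULL
    # interior codons only, so the edit can never touch start or stop
    for (attempt in seq_len(200L)) {
      codon_index <- sample(2:(n_codons - 1L), 1L)
      offset <- sample(1:2, 1L)
      cds_pos <- (codon_index - 1L) * 3L + offset
      cds_seq <- cds_sequence(gene, reference$chromosomes)
      codon_start <- (codon_index - 1L) * 3L + 1L
      ref_codon <- as.character(Biostrings::subseq(cds_seq, codon_start, codon_start + 2L))
      ref_aa <- Biostrings::GENETIC_CODE[[ref_codon]]
      alts <- setdiff(DNA_BASES, substr(ref_codon, offset, offset))
      ok <- character()
      for (a in alts) {
        alt_codon <- ref_codon
        substr(alt_codon, offset, offset) <- a
        aa <- Biostrings::GENETIC_CODE[[alt_codon]]
        if (aa != ref_aa && aa != "*") ok <- c(ok, a)
      }
      if (length(ok)) {
        alt_coding <- sample(ok, 1L)
        pos <- cds_to_genome(gene, cds_pos)
        ref_base <- as.character(
          Biostrings::subseq(reference$chromosomes[[gene$chrom]], pos, pos)
        )
        alt_base <- if (gene$strand == "+") {
          alt_coding
        } else {
          as.character(Biostrings::complement(Biostrings::DNAString(alt_coding)))
        }
        causal <- data.frame(
          chrom = gene$chrom, pos = pos, ref = ref_base, alt = alt_base
        )
        break
      }
    }
    if (is.null(causal)) stopf("could not construct a missense causal variant")

    chrom_name <- names(reference$chromosomes)[1L]
    chrom_len <- Biostrings::width(reference$chromosomes)[1L]
    n_bg <- design$n_background_variants
    bg_pos <- integer()
    if (n_bg > 0L) {
      avail <- setdiff(seq_len(chrom_len), causal$pos)
      bg_pos <- sort(sample(avail, n_bg))
      bg_ref <- strsplit(as.character(Biostrings::subseq(
        reference$chromosomes[[chrom_name]], 1L, chrom_len
      )), "")[[1L]][bg_pos]
      bg_alt <- vapply(bg_ref, function(r) sample(setdiff(DNA_BASES, r), 1L), "")
    }
    af <- if (n_bg > 0L) {
      runif(n_bg, design$background_af_range[1L], design$background_af_range[2L])
    } else {
      numeric()
    }

    sites <- rbind(
      data.frame(
        chrom = causal$chrom, pos = causal$pos, ref = causal$ref,
        alt = causal$alt, causal = TRUE, af = NA_real_
      ),
      if (n_bg > 0L) {
        data.frame(
          chrom = chrom_name, pos = bg_pos, ref = bg_ref, alt = bg_alt,
          causal = FALSE, af = af, row.names = NULL
        )
      }
    )
    ord <- order(sites$pos)
    sites <- sites[ord, , drop = FALSE]
    rownames(sites) <- NULL
    causal_row <- which(sites$causal)

    n_sites <- nrow(sites)
    gmat <- matrix("hom_ref", n_sites, length(samples),
      dimnames = list(NULL, samples)
    )
    for (r in seq_len(n_sites)) {
      if (sites$causal[r]) {
        gmat[r, ids$affected] <- "hom_alt"
        gmat[r, ids$parents] <- "het"
        if (length(ids$controls)) {
          carrier <- runif(length(ids$controls)) < design$carrier_freq_controls
          gmat[r, ids$controls] <- ifelse(carrier, "het", "hom_ref")
        }
      } else {
        p <- sites$af[r]
        u <- runif(length(samples))
        g <- ifelse(u < (1 - p)^2, "hom_ref",
          ifelse(u < (1 - p)^2 + 2 * p * (1 - p), "het", "hom_alt")
        )
        gmat[r, ] <- g
      }
    }
    structure(
      list(
        sites = sites, genotypes = gmat, causal = causal_row,
        samples = ids, design = design
      ),
      class = "truth_set"
    )
  })
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf(
    "<truth_set> %d variant(s) x %d sample(s); causal %s:%d %s>%s\n",
    nrow(x$sites), ncol(x$genotypes),
    x$sites$chrom[x$causal], x$sites$pos[x$causal],
    x$sites$ref[x$causal], x$sites$alt[x$causal]
  ))
  invisible(x)
}

# draw depths; optionally left-truncated by rejection
draw_depths <- function(n, mean_depth, dispersion, min_depth = 0L) {
  d <- rnbinom(n, size = dispersion, mu = mean_depth)
  while (any(d < min_depth)) {
    idx <- which(d < min_depth)
    d[idx] <- rnbinom(length(idx), size = dispersion, mu = mean_depth)
  }
  d
}

#' Write a planted cohort as VCF + PED
#'
#' Simulates per-sample read depths (negative binomial around
#' `mean_depth`), optionally corrupts genotypes at rate `genotyping_error`
#' (a corrupted call is swapped to a uniformly chosen *different* diploid
#' genotype), and writes a VCF v4.2 with `GT:DP` plus a 6-column PED
#' linking the parents to the first affected sample. Output is
#' deterministic given the design seed.
#'
#' @param truth a `truth_set` from [plant_cohort()].
#' @param design the [cohort_design()] used to build it.
#' @param vcf_path,ped_path output paths.
#' @return Invisibly, a list with `vcf`, `ped` and the realized
#'   [variant_set()].
#' @export
write_cohort <- function(truth, design, vcf_path, ped_path) {
  samples <- unlist(truth$samples, use.names = FALSE)
  n_sites <- nrow(truth$sites)
  with_seed(design$seed + 1L, {
    dp <- matrix(
      draw_depths(
        n_sites * length(samples), design$mean_depth,
        design$depth_dispersion
      ),
      n_sites, length(samples),
      dimnames = list(NULL, samples)
    )
    core <- c(truth$samples$affected, truth$samples$parents)
    if (length(core)) {
      dp[truth$causal, core] <- draw_depths(
        length(core), design$mean_depth, design$depth_dispersion,
        min_depth = design$causal_min_depth
      )
    }
    gt <- truth$genotypes
    if (design$genotyping_error > 0) {
      flip <- runif(length(gt)) < design$genotyping_error
      if (any(flip)) {
        gt[flip] <- vapply(
          gt[flip],
          function(g) sample(setdiff(c("hom_ref", "het", "hom_alt"), g), 1L),
          "",
          USE.NAMES = FALSE
        )
      }
    }
    vs <- variant_set(
      truth$sites[, c("chrom", "pos", "ref", "alt")], gt, dp
    )
    write_vcf(vs, vcf_path)
    ped <- cohort_pedigree(design)
    write_ped(ped, ped_path)
    invisible(list(vcf = vcf_path, ped = ped_path, variants = vs))
  })
}

#' Pedigree implied by a cohort design
#'
#' The first affected sample is the offspring of the two parents (when
#' present); remaining affected samples and all controls are founders.
#'
#' @param design a [cohort_design()].
#' @return A [pedigree()].
#' @export
cohort_pedigree <- function(design) {
  ids <- design_sample_ids(design)
  df <- data.frame(
    family = "FAM1",
    id = c(ids$affected, ids$parents, ids$controls),
    sire = "0", dam = "0", sex = "0",
    phenotype = c(
      rep("2", length(ids$affected)),
      rep("1", length(ids$parents) + length(ids$controls))
    ),
    stringsAsFactors = FALSE
  )
  if (length(ids$affected) >= 1L && length(ids$parents) >= 1L) {
    df$sire[df$id == ids$affected[1L]] <- ids$parents[1L]
    if (length(ids$parents) >= 2L) {
      df$dam[df$id == ids$affected[1L]] <- ids$parents[2L]
    }
  }
  df$sex[df$id %in% ids$parents[1L]] <- "1"
  if (length(ids$parents) >= 2L) df$sex[df$id == ids$parents[2L]] <- "2"
  pedigree(df)
}

#' One-call synthetic cohort simulation
#'
#' Convenience wrapper: builds a toy reference, plants the cohort, writes
#' VCF/PED into `dir`, and returns every intermediate object.
#'
#' @param design a [cohort_design()].
#' @param dir output directory (created if needed).
#' @param n_genes,chrom_length forwarded to [build_toy_reference()].
#' @return List with `reference`, `truth`, `variants` (realized
#'   [variant_set()]), `pedigree`, and file paths `vcf`, `ped`, `fasta`,
#'   `gff3`.
#' @examples
#' sim <- simulate_cohort(cohort_design(seed = 7, n_background_variants = 20),
#'   dir = tempfile("cohort")
#' )
#' sim$truth
#' @export
simulate_cohort <- function(design = cohort_design(), dir = tempfile("cohort"),
                            n_genes = 5L, chrom_length = 100000L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reference <- build_toy_reference(design$seed, n_genes, chrom_length)
  truth <- plant_cohort(reference, design)
  vcf <- file.path(dir, "cohort.vcf")
  ped <- file.path(dir, "cohort.ped")
  fasta <- file.path(dir, "reference.fa")
  gff3 <- file.path(dir, "genes.gff3")
  out <- write_cohort(truth, design, vcf, ped)
  write_reference_fasta(reference, fasta)
  write_gene_models_gff3(reference, gff3)
  list(
    reference = reference, truth = truth, variants = out$variants,
    pedigree = cohort_pedigree(design),
    vcf = vcf, ped = ped, fasta = fasta, gff3 = gff3
  )
}
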