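#' Annotate variant consequences against gene models
#'
#' Classifies each record of a variant set by region (within a gene span,
#' within an exon) and coding effect. For SNVs falling in a CDS, the
#' reference and alternate codons are translated under the standard genetic
#' code, strand-aware (minus-strand genes use the complement of the genomic
#' alleles), and classified as `missense`, `synonymous` or `nonsense`
#' (a stop-to-sense change is reported as `missense`). Exonic indels are
#' `indel_exonic`; everything else coding-wise is `non_coding` or
#' `indel_non_exonic`.
#'
#' @param vs a [variant_set()] (or a single-record subset).
#' @param models list of [gene_model()].
#' @param reference a `toy_reference` or named [Biostrings::DNAStringSet].
#' @return data.frame aligned with the records of `vs`: `in_gene`,
#'   `in_exon`, `coding_effect`, `gene_id`, `codon_index`, `ref_aa`,
#'   `alt_aa` (the amino-acid columns are `NA` for non-CDS records).
#' @examples
#' ref <- build_toy_reference(seed = 1, n_genes = 1, chrom_length = 20000)
#' @export
annotate_consequence <- function(vs, models, reference) {
  chromosomes <- if (inherits(reference, "toy_reference")) {
    reference$chromosomes
  } else {
    reference
  }
  n <- nrow(vs$sites)
  out <- data.frame(
    in_gene = logical(n), in_exon = logical(n),
    coding_effect = character(n), gene_id = NA_character_,
    codon_index = NA_integer_, ref_aa = NA_character_, alt_aa = NA_character_
  )
  for (i in seq_len(n)) {
    chrom <- vs$sites$chrom[i]
    pos <- vs$sites$pos[i]
    ref <- vs$sites$ref[i]
    alt <- vs$sites$alt[i]
    is_snv <- vs$sites$kind[i] == "SNV"
    if (!chrom %in% names(chromosomes)) {
      stopf("reference does not cover chromosome '%s'", chrom)
    }
    if (is_snv) {
      ref_base <- as.character(Biostrings::subseq(chromosomes[[chrom]], pos, pos))
      if (ref_base != ref) {
        stopf(
          "reference mismatch at %s:%d: reference has %s, record says %s",
          chrom, pos, ref_base, ref
        )
      }
    }
    hit <- NULL
    for (m in models) {
      if (m$chrom == chrom && pos >= m$start && pos <= m$end) {
        hit <- m
        break
      }
    }
    if (is.null(hit)) {
      out$in_gene[i] <- FALSE
      out$in_exon[i] <- FALSE
      out$coding_effect[i] <- if (is_snv) "non_coding" else "indel_non_exonic"
      next
    }
    out$in_gene[i] <- TRUE
    out$gene_id[i] <- hit$gene_id
    in_exon <- any(pos >= hit$exons$start & pos <= hit$exons$end)
    out$in_exon[i] <- in_exon
    if (!is_snv) {
      out$coding_effect[i] <- if (in_exon) "indel_exonic" else "indel_non_exonic"
      next
    }
    cds_pos <- genome_to_cds(hit, pos)
    if (is.na(cds_pos)) {
      out$coding_effect[i] <- "non_coding"
      next
    }
    codon_index <- (cds_pos - 1L) %/% 3L + 1L
    offset <- (cds_pos - 1L) %% 3L + 1L
    codon_start <- (codon_index - 1L) * 3L + 1L
    cds_seq <- cds_sequence(hit, chromosomes)
    ref_codon <- as.character(Biostrings::subseq(cds_seq, codon_start, codon_start + 2L))
    # the allele as read on the coding strand
    alt_coding <- if (hit$strand == "+") {
      alt
    } else {
      as.character(Biostrings::complement(Biostrings::DNAString(alt)))
    }
    alt_codon <- ref_codon
    substr(alt_codon, offset, offset) <- alt_coding
    ref_aa <- Biostrings::GENETIC_CODE[[ref_codon]]
    alt_aa <- Biostrings::GENETIC_CODE[[alt_codon]]
    out$codon_index[i] <- codon_index
    out$ref_aa[i] <- ref_aa
    out$alt_aa[i] <- alt_aa
    out$coding_effect[i] <- if (ref_aa == alt_aa) {
      "synonymous"
    } else if (alt_aa == "*") {
      "nonsense"
    } else {
      "missense"
    }
  }
  out
}

#' Virtual PCR against a template sequence
#'
#' Locates exact binding sites of the forward primer on the forward strand
#' and of the reverse primer (as its reverse complement) downstream, and
#' returns the implied amplicon. With no valid primer pair the result is an
#' explicit no-product object; with more than one implied product an
#' ambiguity error is raised listing every product.
#'
#' @param template nucleotide sequence (character or
#'   [Biostrings::DNAString]).
#' @param fwd_primer forward primer, 5' to 3' (>= 15 nt).
#' @param rev_primer reverse primer, 5' to 3' on the opposite strand
#'   (>= 15 nt).
#' @return A list of class `pcr_product`: `product` (logical), and when a
#'   product exists, `start`, `end`, `length` and `sequence`.
#' @examples
#' tpl <- paste0(
#'   "TCCAGCTTCTCATCGCCATC", strrep("N", 10),
#'   as.character(Biostrings::reverseComplement(
#'     Biostrings::DNAString("CACCCCACAAAGGGCTTTCA")
#'   ))
#' )
#' virtual_pcr(tpl, "TCCAGCTTCTCATCGCCATC", "CACCCCACAAAGGGCTTTCA")
#' @export
virtual_pcr <- function(template, fwd_primer, rev_primer) {
  template <- as.character(template)
  fwd_primer <- toupper(as.character(fwd_primer))
  rev_primer <- toupper(as.character(rev_primer))
  if (nchar(fwd_primer) < 15L || nchar(rev_primer) < 15L) {
    stopf("primers must be at least 15 nt")
  }
  rev_rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rev_primer)))
  find_all <- function(needle) {
    hits <- gregexpr(needle, template, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) integer() else as.integer(hits)
  }
  fwd_starts <- find_all(fwd_primer)
  rev_starts <- find_all(rev_rc)
  products <- list()
  for (fs in fwd_starts) {
    fe <- fs + nchar(fwd_primer) - 1L
    for (rs in rev_starts) {
      re <- rs + nchar(rev_rc) - 1L
      if (rs > fe) { # reverse site strictly downstream of the forward site
        products[[length(products) + 1L]] <- list(
          product = TRUE, start = fs, end = re, length = re - fs + 1L,
          sequence = substr(template, fs, re)
        )
      }
    }
  }
  if (length(products) == 0L) {
    return(structure(list(product = FALSE), class = "pcr_product"))
  }
  if (length(products) > 1L) {
    lens <- vapply(products, function(p) p$length, integer(1L))
    cond <- structure(
      class = c("trioscreen_pcr_ambiguity", "error", "condition"),
      list(
        message = sprintf(
          "ambiguous PCR: %d products (lengths %s)",
          length(products), paste(lens, collapse = ", ")
        ),
        call = sys.call(-1L),
        products = products
      )
    )
    stop(cond)
  }
  structure(products[[1L]], class = "pcr_product")
}

#' @export
print.pcr_product <- function(x, ...) {
  if (!x$product) {
    cat("<pcr_product> no product\n")
  } else {
    cat(sprintf("<pcr_product> %d bp amplicon [%d-%d]\n", x$length, x$start, x$end))
  }
  invisible(x)
}
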