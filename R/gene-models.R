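#' Gene model
#'
#' A minimal transcript-level gene model: a located, stranded gene with exon
#' intervals and coding (CDS) intervals. Coordinates are 1-based inclusive
#' throughout, matching VCF and GFF3 conventions; no half-open conversion is
#' exposed anywhere in the package.
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with columns `start`, `end` (1-based inclusive).
#' @param cds data.frame with columns `start`, `end`; must lie within exons
#'   and have total length divisible by 3. Defaults to `exons`.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, cds = exons) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L)
  if (!strand %in% c("+", "-")) stopf("strand must be '+' or '-', got '%s'", strand)
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  cds <- cds[order(cds$start), c("start", "end"), drop = FALSE]
  exons[] <- lapply(exons, as.integer)
  cds[] <- lapply(cds, as.integer)
  rownames(exons) <- NULL
  rownames(cds) <- NULL
  if (any(exons$end < exons$start)) stopf("gene %s: exon end < start", gene_id)
  if (nrow(exons) > 1L && any(exons$start[-1L] <= exons$end[-nrow(exons)])) {
    stopf("gene %s: overlapping exons", gene_id)
  }
  # every CDS interval must be contained in some exon
  for (i in seq_len(nrow(cds))) {
    inside <- any(cds$start[i] >= exons$start & cds$end[i] <= exons$end)
    if (!inside) stopf("gene %s: CDS interval outside exons", gene_id)
  }
  total <- sum(cds$end - cds$start + 1L)
  if (nrow(cds) > 0L && total %% 3L != 0L) {
    stopf("gene %s: CDS length %d not divisible by 3", gene_id, total)
  }
  structure(
    list(
      gene_id = gene_id, chrom = chrom, strand = strand,
      start = min(exons$start), end = max(exons$end),
      exons = exons, cds = cds
    ),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf(
    "<gene_model> %s %s:%d-%d (%s), %d exon(s), CDS %d nt\n",
    x$gene_id, x$chrom, x$start, x$end, x$strand,
    nrow(x$exons), cds_length(x)
  ))
  invisible(x)
}

#' Total coding length of a gene model
#' @param model a [gene_model()].
#' @return integer number of coding bases.
#' @export
cds_length <- function(model) {
  as.integer(sum(model$cds$end - model$cds$start + 1L))
}

# CDS intervals in translation order (5' to 3' of the mRNA).
cds_in_translation_order <- function(model) {
  cds <- model$cds
  if (model$strand == "-") cds[rev(seq_len(nrow(cds))), , drop = FALSE] else cds
}

#' Extract the spliced coding sequence of a gene model
#'
#' Concatenates the CDS intervals and, for minus-strand genes, reverse
#' complements the result so the returned sequence always reads 5' to 3'
#' beginning at the start codon.
#'
#' @param model a [gene_model()].
#' @param chromosomes a named [Biostrings::DNAStringSet] covering
#'   `model$chrom`.
#' @return A [Biostrings::DNAString] coding sequence.
#' @export
cds_sequence <- function(model, chromosomes) {
  chrom <- chromosomes[[model$chrom]]
  pieces <- lapply(seq_len(nrow(model$cds)), function(i) {
    Biostrings::subseq(chrom, model$cds$start[i], model$cds$end[i])
  })
  s <- do.call(Biostrings::xscat, pieces)
  if (model$strand == "-") s <- Biostrings::reverseComplement(s)
  s
}

#' Map a coding (cDNA) position to its genomic coordinate
#'
#' @param model a [gene_model()].
#' @param cds_pos 1-based position within the spliced coding sequence.
#' @return 1-based genomic coordinate of that coding base.
#' @export
cds_to_genome <- function(model, cds_pos) {
  stopifnot(cds_pos >= 1L, cds_pos <= cds_length(model))
  cds <- cds_in_translation_order(model)
  lens <- cds$end - cds$start + 1L
  cum <- cumsum(lens)
  i <- which(cds_pos <= cum)[1L]
  before <- if (i == 1L) 0L else cum[i - 1L]
  off <- cds_pos - before # 1-based offset into interval i, in translation order
  if (model$strand == "+") cds$start[i] + off - 1L else cds$end[i] - off + 1L
}

#' Map a genomic coordinate to its coding (cDNA) position
#'
#' @param model a [gene_model()].
#' @param pos 1-based genomic coordinate.
#' @return 1-based coding position, or `NA_integer_` when `pos` is not coding.
#' @export
genome_to_cds <- function(model, pos) {
  cds <- cds_in_translation_order(model)
  lens <- cds$end - cds$start + 1L
  before <- 0L
  for (i in seq_len(nrow(cds))) {
    if (pos >= cds$start[i] && pos <= cds$end[i]) {
      off <- if (model$strand == "+") pos - cds$start[i] + 1L else cds$end[i] - pos + 1L
      return(as.integer(before + off))
    }
    before <- before + lens[i]
  }
  NA_integer_
}

DNA_BASES <- c("A", "C", "G", "T")
NON_STOP_CODONS <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
})
STOP_CODONS <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc == "*"]
})

#' Build a seeded toy reference genome with gene models
#'
#' Generates random chromosome sequence and places non-overlapping protein
#' coding genes on it. Each gene carries a clean open reading frame (ATG
#' start, no internal stop, terminal stop codon) split across several exons
#' on a randomly chosen strand; in the toy models the CDS coincides with the
#' exons (no UTRs). The generator is fully deterministic for a fixed seed.
#'
#' @param seed integer seed; the same seed always yields byte-identical
#'   FASTA/GFF3 output.
#' @param n_genes number of genes to place (may be 0).
#' @param chrom_length chromosome length in bases.
#' @param n_chromosomes number of chromosomes, each of `chrom_length` bases;
#'   genes are distributed round-robin.
#' @return An object of class `toy_reference`: a list with `chromosomes`
#'   (named [Biostrings::DNAStringSet]) and `genes` (list of [gene_model()]).
#' @examples
#' ref <- build_toy_reference(seed = 1, n_genes = 2, chrom_length = 20000)
#' ref$genes[[1]]
#' @export
build_toy_reference <- function(seed, n_genes = 5L, chrom_length = 100000L,
                                n_chromosomes = 1L) {
  stopifnot(n_genes >= 0L, chrom_length >= 1L, n_chromosomes >= 1L)
  with_seed(seed, {
    chrom_names <- paste0("chr", seq_len(n_chromosomes))
    seqs <- lapply(chrom_names, function(nm) {
      paste(sample(DNA_BASES, chrom_length, replace = TRUE), collapse = "")
    })
    names(seqs) <- chrom_names
    genes <- vector("list", n_genes)
    cursor <- setNames(rep(1L, n_chromosomes), chrom_names)
    for (g in seq_len(n_genes)) {
      chrom <- chrom_names[((g - 1L) %% n_chromosomes) + 1L]
      n_codons <- sample(40:120, 1L)
      n_exons <- sample(2:4, 1L)
      cds_len <- 3L * n_codons
      # split the CDS into n_exons positive-length pieces
      cuts <- sort(sample(seq_len(cds_len - 1L), n_exons - 1L))
      piece_len <- diff(c(0L, cuts, cds_len))
      introns <- sample(60:200, n_exons - 1L, replace = TRUE)
      gene_len <- cds_len + sum(introns)
      gap <- sample(200:1000, 1L)
      gstart <- cursor[[chrom]] + gap
      gend <- gstart + gene_len - 1L
      if (gend > chrom_length - 200L) {
        stopf(
          "cannot place gene %d: chromosome %s too short (%d bp) for the requested gene set",
          g, chrom, chrom_length
        )
      }
      cursor[[chrom]] <- gend + 1L

      codons <- c(
        "ATG",
        sample(setdiff(NON_STOP_CODONS, "ATG"), n_codons - 2L, replace = TRUE),
        sample(STOP_CODONS, 1L)
      )
      mrna <- paste(codons, collapse = "")
      # assemble the plus-orientation genomic gene sequence and relative exons
      rel <- data.frame(start = integer(n_exons), end = integer(n_exons))
      parts <- character(2L * n_exons - 1L)
      at <- 1L
      mstart <- 1L
      for (i in seq_len(n_exons)) {
        rel$start[i] <- at
        rel$end[i] <- at + piece_len[i] - 1L
        parts[2L * i - 1L] <- substr(mrna, mstart, mstart + piece_len[i] - 1L)
        mstart <- mstart + piece_len[i]
        at <- at + piece_len[i]
        if (i < n_exons) {
          parts[2L * i] <- paste(sample(DNA_BASES, introns[i], replace = TRUE),
            collapse = ""
          )
          at <- at + introns[i]
        }
      }
      gseq <- paste(parts, collapse = "")
      strand <- sample(c("+", "-"), 1L)
      if (strand == "-") {
        gseq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(gseq)))
        rel <- data.frame(
          start = gene_len - rel$end + 1L,
          end = gene_len - rel$start + 1L
        )
        rel <- rel[order(rel$start), , drop = FALSE]
      }
      substr(seqs[[chrom]], gstart, gend) <- gseq
      genes[[g]] <- gene_model(
        gene_id = sprintf("gene%03d", g), chrom = chrom, strand = strand,
        exons = data.frame(start = gstart - 1L + rel$start, end = gstart - 1L + rel$end)
      )
    }
    structure(
      list(
        chromosomes = Biostrings::DNAStringSet(unlist(seqs)),
        genes = genes
      ),
      class = "toy_reference"
    )
  })
}

#' @export
print.toy_reference <- function(x, ...) {
  cat(sprintf(
    "<toy_reference> %d chromosome(s) (%s bp), %d gene(s)\n",
    length(x$chromosomes),
    paste(Biostrings::width(x$chromosomes), collapse = "+"),
    length(x$genes)
  ))
  invisible(x)
}

#' Write a toy reference to FASTA
#' @param reference a `toy_reference`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(reference, path) {
  Biostrings::writeXStringSet(reference$chromosomes, filepath = path)
  invisible(path)
}

#' Read a reference FASTA
#' @param path FASTA path (plain or gzip).
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  # keep only the first whitespace-delimited token of each header
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Write gene models as GFF3
#'
#' Emits `gene`, `exon` and `CDS` features with 1-based inclusive
#' coordinates and correct CDS phase.
#'
#' @param genes list of [gene_model()] (or a `toy_reference`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(genes, path) {
  if (inherits(genes, "toy_reference")) genes <- genes$genes
  lines <- "##gff-version 3"
  for (m in genes) {
    lines <- c(lines, paste(
      m$chrom, "trioscreen", "gene", m$start, m$end, ".", m$strand, ".",
      sprintf("ID=%s", m$gene_id),
      sep = "\t"
    ))
    for (i in seq_len(nrow(m$exons))) {
      lines <- c(lines, paste(
        m$chrom, "trioscreen", "exon", m$exons$start[i], m$exons$end[i], ".",
        m$strand, ".", sprintf("ID=%s.exon%d;Parent=%s", m$gene_id, i, m$gene_id),
        sep = "\t"
      ))
    }
    cds <- cds_in_translation_order(m)
    before <- 0L
    phases <- integer(nrow(cds))
    for (i in seq_len(nrow(cds))) {
      phases[i] <- (3L - before %% 3L) %% 3L
      before <- before + cds$end[i] - cds$start[i] + 1L
    }
    ord <- order(cds$start)
    for (k in ord) {
      lines <- c(lines, paste(
        m$chrom, "trioscreen", "CDS", cds$start[k], cds$end[k], ".",
        m$strand, phases[k], sprintf("ID=%s.cds;Parent=%s", m$gene_id, m$gene_id),
        sep = "\t"
      ))
    }
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Accepts the subset of GFF3 this package writes: `gene` features with an
#' `ID` attribute and `exon`/`CDS` children linked by `Parent`.
#'
#' @param path GFF3 path (plain or gzip).
#' @return A list of [gene_model()].
#' @export
read_gene_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  tab <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    id = as.character(gr$ID),
    parent = vapply(
      as.list(gr$Parent),
      function(p) if (length(p)) p[[1L]] else NA_character_, ""
    ),
    stringsAsFactors = FALSE
  )
  genes <- tab[tab$type == "gene", , drop = FALSE]
  lapply(seq_len(nrow(genes)), function(i) {
    gid <- genes$id[i]
    ex <- tab[tab$type == "exon" & !is.na(tab$parent) & tab$parent == gid,
      c("start", "end"),
      drop = FALSE
    ]
    cds <- tab[tab$type == "CDS" & !is.na(tab$parent) & tab$parent == gid,
      c("start", "end"),
      drop = FALSE
    ]
    gene_model(
      gene_id = gid, chrom = genes$chrom[i], strand = genes$strand[i],
      exons = ex, cds = if (nrow(cds)) cds else ex
    )
  })
}
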