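AA_THREE <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val", `*` = "Ter"
)

#' Parse an HGVS cDNA substitution
#'
#' Accepts single-nucleotide substitutions in `c.` notation
#' (`c.<pos><ref>><alt>`). Deletions, insertions, duplications and
#' delins edits are out of scope and rejected with an unsupported-syntax
#' error.
#'
#' @param text e.g. `"c.1579G>A"`.
#' @return An object of class `hgvs_cdna`: list with `position`,
#'   `ref_base`, `alt_base`.
#' @examples
#' parse_hgvs_c("c.1579G>A")
#' @export
parse_hgvs_c <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (grepl("(del|ins|dup)", text)) {
    stopf("unsupported HGVS edit type in '%s': only substitutions (ref>alt) are handled", text)
  }
  m <- regmatches(text, regexec("^c\\.([0-9]+)([ACGT])>([ACGT])$", text))[[1L]]
  if (length(m) != 4L) stopf("malformed HGVS cDNA substitution: '%s'", text)
  ref <- m[3L]
  alt <- m[4L]
  if (ref == alt) stopf("ref and alt bases are identical in '%s'", text)
  structure(
    list(position = as.integer(m[2L]), ref_base = ref, alt_base = alt),
    class = "hgvs_cdna"
  )
}

#' @export
print.hgvs_cdna <- function(x, ...) {
  cat(sprintf("<hgvs_cdna> c.%d%s>%s\n", x$position, x$ref_base, x$alt_base))
  invisible(x)
}

#' Map a cDNA coordinate to codon index and within-codon offset
#'
#' `codon_index = ceiling(position / 3)`;
#' `offset = ((position - 1) mod 3) + 1`, so
#' `position = 3 * (codon_index - 1) + offset` always holds.
#'
#' @param position 1-based CDS coordinate(s).
#' @return data.frame with columns `codon_index` and `offset`, one row per
#'   input position.
#' @examples
#' cdna_to_codon(1579) # residue 527, first codon position
#' @export
cdna_to_codon <- function(position) {
  position <- as.integer(position)
  stopifnot(all(position >= 1L))
  data.frame(
    codon_index = (position - 1L) %/% 3L + 1L,
    offset = (position - 1L) %% 3L + 1L
  )
}

#' Apply a cDNA substitution to a coding sequence
#'
#' Translates the affected codon before and after the single-base edit
#' under the standard genetic code.
#'
#' @param cds coding sequence (character or [Biostrings::DNAString]),
#'   beginning at the start codon.
#' @param hgvs an [parse_hgvs_c()] result, or the HGVS string itself.
#' @return An object of class `protein_substitution`: `codon_index`,
#'   `offset`, `ref_aa`, `alt_aa` (single-letter), `start_lost` (the edit
#'   disrupts the initiator codon), `synonymous`.
#' @export
apply_substitution <- function(cds, hgvs) {
  if (is.character(hgvs)) hgvs <- parse_hgvs_c(hgvs)
  cds <- toupper(as.character(cds))
  if (hgvs$position > nchar(cds)) {
    stopf(
      "position %d is beyond the %d nt coding sequence",
      hgvs$position, nchar(cds)
    )
  }
  have <- substr(cds, hgvs$position, hgvs$position)
  if (have != hgvs$ref_base) {
    stopf(
      "reference-base mismatch at c.%d: CDS has %s, substitution says %s",
      hgvs$position, have, hgvs$ref_base
    )
  }
  map <- cdna_to_codon(hgvs$position)
  codon_start <- (map$codon_index - 1L) * 3L + 1L
  ref_codon <- substr(cds, codon_start, codon_start + 2L)
  if (nchar(ref_codon) < 3L) stopf("coding sequence ends mid-codon at c.%d", hgvs$position)
  alt_codon <- ref_codon
  substr(alt_codon, map$offset, map$offset) <- hgvs$alt_base
  ref_aa <- Biostrings::GENETIC_CODE[[ref_codon]]
  alt_aa <- Biostrings::GENETIC_CODE[[alt_codon]]
  structure(
    list(
      codon_index = map$codon_index, offset = map$offset,
      ref_aa = ref_aa, alt_aa = alt_aa,
      start_lost = map$codon_index == 1L && ref_aa == "M" && alt_aa != "M",
      synonymous = ref_aa == alt_aa
    ),
    class = "protein_substitution"
  )
}

#' Format a protein substitution in HGVS p. notation
#' @param x a `protein_substitution`.
#' @return e.g. `"p.Ala527Thr"`; `"p.Met1?"` for a start-codon disruption.
#' @export
format_hgvs_p <- function(x) {
  if (isTRUE(x$start_lost)) {
    return("p.Met1?")
  }
  sprintf("p.%s%d%s", AA_THREE[[x$ref_aa]], x$codon_index, AA_THREE[[x$alt_aa]])
}

#' @export
print.protein_substitution <- function(x, ...) {
  cat(sprintf(
    "<protein_substitution> %s (codon %d, position %d)%s\n",
    format_hgvs_p(x), x$codon_index, x$offset,
    if (x$synonymous) " [synonymous]" else ""
  ))
  invisible(x)
}

#' Alignment scoring configuration
#'
#' @param matrix substitution matrix: a name resolvable by
#'   [Biostrings::pairwiseAlignment()] data (default `"BLOSUM62"`) or a
#'   numeric matrix with letter dimnames.
#' @param gap_open,gap_extend affine gap penalties (a gap of length L costs
#'   `gap_open + gap_extend * L`).
#' @return A list used by [pairwise_identity()].
#' @export
alignment_scoring <- function(matrix = "BLOSUM62", gap_open = 10,
                              gap_extend = 0.5) {
  stopifnot(gap_open >= 0, gap_extend >= 0)
  list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend)
}

resolve_substitution_matrix <- function(m) {
  if (is.matrix(m)) {
    return(m)
  }
  e <- new.env()
  utils::data(list = m, package = "Biostrings", envir = e)
  get(m, envir = e)
}

#' Global pairwise alignment and percent identity
#'
#' Needleman-Wunsch global alignment with a substitution matrix and affine
#' gap penalties (via [Biostrings::pairwiseAlignment()]). Percent identity
#' is `100 * identical columns / denominator`, where the denominator is by
#' default the total number of alignment columns (gapped columns included);
#' `"shorter"` divides by the shorter ungapped sequence length and
#' `"anchor"` by the length of `seq_a`, since published homology
#' percentages rarely state their denominator.
#'
#' @param seq_a,seq_b protein sequences (character or
#'   [Biostrings::AAString]).
#' @param scoring an [alignment_scoring()].
#' @param denominator `"columns"` (default), `"shorter"` or `"anchor"`.
#' @return An object of class `alignment_result`: `aligned_a`, `aligned_b`
#'   (gapped strings of equal length), `identity_pct`, `n_identical`,
#'   `n_columns`, `score`.
#' @examples
#' pairwise_identity("ACDEF", "ACDEF")$identity_pct # exactly 100
#' @export
pairwise_identity <- function(seq_a, seq_b, scoring = alignment_scoring(),
                              denominator = c("columns", "shorter", "anchor")) {
  denominator <- match.arg(denominator)
  seq_a <- toupper(as.character(seq_a))
  seq_b <- toupper(as.character(seq_b))
  if (!nzchar(seq_a) || !nzchar(seq_b)) stopf("sequences must be non-empty")
  mat <- resolve_substitution_matrix(scoring$matrix)
  ok <- rownames(mat)
  bad <- setdiff(
    unique(c(strsplit(seq_a, "")[[1L]], strsplit(seq_b, "")[[1L]])), ok
  )
  if (length(bad)) stopf("non-amino-acid character '%s' in input", bad[1L])
  # canonical orientation: the choice among co-optimal alignments depends on
  # argument order, so align the lexicographically smaller sequence as the
  # pattern and swap back — identity is then exactly symmetric
  swapped <- seq_a > seq_b
  p <- if (swapped) seq_b else seq_a
  s <- if (swapped) seq_a else seq_b
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(p), Biostrings::AAString(s),
    type = "global", substitutionMatrix = mat,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend
  )
  a <- as.character(Biostrings::alignedPattern(aln))
  b <- as.character(Biostrings::alignedSubject(aln))
  if (swapped) {
    tmp <- a
    a <- b
    b <- tmp
  }
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  n_identical <- sum(ca == cb & ca != "-")
  denom <- switch(denominator,
    columns = length(ca),
    shorter = min(nchar(seq_a), nchar(seq_b)),
    anchor = nchar(seq_a)
  )
  structure(
    list(
      aligned_a = a, aligned_b = b,
      identity_pct = 100 * n_identical / denom,
      n_identical = n_identical, n_columns = length(ca),
      score = Biostrings::score(aln), denominator = denominator
    ),
    class = "alignment_result"
  )
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "<alignment_result> %d columns, %d identical (%.1f%%), score %.1f\n",
    x$n_columns, x$n_identical, x$identity_pct, x$score
  ))
  invisible(x)
}

#' Per-domain percent identity from a pairwise alignment
#'
#' Restricts the identity computation to alignment columns whose
#' anchor-sequence residue index falls in each domain's range (columns
#' where the anchor carries a gap belong to no residue and are skipped).
#'
#' @param result an [pairwise_identity()] result.
#' @param domains data.frame with columns `name`, `start`, `end` (1-based
#'   inclusive residue intervals on the anchor sequence).
#' @param anchor `"a"` or `"b"`: which aligned sequence the domain
#'   coordinates refer to.
#' @return data.frame with `name`, `start`, `end`, `n_columns`,
#'   `n_identical`, `identity_pct`.
#' @export
domain_identity <- function(result, domains, anchor = c("a", "b")) {
  anchor <- match.arg(anchor)
  stopifnot(all(c("name", "start", "end") %in% names(domains)))
  ca <- strsplit(result$aligned_a, "")[[1L]]
  cb <- strsplit(result$aligned_b, "")[[1L]]
  anchor_chars <- if (anchor == "a") ca else cb
  resid <- cumsum(anchor_chars != "-")
  resid[anchor_chars == "-"] <- NA_integer_
  n_resid <- max(resid, na.rm = TRUE)
  out <- domains[, c("name", "start", "end")]
  out$n_columns <- NA_integer_
  out$n_identical <- NA_integer_
  out$identity_pct <- NA_real_
  for (i in seq_len(nrow(domains))) {
    if (domains$start[i] < 1L || domains$end[i] > n_resid ||
      domains$start[i] > domains$end[i]) {
      stopf(
        "domain '%s' [%d, %d] outside the anchor's %d residues",
        domains$name[i], domains$start[i], domains$end[i], n_resid
      )
    }
    cols <- which(!is.na(resid) & resid >= domains$start[i] &
      resid <= domains$end[i])
    ident <- sum(ca[cols] == cb[cols] & ca[cols] != "-")
    out$n_columns[i] <- length(cols)
    out$n_identical[i] <- ident
    out$identity_pct[i] <- 100 * ident / length(cols)
  }
  out
}

#' Conservation of the alignment column holding an anchor residue
#'
#' Locates the alignment column containing the anchor sequence's
#' `anchor_residue_index`-th residue and reports the modal residue of that
#' column and the fraction of sequences sharing it (gaps count as
#' non-matching but stay in the denominator).
#'
#' @param msa a named [Biostrings::AAStringSet] of pre-aligned sequences of
#'   equal width, or the path of an aligned FASTA.
#' @param anchor_seq_id name of the anchor sequence in the MSA.
#' @param anchor_residue_index 1-based residue index in the *ungapped*
#'   anchor sequence.
#' @return List with `column`, `consensus`, `fraction`, `n_sequences`.
#' @export
column_conservation <- function(msa, anchor_seq_id, anchor_residue_index) {
  if (is.character(msa) && length(msa) == 1L) {
    msa <- Biostrings::readAAStringSet(msa)
    names(msa) <- sub("\\s.*$", "", names(msa))
  }
  if (length(unique(Biostrings::width(msa))) != 1L) {
    stopf("aligned sequences must all have the same width")
  }
  if (!anchor_seq_id %in% names(msa)) {
    stopf("anchor sequence '%s' not present in the MSA", anchor_seq_id)
  }
  anchor <- strsplit(as.character(msa[[anchor_seq_id]]), "")[[1L]]
  resid <- cumsum(anchor != "-")
  if (anchor_residue_index < 1L || anchor_residue_index > max(resid)) {
    stopf(
      "residue index %d beyond the anchor's %d ungapped residues",
      anchor_residue_index, max(resid)
    )
  }
  column <- which(resid == anchor_residue_index & anchor != "-")[1L]
  chars <- vapply(
    as.character(msa),
    function(s) substr(s, column, column), ""
  )
  residues <- chars[chars != "-"]
  tab <- sort(table(residues), decreasing = TRUE)
  consensus <- names(tab)[1L]
  list(
    column = column, consensus = consensus,
    fraction = unname(tab[1L]) / length(msa),
    n_sequences = length(msa)
  )
}
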