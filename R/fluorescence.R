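#' Simulate endpoint allelic-discrimination fluorescence wells
#'
#' Emulates the endpoint Rn readout of a two-dye (FAM/VIC) allelic
#' discrimination assay. Cluster means follow the canonical scatter-plot
#' geometry: homozygous-mutant wells at high FAM / low VIC (upper-left of a
#' VIC-x/FAM-y plot), heterozygous at high FAM / high VIC, wild-type at low
#' FAM / high VIC, and no-template controls near the origin. Isotropic
#' Gaussian noise with standard deviation `noise_sd` is added and the
#' signals are floored at zero (an Rn ratio cannot be negative).
#'
#' @param genotypes named character vector, sample -> genotype in
#'   `c("wild", "het", "hom_mut")`.
#' @param noise_sd standard deviation of the isotropic Gaussian noise, in
#'   Rn units (cluster separation is 1 Rn unit).
#' @param n_ntc number of no-template control wells.
#' @param seed integer seed.
#' @param separation distance between adjacent cluster means (Rn units).
#' @return data.frame of wells: `sample_id` (`NA` for NTC wells), `fam_rn`,
#'   `vic_rn`, `is_ntc`.
#' @examples
#' wells <- simulate_endpoint_fluorescence(
#'   c(s1 = "wild", s2 = "het", s3 = "hom_mut"),
#'   noise_sd = 0.05, n_ntc = 2, seed = 1
#' )
#' @export
simulate_endpoint_fluorescence <- function(genotypes, noise_sd = 0.05,
                                           n_ntc = 2L, seed = 1L,
                                           separation = 1) {
  stopifnot(noise_sd >= 0, n_ntc >= 0L, separation > 0)
  if (length(genotypes) && is.null(names(genotypes))) {
    stopf("`genotypes` must be a named vector (sample -> genotype)")
  }
  bad <- setdiff(unique(genotypes), ASSAY_GT_LEVELS)
  if (length(bad)) stopf("unknown assay genotype '%s'", bad[1L])
  centroids <- fluorescence_centroids(separation)
  with_seed(seed, {
    n <- length(genotypes)
    fam <- centroids[genotypes, "fam_rn"]
    vic <- centroids[genotypes, "vic_rn"]
    wells <- data.frame(
      sample_id = c(names(genotypes), rep(NA_character_, n_ntc)),
      fam_rn = c(fam, rep(centroids["ntc", "fam_rn"], n_ntc)),
      vic_rn = c(vic, rep(centroids["ntc", "vic_rn"], n_ntc)),
      is_ntc = c(rep(FALSE, n), rep(TRUE, n_ntc)),
      row.names = NULL
    )
    if (noise_sd > 0) {
      wells$fam_rn <- wells$fam_rn + rnorm(nrow(wells), 0, noise_sd)
      wells$vic_rn <- wells$vic_rn + rnorm(nrow(wells), 0, noise_sd)
    }
    wells$fam_rn <- pmax(0, wells$fam_rn)
    wells$vic_rn <- pmax(0, wells$vic_rn)
    wells
  })
}

# Canonical cluster geometry (FAM reports the mutant allele, VIC the
# wild-type allele).
fluorescence_centroids <- function(separation = 1) {
  m <- rbind(
    hom_mut = c(separation, 0),
    het = c(separation, separation),
    wild = c(0, separation),
    ntc = c(0, 0)
  )
  colnames(m) <- c("fam_rn", "vic_rn")
  m
}

#' Write / read a wells table as CSV
#' @param wells data.frame as returned by
#'   [simulate_endpoint_fluorescence()].
#' @param path CSV path.
#' @return `path` (writer, invisibly) or the wells data.frame (reader).
#' @export
write_wells_csv <- function(wells, path) {
  utils::write.csv(wells, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_wells_csv
#' @export
read_wells_csv <- function(path) {
  w <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  stopifnot(all(c("sample_id", "fam_rn", "vic_rn", "is_ntc") %in% names(w)))
  w$is_ntc <- as.logical(w$is_ntc)
  w
}
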