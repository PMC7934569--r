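#' Genotype matrix for a biparental population
#'
#' The central container for the co-segregation scan: an ordered set of
#' biallelic sites and, for every site x sample combination, an unphased
#' genotype call plus its supporting read depth. Genotypes are coded as
#' counts of the alternate allele: \code{0} homozygous reference, \code{1}
#' heterozygous, \code{2} homozygous alternate, \code{NA} missing.
#'
#' @param sites data.frame with columns \code{id} (unique site label),
#'   \code{chrom}, \code{pos} (1-based bp; may be \code{NA} for sites not
#'   assigned to a pseudomolecule), \code{ref}, \code{alt} (allele strings,
#'   \code{ref != alt}) and \code{qual} (phred-like site quality, \code{NA}
#'   allowed).
#' @param samples character vector of unique sample IDs.
#' @param geno integer matrix, \code{nrow(sites)} x \code{length(samples)},
#'   values in \code{0:2} or \code{NA}.
#' @param depth non-negative integer matrix of the same shape.
#' @return an object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(sites, samples, geno, depth) {
  stopifnot(is.data.frame(sites),
            all(c("id", "chrom", "pos", "ref", "alt", "qual") %in% names(sites)))
  samples <- as.character(samples)
  geno <- as.matrix(geno)
  depth <- as.matrix(depth)
  if (anyDuplicated(samples))
    data_error("duplicated sample IDs in genotype matrix")
  key <- paste(sites$chrom, sites$pos, sites$id)
  if (anyDuplicated(key))
    data_error("duplicated (chrom, pos, id) site records")
  if (!all(dim(geno) == c(nrow(sites), length(samples))) ||
      !all(dim(depth) == c(nrow(sites), length(samples))))
    data_error("genotype/depth grid dimensions do not match sites x samples")
  if (nrow(sites) > 0) {
    if (any(sites$ref == sites$alt, na.rm = TRUE))
      data_error("ref and alt alleles must differ at every site")
    if (any(!is.na(sites$pos) & sites$pos < 1))
      data_error("positions must be >= 1")
  }
  bad <- !(geno %in% c(0L, 1L, 2L, NA))
  if (any(bad)) data_error("genotype codes must be 0, 1, 2 or NA")
  if (any(depth < 0, na.rm = TRUE)) data_error("read depths must be non-negative")
  dimnames(geno) <- dimnames(depth) <- list(sites$id, samples)
  structure(list(sites = sites, samples = samples,
                 geno = geno, depth = depth),
            class = "genotype_matrix")
}

#' @export
#' @method print genotype_matrix
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d sites x %d samples\n",
              nrow(x$sites), length(x$samples)))
  n_tot <- length(x$geno)
  if (n_tot > 0)
    cat(sprintf("  missing calls: %.1f%%\n", 100 * mean(is.na(x$geno))))
  if (nrow(x$sites) > 0)
    cat("  chromosomes:", paste(unique(x$sites$chrom), collapse = ", "), "\n")
  invisible(x)
}

#' @export
#' @method dim genotype_matrix
dim.genotype_matrix <- function(x) c(nrow(x$sites), length(x$samples))

# keep a subset of sites (logical or integer index), preserving order
subset_sites <- function(gm, keep) {
  genotype_matrix(gm$sites[keep, , drop = FALSE], gm$samples,
                  gm$geno[keep, , drop = FALSE],
                  gm$depth[keep, , drop = FALSE])
}

#' Phenotype table
#'
#' @param sample character vector of sample IDs (unique).
#' @param phenotype character vector, each one of \code{"double"},
#'   \code{"single"}, \code{"unknown"}.
#' @return data.frame of class \code{phenotype_table} with columns
#'   \code{sample}, \code{phenotype}.
#' @export
phenotype_table <- function(sample, phenotype) {
  sample <- as.character(sample)
  phenotype <- as.character(phenotype)
  if (length(sample) != length(phenotype))
    data_error("sample and phenotype vectors differ in length")
  if (anyDuplicated(sample))
    data_error("each sample may be phenotyped at most once")
  ok <- phenotype %in% c("double", "single", "unknown")
  if (!all(ok))
    data_error(paste0("invalid phenotype value(s): ",
                      paste(unique(phenotype[!ok]), collapse = ", ")))
  structure(data.frame(sample = sample, phenotype = phenotype,
                       stringsAsFactors = FALSE),
            class = c("phenotype_table", "data.frame"))
}

# named lookup vector sample -> phenotype ("unknown" when absent)
phen_lookup <- function(phen, samples) {
  out <- stats::setNames(rep("unknown", length(samples)), samples)
  hit <- match(samples, phen$sample)
  out[!is.na(hit)] <- phen$phenotype[hit[!is.na(hit)]]
  out
}
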