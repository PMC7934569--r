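#' Set low-depth genotype calls to missing
#'
#' Any call supported by fewer than \code{min_depth} reads is treated as
#' missing; the rule is strictly "under", so a call at exactly
#' \code{min_depth} reads is retained. Depths themselves are kept so the
#' operation is idempotent and auditable. The input is not modified.
#'
#' @param gm a [genotype_matrix].
#' @param min_depth minimum read depth (default 5) for a call to be kept.
#' @return a new [genotype_matrix] with sub-threshold calls set missing.
#' @export
apply_depth_missing_rule <- function(gm, min_depth = 5) {
  stopifnot(inherits(gm, "genotype_matrix"), min_depth >= 0)
  geno <- gm$geno
  geno[gm$depth < min_depth] <- NA_integer_
  genotype_matrix(gm$sites, gm$samples, geno, gm$depth)
}

#' Drop sites with too much missing data
#'
#' Removes every site whose fraction of missing calls is greater than or
#' equal to \code{max_missing_fraction} (so with the 0.05 default a
#' 100-sample site with 5 missing calls is removed, with 4 it is kept).
#' Site order is preserved; surviving calls are untouched.
#'
#' @param gm a [genotype_matrix].
#' @param max_missing_fraction missing-call fraction at or above which a
#'   site is removed (default 0.05).
#' @return a filtered [genotype_matrix].
#' @export
filter_by_missingness <- function(gm, max_missing_fraction = 0.05) {
  stopifnot(inherits(gm, "genotype_matrix"),
            max_missing_fraction >= 0, max_missing_fraction <= 1)
  if (nrow(gm$sites) == 0 || length(gm$samples) == 0) return(gm)
  frac <- rowMeans(is.na(gm$geno))
  subset_sites(gm, frac < max_missing_fraction)
}

#' Map-grade SNP selection (VCFtools-style thresholds)
#'
#' The composite filter used for linkage-map SNPs: per-call depth rule,
#' then site quality \code{>= min_quality}, then missing fraction
#' \code{<= max_missing}. Note the missingness comparison here keeps sites
#' at exactly \code{max_missing}, matching the upstream tool's
#' \code{--max-missing} convention, unlike [filter_by_missingness()] which
#' removes at the boundary.
#'
#' @param gm a [genotype_matrix].
#' @param min_depth per-call depth threshold (default 5).
#' @param min_quality minimum site quality (default 10); sites with missing
#'   quality are dropped.
#' @param max_missing maximum tolerated missing-call fraction (default 0.5).
#' @return a filtered [genotype_matrix].
#' @export
select_map_snps <- function(gm, min_depth = 5, min_quality = 10,
                            max_missing = 0.5) {
  stopifnot(min_depth >= 0, min_quality >= 0,
            max_missing >= 0, max_missing <= 1)
  gm <- apply_depth_missing_rule(gm, min_depth)
  if (nrow(gm$sites) == 0) return(gm)
  qual_ok <- !is.na(gm$sites$qual) & gm$sites$qual >= min_quality
  gm <- subset_sites(gm, qual_ok)
  if (nrow(gm$sites) == 0 || length(gm$samples) == 0) return(gm)
  frac <- rowMeans(is.na(gm$geno))
  subset_sites(gm, frac <= max_missing)
}
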