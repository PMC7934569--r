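#' Bundled marker-trait count tables and accession genotypes
#'
#' Small plain-text tables shipped with the package, derived from
#' published marker-trait results for the hydrangea double-flower loci:
#' \itemize{
#'   \item \code{djo_marker_counts()} — per-SNP genotype-class
#'     double-flower counts for the d_jo F2 mapping population (147
#'     offspring; nine SNPs on CHR17 with > 95\% agreement).
#'   \item \code{dsu_marker_counts()} — the corresponding five-SNP table
#'     for the d_su F2 population (93 offspring; most sites unplaced on
#'     the pseudomolecules, hence \code{NA} positions).
#'   \item \code{accession_marker_genotypes()} — CAPS (J01) and INDEL
#'     (S01) marker genotypes with recorded flower phenotypes for 35
#'     cultivated accessions.
#' }
#' The count tables feed [table_fixture()] to rebuild populations whose
#' scan reproduces the printed agreement percentages exactly.
#'
#' @return a data.frame (see each table's columns in the files under
#'   \code{inst/extdata/}).
#' @export
djo_marker_counts <- function() {
  utils::read.delim(system.file("extdata", "djo_marker_counts.tsv",
                                package = "cosegscan"),
                    stringsAsFactors = FALSE)
}

#' @rdname djo_marker_counts
#' @export
dsu_marker_counts <- function() {
  utils::read.delim(system.file("extdata", "dsu_marker_counts.tsv",
                                package = "cosegscan"),
                    stringsAsFactors = FALSE)
}

#' @rdname djo_marker_counts
#' @export
accession_marker_genotypes <- function() {
  utils::read.delim(system.file("extdata", "accession_marker_genotypes.tsv",
                                package = "cosegscan"),
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Default double-flower marker definitions
#'
#' \code{j01_marker_table()}: the CAPS marker J01 — a 167 bp amplicon
#' whose recessive (double-flower) allele carries a TaqI site and scores
#' as 117 + 50 bp after digestion, while the dominant allele stays
#' undigested at 167 bp. Gel-scored, so exact sizing (tolerance 0).
#' \code{s01_marker_table()}: the INDEL marker S01 — amplicon alleles of
#' 280 bp (no deletion), 250 bp (30 bp deletion) and 236 bp (30 + 14 bp
#' deletions, the recessive allele), sized by capillary fragment analysis
#' (tolerance 1 bp).
#'
#' @return a [marker_allele_table].
#' @export
j01_marker_table <- function() {
  marker_allele_table("J01",
                      list("167" = 167, "117_50" = c(117, 50)),
                      tolerance = 0)
}

#' @rdname j01_marker_table
#' @export
s01_marker_table <- function() {
  predict_indel_allele_sizes(280, list(numeric(0), 30, c(30, 14)),
                             marker = "S01", tolerance = 1)
}

#' @rdname j01_marker_table
#' @export
double_flower_recessive_alleles <- function() {
  c(J01 = "117_50", S01 = "236")
}
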