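#' Read a VCF file into a genotype matrix
#'
#' Parses a VCF 4.x file (via \code{vcfR}) and keeps only biallelic SNP
#' records; multiallelic lines and indels are skipped with a message giving
#' the count. Per-sample \code{GT} is decoded to alternate-allele dosage
#' (unphased; \code{|} treated as \code{/}) and \code{./.} becomes missing.
#' Per-sample \code{DP} supplies the read depth; if the FORMAT has no
#' \code{DP} field, depths are set to 0 with a warning.
#'
#' @param path path to a VCF file (plain or gzipped).
#' @return a [genotype_matrix]. The number of skipped non-biallelic-SNP
#'   records is attached as attribute \code{"skipped"}.
#' @seealso [write_vcf()] for the inverse operation.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) usage_error(paste("VCF file not found:", path))
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) data_error(paste("malformed VCF:",
                                                     conditionMessage(e))))
  samples <- setdiff(colnames(v@gt), "FORMAT")
  empty_sites <- data.frame(id = character(), chrom = character(),
                            pos = integer(), ref = character(),
                            alt = character(), qual = numeric(),
                            stringsAsFactors = FALSE)
  if (nrow(v@fix) == 0) {
    gm <- genotype_matrix(empty_sites, samples,
                          matrix(integer(), 0, length(samples)),
                          matrix(integer(), 0, length(samples)))
    attr(gm, "skipped") <- 0L
    return(gm)
  }
  fix <- v@fix
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  is_snp <- !is.na(alt) & !grepl(",", alt) &
    nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skip <- sum(!is_snp)
  if (n_skip > 0)
    message(sprintf("read_vcf: skipped %d non-biallelic-SNP record(s)", n_skip))
  keep <- which(is_snp)
  id <- fix[keep, "ID"]
  id[is.na(id) | id == "."] <-
    paste(fix[keep, "CHROM"], fix[keep, "POS"], sep = "_")[is.na(id) | id == "."]
  sites <- data.frame(id = id,
                      chrom = fix[keep, "CHROM"],
                      pos = as.integer(fix[keep, "POS"]),
                      ref = ref[keep], alt = alt[keep],
                      qual = suppressWarnings(as.numeric(fix[keep, "QUAL"])),
                      stringsAsFactors = FALSE)
  gt_raw <- v@gt[keep, , drop = FALSE]
  fmt <- strsplit(gt_raw[, "FORMAT"], ":", fixed = TRUE)
  smp <- gt_raw[, samples, drop = FALSE]
  n_site <- length(keep)
  geno <- matrix(NA_integer_, n_site, length(samples))
  depth <- matrix(0L, n_site, length(samples))
  has_dp <- TRUE
  for (i in seq_len(n_site)) {
    gt_idx <- match("GT", fmt[[i]])
    dp_idx <- match("DP", fmt[[i]])
    if (is.na(gt_idx))
      data_error("VCF FORMAT lacks the mandatory GT field")
    parts <- strsplit(smp[i, ], ":", fixed = TRUE)
    gt <- vapply(parts, function(p) p[gt_idx], character(1))
    gt <- gsub("|", "/", gt, fixed = TRUE)
    geno[i, ] <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)[gt]
    if (is.na(dp_idx)) {
      has_dp <- FALSE
    } else {
      dp <- suppressWarnings(as.integer(
        vapply(parts, function(p) if (length(p) >= dp_idx) p[dp_idx] else NA_character_,
               character(1))))
      dp[is.na(dp)] <- 0L
      depth[i, ] <- dp
    }
  }
  if (!has_dp)
    warning("VCF has records without a DP field; depths set to 0")
  gm <- genotype_matrix(sites, samples, geno, depth)
  attr(gm, "skipped") <- n_skip
  gm
}

#' Write a genotype matrix as plain-text VCF 4.2
#'
#' Emits one record per site with a \code{GT:DP} FORMAT. Missing calls are
#' written as \code{./.}. The alternate allele is whatever the matrix
#' stores as \code{alt}; for simulated populations that is, by convention,
#' the allele carried by the double-flower parent.
#'
#' @param gm a [genotype_matrix].
#' @param path output file path.
#' @param source_tag value for the \code{##source} header line.
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(gm, path, source_tag = "cosegscan") {
  stopifnot(inherits(gm, "genotype_matrix"))
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##source=", source_tag),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", gm$samples), collapse = "\t"))
  gt_code <- c("0/0", "0/1", "1/1")
  lines <- character(nrow(gm$sites))
  for (i in seq_len(nrow(gm$sites))) {
    g <- gm$geno[i, ]
    gt <- ifelse(is.na(g), "./.", gt_code[g + 1L])
    cells <- paste(gt, gm$depth[i, ], sep = ":")
    s <- gm$sites[i, ]
    lines[i] <- paste(c(s$chrom, s$pos, s$id, s$ref, s$alt,
                        if (is.na(s$qual)) "." else format(s$qual, trim = TRUE),
                        ".", ".", "GT:DP", cells), collapse = "\t")
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a phenotype table
#'
#' Two-column tab-separated file with header \code{sample<TAB>phenotype};
#' phenotype values must be \code{double}, \code{single} or \code{unknown}.
#'
#' @param path path to the TSV file.
#' @return a [phenotype_table].
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) usage_error(paste("phenotype file not found:", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "phenotype") %in% names(df)))
    data_error("phenotype table must have columns 'sample' and 'phenotype'")
  phenotype_table(df$sample, df$phenotype)
}

#' @rdname read_phenotypes
#' @param phen a [phenotype_table] to write.
#' @export
write_phenotypes <- function(phen, path) {
  utils::write.table(phen, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
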