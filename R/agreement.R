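#' Cross design for the recessive single-locus model
#'
#' Identifies the two parents of the mapping population and the cross
#' design. Under \code{"F2"} both parents must be genotyped so alleles can
#' be oriented (double parent homozygous X, single parent homozygous Y).
#' Under \code{"F1_carrier_cross"} (a double-flower parent crossed to a
#' phenotypically single carrier) orientation uses the double parent only
#' and the other parent must be heterozygous; segregation is expected 1:1.
#'
#' @param double_parent sample ID of the double-flower parent.
#' @param single_parent sample ID of the single-flower (or carrier) parent.
#' @param design \code{"F2"} or \code{"F1_carrier_cross"}.
#' @return an object of class \code{cross_model}.
#' @export
cross_model <- function(double_parent, single_parent,
                        design = c("F2", "F1_carrier_cross")) {
  design <- match.arg(design)
  if (identical(double_parent, single_parent))
    usage_error("the two parent IDs must differ")
  structure(list(double_parent = double_parent,
                 single_parent = single_parent,
                 design = design),
            class = "cross_model")
}

#' Assign the double-parent allele at every site
#'
#' For each site, decides which allele (ref or alt) was contributed by the
#' double-flower parent, the orientation needed to evaluate the recessive
#' model. F2: the double parent must be homozygous for one allele and the
#' single parent homozygous for the other. Carrier cross: the double
#' parent must be homozygous and the other parent heterozygous. All other
#' parental configurations (heterozygous where homozygosity is required,
#' missing, or identical homozygotes) make the site uninformative.
#'
#' @param gm a [genotype_matrix] containing both parents.
#' @param model a [cross_model].
#' @return data.frame with one row per site: \code{id},
#'   \code{informative} (logical) and \code{double_allele} /
#'   \code{single_allele} (nucleotide strings, \code{NA} when
#'   uninformative).
#' @export
orient_alleles <- function(gm, model) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(model, "cross_model"))
  for (p in c(model$double_parent, model$single_parent))
    if (!p %in% gm$samples)
      usage_error(paste("parent sample not in genotype matrix:", p))
  dg <- gm$geno[, model$double_parent]
  sg <- gm$geno[, model$single_parent]
  n <- nrow(gm$sites)
  dbl <- rep(NA_character_, n)
  sgl <- rep(NA_character_, n)
  if (model$design == "F2") {
    ok_ref <- !is.na(dg) & !is.na(sg) & dg == 0L & sg == 2L
    ok_alt <- !is.na(dg) & !is.na(sg) & dg == 2L & sg == 0L
  } else {
    ok_ref <- !is.na(dg) & !is.na(sg) & dg == 0L & sg == 1L
    ok_alt <- !is.na(dg) & !is.na(sg) & dg == 2L & sg == 1L
  }
  dbl[ok_ref] <- gm$sites$ref[ok_ref]
  sgl[ok_ref] <- gm$sites$alt[ok_ref]
  dbl[ok_alt] <- gm$sites$alt[ok_alt]
  sgl[ok_alt] <- gm$sites$ref[ok_alt]
  data.frame(id = gm$sites$id,
             informative = ok_ref | ok_alt,
             double_allele = dbl,
             single_allele = sgl,
             double_is_alt = ok_alt,
             stringsAsFactors = FALSE)
}

#' Per-genotype-class double-flower counts
#'
#' Each argument is a pair \code{c(n_double_phenotype, n_total)} for one
#' genotype class: individuals homozygous for the double-parent allele,
#' heterozygotes, and individuals homozygous for the single-parent allele.
#' Missing genotypes and unknown phenotypes are excluded from both members
#' of every pair.
#'
#' @param hom_double,het,hom_single integer pairs \code{c(d, n)}.
#' @return an object of class \code{class_counts}.
#' @export
class_counts <- function(hom_double, het, hom_single) {
  m <- rbind(hom_double = hom_double, het = het, hom_single = hom_single)
  if (ncol(m) != 2 || any(m < 0) || any(m[, 1] > m[, 2]))
    usage_error("each class must be c(n_double_phenotype, n_total) with d <= n")
  structure(list(hom_double = as.integer(hom_double),
                 het = as.integer(het),
                 hom_single = as.integer(hom_single)),
            class = "class_counts")
}

#' Degree of agreement with the recessive single-locus model
#'
#' The model predicts the double-flower phenotype exactly for individuals
#' homozygous for the double-parent allele, and the single-flower
#' phenotype for heterozygotes and individuals homozygous for the
#' single-parent allele. With class pairs (d1,n1), (d2,n2), (d3,n3) for
#' the three genotype classes, the statistic is
#' \deqn{100 \times \frac{d_1 + (n_2 - d_2) + (n_3 - d_3)}{n_1 + n_2 + n_3}}
#' i.e. the percentage of genotyped, phenotyped individuals whose
#' phenotype matches the model's prediction.
#'
#' @param counts a [class_counts] object.
#' @return agreement percentage in \eqn{[0, 100]}, full precision
#'   (display rounding is the caller's concern; see [round_half_up()]).
#' @export
#' @examples
#' score_agreement(class_counts(c(36, 37), c(1, 60), c(1, 49)))  # 143/146
score_agreement <- function(counts) {
  stopifnot(inherits(counts, "class_counts"))
  n <- counts$hom_double[2] + counts$het[2] + counts$hom_single[2]
  if (n == 0)
    data_error("agreement undefined: no genotyped, phenotyped individuals")
  agree <- counts$hom_double[1] +
    (counts$het[2] - counts$het[1]) +
    (counts$hom_single[2] - counts$hom_single[1])
  100 * agree / n
}

#' Scan every SNP for co-segregation with a recessive trait
#'
#' The central fitting function: scores each informative site of a
#' biparental population for its degree of agreement with the model
#' "double phenotype iff homozygous for the double-parent allele"
#' ([score_agreement()]). Parents are excluded from the counts; missing
#' genotypes and unknown phenotypes are excluded per site, so class
#' denominators may vary between sites.
#'
#' @param gm a [genotype_matrix], normally already depth- and
#'   missingness-filtered (see [apply_depth_missing_rule()] and
#'   [filter_by_missingness()]).
#' @param phen a [phenotype_table] for the offspring.
#' @param model a [cross_model].
#' @return an object of class \code{coseg_scan}: list with \code{results}
#'   (one row per informative site, sorted by decreasing agreement, ties by
#'   chromosome then position), \code{model}, \code{n_offspring},
#'   \code{n_uninformative}. Methods: \code{print}, \code{summary},
#'   \code{coef} (named agreement vector), \code{as.data.frame},
#'   \code{plot}.
#' @export
coseg_scan <- function(gm, phen, model) {
  stopifnot(inherits(gm, "genotype_matrix"),
            inherits(phen, "phenotype_table"),
            inherits(model, "cross_model"))
  ori <- orient_alleles(gm, model)
  offspring <- setdiff(gm$samples, c(model$double_parent, model$single_parent))
  ph <- phen_lookup(phen, offspring)
  if (!any(ph != "unknown"))
    data_error("no phenotyped offspring to scan")
  idx <- which(ori$informative)
  res <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    g <- gm$geno[i, offspring]
    # class membership relative to the double-parent allele
    hom_dbl_code <- if (ori$double_is_alt[i]) 2L else 0L
    cls <- ifelse(is.na(g), NA,
                  ifelse(g == hom_dbl_code, 1L, ifelse(g == 1L, 2L, 3L)))
    use <- !is.na(cls) & ph != "unknown"
    dd <- ph == "double" & use
    cc <- class_counts(c(sum(dd[cls == 1L & use]), sum(cls == 1L & use)),
                       c(sum(dd[cls == 2L & use]), sum(cls == 2L & use)),
                       c(sum(dd[cls == 3L & use]), sum(cls == 3L & use)))
    s <- gm$sites[i, ]
    res[[k]] <- data.frame(
      id = s$id, chrom = s$chrom, pos = s$pos,
      double_allele = ori$double_allele[i],
      single_allele = ori$single_allele[i],
      d_hom_double = cc$hom_double[1], n_hom_double = cc$hom_double[2],
      d_het = cc$het[1], n_het = cc$het[2],
      d_hom_single = cc$hom_single[1], n_hom_single = cc$hom_single[2],
      agreement = score_agreement(cc),
      stringsAsFactors = FALSE)
  }
  results <- if (length(res)) do.call(rbind, res) else
    data.frame(id = character(), chrom = character(), pos = integer(),
               double_allele = character(), single_allele = character(),
               d_hom_double = integer(), n_hom_double = integer(),
               d_het = integer(), n_het = integer(),
               d_hom_single = integer(), n_hom_single = integer(),
               agreement = numeric(), stringsAsFactors = FALSE)
  ord <- order(-results$agreement, results$chrom, results$pos)
  results <- results[ord, , drop = FALSE]
  rownames(results) <- NULL
  structure(list(results = results, model = model,
                 n_offspring = length(offspring),
                 n_uninformative = sum(!ori$informative)),
            class = "coseg_scan")
}

#' @export
#' @method print coseg_scan
print.coseg_scan <- function(x, n = 6, ...) {
  cat(sprintf("Recessive-model co-segregation scan (%s design)\n",
              x$model$design))
  cat(sprintf("  %d informative SNPs over %d offspring (%d uninformative)\n",
              nrow(x$results), x$n_offspring, x$n_uninformative))
  if (nrow(x$results)) {
    top <- utils::head(x$results, n)
    top$agreement <- round_half_up(top$agreement, 1)
    print(top[, c("id", "chrom", "pos", "agreement")], row.names = FALSE)
  }
  invisible(x)
}

#' @export
#' @method coef coseg_scan
coef.coseg_scan <- function(object, ...)
  stats::setNames(object$results$agreement, object$results$id)

#' @export
#' @method as.data.frame coseg_scan
as.data.frame.coseg_scan <- function(x, ...) x$results

#' @export
#' @method plot coseg_scan
plot.coseg_scan <- function(x, threshold = 95, ...) {
  r <- x$results[!is.na(x$results$pos), , drop = FALSE]
  if (!nrow(r)) {
    warning("no positioned SNPs to plot")
    return(invisible(x))
  }
  graphics::plot(r$pos / 1e6, r$agreement, xlab = "Position (Mb)",
                 ylab = "Degree of agreement (%)", ylim = c(50, 101),
                 pch = 19, col = ifelse(r$agreement > threshold, 2, 1), ...)
  graphics::abline(h = threshold, lty = 2)
  invisible(x)
}

#' @export
#' @method summary coseg_scan
summary.coseg_scan <- function(object, threshold = 95, ...) {
  rep <- threshold_report(object, threshold)
  interval <- if (nrow(rep$cosegregating) &&
                  any(!is.na(rep$cosegregating$pos)))
    suppressWarnings(infer_locus_interval(rep$cosegregating))
  else NULL
  structure(list(scan = object, threshold = threshold, report = rep,
                 interval = interval),
            class = "summary.coseg_scan")
}

#' @export
#' @method print summary.coseg_scan
print.summary.coseg_scan <- function(x, ...) {
  print(x$scan)
  cat(sprintf("\nSNPs with agreement > %s%%: %d\n", x$threshold,
              nrow(x$report$above)))
  cat(sprintf("Completely co-segregating SNPs (100%%): %d\n",
              nrow(x$report$cosegregating)))
  if (!is.null(x$interval)) {
    cat("Inferred locus interval:\n")
    print(x$interval)
  }
  invisible(x)
}

#' Threshold report: high-agreement and co-segregating SNP sets
#'
#' @param x a \code{coseg_scan} object or its results data.frame.
#' @param threshold agreement percentage; the \code{above} set is strictly
#'   greater than this, compared on unrounded values.
#' @return list with data.frames \code{above} and \code{cosegregating}
#'   (agreement exactly 100).
#' @export
threshold_report <- function(x, threshold = 95) {
  r <- if (inherits(x, "coseg_scan")) x$results else x
  if (!nrow(r)) usage_error("threshold_report needs a non-empty scan")
  list(above = r[r$agreement > threshold, , drop = FALSE],
       cosegregating = r[r$agreement == 100, , drop = FALSE])
}

#' Count distinct scaffolds among scan hits
#'
#' Site IDs of the form \code{<scaffold>_<offset>} are grouped by the text
#' before the first \code{"_"}.
#'
#' @param x a \code{coseg_scan}, results data.frame, or character vector of
#'   site IDs.
#' @return list with \code{n} and \code{scaffolds} (input order preserved).
#' @export
distinct_scaffolds <- function(x) {
  ids <- if (inherits(x, "coseg_scan")) x$results$id
         else if (is.data.frame(x)) x$id else as.character(x)
  sc <- unique(sub("_.*$", "", ids))
  list(n = length(sc), scaffolds = sc)
}

#' Infer the physical locus interval from co-segregating SNPs
#'
#' The interval spanned by the positioned co-segregating SNPs:
#' \code{start_bp} / \code{end_bp} are the min and max positions, and the
#' Mb endpoints are truncated to 0.1 Mb (floor), the convention that turns
#' 43,855,965 bp into 43.8 Mb. Sites without a pseudomolecule position
#' (\code{pos} is \code{NA}) are excluded. If the sites span several
#' chromosomes a warning is raised and one interval per chromosome is
#' returned.
#'
#' @param x a \code{coseg_scan}, a results data.frame, or any data.frame
#'   with \code{chrom} and \code{pos} columns.
#' @return data.frame of class \code{locus_interval} with columns
#'   \code{chrom}, \code{start_bp}, \code{end_bp}, \code{start_mb},
#'   \code{end_mb}.
#' @export
infer_locus_interval <- function(x) {
  r <- if (inherits(x, "coseg_scan")) x$results else x
  r <- r[!is.na(r$pos) & !is.na(r$chrom), , drop = FALSE]
  if (!nrow(r)) usage_error("no positioned sites to infer an interval from")
  chroms <- unique(r$chrom)
  if (length(chroms) > 1)
    warning("co-segregating sites span multiple chromosomes; ",
            "returning one interval per chromosome")
  out <- do.call(rbind, lapply(chroms, function(ch) {
    p <- r$pos[r$chrom == ch]
    data.frame(chrom = ch, start_bp = min(p), end_bp = max(p),
               stringsAsFactors = FALSE)
  }))
  out$start_mb <- floor(out$start_bp / 1e5) / 10
  out$end_mb <- floor(out$end_bp / 1e5) / 10
  class(out) <- c("locus_interval", "data.frame")
  out
}

#' Write a scan report as TSV
#'
#' One row per scanned SNP with the class counts formatted as
#' \code{"d/n"} and the agreement rounded half-up to one decimal.
#'
#' @param x a \code{coseg_scan}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_scan_report <- function(x, path) {
  r <- x$results
  out <- data.frame(
    id = r$id, chrom = r$chrom, pos = r$pos,
    double_parent_allele = r$double_allele,
    single_parent_allele = r$single_allele,
    agreement = round_half_up(r$agreement, 1),
    hom_double = paste(r$d_hom_double, r$n_hom_double, sep = "/"),
    het = paste(r$d_het, r$n_het, sep = "/"),
    hom_single = paste(r$d_hom_single, r$n_hom_single, sep = "/"),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
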