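IUPAC_CODES <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

#' Restriction enzyme definition
#'
#' @param name enzyme name, e.g. \code{"TaqI"}.
#' @param recognition recognition sequence in IUPAC nucleotide codes,
#'   written 5'->3' on the top strand.
#' @param cut_offset position of the cut within the recognition site,
#'   counted from its 5' end on the top strand; TaqI (T^CGA) has offset 1.
#' @return an object of class \code{restriction_enzyme}.
#' @export
restriction_enzyme <- function(name, recognition, cut_offset) {
  recognition <- toupper(recognition)
  letters <- strsplit(recognition, "")[[1]]
  if (length(letters) == 0 || !all(letters %in% IUPAC_CODES))
    usage_error("recognition sequence must be non-empty IUPAC nucleotides")
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0 || cut_offset > nchar(recognition))
    usage_error("cut_offset must lie within the recognition site")
  structure(list(name = name, recognition = recognition,
                 cut_offset = cut_offset),
            class = "restriction_enzyme")
}

#' @export
#' @method print restriction_enzyme
print.restriction_enzyme <- function(x, ...) {
  site <- paste0(substr(x$recognition, 1, x$cut_offset), "^",
                 substr(x$recognition, x$cut_offset + 1, nchar(x$recognition)))
  cat(sprintf("%s (%s)\n", x$name, site))
  invisible(x)
}

#' Load a restriction-enzyme dictionary
#'
#' Reads a tab-separated table with columns \code{name}, \code{recognition}
#' and \code{cut_offset}. The package ships a small curated dictionary
#' (TaqI plus common 4- and 6-cutters) used when \code{path} is omitted.
#'
#' @param path TSV path; default is the bundled dictionary.
#' @return named list of [restriction_enzyme] objects.
#' @export
load_enzymes <- function(path = system.file("extdata", "enzymes.tsv",
                                            package = "cosegscan")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "recognition", "cut_offset") %in% names(df)))
    data_error("enzyme dictionary needs columns name, recognition, cut_offset")
  enz <- lapply(seq_len(nrow(df)), function(i)
    restriction_enzyme(df$name[i], df$recognition[i], df$cut_offset[i]))
  stats::setNames(enz, df$name)
}

check_sequence <- function(sequence) {
  sequence <- toupper(sequence)
  letters <- strsplit(sequence, "")[[1]]
  if (length(letters) == 0 || !all(letters %in% IUPAC_CODES))
    usage_error("sequence contains non-nucleotide characters or is empty")
  sequence
}

#' Find restriction cut positions in a sequence
#'
#' Matches the enzyme's IUPAC recognition pattern against the given strand
#' (ambiguity codes in the pattern are expanded; matching uses
#' \code{Biostrings}); every occurrence, including overlapping ones,
#' yields one cut at \code{site_start - 1 + cut_offset}, i.e. the 1-based
#' position \emph{after} which the duplex is cut. With
#' \code{both_strands = TRUE} matches of the reverse-complement pattern
#' are also reported (relevant only for non-palindromic sites), with the
#' bottom-strand cut mapped onto top-strand coordinates.
#'
#' @param sequence nucleotide string (normalised to uppercase).
#' @param enzyme a [restriction_enzyme].
#' @param both_strands also scan the reverse complement (default FALSE).
#' @return sorted integer vector of cut positions (possibly empty).
#' @export
#' @examples
#' taqi <- restriction_enzyme("TaqI", "TCGA", 1)
#' find_sites("AATCGAAA", taqi)  # cut after position 3
find_sites <- function(sequence, enzyme, both_strands = FALSE) {
  stopifnot(inherits(enzyme, "restriction_enzyme"))
  sequence <- check_sequence(sequence)
  subj <- Biostrings::DNAString(sequence)
  m <- Biostrings::matchPattern(Biostrings::DNAString(enzyme$recognition),
                                subj, fixed = "subject")
  cuts <- Biostrings::start(m) - 1L + enzyme$cut_offset
  if (both_strands) {
    rc <- Biostrings::reverseComplement(
      Biostrings::DNAString(enzyme$recognition))
    m2 <- Biostrings::matchPattern(rc, subj, fixed = "subject")
    # bottom-strand cut_offset counted from the site's 3' end on top strand
    cuts2 <- Biostrings::start(m2) - 1L +
      (nchar(enzyme$recognition) - enzyme$cut_offset)
    cuts <- c(cuts, cuts2)
  }
  cuts <- sort(unique(cuts))
  cuts[cuts >= 1L & cuts < length(subj)]
}

#' PCR amplicon allele
#'
#' @param allele_label label for the allele, conventionally its scored
#'   fragment signature (e.g. \code{"167"}, \code{"117_50"}, \code{"236"}).
#' @param sequence optional nucleotide sequence.
#' @param length_bp amplicon length; defaults to \code{nchar(sequence)}.
#' @return an object of class \code{amplicon_allele}.
#' @export
amplicon_allele <- function(allele_label, sequence = NULL, length_bp = NULL) {
  if (!is.null(sequence)) {
    sequence <- check_sequence(sequence)
    if (is.null(length_bp)) length_bp <- nchar(sequence)
    if (length_bp != nchar(sequence))
      usage_error("length_bp must equal the sequence length when both given")
  }
  if (is.null(length_bp)) usage_error("need a sequence or a length")
  structure(list(allele_label = as.character(allele_label),
                 sequence = sequence, length_bp = as.integer(length_bp)),
            class = "amplicon_allele")
}

#' In-silico restriction digest of an amplicon
#'
#' Cuts the amplicon at every recognition site and returns the fragment
#' lengths between consecutive cuts; lengths always sum to the amplicon
#' length and the fragment count is one more than the cut count.
#'
#' @param amplicon an [amplicon_allele] with a sequence, or a plain
#'   nucleotide string.
#' @param enzyme a [restriction_enzyme].
#' @param both_strands passed to [find_sites()].
#' @return list of class \code{digest_result}: \code{enzyme},
#'   \code{cut_positions}, \code{fragment_lengths} (descending).
#' @export
digest <- function(amplicon, enzyme, both_strands = FALSE) {
  if (is.character(amplicon)) amplicon <- amplicon_allele("amp", amplicon)
  stopifnot(inherits(amplicon, "amplicon_allele"))
  if (is.null(amplicon$sequence))
    usage_error("digest needs an amplicon with a sequence")
  cuts <- find_sites(amplicon$sequence, enzyme, both_strands)
  len <- amplicon$length_bp
  frags <- diff(c(0L, cuts, len))
  structure(list(enzyme = enzyme, cut_positions = cuts,
                 fragment_lengths = sort(as.integer(frags),
                                         decreasing = TRUE)),
            class = "digest_result")
}

#' @export
#' @method print digest_result
print.digest_result <- function(x, ...) {
  cat(sprintf("%s digest: %d cut(s); fragments %s bp\n", x$enzyme$name,
              length(x$cut_positions),
              paste(x$fragment_lengths, collapse = " + ")))
  invisible(x)
}

#' Screen enzymes for a CAPS polymorphism between two alleles
#'
#' Digests both allele sequences with every candidate enzyme and reports
#' only those whose fragment-length multisets differ between the alleles —
#' the enzymes that would make a usable cleaved amplified polymorphic
#' sequence (CAPS) assay for the SNP.
#'
#' @param allele_a,allele_b [amplicon_allele] objects with sequences from
#'   the same amplicon, differing at the SNP.
#' @param enzymes list of [restriction_enzyme] objects (e.g.
#'   [load_enzymes()]).
#' @param both_strands passed to [digest()].
#' @return list of hits, each with \code{enzyme}, \code{digest_a},
#'   \code{digest_b}.
#' @export
caps_screen <- function(allele_a, allele_b, enzymes, both_strands = FALSE) {
  stopifnot(inherits(allele_a, "amplicon_allele"),
            inherits(allele_b, "amplicon_allele"))
  if (inherits(enzymes, "restriction_enzyme")) enzymes <- list(enzymes)
  hits <- list()
  for (enz in enzymes) {
    da <- digest(allele_a, enz, both_strands)
    db <- digest(allele_b, enz, both_strands)
    if (!identical(da$fragment_lengths, db$fragment_lengths))
      hits[[length(hits) + 1L]] <-
        list(enzyme = enz, digest_a = da, digest_b = db)
  }
  hits
}

#' Expected fragment signatures per marker allele
#'
#' @param marker marker name.
#' @param alleles named list: allele label -> numeric vector of expected
#'   fragment/product sizes (bp).
#' @param tolerance sizing tolerance in bp (default 1, capillary
#'   fragment-analysis resolution; use 0 for gel-scored CAPS alleles that
#'   differ by tens of bp).
#' @return object of class \code{marker_allele_table}. Signatures must be
#'   pairwise distinguishable given the tolerance, otherwise an
#'   ambiguity error is raised.
#' @export
marker_allele_table <- function(marker, alleles, tolerance = 1) {
  stopifnot(is.list(alleles), !is.null(names(alleles)))
  labs <- names(alleles)
  for (i in seq_along(alleles))
    if (any(alleles[[i]] <= 0)) usage_error("fragment sizes must be positive")
  if (length(alleles) > 1)
    for (i in seq_len(length(alleles) - 1))
      for (j in seq(i + 1, length(alleles)))
        if (!signatures_differ(alleles[[i]], alleles[[j]], tolerance))
          data_error(sprintf(
            "alleles '%s' and '%s' of marker %s are indistinguishable at %g bp tolerance",
            labs[i], labs[j], marker, tolerance))
  structure(list(marker = marker, alleles = alleles,
                 tolerance = tolerance),
            class = "marker_allele_table")
}

# TRUE when the two size multisets cannot be confused within the tolerance
signatures_differ <- function(a, b, tolerance) {
  a <- sort(a); b <- sort(b)
  if (length(a) != length(b)) return(TRUE)
  any(abs(a - b) > tolerance)
}

#' Predict INDEL marker allele sizes from deletions
#'
#' Each allele's product size is the reference amplicon size minus the sum
#' of the deletions it carries; allele labels are set to the resulting
#' size. Sizes that collide within the tolerance raise an ambiguity error.
#'
#' @param reference_amplicon_bp size of the deletion-free product (bp).
#' @param allele_deletions list, one element per allele, each a numeric
#'   vector of deletion lengths (bp); use \code{numeric(0)} for the
#'   deletion-free allele.
#' @param marker marker name for the resulting table.
#' @param tolerance sizing tolerance (bp) for the resulting table.
#' @return a [marker_allele_table] keyed by the predicted sizes.
#' @export
#' @examples
#' predict_indel_allele_sizes(280, list(c(30, 14), 30, numeric(0)))
predict_indel_allele_sizes <- function(reference_amplicon_bp, allele_deletions,
                                       marker = "INDEL", tolerance = 1) {
  sizes <- vapply(allele_deletions, function(d) {
    if (any(d < 0)) usage_error("deletion lengths must be non-negative")
    if (sum(d) >= reference_amplicon_bp)
      usage_error("deletions must total less than the reference amplicon")
    reference_amplicon_bp - sum(d)
  }, numeric(1))
  alleles <- stats::setNames(as.list(sizes), as.character(sizes))
  marker_allele_table(marker, alleles, tolerance)
}

#' Call a genotype from observed fragment sizes
#'
#' Matches every observed size to the expected allele signatures within
#' the table's tolerance. One matched allele (explaining all sizes) gives
#' a homozygous call \code{"X/X"}; two give \code{"X/Y"}. An observed size
#' explained by no allele is flagged as a novel allele labelled by its
#' measured size and enters the genotype as such. More than two distinct
#' alleles raise a ploidy error.
#'
#' @param observed_sizes numeric vector of scored band sizes (bp).
#' @param table a [marker_allele_table].
#' @return list with \code{genotype} (label string, alleles ordered by
#'   size), \code{alleles} (character vector, length 2), \code{novel}
#'   (character vector of novel-allele labels, possibly empty).
#' @export
call_fragment_genotype <- function(observed_sizes, table) {
  stopifnot(inherits(table, "marker_allele_table"))
  observed_sizes <- as.numeric(observed_sizes)
  if (length(observed_sizes) == 0 || any(observed_sizes <= 0))
    usage_error("observed sizes must be a non-empty positive vector")
  tol <- table$tolerance
  matched <- character(0)
  explained <- rep(FALSE, length(observed_sizes))
  for (lab in names(table$alleles)) {
    sig <- table$alleles[[lab]]
    hit <- vapply(sig, function(s) {
      d <- abs(observed_sizes - s)
      if (min(d) <= tol) which.min(d) else NA_integer_
    }, integer(1))
    if (!anyNA(hit)) {
      matched <- c(matched, lab)
      explained[hit] <- TRUE
    }
  }
  novel <- as.character(sort(unique(observed_sizes[!explained])))
  alleles <- c(matched, novel)
  if (length(alleles) > 2)
    data_error(sprintf("more than two alleles matched (%s): not diploid",
                       paste(alleles, collapse = ", ")))
  if (length(alleles) == 0)
    data_error("no allele matched the observed sizes")
  if (length(alleles) == 1) alleles <- rep(alleles, 2)
  # order by the leading size in the label (117_50 sorts by 117)
  key <- as.numeric(sub("_.*$", "", alleles))
  alleles <- alleles[order(key)]
  list(genotype = paste(alleles, collapse = "/"),
       alleles = alleles, novel = novel)
}

#' Classify an accession from its marker genotypes
#'
#' Under the recessive model an accession is predicted double-flowered iff
#' it is homozygous for the recessive allele at one or more of the
#' genotyped marker loci. The record names the explaining locus
#' (\code{"none"}, a marker name, or \code{"both"}) and lists loci where
#' the accession carries exactly one recessive copy (a carrier).
#'
#' @param genotypes named character vector, marker name -> genotype label
#'   \code{"X/Y"} as produced by [call_fragment_genotype()].
#' @param recessive_alleles named character vector, marker name -> label
#'   of its recessive (double-flower) allele.
#' @return list with \code{predicted_phenotype} (\code{"double"} or
#'   \code{"single"}), \code{locus}, \code{homozygous_at},
#'   \code{carrier_at}.
#' @export
classify_accession <- function(genotypes, recessive_alleles) {
  genotypes <- genotypes[!is.na(genotypes)]
  if (length(genotypes) == 0)
    usage_error("at least one marker genotype is required")
  markers <- intersect(names(genotypes), names(recessive_alleles))
  hom <- character(0)
  carrier <- character(0)
  for (m in markers) {
    al <- strsplit(genotypes[[m]], "/", fixed = TRUE)[[1]]
    n_rec <- sum(al == recessive_alleles[[m]])
    if (length(al) == 2 && n_rec == 2) hom <- c(hom, m)
    else if (n_rec == 1) carrier <- c(carrier, m)
  }
  list(predicted_phenotype = if (length(hom)) "double" else "single",
       locus = if (length(hom) == 0) "none"
               else if (length(hom) == 1) hom else "both",
       homozygous_at = hom,
       carrier_at = carrier)
}

#' Agreement between marker-predicted and recorded phenotypes
#'
#' @param predictions named character vector, sample -> predicted
#'   phenotype (\code{"double"}/\code{"single"}), or a data.frame with
#'   columns \code{sample} and \code{predicted_phenotype}.
#' @param phen a [phenotype_table] with the recorded phenotypes.
#' @return percentage of phenotyped samples whose prediction matches,
#'   full precision.
#' @export
marker_phenotype_agreement <- function(predictions, phen) {
  if (is.data.frame(predictions))
    predictions <- stats::setNames(predictions$predicted_phenotype,
                                   predictions$sample)
  common <- intersect(names(predictions),
                      phen$sample[phen$phenotype != "unknown"])
  if (length(common) == 0)
    data_error("no overlap between predictions and recorded phenotypes")
  obs <- phen_lookup(phen, common)
  100 * mean(predictions[common] == obs)
}
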