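#' Haldane map function
#'
#' Recombination fraction between two loci separated by \code{d_cm}
#' centimorgans under Haldane's no-interference model,
#' \eqn{r = (1 - e^{-2d/100})/2}, and its inverse.
#'
#' @param d_cm genetic distance in cM (non-negative).
#' @return recombination fraction in \eqn{[0, 0.5)}.
#' @export
haldane_r <- function(d_cm) {
  stopifnot(all(d_cm >= 0))
  (1 - exp(-2 * d_cm / 100)) / 2
}

#' @rdname haldane_r
#' @param r recombination fraction in \eqn{[0, 0.5)}.
#' @export
haldane_cm <- function(r) {
  stopifnot(all(r >= 0 & r < 0.5))
  -50 * log(1 - 2 * r)
}

#' Linkage map for the simulator
#'
#' @param chrom chromosome/pseudomolecule ID.
#' @param marker_id character vector of marker names.
#' @param cm genetic positions (cM), non-decreasing.
#' @param bp physical positions (bp), strictly increasing.
#' @param causal_cm genetic position of the causal locus (cM).
#' @return object of class \code{linkage_map}.
#' @export
linkage_map <- function(chrom, marker_id, cm, bp, causal_cm) {
  stopifnot(length(marker_id) == length(cm), length(cm) == length(bp))
  if (is.unsorted(cm)) usage_error("genetic positions must be non-decreasing")
  if (any(diff(bp) <= 0)) usage_error("physical positions must be strictly increasing")
  structure(list(chrom = chrom,
                 markers = data.frame(marker_id = as.character(marker_id),
                                      cm = as.numeric(cm),
                                      bp = as.integer(bp),
                                      stringsAsFactors = FALSE),
                 causal_cm = as.numeric(causal_cm)),
            class = "linkage_map")
}

#' Default linkage map
#'
#' A single-chromosome map emulating the physical neighbourhood of a
#' recessive double-flower locus: nine SNP markers spanning roughly
#' 33.7--43.9 Mb, a cluster of them fully linked to the causal locus and
#' flanking markers a few cM away.
#'
#' @return a [linkage_map].
#' @export
default_linkage_map <- function() {
  linkage_map(
    chrom = "CHR17",
    marker_id = sprintf("M%02d", 1:9),
    cm = c(0.0, 1.0, 1.0, 1.5, 2.0, 2.0, 8.0, 9.0, 9.2),
    bp = c(33708714L, 34478996L, 34485554L, 35213652L, 35610977L,
           35611011L, 43626384L, 43855890L, 43855965L),
    causal_cm = 1.0)
}

#' Simulation configuration
#'
#' Study-like defaults: an F2 of 147 offspring (the size of a typical
#' double-flower mapping population), markers on [default_linkage_map()],
#' overdispersed ddRAD-like read depth (negative binomial, mean 20,
#' dispersion 5), a small flat genotyping error (0.5%) and 3% per-call
#' missingness.
#'
#' @param design \code{"F2"} or \code{"F1_carrier_cross"}.
#' @param n_offspring number of offspring (>= 1).
#' @param map a [linkage_map].
#' @param mean_depth mean of the per-call read-depth distribution.
#' @param depth_dispersion negative-binomial \code{size} parameter
#'   (smaller = more overdispersed).
#' @param error_rate per-genotype flat error rate in \eqn{[0,1]}: with this
#'   probability a call is replaced by one of the two other states.
#' @param missing_rate per-call (site-driven) missingness probability.
#' @param sample_missing_rate additional per-sample missingness
#'   probability (sample-driven dropout).
#' @param seed integer random seed; a fixed seed gives byte-identical
#'   output.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(design = c("F2", "F1_carrier_cross"),
                       n_offspring = 147,
                       map = default_linkage_map(),
                       mean_depth = 20, depth_dispersion = 5,
                       error_rate = 0.005, missing_rate = 0.03,
                       sample_missing_rate = 0, seed = 1) {
  design <- match.arg(design)
  if (n_offspring < 1) usage_error("n_offspring must be >= 1")
  for (r in c(error_rate, missing_rate, sample_missing_rate))
    if (r < 0 || r > 1) usage_error("rates must lie in [0, 1]")
  stopifnot(inherits(map, "linkage_map"), mean_depth >= 0,
            depth_dispersion > 0)
  structure(list(design = design, n_offspring = as.integer(n_offspring),
                 map = map, mean_depth = mean_depth,
                 depth_dispersion = depth_dispersion,
                 error_rate = error_rate, missing_rate = missing_rate,
                 sample_missing_rate = sample_missing_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Sample one gamete from a diplotype
#'
#' Meiosis under Haldane's model: the starting haplotype is chosen at
#' random and a crossover occurs independently in each inter-locus
#' interval with probability \code{haldane_r(diff(cm))}.
#'
#' @param diplotype 2 x L matrix; rows are the two parental haplotypes,
#'   columns loci in map order.
#' @param cm genetic positions (cM) of the L loci, non-decreasing.
#' @return length-L vector: the transmitted haplotype.
#' @export
sample_gamete <- function(diplotype, cm) {
  stopifnot(is.matrix(diplotype), nrow(diplotype) == 2,
            ncol(diplotype) == length(cm))
  L <- length(cm)
  hap <- integer(L)
  cur <- sample.int(2L, 1L)
  hap[1] <- diplotype[cur, 1]
  if (L > 1) {
    r <- haldane_r(diff(cm))
    xo <- stats::runif(L - 1) < r
    for (i in 2:L) {
      if (xo[i - 1]) cur <- 3L - cur
      hap[i] <- diplotype[cur, i]
    }
  }
  hap
}

#' Expected scan agreement at a marker (F2, analytic)
#'
#' For an F2 and a marker at recombination fraction \code{r} from the
#' causal locus, enumerating the four F1 gamete types (parental
#' marker-allele/causal-allele combinations at frequency \eqn{(1-r)/2}
#' each, recombinants at \eqn{r/2}) over all 16 gamete pairings gives the
#' expected degree of agreement \eqn{50 + 50(1-r)^2} percent. Fully linked
#' markers agree 100%; unlinked markers (\eqn{r = 0.5}) still agree 62.5%.
#'
#' @param r recombination fraction in \eqn{[0, 0.5]}.
#' @return expected agreement percentage.
#' @export
expected_agreement <- function(r) {
  if (any(r < 0 | r > 0.5)) usage_error("r must lie in [0, 0.5]")
  50 + 50 * (1 - r)^2
}

#' Simulate a biparental population
#'
#' Generates parents and offspring under the configured cross design with
#' one fully penetrant recessive causal locus: the double-flower parent is
#' homozygous for the alternate allele at every marker and for the
#' recessive causal allele (coupling phase), so in the emitted calls the
#' double-parent allele is always \code{alt}. Offspring gametes are drawn
#' by [sample_gamete()] over markers plus causal locus; phenotype is
#' double iff the causal genotype is homozygous recessive. Observed calls
#' add a flat genotyping error, negative-binomial read depths and
#' missingness per [sim_config()]. Calls below any depth threshold are
#' still emitted — filtering is downstream's job. Parent rows are emitted
#' noise-free (parents are assumed phenotyped and re-genotyped cleanly).
#'
#' @param config a [sim_config].
#' @return list with \code{genotypes} (a [genotype_matrix]; samples are
#'   \code{P_double}, \code{P_single}, then offspring), \code{phenotypes}
#'   (a [phenotype_table]), and \code{truth} (data.frame of true marker
#'   and causal genotypes and the true phenotype per offspring).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  mk <- config$map$markers
  L <- nrow(mk)
  # loci = markers + causal, in cM order (causal inserted at its position)
  cm_all <- c(mk$cm, config$map$causal_cm)
  ord <- order(cm_all, method = "radix")
  causal_slot <- which(ord == L + 1L)
  cm_sorted <- cm_all[ord]
  n <- config$n_offspring
  # haplotype coding: 1 = double-parent (alt / recessive), 0 = single-parent
  hap_dbl <- rep(1L, L + 1L)
  hap_sgl <- rep(0L, L + 1L)
  if (config$design == "F2") {
    par1 <- rbind(hap_dbl, hap_dbl)   # double parent, emitted
    par2 <- rbind(hap_sgl, hap_sgl)   # single parent, emitted
    gam_a_src <- rbind(hap_dbl, hap_sgl)  # F1 x F1
    gam_b_src <- gam_a_src
  } else {
    par1 <- rbind(hap_dbl, hap_dbl)       # double parent (recessive hom)
    par2 <- rbind(hap_dbl, hap_sgl)       # carrier parent (het)
    gam_a_src <- par1
    gam_b_src <- par2
  }
  true_geno <- matrix(0L, n, L + 1L)  # alt dosage in sorted locus order
  for (j in seq_len(n))
    true_geno[j, ] <- sample_gamete(gam_a_src[, ord, drop = FALSE], cm_sorted) +
      sample_gamete(gam_b_src[, ord, drop = FALSE], cm_sorted)
  causal_g <- true_geno[, causal_slot]
  phen_off <- ifelse(causal_g == 2L, "double", "single")
  # back to marker (map) order
  marker_cols <- match(seq_len(L), ord)
  true_mk <- true_geno[, marker_cols, drop = FALSE]
  samples <- c("P_double", "P_single", sprintf("O%03d", seq_len(n)))
  # observed calls: sites x samples
  geno <- matrix(NA_integer_, L, n + 2L)
  geno[, 1] <- par1[1, seq_len(L)] + par1[2, seq_len(L)]
  geno[, 2] <- par2[1, seq_len(L)] + par2[2, seq_len(L)]
  obs <- t(true_mk)
  if (config$error_rate > 0) {
    flip <- matrix(stats::runif(length(obs)) < config$error_rate, L, n)
    shift <- matrix(sample.int(2L, length(obs), replace = TRUE), L, n)
    obs[flip] <- (obs[flip] + shift[flip]) %% 3L
  }
  miss <- matrix(stats::runif(L * n) < config$missing_rate, L, n)
  if (config$sample_missing_rate > 0)
    miss <- miss | matrix(rep(stats::runif(n) < config$sample_missing_rate,
                              each = L), L, n)
  obs[miss] <- NA_integer_
  geno[, 3:(n + 2L)] <- obs
  depth <- matrix(stats::rnbinom(L * (n + 2L), mu = config$mean_depth,
                                 size = config$depth_dispersion),
                  L, n + 2L)
  depth[, 1:2] <- pmax(depth[, 1:2, drop = FALSE], 5L)  # clean parents
  # ref/alt nucleotides per marker, seeded hence reproducible
  nucs <- c("A", "C", "G", "T")
  ref <- sample(nucs, L, replace = TRUE)
  alt <- vapply(ref, function(x) sample(setdiff(nucs, x), 1), character(1))
  qual <- round(stats::runif(L, 30, 999))
  sites <- data.frame(id = mk$marker_id, chrom = config$map$chrom,
                      pos = mk$bp, ref = ref, alt = unname(alt),
                      qual = qual, stringsAsFactors = FALSE)
  gm <- genotype_matrix(sites, samples, geno, depth)
  phen <- phenotype_table(samples,
                          c("double",
                            if (config$design == "F2") "single" else "single",
                            phen_off))
  truth <- data.frame(sample = samples[-(1:2)], true_mk,
                      causal = causal_g, phenotype = phen_off,
                      stringsAsFactors = FALSE)
  names(truth)[2:(L + 1)] <- mk$marker_id
  list(genotypes = gm, phenotypes = phen, truth = truth)
}

#' Build a deterministic population from per-site class-count rows
#'
#' Constructs a genotype matrix and phenotype table whose per-site
#' genotype-class x phenotype contingency exactly matches the given rows,
#' for replaying published marker-trait count tables through the scan.
#' Individuals are assigned greedily in a fixed order; where a site's
#' class totals fall short of the population size the remaining calls are
#' missing. Parents \code{P_double} / \code{P_single} are appended,
#' homozygous alt / ref respectively (the double-parent allele is
#' \code{alt}).
#'
#' @param rows data.frame with columns \code{id}, \code{chrom}, \code{pos}
#'   (\code{NA} allowed), \code{allele_double}, \code{allele_single},
#'   \code{d_hom_double}, \code{n_hom_double}, \code{d_het}, \code{n_het},
#'   \code{d_hom_single}, \code{n_hom_single}.
#' @param n population size (offspring); default is the smallest size
#'   consistent with the rows.
#' @return list with \code{genotypes} and \code{phenotypes}, ready for
#'   [coseg_scan()] with \code{cross_model("P_double", "P_single")}.
#' @export
table_fixture <- function(rows, n = NULL) {
  need <- c("id", "chrom", "pos", "allele_double", "allele_single",
            "d_hom_double", "n_hom_double", "d_het", "n_het",
            "d_hom_single", "n_hom_single")
  if (!all(need %in% names(rows)))
    usage_error(paste("rows must have columns:", paste(need, collapse = ", ")))
  n_dbl_needed <- with(rows, d_hom_double + d_het + d_hom_single)
  n_sgl_needed <- with(rows, (n_hom_double - d_hom_double) +
                         (n_het - d_het) + (n_hom_single - d_hom_single))
  n_dbl <- max(n_dbl_needed)
  n_sgl <- max(n_sgl_needed)
  if (is.null(n)) n <- n_dbl + n_sgl
  if (n < n_dbl + n_sgl)
    data_error("class totals exceed the requested population size")
  ids <- c(sprintf("D%03d", seq_len(n_dbl)), sprintf("S%03d", seq_len(n_sgl)),
           if (n > n_dbl + n_sgl) sprintf("U%03d", seq_len(n - n_dbl - n_sgl)))
  phen_v <- c(rep("double", n_dbl), rep("single", n_sgl),
              rep("unknown", n - n_dbl - n_sgl))
  L <- nrow(rows)
  geno <- matrix(NA_integer_, L, n)
  for (i in seq_len(L)) {
    r <- rows[i, ]
    # doubles: hom_double first, then het, then hom_single, rest missing
    gd <- rep(NA_integer_, n_dbl)
    gd[seq_len(r$d_hom_double)] <- 2L
    if (r$d_het > 0) gd[r$d_hom_double + seq_len(r$d_het)] <- 1L
    if (r$d_hom_single > 0)
      gd[r$d_hom_double + r$d_het + seq_len(r$d_hom_single)] <- 0L
    s1 <- r$n_hom_double - r$d_hom_double
    s2 <- r$n_het - r$d_het
    s3 <- r$n_hom_single - r$d_hom_single
    gs <- rep(NA_integer_, n_sgl)
    if (s1 > 0) gs[seq_len(s1)] <- 2L
    if (s2 > 0) gs[s1 + seq_len(s2)] <- 1L
    if (s3 > 0) gs[s1 + s2 + seq_len(s3)] <- 0L
    geno[i, ] <- c(gd, gs, rep(NA_integer_, n - n_dbl - n_sgl))
  }
  samples <- c(ids, "P_double", "P_single")
  geno <- cbind(geno, rep(2L, L), rep(0L, L))
  depth <- matrix(99L, L, n + 2L)
  depth[is.na(geno)] <- 0L
  sites <- data.frame(id = rows$id, chrom = rows$chrom, pos = rows$pos,
                      ref = rows$allele_single, alt = rows$allele_double,
                      qual = 999, stringsAsFactors = FALSE)
  gm <- genotype_matrix(sites, samples, geno, depth)
  phen <- phenotype_table(samples, c(phen_v, "double", "single"))
  list(genotypes = gm, phenotypes = phen)
}
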