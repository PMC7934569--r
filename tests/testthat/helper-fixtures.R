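# small hand-built genotype matrices and sequences used across tests

make_sites <- function(n, chrom = "CHR1") {
  data.frame(id = sprintf("s%02d", seq_len(n)), chrom = chrom,
             pos = seq_len(n) * 100L,
             ref = rep(c("A", "C", "G", "T"), length.out = n),
             alt = rep(c("G", "T", "A", "C"), length.out = n),
             qual = 999, stringsAsFactors = FALSE)
}

make_gm <- function(geno, depth = NULL, qual = NULL, chrom = "CHR1") {
  geno <- as.matrix(geno)
  if (is.null(depth)) depth <- matrix(10L, nrow(geno), ncol(geno))
  sites <- make_sites(nrow(geno), chrom)
  if (!is.null(qual)) sites$qual <- qual
  genotype_matrix(sites, sprintf("i%02d", seq_len(ncol(geno))), geno, depth)
}

# F2 family fixture: double parent alt-hom, single parent ref-hom, offspring
# genotypes supplied as rows (sites) x columns (offspring)
make_family <- function(off_geno, off_phen) {
  off_geno <- as.matrix(off_geno)
  n <- ncol(off_geno)
  geno <- cbind(rep(2L, nrow(off_geno)), rep(0L, nrow(off_geno)), off_geno)
  gm <- make_gm(geno)
  gm$samples <- c("P_double", "P_single", sprintf("o%02d", seq_len(n)))
  colnames(gm$geno) <- colnames(gm$depth) <- gm$samples
  phen <- phenotype_table(gm$samples, c("double", "single", off_phen))
  list(gm = gm, phen = phen,
       model = cross_model("P_double", "P_single"))
}

# a 167 bp amplicon pair: the double allele carries a single TaqI site cut
# after position 117; the single allele destroys it by a C->A change
make_caps_pair <- function() {
  left <- paste(rep(c("A", "C"), 58), collapse = "")           # 116 bp
  right <- paste(rep(c("A", "C"), length.out = 47), collapse = "")
  seq_double <- paste0(left, "TCGA", right)                    # 167 bp
  seq_single <- sub("TCGA", "TAGA", seq_double, fixed = TRUE)
  list(double = amplicon_allele("117_50", seq_double),
       single = amplicon_allele("167", seq_single))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# brute-force oracle: expected F2 scan agreement at recombination fraction r,
# by enumeration of the 16 gamete pairings (marker allele, causal allele)
enumerate_f2_agreement <- function(r) {
  gam <- data.frame(m = c(1, 0, 1, 0), c = c(1, 0, 0, 1),
                    p = c((1 - r) / 2, (1 - r) / 2, r / 2, r / 2))
  agree <- 0
  for (i in 1:4) for (j in 1:4) {
    m <- gam$m[i] + gam$m[j]
    ca <- gam$c[i] + gam$c[j]
    is_double <- ca == 2
    predicted_double <- m == 2
    if (is_double == predicted_double) agree <- agree + gam$p[i] * gam$p[j]
  }
  100 * agree
}
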