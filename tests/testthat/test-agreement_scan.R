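test_that("allele orientation follows the parent genotypes", {
  # site rows: parents (dbl, sgl) = (C/C hom alt vs A/A hom ref), identical
  # homozygotes, het double parent, missing parent
  sites <- make_sites(4)
  sites$ref <- c("A", "A", "A", "A"); sites$alt <- c("C", "C", "G", "G")
  geno <- rbind(c(2L, 0L, 1L), c(0L, 0L, 1L), c(1L, 0L, 2L), c(NA, 0L, 2L))
  gm <- genotype_matrix(sites, c("Pd", "Ps", "o1"), geno,
                        matrix(10L, 4, 3))
  ori <- orient_alleles(gm, cross_model("Pd", "Ps"))
  expect_equal(ori$informative, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(ori$double_allele[1], "C")
  expect_equal(ori$single_allele[1], "A")
  expect_error(orient_alleles(gm, cross_model("absent", "Ps")),
               class = "cosegscan_usage_error")
})

test_that("carrier-cross orientation needs hom double parent x het parent", {
  sites <- make_sites(2)
  geno <- rbind(c(2L, 1L, 1L), c(2L, 0L, 1L))
  gm <- genotype_matrix(sites, c("Pd", "Pc", "o1"), geno, matrix(9L, 2, 3))
  ori <- orient_alleles(gm, cross_model("Pd", "Pc", "F1_carrier_cross"))
  expect_equal(ori$informative, c(TRUE, FALSE))
  expect_equal(ori$double_allele[1], sites$alt[1])
})

test_that("agreement statistic reproduces the published class-count examples", {
  cases <- list(
    list(c(36, 37), c(1, 60), c(1, 49), 143 / 146 * 100, 97.9),
    list(c(22, 22), c(0, 51), c(1, 20), 92 / 93 * 100, 98.9),
    list(c(22, 25), c(0, 44), c(1, 24), 89 / 93 * 100, 95.7),
    list(c(37, 37), c(0, 61), c(0, 47), 100, 100))
  for (cs in cases) {
    a <- score_agreement(class_counts(cs[[1]], cs[[2]], cs[[3]]))
    expect_equal(a, cs[[4]])
    expect_equal(round_half_up(a, 1), cs[[5]])
  }
  # all classes fully agreeing, no doubles at all -> 100
  expect_equal(score_agreement(class_counts(c(0, 0), c(0, 5), c(0, 5))), 100)
  expect_error(score_agreement(class_counts(c(0, 0), c(0, 0), c(0, 0))),
               class = "cosegscan_data_error")
})

test_that("agreement is 100 iff every individual fits, and adding a
           disagreeing individual never increases it", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(3:40, 3, replace = TRUE)
    d <- c(sample(0:n[1], 1), sample(0:n[2], 1), sample(0:n[3], 1))
    cc <- class_counts(c(d[1], n[1]), c(d[2], n[2]), c(d[3], n[3]))
    a <- score_agreement(cc)
    expect_gte(a, 0); expect_lte(a, 100)
    fits_all <- d[1] == n[1] && d[2] == 0 && d[3] == 0
    expect_equal(a == 100, fits_all)
    # one extra disagreeing individual in each class
    worse <- list(class_counts(c(d[1], n[1] + 1), c(d[2], n[2]), c(d[3], n[3])),
                  class_counts(c(d[1], n[1]), c(d[2] + 1, n[2] + 1), c(d[3], n[3])),
                  class_counts(c(d[1], n[1]), c(d[2], n[2]), c(d[3] + 1, n[3] + 1)))
    for (w in worse) expect_lte(score_agreement(w), a)
    # swapping het and hom_single classes leaves the statistic unchanged
    swapped <- class_counts(c(d[1], n[1]), c(d[3], n[3]), c(d[2], n[2]))
    expect_equal(score_agreement(swapped), a)
  }
})

test_that("scan reproduces both published count tables exactly", {
  for (tab in list(djo_marker_counts(), dsu_marker_counts())) {
    fx <- table_fixture(tab)
    fit <- coseg_scan(fx$genotypes, fx$phenotypes,
                      cross_model("P_double", "P_single"))
    res <- as.data.frame(fit)
    expect_equal(nrow(res), nrow(tab))
    m <- match(tab$id, res$id)
    expect_false(anyNA(m))
    for (col in c("d_hom_double", "n_hom_double", "d_het", "n_het",
                  "d_hom_single", "n_hom_single"))
      expect_equal(res[[col]][m], tab[[col]], info = col)
    # recomputed agreement matches the statistic applied to the printed counts
    expect_equal(res$agreement[m],
                 with(tab, 100 * (d_hom_double + (n_het - d_het) +
                                    (n_hom_single - d_hom_single)) /
                        (n_hom_double + n_het + n_hom_single)))
    expect_equal(res$double_allele[m], tab$allele_double)
  }
})

test_that("scan orders by agreement then chromosome and position, and
           excludes parents and unknown phenotypes", {
  fam <- make_family(rbind(c(2L, 2L, 1L, 0L),
                           c(2L, 1L, 1L, 0L)),
                     c("double", "double", "single", "unknown"))
  fit <- coseg_scan(fam$gm, fam$phen, fam$model)
  res <- as.data.frame(fit)
  # site 1: doubles o1,o2 hom_double; o3 het single; o4 unknown excluded
  expect_equal(res$n_hom_double[res$id == "s01"], 2)
  expect_equal(res$n_het[res$id == "s01"], 1)
  expect_equal(res$n_hom_single[res$id == "s01"], 0)
  expect_equal(res$agreement[res$id == "s01"], 100)
  # site 2: o2 is double but het -> one disagreement out of 3
  expect_equal(res$agreement[res$id == "s02"], 100 * 2 / 3)
  expect_equal(res$id, c("s01", "s02"))  # descending agreement
})

test_that("threshold report uses strict unrounded comparison", {
  fx <- table_fixture(djo_marker_counts())
  fit <- coseg_scan(fx$genotypes, fx$phenotypes,
                    cross_model("P_double", "P_single"))
  rep95 <- threshold_report(fit, 95)
  expect_equal(nrow(rep95$above), 9)
  expect_equal(nrow(rep95$cosegregating), 6)
  rep100 <- threshold_report(fit, 100)
  expect_equal(nrow(rep100$above), 0)            # strictly greater
  expect_equal(nrow(rep100$cosegregating), 6)
  # d_su table: five above 95, none co-segregating
  fx2 <- table_fixture(dsu_marker_counts())
  fit2 <- coseg_scan(fx2$genotypes, fx2$phenotypes,
                     cross_model("P_double", "P_single"))
  rep2 <- threshold_report(fit2, 95)
  expect_equal(nrow(rep2$above), 5)
  expect_equal(nrow(rep2$cosegregating), 0)
})

test_that("distinct scaffolds are counted from site-ID prefixes", {
  ids <- c("0577F_1204837", "3145F_55089", "3145F_55109", "3145F_55446",
           "0109F_868569")
  sc <- distinct_scaffolds(ids)
  expect_equal(sc$n, 3)
  expect_equal(sc$scaffolds, c("0577F", "3145F", "0109F"))
  expect_equal(distinct_scaffolds("0008F-2_3250598")$n, 1)
  expect_equal(distinct_scaffolds(character(0))$n, 0)
})

test_that("locus interval spans the co-segregating SNPs with truncated Mb", {
  fx <- table_fixture(djo_marker_counts())
  fit <- coseg_scan(fx$genotypes, fx$phenotypes,
                    cross_model("P_double", "P_single"))
  iv <- infer_locus_interval(threshold_report(fit)$cosegregating)
  expect_equal(iv$chrom, "CHR17")
  expect_equal(iv$start_bp, 33708714)
  expect_equal(iv$end_bp, 43855965)
  expect_equal(iv$start_mb, 33.7)   # truncation, not rounding
  expect_equal(iv$end_mb, 43.8)
  # single SNP: zero-width interval
  one <- data.frame(chrom = "CHR04", pos = 57436162)
  iv1 <- infer_locus_interval(one)
  expect_equal(iv1$start_bp, iv1$end_bp)
  # unplaced sites are excluded; multiple chromosomes warn
  two <- data.frame(chrom = c("CHR04", NA, "CHR17"),
                    pos = c(100L, NA, 200L))
  expect_warning(iv2 <- infer_locus_interval(two), "multiple chromosomes")
  expect_equal(nrow(iv2), 2)
})

test_that("coseg_scan S3 surface: coef, summary, print", {
  fx <- table_fixture(djo_marker_counts())
  fit <- coseg_scan(fx$genotypes, fx$phenotypes,
                    cross_model("P_double", "P_single"))
  expect_named(coef(fit)[1:6])
  expect_true(all(coef(fit) >= 0 & coef(fit) <= 100))
  s <- summary(fit)
  expect_s3_class(s, "summary.coseg_scan")
  expect_equal(s$interval$start_mb, 33.7)
  expect_output(print(fit), "9 informative SNPs")
  expect_output(print(s), "co-segregating")
})
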