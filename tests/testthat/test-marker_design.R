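taqi <- restriction_enzyme("TaqI", "TCGA", 1)

test_that("recognition-site matching reports every cut, including overlaps", {
  expect_equal(find_sites("AATCGAAA", taqi), 3L)       # T^CGA after pos 3
  expect_equal(find_sites("GGGGGGGG", taqi), integer(0))
  expect_equal(find_sites("TCGATCGA", taqi), c(1L, 5L))
  # IUPAC ambiguity in the pattern: DdeI CTNAG
  ddei <- restriction_enzyme("DdeI", "CTNAG", 1)
  expect_equal(find_sites("AACTGAGAA", ddei), 3L)
  expect_equal(find_sites("AACTTAGAA", ddei), 3L)
  expect_error(find_sites("ACGX", taqi), class = "cosegscan_usage_error")
  expect_error(restriction_enzyme("bad", "TCGA", 9),
               class = "cosegscan_usage_error")
})

test_that("digest turns the 167 bp CAPS amplicon into 117 + 50", {
  pair <- make_caps_pair()
  dd <- digest(pair$double, taqi)
  expect_equal(dd$cut_positions, 117L)
  expect_equal(dd$fragment_lengths, c(117L, 50L))
  ds <- digest(pair$single, taqi)
  expect_equal(ds$fragment_lengths, 167L)              # undigested allele
})

test_that("digest conserves total length on random sequences and enzymes", {
  set.seed(31)
  enzymes <- load_enzymes()
  for (i in 1:40) {
    s <- random_dna(sample(20:400, 1))
    enz <- enzymes[[sample(length(enzymes), 1)]]
    d <- digest(s, enz)
    expect_equal(sum(d$fragment_lengths), nchar(s))
    expect_equal(length(d$fragment_lengths), length(d$cut_positions) + 1)
  }
})

test_that("CAPS screening reports only discriminating enzymes, symmetrically", {
  pair <- make_caps_pair()
  enzymes <- load_enzymes()
  hits <- caps_screen(pair$double, pair$single, enzymes)
  hit_names <- vapply(hits, function(h) h$enzyme$name, character(1))
  expect_true("TaqI" %in% hit_names)
  tq <- hits[[which(hit_names == "TaqI")]]
  expect_equal(tq$digest_a$fragment_lengths, c(117L, 50L))
  expect_equal(tq$digest_b$fragment_lengths, 167L)
  # identical alleles: no hits for any enzyme
  expect_length(caps_screen(pair$double, pair$double, enzymes), 0)
  # swapping alleles swaps patterns but not the hit set
  rev_hits <- caps_screen(pair$single, pair$double, enzymes)
  expect_equal(sort(vapply(rev_hits, function(h) h$enzyme$name, character(1))),
               sort(hit_names))
  rtq <- rev_hits[[which(vapply(rev_hits, function(h) h$enzyme$name,
                                character(1)) == "TaqI")]]
  expect_equal(rtq$digest_a$fragment_lengths, tq$digest_b$fragment_lengths)
  expect_equal(rtq$digest_b$fragment_lengths, tq$digest_a$fragment_lengths)
})

test_that("INDEL allele sizes derive from the reference minus deletions", {
  tab <- predict_indel_allele_sizes(280, list(c(30, 14), 30, numeric(0)),
                                    marker = "S01")
  expect_setequal(names(tab$alleles), c("236", "250", "280"))
  expect_equal(tab$alleles[["236"]], 236)
  expect_equal(tab$alleles[["280"]], 280)
  # collision within tolerance is an ambiguity error
  expect_error(predict_indel_allele_sizes(280, list(10, 11), tolerance = 1),
               class = "cosegscan_data_error")
  expect_error(predict_indel_allele_sizes(100, list(100)),
               class = "cosegscan_usage_error")
})

test_that("fragment genotype calls match the published accession patterns", {
  s01 <- s01_marker_table()
  expect_equal(call_fragment_genotype(236, s01)$genotype, "236/236")
  expect_equal(call_fragment_genotype(c(250, 280), s01)$genotype, "250/280")
  novel <- call_fragment_genotype(282, s01)
  expect_equal(novel$genotype, "282/282")
  expect_equal(novel$novel, "282")
  j01 <- j01_marker_table()
  expect_equal(call_fragment_genotype(c(117, 50), j01)$genotype,
               "117_50/117_50")
  expect_equal(call_fragment_genotype(c(50, 117, 167), j01)$genotype,
               "117_50/167")
  expect_error(call_fragment_genotype(c(236, 250, 280), s01),
               class = "cosegscan_data_error")   # three alleles: not diploid
})

test_that("size jitter below the tolerance does not change the call", {
  s01 <- s01_marker_table()
  set.seed(5)
  for (true in list(c(236), c(250), c(280), c(236, 250), c(250, 280),
                    c(236, 280))) {
    lab <- paste(sort(true), collapse = "/")
    if (length(true) == 1) lab <- paste(true, true, sep = "/")
    obs <- true + stats::runif(length(true), -0.9, 0.9)
    expect_equal(call_fragment_genotype(obs, s01)$genotype, lab)
  }
})

test_that("accession classification reproduces every recorded accession phenotype", {
  acc <- accession_marker_genotypes()
  rec <- double_flower_recessive_alleles()
  tables <- list(J01 = j01_marker_table(), S01 = s01_marker_table())
  n_j01_hom <- 0; n_s01_hom <- 0
  predictions <- character(nrow(acc))
  for (i in seq_len(nrow(acc))) {
    geno <- character(0)
    for (m in names(tables)) {
      call <- call_fragment_genotype(expand_genotype_sizes(acc[[m]][i]),
                                     tables[[m]])
      expect_equal(call$genotype, acc[[m]][i])  # re-called from band sizes
      geno[m] <- call$genotype
    }
    cls <- classify_accession(geno, rec)
    predictions[i] <- cls$predicted_phenotype
    if (cls$predicted_phenotype == "double") {
      if ("J01" %in% cls$homozygous_at) n_j01_hom <- n_j01_hom + 1
      if ("S01" %in% cls$homozygous_at) n_s01_hom <- n_s01_hom + 1
    }
  }
  expect_equal(predictions, acc$phenotype)
  expect_equal(n_j01_hom, 10)   # doubles homozygous 117_50 at J01
  expect_equal(n_s01_hom, 4)    # doubles homozygous 236 at S01
  phen <- phenotype_table(acc$accession, acc$phenotype)
  expect_equal(marker_phenotype_agreement(
    stats::setNames(predictions, acc$accession), phen), 100)
})

test_that("carrier accessions are flagged without a double prediction", {
  cls <- classify_accession(c(J01 = "117_50/167", S01 = "280/280"),
                            double_flower_recessive_alleles())
  expect_equal(cls$predicted_phenotype, "single")
  expect_equal(cls$locus, "none")
  expect_equal(cls$carrier_at, "J01")
  both <- classify_accession(c(J01 = "117_50/117_50", S01 = "236/236"),
                             double_flower_recessive_alleles())
  expect_equal(both$locus, "both")
})

test_that("prediction-phenotype agreement handles mismatches and no overlap", {
  phen <- phenotype_table(sprintf("a%02d", 1:98),
                          rep(c("double", "single"), 49))
  pred <- stats::setNames(rep(c("double", "single"), 49),
                          sprintf("a%02d", 1:98))
  expect_equal(marker_phenotype_agreement(pred, phen), 100)
  pred[1] <- "single"  # one mismatch in 98
  expect_equal(round_half_up(marker_phenotype_agreement(pred, phen), 1), 99.0)
  expect_error(marker_phenotype_agreement(c(zz = "double"), phen),
               class = "cosegscan_data_error")
})
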