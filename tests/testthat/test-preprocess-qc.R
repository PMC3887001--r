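test_that("presence/absence encoding maps the three classes correctly", {
  panel <- random_panel(6, 8, 31, missing_rate = 0.2)
  enc <- encode_presence(panel)
  expect_equal(ncol(enc$values), 2L * n_snps(panel))
  for (i in seq_len(6)) {
    for (j in seq_len(8)) {
      cell <- panel$calls[i, j]
      got <- enc$values[i, c(2L * j - 1L, 2L * j)]
      want <- switch(ifelse(is.na(cell), "NA", cell),
                     AA = c(1, 0), AB = c(1, 1), BB = c(0, 1),
                     "NA" = c(NA_real_, NA_real_))
      expect_equal(unname(got), want)
    }
  }
  # per-SNP block row sums are 1 (hom) or 2 (het) when called
  blocks <- enc$values[, seq(1, 15, by = 2)] + enc$values[, seq(2, 16, by = 2)]
  called <- !is.na(panel$calls)
  expect_true(all(blocks[called] %in% c(1, 2)))
})

test_that("mean imputation fills missing entries and preserves column means", {
  calls <- matrix(c("AA", "AA", NA, "AA", "BB", NA), 3, 2,
                  dimnames = list(NULL, NULL))
  panel <- genotype_panel(calls,
                          data.frame(sample_id = c("a", "b", "c"),
                                     ploidy = 2L, population = "p"),
                          data.frame(snp_id = c("m1", "m2"), chrom = "chr1",
                                     pos = c(1L, 2L), allele_a = "A",
                                     allele_b = "G"))
  enc <- impute_mean(encode_presence(panel))
  expect_equal(unname(enc$values[3, 1:2]), c(1, 0))    # constant column
  expect_equal(unname(enc$values[3, 3:4]), c(0.5, 0.5)) # (1,0,NA) -> 0.5

  panel2 <- random_panel(20, 15, 32, missing_rate = 0.25)
  e0 <- encode_presence(panel2)
  e1 <- impute_mean(e0)
  expect_false(anyNA(e1$values))
  expect_equal(colMeans(e1$values), colMeans(e0$values, na.rm = TRUE))
  obs <- !is.na(e0$values)
  expect_identical(e1$values[obs], e0$values[obs])
})

test_that("imputation errors on an all-missing marker, naming it", {
  calls <- matrix(c("AA", "AB", NA, NA), 2, 2)
  panel <- genotype_panel(calls,
                          data.frame(sample_id = c("a", "b"), ploidy = 2L,
                                     population = "p"),
                          data.frame(snp_id = c("good", "bad"), chrom = "chr1",
                                     pos = c(1L, 2L), allele_a = "A",
                                     allele_b = "G"))
  expect_error(impute_mean(encode_presence(panel)), "bad")
})

test_that("allele frequencies follow diploid-equivalent counting", {
  panel <- toy_panel()
  ft <- allele_freqs(panel, rep("all", 6))
  # brute-force recount, independent of the implementation
  for (j in seq_len(10)) {
    col <- panel$calls[, j]
    col <- col[!is.na(col)]
    want <- (2 * sum(col == "AA") + sum(col == "AB")) / (2 * length(col))
    expect_equal(unname(ft$freq_a[1, j]), want)
  }
  # trivial cases
  ft2 <- allele_freqs(
    genotype_panel(matrix(c("AA", "AA", "AB", "BB", "AA", "AB", "BB", "AB"),
                          4, 2),
                   data.frame(sample_id = paste0("s", 1:4), ploidy = 2L,
                              population = "p"),
                   data.frame(snp_id = c("m1", "m2"), chrom = "chr1",
                              pos = 1:2, allele_a = "A", allele_b = "G")),
    rep("g", 4))
  expect_equal(unname(ft2$freq_a[1, ]), c(0.625, 0.5))
})

test_that("a group with no called samples at a locus yields a flagged NA", {
  calls <- matrix(c(NA, "AB", NA, "AA"), 2, 2)
  panel <- genotype_panel(calls,
                          data.frame(sample_id = c("a", "b"), ploidy = 2L,
                                     population = c("x", "y")),
                          data.frame(snp_id = c("m1", "m2"), chrom = "chr1",
                                     pos = 1:2, allele_a = "A", allele_b = "G"))
  ft <- allele_freqs(panel)
  expect_true(is.na(ft$freq_a["x", "m1"]))
  expect_equal(ft$n_called["x", "m1"], 0L)
  expect_false(is.na(ft$freq_a["y", "m1"]))
})

test_that("sample heterozygosity and call rate match direct computation", {
  calls <- matrix(c("AA", "AB", "BB", "AB", NA, NA, NA, NA), 2, 4,
                  byrow = TRUE)
  panel <- genotype_panel(calls,
                          data.frame(sample_id = c("a", "b"), ploidy = 2L,
                                     population = "p"),
                          data.frame(snp_id = paste0("m", 1:4), chrom = "chr1",
                                     pos = 1:4, allele_a = "A", allele_b = "G"))
  qc <- sample_qc(panel)
  expect_equal(qc$het_pct[1], 50)
  expect_equal(qc$call_rate[1], 1)
  expect_equal(qc$call_rate[2], 0)
  expect_true(is.na(qc$het_pct[2]))
})

test_that("collapsed heterozygosity is monotone in ploidy at fixed frequency", {
  set.seed(41)
  p <- runif(300, 0.2, 0.8)
  dip <- balding_nichols_panel(p, fst = 0.05, K = 1, samples_per_pop = 300,
                               ploidy = 2L, seed = 51)
  tet <- balding_nichols_panel(p, fst = 0.05, K = 1, samples_per_pop = 300,
                               ploidy = 4L, seed = 52)
  h_dip <- mean(sample_qc(dip)$het_pct)
  h_tet <- mean(sample_qc(tet)$het_pct)
  expect_gt(h_tet, h_dip)
})

test_that("polymorphism sharing matches a brute-force recount", {
  panel <- random_panel(12, 20, 33, missing_rate = 0.15)
  ps <- polymorphism_sharing(panel, "population")
  labels <- panel$samples$population
  groups <- sort(unique(labels))
  brute <- sapply(seq_len(20), function(j) {
    members <- groups[vapply(groups, function(g) {
      calls <- panel$calls[labels == g, j]
      length(unique(calls[!is.na(calls)])) >= 2L
    }, logical(1))]
    paste(members, collapse = "+")
  })
  brute <- table(brute[brute != ""])
  expect_equal(ps$venn$n_snps[order(ps$venn$clusters)],
               as.integer(brute[order(names(brute))]))
  expect_equal(sum(ps$venn$n_snps), sum(brute))
})

test_that("MAF filter excludes below-threshold SNPs and keeps the boundary", {
  calls <- cbind(c(rep("AA", 97), rep("AB", 3)),   # freq B = 0.015 -> out
                 c(rep("AA", 90), rep("AB", 10)),  # freq B = 0.050 -> kept
                 c(rep("AA", 50), rep("AB", 50)))  # freq B = 0.250 -> kept
  panel <- genotype_panel(calls,
                          data.frame(sample_id = sprintf("s%03d", 1:100),
                                     ploidy = 2L, population = "p"),
                          data.frame(snp_id = c("rare", "edge", "common"),
                                     chrom = "chr1", pos = 1:3,
                                     allele_a = "A", allele_b = "G"))
  kept <- suppressMessages(maf_filter(panel, 0.05))
  expect_equal(kept$snps$snp_id, c("edge", "common"))
  expect_equal(attr(kept, "n_removed"), 1L)

  panel2 <- random_panel(40, 30, 34, missing_rate = 0.1)
  kept2 <- suppressMessages(maf_filter(panel2, 0.2))
  ft <- allele_freqs(panel2, rep("all", 40))
  want <- panel2$snps$snp_id[!is.na(ft$freq_a[1, ]) &
                               pmin(ft$freq_a[1, ], 1 - ft$freq_a[1, ]) >= 0.2]
  expect_equal(kept2$snps$snp_id, want)
})

test_that("encoding, imputation and frequencies commute with sample order", {
  panel <- random_panel(10, 12, 35, missing_rate = 0.2)
  set.seed(1)
  perm <- sample(10)
  shuffled <- panel[perm, ]
  e_orig <- impute_mean(encode_presence(panel))
  e_perm <- impute_mean(encode_presence(shuffled))
  expect_equal(e_perm$values, e_orig$values[perm, ])
  f_orig <- allele_freqs(panel)
  f_perm <- allele_freqs(shuffled)
  expect_equal(f_perm$freq_a, f_orig$freq_a)
})
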