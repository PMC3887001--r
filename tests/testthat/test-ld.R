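test_that("EM equals phased counting when no double heterozygotes occur", {
  # draw individuals from random haplotype frequencies, redrawing any
  # double heterozygote, so phase is fully observed
  for (seed in 1:10) {
    set.seed(seed)
    repeat {
      hf <- as.vector(stats::rmultinom(1, 30, rep(0.25, 4))) / 30 + 0.01
      hf <- hf / sum(hf)
      g_i <- integer(0)
      g_j <- integer(0)
      while (length(g_i) < 80L) {
        h1 <- sample(0:3, 1, prob = hf)
        h2 <- sample(0:3, 1, prob = hf)
        gi <- (h1 >= 2) + (h2 >= 2)
        gj <- (h1 %% 2) + (h2 %% 2)
        if (gi == 1L && gj == 1L) next
        g_i <- c(g_i, gi)
        g_j <- c(g_j, gj)
      }
      if (length(unique(g_i)) > 1L && length(unique(g_j)) > 1L) break
    }
    em <- r2_em(dosage_to_calls(g_i), dosage_to_calls(g_j))
    expect_equal(em$r2, phased_count_r2(g_i, g_j), tolerance = 1e-10)
  }
})

test_that("identical calls with all three classes give r2 = 1", {
  calls <- c(rep("AA", 5), rep("AB", 4), rep("BB", 3))
  em <- r2_em(calls, calls)
  expect_equal(em$r2, 1, tolerance = 1e-9)
})

test_that("EM matches the grid-search likelihood maximum", {
  for (seed in 1:20) {
    dat <- random_two_locus(200, seed)
    em <- r2_em(dosage_to_calls(dat$g_i), dosage_to_calls(dat$g_j))
    expect_lt(abs(em$r2 - grid_ml_r2(dat$g_i, dat$g_j)), 1e-3)
  }
})

test_that("r2 is invariant to allele relabeling and sample order", {
  dat <- random_two_locus(150, 77)
  ci <- dosage_to_calls(dat$g_i)
  cj <- dosage_to_calls(dat$g_j)
  base <- r2_em(ci, cj)$r2
  swap <- c(AA = "BB", AB = "AB", BB = "AA")
  expect_equal(r2_em(unname(swap[ci]), cj)$r2, base, tolerance = 1e-9)
  expect_equal(r2_em(ci, unname(swap[cj]))$r2, base, tolerance = 1e-9)
  set.seed(78)
  perm <- sample(length(ci))
  expect_equal(r2_em(ci[perm], cj[perm])$r2, base, tolerance = 1e-12)
})

test_that("monomorphic loci and missing data are handled pairwise", {
  em <- r2_em(rep("AA", 20), dosage_to_calls(random_two_locus(20, 5)$g_j))
  expect_true(is.na(em$r2))
  dat <- random_two_locus(100, 6)
  ci <- dosage_to_calls(dat$g_i)
  cj <- dosage_to_calls(dat$g_j)
  ci[1:10] <- NA
  em2 <- r2_em(ci, cj)
  expect_equal(em2$n, 90L)
  expect_equal(em2$r2, r2_em(ci[11:100], cj[11:100])$r2, tolerance = 1e-12)
})

test_that("compute_ld emits exactly the intra-chromosome pairs", {
  panel <- random_panel(40, 12, 151, missing_rate = 0.05)
  panel$snps$chrom <- rep(c("chr1", "chr2"), each = 6)
  pairs <- suppressMessages(compute_ld(panel, maf = 0))
  expect_true(all(pairs$chrom %in% c("chr1", "chr2")))
  # brute-force expected pair set per chromosome
  n_expected <- 0L
  for (ch in c("chr1", "chr2")) {
    ids <- panel$snps$snp_id[panel$snps$chrom == ch]
    sub <- pairs[pairs$chrom == ch, ]
    expect_true(all(sub$snp_i %in% ids & sub$snp_j %in% ids))
    defined <- 0L
    for (a in seq_along(ids)) {
      for (b in seq_len(a - 1L)) {
        if (!is.na(r2_em(panel$calls[, ids[a]], panel$calls[, ids[b]])$r2))
          defined <- defined + 1L
      }
    }
    expect_equal(nrow(sub), defined)
    n_expected <- n_expected + defined
  }
  expect_equal(nrow(pairs) + attr(pairs, "n_undefined"),
               2L * choose(6, 2))
  expect_equal(nrow(pairs), n_expected)
  # deterministic ordering by (chrom, pos_i, pos_j)
  pos_i <- panel$snps$pos[match(pairs$snp_i, panel$snps$snp_id)]
  ord <- order(pairs$chrom, pos_i, pairs$d)
  expect_equal(ord, seq_len(nrow(pairs)))
})

test_that("pipeline r2 equals r2_em applied per pair", {
  panel <- random_panel(50, 8, 152, missing_rate = 0.1)
  panel$snps$chrom <- "chr1"
  pairs <- suppressMessages(compute_ld(panel, maf = 0.05))
  expect_gt(nrow(pairs), 0)
  for (k in seq_len(nrow(pairs))) {
    direct <- r2_em(panel$calls[, pairs$snp_i[k]],
                    panel$calls[, pairs$snp_j[k]])
    expect_equal(pairs$r2[k], direct$r2, tolerance = 1e-12)
    expect_equal(pairs$n[k], direct$n)
  }
})

test_that("max_d and MAF filtering restrict the pair list", {
  panel <- random_panel(40, 10, 153, missing_rate = 0)
  panel$snps$chrom <- "chr1"
  panel$snps$pos <- seq(1000L, 10000L, by = 1000L)
  all_pairs <- suppressMessages(compute_ld(panel, maf = 0))
  near <- suppressMessages(compute_ld(panel, maf = 0, max_d = 3000))
  expect_true(all(near$d <= 3000))
  expect_equal(nrow(near),
               nrow(all_pairs[all_pairs$d <= 3000, ]))
})

test_that("sved decay fit recovers noiseless parameters to closed form", {
  d <- 10^seq(2, 6, length.out = 100)
  fit <- ld_decay_fit(data.frame(d = d, r2 = decay_curve(d, 1e-5)),
                      r2_targets = 0.2)
  expect_equal(fit$a, 1e-5, tolerance = 1e-8)
  expect_equal(fit$d_at[["0.2"]], 1e5, tolerance = 1e-6)
  expect_equal(decay_curve(0, fit$a), 1)  # E(r2) = 1 at d = 0
  expect_equal(unname(coef(fit)["a"]), fit$a)
  expect_equal(predict(fit, data.frame(d = 0)), 1)
})

test_that("noisy sved data is recovered within a few percent", {
  set.seed(161)
  d <- 10^runif(5000, 2, 6)
  r2 <- decay_curve(d, 2e-5) + rnorm(5000, sd = 0.05)
  fit <- suppressWarnings(ld_decay_fit(data.frame(d = d, r2 = r2)))
  expect_lt(abs(fit$a - 2e-5) / 2e-5, 0.05)
  expect_lt(abs(fit$d_at[["0.2"]] - 1 / fit$a), 1e-6 / fit$a)
})

test_that("the finite-sample curve approaches the sved curve for large C and n", {
  a <- 2e-5
  d <- 10^seq(4.2, 6.5, length.out = 40)  # C = 4ad >= 10 over this range
  C <- 4 * a * d
  expect_true(all(C[1] >= 1))
  gap <- abs(decay_curve(d, a, "hill_weir_n", n = 1e4) - decay_curve(d, a))
  expect_lt(max(gap[C >= 10]), 0.02)
  # the 1/n correction itself vanishes as n grows
  corr <- abs(decay_curve(d, a, "hill_weir_n", n = 1e8) -
                decay_curve(d, a, "hill_weir_n", n = 1e4))
  expect_lt(max(corr), max(abs(decay_curve(d, a, "hill_weir_n", n = 20) -
                                 decay_curve(d, a, "hill_weir_n", n = 1e4))))
})

test_that("hill_weir_n fits and reports a numeric threshold distance", {
  set.seed(162)
  d <- 10^runif(2000, 2, 6)
  r2 <- decay_curve(d, 1e-5, "hill_weir_n", n = 100) + rnorm(2000, sd = 0.03)
  fit <- ld_decay_fit(data.frame(d = d, r2 = r2), variant = "hill_weir_n",
                      n = 100, r2_targets = 0.2)
  expect_lt(abs(fit$a - 1e-5) / 1e-5, 0.1)
  expect_equal(decay_curve(fit$d_at[["0.2"]], fit$a, "hill_weir_n", n = 100),
               0.2, tolerance = 1e-4)
})

test_that("equilibrium pool LD fitted on recombination fraction recovers n_e", {
  all_pairs <- list()
  for (seed in 201:208) {
    cfg <- sim_config(n_e = 100, n_loci = 150, chrom_length = 1e6,
                      rec_rate = 1e-7, n_generations = 400, n_subpops = 1,
                      split_generation = 0, ploidy_per_pop = 2L,
                      samples_per_pop = 5, seed = seed)
    all_pairs[[length(all_pairs) + 1L]] <- pool_ld_pairs(simulate_wf(cfg), 1)
  }
  pr <- do.call(rbind, all_pairs)
  # with distance measured as recombination fraction, a estimates n_e
  fit <- ld_decay_fit(data.frame(d = pr$c, r2 = pr$r2))
  expect_lt(abs(fit$a - 100) / 100, 0.3)
})

test_that("identical LD tables give r_LD = 1 in every window", {
  panel <- random_panel(60, 10, 171, missing_rate = 0)
  panel$snps$chrom <- "chr1"
  panel$snps$pos <- sort(sample.int(5e5, 10))
  pairs <- suppressMessages(compute_ld(panel, maf = 0.05))
  cons <- ld_consistency(pairs, pairs)
  expect_gt(nrow(cons), 0)
  expect_equal(cons$r_ld, rep(1, nrow(cons)), tolerance = 1e-12)
})

test_that("permuting one table's r2 values kills the correlation", {
  cfg <- sim_config(n_e = 50, n_loci = 80, n_generations = 150,
                    n_subpops = 1, split_generation = 0,
                    ploidy_per_pop = 2L, samples_per_pop = 5, seed = 181)
  pairs <- pool_ld_pairs(simulate_wf(cfg), 1)
  shuffled <- pairs
  set.seed(182)
  shuffled$r2 <- sample(shuffled$r2)
  cons <- suppressMessages(ld_consistency(pairs, shuffled, windows = 1e6))
  expect_lt(abs(cons$r_ld), 3 / sqrt(cons$n_pairs))
})
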