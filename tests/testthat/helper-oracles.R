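# Independent oracles and fixture builders used across the suite.

dosage_to_calls <- function(g) c("AA", "AB", "BB")[g + 1L]

# Brute-force maximum-likelihood r2 for two unphased loci: coarse-to-fine
# grid over the haplotype-frequency simplex (p1 = p(A,A), p2 = p(A,B),
# p3 = p(B,A), p4 = 1 - p1 - p2 - p3), refined three times to a final
# resolution of 2e-5 per frequency. Independent of the EM code path.
grid_ml_r2 <- function(g_i, g_j) {
  cnt <- tabulate(3L * g_i + g_j + 1L, nbins = 9L)
  loglik <- function(p1, p2, p3) {
    p4 <- 1 - p1 - p2 - p3
    cells <- list(p1^2, 2 * p1 * p2, p2^2,
                  2 * p1 * p3, 2 * p1 * p4 + 2 * p2 * p3, 2 * p2 * p4,
                  p3^2, 2 * p3 * p4, p4^2)
    ll <- 0
    for (k in 1:9) if (cnt[k] > 0) ll <- ll + cnt[k] * log(pmax(cells[[k]], 1e-300))
    ll
  }
  lo <- c(0, 0, 0)
  hi <- c(1, 1, 1)
  step <- 1 / 50
  best <- NULL
  for (round in 1:4) {
    gr <- expand.grid(p1 = seq(lo[1], hi[1], by = step),
                      p2 = seq(lo[2], hi[2], by = step),
                      p3 = seq(lo[3], hi[3], by = step))
    gr <- gr[gr$p1 + gr$p2 + gr$p3 <= 1 + 1e-12, ]
    ll <- loglik(gr$p1, gr$p2, gr$p3)
    b <- which.max(ll)
    best <- c(gr$p1[b], gr$p2[b], gr$p3[b])
    lo <- pmax(best - 1.5 * step, 0)
    hi <- pmin(best + 1.5 * step, 1)
    step <- step / 10
  }
  p <- c(best, 1 - sum(best))
  d_coef <- p[1] - (p[1] + p[2]) * (p[1] + p[3])
  pa <- p[1] + p[2]
  pb <- p[1] + p[3]
  d_coef^2 / (pa * (1 - pa) * pb * (1 - pb))
}

# Random unphased two-locus dataset: haplotype frequencies from a
# perturbed multinomial, individuals formed by random union of gametes;
# redraws until both loci are polymorphic. Returns B-dosage vectors.
random_two_locus <- function(n, seed) {
  set.seed(seed)
  repeat {
    hf <- as.vector(stats::rmultinom(1, 40, rep(0.25, 4))) / 40 + 0.002
    hf <- hf / sum(hf)
    h1 <- sample(0:3, n, TRUE, hf)
    h2 <- sample(0:3, n, TRUE, hf)
    g_i <- (h1 >= 2) + (h2 >= 2)
    g_j <- (h1 %% 2) + (h2 %% 2)
    if (length(unique(g_i)) > 1L && length(unique(g_j)) > 1L &&
        sum(g_i) %% (2 * n) != 0 && sum(g_j) %% (2 * n) != 0)
      return(list(g_i = g_i, g_j = g_j))
  }
}

# Phased-count r2: valid when phase is unambiguous (no double
# heterozygote), in which case haplotype counts are read off directly.
phased_count_r2 <- function(g_i, g_j) {
  cnt <- tabulate(3L * g_i + g_j + 1L, nbins = 9L)
  nm <- matrix(cnt, 3L, 3L, byrow = TRUE)
  stopifnot(nm[2L, 2L] == 0L)
  n <- length(g_i)
  hap <- c(2 * nm[1, 1] + nm[1, 2] + nm[2, 1],
           2 * nm[1, 3] + nm[1, 2] + nm[2, 3],
           2 * nm[3, 1] + nm[2, 1] + nm[3, 2],
           2 * nm[3, 3] + nm[2, 3] + nm[3, 2]) / (2 * n)
  d_coef <- hap[1] - (hap[1] + hap[2]) * (hap[1] + hap[3])
  pa <- hap[1] + hap[2]
  pb <- hap[1] + hap[3]
  d_coef^2 / (pa * (1 - pa) * pb * (1 - pb))
}

# Random three-class panel for round-trip and recount tests.
random_panel <- function(n_s, n_m, seed, missing_rate = 0.1, n_pops = 2L) {
  set.seed(seed)
  calls <- matrix(sample(c("AA", "AB", "BB"), n_s * n_m, TRUE), n_s, n_m)
  calls[matrix(stats::runif(n_s * n_m) < missing_rate, n_s, n_m)] <- NA
  samples <- data.frame(sample_id = sprintf("s%03d", seq_len(n_s)),
                        ploidy = sample(c(2L, 4L), n_s, TRUE),
                        population = paste0("pop", rep_len(seq_len(n_pops), n_s)),
                        stringsAsFactors = FALSE)
  snps <- data.frame(snp_id = sprintf("m%03d", seq_len(n_m)),
                     chrom = sample(c("chr1", "chr2"), n_m, TRUE),
                     pos = sample.int(1e6, n_m),
                     allele_a = "A", allele_b = "C",
                     stringsAsFactors = FALSE)
  genotype_panel(calls, samples, snps)
}

# Best label agreement between true populations and cluster assignments,
# maximized over label permutations.
label_agreement <- function(truth, assign) {
  truth <- as.integer(factor(truth))
  assign <- as.integer(factor(assign))
  k <- max(truth, assign)
  if (k > 5L) stop("label_agreement: too many labels")
  perms <- gtools_perms(k)
  tab <- table(factor(truth, levels = 1:k), factor(assign, levels = 1:k))
  best <- 0
  for (r in seq_len(nrow(perms))) {
    best <- max(best, sum(tab[cbind(1:k, perms[r, ])]))
  }
  best / length(truth)
}

# all permutations of 1..k (tiny k)
gtools_perms <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- gtools_perms(k - 1L)
  out <- NULL
  for (pos in seq_len(k)) {
    out <- rbind(out, cbind(sub[, seq_len(pos - 1L), drop = FALSE], k,
                            sub[, seq(pos, k - 1L)[seq_len(k - pos)],
                                drop = FALSE]))
  }
  out
}

# Hand-specified 6-sample / 10-SNP toy panel over two clusters (X = s1-s3,
# Y = s4-s6); the expected MAF-filter and polymorphism-sharing results are
# computed by hand in the tests that use it.
toy_panel <- function() {
  calls <- rbind(
    #        snp01 snp02 snp03 snp04 snp05 snp06 snp07 snp08 snp09 snp10
    s1 = c("AA", "AA", "AA", "AA", "BB", "AB", "AA", "AB", "BB", "AA"),
    s2 = c("AA", "AB", "AB", "AA", "BB", "AB", NA,   "AA", "AB", "AA"),
    s3 = c("AA", "AA", "BB", "AA", "BB", "AB", "AA", "AA", "BB", "AB"),
    s4 = c("AA", "AA", "AB", "AA", "BB", "AB", NA,   "AA", "BB", "AB"),
    s5 = c("AB", "AA", "AB", "AA", "BB", "AB", "AB", "AA", "BB", "AA"),
    s6 = c("AA", "AA", "AA", "AA", "BB", "AB", "BB", "AB", NA,   "AA"))
  colnames(calls) <- sprintf("snp%02d", 1:10)
  samples <- data.frame(sample_id = rownames(calls),
                        ploidy = c(2L, 2L, 2L, 4L, 4L, 4L),
                        population = rep(c("X", "Y"), each = 3L),
                        stringsAsFactors = FALSE)
  snps <- data.frame(snp_id = colnames(calls), chrom = "chr1",
                     pos = seq(1000L, 10000L, by = 1000L),
                     allele_a = "A", allele_b = "G", stringsAsFactors = FALSE)
  genotype_panel(calls, samples, snps)
}

# Additive distance matrix from a random binary tree with positive branch
# lengths (path-length metric), plus the tree itself.
random_additive_matrix <- function(n_taxa, seed) {
  set.seed(seed)
  tree <- ape::rtree(n_taxa, rooted = FALSE,
                     br = function(n) stats::runif(n, 0.1, 1))
  list(tree = tree, D = ape::cophenetic.phylo(tree))
}
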