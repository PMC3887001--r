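#' Simulation configuration for the Wright-Fisher panel generator
#'
#' Bundles and validates the parameters of \code{\link{simulate_wf}} /
#' \code{\link{sample_panel}}. The defaults emulate a structured SNP-array
#' panel at desk scale: K = 3 subpopulations (two tetraploid, one diploid)
#' diverged from a common ancestor, within-population LD decaying with
#' physical distance at drift-recombination equilibrium, and a low missing
#' call rate.
#'
#' One global \code{seed} drives a splittable stream per stage: haplotype
#' simulation uses \code{seed}, genotype sampling \code{seed + 1000000} and
#' missingness injection \code{seed + 2000000}, so fixtures are
#' byte-reproducible stage by stage.
#'
#' @param n_e Wright-Fisher population size; the haplotype pool holds
#'   \code{2 * n_e} haplotypes.
#' @param n_loci number of biallelic loci (>= 2).
#' @param chrom_length chromosome length in bp; locus positions are drawn
#'   uniformly on \code{[1, chrom_length]} and sorted.
#' @param rec_rate per-bp recombination probability per meiosis; must
#'   satisfy \code{rec_rate * chrom_length <= 0.5}.
#' @param n_generations total generations of forward simulation; values
#'   >= \code{4 * n_e} put the pool near drift-recombination equilibrium.
#' @param n_subpops number of subpopulations K after the split.
#' @param split_generation generation at which the ancestral pool splits
#'   into K independently drifting copies.
#' @param founder_freq_low,founder_freq_high bounds of the uniform law for
#'   founder allele-A frequencies.
#' @param samples_per_pop samples drawn per subpopulation by
#'   \code{\link{sample_panel}}.
#' @param ploidy_per_pop integer vector of length K with entries in
#'   \{2, 4\}.
#' @param missing_rate i.i.d. missing-call probability in [0, 1].
#' @param seed integer master seed.
#' @return a validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_e = 100L, n_loci = 200L, chrom_length = 1e6,
                       rec_rate = 1e-7, n_generations = 400L,
                       n_subpops = 3L, split_generation = 200L,
                       founder_freq_low = 0.1, founder_freq_high = 0.9,
                       samples_per_pop = 30L,
                       ploidy_per_pop = c(4L, 4L, 2L)[seq_len(n_subpops)],
                       missing_rate = 0.01, seed = 1L) {
  cfg <- list(n_e = as.integer(n_e), n_loci = as.integer(n_loci),
              chrom_length = chrom_length, rec_rate = rec_rate,
              n_generations = as.integer(n_generations),
              n_subpops = as.integer(n_subpops),
              split_generation = as.integer(split_generation),
              founder_freq_low = founder_freq_low,
              founder_freq_high = founder_freq_high,
              samples_per_pop = as.integer(samples_per_pop),
              ploidy_per_pop = as.integer(ploidy_per_pop),
              missing_rate = missing_rate, seed = as.integer(seed))
  if (cfg$n_e < 2L) stop("n_e must be >= 2")
  if (cfg$n_loci < 2L) stop("n_loci must be >= 2")
  if (cfg$chrom_length < cfg$n_loci) stop("chrom_length too short for n_loci")
  if (cfg$rec_rate < 0 || cfg$rec_rate * cfg$chrom_length > 0.5)
    stop("rec_rate * chrom_length must lie in [0, 0.5]")
  if (cfg$n_generations < 1L || cfg$n_subpops < 1L ||
      cfg$samples_per_pop < 1L)
    stop("all counts must be positive")
  if (cfg$split_generation < 0L || cfg$split_generation > cfg$n_generations)
    stop("split_generation must lie in [0, n_generations]")
  if (length(cfg$ploidy_per_pop) != cfg$n_subpops ||
      !all(cfg$ploidy_per_pop %in% c(2L, 4L)))
    stop("ploidy_per_pop must have one entry in {2, 4} per subpopulation")
  if (cfg$missing_rate < 0 || cfg$missing_rate > 1)
    stop("missing_rate must lie in [0, 1]")
  if (!(cfg$founder_freq_low >= 0 && cfg$founder_freq_high <= 1 &&
        cfg$founder_freq_low <= cfg$founder_freq_high))
    stop("founder frequency bounds must satisfy 0 <= low <= high <= 1")
  structure(cfg, class = "sim_config")
}

# One WF generation: each offspring haplotype recombines two uniformly
# drawn parents, with an independent Bernoulli crossover per adjacent-locus
# interval (no interference).
wf_generation <- function(pool, c_int) {
  h <- nrow(pool)
  l <- ncol(pool)
  p1 <- pool[sample.int(h, h, replace = TRUE), , drop = FALSE]
  if (l == 1L || all(c_int == 0)) {
    return(p1)
  }
  p2 <- pool[sample.int(h, h, replace = TRUE), , drop = FALSE]
  xo <- matrix(stats::rbinom(h * (l - 1L), 1L, rep(c_int, each = h)),
               h, l - 1L)
  phase <- matrix(0L, h, l)
  phase[, 1L] <- stats::rbinom(h, 1L, 0.5)
  for (k in seq_len(l - 1L)) {
    phase[, k + 1L] <- (phase[, k] + xo[, k]) %% 2L
  }
  sel <- phase == 1L
  p1[sel] <- p2[sel]
  p1
}

#' Forward Wright-Fisher simulation with recombination
#'
#' Simulates a pool of \code{2 * n_e} haplotypes forward in time. Each
#' generation every offspring haplotype is a recombinant of two uniformly
#' drawn parent haplotypes, with crossovers placed as independent
#' Bernoulli(\code{rec_rate * interval_length}) events per adjacent-locus
#' interval (no interference). Founder haplotypes are in linkage
#' equilibrium with per-locus allele-A frequencies drawn from the
#' configured uniform law. After \code{split_generation} the pool is copied
#' into K pools that drift independently (no migration, no mutation).
#'
#' Run long enough (about \code{4 * n_e} generations and beyond), the
#' within-pool expectation of r-squared at recombination fraction c
#' approaches the drift-recombination equilibrium value
#' \code{1 / (1 + 4 * n_e * c) + 1 / (2 * n_e)}; see
#' \code{\link{expected_r2_drift}}.
#'
#' @param config a \code{\link{sim_config}}.
#' @return an object of class \code{sim_truth}: list with \code{pools} (per
#'   subpopulation 0/1 haplotype matrix, rows = haplotypes), \code{pos}
#'   (sorted locus positions, bp), \code{chrom}, \code{snp_id} and
#'   \code{config}.
#' @export
simulate_wf <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  l <- config$n_loci
  pos <- sort(sample.int(config$chrom_length, l, replace = FALSE))
  c_int <- pmin(config$rec_rate * diff(pos), 0.5)
  p0 <- stats::runif(l, config$founder_freq_low, config$founder_freq_high)
  h <- 2L * config$n_e
  # allele 1 codes allele B so founder freq law applies to allele A (0)
  pool <- matrix(stats::rbinom(h * l, 1L, rep(1 - p0, each = h)), h, l)
  for (g in seq_len(config$split_generation)) {
    pool <- wf_generation(pool, c_int)
  }
  pools <- rep(list(pool), config$n_subpops)
  for (g in seq_len(config$n_generations - config$split_generation)) {
    for (k in seq_len(config$n_subpops)) {
      pools[[k]] <- wf_generation(pools[[k]], c_int)
    }
  }
  names(pools) <- paste0("pop", seq_len(config$n_subpops))
  structure(list(pools = pools, pos = pos, chrom = "chr1",
                 snp_id = sprintf("snp%04d", seq_len(l)), config = config),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("sim_truth: ", length(x$pools), " subpopulation pool(s) of ",
      nrow(x$pools[[1L]]), " haplotypes x ", length(x$pos), " loci\n", sep = "")
  invisible(x)
}

#' Draw a genotype panel from simulated haplotype pools
#'
#' Each sample draws \code{ploidy} haplotypes with replacement from its
#' subpopulation pool; the per-locus call is AA if every drawn allele is A,
#' BB if every allele is B, and AB otherwise — i.e. tetraploid dosage
#' classes are collapsed exactly as the array scoring does. Missing calls
#' are then injected i.i.d. at \code{missing_rate}.
#'
#' @param truth a \code{sim_truth} from \code{\link{simulate_wf}}.
#' @param config the same \code{\link{sim_config}} (defaults to the one
#'   stored in \code{truth}).
#' @return a \code{\link{genotype_panel}} with samples labelled by their
#'   source subpopulation (the simulator's ground-truth clusters).
#' @export
sample_panel <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "sim_truth"))
  if (!all(config$ploidy_per_pop %in% c(2L, 4L)))
    stop("ploidy not in {2, 4}")
  set.seed(config$seed + 1000000L)
  l <- length(truth$pos)
  k <- length(truth$pools)
  n_tot <- k * config$samples_per_pop
  calls <- matrix(NA_character_, n_tot, l)
  samples <- data.frame(sample_id = character(n_tot), ploidy = integer(n_tot),
                        population = character(n_tot),
                        stringsAsFactors = FALSE)
  row <- 0L
  for (ki in seq_len(k)) {
    pool <- truth$pools[[ki]]
    pl <- config$ploidy_per_pop[ki]
    for (s in seq_len(config$samples_per_pop)) {
      row <- row + 1L
      hap <- pool[sample.int(nrow(pool), pl, replace = TRUE), , drop = FALSE]
      b <- colSums(hap)
      calls[row, ] <- ifelse(b == 0L, "AA", ifelse(b == pl, "BB", "AB"))
      samples$sample_id[row] <- sprintf("%s_s%03d", names(truth$pools)[ki], s)
      samples$ploidy[row] <- pl
      samples$population[row] <- names(truth$pools)[ki]
    }
  }
  if (config$missing_rate > 0) {
    set.seed(config$seed + 2000000L)
    drop <- matrix(stats::runif(n_tot * l) < config$missing_rate, n_tot, l)
    calls[drop] <- NA_character_
  }
  snps <- data.frame(snp_id = truth$snp_id, chrom = truth$chrom,
                     pos = truth$pos, allele_a = "A", allele_b = "B",
                     stringsAsFactors = FALSE)
  genotype_panel(calls, samples, snps)
}

#' Balding-Nichols panel of unlinked loci
#'
#' Structured-population generator for clustering tests: each
#' subpopulation's allele-A frequency at a locus is drawn from
#' Beta(p(1-F)/F, (1-p)(1-F)/F) around the ancestral frequency p, so that
#' across-subpopulation frequency variance is p(1-p)F. Genotypes are
#' binomial draws at the sample's ploidy, collapsed to three classes. Loci
#' are unlinked: each is assigned its own chromosome so no LD pair is ever
#' formed from such a panel.
#'
#' @param p_anc numeric vector of ancestral allele-A frequencies in (0,1),
#'   one per locus.
#' @param fst divergence parameter F in (0, 1).
#' @param K number of subpopulations.
#' @param samples_per_pop samples per subpopulation.
#' @param ploidy scalar or length-K vector with entries in \{2, 4\}.
#' @param seed integer seed.
#' @param missing_rate i.i.d. missing-call probability.
#' @return a \code{\link{genotype_panel}} with population labels
#'   \code{pop1..popK} (the ground-truth clusters).
#' @export
balding_nichols_panel <- function(p_anc, fst, K, samples_per_pop,
                                  ploidy = 2L, seed = 1L, missing_rate = 0) {
  if (!(fst > 0 && fst < 1)) stop("fst must lie in (0, 1)")
  if (any(p_anc <= 0 | p_anc >= 1)) stop("p_anc must lie in (0, 1)")
  ploidy <- rep_len(as.integer(ploidy), K)
  if (!all(ploidy %in% c(2L, 4L))) stop("ploidy must be 2 or 4")
  set.seed(seed)
  l <- length(p_anc)
  n_tot <- K * samples_per_pop
  calls <- matrix(NA_character_, n_tot, l)
  samples <- data.frame(sample_id = sprintf("s%04d", seq_len(n_tot)),
                        ploidy = rep(ploidy, each = samples_per_pop),
                        population = rep(paste0("pop", seq_len(K)),
                                         each = samples_per_pop),
                        stringsAsFactors = FALSE)
  shape_scale <- (1 - fst) / fst
  for (ki in seq_len(K)) {
    p_k <- stats::rbeta(l, p_anc * shape_scale, (1 - p_anc) * shape_scale)
    rows <- (ki - 1L) * samples_per_pop + seq_len(samples_per_pop)
    pl <- ploidy[ki]
    # dosage of allele B per sample per locus
    b <- matrix(stats::rbinom(samples_per_pop * l, pl,
                              rep(1 - p_k, each = samples_per_pop)),
                samples_per_pop, l)
    calls[rows, ] <- ifelse(b == 0L, "AA", ifelse(b == pl, "BB", "AB"))
  }
  if (missing_rate > 0) {
    drop <- matrix(stats::runif(n_tot * l) < missing_rate, n_tot, l)
    calls[drop] <- NA_character_
  }
  snps <- data.frame(snp_id = sprintf("snp%04d", seq_len(l)),
                     chrom = sprintf("chrU%04d", seq_len(l)),
                     pos = 1L, allele_a = "A", allele_b = "B",
                     stringsAsFactors = FALSE)
  genotype_panel(calls, samples, snps)
}

#' Phased r-squared pairs from a simulated haplotype pool
#'
#' Truth LD for oracle tests is computed from the phased haplotype pool,
#' not from sampled genotypes, which separates sampling noise from
#' estimator error. For loci i < j the recombination fraction is
#' \code{1 - prod(1 - c_k)} over the intervening adjacent intervals.
#'
#' @param truth a \code{sim_truth}.
#' @param pop subpopulation name or index (default first).
#' @param maf pool minor-allele-frequency threshold; pairs involving loci
#'   below it are excluded (monomorphic loci always are).
#' @return data.frame with columns \code{snp_i}, \code{snp_j}, \code{d}
#'   (bp), \code{c} (recombination fraction), \code{r2}, \code{n}.
#' @export
pool_ld_pairs <- function(truth, pop = 1L, maf = 0.05) {
  stopifnot(inherits(truth, "sim_truth"))
  pool <- truth$pools[[pop]]
  freq_b <- colMeans(pool)
  keep <- pmin(freq_b, 1 - freq_b) >= maf
  idx <- which(keep)
  if (length(idx) < 2L)
    return(data.frame(snp_i = character(0), snp_j = character(0),
                      d = numeric(0), c = numeric(0), r2 = numeric(0),
                      n = integer(0)))
  c_int <- pmin(truth$config$rec_rate * diff(truth$pos), 0.5)
  log1m <- c(0, cumsum(log1p(-c_int)))  # cumulative over intervals
  r <- stats::cor(pool[, idx, drop = FALSE])
  ut <- which(upper.tri(r), arr.ind = TRUE)
  i <- idx[ut[, 1L]]
  j <- idx[ut[, 2L]]
  data.frame(snp_i = truth$snp_id[i], snp_j = truth$snp_id[j],
             d = abs(truth$pos[j] - truth$pos[i]),
             c = 1 - exp(log1m[j] - log1m[i]),
             r2 = r[ut]^2, n = nrow(pool), stringsAsFactors = FALSE)
}

#' Drift-recombination equilibrium expectation of r-squared
#'
#' \code{1 / (1 + 4 * n_e * c) + 1 / (2 * n_e)}: the equilibrium value at
#' recombination fraction \code{c} in a Wright-Fisher population of size
#' \code{n_e}, plus the finite-pool sampling floor.
#'
#' @param n_e population size.
#' @param c recombination fraction (vectorized).
#' @return expected r-squared.
#' @export
expected_r2_drift <- function(n_e, c) 1 / (1 + 4 * n_e * c) + 1 / (2 * n_e)
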