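# integer coding of collapsed calls: 0, 1, 2 copies of allele B; NA missing
calls_to_dosage <- function(calls) {
  match(calls, c("AA", "AB", "BB")) - 1L
}

#' Maximum-likelihood r-squared between two unphased loci via EM
#'
#' Treats every sample as diploid-equivalent under the collapsed
#' three-class coding and maximizes the two-locus haplotype-frequency
#' likelihood (p_AB, p_Ab, p_aB, p_ab) by EM. Only double heterozygotes
#' carry phase ambiguity; they are split between coupling and repulsion by
#' the posterior under the current estimate each iteration. With no double
#' heterozygotes the EM fixed point equals direct phased counting.
#' r-squared is D^2 / (p_A p_a p_B p_b) at the converged frequencies.
#' Samples missing at either locus are dropped pairwise.
#'
#' @param calls_i,calls_j character vectors of collapsed calls ("AA",
#'   "AB", "BB", NA), one entry per sample, same length.
#' @param max_iter,tol EM cap (default 1000) and convergence tolerance on
#'   haplotype frequencies (default 1e-10).
#' @return list with \code{r2} (NA if either locus is monomorphic among
#'   jointly called samples), \code{n} (samples used) and \code{hap_freq}
#'   (converged haplotype frequencies, order AB-coupling convention:
#'   p(A,A), p(A,B), p(B,A), p(B,B) across the two loci).
#' @export
r2_em <- function(calls_i, calls_j, max_iter = 1000L, tol = 1e-10) {
  g_i <- calls_to_dosage(calls_i)
  g_j <- calls_to_dosage(calls_j)
  ok <- !is.na(g_i) & !is.na(g_j)
  r2_em_dosage(g_i[ok], g_j[ok], max_iter, tol)
}

r2_em_dosage <- function(g_i, g_j, max_iter = 1000L, tol = 1e-10) {
  n <- length(g_i)
  if (n == 0L) return(list(r2 = NA_real_, n = 0L, hap_freq = rep(NA_real_, 4)))
  # 3x3 genotype cross-tab, cells indexed 3*g_i + g_j
  cnt <- tabulate(3L * g_i + g_j + 1L, nbins = 9L)
  nm <- matrix(cnt, 3L, 3L, byrow = TRUE) # nm[gi+1, gj+1]
  p_a_i <- 1 - sum(g_i) / (2 * n)  # freq of allele A at locus i
  p_a_j <- 1 - sum(g_j) / (2 * n)
  if (p_a_i <= 0 || p_a_i >= 1 || p_a_j <= 0 || p_a_j >= 1)
    return(list(r2 = NA_real_, n = n, hap_freq = rep(NA_real_, 4)))
  # haplotype freqs p[1]=p(AA), p[2]=p(AB), p[3]=p(BA), p[4]=p(BB),
  # first letter = locus i allele; start at linkage equilibrium
  p <- c(p_a_i * p_a_j, p_a_i * (1 - p_a_j),
         (1 - p_a_i) * p_a_j, (1 - p_a_i) * (1 - p_a_j))
  n_dh <- nm[2L, 2L]
  base <- c(2 * nm[1, 1] + nm[1, 2] + nm[2, 1],
            2 * nm[1, 3] + nm[1, 2] + nm[2, 3],
            2 * nm[3, 1] + nm[2, 1] + nm[3, 2],
            2 * nm[3, 3] + nm[2, 3] + nm[3, 2])
  for (it in seq_len(max_iter)) {
    cpl <- p[1] * p[4]
    rpl <- p[2] * p[3]
    w <- if (cpl + rpl > 0) cpl / (cpl + rpl) else 0.5
    p_new <- (base + n_dh * c(w, 1 - w, 1 - w, w)) / (2 * n)
    if (max(abs(p_new - p)) < tol) {
      p <- p_new
      break
    }
    p <- p_new
  }
  d_coef <- p[1] - (p[1] + p[2]) * (p[1] + p[3])
  denom <- p_a_i * (1 - p_a_i) * p_a_j * (1 - p_a_j)
  list(r2 = min(d_coef^2 / denom, 1), n = n, hap_freq = p)
}

#' All intra-chromosome LD pairs of a panel
#'
#' Applies the per-group MAF filter, drops SNPs without reference
#' coordinates (logged), and computes EM r-squared for every
#' intra-chromosome SNP pair within \code{max_d} bp, with pairwise
#' deletion of missing calls. Inter-chromosome pairs have undefined
#' physical distance and are never emitted. Output rows are ordered by
#' (chrom, pos_i, pos_j).
#'
#' @param panel a \code{\link{genotype_panel}}.
#' @param group optional sample subset (sample_ids, logical or integer
#'   index); MAF is computed within this group.
#' @param maf minor-allele-frequency threshold (SNPs strictly below are
#'   excluded).
#' @param max_d maximum pair distance in bp (default Inf).
#' @return data.frame with columns \code{snp_i}, \code{snp_j},
#'   \code{chrom}, \code{d} (bp), \code{r2}, \code{n}; pairs whose EM is
#'   undefined (monomorphic after pairwise deletion) are omitted and
#'   counted in attribute \code{n_undefined}.
#' @export
compute_ld <- function(panel, group = NULL, maf = 0.05, max_d = Inf) {
  if (!is.null(group)) panel <- panel[group, ]
  if (n_samples(panel) < 10L)
    warning("group has fewer than 10 samples; r2 estimates will be noisy")
  unplaced <- is.na(panel$snps$pos) | is.na(panel$snps$chrom)
  if (any(unplaced)) {
    message("compute_ld: excluding ", sum(unplaced),
            " SNP(s) without reference coordinates")
    panel <- panel[, !unplaced]
  }
  panel <- maf_filter(panel, threshold = maf)
  dosage <- matrix(calls_to_dosage(panel$calls),
                   nrow(panel$calls), ncol(panel$calls))
  ord <- order(panel$snps$chrom, panel$snps$pos)
  out <- list()
  n_undef <- 0L
  for (ch in unique(panel$snps$chrom[ord])) {
    idx <- ord[panel$snps$chrom[ord] == ch]
    if (length(idx) < 2L) next
    pos <- panel$snps$pos[idx]
    for (ii in seq_len(length(idx) - 1L)) {
      for (jj in seq((ii + 1L), length(idx))) {
        d <- pos[jj] - pos[ii]
        if (d > max_d) break
        g_i <- dosage[, idx[ii]]
        g_j <- dosage[, idx[jj]]
        keep <- !is.na(g_i) & !is.na(g_j)
        fit <- r2_em_dosage(g_i[keep], g_j[keep])
        if (is.na(fit$r2)) {
          n_undef <- n_undef + 1L
          next
        }
        out[[length(out) + 1L]] <-
          data.frame(snp_i = panel$snps$snp_id[idx[ii]],
                     snp_j = panel$snps$snp_id[idx[jj]],
                     chrom = ch, d = d, r2 = fit$r2, n = fit$n,
                     stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(snp_i = character(0), snp_j = character(0),
               chrom = character(0), d = numeric(0), r2 = numeric(0),
               n = integer(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "n_undefined") <- n_undef
  res
}

#' Cross-population LD consistency (r_LD)
#'
#' For SNP pairs present in both populations' LD tables and closer than
#' each distance window, computes the correlation between the two
#' populations' r-squared values. High r_LD at a window means the two
#' populations share LD structure at that physical scale, the condition
#' for transferring association or genomic-selection models between them.
#'
#' @param pairsA,pairsB LD pair data.frames from \code{\link{compute_ld}}
#'   computed over the same SNP map.
#' @param windows maximum pair distances in bp (default 0.1, 0.2 and 1.0
#'   Mbp); pairs at d < window enter the correlation.
#' @param genetic_distance optional Nei distance between the populations,
#'   carried through to the output for plotting r_LD against divergence.
#' @param method correlation type, "pearson" (default) or "spearman".
#' @return data.frame with columns \code{window}, \code{r_ld},
#'   \code{n_pairs}, \code{genetic_distance}; windows with fewer than 2
#'   shared pairs are omitted with a message.
#' @export
ld_consistency <- function(pairsA, pairsB, windows = c(1e5, 2e5, 1e6),
                           genetic_distance = NA_real_,
                           method = c("pearson", "spearman")) {
  method <- match.arg(method)
  key_a <- paste(pairsA$snp_i, pairsA$snp_j, sep = "|")
  key_b <- paste(pairsB$snp_i, pairsB$snp_j, sep = "|")
  idx <- match(key_a, key_b)
  shared <- !is.na(idx)
  out <- list()
  for (w in windows) {
    sel <- shared & pairsA$d < w
    n_pairs <- sum(sel)
    if (n_pairs < 2L) {
      message("ld_consistency: < 2 shared pairs below ", w, " bp; omitted")
      next
    }
    out[[length(out) + 1L]] <-
      data.frame(window = w,
                 r_ld = stats::cor(pairsA$r2[sel], pairsB$r2[idx[sel]],
                                   method = method),
                 n_pairs = n_pairs, genetic_distance = genetic_distance)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(window = numeric(0), r_ld = numeric(0),
               n_pairs = integer(0), genetic_distance = numeric(0))
}
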