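#' Presence/absence encoding of a genotype panel
#'
#' Each allele of each SNP is scored 1 (present) or 0 (absent), giving two
#' columns per SNP: AA -> (1, 0), AB -> (1, 1), BB -> (0, 1). Missing calls
#' leave both columns \code{NA} until \code{\link{impute_mean}} fills them.
#' This is the multivariate input for PCA and clustering.
#'
#' @param panel a \code{\link{genotype_panel}}.
#' @return an object of class \code{encoded_matrix}: list with
#'   \code{values} (n_samples x 2*n_snps numeric matrix, columns named
#'   \code{<snp_id>.A} / \code{<snp_id>.B}) and \code{column_map}
#'   (data.frame snp_id, allele, column).
#' @export
encode_presence <- function(panel) {
  calls <- panel$calls
  n <- nrow(calls)
  m <- ncol(calls)
  a_col <- matrix(NA_real_, n, m)
  b_col <- matrix(NA_real_, n, m)
  a_col[calls %in% c("AA", "AB")] <- 1
  a_col[calls == "BB"] <- 0
  b_col[calls %in% c("BB", "AB")] <- 1
  b_col[calls == "AA"] <- 0
  values <- matrix(NA_real_, n, 2L * m)
  values[, seq(1L, 2L * m, by = 2L)] <- a_col
  values[, seq(2L, 2L * m, by = 2L)] <- b_col
  snp_ids <- panel$snps$snp_id
  colnames(values) <- as.vector(rbind(paste0(snp_ids, ".A"),
                                      paste0(snp_ids, ".B")))
  rownames(values) <- panel$samples$sample_id
  column_map <- data.frame(snp_id = rep(snp_ids, each = 2L),
                           allele = rep(c("A", "B"), m),
                           column = seq_len(2L * m),
                           stringsAsFactors = FALSE)
  structure(list(values = values, column_map = column_map),
            class = "encoded_matrix")
}

#' @export
print.encoded_matrix <- function(x, ...) {
  cat("encoded_matrix: ", nrow(x$values), " samples x ", ncol(x$values),
      " allele columns (", sum(is.na(x$values)), " missing entries)\n",
      sep = "")
  invisible(x)
}

#' Mean imputation of missing encoded values
#'
#' Missing entries of the presence/absence matrix are replaced by the
#' non-missing mean of their column (the marker's mean across all
#' individuals); observed entries are untouched, so column means are
#' invariant under imputation.
#'
#' @param encoded an \code{encoded_matrix} from \code{\link{encode_presence}}.
#' @return an \code{encoded_matrix} with no missing values.
#' @export
impute_mean <- function(encoded) {
  v <- encoded$values
  mu <- colMeans(v, na.rm = TRUE)
  all_missing <- !is.finite(mu)
  if (any(all_missing)) {
    snp <- unique(encoded$column_map$snp_id[all_missing])
    stop("cannot impute: no non-missing calls for SNP(s) ",
         paste(utils::head(snp, 5L), collapse = ", "))
  }
  idx <- which(is.na(v), arr.ind = TRUE)
  if (nrow(idx)) v[idx] <- mu[idx[, 2L]]
  encoded$values <- v
  encoded
}

#' Per-population allele frequencies
#'
#' Under the collapsed three-class coding every sample is treated as
#' diploid-equivalent regardless of ploidy:
#' freq(A) = (2 n_AA + n_AB) / (2 n_called) per locus per group. For
#' collapsed tetraploids this biases frequencies toward 0.5 (dosage is
#' unobservable after collapse); that convention is deliberate and matches
#' the three-class scoring of mixed panels.
#'
#' @param panel a \code{\link{genotype_panel}}.
#' @param grouping either a character vector of labels (one per sample) or
#'   the name of a sample-metadata column (default \code{"population"}).
#' @return object of class \code{freq_table}: list with \code{freq_a}
#'   (groups x SNPs matrix; \code{NA} where a group has no called sample at
#'   a locus), \code{n_called} (same shape), \code{groups}, \code{snp_id}.
#' @export
allele_freqs <- function(panel, grouping = "population") {
  labels <- resolve_grouping(panel, grouping)
  groups <- sort(unique(labels))
  m <- ncol(panel$calls)
  freq_a <- matrix(NA_real_, length(groups), m,
                   dimnames = list(groups, panel$snps$snp_id))
  n_called <- matrix(0L, length(groups), m,
                     dimnames = list(groups, panel$snps$snp_id))
  for (g in seq_along(groups)) {
    sub <- panel$calls[labels == groups[g], , drop = FALSE]
    n_aa <- colSums(sub == "AA", na.rm = TRUE)
    n_ab <- colSums(sub == "AB", na.rm = TRUE)
    n_bb <- colSums(sub == "BB", na.rm = TRUE)
    called <- n_aa + n_ab + n_bb
    n_called[g, ] <- called
    ok <- called > 0L
    freq_a[g, ok] <- (2 * n_aa[ok] + n_ab[ok]) / (2 * called[ok])
  }
  structure(list(freq_a = freq_a, n_called = n_called, groups = groups,
                 snp_id = panel$snps$snp_id),
            class = "freq_table")
}

resolve_grouping <- function(panel, grouping) {
  if (length(grouping) == 1L && is.character(grouping) &&
      grouping %in% names(panel$samples)) {
    labels <- as.character(panel$samples[[grouping]])
  } else {
    labels <- as.character(grouping)
    if (length(labels) != nrow(panel$samples))
      stop("grouping must name a sample column or give one label per sample")
  }
  if (anyNA(labels)) stop("grouping labels contain NA")
  labels
}

#' Per-sample call rate and heterozygosity
#'
#' Heterozygosity is the percentage of a sample's non-missing calls that
#' are heterozygous (AB). Under the collapsed coding, tetraploids at
#' Hardy-Weinberg frequency p carry expected H = 100 (1 - p^4 - (1-p)^4)
#' versus 100 (1 - p^2 - (1-p)^2) for diploids, so tetraploid panels show
#' markedly higher H at the same allele frequencies.
#'
#' @param panel a \code{\link{genotype_panel}}.
#' @return data.frame with columns \code{sample_id}, \code{call_rate} (in
#'   [0, 1]) and \code{het_pct} (percentage; \code{NA} when no call).
#' @export
sample_qc <- function(panel) {
  calls <- panel$calls
  n_called <- rowSums(!is.na(calls))
  n_ab <- rowSums(calls == "AB", na.rm = TRUE)
  data.frame(sample_id = panel$samples$sample_id,
             call_rate = n_called / ncol(calls),
             het_pct = ifelse(n_called > 0L, 100 * n_ab / n_called, NA_real_),
             stringsAsFactors = FALSE)
}

#' Polymorphic-SNP counts within and shared between clusters
#'
#' A SNP is polymorphic within a cluster iff at least two distinct
#' non-missing calls occur among that cluster's samples. Counts are
#' reported per Venn cell: for every non-empty subset of clusters, the
#' number of SNPs polymorphic in exactly that subset. Cells sum to the
#' total number of SNPs polymorphic anywhere.
#'
#' @param panel a \code{\link{genotype_panel}}.
#' @param clusters grouping as in \code{\link{allele_freqs}}.
#' @return list with \code{per_cluster} (named integer vector of
#'   within-cluster polymorphic counts) and \code{venn} (data.frame
#'   \code{clusters} = "+"-joined subset label, \code{n_snps}).
#' @export
polymorphism_sharing <- function(panel, clusters = "population") {
  labels <- resolve_grouping(panel, clusters)
  groups <- sort(unique(labels))
  if (length(groups) < 2L) stop("need >= 2 clusters")
  poly <- vapply(groups, function(g) {
    sub <- panel$calls[labels == g, , drop = FALSE]
    apply(sub, 2L, function(col) length(unique(col[!is.na(col)])) >= 2L)
  }, logical(ncol(panel$calls)))
  per_cluster <- colSums(poly)
  membership <- apply(poly, 1L, function(row) {
    paste(groups[row], collapse = "+")
  })
  membership <- membership[membership != ""]
  venn <- as.data.frame(table(membership), stringsAsFactors = FALSE)
  names(venn) <- c("clusters", "n_snps")
  venn$n_snps <- as.integer(venn$n_snps)
  list(per_cluster = per_cluster, venn = venn)
}

#' Filter SNPs on minor allele frequency
#'
#' Removes SNPs whose minor allele frequency, computed over the analysis
#' group under the diploid-equivalent coding, is strictly below
#' \code{threshold}; a SNP at exactly the threshold is retained. The
#' default reproduces the usual exclusion of MAF < 5\% SNPs before LD
#' estimation. The number removed is attached as attribute
#' \code{n_removed} and reported via \code{message()}.
#'
#' @param panel a \code{\link{genotype_panel}}.
#' @param threshold MAF threshold (default 0.05).
#' @param group optional character vector of sample_ids (or logical/integer
#'   index) restricting the samples over which MAF is computed and which
#'   are kept; default all samples.
#' @return the filtered \code{\link{genotype_panel}}.
#' @export
maf_filter <- function(panel, threshold = 0.05, group = NULL) {
  if (!is.null(group)) panel <- panel[group, ]
  ft <- allele_freqs(panel, rep("all", n_samples(panel)))
  f <- ft$freq_a[1L, ]
  maf <- pmin(f, 1 - f)
  keep <- !is.na(maf) & maf >= threshold
  removed <- sum(!keep)
  message("maf_filter: removed ", removed, " of ", length(keep),
          " SNPs (MAF < ", threshold, " or no calls)")
  out <- panel[, keep]
  attr(out, "n_removed") <- removed
  out
}
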