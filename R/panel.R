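#' Genotype calls used throughout the package
#'
#' All genotypes are stored as collapsed three-class calls: \code{"AA"},
#' \code{"AB"}, \code{"BB"}, with \code{NA} for missing. Tetraploid dosage
#' classes are never stored; any heterozygous dosage (simplex, duplex,
#' triplex) is collapsed to \code{"AB"} at ingest, which makes tetraploid
#' data diploid-like for every downstream computation.
#'
#' @name genotype-calls
#' @keywords internal
NULL

CALL_LEVELS <- c("AA", "AB", "BB")
MISSING_TOKEN <- "--"

#' Construct a genotype panel
#'
#' A \code{genotype_panel} is the universal currency of the pipeline: a
#' samples-by-SNPs matrix of collapsed three-class genotype calls together
#' with per-sample metadata (ploidy, population label, optional cluster
#' label) and per-SNP metadata (chromosome, 1-based bp position on a
#' reference, alleles).
#'
#' @param calls character matrix, \code{n_samples x n_snps}, entries
#'   \code{"AA"}, \code{"AB"}, \code{"BB"} or \code{NA} (missing).
#' @param samples data.frame with columns \code{sample_id}, \code{ploidy}
#'   (2 or 4), \code{population}; an optional \code{cluster} column is
#'   added (as \code{NA}) if absent.
#' @param snps data.frame with columns \code{snp_id}, \code{chrom},
#'   \code{pos} (1-based bp; \code{NA} allowed for unplaced SNPs, which are
#'   excluded from LD), \code{allele_a}, \code{allele_b}.
#' @return an object of class \code{genotype_panel}.
#' @examples
#' calls <- matrix(c("AA", "AB", "BB", NA), nrow = 2,
#'                 dimnames = list(c("s1", "s2"), c("snp1", "snp2")))
#' samples <- data.frame(sample_id = c("s1", "s2"), ploidy = c(2L, 4L),
#'                       population = "p1")
#' snps <- data.frame(snp_id = c("snp1", "snp2"), chrom = "chr1",
#'                    pos = c(100L, 5000L), allele_a = "A", allele_b = "G")
#' genotype_panel(calls, samples, snps)
#' @export
genotype_panel <- function(calls, samples, snps) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  if (!is.matrix(calls) || !is.character(calls))
    stop("'calls' must be a character matrix")
  need_s <- c("sample_id", "ploidy", "population")
  if (!all(need_s %in% names(samples)))
    stop("'samples' must have columns: ", paste(need_s, collapse = ", "))
  need_m <- c("snp_id", "chrom", "pos", "allele_a", "allele_b")
  if (!all(need_m %in% names(snps)))
    stop("'snps' must have columns: ", paste(need_m, collapse = ", "))
  if (!("cluster" %in% names(samples))) samples$cluster <- NA_character_
  if (nrow(calls) != nrow(samples))
    stop("dimension mismatch: ", nrow(calls), " call rows vs ",
         nrow(samples), " sample records")
  if (ncol(calls) != nrow(snps))
    stop("dimension mismatch: ", ncol(calls), " call columns vs ",
         nrow(snps), " SNP records")
  if (anyDuplicated(samples$sample_id))
    stop("duplicated sample_id: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "))
  if (anyDuplicated(snps$snp_id))
    stop("duplicated snp_id: ",
         paste(unique(snps$snp_id[duplicated(snps$snp_id)]), collapse = ", "))
  if (!all(samples$ploidy %in% c(2L, 4L)))
    stop("ploidy must be 2 or 4")
  bad <- !is.na(calls) & !(calls %in% CALL_LEVELS)
  if (any(bad))
    stop("illegal call token(s): ", paste(unique(calls[bad]), collapse = ", "))
  pos_ok <- is.na(snps$pos) | snps$pos >= 1
  if (!all(pos_ok)) stop("SNP positions must be >= 1 (1-based)")
  if (any(!is.na(snps$allele_a) & !is.na(snps$allele_b) &
          snps$allele_a == snps$allele_b))
    stop("allele_a and allele_b must differ")
  dimnames(calls) <- list(samples$sample_id, snps$snp_id)
  structure(list(calls = calls, samples = samples, snps = snps),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  miss <- mean(is.na(x$calls))
  cat("genotype_panel: ", nrow(x$calls), " samples x ", ncol(x$calls),
      " SNPs\n", sep = "")
  pl <- table(x$samples$ploidy)
  cat("  ploidy: ", paste0(names(pl), "x:", as.integer(pl), collapse = " "),
      "\n", sep = "")
  cat("  populations: ", paste(sort(unique(x$samples$population)),
      collapse = ", "), "\n", sep = "")
  cat("  missing calls: ", sprintf("%.2f%%", 100 * miss), "\n", sep = "")
  invisible(x)
}

#' Number of samples / SNPs in a panel
#' @param panel a \code{genotype_panel}
#' @return integer count
#' @export
n_samples <- function(panel) nrow(panel$calls)

#' @rdname n_samples
#' @export
n_snps <- function(panel) ncol(panel$calls)

#' Subset a panel by samples and/or SNPs
#'
#' @param x a \code{genotype_panel}
#' @param i sample index (logical, integer or sample_id character)
#' @param j SNP index (logical, integer or snp_id character)
#' @param ... ignored
#' @return a \code{genotype_panel}
#' @export
`[.genotype_panel` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$calls))
  if (missing(j)) j <- seq_len(ncol(x$calls))
  if (is.character(i)) i <- match(i, x$samples$sample_id)
  if (is.character(j)) j <- match(j, x$snps$snp_id)
  genotype_panel(x$calls[i, j, drop = FALSE],
                 x$samples[i, , drop = FALSE],
                 x$snps[j, , drop = FALSE])
}

#' Collapse a multiset of allele dosages to a three-class call
#'
#' Pure function of the allele multiset: all-reference is \code{"AA"},
#' all-alternate is \code{"BB"}, any mixture is \code{"AB"} (the tetraploid
#' simplex/duplex/triplex classes AAAB, AABB, ABBB all collapse to AB). Any
#' missing allele yields \code{NA}.
#'
#' @param alleles integer vector of 0 (allele A) / 1 (allele B) dosages,
#'   length = ploidy; \code{NA} marks a missing allele.
#' @return \code{"AA"}, \code{"AB"}, \code{"BB"} or \code{NA_character_}
#' @export
collapse_dosage <- function(alleles) {
  if (anyNA(alleles)) return(NA_character_)
  b <- sum(alleles)
  if (b == 0L) "AA" else if (b == length(alleles)) "BB" else "AB"
}
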