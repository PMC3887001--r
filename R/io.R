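#' Read a genotype panel from the package's TSV dialect
#'
#' The calls file has a header line
#' \code{sample_id<TAB>ploidy<TAB>population<TAB><snp_id_1>...<snp_id_n>}
#' and one row per sample; calls are \code{AA}/\code{AB}/\code{BB} and
#' missing is \code{--}. A companion SNP map TSV holds
#' \code{snp_id<TAB>chrom<TAB>pos<TAB>allele_a<TAB>allele_b}; unplaced SNPs
#' use \code{--} in the \code{chrom}/\code{pos} columns.
#'
#' @param calls_path path to the calls TSV.
#' @param map_path path to the SNP map TSV; defaults to the calls path with
#'   \code{.tsv} replaced by \code{.map.tsv}.
#' @return a \code{\link{genotype_panel}} whose calls round-trip bit-exactly
#'   through \code{\link{write_panel_tsv}}.
#' @seealso \code{\link{write_panel_tsv}}, \code{\link{read_panel_vcf}}
#' @export
read_panel_tsv <- function(calls_path, map_path = default_map_path(calls_path)) {
  lines <- readLines(calls_path)
  if (length(lines) < 1L) stop("empty panel file: ", calls_path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 4L ||
      !identical(header[1:3], c("sample_id", "ploidy", "population")))
    stop("malformed header at line 1: expected ",
         "'sample_id\\tploidy\\tpopulation\\t<snp ids>'")
  snp_ids <- header[-(1:3)]
  body <- lines[-1L]
  body <- body[nzchar(body)]
  n <- length(body)
  calls <- matrix(NA_character_, n, length(snp_ids))
  samples <- data.frame(sample_id = character(n), ploidy = integer(n),
                        population = character(n), stringsAsFactors = FALSE)
  for (k in seq_len(n)) {
    fields <- strsplit(body[[k]], "\t", fixed = TRUE)[[1L]]
    lineno <- k + 1L
    if (length(fields) != length(header))
      stop("line ", lineno, ": expected ", length(header), " fields, got ",
           length(fields))
    pl <- suppressWarnings(as.integer(fields[2L]))
    if (is.na(pl) || !(pl %in% c(2L, 4L)))
      stop("line ", lineno, ": illegal ploidy '", fields[2L], "'")
    samples$sample_id[k] <- fields[1L]
    samples$ploidy[k] <- pl
    samples$population[k] <- fields[3L]
    toks <- fields[-(1:3)]
    bad <- !(toks %in% c(CALL_LEVELS, MISSING_TOKEN))
    if (any(bad))
      stop("line ", lineno, ": illegal call token '", toks[which(bad)[1L]], "'")
    toks[toks == MISSING_TOKEN] <- NA_character_
    calls[k, ] <- toks
  }
  if (anyDuplicated(samples$sample_id))
    stop("duplicated sample_id in ", calls_path)
  map <- utils::read.table(map_path, header = TRUE, sep = "\t",
                           colClasses = "character", na.strings = MISSING_TOKEN,
                           stringsAsFactors = FALSE)
  need <- c("snp_id", "chrom", "pos", "allele_a", "allele_b")
  if (!all(need %in% names(map)))
    stop("malformed SNP map header in ", map_path)
  map$pos <- suppressWarnings(as.integer(map$pos))
  idx <- match(snp_ids, map$snp_id)
  if (anyNA(idx))
    stop("SNP map is missing entries for: ",
         paste(utils::head(snp_ids[is.na(idx)], 5L), collapse = ", "))
  genotype_panel(calls, samples, map[idx, need])
}

#' Companion SNP-map path for a calls TSV
#'
#' @param calls_path path to a panel calls TSV.
#' @return the conventional map path (\code{.tsv} -> \code{.map.tsv}).
#' @export
default_map_path <- function(calls_path) sub("\\.tsv$", ".map.tsv", calls_path)

#' Write a genotype panel to the package's TSV dialect
#'
#' @param panel a \code{\link{genotype_panel}}.
#' @param calls_path output path for the calls TSV.
#' @param map_path output path for the SNP map TSV.
#' @return invisibly, the calls path.
#' @export
write_panel_tsv <- function(panel, calls_path,
                            map_path = default_map_path(calls_path)) {
  calls <- panel$calls
  calls[is.na(calls)] <- MISSING_TOKEN
  header <- paste(c("sample_id", "ploidy", "population", panel$snps$snp_id),
                  collapse = "\t")
  rows <- vapply(seq_len(nrow(calls)), function(i) {
    paste(c(panel$samples$sample_id[i], panel$samples$ploidy[i],
            panel$samples$population[i], calls[i, ]), collapse = "\t")
  }, character(1L))
  writeLines(c(header, rows), calls_path)
  map <- panel$snps[, c("snp_id", "chrom", "pos", "allele_a", "allele_b")]
  map_lines <- c(paste(names(map), collapse = "\t"),
                 vapply(seq_len(nrow(map)), function(i) {
                   f <- as.character(unlist(map[i, ], use.names = FALSE))
                   f[is.na(f)] <- MISSING_TOKEN
                   paste(f, collapse = "\t")
                 }, character(1L)))
  writeLines(map_lines, map_path)
  invisible(calls_path)
}

#' Read a genotype panel from a VCF
#'
#' Biallelic SNP records are converted to collapsed three-class calls from
#' the GT field: for diploids 0/0 -> AA, 0/1 -> AB, 1/1 -> BB, ./. ->
#' missing; for tetraploids (4-allele GT) all-0 -> AA, all-1 -> BB and any
#' mixture of 0 and 1 -> AB, so the simplex/duplex/triplex dosage classes
#' are collapsed at ingest. Multiallelic records and non-SNP (indel) ALT
#' alleles are skipped, not errored, because array panels are biallelic by
#' construction; the number skipped is reported as a warning and attached
#' as attribute \code{n_skipped}.
#'
#' @param path path to a VCF 4.x file (plain or bgzipped).
#' @param population population label(s) for the samples (VCF carries
#'   none); recycled to the number of samples.
#' @return a \code{\link{genotype_panel}}; sample ploidy is inferred from
#'   the number of alleles in each sample's GT.
#' @export
read_panel_vcf <- function(path, population = "pop1") {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (nrow(fix) == 0L) stop("no records in VCF: ", path)
  gt_all <- vcf@gt
  if (is.null(gt_all) || !("FORMAT" %in% colnames(gt_all)))
    stop("VCF has no genotype (FORMAT) section: ", path)
  has_gt <- grepl("(^|:)GT(:|$)", gt_all[, "FORMAT"])
  if (!all(has_gt)) stop("GT missing from FORMAT in VCF: ", path)
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp_ok <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    !grepl(",", alt, fixed = TRUE)
  n_skipped <- sum(!snp_ok)
  if (n_skipped > 0L)
    warning(n_skipped, " multiallelic/non-SNP record(s) skipped")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[snp_ok, , drop = FALSE]
  fix <- fix[snp_ok, , drop = FALSE]
  sample_ids <- colnames(gt)
  n_s <- length(sample_ids)
  n_m <- nrow(gt)
  calls <- matrix(NA_character_, n_s, n_m)
  ploidy <- rep(NA_integer_, n_s)
  for (j in seq_len(n_s)) {
    toks <- strsplit(gt[, j], "[/|]")
    len <- lengths(toks)
    pl <- max(len, na.rm = TRUE)
    if (!(pl %in% c(2L, 4L)))
      stop("sample ", sample_ids[j], ": GT ploidy ", pl, " not in {2, 4}")
    ploidy[j] <- pl
    calls[j, ] <- vapply(toks, function(a) {
      collapse_dosage(suppressWarnings(as.integer(a)))
    }, character(1L))
  }
  ids <- fix[, "ID"]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix[no_id, "CHROM"], "_", fix[no_id, "POS"])
  snps <- data.frame(snp_id = ids, chrom = fix[, "CHROM"],
                     pos = as.integer(fix[, "POS"]),
                     allele_a = fix[, "REF"], allele_b = fix[, "ALT"],
                     stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = sample_ids, ploidy = ploidy,
                        population = rep_len(population, n_s),
                        stringsAsFactors = FALSE)
  panel <- genotype_panel(calls, samples, snps)
  attr(panel, "n_skipped") <- n_skipped
  panel
}

#' Serialize a tree to Newick text
#'
#' @param tree an \code{ape} \code{phylo} object, e.g. from
#'   \code{\link{neighbor_joining}}.
#' @param path optional file path; when given the text is also written there.
#' @return the Newick string (with branch lengths), invisibly when
#'   \code{path} is given.
#' @export
write_newick <- function(tree, path = NULL) {
  if (is.null(tree) || !inherits(tree, "phylo") || length(tree$tip.label) == 0L)
    stop("empty tree")
  txt <- ape::write.tree(tree)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
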