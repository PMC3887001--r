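#' Read a flat key = value run configuration
#'
#' The run configuration is a plain-text file of \code{key = value} lines
#' (\code{#} comments and blank lines ignored) — diff-able provenance that
#' is echoed verbatim into every output directory. List-valued keys use
#' commas (e.g. \code{ploidy_per_pop = 4,4,2}).
#'
#' Recognised keys and defaults come from \code{\link{default_run_config}};
#' an unknown key is an error naming the key.
#'
#' @param path path to the config file.
#' @return a named list merging the file over the defaults.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- default_run_config()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 1L) stop("malformed config line: '", ln, "'")
    key <- trimws(substr(ln, 1L, eq - 1L))
    val <- trimws(substr(ln, eq + 1L, nchar(ln)))
    if (!nzchar(key)) stop("malformed config line: '", ln, "'")
    if (!(key %in% names(cfg))) stop("unknown config key: '", key, "'")
    proto <- cfg[[key]]
    if (!nzchar(val)) next
    cfg[[key]] <- if (is.character(proto)) {
      if (grepl(",", val)) trimws(strsplit(val, ",")[[1L]]) else val
    } else if (is.integer(proto)) {
      as.integer(strsplit(val, ",")[[1L]])
    } else {
      as.numeric(strsplit(val, ",")[[1L]])
    }
  }
  cfg
}

#' Default run configuration
#'
#' @return named list of every recognised run-config key with its default.
#' @export
default_run_config <- function() {
  list(panel = "",              # calls TSV for analyze (map alongside)
       n_e = 100L, n_loci = 200L, chrom_length = 1e6, rec_rate = 1e-7,
       n_generations = 400L, n_subpops = 3L, split_generation = 200L,
       founder_freq_low = 0.1, founder_freq_high = 0.9,
       samples_per_pop = 30L, ploidy_per_pop = c(4L, 4L, 2L),
       missing_rate = 0.01,
       maf = 0.05, n_pcs = 5L, k_min = 1L, k_max = 8L,
       r2_target = 0.2, max_d = 1e6, windows = c(1e5, 2e5, 1e6),
       variant = "sved",
       stages = c("qc", "structure", "ld", "consistency"),
       seed = 1L)
}

echo_config <- function(cfg, out_dir) {
  lines <- vapply(names(cfg), function(k) {
    paste0(k, " = ", paste(cfg[[k]], collapse = ","))
  }, character(1L))
  writeLines(lines, file.path(out_dir, "config_echo.txt"))
}

make_logger <- function(out_dir) {
  log_path <- file.path(out_dir, "run.log")
  function(...) {
    msg <- paste0(...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    message(msg)
  }
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Simulate a structured panel to disk
#'
#' Thin wrapper over \code{\link{simulate_wf}} / \code{\link{sample_panel}}
#' that writes the panel TSV + SNP map, the per-subpopulation truth
#' haplotype matrices, and a verbatim config echo, so a run is
#' reproducible from the output directory alone.
#'
#' @param config named list as from \code{\link{read_run_config}} (missing
#'   keys take defaults).
#' @param out_dir output directory, created if needed.
#' @return invisibly, a list with the panel and truth objects and file
#'   paths.
#' @export
pipeline_simulate <- function(config = list(), out_dir) {
  cfg <- utils::modifyList(default_run_config(), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- make_logger(out_dir)
  sc <- sim_config(n_e = cfg$n_e, n_loci = cfg$n_loci,
                   chrom_length = cfg$chrom_length, rec_rate = cfg$rec_rate,
                   n_generations = cfg$n_generations,
                   n_subpops = cfg$n_subpops,
                   split_generation = cfg$split_generation,
                   founder_freq_low = cfg$founder_freq_low,
                   founder_freq_high = cfg$founder_freq_high,
                   samples_per_pop = cfg$samples_per_pop,
                   ploidy_per_pop = cfg$ploidy_per_pop,
                   missing_rate = cfg$missing_rate, seed = cfg$seed)
  log("simulate: Wright-Fisher, n_e = ", sc$n_e, ", ", sc$n_loci,
      " loci, K = ", sc$n_subpops, ", seed = ", sc$seed)
  truth <- simulate_wf(sc)
  panel <- sample_panel(truth, sc)
  calls_path <- file.path(out_dir, "panel.tsv")
  write_panel_tsv(panel, calls_path)
  for (k in seq_along(truth$pools)) {
    hp <- file.path(out_dir,
                    paste0("truth_haplotypes_", names(truth$pools)[k], ".tsv"))
    utils::write.table(truth$pools[[k]], hp, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = truth$snp_id)
  }
  echo_config(cfg, out_dir)
  log("simulate: wrote ", n_samples(panel), " samples x ", n_snps(panel),
      " SNPs to ", calls_path)
  invisible(list(panel = panel, truth = truth, calls_path = calls_path))
}

#' Run the analysis pipeline on a panel
#'
#' Orchestrates preprocess -> PCA -> GMM/BIC clustering -> Nei distances ->
#' neighbor-joining -> LD -> decay fits -> cross-population consistency,
#' per the stage toggles in the config. Every numeric output lands in a
#' TSV under \code{out_dir}; \code{run.log} records seeds and the
#' input/output counts of every filter, which reconcile exactly with the
#' input size.
#'
#' @param config named list as from \code{\link{read_run_config}}; either
#'   \code{config$panel} names a calls TSV or \code{panel} is given
#'   directly.
#' @param out_dir output directory, created if needed.
#' @param panel optional \code{\link{genotype_panel}} (overrides
#'   \code{config$panel}).
#' @return invisibly, a list of the stage results.
#' @export
pipeline_analyze <- function(config = list(), out_dir, panel = NULL) {
  cfg <- utils::modifyList(default_run_config(), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- make_logger(out_dir)
  if (is.null(panel)) {
    if (!nzchar(cfg$panel)) stop("no panel: set config$panel or pass one")
    if (!file.exists(cfg$panel)) stop("panel file not found: ", cfg$panel)
    panel <- read_panel_tsv(cfg$panel)
  }
  echo_config(cfg, out_dir)
  log("analyze: ", n_samples(panel), " samples x ", n_snps(panel),
      " SNPs; stages: ", paste(cfg$stages, collapse = ", "),
      "; seed = ", cfg$seed)
  res <- list(panel = panel)
  pops <- sort(unique(panel$samples$population))

  if ("qc" %in% cfg$stages) {
    qc <- sample_qc(panel)
    write_tsv(qc, file.path(out_dir, "qc_report.tsv"))
    log("qc: mean call rate ", sprintf("%.4f", mean(qc$call_rate)),
        ", mean heterozygosity ",
        sprintf("%.1f%%", mean(qc$het_pct, na.rm = TRUE)))
    if (length(pops) >= 2L) {
      ps <- polymorphism_sharing(panel, "population")
      write_tsv(ps$venn, file.path(out_dir, "venn_counts.tsv"))
      log("qc: ", sum(ps$venn$n_snps), " SNPs polymorphic in >= 1 population")
    }
    res$qc <- qc
  }

  if ("structure" %in% cfg$stages) {
    enc <- impute_mean(encode_presence(panel))
    pca <- panel_pca(enc, n_components = cfg$n_pcs)
    write_tsv(data.frame(sample_id = panel$samples$sample_id, pca$scores),
              file.path(out_dir, "pca_scores.tsv"))
    log("structure: first ", ncol(pca$scores), " PCs explain ",
        sprintf("%.1f%%", 100 * pca$total_explained), " of total variance")
    gmm <- fit_gmm_bic(pca$scores, K_range = cfg$k_min:cfg$k_max,
                       seed = cfg$seed)
    log("structure: BIC selects K = ", gmm$K, " (", gmm$covariance_model,
        " covariance)")
    clusters <- paste0("C", gmm$assignments)
    panel$samples$cluster <- clusters
    write_tsv(data.frame(sample_id = panel$samples$sample_id,
                         population = panel$samples$population,
                         cluster = clusters),
              file.path(out_dir, "cluster_assignments.tsv"))
    groups <- if (length(unique(clusters)) >= 2L) clusters else
      panel$samples$population
    ft <- allele_freqs(panel, groups)
    D <- nei_distance_matrix(ft)
    write_tsv(data.frame(group = rownames(D), D, check.names = FALSE),
              file.path(out_dir, "nei_distances.tsv"))
    if (nrow(D) >= 3L && all(is.finite(D))) {
      tree <- neighbor_joining(D)
      write_newick(tree, file.path(out_dir, "tree.nwk"))
      log("structure: wrote NJ tree over ", nrow(D), " groups")
    }
    res$pca <- pca
    res$gmm <- gmm
    res$nei <- D
  }

  if ("ld" %in% cfg$stages) {
    ld_by_pop <- list()
    fits <- list()
    for (p in pops) {
      keep <- panel$samples$population == p
      pairs <- withCallingHandlers(
        compute_ld(panel, group = keep, maf = cfg$maf, max_d = cfg$max_d),
        message = function(m) {
          log("ld[", p, "]: ", trimws(conditionMessage(m)))
          invokeRestart("muffleMessage")
        })
      write_tsv(pairs, file.path(out_dir, paste0("ld_", p, ".tsv")))
      log("ld[", p, "]: ", nrow(pairs), " pairs")
      ld_by_pop[[p]] <- pairs
      if (nrow(pairs) >= 10L) {
        fit <- ld_decay_fit(pairs, variant = cfg$variant,
                            r2_targets = cfg$r2_target)
        fits[[p]] <- data.frame(population = p, variant = fit$variant,
                                a = fit$a, rss = fit$rss,
                                d_at = fit$d_at[[1L]])
        log("ld[", p, "]: a = ", signif(fit$a, 4), ", d_at(r2 = ",
            cfg$r2_target, ") = ", sprintf("%.1f Kbp", fit$d_at[[1L]] / 1e3))
      }
    }
    if (length(fits))
      write_tsv(do.call(rbind, fits), file.path(out_dir, "decay_fits.tsv"))
    res$ld <- ld_by_pop
    res$decay <- fits
  }

  if ("consistency" %in% cfg$stages && length(pops) >= 2L) {
    if (is.null(res$ld)) stop("consistency stage needs the ld stage")
    ft_pop <- allele_freqs(panel, "population")
    rows <- list()
    for (i in seq_along(pops)) {
      for (j in seq_len(i - 1L)) {
        cp <- ld_consistency(res$ld[[pops[j]]], res$ld[[pops[i]]],
                             windows = cfg$windows,
                             genetic_distance =
                               nei_distance(ft_pop, pops[j], pops[i]))
        if (nrow(cp)) {
          cp$pop_a <- pops[j]
          cp$pop_b <- pops[i]
          rows[[length(rows) + 1L]] <- cp
        }
      }
    }
    if (length(rows)) {
      cons <- do.call(rbind, rows)
      write_tsv(cons, file.path(out_dir, "consistency.tsv"))
      log("consistency: ", nrow(cons), " (pair, window) points")
      res$consistency <- cons
    }
  }
  invisible(res)
}
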