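#' Run configuration for the scan/associate pipeline
#'
#' @param cohort_root Directory with the per-group alignment layout.
#' @param metadata_path,immunity_path Paths to the metadata and immunity
#'   tables.
#' @param annotations_path Optional gene-annotation table (gene_id,
#'   category).
#' @param out_dir Output directory.
#' @param group_threshold Deviation cutoff for group flagging
#'   (default 0.009).
#' @param gene_mode,gene_level Gene-scan flagging mode and level (defaults
#'   "percentile", 90).
#' @param fisher_sided Sidedness of Fisher tests (default "two").
#' @param immunity_cutoffs Frequency cutoffs for the immunity association
#'   sweep (default c(0.8, 0.7, 0.6)).
#' @return List of class `phg_run_config`.
#' @export
run_config <- function(cohort_root, metadata_path = NULL,
                       immunity_path = NULL, annotations_path = NULL,
                       out_dir = "phagerecomb_out",
                       group_threshold = 0.009,
                       gene_mode = "percentile", gene_level = 90,
                       fisher_sided = "two",
                       immunity_cutoffs = c(0.8, 0.7, 0.6)) {
  structure(list(cohort_root = cohort_root, metadata_path = metadata_path,
                 immunity_path = immunity_path,
                 annotations_path = annotations_path, out_dir = out_dir,
                 group_threshold = group_threshold, gene_mode = gene_mode,
                 gene_level = gene_level, fisher_sided = fisher_sided,
                 immunity_cutoffs = immunity_cutoffs),
            class = "phg_run_config")
}

write_resolved_config <- function(config, path) {
  vals <- lapply(unclass(config), function(v) {
    if (is.null(v)) "" else paste(format(v, digits = 8, trim = TRUE),
                                  collapse = ",")
  })
  df <- data.frame(key = names(vals), value = unlist(vals),
                   stringsAsFactors = FALSE)
  write_table(df, path)
}

#' Scan a cohort: per-gene statistics, group scan, per-group gene scans
#'
#' Runs the full recombination-intensity scan: reads (or accepts) a cohort
#' of per-gene alignments, computes per-gene R_m and nucleotide diversity,
#' aggregates per group, fits the group-level regression and flags
#' recombination-intense groups, then runs the gene-level regression within
#' each flagged group. Writes `gene_stats.tsv`, `breakpoints.tsv`,
#' `group_stats.tsv`, `group_scan.tsv`, `gene_scan.tsv`, `model.json`, the
#' resolved configuration, and a key-value `run_summary.tsv`.
#'
#' @param config A [run_config()].
#' @param cohort Optional pre-loaded cohort (as from [read_cohort()] or
#'   `simulate_cohort()$cohort`); when `NULL` it is read from
#'   `config$cohort_root`.
#' @return List with gene_stats, breakpoints, group_stats, model,
#'   group_scan, gene_scan (data.frame over flagged groups), summary.
#' @export
run_scan <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "phg_run_config"))
  if (is.null(cohort)) cohort <- read_cohort(config$cohort_root)
  if (length(cohort) == 0L) stop("empty cohort: nothing to scan")
  st <- cohort_stats_all(cohort)
  gene_stats <- st$gene_stats
  breakpoints <- st$breakpoints
  group_stats <- cohort_group_stats(gene_stats)
  scan <- scan_groups(group_stats, threshold = config$group_threshold)
  flagged <- scan$records$unit_id[scan$records$flagged]
  gene_scans <- list()
  for (g in flagged) {
    gs <- scan_genes(gene_stats[gene_stats$group_id == g, , drop = FALSE],
                     mode = config$gene_mode, level = config$gene_level)
    if (!is.null(gs)) {
      gene_scans[[g]] <- data.frame(group_id = g, gs$records,
                                    stringsAsFactors = FALSE)
    }
  }
  gene_scan <- if (length(gene_scans) > 0L) {
    do.call(rbind, c(gene_scans, list(make.row.names = FALSE)))
  } else {
    data.frame(group_id = character(0), unit_id = character(0),
               y = numeric(0), x1 = numeric(0), x2 = numeric(0),
               fitted = numeric(0), deviation = numeric(0),
               flagged = logical(0), threshold_used = numeric(0))
  }
  summary <- data.frame(
    key = c("groups_read", "genes_read", "genes_usable", "groups_scanned",
            "groups_flagged", "genes_flagged"),
    value = c(length(cohort), nrow(gene_stats), sum(gene_stats$usable),
              nrow(group_stats), length(flagged), sum(gene_scan$flagged)),
    stringsAsFactors = FALSE)
  out <- list(gene_stats = gene_stats, breakpoints = breakpoints,
              group_stats = group_stats, model = scan$model,
              group_scan = scan$records, gene_scan = gene_scan,
              summary = summary)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table(gene_stats, file.path(config$out_dir, "gene_stats.tsv"))
    write_table(breakpoints, file.path(config$out_dir, "breakpoints.tsv"))
    write_table(group_stats, file.path(config$out_dir, "group_stats.tsv"))
    write_table(scan$records, file.path(config$out_dir, "group_scan.tsv"))
    write_table(gene_scan, file.path(config$out_dir, "gene_scan.tsv"))
    m <- scan$model
    jsonlite::write_json(
      list(beta0 = m$beta0, beta1 = m$beta1, beta2 = m$beta2,
           residual_sd = m$residual_sd, n_points = m$n_points,
           x2_mean = m$x2_mean, threshold = config$group_threshold),
      file.path(config$out_dir, "model.json"),
      auto_unbox = TRUE, digits = NA)
    write_resolved_config(config,
                          file.path(config$out_dir, "run_config.tsv"))
    write_table(summary, file.path(config$out_dir, "run_summary.tsv"))
  }
  out
}

#' Run the categorical association battery on scan results
#'
#' Tests (1) enrichment of flagged groups in oral samples (Fisher's exact
#' test on the flagged x oral table), (2) the association between flagged
#' groups and high host immune-system frequency, for each of the four
#' systems and each cutoff in the configured sweep, and (3) when gene
#' annotations are supplied, the chi-squared enrichment of functional
#' categories among flagged genes versus the background pan-genome. Writes
#' `associations.tsv`.
#'
#' @param config A [run_config()].
#' @param scan_result Result of [run_scan()].
#' @param metadata,immunity Optional pre-loaded tables (read from the
#'   configured paths when `NULL`).
#' @param annotations Optional data.frame (gene_id, category).
#' @return data.frame report: test, system, cutoff, a, b, c, d, statistic,
#'   df, p_value, sided.
#' @export
run_associate <- function(config, scan_result, metadata = NULL,
                          immunity = NULL, annotations = NULL) {
  stopifnot(inherits(config, "phg_run_config"))
  if (is.null(metadata)) {
    if (is.null(config$metadata_path)) stop("no metadata table configured")
    metadata <- read_group_metadata(config$metadata_path)
  }
  if (is.null(immunity)) {
    if (is.null(config$immunity_path)) stop("no immunity table configured")
    immunity <- read_immunity(config$immunity_path)
  }
  if (is.null(annotations) && !is.null(config$annotations_path)) {
    annotations <- utils::read.delim(config$annotations_path,
                                     stringsAsFactors = FALSE)
  }
  scan <- scan_result$group_scan
  rows <- list()
  enr <- test_sample_enrichment(scan, metadata, sided = config$fisher_sided)
  rows[[1L]] <- data.frame(
    test = "oral_enrichment", system = "", cutoff = NA_real_,
    a = enr$table[1, 1], b = enr$table[1, 2], c = enr$table[2, 1],
    d = enr$table[2, 2], statistic = enr$odds_ratio, df = NA_real_,
    p_value = enr$p_value, sided = config$fisher_sided,
    stringsAsFactors = FALSE)
  for (sys in c("type1", "type2", "type3", "crispr")) {
    imm <- test_immunity_association(scan, immunity, metadata, system = sys,
                                     cutoff = config$immunity_cutoffs,
                                     sided = config$fisher_sided)
    rows[[length(rows) + 1L]] <- data.frame(
      test = "immunity_association", system = imm$system,
      cutoff = imm$cutoff, a = imm$a, b = imm$b, c = imm$c, d = imm$d,
      statistic = imm$odds_ratio, df = NA_real_, p_value = imm$p_value,
      sided = imm$sided, stringsAsFactors = FALSE)
  }
  if (!is.null(annotations) && nrow(scan_result$gene_scan) > 0L) {
    enrich <- gene_category_enrichment(scan_result$gene_scan,
                                       scan_result$gene_stats, annotations)
    if (!is.null(enrich)) {
      rows[[length(rows) + 1L]] <- data.frame(
        test = "gene_category_enrichment", system = "", cutoff = NA_real_,
        a = NA_real_, b = NA_real_, c = NA_real_, d = NA_real_,
        statistic = enrich$statistic, df = enrich$df,
        p_value = enrich$p_value, sided = "two", stringsAsFactors = FALSE)
    }
  }
  report <- do.call(rbind, rows)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table(report, file.path(config$out_dir, "associations.tsv"))
  }
  report
}

#' Chi-squared enrichment of functional categories among flagged genes
#'
#' Compares category counts of flagged genes against the background counts
#' of all other genes. Categories absent from both rows are dropped; returns
#' `NULL` when fewer than two categories remain.
#'
#' @param gene_scan Gene-scan records (with group_id, unit_id, flagged).
#' @param gene_stats Full per-gene statistics table.
#' @param annotations data.frame with gene_id (or group_id + gene_id) and
#'   category.
#' @return List(statistic, df, p_value, table) or `NULL`.
#' @export
gene_category_enrichment <- function(gene_scan, gene_stats, annotations) {
  stopifnot(all(c("gene_id", "category") %in% names(annotations)))
  key_scan <- paste(gene_scan$group_id, gene_scan$unit_id, sep = "\r")
  key_all <- paste(gene_stats$group_id, gene_stats$gene_id, sep = "\r")
  if ("group_id" %in% names(annotations)) {
    key_ann <- paste(annotations$group_id, annotations$gene_id, sep = "\r")
  } else {
    key_ann <- annotations$gene_id
    key_scan <- gene_scan$unit_id
    key_all <- gene_stats$gene_id
  }
  cat_of <- annotations$category[match(key_all, key_ann)]
  flagged_keys <- key_scan[gene_scan$flagged]
  is_flagged <- key_all %in% flagged_keys
  known <- !is.na(cat_of)
  cats <- sort_c(unique(cat_of[known]))
  if (length(cats) < 2L) return(NULL)
  fl <- table(factor(cat_of[known & is_flagged], levels = cats))
  bg <- table(factor(cat_of[known & !is_flagged], levels = cats))
  keep <- (fl + bg) > 0
  fl <- as.integer(fl[keep]); bg <- as.integer(bg[keep])
  if (length(fl) < 2L || sum(fl) == 0L || sum(bg) == 0L) return(NULL)
  res <- chi_squared_2xk(fl, bg)
  res$table <- rbind(flagged = fl, background = bg)
  colnames(res$table) <- cats[keep]
  res
}

#' Simulate a cohort to disk (pipeline entry point)
#'
#' Thin wrapper over [simulate_cohort()] that always writes the on-disk
#' layout and prints a truth summary.
#'
#' @param config A [sim_config()].
#' @param dir Output directory.
#' @return The [simulate_cohort()] result, invisibly.
#' @export
run_simulate <- function(config = sim_config(), dir) {
  sim <- simulate_cohort(config, dir = dir)
  message(sprintf(
    "simulated %d groups (%d hot, %d oral), %d genes, %d crossovers -> %s",
    config$n_groups, sum(sim$group_truth$hot), sum(sim$group_truth$is_oral),
    nrow(sim$gene_truth), sum(sim$gene_truth$n_crossovers), dir))
  invisible(sim)
}
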