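#' Aggregate per-gene statistics into group-level recombination intensity
#'
#' The group response is total R_m divided by total filtered gene length
#' (summed over genes with at least four haplotypes, where R_m is defined),
#' and the diversity covariate is the unweighted mean of nucleotide
#' diversity over all usable genes.
#'
#' @param stats data.frame of gene statistics for one group (rows of
#'   [cohort_gene_stats()]).
#' @param n_individuals Number of individuals (scaffolds/haplotypes) in the
#'   group.
#' @return One-row data.frame with group_id, n_individuals, total_rmin,
#'   total_len, rmin_per_nt, mean_pi, n_genes_used — or `NULL` when the
#'   group has no usable gene (caller logs the exclusion).
#' @export
aggregate_group <- function(stats, n_individuals) {
  usable <- stats[stats$usable, , drop = FALSE]
  if (nrow(usable) == 0L) return(NULL)
  contrib <- usable[usable$n_seqs >= 4L, , drop = FALSE]
  if (nrow(contrib) == 0L || sum(contrib$L) == 0L) return(NULL)
  data.frame(
    group_id = usable$group_id[1L],
    n_individuals = n_individuals,
    total_rmin = sum(contrib$rmin),
    total_len = sum(contrib$L),
    rmin_per_nt = sum(contrib$rmin) / sum(contrib$L),
    mean_pi = mean(usable$pi),
    n_genes_used = nrow(usable),
    stringsAsFactors = FALSE
  )
}

#' Group-level statistics for a whole cohort
#'
#' @param gene_stats data.frame from [cohort_gene_stats()].
#' @return data.frame with one row per group that has at least one usable
#'   gene; groups with none are dropped with a message. n_individuals is the
#'   maximum sequence count over the group's genes (every member scaffold
#'   contributes to at least the core genes).
#' @export
cohort_group_stats <- function(gene_stats) {
  rows <- list()
  for (g in sort_c(unique(gene_stats$group_id))) {
    gs <- gene_stats[gene_stats$group_id == g, , drop = FALSE]
    rec <- aggregate_group(gs, n_individuals = max(gs$n_seqs))
    if (is.null(rec)) {
      message("group ", g, " excluded: no usable gene with >= 4 sequences")
    } else {
      rows[[length(rows) + 1L]] <- rec
    }
  }
  if (length(rows) == 0L) {
    stop("no group with usable genes")
  }
  do.call(rbind, rows)
}

#' Fit the recombination-intensity regression
#'
#' Ordinary least squares for y = b0 + b1 * x1 + b2 * x2 + e, where y is
#' R_m per nucleotide, x1 is nucleotide diversity and x2 the number of
#' individuals (group level) or aligned sequences (gene level). The model
#' captures the mechanical dependence of detectable recombination on
#' polymorphism and sample size, so that residuals isolate excess
#' recombination intensity.
#'
#' @param points data.frame with columns y, x1, x2.
#' @return List of class `phg_regression` with beta0, beta1, beta2,
#'   n_points, residual_sd, x2_mean.
#' @export
fit_regression <- function(points) {
  stopifnot(all(c("y", "x1", "x2") %in% names(points)))
  if (nrow(points) < 4L) {
    stop("regression needs at least 4 points, got ", nrow(points))
  }
  fit <- stats::lm(y ~ x1 + x2, data = points)
  beta <- stats::coef(fit)
  if (anyNA(beta) || fit$rank < 3L) {
    stop("rank-deficient design: x1 and/or x2 constant or collinear")
  }
  res <- stats::residuals(fit)
  structure(
    list(beta0 = unname(beta[1L]), beta1 = unname(beta[2L]),
         beta2 = unname(beta[3L]), n_points = nrow(points),
         residual_sd = stats::sd(res), x2_mean = mean(points$x2)),
    class = "phg_regression"
  )
}

#' @export
print.phg_regression <- function(x, ...) {
  cat(sprintf(
    "<phg_regression> y = %.6g + %.6g*x1 + %.6g*x2  (n = %d, residual sd = %.4g)\n",
    x$beta0, x$beta1, x$beta2, x$n_points, x$residual_sd))
  invisible(x)
}

#' Score units against a fitted regression and flag outliers
#'
#' The deviation of a unit is its raw residual from the full fitted model,
#' y - (b0 + b1*x1 + b2*x2); a unit is flagged recombination-intense when
#' its deviation strictly exceeds the threshold.
#'
#' @param model A `phg_regression`.
#' @param units data.frame with columns unit_id, y, x1, x2.
#' @param threshold Flagging threshold on the deviation (strict `>`).
#' @return data.frame unit_id, y, x1, x2, fitted, deviation, flagged,
#'   threshold_used — sorted by deviation descending.
#' @export
score_deviations <- function(model, units, threshold) {
  stopifnot(inherits(model, "phg_regression"))
  threshold <- unname(threshold)
  fitted <- model$beta0 + model$beta1 * units$x1 + model$beta2 * units$x2
  dev <- units$y - fitted
  out <- data.frame(unit_id = units$unit_id, y = units$y, x1 = units$x1,
                    x2 = units$x2, fitted = fitted, deviation = dev,
                    flagged = dev > threshold, threshold_used = threshold,
                    stringsAsFactors = FALSE)
  id_rank <- match(out$unit_id, sort_c(unique(out$unit_id)))
  out <- out[order(-out$deviation, id_rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan viral groups for recombination intensity
#'
#' Fits the group-level regression of R_m per nucleotide on mean nucleotide
#' diversity and number of individuals, then flags groups whose deviation
#' from the fitted model exceeds the threshold (default 0.009, roughly the
#' top decile of deviations in a cohort of a few hundred phage groups).
#'
#' @param group_stats data.frame from [cohort_group_stats()].
#' @param threshold Deviation cutoff, strict (default 0.009).
#' @return List with `model` (`phg_regression`) and `records` (scored
#'   data.frame, deviation descending).
#' @export
scan_groups <- function(group_stats, threshold = 0.009) {
  pts <- data.frame(y = group_stats$rmin_per_nt, x1 = group_stats$mean_pi,
                    x2 = group_stats$n_individuals)
  model <- fit_regression(pts)
  units <- data.frame(unit_id = group_stats$group_id, pts,
                      stringsAsFactors = FALSE)
  list(model = model, records = score_deviations(model, units, threshold))
}

#' Scan genes within one group for recombination intensity
#'
#' Same regression form at the gene level: y = gene R_m / filtered length,
#' x1 = gene nucleotide diversity, x2 = number of aligned sequences. Genes
#' with fewer than four sequences are excluded (their R_m = 0 is structural,
#' not biological). With no stated absolute cutoff at the gene level,
#' flagging defaults to the empirical 90th percentile of deviations.
#'
#' @param stats data.frame of gene statistics for one group.
#' @param mode "percentile" (flag deviations strictly above the empirical
#'   `level` percentile) or "absolute" (strictly above `level`).
#' @param level Percentile in (0, 100) or absolute deviation cutoff.
#' @return List with `model`, `records` and `n_genes_used`, or `NULL` if the
#'   group has fewer than 4 eligible genes (skipped with a message).
#' @export
scan_genes <- function(stats, mode = c("percentile", "absolute"),
                       level = 90) {
  mode <- match.arg(mode)
  elig <- stats[stats$usable & stats$n_seqs >= 4L, , drop = FALSE]
  if (nrow(elig) < 4L) {
    message("group ", if (nrow(stats) > 0L) stats$group_id[1L] else "?",
            " skipped in gene scan: ", nrow(elig), " eligible genes (< 4)")
    return(NULL)
  }
  pts <- data.frame(y = elig$rmin_per_nt, x1 = elig$pi, x2 = elig$n_seqs)
  model <- fit_regression(pts)
  units <- data.frame(unit_id = elig$gene_id, pts, stringsAsFactors = FALSE)
  dev <- units$y - (model$beta0 + model$beta1 * units$x1 +
                      model$beta2 * units$x2)
  thr <- if (mode == "percentile") {
    unname(stats::quantile(dev, probs = level / 100, type = 7))
  } else {
    level
  }
  list(model = model, records = score_deviations(model, units, thr),
       n_genes_used = nrow(elig))
}

#' Regression line for plotting at fixed sample size
#'
#' Evaluates the fitted plane along a diversity grid while holding the
#' sample-size covariate at its training mean — the standard display of a
#' covariate-adjusted fit in two dimensions.
#'
#' @param model A `phg_regression`.
#' @param x1_grid Numeric vector of diversity values.
#' @return data.frame with columns x1, y_hat.
#' @export
regression_line <- function(model, x1_grid) {
  stopifnot(inherits(model, "phg_regression"))
  data.frame(x1 = x1_grid,
             y_hat = model$beta0 + model$beta1 * x1_grid +
               model$beta2 * model$x2_mean)
}
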