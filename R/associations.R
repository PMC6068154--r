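#' Categorize an immune-system frequency
#'
#' Host-immunity frequencies are displayed in three categories:
#' 1 (rare, below `low`), 2 (intermediate, `low` to `high` inclusive) and
#' 3 (common, above `high`). Boundary values fall in the middle category.
#'
#' @param f Frequency in [0, 1] (vectorized).
#' @param low,high Category cutoffs (defaults 0.20 and 0.80).
#' @return Integer vector of categories in {1, 2, 3}.
#' @export
categorize_frequency <- function(f, low = 0.20, high = 0.80) {
  stopifnot(low < high)
  if (any(f < 0 | f > 1, na.rm = TRUE)) stop("frequency outside [0,1]")
  ifelse(f < low, 1L, ifelse(f > high, 3L, 2L))
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact conditional (hypergeometric) test with the point-probability
#' convention for the two-sided p-value: the sum of probabilities, over all
#' tables with the observed margins, that do not exceed the observed table's
#' probability (within the customary 1e-7 relative slack). The reported odds
#' ratio is the sample estimate (a*d)/(b*c), `Inf` when b*c = 0 and some
#' association is observable, `NaN` for a degenerate margin.
#'
#' @param tab 2x2 matrix (or object coercible to one) of non-negative
#'   counts; rows = condition (e.g. flagged vs not), columns = attribute.
#' @param sided "two" (default), "greater" or "less" (alternative on the
#'   odds ratio of the first row/first column cell).
#' @return List with `odds_ratio`, `p_value`, `table`, `sided`.
#' @export
fisher_exact <- function(tab, sided = c("two", "greater", "less")) {
  sided <- match.arg(sided)
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2L, 2L)), all(tab >= 0))
  if (sum(tab) == 0) stop("all-zero contingency table")
  alt <- switch(sided, two = "two.sided", greater = "greater", less = "less")
  p <- stats::fisher.test(tab, alternative = alt)$p.value
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(odds_ratio = or, p_value = unname(p), table = tab, sided = sided)
}

#' Sample-origin enrichment of flagged viral groups
#'
#' Cross-tabulates recombination-intense flags against oral origin and tests
#' for enrichment with Fisher's exact test. In the human-virome setting this
#' asks whether recombination-intense phage groups concentrate in oral
#' samples.
#'
#' @param scan data.frame of group scan records (from [scan_groups()]).
#' @param meta Group metadata (from [read_group_metadata()]).
#' @param sided Fisher sidedness (default two-sided).
#' @return List with `table` (rows flagged/not, columns oral/not),
#'   `odds_ratio`, `p_value`, `sided`.
#' @export
test_sample_enrichment <- function(scan, meta, sided = "two") {
  idx <- match(scan$unit_id, meta$group_id)
  if (anyNA(idx)) {
    stop("groups missing from metadata: ",
         paste(scan$unit_id[is.na(idx)], collapse = ", "))
  }
  oral <- meta$is_oral[idx]
  tab <- matrix(c(sum(scan$flagged & oral), sum(scan$flagged & !oral),
                  sum(!scan$flagged & oral), sum(!scan$flagged & !oral)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("flagged", "not_flagged"),
                                c("oral", "other")))
  ft <- fisher_exact(tab, sided)
  list(table = tab, odds_ratio = ft$odds_ratio, p_value = ft$p_value,
       sided = sided)
}

#' Association between flagged groups and host immune-system frequency
#'
#' Dichotomizes host species at `cutoff` frequency for the chosen immune
#' system (attribute = frequency strictly above cutoff) and tests the 2x2
#' flagged-by-attribute table with Fisher's exact test. An odds ratio below
#' 1 means hosts dense in that immune system are under-represented among
#' recombination-intense groups — the inverse association expected if the
#' system (e.g. Type II restriction endonucleases) suppresses phage
#' recombination.
#'
#' @param scan data.frame of group scan records.
#' @param immunity Host immunity table (from [read_immunity()]).
#' @param meta Group metadata.
#' @param system One of "type1", "type2", "type3", "crispr".
#' @param cutoff Frequency cutoff(s); a vector runs one test per cutoff
#'   (default `c(0.8, 0.7, 0.6)` for the robustness sweep).
#' @param sided Fisher sidedness.
#' @return data.frame with one row per cutoff: system, cutoff, table cells
#'   (a = flagged & high-frequency host, b = flagged & not, c, d),
#'   odds_ratio, p_value, sided.
#' @export
test_immunity_association <- function(scan, immunity, meta,
                                      system = c("type2", "type1", "type3",
                                                 "crispr"),
                                      cutoff = c(0.8, 0.7, 0.6),
                                      sided = "two") {
  system <- match.arg(system)
  idx <- match(scan$unit_id, meta$group_id)
  if (anyNA(idx)) {
    stop("groups missing from metadata: ",
         paste(scan$unit_id[is.na(idx)], collapse = ", "))
  }
  sp <- meta$host_species[idx]
  sidx <- match(sp, immunity$species)
  if (anyNA(sidx)) {
    stop("host species missing from immunity table: ",
         paste(unique(sp[is.na(sidx)]), collapse = ", "))
  }
  freq <- immunity[[paste0("freq_", system)]][sidx]
  rows <- lapply(cutoff, function(cut) {
    high <- freq > cut
    a <- sum(scan$flagged & high);  b <- sum(scan$flagged & !high)
    cc <- sum(!scan$flagged & high); d <- sum(!scan$flagged & !high)
    ft <- fisher_exact(matrix(c(a, b, cc, d), 2L, byrow = TRUE), sided)
    data.frame(system = system, cutoff = cut, a = a, b = b, c = cc, d = d,
               odds_ratio = ft$odds_ratio, p_value = ft$p_value,
               sided = sided, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pearson chi-squared test on a 2 x k table
#'
#' Used for category-enrichment comparisons such as functional categories of
#' flagged genes versus the background pan-genome. No continuity correction
#' (the intended use is on large counts).
#'
#' @param counts_a,counts_b Integer count vectors of equal length k >= 2
#'   (the two rows of the table).
#' @return List with `statistic`, `df` (k - 1) and `p_value`.
#' @export
chi_squared_2xk <- function(counts_a, counts_b) {
  if (length(counts_a) != length(counts_b) || length(counts_a) < 2L) {
    stop("need two count vectors of equal length >= 2")
  }
  tab <- rbind(counts_a, counts_b)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero row or column margin")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' One-sided Welch's t-test
#'
#' Welch statistic with Welch-Satterthwaite degrees of freedom; one-sided
#' p-value for the alternative mean(a) > mean(b). Intended use: comparing
#' gene-level R_m per nucleotide inside versus outside a genomic region
#' (e.g. a high-coverage region suspected of assembly artefacts).
#'
#' @param sample_a,sample_b Numeric vectors, each of length >= 2.
#' @return List with `t`, `df` and `p_value`.
#' @export
welch_one_sided <- function(sample_a, sample_b) {
  if (length(sample_a) < 2L || length(sample_b) < 2L) {
    stop("each sample needs at least 2 observations")
  }
  tt <- stats::t.test(sample_a, sample_b, alternative = "greater",
                      var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = unname(tt$p.value))
}
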