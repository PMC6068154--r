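#' Remove gap and ambiguity columns from an alignment
#'
#' Every alignment column containing any character outside {A, C, G, T} in
#' any sequence is dropped. Gaps, N and all IUPAC ambiguity codes are treated
#' alike: ambiguous calls in metagenome assemblies are unreliable, so a
#' column is either fully resolved in every haplotype or it is excluded from
#' all downstream statistics.
#'
#' @param a A [alignment()] object.
#' @return List of class `phg_filtered` with `gene_id`, `group_id`,
#'   `retained_positions` (1-based columns of the raw alignment that
#'   survived, strictly increasing), `mat` (character matrix over
#'   {A,C,G,T}), `n_seqs`, `L` (number of retained columns, possibly 0).
#' @export
filter_columns <- function(a) {
  stopifnot(inherits(a, "phg_alignment"))
  code <- match(a$mat, c("A", "C", "G", "T"))
  dim(code) <- dim(a$mat)
  keep <- which(colSums(is.na(code)) == 0L)
  structure(
    list(gene_id = a$gene_id, group_id = a$group_id,
         retained_positions = keep,
         mat = a$mat[, keep, drop = FALSE],
         imat = code[, keep, drop = FALSE],
         n_seqs = a$n_seqs, L = length(keep)),
    class = "phg_filtered"
  )
}

#' Extract biallelic segregating sites
#'
#' Columns of the filtered alignment with exactly two distinct residues
#' become sites, encoded 0/1 with the first sequence's allele as 0.
#' Monomorphic columns carry no information about recombination; columns
#' with three or more alleles are excluded because the four-gamete argument
#' is defined on biallelic sites (they still count toward diversity and
#' length).
#'
#' @param f A `phg_filtered` object from [filter_columns()].
#' @return List of class `phg_sites` with `gene_id`, `positions` (1-based
#'   raw-alignment coordinates), `states` (n_seqs x S integer 0/1 matrix)
#'   and `S`.
#' @export
segregating_sites <- function(f) {
  stopifnot(inherits(f, "phg_filtered"))
  n <- f$n_seqs
  if (f$L == 0L || n < 2L) {
    return(structure(list(gene_id = f$gene_id, positions = integer(0),
                          states = matrix(0L, nrow = n, ncol = 0),
                          S = 0L, n_seqs = n),
                     class = "phg_sites"))
  }
  im <- f$imat
  nallele <- (colSums(im == 1L) > 0L) + (colSums(im == 2L) > 0L) +
    (colSums(im == 3L) > 0L) + (colSums(im == 4L) > 0L)
  keep <- which(nallele == 2L)
  states <- matrix(0L, nrow = n, ncol = 0)
  if (length(keep) > 0L) {
    differs <- im[, keep, drop = FALSE] !=
      matrix(im[1L, keep], nrow = n, ncol = length(keep), byrow = TRUE)
    states <- matrix(as.integer(differs), nrow = n)
  }
  structure(
    list(gene_id = f$gene_id,
         positions = f$retained_positions[keep],
         states = states, S = length(keep), n_seqs = n),
    class = "phg_sites"
  )
}

#' Four-gamete test for a pair of biallelic sites
#'
#' Two biallelic sites are incompatible with a single mutation history
#' (infinite sites, no recurrent mutation) when all four haplotypes
#' 00, 01, 10, 11 occur in the sample; at least one recombination event
#' between the sites is then required.
#'
#' @param col_a,col_b Equal-length 0/1 vectors (one entry per haplotype).
#' @return `TRUE` iff all four gametes are present.
#' @export
four_gamete_incompatible <- function(col_a, col_b) {
  if (length(col_a) != length(col_b)) {
    stop("site columns have different lengths (", length(col_a), " vs ",
         length(col_b), ")")
  }
  length(unique(2L * col_a + col_b)) == 4L
}

#' All four-gamete-incompatible site pairs of a gene
#'
#' @param m A `phg_sites` object.
#' @return data.frame with columns `left_pos`, `right_pos` (1-based
#'   raw-alignment coordinates of the flanking segregating sites,
#'   left < right), sorted by (left_pos, right_pos). Each row is an interval
#'   that must contain at least one recombination breakpoint.
#' @export
incompatible_intervals <- function(m) {
  stopifnot(inherits(m, "phg_sites"))
  S <- m$S
  empty <- quick_df(left_pos = integer(0), right_pos = integer(0))
  if (S < 2L || m$n_seqs < 4L) return(empty)
  # gamete co-occurrence counts for every site pair at once:
  # n11[i,j] = haplotypes carrying 1 at both sites, etc.
  st <- m$states
  storage.mode(st) <- "double"
  n11 <- crossprod(st)
  n10 <- crossprod(st, 1 - st)
  n00 <- crossprod(1 - st)
  bad <- n11 > 0 & n10 > 0 & t(n10) > 0 & n00 > 0
  idx <- which(bad & upper.tri(bad), arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)
  out <- quick_df(left_pos = m$positions[idx[, 1L]],
                  right_pos = m$positions[idx[, 2L]])
  out <- out[order(out$left_pos, out$right_pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hudson-Kaplan minimum number of recombination events
#'
#' Computes R_m, the classic lower bound on the number of recombination
#' events in the sample's history: the maximum number of pairwise disjoint
#' intervals each bracketed by a four-gamete-incompatible site pair
#' (intervals are disjoint when they share at most an endpoint). The
#' algorithm (1) lists all incompatible site pairs, (2) removes any interval
#' that strictly contains another (it is implied by the contained one),
#' (3) sorts survivors by right endpoint (ties by left endpoint), and
#' (4) greedily selects each interval whose left endpoint is at or beyond
#' the last selected right endpoint. The greedy count equals the maximum
#' disjoint-set size; the tie-break fixes which representative intervals are
#' reported as breakpoint localizations.
#'
#' @param m A `phg_sites` object.
#' @return List with `rmin` (non-negative integer) and `chosen` (data.frame
#'   of the selected disjoint intervals, columns left_pos/right_pos).
#' @export
hudson_kaplan_rmin <- function(m) {
  iv <- incompatible_intervals(m)
  if (nrow(iv) == 0L) {
    return(list(rmin = 0L, chosen = iv))
  }
  # drop intervals strictly containing another incompatible interval:
  # scanning by decreasing left endpoint (ties: increasing right), every
  # previously seen interval has left' >= left, so [l, r] contains another
  # iff the running minimum of seen right endpoints is <= r
  o <- order(-iv$left_pos, iv$right_pos)
  r_seen <- cummin(c(Inf, iv$right_pos[o][-nrow(iv)]))
  keep_o <- iv$right_pos[o] < r_seen
  iv <- iv[sort(o[keep_o]), , drop = FALSE]
  iv <- iv[order(iv$right_pos, iv$left_pos), , drop = FALSE]
  chosen <- logical(nrow(iv))
  last_right <- -Inf
  for (k in seq_len(nrow(iv))) {
    if (iv$left_pos[k] >= last_right) {
      chosen[k] <- TRUE
      last_right <- iv$right_pos[k]
    }
  }
  out <- iv[chosen, , drop = FALSE]
  rownames(out) <- NULL
  list(rmin = sum(chosen), chosen = out)
}

#' Nucleotide diversity of a filtered alignment
#'
#' The average proportion of differing columns between two sequences drawn
#' from the sample: the sum over unordered sequence pairs of per-pair
#' mismatch counts, divided by choose(n, 2) * L. The plain
#' average-pairwise-difference estimator is used, with no finite-sample
#' n/(n-1) factor and no multiple-hit correction; gap and ambiguity columns
#' have already been removed listwise by [filter_columns()].
#'
#' @param f A `phg_filtered` object.
#' @return pi in [0, 1], or `NA_real_` when n_seqs < 2 or L = 0 (the gene is
#'   then unusable downstream).
#' @export
nucleotide_diversity <- function(f) {
  stopifnot(inherits(f, "phg_filtered"))
  n <- f$n_seqs
  if (n < 2L || f$L == 0L) return(NA_real_)
  # per column, number of differing unordered pairs = (n^2 - sum n_b^2) / 2
  im <- f$imat
  sumsq <- colSums(im == 1L)^2 + colSums(im == 2L)^2 +
    colSums(im == 3L)^2 + colSums(im == 4L)^2
  sum((n * n - sumsq) / 2) / (choose(n, 2) * f$L)
}

#' Per-gene recombination and diversity summary
#'
#' Runs the full per-gene pipeline: gap/ambiguity column filtering,
#' biallelic segregating-site extraction, Hudson-Kaplan R_m and nucleotide
#' diversity. R_m requires at least four haplotypes, so it is structurally 0
#' (with no breakpoint intervals) for smaller genes; a gene is unusable when
#' it has fewer than two sequences or no retained columns.
#'
#' @param a A [alignment()] object.
#' @return List of class `phg_gene_stats` with gene_id, group_id, n_seqs,
#'   L (filtered length), S, rmin, pi, rmin_per_nt, usable, and breakpoints
#'   (data.frame of the disjoint incompatible intervals counted by rmin, in
#'   raw-alignment coordinates).
#' @export
gene_stats <- function(a) {
  f <- filter_columns(a)
  usable <- f$n_seqs >= 2L && f$L > 0L
  pi <- nucleotide_diversity(f)
  if (f$n_seqs >= 4L && usable) {
    m <- segregating_sites(f)
    hk <- hudson_kaplan_rmin(m)
    S <- m$S
  } else {
    S <- if (usable) segregating_sites(f)$S else 0L
    hk <- list(rmin = 0L,
               chosen = quick_df(left_pos = integer(0),
                                 right_pos = integer(0)))
  }
  structure(
    list(gene_id = a$gene_id, group_id = a$group_id, n_seqs = f$n_seqs,
         L = f$L, S = S, rmin = hk$rmin, pi = pi,
         rmin_per_nt = if (usable) hk$rmin / f$L else NA_real_,
         usable = usable, breakpoints = hk$chosen),
    class = "phg_gene_stats"
  )
}

#' Gene statistics for a whole cohort
#'
#' @param cohort Named list of lists of alignments, as returned by
#'   [read_cohort()] or [simulate_cohort()].
#' @return data.frame with one row per gene: gene_id, group_id, n_seqs, L,
#'   S, rmin, pi, rmin_per_nt, usable.
#' @export
cohort_gene_stats <- function(cohort) {
  cohort_stats_all(cohort)$gene_stats
}

# single pass over a cohort collecting both the per-gene summary table and
# the breakpoint intervals
cohort_stats_all <- function(cohort) {
  alns <- unlist(unname(cohort), recursive = FALSE)
  n <- length(alns)
  gene_id <- character(n); group_id <- character(n)
  n_seqs <- integer(n); L <- integer(n); S <- integer(n)
  rmin <- integer(n); pi <- numeric(n); rpn <- numeric(n)
  usable <- logical(n)
  bps <- vector("list", n)
  for (i in seq_len(n)) {
    st <- gene_stats(alns[[i]])
    gene_id[i] <- st$gene_id; group_id[i] <- st$group_id
    n_seqs[i] <- st$n_seqs; L[i] <- st$L; S[i] <- st$S
    rmin[i] <- st$rmin; pi[i] <- st$pi; rpn[i] <- st$rmin_per_nt
    usable[i] <- st$usable
    if (nrow(st$breakpoints) > 0L) {
      bps[[i]] <- data.frame(gene_id = st$gene_id, group_id = st$group_id,
                             st$breakpoints, stringsAsFactors = FALSE)
    }
  }
  gs <- data.frame(gene_id = gene_id, group_id = group_id, n_seqs = n_seqs,
                   L = L, S = S, rmin = rmin, pi = pi, rmin_per_nt = rpn,
                   usable = usable, stringsAsFactors = FALSE)
  bps <- bps[!vapply(bps, is.null, logical(1))]
  bp <- if (length(bps) > 0L) {
    do.call(rbind, c(bps, list(make.row.names = FALSE)))
  } else {
    data.frame(gene_id = character(0), group_id = character(0),
               left_pos = integer(0), right_pos = integer(0))
  }
  list(gene_stats = gs, breakpoints = bp)
}

#' Breakpoint intervals for a whole cohort
#'
#' @param cohort as in [cohort_gene_stats()].
#' @return data.frame gene_id, group_id, left_pos, right_pos — one row per
#'   disjoint incompatible interval counted by R_m, in raw-alignment
#'   coordinates so intervals can be drawn against the original gene.
#' @export
cohort_breakpoints <- function(cohort) {
  cohort_stats_all(cohort)$breakpoints
}
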