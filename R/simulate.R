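#' Simulation configuration for synthetic phage cohorts
#'
#' Defaults emulate the statistical structure of a human-microbiome phage
#' cohort: a few hundred species-level viral groups, each with a dozen to a
#' few dozen member scaffolds, a pan-genome of tens of genes a few hundred
#' bp long, moderate per-gene polymorphism, a low background crossover rate, a
#' minority of recombination-"hot" groups, mostly oral sample origins, and
#' an inverse association between hotness and high Type II restriction
#' endonuclease frequency in the host species. Mutation and crossover rates
#' are calibrated so that typical per-gene nucleotide diversity falls around
#' 0.02-0.05 and recombination-hot groups reach R_m per nucleotide of a few
#' hundredths — the magnitudes observed in human-microbiome phage cohorts —
#' which makes the conventional 0.009 deviation flagging threshold
#' meaningful on simulated data.
#'
#' @param n_groups Number of viral groups (default 211).
#' @param n_individuals_range Min/max scaffolds per group (default c(12, 30);
#'   the four-gamete test loses most of its power below roughly a dozen
#'   haplotypes, so the default cohort emulates moderately sampled groups).
#' @param genes_per_group_range Min/max genes per group (default c(20, 40)).
#' @param gene_length_range Min/max gene length in bp (default c(300, 900)).
#' @param mutations_per_gene_mean Poisson mean of infinite-sites mutations
#'   per gene (default 120, capped at the gene length).
#' @param crossovers_per_gene_mean Poisson mean of crossover events per gene
#'   in a background ("cold") group (default 5).
#' @param hot_group_fraction Fraction of groups that are recombination-hot
#'   (default 0.12; the planted count is `round(n_groups * fraction)`).
#' @param hot_multiplier Crossover-mean multiplier for hot groups
#'   (default 5).
#' @param oral_fraction Probability a group originates from an oral sample
#'   (default 0.75).
#' @param immunity_association_strength s in [0, 1]: hot groups' hosts carry
#'   Type II endonucleases above 80% frequency with probability
#'   (1 - s) * type2_high_rate versus type2_high_rate for cold groups.
#'   s = 0 is the null (no association); default 0.9, a strong planted
#'   inverse association.
#' @param type2_high_rate Background probability q that a host species has
#'   Type II frequency above 0.8 (default 0.5).
#' @param seed Integer RNG seed.
#' @return List of class `phg_sim_config`.
#' @export
sim_config <- function(n_groups = 211L,
                       n_individuals_range = c(12L, 30L),
                       genes_per_group_range = c(20L, 40L),
                       gene_length_range = c(300L, 900L),
                       mutations_per_gene_mean = 120,
                       crossovers_per_gene_mean = 5,
                       hot_group_fraction = 0.12,
                       hot_multiplier = 5,
                       oral_fraction = 0.75,
                       immunity_association_strength = 0.9,
                       type2_high_rate = 0.5,
                       seed = 1L) {
  cfg <- list(n_groups = as.integer(n_groups),
              n_individuals_range = as.integer(n_individuals_range),
              genes_per_group_range = as.integer(genes_per_group_range),
              gene_length_range = as.integer(gene_length_range),
              mutations_per_gene_mean = mutations_per_gene_mean,
              crossovers_per_gene_mean = crossovers_per_gene_mean,
              hot_group_fraction = hot_group_fraction,
              hot_multiplier = hot_multiplier,
              oral_fraction = oral_fraction,
              immunity_association_strength = immunity_association_strength,
              type2_high_rate = type2_high_rate,
              seed = as.integer(seed))
  stopifnot(cfg$n_groups >= 1L,
            length(cfg$n_individuals_range) == 2L,
            cfg$n_individuals_range[1L] >= 2L,
            diff(cfg$n_individuals_range) >= 0L,
            cfg$genes_per_group_range[1L] >= 1L,
            diff(cfg$genes_per_group_range) >= 0L,
            cfg$gene_length_range[1L] >= 1L,
            diff(cfg$gene_length_range) >= 0L,
            cfg$mutations_per_gene_mean >= 0,
            cfg$crossovers_per_gene_mean >= 0,
            cfg$hot_group_fraction >= 0, cfg$hot_group_fraction <= 1,
            cfg$hot_multiplier >= 1,
            cfg$oral_fraction >= 0, cfg$oral_fraction <= 1,
            cfg$immunity_association_strength >= 0,
            cfg$immunity_association_strength <= 1,
            cfg$type2_high_rate >= 0, cfg$type2_high_rate <= 1)
  class(cfg) <- "phg_sim_config"
  cfg
}

#' Simulate one gene alignment with known recombination truth
#'
#' Polymorphism is generated under infinite sites on an explicit random
#' coalescent genealogy: (1) a binary topology over `n_seqs` tips is built
#' by uniform sequential pair-merging, with exponential epoch durations at
#' the Kingman rate (choose(j, 2) while j lineages remain), giving every
#' branch a coalescent length; (2) each of `n_mutations` mutations is placed
#' on a branch chosen with probability proportional to its length — so the
#' expected per-mutation contribution to pairwise diversity does not depend
#' on the sample size — and assigned a distinct, uniformly chosen,
#' previously unused column, so derived alleles form nested-or-disjoint tip
#' sets and the data are tree-compatible (R_m = 0 without recombination);
#' (3) each of `n_crossovers` crossovers picks a recipient tip, a distinct
#' donor tip and a uniform breakpoint column, replacing the recipient's
#' suffix from that column with the donor's. The crossover count is exact
#' truth: R_m of the resulting alignment can never exceed it.
#'
#' Uses the current RNG state; seed outside for reproducibility.
#'
#' @param n_seqs Number of haplotypes (>= 2).
#' @param length Gene length in bp (>= 1).
#' @param n_mutations Number of segregating mutations (<= length).
#' @param n_crossovers Number of crossover events (>= 0).
#' @param gene_id,group_id Identifiers for the emitted alignment.
#' @return List with `alignment` (ungapped [alignment()]) and `truth`
#'   (one-row data.frame: gene_id, group_id, n_seqs, length, n_mutations,
#'   n_crossovers).
#' @export
simulate_gene <- function(n_seqs, length, n_mutations, n_crossovers,
                          gene_id = "gene", group_id = "group") {
  stopifnot(n_seqs >= 2L, length >= 1L, n_crossovers >= 0L)
  if (n_mutations > length) {
    stop("infinite sites exhausted: ", n_mutations, " mutations > ",
         length, " columns")
  }
  bases <- c("A", "C", "G", "T")
  # random coalescent genealogy: uniform pair-merging with exponential
  # epoch durations; every lineage except the root is a branch subtending a
  # proper tip subset, with length = time from its creation to its merge
  lineages <- lapply(seq_len(n_seqs), identity)
  birth <- numeric(n_seqs)
  branches <- vector("list", 2L * (n_seqs - 1L))
  blen <- numeric(2L * (n_seqs - 1L))
  nb <- 0L
  t_now <- 0
  while (length(lineages) > 1L) {
    j <- length(lineages)
    t_now <- t_now + stats::rexp(1L, rate = j * (j - 1L) / 2)
    pair <- sample.int(j, 2L)
    for (p in pair) {
      nb <- nb + 1L
      branches[[nb]] <- lineages[[p]]
      blen[nb] <- t_now - birth[p]
    }
    merged <- c(lineages[[pair[1L]]], lineages[[pair[2L]]])
    lineages <- c(lineages[-pair], list(merged))
    birth <- c(birth[-pair], t_now)
  }
  anc_code <- sample.int(4L, length, replace = TRUE)
  code <- matrix(anc_code, nrow = n_seqs, ncol = length, byrow = TRUE)
  if (n_mutations > 0L) {
    cols <- sample.int(length, n_mutations)
    br <- sample.int(nb, n_mutations, replace = TRUE, prob = blen[seq_len(nb)])
    # derived allele: one of the three non-ancestral bases, uniformly
    alt <- (anc_code[cols] - 1L + sample.int(3L, n_mutations,
                                             replace = TRUE)) %% 4L + 1L
    for (k in seq_len(n_mutations)) {
      code[branches[[br[k]]], cols[k]] <- alt[k]
    }
  }
  if (n_crossovers > 0L) {
    recipients <- sample.int(n_seqs, n_crossovers, replace = TRUE)
    shift <- sample.int(n_seqs - 1L, n_crossovers, replace = TRUE)
    donors <- (recipients - 1L + shift) %% n_seqs + 1L
    bps <- sample.int(length, n_crossovers)
    for (k in seq_len(n_crossovers)) {
      code[recipients[k], bps[k]:length] <- code[donors[k], bps[k]:length]
    }
  }
  mat <- matrix(bases[code], nrow = n_seqs, ncol = length)
  rownames(mat) <- sprintf("seq%03d", seq_len(n_seqs))
  list(alignment = new_alignment(gene_id, group_id, mat),
       truth = quick_df(gene_id = gene_id, group_id = group_id,
                        n_seqs = n_seqs, length = length,
                        n_mutations = n_mutations,
                        n_crossovers = n_crossovers))
}

#' Simulate all genes of one viral group
#'
#' Draws the gene count, per-gene lengths and Poisson mutation and crossover
#' counts (the crossover mean is multiplied by `hot_multiplier` for hot
#' groups); all genes share the group's number of individuals. Uses the
#' current RNG state.
#'
#' @param config A [sim_config()].
#' @param group_id Group identifier.
#' @param n_individuals Number of scaffolds in the group.
#' @param hot Logical: is this a recombination-hot group?
#' @return List with `alignments` (named list) and `gene_truth` (data.frame).
#' @export
simulate_group <- function(config, group_id, n_individuals, hot) {
  gr <- config$genes_per_group_range
  n_genes <- if (gr[1L] == gr[2L]) gr[1L] else
    sample(gr[1L]:gr[2L], 1L)
  lr <- config$gene_length_range
  xov_mean <- config$crossovers_per_gene_mean *
    (if (hot) config$hot_multiplier else 1)
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  lens <- if (lr[1L] == lr[2L]) rep(lr[1L], n_genes) else
    sample(lr[1L]:lr[2L], n_genes, replace = TRUE)
  n_muts <- pmin(stats::rpois(n_genes, config$mutations_per_gene_mean), lens)
  n_xovs <- stats::rpois(n_genes, xov_mean)
  alns <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    g <- simulate_gene(n_individuals, lens[i], n_muts[i], n_xovs[i],
                       gene_id = gene_ids[i], group_id = group_id)
    alns[[i]] <- g$alignment
  }
  names(alns) <- gene_ids
  truth <- quick_df(gene_id = gene_ids,
                    group_id = rep(group_id, n_genes),
                    n_seqs = rep(as.integer(n_individuals), n_genes),
                    length = lens, n_mutations = n_muts,
                    n_crossovers = n_xovs)
  list(alignments = alns, gene_truth = truth)
}

#' Simulate cohort-level metadata, hosts and immunity profiles
#'
#' The metadata layer of the generator: which groups are hot, their sample
#' origin, one synthetic host species per group, and host immune-system
#' frequencies. With association strength s, a hot group's host has Type II
#' frequency above 0.8 with probability (1 - s) * q and a cold group's with
#' probability q (q = `type2_high_rate`), planting an inverse association;
#' s = 0 gives the null. Other immune systems are drawn uniformly,
#' unassociated with hotness. Uses the current RNG state.
#'
#' @param config A [sim_config()].
#' @return List with `metadata` (group_id, sample_type, is_oral,
#'   host_species), `immunity` (one row per host species) and `group_truth`
#'   (group_id, hot, is_oral, host_species, n_individuals).
#' @export
simulate_metadata <- function(config) {
  n <- config$n_groups
  group_id <- sprintf("group%03d", seq_len(n))
  n_hot <- round(n * config$hot_group_fraction)
  hot <- rep(FALSE, n)
  if (n_hot > 0L) hot[sample.int(n, n_hot)] <- TRUE
  is_oral <- stats::runif(n) < config$oral_fraction
  sample_type <- ifelse(is_oral, "Oral (synthetic)", "Gut (synthetic)")
  host_species <- sprintf("Synthhost_species_%03d", seq_len(n))
  ir <- config$n_individuals_range
  n_individuals <- if (ir[1L] == ir[2L]) rep(ir[1L], n) else
    sample(ir[1L]:ir[2L], n, replace = TRUE)
  q <- config$type2_high_rate
  s <- config$immunity_association_strength
  p_high <- ifelse(hot, (1 - s) * q, q)
  high2 <- stats::runif(n) < p_high
  freq_type2 <- ifelse(high2,
                       stats::runif(n, 0.8, 1),
                       stats::runif(n, 0, 0.8))
  immunity <- data.frame(
    species = host_species,
    n_genomes = sample(5:60, n, replace = TRUE),
    freq_type1 = stats::runif(n),
    freq_type2 = freq_type2,
    freq_type3 = stats::runif(n),
    freq_crispr = stats::runif(n),
    stringsAsFactors = FALSE)
  metadata <- data.frame(group_id = group_id, sample_type = sample_type,
                         is_oral = is_oral, host_species = host_species,
                         stringsAsFactors = FALSE)
  group_truth <- data.frame(group_id = group_id, hot = hot,
                            is_oral = is_oral, host_species = host_species,
                            n_individuals = n_individuals,
                            stringsAsFactors = FALSE)
  list(metadata = metadata, immunity = immunity, group_truth = group_truth)
}

#' Simulate a full phage pan-genome cohort
#'
#' Generates metadata, immunity profiles and per-group gene alignments with
#' known truth. Randomness is fully determined by `config$seed`: a global
#' stream draws the metadata and one sub-seed per group, and each group's
#' genes are generated from its own sub-stream, so cohorts are reproducible
#' and groups independent.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory. When given, writes the on-disk
#'   cohort layout consumed by [read_cohort()]: one subdirectory per group
#'   of per-gene FASTA files, plus `metadata.tsv`, `immunity.tsv`,
#'   `truth_groups.tsv`, `truth_genes.tsv` and `sim_config.tsv`.
#' @return List with `cohort` (named list of lists of alignments),
#'   `metadata`, `immunity`, `group_truth`, `gene_truth`, `config`, `dir`.
#' @export
simulate_cohort <- function(config = sim_config(), dir = NULL) {
  stopifnot(inherits(config, "phg_sim_config"))
  set.seed(config$seed)
  meta <- simulate_metadata(config)
  group_seeds <- sample.int(.Machine$integer.max - 1L, config$n_groups)
  cohort <- vector("list", config$n_groups)
  names(cohort) <- meta$group_truth$group_id
  gene_truths <- vector("list", config$n_groups)
  for (i in seq_len(config$n_groups)) {
    set.seed(group_seeds[i])
    g <- simulate_group(config, meta$group_truth$group_id[i],
                        meta$group_truth$n_individuals[i],
                        meta$group_truth$hot[i])
    cohort[[i]] <- g$alignments
    gene_truths[[i]] <- g$gene_truth
  }
  gene_truth <- do.call(rbind, gene_truths)
  out <- list(cohort = cohort, metadata = meta$metadata,
              immunity = meta$immunity, group_truth = meta$group_truth,
              gene_truth = gene_truth, config = config, dir = dir)
  if (!is.null(dir)) write_cohort(out, dir)
  out
}

#' Write a simulated cohort to disk in the standard input layout
#'
#' @param sim Result of [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (g in names(sim$cohort)) {
    gdir <- file.path(dir, g)
    dir.create(gdir, showWarnings = FALSE)
    for (a in sim$cohort[[g]]) {
      seqs <- Biostrings::DNAStringSet(apply(a$mat, 1L, paste0,
                                             collapse = ""))
      Biostrings::writeXStringSet(
        seqs, file.path(gdir, paste0(a$gene_id, ".fasta")))
    }
  }
  write_table(sim$metadata, file.path(dir, "metadata.tsv"))
  write_table(sim$immunity, file.path(dir, "immunity.tsv"))
  write_table(sim$group_truth, file.path(dir, "truth_groups.tsv"))
  write_table(sim$gene_truth, file.path(dir, "truth_genes.tsv"))
  cfg <- sim$config
  cfgdf <- data.frame(
    key = names(cfg),
    value = vapply(cfg, function(v) paste(v, collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  write_table(cfgdf, file.path(dir, "sim_config.tsv"))
  invisible(dir)
}
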