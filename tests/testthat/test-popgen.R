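# The 4-haplotype, 3-site worked example used throughout: binary rows
# 000, 011, 101, 110 — every site pair shows all four gametes.
toy_states <- matrix(c(0L, 0L, 1L, 1L,
                       0L, 1L, 0L, 1L,
                       0L, 1L, 1L, 0L), nrow = 4)
toy_alignment <- make_alignment(c("AAA", "ACC", "CAC", "CCA"))

test_that("gap and ambiguity columns are filtered out listwise", {
  f <- filter_columns(make_alignment(c("AC-T", "ACGT")))
  expect_equal(f$retained_positions, c(1L, 2L, 4L))
  expect_equal(f$mat, matrix(c("A", "A", "C", "C", "T", "T"), nrow = 2),
               ignore_attr = TRUE)

  f2 <- filter_columns(make_alignment(c("ANGT", "ACGT")))
  expect_equal(f2$retained_positions, c(1L, 3L, 4L))
  # IUPAC ambiguity codes are treated like gaps
  f3 <- filter_columns(make_alignment(c("ARGT", "ACGT")))
  expect_equal(f3$retained_positions, c(1L, 3L, 4L))

  f4 <- filter_columns(make_alignment(c("ACGT", "ACGA")))
  expect_equal(f4$retained_positions, 1:4)
  expect_equal(f4$L, 4L)

  f5 <- filter_columns(make_alignment(c("----", "ACGT")))
  expect_equal(f5$L, 0L)
})

test_that("segregating sites are the biallelic polymorphic columns", {
  s0 <- segregating_sites(filter_columns(make_alignment(c("ACGT", "ACGT"))))
  expect_equal(s0$S, 0L)

  # triallelic column excluded
  s1 <- segregating_sites(filter_columns(make_alignment(c("AA", "CA", "GA"))))
  expect_equal(s1$S, 0L)

  s2 <- segregating_sites(filter_columns(toy_alignment))
  expect_equal(s2$S, 3L)
  expect_equal(s2$states, toy_states, ignore_attr = TRUE)
  expect_equal(s2$positions, 1:3)

  # first sequence's allele is encoded 0 even when it is the rarer one
  s3 <- segregating_sites(filter_columns(make_alignment(c("T", "A", "A", "A"))))
  expect_equal(as.integer(s3$states), c(0L, 1L, 1L, 1L))
})

test_that("the four-gamete test detects exactly the complete gamete sets", {
  expect_true(four_gamete_incompatible(c(0, 0, 1, 1), c(0, 1, 0, 1)))
  expect_false(four_gamete_incompatible(c(0, 0, 1, 1), c(0, 0, 1, 1)))
  expect_false(four_gamete_incompatible(c(0, 1, 1), c(1, 0, 1)))
  expect_error(four_gamete_incompatible(c(0, 1), c(0, 1, 1)), "length")

  # agreement with explicit gamete-set enumeration on random pairs
  set.seed(401)
  for (i in 1:200) {
    n <- sample(4:12, 1)
    a <- rbinom(n, 1, 0.5); b <- rbinom(n, 1, 0.5)
    expect_equal(four_gamete_incompatible(a, b),
                 length(gametes_of(a, b)) == 4L)
  }
})

test_that("incompatible intervals enumerate failing site pairs in order", {
  expect_equal(nrow(incompatible_intervals(rand_sites(6, 1))), 0L)

  m <- make_sites(toy_states, positions = c(10L, 20L, 30L))
  iv <- incompatible_intervals(m)
  expect_equal(iv$left_pos, c(10L, 10L, 20L))
  expect_equal(iv$right_pos, c(20L, 30L, 30L))

  m2 <- make_sites(cbind(c(0L, 0L, 1L, 1L), c(0L, 0L, 0L, 1L),
                         c(0L, 1L, 1L, 0L)), positions = c(5L, 9L, 14L))
  iv2 <- incompatible_intervals(m2)
  expect_equal(nrow(iv2), 1L)
  expect_equal(c(iv2$left_pos, iv2$right_pos), c(5L, 14L))
})

test_that("Hudson-Kaplan R_m matches the worked examples", {
  m <- make_sites(toy_states)
  hk <- hudson_kaplan_rmin(m)
  expect_equal(hk$rmin, 2L)
  # the containing interval (1,3) is removed; the two short ones share only
  # an endpoint, so both are chosen
  expect_equal(hk$chosen$left_pos, c(1L, 2L))
  expect_equal(hk$chosen$right_pos, c(2L, 3L))

  one <- make_sites(cbind(c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L)))
  expect_equal(hudson_kaplan_rmin(one)$rmin, 1L)

  none <- make_sites(cbind(c(0L, 0L, 1L, 1L), c(0L, 0L, 1L, 1L)))
  expect_equal(hudson_kaplan_rmin(none)$rmin, 0L)
  expect_equal(nrow(hudson_kaplan_rmin(none)$chosen), 0L)
})

test_that("R_m equals the maximum disjoint-interval count on random sites", {
  set.seed(402)
  for (i in 1:150) {
    m <- rand_sites(sample(4:10, 1), sample(2:12, 1))
    iv <- incompatible_intervals(m)
    expect_equal(hudson_kaplan_rmin(m)$rmin, dp_max_disjoint(iv))
    if (nrow(iv) <= 12L) {
      expect_equal(hudson_kaplan_rmin(m)$rmin, exhaustive_max_disjoint(iv))
    }
  }
})

test_that("R_m is invariant under row permutation, allele swap and position relabeling", {
  set.seed(403)
  for (i in 1:40) {
    m <- rand_sites(sample(4:9, 1), sample(3:10, 1))
    r0 <- hudson_kaplan_rmin(m)$rmin
    # row permutation
    mp <- make_sites(m$states[sample(nrow(m$states)), , drop = FALSE],
                     m$positions)
    expect_equal(hudson_kaplan_rmin(mp)$rmin, r0)
    # 0/1 swap at a random site
    ms <- m$states
    j <- sample(ncol(ms), 1)
    ms[, j] <- 1L - ms[, j]
    expect_equal(hudson_kaplan_rmin(make_sites(ms, m$positions))$rmin, r0)
    # order-preserving position relabeling
    mr <- make_sites(m$states, positions = m$positions * 7L + 3L)
    expect_equal(hudson_kaplan_rmin(mr)$rmin, r0)
    # upper bound
    expect_lte(r0, ncol(ms) - 1L)
  }
})

test_that("nucleotide diversity matches its definition", {
  # 2 sequences, 10 columns, 1 mismatch
  f <- filter_columns(make_alignment(c("ACGTACGTAC", "ACGTACGTAT")))
  expect_equal(nucleotide_diversity(f), 0.1)

  f2 <- filter_columns(make_alignment(rep("ACGTAC", 5)))
  expect_equal(nucleotide_diversity(f2), 0)

  # toy example: all 6 pairs differ at 2 of 3 columns
  expect_equal(nucleotide_diversity(filter_columns(toy_alignment)), 2 / 3)

  # undefined cases
  expect_true(is.na(nucleotide_diversity(filter_columns(make_alignment("ACGT")))))
  expect_true(is.na(nucleotide_diversity(filter_columns(make_alignment(c("--", "--"))))))
})

test_that("pi is a row-permutation-invariant fraction that matches brute force", {
  set.seed(404)
  for (i in 1:25) {
    n <- sample(2:8, 1); L <- sample(5:30, 1)
    mat <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n, L)
    rownames(mat) <- sprintf("s%d", 1:n)
    f <- filter_columns(alignment("g", "grp", mat))
    pi <- nucleotide_diversity(f)
    # brute force over pairs
    tot <- 0
    for (a in 1:(n - 1)) for (b in (a + 1):n) {
      tot <- tot + sum(mat[a, ] != mat[b, ])
    }
    expect_equal(pi, tot / (choose(n, 2) * L))
    expect_gte(pi, 0); expect_lte(pi, 1)
    perm <- alignment("g", "grp", mat[sample(n), , drop = FALSE])
    expect_equal(nucleotide_diversity(filter_columns(perm)), pi)
  }
})

test_that("gene_stats composes the per-gene pipeline", {
  st <- gene_stats(make_alignment(rep("ACGTACGT", 4)))
  expect_true(st$usable)
  expect_equal(st$S, 0L)
  expect_equal(st$rmin, 0L)
  expect_equal(st$pi, 0)

  # fewer than 4 haplotypes: R_m structurally 0, pi still computed
  st3 <- gene_stats(make_alignment(c("AAA", "ACC", "CAC")))
  expect_equal(st3$rmin, 0L)
  expect_equal(nrow(st3$breakpoints), 0L)
  expect_gt(st3$pi, 0)

  sttoy <- gene_stats(toy_alignment)
  expect_equal(sttoy$rmin, 2L)
  expect_equal(sttoy$pi, 2 / 3, tolerance = 1e-12)
  expect_equal(sttoy$rmin_per_nt, 2 / 3)
  expect_equal(sttoy$L, 3L)

  # single sequence or zero filtered length: unusable
  expect_false(gene_stats(make_alignment("ACGT"))$usable)
  expect_false(gene_stats(make_alignment(c("-N-", "-N-", "-N-", "-N-")))$usable)
})
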