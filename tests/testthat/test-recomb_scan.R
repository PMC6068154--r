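gene_row <- function(gene_id, group_id = "g1", n_seqs = 10L, L = 300L,
                     rmin = 0L, pi = 0.02, usable = TRUE) {
  data.frame(gene_id = gene_id, group_id = group_id, n_seqs = n_seqs,
             L = L, S = 10L, rmin = rmin, pi = pi,
             rmin_per_nt = if (usable) rmin / L else NA_real_,
             usable = usable, stringsAsFactors = FALSE)
}

test_that("group aggregation sums R_m over gene length and averages pi", {
  stats <- rbind(gene_row("a", rmin = 2L, L = 300L, pi = 0.05),
                 gene_row("b", rmin = 1L, L = 200L, pi = 0.07))
  g <- aggregate_group(stats, n_individuals = 5L)
  expect_equal(g$rmin_per_nt, 3 / 500)
  expect_equal(g$mean_pi, 0.06)
  expect_equal(g$n_genes_used, 2L)

  one <- aggregate_group(gene_row("a", rmin = 4L, L = 250L), 6L)
  expect_equal(one$rmin_per_nt, 4 / 250)

  # genes with < 4 sequences contribute pi but not the R_m sums
  mixed <- rbind(gene_row("a", rmin = 2L, L = 300L, pi = 0.05),
                 gene_row("b", n_seqs = 3L, rmin = 0L, L = 999L, pi = 0.09))
  gm <- aggregate_group(mixed, 5L)
  expect_equal(gm$total_len, 300L)
  expect_equal(gm$mean_pi, 0.07)

  none <- gene_row("a", usable = FALSE)
  expect_null(aggregate_group(none, 5L))
})

test_that("the regression recovers exact linear structure and rejects bad designs", {
  set.seed(501)
  x1 <- runif(20); x2 <- sample(5:30, 20, replace = TRUE)
  pts <- data.frame(y = 0.001 + 0.5 * x1 + 1e-4 * x2, x1 = x1, x2 = x2)
  m <- fit_regression(pts)
  expect_equal(m$beta0, 0.001, tolerance = 1e-8)
  expect_equal(m$beta1, 0.5, tolerance = 1e-8)
  expect_equal(m$beta2, 1e-4, tolerance = 1e-8)
  expect_equal(m$x2_mean, mean(x2))

  expect_error(fit_regression(pts[1:3, ]), "at least 4")
  const <- pts; const$x1 <- 0.3
  expect_error(fit_regression(const), "rank-deficient")
})

test_that("OLS agrees with the normal equations and residuals sum to zero", {
  set.seed(502)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    pts <- data.frame(x1 = runif(n), x2 = runif(n, 4, 40))
    pts$y <- rnorm(n, 0.005 + 0.2 * pts$x1 - 1e-4 * pts$x2, 0.002)
    m <- fit_regression(pts)
    beta <- ols_normal_equations(pts)
    expect_equal(c(m$beta0, m$beta1, m$beta2), beta, tolerance = 1e-8)
    res <- pts$y - (m$beta0 + m$beta1 * pts$x1 + m$beta2 * pts$x2)
    expect_lt(abs(sum(res)) / max(abs(pts$y)), 1e-8)
  }
})

test_that("deviations flag strictly above the threshold", {
  pts <- data.frame(y = c(0.01, 0.02, 0.03, 0.05),
                    x1 = c(0.01, 0.02, 0.03, 0.04),
                    x2 = c(7, 12, 9, 20))
  m <- fit_regression(pts)
  on_plane <- data.frame(unit_id = "u",
                         x1 = 0.025, x2 = 12)
  on_plane$y <- m$beta0 + m$beta1 * on_plane$x1 + m$beta2 * on_plane$x2
  rec <- score_deviations(m, on_plane, threshold = 1e-9)
  expect_equal(rec$deviation, 0, tolerance = 1e-12)
  expect_false(rec$flagged)

  # deviation exactly equal to the threshold is NOT flagged
  at <- on_plane; at$y <- at$y + 0.009
  dev <- score_deviations(m, at, threshold = 1)$deviation
  expect_equal(dev, 0.009, tolerance = 1e-12)
  rec2 <- score_deviations(m, at, threshold = dev)
  expect_false(rec2$flagged)
  rec3 <- score_deviations(m, at, threshold = dev - 1e-12)
  expect_true(rec3$flagged)
})

test_that("a 90th-percentile threshold flags about the top decile", {
  set.seed(503)
  n <- 200
  units <- data.frame(unit_id = sprintf("u%03d", 1:n), x1 = runif(n),
                      x2 = runif(n, 5, 30))
  units$y <- 0.002 + 0.1 * units$x1 + 1e-4 * units$x2 + rnorm(n, 0, 0.001)
  m <- fit_regression(units[, c("y", "x1", "x2")])
  dev <- units$y - (m$beta0 + m$beta1 * units$x1 + m$beta2 * units$x2)
  rec <- score_deviations(m, units, threshold = quantile(dev, 0.9))
  expect_equal(sum(rec$flagged), sum(dev > quantile(dev, 0.9)))
  expect_lte(abs(sum(rec$flagged) - 0.1 * n), 0.02 * n + 1)
})

test_that("group scanning orders by deviation and is permutation invariant", {
  set.seed(504)
  n <- 40
  gs <- data.frame(group_id = sprintf("g%02d", 1:n),
                   n_individuals = sample(12:30, n, replace = TRUE),
                   total_rmin = 0L, total_len = 0L,
                   rmin_per_nt = NA_real_,
                   mean_pi = runif(n, 0.01, 0.08),
                   n_genes_used = 30L, stringsAsFactors = FALSE)
  gs$rmin_per_nt <- 0.001 + 0.05 * gs$mean_pi + 1e-4 * gs$n_individuals +
    rnorm(n, 0, 5e-4)
  out <- scan_groups(gs, threshold = 0.009)
  expect_equal(nrow(out$records), n)
  expect_true(all(diff(out$records$deviation) <= 0))
  expect_equal(out$records$flagged, out$records$deviation > 0.009)

  out2 <- scan_groups(gs[sample(n), ], threshold = 0.009)
  expect_equal(sort(out2$records$unit_id[out2$records$flagged]),
               sort(out$records$unit_id[out$records$flagged]))
  expect_equal(out2$records$unit_id, out$records$unit_id)
})

test_that("near-identical groups produce no flags at the default threshold", {
  set.seed(505)
  n <- 30
  gs <- data.frame(group_id = sprintf("g%02d", 1:n),
                   n_individuals = sample(12:30, n, replace = TRUE),
                   total_rmin = 3L, total_len = 1000L,
                   rmin_per_nt = 0.003 + rnorm(n, 0, 1e-5),
                   mean_pi = 0.03 + rnorm(n, 0, 1e-4),
                   n_genes_used = 30L, stringsAsFactors = FALSE)
  out <- scan_groups(gs, threshold = 0.009)
  expect_equal(sum(out$records$flagged), 0L)
})

test_that("adding a constant to y shifts the intercept and not the deviations", {
  set.seed(506)
  n <- 25
  pts <- data.frame(unit_id = sprintf("u%d", 1:n), x1 = runif(n),
                    x2 = runif(n, 4, 30))
  pts$y <- 0.01 * pts$x1 + rnorm(n, 0, 0.001)
  m1 <- fit_regression(pts)
  shifted <- pts; shifted$y <- shifted$y + 0.42
  m2 <- fit_regression(shifted)
  expect_equal(m2$beta0, m1$beta0 + 0.42, tolerance = 1e-9)
  expect_equal(m2$beta1, m1$beta1, tolerance = 1e-9)
  r1 <- score_deviations(m1, pts, 0.001)
  r2 <- score_deviations(m2, shifted, 0.001)
  expect_equal(r2$deviation[order(r2$unit_id)], r1$deviation[order(r1$unit_id)],
               tolerance = 1e-9)
})

test_that("gene-level scans flag outliers and exclude structural zeros", {
  set.seed(507)
  n <- 30
  stats <- do.call(rbind, lapply(1:n, function(i) {
    gene_row(sprintf("gene%02d", i), n_seqs = sample(8:20, 1),
             L = sample(300:900, 1), rmin = rpois(1, 3),
             pi = runif(1, 0.02, 0.06))
  }))
  stats$rmin_per_nt <- stats$rmin / stats$L
  # one gene far above the rest
  stats$rmin[1] <- 60L
  stats$rmin_per_nt[1] <- 60 / stats$L[1]
  # a structural-zero gene that must not enter the fit
  stats$n_seqs[2] <- 3L

  out <- scan_genes(stats, mode = "percentile", level = 90)
  expect_equal(out$n_genes_used, n - 1L)
  expect_false("gene02" %in% out$records$unit_id)
  expect_true(out$records$flagged[out$records$unit_id == "gene01"])
  expect_equal(out$records$unit_id[1], "gene01")

  # absolute mode with a huge cutoff flags nothing
  out2 <- scan_genes(stats, mode = "absolute", level = 1)
  expect_equal(sum(out2$records$flagged), 0L)

  few <- stats[1:5, ]; few$n_seqs <- 3L
  expect_message(res <- scan_genes(few), "skipped")
  expect_null(res)
})

test_that("the display line holds the sample-size covariate at its mean", {
  pts <- data.frame(y = c(0.01, 0.02, 0.03, 0.05), x1 = c(1, 2, 3, 4) / 100,
                    x2 = c(7, 12, 9, 20))
  m <- fit_regression(pts)
  line <- regression_line(m, c(0, 0.09))
  expect_equal(line$y_hat[1], m$beta0 + m$beta2 * m$x2_mean)
  expect_equal(diff(line$y_hat) / diff(line$x1), m$beta1, tolerance = 1e-10)
})
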