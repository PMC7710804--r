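# step-down procedure written directly from its definition, as an oracle
oracle_holm_sidak_reject <- function(p, alpha = 0.05) {
  m <- length(p)
  ord <- order(p)
  reject <- logical(m)
  for (i in seq_len(m)) {
    thr <- 1 - (1 - alpha)^(1 / (m - i + 1))
    if (p[ord[i]] <= thr) reject[ord[i]] <- TRUE else break
  }
  reject
}

test_that("the pooled t-test matches t.test with equal variances", {
  set.seed(121)
  for (r in 1:15) {
    a <- rnorm(sample(3:12, 1), mean = runif(1, -1, 1))
    b <- rnorm(sample(3:12, 1))
    mine <- pooled_t_test(a, b)
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$df, unname(ref$parameter))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    g <- pooled_t_test(a, b, "one_greater")$p_value
    l <- pooled_t_test(a, b, "one_less")$p_value
    expect_equal(mine$p_value, 2 * min(g, l), tolerance = 1e-12)
    expect_equal(g + l, 1, tolerance = 1e-12)
  }
})

test_that("degenerate samples are rejected with clear errors", {
  expect_equal(pooled_t_test(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(pooled_t_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_lt(pooled_t_test(c(1, 2, 3), c(11, 12, 13))$p_value, 0.001)
  expect_error(pooled_t_test(c(0, 0), c(0, 0)), "degenerate samples")
  expect_error(pooled_t_test(1, c(1, 2)), "at least 2")
})

test_that("Holm-Sidak reproduces its worked examples", {
  hs <- holm_sidak(c(0.001, 0.02, 0.04), alpha = 0.05)
  expect_equal(hs$reject, rep(TRUE, 3))
  hs2 <- holm_sidak(c(0.02, 0.03, 0.5), alpha = 0.05)
  expect_equal(hs2$reject, rep(FALSE, 3))
  # m = 1 reduces to a plain alpha-level test with untouched p
  one <- holm_sidak(0.03, alpha = 0.05)
  expect_true(one$reject)
  expect_equal(one$adjusted_p, 0.03)
  expect_error(holm_sidak(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Holm-Sidak agrees with the step-down oracle on m <= 5", {
  set.seed(131)
  for (r in 1:200) {
    m <- sample(1:5, 1)
    p <- round(runif(m), 3)
    alpha <- sample(c(0.01, 0.05, 0.1), 1)
    hs <- holm_sidak(p, alpha)
    expect_equal(hs$reject, oracle_holm_sidak_reject(p, alpha))
    expect_gte(min(hs$adjusted_p - p), -1e-12)     # adjusted >= raw
    ord <- order(p)
    expect_true(all(diff(hs$adjusted_p[ord]) >= -1e-12))  # monotone
  }
})

test_that("adjusted p-values are permutation-equivariant", {
  set.seed(141)
  p <- runif(12)
  perm <- sample(12)
  hs <- holm_sidak(p)
  hsp <- holm_sidak(p[perm])
  expect_equal(hsp$adjusted_p, hs$adjusted_p[perm])
  expect_equal(hsp$reject, hs$reject[perm])
})

test_that("nodewise comparison tests every node and recovers a planted shift", {
  set.seed(151)
  n_nodes <- 30
  msni <- matrix(rnorm(8 * n_nodes, 100, 5), 8, n_nodes)
  msci <- matrix(rnorm(12 * n_nodes, 100, 5), 12, n_nodes)
  msci[, c(5, 17)] <- msci[, c(5, 17)] - 30
  tab <- nodewise_comparison(msci, msni, measure_name = "strength")
  expect_s3_class(tab, "node_stats_table")
  expect_equal(nrow(tab), n_nodes)
  expect_equal(attr(tab, "m"), n_nodes)
  expect_equal(which(tab$reject), c(5, 17))
  expect_equal(tab$direction[c(5, 17)], c(-1, -1))
  expect_true(all(tab$adjusted_p >= tab$raw_p - 1e-12))

  expect_error(nodewise_comparison(msci[1, , drop = FALSE], msni),
               "at least 2")
})

test_that("untestable zero-variance nodes shrink the corrected family", {
  set.seed(161)
  A <- matrix(rnorm(40), 5, 8)
  B <- matrix(rnorm(40), 5, 8)
  A[, 3] <- B[, 3] <- 0  # isolated in every subject
  expect_message(tab <- nodewise_comparison(A, B), "m = 7")
  expect_true(is.na(tab$raw_p[3]))
  expect_false(tab$reject[3])
  expect_equal(attr(tab, "m"), 7)
})

test_that("a full-size parcellation yields one test per node", {
  set.seed(171)
  msni <- matrix(rlnorm(10 * 333, 5, 0.2), 10, 333)
  msci <- matrix(rlnorm(31 * 333, 5, 0.2), 31, 333)
  tab <- nodewise_comparison(msci, msni)
  expect_equal(nrow(tab), 333)
  expect_equal(attr(tab, "m"), 333)
})

test_that("global comparison is one-tailed with explicit directions", {
  dirs <- global_test_directions(characteristic_path_length = "msci_greater",
                                 diameter = "msci_greater")
  expect_error(global_test_directions(), "explicitly")
  expect_length(dirs, 7)

  set.seed(181)
  vals <- matrix(rnorm(7 * 12), 12, 7)
  colnames(vals) <- names(dirs)
  msci <- as.data.frame(vals[1:6, ])
  msni <- as.data.frame(vals[7:12, ])
  same <- global_comparison(msci, msci + 0, dirs)
  expect_equal(nrow(same), 7)
  expect_false(any(same$reject))

  # a strong planted deficit in the hypothesized direction is detected
  msci$curvature <- msci$curvature - 10
  got <- global_comparison(msci, msni, dirs)
  expect_true(got$reject[got$measure == "curvature"])
  # and a deficit against the stated tail is not rejected
  msci$density <- msci$density + 10
  got2 <- global_comparison(msci, msni, dirs)
  expect_false(got2$reject[got2$measure == "density"])
})

test_that("correlation with the CI index matches cor.test", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlate_with_ci(x, x / 5)$pearson_r, 1)
  expect_equal(correlate_with_ci(x, -x)$pearson_r, -1)
  set.seed(191)
  for (r in 1:10) {
    v <- rnorm(15)
    ci <- 0.3 * v + rnorm(15)
    mine <- correlate_with_ci(v, ci)
    ref <- cor.test(v, ci)
    expect_equal(mine$pearson_r, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
  expect_error(correlate_with_ci(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(correlate_with_ci(c(1, 2), c(1, 2)), "at least 3")
})

test_that("nodewise correlations report the requested nodes", {
  set.seed(201)
  tabm <- matrix(rnorm(20 * 6), 20, 6)
  ci <- runif(20)
  out <- correlate_nodes_with_ci(tabm, ci, nodes = c(2, 5),
                                 measure_name = "strength")
  expect_equal(out$node, c(2, 5))
  expect_equal(out$n, c(20, 20))
  corr <- correlate_nodes_with_ci(tabm, ci, correct = TRUE)
  expect_true(all(corr$adjusted_p >= corr$p_value - 1e-12))
})
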