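two_group_expr <- function(values, n1, n2) {
  labels <- stats::setNames(rep(c("A", "B"), c(n1, n2)),
                            sprintf("s%03d", seq_len(n1 + n2)))
  colnames(values) <- names(labels)
  make_expr(values, labels)
}

test_that("d statistic matches the defining formula gene by gene", {
  set.seed(5)
  n1 <- 6; n2 <- 8
  expr <- two_group_expr(matrix(rnorm(100 * (n1 + n2)), 100), n1, n2)
  labels <- factor(expr$sample_labels, levels = c("A", "B"))
  s0 <- 0.2
  d <- compute_d_statistics(expr, labels, s0)
  for (i in c(1, 17, 50, 100)) {
    x1 <- expr$values[i, 1:n1]; x2 <- expr$values[i, n1 + 1:n2]
    si <- sqrt((1 / n1 + 1 / n2) *
                 (sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)) /
                 (n1 + n2 - 2))
    expect_equal(unname(d[i]), (mean(x2) - mean(x1)) / (si + s0))
  }
})

test_that("d is zero for equal group means and follows the fudge-factor arithmetic", {
  v <- rbind(c(0, 0, 0, 1, 1, 1),
             c(0, 0, 0, 5, 5, 5))
  v[1, ] <- c(2, 2, 2, 2, 2, 2) + c(-1, 0, 1, -1, 0, 1)
  expr <- two_group_expr(v, 3, 3)
  labels <- factor(expr$sample_labels, levels = c("A", "B"))
  d <- compute_d_statistics(expr, labels, s0 = 0.1)
  expect_equal(unname(d[1]), 0)           # same means in both groups
  expect_equal(unname(d[2]), 5 / 0.1)     # zero within-group variance: d = diff/s0
})

test_that("zero-variance genes with s0 = 0 are rejected", {
  v <- rbind(rep(1, 8), rnorm(8))
  expr <- two_group_expr(v, 4, 4)
  labels <- factor(expr$sample_labels, levels = c("A", "B"))
  expect_error(compute_d_statistics(expr, labels, s0 = 0), "s0")
  expect_silent(compute_d_statistics(expr, labels, s0 = 0.01))
})

test_that("d is antisymmetric under group-label swap", {
  set.seed(9)
  expr <- two_group_expr(matrix(rnorm(50 * 12), 50), 5, 7)
  f1 <- factor(expr$sample_labels, levels = c("A", "B"))
  f2 <- factor(expr$sample_labels, levels = c("B", "A"))
  expect_equal(compute_d_statistics(expr, f1, 0.3),
               -compute_d_statistics(expr, f2, 0.3))
})

test_that("s0 estimate lies on the percentile grid and is deterministic", {
  set.seed(21)
  # heteroskedastic genes: SD grows with index
  v <- matrix(rnorm(200 * 16), 200) * seq(0.1, 3, length.out = 200)
  expr <- two_group_expr(v, 8, 8)
  labels <- factor(expr$sample_labels, levels = c("A", "B"))
  s0 <- estimate_s0(expr, labels)
  p <- regsig:::.d_parts(expr$values, expr$sample_labels == "B")
  grid <- unname(stats::quantile(p$s, seq(0, 1, by = 0.05), type = 7))
  expect_true(any(abs(grid - s0) < 1e-12))
  expect_identical(estimate_s0(expr, labels), s0)

  # independent exhaustive grid search over the same objective
  strata <- cut(rank(p$s, ties.method = "first"), breaks = 10, labels = FALSE)
  cv <- sapply(grid, function(cand) {
    d <- p$num / (p$s + cand)
    mads <- tapply(d, strata, stats::mad)
    stats::sd(mads) / mean(mads)
  })
  expect_equal(s0, grid[which.min(cv)])
})

test_that("equal spreads give a flat objective resolved toward the smallest candidate", {
  set.seed(4)
  # all genes share one spread: every candidate yields identical stratified
  # CV, so the tie-break must return the first grid value
  base <- rnorm(16)
  v <- t(sapply(1:40, function(i) base + i))   # same deviations, shifted
  expr <- two_group_expr(v, 8, 8)
  labels <- factor(expr$sample_labels, levels = c("A", "B"))
  p <- regsig:::.d_parts(expr$values, expr$sample_labels == "B")
  expect_true(diff(range(p$s)) < 1e-12)
  expect_equal(estimate_s0(expr, labels), unname(stats::quantile(p$s, 0)))
})

test_that("SAM result is invariant to a column permutation with labels carried along", {
  set.seed(13)
  v <- matrix(rnorm(80 * 16), 80,
              dimnames = list(sprintf("g%02d", 1:80), sprintf("s%02d", 1:16)))
  v[1:5, 9:16] <- v[1:5, 9:16] + 4
  labels <- stats::setNames(rep(c("A", "B"), each = 8), colnames(v))
  expr <- make_expr(v, labels)
  res <- sam_significant_genes(expr, factor(labels, c("A", "B")),
                               n_permutations = 100, seed = 3)
  perm <- sample(16)
  expr2 <- make_expr(v[, perm], labels[perm])
  res2 <- sam_significant_genes(expr2, factor(labels[perm], c("A", "B")),
                                n_permutations = 100, seed = 3)
  expect_equal(sort(res2$significant_up), sort(res$significant_up))
  expect_equal(sort(res2$significant_down), sort(res$significant_down))
  expect_equal(res2$d[names(res$d)], res$d)
})

test_that("significant sets are disjoint, directional, and monotone in delta", {
  set.seed(31)
  v <- matrix(rnorm(300 * 20), 300,
              dimnames = list(sprintf("g%03d", 1:300), sprintf("s%02d", 1:20)))
  v[1:10, 11:20] <- v[1:10, 11:20] + 3
  v[11:20, 11:20] <- v[11:20, 11:20] - 3
  labels <- stats::setNames(rep(c("A", "B"), each = 10), colnames(v))
  expr <- make_expr(v, labels)
  res <- sam_significant_genes(expr, factor(labels, c("A", "B")),
                               n_permutations = 150, seed = 2)
  expect_length(intersect(res$significant_up, res$significant_down), 0)
  expect_true(all(res$d[res$significant_up] > 0))
  expect_true(all(res$d[res$significant_down] < 0))

  # monotone thresholding: calls at a larger delta are a subset
  dsort <- sort(unname(res$d))
  for (mult in c(1.5, 3)) {
    cuts <- regsig:::.sam_cutoffs(dsort, res$expected_d, res$delta * mult)
    up2 <- names(res$d)[res$d >= cuts$cutup]
    dn2 <- names(res$d)[res$d <= cuts$cutlow]
    expect_true(all(up2 %in% res$significant_up))
    expect_true(all(dn2 %in% res$significant_down))
  }
})

test_that("the FDR estimate near delta = 0 is about 1 on pure noise", {
  fdrs <- sapply(1:10, function(seed) {
    set.seed(seed * 100)
    v <- matrix(rnorm(200 * 16), 200,
                dimnames = list(sprintf("g%03d", 1:200), sprintf("s%02d", 1:16)))
    labels <- stats::setNames(rep(c("A", "B"), each = 8), colnames(v))
    expr <- make_expr(v, labels)
    g2 <- labels == "B"
    s0 <- estimate_s0(expr, factor(labels, c("A", "B")))
    d <- compute_d_statistics(expr, factor(labels, c("A", "B")), s0)
    set.seed(seed)
    Dperm <- sapply(1:100, function(b) {
      gp <- sample(g2)
      p <- regsig:::.d_parts(v, gp)
      sort(p$num / (p$s + s0))
    })
    dsort <- sort(unname(d))
    cuts <- regsig:::.sam_cutoffs(dsort, rowMeans(Dperm), 1e-9)
    calls <- sum(d >= cuts$cutup) + sum(d <= cuts$cutlow)
    false <- mean(sapply(1:100, function(b) {
      sum(Dperm[, b] >= cuts$cutup) + sum(Dperm[, b] <= cuts$cutlow)
    }))
    min(1, false / calls)
  })
  expect_true(abs(mean(fdrs) - 1) < 0.1)
})

test_that("degenerate labelings are rejected", {
  v <- matrix(rnorm(20 * 4), 20,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("s%d", 1:4)))
  labels <- stats::setNames(c("A", "A", "B", "B"), colnames(v))
  expr <- make_expr(v, labels)
  expect_error(sam_significant_genes(expr, factor(c("A", "A", "A", "A"),
                                                  levels = c("A", "B")),
                                     n_permutations = 100),
               "two groups")
})
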