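test_that("jackknife correlation handles exact and enumerated cases", {
  x <- c(0, 1, 2, 3, 4)
  expect_equal(jackknife_correlation(x, x), 1)
  expect_equal(jackknife_correlation(x, -x), -1)

  y <- c(0, 1, 2, 3, 100)
  manual <- min(sapply(1:5, function(j) stats::cor(x[-j], y[-j])))
  expect_equal(jackknife_correlation(x, y), manual)
  # the outlying fifth sample drives the correlation: deleting it must hurt
  expect_lt(jackknife_correlation(x, y), stats::cor(x, y))

  expect_error(jackknife_correlation(c(1, 1, 1, 2), c(1, 2, 3, 4)),
               "constant")
})

test_that("the pairwise jackknife matrix agrees with per-pair enumeration", {
  set.seed(12)
  v <- matrix(rnorm(8 * 10), 8,
              dimnames = list(sprintf("g%d", 1:8), sprintf("s%02d", 1:10)))
  expect_equal(regsig:::.jackknife_cor_matrix(v), jk_matrix_oracle(v),
               tolerance = 1e-12)
})

test_that("defaults are a 0.4 correlation floor and minimum size 15", {
  expect_equal(formals(qt_cluster)$similarity_cutoff, 0.4)
  expect_equal(formals(qt_cluster)$min_size, 15L)
})

test_that("a planted shared-factor cluster is recovered exactly", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 30
    latent <- rnorm(n)
    planted <- t(sapply(1:20, function(i) latent + rnorm(n, 0, 0.3)))
    noise <- matrix(rnorm(30 * n), 30)
    v <- rbind(planted, noise)
    rownames(v) <- c(sprintf("plant%02d", 1:20), sprintf("noise%02d", 1:30))
    expr <- make_expr(v)
    clusters <- qt_cluster(expr, similarity_cutoff = 0.4, min_size = 15)
    expect_length(clusters, 1)
    expect_true(all(sprintf("plant%02d", 1:20) %in% clusters[[1]]$members))
    expect_gte(clusters[[1]]$min_pairwise_similarity, 0.4)
  }
})

test_that("no admissible pair means no clusters", {
  set.seed(77)
  v <- matrix(rnorm(10 * 40), 10,
              dimnames = list(sprintf("g%d", 1:10), sprintf("s%02d", 1:40)))
  clusters <- qt_cluster(make_expr(v), similarity_cutoff = 0.95, min_size = 2)
  expect_length(clusters, 0)
  expect_error(qt_cluster(make_expr(v), min_size = 1), "min_size")
})

test_that("emitted clusters are disjoint and satisfy the cutoff post hoc", {
  set.seed(19)
  n <- 12
  v <- rbind(
    t(sapply(1:6, function(i) rnorm(n))),
    t(sapply(1:4, function(i) rep(rnorm(1), n) + rnorm(n))))
  base1 <- rnorm(n); base2 <- rnorm(n)
  v <- rbind(v,
             t(sapply(1:4, function(i) base1 + rnorm(n, 0, 0.2))),
             t(sapply(1:3, function(i) base2 + rnorm(n, 0, 0.2))))
  rownames(v) <- sprintf("g%02d", seq_len(nrow(v)))
  expr <- make_expr(v)
  clusters <- qt_cluster(expr, similarity_cutoff = 0.4, min_size = 2)
  members <- unlist(lapply(clusters, `[[`, "members"))
  expect_equal(anyDuplicated(members), 0)
  expect_true(all(members %in% rownames(v)))
  std <- t(scale(t(v)))
  for (cl in clusters) {
    jk <- jk_matrix_oracle(std[cl$members, , drop = FALSE])
    expect_gte(min(jk[lower.tri(jk)]), 0.4)
  }
})

test_that("small instances match the exhaustive-growth oracle and attain maximal sizes", {
  for (seed in 1:8) {
    set.seed(seed)
    g <- sample(8:11, 1); n <- 8
    v <- matrix(rnorm(g * n), g,
                dimnames = list(sprintf("g%02d", 1:g), sprintf("s%d", 1:n)))
    for (i in 1:3) {
      a <- sample(g, 1); b <- sample(g, 1)
      if (a != b) v[b, ] <- v[a, ] * 0.8 + rnorm(n, 0, 0.4)
    }
    expr <- make_expr(v)
    got <- lapply(qt_cluster(expr, 0.4, min_size = 2),
                  function(cl) match(cl$members, rownames(v)))
    jk <- jk_matrix_oracle(t(scale(t(v))))
    expect_equal(got, qt_cluster_oracle(jk, 0.4, min_size = 2))
    # each emitted cluster is as large as any admissible subset available
    available <- seq_len(g)
    for (cl in got) {
      expect_equal(length(cl), qt_max_admissible_size(jk, 0.4, available))
      available <- setdiff(available, cl)
    }
  }
})

test_that("the diameter reading of the cutoff converts to a similarity floor", {
  set.seed(55)
  n <- 10
  base <- rnorm(n)
  v <- rbind(t(sapply(1:4, function(i) base + rnorm(n, 0, 0.3))),
             matrix(rnorm(4 * n), 4))
  rownames(v) <- sprintf("g%d", 1:8)
  expr <- make_expr(v)
  a <- qt_cluster(expr, similarity_cutoff = 0.4, min_size = 2,
                  cutoff_type = "similarity")
  b <- qt_cluster(expr, similarity_cutoff = 0.6, min_size = 2,
                  cutoff_type = "diameter")  # 1 - 0.6 = 0.4 floor
  expect_equal(lapply(a, `[[`, "members"), lapply(b, `[[`, "members"))
})
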