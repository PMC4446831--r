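#' Build a one-vs-rest two-group label vector
#'
#' Convenience for subtype signatures: contrasts one subtype against all
#' remaining samples. The returned factor has levels `c("rest", group)`, so
#' positive SAM d statistics mean "up in `group`".
#'
#' @param expr An `ExpressionMatrix`.
#' @param group A group label present in `expr$sample_labels`.
#' @return A named factor over the samples with two levels.
#' @export
contrast_labels <- function(expr, group) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (!group %in% expr$sample_labels) {
    stop("group ", dQuote(group), " not present among sample labels")
  }
  lab <- ifelse(expr$sample_labels == group, group, "rest")
  factor(stats::setNames(lab, names(expr$sample_labels)),
         levels = c("rest", group))
}

.check_two_groups <- function(expr, labels) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2L) stop("labels must define exactly two groups")
  labels <- droplevels(labels)
  if (length(labels) != ncol(expr$values)) {
    stop("labels length must equal the number of samples")
  }
  if (any(table(labels) < 2L)) stop("each group needs at least 2 samples")
  labels
}

# per-gene relative difference and pooled standard error; group2 = second level
.d_parts <- function(values, g2) {
  n1 <- sum(!g2); n2 <- sum(g2)
  m1 <- rowMeans(values[, !g2, drop = FALSE])
  m2 <- rowMeans(values[, g2, drop = FALSE])
  ss1 <- rowSums((values[, !g2, drop = FALSE] - m1)^2)
  ss2 <- rowSums((values[, g2, drop = FALSE] - m2)^2)
  s <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
  list(num = m2 - m1, s = s)
}

#' SAM relative-difference statistic
#'
#' Computes the per-gene moderated statistic
#' `d_i = (mean2_i - mean1_i) / (s_i + s0)`, where `s_i` is the pooled
#' standard error of the mean difference and `s0` a small positive "fudge"
#' constant that damps genes with near-zero spread.
#'
#' @param expr An `ExpressionMatrix`.
#' @param labels Two-group factor over samples (second level is "group 2";
#'   positive d = higher in group 2). See [contrast_labels()].
#' @param s0 Non-negative fudge factor; see [estimate_s0()].
#' @return Named numeric vector of d statistics (one per gene).
#' @export
compute_d_statistics <- function(expr, labels, s0) {
  stopifnot(inherits(expr, "ExpressionMatrix"), s0 >= 0)
  labels <- .check_two_groups(expr, labels)
  g2 <- labels == levels(labels)[2]
  p <- .d_parts(expr$values, g2)
  if (s0 == 0 && any(p$s == 0)) {
    stop("gene(s) with zero variance in both groups and s0 = 0; ",
         "use s0 > 0 (e.g. estimate_s0())")
  }
  stats::setNames(p$num / (p$s + s0), rownames(expr$values))
}

#' Estimate the SAM fudge factor s0
#'
#' Follows the percentile-search recipe: candidate values are the 0th, 5th,
#' ..., 100th percentiles of the per-gene standard errors `s_i`. For each
#' candidate the genes are cut into strata by `s_i` quantiles, the median
#' absolute deviation of `d` is computed per stratum, and the candidate
#' minimizing the coefficient of variation of these MADs is returned. Ties
#' break toward the smallest grid index, so the result is deterministic.
#'
#' @param expr An `ExpressionMatrix` with at least 10 genes.
#' @param labels Two-group factor over samples.
#' @param n_strata Number of `s_i` quantile strata (default 10, reduced if
#'   there are few genes).
#' @return The selected s0 (a value from the percentile grid).
#' @export
estimate_s0 <- function(expr, labels, n_strata = 10L) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  labels <- .check_two_groups(expr, labels)
  m <- nrow(expr$values)
  if (m < 10L) stop("need at least 10 genes to estimate s0")
  g2 <- labels == levels(labels)[2]
  p <- .d_parts(expr$values, g2)
  grid <- unname(stats::quantile(p$s, probs = seq(0, 1, by = 0.05), type = 7))
  n_strata <- max(2L, min(n_strata, m %/% 5L))
  strata <- cut(rank(p$s, ties.method = "first"),
                breaks = n_strata, labels = FALSE)
  cv <- vapply(grid, function(s0c) {
    d <- p$num / (p$s + s0c)
    mads <- vapply(split(d, strata), stats::mad, 0)
    mu <- mean(mads)
    if (mu == 0) 0 else stats::sd(mads) / mu
  }, 0)
  grid[which.min(cv)] # which.min takes the first (smallest grid index) on ties
}

# cutoffs for every candidate delta at once.
# dsort ascending, dbar the expected order statistics.
# cut_up(delta)  = min observed d among sorted positions with dbar >= 0 and
#                  dsort - dbar >= delta (Inf when none)
# cut_low(delta) = max observed d among positions with dbar <= 0 and
#                  dbar - dsort >= delta (-Inf when none)
.sam_cutoffs <- function(dsort, dbar, deltas) {
  diffs_up <- ifelse(dbar >= 0, dsort - dbar, -Inf)
  diffs_dn <- ifelse(dbar <= 0, dbar - dsort, -Inf)
  ord <- order(diffs_up, decreasing = TRUE)
  cmin <- cummin(dsort[ord])
  nup <- vapply(deltas, function(del) sum(diffs_up >= del), 0L)
  cutup <- ifelse(nup > 0L, cmin[pmax(nup, 1L)], Inf)
  ord2 <- order(diffs_dn, decreasing = TRUE)
  cmax <- cummax(dsort[ord2])
  ndn <- vapply(deltas, function(del) sum(diffs_dn >= del), 0L)
  cutlow <- ifelse(ndn > 0L, cmax[pmax(ndn, 1L)], -Inf)
  list(cutup = cutup, cutlow = cutlow)
}

#' Significance Analysis of Microarrays with permutation FDR
#'
#' Two-class SAM: computes the observed d statistics, recomputes them under
#' random relabelings of the samples to obtain the expected order statistics
#' and the null spread, then finds the smallest threshold `delta` whose
#' estimated FDR is at or below `target_fdr`. The FDR at a delta is
#' `pi0 * (summary of permuted false-call counts) / (observed call count)`,
#' with `pi0` the usual interquartile estimate of the null fraction, capped
#' at 1. The false-call summary across permutations is the mean by default
#' (the original SAM convention); `"median"` and `"q90"` are available.
#'
#' With `target_fdr = 0` (the setting used for subtype signatures) a gene is
#' only called when no permuted statistic anywhere in the null ensemble
#' falls beyond the cut point, which makes the call list highly specific.
#'
#' @param expr An `ExpressionMatrix`.
#' @param labels Two-group factor over samples (see [contrast_labels()]).
#' @param n_permutations Number of label permutations (default 1000). When
#'   the number of distinct assignments is at most this, all are enumerated.
#' @param target_fdr Target FDR in `[0, 1]` (default 0).
#' @param seed Integer seed for the permutation stream.
#' @param s0 Optional fudge factor; estimated via [estimate_s0()] if `NULL`.
#' @param false_count Summary of permuted false-call counts: `"mean"`
#'   (default), `"median"` or `"q90"`.
#' @return A `SAMResult`: list with `d` (named vector), `expected_d` (the
#'   null expected order statistics, aligned with `sort(d)`), `s0`, `delta`,
#'   `cutup`, `cutlow`, `significant_up`, `significant_down` (gene ids),
#'   `estimated_fdr`, `pi0`, `n_permutations`, `seed`.
#' @export
sam_significant_genes <- function(expr, labels, n_permutations = 1000L,
                                  target_fdr = 0, seed = 1L, s0 = NULL,
                                  false_count = c("mean", "median", "q90")) {
  false_count <- match.arg(false_count)
  stopifnot(inherits(expr, "ExpressionMatrix"),
            n_permutations >= 100L, target_fdr >= 0, target_fdr <= 1)
  labels <- .check_two_groups(expr, labels)
  g2 <- labels == levels(labels)[2]
  n <- length(g2); n2 <- sum(g2); m <- nrow(expr$values)
  values <- expr$values

  if (is.null(s0)) s0 <- estimate_s0(expr, labels)
  p <- .d_parts(values, g2)
  if (s0 == 0 && any(p$s == 0)) {
    stop("zero-variance gene(s) with s0 = 0; supply s0 > 0")
  }
  d <- stats::setNames(p$num / (p$s + s0), rownames(values))

  n_distinct <- choose(n, n2)
  if (n_distinct < 2) stop("labels admit no alternative permutation")
  set.seed(seed)
  if (n_distinct <= n_permutations) {
    combs <- utils::combn(n, n2)
    perms <- lapply(seq_len(ncol(combs)), function(j) {
      gp <- rep(FALSE, n); gp[combs[, j]] <- TRUE; gp
    })
  } else {
    perms <- lapply(seq_len(n_permutations), function(j) sample(g2))
  }
  B <- length(perms)
  Dperm <- vapply(perms, function(gp) {
    pp <- .d_parts(values, gp)
    sort(pp$num / (pp$s + s0))
  }, numeric(m))

  dsort <- sort(unname(d))
  dbar <- rowMeans(Dperm)
  q <- stats::quantile(Dperm, c(0.25, 0.75))
  pi0 <- min(1, sum(d >= q[1] & d <= q[2]) / (0.5 * m))

  diffs <- abs(dsort - dbar)
  deltas <- sort(unique(diffs))
  deltas <- c(deltas, deltas[length(deltas)] + 1) # sentinel: empty call set
  cuts <- .sam_cutoffs(dsort, dbar, deltas)

  calls <- (m - findInterval(cuts$cutup, dsort, left.open = TRUE)) +
    findInterval(cuts$cutlow, dsort)
  false_mat <- vapply(seq_len(B), function(b) {
    (m - findInterval(cuts$cutup, Dperm[, b], left.open = TRUE)) +
      findInterval(cuts$cutlow, Dperm[, b])
  }, numeric(length(deltas)))
  fc <- switch(false_count,
               mean = rowMeans(false_mat),
               median = apply(false_mat, 1, stats::median),
               q90 = apply(false_mat, 1, stats::quantile, probs = 0.9))
  fdr <- ifelse(calls > 0, pmin(1, pi0 * fc / calls), 0)

  idx <- which(fdr <= target_fdr)[1] # deltas ascending: smallest qualifying
  delta <- deltas[idx]
  cutup <- cuts$cutup[idx]; cutlow <- cuts$cutlow[idx]
  up <- names(d)[d >= cutup]
  down <- names(d)[d <= cutlow]

  structure(list(d = d, expected_d = dbar, s0 = s0, delta = delta,
                 cutup = cutup, cutlow = cutlow,
                 significant_up = up, significant_down = down,
                 estimated_fdr = unname(fdr[idx]), pi0 = pi0,
                 n_permutations = B, seed = seed,
                 false_count = false_count, target_fdr = target_fdr),
            class = "SAMResult")
}

#' @export
print.SAMResult <- function(x, ...) {
  cat("SAM two-class result\n",
      "  genes: ", length(x$d), ", permutations: ", x$n_permutations, "\n",
      "  s0 = ", signif(x$s0, 4), ", delta = ", signif(x$delta, 4),
      ", estimated FDR = ", signif(x$estimated_fdr, 4), "\n",
      "  significant: ", length(x$significant_up), " up, ",
      length(x$significant_down), " down\n", sep = "")
  invisible(x)
}

#' Write a SAMResult as TSV plus a run-metadata JSON
#'
#' @param result A `SAMResult`.
#' @param path Output TSV path (gene, d, expected d at the gene's rank,
#'   significant flag, direction). A JSON with s0, delta, seed and
#'   permutation count is written next to it (`<path>.json`).
#' @return `path`, invisibly.
#' @export
write_sam_result <- function(result, path) {
  stopifnot(inherits(result, "SAMResult"))
  ord <- order(result$d)
  genes <- names(result$d)[ord]
  dir <- ifelse(genes %in% result$significant_up, "up",
                ifelse(genes %in% result$significant_down, "down", "none"))
  df <- data.frame(gene = genes, d = unname(result$d[ord]),
                   expected_d = result$expected_d,
                   significant = dir != "none", direction = dir)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(s0 = result$s0, delta = result$delta, seed = result$seed,
               n_permutations = result$n_permutations,
               target_fdr = result$target_fdr,
               false_count = result$false_count,
               estimated_fdr = result$estimated_fdr, pi0 = result$pi0)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
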