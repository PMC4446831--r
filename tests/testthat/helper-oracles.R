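# Independent reference implementations used to cross-check the package.
# These deliberately follow the defining formulas directly (explicit tail
# summation, all-pairs scans, exhaustive enumeration) rather than the
# package's computational paths.

# upper hypergeometric tail P(X >= k) for X ~ Hypergeom(N total, K marked,
# n drawn), by direct summation of the probability mass terms
hyper_tail_oracle <- function(k, N, K, n) {
  lo <- max(0, n - (N - K))
  hi <- min(K, n)
  if (k > hi) return(0)
  kk <- max(k, lo):hi
  sum(exp(lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n)))
}

# all-pairs interval-overlap scan: counts peaks overlapping each window by
# >= 1 bp (0-based half-open coordinates on both sides)
brute_overlap_counts <- function(promoters, peaks) {
  vapply(seq_len(nrow(promoters)), function(i) {
    same <- peaks$chrom == promoters$chrom[i]
    ov <- pmin(peaks$end[same], promoters$end[i]) -
      pmax(peaks$start[same], promoters$start[i])
    sum(ov >= 1)
  }, 0L)
}

# pairwise jackknife correlation recomputed from the definition: explicit
# leave-one-out Pearson for every pair (no shared-correlation-matrix path)
jk_matrix_oracle <- function(values) {
  g <- nrow(values)
  jk <- diag(1, g)
  for (a in seq_len(g - 1)) {
    for (b in (a + 1):g) {
      jk[a, b] <- jk[b, a] <- jackknife_correlation(values[a, ], values[b, ])
    }
  }
  dimnames(jk) <- list(rownames(values), rownames(values))
  jk
}

# exhaustive QT-cluster oracle sharing the implementation's documented
# tie-breaks: candidate clusters are grown from every seed by literally
# re-evaluating, for each possible addition, the minimum pairwise similarity
# of the would-be cluster from scratch (no incremental state); the largest
# candidate wins (size ties: larger minimum pairwise similarity, then the
# smallest seed index); growth ties break toward the smallest gene index.
# Additionally each emitted cluster's size is checked against a full subset
# enumeration in qt_max_admissible_size().
qt_cluster_oracle <- function(jk, cutoff, min_size = 2L) {
  pair_min <- function(s) {
    if (length(s) < 2) return(1)
    sub <- jk[s, s, drop = FALSE]
    min(sub[lower.tri(sub)])
  }
  grow <- function(seed_idx, available) {
    members <- seed_idx
    repeat {
      cand <- setdiff(available, members)
      if (!length(cand)) break
      objs <- vapply(cand, function(c0) pair_min(c(members, c0)), 0)
      best <- which(objs == max(objs))[1]
      if (objs[best] < cutoff) break
      members <- c(members, cand[best])
    }
    members
  }
  available <- seq_len(nrow(jk))
  clusters <- list()
  repeat {
    if (length(available) < max(2L, min_size)) break
    best <- NULL
    for (s in available) {
      memb <- grow(s, available)
      if (is.null(best) || length(memb) > length(best) ||
          (length(memb) == length(best) &&
             pair_min(memb) > pair_min(best))) {
        best <- memb
      }
    }
    if (length(best) < min_size) break
    clusters[[length(clusters) + 1L]] <- best
    available <- setdiff(available, best)
  }
  clusters
}

# size of the largest admissible subset (min pairwise similarity >= cutoff)
# among the given gene indices, by full subset enumeration
qt_max_admissible_size <- function(jk, cutoff, available) {
  n <- length(available)
  best <- if (n >= 1) 1L else 0L
  for (sz in n:2) {
    if (sz <= best) break
    combs <- utils::combn(available, sz)
    for (j in seq_len(ncol(combs))) {
      s <- combs[, j]
      sub <- jk[s, s]
      if (min(sub[lower.tri(sub)]) >= cutoff) {
        best <- sz
        break
      }
    }
    if (best == sz) break
  }
  best
}

# small helper: ExpressionMatrix from a bare matrix with one or two groups
make_expr <- function(values, labels = NULL) {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%03d", seq_len(ncol(values)))
  }
  if (is.null(labels)) {
    labels <- stats::setNames(rep("A", ncol(values)), colnames(values))
  }
  ExpressionMatrix(values, labels)
}

# binding matrix with a prescribed bound pattern and per-bound-gene peaks
make_binding <- function(bound, peaks_per_bound = 1L, factor = "TF") {
  pc <- matrix(as.integer(bound) * peaks_per_bound, ncol = 1,
               dimnames = list(names(bound), factor))
  BindingMatrix(pc)
}
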