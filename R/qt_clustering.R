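#' Jackknife correlation of two sample vectors
#'
#' The minimum Pearson correlation over all leave-one-sample-out deletions.
#' Robust against a single outlying sample inflating an otherwise weak
#' correlation.
#'
#' @param x,y Numeric vectors of equal length (at least 4 samples).
#' @return The minimum leave-one-out Pearson correlation.
#' @export
jackknife_correlation <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 4L)
  r <- vapply(seq_len(n), function(j) {
    xs <- x[-j]; ys <- y[-j]
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
      stop("constant vector after deleting sample ", j,
           "; filter zero-variance genes first")
    }
    stats::cor(xs, ys)
  }, 0)
  min(r)
}

# all-pairs jackknife correlation matrix: elementwise min over the n
# leave-one-sample-out Pearson correlation matrices
.jackknife_cor_matrix <- function(values) {
  n <- ncol(values)
  if (n < 4L) stop("need at least 4 samples for jackknife correlation")
  sds <- apply(values, 1, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance gene(s): ",
         paste(utils::head(rownames(values)[sds == 0], 5), collapse = ", "))
  }
  jk <- NULL
  for (j in seq_len(n)) {
    sub <- values[, -j, drop = FALSE]
    if (any(apply(sub, 1, stats::sd) == 0)) {
      stop("gene constant after deleting sample ", j,
           "; filter near-constant genes first")
    }
    cj <- stats::cor(t(sub))
    jk <- if (is.null(jk)) cj else pmin(jk, cj)
  }
  jk
}

# greedy growth from one seed: at each step add the gene maximizing the
# cluster's minimum pairwise similarity, requiring it to stay >= cutoff;
# ties break toward the smallest gene index
.grow_cluster <- function(jk, seed_idx, available, cutoff) {
  members <- seed_idx
  minsim <- rep(Inf, nrow(jk))       # min similarity of each gene to members
  cand <- setdiff(available, seed_idx)
  minsim[cand] <- jk[cand, seed_idx]
  cur_min <- Inf
  repeat {
    if (!length(cand)) break
    obj <- pmin(cur_min, minsim[cand])
    best <- which(obj == max(obj))[1]
    if (obj[best] < cutoff) break
    g <- cand[best]
    cur_min <- obj[best]
    members <- c(members, g)
    cand <- cand[-best]
    if (length(cand)) minsim[cand] <- pmin(minsim[cand], jk[cand, g])
  }
  list(members = members, min_sim = if (length(members) > 1) cur_min else 1)
}

#' Quality-Threshold clustering under jackknife correlation
#'
#' Classic QT scheme: every remaining gene seeds a candidate cluster that is
#' grown greedily -- each step adds the gene that keeps the cluster's minimum
#' pairwise jackknife correlation as high as possible, stopping when no
#' addition keeps it at or above `similarity_cutoff`. The largest candidate
#' cluster is emitted, its members removed, and the procedure repeats until
#' the largest candidate falls below `min_size`.
#'
#' Determinism: among equally large candidate clusters the one with the
#' larger minimum pairwise similarity (the quality objective itself) wins,
#' and remaining ties fall to the smallest seed-gene input index; growth
#' ties break toward the smallest gene index.
#'
#' Note that growing by maximal minimum similarity is the same rule as
#' growing by minimal cluster diameter under the distance `1 - r`, so the
#' two classic formulations coincide here; `cutoff_type = "diameter"` merely
#' reinterprets the cutoff value as a ceiling on `1 - r`.
#'
#' @param expr An `ExpressionMatrix` (genes are clustered across samples).
#'   Rows are standardized to mean 0, SD 1 before clustering (a no-op for
#'   Pearson correlation itself).
#' @param similarity_cutoff Minimum pairwise jackknife correlation within a
#'   cluster (default 0.4).
#' @param min_size Minimum cluster size to emit (default 15; must be >= 2).
#' @param cutoff_type `"similarity"` (default: cutoff is a correlation
#'   floor) or `"diameter"` (cutoff is a ceiling on `1 - r`, i.e. a floor of
#'   `1 - cutoff` on r).
#' @return List of `QTCluster` objects, each a list with `members` (gene
#'   ids, in growth order), `seed_gene`, and `min_pairwise_similarity`.
#' @export
qt_cluster <- function(expr, similarity_cutoff = 0.4, min_size = 15L,
                       cutoff_type = c("similarity", "diameter")) {
  cutoff_type <- match.arg(cutoff_type)
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (min_size < 2L) stop("min_size must be at least 2")
  cutoff <- if (cutoff_type == "similarity") similarity_cutoff else 1 - similarity_cutoff

  values <- expr$values
  values <- t(scale(t(values)))  # row-standardize (cosmetic for Pearson)
  jk <- .jackknife_cor_matrix(values)
  genes <- rownames(expr$values)

  available <- seq_along(genes)
  clusters <- list()
  repeat {
    if (length(available) < max(2L, min_size)) break
    best <- NULL
    for (s in available) {
      cand <- .grow_cluster(jk, s, available, cutoff)
      if (is.null(best) ||
          length(cand$members) > length(best$members) ||
          (length(cand$members) == length(best$members) &&
             cand$min_sim > best$min_sim)) {
        best <- cand
      }
    }
    if (length(best$members) < min_size) break
    idx <- best$members
    clusters[[length(clusters) + 1L]] <- structure(
      list(members = genes[idx], seed_gene = genes[idx[1]],
           min_pairwise_similarity = best$min_sim),
      class = "QTCluster")
    available <- setdiff(available, idx)
  }
  clusters
}

#' Write QT clusters as TSV
#'
#' @param clusters List of `QTCluster` objects (from [qt_cluster()]).
#' @param path Output path; columns `cluster_id`, `gene`, `is_seed`.
#' @return `path`, invisibly.
#' @export
write_qt_clusters <- function(clusters, path) {
  rows <- lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    data.frame(cluster_id = i, gene = cl$members,
               is_seed = cl$members == cl$seed_gene)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster_id = integer(), gene = character(), is_seed = logical())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
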