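.check_query <- function(binding, query) {
  universe <- rownames(binding$bound)
  missing_g <- setdiff(query, universe)
  if (length(missing_g)) {
    stop("query gene(s) absent from the binding universe: ",
         paste(utils::head(missing_g, 10), collapse = ", "))
  }
  universe
}

#' One-tailed Fisher's exact test for promoter-binding enrichment
#'
#' Tests whether a query gene list contains more promoters bound by `factor`
#' than expected from the binding universe: the upper hypergeometric tail
#' `P(X >= n_bound_query)` with parameters (universe size, bound promoters
#' in the universe, query size). Enrichment direction only.
#'
#' @param binding A `BindingMatrix`; its genes are the universe.
#' @param query Character vector of query gene identifiers.
#' @param factor Column (factor) name in the binding matrix.
#' @return An `EnrichmentResult` with the count fields and `fisher_p`
#'   filled in.
#' @export
fisher_enrichment <- function(binding, query, factor) {
  stopifnot(inherits(binding, "BindingMatrix"),
            factor %in% colnames(binding$bound))
  universe <- .check_query(binding, query)
  bound <- binding$bound[, factor]
  N <- length(universe)
  K <- sum(bound)
  n <- length(query)
  k <- sum(bound[query])
  # upper tail P(X >= k) of Hypergeometric(N, K, n)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  structure(list(factor = factor, query_size = n, n_bound_query = k,
                 n_bound_universe = K, universe_size = N,
                 total_peaks_query = sum(binding$peak_count[query, factor]),
                 fisher_p = p, resampling_p_bound = NA_real_,
                 resampling_p_peaks = NA_real_, n_resamples = NA_integer_,
                 seed = NA_integer_),
            class = "EnrichmentResult")
}

#' Resampling test for promoter-binding enrichment
#'
#' Compares the query list against random gene lists of equal size drawn
#' without replacement from the universe, on two statistics at once: the
#' number of bound promoters and the total number of peaks. Empirical
#' p-values use the add-one convention `(1 + #{draw >= observed}) /
#' (n_resamples + 1)`, so they are never zero and ties count toward the
#' tail.
#'
#' @param binding A `BindingMatrix`.
#' @param query Character vector of query gene identifiers.
#' @param factor Column (factor) name in the binding matrix.
#' @param n_resamples Number of random gene lists (default 100000).
#' @param seed Integer seed.
#' @param keep_null Keep the per-draw null statistics (for histogram
#'   output)? Default `FALSE`.
#' @return An `EnrichmentResult` with both Fisher and resampling fields;
#'   when `keep_null` is `TRUE`, the null draws are attached as
#'   `null_bound` and `null_peaks`.
#' @export
resampling_enrichment <- function(binding, query, factor,
                                  n_resamples = 100000L, seed = 1L,
                                  keep_null = FALSE) {
  stopifnot(n_resamples >= 100L)
  res <- fisher_enrichment(binding, query, factor)
  universe <- rownames(binding$bound)
  N <- length(universe)
  n <- length(query)
  if (n > N) stop("query larger than the universe")
  bound <- as.numeric(binding$bound[, factor])
  pk <- as.numeric(binding$peak_count[, factor])

  set.seed(seed)
  null_bound <- integer(n_resamples)
  null_peaks <- numeric(n_resamples)
  # chunked to bound memory at large n_resamples
  chunk <- max(1L, min(n_resamples, 20000L))
  done <- 0L
  while (done < n_resamples) {
    nb <- min(chunk, n_resamples - done)
    for (i in seq_len(nb)) {
      idx <- sample.int(N, n)
      null_bound[done + i] <- sum(bound[idx])
      null_peaks[done + i] <- sum(pk[idx])
    }
    done <- done + nb
  }
  res$resampling_p_bound <-
    (1 + sum(null_bound >= res$n_bound_query)) / (n_resamples + 1)
  res$resampling_p_peaks <-
    (1 + sum(null_peaks >= res$total_peaks_query)) / (n_resamples + 1)
  res$n_resamples <- n_resamples
  res$seed <- seed
  if (keep_null) {
    res$null_bound <- null_bound
    res$null_peaks <- null_peaks
  }
  res
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat("Binding enrichment for factor ", x$factor, "\n",
      "  query: ", x$n_bound_query, "/", x$query_size, " bound; universe: ",
      x$n_bound_universe, "/", x$universe_size, " bound\n",
      "  total peaks in query promoters: ", x$total_peaks_query, "\n",
      "  Fisher one-tailed p = ", format(x$fisher_p, digits = 4), "\n", sep = "")
  if (!is.na(x$resampling_p_bound)) {
    cat("  resampling p (bound promoters) = ",
        format(x$resampling_p_bound, digits = 4),
        "; resampling p (peak count) = ",
        format(x$resampling_p_peaks, digits = 4),
        "  [", x$n_resamples, " draws]\n", sep = "")
  }
  invisible(x)
}

#' Hypergeometric overlap test between two gene lists
#'
#' @param list_a,list_b Character vectors, both subsets of `universe`.
#' @param universe Character vector of the gene universe.
#' @return List with `overlap` (size of the intersection) and `p`, the upper
#'   hypergeometric tail `P(X >= overlap)` with parameters
#'   (|universe|, |list_b|, |list_a|).
#' @export
gene_list_overlap <- function(list_a, list_b, universe) {
  out_a <- setdiff(list_a, universe)
  out_b <- setdiff(list_b, universe)
  if (length(out_a) || length(out_b)) {
    stop("gene(s) outside the universe: ",
         paste(utils::head(c(out_a, out_b), 10), collapse = ", "))
  }
  list_a <- unique(list_a); list_b <- unique(list_b)
  ov <- length(intersect(list_a, list_b))
  p <- stats::phyper(ov - 1, length(list_b),
                     length(universe) - length(list_b),
                     length(list_a), lower.tail = FALSE)
  list(overlap = ov, p = p)
}

#' Write an EnrichmentResult (and optional null histogram) as TSV
#'
#' @param result An `EnrichmentResult`.
#' @param path Output path for the one-row result table.
#' @param null_path Optional path; when given and the result carries null
#'   draws, writes the two null-statistic samples for histogram plotting.
#' @return `path`, invisibly.
#' @export
write_enrichment_result <- function(result, path, null_path = NULL) {
  stopifnot(inherits(result, "EnrichmentResult"))
  fields <- c("factor", "query_size", "n_bound_query", "n_bound_universe",
              "universe_size", "total_peaks_query", "fisher_p",
              "resampling_p_bound", "resampling_p_peaks", "n_resamples",
              "seed")
  df <- as.data.frame(result[fields], stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(null_path) && !is.null(result$null_bound)) {
    utils::write.table(
      data.frame(null_bound = result$null_bound,
                 null_peaks = result$null_peaks),
      null_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
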