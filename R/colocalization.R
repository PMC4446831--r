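#' Spatial colocalization profile of one factor's peaks around another's
#'
#' For every anchor-factor peak that overlaps a query-gene promoter, offsets
#' to all other-factor peak midpoints within `+/- window_bp` are collected
#' (other midpoint minus anchor midpoint) and histogrammed into bins of
#' `bin_width_bp`. Peak position is the interval midpoint (integer floor).
#' Each (anchor, other) peak pair within the window counts once; anchors
#' overlapping several promoters are not deduplicated across promoters but
#' each anchor *peak* contributes its pairs once.
#'
#' @param anchor A `PeakSet` providing the centering events.
#' @param other A `PeakSet` whose peaks are profiled around the anchors.
#' @param promoters A `PromoterSet`.
#' @param query Character vector of gene ids restricting the promoters in
#'   scope; `NULL` uses all promoters.
#' @param window_bp Half-window in bp (default 1000).
#' @param bin_width_bp Bin width in bp (default 50); must divide
#'   `window_bp`.
#' @return A `ColocProfile`: list with `anchor_factor`, `other_factor`,
#'   `window_bp`, `bin_width_bp`, `bins` (data.frame `bin_left`,
#'   `bin_right`, left-closed, last bin right-closed), `counts`, and
#'   `n_anchor_events`.
#' @export
colocalization_profile <- function(anchor, other, promoters, query = NULL,
                                   window_bp = 1000L, bin_width_bp = 50L) {
  stopifnot(inherits(anchor, "PeakSet"), inherits(other, "PeakSet"),
            inherits(promoters, "PromoterSet"))
  if (window_bp <= 0) stop("window_bp must be positive")
  if (window_bp %% bin_width_bp != 0) {
    stop("window_bp (", window_bp, ") must be divisible by bin_width_bp (",
         bin_width_bp, ")")
  }
  if (!is.null(query)) {
    missing_g <- setdiff(query, promoters$gene_id)
    if (length(missing_g)) {
      stop("query gene(s) without promoter windows: ",
           paste(utils::head(missing_g, 10), collapse = ", "))
    }
    promoters <- promoters[promoters$gene_id %in% query, , drop = FALSE]
  }

  aiv <- anchor$intervals
  prom_gr <- .granges0(promoters$chrom, promoters$start, promoters$end)
  in_scope <- rep(FALSE, nrow(aiv))
  if (nrow(aiv) && nrow(promoters)) {
    a_gr <- .granges0(aiv$chrom, aiv$start, aiv$end)
    in_scope <- IRanges::overlapsAny(a_gr, prom_gr, minoverlap = 1L)
  }
  a_mid <- floor((aiv$start + aiv$end) / 2)[in_scope]
  a_chr <- aiv$chrom[in_scope]

  oiv <- other$intervals
  o_mid <- floor((oiv$start + oiv$end) / 2)
  o_chr <- oiv$chrom

  edges <- seq(-window_bp, window_bp, by = bin_width_bp)
  counts <- integer(length(edges) - 1L)
  for (chr in unique(a_chr)) {
    am <- a_mid[a_chr == chr]
    om <- sort(o_mid[o_chr == chr])
    if (!length(om)) next
    for (a in am) {
      off <- om[om >= a - window_bp & om <= a + window_bp] - a
      if (length(off)) {
        h <- findInterval(off, edges, rightmost.closed = TRUE)
        counts <- counts + tabulate(h, nbins = length(counts))
      }
    }
  }
  structure(list(anchor_factor = anchor$factor, other_factor = other$factor,
                 window_bp = window_bp, bin_width_bp = bin_width_bp,
                 bins = data.frame(bin_left = edges[-length(edges)],
                                   bin_right = edges[-1]),
                 counts = counts, n_anchor_events = length(a_mid)),
            class = "ColocProfile")
}

#' Write a colocalization profile as TSV
#'
#' @param profile A `ColocProfile`.
#' @param path Output path; columns `bin_left`, `bin_right`, `count`.
#' @return `path`, invisibly.
#' @export
write_coloc_profile <- function(profile, path) {
  stopifnot(inherits(profile, "ColocProfile"))
  df <- cbind(profile$bins, count = profile$counts)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
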