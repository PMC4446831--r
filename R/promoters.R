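#' Build strand-aware promoter windows around each TSS
#'
#' For a plus-strand gene the window is `[tss - upstream, tss + downstream)`;
#' for a minus-strand gene it is mirrored about the TSS,
#' `[tss - downstream + 1, tss + upstream + 1)`, so that the window covers
#' the same transcribed-relative positions and has length exactly
#' `upstream + downstream`. Windows are clamped at position 0 and, when
#' chromosome sizes are attached to the annotation, at the chromosome end.
#'
#' @param annotation A `GeneAnnotation`.
#' @param upstream Base pairs upstream of the TSS (default 5000).
#' @param downstream Base pairs downstream of the TSS (default 1000).
#' @return A `PromoterSet`: data.frame with columns `gene_id`, `chrom`,
#'   `start`, `end`, `strand` (0-based half-open), with the window
#'   parameters attached as attributes `upstream` and `downstream`.
#' @export
build_promoter_windows <- function(annotation, upstream = 5000, downstream = 1000) {
  stopifnot(inherits(annotation, "GeneAnnotation"),
            upstream >= 0, downstream >= 0)
  plus <- annotation$strand == "+"
  start <- ifelse(plus, annotation$tss - upstream,
                  annotation$tss - downstream + 1)
  end <- ifelse(plus, annotation$tss + downstream,
                annotation$tss + upstream + 1)
  start <- pmax(start, 0)
  sizes <- attr(annotation, "chrom_sizes")
  if (!is.null(sizes)) {
    known <- annotation$chrom %in% names(sizes)
    end[known] <- pmin(end[known], sizes[annotation$chrom[known]])
  }
  out <- data.frame(gene_id = annotation$gene_id, chrom = annotation$chrom,
                    start = start, end = pmax(end, start),
                    strand = annotation$strand, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "upstream") <- upstream
  attr(out, "downstream") <- downstream
  class(out) <- c("PromoterSet", "data.frame")
  out
}

#' Write a PromoterSet as BED6
#'
#' @param promoters A `PromoterSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_promoters_bed <- function(promoters, path) {
  stopifnot(inherits(promoters, "PromoterSet"))
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", promoters$chrom,
                     as.integer(promoters$start), as.integer(promoters$end),
                     promoters$gene_id, promoters$strand), path)
  invisible(path)
}

# GRanges from 0-based half-open intervals; zero-width windows collapse to
# width-0 ranges that can never satisfy minoverlap >= 1
.granges0 <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start + 1, end = end))
}

#' Map peak calls onto promoter windows
#'
#' Counts, for every gene and factor, the peaks with at least `min_overlap`
#' base pairs of overlap with the gene's promoter window. A peak overlapping
#' k windows is counted once in each. Several `PeakSet`s may carry the same
#' factor name (e.g. different cell contexts); by default their counts add,
#' or with `combine = "or"` the bound flag is the union while `peak_count`
#' keeps the summed counts' cap at per-context presence.
#'
#' @param promoters A `PromoterSet`.
#' @param peaksets A list of `PeakSet` objects (or a single one).
#' @param min_overlap Minimum overlap in bp for a peak to count (default 1).
#' @param combine How to combine multiple peak sets of one factor: `"add"`
#'   (default; counts add) or `"or"` (bound if bound in any context;
#'   `peak_count` is the number of contexts binding the promoter).
#' @return A `BindingMatrix`: list with `bound` (genes x factors logical) and
#'   `peak_count` (genes x factors integer).
#' @export
map_peaks_to_promoters <- function(promoters, peaksets, min_overlap = 1,
                                   combine = c("add", "or")) {
  combine <- match.arg(combine)
  stopifnot(inherits(promoters, "PromoterSet"))
  if (inherits(peaksets, "PeakSet")) peaksets <- list(peaksets)
  if (nrow(promoters) == 0L) stop("empty PromoterSet")
  if (!length(peaksets)) stop("no peak sets supplied")
  factors <- unique(vapply(peaksets, `[[`, "", "factor"))
  prom_gr <- .granges0(promoters$chrom, promoters$start, promoters$end)
  counts <- matrix(0L, nrow = nrow(promoters), ncol = length(factors),
                   dimnames = list(promoters$gene_id, factors))
  for (ps in peaksets) {
    iv <- ps$intervals
    if (nrow(iv) == 0L) next
    pk_gr <- .granges0(iv$chrom, iv$start, iv$end)
    hits <- GenomicRanges::findOverlaps(prom_gr, pk_gr,
                                        minoverlap = min_overlap)
    per_gene <- tabulate(S4Vectors::queryHits(hits), nbins = nrow(promoters))
    if (combine == "or") per_gene <- as.integer(per_gene > 0L)
    counts[, ps$factor] <- counts[, ps$factor] + per_gene
  }
  BindingMatrix(counts)
}

#' Construct a BindingMatrix from a peak-count matrix
#'
#' @param peak_count Genes x factors non-negative integer matrix with
#'   dimnames.
#' @return A `BindingMatrix` object (`bound` is derived as
#'   `peak_count > 0`).
#' @export
BindingMatrix <- function(peak_count) {
  stopifnot(is.matrix(peak_count), !is.null(rownames(peak_count)),
            !is.null(colnames(peak_count)), all(peak_count >= 0))
  storage.mode(peak_count) <- "integer"
  structure(list(bound = peak_count > 0L, peak_count = peak_count),
            class = "BindingMatrix")
}

#' Write a BindingMatrix as a TSV of peak counts
#'
#' @param binding A `BindingMatrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_binding_matrix <- function(binding, path) {
  stopifnot(inherits(binding, "BindingMatrix"))
  df <- data.frame(gene_id = rownames(binding$peak_count),
                   binding$peak_count, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Count query genes bound by at least k of the given factors
#'
#' @param binding A `BindingMatrix`.
#' @param query Character vector of gene identifiers (must all be in the
#'   matrix).
#' @param factors Factors to consider (default: all columns).
#' @param k Minimum number of distinct factors bound (default 2).
#' @return List with `count` (genes bound by >= k factors) and `fraction`
#'   (`count / length(query)`).
#' @export
count_cobound <- function(binding, query, factors = colnames(binding$bound),
                          k = 2L) {
  stopifnot(inherits(binding, "BindingMatrix"),
            k >= 1L, k <= length(factors),
            all(factors %in% colnames(binding$bound)))
  missing_g <- setdiff(query, rownames(binding$bound))
  if (length(missing_g)) {
    stop("query gene(s) absent from binding matrix: ",
         paste(utils::head(missing_g, 10), collapse = ", "))
  }
  nf <- rowSums(binding$bound[query, factors, drop = FALSE])
  count <- sum(nf >= k)
  list(count = count, fraction = count / length(query))
}
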