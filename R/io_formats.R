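#' Read a refFlat-like gene annotation and select the longest transcript
#'
#' Reads a tab-separated annotation with columns `gene_id`, `chrom`, `strand`,
#' `txStart`, `txEnd` (transcript span in 0-based half-open coordinates) and
#' reduces it to one record per gene: the transcript with the largest span.
#' The transcription start site (TSS) is `txStart` on the plus strand and
#' `txEnd - 1` on the minus strand.
#'
#' Ties on transcript length are broken by the lexicographically smallest
#' `(chrom, txStart)` pair, so selection is deterministic under any row
#' permutation of the input. Rows that duplicate a `(gene_id, chrom, strand,
#' txStart, txEnd)` combination exactly are collapsed with a warning.
#'
#' @param path Path to the annotation file. A header line is optional and
#'   detected by the literal column name `gene_id` in the first field.
#' @param chrom_sizes Optional path to a two-column TSV (`chrom`, `size`).
#'   When given, every TSS must lie within its chromosome; violations error.
#' @param one_based Set `TRUE` if `txStart` is 1-based inclusive; coordinates
#'   are then shifted down by one on read. Default `FALSE` (BED convention).
#' @return A `GeneAnnotation`: a data.frame with columns `gene_id`, `chrom`,
#'   `strand`, `tss`, `transcript_length`, one row per gene. When
#'   `chrom_sizes` is supplied the sizes are attached as attribute
#'   `chrom_sizes` (a named numeric vector).
#' @export
read_gene_annotation <- function(path, chrom_sizes = NULL, one_based = FALSE) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) stop("annotation file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  has_header <- identical(fields[[1]][1], "gene_id")
  offset <- if (has_header) 1L else 0L
  if (has_header) fields <- fields[-1L]
  if (length(fields) == 0L) stop("annotation file has a header but no records: ", path)
  nf <- lengths(fields)
  bad <- which(nf < 5L)
  if (length(bad)) {
    stop("annotation line ", bad[1] + offset, ": expected 5 tab-separated fields, got ",
         nf[bad[1]])
  }
  df <- data.frame(
    gene_id = vapply(fields, `[`, "", 1L),
    chrom   = vapply(fields, `[`, "", 2L),
    strand  = vapply(fields, `[`, "", 3L),
    txStart = suppressWarnings(as.numeric(vapply(fields, `[`, "", 4L))),
    txEnd   = suppressWarnings(as.numeric(vapply(fields, `[`, "", 5L))),
    stringsAsFactors = FALSE
  )
  bad_strand <- which(!df$strand %in% c("+", "-"))
  if (length(bad_strand)) {
    stop("annotation line ", bad_strand[1] + offset, ": malformed strand ",
         dQuote(df$strand[bad_strand[1]]), " (must be '+' or '-')")
  }
  bad_num <- which(is.na(df$txStart) | is.na(df$txEnd))
  if (length(bad_num)) {
    stop("annotation line ", bad_num[1] + offset, ": non-numeric txStart/txEnd")
  }
  if (one_based) df$txStart <- df$txStart - 1
  bad_span <- which(df$txStart >= df$txEnd | df$txStart < 0)
  if (length(bad_span)) {
    stop("annotation line ", bad_span[1] + offset, ": invalid transcript span [",
         df$txStart[bad_span[1]], ", ", df$txEnd[bad_span[1]], ")")
  }

  key <- paste(df$gene_id, df$chrom, df$strand, df$txStart, df$txEnd, sep = "\r")
  if (anyDuplicated(key)) {
    warning("collapsed ", sum(duplicated(key)), " duplicated annotation row(s)")
    df <- df[!duplicated(key), , drop = FALSE]
  }

  df$transcript_length <- df$txEnd - df$txStart
  # longest transcript per gene; ties -> smallest (chrom, txStart)
  ord <- order(df$gene_id, -df$transcript_length, df$chrom, df$txStart)
  df <- df[ord, , drop = FALSE]
  df <- df[!duplicated(df$gene_id), , drop = FALSE]
  df$tss <- ifelse(df$strand == "+", df$txStart, df$txEnd - 1)

  out <- df[, c("gene_id", "chrom", "strand", "tss", "transcript_length")]
  rownames(out) <- NULL
  if (!is.null(chrom_sizes)) {
    cs <- utils::read.table(chrom_sizes, sep = "\t", header = FALSE,
                            col.names = c("chrom", "size"),
                            colClasses = c("character", "numeric"))
    sizes <- stats::setNames(cs$size, cs$chrom)
    known <- out$chrom %in% names(sizes)
    over <- known & out$tss >= sizes[out$chrom]
    if (any(over)) {
      stop("TSS beyond declared chromosome length for gene(s): ",
           paste(utils::head(out$gene_id[over], 5), collapse = ", "))
    }
    attr(out, "chrom_sizes") <- sizes
  }
  class(out) <- c("GeneAnnotation", "data.frame")
  out
}

#' Read ChIP-Seq peak calls from a BED3+ file
#'
#' Columns beyond the third are ignored; intervals are kept verbatim in
#' 0-based half-open coordinates and are never merged.
#'
#' @param path Path to a BED3+ file. Lines starting with `#`, `track` or
#'   `browser` are skipped.
#' @param factor Name of the assayed transcription factor.
#' @param cell_context Free-text provenance label (e.g. source cell line).
#' @return A `PeakSet`: a list with elements `factor`, `cell_context` and
#'   `intervals` (data.frame `chrom`, `start`, `end`).
#' @export
read_peaks <- function(path, factor, cell_context = "") {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (length(fields)) {
    nf <- lengths(fields)
    if (any(nf < 3L)) {
      i <- which(nf < 3L)[1]
      stop("BED line ", lineno[i], ": fewer than 3 fields")
    }
  }
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end   <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop("BED line ", lineno[bad[1]], ": non-numeric coordinates")
  bad <- which(start >= end | start < 0)
  if (length(bad)) {
    stop("BED line ", lineno[bad[1]], ": invalid interval [",
         start[bad[1]], ", ", end[bad[1]], ")")
  }
  PeakSet(factor, data.frame(chrom = chrom, start = start, end = end,
                             stringsAsFactors = FALSE),
          cell_context = cell_context)
}

#' Construct a PeakSet from in-memory intervals
#'
#' @param factor Factor name.
#' @param intervals data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param cell_context Free-text provenance label.
#' @return A `PeakSet` object.
#' @export
PeakSet <- function(factor, intervals, cell_context = "") {
  stopifnot(is.character(factor), length(factor) == 1L,
            all(c("chrom", "start", "end") %in% names(intervals)))
  if (nrow(intervals) && any(intervals$start >= intervals$end)) {
    stop("PeakSet intervals must satisfy start < end")
  }
  rownames(intervals) <- NULL
  structure(list(factor = factor, cell_context = cell_context,
                 intervals = intervals[, c("chrom", "start", "end")]),
            class = "PeakSet")
}

#' Write a PeakSet as BED3
#'
#' @param peaks A `PeakSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  stopifnot(inherits(peaks, "PeakSet"))
  iv <- peaks$intervals
  writeLines(sprintf("%s\t%d\t%d", iv$chrom, as.integer(iv$start),
                     as.integer(iv$end)), path)
  invisible(path)
}

#' Read a log-scale expression matrix with sample group labels
#'
#' The matrix file is tab-separated with gene identifiers in the first column
#' and sample identifiers in the header. The labels file maps every sample to
#' a group (two tab-separated columns, optional header `sample_id`/`group`).
#'
#' When `annotation` is supplied, rows are restricted to genes present in the
#' annotation (the "RefSeq genes only" rule). When several rows share one
#' gene identifier the row with the largest interquartile range across
#' samples is retained.
#'
#' @param path Path to the expression matrix TSV.
#' @param labels_path Path to the two-column sample-label TSV.
#' @param annotation Optional `GeneAnnotation` used to restrict rows.
#' @param impute How to treat missing cells: `"reject"` (default, error) or
#'   `"median"` (replace by the gene's median across samples).
#' @return An `ExpressionMatrix`: list with `values` (genes x samples numeric
#'   matrix, log scale) and `sample_labels` (named character vector).
#' @export
read_expression <- function(path, labels_path, annotation = NULL,
                            impute = c("reject", "median")) {
  impute <- match.arg(impute)
  tab <- utils::read.table(path, sep = "\t", header = TRUE, row.names = NULL,
                           check.names = FALSE, stringsAsFactors = FALSE)
  gene_id <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    # locate the first offending cell for the error message
    for (j in seq_len(ncol(mat))) {
      v <- suppressWarnings(as.numeric(tab[[j + 1]]))
      bad <- which(is.na(v) & !is.na(tab[[j + 1]]) & tab[[j + 1]] != "NA")
      if (length(bad)) {
        stop("non-numeric expression value at gene ", gene_id[bad[1]],
             ", sample ", colnames(mat)[j], ": ", dQuote(tab[[j + 1]][bad[1]]))
      }
    }
    mat <- apply(mat, 2, as.numeric)
  }
  if (anyNA(mat)) {
    if (impute == "reject") {
      ij <- which(is.na(mat), arr.ind = TRUE)[1, ]
      stop("missing expression value at gene ", gene_id[ij[1]], ", sample ",
           colnames(mat)[ij[2]], "; re-run with impute = \"median\" to impute")
    }
    for (i in which(rowSums(is.na(mat)) > 0)) {
      mat[i, is.na(mat[i, ])] <- stats::median(mat[i, ], na.rm = TRUE)
    }
    if (anyNA(mat)) stop("gene(s) with all values missing cannot be imputed")
  }

  lab <- utils::read.table(labels_path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (identical(lab[1, 1], "sample_id")) lab <- lab[-1, , drop = FALSE]
  sample_labels <- stats::setNames(as.character(lab[[2]]), as.character(lab[[1]]))
  missing_lab <- setdiff(colnames(mat), names(sample_labels))
  if (length(missing_lab)) {
    stop("sample(s) missing from labels file: ",
         paste(missing_lab, collapse = ", "))
  }
  sample_labels <- sample_labels[colnames(mat)]

  if (!is.null(annotation)) {
    keep <- gene_id %in% annotation$gene_id
    mat <- mat[keep, , drop = FALSE]
    gene_id <- gene_id[keep]
  }
  if (anyDuplicated(gene_id)) {
    iqr <- apply(mat, 1, stats::IQR)
    ord <- order(gene_id, -iqr)
    keep <- ord[!duplicated(gene_id[ord])]
    keep <- sort(keep)
    mat <- mat[keep, , drop = FALSE]
    gene_id <- gene_id[keep]
  }
  rownames(mat) <- gene_id
  ExpressionMatrix(mat, sample_labels)
}

#' Construct an ExpressionMatrix from a numeric matrix
#'
#' @param values Genes x samples numeric matrix (log scale) with rownames
#'   (gene identifiers) and colnames (sample identifiers).
#' @param sample_labels Named character vector mapping sample to group label.
#' @return An `ExpressionMatrix` object.
#' @export
ExpressionMatrix <- function(values, sample_labels) {
  stopifnot(is.matrix(values), is.numeric(values),
            !is.null(rownames(values)), !is.null(colnames(values)))
  if (anyDuplicated(rownames(values))) stop("gene identifiers must be unique")
  if (anyNA(values)) stop("ExpressionMatrix must not contain missing values")
  missing_lab <- setdiff(colnames(values), names(sample_labels))
  if (length(missing_lab)) {
    stop("sample(s) without a group label: ", paste(missing_lab, collapse = ", "))
  }
  structure(list(values = values,
                 sample_labels = sample_labels[colnames(values)]),
            class = "ExpressionMatrix")
}

#' Read gene sets in GMT format
#'
#' Each line holds a set name, a description and one or more gene
#' identifiers, tab-separated. Gene order is preserved; duplicates within a
#' set are removed with a warning.
#'
#' @param path Path to the GMT file.
#' @return A `GeneSetCollection`: list with `sets` (named list of character
#'   vectors) and `description` (named character vector).
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !grepl("^#", lines)
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    i <- which(nf < 3L)[1]
    stop("GMT line ", lineno[i], ": expected at least 3 fields (name, ",
         "description, >=1 gene), got ", nf[i])
  }
  nm <- vapply(fields, `[`, "", 1L)
  desc <- stats::setNames(vapply(fields, `[`, "", 2L), nm)
  sets <- lapply(fields, function(f) f[-(1:2)])
  ndup <- sum(vapply(sets, anyDuplicated, 0L) > 0L)
  if (ndup) warning("removed duplicate genes within ", ndup, " gene set(s)")
  sets <- stats::setNames(lapply(sets, unique), nm)
  GeneSetCollection(sets, desc)
}

#' Construct a GeneSetCollection
#'
#' @param sets Named list of character vectors (gene identifiers).
#' @param description Optional named character vector of set descriptions.
#' @return A `GeneSetCollection` object.
#' @export
GeneSetCollection <- function(sets, description = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (any(lengths(sets) == 0L)) {
    stop("empty gene set(s): ",
         paste(names(sets)[lengths(sets) == 0L], collapse = ", "))
  }
  if (any(vapply(sets, anyDuplicated, 0L) > 0L)) {
    stop("duplicate gene within a set; deduplicate first")
  }
  if (is.null(description)) {
    description <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(list(sets = sets, description = description[names(sets)]),
            class = "GeneSetCollection")
}

#' Write a GeneSetCollection in GMT format
#'
#' @param gsc A `GeneSetCollection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(gsc, path) {
  stopifnot(inherits(gsc, "GeneSetCollection"))
  desc <- gsc$description
  desc[is.na(desc)] <- ""
  writeLines(vapply(names(gsc$sets), function(nm) {
    paste(c(nm, desc[[nm]], gsc$sets[[nm]]), collapse = "\t")
  }, ""), path)
  invisible(path)
}

#' Read mitosis records from a TSV file
#'
#' Expected columns: `tumor_id`, `angle_deg`, `layer`, `group` (header
#' required). `angle_deg` is the division angle relative to the nearest basal
#' membrane in degrees (0-90); `layer` is the distance to the basal membrane
#' in cell layers (0 = touching).
#'
#' @param path Path to the TSV file.
#' @return A `MitosisRecords` data.frame.
#' @export
read_mitoses <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("tumor_id", "angle_deg", "layer", "group")
  if (!all(need %in% names(df))) {
    stop("mitosis file must have columns: ", paste(need, collapse = ", "))
  }
  MitosisRecords(df[, need])
}

#' Construct mitosis records
#'
#' @param df data.frame with columns `tumor_id`, `angle_deg` (degrees, 0-90),
#'   `layer` (non-negative integer cell layers), `group`.
#' @return A `MitosisRecords` data.frame.
#' @export
MitosisRecords <- function(df) {
  bad <- which(df$angle_deg < 0 | df$angle_deg > 90)
  if (length(bad)) {
    stop("division angle outside [0, 90] for record(s): ",
         paste(utils::head(df$tumor_id[bad], 5), collapse = ", "))
  }
  if (any(df$layer < 0)) stop("cell layer must be non-negative")
  rownames(df) <- NULL
  class(df) <- c("MitosisRecords", "data.frame")
  df
}
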