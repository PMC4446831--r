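#' Default anterior HOX gene list (HOXA1-7 and HOXB2-8)
#' @export
hox_anterior_default <- function() {
  c(paste0("HOXA", 1:7), paste0("HOXB", 2:8))
}

#' Default posterior HOX gene list (HOXA9-13)
#' @export
hox_posterior_default <- function() {
  paste0("HOXA", 9:13)
}

#' Per-sample anterior/posterior HOX switch score
#'
#' Each available HOX gene row is standardized to mean 0, SD 1 across
#' samples; a sample's score is the mean anterior z minus the mean posterior
#' z. High scores mark tumors expressing anterior HOXA/HOXB genes, low
#' scores tumors expressing only posterior HOXA genes; ranking samples by
#' score orders the cohort along the anterior/posterior switch.
#'
#' Zero-variance gene rows are dropped with a warning (their z-score is
#' undefined); if either list loses all its genes the function errors.
#'
#' @param expr An `ExpressionMatrix` (log scale).
#' @param anterior,posterior Gene lists; defaults are HOXA1-7 + HOXB2-8 and
#'   HOXA9-13 respectively.
#' @return A `HoxScore` data.frame with columns `sample_id`, `score`,
#'   `group`; the gene lists actually used are attached as attributes
#'   `anterior_genes_used` and `posterior_genes_used`.
#' @export
compute_hox_score <- function(expr, anterior = hox_anterior_default(),
                              posterior = hox_posterior_default()) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  genes <- rownames(expr$values)
  ant <- intersect(anterior, genes)
  pos <- intersect(posterior, genes)
  if (!length(ant) || !length(pos)) {
    stop("no ", if (!length(ant)) "anterior" else "posterior",
         " genes found in the matrix; defaults are anterior = {",
         paste(hox_anterior_default(), collapse = ", "), "}, posterior = {",
         paste(hox_posterior_default(), collapse = ", "), "}")
  }
  sub <- expr$values[c(ant, pos), , drop = FALSE]
  sds <- apply(sub, 1, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance HOX gene row(s): ",
            paste(rownames(sub)[sds == 0], collapse = ", "))
    ant <- setdiff(ant, rownames(sub)[sds == 0])
    pos <- setdiff(pos, rownames(sub)[sds == 0])
    if (!length(ant) || !length(pos)) {
      stop("all anterior or all posterior genes have zero variance")
    }
  }
  z <- t(scale(t(expr$values[c(ant, pos), , drop = FALSE])))
  score <- colMeans(z[ant, , drop = FALSE]) - colMeans(z[pos, , drop = FALSE])
  out <- data.frame(sample_id = colnames(expr$values), score = unname(score),
                    group = unname(expr$sample_labels),
                    stringsAsFactors = FALSE)
  attr(out, "anterior_genes_used") <- ant
  attr(out, "posterior_genes_used") <- pos
  class(out) <- c("HoxScore", "data.frame")
  out
}

#' Per-sample marker expression log-ratio
#'
#' For log-scale expression, the ratio between two marker groups (e.g.
#' FABP4/FABP5 versus CRABP2) is a difference of means on the log scale:
#' `mean(log expr of numerator genes) - mean(log expr of denominator
#' genes)`. The antilog (base 2, the usual array log scale) is reported
#' alongside.
#'
#' @param expr An `ExpressionMatrix` (log scale).
#' @param numerator,denominator Gene lists; all genes must be present.
#' @param log_base Base of the expression log scale (default 2), used only
#'   for the antilog column.
#' @return data.frame with `sample_id`, `log_ratio`, `ratio`, `group`.
#' @export
compute_marker_ratio <- function(expr, numerator, denominator, log_base = 2) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  missing_g <- setdiff(c(numerator, denominator), rownames(expr$values))
  if (length(missing_g)) {
    stop("marker gene(s) absent from the matrix: ",
         paste(missing_g, collapse = ", "))
  }
  num <- colMeans(expr$values[numerator, , drop = FALSE])
  den <- colMeans(expr$values[denominator, , drop = FALSE])
  lr <- num - den
  data.frame(sample_id = colnames(expr$values), log_ratio = unname(lr),
             ratio = unname(log_base^lr), group = unname(expr$sample_labels),
             stringsAsFactors = FALSE)
}

#' Write per-sample HOX scores as TSV
#'
#' @param scores A `HoxScore` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hox_scores <- function(scores, path) {
  utils::write.table(as.data.frame(scores), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
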