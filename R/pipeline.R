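.param_defaults <- function() {
  list(
    `promoter.upstream` = 5000, `promoter.downstream` = 1000,
    `qtc.cutoff` = 0.4, `qtc.min_size` = 15, `qtc.max_genes` = 500,
    `sam.n_permutations` = 1000, `sam.target_fdr` = 0, `sam.groups` = NULL,
    `enrichment.n_resamples` = 100000,
    `coloc.window_bp` = 1000, `coloc.bin_width_bp` = 50,
    `coloc.anchor` = NULL,
    `cobind.min_factors` = 2,
    `angles.n_resamples` = 10000, `angles.basal_max_layer` = 0,
    `angles.null` = "uniform",
    `hox.anterior` = hox_anterior_default(),
    `hox.posterior` = hox_posterior_default(),
    `markers.numerator` = NULL, `markers.denominator` = NULL
  )
}

.known_path_keys <- c("annotation", "peaks", "expression", "labels",
                      "gene_sets", "mitoses", "chrom_sizes")

#' Validate a pipeline configuration and inject defaults
#'
#' The configuration is a list (or a YAML file) with blocks `paths`,
#' `params`, plus top-level `seed` and `output_dir`. Unknown parameter or
#' path keys error (with a nearest-key suggestion) rather than being
#' silently ignored; out-of-range values error naming the violated bound.
#' Missing parameters receive the package defaults: promoter window
#' -5000/+1000 bp, QTC cutoff 0.4 with minimum cluster size 15, SAM target
#' FDR 0, 100000 enrichment resamples, colocalization window +/-1000 bp,
#' 10000 angle-test resamples.
#'
#' @param config A list, or a path to a YAML file.
#' @return The validated config with all defaults filled in (class
#'   `PipelineConfig`).
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  known_top <- c("paths", "params", "seed", "output_dir")
  .check_keys(names(config), known_top, "config")

  paths <- config$paths
  if (is.null(paths)) stop("config must have a 'paths' block")
  .check_keys(names(paths), .known_path_keys, "paths")
  for (k in setdiff(names(paths), "peaks")) {
    if (!file.exists(paths[[k]])) stop("paths.", k, ": file not found: ", paths[[k]])
  }
  if (is.null(paths$peaks) || !length(paths$peaks)) {
    stop("paths.peaks must map at least one factor name to a BED file")
  }
  for (f in names(paths$peaks)) {
    if (!file.exists(paths$peaks[[f]])) {
      stop("paths.peaks.", f, ": file not found: ", paths$peaks[[f]])
    }
  }
  for (k in c("annotation", "expression", "labels")) {
    if (is.null(paths[[k]])) stop("paths.", k, " is required")
  }

  defaults <- .param_defaults()
  params <- if (is.null(config$params)) list() else config$params
  .check_keys(names(params), names(defaults), "params")
  for (k in names(defaults)) {
    if (is.null(params[[k]])) params[[k]] <- defaults[[k]]
  }
  .check_range(params, "promoter.upstream", 0, Inf)
  .check_range(params, "promoter.downstream", 0, Inf)
  .check_range(params, "qtc.cutoff", -1, 1)
  .check_range(params, "qtc.min_size", 2, Inf)
  .check_range(params, "qtc.max_genes", 2, Inf)
  .check_range(params, "sam.n_permutations", 100, Inf)
  .check_range(params, "sam.target_fdr", 0, 1)
  .check_range(params, "enrichment.n_resamples", 100, Inf)
  .check_range(params, "coloc.window_bp", 1, Inf)
  .check_range(params, "angles.n_resamples", 100, Inf)
  .check_range(params, "angles.basal_max_layer", 0, Inf)
  if (params$coloc.window_bp %% params$coloc.bin_width_bp != 0) {
    stop("coloc.window_bp must be divisible by coloc.bin_width_bp")
  }

  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  output_dir <- if (is.null(config$output_dir)) "regsig_output" else config$output_dir
  structure(list(paths = paths, params = params, seed = seed,
                 output_dir = output_dir),
            class = "PipelineConfig")
}

.check_keys <- function(keys, known, block) {
  unknown <- setdiff(keys, known)
  if (length(unknown)) {
    k <- unknown[1]
    dist <- utils::adist(k, known)
    hint <- known[which.min(dist)]
    stop("unknown ", block, " key ", dQuote(k),
         if (min(dist) <= 3) paste0("; did you mean ", dQuote(hint), "?") else "")
  }
}

.check_range <- function(params, key, lo, hi) {
  v <- params[[key]]
  if (!is.numeric(v) || length(v) != 1L || v < lo || v > hi) {
    stop(key, " = ", paste(v, collapse = ","), " outside [", lo, ", ", hi, "]")
  }
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline from a validated configuration
#'
#' Loads the annotation, peak files and expression cohort; builds promoter
#' windows and the binding matrix; derives per-group up/down signatures with
#' SAM and co-expression clusters with QT clustering; runs Fisher +
#' resampling binding enrichment for every (signature, factor) pair and a
#' co-binding summary; computes colocalization profiles around the anchor
#' factor; computes HOX switch scores (and marker ratios when configured);
#' runs the basal division-angle test when mitosis records are provided;
#' and writes everything, plus a fully resolved config and a run-metadata
#' JSON, into the output directory. Deterministic for a fixed config and
#' seed.
#'
#' @param config A `PipelineConfig` (or anything accepted by
#'   [validate_config()]).
#' @return The output directory path, invisibly.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "PipelineConfig")) config <- validate_config(config)
  p <- config$params
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  annotation <- .stage("load annotation", read_gene_annotation(
    config$paths$annotation, chrom_sizes = config$paths$chrom_sizes))
  peaksets <- .stage("load peaks", lapply(names(config$paths$peaks), function(f) {
    read_peaks(config$paths$peaks[[f]], factor = f)
  }))
  factors <- vapply(peaksets, `[[`, "", "factor")
  expr <- .stage("load expression", read_expression(
    config$paths$expression, config$paths$labels, annotation = annotation))

  promoters <- .stage("promoter windows", build_promoter_windows(
    annotation, p$promoter.upstream, p$promoter.downstream))
  binding <- .stage("binding matrix",
                    map_peaks_to_promoters(promoters, peaksets))
  write_binding_matrix(binding, file.path(out, "binding_matrix.tsv"))
  write_promoters_bed(promoters, file.path(out, "promoters.bed"))

  groups <- p$sam.groups
  if (is.null(groups)) groups <- unique(unname(expr$sample_labels))
  groups <- intersect(groups, unique(expr$sample_labels))
  signatures <- list()
  for (i in seq_along(groups)) {
    g <- groups[i]
    res <- .stage(paste0("SAM ", g), sam_significant_genes(
      expr, contrast_labels(expr, g),
      n_permutations = p$sam.n_permutations,
      target_fdr = p$sam.target_fdr,
      seed = derive_seed(config$seed, 10L + i)))
    write_sam_result(res, file.path(out, paste0("sam_", g, ".tsv")))
    if (length(res$significant_up)) {
      signatures[[paste0(g, "-up")]] <- res$significant_up
    }
    if (length(res$significant_down)) {
      signatures[[paste0(g, "-down")]] <- res$significant_down
    }
  }

  # QTC is quadratic in gene count; cluster the most variable genes only
  qtc_expr <- expr
  if (nrow(expr$values) > p$qtc.max_genes) {
    v <- apply(expr$values, 1, stats::var)
    keep <- order(v, decreasing = TRUE)[seq_len(p$qtc.max_genes)]
    qtc_expr <- ExpressionMatrix(expr$values[sort(keep), , drop = FALSE],
                                 expr$sample_labels)
  }
  clusters <- .stage("QT clustering", qt_cluster(
    qtc_expr, similarity_cutoff = p$qtc.cutoff, min_size = p$qtc.min_size))
  write_qt_clusters(clusters, file.path(out, "qtc_clusters.tsv"))

  universe <- rownames(binding$bound)
  enrich_rows <- list()
  for (i in seq_along(signatures)) {
    sig_name <- names(signatures)[i]
    sig <- intersect(signatures[[i]], universe)
    if (!length(sig)) next
    for (j in seq_along(factors)) {
      res <- .stage(paste0("enrichment ", sig_name, " / ", factors[j]),
                    resampling_enrichment(
                      binding, sig, factors[j],
                      n_resamples = p$enrichment.n_resamples,
                      seed = derive_seed(config$seed, 100L + 10L * i + j)))
      write_enrichment_result(res, file.path(
        out, paste0("enrichment_", sig_name, "_", factors[j], ".tsv")))
      enrich_rows[[length(enrich_rows) + 1L]] <-
        data.frame(signature = sig_name, factor = factors[j],
                   query_size = res$query_size,
                   n_bound_query = res$n_bound_query,
                   fisher_p = res$fisher_p,
                   resampling_p_bound = res$resampling_p_bound,
                   resampling_p_peaks = res$resampling_p_peaks)
    }
    cb <- count_cobound(binding, sig, factors,
                        k = min(p$cobind.min_factors, length(factors)))
    utils::write.table(
      data.frame(signature = sig_name, k = p$cobind.min_factors,
                 count = cb$count, fraction = cb$fraction),
      file.path(out, paste0("cobinding_", sig_name, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (length(enrich_rows)) {
    utils::write.table(do.call(rbind, enrich_rows),
                       file.path(out, "enrichment_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  anchor_name <- if (is.null(p$coloc.anchor)) factors[1] else p$coloc.anchor
  anchor <- peaksets[[match(anchor_name, factors)]]
  coloc_query <- if (length(signatures)) {
    intersect(signatures[[1]], promoters$gene_id)
  } else promoters$gene_id
  if (length(coloc_query)) {
    for (ps in peaksets) {
      if (ps$factor == anchor_name) next
      prof <- .stage(paste0("colocalization ", anchor_name, " / ", ps$factor),
                     colocalization_profile(
                       anchor, ps, promoters, query = coloc_query,
                       window_bp = p$coloc.window_bp,
                       bin_width_bp = p$coloc.bin_width_bp))
      write_coloc_profile(prof, file.path(
        out, paste0("coloc_", anchor_name, "_", ps$factor, ".tsv")))
    }
  }

  hox_present <- length(intersect(p$hox.anterior, rownames(expr$values))) &&
    length(intersect(p$hox.posterior, rownames(expr$values)))
  if (hox_present) {
    hs <- .stage("HOX score",
                 compute_hox_score(expr, p$hox.anterior, p$hox.posterior))
    write_hox_scores(hs, file.path(out, "hox_scores.tsv"))
  }
  if (!is.null(p$markers.numerator) && !is.null(p$markers.denominator)) {
    mr <- .stage("marker ratio", compute_marker_ratio(
      expr, p$markers.numerator, p$markers.denominator))
    utils::write.table(mr, file.path(out, "marker_ratios.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  if (!is.null(config$paths$mitoses)) {
    records <- .stage("load mitoses", read_mitoses(config$paths$mitoses))
    .stage("angle tests", angle_tests_by_group(
      records, basal_max_layer = p$angles.basal_max_layer,
      n_resamples = p$angles.n_resamples, null = p$angles.null,
      seed = derive_seed(config$seed, 200L),
      path = file.path(out, "angle_tests.tsv")))
  }

  resolved <- list(paths = config$paths, params = p, seed = config$seed,
                   output_dir = out)
  yaml::write_yaml(resolved, file.path(out, "resolved_config.yaml"))
  meta <- list(package = "regsig",
               version = as.character(utils::packageVersion("regsig")),
               seed = config$seed, n_genes = nrow(expr$values),
               n_samples = ncol(expr$values), factors = factors,
               signatures = lapply(signatures, length),
               n_qt_clusters = length(clusters))
  jsonlite::write_json(meta, file.path(out, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}
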