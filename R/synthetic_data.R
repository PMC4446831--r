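#' Derive an independent sub-stream seed from a master seed
#'
#' Deterministic splitting of one integer seed into per-generator streams,
#' so that adding a generator to a simulation never perturbs the draws of
#' the existing ones. Uses one step of a Lehmer (multiplicative
#' congruential) map over the Mersenne prime modulus 2^31 - 1, offset by a
#' stream index.
#'
#' @param seed Master integer seed.
#' @param stream Small non-negative integer stream index.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stream = 0L) {
  m <- 2147483647
  x <- (abs(as.numeric(seed)) %% m) + 1
  x <- (x * 48271) %% m
  x <- (x + 7919 * (as.numeric(stream) + 1)) %% m
  as.integer(if (x == 0) 1 else x)
}

#' Generate a synthetic gene annotation
#'
#' Lays out TSSs on a jittered grid over `n_chroms` chromosomes, with 50/50
#' random strand assignment and random transcript lengths. With the default
#' spacing no two default promoter windows (-5000/+1000) overlap.
#'
#' @param n_genes Number of genes.
#' @param n_chroms Number of chromosomes (default 3).
#' @param gene_spacing_bp Grid spacing in bp (default 20000).
#' @param jitter_bp Uniform TSS jitter within the grid cell (default 2000).
#' @param seed Integer seed.
#' @return A `GeneAnnotation`.
#' @export
generate_annotation <- function(n_genes, n_chroms = 3L,
                                gene_spacing_bp = 20000L, jitter_bp = 2000L,
                                seed = 1L) {
  stopifnot(n_genes >= 1, n_chroms >= 1, gene_spacing_bp > 2 * jitter_bp)
  set.seed(seed)
  chrom <- paste0("chr", 1 + (seq_len(n_genes) - 1) %% n_chroms)
  slot <- (seq_len(n_genes) - 1) %/% n_chroms
  tss <- 10000 + slot * gene_spacing_bp +
    sample.int(jitter_bp + 1, n_genes, replace = TRUE) - 1
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  tlen <- sample(500:5000, n_genes, replace = TRUE)
  out <- data.frame(
    gene_id = sprintf("GENE%05d", seq_len(n_genes)),
    chrom = chrom, strand = strand, tss = tss, transcript_length = tlen,
    stringsAsFactors = FALSE)
  class(out) <- c("GeneAnnotation", "data.frame")
  out
}

#' Write a GeneAnnotation as a refFlat-like TSV readable by
#' [read_gene_annotation()]
#'
#' @param annotation A `GeneAnnotation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "GeneAnnotation"))
  plus <- annotation$strand == "+"
  txStart <- ifelse(plus, annotation$tss,
                    annotation$tss - annotation$transcript_length + 1)
  txEnd <- txStart + annotation$transcript_length
  lines <- c("gene_id\tchrom\tstrand\ttxStart\ttxEnd",
             sprintf("%s\t%s\t%s\t%d\t%d", annotation$gene_id,
                     annotation$chrom, annotation$strand,
                     as.integer(txStart), as.integer(txEnd)))
  writeLines(lines, path)
  invisible(path)
}

#' Generate a synthetic peak set with planted promoter-binding enrichment
#'
#' Every gene's promoter (default -5000/+1000 window) receives at least one
#' peak with probability `baseline_rate`, or `enriched_rate` for genes in
#' `enriched_set`. The number of peaks in a bound promoter is
#' `1 + Poisson(extra_peaks_lambda)`; peak midpoints are uniform within the
#' window and peaks are `peak_width` bp wide (clipped to stay on the
#' chromosome).
#'
#' @param annotation A `GeneAnnotation`.
#' @param factor Factor name for the peak set.
#' @param baseline_rate Binding probability for background genes.
#' @param enriched_set Gene ids with elevated binding (may be empty).
#' @param enriched_rate Binding probability for `enriched_set` genes.
#' @param extra_peaks_lambda Poisson mean for extra peaks per bound
#'   promoter (default 0.5).
#' @param peak_width Peak width in bp (default 200).
#' @param upstream,downstream Promoter window used for placement
#'   (defaults 5000/1000).
#' @param seed Integer seed.
#' @return List with `peaks` (a `PeakSet`) and `truth` (list: `factor`,
#'   `bound_genes`, `realized_baseline_rate`, `realized_enriched_rate`).
#' @export
generate_peaks <- function(annotation, factor, baseline_rate = 0.2,
                           enriched_set = character(), enriched_rate = baseline_rate,
                           extra_peaks_lambda = 0.5, peak_width = 200L,
                           upstream = 5000L, downstream = 1000L, seed = 1L) {
  stopifnot(inherits(annotation, "GeneAnnotation"),
            baseline_rate >= 0, baseline_rate <= enriched_rate,
            enriched_rate <= 1)
  bad <- setdiff(enriched_set, annotation$gene_id)
  if (length(bad)) {
    stop("enriched_set gene(s) not in annotation: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  set.seed(seed)
  prom <- build_promoter_windows(annotation, upstream, downstream)
  enriched <- prom$gene_id %in% enriched_set
  rate <- ifelse(enriched, enriched_rate, baseline_rate)
  bound <- stats::runif(nrow(prom)) < rate
  n_peaks <- ifelse(bound, 1L + stats::rpois(nrow(prom), extra_peaks_lambda), 0L)
  idx <- rep(seq_len(nrow(prom)), n_peaks)
  mid <- prom$start[idx] +
    floor(stats::runif(length(idx)) * (prom$end[idx] - prom$start[idx]))
  start <- pmax(0, mid - peak_width %/% 2)
  iv <- data.frame(chrom = prom$chrom[idx], start = start,
                   end = start + peak_width, stringsAsFactors = FALSE)
  ord <- order(iv$chrom, iv$start, iv$end)
  truth <- list(factor = factor,
                bound_genes = prom$gene_id[bound],
                realized_baseline_rate = mean(bound[!enriched]),
                realized_enriched_rate =
                  if (any(enriched)) mean(bound[enriched]) else NA_real_)
  list(peaks = PeakSet(factor, iv[ord, , drop = FALSE],
                       cell_context = "synthetic"),
       truth = truth)
}

#' Generate a synthetic multi-subtype expression cohort
#'
#' Background values are `N(0, noise_sd^2)`. Genes in `planted_up`
#' (`planted_down`) are shifted by `+effect_sd * noise_sd`
#' (`-effect_sd * noise_sd`) in the `planted_group` samples. Optionally a
#' tight co-expression cluster is planted (a shared standard-normal latent
#' factor per sample plus `N(0, cluster_noise_sd^2)` residuals, giving
#' expected pairwise correlation `1 / (1 + cluster_noise_sd^2)`), and a HOX
#' block (anterior genes shifted up and posterior genes down in one half of
#' the cohort, reversed in the other half).
#'
#' The default group sizes mirror a four-subtype urothelial carcinoma
#' cohort with its characteristic imbalance (131/21/85/29).
#'
#' @param n_genes Number of background genes (planted cluster/HOX genes are
#'   added on top).
#' @param groups Named integer vector of samples per group.
#' @param planted_up,planted_down Disjoint gene-id lists to shift in
#'   `planted_group` (ids must be of the form GENExxxxx within `n_genes`,
#'   or they are appended as extra rows).
#' @param planted_group Group receiving the shifts (default `"SCCL"`).
#' @param effect_sd Shift size in noise-SD units (default 3).
#' @param noise_sd Background standard deviation (default 1).
#' @param cluster_config Optional list: `n_genes` (cluster size),
#'   `noise_sd` (residual SD, default 0.3). Cluster genes are named
#'   `CLUST...`.
#' @param hox_config Optional list: `anterior`, `posterior` (gene-id
#'   vectors, defaults [hox_anterior_default()] / [hox_posterior_default()]),
#'   `shift` (default 2), `anterior_high_group_fraction` (default 0.5).
#' @param seed Integer seed (split internally per component).
#' @return List with `expr` (an `ExpressionMatrix`) and `truth` (a
#'   `SyntheticTruth`-style list).
#' @export
generate_expression <- function(n_genes, groups = c(UroA = 131L, UroB = 21L,
                                                    GU = 85L, SCCL = 29L),
                                planted_up = character(),
                                planted_down = character(),
                                planted_group = "SCCL", effect_sd = 3,
                                noise_sd = 1, cluster_config = NULL,
                                hox_config = NULL, seed = 1L) {
  stopifnot(n_genes >= 1, effect_sd >= 0, noise_sd > 0)
  if (length(intersect(planted_up, planted_down))) {
    stop("planted_up and planted_down must be disjoint")
  }
  if (length(c(planted_up, planted_down)) && !planted_group %in% names(groups)) {
    stop("planted_group ", dQuote(planted_group), " not among the groups")
  }
  n_samples <- sum(groups)
  sample_id <- sprintf("S%04d", seq_len(n_samples))
  sample_labels <- stats::setNames(rep(names(groups), groups), sample_id)

  gene_id <- sprintf("GENE%05d", seq_len(n_genes))
  extra <- setdiff(c(planted_up, planted_down), gene_id)
  gene_id <- c(gene_id, extra)

  set.seed(derive_seed(seed, 0L))
  values <- matrix(stats::rnorm(length(gene_id) * n_samples, 0, noise_sd),
                   nrow = length(gene_id),
                   dimnames = list(gene_id, sample_id))
  in_group <- sample_labels == planted_group
  if (length(planted_up)) {
    values[planted_up, in_group] <- values[planted_up, in_group] +
      effect_sd * noise_sd
  }
  if (length(planted_down)) {
    values[planted_down, in_group] <- values[planted_down, in_group] -
      effect_sd * noise_sd
  }

  cluster_genes <- character()
  if (!is.null(cluster_config)) {
    k <- cluster_config[["n_genes"]]
    cn <- if (is.null(cluster_config[["noise_sd"]])) 0.3 else
      cluster_config[["noise_sd"]]
    cluster_genes <- sprintf("CLUST%04d", seq_len(k))
    set.seed(derive_seed(seed, 1L))
    latent <- stats::rnorm(n_samples)
    block <- matrix(rep(latent, each = k), nrow = k) +
      matrix(stats::rnorm(k * n_samples, 0, cn), nrow = k)
    rownames(block) <- cluster_genes
    colnames(block) <- sample_id
    values <- rbind(values, block)
  }

  hox_assignment <- NULL
  if (!is.null(hox_config)) {
    # [[ for exact name matching: $ would partial-match e.g. "anterior" to
    # "anterior_high_group_fraction"
    ant <- if (is.null(hox_config[["anterior"]])) hox_anterior_default() else
      hox_config[["anterior"]]
    pos <- if (is.null(hox_config[["posterior"]])) hox_posterior_default() else
      hox_config[["posterior"]]
    shift <- if (is.null(hox_config[["shift"]])) 2 else hox_config[["shift"]]
    frac <- if (is.null(hox_config[["anterior_high_group_fraction"]])) 0.5 else
      hox_config[["anterior_high_group_fraction"]]
    set.seed(derive_seed(seed, 2L))
    hox_genes <- c(ant, pos)
    block <- matrix(stats::rnorm(length(hox_genes) * n_samples, 0, noise_sd),
                    nrow = length(hox_genes),
                    dimnames = list(hox_genes, sample_id))
    n_high <- round(frac * n_samples)
    high <- seq_len(n_samples) <= n_high
    block[ant, high] <- block[ant, high] + shift * noise_sd
    block[pos, !high] <- block[pos, !high] + shift * noise_sd
    values <- rbind(values[setdiff(rownames(values), hox_genes), , drop = FALSE],
                    block)
    hox_assignment <- stats::setNames(
      ifelse(high, "anterior-high", "posterior-high"), sample_id)
  }

  truth <- list(planted_signature_up = planted_up,
                planted_signature_down = planted_down,
                planted_group = planted_group, effect_sd = effect_sd,
                noise_sd = noise_sd, planted_cluster = cluster_genes,
                hox_group_assignment = hox_assignment, seed = seed)
  list(expr = ExpressionMatrix(values, sample_labels), truth = truth)
}

#' Write an ExpressionMatrix as matrix TSV + labels TSV
#'
#' @param expr An `ExpressionMatrix`.
#' @param path Matrix output path.
#' @param labels_path Labels output path.
#' @param digits Significant digits for the values (default 6).
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, labels_path, digits = 6) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  df <- data.frame(gene_id = rownames(expr$values),
                   signif(expr$values, digits), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(expr$sample_labels),
               group = unname(expr$sample_labels)),
    labels_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Generate synthetic mitosis records with a planted basal angle bias
#'
#' Basal records (layer 0) draw angles from a normal truncated to
#' \[0, 90\] degrees; non-basal records (layers 1-5, geometric-ish decay)
#' draw uniform angles.
#'
#' @param n Number of records.
#' @param basal_fraction Fraction of records at layer 0 (default 0.5).
#' @param basal_angle_mean,basal_angle_sd Truncated-normal parameters for
#'   basal angles (defaults 80 and 10 degrees).
#' @param group Group label for all records (default "UroA").
#' @param seed Integer seed.
#' @return List with `records` (a `MitosisRecords` data.frame) and `truth`.
#' @export
generate_mitoses <- function(n, basal_fraction = 0.5, basal_angle_mean = 80,
                             basal_angle_sd = 10, group = "UroA", seed = 1L) {
  stopifnot(n >= 1, basal_fraction >= 0, basal_fraction <= 1)
  set.seed(seed)
  n_basal <- round(n * basal_fraction)
  layer <- c(rep(0L, n_basal),
             1L + stats::rgeom(n - n_basal, prob = 0.5) %% 5L)
  # inverse-CDF truncated normal on [0, 90]
  lo <- stats::pnorm(0, basal_angle_mean, basal_angle_sd)
  hi <- stats::pnorm(90, basal_angle_mean, basal_angle_sd)
  basal_ang <- stats::qnorm(lo + stats::runif(n_basal) * (hi - lo),
                            basal_angle_mean, basal_angle_sd)
  other_ang <- stats::runif(n - n_basal, 0, 90)
  df <- data.frame(tumor_id = sprintf("T%04d", seq_len(n)),
                   angle_deg = pmin(90, pmax(0, c(basal_ang, other_ang))),
                   layer = layer, group = group, stringsAsFactors = FALSE)
  truth <- list(basal_angle_mean = basal_angle_mean,
                basal_angle_sd = basal_angle_sd,
                basal_fraction = basal_fraction, seed = seed)
  list(records = MitosisRecords(df), truth = truth)
}

#' Write mitosis records as TSV
#'
#' @param records A `MitosisRecords` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mitoses <- function(records, path) {
  utils::write.table(as.data.frame(records), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Serialize a synthetic-truth ledger to JSON (lossless round-trip)
#'
#' @param truth A list of ground-truth entries from the generators.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a synthetic-truth ledger back from JSON
#'
#' @param path JSON path written by [write_truth()].
#' @return The truth list.
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
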