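#' Generate a complete synthetic study on disk
#'
#' Convenience wrapper composing the synthetic generators into a full input
#' set for [run_pipeline()]: a gene annotation, one peak file per factor
#' (the first factor enriched in the planted down-signature, the others at
#' baseline), an expression cohort with a planted down-signature in one
#' subtype, a planted tight co-expression cluster, a planted anterior/
#' posterior HOX gradient, and mitosis records with a planted near-90-degree
#' basal angle bias. All files are plain text; `truth.json` records the
#' planted ground truth.
#'
#' @param dir Output directory (created if needed).
#' @param seed Master integer seed (split per generator).
#' @param n_genes Number of background genes (default 2000).
#' @param groups Named integer vector of cohort group sizes (default
#'   `c(UroA = 131, UroB = 21, GU = 85, SCCL = 29)`).
#' @param n_signature Planted down-signature size (default 100).
#' @param planted_group Subtype carrying the planted signature (default
#'   `"SCCL"`).
#' @param factors Factor names; the first is enriched (default
#'   `c("TF_ENR", "TF_CTRL")`).
#' @param baseline_rate,enriched_rate Promoter binding rates (defaults 0.2
#'   and 0.6).
#' @param effect_sd Signature shift in noise-SD units (default 3).
#' @param cluster_size Planted cluster size (default 20).
#' @param n_mitoses Number of mitosis records (default 200).
#' @return List with `config` (a list ready for [validate_config()]) and
#'   `truth`.
#' @export
simulate_study <- function(dir, seed = 1L, n_genes = 2000L,
                           groups = c(UroA = 131L, UroB = 21L, GU = 85L,
                                      SCCL = 29L),
                           n_signature = 100L, planted_group = "SCCL",
                           factors = c("TF_ENR", "TF_CTRL"),
                           baseline_rate = 0.2, enriched_rate = 0.6,
                           effect_sd = 3, cluster_size = 20L,
                           n_mitoses = 200L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # the annotation must also carry the planted-cluster and HOX gene ids so
  # the RefSeq-only expression filter keeps them
  extra_ids <- c(sprintf("CLUST%04d", seq_len(cluster_size)),
                 hox_anterior_default(), hox_posterior_default())
  annotation <- generate_annotation(n_genes + length(extra_ids),
                                    seed = derive_seed(seed, 31L))
  annotation$gene_id[n_genes + seq_along(extra_ids)] <- extra_ids
  planted_down <- annotation$gene_id[seq_len(n_signature)]

  ann_path <- file.path(dir, "annotation.tsv")
  write_annotation(annotation, ann_path)

  peak_paths <- list()
  truth_peaks <- list()
  for (i in seq_along(factors)) {
    g <- generate_peaks(annotation, factors[i],
                        baseline_rate = baseline_rate,
                        enriched_set = if (i == 1L) planted_down else character(),
                        enriched_rate = if (i == 1L) enriched_rate else baseline_rate,
                        seed = derive_seed(seed, 40L + i))
    pth <- file.path(dir, paste0("peaks_", factors[i], ".bed"))
    write_peaks(g$peaks, pth)
    peak_paths[[factors[i]]] <- pth
    truth_peaks[[factors[i]]] <- g$truth
  }

  ge <- generate_expression(
    n_genes, groups = groups, planted_down = planted_down,
    planted_group = planted_group, effect_sd = effect_sd,
    cluster_config = list(n_genes = cluster_size),
    hox_config = list(), seed = derive_seed(seed, 50L))
  expr_path <- file.path(dir, "expression.tsv")
  labels_path <- file.path(dir, "labels.tsv")
  write_expression(ge$expr, expr_path, labels_path)

  mg <- generate_mitoses(n_mitoses, basal_angle_mean = 85, basal_angle_sd = 8,
                         seed = derive_seed(seed, 60L))
  mit_path <- file.path(dir, "mitoses.tsv")
  write_mitoses(mg$records, mit_path)

  gmt_path <- file.path(dir, "gene_sets.gmt")
  write_gene_sets(GeneSetCollection(
    list(PLANTED_DOWN = planted_down),
    c(PLANTED_DOWN = "planted down-signature")), gmt_path)

  truth <- list(peaks = truth_peaks, expression = ge$truth,
                mitoses = mg$truth, seed = seed)
  write_truth(truth, file.path(dir, "truth.json"))

  config <- list(
    paths = list(annotation = ann_path, peaks = peak_paths,
                 expression = expr_path, labels = labels_path,
                 gene_sets = gmt_path, mitoses = mit_path),
    params = list(`sam.groups` = planted_group),
    seed = seed,
    output_dir = file.path(dir, "output"))
  list(config = config, truth = truth)
}
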