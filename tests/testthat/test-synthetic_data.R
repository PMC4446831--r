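test_that("generators are pure functions of their seed", {
  a1 <- generate_annotation(100, seed = 1)
  a2 <- generate_annotation(100, seed = 1)
  expect_identical(a1, a2)
  expect_false(identical(a1, generate_annotation(100, seed = 2)))
  expect_equal(nrow(a1), 100)
  expect_equal(anyDuplicated(a1$gene_id), 0)

  g1 <- generate_peaks(a1, "TF", baseline_rate = 0.3, seed = 5)
  g2 <- generate_peaks(a1, "TF", baseline_rate = 0.3, seed = 5)
  expect_identical(g1, g2)

  e1 <- generate_expression(50, groups = c(A = 10L, B = 10L), seed = 3)
  e2 <- generate_expression(50, groups = c(A = 10L, B = 10L), seed = 3)
  expect_identical(e1$expr$values, e2$expr$values)

  m1 <- generate_mitoses(50, seed = 9)
  m2 <- generate_mitoses(50, seed = 9)
  expect_identical(m1$records, m2$records)
})

test_that("same-seed peak generation writes byte-identical BED files", {
  ann <- generate_annotation(200, seed = 4)
  p1 <- withr::local_tempfile(fileext = ".bed")
  p2 <- withr::local_tempfile(fileext = ".bed")
  write_peaks(generate_peaks(ann, "TF", 0.25, seed = 8)$peaks, p1)
  write_peaks(generate_peaks(ann, "TF", 0.25, seed = 8)$peaks, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("default-spacing annotations give non-overlapping promoter windows", {
  ann <- generate_annotation(150, n_chroms = 2, seed = 6)
  prom <- build_promoter_windows(ann)
  # pairwise check within each chromosome
  for (chr in unique(prom$chrom)) {
    p <- prom[prom$chrom == chr, ]
    p <- p[order(p$start), ]
    expect_true(all(p$start[-1] >= p$end[-nrow(p)]))
  }
})

test_that("planted binding rates behave at the extremes and concentrate at baseline", {
  ann <- generate_annotation(2000, seed = 2)
  enriched <- ann$gene_id[1:100]
  ext <- generate_peaks(ann, "TF", baseline_rate = 0,
                        enriched_set = enriched, enriched_rate = 1, seed = 3)
  expect_setequal(ext$truth$bound_genes, enriched)
  prom <- build_promoter_windows(ann)
  bm <- map_peaks_to_promoters(prom, list(ext$peaks))
  expect_setequal(rownames(bm$bound)[bm$bound[, "TF"]], enriched)

  base <- generate_peaks(ann, "TF", baseline_rate = 0.2, seed = 4)
  expect_lt(abs(base$truth$realized_baseline_rate - 0.2), 0.03)
  expect_error(generate_peaks(ann, "TF", enriched_set = "NOPE", seed = 1),
               "NOPE")
})

test_that("planted expression effects land where declared", {
  ge <- generate_expression(200, groups = c(A = 20L, B = 20L),
                            planted_up = sprintf("GENE%05d", 1:10),
                            planted_down = sprintf("GENE%05d", 11:20),
                            planted_group = "B", effect_sd = 3, seed = 7)
  v <- ge$expr$values
  inB <- ge$expr$sample_labels == "B"
  up_shift <- mean(v[1:10, inB]) - mean(v[1:10, !inB])
  dn_shift <- mean(v[11:20, inB]) - mean(v[11:20, !inB])
  expect_lt(abs(up_shift - 3), 0.5)
  expect_lt(abs(dn_shift + 3), 0.5)
  expect_error(generate_expression(50, planted_up = "GENE00001",
                                   planted_down = "GENE00001"),
               "disjoint")
})

test_that("the planted cluster reaches its designed pairwise correlation", {
  ge <- generate_expression(100, groups = c(A = 60L, B = 60L),
                            cluster_config = list(n_genes = 20,
                                                  noise_sd = 0.3),
                            seed = 12)
  cl <- ge$truth$planted_cluster
  cc <- stats::cor(t(ge$expr$values[cl, ]))
  # shared-factor model: expected r = 1 / (1 + 0.3^2) ~ 0.917
  expect_lt(abs(mean(cc[lower.tri(cc)]) - 1 / 1.09), 0.05)
})

test_that("basal angle bias propagates through the angle test", {
  gen <- generate_mitoses(120, basal_fraction = 0.5, basal_angle_mean = 90,
                          basal_angle_sd = 1e-6, seed = 5)
  basal <- stratify_mitoses(gen$records)$basal[[1]]
  res <- median_angle_test(basal, n_resamples = 2000, seed = 1)
  expect_lte(res$p_high, 2 / 2001)

  none <- generate_mitoses(40, basal_fraction = 0, seed = 6)
  s <- stratify_mitoses(none$records)
  expect_length(s$basal[[1]], 0)
  expect_error(median_angle_test(s$basal[[1]]), "empty")
})

test_that("the truth ledger round-trips through JSON losslessly", {
  sim_dir <- withr::local_tempdir()
  sim <- simulate_study(sim_dir, seed = 3, n_genes = 120,
                        groups = c(A = 10L, SCCL = 8L), n_signature = 15,
                        cluster_size = 5, n_mitoses = 30)
  back <- read_truth(file.path(sim_dir, "truth.json"))
  expect_equal(back$expression$planted_signature_down,
               sim$truth$expression$planted_signature_down)
  expect_equal(back$peaks$TF_ENR$realized_enriched_rate,
               sim$truth$peaks$TF_ENR$realized_enriched_rate)
  expect_equal(back$seed, 3)
})

test_that("derived seeds stay in the 32-bit range and separate streams", {
  s <- vapply(0:50, function(k) derive_seed(123456, k), 1L)
  expect_true(all(s >= 1 & s < 2^31))
  expect_equal(anyDuplicated(s), 0)
  expect_identical(derive_seed(9, 3), derive_seed(9, 3))
})
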