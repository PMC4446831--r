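make_ann <- function(gene_id, chrom, strand, tss, len = 1000,
                     chrom_sizes = NULL) {
  out <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                    tss = tss, transcript_length = len,
                    stringsAsFactors = FALSE)
  if (!is.null(chrom_sizes)) attr(out, "chrom_sizes") <- chrom_sizes
  class(out) <- c("GeneAnnotation", "data.frame")
  out
}

test_that("promoter windows are strand-mirrored, default -5000/+1000, clamped at 0", {
  ann <- make_ann(c("Gp", "Gm", "Gc"), "chr1", c("+", "-", "+"),
                  c(10000, 10000, 3000))
  prom <- build_promoter_windows(ann)
  expect_equal(attr(prom, "upstream"), 5000)
  expect_equal(attr(prom, "downstream"), 1000)
  expect_equal(c(prom$start[1], prom$end[1]), c(5000, 11000))
  expect_equal(c(prom$start[2], prom$end[2]), c(9001, 15001))
  expect_equal(c(prom$start[3], prom$end[3]), c(0, 4000))
  # unclamped windows have length upstream + downstream on both strands
  expect_equal(prom$end[1:2] - prom$start[1:2], c(6000, 6000))
})

test_that("windows are clamped at the chromosome end when sizes are known", {
  ann <- make_ann("G1", "chr1", "-", 9800, chrom_sizes = c(chr1 = 10000))
  prom <- build_promoter_windows(ann)
  expect_equal(prom$end, 10000)
})

test_that("peak-to-promoter mapping obeys half-open boundaries", {
  ann <- make_ann("G1", "chr1", "+", 10000)
  prom <- build_promoter_windows(ann)   # [5000, 11000)
  inside <- PeakSet("TF", data.frame(chrom = "chr1", start = 5500, end = 5600))
  abut <- PeakSet("TF", data.frame(chrom = "chr1", start = 11000, end = 11100))
  bm <- map_peaks_to_promoters(prom, list(inside))
  expect_true(bm$bound["G1", "TF"])
  expect_equal(bm$peak_count["G1", "TF"], 1L)
  bm2 <- map_peaks_to_promoters(prom, list(abut))
  expect_false(bm2$bound["G1", "TF"])
})

test_that("mapping equals a brute-force all-pairs scan on random instances", {
  for (seed in 1:3) {
    set.seed(seed)
    n_g <- 200; n_p <- 500
    ann <- make_ann(sprintf("G%03d", 1:n_g),
                    sample(paste0("chr", 1:3), n_g, replace = TRUE),
                    sample(c("+", "-"), n_g, replace = TRUE),
                    sample.int(3e6, n_g))
    prom <- build_promoter_windows(ann)
    start <- sample.int(3e6, n_p)
    peaks <- PeakSet("TF", data.frame(
      chrom = sample(paste0("chr", 1:3), n_p, replace = TRUE),
      start = start, end = start + sample.int(2000, n_p)))
    bm <- map_peaks_to_promoters(prom, list(peaks))
    expect_equal(unname(bm$peak_count[, "TF"]),
                 brute_overlap_counts(prom, peaks$intervals))
  }
})

test_that("binding counts are invariant to peak row order and add across split files", {
  set.seed(11)
  ann <- make_ann(sprintf("G%02d", 1:30), "chr1", "+",
                  seq(10000, by = 20000, length.out = 30))
  prom <- build_promoter_windows(ann)
  start <- sample.int(6e5, 300)
  iv <- data.frame(chrom = "chr1", start = start, end = start + 300)
  whole <- map_peaks_to_promoters(prom, list(PeakSet("TF", iv)))
  shuffled <- map_peaks_to_promoters(
    prom, list(PeakSet("TF", iv[sample(nrow(iv)), ])))
  expect_equal(shuffled$peak_count, whole$peak_count)
  split2 <- map_peaks_to_promoters(prom, list(
    PeakSet("TF", iv[1:100, ], "ctx1"), PeakSet("TF", iv[101:300, ], "ctx2")))
  expect_equal(split2$peak_count, whole$peak_count)
})

test_that("zero-width windows bind nothing", {
  ann <- make_ann("G1", "chr1", "+", 10000)
  prom <- build_promoter_windows(ann, upstream = 0, downstream = 0)
  peaks <- PeakSet("TF", data.frame(chrom = "chr1", start = 9000, end = 11000))
  bm <- map_peaks_to_promoters(prom, list(peaks))
  expect_false(bm$bound["G1", "TF"])
})

test_that("count_cobound matches direct enumeration", {
  pc <- cbind(A = c(1L, 2L, 0L), B = c(0L, 1L, 0L))
  rownames(pc) <- c("g1", "g2", "g3")
  bm <- BindingMatrix(pc)
  r2 <- count_cobound(bm, c("g1", "g2", "g3"), k = 2)
  expect_equal(r2$count, 1)
  expect_equal(r2$fraction, 1 / 3)
  r1 <- count_cobound(bm, c("g1", "g2", "g3"), k = 1)
  expect_equal(r1$count, 2)
  expect_error(count_cobound(bm, c("g1", "gX")), "gX")

  # random instance vs per-gene enumeration
  set.seed(3)
  pc <- matrix(rbinom(50 * 4, 1, 0.4), 50, 4,
               dimnames = list(sprintf("g%02d", 1:50), LETTERS[1:4]))
  bm <- BindingMatrix(pc)
  query <- sample(rownames(pc), 30)
  for (k in 1:4) {
    manual <- sum(vapply(query, function(g) sum(pc[g, ] > 0) >= k, TRUE))
    expect_equal(count_cobound(bm, query, k = k)$count, manual)
  }
})
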