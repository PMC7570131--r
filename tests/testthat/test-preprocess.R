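txSE <- function(est, gene, unspliced) {
  SummarizedExperiment::SummarizedExperiment(
    assays = list(est_counts = est),
    rowData = S4Vectors::DataFrame(tx_id = rownames(est), gene_id = gene,
                                   unspliced = unspliced,
                                   length = rep(1000L, nrow(est)),
                                   eff_length = rep(750L, nrow(est)),
                                   row.names = rownames(est)))
}

test_that("gene aggregation sums mature transcripts and omits unspliced ones", {
  est <- matrix(c(10, 5, 3, 7, 2), ncol = 1,
                dimnames = list(paste0("t", 1:5), "s1"))
  se <- txSE(est, gene = c("gA", "gA", "gA", "gB", "gB"),
             unspliced = c(FALSE, FALSE, TRUE, FALSE, TRUE))
  agg <- aggregateToGenes(se)
  expect_equal(SummarizedExperiment::assay(agg)["gA", "s1"], 15)
  expect_equal(SummarizedExperiment::assay(agg)["gB", "s1"], 7)
  ## mass conservation over mature transcripts
  expect_equal(sum(SummarizedExperiment::assay(agg)), 10 + 5 + 7)
  ## lexicographic gene order
  expect_identical(rownames(agg), c("gA", "gB"))

  ## gene with only unspliced transcripts is retained as a zero row
  se0 <- txSE(matrix(c(4, 9), ncol = 1,
                     dimnames = list(c("u1", "m1"), "s1")),
              gene = c("gU", "gM"), unspliced = c(TRUE, FALSE))
  agg0 <- aggregateToGenes(se0)
  expect_equal(SummarizedExperiment::assay(agg0)["gU", "s1"], 0)

  ## missing mapping is an error naming the transcript
  seNA <- txSE(est, gene = c("gA", NA, "gA", "gB", "gB"),
               unspliced = rep(FALSE, 5))
  expect_error(aggregateToGenes(seNA), "t2")
})

test_that("the detection filter applies the at-least-half rule at the boundary", {
  ## 24 samples, lib size 1e6 each: CPM == count
  libScale <- 1e6
  counts <- rbind(
    removed12 = c(rep(0.5, 12), rep(10, 12)),  # below 0.66 in exactly 12
    kept13 = c(rep(0.5, 11), rep(10, 13)),     # detected in 13
    allzero = rep(0, 24),
    high = rep(50, 24))
  filler <- matrix(rep(libScale / 10 - colSums(counts) / 10, each = 10),
                   nrow = 10, byrow = FALSE)
  rownames(filler) <- paste0("fill", 1:10)
  se <- geneSE(rbind(counts, filler))
  out <- filterUndetected(se, cpmThreshold = 0.66, minUndetected = 12)
  expect_false("removed12" %in% rownames(out))
  expect_false("allzero" %in% rownames(out))
  expect_true(all(c("kept13", "high") %in% rownames(out)))
  ## library sizes recomputed on retained genes
  expect_equal(unname(SummarizedExperiment::colData(out)$lib_size),
               unname(colSums(SummarizedExperiment::assay(out))))
  ## idempotent
  out2 <- filterUndetected(out, cpmThreshold = 0.66, minUndetected = 12)
  expect_identical(rownames(out2), rownames(out))
})

test_that("TMM factors match the published definition computed by brute force", {
  set.seed(42)
  for (rep in 1:3) {
    counts <- matrix(rnbinom(800 * 4, mu = 60 * rep, size = 5), 800, 4)
    counts[1:40, 2] <- counts[1:40, 2] * 6   # asymmetric distortion
    se <- geneSE(counts, meta = data.frame(sample = sprintf("s%02d", 1:4)))
    out <- tmmNormalize(se)
    f <- SummarizedExperiment::colData(out)$norm_factor
    expect_equal(f, oracleTMM(counts), tolerance = 1e-12)
    expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
  }
})

test_that("TMM is unity for identical or proportionally scaled samples and invariant to global rescale", {
  base <- rnbinom(500, mu = 100, size = 10) + 1
  same <- geneSE(matrix(base, 500, 3),
                 meta = data.frame(sample = c("s01", "s02", "s03")))
  expect_equal(SummarizedExperiment::colData(tmmNormalize(same))$norm_factor,
               rep(1, 3))
  ## doubling every gene is absorbed by the library size
  prop <- geneSE(matrix(c(base, 2 * base, base, 2 * base), 500, 4),
                 meta = data.frame(sample = sprintf("s%02d", 1:4)))
  expect_equal(SummarizedExperiment::colData(tmmNormalize(prop))$norm_factor,
               rep(1, 4))
  ## global rescale invariance
  set.seed(7)
  counts <- matrix(rnbinom(600 * 4, mu = 80, size = 5), 600, 4)
  f1 <- SummarizedExperiment::colData(tmmNormalize(geneSE(counts)))
  f2 <- SummarizedExperiment::colData(tmmNormalize(geneSE(counts * 3)))
  expect_equal(f1$norm_factor, f2$norm_factor, tolerance = 1e-12)
  ## all-zero sample is an error
  bad <- counts; bad[, 2] <- 0
  expect_error(tmmNormalize(geneSE(bad)), "all-zero")
})

test_that("CPM conserves column totals and respects effective library sizes", {
  counts <- matrix(c(1, 1, 3, 5), 2, 2,
                   dimnames = list(c("gA", "gB"), c("s1", "s2")))
  se <- geneSE(counts, meta = data.frame(sample = c("s1", "s2")))
  cpm <- cpmMatrix(se)
  expect_equal(unname(cpm[, "s1"]), c(5e5, 5e5))
  expect_equal(unname(colSums(cpm)), c(1e6, 1e6))
  ## monotone within sample
  expect_gt(cpm["gB", "s2"], cpm["gA", "s2"])
  ## log variant is finite and ordered
  lcpm <- cpmMatrix(se, log = TRUE)
  expect_true(all(is.finite(lcpm)))
  expect_gt(lcpm["gB", "s2"], lcpm["gA", "s2"])
})
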