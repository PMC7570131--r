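test_that("a fixed seed gives bit-identical simulations", {
  cfg <- simConfig(nGenes = 300, nSets = 8, setSizeRange = c(5, 15),
                   seed = 1)
  s1 <- simulateExperiment(cfg)
  s2 <- simulateExperiment(cfg)
  expect_identical(SummarizedExperiment::assay(s1$se),
                   SummarizedExperiment::assay(s2$se))
  expect_identical(geneSets(s1$sets), geneSets(s2$sets))
  expect_identical(s1$truth$W, s2$truth$W)
})

test_that("gene-set generation honours count, disjointness and forced overlap", {
  cfg <- simConfig(nGenes = 4000, nSets = 50, setSizeRange = c(10, 50),
                   seed = 2, perturbedSets = data.frame(
                     set = character(0), contrast = character(0),
                     logFC = numeric(0), fraction = numeric(0)))
  gsc <- simulateGeneSets(cfg)
  expect_length(gsc, 50L)
  members <- unlist(geneSets(gsc), use.names = FALSE)
  expect_identical(anyDuplicated(members), 0L)  # overlap 0 => disjoint

  cfgOv <- simConfig(nGenes = 1000, nSets = 3, setSizeRange = c(100, 100),
                     setOverlap = 0.5, seed = 3, perturbedSets = data.frame(
                       set = character(0), contrast = character(0),
                       logFC = numeric(0), fraction = numeric(0)))
  gov <- simulateGeneSets(cfgOv)
  expect_identical(length(intersect(gov[[1]], gov[[2]])), 50L)
  expect_identical(length(intersect(gov[[2]], gov[[3]])), 50L)
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(groupSizes = c(a = 4L)), "group")
  expect_error(simConfig(nGenes = 100, setSizeRange = c(50, 200)),
               "set size")
  expect_error(simConfig(perturbedSets = data.frame(
    set = "set001", contrast = "wildtype", logFC = 0.3, fraction = 0.8)),
    "non-baseline")
  expect_error(simConfig(dispersionTrend = c(0, 0)), "positive")
  cfg <- simConfig(nGenes = 200, nSets = 60, setSizeRange = c(5, 10),
                   seed = 1)
  expect_error(simulateGeneSets(cfg), "pool exhausted")
})

test_that("the truth object is sufficient bookkeeping for the generated data", {
  sim <- smallSim(seed = 4, nGenes = 400, nSets = 8)
  ## mature transcript sums reproduce the recorded gene counts
  agg <- aggregateToGenes(sim$se)
  expect_equal(SummarizedExperiment::assay(agg, "counts"),
               sim$truth$geneCounts[rownames(agg), ], tolerance = 0)
  ## unspliced rows exist and are flagged
  rd <- SummarizedExperiment::rowData(sim$se)
  expect_true(any(rd$unspliced))
  expect_true(all(grepl("\\.unspliced$", rd$tx_id[rd$unspliced])))
  ## every planted gene and set exists
  expect_true(all(sim$truth$deGenes$gene %in% rd$gene_id))
  expect_true(all(sim$truth$perturbedSets$set %in% names(sim$sets)))
  shifted <- unlist(sim$truth$perturbedSets$genesShifted)
  expect_true(all(shifted %in% unlist(geneSets(sim$sets))))
})

test_that("with all effects at zero the generative law depends on samples only through library size", {
  cfg <- simConfig(nGenes = 2000, nSets = 5, setSizeRange = c(10, 20),
                   seed = 5,
                   perturbedSets = data.frame(
                     set = character(0), contrast = character(0),
                     logFC = numeric(0), fraction = numeric(0)),
                   nDEGenes = 0L,
                   sexEffect = list(fraction = 0, sd = 0),
                   tankEffect = list(fraction = 0, sd = 0),
                   latentFactor = list(scale = 0, fraction = 0, rho = 0))
  sim <- simulateExperiment(cfg)
  expect_true(all(sim$truth$betaGenotype == 0))
  expect_true(all(sim$truth$latentLoadings == 0))
  counts <- sim$truth$geneCounts
  libs <- sim$truth$libSizes
  ## observed gene means track the configured NB means p_i * mean(L)
  expMean <- sim$truth$baselineProp * mean(libs)
  obsMean <- rowMeans(counts)
  keep <- expMean > 5
  expect_gt(cor(log(obsMean[keep]), log(expMean[keep])), 0.99)
  ## overdispersion present: variance exceeds the mean for expressed genes
  v <- apply(counts[keep, ], 1L, var)
  expect_gt(mean(v > obsMean[keep]), 0.8)
  ## dispersions strictly positive
  expect_true(all(sim$truth$dispersion > 0))
})
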