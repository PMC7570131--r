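test_that("the design matrix encodes the stated baselines and accepts latent factors", {
  se <- nullCountsSE(nGenes = 10, seed = 1)
  X <- designMatrix(se)
  expect_identical(colnames(X)[1], "(Intercept)")
  expect_identical(attr(X, "genotypeCoefs"), c("eofad", "null", "trans"))
  expect_true("sexmale" %in% colnames(X))       # female is the reference
  expect_true(all(c("tanktank2", "tanktank3") %in% colnames(X)))
  ## wild-type female tank1 rows are intercept-only
  wtRow <- which(studyDesignTable()$genotype == "wildtype" &
                   studyDesignTable()$sex == "female" &
                   studyDesignTable()$tank == "tank1")[1]
  expect_equal(sum(X[wtRow, ]), 1)
  W <- matrix(rnorm(24), 24, 1)
  XW <- designMatrix(se, W = W)
  expect_identical(colnames(XW)[ncol(XW)], "W_1")
  ## rank deficiency is an error
  expect_error(designMatrix(se, W = X[, "eofad", drop = FALSE]),
               "full column rank")
})

test_that("BH adjustment equals the step-up definition and rejects bad input", {
  expect_equal(adjustBH(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjustBH(rep(1, 5)), rep(1, 5))
  set.seed(2)
  for (i in 1:5) {
    p <- runif(50)^2
    expect_equal(adjustBH(p), oracleBH(p), tolerance = 1e-14)
  }
  expect_error(adjustBH(c(0.1, NaN)), "NA")
  expect_error(adjustBH(c(0.1, 1.2)), "0, 1")
})

test_that("a constant gene is null and likelihood ratios are non-negative", {
  se <- nullCountsSE(nGenes = 60, seed = 3)
  counts <- SummarizedExperiment::assay(se)
  counts[1, ] <- 100                       # identical in every sample
  se2 <- geneSE(counts)
  ## equal offsets so the constant gene is exactly the intercept-only fit
  SummarizedExperiment::colData(se2)$lib_size <-
    rep(mean(SummarizedExperiment::colData(se2)$lib_size), 24)
  de <- fitDE(se2, designMatrix(se2))
  flat <- deTable(de)[deTable(de)$gene == rownames(counts)[1], ]
  expect_true(all(abs(flat$logFC) < 0.05))
  expect_true(all(flat$PValue > 0.9))
  expect_true(all(deTable(de)$FDR >= deTable(de)$PValue - 1e-12))
})

test_that("genotype inference is invariant to relabelling tank levels", {
  se <- nullCountsSE(nGenes = 150, seed = 4)
  de1 <- fitDE(se, designMatrix(se))
  se2 <- se
  cd <- SummarizedExperiment::colData(se2)
  cd$tank <- factor(cd$tank, levels = c("tank1", "tank2", "tank3"),
                    labels = c("tank1", "tank3", "tank2"))
  cd$tank <- factor(cd$tank, levels = c("tank1", "tank2", "tank3"))
  SummarizedExperiment::colData(se2) <- cd
  de2 <- fitDE(se2, designMatrix(se2))
  expect_equal(deTable(de1)$PValue, deTable(de2)$PValue, tolerance = 1e-8)
})

test_that("per-contrast type-I error is calibrated on null data", {
  se <- nullCountsSE(nGenes = 2000, mu = 150, phi = 0.1, seed = 5)
  de <- fitDE(se, designMatrix(se))
  for (ct in deContrasts(de)) {
    frac <- mean(deTable(de, ct)$PValue < 0.05)
    expect_gte(frac, 0.03)
    expect_lte(frac, 0.07)
  }
  ## joint test present for every gene, usable for control selection
  expect_identical(nrow(jointTest(de)), 2000L)
})

test_that("dispersion estimation approaches zero for Poisson data and matches an APL grid oracle", {
  set.seed(6)
  counts <- matrix(rpois(600 * 24, lambda = 120), 600, 24)
  de <- fitDE(geneSE(counts), designMatrix(geneSE(counts)))
  expect_lt(median(dispersions(de)), 0.05)

  ## single-gene common dispersion against direct 1-D APL maximisation
  set.seed(7)
  X <- cbind(1, rep(c(0, 1), each = 12))
  offs <- rep(0, 24)
  for (phiTrue in c(0.05, 0.2)) {
    y <- rnbinom(24, mu = 200 * exp(X[, 2] * 0.4), size = 1 / phiTrue)
    edg <- edgeR::estimateGLMCommonDisp(matrix(y, 1), design = X,
                                        offset = offs)
    grid <- oracleCommonDispersion(y, X, offs)
    expect_equal(log(edg), log(grid), tolerance = 0.15)
  }
})
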