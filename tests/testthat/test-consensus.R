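test_that("the harmonic mean p-value obeys its closed forms and bounds", {
  expect_equal(harmonicMeanP(c(0.2, 0.2, 0.2)), 0.2)
  expect_equal(harmonicMeanP(c(0.01, 0.1, 1)), 3 / 111)
  expect_equal(harmonicMeanP(c(0.01, 0.1, 1)), oracleHMP(c(0.01, 0.1, 1)))
  ## weighted version
  expect_equal(harmonicMeanP(c(0.1, 0.4), w = c(3, 1)),
               1 / (0.75 / 0.1 + 0.25 / 0.4))
  set.seed(1)
  for (i in 1:20) {
    p <- runif(3, min = 1e-6)
    h <- harmonicMeanP(p)
    expect_gte(h, min(p))
    expect_lte(h, max(p))
    expect_lte(h, 3 * min(p))     # L = 3 equal weights
  }
  ## monotone in every component
  p <- c(0.02, 0.3, 0.7)
  for (j in 1:3) {
    p2 <- p; p2[j] <- p[j] * 1.5
    expect_gte(harmonicMeanP(pmin(p2, 1)), harmonicMeanP(p))
  }
  expect_error(harmonicMeanP(c(0, 0.5)), "exactly 0")
  expect_error(harmonicMeanP(c(0.5, 1.2)), "\\(0, 1\\]")
  expect_error(harmonicMeanP(c(0.5, 0.5), w = c(1, -1)), "positive")
})

methodTab <- function(sets, p, extra = NULL) {
  out <- data.frame(set = sets, size = 10L, stat = 1,
                    direction = "Up", PValue = p,
                    stringsAsFactors = FALSE)
  if (!is.null(extra)) out$leadingEdge <- extra
  out
}

test_that("the consensus table combines, adjusts and flags correctly", {
  rot <- methodTab("S1", 0.5)
  comp <- methodTab("S1", 0.5)
  gsea <- methodTab("S1", 0.5, extra = I(list(c("g1", "g2"))))
  cons <- buildConsensus(rot, comp, gsea)
  expect_equal(cons$hmp, 0.5)
  expect_equal(cons$fdr_hmp, 0.5)
  expect_false(cons$significant)

  ## BH monotonicity: adding an all-1 set never lowers others' fdr
  rot2 <- methodTab(c("S1", "S2"), c(0.5, 1))
  comp2 <- methodTab(c("S1", "S2"), c(0.5, 1))
  gsea2 <- methodTab(c("S1", "S2"), c(0.5, 1),
                     extra = I(list(c("g1"), c("g9"))))
  cons2 <- buildConsensus(rot2, comp2, gsea2)
  expect_gte(cons2$fdr_hmp[cons2$set == "S1"], cons$fdr_hmp)

  ## invariants on the combined table
  expect_true(all(cons2$hmp >= pmin(cons2$p_rotation, cons2$p_competitive,
                                    cons2$p_gsea)))
  expect_true(all(cons2$fdr_hmp >= cons2$hmp))

  ## sets missing from one method are excluded with a message
  expect_message(cons3 <- buildConsensus(rot2, comp, gsea2), "excluded")
  expect_identical(cons3$set, "S1")

  ## disjoint universes are an error
  expect_error(buildConsensus(methodTab("A", 0.5), methodTab("B", 0.5),
                              methodTab("C", 0.5, extra = I(list("g")))),
               "disjoint")
})

test_that("leading-edge overlaps report pairwise and multi-way intersections above threshold", {
  ## disjoint edges: empty table
  expect_identical(nrow(leadingEdgeOverlap(list(A = c("a", "b"),
                                                B = c("c", "d")))), 0L)
  ## identical edges of size 10: one pairwise intersection of size 10
  ten <- sprintf("g%02d", 1:10)
  out <- leadingEdgeOverlap(list(A = ten, B = ten))
  expect_identical(nrow(out), 1L)
  expect_identical(out$size, 10L)
  ## three sets sharing exactly three genes
  core <- c("g1", "g2", "g3")
  edges <- list(A = c(core, "a1"), B = c(core, "b1"), C = c(core, "c1"))
  out3 <- leadingEdgeOverlap(edges, minShared = 3)
  expect_true("A+B+C" %in% out3$sets)
  expect_identical(out3$size[out3$sets == "A+B+C"], 3L)
  expect_identical(nrow(leadingEdgeOverlap(edges, minShared = 4)), 0L)
})
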