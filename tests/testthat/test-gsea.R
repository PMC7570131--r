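rankedToy <- function(N = 20, seed = 1) {
  set.seed(seed)
  stats <- sort(rnorm(N, sd = 2), decreasing = TRUE)
  names(stats) <- sprintf("g%02d", seq_len(N))
  stats
}

test_that("the ranking metric is signed -log10(p) with a stable order", {
  tab <- data.frame(gene = c("a", "b", "c", "d"),
                    contrast = "eofad",
                    logFC = c(-1, 2, 0.5, -0.2),
                    logCPM = 1,
                    PValue = c(0.01, 1, 0.1, 0.1),
                    FDR = c(0.04, 1, 0.2, 0.2), DE = FALSE)
  de <- new("DEResult", table = tab,
            joint = data.frame(gene = tab$gene, PValue = 1, FDR = 1),
            design = matrix(1), dispersion = rep(0.1, 4),
            contrasts = "eofad")
  r <- rankGenes(de, "eofad")
  expect_equal(unname(r["a"]), -2)
  expect_equal(unname(r["b"]), 0)          # p = 1 kills the sign
  expect_equal(unname(r["c"]), 1)
  ## order is invariant to a monotone rescaling of all p-values
  tab2 <- tab; tab2$PValue <- tab$PValue^0.5; tab2$FDR <- pmin(1, tab2$PValue * 2)
  de2 <- new("DEResult", table = tab2, joint = de@joint,
             design = matrix(1), dispersion = rep(0.1, 4),
             contrasts = "eofad")
  expect_identical(names(rankGenes(de2, "eofad")), names(r))
})

test_that("ES matches the dense running-sum oracle and fgsea exactly", {
  skip_if_not_installed("fgsea")
  stats <- rankedToy(60, seed = 2)
  set.seed(3)
  for (m in c(3, 8, 15)) {
    members <- sample(names(stats), m)
    gsc <- GeneSetCollection(list(S = members))
    res <- gseaPreranked(stats, gsc, nPerm = 10, weight = 1, seed = 1)
    expect_equal(res$ES, oracleESDense(stats, members, weight = 1),
                 tolerance = 1e-12)
    expect_equal(res$ES,
                 fgsea::calcGseaStat(stats,
                                     selectedStats = match(members,
                                                           names(stats)),
                                     gseaParam = 1),
                 tolerance = 1e-12)
    expect_lte(abs(res$ES), 1)
  }
})

test_that("a single top-ranked hit gives ES = 1 and mirroring negates ES with the same p", {
  stats <- rankedToy(20, seed = 4)
  gsc <- GeneSetCollection(list(top = names(stats)[1]))
  res <- gseaPreranked(stats, gsc, nPerm = 200, seed = 5)
  expect_equal(res$ES, 1)

  set.seed(6)
  members <- sample(names(stats), 5)
  gsc2 <- GeneSetCollection(list(S = members))
  plus <- gseaPreranked(stats, gsc2, nPerm = 500, seed = 7)
  minus <- gseaPreranked(-stats, gsc2, nPerm = 500, seed = 7)
  expect_equal(minus$ES, -plus$ES, tolerance = 1e-12)
  expect_equal(minus$PValue, plus$PValue)
})

test_that("with weight 0 the ES is invariant to monotone transformation of the statistics", {
  stats <- rankedToy(30, seed = 8)
  members <- names(stats)[c(2, 5, 9, 20)]
  gsc <- GeneSetCollection(list(S = members))
  a <- gseaPreranked(stats, gsc, nPerm = 10, weight = 0, seed = 1)
  b <- gseaPreranked(sign(stats) * abs(stats)^3 + 0 * stats, gsc,
                     nPerm = 10, weight = 0, seed = 1)
  expect_equal(a$ES, b$ES, tolerance = 1e-12)
})

test_that("the Monte-Carlo p agrees with exhaustive enumeration on a tiny list", {
  stats <- rankedToy(20, seed = 9)
  m <- 5
  set.seed(10)
  members <- sample(names(stats), m)
  gsc <- GeneSetCollection(list(S = members))
  nPerm <- 4000
  res <- gseaPreranked(stats, gsc, nPerm = nPerm, seed = 11)

  allES <- oracleESEnumerate(stats, m)       # all C(20,5) = 15504 sets
  obs <- res$ES
  if (obs >= 0) {
    pExact <- (1 + sum(allES >= obs)) / (1 + sum(allES >= 0))
  } else {
    pExact <- (1 + sum(allES <= obs)) / (1 + sum(allES < 0))
  }
  se3 <- 3 * sqrt(pExact * (1 - pExact) / nPerm)
  expect_lt(abs(res$PValue - pExact), se3 + 1e-3)
  ## leading edge is inside the set and non-empty
  expect_true(all(res$leadingEdge[[1]] %in% members))
  expect_gt(length(res$leadingEdge[[1]]), 0)
})

test_that("GSEA p-values are in (0, 1] and disjoint sets are skipped", {
  stats <- rankedToy(50, seed = 12)
  gsc <- GeneSetCollection(list(S = names(stats)[1:6],
                                gone = c("zz1", "zz2")))
  expect_message(res <- gseaPreranked(stats, gsc, nPerm = 100, seed = 1),
                 "disjoint")
  expect_identical(res$set, "S")
  expect_true(all(res$PValue > 0 & res$PValue <= 1))
})
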