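#' Simulation configuration for the four-genotype sibling design
#'
#' Builds the parameter object for the truth-known negative-binomial
#' simulator. Defaults emulate the study design this pipeline targets: 24
#' sibling fish in four genotype groups (wild type n = 8 as baseline,
#' EOfAD-like/+ n = 6, null/+ n = 4, transheterozygous n = 6), balanced sex,
#' three rearing tanks, one latent factor of unwanted variation correlated
#' with library size, and subtle coordinated shifts planted in a few gene
#' sets with only a handful of large-effect individual genes.
#'
#' @param nGenes Number of genes.
#' @param groupSizes Named integer vector of samples per genotype; the first
#'   level is the baseline (intercept) genotype.
#' @param nTanks Number of rearing tanks, assigned round-robin.
#' @param libSizeRange Range of per-sample library sizes. The default is
#'   scaled down (~10^6) to keep analyses fast; set
#'   \code{realisticLibSizes = TRUE} for sequencing-scale totals (13-23 M).
#' @param realisticLibSizes Use sequencing-scale library sizes.
#' @param baselineLogMean \code{c(meanlog, sdlog)} of the lognormal relative
#'   abundance weights.
#' @param dispersionTrend \code{c(asymptote, slope)} of the mean-dispersion
#'   trend \eqn{\phi_i = asymptote + slope / \mu_i}; the asymptote is the
#'   squared biological coefficient of variation of highly expressed genes.
#' @param txPerGeneRange Range of mature transcripts per gene.
#' @param unsplicedFraction Expected unspliced (intron-retaining) transcript
#'   counts as a fraction of the gene mean; unspliced rows carry a
#'   \code{".unspliced"} identifier suffix and are excluded at aggregation.
#' @param nSets,setSizeRange,setOverlap Gene-set collection parameters: the
#'   number of sets, member-count range, and the fraction of each set shared
#'   with the previous set (0 gives pairwise-disjoint sets).
#' @param perturbedSets data.frame(set, contrast, logFC, fraction) of planted
#'   coordinated shifts: \code{logFC} (log2) added to a random
#'   \code{fraction} of the set's members for the given genotype contrast.
#' @param nDEGenes,deLogFC Number of individually differentially expressed
#'   genes (placed outside any gene set, spread round-robin over the
#'   non-baseline genotypes) and their absolute log2 fold change.
#' @param deMinCpm Minimum expected CPM of planted DE genes, so individual
#'   effects are placed at detectable expression.
#' @param sexEffect,tankEffect \code{list(fraction, sd)} nuisance effects: a
#'   random fraction of genes receives a N(0, sd^2) log2 shift for male sex /
#'   each non-reference tank.
#' @param latentFactor \code{list(scale, fraction, rho)}: the latent sample
#'   score w is standardised with correlation \code{rho} to log library
#'   size; a random \code{fraction} of genes gets loading N(0, scale^2)
#'   (log2 per unit w).
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A validated list of class \code{"SimConfig"}.
#' @export
simConfig <- function(nGenes = 12000L,
                      groupSizes = c(wildtype = 8L, eofad = 6L, null = 4L,
                                     trans = 6L),
                      nTanks = 3L,
                      libSizeRange = c(5e5, 1e6),
                      realisticLibSizes = FALSE,
                      baselineLogMean = c(meanlog = 2, sdlog = 1.8),
                      dispersionTrend = c(asymptote = 0.05, slope = 3),
                      txPerGeneRange = c(1L, 3L),
                      unsplicedFraction = 0.05,
                      nSets = 100L,
                      setSizeRange = c(15L, 200L),
                      setOverlap = 0,
                      perturbedSets = NULL,
                      nDEGenes = 8L,
                      deLogFC = 2,
                      deMinCpm = 50,
                      sexEffect = list(fraction = 0.05, sd = 0.2),
                      tankEffect = list(fraction = 0.05, sd = 0.1),
                      latentFactor = list(scale = 0.5, fraction = 0.5,
                                          rho = 0.8),
                      seed = 1L) {
  if (realisticLibSizes) libSizeRange <- c(13e6, 23e6)
  if (is.null(perturbedSets)) {
    perturbedSets <- data.frame(
      set = sprintf("set%03d", 1:6),
      contrast = rep(c("eofad", "null", "trans"), each = 2L),
      logFC = rep(c(0.3, -0.3), 3L),
      fraction = 0.8,
      stringsAsFactors = FALSE
    )
  }
  cfg <- list(nGenes = as.integer(nGenes), groupSizes = groupSizes,
              nTanks = as.integer(nTanks), libSizeRange = libSizeRange,
              baselineLogMean = baselineLogMean,
              dispersionTrend = dispersionTrend,
              txPerGeneRange = as.integer(txPerGeneRange),
              unsplicedFraction = unsplicedFraction,
              nSets = as.integer(nSets),
              setSizeRange = as.integer(setSizeRange),
              setOverlap = setOverlap,
              perturbedSets = perturbedSets,
              nDEGenes = as.integer(nDEGenes), deLogFC = deLogFC,
              deMinCpm = deMinCpm,
              sexEffect = sexEffect, tankEffect = tankEffect,
              latentFactor = latentFactor, seed = as.integer(seed))
  class(cfg) <- "SimConfig"
  validateSimConfig(cfg)
  cfg
}

validateSimConfig <- function(cfg) {
  stopIfNot(cfg$nGenes > 0L, "nGenes must be positive")
  stopIfNot(all(cfg$groupSizes > 0L) && length(cfg$groupSizes) >= 2L,
            "all genotype groups must be non-empty")
  stopIfNot(!is.null(names(cfg$groupSizes)) &&
              !anyDuplicated(names(cfg$groupSizes)),
            "groupSizes must carry unique genotype names")
  stopIfNot(cfg$nTanks >= 1L, "need at least one tank")
  stopIfNot(all(cfg$libSizeRange > 0) && diff(cfg$libSizeRange) >= 0,
            "libSizeRange must be positive and ordered")
  stopIfNot(all(cfg$dispersionTrend >= 0) && cfg$dispersionTrend[1] > 0,
            "dispersion trend must give strictly positive dispersions")
  stopIfNot(cfg$setSizeRange[2] <= cfg$nGenes,
            "set size range exceeds nGenes")
  stopIfNot(cfg$setOverlap >= 0 && cfg$setOverlap < 1,
            "setOverlap must be in [0, 1)")
  pert <- cfg$perturbedSets
  if (nrow(pert)) {
    stopIfNot(all(pert$contrast %in% names(cfg$groupSizes)[-1]),
              "perturbed-set contrasts must be non-baseline genotypes")
    stopIfNot(all(pert$fraction > 0 & pert$fraction <= 1),
              "perturbed fractions must be in (0, 1]")
    stopIfNot(all(pert$set %in% sprintf("set%03d", seq_len(cfg$nSets))),
              "perturbed set names must exist in the generated collection")
  }
  invisible(cfg)
}

simGeneIds <- function(nGenes) sprintf("gene%05d", seq_len(nGenes))

#' Generate a gene-set collection for the simulator
#'
#' Draws \code{nSets} sets with sizes uniform over \code{setSizeRange}. When
#' \code{setOverlap > 0}, each set shares that fraction of its members with
#' the previous set (giving a controllable chained overlap); at 0 all sets
#' are pairwise disjoint.
#'
#' @param config A \code{\link{simConfig}} object.
#' @return A \linkS4class{GeneSetCollection} with provenance
#'   \code{"simulated"}.
#' @export
simulateGeneSets <- function(config) {
  validateSimConfig(config)
  withSeed(subSeed(config$seed, 101), {
    genes <- simGeneIds(config$nGenes)
    pool <- sample(genes)   # randomised order; drawn from the front
    sets <- vector("list", config$nSets)
    names(sets) <- sprintf("set%03d", seq_len(config$nSets))
    prev <- character(0)
    for (i in seq_len(config$nSets)) {
      size <- if (config$setSizeRange[1] == config$setSizeRange[2]) {
        config$setSizeRange[1]
      } else {
        sample(config$setSizeRange[1]:config$setSizeRange[2], 1L)
      }
      nShared <- if (i == 1L) 0L else round(config$setOverlap * size)
      nShared <- min(nShared, length(prev))
      nNew <- size - nShared
      stopIfNot(nNew <= length(pool),
                "gene pool exhausted while drawing set ", i,
                "; reduce nSets/setSizeRange or raise nGenes")
      members <- c(if (nShared) sample(prev, nShared) else character(0),
                   pool[seq_len(nNew)])
      pool <- pool[-seq_len(nNew)]
      sets[[i]] <- members
      prev <- members
    }
    GeneSetCollection(sets, provenance = "simulated")
  })
}

#' Simulate a transcript-level RNA-seq experiment with known truth
#'
#' Draws gene-level counts from per-gene negative-binomial laws
#' \eqn{NB(\mu_{ij}, \phi_i)} with
#' \eqn{\mu_{ij} = p_i L_j 2^{x_j^T \beta_i + w_j a_i}} (baseline relative
#' abundance \eqn{p_i}, library size \eqn{L_j}, genotype/sex/tank effects
#' \eqn{\beta_i}, latent factor \eqn{w}), splits each gene's count over its
#' mature transcripts, and adds low-abundance unspliced transcript rows
#' (identifier suffix \code{".unspliced"}) that the aggregation step must
#' exclude.
#'
#' @param config A \code{\link{simConfig}} object.
#' @return A list with elements \code{se} (transcript-level
#'   \code{SummarizedExperiment}: assay \code{est_counts}, rowData
#'   \code{gene_id}/\code{unspliced}/\code{length}/\code{eff_length}, colData
#'   \code{genotype}/\code{sex}/\code{tank}), \code{sets} (the
#'   \linkS4class{GeneSetCollection}) and \code{truth} (planted DE genes and
#'   set shifts, latent factor scores, library sizes, dispersions and gene
#'   effect parameters).
#' @export
simulateExperiment <- function(config) {
  validateSimConfig(config)
  sets <- simulateGeneSets(config)
  genes <- simGeneIds(config$nGenes)
  G <- config$nGenes
  n <- sum(config$groupSizes)
  genotypes <- factor(rep(names(config$groupSizes), config$groupSizes),
                      levels = names(config$groupSizes))
  contrasts <- names(config$groupSizes)[-1]

  withSeed(subSeed(config$seed, 202), {
    ## --- samples -----------------------------------------------------------
    sampleIds <- sprintf("sample%02d", seq_len(n))
    sex <- factor(unlist(lapply(config$groupSizes, function(k) {
      rep_len(c("female", "male"), k)
    }), use.names = FALSE), levels = c("female", "male"))
    tank <- factor(paste0("tank", rep_len(seq_len(config$nTanks), n)),
                   levels = paste0("tank", seq_len(config$nTanks)))
    libSizes <- runif(n, config$libSizeRange[1], config$libSizeRange[2])
    rho <- config$latentFactor$rho
    zlib <- as.numeric(scale(log(libSizes)))
    if (!is.finite(sd(log(libSizes))) || sd(log(libSizes)) == 0) zlib <- rep(0, n)
    w <- rho * zlib + sqrt(max(0, 1 - rho^2)) * rnorm(n)
    w <- as.numeric(scale(w))

    ## --- gene-level parameters --------------------------------------------
    weight <- stats::rlnorm(G, config$baselineLogMean[["meanlog"]],
                            config$baselineLogMean[["sdlog"]])
    p <- weight / sum(weight)
    muTyp <- p * exp(mean(log(libSizes)))
    phi <- config$dispersionTrend[[1]] +
      config$dispersionTrend[[2]] / pmax(muTyp, 1e-8)

    betaGeno <- matrix(0, G, length(contrasts),
                       dimnames = list(genes, contrasts))
    pert <- config$perturbedSets
    shiftedGenes <- vector("list", nrow(pert))
    for (r in seq_len(nrow(pert))) {
      members <- sets[[pert$set[r]]]
      nShift <- max(1L, round(pert$fraction[r] * length(members)))
      chosen <- sample(members, nShift)
      betaGeno[chosen, pert$contrast[r]] <-
        betaGeno[chosen, pert$contrast[r]] + pert$logFC[r]
      shiftedGenes[[r]] <- chosen
    }

    inSet <- unique(unlist(geneSets(sets), use.names = FALSE))
    freeGenes <- setdiff(genes, inSet)
    deGenes <- data.frame(gene = character(0), contrast = character(0),
                          logFC = numeric(0), stringsAsFactors = FALSE)
    if (config$nDEGenes > 0L) {
      poolDE <- if (length(freeGenes) >= config$nDEGenes) freeGenes else genes
      ## plant individual DE genes at detectable expression levels
      expressed <- poolDE[p[match(poolDE, genes)] * 1e6 >= config$deMinCpm]
      if (length(expressed) >= config$nDEGenes) poolDE <- expressed
      chosen <- sample(poolDE, config$nDEGenes)
      ct <- rep_len(contrasts, config$nDEGenes)
      lfc <- config$deLogFC * sample(c(-1, 1), config$nDEGenes, replace = TRUE)
      for (k in seq_len(config$nDEGenes)) {
        betaGeno[chosen[k], ct[k]] <- betaGeno[chosen[k], ct[k]] + lfc[k]
      }
      deGenes <- data.frame(gene = chosen, contrast = ct, logFC = lfc,
                            stringsAsFactors = FALSE)
    }

    betaSex <- numeric(G)
    idx <- sample.int(G, round(config$sexEffect$fraction * G))
    betaSex[idx] <- rnorm(length(idx), 0, config$sexEffect$sd)
    betaTank <- matrix(0, G, config$nTanks)
    for (t in seq_len(config$nTanks)[-1]) {
      idx <- sample.int(G, round(config$tankEffect$fraction * G))
      betaTank[idx, t] <- rnorm(length(idx), 0, config$tankEffect$sd)
    }
    a <- numeric(G)
    idx <- sample.int(G, round(config$latentFactor$fraction * G))
    a[idx] <- rnorm(length(idx), 0, config$latentFactor$scale)

    ## --- per-sample means and NB counts -------------------------------------
    log2mu <- outer(log2(p), log2(libSizes), `+`)
    for (ct in contrasts) {
      cols <- which(genotypes == ct)
      if (length(cols)) log2mu[, cols] <- log2mu[, cols] + betaGeno[, ct]
    }
    maleCols <- which(sex == "male")
    if (length(maleCols)) log2mu[, maleCols] <- log2mu[, maleCols] + betaSex
    for (t in seq_len(config$nTanks)[-1]) {
      cols <- which(tank == paste0("tank", t))
      if (length(cols)) log2mu[, cols] <- log2mu[, cols] + betaTank[, t]
    }
    log2mu <- log2mu + outer(a, w)
    mu <- 2^log2mu

    counts <- matrix(rnbinom(G * n, mu = mu, size = rep(1 / phi, n)), G, n,
                     dimnames = list(genes, sampleIds))

    ## --- transcript structure ------------------------------------------------
    nTx <- if (config$txPerGeneRange[1] == config$txPerGeneRange[2]) {
      rep(config$txPerGeneRange[1], G)
    } else {
      sample(config$txPerGeneRange[1]:config$txPerGeneRange[2], G,
             replace = TRUE)
    }
    txProps <- lapply(nTx, function(k) {
      q <- stats::rexp(k) + 0.1
      q / sum(q)
    })
    maxTx <- max(nTx)
    txCounts <- vector("list", maxTx)
    rem <- counts
    remProp <- rep(1, G)
    for (k in seq_len(maxTx)) {
      has <- nTx >= k
      ck <- matrix(0, G, n)
      last <- nTx == k
      qk <- vapply(txProps, function(q) if (length(q) >= k) q[k] else 0,
                   numeric(1))
      draw <- has & !last
      if (any(draw)) {
        pr <- pmin(pmax(qk[draw] / remProp[draw], 0), 1)
        ck[draw, ] <- matrix(
          rbinom(sum(draw) * n, size = as.integer(rem[draw, ]),
                 prob = rep(pr, n)),
          sum(draw), n)
      }
      ck[last, ] <- rem[last, ]
      rem <- rem - ck
      remProp <- remProp - qk
      txCounts[[k]] <- ck
    }

    unspliced <- matrix(rpois(G * n, lambda = config$unsplicedFraction * mu),
                        G, n)

    txId <- character(0); txGene <- character(0); txUnspliced <- logical(0)
    blocks <- vector("list", maxTx + 1L)
    for (k in seq_len(maxTx)) {
      has <- which(nTx >= k)
      txId <- c(txId, sprintf("%s.t%d", genes[has], k))
      txGene <- c(txGene, genes[has])
      txUnspliced <- c(txUnspliced, rep(FALSE, length(has)))
      blocks[[k]] <- txCounts[[k]][has, , drop = FALSE]
    }
    txId <- c(txId, paste0(genes, ".unspliced"))
    txGene <- c(txGene, genes)
    txUnspliced <- c(txUnspliced, rep(TRUE, G))
    blocks[[maxTx + 1L]] <- unspliced
    est <- do.call(rbind, blocks)
    rownames(est) <- txId
    colnames(est) <- sampleIds

    txLen <- sample(500:5000, length(txId), replace = TRUE)
    txLen[txUnspliced] <- txLen[txUnspliced] + 1500L
    effLen <- pmax(txLen - 250L, 1L)

    coldata <- S4Vectors::DataFrame(
      sample = sampleIds, genotype = genotypes, sex = sex, tank = tank,
      row.names = sampleIds)
    rowdata <- S4Vectors::DataFrame(
      tx_id = txId, gene_id = txGene, unspliced = txUnspliced,
      length = txLen, eff_length = effLen, row.names = txId)
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(est_counts = est), rowData = rowdata, colData = coldata)

    pertOut <- pert
    pertOut$genesShifted <- I(shiftedGenes)
    truth <- list(
      deGenes = deGenes,
      perturbedSets = pertOut,
      W = structure(w, names = sampleIds),
      libSizes = structure(libSizes, names = sampleIds),
      dispersion = structure(phi, names = genes),
      baselineProp = structure(p, names = genes),
      betaGenotype = betaGeno,
      latentLoadings = structure(a, names = genes),
      geneCounts = counts
    )
    list(se = se, sets = sets, truth = truth)
  })
}
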