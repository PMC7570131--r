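#' Gene-label permutation validation of the consensus
#'
#' The validation experiment for the consensus pipeline: gene identifiers
#' are randomly reassigned to expression rows (breaking gene-set membership
#' while leaving the expression matrix, the design and therefore every
#' per-gene statistic's empirical distribution intact), the three enrichment
#' tests and the harmonic-mean-p consensus are rerun per contrast, and the
#' number of FDR-significant sets is recorded per permutation. Shuffles are
#' drawn uniformly over non-identity permutations. A well-calibrated
#' consensus finds (almost) no significant sets under this null.
#'
#' Because the per-gene statistics do not change under relabelling, the
#' rotation null matrix, the camera-style moderated z and the GSEA null
#' distributions are computed once per contrast and reused across
#' permutations; only the set memberships move.
#'
#' @param fit A \code{"ConsensusPipeline"} object from
#'   \code{\link{runPipeline}}.
#' @param nPerm Number of label permutations (default 100).
#' @param seed Integer seed.
#' @param alpha FDR threshold; defaults to the pipeline's.
#' @return A list of class \code{"PermutationReport"} with
#'   \code{nPermutations}, \code{seed}, \code{alpha} and \code{counts}, a
#'   data.frame of per-permutation, per-contrast significant-set counts for
#'   each method's own FDR and for the consensus FDR.
#' @export
permuteLabelValidation <- function(fit, nPerm = 100L, seed = 1L,
                                   alpha = NULL) {
  stopIfNot(inherits(fit, "ConsensusPipeline"),
            "fit must be a ConsensusPipeline object")
  stopIfNot(nPerm >= 1L, "nPerm must be at least 1")
  if (is.null(alpha)) alpha <- fit$params$alpha
  E <- fit$logcpm
  G <- nrow(E)
  ids <- rownames(E)
  contrasts <- deContrasts(fit$de)
  idx0 <- setIndexList(fit$sets, ids)
  stopIfNot(length(idx0) > 0L, "no testable sets")

  ## per-contrast reusable states
  states <- lapply(seq_along(contrasts), function(ci) {
    ct <- contrasts[ci]
    ranked <- rankGenes(fit$de, ct)
    list(
      rot = rotationState(E, fit$design, ct, nRot = fit$params$nRot,
                          seed = subSeed(seed, 5000 + ci)),
      comp = competitiveState(E, fit$design, ct),
      gseaRanked = ranked,
      gsea = gseaState(ranked, weight = fit$params$gseaWeight,
                       nPerm = fit$params$nPermGsea,
                       sizes = lengths(idx0),
                       seed = subSeed(seed, 6000 + ci)),
      mapRank = match(ids, names(ranked))
    )
  })
  names(states) <- contrasts

  counts <- withSeed(subSeed(seed, 7000), {
    rows <- vector("list", nPerm * length(contrasts))
    r <- 0L
    for (b in seq_len(nPerm)) {
      repeat {
        perm <- sample.int(G)
        if (any(perm != seq_len(G))) break  # identity excluded by design
      }
      idxPerm <- lapply(idx0, function(s) perm[s])
      for (ci in seq_along(contrasts)) {
        st <- states[[ci]]
        rotP <- rotationFromState(st$rot, idxPerm)$PValue
        compP <- competitiveFromState(st$comp, idxPerm)$PValue
        idxRank <- lapply(idxPerm, function(s) st$mapRank[s])
        gseaTab <- gseaFromState(st$gsea, idxRank)
        gseaP <- gseaTab$PValue
        hmp <- mapply(function(a, b2, c2) harmonicMeanP(c(a, b2, c2),
                                                        w = fit$params$weights),
                      rotP, compP, gseaP)
        r <- r + 1L
        rows[[r]] <- data.frame(
          perm = b, contrast = contrasts[ci],
          nSigRotation = sum(p.adjust(rotP, "BH") < alpha),
          nSigCompetitive = sum(p.adjust(compP, "BH") < alpha),
          nSigGsea = sum(p.adjust(gseaP, "BH") < alpha),
          nSigConsensus = sum(p.adjust(hmp, "BH") < alpha),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })

  structure(list(nPermutations = as.integer(nPerm), seed = seed,
                 alpha = alpha, counts = counts),
            class = "PermutationReport")
}

#' @export
print.PermutationReport <- function(x, ...) {
  perPerm <- tapply(x$counts$nSigConsensus, x$counts$perm, sum)
  cat("PermutationReport:", x$nPermutations, "gene-label permutations\n")
  cat(sprintf("  permutations with zero consensus-significant sets: %d/%d\n",
              sum(perPerm == 0), x$nPermutations))
  cat("  mean consensus-significant sets per permutation:",
      round(mean(perPerm), 3), "\n")
  invisible(x)
}
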