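#' Run the full consensus enrichment pipeline
#'
#' End-to-end orchestration: gene-level aggregation (when given a
#' transcript-level input), detection filtering, TMM normalisation, the
#' two-pass unwanted-variation protocol (initial DE fit, negative-control
#' selection, RUVg factors), the final NB GLM differential expression fit
#' with W in the design, the three gene-set tests per genotype contrast, and
#' the harmonic-mean-p consensus with FDR control. All randomness flows from
#' \code{seed} through named substreams, so a fixed seed reproduces the run
#' exactly.
#'
#' @param se A transcript-level \code{SummarizedExperiment} (assay
#'   \code{est_counts}) or gene-level one (assay \code{counts}), with
#'   genotype/sex/tank colData.
#' @param gsc A \linkS4class{GeneSetCollection}; it is restricted to the
#'   filtered gene universe (minimum set size \code{minSetSize}).
#' @param cpmThreshold,minUndetected Detection filter parameters (see
#'   \code{\link{filterUndetected}}).
#' @param nControls Number of negative-control genes (default 5000).
#' @param k Number of unwanted-variation factors (default 1).
#' @param priorDF Dispersion shrinkage prior degrees of freedom.
#' @param test DE test type, \code{"lrt"} or \code{"ql"}.
#' @param nRot Rotations for the self-contained test.
#' @param nPermGsea Null draws per set size for preranked GSEA.
#' @param gseaWeight GSEA weighting exponent.
#' @param minSetSize Minimum testable set size after restriction.
#' @param weights Optional method weights for the harmonic mean.
#' @param alpha FDR threshold for DE genes and consensus significance.
#' @param seed Master seed.
#' @param verbose Emit stage-level progress messages with counts.
#' @return A list of class \code{"ConsensusPipeline"}: the filtered
#'   normalised \code{se}, \code{logcpm}, \code{design}, latent factors
#'   \code{W}, \code{controlGenes}, \code{initialDE}, final \code{de},
#'   restricted \code{sets}, per-contrast \code{enrichment} (three method
#'   tables) and \code{consensus} tables, \code{params} and a run
#'   \code{manifest}.
#' @export
runPipeline <- function(se, gsc,
                        cpmThreshold = 0.66, minUndetected = NULL,
                        nControls = 5000L, k = 1L,
                        priorDF = 10, test = "lrt",
                        nRot = 9999L, nPermGsea = 10000L, gseaWeight = 1,
                        minSetSize = 5L, weights = NULL,
                        alpha = 0.05, seed = 1L, verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if ("est_counts" %in% SummarizedExperiment::assayNames(se)) {
    se <- stage("aggregate", aggregateToGenes(se))
    say("aggregated to ", nrow(se), " genes")
  }
  nGenesIn <- nrow(se)
  se <- stage("filter",
              filterUndetected(se, cpmThreshold = cpmThreshold,
                               minUndetected = minUndetected))
  say("detection filter kept ", nrow(se), " of ", nGenesIn, " genes; ",
      "library sizes ",
      paste(round(range(SummarizedExperiment::colData(se)$lib_size)),
            collapse = " - "))
  se <- stage("normalize", tmmNormalize(se))

  ruv <- stage("unwanted-variation",
               estimateUnwantedVariation(se, nControls = nControls, k = k,
                                         priorDF = priorDF, test = test))
  design <- stage("design", designMatrix(se, W = ruv$W))
  de <- stage("differential-expression",
              fitDE(se, design, priorDF = priorDF, test = test,
                    alpha = alpha))
  contrasts <- deContrasts(de)
  for (ct in contrasts) {
    say("  ", ct, ": ", sum(deTable(de, ct)$DE), " DE genes at FDR < ",
        alpha)
  }

  logcpm <- cpmMatrix(se, log = TRUE)
  sets <- stage("gene-sets",
                restrictToUniverse(gsc, rownames(se), minSize = minSetSize,
                                   verbose = verbose))
  say("testing ", length(sets), " gene sets on a universe of ",
      nrow(se), " genes")

  enrichment <- list()
  consensus <- list()
  for (ci in seq_along(contrasts)) {
    ct <- contrasts[ci]
    rot <- stage(paste0("rotation:", ct),
                 rotationTest(logcpm, design, ct, sets, nRot = nRot,
                              seed = subSeed(seed, 1000 + ci)))
    comp <- stage(paste0("competitive:", ct),
                  competitiveTest(logcpm, design, ct, sets))
    ranked <- rankGenes(de, ct)
    gsea <- stage(paste0("gsea:", ct),
                  gseaPreranked(ranked, sets, nPerm = nPermGsea,
                                weight = gseaWeight,
                                seed = subSeed(seed, 2000 + ci)))
    enrichment[[ct]] <- list(rotation = rot, competitive = comp,
                             gsea = gsea)
    consensus[[ct]] <- stage(paste0("consensus:", ct),
                             buildConsensus(rot, comp, gsea,
                                            weights = weights,
                                            alpha = alpha))
    say("  ", ct, ": ", sum(consensus[[ct]]$significant),
        " consensus-significant sets")
  }

  params <- list(cpmThreshold = cpmThreshold, minUndetected = minUndetected,
                 nControls = nControls, k = k, priorDF = priorDF,
                 test = test, nRot = nRot, nPermGsea = nPermGsea,
                 gseaWeight = gseaWeight, minSetSize = minSetSize,
                 weights = weights, alpha = alpha, seed = seed)
  manifest <- list(
    rVersion = R.version.string,
    packageVersion = as.character(utils::packageVersion("consensusGSA")),
    params = params,
    counts = list(genesIn = nGenesIn, genesFiltered = nrow(se),
                  setsTested = length(sets),
                  libSizeRange = range(SummarizedExperiment::colData(se)$lib_size),
                  deGenes = vapply(contrasts,
                                   function(ct) sum(deTable(de, ct)$DE),
                                   integer(1)),
                  significantSets = vapply(consensus,
                                           function(x) sum(x$significant),
                                           integer(1))))
  structure(list(se = se, logcpm = logcpm, design = design, W = ruv$W,
                 controlGenes = ruv$controlGenes, initialDE = ruv$initialDE,
                 de = de, sets = sets, enrichment = enrichment,
                 consensus = consensus, params = params,
                 manifest = manifest),
            class = "ConsensusPipeline")
}

#' @export
print.ConsensusPipeline <- function(x, ...) {
  cat("ConsensusPipeline run\n")
  cat("  genes tested:", nrow(x$se), " sets tested:", length(x$sets), "\n")
  for (ct in names(x$consensus)) {
    cat(sprintf("  %-12s %2d DE genes, %2d consensus-significant sets\n",
                ct, sum(deTable(x$de, ct)$DE),
                sum(x$consensus[[ct]]$significant)))
  }
  invisible(x)
}
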