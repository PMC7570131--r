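#' Select negative-control genes from an initial DE fit
#'
#' Returns the genes least affected by genotype: the \code{nControls} genes
#' with the largest p-value in the joint (ANOVA-type) test over all genotype
#' coefficients. Ties are broken by gene identifier order.
#'
#' @param de A \linkS4class{DEResult} from the initial fit (without latent
#'   factors).
#' @param nControls Number of control genes (default 5000).
#' @return Character vector of gene identifiers.
#' @export
selectNegativeControls <- function(de, nControls = 5000L) {
  joint <- jointTest(de)
  stopIfNot(nControls <= nrow(joint),
            "nControls (", nControls, ") exceeds the number of genes (",
            nrow(joint), ")")
  ord <- order(-joint$PValue, joint$gene)
  sort(joint$gene[ord][seq_len(nControls)])
}

#' Estimate factors of unwanted variation from control genes (RUVg)
#'
#' Factor analysis of the negative-control genes: the control-gene
#' log-counts (pseudo-count offset) are row-centred and the first \code{k}
#' sample-side singular vectors taken as the latent factor scores W. Columns
#' of W have unit norm (the scale is absorbed by the regression
#' coefficients when W enters the design matrix); the sign of each column is
#' fixed so its largest-magnitude loading is positive.
#'
#' @param se Gene-level \code{SummarizedExperiment}.
#' @param controls Character vector of control gene identifiers (subset of
#'   rownames).
#' @param k Number of factors (default 1).
#' @param pseudoCount Offset for the log transform (default 1).
#' @return A list of class \code{"LatentFactors"} with \code{W} (samples x k
#'   matrix, columns \code{W_1}, ...) and \code{controlGenes}.
#' @export
estimateRUV <- function(se, controls, k = 1L, pseudoCount = 1) {
  counts <- SummarizedExperiment::assay(se, "counts")
  missing <- setdiff(controls, rownames(counts))
  stopIfNot(length(missing) == 0L,
            "control genes absent from the matrix: ",
            paste(head(missing, 5L), collapse = ", "))
  stopIfNot(length(controls) >= k, "need at least k control genes")
  Y <- log(counts[controls, , drop = FALSE] + pseudoCount)
  Yc <- Y - rowMeans(Y)
  sv <- svd(Yc, nu = 0, nv = min(dim(Yc)))
  rank <- sum(sv$d > max(sv$d[1], 1e-12) * 1e-10)
  stopIfNot(k <= rank,
            "k (", k, ") exceeds the rank (", rank,
            ") of the centred control-gene matrix")
  W <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (W[which.max(abs(W[, j])), j] < 0) W[, j] <- -W[, j]
  }
  dimnames(W) <- list(colnames(counts), paste0("W_", seq_len(k)))
  structure(list(W = W, controlGenes = controls), class = "LatentFactors")
}

#' @export
print.LatentFactors <- function(x, ...) {
  cat("LatentFactors:", ncol(x$W), "factor(s) estimated from",
      length(x$controlGenes), "control genes\n")
  invisible(x)
}

#' Two-pass estimation of unwanted variation
#'
#' Encodes the full control-gene protocol as one operation: fit the initial
#' per-gene NB GLM without latent factors, take the \code{nControls} genes
#' least differentially expressed across all genotypes as negative controls,
#' and estimate \code{k} factors of unwanted variation from them.
#'
#' @param se Normalised gene-level \code{SummarizedExperiment} with
#'   genotype/sex/tank colData.
#' @param nControls Number of negative-control genes.
#' @param k Number of latent factors.
#' @param priorDF Prior degrees of freedom for dispersion shrinkage.
#' @param test \code{"lrt"} (default) or \code{"ql"}.
#' @return A list with \code{W} (samples x k), \code{controlGenes},
#'   \code{initialDE} (the first-pass \linkS4class{DEResult}).
#' @export
estimateUnwantedVariation <- function(se, nControls = 5000L, k = 1L,
                                      priorDF = 10, test = "lrt") {
  design0 <- designMatrix(se)
  de0 <- fitDE(se, design0, priorDF = priorDF, test = test)
  controls <- selectNegativeControls(de0, nControls = nControls)
  ruv <- estimateRUV(se, controls, k = k)
  list(W = ruv$W, controlGenes = controls, initialDE = de0)
}
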