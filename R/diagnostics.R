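#' PCA diagnostic for library-size confounding
#'
#' Centred principal component analysis of the per-sample logCPM profiles,
#' reporting the Pearson correlation of the first two PCs with log library
#' size, before and (when latent factors are supplied) after regressing the
#' expression matrix on W. In a confounded dataset PC1 tracks library size
#' before adjustment and should no longer do so afterwards.
#'
#' @param logcpm Genes x samples logCPM matrix.
#' @param libSizes Per-sample library sizes.
#' @param W Optional samples x k latent factor matrix to regress out.
#' @return A list with \code{before} and (if \code{W} given) \code{after},
#'   each holding \code{coords} (samples x 2), \code{corLibSize} (named
#'   length-2 vector) and \code{varExplained}.
#' @export
pcaDiagnostic <- function(logcpm, libSizes, W = NULL) {
  stopIfNot(ncol(logcpm) >= 3L, "need at least 3 samples")
  stopIfNot(length(libSizes) == ncol(logcpm),
            "libSizes must match the number of samples")
  stopIfNot(sd(as.numeric(logcpm)) > 0, "expression matrix is constant")

  pcaOf <- function(E) {
    pr <- prcomp(t(E), center = TRUE, scale. = FALSE)
    coords <- pr$x[, 1:2, drop = FALSE]
    ve <- pr$sdev^2 / sum(pr$sdev^2)
    corLib <- apply(coords, 2L, function(pc) {
      if (sd(pc) == 0) 0 else cor(pc, log(libSizes))
    })
    list(coords = coords, corLibSize = structure(corLib,
                                                 names = c("PC1", "PC2")),
         varExplained = ve[1:2])
  }

  out <- list(before = pcaOf(logcpm))
  if (!is.null(W)) {
    M <- cbind(1, as.matrix(W))
    P <- M %*% solve(crossprod(M), t(M))    # sample-space projection onto W
    out$after <- pcaOf(logcpm - logcpm %*% P)
  }
  out
}

#' Cell-type marker expression distributions per sample
#'
#' Summarises the logCPM distribution of each marker list (e.g. neuron,
#' astrocyte, oligodendrocyte, microglia markers) in every sample and flags
#' samples whose marker median deviates from the cohort median by more than
#' \code{madThreshold} pooled MADs — a screen for gross cell-type
#' composition differences.
#'
#' @param logcpm Genes x samples logCPM matrix.
#' @param markerLists Named list of marker gene identifier vectors.
#' @param madThreshold Deviation threshold in MAD units (default 2).
#' @return data.frame with columns \code{cellType}, \code{sample},
#'   \code{median}, \code{q25}, \code{q75}, \code{flag}.
#' @export
markerDistribution <- function(logcpm, markerLists, madThreshold = 2) {
  stopIfNot(length(markerLists) > 0L && !is.null(names(markerLists)),
            "markerLists must be a named list")
  rows <- list()
  for (ctype in names(markerLists)) {
    markers <- intersect(markerLists[[ctype]], rownames(logcpm))
    if (!length(markers)) {
      message("marker list '", ctype, "' has no genes in the matrix; skipped")
      next
    }
    sub <- logcpm[markers, , drop = FALSE]
    med <- apply(sub, 2L, median)
    q25 <- apply(sub, 2L, quantile, probs = 0.25)
    q75 <- apply(sub, 2L, quantile, probs = 0.75)
    centre <- median(med)
    spread <- mad(med)
    ## zero spread (identical medians) must not mask a gross outlier
    flag <- abs(med - centre) > pmax(madThreshold * spread, 1e-8)
    rows[[ctype]] <- data.frame(
      cellType = ctype, sample = colnames(logcpm), median = med,
      q25 = q25, q75 = q75, flag = flag,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  stopIfNot(length(rows) > 0L, "no marker list overlaps the matrix")
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
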