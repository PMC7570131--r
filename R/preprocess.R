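#' Aggregate transcript abundances to gene level
#'
#' Sums estimated counts of each gene's mature transcripts, omitting
#' unspliced (intron-retaining) transcripts. Counts stay fractional, as is
#' usual for pseudo-aligner output. Genes whose only transcripts are
#' unspliced are retained with a zero row. Gene order is lexicographic.
#'
#' @param se Transcript-level \code{SummarizedExperiment} from
#'   \code{\link{readKallisto}} (assay \code{est_counts}, rowData
#'   \code{gene_id} and \code{unspliced}).
#' @return Gene-level \code{SummarizedExperiment} with assay \code{counts},
#'   colData \code{lib_size} (column sums) and \code{norm_factor} (1).
#' @export
aggregateToGenes <- function(se) {
  rd <- SummarizedExperiment::rowData(se)
  stopIfNot(all(c("gene_id", "unspliced") %in% colnames(rd)),
            "rowData must carry gene_id and unspliced columns")
  if (anyNA(rd$gene_id)) {
    stop("transcript(s) with no gene mapping: ",
         paste(head(rownames(se)[is.na(rd$gene_id)], 10L), collapse = ", "),
         call. = FALSE)
  }
  est <- SummarizedExperiment::assay(se, "est_counts")
  genes <- sort(unique(rd$gene_id))
  mature <- !rd$unspliced
  agg <- rowsum(est[mature, , drop = FALSE],
                group = rd$gene_id[mature], reorder = TRUE)
  counts <- matrix(0, length(genes), ncol(est),
                   dimnames = list(genes, colnames(est)))
  counts[rownames(agg), ] <- agg
  makeGeneSE(counts, coldata = SummarizedExperiment::colData(se))
}

#' Filter undetectable genes
#'
#' Removes a gene when its counts-per-million falls below
#' \code{cpmThreshold} in at least \code{minUndetected} samples. CPM is
#' computed on the pre-filter library sizes; library sizes are recomputed on
#' the retained genes. Defaults follow the half-of-libraries rule: a
#' threshold of 0.66 CPM in at least \code{ceiling(n/2)} libraries (12 of 24
#' in the emulated design).
#'
#' @param se Gene-level \code{SummarizedExperiment}.
#' @param cpmThreshold Detection threshold in CPM.
#' @param minUndetected Minimum number of below-threshold samples for
#'   removal.
#' @return The filtered \code{SummarizedExperiment}.
#' @export
filterUndetected <- function(se, cpmThreshold = 0.66, minUndetected = NULL) {
  n <- ncol(se)
  if (is.null(minUndetected)) minUndetected <- ceiling(n / 2)
  stopIfNot(cpmThreshold > 0, "cpmThreshold must be positive")
  stopIfNot(minUndetected >= 1 && minUndetected <= n,
            "minUndetected must be in [1, n]")
  counts <- SummarizedExperiment::assay(se, "counts")
  libs <- SummarizedExperiment::colData(se)$lib_size
  cpmRaw <- t(t(counts) / libs) * 1e6
  undetected <- rowSums(cpmRaw < cpmThreshold)
  keep <- undetected < minUndetected
  if (!any(keep)) warning("no genes pass the detection filter")
  out <- se[keep, ]
  SummarizedExperiment::colData(out)$lib_size <-
    colSums(SummarizedExperiment::assay(out, "counts"))
  out
}

#' TMM normalisation factors
#'
#' Computes trimmed-mean-of-M-values scaling factors between libraries
#' (weighted trimmed mean of gene-wise log ratios against a reference
#' sample, with the published 30\% M-trim and 5\% A-trim defaults), rescaled
#' to geometric mean 1, and stores them in \code{colData(se)$norm_factor}.
#'
#' @param se Gene-level \code{SummarizedExperiment}.
#' @param logratioTrim,sumTrim Trim fractions for the M and A components.
#' @return \code{se} with updated \code{norm_factor}.
#' @export
tmmNormalize <- function(se, logratioTrim = 0.3, sumTrim = 0.05) {
  stopIfNot(ncol(se) >= 2L, "TMM needs at least 2 samples")
  counts <- SummarizedExperiment::assay(se, "counts")
  if (any(colSums(counts) == 0)) {
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[colSums(counts) == 0], collapse = ", "),
         call. = FALSE)
  }
  f <- edgeR::calcNormFactors(counts,
                              lib.size = SummarizedExperiment::colData(se)$lib_size,
                              method = "TMM",
                              logratioTrim = logratioTrim, sumTrim = sumTrim)
  SummarizedExperiment::colData(se)$norm_factor <- as.numeric(f)
  se
}

#' Counts per million
#'
#' CPM on effective library sizes (library size times normalisation
#' factor); the log variant is prior-count-offset log2-CPM.
#'
#' @param se Gene-level \code{SummarizedExperiment}.
#' @param log Return log2 values.
#' @param priorCount Prior count for the log transform.
#' @return A genes-by-samples numeric matrix.
#' @export
cpmMatrix <- function(se, log = FALSE, priorCount = 0.5) {
  counts <- SummarizedExperiment::assay(se, "counts")
  cd <- SummarizedExperiment::colData(se)
  effLib <- cd$lib_size * cd$norm_factor
  stopIfNot(all(effLib > 0), "effective library sizes must be positive")
  edgeR::cpm(counts, lib.size = effLib, log = log, prior.count = priorCount)
}
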