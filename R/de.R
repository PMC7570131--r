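#' Build the study design matrix
#'
#' Encodes the design with the baseline genotype as the intercept, one
#' coefficient per non-baseline genotype, sex (first level reference) and
#' tank (first level reference), plus optional latent factor columns W.
#' Genotype coefficient columns are named after the genotype levels so they
#' can be used directly as contrast names.
#'
#' @param se Gene-level \code{SummarizedExperiment} whose colData carries
#'   \code{genotype}, and optionally \code{sex} and \code{tank}, as factors.
#' @param W Optional samples x k matrix of latent factors.
#' @return A full-rank numeric design matrix.
#' @export
designMatrix <- function(se, W = NULL) {
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  stopIfNot("genotype" %in% colnames(cd), "colData must carry genotype")
  terms <- "genotype"
  for (v in c("sex", "tank")) {
    if (v %in% colnames(cd) && nlevels(factor(cd[[v]])) > 1L) {
      terms <- c(terms, v)
    }
  }
  form <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  X <- model.matrix(form, data = cd)
  gl <- levels(factor(cd$genotype))
  colnames(X) <- sub("^genotype", "", colnames(X))
  if (!is.null(W)) {
    W <- as.matrix(W)
    stopIfNot(nrow(W) == nrow(X), "W must have one row per sample")
    if (is.null(colnames(W))) colnames(W) <- paste0("W_", seq_len(ncol(W)))
    X <- cbind(X, W)
  }
  qrX <- qr(X)
  stopIfNot(qrX$rank == ncol(X), "design matrix is not of full column rank")
  attr(X, "genotypeCoefs") <- intersect(colnames(X), gl[-1L])
  X
}

#' Fit per-gene negative-binomial GLMs and test genotype contrasts
#'
#' Estimates gene-wise dispersions by adjusted-profile-likelihood
#' maximisation with empirical-Bayes shrinkage towards the mean-dispersion
#' trend, fits NB GLMs with a log link and effective-library-size offset,
#' and runs likelihood-ratio tests for each genotype coefficient against the
#' baseline plus the joint (ANOVA-type) test over all genotype coefficients.
#' Fractional pseudo-aligner counts are used as-is. P-values are
#' Benjamini-Hochberg adjusted per contrast; a gene is flagged DE when its
#' FDR-adjusted p-value is below \code{alpha}.
#'
#' @param se Normalised gene-level \code{SummarizedExperiment}.
#' @param design Design matrix from \code{\link{designMatrix}}.
#' @param contrasts Coefficient names to test; defaults to the genotype
#'   coefficients recorded on the design.
#' @param priorDF Prior degrees of freedom for dispersion shrinkage
#'   (default 10).
#' @param test \code{"lrt"} for likelihood-ratio tests (default) or
#'   \code{"ql"} for quasi-likelihood F-tests.
#' @param alpha FDR threshold for the DE flag.
#' @return A \linkS4class{DEResult}.
#' @export
fitDE <- function(se, design, contrasts = NULL, priorDF = 10,
                  test = c("lrt", "ql"), alpha = 0.05) {
  test <- match.arg(test)
  counts <- SummarizedExperiment::assay(se, "counts")
  cd <- SummarizedExperiment::colData(se)
  stopIfNot(nrow(design) == ncol(counts), "design/sample mismatch")
  stopIfNot(ncol(counts) > ncol(design),
            "need more samples than coefficients")
  if (is.null(contrasts)) contrasts <- attr(design, "genotypeCoefs")
  stopIfNot(length(contrasts) >= 1L && all(contrasts %in% colnames(design)),
            "contrasts must name design columns")

  y <- edgeR::DGEList(counts = counts,
                      lib.size = cd$lib_size,
                      norm.factors = cd$norm_factor)
  y <- edgeR::estimateDisp(y, design, prior.df = priorDF)
  fit <- if (test == "ql") edgeR::glmQLFit(y, design) else
    edgeR::glmFit(y, design)

  testOne <- function(coefs) {
    res <- if (test == "ql") edgeR::glmQLFTest(fit, coef = coefs) else
      edgeR::glmLRT(fit, coef = coefs)
    tab <- res$table
    tab$PValue[!is.finite(tab$PValue)] <- 1  # non-convergent: conservative
    tab
  }

  tabs <- lapply(contrasts, function(ct) {
    tab <- testOne(ct)
    fdr <- p.adjust(tab$PValue, method = "BH")
    data.frame(gene = rownames(tab), contrast = ct, logFC = tab$logFC,
               logCPM = tab$logCPM, PValue = tab$PValue, FDR = fdr,
               DE = fdr < alpha, stringsAsFactors = FALSE, row.names = NULL)
  })
  table <- do.call(rbind, tabs)

  jt <- testOne(contrasts)
  joint <- data.frame(gene = rownames(jt), PValue = jt$PValue,
                      FDR = p.adjust(jt$PValue, method = "BH"),
                      stringsAsFactors = FALSE, row.names = NULL)

  new("DEResult", table = table, joint = joint, design = unclass(design),
      dispersion = structure(y$tagwise.dispersion, names = rownames(counts)),
      contrasts = contrasts)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment, monotone and capped at 1. Thin wrapper kept as an
#' explicit pipeline operation.
#'
#' @param p Numeric vector of p-values in [0, 1]; NaN is an error.
#' @return Adjusted p-values.
#' @export
adjustBH <- function(p) {
  stopIfNot(!anyNA(p), "p-values must not contain NA/NaN")
  stopIfNot(all(p >= 0 & p <= 1), "p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}
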