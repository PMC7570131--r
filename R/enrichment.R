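#' Rank genes for preranked GSEA
#'
#' Ranking statistic: sign(logFC) times -log10(p). Genes are sorted
#' decreasing with ties broken by gene identifier, giving a stable total
#' order. Zero p-values are capped at a configurable magnitude.
#'
#' @param de A \linkS4class{DEResult}.
#' @param contrast Contrast name.
#' @param cap Magnitude cap applied when p underflows to 0 (default 300).
#' @return Named numeric vector sorted decreasing, with attributes
#'   \code{contrast} and \code{metric}.
#' @export
rankGenes <- function(de, contrast, cap = 300) {
  tab <- deTable(de, contrast)
  if (any(tab$PValue == 0)) {
    message(sum(tab$PValue == 0),
            " zero p-value(s); ranking statistic capped at ", cap)
  }
  stat <- sign(tab$logFC) * pmin(-log10(tab$PValue), cap)
  ord <- order(-stat, tab$gene)
  out <- structure(stat[ord], names = tab$gene[ord])
  attr(out, "contrast") <- contrast
  attr(out, "metric") <- "signed -log10(p)"
  out
}

## ---------------------------------------------------------------------------
## Shared linear-model machinery: QR effects decomposition for one tested
## coefficient, moderated t via empirical-Bayes variance shrinkage, and the
## residual effect matrix used both for the competitive test's inter-gene
## correlation and for rotations.
## ---------------------------------------------------------------------------
lmEffects <- function(E, design, contrast) {
  E <- as.matrix(E)
  design <- as.matrix(design)
  n <- ncol(E); G <- nrow(E); p <- ncol(design)
  stopIfNot(nrow(design) == n, "design/sample mismatch")
  if (is.character(contrast)) {
    ci <- match(contrast, colnames(design))
    stopIfNot(!is.na(ci), "contrast '", contrast, "' not in design")
  } else ci <- as.integer(contrast)
  d <- n - p
  stopIfNot(d >= 1L, "no residual degrees of freedom")
  ## move the tested coefficient to the last position so its effect is the
  ## p-th orthogonal component
  design <- design[, c(seq_len(p)[-ci], ci), drop = FALSE]
  QR <- qr(design)
  stopIfNot(QR$rank == p, "design matrix is not of full rank")
  eff <- qr.qty(QR, t(E))              # n x G
  unscaled <- eff[p, ]
  if (QR$qr[p, p] < 0) unscaled <- -unscaled
  U <- eff[(p + 1):n, , drop = FALSE]  # d x G residual effects
  sigma2 <- colMeans(U^2)
  ## genes with no variation beyond numerical noise carry no evidence
  degenerate <- (unscaled^2 + d * sigma2) <= rowSums(E^2) * 1e-20
  sv <- limma::squeezeVar(sigma2, df = d)
  modt <- unscaled / sqrt(pmax(sv$var.post, 1e-300))
  modt[degenerate] <- 0
  dfTotal <- min(d + sv$df.prior, G * d)
  z <- limma::zscoreT(modt, df = dfTotal, approx = TRUE, method = "hill")
  z[!is.finite(z)] <- 0
  list(unscaled = unscaled, U = U, sigma2 = sigma2,
       varPost = sv$var.post, varPrior = sv$var.prior,
       dfPrior = sv$df.prior, dfResidual = d, dfTotal = dfTotal,
       modt = modt, z = z, G = G, degenerate = degenerate)
}

## Map gene-set members to row positions of a statistic vector/matrix,
## dropping sets with no overlap (with a message).
setIndexList <- function(gsc, ids) {
  idx <- lapply(geneSets(gsc), function(members) {
    i <- match(members, ids)
    i[!is.na(i)]
  })
  empty <- lengths(idx) == 0L
  if (any(empty)) {
    message(sum(empty), " set(s) disjoint from the universe skipped: ",
            paste(head(names(idx)[empty], 5L), collapse = ", "))
  }
  idx[!empty]
}

## ---------------------------------------------------------------------------
## Competitive test (camera-style): moderated t -> z, per-set inter-gene
## residual correlation, VIF-inflated two-sample test.
## ---------------------------------------------------------------------------
competitiveState <- function(E, design, contrast) {
  le <- lmEffects(E, design, contrast)
  norms <- sqrt(colSums(le$U^2))
  unitU <- sweep(le$U, 2L, pmax(norms, 1e-300), `/`)  # unit-norm gene columns
  list(z = le$z, unitU = unitU, G = le$G,
       dfCamera = min(le$dfResidual, le$G - 2L),
       meanStat = mean(le$z), varStat = var(le$z))
}

competitiveFromState <- function(state, idx, useVIF = TRUE,
                                 allowNegCor = TRUE) {
  G <- state$G
  out <- data.frame(set = names(idx), size = lengths(idx),
                    correlation = NA_real_, vif = 1, stat = NA_real_,
                    direction = NA_character_, PValue = NA_real_,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (i in seq_along(idx)) {
    s <- idx[[i]]
    m <- length(s); m2 <- G - m
    vif <- 1; correlation <- 0
    if (m > 1L && useVIF) {
      colSumU <- rowSums(state$unitU[, s, drop = FALSE])
      vif <- sum(colSumU^2) / m
      correlation <- (vif - 1) / (m - 1)
      if (!allowNegCor) vif <- max(1, vif)
    }
    meanIn <- mean(state$z[s])
    delta <- G / m2 * (meanIn - state$meanStat)
    varPooled <- ((G - 1) * state$varStat - delta^2 * m * m2 / G) / (G - 2)
    tstat <- delta / sqrt(varPooled * (vif / m + 1 / m2))
    pLow <- pt(tstat, df = state$dfCamera)
    pHigh <- pt(tstat, df = state$dfCamera, lower.tail = FALSE)
    out$correlation[i] <- correlation
    out$vif[i] <- vif
    out$stat[i] <- meanIn
    out$direction[i] <- if (pHigh <= pLow) "Up" else "Down"
    out$PValue[i] <- max(2 * min(pLow, pHigh), .Machine$double.xmin)
  }
  out$PValue <- pmin(out$PValue, 1)
  out
}

#' Competitive gene-set test adjusted for inter-gene correlation
#'
#' Tests whether a set's genes carry more differential-expression signal
#' than genes outside the set. Per-gene moderated t statistics (linear model
#' on logCPM, empirical-Bayes variance shrinkage) are transformed to z; each
#' set's mean inter-gene residual correlation is estimated from the
#' row-standardised residual effects, giving a variance inflation factor
#' VIF = 1 + (m - 1) * rho-bar for the two-sided two-sample comparison of
#' set versus non-set z means.
#'
#' @param E Genes x samples logCPM matrix.
#' @param design Design matrix.
#' @param contrast Tested coefficient (column name of \code{design}).
#' @param gsc A \linkS4class{GeneSetCollection} (restricted to the universe).
#' @param useVIF Apply the correlation adjustment (default TRUE; FALSE gives
#'   the uncorrected two-sample z test, for calibration studies only).
#' @param allowNegCor Allow VIF < 1 from negative estimated correlations
#'   (default TRUE, the plain VIF formula, which is calibrated under
#'   independence; FALSE clips VIF at 1, which is mildly conservative).
#' @return data.frame with per-set size, estimated correlation, VIF, mean
#'   set statistic, direction and two-sided p-value.
#' @export
competitiveTest <- function(E, design, contrast, gsc, useVIF = TRUE,
                            allowNegCor = TRUE) {
  stopIfNot(nrow(E) >= 3L, "need at least 3 genes")
  state <- competitiveState(E, design, contrast)
  idx <- setIndexList(gsc, rownames(E))
  competitiveFromState(state, idx, useVIF = useVIF,
                       allowNegCor = allowNegCor)
}

## ---------------------------------------------------------------------------
## Self-contained rotation test: the tested coefficient's orthogonal effect
## plus the residual effects form a (d+1)-vector per gene that is spherically
## symmetric under the null; random unit vectors rotate all genes jointly,
## preserving inter-gene correlation. Moderated t is recomputed per rotation
## with the shrinkage hyperparameters frozen at their observed values.
## ---------------------------------------------------------------------------
rotationState <- function(E, design, contrast, nRot = 9999L, seed = NULL) {
  if (nRot < 99L) warning("fewer than 99 rotations gives a very coarse p")
  le <- lmEffects(E, design, contrast)
  d <- le$dfResidual
  Z <- rbind(le$unscaled, le$U)          # (d+1) x G
  Z2 <- colSums(Z^2)
  d0 <- le$dfPrior; s02 <- le$varPrior
  Tr <- withSeed(seed, {
    R <- matrix(rnorm(nRot * (d + 1L)), nRot, d + 1L)
    R <- R / sqrt(rowSums(R^2))
    Er <- R %*% Z                        # nRot x G rotated effects
    s2r <- sweep(-(Er^2), 2L, Z2, `+`) / d
    s2post <- if (is.finite(d0)) (d0 * s02 + d * s2r) / (d0 + d) else
      matrix(s02, nrow(s2r), ncol(s2r))
    Tmat <- Er / sqrt(pmax(s2post, 1e-300))
    Tmat[, le$degenerate] <- 0
    Tmat
  })
  tObs <- le$modt
  tObs[!is.finite(tObs)] <- 0
  list(tObs = tObs, Tr = Tr, nRot = as.integer(nRot), ids = rownames(E))
}

rotationFromState <- function(state, idx) {
  out <- data.frame(set = names(idx), size = lengths(idx), stat = NA_real_,
                    direction = NA_character_, nMoreExtreme = NA_integer_,
                    PValue = NA_real_, stringsAsFactors = FALSE,
                    row.names = NULL)
  for (i in seq_along(idx)) {
    s <- idx[[i]]
    obs <- mean(state$tObs[s])
    rot <- rowMeans(state$Tr[, s, drop = FALSE])
    b <- sum(abs(rot) >= abs(obs))
    out$stat[i] <- obs
    out$direction[i] <- if (obs >= 0) "Up" else "Down"
    out$nMoreExtreme[i] <- b
    out$PValue[i] <- (b + 1) / (state$nRot + 1)
  }
  out
}

#' Self-contained gene-set test by Monte-Carlo rotation
#'
#' Tests whether a set shows any coordinated signal for a contrast,
#' ignoring genes outside the set. The observed directional set statistic is
#' the mean of the members' moderated t; the null is generated by random
#' rotations of the joint (effect, residual) space that preserve the fitted
#' nuisance structure and the inter-gene correlation. The two-sided p-value
#' is (b + 1) / (nRot + 1) with b the number of rotations at least as
#' extreme in absolute value.
#'
#' @inheritParams competitiveTest
#' @param nRot Number of random rotations (default 9999).
#' @param seed Integer seed for the rotations.
#' @return data.frame with per-set size, set statistic, direction, number of
#'   more-extreme rotations and p-value.
#' @export
rotationTest <- function(E, design, contrast, gsc, nRot = 9999L,
                         seed = NULL) {
  state <- rotationState(E, design, contrast, nRot = nRot, seed = seed)
  idx <- setIndexList(gsc, rownames(E))
  rotationFromState(state, idx)
}

## ---------------------------------------------------------------------------
## Preranked GSEA: weighted Kolmogorov-Smirnov running sum over the ranked
## list, null by random same-size gene sets drawn from the list.
## ---------------------------------------------------------------------------

## ES from sorted hit positions. absw = |stat|^weight over the whole list.
## Running-sum extrema occur just before / just after hits, so only those 2m
## candidate values are evaluated.
esFromPositions <- function(pos, absw, N) {
  m <- length(pos)
  hitw <- absw[pos]
  NR <- sum(hitw)
  cumhit <- if (NR > 0) cumsum(hitw) / NR else seq_len(m) / m
  missStep <- (pos - seq_len(m)) / (N - m)
  top <- cumhit - missStep
  bottom <- c(0, cumhit[-m]) - missStep
  maxP <- max(top)
  minP <- min(bottom)
  if (maxP > -minP) {
    list(es = maxP, peak = which.max(top), positive = TRUE)
  } else {
    list(es = minP, peak = which.min(bottom), positive = FALSE)
  }
}

gseaState <- function(stats, weight = 1, nPerm = 10000L, sizes = integer(0),
                      seed = NULL) {
  N <- length(stats)
  absw <- abs(stats)^weight
  nullES <- list()
  if (length(sizes)) {
    sizes <- sort(unique(as.integer(sizes)))
    ## null sets are drawn in the canonical (alphabetical) gene order, then
    ## mapped to ranked positions, so a mirrored list (all statistics
    ## negated) sees the same null gene sets and exactly negated null ES
    canonPos <- order(names(stats))
    nullES <- withSeed(seed, {
      lapply(sizes, function(m) {
        vapply(seq_len(nPerm), function(i) {
          pos <- sort.int(canonPos[sample.int(N, m)])
          esFromPositions(pos, absw, N)$es
        }, numeric(1))
      })
    })
    names(nullES) <- as.character(sizes)
  }
  list(stats = stats, absw = absw, N = N, weight = weight,
       nPerm = as.integer(nPerm), nullES = nullES)
}

gseaFromState <- function(state, idx) {
  out <- data.frame(set = names(idx), size = lengths(idx), ES = NA_real_,
                    NES = NA_real_, nMoreExtreme = NA_integer_,
                    PValue = NA_real_, stringsAsFactors = FALSE,
                    row.names = NULL)
  leading <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    pos <- sort.int(idx[[i]])
    m <- length(pos)
    stopIfNot(m < state$N, "set '", names(idx)[i],
              "' covers the whole ranked list")
    e <- esFromPositions(pos, state$absw, state$N)
    null <- state$nullES[[as.character(m)]]
    stopIfNot(!is.null(null), "no null draws cached for set size ", m)
    if (e$positive) {
      same <- null >= 0
      b <- sum(null >= e$es)
    } else {
      same <- null < 0
      b <- sum(null <= e$es)
    }
    nSame <- sum(same)
    out$ES[i] <- e$es
    out$NES[i] <- if (nSame > 0) e$es / mean(abs(null[same])) else NA_real_
    out$nMoreExtreme[i] <- b
    out$PValue[i] <- if (nSame > 0) (b + 1) / (nSame + 1) else 1
    leading[[i]] <- if (e$positive) {
      names(state$stats)[pos[seq_len(e$peak)]]
    } else {
      names(state$stats)[pos[e$peak:m]]
    }
  }
  out$leadingEdge <- I(leading)
  out
}

#' Preranked gene-set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov-style GSEA on a ranked gene list: hits
#' increment the running sum proportionally to |stat|^weight (normalised),
#' misses decrement it by 1/(N - m); the enrichment score ES is the maximal
#' signed deviation. P-values come from random same-size gene sets drawn
#' from the ranked list (two-tailed by ES sign, with the +1 correction on
#' numerator and denominator); NES divides ES by the mean |ES| of same-sign
#' null draws. The leading edge contains the members at or before the ES
#' extremum (at or after it, for negative ES).
#'
#' @param ranked Named statistic vector from \code{\link{rankGenes}}.
#' @param gsc A \linkS4class{GeneSetCollection}.
#' @param nPerm Number of null gene-set draws per set size (default 10000).
#' @param weight GSEA weighting exponent (default 1; 0 gives the classic
#'   rank-only Kolmogorov-Smirnov statistic).
#' @param seed Integer seed for the null draws.
#' @return data.frame with per-set size, ES, NES, number of more-extreme
#'   null draws, p-value and a \code{leadingEdge} list-column.
#' @export
gseaPreranked <- function(ranked, gsc, nPerm = 10000L, weight = 1,
                          seed = NULL) {
  stopIfNot(!anyNA(ranked), "ranking statistics must not contain NA")
  ord <- order(-ranked, names(ranked))
  ranked <- ranked[ord]
  idx <- setIndexList(gsc, names(ranked))
  state <- gseaState(ranked, weight = weight, nPerm = nPerm,
                     sizes = lengths(idx), seed = seed)
  gseaFromState(state, idx)
}
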