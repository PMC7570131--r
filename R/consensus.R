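#' Harmonic mean p-value
#'
#' Combines dependent p-values: HMP = (sum w_i) / (sum w_i / p_i) with
#' positive weights (equal by default, normalised to sum 1). The raw HMP is
#' returned without asymptotic recalibration, as it is FDR-adjusted
#' downstream.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param w Optional positive weights, recycled and normalised to sum 1.
#' @return The harmonic mean p-value (scalar).
#' @examples
#' harmonicMeanP(c(0.01, 0.1, 1))  # 3/111
#' @export
harmonicMeanP <- function(p, w = NULL) {
  stopIfNot(length(p) >= 1L && !anyNA(p), "p must be non-empty without NA")
  stopIfNot(all(p > 0), "p-values of exactly 0 are not combinable")
  stopIfNot(all(p <= 1), "p-values must lie in (0, 1]")
  if (is.null(w)) w <- rep(1, length(p))
  w <- rep_len(w, length(p))
  stopIfNot(all(w > 0), "weights must be positive")
  w <- w / sum(w)
  1 / sum(w / p)
}

#' Build the consensus table across the three enrichment methods
#'
#' Merges the per-set p-values of the rotation, competitive and preranked
#' GSEA tests for one contrast, combines them by the harmonic mean p-value,
#' applies Benjamini-Hochberg adjustment across all sets in the table, and
#' flags significance at \code{alpha}. Sets missing from some methods are
#' excluded with a message; fully inconsistent set universes are an error.
#'
#' @param rotation,competitive,gsea Per-method result data.frames for the
#'   same contrast (from \code{\link{rotationTest}},
#'   \code{\link{competitiveTest}}, \code{\link{gseaPreranked}}).
#' @param weights Optional method weights for the harmonic mean (rotation,
#'   competitive, gsea), equal by default.
#' @param alpha Significance threshold on the FDR-adjusted HMP.
#' @return data.frame with per-set method p-values, \code{hmp},
#'   \code{fdr_hmp}, \code{significant}, \code{direction} (from the rotation
#'   statistic) and the GSEA \code{leadingEdge}.
#' @export
buildConsensus <- function(rotation, competitive, gsea, weights = NULL,
                           alpha = 0.05) {
  shared <- Reduce(intersect, list(rotation$set, competitive$set, gsea$set))
  stopIfNot(length(shared) > 0L,
            "the three methods report disjoint set universes")
  all3 <- unique(c(rotation$set, competitive$set, gsea$set))
  if (length(shared) < length(all3)) {
    message(length(all3) - length(shared),
            " set(s) not reported by all three methods excluded")
  }
  r <- rotation[match(shared, rotation$set), ]
  c2 <- competitive[match(shared, competitive$set), ]
  g <- gsea[match(shared, gsea$set), ]
  hmp <- vapply(seq_along(shared), function(i) {
    harmonicMeanP(c(r$PValue[i], c2$PValue[i], g$PValue[i]), w = weights)
  }, numeric(1))
  fdr <- p.adjust(hmp, method = "BH")
  out <- data.frame(
    set = shared, size = r$size,
    p_rotation = r$PValue, p_competitive = c2$PValue, p_gsea = g$PValue,
    hmp = hmp, fdr_hmp = fdr, significant = fdr < alpha,
    direction = r$direction, stringsAsFactors = FALSE, row.names = NULL)
  out$leadingEdge <- g$leadingEdge
  out[order(out$hmp, out$set), ]
}

#' Leading-edge overlaps among gene sets
#'
#' Computes the sizes of all pairwise and multi-way intersections among
#' leading edges (upset-style), reporting only intersections with at least
#' \code{minShared} genes. Higher-order combinations are grown only from
#' reportable lower-order ones (an intersection can never exceed any of its
#' sub-intersections).
#'
#' @param leadingEdges Named list of leading-edge gene vectors (e.g. from
#'   the consensus table's significant sets).
#' @param minShared Minimum intersection size to report (default 3).
#' @return data.frame with columns \code{sets} (names joined by \code{"+"}),
#'   \code{degree}, \code{size} and a \code{genes} list-column.
#' @export
leadingEdgeOverlap <- function(leadingEdges, minShared = 3L) {
  empty <- data.frame(sets = character(0), degree = integer(0),
                      size = integer(0), stringsAsFactors = FALSE)
  empty$genes <- I(list())
  k <- length(leadingEdges)
  if (k < 2L) return(empty)
  nm <- names(leadingEdges)
  stopIfNot(!is.null(nm) && all(nzchar(nm)), "leading edges must be named")

  rows <- list()
  ## frontier holds combos (index vectors) whose intersections still qualify
  frontier <- list()
  for (pair in utils::combn(k, 2L, simplify = FALSE)) {
    genes <- intersect(leadingEdges[[pair[1L]]], leadingEdges[[pair[2L]]])
    if (length(genes) >= minShared) {
      rows[[length(rows) + 1L]] <- list(idx = pair, genes = genes)
      frontier[[length(frontier) + 1L]] <- list(idx = pair, genes = genes)
    }
  }
  while (length(frontier)) {
    nxt <- list()
    for (node in frontier) {
      last <- max(node$idx)
      for (j in seq_len(k)[-seq_len(last)]) {
        genes <- intersect(node$genes, leadingEdges[[j]])
        if (length(genes) >= minShared) {
          entry <- list(idx = c(node$idx, j), genes = genes)
          rows[[length(rows) + 1L]] <- entry
          nxt[[length(nxt) + 1L]] <- entry
        }
      }
    }
    frontier <- nxt
  }
  if (!length(rows)) return(empty)
  out <- data.frame(
    sets = vapply(rows, function(r) paste(nm[r$idx], collapse = "+"),
                  character(1)),
    degree = vapply(rows, function(r) length(r$idx), integer(1)),
    size = vapply(rows, function(r) length(r$genes), integer(1)),
    stringsAsFactors = FALSE)
  out$genes <- I(lapply(rows, `[[`, "genes"))
  out[order(out$degree, -out$size, out$sets), ]
}
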