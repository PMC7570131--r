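#' Gene set collections
#'
#' An S4 container for named gene sets with per-set provenance labels
#' (e.g. \code{"KEGG"}, \code{"HALLMARK"}, \code{"IRE"}, \code{"custom"}) and
#' an optional testing universe (the filtered gene list). Member identifiers
#' within each set are de-duplicated; set names are unique.
#'
#' @slot sets Named list of character vectors of gene identifiers.
#' @slot provenance Character vector, one label per set.
#' @slot universe Character vector of gene identifiers defining the testing
#'   universe, or \code{character(0)} when unset.
#'
#' @aliases GeneSetCollection-class
#' @export
setClass("GeneSetCollection",
  representation(
    sets = "list",
    provenance = "character",
    universe = "character"
  ),
  prototype(sets = list(), provenance = character(0), universe = character(0))
)

setValidity("GeneSetCollection", function(object) {
  msg <- character(0)
  if (length(object@sets)) {
    if (is.null(names(object@sets)) || anyNA(names(object@sets)) ||
        any(names(object@sets) == "")) {
      msg <- c(msg, "all sets must be named")
    }
    if (anyDuplicated(names(object@sets))) {
      msg <- c(msg, "set names must be unique")
    }
    if (!all(vapply(object@sets, is.character, logical(1)))) {
      msg <- c(msg, "set members must be character vectors")
    }
    if (any(vapply(object@sets, anyDuplicated, integer(1)) > 0L)) {
      msg <- c(msg, "set members must be de-duplicated")
    }
  }
  if (length(object@provenance) != length(object@sets)) {
    msg <- c(msg, "provenance must have one entry per set")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GeneSetCollection
#'
#' @param sets Named list of character vectors of gene identifiers. Duplicate
#'   members within a set are collapsed.
#' @param provenance Character scalar or vector of per-set provenance labels.
#' @param universe Optional character vector of gene identifiers.
#' @return A \linkS4class{GeneSetCollection}.
#' @examples
#' gsc <- GeneSetCollection(list(S1 = c("g1", "g2"), S2 = c("g2", "g3")))
#' geneSets(gsc)
#' @export
GeneSetCollection <- function(sets, provenance = "custom",
                              universe = character(0)) {
  sets <- lapply(sets, function(x) unique(as.character(x)))
  provenance <- rep_len(as.character(provenance), length(sets))
  new("GeneSetCollection", sets = sets, provenance = provenance,
      universe = as.character(universe))
}

#' @describeIn GeneSetCollection List of member identifiers per set.
#' @param x,object A \code{GeneSetCollection}.
#' @export
geneSets <- function(x) x@sets

#' @describeIn GeneSetCollection Per-set provenance labels (named by set).
#' @export
provenance <- function(x) structure(x@provenance, names = names(x@sets))

#' @describeIn GeneSetCollection The testing universe.
#' @export
setUniverse <- function(x) x@universe

#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @export
setMethod("names", "GeneSetCollection", function(x) names(x@sets))

#' @export
setMethod("[[", "GeneSetCollection", function(x, i) x@sets[[i]])

#' @param i Index or set names to keep.
#' @describeIn GeneSetCollection Subset the collection by set.
#' @export
setMethod("[", "GeneSetCollection", function(x, i) {
  new("GeneSetCollection", sets = x@sets[i],
      provenance = structure(x@provenance, names = names(x@sets))[i],
      universe = x@universe)
})

#' @export
setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection with", length(object@sets), "sets\n")
  if (length(object@sets)) {
    sz <- lengths(object@sets)
    cat("  set sizes:", min(sz), "-", max(sz), "\n")
    cat("  provenance:",
        paste(names(table(object@provenance)), collapse = ", "), "\n")
  }
  cat("  universe:", length(object@universe), "genes\n")
})

#' Differential expression results
#'
#' Per-gene negative-binomial GLM test results for each genotype contrast
#' against the wild-type baseline, plus the joint (ANOVA-type) test over all
#' genotype coefficients used for negative-control selection.
#'
#' @slot table data.frame with columns \code{gene}, \code{contrast},
#'   \code{logFC}, \code{logCPM}, \code{PValue}, \code{FDR}, \code{DE}.
#' @slot joint data.frame with columns \code{gene}, \code{PValue}, \code{FDR}
#'   for the joint test of all genotype coefficients.
#' @slot design Numeric design matrix used for the fit.
#' @slot dispersion Named per-gene dispersion estimates.
#' @slot contrasts Character vector of tested coefficient names.
#'
#' @aliases DEResult-class
#' @export
setClass("DEResult",
  representation(
    table = "data.frame",
    joint = "data.frame",
    design = "matrix",
    dispersion = "numeric",
    contrasts = "character"
  )
)

setValidity("DEResult", function(object) {
  msg <- character(0)
  need <- c("gene", "contrast", "logFC", "logCPM", "PValue", "FDR", "DE")
  if (!all(need %in% colnames(object@table))) {
    msg <- c(msg, "table lacks required columns")
  } else {
    p <- object@table$PValue
    if (any(p < 0 | p > 1, na.rm = TRUE)) msg <- c(msg, "p-values outside [0,1]")
    if (any(object@table$FDR < p - 1e-12, na.rm = TRUE)) {
      msg <- c(msg, "FDR must be >= raw p")
    }
  }
  if (!all(c("gene", "PValue", "FDR") %in% colnames(object@joint))) {
    msg <- c(msg, "joint table lacks required columns")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn DEResult Long per-contrast results table (optionally for one
#'   contrast).
#' @param x,object A \code{DEResult}.
#' @param contrast Optional contrast name to subset on.
#' @export
deTable <- function(x, contrast = NULL) {
  tab <- x@table
  if (!is.null(contrast)) {
    stopIfNot(contrast %in% x@contrasts,
              "unknown contrast '", contrast, "'")
    tab <- tab[tab$contrast == contrast, , drop = FALSE]
    rownames(tab) <- tab$gene
  }
  tab
}

#' @describeIn DEResult Joint ANOVA-type test table over all genotype
#'   coefficients.
#' @export
jointTest <- function(x) x@joint

#' @describeIn DEResult Names of the tested contrasts.
#' @export
deContrasts <- function(x) x@contrasts

#' @describeIn DEResult Per-gene dispersion estimates.
#' @export
dispersions <- function(x) x@dispersion

#' @export
setMethod("show", "DEResult", function(object) {
  cat("DEResult:", length(unique(object@table$gene)), "genes,",
      length(object@contrasts), "contrasts\n")
  for (ct in object@contrasts) {
    n <- sum(object@table$DE[object@table$contrast == ct])
    cat(sprintf("  %-12s %d DE genes at FDR < 0.05\n", ct, n))
  }
})
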