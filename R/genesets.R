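#' Read a GMT gene-set file
#'
#' Parses the standard tab-separated GMT dialect (set name, description,
#' member identifiers). Duplicate members within a set are collapsed,
#' preserving first-occurrence order.
#'
#' @param path Path to a GMT file.
#' @param provenance Provenance label attached to every set read.
#' @return A \linkS4class{GeneSetCollection}.
#' @export
readGMT <- function(path, provenance = "custom") {
  stopIfNot(file.exists(path), "GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(GeneSetCollection(list(), provenance))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    stop("malformed GMT line(s) (fewer than 3 fields) at line ",
         paste(bad, collapse = ", "), " of ", path, call. = FALSE)
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  GeneSetCollection(sets, provenance = provenance)
}

#' Write a GeneSetCollection as GMT
#'
#' @param gsc A \linkS4class{GeneSetCollection}.
#' @param path Output path.
#' @param descriptions Optional per-set description column; defaults to the
#'   provenance label.
#' @return Invisibly, \code{path}.
#' @export
writeGMT <- function(gsc, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- provenance(gsc)
  lines <- character(length(gsc))
  sets <- geneSets(gsc)
  for (i in seq_along(sets)) {
    lines[i] <- paste(c(names(sets)[i], descriptions[i], sets[[i]]),
                      collapse = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Map gene-set identifiers to another namespace
#'
#' Replaces each member by all of its targets in a (source, target) mapping
#' table, as when converting human Entrez identifiers to zebrafish Ensembl
#' identifiers via a biomart export. One-to-many expansions are kept; members
#' absent from the mapping are dropped and counted.
#'
#' @param gsc A \linkS4class{GeneSetCollection}.
#' @param mapping A two-column data.frame (source_id, target_id).
#' @param verbose Report the number of dropped members per collection.
#' @return A mapped \linkS4class{GeneSetCollection}; the number of unmapped
#'   members dropped is recorded in the \code{"dropped"} attribute.
#' @export
mapSetIds <- function(gsc, mapping, verbose = TRUE) {
  stopIfNot(is.data.frame(mapping) && ncol(mapping) >= 2L && nrow(mapping) > 0L,
            "mapping must be a non-empty two-column table")
  src <- as.character(mapping[[1L]])
  tgt <- as.character(mapping[[2L]])
  lut <- split(tgt, src)
  dropped <- 0L
  sets <- lapply(geneSets(gsc), function(members) {
    hit <- members %in% names(lut)
    dropped <<- dropped + sum(!hit)
    unique(unlist(lut[members[hit]], use.names = FALSE))
  })
  if (verbose && dropped > 0L) {
    message(dropped, " unmapped member(s) dropped during ID mapping")
  }
  out <- GeneSetCollection(sets, provenance = provenance(gsc),
                           universe = setUniverse(gsc))
  attr(out, "dropped") <- dropped
  out
}

#' Restrict a collection to a testing universe
#'
#' Intersects every set with the universe (typically the filtered gene list)
#' and drops sets that fall below the minimum testable size.
#'
#' @param gsc A \linkS4class{GeneSetCollection}.
#' @param universe Character vector of gene identifiers.
#' @param minSize Minimum post-restriction set size to keep (default 5).
#' @param verbose Report dropped sets.
#' @return A restricted \linkS4class{GeneSetCollection} with its
#'   \code{universe} slot populated.
#' @export
restrictToUniverse <- function(gsc, universe, minSize = 5L, verbose = TRUE) {
  universe <- unique(as.character(universe))
  sets <- lapply(geneSets(gsc), intersect, y = universe)
  keep <- lengths(sets) >= minSize
  if (verbose && any(!keep)) {
    message(sum(!keep), " set(s) below min size ", minSize,
            " after restriction to the universe: ",
            paste(head(names(sets)[!keep], 5L), collapse = ", "),
            if (sum(!keep) > 5L) ", ..." else "")
  }
  GeneSetCollection(sets[keep],
                    provenance = provenance(gsc)[keep],
                    universe = universe)
}
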