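#' Write a simulated experiment as an on-disk fixture tree
#'
#' Emits the file layout the reader side of the pipeline consumes: one
#' kallisto-style \code{abundance.tsv} per sample (columns \code{target_id},
#' \code{length}, \code{eff_length}, \code{est_counts}, \code{tpm}), a
#' transcript-to-gene map, sample metadata, a GMT file of the gene sets, and
#' the simulation truth as JSON.
#'
#' @param dir Output directory (created if needed).
#' @param sim Result of \code{\link{simulateExperiment}}.
#' @return Invisibly, \code{dir}.
#' @export
writeFixture <- function(dir, sim) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  stopIfNot(ok, "cannot create fixture directory: ", dir)
  se <- sim$se
  est <- SummarizedExperiment::assay(se, "est_counts")
  rd <- SummarizedExperiment::rowData(se)
  cd <- SummarizedExperiment::colData(se)

  abdir <- file.path(dir, "abundances")
  for (s in colnames(se)) {
    sdir <- file.path(abdir, s)
    ok <- dir.exists(sdir) || dir.create(sdir, recursive = TRUE)
    stopIfNot(ok, "cannot create sample directory: ", sdir)
    rate <- est[, s] / rd$eff_length
    tab <- data.frame(
      target_id = rd$tx_id,
      length = rd$length,
      eff_length = rd$eff_length,
      est_counts = est[, s],
      tpm = if (sum(rate) > 0) rate / sum(rate) * 1e6 else rate
    )
    f <- file.path(sdir, "abundance.tsv")
    tryCatch(
      write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE),
      error = function(e) stop("failed writing ", f, ": ", conditionMessage(e),
                               call. = FALSE))
  }

  write.table(data.frame(transcript_id = rd$tx_id, gene_id = rd$gene_id),
              file.path(dir, "tx2gene.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(cd),
              file.path(dir, "metadata.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeGMT(sim$sets, file.path(dir, "sets.gmt"))

  truth <- sim$truth
  truthJson <- list(
    deGenes = truth$deGenes,
    perturbedSets = data.frame(
      set = truth$perturbedSets$set,
      contrast = truth$perturbedSets$contrast,
      logFC = truth$perturbedSets$logFC,
      fraction = truth$perturbedSets$fraction
    ),
    genesShifted = lapply(truth$perturbedSets$genesShifted, as.character),
    W = as.list(truth$W),
    libSizes = as.list(truth$libSizes)
  )
  jsonlite::write_json(truthJson, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read kallisto-style per-sample abundance tables
#'
#' Reads \code{<dir>/<sample>/abundance.tsv} for each sample and assembles a
#' transcript-level \code{SummarizedExperiment} of estimated counts.
#' Transcripts are flagged as unspliced when their identifier matches
#' \code{unsplicedPattern}, so the aggregation step can omit them.
#'
#' @param dir Directory holding one sub-directory per sample.
#' @param tx2gene data.frame with columns \code{transcript_id},
#'   \code{gene_id}; must cover every transcript.
#' @param samples Sample names; defaults to the sub-directories of \code{dir}.
#' @param metadata Optional data.frame of sample covariates with a
#'   \code{sample} column; carried into colData.
#' @param unsplicedPattern Regular expression identifying unspliced
#'   transcript identifiers.
#' @return A transcript-level \code{SummarizedExperiment} with assay
#'   \code{est_counts}.
#' @export
readKallisto <- function(dir, tx2gene, samples = NULL, metadata = NULL,
                         unsplicedPattern = "\\.unspliced$") {
  stopIfNot(dir.exists(dir), "abundance directory not found: ", dir)
  if (is.null(samples)) {
    samples <- sort(list.dirs(dir, recursive = FALSE, full.names = FALSE))
  }
  stopIfNot(length(samples) > 0L, "no sample sub-directories under ", dir)
  tabs <- lapply(samples, function(s) {
    f <- file.path(dir, s, "abundance.tsv")
    stopIfNot(file.exists(f), "missing abundance file: ", f)
    read.delim(f, stringsAsFactors = FALSE)
  })
  txIds <- tabs[[1L]]$target_id
  est <- vapply(seq_along(tabs), function(j) {
    tab <- tabs[[j]]
    stopIfNot(identical(tab$target_id, txIds),
              "transcript order differs in sample ", samples[j])
    tab$est_counts
  }, numeric(length(txIds)))
  dimnames(est) <- list(txIds, samples)

  stopIfNot(all(c("transcript_id", "gene_id") %in% colnames(tx2gene)),
            "tx2gene must have transcript_id and gene_id columns")
  hit <- match(txIds, tx2gene$transcript_id)
  if (anyNA(hit)) {
    stop("transcripts with no gene mapping: ",
         paste(head(txIds[is.na(hit)], 10L), collapse = ", "),
         if (sum(is.na(hit)) > 10L) ", ..." else "", call. = FALSE)
  }
  rowdata <- S4Vectors::DataFrame(
    tx_id = txIds,
    gene_id = tx2gene$gene_id[hit],
    unspliced = grepl(unsplicedPattern, txIds),
    length = tabs[[1L]]$length,
    eff_length = tabs[[1L]]$eff_length,
    row.names = txIds)

  coldata <- S4Vectors::DataFrame(sample = samples, row.names = samples)
  if (!is.null(metadata)) {
    stopIfNot("sample" %in% colnames(metadata),
              "metadata must have a 'sample' column")
    m <- match(samples, metadata$sample)
    stopIfNot(!anyNA(m), "metadata missing sample(s): ",
              paste(samples[is.na(m)], collapse = ", "))
    md <- metadata[m, , drop = FALSE]
    for (cn in setdiff(colnames(md), "sample")) {
      v <- md[[cn]]
      coldata[[cn]] <- if (is.character(v)) factor(v) else v
    }
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(est_counts = est), rowData = rowdata, colData = coldata)
}

#' Read a fixture tree written by writeFixture
#'
#' @param dir Fixture directory.
#' @return A list with \code{se} (transcript-level
#'   \code{SummarizedExperiment}), \code{sets}
#'   (\linkS4class{GeneSetCollection}) and \code{truth} (parsed JSON).
#' @export
readFixture <- function(dir) {
  stopIfNot(dir.exists(dir), "fixture directory not found: ", dir)
  metadata <- read.delim(file.path(dir, "metadata.tsv"),
                         stringsAsFactors = FALSE)
  tx2gene <- read.delim(file.path(dir, "tx2gene.tsv"),
                        stringsAsFactors = FALSE)
  se <- readKallisto(file.path(dir, "abundances"), tx2gene = tx2gene,
                     samples = metadata$sample, metadata = metadata)
  sets <- readGMT(file.path(dir, "sets.gmt"), provenance = "simulated")
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  list(se = se, sets = sets, truth = truth)
}

#' Read a plain genes-by-samples count matrix TSV
#'
#' First column gene identifiers, remaining columns one per sample.
#'
#' @param path TSV path.
#' @param metadata Optional sample covariate data.frame with a \code{sample}
#'   column.
#' @return A gene-level \code{SummarizedExperiment} with assay
#'   \code{counts}, colData \code{lib_size} and \code{norm_factor} (1).
#' @export
readCountMatrix <- function(path, metadata = NULL) {
  stopIfNot(file.exists(path), "count matrix not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  counts <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(counts) <- tab[[1L]]
  makeGeneSE(counts, metadata)
}

## Assemble a gene-level SummarizedExperiment with lib sizes / unit factors.
makeGeneSE <- function(counts, metadata = NULL, coldata = NULL) {
  if (is.null(coldata)) {
    coldata <- S4Vectors::DataFrame(sample = colnames(counts),
                                    row.names = colnames(counts))
    if (!is.null(metadata)) {
      m <- match(colnames(counts), metadata$sample)
      stopIfNot(!anyNA(m), "metadata missing sample(s)")
      md <- metadata[m, , drop = FALSE]
      for (cn in setdiff(colnames(md), "sample")) {
        v <- md[[cn]]
        coldata[[cn]] <- if (is.character(v)) factor(v) else v
      }
    }
  }
  coldata$lib_size <- colSums(counts)
  coldata$norm_factor <- rep(1, ncol(counts))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = coldata)
}
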