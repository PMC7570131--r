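## Shared fixture builders for the test suite. Everything is generated in
## code under fixed seeds; nothing is read from disk.

## The emulated 24-sample four-genotype sibling design.
studyDesignTable <- function() {
  data.frame(
    sample = sprintf("s%02d", 1:24),
    genotype = factor(rep(c("wildtype", "eofad", "null", "trans"),
                          c(8, 6, 4, 6)),
                      levels = c("wildtype", "eofad", "null", "trans")),
    sex = factor(rep_len(c("female", "male"), 24)),
    tank = factor(paste0("tank", rep_len(1:3, 24))),
    stringsAsFactors = FALSE)
}

## Gene-level SummarizedExperiment from a counts matrix (+ the study design
## when the sample count matches).
geneSE <- function(counts, meta = NULL) {
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("g%04d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("s%02d", seq_len(ncol(counts)))
  }
  if (is.null(meta) && ncol(counts) == 24L) meta <- studyDesignTable()
  consensusGSA:::makeGeneSE(counts, metadata = meta)
}

## Null NB counts under the study design: no genotype/sex/tank effects.
nullCountsSE <- function(nGenes = 500, mu = 100, phi = 0.1, seed = 1,
                         n = 24) {
  set.seed(seed)
  counts <- matrix(rnbinom(nGenes * n, mu = mu, size = 1 / phi), nGenes, n)
  geneSE(counts)
}

## A small transcript-level simulation; fast enough for unit tests.
smallSim <- function(seed = 1, nGenes = 800, nSets = 15,
                     setSizeRange = c(10, 40), ...) {
  simulateExperiment(simConfig(nGenes = nGenes, nSets = nSets,
                               setSizeRange = setSizeRange, seed = seed,
                               ...))
}

## Random disjoint gene sets over given ids.
randomSets <- function(ids, nSets, size, seed = 1) {
  set.seed(seed)
  pool <- sample(ids)
  sets <- split(pool[seq_len(nSets * size)], rep(seq_len(nSets), each = size))
  names(sets) <- sprintf("rs%03d", seq_len(nSets))
  GeneSetCollection(sets)
}
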