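## Independent brute-force oracles used to verify the pipeline's operations.
## These deliberately re-derive each quantity from its published definition
## with plain loops, sharing no code with the implementation under test.

## Trimmed mean of M-values, straight from the definition: pick the sample
## whose 75th percentile of count/libsize is closest to the mean as
## reference; per sample, compute gene-wise M (log ratio) and A (abundance)
## against the reference with explicit loops, drop trimmed ranks, take the
## inverse-variance weighted mean of M, and rescale factors to geometric
## mean one.
oracleTMM <- function(counts, libs = colSums(counts),
                      logratioTrim = 0.3, sumTrim = 0.05) {
  nsamp <- ncol(counts)
  q75 <- numeric(nsamp)
  for (j in seq_len(nsamp)) {
    q75[j] <- quantile(counts[, j], probs = 0.75) / libs[j]
  }
  ref <- which.min(abs(q75 - mean(q75)))
  f <- numeric(nsamp)
  for (j in seq_len(nsamp)) {
    M <- numeric(0); A <- numeric(0); w <- numeric(0)
    for (g in seq_len(nrow(counts))) {
      o <- counts[g, j]; r <- counts[g, ref]
      pO <- o / libs[j]; pR <- r / libs[ref]
      m <- log2(pO / pR); a <- (log2(pO) + log2(pR)) / 2
      if (is.finite(m) && is.finite(a)) {
        M <- c(M, m); A <- c(A, a)
        w <- c(w, (libs[j] - o) / (libs[j] * o) +
                 (libs[ref] - r) / (libs[ref] * r))
      }
    }
    if (max(abs(M)) < 1e-6) { f[j] <- 1; next }
    n <- length(M)
    loL <- floor(n * logratioTrim) + 1; hiL <- n + 1 - loL
    loS <- floor(n * sumTrim) + 1; hiS <- n + 1 - loS
    keep <- rank(M) >= loL & rank(M) <= hiL &
      rank(A) >= loS & rank(A) <= hiS
    f[j] <- 2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  }
  f / exp(mean(log(f)))
}

## Benjamini-Hochberg by its step-up definition.
oracleBH <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- 1
  for (i in n:1) {
    running <- min(running, p[o[i]] * n / i)
    adj[o[i]] <- running
  }
  adj
}

## GSEA enrichment score by walking the whole ranked list position by
## position (the dense O(N) running sum).
oracleESDense <- function(stats, members, weight = 1) {
  hit <- names(stats) %in% members
  m <- sum(hit)
  N <- length(stats)
  NR <- sum(abs(stats[hit])^weight)
  run <- 0
  best <- 0
  for (i in seq_len(N)) {
    run <- if (hit[i]) {
      run + (if (NR > 0) abs(stats[i])^weight / NR else 1 / m)
    } else {
      run - 1 / (N - m)
    }
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

## Exact two-tailed GSEA p-value by full enumeration of all same-size gene
## sets (feasible only for tiny lists).
oracleESEnumerate <- function(stats, m, weight = 1) {
  apply(combn(length(stats), m), 2L, function(pos) {
    oracleESDense(stats, names(stats)[pos], weight)
  })
}

## Harmonic mean p-value, equal weights.
oracleHMP <- function(p) length(p) / sum(1 / p)

## Rotation gene-set p by explicit QR-based construction: build a full
## random orthogonal matrix per rotation, rotate each gene's joint
## (effect, residual) coefficient vector, and recompute moderated t from
## scratch. Independent RNG stream and no shared code with the package.
oracleRotationP <- function(E, design, contrast, members, nRot = 200,
                            seed = 1) {
  E <- as.matrix(E)
  n <- ncol(E); p <- ncol(design)
  ci <- match(contrast, colnames(design))
  X <- design[, c(seq_len(p)[-ci], ci), drop = FALSE]
  QR <- qr(X)
  Q <- qr.Q(QR, complete = TRUE)
  Zt <- E %*% Q[, p:n, drop = FALSE]       # G x (d+1): effect + residuals
  if (QR$qr[p, p] < 0) Zt[, 1] <- -Zt[, 1]
  d <- n - p
  sigma2 <- rowSums(Zt[, -1, drop = FALSE]^2) / d
  sv <- limma::squeezeVar(sigma2, df = d)
  d0 <- sv$df.prior; s02 <- sv$var.prior
  tFrom <- function(effect, tot2) {
    s2 <- (tot2 - effect^2) / d
    s2post <- if (is.finite(d0)) (d0 * s02 + d * s2) / (d0 + d) else s02
    effect / sqrt(pmax(s2post, 1e-300))
  }
  tot2 <- rowSums(Zt^2)
  rows <- match(members, rownames(E))
  obs <- mean(tFrom(Zt[rows, 1], tot2[rows]))
  set.seed(seed)
  b <- 0L
  for (i in seq_len(nRot)) {
    O <- qr.Q(qr(matrix(rnorm((d + 1)^2), d + 1)))
    eff <- as.numeric(Zt %*% O[, 1])
    stat <- mean(tFrom(eff[rows], tot2[rows]))
    if (abs(stat) >= abs(obs)) b <- b + 1L
  }
  (b + 1) / (nRot + 1)
}

## Adjusted profile likelihood for a single gene's NB dispersion, maximised
## by grid search. Fits the GLM at each fixed dispersion with MASS and adds
## the Cox-Reid adjustment.
oracleCommonDispersion <- function(y, X, offset,
                                   grid = exp(seq(log(1e-4), log(4),
                                                  length.out = 600))) {
  apl <- vapply(grid, function(phi) {
    fit <- suppressWarnings(glm.fit(
      X, y, family = MASS::negative.binomial(theta = 1 / phi),
      offset = offset))
    mu <- fit$fitted.values
    ll <- sum(dnbinom(round(y), size = 1 / phi, mu = mu, log = TRUE))
    W <- diag(mu / (1 + phi * mu))
    cr <- 0.5 * determinant(t(X) %*% W %*% X, logarithm = TRUE)$modulus
    ll - as.numeric(cr)
  }, numeric(1))
  grid[which.max(apl)]
}
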