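# Small in-code fixtures shared across test files.

# CallMatrix for one marker from per-state counts
rowFromCounts <- function(nAA = 0, nAB = 0, nBB = 0, nNN = 0, nNC = 0) {
  rep(c("AA", "AB", "BB", "NN", "NC"), c(nAA, nAB, nBB, nNN, nNC))
}

callMatrixFromRows <- function(rows, groups = NULL) {
  calls <- do.call(rbind, rows)
  rownames(calls) <- names(rows) %||% sprintf("M%02d", seq_along(rows))
  colnames(calls) <- sprintf("S%02d", seq_len(ncol(calls)))
  IntroMap::CallMatrix(calls, groups)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# DhPopulation from a character matrix given as rows of strings like "AB-A"
dhFromStrings <- function(strs) {
  rows <- lapply(strs, function(s) {
    v <- strsplit(s, "")[[1]]
    v[v == "-"] <- NA
    v
  })
  calls <- do.call(rbind, rows)
  rownames(calls) <- names(strs) %||% sprintf("M%02d", seq_along(strs))
  colnames(calls) <- sprintf("L%03d", seq_len(ncol(calls)))
  IntroMap::DhPopulation(calls)
}

# rf container from a plain symmetric matrix (order/ripple tests)
rfFromMatrix <- function(r) {
  dimnames(r) <- list(sprintf("M%02d", seq_len(nrow(r))),
                      sprintf("M%02d", seq_len(nrow(r))))
  list(r = r, n = matrix(100, nrow(r), ncol(r), dimnames = dimnames(r)),
       R = round(r * 100))
}

# rf matrix consistent with true positions plus optional noise
rfFromPositions <- function(pos, noise = 0, seed = 1) {
  d <- abs(outer(pos, pos, "-"))
  r <- IntroMap::inverseKosambi(d)
  if (noise > 0) {
    set.seed(seed)
    eps <- matrix(stats::rnorm(length(r), 0, noise), nrow(r))
    eps <- (eps + t(eps)) / 2
    r <- pmin(pmax(r + eps, 0), 0.49)
    diag(r) <- 0
  }
  rfFromMatrix(r)
}
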