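# Independent brute-force oracles used for dual-route checks. These stay
# deliberately naive (loops, no shared code with the package internals).

# strip names and bookkeeping attributes for value-only comparisons
bare <- function(m) {
  attributes(m) <- list(dim = dim(m))
  m
}

# entrywise double-loop Pearson between all row pairs
oraclePairwiseCor <- function(x) {
  n <- nrow(x)
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      out[i, j] <- stats::cor(x[i, ], x[j, ])
    }
  }
  out
}

# exhaustive priority-flood watershed: seeds at local minima (plateau-
# connected minima merged), then repeatedly flood the unlabeled vertex
# adjacent to labeled territory with the smallest (value, index)
oracleWatershed <- function(values, rings) {
  V <- length(values)
  ismin <- vapply(seq_len(V), function(v) all(values[rings[[v]]] >= values[v]),
                  TRUE)
  label <- rep(NA_integer_, V)
  nb <- 0L
  for (v in seq_len(V)) {
    if (!ismin[v] || !is.na(label[v])) next
    nb <- nb + 1L
    queue <- v
    label[v] <- nb
    while (length(queue)) {
      u <- queue[1]
      queue <- queue[-1]
      for (w in rings[[u]]) {
        if (ismin[w] && is.na(label[w]) && values[w] == values[u]) {
          label[w] <- nb
          queue <- c(queue, w)
        }
      }
    }
  }
  repeat {
    unl <- which(is.na(label))
    if (!length(unl)) break
    adj <- unl[vapply(unl, function(v) any(!is.na(label[rings[[v]]])), TRUE)]
    if (!length(adj)) break
    u <- adj[order(values[adj], adj)][1]
    labs <- label[rings[[u]]]
    labs <- unique(labs[!is.na(labs) & labs > 0])
    label[u] <- if (length(labs) == 1L) labs else 0L
  }
  list(labels = label, boundary = label == 0L, nBasins = nb)
}

# direct comparison-counting differential power
oracleDp <- function(vals) {
  n <- dim(vals)[1]
  nC <- dim(vals)[3]
  per <- matrix(0, n, nC)
  for (i in seq_len(n)) {
    for (v in seq_len(nC)) {
      cnt <- 0
      for (j in seq_len(n)) {
        if (j == i) next
        if (vals[i, i, v] < vals[i, j, v]) cnt <- cnt + 1
        if (vals[i, i, v] < vals[j, i, v]) cnt <- cnt + 1
      }
      if (cnt == 0) cnt <- 0.5
      per[i, v] <- -log(cnt / (2 * (n - 1)))
    }
  }
  list(perSubject = per, population = colSums(per))
}

# closed-form normal-equation simple OLS
oracleOls <- function(x, y) {
  alpha <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  beta <- mean(y) - alpha * mean(x)
  c(alpha = alpha, beta = beta)
}

# paired-cohort tensor from two named LGM sets over all centres
pairedTensor <- function(set1, set2, mesh, ...) {
  buildLcmTensor(set1, set2, mesh, ...)
}

# random LcmTensor with given dimensions
randomTensor <- function(nT, nB, nC, seed, targetIds = sprintf("s%02d", seq_len(nT)),
                         baseIds = sprintf("s%02d", seq_len(nB))) {
  set.seed(seed)
  new("LcmTensor",
      values = array(stats::runif(nT * nB * nC, -1, 1), c(nT, nB, nC)),
      centers = seq_len(nC), r = 1L, deformable = FALSE,
      targetIds = targetIds, baseIds = baseIds,
      flags = array(FALSE, c(nT, nB, nC)))
}
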