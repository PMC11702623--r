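## Vertex-wise contributions to identification: uniqueness (OLS residual of
## inter- on intra-individual variability) and differential power (a rank
## statistic of self- vs cross-subject local correlations).

# square paired-cohort tensor check: entry (i, j, v) is the LCM between
# subject i's target-session map and subject j's base-session map
checkPaired <- function(tensor) {
  d <- dim(tensor@values)
  if (d[1] != d[2] || !identical(tensor@targetIds, tensor@baseIds))
    stop("need a paired cohort tensor: square, same subject order on both axes")
  d
}

#' Mean intra-individual local correlation map
#'
#' Average of the diagonal (self-pair) maps: how similar each subject's two
#' sessions are, per centre.
#'
#' @param tensor a paired-cohort [LcmTensor-class] (n x n x centres)
#' @return numeric per-centre map
#' @export
meanIntra <- function(tensor) {
  d <- checkPaired(tensor)
  n <- d[1]
  acc <- numeric(d[3])
  for (i in seq_len(n)) acc <- acc + tensor@values[i, i, ]
  acc / n
}

#' Mean inter-individual local correlation map
#'
#' Average of the n(n-1) cross-pair maps: how similar different subjects
#' are, per centre.
#'
#' @param tensor a paired-cohort [LcmTensor-class] with n >= 2
#' @return numeric per-centre map
#' @export
meanInter <- function(tensor) {
  d <- checkPaired(tensor)
  n <- d[1]
  if (n < 2) stop("need n >= 2 subjects")
  acc <- numeric(d[3])
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) acc <- acc + tensor@values[i, j, ]
  }
  acc / (n * (n - 1))
}

#' Uniqueness map
#'
#' Regresses the inter-individual variability \eqn{y(v) = 1 - C_{inter}(v)}
#' on the intra-individual variability \eqn{x(v) = 1 - C_{intra}(v)} by
#' ordinary least squares across centres; the residual
#' \eqn{U(v) = y(v) - \alpha x(v) - \beta} is highest where subjects differ
#' from each other while agreeing with themselves across sessions.
#'
#' @param tensor a paired-cohort [LcmTensor-class] with n >= 2
#' @return list with `U` (per-centre residuals), `alpha` (slope), `beta`
#'   (intercept), `cIntra`, `cInter`
#' @export
uniquenessMap <- function(tensor) {
  cIntra <- meanIntra(tensor)
  cInter <- meanInter(tensor)
  x <- 1 - cIntra
  y <- 1 - cInter
  if (stats::sd(x) == 0) stop("constant intra-individual variability: slope undefined")
  fit <- stats::lm.fit(cbind(1, x), y)
  beta <- unname(fit$coefficients[1])
  alpha <- unname(fit$coefficients[2])
  list(U = y - alpha * x - beta, alpha = alpha, beta = beta,
       cIntra = cIntra, cInter = cInter)
}

#' Differential power maps
#'
#' For subject i at centre v, counts how often a cross-subject correlation
#' beats the self-correlation: \eqn{c_1 = \#\{j \ne i : C_{ii}(v) < C_{ij}(v)\}}
#' (base-to-target direction) and \eqn{c_2 = \#\{j \ne i : C_{ii}(v) < C_{ji}(v)\}}
#' (target-to-base), then
#' \eqn{DP_i(v) = -\ln[(c_1 + c_2) / (2(N-1))]}. A zero count is replaced by
#' 0.5 before dividing (continuity correction), capping the map at
#' \eqn{-\ln(0.5 / (2(N-1)))} instead of infinity. The population map is the
#' sum over subjects. Strictly increasing transforms of the correlations at
#' a centre leave DP unchanged (it is a rank statistic).
#'
#' @param tensor a paired-cohort [LcmTensor-class] with n >= 2
#' @return list with `perSubject` (n x centres matrix) and `population`
#'   (per-centre sums)
#' @export
differentialPower <- function(tensor) {
  d <- checkPaired(tensor)
  n <- d[1]
  if (n < 2) stop("need n >= 2 subjects")
  nC <- d[3]
  per <- matrix(0, n, nC)
  for (i in seq_len(n)) {
    self <- tensor@values[i, i, ]
    cnt <- numeric(nC)
    for (j in seq_len(n)) {
      if (j == i) next
      cnt <- cnt + (self < tensor@values[i, j, ]) + (self < tensor@values[j, i, ])
    }
    cnt[cnt == 0] <- 0.5
    per[i, ] <- -log(cnt / (2 * (n - 1)))
  }
  list(perSubject = per, population = colSums(per))
}

#' Per-network mean and standard deviation of a vertex map
#'
#' @param map per-centre (or per-vertex) values
#' @param labels network id per entry of `map`
#' @return data.frame with columns `network`, `mean`, `sd`, `n`; networks
#'   with no members are absent (reported missing, not zero)
#' @export
networkSummary <- function(map, labels) {
  map <- asMapValues(map)
  if (length(map) != length(labels)) stop("map and labels lengths differ")
  nets <- sort(unique(labels))
  data.frame(
    network = nets,
    mean = vapply(nets, function(g) mean(map[labels == g]), 0),
    sd = vapply(nets, function(g) stats::sd(map[labels == g]), 0),
    n = vapply(nets, function(g) sum(labels == g), 0L)
  )
}

#' Average contribution maps across cohorts
#'
#' Thin wrapper: arithmetic mean of per-centre maps (uniqueness or DP)
#' computed on separate cohorts/datasets.
#'
#' @param maps list of equal-length numeric maps
#' @return numeric mean map
#' @export
averageMaps <- function(maps) {
  if (!length(maps)) stop("no maps given")
  lens <- lengths(maps)
  if (length(unique(lens)) != 1) stop("maps must have equal length")
  Reduce(`+`, lapply(maps, asMapValues)) / length(maps)
}
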