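# Sharing between QTL classes: Storey pi0 with bootstrap lambda
# selection, the minimum-p order-statistic transform for two-phenotype
# association, and closed-form overlap arithmetic.

#' Storey pi0 estimate with bootstrap lambda selection
#'
#' Estimates the proportion of tests generated under the null from a
#' p-value distribution: pi0(lambda) = #\{p > lambda\} / (m (1 - lambda))
#' over a lambda grid, with the tuning parameter chosen to minimize the
#' bootstrap mean squared error against the plug-in minimum over the
#' grid (the Storey-Tibshirani 2003 bootstrap variant).  1 - pi0
#' estimates the fraction of true associations while accounting for
#' incomplete power.
#'
#' @param p p-values in [0, 1] (>= 50 of them).
#' @param lambda grid in [0, 1) (default 0, 0.05, ..., 0.95).
#' @param nBootstrap bootstrap resamples (default 100).
#' @param seed RNG seed.
#' @return A \linkS4class{Pi0Estimate}.
#' @examples
#' est <- pi0Storey(runif(5000), seed = 1)
#' pi0(est)
#' @export
pi0Storey <- function(p, lambda = seq(0, 0.95, by = 0.05),
                      nBootstrap = 100L, seed = 1L) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p <- p[!is.na(p)]
  m <- length(p)
  if (m < 50L) stop("need at least 50 p-values")
  if (any(lambda < 0 | lambda >= 1)) stop("lambda grid must lie in [0, 1)")
  plugin <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  minPi0 <- min(plugin)
  set.seed(as.integer(seed))
  boot <- matrix(NA_real_, nBootstrap, length(lambda))
  for (b in seq_len(nBootstrap)) {
    pb <- p[sample.int(m, m, replace = TRUE)]
    boot[b, ] <- vapply(lambda, function(l) mean(pb > l) / (1 - l),
                        numeric(1))
  }
  mse <- colMeans((boot - minPi0)^2)
  sel <- which.min(mse)
  pi0Hat <- min(max(plugin[sel], 0), 1)
  ci <- pmin(pmax(stats::quantile(boot[, sel], c(0.025, 0.975),
                                  names = FALSE), 0), 1)
  new("Pi0Estimate", lambda = lambda, pi0Lambda = plugin,
      selectedLambda = lambda[sel], pi0 = pi0Hat, ci = ci,
      nBootstrap = as.integer(nBootstrap))
}

#' Minimum-p transform for joint two-phenotype association
#'
#' When the stronger of two independent association tests is selected
#' per variant (e.g. decay rate or chromatin sensitivity), the minimum
#' of two independent uniform p-values is no longer uniform; the
#' order-statistic CDF restores uniformity under the joint null:
#' p_combined = 1 - (1 - min(p_a, p_b))^2.  This closed form is the
#' unique monotone transform of the minimum that is exactly uniform
#' when both inputs are independent U(0, 1).
#'
#' @param pA,pB p-value vectors in [0, 1] (recycled).
#' @return combined p-values in [0, 1].
#' @examples
#' minPTransform(0.5, 0.9)  # 0.75
#' @export
minPTransform <- function(pA, pB) {
  if (any(pA < 0 | pA > 1, na.rm = TRUE) ||
      any(pB < 0 | pB > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  1 - (1 - pmin(pA, pB))^2
}

#' Expected chance overlap between two QTL classes
#'
#' Hypergeometric expectation n_a * n_b / n_total for the overlap of
#' two sets drawn from the same universe, with its nearest-integer
#' rounding and, when an observed overlap is supplied, the upper-tail
#' hypergeometric significance of the excess.
#'
#' @param nA,nB set sizes; `nTotal` universe size.
#' @param observed optional observed overlap count.
#' @return list: `expected`, `rounded`, and `p` (NA without
#'   `observed`).
#' @examples
#' expectedOverlap(171, 168, 1147, observed = 33)
#' @export
expectedOverlap <- function(nA, nB, nTotal, observed = NULL) {
  if (nTotal <= 0) stop("nTotal must be positive")
  if (nA > nTotal || nB > nTotal) stop("set sizes cannot exceed nTotal")
  expected <- nA * nB / nTotal
  p <- NA_real_
  if (!is.null(observed)) {
    if (observed > min(nA, nB)) stop("observed overlap exceeds set sizes")
    p <- stats::phyper(observed - 1, nA, nTotal - nA, nB,
                       lower.tail = FALSE)
  }
  list(expected = expected, rounded = round(expected), p = p)
}

#' Fraction of a universe covered by the union of two sets
#'
#' (n_a + n_b - n_overlap) / n_total, reported as a percentage to one
#' decimal -- e.g. the share of eQTLs also classified as rdQTLs and/or
#' dsQTLs.
#'
#' @param nA,nB set sizes; `nOverlap` their intersection; `nTotal`
#'   universe size.
#' @return list: `fraction` (in [0, 1]) and `percent` (one decimal).
#' @examples
#' unionFraction(171, 168, 33, 1147)$percent  # 26.7
#' @export
unionFraction <- function(nA, nB, nOverlap, nTotal) {
  if (nTotal <= 0) stop("nTotal must be positive")
  if (nOverlap > min(nA, nB))
    stop("overlap cannot exceed either set size")
  if (nA + nB - nOverlap > nTotal)
    stop("union cannot exceed nTotal")
  frac <- (nA + nB - nOverlap) / nTotal
  list(fraction = frac, percent = round(100 * frac, 1))
}
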