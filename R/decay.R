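# Decay-rate estimation from the transcription-arrest time course.
#
# First-order decay, m(t) = m(0) * 2^(-k_abs t), becomes linear on the
# log2 scale.  Because an equal RNA mass is hybridized at every time
# point, the observed intensities are y(t) = B0 - k t + e with
# k = k_abs - lambda_bar the decay rate *relative* to the mean cellular
# rate: k = 0 means the transcript decays exactly at the cell-wide
# average.  Each gene x individual profile is fit by ordinary least
# squares over the time points.

#' Fit a relative decay rate to one expression profile
#'
#' OLS of log2 intensity on time.  The decay rate is minus the slope
#' (positive k = faster than the mean cellular rate), with standard
#' error from the residual variance and a two-sided t-test on the slope
#' (n - 2 degrees of freedom).  A zero-residual profile is flagged
#' `exact` with se = 0 and p = 0 (or p = 1 when also flat).
#'
#' @param log2Values numeric, one intensity per time point.
#' @param timePointsH hours, same length (>= 3).
#' @return list: `k`, `se`, `p`, `b0` (intercept), `exact`.
#' @examples
#' fitDecayRate(10 - 0.5 * c(0, 0.5, 1, 2, 4), c(0, 0.5, 1, 2, 4))
#' @export
fitDecayRate <- function(log2Values, timePointsH) {
  if (length(timePointsH) < 3L)
    stop("need at least 3 time points to fit a decay rate")
  if (length(log2Values) != length(timePointsH))
    stop("one intensity per time point required")
  if (any(!is.finite(log2Values)) || any(!is.finite(timePointsH)))
    stop("values and time points must be finite")
  f <- .rowOLSvec(timePointsH, matrix(log2Values, 1L))
  list(k = -f$beta, se = f$se, p = f$p, b0 = f$intercept,
       exact = isTRUE(f$exact))
}

#' Fit decay rates for every gene and individual
#'
#' Applies the per-profile OLS fit across the whole cube in one
#' vectorized pass.  Profiles that cannot be fit (missing values
#' leaving < 3 time points) are recorded as NA and counted in the
#' `"nFailed"` attribute.
#'
#' @param de a gene-level \linkS4class{DecayExperiment}.
#' @return A \linkS4class{DecayMatrix} (genes x individuals) with
#'   assays `k`, `se`, `p`, `b0`, `exact`; the per-gene median k is
#'   available through [medianDecay()].
#' @export
fitDecayMatrix <- function(de) {
  stopifnot(is(de, "DecayExperiment"))
  if (de@featureLevel != "gene")
    stop("aggregate probes to genes before fitting decay rates")
  arr <- .cubeArray(de)
  tps <- attr(arr, "time_h")
  if (length(tps) < 3L) stop("need at least 3 time points")
  G <- dim(arr)[1]; N <- dim(arr)[2]
  flat <- matrix(arr, nrow = G * N)     # rows: gene within individual
  f <- .rowOLS(matrix(tps, G * N, length(tps), byrow = TRUE), flat)
  shape <- function(v) matrix(v, G, N,
    dimnames = list(dimnames(arr)[[1]], dimnames(arr)[[2]]))
  k <- shape(-f$beta)
  out <- SummarizedExperiment(assays = list(
    k = k, se = shape(f$se), p = shape(f$p), b0 = shape(f$intercept),
    exact = shape(f$exact)))
  dm <- new("DecayMatrix", out)
  attr(dm, "nFailed") <- sum(is.na(k))
  dm
}

#' Estimate the mean cellular decay rate from the harvest design
#'
#' The equal-mass hybridization hides the cell-wide decay of total RNA;
#' it is recovered from the design: per-cell RNA = yield / cells, and
#' lambda-bar is minus the OLS slope of log2(per-cell RNA) on time.
#'
#' @param cellsPerTimepoint,rnaYields positive, one per time point.
#' @param timePointsH hours (>= 3 points).
#' @return list: `lambdaBar` (log2-units/h), `se`.
#' @examples
#' # per-cell RNA halving every hour
#' estimateMeanCellularRate(c(1, 1, 1), c(8, 4, 2) * 1e6, c(0, 1, 2))
#' @export
estimateMeanCellularRate <- function(cellsPerTimepoint, rnaYields,
                                     timePointsH) {
  if (any(cellsPerTimepoint <= 0) || any(rnaYields <= 0))
    stop("cells and yields must be positive")
  if (length(timePointsH) < 3L) stop("need at least 3 time points")
  perCell <- rnaYields / cellsPerTimepoint
  f <- .rowOLSvec(timePointsH, matrix(log2(perCell), 1L))
  list(lambdaBar = -f$beta, se = f$se)
}

#' Convert relative decay rates to absolute rates and half-lives
#'
#' Absolute rate = relative rate + mean cellular rate.  Half-life is
#' 1 / k_abs hours where k_abs > 0; transcripts with k_abs <= 0 decay
#' slower than measurable under the relative normalization and get an
#' undefined (NA) half-life.
#'
#' @param dm a \linkS4class{DecayMatrix} of relative rates.
#' @param lambdaBar mean cellular rate (single value or one per
#'   individual/column).
#' @return The \linkS4class{DecayMatrix} with extra assays `k_abs` and
#'   `half_life_h`.
#' @export
toAbsoluteRates <- function(dm, lambdaBar) {
  stopifnot(is(dm, "DecayMatrix"))
  if (!length(lambdaBar) %in% c(1L, ncol(dm)))
    stop("lambdaBar must be scalar or one value per individual")
  kAbs <- sweep(assay(dm, "k"), 2L, rep(lambdaBar, length.out = ncol(dm)), "+")
  half <- ifelse(kAbs > 0, 1 / kAbs, NA_real_)
  assays(dm)$k_abs <- kAbs
  assays(dm)$half_life_h <- half
  dm
}

#' Classify consistently fast- and slow-decaying genes
#'
#' A gene is "fast" when at least `minFrac` of individuals (with
#' non-missing estimates) have k significantly greater than 0
#' (p < `alpha`, k > 0), "slow" when the same fraction is significantly
#' negative, and "neither" otherwise.  Fast and slow are mutually
#' exclusive by construction.
#'
#' @param dm a \linkS4class{DecayMatrix}.
#' @param alpha per-individual significance threshold (default 0.1).
#' @param minFrac required fraction of individuals (default 0.8).
#' @return data.frame: gene_id, class, nFast, nSlow, nIndividuals.
#' @export
classifyDecayGenes <- function(dm, alpha = 0.1, minFrac = 0.8) {
  stopifnot(is(dm, "DecayMatrix"))
  .assertFraction(minFrac, "minFrac")
  k <- assay(dm, "k"); p <- assay(dm, "p")
  sigPos <- rowSums(p < alpha & k > 0, na.rm = TRUE)
  sigNeg <- rowSums(p < alpha & k < 0, na.rm = TRUE)
  nOk <- rowSums(!is.na(k) & !is.na(p))
  cls <- rep("neither", nrow(dm))
  cls[nOk > 0 & sigPos / pmax(nOk, 1L) >= minFrac] <- "fast"
  cls[nOk > 0 & sigNeg / pmax(nOk, 1L) >= minFrac] <- "slow"
  data.frame(gene_id = rownames(dm), class = cls, nFast = sigPos,
             nSlow = sigNeg, nIndividuals = nOk)
}

#' Rank correlation between a gene feature and decay rates
#'
#' Spearman correlation (two-sided p via the t approximation) between a
#' per-gene feature -- e.g. gene length, 3'UTR length, miRNA site
#' density -- and the per-gene median decay rate, optionally restricted
#' to a gene subset such as the consistently fast/slow decayers.
#'
#' @param feature named numeric vector (per gene).
#' @param medianK named numeric vector of median decay rates.
#' @param subset optional character vector of gene ids.
#' @return list: `rho`, `p`, `n`.
#' @export
featureRankCorrelation <- function(feature, medianK, subset = NULL) {
  genes <- intersect(names(feature), names(medianK))
  if (!is.null(subset)) genes <- intersect(genes, subset)
  x <- feature[genes]; y <- medianK[genes]
  ok <- !(is.na(x) | is.na(y))
  if (sum(ok) < 4L) stop("need at least 4 paired non-missing values")
  if (diff(range(x[ok])) == 0 || diff(range(y[ok])) == 0)
    stop("rank correlation undefined for a constant vector")
  ct <- suppressWarnings(
    stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
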