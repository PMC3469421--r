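# Decay-expression association across individuals, permutation-based
# FDR and tail-overlap analysis.

#' Associate steady-state expression with decay rates across individuals
#'
#' Per gene, OLS of steady-state expression on the decay-rate estimate
#' across individuals: y_i = mu + beta * r_i + e.  A negative
#' t-statistic (faster decay, lower expression) is labelled
#' "concordant", a positive one "discordant".  Genes whose decay vector
#' is constant are returned NA.
#'
#' @param steadyState,decay matched genes x individuals matrices.
#' @return data.frame: gene_id, beta, t, p, direction.
#' @export
decayExpressionAssociation <- function(steadyState, decay) {
  stopifnot(is.matrix(steadyState), is.matrix(decay),
            all(dim(steadyState) == dim(decay)))
  if (ncol(steadyState) < 4L) stop("need at least 4 individuals")
  if (!is.null(rownames(steadyState)) && !is.null(rownames(decay)))
    stopifnot(identical(rownames(steadyState), rownames(decay)))
  f <- .rowOLS(decay, steadyState)
  direction <- ifelse(is.na(f$tstat), NA_character_,
                      ifelse(f$tstat < 0, "concordant", "discordant"))
  data.frame(gene_id = rownames(steadyState) %||% seq_len(nrow(steadyState)),
             beta = f$beta, t = f$tstat, p = f$p, direction = direction,
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Empirical FDR and q-values from permutation null p-values
#'
#' Compares the observed p-value distribution with a pooled empirical
#' null built from label permutations.  At threshold t the estimated
#' FDR is (#\{null p <= t\} / nPerms) / max(1, #\{observed p <= t\}); the
#' per-test q-value is the minimum FDR over thresholds at or above the
#' test's p, monotonized and clipped to [0, 1].
#'
#' @param observedP per-test observed p-values.
#' @param nullP pooled permuted p-values.
#' @param nPerms number of permutations that produced `nullP`.
#' @param targetFdr FDR level used for the significance count.
#' @return data.frame (rows aligned with `observedP`): p, q,
#'   significant; attribute `"threshold"` holds the largest p achieving
#'   the target FDR (or NA when none does).
#' @export
permutationFdr <- function(observedP, nullP, nPerms, targetFdr = 0.10) {
  if (nPerms < 1L) stop("nPerms must be >= 1")
  if (!length(nullP)) stop("empty permutation null")
  ok <- !is.na(observedP)
  p <- observedP[ok]
  ord <- order(p)
  ps <- p[ord]
  nullSorted <- sort(nullP)
  nullLE <- findInterval(ps, nullSorted)        # null p <= threshold
  obsLE <- seq_along(ps)
  fdr <- (nullLE / nPerms) / pmax(1, obsLE)
  q <- rev(cummin(rev(pmin(fdr, 1))))
  qFull <- rep(NA_real_, length(observedP))
  qFull[ok] <- q[order(ord)]
  out <- data.frame(p = observedP, q = qFull,
                    significant = !is.na(qFull) & qFull <= targetFdr)
  thr <- if (any(q <= targetFdr)) max(ps[q <= targetFdr]) else NA_real_
  attr(out, "threshold") <- thr
  out
}

#' Genes in the upper tails of both decay and expression
#'
#' Returns the genes lying in the top `q` fraction of the per-gene
#' decay-rate distribution AND the top `q` fraction of the steady-state
#' expression distribution -- the discordant fast-decay/high-expression
#' set.  Tail membership is strict: values above the nearest-rank
#' (1 - q) quantile.
#'
#' @param medianDecay,medianExpression named per-gene vectors.
#' @param q tail fraction in (0, 0.5).
#' @return character vector of gene ids (stable input order).
#' @export
tailOverlap <- function(medianDecay, medianExpression, q) {
  if (q <= 0 || q >= 0.5) stop("q must lie in (0, 0.5)")
  genes <- intersect(names(medianDecay), names(medianExpression))
  d <- medianDecay[genes]; e <- medianExpression[genes]
  cutD <- stats::quantile(d, 1 - q, type = 1, na.rm = TRUE)
  cutE <- stats::quantile(e, 1 - q, type = 1, na.rm = TRUE)
  genes[!is.na(d) & !is.na(e) & d > cutD & e > cutE]
}
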