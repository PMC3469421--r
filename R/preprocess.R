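# Preprocessing: array normalization, detection filtering, probe
# aggregation, SNP-in-probe correction and steady-state summaries.

# DecayExperiment -> 3D array [feature, individual, time point].
# Individuals keep their first-appearance order; times are sorted.
.cubeArray <- function(de, assay = "log2") {
  cd <- colData(de)
  inds <- unique(cd$individual)
  tps <- sort(unique(cd$time_h))
  m <- SummarizedExperiment::assay(de, assay)
  arr <- array(NA, c(nrow(de), length(inds), length(tps)),
               dimnames = list(rownames(de), inds, paste0("t", tps)))
  for (j in seq_along(tps)) {
    sel <- which(cd$time_h == tps[j])
    arr[, match(cd$individual[sel], inds), j] <- m[, sel]
  }
  attr(arr, "time_h") <- tps
  arr
}

#' Quantile-normalize arrays across all samples
#'
#' Forces every array (one individual at one time point) to share the
#' identical sorted intensity vector -- the across-array mean of sorted
#' values -- while preserving within-array ranks (ties averaged).  This
#' is the standard across-array normalization that makes intensities
#' comparable over the whole individual-by-time-point grid; under the
#' equal-mass hybridization design it is also what pins each gene's
#' measured decay to the mean cellular rate.  All-constant
#' (rank-degenerate) arrays are left unchanged.
#'
#' @param de a \linkS4class{DecayExperiment} with >= 2 samples.
#' @return The normalized \linkS4class{DecayExperiment}.
#' @export
quantileNormalizeArrays <- function(de) {
  stopifnot(is(de, "DecayExperiment"))
  if (ncol(de) < 2L) stop("need at least 2 arrays to normalize")
  m <- assay(de, "log2")
  constant <- apply(m, 2L, function(v) diff(range(v)) == 0)
  norm <- limma::normalizeQuantiles(m, ties = TRUE)
  norm[, constant] <- m[, constant]
  dimnames(norm) <- dimnames(m)
  assay(de, "log2") <- norm
  de
}

#' Filter features on detection above background
#'
#' Retains features detected above array background at the untreated
#' time point in at least `minFrac` of individuals AND at the final
#' time point in at least `minFrac` of individuals (both thresholds
#' inclusive).  The number of features failing each rule is reported in
#' attributes `"droppedAtZero"` / `"droppedAtFinal"`.
#'
#' @param de a \linkS4class{DecayExperiment} carrying a `"detected"`
#'   assay (logical).
#' @param minFrac detection fraction threshold, default 0.8.
#' @return The filtered \linkS4class{DecayExperiment}.
#' @export
filterDetectedGenes <- function(de, minFrac = 0.8) {
  stopifnot(is(de, "DecayExperiment"))
  .assertFraction(minFrac, "minFrac")
  if (!"detected" %in% assayNames(de))
    stop("no 'detected' assay: supply a detection mask ",
         "(or skip detection filtering)")
  det <- .cubeArray(de, "detected")
  tps <- attr(det, "time_h")
  frac0 <- rowMeans(det[, , 1L, drop = FALSE], na.rm = TRUE)
  fracT <- rowMeans(det[, , length(tps), drop = FALSE], na.rm = TRUE)
  keep <- frac0 >= minFrac & fracT >= minFrac
  out <- de[keep, ]
  attr(out, "droppedAtZero") <- sum(frac0 < minFrac)
  attr(out, "droppedAtFinal") <- sum(fracT < minFrac)
  out
}

#' Aggregate probe-level intensities to gene level
#'
#' Gene expression is the unweighted mean of the gene's probes per
#' sample.  Probes without a gene mapping are dropped with a warning.
#' A gene is flagged detected in a sample when any of its probes is.
#'
#' @param de probe-level \linkS4class{DecayExperiment}.
#' @param probeMap data.frame with columns `probe_id`, `gene_id`
#'   (many probes to one gene).
#' @return A gene-level \linkS4class{DecayExperiment}.
#' @export
aggregateProbesToGenes <- function(de, probeMap) {
  stopifnot(is(de, "DecayExperiment"))
  if (de@featureLevel != "probe")
    stop("cube is not probe-level")
  stopifnot(all(c("probe_id", "gene_id") %in% colnames(probeMap)))
  if (anyDuplicated(probeMap$probe_id))
    stop("each probe must map to exactly one gene")
  idx <- match(rownames(de), probeMap$probe_id)
  unmapped <- is.na(idx)
  if (any(unmapped))
    warning(sprintf("dropping %d probes without a gene mapping",
                    sum(unmapped)))
  de2 <- de[!unmapped, ]
  gene <- probeMap$gene_id[idx[!unmapped]]
  m <- rowsum(assay(de2, "log2"), gene) /
    as.vector(table(gene)[sort(unique(gene))])
  det <- NULL
  if ("detected" %in% assayNames(de2))
    det <- rowsum(assay(de2, "detected") + 0, gene) > 0
  cd <- colData(de2)
  DecayExperiment(m, cd$individual, cd$time_h, detected = det,
                  featureLevel = "gene")
}

#' Remove SNP-in-probe hybridization artifacts from steady-state values
#'
#' A SNP under an array probe can bias hybridization and masquerade as
#' an expression difference.  The steady-state values are regressed on
#' the dosage of the in-probe SNP; if the slope is significant
#' (p < `alpha`) the centered residuals replace the measurements,
#' otherwise they are returned unchanged.  Monomorphic dosages leave
#' the input untouched (regression undefined).
#'
#' @param values numeric per-individual steady-state expression.
#' @param dosage per-individual dosages in \{0, 1, 2\}.
#' @param alpha significance threshold, default 0.05.
#' @return list with `values` (possibly residualized), `corrected`
#'   (logical) and the regression `p`.
#' @export
correctProbeSnp <- function(values, dosage, alpha = 0.05) {
  stopifnot(length(values) == length(dosage))
  ok <- !(is.na(values) | is.na(dosage))
  if (sum(ok) < 3L || length(unique(dosage[ok])) < 2L)
    return(list(values = values, corrected = FALSE, p = NA_real_))
  fit <- .rowOLSvec(dosage[ok], matrix(values[ok], 1L))
  # guard: all-equal expression gives an exact flat fit (p = 1)
  if (!is.na(fit$p) && fit$p < alpha) {
    res <- values
    res[ok] <- values[ok] - (fit$intercept + fit$beta * dosage[ok])
    list(values = res, corrected = TRUE, p = fit$p)
  } else {
    list(values = values, corrected = FALSE, p = fit$p)
  }
}

#' Steady-state expression as the mean across time points
#'
#' Steady-state expression is summarized as the mean of the log2
#' intensities over all time points for each gene and individual.
#' Under the null of no decay-expression association this summary is
#' statistically independent of the fitted decay slope (the OLS mean
#' and slope estimators are uncorrelated), which is exactly why it is
#' preferred over the untreated time point alone.
#'
#' @param de a gene-level \linkS4class{DecayExperiment}.
#' @return numeric matrix, genes x individuals.
#' @export
steadyStateExpression <- function(de) {
  stopifnot(is(de, "DecayExperiment"))
  arr <- .cubeArray(de)
  apply(arr, c(1, 2), mean)
}

#' Standardize intensities by harvested cell counts
#'
#' Converts relative measurements to an absolute-like scale for
#' visualization by subtracting log2(cells_t / cells_0) from each time
#' point's arrays.  In a noiseless equal-mass design this turns the
#' per-gene slope into the negative absolute decay rate.
#'
#' @param de a \linkS4class{DecayExperiment}.
#' @param cellsPerTimepoint positive counts, one per time point (in
#'   ascending time order).
#' @return The standardized \linkS4class{DecayExperiment}.
#' @export
standardizeByCellCounts <- function(de, cellsPerTimepoint) {
  stopifnot(is(de, "DecayExperiment"))
  tps <- sort(unique(colData(de)$time_h))
  if (length(cellsPerTimepoint) != length(tps))
    stop("need one cell count per time point")
  if (any(cellsPerTimepoint <= 0)) stop("cell counts must be positive")
  offset <- log2(cellsPerTimepoint / cellsPerTimepoint[1])
  m <- assay(de, "log2")
  m <- m - rep(offset[match(colData(de)$time_h, tps)], each = nrow(m))
  assay(de, "log2") <- m
  de
}
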