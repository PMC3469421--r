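#' @import methods
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @import SummarizedExperiment
NULL

#' DecayExperiment: a transcription-arrest expression time course
#'
#' A \linkS4class{SummarizedExperiment} holding log2 expression
#' intensities for features (probes or genes) across samples, where each
#' sample is one individual measured at one time point after
#' transcriptional arrest.  The \code{colData} must carry an
#' \code{individual} identifier and a numeric \code{time_h} (hours since
#' arrest), and every individual must be measured at every time point.
#'
#' Assays: \code{"log2"} (required) and optionally \code{"detected"}, a
#' logical mask marking intensities distinguishable from array
#' background.
#'
#' @slot featureLevel either \code{"probe"} or \code{"gene"}.
#' @export
setClass("DecayExperiment",
  contains = "SummarizedExperiment",
  slots = c(featureLevel = "character"),
  prototype = prototype(featureLevel = "gene")
)

.validDecayExperiment <- function(object) {
  msg <- NULL
  cd <- colData(object)
  if (!all(c("individual", "time_h") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'individual' and 'time_h'")
  if (!"log2" %in% assayNames(object))
    msg <- c(msg, "assay 'log2' is required")
  if (length(object@featureLevel) != 1L ||
      !object@featureLevel %in% c("probe", "gene"))
    msg <- c(msg, "featureLevel must be 'probe' or 'gene'")
  if (is.null(msg) && ncol(object) > 0L) {
    tab <- table(cd$individual, cd$time_h)
    if (any(tab != 1L))
      msg <- c(msg, "each individual must appear exactly once per time point")
    if (!is.numeric(cd$time_h))
      msg <- c(msg, "time_h must be numeric (hours)")
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("DecayExperiment", .validDecayExperiment)

#' Construct a DecayExperiment
#'
#' @param log2 numeric matrix of log2 intensities, features x samples.
#' @param individual character/factor of length \code{ncol(log2)}.
#' @param time_h numeric vector of hours since transcriptional arrest,
#'   length \code{ncol(log2)}.
#' @param detected optional logical matrix, same shape as \code{log2}.
#' @param featureLevel \code{"gene"} (default) or \code{"probe"}.
#' @param rowData optional \code{DataFrame} of feature annotation.
#' @return A \linkS4class{DecayExperiment}.
#' @examples
#' m <- matrix(rnorm(20), 2, 10,
#'   dimnames = list(c("g1", "g2"), NULL))
#' de <- DecayExperiment(m, rep(c("i1", "i2"), each = 5),
#'   rep(c(0, 0.5, 1, 2, 4), 2))
#' @export
DecayExperiment <- function(log2, individual, time_h, detected = NULL,
                            featureLevel = c("gene", "probe"),
                            rowData = NULL) {
  featureLevel <- match.arg(featureLevel)
  cd <- DataFrame(individual = as.character(individual),
                  time_h = as.numeric(time_h))
  if (is.null(colnames(log2)))
    colnames(log2) <- sprintf("%s_t%g", cd$individual, cd$time_h)
  assays <- list(log2 = log2)
  if (!is.null(detected)) {
    dimnames(detected) <- dimnames(log2)
    assays$detected <- detected
  }
  se <- SummarizedExperiment(assays = assays, colData = cd)
  if (!is.null(rowData)) rowData(se) <- rowData
  new("DecayExperiment", se, featureLevel = featureLevel)
}

#' GenotypeMatrix: variant-by-individual minor-allele dosages
#'
#' A \linkS4class{RangedSummarizedExperiment} with one assay
#' \code{"dosage"} holding counts (0, 1, 2, or NA) of the minor allele,
#' where "minor" is defined from the analyzed cohort's allele
#' frequencies (ties at 0.5 broken by alphabetical allele order).  Row
#' ranges give 1-based variant positions (VCF convention); rowData
#' carries \code{ref}, \code{alt} and the empirical \code{maf}.
#'
#' @export
setClass("GenotypeMatrix", contains = "RangedSummarizedExperiment")

.validGenotypeMatrix <- function(object) {
  msg <- NULL
  if (!"dosage" %in% assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- assay(object, "dosage")
    if (!all(d %in% c(0, 1, 2) | is.na(d)))
      msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  }
  if (!"maf" %in% colnames(rowData(object)))
    msg <- c(msg, "rowData must contain 'maf'")
  else {
    maf <- rowData(object)$maf
    if (any(maf < 0 | maf > 0.5, na.rm = TRUE))
      msg <- c(msg, "maf must lie in [0, 0.5]")
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("GenotypeMatrix", .validGenotypeMatrix)

#' Construct a GenotypeMatrix
#'
#' Dosages are recoded so that they count the cohort minor allele: if
#' the supplied allele's frequency exceeds 0.5 the coding is flipped
#' (d -> 2 - d).  At a frequency of exactly 0.5 the counted allele is
#' whichever of ref/alt sorts first alphabetically.
#'
#' @param dosage integer matrix (variants x individuals) counting copies
#'   of the alternate allele.
#' @param ranges \linkS4class{GRanges} of variant positions (1-based),
#'   one per row of \code{dosage}.
#' @param ref,alt allele character vectors (defaults "A"/"C").
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
GenotypeMatrix <- function(dosage, ranges, ref = NULL, alt = NULL) {
  stopifnot(is.matrix(dosage), length(ranges) == nrow(dosage))
  if (is.null(ref)) ref <- rep("A", nrow(dosage))
  if (is.null(alt)) alt <- rep("C", nrow(dosage))
  f_alt <- rowMeans(dosage, na.rm = TRUE) / 2
  flip <- f_alt > 0.5 | (f_alt == 0.5 & alt > ref)
  flip[is.na(flip)] <- FALSE
  dosage[flip, ] <- 2 - dosage[flip, , drop = FALSE]
  minor_allele <- ifelse(flip, ref, alt)
  maf <- pmin(f_alt, 1 - f_alt)
  rd <- DataFrame(ref = ref, alt = alt, minor_allele = minor_allele,
                  maf = as.numeric(maf))
  names(ranges) <- NULL
  se <- SummarizedExperiment(assays = list(dosage = dosage),
                             rowRanges = ranges)
  rowData(se) <- cbind(rowData(se), rd)
  if (is.null(rownames(se)) && !is.null(rownames(dosage)))
    rownames(se) <- rownames(dosage)
  new("GenotypeMatrix", se)
}

#' DecayMatrix: per gene x individual decay estimates
#'
#' A \linkS4class{SummarizedExperiment} (genes x individuals) with
#' assays \code{k} (relative decay rate, log2-units/h; positive = faster
#' than the mean cellular rate), \code{se}, \code{p} (two-sided p for
#' k != 0), \code{b0} (fitted log2 abundance at t = 0) and \code{exact}
#' (logical: zero-residual fit).
#'
#' @export
setClass("DecayMatrix", contains = "SummarizedExperiment")

.validDecayMatrix <- function(object) {
  need <- c("k", "se", "p", "b0", "exact")
  miss <- setdiff(need, assayNames(object))
  if (length(miss))
    return(sprintf("missing assays: %s", paste(miss, collapse = ", ")))
  p <- assay(object, "p")
  if (any(p < 0 | p > 1, na.rm = TRUE)) return("p must lie in [0, 1]")
  if (any(assay(object, "se") < 0, na.rm = TRUE)) return("se must be >= 0")
  TRUE
}
setValidity("DecayMatrix", .validDecayMatrix)

#' QtlScan: results of a cis-QTL scan
#'
#' @slot results per-gene table: best cis variant, effect gamma, minimum
#'   p, number of variants tested, permutation q-value.
#' @slot tests per gene-variant pair table of all cis tests.
#' @slot permMinP matrix (genes x permutations) of permuted per-gene
#'   minimum p-values.
#' @slot nPerms number of label permutations.
#' @slot phenotype free-text phenotype label ("decay", "expression", ...).
#' @export
setClass("QtlScan",
  slots = c(results = "DataFrame", tests = "DataFrame",
            permMinP = "matrix", nPerms = "integer",
            phenotype = "character"))

#' Pi0Estimate: Storey pi0 with bootstrap lambda selection
#'
#' @slot lambda tuning-parameter grid.
#' @slot pi0Lambda plug-in pi0 estimate at each lambda.
#' @slot selectedLambda lambda minimizing the bootstrap MSE.
#' @slot pi0 final estimate, clipped to [0, 1].
#' @slot ci percentile bootstrap confidence interval.
#' @slot nBootstrap number of bootstrap resamples.
#' @export
setClass("Pi0Estimate",
  slots = c(lambda = "numeric", pi0Lambda = "numeric",
            selectedLambda = "numeric", pi0 = "numeric",
            ci = "numeric", nBootstrap = "integer"))

setMethod("show", "DecayExperiment", function(object) {
  cat(sprintf("DecayExperiment (%s-level): %d features, %d individuals x %d time points\n",
    object@featureLevel, nrow(object),
    length(unique(colData(object)$individual)),
    length(unique(colData(object)$time_h))))
  cat("  time points (h):",
      paste(sort(unique(colData(object)$time_h)), collapse = ", "), "\n")
  cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d variants x %d individuals\n",
              nrow(object), ncol(object)))
  if (nrow(object))
    cat(sprintf("  MAF range: %.3f - %.3f\n",
                min(rowData(object)$maf), max(rowData(object)$maf)))
})

setMethod("show", "DecayMatrix", function(object) {
  k <- assay(object, "k")
  cat(sprintf("DecayMatrix: %d genes x %d individuals\n",
              nrow(object), ncol(object)))
  cat(sprintf("  median |k|: %.3f log2-units/h; %d missing fits\n",
              stats::median(abs(k), na.rm = TRUE), sum(is.na(k))))
})

setMethod("show", "QtlScan", function(object) {
  cat(sprintf("QtlScan (%s): %d genes, %d permutations\n",
              object@phenotype, nrow(object@results), object@nPerms))
  if ("q" %in% colnames(object@results))
    cat(sprintf("  genes with q <= 0.15: %d\n",
                sum(object@results$q <= 0.15, na.rm = TRUE)))
})

setMethod("show", "Pi0Estimate", function(object) {
  cat(sprintf("Pi0Estimate: pi0 = %.3f (lambda = %.2f, 95%% CI %.3f-%.3f)\n",
              object@pi0, object@selectedLambda, object@ci[1], object@ci[2]))
})
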