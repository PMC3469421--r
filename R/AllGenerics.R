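#' Accessors for decayQTL classes
#'
#' \code{dosages()} returns the minor-allele dosage matrix of a
#' \linkS4class{GenotypeMatrix}; \code{variantMaf()} its per-variant
#' empirical minor allele frequencies.  \code{decayRates()},
#' \code{decaySE()} and \code{decayPvalues()} return the k, se and p
#' assays of a \linkS4class{DecayMatrix}; \code{medianDecay()} the
#' per-gene median of k across individuals.  \code{qtlResults()} and
#' \code{qtlTests()} return the per-gene and per-variant tables of a
#' \linkS4class{QtlScan}; \code{permNull()} its matrix of permuted
#' per-gene minimum p-values.  \code{pi0()} extracts the point estimate
#' from a \linkS4class{Pi0Estimate}.
#'
#' @param x an object of the documented class.
#' @return See description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname accessors
#' @export
setMethod("dosages", "GenotypeMatrix", function(x) assay(x, "dosage"))

#' @rdname accessors
#' @export
setGeneric("variantMaf", function(x) standardGeneric("variantMaf"))
#' @rdname accessors
#' @export
setMethod("variantMaf", "GenotypeMatrix", function(x) {
  stats::setNames(rowData(x)$maf, rownames(x))
})

#' @rdname accessors
#' @export
setGeneric("decayRates", function(x) standardGeneric("decayRates"))
#' @rdname accessors
#' @export
setMethod("decayRates", "DecayMatrix", function(x) assay(x, "k"))

#' @rdname accessors
#' @export
setGeneric("decaySE", function(x) standardGeneric("decaySE"))
#' @rdname accessors
#' @export
setMethod("decaySE", "DecayMatrix", function(x) assay(x, "se"))

#' @rdname accessors
#' @export
setGeneric("decayPvalues", function(x) standardGeneric("decayPvalues"))
#' @rdname accessors
#' @export
setMethod("decayPvalues", "DecayMatrix", function(x) assay(x, "p"))

#' @rdname accessors
#' @export
setGeneric("medianDecay", function(x) standardGeneric("medianDecay"))
#' @rdname accessors
#' @export
setMethod("medianDecay", "DecayMatrix", function(x) {
  apply(assay(x, "k"), 1L, stats::median, na.rm = TRUE)
})

#' @rdname accessors
#' @export
setGeneric("qtlResults", function(x) standardGeneric("qtlResults"))
#' @rdname accessors
#' @export
setMethod("qtlResults", "QtlScan", function(x) x@results)

#' @rdname accessors
#' @export
setGeneric("qtlTests", function(x) standardGeneric("qtlTests"))
#' @rdname accessors
#' @export
setMethod("qtlTests", "QtlScan", function(x) x@tests)

#' @rdname accessors
#' @export
setGeneric("permNull", function(x) standardGeneric("permNull"))
#' @rdname accessors
#' @export
setMethod("permNull", "QtlScan", function(x) x@permMinP)

#' @rdname accessors
#' @export
setGeneric("pi0", function(x) standardGeneric("pi0"))
#' @rdname accessors
#' @export
setMethod("pi0", "Pi0Estimate", function(x) x@pi0)
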