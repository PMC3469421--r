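# Shared fixtures: small studies and hand-built objects used across
# test files.  Everything is generated in code at test time.

tinyConfig <- function(...) {
  args <- utils::modifyList(
    list(nGenes = 24L, nIndividuals = 10L, noiseSdLog2 = 0,
         fracRdqtl = 0, fracEqtlBaseline = 0, seed = 42L),
    list(...))
  do.call(simConfig, args)
}

# DecayExperiment with a single individual profiled over the default
# time points (one row per gene supplied as a matrix row).
profileExperiment <- function(values, timePointsH = c(0, 0.5, 1, 2, 4),
                              nIndividuals = 1L) {
  if (is.vector(values)) values <- matrix(values, nrow = 1)
  m <- values[, rep(seq_along(timePointsH), nIndividuals), drop = FALSE]
  rownames(m) <- sprintf("g%02d", seq_len(nrow(m)))
  DecayExperiment(m,
                  individual = rep(sprintf("i%02d", seq_len(nIndividuals)),
                                   each = length(timePointsH)),
                  time_h = rep(timePointsH, nIndividuals))
}

# DecayMatrix built directly from k and p grids (se/b0 filled in).
makeDecayMatrix <- function(k, p) {
  se <- abs(k) * 0 + 0.1
  dm <- SummarizedExperiment::SummarizedExperiment(assays = list(
    k = k, se = se, p = p, b0 = k * 0,
    exact = matrix(FALSE, nrow(k), ncol(k))))
  new("DecayMatrix", dm)
}

# GenotypeMatrix from a raw alt-dosage matrix and 1-based positions.
makeGenotypes <- function(dosage, pos, chrom = "chr1") {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L))
  names(gr) <- rownames(dosage)
  GenotypeMatrix(dosage, gr)
}
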