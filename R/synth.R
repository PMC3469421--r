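#' Configuration for a synthetic decay-QTL study
#'
#' Builds and validates the parameter set for [simulateStudy()].  The
#' defaults emulate the study design the package targets: a cohort of
#' lymphoblastoid cell lines measured on expression arrays at 0, 0.5,
#' 1, 2 and 4 hours after transcriptional arrest, with RNA extracted
#' from an increasing number of cells so that an equal RNA mass is
#' hybridized at every time point.  That equal-mass design is what makes
#' measured decay rates *relative* to the mean cellular decay rate.
#'
#' Decay is first order per cell, m(t) = m(0) * 2^(-kAbs * t), with all
#' rates in log2-units/hour (half-life = 1/kAbs hours).  Baseline
#' abundance follows the first-order steady state m(0) =
#' transcription / kAbs, so a planted decay QTL automatically induces a
#' concordant effect on steady-state expression.  `couplingRho` plants
#' transcription effects at the same variants scaled so that the net
#' per-dosage effect on measured steady-state expression equals
#' (2 * couplingRho - 1) times the magnitude of the pure kinetic
#' effect: rho = 0 gives fully concordant decay QTLs, rho > 0.5
#' discordant ones.
#'
#' @param nGenes,nIndividuals study dimensions.
#' @param timePointsH hours since arrest; strictly increasing, first 0.
#' @param cellsPerTimepoint cells harvested per time point
#'   (non-decreasing).  Default: scaled as 2^(meanRate * t) so total RNA
#'   yield is constant across time points.
#' @param noiseSdLog2 Gaussian sd of log2 intensity noise.
#' @param fracRdqtl,fracEqtlBaseline fractions of genes with a planted
#'   decay QTL / pure transcription QTL (disjoint gene sets).
#' @param decayEffectA additive shift of the absolute decay rate per
#'   minor-allele dosage (log2-units/h, >= 0: the minor allele speeds
#'   decay).
#' @param couplingRho transcription-decay coupling in [0, 1].
#' @param mafRange allele-frequency range (low, high] within (0, 0.5].
#' @param variantsPerGeneWindow variants simulated per cis window.
#' @param meanRateMode `"exact"` (mean cellular rate imposed; clean
#'   recovery) or `"pool"` (emergent from the simulated transcript
#'   pool).
#' @param meanRate target mean cellular decay rate lambda-bar
#'   (log2-units/h).
#' @param rateSpreadLog2 sd of per-gene log2 rate dispersion around
#'   `meanRate`.
#' @param eqtlEffectLog2 per-dosage log2 shift of baseline abundance
#'   for pure transcription QTLs.
#' @param baselineSdLog2 sd of per-individual biological variation in
#'   log2 transcription.
#' @param detectionLimitLog2 intensities below this are flagged
#'   undetected (default -Inf: everything detected).
#' @param seed root RNG seed; per-component streams are derived from it
#'   deterministically.
#' @return A validated list of class `"SimConfig"`.
#' @export
simConfig <- function(nGenes = 200L, nIndividuals = 50L,
                      timePointsH = c(0, 0.5, 1, 2, 4),
                      cellsPerTimepoint = NULL,
                      noiseSdLog2 = 0.2,
                      fracRdqtl = 0.1, fracEqtlBaseline = 0.1,
                      decayEffectA = 0.2, couplingRho = 0,
                      mafRange = c(0.2, 0.5),
                      variantsPerGeneWindow = 5L,
                      meanRateMode = c("exact", "pool"),
                      meanRate = 0.3, rateSpreadLog2 = 0.5,
                      eqtlEffectLog2 = 0.5, baselineSdLog2 = 0.3,
                      detectionLimitLog2 = -Inf, seed = 1L) {
  meanRateMode <- match.arg(meanRateMode)
  if (length(timePointsH) < 3L || timePointsH[1] != 0 ||
      any(diff(timePointsH) <= 0))
    stop("timePointsH must be strictly increasing with first element 0")
  if (is.null(cellsPerTimepoint))
    cellsPerTimepoint <- round(1e6 * 2^(meanRate * timePointsH))
  if (length(cellsPerTimepoint) != length(timePointsH) ||
      any(cellsPerTimepoint <= 0) || any(diff(cellsPerTimepoint) < 0))
    stop("cellsPerTimepoint must be positive, non-decreasing, one per time point")
  .assertFraction(fracRdqtl, "fracRdqtl")
  .assertFraction(fracEqtlBaseline, "fracEqtlBaseline")
  .assertFraction(couplingRho, "couplingRho")
  if (fracRdqtl + fracEqtlBaseline > 1)
    stop("fracRdqtl + fracEqtlBaseline must not exceed 1")
  if (noiseSdLog2 < 0) stop("noiseSdLog2 must be >= 0")
  if (decayEffectA < 0)
    stop("decayEffectA must be >= 0 (minor allele speeds decay)")
  if (length(mafRange) != 2L || mafRange[1] <= 0 || mafRange[2] > 0.5 ||
      mafRange[1] > mafRange[2])
    stop("mafRange must satisfy 0 < low <= high <= 0.5")
  if (variantsPerGeneWindow < 1L)
    stop("each gene needs at least one cis variant")
  if (meanRate <= 0) stop("meanRate must be > 0")
  structure(list(
    nGenes = as.integer(nGenes), nIndividuals = as.integer(nIndividuals),
    timePointsH = as.numeric(timePointsH),
    cellsPerTimepoint = as.numeric(cellsPerTimepoint),
    noiseSdLog2 = noiseSdLog2, fracRdqtl = fracRdqtl,
    fracEqtlBaseline = fracEqtlBaseline, decayEffectA = decayEffectA,
    couplingRho = couplingRho, mafRange = as.numeric(mafRange),
    variantsPerGeneWindow = as.integer(variantsPerGeneWindow),
    meanRateMode = meanRateMode, meanRate = meanRate,
    rateSpreadLog2 = rateSpreadLog2, eqtlEffectLog2 = eqtlEffectLog2,
    baselineSdLog2 = baselineSdLog2,
    detectionLimitLog2 = detectionLimitLog2,
    seed = as.integer(seed)), class = "SimConfig")
}

#' Simulate genotype dosages
#'
#' Draws per-variant allele frequencies uniformly from `mafRange` and
#' dosages as Binomial(2, f) per individual (Hardy-Weinberg,
#' independent variants).  Dosages are recoded to count the empirical
#' cohort minor allele (see [GenotypeMatrix()]).
#'
#' @param nVariants,nIndividuals dimensions.
#' @param mafRange (low, high] with 0 < low <= high <= 0.5.
#' @param seed RNG seed.
#' @param positions optional 1-based positions (default 1..nVariants).
#' @param chrom chromosome name.
#' @return A \linkS4class{GenotypeMatrix}.
#' @examples
#' g <- simulateGenotypes(10, 20, c(0.2, 0.5), seed = 1)
#' dosages(g)[1:3, 1:5]
#' @export
simulateGenotypes <- function(nVariants, nIndividuals,
                              mafRange = c(0.2, 0.5), seed = 1L,
                              positions = NULL, chrom = "chr1") {
  if (mafRange[1] <= 0 || mafRange[2] > 0.5 || mafRange[1] > mafRange[2])
    stop("mafRange must satisfy 0 < low <= high <= 0.5 (monomorphic variants disallowed)")
  set.seed(as.integer(seed))
  f <- stats::runif(nVariants, mafRange[1], mafRange[2])
  d <- matrix(stats::rbinom(nVariants * nIndividuals, 2L, rep(f, nIndividuals)),
              nrow = nVariants, ncol = nIndividuals)
  rownames(d) <- sprintf("var%05d", seq_len(nVariants))
  colnames(d) <- sprintf("ind%03d", seq_len(nIndividuals))
  if (is.null(positions)) positions <- seq_len(nVariants)
  gr <- GRanges(chrom, IRanges(positions, width = 1L))
  names(gr) <- rownames(d)
  GenotypeMatrix(d, gr)
}

#' Simulate a complete synthetic decay-QTL study
#'
#' Generates an expression time-course cube, genotypes, gene
#' annotations and the harvest design, together with the ground-truth
#' parameters, under the kinetic model described in [simConfig()].
#' The measured log2 intensity for gene g, individual i at time t is
#' `baseline - (kAbs - lambdaBar) * t + noise` in `"exact"` mode; in
#' `"pool"` mode the subtracted term is the log2 mass of the simulated
#' transcript pool, so the mean cellular rate is emergent rather than
#' imposed.
#'
#' @param config a [simConfig()] object.
#' @return A list of class `"SimulatedStudy"` with elements
#'   `cube` (\linkS4class{DecayExperiment}, gene level),
#'   `genotypes` (\linkS4class{GenotypeMatrix}),
#'   `annotations` (\linkS4class{GRanges} with `gene_id`),
#'   `design` (data.frame: individual, time_h, cells, rna_yield),
#'   `truth` (list: kAbs and baselineLog2 matrices, lambdaBar per
#'   individual, qtlTable data.frame, the config).
#' @examples
#' study <- simulateStudy(simConfig(nGenes = 20, nIndividuals = 10))
#' study$cube
#' @export
simulateStudy <- function(config) {
  if (!inherits(config, "SimConfig"))
    stop("config must be created with simConfig()")
  G <- config$nGenes; N <- config$nIndividuals
  tp <- config$timePointsH; TT <- length(tp)
  geneIds <- sprintf("gene%04d", seq_len(G))
  indIds <- sprintf("ind%03d", seq_len(N))

  # gene annotations: one gene per 100 kb so 25 kb cis windows are disjoint
  geneStart <- (seq_len(G) - 1L) * 100000L + 30001L
  ann <- GRanges("chr1", IRanges(geneStart, geneStart + 9999L),
                 strand = "+", gene_id = geneIds)
  names(ann) <- geneIds

  # variants: uniform within each gene's cis window (25 kb each side)
  V <- G * config$variantsPerGeneWindow
  set.seed(.childSeed(config$seed, "positions"))
  pos <- unlist(lapply(seq_len(G), function(g) {
    sort(sample.int(60000L, config$variantsPerGeneWindow) +
           geneStart[g] - 25001L)
  }))
  genotypes <- simulateGenotypes(V, N, config$mafRange,
                                 seed = .childSeed(config$seed, "genotypes"),
                                 positions = pos)
  colnames(genotypes) <- indIds
  dos <- dosages(genotypes)
  geneOfVariant <- rep(seq_len(G), each = config$variantsPerGeneWindow)

  # per-gene absolute rates and planted effects
  set.seed(.childSeed(config$seed, "rates"))
  kGene <- config$meanRate * 2^stats::rnorm(G, 0, config$rateSpreadLog2)
  nRd <- floor(config$fracRdqtl * G)
  nEq <- floor(config$fracEqtlBaseline * G)
  rdGenes <- if (nRd) sort(sample.int(G, nRd)) else integer(0)
  eqGenes <- if (nEq) sort(sample(setdiff(seq_len(G), rdGenes), nEq)) else integer(0)
  pickVariant <- function(g) {
    cand <- which(geneOfVariant == g)
    cand[sample.int(length(cand), 1L)]
  }
  rdVariant <- vapply(rdGenes, pickVariant, integer(1))
  eqVariant <- vapply(eqGenes, pickVariant, integer(1))

  kAbs <- matrix(kGene, G, N, dimnames = list(geneIds, indIds))
  a <- config$decayEffectA
  if (length(rdGenes))
    kAbs[rdGenes, ] <- kAbs[rdGenes, , drop = FALSE] +
      a * dos[rdVariant, , drop = FALSE]
  if (any(kAbs <= 0))
    stop("decayEffectA drives some absolute decay rates to <= 0; ",
         "reduce the effect or raise meanRate")

  # transcription (log2): gene base + biological noise + planted effects
  set.seed(.childSeed(config$seed, "transcription"))
  tBase <- stats::rnorm(G, 8, 1)
  log2T <- matrix(tBase, G, N, dimnames = list(geneIds, indIds)) +
    matrix(stats::rnorm(G * N, 0, config$baselineSdLog2), G, N)
  effB <- numeric(length(rdGenes))
  if (length(rdGenes)) {
    # kinetic per-dosage loss in measured steady state (mean over time
    # points): baseline drop + slope term; coupling plants 2*rho times
    # that on transcription, giving net effect (2*rho - 1) * kinetic
    kinetic <- log2((kGene[rdGenes] + a) / kGene[rdGenes]) + a * mean(tp)
    effB <- 2 * config$couplingRho * kinetic
    log2T[rdGenes, ] <- log2T[rdGenes, , drop = FALSE] +
      effB * dos[rdVariant, , drop = FALSE]
  }
  if (length(eqGenes))
    log2T[eqGenes, ] <- log2T[eqGenes, , drop = FALSE] +
      config$eqtlEffectLog2 * dos[eqVariant, , drop = FALSE]

  # steady-state baseline abundance: m(0) = transcription / kAbs
  baselineLog2 <- log2T - log2(kAbs)

  # intensities
  set.seed(.childSeed(config$seed, "noise"))
  y <- array(NA_real_, c(G, N, TT),
             dimnames = list(geneIds, indIds, paste0("t", tp)))
  if (config$meanRateMode == "exact") {
    lambdaBar <- stats::setNames(rep(config$meanRate, N), indIds)
    for (j in seq_len(TT))
      y[, , j] <- baselineLog2 - (kAbs - config$meanRate) * tp[j]
    poolLog2 <- outer(rep(1, N), -config$meanRate * tp)
    rownames(poolLog2) <- indIds
  } else {
    # per-individual transcript pool M_i(t) = sum_g m_gi(t)
    poolLog2 <- matrix(NA_real_, N, TT, dimnames = list(indIds, NULL))
    m0 <- 2^baselineLog2
    for (j in seq_len(TT)) {
      M <- colSums(m0 * 2^(-kAbs * tp[j]))
      poolLog2[, j] <- log2(M)
    }
    poolLog2 <- poolLog2 - poolLog2[, 1]   # relative to t = 0
    for (j in seq_len(TT))
      y[, , j] <- baselineLog2 - kAbs * tp[j] -
        matrix(poolLog2[, j], G, N, byrow = TRUE)
    lambdaBar <- apply(poolLog2, 1L, function(v)
      -.rowOLSvec(tp, matrix(v, 1L))$beta)
  }
  if (config$noiseSdLog2 > 0)
    y <- y + array(stats::rnorm(length(y), 0, config$noiseSdLog2), dim(y))

  # flatten to feature x sample matrix (individual-major, time within)
  mat <- matrix(aperm(y, c(1, 3, 2)), nrow = G,
                dimnames = list(geneIds, NULL))
  individual <- rep(indIds, each = TT)
  time_h <- rep(tp, N)
  detected <- mat > config$detectionLimitLog2
  cube <- DecayExperiment(mat, individual, time_h, detected = detected,
                          featureLevel = "gene")

  # harvest design: per-cell RNA mass follows the pool; yields scale
  # with cells harvested (units: pg/cell baseline mass of 10)
  massPerCell <- 10 * 2^poolLog2           # N x TT
  design <- data.frame(
    individual = rep(indIds, each = TT),
    time_h = rep(tp, N),
    cells = rep(config$cellsPerTimepoint, N),
    rna_yield = as.vector(t(massPerCell)) * rep(config$cellsPerTimepoint, N))

  qtlTable <- rbind(
    if (length(rdGenes)) data.frame(
      gene_id = geneIds[rdGenes],
      variant_id = rownames(dos)[rdVariant],
      type = "decay", effect_decay = a,
      effect_baseline_log2 = effB),
    if (length(eqGenes)) data.frame(
      gene_id = geneIds[eqGenes],
      variant_id = rownames(dos)[eqVariant],
      type = "baseline", effect_decay = 0,
      effect_baseline_log2 = config$eqtlEffectLog2))
  if (is.null(qtlTable))
    qtlTable <- data.frame(gene_id = character(), variant_id = character(),
                           type = character(), effect_decay = numeric(),
                           effect_baseline_log2 = numeric())

  structure(list(cube = cube, genotypes = genotypes, annotations = ann,
                 design = design,
                 truth = list(kAbs = kAbs, lambdaBar = lambdaBar,
                              baselineLog2 = baselineLog2,
                              qtlTable = qtlTable, config = config)),
            class = "SimulatedStudy")
}

#' @export
print.SimulatedStudy <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf("SimulatedStudy: %d genes x %d individuals x %d time points (%s mode)\n",
              cfg$nGenes, cfg$nIndividuals, length(cfg$timePointsH),
              cfg$meanRateMode))
  cat(sprintf("  planted QTLs: %d decay, %d baseline (coupling rho = %g)\n",
              sum(x$truth$qtlTable$type == "decay"),
              sum(x$truth$qtlTable$type == "baseline"), cfg$couplingRho))
  invisible(x)
}
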