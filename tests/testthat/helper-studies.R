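# Simulation harnesses shared by the calibration and power tests.
# Sizes follow the package's reference study conditions: 200 genes x
# 50 individuals, five time points, log2 noise sd 0.2.  The synthetic
# generator plants no hidden confounders, so the QTL scans in these
# harnesses run without PC removal (nPcs = 0); regressOutPCs() is
# exercised directly in its own tests.

referenceStudy <- function(seed = 1L, ...) {
  simulateStudy(simConfig(seed = seed, ...))
}

# Fraction of genes called rdQTLs at q <= targetFdr, plus truth labels.
rdqtlScan <- function(study, nPerms = 20L, seed = 1L, targetFdr = 0.15) {
  k <- decayRates(fitDecayMatrix(study$cube))
  kc <- regressOutPCs(k, 0)
  scan <- mapCisQtl(kc, study$genotypes, study$annotations,
                    nPerms = nPerms, seed = seed, targetFdr = targetFdr,
                    phenotypeLabel = "decay")
  res <- as.data.frame(qtlResults(scan))
  truthG <- study$truth$qtlTable$gene_id[
    study$truth$qtlTable$type == "decay"]
  list(scan = scan, results = res,
       called = res$gene_id[res$significant], truthGenes = truthG)
}

powerAndFdp <- function(effect, seed, nPerms = 20L) {
  st <- referenceStudy(seed = seed, fracRdqtl = 0.1,
                       decayEffectA = effect)
  sc <- rdqtlScan(st, nPerms = nPerms, seed = seed + 7000L)
  tp <- sum(sc$called %in% sc$truthGenes)
  c(power = tp / max(1, length(sc$truthGenes)),
    fdp = if (length(sc$called))
      (length(sc$called) - tp) / length(sc$called) else 0)
}
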