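# PC correction, cis windows, QTL mapping, concordance and
# expression-matched enrichment.

test_that("PC regression removes components and nothing else", {
  set.seed(3)
  y <- matrix(rnorm(50 * 20), 50, dimnames = list(paste0("g", 1:50), NULL))
  # 0 PCs: row centering only
  expect_equal(regressOutPCs(y, 0), y - rowMeans(y), tolerance = 1e-12)
  # residuals orthogonal to every removed eigenvector
  r <- regressOutPCs(y, 5)
  E <- eigen(cor(y), symmetric = TRUE)$vectors[, 1:5]
  expect_lt(max(abs(r %*% E)), 1e-10)
  expect_error(regressOutPCs(y, 20), "smaller")
  # rank-1 phenotype with a two-level individual direction vanishes
  d <- rep(c(-1, 2), 10)
  y1 <- outer(rnorm(50), d)
  rownames(y1) <- paste0("g", 1:50)
  expect_lt(max(abs(regressOutPCs(y1, 1))), 1e-8)
})

test_that("cis windows are 25 kb inclusive with a strict MAF filter", {
  gene <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100001, 110000),
                                 strand = "+", gene_id = "g1")
  names(gene) <- "g1"
  # empirical MAF: 4/40 = 0.10 (excluded), 8/40 = 0.20 (kept)
  d <- rbind(v_at_edge   = rep(c(1, 0), c(8, 12)),
             v_outside   = rep(c(1, 0), c(8, 12)),
             v_low_maf   = rep(c(1, 0), c(4, 16)),
             v_downstream= rep(c(1, 0), c(8, 12)))
  g <- makeGenotypes(d, pos = c(75001, 75000, 105000, 135000))
  hits <- cisVariants(gene, g, windowKb = 25, mafMin = 0.10)
  expect_true("v_at_edge" %in% hits)      # exactly 25 kb upstream of TSS
  expect_false("v_outside" %in% hits)     # one bp beyond
  expect_false("v_low_maf" %in% hits)     # MAF not strictly > 0.10
  expect_true("v_downstream" %in% hits)   # exactly 25 kb downstream of TES
})

test_that("cis-QTL mapping finds planted variants and matches the lm() oracle", {
  cfg <- simConfig(nGenes = 30, nIndividuals = 50, noiseSdLog2 = 0.1,
                   fracRdqtl = 0.2, decayEffectA = 0.5, seed = 7)
  st <- simulateStudy(cfg)
  k <- decayRates(fitDecayMatrix(st$cube))
  kc <- regressOutPCs(k, 0)
  scan <- mapCisQtl(kc, st$genotypes, st$annotations, nPerms = 3, seed = 9,
                    phenotypeLabel = "decay")
  res <- as.data.frame(qtlResults(scan))
  qt <- st$truth$qtlTable
  qt <- qt[qt$type == "decay", ]
  hit <- match(qt$gene_id, res$gene_id)
  expect_true(all(res$best_variant_id[hit] == qt$variant_id))
  expect_true(all(res$gamma[hit] > 0))
  # every per-variant test equals the closed-form regression oracle
  tests <- as.data.frame(qtlTests(scan))
  set.seed(1)
  some <- tests[sample(nrow(tests), 25), ]
  dos <- dosages(st$genotypes)
  for (i in seq_len(nrow(some))) {
    fit <- summary(lm(kc[some$gene_id[i], ] ~
                        dos[some$variant_id[i], ]))$coefficients
    expect_equal(some$gamma[i], fit[2, 1], tolerance = 1e-10)
    expect_equal(some$p[i], fit[2, 4], tolerance = 1e-10)
  }
  # min-p invariant of the per-gene table
  byGene <- tapply(tests$p, tests$gene_id, min)
  expect_equal(as.numeric(byGene[res$gene_id]), res$p_best,
               tolerance = 1e-12)
})

test_that("QTL effects are shift-invariant and coding-canonical", {
  cfg <- simConfig(nGenes = 10, nIndividuals = 40, noiseSdLog2 = 0.1,
                   fracRdqtl = 0.3, seed = 11)
  st <- simulateStudy(cfg)
  k <- regressOutPCs(decayRates(fitDecayMatrix(st$cube)), 0)
  s1 <- mapCisQtl(k, st$genotypes, st$annotations, nPerms = 2, seed = 5)
  s2 <- mapCisQtl(k + 3, st$genotypes, st$annotations, nPerms = 2, seed = 5)
  expect_equal(qtlResults(s1)$gamma, qtlResults(s2)$gamma,
               tolerance = 1e-10)
  # flipping the stored allele coding on input leaves results unchanged
  # (the constructor recodes to cohort minor alleles)
  dos <- dosages(st$genotypes)
  gr <- GenomicRanges::granges(SummarizedExperiment::rowRanges(st$genotypes))
  gFlip <- GenotypeMatrix(2 - dos, gr, ref = rep("C", nrow(dos)),
                          alt = rep("A", nrow(dos)))
  expect_equal(unname(dosages(gFlip)), unname(dos))
  # negating the phenotype flips every effect sign
  s3 <- mapCisQtl(-k, st$genotypes, st$annotations, nPerms = 2, seed = 5)
  expect_equal(qtlResults(s3)$gamma, -qtlResults(s1)$gamma,
               tolerance = 1e-10)
})

test_that("permuted minimum p-values dominate observed ones under planted signals", {
  cfg <- simConfig(nGenes = 100, nIndividuals = 50, fracRdqtl = 0.3,
                   decayEffectA = 0.3, seed = 13)
  st <- simulateStudy(cfg)
  k <- regressOutPCs(decayRates(fitDecayMatrix(st$cube)), 0)
  scan <- mapCisQtl(k, st$genotypes, st$annotations, nPerms = 5, seed = 15)
  ks <- suppressWarnings(
    ks.test(qtlResults(scan)$p_best, as.vector(permNull(scan)),
            alternative = "greater"))
  expect_lt(ks$p.value, 1e-6)
})

test_that("concordance labels follow the allele sign rule", {
  mkScan <- function(gamma, pheno) {
    res <- S4Vectors::DataFrame(gene_id = paste0("g", seq_along(gamma)),
                                best_variant_id = paste0("v", seq_along(gamma)),
                                gamma = gamma, se = 0.1,
                                p_best = 1e-6, n_variants = 1L)
    tst <- S4Vectors::DataFrame(gene_id = res$gene_id,
                                variant_id = res$best_variant_id,
                                gamma = gamma, se = 0.1, t = 1, p = 1e-6)
    new("QtlScan", results = res, tests = tst,
        permMinP = matrix(0.5, length(gamma), 1), nPerms = 1L,
        phenotype = pheno)
  }
  eq <- mkScan(c(-0.4, -0.4, 0.3), "expression")
  rd <- mkScan(c(0.2, -0.2, 0.2), "decay")
  cc <- qtlConcordance(eq, rd)
  expect_identical(cc$label, c("concordant", "discordant", "discordant"))
  expect_error(qtlConcordance(eq, qtlTests(rd)[1:2, ]), "missing")
})

test_that("expression-matched resampling preserves the decile histogram", {
  set.seed(17)
  genes <- sprintf("g%04d", 1:1000)
  expr <- setNames(sort(rnorm(1000)), genes)  # deciles = consecutive blocks
  sig <- c(genes[1:30], genes[501:520])       # 30 in decile 1, 20 in decile 6
  # mark exactly the deciles the significant set occupies: any matched
  # draw must then reproduce the observed count exactly
  inDeciles <- setNames(genes %in% c(genes[1:100], genes[501:600]), genes)
  r <- enrichmentResample(inDeciles, sig, expr, nDraws = 50, seed = 1)
  expect_equal(r$observed, 50)
  expect_true(all(r$nullCounts == 50))
  # no enrichment: p is not small
  set.seed(19)
  flag <- setNames(runif(1000) < 0.2, genes)
  ps <- replicate(10, {
    s <- sample(genes, 50)
    enrichmentResample(flag, s, expr, nDraws = 200,
                       seed = sample.int(1e6, 1))$p
  })
  expect_gt(mean(ps), 0.2)
  # extreme case: observed maximal, null never reaches it
  flag2 <- setNames(genes %in% genes[1:30], genes)
  r2 <- enrichmentResample(flag2, genes[1:30], expr, nDraws = 99, seed = 3)
  expect_equal(r2$observed, 30)
  expect_equal(r2$p, 1 / 100, tolerance = 1e-12)
})

test_that("annotation QQ tables flag inflated variant sets", {
  set.seed(23)
  p <- setNames(runif(2000), sprintf("v%04d", 1:2000))
  p[1:100] <- 10^-runif(100, 3, 8)
  qq <- annotationQQ(p, list(planted = names(p)[1:100],
                             background = names(p)[101:2000]))
  expect_gt(qq$inflation["planted"], qq$inflation["background"])
  expect_lt(abs(qq$inflation["background"] - 1), 0.2)
  qq2 <- annotationQQ(setNames(rep(1e-6, 50), paste0("x", 1:50)),
                      list(s = paste0("x", 1:50)))
  expect_true(all(abs(qq2$table$observed - 6) < 1e-12))
  expect_warning(annotationQQ(p, list(empty = "nope")), "empty")
})
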