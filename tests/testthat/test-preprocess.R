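# Normalization, detection filtering, probe aggregation, SNP-in-probe
# correction and steady-state summaries.

test_that("quantile normalization equalizes sorted array values", {
  de <- profileExperiment(matrix(c(1, 4, 2, 5, 3, 6), nrow = 3,
                                 byrow = TRUE),
                          timePointsH = c(0, 1))
  qn <- assay(quantileNormalizeArrays(de), "log2")
  expect_equal(unname(qn[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn[, 2]), c(2.5, 3.5, 4.5))

  set.seed(7)
  m <- matrix(rnorm(200), 20, 10)
  de2 <- DecayExperiment(m, rep(letters[1:2], each = 5),
                         rep(c(0, 0.5, 1, 2, 4), 2))
  qn2 <- assay(quantileNormalizeArrays(de2), "log2")
  sorted <- apply(qn2, 2, sort)
  expect_lt(max(abs(sorted - sorted[, 1])), 1e-12)
  # idempotent
  qn3 <- assay(quantileNormalizeArrays(quantileNormalizeArrays(de2)), "log2")
  expect_equal(qn3, qn2, tolerance = 1e-12)
})

test_that("identical and rank-degenerate arrays pass through normalization", {
  m <- matrix(c(1, 2, 3, 1, 2, 3), 3, 2)
  de <- profileExperiment(matrix(c(1, 1, 2, 2, 3, 3), nrow = 3,
                                 byrow = TRUE), timePointsH = c(0, 1))
  expect_equal(assay(quantileNormalizeArrays(de), "log2"),
               assay(de, "log2"))
  # an all-constant array is left unchanged
  m2 <- cbind(c(1, 2, 3), c(5, 5, 5))
  rownames(m2) <- paste0("g", 1:3)
  de2 <- DecayExperiment(m2, c("a", "a"), c(0, 1))
  out <- assay(quantileNormalizeArrays(de2), "log2")
  expect_equal(unname(out[, 2]), c(5, 5, 5))
})

test_that("detection filter keeps genes detected at first and last time points", {
  tp <- c(0, 1, 2)
  n <- 10L
  m <- matrix(0, 3, n * 3, dimnames = list(paste0("g", 1:3), NULL))
  det <- array(TRUE, dim(m))
  # columns ordered individual-major: ind i occupies (i-1)*3 + 1:3
  t0cols <- seq(1, n * 3, by = 3)
  t2cols <- seq(3, n * 3, by = 3)
  det[1, t0cols[1:2]] <- FALSE          # detected at t0 in 8/10 -> keep
  det[2, t0cols[1:3]] <- FALSE          # 7/10 -> drop
  det[3, t2cols[1:3]] <- FALSE          # final time 7/10 -> drop
  de <- DecayExperiment(m, rep(sprintf("i%02d", 1:n), each = 3),
                        rep(tp, n), detected = det)
  kept <- filterDetectedGenes(de, minFrac = 0.8)
  expect_identical(rownames(kept), "g1")
  expect_identical(attr(kept, "droppedAtZero"), 1L)
  expect_identical(attr(kept, "droppedAtFinal"), 1L)
  # identity when everything is detected
  de2 <- DecayExperiment(m, rep(sprintf("i%02d", 1:n), each = 3),
                         rep(tp, n), detected = array(TRUE, dim(m)))
  expect_identical(nrow(filterDetectedGenes(de2)), 3L)
  expect_error(filterDetectedGenes(profileExperiment(1:5)), "detected")
})

test_that("detection filtering is monotone in the threshold", {
  set.seed(21)
  n <- 12L; tp <- c(0, 1, 4)
  m <- matrix(rnorm(30 * n * 3), 30)
  det <- matrix(runif(length(m)) < 0.9, nrow(m))
  de <- DecayExperiment(m, rep(sprintf("i%02d", 1:n), each = 3),
                        rep(tp, n), detected = det)
  prev <- rownames(filterDetectedGenes(de, 0.5))
  for (f in c(0.7, 0.8, 0.9, 1)) {
    cur <- rownames(filterDetectedGenes(de, f))
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("probe aggregation takes the unweighted mean per gene", {
  m <- matrix(c(4, 6, 10, 1, 3, 8), nrow = 3,
              dimnames = list(c("p1", "p2", "p3"), NULL))
  de <- DecayExperiment(m, c("a", "a"), c(0, 1), featureLevel = "probe")
  pm <- data.frame(probe_id = c("p1", "p2", "p3"),
                   gene_id = c("gA", "gA", "gB"))
  ge <- aggregateProbesToGenes(de, pm)
  expect_equal(unname(assay(ge, "log2")["gA", ]), c(5, 2))
  expect_equal(unname(assay(ge, "log2")["gB", ]), c(10, 8))
  # one probe per gene: identity
  pm1 <- data.frame(probe_id = rownames(m), gene_id = paste0("g", 1:3))
  ge1 <- aggregateProbesToGenes(de, pm1)
  expect_equal(unname(assay(ge1, "log2")), unname(m))
  # random many-probe gene equals the arithmetic mean
  set.seed(3)
  m2 <- matrix(rnorm(6 * 4), 6,
               dimnames = list(paste0("p", 1:6), NULL))
  de2 <- DecayExperiment(m2, rep("a", 4), c(0, 1, 2, 4),
                         featureLevel = "probe")
  pm2 <- data.frame(probe_id = paste0("p", 1:6),
                    gene_id = rep(c("g1", "g2"), each = 3))
  ge2 <- aggregateProbesToGenes(de2, pm2)
  expect_equal(assay(ge2, "log2")["g1", ], colMeans(m2[1:3, ]),
               tolerance = 1e-12, ignore_attr = TRUE)
  # unmapped probes dropped with a warning
  expect_warning(aggregateProbesToGenes(de, pm[1:2, ]), "without a gene")
})

test_that("SNP-in-probe correction residualizes only significant regressions", {
  set.seed(5)
  dosage <- rep(0:2, each = 10)
  # independent: unchanged
  x <- rnorm(30)
  r <- correctProbeSnp(x, sample(dosage))
  if (!r$corrected) expect_identical(r$values, x)
  # exact dependence: residuals vanish
  y <- 2 * dosage + 1
  r2 <- correctProbeSnp(y, dosage)
  expect_true(r2$corrected)
  expect_lt(max(abs(r2$values)), 1e-10)
  # noisy case matches the lm() residual oracle
  z <- 1.5 * dosage + rnorm(30, sd = 0.5)
  r3 <- correctProbeSnp(z, dosage)
  fit <- lm(z ~ dosage)
  expect_true(r3$corrected)
  expect_equal(r3$values, unname(resid(fit)), tolerance = 1e-10)
  expect_equal(r3$p, summary(fit)$coefficients[2, 4], tolerance = 1e-10)
  # monomorphic: untouched
  r4 <- correctProbeSnp(z, rep(1, 30))
  expect_false(r4$corrected)
  expect_identical(r4$values, z)
})

test_that("steady-state expression is the mean across time points", {
  de <- profileExperiment(c(10, 9, 8, 7, 6))
  expect_equal(unname(steadyStateExpression(de)[1, 1]), 8)
  de2 <- profileExperiment(rep(5, 5))
  expect_equal(unname(steadyStateExpression(de2)[1, 1]), 5)
  st <- simulateStudy(tinyConfig(noiseSdLog2 = 0.3, seed = 8))
  arr <- decayQTL:::.cubeArray(st$cube)
  expect_equal(steadyStateExpression(st$cube),
               apply(arr, c(1, 2), mean), ignore_attr = TRUE)
})

test_that("steady-state summarization commutes with probe aggregation", {
  set.seed(9)
  m <- matrix(rnorm(6 * 10), 6, dimnames = list(paste0("p", 1:6), NULL))
  de <- DecayExperiment(m, rep(c("a", "b"), each = 5),
                        rep(c(0, 0.5, 1, 2, 4), 2),
                        featureLevel = "probe")
  pm <- data.frame(probe_id = paste0("p", 1:6),
                   gene_id = rep(c("g1", "g2"), 3))
  aggThenMean <- steadyStateExpression(aggregateProbesToGenes(de, pm))
  ssProbe <- steadyStateExpression(de)
  meanThenAgg <- rowsum(ssProbe, pm$gene_id[match(rownames(ssProbe),
                                                  pm$probe_id)]) / 3
  expect_equal(aggThenMean, meanThenAgg[rownames(aggThenMean), ],
               tolerance = 1e-12)
})

test_that("cell-count standardization recovers absolute decay slopes", {
  de <- profileExperiment(rep(3, 5))
  # equal cells: unchanged
  expect_equal(assay(standardizeByCellCounts(de, rep(1e6, 5)), "log2"),
               assay(de, "log2"))
  # doubling cells at a time point shifts it down one log2 unit
  de2 <- profileExperiment(rep(3, 2), timePointsH = c(0, 1))
  out <- assay(standardizeByCellCounts(de2, c(1e6, 2e6)), "log2")
  expect_equal(unname(out[1, ]), c(3, 2))
  expect_error(standardizeByCellCounts(de2, c(1e6, -1)), "positive")
  # noiseless equal-mass study: standardized slope = -kAbs
  cfg <- tinyConfig(rateSpreadLog2 = 0.4, seed = 13,
                    cellsPerTimepoint = 1e6 * 2^(0.3 * c(0, 0.5, 1, 2, 4)))
  st <- simulateStudy(cfg)
  std <- standardizeByCellCounts(st$cube, cfg$cellsPerTimepoint)
  kStd <- decayRates(fitDecayMatrix(std))
  expect_equal(kStd, st$truth$kAbs, tolerance = 1e-10)
})
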