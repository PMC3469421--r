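# cis-QTL mapping for decay rates (rdQTLs) and steady-state expression
# (eQTLs): hidden-confounder PC correction, additive per-variant
# regression, permutation minimum-p FDR, concordance classification and
# matched-resampling enrichment.

#' Quantile-transform each gene to normal scores
#'
#' Maps each gene's values across individuals to standard-normal
#' quantiles by rank (ties averaged), the usual guard against outliers
#' in eQTL phenotypes.  Applied to the expression phenotype before PC
#' correction; decay phenotypes stay on their natural scale.
#'
#' @param phenotype genes x individuals matrix.
#' @return matrix of the same shape.
#' @export
normalScores <- function(phenotype) {
  t(apply(phenotype, 1L, function(v) {
    ok <- !is.na(v)
    v[ok] <- stats::qnorm(rank(v[ok]) / (sum(ok) + 1))
    v
  }))
}

#' Regress out hidden-confounder principal components
#'
#' Computes the eigenvectors of the individual-by-individual
#' correlation matrix of the phenotype and removes the top `nPcs`
#' components (plus intercept) from each gene's vector by OLS,
#' returning residuals.  This is the standard correction for
#' unmeasured technical and environmental confounders in QTL mapping;
#' with `nPcs = 0` only the per-gene mean is removed.
#'
#' @param phenotype genes x individuals matrix (complete).
#' @param nPcs number of components (default 13), < n individuals.
#' @return residual matrix of the same shape.
#' @export
regressOutPCs <- function(phenotype, nPcs = 13L) {
  stopifnot(is.matrix(phenotype))
  N <- ncol(phenotype)
  if (nPcs >= N) stop("nPcs must be smaller than the number of individuals")
  if (anyNA(phenotype))
    stop("phenotype must be complete; impute or drop missing estimates first")
  if (nPcs == 0L)
    return(phenotype - rowMeans(phenotype))
  C <- stats::cor(phenotype)           # individuals x individuals
  E <- eigen(C, symmetric = TRUE)$vectors[, seq_len(nPcs), drop = FALSE]
  .rowResiduals(phenotype, E)
}

#' Select cis-candidate variants for a gene
#'
#' The cis window runs from 25 kb upstream of the transcription start
#' site to 25 kb downstream of the transcription end site (boundaries
#' inclusive, positions 1-based).  Variants must have minor allele
#' frequency strictly greater than `mafMin`.
#'
#' @param gene a length-1 \linkS4class{GRanges} (1-based, as stored in
#'   a study's `annotations`; convert BED half-open inputs first, see
#'   [readAnnotations()]).
#' @param genotypes a \linkS4class{GenotypeMatrix}.
#' @param windowKb window size in kb on each side (default 25).
#' @param mafMin MAF threshold, strict (default 0.10).
#' @return character vector of variant ids (possibly empty).
#' @export
cisVariants <- function(gene, genotypes, windowKb = 25, mafMin = 0.10) {
  stopifnot(is(gene, "GRanges"), length(gene) == 1L,
            is(genotypes, "GenotypeMatrix"))
  w <- round(windowKb * 1000)
  lo <- max(1L, start(gene) - w)
  hi <- end(gene) + w
  v <- rowRanges(genotypes)
  hit <- as.character(seqnames(v)) == as.character(seqnames(gene)) &
    start(v) >= lo & start(v) <= hi &
    rowData(genotypes)$maf > mafMin
  rownames(genotypes)[hit]
}

#' Map cis QTLs with a permutation minimum-p null
#'
#' Per gene, each cis variant is tested by OLS of the (already
#' PC-corrected) phenotype on minor-allele dosage under an additive
#' model; the minimum p across variants and the corresponding effect
#' gamma are recorded.  For each permutation the individual labels of
#' the phenotype are shuffled once (the same shuffle for every gene,
#' preserving gene-gene correlation) and per-gene minimum p-values are
#' recollected; pooled across genes these form the empirical null for
#' [permutationFdr()].
#'
#' @param phenotype genes x individuals matrix, PC-corrected.
#' @param genotypes \linkS4class{GenotypeMatrix} with matching
#'   individuals (columns).
#' @param annotations \linkS4class{GRanges} named by gene id.
#' @param nPerms label permutations (default 3).
#' @param seed RNG seed for the permutations.
#' @param windowKb,mafMin passed to [cisVariants()].
#' @param targetFdr FDR level for the significance flag (default 0.15).
#' @param phenotypeLabel free-text label stored in the result.
#' @return A \linkS4class{QtlScan}.  Genes without qualifying cis
#'   variants are omitted; their count is in `metadata`-like attribute
#'   `"nSkipped"`.
#' @export
mapCisQtl <- function(phenotype, genotypes, annotations, nPerms = 3L,
                      seed = 1L, windowKb = 25, mafMin = 0.10,
                      targetFdr = 0.15, phenotypeLabel = "phenotype") {
  stopifnot(is.matrix(phenotype), is(genotypes, "GenotypeMatrix"))
  genes <- intersect(rownames(phenotype), names(annotations))
  if (!length(genes)) stop("no genes shared between phenotype and annotations")
  N <- ncol(phenotype)
  if (ncol(genotypes) != N)
    stop("phenotype and genotypes must cover the same individuals")
  if (!is.null(colnames(phenotype)) && !is.null(colnames(genotypes)) &&
      !identical(colnames(phenotype), colnames(genotypes)))
    stop("individual order differs between phenotype and genotypes")
  dos <- dosages(genotypes)
  nPerms <- as.integer(nPerms)
  set.seed(as.integer(seed))
  perms <- replicate(nPerms, sample.int(N), simplify = FALSE)

  resRows <- vector("list", length(genes))
  testRows <- vector("list", length(genes))
  permMinP <- matrix(NA_real_, length(genes), nPerms,
                     dimnames = list(genes, NULL))
  skipped <- 0L
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    vids <- cisVariants(annotations[g], genotypes, windowKb, mafMin)
    if (!length(vids)) { skipped <- skipped + 1L; next }
    D <- dos[vids, , drop = FALSE]
    y <- phenotype[g, ]
    f <- .rowOLS(D, matrix(y, length(vids), N, byrow = TRUE))
    keep <- !is.na(f$p)
    if (!any(keep)) { skipped <- skipped + 1L; next }
    best <- which(f$p == min(f$p[keep]))[1]
    resRows[[gi]] <- data.frame(
      gene_id = g, best_variant_id = vids[best], gamma = f$beta[best],
      se = f$se[best], p_best = f$p[best], n_variants = sum(keep))
    testRows[[gi]] <- data.frame(
      gene_id = g, variant_id = vids, gamma = f$beta, se = f$se,
      t = f$tstat, p = f$p)
    for (b in seq_len(nPerms)) {
      yp <- y[perms[[b]]]
      fp <- .rowOLS(D, matrix(yp, length(vids), N, byrow = TRUE))
      permMinP[gi, b] <- min(fp$p, na.rm = TRUE)
    }
  }
  res <- do.call(rbind, resRows)
  if (is.null(res)) stop("no gene had qualifying cis variants")
  tests <- do.call(rbind, testRows)
  permMinP <- permMinP[res$gene_id, , drop = FALSE]
  fdr <- permutationFdr(res$p_best, as.vector(permMinP), nPerms,
                        targetFdr = targetFdr)
  res$q <- fdr$q
  res$significant <- fdr$significant
  out <- new("QtlScan", results = DataFrame(res), tests = DataFrame(tests),
             permMinP = permMinP, nPerms = nPerms,
             phenotype = phenotypeLabel)
  attr(out, "nSkipped") <- skipped
  out
}

#' Classify eQTL-rdQTL effect concordance
#'
#' For genes carrying both an expression and a decay association at the
#' same variant (same minor-allele coding), the pair is "concordant"
#' when the allele lowering expression speeds decay --
#' sign(gamma_expression) * sign(gamma_decay) < 0 -- and "discordant"
#' when the signs agree; a zero effect leaves the call undefined (NA).
#'
#' @param eqtl \linkS4class{QtlScan} for expression (per-gene best
#'   variants are used).
#' @param rdqtlTests per-variant decay tests, either a
#'   \linkS4class{QtlScan} or its [qtlTests()] table, containing the
#'   eQTL variants.
#' @param genes optional gene ids to restrict to (e.g. the jointly
#'   significant eQTL/rdQTL genes).
#' @return data.frame: gene_id, variant_id, gamma_expr, gamma_decay,
#'   label.
#' @export
qtlConcordance <- function(eqtl, rdqtlTests, genes = NULL) {
  stopifnot(is(eqtl, "QtlScan"))
  if (is(rdqtlTests, "QtlScan")) rdqtlTests <- qtlTests(rdqtlTests)
  rd <- as.data.frame(rdqtlTests)
  eq <- as.data.frame(qtlResults(eqtl))
  if (!is.null(genes)) eq <- eq[eq$gene_id %in% genes, , drop = FALSE]
  key <- paste(rd$gene_id, rd$variant_id)
  idx <- match(paste(eq$gene_id, eq$best_variant_id), key)
  if (anyNA(idx))
    stop("decay tests are missing for some eQTL gene/variant pairs")
  gd <- rd$gamma[idx]
  prod <- sign(eq$gamma) * sign(gd)
  label <- ifelse(prod < 0, "concordant",
                  ifelse(prod > 0, "discordant", NA_character_))
  data.frame(gene_id = eq$gene_id, variant_id = eq$best_variant_id,
             gamma_expr = eq$gamma, gamma_decay = gd, label = label)
}

#' Expression-matched resampling enrichment test
#'
#' Tests whether significant-eQTL genes are enriched for decay
#' associations at their best SNPs, against random gene sets of equal
#' size drawn to match the expression-level decile histogram of the
#' significant set (associations are easier to detect for highly
#' expressed genes, so naive resampling would be anti-conservative).
#' The permutation p-value is (1 + #\{null >= observed\}) / (nDraws + 1).
#'
#' @param decaySignificant named logical: per gene, does its best eQTL
#'   SNP show a significant decay association?
#' @param significantGenes gene ids of the significant eQTLs.
#' @param expressionLevels named per-gene expression summary.
#' @param nDraws resampling draws (default 1000).
#' @param seed RNG seed.
#' @return list: `observed`, `nullCounts`, `p`.
#' @export
enrichmentResample <- function(decaySignificant, significantGenes,
                               expressionLevels, nDraws = 1000L,
                               seed = 1L) {
  genes <- names(decaySignificant)
  stopifnot(!is.null(genes), all(significantGenes %in% genes),
            all(genes %in% names(expressionLevels)))
  expr <- expressionLevels[genes]
  br <- stats::quantile(expr, seq(0, 1, 0.1))
  br[1] <- -Inf; br[length(br)] <- Inf
  decile <- cut(expr, breaks = br, labels = FALSE)
  names(decile) <- genes
  sigDecile <- table(factor(decile[significantGenes], levels = 1:10))
  poolByDecile <- split(genes, decile)
  for (d in names(sigDecile)) {
    need <- sigDecile[[d]]
    have <- length(poolByDecile[[d]])
    if (need > have)
      stop(sprintf("expression decile %s has %d genes but %d are needed",
                   d, have, need))
  }
  observed <- sum(decaySignificant[significantGenes])
  set.seed(as.integer(seed))
  nullCounts <- vapply(seq_len(nDraws), function(i) {
    draw <- unlist(lapply(names(sigDecile), function(d) {
      n <- sigDecile[[d]]
      if (n == 0L) return(character(0))
      sample(poolByDecile[[d]], n)
    }))
    sum(decaySignificant[draw])
  }, numeric(1))
  p <- (1 + sum(nullCounts >= observed)) / (nDraws + 1)
  list(observed = observed, nullCounts = nullCounts, p = p)
}

#' Observed-vs-expected quantile table for annotated variant sets
#'
#' For each named variant set, pairs the sorted -log10 p-values with
#' uniform expected quantiles (a QQ-plot table) and summarizes
#' inflation as median(observed) / median(expected).  Used to compare
#' e.g. variants in predicted miRNA binding sites against all 3'UTR
#' variants.
#'
#' @param assocP named per-variant association p-values.
#' @param annotationSets named list of variant-id vectors (subsets of
#'   `names(assocP)`).
#' @return list: `table` (data.frame set, expected, observed) and
#'   `inflation` (named numeric).
#' @export
annotationQQ <- function(assocP, annotationSets) {
  stopifnot(!is.null(names(assocP)), is.list(annotationSets))
  rows <- list(); infl <- numeric(0)
  for (s in names(annotationSets)) {
    ids <- intersect(annotationSets[[s]], names(assocP))
    if (!length(ids)) { warning(sprintf("set '%s' is empty; skipped", s)); next }
    p <- sort(assocP[ids])
    m <- length(p)
    expected <- -log10((seq_len(m) - 0.5) / m)
    observed <- -log10(p)
    rows[[s]] <- data.frame(set = s, expected = rev(expected),
                            observed = rev(observed))
    infl[s] <- stats::median(observed) / stats::median(expected)
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       inflation = infl)
}
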