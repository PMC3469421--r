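# File formats and the pipeline driver.  All coordinate conversions
# live here: annotation files use BED convention (0-based, half-open),
# VCF and in-memory GRanges are 1-based.

#' Read gene annotations (BED-like TSV)
#'
#' Columns: chrom, start, end, strand, gene_id, with BED 0-based
#' half-open coordinates; converted to 1-based inclusive
#' \linkS4class{GRanges} on read.
#'
#' @param path TSV file.
#' @return \linkS4class{GRanges} named by gene_id.
#' @export
readAnnotations <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "strand", "gene_id")
  stopifnot(all(need %in% colnames(d)))
  gr <- GRanges(d$chrom, IRanges(d$start + 1L, d$end),
                strand = d$strand, gene_id = d$gene_id)
  names(gr) <- d$gene_id
  gr
}

#' @rdname readAnnotations
#' @param annotations a \linkS4class{GRanges} named by gene id.
#' @export
writeAnnotations <- function(annotations, path) {
  d <- data.frame(chrom = as.character(seqnames(annotations)),
                  start = start(annotations) - 1L,
                  end = end(annotations),
                  strand = as.character(strand(annotations)),
                  gene_id = annotations$gene_id)
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an expression cube from long-format TSV
#'
#' Columns: gene_id, individual_id, time_h, log2_intensity (optionally
#' detected).
#'
#' @param path TSV file.
#' @return \linkS4class{DecayExperiment} (gene level).
#' @export
readExpressionCube <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("gene_id", "individual_id", "time_h", "log2_intensity")
  stopifnot(all(need %in% colnames(d)))
  genes <- unique(d$gene_id)
  samples <- unique(d[, c("individual_id", "time_h")])
  samples <- samples[order(match(samples$individual_id,
                                 unique(samples$individual_id)),
                           samples$time_h), ]
  key <- paste(samples$individual_id, samples$time_h)
  col <- match(paste(d$individual_id, d$time_h), key)
  row <- match(d$gene_id, genes)
  m <- matrix(NA_real_, length(genes), nrow(samples),
              dimnames = list(genes, NULL))
  m[cbind(row, col)] <- d$log2_intensity
  det <- NULL
  if ("detected" %in% colnames(d)) {
    det <- matrix(NA, length(genes), nrow(samples))
    det[cbind(row, col)] <- as.logical(d$detected)
  }
  DecayExperiment(m, samples$individual_id, samples$time_h,
                  detected = det, featureLevel = "gene")
}

#' @rdname readExpressionCube
#' @param de a \linkS4class{DecayExperiment}.
#' @export
writeExpressionCube <- function(de, path) {
  cd <- colData(de)
  m <- assay(de, "log2")
  d <- data.frame(
    gene_id = rep(rownames(m), times = ncol(m)),
    individual_id = rep(cd$individual, each = nrow(m)),
    time_h = rep(cd$time_h, each = nrow(m)),
    log2_intensity = as.vector(m))
  if ("detected" %in% assayNames(de))
    d$detected <- as.vector(assay(de, "detected"))
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read genotypes from VCF or a TSV dosage matrix
#'
#' VCF input (diploid GT fields) is converted to alternate-allele
#' counts; TSV input must have columns variant_id, chrom, pos, ref,
#' alt, then one column per individual.  In both cases dosages are
#' recoded to count the cohort minor allele, variants with missing
#' calls in more than 10% of individuals are dropped, and remaining
#' missing calls are imputed to the variant's rounded mean dosage.
#'
#' @param path input file (format by extension: `.vcf` vs anything
#'   else).
#' @param maxMissing missing-call fraction above which a variant is
#'   dropped (default 0.10).
#' @return \linkS4class{GenotypeMatrix}; the number of imputed calls is
#'   in attribute `"nImputed"`.
#' @export
readGenotypes <- function(path, maxMissing = 0.10) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    bad <- grepl("^[0-9.]+[/|][0-9.]+[/|]", gt)  # >2 alleles
    if (any(bad, na.rm = TRUE)) stop("non-diploid GT encountered")
    alleles <- function(x) {
      a <- strsplit(x, "[/|]")
      vapply(a, function(z) {
        if (length(z) != 2L || any(z == ".")) return(NA_real_)
        sum(z != "0")
      }, numeric(1))
    }
    d <- apply(gt, 2L, alleles)
    if (is.null(dim(d))) d <- matrix(d, nrow = nrow(gt))
    dimnames(d) <- dimnames(gt)
    fix <- vcfR::getFIX(v)
    gr <- GRanges(fix[, "CHROM"],
                  IRanges(as.integer(fix[, "POS"]), width = 1L))
    names(gr) <- rownames(d) <- fix[, "ID"]
    ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  } else {
    t0 <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
    need <- c("variant_id", "chrom", "pos", "ref", "alt")
    stopifnot(all(need %in% colnames(t0)))
    d <- as.matrix(t0[, setdiff(colnames(t0), need), drop = FALSE])
    rownames(d) <- t0$variant_id
    gr <- GRanges(t0$chrom, IRanges(t0$pos, width = 1L))
    names(gr) <- t0$variant_id
    ref <- t0$ref; alt <- t0$alt
  }
  missFrac <- rowMeans(is.na(d))
  keep <- missFrac <= maxMissing
  d <- d[keep, , drop = FALSE]; gr <- gr[keep]
  ref <- ref[keep]; alt <- alt[keep]
  nImputed <- 0L
  if (anyNA(d)) {
    for (i in which(rowSums(is.na(d)) > 0)) {
      na <- is.na(d[i, ])
      d[i, na] <- round(mean(d[i, !na]))
      nImputed <- nImputed + sum(na)
    }
  }
  gm <- GenotypeMatrix(d, gr, ref = ref, alt = alt)
  attr(gm, "nImputed") <- nImputed
  gm
}

#' Write genotypes as a minimal VCF and as a dosage TSV
#'
#' The VCF carries CHROM, POS, ID, REF, ALT and diploid GT fields
#' reconstructed from dosages (0/0, 0/1, 1/1 counting the stored
#' allele).  Note the stored dosage counts the cohort *minor* allele,
#' so REF/ALT are written as major/minor.
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @param path output path (`.vcf` for VCF, otherwise TSV).
#' @export
writeGenotypes <- function(gm, path) {
  stopifnot(is(gm, "GenotypeMatrix"))
  d <- dosages(gm)
  rd <- rowData(gm)
  minor <- rd$minor_allele
  major <- ifelse(minor == rd$alt, rd$ref, rd$alt)
  gr <- rowRanges(gm)
  if (grepl("\\.vcf$", path)) {
    gtCodes <- c("0/0", "0/1", "1/1")
    lines <- c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", colnames(d)),
                     collapse = "\t"))
    body <- vapply(seq_len(nrow(d)), function(i) {
      paste(c(as.character(seqnames(gr))[i], start(gr)[i], rownames(d)[i],
              major[i], minor[i], ".", "PASS", ".", "GT",
              gtCodes[d[i, ] + 1L]), collapse = "\t")
    }, character(1))
    writeLines(c(lines, body), path)
  } else {
    out <- data.frame(variant_id = rownames(d),
                      chrom = as.character(seqnames(gr)),
                      pos = start(gr), ref = major, alt = minor,
                      check.names = FALSE)
    out <- cbind(out, as.data.frame(d, check.names = FALSE))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Write a simulated study to a directory
#'
#' Emits the long-format expression TSV, dosage TSV + minimal VCF,
#' BED-like annotations, harvest design and ground-truth tables.
#'
#' @param study a [simulateStudy()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeStudy <- function(study, dir) {
  stopifnot(inherits(study, "SimulatedStudy"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeExpressionCube(study$cube, file.path(dir, "expression.tsv"))
  writeGenotypes(study$genotypes, file.path(dir, "genotypes.tsv"))
  writeGenotypes(study$genotypes, file.path(dir, "genotypes.vcf"))
  writeAnnotations(study$annotations, file.path(dir, "annotations.tsv"))
  utils::write.table(study$design, file.path(dir, "design.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$truth$qtlTable,
                     file.path(dir, "truth_qtls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Run the full decay-QTL pipeline
#'
#' Stages, in order: optional quantile normalization and detection
#' filtering; decay-rate fitting; fast/slow classification; steady
#' state summarization; decay-expression association with permutation
#' FDR; hidden-confounder PC correction; cis rdQTL and eQTL scans with
#' permutation minimum-p FDR; eQTL-rdQTL concordance; overlap
#' arithmetic.  Outputs are written as TSV plus a JSON manifest
#' (parameters, seed, input hashes, stage counts); rerunning with the
#' same config reproduces them exactly.
#'
#' @param config named list: either `study` (a [simulateStudy()]
#'   result) or paths `expression`, `genotypes`, `annotations`; plus
#'   optional `outDir`, `seed` (default 1), `nPerms` (default 3),
#'   `nPcs` (default 13), `windowKb` (25), `mafMin` (0.10), `alpha`
#'   (0.1), `minFrac` (0.8), `fdrAssoc` (0.10), `fdrQtl` (0.15),
#'   `normalize` (FALSE), `filterDetection` (FALSE).  A path to a YAML
#'   file with these keys is also accepted.
#' @return list of stage results (decay matrix, classification,
#'   association, rdQTL and eQTL scans, concordance, overlap summary,
#'   manifest).
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(
    list(outDir = NULL, seed = 1L, nPerms = 3L, nPcs = 13L,
         windowKb = 25, mafMin = 0.10, alpha = 0.1, minFrac = 0.8,
         fdrAssoc = 0.10, fdrQtl = 0.15, normalize = FALSE,
         filterDetection = FALSE),
    config)
  inputs <- character(0)
  if (!is.null(cfg$study)) {
    cube <- cfg$study$cube
    genotypes <- cfg$study$genotypes
    annotations <- cfg$study$annotations
  } else {
    for (f in c("expression", "genotypes", "annotations"))
      if (is.null(cfg[[f]]) || !file.exists(cfg[[f]]))
        stop(sprintf("input '%s' missing or not found", f))
    inputs <- c(expression = cfg$expression, genotypes = cfg$genotypes,
                annotations = cfg$annotations)
    cube <- readExpressionCube(cfg$expression)
    genotypes <- readGenotypes(cfg$genotypes)
    annotations <- readAnnotations(cfg$annotations)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  counts <- list(genesIn = nrow(cube))
  if (isTRUE(cfg$normalize))
    cube <- stage("normalize", quantileNormalizeArrays(cube))
  if (isTRUE(cfg$filterDetection)) {
    cube <- stage("detection-filter",
                  filterDetectedGenes(cube, cfg$minFrac))
    counts$genesAfterDetection <- nrow(cube)
  }
  dm <- stage("fit-decay", fitDecayMatrix(cube))
  cls <- stage("classify", classifyDecayGenes(dm, cfg$alpha, cfg$minFrac))
  ss <- stage("steady-state", steadyStateExpression(cube))
  k <- decayRates(dm)
  assoc <- stage("association",
    associationFdr(ss, k, nPerms = cfg$nPerms,
                   seed = .childSeed(cfg$seed, "assoc"),
                   targetFdr = cfg$fdrAssoc))
  decayResid <- stage("pc-correct-decay",
                      regressOutPCs(k, min(cfg$nPcs, ncol(k) - 1L)))
  exprResid <- stage("pc-correct-expression",
    regressOutPCs(normalScores(ss), min(cfg$nPcs, ncol(ss) - 1L)))
  rd <- stage("map-rdqtl",
    mapCisQtl(decayResid, genotypes, annotations, nPerms = cfg$nPerms,
              seed = .childSeed(cfg$seed, "rdqtl"),
              windowKb = cfg$windowKb, mafMin = cfg$mafMin,
              targetFdr = cfg$fdrQtl, phenotypeLabel = "decay"))
  eq <- stage("map-eqtl",
    mapCisQtl(exprResid, genotypes, annotations, nPerms = cfg$nPerms,
              seed = .childSeed(cfg$seed, "eqtl"),
              windowKb = cfg$windowKb, mafMin = cfg$mafMin,
              targetFdr = cfg$fdrQtl, phenotypeLabel = "expression"))
  conc <- stage("concordance", qtlConcordance(eq, rd))
  nE <- sum(qtlResults(eq)$significant)
  nR <- sum(qtlResults(rd)$significant)
  joint <- sum(qtlResults(eq)$significant &
               qtlResults(eq)$gene_id %in%
                 qtlResults(rd)$gene_id[qtlResults(rd)$significant])
  nGenes <- nrow(qtlResults(eq))
  ov <- stage("overlap", list(
    nEqtl = nE, nRdqtl = nR, nJoint = joint, nGenes = nGenes,
    expected = expectedOverlap(nE, nR, nGenes, observed = joint)))
  counts$fastGenes <- sum(cls$class == "fast")
  counts$slowGenes <- sum(cls$class == "slow")
  counts$assocSignificant <- sum(assoc$significant, na.rm = TRUE)
  counts$rdqtl <- nR
  counts$eqtl <- nE
  manifest <- list(parameters = cfg[setdiff(names(cfg), "study")],
                   seed = cfg$seed, counts = counts,
                   inputs = as.list(tools::md5sum(inputs)))
  out <- list(decay = dm, classification = cls, steadyState = ss,
              association = assoc, rdqtl = rd, eqtl = eq,
              concordance = conc, overlap = ov, manifest = manifest)
  if (!is.null(cfg$outDir)) {
    dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
    w <- function(d, f) utils::write.table(
      d, file.path(cfg$outDir, f), sep = "\t", quote = FALSE,
      row.names = FALSE)
    kd <- decayRates(dm)
    w(data.frame(gene_id = rep(rownames(kd), ncol(kd)),
                 individual_id = rep(colnames(kd), each = nrow(kd)),
                 k = as.vector(kd),
                 se = as.vector(decaySE(dm)),
                 p = as.vector(decayPvalues(dm))), "decay_matrix.tsv")
    w(cls, "decay_classes.tsv")
    w(assoc, "association.tsv")
    w(as.data.frame(qtlResults(rd)), "rdqtl.tsv")
    w(as.data.frame(qtlResults(eq)), "eqtl.tsv")
    w(conc, "concordance.tsv")
    jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
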