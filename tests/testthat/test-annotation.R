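test_that("GTF parsing round-trips exon coordinates on both strands", {
  dir <- withr::local_tempdir()
  ann <- generateAnnotation(8, list(ejc = 0.5, uorf = 0.25), seed = 101,
                            outDir = dir)
  models <- parseTranscriptModels(ann$gtfFile, ann$fastaFile)
  expect_length(models, 8)

  for (m in models) {
    tp <- seq.int(0L, transcriptLength(m) - 1L)
    gp <- transcriptToGenomic(m, tp)
    expect_false(anyNA(gp))
    expect_identical(genomicToTranscript(m, gp), tp)
    # intronic position maps to NA on multi-exon transcripts
    if (nrow(m@exons) > 1) {
      gapPos <- if (m@strand == "+") m@exons[1, 2] else m@exons[1, 1] - 1L
      expect_true(is.na(genomicToTranscript(m, gapPos)))
    }
  }
  strands <- vapply(models, function(m) m@strand, character(1))
  expect_setequal(unique(strands), c("+", "-"))

  # minus-strand exons reported 5'->3' in transcript orientation
  minus <- models[[which(strands == "-")[1]]]
  expect_true(all(diff(minus@exons[, 1]) < 0))
})

test_that("transcripts without CDS are skipped with a warning and missing chromosomes error", {
  dir <- withr::local_tempdir()
  ann <- generateAnnotation(4, list(ejc = 0), seed = 5, outDir = dir)
  # append an exon-only transcript
  extra <- paste("chrS", "toy", "exon", 10, 60, ".", "+", ".",
                 'gene_id "GX"; transcript_id "GX.T1";', sep = "\t")
  gtf2 <- file.path(dir, "plus_noncds.gtf")
  writeLines(c(ann$gtfLines, extra), gtf2)
  expect_warning(models <- parseTranscriptModels(gtf2, ann$fastaFile),
                 "no CDS")
  expect_false("GX.T1" %in% names(models))
  expect_length(models, 4)

  bad <- paste("chrMISSING", "toy", "exon", 10, 60, ".", "+", ".",
               'gene_id "GY"; transcript_id "GY.T1";', sep = "\t")
  gtf3 <- file.path(dir, "badchrom.gtf")
  writeLines(c(ann$gtfLines, bad), gtf3)
  expect_error(parseTranscriptModels(gtf3, ann$fastaFile), "chrMISSING")
})

test_that("uORF detection requires in-UTR termination and minimum length", {
  # 5'UTR: 10 nt pad + ATG + 8 codons + TAA (30 nt uORF) + pad
  pad <- strrep("C", 10)
  uorf <- paste0("ATG", strrep("GGC", 8), "TAA")
  utr5 <- paste0(pad, uorf, strrep("C", 7))
  cds <- paste0("ATG", strrep("GGC", 20), "TGA")
  utr3 <- strrep("GCAT", 30)
  tx <- paste0(utr5, cds, utr3)
  genome <- Biostrings::DNAStringSet(setNames(tx, "chrU"))
  model <- TranscriptModel("U.T1", "U", "chrU", "+",
                           matrix(c(0L, nchar(tx)), 1), nchar(utr5),
                           nchar(utr5) + nchar(cds))
  prof <- annotateNmdFeatures(model, genome)
  expect_identical(prof$nQualifyingUorfs, 1L)
  expect_identical(prof$uorfs$start, 10L)
  expect_identical(prof$uorfs$length, 30L)

  # 29-nt ORF (7 inner codons) falls below the 30 nt minimum
  short <- paste0(pad, "ATG", strrep("GGC", 7), "TAA", strrep("C", 7))
  tx2 <- paste0(short, cds, utr3)
  g2 <- Biostrings::DNAStringSet(setNames(tx2, "chrU"))
  m2 <- TranscriptModel("U.T2", "U", "chrU", "+",
                        matrix(c(0L, nchar(tx2)), 1), nchar(short),
                        nchar(short) + nchar(cds))
  expect_identical(annotateNmdFeatures(m2, g2)$nQualifyingUorfs, 0L)

  # an AUG whose frame reaches the CDS without a stop is not a uORF
  noStop <- paste0(pad, "ATG", strrep("GGC", 9))  # runs into the CDS
  tx3 <- paste0(noStop, cds, utr3)
  g3 <- Biostrings::DNAStringSet(setNames(tx3, "chrU"))
  m3 <- TranscriptModel("U.T3", "U", "chrU", "+",
                        matrix(c(0L, nchar(tx3)), 1), nchar(noStop),
                        nchar(noStop) + nchar(cds))
  expect_identical(annotateNmdFeatures(m3, g3)$nQualifyingUorfs, 0L)
})

test_that("3'UTR EJC detection uses a strict 50 nt rule and GC is computed", {
  dir <- withr::local_tempdir()
  ann <- generateAnnotation(12, list(ejc = 0.5, uorf = 0.25), seed = 77,
                            outDir = dir)
  models <- parseTranscriptModels(ann$gtfFile, ann$fastaFile)
  ft <- annotateNmdFeatureTable(models)
  chk <- merge(ft, ann$truth, by = "transcript_id")
  expect_equal(chk$has_3utr_ejc, chk$has_3utr_ejc_truth)
  expect_equal(chk$n_qualifying_uorfs, chk$n_uorfs_truth)
  # boundary transcripts: junction at 40 and 50 nt are not triggers, 60 is
  b <- chk[chk$label == "boundary", ]
  expect_identical(b$has_3utr_ejc[order(b$ejc_distance_truth)],
                   c(FALSE, FALSE, TRUE))
  expect_true(all(chk$utr3_gc >= 0 & chk$utr3_gc <= 1))

  # empty 3'UTR: GC undefined, no EJC
  tx <- paste0(strrep("C", 12), "ATG", strrep("GGC", 10), "TGA")
  g <- Biostrings::DNAStringSet(setNames(tx, "chrU"))
  m <- TranscriptModel("E.T1", "E", "chrU", "+",
                       matrix(c(0L, nchar(tx)), 1), 12L, nchar(tx))
  p <- annotateNmdFeatures(m, g)
  expect_false(p$utr3Defined)
  expect_true(is.na(p$utr3Gc))
  expect_false(p$has3UtrEjc)
})

test_that("feature detection is strand-symmetric", {
  dir <- withr::local_tempdir()
  ann <- generateAnnotation(6, list(ejc = 0.5, uorf = 0.5), seed = 31,
                            outDir = dir)
  models <- parseTranscriptModels(ann$gtfFile, ann$fastaFile)
  genome <- attr(models, "genome")
  # reverse-complement the whole chromosome and flip every model
  rcGenome <- Biostrings::reverseComplement(genome)
  L <- Biostrings::width(genome)[1]
  for (m in models) {
    ex <- m@exons
    flipped <- TranscriptModel(
      m@transcriptId, m@geneId, m@chrom,
      if (m@strand == "+") "-" else "+",
      cbind(L - ex[, 2L], L - ex[, 1L]),
      m@cdsStart, m@cdsEnd)
    p1 <- annotateNmdFeatures(m, genome)
    p2 <- annotateNmdFeatures(flipped, rcGenome)
    expect_identical(p1$nQualifyingUorfs, p2$nQualifyingUorfs)
    expect_identical(p1$has3UtrEjc, p2$has3UtrEjc)
    expect_identical(p1$ejcDistancesNt, p2$ejcDistancesNt)
    expect_equal(p1$utr3Gc, p2$utr3Gc)
  }
})

test_that("gene sets follow the >=2-studies consensus rule and controls avoid study genes", {
  studies <- list(tani = c("g1", "g2", "g3"),
                  colombo = c("g2", "g3", "g4"),
                  karousis = c("g3", "g5"))
  features <- data.frame(
    gene_id = c(paste0("g", 1:5), paste0("f", 1:30), paste0("n", 1:30)),
    has_features = c(rep(TRUE, 5), rep(TRUE, 30), rep(FALSE, 30)))
  sets <- buildGeneSets(studies, features, nRandom = 10, rngSeed = 4)
  expect_setequal(sets$consensus, c("g2", "g3"))
  expect_setequal(sets$all, paste0("g", 1:5))
  expect_false(any(sets$random_with_features %in% sets$all))
  expect_false(any(sets$random_without_features %in% sets$all))
  expect_true(all(sets$random_with_features %in% paste0("f", 1:30)))
  expect_true(all(sets$random_without_features %in% paste0("n", 1:30)))
  expect_error(buildGeneSets(studies, features, nRandom = 100),
               "larger than eligible pool")
  expect_error(buildGeneSets(studies[1], features), "at least 2")
})

test_that("target/control pair selection enforces thresholds, GC tie-break and the 0.9 ratio", {
  base <- data.frame(
    transcript_id = c("tA", "tB", "ctrl"),
    gene_id = "G",
    median_log_tpm = c(1.5, 1.5, 3.2),
    has_3utr_ejc = c(TRUE, TRUE, FALSE),
    n_qualifying_uorfs = c(0L, 0L, 0L),
    utr3_gc = c(0.55, 0.62, 0.4))
  pair <- selectTargetControlPairs(base)
  expect_identical(pair$target_id, "tB")     # highest 3'UTR GC wins
  expect_identical(pair$control_id, "ctrl")
  expect_lt(pair$expression_ratio, 0.9)

  # ratio above 0.9 -> no pair (target at log TPM 3.15 vs control 3.2)
  hot <- base; hot$median_log_tpm <- c(3.1, 3.15, 3.2)
  expect_null(selectTargetControlPairs(hot))

  # target below expression threshold -> no pair
  low <- base; low$median_log_tpm[1:2] <- 0.5
  expect_null(selectTargetControlPairs(low))

  # control with features is not eligible
  feat <- base; feat$has_3utr_ejc[3] <- TRUE
  expect_null(selectTargetControlPairs(feat))

  # >= 2 uORFs qualify a target without an EJC
  uorf <- base
  uorf$has_3utr_ejc <- c(FALSE, FALSE, FALSE)
  uorf$n_qualifying_uorfs <- c(2L, 0L, 0L)
  expect_identical(selectTargetControlPairs(uorf)$target_id, "tA")

  # wild-type cell-line ratio above 0.9 vetoes the pair
  expect_null(selectTargetControlPairs(
    base, wildtypeCelllineRatios = c(tB = 0.95)))
  expect_identical(
    selectTargetControlPairs(base,
                             wildtypeCelllineRatios = c(tB = 0.8))$target_id,
    "tB")
})
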