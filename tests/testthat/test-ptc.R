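# Variants are constructed on generator transcripts and checked against the
# naive mutate-and-translate oracle; classification is checked against direct
# position arithmetic over every nt of toy transcripts.

makeVariantAt <- function(model, genome, t0, type = c("snv_stop", "del1",
                                                      "ins1", "del3")) {
  type <- match.arg(type)
  txSeq <- as.character(splicedSequence(model, genome))
  chromSeq <- as.character(genome[[model@chrom]])
  refBaseAt <- function(g0) substr(chromSeq, g0 + 1, g0 + 1)
  if (type == "snv_stop") {
    # force the codon containing t0 to TGA by editing its first base to T,
    # second to G, third to A — pick the single base that completes a stop
    k <- (t0 - model@cdsStart) %/% 3
    codStart <- model@cdsStart + 3 * k
    cod <- substr(txSeq, codStart + 1, codStart + 3)
    for (i in 1:3) for (b in c("T", "G", "A")) {
      cand <- cod
      substr(cand, i, i) <- b
      if (cand %in% c("TAA", "TAG", "TGA") && cand != cod) {
        tpos <- codStart + i - 1
        g0 <- transcriptToGenomic(model, tpos)
        refG <- refBaseAt(g0)
        altG <- if (model@strand == "+") b else
          as.character(Biostrings::reverseComplement(Biostrings::DNAString(b)))
        return(list(chrom = model@chrom, pos = g0 + 1, ref = refG, alt = altG,
                    txPos0 = tpos, refT = substr(txSeq, tpos + 1, tpos + 1),
                    altT = b))
      }
    }
    return(NULL)
  }
  nDel <- switch(type, del1 = 1L, del3 = 3L, ins1 = 0L)
  # anchor at the base before t0 (transcript orientation), VCF-style
  anchor0 <- t0 - 1L
  span0 <- anchor0:(anchor0 + nDel)           # transcript positions of ref
  gpos <- transcriptToGenomic(model, span0)
  if (anyNA(gpos) || (length(gpos) > 1 && any(abs(diff(gpos)) != 1)))
    return(NULL)                               # edit crosses a junction
  refT <- substr(txSeq, anchor0 + 1, anchor0 + 1 + nDel)
  altT <- if (type == "ins1") paste0(substr(refT, 1, 1), "G")
          else substr(refT, 1, 1)
  if (model@strand == "+") {
    pos <- min(gpos) + 1
    ref <- refT; alt <- altT
  } else {
    pos <- min(gpos) + 1
    ref <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(refT)))
    alt <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(altT)))
  }
  list(chrom = model@chrom, pos = pos, ref = ref, alt = alt,
       txPos0 = anchor0, refT = refT, altT = altT)
}

test_that("indel and nonsense PTC prediction matches mutate-and-translate on a constructed fixture", {
  dir <- withr::local_tempdir()
  ann <- generateAnnotation(10, list(ejc = 0.4, uorf = 0.2), seed = 202,
                            outDir = dir)
  models <- parseTranscriptModels(ann$gtfFile, ann$fastaFile)
  genome <- attr(models, "genome")

  nChecked <- 0
  for (m in models) {
    txSeq <- as.character(splicedSequence(m, genome))
    cdsLen <- m@cdsEnd - m@cdsStart
    offsets <- c(12L, 31L, 62L, 100L)
    offsets <- offsets[offsets < cdsLen - 6L]
    for (off in offsets) for (type in c("del1", "ins1", "del3")) {
      v <- makeVariantAt(m, genome, m@cdsStart + off, type)
      if (is.null(v)) next
      p <- predictPtc(v[c("chrom", "pos", "ref", "alt")], m, genome)
      oracle <- bruteMutateTranslate(txSeq, m@cdsStart, cdsLen,
                                     v$txPos0, v$refT, v$altT)
      expect_identical(p$has_ptc, !is.na(oracle),
                       info = sprintf("%s %s off=%d", m@transcriptId, type, off))
      if (p$has_ptc) expect_identical(p$ptc_cds_pos_nt, oracle)
      nChecked <- nChecked + 1
    }
    # one forced nonsense SNV per transcript
    v <- makeVariantAt(m, genome, m@cdsStart + 60L, "snv_stop")
    if (!is.null(v)) {
      p <- predictPtc(v[c("chrom", "pos", "ref", "alt")], m, genome)
      expect_true(p$has_ptc)
      expect_identical(p$ptc_cds_pos_nt, (60L %/% 3L) * 3L + 1L)
      # the genomic position maps back onto the stop codon's first nt
      expect_identical(
        genomicToTranscript(m, p$ptc_genomic_pos - 1L),
        m@cdsStart + (60L %/% 3L) * 3L)
      nChecked <- nChecked + 1
    }
  }
  expect_gte(nChecked, 25)
})

test_that("a nonsense SNV at codon 100 yields a PTC at CDS nt 298", {
  codons <- rep("GGC", 120)
  codons[99] <- "TAC"                 # codon 100 of the CDS (after ATG)
  cds <- paste0("ATG", paste(codons, collapse = ""), "TGA")
  tx <- paste0(strrep("C", 20), cds, strrep("GCAT", 20))
  genome <- Biostrings::DNAStringSet(setNames(tx, "chrU"))
  m <- TranscriptModel("N.T1", "N", "chrU", "+",
                       matrix(c(0L, nchar(tx)), 1), 20L, 20L + nchar(cds))
  # codon 100 occupies CDS nt 298-300 = TAC; C->A makes the TAA stop
  v <- list(chrom = "chrU", pos = 20L + 300L, ref = "C", alt = "A")
  p <- predictPtc(v, m, genome)
  expect_true(p$has_ptc)
  expect_identical(p$ptc_cds_pos_nt, 298L)
  expect_identical(p$ptc_genomic_pos, 20L + 298L)
})

test_that("in-frame deletions without a new stop yield no PTC and non-CDS variants error", {
  tx <- paste0(strrep("C", 15), "ATG", strrep("GGCTACGAC", 30), "TGA",
               strrep("GCAT", 25))
  genome <- Biostrings::DNAStringSet(setNames(tx, "chrU"))
  cdsLen <- 3L + 270L + 3L
  m <- TranscriptModel("D.T1", "D", "chrU", "+",
                       matrix(c(0L, nchar(tx)), 1), 15L, 15L + cdsLen)
  # 3-bp in-frame deletion of one GGC-TAC-GAC-aligned codon
  anchor <- 15L + 3L + 8L  # 0-based
  v <- list(chrom = "chrU", pos = anchor + 1,
            ref = substr(tx, anchor + 1, anchor + 4),
            alt = substr(tx, anchor + 1, anchor + 1))
  p <- predictPtc(v, m, genome)
  expect_false(p$has_ptc)
  expect_false(p$frameshift)
  # variant in the 3'UTR errors distinguishably
  vOut <- list(chrom = "chrU", pos = 15L + cdsLen + 10L, ref = "G", alt = "A")
  vOut$ref <- substr(tx, vOut$pos, vOut$pos)
  expect_error(predictPtc(vOut, m, genome), "outside the CDS")
})

test_that("PTC classification agrees with brute-force position arithmetic on every nt", {
  cases <- list(
    list(exonLens = c(120L, 300L, 90L, 200L), hasEjc = FALSE),
    list(exonLens = c(120L, 300L, 90L, 200L), hasEjc = TRUE),
    list(exonLens = c(260L, 700L, 1100L, 80L, 150L), hasEjc = FALSE),
    list(exonLens = c(260L, 700L, 1100L, 80L, 150L), hasEjc = TRUE),
    list(exonLens = c(400L, 501L, 999L, 1000L, 60L), hasEjc = FALSE))
  ruleSets <- list(aseRules(), dndsRules())
  for (cs in cases) {
    m <- makeToyModel(cs$exonLens, cdsStartNt = 10L,
                      cdsLenNt = sum(cs$exonLens) - 40L)
    profile <- list(has3UtrEjc = cs$hasEjc)
    for (rules in ruleSets) {
      got <- vapply(seq_len(transcriptLength(m)) - 1L, function(p0)
        classifyPtcNmd(p0, m, profile, rules), character(1))
      want <- vapply(seq_len(transcriptLength(m)), function(p1)
        bruteClassify(p1, cs$exonLens, cs$hasEjc, rules), character(1))
      expect_identical(got, want,
                       info = sprintf("exons=%s ejc=%s rules=%s",
                                      paste(cs$exonLens, collapse = ","),
                                      cs$hasEjc, rules@name))
    }
  }
})

test_that("rule-set boundary calls match the printed rules", {
  m <- makeToyModel(c(300L, 700L, 400L, 250L), 10L, 1500L)
  noEjc <- list(has3UtrEjc = FALSE)
  ejc <- list(has3UtrEjc = TRUE)
  lens <- c(300L, 700L, 400L, 250L)
  lastExonPos0 <- sum(lens[1:3]) + 50L
  # last exon, no EJC -> evading; with a 3'UTR splice site -> triggering
  expect_identical(classifyPtcNmd(lastExonPos0, m, noEjc, aseRules()),
                   "evading")
  expect_identical(classifyPtcNmd(lastExonPos0, m, ejc, aseRules()),
                   "triggering")
  # within first ~200 nt -> evading regardless of EJC
  expect_identical(classifyPtcNmd(99L, m, ejc, aseRules()), "evading")
  expect_identical(classifyPtcNmd(200L - 1L, m, noEjc, aseRules()), "evading")
  expect_identical(classifyPtcNmd(200L, m, noEjc, aseRules()), "triggering")
  # last 55 nt of the penultimate exon
  penultEnd <- sum(lens[1:3])
  expect_identical(classifyPtcNmd(penultEnd - 55L, m, noEjc, aseRules()),
                   "evading")
  expect_identical(classifyPtcNmd(penultEnd - 56L, m, noEjc, aseRules()),
                   "triggering")
  # dnds: PTC in a 700-nt internal exon, 300 nt from the TSS -> buffer
  expect_identical(classifyPtcNmd(299L + 1L, m, noEjc, dndsRules()), "buffer")
  # dnds start-proximal threshold is 250 nt
  expect_identical(classifyPtcNmd(249L, m, noEjc, dndsRules()), "evading")
})
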