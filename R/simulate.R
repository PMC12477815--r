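#' Deterministic child seeds
#'
#' One global seed fans out to per-component child seeds via a fixed
#' counter scheme, so adding a component never perturbs the streams of
#' existing ones. Values stay below 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param component character component name.
#' @param counter integer stream counter within the component.
#' @return integer child seed.
#' @export
childSeed <- function(seed, component, counter = 0L) {
  h <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)))
  as.integer((as.numeric(seed) * 48271 + h * 9973 + counter * 101) %% 2147483647)
}

# sequence helpers: A-free alphabet keeps planted uORF counts exact
.randChars <- function(n, alphabet) paste(sample(alphabet, n, replace = TRUE),
                                          collapse = "")
.NONSTOP_AFREE <- {
  cods <- as.vector(outer(as.vector(outer(c("C", "G", "T"), c("C", "G", "T"),
                                          paste0)), c("C", "G", "T"), paste0))
  setdiff(cods, c("TAA", "TAG", "TGA"))
}
.NONSTOP_ALL <- {
  b <- c("A", "C", "G", "T")
  cods <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
  setdiff(cods, c("TAA", "TAG", "TGA"))
}
.revcomp <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

#' Generate a toy annotated genome with planted NMD features
#'
#' Builds a deterministic multi-gene locus: one coding transcript per gene,
#' multi-exon, alternating strands, with constructed 5'UTR uORFs and 3'UTR
#' exon-exon junctions at controlled distances downstream of the stop codon.
#' When at least three genes are requested, boundary-case transcripts with a
#' 3'UTR junction at exactly 40, 50 and 60 nt are always included (only the
#' 60 nt one is a true EJC trigger under the strict > 50 nt rule). The truth
#' table records the planted feature of every transcript.
#'
#' @param nGenes number of genes.
#' @param featureMix list of fractions \code{ejc}, \code{uorf} (remainder:
#'   featureless). Must sum to <= 1.
#' @param seed integer seed (full determinism: identical output bytes for
#'   identical inputs).
#' @param outDir optional directory; when given, \code{genes.gtf},
#'   \code{genome.fa} and \code{truth.tsv} are written there.
#' @return list: \code{gtfLines}, \code{fastaLines}, \code{truth} data.frame
#'   (\code{transcript_id}, \code{gene_id}, \code{strand}, \code{label},
#'   \code{n_uorfs_truth}, \code{ejc_distance_truth},
#'   \code{has_3utr_ejc_truth}), and file paths when \code{outDir} is set.
#' @export
generateAnnotation <- function(nGenes, featureMix = list(ejc = 0.4, uorf = 0.3),
                               seed = 1L, outDir = NULL) {
  fEjc <- featureMix$ejc %||% 0
  fUorf <- featureMix$uorf %||% 0
  if (fEjc + fUorf > 1) stop("infeasible feature mix: fractions sum to > 1")
  set.seed(childSeed(seed, "annotation"))

  nEjc <- round(fEjc * nGenes)
  nUorf <- round(fUorf * nGenes)
  labels <- c(rep("ejc", nEjc), rep("uorf", nUorf),
              rep("none", nGenes - nEjc - nUorf))
  # boundary cases ride on top of the first genes when there is room
  ejcDist <- ifelse(labels == "ejc", 60L, NA_integer_)
  if (nGenes >= 3L) {
    boundary <- c(40L, 50L, 60L)
    for (i in 1:3) { labels[i] <- "boundary"; ejcDist[i] <- boundary[i] }
  }
  extraEjc <- which(labels == "ejc")
  if (length(extraEjc) > 1L)   # vary distances above the boundary
    ejcDist[extraEjc] <- 60L + 10L * (seq_along(extraEjc) - 1L)

  chromName <- "chrS"
  chromParts <- character(0)
  offset <- 50L
  pad0 <- .randChars(50L, c("C", "G", "T"))
  chromParts <- pad0
  gtf <- character(0)
  truth <- vector("list", nGenes)

  for (g in seq_len(nGenes)) {
    lab <- labels[g]
    strand <- if (g %% 2L == 0L) "-" else "+"
    gid <- sprintf("G%03d", g)
    tid <- sprintf("%s.T1", gid)

    nUorfsHere <- if (lab == "uorf") 2L else 0L
    utr5 <- .randChars(25L, c("C", "G", "T"))
    if (nUorfsHere == 2L) {
      mkUorf <- function(nCodonsInner)
        paste0("ATG", paste(sample(.NONSTOP_AFREE, nCodonsInner, TRUE),
                            collapse = ""), "TAA")
      utr5 <- paste0(utr5, mkUorf(8L), strrep("C", 6L), mkUorf(10L),
                     strrep("C", 5L))
    }
    nCodons <- sample(40:70, 1L)
    cds <- paste0("ATG", paste(sample(.NONSTOP_ALL, nCodons, TRUE),
                               collapse = ""), "TGA")
    utr3Len <- 140L
    utr3 <- .randChars(utr3Len, c("A", "C", "G", "T"))
    tx <- paste0(utr5, cds, utr3)
    cdsStart <- nchar(utr5)
    cdsEnd <- cdsStart + nchar(cds)
    txLen <- nchar(tx)

    # junctions in transcript coordinates (0-based boundary positions)
    junctions <- c(cdsStart + 33L, cdsStart + 90L)
    if (!is.na(ejcDist[g])) junctions <- c(junctions, cdsEnd + ejcDist[g])
    junctions <- sort(unique(junctions[junctions > 0 & junctions < txLen]))

    bounds <- c(0L, junctions, txLen)
    exLensTx <- diff(bounds)
    introns <- vapply(seq_len(length(exLensTx) - 1L),
                      function(i) .randChars(sample(60:120, 1L),
                                             c("A", "C", "G", "T")),
                      character(1))
    exSeqs <- substring(tx, bounds[-length(bounds)] + 1L, bounds[-1L])
    pieces <- character(0)
    for (i in seq_along(exSeqs)) {
      pieces <- c(pieces, exSeqs[i])
      if (i < length(exSeqs)) pieces <- c(pieces, introns[i])
    }
    geneBlockTx <- paste(pieces, collapse = "")
    blockLen <- nchar(geneBlockTx)

    # genomic exon intervals (0-based half-open), transcript order
    cum <- 0L
    exG <- matrix(0L, nrow = length(exSeqs), ncol = 2L)
    for (i in seq_along(exSeqs)) {
      exG[i, ] <- c(cum, cum + nchar(exSeqs[i]))
      cum <- cum + nchar(exSeqs[i]) +
        if (i < length(exSeqs)) nchar(introns[i]) else 0L
    }
    if (strand == "+") {
      block <- geneBlockTx
      exGen <- exG + offset
    } else {
      block <- .revcomp(geneBlockTx)
      exGen <- cbind(blockLen - exG[, 2L], blockLen - exG[, 1L]) + offset
    }

    # GTF records (1-based closed); exon order as in transcript orientation
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; transcript_biotype "protein_coding";',
                     gid, tid)
    for (i in seq_len(nrow(exGen)))
      gtf <- c(gtf, paste(chromName, "toy", "exon",
                          exGen[i, 1L] + 1L, exGen[i, 2L], ".", strand, ".",
                          attrs, sep = "\t"))
    # CDS segments: overlap of [cdsStart, cdsEnd) with each transcript exon
    for (i in seq_along(exSeqs)) {
      s <- max(bounds[i], cdsStart); e <- min(bounds[i + 1L], cdsEnd)
      if (s >= e) next
      offIn <- s - bounds[i]; lenIn <- e - s
      if (strand == "+") {
        gs <- exGen[i, 1L] + offIn
        ge <- gs + lenIn
      } else {
        ge <- exGen[i, 2L] - offIn
        gs <- ge - lenIn
      }
      gtf <- c(gtf, paste(chromName, "toy", "CDS",
                          gs + 1L, ge, ".", strand, ".", attrs, sep = "\t"))
    }

    chromParts <- c(chromParts, block,
                    .randChars(100L, c("C", "G", "T")))
    offset <- offset + blockLen + 100L

    truth[[g]] <- data.frame(
      transcript_id = tid, gene_id = gid, strand = strand, label = lab,
      n_uorfs_truth = nUorfsHere,
      ejc_distance_truth = ejcDist[g],
      has_3utr_ejc_truth = !is.na(ejcDist[g]) && ejcDist[g] > 50L)
  }

  chromSeq <- paste(chromParts, collapse = "")
  fastaLines <- c(paste0(">", chromName),
                  substring(chromSeq,
                            seq(1L, nchar(chromSeq), 70L),
                            pmin(seq(1L, nchar(chromSeq), 70L) + 69L,
                                 nchar(chromSeq))))
  truth <- do.call(rbind, truth)
  out <- list(gtfLines = gtf, fastaLines = fastaLines, truth = truth)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    out$gtfFile <- file.path(outDir, "genes.gtf")
    out$fastaFile <- file.path(outDir, "genome.fa")
    out$truthFile <- file.path(outDir, "truth.tsv")
    writeLines(gtf, out$gtfFile)
    writeLines(fastaLines, out$fastaFile)
    write.table(truth, out$truthFile, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  out
}

#' Specification of a simulated multi-tissue cohort
#'
#' Draws one ground-truth NMD efficiency per sample:
#' \code{eta = baseEta + tissue effect + N(0, individualEffectSd)}.
#'
#' @param tissues data.frame with columns \code{name}, \code{nSamples},
#'   \code{delta} (tissue-level efficiency shift).
#' @param baseEta cohort baseline efficiency (natural-log scale).
#' @param individualEffectSd per-sample effect SD.
#' @param theta negative-binomial dispersion of downstream count simulators.
#' @param depth mean reads per transcript/locus.
#' @param seed integer seed.
#' @return list of class \code{CohortSpec}: \code{samples} data.frame
#'   (\code{sample_id}, \code{tissue}, \code{eta}), \code{theta},
#'   \code{depth}, \code{seed}.
#' @export
cohortSpec <- function(tissues, baseEta = 1, individualEffectSd = 0.3,
                       theta = 10, depth = 100, seed = 1L) {
  stopifnot(theta > 0, depth > 0)
  set.seed(childSeed(seed, "cohort"))
  rows <- lapply(seq_len(nrow(tissues)), function(i) {
    n <- tissues$nSamples[i]
    data.frame(
      sample_id = sprintf("%s_S%03d", tissues$name[i], seq_len(n)),
      tissue = tissues$name[i],
      eta = baseEta + tissues$delta[i] + rnorm(n, 0, individualEffectSd))
  })
  structure(list(samples = do.call(rbind, rows), theta = theta,
                 depth = depth, seed = as.integer(seed)),
            class = "CohortSpec")
}

#' Simulate ETG transcript counts for a cohort
#'
#' Inverts the ETG model: for each gene pair, the control transcript count is
#' \code{NB(mean = baseline_g * depth * libFactor_s, theta)} and the target
#' count is the same mean attenuated by \code{exp(-eta_s)}. Gene baselines are
#' log-normal; optional per-sample library-size factors are log-normal too.
#'
#' @param eta named numeric vector of per-sample true efficiencies.
#' @param nPairs number of target/control pairs.
#' @param depth mean control reads per transcript.
#' @param theta NB dispersion.
#' @param seed integer seed.
#' @param baselineSdLog SD of log gene baselines.
#' @param librarySdLog SD of log library-size factors (0 disables).
#' @return list: \code{counts} (transcripts x samples integer matrix),
#'   \code{pairs} (gene_id, target_id, control_id),
#'   \code{transcriptInfo}, and \code{manifest} (per-sample eta, seeds,
#'   baselines, library factors).
#' @export
simulateEtgCounts <- function(eta, nPairs = 50L, depth = 100, theta = 10,
                              seed = 1L, baselineSdLog = 0.5,
                              librarySdLog = 0) {
  set.seed(childSeed(seed, "etg_counts"))
  nS <- length(eta)
  samples <- names(eta) %||% sprintf("S%03d", seq_len(nS))
  genes <- sprintf("G%04d", seq_len(nPairs))
  baseline <- rlnorm(nPairs, meanlog = 0, sdlog = baselineSdLog)
  libf <- if (librarySdLog > 0) rlnorm(nS, 0, librarySdLog) else rep(1, nS)
  muC <- outer(baseline * depth, libf)                      # pairs x samples
  muT <- sweep(muC, 2L, exp(-eta), `*`)
  counts <- matrix(0L, 2L * nPairs, nS,
                   dimnames = list(c(paste0(genes, "_T"), paste0(genes, "_C")),
                                   samples))
  counts[seq_len(nPairs), ] <- rnbinom(nPairs * nS, mu = muT, size = theta)
  counts[nPairs + seq_len(nPairs), ] <- rnbinom(nPairs * nS, mu = muC,
                                                size = theta)
  pairs <- data.frame(gene_id = genes,
                      target_id = paste0(genes, "_T"),
                      control_id = paste0(genes, "_C"))
  txInfo <- data.frame(
    transcript_id = c(paste0(genes, "_T"), paste0(genes, "_C")),
    is_coding = TRUE,
    transcript_length = rep(1500L, 2L * nPairs))
  list(counts = counts, pairs = pairs, transcriptInfo = txInfo,
       manifest = list(eta = setNames(as.numeric(eta), samples),
                       baseline = setNames(baseline, genes),
                       libraryFactor = setNames(libf, samples),
                       depth = depth, theta = theta, seed = seed))
}

#' Simulate allele-specific expression counts at germline PTC loci
#'
#' For each individual, draws \code{nVariants} heterozygous loci; WT allele
#' counts are \code{NB(depth * locusFactor, theta)} and MUT counts use the
#' same mean attenuated by \code{exp(-eta)} for NMD-triggering PTCs (ratio 1
#' for evading and synonymous variants). Optionally plants filter-violating
#' variants (coverage 4, MAF 25\%, homozygous), flagged in the truth columns.
#'
#' @param eta named numeric per-individual efficiencies.
#' @param nVariants variants per individual.
#' @param classMix named fractions over \code{triggering}, \code{evading},
#'   \code{synonymous} (must sum to 1).
#' @param depth mean coverage per allele.
#' @param theta NB dispersion.
#' @param seed integer seed.
#' @param plantViolations integer count of filter-violating variants to add
#'   per individual (0 disables).
#' @return data.frame of variants across individuals with allele counts, the
#'   filter annotation columns consumed by \code{\link{filterAseVariants}},
#'   and truth columns \code{true_class}, \code{planted_violation}.
#' @export
simulateAseCounts <- function(eta, nVariants = 10L,
                              classMix = c(triggering = 1, evading = 0,
                                           synonymous = 0),
                              depth = 30, theta = 10, seed = 1L,
                              plantViolations = 0L) {
  stopifnot(abs(sum(classMix) - 1) < 1e-9)
  set.seed(childSeed(seed, "ase_counts"))
  samples <- names(eta) %||% sprintf("S%03d", seq_along(eta))
  classes <- rep(names(classMix), round(classMix * nVariants))
  classes <- c(classes, rep(names(classMix)[1],
                            max(0L, nVariants - length(classes))))[1:nVariants]
  out <- vector("list", length(eta))
  for (s in seq_along(eta)) {
    locusFactor <- rlnorm(nVariants, 0, 0.3)
    muW <- depth * locusFactor
    atten <- ifelse(classes == "triggering", exp(-eta[s]), 1)
    wt <- rnbinom(nVariants, mu = muW, size = theta)
    mut <- rnbinom(nVariants, mu = muW * atten, size = theta)
    v <- data.frame(
      individual_id = samples[s],
      variant_id = sprintf("%s_v%03d", samples[s], seq_len(nVariants)),
      gene_id = sprintf("AG%03d", seq_len(nVariants)),
      variant_class = ifelse(classes == "synonymous", "synonymous",
                             "nonsense"),
      nmd_class = ifelse(classes == "synonymous", "none", classes),
      filter_status = "PASS", genotype = "het",
      population_maf = runif(nVariants, 0, 0.15),
      gene_loeuf_percentile = runif(nVariants, 0.15, 1),
      wt_count = wt, mut_count = mut,
      n_exons = 3L, is_coding = TRUE,
      true_class = classes, planted_violation = "none")
    if (plantViolations > 0L) {
      kinds <- rep(c("coverage", "maf", "homozygous"),
                   length.out = plantViolations)
      pv <- data.frame(
        individual_id = samples[s],
        variant_id = sprintf("%s_bad%02d", samples[s],
                             seq_len(plantViolations)),
        gene_id = sprintf("BAD%02d", seq_len(plantViolations)),
        variant_class = "nonsense", nmd_class = "triggering",
        filter_status = "PASS",
        genotype = ifelse(kinds == "homozygous", "hom", "het"),
        population_maf = ifelse(kinds == "maf", 0.25, 0.05),
        gene_loeuf_percentile = 0.8,
        wt_count = ifelse(kinds == "coverage", 2L, 20L),
        mut_count = ifelse(kinds == "coverage", 2L, 10L),
        n_exons = 3L, is_coding = TRUE,
        true_class = "triggering", planted_violation = kinds)
      v <- rbind(v, pv)
    }
    out[[s]] <- v
  }
  do.call(rbind, out)
}

#' Simulate a GISTIC-style CNA matrix with planted segments
#'
#' Genes lie on one synthetic chromosome in index order. Each planted segment
#' assigns its carriers (a random sample fraction) a dosage score of about
#' \code{score} over the segment genes, plus Gaussian noise everywhere;
#' carriers' true NMD efficiency is decremented by the segment's
#' \code{etaEffect}.
#'
#' @param nGenes,nSamples matrix dimensions.
#' @param segments data.frame with columns \code{startGene}, \code{endGene}
#'   (1-based inclusive gene indices), \code{carrierFraction},
#'   \code{etaEffect}, optional \code{score} (default 1). Overlapping
#'   segments are an error.
#' @param baseEta baseline efficiency for all samples.
#' @param noiseSd score noise SD.
#' @param seed integer seed.
#' @return list: \code{gisticTable} (gene, chrom, start, arm, sample
#'   columns), \code{eta} (named per-sample efficiency after carrier
#'   decrements), \code{carriers} (logical matrix segments x samples),
#'   \code{manifest}.
#' @export
simulateCnaMatrix <- function(nGenes, nSamples, segments, baseEta = 1,
                              noiseSd = 0.05, seed = 1L) {
  if (nrow(segments) > 1L) {
    o <- order(segments$startGene)
    s <- segments[o, ]
    if (any(s$startGene[-1L] <= s$endGene[-nrow(s)]))
      stop("overlapping planted segments")
  }
  if (any(segments$endGene > nGenes)) stop("segment outside gene range")
  set.seed(childSeed(seed, "cna"))
  samples <- sprintf("S%03d", seq_len(nSamples))
  genes <- sprintf("CG%04d", seq_len(nGenes))
  scores <- matrix(rnorm(nGenes * nSamples, 0, noiseSd), nGenes, nSamples,
                   dimnames = list(genes, samples))
  eta <- setNames(rep(baseEta, nSamples), samples)
  carriers <- matrix(FALSE, nrow(segments), nSamples,
                     dimnames = list(NULL, samples))
  for (i in seq_len(nrow(segments))) {
    seg <- segments[i, ]
    segScore <- seg$score %||% 1
    if (is.na(segScore)) segScore <- 1
    nC <- round(seg$carrierFraction * nSamples)
    idx <- sample.int(nSamples, nC)
    carriers[i, idx] <- TRUE
    rows <- seg$startGene:seg$endGene
    scores[rows, idx] <- scores[rows, idx] + segScore
    eta[idx] <- eta[idx] - seg$etaEffect
  }
  gisticTable <- data.frame(gene = genes, chrom = "chrS",
                            start = seq_len(nGenes) * 1000L,
                            arm = "chrS_q", scores, check.names = FALSE)
  list(gisticTable = gisticTable, eta = eta, carriers = carriers,
       manifest = list(segments = segments, baseEta = baseEta,
                       noiseSd = noiseSd, seed = seed))
}

#' Write a ground-truth manifest as JSON
#'
#' @param manifest list (e.g. the \code{manifest} element of a simulator
#'   result).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeManifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
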