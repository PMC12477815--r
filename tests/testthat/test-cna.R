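makeGistic <- function(nGenes = 40, nSamples = 12, seed = 1) {
  set.seed(seed)
  tab <- data.frame(gene = sprintf("g%03d", 1:nGenes), chrom = "chr1",
                    start = (1:nGenes) * 1000L, arm = "1q")
  for (s in sprintf("S%02d", 1:nSamples))
    tab[[s]] <- round(rnorm(nGenes, 0, 0.4), 3)
  tab
}

test_that("gain/loss split reconstructs the original scores exactly", {
  tab <- makeGistic()
  gl <- buildGainLossMatrix(tab)
  sc <- glScores(gl)
  info <- glRowInfo(gl)
  amp <- sc[info$type == "amp", ]
  del <- sc[info$type == "del", ]
  expect_true(all(amp >= 0))
  expect_true(all(del <= 0))
  orig <- as.matrix(tab[, sprintf("S%02d", 1:12)])
  rownames(orig) <- tab$gene
  expect_equal(amp + del, orig, ignore_attr = TRUE)
  # +0.5 -> amp 0.5 / del 0; -0.3 -> amp 0 / del -0.3; 0 -> 0/0
  t2 <- tab; t2[1, "S01"] <- 0.5; t2[2, "S01"] <- -0.3; t2[3, "S01"] <- 0
  g2 <- buildGainLossMatrix(t2)
  s2 <- glScores(g2); i2 <- glRowInfo(g2)
  expect_identical(s2[i2$type == "amp" & i2$gene == "g001", "S01"], 0.5)
  expect_identical(s2[i2$type == "del" & i2$gene == "g001", "S01"], 0)
  expect_identical(s2[i2$type == "amp" & i2$gene == "g002", "S01"], 0)
  expect_identical(s2[i2$type == "del" & i2$gene == "g002", "S01"], -0.3)
  expect_identical(s2[i2$type == "amp" & i2$gene == "g003", "S01"], 0)
  # genes without coordinates are dropped with a warning
  t3 <- tab; t3$start[5] <- NA
  expect_warning(g3 <- buildGainLossMatrix(t3), "without coordinates")
  expect_false("g005" %in% glRowInfo(g3)$gene)
})

test_that("autocorrelation distinguishes blocks, noise and alternation", {
  block <- c(rep(0, 50), rep(0.7, 60), rep(0, 40))
  expect_gt(autocorrelationScore(block), 0.9)
  set.seed(5)
  noise <- rnorm(400)
  expect_lt(abs(autocorrelationScore(noise)), 2 / sqrt(400))
  alt <- rep(c(1, -1), 50)
  expect_equal(autocorrelationScore(alt), -1)
  const <- rep(0.5, 20)
  expect_identical(as.numeric(autocorrelationScore(const)), 0)
  expect_true(attr(autocorrelationScore(const), "constant"))
  expect_error(autocorrelationScore(c(1, 2)), "at least 3")
})

test_that("sparse PCA recovers a planted arm-level gain as one effective PC", {
  seg <- data.frame(startGene = 101, endGene = 300, carrierFraction = 0.3,
                    etaEffect = 0.3, score = 1)
  sim <- simulateCnaMatrix(1000, 120, seg, seed = 9)
  gl <- buildGainLossMatrix(sim$gisticTable)
  tune <- tuneSparsePca(gl, alphaGrid = c(0.05, 0.15, 0.3), kGrid = 5)
  eff <- which(vapply(tune$signatures, `[[`, logical(1), "effective"))
  expect_identical(length(eff), 1L)
  sig <- tune$signatures[[eff]]
  support <- which(sig$loadings != 0)
  planted <- which(glRowInfo(gl)$type == "amp")[101:300]
  jaccard <- length(intersect(support, planted)) /
    length(union(support, planted))
  expect_gte(jaccard, 0.9)
  expect_gt(sig$autocorrelation, 0.9)
  # sample scores separate carriers (point-biserial correlation)
  carrier <- sim$carriers[1, names(sig$sampleScores)]
  expect_gte(abs(cor(sig$sampleScores, as.numeric(carrier))), 0.9)
  # determinism without seeds
  tune2 <- tuneSparsePca(gl, alphaGrid = c(0.05, 0.15, 0.3), kGrid = 5)
  expect_identical(tune$signatures[[eff]]$loadings, sig$loadings)
})

test_that("alpha is a monotone sparsity control and pure noise warns", {
  seg <- data.frame(startGene = 21, endGene = 60, carrierFraction = 0.4,
                    etaEffect = 0, score = 1)
  sim <- simulateCnaMatrix(200, 60, seg, seed = 15)
  x <- glScores(buildGainLossMatrix(sim$gisticTable))
  nz <- vapply(c(0, 0.1, 0.3, 0.6, 0.9),
               function(a) sum(sparsePca(x, 2, a)$loadings[, 1] != 0),
               numeric(1))
  expect_true(all(diff(nz) <= 0))

  set.seed(21)
  noiseTab <- makeGistic(60, 30, seed = 33)
  glN <- buildGainLossMatrix(noiseTab)
  expect_warning(tuneN <- tuneSparsePca(glN, alphaGrid = 0.2, kGrid = 3,
                                        closenessThreshold = 0.9),
                 "threshold")
  expect_lt(tuneN$tuningScore, 0.5)
})

test_that("discovery/validation association replicates a planted effect with sign control", {
  set.seed(41)
  n <- 150
  scores <- matrix(rnorm(n * 3), n, 3,
                   dimnames = list(sprintf("S%03d", 1:n), NULL))
  eta <- 1 - 0.3 * scores[, 2] + rnorm(n, 0, 0.1)
  ase <- data.frame(individual_id = rownames(scores),
                    inmdeff = eta + rnorm(n, 0, 0.15))
  etg <- data.frame(individual_id = rownames(scores),
                    inmdeff = eta + rnorm(n, 0, 0.1))
  out <- associateSignatures(scores, ase, etg)
  expect_true(out$replicated[2])
  expect_lt(out$beta_ase[2], 0)
  expect_lt(out$beta_etg[2], 0)
  expect_false(any(out$replicated[c(1, 3)]))

  # flipping the sign of all scores flips betas and nothing else
  out2 <- associateSignatures(-scores, ase, etg)
  expect_equal(out2$beta_ase, -out$beta_ase, tolerance = 1e-10)
  expect_equal(out2$p_ase, out$p_ase, tolerance = 1e-10)
  expect_identical(out2$replicated, out$replicated)

  # sign-discordant planted effects are flagged not replicated
  etgFlip <- data.frame(individual_id = rownames(scores),
                        inmdeff = -eta + rnorm(n, 0, 0.1))
  out3 <- associateSignatures(scores, ase, etgFlip)
  expect_false(out3$replicated[2])
})

test_that("gene-wise focal scores dip over the planted segment and arm-level events are excluded", {
  nGenes <- 200; nSamples <- 80
  seg <- data.frame(startGene = 61, endGene = 80, carrierFraction = 0.25,
                    etaEffect = 0.4, score = 1)
  sim <- simulateCnaMatrix(nGenes, nSamples, seg, baseEta = 2, seed = 51)
  track <- genewiseFocalInmdeff(sim$gisticTable, sim$eta)
  inSeg <- track$gene %in% sprintf("CG%04d", 61:80)
  expect_true(all(is.finite(track$median_inmdeff[inSeg])))
  expect_lt(max(track$median_inmdeff[inSeg]), 1.7)   # carriers at 1.6
  # genes outside the segment have no focal carriers under a clean matrix
  expect_true(all(track$n_focal_carriers[!inSeg] == 0))
  expect_true(all(is.na(track$median_inmdeff[!inSeg])))

  # an arm-spanning gain is not focal
  segArm <- data.frame(startGene = 1, endGene = 180, carrierFraction = 0.3,
                       etaEffect = 0.4, score = 1)
  simArm <- simulateCnaMatrix(nGenes, nSamples, segArm, baseEta = 2, seed = 53)
  trackArm <- genewiseFocalInmdeff(simArm$gisticTable, simArm$eta)
  expect_true(all(trackArm$n_focal_carriers[1:180] == 0))

  # simple median example: carriers {1, 2, 9} -> 2
  tab <- data.frame(gene = c("gA", "gB"), chrom = "chr1",
                    start = c(1000L, 2000L), arm = "1q",
                    s1 = c(1, 0), s2 = c(1, 0), s3 = c(1, 0), s4 = c(0, 0))
  eta <- c(s1 = 1, s2 = 2, s3 = 9, s4 = 5)
  tr <- genewiseFocalInmdeff(tab, eta,
                             focality = list(maxArmFraction = 0.9))
  expect_identical(tr$median_inmdeff[tr$gene == "gA"], 2)
  expect_true(is.na(tr$median_inmdeff[tr$gene == "gB"]))
})

test_that("candidate prioritization needs both correlation criteria", {
  set.seed(61)
  n <- 120
  cnaCausal <- rbinom(n, 1, 0.4)
  exprCausal <- cnaCausal + rnorm(n, 0, 0.3)
  inmdeff <- 1 - 0.5 * exprCausal + rnorm(n, 0, 0.2)
  cnaPassenger <- rbinom(n, 1, 0.4)               # independent event
  exprPassenger <- cnaPassenger + rnorm(n, 0, 0.3) # CNA-linked, no eta link
  exprOutside <- rnorm(n)
  expression <- rbind(causal = exprCausal, passenger = exprPassenger,
                      outside = exprOutside)
  cna <- rbind(causal = cnaCausal, passenger = cnaPassenger,
               outside = rnorm(n))
  colnames(expression) <- colnames(cna) <- sprintf("S%03d", 1:n)
  names(inmdeff) <- colnames(expression)
  res <- prioritizeCandidates(expression, inmdeff, cna)
  expect_true(res$candidate[res$gene == "causal"])
  expect_false(res$candidate[res$gene == "passenger"])  # eta criterion fails
  expect_false(res$candidate[res$gene == "outside"])    # CNA criterion fails
})

test_that("overlapping planted segments are rejected", {
  segs <- data.frame(startGene = c(10, 30), endGene = c(40, 60),
                     carrierFraction = 0.2, etaEffect = 0.1)
  expect_error(simulateCnaMatrix(100, 20, segs, seed = 1), "overlapping")
  expect_error(simulateCnaMatrix(
    50, 20, data.frame(startGene = 10, endGene = 60, carrierFraction = 0.2,
                       etaEffect = 0.1), seed = 1), "outside gene range")
})
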