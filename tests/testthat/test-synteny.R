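regionsDf <- function(chrom, start, end, direction, id = NULL) {
  d <- data.frame(chrom = chrom, start = start, end = end,
                  direction = direction,
                  peak_pos = (start + end) / 2, peak_height = 1,
                  stringsAsFactors = FALSE)
  if (!is.null(id)) d$region_id <- id
  d
}

test_that("gene-to-region assignment uses the any-overlap rule", {
  genes <- data.frame(
    gene_id = c("inside", "straddle", "outside", "otherchrom"),
    chrom = c("c1", "c1", "c1", "c2"),
    start = c(2e6, 0.5e6, 9e6, 2e6),
    end = c(3e6, 1.5e6, 9.5e6, 3e6), stringsAsFactors = FALSE)
  reg <- regionsDf("c1", 1e6, 5e6, "gain")
  asg <- genesInRegions(genes, reg)
  expect_setequal(asg$gene_id, c("inside", "straddle"))
  expect_true(all(asg$direction == "gain"))
  # empty inputs give empty assignments
  expect_equal(nrow(genesInRegions(genes[0, ], reg)), 0)
  expect_equal(nrow(genesInRegions(genes, reg[0, ])), 0)
})

test_that("conserved pairs require matching aberration directions", {
  orth <- buildOrthologTable(
    toyGenome(1, species = "A"), toyGenome(1, species = "B"),
    syntenyBlock("c1", 1e6, "c1", 2e6, 3))
  gA <- orthologGenes(orth, "A")
  gB <- orthologGenes(orth, "B")
  regGain <- regionsDf("c1", 0, 5e7, "gain", id = "RA1")
  regLossB <- regionsDf("c1", 0, 5e7, "loss", id = "RB1")
  regGainB <- regionsDf("c1", 0, 5e7, "gain", id = "RB1")
  aA <- genesInRegions(gA, regGain)
  expect_equal(nrow(conservedPairs(orth, aA,
                                   genesInRegions(gB, regGainB))), 3)
  expect_equal(nrow(conservedPairs(orth, aA,
                                   genesInRegions(gB, regLossB))), 0)
})

test_that("overlaps span first-gene start to last-gene end with counts", {
  orth <- data.frame(
    pair_id = c("p1", "p2"),
    geneA_id = c("A1", "A2"), chromA = "c1",
    startA = c(10e6, 30e6), endA = c(20e6, 40e6), strandA = "+",
    geneB_id = c("B1", "B2"), chromB = "c5",
    startB = c(50e6, 60e6), endB = c(55e6, 65e6), strandB = "+",
    stringsAsFactors = FALSE)
  aA <- data.frame(gene_id = c("A1", "A2"), region_id = "RA",
                   direction = "gain", chrom = "c1",
                   start = c(10e6, 30e6), end = c(20e6, 40e6),
                   stringsAsFactors = FALSE)
  aB <- data.frame(gene_id = c("B1", "B2"), region_id = "RB",
                   direction = "gain", chrom = "c5",
                   start = c(50e6, 60e6), end = c(55e6, 65e6),
                   stringsAsFactors = FALSE)
  ov <- clusterOverlaps(conservedPairs(orth, aA, aB))
  expect_equal(nrow(ov), 1)
  expect_equal(ov$startA, 10e6)
  expect_equal(ov$endA, 40e6)
  expect_equal(ov$startB, 50e6)
  expect_equal(ov$endB, 65e6)
  expect_equal(ov$n_genes_A, 2L)
  expect_equal(ov$n_genes_B, 2L)
  expect_equal(ov$n_pairs, 2L)
  expect_equal(ov$inversion, 1)
  expect_false(ov$singleton)
})

test_that("single-pair overlaps are flagged and have no inversion call", {
  pairs <- data.frame(
    pair_id = "p1", geneA_id = "A1", regionA_id = "RA",
    geneB_id = "B1", regionB_id = "RB", direction = "loss",
    chromA = "c1", startA = 1e6, endA = 2e6,
    chromB = "c2", startB = 3e6, endB = 4e6, stringsAsFactors = FALSE)
  ov <- clusterOverlaps(pairs)
  expect_true(ov$singleton)
  expect_true(is.na(ov$inversion))
  expect_true(is.na(inversionFlag(pairs)))
})

test_that("inversion flag is the sign of the cross-species gene order", {
  fwd <- data.frame(geneA_id = c("A1", "A2", "A3"),
                    geneB_id = c("B1", "B2", "B3"),
                    startA = c(1e6, 2e6, 3e6), startB = c(5e6, 6e6, 7e6))
  expect_equal(inversionFlag(fwd), 1)
  rev <- transform(fwd, startB = c(7e6, 6e6, 5e6))
  expect_equal(inversionFlag(rev), -1)
})

test_that("species roles can be swapped symmetrically", {
  gA <- toyGenome(2, species = "A")
  gB <- toyGenome(2, species = "B")
  blocks <- rbind(syntenyBlock("c1", 10e6, "c2", 40e6, 4),
                  syntenyBlock("c2", 20e6, "c1", 5e6, 3, inverted = TRUE))
  orth <- buildOrthologTable(gA, gB, blocks)
  regA <- regionsDf(c("c1", "c2"), c(5e6, 15e6), c(30e6, 30e6),
                    c("gain", "loss"), id = c("RA1", "RA2"))
  regB <- regionsDf(c("c2", "c1"), c(35e6, 2e6), c(60e6, 20e6),
                    c("gain", "loss"), id = c("RB1", "RB2"))
  ov <- syntenicOverlaps(orth, regA, regB)

  swapped <- orth
  names(swapped) <- sub("A", "X", names(swapped))
  names(swapped) <- sub("B", "A", names(swapped))
  names(swapped) <- sub("X", "B", names(swapped))
  ovSwap <- syntenicOverlaps(swapped[names(orth)], regB, regA)
  expect_equal(nrow(ovSwap), nrow(ov))
  o1 <- ov[order(ov$regionA_id, ov$regionB_id), ]
  o2 <- ovSwap[order(ovSwap$regionB_id, ovSwap$regionA_id), ]
  expect_equal(o1$startA, o2$startB)
  expect_equal(o1$endA, o2$endB)
  expect_equal(o1$n_genes_A, o2$n_genes_B)
  expect_equal(o1$n_pairs, o2$n_pairs)
  expect_equal(o1$inversion, o2$inversion)
})

test_that("every retained pair lands in exactly one overlap", {
  gA <- toyGenome(2, species = "A")
  gB <- toyGenome(2, species = "B")
  blocks <- rbind(syntenyBlock("c1", 10e6, "c2", 40e6, 5),
                  syntenyBlock("c1", 60e6, "c1", 5e6, 4),
                  syntenyBlock("c2", 20e6, "c1", 50e6, 3, inverted = TRUE))
  orth <- buildOrthologTable(gA, gB, blocks)
  regA <- regionsDf(c("c1", "c1", "c2"), c(0, 55e6, 15e6),
                    c(40e6, 90e6, 40e6), c("gain", "gain", "loss"),
                    id = c("RA1", "RA2", "RA3"))
  regB <- regionsDf(c("c2", "c1", "c1"), c(30e6, 0, 45e6),
                    c(70e6, 20e6, 70e6), c("gain", "gain", "loss"),
                    id = c("RB1", "RB2", "RB3"))
  aA <- genesInRegions(orthologGenes(orth, "A"), regA)
  aB <- genesInRegions(orthologGenes(orth, "B"), regB)
  pairs <- conservedPairs(orth, aA, aB)
  ov <- clusterOverlaps(pairs)
  totalPairs <- sum(ov$n_pairs)
  expect_equal(totalPairs, length(unique(pairs$pair_id)))
  expect_equal(sum(ov$n_pairs), nrow(pairs))  # no pair split across keys
})

test_that("planted conserved blocks are recovered end to end", {
  gA <- toyGenome(2, species = "A")
  gB <- toyGenome(2, species = "B")
  blocks <- rbind(
    syntenyBlock("c1", 30e6, "c2", 10e6, 6),               # conserved gain
    syntenyBlock("c2", 40e6, "c1", 60e6, 5, inverted = TRUE))  # conserved loss
  orth <- buildOrthologTable(gA, gB, blocks)
  pmA <- buildProbeMap(gA, 120, seed = 61)
  pmB <- buildProbeMap(gB, 120, seed = 62)
  span <- 6 * 1e5 - 5e4
  cnasA <- rbind(
    cnaSpec("c1", 28e6, 33e6, "gain", frequency = 1, amplitudeMean = 0.9),
    cnaSpec("c2", 38e6, 43e6, "loss", frequency = 1, amplitudeMean = -0.9))
  cnasB <- rbind(
    cnaSpec("c2", 8e6, 13e6, "gain", frequency = 1, amplitudeMean = 0.9),
    cnaSpec("c1", 58e6, 63e6, "loss", frequency = 1, amplitudeMean = -0.9))
  p <- KSEParams(kernelWidth = 4e6, gridStep = 2e5)
  callsFor <- function(pm, cnas, label) {
    gset <- simulateGroup(pm, label, 10, noiseSd = 0, cnas = cnas,
                          seed = 63)
    rbind(callRegions(groupKSE(gset, "gains", p), 0.5),
          callRegions(groupKSE(gset, "losses", p), 0.5))
  }
  regA <- callsFor(pmA, cnasA, "A")
  regB <- callsFor(pmB, cnasB, "B")
  ov <- syntenicOverlaps(orth, regA, regB)
  expect_equal(nrow(ov), 2)
  gain <- ov[ov$direction == "gain", ]
  loss <- ov[ov$direction == "loss", ]
  expect_equal(gain$startA, 30e6)
  expect_equal(gain$endA, 30e6 + span)
  expect_equal(gain$inversion, 1)
  expect_equal(loss$inversion, -1)
  expect_equal(loss$n_pairs, 5L)
})
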