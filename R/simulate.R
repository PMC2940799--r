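#' Build a synthetic BAC probe map
#'
#' Allots \code{nProbes} probes to chromosomes proportionally to
#' chromosome length (largest-remainder rounding, at least one probe
#' per chromosome) and draws each probe's midposition uniformly at
#' random within its chromosome, then sorts. The irregular spacing
#' deliberately exercises the probe-density sensitivity of the
#' kernel-smoothed estimate.
#'
#' @param genome a \linkS4class{Genome}.
#' @param nProbes total probe count; defaults to 3080, a typical
#'   full-genome mouse BAC array.
#' @param seed integer seed; the map is deterministic given the seed.
#' @return data.frame with columns \code{probe_id}, \code{chrom},
#'   \code{mid_bp} (0-based bp), sorted by (chromosome, position),
#'   with the genome attached as attribute \code{"genome"}.
#' @examples
#' pm <- buildProbeMap(mouseGenome(), 3080, seed = 1)
#' nrow(pm)
#' @export
buildProbeMap <- function(genome, nProbes = 3080, seed = 1) {
  len <- chromLengths(genome)
  nc <- length(len)
  if (nProbes < nc)
    stop("nProbes must be at least the number of chromosomes (", nc, ")")
  frac <- nProbes * len / sum(len)
  counts <- pmax(1L, floor(frac))
  rem <- nProbes - sum(counts)
  if (rem > 0) {
    extra <- order(frac - floor(frac), decreasing = TRUE)
    counts[extra[seq_len(rem)]] <- counts[extra[seq_len(rem)]] + 1L
  } else if (rem < 0) {
    # possible only when many tiny chromosomes were floored up to 1
    drop <- order(counts - frac, decreasing = TRUE)
    i <- 1L
    while (rem < 0) {
      j <- drop[i]
      if (counts[j] > 1L) { counts[j] <- counts[j] - 1L; rem <- rem + 1L }
      i <- if (i == nc) 1L else i + 1L
    }
  }
  withr::with_seed(seed, {
    pos <- lapply(seq_len(nc), function(i) {
      p <- sort(floor(runif(counts[i]) * len[i]))
      while (anyDuplicated(p))          # integer-bp collisions are resampled
        p <- sort(unique(c(p[!duplicated(p)],
                           floor(runif(sum(duplicated(p))) * len[i]))))
      p
    })
  })
  pm <- data.frame(
    probe_id = sprintf("probe%05d", seq_len(nProbes)),
    chrom = rep(names(len), counts),
    mid_bp = unlist(pos), row.names = NULL, stringsAsFactors = FALSE)
  attr(pm, "genome") <- genome
  pm
}

#' Specify a copy-number aberration to plant
#'
#' @param chrom chromosome name.
#' @param start,end 0-based half-open bounds in bp (ignored, and filled
#'   with the full chromosome, when \code{wholeChromosome = TRUE}).
#' @param direction "gain" or "loss".
#' @param frequency fraction of samples carrying the event, in [0, 1].
#' @param amplitudeMean mean log2-ratio shift of a carried event
#'   (> 0 for gains, < 0 for losses).
#' @param amplitudeSd between-carrier standard deviation of the shift
#'   (log2 units, >= 0); within one carrier the shift is constant
#'   across all probes of the event, matching segment-level biology.
#' @param wholeChromosome flag for whole-chromosome events.
#' @return one-row data.frame understood by \code{\link{simulateGroup}}.
#' @export
cnaSpec <- function(chrom, start = NA_real_, end = NA_real_,
                    direction = c("gain", "loss"), frequency,
                    amplitudeMean, amplitudeSd = 0,
                    wholeChromosome = FALSE) {
  direction <- match.arg(direction)
  stopifnot(frequency >= 0, frequency <= 1, amplitudeSd >= 0)
  if ((direction == "gain") != (amplitudeMean > 0))
    stop("sign of amplitudeMean must match direction")
  if (!wholeChromosome && (!is.finite(start) || !is.finite(end) || start >= end))
    stop("need 0 <= start < end for a focal event")
  data.frame(chrom = chrom, start = start, end = end,
             direction = direction, frequency = frequency,
             amplitude_mean = amplitudeMean, amplitude_sd = amplitudeSd,
             whole_chromosome = wholeChromosome,
             stringsAsFactors = FALSE)
}

#' Simulate one aCGH tumor group with planted aberrations
#'
#' Each sample carries each planted event independently with
#' probability \code{frequency}; a carried event adds one
#' Normal(amplitude_mean, amplitude_sd) draw to every probe inside its
#' interval, then independent Normal(0, noiseSd) measurement noise is
#' added per probe per sample, and tumor types are drawn from
#' \code{tumorTypeMix}.
#'
#' Random draws are consumed in a fixed order so the generator is
#' reproducible across implementations: (1) carrier indicators, one
#' uniform per sample per event, events in listed order; (2) carrier
#' amplitudes, one normal per carrier, events in listed order, samples
#' in index order; (3) the noise matrix, probes x samples, filled
#' column by column (sample-major); (4) tumor-type draws, one per
#' sample.
#'
#' @param map probe map from \code{\link{buildProbeMap}} (or any
#'   data.frame with probe_id, chrom, mid_bp and a "genome" attribute).
#' @param groupLabel group label for all samples.
#' @param nSamples number of samples (>= 2).
#' @param noiseSd per-probe log2 noise standard deviation (>= 0).
#' @param cnas data.frame of planted events (rbind of
#'   \code{\link{cnaSpec}} rows) or NULL for a null cohort.
#' @param tumorTypeMix named fractions summing to 1, e.g.
#'   \code{c(carcinoma = 0.5, carcinosarcoma = 0.5)}.
#' @param seed integer seed.
#' @param samplePrefix prefix for generated sample ids.
#' @return An \linkS4class{ACGHSet} whose \code{\link{groundTruth}}
#'   records exactly which sample carries which event and at what
#'   amplitude. An event interval containing no probes triggers a
#'   warning but is still logged.
#' @examples
#' pm <- buildProbeMap(mouseGenome(), 500, seed = 1)
#' g <- simulateGroup(pm, "p53", nSamples = 10, noiseSd = 0.2,
#'                    cnas = cnaSpec("6", 40e6, 70e6, "gain",
#'                                   frequency = 0.6, amplitudeMean = 0.8),
#'                    seed = 7)
#' g
#' @export
simulateGroup <- function(map, groupLabel, nSamples, noiseSd,
                          cnas = NULL, tumorTypeMix = c(unknown = 1),
                          seed = 1, samplePrefix = groupLabel) {
  genome <- attr(map, "genome")
  stopifnot(is(genome, "Genome"), nSamples >= 2, noiseSd >= 0)
  if (abs(sum(tumorTypeMix) - 1) > 1e-8)
    stop("tumorTypeMix fractions must sum to 1")
  len <- chromLengths(genome)
  if (!is.null(cnas) && nrow(cnas)) {
    if (!all(cnas$chrom %in% names(len)))
      stop("CNA chromosome not present in the probe map's genome")
    wc <- cnas$whole_chromosome
    cnas$start[wc] <- 0
    cnas$end[wc] <- len[cnas$chrom[wc]]
    if (any(cnas$start < 0) || any(cnas$end > len[cnas$chrom]))
      stop("CNA interval exceeds chromosome bounds")
  }
  nP <- nrow(map)
  nE <- if (is.null(cnas)) 0L else nrow(cnas)
  M <- matrix(0, nP, nSamples)
  sid <- sprintf("%s_s%03d", samplePrefix, seq_len(nSamples))
  truth <- NULL
  withr::with_seed(seed, {
    carriers <- lapply(seq_len(nE), function(j)
      runif(nSamples) < cnas$frequency[j])
    for (j in seq_len(nE)) {
      idx <- which(map$chrom == cnas$chrom[j] &
                   map$mid_bp >= cnas$start[j] & map$mid_bp < cnas$end[j])
      if (!length(idx))
        warning(sprintf("planted event %s:%g-%g contains no probes",
                        cnas$chrom[j], cnas$start[j], cnas$end[j]))
      who <- which(carriers[[j]])
      amp <- rnorm(length(who), cnas$amplitude_mean[j], cnas$amplitude_sd[j])
      for (k in seq_along(who))
        M[idx, who[k]] <- M[idx, who[k]] + amp[k]
      if (length(who))
        truth <- rbind(truth, data.frame(
          sample_id = sid[who], chrom = cnas$chrom[j],
          start = cnas$start[j], end = cnas$end[j],
          direction = cnas$direction[j], amplitude = amp,
          stringsAsFactors = FALSE))
    }
    if (noiseSd > 0)
      M <- M + matrix(rnorm(nP * nSamples, 0, noiseSd), nP, nSamples)
    types <- sample(names(tumorTypeMix), nSamples, replace = TRUE,
                    prob = tumorTypeMix)
  })
  samples <- data.frame(sample_id = sid, group = groupLabel,
                        tumor_type = types, stringsAsFactors = FALSE)
  ACGHSet(M, map, samples, genome, groundTruth = truth)
}

#' Specify a synteny block shared by two genomes
#'
#' @param chromA,startA location of the block in species A (bp, 0-based).
#' @param chromB,startB location in species B.
#' @param nGenes number of ortholog pairs the block emits (>= 1).
#' @param inverted flag: the block's gene order and strands are
#'   reversed in species B.
#' @param geneLength,geneGap gene extent and intergenic gap in bp.
#' @return one-row data.frame understood by
#'   \code{\link{buildOrthologTable}}.
#' @export
syntenyBlock <- function(chromA, startA, chromB, startB, nGenes,
                         inverted = FALSE, geneLength = 5e4, geneGap = 5e4) {
  stopifnot(nGenes >= 1, geneLength > 0, geneGap >= 0)
  data.frame(chromA = chromA, startA = startA, chromB = chromB,
             startB = startB, n_genes = as.integer(nGenes),
             inverted = inverted, gene_length = geneLength,
             gene_gap = geneGap, stringsAsFactors = FALSE)
}

#' Build an ortholog table from synteny blocks
#'
#' Lays out \code{n_genes} equally spaced genes per block in each
#' species; in inverted blocks the species-B gene order is reversed
#' and strands flipped, emulating a strand inversion of the syntenic
#' segment. The layout is fully deterministic; the \code{seed}
#' argument is accepted for interface symmetry with the other
#' generators.
#'
#' @param genomeA,genomeB \linkS4class{Genome} objects.
#' @param blocks data.frame of \code{\link{syntenyBlock}} rows.
#' @param seed unused (deterministic construction).
#' @return ortholog table: data.frame with columns pair_id, geneA_id,
#'   chromA, startA, endA, strandA, geneB_id, chromB, startB, endB,
#'   strandB (coordinates 0-based half-open). Overlapping genes within
#'   one species are an error.
#' @export
buildOrthologTable <- function(genomeA, genomeB, blocks, seed = 1) {
  lenA <- chromLengths(genomeA); lenB <- chromLengths(genomeB)
  rows <- lapply(seq_len(nrow(blocks)), function(b) {
    bl <- blocks[b, ]
    step <- bl$gene_length + bl$gene_gap
    span <- bl$n_genes * step - bl$gene_gap
    if (!bl$chromA %in% names(lenA) || bl$startA + span > lenA[bl$chromA])
      stop("block ", b, " does not fit in species-A genome")
    if (!bl$chromB %in% names(lenB) || bl$startB + span > lenB[bl$chromB])
      stop("block ", b, " does not fit in species-B genome")
    i <- seq_len(bl$n_genes)
    sA <- bl$startA + (i - 1) * step
    slotB <- if (bl$inverted) rev(i) else i
    sB <- bl$startB + (slotB - 1) * step
    data.frame(
      geneA_id = sprintf("gA_b%02d_%03d", b, i),
      chromA = bl$chromA, startA = sA, endA = sA + bl$gene_length,
      strandA = "+",
      geneB_id = sprintf("gB_b%02d_%03d", b, i),
      chromB = bl$chromB, startB = sB, endB = sB + bl$gene_length,
      strandB = if (bl$inverted) "-" else "+",
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- cbind(pair_id = sprintf("pair%05d", seq_len(nrow(tab))), tab,
               stringsAsFactors = FALSE)
  .checkNoOverlap(tab$chromA, tab$startA, tab$endA, "A")
  .checkNoOverlap(tab$chromB, tab$startB, tab$endB, "B")
  rownames(tab) <- NULL
  tab
}

.checkNoOverlap <- function(chrom, start, end, label) {
  for (ch in unique(chrom)) {
    i <- chrom == ch
    o <- order(start[i])
    s <- start[i][o]; e <- end[i][o]
    if (any(s[-1] < e[-length(e)]))
      stop("overlapping genes within species ", label, " on chromosome ", ch)
  }
  invisible(TRUE)
}
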