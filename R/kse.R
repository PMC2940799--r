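#' Kernel parameters constructor
#'
#' @param kernelWidth smoothing scale in bp; 20 Mb is the scale found
#'   to smooth BAC-array noise while retaining focal and arm-level
#'   aberrations in both mouse and human profiles.
#' @param sigma Gaussian standard deviation (default kernelWidth / 4,
#'   so that +/- 2 sigma spans the kernel width).
#' @param truncationRadius support half-width beyond which the kernel
#'   is cut to exactly zero (default one kernel width = 4 sigma, where
#'   the Gaussian has fallen to exp(-8) ~ 3e-4 of its height).
#' @param gridStep regular evaluation-grid step (default
#'   kernelWidth / 200, i.e. 100 kb at 20 Mb). Probe midpositions are
#'   always added to the grid.
#' @return A \linkS4class{KSEParams} object.
#' @export
KSEParams <- function(kernelWidth = 20e6, sigma = kernelWidth / 4,
                      truncationRadius = kernelWidth,
                      gridStep = kernelWidth / 200) {
  new("KSEParams", kernelWidth = kernelWidth, sigma = sigma,
      truncationRadius = truncationRadius, gridStep = gridStep)
}

setMethod("show", "KSEParams", function(object) {
  cat(sprintf(
    "KSEParams: kernel width %.3g Mb (sigma %.3g Mb, truncated at %.3g Mb), grid step %.3g kb\n",
    object@kernelWidth / 1e6, object@sigma / 1e6,
    object@truncationRadius / 1e6, object@gridStep / 1e3))
})

# Per-chromosome evaluation grid: regular steps plus probe midpositions.
.kseGrid <- function(genome, probes, params) {
  len <- chromLengths(genome)
  lapply(setNames(names(len), names(len)), function(ch) {
    g <- seq(0, len[ch], by = params@gridStep)
    sort(unique(c(g, probes$mid_bp[probes$chrom == ch])))
  })
}

# Truncated-Gaussian kernel matrices, one per chromosome:
# K[[ch]] is grid x probes with K[i,j] = exp(-d^2/(2 sigma^2)) for
# |d| <= truncationRadius and 0 beyond; kernels never cross
# chromosome boundaries because probes and grids are per-chromosome.
.kernelMatrices <- function(genome, probes, params, grid = NULL) {
  if (is.null(grid)) grid <- .kseGrid(genome, probes, params)
  s2 <- 2 * params@sigma^2
  r <- params@truncationRadius
  out <- lapply(setNames(names(grid), names(grid)), function(ch) {
    p <- probes$mid_bp[probes$chrom == ch]
    g <- grid[[ch]]
    if (!length(p))
      return(list(pos = g, K = matrix(0, length(g), 0),
                  idx = integer(0)))
    D <- outer(g, p, "-")
    K <- exp(-D * D / s2)
    K[abs(D) > r] <- 0
    list(pos = g, K = K, idx = which(probes$chrom == ch))
  })
  out
}

# Per-probe aggregate kernel heights H(p): the sum over samples of the
# positive parts (gains), negative parts (losses) or raw values
# (combined) of each probe's log2 ratios. Missing values are excluded.
.probeAggregates <- function(M, sign) {
  switch(sign,
    gains = rowSums(pmax(M, 0), na.rm = TRUE),
    losses = rowSums(pmin(M, 0), na.rm = TRUE),
    combined = rowSums(M, na.rm = TRUE),
    stop("sign must be gains, losses or combined"))
}

#' Kernel-smoothed estimate of recurrent aberration for a tumor group
#'
#' At every grid position x on a chromosome, the KSE is the sum over
#' probes p within the truncation radius of
#' exp(-(x - pos(p))^2 / (2 sigma^2)) * H(p), where H(p) aggregates
#' the group's log2 ratios at probe p: the sum of positive parts for
#' the gains curve, of negative parts for the losses curve, or of raw
#' values for the combined curve. Kernels never cross chromosome
#' boundaries. The combined curve equals gains + losses at every
#' position.
#'
#' @param acgh an \linkS4class{ACGHSet} (one tumor group, or a subset
#'   of a combined set).
#' @param sign "gains", "losses" or "combined".
#' @param params a \linkS4class{KSEParams}.
#' @return A \linkS4class{KSECurve}.
#' @examples
#' pm <- buildProbeMap(mouseGenome(), 400, seed = 1)
#' g <- simulateGroup(pm, "grp", 5, noiseSd = 0.1, seed = 2)
#' curve <- groupKSE(g, "gains", KSEParams(gridStep = 1e6))
#' head(kseTable(curve))
#' @export
groupKSE <- function(acgh, sign = c("gains", "losses", "combined"),
                     params = KSEParams()) {
  sign <- match.arg(sign)
  stopifnot(ncol(acgh) >= 1)
  probes <- probeTable(acgh)
  genome <- acghGenome(acgh)
  H <- .probeAggregates(log2Ratios(acgh), sign)
  km <- .kernelMatrices(genome, probes, params)
  tab <- do.call(rbind, lapply(names(km), function(ch) {
    v <- if (ncol(km[[ch]]$K)) drop(km[[ch]]$K %*% H[km[[ch]]$idx])
         else numeric(length(km[[ch]]$pos))
    data.frame(chrom = ch, pos = km[[ch]]$pos, kse = v,
               stringsAsFactors = FALSE)
  }))
  tab$chrom <- factor(tab$chrom, levels = chromNames(genome))
  new("KSECurve", sign = sign, table = tab, params = params,
      genome = genome)
}

#' @describeIn groupKSE the curve's (chrom, pos, kse) data.frame.
#' @param curve a \linkS4class{KSECurve}.
#' @export
kseTable <- function(curve) {
  stopifnot(is(curve, "KSECurve"))
  curve@table
}

#' @describeIn groupKSE the curve's sign tag.
#' @export
kseSign <- function(curve) curve@sign

setMethod("show", "KSECurve", function(object) {
  cat(sprintf("KSECurve (%s): %d grid points on %d chromosomes, range [%.3g, %.3g]\n",
              object@sign, nrow(object@table),
              length(unique(object@table$chrom)),
              min(object@table$kse), max(object@table$kse)))
})

#' Genome-wide permutation significance threshold for a KSE curve
#'
#' Builds the null distribution of the genome-wide maximum absolute
#' KSE by shuffling the per-probe aggregate values H(p) uniformly
#' across all probe positions genome-wide (destroying spatial
#' structure while preserving the aggregate marginal distribution) and
#' recomputing the full curve for each permutation. The threshold is
#' the empirical (1 - alpha) quantile of the null maxima, taken
#' conservatively as the k-th largest with k = floor(alpha * nPerm) + 1.
#' A gain or loss anywhere on the observed curve exceeding this value
#' is significant at familywise level alpha.
#'
#' @param acgh an \linkS4class{ACGHSet}.
#' @param sign "gains" or "losses".
#' @param params a \linkS4class{KSEParams}.
#' @param nPerm number of permutations (>= 20).
#' @param alpha familywise significance level.
#' @param seed integer seed for the permutations.
#' @param unit what is permuted: \code{"aggregate"} shuffles the
#'   per-probe aggregates H(p) across positions (default);
#'   \code{"sample"} shuffles each sample's probe values independently
#'   before re-aggregating.
#' @return A \linkS4class{KSEThreshold}. All-zero aggregates give a
#'   degenerate threshold of 0 with a warning.
#' @export
significanceThreshold <- function(acgh, sign = c("gains", "losses"),
                                  params = KSEParams(), nPerm = 1000,
                                  alpha = 0.05, seed = 1,
                                  unit = c("aggregate", "sample")) {
  sign <- match.arg(sign)
  unit <- match.arg(unit)
  stopifnot(nPerm >= 20)
  probes <- probeTable(acgh)
  genome <- acghGenome(acgh)
  M <- log2Ratios(acgh)
  H <- .probeAggregates(M, sign)
  if (all(H == 0)) {
    warning("all per-probe aggregates are zero: degenerate null, threshold 0")
    return(new("KSEThreshold", sign = sign, value = 0, alpha = alpha,
               nPerm = nPerm, nullMax = rep(0, nPerm)))
  }
  nP <- length(H)
  withr::with_seed(seed, {
    if (unit == "aggregate") {
      Hperm <- vapply(seq_len(nPerm), function(i) H[sample.int(nP)],
                      numeric(nP))
    } else {
      Hperm <- vapply(seq_len(nPerm), function(i) {
        Mp <- apply(M, 2, function(col) col[sample.int(nP)])
        .probeAggregates(Mp, sign)
      }, numeric(nP))
    }
  })
  km <- .kernelMatrices(genome, probes, params)
  maxima <- rep(0, nPerm)
  for (ch in names(km)) {
    if (!ncol(km[[ch]]$K)) next
    V <- km[[ch]]$K %*% Hperm[km[[ch]]$idx, , drop = FALSE]
    maxima <- pmax(maxima, apply(abs(V), 2, max))
  }
  k <- floor(alpha * nPerm) + 1
  value <- sort(maxima, decreasing = TRUE)[k]
  new("KSEThreshold", sign = sign, value = value, alpha = alpha,
      nPerm = nPerm, nullMax = maxima)
}

#' @describeIn significanceThreshold the threshold value (KSE units,
#'   non-negative; applied as its negative to losses curves).
#' @param threshold a \linkS4class{KSEThreshold}.
#' @export
thresholdValue <- function(threshold) {
  stopifnot(is(threshold, "KSEThreshold"))
  threshold@value
}

#' @describeIn significanceThreshold the null genome-wide maxima.
#' @export
nullMaxima <- function(threshold) threshold@nullMax

setMethod("show", "KSEThreshold", function(object) {
  cat(sprintf(
    "KSEThreshold (%s): %.4g at alpha = %g (%d permutations)\n",
    object@sign, object@value, object@alpha, object@nPerm))
})
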