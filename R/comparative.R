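#' Per-sample combined KSE matrix
#'
#' Smooths every individual tumor profile with the same Gaussian
#' kernel used for group curves, without separating gains and losses:
#' each probe contributes a kernel of height equal to its raw log2
#' value. All samples are evaluated on one shared grid so their curves
#' can be compared position by position.
#'
#' By default each position is normalized by the summed kernel weights
#' of the contributing probes (a kernel-weighted local average), which
#' keeps per-sample curves on the log2-ratio scale so that aberration
#' count thresholds such as 0.15 are interpretable log2 units. The
#' per-position SNR of the comparative analysis is unchanged by this
#' normalization (it rescales every sample identically at each
#' position). With \code{normalize = FALSE} each row is the plain
#' kernel sum and equals the sum of that sample's gains and losses
#' curves.
#'
#' @param acgh an \linkS4class{ACGHSet}, or a list of them sharing one
#'   probe map (combined with \code{\link{combineGroups}}).
#' @param params a \linkS4class{KSEParams}.
#' @param normalize divide each position by the local sum of kernel
#'   weights (default TRUE).
#' @return A \linkS4class{SampleKSE}.
#' @export
sampleKSEMatrix <- function(acgh, params = KSEParams(), normalize = TRUE) {
  if (is.list(acgh) && !is(acgh, "ACGHSet"))
    acgh <- combineGroups(acgh)
  probes <- probeTable(acgh)
  genome <- acghGenome(acgh)
  M <- log2Ratios(acgh)
  M[is.na(M)] <- 0                    # missing values contribute nothing
  km <- .kernelMatrices(genome, probes, params)
  pieces <- lapply(names(km), function(ch) {
    if (!ncol(km[[ch]]$K))
      return(matrix(0, ncol(M), length(km[[ch]]$pos)))
    V <- km[[ch]]$K %*% M[km[[ch]]$idx, , drop = FALSE]
    if (normalize) {
      w <- rowSums(km[[ch]]$K)
      V <- V / ifelse(w > 0, w, 1)    # positions with no probe in reach stay 0
    }
    t(V)
  })
  kse <- do.call(cbind, pieces)
  rownames(kse) <- colnames(M)
  grid <- do.call(rbind, lapply(names(km), function(ch)
    data.frame(chrom = ch, pos = km[[ch]]$pos, stringsAsFactors = FALSE)))
  grid$chrom <- factor(grid$chrom, levels = chromNames(genome))
  new("SampleKSE", grid = grid, kse = kse, groups = sampleGroups(acgh),
      params = params, genome = genome)
}

#' @describeIn sampleKSEMatrix the samples x positions KSE matrix.
#' @param x a \linkS4class{SampleKSE}.
#' @export
kseMatrix <- function(x) {
  stopifnot(is(x, "SampleKSE"))
  x@kse
}

#' @describeIn sampleKSEMatrix the shared evaluation grid (chrom, pos).
#' @export
kseGrid <- function(x) {
  stopifnot(is(x, "SampleKSE"))
  x@grid
}

setMethod("show", "SampleKSE", function(object) {
  cat(sprintf("SampleKSE: %d samples x %d grid positions (%s)\n",
              nrow(object@kse), ncol(object@kse),
              paste(unique(object@groups), collapse = ", ")))
})

# Row-subset group statistics of a samples x positions matrix.
.groupStats <- function(K, idx) {
  n <- length(idx)
  m <- colMeans(K[idx, , drop = FALSE])
  v <- (colSums(K[idx, , drop = FALSE]^2) - n * m^2) / (n - 1)
  list(mean = m, sd = sqrt(pmax(v, 0)))
}

.snrValues <- function(mA, sdA, mB, sdB) {
  num <- mA - mB
  den <- sdA + sdB
  snr <- num / den
  snr[den == 0 & num == 0] <- 0       # 0/0 convention
  snr
}

#' Signal-to-noise ratio curve between two tumor groups
#'
#' At each grid position the per-sample KSE values of group A are
#' compared with those of group B through
#' SNR = (mean_A - mean_B) / (sd_A + sd_B), using (n - 1) sample
#' standard deviations; 0/0 is defined as 0. The curve is
#' antisymmetric under swapping the two groups. Positions where the
#' groups are equally aberrated, however strongly, score near zero -
#' shared aberrations are suppressed by construction.
#'
#' @param mat a \linkS4class{SampleKSE}.
#' @param labelA,labelB group labels, each with >= 2 samples.
#' @return An \linkS4class{SNRCurve}.
#' @export
snrCurve <- function(mat, labelA, labelB) {
  stopifnot(is(mat, "SampleKSE"))
  iA <- which(mat@groups == labelA)
  iB <- which(mat@groups == labelB)
  if (length(iA) < 2 || length(iB) < 2)
    stop("both groups need >= 2 samples (sd undefined otherwise)")
  a <- .groupStats(mat@kse, iA)
  b <- .groupStats(mat@kse, iB)
  new("SNRCurve", grid = mat@grid,
      snr = .snrValues(a$mean, a$sd, b$mean, b$sd),
      groupA = labelA, groupB = labelB)
}

#' @describeIn snrCurve the per-position SNR values.
#' @param snr an \linkS4class{SNRCurve}.
#' @export
snrValues <- function(snr) {
  stopifnot(is(snr, "SNRCurve"))
  snr@snr
}

setMethod("show", "SNRCurve", function(object) {
  cat(sprintf("SNRCurve: %s vs %s, %d positions, range [%.3g, %.3g]\n",
              object@groupA, object@groupB, length(object@snr),
              min(object@snr), max(object@snr)))
})

# counts of sorted-vector elements >= x / <= x, vectorized over x.
# A relative tolerance absorbs round-off between the matrix-algebra
# permutation path and the per-position observed path, so that
# mathematically tied values always count as in the tail.
.tieEps <- function(x) 1e-9 * pmax(1, abs(x))
.countGE <- function(x, sortedv)
  length(sortedv) - findInterval(x - .tieEps(x), sortedv, left.open = TRUE)
.countLE <- function(x, sortedv) findInterval(x + .tieEps(x), sortedv)

#' Class-label-permutation FDR cutoffs for an SNR curve
#'
#' Permutes the group labels across the pooled samples (all distinct
#' label assignments are enumerated when there are no more of them
#' than \code{nPerm}; otherwise \code{nPerm} random assignments are
#' drawn) and recomputes the SNR curve for each assignment. For a
#' candidate cutoff c >= 0 the positive-tail FDR estimate is the mean
#' permutation count of positions with SNR >= c divided by the
#' observed count (floored at 1); the positive cutoff is the smallest
#' observed SNR value whose estimated FDR is at or below q. The
#' negative tail is treated symmetrically. \code{Inf} cutoffs mean no
#' significant positions in that direction.
#'
#' @param mat a \linkS4class{SampleKSE}.
#' @param labelA,labelB the ordered group pair (must differ).
#' @param nPerm number of label assignments (default 6000).
#' @param q target false discovery rate (default 0.05).
#' @param seed integer seed for random assignments.
#' @return An \linkS4class{SNRCutoffs}.
#' @export
snrFdrCutoffs <- function(mat, labelA, labelB, nPerm = 6000, q = 0.05,
                          seed = 1) {
  stopifnot(is(mat, "SampleKSE"))
  if (identical(labelA, labelB)) stop("group labels must differ")
  pool <- which(mat@groups %in% c(labelA, labelB))
  K <- mat@kse[pool, , drop = FALSE]
  lab <- mat@groups[pool]
  nA <- sum(lab == labelA)
  n <- length(pool)
  if (nA < 2 || n - nA < 2) stop("both groups need >= 2 samples")
  obsA <- which(lab == labelA)
  obs <- local({
    a <- .groupStats(K, obsA); b <- .groupStats(K, setdiff(seq_len(n), obsA))
    .snrValues(a$mean, a$sd, b$mean, b$sd)
  })
  nDistinct <- choose(n, nA)
  exhaustive <- nDistinct <= nPerm
  assignments <- if (exhaustive) {
    asplit(combn(n, nA), 2)
  } else {
    withr::with_seed(seed,
      lapply(seq_len(nPerm), function(i) sample.int(n, nA)))
  }
  nUsed <- length(assignments)
  candPos <- sort(unique(obs[is.finite(obs) & obs > 0]))
  candNeg <- sort(unique(-obs[is.finite(obs) & obs < 0]))
  posTot <- numeric(length(candPos))
  negTot <- numeric(length(candNeg))
  permAbsMax <- numeric(nUsed)
  K2 <- K^2
  chunk <- 500L
  for (off in seq(1L, nUsed, by = chunk)) {
    ids <- off:min(off + chunk - 1L, nUsed)
    IA <- matrix(0, length(ids), n)
    for (r in seq_along(ids)) IA[r, assignments[[ids[r]]]] <- 1
    SA1 <- IA %*% K;  SB1 <- (1 - IA) %*% K
    SA2 <- IA %*% K2; SB2 <- (1 - IA) %*% K2
    mA <- SA1 / nA; mB <- SB1 / (n - nA)
    sdA <- sqrt(pmax((SA2 - nA * mA^2) / (nA - 1), 0))
    sdB <- sqrt(pmax((SB2 - (n - nA) * mB^2) / (n - nA - 1), 0))
    S <- .snrValues(mA, sdA, mB, sdB)
    permAbsMax[ids] <- apply(abs(S), 1, max)
    sv <- sort(as.vector(S))
    if (length(candPos))
      posTot <- posTot + .countGE(candPos, sv)
    if (length(candNeg))
      negTot <- negTot + .countLE(-candNeg, sv)
  }
  sObs <- sort(obs)
  fdrPos <- if (length(candPos))
    (posTot / nUsed) / pmax(1, .countGE(candPos, sObs)) else numeric(0)
  fdrNeg <- if (length(candNeg))
    (negTot / nUsed) / pmax(1, .countLE(-candNeg, sObs)) else numeric(0)
  posCut <- if (any(fdrPos <= q)) min(candPos[fdrPos <= q]) else Inf
  negCut <- if (any(fdrNeg <= q)) min(candNeg[fdrNeg <= q]) else Inf
  new("SNRCutoffs", posCutoff = posCut, negCutoff = negCut, q = q,
      nPerm = nUsed, exhaustive = exhaustive,
      groupA = labelA, groupB = labelB,
      permSummary = list(
        permAbsMax = permAbsMax,
        fdrPos = if (length(candPos))
          data.frame(cutoff = candPos, fdr = fdrPos) else NULL,
        fdrNeg = if (length(candNeg))
          data.frame(cutoff = candNeg, fdr = fdrNeg) else NULL,
        seed = seed))
}

#' @describeIn snrFdrCutoffs the positive-tail (A > B) cutoff.
#' @param cutoffs an \linkS4class{SNRCutoffs}.
#' @export
posCutoff <- function(cutoffs) {
  stopifnot(is(cutoffs, "SNRCutoffs"))
  cutoffs@posCutoff
}

#' @describeIn snrFdrCutoffs the negative-tail (B > A) cutoff magnitude.
#' @export
negCutoff <- function(cutoffs) {
  stopifnot(is(cutoffs, "SNRCutoffs"))
  cutoffs@negCutoff
}

setMethod("show", "SNRCutoffs", function(object) {
  pc <- if (is.finite(object@posCutoff))
    sprintf("%.4g", object@posCutoff) else "none"
  nc <- if (is.finite(object@negCutoff))
    sprintf("%.4g", object@negCutoff) else "none"
  cat(sprintf(
    "SNRCutoffs %s vs %s at FDR %g: A>B cutoff %s, B>A cutoff %s (%d %s permutations)\n",
    object@groupA, object@groupB, object@q, pc, nc, object@nPerm,
    if (object@exhaustive) "exhaustive" else "sampled"))
})

#' Differentially aberrated regions between two tumor groups
#'
#' Maximal grid runs where the SNR is at or above the positive cutoff
#' become regions with direction "A>B"; runs at or below the negated
#' negative cutoff become "B>A" regions. Region bounds are linearly
#' interpolated at the cutoff crossings, as in \code{\link{callRegions}}.
#'
#' @param snr an \linkS4class{SNRCurve}.
#' @param cutoffs a matching \linkS4class{SNRCutoffs} (same ordered
#'   group pair).
#' @return data.frame with columns chrom, start, end, direction,
#'   peak_pos, peak_height (signed SNR units).
#' @export
differentialRegions <- function(snr, cutoffs) {
  stopifnot(is(snr, "SNRCurve"), is(cutoffs, "SNRCutoffs"))
  if (!identical(snr@groupA, cutoffs@groupA) ||
      !identical(snr@groupB, cutoffs@groupB))
    stop("cutoffs were computed for a different ordered group pair")
  tab <- snr@grid
  v <- snr@snr
  dirUp <- paste0(snr@groupA, ">", snr@groupB)
  dirDn <- paste0(snr@groupB, ">", snr@groupA)
  out <- lapply(levels(tab$chrom), function(ch) {
    i <- tab$chrom == ch
    g <- tab$pos[i]; vc <- v[i]
    up <- if (is.finite(cutoffs@posCutoff))
      .scanRunsAbove(g, vc, cutoffs@posCutoff) else NULL
    dn <- if (is.finite(cutoffs@negCutoff))
      .scanRunsAbove(g, -vc, cutoffs@negCutoff) else NULL
    rows <- NULL
    if (!is.null(up))
      rows <- rbind(rows, data.frame(
        chrom = ch, start = up$start, end = up$end, direction = dirUp,
        peak_pos = up$peak_pos, peak_height = up$peak_height,
        stringsAsFactors = FALSE))
    if (!is.null(dn))
      rows <- rbind(rows, data.frame(
        chrom = ch, start = dn$start, end = dn$end, direction = dirDn,
        peak_pos = dn$peak_pos, peak_height = -dn$peak_height,
        stringsAsFactors = FALSE))
    rows
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), direction = character(),
                      peak_pos = numeric(), peak_height = numeric(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
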