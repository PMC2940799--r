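# Maximal runs of v above `thr` on grid g (one chromosome).
# strict: runs use v > thr; otherwise v >= thr. Bounds are placed at
# the linear-interpolated crossing between the bounding grid points;
# a run touching a chromosome end keeps the endpoint as its bound.
# Returns data.frame(start, end, peak_pos, peak_height) in grid units.
.scanRunsAbove <- function(g, v, thr, strict = FALSE) {
  above <- if (strict) v > thr else v >= thr
  above[is.na(above)] <- FALSE
  if (!any(above)) return(NULL)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  out <- lapply(runs, function(k) {
    i <- starts[k]; j <- ends[k]
    s <- if (i == 1L) g[1L] else
      g[i - 1L] + (thr - v[i - 1L]) / (v[i] - v[i - 1L]) * (g[i] - g[i - 1L])
    e <- if (j == length(g)) g[length(g)] else
      g[j] + (v[j] - thr) / (v[j] - v[j + 1L]) * (g[j + 1L] - g[j])
    w <- i - 1L + which.max(v[i:j])
    data.frame(start = s, end = e, peak_pos = g[w], peak_height = v[w])
  })
  do.call(rbind, out)
}

#' Call significant regions from a KSE curve and its threshold
#'
#' Significant regions are the maximal contiguous stretches where the
#' curve is at or beyond the significance threshold (KSE >= value for
#' gains, KSE <= -value for losses). Region bounds are placed where
#' the curve crosses the threshold, linearly interpolated between the
#' bounding grid points; each region carries its extreme peak.
#'
#' @param curve a \linkS4class{KSECurve} (gains or losses).
#' @param threshold a matching \linkS4class{KSEThreshold}, or a single
#'   non-negative number in KSE units.
#' @return data.frame with columns chrom, start, end, direction
#'   ("gain"/"loss"), peak_pos, peak_height (signed KSE units); zero
#'   rows when nothing exceeds the threshold.
#' @export
callRegions <- function(curve, threshold) {
  stopifnot(is(curve, "KSECurve"))
  if (is(threshold, "KSEThreshold")) {
    if (threshold@sign != curve@sign)
      stop("curve sign (", curve@sign, ") does not match threshold sign (",
           threshold@sign, ")")
    thr <- threshold@value
  } else {
    thr <- as.numeric(threshold)
    stopifnot(length(thr) == 1L, thr >= 0)
  }
  if (curve@sign == "combined")
    stop("call regions on gains or losses curves, not combined")
  dirn <- if (curve@sign == "gains") "gain" else "loss"
  flip <- if (curve@sign == "losses") -1 else 1
  tab <- curve@table
  out <- lapply(levels(tab$chrom), function(ch) {
    i <- tab$chrom == ch
    runs <- .scanRunsAbove(tab$pos[i], flip * tab$kse[i], thr)
    if (is.null(runs)) return(NULL)
    data.frame(chrom = ch, start = runs$start, end = runs$end,
               direction = dirn, peak_pos = runs$peak_pos,
               peak_height = flip * runs$peak_height,
               stringsAsFactors = FALSE)
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

# Interior local extrema of v on one chromosome. Plateaus report their
# leftmost point; runs touching a chromosome end are excluded.
# maxima = TRUE finds strict local maxima, FALSE strict minima.
.localExtrema <- function(v, maxima = TRUE) {
  if (length(v) < 3L) return(integer(0))
  w <- if (maxima) v else -v
  r <- rle(w)
  n <- length(r$values)
  if (n < 3L) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(seq_len(n) > 1L & seq_len(n) < n &
                r$values > c(-Inf, r$values)[seq_len(n)] &
                r$values > c(r$values[-1L], -Inf))
  starts[keep]
}

#' Locate KSE peaks
#'
#' A peak is an interior grid position whose KSE value strictly
#' exceeds both neighboring grid values (gains) or lies strictly below
#' both (losses). Plateaus of tied values report their leftmost point;
#' chromosome endpoints are never peaks. Local peaks inside a broader
#' gain or loss are reported: they are part of the curve and may mark
#' the genes driving the wider aberration. For a combined curve,
#' maxima at positive values and minima at negative values are
#' both reported.
#'
#' @param curve a \linkS4class{KSECurve}.
#' @return data.frame with columns chrom, pos, height.
#' @export
findPeaks <- function(curve) {
  stopifnot(is(curve, "KSECurve"))
  tab <- curve@table
  out <- lapply(levels(tab$chrom), function(ch) {
    i <- which(tab$chrom == ch)
    v <- tab$kse[i]; g <- tab$pos[i]
    idx <- switch(curve@sign,
      gains = .localExtrema(v, TRUE),
      losses = .localExtrema(v, FALSE),
      combined = sort(c(
        .localExtrema(v, TRUE)[v[.localExtrema(v, TRUE)] > 0],
        .localExtrema(v, FALSE)[v[.localExtrema(v, FALSE)] < 0])))
    if (!length(idx)) return(NULL)
    data.frame(chrom = ch, pos = g[idx], height = v[idx],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), pos = numeric(),
                      height = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Scale a KSE curve by its significance threshold
#'
#' Divides all curve values by the threshold value so that the
#' significance level sits at +1 for gains and -1 for losses; this
#' puts curves from cohorts of different sizes and noise levels on a
#' common display scale.
#'
#' @param curve a \linkS4class{KSECurve}.
#' @param threshold a \linkS4class{KSEThreshold} (or positive number).
#' @return the rescaled \linkS4class{KSECurve}.
#' @export
scaleCurve <- function(curve, threshold) {
  thr <- if (is(threshold, "KSEThreshold")) threshold@value
         else as.numeric(threshold)
  if (thr <= 0) stop("cannot scale by a degenerate (zero) threshold")
  curve@table$kse <- curve@table$kse / thr
  curve
}
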