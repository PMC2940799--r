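#' Fraction of probes beyond an absolute log2 cutoff
#'
#' The per-tumor genomic-instability measure: the fraction of probes
#' reporting a gain (log2 ratio strictly above \code{cutoff}) and a
#' loss (strictly below \code{-cutoff}). Missing probes are excluded
#' from both numerator and denominator. BAC-array mouse profiles are
#' conventionally scored at 0.3 and the dimmer human profiles at 0.2;
#' the cutoff is a parameter, not a constant.
#'
#' @param values numeric vector of one sample's log2 ratios.
#' @param cutoff positive log2 cutoff; values exactly at the cutoff do
#'   not count.
#' @return named numeric c(gain = , loss = ), both in [0, 1].
#' @examples
#' aberrantFraction(c(0.4, -0.5, 0.1), 0.3)
#' @export
aberrantFraction <- function(values, cutoff) {
  stopifnot(cutoff > 0)
  ok <- !is.na(values)
  if (!any(ok)) stop("all values are missing")
  c(gain = sum(values[ok] > cutoff) / sum(ok),
    loss = sum(values[ok] < -cutoff) / sum(ok))
}

#' Welch two-sample t test
#'
#' Unequal-variance two-tailed t test (Welch-Satterthwaite degrees of
#' freedom), as used for all group contrasts of instability measures.
#' Degenerate inputs where both groups are constant are resolved
#' explicitly: equal means give t = 0, p = 1; different means give
#' p = 0 with a warning.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return named list with elements \code{t} and \code{p}.
#' @export
welchTest <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p = 1))
    warning("both groups constant with different means: degenerate contrast")
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0))
  }
  tt <- t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' Per-sample aberrant fractions with group summaries and contrasts
#'
#' Computes \code{\link{aberrantFraction}} for every sample, the
#' per-group mean and standard error of the mean, and a Welch contrast
#' (gains and losses separately) for every pair of groups.
#'
#' @param acgh an \linkS4class{ACGHSet}.
#' @param cutoff positive absolute log2 cutoff.
#' @return list with elements \code{samples} (sample_id, group,
#'   gain_frac, loss_frac), \code{groups} (group, direction, mean,
#'   sem, n) and \code{contrasts} (group_a, group_b, direction, t, p).
#' @export
instabilitySummary <- function(acgh, cutoff) {
  M <- log2Ratios(acgh)
  info <- sampleInfo(acgh)
  fr <- t(apply(M, 2, aberrantFraction, cutoff = cutoff))
  samples <- data.frame(sample_id = info$sample_id, group = info$group,
                        gain_frac = fr[, "gain"], loss_frac = fr[, "loss"],
                        row.names = NULL, stringsAsFactors = FALSE)
  groups <- do.call(rbind, lapply(split(samples, samples$group), function(d)
    data.frame(group = d$group[1], direction = c("gain", "loss"),
               mean = c(mean(d$gain_frac), mean(d$loss_frac)),
               sem = c(sd(d$gain_frac), sd(d$loss_frac)) / sqrt(nrow(d)),
               n = nrow(d), stringsAsFactors = FALSE)))
  rownames(groups) <- NULL
  gl <- unique(samples$group)
  contrasts <- NULL
  if (length(gl) >= 2) {
    prs <- combn(gl, 2)
    contrasts <- do.call(rbind, lapply(seq_len(ncol(prs)), function(k) {
      a <- samples[samples$group == prs[1, k], ]
      b <- samples[samples$group == prs[2, k], ]
      wg <- welchTest(a$gain_frac, b$gain_frac)
      wl <- welchTest(a$loss_frac, b$loss_frac)
      data.frame(group_a = prs[1, k], group_b = prs[2, k],
                 direction = c("gain", "loss"),
                 t = c(wg$t, wl$t), p = c(wg$p, wl$p),
                 stringsAsFactors = FALSE)
    }))
  }
  list(samples = samples, groups = groups, contrasts = contrasts)
}

# Count of aberrations in one sample's combined KSE vector at
# threshold t: maximal runs with value > t plus runs with value < -t,
# never crossing chromosome boundaries. peaks = TRUE counts local
# maxima above t plus local minima below -t instead.
.countAberrations <- function(chromIdx, v, t, peaks = FALSE) {
  total <- 0L
  for (i in chromIdx) {
    vc <- v[i]
    if (peaks) {
      mx <- .localExtrema(vc, TRUE)
      mn <- .localExtrema(vc, FALSE)
      total <- total + sum(vc[mx] > t) + sum(vc[mn] < -t)
    } else {
      r1 <- rle(vc > t);  total <- total + sum(r1$values)
      r2 <- rle(vc < -t); total <- total + sum(r2$values)
    }
  }
  total
}

#' Sweep of per-tumor aberration counts across KSE thresholds
#'
#' For each sample and each threshold t, counts the aberrations in the
#' sample's combined KSE curve: maximal contiguous runs exceeding +t
#' plus runs below -t (strict inequality; runs never cross chromosome
#' boundaries). Group means are compared per threshold with
#' \code{\link{welchTest}} for every group pair, and the contiguous
#' threshold intervals with p < 0.05 are reported - the intervals over
#' which one group is significantly more unstable than another.
#' \code{mode = "peaks"} counts local extrema beyond the threshold
#' instead of runs.
#'
#' @param skse a \linkS4class{SampleKSE}.
#' @param thresholds positive increasing numeric vector of KSE
#'   thresholds (default 0.02 to 0.8 in 0.02 steps, covering the range
#'   over which BAC-array cohorts separate).
#' @param mode "runs" (default) or "peaks".
#' @return list with elements \code{thresholds}, \code{counts}
#'   (samples x thresholds integer matrix), \code{groupMeans} (groups
#'   x thresholds), \code{pvalues} (data.frame: group_a, group_b,
#'   threshold, p) and \code{significant} (data.frame of contiguous
#'   significant threshold intervals per contrast).
#' @export
cnaCountSweep <- function(skse, thresholds = seq(0.02, 0.8, by = 0.02),
                          mode = c("runs", "peaks")) {
  mode <- match.arg(mode)
  stopifnot(is(skse, "SampleKSE"), all(thresholds > 0),
            !is.unsorted(thresholds, strictly = TRUE))
  chromIdx <- lapply(levels(skse@grid$chrom),
                     function(ch) which(skse@grid$chrom == ch))
  K <- skse@kse
  counts <- matrix(0L, nrow(K), length(thresholds),
                   dimnames = list(rownames(K), NULL))
  for (s in seq_len(nrow(K)))
    counts[s, ] <- vapply(thresholds, function(t)
      .countAberrations(chromIdx, K[s, ], t, peaks = (mode == "peaks")),
      integer(1))
  groups <- skse@groups
  gl <- unique(groups)
  groupMeans <- t(vapply(gl, function(g)
    colMeans(counts[groups == g, , drop = FALSE]),
    numeric(length(thresholds))))
  rownames(groupMeans) <- gl
  pvalues <- NULL
  significant <- NULL
  if (length(gl) >= 2) {
    prs <- combn(gl, 2)
    # contrasts need >= 2 samples on both sides
    ok <- vapply(seq_len(ncol(prs)), function(k)
      sum(groups == prs[1, k]) >= 2 && sum(groups == prs[2, k]) >= 2,
      logical(1))
    prs <- prs[, ok, drop = FALSE]
  }
  if (length(gl) >= 2 && ncol(prs)) {
    pvalues <- do.call(rbind, lapply(seq_len(ncol(prs)), function(k) {
      ia <- groups == prs[1, k]; ib <- groups == prs[2, k]
      p <- vapply(seq_along(thresholds), function(j)
        welchTest(counts[ia, j], counts[ib, j])$p, numeric(1))
      data.frame(group_a = prs[1, k], group_b = prs[2, k],
                 threshold = thresholds, p = p, stringsAsFactors = FALSE)
    }))
    significant <- do.call(rbind, lapply(seq_len(ncol(prs)), function(k) {
      d <- pvalues[pvalues$group_a == prs[1, k] &
                   pvalues$group_b == prs[2, k], ]
      sig <- d$p < 0.05
      if (!any(sig)) return(NULL)
      r <- rle(sig)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      keep <- which(r$values)
      data.frame(group_a = prs[1, k], group_b = prs[2, k],
                 from = thresholds[starts[keep]],
                 to = thresholds[ends[keep]], stringsAsFactors = FALSE)
    }))
  }
  list(thresholds = thresholds, counts = counts, groupMeans = groupMeans,
       pvalues = pvalues, significant = significant, mode = mode)
}

#' Expression-based tumor-type call from E-cadherin and Vimentin
#'
#' Mammary tumors are typed from the log-scale expression of the
#' epithelial marker E-cadherin and the mesenchymal marker Vimentin:
#' a tumor is Mesenchymal when Vimentin exceeds E-cadherin by more
#' than \code{margin} log units, Epithelial when E-cadherin exceeds
#' Vimentin by more than \code{margin}, and Ambiguous otherwise
#' (a difference of exactly \code{margin} is Ambiguous).
#'
#' @param ecadherin,vimentin log-scale expression values (vectorized).
#' @param margin log-units margin (default 0.5).
#' @return character vector in \{"Epithelial", "Mesenchymal",
#'   "Ambiguous"\}.
#' @examples
#' classifyTumorType(c(0, 1.2), c(0.8, 0.1))
#' @export
classifyTumorType <- function(ecadherin, vimentin, margin = 0.5) {
  stopifnot(all(is.finite(ecadherin)), all(is.finite(vimentin)))
  d <- vimentin - ecadherin
  ifelse(d > margin, "Mesenchymal",
         ifelse(-d > margin, "Epithelial", "Ambiguous"))
}

#' Histopathological composition of the three mouse mammary-tumor cohorts
#'
#' Published tumor-type counts for the Brca1;p53-, Brca2;p53- and
#' p53-deficient mouse mammary-tumor cohorts: cohort size, the number
#' of tumors scored by histopathology, and the counts of carcinomas,
#' carcinosarcomas and adenomyoepitheliomas among them (the remainder
#' could not be scored). These counts are inputs for composition
#' summaries and worked examples.
#'
#' @return data.frame with columns group, cohort_n, scored, carcinoma,
#'   carcinosarcoma, adenomyoepithelioma, not_scored.
#' @export
mouseCohortComposition <- function() {
  data.frame(
    group = c("Brca1;p53", "Brca2;p53", "p53"),
    cohort_n = c(35L, 62L, 33L),
    scored = c(34L, 54L, 28L),
    carcinoma = c(31L, 49L, 11L),
    carcinosarcoma = c(1L, 5L, 14L),
    adenomyoepithelioma = c(2L, 0L, 3L),
    not_scored = c(1L, 8L, 5L),
    stringsAsFactors = FALSE)
}

#' Tumor-type composition percentages from scored counts
#'
#' @param counts data.frame in the layout of
#'   \code{\link{mouseCohortComposition}}.
#' @return the same data.frame with \code{*_pct} columns: each type
#'   count as a percentage of the tumors scored.
#' @export
compositionPercentages <- function(counts = mouseCohortComposition()) {
  for (col in c("carcinoma", "carcinosarcoma", "adenomyoepithelioma"))
    counts[[paste0(col, "_pct")]] <- 100 * counts[[col]] / counts$scored
  counts
}
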