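#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames rowData colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats rnorm runif sd setNames t.test quantile cor var
#' @importFrom utils read.delim write.table combn head
NULL

#' Genome description
#'
#' A minimal genome model: an ordered set of named chromosomes with
#' lengths in base pairs. The chromosome order fixed here is used for
#' all plotting, table and curve output.
#'
#' @slot species single character, species label.
#' @slot lengths named numeric vector of chromosome lengths (bp), in
#'   natural order (1..n autosomes, then X).
#' @exportClass Genome
setClass("Genome", representation(species = "character", lengths = "numeric"))

setValidity("Genome", function(object) {
  msg <- NULL
  if (length(object@species) != 1L) msg <- c(msg, "species must be a single string")
  nm <- names(object@lengths)
  if (is.null(nm) || anyDuplicated(nm)) msg <- c(msg, "chromosome names must be unique and non-NULL")
  if (any(!is.finite(object@lengths)) || any(object@lengths <= 0))
    msg <- c(msg, "chromosome lengths must be positive and finite")
  if (is.null(msg)) TRUE else msg
})

#' Gaussian kernel parameters for smoothed copy-number estimates
#'
#' The kernel width is the user-facing smoothing scale (default 20 Mb,
#' the scale at which BAC-array noise is smoothed away while focal and
#' arm-level aberrations remain visible). The Gaussian standard
#' deviation defaults to a quarter of the kernel width so that +/- 2
#' standard deviations span the stated width; the kernel is truncated
#' at \code{truncationRadius} (default one kernel width, i.e. 4 sd).
#' The evaluation grid is regular with step \code{gridStep} per
#' chromosome, augmented with the probe midpositions.
#'
#' @slot kernelWidth numeric, smoothing scale in bp.
#' @slot sigma numeric, Gaussian standard deviation in bp.
#' @slot truncationRadius numeric, kernel support half-width in bp.
#' @slot gridStep numeric, regular evaluation-grid step in bp.
#' @exportClass KSEParams
setClass("KSEParams", representation(
  kernelWidth = "numeric", sigma = "numeric",
  truncationRadius = "numeric", gridStep = "numeric"))

setValidity("KSEParams", function(object) {
  msg <- NULL
  if (object@sigma <= 0) msg <- c(msg, "sigma must be > 0")
  if (object@truncationRadius < 2 * object@sigma)
    msg <- c(msg, "truncationRadius must be >= 2*sigma")
  if (object@gridStep <= 0) msg <- c(msg, "gridStep must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' Kernel-smoothed estimate (KSE) curve
#'
#' Genome-wide kernel-smoothed estimate of aggregate copy-number
#' change for one tumor group, evaluated on a per-chromosome grid.
#' The \code{sign} tag records whether positive parts (gains),
#' negative parts (losses) or raw log2 values (combined) of the probe
#' ratios were aggregated; gains curves are non-negative and losses
#' curves non-positive everywhere.
#'
#' @slot sign one of "gains", "losses", "combined".
#' @slot table data.frame with columns chrom (factor in genome order),
#'   pos (bp) and kse (summed weighted log2 units).
#' @slot params the \linkS4class{KSEParams} used.
#' @slot genome the \linkS4class{Genome} the curve lives on.
#' @exportClass KSECurve
setClass("KSECurve", representation(
  sign = "character", table = "data.frame",
  params = "KSEParams", genome = "Genome"))

setValidity("KSECurve", function(object) {
  msg <- NULL
  if (!object@sign %in% c("gains", "losses", "combined"))
    msg <- c(msg, "sign must be gains, losses or combined")
  tb <- object@table
  if (!all(c("chrom", "pos", "kse") %in% names(tb)))
    msg <- c(msg, "table must have columns chrom, pos, kse")
  else {
    tol <- 1e-9
    if (object@sign == "gains" && any(tb$kse < -tol))
      msg <- c(msg, "gains curve must be >= 0 everywhere")
    if (object@sign == "losses" && any(tb$kse > tol))
      msg <- c(msg, "losses curve must be <= 0 everywhere")
    if (is.unsorted(order(tb$chrom), strictly = FALSE) ||
        any(unlist(tapply(tb$pos, tb$chrom, is.unsorted, strictly = TRUE))))
      msg <- c(msg, "grid positions must be strictly increasing within chromosomes")
  }
  if (is.null(msg)) TRUE else msg
})

#' Genome-wide permutation significance threshold
#'
#' The empirical (1 - alpha) quantile of the null distribution of
#' genome-wide maximum absolute KSE peak heights obtained by permuting
#' per-probe aggregate values across probe positions. Exceeding this
#' threshold anywhere controls the familywise error rate at alpha.
#'
#' @slot sign "gains" or "losses" (the threshold is stored as a
#'   non-negative value; it is applied as its negative to losses).
#' @slot value non-negative numeric threshold in KSE units.
#' @slot alpha significance level.
#' @slot nPerm number of permutations used.
#' @slot nullMax numeric vector of null genome-wide maxima.
#' @exportClass KSEThreshold
setClass("KSEThreshold", representation(
  sign = "character", value = "numeric", alpha = "numeric",
  nPerm = "numeric", nullMax = "numeric"))

setValidity("KSEThreshold", function(object) {
  msg <- NULL
  if (object@value < 0) msg <- c(msg, "threshold value must be >= 0")
  if (object@alpha <= 0 || object@alpha >= 1) msg <- c(msg, "alpha must be in (0,1)")
  if (is.null(msg)) TRUE else msg
})

#' Per-sample KSE matrix
#'
#' Combined-sign kernel-smoothed profile of every individual tumor,
#' evaluated on one shared genome grid. This is the substrate of the
#' comparative analysis and of per-tumor instability sweeps.
#'
#' @slot grid data.frame with columns chrom, pos.
#' @slot kse numeric matrix, samples x grid positions.
#' @slot groups named character vector mapping sample id to group label.
#' @slot params the \linkS4class{KSEParams} used.
#' @slot genome the \linkS4class{Genome}.
#' @exportClass SampleKSE
setClass("SampleKSE", representation(
  grid = "data.frame", kse = "matrix", groups = "character",
  params = "KSEParams", genome = "Genome"))

setValidity("SampleKSE", function(object) {
  msg <- NULL
  if (nrow(object@grid) != ncol(object@kse))
    msg <- c(msg, "grid length must match kse column count")
  if (length(object@groups) != nrow(object@kse) ||
      is.null(names(object@groups)) ||
      !identical(names(object@groups), rownames(object@kse)))
    msg <- c(msg, "groups must be named by the kse row names")
  if (is.null(msg)) TRUE else msg
})

#' Signal-to-noise ratio curve between two tumor groups
#'
#' Per-position SNR between the per-sample KSE values of an ordered
#' group pair (A, B): (mean_A - mean_B) / (sd_A + sd_B), with 0/0
#' defined as 0. Antisymmetric under swapping A and B.
#'
#' @slot grid data.frame with columns chrom, pos.
#' @slot snr numeric vector of SNR values.
#' @slot groupA,groupB group labels of the ordered pair.
#' @exportClass SNRCurve
setClass("SNRCurve", representation(
  grid = "data.frame", snr = "numeric",
  groupA = "character", groupB = "character"))

#' Permutation-FDR cutoffs for an SNR curve
#'
#' Per-tail SNR cutoffs obtained by class-label permutation: for a
#' candidate cutoff c >= 0 the positive-tail FDR estimate is the mean
#' permutation count of positions with SNR >= c divided by the
#' observed count; the cutoff is the smallest observed SNR value whose
#' estimated FDR is at or below q. \code{Inf} means no cutoff
#' qualified (no significant positions in that direction).
#'
#' @slot posCutoff,negCutoff non-negative cutoffs (magnitudes); the
#'   negative cutoff applies to SNR <= -negCutoff.
#' @slot q target false discovery rate.
#' @slot nPerm number of label assignments evaluated.
#' @slot exhaustive logical, TRUE when all distinct assignments were
#'   enumerated.
#' @slot groupA,groupB the ordered group pair.
#' @slot permSummary list with summary statistics of the permuted SNR
#'   pool (quantiles, counts).
#' @exportClass SNRCutoffs
setClass("SNRCutoffs", representation(
  posCutoff = "numeric", negCutoff = "numeric", q = "numeric",
  nPerm = "numeric", exhaustive = "logical",
  groupA = "character", groupB = "character", permSummary = "list"))
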