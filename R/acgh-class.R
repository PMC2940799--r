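#' aCGH tumor-group container
#'
#' An \code{ACGHSet} holds the log2-ratio matrix of one or more tumor
#' groups profiled on a common BAC array, as a
#' \linkS4class{SummarizedExperiment} with probes as rows and samples
#' as columns. \code{rowData} carries the probe map (probe id,
#' chromosome, genomic midposition in bp, 0-based); \code{colData}
#' carries sample id, group label and tumor type. The
#' \linkS4class{Genome} and, for simulated cohorts, the ground-truth
#' event log live in \code{metadata}.
#'
#' Probes are kept sorted by (chromosome order, midposition); missing
#' log2 ratios are allowed (\code{NA}) and are excluded from all
#' kernel sums and instability denominators.
#'
#' @exportClass ACGHSet
setClass("ACGHSet", contains = "SummarizedExperiment")

setValidity("ACGHSet", function(object) {
  msg <- NULL
  rd <- SummarizedExperiment::rowData(object)
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("probe_id", "chrom", "mid_bp") %in% names(rd)))
    return("rowData must have probe_id, chrom, mid_bp")
  if (!all(c("sample_id", "group", "tumor_type") %in% names(cd)))
    return("colData must have sample_id, group, tumor_type")
  if (anyDuplicated(rd$probe_id)) msg <- c(msg, "probe ids must be unique")
  if (anyDuplicated(cd$sample_id)) msg <- c(msg, "sample ids must be unique")
  g <- S4Vectors::metadata(object)$genome
  if (!is(g, "Genome")) return("metadata$genome must be a Genome")
  if (!all(rd$chrom %in% chromNames(g)))
    msg <- c(msg, "all probe chromosomes must exist in the genome")
  ord <- chromNames(g)
  ci <- match(rd$chrom, ord)
  if (is.unsorted(ci))
    msg <- c(msg, "probes must be sorted by genome chromosome order")
  else {
    bad <- tapply(rd$mid_bp, factor(rd$chrom, levels = ord),
                  function(p) length(p) > 1 && is.unsorted(p, strictly = TRUE))
    if (any(unlist(bad), na.rm = TRUE))
      msg <- c(msg, "midpositions must be strictly increasing within chromosomes")
  }
  if (!"log2" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'log2' is required")
  if (is.null(msg)) TRUE else msg
})

#' Construct an ACGHSet
#'
#' @param log2 numeric matrix, probes x samples, of log2 tumor/normal
#'   ratios (NA = missing measurement).
#' @param probes data.frame with columns \code{probe_id}, \code{chrom},
#'   \code{mid_bp} (genomic midposition, bp). Rows are re-sorted by
#'   genome chromosome order and midposition; the matrix is sorted
#'   along with them.
#' @param samples data.frame with columns \code{sample_id},
#'   \code{group}, \code{tumor_type}.
#' @param genome a \linkS4class{Genome}.
#' @param groundTruth optional data.frame logging planted events of a
#'   simulated cohort (sample_id, chrom, start, end, direction,
#'   amplitude).
#' @return An \linkS4class{ACGHSet}.
#' @export
ACGHSet <- function(log2, probes, samples, genome, groundTruth = NULL) {
  log2 <- as.matrix(log2)
  stopifnot(nrow(log2) == nrow(probes), ncol(log2) == nrow(samples))
  ord <- order(match(probes$chrom, chromNames(genome)), probes$mid_bp)
  probes <- probes[ord, , drop = FALSE]
  log2 <- log2[ord, , drop = FALSE]
  rownames(log2) <- probes$probe_id
  colnames(log2) <- samples$sample_id
  md <- list(genome = genome)
  if (!is.null(groundTruth)) md$groundTruth <- groundTruth
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2 = log2),
    rowData = S4Vectors::DataFrame(probes, row.names = probes$probe_id),
    colData = S4Vectors::DataFrame(samples, row.names = samples$sample_id),
    metadata = md)
  new("ACGHSet", se)
}

#' Accessors for ACGHSet
#'
#' @param x an \linkS4class{ACGHSet}.
#' @return \code{log2Ratios}: the probes x samples matrix;
#'   \code{probeTable}: the probe map as a data.frame;
#'   \code{sampleInfo}: the sample annotation data.frame;
#'   \code{acghGenome}: the \linkS4class{Genome};
#'   \code{groundTruth}: the planted-event log (or NULL);
#'   \code{sampleGroups}: named character vector sample id -> group.
#' @name acgh-accessors
NULL

#' @rdname acgh-accessors
#' @export
log2Ratios <- function(x) SummarizedExperiment::assay(x, "log2")

#' @rdname acgh-accessors
#' @export
probeTable <- function(x)
  as.data.frame(SummarizedExperiment::rowData(x))

#' @rdname acgh-accessors
#' @export
sampleInfo <- function(x)
  as.data.frame(SummarizedExperiment::colData(x))

#' @rdname acgh-accessors
#' @export
acghGenome <- function(x) S4Vectors::metadata(x)$genome

#' @rdname acgh-accessors
#' @export
groundTruth <- function(x) S4Vectors::metadata(x)$groundTruth

#' @rdname acgh-accessors
#' @export
sampleGroups <- function(x) {
  cd <- sampleInfo(x)
  setNames(as.character(cd$group), cd$sample_id)
}

setMethod("show", "ACGHSet", function(object) {
  cd <- sampleInfo(object)
  cat(sprintf("ACGHSet: %d probes x %d samples (%s)\n",
              nrow(object), ncol(object), acghGenome(object)@species))
  tab <- table(cd$group)
  cat("  groups:", paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                         collapse = ", "), "\n")
  if (!is.null(groundTruth(object)))
    cat(sprintf("  ground truth: %d planted events\n",
                nrow(groundTruth(object))))
})

#' Combine aCGH groups sharing one probe map
#'
#' Column-binds several \linkS4class{ACGHSet} objects (e.g. two tumor
#' groups to be contrasted) after checking that they were profiled on
#' the identical probe map and genome.
#'
#' @param ... two or more ACGHSet objects.
#' @return A single \linkS4class{ACGHSet}; ground-truth logs are
#'   concatenated.
#' @export
combineGroups <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !is(sets[[1]], "ACGHSet"))
    sets <- sets[[1]]
  stopifnot(length(sets) >= 1L)
  ref <- probeTable(sets[[1]])
  for (s in sets[-1]) {
    pt <- probeTable(s)
    if (!identical(ref$probe_id, pt$probe_id) ||
        !identical(ref$chrom, pt$chrom) ||
        !identical(ref$mid_bp, pt$mid_bp))
      stop("probe maps differ between groups; cannot combine")
  }
  log2 <- do.call(cbind, lapply(sets, log2Ratios))
  samples <- do.call(rbind, lapply(sets, sampleInfo))
  gt <- do.call(rbind, Filter(Negate(is.null), lapply(sets, groundTruth)))
  ACGHSet(log2, ref, samples, acghGenome(sets[[1]]), groundTruth = gt)
}
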