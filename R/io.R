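#' Read an aCGH table with its sample annotation
#'
#' The aCGH table is tab-delimited with header columns
#' \code{probe_id, chrom, mid_bp, <sample1>, <sample2>, ...}; the
#' annotation table has columns \code{sample_id, group, tumor_type}.
#' Probes are sorted by (genome chromosome order, midposition) on
#' load. Ratio cells that do not parse as numbers become missing
#' values and are counted in the load message; a sample present in
#' the data but absent from the annotation is an error naming the
#' sample.
#'
#' @param dataPath path of the aCGH TSV.
#' @param annotPath path of the annotation TSV.
#' @param genome a \linkS4class{Genome}; chromosomes found in the file
#'   but not in the genome are an error.
#' @return An \linkS4class{ACGHSet}.
#' @export
readACGH <- function(dataPath, annotPath, genome) {
  raw <- read.delim(dataPath, check.names = FALSE,
                    colClasses = "character")
  if (!all(c("probe_id", "chrom", "mid_bp") %in% names(raw)))
    stop("aCGH table must start with probe_id, chrom, mid_bp")
  if (anyDuplicated(raw$probe_id))
    stop("duplicate probe id: ",
         raw$probe_id[anyDuplicated(raw$probe_id)])
  annot <- read.delim(annotPath, check.names = FALSE,
                      colClasses = "character")
  if (!all(c("sample_id", "group", "tumor_type") %in% names(annot)))
    stop("annotation table must have sample_id, group, tumor_type")
  sampleCols <- setdiff(names(raw), c("probe_id", "chrom", "mid_bp"))
  missing <- setdiff(sampleCols, annot$sample_id)
  if (length(missing))
    stop("sample(s) present in data but absent from annotations: ",
         paste(missing, collapse = ", "))
  annot <- annot[match(sampleCols, annot$sample_id), , drop = FALSE]
  M <- suppressWarnings(
    vapply(sampleCols, function(s) as.numeric(raw[[s]]),
           numeric(nrow(raw))))
  if (nrow(raw) == 1L) M <- matrix(M, nrow = 1, dimnames = list(NULL, sampleCols))
  message(sprintf("readACGH: %d probes, %d samples, %d missing/unparseable cells",
                  nrow(raw), length(sampleCols), sum(is.na(M))))
  probes <- data.frame(probe_id = raw$probe_id, chrom = raw$chrom,
                       mid_bp = as.numeric(raw$mid_bp),
                       stringsAsFactors = FALSE)
  if (!all(probes$chrom %in% chromNames(genome)))
    stop("chromosome(s) not in genome: ",
         paste(setdiff(probes$chrom, chromNames(genome)), collapse = ", "))
  ACGHSet(M, probes, annot[, c("sample_id", "group", "tumor_type")],
          genome)
}

#' Write an aCGH table and its sample annotation
#'
#' Inverse of \code{\link{readACGH}}; ratios are written with six
#' decimals, so a write/read round trip reproduces values at that
#' precision.
#'
#' @param acgh an \linkS4class{ACGHSet}.
#' @param dataPath,annotPath output paths.
#' @export
writeACGH <- function(acgh, dataPath, annotPath) {
  M <- log2Ratios(acgh)
  txt <- apply(M, 2, function(col)
    ifelse(is.na(col), "NA", sprintf("%.6f", col)))
  if (nrow(M) == 1L) txt <- matrix(txt, nrow = 1, dimnames = dimnames(M))
  out <- cbind(probeTable(acgh)[, c("probe_id", "chrom", "mid_bp")], txt)
  write.table(out, dataPath, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sampleInfo(acgh)[, c("sample_id", "group", "tumor_type")],
              annotPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

.orthologCols <- c("pair_id", "geneA_id", "chromA", "startA", "endA",
                   "strandA", "geneB_id", "chromB", "startB", "endB",
                   "strandB")

#' Read an ortholog table
#'
#' Expects an 11-column tab-delimited file with header
#' \code{pair_id, geneA_id, chromA, startA, endA, strandA, geneB_id,
#' chromB, startB, endB, strandB} (coordinates 0-based half-open).
#' Rows are validated (start < end, strand in +/-, with the offending
#' row number in the error); duplicated (geneA, geneB) combinations
#' are collapsed to one row with a message. A gene id may legally
#' recur across rows: one gene can have several homologs in the other
#' species.
#'
#' @param path input path.
#' @return ortholog table data.frame.
#' @export
readOrthologs <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!identical(names(tab), .orthologCols))
    stop("ortholog table must have columns: ",
         paste(.orthologCols, collapse = ", "))
  badS <- which(!(tab$strandA %in% c("+", "-")) |
                !(tab$strandB %in% c("+", "-")))
  if (length(badS))
    stop("unknown strand symbol at row ", badS[1])
  badC <- which(tab$startA >= tab$endA | tab$startB >= tab$endB)
  if (length(badC))
    stop("start >= end at row ", badC[1])
  key <- paste(tab$geneA_id, tab$geneB_id)
  ndup <- sum(duplicated(key))
  if (ndup > 0) {
    message(sprintf("readOrthologs: collapsed %d duplicated gene pair(s)", ndup))
    tab <- tab[!duplicated(key), , drop = FALSE]
  }
  message(sprintf("readOrthologs: %d ortholog pairs", nrow(tab)))
  rownames(tab) <- NULL
  tab
}

#' @rdname readOrthologs
#' @param orthologs ortholog table to write.
#' @export
writeOrthologs <- function(orthologs, path) {
  write.table(orthologs[, .orthologCols], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Write called regions as TSV or BED
#'
#' TSV style keeps all columns at full precision (group, chrom, start,
#' end, direction, peak_pos, peak_height) and round-trips through
#' \code{\link{readRegions}}. BED style is 0-based half-open with the
#' direction in the name field and the peak height in the score field
#' (fractional interpolated bounds are rounded outward to whole
#' bases).
#'
#' @param regions region data.frame from \code{\link{callRegions}} or
#'   \code{\link{differentialRegions}}.
#' @param path output path.
#' @param style "tsv" or "bed".
#' @param group group label written into the TSV (recycled).
#' @export
writeRegions <- function(regions, path, style = c("tsv", "bed"),
                         group = "group") {
  style <- match.arg(style)
  if (style == "bed") {
    if (!nrow(regions)) {
      file.create(path)
      return(invisible(NULL))
    }
    bed <- data.frame(chrom = regions$chrom,
                      start = floor(regions$start),
                      end = ceiling(regions$end),
                      name = regions$direction,
                      score = regions$peak_height,
                      stringsAsFactors = FALSE)
    write.table(bed, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else {
    out <- data.frame(group = if (nrow(regions)) group else character(),
                      regions[, c("chrom", "start", "end", "direction",
                                  "peak_pos", "peak_height")],
                      stringsAsFactors = FALSE)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(NULL)
}

#' @rdname writeRegions
#' @export
readRegions <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("group", "chrom", "start", "end", "direction",
                  "peak_pos", "peak_height") %in% names(tab)))
  tab$chrom <- as.character(tab$chrom)
  tab
}
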