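#' Assign genes to significant regions
#'
#' A gene is assigned to every region on its chromosome that its
#' [start, end) interval overlaps by at least one base pair
#' (any-overlap rule); genes straddling a region boundary are
#' therefore assigned.
#'
#' @param genes data.frame with columns gene_id, chrom, start, end
#'   (0-based half-open bp; a strand column is carried through if
#'   present).
#' @param regions data.frame of regions as produced by
#'   \code{\link{callRegions}} or \code{\link{differentialRegions}};
#'   a \code{region_id} column is added from the row index when
#'   absent.
#' @return data.frame with columns gene_id, region_id, direction,
#'   chrom, start, end (gene coordinates), one row per (gene, region)
#'   assignment.
#' @export
genesInRegions <- function(genes, regions) {
  if (!nrow(regions) || !nrow(genes))
    return(data.frame(gene_id = character(), region_id = character(),
                      direction = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE))
  if (is.null(regions$region_id))
    regions$region_id <- sprintf("R%03d", seq_len(nrow(regions)))
  out <- lapply(seq_len(nrow(regions)), function(r) {
    hit <- genes$chrom == regions$chrom[r] &
      genes$start < regions$end[r] & genes$end > regions$start[r]
    if (!any(hit)) return(NULL)
    data.frame(gene_id = genes$gene_id[hit],
               region_id = regions$region_id[r],
               direction = regions$direction[r],
               chrom = genes$chrom[hit], start = genes$start[hit],
               end = genes$end[hit], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(gene_id = character(), region_id = character(),
                      direction = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Split an ortholog table into per-species gene tables.
.speciesGenes <- function(orthologs, side = c("A", "B")) {
  side <- match.arg(side)
  data.frame(gene_id = orthologs[[paste0("gene", side, "_id")]],
             chrom = orthologs[[paste0("chrom", side)]],
             start = orthologs[[paste0("start", side)]],
             end = orthologs[[paste0("end", side)]],
             strand = orthologs[[paste0("strand", side)]],
             stringsAsFactors = FALSE)
}

#' @describeIn genesInRegions unique genes of one species of an
#'   ortholog table, as a gene table suitable for assignment.
#' @param orthologs an ortholog table (see
#'   \code{\link{readOrthologs}}).
#' @param side "A" or "B".
#' @export
orthologGenes <- function(orthologs, side = c("A", "B")) {
  g <- .speciesGenes(orthologs, side)
  g[!duplicated(g$gene_id), , drop = FALSE]
}

#' Ortholog pairs conserved in aberrant regions of both species
#'
#' Retains an ortholog pair when its species-A gene and species-B gene
#' are both assigned to significant regions of the same direction
#' (gain with gain, loss with loss; for comparative-analysis regions,
#' the same contrast direction). Such pairs mark aberrations selected
#' in both species' tumors.
#'
#' @param orthologs ortholog table (one row per ortholog pair).
#' @param assignA,assignB gene-to-region assignments from
#'   \code{\link{genesInRegions}} for species A and B.
#' @return data.frame with one row per retained (pair, regionA,
#'   regionB) combination: pair_id, geneA_id, regionA_id, geneB_id,
#'   regionB_id, direction, plus both genes' coordinates.
#' @export
conservedPairs <- function(orthologs, assignA, assignB) {
  empty <- data.frame(pair_id = character(), geneA_id = character(),
                      regionA_id = character(), geneB_id = character(),
                      regionB_id = character(), direction = character(),
                      chromA = character(), startA = numeric(),
                      endA = numeric(), chromB = character(),
                      startB = numeric(), endB = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(assignA) || !nrow(assignB)) return(empty)
  a <- merge(orthologs, assignA[, c("gene_id", "region_id", "direction")],
             by.x = "geneA_id", by.y = "gene_id")
  names(a)[names(a) == "region_id"] <- "regionA_id"
  names(a)[names(a) == "direction"] <- "directionA"
  ab <- merge(a, assignB[, c("gene_id", "region_id", "direction")],
              by.x = "geneB_id", by.y = "gene_id")
  names(ab)[names(ab) == "region_id"] <- "regionB_id"
  names(ab)[names(ab) == "direction"] <- "directionB"
  ab <- ab[ab$directionA == ab$directionB, , drop = FALSE]
  if (!nrow(ab)) return(empty)
  out <- data.frame(pair_id = ab$pair_id, geneA_id = ab$geneA_id,
                    regionA_id = ab$regionA_id, geneB_id = ab$geneB_id,
                    regionB_id = ab$regionB_id, direction = ab$directionA,
                    chromA = ab$chromA, startA = ab$startA, endA = ab$endA,
                    chromB = ab$chromB, startB = ab$startB, endB = ab$endB,
                    stringsAsFactors = FALSE)
  out <- out[order(out$regionA_id, out$regionB_id, out$startA), ]
  rownames(out) <- NULL
  out
}

#' Strand-inversion flag for one syntenic overlap
#'
#' +1 when the gene order of the overlap is preserved between the two
#' species, -1 when it is reversed, NA when either species contributes
#' only one gene (order undefined). The general statistic is the sign
#' of the rank correlation between species-A and species-B gene-start
#' orders; an exactly zero correlation is reported as +1 with a
#' warning.
#'
#' @param pairs data.frame of conserved pairs belonging to one
#'   overlap, with columns startA and startB.
#' @return +1, -1 or NA.
#' @export
inversionFlag <- function(pairs) {
  if (length(unique(pairs$geneA_id)) < 2 ||
      length(unique(pairs$geneB_id)) < 2)
    return(NA_real_)
  rho <- suppressWarnings(
    cor(rank(pairs$startA), rank(pairs$startB), method = "spearman"))
  if (is.na(rho) || rho == 0) {
    warning("tied gene orders between species; reporting +1")
    return(1)
  }
  sign(rho)
}

#' Cluster conserved ortholog pairs into syntenic overlaps
#'
#' Conserved pairs sharing the same (species-A region, species-B
#' region) combination form one syntenic overlap. The overlap bounds
#' in each species run from the start of its first gene to the end of
#' its last gene; distinct gene and pair counts and the strand
#' inversion flag are recorded. Overlaps supported by a single
#' ortholog pair are flagged (\code{singleton}) so abbreviated
#' reports can drop them while full output keeps them.
#'
#' @param pairs data.frame from \code{\link{conservedPairs}}.
#' @return data.frame with one row per overlap: regionA_id,
#'   regionB_id, direction, chromA, startA, endA, chromB, startB,
#'   endB, n_genes_A, n_genes_B, n_pairs, inversion, singleton, and
#'   comma-separated gene id lists genesA, genesB.
#' @export
clusterOverlaps <- function(pairs) {
  if (!nrow(pairs))
    return(data.frame(regionA_id = character(), regionB_id = character(),
                      direction = character(), chromA = character(),
                      startA = numeric(), endA = numeric(),
                      chromB = character(), startB = numeric(),
                      endB = numeric(), n_genes_A = integer(),
                      n_genes_B = integer(), n_pairs = integer(),
                      inversion = numeric(), singleton = logical(),
                      genesA = character(), genesB = character(),
                      stringsAsFactors = FALSE))
  key <- paste(pairs$regionA_id, pairs$regionB_id, sep = "\r")
  out <- lapply(split(pairs, key), function(d) {
    gA <- d[!duplicated(d$geneA_id), , drop = FALSE]
    gB <- d[!duplicated(d$geneB_id), , drop = FALSE]
    data.frame(
      regionA_id = d$regionA_id[1], regionB_id = d$regionB_id[1],
      direction = d$direction[1],
      chromA = d$chromA[1], startA = min(gA$startA), endA = max(gA$endA),
      chromB = d$chromB[1], startB = min(gB$startB), endB = max(gB$endB),
      n_genes_A = nrow(gA), n_genes_B = nrow(gB),
      n_pairs = length(unique(d$pair_id)),
      inversion = inversionFlag(d),
      singleton = length(unique(d$pair_id)) == 1L,
      genesA = paste(sort(unique(d$geneA_id)), collapse = ","),
      genesB = paste(sort(unique(d$geneB_id)), collapse = ","),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$regionA_id, out$regionB_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map significant regions between two species in one call
#'
#' Convenience wrapper chaining \code{\link{genesInRegions}},
#' \code{\link{conservedPairs}} and \code{\link{clusterOverlaps}} for
#' two region sets and one ortholog table.
#'
#' @param orthologs ortholog table.
#' @param regionsA,regionsB region data.frames for species A and B.
#' @return the \code{\link{clusterOverlaps}} data.frame.
#' @export
syntenicOverlaps <- function(orthologs, regionsA, regionsB) {
  aA <- genesInRegions(orthologGenes(orthologs, "A"), regionsA)
  aB <- genesInRegions(orthologGenes(orthologs, "B"), regionsB)
  clusterOverlaps(conservedPairs(orthologs, aA, aB))
}
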