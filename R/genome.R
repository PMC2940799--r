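#' Construct a Genome
#'
#' @param species single character label ("mouse", "human", ...).
#' @param lengths named numeric vector of chromosome lengths in bp, in
#'   the order chromosomes should appear in all output.
#' @return A \linkS4class{Genome} object.
#' @examples
#' Genome("toy", c(chr1 = 1e8, chr2 = 5e7))
#' @export
Genome <- function(species, lengths) {
  new("Genome", species = as.character(species), lengths = lengths)
}

#' @describeIn Genome chromosome lengths accessor (named numeric, bp).
#' @param x a Genome.
#' @export
chromLengths <- function(x) {
  stopifnot(is(x, "Genome"))
  x@lengths
}

#' @describeIn Genome chromosome names in genome order.
#' @export
chromNames <- function(x) names(chromLengths(x))

#' @describeIn Genome species label accessor.
#' @export
species <- function(x) {
  stopifnot(is(x, "Genome"))
  x@species
}

setMethod("show", "Genome", function(object) {
  cat(sprintf("Genome: %s (%d chromosomes, %.1f Mb total)\n",
              object@species, length(object@lengths),
              sum(object@lengths) / 1e6))
})

#' Built-in genome presets
#'
#' Approximate autosome + X chromosome lengths for the mouse and human
#' reference assemblies used by BAC-array studies. Lengths are rounded
#' to 0.1 Mb; they set the scale of simulated cohorts and the extent
#' of evaluation grids, for which assembly-patch precision is
#' irrelevant.
#'
#' @return A \linkS4class{Genome}.
#' @examples
#' mouseGenome()
#' @export
mouseGenome <- function() {
  len <- c(197.1, 181.7, 159.6, 155.6, 152.5, 149.5, 145.1, 132.1,
           124.1, 130.1, 121.8, 120.5, 120.3, 125.2, 103.5, 98.3,
           95.2, 90.7, 61.3, 165.6) * 1e6
  names(len) <- c(as.character(1:19), "X")
  Genome("mouse", len)
}

#' @rdname mouseGenome
#' @export
humanGenome <- function() {
  len <- c(247.2, 243.0, 199.5, 191.3, 180.9, 170.9, 158.8, 146.3,
           140.3, 135.4, 134.5, 132.3, 114.1, 106.4, 100.3, 88.8,
           78.8, 76.1, 63.8, 62.4, 46.9, 49.7, 154.9) * 1e6
  names(len) <- c(as.character(1:22), "X")
  Genome("human", len)
}
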