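#' Simulate a full two-group scenario from a config file
#'
#' A YAML scenario file fully describes a simulated cohort study:
#' the genome (a preset name, \code{"mouse"} or \code{"human"}, or an
#' explicit species + chromosome-length map), the probe count, and one
#' entry per tumor group giving the group label, sample count, noise
#' level, tumor-type mix and the list of planted events (fields as in
#' \code{\link{cnaSpec}}, with snake_case keys). Example:
#'
#' \preformatted{
#' seed: 1
#' genome: mouse
#' n_probes: 3080
#' groups:
#'   - label: brca1
#'     n_samples: 30
#'     noise_sd: 0.2
#'     tumor_type_mix: {carcinoma: 0.9, carcinosarcoma: 0.1}
#'     cnas:
#'       - {chrom: "6", start: 40.0e6, end: 70.0e6, direction: gain,
#'          frequency: 0.6, amplitude_mean: 0.8}
#'       - {chrom: "14", direction: loss, frequency: 0.4,
#'          amplitude_mean: -0.6, whole_chromosome: true}
#'   - label: control
#'     n_samples: 30
#'     noise_sd: 0.2
#' }
#'
#' Group seeds are derived deterministically from the scenario seed
#' (seed + group index), so the whole scenario is reproducible from
#' the file alone; a \code{seed} argument overrides the file's.
#'
#' @param config path to a YAML scenario file, or an equivalent nested
#'   list.
#' @param seed optional integer overriding the scenario seed.
#' @param outDir optional directory; when given, the aCGH table,
#'   sample annotation and ground-truth event log are written there as
#'   TSV (\code{acgh.tsv}, \code{samples.tsv}, \code{ground_truth.tsv}).
#' @return A list with elements \code{acgh} (the combined
#'   \linkS4class{ACGHSet} over all groups) and \code{probeMap}.
#' @export
simulateScenario <- function(config, seed = NULL, outDir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(seed)) seed <- config$seed
  if (is.null(seed)) stop("scenario needs a seed (file key 'seed' or argument)")
  seed <- as.integer(seed)
  num <- function(x) {                # YAML "1.0e8" arrives as character
    v <- as.numeric(unlist(x))
    names(v) <- names(unlist(x))
    v
  }
  genome <- if (is.character(config$genome)) {
    switch(config$genome, mouse = mouseGenome(), human = humanGenome(),
           stop("unknown genome preset: ", config$genome))
  } else {
    Genome(config$genome$species, num(config$genome$chromosomes))
  }
  nProbes <- if (is.null(config$n_probes)) 3080L else as.integer(config$n_probes)
  pm <- buildProbeMap(genome, nProbes, seed = seed)
  groups <- lapply(seq_along(config$groups), function(i) {
    gc <- config$groups[[i]]
    cnas <- if (length(gc$cnas)) do.call(rbind, lapply(gc$cnas, function(cn)
      cnaSpec(chrom = as.character(cn$chrom),
              start = if (is.null(cn$start)) NA_real_ else num(cn$start),
              end = if (is.null(cn$end)) NA_real_ else num(cn$end),
              direction = cn$direction,
              frequency = num(cn$frequency),
              amplitudeMean = num(cn$amplitude_mean),
              amplitudeSd = if (is.null(cn$amplitude_sd)) 0 else num(cn$amplitude_sd),
              wholeChromosome = isTRUE(cn$whole_chromosome))))
    mix <- if (is.null(gc$tumor_type_mix)) c(unknown = 1)
           else num(gc$tumor_type_mix)
    simulateGroup(pm, gc$label, nSamples = as.integer(gc$n_samples),
                  noiseSd = num(gc$noise_sd), cnas = cnas,
                  tumorTypeMix = mix, seed = seed + i)
  })
  acgh <- if (length(groups) > 1) combineGroups(groups) else groups[[1]]
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeACGH(acgh, file.path(outDir, "acgh.tsv"),
              file.path(outDir, "samples.tsv"))
    gt <- groundTruth(acgh)
    if (is.null(gt))
      gt <- data.frame(sample_id = character(), chrom = character(),
                       start = numeric(), end = numeric(),
                       direction = character(), amplitude = numeric())
    write.table(gt, file.path(outDir, "ground_truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(acgh = acgh, probeMap = pm)
}
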