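# Small deterministic fixtures shared across test files.

toyGenome <- function(nchr = 2, len = 1e8, species = "toy") {
  Genome(species, setNames(rep(len, nchr), paste0("c", seq_len(nchr))))
}

# Build an ACGHSet directly from a probe layout and a log2 matrix.
# positions: named list chrom -> numeric midpositions.
makeSet <- function(positions, M, genome, group = "g",
                    sampleIds = NULL) {
  probes <- do.call(rbind, lapply(names(positions), function(ch)
    data.frame(chrom = ch, mid_bp = positions[[ch]],
               stringsAsFactors = FALSE)))
  probes <- data.frame(probe_id = sprintf("p%03d", seq_len(nrow(probes))),
                       probes, stringsAsFactors = FALSE)
  if (is.null(sampleIds))
    sampleIds <- sprintf("%s_s%02d", group, seq_len(ncol(M)))
  samples <- data.frame(sample_id = sampleIds, group = group,
                        tumor_type = "unknown", stringsAsFactors = FALSE)
  ACGHSet(M, probes, samples, genome)
}

# A KSECurve built directly from explicit grid values (for geometry
# tests of region calling and peak finding).
makeCurve <- function(positions, values, sign = "gains",
                      genome = NULL, params = KSEParams()) {
  if (is.null(genome))
    genome <- Genome("toy", setNames(
      vapply(positions, max, numeric(1)) + 1, names(positions)))
  tab <- do.call(rbind, lapply(names(positions), function(ch)
    data.frame(chrom = ch, pos = positions[[ch]], kse = values[[ch]],
               stringsAsFactors = FALSE)))
  tab$chrom <- factor(tab$chrom, levels = chromNames(genome))
  new("KSECurve", sign = sign, table = tab, params = params,
      genome = genome)
}

# A SampleKSE built directly from a samples x positions matrix.
makeSampleKSE <- function(positions, K, groups,
                          params = KSEParams()) {
  genome <- Genome("toy", setNames(
    vapply(positions, max, numeric(1)) + 1, names(positions)))
  grid <- do.call(rbind, lapply(names(positions), function(ch)
    data.frame(chrom = ch, pos = positions[[ch]],
               stringsAsFactors = FALSE)))
  grid$chrom <- factor(grid$chrom, levels = chromNames(genome))
  if (is.null(rownames(K)))
    rownames(K) <- sprintf("s%02d", seq_len(nrow(K)))
  new("SampleKSE", grid = grid, kse = K,
      groups = setNames(groups, rownames(K)),
      params = params, genome = genome)
}
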