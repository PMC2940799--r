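# Independent brute-force oracles. These re-derive expected values by
# direct enumeration or naive double loops and never share code with
# the implementation they check.

# Naive O(samples x probes x grid) kernel-smoothed estimate.
# acgh: ACGHSet; sign: gains/losses/combined; evaluated at the given
# (chrom, pos) grid data.frame. Returns a numeric vector.
bruteKSE <- function(acgh, sign, grid, sigma, radius) {
  probes <- probeTable(acgh)
  M <- log2Ratios(acgh)
  out <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    x <- grid$pos[i]; ch <- as.character(grid$chrom[i])
    acc <- 0
    for (p in seq_len(nrow(probes))) {
      if (probes$chrom[p] != ch) next
      d <- x - probes$mid_bp[p]
      if (abs(d) > radius) next
      h <- 0
      for (s in seq_len(ncol(M))) {
        v <- M[p, s]
        if (is.na(v)) next
        h <- h + switch(sign,
                        gains = max(v, 0),
                        losses = min(v, 0),
                        combined = v)
      }
      acc <- acc + exp(-d^2 / (2 * sigma^2)) * h
    }
    out[i] <- acc
  }
  out
}

# Naive run scanner: maximal index runs with v >= thr (or > thr).
bruteRuns <- function(v, thr, strict = FALSE) {
  ok <- if (strict) v > thr else v >= thr
  runs <- list()
  i <- 1
  while (i <= length(v)) {
    if (ok[i]) {
      j <- i
      while (j < length(v) && ok[j + 1]) j <- j + 1
      runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else i <- i + 1
  }
  runs
}

# Welch t statistic and two-tailed p from the textbook formulas.
bruteWelch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, p = 2 * stats::pt(-abs(t), df))
}

# Exhaustive class-label permutation FDR cutoffs computed by direct
# enumeration with per-position loops (oracle for snrFdrCutoffs on
# toys where all assignments can be listed).
bruteFdrCutoffs <- function(K, labels, labelA, labelB, q) {
  pool <- which(labels %in% c(labelA, labelB))
  K <- K[pool, , drop = FALSE]
  labels <- labels[pool]
  n <- nrow(K); nA <- sum(labels == labelA)
  snrFor <- function(idxA) {
    idxB <- setdiff(seq_len(n), idxA)
    vapply(seq_len(ncol(K)), function(j) {
      a <- K[idxA, j]; b <- K[idxB, j]
      num <- mean(a) - mean(b); den <- sd(a) + sd(b)
      if (den == 0 && num == 0) 0 else num / den
    }, numeric(1))
  }
  obs <- snrFor(which(labels == labelA))
  combos <- combn(n, nA)
  perms <- lapply(seq_len(ncol(combos)), function(k) snrFor(combos[, k]))
  candPos <- sort(unique(obs[obs > 0]))
  candNeg <- sort(unique(-obs[obs < 0]))
  fdrP <- vapply(candPos, function(c) {
    mean(vapply(perms, function(s) sum(s >= c), numeric(1))) /
      max(1, sum(obs >= c))
  }, numeric(1))
  fdrN <- vapply(candNeg, function(c) {
    mean(vapply(perms, function(s) sum(s <= -c), numeric(1))) /
      max(1, sum(obs <= -c))
  }, numeric(1))
  list(pos = if (any(fdrP <= q)) min(candPos[fdrP <= q]) else Inf,
       neg = if (any(fdrN <= q)) min(candNeg[fdrN <= q]) else Inf,
       fdrPos = data.frame(cutoff = candPos, fdr = fdrP),
       fdrNeg = data.frame(cutoff = candNeg, fdr = fdrN))
}
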