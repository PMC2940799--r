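toyParams <- KSEParams(kernelWidth = 2e7, gridStep = 1e6)

test_that("all-zero data give an identically zero curve and degenerate null", {
  g <- toyGenome(2)
  pm <- buildProbeMap(g, 20, seed = 1)
  gset <- simulateGroup(pm, "z", 3, noiseSd = 0, seed = 1)
  for (sgn in c("gains", "losses", "combined"))
    expect_true(all(kseTable(groupKSE(gset, sgn, toyParams))$kse == 0))
  expect_warning(th <- significanceThreshold(gset, "gains", toyParams,
                                             nPerm = 50, seed = 1),
                 "degenerate")
  expect_equal(thresholdValue(th), 0)
})

test_that("a single positive probe reproduces the closed-form kernel", {
  g <- toyGenome(1)
  q <- 5e7; v <- 0.9
  gset <- makeSet(list(c1 = q), matrix(v, 1, 1), g)
  cu <- kseTable(groupKSE(gset, "gains", toyParams))
  d <- cu$pos - q
  expected <- ifelse(abs(d) <= toyParams@truncationRadius,
                     v * exp(-d^2 / (2 * toyParams@sigma^2)), 0)
  expect_equal(cu$kse, expected, tolerance = 1e-12)
  expect_true(all(kseTable(groupKSE(gset, "losses", toyParams))$kse == 0))
})

test_that("optimized convolution equals the brute-force double sum", {
  g <- toyGenome(2, len = 5e7)
  for (rep in 1:5) {
    set.seed(100 + rep)
    n <- sample(5:10, 1); s <- sample(2:4, 1)
    pos <- list(c1 = sort(sample.int(5e7, n)),
                c2 = sort(sample.int(5e7, n)))
    M <- matrix(rnorm(2 * n * s, sd = 0.5), 2 * n, s)
    gset <- makeSet(pos, M, g)
    for (sgn in c("gains", "losses", "combined")) {
      cu <- kseTable(groupKSE(gset, sgn, toyParams))
      oracle <- bruteKSE(gset, sgn, cu, toyParams@sigma,
                         toyParams@truncationRadius)
      expect_lt(max(abs(cu$kse - oracle)), 1e-9)
    }
  }
})

test_that("combined curve is additive and group KSE is linear in samples", {
  g <- toyGenome(2, len = 5e7)
  set.seed(42)
  pos <- list(c1 = sort(sample.int(5e7, 8)), c2 = sort(sample.int(5e7, 8)))
  M <- matrix(rnorm(32, sd = 0.4), 16, 2)
  gset <- makeSet(pos, M, g)
  gains <- kseTable(groupKSE(gset, "gains", toyParams))$kse
  losses <- kseTable(groupKSE(gset, "losses", toyParams))$kse
  comb <- kseTable(groupKSE(gset, "combined", toyParams))$kse
  expect_equal(comb, gains + losses, tolerance = 1e-12)

  s1 <- makeSet(pos, M[, 1, drop = FALSE], g)
  s2 <- makeSet(pos, M[, 2, drop = FALSE], g)
  expect_equal(comb,
               kseTable(groupKSE(s1, "combined", toyParams))$kse +
               kseTable(groupKSE(s2, "combined", toyParams))$kse,
               tolerance = 1e-12)
})

test_that("missing log2 values are excluded from kernel sums", {
  g <- toyGenome(1)
  gset <- makeSet(list(c1 = c(4e7, 5e7)),
                  matrix(c(0.5, NA, 0.5, 0.3), 2, 2), g)
  cu <- kseTable(groupKSE(gset, "gains", toyParams))
  # probe 2 aggregates only the observed 0.3
  at2 <- cu$kse[cu$pos == 5e7]
  expect_equal(at2, 0.3 + 1.0 * exp(-(1e7)^2 / (2 * toyParams@sigma^2)),
               tolerance = 1e-12)
})

test_that("the null threshold follows the k-th largest quantile convention", {
  g <- toyGenome(1)
  pm <- buildProbeMap(g, 50, seed = 2)
  gset <- simulateGroup(pm, "n", 10, noiseSd = 0.3, seed = 3)
  th <- significanceThreshold(gset, "gains", toyParams, nPerm = 100,
                              alpha = 0.05, seed = 4)
  expect_equal(thresholdValue(th),
               sort(nullMaxima(th), decreasing = TRUE)[6])
  th2 <- significanceThreshold(gset, "gains", toyParams, nPerm = 100,
                               alpha = 0.05, seed = 4)
  expect_equal(nullMaxima(th2), nullMaxima(th))
})

test_that("null maxima match exhaustive enumeration on a sparse toy", {
  # 4 probes, aggregates {a,0,0,0}: every assignment places the single
  # kernel at a probe position, where the grid evaluates it at full
  # height, so each null maximum equals a exactly.
  g <- toyGenome(1)
  a <- 0.73
  gset <- makeSet(list(c1 = c(1e7, 3e7, 6e7, 9e7)),
                  matrix(c(a, 0, 0, 0), 4, 1), g)
  th <- significanceThreshold(gset, "gains", toyParams, nPerm = 40,
                              seed = 5)
  expect_equal(unname(nullMaxima(th)), rep(a, 40), tolerance = 1e-12)
  expect_equal(thresholdValue(th), a, tolerance = 1e-12)

  # richer aggregates: sampled maxima live inside the exhaustively
  # enumerated set of assignment maxima
  H <- c(1, 0.5, 0, 0)
  gset2 <- makeSet(list(c1 = c(1e7, 1.2e7, 6e7, 9e7)),
                   matrix(H, 4, 1), g)
  th2 <- significanceThreshold(gset2, "gains", toyParams, nPerm = 60,
                               seed = 6)
  cu <- kseTable(groupKSE(gset2, "gains", toyParams))
  perms <- asplit(rbind(
    c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 3, 2), c(2, 1, 3, 4),
    c(2, 3, 1, 4), c(2, 4, 3, 1), c(3, 2, 1, 4), c(4, 2, 3, 1),
    c(3, 1, 2, 4), c(4, 1, 3, 2), c(3, 4, 1, 2), c(4, 3, 2, 1),
    c(1, 2, 4, 3), c(2, 1, 4, 3), c(3, 4, 2, 1), c(4, 3, 1, 2),
    c(1, 3, 4, 2), c(1, 4, 2, 3), c(2, 3, 4, 1), c(2, 4, 1, 3),
    c(3, 1, 4, 2), c(3, 2, 4, 1), c(4, 1, 2, 3), c(4, 2, 1, 3)), 1)
  enumerated <- vapply(perms, function(pp) {
    gs <- makeSet(list(c1 = c(1e7, 1.2e7, 6e7, 9e7)),
                  matrix(H[pp], 4, 1), g)
    max(abs(kseTable(groupKSE(gs, "gains", toyParams))$kse))
  }, numeric(1))
  expect_true(all(vapply(nullMaxima(th2), function(m)
    any(abs(m - enumerated) < 1e-9), logical(1))))
})

test_that("regions are bounded by interpolated threshold crossings", {
  cu <- makeCurve(list(c1 = c(0, 1e6, 2e6, 3e6)),
                  list(c1 = c(0, 2, 2, 0)))
  reg <- callRegions(cu, 1)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$start, 0.5e6)
  expect_equal(reg$end, 2.5e6)
  expect_equal(reg$peak_height, 2)
  expect_equal(reg$direction, "gain")

  # everywhere below threshold: no regions
  expect_equal(nrow(callRegions(cu, 3)), 0)

  # losses mirror gains
  cl <- makeCurve(list(c1 = c(0, 1e6, 2e6, 3e6)),
                  list(c1 = c(0, -2, -2, 0)), sign = "losses")
  regl <- callRegions(cl, 1)
  expect_equal(regl$start, 0.5e6)
  expect_equal(regl$direction, "loss")
  expect_equal(regl$peak_height, -2)
})

test_that("region calling agrees with a brute-force run scanner", {
  set.seed(7)
  for (rep in 1:10) {
    v <- abs(rnorm(30))
    pos <- sort(sample.int(1e8, 30))
    cu <- makeCurve(list(c1 = pos), list(c1 = v))
    thr <- quantile(v, 0.7)
    reg <- callRegions(cu, unname(thr))
    runs <- bruteRuns(v, thr)
    expect_equal(nrow(reg), length(runs))
    for (k in seq_along(runs)) {
      i <- runs[[k]][1]; j <- runs[[k]][2]
      expect_equal(reg$peak_height[k], max(v[i:j]))
      expect_true(reg$start[k] <= pos[i] && reg$end[k] >= pos[j])
    }
  }
})

test_that("peaks are strict interior extrema with leftmost-plateau ties", {
  mono <- makeCurve(list(c1 = c(0, 1e6, 2e6, 3e6)),
                    list(c1 = c(0, 1, 2, 3)))
  expect_equal(nrow(findPeaks(mono)), 0)

  single <- makeCurve(list(c1 = c(0, 1e6, 2e6)), list(c1 = c(0, 1, 0)))
  pk <- findPeaks(single)
  expect_equal(pk$pos, 1e6)
  expect_equal(pk$height, 1)

  plateau <- makeCurve(list(c1 = c(0, 1e6, 2e6, 3e6)),
                       list(c1 = c(0, 1, 1, 0)))
  pk2 <- findPeaks(plateau)
  expect_equal(pk2$pos, 1e6)

  # chromosome endpoints are never peaks
  edge <- makeCurve(list(c1 = c(0, 1e6, 2e6)), list(c1 = c(3, 1, 2)))
  expect_equal(nrow(findPeaks(edge)), 0)

  # losses: strict minima
  dip <- makeCurve(list(c1 = c(0, 1e6, 2e6)), list(c1 = c(0, -1, 0)),
                   sign = "losses")
  expect_equal(findPeaks(dip)$height, -1)
})

test_that("scaling maps the threshold to one and commutes with calling", {
  cu <- makeCurve(list(c1 = c(0, 1e6, 2e6, 3e6)),
                  list(c1 = c(0, 1.2, 2.4, 0)))
  sc <- scaleCurve(cu, 1.2)
  expect_equal(max(kseTable(sc)$kse), 2.0)
  r1 <- callRegions(sc, 1)
  r2 <- callRegions(cu, 1.2)
  expect_equal(r1$start, r2$start)
  expect_equal(r1$end, r2$end)
  expect_equal(r1$peak_height * 1.2, r2$peak_height)
  expect_error(scaleCurve(cu, 0), "degenerate")

  cl <- makeCurve(list(c1 = c(0, 1e6)), list(c1 = c(0, -1.2)),
                  sign = "losses")
  expect_equal(min(kseTable(scaleCurve(cl, 1.2))$kse), -1)
})

test_that("per-sample permutation null is available as an option", {
  g <- toyGenome(1)
  pm <- buildProbeMap(g, 40, seed = 8)
  gset <- simulateGroup(pm, "n", 6, noiseSd = 0.3, seed = 9)
  th <- significanceThreshold(gset, "gains", toyParams, nPerm = 50,
                              seed = 10, unit = "sample")
  expect_gt(thresholdValue(th), 0)
})
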