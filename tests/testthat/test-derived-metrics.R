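test_that("metapopulation capacity matches closed forms", {
  two <- PatchNetwork(c("a", "b"), x = c(0, 1), y = c(0, 0),
                      length = c(1, 1))
  expect_equal(metapopCapacity(two, alpha = 1), exp(-1), tolerance = 1e-9)

  # equilateral triangle with equal lengths A: M = A^2 e^{-ad} (J - I),
  # dominant eigenvalue 2 A^2 e^{-ad}
  A <- 1.3; d <- 0.9; a <- 0.6
  tri <- PatchNetwork(c("a", "b", "c"),
                      x = c(0, d, d / 2), y = c(0, 0, d * sqrt(3) / 2),
                      length = rep(A, 3))
  expect_equal(metapopCapacity(tri, a), 2 * A^2 * exp(-a * d),
               tolerance = 1e-9)

  one <- PatchNetwork("a", 0, 0, 1)
  expect_warning(l <- metapopCapacity(one, 1), "single patch")
  expect_equal(l, 0)
})

test_that("capacity agrees with a dense power-iteration oracle", {
  net <- toyNetwork(30, seed = 77)
  a <- 0.8
  A <- unname(patchLengths(net))
  M <- outer(A, A) * exp(-a * patchDistances(net))
  diag(M) <- 0
  v <- rep(1, 30)
  for (k in 1:4000) {
    w <- M %*% v
    v <- w / sqrt(sum(w^2))
  }
  lref <- as.numeric(t(v) %*% M %*% v)
  expect_equal(metapopCapacity(net, a), lref, tolerance = 1e-9)
})

test_that("capacity is relabel-invariant, grows with patches, shrinks with alpha", {
  net <- toyNetwork(12, seed = 31)
  perm <- sample(12)
  xy <- patchCoords(net)
  netp <- PatchNetwork(patchIds(net)[perm], xy[perm, 1], xy[perm, 2],
                       unname(patchLengths(net))[perm])
  expect_equal(metapopCapacity(net, 0.7), metapopCapacity(netp, 0.7),
               tolerance = 1e-9)

  bigger <- PatchNetwork(c(patchIds(net), "extra"),
                         c(xy[, 1], 2), c(xy[, 2], 2),
                         c(unname(patchLengths(net)), 0.8))
  expect_gte(metapopCapacity(bigger, 0.7), metapopCapacity(net, 0.7))

  ls <- vapply(c(0.2, 0.5, 1, 2), function(a) metapopCapacity(net, a),
               numeric(1))
  expect_true(all(diff(ls) < 0))
})

test_that("capacity posterior propagates and mixes alpha draws", {
  net <- toyNetwork(8, seed = 19)
  # degenerate posterior: zero-width interval at the point value
  d0 <- cbind(alpha = rep(0.6, 50))
  cp0 <- capacityPosterior(drawsObject(d0), net)
  expect_equal(cp0$summary$q025, cp0$summary$q975)
  expect_equal(cp0$summary$mean, metapopCapacity(net, 0.6),
               tolerance = 1e-12)

  # two-point mixture: summary equals the hand-mixed analytic lambdas
  a1 <- 0.4; a2 <- 1.2
  d <- cbind(alpha = rep(c(a1, a2), each = 100))
  cp <- capacityPosterior(drawsObject(d), net)
  l1 <- metapopCapacity(net, a1); l2 <- metapopCapacity(net, a2)
  expect_equal(cp$summary$mean, (l1 + l2) / 2, tolerance = 1e-9)
  expect_equal(sort(unique(cp$lambdaDraws[, 1])), sort(c(l1, l2)),
               tolerance = 1e-9)

  # per-draw lambda is strictly decreasing in that draw's alpha
  set.seed(3)
  dr <- cbind(alpha = runif(40, 0.2, 2))
  cpm <- capacityPosterior(drawsObject(dr), net)
  o <- order(dr[, "alpha"])
  expect_true(all(diff(cpm$lambdaDraws[o, 1]) < 0))
})

test_that("annual capacities use each year's alpha draws", {
  net <- toyNetwork(6, seed = 23)
  d <- cbind(alpha = c(0.5, 0.7), alpha_t2 = c(0.6, 0.9),
             alpha_t3 = c(1.1, 0.4))
  cp <- capacityPosterior(drawsObject(d, modelSpec("DV")), net)
  expect_equal(cp$summary$series, c("overall", "2", "3"))
  expect_equal(unname(cp$lambdaDraws[1, "2"]), metapopCapacity(net, 0.6),
               tolerance = 1e-9)
  expect_equal(unname(cp$lambdaDraws[2, "3"]), metapopCapacity(net, 0.4),
               tolerance = 1e-9)
})

test_that("colonization surfaces obey their closed form", {
  net <- PatchNetwork(c("a", "b"), x = c(0, 5), y = c(0, 0),
                      length = c(1.5, 1))
  # beta = 0 or no occupied source: identically zero
  expect_equal(max(colonizationSurface(net, c(1, 1), 1, 0)$grid), 0)
  expect_equal(max(colonizationSurface(net, c(0, 0), 1, 0.5)$grid), 0)

  # hand evaluation with a single occupied source
  sf <- colonizationSurface(net, c(1, 0), alpha = 0.4, beta = 0.3,
                            cellsize = 1, buffer = 2)
  ny <- nrow(sf$grid); nx <- ncol(sf$grid)
  for (cell in list(c(1, 1), c(2, 3), c(ny, nx), c(3, 6))) {
    px <- sf$origin[1] + (cell[2] - 0.5) * sf$cellsize
    py <- sf$origin[2] + (ny - cell[1] + 0.5) * sf$cellsize
    dref <- sqrt((px - 0)^2 + (py - 0)^2)
    gref <- 1 - exp(-0.3 * 1.5 * exp(-0.4 * dref))
    expect_equal(sf$grid[cell[1], cell[2]], gref, tolerance = 1e-12)
  }
  expect_true(all(sf$grid >= 0 & sf$grid < 1))
  expect_equal(unname(sf$summary["mean"]), mean(sf$grid))
})

test_that("network colonization averages the patch-level kernel", {
  # alpha = 0 and unit lengths: S_i = beta (n - 1); pick beta for gamma = 0.5
  n <- 6
  net <- PatchNetwork(sprintf("p%d", 1:n), x = seq_len(n), y = rep(0, n),
                      length = rep(1, n))
  beta <- log(2) / (n - 1)
  expect_equal(networkColonization(net, rep(1, n), alpha = 0, beta = beta),
               0.5, tolerance = 1e-12)

  one <- PatchNetwork("a", 0, 0, 1)
  expect_equal(networkColonization(one, 1, 1, 0.5), 0)

  net5 <- toyNetwork(5, seed = 41)
  z <- c(1, 0, 1, 1, 0)
  A <- unname(patchLengths(net5)); D <- patchDistances(net5)
  ref <- 0
  for (i in 1:5) {
    s <- 0
    for (j in 1:5) if (j != i) s <- s + A[j] * z[j] * exp(-0.6 * D[i, j])
    ref <- ref + (1 - exp(-0.25 * s)) / 5
  }
  expect_equal(networkColonization(net5, z, 0.6, 0.25), ref,
               tolerance = 1e-12)
})

test_that("the Freeman-Tukey discrepancy and GOF bookkeeping are sound", {
  expect_equal(freemanTukeyStatistic(c(0, 1), c(0.25, 0.25)), 0.5)
  expect_equal(freemanTukeyStatistic(c(2, 3, 0), c(2, 3, 0)), 0)

  sim <- simulateScenario(smallScenario(n = 12, T = 6, seed = 17))
  fit <- fitSPOM(sim$history, sim$network, modelSpec("DI"),
                 quickConfig(nIter = 1500, seed = 5))
  g <- freemanTukeyGOF(sim$history, fit, seed = 2, maxDraws = 200)
  expect_true(g$pValue >= 0 && g$pValue <= 1)
  expect_equal(length(g$Tobs), length(g$Trep))
  expect_true(all(g$Tobs >= 0))

  # observed discrepancy is invariant to consistent patch reordering
  perm <- sample(nPatches(sim$network))
  y <- detectionArray(sim$history)[perm, , ]
  histp <- DetectionHistory(y, yearLabels(sim$history),
                            patchIds(sim$history)[perm])
  fitp <- fit
  fitp@zDraws <- fit@zDraws[, perm, , drop = FALSE]
  gp <- freemanTukeyGOF(histp, fitp, seed = 2, maxDraws = 200)
  expect_equal(gp$Tobs, g$Tobs, tolerance = 1e-10)
  expect_lt(abs(gp$pValue - g$pValue), 0.1)
})
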