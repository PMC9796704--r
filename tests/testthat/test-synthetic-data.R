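test_that("network generation is deterministic and hits its length targets", {
  cfg <- assyntScenario(seed = 11)
  net1 <- generateNetwork(cfg)
  net2 <- generateNetwork(cfg)
  expect_identical(patchCoords(net1), patchCoords(net2))
  expect_identical(patchLengths(net1), patchLengths(net2))

  expect_equal(nPatches(net1), 98L)
  len <- unname(patchLengths(net1))
  expect_true(all(len >= 0.05 & len <= 3))
  expect_lt(abs(mean(len) - 0.847) / 0.847, 0.05)

  one <- generateNetwork(scenarioConfig(nPatches = 1, T = 2, seed = 1))
  expect_equal(unname(patchDistances(one)), matrix(0, 1, 1))

  expect_error(scenarioConfig(nPatches = 5, lengthRange = c(1, 2),
                              lengthMean = 3, T = 5), "infeasible")
})

test_that("occupancy simulation honours absorbing edge cases", {
  net <- toyNetwork(6, seed = 2)
  # nothing can ever colonize when beta = 0 and the system starts empty
  zc <- simulateOccupancy(net, spomParameters(psi1 = 0, beta = 0,
                                              alpha = 1),
                          modelSpec("DI"), T = 6, seed = 3)
  expect_true(all(zc == 0L))
  # extinction ~ 0 keeps a fully occupied system occupied
  zf <- simulateOccupancy(net, spomParameters(psi1 = 1, delta0 = -20,
                                              delta1 = 0, alpha = 1,
                                              beta = 0.1),
                          modelSpec("DI"), T = 6, seed = 3)
  expect_true(all(zf == 1L))
  # determinism
  p <- spomParameters(psi1 = 0.5, delta0 = 1, delta1 = -1, alpha = 0.6,
                      beta = 0.3)
  expect_identical(simulateOccupancy(net, p, modelSpec("DI"), 8, seed = 9),
                   simulateOccupancy(net, p, modelSpec("DI"), 8, seed = 9))
})

test_that("two-patch occupancy matches the exact 4-state Markov chain", {
  net <- PatchNetwork(c("a", "b"), x = c(0, 0.8), y = c(0, 0),
                      length = c(0.9, 1.1))
  pars <- spomParameters(psi1 = 0.5, delta0 = 0.2, delta1 = -0.8,
                         alpha = 0.7, beta = 0.9)
  # structural connectivity keeps colonization positive everywhere, so
  # the 4-state chain is irreducible and has a proper stationary law
  # (under demographic weighting the empty state would be absorbing)
  mod <- modelSpec("UI")
  A <- unname(patchLengths(net)); d <- patchDistances(net)[1, 2]
  eps <- plogis(0.2 - 0.8 * A)
  gam <- 1 - exp(-0.9 * c(A[2], A[1]) * exp(-0.7 * d))
  # exact transition matrix over states (z1, z2) in {00, 10, 01, 11}
  states <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  P <- matrix(0, 4, 4)
  for (s in 1:4) {
    z <- states[s, ]
    psi <- ifelse(z == 1, 1 - eps, gam)
    for (s2 in 1:4) {
      z2 <- states[s2, ]
      P[s, s2] <- prod(ifelse(z2 == 1, psi, 1 - psi))
    }
  }
  ev <- eigen(t(P))
  stat <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  stat <- stat / sum(stat)
  exactOcc <- sum(stat * rowSums(states)) / 2

  Tlong <- 30000
  z <- simulateOccupancy(net, pars, mod, T = Tlong, seed = 13)
  expect_lt(abs(mean(z) - exactOcc), 0.02)
})

test_that("simulated transition frequencies follow the Markov kernel", {
  net <- toyNetwork(3, seed = 21, lengths = c(0.5, 1, 1.5))
  A <- unname(patchLengths(net))
  eps <- plogis(1 - 1.5 * A)
  # persistence: start fully occupied, one step
  pars <- spomParameters(psi1 = 1, delta0 = 1, delta1 = -1.5, alpha = 0.6,
                         beta = 0.2)
  M <- 3000
  surv <- matrix(0L, M, 3)
  for (r in seq_len(M))
    surv[r, ] <- simulateOccupancy(net, pars, modelSpec("DI"), 2,
                                   seed = 5000 + r)[, 2]
  for (i in 1:3) {
    pv <- stats::binom.test(sum(surv[, i]), M, 1 - eps[i])$p.value
    expect_gt(pv, 1e-4)
  }
  # colonization under the structural (unweighted) assumption from an
  # empty start: gamma is a landscape constant per patch
  pars0 <- spomParameters(psi1 = 0, delta0 = 1, delta1 = -1.5, alpha = 0.6,
                          beta = 0.8)
  gam <- colonizationProb(connectivityVector(net, NULL, 0.6, 0.8))
  col <- matrix(0L, M, 3)
  for (r in seq_len(M))
    col[r, ] <- simulateOccupancy(net, pars0, modelSpec("UI"), 2,
                                  seed = 9000 + r)[, 2]
  for (i in 1:3) {
    pv <- stats::binom.test(sum(col[, i]), M, gam[i])$p.value
    expect_gt(pv, 1e-4)
  }
})

test_that("detections are false-positive-free and frequency-calibrated", {
  z <- matrix(0L, 10, 4)
  det <- spomParameters(pT = rep(0.9, 4))
  dh <- simulateDetections(z, det, visits = c(2, 2), missingRate = 0,
                           seed = 1)
  expect_true(all(detectionArray(dh) == 0L, na.rm = TRUE))

  z1 <- matrix(1L, 5, 2)
  dh1 <- simulateDetections(z1, spomParameters(pT = c(1, 1)),
                            visits = c(3, 3), missingRate = 0, seed = 2)
  expect_true(all(detectionArray(dh1) == 1L))

  # 10^4 occupied patch-visits at p = 0.6: frequency within 3 binomial SE
  zb <- matrix(1L, 2500, 2)
  dhb <- simulateDetections(zb, spomParameters(pT = c(0.6, 0.6)),
                            visits = c(2, 2), missingRate = 0, seed = 3)
  f <- mean(detectionArray(dhb), na.rm = TRUE)
  expect_lt(abs(f - 0.6), 3 * sqrt(0.6 * 0.4 / 1e4))

  # unsurveyed patch-years are fully missing at about the configured rate
  dhm <- simulateDetections(matrix(1L, 40, 25), spomParameters(
    pT = rep(0.7, 25)), visits = c(1, 4), missingRate = 0.3, seed = 4)
  expect_lt(abs(mean(numVisits(dhm) == 0L) - 0.3), 0.05)
  expect_true(all(is.na(detectionArray(dhm)[numVisits(dhm) == 0L])))
})

test_that("the Assynt preset fluctuates around ~55% occupancy", {
  occ <- vapply(1:4, function(s)
    mean(simulateScenario(assyntScenario(seed = s))$z), numeric(1))
  # wide stochastic band containing the 0.55 long-run average
  expect_gt(mean(occ), 0.40)
  expect_lt(mean(occ), 0.70)
})

test_that("scenario simulation is reproducible and writes its files", {
  cfg <- smallScenario(n = 12, T = 6, seed = 31)
  s1 <- simulateScenario(cfg)
  s2 <- simulateScenario(cfg)
  expect_identical(s1$z, s2$z)
  expect_identical(detectionArray(s1$history), detectionArray(s2$history))

  dir <- withr::local_tempdir()
  writeScenario(s1, dir)
  expect_true(all(file.exists(file.path(dir,
    c("patches.csv", "detections.csv", "truth.csv")))))
  net <- readPatchTable(file.path(dir, "patches.csv"))
  expect_equal(patchLengths(net), patchLengths(s1$network),
               tolerance = 1e-9)
  tr <- utils::read.csv(file.path(dir, "truth.csv"))
  expect_equal(tr$value[tr$parameter == "alpha"], 0.5)
  expect_equal(sum(tr$parameter == "z"), length(s1$z))
})
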