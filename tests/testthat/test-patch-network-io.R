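test_that("PatchNetwork computes Euclidean distances and validates input", {
  net <- PatchNetwork(c("a", "b"), x = c(0, 3), y = c(0, 4),
                      length = c(1, 2))
  expect_equal(patchDistances(net)["a", "b"], 5)
  expect_equal(diag(patchDistances(net)), c(a = 0, b = 0))

  single <- PatchNetwork("a", 0, 0, 1)
  expect_equal(nPatches(single), 1L)
  expect_equal(unname(patchDistances(single)), matrix(0, 1, 1))

  expect_error(PatchNetwork(c("a", "a"), c(0, 1), c(0, 0), c(1, 1)),
               "duplicate")
  expect_error(PatchNetwork(c("a", "b"), c(0, 1), c(0, 0), c(1, -1)),
               "positive")
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(PatchNetwork(c("a", "b"), c(0, 1), c(0, 0), c(1, 1),
                            dist = bad), "symmetric")
})

test_that("stored distances agree with a brute-force double loop", {
  for (n in c(7, 60, 200)) {
    net <- toyNetwork(n, seed = n, extent = c(12, 9))
    xy <- patchCoords(net)
    ref <- matrix(0, n, n)
    for (i in seq_len(n))
      for (j in seq_len(n))
        ref[i, j] <- sqrt(sum((xy[i, ] - xy[j, ])^2))
    expect_lt(max(abs(patchDistances(net) - ref)), 1e-9)
  }
})

test_that("patch tables round-trip, including an explicit distance matrix", {
  net <- toyNetwork(8, seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  fd <- withr::local_tempfile(fileext = ".csv")
  writePatchTable(net, f, distancePath = fd)
  back <- readPatchTable(f)
  expect_equal(patchIds(back), patchIds(net))
  expect_equal(patchLengths(back), patchLengths(net), tolerance = 1e-12)
  expect_equal(patchDistances(back), patchDistances(net), tolerance = 1e-9)

  withDist <- readPatchTable(f, distancePath = fd)
  expect_equal(patchDistances(withDist), patchDistances(net),
               tolerance = 1e-9)

  tab <- utils::read.csv(f)
  names(tab)[2] <- "xkm"
  utils::write.csv(tab, f, row.names = FALSE)
  expect_error(readPatchTable(f), "missing column")
})

test_that("detection histories build the dense array with visit counts", {
  net <- PatchNetwork(c("p1", "p2"), c(0, 1), c(0, 0), c(1, 1))
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patch_id,year,visit,detected",
               "p1,1999,1,1", "p1,1999,2,0",
               "p1,2000,1,0", "p2,1999,3,1"), f)
  dh <- readDetectionHistory(f, net)
  expect_equal(nYears(dh), 2L)
  expect_equal(detectionArray(dh)["p1", "1999", 1:2], c(1L, 0L))
  expect_equal(numVisits(dh)["p1", "1999"], 2L)
  # p2 in 2000 has no records: unsurveyed
  expect_equal(numVisits(dh)["p2", "2000"], 0L)
  expect_true(all(is.na(detectionArray(dh)["p2", "2000", ])))
  # max visit slot across the file sets the array depth
  expect_equal(dim(detectionArray(dh))[3], 3L)

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patch_id,year,visit,detected", "p9,1999,1,1"), f2)
  expect_error(readDetectionHistory(f2, net), "unknown patch")
  writeLines(c("patch_id,year,visit,detected",
               "p1,1999,1,1", "p1,1999,1,0"), f2)
  expect_error(readDetectionHistory(f2, net), "duplicate")
  writeLines(c("patch_id,year,visit,detected",
               "p1,1999,1,1", "p1,2002,1,0"), f2)
  expect_error(readDetectionHistory(f2, net), "gaps")
})

test_that("detection history writing round-trips", {
  sim <- simulateScenario(smallScenario(n = 10, T = 5, seed = 4))
  f <- withr::local_tempfile(fileext = ".csv")
  writeDetectionHistory(sim$history, f)
  back <- readDetectionHistory(f, sim$network)
  expect_equal(numVisits(back), numVisits(sim$history))
  a <- detectionArray(sim$history)
  b <- detectionArray(back)
  # identical realised visits (array depth may differ if a visit slot is
  # globally empty)
  v <- seq_len(min(dim(a)[3], dim(b)[3]))
  expect_identical(a[, , v], b[, , v])
})

test_that("ESRI ASCII rasters write the documented header and round-trip", {
  f <- withr::local_tempfile(fileext = ".asc")
  writeRasterAscii(matrix(0, 2, 2), origin = c(0, 0), cellsize = 1, f)
  lines <- readLines(f)
  expect_equal(lines[1], "ncols 2")
  expect_equal(lines[2], "nrows 2")
  expect_true(all(strsplit(lines[7], " ")[[1]] == "0"))

  g <- matrix(runif(12), 3, 4)
  g[2, 2] <- NA
  writeRasterAscii(g, origin = c(-1.5, 2), cellsize = 0.25, f)
  back <- readRasterAscii(f)
  expect_equal(back$grid, g, tolerance = 1e-12)
  expect_equal(back$origin, c(-1.5, 2))
  expect_equal(back$cellsize, 0.25)
  expect_error(writeRasterAscii(matrix(numeric(0), 0, 0), c(0, 0), 1, f),
               "empty")
})

test_that("surface extent arithmetic covers the buffered bounding box", {
  # two patches 5 km apart, 2 km buffer, 100 m cells: 9 x 4 km extent
  net <- PatchNetwork(c("a", "b"), x = c(0, 5), y = c(0, 0),
                      length = c(1, 1))
  sf <- colonizationSurface(net, c(1, 1), alpha = 1, beta = 0.1,
                            cellsize = 0.1, buffer = 2)
  expect_equal(ncol(sf$grid), 90L)
  expect_equal(nrow(sf$grid), 40L)
  expect_equal(sf$origin, c(-2, -2))
})

test_that("posterior draws round-trip through CSV", {
  d <- cbind(alpha = c(0.4, 0.5, 0.6, 0.7), beta = c(0.1, 0.2, 0.15, 0.12))
  ps <- drawsObject(d)
  f <- withr::local_tempfile(fileext = ".csv")
  writePosterior(ps, f)
  back <- readPosterior(f)
  expect_equal(unclass(back)[, c("alpha", "beta")], d, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(back, "chain"), rep(1L, 4))
})
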