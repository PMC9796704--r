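# Shared fixture builders: small random networks and detection histories
# generated in code (no stored data).

toyNetwork <- function(n = 5, seed = 1, extent = c(4, 4),
                       lengths = NULL) {
  set.seed(seed)
  PatchNetwork(sprintf("t%02d", seq_len(n)),
               x = runif(n, 0, extent[1]), y = runif(n, 0, extent[2]),
               length = lengths %||% runif(n, 0.1, 2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

emptyHistory <- function(network, T, vmax = 2) {
  DetectionHistory(array(NA_integer_, c(nPatches(network), T, vmax)),
                   seq_len(T), patchIds(network))
}

# a small simulated data set under a chosen formulation
smallScenario <- function(n = 25, T = 10, model = modelSpec("DI"),
                          seed = 1, sigma = 0, visits = c(2, 3),
                          missingRate = 0.05) {
  scenarioConfig(
    nPatches = n, extent = c(9, 7), T = T,
    params = spomParameters(psi1 = 0.6, delta0 = 1.2, delta1 = -2.2,
                            alpha = 0.5, beta = 0.15,
                            sigmaAlpha = sigma, sigmaBeta = sigma,
                            muP = 1.4, sigmaP = 0.4),
    model = model, visits = visits, missingRate = missingRate,
    seed = seed)
}

quickConfig <- function(nIter = 3000, nChains = 2, seed = 1,
                        saveZ = TRUE, ...) {
  mcmcConfig(nChains = nChains, nIter = nIter, nBurnin = nIter %/% 2,
             thin = 3, seed = seed, saveZ = saveZ, ...)
}

# a PosteriorSamples shell holding supplied draws (for derived-metric tests)
drawsObject <- function(draws, model = modelSpec("DI")) {
  new("PosteriorSamples", draws = draws,
      chain = rep(1L, nrow(draws)),
      zDraws = array(integer(0), c(0L, 0L, 0L)),
      accept = numeric(), model = model, config = list())
}
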