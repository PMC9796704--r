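#' @include AllClasses.R connectivity.R
NULL

#' Prior hyper-parameters for SPOM fitting
#'
#' Non-informative defaults: psi1 ~ Uniform(0,1) (handled conjugately);
#' delta0, delta1 ~ Normal(0, deltaSd); alpha ~ Uniform(0, alphaMax) km^-1;
#' beta ~ Uniform(0, betaMax); random-effect and detection SDs ~
#' Uniform(0, sigmaMax); mu_p ~ Normal(0, mupSd) on the logit scale.
#'
#' @param deltaSd SD of the Normal priors on the extinction coefficients.
#' @param alphaMax,betaMax upper bounds of the uniform dispersal priors.
#' @param sigmaMax upper bound of the uniform SD priors.
#' @param mupSd SD of the Normal prior on the detection hyper-mean.
#' @return named list of prior settings.
#' @export
spomPriors <- function(deltaSd = 10, alphaMax = 5, betaMax = 5,
                       sigmaMax = 5, mupSd = 1.65) {
  list(delta_sd = deltaSd, alpha_max = alphaMax, beta_max = betaMax,
       sigma_max = sigmaMax, mup_sd = mupSd)
}

#' MCMC configuration
#'
#' Defaults follow the reference analysis scale (three chains of 100,000
#' iterations, half discarded as burn-in); reduce for experimentation.
#'
#' @param nChains number of chains (>= 1).
#' @param nIter iterations per chain.
#' @param nBurnin burn-in iterations discarded (adaptation happens here).
#' @param thin keep every thin-th post-burn-in iteration.
#' @param seed integer seed; chain c uses seed + c - 1.
#' @param priors list from [spomPriors()].
#' @param saveZ save latent occupancy draws (needed for goodness-of-fit).
#' @param pilotIter iterations of the pilot run used to build GVS
#'   pseudo-priors (only used by [fitGVS()] when no pilot fit is supplied).
#' @param tune named list of initial random-walk proposal SDs.
#' @return named list of class \code{"MCMCConfig"}.
#' @export
mcmcConfig <- function(nChains = 3, nIter = 100000, nBurnin = nIter %/% 2,
                       thin = max(1L, (nIter - nBurnin) %/% 1000L),
                       seed = 1, priors = spomPriors(), saveZ = TRUE,
                       pilotIter = max(2000L, nIter %/% 10L),
                       tune = list(delta = 0.3, alpha = 0.3, beta = 0.4,
                                   sigma = 0.5, eps = 0.3, lp = 0.5)) {
  stopifnot(nChains >= 1, nIter > nBurnin, nBurnin >= 0, thin >= 1)
  structure(list(nChains = as.integer(nChains), nIter = as.integer(nIter),
                 nBurnin = as.integer(nBurnin), thin = as.integer(thin),
                 seed = as.integer(seed), priors = priors,
                 saveZ = isTRUE(saveZ), pilotIter = as.integer(pilotIter),
                 tune = tune),
            class = "MCMCConfig")
}

#' Detection log-likelihood for one patch-year
#'
#' Under the false-positive-free observation model
#' \eqn{y_{i,j,t} \mid z_{i,t} \sim \mathrm{Bern}(z_{i,t} p_t)}: if the
#' patch is unoccupied the likelihood is 1 when every realised visit is a
#' non-detection and 0 (log-likelihood \code{-Inf}) if any visit detected
#' the species; if occupied, visits are independent Bernoulli(p) trials.
#' Missing visits contribute nothing.
#'
#' @param y vector of visit outcomes (0/1/NA).
#' @param z occupancy state (0 or 1).
#' @param p detection probability for the year.
#' @return the log-likelihood.
#' @examples
#' detectionLoglik(c(1, 0, NA), z = 1, p = 0.7)  # log(0.7) + log(0.3)
#' detectionLoglik(c(0, 1), z = 0, p = 0.7)      # -Inf
#' @export
detectionLoglik <- function(y, z, p) {
  y <- y[!is.na(y)]
  if (!z %in% c(0, 1)) stop("z must be 0 or 1")
  if (length(y) == 0L) return(0)
  if (z == 0) return(if (any(y == 1)) -Inf else 0)
  if (p <= 0 || p >= 1) {
    if (p == 1 && all(y == 1)) return(0)
    if (p == 0 && all(y == 0)) return(0)
    if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  }
  sum(y * log(p) + (1 - y) * log(1 - p))
}

# year-specific dispersal values for transitions into years 2..T
.dispersalByYear <- function(params, model, T) {
  if (model@timeVarying) {
    if (length(params@alphaT) != T - 1L || length(params@betaT) != T - 1L)
      stop("time-varying models need alphaT and betaT of length T-1")
    list(a = params@alphaT, b = params@betaT)
  } else {
    list(a = rep(params@alpha, T - 1L), b = rep(params@beta, T - 1L))
  }
}

#' Full conditional of one latent occupancy state
#'
#' Computes \eqn{\Pr(z_{i,t} = 1 \mid \cdot)} given all other latent states,
#' the parameters and the data: the product of the detection likelihood,
#' the Markov prior from year t-1 (psi1 at t = 1), the patch's own
#' transition into t+1, and -- for demographically weighted models -- the
#' transition likelihoods of every other patch into t+1, whose colonization
#' pressure depends on \eqn{z_{i,t}}. Any detection at (i, t) forces the
#' probability to 1.
#'
#' This reference implementation mirrors the compiled sampler and is the
#' one used for desk-checking; the compiled sweep is validated against
#' exhaustive enumeration in the package tests.
#'
#' @param i patch index, \code{t} year index (1-based).
#' @param t year index.
#' @param z current occupancy matrix (patch x year).
#' @param network a [PatchNetwork-class].
#' @param params [SPOMParameters-class] with \code{pT} filled (and
#'   \code{alphaT}/\code{betaT} for time-varying models).
#' @param model a [ModelSpec-class].
#' @param data a [DetectionHistory-class].
#' @return \eqn{\Pr(z_{i,t} = 1 \mid \cdot)}.
#' @export
zFullConditional <- function(i, t, z, network, params, model, data) {
  n <- nPatches(network); T <- ncol(z)
  if (i < 1 || i > n || t < 1 || t > T) stop("indices out of range")
  y <- detectionArray(data)[i, t, ]
  if (any(!is.na(y) & y == 1)) return(1)
  disp <- .dispersalByYear(params, model, T)
  eps <- extinctionProb(network@length, params@delta0, params@delta1)
  occ <- function(zcol) if (model@weighted) zcol else NULL
  l1 <- detectionLoglik(y, 1L, params@pT[t])
  l0 <- detectionLoglik(y, 0L, params@pT[t])
  if (t == 1) {
    l1 <- l1 + log(params@psi1)
    l0 <- l0 + log(1 - params@psi1)
  } else if (z[i, t - 1] == 1) {
    l1 <- l1 + log(1 - eps[i])
    l0 <- l0 + log(eps[i])
  } else {
    S <- connectivityVector(network, occ(z[, t - 1]), disp$a[t - 1],
                            disp$b[t - 1])[i]
    g <- colonizationProb(S)
    l1 <- l1 + log(g)
    l0 <- l0 + log(1 - g)
  }
  if (t < T) {
    for (zi in c(1L, 0L)) {
      ztmp <- z
      ztmp[i, t] <- zi
      S <- connectivityVector(network, occ(ztmp[, t]), disp$a[t],
                              disp$b[t])
      gam <- colonizationProb(S)
      psi <- transitionProb(ztmp[, t], gam, eps)
      ks <- if (model@weighted) seq_len(n) else i
      ll <- sum(ifelse(ztmp[ks, t + 1] == 1, log(psi[ks]),
                       log(1 - psi[ks])))
      if (zi == 1L) l1 <- l1 + ll else l0 <- l0 + ll
    }
  }
  if (!is.finite(l1)) return(0)
  if (!is.finite(l0)) return(1)
  unname(1 / (1 + exp(l0 - l1)))
}

# package ysum / J matrices from a DetectionHistory
.detCounts <- function(data) {
  y <- detectionArray(data)
  ysum <- apply(y, c(1L, 2L), function(v) sum(v, na.rm = TRUE))
  storage.mode(ysum) <- "integer"
  list(ysum = ysum, J = numVisits(data))
}

.chainInit <- function(n, T, model, gvs) {
  list(
    psi1 = stats::runif(1, 0.2, 0.8),
    delta0 = stats::rnorm(1, 0, 1),
    delta1 = stats::rnorm(1, 0, 1),
    alpha = stats::runif(1, 0.2, 2),
    beta = stats::runif(1, 0.05, 0.5),
    eps_a = rep(0, T - 1L),
    eps_b = rep(0, T - 1L),
    sigma_a = stats::runif(1, 0.1, 1),
    sigma_b = stats::runif(1, 0.1, 1),
    mu_p = stats::rnorm(1, 1, 0.5),
    sigma_p = stats::runif(1, 0.2, 1),
    lp = stats::rnorm(T, 1, 0.3),
    Iz = if (gvs) stats::rbinom(1, 1, 0.5) else as.integer(model@weighted),
    ID = if (gvs) 1L else as.integer(model@timeVarying),
    z = matrix(1L, n, T)
  )
}

.drawColnames <- function(model, years, gvs) {
  T <- length(years)
  nm <- c("psi1", "delta0", "delta1", "alpha", "beta")
  if (model@timeVarying || gvs)
    nm <- c(nm, "sigma_alpha", "sigma_beta",
            paste0("alpha_t", years[-1L]), paste0("beta_t", years[-1L]))
  nm <- c(nm, "mu_p", "sigma_p", paste0("p_", years))
  if (gvs) nm <- c(nm, "I_z", "I_D")
  c(nm, "loglik")
}

.runChains <- function(data, network, model, config, gvs, pseudo) {
  cnt <- .detCounts(data)
  n <- nPatches(network); T <- nYears(data)
  years <- yearLabels(data)
  tv <- model@timeVarying || gvs
  drawsList <- vector("list", config$nChains)
  zList <- vector("list", config$nChains)
  accMat <- NULL
  for (ch in seq_len(config$nChains)) {
    set.seed(config$seed + ch - 1L)
    init <- .chainInit(n, T, model, gvs)
    res <- .spom_mcmc_cpp(cnt$ysum, cnt$J, network@dist, network@length,
                          model@weighted, tv, gvs, init, config$priors,
                          pseudo, config$tune, config$nIter, config$nBurnin,
                          config$thin, TRUE, config$saveZ)
    drawsList[[ch]] <- res$draws
    accMat <- rbind(accMat, res$accept)
    if (config$saveZ) {
      zc <- array(res$z, dim = c(n, T, res$n_keep))
      zList[[ch]] <- aperm(zc, c(3L, 1L, 2L))
    }
  }
  draws <- do.call(rbind, drawsList)
  colnames(draws) <- .drawColnames(model, years, gvs)
  chain <- rep(seq_len(config$nChains),
               vapply(drawsList, nrow, integer(1L)))
  zDraws <- if (config$saveZ) {
    za <- array(0L, dim = c(nrow(draws), n, T))
    off <- 0L
    for (ch in seq_len(config$nChains)) {
      nk <- dim(zList[[ch]])[1L]
      za[off + seq_len(nk), , ] <- zList[[ch]]
      off <- off + nk
    }
    za
  } else array(integer(0), dim = c(0L, 0L, 0L))
  acc <- colMeans(accMat)
  methods::new("PosteriorSamples", draws = draws, chain = as.integer(chain),
               zDraws = zDraws, accept = acc,
               model = if (gvs) modelSpec("DV") else model,
               config = unclass(config))
}

#' Fit a SPOM by Markov chain Monte Carlo
#'
#' Metropolis-within-Gibbs: latent occupancy states by full-conditional
#' Gibbs (entries with a detection are clamped to 1), continuous
#' parameters by adaptive random-walk Metropolis on transformed scales
#' (log for alpha, beta and the SDs; the initial occupancy probability is
#' conjugate Beta; the detection hyper-mean is conjugate Normal). For
#' time-varying models, year-specific kernel parameters are log-scale
#' random deviates around the static pair. Reproducible given the
#' configured seed.
#'
#' @param data a [DetectionHistory-class].
#' @param network a [PatchNetwork-class] (dimensions must agree).
#' @param model a [ModelSpec-class].
#' @param config an [mcmcConfig()] list.
#' @return a [PosteriorSamples-class].
#' @seealso [fitGVS()], [posteriorSummary()], [convergenceDiagnostics()]
#' @export
fitSPOM <- function(data, network, model = modelSpec("DI"),
                    config = mcmcConfig()) {
  stopifnot(is(data, "DetectionHistory"), is(network, "PatchNetwork"),
            is(model, "ModelSpec"), inherits(config, "MCMCConfig"))
  if (nPatches(data) != nPatches(network))
    stop("detection history and network disagree on the number of patches")
  .runChains(data, network, model, config, gvs = FALSE,
             pseudo = list(dummy = 0))
}

# Normal pseudo-prior moments for the GVS-deactivated random-effect block,
# taken from a pilot fit of the full DV model on the sampling scales
.pseudoFromPilot <- function(pilot, years) {
  d <- posteriorDraws(pilot)
  la <- log(d[, "alpha"]); lb <- log(d[, "beta"])
  aT <- log(d[, paste0("alpha_t", years[-1L]), drop = FALSE]) - la
  bT <- log(d[, paste0("beta_t", years[-1L]), drop = FALSE]) - lb
  lsa <- log(d[, "sigma_alpha"]); lsb <- log(d[, "sigma_beta"])
  sdFloor <- function(x) pmax(x, 0.05)
  list(ea_mean = colMeans(aT), ea_sd = sdFloor(apply(aT, 2L, stats::sd)),
       eb_mean = colMeans(bT), eb_sd = sdFloor(apply(bT, 2L, stats::sd)),
       lsa_mean = mean(lsa), lsa_sd = sdFloor(stats::sd(lsa)),
       lsb_mean = mean(lsb), lsb_sd = sdFloor(stats::sd(lsb)))
}

#' Gibbs variable selection over the four connectivity formulations
#'
#' Embeds two Bernoulli(0.5) indicators in the chain: \code{I_z} switches
#' demographic occupancy weighting on/off and \code{I_D} switches the
#' year-specific dispersal random effects on/off. When \code{I_D} is off,
#' the deactivated deviates and their SDs are drawn from Normal
#' pseudo-priors matched to a pilot run of the full (DV) model, the
#' standard device for keeping indicator mixing workable. Posterior
#' indicator mass is the model support: \code{Pr(I_z = 1)},
#' \code{Pr(I_D = 1)} and the joint 4-cell distribution over UI/UV/DI/DV.
#'
#' @param data a [DetectionHistory-class].
#' @param network a [PatchNetwork-class].
#' @param config an [mcmcConfig()] list.
#' @param pilot optional [PosteriorSamples-class] from a DV [fitSPOM()]
#'   run; when \code{NULL}, a pilot of \code{config$pilotIter} iterations
#'   is run internally.
#' @return a [PosteriorSamples-class] whose draws include \code{I_z} and
#'   \code{I_D}; summarise with [modelProbabilities()].
#' @export
fitGVS <- function(data, network, config = mcmcConfig(), pilot = NULL) {
  stopifnot(is(data, "DetectionHistory"), is(network, "PatchNetwork"))
  if (is.null(pilot)) {
    pcfg <- config
    pcfg$nChains <- 1L
    pcfg$nIter <- config$pilotIter
    pcfg$nBurnin <- config$pilotIter %/% 2L
    pcfg$thin <- max(1L, (pcfg$nIter - pcfg$nBurnin) %/% 500L)
    pcfg$seed <- config$seed + 1000L
    pcfg$saveZ <- FALSE
    pilot <- fitSPOM(data, network, modelSpec("DV"), pcfg)
  } else if (!modelLabel(pilot@model) %in% "DV") {
    stop("the pilot fit must use the full DV model")
  }
  pseudo <- .pseudoFromPilot(pilot, yearLabels(data))
  .runChains(data, network, modelSpec("DV"), config, gvs = TRUE,
             pseudo = pseudo)
}

#' Gibbs-sample latent occupancy states with parameters held fixed
#'
#' Runs the compiled latent-state sweep alone (no parameter updates),
#' which targets the exact conditional posterior of z given the supplied
#' parameters and data. Used for desk-scale validation against exhaustive
#' enumeration and for posterior-predictive work.
#'
#' @param network a [PatchNetwork-class].
#' @param params [SPOMParameters-class] with \code{pT} (and year dispersal
#'   for time-varying models) filled.
#' @param model a [ModelSpec-class].
#' @param data a [DetectionHistory-class].
#' @param nSweeps number of Gibbs sweeps.
#' @param nBurnin discarded initial sweeps.
#' @param thin keep every thin-th sweep.
#' @param seed integer seed.
#' @return integer array (draws x patches x years).
#' @export
sampleOccupancyGibbs <- function(network, params, model, data,
                                 nSweeps = 1000, nBurnin = 100, thin = 1,
                                 seed = 1) {
  cnt <- .detCounts(data)
  n <- nPatches(network); T <- nYears(data)
  disp <- .dispersalByYear(params, model, T)
  if (length(params@pT) != T)
    stop("params@pT must have one entry per year")
  set.seed(seed)
  init <- list(psi1 = params@psi1, delta0 = params@delta0,
               delta1 = params@delta1, alpha = params@alpha,
               beta = params@beta,
               eps_a = if (model@timeVarying)
                 log(disp$a) - log(params@alpha) else rep(0, T - 1L),
               eps_b = if (model@timeVarying)
                 log(disp$b) - log(max(params@beta, 1e-300))
               else rep(0, T - 1L),
               sigma_a = max(params@sigmaAlpha, 1e-6),
               sigma_b = max(params@sigmaBeta, 1e-6),
               mu_p = params@muP, sigma_p = max(params@sigmaP, 1e-6),
               lp = stats::qlogis(pmin(pmax(params@pT, 1e-12), 1 - 1e-12)),
               Iz = as.integer(model@weighted),
               ID = as.integer(model@timeVarying),
               z = matrix(1L, n, T))
  res <- .spom_mcmc_cpp(cnt$ysum, cnt$J, network@dist, network@length,
                        model@weighted, model@timeVarying, FALSE, init,
                        spomPriors(), list(dummy = 0),
                        mcmcConfig(nIter = 2)$tune,
                        as.integer(nSweeps), as.integer(nBurnin),
                        as.integer(thin), FALSE, TRUE)
  aperm(array(res$z, dim = c(n, T, res$n_keep)), c(3L, 1L, 2L))
}

#' Split-chain potential scale reduction factor (r-hat)
#'
#' Gelman-Rubin convergence diagnostic with chain splitting: each chain is
#' halved, the between- and within-half variances are combined, and values
#' near 1 indicate the chains sample the same distribution.
#'
#' @param x numeric matrix of draws, iterations x chains (>= 2 chains
#'   after splitting, i.e. at least one chain of >= 4 draws).
#' @return the split-chain r-hat (>= 1 up to floating point).
#' @export
rhat <- function(x) {
  x <- as.matrix(x)
  n2 <- nrow(x) %/% 2L
  if (n2 < 2L) stop("need at least 4 draws per chain")
  halves <- do.call(cbind, lapply(seq_len(ncol(x)), function(ch)
    cbind(x[seq_len(n2), ch], x[n2 + seq_len(n2), ch])))
  m <- ncol(halves); nn <- nrow(halves)
  mu <- colMeans(halves)
  W <- mean(apply(halves, 2L, stats::var))
  B <- nn * stats::var(mu)
  if (W < .Machine$double.eps) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' @rdname PosteriorSamples-class
#' @param x a \code{PosteriorSamples}.
#' @param pars optional parameter subset.
#' @export
setMethod("convergenceDiagnostics", "PosteriorSamples",
  function(x, pars = NULL) {
    d <- posteriorDraws(x, pars)
    chains <- sort(unique(x@chain))
    if (length(chains) < 2L)
      stop("convergence diagnostics need at least 2 chains")
    n <- min(table(x@chain))
    rh <- vapply(colnames(d), function(p) {
      m <- vapply(chains, function(ch) d[x@chain == ch, p][seq_len(n)],
                  numeric(n))
      rhat(m)
    }, numeric(1L))
    data.frame(parameter = colnames(d), rhat = rh, row.names = NULL)
  })

#' @rdname PosteriorSamples-class
#' @param probs quantiles reported (default central 95% and median).
#' @export
setMethod("posteriorSummary", "PosteriorSamples",
  function(x, pars = NULL, probs = c(0.025, 0.5, 0.975)) {
    d <- posteriorDraws(x, pars)
    qs <- t(apply(d, 2L, stats::quantile, probs = probs))
    out <- data.frame(parameter = colnames(d), mean = colMeans(d),
                      sd = apply(d, 2L, stats::sd), qs, row.names = NULL,
                      check.names = FALSE)
    names(out)[3L + seq_along(probs)] <-
      paste0("q", sub("^0\\.", "", format(probs)))
    if (length(unique(x@chain)) >= 2L)
      out$rhat <- convergenceDiagnostics(x, pars = colnames(d))$rhat
    out
  })

#' @rdname PosteriorSamples-class
#' @export
setMethod("modelProbabilities", "PosteriorSamples", function(x) {
  d <- posteriorDraws(x)
  if (!all(c("I_z", "I_D") %in% colnames(d)))
    stop("model probabilities require a GVS fit (see fitGVS)")
  iz <- d[, "I_z"]; id <- d[, "I_D"]
  joint <- c(
    UI = mean(iz == 0 & id == 0), UV = mean(iz == 0 & id == 1),
    DI = mean(iz == 1 & id == 0), DV = mean(iz == 1 & id == 1))
  list(pIz = mean(iz), pID = mean(id), joint = joint)
})
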