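#' @include AllGenerics.R
NULL

#' PatchNetwork: geometry of a habitat patch network
#'
#' An S4 container for the spatial skeleton of a metapopulation: patch
#' identifiers, planar coordinates (km), riparian patch lengths \eqn{A_i}
#' (km), and the symmetric inter-patch distance matrix \eqn{d_{ij}} (km).
#' Distances are Euclidean between patch reference points unless an explicit
#' distance matrix is supplied (e.g. along-waterway distances measured
#' externally).
#'
#' @slot patchId character vector of unique patch identifiers (length n).
#' @slot coords n x 2 numeric matrix of planar coordinates in km
#'   (columns \code{x}, \code{y}).
#' @slot length numeric vector of patch lengths \eqn{A_i} in km; strictly
#'   positive.
#' @slot dist n x n symmetric numeric matrix of inter-patch distances in km;
#'   zero diagonal, positive off-diagonal.
#'
#' @seealso [PatchNetwork()], [readPatchTable()]
#' @name PatchNetwork-class
#' @aliases PatchNetwork-class nPatches patchIds patchLengths patchCoords
#'   patchDistances
#' @exportClass PatchNetwork
setClass("PatchNetwork",
  representation(
    patchId = "character",
    coords = "matrix",
    length = "numeric",
    dist = "matrix"
  )
)

setValidity("PatchNetwork", function(object) {
  n <- length(object@patchId)
  msg <- character()
  if (n < 1L) msg <- c(msg, "network must contain at least one patch")
  if (anyDuplicated(object@patchId))
    msg <- c(msg, "duplicate patch ids")
  if (!is.numeric(object@coords) || nrow(object@coords) != n ||
      ncol(object@coords) != 2L)
    msg <- c(msg, "coords must be an n x 2 numeric matrix")
  if (length(object@length) != n)
    msg <- c(msg, "length must have one entry per patch")
  else if (any(!is.finite(object@length)) || any(object@length <= 0))
    msg <- c(msg, "patch lengths must be finite and strictly positive")
  d <- object@dist
  if (!is.numeric(d) || nrow(d) != n || ncol(d) != n) {
    msg <- c(msg, "dist must be an n x n numeric matrix")
  } else {
    if (any(abs(diag(d)) > 1e-12))
      msg <- c(msg, "dist must have a zero diagonal")
    if (max(abs(d - t(d))) > 1e-9)
      msg <- c(msg, "dist must be symmetric")
    if (n > 1L && any(d[upper.tri(d)] <= 0))
      msg <- c(msg, "off-diagonal distances must be > 0 (identical locations need an explicit distance matrix with positive entries)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PatchNetwork
#'
#' @param patchId character (or coercible) vector of unique patch ids.
#' @param x,y planar coordinates in km.
#' @param length patch lengths \eqn{A_i} in km (> 0).
#' @param dist optional explicit n x n distance matrix (km). When omitted,
#'   pairwise Euclidean distances are computed from the coordinates.
#' @return a validated [PatchNetwork-class] object.
#' @examples
#' net <- PatchNetwork(c("a", "b"), x = c(0, 3), y = c(0, 4), length = c(1, 2))
#' patchDistances(net)["a", "b"]  # 5
#' @export
PatchNetwork <- function(patchId, x, y, length, dist = NULL) {
  patchId <- as.character(patchId)
  n <- base::length(patchId)
  coords <- cbind(x = as.numeric(x), y = as.numeric(y))
  if (is.null(dist)) {
    dist <- as.matrix(stats::dist(coords))
    dimnames(dist) <- list(patchId, patchId)
  } else {
    dist <- as.matrix(dist)
    if (nrow(dist) != n || ncol(dist) != n)
      stop("explicit distance matrix must be ", n, " x ", n)
    dimnames(dist) <- list(patchId, patchId)
  }
  rownames(coords) <- patchId
  methods::new("PatchNetwork", patchId = patchId, coords = coords,
               length = as.numeric(length), dist = dist)
}

#' @rdname PatchNetwork-class
#' @export
setMethod("nPatches", "PatchNetwork", function(x) length(x@patchId))

#' @rdname PatchNetwork-class
#' @export
setMethod("patchIds", "PatchNetwork", function(x) x@patchId)

#' @rdname PatchNetwork-class
#' @export
setMethod("patchLengths", "PatchNetwork", function(x) {
  stats::setNames(x@length, x@patchId)
})

#' @rdname PatchNetwork-class
#' @export
setMethod("patchCoords", "PatchNetwork", function(x) x@coords)

#' @rdname PatchNetwork-class
#' @export
setMethod("patchDistances", "PatchNetwork", function(x) x@dist)

setMethod("show", "PatchNetwork", function(object) {
  n <- nPatches(object)
  cat("PatchNetwork with", n, "patches\n")
  cat("  mean patch length:", signif(mean(object@length), 4), "km\n")
  if (n > 1L) {
    d <- object@dist
    diag(d) <- Inf
    cat("  mean nearest-neighbour distance:",
        signif(mean(apply(d, 1L, min)), 4), "km\n")
  }
  invisible(object)
})

#' DetectionHistory: patch x year x visit detection records
#'
#' An S4 container for repeated binary detection surveys: the
#' patch-by-year-by-visit array \eqn{y_{i,j,t}} with values 0 (not
#' detected), 1 (detected) or \code{NA} (visit did not take place), the
#' ordered year labels, and the per-patch-year visit counts
#' \eqn{J_{i,t}}. A patch-year with \eqn{J_{i,t} = 0} is unsurveyed.
#'
#' @slot y integer array, dim n x T x Vmax, values in {0, 1, NA}.
#' @slot years integer vector of ordered year labels (length T).
#' @slot patchId character vector aligned with the first dimension of y.
#' @slot visits n x T integer matrix of non-missing visit counts J.
#'
#' @seealso [DetectionHistory()], [readDetectionHistory()]
#' @name DetectionHistory-class
#' @aliases DetectionHistory-class nYears yearLabels numVisits detectionArray
#' @exportClass DetectionHistory
setClass("DetectionHistory",
  representation(
    y = "array",
    years = "integer",
    patchId = "character",
    visits = "matrix"
  )
)

setValidity("DetectionHistory", function(object) {
  msg <- character()
  dm <- dim(object@y)
  if (length(dm) != 3L)
    return("y must be a 3-d array (patch x year x visit)")
  if (dm[1L] != length(object@patchId))
    msg <- c(msg, "first dimension of y must match patchId")
  if (dm[2L] != length(object@years))
    msg <- c(msg, "second dimension of y must match years")
  vals <- object@y[!is.na(object@y)]
  if (length(vals) && !all(vals %in% c(0L, 1L)))
    msg <- c(msg, "non-missing detections must be 0 or 1")
  if (is.unsorted(object@years, strictly = TRUE))
    msg <- c(msg, "years must be strictly increasing")
  J <- apply(!is.na(object@y), c(1L, 2L), sum)
  if (!identical(dim(object@visits), dm[1:2]) ||
      any(object@visits != J))
    msg <- c(msg, "visits must equal the count of non-missing visits")
  if (length(msg)) msg else TRUE
})

#' Construct a DetectionHistory
#'
#' @param y 3-d array (patch x year x visit) with entries 0/1/NA.
#' @param years ordered integer year labels.
#' @param patchId character patch ids aligned with rows of \code{y}.
#' @return a validated [DetectionHistory-class] object.
#' @export
DetectionHistory <- function(y, years, patchId) {
  storage.mode(y) <- "integer"
  years <- as.integer(years)
  patchId <- as.character(patchId)
  visits <- apply(!is.na(y), c(1L, 2L), sum)
  storage.mode(visits) <- "integer"
  dimnames(y) <- list(patchId, years, NULL)
  dimnames(visits) <- list(patchId, years)
  methods::new("DetectionHistory", y = y, years = years,
               patchId = patchId, visits = visits)
}

#' @rdname DetectionHistory-class
#' @export
setMethod("nYears", "DetectionHistory", function(x) length(x@years))

#' @rdname DetectionHistory-class
#' @export
setMethod("yearLabels", "DetectionHistory", function(x) x@years)

#' @rdname DetectionHistory-class
#' @export
setMethod("numVisits", "DetectionHistory", function(x) x@visits)

#' @rdname DetectionHistory-class
#' @export
setMethod("detectionArray", "DetectionHistory", function(x) x@y)

#' @rdname DetectionHistory-class
#' @export
setMethod("nPatches", "DetectionHistory", function(x) length(x@patchId))

#' @rdname DetectionHistory-class
#' @export
setMethod("patchIds", "DetectionHistory", function(x) x@patchId)

setMethod("show", "DetectionHistory", function(object) {
  dm <- dim(object@y)
  cat("DetectionHistory:", dm[1L], "patches x", dm[2L], "years, up to",
      dm[3L], "visits\n")
  surveyed <- mean(object@visits > 0L)
  cat("  surveyed patch-years:", sprintf("%.1f%%", 100 * surveyed), "\n")
  cat("  naive occupancy (any detection):",
      sprintf("%.3f", mean(naiveOccupancy(object)[object@visits > 0L])), "\n")
  invisible(object)
})

#' ModelSpec: which connectivity assumptions a SPOM makes
#'
#' The four model formulations arise from crossing two binary assumptions:
#' \emph{demographic weighting} (connectivity sums over occupied source
#' patches only, versus treating every patch as an occupied source) and
#' \emph{time-varying dispersal} (year-specific kernel parameters
#' \eqn{\alpha_t, \beta_t} as random effects, versus a single static pair).
#' The standard labels are UI (unweighted, invariant), UV (unweighted,
#' varying), DI (weighted, invariant) and DV (weighted, varying).
#'
#' @slot weighted logical; demographic occupancy weighting on/off.
#' @slot timeVarying logical; year-specific dispersal parameters on/off.
#'
#' @seealso [modelSpec()]
#' @name ModelSpec-class
#' @aliases ModelSpec-class modelLabel
#' @exportClass ModelSpec
setClass("ModelSpec",
  representation(weighted = "logical", timeVarying = "logical")
)

setValidity("ModelSpec", function(object) {
  if (length(object@weighted) != 1L || is.na(object@weighted) ||
      length(object@timeVarying) != 1L || is.na(object@timeVarying))
    "weighted and timeVarying must be single non-missing logicals"
  else TRUE
})

#' Specify a SPOM connectivity formulation
#'
#' @param label one of "UI", "UV", "DI", "DV"; alternatively supply the two
#'   flags directly.
#' @param weighted,timeVarying logical flags (used when \code{label} is
#'   missing).
#' @return a [ModelSpec-class] object.
#' @examples
#' modelLabel(modelSpec("DV"))
#' modelSpec(weighted = TRUE, timeVarying = FALSE)  # DI
#' @export
modelSpec <- function(label, weighted = FALSE, timeVarying = FALSE) {
  if (!missing(label)) {
    label <- match.arg(toupper(label), c("UI", "UV", "DI", "DV"))
    weighted <- substr(label, 1L, 1L) == "D"
    timeVarying <- substr(label, 2L, 2L) == "V"
  }
  methods::new("ModelSpec", weighted = isTRUE(weighted),
               timeVarying = isTRUE(timeVarying))
}

#' @rdname ModelSpec-class
#' @export
setMethod("modelLabel", "ModelSpec", function(x) {
  paste0(if (x@weighted) "D" else "U", if (x@timeVarying) "V" else "I")
})

setMethod("show", "ModelSpec", function(object) {
  cat("ModelSpec", modelLabel(object), "-",
      if (object@weighted) "demographically weighted" else "unweighted",
      "connectivity,",
      if (object@timeVarying) "time-varying" else "time-invariant",
      "dispersal\n")
  invisible(object)
})

#' SPOMParameters: the full parameter set of the occupancy model
#'
#' Collects every unknown of the dynamic SPOM: initial occupancy
#' \eqn{\psi_1}; extinction regression \eqn{\delta_0, \delta_1}
#' (logit \eqn{\varepsilon_i = \delta_0 + \delta_1 A_i}); dispersal kernel
#' scale \eqn{\alpha} (km\eqn{^{-1}}) and per-capita effective dispersal
#' rate \eqn{\beta}, optionally year-specific (\code{alphaT}, \code{betaT},
#' one entry per transition year 2..T) with log-scale random-effect SDs
#' \code{sigmaAlpha}, \code{sigmaBeta}; and the detection model
#' (\code{muP}, \code{sigmaP} on the logit scale, year-specific
#' probabilities \code{pT}).
#'
#' @slot psi1 initial-year occupancy probability.
#' @slot delta0,delta1 logit-scale extinction intercept and patch-length slope.
#' @slot alpha,beta static dispersal parameters (alpha > 0, beta >= 0).
#' @slot alphaT,betaT year-specific dispersal parameters (length T-1; may be
#'   empty for time-invariant models).
#' @slot sigmaAlpha,sigmaBeta log-scale random-effect SDs (>= 0).
#' @slot muP,sigmaP logit-scale mean and SD of year detection probabilities.
#' @slot pT year-specific detection probabilities (length T; may be empty
#'   when detection is to be drawn from its hyper-distribution).
#'
#' @seealso [spomParameters()]
#' @name SPOMParameters-class
#' @exportClass SPOMParameters
setClass("SPOMParameters",
  representation(
    psi1 = "numeric", delta0 = "numeric", delta1 = "numeric",
    alpha = "numeric", beta = "numeric",
    alphaT = "numeric", betaT = "numeric",
    sigmaAlpha = "numeric", sigmaBeta = "numeric",
    muP = "numeric", sigmaP = "numeric", pT = "numeric"
  )
)

setValidity("SPOMParameters", function(object) {
  msg <- character()
  chkp <- function(p, nm) {
    if (length(p) && (any(p < 0) || any(p > 1)))
      paste(nm, "must lie in [0, 1]") else NULL
  }
  msg <- c(msg, chkp(object@psi1, "psi1"), chkp(object@pT, "pT"))
  if (length(object@alpha) && object@alpha <= 0)
    msg <- c(msg, "alpha must be > 0")
  if (length(object@beta) && object@beta < 0)
    msg <- c(msg, "beta must be >= 0")
  if (length(object@alphaT) && any(object@alphaT <= 0))
    msg <- c(msg, "alphaT must be > 0")
  if (length(object@betaT) && any(object@betaT < 0))
    msg <- c(msg, "betaT must be >= 0")
  if (length(object@sigmaAlpha) && object@sigmaAlpha < 0)
    msg <- c(msg, "sigmaAlpha must be >= 0")
  if (length(object@sigmaBeta) && object@sigmaBeta < 0)
    msg <- c(msg, "sigmaBeta must be >= 0")
  if (length(object@sigmaP) && object@sigmaP < 0)
    msg <- c(msg, "sigmaP must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct SPOMParameters
#'
#' @param psi1 initial occupancy probability.
#' @param delta0,delta1 extinction logit intercept and slope.
#' @param alpha,beta static dispersal kernel scale (km^-1) and effective
#'   dispersal rate.
#' @param alphaT,betaT optional year-specific dispersal parameters
#'   (one per transition year 2..T).
#' @param sigmaAlpha,sigmaBeta log-scale random-effect SDs.
#' @param muP,sigmaP logit-scale detection hyper-parameters.
#' @param pT optional year-specific detection probabilities.
#' @return a validated [SPOMParameters-class] object.
#' @export
spomParameters <- function(psi1 = 0.5, delta0 = 0, delta1 = 0,
                           alpha = 1, beta = 0.1,
                           alphaT = numeric(), betaT = numeric(),
                           sigmaAlpha = 0, sigmaBeta = 0,
                           muP = 1.5, sigmaP = 0.5, pT = numeric()) {
  methods::new("SPOMParameters",
    psi1 = as.numeric(psi1), delta0 = as.numeric(delta0),
    delta1 = as.numeric(delta1), alpha = as.numeric(alpha),
    beta = as.numeric(beta), alphaT = as.numeric(alphaT),
    betaT = as.numeric(betaT), sigmaAlpha = as.numeric(sigmaAlpha),
    sigmaBeta = as.numeric(sigmaBeta), muP = as.numeric(muP),
    sigmaP = as.numeric(sigmaP), pT = as.numeric(pT))
}

setMethod("show", "SPOMParameters", function(object) {
  cat("SPOMParameters: psi1 =", object@psi1,
      "| delta = (", object@delta0, ",", object@delta1, ")",
      "| alpha =", object@alpha, "| beta =", object@beta, "\n")
  if (length(object@alphaT))
    cat("  year-specific alpha_t in [", signif(min(object@alphaT), 3), ",",
        signif(max(object@alphaT), 3), "]\n")
  cat("  detection: muP =", object@muP, ", sigmaP =", object@sigmaP,
      if (length(object@pT)) paste0(", ", length(object@pT), " year p_t") else "",
      "\n")
  invisible(object)
})

#' PosteriorSamples: MCMC output for a fitted SPOM
#'
#' Saved posterior draws of all scalar parameters (one row per saved
#' iteration, one column per parameter), the chain index of each row,
#' optional latent occupancy-state draws, Metropolis acceptance rates and
#' the fitting configuration.
#'
#' @slot draws numeric matrix (saved iterations x parameters) with column
#'   names.
#' @slot chain integer chain index per row of \code{draws}.
#' @slot zDraws integer array (saved iterations x patches x years) of latent
#'   occupancy states, or a zero-length array when not saved.
#' @slot accept named numeric vector of Metropolis acceptance rates.
#' @slot model the [ModelSpec-class] fitted (for GVS fits, the full DV
#'   structure with indicator columns \code{I_z}, \code{I_D} in
#'   \code{draws}).
#' @slot config list; the MCMC configuration used.
#'
#' @seealso [fitSPOM()], [fitGVS()], [posteriorSummary()]
#' @name PosteriorSamples-class
#' @aliases PosteriorSamples-class posteriorDraws posteriorSummary
#'   latentStateDraws modelProbabilities convergenceDiagnostics
#' @exportClass PosteriorSamples
setClass("PosteriorSamples",
  representation(
    draws = "matrix",
    chain = "integer",
    zDraws = "array",
    accept = "numeric",
    model = "ModelSpec",
    config = "list"
  )
)

setValidity("PosteriorSamples", function(object) {
  msg <- character()
  if (nrow(object@draws) != length(object@chain))
    msg <- c(msg, "chain index must have one entry per saved draw")
  if (is.null(colnames(object@draws)))
    msg <- c(msg, "draws must have column names")
  if (any(!is.finite(object@draws)))
    msg <- c(msg, "draws must be finite")
  if (length(msg)) msg else TRUE
})

#' @rdname PosteriorSamples-class
#' @param pars optional character vector of parameter names to extract.
#' @export
setMethod("posteriorDraws", "PosteriorSamples", function(x, pars = NULL) {
  if (is.null(pars)) x@draws else x@draws[, pars, drop = FALSE]
})

#' @rdname PosteriorSamples-class
#' @export
setMethod("latentStateDraws", "PosteriorSamples", function(x) {
  if (length(x@zDraws) == 0L)
    stop("latent states were not saved for this fit (set saveZ = TRUE)")
  x@zDraws
})

setMethod("show", "PosteriorSamples", function(object) {
  cat("PosteriorSamples:", nrow(object@draws), "draws x",
      ncol(object@draws), "parameters (", modelLabel(object@model),
      "model,", length(unique(object@chain)), "chains )\n")
  invisible(object)
})
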