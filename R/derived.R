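#' @include AllClasses.R connectivity.R mcmc.R
NULL

#' Naive occupancy from a detection history
#'
#' A patch-year is labelled occupied (1) iff at least one visit detected
#' the species, ignoring imperfect detection; unsurveyed patch-years are
#' counted as 0. This is the conventional input for descriptive
#' connectivity summaries.
#'
#' @param data a [DetectionHistory-class].
#' @return integer patch x year matrix.
#' @export
naiveOccupancy <- function(data) {
  y <- detectionArray(data)
  out <- apply(y, c(1L, 2L), function(v) as.integer(any(v == 1L, na.rm = TRUE)))
  dimnames(out) <- list(patchIds(data), yearLabels(data))
  out
}

#' Metapopulation capacity of a patch network
#'
#' The dominant eigenvalue \eqn{\lambda_M} of the landscape matrix
#' \eqn{m_{ij} = A_i A_j e^{-\alpha d_{ij}}} (zero diagonal): a relative,
#' spatially explicit measure of a network's capacity to sustain a
#' metapopulation, integrating patch sizes, configuration and dispersal
#' scale. The matrix is symmetric and non-negative, so the Perron root is
#' real and non-negative. The dispersal rate \eqn{\beta} does not enter
#' the classic capacity definition used here; \code{scaleBeta} multiplies
#' the matrix by a supplied \eqn{\beta} for sensitivity checks.
#'
#' @param network a [PatchNetwork-class] with >= 2 patches (a single patch
#'   has no between-patch process; returns 0 with a warning).
#' @param alpha dispersal kernel scale, km^-1 (> 0).
#' @param scaleBeta optional multiplier applied to the landscape matrix.
#' @return the dominant eigenvalue \eqn{\lambda_M}.
#' @examples
#' net <- PatchNetwork(c("a", "b"), x = c(0, 1), y = c(0, 0), length = c(1, 1))
#' metapopCapacity(net, alpha = 1)  # exp(-1)
#' @export
metapopCapacity <- function(network, alpha, scaleBeta = 1) {
  stopifnot(is(network, "PatchNetwork"), alpha > 0)
  n <- nPatches(network)
  if (n < 2L) {
    warning("metapopulation capacity is undefined for a single patch")
    return(0)
  }
  A <- network@length
  M <- scaleBeta * outer(A, A) * exp(-alpha * network@dist)
  diag(M) <- 0
  max(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
}

#' Posterior distribution of metapopulation capacity
#'
#' Propagates posterior uncertainty in the dispersal scale into the
#' capacity: \eqn{\lambda_M} is computed for every saved draw's
#' \eqn{\alpha} (for time-varying models, for every year's
#' \eqn{\alpha_t} draw, yielding an annual capacity series; the
#' hyper-mean \eqn{\alpha} column is reported as year "overall").
#'
#' @param samples a [PosteriorSamples-class].
#' @param network the [PatchNetwork-class] the fit used.
#' @param annual for time-varying fits, also compute per-year capacities
#'   (default TRUE when year-specific columns are present).
#' @return list with \code{lambdaDraws} (draws x series matrix),
#'   \code{summary} (data.frame: series, mean, q025, q975).
#' @export
capacityPosterior <- function(samples, network, annual = TRUE) {
  d <- posteriorDraws(samples)
  if (!"alpha" %in% colnames(d)) stop("posterior lacks alpha draws")
  cols <- c(overall = "alpha")
  if (annual) {
    at <- grep("^alpha_t", colnames(d), value = TRUE)
    if (length(at)) cols <- c(cols, stats::setNames(at, sub("alpha_t", "", at)))
  }
  alphas <- sort(unique(as.vector(d[, cols])))
  lut <- vapply(alphas, function(a) metapopCapacity(network, a), numeric(1L))
  lam <- vapply(seq_along(cols), function(j)
    lut[match(d[, cols[j]], alphas)], numeric(nrow(d)))
  lam <- matrix(lam, nrow = nrow(d))
  colnames(lam) <- names(cols)
  summary <- data.frame(
    series = names(cols),
    mean = colMeans(lam),
    q025 = apply(lam, 2L, stats::quantile, 0.025),
    q975 = apply(lam, 2L, stats::quantile, 0.975),
    row.names = NULL)
  list(lambdaDraws = lam, summary = summary)
}

#' Landscape colonization-probability surface
#'
#' Evaluates, at each pixel centre x of a raster covering the patch
#' bounding box plus a buffer, the colonization probability
#' \eqn{\gamma(x) = 1 - \exp\{-\beta \sum_j A_j z_j e^{-\alpha d(x, j)}\}}
#' sourced from the currently occupied patches (conventionally the naive
#' occupancy of a focal year). The landscape-level summary is the mean
#' over pixels with the 0.025/0.975 quantiles of the pixel distribution.
#'
#' @param network a [PatchNetwork-class].
#' @param naiveOcc binary source-occupancy vector (length n).
#' @param alpha,beta dispersal parameters.
#' @param cellsize pixel edge, km (default 0.1).
#' @param buffer buffer around the patch bounding box, km (default 2).
#' @return list with \code{grid} (matrix, top row = max y), \code{origin}
#'   (xll, yll), \code{cellsize}, and \code{summary} (mean, q025, q975
#'   over pixels).
#' @export
colonizationSurface <- function(network, naiveOcc, alpha, beta,
                                cellsize = 0.1, buffer = 2) {
  stopifnot(is(network, "PatchNetwork"), cellsize > 0, buffer >= 0)
  n <- nPatches(network)
  if (length(naiveOcc) != n) stop("naiveOcc must have one entry per patch")
  xy <- network@coords
  xr <- range(xy[, "x"]) + c(-buffer, buffer)
  yr <- range(xy[, "y"]) + c(-buffer, buffer)
  nx <- max(1L, ceiling(diff(xr) / cellsize))
  ny <- max(1L, ceiling(diff(yr) / cellsize))
  xc <- xr[1L] + (seq_len(nx) - 0.5) * cellsize
  yc <- yr[1L] + (seq_len(ny) - 0.5) * cellsize
  w <- network@length * as.numeric(naiveOcc)
  src <- which(w > 0)
  grid <- matrix(0, nrow = ny, ncol = nx)
  if (length(src) && beta > 0) {
    for (j in src) {
      dx2 <- (xc - xy[j, "x"])^2
      dy2 <- (yc - xy[j, "y"])^2
      dmat <- sqrt(outer(rev(dy2), dx2, "+")) # row 1 = top (max y)
      grid <- grid + w[j] * exp(-alpha * dmat)
    }
    grid <- -expm1(-beta * grid)
  }
  list(grid = grid, origin = c(xr[1L], yr[1L]), cellsize = cellsize,
       summary = c(mean = mean(grid),
                   q025 = unname(stats::quantile(grid, 0.025)),
                   q975 = unname(stats::quantile(grid, 0.975))))
}

#' Network-level average colonization probability
#'
#' The mean over patches of \eqn{\gamma_i = 1 - e^{-S_i}} with
#' connectivity sourced from the supplied occupancy vector
#' (self-contribution excluded, as in the model).
#'
#' @inheritParams colonizationSurface
#' @return the mean colonization probability across patches.
#' @export
networkColonization <- function(network, naiveOcc, alpha, beta) {
  S <- connectivityVector(network, naiveOcc, alpha, beta)
  mean(colonizationProb(S))
}

#' Freeman-Tukey discrepancy
#'
#' \eqn{T = \sum (\sqrt{y} - \sqrt{e})^2} between observed and expected
#' counts; variance-stabilised, so small expected counts do not dominate.
#'
#' @param observed,expected non-negative count vectors of equal length.
#' @return the discrepancy.
#' @examples
#' freemanTukeyStatistic(c(0, 1), c(0.25, 0.25))  # 0.5
#' @export
freemanTukeyStatistic <- function(observed, expected) {
  stopifnot(length(observed) == length(expected))
  sum((sqrt(observed) - sqrt(expected))^2)
}

#' Posterior-predictive goodness-of-fit (Freeman-Tukey)
#'
#' For every saved posterior draw, patch-year detection counts
#' \eqn{y_{i,t} = \sum_j y_{i,j,t}} are compared with their expectation
#' \eqn{e_{i,t} = J_{i,t} z_{i,t} p_t} under that draw via the
#' Freeman-Tukey discrepancy; a replicate data set is simulated from the
#' fitted model at the same draw and scored identically. The Bayesian
#' p-value is the fraction of draws whose replicate discrepancy is at
#' least the observed one; values near 0 or 1 flag lack of fit.
#'
#' @param data the [DetectionHistory-class] the model was fitted to.
#' @param samples a [PosteriorSamples-class] with saved latent states.
#' @param seed integer seed for the replicate simulations.
#' @param maxDraws cap on the number of draws scored (uniformly thinned;
#'   default 1000).
#' @return list with \code{pValue}, \code{Tobs}, \code{Trep} (per-draw
#'   discrepancies).
#' @export
freemanTukeyGOF <- function(data, samples, seed = 1, maxDraws = 1000) {
  z <- latentStateDraws(samples)
  d <- posteriorDraws(samples)
  if (nrow(d) == 0L) stop("empty posterior")
  J <- numVisits(data)
  ysum <- apply(detectionArray(data), c(1L, 2L),
                function(v) sum(v, na.rm = TRUE))
  years <- yearLabels(data)
  pcols <- paste0("p_", years)
  idx <- unique(round(seq(1L, nrow(d), length.out = min(maxDraws, nrow(d)))))
  set.seed(seed)
  Tobs <- Trep <- numeric(length(idx))
  for (k in seq_along(idx)) {
    dr <- idx[k]
    p <- matrix(d[dr, pcols], nrow(J), ncol(J), byrow = TRUE)
    e <- J * z[dr, , ] * p
    Tobs[k] <- freemanTukeyStatistic(ysum, e)
    yrep <- matrix(stats::rbinom(length(J), as.vector(J),
                                 as.vector(z[dr, , ] * p)),
                   nrow(J), ncol(J))
    Trep[k] <- freemanTukeyStatistic(yrep, e)
  }
  list(pValue = mean(Trep >= Tobs), Tobs = Tobs, Trep = Trep)
}
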