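#' @include AllClasses.R
NULL

#' Patch connectivity under the incidence-function kernel
#'
#' Computes the per-patch connectivity
#' \deqn{S_i = \beta \sum_{j \ne i} A_j \, z_j \, e^{-\alpha d_{ij}},}
#' the distance-weighted aggregate contribution of occupied source patches
#' to colonization pressure at patch \eqn{i}. \eqn{A_j} is the source
#' patch length (km), \eqn{z_j} its occupancy state, \eqn{\alpha}
#' (km\eqn{^{-1}}) the kernel scale (1/\eqn{\alpha} is the mean dispersal
#' distance) and \eqn{\beta} the per-capita effective dispersal rate.
#' Passing \code{occupancy = NULL} applies the structural-connectivity
#' assumption \eqn{z \equiv 1} (all patches treated as occupied sources;
#' models UI/UV).
#'
#' Note on weighting: the source-patch form \eqn{A_j z_j} is used, the
#' standard incidence-function convention in which each source patch's
#' contribution is weighted by \emph{its own} size and occupancy state.
#' Some presentations print the summand with receiving-patch subscripts;
#' \code{literalSubscripts = TRUE} evaluates that literal alternative
#' (\eqn{S_i = \beta A_i z_i \sum_{j \ne i} e^{-\alpha d_{ij}}}) for
#' comparison only.
#'
#' @param network a [PatchNetwork-class].
#' @param occupancy binary vector of source occupancy states (length n), or
#'   \code{NULL} for the structural assumption \eqn{z \equiv 1}.
#' @param alpha kernel scale, km^-1 (> 0; \code{alpha = 0} is allowed and
#'   removes distance decay).
#' @param beta effective dispersal rate (>= 0).
#' @param literalSubscripts evaluate the receiving-patch-subscript variant
#'   (default \code{FALSE}; see Details).
#' @return numeric vector \eqn{S_i \ge 0}, named by patch id.
#' @examples
#' net <- PatchNetwork(c("a", "b"), x = c(0, 1), y = c(0, 0), length = c(1, 1))
#' connectivityVector(net, occupancy = c(1, 0), alpha = 0, beta = 1)  # c(0, 1)
#' @export
connectivityVector <- function(network, occupancy = NULL, alpha, beta,
                               literalSubscripts = FALSE) {
  stopifnot(is(network, "PatchNetwork"))
  if (length(alpha) != 1L || !is.finite(alpha) || alpha < 0)
    stop("alpha must be a single finite value >= 0")
  if (length(beta) != 1L || !is.finite(beta) || beta < 0)
    stop("beta must be a single finite value >= 0")
  n <- nPatches(network)
  if (is.null(occupancy)) {
    z <- rep(1, n)
  } else {
    z <- as.numeric(occupancy)
    if (length(z) != n)
      stop("occupancy must have one state per patch")
    if (any(is.na(z)) || !all(z %in% c(0, 1)))
      stop("occupancy states must be 0 or 1")
  }
  K <- exp(-alpha * network@dist)
  diag(K) <- 0  # self-contribution excluded
  A <- network@length
  S <- if (literalSubscripts) {
    beta * A * z * rowSums(K)
  } else {
    beta * as.vector(K %*% (A * z))
  }
  stats::setNames(S, network@patchId)
}

#' Colonization probability from connectivity
#'
#' \deqn{\gamma = 1 - e^{-S}}: colonization is an asymptotically
#' increasing function of connectivity, zero when no occupied source
#' exists and approaching 1 as connectivity grows.
#'
#' @param S non-negative connectivity value(s).
#' @return probability(ies) in \[0, 1).
#' @examples
#' colonizationProb(log(2))  # 0.5
#' @export
colonizationProb <- function(S) {
  if (any(S < 0)) stop("connectivity must be >= 0")
  -expm1(-S)
}

#' Extinction probability from patch length
#'
#' \deqn{\mathrm{logit}\,\varepsilon_i = \delta_0 + \delta_1 A_i}: local
#' extinction depends on patch length \eqn{A_i} (a proxy for population
#' size) through a logit-linear model. With \eqn{\delta_1 < 0}, longer
#' patches are less extinction-prone.
#'
#' @param A patch length(s), km (> 0).
#' @param delta0,delta1 logit-scale intercept and slope.
#' @return extinction probability(ies) in (0, 1).
#' @examples
#' extinctionProb(0.5, delta0 = 1, delta1 = -2)  # 0.5
#' @export
extinctionProb <- function(A, delta0, delta1) {
  if (any(A <= 0)) stop("patch lengths must be > 0")
  stats::plogis(delta0 + delta1 * A)
}

#' Markov transition probability for patch occupancy
#'
#' \deqn{\psi = (1 - z_{prev})\,\gamma + z_{prev}\,(1 - \varepsilon):}
#' an empty patch is colonized with probability \eqn{\gamma}; an occupied
#' patch persists with probability \eqn{1 - \varepsilon}.
#'
#' @param zPrev previous occupancy state(s), 0 or 1.
#' @param gamma colonization probability(ies).
#' @param epsilon extinction probability(ies).
#' @return occupancy probability(ies) \eqn{\psi}.
#' @export
transitionProb <- function(zPrev, gamma, epsilon) {
  if (any(is.na(zPrev)) || !all(zPrev %in% c(0, 1)))
    stop("zPrev must be binary")
  if (any(gamma < 0 | gamma > 1) || any(epsilon < 0 | epsilon > 1))
    stop("gamma and epsilon must be probabilities")
  (1 - zPrev) * gamma + zPrev * (1 - epsilon)
}

# Kernel matrix exp(-alpha d) with zero diagonal; internal.
.kernelMatrix <- function(network, alpha) {
  K <- exp(-alpha * network@dist)
  diag(K) <- 0
  K
}
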