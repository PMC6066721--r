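#' Triangular root distance density
#'
#' Density of the Euclidean distance from soil to a single vertical (tap)
#' root placed off-center in a cylindrical column, with \code{p} the distance
#' between the root and the column wall. The density rises linearly on
#' \eqn{[0, p]} (perimeter grows linearly with radial distance), falls
#' linearly on \eqn{(p, 2p]} (tailing from the asymmetric root position), and
#' is zero beyond \eqn{2p}:
#' \deqn{f^\Delta_p(d) = d/p^2 \;(0 \le d \le p),\quad (2p-d)/p^2 \;(p < d
#'   \le 2p),\quad 0 \;(d > 2p).}
#'
#' @param d distances in mm, nonnegative.
#' @param p tap-root-to-wall distance in mm, > 0.
#' @return Density values in 1/mm.
#' @examples
#' triangularPdf(2, p = 2)   # peak value 1/p = 0.5
#' @export
triangularPdf <- function(d, p) {
  .checkP(p)
  stopifnot(all(d >= 0))
  ifelse(d <= p, d / p^2, ifelse(d <= 2 * p, (2 * p - d) / p^2, 0))
}

#' @describeIn triangularPdf Closed-form (piecewise quadratic) CDF.
#' @export
triangularCdf <- function(d, p) {
  .checkP(p)
  ifelse(d <= 0, 0,
    ifelse(d <= p, d^2 / (2 * p^2),
      ifelse(d <= 2 * p, 1 - (2 * p - d)^2 / (2 * p^2), 1)))
}

#' @describeIn triangularPdf Inverse CDF (for sampling).
#' @param q probabilities in [0, 1].
#' @export
triangularQuantile <- function(q, p) {
  .checkP(p)
  stopifnot(all(q >= 0 & q <= 1))
  ifelse(q <= 0.5, p * sqrt(2 * q), 2 * p - p * sqrt(2 * (1 - q)))
}

#' Gamma root distance density
#'
#' Density of root distances in a developed root network (tap root plus
#' laterals): a gamma distribution with dimensionless shape \code{k} and
#' scale \code{theta} (mm),
#' \deqn{f^\Gamma_{k,\theta}(d) = d^{k-1} e^{-d/\theta} / (\theta^k
#'   \Gamma(k)).}
#' \code{k = 1} gives the exponential distribution; as \code{k} grows the
#' standardized density approaches a Gaussian. The mean is \eqn{k\theta} and
#' the variance \eqn{k\theta^2}.
#'
#' @param d distances in mm, nonnegative.
#' @param k shape parameter, > 0.
#' @param theta scale parameter in mm, > 0.
#' @return Density values in 1/mm.
#' @examples
#' gammaPdf(0, k = 1, theta = 3)  # exponential intercept 1/theta
#' @export
gammaPdf <- function(d, k, theta) {
  .checkGamma(k, theta)
  stopifnot(all(d >= 0))
  dgamma(d, shape = k, scale = theta)
}

#' Mixed triangular-gamma root distance density
#'
#' Convex combination of the gamma density (weight \code{c}, developed
#' lateral network) and the triangular density (weight \code{1 - c}, single
#' vertical tap root). This four-parameter family describes root distance
#' histograms across all early growth stages, interpolating between the two
#' architectural extremes.
#'
#' @param d distances in mm, nonnegative.
#' @param params a \linkS4class{MixedModelParams} object.
#' @return Density values in 1/mm.
#' @examples
#' pp <- mixedModelParams(c = 0.5, k = 2, theta = 4, p = 20)
#' mixedPdf(c(1, 5, 20), pp)
#' @export
mixedPdf <- function(d, params) {
  stopifnot(is(params, "MixedModelParams"))
  validObject(params)
  stopifnot(all(d >= 0))
  params@c * dgamma(d, shape = params@k, scale = params@theta) +
    (1 - params@c) * triangularPdf(d, params@p)
}

#' @describeIn mixedPdf Cumulative distribution function of the mixture
#'   (gamma CDF plus closed-form triangular CDF).
#' @export
mixedCdf <- function(d, params) {
  stopifnot(is(params, "MixedModelParams"))
  validObject(params)
  stopifnot(all(d >= 0))
  params@c * pgamma(d, shape = params@k, scale = params@theta) +
    (1 - params@c) * triangularCdf(d, params@p)
}

#' @describeIn mixedPdf Analytic mean of the mixture,
#'   \eqn{c k \theta + (1-c) p}.
#' @export
mixedMean <- function(params) {
  stopifnot(is(params, "MixedModelParams"))
  params@c * params@k * params@theta + (1 - params@c) * params@p
}

#' Sample root distances from the mixed triangular-gamma model
#'
#' Draws i.i.d. distances: component chosen Bernoulli(c), triangular
#' component by inverse-CDF, gamma component by the standard sampler.
#'
#' @param params a \linkS4class{MixedModelParams}.
#' @param n number of draws.
#' @param seed integer seed; the same seed reproduces the same draws.
#' @return Numeric vector of n distances (mm).
#' @examples
#' d <- sampleMixed(mixedModelParams(1, 2, 3, 1), n = 1000, seed = 7)
#' mean(d)  # close to k * theta = 6
#' @export
sampleMixed <- function(params, n, seed) {
  stopifnot(is(params, "MixedModelParams"), n >= 1)
  validObject(params)
  set.seed(as.integer(seed))
  fromGamma <- runif(n) < params@c
  out <- numeric(n)
  ng <- sum(fromGamma)
  if (ng > 0)
    out[fromGamma] <- rgamma(ng, shape = params@k, scale = params@theta)
  if (ng < n)
    out[!fromGamma] <- triangularQuantile(runif(n - ng), params@p)
  out
}

.checkP <- function(p) {
  if (length(p) != 1 || !is.finite(p) || p <= 0)
    stop("'p' must be a single positive length (mm)", call. = FALSE)
  invisible(p)
}

.checkGamma <- function(k, theta) {
  if (length(k) != 1 || !is.finite(k) || k <= 0)
    stop("'k' must be a single positive shape", call. = FALSE)
  if (length(theta) != 1 || !is.finite(theta) || theta <= 0)
    stop("'theta' must be a single positive length (mm)", call. = FALSE)
  invisible(NULL)
}
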