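## Sampling of multiplicity, copy numbers and randomized expression
## parameters.  Each sampler takes an explicit seed; draws are laid out
## cell-major so that extending n keeps the first cells' draws unchanged.

## derived sub-seeds: one shared stream per run, deterministic offsets per
## variable block (kept well below 2^31)
subSeed <- function(seed, offset) {
  (as.integer(seed) %% 1000000000L) + as.integer(offset)
}

#' Sample multiplicities of transfection
#'
#' Draws \code{nCells} i.i.d. multiplicities from the configured family.
#' For the lognormal family the values are \code{rlnorm(muM, sigmaM)}; the
#' Poisson and Gamma variants reproduce alternative delivery models with
#' comparable means.
#'
#' @param model a \code{\link{MultiplicityModel}}.
#' @param nCells number of cells.
#' @param seed integer seed; fixed seeds give bit-identical draws.
#' @return numeric vector of \code{nCells} strictly positive multiplicities.
#' @examples
#' m <- sampleMultiplicity(MultiplicityModel(), 1e4, seed = 1)
#' mean(m)  # ~ exp(1.4979 + 1.2686^2 / 2) = 10.0
#' @export
sampleMultiplicity <- function(model, nCells, seed) {
  stopifnot(is(model, "MultiplicityModel"))
  validObject(model)
  nCells <- as.integer(nCells)
  if (is.na(nCells) || nCells < 1L)
    stop("nCells must be >= 1", call. = FALSE)
  set.seed(subSeed(seed, 11L))
  m <- switch(model@family,
    lognormal = if (model@sigmaM == 0) rep(exp(model@muM), nCells)
                else rlnorm(nCells, meanlog = model@muM,
                            sdlog = model@sigmaM),
    poisson   = rpois(nCells, lambda = model@lambda),
    gamma     = rgamma(nCells, shape = model@shapeK, scale = model@scaleTheta))
  ## discrete/continuous draws of 0 would carry no plasmid at all; keep the
  ## cells but floor the multiplicity at a vanishing positive value so the
  ## copy-number model stays defined
  pmax(m, 1e-6)
}

#' Sample per-cell gene copy-number vectors
#'
#' Given multiplicities \code{m}, draws each gene's copy number independently
#' from a normal with mean \eqn{a_i m} and sd \eqn{\epsilon a_i m} (diagonal
#' multivariate normal).  Copy numbers are kept continuous; draws below a
#' small positive floor are truncated so downstream kinetics stay defined.
#' With \code{epsilon = 0} the vector collapses to \eqn{a m} exactly (the
#' single-plasmid setting).
#'
#' @param m multiplicity, scalar or vector (one per cell).
#' @param mix a \code{\link{GeneMix}}.
#' @param seed integer seed.
#' @param floor lower truncation bound for the draws.
#' @return matrix with one row per cell and one column per gene
#'   (\code{k1..kN}).
#' @export
sampleCopyNumbers <- function(m, mix, seed, floor = 1e-6) {
  stopifnot(is(mix, "GeneMix"))
  validObject(mix)
  if (any(!is.finite(m)) || any(m <= 0))
    stop("multiplicities must be > 0", call. = FALSE)
  n <- length(m)
  a <- mix@abundances
  N <- length(a)
  mu <- outer(m, a)                      # n x N means a_i * m_j
  if (mix@epsilon == 0) {
    k <- mu
  } else {
    set.seed(subSeed(seed, 23L))
    ## cell-major layout: the draws of cell j occupy positions (j-1)*N+1 .. j*N
    z <- matrix(rnorm(n * N), nrow = n, ncol = N, byrow = TRUE)
    k <- mu + mix@epsilon * mu * z
    k[k < floor] <- floor
  }
  colnames(k) <- paste0("k", seq_len(N))
  k
}

#' Sample mean-preserving randomized expression parameters
#'
#' Draws per-cell expression parameters around their nominal values with
#' log-space sd \code{sigma}.  The lognormal draw is
#' \eqn{LN(\ln\beta_i - \sigma^2/2, \sigma)}, whose arithmetic mean is
#' exactly \eqn{\beta_i}.  The gamma family solves shape and scale so that
#' mean and variance match the lognormal case at the same sigma
#' (\eqn{k\theta = \beta}, \eqn{k\theta^2 = \beta^2 (e^{\sigma^2} - 1)});
#' at \code{sigma = 0} both families degenerate to the nominal value.
#'
#' @param noise a \code{\link{NoiseModel}} carrying sigma, family and the
#'   nominal means.
#' @param nCells number of cells.
#' @param seed integer seed.
#' @return matrix (\code{nCells} rows) of randomized parameters, one column
#'   per nominal mean.
#' @export
sampleExpressionScalars <- function(noise, nCells, seed) {
  stopifnot(is(noise, "NoiseModel"))
  validObject(noise)
  nominal <- noise@nominalMeans
  if (!length(nominal))
    stop("noise model carries no nominal means", call. = FALSE)
  nCells <- as.integer(nCells)
  if (is.na(nCells) || nCells < 1L)
    stop("nCells must be >= 1", call. = FALSE)
  P <- length(nominal)
  sig <- noise@sigma
  if (sig == 0) {
    ## degenerate draw for either family
    out <- matrix(nominal, nrow = nCells, ncol = P, byrow = TRUE)
  } else {
    set.seed(subSeed(seed, 37L))
    z <- matrix(rnorm(nCells * P), nrow = nCells, ncol = P, byrow = TRUE)
    if (noise@family == "lognormal") {
      mu <- matrix(log(nominal) - sig^2 / 2, nrow = nCells, ncol = P,
                   byrow = TRUE)
      out <- exp(mu + sig * z)
    } else {
      ## gamma with mean beta, variance beta^2 (e^{sigma^2} - 1)
      cv2 <- exp(sig^2) - 1
      shape <- 1 / cv2
      set.seed(subSeed(seed, 37L))
      draws <- rgamma(nCells * P, shape = shape, scale = 1)
      scl <- matrix(nominal * cv2, nrow = nCells, ncol = P, byrow = TRUE)
      out <- matrix(draws, nrow = nCells, ncol = P, byrow = TRUE) * scl
    }
  }
  ## zero nominal means (knocked-out translations) stay exactly zero
  zero <- which(nominal == 0)
  if (length(zero)) out[, zero] <- 0
  colnames(out) <- names(nominal)
  out
}
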