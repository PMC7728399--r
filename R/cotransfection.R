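## Constitutive co-transfection simulator: O_i = k_i * b_i at steady state.

#' Steady-state level of a constitutive gene
#'
#' For a constitutive gene with production rate \code{bBar} (proteins per
#' gene copy per unit time) and first-order degradation \code{delta}, the
#' steady state is \eqn{O = (\bar b/\delta) k = \beta k}.
#'
#' @param k gene copy number (scalar or vector).
#' @param bBar production rate.
#' @param delta degradation rate (> 0).
#' @return steady-state protein level(s).
#' @examples
#' steadyStateConstitutive(10, bBar = 5, delta = 0.5)  # 100
#' @export
steadyStateConstitutive <- function(k, bBar, delta) {
  if (any(!is.finite(delta)) || any(delta <= 0))
    stop("delta must be > 0", call. = FALSE)
  (bBar / delta) * k
}

#' Default channel names of the five-gene constitutive mix
#' @return character vector of channel names in gene order.
#' @export
cotransfectionChannels <- function() {
  c("SBFP2", "Cerulean", "Citrine", "mCherry", "iRFP")
}

#' Simulate a constitutive co-transfection
#'
#' Generates a flow-cytometry-like per-cell table for the co-transfection of
#' \code{nGenes(mix)} independent constitutively expressed genes: per cell,
#' a multiplicity \eqn{m_j} is drawn, then copy numbers \eqn{k_j | m_j},
#' then mean-preserving randomized proportionality coefficients \eqn{b_j};
#' the observed channels are \eqn{O_{ji} = k_{ji} b_{ji}}.  Every latent is
#' stored so downstream analyses can be regenerated without resimulation.
#'
#' @param mix a \code{\link{GeneMix}}.
#' @param multiplicity a \code{\link{MultiplicityModel}}.
#' @param noise a \code{\link{NoiseModel}}; its nominal means are the global
#'   proportionality coefficients \eqn{\beta_i}, one per gene (recycled if a
#'   single value is given).
#' @param nCells number of cells to simulate.
#' @param seed integer seed (all randomness flows from it).
#' @param channels channel names, one per gene.
#' @return a \code{\link{PopulationFrame}} with channels, latents
#'   \code{m}, \code{k*}, \code{b*}, and run metadata.
#' @export
simulateCotransfection <- function(mix = GeneMix(),
                                   multiplicity = MultiplicityModel(),
                                   noise = NoiseModel(nominalMeans =
                                     rep(1000, 5)),
                                   nCells = 5e5, seed = 1,
                                   channels = cotransfectionChannels()) {
  stopifnot(is(mix, "GeneMix"), is(multiplicity, "MultiplicityModel"),
            is(noise, "NoiseModel"))
  nCells <- as.integer(nCells)
  if (is.na(nCells) || nCells < 1L)
    stop("nCells must be >= 1", call. = FALSE)
  N <- nGenes(mix)
  beta <- noise@nominalMeans
  if (length(beta) == 1L) beta <- rep(beta, N)
  if (length(beta) != N)
    stop("need one nominal beta per gene", call. = FALSE)
  names(beta) <- paste0("b", seq_len(N))
  noiseN <- initialize(noise, nominalMeans = beta)
  channels <- channels[seq_len(N)]

  m <- sampleMultiplicity(multiplicity, nCells, seed)
  k <- sampleCopyNumbers(m, mix, seed)
  b <- sampleExpressionScalars(noiseN, nCells, seed)
  O <- k * b
  colnames(O) <- channels

  d <- data.frame(cell = seq_len(nCells), m = m, k, b, O,
                  check.names = FALSE)
  PopulationFrame(d, channels = channels,
                  latents = c("m", colnames(k), colnames(b)),
                  metadata = list(kind = "cotransfection",
                                  sigma = noise@sigma,
                                  epsilon = mix@epsilon,
                                  abundances = mix@abundances,
                                  beta = unname(beta),
                                  referenceChannel = channels[mix@referenceIndex],
                                  multiplicityFamily = multiplicity@family,
                                  noiseFamily = noise@family,
                                  seed = seed))
}
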