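## Stable-vs-transient validation: extract modes from matched
## stable-integration simulations with the same peak finder and correlate
## them with the modes found in the transient data.

#' Extract output (and input) modes from stable-integration frames
#'
#' Applies the identical fitting machinery used by the peak finder to the
#' display-transformed channel distributions of a stable-integration run.
#' No reference binning is involved: all cells of a design share one copy
#' number.
#'
#' @param framesByDox list of \code{\link{PopulationFrame}}s from
#'   \code{\link{simulateStableCircuit}}.
#' @param channels channels to fit (outputs, by default).
#' @param rules an output \code{\link{FitRuleSet}}.
#' @param params biexponential display parameters.
#' @return data.frame with columns design, dox, channel, branch, mode,
#'   weight (modes in display units).
#' @export
extractStableModes <- function(framesByDox,
                               channels = c("Cerulean", "Citrine"),
                               rules = outputFitRules(minEvents = 100),
                               params = biexpParams()) {
  out <- list()
  for (l in seq_along(framesByDox)) {
    fr <- framesByDox[[l]]
    dox <- fr@metadata$dox
    design <- fr@metadata$designBin
    if (is.null(design)) design <- NA_integer_
    for (ch in channels) {
      x <- biexpTransform(channelValues(fr, ch), params)
      mo <- suppressWarnings(fitModes(x, rules))
      if (!nrow(mo)) next
      out[[length(out) + 1L]] <- data.frame(
        design = design, dox = dox, channel = ch,
        branch = mo$branch, mode = mo$mode, weight = mo$weight)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## collapse a set of mode values into HIGH/LOW (or a single MONO value)
.branchSummary <- function(modes, minSep = 0.3) {
  modes <- modes[is.finite(modes)]
  if (!length(modes)) return(NULL)
  if (max(modes) - min(modes) > minSep)
    list(HIGH = max(modes), LOW = min(modes))
  else
    list(MONO = median(modes))
}

#' Pair and correlate transient and stable modes
#'
#' Pairs output modes by (bin/design, Dox level, branch): HIGH with HIGH and
#' LOW with LOW; when one side is monomodal its single mode pairs with the
#' nearer branch of the other side.  Pearson correlation is computed on the
#' pooled pairs per output channel.
#'
#' @param transientIO output of \code{\link{extractIOPoints}} on the
#'   transient data.
#' @param stableModes output of \code{\link{extractStableModes}} (design
#'   indices must correspond to the transient bin indices).
#' @param channels output channels to correlate.
#' @param minPairs fewer matched pairs than this raises an error.
#' @return data.frame with one row per channel: channel, rho, nPairs,
#'   nUnmatched.
#' @export
correlateModes <- function(transientIO, stableModes,
                           channels = c("Cerulean", "Citrine"),
                           minPairs = 3L) {
  res <- list()
  for (ch in channels) {
    tr <- transientIO[transientIO$channel == ch, , drop = FALSE]
    st <- stableModes[stableModes$channel == ch, , drop = FALSE]
    pairsT <- numeric(0); pairsS <- numeric(0); unmatched <- 0L
    keys <- unique(rbind(tr[c("bin", "dox")],
                         setNames(st[c("design", "dox")], c("bin", "dox"))))
    for (r in seq_len(nrow(keys))) {
      b <- keys$bin[r]; dx <- keys$dox[r]
      tsub <- tr[tr$bin == b & tr$dox == dx, , drop = FALSE]
      ssub <- st[st$design == b & st$dox == dx, , drop = FALSE]
      if (!nrow(tsub) || !nrow(ssub)) {
        unmatched <- unmatched + nrow(tsub) + nrow(ssub)
        next
      }
      tb <- .branchSummary(tsub$outputMode)
      sb <- .branchSummary(ssub$mode)
      if (is.null(tb) || is.null(sb)) next
      tBi <- !is.null(tb$HIGH); sBi <- !is.null(sb$HIGH)
      if (tBi && sBi) {
        pairsT <- c(pairsT, tb$HIGH, tb$LOW)
        pairsS <- c(pairsS, sb$HIGH, sb$LOW)
      } else if (!tBi && !sBi) {
        pairsT <- c(pairsT, tb$MONO)
        pairsS <- c(pairsS, sb$MONO)
      } else if (tBi && !sBi) {
        near <- if (abs(tb$HIGH - sb$MONO) <= abs(tb$LOW - sb$MONO))
          tb$HIGH else tb$LOW
        pairsT <- c(pairsT, near); pairsS <- c(pairsS, sb$MONO)
        unmatched <- unmatched + 1L
      } else {
        near <- if (abs(sb$HIGH - tb$MONO) <= abs(sb$LOW - tb$MONO))
          sb$HIGH else sb$LOW
        pairsT <- c(pairsT, tb$MONO); pairsS <- c(pairsS, near)
        unmatched <- unmatched + 1L
      }
    }
    if (length(pairsT) < minPairs)
      stop("fewer than ", minPairs, " matched pairs for channel ", ch,
           call. = FALSE)
    rho <- if (sd(pairsT) == 0 || sd(pairsS) == 0) 1
           else cor(pairsT, pairsS)
    res[[length(res) + 1L]] <- data.frame(
      channel = ch, rho = rho, nPairs = length(pairsT),
      nUnmatched = unmatched)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Full stable-vs-transient validation run
#'
#' Orchestrates the complete comparison for one or more circuits and noise
#' levels: simulate transient transfection across the Dox grid; run the
#' peak finder; derive one stable-integration design per reference bin;
#' simulate the stable scenarios; extract stable modes with the identical
#' fitter; pair and correlate.
#'
#' @param topologies circuit topologies to validate.
#' @param sigmas intrinsic noise levels.
#' @param nCellsPerDox transient cells per Dox level.
#' @param nStablePerDox stable cells per Dox level and design.
#' @param dox Dox grid.
#' @param nBins reference bins.
#' @param seed integer seed.
#' @param params circuit rate constants.
#' @param mix gene mix.
#' @param verbose print progress.
#' @return list with elements \code{rho} (data.frame: topology, sigma,
#'   channel, rho, nPairs), \code{meanRho}, and \code{io} (the transient
#'   I/O points, for plotting).
#' @export
runValidation <- function(topologies = c("FO", "RIFFM"),
                          sigmas = c(0, 0.02, 0.04, 0.08, 0.16, 0.32),
                          nCellsPerDox = 2e4, nStablePerDox = 500,
                          dox = doxGrid(), nBins = 10L, seed = 1,
                          params = defaultCircuitParameters(),
                          mix = GeneMix(), verbose = FALSE) {
  rhoRows <- list()
  ioAll <- list()
  for (topo in topologies) {
    spec <- buildCircuit(topo, params)
    for (s in seq_along(sigmas)) {
      sig <- sigmas[s]
      seedTS <- subSeed(seed, 1000L * match(topo, circuitTopologies()) +
                          17L * s)
      frames <- simulateTransientCircuit(spec, mix = mix, sigma = sig,
                                         dox = dox,
                                         nCellsPerDox = nCellsPerDox,
                                         seed = seedTS)
      pooled <- poolFrames(frames)
      bins <- binByReference(pooled, nBins = nBins, tailFraction = 0.025)
      io <- extractIOPoints(frames, nBins = nBins, edges = bins@edges)
      io$topology <- topo; io$sigma <- sig
      ioAll[[length(ioAll) + 1L]] <- io
      designs <- suppressWarnings(
        stableCopyNumbersFromBins(pooled, bins, mix))
      stModes <- list()
      for (dsg in designs) {
        sframes <- simulateStableCircuit(spec, dsg, sigma = sig, dox = dox,
                                         nCellsPerDox = nStablePerDox,
                                         seed = subSeed(seedTS, 31L * dsg@bin))
        stModes[[length(stModes) + 1L]] <- extractStableModes(sframes)
      }
      stModes <- do.call(rbind, stModes)
      cc <- correlateModes(io, stModes)
      cc <- data.frame(topology = topo, sigma = sig, cc)
      rhoRows[[length(rhoRows) + 1L]] <- cc
      if (verbose)
        message(sprintf("%s sigma=%.2f: rho = %s", topo, sig,
                        paste(sprintf("%.3f", cc$rho), collapse = ", ")))
    }
  }
  rho <- do.call(rbind, rhoRows)
  rownames(rho) <- NULL
  list(rho = rho, meanRho = mean(rho$rho),
       io = do.call(rbind, ioAll))
}
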