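#' @import methods
#' @importFrom stats rnorm rlnorm rpois rgamma median quantile sd optim
#'   setNames approx density cor complete.cases
#' @importFrom utils head tail modifyList
NULL

## ---------------------------------------------------------------------------
## Sampling model classes
## ---------------------------------------------------------------------------

#' Multiplicity-of-transfection model
#'
#' Describes the per-cell distribution of the multiplicity of transfection
#' \eqn{m}, the latent scale of plasmid uptake.  Three families are supported:
#' lognormal (the default for lipofection), Poisson and Gamma.
#'
#' @slot family one of \code{"lognormal"}, \code{"poisson"}, \code{"gamma"}.
#' @slot muM,sigmaM log-scale mean and sd of the lognormal family.
#' @slot lambda rate of the Poisson family.
#' @slot shapeK,scaleTheta shape and scale of the Gamma family.
#' @export
setClass("MultiplicityModel",
  representation(family = "character", muM = "numeric", sigmaM = "numeric",
                 lambda = "numeric", shapeK = "numeric", scaleTheta = "numeric"),
  prototype(family = "lognormal", muM = 1.4979, sigmaM = 1.2686,
            lambda = NA_real_, shapeK = NA_real_, scaleTheta = NA_real_))

setValidity("MultiplicityModel", function(object) {
  fam <- object@family
  if (length(fam) != 1L || !fam %in% c("lognormal", "poisson", "gamma"))
    return("family must be one of 'lognormal', 'poisson', 'gamma'")
  msg <- switch(fam,
    lognormal = {
      if (!is.finite(object@muM) || !is.finite(object@sigmaM))
        "lognormal family requires finite muM and sigmaM"
      else if (object@sigmaM < 0) "sigmaM must be >= 0"
      else TRUE
    },
    poisson = {
      if (!is.finite(object@lambda) || object@lambda <= 0)
        "poisson family requires lambda > 0" else TRUE
    },
    gamma = {
      if (!is.finite(object@shapeK) || object@shapeK <= 0 ||
          !is.finite(object@scaleTheta) || object@scaleTheta <= 0)
        "gamma family requires shapeK > 0 and scaleTheta > 0" else TRUE
    })
  msg
})

#' @param family distribution family for the multiplicity.
#' @param muM,sigmaM lognormal log-scale parameters (defaults fit transient
#'   lipofection data: \code{muM = 1.4979}, \code{sigmaM = 1.2686}).
#' @param lambda Poisson rate.
#' @param shapeK,scaleTheta Gamma shape and scale.
#' @return a \code{MultiplicityModel} object.
#' @rdname MultiplicityModel-class
#' @export
MultiplicityModel <- function(family = c("lognormal", "poisson", "gamma"),
                              muM = 1.4979, sigmaM = 1.2686,
                              lambda = NA_real_, shapeK = NA_real_,
                              scaleTheta = NA_real_) {
  family <- match.arg(family)
  new("MultiplicityModel", family = family, muM = muM, sigmaM = sigmaM,
      lambda = lambda, shapeK = shapeK, scaleTheta = scaleTheta)
}

#' Gene mix for a co-transfection
#'
#' The set of co-delivered genes: relative molar abundances \eqn{a_i}
#' (reference gene fixed at 1), and the copy-number dispersion factor
#' \eqn{\epsilon} that scales the per-gene copy-number sd as
#' \eqn{\epsilon a_i m}.
#'
#' @slot abundances relative molar abundance per gene; entry
#'   \code{referenceIndex} must equal 1.
#' @slot referenceIndex which gene is the transfection marker.
#' @slot epsilon copy-number dispersion factor.
#' @export
setClass("GeneMix",
  representation(abundances = "numeric", referenceIndex = "integer",
                 epsilon = "numeric"))

setValidity("GeneMix", function(object) {
  a <- object@abundances
  if (length(a) < 1L) return("at least one gene is required")
  if (any(!is.finite(a)) || any(a <= 0)) return("all abundances must be > 0")
  ri <- object@referenceIndex
  if (length(ri) != 1L || ri < 1L || ri > length(a))
    return("referenceIndex out of range")
  if (abs(a[ri] - 1) > .Machine$double.eps^0.5)
    return("the reference gene must have abundance exactly 1")
  if (!is.finite(object@epsilon) || object@epsilon < 0)
    return("epsilon must be >= 0")
  TRUE
})

#' @param abundances numeric vector of relative abundances.
#' @param referenceIndex index of the transfection marker gene (abundance 1).
#' @param epsilon copy-number dispersion factor (default 0.04).
#' @return a \code{GeneMix} object.
#' @rdname GeneMix-class
#' @export
GeneMix <- function(abundances = c(1.0, 1.3, 0.8, 0.5, 0.4),
                    referenceIndex = 1L, epsilon = 0.04) {
  new("GeneMix", abundances = as.numeric(abundances),
      referenceIndex = as.integer(referenceIndex), epsilon = epsilon)
}

#' @rdname GeneMix-class
#' @param object,x a \code{GeneMix}.
#' @export
nGenes <- function(x) length(x@abundances)

#' Intrinsic expression-noise model
#'
#' Per-cell randomisation of expression parameters (proportionality
#' coefficients \eqn{b_i} for constitutive genes, translation rates for
#' circuit genes).  Draws are mean-preserving: the arithmetic mean of the
#' drawn values equals the nominal value for every noise level.
#'
#' @slot sigma log-space standard deviation of the randomised parameters.
#' @slot nominalMeans named numeric vector of nominal parameter values.
#' @slot family \code{"lognormal"} (default) or \code{"gamma"}; the gamma
#'   family is moment-matched to the lognormal at the same sigma.
#' @export
setClass("NoiseModel",
  representation(sigma = "numeric", nominalMeans = "numeric",
                 family = "character"),
  prototype(sigma = 0.08, family = "lognormal"))

setValidity("NoiseModel", function(object) {
  if (!is.finite(object@sigma) || object@sigma < 0)
    return("sigma must be >= 0")
  if (!object@family %in% c("lognormal", "gamma"))
    return("family must be 'lognormal' or 'gamma'")
  if (length(object@nominalMeans) &&
      (any(!is.finite(object@nominalMeans)) || any(object@nominalMeans < 0)))
    return("nominal means must be finite and >= 0")
  TRUE
})

#' @param sigma log-space sd (one of the study levels 0.00--0.32, say).
#' @param nominalMeans named nominal parameter values.
#' @param family noise family.
#' @return a \code{NoiseModel} object.
#' @rdname NoiseModel-class
#' @export
NoiseModel <- function(sigma = 0.08, nominalMeans = numeric(0),
                       family = c("lognormal", "gamma")) {
  new("NoiseModel", sigma = sigma, nominalMeans = as.numeric2(nominalMeans),
      family = match.arg(family))
}

## keep names when coercing
as.numeric2 <- function(x) {
  y <- as.numeric(x)
  names(y) <- names(x)
  y
}

## ---------------------------------------------------------------------------
## PopulationFrame
## ---------------------------------------------------------------------------

#' Per-cell population table
#'
#' One row per cell, holding observed channel intensities (linear,
#' flow-cytometer scaled units) and, for simulated data, the latent variables
#' used to generate them (multiplicity \code{m}, copy numbers \code{k_*},
#' randomised parameters \code{b_*}/\code{p_*}).  Log and biexponential
#' transforms are applied lazily by the transform functions, so the frame is
#' the single linear-scale source of truth.
#'
#' @slot data the cell table.
#' @slot channels names of observed channel columns.
#' @slot latents names of latent columns (empty for imported data).
#' @slot metadata run metadata (sigma, epsilon, seed, dox, ...).
#' @export
setClass("PopulationFrame",
  representation(data = "data.frame", channels = "character",
                 latents = "character", metadata = "list"))

setValidity("PopulationFrame", function(object) {
  d <- object@data
  miss <- setdiff(c(object@channels, object@latents), names(d))
  if (length(miss))
    return(paste0("columns missing from data: ", paste(miss, collapse = ", ")))
  for (ch in object@channels) {
    v <- d[[ch]]
    if (!is.numeric(v)) return(paste0("channel '", ch, "' is not numeric"))
    if (any(v < 0, na.rm = TRUE))
      return(paste0("channel '", ch, "' has negative values"))
  }
  TRUE
})

#' @param data,channels,latents,metadata see slots.
#' @rdname PopulationFrame-class
#' @export
PopulationFrame <- function(data, channels, latents = character(0),
                            metadata = list()) {
  new("PopulationFrame", data = as.data.frame(data), channels = channels,
      latents = latents, metadata = metadata)
}

#' @rdname PopulationFrame-class
#' @export
setGeneric("nCells", function(object) standardGeneric("nCells"))

#' @rdname PopulationFrame-class
#' @export
setMethod("nCells", "PopulationFrame", function(object) nrow(object@data))

#' @rdname PopulationFrame-class
#' @export
setGeneric("cells", function(object) standardGeneric("cells"))

#' @rdname PopulationFrame-class
#' @export
setMethod("cells", "PopulationFrame", function(object) object@data)

#' @rdname PopulationFrame-class
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))

#' @rdname PopulationFrame-class
#' @export
setMethod("channelNames", "PopulationFrame", function(object) object@channels)

#' @rdname PopulationFrame-class
#' @export
setGeneric("latentNames", function(object) standardGeneric("latentNames"))

#' @rdname PopulationFrame-class
#' @export
setMethod("latentNames", "PopulationFrame", function(object) object@latents)

#' @rdname PopulationFrame-class
#' @param value observed values of one channel.
#' @param channel channel name.
#' @export
channelValues <- function(object, channel) {
  stopifnot(is(object, "PopulationFrame"))
  if (!channel %in% object@channels)
    stop("unknown channel: ", channel, call. = FALSE)
  object@data[[channel]]
}

#' @rdname PopulationFrame-class
#' @param i row index
#' @export
setMethod("[", "PopulationFrame", function(x, i, ...) {
  initialize(x, data = x@data[i, , drop = FALSE])
})

setMethod("show", "PopulationFrame", function(object) {
  cat("PopulationFrame with", nrow(object@data), "cells\n")
  cat("  channels:", paste(object@channels, collapse = ", "), "\n")
  if (length(object@latents))
    cat("  latents: ", paste(object@latents, collapse = ", "), "\n")
  md <- object@metadata
  if (length(md)) {
    keep <- intersect(c("kind", "topology", "sigma", "epsilon", "dox", "seed"),
                      names(md))
    if (length(keep))
      cat("  metadata:", paste(sprintf("%s=%s", keep,
          vapply(md[keep], function(z) paste(format(z), collapse = "/"),
                 character(1))), collapse = ", "), "\n")
  }
  invisible(NULL)
})

## ---------------------------------------------------------------------------
## Binning
## ---------------------------------------------------------------------------

#' Reference-channel bin partition
#'
#' Tail-trimmed partition of a population by the transfection-reference
#' channel: either equal event counts (the PFAFF default, 10 bins after
#' discarding 2.5% tails) or equal width in log10 signal (the copy-number
#' analytics default, 50/25 bins after 0.1% trimming).
#'
#' @slot channel reference channel name.
#' @slot edges bin edges on the linear signal scale (length nBins + 1).
#' @slot assignment per-cell bin index (NA for trimmed cells).
#' @slot medianY per-bin median of the natural-log reference signal.
#' @slot meanO global arithmetic mean of the (untrimmed) reference signal.
#' @slot method \code{"count"} or \code{"width"}.
#' @slot tailFraction fraction trimmed from each side.
#' @export
setClass("BinPartition",
  representation(channel = "character", edges = "numeric",
                 assignment = "integer", medianY = "numeric",
                 meanO = "numeric", method = "character",
                 tailFraction = "numeric"))

setValidity("BinPartition", function(object) {
  if (is.unsorted(object@edges, strictly = TRUE))
    return("edges must be strictly increasing")
  nb <- length(object@edges) - 1L
  if (length(object@medianY) != nb)
    return("medianY must have one entry per bin")
  TRUE
})

#' @rdname BinPartition-class
#' @param object a \code{BinPartition}.
#' @export
setGeneric("nBins", function(object) standardGeneric("nBins"))

#' @rdname BinPartition-class
#' @export
setMethod("nBins", "BinPartition",
          function(object) length(object@edges) - 1L)

setMethod("show", "BinPartition", function(object) {
  cat("BinPartition of channel", object@channel, "into",
      nBins(object), "bins (", object@method, "method,",
      object@tailFraction, "tail fraction )\n")
  cat("  events per bin:", paste(tabulate(object@assignment, nBins(object)),
                                 collapse = " "), "\n")
  invisible(NULL)
})

## ---------------------------------------------------------------------------
## Mode-fitting rules
## ---------------------------------------------------------------------------

#' Rule set for multimodal Gaussian histogram fitting
#'
#' The decision-tree thresholds of the rule-based peak finder.  All distances
#' are in biexponential display units.  Input-channel and output-channel
#' distributions use different acceptance thresholds and three-component
#' reconciliation rules; see \code{\link{fitModes}}.
#'
#' @slot role \code{"input"} or \code{"output"}.
#' @slot gof1 goodness-of-fit (R squared) acceptance for one Gaussian.
#' @slot gof2 acceptance threshold for two Gaussians.
#' @slot collapseClose input rule: pairwise distance below which a
#'   three-Gaussian fit falls back to two (0.42).
#' @slot mergeNear input rule: distance between the closest-pair mean and a
#'   two-Gaussian mode that triggers the merge rule (0.3).
#' @slot pairHigh output rule: distance between the two highest-intensity
#'   peaks below which the remaining peak is removed (0.9).
#' @slot collapseFinal distance between two final modes below which the call
#'   collapses to one Gaussian (0.75).
#' @slot binWidth histogram bin width in display units.
#' @slot minEvents minimum events required for a fit.
#' @slot modeWindow half-width of the slice taken around a mode (0.1).
#' @export
setClass("FitRuleSet",
  representation(role = "character", gof1 = "numeric", gof2 = "numeric",
                 collapseClose = "numeric", mergeNear = "numeric",
                 pairHigh = "numeric", collapseFinal = "numeric",
                 binWidth = "numeric", minEvents = "numeric",
                 modeWindow = "numeric"))

setValidity("FitRuleSet", function(object) {
  if (!object@role %in% c("input", "output"))
    return("role must be 'input' or 'output'")
  if (object@gof1 <= 0 || object@gof1 > 1 || object@gof2 <= 0 || object@gof2 > 1)
    return("goodness-of-fit thresholds must lie in (0, 1]")
  if (object@binWidth <= 0) return("binWidth must be > 0")
  if (object@minEvents < 1) return("minEvents must be >= 1")
  TRUE
})

#' @param gof1,gof2,binWidth,minEvents,modeWindow see slots.
#' @return a \code{FitRuleSet}.
#' @rdname FitRuleSet-class
#' @export
inputFitRules <- function(gof1 = 0.975, gof2 = 0.99, binWidth = 0.05,
                          minEvents = 200, modeWindow = 0.1) {
  new("FitRuleSet", role = "input", gof1 = gof1, gof2 = gof2,
      collapseClose = 0.42, mergeNear = 0.3, pairHigh = NA_real_,
      collapseFinal = 0.75, binWidth = binWidth, minEvents = minEvents,
      modeWindow = modeWindow)
}

#' @rdname FitRuleSet-class
#' @export
outputFitRules <- function(gof1 = 0.975, gof2 = 0.995, binWidth = 0.05,
                           minEvents = 200, modeWindow = 0.1) {
  new("FitRuleSet", role = "output", gof1 = gof1, gof2 = gof2,
      collapseClose = NA_real_, mergeNear = NA_real_, pairHigh = 0.9,
      collapseFinal = 0.75, binWidth = binWidth, minEvents = minEvents,
      modeWindow = modeWindow)
}

## ---------------------------------------------------------------------------
## Circuit specification
## ---------------------------------------------------------------------------

#' Mass-action circuit specification
#'
#' Declarative description of one of the seven three-node topologies.  All
#' topologies share one underlying species/reaction map (reference reporter,
#' Dox-bound rtTA input stage, PIT2/mCherry input branch, two output branches
#' with translationally linked reporters and repressors); topologies differ
#' only by which repressor translations are nulled ("in silico knockouts")
#' and, for the extended motifs, by the promoter the repressor arm targets.
#'
#' @slot topology one of FO, RIFFM, I1FFL1, I1FFL2, cFFL, negFB, posFB.
#' @slot params full rate-constant list (see
#'   \code{\link{defaultCircuitParameters}}).
#' @slot kniActive,laciActive whether the repressor translation is active.
#' @slot kniTarget,laciTarget promoter targeted by each arm and the sign of
#'   the interaction (\code{"none"}, \code{"P1rep"}, \code{"P2rep"},
#'   \code{"P2act"}).
#' @slot readouts the five steady-state readouts.
#' @export
setClass("CircuitSpec",
  representation(topology = "character", params = "list",
                 kniActive = "logical", laciActive = "logical",
                 kniTarget = "character", laciTarget = "character",
                 readouts = "character"))

setValidity("CircuitSpec", function(object) {
  if (!object@topology %in% circuitTopologies())
    return(paste("unknown topology:", object@topology))
  need <- requiredCircuitRates()
  miss <- setdiff(need, names(object@params))
  if (length(miss))
    return(paste0("missing rate constants: ", paste(miss, collapse = ", ")))
  bad <- vapply(object@params[need], function(v)
    !is.numeric(v) || any(!is.finite(v)) || any(v < 0), logical(1))
  if (any(bad))
    return(paste0("non-finite or negative rates: ",
                  paste(need[bad], collapse = ", ")))
  TRUE
})

setMethod("show", "CircuitSpec", function(object) {
  cat("CircuitSpec:", object@topology, "\n")
  cat("  Kni arm:  ",
      if (object@kniActive) object@kniTarget else "knocked out", "\n")
  cat("  LacI arm: ",
      if (object@laciActive) object@laciTarget else "knocked out", "\n")
  cat("  readouts:", paste(object@readouts, collapse = ", "), "\n")
  invisible(NULL)
})

## ---------------------------------------------------------------------------
## Stable-integration design
## ---------------------------------------------------------------------------

#' Fixed copy-number design for a stable-integration simulation
#'
#' All cells share one copy-number vector whose reference entry is the
#' empirical mode of the reference-gene copy number in one transient bin and
#' whose other entries follow the nominal abundance ratios.
#'
#' @slot k fixed copy-number vector.
#' @slot bin index of the transient bin the design mirrors.
#' @slot y1 median log reference signal of that bin.
#' @export
setClass("StableDesign",
  representation(k = "numeric", bin = "integer", y1 = "numeric"))

setValidity("StableDesign", function(object) {
  if (any(!is.finite(object@k)) || any(object@k <= 0))
    return("copy numbers must be positive")
  TRUE
})

setMethod("show", "StableDesign", function(object) {
  cat("StableDesign (bin", object@bin, "): k =",
      paste(signif(object@k, 4), collapse = ", "), "\n")
  invisible(NULL)
})
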