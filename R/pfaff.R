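## PFAFF core: reference binning, rule-based multimodal Gaussian fitting,
## mode-window slicing and input/output curve assembly.

#' Bin a population by its reference channel
#'
#' Trims the reference-channel tails and partitions the remaining events
#' into bins, either with equal event counts (the peak-finder default: ten
#' bins between the 2.5 and 97.5 percentiles) or with equal width in log10
#' signal (the copy-number analytics default).
#'
#' @param frame a \code{\link{PopulationFrame}}.
#' @param nBins number of bins.
#' @param tailFraction fraction discarded from each side.
#' @param channel reference channel; defaults to the frame's metadata.
#' @param method \code{"count"} (equal events) or \code{"width"} (equal
#'   log10 width).
#' @param edges optional preset linear-scale edges (overrides everything
#'   else); used to apply one partition to another data set.
#' @return a \code{\link{BinPartition}}.
#' @export
binByReference <- function(frame, nBins = 10L, tailFraction = 0.025,
                           channel = NULL, method = c("count", "width"),
                           edges = NULL) {
  stopifnot(is(frame, "PopulationFrame"))
  method <- match.arg(method)
  if (is.null(channel)) channel <- frame@metadata$referenceChannel
  if (is.null(channel)) stop("no reference channel given", call. = FALSE)
  v <- channelValues(frame, channel)
  if (is.null(edges)) {
    if (length(v) < nBins) stop("fewer events than bins", call. = FALSE)
    if (method == "count") {
      probs <- seq(tailFraction, 1 - tailFraction, length.out = nBins + 1L)
      edges <- unname(quantile(v, probs, type = 7))
      ## guard against ties in very discrete data
      edges <- edges + seq(0, 1e-9, length.out = nBins + 1L)
    } else {
      lim <- quantile(v[v > 0], c(tailFraction, 1 - tailFraction))
      edges <- 10^seq(log10(lim[[1]]), log10(lim[[2]]),
                      length.out = nBins + 1L)
    }
  } else nBins <- length(edges) - 1L
  assignment <- findInterval(v, edges, rightmost.closed = TRUE)
  assignment[assignment < 1L | assignment > nBins] <- NA_integer_
  medianY <- vapply(seq_len(nBins), function(b) {
    vb <- v[which(assignment == b)]
    if (length(vb)) median(safeLog(vb)) else NA_real_
  }, numeric(1))
  new("BinPartition", channel = channel, edges = as.numeric(edges),
      assignment = as.integer(assignment), medianY = medianY,
      meanO = mean(v), method = method, tailFraction = tailFraction)
}

## ---------------------------------------------------------------------------
## Gaussian-mixture histogram fitting
## ---------------------------------------------------------------------------

## histogram of display values at fixed bin width
.modeHistogram <- function(x, binWidth) {
  rng <- range(x)
  lo <- floor(rng[1] / binWidth) * binWidth - binWidth
  hi <- ceiling(rng[2] / binWidth) * binWidth + binWidth
  brk <- seq(lo, hi, by = binWidth)
  h <- graphics::hist(x, breaks = brk, plot = FALSE)
  list(mids = h$mids, density = h$density)
}

## local maxima of a lightly smoothed histogram, strongest first
.histPeaks <- function(mids, dens) {
  n <- length(dens)
  if (n < 3L) return(mids[which.max(dens)])
  s <- (c(dens[1], dens[-n]) + dens + c(dens[-1], dens[n])) / 3
  isMax <- s >= c(-Inf, s[-n]) & s > c(s[-1], -Inf)
  pk <- which(isMax & s > 0.02 * max(s))
  if (!length(pk)) pk <- which.max(s)
  pk <- pk[order(s[pk], decreasing = TRUE)]
  mids[pk]
}

## least-squares fit of a k-component Gaussian mixture to a density
## histogram; returns component means/sds/amplitudes and R^2
.fitMixture <- function(mids, dens, k) {
  ybar <- mean(dens)
  sst <- sum((dens - ybar)^2)
  if (sst <= 0) return(NULL)
  bw <- mids[2] - mids[1]
  peaks <- .histPeaks(mids, dens)
  init <- peaks[seq_len(min(k, length(peaks)))]
  if (length(init) < k) {
    extra <- quantile(rep(mids, pmax(1, round(dens / max(dens) * 20))),
                      probs = seq(0.2, 0.8, length.out = k))
    init <- c(init, extra[seq_len(k - length(init))])
  }
  s0 <- max(3 * bw, diff(range(mids)) / (6 * k))
  a0 <- rep(max(dens), k)
  par0 <- c(a0, init, rep(log(s0), k))
  lower <- c(rep(0, k), rep(min(mids), k), rep(log(bw), k))
  upper <- c(rep(4 * max(dens), k), rep(max(mids), k),
             rep(log(diff(range(mids))), k))
  sse <- function(par) {
    A <- par[1:k]; mu <- par[(k + 1):(2 * k)]; s <- exp(par[(2 * k + 1):(3 * k)])
    yhat <- rep(0, length(mids))
    for (j in seq_len(k))
      yhat <- yhat + A[j] * exp(-(mids - mu[j])^2 / (2 * s[j]^2))
    sum((dens - yhat)^2)
  }
  fit <- tryCatch(
    optim(par0, sse, method = "L-BFGS-B", lower = lower, upper = upper,
          control = list(maxit = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  A <- fit$par[1:k]; mu <- fit$par[(k + 1):(2 * k)]
  s <- exp(fit$par[(2 * k + 1):(3 * k)])
  ord <- order(mu)
  list(A = A[ord], mu = mu[ord], sigma = s[ord],
       r2 = 1 - fit$value / sst)
}

## hill-climb from a start position to the local maximum of the lightly
## smoothed histogram: least-squares component means can be displaced into
## the tail of a skewed cluster, while the reported mode must sit on the
## density peak itself
.climbPeak <- function(mids, dens, start) {
  n <- length(dens)
  if (n < 3L) return(start)
  s <- (c(dens[1], dens[-n]) + dens + c(dens[-1], dens[n])) / 3
  i <- which.min(abs(mids - start))
  repeat {
    if (i > 1L && s[i - 1L] > s[i]) i <- i - 1L
    else if (i < n && s[i + 1L] > s[i]) i <- i + 1L
    else break
  }
  ## quadratic interpolation around the peak bin
  if (i > 1L && i < n) {
    d <- (s[i - 1L] - s[i + 1L]) / (2 * (s[i - 1L] - 2 * s[i] + s[i + 1L]))
    if (is.finite(d) && abs(d) <= 0.5)
      return(mids[i] + d * (mids[2] - mids[1]))
  }
  mids[i]
}

## weight = events within +-window of each mode
.modeWeights <- function(x, modes, window) {
  vapply(modes, function(m) sum(abs(x - m) <= window), numeric(1))
}

.modeResult <- function(x, modes, window) {
  modes <- sort(modes)
  w <- .modeWeights(x, modes, window)
  branch <- if (length(modes) == 2L) c("LOW", "HIGH") else "HIGH"
  data.frame(mode = modes, weight = w, branch = branch)
}

#' Rule-based multimodal Gaussian mode finder
#'
#' Approximates a display-transformed channel distribution by a fixed-width
#' histogram and fits Gaussian mixtures (1--3 components) by least squares,
#' walking the decision tree of the peak finder: a single Gaussian is
#' accepted at R-squared above \code{gof1}; otherwise two Gaussians at
#' \code{gof2}; otherwise three components are fitted and reconciled back to
#' at most two modes.  For input-role rules the reconciliation collapses
#' pairs closer than 0.42 back to the two-Gaussian fit and applies the
#' 0.3 closest-pair merge rule; for output-role rules the two
#' highest-intensity peaks closer than 0.9 trigger removal of the remaining
#' peak and a refit.  In either role a final two-mode result closer than
#' 0.75 collapses to the single-Gaussian mode.
#'
#' @param values display-transformed channel values.
#' @param rules an \code{\link{inputFitRules}} or \code{\link{outputFitRules}}
#'   rule set.
#' @return data.frame with columns \code{mode}, \code{weight} (events within
#'   the mode window) and \code{branch} (\code{HIGH}/\code{LOW}); zero rows
#'   if no fit is possible.
#' @export
fitModes <- function(values, rules = inputFitRules()) {
  stopifnot(is(rules, "FitRuleSet"))
  x <- values[is.finite(values)]
  if (length(x) < rules@minEvents) {
    warning("fewer than ", rules@minEvents, " events; no fit", call. = FALSE)
    return(data.frame(mode = numeric(0), weight = numeric(0),
                      branch = character(0)))
  }
  win <- rules@modeWindow
  if (diff(range(x)) < 3 * rules@binWidth)
    return(.modeResult(x, median(x), win))
  h <- .modeHistogram(x, rules@binWidth)
  f1 <- .fitMixture(h$mids, h$density, 1L)
  if (is.null(f1)) return(.modeResult(x, median(x), win))
  if (f1$r2 > rules@gof1) return(.modeResult(x, f1$mu, win))
  f2 <- .fitMixture(h$mids, h$density, 2L)
  modes2 <- if (!is.null(f2)) f2$mu else f1$mu
  if (!is.null(f2) && f2$r2 > rules@gof2) {
    modes <- f2$mu
  } else {
    f3 <- .fitMixture(h$mids, h$density, 3L)
    if (is.null(f3)) {
      modes <- modes2
    } else if (rules@role == "input") {
      dists <- abs(diff(f3$mu))
      if (min(dists) < rules@collapseClose) {
        modes <- modes2
      } else {
        ## closest pair of the three modes; if its mean lies near a
        ## two-Gaussian mode, keep that mode plus the remaining third
        pair <- if (dists[1] <= dists[2]) c(1L, 2L) else c(2L, 3L)
        other <- setdiff(1:3, pair)
        pairMean <- mean(f3$mu[pair])
        dNear <- abs(modes2 - pairMean)
        if (min(dNear) < rules@mergeNear) {
          modes <- c(modes2[which.min(dNear)], f3$mu[other])
        } else {
          ## no rule applies: keep the two strongest components so the
          ## result respects the <=2 input-mode contract
          keep <- order(f3$A, decreasing = TRUE)[1:2]
          modes <- f3$mu[keep]
        }
      }
    } else {
      ## output role: look at the two highest-intensity (rightmost) peaks
      hi <- order(f3$mu, decreasing = TRUE)[1:2]
      lo <- setdiff(order(f3$mu, decreasing = TRUE), hi)
      if (abs(diff(f3$mu[hi])) < rules@pairHigh) {
        ## remove the remaining peak from the data and refit one Gaussian
        ## to the high region
        cut <- mean(c(f3$mu[lo], min(f3$mu[hi])))
        xa <- x[x > cut]
        refit <- if (length(xa) >= rules@minEvents / 4) {
          ha <- .modeHistogram(xa, rules@binWidth)
          .fitMixture(ha$mids, ha$density, 1L)
        } else NULL
        if (!is.null(refit) && !is.null(f2) && refit$r2 >= f2$r2) {
          modes <- c(f3$mu[lo], refit$mu)
        } else {
          modes <- modes2
        }
      } else {
        keep <- order(f3$A, decreasing = TRUE)[1:2]
        modes <- f3$mu[keep]
      }
    }
  }
  modes <- sort(modes)
  if (length(modes) == 2L && diff(modes) < rules@collapseFinal)
    modes <- f1$mu
  ## pin each mode to the density peak its component describes
  modes <- vapply(modes, function(m) .climbPeak(h$mids, h$density, m),
                  numeric(1))
  modes <- unique(sort(modes))
  .modeResult(x, modes, win)
}

#' Empirical mode of a latent (copy-number) distribution
#'
#' Single-Gaussian least-squares fit to the value histogram, falling back to
#' the smoothed-histogram argmax when the fit fails or explains the
#' histogram poorly.
#'
#' @param x numeric values (for instance latent gene copy numbers in a
#'   mode-window slice).
#' @param nbins histogram bins; the default adapts to the sample size with
#'   a Freedman-Diaconis bin width (bounded to 12--64 bins) so that sparse
#'   slices do not produce jittery mode estimates.
#' @return numeric mode location.
#' @export
distributionMode <- function(x, nbins = NULL) {
  x <- x[is.finite(x)]
  if (!length(x)) return(NA_real_)
  if (length(unique(x)) == 1L) return(x[1])
  if (is.null(nbins)) {
    fd <- 2 * stats::IQR(x) / length(x)^(1 / 3)
    nbins <- if (fd > 0) max(12L, min(64L, ceiling(diff(range(x)) / fd)))
             else 12L
  }
  bw <- diff(range(x)) / nbins
  if (bw <= 0) return(median(x))
  h <- .modeHistogram(x, bw)
  f <- .fitMixture(h$mids, h$density, 1L)
  if (!is.null(f) && f$r2 > 0.5 &&
      f$mu >= min(h$mids) && f$mu <= max(h$mids)) return(f$mu)
  ## smoothed argmax fallback
  pk <- .histPeaks(h$mids, h$density)
  pk[1]
}

#' Slice a mode window out of a population
#'
#' Rows whose transformed channel value lies within
#' \code{center +- halfwidth}.  The transform must match the units of the
#' center (biexponential display for peak-finder windows, log10 for
#' copy-number windows).
#'
#' @param frame a \code{\link{PopulationFrame}}.
#' @param channel channel name.
#' @param center window center (transformed units).
#' @param halfwidth window half-width.
#' @param transform function applied to the raw channel values.
#' @return the sliced \code{\link{PopulationFrame}} (possibly zero rows).
#' @export
sliceWindow <- function(frame, channel, center, halfwidth,
                        transform = function(v) biexpTransform(v)) {
  stopifnot(is(frame, "PopulationFrame"))
  if (!is.finite(center)) stop("center must be finite", call. = FALSE)
  v <- transform(channelValues(frame, channel))
  frame[which(abs(v - center) <= halfwidth)]
}

#' Extract input/output mode points from a Dox series
#'
#' The full peak-finder pass: for every reference bin and Dox level, fit the
#' input-channel modes within the bin (biexponential display space); slice
#' the mode window around each input mode; fit the output-channel modes in
#' the slice; and emit up to four [input; output] mode pairs per bin, Dox
#' level and output channel.  High- and low-branch points pooled across Dox
#' levels form the circuit's input/output curves.
#'
#' @param framesByDox list of \code{\link{PopulationFrame}}s, one per Dox
#'   level (as returned by \code{\link{simulateTransientCircuit}}).
#' @param inputChannel,outputChannels channel roles.
#' @param nBins,tailFraction reference binning (defaults 10 bins, 2.5%).
#' @param inputRules,outputRules fit rule sets.
#' @param params biexponential display parameters.
#' @param referenceChannel reference channel; defaults to frame metadata.
#' @param edges optional preset bin edges (linear scale).
#' @return data.frame with columns bin, dox, channel, inputBranch,
#'   inputMode, outputBranch, outputMode, weight (all mode coordinates in
#'   display units).
#' @export
extractIOPoints <- function(framesByDox, inputChannel = "mCherry",
                            outputChannels = c("Cerulean", "Citrine"),
                            nBins = 10L, tailFraction = 0.025,
                            inputRules = inputFitRules(),
                            outputRules = outputFitRules(),
                            params = biexpParams(),
                            referenceChannel = NULL, edges = NULL) {
  stopifnot(length(framesByDox) >= 1L)
  if (is.null(referenceChannel))
    referenceChannel <- framesByDox[[1]]@metadata$referenceChannel
  ## one partition shared across Dox levels: the reference is
  ## Dox-independent, so pooled quantiles define comparable bins
  if (is.null(edges)) {
    pooledRef <- unlist(lapply(framesByDox, channelValues, referenceChannel))
    probs <- seq(tailFraction, 1 - tailFraction, length.out = nBins + 1L)
    edges <- unname(quantile(pooledRef, probs, type = 7))
  }
  nBins <- length(edges) - 1L
  tx <- function(v) biexpTransform(v, params)
  out <- list()
  for (l in seq_along(framesByDox)) {
    fr <- framesByDox[[l]]
    dox <- fr@metadata$dox
    if (is.null(dox)) dox <- l
    ref <- channelValues(fr, referenceChannel)
    bin <- findInterval(ref, edges, rightmost.closed = TRUE)
    for (b in seq_len(nBins)) {
      sub <- fr[which(bin == b)]
      if (nCells(sub) < inputRules@minEvents) next
      xin <- tx(channelValues(sub, inputChannel))
      mi <- suppressWarnings(fitModes(xin, inputRules))
      if (!nrow(mi)) next
      for (ii in seq_len(nrow(mi))) {
        slice <- sub[which(abs(xin - mi$mode[ii]) <= inputRules@modeWindow)]
        if (nCells(slice) < outputRules@minEvents) next
        for (ch in outputChannels) {
          xout <- tx(channelValues(slice, ch))
          mo <- suppressWarnings(fitModes(xout, outputRules))
          if (!nrow(mo)) next
          out[[length(out) + 1L]] <- data.frame(
            bin = b, dox = dox, channel = ch,
            inputBranch = mi$branch[ii], inputMode = mi$mode[ii],
            outputBranch = mo$branch, outputMode = mo$mode,
            weight = mo$weight)
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(bin = integer(0), dox = numeric(0),
                      channel = character(0), inputBranch = character(0),
                      inputMode = numeric(0), outputBranch = character(0),
                      outputMode = numeric(0), weight = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
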