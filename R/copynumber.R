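## Copy-number analytics: anticipated vs empirical copy-number modes,
## conditional noise sigma*, and the bimodality divergence metrics.

#' Anticipated copy number from the reference signal
#'
#' The naive copy-number estimate from the observed log reference level and
#' the global proportionality coefficient:
#' \eqn{k_i^* = \exp(Y_1)/\beta_1 \cdot a_i}.
#'
#' @param Y1 log (natural) reference protein level(s).
#' @param beta1 reference proportionality coefficient (> 0).
#' @param a abundance coefficient(s) of the gene(s).
#' @return anticipated copy number(s).
#' @examples
#' anticipatedCopyNumber(log(10 * 1000), beta1 = 1000)        # 10
#' anticipatedCopyNumber(log(10 * 1000), 1000, a = 1.3)       # 13
#' @export
anticipatedCopyNumber <- function(Y1, beta1, a = 1) {
  if (any(!is.finite(beta1)) || any(beta1 <= 0))
    stop("beta1 must be > 0", call. = FALSE)
  exp(Y1) / beta1 * a
}

## sequential mode-window slicing over channels in log10 space; returns the
## final row index set (indices into `frame`)
.sequentialSlice <- function(frame, channels, halfwidth = 0.15,
                            rules = inputFitRules(minEvents = 200)) {
  idx <- seq_len(nCells(frame))
  d <- cells(frame)
  for (ch in channels) {
    if (length(idx) < rules@minEvents) break
    y <- safeLog(d[[ch]][idx], base = "10")
    mi <- suppressWarnings(fitModes(y, rules))
    if (!nrow(mi)) break
    m0 <- mi$mode[which.max(mi$weight)]
    keep <- which(abs(y - m0) <= halfwidth)
    if (!length(keep)) break
    idx <- idx[keep]
  }
  idx
}

#' Empirical copy-number modes per reference bin
#'
#' For each bin: the expression modes of the non-reference channels are
#' located sequentially (Gaussian fits in log10 space, slicing a +-0.15
#' log10 window around the primary mode of each channel in turn); the gene
#' copy numbers of the cells in the final slice are looked up and the mode
#' of each gene's copy-number distribution is taken.  Requires a simulated
#' frame carrying latent \code{k} columns.
#'
#' @param frame a simulated \code{\link{PopulationFrame}}.
#' @param bins a \code{\link{BinPartition}}.
#' @param channelOrder channels sliced in order (default: all non-reference
#'   channels of the frame).
#' @param halfwidth slice half-width in log10 units.
#' @param minCells sparse slices are skipped with a warning.
#' @return data.frame with one row per bin: \code{bin}, \code{medianY1},
#'   \code{nCells}, and \code{kMode.<gene>} columns.
#' @export
empiricalCopyModes <- function(frame, bins, channelOrder = NULL,
                               halfwidth = 0.15, minCells = 200L) {
  stopifnot(is(frame, "PopulationFrame"), is(bins, "BinPartition"))
  kCols <- grep("^k[0-9]+$", latentNames(frame), value = TRUE)
  if (!length(kCols))
    stop("frame carries no latent copy-number columns", call. = FALSE)
  if (is.null(channelOrder))
    channelOrder <- setdiff(channelNames(frame),
                            c(bins@channel, "rtTADox"))
  d <- cells(frame)
  rows <- list()
  for (b in seq_len(nBins(bins))) {
    sub <- frame[which(bins@assignment == b)]
    if (nCells(sub) < minCells) {
      warning("bin ", b, " too sparse; skipped", call. = FALSE)
      next
    }
    idx <- .sequentialSlice(sub, channelOrder, halfwidth)
    if (length(idx) < minCells) {
      warning("final slice of bin ", b, " too sparse; skipped",
              call. = FALSE)
      next
    }
    ds <- cells(sub)[idx, , drop = FALSE]
    km <- vapply(kCols, function(cc) distributionMode(ds[[cc]]), numeric(1))
    row <- data.frame(bin = b, medianY1 = bins@medianY[b],
                      nCells = length(idx))
    row[paste0("kMode.", kCols)] <- as.list(km)
    rows[[length(rows) + 1L]] <- row
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Conditional log-space noise per reference bin
#'
#' The standard deviation of the log-transformed channel within each
#' reference bin (\eqn{\sigma^* = \sigma_{Y_i | Y_1}}); always at least the
#' intrinsic noise sigma for a copy-number-dispersed population.
#'
#' @param frame a \code{\link{PopulationFrame}}.
#' @param bins a \code{\link{BinPartition}}.
#' @param channel channel name.
#' @return numeric vector, one sigma* per bin.
#' @export
conditionalSigma <- function(frame, bins, channel) {
  stopifnot(is(frame, "PopulationFrame"), is(bins, "BinPartition"))
  v <- channelValues(frame, channel)
  vapply(seq_len(nBins(bins)), function(b) {
    vb <- v[which(bins@assignment == b)]
    if (length(vb) < 2L) return(NA_real_)
    sd(safeLog(vb))
  }, numeric(1))
}

#' Branch-resolved copy-number modes for a (possibly bimodal) circuit bin
#'
#' Circuit variant of \code{\link{empiricalCopyModes}}: per bin, the input
#' channel is sliced on its primary mode; the output channel's modes (up to
#' two) are then located, and for each output branch the cells in the
#' +-0.15 log10 window around the branch mode are collected and every
#' gene's copy-number mode is taken.
#'
#' @param frame a simulated circuit \code{\link{PopulationFrame}} (single
#'   Dox level).
#' @param bins a \code{\link{BinPartition}}.
#' @param inputChannel,outputChannel channel roles.
#' @param halfwidth slice half-width (log10 units).
#' @param minCells sparse slices are skipped.
#' @return data.frame with columns bin, medianY1, channel, branch
#'   (HIGH/LOW), outputMode (log10), nCells, and kMode.<gene> columns.
#' @export
branchCopyModes <- function(frame, bins, inputChannel = "mCherry",
                            outputChannel = "Cerulean", halfwidth = 0.15,
                            minCells = 200L) {
  stopifnot(is(frame, "PopulationFrame"), is(bins, "BinPartition"))
  kCols <- grep("^k[0-9]+$", latentNames(frame), value = TRUE)
  if (!length(kCols))
    stop("frame carries no latent copy-number columns", call. = FALSE)
  inRules <- inputFitRules(minEvents = max(50, minCells))
  outRules <- outputFitRules(minEvents = max(50, minCells))
  rows <- list()
  for (b in seq_len(nBins(bins))) {
    sub <- frame[which(bins@assignment == b)]
    if (nCells(sub) < inRules@minEvents) next
    yin <- safeLog(channelValues(sub, inputChannel), base = "10")
    mi <- suppressWarnings(fitModes(yin, inRules))
    if (!nrow(mi)) next
    m0 <- mi$mode[which.max(mi$weight)]
    slice <- sub[which(abs(yin - m0) <= halfwidth)]
    if (nCells(slice) < outRules@minEvents) next
    yout <- safeLog(channelValues(slice, outputChannel), base = "10")
    mo <- suppressWarnings(fitModes(yout, outRules))
    if (!nrow(mo)) next
    for (jj in seq_len(nrow(mo))) {
      final <- slice[which(abs(yout - mo$mode[jj]) <= halfwidth)]
      if (nCells(final) < minCells) next
      df <- cells(final)
      km <- vapply(kCols, function(cc) distributionMode(df[[cc]]),
                   numeric(1))
      row <- data.frame(bin = b, medianY1 = bins@medianY[b],
                        channel = outputChannel, branch = mo$branch[jj],
                        outputMode = mo$mode[jj], nCells = nCells(final))
      row[paste0("kMode.", kCols)] <- as.list(km)
      rows[[length(rows) + 1L]] <- row
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Copy-number divergence metrics between output branches
#'
#' For every bin of a branch-resolved copy-mode table, computes the two
#' bimodality divergence metrics: the branch difference of copy-number
#' modes normalised by the constitutive-run reference mode,
#' \eqn{\Delta\tilde k_i = (k_i^{MODE,HIGH} - k_i^{MODE,LOW})/\hat k_1^{MODE}},
#' and the difference of within-branch copy-number ratios,
#' \eqn{\Delta\phi_i = k_i^{MODE,HIGH}/k_1^{MODE,HIGH} -
#' k_i^{MODE,LOW}/k_1^{MODE,LOW}}.  Both are zero wherever the branches
#' coincide (monomodal bins).
#'
#' @param branchModes output of \code{\link{branchCopyModes}}.
#' @param constitutiveFrame matched constitutive co-transfection
#'   \code{\link{PopulationFrame}} (same global parameters) supplying the
#'   reference copy-number mode \eqn{\hat k_1^{MODE}} per bin.
#' @param bins the \code{\link{BinPartition}} used for \code{branchModes};
#'   its edges are applied to the constitutive frame.
#' @return data.frame with one row per (bin, gene): bin, medianY1, gene,
#'   deltaKtilde, deltaPhi, kHat1.
#' @export
divergenceMetrics <- function(branchModes, constitutiveFrame, bins) {
  stopifnot(is(constitutiveFrame, "PopulationFrame"), is(bins, "BinPartition"))
  if (is.null(branchModes) || !nrow(branchModes))
    stop("no branch modes supplied", call. = FALSE)
  kCols <- grep("^kMode\\.k[0-9]+$", names(branchModes), value = TRUE)
  genes <- sub("^kMode\\.", "", kCols)
  ## reference copy mode per bin from the constitutive run, on the same
  ## reference edges
  cbins <- binByReference(constitutiveFrame, edges = bins@edges)
  ck1 <- cells(constitutiveFrame)[["k1"]]
  if (is.null(ck1))
    stop("constitutive frame carries no latent k1 column", call. = FALSE)
  kHat1 <- vapply(seq_len(nBins(bins)), function(b) {
    v <- ck1[which(cbins@assignment == b)]
    if (length(v) < 20L) return(NA_real_)
    distributionMode(v)
  }, numeric(1))
  rows <- list()
  for (b in sort(unique(branchModes$bin))) {
    sub <- branchModes[branchModes$bin == b, , drop = FALSE]
    hi <- sub[sub$branch == "HIGH", , drop = FALSE]
    lo <- sub[sub$branch == "LOW", , drop = FALSE]
    for (gi in seq_along(genes)) {
      if (nrow(hi) && nrow(lo)) {
        kH <- hi[[kCols[gi]]][1]; kL <- lo[[kCols[gi]]][1]
        k1H <- hi[["kMode.k1"]][1]; k1L <- lo[["kMode.k1"]][1]
        dkt <- (kH - kL) / kHat1[b]
        dph <- kH / k1H - kL / k1L
      } else {
        dkt <- 0; dph <- 0
      }
      rows[[length(rows) + 1L]] <- data.frame(
        bin = b, medianY1 = sub$medianY1[1], gene = genes[gi],
        deltaKtilde = dkt, deltaPhi = dph, kHat1 = kHat1[b])
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Ratio of empirical to anticipated copy-number modes per bin
#'
#' Convenience wrapper joining \code{\link{empiricalCopyModes}} with the
#' anticipated copy numbers \eqn{k_i^*(Y_1)}: the returned ratios are the
#' central diagnostic of the copy-number analysis (positive deviation below
#' the global reference mean, zero at the mean, negative above).
#'
#' @param frame constitutive \code{\link{PopulationFrame}}.
#' @param bins a \code{\link{BinPartition}} (equal-width log10 bins are the
#'   analytics default).
#' @param beta1 reference proportionality coefficient; defaults to the
#'   frame metadata.
#' @param abundances gene abundances; default from metadata.
#' @param ... passed to \code{\link{empiricalCopyModes}}.
#' @return data.frame with per-bin ratios \code{ratio.<gene>}, plus the
#'   index of the bin containing the global reference mean as attribute
#'   \code{"meanBin"}.
#' @export
copyModeRatios <- function(frame, bins, beta1 = NULL, abundances = NULL,
                           ...) {
  md <- frame@metadata
  if (is.null(beta1)) beta1 <- if (!is.null(md$beta1)) md$beta1 else md$beta[1]
  if (is.null(abundances)) abundances <- md$abundances
  if (is.null(beta1) || is.null(abundances))
    stop("beta1 and abundances must be given or present in metadata",
         call. = FALSE)
  em <- empiricalCopyModes(frame, bins, ...)
  kCols <- grep("^kMode\\.", names(em), value = TRUE)
  genes <- as.integer(sub("^kMode\\.k", "", kCols))
  for (gi in seq_along(kCols)) {
    kStar <- anticipatedCopyNumber(em$medianY1, beta1, abundances[genes[gi]])
    em[paste0("ratio.k", genes[gi])] <- em[[kCols[gi]]] / kStar
  }
  ## bin whose linear edges bracket the global arithmetic mean of O1
  meanBin <- findInterval(bins@meanO, bins@edges, rightmost.closed = TRUE)
  attr(em, "meanBin") <- meanBin
  em
}
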