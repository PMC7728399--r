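## Log and biexponential (display-scale) transforms.  All peak-finder
## thresholds (0.42, 0.75, 0.9, +-0.1) are distances in biexponential display
## units; copy-number analysis windows (+-0.15) are log10 units.

#' Biexponential display-scale parameters
#'
#' The display scale spans \code{M} decades; \code{W} is the linearization
#' width around zero and \code{T} the top-of-scale signal.  Defaults follow
#' the standard cytometry parameterisation \code{M = 4.5}, \code{p = 2},
#' \code{T = 262144}, \code{W = 0.401}.
#'
#' @param M decades spanned by the display axis.
#' @param p width parameter of the quasi-linear region.
#' @param T top-of-scale signal value.
#' @param W linearization width (display units), \code{0 <= W < M}.
#' @return a named list of parameters.
#' @export
biexpParams <- function(M = 4.5, p = 2, T = 262144, W = 0.401) {
  stopifnot(T > 0, M > 0, p >= 1, W >= 0, W < M)
  list(M = M, p = p, T = T, W = W)
}

## core positive branch: delta = X - W >= 0
.biexpS <- function(delta, pr) {
  pr$T * 10^(-(pr$M - pr$W)) *
    (10^delta - pr$p^2 * 10^(-delta / pr$p) + pr$p^2 - 1)
}

.biexpSderiv <- function(delta, pr) {
  pr$T * 10^(-(pr$M - pr$W)) * log(10) * (10^delta + pr$p * 10^(-delta / pr$p))
}

#' Biexponential display-to-signal transform
#'
#' Maps a display coordinate \code{x} (in units where the non-negative data
#' range spans \code{[0, M]}) to the raw signal value.  The function is
#' odd-symmetric about \code{x = W} (negative signals map below \code{W}),
#' strictly increasing, and satisfies \code{biexpInverse(W) == 0} and
#' \code{biexpInverse(M) ~ T}.
#'
#' @param x display coordinates.
#' @param params parameters from \code{\link{biexpParams}}.
#' @return raw signal values.
#' @export
biexpInverse <- function(x, params = biexpParams()) {
  d <- x - params$W
  sgn <- ifelse(d >= 0, 1, -1)
  sgn * .biexpS(abs(d), params)
}

#' Signal-to-display (forward) biexponential transform
#'
#' Numerical inverse of \code{\link{biexpInverse}}: monotone interpolation on
#' a dense display grid followed by Newton polishing, giving a round trip
#' accurate to better than 1e-6 relative.
#'
#' @param v raw signal values (any sign).
#' @param params parameters from \code{\link{biexpParams}}.
#' @return display coordinates.
#' @export
biexpTransform <- function(v, params = biexpParams()) {
  ## dense monotone grid covering well beyond [ -T, T ]
  lo <- params$W - (params$M + 1)
  hi <- params$M + 1
  xg <- seq(lo, hi, length.out = 4096L)
  sg <- biexpInverse(xg, params)
  x <- approx(sg, xg, xout = pmin(pmax(v, sg[1]), sg[length(sg)]),
              ties = "ordered")$y
  ## Newton polish (derivative is even about W)
  for (it in 1:3) {
    f <- biexpInverse(x, params) - v
    df <- .biexpSderiv(abs(x - params$W), params)
    x <- x - f / df
  }
  x
}

#' Floored logarithm
#'
#' Log transform with a positive floor: values below \code{floor} are
#' clamped before taking the logarithm, and the clamp count is reported via
#' a message when \code{verbose} is set.  Order is preserved.
#'
#' @param values numeric vector.
#' @param base \code{"e"} (natural log, the modelling scale) or \code{"10"}.
#' @param floor positive clamp value.
#' @param verbose report the number of clamped values.
#' @return transformed vector.
#' @export
safeLog <- function(values, base = c("e", "10"), floor = 1e-3,
                    verbose = FALSE) {
  base <- match.arg(base)
  if (!is.finite(floor) || floor <= 0)
    stop("floor must be > 0", call. = FALSE)
  nClamped <- sum(values < floor, na.rm = TRUE)
  if (verbose && nClamped > 0)
    message("safeLog: clamped ", nClamped, " values below ", floor)
  v <- pmax(values, floor)
  if (base == "e") log(v) else log10(v)
}
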