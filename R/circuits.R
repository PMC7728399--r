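## Mass-action circuit models.  All seven topologies share one species map:
##   gene 1 (a=1.0): constitutive reference  ->  mRNA1 -> SBFP2
##   gene 5 (a=0.4): constitutive rtTA; rtTA + Dox <-> rtTA:Dox (readout)
##   gene 4 (a=0.5): TRE promoter activated by rtTA:Dox -> mRNA4 -> PIT2, mCherry
##   gene 2 (a=1.3): promoter P1 activated by PIT2 -> mRNA2 -> Cerulean, Kni
##   gene 3 (a=0.8): promoter P2 activated by PIT2 -> mRNA3 -> Citrine, LacI
## Promoter binding/unbinding is treated at quasi-equilibrium, giving
## Hill-form activities; mRNA and protein species are explicit.  Topologies
## differ only by nulled repressor translations ("in silico knockouts") and,
## for the extended motifs, by the promoter the repressor arm targets.

#' Supported circuit topologies
#' @return character vector of topology labels.
#' @export
circuitTopologies <- function() {
  c("FO", "RIFFM", "I1FFL1", "I1FFL2", "cFFL", "negFB", "posFB")
}

#' Names of the eight per-protein translation rates
#' @return character vector.
#' @export
translationNames <- function() {
  c("pi_sbfp2", "pi_rtta", "pi_pit2", "pi_mcherry",
    "pi_cerulean", "pi_kni", "pi_citrine", "pi_laci")
}

requiredCircuitRates <- function() {
  c("ktx1", "ktx2", "ktx3", "ktx4", "ktx5", "dm", "dp",
    "kon", "koff", "Kin", "nin", "bin0", "Kact", "nact", "bact",
    "Krep", "nrep", "bfb", translationNames())
}

#' Default circuit rate constants
#'
#' A documented parameter set, in molecules and seconds, chosen to give
#' biologically plausible expression levels (reference proportionality
#' coefficient \eqn{\beta_1 = 1000} proteins per gene copy) and to reproduce
#' the qualitative circuit behaviours: activation of both outputs for FO,
#' bimodal outputs for RIFFM across the bulk of the reference-intensity
#' range, and adaptive responses for the I1-FFLs.  Every value can be
#' overridden via the \code{overrides} argument or the run configuration.
#'
#' @param overrides named list of rate values replacing the defaults.
#' @return named list of rate constants.
#' @export
defaultCircuitParameters <- function(overrides = list()) {
  p <- list(
    ## transcription (mRNA per gene copy per s) and turnover
    ktx1 = 0.00288, ktx2 = 0.00288, ktx3 = 0.00288, ktx4 = 0.00288,
    ktx5 = 0.00288,
    dm = 2.88e-4,          # mRNA half-life ~40 min
    dp = 1e-4,             # protein half-life ~2 h
    ## Doxycycline binding to rtTA (Dox as a fixed molecule count)
    kon = 1e-6, koff = 1e-2,
    ## TRE activation by rtTA:Dox
    Kin = 1500, nin = 2, bin0 = 0.01,
    ## P1/P2 activation by PIT2
    Kact = 600, nact = 2, bact = 0.02,
    ## repression (and feedback activation) of P1/P2
    Krep = 150, nrep = 2, bfb = 0.1,
    ## translation rates (protein per mRNA per s); repressor rates are
    ## nearly balanced against the nominal gene abundances so the two RIFFM
    ## arms compete closely (a slight detuning keeps nominal-parameter cells
    ## off the separatrix) and copy-number/intrinsic noise decides the branch
    pi_sbfp2 = 0.01, pi_rtta = 0.01, pi_pit2 = 0.01, pi_mcherry = 0.01,
    pi_cerulean = 0.01, pi_kni = 0.004, pi_citrine = 0.01, pi_laci = 0.0064)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(p))
    if (length(unknown))
      stop("unknown circuit parameters: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    p[names(overrides)] <- overrides
  }
  p
}

#' Reference-gene proportionality coefficient implied by the rates
#'
#' \eqn{\beta_1 = (k_{tx,1}/\delta_m)(\pi_{SBFP2}/\delta_p)}: steady-state
#' reference protein molecules per gene copy in the cascade model.
#'
#' @param params circuit rate list.
#' @return numeric scalar.
#' @export
referenceBeta <- function(params = defaultCircuitParameters()) {
  (params$ktx1 / params$dm) * (params$pi_sbfp2 / params$dp)
}

#' Build a circuit specification
#'
#' Assembles the topology-specific spec from the shared reaction map.  FO
#' has both repressor translations nulled; RIFFM has both active (Kni
#' represses P2, LacI represses P1); each I1-FFL keeps exactly one.  The
#' extended motifs re-target the LacI/Kni arm: cFFL (Kni activates P2),
#' negFB (LacI represses its own promoter P2), posFB (LacI activates P2).
#'
#' @param topology one of \code{\link{circuitTopologies}}.
#' @param params full rate list; a missing rate raises a configuration
#'   error naming it.
#' @return a \code{\link{CircuitSpec}}.
#' @export
buildCircuit <- function(topology, params = defaultCircuitParameters()) {
  if (length(topology) != 1L || !topology %in% circuitTopologies())
    stop("unknown topology: ", paste(topology, collapse = ","), call. = FALSE)
  miss <- setdiff(requiredCircuitRates(), names(params))
  if (length(miss))
    stop("missing rate constants: ", paste(miss, collapse = ", "),
         call. = FALSE)
  arms <- switch(topology,
    FO     = list(kni = FALSE, laci = FALSE, kt = "none",  lt = "none"),
    RIFFM  = list(kni = TRUE,  laci = TRUE,  kt = "P2rep", lt = "P1rep"),
    I1FFL1 = list(kni = TRUE,  laci = FALSE, kt = "P2rep", lt = "none"),
    I1FFL2 = list(kni = FALSE, laci = TRUE,  kt = "none",  lt = "P1rep"),
    cFFL   = list(kni = TRUE,  laci = FALSE, kt = "P2act", lt = "none"),
    negFB  = list(kni = FALSE, laci = TRUE,  kt = "none",  lt = "P2rep"),
    posFB  = list(kni = FALSE, laci = TRUE,  kt = "none",  lt = "P2act"))
  new("CircuitSpec", topology = topology, params = params,
      kniActive = arms$kni, laciActive = arms$laci,
      kniTarget = arms$kt, laciTarget = arms$lt,
      readouts = c("SBFP2", "Cerulean", "Citrine", "mCherry", "rtTADox"))
}

#' Tabulate the reactions of a circuit specification
#'
#' Flat table of the reaction map (production, conversion, degradation and
#' binding reactions with their rate constants), with knocked-out
#' translations carried at rate 0 so that two topologies can be diffed
#' reaction by reaction.
#'
#' @param spec a \code{\link{CircuitSpec}}.
#' @return data.frame with columns reaction, rate.
#' @export
reactionTable <- function(spec) {
  p <- spec@params
  pk <- if (spec@kniActive) p$pi_kni else 0
  pl <- if (spec@laciActive) p$pi_laci else 0
  data.frame(
    reaction = c(
      "gene1 -> gene1 + mRNA1", "mRNA1 -> mRNA1 + SBFP2",
      "gene5 -> gene5 + mRNA5", "mRNA5 -> mRNA5 + rtTA",
      "rtTA + Dox -> rtTA:Dox", "rtTA:Dox -> rtTA + Dox",
      "gene4* -> gene4* + mRNA4", "mRNA4 -> mRNA4 + PIT2",
      "mRNA4 -> mRNA4 + mCherry",
      "gene2* -> gene2* + mRNA2", "mRNA2 -> mRNA2 + Cerulean",
      "mRNA2 -> mRNA2 + Kni",
      "gene3* -> gene3* + mRNA3", "mRNA3 -> mRNA3 + Citrine",
      "mRNA3 -> mRNA3 + LacI",
      "mRNA* -> 0", "protein* -> 0"),
    rate = c(p$ktx1, p$pi_sbfp2, p$ktx5, p$pi_rtta, p$kon, p$koff,
             p$ktx4, p$pi_pit2, p$pi_mcherry, p$ktx2, p$pi_cerulean, pk,
             p$ktx3, p$pi_citrine, pl, p$dm, p$dp))
}

## Hill activation helper
.hill <- function(x, K, n) {
  xn <- (x / K)^n
  xn / (1 + xn)
}

## promoter activities for a spec; Kni/LacI given as vectors
.promoterActivities <- function(spec, PIT2, Kni, LacI) {
  p <- spec@params
  A <- p$bact + (1 - p$bact) * .hill(PIT2, p$Kact, p$nact)
  g1 <- 1
  g2 <- 1
  if (spec@laciActive) {
    if (spec@laciTarget == "P1rep")
      g1 <- g1 / (1 + (LacI / p$Krep)^p$nrep)
    else if (spec@laciTarget == "P2rep")
      g2 <- g2 / (1 + (LacI / p$Krep)^p$nrep)
    else if (spec@laciTarget == "P2act")
      g2 <- g2 * (p$bfb + (1 - p$bfb) * .hill(LacI, p$Krep, p$nrep))
  }
  if (spec@kniActive) {
    if (spec@kniTarget == "P2rep")
      g2 <- g2 / (1 + (Kni / p$Krep)^p$nrep)
    else if (spec@kniTarget == "P2act")
      g2 <- g2 * (p$bfb + (1 - p$bfb) * .hill(Kni, p$Krep, p$nrep))
  }
  list(f1 = A * g1, f2 = A * g2)
}

## effective translation rates: knockouts are zeroed
.effectiveTranslation <- function(spec, pvec) {
  if (!spec@kniActive) pvec[["pi_kni"]] <- 0
  if (!spec@laciActive) pvec[["pi_laci"]] <- 0
  pvec
}

#' Simulate one cell of a circuit to steady state
#'
#' Integrates the full mass-action ODE system (five mRNAs, eight proteins
#' and Dox-bound rtTA) from zero initial protein/mRNA conditions with the
#' gene copies \code{k} as conserved quantities, to \code{tEnd} seconds
#' (default 1.5e6 s, the steady-state definition), and returns the five
#' readouts.  The right-hand-side norm at the end point is attached as
#' attribute \code{"rhsNorm"}; cells whose norm exceeds \code{ssTol} times
#' the state norm carry \code{converged = FALSE}.
#'
#' @param spec a \code{\link{CircuitSpec}}.
#' @param k copy-number vector (length 5, genes 1..5); all-zero copies give
#'   all-zero readouts.
#' @param p named per-cell translation rates (see
#'   \code{\link{translationNames}}); defaults to the spec's nominal rates.
#' @param dox Doxycycline molecule count.
#' @param tEnd integration horizon in seconds.
#' @param ssTol relative steady-state tolerance.
#' @return named numeric vector of the five readouts.
#' @export
simulateCell <- function(spec, k, p = NULL, dox, tEnd = 1.5e6,
                         ssTol = 1e-6) {
  stopifnot(is(spec, "CircuitSpec"))
  if (length(k) != 5L || any(!is.finite(k)) || any(k < 0))
    stop("k must be five non-negative copy numbers", call. = FALSE)
  prm <- spec@params
  if (is.null(p)) p <- unlist(prm[translationNames()])
  p <- .effectiveTranslation(spec, p[translationNames()])
  if (any(!is.finite(p)) || any(p < 0))
    stop("translation rates must be non-negative", call. = FALSE)

  derivs <- function(t, y, parms) {
    fin <- prm$bin0 + (1 - prm$bin0) * .hill(y["rtTAD"], prm$Kin, prm$nin)
    act <- .promoterActivities(spec, y["PIT2"], y["Kni"], y["LacI"])
    dy <- c(
      M1    = prm$ktx1 * k[1] - prm$dm * y["M1"],
      SBFP2 = p[["pi_sbfp2"]] * y["M1"] - prm$dp * y["SBFP2"],
      M5    = prm$ktx5 * k[5] - prm$dm * y["M5"],
      rtTA  = p[["pi_rtta"]] * y["M5"] - prm$dp * y["rtTA"] -
              prm$kon * dox * y["rtTA"] + prm$koff * y["rtTAD"],
      rtTAD = prm$kon * dox * y["rtTA"] - (prm$koff + prm$dp) * y["rtTAD"],
      M4    = prm$ktx4 * k[4] * fin - prm$dm * y["M4"],
      PIT2  = p[["pi_pit2"]] * y["M4"] - prm$dp * y["PIT2"],
      mCh   = p[["pi_mcherry"]] * y["M4"] - prm$dp * y["mCh"],
      M2    = prm$ktx2 * k[2] * act$f1 - prm$dm * y["M2"],
      Cer   = p[["pi_cerulean"]] * y["M2"] - prm$dp * y["Cer"],
      Kni   = p[["pi_kni"]] * y["M2"] - prm$dp * y["Kni"],
      M3    = prm$ktx3 * k[3] * act$f2 - prm$dm * y["M3"],
      Cit   = p[["pi_citrine"]] * y["M3"] - prm$dp * y["Cit"],
      LacI  = p[["pi_laci"]] * y["M3"] - prm$dp * y["LacI"])
    list(unname(dy))
  }
  y0 <- setNames(rep(0, 14), c("M1", "SBFP2", "M5", "rtTA", "rtTAD", "M4",
                               "PIT2", "mCh", "M2", "Cer", "Kni", "M3",
                               "Cit", "LacI"))
  sol <- deSolve::lsoda(y0, times = c(0, tEnd), func = derivs, parms = NULL,
                        rtol = 1e-8, atol = 1e-8)
  yEnd <- setNames(as.numeric(sol[2, -1]), names(y0))
  rhs <- derivs(tEnd, yEnd, NULL)[[1]]
  rhsNorm <- sqrt(sum(rhs^2))
  stateNorm <- sqrt(sum(yEnd^2))
  out <- c(SBFP2 = yEnd[["SBFP2"]], Cerulean = yEnd[["Cer"]],
           Citrine = yEnd[["Cit"]], mCherry = yEnd[["mCh"]],
           rtTADox = yEnd[["rtTAD"]])
  attr(out, "rhsNorm") <- rhsNorm
  attr(out, "converged") <- rhsNorm <= ssTol * max(stateNorm, 1)
  out
}

#' Vectorized steady-state solver for a circuit population
#'
#' Accelerated steady-state path for population runs: the linear subsystems
#' (reference cascade, rtTA/Dox binding, readout translations) are solved in
#' closed form; the nonlinear core (input branch and the two output
#' branches) is integrated with an exponential-Euler scheme on a geometric
#' time grid to the same 1.5e6 s horizon as the canonical ODE path, so that
#' multistable cells settle into the basin the dynamics select, followed by
#' damped fixed-point refinement to the attractor.  Agreement with
#' \code{\link{simulateCell}} is part of the test suite.
#'
#' @param spec a \code{\link{CircuitSpec}}.
#' @param K copy-number matrix, cells in rows, genes 1..5 in columns.
#' @param P translation-rate matrix, cells in rows, columns named as
#'   \code{\link{translationNames}}.
#' @param dox Doxycycline molecule count (scalar for the run).
#' @param tEnd integration horizon (s).
#' @param nSteps number of exponential-Euler steps.
#' @return matrix with columns SBFP2, Cerulean, Citrine, mCherry, rtTADox.
#' @export
circuitSteadyState <- function(spec, K, P, dox, tEnd = 1.5e6, nSteps = 220L) {
  stopifnot(is(spec, "CircuitSpec"))
  prm <- spec@params
  K <- as.matrix(K)
  P <- as.matrix(P)
  n <- nrow(K)
  stopifnot(ncol(K) == 5L, nrow(P) == n)
  cn <- colnames(P)
  pv <- function(nm) if (nm %in% cn) P[, nm] else rep(prm[[nm]], n)
  p_sb <- pv("pi_sbfp2"); p_rt <- pv("pi_rtta"); p_pi <- pv("pi_pit2")
  p_mc <- pv("pi_mcherry"); p_ce <- pv("pi_cerulean"); p_kn <- pv("pi_kni")
  p_ci <- pv("pi_citrine"); p_la <- pv("pi_laci")
  if (!spec@kniActive) p_kn <- rep(0, n)
  if (!spec@laciActive) p_la <- rep(0, n)

  dm <- prm$dm; dp <- prm$dp
  M5ss <- prm$ktx5 * K[, 5] / dm

  ## geometric time grid: fine early steps resolve the transient that
  ## selects the basin, capped steps carry the run to the horizon
  h0 <- 20; g <- 1.06; hmax <- 2.5e4
  hs <- pmin(h0 * g^(0:(nSteps - 1)), hmax)
  if (sum(hs) < tEnd)
    hs <- c(hs, rep(hmax, ceiling((tEnd - sum(hs)) / hmax)))
  hs <- hs[cumsum(hs) <= tEnd + hmax]

  z <- rep(0, n)
  rtTA <- z; rtTAD <- z; M4 <- z; PIT2 <- z; M2 <- z; M3 <- z
  Kni <- z; LacI <- z
  t <- 0
  dr <- dp + prm$kon * dox
  dd <- dp + prm$koff
  for (h in hs) {
    edm <- exp(-dm * h); edp <- exp(-dp * h)
    edr <- exp(-dr * h); edd <- exp(-dd * h)
    M5t <- M5ss * (1 - exp(-dm * t))
    fin <- prm$bin0 + (1 - prm$bin0) * .hill(rtTAD, prm$Kin, prm$nin)
    act <- .promoterActivities(spec, PIT2, Kni, LacI)
    prodRt <- p_rt * M5t + prm$koff * rtTAD
    prodRd <- prm$kon * dox * rtTA
    prodM4 <- prm$ktx4 * K[, 4] * fin
    prodPi <- p_pi * M4
    prodM2 <- prm$ktx2 * K[, 2] * act$f1
    prodM3 <- prm$ktx3 * K[, 3] * act$f2
    prodKn <- p_kn * M2
    prodLa <- p_la * M3
    rtTA <- rtTA * edr + (prodRt / dr) * (1 - edr)
    rtTAD <- rtTAD * edd + (prodRd / dd) * (1 - edd)
    M4 <- M4 * edm + (prodM4 / dm) * (1 - edm)
    PIT2 <- PIT2 * edp + (prodPi / dp) * (1 - edp)
    M2 <- M2 * edm + (prodM2 / dm) * (1 - edm)
    M3 <- M3 * edm + (prodM3 / dm) * (1 - edm)
    Kni <- Kni * edp + (prodKn / dp) * (1 - edp)
    LacI <- LacI * edp + (prodLa / dp) * (1 - edp)
    t <- t + h
  }

  ## closed-form linear stages at steady state
  Ttot <- p_rt * M5ss / dp
  q <- prm$kon * dox / (prm$koff + dp)
  rtTAD <- Ttot * q / (1 + q)
  fin <- prm$bin0 + (1 - prm$bin0) * .hill(rtTAD, prm$Kin, prm$nin)
  M4 <- prm$ktx4 * K[, 4] * fin / dm
  PIT2 <- p_pi * M4 / dp

  ## damped fixed-point refinement of the output-branch attractor
  c2 <- prm$ktx2 * K[, 2] / dm
  c3 <- prm$ktx3 * K[, 3] / dm
  for (it in 1:80) {
    act <- .promoterActivities(spec, PIT2, Kni, LacI)
    KniNew <- p_kn * c2 * act$f1 / dp
    LacNew <- p_la * c3 * act$f2 / dp
    dK <- max(abs(KniNew - Kni) / (1 + abs(Kni)),
              abs(LacNew - LacI) / (1 + abs(LacI)))
    Kni <- 0.5 * Kni + 0.5 * KniNew
    LacI <- 0.5 * LacI + 0.5 * LacNew
    if (dK < 1e-12) break
  }
  act <- .promoterActivities(spec, PIT2, Kni, LacI)
  M2 <- c2 * act$f1
  M3 <- c3 * act$f2

  cbind(SBFP2 = (prm$ktx1 * K[, 1] / dm) * p_sb / dp,
        Cerulean = p_ce * M2 / dp,
        Citrine = p_ci * M3 / dp,
        mCherry = p_mc * M4 / dp,
        rtTADox = rtTAD)
}

#' Default Doxycycline input grid
#'
#' Twelve logarithmically spaced molecule counts from 10 to 500,000.
#'
#' @param Z number of levels.
#' @param from,to grid end points (molecules).
#' @return strictly increasing numeric vector.
#' @export
doxGrid <- function(Z = 12L, from = 10, to = 5e5) {
  10^seq(log10(from), log10(to), length.out = Z)
}

## assemble a circuit PopulationFrame from latents and readouts
.circuitFrame <- function(spec, m, K, P, O, dox, sigma, epsilon, seed, kind) {
  d <- data.frame(cell = seq_len(nrow(K)), dox = dox, m = m, K, P, O,
                  check.names = FALSE)
  PopulationFrame(d, channels = colnames(O),
                  latents = c("m", colnames(K), colnames(P)),
                  metadata = list(kind = kind, topology = spec@topology,
                                  sigma = sigma, epsilon = epsilon,
                                  dox = dox, seed = seed,
                                  referenceChannel = "SBFP2",
                                  beta1 = referenceBeta(spec@params)))
}

#' Simulate transient transfection of a circuit across a Dox grid
#'
#' For every Dox level and cell: draw the multiplicity, the copy-number
#' vector and the eight per-protein translation rates (mean-preserving,
#' log-space sd sigma), then run the circuit to steady state.  The
#' constitutive reference gene (SBFP2) is Dox-independent by construction.
#'
#' @param spec a \code{\link{CircuitSpec}}.
#' @param mix a \code{\link{GeneMix}} (five genes).
#' @param multiplicity a \code{\link{MultiplicityModel}}.
#' @param sigma intrinsic noise level (log-space sd of translation rates).
#' @param dox Dox grid (molecule counts).
#' @param nCellsPerDox cells per Dox level.
#' @param seed integer seed.
#' @param noiseFamily \code{"lognormal"} or \code{"gamma"}.
#' @param method \code{"reduced"} (vectorized steady-state solver) or
#'   \code{"ode"} (per-cell integration; slow, for cross-checks).
#' @return named list of \code{\link{PopulationFrame}}s, one per Dox level.
#' @export
simulateTransientCircuit <- function(spec, mix = GeneMix(),
                                     multiplicity = MultiplicityModel(),
                                     sigma = 0.08, dox = doxGrid(),
                                     nCellsPerDox = 2e4, seed = 1,
                                     noiseFamily = "lognormal",
                                     method = c("reduced", "ode")) {
  stopifnot(is(spec, "CircuitSpec"), nGenes(mix) == 5L)
  method <- match.arg(method)
  nominal <- unlist(spec@params[translationNames()])
  nominal <- .effectiveTranslation(spec, nominal)
  noise <- NoiseModel(sigma = sigma, nominalMeans = nominal,
                      family = noiseFamily)
  frames <- vector("list", length(dox))
  names(frames) <- format(dox, trim = TRUE, scientific = FALSE, digits = 6)
  for (l in seq_along(dox)) {
    seedL <- subSeed(seed, 7919L * l)
    m <- sampleMultiplicity(multiplicity, nCellsPerDox, seedL)
    K <- sampleCopyNumbers(m, mix, seedL)
    P <- sampleExpressionScalars(noise, nCellsPerDox, seedL)
    O <- if (method == "reduced") {
      circuitSteadyState(spec, K, P, dox[l])
    } else {
      t(vapply(seq_len(nCellsPerDox), function(j)
        as.numeric(simulateCell(spec, K[j, ], P[j, ], dox[l])),
        numeric(5)))
    }
    colnames(O) <- spec@readouts
    frames[[l]] <- .circuitFrame(spec, m, K, P, O, dox[l], sigma,
                                 mix@epsilon, seedL, "circuit-transient")
  }
  frames
}

#' Derive stable-integration copy numbers from transient bins
#'
#' For each reference bin of a transient run, the design copy number of the
#' reference gene is the empirical mode of the latent \code{k1} distribution
#' in that bin; the other genes follow the nominal abundance ratios.
#'
#' @param frame a transient \code{\link{PopulationFrame}} carrying latent
#'   copy-number columns (pooling Dox levels is fine: the reference gene is
#'   Dox-independent).
#' @param bins a \code{\link{BinPartition}} of the same frame.
#' @param mix the \code{\link{GeneMix}} used for the run.
#' @param minCells bins with fewer cells are skipped with a warning.
#' @return list of \code{\link{StableDesign}} objects (one per usable bin).
#' @export
stableCopyNumbersFromBins <- function(frame, bins, mix, minCells = 50L) {
  stopifnot(is(frame, "PopulationFrame"), is(bins, "BinPartition"))
  if (!"k1" %in% latentNames(frame))
    stop("frame carries no latent copy-number columns", call. = FALSE)
  k1 <- cells(frame)[["k1"]]
  designs <- list()
  for (b in seq_len(nBins(bins))) {
    idx <- which(bins@assignment == b)
    if (length(idx) < minCells) {
      warning("bin ", b, " has fewer than ", minCells,
              " cells; skipped", call. = FALSE)
      next
    }
    k1mode <- distributionMode(k1[idx])
    designs[[length(designs) + 1L]] <-
      new("StableDesign", k = k1mode * mix@abundances, bin = b,
          y1 = bins@medianY[b])
  }
  designs
}

#' Simulate a stable-integration scenario
#'
#' Every cell shares the design's fixed copy-number vector; only the
#' translation rates vary (intrinsic noise).  At \code{sigma = 0} all cells
#' of a Dox level are identical and the input/output cloud collapses to a
#' curve.
#'
#' @param spec a \code{\link{CircuitSpec}}.
#' @param design a \code{\link{StableDesign}}.
#' @param sigma intrinsic noise level.
#' @param dox Dox grid.
#' @param nCellsPerDox cells per Dox level.
#' @param seed integer seed.
#' @param noiseFamily noise family.
#' @return named list of \code{\link{PopulationFrame}}s, one per Dox level.
#' @export
simulateStableCircuit <- function(spec, design, sigma = 0.08,
                                  dox = doxGrid(), nCellsPerDox = 500,
                                  seed = 1, noiseFamily = "lognormal") {
  stopifnot(is(spec, "CircuitSpec"), is(design, "StableDesign"))
  validObject(design)
  nominal <- unlist(spec@params[translationNames()])
  nominal <- .effectiveTranslation(spec, nominal)
  noise <- NoiseModel(sigma = sigma, nominalMeans = nominal,
                      family = noiseFamily)
  K <- matrix(design@k, nrow = nCellsPerDox, ncol = 5L, byrow = TRUE)
  colnames(K) <- paste0("k", 1:5)
  frames <- vector("list", length(dox))
  names(frames) <- format(dox, trim = TRUE, scientific = FALSE, digits = 6)
  for (l in seq_along(dox)) {
    seedL <- subSeed(seed, 104729L + 7919L * l)
    P <- sampleExpressionScalars(noise, nCellsPerDox, seedL)
    O <- circuitSteadyState(spec, K, P, dox[l])
    colnames(O) <- spec@readouts
    frames[[l]] <- .circuitFrame(spec, rep(design@k[1], nCellsPerDox), K, P,
                                 O, dox[l], sigma, 0, seedL, "circuit-stable")
    frames[[l]]@metadata$designBin <- design@bin
  }
  frames
}

#' Pool a list of per-Dox frames into one frame
#'
#' @param frames list of \code{\link{PopulationFrame}}s sharing a schema.
#' @return a single \code{\link{PopulationFrame}} with a \code{dox} column.
#' @export
poolFrames <- function(frames) {
  stopifnot(length(frames) >= 1L)
  d <- do.call(rbind, lapply(frames, cells))
  rownames(d) <- NULL
  f1 <- frames[[1]]
  md <- f1@metadata
  md$dox <- vapply(frames, function(f) f@metadata$dox, numeric(1))
  PopulationFrame(d, channels = channelNames(f1), latents = latentNames(f1),
                  metadata = md)
}
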