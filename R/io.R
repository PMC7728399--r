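## CSV interchange, run configuration and the command-line surface.

#' Read a flow-cytometry event table from CSV
#'
#' Loads a CSV of compensated, scaled channel values (one row per event).
#' Channel columns are mapped to their roles via \code{channelMap}; any
#' extra columns are preserved untouched.  Rows with non-numeric or missing
#' values in a mapped channel are rejected and counted.
#'
#' @param path CSV file.
#' @param channelMap named character vector mapping role names to column
#'   names, e.g. \code{c(SBFP2 = "BV421-A")}; \code{NULL} keeps columns
#'   as-is and treats every \code{SBFP2/Cerulean/...} column as a channel.
#' @param referenceChannel reference channel (after mapping).
#' @return a \code{\link{PopulationFrame}}; latent columns (\code{m},
#'   \code{k*}, \code{b*}/\code{p*}) are detected automatically.
#' @export
readEventsCSV <- function(path, channelMap = NULL,
                          referenceChannel = "SBFP2") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  d <- as.data.frame(data.table::fread(path, check.names = FALSE))
  if (!is.null(channelMap)) {
    miss <- setdiff(unname(channelMap), names(d))
    if (length(miss))
      stop("channel column(s) missing from ", path, ": ",
           paste(miss, collapse = ", "), call. = FALSE)
    for (role in names(channelMap))
      names(d)[names(d) == channelMap[[role]]] <- role
    chans <- names(channelMap)
  } else {
    chans <- intersect(c(cotransfectionChannels(), "rtTADox"), names(d))
    if (!length(chans))
      stop("no recognisable channel columns in ", path, call. = FALSE)
  }
  ## reject rows with unparseable channel values
  keep <- rep(TRUE, nrow(d))
  for (ch in chans) {
    v <- suppressWarnings(as.numeric(d[[ch]]))
    keep <- keep & is.finite(v)
    d[[ch]] <- v
  }
  nBad <- sum(!keep)
  if (nBad > 0) {
    message("readEventsCSV: rejected ", nBad, " malformed row(s)")
    d <- d[keep, , drop = FALSE]
  }
  latents <- grep("^(m|k[0-9]+|b[0-9]+|p_|pi_)", names(d), value = TRUE)
  latents <- setdiff(latents, chans)
  PopulationFrame(d, channels = chans, latents = latents,
                  metadata = list(source = path,
                                  referenceChannel = referenceChannel,
                                  rejectedRows = nBad))
}

#' Write a simulation frame to CSV
#'
#' One row per cell; columns are the cell id, the latent variables
#' (multiplicity, copy numbers, randomized parameters, Dox level where
#' applicable) and every channel readout, all in linear molecule/signal
#' units.  Output is byte-deterministic for a fixed frame.
#'
#' @param frame a \code{\link{PopulationFrame}}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeSimulationCSV <- function(frame, path) {
  stopifnot(is(frame, "PopulationFrame"))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(cells(frame), path)
  invisible(path)
}

#' Default run configuration
#'
#' The reference settings of the workflow: noise levels
#' \code{0.00--0.32}, dispersion \code{epsilon = 0.04}, lognormal
#' multiplicity (\code{muM = 1.4979}, \code{sigmaM = 1.2686}), nominal
#' abundances 1.0:1.3:0.8:0.5:0.4, twelve Dox levels from 10 to 5e5
#' molecules, ten equal-count reference bins with 2.5% tails.
#'
#' @return nested list of defaults.
#' @export
defaultRunConfig <- function() {
  list(
    simulation = list(
      topology = "FO",
      nCells = 5e5,
      nCellsPerDox = 2e4,
      sigma = c(0.00, 0.02, 0.04, 0.08, 0.16, 0.32),
      epsilon = 0.04,
      multiplicity = list(family = "lognormal", muM = 1.4979,
                          sigmaM = 1.2686, lambda = 10,
                          shapeK = 0.7436, scaleTheta = 13.46),
      abundances = c(1.0, 1.3, 0.8, 0.5, 0.4),
      beta = rep(1000, 5),
      dox = list(Z = 12, from = 10, to = 5e5),
      seed = 1),
    pfaff = list(
      referenceChannel = "SBFP2",
      inputChannel = "mCherry",
      outputChannels = c("Cerulean", "Citrine"),
      nBins = 10,
      tailFraction = 0.025,
      biexp = list(M = 4.5, p = 2, T = 262144, W = 0.401)),
    copynumber = list(nBinsCotransfection = 50, nBinsCircuit = 25,
                      tailFraction = 0.001, window = 0.15))
}

#' Read a run configuration (YAML or JSON)
#'
#' Values present in the file override the defaults of
#' \code{\link{defaultRunConfig}}; everything else keeps its reference
#' value.
#'
#' @param path YAML (or JSON: YAML is a superset) configuration file;
#'   \code{NULL} returns the defaults.
#' @return nested configuration list.
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- defaultRunConfig()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("no such config: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  modifyList(cfg, user)
}

.cfgMultiplicity <- function(cfg) {
  mp <- cfg$simulation$multiplicity
  MultiplicityModel(family = mp$family, muM = mp$muM, sigmaM = mp$sigmaM,
                    lambda = if (is.null(mp$lambda)) NA_real_ else mp$lambda,
                    shapeK = if (is.null(mp$shapeK)) NA_real_ else mp$shapeK,
                    scaleTheta = if (is.null(mp$scaleTheta)) NA_real_
                                 else mp$scaleTheta)
}

.cliUsage <- function() {
  cat("usage: pfaff <subcommand> [--config FILE] [options]\n",
      "subcommands:\n",
      "  simulate-cotransfection  --n-cells N --sigma S --seed I --out FILE\n",
      "  simulate-circuit         --topology T --n-cells N --sigma S --dox D",
      " --seed I --out FILE\n",
      "  simulate-stable          --topology T --k1 K --sigma S --seed I",
      " --out FILE\n",
      "  pfaff                    --in FILE[,FILE...] --out FILE\n",
      "  copynumber               --in FILE --out FILE\n",
      "  validate                 --n-cells N --n-stable N --seed I --out DIR\n",
      sep = "")
}

.cliArgs <- function(argv) {
  opts <- list()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a, call. = FALSE)
    key <- substring(a, 3)
    if (i == length(argv) || startsWith(argv[i + 1L], "--"))
      stop("missing value for --", key, call. = FALSE)
    opts[[key]] <- argv[i + 1L]
    i <- i + 2L
  }
  opts
}

.cliNum <- function(opts, key, default) {
  if (is.null(opts[[key]])) default else as.numeric(opts[[key]])
}

#' Command-line entry point
#'
#' Thin shell surface over the package functions; see the package scripts
#' directory for a ready-to-use Rscript wrapper.  Subcommands:
#' \code{simulate-cotransfection}, \code{simulate-circuit},
#' \code{simulate-stable}, \code{pfaff}, \code{copynumber},
#' \code{validate}.  Each accepts \code{--config FILE} plus overrides and
#' writes CSV artifacts; errors return a non-zero status.
#'
#' @param argv character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
pfaffCLI <- function(argv = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(argv)) { .cliUsage(); return(invisible(1L)) }
    cmd <- argv[1]
    opts <- .cliArgs(argv[-1])
    cfg <- readRunConfig(opts[["config"]])
    seed <- as.integer(.cliNum(opts, "seed", cfg$simulation$seed))
    sig <- .cliNum(opts, "sigma", 0.08)
    mix <- GeneMix(cfg$simulation$abundances,
                   epsilon = .cliNum(opts, "epsilon",
                                     cfg$simulation$epsilon))
    mult <- .cfgMultiplicity(cfg)
    doxg <- doxGrid(cfg$simulation$dox$Z, cfg$simulation$dox$from,
                    cfg$simulation$dox$to)
    if (cmd == "simulate-cotransfection") {
      n <- .cliNum(opts, "n-cells", cfg$simulation$nCells)
      fr <- simulateCotransfection(mix, mult,
             NoiseModel(sig, nominalMeans = cfg$simulation$beta),
             nCells = n, seed = seed)
      writeSimulationCSV(fr, opts[["out"]] %||% "cotransfection.csv")
    } else if (cmd == "simulate-circuit") {
      topo <- opts[["topology"]] %||% cfg$simulation$topology
      n <- .cliNum(opts, "n-cells", cfg$simulation$nCellsPerDox)
      spec <- buildCircuit(topo)
      if (!is.null(opts[["dox"]]))
        doxg <- as.numeric(strsplit(opts[["dox"]], ",")[[1]])
      frames <- simulateTransientCircuit(spec, mix, mult, sigma = sig,
                                         dox = doxg, nCellsPerDox = n,
                                         seed = seed)
      writeSimulationCSV(poolFrames(frames),
                         opts[["out"]] %||% "circuit.csv")
    } else if (cmd == "simulate-stable") {
      topo <- opts[["topology"]] %||% cfg$simulation$topology
      spec <- buildCircuit(topo)
      k1 <- .cliNum(opts, "k1", 10)
      dsg <- new("StableDesign", k = k1 * mix@abundances, bin = NA_integer_,
                 y1 = NA_real_)
      frames <- simulateStableCircuit(spec, dsg, sigma = sig, dox = doxg,
                                      nCellsPerDox =
                                        .cliNum(opts, "n-cells", 5000),
                                      seed = seed)
      writeSimulationCSV(poolFrames(frames),
                         opts[["out"]] %||% "stable.csv")
    } else if (cmd == "pfaff") {
      paths <- strsplit(opts[["in"]] %||% stop("--in required"), ",")[[1]]
      frames <- lapply(paths, readEventsCSV,
                       referenceChannel = cfg$pfaff$referenceChannel)
      ## a single file with a dox column is split into per-level frames
      if (length(frames) == 1L && "dox" %in% names(cells(frames[[1]]))) {
        d <- cells(frames[[1]])
        f1 <- frames[[1]]
        frames <- lapply(split(seq_len(nrow(d)), d$dox), function(ix) {
          f <- f1[ix]; f@metadata$dox <- d$dox[ix[1]]; f
        })
      }
      io <- extractIOPoints(frames,
              inputChannel = cfg$pfaff$inputChannel,
              outputChannels = cfg$pfaff$outputChannels,
              nBins = cfg$pfaff$nBins,
              tailFraction = cfg$pfaff$tailFraction,
              params = do.call(biexpParams, cfg$pfaff$biexp),
              referenceChannel = cfg$pfaff$referenceChannel)
      data.table::fwrite(io, opts[["out"]] %||% "pfaff-modes.csv")
    } else if (cmd == "copynumber") {
      fr <- readEventsCSV(opts[["in"]] %||% stop("--in required"),
                          referenceChannel = cfg$pfaff$referenceChannel)
      bins <- binByReference(fr,
                nBins = cfg$copynumber$nBinsCotransfection,
                tailFraction = cfg$copynumber$tailFraction,
                method = "width")
      rep <- copyModeRatios(fr, bins,
               beta1 = .cliNum(opts, "beta1", cfg$simulation$beta[1]),
               abundances = cfg$simulation$abundances)
      data.table::fwrite(rep, opts[["out"]] %||% "copynumber-report.csv")
    } else if (cmd == "validate") {
      res <- runValidation(
        nCellsPerDox = .cliNum(opts, "n-cells", 2000),
        nStablePerDox = .cliNum(opts, "n-stable", 300),
        sigmas = if (!is.null(opts[["sigma"]]))
          as.numeric(strsplit(opts[["sigma"]], ",")[[1]])
        else c(0.08),
        seed = seed, mix = mix)
      outDir <- opts[["out"]] %||% "."
      dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
      data.table::fwrite(res$rho, file.path(outDir, "correlation.csv"))
      data.table::fwrite(res$io, file.path(outDir, "io-points.csv"))
      message(sprintf("mean Pearson rho = %.4f", res$meanRho))
    } else {
      .cliUsage()
      stop("unknown subcommand: ", cmd, call. = FALSE)
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
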