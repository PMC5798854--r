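#' @include spread.R spiking.R toxicity.R
NULL

.TRANSFER_MODES <- c("off_increase", "low_increase", "high_decrease")

#' The 17-entry seed menu
#'
#' Three global seeds (`all1`, `all2`, `all3`: identical initial conditions,
#' different random-number streams) and 14 single-neuron seed classes, one
#' per layer-by-type population of the default composition (layers 2/4/5/6
#' by RS/IB/FS/LTS, IB restricted to layers 5 and 6). Single-neuron seeds
#' add extra pathogenic protein to the soma of one neuron of the first
#' column.
#'
#' @return character vector of 17 seed identifiers.
#' @export
seedMenu <- function() {
  comp <- defaultComposition()
  c(paste0("all", 1:3), paste0("L", comp$layer, comp$type))
}

#' Build a simulation configuration
#'
#' Common settings default to: `dt = 0.025` ms, `fpd = 0.05`,
#' `RPn = RCn = 2e-4`, `RPp = RCp = 2e-5`, `Cnn = Cpn = 0.01`,
#' `tconv = 0.8`. The insoluble regime zeroes pathogenic clearance, makes
#' pathogenic production negligible (0) and starts `Cp` at `1e-4`; the
#' soluble regime starts `Cp` at `Cpn`. The transfer mode couples synaptic
#' transfer and the toxic effect as in the factorial design:
#' `off_increase` (`fst = 0`, threshold increase), `low_increase`
#' (`fst = 1`, increase), `high_decrease` (`fst = 1`, decrease -- the lower
#' threshold raises firing and thereby strengthens transfer).
#'
#' @param networkConfig a [networkConfig()] (ignored when `network` given).
#' @param network optionally a prebuilt [ColumnNetwork-class].
#' @param networkSeed connectivity instance seed.
#' @param solubility `"soluble"` or `"insoluble"`.
#' @param seed seed identifier from [seedMenu()], or `"all"`.
#' @param seedExtraCp extra pathogenic concentration added to the seeded
#'   soma for single-neuron seeds.
#' @param RM misfolding rate (0.08 low, 0.09 high).
#' @param sigmaZ passive-diffusion speed (0 off, 50 low, 500 high).
#' @param fat active-transport fraction (0, 1e-4, 1e-3).
#' @param transferMode one of `"off_increase"`, `"low_increase"`,
#'   `"high_decrease"`.
#' @param pInter intercolumnar spread selectivity (0.01, 1, 100).
#' @param fpd,RPn,RCn,RPp,RCp,Cnn,Cpn,Cmax,tconv common settings.
#' @param insolubleCp0 initial pathogenic concentration in the insoluble
#'   regime.
#' @param dt timestep (ms); `horizon` step budget; `traceStride` toxicity
#'   snapshot stride.
#' @param tsig geodesic-push significance threshold.
#' @param transportProbs anterograde / stay / retrograde probabilities.
#' @param toxicGain threshold shift at full toxicity (mV).
#' @param spiking a [spikingParams()] list.
#' @param processes named logical switches for each process.
#' @param stopWhenDead stop stepping once every neuron has died.
#' @param masterSeed master seed for all run randomness.
#' @return list of class `simConfig`.
#' @export
simulationConfig <- function(networkConfig = miniNetworkConfig(),
                             network = NULL,
                             networkSeed = 101L,
                             solubility = c("soluble", "insoluble"),
                             seed = "all",
                             seedExtraCp = 0.5,
                             RM = 0.08,
                             sigmaZ = 50,
                             fat = 0,
                             transferMode = .TRANSFER_MODES,
                             pInter = 1,
                             fpd = 0.05, RPn = 2e-4, RCn = 2e-4,
                             RPp = 2e-5, RCp = 2e-5,
                             Cnn = 0.01, Cpn = 0.01, Cmax = 1,
                             insolubleCp0 = 1e-4,
                             tconv = 0.8,
                             dt = 0.025, horizon = 10000L, traceStride = 10L,
                             tsig = 1e-6,
                             transportProbs = c(anterograde = 0.154,
                                                stay = 0.73,
                                                retrograde = 0.116),
                             toxicGain = 10,
                             spiking = spikingParams(),
                             processes = c(production = TRUE,
                                           misfolding = TRUE,
                                           clearance = TRUE,
                                           diffusion = TRUE,
                                           transport = TRUE,
                                           transfer = TRUE,
                                           spiking = TRUE,
                                           toxicity = TRUE),
                             stopWhenDead = TRUE,
                             masterSeed = 1L) {
  solubility <- match.arg(solubility)
  transferMode <- match.arg(transferMode)
  procDefault <- c(production = TRUE, misfolding = TRUE, clearance = TRUE,
                   diffusion = TRUE, transport = TRUE, transfer = TRUE,
                   spiking = TRUE, toxicity = TRUE)
  procDefault[names(processes)] <- processes
  .parseSeedId(seed)  # validates the identifier early
  fst <- if (transferMode == "off_increase") 0 else 1
  toxicMode <- if (transferMode == "high_decrease") "decrease" else "increase"
  cfg <- list(networkConfig = networkConfig, network = network,
              networkSeed = as.integer(networkSeed),
              solubility = solubility, seed = seed,
              seedExtraCp = seedExtraCp, RM = RM, sigmaZ = sigmaZ,
              fat = fat, transferMode = transferMode, fst = fst,
              toxicMode = toxicMode, pInter = pInter, fpd = fpd,
              RPn = RPn, RCn = RCn, RPp = RPp, RCp = RCp,
              Cnn = Cnn, Cpn = Cpn, Cmax = Cmax,
              insolubleCp0 = insolubleCp0, tconv = tconv, dt = dt,
              horizon = as.integer(horizon),
              traceStride = as.integer(traceStride), tsig = tsig,
              transportProbs = transportProbs, toxicGain = toxicGain,
              spiking = spiking, processes = procDefault,
              stopWhenDead = stopWhenDead,
              masterSeed = as.integer(masterSeed))
  class(cfg) <- "simConfig"
  cfg
}

# Resolve a seed identifier into layer/type, or NULL for global seeds.
.parseSeedId <- function(seed) {
  if (seed %in% c("all", "all1", "all2", "all3")) return(NULL)
  m <- regmatches(seed, regexec("^L([2456])(RS|IB|FS|LTS)$", seed))[[1]]
  if (length(m) != 3) stop("unknown seed identifier: ", seed)
  list(layer = as.integer(m[2]), type = m[3])
}

#' Initialise a simulation world
#'
#' Builds (or takes) the network, precomputes the spread operators, sets the
#' initial concentrations for the solubility regime, applies the seed
#' specification (single-neuron seeds add `seedExtraCp` to the soma of the
#' first matching neuron of column 1) and seeds the per-process RNG
#' substreams from the master seed.
#'
#' @param config a [simulationConfig()].
#' @return a [ProteinWorld-class].
#' @export
initializeWorld <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  cfg <- config
  net <- if (!is.null(cfg$network)) cfg$network
         else buildNetwork(cfg$networkConfig, cfg$networkSeed)
  N <- nNeurons(net)
  nSec <- 3L * N
  insol <- cfg$solubility == "insoluble"
  RPp <- if (insol) 0 else cfg$RPp
  RCp <- if (insol) 0 else cfg$RCp
  Cn <- rep(cfg$Cnn, nSec)
  Cp <- rep(if (insol) cfg$insolubleCp0 else cfg$Cpn, nSec)
  seedNeuron <- NA_integer_
  seedSpec <- .parseSeedId(cfg$seed)
  if (!is.null(seedSpec)) {
    nrn <- neurons(net)
    cand <- which(nrn$column == 1L & nrn$layer == seedSpec$layer &
                  nrn$type == seedSpec$type)
    if (length(cand) == 0)
      stop("seed population L", seedSpec$layer, seedSpec$type,
           " absent from column 1 of this network")
    seedNeuron <- cand[1]
    soma <- 3L * seedNeuron - 1L
    Cp[soma] <- min(cfg$Cmax - Cn[soma], Cp[soma] + cfg$seedExtraCp)
  }
  ops <- buildSpreadOperators(net, sigmaZ = cfg$sigmaZ, fpd = cfg$fpd,
                              fat = cfg$fat, fst = cfg$fst,
                              pInter = cfg$pInter, tsig = cfg$tsig,
                              transportProbs = cfg$transportProbs)
  e <- new.env(parent = emptyenv())
  e$cfg <- cfg
  e$net <- net
  e$ops <- ops
  e$RPp <- RPp; e$RCp <- RCp
  e$seedNeuron <- seedNeuron
  e$V <- sectionVolumes(net)
  e$Cn <- Cn; e$Cp <- Cp
  e$txc <- numeric(N)
  e$alive <- rep(TRUE, N)
  e$deathTime <- rep(NA_real_, N)
  e$t <- 0L
  e$satCount <- 0L
  e$streams <- makeRngStreams(cfg$masterSeed +
                              1000L * match(cfg$seed, c("all1", "all2", "all3"),
                                            nomatch = 0L),
                              c("production", "clearance", "spiking"))
  e$spk <- initSpikingState(net, cfg$spiking, cfg$dt)
  # passive-diffusion flow matrix (off-diagonal part of M) and transpose
  Fpd <- ops@M
  diag(Fpd) <- 0
  e$Fpd <- Matrix::drop0(Fpd)
  e$Ftpd <- Matrix::t(e$Fpd)
  e$hasDiffusion <- cfg$sigmaZ > 0 && length(e$Fpd@x) > 0
  e$Fat <- ops@Fat
  e$Ftat <- Matrix::t(e$Fat)
  # transfer triplets for quick per-spike row selection
  Gt <- as(ops@G, "TsparseMatrix")
  e$gi <- Gt@i + 1L; e$gj <- Gt@j + 1L; e$gx <- Gt@x
  e$gPre <- (e$gi - 1L) %/% 3L + 1L
  e$gPost <- (e$gj - 1L) %/% 3L + 1L
  # toxicity trace buffer
  nTrace <- cfg$horizon %/% cfg$traceStride + 1L
  e$toxTrace <- matrix(NA_real_, nTrace, N)
  e$traceSteps <- numeric(nTrace)
  e$toxTrace[1L, ] <- e$txc
  e$traceRow <- 1L
  e$spikeBuf <- list()
  new("ProteinWorld", state = e)
}

# Rebuild the cached flow matrices after deaths: diffusion inflow into dead
# sections is disabled (outflow continues); transport stops entirely for
# dead neurons.
.onDeaths <- function(e) {
  deadSec <- rep(3L * which(!e$alive), each = 3L) - c(2L, 1L, 0L)
  if (length(deadSec) && e$hasDiffusion) {
    Fpd <- e$ops@M
    diag(Fpd) <- 0
    Fpd[, deadSec] <- 0
    e$Fpd <- Matrix::drop0(Fpd)
    e$Ftpd <- Matrix::t(e$Fpd)
  }
  if (e$cfg$fat > 0) {
    e$Fat <- .transportMatrix(length(e$alive), e$cfg$fat,
                              e$cfg$transportProbs, e$alive)
    e$Ftat <- Matrix::t(e$Fat)
  }
  invisible(NULL)
}

.checkStateInvariants <- function(e) {
  bad <- e$Cn < -1e-9 | e$Cp < -1e-9 | e$Cn + e$Cp > e$cfg$Cmax + 1e-6
  if (any(bad))
    stop("state invariant violated at step ", e$t, " in sections ",
         paste(utils::head(which(bad), 5), collapse = ", "),
         ": Cn=", signif(e$Cn[which(bad)[1]], 6),
         " Cp=", signif(e$Cp[which(bad)[1]], 6))
  # wash out floating-point dust
  e$Cn[e$Cn < 0] <- 0
  e$Cp[e$Cp < 0] <- 0
  invisible(NULL)
}

#' Advance the simulation world one timestep
#'
#' Applies, in order: production, misfolding, clearance, passive diffusion,
#' active transport, the spiking substep, spike-triggered synaptic
#' transfer, the toxic threshold effect, the toxicity update and the death
#' check. Intermediate states follow each other within the step; the order
#' is part of the model contract. Dead neurons keep only misfolding and
#' diffusion out of their sections.
#'
#' @param world a [ProteinWorld-class] (advanced in place).
#' @return the world, invisibly.
#' @export
stepWorld <- function(world) {
  e <- world@state
  cfg <- e$cfg
  pr <- cfg$processes
  t <- e$t + 1L
  alive <- e$alive
  aliveSec <- rep(alive, each = 3L)

  if (pr[["production"]] && any(alive)) {
    res <- drawFromStream(e$streams, "production", function()
      .produce(e$Cn, e$Cp, alive, cfg$RPn, e$RPp, cfg$Cmax))
    e$Cn <- res$Cn; e$Cp <- res$Cp
  }
  if (pr[["misfolding"]] && cfg$RM > 0) {
    res <- .misfold(e$Cn, e$Cp, cfg$RM)
    e$Cn <- res$Cn; e$Cp <- res$Cp
  }
  if (pr[["clearance"]] && any(alive)) {
    res <- drawFromStream(e$streams, "clearance", function() {
      Cn <- .clearOne(e$Cn, cfg$RCn, cfg$Cnn, aliveSec,
                      otherC = e$Cp, Cmax = cfg$Cmax)
      list(Cn = Cn, Cp = .clearOne(e$Cp, e$RCp, cfg$Cpn, aliveSec,
                                   otherC = Cn, Cmax = cfg$Cmax))
    })
    e$Cn <- res$Cn; e$Cp <- res$Cp
  }
  if (pr[["diffusion"]] && e$hasDiffusion) {
    res <- .applyFlows(e$Cn * e$V, e$Cp * e$V, e$Fpd, e$Ftpd, e$V, cfg$Cmax)
    e$Cn <- res$xn / e$V; e$Cp <- res$xp / e$V
    e$satCount <- e$satCount + res$saturated
  }
  if (pr[["transport"]] && cfg$fat > 0 && any(alive)) {
    res <- .applyFlows(e$Cn * e$V, e$Cp * e$V, e$Fat, e$Ftat, e$V, cfg$Cmax)
    e$Cn <- res$xn / e$V; e$Cp <- res$xp / e$V
    e$satCount <- e$satCount + res$saturated
  }
  spiked <- integer(0)
  if (pr[["spiking"]]) {
    spiked <- drawFromStream(e$streams, "spiking", function()
      stepSpiking(e$spk, cfg$dt, alive))
    if (length(spiked))
      e$spikeBuf[[length(e$spikeBuf) + 1L]] <- cbind(t, spiked)
  }
  if (pr[["transfer"]] && cfg$fst > 0 && length(spiked) && length(e$gx)) {
    sel <- e$gPre %in% spiked & alive[e$gPre] & alive[e$gPost]
    if (any(sel)) {
      Fm <- Matrix::sparseMatrix(i = e$gi[sel], j = e$gj[sel], x = e$gx[sel],
                                 dims = c(length(e$Cn), length(e$Cn)))
      res <- .applyFlows(e$Cn * e$V, e$Cp * e$V, Fm, NULL, e$V, cfg$Cmax)
      e$Cn <- res$xn / e$V; e$Cp <- res$xp / e$V
      e$satCount <- e$satCount + res$saturated
    }
  }
  if (pr[["toxicity"]]) {
    e$spk$VthAdapt <- toxicThresholdShift(e$txc, cfg$toxicMode, cfg$toxicGain)
    inc <- toxicityIncrement(.neuronMeanConc(e$Cn, e$Cp))
    e$txc <- pmin(1, e$txc + ifelse(alive, inc, 0))
    newly <- which(alive & e$txc >= 1)
    if (length(newly)) {
      e$deathTime[newly] <- t
      e$alive[newly] <- FALSE
      .onDeaths(e)
    }
  }
  if (t %% cfg$traceStride == 0L) {
    e$traceRow <- e$traceRow + 1L
    e$toxTrace[e$traceRow, ] <- e$txc
    e$traceSteps[e$traceRow] <- t
  }
  .checkStateInvariants(e)
  e$t <- t
  invisible(world)
}

#' Snapshot of a simulation world
#'
#' @param world a [ProteinWorld-class].
#' @return list with `t`, `state` (a [ProteinState-class]), `txc`, `alive`,
#'   `deathTime`, `seedNeuron`, `saturations`.
#' @export
worldState <- function(world) {
  e <- world@state
  list(t = e$t,
       state = new("ProteinState", Cn = pmax(e$Cn, 0), Cp = pmax(e$Cp, 0)),
       txc = e$txc, alive = e$alive, deathTime = e$deathTime,
       seedNeuron = e$seedNeuron, saturations = e$satCount)
}

#' Run a complete simulation
#'
#' Initialises a world from the configuration and steps it to the horizon
#' (or until every neuron has died, when `stopWhenDead`). Deterministic:
#' identical `(config, masterSeed)` reproduce the identical death order,
#' spike log and toxicity trace.
#'
#' @param config a [simulationConfig()].
#' @return a [SimulationRun-class].
#' @examples
#' cfg <- simulationConfig(horizon = 50L, traceStride = 10L)
#' run <- runSimulation(cfg)
#' run
#' @export
runSimulation <- function(config) {
  world <- initializeWorld(config)
  e <- world@state
  cfg <- e$cfg
  while (e$t < cfg$horizon && !(cfg$stopWhenDead && !any(e$alive)))
    stepWorld(world)
  N <- length(e$alive)
  dead <- which(!is.na(e$deathTime))
  ord <- dead[order(e$deathTime[dead], dead)]
  nrn <- neurons(e$net)
  deathOrder <- data.frame(rank = seq_along(ord), neuron = ord,
                           t = e$deathTime[ord],
                           column = nrn$column[ord], layer = nrn$layer[ord],
                           type = nrn$type[ord])
  spikes <- if (length(e$spikeBuf)) {
    m <- do.call(rbind, e$spikeBuf)
    data.frame(step = m[, 1], time_ms = m[, 1] * cfg$dt, neuron = m[, 2])
  } else {
    data.frame(step = numeric(0), time_ms = numeric(0), neuron = integer(0))
  }
  keep <- seq_len(e$traceRow)
  cfgEcho <- cfg
  cfgEcho$network <- NULL
  cfgEcho$seedNeuron <- e$seedNeuron
  new("SimulationRun",
      config = unclass(cfgEcho),
      network = e$net,
      deathTime = e$deathTime,
      deathOrder = deathOrder,
      toxTrace = e$toxTrace[keep, , drop = FALSE],
      traceSteps = e$traceSteps[keep],
      spikes = spikes,
      horizon = cfg$horizon,
      completedSteps = e$t,
      saturations = as.integer(e$satCount),
      censored = any(is.na(e$deathTime)))
}
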