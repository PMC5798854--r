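#' @include proteospread-package.R
NULL

.CELL_TYPES <- c("RS", "IB", "FS", "LTS")
.EXC_TYPES <- c("RS", "IB")
.LAYERS <- c(2L, 4L, 5L, 6L)
.SECTION_NAMES <- c("dendrite", "soma", "axon")

#' ColumnNetwork: a multi-column network with section-level geometry
#'
#' Neurons live in `K` cortical columns, occupy one of layers 2/4/5/6 and are
#' one of four electrophysiological types (excitatory RS and IB, inhibitory
#' FS and LTS). Each neuron has three cylindrical sections -- dendrite
#' (j = 1), soma (j = 2) and axon (j = 3) -- whose base area and volume are
#' derived from diameter and length. Synapses are directed, originate at the
#' presynaptic axon, carry a non-negative strength `r` (zero-strength
#' synapses are not stored) and are flagged intercolumnar when they cross
#' columns. Sections are addressed by the flattened index
#' `k = 3 * (i - 1) + j`.
#'
#' @slot neurons data.frame with columns `id`, `column`, `layer`, `type`,
#'   `excitatory`.
#' @slot synapses data.frame with columns `pre`, `post`, `postSection`, `r`,
#'   `intercolumnar` (presynaptic section is always the axon, j = 3).
#' @slot geometry data.frame with one row per section in flattened order:
#'   `neuron`, `section`, `D`, `L`, `R`, `V` (micrometre units;
#'   `R = pi * (D/2)^2`, `V = L * R`).
#' @slot K integer number of columns.
#' @slot pInter numeric intercolumnar spread selectivity attached at build
#'   time (selectivity for all other edges is 1).
#' @slot buildSeed integer seed the generator was called with.
#' @export
setClass("ColumnNetwork", slots = c(
  neurons = "data.frame",
  synapses = "data.frame",
  geometry = "data.frame",
  K = "integer",
  pInter = "numeric",
  buildSeed = "integer"
))

setValidity("ColumnNetwork", function(object) {
  msg <- character(0)
  nrn <- object@neurons
  syn <- object@synapses
  geo <- object@geometry
  need <- c("id", "column", "layer", "type", "excitatory")
  if (!all(need %in% names(nrn)))
    return(paste("neurons must have columns:", paste(need, collapse = ", ")))
  N <- nrow(nrn)
  if (!identical(nrn$id, seq_len(N))) msg <- c(msg, "neuron ids must be 1..N")
  if (!all(nrn$type %in% .CELL_TYPES)) msg <- c(msg, "unknown cell type")
  if (!all(nrn$layer %in% .LAYERS)) msg <- c(msg, "layer must be one of 2,4,5,6")
  bad <- nrn$excitatory != (nrn$type %in% .EXC_TYPES)
  if (any(bad)) msg <- c(msg, "RS/IB must be excitatory, FS/LTS inhibitory")
  if (!all(nrn$column %in% seq_len(object@K)))
    msg <- c(msg, "neuron column outside 1..K")
  if (nrow(geo) != 3 * N) msg <- c(msg, "geometry must have 3 rows per neuron")
  if (nrow(geo) > 0) {
    if (any(geo$D <= 0) || any(geo$L <= 0))
      msg <- c(msg, "section diameter and length must be positive")
    if (any(abs(geo$R - pi * (geo$D / 2)^2) > 1e-9 * pmax(1, geo$R)))
      msg <- c(msg, "base area must equal pi*(D/2)^2")
    if (any(abs(geo$V - geo$L * geo$R) > 1e-9 * pmax(1, geo$V)))
      msg <- c(msg, "volume must equal L*R")
  }
  if (nrow(syn) > 0) {
    if (any(syn$r <= 0)) msg <- c(msg, "stored synapse strengths must be > 0")
    if (any(syn$pre < 1 | syn$pre > N | syn$post < 1 | syn$post > N))
      msg <- c(msg, "synapse endpoints outside 1..N")
    if (any(!syn$postSection %in% 1:3))
      msg <- c(msg, "postSection must be in 1..3")
  }
  if (length(object@pInter) != 1 || object@pInter < 0)
    msg <- c(msg, "pInter must be a single non-negative number")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' ProteinState: per-section normal and pathogenic concentration fractions
#'
#' Concentrations are fractions of the saturating concentration
#' `C_max = 1`; after every full timestep `0 <= Cn`, `0 <= Cp` and
#' `Cn + Cp <= 1` hold per section. Vectors are in flattened section order
#' `k = 3 * (i - 1) + j`.
#'
#' @slot Cn numeric normal-protein concentration per section.
#' @slot Cp numeric pathogenic-protein concentration per section.
#' @export
setClass("ProteinState", slots = c(Cn = "numeric", Cp = "numeric"))

setValidity("ProteinState", function(object) {
  if (length(object@Cn) != length(object@Cp))
    return("Cn and Cp must have equal length")
  if (length(object@Cn) %% 3 != 0)
    return("state length must be a multiple of 3 (three sections per neuron)")
  if (any(object@Cn < -1e-9) || any(object@Cp < -1e-9))
    return("concentrations must be non-negative")
  if (any(object@Cn + object@Cp > 1 + 1e-6))
    return("Cn + Cp must not exceed C_max = 1")
  TRUE
})

#' SpreadOperators: precomputed spread machinery for one parameterisation
#'
#' Holds the one-hop neighbour fractions `Z`, the geodesic coefficients `D`
#' (each row a distribution over terminal sections for a unit impulse at the
#' source, self included), the passive-diffusion matrix
#' `M = (1 - f_pd) I + f_pd D` (row-stochastic over source x destination,
#' applied to amounts as `t(M) x`), the intracellular active-transport flow
#' matrix `Fat` and the per-axon synaptic-transfer fractions `G`.
#'
#' @slot Z,D,M,Fat,G sparse section-level matrices (source x destination).
#' @slot sigmaZ,fpd,fat,fst,tsig,pInter scalar parameters used at build time.
#' @slot transportProbs named numeric: anterograde / stay / retrograde
#'   movement probabilities (sum to 1).
#' @export
setClass("SpreadOperators", slots = c(
  Z = "Matrix", D = "Matrix", M = "Matrix", Fat = "Matrix", G = "Matrix",
  sigmaZ = "numeric", fpd = "numeric", fat = "numeric", fst = "numeric",
  tsig = "numeric", pInter = "numeric", transportProbs = "numeric"
))

setValidity("SpreadOperators", function(object) {
  n <- nrow(object@M)
  if (n > 0) {
    rs <- Matrix::rowSums(object@M)
    if (any(abs(rs - 1) > 1e-8))
      return("every row of the diffusion matrix must sum to 1")
  }
  if (abs(sum(object@transportProbs) - 1) > 1e-8)
    return("transport probabilities must sum to 1")
  TRUE
})

#' SimulationRun: the record of one simulation
#'
#' Stores everything the breakdown-pattern metrics consume: per-neuron death
#' times, the death order, a (downsampled) toxicity trace, the spike log and
#' the full configuration echo.
#'
#' @slot config list: configuration echo (including `seedNeuron` and
#'   `masterSeed`).
#' @slot network the [ColumnNetwork-class] the run used.
#' @slot deathTime numeric per-neuron death step (NA for survivors).
#' @slot deathOrder data.frame `rank`, `neuron`, `t`, plus column/layer/type.
#' @slot toxTrace matrix time x neuron toxicity snapshots.
#' @slot traceSteps numeric timestep of each trace row.
#' @slot spikes data.frame `step`, `time_ms`, `neuron`.
#' @slot horizon,completedSteps integer step budget and steps actually run.
#' @slot saturations integer count of concentration-cap events.
#' @slot censored logical: TRUE if some neurons survived to the horizon.
#' @export
setClass("SimulationRun", slots = c(
  config = "list",
  network = "ColumnNetwork",
  deathTime = "numeric",
  deathOrder = "data.frame",
  toxTrace = "matrix",
  traceSteps = "numeric",
  spikes = "data.frame",
  horizon = "integer",
  completedSteps = "integer",
  saturations = "integer",
  censored = "logical"
))

#' ProteinWorld: mutable simulation state handle
#'
#' A thin S4 wrapper around an environment so that [stepWorld()] can advance
#' the simulation in place without copying the state on every timestep.
#' Inspect it with [worldState()].
#'
#' @slot state environment holding the live simulation state.
#' @export
setClass("ProteinWorld", slots = c(state = "environment"))
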