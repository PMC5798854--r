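#' @include network.R
NULL

#' Parameters of the adaptive-threshold spiking engine
#'
#' A simplified leaky integrate-and-fire engine with four cell-type presets
#' and Poisson background drive. It supplies what the protein machinery
#' needs -- spike events to trigger synaptic transfer, and a firing
#' threshold the toxic effect can shift -- not channel-level
#' electrophysiology. IB cells reset close to threshold after a spike and
#' have a short refractory period, producing burst doublets under drive; FS
#' cells are fast (short membrane time constant, brief refractoriness); LTS
#' cells have the lowest threshold.
#'
#' @param Vrest resting potential (mV).
#' @param types data.frame per cell type: `tau` (membrane time constant,
#'   ms), `Vth` (base firing threshold, mV), `reset` (post-spike reset, mV),
#'   `refractory` (ms).
#' @param driveRate Poisson background-event rate per neuron (events/ms).
#' @param driveAmp depolarisation per background event (mV).
#' @param synGain,inhGain depolarisation (hyperpolarisation) per presynaptic
#'   spike per unit synaptic strength (mV).
#' @return list of class `spikingParams`.
#' @export
spikingParams <- function(Vrest = -65,
                          types = data.frame(
                            type = c("RS", "IB", "FS", "LTS"),
                            tau = c(20, 15, 10, 25),
                            Vth = c(-48, -50, -46, -52),
                            reset = c(-68, -56, -68, -68),
                            refractory = c(3, 1.2, 1, 2.5),
                            stringsAsFactors = FALSE),
                          driveRate = 0.75, driveAmp = 1.0,
                          synGain = 3, inhGain = 4) {
  stopifnot(all(.CELL_TYPES %in% types$type), driveRate >= 0)
  p <- list(Vrest = Vrest, types = types, driveRate = driveRate,
            driveAmp = driveAmp, synGain = synGain, inhGain = inhGain)
  class(p) <- "spikingParams"
  p
}

#' Initialise spiking state for a network
#'
#' Returns a mutable environment advanced in place by [stepSpiking()]:
#' membrane potentials start at rest, thresholds at the per-type base values
#' plus a zero adaptive shift `VthAdapt` (the handle for the toxic effect).
#'
#' @param net a [ColumnNetwork-class].
#' @param params a [spikingParams()] list.
#' @param dt timestep (ms).
#' @return environment with fields `V`, `refr`, `VthBase`, `VthAdapt`,
#'   `tau`, `reset`, `refrPeriod`, `Wsyn`, `lastSpikes`, `dt` and the drive
#'   parameters.
#' @export
initSpikingState <- function(net, params = spikingParams(), dt = 0.025) {
  N <- nNeurons(net)
  ti <- match(neurons(net)$type, params$types$type)
  syn <- synapses(net)
  w <- if (nrow(syn)) {
    sign <- ifelse(neurons(net)$excitatory[syn$pre],
                   params$synGain, -params$inhGain)
    Matrix::sparseMatrix(i = syn$pre, j = syn$post, x = sign * syn$r,
                         dims = c(N, N))
  } else {
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(N, N))
  }
  e <- new.env(parent = emptyenv())
  e$V <- rep(params$Vrest, N)
  e$refr <- rep(0, N)
  e$VthBase <- params$types$Vth[ti]
  e$VthAdapt <- rep(0, N)
  e$tau <- params$types$tau[ti]
  e$reset <- params$types$reset[ti]
  e$refrPeriod <- params$types$refractory[ti]
  e$Vrest <- params$Vrest
  e$driveRate <- params$driveRate
  e$driveAmp <- params$driveAmp
  e$Wsyn <- w
  e$lastSpikes <- integer(0)
  e$dt <- dt
  e
}

#' Advance the spiking engine one substep
#'
#' Leaky integration towards rest, Poisson background kicks, synaptic input
#' from the previous substep's spikes (excitatory depolarising, inhibitory
#' hyperpolarising, scaled by strength), then threshold crossing: a neuron
#' fires iff its potential reaches `VthBase + VthAdapt` outside its
#' refractory period. Dead neurons never fire. Draws use the caller's RNG
#' state (the engine wraps this call in its own substream).
#'
#' @param spk environment from [initSpikingState()] (mutated in place).
#' @param dt timestep (ms).
#' @param alive logical per neuron.
#' @return integer ids of the neurons that fired this substep.
#' @export
stepSpiking <- function(spk, dt = spk$dt, alive = NULL) {
  if (dt <= 0) stop("dt must be positive")
  N <- length(spk$V)
  if (is.null(alive)) alive <- rep(TRUE, N)
  spk$V <- spk$V + dt / spk$tau * (spk$Vrest - spk$V)
  if (spk$driveRate > 0 && spk$driveAmp != 0) {
    kicks <- rpois(N, spk$driveRate * dt)
    spk$V <- spk$V + kicks * spk$driveAmp
  }
  if (length(spk$lastSpikes)) {
    inp <- as.numeric(Matrix::colSums(
      spk$Wsyn[spk$lastSpikes, , drop = FALSE]))
    spk$V <- spk$V + inp
  }
  spk$refr <- pmax(0, spk$refr - dt)
  fired <- which(alive & spk$refr <= 0 &
                 spk$V >= spk$VthBase + spk$VthAdapt)
  if (length(fired)) {
    spk$V[fired] <- spk$reset[fired]
    spk$refr[fired] <- spk$refrPeriod[fired]
  }
  spk$lastSpikes <- fired
  fired
}

#' Mean firing rate of a neuron group in a time window
#'
#' `spikes-in-window / window-length / group-size`, in Hz.
#'
#' @param spikes data.frame with columns `time_ms` and `neuron`
#'   (e.g. [spikeLog()] of a run).
#' @param window numeric `c(start, end)` in ms.
#' @param group integer neuron ids of the group (must be non-empty).
#' @return mean rate in Hz.
#' @export
firingFrequency <- function(spikes, window, group) {
  if (length(group) == 0) stop("group must be non-empty")
  if (length(window) != 2 || diff(window) <= 0)
    stop("window must be c(start, end) with positive length")
  n <- if (nrow(spikes) == 0) 0 else
    sum(spikes$time_ms >= window[1] & spikes$time_ms < window[2] &
        spikes$neuron %in% group)
  n / (diff(window) / 1000) / length(group)
}

#' Firing rates per neuron group
#'
#' @param spikes spike log data.frame (`time_ms`, `neuron`).
#' @param window numeric `c(start, end)` in ms.
#' @param groups named list of neuron-id vectors.
#' @return data.frame `group`, `rateHz`.
#' @export
firingFrequencyByGroup <- function(spikes, window, groups) {
  data.frame(group = names(groups),
             rateHz = vapply(groups, function(g)
               firingFrequency(spikes, window, g), numeric(1)),
             row.names = NULL)
}
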