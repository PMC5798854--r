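#' @include kinetics.R
NULL

#' Per-step toxicity increment from protein burden
#'
#' `0.001 * (exp(10 * c) - 1)` where `c` is the mean over the neuron's three
#' sections of the total concentration `Cn + Cp`. Zero at zero
#' concentration; strictly increasing. Normal protein contributes too: the
#' burden is total protein, not only the pathogenic conformer.
#'
#' @param meanConc per-neuron mean section total concentration (vectorised).
#' @return toxicity increment per timestep.
#' @export
toxicityIncrement <- function(meanConc) {
  0.001 * expm1(10 * meanConc)
}

# per-neuron mean over the three sections of Cn + Cp
.neuronMeanConc <- function(Cn, Cp) {
  tot <- Cn + Cp
  .colMeans(tot, 3L, length(tot) %/% 3L)
}

#' Toxicity update
#'
#' Adds the increment of [toxicityIncrement()] to every alive neuron's
#' toxicity and clamps at 1. Toxicity is monotone non-decreasing; dead
#' neurons stop accumulating (their toxicity is already 1).
#'
#' @param txc per-neuron toxicity in `[0, 1]`.
#' @param state a [ProteinState-class].
#' @param alive logical per neuron (default all alive).
#' @return updated toxicity vector.
#' @export
toxicityStep <- function(txc, state, alive = NULL) {
  if (is.null(alive)) alive <- rep(TRUE, length(txc))
  inc <- toxicityIncrement(.neuronMeanConc(state@Cn, state@Cp))
  pmin(1, txc + ifelse(alive, inc, 0))
}

#' Toxic effect on the firing threshold
#'
#' Maps toxicity to the adaptive threshold shift: `+gain * txc` in
#' `increase` mode (loss of function -- firing frequencies fall) or
#' `-gain * txc` in `decrease` mode (gain of function -- hyperexcitability,
#' which indirectly strengthens spike-triggered synaptic transfer).
#'
#' @param txc per-neuron toxicity in `[0, 1]`.
#' @param mode `"increase"` or `"decrease"`.
#' @param gain threshold shift at full toxicity (mV).
#' @return per-neuron threshold shift `VthAdapt` (mV).
#' @export
toxicThresholdShift <- function(txc, mode = c("increase", "decrease"), gain = 10) {
  mode <- match.arg(mode)
  if (mode == "increase") gain * txc else -gain * txc
}

#' Death check
#'
#' Records the first step at which toxicity reaches 1 for each neuron; the
#' death time is set exactly once. Simultaneous crossings are ordered by
#' ascending neuron id, making the death order a total order.
#'
#' @param txc per-neuron toxicity.
#' @param deathTime per-neuron death step (NA while alive).
#' @param t current timestep.
#' @return list with updated `deathTime` and `newlyDead` (ascending ids).
#' @export
deathCheck <- function(txc, deathTime, t) {
  newly <- which(is.na(deathTime) & txc >= 1)
  if (length(newly)) deathTime[newly] <- t
  list(deathTime = deathTime, newlyDead = newly)
}
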