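#' @include AllClasses.R
NULL

#' Construct a ProteinState
#'
#' @param Cn,Cp numeric concentration fractions in flattened section order
#'   (length 3N). Scalars are recycled to `3 * nNeurons`.
#' @param nNeurons neuron count when recycling scalars.
#' @return a [ProteinState-class].
#' @export
proteinState <- function(Cn, Cp, nNeurons = NULL) {
  n <- if (is.null(nNeurons)) max(length(Cn), length(Cp)) else 3L * nNeurons
  new("ProteinState", Cn = as.numeric(rep_len(Cn, n)),
      Cp = as.numeric(rep_len(Cp, n)))
}

# soma indices (j = 2) in flattened order
.somaIndex <- function(N) 3L * seq_len(N) - 1L

# ---- internal vector kernels (shared with the engine) -----------------------

# Production: somata of alive neurons gain draws from N(rate, rate^2);
# dendrites and axons gain nothing. Draws keep their nominal mean (they may
# be negative -- coefficient of variation 1); the applied update is clamped
# so 0 <= C and Cn + Cp <= Cmax. Draws come from the caller's RNG state.
.produce <- function(Cn, Cp, aliveNeurons, RPn, RPp, Cmax = 1) {
  idx <- .somaIndex(length(Cn) %/% 3L)[aliveNeurons]
  n <- length(idx)
  if (n) {
    if (RPn > 0) {
      an <- rnorm(n, RPn, RPn)
      Cn[idx] <- pmin(pmax(Cn[idx] + an, 0), Cmax - Cp[idx])
    }
    if (RPp > 0) {
      ap <- rnorm(n, RPp, RPp)
      Cp[idx] <- pmin(pmax(Cp[idx] + ap, 0), Cmax - Cn[idx])
    }
  }
  list(Cn = Cn, Cp = Cp)
}

# Misfolding: templated conversion b = RM * Cn * Cp per section, moving mass
# from Cn to Cp; conserves Cn + Cp exactly. Applies to dead neurons too.
.misfold <- function(Cn, Cp, RM) {
  b <- pmin(RM * Cn * Cp, Cn)
  list(Cn = Cn - b, Cp = Cp + b, b = b)
}

# Clearance: removals drawn from N(mu, mu^2) with the adaptive mean mu from
# adaptiveClearanceRate(); the applied update is clamped to [0, headroom].
# Alive sections only. otherC gives Cmax - headroom for the joint bound.
.clearOne <- function(C, rate, level, aliveSec, otherC = 0, Cmax = 1) {
  if (rate <= 0) return(C)
  idx <- which(aliveSec & C > 0)
  if (length(idx)) {
    mu <- adaptiveClearanceRate(C[idx], rate, level)
    q <- rnorm(length(idx), mu, mu)
    head <- if (length(otherC) > 1) Cmax - otherC[idx] else Cmax - otherC
    C[idx] <- pmin(pmax(C[idx] - q, 0), head)
  }
  C
}

# ---- exported operations ----------------------------------------------------

#' Production step
#'
#' Adds protein to the soma (j = 2) of every alive neuron: draws from a
#' normal distribution with mean and standard deviation equal to the
#' production rate (coefficient of variation 1; draws may be negative, and
#' the applied update is clamped so concentrations stay within
#' `[0, Cmax]`). Dendrite and axon additions are zero.
#'
#' @param state a [ProteinState-class].
#' @param RPn,RPp normal / pathogenic production rates (concentration
#'   fraction per timestep).
#' @param alive logical per neuron (default all alive).
#' @param Cmax saturating concentration.
#' @return updated ProteinState.
#' @export
productionStep <- function(state, RPn, RPp, alive = NULL, Cmax = 1) {
  N <- nNeurons(state)
  if (is.null(alive)) alive <- rep(TRUE, N)
  res <- .produce(state@Cn, state@Cp, alive, RPn, RPp, Cmax)
  new("ProteinState", Cn = res$Cn, Cp = res$Cp)
}

#' Misfolding step
#'
#' Converts `b = RM * Cn * Cp` from normal to pathogenic per section --
#' templating needs both the substrate and the seed, hence the product form
#' (validated against the particle-level simulation, see [runBox()] and
#' [fitProductModel()]). Applies to dead neurons too: misfolding continues
#' after death. `Cn + Cp` is conserved exactly.
#'
#' @param state a [ProteinState-class].
#' @param RM misfolding rate.
#' @return updated ProteinState.
#' @export
misfoldStep <- function(state, RM) {
  res <- .misfold(state@Cn, state@Cp, RM)
  new("ProteinState", Cn = res$Cn, Cp = res$Cp)
}

#' Adaptive mean clearance rate
#'
#' `mu = rate * log(1 + (e - 1) * C / level)`: clearance adapts to the
#' concentration so that protein tends back to its normal level. At
#' `C = level` the mean equals `rate` exactly; at `C = 0` it is zero.
#'
#' @param C concentration (vectorised), `>= 0`.
#' @param rate clearance rate at the normal concentration level.
#' @param level normal concentration level, `> 0`.
#' @return mean clearance rate, same shape as `C`.
#' @examples
#' adaptiveClearanceRate(0.01, 2e-5, 0.01)  # == 2e-5
#' @export
adaptiveClearanceRate <- function(C, rate, level) {
  if (any(level <= 0)) stop("normal concentration level must be positive")
  if (any(C < 0)) stop("concentration must be non-negative")
  rate * log1p((exp(1) - 1) * C / level)
}

#' Clearance step
#'
#' Removes protein from every alive section: draws from a normal
#' distribution with mean and standard deviation equal to the adaptive rate
#' of [adaptiveClearanceRate()]; the applied update is clamped so
#' concentrations stay within `[0, Cmax]`. Clearance stops at death. A zero
#' clearance rate (insoluble regime) removes nothing.
#'
#' @param state a [ProteinState-class].
#' @param RCn,RCp normal / pathogenic clearance rates at the normal levels.
#' @param Cnn,Cpn normal concentration levels.
#' @param alive logical per neuron (default all alive).
#' @return updated ProteinState.
#' @export
clearanceStep <- function(state, RCn, RCp, Cnn = 0.01, Cpn = 0.01, alive = NULL) {
  N <- nNeurons(state)
  if (is.null(alive)) alive <- rep(TRUE, N)
  aliveSec <- rep(alive, each = 3L)
  Cn <- .clearOne(state@Cn, RCn, Cnn, aliveSec, otherC = state@Cp)
  Cp <- .clearOne(state@Cp, RCp, Cpn, aliveSec, otherC = Cn)
  new("ProteinState", Cn = Cn, Cp = Cp)
}

#' Single-compartment equilibrium model
#'
#' Runs production, misfolding and clearance in one volume and reports the
#' time at which the normal/pathogenic equilibrium is lost -- the first step
#' at which `Cp` exceeds `lossThreshold * Cmax` (the runaway criterion; the
#' divergence is self-reinforcing once templating outpaces the logarithmic
#' clearance response). The behaviour is sensitive to small changes in the
#' misfolding rate.
#'
#' Process magnitudes (production draws, templating `b = RM * Cn * Cp`,
#' adaptive clearance means) are computed from the start-of-step
#' concentrations and applied sequentially. Exactly four normal draws are
#' consumed per step whatever the rates, so runs differing only in `RM`
#' share their noise under a common seed. The inner loop is compiled, so
#' horizons of 1e7-1e8 steps (where noise-driven escape from the
#' metastable equilibrium occurs near the sensitivity knee) are practical.
#'
#' @param Cn0,Cp0 initial concentrations.
#' @param Cnn,Cpn normal concentration levels.
#' @param RPn,RPp production rates; `RCn,RCp` clearance rates.
#' @param RM misfolding rate.
#' @param horizon maximum number of timesteps.
#' @param lossThreshold runaway criterion as a fraction of `Cmax`.
#' @param Cmax saturating concentration.
#' @param seed RNG seed (caller's RNG state is preserved).
#' @param traceStride store every `traceStride`-th step in the trace
#'   (default: about 2000 trace rows over the horizon).
#' @return list with `lossTime` (NA if equilibrium kept to the horizon),
#'   `trace` (data.frame `t`, `Cn`, `Cp`) and the parameters.
#' @export
pointModelRun <- function(Cn0 = 0.05, Cp0 = 0.01, Cnn = 0.05, Cpn = 0.01,
                          RPn = 4e-4, RPp = 0.8e-4, RCn = 4e-4, RCp = 0.8e-4,
                          RM = 0.0626, horizon = 40000, lossThreshold = 0.5,
                          Cmax = 1, seed = 1L, traceStride = NULL) {
  stopifnot(horizon >= 0)
  if (is.null(traceStride)) traceStride <- max(1, floor(horizon / 2000))
  res <- withSeed(seed, .pointModelLoop(Cn0, Cp0, Cnn, Cpn, RPn, RPp,
                                        RCn, RCp, RM, horizon,
                                        lossThreshold, Cmax, traceStride))
  lossTime <- if (res$lossTime < 0) NA_real_ else res$lossTime
  list(lossTime = lossTime,
       trace = data.frame(t = res$t, Cn = res$Cn, Cp = res$Cp),
       params = list(Cn0 = Cn0, Cp0 = Cp0, Cnn = Cnn, Cpn = Cpn, RPn = RPn,
                     RPp = RPp, RCn = RCn, RCp = RCp, RM = RM,
                     horizon = horizon, lossThreshold = lossThreshold,
                     seed = seed))
}

#' Median equilibrium-loss time over seeds for a grid of misfolding rates
#'
#' Convenience wrapper around [pointModelRun()] using common random numbers
#' across rates (seed `s` reuses the same pregenerated noise for every rate).
#'
#' @param RMs numeric vector of misfolding rates.
#' @param seeds integer vector of seeds.
#' @param horizon step budget per run; censored runs enter the median at
#'   the horizon value (a lower bound on their loss time).
#' @param ... forwarded to [pointModelRun()].
#' @return data.frame `RM`, `medianLossTime`, `nLost`.
#' @export
equilibriumLossGrid <- function(RMs, seeds = 1:11, horizon = 2e7, ...) {
  res <- lapply(RMs, function(rm) {
    lt <- vapply(seeds, function(s) {
      v <- pointModelRun(RM = rm, seed = s, horizon = horizon, ...)$lossTime
      if (is.na(v)) horizon else as.numeric(v)
    }, numeric(1))
    c(median = median(lt), n = sum(lt < horizon))
  })
  data.frame(RM = RMs,
             medianLossTime = vapply(res, `[[`, numeric(1), "median"),
             nLost = vapply(res, `[[`, numeric(1), "n"))
}
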