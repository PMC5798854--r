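#' @include network.R
NULL

# ---- passive diffusion building blocks --------------------------------------

#' Boundary fraction for Brownian escape past a section boundary
#'
#' Fraction of the protein in a cylindrical section of length `L` that
#' crosses one of its boundaries in a single timestep when displacement in
#' the primary axis is Gaussian with standard deviation `sigmaZ` centred at
#' the section midpoint: `y = pnorm(-L / (2 * sigmaZ))`. Tends to 0.5 as
#' `L -> 0` (half the mass lies past a zero-width section) and increases
#' with the diffusion speed.
#'
#' @param L section length (micrometres), `>= 0`; vectorised.
#' @param sigmaZ diffusion speed (micrometres per timestep), `> 0`.
#' @return y in (0, 0.5].
#' @export
boundaryFraction <- function(L, sigmaZ) {
  if (any(sigmaZ <= 0)) stop("sigmaZ must be positive")
  if (any(L < 0)) stop("section length must be non-negative")
  pnorm(-L / (2 * sigmaZ))
}

#' One-hop neighbour fraction z
#'
#' Scales the boundary fraction by the entrance-to-source area ratio
#' `min(Rsrc, Rdst) / Rsrc`, the edge weight `w` (20 intracellularly, the
#' synaptic strength `r` intercellularly) and the spread selectivity `p`.
#' Values are raw (uncapped); [buildSpreadOperators()] rescales rows whose
#' total outflow would exceed 1.
#'
#' @param y boundary fraction from [boundaryFraction()].
#' @param Rsrc,Rdst base areas of source and destination sections, `> 0`.
#' @param w edge weight.
#' @param p spread selectivity of the edge.
#' @return z fraction; vectorised.
#' @export
neighbourFraction <- function(y, Rsrc, Rdst, w = 1, p = 1) {
  if (any(Rsrc <= 0) || any(Rdst <= 0)) stop("base areas must be positive")
  y * pmin(Rsrc, Rdst) / Rsrc * w * p
}

#' Geodesic spread coefficients d
#'
#' Propagates a unit impulse from every source section through the one-hop
#' fractions `Z`: a section that receives more than `tsig` re-pushes the
#' received mass by its own `Z` row (retaining `1 - rowSums(Z)`), until all
#' circulating parcels fall below `tsig` and settle where they are. Each row
#' of the result is a distribution (self included) summing to 1.
#'
#' @param Z sparse section-level one-hop fraction matrix with
#'   `rowSums(Z) <= 1` (cap rows first; uncapped rows make the push diverge).
#' @param tsig significance threshold stopping the recursion.
#' @param maxit iteration guard; exceeding it signals uncapped `Z` rows.
#' @return sparse matrix `D`, rows = sources, rows sum to 1.
#' @export
geodesicCoefficients <- function(Z, tsig = 1e-6, maxit = 100000L) {
  n <- nrow(Z)
  rs <- Matrix::rowSums(Z)
  if (any(rs > 1 + 1e-9))
    stop("Z rows must sum to at most 1; rescale before the geodesic push")
  retain <- pmax(0, 1 - rs)
  S <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(n, n))
  # pending parcels, rows = sources (explicit entries: unit impulses)
  P <- Matrix::sparseMatrix(i = seq_len(n), j = seq_len(n), x = rep(1, n),
                            dims = c(n, n))
  for (it in seq_len(maxit)) {
    Pt <- as(P, "TsparseMatrix")
    if (length(Pt@x) == 0) break
    big <- Pt@x > tsig
    if (!any(big)) { S <- S + P; P <- NULL; break }
    if (any(!big)) {
      S <- S + Matrix::sparseMatrix(i = Pt@i[!big] + 1L, j = Pt@j[!big] + 1L,
                                    x = Pt@x[!big], dims = c(n, n))
    }
    Pb <- Matrix::sparseMatrix(i = Pt@i[big] + 1L, j = Pt@j[big] + 1L,
                               x = Pt@x[big], dims = c(n, n))
    # settle the retained share, re-push the rest one hop
    S <- S + Pb %*% Matrix::Diagonal(x = retain)
    P <- Pb %*% Z
    if (it == maxit)
      stop("geodesic push did not converge within maxit (z rows not capped?)")
  }
  Matrix::drop0(S)
}

#' Passive-diffusion matrix M
#'
#' `M = (1 - fpd) * I + fpd * D`, row-stochastic over source x destination.
#' Applied to section amounts `x = C * V` as `t(M) %*% x`; dividing by the
#' destination volumes recovers concentrations. `fpd = 0` gives the
#' identity.
#'
#' @param D geodesic coefficients from [geodesicCoefficients()].
#' @param fpd passive-diffusion fraction in `[0, 1]`.
#' @return sparse row-stochastic matrix.
#' @export
diffusionMatrix <- function(D, fpd) {
  stopifnot(fpd >= 0, fpd <= 1)
  n <- nrow(D)
  rs <- Matrix::rowSums(D)
  if (n > 0 && any(abs(rs - 1) > 1e-8))
    stop("rows of D must sum to 1 (within tolerance)")
  Matrix::drop0((1 - fpd) * Matrix::Diagonal(n) + fpd * D)
}

# ---- shared flow application with saturation handling -----------------------

# Move amounts along a fractional flow matrix Fm (source x destination,
# rowSums <= 1), retaining 1 - rowSums at the source. If a destination would
# exceed Cmax * V, its inflow is proportionally scaled back and the residue
# stays at the sources (the paper states the bound C_max but no mechanism).
# Mass is conserved exactly by construction.
.applyFlows <- function(xn, xp, Fm, Ft = NULL, V, Cmax = 1, maxPass = 8L) {
  if (is.null(Ft)) Ft <- Matrix::t(Fm)
  sat <- 0L
  cap <- Cmax * V
  for (pass in seq_len(maxPass + 1L)) {
    out <- Matrix::rowSums(Fm)
    inN <- as.numeric(Ft %*% xn)
    inP <- as.numeric(Ft %*% xp)
    keepN <- xn * (1 - out)
    keepP <- xp * (1 - out)
    tot <- keepN + keepP + inN + inP
    over <- which(tot > cap * (1 + 1e-12) & (inN + inP) > 0)
    if (length(over) == 0 || pass > maxPass)
      return(list(xn = keepN + inN, xp = keepP + inP, saturated = sat))
    sat <- sat + length(over)
    s <- rep(1, length(xn))
    room <- pmax(0, cap[over] - keepN[over] - keepP[over])
    s[over] <- room / (inN[over] + inP[over])
    Dg <- Matrix::Diagonal(x = s)
    Fm <- Fm %*% Dg
    Ft <- Dg %*% Ft
  }
}

#' Apply one passive-diffusion step
#'
#' Converts concentrations to amounts, moves them along `M` and converts
#' back. Diffusion out of dead sections continues but inflow into dead
#' sections is disabled; the blocked mass stays at its source, so total
#' amount is conserved in all cases.
#'
#' @param state a [ProteinState-class].
#' @param M diffusion matrix from [diffusionMatrix()].
#' @param volumes section volumes, flattened order.
#' @param deadSections integer indices of sections of dead neurons.
#' @param Cmax saturating concentration.
#' @return updated ProteinState; attribute `saturated` counts cap events.
#' @export
applyDiffusion <- function(state, M, volumes, deadSections = integer(0), Cmax = 1) {
  Fm <- M
  diag(Fm) <- 0
  Fm <- Matrix::drop0(Fm)
  if (length(deadSections)) {
    Fm[, deadSections] <- 0
    Fm <- Matrix::drop0(Fm)
  }
  res <- .applyFlows(state@Cn * volumes, state@Cp * volumes, Fm, NULL,
                     volumes, Cmax)
  out <- new("ProteinState", Cn = res$xn / volumes, Cp = res$xp / volumes)
  attr(out, "saturated") <- res$saturated
  out
}

# ---- active transport -------------------------------------------------------

# Intracellular transport flow matrix: anterograde dendrite->soma->axon,
# retrograde axon->soma->dendrite, per-step fractions fat * prob.
.transportMatrix <- function(N, fat, probs, alive = NULL) {
  if (fat == 0 || N == 0)
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(3 * N, 3 * N)))
  if (is.null(alive)) alive <- rep(TRUE, N)
  ids <- which(alive)
  d <- 3L * ids - 2L; s <- d + 1L; a <- d + 2L
  Matrix::sparseMatrix(
    i = c(d, s, s, a), j = c(s, a, d, s),
    x = rep(fat * c(probs[[1]], probs[[1]], probs[[3]], probs[[3]]),
            each = length(ids)),
    dims = c(3 * N, 3 * N))
}

#' Apply one active-transport step
#'
#' Motor-driven intracellular movement: per source section a fraction
#' `fat * 0.154` of the amount moves one section towards the axon
#' (anterograde), `fat * 0.116` towards the dendrite (retrograde) and the
#' remainder stays. Dead neurons do not transport. Mass is conserved within
#' each neuron.
#'
#' @param state a [ProteinState-class].
#' @param volumes section volumes.
#' @param fat active-transport fraction in `[0, 1]`.
#' @param probs anterograde / stay / retrograde probabilities (must sum to 1).
#' @param alive logical per neuron (default all alive).
#' @param Cmax saturating concentration.
#' @return updated ProteinState; attribute `saturated` counts cap events.
#' @export
activeTransportStep <- function(state, volumes, fat,
                                probs = c(anterograde = 0.154, stay = 0.73,
                                          retrograde = 0.116),
                                alive = NULL, Cmax = 1) {
  if (fat < 0 || fat > 1) stop("fat must lie in [0, 1]")
  if (abs(sum(probs) - 1) > 1e-8)
    stop("transport probabilities must sum to 1")
  N <- nNeurons(state)
  if (fat == 0) return(state)
  Fm <- .transportMatrix(N, fat, probs, alive)
  res <- .applyFlows(state@Cn * volumes, state@Cp * volumes, Fm, NULL,
                     volumes, Cmax)
  out <- new("ProteinState", Cn = res$xn / volumes, Cp = res$xp / volumes)
  attr(out, "saturated") <- res$saturated
  out
}

# ---- synaptic transfer ------------------------------------------------------

# Static per-axon outgoing transfer fractions: for each axon with outgoing
# synapses, g = 0.154 * fst * (p * r) / sum(p * r). Rows are axon sections.
.transferMatrix <- function(net, fst, pInter = NULL) {
  N <- nNeurons(net)
  syn <- synapses(net)
  if (fst == 0 || nrow(syn) == 0)
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(3 * N, 3 * N)))
  if (is.null(pInter)) pInter <- net@pInter
  pr <- ifelse(syn$intercolumnar, pInter, 1) * syn$r
  tot <- tapply(pr, syn$pre, sum)
  denom <- as.numeric(tot[as.character(syn$pre)])
  keep <- denom > 0
  g <- 0.154 * fst * pr[keep] / denom[keep]
  Matrix::sparseMatrix(i = 3L * syn$pre[keep],
                       j = 3L * (syn$post[keep] - 1L) + syn$postSection[keep],
                       x = g, dims = c(3 * N, 3 * N))
}

#' Apply one spike-triggered synaptic-transfer step
#'
#' Only the axons of neurons that fired this timestep release protein: each
#' outgoing synapse receives the fraction `g` of the axon content given by
#' the normalised selectivity-weighted strength, totalling `0.154 * fst` per
#' spiking axon; the rest is retained. Transfer to and from dead neurons is
#' disabled (blocked mass stays at the source).
#'
#' @param state a [ProteinState-class].
#' @param volumes section volumes.
#' @param G transfer-fraction matrix (slot `G` of [buildSpreadOperators()]).
#' @param spiked integer ids of neurons that fired this timestep.
#' @param alive logical per neuron.
#' @param Cmax saturating concentration.
#' @return updated ProteinState; attribute `saturated` counts cap events.
#' @export
synapticTransferStep <- function(state, volumes, G, spiked,
                                 alive = NULL, Cmax = 1) {
  if (length(spiked) == 0) return(state)
  N <- nNeurons(state)
  if (!is.null(alive)) spiked <- spiked[alive[spiked]]
  if (length(spiked) == 0) return(state)
  Gt <- as(G, "TsparseMatrix")
  sel <- (Gt@i + 1L) %in% (3L * spiked)
  if (!is.null(alive)) {
    dstNeuron <- (Gt@j) %/% 3L + 1L
    sel <- sel & alive[dstNeuron]
  }
  if (!any(sel)) return(state)
  Fm <- Matrix::sparseMatrix(i = Gt@i[sel] + 1L, j = Gt@j[sel] + 1L,
                             x = Gt@x[sel], dims = dim(G))
  res <- .applyFlows(state@Cn * volumes, state@Cp * volumes, Fm, NULL,
                     volumes, Cmax)
  out <- new("ProteinState", Cn = res$xn / volumes, Cp = res$xp / volumes)
  attr(out, "saturated") <- res$saturated
  out
}

# ---- assembled operators ----------------------------------------------------

#' Precompute all spread operators for a network and parameter setting
#'
#' Builds the one-hop fractions `Z` (rows rescaled to sum at most 1 so the
#' geodesic push converges), the geodesic coefficients `D`, the diffusion
#' matrix `M`, the active-transport flow matrix and the synaptic-transfer
#' fractions. `sigmaZ = 0` switches passive diffusion off (`M = I`).
#'
#' @param net a [ColumnNetwork-class].
#' @param sigmaZ passive-diffusion speed (0 = off; 50 low, 500 high).
#' @param fpd passive-diffusion fraction.
#' @param fat active-transport fraction (0 off, 1e-4 weak, 1e-3 strong).
#' @param fst synaptic-transfer fraction (0 off, 1 on).
#' @param pInter intercolumnar spread selectivity (0.01 avoid, 1 neutral,
#'   100 favour); default the network's stored value.
#' @param tsig significance threshold of the geodesic push.
#' @param transportProbs anterograde / stay / retrograde probabilities.
#' @param wIntra intracellular edge weight.
#' @return a [SpreadOperators-class].
#' @export
buildSpreadOperators <- function(net, sigmaZ = 50, fpd = 0.05, fat = 0,
                                 fst = 0, pInter = NULL, tsig = 1e-6,
                                 transportProbs = c(anterograde = 0.154,
                                                    stay = 0.73,
                                                    retrograde = 0.116),
                                 wIntra = 20) {
  if (is.null(pInter)) pInter <- net@pInter
  stopifnot(fpd >= 0, fpd <= 1, fat >= 0, fat <= 1, fst >= 0, fst <= 1,
            sigmaZ >= 0, tsig > 0)
  if (abs(sum(transportProbs) - 1) > 1e-8)
    stop("transport probabilities must sum to 1")
  nSec <- 3L * nNeurons(net)
  if (sigmaZ > 0) {
    adj <- sectionAdjacency(net, pInter = pInter, wIntra = wIntra)
    geo <- geometry(net)
    y <- boundaryFraction(geo$L[adj$src], sigmaZ)
    z <- neighbourFraction(y, geo$R[adj$src], geo$R[adj$dst], adj$w, adj$p)
    Z <- Matrix::sparseMatrix(i = adj$src, j = adj$dst, x = z,
                              dims = c(nSec, nSec))
    rs <- Matrix::rowSums(Z)
    if (any(rs > 1)) {
      Z <- Matrix::Diagonal(x = ifelse(rs > 1, 1 / rs, 1)) %*% Z
      Z <- as(Z, "CsparseMatrix")
    }
    D <- geodesicCoefficients(Z, tsig)
    M <- diffusionMatrix(D, fpd)
  } else {
    empty <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                  x = numeric(0), dims = c(nSec, nSec))
    Z <- empty
    D <- as(Matrix::Diagonal(nSec), "CsparseMatrix")
    M <- D
  }
  new("SpreadOperators",
      Z = Z, D = D, M = M,
      Fat = .transportMatrix(nNeurons(net), fat, transportProbs),
      G = .transferMatrix(net, fst, pInter),
      sigmaZ = sigmaZ, fpd = fpd, fat = fat, fst = fst, tsig = tsig,
      pInter = pInter, transportProbs = transportProbs)
}
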