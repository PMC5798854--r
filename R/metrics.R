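#' @include AllClasses.R
NULL

#' Synaptic strength gradient (SSG)
#'
#' Difference between a neuron's summed presynaptic (incoming) and
#' postsynaptic (outgoing) connection strengths. Neurons with a high SSG
#' receive much and project little -- 'bottleneck' neurons. The default
#' follows the prose convention (incoming minus outgoing); the printed
#' equation orders the sums the other way round and is available via
#' `convention = "printed"`. SSG sums to zero over any network.
#'
#' @param net a [ColumnNetwork-class].
#' @param convention `"prose"` (incoming - outgoing, default) or
#'   `"printed"` (outgoing - incoming).
#' @return numeric per-neuron SSG.
#' @export
ssg <- function(net, convention = c("prose", "printed")) {
  convention <- match.arg(convention)
  N <- nNeurons(net)
  syn <- synapses(net)
  incoming <- outgoing <- numeric(N)
  if (nrow(syn)) {
    inc <- tapply(syn$r, syn$post, sum)
    out <- tapply(syn$r, syn$pre, sum)
    incoming[as.integer(names(inc))] <- inc
    outgoing[as.integer(names(out))] <- out
  }
  if (convention == "prose") incoming - outgoing else outgoing - incoming
}

#' Survival regression of death time on a neuronal characteristic
#'
#' Ordinary least squares of death times on a per-neuron predictor (SSG or
#' GDS); the R-squared is the survival characteristic. Neurons that never
#' died or have a non-finite predictor are excluded.
#'
#' @param values per-neuron predictor.
#' @param times per-neuron death times (NA = survived).
#' @return list with `slope`, `intercept`, `r.squared`, `n`.
#' @export
survivalRegression <- function(values, times) {
  keep <- is.finite(values) & is.finite(times)
  if (sum(keep) < 3)
    stop("need at least 3 dead neurons with a finite predictor")
  v <- values[keep]; tt <- times[keep]
  if (stats::var(v) == 0)
    stop("predictor has zero variance")
  fit <- lm(tt ~ v)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r.squared = summary(fit)$r.squared, n = sum(keep))
}

#' Dice similarity between two death orders, for every prefix size
#'
#' `D(n)` is the Dice coefficient between the sets of the first `n` neurons
#' to die in each run: `|G_s(n) intersect G_sbar(n)| / n`. Symmetric in its
#' arguments; `D(N) = 1` when both orders cover the same neurons.
#'
#' @param orderA,orderB integer permutations of the same neuron universe
#'   (death order, earliest first).
#' @return numeric `D(n)` for `n = 1..N`.
#' @export
diceCurve <- function(orderA, orderB) {
  N <- length(orderA)
  if (length(orderB) != N || !setequal(orderA, orderB))
    stop("death orders must cover the same neuron universe")
  if (anyDuplicated(orderA) || anyDuplicated(orderB))
    stop("death orders must not contain duplicates")
  posB <- match(orderA, orderB)
  vapply(seq_len(N), function(n) sum(posB[seq_len(n)] <= n) / n, numeric(1))
}

#' Time to convergence of a Dice curve
#'
#' The smallest prefix fraction after which the Dice similarity stays at or
#' above `tconv`: `n0 / N` with `n0` the smallest `n` such that
#' `D(m) >= tconv` for all `m >= n`. Identical orders give `1/N`. If the
#' curve never stays above the threshold the sentinel 1.0 is returned with
#' attribute `converged = FALSE` (with complete runs `D(N) = 1 >= tconv`
#' guarantees existence).
#'
#' @param D Dice curve from [diceCurve()].
#' @param tconv convergence threshold (default 0.8).
#' @param N neuron count (default `length(D)`).
#' @return tc as a fraction of `N`, with attribute `converged`.
#' @export
timeToConvergence <- function(D, tconv = 0.8, N = length(D)) {
  below <- which(D < tconv)
  if (length(below) && max(below) == N) {
    out <- 1.0
    attr(out, "converged") <- FALSE
    return(out)
  }
  n0 <- if (length(below)) max(below) + 1L else 1L
  out <- n0 / N
  attr(out, "converged") <- TRUE
  out
}

#' Pairwise time-to-convergence matrix for a list of death orders
#'
#' @param orders list of death orders (integer vectors over the same
#'   universe).
#' @param tconv convergence threshold.
#' @return symmetric numeric matrix of tc values (diagonal `1/N`).
#' @export
pairwiseTc <- function(orders, tconv = 0.8) {
  m <- length(orders)
  N <- length(orders[[1]])
  tc <- matrix(1 / N, m, m)
  if (m >= 2) {
    for (a in seq_len(m - 1)) for (b in seq((a + 1), m)) {
      v <- as.numeric(timeToConvergence(diceCurve(orders[[a]], orders[[b]]),
                                        tconv, N))
      tc[a, b] <- tc[b, a] <- v
    }
  }
  tc
}

#' Mean time-to-convergence matrix between run sets (CONV)
#'
#' `CONV[i, j]` is the mean tc over all pairs with one run in set `i` and
#' one in set `j`. Pairs of a run with itself are excluded (a self-pair's
#' tc is trivially `1/N` and would bias within-set means).
#'
#' @param tcMat pairwise tc matrix from [pairwiseTc()].
#' @param sets named list of integer index vectors into the runs.
#' @return symmetric matrix, `length(sets)` square.
#' @export
convMatrix <- function(tcMat, sets) {
  m <- length(sets)
  if (m == 0 || any(lengths(sets) == 0)) stop("sets must be non-empty")
  out <- matrix(NA_real_, m, m, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(m)) for (j in seq_len(m)) {
    a <- sets[[i]]; b <- sets[[j]]
    vals <- tcMat[a, b, drop = FALSE]
    self <- outer(a, b, "==")
    vals <- vals[!self]
    out[i, j] <- if (length(vals)) mean(vals) else NA_real_
  }
  out
}

#' Asymmetry of network damage (ASY)
#'
#' The maximum over time of the across-neuron sample standard deviation
#' (divisor N - 1) of neuronal toxicity. High values indicate damage
#' focused in particular neurons -- asymmetric breakdown.
#'
#' @param toxTrace matrix, rows = time points, columns = neurons (>= 2).
#' @return ASY.
#' @export
asymmetry <- function(toxTrace) {
  N <- ncol(toxTrace)
  if (N < 2) stop("need at least 2 neurons")
  mu <- rowMeans(toxTrace)
  sds <- sqrt(rowSums((toxTrace - mu)^2) / (N - 1))
  max(sds)
}

#' Time to network breakdown (TTNB)
#'
#' The timestep of the last cellular death, i.e. when every neuron has
#' died. Returns NA with attribute `censored = TRUE` when some neurons
#' survived to the horizon.
#'
#' @param x a [SimulationRun-class] or a per-neuron death-time vector.
#' @return TTNB in timesteps, with attribute `censored`.
#' @export
ttnb <- function(x) {
  dt <- if (is(x, "SimulationRun")) deathTimes(x) else x
  if (anyNA(dt)) {
    out <- NA_real_
    attr(out, "censored") <- TRUE
  } else {
    out <- max(dt)
    attr(out, "censored") <- FALSE
  }
  out
}

#' Summary metrics of one run
#'
#' TTNB, ASY and the SSG / GDS survival characteristics (regression
#' R-squared of death times on the synaptic strength gradient and on the
#' geodesic distance to the seed). GDS R-squared is only defined for
#' single-neuron seeds. Degenerate regressions (too few deaths, constant
#' predictor) yield NA.
#'
#' @param run a [SimulationRun-class].
#' @return list with `ttnb`, `censored`, `asy`, `ssgR2`, `gdsR2`, `nDead`.
#' @export
runMetrics <- function(run) {
  net <- runNetwork(run)
  dt <- deathTimes(run)
  tb <- ttnb(run)
  safeR2 <- function(vals) {
    tryCatch(survivalRegression(vals, dt)$r.squared, error = function(e) NA_real_)
  }
  gdsR2 <- NA_real_
  seedNeuron <- run@config$seedNeuron
  if (!is.null(seedNeuron) && !is.na(seedNeuron))
    gdsR2 <- safeR2(geodesicDistanceToSeed(net, seedNeuron))
  list(ttnb = as.numeric(tb), censored = attr(tb, "censored"),
       asy = asymmetry(toxicityTrace(run)),
       ssgR2 = safeR2(ssg(net)), gdsR2 = gdsR2,
       nDead = sum(!is.na(dt)))
}
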