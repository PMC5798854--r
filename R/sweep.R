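#' @include engine.R metrics.R
NULL

#' The eight factorial parameter menus
#'
#' Two connectivity instances x two solubility regimes x 17 seeds x two
#' misfolding rates x three diffusion speeds x three active-transport
#' strengths x three transfer/toxic-effect modes x three spread
#' selectivities: 11016 combinations in the full design.
#'
#' @return named list of eight menus, in design order.
#' @export
sweepMenus <- function() {
  list(instance = 1:2,
       solubility = c("soluble", "insoluble"),
       seed = seedMenu(),
       RM = c(0.08, 0.09),
       sigmaZ = c(0, 50, 500),
       fat = c(0, 1e-4, 1e-3),
       transferMode = .TRANSFER_MODES,
       pInter = c(0.01, 1, 100))
}

#' Enumerate a factorial design
#'
#' Cartesian product of the menus in a fixed documented order: the first
#' menu varies fastest (column-major, as `expand.grid`). Run ids are the
#' stable row numbers of this enumeration.
#'
#' @param menus named list of parameter menus (as [sweepMenus()]).
#' @return data.frame, one row per configuration, with a `runId` column.
#' @export
enumerateDesign <- function(menus = sweepMenus()) {
  stopifnot(length(menus) > 0, all(lengths(menus) > 0))
  d <- expand.grid(menus, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  d$runId <- seq_len(nrow(d))
  d
}

#' Parameter-value run sets H
#'
#' One set per (parameter, level) pair present in the design: all runs that
#' share that level. The full eight-menu design yields 35 sets
#' (2+2+17+2+3+3+3+3).
#'
#' @param design data.frame from [enumerateDesign()].
#' @param parameters which design columns to group by (default: all but
#'   `runId`).
#' @return named list of integer row-index vectors.
#' @export
hSets <- function(design, parameters = setdiff(names(design), "runId")) {
  sets <- list()
  for (p in parameters) {
    for (lev in unique(design[[p]])) {
      sets[[paste0(p, "=", lev)]] <- which(design[[p]] == lev)
    }
  }
  sets
}

# masterSeed for one design row and replicate; keep well below 2^31
.runSeed <- function(baseSeed, runId, rep) {
  (abs(baseSeed) * 7919 + runId * 131 + rep * 17) %% 2000000011
}

#' Run a (subset of a) factorial sweep
#'
#' Executes one simulation per design row and replicate on a shared set of
#' connectivity instances, collects per-run metrics (TTNB, ASY, SSG and GDS
#' survival characteristics), the pairwise time-to-convergence table over
#' completed runs and the CONV matrix over the design's parameter-value
#' sets. Deterministic for fixed `(design, baseSeed)`. Censored runs are
#' excluded from tc/CONV and counted.
#'
#' @param design data.frame from [enumerateDesign()] (desk-scale subset).
#' @param networkConfig generator config for the connectivity instances.
#' @param instanceSeeds seeds of the connectivity instances referenced by
#'   the design's `instance` column.
#' @param replicates replicate simulations per design row.
#' @param baseSeed base of all run master seeds.
#' @param horizon step budget per run.
#' @param overrides named list of [simulationConfig()] overrides applied to
#'   every run.
#' @param keepRuns keep the full [SimulationRun-class] objects?
#' @param verbose print one line per run.
#' @return list with `metrics` (data.frame), `tc` (pairwise matrix over
#'   completed runs), `conv` (CONV matrix), `sets`, `design`, `nCensored`
#'   and (optionally) `runs`.
#' @export
runSweep <- function(design,
                     networkConfig = miniNetworkConfig(),
                     instanceSeeds = c(101L, 202L),
                     replicates = 1L,
                     baseSeed = 1L,
                     horizon = 8000L,
                     overrides = list(),
                     keepRuns = TRUE,
                     verbose = FALSE) {
  instances <- sort(unique(if ("instance" %in% names(design)) design$instance else 1L))
  nets <- lapply(instances, function(i)
    buildNetwork(networkConfig, instanceSeeds[i]))
  names(nets) <- as.character(instances)
  rows <- list()
  runs <- list()
  orders <- list()
  runMeta <- integer(0)
  k <- 0L
  for (ri in seq_len(nrow(design))) {
    row <- design[ri, ]
    for (rep in seq_len(replicates)) {
      k <- k + 1L
      args <- list(network = nets[[as.character(
                     if ("instance" %in% names(row)) row$instance else 1L)]],
                   horizon = horizon,
                   masterSeed = as.integer(.runSeed(baseSeed, row$runId, rep)))
      for (p in intersect(names(row), c("solubility", "seed", "RM", "sigmaZ",
                                        "fat", "transferMode", "pInter")))
        args[[p]] <- row[[p]]
      args <- utils::modifyList(args, overrides)
      run <- runSimulation(do.call(simulationConfig, args))
      met <- runMetrics(run)
      rows[[k]] <- data.frame(runId = row$runId, replicate = rep,
                              row[setdiff(names(row), "runId")],
                              ttnb = met$ttnb, censored = met$censored,
                              asy = met$asy, ssgR2 = met$ssgR2,
                              gdsR2 = met$gdsR2, nDead = met$nDead,
                              row.names = NULL)
      orders[[k]] <- deathOrder(run)$neuron
      runMeta[k] <- row$runId
      if (keepRuns) runs[[k]] <- run
      if (verbose)
        message(sprintf("run %d rep %d: ttnb=%s asy=%.4g", row$runId, rep,
                        format(met$ttnb), met$asy))
    }
  }
  metrics <- do.call(rbind, rows)
  complete <- which(!metrics$censored)
  tc <- NULL; conv <- NULL; sets <- hSets(design)
  if (length(complete) >= 2) {
    tc <- pairwiseTc(orders[complete],
                     tconv = if (!is.null(overrides$tconv)) overrides$tconv else 0.8)
    # map design-row sets onto completed-run indices
    runSets <- lapply(sets, function(s) which(runMeta[complete] %in% design$runId[s]))
    runSets <- runSets[lengths(runSets) > 0]
    if (length(runSets)) conv <- convMatrix(tc, runSets)
  }
  out <- list(metrics = metrics, tc = tc, conv = conv, sets = sets,
              design = design, nCensored = sum(metrics$censored))
  if (keepRuns) out$runs <- runs
  out
}
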