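#' @include network.R engine.R
NULL

#' Write a network as two TSV tables
#'
#' Neuron table (`id`, `column`, `layer`, `type`, geometry columns) and
#' edge-list table (`pre`, `pre_section`, `post`, `post_section`, `r`).
#' Deterministic row order, so identical networks serialise byte-identically.
#'
#' @param net a [ColumnNetwork-class].
#' @param neuronsFile,synapsesFile output paths.
#' @return invisibly, the two paths.
#' @export
writeNetwork <- function(net, neuronsFile, synapsesFile) {
  geo <- geometry(net)
  nrn <- neurons(net)
  wide <- cbind(nrn,
                matrix(rbind(geo$D, geo$L), nrow = nrow(nrn), byrow = TRUE,
                       dimnames = list(NULL, c("D1", "L1", "D2", "L2", "D3", "L3"))))
  write.table(wide, neuronsFile, sep = "\t", quote = FALSE, row.names = FALSE)
  syn <- synapses(net)
  out <- data.frame(pre = syn$pre, pre_section = 3L, post = syn$post,
                    post_section = syn$postSection, r = syn$r)
  write.table(out, synapsesFile, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(neuronsFile, synapsesFile))
}

#' Read a network written by [writeNetwork()]
#'
#' @param neuronsFile,synapsesFile input paths.
#' @param K number of columns (default: max column id present).
#' @param pInter intercolumnar spread selectivity to attach.
#' @return a [ColumnNetwork-class].
#' @export
readNetwork <- function(neuronsFile, synapsesFile, K = NULL, pInter = 1) {
  nrn <- read.delim(neuronsFile, stringsAsFactors = FALSE)
  syn <- read.delim(synapsesFile, stringsAsFactors = FALSE)
  geo <- data.frame(
    D = as.numeric(t(as.matrix(nrn[, c("D1", "D2", "D3")]))),
    L = as.numeric(t(as.matrix(nrn[, c("L1", "L2", "L3")]))))
  synDf <- if (nrow(syn)) {
    data.frame(pre = syn$pre, post = syn$post,
               postSection = syn$post_section, r = syn$r)
  } else NULL
  columnNetwork(nrn[, c("column", "layer", "type")], synDf, geometry = geo,
                K = if (is.null(K)) max(nrn$column) else K, pInter = pInter)
}

#' Write the death order of a run as CSV
#'
#' Columns: rank, neuron_id, t, column, layer, type.
#'
#' @param run a [SimulationRun-class].
#' @param file output path.
#' @return invisibly, the path.
#' @export
writeDeathOrder <- function(run, file) {
  d <- deathOrder(run)
  names(d)[names(d) == "neuron"] <- "neuron_id"
  write.table(d, file, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write the spike log of a run as TSV (time_ms, neuron_id)
#'
#' @param run a [SimulationRun-class].
#' @param file output path.
#' @return invisibly, the path.
#' @export
writeSpikeLog <- function(run, file) {
  s <- spikeLog(run)
  write.table(data.frame(time_ms = s$time_ms, neuron_id = s$neuron),
              file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write the summary metrics of a run as JSON
#'
#' @param run a [SimulationRun-class].
#' @param file output path.
#' @return invisibly, the metrics list.
#' @export
writeRunMetrics <- function(run, file) {
  met <- runMetrics(run)
  jsonlite::write_json(met, file, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(met)
}

#' Dump a sparse operator matrix as coordinate triplets
#'
#' Plain-text `row col value` table (1-based indices) for inspection.
#'
#' @param M a sparse Matrix (e.g. from [operatorMatrix()]).
#' @param file output path.
#' @return invisibly, the path.
#' @export
writeSparseTriplets <- function(M, file) {
  Tm <- as(as(M, "CsparseMatrix"), "TsparseMatrix")
  ord <- order(Tm@i, Tm@j)
  write.table(data.frame(row = Tm@i[ord] + 1L, col = Tm@j[ord] + 1L,
                         value = Tm@x[ord]),
              file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write a simulation configuration as YAML
#'
#' Network objects are not serialised; the generator config and seeds are.
#'
#' @param config a [simulationConfig()].
#' @param file output path.
#' @return invisibly, the path.
#' @export
writeSimulationConfig <- function(config, file) {
  cfg <- unclass(config)
  cfg$network <- NULL
  cfg$spiking <- unclass(cfg$spiking)
  nc <- unclass(cfg$networkConfig)
  nc$composition <- as.list(nc$composition)
  nc$density <- list(types = colnames(nc$density),
                     values = as.numeric(nc$density))
  cfg$networkConfig <- nc
  yaml::write_yaml(cfg, file)
  invisible(file)
}

#' Read a simulation configuration written by [writeSimulationConfig()]
#'
#' @param file input path.
#' @return a [simulationConfig()].
#' @export
readSimulationConfig <- function(file) {
  y <- yaml::read_yaml(file)
  nc <- y$networkConfig
  dens <- matrix(nc$density$values, 4, 4,
                 dimnames = list(nc$density$types, nc$density$types))
  netCfg <- networkConfig(K = nc$K,
                          composition = as.data.frame(nc$composition,
                                                      stringsAsFactors = FALSE),
                          density = dens, interScale = nc$interScale,
                          strengthRange = unlist(nc$strengthRange),
                          geometry = lapply(nc$geometry, unlist),
                          pInter = nc$pInter)
  sp <- do.call(spikingParams, utils::modifyList(
    list(), y$spiking[c("Vrest", "driveRate", "driveAmp", "synGain", "inhGain")]))
  simulationConfig(networkConfig = netCfg,
                   networkSeed = y$networkSeed,
                   solubility = y$solubility, seed = y$seed,
                   seedExtraCp = y$seedExtraCp, RM = y$RM, sigmaZ = y$sigmaZ,
                   fat = y$fat, transferMode = y$transferMode,
                   pInter = y$pInter, fpd = y$fpd, RPn = y$RPn, RCn = y$RCn,
                   RPp = y$RPp, RCp = y$RCp, Cnn = y$Cnn, Cpn = y$Cpn,
                   Cmax = y$Cmax, insolubleCp0 = y$insolubleCp0,
                   tconv = y$tconv, dt = y$dt, horizon = y$horizon,
                   traceStride = y$traceStride, tsig = y$tsig,
                   transportProbs = unlist(y$transportProbs),
                   toxicGain = y$toxicGain, spiking = sp,
                   processes = unlist(y$processes),
                   stopWhenDead = y$stopWhenDead,
                   masterSeed = y$masterSeed)
}
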