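#' @include AllGenerics.R
NULL

#' @rdname nNeurons
#' @export
setMethod("nNeurons", "ColumnNetwork", function(x) nrow(x@neurons))

#' @rdname nNeurons
#' @export
setMethod("nNeurons", "ProteinState", function(x) length(x@Cn) %/% 3L)

#' @rdname nNeurons
#' @export
setMethod("nNeurons", "SimulationRun", function(x) length(x@deathTime))

#' @rdname nColumns
#' @export
setMethod("nColumns", "ColumnNetwork", function(x) x@K)

#' @rdname neurons
#' @export
setMethod("neurons", "ColumnNetwork", function(x) x@neurons)

#' @rdname synapses
#' @export
setMethod("synapses", "ColumnNetwork", function(x) x@synapses)

#' @rdname geometry
#' @export
setMethod("geometry", "ColumnNetwork", function(x) x@geometry)

#' @rdname sectionVolumes
#' @export
setMethod("sectionVolumes", "ColumnNetwork", function(x) x@geometry$V)

#' @rdname normalConcentration
#' @export
setMethod("normalConcentration", "ProteinState", function(x) x@Cn)

#' @rdname pathogenicConcentration
#' @export
setMethod("pathogenicConcentration", "ProteinState", function(x) x@Cp)

#' @rdname deathOrder
#' @export
setMethod("deathOrder", "SimulationRun", function(x) x@deathOrder)

#' @rdname deathTimes
#' @export
setMethod("deathTimes", "SimulationRun", function(x) x@deathTime)

#' @rdname toxicityTrace
#' @export
setMethod("toxicityTrace", "SimulationRun", function(x) x@toxTrace)

#' @rdname spikeLog
#' @export
setMethod("spikeLog", "SimulationRun", function(x) x@spikes)

#' @rdname runConfig
#' @export
setMethod("runConfig", "SimulationRun", function(x) x@config)

#' @rdname runNetwork
#' @export
setMethod("runNetwork", "SimulationRun", function(x) x@network)

#' @rdname isCensored
#' @export
setMethod("isCensored", "SimulationRun", function(x) x@censored)

#' @rdname operatorMatrix
#' @export
setMethod("operatorMatrix", "SpreadOperators", function(x, which = "M") {
  which <- match.arg(which, c("Z", "D", "M", "Fat", "G"))
  slot(x, which)
})

setMethod("show", "ColumnNetwork", function(object) {
  cat("ColumnNetwork:", nNeurons(object), "neurons in", object@K, "columns\n")
  tab <- table(object@neurons$type)
  cat("  types:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  synapses:", nrow(object@synapses),
      sprintf("(%d intercolumnar)", sum(object@synapses$intercolumnar)), "\n")
  cat("  intercolumnar selectivity p:", object@pInter,
      " build seed:", object@buildSeed, "\n")
})

setMethod("show", "ProteinState", function(object) {
  N <- nNeurons(object)
  cat("ProteinState:", N, "neurons x 3 sections\n")
  cat(sprintf("  Cn in [%.4g, %.4g], Cp in [%.4g, %.4g]\n",
              min(object@Cn), max(object@Cn), min(object@Cp), max(object@Cp)))
})

setMethod("show", "SpreadOperators", function(object) {
  cat("SpreadOperators on", nrow(object@M), "sections\n")
  cat(sprintf("  sigma_z=%g f_pd=%g f_at=%g f_st=%g p_inter=%g t_sig=%g\n",
              object@sigmaZ, object@fpd, object@fat, object@fst,
              object@pInter, object@tsig))
})

setMethod("show", "SimulationRun", function(object) {
  nd <- sum(!is.na(object@deathTime))
  cat("SimulationRun:", nNeurons(object), "neurons,",
      object@completedSteps, "of", object@horizon, "steps\n")
  cat("  deaths:", nd, if (object@censored) "(censored)" else "(complete)", "\n")
  cat("  spikes:", nrow(object@spikes),
      " saturation events:", object@saturations, "\n")
})

setMethod("show", "ProteinWorld", function(object) {
  e <- object@state
  cat("ProteinWorld at step", e$t, "-", sum(e$alive), "of",
      length(e$alive), "neurons alive\n")
})
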