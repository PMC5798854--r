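#' @include AllClasses.R
NULL

#' Number of neurons
#' @param x a ColumnNetwork, ProteinState or SimulationRun.
#' @return integer count.
#' @export
setGeneric("nNeurons", function(x) standardGeneric("nNeurons"))

#' Number of cortical columns
#' @param x a ColumnNetwork.
#' @return integer count.
#' @export
setGeneric("nColumns", function(x) standardGeneric("nColumns"))

#' Neuron table accessor
#' @param x a ColumnNetwork.
#' @return data.frame of neurons.
#' @export
setGeneric("neurons", function(x) standardGeneric("neurons"))

#' Synapse table accessor
#' @param x a ColumnNetwork.
#' @return data.frame of synapses.
#' @export
setGeneric("synapses", function(x) standardGeneric("synapses"))

#' Section geometry accessor
#' @param x a ColumnNetwork.
#' @return data.frame of section geometry in flattened order.
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))

#' Section volumes in flattened order
#' @param x a ColumnNetwork.
#' @return numeric vector of length 3N (cubic micrometres).
#' @export
setGeneric("sectionVolumes", function(x) standardGeneric("sectionVolumes"))

#' Normal-protein concentrations
#' @param x a ProteinState.
#' @return numeric vector, flattened section order.
#' @export
setGeneric("normalConcentration", function(x) standardGeneric("normalConcentration"))

#' Pathogenic-protein concentrations
#' @param x a ProteinState.
#' @return numeric vector, flattened section order.
#' @export
setGeneric("pathogenicConcentration", function(x) standardGeneric("pathogenicConcentration"))

#' Death order accessor
#' @param x a SimulationRun.
#' @return data.frame with rank, neuron, t.
#' @export
setGeneric("deathOrder", function(x) standardGeneric("deathOrder"))

#' Death times accessor
#' @param x a SimulationRun.
#' @return numeric per-neuron death step, NA for survivors.
#' @export
setGeneric("deathTimes", function(x) standardGeneric("deathTimes"))

#' Toxicity trace accessor
#' @param x a SimulationRun.
#' @return matrix time x neuron.
#' @export
setGeneric("toxicityTrace", function(x) standardGeneric("toxicityTrace"))

#' Spike log accessor
#' @param x a SimulationRun.
#' @return data.frame with step, time_ms, neuron.
#' @export
setGeneric("spikeLog", function(x) standardGeneric("spikeLog"))

#' Configuration echo accessor
#' @param x a SimulationRun.
#' @return list configuration.
#' @export
setGeneric("runConfig", function(x) standardGeneric("runConfig"))

#' Network used by a run
#' @param x a SimulationRun.
#' @return the ColumnNetwork.
#' @export
setGeneric("runNetwork", function(x) standardGeneric("runNetwork"))

#' Was the run censored at its horizon?
#' @param x a SimulationRun.
#' @return logical.
#' @export
setGeneric("isCensored", function(x) standardGeneric("isCensored"))

#' Extract one precomputed spread operator matrix
#' @param x a SpreadOperators object.
#' @param which one of "Z", "D", "M", "Fat", "G".
#' @return a sparse Matrix.
#' @export
setGeneric("operatorMatrix", function(x, which = "M") standardGeneric("operatorMatrix"))
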