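#' @include AllClasses.R
NULL

# ---- configuration ----------------------------------------------------------

.defaultGeometry <- function() {
  # Paper-style symbols D (diameter) and L (length) in micrometres; values
  # are package defaults (uniform across cell types), overridable in config.
  list(dendrite = c(D = 2, L = 150),
       soma = c(D = 20, L = 20),
       axon = c(D = 1, L = 300))
}

.defaultDensity <- function(value = NULL) {
  # Connection probability per ordered (pre-type, post-type) neuron pair
  # within a column. The published network takes its densities from an
  # external reference table; these are configurable stand-ins.
  if (is.null(value)) {
    m <- matrix(0.10, 4, 4, dimnames = list(.CELL_TYPES, .CELL_TYPES))
    m[c("FS", "LTS"), ] <- 0.15
  } else {
    m <- matrix(value, 4, 4, dimnames = list(.CELL_TYPES, .CELL_TYPES))
  }
  m
}

#' Per-column layer/type composition of the full-size network
#'
#' 470 neurons per column across layers 2/4/5/6; IB (intrinsically bursting)
#' cells are restricted to the deep layers 5 and 6, giving 14 layer-by-type
#' populations.
#'
#' @return data.frame with columns `layer`, `type`, `count` summing to 470.
#' @export
defaultComposition <- function() {
  data.frame(
    layer = c(2L, 2L, 2L, 4L, 4L, 4L, 5L, 5L, 5L, 5L, 6L, 6L, 6L, 6L),
    type = c("RS", "FS", "LTS", "RS", "FS", "LTS",
             "RS", "IB", "FS", "LTS", "RS", "IB", "FS", "LTS"),
    count = c(80L, 18L, 12L, 90L, 20L, 10L,
              65L, 25L, 20L, 10L, 60L, 30L, 20L, 10L),
    stringsAsFactors = FALSE
  )
}

#' Per-column composition of the reduced test network (10 neurons/column)
#' @return data.frame with columns `layer`, `type`, `count` summing to 10.
#' @export
miniComposition <- function() {
  data.frame(
    layer = c(2L, 2L, 4L, 4L, 5L, 5L, 5L, 6L),
    type = c("RS", "FS", "RS", "LTS", "RS", "IB", "FS", "RS"),
    count = c(2L, 1L, 2L, 1L, 1L, 1L, 1L, 1L),
    stringsAsFactors = FALSE
  )
}

#' Build a network-generator configuration
#'
#' @param K number of cortical columns.
#' @param composition data.frame `layer`, `type`, `count`: per-column
#'   population sizes.
#' @param density 4x4 matrix of connection probabilities per ordered
#'   (pre-type, post-type) neuron pair within a column, values in `[0, 1]`.
#' @param interScale multiplier applied to `density` for neuron pairs in
#'   different columns, in `[0, 1]`.
#' @param strengthRange range of the uniform synaptic strength distribution.
#' @param geometry list with `dendrite`, `soma`, `axon`, each `c(D=, L=)` in
#'   micrometres.
#' @param pInter intrinsic tendency of protein to spread via intercolumnar
#'   synapses (0.01 avoid, 1 neutral, 100 favour); attached to the network
#'   and overridable when building spread operators.
#' @return a list of class `networkConfig`.
#' @export
networkConfig <- function(K = 3L,
                          composition = defaultComposition(),
                          density = .defaultDensity(),
                          interScale = 0.1,
                          strengthRange = c(0.1, 1),
                          geometry = .defaultGeometry(),
                          pInter = 1) {
  stopifnot(K >= 1, is.data.frame(composition),
            all(c("layer", "type", "count") %in% names(composition)))
  if (!all(composition$type %in% .CELL_TYPES))
    stop("composition types must be RS, IB, FS or LTS")
  if (!all(composition$layer %in% .LAYERS))
    stop("composition layers must be 2, 4, 5 or 6")
  if (any(composition$count < 0))
    stop("composition counts must be non-negative")
  if (any(density < 0) || any(density > 1))
    stop("connection densities must lie in [0, 1]")
  if (interScale < 0 || interScale > 1)
    stop("interScale must lie in [0, 1]")
  stopifnot(length(strengthRange) == 2, strengthRange[1] > 0,
            strengthRange[2] >= strengthRange[1])
  cfg <- list(K = as.integer(K), composition = composition,
              density = density, interScale = interScale,
              strengthRange = strengthRange, geometry = geometry,
              pInter = pInter)
  class(cfg) <- "networkConfig"
  cfg
}

#' Full-size network configuration: 3 columns of 470 neurons
#' @param ... overrides passed to [networkConfig()].
#' @return a `networkConfig`.
#' @export
defaultNetworkConfig <- function(...) {
  networkConfig(K = 3L, composition = defaultComposition(), ...)
}

#' Reduced network configuration: 3 columns of 10 neurons
#'
#' Denser connectivity than the full-size default so that the tiny synapse
#' graph stays well connected; the first-class substrate for tests and
#' desk-scale sweeps.
#'
#' @param ... overrides passed to [networkConfig()].
#' @return a `networkConfig`.
#' @export
miniNetworkConfig <- function(...) {
  args <- list(...)
  defaults <- list(K = 3L, composition = miniComposition(),
                   density = .defaultDensity(0.35), interScale = 0.3)
  do.call(networkConfig, utils::modifyList(defaults, args))
}

# ---- construction -----------------------------------------------------------

.makeGeometry <- function(N, geom) {
  D <- rep(c(geom$dendrite["D"], geom$soma["D"], geom$axon["D"]), N)
  L <- rep(c(geom$dendrite["L"], geom$soma["L"], geom$axon["L"]), N)
  R <- pi * (D / 2)^2
  data.frame(neuron = rep(seq_len(N), each = 3), section = rep(1:3, N),
             D = unname(D), L = unname(L), R = unname(R), V = unname(L * R))
}

#' Low-level ColumnNetwork constructor
#'
#' Builds a validated network from explicit tables; used by [buildNetwork()]
#' and handy for constructing small fixtures. Base area and volume are
#' derived from `D` and `L`.
#'
#' @param neurons data.frame `column`, `layer`, `type` (ids assigned 1..N in
#'   row order; `excitatory` derived from type).
#' @param synapses data.frame `pre`, `post`, `postSection`, `r`
#'   (`intercolumnar` derived). Zero-strength rows are dropped.
#' @param geometry list as in [networkConfig()], or a full 3N-row data.frame
#'   with `D` and `L`.
#' @param K number of columns (default: max column present).
#' @param pInter intercolumnar spread selectivity.
#' @param buildSeed seed annotation.
#' @return a [ColumnNetwork-class].
#' @export
columnNetwork <- function(neurons, synapses = NULL, geometry = .defaultGeometry(),
                          K = max(neurons$column), pInter = 1, buildSeed = NA_integer_) {
  N <- nrow(neurons)
  nrn <- data.frame(id = seq_len(N), column = as.integer(neurons$column),
                    layer = as.integer(neurons$layer),
                    type = as.character(neurons$type),
                    excitatory = as.character(neurons$type) %in% .EXC_TYPES,
                    stringsAsFactors = FALSE)
  if (is.null(synapses) || nrow(synapses) == 0) {
    syn <- data.frame(pre = integer(0), post = integer(0),
                      postSection = integer(0), r = numeric(0),
                      intercolumnar = logical(0))
  } else {
    syn <- synapses[synapses$r > 0, , drop = FALSE]
    syn <- data.frame(pre = as.integer(syn$pre), post = as.integer(syn$post),
                      postSection = as.integer(syn$postSection), r = syn$r,
                      intercolumnar = nrn$column[syn$pre] != nrn$column[syn$post])
  }
  geo <- if (is.data.frame(geometry)) {
    data.frame(neuron = rep(seq_len(N), each = 3), section = rep(1:3, N),
               D = geometry$D, L = geometry$L,
               R = pi * (geometry$D / 2)^2,
               V = geometry$L * pi * (geometry$D / 2)^2)
  } else {
    .makeGeometry(N, geometry)
  }
  new("ColumnNetwork", neurons = nrn, synapses = syn, geometry = geo,
      K = as.integer(K), pInter = pInter, buildSeed = as.integer(buildSeed))
}

#' Generate a synthetic multi-column network
#'
#' Draws directed synapses independently per ordered neuron pair with
#' probability `density[pre type, post type]`, scaled by `interScale` when
#' the pair crosses columns. Every synapse originates at the presynaptic
#' axon; excitatory synapses land on the postsynaptic dendrite, inhibitory
#' synapses on the soma. Strengths are uniform on `strengthRange`.
#' Deterministic for a given `(config, seed)` pair.
#'
#' @param config a [networkConfig()].
#' @param seed integer RNG seed for the connectivity instance.
#' @return a [ColumnNetwork-class].
#' @examples
#' net <- buildNetwork(miniNetworkConfig(), seed = 1)
#' nNeurons(net)
#' @export
buildNetwork <- function(config = defaultNetworkConfig(), seed = 1L) {
  stopifnot(inherits(config, "networkConfig"))
  comp <- config$composition
  perColumn <- sum(comp$count)
  nrn <- do.call(rbind, lapply(seq_len(config$K), function(col) {
    data.frame(column = col,
               layer = rep(comp$layer, comp$count),
               type = rep(comp$type, comp$count),
               stringsAsFactors = FALSE)
  }))
  N <- nrow(nrn)
  stopifnot(N == config$K * perColumn)
  typeIdx <- match(nrn$type, .CELL_TYPES)
  syn <- withSeed(seed, {
    prob <- config$density[typeIdx, typeIdx, drop = FALSE]
    sameCol <- outer(nrn$column, nrn$column, "==")
    prob[!sameCol] <- prob[!sameCol] * config$interScale
    diag(prob) <- 0
    hit <- which(matrix(runif(N * N), N, N) < prob, arr.ind = TRUE)
    r <- runif(nrow(hit), config$strengthRange[1], config$strengthRange[2])
    data.frame(pre = as.integer(hit[, 1]), post = as.integer(hit[, 2]),
               postSection = ifelse(nrn$type[hit[, 1]] %in% .EXC_TYPES, 1L, 2L),
               r = r)
  })
  # stable order so serialisation is byte-identical for a given seed
  if (nrow(syn)) syn <- syn[order(syn$pre, syn$post), , drop = FALSE]
  rownames(syn) <- NULL
  columnNetwork(nrn, syn, geometry = config$geometry, K = config$K,
                pInter = config$pInter, buildSeed = seed)
}

#' Expected synapse count of a generator configuration
#'
#' Closed-form sum of `density * n_pre * n_post` over ordered type pairs and
#' column pairs; the mean of the binomial draw [buildNetwork()] performs.
#'
#' @param config a [networkConfig()].
#' @return list with `mean` and `sd` of the synapse count.
#' @export
expectedSynapseCount <- function(config) {
  comp <- config$composition
  perColumn <- sum(comp$count)
  typeCount <- tapply(comp$count, comp$type, sum)
  typeCount <- setNames(as.numeric(typeCount[.CELL_TYPES]), .CELL_TYPES)
  typeCount[is.na(typeCount)] <- 0
  K <- config$K
  m <- 0; v <- 0
  for (a in .CELL_TYPES) for (b in .CELL_TYPES) {
    nIntra <- K * (typeCount[a] * typeCount[b] - (a == b) * typeCount[a])
    nInter <- K * (K - 1) * typeCount[a] * typeCount[b]
    pIntra <- config$density[a, b]
    pInter <- config$density[a, b] * config$interScale
    m <- m + nIntra * pIntra + nInter * pInter
    v <- v + nIntra * pIntra * (1 - pIntra) + nInter * pInter * (1 - pInter)
  }
  list(mean = unname(m), sd = unname(sqrt(v)))
}

# ---- section-level adjacency ------------------------------------------------

#' Section-level weighted directed adjacency
#'
#' Intracellular edges run dendrite-soma and soma-axon in both directions
#' with weight `wIntra = 20`; intercellular edges run from the presynaptic
#' axon to the postsynaptic section with weight equal to the synaptic
#' strength `r`. Spread selectivity `p` is attached per edge: `pInter` for
#' intercolumnar synapses, 1 otherwise.
#'
#' @param net a [ColumnNetwork-class].
#' @param pInter selectivity override (default: the value stored in `net`).
#' @param wIntra intracellular edge weight.
#' @return data.frame `src`, `dst` (flattened section indices), `w`, `p`,
#'   `intracellular`, `intercolumnar`.
#' @export
sectionAdjacency <- function(net, pInter = NULL, wIntra = 20) {
  if (is.null(pInter)) pInter <- net@pInter
  N <- nNeurons(net)
  d <- 3 * seq_len(N) - 2L
  s <- d + 1L
  a <- d + 2L
  intra <- data.frame(src = c(d, s, s, a), dst = c(s, d, a, s),
                      w = wIntra, p = 1,
                      intracellular = TRUE, intercolumnar = FALSE)
  syn <- synapses(net)
  if (nrow(syn)) {
    inter <- data.frame(src = 3L * syn$pre,
                        dst = 3L * (syn$post - 1L) + syn$postSection,
                        w = syn$r,
                        p = ifelse(syn$intercolumnar, pInter, 1),
                        intracellular = FALSE,
                        intercolumnar = syn$intercolumnar)
    rbind(intra, inter)
  } else intra
}

# ---- geodesic distance to seed ----------------------------------------------

#' Hop distance from a seed neuron on the synapse graph (GDS)
#'
#' Shortest hop counts from `seedNeuron` to every neuron on the neuron-level
#' synapse graph. By default distances follow synapse direction (anterograde,
#' matching the modelled spread bias); set `directed = FALSE` for the
#' undirected variant. Unreachable neurons get `Inf`.
#'
#' @param net a [ColumnNetwork-class].
#' @param seedNeuron neuron id.
#' @param directed follow synapse direction?
#' @return numeric vector of length N; `GDS[seedNeuron] == 0`.
#' @export
geodesicDistanceToSeed <- function(net, seedNeuron, directed = TRUE) {
  N <- nNeurons(net)
  if (length(seedNeuron) != 1 || is.na(seedNeuron) ||
      seedNeuron < 1 || seedNeuron > N)
    stop("seedNeuron must be a single neuron id in 1..", N)
  syn <- synapses(net)
  g <- igraph::graph_from_data_frame(
    data.frame(from = syn$pre, to = syn$post),
    directed = TRUE,
    vertices = data.frame(name = seq_len(N)))
  d <- igraph::distances(g, v = as.character(seedNeuron),
                         to = as.character(seq_len(N)),
                         mode = if (directed) "out" else "all",
                         weights = NA)
  as.numeric(d[1, ])
}
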