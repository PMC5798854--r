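# Shared fixtures and independent oracles, built in code.

.fixtureEnv <- new.env()

# The reduced 30-neuron network, built once per test session.
miniNet <- function(seed = 101L) {
  key <- paste0("mini", seed)
  if (is.null(.fixtureEnv[[key]]))
    .fixtureEnv[[key]] <- buildNetwork(miniNetworkConfig(), seed = seed)
  .fixtureEnv[[key]]
}

# A hand-built chain network: A -> B -> C (axon to dendrite), strengths given.
chainNet <- function(r = c(0.5, 0.25)) {
  columnNetwork(
    neurons = data.frame(column = c(1, 1, 1), layer = c(2, 2, 2),
                         type = c("RS", "RS", "RS")),
    synapses = data.frame(pre = c(1, 2), post = c(2, 3),
                          postSection = c(1, 1), r = r),
    K = 3)
}

# Independent breadth-first search oracle on a directed edge list.
bfsOracle <- function(pre, post, seed, N) {
  dist <- rep(Inf, N)
  dist[seed] <- 0
  frontier <- seed
  while (length(frontier)) {
    nxt <- unique(post[pre %in% frontier])
    nxt <- nxt[!is.finite(dist[nxt])]
    if (!length(nxt)) break
    dist[nxt] <- dist[frontier[1]] + 1
    frontier <- nxt
  }
  dist
}
# (frontier always holds nodes of one BFS layer, so frontier[1]'s distance
# is the layer depth)

# Independent brute-force push oracle for the geodesic coefficients: one
# source at a time, dense arithmetic, explicit per-round loops. Each round,
# every section holding more than tsig re-pushes its held mass through its
# own z row (keeping the 1 - sum(z) retention); held mass at or below tsig
# settles where it is.
brutePush <- function(Z, source, tsig) {
  n <- nrow(Z)
  Zm <- as.matrix(Z)
  retain <- 1 - rowSums(Zm)
  settled <- numeric(n)
  pending <- numeric(n)
  pending[source] <- 1
  for (round in 1:100000) {
    if (all(pending <= tsig)) {
      settled <- settled + pending
      return(settled)
    }
    nxt <- numeric(n)
    for (s in seq_len(n)) {
      if (pending[s] == 0) next
      if (pending[s] <= tsig) {
        settled[s] <- settled[s] + pending[s]
      } else {
        settled[s] <- settled[s] + pending[s] * retain[s]
        for (d in seq_len(n))
          nxt[d] <- nxt[d] + pending[s] * Zm[s, d]
      }
    }
    pending <- nxt
  }
  stop("oracle push did not converge")
}

# Brute-force Dice curve via explicit set intersection.
bruteDice <- function(a, b) {
  vapply(seq_along(a), function(n)
    length(intersect(a[seq_len(n)], b[seq_len(n)])) / n, numeric(1))
}

# Brute-force time to convergence from the definition.
bruteTc <- function(D, tconv, N) {
  for (n in seq_len(N)) {
    if (all(D[n:N] >= tconv)) return(n / N)
  }
  NA_real_
}

# A tiny two-neuron network joined by one synapse, for transfer tests.
pairNet <- function(r = 0.5, postSection = 1L) {
  columnNetwork(
    neurons = data.frame(column = c(1, 2), layer = c(2, 2),
                         type = c("RS", "RS")),
    synapses = data.frame(pre = 1, post = 2, postSection = postSection, r = r),
    K = 3)
}

# Uniform type-by-type density matrix.
densityMatrix <- function(v) {
  types <- c("RS", "IB", "FS", "LTS")
  matrix(v, 4, 4, dimnames = list(types, types))
}
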