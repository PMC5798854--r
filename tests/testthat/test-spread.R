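test_that("boundary fraction behaves like a Brownian escape probability", {
  expect_equal(boundaryFraction(0, 50), 0.5)
  expect_equal(boundaryFraction(100, 50), pnorm(-1), tolerance = 1e-12)
  expect_equal(boundaryFraction(100, 50), 0.158655, tolerance = 1e-4)
  # strictly increasing with diffusion speed at fixed length
  y <- boundaryFraction(rep(100, 4), c(10, 50, 200, 1000))
  expect_true(all(diff(y) > 0))
  expect_error(boundaryFraction(10, 0), "sigmaZ")
})

test_that("neighbour fraction combines area ratio, weight and selectivity", {
  expect_equal(neighbourFraction(0.2, 5, 5, 1, 1), 0.2)
  # small destination: z -> y * Rdst/Rsrc * w * p
  expect_equal(neighbourFraction(0.2, 10, 1, 2, 1), 0.2 * 0.1 * 2)
  # selectivity scales linearly
  expect_equal(neighbourFraction(0.2, 5, 5, 1, 0.01),
               neighbourFraction(0.2, 5, 5, 1, 1) * 0.01)
  expect_error(neighbourFraction(0.2, 0, 5, 1, 1), "area")
})

test_that("geodesic coefficients match an independent brute-force push", {
  # isolated section
  Z0 <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                             dims = c(1, 1))
  D0 <- geodesicCoefficients(Z0, 1e-6)
  expect_equal(as.numeric(D0), 1)

  # two-section chain with symmetric hops
  Z <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 1), x = c(0.1, 0.1),
                            dims = c(2, 2))
  D <- geodesicCoefficients(Z, 1e-6)
  for (s in 1:2)
    expect_equal(as.numeric(D[s, ]), brutePush(Z, s, 1e-6), tolerance = 1e-9)

  # random 5-section toys, per-source unit impulses
  withr::with_seed(9, {
    for (rep in 1:5) {
      m <- matrix(runif(25, 0, 0.3) * (matrix(runif(25), 5) < 0.5), 5, 5)
      diag(m) <- 0
      m <- sweep(m, 1, pmax(1, rowSums(m) / 0.9), "/")  # rows capped < 1
      Zr <- as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
      Dr <- geodesicCoefficients(Zr, 1e-6)
      expect_equal(unname(Matrix::rowSums(Dr)), rep(1, 5), tolerance = 1e-12)
      for (s in 1:5)
        expect_equal(as.numeric(Dr[s, ]), brutePush(Zr, s, 1e-6),
                     tolerance = 1e-6)
    }
  })
})

test_that("a high significance threshold reduces to the one-hop push", {
  Z <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 1), x = c(0.1, 0.2),
                            dims = c(2, 2))
  D <- geodesicCoefficients(Z, tsig = 0.5)  # above every z: no recursion
  expect_equal(as.matrix(D), matrix(c(0.9, 0.2, 0.1, 0.8), 2),
               ignore_attr = TRUE)
})

test_that("uncapped z rows are rejected", {
  Z <- Matrix::sparseMatrix(i = 1, j = 2, x = 1.5, dims = c(2, 2))
  expect_error(geodesicCoefficients(Z, 1e-6), "sum to at most 1")
})

test_that("diffusion matrix is row-stochastic and fpd = 0 is the identity", {
  net <- miniNet()
  ops <- buildSpreadOperators(net, sigmaZ = 50, fpd = 0.05)
  M <- operatorMatrix(ops, "M")
  expect_equal(unname(Matrix::rowSums(M)), rep(1, nrow(M)), tolerance = 1e-12)
  D <- operatorMatrix(ops, "D")
  expect_equal(as.matrix(diffusionMatrix(D, 0)),
               diag(nrow(D)), ignore_attr = TRUE, tolerance = 1e-12)

  st <- proteinState(0.01, 0.002, nNeurons = nNeurons(net))
  un <- applyDiffusion(st, diffusionMatrix(D, 0), sectionVolumes(net))
  expect_equal(normalConcentration(un), normalConcentration(st))
})

test_that("passive diffusion conserves total amount", {
  net <- miniNet()
  V <- sectionVolumes(net)
  ops <- buildSpreadOperators(net, sigmaZ = 500, fpd = 0.05)
  st <- proteinState(rep(c(0.03, 0.01, 0.002), nNeurons(net)),
                     rep(c(0, 0.5, 0.001), nNeurons(net)))
  tot0 <- sum((normalConcentration(st) + pathogenicConcentration(st)) * V)
  for (i in 1:50)
    st <- applyDiffusion(st, operatorMatrix(ops, "M"), V)
  tot1 <- sum((normalConcentration(st) + pathogenicConcentration(st)) * V)
  expect_equal(tot1, tot0, tolerance = 1e-12)
})

test_that("diffusion into dead sections is blocked, outflow continues", {
  net <- pairNet(r = 0.5)
  V <- sectionVolumes(net)
  ops <- buildSpreadOperators(net, sigmaZ = 500, fpd = 0.05)
  st <- proteinState(c(0, 0, 0.5, 0, 0, 0), 0, nNeurons = 2)
  dead2 <- 4:6
  out <- applyDiffusion(st, operatorMatrix(ops, "M"), V, deadSections = dead2)
  # nothing entered the dead neuron
  expect_equal(normalConcentration(out)[4:6], c(0, 0, 0))
  # the live neuron's axon still lost protein intracellularly
  expect_lt(normalConcentration(out)[3], 0.5)
  # and mass is conserved
  expect_equal(sum(normalConcentration(out) * V), 0.5 * V[3],
               tolerance = 1e-12)
})

test_that("active transport favours the anterograde direction and conserves mass", {
  net <- chainNet()
  V <- sectionVolumes(net)
  st <- proteinState(1 / V, 0)   # one amount unit in every section
  expect_identical(activeTransportStep(st, V, fat = 0), st)
  out <- activeTransportStep(st, V, fat = 0.5)
  perNeuron0 <- tapply(normalConcentration(st) * V, rep(1:3, each = 3), sum)
  perNeuron1 <- tapply(normalConcentration(out) * V, rep(1:3, each = 3), sum)
  expect_equal(unname(perNeuron1), unname(perNeuron0), tolerance = 1e-12)
  # with equal amounts, the axon gains (0.154 in, 0.116 out) and the
  # dendrite loses (0.154 out, 0.116 in): the anterograde bias
  expect_gt(normalConcentration(out)[3] * V[3], 1)
  expect_lt(normalConcentration(out)[1] * V[1], 1)
  expect_error(activeTransportStep(st, V, fat = 2), "fat")
  expect_error(activeTransportStep(st, V, fat = 0.1, probs = c(0.5, 0.2, 0.2)),
               "sum to 1")
})

test_that("synaptic transfer moves protein only on spikes, conserving mass", {
  net <- pairNet(r = 0.5)
  V <- sectionVolumes(net)
  opsOn <- buildSpreadOperators(net, sigmaZ = 0, fst = 1)
  G <- operatorMatrix(opsOn, "G")
  st <- proteinState(c(0, 0, 0.4, 0, 0, 0), 0, nNeurons = 2)

  # no spike: unchanged
  expect_identical(synapticTransferStep(st, V, G, integer(0)), st)
  # fst = 0: G is empty, nothing moves
  G0 <- operatorMatrix(buildSpreadOperators(net, sigmaZ = 0, fst = 0), "G")
  expect_equal(length(G0@x), 0L)

  # single outgoing synapse: g = 0.154 * fst exactly
  out <- synapticTransferStep(st, V, G, spiked = 1L)
  moved <- 0.154 * 0.4 * V[3]
  expect_equal(normalConcentration(out)[3], (0.4 * V[3] - moved) / V[3])
  expect_equal(normalConcentration(out)[4], moved / V[4])
  tot0 <- sum(normalConcentration(st) * V)
  expect_equal(sum(normalConcentration(out) * V), tot0, tolerance = 1e-12)

  # dead postsynaptic neuron blocks the transfer
  kept <- synapticTransferStep(st, V, G, spiked = 1L,
                               alive = c(TRUE, FALSE))
  expect_equal(normalConcentration(kept), normalConcentration(st))
})

test_that("saturation scales back inflow and keeps the residue at the source", {
  net <- pairNet(r = 0.5)
  V <- sectionVolumes(net)
  G <- operatorMatrix(buildSpreadOperators(net, sigmaZ = 0, fst = 1), "G")
  # destination dendrite nearly full; axon holds a lot in a large volume
  st <- proteinState(Cn = c(0, 0, 0.9, 0.98, 0, 0),
                     Cp = c(0, 0, 0, 0.019, 0, 0))
  out <- synapticTransferStep(st, V, G, spiked = 1L)
  expect_lte(normalConcentration(out)[4] + pathogenicConcentration(out)[4],
             1 + 1e-9)
  expect_equal(sum((normalConcentration(out) + pathogenicConcentration(out)) * V),
               sum((normalConcentration(st) + pathogenicConcentration(st)) * V),
               tolerance = 1e-12)
  expect_gt(attr(out, "saturated"), 0)
})

test_that("stronger intercolumnar selectivity speeds cross-column spread", {
  net <- miniNet()
  V <- sectionVolumes(net)
  otherCols <- which(rep(neurons(net)$column, each = 3) != 1)
  timeToReach <- function(p) {
    ops <- buildSpreadOperators(net, sigmaZ = 500, fpd = 0.05, pInter = p)
    st <- proteinState(0, 0, nNeurons = nNeurons(net))
    st@Cp[2] <- 0.5                     # soma of a column-1 neuron
    for (i in 1:400) {
      st <- applyDiffusion(st, operatorMatrix(ops, "M"), V)
      if (max(pathogenicConcentration(st)[otherCols]) > 1e-4) return(i)
    }
    Inf
  }
  expect_lt(timeToReach(100), timeToReach(1))
})
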