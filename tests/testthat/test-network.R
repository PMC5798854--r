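test_that("default network has the published structure", {
  net <- buildNetwork(defaultNetworkConfig(), seed = 101)
  expect_equal(nNeurons(net), 1410L)
  expect_equal(nColumns(net), 3L)
  expect_equal(unname(table(neurons(net)$column)), rep(470L, 3),
               ignore_attr = TRUE)
  expect_equal(nrow(geometry(net)), 3 * 1410)
})

test_that("section geometry derives area and volume from diameter and length", {
  net <- miniNet()
  geo <- geometry(net)
  expect_equal(geo$R, pi * (geo$D / 2)^2)
  expect_equal(geo$V, geo$L * geo$R)
  expect_true(all(geo$D > 0 & geo$L > 0))
})

test_that("zero densities give an empty synapse list and a valid network", {
  cfg <- miniNetworkConfig(density = densityMatrix(0))
  net <- buildNetwork(cfg, seed = 1)
  expect_equal(nrow(synapses(net)), 0L)
  expect_true(validObject(net))
})

test_that("generation is deterministic in (config, seed)", {
  a <- buildNetwork(miniNetworkConfig(), seed = 7)
  b <- buildNetwork(miniNetworkConfig(), seed = 7)
  c <- buildNetwork(miniNetworkConfig(), seed = 8)
  expect_identical(synapses(a), synapses(b))
  expect_identical(neurons(a), neurons(b))
  expect_false(identical(synapses(a), synapses(c)))
})

test_that("invalid generator configurations are rejected", {
  expect_error(networkConfig(density = densityMatrix(1.5)), "densities")
  expect_error(networkConfig(interScale = 2), "interScale")
  expect_error(networkConfig(composition = data.frame(
    layer = 3L, type = "RS", count = 5L)), "layer")
})

test_that("synapse counts match the binomial expectation over 20 draws", {
  cfg <- miniNetworkConfig()
  exp_ <- expectedSynapseCount(cfg)
  counts <- vapply(1:20, function(s) nrow(synapses(buildNetwork(cfg, s))),
                   numeric(1))
  se <- exp_$sd / sqrt(20)
  expect_lt(abs(mean(counts) - exp_$mean), 3 * se + 1e-9)
})

test_that("every generated synapse originates at an axon and lands per type", {
  net <- miniNet()
  syn <- synapses(net)
  nrn <- neurons(net)
  expect_true(all(syn$postSection[nrn$excitatory[syn$pre]] == 1))
  expect_true(all(syn$postSection[!nrn$excitatory[syn$pre]] == 2))
  expect_true(all(syn$r > 0))
})

test_that("section adjacency has the stated intracellular and synaptic edges", {
  lone <- columnNetwork(neurons = data.frame(column = 1, layer = 2, type = "RS"),
                        K = 1)
  adj <- sectionAdjacency(lone)
  expect_equal(nrow(adj), 4L)
  expect_true(all(adj$w == 20))
  expect_setequal(paste(adj$src, adj$dst),
                  c("1 2", "2 1", "2 3", "3 2"))

  net <- pairNet(r = 0.5)
  adj <- sectionAdjacency(net)
  synEdge <- adj[!adj$intracellular, ]
  expect_equal(nrow(synEdge), 1L)
  expect_equal(synEdge$src, 3L)        # axon of neuron 1
  expect_equal(synEdge$dst, 4L)        # dendrite of neuron 2
  expect_equal(synEdge$w, 0.5)
})

test_that("selectivity is attached per edge class", {
  net <- pairNet()                      # the pair crosses columns
  adj <- sectionAdjacency(net, pInter = 0.01)
  expect_equal(adj$p[!adj$intracellular], 0.01)
  expect_true(all(adj$p[adj$intracellular] == 1))
})

test_that("geodesic distance to seed matches an independent BFS", {
  net <- chainNet()
  expect_equal(geodesicDistanceToSeed(net, 1), c(0, 1, 2))
  expect_equal(geodesicDistanceToSeed(net, 3), c(Inf, Inf, 0))
  expect_equal(geodesicDistanceToSeed(net, 3, directed = FALSE), c(2, 1, 0))
  expect_error(geodesicDistanceToSeed(net, 99), "seedNeuron")

  # random 50-neuron graph vs oracle
  withr::with_seed(42, {
    pre <- sample(50, 120, replace = TRUE)
    post <- sample(50, 120, replace = TRUE)
    keep <- pre != post
    syn <- data.frame(pre = pre[keep], post = post[keep],
                      postSection = 1L, r = 0.5)
    syn <- syn[!duplicated(syn[, 1:2]), ]
    net50 <- columnNetwork(
      neurons = data.frame(column = 1, layer = 2, type = "RS")[rep(1, 50), ],
      synapses = syn, K = 1)
    for (seed in c(1, 17, 50)) {
      expect_equal(geodesicDistanceToSeed(net50, seed),
                   bfsOracle(syn$pre, syn$post, seed, 50))
    }
  })
})

test_that("neuron counts are conserved for any valid composition", {
  for (K in c(1L, 3L)) {
    cfg <- networkConfig(K = K, composition = miniComposition(),
                         density = densityMatrix(0.2))
    net <- buildNetwork(cfg, seed = 3)
    expect_equal(nNeurons(net), K * sum(miniComposition()$count))
  }
})
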