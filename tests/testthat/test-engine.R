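test_that("initialisation follows the solubility regime and seed spec", {
  net <- miniNet()
  wS <- initializeWorld(simulationConfig(network = net,
                                         solubility = "soluble"))
  sS <- worldState(wS)$state
  expect_equal(normalConcentration(sS), rep(0.01, 90))
  expect_equal(pathogenicConcentration(sS), rep(0.01, 90))

  wI <- initializeWorld(simulationConfig(network = net,
                                         solubility = "insoluble"))
  sI <- worldState(wI)$state
  expect_equal(pathogenicConcentration(sI), rep(1e-4, 90))

  wL <- initializeWorld(simulationConfig(network = net, seed = "L2RS"))
  st <- worldState(wL)
  seed <- st$seedNeuron
  nrn <- neurons(net)
  expect_equal(nrn$column[seed], 1L)
  expect_equal(nrn$layer[seed], 2L)
  expect_equal(nrn$type[seed], "RS")
  cp <- pathogenicConcentration(st$state)
  soma <- 3 * seed - 1
  expect_equal(cp[soma], 0.51)
  expect_equal(cp[-soma], rep(0.01, 89))

  expect_error(initializeWorld(simulationConfig(network = net, seed = "L6LTS")),
               "absent")
  expect_error(simulationConfig(seed = "L9XX"))
})

test_that("with all rates and fractions zero the protein state is frozen", {
  net <- miniNet()
  cfg <- simulationConfig(network = net, RM = 0, sigmaZ = 0, fat = 0,
                          RPn = 0, RPp = 0, RCn = 0, RCp = 0,
                          transferMode = "off_increase",
                          horizon = 50L, processes = c(toxicity = FALSE))
  w <- initializeWorld(cfg)
  before <- worldState(w)$state
  for (i in 1:50) stepWorld(w)
  after <- worldState(w)$state
  expect_equal(normalConcentration(after), normalConcentration(before))
  expect_equal(pathogenicConcentration(after), pathogenicConcentration(before))
})

test_that("a production-only step raises somata and nothing else", {
  net <- miniNet()
  cfg <- simulationConfig(network = net,
                          processes = c(misfolding = FALSE, clearance = FALSE,
                                        diffusion = FALSE, transport = FALSE,
                                        transfer = FALSE, spiking = FALSE,
                                        toxicity = FALSE),
                          horizon = 1L, masterSeed = 6L)
  w <- initializeWorld(cfg)
  before <- worldState(w)$state
  stepWorld(w)
  after <- worldState(w)$state
  soma <- 3 * seq_len(30) - 1
  delta <- normalConcentration(after) - normalConcentration(before)
  expect_true(all(delta[-soma] == 0))
  expect_true(any(delta[soma] != 0))
})

test_that("the process order is load-bearing", {
  # misfold-then-diffuse differs from diffuse-then-misfold on the same state
  net <- pairNet(r = 0.5)
  V <- sectionVolumes(net)
  ops <- buildSpreadOperators(net, sigmaZ = 500, fpd = 0.05)
  M <- operatorMatrix(ops, "M")
  st <- proteinState(c(0.3, 0.2, 0.1, 0, 0, 0), c(0, 0.4, 0.1, 0, 0, 0))
  a <- applyDiffusion(misfoldStep(st, 0.5), M, V)
  b <- misfoldStep(applyDiffusion(st, M, V), 0.5)
  expect_false(isTRUE(all.equal(pathogenicConcentration(a),
                                pathogenicConcentration(b))))
})

test_that("identical configuration and master seed replay end to end", {
  net <- miniNet()
  cfg <- simulationConfig(network = net, RM = 0.09, sigmaZ = 50,
                          fat = 1e-3, transferMode = "low_increase",
                          horizon = 2500L, masterSeed = 31L)
  a <- runSimulation(cfg)
  b <- runSimulation(cfg)
  expect_identical(deathOrder(a), deathOrder(b))
  expect_identical(deathTimes(a), deathTimes(b))
  expect_identical(toxicityTrace(a), toxicityTrace(b))
  expect_identical(spikeLog(a), spikeLog(b))
  expect_identical(runMetrics(a), runMetrics(b))
  c <- runSimulation(simulationConfig(network = net, RM = 0.09, sigmaZ = 50,
                                      fat = 1e-3, transferMode = "low_increase",
                                      horizon = 2500L, masterSeed = 32L))
  expect_false(identical(deathOrder(a), deathOrder(c)))
})

test_that("an insoluble high-pathology run breaks the whole network down", {
  net <- miniNet()
  cfg <- simulationConfig(network = net, solubility = "insoluble",
                          seed = "L2RS", RM = 0.09, sigmaZ = 500, fat = 1e-3,
                          horizon = 20000L, masterSeed = 1L)
  run <- runSimulation(cfg)
  expect_false(isCensored(run))
  expect_equal(nrow(deathOrder(run)), 30L)
  tb <- ttnb(run)
  expect_false(attr(tb, "censored"))
  expect_true(all(deathTimes(run) <= as.numeric(tb)))
})

test_that("the death order is a total order consistent with death times", {
  net <- miniNet()
  run <- runSimulation(simulationConfig(network = net, RM = 0.09,
                                        horizon = 3000L, masterSeed = 17L))
  d <- deathOrder(run)
  expect_false(any(duplicated(d$neuron)))
  expect_true(all(diff(d$t) >= 0))
  ties <- split(d$neuron, d$t)
  expect_true(all(vapply(ties, function(x) all(diff(x) > 0), logical(1))))
})
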