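test_that("production targets only the soma and matches its nominal mean", {
  st <- proteinState(0.01, 0.01, nNeurons = 4)
  withr::with_seed(1, {
    out <- productionStep(st, RPn = 2e-4, RPp = 2e-5)
  })
  notSoma <- setdiff(seq_len(12), 3 * (1:4) - 1)
  expect_equal(normalConcentration(out)[notSoma],
               normalConcentration(st)[notSoma])
  expect_equal(pathogenicConcentration(out)[notSoma],
               pathogenicConcentration(st)[notSoma])

  # RPp = 0: no pathogenic production (insoluble regime)
  withr::with_seed(1, out0 <- productionStep(st, RPn = 2e-4, RPp = 0))
  expect_equal(pathogenicConcentration(out0), pathogenicConcentration(st))

  # Monte-Carlo mean of the soma additions over many draws
  RPp <- 2e-5
  big <- proteinState(0.01, 0.01, nNeurons = 1e5)
  withr::with_seed(7, outB <- productionStep(big, RPn = 0, RPp = RPp))
  adds <- pathogenicConcentration(outB)[3 * (1:1e5) - 1] - 0.01
  se <- RPp / sqrt(1e5)                 # sd of a draw equals its mean
  expect_lt(abs(mean(adds) - RPp), 3 * se)
})

test_that("dead neurons neither produce nor clear", {
  st <- proteinState(0.01, 0.01, nNeurons = 2)
  alive <- c(TRUE, FALSE)
  withr::with_seed(3, out <- productionStep(st, 2e-4, 2e-5, alive = alive))
  expect_equal(normalConcentration(out)[4:6], rep(0.01, 3))
  withr::with_seed(3, out <- clearanceStep(st, 2e-4, 2e-5, alive = alive))
  expect_equal(normalConcentration(out)[4:6], rep(0.01, 3))
})

test_that("misfolding is the product law and conserves total protein", {
  st <- proteinState(0.5, 0.5, nNeurons = 1)
  out <- misfoldStep(st, RM = 1)
  expect_equal(normalConcentration(out), rep(0.25, 3))
  expect_equal(pathogenicConcentration(out), rep(0.75, 3))

  # no templating without a pathogenic seed
  st0 <- proteinState(0.4, 0, nNeurons = 2)
  expect_equal(misfoldStep(st0, RM = 1)@Cp, rep(0, 6))

  # conservation for arbitrary states and rates
  withr::with_seed(5, {
    for (i in 1:20) {
      cn <- runif(6, 0, 0.6); cp <- runif(6, 0, 0.4)
      s <- proteinState(cn, cp)
      o <- misfoldStep(s, RM = runif(1, 0, 1))
      expect_equal(o@Cn + o@Cp, cn + cp, tolerance = 1e-14)
      expect_true(all(o@Cn >= 0))
    }
  })
})

test_that("adaptive clearance rate has its closed-form anchor points", {
  expect_equal(adaptiveClearanceRate(0.01, 2e-5, 0.01), 2e-5)
  expect_equal(adaptiveClearanceRate(0, 2e-5, 0.01), 0)
  expect_equal(adaptiveClearanceRate(0.02, 2e-5, 0.01),
               2e-5 * log1p(2 * (exp(1) - 1)))
  expect_equal(adaptiveClearanceRate(0.02, 2e-5, 0.01) / 2e-5, 1.48988,
               tolerance = 1e-5)
  expect_error(adaptiveClearanceRate(0.01, 2e-5, 0), "level")
  expect_error(adaptiveClearanceRate(-1, 2e-5, 0.01), "non-negative")
})

test_that("clearance removes nothing at zero concentration or zero rate", {
  st <- proteinState(0.01, 0, nNeurons = 3)
  withr::with_seed(2, out <- clearanceStep(st, RCn = 2e-4, RCp = 2e-5))
  expect_equal(pathogenicConcentration(out), rep(0, 9))
  # insoluble regime: pathogenic clearance identically zero
  st2 <- proteinState(0.01, 0.3, nNeurons = 3)
  withr::with_seed(2, out2 <- clearanceStep(st2, RCn = 2e-4, RCp = 0))
  expect_equal(pathogenicConcentration(out2), rep(0.3, 9))
})

test_that("clearance at the normal level removes the nominal rate on average", {
  n <- 1e5
  st <- proteinState(rep(0.01, 3 * n), 0)
  withr::with_seed(11, out <- clearanceStep(st, RCn = 2e-4, RCp = 0,
                                            Cnn = 0.01))
  removed <- 0.01 - normalConcentration(out)
  se <- 2e-4 / sqrt(3 * n)
  expect_lt(abs(mean(removed) - 2e-4), 3 * se)
})

test_that("the point model keeps equilibrium without misfolding", {
  r0 <- pointModelRun(RM = 0, horizon = 1e5, seed = 4)
  expect_true(is.na(r0$lossTime))
  # mean-stationary around the normal levels
  se <- 0.0053 / sqrt(nrow(r0$trace) / 50)  # OU stationary sd, thinned
  expect_lt(abs(mean(r0$trace$Cn) - 0.05), 3 * se + 0.003)
  expect_lt(abs(mean(r0$trace$Cp) - 0.01), 0.002)
})

test_that("point-model trajectories replay exactly for a given seed", {
  a <- pointModelRun(RM = 0.0626, horizon = 5e4, seed = 9)
  b <- pointModelRun(RM = 0.0626, horizon = 5e4, seed = 9)
  expect_identical(a$trace, b$trace)
  expect_identical(a$lossTime, b$lossTime)
})

test_that("equilibrium-loss time is non-increasing in the misfolding rate", {
  g <- equilibriumLossGrid(c(0.060, 0.062, 0.0624, 0.0626, 0.065),
                           seeds = 1:5, horizon = 6e6)
  expect_true(all(diff(g$medianLossTime) <= 0))
  expect_true(all(g$nLost == 5))
})
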