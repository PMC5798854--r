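test_that("SSG follows the incoming-minus-outgoing convention and telescopes", {
  lone <- columnNetwork(neurons = data.frame(column = 1, layer = 2, type = "RS"),
                        K = 1)
  expect_equal(ssg(lone), 0)

  net <- pairNet(r = 0.5)
  expect_equal(ssg(net), c(-0.5, 0.5))
  expect_equal(ssg(net, convention = "printed"), c(0.5, -0.5))

  expect_equal(sum(ssg(miniNet())), 0, tolerance = 1e-12)
})

test_that("survival regression recovers exact linear relations", {
  v <- c(1, 2, 3, 4, 5)
  fit <- suppressWarnings(survivalRegression(v, 10 - 2 * v))
  expect_equal(fit$r.squared, 1)
  expect_equal(fit$slope, -2)
  expect_equal(fit$intercept, 10)
  expect_error(survivalRegression(rep(1, 5), 1:5), "variance")
  expect_error(survivalRegression(1:2, 1:2), "at least 3")
  # survivors and non-finite predictors are dropped
  fit2 <- suppressWarnings(survivalRegression(c(v, Inf), c(10 - 2 * v, 3)))
  expect_equal(fit2$n, 5)
})

test_that("shuffled predictors give the permutation-null R-squared", {
  n <- 20
  v <- seq_len(n)
  withr::with_seed(13, {
    r2 <- vapply(1:1000, function(i)
      survivalRegression(v, sample(n))$r.squared, numeric(1))
  })
  expect_lt(abs(mean(r2) - 1 / (n - 1)), 0.02)
})

test_that("Dice curves match brute-force set intersections", {
  expect_equal(diceCurve(1:4, 1:4), rep(1, 4))
  expect_equal(diceCurve(c(1, 2, 3, 4), c(3, 4, 1, 2)), c(0, 0, 2/3, 1))
  expect_error(diceCurve(1:4, 1:5), "universe")
  expect_error(diceCurve(c(1, 1, 2), c(1, 2, 3)), "universe|duplicates")

  withr::with_seed(21, {
    for (i in 1:30) {
      N <- sample(5:50, 1)
      a <- sample(N); b <- sample(N)
      expect_equal(diceCurve(a, b), bruteDice(a, b))
      expect_equal(diceCurve(a, b), diceCurve(b, a))   # symmetry
    }
  })
})

test_that("time to convergence follows its definition", {
  expect_equal(as.numeric(timeToConvergence(rep(1, 10))), 1 / 10)
  D <- c(0, 0, 2/3, 1)
  expect_equal(as.numeric(timeToConvergence(D, 0.8)), 1)
  expect_equal(as.numeric(timeToConvergence(D, tconv = 0)), 1 / 4)
  # sentinel when the curve never stays above threshold
  bad <- c(1, 0.5, 0.5, 0.5)
  out <- timeToConvergence(bad, 0.8)
  expect_equal(as.numeric(out), 1)
  expect_false(attr(out, "converged"))

  withr::with_seed(22, {
    for (i in 1:30) {
      N <- sample(5:50, 1)
      D <- diceCurve(sample(N), sample(N))
      expect_equal(as.numeric(timeToConvergence(D, 0.8, N)),
                   bruteTc(D, 0.8, N))
    }
  })
})

test_that("the CONV matrix averages cross pairs and is symmetric", {
  # all runs identical: every cross tc is 1/N
  orders <- replicate(4, 1:10, simplify = FALSE)
  tc <- pairwiseTc(orders)
  conv <- convMatrix(tc, list(a = 1:2, b = 3:4))
  expect_equal(unname(conv), matrix(0.1, 2, 2))

  # hand-computed 2x2 example
  o <- list(c(1, 2, 3, 4), c(2, 1, 3, 4), c(3, 4, 1, 2), c(4, 3, 2, 1))
  tc <- pairwiseTc(o, tconv = 0.8)
  sets <- list(x = 1:2, y = 3:4)
  conv <- convMatrix(tc, sets)
  handXY <- mean(c(tc[1, 3], tc[1, 4], tc[2, 3], tc[2, 4]))
  expect_equal(conv["x", "y"], handXY)
  expect_equal(conv, Matrix::t(conv), ignore_attr = TRUE)
  # within-set means exclude the self pair
  expect_equal(conv["x", "x"], tc[1, 2])
  expect_error(convMatrix(tc, list(a = integer(0))), "non-empty")
})

test_that("asymmetry is the peak across-neuron toxicity spread", {
  expect_equal(asymmetry(matrix(0.3, 5, 4)), 0)
  expect_equal(asymmetry(matrix(c(0, 1), 1, 2)), sqrt(0.5))
  expect_equal(asymmetry(matrix(c(0, 1), 1, 2)), 0.70711, tolerance = 1e-5)
  tr <- matrix(c(0, 0, 0.2, 0.4), 2, 2, byrow = TRUE)
  expect_gte(asymmetry(rbind(tr, c(0, 1))), asymmetry(tr))  # max is monotone
  expect_error(asymmetry(matrix(0, 3, 1)), "2 neurons")
})

test_that("TTNB is the last death time, censored when neurons survive", {
  done <- c(10, 40, 25)
  out <- ttnb(done)
  expect_equal(as.numeric(out), 40)
  expect_false(attr(out, "censored"))
  expect_true(all(as.numeric(out) >= done))
  cen <- ttnb(c(10, NA, 25))
  expect_true(is.na(as.numeric(cen)))
  expect_true(attr(cen, "censored"))
})
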