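test_that("the model constructor zeroes the rate diagonal and stores E/S", {
  m <- h2mmModel(rates = matrix(c(9, 1 / 6.1, 1 / 27.5, 9), 2, byrow = TRUE),
                 E = c(0.40, 0.75), S = c(0.60, 0.60))
  expect_s4_class(m, "H2MMModel")
  expect_equal(diag(m@rates), c(0, 0))
  es <- stateES(m)
  expect_equal(es$E, c(0.40, 0.75))
  expect_equal(es$S, c(0.60, 0.60))
  expect_output(show(m), "H2MMModel")
})

test_that("the per-tick transition matrix is row-stochastic and guarded", {
  m <- h2mmModel(rates = matrix(c(0, 2, 0.5, 0), 2, byrow = TRUE),
                 E = c(0.4, 0.8), S = c(0.6, 0.6))
  A <- transitionMatrix(m)
  expect_equal(rowSums(A), c(1, 1))
  expect_equal(A[1, 2], 2 * 5e-5)
  fast <- h2mmModel(rates = matrix(c(0, 1e6, 1, 0), 2, byrow = TRUE),
                    E = c(0.4, 0.8), S = c(0.6, 0.6))
  expect_error(transitionMatrix(fast), "clock")
})

test_that("likelihood matches exhaustive enumeration on random instances", {
  set.seed(101)
  for (i in 1:50) {
    inst <- randomInstance()
    m <- instanceModel(inst)
    ll <- burstLogLik(m, list(dt = list(inst$dt), streams = list(inst$streams)))
    ref <- bruteLogLik(inst$dt, inst$streams, inst$pi, inst$A, inst$B)
    expect_equal(as.numeric(ll), ref, tolerance = 1e-10)
  }
})

test_that("Viterbi attains the enumerated maximal path probability", {
  set.seed(102)
  for (i in 1:50) {
    inst <- randomInstance()
    m <- instanceModel(inst)
    p <- viterbiPaths(m, list(dt = list(inst$dt),
                              streams = list(inst$streams)))[[1]]
    expect_length(p, inst$n)
    got <- pathProb(p, inst$dt, inst$streams, inst$pi, inst$A, inst$B)
    ref <- brutePathMax(inst$dt, inst$streams, inst$pi, inst$A, inst$B)
    expect_equal(got, ref, tolerance = 1e-10)
  }
})

test_that("per-burst log-likelihoods sum to the total", {
  bs <- simulateBurstSet(20, 2, 5, seed = 1)
  m <- h2mmModel(rates = matrix(c(0, 0.5, 0.2, 0), 2, byrow = TRUE),
                 E = c(0.40, 0.75), S = c(0.60, 0.60))
  ll <- burstLogLik(m, bs)
  expect_equal(sum(attr(ll, "perBurst")), as.numeric(ll))
  expect_length(attr(ll, "perBurst"), 20L)
})

test_that("EM increases the likelihood monotonically and converges", {
  bs <- simulateBurstSet(150, 2, 5, seed = 2)
  fit <- fitH2MM(bs, nStates = 2, restarts = 1, seed = 3, tol = 1e-4,
                 maxIter = 200)
  expect_s4_class(fit, "H2MMFit")
  expect_true(all(diff(fit@loglikTrace) > -1e-8))
  expect_true(fit@converged)
  expect_output(show(fit), "H2MMFit")
})

test_that("EM recovers two-state kinetics and emissions", {
  bs <- simulateBurstSet(500, 2, 5, seed = 4)
  fit <- fitH2MM(bs, nStates = 2, restarts = 2, seed = 4, tol = 1e-5)
  lab <- classifyStates(stateES(fit@model))
  fit@model@stateLabels <- lab
  tau <- dwellTimesFromModel(fit@model)
  expect_equal(unname(tau[["open"]]), 2, tolerance = 0.25)
  expect_equal(unname(tau[["closed"]]), 5, tolerance = 0.25)
  es <- stateES(fit@model)
  expect_equal(sort(es$E), c(0.40, 0.75), tolerance = 0.05)
})

test_that("refitting from the truth does not leave it", {
  bs <- simulateBurstSet(300, 2, 5, seed = 5)
  truth <- h2mmModel(initProb = c(2, 5) / 7,
                     rates = matrix(c(0, 1 / 2, 1 / 5, 0), 2, byrow = TRUE),
                     E = c(0.40, 0.75), S = c(0.60, 0.60))
  fit <- fitH2MM(bs, initial = truth, tol = 1e-5)
  expect_gte(fit@loglik, as.numeric(burstLogLik(truth, bs)))
  expect_equal(1 / fit@model@rates[1, 2], 2, tolerance = 0.3)
  expect_equal(1 / fit@model@rates[2, 1], 5, tolerance = 0.3)
})

test_that("BIC' is zero at the minimum and ranks models", {
  bp <- bicPrime(c(1000, 900, 905))
  expect_equal(bp[2], 0)
  expect_true(all(bp >= 0))
  expect_equal(bp[3], 5 / 900)
})

test_that("state selection prefers two states for two-state data", {
  bs <- simulateBurstSet(200, 1, 1, seed = 6)
  sel <- selectStates(bs, nRange = 1:2, restarts = 1, seed = 6,
                      tol = 1e-3, maxIter = 100)
  expect_equal(sel$chosen, 2L)
  expect_equal(sel$table$nParams, c(2, 7))
  expect_output(print(sel), "chosen")
})

test_that("state classification follows the S extremes and the E order", {
  es <- data.frame(E = c(0.75, 0.05, 0.40, 0.80),
                   S = c(0.60, 0.95, 0.60, 0.05))
  expect_equal(classifyStates(es),
               c("closed", "donorOnly", "open", "acceptorOnly"))
  expect_equal(classifyStates(data.frame(E = c(0.7, 0.3), S = c(0.5, 0.6))),
               c("closed", "open"))
  # ambiguous geometries are refused, not guessed
  expect_error(classifyStates(data.frame(E = c(0.1, 0.2, 0.3, 0.4),
                                         S = c(0.9, 0.95, 0.6, 0.6))),
               "ambiguous")
  expect_error(classifyStates(data.frame(E = c(0.3, 0.4), S = c(0.95, 0.6))),
               "ambiguous")
  expect_error(classifyStates(data.frame(E = 0.5, S = 0.5)), "2 or 4")
})

test_that("models survive a JSON round-trip exactly", {
  m <- h2mmModel(initProb = c(0.3, 0.7),
                 rates = matrix(c(0, 1 / 3, 1 / 11, 0), 2, byrow = TRUE),
                 E = c(0.44, 0.81), S = c(0.57, 0.62),
                 stateLabels = c("open", "closed"))
  f <- withr::local_tempfile(fileext = ".json")
  writeH2MMModel(m, f)
  back <- readH2MMModel(f)
  expect_equal(back@initProb, m@initProb)
  expect_equal(unname(back@rates), unname(m@rates))
  expect_equal(unname(back@emission), unname(m@emission))
  expect_identical(back@stateLabels, m@stateLabels)
  expect_equal(back@clockPeriod, m@clockPeriod)
})

test_that("degenerate inputs are refused with clear errors", {
  expect_error(fitH2MM(list(dt = list(), streams = list())), "no photons")
  m <- h2mmModel(rates = matrix(c(0, 1, 1, 0), 2, byrow = TRUE),
                 E = c(0.4, 0.8), S = c(0.6, 0.6))
  expect_error(burstLogLik(m, list(dt = list(c(0, -3)),
                                   streams = list(c(0L, 1L)))),
               "negative")
})
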