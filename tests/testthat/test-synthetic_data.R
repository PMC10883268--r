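test_that("telegraph trajectories alternate states and fill the duration", {
  tr <- simulateTwoStateTrajectory(2, 5, 500, seed = 1)
  expect_equal(sum(tr$duration), 500)
  expect_true(all(tr$duration >= 0))
  s <- as.character(tr$state)
  expect_true(all(s[-1] != s[-length(s)])) # strict alternation
})

test_that("telegraph occupancy and mean dwells match the configured taus", {
  tr <- simulateTwoStateTrajectory(2, 5, 2e5, seed = 7)
  occ <- sum(tr$duration[tr$state == "open"]) / sum(tr$duration)
  expect_equal(occ, 2 / 7, tolerance = 0.03)
  # drop the truncated final dwell from the means
  d <- tr$duration[-nrow(tr)]
  s <- tr$state[-nrow(tr)]
  expect_equal(mean(d[s == "open"]), 2, tolerance = 0.05)
  expect_equal(mean(d[s == "closed"]), 5, tolerance = 0.05)
})

test_that("a fixed initial state is honoured and seeds reproduce", {
  tr <- simulateTwoStateTrajectory(2, 5, 50, seed = 3, initState = "closed")
  expect_equal(as.character(tr$state[1]), "closed")
  tr2 <- simulateTwoStateTrajectory(2, 5, 50, seed = 3, initState = "closed")
  expect_identical(tr, tr2)
})

test_that("stream probabilities follow the PIE arithmetic and sum to one", {
  p <- streamProbs(c(0.3, 0.9), c(0.6, 0.5))
  expect_equal(unname(p[1, ]), c(0.6 * 0.7, 0.6 * 0.3, 0.4))
  expect_equal(unname(rowSums(p)), c(1, 1))
  expect_error(streamProbs(1.2, 0.5))
})

test_that("emitted photons follow the state emission probabilities", {
  tr <- data.frame(state = "closed", duration = 2000)
  pd <- emitPhotons(tr, photonRate = 50, seed = 5)
  expect_s4_class(pd, "PhotonData")
  n <- nPhotons(pd)
  expect_equal(n, 50 * 2000, tolerance = 0.05)
  frac <- table(streams(pd)) / n
  es <- defaultEmission()["closed", ]
  want <- streamProbs(es["E"], es["S"])
  expect_equal(as.numeric(frac), as.numeric(want), tolerance = 0.05)
  expect_true(all(groundTruth(pd)$state == "closed"))
})

test_that("background photons are labelled and roughly at the asked rate", {
  tr <- data.frame(state = "open", duration = 50000)
  pd <- emitPhotons(tr, photonRate = 0, background = c(1, 0.5, 0.25),
                    seed = 6)
  expect_true(all(groundTruth(pd)$origin == "background"))
  expect_equal(nPhotons(pd), 1.75 * 50000, tolerance = 0.05)
})

test_that("a measurement is sorted, bounded and reproducible", {
  cfg <- simConfig(seed = 10, acquisitionDuration = 10)
  pd <- simulateMeasurement(cfg)
  expect_false(is.unsorted(timestamps(pd)))
  expect_true(max(photonTimesMs(pd)) <= 10 * 1e3)
  pd2 <- simulateMeasurement(cfg)
  expect_identical(timestamps(pd), timestamps(pd2))
  gt <- groundTruth(pd)
  expect_true(all(c("dual", "donorOnly", "acceptorOnly", "background") %in%
                    gt$species))
  expect_true(all(is.na(gt$burstId[gt$species == "background"])))
})

test_that("apo measurements carry no condition population", {
  cfg <- simConfig(seed = 11, acquisitionDuration = 10)
  gt <- groundTruth(simulateMeasurement(cfg))
  expect_true(all(gt$population[gt$species == "dual"] == "apo"))
  gt2 <- groundTruth(simulateMeasurement(cfg, kinetics = c(0.5, 14.5)))
  expect_setequal(unique(gt2$population[gt2$species == "dual"]),
                  c("apo", "condition"))
})

test_that("orientationWeight 0 sends every dual burst to the condition", {
  cfg <- simConfig(seed = 12, acquisitionDuration = 10,
                   orientationWeight = 0)
  gt <- groundTruth(simulateMeasurement(cfg, kinetics = c(1, 1)))
  expect_true(all(gt$population[gt$species == "dual"] == "condition"))
})

test_that("technical repeats differ but derive deterministically", {
  cfg <- simConfig(seed = 13, acquisitionDuration = 5, nRepeats = 3L)
  reps <- simulateRepeats(cfg)
  expect_length(reps, 3L)
  expect_false(identical(timestamps(reps[[1]]), timestamps(reps[[2]])))
  again <- simulateRepeats(cfg)
  expect_identical(timestamps(reps[[2]]), timestamps(again[[2]]))
  expect_equal(vapply(reps, function(r) r@repeatId, 1L), 1:3)
})

test_that("burst sets honour size, minimum photons and the leading gap", {
  bs <- simulateBurstSet(40, 2, 5, minPhotons = 60, seed = 21)
  expect_length(bs$dt, 40L)
  expect_true(all(lengths(bs$streams) >= 60))
  expect_true(all(vapply(bs$dt, function(d) d[1] == 0, TRUE)))
  expect_true(all(unlist(bs$streams) %in% 0:2))
  expect_identical(lengths(bs$dt), lengths(bs$states))
  bs2 <- simulateBurstSet(40, 2, 5, minPhotons = 60, seed = 21)
  expect_identical(bs, bs2)
})

test_that("burst-set dwell composition reflects the stationary occupancy", {
  bs <- simulateBurstSet(300, 2, 5, seed = 22)
  fracOpen <- mean(unlist(bs$states) == "open")
  expect_equal(fracOpen, 2 / 7, tolerance = 0.1)
})

test_that("the lag table is exact at zero noise", {
  tab <- simulateLagTable(2.85, t0 = 7, positions = c(100, 200, 300))
  expect_equal(tab$lag, 7 + c(100, 200, 300) / 2.85)
  expect_error(simulateLagTable(-1, positions = 10))
})
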