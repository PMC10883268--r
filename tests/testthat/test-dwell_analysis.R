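test_that("dwells follow the half-gap rule with positions and per-dwell E", {
  # ticks -> ms with the default 5e-5 ms tick
  bl <- list(dt = list(c(0, 2000, 2000, 2000, 2000)),
             streams = list(c(0L, 1L, 1L, 0L, 0L)),
             ticks = list(c(0, 2000, 4000, 6000, 8000)),
             clockPeriod = 5e-8)
  paths <- list(c(1L, 2L, 2L, 1L, 1L))
  dw <- extractDwells(bl, paths, c("open", "closed"))
  expect_equal(nrow(dw), 3L)
  expect_equal(dw$state, c("open", "closed", "open"))
  expect_equal(dw$position, c("initial", "mid", "terminal"))
  # photon times: 0, .1, .2, .3, .4 ms; runs {1}, {2,3}, {4,5}
  expect_equal(dw$duration, c(0.05, 0.2, 0.15), tolerance = 1e-10)
  expect_equal(dw$nPhotons, c(1L, 2L, 2L))
  expect_equal(dw$Eraw, c(0, 1, 0))
  expect_false(any(dw$photophysical))
})

test_that("single-run bursts are whole-burst dwells", {
  bl <- list(dt = list(c(0, 1000)), streams = list(c(0L, 1L)),
             ticks = list(c(0, 1000)), clockPeriod = 5e-8)
  dw <- extractDwells(bl, list(c(2L, 2L)), c("open", "closed"))
  expect_equal(dw$position, "whole-burst")
  expect_equal(dw$state, "closed")
})

test_that("photophysical dwells are retained but flagged", {
  bl <- list(dt = list(c(0, 1000, 1000)), streams = list(c(0L, 0L, 2L)),
             ticks = list(c(0, 1000, 2000)), clockPeriod = 5e-8)
  dw <- extractDwells(bl, list(c(3L, 3L, 1L)),
                      c("open", "closed", "donorOnly"))
  expect_identical(dw$photophysical, c(TRUE, FALSE))
})

test_that("model dwell times use only the conformational submatrix", {
  k <- matrix(0, 4, 4)
  labels <- c("open", "closed", "donorOnly", "acceptorOnly")
  k[1, 2] <- 1 / 6.1 # open -> closed
  k[2, 1] <- 1 / 27.5 # closed -> open
  k[1, 3] <- 5 # spurious coupling into a photophysical state
  k[2, 4] <- 7
  m <- h2mmModel(rates = k, E = c(0.4, 0.75, 0.05, 0.8),
                 S = c(0.6, 0.6, 0.95, 0.05), stateLabels = labels)
  expect_warning(tau <- dwellTimesFromModel(m), "absorbing")
  expect_equal(unname(tau[["open"]]), 6.1)
  expect_equal(unname(tau[["closed"]]), 27.5)
  expect_true(is.infinite(tau[["donorOnly"]]))
})

test_that("percent open matches the ratio and rejects degenerate input", {
  expect_equal(percentOpen(6.1, 27.5), 100 * 6.1 / 33.6)
  expect_equal(percentOpen(3, 0), 100)
  expect_error(percentOpen(0, 0), "zero")
  expect_error(percentOpen(-1, 2))
})

test_that("repeat aggregation reproduces the Student-t interval", {
  x <- c(17, 21, 18, 23, 19)
  a <- aggregateRepeats(x, level = 0.90)
  half <- qt(0.95, 4) * sd(x) / sqrt(5)
  expect_equal(a$mean, mean(x))
  expect_equal(a$upper - a$mean, half)
  expect_equal(a$mean - a$lower, half)
  expect_warning(one <- aggregateRepeats(5), "fewer than 2")
  expect_true(is.na(one$lower))
})

test_that("dwell statistics average the per-repeat occupancy ratio", {
  pr <- data.frame(tauOpen = c(6, 7), tauClosed = c(24, 28))
  st <- dwellStats(pr, condition = "apo")
  expect_s3_class(st, "DwellStats")
  expect_equal(st$percentOpen$mean, mean(c(100 * 6 / 30, 100 * 7 / 35)))
  expect_output(print(st), "apo")
})

test_that("occupancy orientation correction unmixes a known mixture", {
  apoStats <- dwellStats(data.frame(tauOpen = rep(6.1, 3),
                                    tauClosed = rep(27.5, 3)), "apo")
  pApo <- 100 * 6.1 / 33.6
  pTrue <- 64
  pObs <- 0.5 * pApo + 0.5 * pTrue
  obs <- dwellStats(data.frame(tauOpen = rep(1, 3),
                               tauClosed = rep(1, 3)), "ADP.AlFx")
  obs$perRepeat$percentOpen <- rep(pObs, 3)
  corr <- orientationCorrection(obs, apoStats, w = 0.5)
  expect_equal(corr$percentOpen$mean, pTrue)
  expect_match(corr$condition, "corrected")
})

test_that("out-of-range corrected occupancies are clipped with a warning", {
  apoStats <- dwellStats(data.frame(tauOpen = rep(6.1, 2),
                                    tauClosed = rep(27.5, 2)), "apo")
  obs <- dwellStats(data.frame(tauOpen = rep(1, 2),
                               tauClosed = rep(99, 2)), "ADP")
  expect_warning(corr <- orientationCorrection(obs, apoStats, w = 0.5),
                 "clipped")
  expect_true(all(corr$perRepeat$percentOpen >= 0))
  expect_error(orientationCorrection(obs, apoStats, w = 1), "w must")
})

test_that("the fixed-weight exponential mixture recovers the free tau", {
  set.seed(31)
  d <- c(rexp(4000, 1 / 6.1), rexp(4000, 1 / 0.5)) # w = 0.5 apo + fast
  tau <- correctDwellMixture(d, apoTau = 6.1, w = 0.5)
  expect_equal(tau, 0.5, tolerance = 0.1)
  expect_error(correctDwellMixture(numeric(0), 6.1, 0.5), "no dwell")
})

test_that("dwell-mode orientation correction uses the mixture fit", {
  set.seed(32)
  apoStats <- dwellStats(data.frame(tauOpen = rep(6.1, 2),
                                    tauClosed = rep(27.5, 2)), "apo")
  obs <- dwellStats(data.frame(tauOpen = rep(3, 2), tauClosed = rep(10, 2)),
                    "ADP")
  dwells <- data.frame(
    state = rep(c("open", "closed"), each = 6000),
    duration = c(rexp(3000, 1 / 6.1), rexp(3000, 1 / 0.5),
                 rexp(3000, 1 / 27.5), rexp(3000, 1 / 14.5)))
  tau <- orientationCorrection(obs, apoStats, w = 0.5, mode = "dwell",
                               dwells = dwells)
  expect_equal(unname(tau[["tauOpen"]]), 0.5, tolerance = 0.15)
  expect_equal(unname(tau[["tauClosed"]]), 14.5, tolerance = 0.25)
  expect_error(orientationCorrection(obs, apoStats, mode = "dwell"),
               "requires")
})

test_that("the condition report is tidy and feeds the dwell map", {
  s1 <- dwellStats(data.frame(tauOpen = c(6, 7, 6.5),
                              tauClosed = c(26, 29, 27)), "apo")
  s2 <- dwellStats(data.frame(tauOpen = c(0.5, 0.6, 0.4),
                              tauClosed = c(14, 15, 14.5)), "ADP")
  rep <- conditionReport(list(s1, s2))
  expect_equal(nrow(rep), 2L)
  expect_equal(rep$condition, c("apo", "ADP"))
  expect_true(all(rep$tauOpenLo < rep$tauOpen & rep$tauOpen < rep$tauOpenHi))
  p <- plotDwellMap(rep)
  expect_s3_class(p, "ggplot")
  expect_equal(nrow(conditionReport(list())), 0L)
})
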