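# a synthetic record with known structure: Poisson background in all three
# streams plus dense rectangular bursts at known times
makeRecord <- function(bgKhz = c(1, 1, 1), burstsAtMs = numeric(0),
                       burstLenMs = 2, burstKhz = 60, durS = 30,
                       burstStreamProb = c(0.25, 0.35, 0.4), seed = 1) {
  set.seed(seed)
  durMs <- durS * 1e3
  t <- c(); s <- c()
  for (k in 1:3) {
    n <- rpois(1, bgKhz[k] * durMs)
    t <- c(t, runif(n, 0, durMs)); s <- c(s, rep(k - 1L, n))
  }
  for (b in burstsAtMs) {
    n <- rpois(1, burstKhz * burstLenMs)
    t <- c(t, runif(n, b, b + burstLenMs))
    s <- c(s, sample(0:2, n, replace = TRUE, prob = burstStreamProb))
  }
  o <- order(t)
  PhotonData(timestamps = floor(t[o] / (5e-8 * 1e3)), streams = s[o],
             acquisitionDuration = durS)
}

test_that("background estimation recovers known Poisson rates", {
  pd <- makeRecord(bgKhz = c(0.8, 0.5, 0.3), seed = 2)
  bg <- estimateBackground(pd)
  expect_equal(unname(unclass(bg)[1:3]), c(0.8, 0.5, 0.3), tolerance = 0.15)
})

test_that("background estimation is robust to interleaved bursts", {
  pd <- makeRecord(bgKhz = c(0.8, 0.5, 0.3),
                   burstsAtMs = seq(500, 29500, by = 150), seed = 3)
  bg <- estimateBackground(pd)
  expect_equal(unname(unclass(bg)[1:3]), c(0.8, 0.5, 0.3), tolerance = 0.25)
})

test_that("too few photons raises an error naming the stream", {
  pd <- PhotonData(timestamps = seq(0, 2900, by = 100),
                   streams = rep(0:1, 15), acquisitionDuration = 1)
  expect_error(estimateBackground(pd), "AexAem")
})

test_that("the sliding-window search finds the planted bursts", {
  at <- c(2000, 9000, 17000, 26000)
  pd <- makeRecord(bgKhz = c(0.3, 0.3, 0.3), burstsAtMs = at, seed = 4)
  bg <- estimateBackground(pd)
  b <- searchBursts(pd, bg)
  expect_equal(nrow(b), length(at))
  # every found burst covers its planted core and starts near it
  expect_true(all(b$startMs < at + 0.5 & b$startMs > at - 5))
  expect_true(all(b$stopMs > at + 1.5 & b$stopMs < at + 7))
  expect_true(all(b$size >= 50))
  expect_true(all(diff(b$startMs) > 0))
  expect_true(all(b$stopMs[-nrow(b)] < b$startMs[-1])) # non-overlapping
  # index range and times agree
  tms <- photonTimesMs(pd)
  expect_equal(tms[b$iStart], b$startMs)
  expect_equal(tms[b$iEnd - 1L], b$stopMs)
})

test_that("minSize filters small bursts", {
  at <- c(2000, 9000)
  pd <- makeRecord(bgKhz = c(0.3, 0.3, 0.3), burstsAtMs = at, seed = 5)
  bg <- estimateBackground(pd)
  b <- searchBursts(pd, bg, burstSearchParams(minSize = 100000L))
  expect_equal(nrow(b), 0L)
})

test_that("dual-channel AND logic suppresses donor-only molecules", {
  # donor-only bursts emit almost no AexAem photons
  at <- c(4000, 12000, 20000)
  pd <- makeRecord(bgKhz = c(0.3, 0.3, 0.3), burstsAtMs = at,
                   burstStreamProb = c(0.93, 0.05, 0.02), seed = 6)
  bg <- estimateBackground(pd)
  bAnd <- searchBursts(pd, bg, burstSearchParams(channelLogic = "and"))
  bAll <- searchBursts(pd, bg, burstSearchParams(channelLogic = "all"))
  expect_equal(nrow(bAll), length(at))
  expect_lt(nrow(bAnd), nrow(bAll))
})

test_that("burst metrics implement the raw E and S ratios", {
  tab <- data.frame(nDD = c(30, 0, 10), nDA = c(70, 0, 0),
                    nAA = c(100, 50, 0))
  m <- burstMetrics(tab)
  expect_equal(m$Eraw, c(0.7, NA, 0))
  expect_equal(m$Sraw, c(0.5, 0, 1))
  expect_identical(m$EUndefined, c(FALSE, TRUE, FALSE))
})

test_that("burst photon lists carry tick gaps and 0-based streams", {
  pd <- PhotonData(timestamps = c(0, 5, 7, 100, 108, 120),
                   streams = c(0, 1, 2, 1, 0, 2),
                   acquisitionDuration = 1)
  bursts <- data.frame(iStart = c(1L, 4L), iEnd = c(4L, 7L))
  bl <- burstPhotonList(pd, bursts)
  expect_equal(bl$dt, list(c(0, 5, 2), c(0, 8, 12)))
  expect_equal(bl$streams, list(c(0L, 1L, 2L), c(1L, 0L, 2L)))
  expect_equal(bl$ticks, list(c(0, 5, 7), c(100, 108, 120)))
  expect_equal(bl$clockPeriod, 5e-8)
})

test_that("an empty record yields an empty burst table", {
  pd <- PhotonData(timestamps = numeric(0), streams = numeric(0),
                   acquisitionDuration = 1)
  b <- searchBursts(pd, c(DexDem = 1, DexAem = 1, AexAem = 1))
  expect_equal(nrow(b), 0L)
})

test_that("BVA flags dynamic bursts and spares static ones", {
  set.seed(8)
  mk <- function(evec) {
    # one long "burst": windows alternate between the E values in evec
    n <- 600
    E <- rep(evec, length.out = n %/% 5 + 1)[ceiling(seq_len(n) / 5)]
    s <- ifelse(runif(n) < E, 1L, 0L) # Dex photons only
    PhotonData(timestamps = seq_len(n) * 20, streams = s,
               acquisitionDuration = 1)
  }
  bursts <- data.frame(burstId = 1L, iStart = 1L, iEnd = 601L)
  static <- burstVarianceAnalysis(mk(0.5), bursts, seed = 1)
  dynamic <- burstVarianceAnalysis(mk(c(0.1, 0.9)), bursts, seed = 1)
  expect_false(static$bursts$exceeds[1])
  expect_true(dynamic$bursts$exceeds[1])
  expect_equal(dynamic$shotNoiseSd(0.5), sqrt(0.25 / 5))
})

test_that("BVA warns and returns an empty result on tiny bursts", {
  pd <- PhotonData(timestamps = c(0, 10, 20), streams = c(0, 1, 0),
                   acquisitionDuration = 1)
  bursts <- data.frame(burstId = 1L, iStart = 1L, iEnd = 4L)
  expect_warning(r <- burstVarianceAnalysis(pd, bursts), "empty")
  expect_equal(nrow(r$bursts), 0L)
  expect_true(is.na(r$dynamicFraction))
})
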