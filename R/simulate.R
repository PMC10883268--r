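#' Default synthetic measurement configuration
#'
#' Defaults emulate the study conditions of diffusion smFRET on
#' proteoliposome-reconstituted SecYEG at ~30 pM: sparse single-molecule
#' bursts, a dual-labelled population alongside donor-only and
#' acceptor-only photophysical contaminants, a 50/50 orientation mixture
#' (half the molecules present their SecA face to the lumen and keep apo
#' kinetics when SecA is added), apo reference dwell times 6.1 / 27.5 ms,
#' and five technical repeats per condition.
#'
#' @param speciesFractions named fractions for dual / donorOnly /
#'   acceptorOnly molecules
#' @param orientationWeight fraction of dual-labelled molecules locked in
#'   apo kinetics under +SecA conditions
#' @param emission 4 x 2 matrix of per-state (E, S)
#' @param apoTauOpen,apoTauClosed apo reference dwell times (ms)
#' @param meanBurstDuration mean burst (transit) duration, ms
#' @param burstPhotonRate within-burst photon rate, kHz
#' @param burstRate burst arrivals per second
#' @param background per-stream background rates, kHz
#' @param acquisitionDuration seconds
#' @param nRepeats technical repeats
#' @param seed master seed
#' @param clockPeriod seconds per tick
#' @return a validated \linkS4class{SimConfig}
#' @export
simConfig <- function(speciesFractions = c(dual = 0.5, donorOnly = 0.3,
                                           acceptorOnly = 0.2),
                      orientationWeight = 0.5,
                      emission = defaultEmission(),
                      apoTauOpen = 6.1, apoTauClosed = 27.5,
                      meanBurstDuration = 4, burstPhotonRate = 50,
                      burstRate = 5,
                      background = c(DexDem = 0.6, DexAem = 0.4,
                                     AexAem = 0.5),
                      acquisitionDuration = 60, nRepeats = 5L,
                      seed = 1L, clockPeriod = 5e-8) {
  new("SimConfig",
      speciesFractions = speciesFractions,
      orientationWeight = orientationWeight,
      emission = emission,
      apoTauOpen = apoTauOpen, apoTauClosed = apoTauClosed,
      meanBurstDuration = meanBurstDuration,
      burstPhotonRate = burstPhotonRate,
      burstRate = burstRate,
      background = background,
      acquisitionDuration = acquisitionDuration,
      nRepeats = as.integer(nRepeats), seed = as.integer(seed),
      clockPeriod = clockPeriod)
}

#' Default per-state raw FRET / stoichiometry signatures
#'
#' The open channel is the lower-FRET conformation (larger lateral-gate
#' separation between the label sites), the closed channel the higher-FRET
#' one; donor-only species sit at high S / low E and acceptor-only species
#' at low S.
#'
#' @return 4 x 2 matrix with rows open/closed/donorOnly/acceptorOnly and
#'   columns E, S
#' @export
defaultEmission <- function() {
  m <- rbind(open = c(0.40, 0.60), closed = c(0.75, 0.60),
             donorOnly = c(0.05, 0.95), acceptorOnly = c(0.80, 0.05))
  colnames(m) <- c("E", "S")
  m
}

#' Per-stream emission probabilities from (E, S)
#'
#' p(DexDem) = S(1-E), p(DexAem) = S E, p(AexAem) = 1 - S; the three always
#' sum to one exactly.
#'
#' @param E,S raw FRET efficiency and stoichiometry, each in [0, 1]
#' @return matrix with one row per (E, S) pair and columns the streams
#' @export
streamProbs <- function(E, S) {
  stopifnot(all(E >= 0 & E <= 1), all(S >= 0 & S <= 1))
  cbind(DexDem = S * (1 - E), DexAem = S * E, AexAem = 1 - S)
}

#' Simulate a two-state telegraph trajectory
#'
#' Continuous-time two-state Markov realization with exponential dwell
#' durations of means \code{tauOpen} and \code{tauClosed}; the initial state
#' is drawn from the stationary distribution and the final dwell is
#' truncated at \code{duration}.
#'
#' @param tauOpen,tauClosed mean dwell times, ms (> 0)
#' @param duration trajectory length, ms (> 0)
#' @param seed optional seed
#' @param initState optional "open"/"closed" to pin the first state
#' @return data.frame with columns \code{state} (factor open/closed) and
#'   \code{duration} (ms); attribute \code{totalDuration}
#' @examples
#' tr <- simulateTwoStateTrajectory(6.1, 27.5, 1000, seed = 1)
#' sum(tr$duration[tr$state == "open"]) / sum(tr$duration)
#' @export
simulateTwoStateTrajectory <- function(tauOpen, tauClosed, duration,
                                       seed = NULL, initState = NULL) {
  assertPositive(tauOpen, "tauOpen")
  assertPositive(tauClosed, "tauClosed")
  assertPositive(duration, "duration")
  withSeed(seed, {
    pOpen <- tauOpen / (tauOpen + tauClosed)
    state <- initState %||% if (runif(1) < pOpen) "open" else "closed"
    other <- function(s) if (s == "open") "closed" else "open"
    # states alternate deterministically, so dwells can be drawn in
    # vectorized chunks with alternating rates
    states <- character(0); durs <- numeric(0)
    t <- 0
    repeat {
      n <- max(8L, ceiling(1.5 * (duration - t) /
                             mean(c(tauOpen, tauClosed))))
      sts <- rep(c(state, other(state)), length.out = n)
      d <- rexp(n, rate = 1 / ifelse(sts == "open", tauOpen, tauClosed))
      states <- c(states, sts); durs <- c(durs, d)
      cum <- cumsum(durs)
      t <- cum[length(cum)]
      if (t >= duration) {
        cut <- which(cum >= duration)[1]
        states <- states[seq_len(cut)]; durs <- durs[seq_len(cut)]
        durs[cut] <- durs[cut] - (cum[cut] - duration)
        break
      }
      state <- other(sts[n])
    }
    out <- data.frame(state = factor(states, levels = c("open", "closed")),
                      duration = durs)
    attr(out, "totalDuration") <- duration
    out
  })
}

#' Emit photons along a state trajectory
#'
#' Homogeneous Poisson photons at \code{photonRate} within the trajectory;
#' each photon's stream is drawn from the occupying state's probabilities
#' (see [streamProbs()]); independent per-stream Poisson background is
#' superposed; timestamps are quantized to clock ticks. Ground truth records
#' each photon's state ("background" photons carry NA).
#'
#' @param traj a trajectory from [simulateTwoStateTrajectory()], or any
#'   data.frame with \code{state}/\code{duration} columns whose states index
#'   rows of \code{emission}
#' @param emission matrix with rownames covering the trajectory states and
#'   columns E, S
#' @param photonRate within-trajectory photon rate, kHz
#' @param background per-stream background rates, kHz (length 3)
#' @param clockPeriod seconds per tick
#' @param seed optional seed
#' @return a \linkS4class{PhotonData} with ground truth columns
#'   \code{state} and \code{origin}
#' @export
emitPhotons <- function(traj, emission = defaultEmission(), photonRate,
                        background = c(0, 0, 0), clockPeriod = 5e-8,
                        seed = NULL) {
  stopifnot(photonRate >= 0, all(background >= 0))
  withSeed(seed, {
    segs <- as.data.frame(traj)
    total <- sum(segs$duration)
    starts <- cumsum(c(0, head(segs$duration, -1)))
    tms <- numeric(0); st <- character(0); strm <- integer(0)
    if (photonRate > 0) {
      n <- rpois(nrow(segs), photonRate * segs$duration)
      for (i in seq_len(nrow(segs))) {
        if (n[i] == 0L) next
        t <- sort(runif(n[i], starts[i], starts[i] + segs$duration[i]))
        p <- streamProbs(emission[as.character(segs$state[i]), "E"],
                         emission[as.character(segs$state[i]), "S"])
        tms <- c(tms, t)
        st <- c(st, rep(as.character(segs$state[i]), n[i]))
        strm <- c(strm, sample.int(3L, n[i], replace = TRUE, prob = p))
      }
    }
    for (s in 1:3) {
      nb <- rpois(1, background[s] * total)
      if (nb == 0L) next
      tms <- c(tms, runif(nb, 0, total))
      st <- c(st, rep(NA_character_, nb))
      strm <- c(strm, rep(s, nb))
    }
    o <- order(tms)
    deltaMs <- clockPeriod * 1e3
    PhotonData(
      timestamps = floor(tms[o] / deltaMs),
      streams = PHOTON_STREAMS[strm[o]],
      clockPeriod = clockPeriod,
      acquisitionDuration = total / 1e3,
      groundTruth = data.frame(
        state = st[o],
        origin = ifelse(is.na(st[o]), "background", "signal"))
    )
  })
}

#' Simulate one diffusion smFRET measurement
#'
#' Bursts arrive as a Poisson process at \code{burstRate}; each burst draws
#' a species from the configured fractions. Dual-labelled bursts draw their
#' kinetics from the SecA-accessible population with probability
#' \code{1 - orientationWeight}, otherwise they keep the apo reference
#' kinetics (the inaccessible liposome orientation). Burst durations are
#' exponential; the full acquisition carries per-stream Poisson background.
#' Ground truth records species, per-photon state, population and burst id.
#'
#' @param config a \linkS4class{SimConfig}
#' @param kinetics optional c(tauOpen, tauClosed) ms of the SecA-accessible
#'   population; \code{NULL} means an apo measurement (every molecule runs
#'   the apo kinetics and no orientation split applies)
#' @param seed seed (defaults to the config's)
#' @return a \linkS4class{PhotonData}
#' @export
simulateMeasurement <- function(config, kinetics = NULL, seed = NULL) {
  validObject(config)
  if (!is.null(kinetics)) {
    stopifnot(length(kinetics) == 2L)
    assertPositive(kinetics, "kinetics")
  }
  seed <- seed %||% config@seed
  withSeed(seed, {
    em <- config@emission
    durS <- config@acquisitionDuration
    durMs <- durS * 1e3
    deltaMs <- config@clockPeriod * 1e3
    nBursts <- rpois(1, config@burstRate * durS)
    startMs <- sort(runif(nBursts, 0, durMs))
    lenMs <- rexp(nBursts, 1 / config@meanBurstDuration)
    species <- sample(names(config@speciesFractions), nBursts, replace = TRUE,
                      prob = config@speciesFractions)
    apo <- is.null(kinetics) |
      (runif(nBursts) < config@orientationWeight)
    acc <- vector("list", nBursts + 3L)
    for (b in seq_len(nBursts)) {
      if (species[b] == "dual") {
        kin <- if (apo[b]) c(config@apoTauOpen, config@apoTauClosed) else
          kinetics
        traj <- simulateTwoStateTrajectory(kin[1], kin[2], lenMs[b])
        segStart <- cumsum(c(0, head(traj$duration, -1)))
        n <- rpois(nrow(traj), config@burstPhotonRate * traj$duration)
        tot <- sum(n)
        if (tot == 0L) next
        segState <- as.character(traj$state)
        t <- numeric(tot); s3 <- integer(tot); stv <- character(tot)
        pos <- 0L
        for (i in seq_len(nrow(traj))) {
          if (n[i] == 0L) next
          ii <- pos + seq_len(n[i])
          t[ii] <- startMs[b] +
            sort(runif(n[i], segStart[i], segStart[i] + traj$duration[i]))
          p <- streamProbs(em[segState[i], "E"], em[segState[i], "S"])
          s3[ii] <- sample.int(3L, n[i], replace = TRUE, prob = p)
          stv[ii] <- segState[i]
          pos <- pos + n[i]
        }
        acc[[b]] <- data.frame(
          t = t, strm = s3, st = stv, sp = "dual", bid = b,
          pop = if (apo[b]) "apo" else "condition")
      } else {
        n <- rpois(1, config@burstPhotonRate * lenMs[b])
        if (n == 0L) next
        p <- streamProbs(em[species[b], "E"], em[species[b], "S"])
        acc[[b]] <- data.frame(
          t = startMs[b] + sort(runif(n, 0, lenMs[b])),
          strm = sample.int(3L, n, replace = TRUE, prob = p),
          st = species[b], sp = species[b], bid = b, pop = NA_character_)
      }
    }
    for (s in 1:3) {
      nb <- rpois(1, config@background[s] * durMs)
      if (nb == 0L) next
      acc[[nBursts + s]] <- data.frame(
        t = runif(nb, 0, durMs), strm = s, st = NA_character_,
        sp = "background", bid = NA_integer_, pop = NA_character_)
    }
    all <- do.call(rbind, acc[!vapply(acc, is.null, logical(1))])
    if (is.null(all))
      all <- data.frame(t = numeric(0), strm = integer(0),
                        st = character(0), sp = character(0),
                        bid = integer(0), pop = character(0))
    tms <- all$t; strm <- all$strm; st <- all$st
    sp <- all$sp; bid <- all$bid; pop <- all$pop
    keep <- tms <= durMs
    o <- order(tms[keep])
    idx <- which(keep)[o]
    PhotonData(
      timestamps = floor(tms[idx] / deltaMs),
      streams = PHOTON_STREAMS[strm[idx]],
      clockPeriod = config@clockPeriod,
      acquisitionDuration = durS,
      conditionLabel = if (is.null(kinetics)) "apo" else "condition",
      groundTruth = data.frame(species = sp[idx], state = st[idx],
                               population = pop[idx], burstId = bid[idx])
    )
  })
}

#' Simulate technical repeats of a measurement
#'
#' Repeat-level seeds are derived deterministically from the master seed via
#' [childSeed()], so each repeat is independent yet the whole set is
#' reproducible.
#'
#' @inheritParams simulateMeasurement
#' @param nRepeats number of repeats (defaults to the config's)
#' @return list of \linkS4class{PhotonData}
#' @export
simulateRepeats <- function(config, kinetics = NULL,
                            nRepeats = config@nRepeats, seed = NULL) {
  stopifnot(nRepeats >= 1)
  seed <- seed %||% config@seed
  lapply(seq_len(nRepeats), function(r) {
    pd <- simulateMeasurement(config, kinetics, seed = childSeed(seed, r))
    pd@repeatId <- as.integer(r)
    pd
  })
}

#' Simulate a calibration burst set directly from the generative model
#'
#' Generates burst photon records straight from the hidden-Markov generative
#' process — per burst an exponential duration, a two-state telegraph
#' trajectory started from its stationary distribution, homogeneous Poisson
#' photons whose streams follow the occupying state's (E, S), and timestamps
#' quantized to clock ticks. No diffusion background, no molecular
#' coincidence and no burst-search step intervene, so the output isolates
#' the estimator from detection artifacts: it is the right input for
#' parameter-recovery and model-selection calibration experiments. The
#' realistic end-to-end path is [simulateMeasurement()] plus
#' [searchBursts()].
#'
#' @param nBursts number of bursts to return
#' @param tauOpen,tauClosed mean dwell times, ms
#' @param emission 2-row matrix (open, closed) with columns E and S
#' @param photonRate photon rate inside a burst, kHz
#' @param meanBurstDuration mean exponential burst duration, ms
#' @param minPhotons bursts with fewer photons are redrawn (photon count is
#'   independent of the hidden state, so this does not bias the kinetics)
#' @param clockPeriod seconds per tick
#' @param seed optional seed
#' @return a burst photon list as produced by [burstPhotonList()]:
#'   \code{dt} (tick gaps, leading 0), \code{streams} (0-based codes),
#'   \code{ticks}, \code{clockPeriod}, plus \code{states} (true per-photon
#'   state labels)
#' @examples
#' bs <- simulateBurstSet(50, 2, 5, seed = 1)
#' length(bs$dt)
#' @export
simulateBurstSet <- function(nBursts, tauOpen, tauClosed,
                             emission = defaultEmission()[c("open", "closed"), ],
                             photonRate = 50, meanBurstDuration = 4,
                             minPhotons = 50L, clockPeriod = 5e-8,
                             seed = NULL) {
  assertPositive(c(tauOpen, tauClosed, photonRate, meanBurstDuration),
                 "rates and durations")
  withSeed(seed, {
    deltaMs <- clockPeriod * 1e3
    p <- streamProbs(emission[, "E"], emission[, "S"])
    dts <- vector("list", nBursts)
    strms <- vector("list", nBursts)
    stl <- vector("list", nBursts)
    tks <- vector("list", nBursts)
    b <- 0L
    while (b < nBursts) {
      dur <- rexp(1, 1 / meanBurstDuration)
      traj <- simulateTwoStateTrajectory(tauOpen, tauClosed, dur)
      n <- rpois(nrow(traj), photonRate * traj$duration)
      if (sum(n) < minPhotons) next
      segStart <- cumsum(c(0, head(traj$duration, -1)))
      t <- unlist(lapply(seq_len(nrow(traj)), function(i)
        if (n[i]) sort(runif(n[i], segStart[i],
                             segStart[i] + traj$duration[i])) else numeric(0)))
      st <- rep(as.character(traj$state), n)
      s3 <- unlist(lapply(seq_len(nrow(traj)), function(i)
        if (n[i]) sample.int(3L, n[i], replace = TRUE,
                             prob = p[as.character(traj$state[i]), ])
        else integer(0)))
      b <- b + 1L
      ticks <- floor(t / deltaMs)
      dts[[b]] <- c(0, diff(ticks))
      strms[[b]] <- s3 - 1L
      stl[[b]] <- st
      tks[[b]] <- ticks
    }
    list(dt = dts, streams = strms, ticks = tks,
         clockPeriod = clockPeriod, states = stl)
  })
}

#' Simulate a translocation lag table
#'
#' The NanoLuc split-luciferase assay reports, per probe insertion position,
#' the lag before chemiluminescence onset:
#' \code{lag = t0 + position / v + noise}.
#'
#' @param v transport rate, amino acids per second (> 0)
#' @param t0 position-independent lag offset, s
#' @param positions probe insertion positions, amino acids from the
#'   N-terminus (all > 0)
#' @param noiseSd Gaussian noise sd on the lag, s
#' @param seed optional seed
#' @param condition condition label
#' @return data.frame with columns \code{position} and \code{lag}
#' @export
simulateLagTable <- function(v, t0 = 0, positions, noiseSd = 0, seed = NULL,
                             condition = "") {
  assertPositive(v, "v")
  stopifnot(all(positions > 0))
  withSeed(seed, {
    lag <- t0 + positions / v +
      if (noiseSd > 0) rnorm(length(positions), 0, noiseSd) else 0
    structure(data.frame(position = positions, lag = lag),
              condition = condition)
  })
}
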