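#' Equilibrium free-energy difference between open and closed states
#'
#' With occupancies proportional to the dwell times, the open-minus-closed
#' free energy is \code{-log(tauOpen / tauClosed)} in units of kT: positive
#' when the channel is mostly closed (the open well sits higher).
#'
#' @param tauOpen,tauClosed mean dwell times (ms), > 0
#' @return free-energy difference in kT
#' @examples
#' equilibriumFreeEnergy(6.1, 27.5) # apo: open well ~1.5 kT above closed
#' @export
equilibriumFreeEnergy <- function(tauOpen, tauClosed) {
  assertPositive(tauOpen, "tauOpen")
  assertPositive(tauClosed, "tauClosed")
  -log(tauOpen / tauClosed)
}

#' Simplified two-well landscape with qualitative barriers
#'
#' Arrhenius-style barriers against an explicitly stated reference
#' prefactor \code{k0}: the barrier out of a state is \code{log(k0 * tau)}
#' kT. The prefactor has no experimental estimate, so both barrier heights
#' carry a permanent qualitative flag and only their difference (which is
#' prefactor-independent and equals the equilibrium free energy) is
#' quantitative.
#'
#' @param tauOpen,tauClosed mean dwell times (ms), > 0
#' @param k0 reference attempt rate, per ms (> 0); must be given explicitly
#' @return list of class \code{Landscape}: \code{deltaG} (open - closed,
#'   kT), \code{barrierOpenToClosed}, \code{barrierClosedToOpen} (kT),
#'   \code{k0}, \code{qualitativeBarriers = TRUE}
#' @export
barrierProfile <- function(tauOpen, tauClosed, k0) {
  assertPositive(tauOpen, "tauOpen")
  assertPositive(tauClosed, "tauClosed")
  assertPositive(k0, "k0")
  structure(list(
    deltaG = equilibriumFreeEnergy(tauOpen, tauClosed),
    barrierOpenToClosed = log(k0 * tauOpen),
    barrierClosedToOpen = log(k0 * tauClosed),
    k0 = k0, qualitativeBarriers = TRUE
  ), class = "Landscape")
}

#' @export
print.Landscape <- function(x, ...) {
  cat(sprintf("Landscape: deltaG(open - closed) = %+.3f kT\n", x$deltaG))
  cat(sprintf("  barriers (QUALITATIVE, prefactor k0 = %g /ms):\n", x$k0))
  cat(sprintf("    open -> closed  %.3f kT\n", x$barrierOpenToClosed))
  cat(sprintf("    closed -> open  %.3f kT\n", x$barrierClosedToOpen))
  invisible(x)
}

#' Construct an ATPase-clock configuration
#'
#' Defaults use the translocation turnover \code{kcat = 6.52} per second
#' and phosphate release at 17.9 per second, giving an ATP-bound phase of
#' ~55.9 ms and a post-hydrolysis ADP phase of ~97.5 ms per ~153.4 ms
#' cycle. Default phase kinetics: ATP-bound phase (0.4, 1.1) ms, ADP-PH
#' phase (3.5, 1.9) ms, the optional ADP-L phase (0.5, 14.5) ms.
#'
#' @param kcat ATP turnover per second
#' @param phosphateReleaseRate phosphate release per second
#' @param atpKinetics,adpPhKinetics,adpLKinetics c(tauOpen, tauClosed) ms
#' @param includeAdpL append the loosely-bound ADP phase (default FALSE,
#'   its contribution being marginal)
#' @param adpLFraction fraction of the post-release remainder given to
#'   ADP-L when enabled
#' @return a validated \linkS4class{ClockConfig}
#' @export
clockConfig <- function(kcat = 6.52, phosphateReleaseRate = 17.9,
                        atpKinetics = c(0.4, 1.1),
                        adpPhKinetics = c(3.5, 1.9),
                        adpLKinetics = c(0.5, 14.5),
                        includeAdpL = FALSE, adpLFraction = 0.1) {
  new("ClockConfig", kcat = kcat,
      phosphateReleaseRate = phosphateReleaseRate,
      atpKinetics = as.numeric(atpKinetics),
      adpPhKinetics = as.numeric(adpPhKinetics),
      adpLKinetics = as.numeric(adpLKinetics),
      includeAdpL = includeAdpL, adpLFraction = adpLFraction)
}

#' Phase durations of the deterministic ATPase clock
#'
#' @param config a \linkS4class{ClockConfig}
#' @return named numeric of phase durations in ms, summing to
#'   \code{1000 / kcat}
#' @export
clockPhaseDurations <- function(config) {
  validObject(config)
  cycle <- 1000 / config@kcat
  atp <- 1000 / config@phosphateReleaseRate
  rest <- cycle - atp
  if (rest <= 0) stop("negative post-hydrolysis phase duration")
  if (config@includeAdpL) {
    adpL <- rest * config@adpLFraction
    c(ATP = atp, `ADP-PH` = rest - adpL, `ADP-L` = adpL)
  } else c(ATP = atp, `ADP-PH` = rest)
}

#' Simulate channel gating around the SecA ATPase clock
#'
#' Each cycle is partitioned deterministically into its phases (see
#' [clockPhaseDurations()]); within a phase the channel runs the two-state
#' telegraph process with that phase's dwell times, and the conformational
#' state carries over continuously across phase and cycle boundaries
#' (memorylessness makes redrawing the residual dwell at each boundary
#' exact for the time-inhomogeneous chain).
#'
#' @param config a \linkS4class{ClockConfig}
#' @param nCycles number of cycles
#' @param seed optional seed
#' @return list of class \code{ClockTrajectory}: \code{segments}
#'   (state, duration ms, phase, cycle), \code{phaseOccupancy} (fraction of
#'   phase time open), \code{perCycle} (per-cycle, per-phase open
#'   fractions), \code{cyclePeriodMs}, \code{phaseDurations}
#' @export
simulateAtpaseClock <- function(config, nCycles = 100L, seed = NULL) {
  stopifnot(nCycles >= 1)
  phases <- clockPhaseDurations(config)
  kin <- list(`ATP` = config@atpKinetics, `ADP-PH` = config@adpPhKinetics,
              `ADP-L` = config@adpLKinetics)
  withSeed(seed, {
    # initial state from the ATP-phase stationary distribution
    p0 <- config@atpKinetics[1] / sum(config@atpKinetics)
    state <- if (runif(1) < p0) "open" else "closed"
    nPhase <- nCycles * length(phases)
    accSt <- vector("list", nPhase); accDu <- vector("list", nPhase)
    accPh <- character(nPhase); accCy <- integer(nPhase)
    pc <- matrix(0, nCycles, length(phases),
                 dimnames = list(NULL, names(phases)))
    si <- 0L
    for (cyc in seq_len(nCycles)) {
      for (ph in names(phases)) {
        tau <- kin[[ph]]
        D <- phases[[ph]]
        # dwell states alternate deterministically from the entry state, so
        # a whole phase can be drawn in vectorized chunks
        st <- character(0); du <- numeric(0)
        repeat {
          mMean <- mean(tau)
          n <- max(8L, ceiling(1.5 * (D - sum(du)) / mMean))
          first <- if (length(st)) {
            if (st[length(st)] == "open") "closed" else "open"
          } else state
          sts <- rep(c(first, setdiff(c("open", "closed"), first)),
                     length.out = n)
          d <- rexp(n, 1 / ifelse(sts == "open", tau[1], tau[2]))
          st <- c(st, sts); du <- c(du, d)
          cum <- cumsum(du)
          if (cum[length(cum)] >= D) {
            cut <- which(cum >= D)[1]
            st <- st[seq_len(cut)]; du <- du[seq_len(cut)]
            du[cut] <- du[cut] - (cum[cut] - D)
            break
          }
        }
        state <- st[length(st)] # carries over the boundary
        si <- si + 1L
        accSt[[si]] <- st; accDu[[si]] <- du
        accPh[si] <- ph; accCy[si] <- cyc
        pc[cyc, ph] <- sum(du[st == "open"]) / D
      }
    }
    lens <- lengths(accSt)
    segments <- data.frame(state = unlist(accSt),
                           duration = unlist(accDu),
                           phase = rep(accPh, lens),
                           cycle = rep(accCy, lens))
    occ <- colMeans(pc)
    structure(list(segments = segments, phaseOccupancy = occ,
                   perCycle = pc, cyclePeriodMs = sum(phases),
                   phaseDurations = phases, nCycles = nCycles),
              class = "ClockTrajectory")
  })
}

#' @export
print.ClockTrajectory <- function(x, ...) {
  cat(sprintf("ClockTrajectory: %d cycles of %.1f ms (%s)\n", x$nCycles,
              x$cyclePeriodMs,
              paste(sprintf("%s %.1f ms", names(x$phaseDurations),
                            x$phaseDurations), collapse = ", ")))
  cat("  open occupancy by phase:",
      paste(sprintf("%s=%.3f", names(x$phaseOccupancy), x$phaseOccupancy),
            collapse = ", "), "\n")
  invisible(x)
}
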