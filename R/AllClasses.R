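#' PhotonData: a timestamped, stream-labelled photon record
#'
#' The universal input of the pipeline: one confocal measurement as integer
#' clock-tick timestamps with a PIE stream label per photon
#' (\code{DexDem}, \code{DexAem} or \code{AexAem}), plus acquisition
#' metadata and optional simulator ground-truth annotations.
#'
#' Timestamps are stored as integer-valued doubles (clock ticks can exceed
#' the 32-bit integer range at MHz clocks over hour-long acquisitions) and
#' must be non-decreasing. \code{clockPeriod} is seconds per tick.
#'
#' @slot timestamps numeric, integer-valued clock ticks, non-decreasing
#' @slot streams factor with levels \code{PHOTON_STREAMS}
#' @slot clockPeriod seconds per clock tick (> 0)
#' @slot acquisitionDuration seconds
#' @slot conditionLabel free-text condition tag, e.g. \code{"SecYEG:A:ATP"}
#' @slot repeatId technical-repeat index
#' @slot groundTruth zero-row data.frame, or one row per photon with
#'   simulator annotations (species, state, burst id, ...)
#' @export
setClass("PhotonData",
  representation(
    timestamps = "numeric",
    streams = "factor",
    clockPeriod = "numeric",
    acquisitionDuration = "numeric",
    conditionLabel = "character",
    repeatId = "integer",
    groundTruth = "data.frame"
  ),
  prototype(
    timestamps = numeric(0),
    streams = factor(character(0), levels = c("DexDem", "DexAem", "AexAem")),
    clockPeriod = 5e-8,
    acquisitionDuration = 0,
    conditionLabel = "",
    repeatId = 1L,
    groundTruth = data.frame()
  )
)

setValidity("PhotonData", function(object) {
  v <- validatePhotonData(object)
  if (length(v) == 0L) TRUE else v
})

#' H2MMModel: hidden-state kinetic and emission model
#'
#' A photon-by-photon hidden Markov model. The hidden chain steps once per
#' clock tick; transition structure is stored as off-diagonal rates
#' \code{rates[i, j]} (events per ms, diagonal zero), with the per-tick
#' transition matrix \code{A = I + Q * delta} for tick length \code{delta}
#' and exact interval kernels \code{A^dt} obtained spectrally. Each state
#' emits photons into the three PIE streams with probabilities
#' \code{emission[i, ]}.
#'
#' @slot nStates number of hidden states
#' @slot initProb initial state distribution (sums to 1)
#' @slot rates N x N off-diagonal transition rates per ms, diagonal 0
#' @slot emission N x 3 row-stochastic stream-emission matrix
#' @slot clockPeriod seconds per tick
#' @slot stateLabels optional labels ("open", "closed", "donorOnly",
#'   "acceptorOnly"), length 0 or N
#' @export
setClass("H2MMModel",
  representation(
    nStates = "integer",
    initProb = "numeric",
    rates = "matrix",
    emission = "matrix",
    clockPeriod = "numeric",
    stateLabels = "character"
  )
)

setValidity("H2MMModel", function(object) {
  msg <- character(0)
  N <- object@nStates
  if (length(object@initProb) != N)
    msg <- c(msg, "initProb length must equal nStates")
  if (any(object@initProb < 0) || abs(sum(object@initProb) - 1) > 1e-10)
    msg <- c(msg, "initProb must be a probability vector (sum 1 within 1e-10)")
  if (!all(dim(object@rates) == c(N, N)))
    msg <- c(msg, "rates must be N x N")
  else {
    if (any(diag(object@rates) != 0))
      msg <- c(msg, "rates diagonal must be zero")
    if (any(object@rates < 0))
      msg <- c(msg, "rates must be non-negative")
  }
  if (!all(dim(object@emission) == c(N, 3L)))
    msg <- c(msg, "emission must be N x 3")
  else if (any(object@emission < 0) ||
           any(abs(rowSums(object@emission) - 1) > 1e-10))
    msg <- c(msg, "emission rows must sum to 1 within 1e-10")
  if (length(object@clockPeriod) != 1L || object@clockPeriod <= 0)
    msg <- c(msg, "clockPeriod must be a single positive number")
  if (length(object@stateLabels) &&
      length(object@stateLabels) != N)
    msg <- c(msg, "stateLabels must be empty or length nStates")
  if (length(msg)) msg else TRUE
})

#' H2MMFit: a fitted photon-by-photon HMM
#'
#' @slot model the fitted \linkS4class{H2MMModel}
#' @slot loglik final total log-likelihood
#' @slot loglikTrace per-iteration log-likelihood (non-decreasing)
#' @slot converged logical
#' @slot iterations EM iterations used
#' @slot nPhotons photons entering the fit
#' @slot nBursts bursts entering the fit
#' @export
setClass("H2MMFit",
  representation(
    model = "H2MMModel",
    loglik = "numeric",
    loglikTrace = "numeric",
    converged = "logical",
    iterations = "integer",
    nPhotons = "numeric",
    nBursts = "integer"
  )
)

#' SimConfig: synthetic measurement configuration
#'
#' Describes the statistical structure of one simulated smFRET measurement
#' of proteoliposome-reconstituted SecYEG: species mixture (dual-labelled
#' molecules plus donor-only and acceptor-only photophysical contaminants),
#' the 50/50 liposome-orientation mixture that leaves about half of the
#' molecules SecA-inaccessible, per-state raw FRET/stoichiometry signatures,
#' apo reference kinetics, a burst model (exponential burst durations at a
#' constant within-burst photon rate, Poisson burst arrivals) and
#' per-stream Poisson background.
#'
#' @slot speciesFractions named fractions (dual, donorOnly, acceptorOnly)
#'   summing to 1
#' @slot orientationWeight fraction of dual-labelled molecules locked in apo
#'   kinetics when SecA is present (default 0.5)
#' @slot emission 4 x 2 matrix, rows open/closed/donorOnly/acceptorOnly,
#'   columns E and S
#' @slot apoTauOpen,apoTauClosed apo reference dwell times (ms)
#' @slot meanBurstDuration mean single-molecule transit (ms)
#' @slot burstPhotonRate within-burst photon rate (kHz)
#' @slot burstRate burst arrivals per second
#' @slot background per-stream background rates (kHz), named by stream
#' @slot acquisitionDuration seconds
#' @slot nRepeats technical repeats per condition (default 5)
#' @slot seed master seed
#' @slot clockPeriod seconds per tick
#' @export
setClass("SimConfig",
  representation(
    speciesFractions = "numeric",
    orientationWeight = "numeric",
    emission = "matrix",
    apoTauOpen = "numeric",
    apoTauClosed = "numeric",
    meanBurstDuration = "numeric",
    burstPhotonRate = "numeric",
    burstRate = "numeric",
    background = "numeric",
    acquisitionDuration = "numeric",
    nRepeats = "integer",
    seed = "integer",
    clockPeriod = "numeric"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character(0)
  f <- object@speciesFractions
  if (length(f) != 3L || is.null(names(f)) ||
      !setequal(names(f), c("dual", "donorOnly", "acceptorOnly")))
    msg <- c(msg, "speciesFractions must be named dual/donorOnly/acceptorOnly")
  else if (any(f < 0) || abs(sum(f) - 1) > 1e-12)
    msg <- c(msg, "speciesFractions must be non-negative and sum to 1 (1e-12)")
  w <- object@orientationWeight
  if (length(w) != 1L || w < 0 || w > 1)
    msg <- c(msg, "orientationWeight must be in [0, 1]")
  em <- object@emission
  if (!all(dim(em) == c(4L, 2L)) ||
      !identical(rownames(em), c("open", "closed", "donorOnly", "acceptorOnly")))
    msg <- c(msg, "emission must be 4 x 2 with rows open/closed/donorOnly/acceptorOnly")
  else if (any(em < 0) || any(em > 1))
    msg <- c(msg, "emission E and S values must lie in [0, 1]")
  for (nm in c("apoTauOpen", "apoTauClosed", "meanBurstDuration",
               "acquisitionDuration", "clockPeriod"))
    if (slot(object, nm) <= 0)
      msg <- c(msg, sprintf("%s must be positive", nm))
  if (any(c(object@burstPhotonRate, object@burstRate, object@background) < 0))
    msg <- c(msg, "rates must be non-negative")
  if (object@nRepeats < 1L)
    msg <- c(msg, "nRepeats must be >= 1")
  if (length(msg)) msg else TRUE
})

#' ClockConfig: SecA ATPase-cycle phase structure
#'
#' The hydrolysis cycle is rendered as a deterministic "clock": an ATP-bound
#' phase lasting \code{1000 / phosphateReleaseRate} ms, then a
#' post-hydrolysis ADP phase (ADP-PH) filling the rest of the
#' \code{1000 / kcat} ms cycle; a loosely-bound ADP phase (ADP-L) can be
#' appended, taking \code{adpLFraction} of the post-release remainder.
#' Within each phase the channel runs a two-state telegraph process with
#' that phase's dwell times, the conformational state carrying over
#' continuously across phase boundaries.
#'
#' @slot kcat ATP turnover per second during translocation (default 6.52)
#' @slot phosphateReleaseRate phosphate release per second (default 17.9)
#' @slot atpKinetics c(tauOpen, tauClosed) ms for the ATP-bound phase
#' @slot adpPhKinetics c(tauOpen, tauClosed) ms for the ADP-PH phase
#' @slot adpLKinetics c(tauOpen, tauClosed) ms for the optional ADP-L phase
#' @slot includeAdpL logical, default FALSE (its contribution is marginal)
#' @slot adpLFraction fraction of the post-release remainder assigned to
#'   ADP-L when enabled
#' @export
setClass("ClockConfig",
  representation(
    kcat = "numeric",
    phosphateReleaseRate = "numeric",
    atpKinetics = "numeric",
    adpPhKinetics = "numeric",
    adpLKinetics = "numeric",
    includeAdpL = "logical",
    adpLFraction = "numeric"
  )
)

setValidity("ClockConfig", function(object) {
  msg <- character(0)
  if (object@kcat <= 0 || object@phosphateReleaseRate <= 0)
    msg <- c(msg, "rates must be positive")
  else if (1 / object@phosphateReleaseRate >= 1 / object@kcat)
    msg <- c(msg, "phosphate release must be faster than overall turnover")
  for (nm in c("atpKinetics", "adpPhKinetics", "adpLKinetics")) {
    k <- slot(object, nm)
    if (length(k) != 2L || any(k <= 0))
      msg <- c(msg, sprintf("%s must be two positive dwell times (ms)", nm))
  }
  if (object@adpLFraction < 0 || object@adpLFraction >= 1)
    msg <- c(msg, "adpLFraction must be in [0, 1)")
  if (length(msg)) msg else TRUE
})
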