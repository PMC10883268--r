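#' Extract dwells from Viterbi state paths
#'
#' Maximal constant-state runs per burst. A dwell's duration is the
#' first-to-last photon span of the run plus half of each flanking
#' inter-photon gap (interior dwells); initial/terminal dwells only get the
#' flank they have. Position classes (\code{initial}, \code{mid},
#' \code{terminal}, \code{whole-burst}) partition each burst's dwell
#' sequence. Dwells in photophysical states are retained but flagged.
#'
#' @param bursts a [burstPhotonList()]
#' @param paths Viterbi paths from [viterbiPaths()]
#' @param labels state labels (from [classifyStates()] or the model)
#' @return data.frame: burstId, state, duration (ms), position, nPhotons,
#'   Eraw, Sraw, photophysical
#' @export
extractDwells <- function(bursts, paths, labels) {
  deltaMs <- bursts$clockPeriod * 1e3
  out <- vector("list", length(paths))
  for (b in seq_along(paths)) {
    p <- paths[[b]]
    if (!length(p)) next
    t <- bursts$ticks[[b]] * deltaMs
    s <- bursts$streams[[b]] # 0-based
    r <- rle(p)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    nr <- length(r$values)
    dur <- numeric(nr); E <- numeric(nr); S <- numeric(nr)
    for (i in seq_len(nr)) {
      a <- starts[i]; z <- ends[i]
      d <- t[z] - t[a]
      if (a > 1L) d <- d + (t[a] - t[a - 1L]) / 2
      if (z < length(p)) d <- d + (t[z + 1L] - t[z]) / 2
      dur[i] <- max(d, deltaMs)
      cnt <- tabulate(s[a:z] + 1L, 3L)
      E[i] <- if (cnt[1] + cnt[2] > 0) cnt[2] / (cnt[1] + cnt[2]) else NA
      S[i] <- if (sum(cnt) > 0) (cnt[1] + cnt[2]) / sum(cnt) else NA
    }
    pos <- if (nr == 1L) "whole-burst" else
      c("initial", rep("mid", max(nr - 2L, 0L)), "terminal")
    lab <- labels[r$values]
    out[[b]] <- data.frame(
      burstId = b, state = lab, duration = dur, position = pos,
      nPhotons = r$lengths, Eraw = E, Sraw = S,
      photophysical = lab %in% c("donorOnly", "acceptorOnly"))
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(burstId = integer(0), state = character(0),
                      duration = numeric(0), position = character(0),
                      nPhotons = integer(0), Eraw = numeric(0),
                      Sraw = numeric(0), photophysical = logical(0)))
  do.call(rbind, out)
}

#' Conformational dwell times implied by a fitted model
#'
#' For the open and closed states the mean residence time is taken from the
#' open/closed rate submatrix only: \code{tau_open = 1 / k(open -> closed)}
#' and vice versa. Transitions into photophysical states are excluded
#' (donor-only/acceptor-only bursts are distinct molecules, not kinetic
#' exchange partners). Other states report the reciprocal of their total
#' exit rate. A state with zero exit rate is flagged infinite.
#'
#' @param model an \linkS4class{H2MMModel} or \linkS4class{H2MMFit}
#' @param labels state labels; defaults to the model's
#' @return named numeric of per-state mean dwell times (ms); names are the
#'   labels
#' @export
dwellTimesFromModel <- function(model, labels = NULL) {
  if (is(model, "H2MMFit")) model <- model@model
  labels <- labels %||% model@stateLabels
  if (!length(labels)) stop("state labels required; run classifyStates()")
  k <- model@rates
  tau <- numeric(model@nStates)
  for (i in seq_len(model@nStates)) {
    exit <- if (labels[i] %in% c("open", "closed")) {
      j <- which(labels == setdiff(c("open", "closed"), labels[i]))
      sum(k[i, j])
    } else sum(k[i, -i])
    tau[i] <- if (exit > 0) 1 / exit else Inf
  }
  if (any(!is.finite(tau)))
    warning("absorbing state (zero exit rate): infinite dwell time flagged")
  setNames(tau, labels)
}

#' Percent of time in the open state
#'
#' \code{100 * tau_open / (tau_open + tau_closed)}.
#'
#' @param tauOpen,tauClosed mean dwell times (ms), non-negative, not both 0
#' @return percent open, in [0, 100]
#' @examples
#' percentOpen(6.1, 27.5) # apo SecYEG, ~18.2
#' @export
percentOpen <- function(tauOpen, tauClosed) {
  stopifnot(all(tauOpen >= 0), all(tauClosed >= 0))
  if (any(tauOpen + tauClosed == 0))
    stop("tauOpen and tauClosed cannot both be zero")
  100 * tauOpen / (tauOpen + tauClosed)
}

#' Mean and Student-t confidence interval over technical repeats
#'
#' @param values per-repeat values (>= 2 for a CI)
#' @param level two-sided confidence level (default 0.90)
#' @return list with \code{mean}, \code{lower}, \code{upper}, \code{level},
#'   \code{n}; with one repeat the interval is NA-flagged
#' @export
aggregateRepeats <- function(values, level = 0.90) {
  values <- values[is.finite(values)]
  n <- length(values)
  m <- mean(values)
  if (n < 2L) {
    warning("confidence interval undefined with fewer than 2 repeats")
    return(list(mean = m, lower = NA_real_, upper = NA_real_,
                level = level, n = n))
  }
  half <- qt((1 + level) / 2, n - 1) * sd(values) / sqrt(n)
  list(mean = m, lower = m - half, upper = m + half, level = level, n = n)
}

#' Per-condition dwell statistics over technical repeats
#'
#' Collects per-repeat (tauOpen, tauClosed), forms the per-repeat percent
#' open (the ratio is taken per repeat, then averaged), and aggregates each
#' quantity with a Student-t interval.
#'
#' @param perRepeat data.frame with columns \code{tauOpen}, \code{tauClosed}
#'   (ms), one row per technical repeat
#' @param condition condition label
#' @param level confidence level (default 0.90)
#' @return list of class \code{DwellStats}
#' @export
dwellStats <- function(perRepeat, condition = "", level = 0.90) {
  stopifnot(all(c("tauOpen", "tauClosed") %in% names(perRepeat)))
  perRepeat$percentOpen <- percentOpen(perRepeat$tauOpen,
                                       perRepeat$tauClosed)
  structure(list(
    condition = condition,
    perRepeat = perRepeat,
    tauOpen = aggregateRepeats(perRepeat$tauOpen, level),
    tauClosed = aggregateRepeats(perRepeat$tauClosed, level),
    percentOpen = aggregateRepeats(perRepeat$percentOpen, level),
    nRepeats = nrow(perRepeat), level = level
  ), class = "DwellStats")
}

#' @export
print.DwellStats <- function(x, ...) {
  fmt <- function(a, unit) sprintf("%.3g [%.3g, %.3g] %s", a$mean, a$lower,
                                   a$upper, unit)
  cat(sprintf("DwellStats '%s' (%d repeats, %d%% CI)\n", x$condition,
              x$nRepeats, round(100 * x$level)))
  cat("  tauOpen    ", fmt(x$tauOpen, "ms"), "\n")
  cat("  tauClosed  ", fmt(x$tauClosed, "ms"), "\n")
  cat("  percentOpen", fmt(x$percentOpen, "%"), "\n")
  invisible(x)
}

#' Correct dwell statistics for the inaccessible liposome orientation
#'
#' Roughly half of the reconstituted channels face away from SecA and keep
#' apo kinetics under +SecA conditions, so observed statistics are a
#' mixture. Two correction modes act where the mixture is linear or
#' identifiable:
#' \describe{
#'   \item{occupancy}{per-repeat percent open is linearly unmixed:
#'     \code{p_corr = (p_obs - w p_apo) / (1 - w)} with \code{p_apo} the
#'     apo reference mean, clipped to [0, 100] with a warning.}
#'   \item{dwell}{per-state dwell durations are fit as a two-component
#'     exponential mixture with one component fixed at the apo rate and
#'     weight \code{w}; the free component's dwell time is returned by
#'     maximum likelihood (see [correctDwellMixture()]). Requires
#'     \code{dwells}.}
#' }
#'
#' @param observed a \code{DwellStats} measured with SecA present
#' @param apo the apo reference \code{DwellStats} (matched settings)
#' @param w apo mixture weight in [0, 1) (default 0.5)
#' @param mode \code{"occupancy"} or \code{"dwell"}
#' @param dwells for dwell mode: data.frame of observed dwells (columns
#'   \code{state}, \code{duration}) pooled over repeats
#' @return corrected \code{DwellStats} (occupancy mode) or a named numeric
#'   of corrected c(tauOpen, tauClosed) (dwell mode)
#' @export
orientationCorrection <- function(observed, apo, w = 0.5,
                                  mode = c("occupancy", "dwell"),
                                  dwells = NULL) {
  mode <- match.arg(mode)
  if (w >= 1 || w < 0) stop("w must be in [0, 1)")
  if (mode == "occupancy") {
    pApo <- apo$percentOpen$mean
    pr <- observed$perRepeat
    corr <- (pr$percentOpen - w * pApo) / (1 - w)
    if (any(corr < 0 | corr > 100))
      warning("corrected occupancy outside [0, 100]; clipped")
    pr$percentOpen <- pmin(pmax(corr, 0), 100)
    out <- observed
    out$perRepeat <- pr
    out$percentOpen <- aggregateRepeats(pr$percentOpen, observed$level)
    out$condition <- paste0(observed$condition, " (orientation-corrected)")
    return(out)
  }
  if (is.null(dwells)) stop("dwell mode requires the observed dwells")
  tauO <- correctDwellMixture(dwells$duration[dwells$state == "open"],
                              apo$tauOpen$mean, w)
  tauC <- correctDwellMixture(dwells$duration[dwells$state == "closed"],
                              apo$tauClosed$mean, w)
  c(tauOpen = tauO, tauClosed = tauC)
}

#' Free dwell time of a fixed-weight exponential mixture
#'
#' Maximum-likelihood estimate of \code{tau} in the density
#' \code{w dexp(d | apoTau) + (1 - w) dexp(d | tau)} given observed dwell
#' durations.
#'
#' @param durations observed dwell durations (ms)
#' @param apoTau fixed apo component mean (ms)
#' @param w fixed apo weight in [0, 1)
#' @return the free component's mean dwell time (ms)
#' @export
correctDwellMixture <- function(durations, apoTau, w) {
  durations <- durations[is.finite(durations) & durations > 0]
  if (!length(durations)) stop("no dwell durations supplied")
  nll <- function(logTau) {
    tau <- exp(logTau)
    -sum(log(w * dexp(durations, 1 / apoTau) +
               (1 - w) * dexp(durations, 1 / tau)))
  }
  exp(optimize(nll, c(log(1e-3), log(1e5)))$minimum)
}

#' Tidy per-condition dwell report
#'
#' One row per condition with the aggregated dwell times, percent open and
#' their intervals; the input of the two-dimensional dwell plot.
#'
#' @param statsList list of \code{DwellStats}
#' @return tidy data.frame
#' @export
conditionReport <- function(statsList) {
  if (!length(statsList))
    return(data.frame(condition = character(0), tauOpen = numeric(0),
                      tauOpenLo = numeric(0), tauOpenHi = numeric(0),
                      tauClosed = numeric(0), tauClosedLo = numeric(0),
                      tauClosedHi = numeric(0), percentOpen = numeric(0),
                      percentOpenLo = numeric(0), percentOpenHi = numeric(0),
                      nRepeats = integer(0)))
  do.call(rbind, lapply(statsList, function(s) data.frame(
    condition = s$condition,
    tauOpen = s$tauOpen$mean, tauOpenLo = s$tauOpen$lower,
    tauOpenHi = s$tauOpen$upper,
    tauClosed = s$tauClosed$mean, tauClosedLo = s$tauClosed$lower,
    tauClosedHi = s$tauClosed$upper,
    percentOpen = s$percentOpen$mean, percentOpenLo = s$percentOpen$lower,
    percentOpenHi = s$percentOpen$upper,
    nRepeats = s$nRepeats)))
}

#' Two-dimensional dwell-time plot
#'
#' tau_open versus tau_closed per condition on log axes with confidence
#' intervals, the standard rendering of channel-gating kinetics.
#'
#' @param report a [conditionReport()] table
#' @return a ggplot object
#' @export
plotDwellMap <- function(report) {
  ggplot2::ggplot(report, ggplot2::aes(x = .data$tauClosed,
                                       y = .data$tauOpen,
                                       colour = .data$condition)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$tauOpenLo,
                                        ymax = .data$tauOpenHi),
                           width = 0) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$tauClosedLo,
                                         xmax = .data$tauClosedHi),
                            height = 0) +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(tau[closed] ~ "(ms)"),
                  y = expression(tau[open] ~ "(ms)")) +
    ggplot2::theme_minimal()
}
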