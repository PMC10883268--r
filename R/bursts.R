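#' Estimate per-stream background rates
#'
#' For each stream the inter-photon delay distribution is a mixture of
#' short in-burst gaps and long background gaps; the background rate is the
#' maximum-likelihood exponential rate of the delay tail. The tail
#' threshold is found iteratively (start at the 95th delay percentile,
#' re-set it to twice the current mean background gap, repeat to
#' convergence), which is robust whether or not the record is bursty.
#' Estimates are formed per time window and averaged.
#'
#' @param data a \linkS4class{PhotonData}
#' @param window estimation window, seconds (default 30)
#' @return object of class \code{BackgroundRates}: named kHz rates per
#'   stream with the window and method recorded as attributes
#' @export
estimateBackground <- function(data, window = 30) {
  tms <- photonTimesMs(data)
  durMs <- max(data@acquisitionDuration * 1e3, if (length(tms)) max(tms) else 0)
  nWin <- max(1L, floor(durMs / (window * 1e3)))
  edges <- seq(0, durMs, length.out = nWin + 1L)
  rates <- vapply(PHOTON_STREAMS, function(s) {
    t <- tms[data@streams == s]
    if (length(t) < 10L)
      stop("too few photons to estimate background in stream ", s)
    est <- vapply(seq_len(nWin), function(w) {
      tw <- t[t >= edges[w] & t < edges[w + 1L]]
      if (length(tw) < 10L) return(NA_real_)
      tailRate(diff(tw))
    }, numeric(1))
    est <- est[is.finite(est)]
    if (!length(est))
      stop("too few photons to estimate background in stream ", s)
    mean(est)
  }, numeric(1))
  structure(rates, class = "BackgroundRates", window = window,
            method = "iterative-tail-mle")
}

# ML exponential rate (kHz) of the delay tail; delays in ms
tailRate <- function(d) {
  d <- d[d > 0]
  if (length(d) < 5L) return(NA_real_)
  thr <- as.numeric(quantile(d, 0.95))
  for (i in 1:50) {
    tl <- d[d > thr]
    if (length(tl) < 5L) {
      thr <- thr / 2
      next
    }
    rate <- 1 / (mean(tl) - thr) # memoryless shift
    new <- 2 / rate
    if (abs(new - thr) < 1e-3 * thr) break
    thr <- new
  }
  rate
}

#' @export
print.BackgroundRates <- function(x, ...) {
  cat("Background rates (kHz):",
      paste(sprintf("%s=%.3g", names(unclass(x)), unclass(x)),
            collapse = ", "),
      sprintf("| window %gs, %s\n", attr(x, "window"), attr(x, "method")))
  invisible(x)
}

#' Burst search parameters
#'
#' @param m sliding window length, photons (>= 2)
#' @param F rate factor: a window is "hot" when its local photon rate
#'   exceeds \code{F} times the background rate of its channel
#' @param minSize minimum photons per burst
#' @param channelLogic \code{"and"} requires both the donor-excitation
#'   channel (DexDem + DexAem) and the acceptor-excitation channel (AexAem)
#'   to exceed their thresholds (suppresses donor-only/acceptor-only
#'   molecules); \code{"all"} runs a single all-photon search
#' @return a list of class \code{BurstSearchParams}
#' @export
burstSearchParams <- function(m = 10L, F = 6, minSize = 50L,
                              channelLogic = c("and", "all")) {
  stopifnot(m >= 2L, F > 0, minSize >= 1L)
  structure(list(m = as.integer(m), F = F, minSize = as.integer(minSize),
                 channelLogic = match.arg(channelLogic)),
            class = "BurstSearchParams")
}

# sliding-window search on one photon-time vector (ms); returns a matrix of
# [start, stop] ms intervals of maximal in-burst runs
slidingWindowIntervals <- function(t, m, maxSpan) {
  n <- length(t)
  if (n < m) return(matrix(numeric(0), ncol = 2))
  span <- t[m:n] - t[1:(n - m + 1L)]
  hot <- which(span <= maxSpan)
  if (!length(hot)) return(matrix(numeric(0), ncol = 2))
  # in-burst photons: union of windows [i, i + m - 1]
  inb <- logical(n)
  for (i in hot) inb[i:(i + m - 1L)] <- TRUE
  r <- rle(inb)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  cbind(t[starts[runs]], t[ends[runs]])
}

intersectIntervals <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(matrix(numeric(0), ncol = 2))
  out <- matrix(numeric(0), ncol = 2)
  i <- 1L; j <- 1L
  while (i <= nrow(a) && j <= nrow(b)) {
    lo <- max(a[i, 1], b[j, 1]); hi <- min(a[i, 2], b[j, 2])
    if (lo <= hi) out <- rbind(out, c(lo, hi))
    if (a[i, 2] < b[j, 2]) i <- i + 1L else j <- j + 1L
  }
  out
}

#' Find single-molecule bursts
#'
#' Sliding-window search: a photon is in-burst when the local rate over
#' \code{m} consecutive photons of the required channel exceeds
#' \code{F} times that channel's background rate; overlapping in-burst
#' windows are merged into maximal runs, dual-channel runs are intersected
#' when \code{channelLogic = "and"}, and bursts smaller than \code{minSize}
#' total photons are discarded.
#'
#' @param data a \linkS4class{PhotonData}
#' @param bg a \code{BackgroundRates} from [estimateBackground()], or a
#'   named numeric of per-stream kHz rates
#' @param params a [burstSearchParams()]
#' @return data.frame of bursts: half-open photon index range
#'   \code{iStart}/\code{iEnd} into \code{data}, start/stop times (ms),
#'   per-stream counts \code{nDD}/\code{nDA}/\code{nAA}, \code{size} and
#'   \code{duration} (ms); non-overlapping and ordered
#' @export
searchBursts <- function(data, bg, params = burstSearchParams()) {
  stopifnot(inherits(params, "BurstSearchParams"))
  bg <- unclass(bg)[PHOTON_STREAMS]
  if (anyNA(bg)) stop("background rates must be named by stream")
  tms <- photonTimesMs(data)
  if (!length(tms))
    return(emptyBurstTable())
  if (params$channelLogic == "and") {
    dex <- data@streams %in% c("DexDem", "DexAem")
    aex <- data@streams == "AexAem"
    iv1 <- slidingWindowIntervals(tms[dex], params$m,
                                  params$m / (params$F * (bg[1] + bg[2])))
    iv2 <- slidingWindowIntervals(tms[aex], params$m,
                                  params$m / (params$F * bg[3]))
    iv <- intersectIntervals(iv1, iv2)
  } else {
    iv <- slidingWindowIntervals(tms, params$m,
                                 params$m / (params$F * sum(bg)))
  }
  if (!nrow(iv)) return(emptyBurstTable())
  rows <- lapply(seq_len(nrow(iv)), function(k) {
    i0 <- findInterval(iv[k, 1], tms, left.open = TRUE) + 1L
    i1 <- findInterval(iv[k, 2], tms) # last photon <= stop
    if (i1 < i0) return(NULL)
    idx <- i0:i1
    cnt <- tabulate(as.integer(data@streams[idx]), 3L)
    data.frame(iStart = i0, iEnd = i1 + 1L,
               startMs = tms[i0], stopMs = tms[i1],
               nDD = cnt[1], nDA = cnt[2], nAA = cnt[3],
               size = length(idx), duration = tms[i1] - tms[i0])
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) return(emptyBurstTable())
  out <- out[out$size >= params$minSize, , drop = FALSE]
  if (!nrow(out)) return(emptyBurstTable())
  out$burstId <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[c("burstId", setdiff(names(out), "burstId"))]
}

emptyBurstTable <- function() {
  data.frame(burstId = integer(0), iStart = integer(0), iEnd = integer(0),
             startMs = numeric(0), stopMs = numeric(0), nDD = integer(0),
             nDA = integer(0), nAA = integer(0), size = integer(0),
             duration = numeric(0))
}

#' Raw burst metrics E and S
#'
#' \code{Eraw = nDA / (nDD + nDA)}, \code{Sraw = (nDD + nDA) /
#' (nDD + nDA + nAA)}. Undefined ratios (zero denominator) are returned as
#' \code{NA} with the \code{EUndefined} flag set.
#'
#' @param bursts a burst table from [searchBursts()] (or any data.frame
#'   with \code{nDD}, \code{nDA}, \code{nAA})
#' @return the table with \code{Eraw}, \code{Sraw} and \code{EUndefined}
#'   columns appended
#' @export
burstMetrics <- function(bursts) {
  dex <- bursts$nDD + bursts$nDA
  tot <- dex + bursts$nAA
  bursts$Eraw <- ifelse(dex > 0, bursts$nDA / dex, NA_real_)
  bursts$Sraw <- ifelse(tot > 0, dex / tot, NA_real_)
  bursts$EUndefined <- dex == 0
  bursts
}

#' Per-burst photon lists for model fitting
#'
#' Extracts, for each burst, the inter-photon intervals in clock ticks
#' (first entry 0) and 0-based stream codes, the representation consumed by
#' the HMM routines.
#'
#' @param data a \linkS4class{PhotonData}
#' @param bursts a burst table from [searchBursts()]
#' @return list with components \code{dt}, \code{streams}, \code{ticks}
#'   (parallel lists, one element per burst) and \code{clockPeriod}
#' @export
burstPhotonList <- function(data, bursts) {
  dt <- vector("list", nrow(bursts))
  sl <- vector("list", nrow(bursts))
  tk <- vector("list", nrow(bursts))
  for (k in seq_len(nrow(bursts))) {
    idx <- bursts$iStart[k]:(bursts$iEnd[k] - 1L)
    t <- data@timestamps[idx]
    dt[[k]] <- c(0, diff(t))
    sl[[k]] <- as.integer(data@streams[idx]) - 1L
    tk[[k]] <- t
  }
  list(dt = dt, streams = sl, ticks = tk, clockPeriod = data@clockPeriod)
}
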