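#' Construct a PhotonData record
#'
#' @param timestamps integer-valued clock ticks, non-decreasing
#' @param streams stream labels; character/factor with the
#'   \code{PHOTON_STREAMS} levels, or numeric codes 0/1/2 mapped to
#'   DexDem/DexAem/AexAem
#' @param clockPeriod seconds per tick (default 50 ns, i.e. a 20 MHz clock)
#' @param acquisitionDuration seconds; defaults (with a warning) to the time
#'   of the last photon
#' @param conditionLabel free-text condition tag
#' @param repeatId technical-repeat index
#' @param groundTruth optional data.frame with one row per photon
#' @return a validated \linkS4class{PhotonData}
#' @examples
#' pd <- PhotonData(c(0, 40, 100), c("DexDem", "DexAem", "AexAem"),
#'                  acquisitionDuration = 1)
#' nPhotons(pd)
#' @export
PhotonData <- function(timestamps, streams, clockPeriod = 5e-8,
                       acquisitionDuration = NULL, conditionLabel = "",
                       repeatId = 1L, groundTruth = NULL) {
  timestamps <- as.numeric(timestamps)
  streams <- streamFactor(streams)
  if (is.null(acquisitionDuration)) {
    acquisitionDuration <- if (length(timestamps))
      max(timestamps) * clockPeriod else 0
    warning("acquisitionDuration not given; defaulting to the last photon time")
  }
  new("PhotonData",
      timestamps = timestamps, streams = streams,
      clockPeriod = as.numeric(clockPeriod),
      acquisitionDuration = as.numeric(acquisitionDuration),
      conditionLabel = as.character(conditionLabel),
      repeatId = as.integer(repeatId),
      groundTruth = if (is.null(groundTruth)) data.frame() else
        as.data.frame(groundTruth))
}

#' List invariant violations of a PhotonData record
#'
#' Checks are returned, not raised: an empty character vector means the
#' record satisfies every invariant (sorted non-negative timestamps inside
#' the acquisition window, known stream labels, ground truth aligned with
#' the photons).
#'
#' @param data a \linkS4class{PhotonData} (validity is not re-run)
#' @return character vector of violation messages, empty if valid
#' @export
validatePhotonData <- function(data) {
  msg <- character(0)
  ts <- data@timestamps
  if (length(data@clockPeriod) != 1L || !is.finite(data@clockPeriod) ||
      data@clockPeriod <= 0)
    msg <- c(msg, "clockPeriod must be a single positive number")
  if (length(data@streams) != length(ts))
    msg <- c(msg, "streams must have one label per photon")
  if (anyNA(ts) || (length(ts) && any(ts < 0)))
    msg <- c(msg, "timestamps must be non-negative")
  if (is.unsorted(ts))
    msg <- c(msg, sprintf("timestamps must be non-decreasing (first violation at photon %d)",
                          which(diff(ts) < 0)[1] + 1L))
  if (length(ts) && length(data@clockPeriod) == 1L && data@clockPeriod > 0 &&
      length(data@acquisitionDuration) == 1L) {
    lim <- data@acquisitionDuration / data@clockPeriod
    if (any(ts > lim, na.rm = TRUE))
      msg <- c(msg, sprintf("timestamp exceeds the acquisition window at photon %d",
                            which(ts > lim)[1]))
  }
  bad <- which(is.na(data@streams))
  if (length(bad))
    msg <- c(msg, sprintf("unknown stream label at photon %d", bad[1]))
  gt <- data@groundTruth
  if (nrow(gt) > 0L && nrow(gt) != length(ts))
    msg <- c(msg, "groundTruth must have one row per photon")
  msg
}

#' @describeIn PhotonData number of photons
#' @param data,object a PhotonData
#' @export
nPhotons <- function(data) length(data@timestamps)

#' @describeIn PhotonData photon timestamps in clock ticks
#' @export
timestamps <- function(data) data@timestamps

#' @describeIn PhotonData photon stream labels (factor)
#' @export
streams <- function(data) data@streams

#' @describeIn PhotonData seconds per clock tick
#' @export
clockPeriod <- function(data) data@clockPeriod

#' @describeIn PhotonData acquisition duration in seconds
#' @export
acquisitionDuration <- function(data) data@acquisitionDuration

#' @describeIn PhotonData condition tag
#' @export
conditionLabel <- function(data) data@conditionLabel

#' @describeIn PhotonData ground-truth annotations (may be zero-row)
#' @export
groundTruth <- function(data) data@groundTruth

#' Photon times in milliseconds
#' @param data a \linkS4class{PhotonData}
#' @return numeric vector, ticks converted to ms
#' @export
photonTimesMs <- function(data) data@timestamps * data@clockPeriod * 1e3

setMethod("show", "PhotonData", function(object) {
  cat(sprintf("PhotonData: %d photons over %.3g s (clock %.3g ns/tick)\n",
              nPhotons(object), object@acquisitionDuration,
              object@clockPeriod * 1e9))
  tb <- table(object@streams)
  cat("  streams:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
      "\n")
  if (nzchar(object@conditionLabel))
    cat(sprintf("  condition: %s (repeat %d)\n", object@conditionLabel,
                object@repeatId))
  if (nrow(object@groundTruth))
    cat("  ground truth:", paste(names(object@groundTruth), collapse = ", "),
        "\n")
})
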