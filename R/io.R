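#' Read a photon record from disk
#'
#' Two plain-text dialects are supported. \code{"tabular"} is a TSV with
#' commented header lines carrying the metadata and columns \code{tick} and
#' \code{stream} (numeric codes 0/1/2 for DexDem/DexAem/AexAem), plus any
#' ground-truth columns. \code{"phdf5-json"} is a JSON container mirroring
#' the photon-HDF5 group layout (\code{photon_data/timestamps},
#' \code{photon_data/detectors}, \code{setup}, \code{metadata}), kept as
#' text so fixtures stay human-readable and diffable.
#'
#' @param path file to read
#' @param dialect \code{"tabular"} or \code{"phdf5-json"}; by default
#'   inferred from the extension (\code{.json} vs anything else)
#' @return a validated \linkS4class{PhotonData}
#' @seealso [writePhotonData()]
#' @export
readPhotonData <- function(path, dialect = c("auto", "tabular", "phdf5-json")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto")
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE))
      "phdf5-json" else "tabular"
  pd <- if (dialect == "tabular") readTabular(path) else readPhdf5Json(path)
  v <- validatePhotonData(pd)
  if (length(v)) stop("invalid photon record in ", path, ":\n  ",
                      paste(v, collapse = "\n  "))
  pd
}

readTabular <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), "\t", fixed = TRUE)[[1]]
    if (length(kv) == 2L) meta[[kv[1]]] <- kv[2]
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (length(body) < 1L)
    stop("malformed tabular photon file (no column header): ", path)
  df <- read.table(text = body, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  if (!all(c("tick", "stream") %in% names(df)))
    stop("malformed tabular photon file: need 'tick' and 'stream' columns")
  gt <- df[setdiff(names(df), c("tick", "stream"))]
  suppressWarnings(PhotonData(
    timestamps = df$tick,
    streams = df$stream,
    clockPeriod = as.numeric(meta$clock_period %||% 5e-8),
    acquisitionDuration = as.numeric(meta$acquisition_duration %||% NA) |>
      (\(x) if (is.na(x)) NULL else x)(),
    conditionLabel = meta$condition_label %||% "",
    repeatId = as.integer(meta$repeat_id %||% 1L),
    groundTruth = if (ncol(gt)) gt else NULL
  ))
}

readPhdf5Json <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("malformed JSON photon container: ",
                         conditionMessage(e), call. = FALSE))
  ph <- obj$photon_data
  if (is.null(ph) || is.null(ph$timestamps) || is.null(ph$detectors))
    stop("malformed photon container: missing photon_data/timestamps or /detectors")
  setup <- obj$setup %||% list()
  metad <- obj$metadata %||% list()
  gt <- obj$ground_truth
  suppressWarnings(PhotonData(
    timestamps = as.numeric(ph$timestamps),
    streams = as.numeric(ph$detectors),
    clockPeriod = as.numeric(setup$clock_period %||% 5e-8),
    acquisitionDuration = setup$acquisition_duration,
    conditionLabel = metad$condition_label %||% "",
    repeatId = as.integer(metad$repeat_id %||% 1L),
    groundTruth = if (!is.null(gt)) as.data.frame(gt) else NULL
  ))
}

#' Write a photon record to disk
#'
#' Produces a file that [readPhotonData()] reads back with bit-identical
#' timestamps and streams, in either dialect. Ground-truth annotations are
#' preserved.
#'
#' @param data a valid \linkS4class{PhotonData}
#' @param path output file
#' @param dialect \code{"tabular"} or \code{"phdf5-json"} (default inferred
#'   from the extension)
#' @return \code{path}, invisibly
#' @export
writePhotonData <- function(data, path,
                            dialect = c("auto", "tabular", "phdf5-json")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE))
      "phdf5-json" else "tabular"
  v <- validatePhotonData(data)
  if (length(v)) stop("refusing to write an invalid photon record:\n  ",
                      paste(v, collapse = "\n  "))
  if (dialect == "tabular") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      "# secgate photon record v1",
      sprintf("# clock_period\t%.17g", data@clockPeriod),
      sprintf("# acquisition_duration\t%.17g", data@acquisitionDuration),
      sprintf("# condition_label\t%s", data@conditionLabel),
      sprintf("# repeat_id\t%d", data@repeatId)
    ), con)
    df <- data.frame(tick = sprintf("%.0f", data@timestamps),
                     stream = as.integer(data@streams) - 1L)
    if (nrow(data@groundTruth)) df <- cbind(df, data@groundTruth)
    suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                                 row.names = FALSE))
  } else {
    obj <- list(
      photon_data = list(timestamps = data@timestamps,
                         detectors = as.integer(data@streams) - 1L),
      setup = list(clock_period = data@clockPeriod,
                   acquisition_duration = data@acquisitionDuration,
                   streams = PHOTON_STREAMS),
      metadata = list(condition_label = data@conditionLabel,
                      repeat_id = data@repeatId)
    )
    if (nrow(data@groundTruth)) obj$ground_truth <- data@groundTruth
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(path)
}
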