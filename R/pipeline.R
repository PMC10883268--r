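#' Run the full analysis pipeline from a single configuration
#'
#' Orchestrates simulate (or load) -> background -> burst search -> HMM fit
#' -> Viterbi dwells -> per-condition statistics, writing \code{stats.tsv},
#' \code{dwells.tsv}, \code{models.json} and a \code{manifest.json}
#' recording versions, seed and parameters. All randomness derives from the
#' manifest seed, so the same configuration produces byte-identical
#' statistics.
#'
#' The configuration is a YAML file or an equivalent nested list:
#' \preformatted{
#' seed: 1
#' condition: "apo"
#' simulate:                 # or input: {paths: [a.tsv, b.tsv]}
#'   kinetics: null          # [tauOpen, tauClosed] of the +SecA population
#'   n_repeats: 2
#'   acquisition_duration: 30
#' burst: {m: 10, F: 6, min_size: 50, channel_logic: and}
#' fit: {n_states: 4, restarts: 2, tol: 1e-4, max_iter: 300}
#' }
#'
#' @param config path to a YAML file, or a list
#' @param outDir output directory (created if needed)
#' @return the manifest, invisibly
#' @export
runPipeline <- function(config, outDir = "secgate-run") {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  seed <- config$seed %||% 1L
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  # validate inputs before any stage runs
  if (!is.null(config$input)) {
    missing <- config$input$paths[!file.exists(unlist(config$input$paths))]
    if (length(missing))
      stop("input path does not exist: ", paste(missing, collapse = ", "))
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stages <- character(0)

  records <- stage("load", {
    if (!is.null(config$input)) {
      lapply(unlist(config$input$paths), readPhotonData)
    } else {
      sc <- config$simulate %||% list()
      cfg <- simConfig(
        acquisitionDuration = sc$acquisition_duration %||% 30,
        burstRate = sc$burst_rate %||% 5,
        nRepeats = sc$n_repeats %||% 2L,
        seed = seed)
      simulateRepeats(cfg, kinetics = unlist(sc$kinetics))
    }
  })
  stages <- c(stages, "load")

  bp <- config$burst %||% list()
  params <- burstSearchParams(m = bp$m %||% 10L, F = bp$F %||% 6,
                              minSize = bp$min_size %||% 50L,
                              channelLogic = bp$channel_logic %||% "and")
  fp <- config$fit %||% list()
  perRepeat <- list(); models <- list(); dwellTabs <- list()
  for (r in seq_along(records)) {
    data <- records[[r]]
    bg <- stage("background", estimateBackground(data))
    bursts <- stage("bursts", searchBursts(data, bg, params))
    if (!nrow(bursts)) stop("pipeline stage 'bursts' found no bursts")
    bl <- burstPhotonList(data, bursts)
    fit <- stage("fit", fitH2MM(
      bl, nStates = fp$n_states %||% 4L,
      tol = fp$tol %||% 1e-4, maxIter = fp$max_iter %||% 500L,
      restarts = fp$restarts %||% 2L, seed = childSeed(seed, 1000 + r)))
    labels <- stage("classify", classifyStates(stateES(fit@model)))
    fit@model@stateLabels <- labels
    tau <- dwellTimesFromModel(fit@model)
    paths <- stage("dwells", viterbiPaths(fit, bl))
    dw <- extractDwells(bl, paths, labels)
    dw$repeatId <- r
    dwellTabs[[r]] <- dw
    models[[r]] <- fit@model
    perRepeat[[r]] <- data.frame(repeatId = r, tauOpen = tau[["open"]],
                                 tauClosed = tau[["closed"]],
                                 nBursts = nrow(bursts),
                                 loglik = fit@loglik)
  }
  stages <- c(stages, "background", "bursts", "fit", "classify", "dwells")

  pr <- do.call(rbind, perRepeat)
  stats <- stage("stats",
                 dwellStats(pr, condition = config$condition %||% ""))
  stages <- c(stages, "stats")

  statsPath <- file.path(outDir, "stats.tsv")
  rep <- conditionReport(list(stats))
  write.table(rep, statsPath, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(do.call(rbind, dwellTabs), file.path(outDir, "dwells.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(lapply(models, function(m) list(
    nStates = m@nStates, initProb = m@initProb, rates = m@rates,
    emission = m@emission, clockPeriod = m@clockPeriod,
    stateLabels = m@stateLabels)),
    file.path(outDir, "models.json"), digits = NA)

  manifest <- list(
    package = "secgate",
    version = as.character(packageVersion("secgate")),
    seed = seed,
    stages = stages,
    parameters = list(burst = unclass(params), fit = fp),
    condition = config$condition %||% "",
    nRepeats = length(records),
    outputs = c("stats.tsv", "dwells.tsv", "models.json")
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
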