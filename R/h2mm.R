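#' Construct an H2MMModel
#'
#' @param initProb initial state distribution
#' @param rates N x N matrix of off-diagonal transition rates per ms
#'   (diagonal forced to zero)
#' @param emission N x 3 row-stochastic stream-emission matrix, or
#'   \code{NULL} to build it from \code{E}/\code{S}
#' @param E,S per-state raw FRET efficiency and stoichiometry, used when
#'   \code{emission} is \code{NULL}
#' @param clockPeriod seconds per tick
#' @param stateLabels optional state labels
#' @return an \linkS4class{H2MMModel}
#' @examples
#' m <- h2mmModel(rates = matrix(c(0, 1/6.1, 1/27.5, 0), 2, byrow = TRUE),
#'                E = c(0.40, 0.75), S = c(0.60, 0.60))
#' stateES(m)
#' @export
h2mmModel <- function(initProb = NULL, rates, emission = NULL, E = NULL,
                      S = NULL, clockPeriod = 5e-8,
                      stateLabels = character()) {
  if (is.null(emission)) {
    stopifnot(!is.null(E), !is.null(S), length(E) == length(S))
    emission <- streamProbs(E, S)
  }
  emission <- as.matrix(emission)
  N <- nrow(emission)
  if (is.null(initProb)) initProb <- rep(1 / N, N)
  rates <- as.matrix(rates)
  diag(rates) <- 0
  colnames(emission) <- PHOTON_STREAMS
  new("H2MMModel", nStates = as.integer(N), initProb = as.numeric(initProb),
      rates = rates, emission = emission, clockPeriod = clockPeriod,
      stateLabels = stateLabels)
}

#' Per-tick transition matrix of a model
#'
#' \code{A = I + Q * delta} with \code{Q} the rate matrix (per ms) and
#' \code{delta} the tick length in ms. Off-diagonal entries are tiny
#' (~1e-5) so the diagonal is formed as \code{1 - sum(off-diagonal)} from
#' the rates directly, never recovered by subtracting from a stored
#' diagonal.
#'
#' @param model an \linkS4class{H2MMModel}
#' @return N x N row-stochastic matrix
#' @export
transitionMatrix <- function(model) {
  deltaMs <- model@clockPeriod * 1e3
  A <- model@rates * deltaMs
  diag(A) <- 1 - rowSums(A)
  if (any(diag(A) < 0))
    stop("rates too fast for the clock period (per-tick exit probability > 1)")
  A
}

#' Per-state (E, S) implied by the emission matrix
#'
#' Inverse of [streamProbs()]: \code{E = B[, DexAem] / (B[, DexDem] +
#' B[, DexAem])}, \code{S = B[, DexDem] + B[, DexAem]}.
#'
#' @param model an \linkS4class{H2MMModel} (or a bare emission matrix)
#' @return data.frame with columns \code{E}, \code{S} (and labels if set)
#' @export
stateES <- function(model) {
  B <- if (is(model, "H2MMModel")) model@emission else as.matrix(model)
  dex <- B[, 1] + B[, 2]
  out <- data.frame(E = ifelse(dex > 0, B[, 2] / dex, NA_real_), S = dex)
  if (is(model, "H2MMModel") && length(model@stateLabels))
    out$label <- model@stateLabels
  out
}

setMethod("show", "H2MMModel", function(object) {
  es <- stateES(object)
  cat(sprintf("H2MMModel with %d states (clock %.3g ns/tick)\n",
              object@nStates, object@clockPeriod * 1e9))
  for (i in seq_len(object@nStates)) {
    lab <- if (length(object@stateLabels)) object@stateLabels[i] else
      paste0("state", i)
    cat(sprintf("  %-12s E=%.3f S=%.3f exit rate %.4g /ms\n", lab,
                es$E[i], es$S[i], sum(object@rates[i, ])))
  }
})

setMethod("show", "H2MMFit", function(object) {
  cat(sprintf(
    "H2MMFit: logLik %.2f after %d iterations (%s), %g photons in %d bursts\n",
    object@loglik, object@iterations,
    if (object@converged) "converged" else "not converged",
    object@nPhotons, object@nBursts))
  show(object@model)
})

#' Log-likelihood of bursts under a model
#'
#' The photon-by-photon likelihood on tick-granular inter-photon intervals,
#' computed in scaled form so long bursts do not underflow.
#'
#' @param model an \linkS4class{H2MMModel}
#' @param bursts a [burstPhotonList()] (components \code{dt},
#'   \code{streams})
#' @return total log-likelihood, with attribute \code{perBurst}
#' @export
burstLogLik <- function(model, bursts) {
  if (any(unlist(bursts$dt) < 0)) stop("negative inter-photon interval")
  r <- h2mm_forward_backward(bursts$dt, bursts$streams, model@initProb,
                             transitionMatrix(model), model@emission, FALSE)
  structure(r$loglik, perBurst = r$loglik_burst)
}

#' Fit an H2MMModel by expectation-maximization
#'
#' Baum-Welch on the photon-interval likelihood with interval-resolved
#' expected transition counts (the per-tick chain is never unrolled; the
#' spectral geometric sum over intermediate ticks is exact). Per-iteration
#' log-likelihood is non-decreasing; the best of \code{restarts} seeded
#' initializations is returned. Initial emission rows are seeded from
#' k-means on burst-level (E, S) plus jitter, transition rates from a 1 ms
#' dwell guess.
#'
#' @param bursts a [burstPhotonList()]
#' @param nStates number of hidden states (ignored when \code{initial} is
#'   given)
#' @param initial optional \linkS4class{H2MMModel} to start from (fitted as
#'   the single restart)
#' @param tol absolute log-likelihood gain per iteration at which EM stops
#' @param maxIter iteration cap
#' @param restarts number of seeded initializations
#' @param seed seed for initialization jitter
#' @return an \linkS4class{H2MMFit}
#' @export
fitH2MM <- function(bursts, nStates = 2L, initial = NULL, tol = 1e-6,
                    maxIter = 3000L, restarts = 5L, seed = 1L) {
  nb <- length(bursts$dt)
  if (nb < 1L || sum(lengths(bursts$streams)) == 0L)
    stop("no photons to fit")
  nPhotons <- sum(lengths(bursts$streams))
  inits <- if (!is.null(initial)) list(initial) else
    withSeed(seed, initialModels(bursts, nStates, restarts))
  best <- NULL
  for (ini in inits) {
    fit <- emRun(bursts, ini, tol, maxIter)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  new("H2MMFit", model = best$model, loglik = best$loglik,
      loglikTrace = best$trace, converged = best$converged,
      iterations = length(best$trace), nPhotons = nPhotons,
      nBursts = as.integer(nb))
}

emRun <- function(bursts, model, tol, maxIter) {
  A <- transitionMatrix(model)
  pi <- model@initProb
  B <- model@emission
  deltaMs <- model@clockPeriod * 1e3
  trace <- numeric(0)
  prev <- -Inf
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    e <- h2mm_forward_backward(bursts$dt, bursts$streams, pi, A, B, TRUE)
    if (!is.finite(e$loglik))
      stop("non-finite likelihood during EM (iteration ", it,
           "); check emissions and intervals")
    trace <- c(trace, e$loglik)
    if (e$loglik - prev < tol && it > 1L) { converged <- TRUE; break }
    prev <- e$loglik
    # M-step
    piN <- e$gamma1 / sum(e$gamma1)
    Crs <- rowSums(e$C)
    AN <- A
    ok <- Crs > 0
    AN[ok, ] <- e$C[ok, , drop = FALSE] / Crs[ok]
    BN <- e$Bnum + 1e-12
    BN <- BN / rowSums(BN)
    pi <- piN; A <- AN; B <- BN
  }
  rates <- A / deltaMs
  diag(rates) <- 0
  list(model = h2mmModel(pi, rates, B, clockPeriod = model@clockPeriod),
       loglik = trace[length(trace)], trace = trace, converged = converged)
}

initialModels <- function(bursts, nStates, restarts) {
  cnt <- t(vapply(bursts$streams, function(s) tabulate(s + 1L, 3L),
                  numeric(3)))
  es <- stateES(cnt / pmax(rowSums(cnt), 1))
  es <- es[complete.cases(es), , drop = FALSE]
  centers <- if (nStates == 1L || nrow(es) <= nStates) {
    cbind(E = seq(0.2, 0.8, length.out = nStates),
          S = seq(0.8, 0.2, length.out = nStates))
  } else {
    km <- tryCatch(kmeans(es[c("E", "S")], centers = nStates, nstart = 5),
                   error = function(e) NULL)
    if (is.null(km))
      cbind(E = seq(0.2, 0.8, length.out = nStates),
            S = seq(0.8, 0.2, length.out = nStates)) else km$centers
  }
  lapply(seq_len(restarts), function(r) {
    E <- pmin(pmax(centers[, 1] + if (r > 1) runif(nStates, -0.08, 0.08)
                   else 0, 0.02), 0.98)
    S <- pmin(pmax(centers[, 2] + if (r > 1) runif(nStates, -0.08, 0.08)
                   else 0, 0.02), 0.98)
    base <- 1 / (1 * pmax(nStates - 1L, 1L)) # 1 ms dwell guess, split evenly
    k <- matrix(base, nStates, nStates)
    if (r > 1) k <- k * matrix(exp(runif(nStates^2, log(0.3), log(3))),
                               nStates)
    diag(k) <- 0
    h2mmModel(rep(1 / nStates, nStates), k, E = E, S = S,
              clockPeriod = bursts$clockPeriod)
  })
}

#' Most-likely state paths (Viterbi)
#'
#' @param model an \linkS4class{H2MMModel} or \linkS4class{H2MMFit}
#' @param bursts a [burstPhotonList()]
#' @return list of integer vectors (1-based state indices), one per burst
#' @export
viterbiPaths <- function(model, bursts) {
  if (is(model, "H2MMFit")) model <- model@model
  lapply(h2mm_viterbi_cpp(bursts$dt, bursts$streams, model@initProb,
                          transitionMatrix(model), model@emission),
         function(p) p + 1L)
}

#' Choose the number of hidden-state classes by BIC'
#'
#' Fits each candidate state count and computes
#' \code{BIC = -2 logL + p log(nPhotons)} with
#' \code{p = N(N-1) + 2N + (N-1)} free parameters, then the normalized
#' \code{BIC' = (BIC - min BIC) / |min BIC|}. The chosen model is the
#' smallest N whose BIC' falls below the threshold (0.005 by default).
#'
#' @param bursts a [burstPhotonList()]
#' @param nRange candidate state counts (subset of 1..6)
#' @param threshold BIC' acceptance threshold
#' @param ... passed to [fitH2MM()] (tol, maxIter, restarts, seed)
#' @return list of class \code{ModelSelection}: \code{table} (nStates,
#'   loglik, nParams, BIC, BICprime, passed), \code{chosen}, \code{fits},
#'   \code{threshold}
#' @export
selectStates <- function(bursts, nRange = 1:5, threshold = 0.005, ...) {
  stopifnot(all(nRange %in% 1:6))
  fits <- vector("list", length(nRange))
  ll <- rep(NA_real_, length(nRange))
  for (i in seq_along(nRange)) {
    fits[[i]] <- tryCatch(fitH2MM(bursts, nStates = nRange[i], ...),
                          error = function(e) {
                            warning("fit failed for N=", nRange[i], ": ",
                                    conditionMessage(e))
                            NULL
                          })
    if (!is.null(fits[[i]])) ll[i] <- fits[[i]]@loglik
  }
  nPhotons <- sum(lengths(bursts$streams))
  p <- nRange * (nRange - 1) + 2 * nRange + (nRange - 1)
  tab <- data.frame(nStates = nRange, loglik = ll, nParams = p,
                    BIC = -2 * ll + p * log(nPhotons))
  tab$BICprime <- bicPrime(tab$BIC)
  tab$passed <- !is.na(tab$BICprime) & tab$BICprime < threshold
  chosen <- if (any(tab$passed)) min(tab$nStates[tab$passed]) else NA_integer_
  structure(list(table = tab, chosen = chosen, threshold = threshold,
                 fits = setNames(fits, paste0("N", nRange))),
            class = "ModelSelection")
}

#' Normalized BIC
#'
#' \code{BIC' = (BIC - min BIC) / |min BIC|}; zero for the minimum-BIC
#' model, non-negative everywhere.
#'
#' @param bic numeric vector of BIC values (NAs tolerated)
#' @return numeric vector of BIC' values
#' @export
bicPrime <- function(bic) {
  m <- min(bic, na.rm = TRUE)
  (bic - m) / abs(m)
}

#' @export
print.ModelSelection <- function(x, ...) {
  cat("State-number selection (BIC' threshold", x$threshold, ")\n")
  print(x$table, row.names = FALSE)
  cat("chosen:", x$chosen, "\n")
  invisible(x)
}

#' Assign physical labels to fitted states
#'
#' States at extreme stoichiometry are the photophysical species (high S:
#' donor-only / dark acceptor; low S: acceptor-only / dark donor); the
#' remaining FRET states are ranked by E, the higher-FRET one being the
#' closed channel and the lower-FRET one the open channel.
#'
#' @param es data.frame with columns E and S (from [stateES()]), 2 or 4 rows
#' @param sHigh,sLow stoichiometry cutoffs for the photophysical classes
#' @return character labels in table order
#' @export
classifyStates <- function(es, sHigh = 0.8, sLow = 0.2) {
  N <- nrow(es)
  labels <- rep(NA_character_, N)
  if (N == 4L) {
    dOnly <- which(es$S >= sHigh)
    aOnly <- which(es$S <= sLow)
    if (length(dOnly) != 1L || length(aOnly) != 1L)
      stop("ambiguous state geometry: expected exactly one high-S and one ",
           "low-S state; label states manually")
    labels[dOnly] <- "donorOnly"
    labels[aOnly] <- "acceptorOnly"
    fret <- setdiff(seq_len(N), c(dOnly, aOnly))
  } else if (N == 2L) {
    if (any(es$S >= sHigh | es$S <= sLow))
      stop("ambiguous state geometry for a FRET-only pair; label states ",
           "manually")
    fret <- 1:2
  } else {
    stop("classifyStates expects 2 or 4 states; label states manually")
  }
  labels[fret[which.max(es$E[fret])]] <- "closed"
  labels[fret[which.min(es$E[fret])]] <- "open"
  labels
}

#' Write / read a model as JSON
#'
#' @param model an \linkS4class{H2MMModel}
#' @param path file path
#' @return \code{path} (write) or the model (read)
#' @export
writeH2MMModel <- function(model, path) {
  jsonlite::write_json(list(
    nStates = model@nStates, initProb = model@initProb,
    rates = model@rates, emission = model@emission,
    clockPeriod = model@clockPeriod, stateLabels = model@stateLabels),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeH2MMModel
#' @export
readH2MMModel <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  h2mmModel(o$initProb, as.matrix(o$rates), as.matrix(o$emission),
            clockPeriod = o$clockPeriod,
            stateLabels = o$stateLabels %||% character())
}
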