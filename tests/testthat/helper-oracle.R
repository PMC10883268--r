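# Reference implementations by exhaustive path enumeration, used to verify
# the compiled likelihood/Viterbi routines on small instances.

matPow <- function(A, k) {
  out <- diag(nrow(A))
  for (i in seq_len(k)) out <- out %*% A
  out
}

# total likelihood of one burst by summing over every hidden-state path
bruteLogLik <- function(dt, streams, pi, A, B) {
  n <- length(streams)
  N <- length(pi)
  Apow <- lapply(dt, function(d) matPow(A, d))
  paths <- as.matrix(expand.grid(rep(list(seq_len(N)), n)))
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    p <- pi[s[1]] * B[s[1], streams[1] + 1L]
    if (n > 1L) for (k in 2:n)
      p <- p * Apow[[k]][s[k - 1L], s[k]] * B[s[k], streams[k] + 1L]
    tot <- tot + p
  }
  log(tot)
}

# probability of one specific hidden-state path
pathProb <- function(path, dt, streams, pi, A, B) {
  n <- length(streams)
  Apow <- lapply(dt, function(d) matPow(A, d))
  p <- pi[path[1]] * B[path[1], streams[1] + 1L]
  if (n > 1L) for (k in 2:n)
    p <- p * Apow[[k]][path[k - 1L], path[k]] * B[path[k], streams[k] + 1L]
  p
}

# maximal path probability by enumeration
brutePathMax <- function(dt, streams, pi, A, B) {
  n <- length(streams)
  N <- length(pi)
  paths <- as.matrix(expand.grid(rep(list(seq_len(N)), n)))
  max(apply(paths, 1, pathProb, dt, streams, pi, A, B))
}

# random small H2MM instance: row-stochastic A with a dominant diagonal,
# row-stochastic emission, gaps of up to 30 ticks
randomInstance <- function(maxStates = 3L, maxPhotons = 8L) {
  N <- sample.int(maxStates, 1)
  n <- sample.int(maxPhotons, 1)
  pi <- runif(N); pi <- pi / sum(pi)
  A <- matrix(runif(N * N, 0.001, 0.05), N, N)
  diag(A) <- 0
  diag(A) <- 1 - rowSums(A)
  B <- matrix(runif(N * 3, 0.05, 1), N, 3)
  B <- B / rowSums(B)
  list(dt = c(0L, sample.int(30L, max(n - 1L, 0L), replace = TRUE)),
       streams = sample(0:2, n, replace = TRUE),
       pi = pi, A = A, B = B, N = N, n = n)
}

# wrap a plain (pi, A, B) instance as an H2MMModel whose per-tick
# transition matrix equals A exactly
instanceModel <- function(inst, clockPeriod = 5e-8) {
  deltaMs <- clockPeriod * 1e3
  rates <- inst$A / deltaMs
  diag(rates) <- 0
  h2mmModel(inst$pi, rates, inst$B, clockPeriod = clockPeriod)
}
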