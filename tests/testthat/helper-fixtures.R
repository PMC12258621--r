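# shared builders for synthetic inputs; all stochastic helpers take a seed

ou_ref <- function(kappa = 800, sigma = 1.5, fs = 500) {
  ou_params(kappa = kappa, sigma_stat = sigma, dt = 1 / fs)
}

# single-level OU trace (independent of the package generator's state-path
# machinery beyond the AR(1) recursion itself)
ou_trace <- function(n, mu = 0, kappa = 800, sigma = 1.5, fs = 500,
                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dt <- 1 / fs
  a <- exp(-kappa * dt)
  eps <- rnorm(n)
  x <- numeric(n)
  x[1] <- mu + sigma * eps[1]
  se <- sigma * sqrt(1 - a^2)
  for (i in seq_len(n)[-1]) x[i] <- mu + a * (x[i - 1] - mu) + se * eps[i]
  twist_trace(theta = x, sample_rate = fs)
}

# OU trace with one mean step at sample `at`
step_trace <- function(n, at, h, kappa = 800, sigma = 1.5, fs = 500,
                       seed = NULL) {
  tr <- ou_trace(n, 0, kappa, sigma, fs, seed)
  tr$theta[(at + 1):n] <- tr$theta[(at + 1):n] + h
  tr
}

# hand-built state sequence from labels and dwells
seq_from <- function(labels, dwells, levels = c(C = 0, I = 10, O = 20,
                                                overwound = -2)) {
  ends <- cumsum(dwells)
  state_sequence(label = labels, delta_theta0 = unname(levels[labels]),
                 dwell = dwells, start = c(0, ends[-length(ends)]),
                 end = ends)
}

# state sequence read directly off a latent path (noise-free idealization)
seq_from_path <- function(path, levels = c(C = 0, I = 10, O = 20)) {
  ends <- c(path$times[-1], path$duration)
  dw <- ends - path$times
  keep <- dw > 0
  state_sequence(label = path$states[keep],
                 delta_theta0 = unname(levels[path$states[keep]]),
                 dwell = dw[keep], start = path$times[keep],
                 end = ends[keep])
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
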