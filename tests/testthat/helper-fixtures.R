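# Fixtures built in code: magnitude-style series and recordings with known
# structure, used across the detector and evaluation tests.

# A half-sine pulse train on a 1 g baseline: one pulse per `period_s`, peak
# `baseline + amplitude`. Returns the series; pulse centers are at
# (k - 0.5) * period_s for k = 1..n_pulses.
pulse_train_series <- function(period_s, duration_s, sample_rate_hz = 15,
                               amplitude = 0.8, baseline = 1,
                               pulse_frac = 0.5) {
  n <- round(duration_s * sample_rate_hz)
  t <- (seq_len(n) - 1) / sample_rate_hz
  phase <- (t %% period_s) / period_s
  s <- rep(baseline, n)
  on_pulse <- phase < pulse_frac
  s[on_pulse] <- baseline + amplitude * sin(pi * phase[on_pulse] / pulse_frac)
  s
}

pulse_train_centers <- function(period_s, duration_s, pulse_frac = 0.5) {
  k <- seq_len(floor(duration_s / period_s))
  (k - 1) * period_s + pulse_frac * period_s / 2
}

# Wrap a magnitude-style series into a recording (signal on the vertical
# axis, zeros elsewhere), so magnitude(rec) == abs(series).
series_recording <- function(series, sample_rate_hz = 15, position = "hip") {
  accel_recording(numeric(length(series)), numeric(length(series)), series,
                  sample_rate_hz = sample_rate_hz, position = position,
                  clip = FALSE)
}

# Brute-force strict local-maxima scan over all interior indices (oracle
# for find_peaks with no separation constraint).
scan_local_maxima <- function(series) {
  n <- length(series)
  if (n < 3) return(integer(0))
  which(vapply(2:(n - 1), function(i) {
    series[i] > series[i - 1] && series[i] > series[i + 1]
  }, logical(1))) + 1L
}

# Maximum-cardinality matching within tolerance via igraph (independent
# oracle for the greedy event matcher).
max_matching_size <- function(detected, truth, tol = 0.5) {
  nd <- length(detected); nt <- length(truth)
  if (nd == 0 || nt == 0) return(0L)
  edges <- integer(0)
  for (i in seq_len(nt)) {
    js <- which(abs(detected - truth[i]) <= tol)
    for (j in js) edges <- c(edges, i, nt + j)
  }
  if (!length(edges)) return(0L)
  g <- igraph::make_bipartite_graph(c(rep(TRUE, nt), rep(FALSE, nd)),
                                    edges = edges)
  igraph::max_bipartite_match(g)$matching_size
}

regimes3 <- c("regular", "semi_regular", "unstructured")
positions3 <- c("wrist", "hip", "ankle")
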