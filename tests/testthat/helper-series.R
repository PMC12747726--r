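# small constructors used across test files

wsFromTau <- function(tau, areas = rep(1, dim(tau)[1]), period = 1) {
  n <- dim(tau)[3]
  new("WallShearSeries", tau = tau, areas = areas,
      times = (seq_len(n) - 1) * period / n, period = period)
}

randomWallShear <- function(seed, nNodes = 12, nFrames = 7) {
  set.seed(seed)
  wsFromTau(array(rnorm(nNodes * 3 * nFrames), c(nNodes, 3, nFrames)),
            areas = runif(nNodes, 0.5, 2))
}

# cyclic trapezoid integral oracle: plain loop over segments
trapCyclic <- function(f, times, period) {
  n <- length(times)
  total <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    dt <- if (i == n) times[1] + period - times[n] else times[j] - times[i]
    total <- total + dt * (f[i] + f[j]) / 2
  }
  total
}

# a cubic all-lumen domain for hand-built flow fields
cubeDomain <- function(d = c(7, 7, 7), spacing = 0.5) {
  new("AneurysmDomain", sacMask = array(TRUE, d), spacing = spacing,
      ostiumPoint = c(0, 0, -(d[3] + 1) / 2 * spacing + 2 * spacing),
      ostiumNormal = c(0, 0, 1),
      wallPoints = matrix(c(0, 0, 1), 1, 3),
      wallNormals = matrix(c(0, 0, 1), 1, 3),
      wallAreas = 1)
}

flowFromFrames <- function(frames, domain, period = 1) {
  n <- length(frames)
  new("FlowSeries", frames = frames, times = (seq_len(n) - 1) * period / n,
      period = period, domain = domain)
}
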