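## Independent oracles and small fixture builders used across the suite.

## Brute-force isotopologue enumeration: every atom picks one isotope,
## abundances multiply, masses add; aggregate by total neutron offset
## with abundance-weighted mean masses. Independent of the package's
## convolution path; only feasible for compositions with few atoms.
bruteForceEnvelope <- function(composition) {
  iso <- list(
    C = data.frame(offset = c(0, 1), mass = c(12.0000000, 13.0033548),
                   ab = c(0.9893, 0.0107)),
    H = data.frame(offset = c(0, 1), mass = c(1.0078250, 2.0141018),
                   ab = c(0.999885, 0.000115)),
    N = data.frame(offset = c(0, 1), mass = c(14.0030740, 15.0001089),
                   ab = c(0.99636, 0.00364)),
    O = data.frame(offset = c(0, 1, 2),
                   mass = c(15.9949146, 16.9991315, 17.9991604),
                   ab = c(0.99757, 0.00038, 0.00205)),
    S = data.frame(offset = c(0, 1, 2, 4),
                   mass = c(31.9720707, 32.9714585, 33.9678668,
                            35.9670809),
                   ab = c(0.9499, 0.0075, 0.0425, 0.0001)))
  atoms <- unlist(mapply(function(el, n) rep(el, n),
                         names(composition), composition))
  stopifnot(length(atoms) <= 10)
  choices <- lapply(atoms, function(el) seq_len(nrow(iso[[el]])))
  grid <- expand.grid(choices)
  res <- apply(grid, 1, function(idx) {
    off <- 0; m <- 0; p <- 1
    for (k in seq_along(atoms)) {
      row <- iso[[atoms[k]]][idx[k], ]
      off <- off + row$offset; m <- m + row$mass; p <- p * row$ab
    }
    c(off, m, p)
  })
  off <- res[1, ]; m <- res[2, ]; p <- res[3, ]
  agg <- lapply(sort(unique(off)), function(o) {
    sel <- off == o
    c(mass = sum(m[sel] * p[sel]) / sum(p[sel]),
      abundance = sum(p[sel]))
  })
  out <- do.call(rbind, agg)
  data.frame(mass = out[, "mass"], abundance = out[, "abundance"])
}

## Stick envelope sampled from one or two Gaussian components on a
## regular grid (fine enough that the discrete moments match the
## continuous ones to well below 1e-6 relative).
gaussianSticks <- function(mu, sigma, amplitude, spacing = 0.5,
                           pad = 12) {
  lo <- min(mu - pad * max(sigma))
  hi <- max(mu + pad * max(sigma))
  x <- seq(lo, hi, by = spacing)
  y <- rep(0, length(x))
  for (i in seq_along(mu))
    y <- y + amplitude[i] * exp(-(x - mu[i])^2 / (2 * sigma[i]^2))
  IsotopeEnvelope(x, y)
}

## Noiseless single-replicate pulse spectrum at a chosen generating
## fraction, plus the matching reference states.
noiselessPulse <- function(fraction, seed = 1) {
  pr <- empiricalPreset("oracle", fraction, 5)
  simulatePulseSpectra(pr, replicates = 1,
                       noise = noiseModel(cv = 0, baseline = 0,
                                          seed = seed))[[1]]
}

diagnosticRefs <- function() referenceStates()
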