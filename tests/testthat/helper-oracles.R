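# Independent oracles used across the suite. These deliberately avoid the
# package's closed-form / compiled code paths: plain-R evaluation of the
# single-pulse decay, explicit pulse-train summation, exhaustive searches.

# single-pulse bi-exponential, written out directly
oracle_decay <- function(t, params) {
  params$amplitude * (params$alpha1 * exp(-t / params$tau1) +
                      params$alpha2 * exp(-t / params$tau2)) + params$offset_c
}

# brute-force steady-state pulse train: sum the tails of n_pulses
# preceding pulses term by term
oracle_periodic <- function(t, params, acq, n_pulses = 10000) {
  k <- 0:(n_pulses - 1)
  vapply(t, function(ti) {
    params$amplitude *
      (params$alpha1 * sum(exp(-(ti + k * acq$period_t) / params$tau1)) +
       params$alpha2 * sum(exp(-(ti + k * acq$period_t) / params$tau2))) +
      params$offset_c
  }, numeric(1))
}

# expected bin counts by numerical quadrature of the brute-force curve
oracle_bin_means <- function(params, acq, n_pulses = 2000, n_sub = 64) {
  vapply(seq_len(acq$n_bins), function(j) {
    tt <- seq((j - 1) * acq$bin_width, j * acq$bin_width, length.out = n_sub)
    v <- oracle_periodic(tt, params, acq, n_pulses)
    sum((v[-1] + v[-n_sub]) / 2 * diff(tt))
  }, numeric(1))
}

# exhaustive Otsu: try every candidate split of the 256-bin histogram and
# maximise between-class variance directly
oracle_otsu <- function(image, levels = 256) {
  x <- as.numeric(image)
  br <- seq(min(x), max(x), length.out = levels + 1)
  bin <- pmin(findInterval(x, br, rightmost.closed = TRUE), levels)
  mids <- (br[-1] + br[-(levels + 1)]) / 2
  best <- -Inf
  best_t <- NA
  for (t in 1:(levels - 1)) {
    lo <- bin <= t
    w0 <- mean(lo)
    if (w0 == 0 || w0 == 1) next
    mu0 <- mean(mids[bin[lo]])
    mu1 <- mean(mids[bin[!lo]])
    bcv <- w0 * (1 - w0) * (mu0 - mu1)^2
    if (bcv > best) {
      best <- bcv
      best_t <- mids[t]
    }
  }
  best_t
}

# bin integrals via explicit truncated pulse-train summation (analytic
# per-bin integral of each shifted exponential, no geometric-series closed
# form) — fast enough for grid searches
oracle_bin_sum <- function(params, acq, n_pulses = 500) {
  tj <- (seq_len(acq$n_bins) - 1) * acq$bin_width
  kT <- (0:(n_pulses - 1)) * acq$period_t
  comp <- function(tau) {
    tau * (1 - exp(-acq$bin_width / tau)) *
      rowSums(exp(-outer(tj, kT, "+") / tau))
  }
  params$amplitude * (params$alpha1 * comp(params$tau1) +
                      params$alpha2 * comp(params$tau2)) + params$offset_c
}

# Poisson deviance of a histogram against the brute-force model, used by the
# grid-search fitting oracle
oracle_deviance <- function(h, params, acq) {
  mu <- pmax(oracle_bin_sum(params, acq), 1e-12)
  sum(mu - h + ifelse(h > 0, h * log(h / mu), 0))
}

# simulate a Poisson TCSPC histogram for a mono-exponential lifetime
sim_mono_hist <- function(tau, photons, acq, seed) {
  set.seed(seed)
  p <- decay_params(0, 1, tau, tau)
  mu <- periodic_bin_means(p, acq)
  stats::rpois(acq$n_bins, mu / sum(mu) * photons)
}

make_acq <- function(n_bins = 64) acquisition_spec(80, n_bins)
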