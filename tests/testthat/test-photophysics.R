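test_that("decay_value matches direct evaluation and its defining examples", {
  # value at origin equals the amplitude; value at t = tau is 1/e
  p1 <- decay_params(1, 0, tau1 = 1, tau2 = 1)
  expect_equal(decay_value(0, p1), 1.0)
  expect_equal(decay_value(1, p1), exp(-1), tolerance = 1e-12)

  # published P-GSH lifetimes, equal amplitudes: term-by-term oracle
  p <- decay_params(0.5, 0.5, tau1 = 6, tau2 = 225)
  for (t in c(0, 1, 3, 7.2, 12.4))
    expect_equal(decay_value(t, p), oracle_decay(t, p), tolerance = 1e-14)

  # strictly decreasing in t for positive amplitude
  tt <- seq(0, 12, by = 0.5)
  expect_true(all(diff(decay_value(tt, p)) < 0))
})

test_that("invalid decay parameters are rejected", {
  expect_error(decay_params(0.6, 0.5, 1, 2), "alpha1 \\+ alpha2")
  expect_error(decay_params(0.5, 0.5, -1, 2), "positive")
  expect_error(decay_params(0.5, 0.5, 5, 2), "tau1")
  expect_error(decay_params(0.5, 0.5, 1, 2, offset_c = -1), "offset_c")
  expect_error(decay_params(0.5, 0.5, NaN, 2), "finite")
  expect_error(decay_value(-1, decay_params(1, 0, 1, 1)))
})

test_that("closed-form periodic model equals brute-force pulse summation", {
  acq <- acquisition_spec(80, 32)
  taus <- c(0.5, 2.5, 4.3, 5.5, 6, 90.5, 146, 225)
  tt <- c(0, 3.1, 6.25, 12.4)
  for (tau in taus) {
    p <- decay_params(0, 1, tau, tau)
    got <- periodic_decay_value(tt, p, acq)
    want <- oracle_periodic(tt, p, acq, n_pulses = 10000)
    expect_lt(max(abs(got - want) / want), 1e-10)
  }
  # a genuinely bi-exponential case with offset
  p <- decay_params(0.3, 0.7, 4.3, 90.5, offset_c = 0.2, amplitude = 2.5)
  expect_lt(max(abs(periodic_decay_value(tt, p, acq) -
                    oracle_periodic(tt, p, acq)) /
                oracle_periodic(tt, p, acq)), 1e-10)
})

test_that("periodic model dominates the plain model and converges to it", {
  acq <- acquisition_spec(80, 64)
  tt <- seq(0, 12.4, by = 0.4)
  for (tau in c(2.5, 6, 225)) {
    p <- decay_params(0, 1, tau, tau)
    expect_true(all(periodic_decay_value(tt, p, acq) >= decay_value(tt, p)))
  }
  # fast decay completes within one period: wrap factor ~ 1
  pf <- decay_params(0, 1, 0.125, 0.125)  # tau = T/100
  expect_equal(periodic_decay_value(tt[tt < 12], pf, acq),
               decay_value(tt[tt < 12], pf), tolerance = 1e-12)
  # T -> infinity limit recovers the single-pulse model
  p <- decay_params(0.5, 0.5, 6, 225)
  acq_long <- acquisition_spec(rep_rate = 1000 / (1e4 * 225), n_bins = 64)
  expect_equal(periodic_decay_value(5, p, acq_long), decay_value(5, p),
               tolerance = 1e-9)
})

test_that("reacted long-lifetime curves are flatter across the window", {
  acq <- acquisition_spec(80, 64)
  pha <- flim_probes("P-HA")
  drop_of <- function(tau) {
    p <- decay_params(0, 1, tau, tau)
    v <- periodic_decay_value(c(0, acq$period_t * 0.999), p, acq)
    (v[1] - v[2]) / v[1]
  }
  expect_lt(drop_of(pha$tau_reacted), drop_of(pha$tau_unreacted))
})

test_that("expected bin counts integrate the periodic curve exactly", {
  acq <- acquisition_spec(80, 32)
  p <- decay_params(0.4, 0.6, 5.5, 146, offset_c = 0, amplitude = 3)
  got <- periodic_bin_means(p, acq)
  want <- oracle_bin_means(p, acq, n_pulses = 2000, n_sub = 201)
  expect_equal(got, want, tolerance = 1e-6)
  # total photons over one period = A (a1 tau1 + a2 tau2): the wrapped
  # pulse train restores the full single-pulse integral
  expect_equal(sum(got),
               p$amplitude * (p$alpha1 * p$tau1 + p$alpha2 * p$tau2),
               tolerance = 1e-12)
})

test_that("the 80 MHz repetition rate gives a 12.5 ns window exactly", {
  acq <- acquisition_spec(80, 256)
  expect_identical(acq$period_t, 12.5)
  expect_identical(acq$period_t * acq$rep_rate, 1000)
  expect_equal(acq$bin_width, 12.5 / 256)
  expect_error(acquisition_spec(80, 8), "n_bins")
})

test_that("packaged probes carry the published lifetimes", {
  pr <- flim_probes()
  expect_named(pr, c("P-GSH", "P-HP", "P-HA"))
  gsh <- pr[["P-GSH"]]
  expect_equal(c(gsh$tau_unreacted, gsh$tau_reacted), c(6, 225))
  expect_equal(gsh$tau_reacted / gsh$tau_unreacted, 37.5)  # the 38-fold step
  expect_equal(c(pr[["P-HP"]]$tau_unreacted, pr[["P-HP"]]$tau_reacted),
               c(5.5, 146))
  expect_equal(c(pr[["P-HA"]]$tau_unreacted, pr[["P-HA"]]$tau_reacted),
               c(4.3, 90.5))
  expect_gt(pr[["P-HP"]]$tau_reacted / pr[["P-HP"]]$tau_unreacted, 20)
  expect_gt(pr[["P-HA"]]$tau_reacted / pr[["P-HA"]]$tau_unreacted, 20)
  expect_equal(gsh$linear_limit, 10)
  expect_equal(gsh$saturation_conc, 20)
  expect_error(flim_probes("P-XX"), "unknown probe")
})

test_that("reacted_fraction is linear up to saturation and clamped at 1", {
  gsh <- flim_probes("P-GSH")
  expect_equal(reacted_fraction(0, gsh), 0)
  expect_equal(reacted_fraction(20, gsh), 1)   # maximal response at 20 uM
  expect_equal(reacted_fraction(50, gsh), 1)
  # exact proportionality on the linear segment
  expect_equal(reacted_fraction(5, gsh) / reacted_fraction(10, gsh), 0.5)
  # monotone nondecreasing over a fine grid
  cc <- seq(0, 40, by = 0.25)
  expect_true(all(diff(reacted_fraction(cc, gsh)) >= 0))
  expect_error(reacted_fraction(-1, gsh), ">= 0")
})

test_that("mix_decay composes probe states and autofluorescence", {
  gsh <- flim_probes("P-GSH")
  # half reacted, no background: the published two-lifetime pair
  m <- mix_decay(0.5, gsh)
  expect_equal(c(m$alpha1, m$alpha2, m$tau1, m$tau2), c(0.5, 0.5, 6, 225))
  # extremes
  m0 <- mix_decay(0, gsh)
  expect_equal(m0$alpha2, 0)
  m1 <- mix_decay(1, gsh)
  expect_equal(m1$alpha2, 1)
  expect_equal(m1$tau2, 225)
  # autofluorescence pooled into the fast component, photon-preserving mean
  mb <- mix_decay(0.5, gsh, af_frac = 0.2, af_tau = 2.5)
  expect_equal(mb$alpha2, 0.5 * 0.8)
  w_un <- 0.5 * 0.8
  expect_equal(mb$tau1, (w_un * 6 + 0.2 * 2.5) / (w_un + 0.2))
  expect_equal(mb$alpha1 + mb$alpha2, 1)
  expect_error(mix_decay(1.2, gsh), "reacted_frac")
})
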