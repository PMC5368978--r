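test_that("noiseless histograms are recovered to solver tolerance", {
  acq <- acquisition_spec(80, 256)
  cases <- list(c(a2 = 0.4, t1 = 4, t2 = 120),
                c(a2 = 0.5, t1 = 6, t2 = 225),
                c(a2 = 0.7, t1 = 2.5, t2 = 90.5),
                c(a2 = 0.2, t1 = 5.5, t2 = 146))
  for (cs in cases) {
    truth <- decay_params(1 - cs["a2"], cs["a2"], cs["t1"], cs["t2"])
    h <- periodic_bin_means(truth, acq) * 5e4
    f <- fit_histogram(h, acq, fit_options(fix_offset = 0))
    expect_true(f$converged)
    expect_lt(abs(f$params$alpha2 - cs["a2"]) / cs["a2"], 1e-5)
    expect_lt(abs(f$params$tau1 - cs["t1"]) / cs["t1"], 1e-5)
    expect_lt(abs(f$params$tau2 - cs["t2"]) / cs["t2"], 1e-5)
    # optimality sanity: the fit is at least as likely as the truth
    mu_true <- periodic_bin_means(truth, acq) * 5e4
    ll_true <- sum(h * log(mu_true) - mu_true - lgamma(h + 1))
    expect_gte(f$loglik, ll_true - 1e-6)
  }
})

test_that("fitted optimum matches a brute-force grid-search oracle", {
  acq <- acquisition_spec(80, 64)
  for (cs in list(c(a2 = 0.5, t1 = 4, t2 = 100),
                  c(a2 = 0.3, t1 = 6, t2 = 60))) {
    truth <- decay_params(1 - cs["a2"], cs["a2"], cs["t1"], cs["t2"])
    h <- periodic_bin_means(truth, acq) * 2e4
    f <- fit_histogram(h, acq, fit_options(fix_offset = 0))
    # coarse grid around (but not centred on) the truth, amplitude profiled
    N <- sum(h)
    grid_a2 <- seq(cs["a2"] * 0.7, cs["a2"] * 1.3, length.out = 13)
    grid_t1 <- seq(cs["t1"] * 0.7, cs["t1"] * 1.3, length.out = 13)
    grid_t2 <- seq(cs["t2"] * 0.7, cs["t2"] * 1.3, length.out = 13)
    best <- list(dev = Inf)
    for (a2 in grid_a2) for (t1 in grid_t1) for (t2 in grid_t2) {
      p1 <- decay_params(1 - a2, a2, t1, t2)
      s <- oracle_bin_sum(p1, acq)
      pA <- decay_params(1 - a2, a2, t1, t2, amplitude = N / sum(s))
      dev <- oracle_deviance(h, pA, acq)
      if (dev < best$dev) best <- list(dev = dev, a2 = a2, t1 = t1, t2 = t2)
    }
    # grid optimum sits at the grid point nearest the fitted optimum ...
    expect_lt(abs(best$a2 - f$params$alpha2), diff(grid_a2[1:2]))
    expect_lt(abs(best$t1 - f$params$tau1), diff(grid_t1[1:2]))
    expect_lt(abs(best$t2 - f$params$tau2), diff(grid_t2[1:2]))
    # ... and the continuous fit is at least as good as the best grid point
    f_dev <- oracle_deviance(h, f$params, acq)
    expect_lte(f_dev, best$dev + 1e-6)
  }
})

test_that("published lifetimes are recovered from Poisson simulations", {
  # desk-scale version of the full recovery study (see acceptance tests):
  # 20 replicates per lifetime at 1e6 photons
  acq <- acquisition_spec(80, 256)
  opts <- fit_options(fix_offset = 0, compute_stderr = FALSE)
  for (tau in c(6, 90.5, 225)) {
    taus <- vapply(1:20, function(s) {
      h <- sim_mono_hist(tau, 1e6, acq, seed = 40000 + s)
      fit_histogram(h, acq, opts)$params$tau2
    }, numeric(1))
    expect_lt(abs(median(taus) - tau) / tau, 0.10)
  }
})

test_that("low-count histograms are masked, not fitted", {
  acq <- make_acq(64)
  h <- rep(1, 64)
  f <- fit_histogram(h, acq, fit_options(min_photons = 100))
  expect_true(f$masked)
  expect_null(f$params)
  expect_error(fit_histogram(rep(1, 32), acq), "n_bins")
  expect_error(fit_histogram(rep(-1, 64), acq), ">= 0")
})

test_that("slow-lifetime uncertainty inflates as tau2 leaves the window", {
  # with a free offset, tau2 >> T is near-degenerate with the baseline:
  # the curvature-based stderr must blow up as tau2 crosses out of the
  # window (strong growth in rank and magnitude; pointwise values sit on
  # whichever ridge point the MLE lands on, so strict monotonicity is not
  # a property of the estimator)
  acq <- make_acq(64)
  grid <- c(4, 8, 16, 32, 64, 128)
  ses <- vapply(grid, function(t2) {
    truth <- decay_params(0.5, 0.5, 2, t2, offset_c = 0.02)
    h <- periodic_bin_means(truth, acq) * 1e4
    fit_histogram(h, acq, fit_options())$stderr_tau2
  }, numeric(1))
  expect_true(all(is.finite(ses)))
  expect_gt(ses[length(ses)], 10 * ses[1])
  expect_gt(cor(seq_along(grid), ses, method = "spearman"), 0.8)
})

test_that("reduced chi-square is calibrated on well-specified simulations", {
  acq <- make_acq(64)
  truth <- decay_params(0.5, 0.5, 4, 80)
  mu <- periodic_bin_means(truth, acq)
  mu <- mu / sum(mu) * 1e5
  opts <- fit_options(fix_offset = 0, compute_stderr = FALSE)
  chis <- vapply(1:50, function(s) {
    set.seed(50000 + s)
    fit_histogram(rpois(64, mu), acq, opts)$chisq_reduced
  }, numeric(1))
  expect_gt(mean(chis), 0.8)
  expect_lt(mean(chis), 1.2)
})

test_that("roi_decay sums regions and conserves the stack", {
  acq <- acquisition_spec(80, 16)
  set.seed(1)
  counts <- array(rpois(4 * 4 * 16, 5), c(4, 4, 16))
  st <- flim_stack(counts, acq)
  expect_equal(roi_decay(st, cbind(2, 3)), counts[2, 3, ])
  expect_equal(roi_decay(st, rbind(c(1, 1), c(4, 2))),
               counts[1, 1, ] + counts[4, 2, ])
  expect_equal(roi_decay(st, matrix(TRUE, 4, 4)), apply(counts, 3, sum))
  expect_error(roi_decay(st, matrix(FALSE, 4, 4)), "empty")
  expect_error(roi_decay(st, cbind(5, 1)), "out of bounds")
})

test_that("map fitting separates reacted from unreacted regions", {
  # two-region stack: left half unreacted (fast), right half reacted (slow)
  acq <- make_acq(48)
  gsh <- flim_probes("P-GSH")
  nr <- 24; nc <- 24
  p_fast <- mix_decay(0, gsh, af_frac = 0.1)
  p_slow <- mix_decay(0.9, gsh, af_frac = 0.1)
  sh_fast <- periodic_bin_means(p_fast, acq)
  sh_slow <- periodic_bin_means(p_slow, acq)
  set.seed(77)
  counts <- array(0L, c(nr, nc, 48))
  for (i in 1:nr) for (j in 1:nc) {
    sh <- if (j <= nc / 2) sh_fast else sh_slow
    counts[i, j, ] <- rpois(48, sh / sum(sh) * 4000)
  }
  st <- flim_stack(counts, acq)
  maps <- fit_stack(st, fit_options(fix_offset = 0, restart_chisq = 1.5))
  expect_true(all(!maps$mask))
  # pixel-wise agreement with the planted split, each pixel assigned to
  # the nearest planted class (geometric midpoint of the two lifetimes)
  midpoint <- sqrt(p_fast$tau1 * p_slow$tau2)
  called_slow <- maps$tau2 > midpoint
  planted_slow <- col(called_slow) > nc / 2
  expect_gte(mean(called_slow == planted_slow), 0.95)
  # reacted region exceeds the cell positivity threshold in aggregate
  expect_gt(median(maps$tau2[planted_slow]), 100)
  # alpha maps sum to one, lifetimes ordered, where fitted
  expect_equal(maps$alpha1 + maps$alpha2, matrix(1, nr, nc),
               tolerance = 1e-9)
  expect_true(all(maps$tau2 >= maps$tau1))
})

test_that("uniform stacks give spatially homogeneous lifetime maps", {
  acq <- make_acq(48)
  # mono-exponential truth, mono fit
  truth <- decay_params(0, 1, 5, 5)
  mu <- periodic_bin_means(truth, acq)
  mu <- mu / sum(mu) * 5000
  set.seed(12)
  counts <- array(rpois(12 * 12 * 48, rep(mu, each = 144)), c(12, 12, 48))
  maps <- fit_stack(flim_stack(counts, acq),
                    fit_options(fix_offset = 0, components = 1))
  expect_true(all(!maps$mask))
  expect_lt(stats::sd(maps$tau2) / mean(maps$tau2), 0.1)
  expect_lt(abs(mean(maps$tau2) - 5) / 5, 0.05)
  # bi-exponential truth in the identifiable (sub-window) regime
  truth2 <- decay_params(0.5, 0.5, 1.5, 8)
  mu2 <- periodic_bin_means(truth2, acq)
  mu2 <- mu2 / sum(mu2) * 2e4
  set.seed(13)
  counts2 <- array(rpois(12 * 12 * 48, rep(mu2, each = 144)), c(12, 12, 48))
  maps2 <- fit_stack(flim_stack(counts2, acq), fit_options(fix_offset = 0))
  expect_true(all(!maps2$mask))
  expect_lt(stats::sd(maps2$tau2) / mean(maps2$tau2), 0.15)
  expect_lt(abs(mean(maps2$tau2) - 8) / 8, 0.1)
})

test_that("stack and histogram fitters agree on the same data", {
  acq <- make_acq(64)
  truth <- decay_params(0.35, 0.65, 4, 110)
  mu <- periodic_bin_means(truth, acq)
  mu <- mu / sum(mu) * 5e5
  set.seed(31)
  h <- rpois(64, mu)
  fR <- fit_histogram(h, acq, fit_options(fix_offset = 0))
  st <- flim_stack(array(h, c(1, 1, 64)), acq)
  mC <- fit_stack(st, fit_options(fix_offset = 0))
  expect_lt(abs(mC$tau2[1, 1] - fR$params$tau2) / fR$params$tau2, 0.02)
  expect_lt(abs(mC$tau1[1, 1] - fR$params$tau1) / fR$params$tau1, 0.05)
  expect_lt(abs(mC$alpha2[1, 1] - fR$params$alpha2), 0.02)
})

test_that("spatial binning pools neighbourhoods", {
  acq <- acquisition_spec(80, 16)
  counts <- array(1L, c(5, 5, 16))
  st <- flim_stack(counts, acq)
  maps <- fit_stack(st, fit_options(min_photons = 1e9), binning = 1)
  # interior pixel pools (2*1+1)^2 = 9 pixels of 16 photons each
  expect_equal(maps$n_photons[3, 3], 9 * 16)
  expect_equal(maps$n_photons[1, 1], 4 * 16)  # corner: 2x2 neighbourhood
})
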