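#' Options for incomplete-decay fitting
#'
#' @param fix_offset `NULL` to fit the constant baseline `C` freely, or a
#'   single number to hold it fixed (e.g. `0`). Long slow lifetimes and a
#'   free baseline are near-degenerate over a short window, so fixing the
#'   offset is required for accurate recovery of lifetimes far beyond the
#'   inter-pulse period.
#' @param min_photons Minimum total photons in a histogram for a fit to be
#'   attempted; below this the result is masked.
#' @param components 2 (default) for the bi-exponential model, 1 for a
#'   mono-exponential.
#' @param n_starts Number of deterministic restarts from perturbed
#'   initialisations; the best likelihood wins.
#' @param tau_min,tau1_max,tau2_max Lifetime box constraints, ns: the fast
#'   lifetime is searched in `[tau_min, tau1_max]`, the slow one in
#'   `[tau_min, tau2_max]` (components are ordered by lifetime after the
#'   fit).
#' @param min_alpha Amplitude-fraction floor: if the fitted minor component
#'   falls below this, the decay is effectively mono-exponential, the minor
#'   lifetime is unidentifiable, and the histogram is refit with one
#'   component (reported with `tau1 = tau2`).
#' @param restart_chisq Run the extra restarts only when the first fit's
#'   reduced chi-squared exceeds this (Inf = always run all restarts).
#' @param collapse_z Statistical collapse threshold: a fitted component
#'   whose photon content (`A * alpha * tau`) falls below
#'   `collapse_z * sqrt(total photons)` is not significantly nonzero, so the
#'   decay is treated as mono-exponential and refit (0 disables). Stops
#'   noise-driven phantom slow components at low counts.
#' @param compute_stderr Compute the curvature-based standard error of the
#'   slow lifetime (costs a numeric Hessian; per-pixel map fitting turns it
#'   off).
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(fix_offset = NULL, min_photons = 100, components = 2,
                        n_starts = 3, tau_min = 0.1, tau1_max = 12.5,
                        tau2_max = 2000, min_alpha = 0.01,
                        restart_chisq = Inf, collapse_z = 3,
                        compute_stderr = TRUE) {
  stopifnot(components %in% c(1, 2), n_starts >= 1,
            tau_min > 0, tau1_max > tau_min, tau2_max >= tau1_max,
            collapse_z >= 0)
  if (!is.null(fix_offset)) stopifnot(is.numeric(fix_offset), fix_offset >= 0)
  structure(list(fix_offset = fix_offset, min_photons = min_photons,
                 components = components, n_starts = n_starts,
                 tau_min = tau_min, tau1_max = tau1_max, tau2_max = tau2_max,
                 min_alpha = min_alpha, restart_chisq = restart_chisq,
                 collapse_z = collapse_z, compute_stderr = compute_stderr),
            class = "fit_options")
}

# Poisson log-likelihood valid for non-integer "counts" too
.pois_loglik <- function(n, mu) {
  mu <- pmax(mu, 1e-12)
  sum(n * log(mu) - mu - lgamma(n + 1))
}

.reduced_chisq <- function(n, mu, n_par) {
  ok <- mu > 1e-9
  sum((n[ok] - mu[ok])^2 / mu[ok]) / max(1, sum(ok) - n_par)
}

# Tail/head log-linear initialisation. Returns list(tau1, tau2, f2, c0).
.init_decay <- function(h, acq, opt) {
  nb <- acq$n_bins
  tc <- (seq_len(nb) - 0.5) * acq$bin_width
  c0 <- if (is.null(opt$fix_offset)) 0.5 * min(h) else opt$fix_offset
  hc <- pmax(h - c0, 0)
  # slow lifetime from the tail
  tail_idx <- seq.int(max(1L, floor(0.6 * nb)), nb)
  yt <- log(pmax(hc[tail_idx], 0.5))
  ft <- stats::lm.fit(cbind(1, tc[tail_idx]), yt)
  slope <- ft$coefficients[2]
  tau2 <- if (is.finite(slope) && slope < -1e-9) -1 / slope else 10 * acq$period_t
  tau2 <- min(max(tau2, 2), opt$tau2_max)
  # fast lifetime from the head after removing the extrapolated tail
  slow_pred <- exp(ft$coefficients[1] + slope * tc)
  head_idx <- seq_len(max(3L, floor(0.3 * nb)))
  resid <- pmax(hc[head_idx] - slow_pred[head_idx], 0)
  tau1 <- 3
  if (sum(resid > 0) >= 3) {
    fh <- stats::lm.fit(cbind(1, tc[head_idx]), log(pmax(resid, 0.5)))
    sh <- fh$coefficients[2]
    if (is.finite(sh) && sh < -1e-9) tau1 <- -1 / sh
  }
  tau1 <- min(max(tau1, opt$tau_min), opt$tau1_max)
  f2 <- min(max(sum(pmin(slow_pred, hc)) / max(sum(hc), 1), 0.02), 0.98)
  list(tau1 = tau1, tau2 = tau2, f2 = f2, c0 = c0)
}

# Core fitter on a raw histogram; no input validation (see fit_histogram).
.fit_core <- function(h, acq, opt) {
  nb <- acq$n_bins
  N <- sum(h)
  T <- acq$period_t
  free_c <- is.null(opt$fix_offset)
  c_fix <- if (free_c) NA_real_ else opt$fix_offset
  ini <- .init_decay(h, acq, opt)
  two <- opt$components == 2

  unit_total <- function(a2, t1, t2) {
    # expected counts at amplitude 1, C 0
    sum(cpp_bin_means(1, 1 - a2, a2, t1, t2, 0, T, nb))
  }
  make_p0 <- function(t2_mul, f2_mul) {
    t2 <- min(max(ini$tau2 * t2_mul, opt$tau_min * 2), opt$tau2_max)
    f2 <- min(max(ini$f2 * f2_mul, 0.01), 0.99)
    t1 <- ini$tau1
    # photon fraction -> amplitude fraction (wrapped component integrates
    # to A * alpha * tau over one period)
    a2 <- (f2 / t2) / (f2 / t2 + (1 - f2) / t1)
    a2 <- min(max(a2, 0.01), 0.99)
    Nd <- max(N - (if (free_c) ini$c0 else c_fix) * nb, nb * 0.1)
    A0 <- Nd / max(unit_total(if (two) a2 else 1,
                              if (two) t1 else t2, t2), 1e-9)
    if (two) {
      p <- c(log(A0), stats::qlogis(a2), log(t1), log(t2))
    } else {
      p <- c(log(A0), log(t2))
    }
    if (free_c) p <- c(p, ini$c0)
    p
  }

  if (two) {
    lower <- c(-30, -12, log(opt$tau_min), log(opt$tau_min))
    upper <- c(40, 12, log(opt$tau1_max), log(opt$tau2_max))
  } else {
    lower <- c(-30, log(opt$tau_min))
    upper <- c(40, log(opt$tau2_max))
  }
  if (free_c) {
    lower <- c(lower, 0)
    upper <- c(upper, Inf)
  }

  obj <- if (two) {
    function(p) {
      a2 <- stats::plogis(p[2])
      cc <- if (free_c) p[5] else c_fix
      cpp_pois_nll(h, exp(p[1]), 1 - a2, a2, exp(p[3]), exp(p[4]), cc, T)
    }
  } else {
    function(p) {
      cc <- if (free_c) p[3] else c_fix
      cpp_pois_nll(h, exp(p[1]), 0, 1, exp(p[2]), exp(p[2]), cc, T)
    }
  }
  # analytic gradient, chain-ruled through the (log, logit) transforms
  grd <- if (two) {
    function(p) {
      a2 <- stats::plogis(p[2])
      cc <- if (free_c) p[5] else c_fix
      A <- exp(p[1]); t1 <- exp(p[3]); t2 <- exp(p[4])
      G <- cpp_pois_nll_grad(h, A, a2, t1, t2, cc, T)
      g <- c(A * G[1], a2 * (1 - a2) * G[2], t1 * G[3], t2 * G[4])
      if (free_c) c(g, G[5]) else g
    }
  } else {
    function(p) {
      cc <- if (free_c) p[3] else c_fix
      A <- exp(p[1]); tt <- exp(p[2])
      G <- cpp_pois_nll_grad(h, A, 1, tt, tt, cc, T)
      g <- c(A * G[1], tt * G[4])
      if (free_c) c(g, G[5]) else g
    }
  }

  starts <- list(c(1, 1), c(0.25, 0.5), c(4, 1.5), c(1, 0.25), c(0.5, 2))
  n_starts <- min(opt$n_starts, length(starts))
  best <- NULL
  for (s in seq_len(n_starts)) {
    p0 <- make_p0(starts[[s]][1], starts[[s]][2])
    fit <- tryCatch(
      stats::optim(p0, obj, grd, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
    if (s == 1 && is.finite(opt$restart_chisq)) {
      mu1 <- .mu_from_p(best$par, h, acq, opt, two, free_c, c_fix)
      if (.reduced_chisq(h, mu1, length(p0)) <= opt$restart_chisq) break
    }
  }
  if (is.null(best)) {
    return(.masked_fit(N, converged = FALSE))
  }
  # polish passes from the incumbent optimum with a tight tolerance; the
  # multi-exponential valley is shallow, so iterate until no further gain.
  # When C is fixed at 0 the amplitude has the closed-form Poisson MLE
  # A* = N / sum(shape), which we re-impose between passes.
  stationary <- FALSE
  for (rep in 1:4) {
    p1 <- best$par
    if (!free_c && c_fix == 0) {
      s_tot <- if (two)
        unit_total(stats::plogis(p1[2]), exp(p1[3]), exp(p1[4]))
      else unit_total(1, exp(p1[2]), exp(p1[2]))
      p1[1] <- log(N / max(s_tot, 1e-12))
    }
    polish <- tryCatch(
      stats::optim(p1, obj, grd, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 1000, factr = 10)),
      error = function(e) NULL)
    if (is.null(polish)) break
    improved <- polish$value < best$value - 1e-10 * (abs(best$value) + 1)
    if (polish$value <= best$value) best <- polish
    if (!improved) {
      # a fresh tight-tolerance restart could not move the optimum
      stationary <- TRUE
      break
    }
  }
  best$convergence <- if (stationary || best$convergence == 0) 0L else 1L

  p <- best$par
  if (two) {
    a2 <- stats::plogis(p[2]); t1 <- exp(p[3]); t2 <- exp(p[4])
    if (t2 < t1) { tmp <- t1; t1 <- t2; t2 <- tmp; a2 <- 1 - a2 }
    a1 <- 1 - a2
    cc <- if (free_c) p[5] else c_fix
    collapsed <- FALSE
    A_fit <- exp(p[1])
    min_share <- min(A_fit * a1 * t1, A_fit * a2 * t2)  # photons in minor comp
    if (min(a1, a2) < opt$min_alpha ||
        (opt$collapse_z > 0 && min_share < opt$collapse_z * sqrt(max(N, 1)))) {
      opt1 <- opt; opt1$components <- 1
      res1 <- .fit_core(h, acq, opt1)
      res1$collapsed <- TRUE
      return(res1)
    }
  } else {
    a1 <- 0; a2 <- 1; t1 <- exp(p[2]); t2 <- t1
    cc <- if (free_c) p[3] else c_fix
    collapsed <- FALSE
  }
  A <- exp(p[1])
  params <- decay_params(a1, a2, t1, t2, offset_c = cc, amplitude = A)
  mu <- periodic_bin_means(params, acq)
  n_par <- length(p)
  # curvature-based uncertainty on tau2 (delta method from log tau2)
  se_t2 <- NA_real_
  Hs <- if (opt$compute_stderr)
    tryCatch(stats::optimHess(p, obj, grd), error = function(e) NULL)
  else NULL
  if (!is.null(Hs)) {
    V <- tryCatch(solve(Hs), error = function(e) NULL)
    i_t2 <- if (two) 4L else 2L
    if (!is.null(V) && is.finite(V[i_t2, i_t2]) && V[i_t2, i_t2] > 0)
      se_t2 <- t2 * sqrt(V[i_t2, i_t2])
  }
  structure(list(params = params,
                 loglik = .pois_loglik(h, mu),
                 chisq_reduced = .reduced_chisq(h, mu, n_par),
                 n_photons = N,
                 converged = best$convergence == 0,
                 collapsed = collapsed,
                 masked = FALSE,
                 stderr_tau2 = se_t2),
            class = "fit_result")
}

.mu_from_p <- function(p, h, acq, opt, two, free_c, c_fix) {
  if (two) {
    a2 <- stats::plogis(p[2])
    cc <- if (free_c) p[5] else c_fix
    cpp_bin_means(exp(p[1]), 1 - a2, a2, exp(p[3]), exp(p[4]), cc,
                  acq$period_t, acq$n_bins)
  } else {
    cc <- if (free_c) p[3] else c_fix
    cpp_bin_means(exp(p[1]), 0, 1, exp(p[2]), exp(p[2]), cc,
                  acq$period_t, acq$n_bins)
  }
}

.masked_fit <- function(N, converged = FALSE) {
  structure(list(params = NULL, loglik = NA_real_, chisq_reduced = NA_real_,
                 n_photons = N, converged = converged, collapsed = FALSE,
                 masked = TRUE, stderr_tau2 = NA_real_),
            class = "fit_result")
}

#' Fit the incomplete-decay bi-exponential model to a decay histogram
#'
#' Maximises the Poisson likelihood of the bin-integrated periodic
#' (incomplete-decay) bi-exponential model over amplitude, amplitude
#' fractions (constrained to sum to 1), both lifetimes and, optionally, the
#' constant baseline. Initialisation is a log-linear fit to the histogram
#' tail (slow component) and head (fast component), followed by boxed
#' L-BFGS-B with deterministic multi-start. Components are ordered so that
#' `tau1 <= tau2`; an amplitude fraction below `min_alpha` triggers a
#' mono-exponential refit (see [fit_options()]).
#'
#' @param hist Numeric vector of per-bin photon counts, length
#'   `acq$n_bins`.
#' @param acq An [acquisition_spec()].
#' @param options A [fit_options()] list.
#' @return A `fit_result`: `params` ([decay_params()]), `loglik`
#'   (Poisson log-likelihood at the optimum), `chisq_reduced` (Pearson),
#'   `n_photons`, `converged`, `collapsed`, `masked`, and `stderr_tau2`
#'   (curvature-based standard error of the slow lifetime, ns).
#' @export
#' @examples
#' acq <- acquisition_spec(80, 64)
#' truth <- decay_params(0.5, 0.5, 6, 225)
#' h <- periodic_bin_means(truth, acq) * 1e5
#' fit_histogram(h, acq, fit_options(fix_offset = 0))$params
fit_histogram <- function(hist, acq, options = fit_options()) {
  stopifnot(inherits(acq, "acquisition_spec"), inherits(options, "fit_options"),
            is.numeric(hist))
  if (length(hist) != acq$n_bins)
    stop("histogram length (", length(hist), ") must equal acq$n_bins (",
         acq$n_bins, ")")
  if (any(!is.finite(hist)) || any(hist < 0))
    stop("histogram counts must be finite and >= 0")
  if (sum(hist) < options$min_photons) return(.masked_fit(sum(hist)))
  .fit_core(hist, acq, options)
}

#' @export
print.fit_result <- function(x, ...) {
  if (x$masked) {
    cat(sprintf("<fit_result> masked (%.0f photons)\n", x$n_photons))
  } else {
    cat(sprintf(
      "<fit_result> tau = (%.3g, %.3g) ns, alpha2 = %.3g, C = %.3g, chisq_r = %.3g%s\n",
      x$params$tau1, x$params$tau2, x$params$alpha2, x$params$offset_c,
      x$chisq_reduced, if (x$collapsed) " [mono]" else ""))
  }
  invisible(x)
}

#' Sum the decay histogram over a region of interest
#'
#' @param stack A `flim_stack` (see [render_flim()] / [read_flim_stack()]).
#' @param region Either a logical matrix of the stack's spatial shape or a
#'   two-column matrix of (row, col) indices. Must select at least one
#'   pixel.
#' @return Numeric vector of per-bin counts summed over the region.
#' @export
roi_decay <- function(stack, region) {
  stopifnot(inherits(stack, "flim_stack"))
  d <- dim(stack$counts)
  if (is.logical(region)) {
    if (!identical(dim(region), d[1:2]))
      stop("logical region must match the stack's spatial shape")
    idx <- which(region)
  } else {
    region <- as.matrix(region)
    if (ncol(region) != 2) stop("region must be logical or a 2-column index matrix")
    if (nrow(region) == 0) stop("region is empty")
    if (any(region < 1) || any(region[, 1] > d[1]) || any(region[, 2] > d[2]))
      stop("region indices out of bounds")
    idx <- (region[, 2] - 1L) * d[1] + region[, 1]
  }
  if (length(idx) == 0) stop("region is empty")
  m <- matrix(stack$counts, d[1] * d[2], d[3])
  colSums(m[idx, , drop = FALSE])
}

#' Fit the decay model to every pixel of a FLIM stack
#'
#' Optionally pools each pixel's histogram with its square neighbourhood
#' (spatial binning radius `binning` pools `(2*binning+1)^2` pixels, the
#' usual trick for low per-pixel counts), then runs [fit_histogram()] per
#' pixel. Pixels below `min_photons`, outside `mask`, or failing to fit are
#' masked.
#'
#' @param stack A `flim_stack`.
#' @param options A [fit_options()]; per-pixel fitting defaults to lazy
#'   restarts (`restart_chisq = 1.5`).
#' @param binning Spatial binning radius in pixels (0 = off).
#' @param mask Optional logical matrix; only `TRUE` pixels are fitted.
#' @return A `lifetime_maps` object: matrices `tau1`, `tau2`, `alpha1`,
#'   `alpha2`, `offset`, `chisq`, `n_photons`, and logical `mask`
#'   (`TRUE` = excluded), plus the options used.
#' @export
fit_stack <- function(stack,
                      options = fit_options(restart_chisq = 1.5,
                                            compute_stderr = FALSE),
                      binning = 0, mask = NULL) {
  options$compute_stderr <- FALSE  # maps never need per-pixel Hessians
  stopifnot(inherits(stack, "flim_stack"))
  d <- dim(stack$counts)
  nr <- d[1]; nc <- d[2]; nb <- d[3]
  acq <- stack$acq
  stopifnot(nb == acq$n_bins)
  counts <- stack$counts
  if (binning > 0) {
    for (b in seq_len(nb)) counts[, , b] <- .box_sum(counts[, , b], binning)
  }
  photons <- rowSums(counts, dims = 2)
  fit_px <- photons >= options$min_photons
  if (!is.null(mask)) {
    stopifnot(is.logical(mask), identical(dim(mask), d[1:2]))
    fit_px <- fit_px & mask
  }
  empty <- matrix(NA_real_, nr, nc)
  maps <- list(tau1 = empty, tau2 = empty, alpha1 = empty, alpha2 = empty,
               offset = empty, chisq = empty,
               n_photons = photons, mask = !fit_px)
  cmat <- matrix(counts, nr * nc, nb)
  idx <- which(fit_px)
  if (length(idx) > 0) {
    opts <- c(if (is.null(options$fix_offset)) NA_real_ else
                options$fix_offset,
              options$tau_min, options$tau1_max, options$tau2_max,
              options$min_alpha, options$collapse_z, options$restart_chisq,
              options$min_photons, options$components)
    res <- cpp_fit_stack(cmat[idx, , drop = FALSE], acq$period_t, opts)
    # keep iteration-capped fits whose deviance is still acceptable; mask
    # outright failures
    n_par_dev <- (if (is.null(options$fix_offset)) 5L else 4L)
    ok <- is.finite(res[, 4]) &
      (res[, 8] > 0 | res[, 7] / pmax(nb - n_par_dev, 1) < 2)
    maps$mask[idx[!ok]] <- TRUE
    good <- idx[ok]
    maps$tau1[good] <- res[ok, 3]
    maps$tau2[good] <- res[ok, 4]
    maps$alpha1[good] <- res[ok, 1]
    maps$alpha2[good] <- res[ok, 2]
    maps$offset[good] <- res[ok, 5]
    # per-pixel reduced chi-squared approximated by deviance / dof
    n_par <- (if (options$components == 2) 4L else 2L) +
      (if (is.null(options$fix_offset)) 1L else 0L)
    maps$chisq[good] <- res[ok, 7] / pmax(nb - n_par, 1)
  }
  maps$acq <- acq
  maps$options <- options
  maps$binning <- binning
  class(maps) <- "lifetime_maps"
  maps
}

#' @export
print.lifetime_maps <- function(x, ...) {
  n_ok <- sum(!x$mask)
  cat(sprintf("<lifetime_maps> %d x %d px, %d fitted; median tau2 = %.3g ns\n",
              nrow(x$tau2), ncol(x$tau2), n_ok,
              stats::median(x$tau2[!x$mask], na.rm = TRUE)))
  invisible(x)
}

# Sum of a (2r+1)^2 box around each pixel, zero-padded at the borders.
.box_sum <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  cs <- matrix(0, nr + 1, nc + 1)
  cs[-1, -1] <- apply(apply(m, 2, cumsum), 1, cumsum) |> t()
  i1 <- pmax(seq_len(nr) - r, 1); i2 <- pmin(seq_len(nr) + r, nr)
  j1 <- pmax(seq_len(nc) - r, 1); j2 <- pmin(seq_len(nc) + r, nc)
  cs[i2 + 1, j2 + 1, drop = FALSE] - cs[i1, j2 + 1, drop = FALSE] -
    cs[i2 + 1, j1, drop = FALSE] + cs[i1, j1, drop = FALSE]
}
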