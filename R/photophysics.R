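#' Bi-exponential decay parameters
#'
#' Container for the parameters of the bi-exponential fluorescence decay
#' model \deqn{F(t) = A\,(\alpha_1 e^{-t/\tau_1} + \alpha_2 e^{-t/\tau_2}) + C,}
#' the standard per-pixel model for TCSPC lifetime data with a fast
#' (autofluorescence / unreacted probe) and a slow (reacted long-lifetime
#' probe) component. The amplitude fractions satisfy
#' \eqn{\alpha_1 + \alpha_2 = 1} and \eqn{\tau_1 \le \tau_2}.
#'
#' @param alpha1,alpha2 Amplitude fractions of the fast and slow component;
#'   must sum to 1.
#' @param tau1,tau2 Fast and slow decay lifetimes in ns; `0 < tau1 <= tau2`.
#' @param offset_c Constant baseline ('offset'), expected counts per bin;
#'   `>= 0`.
#' @param amplitude Peak decay rate `A` (value of the decaying part at
#'   `t = 0`), arbitrary units; `>= 0`.
#' @return An object of class `decay_params`.
#' @seealso [decay_value()], [periodic_decay_value()]
#' @export
#' @examples
#' decay_params(0.5, 0.5, tau1 = 6, tau2 = 225)
decay_params <- function(alpha1, alpha2, tau1, tau2, offset_c = 0, amplitude = 1) {
  stopifnot(is.numeric(alpha1), is.numeric(alpha2), is.numeric(tau1),
            is.numeric(tau2), is.numeric(offset_c), is.numeric(amplitude))
  if (!all(is.finite(c(alpha1, alpha2, tau1, tau2, offset_c, amplitude))))
    stop("decay parameters must be finite")
  if (abs(alpha1 + alpha2 - 1) > 1e-12)
    stop("alpha1 + alpha2 must equal 1 (got ", alpha1 + alpha2, ")")
  if (tau1 <= 0 || tau2 <= 0) stop("lifetimes must be positive")
  if (tau1 > tau2) stop("tau1 must not exceed tau2")
  if (offset_c < 0) stop("offset_c must be >= 0")
  if (amplitude < 0) stop("amplitude must be >= 0")
  structure(list(alpha1 = alpha1, alpha2 = alpha2, tau1 = tau1, tau2 = tau2,
                 offset_c = offset_c, amplitude = amplitude),
            class = "decay_params")
}

#' @export
print.decay_params <- function(x, ...) {
  cat(sprintf(
    "<decay_params> alpha = (%.4g, %.4g), tau = (%.4g, %.4g) ns, C = %.4g, A = %.4g\n",
    x$alpha1, x$alpha2, x$tau1, x$tau2, x$offset_c, x$amplitude))
  invisible(x)
}

#' TCSPC acquisition geometry
#'
#' Laser repetition rate and TCSPC binning. The inter-pulse period is
#' `1000 / rep_rate` ns; an 80 MHz titanium-sapphire source gives the
#' 12.5 ns measurement window typical of multiphoton FLIM.
#'
#' @param rep_rate Laser repetition rate, MHz.
#' @param n_bins Number of TCSPC time bins spanning one period (`>= 16`).
#' @return An object of class `acquisition_spec` with fields `rep_rate`,
#'   `period_t` (ns), `n_bins`, `bin_width` (ns).
#' @export
#' @examples
#' acquisition_spec(80, 256)$period_t  # 12.5 ns
acquisition_spec <- function(rep_rate = 80, n_bins = 256) {
  stopifnot(is.numeric(rep_rate), length(rep_rate) == 1, rep_rate > 0)
  n_bins <- as.integer(n_bins)
  if (n_bins < 16L) stop("n_bins must be >= 16")
  period_t <- 1000 / rep_rate
  structure(list(rep_rate = rep_rate, period_t = period_t, n_bins = n_bins,
                 bin_width = period_t / n_bins),
            class = "acquisition_spec")
}

#' @export
print.acquisition_spec <- function(x, ...) {
  cat(sprintf("<acquisition_spec> %g MHz, T = %g ns, %d bins of %g ns\n",
              x$rep_rate, x$period_t, x$n_bins, x$bin_width))
  invisible(x)
}

#' Two-state probe photophysics
#'
#' Lifetime and dose-response parameters of a turn-on lifetime probe with an
#' unreacted (PET-quenched, short-lifetime) and a reacted (long-lifetime)
#' state. Use [flim_probes()] for the packaged GSH / H2O2 / HOCl probes.
#'
#' @param name Probe label.
#' @param tau_unreacted,tau_reacted Lifetimes of the two states, ns;
#'   `tau_reacted > tau_unreacted`.
#' @param linear_limit Upper end of the linear dose-response range, uM.
#' @param saturation_conc Analyte concentration at which the response is
#'   maximal, uM; `>= linear_limit`.
#' @return An object of class `probe_spec`.
#' @export
probe_spec <- function(name, tau_unreacted, tau_reacted,
                       linear_limit, saturation_conc) {
  stopifnot(is.character(name), length(name) == 1)
  if (!all(is.finite(c(tau_unreacted, tau_reacted, linear_limit, saturation_conc))))
    stop("probe parameters must be finite")
  if (tau_reacted <= tau_unreacted)
    stop("tau_reacted must exceed tau_unreacted")
  if (linear_limit <= 0 || saturation_conc < linear_limit)
    stop("need 0 < linear_limit <= saturation_conc")
  structure(list(name = name, tau_unreacted = tau_unreacted,
                 tau_reacted = tau_reacted, linear_limit = linear_limit,
                 saturation_conc = saturation_conc),
            class = "probe_spec")
}

#' @export
print.probe_spec <- function(x, ...) {
  cat(sprintf("<probe_spec> %s: tau %g -> %g ns, linear to %g uM, max at %g uM\n",
              x$name, x$tau_unreacted, x$tau_reacted, x$linear_limit,
              x$saturation_conc))
  invisible(x)
}

#' Packaged probe definitions
#'
#' The three published probes: P-GSH (glutathione; 6 to 225 ns, a 38-fold
#' lifetime increase), P-HP (hydrogen peroxide; 5.5 to 146 ns) and P-HA
#' (hypochlorous acid; 4.3 to 90.5 ns). Read from the JSON defaults file
#' shipped in `extdata/probes.json`.
#'
#' @param name Optional single probe name (`"P-GSH"`, `"P-HP"`, `"P-HA"`).
#' @return A named list of [probe_spec()] objects, or a single one if
#'   `name` is given.
#' @export
#' @examples
#' flim_probes("P-GSH")
flim_probes <- function(name = NULL) {
  path <- system.file("extdata", "probes.json", package = "oxiflim")
  raw <- jsonlite::read_json(path)
  probes <- lapply(raw, function(p)
    probe_spec(p$name, p$tau_unreacted, p$tau_reacted,
               p$linear_limit, p$saturation_conc))
  names(probes) <- vapply(probes, `[[`, "", "name")
  if (is.null(name)) return(probes)
  if (!name %in% names(probes))
    stop("unknown probe '", name, "'; available: ",
         paste(names(probes), collapse = ", "))
  probes[[name]]
}

#' Evaluate the plain bi-exponential decay
#'
#' `F(t) = A (alpha1 exp(-t/tau1) + alpha2 exp(-t/tau2)) + C`, the
#' single-pulse (complete-decay) model.
#'
#' @param t Time(s) since excitation, ns; `>= 0`. Vectorised.
#' @param params A [decay_params()] object.
#' @return Expected signal at `t` (same units as `amplitude`).
#' @export
decay_value <- function(t, params) {
  stopifnot(inherits(params, "decay_params"), is.numeric(t))
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be finite and >= 0")
  params$amplitude * (params$alpha1 * exp(-t / params$tau1) +
                      params$alpha2 * exp(-t / params$tau2)) + params$offset_c
}

#' Evaluate the incomplete-decay (periodic) model
#'
#' Under pulsed excitation at period `T`, a fluorophore whose lifetime is
#' comparable to or longer than `T` has not finished decaying when the next
#' pulse arrives; the measured signal is the steady-state superposition of
#' the tails of all preceding pulses,
#' \deqn{F_T(t) = \sum_{k \ge 0} F(t + kT)
#'   = A\left[\frac{\alpha_1 e^{-t/\tau_1}}{1 - e^{-T/\tau_1}}
#'          + \frac{\alpha_2 e^{-t/\tau_2}}{1 - e^{-T/\tau_2}}\right] + C,}
#' the geometric-series closed form of the periodic pulse train. For the
#' long-lifetime reacted probes this accumulated tail is a large
#' quasi-continuous background and the incomplete model is mandatory.
#'
#' @param t Time(s) within one period, ns; `0 <= t < period_t`. Vectorised.
#' @param params A [decay_params()] object.
#' @param acq An [acquisition_spec()] object.
#' @return Expected signal at `t` under steady-state pulsing.
#' @export
#' @examples
#' p <- decay_params(0, 1, tau1 = 225, tau2 = 225)
#' periodic_decay_value(0, p, acquisition_spec(80)) # wrap factor 1/(1-e^-T/tau)
periodic_decay_value <- function(t, params, acq) {
  stopifnot(inherits(params, "decay_params"), inherits(acq, "acquisition_spec"),
            is.numeric(t))
  if (any(!is.finite(t)) || any(t < 0) || any(t >= acq$period_t))
    stop("t must lie in [0, period_t)")
  T <- acq$period_t
  w1 <- 1 / (1 - exp(-T / params$tau1))
  w2 <- 1 / (1 - exp(-T / params$tau2))
  params$amplitude * (params$alpha1 * w1 * exp(-t / params$tau1) +
                      params$alpha2 * w2 * exp(-t / params$tau2)) +
    params$offset_c
}

#' Expected counts per TCSPC bin under the incomplete-decay model
#'
#' Integrates the periodic model over each of the `n_bins` bins of one
#' period (analytic integral of each exponential), returning the expected
#' photon count per bin. `offset_c` is interpreted as counts per bin and is
#' added as-is.
#'
#' @param params A [decay_params()] object.
#' @param acq An [acquisition_spec()] object.
#' @return Numeric vector of length `acq$n_bins`.
#' @export
periodic_bin_means <- function(params, acq) {
  stopifnot(inherits(params, "decay_params"), inherits(acq, "acquisition_spec"))
  cpp_bin_means(params$amplitude, params$alpha1, params$alpha2,
                params$tau1, params$tau2, params$offset_c,
                acq$period_t, acq$n_bins)
}

#' Fraction of probe reacted at a given analyte concentration
#'
#' Dose-response of the turn-on probe: proportional up to the saturating
#' concentration and exactly 1 beyond it. This reproduces the measured
#' behaviour (linear response over the stated linear range, maximal signal
#' at the saturation concentration) with a single proportionality constant.
#'
#' @param conc Analyte concentration(s), uM; `>= 0`. Vectorised.
#' @param probe A [probe_spec()] object.
#' @return Reacted fraction(s) in `[0, 1]`.
#' @export
#' @examples
#' reacted_fraction(c(0, 5, 10, 20, 50), flim_probes("P-GSH"))
reacted_fraction <- function(conc, probe) {
  stopifnot(inherits(probe, "probe_spec"), is.numeric(conc))
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("concentration must be finite and >= 0")
  pmin(conc / probe$saturation_conc, 1)
}

#' Combine probe states and autofluorescence into one bi-exponential
#'
#' Expresses a pixel containing partially reacted probe plus short-lifetime
#' tissue autofluorescence as a single bi-exponential: the slow component is
#' the reacted probe (weight proportional to the reacted fraction) and the
#' fast component pools the unreacted probe with autofluorescence at their
#' amplitude-weighted mean lifetime (which preserves the pool's integrated
#' photon count). Tissue autofluorescence lives at 2-3 ns; the default is
#' the 2.5 ns midpoint.
#'
#' @param reacted_frac Fraction of the probe in the reacted state, `[0, 1]`.
#' @param probe A [probe_spec()] object.
#' @param af_frac Fraction of total decay amplitude contributed by
#'   autofluorescence, `[0, 1)`.
#' @param af_tau Autofluorescence lifetime, ns.
#' @param amplitude,offset_c Passed to the resulting [decay_params()].
#' @return A [decay_params()] object.
#' @export
#' @examples
#' mix_decay(0.5, flim_probes("P-GSH"))  # alpha = (0.5, 0.5), tau = (6, 225)
mix_decay <- function(reacted_frac, probe, af_frac = 0, af_tau = 2.5,
                      amplitude = 1, offset_c = 0) {
  stopifnot(inherits(probe, "probe_spec"))
  if (!is.finite(reacted_frac) || reacted_frac < 0 || reacted_frac > 1)
    stop("reacted_frac must be in [0, 1]")
  if (af_frac < 0 || af_frac >= 1) stop("af_frac must be in [0, 1)")
  probe_w <- 1 - af_frac
  a2 <- reacted_frac * probe_w
  w_unreacted <- (1 - reacted_frac) * probe_w
  a1 <- w_unreacted + af_frac
  if (a1 > 0) {
    tau1 <- (w_unreacted * probe$tau_unreacted + af_frac * af_tau) / a1
  } else {
    tau1 <- probe$tau_unreacted  # zero-weight placeholder
  }
  decay_params(alpha1 = a1, alpha2 = a2, tau1 = tau1,
               tau2 = probe$tau_reacted, offset_c = offset_c,
               amplitude = amplitude)
}
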