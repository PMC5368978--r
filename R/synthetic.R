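#' Scene templates for the synthetic liver-injury experiment
#'
#' Default per-cell intensity structure (expected photons per pixel over one
#' frame) for the three experimental conditions and the two probe channels.
#' The injury condition plants *two* intensity subpopulations of
#' probe-positive cells in the antioxidant (GSH) channel, both dimmer than
#' the control mean — the signature of a differentially susceptible cell
#' subpopulation — while control and treated conditions plant a single
#' population. The reactive-oxygen (ROS) channel plants one population whose
#' mean rises with injury and falls with treatment.
#'
#' @param template `"control"`, `"injury"` or `"treated"`.
#' @param probe_role `"gsh"` (antioxidant channel) or `"ros"`.
#' @return A list with `pop_means`, `pop_sds`, `pop_weights`,
#'   `positive_frac`, `neg_mean`, `neg_sd`.
#' @export
scene_template <- function(template = c("control", "injury", "treated"),
                           probe_role = c("gsh", "ros")) {
  template <- match.arg(template)
  probe_role <- match.arg(probe_role)
  if (probe_role == "gsh") {
    cfg <- switch(template,
      control = list(pop_means = 1200, pop_sds = 100, pop_weights = 1,
                     positive_frac = 0.9),
      injury  = list(pop_means = c(400, 800), pop_sds = c(60, 60),
                     pop_weights = c(0.5, 0.5), positive_frac = 0.75),
      treated = list(pop_means = 1000, pop_sds = 100, pop_weights = 1,
                     positive_frac = 0.9))
  } else {
    cfg <- switch(template,
      control = list(pop_means = 200, pop_sds = 30, pop_weights = 1,
                     positive_frac = 0.15),
      injury  = list(pop_means = 900, pop_sds = 80, pop_weights = 1,
                     positive_frac = 0.8),
      treated = list(pop_means = 300, pop_sds = 40, pop_weights = 1,
                     positive_frac = 0.3))
  }
  # probe-negative cells still carry FAD autofluorescence in this channel
  cfg$neg_mean <- 280
  cfg$neg_sd <- 40
  cfg
}

#' Plant a synthetic cell scene with ground truth
#'
#' Places non-overlapping round cells (discs) of diameters drawn from
#' `diam_range`, assigns each cell a subpopulation label and intensity from
#' the template's Gaussian intensity populations, marks a planted fraction
#' as probe-positive (reacted probe, long lifetime) and the rest as
#' probe-negative (unreacted probe, short lifetime), and records everything
#' needed to score downstream stages: the pixel label map, per-pixel true
#' decay parameters, per-cell truth table, and the population parameters.
#'
#' @param template Condition name, see [scene_template()].
#' @param probe_role `"gsh"` or `"ros"` channel.
#' @param n_cells Number of cells to plant.
#' @param image_shape `c(rows, cols)` in pixels.
#' @param diam_range Cell diameter range, px. The segmenter's published
#'   filter retains 30-70 px objects; the default plants within that range.
#' @param seed Integer RNG seed; the scene is a deterministic function of it.
#' @param min_gap Minimum edge-to-edge distance between planted cells, px.
#'   Must exceed the segmenter's smoothing reach or neighbouring cells merge
#'   into one thresholded object.
#' @param probe A [probe_spec()]; defaults to P-GSH for the gsh role and
#'   P-HP for ros.
#' @param reacted_frac_positive Reacted probe fraction inside positive
#'   cells.
#' @param af_frac Autofluorescence share of in-cell decay amplitude.
#' @param af_tau Autofluorescence lifetime, ns (tissue: 2-3 ns).
#' @param background_level Expected photons per background pixel.
#' @param bright_negative_frac Fraction of cells planted intensity-bright
#'   but with *unreacted* probe — the intensity-only false positives that
#'   lifetime imaging is designed to reject.
#' @param config Named list overriding any [scene_template()] field.
#' @return A list of class `flim_scene` with elements `cells` (per-cell
#'   truth data frame), `label_map`, `intensity_map`, `tau1_map`,
#'   `tau2_map`, `alpha2_map`, `params_by_cell`, `background_params`,
#'   `template`, `probe`, `pop` (population truth) and `seed`.
#' @export
#' @examples
#' sc <- make_scene("injury", n_cells = 4, image_shape = c(128, 128), seed = 1)
#' table(sc$cells$subpop)
make_scene <- function(template = c("control", "injury", "treated"),
                       probe_role = c("gsh", "ros"),
                       n_cells = 40, image_shape = c(512, 512),
                       diam_range = c(30, 70), seed = 1, min_gap = 8,
                       probe = NULL, reacted_frac_positive = 0.9,
                       af_frac = 0.1, af_tau = 2.5, background_level = 20,
                       bright_negative_frac = 0, config = list()) {
  template <- match.arg(template)
  probe_role <- match.arg(probe_role)
  stopifnot(length(image_shape) == 2, all(image_shape >= 32),
            diam_range[1] <= diam_range[2], n_cells >= 0)
  if (is.null(probe))
    probe <- flim_probes(if (probe_role == "gsh") "P-GSH" else "P-HP")
  cfg <- scene_template(template, probe_role)
  cfg[names(config)] <- config
  set.seed(seed)
  nr <- image_shape[1]; nc <- image_shape[2]

  # --- placement: rejection-sample non-overlapping in-bounds discs
  diam <- stats::runif(n_cells, diam_range[1], diam_range[2])
  cx <- cy <- numeric(n_cells)
  if (n_cells > 0) {
    for (i in seq_len(n_cells)) {
      r <- diam[i] / 2
      placed <- FALSE
      for (try in seq_len(4000)) {
        x <- stats::runif(1, r + 2, nr - r - 2)
        y <- stats::runif(1, r + 2, nc - r - 2)
        if (i == 1 || all(sqrt((x - cx[seq_len(i - 1)])^2 +
                               (y - cy[seq_len(i - 1)])^2) >
                          (r + diam[seq_len(i - 1)] / 2 + min_gap))) {
          cx[i] <- x; cy[i] <- y; placed <- TRUE; break
        }
      }
      if (!placed)
        stop("infeasible packing: could not place cell ", i, " of ", n_cells)
    }
  }

  # --- per-cell labels and intensities
  k <- length(cfg$pop_means)
  positive <- stats::runif(n_cells) < cfg$positive_frac
  bright_neg <- !positive & (stats::runif(n_cells) < bright_negative_frac /
                               max(1 - cfg$positive_frac, 1e-9))
  subpop <- integer(n_cells)
  subpop[positive] <- sample.int(k, sum(positive), replace = TRUE,
                                 prob = cfg$pop_weights)
  intensity <- numeric(n_cells)
  if (any(positive))
    intensity[positive] <- stats::rnorm(sum(positive),
                                        cfg$pop_means[subpop[positive]],
                                        cfg$pop_sds[subpop[positive]])
  if (any(!positive))
    intensity[!positive] <- stats::rnorm(sum(!positive), cfg$neg_mean,
                                         cfg$neg_sd)
  if (any(bright_neg))
    intensity[bright_neg] <- stats::rnorm(sum(bright_neg),
                                          max(cfg$pop_means),
                                          cfg$pop_sds[which.max(cfg$pop_means)])
  intensity <- pmax(intensity, 10)
  rf <- ifelse(positive, reacted_frac_positive, 0)

  # --- rasterise
  label_map <- matrix(0L, nr, nc)
  intensity_map <- matrix(background_level, nr, nc)
  bg_params <- decay_params(0, 1, af_tau, af_tau)
  tau1_map <- matrix(bg_params$tau1, nr, nc)
  tau2_map <- matrix(bg_params$tau2, nr, nc)
  alpha2_map <- matrix(1, nr, nc)
  params_by_cell <- vector("list", n_cells)
  rows <- row(label_map); cols <- col(label_map)
  for (i in seq_len(n_cells)) {
    px <- (rows - cx[i])^2 + (cols - cy[i])^2 <= (diam[i] / 2)^2
    label_map[px] <- i
    intensity_map[px] <- intensity[i]
    p <- mix_decay(rf[i], probe, af_frac = af_frac, af_tau = af_tau)
    params_by_cell[[i]] <- p
    tau1_map[px] <- p$tau1
    # effective slow lifetime: with no reacted amplitude the decay is
    # mono-exponential at the fast lifetime, which is what any fitter
    # (and the positivity rule) sees
    tau2_map[px] <- if (p$alpha2 > 0) p$tau2 else p$tau1
    alpha2_map[px] <- p$alpha2
  }

  cells <- data.frame(
    cell_id = seq_len(n_cells), row = cx, col = cy, diameter = diam,
    subpop = subpop, positive = positive, bright_negative = bright_neg,
    reacted_frac = rf, intensity = intensity)
  structure(list(cells = cells, label_map = label_map,
                 intensity_map = intensity_map, tau1_map = tau1_map,
                 tau2_map = tau2_map, alpha2_map = alpha2_map,
                 params_by_cell = params_by_cell,
                 background_params = bg_params,
                 template = template, probe_role = probe_role, probe = probe,
                 pop = cfg, image_shape = image_shape,
                 background_level = background_level, seed = seed),
            class = "flim_scene")
}

#' @export
print.flim_scene <- function(x, ...) {
  cat(sprintf("<flim_scene> %s/%s: %d cells on %d x %d px (seed %d)\n",
              x$template, x$probe_role, nrow(x$cells), x$image_shape[1],
              x$image_shape[2], x$seed))
  invisible(x)
}

#' Simulate a TCSPC photon-count stack from a planted scene
#'
#' Forward model for the FLIM acquisition: each pixel's expected per-bin
#' counts are its planted intensity times the (normalised) bin-integrated
#' incomplete-decay curve of its true decay parameters; observed counts are
#' independent Poisson draws. Pixels inside a cell decay with the cell's
#' probe mixture; background pixels with the short autofluorescence
#' lifetime.
#'
#' @param scene A `flim_scene` from [make_scene()].
#' @param acq An [acquisition_spec()].
#' @param seed Integer RNG seed for the photon noise.
#' @param channel Spectral-window label stored with the stack.
#' @return A `flim_stack`: integer `counts` array (rows x cols x n_bins),
#'   `acq`, and `channel`.
#' @export
render_flim <- function(scene, acq = acquisition_spec(80, 64), seed = 1,
                        channel = "515-620nm") {
  stopifnot(inherits(scene, "flim_scene"), inherits(acq, "acquisition_spec"))
  set.seed(seed)
  nr <- scene$image_shape[1]; nc <- scene$image_shape[2]
  nb <- acq$n_bins
  counts <- array(0L, dim = c(nr, nc, nb))
  cmat <- matrix(0L, nr * nc, nb)
  shape_of <- function(p) {
    b <- periodic_bin_means(p, acq)
    b / sum(b)
  }
  groups <- c(list(shape_of(scene$background_params)),
              lapply(scene$params_by_cell, shape_of))
  lab <- as.vector(scene$label_map)
  intens <- as.vector(scene$intensity_map)
  for (g in seq_along(groups)) {
    idx <- which(lab == g - 1L)
    if (length(idx) == 0) next
    mu <- outer(intens[idx], groups[[g]])
    cmat[idx, ] <- stats::rpois(length(mu), mu)
  }
  counts[] <- cmat
  structure(list(counts = counts, acq = acq, channel = channel),
            class = "flim_stack")
}

#' Construct a FLIM photon-count stack
#'
#' @param counts Nonnegative integer array, rows x cols x time bins; the
#'   third dimension must equal `acq$n_bins`.
#' @param acq An [acquisition_spec()].
#' @param channel Spectral-window label.
#' @return A `flim_stack`.
#' @export
flim_stack <- function(counts, acq, channel = "515-620nm") {
  stopifnot(inherits(acq, "acquisition_spec"), is.array(counts),
            length(dim(counts)) == 3)
  if (dim(counts)[3] != acq$n_bins)
    stop("third dimension of counts (", dim(counts)[3],
         ") must equal acq$n_bins (", acq$n_bins, ")")
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be finite and >= 0")
  structure(list(counts = counts, acq = acq, channel = channel),
            class = "flim_stack")
}

#' @export
print.flim_stack <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<flim_stack> %d x %d px x %d bins (%s), %.3g photons total\n",
              d[1], d[2], d[3], x$channel, sum(x$counts)))
  invisible(x)
}

#' Time-integrated intensity image of a FLIM stack
#'
#' The fluorescence intensity image acquired jointly with FLIM is the
#' per-pixel photon sum over all time bins; total photons are conserved.
#'
#' @param stack A `flim_stack`.
#' @return Numeric matrix of per-pixel photon counts.
#' @export
render_intensity <- function(stack) {
  stopifnot(inherits(stack, "flim_stack"))
  rowSums(stack$counts, dims = 2)
}
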