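#' Optical oxidative stress index
#'
#' The optical OSI is the ratio of the mean per-cell ROS-probe intensity to
#' the mean per-cell antioxidant (GSH)-probe intensity, a composite imaging
#' endpoint of redox balance: it rises when ROS accumulate or the GSH pool
#' is consumed, and falls on successful antioxidant treatment. By default
#' only probe-positive cells (lifetime-verified) enter each mean, so
#' intensity-only false positives cannot contaminate the index. The two
#' probes cannot be co-injected, so the ROS and GSH records come from
#' parallel scenes of the same condition.
#'
#' @param ros_cells,gsh_cells Cell-record data frames from
#'   [quantify_cells()] for the ROS-probe and GSH-probe scenes.
#' @param positive_only Use only probe-positive cells (default `TRUE`).
#' @param group,timepoint Optional labels carried into the result.
#' @return An `osi_result` list: `mean_ros_intensity`, `mean_gsh_intensity`,
#'   `osi`, `n_cells_ros`, `n_cells_gsh`, `group`, `timepoint`.
#' @export
#' @examples
#' ros <- data.frame(mean_intensity = c(20, 20), classified = TRUE, positive = TRUE)
#' gsh <- data.frame(mean_intensity = c(40, 40), classified = TRUE, positive = TRUE)
#' compute_osi(ros, gsh)$osi  # 0.5
compute_osi <- function(ros_cells, gsh_cells, positive_only = TRUE,
                        group = NA_character_, timepoint = NA_character_) {
  pick <- function(df, what) {
    stopifnot(is.data.frame(df))
    if (positive_only && all(c("classified", "positive") %in% names(df)))
      df <- df[df$classified & df$positive %in% TRUE, , drop = FALSE]
    v <- df$mean_intensity
    if (length(v) == 0) stop("no usable ", what, " cells")
    if (any(!is.finite(v))) stop("non-finite ", what, " intensities")
    v
  }
  ros <- pick(ros_cells, "ROS")
  gsh <- pick(gsh_cells, "GSH")
  m_ros <- mean(ros)
  m_gsh <- mean(gsh)
  if (m_gsh <= 0) stop("mean GSH intensity must be positive")
  structure(list(mean_ros_intensity = m_ros, mean_gsh_intensity = m_gsh,
                 osi = m_ros / m_gsh, n_cells_ros = length(ros),
                 n_cells_gsh = length(gsh), group = group,
                 timepoint = timepoint),
            class = "osi_result")
}

#' @export
print.osi_result <- function(x, ...) {
  cat(sprintf("<osi_result> OSI = %.4g (ROS %.4g / GSH %.4g; n = %d, %d)\n",
              x$osi, x$mean_ros_intensity, x$mean_gsh_intensity,
              x$n_cells_ros, x$n_cells_gsh))
  invisible(x)
}

#' Pairwise Student's t tests with Bonferroni correction
#'
#' Two-sided two-sample t tests between every pair of groups (or a supplied
#' subset of pairs), with the Bonferroni multiplier equal to the number of
#' comparisons performed: `p_adj = min(1, p_raw * m)`. Classic
#' equal-variance Student's t by default; set `var_equal = FALSE` for
#' Welch.
#'
#' @param samples Named list of numeric vectors, one per group; each needs
#'   at least 2 values.
#' @param alpha Significance level for the `significant` flag.
#' @param var_equal Pool the variances (Student) or not (Welch).
#' @param m Bonferroni multiplier; defaults to the number of pairs tested.
#' @return A data frame with one row per pair: `group1`, `group2`, `n1`,
#'   `n2`, `t`, `df`, `p_raw`, `p_adj`, `significant`.
#' @export
#' @examples
#' compare_groups(list(a = rnorm(10), b = rnorm(10, 3), c = rnorm(10)))
compare_groups <- function(samples, alpha = 0.05, var_equal = TRUE, m = NULL) {
  stopifnot(is.list(samples), length(samples) >= 2)
  if (is.null(names(samples)) || any(names(samples) == ""))
    names(samples) <- paste0("group", seq_along(samples))
  ns <- lengths(samples)
  if (any(ns < 2)) stop("every group needs at least 2 values")
  pairs <- utils::combn(names(samples), 2)
  n_pairs <- ncol(pairs)
  if (is.null(m)) m <- n_pairs
  out <- lapply(seq_len(n_pairs), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    tt <- stats::t.test(samples[[g1]], samples[[g2]], var.equal = var_equal)
    data.frame(group1 = g1, group2 = g2,
               n1 = length(samples[[g1]]), n2 = length(samples[[g2]]),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value, p_adj = min(1, tt$p.value * m))
  })
  res <- do.call(rbind, out)
  res$significant <- res$p_adj < alpha
  res
}
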