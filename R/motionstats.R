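## Population movement statistics for pooled movement vectors.
## Headings are degrees clockwise from the upward axis (0 = up, 90 = right,
## 180 = down); all statistics are plain functions of the heading list so
## they can be checked against closed forms.

check_headings <- function(headings) {
  if (length(headings) == 0)
    stop("headings must be non-empty", call. = FALSE)
  stop_if_not_finite(headings, "headings")
  invisible(headings)
}

#' Mean resultant length (r-value) of a set of headings
#'
#' The precision of orientation of the population: 0 means no common
#' movement direction, 1 means all cells swim in the same direction.
#' r = sqrt((sum cos)^2 + (sum sin)^2) / n.
#'
#' @param headings numeric vector of headings, degrees.
#' @return r in `[0, 1]`.
#' @examples
#' r_value(rep(37, 10))          # 1
#' r_value(c(0, 90, 180, 270))   # 0
#' @export
r_value <- function(headings) {
  check_headings(headings)
  th <- deg2rad(headings)
  min(sqrt(sum(cos(th))^2 + sum(sin(th))^2) / length(th), 1)
}

#' Circular mean heading, degrees
#'
#' Direction of the resultant vector of all headings.
#'
#' @param headings numeric vector of headings, degrees.
#' @return mean heading in `[0, 360)`.
#' @export
mean_heading <- function(headings) {
  check_headings(headings)
  th <- deg2rad(headings)
  wrap360(rad2deg(atan2(sum(sin(th)), sum(cos(th)))))
}

#' Alignment: vertical vs horizontal swimming
#'
#' Second-order (axial) orientation statistic, mean of cos(2 theta):
#' positive when cells swim vertically (up or down alike), negative when
#' they swim horizontally, near zero without orientation.
#'
#' @param headings numeric vector of headings, degrees.
#' @return alignment in `[-1, 1]`.
#' @export
alignment <- function(headings) {
  check_headings(headings)
  mean(cos(2 * deg2rad(headings)))
}

#' Direction index: upward minus downward fraction
#'
#' Fraction of cells swimming upward minus fraction swimming downward.
#' Negative values mean downward swimming (positive gravitaxis), positive
#' values upward swimming (negative gravitaxis). Headings exactly on the
#' horizontal (90 or 270 degrees) count as neither.
#'
#' @param headings numeric vector of headings, degrees.
#' @return direction index in `[-1, 1]`.
#' @export
direction_index <- function(headings) {
  check_headings(headings)
  h <- wrap360(headings)
  up <- (h >= 0 & h < 90) | (h > 270 & h < 360)
  down <- h > 90 & h < 270
  (sum(up) - sum(down)) / length(h)
}

#' Fraction of cells swimming upward within a 120-degree cone
#'
#' Fraction of headings within +/- 60 degrees of the upward axis (cone
#' boundary included).
#'
#' @param headings numeric vector of headings, degrees.
#' @return fraction in `[0, 1]`.
#' @export
upward120 <- function(headings) {
  check_headings(headings)
  h <- wrap360(headings)
  dist0 <- pmin(h, 360 - h)  # angular distance to 0
  mean(dist0 <= 60)
}

#' Form factor (circularity) of an object
#'
#' Squared circumference over area, normalized so a circle scores exactly
#' 1; elongated cells score higher.
#'
#' @param perimeter object circumference (any length unit).
#' @param area object area (same unit squared).
#' @return form factor >= 1 for exact geometry (discretized contours can
#'   dip slightly below).
#' @examples
#' form_factor(2 * pi, pi)  # circle of radius 1 -> 1
#' form_factor(4, 1)        # unit square -> 4 / pi
#' @export
form_factor <- function(perimeter, area) {
  if (any(perimeter <= 0) || any(area <= 0))
    stop("perimeter and area must be > 0", call. = FALSE)
  perimeter^2 / (4 * pi * area)
}

#' Velocity and motility of a vector population
#'
#' Motility is the percentage of vectors at or above the speed threshold;
#' velocity is the mean speed of those motile vectors only.
#'
#' @param speeds numeric vector of vector speeds, um/s.
#' @param speed_threshold motility cut-off, um/s (>= 0).
#' @return list with `velocity` (um/s; `NA` with a warning when nothing is
#'   motile) and `motility` (percent).
#' @export
velocity_and_motility <- function(speeds, speed_threshold = 10) {
  stopifnot(speed_threshold >= 0, length(speeds) > 0)
  motile <- speeds >= speed_threshold
  motility <- 100 * mean(motile)
  if (!any(motile)) {
    warning("no motile vectors at this threshold; velocity undefined")
    return(list(velocity = NA_real_, motility = motility))
  }
  list(velocity = mean(speeds[motile]), motility = motility)
}

#' Circular histogram of headings
#'
#' Counts per angular bin over half-open bins
#' `[k*360/n_bins, (k+1)*360/n_bins)`; an angle exactly on a bin edge goes
#' to the upper bin.
#'
#' @param headings numeric vector of headings, degrees (may be empty).
#' @param n_bins number of bins, >= 4.
#' @return data.frame `bin_start_deg`, `count`; counts sum to
#'   `length(headings)`.
#' @export
polar_histogram <- function(headings, n_bins = 64) {
  stopifnot(n_bins >= 4)
  width <- 360 / n_bins
  starts <- (seq_len(n_bins) - 1) * width
  if (length(headings) == 0)
    return(data.frame(bin_start_deg = starts, count = rep(0L, n_bins)))
  stop_if_not_finite(headings, "headings")
  k <- floor(wrap360(headings) / width) + 1
  k[k > n_bins] <- n_bins  # numeric fuzz just under 360
  data.frame(bin_start_deg = starts,
             count = tabulate(k, nbins = n_bins))
}

#' Summarize a pooled vector population into the eight movement parameters
#'
#' Computes the full behavioural readout of one (or several pooled)
#' measurements: motility over all vectors; velocity, orientation
#' statistics (r-value, mean heading, alignment, direction, 120-degree
#' upward fraction) and the circular histogram over the motile subset
#' (immotile jitter has meaningless headings); mean form factor over all
#' vectors carrying shape information.
#'
#' @param vectors data.frame of movement vectors as produced by
#'   [link_tracks()] (needs `heading_deg`, `speed_um_s`; `mean_area` and
#'   `mean_perimeter` optional).
#' @param speed_threshold motility cut-off, um/s.
#' @param n_bins histogram bins.
#' @return object of class `motion_summary`: a list with `n_vectors`,
#'   `n_motile`, `velocity`, `motility`, `form_factor`, `alignment`,
#'   `direction`, `upward120`, `r_value`, `mean_heading_deg` and
#'   `histogram`.
#' @export
summarize_motion <- function(vectors, speed_threshold = 10, n_bins = 64) {
  stopifnot(is.data.frame(vectors))
  if (nrow(vectors) == 0) stop("no movement vectors", call. = FALSE)
  vm <- velocity_and_motility(vectors$speed_um_s, speed_threshold)
  motile <- vectors[vectors$speed_um_s >= speed_threshold, , drop = FALSE]
  ff <- if (!is.null(vectors$mean_perimeter) &&
            any(is.finite(vectors$mean_perimeter))) {
    ok <- is.finite(vectors$mean_perimeter) & is.finite(vectors$mean_area)
    mean(form_factor(vectors$mean_perimeter[ok], vectors$mean_area[ok]))
  } else NA_real_
  h <- motile$heading_deg
  res <- list(
    n_vectors = nrow(vectors),
    n_motile = nrow(motile),
    velocity = vm$velocity,
    motility = vm$motility,
    form_factor = ff,
    alignment = if (nrow(motile)) alignment(h) else NA_real_,
    direction = if (nrow(motile)) direction_index(h) else NA_real_,
    upward120 = if (nrow(motile)) upward120(h) else NA_real_,
    r_value = if (nrow(motile)) r_value(h) else NA_real_,
    mean_heading_deg = if (nrow(motile)) mean_heading(h) else NA_real_,
    histogram = polar_histogram(h, n_bins))
  class(res) <- "motion_summary"
  res
}

#' @export
print.motion_summary <- function(x, ...) {
  cat("Population movement summary (", x$n_vectors, " vectors, ",
      x$n_motile, " motile)\n", sep = "")
  cat(sprintf("  velocity      %8.2f um/s\n", x$velocity))
  cat(sprintf("  motility      %8.2f %%\n", x$motility))
  cat(sprintf("  form factor   %8.3f\n", x$form_factor))
  cat(sprintf("  alignment     %+8.3f\n", x$alignment))
  cat(sprintf("  direction     %+8.3f\n", x$direction))
  cat(sprintf("  120deg upward %8.3f\n", x$upward120))
  cat(sprintf("  r-value       %8.3f\n", x$r_value))
  cat(sprintf("  mean heading  %8.1f deg\n", x$mean_heading_deg))
  invisible(x)
}

#' Draw the circular histogram of a motion summary
#'
#' Polar rose plot with 0 degrees (upward) at the top and angles running
#' clockwise, matching the heading convention.
#'
#' @param summary a `motion_summary` or a histogram data.frame
#'   (`bin_start_deg`, `count`).
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the histogram data.frame.
#' @export
plot_polar_histogram <- function(summary, ...) {
  h <- if (inherits(summary, "motion_summary")) summary$histogram else summary
  n <- nrow(h)
  width <- 360 / n
  r <- h$count / max(h$count, 1)
  mid <- deg2rad(h$bin_start_deg + width / 2)
  # polar -> cartesian with 0 deg up, clockwise
  graphics::plot(NA, xlim = c(-1, 1), ylim = c(-1, 1), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", ...)
  graphics::symbols(0, 0, circles = 1, inches = FALSE, add = TRUE,
                    fg = "grey70")
  for (i in seq_len(n)) {
    a0 <- deg2rad(h$bin_start_deg[i])
    a1 <- deg2rad(h$bin_start_deg[i] + width)
    aa <- seq(a0, a1, length.out = 8)
    graphics::polygon(c(0, r[i] * sin(aa)), c(0, r[i] * cos(aa)),
                      col = "steelblue", border = "white")
  }
  graphics::text(0, 1.05, "0°"); graphics::text(1.08, 0, "90°")
  graphics::text(0, -1.05, "180°"); graphics::text(-1.1, 0, "270°")
  invisible(h)
}
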