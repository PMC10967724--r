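#' Configuration for the swimming-population simulator
#'
#' Bundles and validates all parameters of [simulate_tracks()]. Geometry is
#' in micrometres throughout; pixels enter only if frames are rasterized.
#' The defaults describe one 3-minute dark-room measurement at 20 frames
#' per second, the recording regime the behavioural statistics assume.
#'
#' @param n_cells number of cells in the field.
#' @param motile_fraction fraction of cells that swim (the rest only
#'   jitter), in `[0, 1]`.
#' @param mu_deg population mean heading, degrees (0 = upward, 180 =
#'   downward, clockwise positive).
#' @param kappa von Mises concentration of per-cell headings, >= 0
#'   (0 = random orientation).
#' @param speed_mean,speed_sd mean and SD of per-cell swimming speed, um/s.
#' @param fps frame rate, frames per second.
#' @param duration_s recording duration, seconds.
#' @param px_per_um pixels per micrometre (used only when rasterizing).
#' @param cell_major_um,cell_minor_um ellipse axis lengths of a cell, um.
#' @param arena_w_um,arena_h_um field of view, um.
#' @param heading_jitter_sd_deg per-frame angular jitter SD, degrees; keeps
#'   5-frame runs nearly straight while avoiding perfectly rigid motion.
#' @param immotile_jitter_um positional jitter SD of immotile cells,
#'   um/frame; small enough to stay under any sensible motility threshold.
#' @param seed RNG seed.
#' @return a validated list of class `track_sim_config`.
#' @export
track_sim_config <- function(n_cells = 200,
                             motile_fraction = 0.9,
                             mu_deg = 0,
                             kappa = 2,
                             speed_mean = 50,
                             speed_sd = 10,
                             fps = 20,
                             duration_s = 180,
                             px_per_um = 0.5,
                             cell_major_um = 50,
                             cell_minor_um = 10,
                             arena_w_um = 2000,
                             arena_h_um = 2000,
                             heading_jitter_sd_deg = 5,
                             immotile_jitter_um = 0.5,
                             seed = 1L) {
  cfg <- list(n_cells = as.integer(n_cells),
              motile_fraction = motile_fraction, mu_deg = mu_deg,
              kappa = kappa, speed_mean = speed_mean, speed_sd = speed_sd,
              fps = fps, duration_s = duration_s, px_per_um = px_per_um,
              cell_major_um = cell_major_um, cell_minor_um = cell_minor_um,
              arena_w_um = arena_w_um, arena_h_um = arena_h_um,
              heading_jitter_sd_deg = heading_jitter_sd_deg,
              immotile_jitter_um = immotile_jitter_um,
              seed = as.integer(seed))
  num <- unlist(cfg[setdiff(names(cfg), "seed")])
  stop_if_not_finite(num, "track_sim_config")
  if (cfg$kappa < 0) stop("kappa must be >= 0", call. = FALSE)
  if (cfg$motile_fraction < 0 || cfg$motile_fraction > 1)
    stop("motile_fraction must be in [0, 1]", call. = FALSE)
  if (cfg$fps <= 0) stop("fps must be > 0", call. = FALSE)
  if (cfg$speed_mean < 0 || cfg$speed_sd < 0)
    stop("speeds must be >= 0", call. = FALSE)
  if (cfg$n_cells < 0 || cfg$duration_s <= 0 ||
      cfg$arena_w_um <= 0 || cfg$arena_h_um <= 0 ||
      cfg$cell_major_um <= 0 || cfg$cell_minor_um <= 0 ||
      cfg$px_per_um <= 0 || cfg$immotile_jitter_um < 0 ||
      cfg$heading_jitter_sd_deg < 0)
    stop("invalid (negative or zero) geometry in track_sim_config",
         call. = FALSE)
  class(cfg) <- "track_sim_config"
  cfg
}

## Reflect a coordinate into [0, w], mirroring as many times as needed,
## and report whether the net number of reflections is odd.
reflect_coord <- function(x, w) {
  period <- 2 * w
  xm <- x %% period
  flipped <- xm > w
  xr <- ifelse(flipped, period - xm, xm)
  list(x = xr, flipped = flipped)
}

#' Simulate a swimming Euglena population as per-frame object tables
#'
#' Motile cells get one fixed heading drawn from von Mises(`mu_deg`,
#' `kappa`) plus small per-frame angular jitter, and a per-cell speed with
#' per-frame jitter; immotile cells only wobble in place. Positions reflect
#' at the arena walls with mirrored headings. The frame table carries no
#' object identity: the tracking stage has to recover it.
#'
#' @param config a [track_sim_config()].
#' @return list with `frames` (data.frame `frame`, `x_um`, `y_um`,
#'   `area_um2`, `perimeter_um`; row order randomized within each frame)
#'   and `truth` (data.frame `cell`, `motile`, `heading_deg`,
#'   `speed_um_s`). y points up; headings are degrees clockwise from up.
#' @export
simulate_tracks <- function(config = track_sim_config()) {
  stopifnot(inherits(config, "track_sim_config"))
  set.seed(config$seed)
  n <- config$n_cells
  n_frames <- as.integer(round(config$duration_s * config$fps)) + 1L
  dt <- 1 / config$fps

  motile <- stats::runif(n) < config$motile_fraction
  heading <- rvonmises_deg(n, config$mu_deg, config$kappa)
  speed <- pmax(stats::rnorm(n, config$speed_mean, config$speed_sd), 0)
  speed[!motile] <- 0

  # ellipse area and Ramanujan perimeter, with mild per-cell size variation
  a <- config$cell_major_um / 2 * stats::runif(n, 0.9, 1.1)
  b <- config$cell_minor_um / 2 * stats::runif(n, 0.9, 1.1)
  area <- pi * a * b
  h <- ((a - b) / (a + b))^2
  perim <- pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))

  x0 <- stats::runif(n, 0, config$arena_w_um)
  y0 <- stats::runif(n, 0, config$arena_h_um)

  ## unreflected trajectories, then fold into the arena; the fold mirrors
  ## the instantaneous heading automatically, which is what a wall does
  jit_ang <- matrix(stats::rnorm(n * n_frames, 0,
                                 config$heading_jitter_sd_deg),
                    nrow = n)
  jit_spd <- matrix(pmax(stats::rnorm(n * n_frames, 1, 0.05), 0), nrow = n)
  theta <- deg2rad(heading + jit_ang)          # n x n_frames
  step <- speed * dt * jit_spd
  dx <- step * sin(theta)
  dy <- step * cos(theta)
  # immotile: pure positional jitter, no persistent direction
  if (any(!motile)) {
    k <- sum(!motile)
    dx[!motile, ] <- stats::rnorm(k * n_frames, 0, config$immotile_jitter_um)
    dy[!motile, ] <- stats::rnorm(k * n_frames, 0, config$immotile_jitter_um)
  }
  X <- x0 + t(apply(cbind(0, dx[, -n_frames, drop = FALSE]), 1, cumsum))
  Y <- y0 + t(apply(cbind(0, dy[, -n_frames, drop = FALSE]), 1, cumsum))
  Xr <- reflect_coord(X, config$arena_w_um)$x
  Yr <- reflect_coord(Y, config$arena_h_um)$x

  frames <- data.frame(
    frame = rep(seq_len(n_frames) - 1L, each = n),
    x_um = as.vector(Xr), y_um = as.vector(Yr),
    area_um2 = rep(area, n_frames),
    perimeter_um = rep(perim, n_frames))
  # hide identity: shuffle rows within each frame
  ord <- order(frames$frame, stats::runif(nrow(frames)))
  frames <- frames[ord, , drop = FALSE]
  rownames(frames) <- NULL

  truth <- data.frame(cell = seq_len(n), motile = motile,
                      heading_deg = ifelse(motile, heading, NA_real_),
                      speed_um_s = speed)
  list(frames = frames, truth = truth)
}
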