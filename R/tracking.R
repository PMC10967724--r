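#' Detect objects in a grayscale frame
#'
#' Thresholds the image and labels 8-connected foreground components. Each
#' component becomes one object with centroid (mean of member pixel
#' centres), area (pixel count) and perimeter (Moore boundary-trace contour
#' length), all converted from pixels to micrometres with `px_per_um`.
#'
#' Raster convention: rows are y (increasing downward), columns are x. The
#' returned coordinates are in this image frame; the downward y-axis is
#' converted to the "0 degrees = upward" heading convention once, inside
#' [link_tracks()] via `y_axis = "down"`.
#'
#' @param frame_image numeric matrix of intensities.
#' @param threshold intensity cut; pixels strictly above it are foreground.
#' @param px_per_um pixels per micrometre.
#' @return data.frame with columns `x`, `y` (um, image frame), `area`
#'   (um^2), `perimeter` (um), ordered by first pixel encountered
#'   (column-major), i.e. left-to-right for laterally separated objects.
#' @export
detect_objects <- function(frame_image, threshold, px_per_um = 1) {
  stopifnot(is.matrix(frame_image), px_per_um > 0)
  stop_if_not_finite(frame_image, "frame_image")
  stopifnot(is.finite(threshold))
  fg <- which(frame_image > threshold)
  empty <- data.frame(x = numeric(0), y = numeric(0),
                      area = numeric(0), perimeter = numeric(0))
  if (length(fg) == 0) return(empty)

  nr <- nrow(frame_image)
  row <- (fg - 1L) %% nr + 1L
  col <- (fg - 1L) %/% nr + 1L

  labels <- label_components_8(fg, row, col, nr)
  ids <- unique(labels)  # in order of first (column-major) appearance

  xs <- ys <- ar <- pe <- numeric(length(ids))
  for (i in seq_along(ids)) {
    m <- labels == ids[i]
    rr <- row[m]; cc <- col[m]
    # pixel (r, c) has centre (x = c - 0.5, y = r - 0.5)
    xs[i] <- mean(cc) - 0.5
    ys[i] <- mean(rr) - 0.5
    ar[i] <- sum(m)
    pe[i] <- trace_perimeter(rr, cc)
  }
  data.frame(x = xs / px_per_um, y = ys / px_per_um,
             area = ar / px_per_um^2, perimeter = pe / px_per_um)
}

## 8-connected components over foreground pixel indices of an nr-row
## matrix, via the pixel adjacency graph. Returns a component label per
## foreground pixel, numbered by first column-major appearance.
label_components_8 <- function(fg, row, col, nr) {
  idx_of <- integer(0)
  idx_of[fg] <- seq_along(fg)  # sparse lookup: linear index -> fg position
  offs <- rbind(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
                c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(offs))) {
    r2 <- row + offs[k, 1L]; c2 <- col + offs[k, 2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L
    lin <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- !is.na(idx_of[lin]) & idx_of[lin] > 0
    hit[is.na(hit)] <- FALSE
    from <- c(from, which(ok)[hit])
    to <- c(to, idx_of[lin[hit]])
  }
  g <- igraph::make_graph(rbind(from, to), n = length(fg), directed = FALSE)
  comp <- igraph::components(g)$membership
  # renumber by first appearance so output order is deterministic
  match(comp, unique(comp))
}

## Contour length of one pixel blob by Moore-neighbour boundary tracing.
## Steps between 8-adjacent boundary pixels contribute 1 or sqrt(2).
## Single pixels and thin lines fall back to small closed contours.
trace_perimeter <- function(rr, cc) {
  n <- length(rr)
  if (n == 1) return(4)          # unit square outline
  key <- paste(rr, cc)
  inside <- new.env(hash = TRUE, size = n)
  for (k in key) assign(k, TRUE, envir = inside)
  is_in <- function(r, c) exists(paste(r, c), envir = inside)

  # start: topmost of leftmost pixels (guaranteed boundary)
  o <- order(cc, rr)
  r0 <- rr[o[1]]; c0 <- cc[o[1]]
  # Moore neighbourhood in clockwise order starting from "west"
  dr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  # Moore tracing (Jacob's stopping criterion kept simple: stop when the
  # start pixel is re-entered from the initial backtrack direction)
  path_r <- r0; path_c <- c0
  b <- 1L  # backtrack points west of start (start is leftmost, so west is bg)
  r <- r0; c <- c0
  repeat {
    found <- FALSE
    for (s in 1:8) {
      j <- ((b - 1L + s - 1L) %% 8L) + 1L
      r2 <- r + dr[j]; c2 <- c + dc[j]
      if (is_in(r2, c2)) {
        # new backtrack: the neighbour just before the hit, relative to r2
        prev <- ((j - 2L) %% 8L) + 1L
        br <- r + dr[prev]; bc <- c + dc[prev]
        # direction index of (br,bc) as seen from (r2,c2)
        ddr <- br - r2; ddc <- bc - c2
        b <- which(dr == ddr & dc == ddc)
        r <- r2; c <- c2
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated after all (shouldn't happen for n > 1)
    if (r == r0 && c == c0 && length(path_r) > 1) break
    path_r <- c(path_r, r); path_c <- c(path_c, c)
    if (length(path_r) > 4 * n + 8) break  # safety
  }
  if (length(path_r) == 1) return(4)
  stepr <- diff(c(path_r, path_r[1]))
  stepc <- diff(c(path_c, path_c[1]))
  sum(sqrt(stepr^2 + stepc^2))
}

#' Keep objects within an area range
#'
#' Size selection excludes detritus and air bubbles from tracking.
#'
#' @param objects data.frame with an `area` column (um^2).
#' @param min_area,max_area inclusive bounds, um^2.
#' @return the filtered data.frame, order preserved.
#' @export
filter_by_size <- function(objects, min_area = 0, max_area = Inf) {
  if (min_area < 0 || max_area < 0)
    stop("area bounds must be >= 0", call. = FALSE)
  if (min_area > max_area)
    stop("min_area must be <= max_area", call. = FALSE)
  objects[objects$area >= min_area & objects$area <= max_area, ,
          drop = FALSE]
}

#' Link objects across frames into fixed-window movement vectors
#'
#' Follows every object over `window` consecutive frame-to-frame
#' transitions by greedy nearest-neighbour assignment: objects in frame t
#' (in listed order) each claim the nearest unclaimed object in frame t+1
#' within `max_disp`; equidistant candidates go to the lowest index. A
#' movement vector is emitted for a start frame only if all `window` links
#' succeed; broken tracks are dropped, matching a system that pools
#' fixed-length vectors. Successive start frames slide by one, so tracks
#' overlap.
#'
#' The vector is the net displacement between frames t and t+window (not
#' the summed path). Heading is degrees clockwise from upward; `y_axis`
#' declares whether the input y coordinates point up (world/TSV data) or
#' down (raster detections) and is the only place that conversion happens.
#'
#' @param frames list of per-frame object data.frames (columns `x`, `y`,
#'   and optionally `area`, `perimeter`), in frame order.
#' @param window number of transitions per vector (default 5).
#' @param max_disp maximum per-transition displacement, um.
#' @param fps frame rate, Hz.
#' @param y_axis `"up"` (default) or `"down"`.
#' @param start_frame0 frame index of `frames[[1]]` (for bookkeeping).
#' @return data.frame of movement vectors: `start_frame`, `x0`, `y0`,
#'   `x1`, `y1`, `heading_deg`, `speed_um_s`, `mean_area`,
#'   `mean_perimeter`, `n_links`.
#' @export
link_tracks <- function(frames, window = 5L, max_disp = 10,
                        fps = 20, y_axis = c("up", "down"),
                        start_frame0 = 0L) {
  y_axis <- match.arg(y_axis)
  stopifnot(window >= 1, max_disp > 0, fps > 0)
  nf <- length(frames)
  empty <- data.frame(start_frame = integer(0), x0 = numeric(0),
                      y0 = numeric(0), x1 = numeric(0), y1 = numeric(0),
                      heading_deg = numeric(0), speed_um_s = numeric(0),
                      mean_area = numeric(0), mean_perimeter = numeric(0),
                      n_links = integer(0))
  if (nf < window + 1) {
    warning(sprintf("need at least %d frames for a %d-transition window",
                    window + 1, window))
    return(empty)
  }

  # one greedy link map per transition: next_of[[t]][i] = index in frame
  # t+1 linked to object i of frame t, or NA
  next_of <- vector("list", nf - 1L)
  for (t in seq_len(nf - 1L)) {
    a <- frames[[t]]; b <- frames[[t + 1L]]
    na_ <- nrow(a); nb <- nrow(b)
    link <- rep(NA_integer_, na_)
    if (na_ > 0 && nb > 0) {
      claimed <- rep(FALSE, nb)
      for (i in seq_len(na_)) {
        d2 <- (b$x - a$x[i])^2 + (b$y - a$y[i])^2
        d2[claimed] <- Inf
        j <- which.min(d2)  # ties -> lowest index
        if (is.finite(d2[j]) && d2[j] <= max_disp^2) {
          link[i] <- j
          claimed[j] <- TRUE
        }
      }
    }
    next_of[[t]] <- link
  }

  dt <- window / fps
  out <- vector("list", nf - window)
  for (t in seq_len(nf - window)) {
    a <- frames[[t]]
    if (nrow(a) == 0) next
    idx <- seq_len(nrow(a))
    chain <- matrix(NA_integer_, nrow(a), window + 1L)
    chain[, 1L] <- idx
    cur <- idx
    alive <- rep(TRUE, nrow(a))
    for (s in seq_len(window)) {
      nxt <- rep(NA_integer_, nrow(a))
      nxt[alive] <- next_of[[t + s - 1L]][cur[alive]]
      alive <- alive & !is.na(nxt)
      cur <- nxt
      chain[, s + 1L] <- nxt
    }
    if (!any(alive)) next
    ai <- which(alive)
    x0 <- a$x[ai]; y0 <- a$y[ai]
    bN <- frames[[t + window]]
    x1 <- bN$x[chain[ai, window + 1L]]
    y1 <- bN$y[chain[ai, window + 1L]]
    dx <- x1 - x0
    dy <- if (y_axis == "down") -(y1 - y0) else y1 - y0
    heading <- wrap360(rad2deg(atan2(dx, dy)))
    speed <- sqrt(dx^2 + dy^2) / dt
    has_shape <- !is.null(a$area) && !is.null(a$perimeter)
    marea <- mper <- rep(NA_real_, length(ai))
    if (has_shape) {
      for (k in seq_along(ai)) {
        ar <- pr <- numeric(window + 1L)
        for (s in seq_len(window + 1L)) {
          fr <- frames[[t + s - 1L]]
          ar[s] <- fr$area[chain[ai[k], s]]
          pr[s] <- fr$perimeter[chain[ai[k], s]]
        }
        marea[k] <- mean(ar); mper[k] <- mean(pr)
      }
    }
    out[[t]] <- data.frame(
      start_frame = start_frame0 + t - 1L, x0 = x0, y0 = y0,
      x1 = x1, y1 = y1, heading_deg = heading, speed_um_s = speed,
      mean_area = marea, mean_perimeter = mper, n_links = window)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) empty else res
}

#' Split a long-format frame table into a per-frame list
#'
#' @param frames_df data.frame with columns `frame`, `x_um`, `y_um` and
#'   optionally `area_um2`, `perimeter_um` (the simulator/TSV schema).
#' @return list of per-frame data.frames with columns `x`, `y`, `area`,
#'   `perimeter`, ordered by frame index (gaps filled with empty frames).
#' @export
split_frames <- function(frames_df) {
  stopifnot(all(c("frame", "x_um", "y_um") %in% names(frames_df)))
  f0 <- min(frames_df$frame)
  fmax <- max(frames_df$frame)
  idx <- split(seq_len(nrow(frames_df)),
               factor(frames_df$frame, levels = f0:fmax))
  lapply(idx, function(i) {
    data.frame(x = frames_df$x_um[i], y = frames_df$y_um[i],
               area = if ("area_um2" %in% names(frames_df))
                 frames_df$area_um2[i] else rep(NA_real_, length(i)),
               perimeter = if ("perimeter_um" %in% names(frames_df))
                 frames_df$perimeter_um[i] else rep(NA_real_, length(i)))
  })
}
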