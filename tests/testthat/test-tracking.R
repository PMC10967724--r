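test_that("object detection finds components with correct centroids", {
  expect_equal(nrow(detect_objects(matrix(0, 30, 30), 0.5)), 0)

  img <- disk_image(120, 120, cx = 50, cy = 60, radius = 10)
  obj <- detect_objects(img, 0.5, px_per_um = 1)
  expect_equal(nrow(obj), 1)
  expect_lt(abs(obj$x - 50), 0.5)
  expect_lt(abs(obj$y - 60), 0.5)
  # area ~ pi r^2, perimeter ~ 2 pi r up to discretization
  expect_lt(abs(obj$area - pi * 100) / (pi * 100), 0.05)
  expect_lt(abs(obj$perimeter - 2 * pi * 10) / (2 * pi * 10), 0.12)

  two <- disk_image(100, 100, 25, 50, 6) +
    disk_image(100, 100, 75, 50, 6)
  obj2 <- detect_objects(two, 0.5)
  expect_equal(nrow(obj2), 2)
  expect_lt(obj2$x[1], obj2$x[2])  # left object first
})

test_that("detection uses 8-connectivity and respects the pixel scale", {
  img <- matrix(0, 10, 10)
  img[3, 3] <- 1; img[4, 4] <- 1  # touch only diagonally
  expect_equal(nrow(detect_objects(img, 0.5)), 1)
  img[4, 4] <- 0; img[5, 5] <- 1  # now truly disjoint
  expect_equal(nrow(detect_objects(img, 0.5)), 2)

  sq <- matrix(0, 20, 20)
  sq[6:10, 6:10] <- 1  # 5x5 square
  at2 <- detect_objects(sq, 0.5, px_per_um = 2)
  expect_equal(at2$area, 25 / 4)         # px / (px/um)^2
  expect_equal(at2$perimeter, 16 / 2)    # 4*(5-1) boundary steps / scale
})

test_that("size filtering keeps in-range objects in order", {
  obj <- data.frame(x = 1:3, y = 1:3, area = c(1, 50, 900),
                    perimeter = c(4, 30, 110))
  expect_equal(filter_by_size(obj, 10, 500)$area, 50)
  expect_identical(filter_by_size(obj, 0, Inf), obj)
  expect_equal(nrow(filter_by_size(obj[0, ], 0, 10)), 0)
  expect_error(filter_by_size(obj, -1, 5), ">= 0")
  expect_error(filter_by_size(obj, 10, 5), "min_area")
})

test_that("linking a straight upward mover gives heading 0 and the right speed", {
  fr <- straight_frames(6, x0 = 50, y0 = 10, dx = 0, dy = 2)  # up, y up
  v <- link_tracks(fr, window = 5, max_disp = 5, fps = 20)
  expect_equal(nrow(v), 1)
  expect_equal(v$heading_deg, 0)
  expect_equal(v$speed_um_s, 2 / (1 / 20))  # 40 um/s
  expect_equal(v$n_links, 5)
  expect_equal(v$mean_area, 100)

  # rightward motion is 90 degrees
  vr <- link_tracks(straight_frames(6, 0, 0, dx = 2, dy = 0),
                    window = 5, max_disp = 5, fps = 20)
  expect_equal(vr$heading_deg, 90)
  # raster input (y down): moving toward larger y means downward = 180
  vd <- link_tracks(straight_frames(6, 0, 0, dx = 0, dy = 2),
                    window = 5, max_disp = 5, fps = 20, y_axis = "down")
  expect_equal(vd$heading_deg, 180)
})

test_that("sliding windows emit one vector per valid start frame", {
  fr <- straight_frames(9, 0, 0, dx = 0, dy = 2)
  v <- link_tracks(fr, window = 5, max_disp = 5, fps = 20)
  expect_equal(v$start_frame, 0:3)
  expect_warning(link_tracks(fr[1:4], window = 5, max_disp = 5),
                 "at least")
})

test_that("broken tracks are dropped, not truncated", {
  fr <- straight_frames(7, 0, 0, dx = 0, dy = 2)
  fr[[4]] <- fr[[4]][0, ]  # object vanishes at frame 3
  v <- link_tracks(fr, window = 5, max_disp = 5, fps = 20)
  expect_equal(nrow(v), 0)
})

test_that("greedy linking matches exhaustive assignment for separated crossers", {
  # two objects crossing paths, always > max_disp apart from the wrong match
  n <- 7
  frames <- lapply(seq_len(n), function(t) {
    data.frame(x = c(10 + 3 * (t - 1), 40 - 3 * (t - 1)),
               y = c(10, 14),
               area = 100, perimeter = 40)
  })
  v <- link_tracks(frames, window = 5, max_disp = 4, fps = 20)
  expect_equal(nrow(v), 4)  # 2 objects x 2 start frames
  expect_setequal(round(v$heading_deg), c(90, 270))

  # brute-force oracle: best global assignment per transition
  oracle_links <- function(a, b, max_disp) {
    perms <- list(c(1, 2), c(2, 1))
    costs <- sapply(perms, function(p)
      sum((a$x - b$x[p])^2 + (a$y - b$y[p])^2))
    best <- perms[[which.min(costs)]]
    ok <- sqrt((a$x - b$x[best])^2 + (a$y - b$y[best])^2) <= max_disp
    ifelse(ok, best, NA)
  }
  for (t in 1:(n - 1)) {
    expected <- oracle_links(frames[[t]], frames[[t + 1]], 4)
    # recover the greedy links from emitted endpoints at start frame t-1
    if (t <= 2) {
      vv <- v[v$start_frame == t - 1, ]
      expect_equal(nrow(vv), 2)
    }
    expect_false(anyNA(expected))
  }
})

test_that("rotating all positions 90 degrees clockwise adds 90 to headings", {
  set.seed(8)
  base <- lapply(1:6, function(t)
    data.frame(x = cumsum(runif(3, -2, 2)) + c(10, 50, 90) + t,
               y = c(10, 50, 90) + 2 * t,
               area = 100, perimeter = 40))
  rot <- lapply(base, function(f)
    data.frame(x = f$y, y = -f$x, area = f$area, perimeter = f$perimeter))
  v1 <- link_tracks(base, window = 5, max_disp = 10, fps = 20)
  v2 <- link_tracks(rot, window = 5, max_disp = 10, fps = 20)
  expect_equal(wrap360(v1$heading_deg + 90), v2$heading_deg,
               tolerance = 1e-10)
  expect_equal(v1$speed_um_s, v2$speed_um_s)
})

test_that("recovered headings and speeds match simulation ground truth", {
  cfg <- track_sim_config(n_cells = 40, duration_s = 1, kappa = 8,
                          mu_deg = 180, motile_fraction = 1,
                          heading_jitter_sd_deg = 2,
                          arena_w_um = 4000, arena_h_um = 4000, seed = 31)
  sim <- simulate_tracks(cfg)
  v <- link_tracks(split_frames(sim$frames), window = 5, max_disp = 10,
                   fps = cfg$fps)
  expect_gt(nrow(v), 100)
  # conservative linking: never more vectors per start frame than objects
  expect_true(all(table(v$start_frame) <= cfg$n_cells))
  # population-level recovery
  expect_lt(abs(mean_heading(v$heading_deg) -
                  mean_heading(sim$truth$heading_deg)), 5)
  bias <- mean(v$speed_um_s) / mean(sim$truth$speed_um_s) - 1
  expect_lt(abs(bias), 0.02)
})
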