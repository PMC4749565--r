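test_that("SG window is the nearest odd frame count to the span", {
  tr <- gen_trajectory(2, fps = 30, speed = 50, curvature_schedule = 0.05)
  a <- smooth_asp(tr, span_ms = 200)           # 0.2 s x 30 = 6 -> 7
  expect_identical(attr(a, "window_frames"), 7L)
  expect_identical(attr(smooth_asp(tr, span_ms = 167), "window_frames"), 5L)
  expect_error(smooth_asp(gen_trajectory(0.1, fps = 30, speed = 10,
                                         curvature_schedule = 0),
                          span_ms = 400), "at least")
})

test_that("order-2 SG reproduces quadratic paths exactly, derivatives too", {
  t <- (0:59) / 30
  x <- 3 + 2 * t + 5 * t^2
  y <- -1 + 4 * t - 2 * t^2
  tr <- trajectory(t, x, y)
  a <- smooth_asp(tr)
  expect_equal(a$x, x, tolerance = 1e-9)
  expect_equal(a$y, y, tolerance = 1e-9)        # everywhere, edges included
  expect_equal(a$dx, 2 + 10 * t, tolerance = 1e-7)
  expect_equal(a$dy, 4 - 4 * t, tolerance = 1e-7)
  expect_equal(a$d2x, rep(10, length(t)), tolerance = 1e-6)
  expect_equal(a$d2y, rep(-4, length(t)), tolerance = 1e-6)
})

test_that("SG smoothing attenuates white noise by the coefficient norm", {
  # closed-form order-2 window-7 kernel (-2,3,6,7,6,3,-2)/21: gain 1/3
  set.seed(404)
  n <- 4000
  t <- (seq_len(n) - 1) / 30
  x <- rnorm(n); y <- rnorm(n)
  a <- smooth_asp(trajectory(t, x, y))
  gain <- var(a$x[!a$boundary]) / var(x)
  expect_equal(gain, sum(c(-2, 3, 6, 7, 6, 3, -2)^2) / 21^2,
               tolerance = 0.06)
})

test_that("curvature matches closed forms on circle, line and spiral", {
  # circle r = 10 um at a moderate turn rate (2 rad/s)
  tr <- gen_trajectory(3, speed = 20, curvature_schedule = 0.1)
  a <- smooth_asp(tr)
  k <- curvature(a)[!a$boundary]
  expect_equal(mean(abs(k)), 0.1, tolerance = 0.01)

  # straight line: zero everywhere
  tr0 <- gen_trajectory(2, speed = 50, curvature_schedule = 0)
  a0 <- smooth_asp(tr0)
  expect_equal(max(abs(curvature(a0)[!a0$boundary])), 0, tolerance = 1e-10)

  # Archimedean spiral against its polar closed form
  t <- seq(0, 12, by = 1 / 30)
  sp <- spiral_path(t, a = 30, b = 2)
  tr_s <- trajectory(t, sp$x, sp$y)
  a_s <- smooth_asp(tr_s)
  k_s <- curvature(a_s)
  interior <- which(!a_s$boundary)
  interior <- interior[interior > 10 & interior < length(t) - 10]
  expect_equal(k_s[interior],
               spiral_kappa_oracle(sp$phi[interior], 30, 2),
               tolerance = 0.02)
})

test_that("curvature is rigid-motion invariant and flips under reflection", {
  tr <- gen_trajectory(2, speed = 30, curvature_schedule = 0.08,
                       heading_noise_sd = 0.2, seed = 21)
  k0 <- curvature(smooth_asp(tr))
  set.seed(5)
  for (rep in 1:4) {
    th <- runif(1, 0, 2 * pi); dx <- runif(1, -50, 50); dy <- runif(1, -50, 50)
    xr <- cos(th) * tr$x - sin(th) * tr$y + dx
    yr <- sin(th) * tr$x + cos(th) * tr$y + dy
    kr <- curvature(smooth_asp(trajectory(tr$t, xr, yr)))
    expect_equal(kr, k0, tolerance = 1e-8)
  }
  km <- curvature(smooth_asp(trajectory(tr$t, tr$x, -tr$y)))
  expect_equal(km, -k0, tolerance = 1e-8)
})

test_that("slow samples are masked in curvature, not zeroed", {
  t <- (0:89) / 30
  tr <- trajectory(t, x = rep(5, 90) + 1e-4 * t, y = rep(5, 90))
  a <- smooth_asp(tr)
  expect_true(all(is.na(curvature(a))))
})

test_that("VAP recovers the programmed speed", {
  tr <- gen_trajectory(3, speed = 100, curvature_schedule = 0.02)
  expect_equal(vap(smooth_asp(tr)), 100, tolerance = 0.01)

  # stationary point: zero VAP
  t <- (0:59) / 30
  still <- trajectory(t, rep(1, 60) + 1e-9 * t, rep(2, 60))
  expect_equal(vap(smooth_asp(still)), 0, tolerance = 1e-6)

  # noisy track at 80 um/s recovered within 5%
  trn <- gen_trajectory(4, speed = 80, curvature_schedule = 0.02,
                        position_noise_sd = 0.3, seed = 77)
  expect_equal(vap(smooth_asp(trn)), 80, tolerance = 0.05)

  expect_error(vap(smooth_asp(tr), window = c(100, 101)), "empty")
})

test_that("flash response reproduces programmed curvature steps", {
  # one flash: kappa 0.02 -> 0.2, ratio ~ 10
  sch <- data.frame(t_start = c(0, 3), kappa = c(0.02, 0.2))
  tr <- gen_trajectory(6, speed = 25, curvature_schedule = sch)
  fr <- flash_response(tr, flash_times = 3)
  expect_equal(fr$post_curvature / fr$pre_curvature, 10, tolerance = 0.1)

  # no change: pre and post agree within noise
  tr0 <- gen_trajectory(6, speed = 25, curvature_schedule = 0.05,
                        heading_noise_sd = 0.05, seed = 9)
  fr0 <- flash_response(tr0, flash_times = 3)
  expect_equal(fr0$post_curvature, fr0$pre_curvature, tolerance = 0.06)

  # two consecutive steps: monotone pre < post1 < post2
  sch2 <- data.frame(t_start = c(0, 2, 4), kappa = c(0.02, 0.08, 0.2))
  tr2 <- gen_trajectory(6, speed = 25, curvature_schedule = sch2)
  fr2 <- flash_response(tr2, flash_times = c(2, 4))
  expect_lt(fr2$pre_curvature[1], fr2$post_curvature[1])
  expect_lt(fr2$post_curvature[1], fr2$post_curvature[2])

  expect_error(flash_response(tr, flash_times = 99), "support")
  expect_warning(flash_response(tr, flash_times = 0.5, pre_window = 1),
                 "truncated")
})

test_that("spot detection finds the right spots at sub-pixel accuracy", {
  # blank frame -> nothing
  expect_identical(nrow(detect_spots(matrix(rnorm(400, 10), 20, 20))), 0L)
  # constant frame -> warning and nothing
  expect_warning(d0 <- detect_spots(matrix(5, 20, 20)), "constant")
  expect_identical(nrow(d0), 0L)

  # one rendered spot at SNR 20: centroid within 0.2 px
  tr <- trajectory((0:4) / 30, rep(21.4, 5), rep(18.8, 5))
  st <- render_video(tr, image_size = 48, pixel_size = 1, psf_sigma = 2,
                     snr = 20, seed = 14)
  d <- detect_spots(st[, , 1], pixel_size = 1)
  expect_identical(nrow(d), 1L)
  expect_equal(d$x, 21.4, tolerance = 0.2)
  expect_equal(d$y, 18.8, tolerance = 0.2)

  # two spots 20 px apart: exactly 2, matching the local-maxima oracle
  g <- function(cx, cy) {
    xs <- outer(rep(1, 64), 1:64) - 0.5
    ys <- outer(1:64, rep(1, 64)) - 0.5
    exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * 4))
  }
  frame2 <- 10 + 80 * g(20, 30) + 80 * g(40, 30) +
    matrix(rnorm(64 * 64, 0, 1), 64, 64)
  d2 <- detect_spots(frame2, threshold_sd = 8)
  expect_identical(nrow(d2), 2L)
  expect_identical(local_maxima_oracle(frame2, 10 + 8 * mad(frame2)), 2L)
})

test_that("greedy linking builds, splits and separates tracks correctly", {
  # single moving spot -> one track over all frames
  dets <- lapply(0:19, function(k) data.frame(x = 2 + k, y = 5))
  trs <- link_tracks(dets, fps = 30, max_disp = 2)
  expect_length(trs, 1L)
  expect_identical(nrow(trs[[1]]), 20L)

  # two parallel non-crossing spots -> two tracks, no identity switches
  dets2 <- lapply(0:19, function(k)
    data.frame(x = c(2 + k, 2 + k), y = c(5, 25)))
  trs2 <- link_tracks(dets2, fps = 30, max_disp = 2)
  expect_length(trs2, 2L)
  ys <- sort(vapply(trs2, function(tr) mean(tr$y), 0))
  expect_equal(ys, c(5, 25))
  expect_true(all(vapply(trs2, function(tr) var(tr$y) == 0, TRUE)))

  # displacement beyond the gate splits the track in two
  dets3 <- lapply(0:19, function(k)
    data.frame(x = 2 + k + if (k >= 10) 50 else 0, y = 5))
  trs3 <- link_tracks(dets3, fps = 30, max_disp = 2)
  expect_length(trs3, 2L)
  expect_identical(vapply(trs3, nrow, 0L), c(10L, 10L))
})

test_that("video -> detect -> link -> smooth -> curvature closes the loop", {
  for (par in list(c(kappa = 0.1, speed = 20, seed = 1),
                   c(kappa = 0.3, speed = 10, seed = 2))) {
    tr <- gen_trajectory(4, speed = par[["speed"]],
                         curvature_schedule = par[["kappa"]],
                         seed = par[["seed"]], x0 = 48, y0 = 48)
    st <- render_video(tr, image_size = 96, pixel_size = 1, psf_sigma = 2,
                       snr = 10, seed = par[["seed"]] + 100)
    res <- track_video(st, max_disp = 5)
    expect_length(res$tracks, 1L)
    a <- res$asps[[1]]
    k_hat <- abs(mean(curvature(a)[!a$boundary], na.rm = TRUE))
    expect_equal(k_hat, par[["kappa"]], tolerance = 0.1)
  }
})
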