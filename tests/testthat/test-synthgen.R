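test_that("noise-free trajectories are exact arcs and lines", {
  # circle: speed 100 um/s, kappa 0.1 -> radius 10 um
  tr <- gen_trajectory(2, speed = 100, curvature_schedule = 0.1)
  ora <- arc_oracle(tr$t, 100, 0.1)
  expect_equal(tr$x, ora$x, tolerance = 1e-10)
  expect_equal(tr$y, ora$y, tolerance = 1e-10)
  cx <- tr$x[1] - sin(0) / 0.1   # circle centre from start/heading
  cy <- tr$y[1] + cos(0) / 0.1
  expect_equal(sqrt((tr$x - cx)^2 + (tr$y - cy)^2), rep(10, nrow(tr)),
               tolerance = 1e-10)

  # kappa = 0: straight line, all turning angles zero
  tr0 <- gen_trajectory(1, speed = 50, curvature_schedule = 0)
  dx <- diff(tr0$x); dy <- diff(tr0$y)
  turn <- diff(atan2(dy, dx))
  expect_equal(turn, rep(0, length(turn)), tolerance = 1e-12)
  expect_equal(tr0$y, rep(0, nrow(tr0)), tolerance = 1e-12)
})

test_that("a scheduled curvature step produces two concatenated exact arcs", {
  sch <- data.frame(t_start = c(0, 5), kappa = c(0.02, 0.2))
  tr <- gen_trajectory(10, fps = 30, speed = 40, curvature_schedule = sch)
  seg1 <- tr$t <= 5 + 1e-9
  o1 <- arc_oracle(tr$t[seg1], 40, 0.02)
  expect_equal(tr$x[seg1], o1$x, tolerance = 1e-9)
  expect_equal(tr$y[seg1], o1$y, tolerance = 1e-9)
  # second arc continues from the junction state
  k1 <- max(which(seg1))
  o2 <- arc_oracle(tr$t[!seg1] - tr$t[k1], 40, 0.2,
                   x0 = tr$x[k1], y0 = tr$y[k1],
                   heading0 = tail(o1$heading, 1))
  expect_equal(tr$x[!seg1], o2$x, tolerance = 1e-9)
  expect_equal(tr$y[!seg1], o2$y, tolerance = 1e-9)
})

test_that("turning angle per arc-length step recovers kappa to 1e-6", {
  for (kap in c(0.02, 0.1, 0.3)) {
    tr <- gen_trajectory(2, fps = 30, speed = 60, curvature_schedule = kap)
    dx <- diff(tr$x); dy <- diff(tr$y)
    turn <- diff(atan2(dy, dx))
    turn <- atan2(sin(turn), cos(turn))       # wrap
    arc_step <- 60 / 30                       # speed * dt
    expect_equal(turn / arc_step, rep(kap, length(turn)),
                 tolerance = 1e-6)
  }
})

test_that("generators are bit-identical under a fixed seed", {
  a <- gen_trajectory(1, speed = 80, curvature_schedule = 0.05,
                      heading_noise_sd = 0.3, position_noise_sd = 0.4,
                      seed = 42)
  b <- gen_trajectory(1, speed = 80, curvature_schedule = 0.05,
                      heading_noise_sd = 0.3, position_noise_sd = 0.4,
                      seed = 42)
  expect_identical(a$x, b$x)
  expect_identical(a$y, b$y)

  m <- channel_model(noise_sd = 3)
  p <- step_protocol(step_duration_ms = 40)
  expect_identical(gen_sweeps(m, p, seed = 7)$traces,
                   gen_sweeps(m, p, seed = 7)$traces)

  expect_identical(
    gen_dose_response(4.5, 1, c(1, 3, 10), seed = 3)$response,
    gen_dose_response(4.5, 1, c(1, 3, 10), seed = 3)$response)

  expect_identical(gen_stopped_flow(noise_sd = 2, seed = 5)$ch1,
                   gen_stopped_flow(noise_sd = 2, seed = 5)$ch1)

  # and the seed never leaks into the caller's RNG stream
  set.seed(99); x1 <- runif(3)
  set.seed(99); invisible(gen_trajectory(1, speed = 10,
                                         curvature_schedule = 0, seed = 1))
  x2 <- runif(3)
  expect_identical(x1, x2)
})

test_that("generator rejects invalid inputs", {
  expect_error(gen_trajectory(-1, speed = 10, curvature_schedule = 0),
               "duration")
  expect_error(gen_trajectory(1, speed = 10, curvature_schedule = NaN),
               "finite")
  expect_error(gen_trajectory(1, speed = 10,
                              curvature_schedule = data.frame(
                                t_start = c(0, 2), kappa = c(0, 0.1))),
               "within")
  expect_error(gen_dose_response(4.5, 1, numeric(0)), "empty")
  expect_error(gen_stopped_flow(dead_time = -0.1), "dead_time")
})

test_that("simulated sweeps cross zero at the Nernst potential", {
  m <- channel_model(g_max = 1, ion_concs = list(K = c("in" = 130, out = 5.4)),
                     temperature = 293.15)
  sw <- gen_sweeps(m, step_protocol())
  iv <- extract_iv(sw)
  vr <- estimate_vrev(iv)
  nernst <- 58.17 * log10(5.4 / 130)          # (RT/F) ln10 = 58.17 mV, 293 K
  expect_equal(vr$v_rev, nernst, tolerance = 0.01)
  expect_equal(vr$v_rev, sw$v_rev_true, tolerance = 0.01)

  # symmetric concentrations reverse at exactly 0 mV
  m0 <- channel_model(ion_concs = list(K = c("in" = 100, out = 100)))
  expect_equal(estimate_vrev(extract_iv(gen_sweeps(m0, step_protocol())))$v_rev,
               0, tolerance = 1e-9)
})

test_that("a proton gate at its half-activation pH halves every current", {
  p <- step_protocol()
  half <- gen_sweeps(channel_model(ph_gate = c(pk = 7.08, h = 1),
                                   ph_i = 7.08), p)
  full <- gen_sweeps(channel_model(ph_gate = c(pk = 7.08, h = 1),
                                   ph_i = 12), p)
  i_h <- extract_iv(half)$i
  i_f <- extract_iv(full)$i
  big <- abs(i_f) > 1
  # pHi 12 leaves the gate at 1 - 8e-6, hence the 1e-4 tolerance
  expect_equal(i_h[big] / i_f[big], rep(0.5, sum(big)), tolerance = 1e-4)
})

test_that("ghk mode requires both-side concentrations for permeant ions", {
  expect_error(channel_model(reversal_mode = "ghk",
                             ion_concs = list(K = c("in" = 130, out = 5.4)),
                             permeabilities = c(K = 1, Na = 0.1)),
               "both-side")
})

test_that("dose-response generator honours the Hill half-point and limits", {
  expect_equal(hill_activation(4.5, 4.5, 2), 0.5)
  expect_equal(hill_block(4.5, 4.5, 2), 0.5)
  expect_equal(hill_block(0, 4.5, 1), 1)       # no block without blocker
  expect_equal(hill_activation(0, 4.5, 1), 0)
  d <- gen_dose_response(2, 1.5, c(0, 2, 20), n_replicates = 2,
                         noise_cv = 0, seed = 1)
  expect_equal(d$response[d$dose == 2], c(0.5, 0.5))
})

test_that("dose-response replicate means obey the law of large numbers", {
  doses <- c(0.5, 1.5, 4.5)
  n <- 1e4
  d <- gen_dose_response(1.5, 1, doses, n_replicates = n, noise_cv = 0.1,
                         mode = "activation", seed = 808)
  truth <- hill_activation(doses, 1.5, 1)
  mu <- tapply(d$response, d$dose, mean)[as.character(doses)]
  se <- truth * 0.1 / sqrt(n)
  expect_true(all(abs(mu - truth) < 3 * se))
})

test_that("stopped-flow generator: baseline, plateau and dual channels", {
  tr <- gen_stopped_flow(baseline = 120, amplitude = 60, tau = 0.05,
                         dead_time = 0.02, duration = 1)
  pre <- tr$ch1[tr$t < 0.02]
  expect_equal(mean(pre), 120)
  expect_equal(tail(tr$ch1, 1), 180, tolerance = 1e-3)

  # zero amplitude: dF/F identically zero after normalization
  flat <- gen_stopped_flow(baseline = 100, amplitude = 0, dead_time = 0.02)
  expect_equal(normalize_trace(flat)$ch1, rep(0, nrow(flat)))

  # BCECF-style alkalization: ratio trace rises monotonically
  dual <- gen_stopped_flow(baseline = 100, amplitude = 40, tau = 0.1,
                           dead_time = 0.02, dual_channel = TRUE)
  rat <- compute_ratio(dual)
  post <- rat$ch1[rat$t >= 0.02]
  expect_true(all(diff(post) >= -1e-12))
  expect_gt(tail(post, 1), post[1])
})

test_that("rendered spots sit at the ground-truth positions", {
  # static point, no noise: every frame centroid within 0.01 px
  tr <- trajectory(t = (0:9) / 30, x = rep(20.3, 10), y = rep(24.7, 10))
  st <- render_video(tr, image_size = 48, pixel_size = 1, psf_sigma = 2)
  for (k in c(1, 5, 10)) {
    w <- st[, , k] - 10                        # remove flat background
    cx <- sum((col(w) - 0.5) * w) / sum(w)
    cy <- sum((row(w) - 0.5) * w) / sum(w)
    expect_equal(cx, 20.3, tolerance = 0.01)
    expect_equal(cy, 24.7, tolerance = 0.01)
  }
  # out-of-frame trajectories are rejected with the offending frames
  bad <- trajectory(t = (0:9) / 30, x = seq(40, 60, length.out = 10),
                    y = rep(24, 10))
  expect_error(render_video(bad, image_size = 48), "frame")
})
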