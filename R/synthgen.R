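# Synthetic-data generators: every downstream stage (tracking, kinematics,
# IV analysis, Hill fitting, photometry) can be validated against the known
# ground truth these produce. Seeds are explicit arguments and never touch
# the caller's RNG state.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Simulate a sperm swimming trajectory with a programmed curvature schedule
#'
#' The path model is a constant-speed planar swimmer whose heading angle
#' integrates `d(theta)/dt = speed * kappa(t)` plus optional white heading
#' noise; this is the simplest model producing the arcs and inward spirals
#' seen in flash-response experiments. Between samples the position is
#' advanced along an exact circular arc, so with zero noise each schedule
#' segment is an exact arc of radius `1/kappa`.
#'
#' @param duration recording length in seconds.
#' @param fps frame rate in frames per second (dark-field movies are
#'   typically recorded at 30 Hz).
#' @param speed swimming speed along the path, um/s.
#' @param curvature_schedule data frame with columns `t_start` (s, strictly
#'   increasing within `[0, duration)`) and `kappa` (signed curvature,
#'   1/um) — the curvature in force from each `t_start` onward. A single
#'   number is shorthand for a constant curvature.
#' @param heading_noise_sd white-noise intensity on the heading, rad/sqrt(s).
#' @param position_noise_sd additive Gaussian localisation noise, um.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @param x0,y0,heading0 initial position (um) and heading (rad).
#' @return A [trajectory()] with attribute `ground_truth` holding the
#'   generator parameters.
#' @examples
#' # circle of radius 10 um
#' tr <- gen_trajectory(2, speed = 100, curvature_schedule = 0.1)
#' @export
gen_trajectory <- function(duration, fps = 30, speed,
                           curvature_schedule,
                           heading_noise_sd = 0, position_noise_sd = 0,
                           seed = NULL, x0 = 0, y0 = 0, heading0 = 0) {
  if (!is.finite(duration) || duration <= 0) stop_bad("duration must be > 0")
  if (!is.finite(fps) || fps <= 0) stop_bad("fps must be > 0")
  if (!is.finite(speed) || speed < 0) stop_bad("speed must be >= 0 and finite")
  if (is.numeric(curvature_schedule) && is.null(dim(curvature_schedule)))
    curvature_schedule <- data.frame(t_start = 0, kappa = curvature_schedule[1])
  sch <- as.data.frame(curvature_schedule)
  if (!all(c("t_start", "kappa") %in% names(sch)))
    stop_bad("curvature_schedule needs columns t_start, kappa")
  check_finite(sch$kappa, "kappa")
  if (any(diff(sch$t_start) <= 0) || sch$t_start[1] < 0 ||
      sch$t_start[nrow(sch)] >= duration)
    stop_bad("schedule t_start must be strictly increasing within [0, duration)")
  dt <- 1 / fps
  n <- floor(duration * fps) + 1L
  t <- (seq_len(n) - 1L) * dt
  kappa_of <- function(tt) sch$kappa[findInterval(tt, sch$t_start,
                                                 rightmost.closed = FALSE)]
  kap <- kappa_of(pmax(t, sch$t_start[1]))
  with_seed(seed, {
    x <- y <- numeric(n)
    x[1] <- x0; y[1] <- y0
    th <- heading0
    hn <- if (heading_noise_sd > 0)
      rnorm(n - 1L, 0, heading_noise_sd * sqrt(dt)) else numeric(n - 1L)
    for (k in seq_len(n - 1L)) {
      dth <- speed * kap[k] * dt + hn[k]
      if (abs(dth) < 1e-12) {          # straight segment
        x[k + 1L] <- x[k] + speed * dt * cos(th)
        y[k + 1L] <- y[k] + speed * dt * sin(th)
      } else {                         # exact arc with turn dth
        r_eff <- speed * dt / dth      # signed radius
        x[k + 1L] <- x[k] + r_eff * (sin(th + dth) - sin(th))
        y[k + 1L] <- y[k] - r_eff * (cos(th + dth) - cos(th))
      }
      th <- th + dth
    }
    if (position_noise_sd > 0) {
      x <- x + rnorm(n, 0, position_noise_sd)
      y <- y + rnorm(n, 0, position_noise_sd)
    }
    out <- trajectory(t, x, y, fps = fps, id = "sim")
    attr(out, "ground_truth") <- list(
      duration = duration, fps = fps, speed = speed, schedule = sch,
      heading_noise_sd = heading_noise_sd,
      position_noise_sd = position_noise_sd, seed = seed)
    out
  })
}

#' Render a trajectory as a synthetic dark-field movie
#'
#' One Gaussian spot per time point on a constant background, with Poisson
#' shot noise plus additive Gaussian read noise — the standard camera model
#' for EMCCD-like dark-field recordings. `snr = Inf` disables all noise.
#'
#' @param traj a [trajectory()] (positions in um).
#' @param image_size frame size in pixels, one number (square) or
#'   `c(nx, ny)`.
#' @param pixel_size um per pixel.
#' @param psf_sigma spot standard deviation in pixels.
#' @param snr peak signal amplitude over the background noise standard
#'   deviation; `Inf` for a noise-free render.
#' @param seed integer seed for the noise.
#' @param background mean background level, counts.
#' @param read_noise_sd Gaussian read noise, counts.
#' @return A `frame_stack`: numeric array `[ny, nx, nframes]` with
#'   attributes `fps`, `pixel_size`.
#' @export
render_video <- function(traj, image_size = 64, pixel_size = 1,
                         psf_sigma = 2, snr = Inf, seed = NULL,
                         background = 10, read_noise_sd = 1) {
  stopifnot(inherits(traj, "trajectory"))
  sz <- rep(as.integer(image_size), length.out = 2L)
  nx <- sz[1]; ny <- sz[2]
  px <- traj$x / pixel_size
  py <- traj$y / pixel_size
  margin <- 3 * psf_sigma
  bad <- which(px < margin | px > nx - margin | py < margin | py > ny - margin)
  if (length(bad))
    stop_bad("trajectory leaves the field of view in frame(s): ",
             paste(head(bad, 10L), collapse = ", "),
             if (length(bad) > 10L) " ..." else "")
  noise_free <- !is.finite(snr)
  amp <- if (noise_free) 100 else snr * sqrt(background + read_noise_sd^2)
  n <- nrow(traj)
  cx <- (seq_len(nx) - 0.5)  # pixel-centre coordinates, px units
  cy <- (seq_len(ny) - 0.5)
  stack <- array(0, dim = c(ny, nx, n))
  with_seed(seed, {
    for (k in seq_len(n)) {
      gx <- exp(-(cx - px[k])^2 / (2 * psf_sigma^2))
      gy <- exp(-(cy - py[k])^2 / (2 * psf_sigma^2))
      frame <- background + amp * outer(gy, gx)
      if (!noise_free) {
        frame <- rpois(length(frame), frame) +
          rnorm(length(frame), 0, read_noise_sd)
        dim(frame) <- c(ny, nx)
      }
      stack[, , k] <- frame
    }
  })
  structure(stack, fps = fps(traj), pixel_size = pixel_size,
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<frame_stack> %d frames of %d x %d px, %.4g fps, %.4g µm/px\n",
              d[3], d[2], d[1], attr(x, "fps"), attr(x, "pixel_size")))
  invisible(x)
}

#' Channel model for simulated voltage-clamp sweeps
#'
#' Parameters of a pH-gated K+ conductance with optional voltage-dependent
#' intracellular Na+ block (Woodhull single-site) and an ohmic leak.
#'
#' @param g_max maximal conductance, nS.
#' @param reversal_mode `"nernst"` (K+ only) or `"ghk"` (multi-ion).
#' @param ion_concs named list; each element is `c(in = ..., out = ...)`
#'   in mM, e.g. `list(K = c(in = 130, out = 5.4))`.
#' @param permeabilities named numeric vector of relative permeabilities
#'   (required for `"ghk"`, e.g. `c(K = 1, Na = 0.05)`).
#' @param temperature kelvin.
#' @param ph_gate `c(pk = ..., h = ...)`: half-activation pH and slope of
#'   the proton gate, or `NULL` for a pH-insensitive channel.
#' @param ph_i intracellular pH seen by the gate.
#' @param na_block `c(kd0 = ..., delta = ...)`: zero-voltage dissociation
#'   constant (mM) and fractional electrical distance of the Na+ blocking
#'   site, or `NULL` for no block.
#' @param leak_g,leak_rev leak conductance (nS) and reversal (mV).
#' @param noise_sd additive current noise per sample, pA.
#' @return A `channel_model` list.
#' @export
channel_model <- function(g_max = 1, reversal_mode = c("nernst", "ghk"),
                          ion_concs = list(K = c("in" = 130, out = 5.4)),
                          permeabilities = c(K = 1),
                          temperature = 293.15,
                          ph_gate = NULL, ph_i = 7.4,
                          na_block = NULL,
                          leak_g = 0, leak_rev = 0, noise_sd = 0) {
  reversal_mode <- match.arg(reversal_mode)
  if (g_max < 0) stop_bad("g_max must be >= 0")
  for (ion in names(ion_concs)) {
    cc <- ion_concs[[ion]]
    if (any(cc <= 0)) stop_bad("concentrations must be > 0 (ion ", ion, ")")
  }
  if (reversal_mode == "ghk") {
    for (ion in names(permeabilities)) {
      cc <- ion_concs[[ion]]
      if (is.null(cc) || !all(c("in", "out") %in% names(cc)))
        stop_bad("ghk mode needs both-side concentrations for permeant ion '",
                 ion, "'")
    }
  }
  if (!is.null(na_block)) {
    if (na_block[["delta"]] < 0 || na_block[["delta"]] > 1)
      stop_bad("na_block delta must lie in [0, 1]")
    if (na_block[["kd0"]] <= 0) stop_bad("na_block kd0 must be > 0")
  }
  structure(list(g_max = g_max, reversal_mode = reversal_mode,
                 ion_concs = ion_concs, permeabilities = permeabilities,
                 temperature = temperature, ph_gate = ph_gate, ph_i = ph_i,
                 na_block = na_block, leak_g = leak_g, leak_rev = leak_rev,
                 noise_sd = noise_sd),
            class = "channel_model")
}

#' Voltage-step protocol
#'
#' @param holding_mV holding potential, mV.
#' @param step_levels command voltages, mV (at least two).
#' @param step_duration_ms duration of each step, ms.
#' @param sample_rate_khz sampling rate, kHz.
#' @param pre_ms holding segment recorded before the step, ms.
#' @return A `step_protocol` list.
#' @export
step_protocol <- function(holding_mV = -65,
                          step_levels = seq(-115, 25, by = 10),
                          step_duration_ms = 100, sample_rate_khz = 10,
                          pre_ms = 10) {
  if (length(step_levels) < 2L) stop_bad("need at least 2 step levels")
  if (step_duration_ms <= 0) stop_bad("step_duration_ms must be > 0")
  structure(list(holding_mV = holding_mV, step_levels = step_levels,
                 step_duration_ms = step_duration_ms,
                 sample_rate_khz = sample_rate_khz, pre_ms = pre_ms),
            class = "step_protocol")
}

# Proton-gate open fraction: 1 / (1 + 10^(h * (pK - pH)))
gate_open_fraction <- function(ph, pk, h = 1) 1 / (1 + 10^(h * (pk - ph)))

#' Simulate a voltage-step sweep family
#'
#' Per-step current is
#' `gate(pHi) * unblocked(V) * g_max * (V - Vrev) + leak + noise`, where the
#' K+ reversal follows the Nernst or GHK closed form. Capacitive transients
#' are omitted by default (steady-state analysis windows only); a simple
#' exponential spike can be switched on.
#'
#' @param model a [channel_model()].
#' @param protocol a [step_protocol()].
#' @param seed integer seed for the current noise.
#' @param capacitive optional `c(amp_pA = ..., tau_ms = ...)` transient
#'   added at the step onset.
#' @return A `sweep_set`: list with `protocol`, `t_ms`, `traces`
#'   (steps x samples matrix, pA), `step_onset_ms`, `solutions`,
#'   `temperature` and the generating `model`.
#' @export
gen_sweeps <- function(model, protocol, seed = NULL, capacitive = NULL) {
  stopifnot(inherits(model, "channel_model"), inherits(protocol, "step_protocol"))
  dt <- 1 / protocol$sample_rate_khz                     # ms
  n_pre <- round(protocol$pre_ms / dt)
  n_step <- round(protocol$step_duration_ms / dt)
  t_ms <- (seq_len(n_pre + n_step) - 1L) * dt
  v_rev <- channel_vrev(model)
  gate <- if (is.null(model$ph_gate)) 1 else
    gate_open_fraction(model$ph_i, model$ph_gate[["pk"]], model$ph_gate[["h"]])
  i_of_v <- function(v) {
    unblocked <- if (is.null(model$na_block)) 1 else
      na_block_fraction(v, na_in = model$ion_concs$Na[["in"]],
                        kd0 = model$na_block[["kd0"]],
                        delta = model$na_block[["delta"]],
                        temperature = model$temperature)
    gate * unblocked * model$g_max * (v - v_rev) +
      model$leak_g * (v - model$leak_rev)
  }
  nl <- length(protocol$step_levels)
  traces <- matrix(0, nrow = nl, ncol = length(t_ms))
  with_seed(seed, {
    for (s in seq_len(nl)) {
      v <- protocol$step_levels[s]
      tr <- c(rep(i_of_v(protocol$holding_mV), n_pre),
              rep(i_of_v(v), n_step))
      if (!is.null(capacitive)) {
        tt <- t_ms[-seq_len(n_pre)] - protocol$pre_ms
        spike <- capacitive[["amp_pA"]] * sign(v - protocol$holding_mV) *
          exp(-tt / capacitive[["tau_ms"]])
        tr[-seq_len(n_pre)] <- tr[-seq_len(n_pre)] + spike
      }
      if (model$noise_sd > 0) tr <- tr + rnorm(length(tr), 0, model$noise_sd)
      traces[s, ] <- tr
    }
  })
  structure(list(protocol = protocol, t_ms = t_ms, traces = traces,
                 step_onset_ms = protocol$pre_ms,
                 solutions = model$ion_concs,
                 temperature = model$temperature, model = model,
                 v_rev_true = v_rev),
            class = "sweep_set")
}

# Reversal potential of the conductive (K+) component of a channel model
channel_vrev <- function(model) {
  if (model$reversal_mode == "nernst") {
    k <- model$ion_concs$K
    predict_vrev("nernst", concentrations = list(K = k),
                 temperature = model$temperature)
  } else {
    predict_vrev("ghk", concentrations = model$ion_concs,
                 permeability_ratios = model$permeabilities,
                 temperature = model$temperature)
  }
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf(
    "<sweep_set> %d steps (%g..%g mV), %g ms at %g kHz, Vrev(K) = %.2f mV\n",
    length(x$protocol$step_levels), min(x$protocol$step_levels),
    max(x$protocol$step_levels), x$protocol$step_duration_ms,
    x$protocol$sample_rate_khz, x$v_rev_true))
  invisible(x)
}

#' Hill curves
#'
#' `hill_activation()` is `1 / (1 + (K/c)^h)` (0 at `c = 0`);
#' `hill_block()` is `1 / (1 + (c/K)^h)` (1 at `c = 0`, i.e. the fraction
#' of current remaining).
#'
#' @param conc dose(s), same units as `K`.
#' @param K half-effect concentration.
#' @param h Hill coefficient.
#' @return Fractional response in `[0, 1]`.
#' @export
hill_activation <- function(conc, K, h = 1) {
  ch <- conc^h
  ch / (ch + K^h)
}

#' @rdname hill_activation
#' @export
hill_block <- function(conc, K, h = 1) {
  K^h / (conc^h + K^h)
}

#' Simulate replicate dose-response tables
#'
#' Draws `n_replicates` noisy copies of a Hill curve with multiplicative
#' Gaussian noise of the stated coefficient of variation.
#'
#' @param K half-effect concentration, mM.
#' @param h Hill coefficient.
#' @param doses dose vector, mM (non-negative).
#' @param n_replicates replicates per dose.
#' @param noise_cv multiplicative noise CV (0.1 = 10\%).
#' @param mode `"block"` or `"activation"`.
#' @param seed integer seed.
#' @return A data frame `(dose, replicate, response)` of class
#'   `dose_response_set` with attribute `truth`.
#' @export
gen_dose_response <- function(K, h, doses, n_replicates = 5,
                              noise_cv = 0.1, mode = c("block", "activation"),
                              seed = NULL) {
  mode <- match.arg(mode)
  if (length(doses) == 0L) stop_bad("empty dose list")
  if (K <= 0 || h <= 0) stop_bad("K and h must be > 0")
  if (any(doses < 0)) stop_bad("doses must be >= 0")
  f <- if (mode == "block") hill_block(doses, K, h) else
    hill_activation(doses, K, h)
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
      data.frame(dose = doses, replicate = r,
                 response = f * (1 + rnorm(length(doses), 0, noise_cv)))
    }))
    attr(out, "truth") <- list(K = K, h = h, mode = mode, noise_cv = noise_cv)
    class(out) <- c("dose_response_set", "data.frame")
    out
  })
}

#' Simulate a stopped-flow fluorescence trace
#'
#' Mono-exponential rise after the instrument dead time; the pre-onset
#' segment sits at the baseline. With `dual_channel = TRUE` a BCECF-style
#' pair is produced: channel 1 (pH-sensitive emission) carries the rise,
#' channel 2 (reference emission) stays at its baseline, so the
#' channel-1/channel-2 ratio rises upon alkalization.
#'
#' @param baseline pre-stimulus fluorescence, a.u. (> 0).
#' @param amplitude plateau rise above baseline, a.u.
#' @param tau rise time constant, s (> 0).
#' @param dead_time instrument dead time, s (>= 0); signal onset.
#' @param noise_sd additive Gaussian noise per sample, a.u.
#' @param dual_channel generate a two-channel (ratiometric) trace.
#' @param duration,dt trace length and sample interval, s.
#' @param baseline2 channel-2 baseline (dual-channel only).
#' @param seed integer seed.
#' @return An `sf_trace`: data frame `(t, ch1[, ch2])` with attribute
#'   `mix_time` (the signal onset, s).
#' @export
gen_stopped_flow <- function(baseline = 100, amplitude = 50, tau = 0.1,
                             dead_time = 0.01, noise_sd = 0,
                             dual_channel = FALSE, duration = 1, dt = 0.001,
                             baseline2 = 100, seed = NULL) {
  if (tau <= 0) stop_bad("tau must be > 0")
  if (dead_time < 0) stop_bad("dead_time must be >= 0")
  if (baseline <= 0) stop_bad("baseline must be > 0")
  t <- seq(0, duration, by = dt)
  rise <- ifelse(t < dead_time, 0,
                 amplitude * (1 - exp(-(t - dead_time) / tau)))
  with_seed(seed, {
    ch1 <- baseline + rise
    if (noise_sd > 0) ch1 <- ch1 + rnorm(length(t), 0, noise_sd)
    d <- data.frame(t = t, ch1 = ch1)
    if (dual_channel) {
      ch2 <- rep(baseline2, length(t))
      if (noise_sd > 0) ch2 <- ch2 + rnorm(length(t), 0, noise_sd)
      d$ch2 <- ch2
    }
    sf_trace(d, mix_time = dead_time)
  })
}
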