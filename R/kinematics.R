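# CASA-style kinematics: average swimming path (ASP) by Savitzky-Golay
# smoothing, signed path curvature, averaged-path velocity (VAP), and
# flash-response statistics. Units are um, s, 1/um throughout.

# Savitzky-Golay smoothing with simultaneous derivative estimation.
# Returns the value, first and second derivative of the local polynomial
# fit (per-index units); interior points by convolution, the first/last
# half-window by evaluating the edge-window polynomial off-centre
# (scipy-style 'interp' edges), so exact polynomials of degree <= poly_order
# are reproduced everywhere including the edges.
sgolay_filter <- function(y, window, poly_order) {
  n <- length(y)
  if (window %% 2L != 1L) stop_bad("window must be odd")
  if (window < poly_order + 1L) stop_bad("window must be >= poly_order + 1")
  if (n < window) stop_bad("series shorter than window (need >= ", window, ")")
  m <- (window - 1L) %/% 2L
  A <- outer(-m:m, 0:poly_order, `^`)
  C <- solve(crossprod(A), t(A))       # (poly_order+1) x window
  val <- d1 <- d2 <- numeric(n)
  # interior: polynomial evaluated at the window centre
  for (i in (m + 1L):(n - m)) {
    w <- y[(i - m):(i + m)]
    beta <- C %*% w
    val[i] <- beta[1L]
    d1[i] <- if (poly_order >= 1L) beta[2L] else 0
    d2[i] <- if (poly_order >= 2L) 2 * beta[3L] else 0
  }
  poly_eval <- function(beta, s) {
    p <- length(beta) - 1L
    v <- sum(beta * s^(0:p))
    dv <- if (p >= 1L) sum(beta[-1L] * (1:p) * s^(0:(p - 1L))) else 0
    d2v <- if (p >= 2L) sum(beta[-(1:2)] * (2:p) * (1:(p - 1L)) *
                              s^(0:(p - 2L))) else 0
    c(v, dv, d2v)
  }
  beta_l <- C %*% y[1:window]
  beta_r <- C %*% y[(n - window + 1L):n]
  for (j in 1:m) {
    e <- poly_eval(beta_l, j - m - 1L)
    val[j] <- e[1]; d1[j] <- e[2]; d2[j] <- e[3]
    e <- poly_eval(beta_r, j)   # offset from the last full-window centre
    i <- n - m + j
    val[i] <- e[1]; d1[i] <- e[2]; d2[i] <- e[3]
  }
  list(value = val, d1 = d1, d2 = d2)
}

#' Average swimming path by Savitzky-Golay filtering
#'
#' Smooths the tracked head coordinates with a second-degree
#' Savitzky-Golay filter over a 200 ms span (the standard ASP recipe for
#' 30 Hz dark-field movies), removing the flagellar-beat wobble. First and
#' second time derivatives come from the same local polynomial fit, scaled
#' by the frame rate — a single consistent estimator rather than finite
#' differences of the smoothed positions.
#'
#' The window is `span_ms * fps / 1000` rounded to the nearest odd integer
#' (7 frames for 200 ms at 30 Hz). The half-window at each end is fitted
#' with the edge-window polynomial and flagged as boundary; summaries
#' ([vap()], [flash_response()]) exclude boundary samples.
#'
#' @param traj a [trajectory()].
#' @param span_ms filter span in milliseconds.
#' @param poly_order polynomial degree of the local fit.
#' @return An `asp` object: data frame with columns `t`, `x`, `y`
#'   (smoothed, um), `dx`, `dy` (um/s), `d2x`, `d2y` (um/s^2), `boundary`
#'   (logical), plus attributes `fps`, `window_frames`, `poly_order`.
#' @examples
#' tr <- gen_trajectory(2, speed = 100, curvature_schedule = 0.1)
#' a <- smooth_asp(tr)
#' attr(a, "window_frames")  # 7 at 30 Hz / 200 ms
#' @export
smooth_asp <- function(traj, span_ms = 200, poly_order = 2) {
  stopifnot(inherits(traj, "trajectory"))
  f <- fps(traj)
  w <- span_ms * f / 1000
  window <- 2L * as.integer(floor(w / 2)) + 1L  # nearest odd (ties round up)
  if (window < poly_order + 1L) window <- poly_order + (poly_order %% 2L) + 1L
  if (nrow(traj) < window)
    stop_bad("trajectory has ", nrow(traj), " frames; the ", span_ms,
             " ms window needs at least ", window)
  sx <- sgolay_filter(traj$x, window, poly_order)
  sy <- sgolay_filter(traj$y, window, poly_order)
  m <- (window - 1L) %/% 2L
  n <- nrow(traj)
  boundary <- rep(FALSE, n)
  boundary[c(seq_len(m), (n - m + 1L):n)] <- TRUE
  out <- data.frame(t = traj$t, x = sx$value, y = sy$value,
                    dx = sx$d1 * f, dy = sy$d1 * f,
                    d2x = sx$d2 * f^2, d2y = sy$d2 * f^2,
                    boundary = boundary)
  attr(out, "fps") <- f
  attr(out, "window_frames") <- window
  attr(out, "poly_order") <- poly_order
  class(out) <- c("asp", "data.frame")
  out
}

#' @export
print.asp <- function(x, ...) {
  cat(sprintf("<asp> %d samples, SG window %d frames (order %d) at %.4g fps\n",
              nrow(x), attr(x, "window_frames"), attr(x, "poly_order"),
              attr(x, "fps")))
  invisible(x)
}

#' Signed curvature of the average swimming path
#'
#' \deqn{\kappa = (\dot x \ddot y - \dot y \ddot x) /
#'       (\dot x^2 + \dot y^2)^{3/2}}
#' The sign encodes turn direction; a circle of radius r has |kappa| = 1/r.
#' Samples slower than `min_speed` are masked (`NA`) rather than silently
#' zeroed, since the formula degenerates at vanishing speed.
#'
#' @param asp an [smooth_asp()] result.
#' @param min_speed mask threshold, um/s.
#' @return Numeric vector of signed curvature, 1/um, one value per sample
#'   (`NA` where masked).
#' @export
curvature <- function(asp, min_speed = 1) {
  stopifnot(inherits(asp, "asp"))
  sp2 <- asp$dx^2 + asp$dy^2
  k <- (asp$dx * asp$d2y - asp$dy * asp$d2x) / sp2^1.5
  k[sqrt(sp2) < min_speed] <- NA_real_
  k
}

#' Averaged-path velocity (VAP)
#'
#' Time-average of the ASP speed `sqrt(dx^2 + dy^2)` over an analysis
#' window; boundary (half-window) samples are excluded.
#'
#' @param asp an [smooth_asp()] result.
#' @param window optional `c(t_start, t_end)` in seconds; default is the
#'   whole (interior) trace.
#' @return VAP in um/s.
#' @export
vap <- function(asp, window = NULL) {
  stopifnot(inherits(asp, "asp"))
  keep <- !asp$boundary
  if (!is.null(window)) keep <- keep & asp$t >= window[1] & asp$t <= window[2]
  if (!any(keep)) stop_bad("empty analysis window")
  mean(sqrt(asp$dx[keep]^2 + asp$dy[keep]^2))
}

# mean |kappa| and VAP over a time window (interior samples only)
kin_summary <- function(asp, t0, t1, min_speed = 1) {
  keep <- !asp$boundary & asp$t >= t0 & asp$t <= t1
  if (!any(keep)) return(list(mean_curvature = NA_real_, vap = NA_real_,
                              n = 0L, window = c(t0, t1)))
  k <- curvature(asp, min_speed = min_speed)[keep]
  list(mean_curvature = mean(abs(k), na.rm = TRUE),
       vap = mean(sqrt(asp$dx[keep]^2 + asp$dy[keep]^2)),
       n = sum(keep), window = c(t0, t1))
}

#' Kinematics before and after UV flashes
#'
#' For each flash, mean |curvature| and VAP are computed over
#' `[t_flash - pre_window, t_flash)` and `(t_flash, t_flash + post_window]`,
#' supporting consecutive flashes (the "+" and "++" conditions of
#' caged-Ca2+ experiments). Windows extending beyond the data are
#' truncated with a warning.
#'
#' @param traj a [trajectory()].
#' @param flash_times flash times, s, inside the trajectory support.
#' @param pre_window,post_window window lengths, s.
#' @param span_ms,poly_order passed to [smooth_asp()].
#' @return Data frame of class `flash_response` with one row per flash:
#'   `flash_t`, `pre_curvature`, `post_curvature`, `pre_vap`, `post_vap`,
#'   `pre_n`, `post_n`.
#' @export
flash_response <- function(traj, flash_times, pre_window = 1,
                           post_window = 1, span_ms = 200, poly_order = 2) {
  stopifnot(inherits(traj, "trajectory"))
  rng <- range(traj$t)
  if (any(flash_times < rng[1] | flash_times > rng[2]))
    stop_bad("flash times must lie inside the trajectory support")
  asp <- smooth_asp(traj, span_ms = span_ms, poly_order = poly_order)
  rows <- lapply(seq_along(flash_times), function(i) {
    tf <- flash_times[i]
    t0 <- tf - pre_window
    t1 <- tf + post_window
    if (t0 < rng[1] || t1 > rng[2]) {
      warning("flash ", i, ": window truncated to the data support",
              call. = FALSE)
      t0 <- max(t0, rng[1]); t1 <- min(t1, rng[2])
    }
    # keep windows clear of neighbouring flashes
    if (i > 1L) t0 <- max(t0, flash_times[i - 1L])
    if (i < length(flash_times)) t1 <- min(t1, flash_times[i + 1L])
    pre <- kin_summary(asp, t0, tf - .Machine$double.eps^0.5)
    post <- kin_summary(asp, tf + .Machine$double.eps^0.5, t1)
    data.frame(flash_t = tf,
               pre_curvature = pre$mean_curvature,
               post_curvature = post$mean_curvature,
               pre_vap = pre$vap, post_vap = post$vap,
               pre_n = pre$n, post_n = post$n)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("flash_response", "data.frame")
  out
}

#' Detect bright spots in a dark-field frame
#'
#' Pixels brighter than `background + threshold_sd * robust SD` (median and
#' MAD) are grouped into 8-connected components; components of at least
#' `min_area` pixels are reported as intensity-weighted centroids
#' (sub-pixel), converted to micrometres.
#'
#' @param frame 2-D numeric matrix (row = y, column = x).
#' @param pixel_size um per pixel.
#' @param threshold_sd threshold in robust SDs above background.
#' @param min_area minimum component area, px.
#' @return Data frame `(x, y)` in um (possibly 0 rows).
#' @export
detect_spots <- function(frame, pixel_size = 1, threshold_sd = 5,
                         min_area = 3) {
  if (!is.matrix(frame) || !all(is.finite(frame)))
    stop_bad("frame must be a finite 2-D matrix")
  bg <- median(frame)
  s <- mad(frame)
  if (s == 0) {
    warning("constant or saturated frame; no detections", call. = FALSE)
    return(data.frame(x = numeric(0), y = numeric(0)))
  }
  mask <- frame > bg + threshold_sd * s
  if (!any(mask)) return(data.frame(x = numeric(0), y = numeric(0)))
  lab <- label_components(mask)
  xs <- ys <- numeric(0)
  for (l in seq_len(attr(lab, "n"))) {
    idx <- which(lab == l, arr.ind = TRUE)
    if (nrow(idx) < min_area) next
    w <- frame[idx] - bg                     # background-subtracted weights
    w <- pmax(w, 0)
    # pixel (r, c) is centred at (c - 0.5, r - 0.5) in px units
    xs <- c(xs, sum((idx[, 2] - 0.5) * w) / sum(w))
    ys <- c(ys, sum((idx[, 1] - 0.5) * w) / sum(w))
  }
  data.frame(x = xs * pixel_size, y = ys * pixel_size)
}

# two-pass-free 8-connected component labelling via flood fill
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nlab <- 0L
  todo <- which(mask)
  for (start in todo) {
    if (lab[start] != 0L) next
    nlab <- nlab + 1L
    queue <- start
    lab[start] <- nlab
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (p - 1L) %% nr + 1L
      c <- (p - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
        q <- (cc - 1L) * nr + rr
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- nlab
          queue <- c(queue, q)
        }
      }
    }
  }
  attr(lab, "n") <- nlab
  lab
}

#' Link per-frame detections into trajectories
#'
#' Greedy nearest-neighbour assignment frame to frame: candidate links are
#' sorted by distance (ties broken by lowest detection index) and accepted
#' while unassigned, but only if the displacement is at most `max_disp`.
#' Unmatched detections open new tracks; unmatched tracks terminate (gaps
#' are not bridged). Tracks shorter than `min_length` frames are discarded.
#'
#' @param detections list with one `(x, y)` data frame (um) per frame.
#' @param fps frame rate, frames/s.
#' @param max_disp maximum displacement per frame, um.
#' @param min_length minimum track length in frames.
#' @return List of [trajectory()] objects.
#' @export
link_tracks <- function(detections, fps, max_disp, min_length = 5) {
  if (length(detections) < 2L) stop_bad("need detections for >= 2 frames")
  tracks <- list()    # each: list(frames, x, y, active)
  active <- integer(0)
  d1 <- detections[[1]]
  for (j in seq_len(nrow(d1))) {
    tracks[[length(tracks) + 1L]] <- list(frames = 1L, x = d1$x[j], y = d1$y[j])
    active <- c(active, length(tracks))
  }
  for (f in 2L:length(detections)) {
    det <- detections[[f]]
    nd <- nrow(det)
    if (length(active) && nd) {
      last_x <- vapply(tracks[active], function(tr) tail(tr$x, 1L), 0)
      last_y <- vapply(tracks[active], function(tr) tail(tr$y, 1L), 0)
      dist <- sqrt(outer(last_x, det$x, `-`)^2 + outer(last_y, det$y, `-`)^2)
      cand <- which(dist <= max_disp, arr.ind = TRUE)
      if (nrow(cand)) {
        ord <- order(dist[cand], cand[, 2])   # distance, then detection index
        cand <- cand[ord, , drop = FALSE]
      }
      used_tr <- logical(length(active)); used_det <- logical(nd)
      for (r in seq_len(nrow(cand))) {
        i <- cand[r, 1]; j <- cand[r, 2]
        if (used_tr[i] || used_det[j]) next
        used_tr[i] <- TRUE; used_det[j] <- TRUE
        ti <- active[i]
        tracks[[ti]]$frames <- c(tracks[[ti]]$frames, f)
        tracks[[ti]]$x <- c(tracks[[ti]]$x, det$x[j])
        tracks[[ti]]$y <- c(tracks[[ti]]$y, det$y[j])
      }
      active <- active[used_tr]               # unmatched tracks terminate
      new_idx <- which(!used_det)
    } else {
      active <- integer(0)
      new_idx <- seq_len(nd)
    }
    for (j in new_idx) {
      tracks[[length(tracks) + 1L]] <- list(frames = f, x = det$x[j],
                                            y = det$y[j])
      active <- c(active, length(tracks))
    }
  }
  keep <- Filter(function(tr) length(tr$frames) >= min_length, tracks)
  lapply(seq_along(keep), function(i) {
    tr <- keep[[i]]
    trajectory((tr$frames - 1L) / fps, tr$x, tr$y, fps = fps,
               id = sprintf("track%03d", i))
  })
}

#' Full video-to-kinematics pipeline
#'
#' Convenience wrapper: [detect_spots()] on every frame, [link_tracks()],
#' then [smooth_asp()] per track.
#'
#' @param stack a `frame_stack` from [render_video()] or [read_tiff_stack()].
#' @param threshold_sd,min_area passed to [detect_spots()].
#' @param max_disp passed to [link_tracks()], um/frame.
#' @param span_ms,poly_order passed to [smooth_asp()].
#' @return List with elements `tracks` (trajectories) and `asps`.
#' @export
track_video <- function(stack, threshold_sd = 5, min_area = 3,
                        max_disp = 10, span_ms = 200, poly_order = 2) {
  stopifnot(inherits(stack, "frame_stack"))
  px <- attr(stack, "pixel_size")
  dets <- lapply(seq_len(dim(stack)[3]), function(k)
    detect_spots(stack[, , k], pixel_size = px, threshold_sd = threshold_sd,
                 min_area = min_area))
  tracks <- link_tracks(dets, fps = attr(stack, "fps"), max_disp = max_disp)
  asps <- lapply(tracks, smooth_asp, span_ms = span_ms,
                 poly_order = poly_order)
  list(tracks = tracks, asps = asps)
}
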