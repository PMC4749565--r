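# Independent oracles used across tests; each is a brute-force or
# closed-form route that never calls the implementation it checks.

# closed-form sample positions of a constant-speed arc: heading integrates
# linearly, position follows the circle of radius 1/kappa
arc_oracle <- function(t, speed, kappa, x0 = 0, y0 = 0, heading0 = 0) {
  th <- heading0 + speed * kappa * t
  if (abs(kappa) < 1e-15) {
    list(x = x0 + speed * t * cos(heading0),
         y = y0 + speed * t * sin(heading0), heading = th)
  } else {
    list(x = x0 + (sin(th) - sin(heading0)) / kappa,
         y = y0 - (cos(th) - cos(heading0)) / kappa, heading = th)
  }
}

# brute-force local-maxima spot counter: a pixel above `thr` that is the
# maximum of its 3x3 neighbourhood, de-duplicated within `min_sep` px
local_maxima_oracle <- function(frame, thr, min_sep = 4) {
  nr <- nrow(frame); nc <- ncol(frame)
  peaks <- NULL
  for (r in 2:(nr - 1)) for (c in 2:(nc - 1)) {
    v <- frame[r, c]
    if (v <= thr) next
    if (v >= max(frame[(r - 1):(r + 1), (c - 1):(c + 1)]))
      peaks <- rbind(peaks, c(r, c, v))
  }
  if (is.null(peaks)) return(0L)
  keep <- rep(TRUE, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(peaks))) {
      if (i == j || !keep[j]) next
      if (sqrt(sum((peaks[i, 1:2] - peaks[j, 1:2])^2)) < min_sep &&
          peaks[j, 3] <= peaks[i, 3]) keep[j] <- FALSE
    }
  }
  sum(keep)
}

# exhaustive grid search of the Hill least-squares problem: for every
# (K, h) on a log grid the best floor/ceiling follow by linear regression,
# with the same floor >= 0 constraint the estimator imposes
grid_hill_oracle <- function(doses, responses, mode,
                             k_grid = 10^seq(-2, 3, length.out = 161),
                             h_grid = seq(0.25, 4, by = 0.05)) {
  best <- list(sse = Inf)
  for (K in k_grid) for (h in h_grid) {
    f <- if (mode == "block") K^h / (doses^h + K^h)
         else doses^h / (doses^h + K^h)
    fit <- lm(responses ~ f)
    flo <- coef(fit)[[1]]; cei <- coef(fit)[[2]]
    if (flo < min(0, min(responses))) {   # active constraint: refit floor = 0
      cei <- sum(responses * f) / sum(f^2)
      flo <- 0
    }
    sse <- sum((responses - flo - cei * f)^2)
    if (sse < best$sse)
      best <- list(sse = sse, K = K, h = h, floor = flo, ceiling = cei)
  }
  best
}

# curvature of the Archimedean spiral r = a + b*phi (polar closed form)
spiral_kappa_oracle <- function(phi, a, b) {
  r <- a + b * phi
  (r^2 + 2 * b^2) / (r^2 + b^2)^1.5
}

# spiral sample path at constant angular rate
spiral_path <- function(t, a, b, phi_dot = 1) {
  phi <- phi_dot * t
  r <- a + b * phi
  list(x = r * cos(phi), y = r * sin(phi), phi = phi)
}
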