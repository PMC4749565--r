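#' Trajectory container
#'
#' A trajectory is a data frame of time-stamped 2-D head positions with
#' columns `t` (s), `x` and `y` (um), uniformly sampled at `fps` frames per
#' second. Positions are in micrometres; the pixel-to-um conversion happens
#' at detection time, never later.
#'
#' @param t time stamps in seconds, strictly increasing, uniformly spaced.
#' @param x,y head positions in micrometres.
#' @param fps frame rate in frames per second. Inferred from `t` if missing.
#' @param id optional track identifier.
#' @return An object of class `trajectory` (a data frame with columns
#'   `t`, `x`, `y` and attributes `fps`, `id`).
#' @examples
#' tr <- trajectory(t = (0:29) / 30, x = cos(0:29 / 5), y = sin(0:29 / 5))
#' fps(tr)
#' @export
trajectory <- function(t, x, y, fps = NULL, id = NA_character_) {
  if (length(t) != length(x) || length(t) != length(y))
    stop_bad("t, x, y must have equal length")
  if (length(t) < 3L) stop_bad("a trajectory needs at least 3 points")
  check_finite(t, "t"); check_finite(x, "x"); check_finite(y, "y")
  dt <- diff(t)
  if (any(dt <= 0)) stop_bad("t must be strictly increasing")
  if (max(dt) - min(dt) > 1e-6)
    stop_bad("sampling must be uniform within 1e-6 s (got jitter ",
             format(max(dt) - min(dt)), " s)")
  if (is.null(fps)) fps <- 1 / mean(dt)
  if (abs(mean(dt) - 1 / fps) > 1e-6)
    stop_bad("t spacing inconsistent with fps = ", fps)
  out <- data.frame(t = t, x = x, y = y)
  attr(out, "fps") <- fps
  attr(out, "id") <- id
  class(out) <- c("trajectory", "data.frame")
  out
}

#' @rdname trajectory
#' @param traj a `trajectory`.
#' @export
fps <- function(traj) attr(traj, "fps")

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames at %.4g fps, %.3g s, id = %s\n",
              nrow(x), attr(x, "fps"), x$t[nrow(x)] - x$t[1],
              as.character(attr(x, "id"))))
  invisible(x)
}

#' @export
plot.trajectory <- function(x, ..., asp = 1, type = "l",
                            xlab = "x (µm)", ylab = "y (µm)") {
  plot(x$x, x$y, asp = asp, type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Read and write trajectory CSV files
#'
#' The on-disk form is a plain CSV with columns `t_s`, `x_um`, `y_um`.
#'
#' @param file path to a CSV file.
#' @param fps frame rate; inferred from the time stamps if missing.
#' @return `read_trajectory()` returns a [trajectory()];
#'   `write_trajectory()` returns `file` invisibly.
#' @export
read_trajectory <- function(file, fps = NULL) {
  d <- read.csv(file)
  need <- c("t_s", "x_um", "y_um")
  if (!all(need %in% names(d)))
    stop_bad("trajectory CSV needs columns: ", paste(need, collapse = ", "))
  trajectory(d$t_s, d$x_um, d$y_um, fps = fps)
}

#' @rdname read_trajectory
#' @param traj a `trajectory`.
#' @export
write_trajectory <- function(traj, file) {
  write.csv(data.frame(t_s = traj$t, x_um = traj$x, y_um = traj$y),
            file, row.names = FALSE)
  invisible(file)
}
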