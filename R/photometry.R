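# Stopped-flow photometry: dual-emission ratio, baseline normalization
# (dF/F, dR/R) and repeat averaging. No background subtraction anywhere,
# matching the acquisition convention.

#' Stopped-flow trace container
#'
#' @param data data frame with columns `t` (s, monotone) and `ch1`
#'   (a.u.), optionally `ch2` for dual-emission recordings.
#' @param mix_time signal onset (instrument trigger + dead time), s. Comes
#'   from the device metadata, never inferred from the trace.
#' @return An `sf_trace` object.
#' @export
sf_trace <- function(data, mix_time) {
  if (!all(c("t", "ch1") %in% names(data)))
    stop_bad("trace needs columns t, ch1")
  if (any(diff(data$t) <= 0)) stop_bad("t must be strictly increasing")
  if (mix_time < 0) stop_bad("mix_time must be >= 0")
  out <- as.data.frame(data)
  attr(out, "mix_time") <- mix_time
  class(out) <- c("sf_trace", "data.frame")
  out
}

#' @export
print.sf_trace <- function(x, ...) {
  cat(sprintf("<sf_trace> %d samples, %d channel(s), mix at %g s%s\n",
              nrow(x), sum(c("ch1", "ch2") %in% names(x)),
              attr(x, "mix_time"),
              if (!is.null(attr(x, "normalized"))) ", normalized" else ""))
  invisible(x)
}

#' @export
plot.sf_trace <- function(x, ..., xlab = "t (s)", ylab = "F (a.u.)") {
  plot(x$t, x$ch1, type = "l", xlab = xlab, ylab = ylab, ...)
  if ("ch2" %in% names(x)) lines(x$t, x$ch2, col = "steelblue")
  abline(v = attr(x, "mix_time"), lty = 3, col = "grey60")
  invisible(x)
}

#' Dual-emission ratio trace
#'
#' Elementwise channel ratio for ratiometric indicators (e.g. BCECF).
#' Both orientations occur in practice; the one used is recorded in the
#' output's `ratio_orientation` attribute rather than guessed downstream.
#' The default `"ch1_over_ch2"` corresponds to F494/F549 with channel 1 =
#' 494 nm emission. Non-positive denominator samples are masked with a
#' warning.
#'
#' @param trace a two-channel [sf_trace()].
#' @param orientation `"ch1_over_ch2"` or `"ch2_over_ch1"`.
#' @return A single-channel `sf_trace` whose `ch1` is the ratio.
#' @export
compute_ratio <- function(trace, orientation = c("ch1_over_ch2",
                                                 "ch2_over_ch1")) {
  stopifnot(inherits(trace, "sf_trace"))
  orientation <- match.arg(orientation)
  if (!"ch2" %in% names(trace)) stop_bad("trace has no second channel")
  num <- if (orientation == "ch1_over_ch2") trace$ch1 else trace$ch2
  den <- if (orientation == "ch1_over_ch2") trace$ch2 else trace$ch1
  r <- num / den
  bad <- den <= 0
  if (any(bad)) {
    warning(sum(bad), " sample(s) with non-positive denominator masked",
            call. = FALSE)
    r[bad] <- NA_real_
  }
  out <- sf_trace(data.frame(t = trace$t, ch1 = r),
                  mix_time = attr(trace, "mix_time"))
  attr(out, "ratio_orientation") <- orientation
  out
}

#' Baseline normalization: dF/F (or dR/R)
#'
#' `(F - F0)/F0` with `F0` the mean of the first `n_baseline` samples
#' before the signal onset — no background subtraction. Applied to a
#' ratio trace this yields dR/R. The result is invariant under any global
#' gain change of the raw trace.
#'
#' @param trace an [sf_trace()] (single channel; run [compute_ratio()]
#'   first for dual-emission data).
#' @param n_baseline number of pre-onset samples averaged (5-10).
#' @return An `sf_trace` with `ch1` = dF/F, attribute `f0`.
#' @export
normalize_trace <- function(trace, n_baseline = 8) {
  stopifnot(inherits(trace, "sf_trace"))
  if (n_baseline < 5 || n_baseline > 10)
    stop_bad("n_baseline must lie in [5, 10]")
  pre <- which(trace$t < attr(trace, "mix_time"))
  if (length(pre) < n_baseline)
    stop_bad("only ", length(pre), " samples before mix_time; need ",
             n_baseline)
  f0 <- mean(trace$ch1[head(pre, n_baseline)])
  if (!is.finite(f0) || f0 <= 0) stop_bad("baseline F0 must be > 0")
  out <- sf_trace(data.frame(t = trace$t, ch1 = (trace$ch1 - f0) / f0),
                  mix_time = attr(trace, "mix_time"))
  attr(out, "f0") <- f0
  attr(out, "normalized") <- TRUE
  attr(out, "ratio_orientation") <- attr(trace, "ratio_orientation")
  out
}

#' Average repeated stopped-flow recordings
#'
#' Pointwise mean and SD over 3-6 (>= 2) repeats; traces on different
#' time bases are resampled onto the first trace's time base by linear
#' interpolation.
#'
#' @param traces list of single-channel [sf_trace()] objects.
#' @return An `sf_trace` with columns `t`, `ch1` (mean), `sd`; attribute
#'   `n_repeats`.
#' @export
average_repeats <- function(traces) {
  if (length(traces) < 2L) stop_bad("need at least 2 traces to average")
  stopifnot(all(vapply(traces, inherits, TRUE, "sf_trace")))
  base <- traces[[1]]
  mat <- vapply(traces, function(tr) {
    if (identical(tr$t, base$t)) tr$ch1
    else approx(tr$t, tr$ch1, xout = base$t, rule = 2)$y
  }, numeric(nrow(base)))
  out <- sf_trace(data.frame(t = base$t, ch1 = rowMeans(mat)),
                  mix_time = attr(base, "mix_time"))
  out$sd <- apply(mat, 1, sd)
  attr(out, "n_repeats") <- length(traces)
  out
}

#' Read and write stopped-flow trace CSV files
#'
#' Columns `t_s`, `ch1` and optionally `ch2`; the mix time travels in a
#' JSON sidecar (or is given directly).
#'
#' @param file CSV path.
#' @param mix_time signal onset in seconds; if `NULL`, read from
#'   `<file>.json` (`{"mix_time": ...}`).
#' @return `read_sf_trace()` returns an [sf_trace()].
#' @export
read_sf_trace <- function(file, mix_time = NULL) {
  d <- read.csv(file)
  if (is.null(mix_time)) {
    side <- paste0(file, ".json")
    if (!file.exists(side)) stop_bad("no mix_time given and no sidecar ", side)
    mix_time <- jsonlite::read_json(side)$mix_time
  }
  names(d)[names(d) == "t_s"] <- "t"
  sf_trace(d, mix_time = mix_time)
}

#' @rdname read_sf_trace
#' @param trace an [sf_trace()].
#' @export
write_sf_trace <- function(trace, file) {
  d <- as.data.frame(trace)
  names(d)[names(d) == "t"] <- "t_s"
  write.csv(d, file, row.names = FALSE)
  jsonlite::write_json(list(mix_time = attr(trace, "mix_time")),
                       paste0(file, ".json"), auto_unbox = TRUE)
  invisible(file)
}
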