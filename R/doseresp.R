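# Hill dose-response fitting, pH-titration fitting, and the NH4Cl -> pHi
# superposition calibration. fit_hill()/fit_ph_activation() are the
# package's estimators and return classed model objects with the usual
# print/summary/coef/predict/plot/residuals/simulate methods.

#' Fit the Hill equation to a dose-response curve
#'
#' Nonlinear least squares of
#' `response = floor + (ceiling - floor) * f(c; K, h)` with
#' `f = 1/(1 + (K/c)^h)` (activation) or `f = 1/(1 + (c/K)^h)` (block).
#' `K` is fitted on the log scale for conditioning; starting values come
#' from a log-midpoint heuristic (the dose where the range-scaled response
#' crosses one half). Fits are unweighted unless replicate SDs are
#' supplied, in which case `1/SD^2` weights apply.
#'
#' @param doses dose vector (>= 0; at least 4 points spanning the
#'   transition).
#' @param responses matching responses (current, fraction, ...).
#' @param mode `"block"` or `"activation"`.
#' @param weights optional fit weights (e.g. `1/sd^2`).
#' @return A `hill_fit` object; components include `coefficients`
#'   (`K`, `h`, `floor`, `ceiling`), `se`, `vcov`, `mode`, `data`,
#'   `fitted.values`, `residuals`.
#' @examples
#' d <- gen_dose_response(K = 4.5, h = 1, doses = c(.1, .3, 1, 3, 10, 30, 100),
#'                        n_replicates = 1, noise_cv = 0, mode = "block")
#' fit <- fit_hill(d$dose, d$response, mode = "block")
#' coef(fit)
#' @export
fit_hill <- function(doses, responses, mode = c("block", "activation"),
                     weights = NULL) {
  mode <- match.arg(mode)
  if (length(doses) != length(responses)) stop_bad("length mismatch")
  if (length(unique(doses)) < 4L)
    stop_bad("need >= 4 distinct dose points spanning the transition")
  if (any(doses < 0)) stop_bad("doses must be >= 0")
  ok <- is.finite(doses) & is.finite(responses)
  doses <- doses[ok]; responses <- responses[ok]
  f_of <- if (mode == "block") hill_block else hill_activation
  rng <- range(responses)
  if (diff(rng) <= 0)
    stop_bad("no transition in the data: responses are constant")
  # log-midpoint start: dose where the range-scaled mean response crosses 1/2
  mu <- tapply(responses, doses, mean)
  du <- as.numeric(names(mu))
  fr <- (mu - min(mu)) / diff(range(mu))
  if (mode == "block") fr <- 1 - fr
  pos <- du > 0
  k0 <- tryCatch(10^approx(fr[pos], log10(du[pos]), xout = 0.5,
                           ties = mean)$y,
                 error = function(e) NA_real_)
  if (!is.finite(k0)) k0 <- exp(mean(log(du[pos])))
  start <- list(logK = log(k0), h = 1,
                floor = if (mode == "block") min(mu) else min(mu),
                ceiling = max(mu) - min(mu))
  df <- data.frame(dose = doses, response = responses)
  w <- weights %||% rep(1, nrow(df))
  # the fully-blocked / unactivated level cannot undershoot the data:
  # floor >= 0 for magnitude responses (relaxed only if the data go lower)
  floor_min <- min(0, min(responses))
  fit <- tryCatch(
    suppressWarnings(
      nls(response ~ floor + ceiling * f_of(dose, exp(logK), h),
          data = df, start = start, weights = w, algorithm = "port",
          lower = c(logK = log(min(du[pos])) - 10, h = 1e-3,
                    floor = floor_min, ceiling = 1e-12),
          control = list(maxiter = 200, warnOnly = TRUE))),
    error = function(e)
      stop_bad("Hill fit did not converge (no clear transition in the ",
               "data?): ", conditionMessage(e)))
  cf <- coef(fit)
  sig <- sqrt(sum(as.numeric(resid(fit))^2) / max(1, nrow(df) - 4))
  if (cf[["ceiling"]] < 3 * sig)
    stop_bad("no transition in the data: fitted dynamic range (",
             format(cf[["ceiling"]], digits = 3),
             ") is below 3x the residual noise")
  K <- exp(cf[["logK"]])
  est <- c(K = K, h = cf[["h"]], floor = cf[["floor"]],
           ceiling = cf[["ceiling"]])
  V <- tryCatch(vcov(fit), error = function(e) matrix(NA_real_, 4, 4))
  # delta method: var(K) = K^2 var(logK)
  J <- diag(c(K, 1, 1, 1))
  Vp <- J %*% V %*% t(J)
  dimnames(Vp) <- list(names(est), names(est))
  se <- sqrt(pmax(diag(Vp), 0))
  structure(list(coefficients = est, se = se, vcov = Vp, mode = mode,
                 data = df, weights = w,
                 fitted.values = as.numeric(fitted(fit)),
                 residuals = df$response - as.numeric(fitted(fit)),
                 sigma = sig, nls = fit),
            class = "hill_fit")
}

#' @export
coef.hill_fit <- function(object, ...) object$coefficients

#' @export
vcov.hill_fit <- function(object, ...) object$vcov

#' @export
residuals.hill_fit <- function(object, ...) object$residuals

#' @export
fitted.hill_fit <- function(object, ...) object$fitted.values

#' @export
print.hill_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Hill fit (%s mode), %d points\n", x$mode, nrow(x$data)))
  cat(sprintf("  K = %s +/- %s,  h = %s +/- %s\n",
              format(x$coefficients[["K"]], digits = digits),
              format(x$se[["K"]], digits = 2),
              format(x$coefficients[["h"]], digits = digits),
              format(x$se[["h"]], digits = 2)))
  cat(sprintf("  floor = %s, ceiling = %s, residual sigma = %s\n",
              format(x$coefficients[["floor"]], digits = digits),
              format(x$coefficients[["ceiling"]], digits = digits),
              format(x$sigma, digits = 3)))
  invisible(x)
}

#' @export
summary.hill_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se)
  structure(list(coefficients = tab, mode = object$mode,
                 sigma = object$sigma, n = nrow(object$data)),
            class = "summary.hill_fit")
}

#' @export
print.summary.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit (%s mode): n = %d, residual sigma = %.4g\n",
              x$mode, x$n, x$sigma))
  print(x$coefficients)
  invisible(x)
}

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  doses <- if (is.null(newdata)) object$data$dose
           else if (is.data.frame(newdata)) newdata$dose else newdata
  cf <- object$coefficients
  f <- if (object$mode == "block") hill_block else hill_activation
  cf[["floor"]] + cf[["ceiling"]] * f(doses, cf[["K"]], cf[["h"]])
}

#' @export
plot.hill_fit <- function(x, ..., xlab = "dose", ylab = "response") {
  d <- x$data
  pos <- d$dose > 0
  xs <- exp(seq(log(min(d$dose[pos])), log(max(d$dose)), length.out = 200))
  plot(d$dose[pos], d$response[pos], log = "x", xlab = xlab, ylab = ylab, ...)
  lines(xs, predict(x, xs), col = "firebrick")
  invisible(x)
}

#' @export
simulate.hill_fit <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed(seed, {
    mu <- object$fitted.values
    out <- as.data.frame(replicate(nsim, mu + rnorm(length(mu),
                                                    0, object$sigma)))
    names(out) <- paste0("sim_", seq_len(nsim))
    cbind(dose = object$data$dose, out)
  })
}

#' Normalize a blocked current by the fitted Hill floor and ceiling
#'
#' Returns `(I - I_minFit) / I_maxFit`, the convention used to pool
#' TEA-block curves from cells with different maximal currents so they
#' superimpose.
#'
#' @param I current value(s), same units as the fitted responses.
#' @param fit a converged [fit_hill()] object.
#' @return Normalized (unitless) value(s).
#' @export
normalize_block <- function(I, fit) {
  stopifnot(inherits(fit, "hill_fit"))
  cf <- coef(fit)
  if (abs(cf[["ceiling"]]) < 1e-12)
    stop_bad("fitted ceiling (I_maxFit) is zero; cannot normalize")
  (I - cf[["floor"]]) / cf[["ceiling"]]
}

#' Fit a pH-titration (proton-gating) curve
#'
#' Fits `I = i_max / (1 + 10^(slope * (ph_half - pH)))` — a Hill curve in
#' [H+], parameterized directly in pH (log space) for numerical
#' conditioning. `ph_half` is the half-activation pH; `slope` the apparent
#' Hill coefficient for protons.
#'
#' @param ph_values intracellular pH values (>= 4 spanning the transition,
#'   e.g. 6.4, 6.9, 7.4, 7.9, 8.4).
#' @param currents matching mean currents (any consistent units).
#' @param weights optional fit weights.
#' @return A `ph_fit` object with coefficients `ph_half`, `slope`,
#'   `i_max`.
#' @export
fit_ph_activation <- function(ph_values, currents, weights = NULL) {
  if (length(ph_values) != length(currents)) stop_bad("length mismatch")
  if (length(unique(ph_values)) < 4L)
    stop_bad("need >= 4 pH points spanning the transition")
  i_max0 <- max(currents)
  fr <- currents / i_max0
  ph0 <- tryCatch(approx(fr, ph_values, xout = 0.5, ties = mean)$y,
                  error = function(e) NA_real_)
  if (!is.finite(ph0)) ph0 <- mean(range(ph_values))
  df <- data.frame(ph = ph_values, i = currents)
  w <- weights %||% rep(1, nrow(df))
  fit <- tryCatch(
    nls(i ~ i_max / (1 + 10^(slope * (ph_half - ph))), data = df,
        start = list(ph_half = ph0, slope = 1, i_max = i_max0),
        weights = w, algorithm = "port",
        lower = c(ph_half = 0, slope = 1e-3, i_max = 1e-12),
        upper = c(ph_half = 14, slope = 100, i_max = Inf)),
    error = function(e)
      stop_bad("pH fit did not converge: ", conditionMessage(e)))
  cf <- coef(fit)
  V <- tryCatch(vcov(fit), error = function(e) matrix(NA_real_, 3, 3))
  se <- sqrt(pmax(diag(V), 0))
  names(se) <- names(cf)
  structure(list(coefficients = cf, se = se, vcov = V, data = df,
                 fitted.values = as.numeric(fitted(fit)),
                 residuals = df$i - as.numeric(fitted(fit)), nls = fit),
            class = "ph_fit")
}

#' @export
coef.ph_fit <- function(object, ...) object$coefficients

#' @export
print.ph_fit <- function(x, digits = 4, ...) {
  cat(sprintf("pH-titration fit: ph_half = %s +/- %s, slope = %s +/- %s\n",
              format(x$coefficients[["ph_half"]], digits = digits),
              format(x$se[["ph_half"]], digits = 2),
              format(x$coefficients[["slope"]], digits = digits),
              format(x$se[["slope"]], digits = 2)))
  invisible(x)
}

#' @export
predict.ph_fit <- function(object, newdata = NULL, ...) {
  ph <- if (is.null(newdata)) object$data$ph
        else if (is.data.frame(newdata)) newdata$ph else newdata
  cf <- object$coefficients
  cf[["i_max"]] / (1 + 10^(cf[["slope"]] * (cf[["ph_half"]] - ph)))
}

#' @export
plot.ph_fit <- function(x, ..., xlab = "pH", ylab = "current") {
  d <- x$data
  xs <- seq(min(d$ph) - 0.2, max(d$ph) + 0.2, length.out = 200)
  plot(d$ph, d$i, xlab = xlab, ylab = ylab, ...)
  lines(xs, predict(x, xs), col = "firebrick")
  invisible(x)
}

#' NH4Cl -> intracellular pH calibration by superposition
#'
#' The fractional current activated by NH4Cl (a Hill curve in [NH4Cl])
#' and the fractional current as a function of pHi (the pH-titration
#' curve) report the same gate, so equating the two fractions maps each
#' NH4Cl dose to the pHi it produces:
#' `pHi(c) = ph_curve^-1(nh4cl_curve(c))`, clipped below at the resting
#' `baseline_ph`. By default the NH4Cl curve has Hill coefficient 1 and
#' half-max at 1.5 mM, the parameter pair consistent with both printed
#' anchors (about 40\% activation at 1 mM; half-maximal response at
#' 1.5 mM, the dose mapping the resting pH 6.4 to the half-activation pH).
#'
#' @param nh4cl_fit the NH4Cl activation curve: a [fit_hill()] object
#'   (activation mode) or a list/vector with elements `K` (mM) and `h`.
#' @param ph_fit the pH curve: a [fit_ph_activation()] object or a
#'   list/vector with `ph_half` and `slope`.
#' @param baseline_ph resting intracellular pH (clip floor).
#' @return An `nh4cl_calibration` object; use `predict(cal, conc)` to map
#'   NH4Cl concentrations (mM) to pHi. Fractions at or above the pH
#'   curve's saturating branch are flagged via the `"boundary"` attribute
#'   of the prediction.
#' @examples
#' cal <- calibrate_nh4cl()
#' predict(cal, c(0, 1, 1.5, 10))
#' @export
calibrate_nh4cl <- function(nh4cl_fit = list(K = 1.5, h = 1),
                            ph_fit = list(ph_half = 7.08, slope = 1),
                            baseline_ph = 6.4) {
  kh <- if (inherits(nh4cl_fit, "hill_fit")) {
    if (nh4cl_fit$mode != "activation")
      stop_bad("nh4cl_fit must be an activation-mode curve")
    coef(nh4cl_fit)[c("K", "h")]
  } else c(K = nh4cl_fit[["K"]], h = nh4cl_fit[["h"]] %||% 1)
  ps <- if (inherits(ph_fit, "ph_fit"))
    coef(ph_fit)[c("ph_half", "slope")]
  else c(ph_half = ph_fit[["ph_half"]], slope = ph_fit[["slope"]] %||% 1)
  if (kh[["K"]] <= 0 || kh[["h"]] <= 0 || ps[["slope"]] <= 0)
    stop_bad("calibration curves must be monotone (positive K, h, slope)")
  structure(list(nh4cl_K = kh[["K"]], nh4cl_h = kh[["h"]],
                 ph_half = ps[["ph_half"]], ph_slope = ps[["slope"]],
                 baseline_ph = baseline_ph),
            class = "nh4cl_calibration")
}

#' @export
print.nh4cl_calibration <- function(x, ...) {
  cat(sprintf(paste0("NH4Cl -> pHi calibration: K = %g mM (h = %g), ",
                     "ph_half = %g (slope = %g), baseline pHi = %g\n"),
              x$nh4cl_K, x$nh4cl_h, x$ph_half, x$ph_slope, x$baseline_ph))
  invisible(x)
}

#' @export
predict.nh4cl_calibration <- function(object, newdata, ...) {
  conc <- if (is.data.frame(newdata)) newdata$conc else newdata
  if (any(conc < 0)) stop_bad("concentrations must be >= 0")
  f <- hill_activation(conc, object$nh4cl_K, object$nh4cl_h)
  boundary <- f >= 1 | f <= 0
  ph <- ifelse(f <= 0, -Inf,
               ifelse(f >= 1, Inf,
                      object$ph_half -
                        log10(1 / f - 1) / object$ph_slope))
  ph <- pmax(ph, object$baseline_ph)     # clip at resting pH
  boundary <- boundary | !is.finite(ph)
  ph[ph == Inf] <- NA_real_              # beyond the invertible range
  structure(ph, boundary = boundary)
}

#' @rdname calibrate_nh4cl
#' @param calibration an `nh4cl_calibration`.
#' @param conc NH4Cl concentrations, mM.
#' @export
map_nh4cl_to_ph <- function(calibration, conc) {
  as.numeric(predict(calibration, conc))
}
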