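# Voltage-clamp analysis: sweep sets -> IV relations, reversal potentials,
# K+-dependence slopes, normalized IV curves and Na+-block quantities.
# All voltages are assumed liquid-junction-corrected; an optional offset can
# be applied exactly once via correct_junction().

#' IV curve container
#'
#' @param v command voltages, mV, strictly increasing.
#' @param i steady-state currents, pA.
#' @param i_sd optional per-point SD, pA.
#' @param window_fraction fraction of the step used for the steady-state
#'   window (bookkeeping).
#' @return An `iv_curve` data frame with columns `v`, `i`, `i_sd`.
#' @export
iv_curve <- function(v, i, i_sd = NA_real_, window_fraction = NA_real_) {
  if (length(v) != length(i)) stop_bad("v and i must have equal length")
  if (any(diff(v) <= 0)) stop_bad("v must be strictly increasing")
  out <- data.frame(v = v, i = i, i_sd = rep_len(i_sd, length(v)))
  attr(out, "window_fraction") <- window_fraction
  class(out) <- c("iv_curve", "data.frame")
  out
}

#' @export
print.iv_curve <- function(x, ...) {
  cat(sprintf("<iv_curve> %d points, %g..%g mV\n", nrow(x), min(x$v), max(x$v)))
  if (!is.null(attr(x, "normalized")))
    cat(sprintf("  normalized to %g at %g mV\n",
                attr(x, "normalized")$ref_val, attr(x, "normalized")$ref_v))
  invisible(x)
}

#' @export
plot.iv_curve <- function(x, ..., xlab = "V (mV)", ylab = "I (pA)",
                          type = "b") {
  plot(x$v, x$i, type = type, xlab = xlab, ylab = ylab, ...)
  abline(h = 0, v = 0, col = "grey70", lty = 3)
  invisible(x)
}

#' Reduce a sweep set to a steady-state IV relation
#'
#' Per step, mean and SD of the current over the trailing
#' `window_fraction` of the step. The window must exclude the first 10 ms
#' of the step, where capacitive transients would live.
#'
#' @param sweeps a `sweep_set` (see [gen_sweeps()] or [read_sweep_set()]).
#' @param window_fraction trailing fraction of the step to average.
#' @return An [iv_curve()] (points sorted by voltage).
#' @export
extract_iv <- function(sweeps, window_fraction = 0.25) {
  stopifnot(inherits(sweeps, "sweep_set"))
  if (window_fraction <= 0 || window_fraction > 1)
    stop_bad("window_fraction must be in (0, 1]")
  dur <- sweeps$protocol$step_duration_ms
  if ((1 - window_fraction) * dur < 10)
    stop_bad("steady-state window would start ",
             format((1 - window_fraction) * dur),
             " ms into the step, inside the 10 ms capacitive region; ",
             "use a smaller window_fraction")
  t_step <- sweeps$t_ms - sweeps$step_onset_ms
  in_win <- t_step >= (1 - window_fraction) * dur & t_step <= dur
  mu <- apply(sweeps$traces[, in_win, drop = FALSE], 1, mean)
  sdv <- apply(sweeps$traces[, in_win, drop = FALSE], 1, sd)
  ord <- order(sweeps$protocol$step_levels)
  iv_curve(sweeps$protocol$step_levels[ord], mu[ord], sdv[ord],
           window_fraction = window_fraction)
}

#' Reversal potential from an IV relation
#'
#' Linear interpolation between the pair of IV points bracketing zero
#' current — the robust visual-read-off estimator, insensitive to
#' rectification away from the crossing. With no sign change the two
#' points nearest zero current are extrapolated and the estimate flagged.
#'
#' @param iv an [iv_curve()].
#' @return A `vrev_estimate` list: `v_rev` (mV), `method`, `bracket`,
#'   `extrapolated`.
#' @export
estimate_vrev <- function(iv) {
  stopifnot(inherits(iv, "iv_curve"))
  s <- sign(iv$i)
  cross <- which(s[-1] * s[-length(s)] < 0 | s[-length(s)] == 0)
  if (length(cross) > 1L)
    stop_bad("IV is non-monotone around zero: ", length(cross),
             " sign changes (voltages near ",
             paste(round(iv$v[cross], 1), collapse = ", "), " mV)")
  if (length(cross) == 1L) {
    k <- cross
    v1 <- iv$v[k]; v2 <- iv$v[k + 1]
    i1 <- iv$i[k]; i2 <- iv$i[k + 1]
    vr <- v1 - i1 * (v2 - v1) / (i2 - i1)
    out <- list(v_rev = vr, method = "linear-interpolation",
                bracket = c(v1, v2), extrapolated = FALSE)
  } else {
    # no crossing: extrapolate from the two points nearest zero current
    k <- order(abs(iv$i))[1:2]
    k <- sort(k)
    v1 <- iv$v[k[1]]; v2 <- iv$v[k[2]]
    i1 <- iv$i[k[1]]; i2 <- iv$i[k[2]]
    vr <- v1 - i1 * (v2 - v1) / (i2 - i1)
    out <- list(v_rev = vr, method = "extrapolation",
                bracket = c(v1, v2), extrapolated = TRUE)
    warning("no zero-current crossing; V_rev extrapolated", call. = FALSE)
  }
  class(out) <- "vrev_estimate"
  out
}

#' @export
print.vrev_estimate <- function(x, ...) {
  cat(sprintf("V_rev = %.2f mV (%s%s, bracket %g..%g mV)\n", x$v_rev,
              x$method, if (x$extrapolated) ", flagged" else "",
              x$bracket[1], x$bracket[2]))
  invisible(x)
}

#' Slope of the reversal potential versus log10 [K+]o
#'
#' Least-squares regression of V_rev on log10 of the extracellular K+
#' concentration; a perfectly K+-selective channel gives the Nernstian
#' 58.17 mV per decade at 20 C.
#'
#' @param vrevs reversal potentials, mV.
#' @param k_out matching extracellular K+ concentrations, mM.
#' @return List: `slope` (mV/decade), `se`, `intercept`, `fit` (the `lm`).
#' @export
nernst_slope <- function(vrevs, k_out) {
  if (length(vrevs) != length(k_out)) stop_bad("length mismatch")
  if (length(unique(k_out)) < 2L)
    stop_bad("need at least 2 distinct [K+]o values")
  fit <- lm(vrevs ~ log10(k_out))
  co <- summary(fit)$coefficients
  list(slope = co[2, 1],
       se = if (nrow(co) >= 2 && length(vrevs) > 2) co[2, 2] else NA_real_,
       intercept = co[1, 1], fit = fit)
}

#' Nernst / GHK reversal potential
#'
#' Nernst: `(RT/zF) ln([X]o/[X]i)`. GHK voltage equation (monovalent):
#' `RT/F ln((sum P_cat [cat]o + sum P_an [an]i) /
#'          (sum P_cat [cat]i + sum P_an [an]o))`.
#'
#' @param mode `"nernst"` or `"ghk"`.
#' @param concentrations named list of `c(in = ..., out = ...)` in mM.
#'   For `"nernst"` exactly one ion is used (the first).
#' @param permeability_ratios named relative permeabilities (ghk mode);
#'   ions named in `anions` contribute with sides swapped.
#' @param temperature kelvin.
#' @param z valence (nernst mode).
#' @param anions character vector naming anionic species (default `"Cl"`).
#' @return Reversal potential in mV.
#' @examples
#' predict_vrev("nernst", list(K = c("in" = 130, out = 5.4)))  # -80.37 mV
#' @export
predict_vrev <- function(mode = c("nernst", "ghk"), concentrations,
                         permeability_ratios = NULL, temperature = 293.15,
                         z = 1, anions = "Cl") {
  mode <- match.arg(mode)
  for (ion in names(concentrations))
    if (any(concentrations[[ion]] <= 0))
      stop_bad("concentrations must be > 0 (ion ", ion, ")")
  if (mode == "nernst") {
    cc <- concentrations[[1]]
    return(rtf_mV(temperature) / z * log(cc[["out"]] / cc[["in"]]))
  }
  if (is.null(permeability_ratios)) stop_bad("ghk mode needs permeabilities")
  num <- den <- 0
  for (ion in names(permeability_ratios)) {
    cc <- concentrations[[ion]]
    if (is.null(cc) || !all(c("in", "out") %in% names(cc)))
      stop_bad("ghk mode needs both-side concentrations for '", ion, "'")
    p <- permeability_ratios[[ion]]
    if (ion %in% anions) {
      num <- num + p * cc[["in"]]
      den <- den + p * cc[["out"]]
    } else {
      num <- num + p * cc[["out"]]
      den <- den + p * cc[["in"]]
    }
  }
  rtf_mV(temperature) * log(num / den)
}

# current at an arbitrary voltage by linear interpolation of the IV points
iv_interp <- function(iv, v) {
  if (v < min(iv$v) || v > max(iv$v))
    stop_bad("voltage ", v, " mV outside the IV support")
  approx(iv$v, iv$i, xout = v)$y
}

#' Normalize an IV relation to a reference voltage
#'
#' All currents are divided by |I(ref_v)| (interpolated if needed), with
#' the sign chosen so the value at `ref_v` equals `ref_val` (convention:
#' -1 at -115 mV). Normalization is idempotent and scale-invariant, so
#' curves differing only in maximal conductance superimpose.
#'
#' @param iv an [iv_curve()].
#' @param ref_v reference voltage, mV.
#' @param ref_val value assigned at `ref_v` (-1 or +1).
#' @return A normalized [iv_curve()] (unitless currents).
#' @export
normalize_iv <- function(iv, ref_v = -115, ref_val = -1) {
  stopifnot(inherits(iv, "iv_curve"), abs(ref_val) == 1)
  i_ref <- iv_interp(iv, ref_v)
  if (abs(i_ref) < 0.01 * max(abs(iv$i)))
    stop_bad("current at the reference voltage is < 1% of the maximum; ",
             "cannot normalize")
  sc <- abs(i_ref)
  # sign factor ref_val/sign(i_ref) sends I(ref_v) to exactly ref_val
  i_new <- iv$i / sc * (ref_val / sign(i_ref))
  out <- iv_curve(iv$v, i_new, iv$i_sd / sc,
                  window_fraction = attr(iv, "window_fraction"))
  attr(out, "normalized") <- list(ref_v = ref_v, ref_val = ref_val)
  out
}

#' Woodhull fraction of current unblocked by intracellular Na+
#'
#' Single-site voltage-dependent block: the blocker senses a fraction
#' `delta` of the membrane field, so its effective dissociation constant is
#' `kd0 * exp(-delta * z F V / RT)` and
#' `unblocked = 1 / (1 + [Na]i / Kd(V))`. Block deepens with
#' depolarization and with [Na]i.
#'
#' @param v membrane voltage, mV (vectorized).
#' @param na_in intracellular Na+, mM.
#' @param kd0 dissociation constant at 0 mV, mM.
#' @param delta fractional electrical distance, 0-1.
#' @param temperature kelvin.
#' @param z blocker valence.
#' @return Fraction of current not blocked, in (0, 1].
#' @export
na_block_fraction <- function(v, na_in, kd0, delta, temperature = 293.15,
                              z = 1) {
  if (kd0 <= 0) stop_bad("kd0 must be > 0")
  if (delta < 0 || delta > 1) stop_bad("delta must lie in [0, 1]")
  if (na_in < 0) stop_bad("na_in must be >= 0")
  kd_v <- kd0 * exp(-delta * z * v / rtf_mV(temperature))
  1 / (1 + na_in / kd_v)
}

#' Outward rectification index of an IV relation
#'
#' `|I(v_out)| / |I(v_in)|`; identical for raw and normalized curves
#' (the scale cancels). Used to compare Na+-blocked and unblocked
#' channels.
#'
#' @param iv an [iv_curve()].
#' @param v_out,v_in outward and inward reference voltages, mV.
#' @return Unitless index.
#' @export
rectification_index <- function(iv, v_out = 25, v_in = -115) {
  i_in <- iv_interp(iv, v_in)
  if (abs(i_in) < 1e-12 * max(abs(iv$i)))
    stop_bad("current at v_in is zero; index undefined")
  abs(iv_interp(iv, v_out)) / abs(i_in)
}

#' Apply a liquid-junction-potential correction once
#'
#' Subtracts `offset_mV` from all voltages and records the fact; applying
#' a correction twice is an error by contract.
#'
#' @param iv an [iv_curve()].
#' @param offset_mV junction potential to subtract, mV.
#' @return The corrected [iv_curve()].
#' @export
correct_junction <- function(iv, offset_mV) {
  stopifnot(inherits(iv, "iv_curve"))
  if (!is.null(attr(iv, "junction_corrected")))
    stop_bad("junction correction already applied (",
             attr(iv, "junction_corrected"), " mV)")
  out <- iv_curve(iv$v - offset_mV, iv$i, iv$i_sd,
                  window_fraction = attr(iv, "window_fraction"))
  attr(out, "junction_corrected") <- offset_mV
  out
}
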