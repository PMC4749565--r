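# Multi-ligand metal-buffer equilibria: EGTA/ATP with Ca2+/Mg2+/H+ at fixed
# pH, in the style of the classic free-calcium calculators. Stability
# constants are critical-stability (Martell & Smith) association constants
# referenced at I = 0.1 M, 20 C; they are moved to the working ionic
# strength with a Davies activity correction, and the pH-meter reading is
# treated as proton activity (converted to concentration with gamma_H).

# log10 association constants at I = 0.1 M, 20 C.
# kh: stepwise proton association (H + L -> HL, H + HL -> H2L, ...)
# km: metal association M + L -> ML; kmh: M + HL -> MHL
.CHELATOR_CONSTANTS <- list(
  EGTA = list(kh = c(9.47, 8.85, 2.66, 2.0),
              km = c(Ca = 10.86, Mg = 5.21),
              kmh = c(Ca = 5.33, Mg = 3.37)),
  ATP = list(kh = c(6.48, 4.00),
             km = c(Ca = 3.98, Mg = 4.29),
             kmh = c(Ca = 2.13, Mg = 2.39))
)
.CONSTANT_SET <- "Martell-Smith critical stability (I=0.1 M, 20 C reference)"
.I_REF <- 0.1

# charge change z(A)^2 + z(B)^2 - z(AB)^2 for each association step,
# ligand charge -4 (EGTA, ATP), metals +2, proton +1
.DZ2_H <- c(8, 6, 4, 2)   # H+L(4-), H+HL(3-), H+H2L(2-), H+H3L(1-)
.DZ2_M <- 16              # M(2+) + L(4-)
.DZ2_MH <- 12             # M(2+) + HL(3-)

# Debye-Hueckel A parameter at temperature T (kelvin), water
debye_A <- function(temperature) {
  t <- temperature - 273.15
  eps <- 87.74 - 0.4008 * t + 9.398e-4 * t^2 - 1.41e-6 * t^3
  1.8246e6 / (eps * temperature)^1.5
}

davies_f <- function(I) sqrt(I) / (1 + sqrt(I)) - 0.3 * I

# association logK moved from the reference to ionic strength I
adjust_logk <- function(logk_ref, dz2, I, temperature) {
  A <- debye_A(temperature)
  logk_ref - dz2 * A * (davies_f(I) - davies_f(.I_REF))
}

# proton concentration from a pH-meter reading (activity -> concentration)
h_conc <- function(pH, I, temperature) {
  log_gamma <- -debye_A(temperature) * davies_f(I)
  10^(-pH - log_gamma)
}

# effective association constant of all M-L forms per free ligand pool:
# K_eff = [ML + MHL] / ([M] [L']), L' = all non-metal-bound ligand forms
k_eff <- function(ligand, metal, h, I, temperature, include_mhl = TRUE) {
  cst <- .CHELATOR_CONSTANTS[[ligand]]
  nh <- length(cst$kh)
  kh <- 10^adjust_logk(cst$kh, .DZ2_H[seq_len(nh)], I, temperature)
  # cumulative protonation terms: [H_jL]/[L]
  cum <- cumprod(kh * h)
  prot_sum <- 1 + sum(cum)
  beta_m <- 10^adjust_logk(cst$km[[metal]], .DZ2_M, I, temperature)
  beta_mh <- if (include_mhl && metal %in% names(cst$kmh))
    10^adjust_logk(cst$kmh[[metal]], .DZ2_MH, I, temperature) else 0
  (beta_m + beta_mh * kh[1] * h) / prot_sum
}

#' Apparent (pH- and ionic-strength-corrected) dissociation constant
#'
#' The proton-competition correction behind every chelator calculator:
#' with only the unprotonated ligand binding,
#' `Kd_app = Kd_abs * prod(1 + [H+]/Ka_i)` over the ligand's protonation
#' steps; the metal-protonated (MHL) complex, included by default, adds a
#' parallel binding path. Constants are Davies-adjusted to the working
#' ionic strength and the pH reading is converted from activity to
#' concentration.
#'
#' @param ligand `"EGTA"` or `"ATP"`.
#' @param metal `"Ca"` or `"Mg"`.
#' @param pH pH-meter reading.
#' @param temperature kelvin.
#' @param ionic_strength mol/L.
#' @param include_mhl include the protonated MHL complex.
#' @return Apparent dissociation constant in mol/L.
#' @examples
#' apparent_kd("EGTA", "Ca", pH = 7.4)           # tens of nM
#' apparent_kd("EGTA", "Ca", pH = 6.4)           # ~100x weaker
#' @export
apparent_kd <- function(ligand, metal, pH, temperature = 293.15,
                        ionic_strength = 0.16, include_mhl = TRUE) {
  if (!ligand %in% names(.CHELATOR_CONSTANTS))
    stop_bad("unknown ligand '", ligand, "'; supported: ",
             paste(names(.CHELATOR_CONSTANTS), collapse = ", "))
  if (!metal %in% names(.CHELATOR_CONSTANTS[[ligand]]$km))
    stop_bad("no ", ligand, "-", metal, " constants")
  if (pH <= 0 || pH >= 14) stop_bad("pH must lie in (0, 14)")
  h <- h_conc(pH, ionic_strength, temperature)
  1 / k_eff(ligand, metal, h, ionic_strength, temperature, include_mhl)
}

#' Solution recipe for equilibrium solving
#'
#' @param totals named total concentrations in mM. Recognised chelators:
#'   `EGTA`, `ATP`; metals: `Ca`, `Mg`; everything else (K, Na, Cl,
#'   aspartate, ...) is background electrolyte entering only the ionic
#'   strength. Aspartate is treated as non-chelating.
#' @param pH pH-meter reading (0-14).
#' @param temperature kelvin.
#' @param ionic_strength mol/L; computed from the recipe
#'   (`0.5 * sum(c z^2)` with nominal charges) when `NULL`.
#' @return A `solution_recipe` list.
#' @examples
#' # standard pipette solution: NaCl 10, K-aspartate 130, MgCl2 2,
#' # EGTA 1, Na2ATP 2 (+ residual 1 uM Ca from water)
#' r <- solution_recipe(
#'   totals = c(EGTA = 1, ATP = 2, Ca = 0.001, Mg = 2,
#'              K = 130, Na = 14, Cl = 14, aspartate = 130),
#'   pH = 7.4)
#' @export
solution_recipe <- function(totals, pH, temperature = 293.15,
                            ionic_strength = NULL) {
  if (any(totals < 0)) stop_bad("totals must be >= 0")
  if (pH <= 0 || pH >= 14) stop_bad("pH must lie in (0, 14)")
  if (is.null(names(totals)) || any(!nzchar(names(totals))))
    stop_bad("totals must be a fully named vector")
  charges <- c(EGTA = -4, ATP = -4, Ca = 2, Mg = 2, K = 1, Na = 1,
               Cl = -1, aspartate = -1, HEPES = 0, glucose = 0)
  if (is.null(ionic_strength)) {
    z <- charges[names(totals)]
    z[is.na(z)] <- 1   # unknown species counted as monovalent
    ionic_strength <- 0.5 * sum((totals / 1000) * z^2)
  }
  structure(list(totals = totals, pH = pH, temperature = temperature,
                 ionic_strength = ionic_strength),
            class = "solution_recipe")
}

#' @export
print.solution_recipe <- function(x, ...) {
  cat(sprintf("<solution_recipe> pH %g, %g K, I = %.3f M\n",
              x$pH, x$temperature, x$ionic_strength))
  print(x$totals)
  invisible(x)
}

#' Read a solution recipe from JSON
#'
#' Expects `{"totals_mM": {...}, "pH": ..., "temperature_K": ...,
#' "ionic_strength_M": ...}` (the last two optional).
#'
#' @param file JSON path.
#' @return A [solution_recipe()].
#' @export
read_recipe <- function(file) {
  j <- jsonlite::read_json(file, simplifyVector = TRUE)
  solution_recipe(unlist(j$totals_mM), pH = j$pH,
                  temperature = j$temperature_K %||% 293.15,
                  ionic_strength = j$ionic_strength_M)
}

#' Solve the metal-ligand equilibrium of a recipe
#'
#' Simultaneous mass balance for free Ca2+, Mg2+ and the
#' metal-unbound ligand pools at fixed pH, by damped successive
#' substitution on the coupled binding equations
#' `L'_j = Ltot_j / (1 + sum_i M_i K_ij)` and
#' `M_i = Mtot_i / (1 + sum_j L'_j K_ij)`. Converges to a mass-balance
#' residual below `tol` (1e-12 relative) in a few dozen iterations for
#' physiological recipes.
#'
#' @param recipe a [solution_recipe()].
#' @param tol relative mass-balance tolerance.
#' @param max_iter iteration cap; non-convergence is an error reporting
#'   the last residual.
#' @return An `equilibrium_result`: `free` (M; free metals and free
#'   chelator pools), `bound` (M per metal-ligand pair),
#'   `apparent_kd` (M), `residual`, `ionic_strength`, `constant_set`.
#' @examples
#' r <- solution_recipe(c(EGTA = 1, ATP = 2, Ca = 0.001, Mg = 2,
#'                        K = 130, Na = 14, Cl = 14, aspartate = 130),
#'                      pH = 7.4)
#' eq <- solve_equilibrium(r)
#' eq$free["Ca"] * 1e12   # free Ca2+ in pM
#' @export
solve_equilibrium <- function(recipe, tol = 1e-12, max_iter = 10000) {
  stopifnot(inherits(recipe, "solution_recipe"))
  tot <- recipe$totals / 1000   # mM -> M
  metals <- intersect(c("Ca", "Mg"), names(tot))
  metals <- metals[tot[metals] > 0]
  ligands <- intersect(names(.CHELATOR_CONSTANTS), names(tot))
  ligands <- ligands[tot[ligands] > 0]
  I <- recipe$ionic_strength
  h <- h_conc(recipe$pH, I, recipe$temperature)
  if (length(ligands) == 0L || length(metals) == 0L) {
    free <- tot[metals]
    return(structure(list(free = free, bound = NULL,
                          apparent_kd = NULL, residual = 0,
                          ionic_strength = I,
                          constant_set = .CONSTANT_SET),
                     class = "equilibrium_result"))
  }
  K <- matrix(0, length(metals), length(ligands),
              dimnames = list(metals, ligands))
  for (m in metals) for (l in ligands)
    K[m, l] <- k_eff(l, m, h, I, recipe$temperature)
  M <- tot[metals]              # start from totals
  Lp <- tot[ligands]
  damp <- 0.5
  resid <- Inf
  for (it in seq_len(max_iter)) {
    Lp_new <- tot[ligands] / (1 + as.numeric(M %*% K))
    M_new <- tot[metals] / (1 + as.numeric(K %*% Lp_new))
    # damping in log space keeps the iteration stable when buffering is stiff
    M <- exp((1 - damp) * log(M) + damp * log(M_new))
    Lp <- exp((1 - damp) * log(Lp) + damp * log(Lp_new))
    bound <- outer(M, Lp) * K
    resid <- max(abs(M + rowSums(bound) - tot[metals]) / tot[metals],
                 abs(Lp + colSums(bound) - tot[ligands]) / tot[ligands])
    if (resid < tol) break
  }
  if (resid >= tol)
    stop_bad("equilibrium solver did not converge after ", max_iter,
             " iterations (residual ", format(resid), ")")
  kd <- 1 / K
  structure(list(free = c(M, setNames(Lp, ligands)),
                 bound = outer(M, Lp) * K,
                 apparent_kd = kd, residual = resid,
                 ionic_strength = I, pH = recipe$pH,
                 temperature = recipe$temperature,
                 constant_set = .CONSTANT_SET, iterations = it),
            class = "equilibrium_result")
}

#' @export
print.equilibrium_result <- function(x, ...) {
  cat(sprintf("<equilibrium_result> pH %g, I = %.3f M (%s)\n",
              x$pH %||% NA, x$ionic_strength, x$constant_set))
  for (nm in names(x$free)) {
    v <- x$free[[nm]]
    unit <- if (v < 1e-9) c(1e12, "pM") else if (v < 1e-6) c(1e9, "nM")
            else if (v < 1e-3) c(1e6, "µM") else c(1e3, "mM")
    cat(sprintf("  free %-6s %8.3g %s\n", nm,
                v * as.numeric(unit[1]), unit[2]))
  }
  cat(sprintf("  mass-balance residual %.2e\n", x$residual))
  invisible(x)
}

#' Free Ca2+ of the standard pipette solution
#'
#' Convenience wrapper reproducing the published pipette-solution
#' calculation: NaCl 10, K-aspartate 130, MgCl2 2, EGTA 1, Na2ATP 2 (mM)
#' with a residual total Ca2+ of 1 uM from water, at the requested pH.
#'
#' @param pH pipette pH.
#' @param ca_total_mM total Ca2+, mM (default 0.001 = 1 uM).
#' @param temperature kelvin.
#' @return Free Ca2+ concentration in mol/L.
#' @export
pipette_free_ca <- function(pH, ca_total_mM = 0.001, temperature = 293.15) {
  r <- solution_recipe(
    totals = c(EGTA = 1, ATP = 2, Ca = ca_total_mM, Mg = 2,
               K = 130, Na = 14, Cl = 14, aspartate = 130),
    pH = pH, temperature = temperature)
  unname(solve_equilibrium(r)$free["Ca"])
}
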