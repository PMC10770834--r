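#' @keywords internal
GAS_CONSTANT <- 8.314  # J / (mol K)

#' Double-reciprocal (Benesi-Hildebrand-type) binding fit
#'
#' Fits the 1:1 binding linearization
#' \deqn{1/\Delta F = 1/\Delta F_{max} + 1/(K_b [L]) \cdot 1/\Delta F_{max}}
#' by ordinary least squares of \eqn{y = 1/\Delta F} on \eqn{x = 1/[L]}.
#' The binding constant is the intercept/slope ratio and the saturation
#' fluorescence change is the reciprocal intercept.
#'
#' @param points Data frame (or list) with columns `concentration` (mol/L,
#'   all > 0) and `delta_f` (a.u., all > 0); at least 3 points. Typically
#'   the output of [delta_f_series()].
#' @param wavelength Analysis wavelength in nm (metadata, default 340).
#' @param temperature Temperature in K (metadata).
#'
#' @return Object of class `binding_fit` with elements `kb` (M^-1),
#'   `delta_f_max` (a.u.), `slope`, `intercept`, `r_squared` (squared
#'   Pearson correlation of the transformed variables), `n_points`,
#'   `wavelength`, `temperature`.
#' @export
#' @examples
#' c_um <- c(5, 10, 20, 40) * 1e-6
#' df <- 200 * 5e4 * c_um / (1 + 5e4 * c_um)   # noiseless hyperbola
#' fit_double_reciprocal(data.frame(concentration = c_um, delta_f = df),
#'                       340, 298.15)
fit_double_reciprocal <- function(points, wavelength = 340, temperature = NA_real_) {
  conc <- points$concentration
  df <- points$delta_f
  if (length(conc) < 3L) stop("need at least 3 points for the double-reciprocal fit")
  if (any(conc <= 0)) stop("all concentrations must be positive")
  if (any(df <= 0)) stop("all delta F values must be positive")
  x <- 1 / conc
  y <- 1 / df
  if (stats::sd(x) == 0) stop("degenerate fit: all concentrations equal")
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  if (slope <= 0 || intercept <= 0)
    stop("no physically meaningful binding constant: non-positive slope or intercept in reciprocal space")
  structure(list(
    kb = intercept / slope,
    delta_f_max = 1 / intercept,
    slope = slope, intercept = intercept,
    r_squared = stats::cor(x, y)^2,
    n_points = length(conc),
    wavelength = wavelength, temperature = temperature), class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("binding_fit: Kb = %.4g M^-1, dFmax = %.4g a.u., R2 = %.4f (n = %d, %g nm, %.2f K)\n",
              x$kb, x$delta_f_max, x$r_squared, x$n_points, x$wavelength, x$temperature))
  invisible(x)
}

#' Direct hyperbolic binding fit (alternative route)
#'
#' Nonlinear least squares of the untransformed isotherm
#' \eqn{\Delta F = \Delta F_{max} K_b [L] / (1 + K_b [L])}, seeded from the
#' double-reciprocal estimates. Provided as a labelled alternative; the
#' double-reciprocal fit is the default route throughout the package.
#'
#' @inheritParams fit_double_reciprocal
#' @return A `binding_fit` with an additional element `method = "hyperbolic"`.
#' @export
fit_hyperbolic <- function(points, wavelength = 340, temperature = NA_real_) {
  start <- fit_double_reciprocal(points, wavelength, temperature)
  conc <- points$concentration; df <- points$delta_f
  nl <- stats::nls(df ~ fmax * kb * conc / (1 + kb * conc),
                   start = list(fmax = start$delta_f_max, kb = start$kb),
                   control = stats::nls.control(maxiter = 200, scaleOffset = 1))
  co <- stats::coef(nl)
  pred <- stats::fitted(nl)
  out <- start
  out$kb <- unname(co["kb"]); out$delta_f_max <- unname(co["fmax"])
  out$slope <- NA_real_; out$intercept <- NA_real_
  out$r_squared <- 1 - sum((df - pred)^2) / sum((df - mean(df))^2)
  out$method <- "hyperbolic"
  out
}

#' Van 't Hoff thermodynamic analysis
#'
#' Regresses \eqn{\ln K_b} on \eqn{1/T}:
#' \deqn{\ln K_b = -\Delta H/(RT) + \Delta S/R}
#' so that \eqn{\Delta H = -R \cdot slope} and \eqn{\Delta S = R \cdot
#' intercept}, then evaluates \eqn{\Delta G(T) = \Delta H - T\Delta S} at
#' every input temperature. The direct estimate \eqn{-RT\ln K_b} is kept per
#' temperature as a cross-check. The signs of the fitted enthalpy and
#' entropy classify the dominant binding forces (see [classify_forces()]).
#'
#' @param k_by_temperature Named numeric vector or list mapping temperature
#'   in K (names, coercible to numeric) to Kb in M^-1; at least 2 distinct
#'   temperatures, all Kb > 0.
#' @return Object of class `thermo_result` with `delta_h` (J/mol), `delta_s`
#'   (J/(mol K)), `delta_g_by_temperature` (named, J/mol),
#'   `delta_g_direct` (named, -RT ln Kb, J/mol), `r_squared`,
#'   `gas_constant`, `force_class`.
#' @export
#' @examples
#' vant_hoff(c("298.15" = 3.1e4, "308.15" = 3.3e4, "318.15" = 3.6e4))
vant_hoff <- function(k_by_temperature) {
  kb <- unlist(k_by_temperature)
  temps <- as.numeric(names(kb))
  if (anyNA(temps)) stop("temperatures must be supplied as numeric names (K)")
  if (length(unique(temps)) < 2L) stop("need at least 2 distinct temperatures")
  if (any(kb <= 0)) stop("all Kb must be positive")
  ord <- order(temps); temps <- temps[ord]; kb <- kb[ord]
  x <- 1 / temps
  y <- log(kb)
  R <- GAS_CONSTANT
  if (stats::sd(x) == 0) stop("need at least 2 distinct temperatures")
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  delta_h <- -R * slope
  delta_s <- R * intercept
  dg <- delta_h - temps * delta_s
  names(dg) <- format(temps, trim = TRUE)
  dg_direct <- -R * temps * y
  names(dg_direct) <- names(dg)
  r2 <- if (stats::sd(y) == 0) 1 else stats::cor(x, y)^2
  structure(list(
    delta_h = delta_h, delta_s = delta_s,
    delta_g_by_temperature = dg, delta_g_direct = dg_direct,
    r_squared = r2, gas_constant = R,
    temperatures = temps, kb = unname(kb),
    force_class = classify_forces(delta_h, delta_s)), class = "thermo_result")
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf("thermo_result: dH = %.1f kJ/mol, dS = %.1f J/(mol K), forces: %s\n",
              x$delta_h / 1000, x$delta_s, x$force_class))
  for (i in seq_along(x$temperatures))
    cat(sprintf("  T = %.2f K: Kb = %.3g M^-1, dG = %.1f kJ/mol (direct %.1f)\n",
                x$temperatures[i], x$kb[i],
                x$delta_g_by_temperature[i] / 1000, x$delta_g_direct[i] / 1000))
  invisible(x)
}

#' Classify dominant binding forces from thermodynamic signs
#'
#' Sign-based (Ross-Subramanian) classification: positive enthalpy and
#' entropy changes indicate hydrophobic association; both negative indicate
#' hydrogen bonding / van der Waals; near-zero enthalpy with positive
#' entropy indicates electrostatic interaction.
#'
#' @param delta_h Enthalpy change, J/mol.
#' @param delta_s Entropy change, J/(mol K).
#' @param h_threshold Magnitude below which the enthalpy counts as
#'   "near zero" for the electrostatic class, J/mol (default 1000).
#' @return One of `"hydrophobic"`, `"hydrogen-bond/van-der-Waals"`,
#'   `"electrostatic"`, `"indeterminate"`.
#' @export
classify_forces <- function(delta_h, delta_s, h_threshold = 1000) {
  if (!is.finite(delta_h) || !is.finite(delta_s)) stop("delta_h and delta_s must be finite")
  if (abs(delta_h) <= h_threshold && delta_s > 0) return("electrostatic")
  if (delta_h > 0 && delta_s > 0) return("hydrophobic")
  if (delta_h < 0 && delta_s < 0) return("hydrogen-bond/van-der-Waals")
  "indeterminate"
}

#' Free energy from a binding constant
#'
#' Standard relation \eqn{\Delta G = -RT \ln K_b}.
#'
#' @param kb Binding constant, M^-1 (> 0).
#' @param temperature Temperature, K (> 0).
#' @return Free energy change in J/mol.
#' @export
delta_g_direct <- function(kb, temperature) {
  if (any(kb <= 0) || any(temperature <= 0))
    stop("kb and temperature must be positive")
  -GAS_CONSTANT * temperature * log(kb)
}
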