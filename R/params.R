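#' Experimental conditions for chemical denaturation analysis
#'
#' Bundles the absolute temperature and the gas constant used to convert
#' free energies to equilibrium constants (\eqn{K = e^{-\Delta G / RT}}).
#' Chemical denaturation analyses in this package default to 25 degC
#' (298.15 K), the incubation temperature of a typical equilibrium
#' unfolding experiment.
#'
#' @param temperature Absolute temperature in kelvin (default 298.15).
#' @param celsius If `TRUE`, `temperature` is taken in degrees Celsius and
#'   converted to kelvin.
#' @return An object of class `unfold_conditions` with elements
#'   `temperature` (K) and `R` (1.987e-3 kcal mol^-1 K^-1).
#' @examples
#' conditions()                      # 298.15 K
#' conditions(25, celsius = TRUE)    # same
#' @export
conditions <- function(temperature = 298.15, celsius = FALSE) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            is.finite(temperature))
  if (isTRUE(celsius)) temperature <- temperature + 273.15
  if (temperature <= 0)
    stop("absolute temperature must be positive", call. = FALSE)
  structure(list(temperature = temperature, R = 1.987e-3),
            class = "unfold_conditions")
}

#' @export
print.unfold_conditions <- function(x, ...) {
  cat(sprintf("Conditions: T = %.2f K (%.2f degC), R = %.3e kcal/(mol K)\n",
              x$temperature, x$temperature - 273.15, x$R))
  invisible(x)
}

## RT in kcal/mol for a conditions object
.rt <- function(cond) cond$R * cond$temperature

.check_num <- function(x, name, n = 1L) {
  if (!is.numeric(x) || length(x) != n || any(!is.finite(x)))
    stop(sprintf("'%s' must be a finite numeric of length %d", name, n),
         call. = FALSE)
  invisible(x)
}

#' Two-state unfolding parameters
#'
#' Parameter set for the two-state linear-extrapolation model
#' N \eqn{\rightleftharpoons} U: the unfolding free energy in water
#' \eqn{\Delta G^{H_2O}_{NU}} (kcal/mol), its denaturant dependence
#' \eqn{m_{NU}} (kcal mol^-1 M^-1), and linear native and unfolded
#' baselines \eqn{S_N = a_1 + b_1 c}, \eqn{S_U = c_1 + p_1 c}.
#'
#' @param dG0 Unfolding free energy in water, kcal/mol.
#' @param m Denaturant dependence (m-value), kcal mol^-1 M^-1; must be > 0
#'   for an unfolding transition.
#' @param a1,b1 Intercept and slope of the native baseline.
#' @param c1,p1 Intercept and slope of the unfolded baseline.
#' @return An object of class `c("two_state_params", "unfold_params")`.
#' @seealso [three_state_params()], [thermal_params()], [midpoint()]
#' @examples
#' p <- two_state_params(dG0 = 4.32, m = 0.8)
#' midpoint(p$dG0, p$m)
#' @export
two_state_params <- function(dG0, m, a1 = 1, b1 = 0, c1 = 0, p1 = 0) {
  .check_num(dG0, "dG0"); .check_num(m, "m")
  for (nm in c("a1", "b1", "c1", "p1")) .check_num(get(nm), nm)
  if (m <= 0) stop("m must be > 0 for an unfolding transition", call. = FALSE)
  structure(list(dG0 = dG0, m = m, a1 = a1, b1 = b1, c1 = c1, p1 = p1),
            class = c("two_state_params", "unfold_params"))
}

#' Three-state unfolding parameters
#'
#' Parameter set for the three-state linear-extrapolation model
#' N \eqn{\rightleftharpoons} I \eqn{\rightleftharpoons} U, with two free
#' energies measured from the native state (\eqn{\Delta G^{H_2O}_{NI}},
#' \eqn{\Delta G^{H_2O}_{NU}}), their m-values, and three linear baselines:
#' native \eqn{S_N = a_1 + b_1 c}, intermediate \eqn{S_I = c_1 + p_1 c},
#' unfolded \eqn{S_U = e_1 + g_1 c}.
#'
#' The stability ordering \eqn{\Delta G^{H_2O}_{NU} \ge \Delta G^{H_2O}_{NI}}
#' is enforced: otherwise the intermediate is never the dominant species
#' between the two transitions.  Derived quantities are available through
#' [derived_params()]: \eqn{\Delta G^{H_2O}_{IU} = \Delta G_{NU} - \Delta
#' G_{NI}}, \eqn{m_{IU} = m_{NU} - m_{NI}}, and the two midpoints.
#'
#' @param dG_NI0,m_NI Free energy (kcal/mol) and m-value (kcal mol^-1 M^-1)
#'   of the N to I transition in water.
#' @param dG_NU0,m_NU Same for the full N to U transition.
#' @param a1,b1 Native baseline intercept/slope.
#' @param c1,p1 Intermediate baseline intercept/slope.
#' @param e1,g1 Unfolded baseline intercept/slope.
#' @return An object of class `c("three_state_params", "unfold_params")`.
#' @examples
#' # GdnHCl unfolding of a three-state protein (fluorescence probe)
#' p <- three_state_params(dG_NI0 = 1.4, m_NI = 0.8, dG_NU0 = 4.7, m_NU = 1.7)
#' derived_params(p)
#' @export
three_state_params <- function(dG_NI0, m_NI, dG_NU0, m_NU,
                               a1 = 1, b1 = 0, c1 = 0.5, p1 = 0,
                               e1 = 0, g1 = 0) {
  for (nm in c("dG_NI0", "m_NI", "dG_NU0", "m_NU",
               "a1", "b1", "c1", "p1", "e1", "g1"))
    .check_num(get(nm), nm)
  if (m_NI <= 0 || m_NU <= 0)
    stop("m_NI and m_NU must be > 0", call. = FALSE)
  if (dG_NU0 < dG_NI0)
    stop("dG_NU0 must be >= dG_NI0 (N -> I -> U stability ordering)",
         call. = FALSE)
  structure(list(dG_NI0 = dG_NI0, m_NI = m_NI,
                 dG_NU0 = dG_NU0, m_NU = m_NU,
                 a1 = a1, b1 = b1, c1 = c1, p1 = p1, e1 = e1, g1 = g1),
            class = c("three_state_params", "unfold_params"))
}

#' Thermal (van't Hoff) two-state parameters
#'
#' Parameter set for a two-state thermal melt: midpoint temperature `Tm`
#' (kelvin) and van't Hoff enthalpy `dH_vH` (kcal/mol) at `Tm`, with
#' baselines linear in temperature.  The heat-capacity change is neglected
#' (\eqn{\Delta C_p = 0}), so
#' \eqn{\Delta G(T) = \Delta H_{vH} (1 - T/T_m)}.
#'
#' @param Tm Midpoint temperature.  Kelvin by default; Celsius if
#'   `celsius = TRUE`.
#' @param dH_vH van't Hoff enthalpy at `Tm`, kcal/mol; must be > 0.
#' @param a1,b1 Native baseline intercept/slope (vs T in kelvin).
#' @param c1,p1 Unfolded baseline intercept/slope (vs T in kelvin).
#' @param celsius Interpret `Tm` in degrees Celsius.
#' @return An object of class `c("thermal_params", "unfold_params")`.
#' @examples
#' thermal_params(Tm = 43.3, dH_vH = 70, celsius = TRUE)
#' @export
thermal_params <- function(Tm, dH_vH, a1 = 1, b1 = 0, c1 = 0, p1 = 0,
                           celsius = FALSE) {
  for (nm in c("Tm", "dH_vH", "a1", "b1", "c1", "p1")) .check_num(get(nm), nm)
  if (isTRUE(celsius)) Tm <- Tm + 273.15
  if (Tm <= 0) stop("Tm must be a positive absolute temperature",
                    call. = FALSE)
  if (dH_vH <= 0) stop("dH_vH must be > 0", call. = FALSE)
  structure(list(Tm = Tm, dH_vH = dH_vH, a1 = a1, b1 = b1, c1 = c1, p1 = p1),
            class = c("thermal_params", "unfold_params"))
}

#' Derived thermodynamic quantities of a parameter set
#'
#' Computes the quantities implied by a parameter set through the
#' linear-extrapolation identities: transition midpoints
#' (\eqn{D_m = \Delta G^{H_2O}/m}), and for the three-state model the
#' intermediate-to-unfolded free energy
#' \eqn{\Delta G^{H_2O}_{IU} = \Delta G^{H_2O}_{NU} - \Delta G^{H_2O}_{NI}}
#' and m-value \eqn{m_{IU} = m_{NU} - m_{NI}}.
#'
#' @param p An `unfold_params` object.
#' @return A named numeric vector of derived quantities.
#' @examples
#' derived_params(three_state_params(1.5, 0.9, 4.3, 1.4))
#' @export
derived_params <- function(p) {
  UseMethod("derived_params")
}

#' @export
derived_params.two_state_params <- function(p) {
  c(Dm = midpoint(p$dG0, p$m))
}

#' @export
derived_params.three_state_params <- function(p) {
  c(Dm_NI  = midpoint(p$dG_NI0, p$m_NI),
    Dm_NU  = midpoint(p$dG_NU0, p$m_NU),
    dG_IU0 = p$dG_NU0 - p$dG_NI0,
    m_IU   = p$m_NU - p$m_NI)
}

#' @export
derived_params.thermal_params <- function(p) {
  c(Tm_C = p$Tm - 273.15)
}

#' @export
print.unfold_params <- function(x, ...) {
  cat(sprintf("<%s>\n", class(x)[1L]))
  v <- unlist(x)
  print(round(v, 4))
  d <- derived_params(x)
  cat("derived:", paste(sprintf("%s = %.4g", names(d), d), collapse = ", "),
      "\n")
  invisible(x)
}
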