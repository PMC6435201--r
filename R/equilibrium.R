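## Analytic layer: Donnan and Double Donnan predictions, chord-conductance
## and pump voltages, energy accounting, and the osmolarity-charge
## asymmetry theory of passive cation equilibria.

#' Donnan product residual
#'
#' `Na_i * Cl_i / (Na_o * Cl_o) - 1`: zero at exact Donnan equilibrium.
#'
#' @inheritParams validate_state
#' @return Dimensionless residual.
#' @examples
#' donnan_residual(cell_state(Na_i = 231.8, Cl_i = 96.8),
#'                 bath_state(Na_o = 150, Cl_o = 150))
#' @export
donnan_residual <- function(state, bath) {
  if (min(state$Na_i, state$Cl_i, bath$Na_o, bath$Cl_o) <= 0)
    stop("Donnan residual needs positive Na+ and Cl- concentrations")
  state$Na_i * state$Cl_i / (bath$Na_o * bath$Cl_o) - 1
}

#' Donnan-limited intracellular Cl- at fixed internal Na+
#'
#' Solves `Na_i * Cl_i = Na_o * Cl_o` for `Cl_i`.  With instant water the
#' internal Na+ of a swelling Na+/Cl- Donnan system is pinned to a constant
#' (dilution exactly cancels influx), so this gives the limiting Cl-.
#'
#' @param Na_o,Cl_o bath concentrations, mM.
#' @param Na_i internal Na+ held fixed, mM.
#' @return Limiting `Cl_i`, mM.
#' @export
donnan_limit_cl <- function(Na_o, Cl_o, Na_i) {
  stopifnot(Na_o > 0, Cl_o > 0, Na_i > 0)
  Na_o * Cl_o / Na_i
}

#' Closed-form Double Donnan equilibrium with monovalent internal anion
#'
#' For a cell with permeant Na+ and Cl-, impermeant monovalent internal
#' anion (`z = -1`), no internal neutral osmolyte and an external
#' impermeant neutral osmolyte, the equilibrium satisfies the Donnan
#' product, internal electroneutrality `Na_i = Cl_i + An_i` and osmotic
#' balance.  The solution is `Na_i = (Na_o + Cl_o + osm_o) / 2` and
#' `Cl_i = Na_o * Cl_o / Na_i`.
#'
#' @param Na_o,Cl_o,osm_o bath composition, mM.
#' @return Named vector `c(Na_i, Cl_i, An_i)`, mM.
#' @examples
#' double_donnan_cl(145, 145, 10)  # Cl_i 140.17 mM
#' @export
double_donnan_cl <- function(Na_o, Cl_o, osm_o) {
  stopifnot(Na_o > 0, Cl_o > 0, osm_o >= 0)
  Na_i <- (Na_o + Cl_o + osm_o) / 2
  Cl_i <- Na_o * Cl_o / Na_i
  c(Na_i = Na_i, Cl_i = Cl_i, An_i = Na_i - Cl_i)
}

#' Osmolarity-charge asymmetry coefficient and its equilibrium predictions
#'
#' The asymmetry coefficient
#' `ka = (-z*An_i + Cl_i) / (An_i + Cl_i + osm_i - osm_o)`
#' is the ratio of all intracellular negative charge to all non-cation
#' intracellular osmolytes net of the external neutral osmolyte.  In a
#' pump-free cation-permeable cell (Cl- impermeant) it fully determines the
#' passive equilibrium: the cation ratio is `[cat]_i/[cat]_o = 2ka/(ka+1)`
#' and the resting potential is `Em = -(RT/F) * ln(2ka/(ka+1))`, negative
#' when the cell holds excess cations (`ka > 1`).
#'
#' @inheritParams validate_state
#' @return List of class `asymmetry_report`: `ka`, `cation_ratio`,
#'   `Em` (V), `d_osm = osm_i - osm_o` (mM).
#' @examples
#' # trivalent impermeant anion, no neutral osmolytes: ka = 2.5, Em ~ -9.5 mV
#' s <- cell_state(Na_i = 207.14, K_i = 7.14, Cl_i = 21.43, An_i = 64.29)
#' b <- bath_state(Na_o = 145, K_o = 5, Cl_o = 150)
#' asymmetry_coefficient(s, b, membrane_params(z = -3))
#' @export
asymmetry_coefficient <- function(state, bath, params) {
  denom <- state$An_i + state$Cl_i + state$osm_i - bath$osm_o
  if (denom <= 0)
    stop("asymmetry coefficient undefined: non-positive osmolyte denominator")
  ka <- (-params$z * state$An_i + state$Cl_i) / denom
  ratio <- 2 * ka / (ka + 1)
  k <- physical_constants()
  Em <- -(k$R * params$T / k$F) * log(ratio)
  structure(list(ka = ka, cation_ratio = ratio, Em = Em,
                 d_osm = state$osm_i - bath$osm_o),
            class = "asymmetry_report")
}

#' @export
print.asymmetry_report <- function(x, ...) {
  cat(sprintf(
    "<asymmetry_report> ka %.4g  [cat]i/[cat]o %.4g  Em %.4g mV  d_osm %.4g mM\n",
    x$ka, x$cation_ratio, 1e3 * x$Em, x$d_osm))
  invisible(x)
}

#' Input resistance of the modelled cell
#'
#' `1 / ((gNa + gK + gCl) * e)` in ohms; 2e10 ions/(s V) of total
#' conductance is 3.2 nS, i.e. 312.5 Mohm.
#'
#' @param params a [membrane_params()].
#' @return Input resistance, ohm.
#' @export
input_resistance <- function(params) {
  g <- params$gNa + params$gK + params$gCl
  if (g <= 0) stop("total conductance must be > 0")
  1 / (g * physical_constants()$e)
}

#' Chord-conductance membrane potential with a pump-current term
#'
#' `(gK*E_K + gNa*E_Na) / (gK + gNa) - pump_current * R_input`.  The pump
#' current is signed outward-positive (`(x - y) * Ap * e` for an x:y
#' pump), so net outward pumping contributes a negative voltage.  This is
#' the analytic cross-check of the simulated steady-state potential in the
#' cation-only system.
#'
#' @param gNa,gK conductances, ions s-1 V-1.
#' @param E_Na,E_K Nernst potentials, V.
#' @param pump_current pump current, A, outward positive (default 0).
#' @param R_input input resistance, ohm.
#' @return Predicted membrane potential, V.
#' @export
chord_em <- function(gNa, gK, E_Na, E_K, pump_current = 0, R_input = 0) {
  if (gNa + gK <= 0) stop("gNa + gK must be > 0")
  (gK * E_K + gNa * E_Na) / (gK + gNa) - pump_current * R_input
}

#' Steady-state energy expenditure
#'
#' The pump activity at a converged steady state, in cycles (ATP molecules)
#' per second.
#'
#' @param report a `steady_state_report` from [run_to_steady_state()].
#' @return ATP molecules hydrolysed per second.
#' @export
energy_rate <- function(report) {
  if (!inherits(report, "steady_state_report"))
    stop("energy_rate expects a steady_state_report")
  if (!report$converged)
    stop("energy_rate is only defined for a converged steady state")
  report$atp_per_sec
}

#' Thermodynamic Cl- limits of the cation-Cl- cotransporters
#'
#' Setting the NKCC log driving force to zero and solving
#' `Na_o*K_o*Cl_o^2 = Na_i*K_i*Cl_i^2` gives the largest intracellular Cl-
#' the Na+,K+,2Cl- cotransporter can produce; setting the KCC driving force
#' to zero gives the smallest Cl- the K+,Cl- cotransporter can reach,
#' `K_o*Cl_o / K_i`.
#'
#' @param bath a [bath_state()].
#' @param Na_i,K_i intracellular cation concentrations, mM.
#' @return Limiting `Cl_i`, mM.
#' @examples
#' b <- bath_state(Na_o = 145, K_o = 5, Cl_o = 150)
#' nkcc_limit_cl(b, Na_i = 17.9, K_i = 132.1)  # 83.06 mM
#' kcc_limit_cl(b, K_i = 132.1)                # 5.68 mM
#' @export
nkcc_limit_cl <- function(bath, Na_i, K_i) {
  stopifnot(Na_i > 0, K_i > 0, bath$Na_o > 0, bath$K_o > 0, bath$Cl_o > 0)
  sqrt(bath$Na_o * bath$K_o * bath$Cl_o^2 / (Na_i * K_i))
}

#' @rdname nkcc_limit_cl
#' @export
kcc_limit_cl <- function(bath, K_i) {
  stopifnot(K_i > 0, bath$K_o > 0, bath$Cl_o > 0)
  bath$K_o * bath$Cl_o / K_i
}
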