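#' Physical constants used throughout the simulator
#'
#' Gas constant `R` (J mol-1 K-1), Faraday constant `F` (C mol-1), Avogadro
#' number `L` (mol-1) and the elementary charge `e` (C).  At the default
#' simulation temperature of 309.85 K (36.7 degrees C) the Nernst slope
#' `RT/F * ln(10)` is 61.48 mV per tenfold concentration ratio, which is the
#' decade potential used by all worked examples in the package.
#'
#' @return A named list with components `R`, `F`, `L`, `e`.
#' @examples
#' k <- physical_constants()
#' k$e * k$L / k$F  # ~ 1
#' @export
physical_constants <- function() {
  list(R = 8.314, F = 96485, L = 6.02e23, e = 1.6e-19)
}

## default cell geometry: effective water volume of a 10 um cube with 25%
## occupied by organelles; fixed surface area => fixed capacitance.
DEFAULT_VOLUME <- 7.5e-13    # L
DEFAULT_CAPACITANCE <- 1.2e-11  # F
DEFAULT_TEMPERATURE <- 309.85   # K

#' Intracellular state of the modelled cell
#'
#' Concentrations are in mM, membrane potential in volts, effective water
#' volume in litres.  `Em` is a genuine state variable of the
#' charge-difference method: it is only ever incremented by `dQ/c`, never
#' recomputed from concentrations.  `atp_total` accumulates pump cycles
#' (equal to ATP molecules hydrolysed).
#'
#' @param Na_i,K_i,Cl_i intracellular Na+, K+, Cl- concentrations, mM.
#' @param An_i intracellular impermeant-anion concentration, mM (its mean
#'   valence lives in [membrane_params()]).
#' @param osm_i intracellular neutral impermeant osmolyte, mM.
#' @param Em membrane potential, V.
#' @param vol effective water volume, L.
#' @param t simulated time, s.
#' @param atp_total cumulative pump cycles (dimensionless).
#' @return An object of class `cell_state`.
#' @export
cell_state <- function(Na_i, K_i = 0, Cl_i = 0, An_i = 0, osm_i = 0,
                       Em = 0, vol = DEFAULT_VOLUME, t = 0, atp_total = 0) {
  s <- list(Na_i = Na_i, K_i = K_i, Cl_i = Cl_i, An_i = An_i, osm_i = osm_i,
            Em = Em, vol = vol, t = t, atp_total = atp_total)
  stopifnot(vapply(s, function(x) is.numeric(x) && length(x) == 1, TRUE))
  structure(s, class = "cell_state")
}

#' Extracellular (bath) state
#'
#' Bath concentrations are held fixed within a time step; buildups (see
#' [buildup_schedule()]) modify them between flux evaluations, as for an
#' isolated cell in a perfused dish.
#'
#' @param Na_o,K_o,Cl_o extracellular concentrations, mM.
#' @param osm_o external impermeant neutral osmolyte, mM.
#' @return An object of class `bath_state`.
#' @export
bath_state <- function(Na_o, K_o = 0, Cl_o = 0, osm_o = 0) {
  b <- list(Na_o = Na_o, K_o = K_o, Cl_o = Cl_o, osm_o = osm_o)
  stopifnot(vapply(b, function(x) is.numeric(x) && length(x) == 1, TRUE))
  structure(b, class = "bath_state")
}

#' Membrane and transporter parameters
#'
#' @param gNa,gK,gCl linear conductances, ions s-1 V-1.  The package uses the
#'   ion-count convention throughout; 2e10 ions/(s V) equals 3.2 nS and an
#'   input resistance of 312.5 Mohm (see [input_resistance()]).
#' @param c membrane capacitance, F (fixed; volume changes are assumed not to
#'   change the surface area).
#' @param T absolute temperature, K.
#' @param Rp Na+/K+-ATPase rate, cycles s-1: the theoretical maximum of the
#'   activity as intracellular Na+ grows large.
#' @param hNa Na+ concentration of half-occupation of the pump Na site, mM.
#'   The activity is `Rp / (1 + hNa/Na_i)^3`, so `Ap = Rp/8` at `Na_i = hNa`.
#' @param x,y Na+ and K+ ions moved per pump cycle (non-negative integers;
#'   3:2 physiological, 3:3 electroneutral, 3:0 pure Na+ pump, ...).
#' @param Rnkc,Rkc Na+,K+,2Cl- and K+,Cl- cotransporter rates, cycles s-1.
#' @param z mean valence of the impermeant intracellular anion (negative).
#' @param tau time constant of osmotic volume relaxation, s.  `tau <= st`
#'   means effectively instant water; `tau > 1e8` disables water flux
#'   entirely (pure Donnan setting).
#' @return An object of class `membrane_params`.
#' @export
membrane_params <- function(gNa = 0, gK = 0, gCl = 0,
                            c = DEFAULT_CAPACITANCE, T = DEFAULT_TEMPERATURE,
                            Rp = 0, hNa = 8, x = 3, y = 2,
                            Rnkc = 0, Rkc = 0, z = -1, tau = 1) {
  p <- list(gNa = gNa, gK = gK, gCl = gCl, c = c, T = T,
            Rp = Rp, hNa = hNa, x = x, y = y,
            Rnkc = Rnkc, Rkc = Rkc, z = z, tau = tau)
  stopifnot(vapply(p, function(v) is.numeric(v) && length(v) == 1, TRUE))
  if (min(gNa, gK, gCl, Rp, Rnkc, Rkc) < 0)
    stop("conductances and transporter rates must be >= 0")
  if (hNa <= 0) stop("hNa must be > 0")
  if (c <= 0) stop("capacitance must be > 0")
  if (x < 0 || y < 0 || x != round(x) || y != round(y))
    stop("pump stoichiometry x, y must be non-negative integers")
  if (z >= 0) stop("mean impermeant-anion valence z must be negative")
  if (tau < 0) stop("tau must be >= 0")
  structure(p, class = "membrane_params")
}

#' Time-windowed osmolyte buildup schedule
#'
#' Buildups are exogenous additions, distinguished from transmembrane fluxes:
#' they change concentrations at a fixed rate inside a time window but never
#' contribute to the membrane charge balance.  Four kinds are supported:
#' external neutral osmolyte (`bOso`), external NaCl (`bNaCl`, moving Na+ and
#' Cl- together), internal neutral osmolyte (`bOsi`) and internal impermeant
#' anion (`bAn`).  An anion buildup is accompanied, for electroneutrality, by
#' internal Na+ added at `-z` times the anion rate.
#'
#' @param bOso,bNaCl,bOsi,bAn rates, mM s-1 (each >= 0).
#' @param t_on,t_off common window, s; a rate applies while
#'   `t_on <= t < t_off`.  Use per-kind windows by combining schedules in a
#'   scenario's event list.
#' @return An object of class `buildup_schedule`.
#' @export
buildup_schedule <- function(bOso = 0, bNaCl = 0, bOsi = 0, bAn = 0,
                             t_on = 0, t_off = Inf) {
  if (min(bOso, bNaCl, bOsi, bAn) < 0) stop("buildup rates must be >= 0")
  if (t_off < t_on) stop("t_off must be >= t_on")
  structure(list(bOso = bOso, bNaCl = bNaCl, bOsi = bOsi, bAn = bAn,
                 t_on = t_on, t_off = t_off),
            class = "buildup_schedule")
}

#' Integration settings
#'
#' @param st time step, s.  The discrete step is part of the method's
#'   identity; 1e-4 s resolves membrane-charging transients, 1e-3 s is enough
#'   for slow concentration dynamics.
#' @param t_end simulated duration, s (for fixed-horizon runs).
#' @param record_every record a snapshot every this many steps (1 = every
#'   step; larger values thin long trajectories).
#' @param steady_tol steady-state tolerance: every per-ion net flux,
#'   expressed as a concentration rate, must stay below this value (mM s-1).
#' @param max_steady_time give up on convergence after this much simulated
#'   time, s.
#' @param seed integer; the core is deterministic, the slot is reserved for
#'   callers that randomise scenario parameters.
#' @return An object of class `sim_settings`.
#' @export
sim_settings <- function(st = 1e-3, t_end = 60, record_every = 100,
                         steady_tol = 1e-9, max_steady_time = 600,
                         seed = 1L) {
  if (st <= 0) stop("st must be > 0")
  if (steady_tol <= 0) stop("steady_tol must be > 0")
  structure(list(st = st, t_end = t_end, record_every = as.integer(record_every),
                 steady_tol = steady_tol, max_steady_time = max_steady_time,
                 seed = as.integer(seed)),
            class = "sim_settings")
}

#' Check state, bath and parameter invariants
#'
#' Returns a character vector of violations (empty when everything holds).
#' Besides sign and positivity checks it reports, as attributes, the
#' macroscopic electroneutrality residual `(Na_i + K_i) - (-z*An_i + Cl_i)`
#' (mM) and its equivalent charge in coulombs, which for a consistent state
#' equals `Em * c` up to the tiny capacitive charge.
#'
#' @param state a [cell_state()].
#' @param bath a [bath_state()].
#' @param params a [membrane_params()].
#' @return character vector of violations, with attributes
#'   `electroneutrality_mM`, `electroneutrality_C` and `capacitive_C`.
#' @examples
#' s <- cell_state(Na_i = 150, Cl_i = 15, An_i = 135)
#' b <- bath_state(Na_o = 150, Cl_o = 150)
#' validate_state(s, b, membrane_params(z = -1))
#' @export
validate_state <- function(state, bath, params) {
  v <- character()
  conc <- c(state$Na_i, state$K_i, state$Cl_i, state$An_i, state$osm_i)
  if (any(conc < 0)) v <- c(v, "negative intracellular concentration")
  if (state$vol <= 0) v <- c(v, "non-positive cell volume")
  if (any(c(bath$Na_o, bath$K_o, bath$Cl_o, bath$osm_o) < 0))
    v <- c(v, "negative bath concentration")
  k <- physical_constants()
  resid_mM <- (state$Na_i + state$K_i) - (-params$z * state$An_i + state$Cl_i)
  resid_C <- resid_mM * 1e-3 * state$vol * k$L * k$e
  cap_C <- state$Em * params$c
  attr(v, "electroneutrality_mM") <- resid_mM
  attr(v, "electroneutrality_C") <- resid_C
  attr(v, "capacitive_C") <- cap_C
  v
}

#' @export
print.cell_state <- function(x, ...) {
  cat(sprintf(
    "<cell_state t = %g s>\n  Na_i %.4g  K_i %.4g  Cl_i %.4g  An_i %.4g  osm_i %.4g mM\n  Em %.4g mV   vol %.4g L   ATP used %.4g\n",
    x$t, x$Na_i, x$K_i, x$Cl_i, x$An_i, x$osm_i,
    1e3 * x$Em, x$vol, x$atp_total))
  invisible(x)
}

#' @export
print.bath_state <- function(x, ...) {
  cat(sprintf("<bath_state> Na_o %.4g  K_o %.4g  Cl_o %.4g  osm_o %.4g mM\n",
              x$Na_o, x$K_o, x$Cl_o, x$osm_o))
  invisible(x)
}

## internal: pack containers into the numeric vectors the C++ stepper takes.
## concentrations cross this boundary in mol/L so that the amount-to-
## concentration conversion dX/(vol*L) needs no hidden factor of 1000.
pack_state <- function(state) {
  c(1e-3 * c(state$Na_i, state$K_i, state$Cl_i, state$An_i, state$osm_i),
    state$Em, state$vol, state$t, state$atp_total)
}

pack_bath <- function(bath) {
  1e-3 * c(bath$Na_o, bath$K_o, bath$Cl_o, bath$osm_o)
}

pack_params <- function(params) {
  k <- physical_constants()
  c(params$gNa, params$gK, params$gCl, params$c, params$T,
    params$Rp, params$hNa, params$x, params$y,
    params$Rnkc, params$Rkc, params$z, params$tau,
    k$R, k$F, k$L, k$e)
}

pack_buildups <- function(buildups) {
  if (is.null(buildups)) buildups <- buildup_schedule()
  cbind(rate = 1e-3 * c(buildups$bOso, buildups$bNaCl, buildups$bOsi, buildups$bAn),
        t_on = buildups$t_on, t_off = buildups$t_off)
}

unpack_state <- function(v) {
  cell_state(Na_i = v[1] * 1e3, K_i = v[2] * 1e3, Cl_i = v[3] * 1e3,
             An_i = v[4] * 1e3, osm_i = v[5] * 1e3,
             Em = v[6], vol = v[7], t = v[8], atp_total = v[9])
}

unpack_bath <- function(v) {
  bath_state(Na_o = v[1] * 1e3, K_o = v[2] * 1e3, Cl_o = v[3] * 1e3,
             osm_o = v[4] * 1e3)
}
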