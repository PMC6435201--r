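## Calculation sets 2 and 3 of the charge-difference cycle, plus the
## time-course and steady-state drivers.  cd_step() is a pure-R reference
## composition of one cycle; cd_run() and run_to_steady_state() call the
## compiled stepper, which performs the identical arithmetic.

#' Accumulate ion amounts, buildups and charge over one step
#'
#' Converts the per-second fluxes into amount changes `dNa`, `dK`, `dCl`
#' (ions per step), applies any active buildups, and updates intracellular
#' concentrations by `dX / (vol * L)`.  An internal-anion buildup is
#' accompanied by Na+ at `-z` times its rate for electroneutrality.  The net
#' charge change is `dQ = (dNa + dK - dCl) * e`; buildups never contribute
#' to it.
#'
#' @inheritParams validate_state
#' @param fluxes a `flux_set` from [compute_fluxes()].
#' @param buildups a [buildup_schedule()] or `NULL`.
#' @param st time step, s.
#' @return List with updated `state`, `bath` and a `diagnostics` list
#'   (`dNa`, `dK`, `dCl` in ions; `dQ` in coulombs).
#' @export
accumulate <- function(state, bath, fluxes, buildups = NULL, st,
                       params = membrane_params()) {
  stopifnot(st > 0)
  k <- physical_constants()
  dNa <- (fluxes$NaFc + fluxes$NaFp + fluxes$NaFnkc) * st
  dK <- (fluxes$KFc + fluxes$KFp + fluxes$KFnkc + fluxes$KFkc) * st
  dCl <- (fluxes$ClFc + fluxes$ClFnkc + fluxes$ClFkc) * st

  b <- c(bOso = 0, bNaCl = 0, bOsi = 0, bAn = 0)
  if (!is.null(buildups) &&
      state$t >= buildups$t_on && state$t < buildups$t_off) {
    b <- c(bOso = buildups$bOso, bNaCl = buildups$bNaCl,
           bOsi = buildups$bOsi, bAn = buildups$bAn)
  }

  bath$osm_o <- bath$osm_o + b[["bOso"]] * st
  bath$Na_o <- bath$Na_o + b[["bNaCl"]] * st
  bath$Cl_o <- bath$Cl_o + b[["bNaCl"]] * st

  ## dX/(vol*L) is mol/L; interface concentrations are mM
  volL <- state$vol * k$L
  state$osm_i <- state$osm_i + b[["bOsi"]] * st
  state$An_i <- state$An_i + b[["bAn"]] * st
  state$Na_i <- state$Na_i + 1e3 * dNa / volL + b[["bAn"]] * st * (-params$z)
  state$K_i <- state$K_i + 1e3 * dK / volL
  state$Cl_i <- state$Cl_i + 1e3 * dCl / volL

  dQ <- (dNa + dK - dCl) * k$e
  state$atp_total <- state$atp_total + fluxes$Ap * st
  list(state = state, bath = bath,
       diagnostics = list(dNa = dNa, dK = dK, dCl = dCl, dQ = dQ))
}

#' Increment membrane potential from transferred charge
#'
#' `Em_f = Em_e + dQ / c`.  This is the whole voltage model: no
#' electroneutrality closure, no Goldman equation.
#'
#' @param Em membrane potential before the update, V.
#' @param dQ net charge moved into the cell during the step, C.
#' @param c membrane capacitance, F.
#' @return Updated membrane potential, V.
#' @export
update_em <- function(Em, dQ, c) {
  if (c <= 0) stop("capacitance must be > 0")
  Em + dQ / c
}

#' Osmotic volume relaxation
#'
#' Computes the instant-water correction factor
#' `osV = osm_internal / osm_external`, scales it by the finite water
#' permeability (`chV = 1 - (1 - osV) * VoR * st`, with `VoR = 1/tau`
#' clamped to `1/st` when `tau < st` and to 0 when `tau > 1e8` s), then
#' multiplies the volume and divides all five intracellular concentrations
#' by `chV`.  For a single osmotic disturbance at otherwise constant
#' composition this recursion is the exact Euler discretisation of
#' exponential volume relaxation with time constant `tau`.
#'
#' @inheritParams validate_state
#' @param st time step, s.
#' @return List with updated `state` and a `diagnostics` list
#'   (`osV`, `chV`, `VoR`).
#' @export
relax_volume <- function(state, bath, params, st) {
  osV <- (state$Na_i + state$K_i + state$Cl_i + state$An_i + state$osm_i) /
    (bath$Na_o + bath$K_o + bath$Cl_o + bath$osm_o)
  VoR <- if (params$tau > 1e8) 0 else if (params$tau < st) 1 / st else 1 / params$tau
  chV <- 1 - (1 - osV) * VoR * st
  if (chV <= 0)
    stop("osmotic collapse: chV <= 0 (time step too large for tau)")
  state$vol <- state$vol * chV
  for (f in c("Na_i", "K_i", "Cl_i", "An_i", "osm_i"))
    state[[f]] <- state[[f]] / chV
  list(state = state, diagnostics = list(osV = osV, chV = chV, VoR = VoR))
}

#' One full charge-difference cycle (reference implementation)
#'
#' Composes the three calculation sets exactly once, in the fixed order
#' fluxes -> accumulation -> membrane potential -> volume.  The compiled
#' stepper used by [cd_run()] performs the same arithmetic; this R version
#' exists for inspection and testing of single steps.
#'
#' @inheritParams accumulate
#' @return List with updated `state`, `bath`, the `flux_set` used, and
#'   step `diagnostics`.
#' @export
cd_step <- function(state, bath, params, buildups = NULL, st) {
  f <- compute_fluxes(state, bath, params)
  acc <- accumulate(state, bath, f, buildups, st, params)
  st2 <- acc$state
  st2$Em <- update_em(st2$Em, acc$diagnostics$dQ, params$c)
  rv <- relax_volume(st2, acc$bath, params, st)
  st3 <- rv$state
  st3$t <- state$t + st
  list(state = st3, bath = acc$bath, fluxes = f,
       diagnostics = c(acc$diagnostics, rv$diagnostics))
}

traj_to_df <- function(m) {
  d <- as.data.frame(m)
  names(d) <- c("t", "Na_i", "K_i", "Cl_i", "An_i", "osm_i", "Em", "vol",
                "Ap", "Ankc", "Akc", "atp_total", "q_cum",
                "Na_o", "K_o", "Cl_o", "osm_o")
  conc <- c("Na_i", "K_i", "Cl_i", "An_i", "osm_i", "Na_o", "K_o", "Cl_o", "osm_o")
  d[conc] <- lapply(d[conc], function(x) x * 1e3)  # mol/L -> mM
  d
}

#' Run the charge-difference simulation for a fixed horizon
#'
#' Fixed-step integration from `state$t` to `state$t + t_end`, recording
#' thinned snapshots.  Fully deterministic.
#'
#' @inheritParams validate_state
#' @param buildups optional [buildup_schedule()].
#' @param settings a [sim_settings()]; `t_end`, `st` and `record_every` are
#'   used here.
#' @return A `cd_trajectory`: a data frame of snapshots (concentrations mM,
#'   `Em` V, `vol` L, activities cycles s-1, cumulative charge `q_cum` C)
#'   with the final `cell_state` and `bath_state` attached as attributes
#'   `final_state` and `final_bath`.
#' @examples
#' s <- cell_state(Na_i = 150, Cl_i = 15, An_i = 135)
#' b <- bath_state(Na_o = 150, Cl_o = 150)
#' p <- membrane_params(gNa = 1e10, gCl = 1e10, z = -1, tau = 1e9)
#' tr <- cd_run(s, b, p, settings = sim_settings(st = 1e-3, t_end = 5))
#' tail(tr, 1)
#' @export
cd_run <- function(state, bath, params, buildups = NULL, settings) {
  res <- .cd_integrate(pack_state(state), pack_bath(bath),
                       pack_params(params), pack_buildups(buildups),
                       st = settings$st, t_end = settings$t_end,
                       record_every = max(1L, settings$record_every),
                       steady_mode = FALSE, steady_tol = settings$steady_tol,
                       check_every = 1000L, steady_need = 10L,
                       vol_max_ratio = Inf)
  out <- traj_to_df(res$traj)
  attr(out, "final_state") <- unpack_state(res$state)
  attr(out, "final_bath") <- unpack_bath(res$bath)
  attr(out, "q_cum") <- res$q_cum
  class(out) <- c("cd_trajectory", class(out))
  out
}

#' Integrate until every per-ion net flux vanishes
#'
#' Runs with a fixed step until the absolute net flux of each of Na+, K+
#' and Cl-, expressed as a concentration rate (mM s-1), stays below
#' `settings$steady_tol` for ten consecutive checks, or until
#' `settings$max_steady_time` of simulated time has elapsed.  A monotonic
#' volume increase beyond ten times the initial volume is reported as
#' non-convergent unbounded swelling (the fate of a water-permeable pure
#' Donnan system) instead of integrating forever.
#'
#' @inheritParams cd_run
#' @return A `steady_state_report`: list with `state`, `bath`, `converged`,
#'   `swelling`, `elapsed` (s), `net_flux` (ions s-1, per ion),
#'   `atp_per_sec` (pump activity at the final state), `Ankc`, `Akc`.
#' @export
run_to_steady_state <- function(state, bath, params, settings,
                                buildups = NULL) {
  res <- .cd_integrate(pack_state(state), pack_bath(bath),
                       pack_params(params), pack_buildups(buildups),
                       st = settings$st, t_end = settings$max_steady_time,
                       record_every = 0L,
                       steady_mode = TRUE, steady_tol = settings$steady_tol * 1e-3,
                       check_every = 200L, steady_need = 10L,
                       vol_max_ratio = 10)
  fs <- unpack_state(res$state)
  structure(list(state = fs, bath = unpack_bath(res$bath),
                 converged = res$converged, swelling = res$swelling,
                 elapsed = fs$t - state$t, net_flux = res$net_flux,
                 atp_per_sec = res$Ap, Ankc = res$Ankc, Akc = res$Akc),
            class = "steady_state_report")
}

#' @export
print.steady_state_report <- function(x, ...) {
  cat(sprintf("<steady_state_report> %s after %.3g s\n",
              if (x$converged) "converged"
              else if (x$swelling) "unbounded swelling" else "not converged",
              x$elapsed))
  cat(sprintf("  Na_i %.5g  K_i %.5g  Cl_i %.5g mM   Em %.4g mV   vol %.4g L\n",
              x$state$Na_i, x$state$K_i, x$state$Cl_i,
              1e3 * x$state$Em, x$state$vol))
  cat(sprintf("  pump activity %.5g ATP/s   max |net flux| %.3g ions/s\n",
              x$atp_per_sec, max(abs(x$net_flux))))
  invisible(x)
}

#' Membrane-charging time constant from a recorded voltage transient
#'
#' Takes the time at which the membrane potential first reaches 63.21%
#' (1 - 1/e) of its excursion from the first to the last sample, with
#' linear interpolation between samples.  For an RC-type relaxation this is
#' the time constant; the analytic value for a passive membrane is
#' `c / (g_total * e)`.
#'
#' @param time sample times, s.
#' @param Em membrane potential samples, V.
#' @return Fitted time constant, s.
#' @export
fit_rc_tau <- function(time, Em) {
  stopifnot(length(time) == length(Em), length(Em) > 2)
  e0 <- Em[1]
  target <- e0 + (1 - exp(-1)) * (Em[length(Em)] - e0)
  dir <- sign(Em[length(Em)] - e0)
  crossed <- which(dir * (Em - target) >= 0)
  if (!length(crossed)) stop("transient never reaches 63.2% of its excursion")
  i <- crossed[1]
  if (i == 1) return(time[1] - time[1])
  frac <- (target - Em[i - 1]) / (Em[i] - Em[i - 1])
  (time[i - 1] + frac * (time[i] - time[i - 1])) - time[1]
}
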