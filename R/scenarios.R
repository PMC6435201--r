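## Scenario registry: ready-made initial conditions mirroring classic
## experiments on the simulated cell (pure Donnan, Double Donnan, pump
## transients and sweeps, Cl- conductance opening, cotransporter sweeps,
## osmolyte buildups, asymmetry sweeps), plus the sweep and rate-finding
## drivers that generate steady-state curves.

#' Construct a simulation scenario
#'
#' A scenario bundles an initial [cell_state()] and [bath_state()], the
#' [membrane_params()], an optional [buildup_schedule()], [sim_settings()]
#' and a list of timed parameter changes (each `list(t =, param =, value =)`
#' with `param` naming a membrane parameter).  Events at `t <= 0` are
#' applied before the first step; later events split the run into segments.
#'
#' @param name scenario name.
#' @param state,bath,params,settings,buildups components; see the
#'   constructors.
#' @param events list of timed parameter changes.
#' @param description one-line human-readable summary.
#' @return An object of class `scenario`.
#' @export
scenario <- function(name, state, bath, params, settings,
                     buildups = NULL, events = list(), description = "") {
  ev_t <- vapply(events, function(e) e$t, 0)
  if (is.unsorted(ev_t)) events <- events[order(ev_t)]
  for (e in events)
    if (!e$param %in% names(params))
      stop("event refers to unknown parameter: ", e$param)
  structure(list(name = name, state = state, bath = bath, params = params,
                 settings = settings, buildups = buildups, events = events,
                 description = description),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario '%s'> %s\n", x$name, x$description))
  print(x$state); print(x$bath)
  if (length(x$events))
    for (e in x$events)
      cat(sprintf("  at t = %g s: %s <- %g\n", e$t, e$param, e$value))
  invisible(x)
}

## rate needed for a 3-site pump to show a given activity at a given Na_i
rate_for_activity <- function(activity, Na_i, hNa = 8) {
  activity * (1 + hNa / Na_i)^3
}

## "simplified": monovalent impermeant anion, no neutral osmolytes.
## "realistic": z = -1.5 plus 6 mM external neutral osmolyte, an
## osmolarity-charge asymmetric configuration.
resting_bath <- function(conditions) {
  bath_state(Na_o = 145, K_o = 5, Cl_o = 150,
             osm_o = if (conditions == "realistic") 6 else 0)
}

scenario_registry <- function() {
  list(
    donnan_novol = function(st = 1e-3) {
      scenario("donnan_novol",
        cell_state(Na_i = 150, Cl_i = 15, An_i = 135),
        bath_state(Na_o = 150, Cl_o = 150),
        membrane_params(z = -1, tau = 1e9),
        sim_settings(st = st, t_end = 1200, record_every = 10000),
        events = list(list(t = 0, param = "gNa", value = 1e10),
                      list(t = 0, param = "gCl", value = 1e10)),
        description = "Na+/Cl- Donnan relaxation, water-impermeable membrane")
    },
    donnan_water = function(tau = 0, st = 1e-3) {
      scenario("donnan_water",
        cell_state(Na_i = 150, Cl_i = 15, An_i = 135),
        bath_state(Na_o = 150, Cl_o = 150),
        membrane_params(z = -1, tau = tau),
        sim_settings(st = st, t_end = 1200, record_every = 10000,
                     max_steady_time = 36000),
        events = list(list(t = 0, param = "gNa", value = 1e10),
                      list(t = 0, param = "gCl", value = 1e10)),
        description = "same opening with osmotically obliged water: unbounded swelling")
    },
    water_perm_sweep = function(tau = 60, st = 1e-3) {
      sc <- scenario_registry()$donnan_water(tau = tau, st = st)
      sc$name <- "water_perm_sweep"
      sc$description <- "Donnan opening at a chosen water-permeability time constant"
      sc
    },
    double_donnan_na = function(st = 1e-3) {
      scenario("double_donnan_na",
        cell_state(Na_i = 150, Cl_i = 15, An_i = 135),
        bath_state(Na_o = 82.5, Cl_o = 82.5, osm_o = 135),
        membrane_params(z = -1, tau = 0),
        sim_settings(st = st, t_end = 1800, record_every = 10000,
                     max_steady_time = 7200),
        events = list(list(t = 0, param = "gNa", value = 1e10),
                      list(t = 0, param = "gCl", value = 1e10)),
        description = "Double Donnan stabilised by 135 mM external neutral osmolyte")
    },
    double_donnan_k = function(st = 1e-3) {
      scenario("double_donnan_k",
        cell_state(Na_i = 145, K_i = 5, Cl_i = 15, An_i = 135),
        bath_state(Na_o = 145, K_o = 5, Cl_o = 150),
        membrane_params(z = -1, tau = 0),
        sim_settings(st = st, t_end = 1800, record_every = 10000,
                     max_steady_time = 7200),
        events = list(list(t = 0, param = "gK", value = 1e10),
                      list(t = 0, param = "gCl", value = 1e10)),
        description = "K+/Cl- Double Donnan with a Na+-impermeable membrane")
    },
    pump_neutral_transient = function(st = 1e-4) {
      scenario("pump_neutral_transient",
        cell_state(Na_i = 145, K_i = 5, Cl_i = 15, An_i = 135),
        bath_state(Na_o = 145, K_o = 5, Cl_o = 150),
        membrane_params(gNa = 1e10, gK = 1e10, x = 3, y = 3, z = -1, tau = 1),
        sim_settings(st = st, t_end = 5, record_every = 10,
                     max_steady_time = 600),
        events = list(list(t = 0, param = "Rp", value = 2.4e10)),
        description = "electroneutral 3:3 pump switched on at rate 2.4e10 cycles/s")
    },
    pump_sweep = function(x = 3, y = 3, st = 1e-3) {
      scenario("pump_sweep",
        cell_state(Na_i = 145, K_i = 5, Cl_i = 15, An_i = 135),
        bath_state(Na_o = 145, K_o = 5, Cl_o = 150),
        membrane_params(gNa = 1e10, gK = 1e10, x = x, y = y, z = -1, tau = 1),
        sim_settings(st = st, t_end = 60, record_every = 1000,
                     max_steady_time = 20000),
        description = "cation-only system; sweep Rp for steady-state curves")
    },
    gcl_opening = function(Cl_i = 15, gCl = 1e10, conditions = "simplified",
                           st = NULL) {
      if (is.null(st)) st <- if (gCl > 1e10) 1e-4 else 5e-4
      if (conditions == "simplified") {
        state <- cell_state(Na_i = 17.9, K_i = 132.1, Cl_i = Cl_i,
                            An_i = 150 - Cl_i)
        z <- -1
      } else {
        state <- if (Cl_i <= 20)
          cell_state(Na_i = 18.5, K_i = 161.5, Cl_i = 18, An_i = 108)
        else
          cell_state(Na_i = 18.4, K_i = 154.8, Cl_i = 52, An_i = 80.8)
        z <- -1.5
      }
      scenario("gcl_opening", state, resting_bath(conditions),
        membrane_params(gNa = 8e9, gK = 1.2e10, x = 3, y = 2, z = z, tau = 1,
                        Rp = rate_for_activity(2.64e8, state$Na_i)),
        sim_settings(st = st, t_end = 600, record_every = 2000,
                     max_steady_time = 7200),
        events = list(list(t = 0, param = "gCl", value = gCl)),
        description = "Cl- conductance opened on a pump-leak cation resting state")
    },
    gna_step = function(pump = c("neutral", "electrogenic"), gCl = 1e10,
                        st = 5e-4) {
      pump <- match.arg(pump)
      if (pump == "neutral") {
        state <- cell_state(Na_i = 16.3, K_i = 158.3, Cl_i = 45.3, An_i = 86.2)
        y <- 3; act <- 2.41e8
      } else {
        state <- cell_state(Na_i = 18.5, K_i = 160.0, Cl_i = 25.7, An_i = 101.9)
        y <- 2; act <- 2.72e8
      }
      scenario("gna_step", state, resting_bath("realistic"),
        membrane_params(gNa = 8e9, gK = 1.2e10, gCl = gCl, x = 3, y = y,
                        z = -1.5, tau = 1,
                        Rp = rate_for_activity(act, state$Na_i)),
        sim_settings(st = st, t_end = 20, record_every = 200),
        events = list(list(t = 0, param = "gNa", value = 2e9),
                      list(t = 10, param = "gNa", value = 8e9)),
        description = "transient four-fold gNa reduction for 10 s")
    },
    nkcc_sweep = function(gCl = 1e8, conditions = "simplified", st = 1e-3) {
      state <- if (conditions == "simplified")
        cell_state(Na_i = 17.9, K_i = 132.1, Cl_i = 29.6, An_i = 120.4)
      else
        cell_state(Na_i = 18.5, K_i = 160.0, Cl_i = 25.7, An_i = 101.9)
      scenario("nkcc_sweep", state, resting_bath(conditions),
        membrane_params(gNa = 8e9, gK = 1.2e10, gCl = gCl, x = 3, y = 2,
                        z = if (conditions == "simplified") -1 else -1.5,
                        tau = 1, Rp = rate_for_activity(2.64e8, state$Na_i)),
        sim_settings(st = st, t_end = 600, record_every = 5000,
                     max_steady_time = 20000),
        description = "sweep Rnkc: NKCC loads Cl- toward its thermodynamic limit")
    },
    kcc_sweep = function(gCl = 1e8, conditions = "simplified", st = 1e-3) {
      sc <- scenario_registry()$nkcc_sweep(gCl = gCl, conditions = conditions,
                                           st = st)
      sc$name <- "kcc_sweep"
      sc$description <- "sweep Rkc: KCC extrudes Cl- toward its thermodynamic limit"
      sc
    },
    buildup_ext_neutral = function(gCl = 1e10, st = 1e-3) {
      buildup_base("buildup_ext_neutral", gCl, st,
                   buildup_schedule(bOso = 0.5, t_on = 0, t_off = 60),
                   "external neutral osmolyte raised 30 mM over 1 min")
    },
    buildup_ext_nacl = function(gCl = 1e10, st = 1e-3) {
      buildup_base("buildup_ext_nacl", gCl, st,
                   buildup_schedule(bNaCl = 0.25, t_on = 0, t_off = 60),
                   "external NaCl raised 15 mM over 1 min")
    },
    buildup_int_neutral = function(gCl = 1e10, st = 1e-3) {
      buildup_base("buildup_int_neutral", gCl, st,
                   buildup_schedule(bOsi = 0.05, t_on = 0, t_off = 600),
                   "internal neutral osmolyte raised 30 mM over 10 min")
    },
    buildup_int_anion = function(gCl = 1e10, st = 1e-3) {
      buildup_base("buildup_int_anion", gCl, st,
                   buildup_schedule(bAn = 0.02, t_on = 0, t_off = 600),
                   "internal impermeant anion (z = -1.5) built up with matched Na+")
    },
    ka_sweep = function(osm_i = 60, osm_o = 0, st = 1e-3) {
      scenario("ka_sweep",
        cell_state(Na_i = 145, K_i = 5, Cl_i = 30, An_i = 60, osm_i = osm_i),
        bath_state(Na_o = 145, K_o = 5, Cl_o = 150, osm_o = osm_o),
        membrane_params(gNa = 1e10, gK = 1e10, z = -2, tau = 1),
        sim_settings(st = st, t_end = 1800, record_every = 10000,
                     max_steady_time = 7200),
        description = "pump-free cation equilibrium at a chosen osmolarity-charge asymmetry")
    }
  )
}

buildup_base <- function(name, gCl, st, buildups, description) {
  state <- cell_state(Na_i = 18.5, K_i = 160.0, Cl_i = 25.7, An_i = 101.9)
  scenario(name, state, resting_bath("realistic"),
    membrane_params(gNa = 8e9, gK = 1.2e10, gCl = gCl, x = 3, y = 2,
                    z = -1.5, tau = 1,
                    Rp = rate_for_activity(2.72e8, state$Na_i)),
    sim_settings(st = st, t_end = 1800, record_every = 5000),
    buildups = buildups, description = description)
}

#' List the registered scenario names
#' @return Character vector of names accepted by [get_scenario()].
#' @export
list_scenarios <- function() names(scenario_registry())

#' Retrieve a registered scenario
#'
#' @param name one of [list_scenarios()].
#' @param ... scenario-specific options (for example `Cl_i`, `gCl` and
#'   `conditions` for `"gcl_opening"`; `tau` for `"water_perm_sweep"`;
#'   `x`, `y` for `"pump_sweep"`; `st` everywhere).
#' @return A [scenario()].
#' @export
get_scenario <- function(name, ...) {
  reg <- scenario_registry()
  if (!name %in% names(reg))
    stop("unknown scenario '", name, "'; available: ",
         paste(names(reg), collapse = ", "))
  reg[[name]](...)
}

apply_events <- function(params, events, upto) {
  for (e in events) if (e$t <= upto) params[[e$param]] <- e$value
  params
}

#' Run a scenario, honouring its timed parameter changes
#'
#' Events at `t <= 0` are applied before the first step; the run is split
#' into fixed-step segments at later event times.
#'
#' @param scn a [scenario()].
#' @param t_end,st,record_every optional overrides of the scenario settings.
#' @return A `cd_trajectory` (see [cd_run()]).
#' @export
run_scenario <- function(scn, t_end = NULL, st = NULL, record_every = NULL) {
  settings <- scn$settings
  if (!is.null(t_end)) settings$t_end <- t_end
  if (!is.null(st)) settings$st <- st
  if (!is.null(record_every)) settings$record_every <- as.integer(record_every)

  params <- apply_events(scn$params, scn$events, upto = 0)
  later <- Filter(function(e) e$t > 0 && e$t < settings$t_end, scn$events)
  cuts <- sort(unique(c(vapply(later, function(e) e$t, 0), settings$t_end)))

  state <- scn$state
  bath <- scn$bath
  pieces <- list()
  t0 <- 0
  for (tc in cuts) {
    seg <- settings
    seg$t_end <- tc - t0
    tr <- cd_run(state, bath, params, scn$buildups, seg)
    state <- attr(tr, "final_state")
    bath <- attr(tr, "final_bath")
    pieces[[length(pieces) + 1]] <-
      if (length(pieces)) tr[-1, , drop = FALSE] else tr
    params <- apply_events(scn$params, scn$events, upto = tc)
    t0 <- tc
  }
  out <- do.call(rbind, pieces)
  attr(out, "final_state") <- state
  attr(out, "final_bath") <- bath
  attr(out, "scenario") <- scn$name
  class(out) <- c("cd_trajectory", "data.frame")
  out
}

#' Run a scenario to its steady state
#'
#' Applies the scenario's `t <= 0` events, then integrates until every
#' per-ion net flux vanishes (see [run_to_steady_state()]).  Refuses
#' scenarios with active buildups, whose end state depends on the schedule.
#'
#' @param scn a [scenario()].
#' @param st,max_steady_time optional overrides.
#' @return A `steady_state_report`.
#' @export
steady_scenario <- function(scn, st = NULL, max_steady_time = NULL) {
  if (!is.null(scn$buildups) &&
      any(c(scn$buildups$bOso, scn$buildups$bNaCl,
            scn$buildups$bOsi, scn$buildups$bAn) > 0))
    stop("steady_scenario: scenario has active buildups")
  if (any(vapply(scn$events, function(e) e$t, 0) > 0))
    stop("steady_scenario: scenario has events after t = 0")
  settings <- scn$settings
  if (!is.null(st)) settings$st <- st
  if (!is.null(max_steady_time)) settings$max_steady_time <- max_steady_time
  params <- apply_events(scn$params, scn$events, upto = 0)
  run_to_steady_state(scn$state, scn$bath, params, settings)
}

set_scenario_value <- function(scn, param_path, value) {
  parts <- strsplit(param_path, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2 ||
      !parts[1] %in% c("params", "state", "bath"))
    stop("param_path must look like 'params.Rp', 'state.osm_i' or 'bath.osm_o'")
  if (!parts[2] %in% names(scn[[parts[1]]]))
    stop("unknown field in param_path: ", param_path)
  scn[[parts[1]]][[parts[2]]] <- value
  scn
}

#' Steady-state sweep over a parameter
#'
#' Runs one steady-state computation per value of the swept parameter and
#' tabulates the converged states.  Transporter sweeps report both the
#' swept rate and the realised activity (cycles/s), which is the
#' concentration-dependent quantity usually plotted.
#'
#' @param base a [scenario()] used as the template.
#' @param param_path which field to sweep, e.g. `"params.Rp"`,
#'   `"params.Rnkc"`, `"state.osm_i"`.
#' @param values numeric vector of parameter values.
#' @param st,max_steady_time optional overrides.
#' @return A data frame with one row per value: the swept `value`, pump
#'   activity `Ap`, cotransporter activities, concentrations (mM), `Em_mV`,
#'   `vol_pct` (percent of the scenario's initial volume) and `converged`.
#' @export
sweep_steady_states <- function(base, param_path, values,
                                st = NULL, max_steady_time = NULL) {
  empty <- data.frame(value = numeric(), Ap = numeric(), Ankc = numeric(),
                      Akc = numeric(), Na_i = numeric(), K_i = numeric(),
                      Cl_i = numeric(), An_i = numeric(), osm_i = numeric(),
                      Em_mV = numeric(), vol_pct = numeric(),
                      converged = logical(), swelling = logical())
  if (!length(values)) return(empty)
  rows <- lapply(values, function(v) {
    rep <- steady_scenario(set_scenario_value(base, param_path, v),
                           st = st, max_steady_time = max_steady_time)
    data.frame(value = v, Ap = rep$atp_per_sec,
               Ankc = rep$Ankc, Akc = rep$Akc,
               Na_i = rep$state$Na_i, K_i = rep$state$K_i,
               Cl_i = rep$state$Cl_i, An_i = rep$state$An_i,
               osm_i = rep$state$osm_i,
               Em_mV = 1e3 * rep$state$Em,
               vol_pct = 100 * rep$state$vol / base$state$vol,
               converged = rep$converged, swelling = rep$swelling)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Find the transporter rate that satisfies a steady-state condition
#'
#' Bisection (via [stats::uniroot()] on the log10 rate) for the rate at
#' which a scalar predicate of the steady state crosses zero.  The
#' predicate must be monotone in the rate over the bracket, which is
#' verified at the endpoints.
#'
#' @param base a [scenario()].
#' @param predicate function of a `steady_state_report` returning a signed
#'   residual (e.g. `function(r) r$state$Na_i - r$state$K_i`).
#' @param bracket length-2 positive numeric: rate bracket.
#' @param param_path swept field, default `"params.Rp"`.
#' @param tol relative rate tolerance of the bisection.
#' @param st,max_steady_time optional overrides.
#' @return List with `rate`, the final `report`, and `activity` at steady
#'   state.
#' @export
find_rate_for_condition <- function(base, predicate, bracket,
                                    param_path = "params.Rp", tol = 1e-6,
                                    st = NULL, max_steady_time = NULL) {
  stopifnot(length(bracket) == 2, all(bracket > 0), bracket[1] < bracket[2])
  eval_at <- function(rate) {
    rep <- steady_scenario(set_scenario_value(base, param_path, rate),
                           st = st, max_steady_time = max_steady_time)
    if (!rep$converged)
      stop("steady state did not converge at rate ", format(rate))
    list(rep = rep, res = predicate(rep))
  }
  lo <- eval_at(bracket[1])
  if (lo$res == 0) return(list(rate = bracket[1], report = lo$rep,
                               activity = lo$rep$atp_per_sec))
  hi <- eval_at(bracket[2])
  if (sign(lo$res) == sign(hi$res))
    stop("bracket does not straddle the condition: residuals ",
         format(lo$res), " and ", format(hi$res))
  root <- stats::uniroot(function(lr) eval_at(10^lr)$res,
                         interval = log10(bracket), tol = tol)
  rate <- 10^root$root
  fin <- eval_at(rate)
  list(rate = rate, report = fin$rep, activity = fin$rep$atp_per_sec)
}
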