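#' Nernst equilibrium potential
#'
#' `(RT / (valence * F)) * ln(c_out / c_in)`, in volts.  At 309.85 K a
#' tenfold inward cation gradient gives +61.48 mV.
#'
#' @param c_out,c_in concentrations on either side of the membrane (any
#'   common unit; only the ratio matters).  Both must be > 0.
#' @param valence signed ion valence (+1 for Na+/K+, -1 for Cl-).
#' @param T absolute temperature, K.
#' @return Equilibrium potential, V.
#' @examples
#' 1e3 * nernst_potential(150, 15, +1)   # 61.48 mV
#' @export
nernst_potential <- function(c_out, c_in, valence = 1L,
                             T = DEFAULT_TEMPERATURE) {
  if (any(c_out <= 0) || any(c_in <= 0))
    stop("nernst_potential: concentrations must be > 0")
  if (any(valence == 0)) stop("nernst_potential: valence must be non-zero")
  k <- physical_constants()
  (k$R * T / (valence * k$F)) * log(c_out / c_in)
}

#' Conductive (channel) fluxes
#'
#' Linear driving-force fluxes, inward positive, in ions per second:
#' `NaFc = gNa * (E_Na - Em)`, `KFc = gK * (E_K - Em)` and
#' `ClFc = gCl * ((RT/F) * ln(Cl_o/Cl_i) + Em)`.  The Cl- expression adds
#' `Em` because a negative membrane potential repels the anion; it is
#' identical to `gCl * (Em - E_Cl)` with the cation-convention Nernst
#' potential `E_Cl = -(RT/F) ln(Cl_o/Cl_i)`.
#'
#' A conductance of exactly zero silences its ion without touching its
#' concentrations, so fully impermeant ions (even at zero concentration)
#' are representable.
#'
#' @inheritParams validate_state
#' @return Named numeric vector `c(NaFc, KFc, ClFc)`, ions s-1.
#' @export
conductive_fluxes <- function(state, bath, params) {
  rtf <- physical_constants()$R * params$T / physical_constants()$F
  NaFc <- if (params$gNa > 0)
    params$gNa * (nernst_potential(bath$Na_o, state$Na_i, 1L, params$T) - state$Em)
  else 0
  KFc <- if (params$gK > 0)
    params$gK * (nernst_potential(bath$K_o, state$K_i, 1L, params$T) - state$Em)
  else 0
  ClFc <- if (params$gCl > 0) {
    if (bath$Cl_o <= 0 || state$Cl_i <= 0)
      stop("non-positive Cl- concentration with gCl > 0")
    params$gCl * (rtf * log(bath$Cl_o / state$Cl_i) + state$Em)
  } else 0
  c(NaFc = NaFc, KFc = KFc, ClFc = ClFc)
}

#' Na+/K+-ATPase activity
#'
#' `Ap = Rp / (1 + hNa/Na_i)^3`: third order in intracellular Na+, with
#' `Ap = Rp/8` at `Na_i = hNa` and `Ap -> Rp` as `Na_i` grows large.  The
#' activity equals the number of ATP molecules hydrolysed per second.
#'
#' @param Na_i intracellular Na+, mM (0 gives 0 by continuity).
#' @param Rp pump rate (capacity), cycles s-1.
#' @param hNa half-occupation Na+ concentration, mM.
#' @return Pump activity, cycles s-1.
#' @export
pump_activity <- function(Na_i, Rp, hNa = 8) {
  if (hNa <= 0) stop("hNa must be > 0")
  ifelse(Na_i <= 0, 0, Rp / (1 + hNa / Na_i)^3)
}

#' Pump fluxes from activity and stoichiometry
#'
#' @param Ap pump activity, cycles s-1.
#' @param x,y Na+ out and K+ in per cycle.
#' @return `c(NaFp, KFp)`, ions s-1 (NaFp <= 0: outward).
#' @export
pump_fluxes <- function(Ap, x = 3, y = 2) {
  c(NaFp = -x * Ap, KFp = y * Ap)
}

#' Na+,K+,2Cl- cotransporter fluxes
#'
#' Activity is the rate times the log driving force
#' `log10((Na_o*K_o*Cl_o^2) / (Na_i*K_i*Cl_i^2))`; it can be negative
#' (reverse mode).  Each cycle carries one Na+, one K+ and two Cl-, so the
#' transporter is electroneutral.
#'
#' @inheritParams validate_state
#' @param Rnkc cotransporter rate, cycles s-1.
#' @return Named vector `c(Ankc, NaFnkc, KFnkc, ClFnkc)`.
#' @export
nkcc_fluxes <- function(state, bath, Rnkc) {
  if (Rnkc == 0)
    return(c(Ankc = 0, NaFnkc = 0, KFnkc = 0, ClFnkc = 0))
  cs <- c(bath$Na_o, bath$K_o, bath$Cl_o, state$Na_i, state$K_i, state$Cl_i)
  if (any(cs <= 0)) stop("non-positive concentration in NKCC driving force")
  Ankc <- Rnkc * log10((bath$Na_o * bath$K_o * bath$Cl_o^2) /
                       (state$Na_i * state$K_i * state$Cl_i^2))
  c(Ankc = Ankc, NaFnkc = Ankc, KFnkc = Ankc, ClFnkc = 2 * Ankc)
}

#' K+,Cl- cotransporter fluxes
#'
#' Activity is `Rkc * log10((K_o*Cl_o) / (K_i*Cl_i))`; with the usual
#' gradients the intracellular product is larger, the activity is negative
#' and the transporter extrudes K+ and Cl-.
#'
#' @inheritParams validate_state
#' @param Rkc cotransporter rate, cycles s-1.
#' @return Named vector `c(Akc, KFkc, ClFkc)`.
#' @export
kcc_fluxes <- function(state, bath, Rkc) {
  if (Rkc == 0) return(c(Akc = 0, KFkc = 0, ClFkc = 0))
  cs <- c(bath$K_o, bath$Cl_o, state$K_i, state$Cl_i)
  if (any(cs <= 0)) stop("non-positive concentration in KCC driving force")
  Akc <- Rkc * log10((bath$K_o * bath$Cl_o) / (state$K_i * state$Cl_i))
  c(Akc = Akc, KFkc = Akc, ClFkc = Akc)
}

#' All instantaneous fluxes for a state
#'
#' Evaluates every transport pathway from the same beginning-of-step state
#' (conditions are treated as frozen within a step).
#'
#' @inheritParams validate_state
#' @return A named list of class `flux_set` with all per-pathway fluxes
#'   (ions s-1) and activities (cycles s-1).
#' @export
compute_fluxes <- function(state, bath, params) {
  fc <- conductive_fluxes(state, bath, params)
  Ap <- pump_activity(state$Na_i, params$Rp, params$hNa)
  fp <- pump_fluxes(Ap, params$x, params$y)
  fn <- nkcc_fluxes(state, bath, params$Rnkc)
  fk <- kcc_fluxes(state, bath, params$Rkc)
  structure(list(
    NaFc = unname(fc["NaFc"]), KFc = unname(fc["KFc"]), ClFc = unname(fc["ClFc"]),
    Ap = Ap, NaFp = unname(fp["NaFp"]), KFp = unname(fp["KFp"]),
    Ankc = unname(fn["Ankc"]), NaFnkc = unname(fn["NaFnkc"]),
    KFnkc = unname(fn["KFnkc"]), ClFnkc = unname(fn["ClFnkc"]),
    Akc = unname(fk["Akc"]), KFkc = unname(fk["KFkc"]),
    ClFkc = unname(fk["ClFkc"])), class = "flux_set")
}

#' Per-ion net fluxes
#'
#' @param fluxes a `flux_set` from [compute_fluxes()].
#' @return `c(Na, K, Cl)` net fluxes, ions s-1, inward positive.
#' @export
net_ion_fluxes <- function(fluxes) {
  c(Na = fluxes$NaFc + fluxes$NaFp + fluxes$NaFnkc,
    K = fluxes$KFc + fluxes$KFp + fluxes$KFnkc + fluxes$KFkc,
    Cl = fluxes$ClFc + fluxes$ClFnkc + fluxes$ClFkc)
}
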