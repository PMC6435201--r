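# Shared fixtures and independent oracles.

RTF <- 8.314 * 309.85 / 96485  # Nernst slope at 36.7 C, V

# symmetric passive start (pure Donnan opening)
donnan_start <- function() {
  list(state = cell_state(Na_i = 150, Cl_i = 15, An_i = 135),
       bath = bath_state(Na_o = 150, Cl_o = 150),
       params = membrane_params(gNa = 1e10, gCl = 1e10, z = -1, tau = 1e9))
}

# cation-only pump-leak start (symmetric monovalent-anion configuration)
pump_start <- function(x = 3, y = 3, Rp = 0) {
  list(state = cell_state(Na_i = 145, K_i = 5, Cl_i = 15, An_i = 135),
       bath = bath_state(Na_o = 145, K_o = 5, Cl_o = 150),
       params = membrane_params(gNa = 1e10, gK = 1e10, Rp = Rp,
                                x = x, y = y, z = -1, tau = 1))
}

# Independent algebraic steady-state solver for the pump-leak system with an
# equilibrated (or absent) Cl- conductance: solves flux balance, osmotic
# balance and electroneutrality by nested root-finding.  Shares no code with
# the time stepper.
oracle_pump_steady <- function(Rp, x, y, gNa, gK, bath, z,
                               osm_i = 0, with_cl = FALSE, Cl_fixed = NA) {
  na_of_em <- function(Em) {
    f <- function(Na) {
      Ap <- Rp / (1 + 8 / Na)^3
      gNa * (RTF * log(bath$Na_o / Na) - Em) - x * Ap
    }
    stats::uniroot(f, c(1e-3, bath$Na_o * 3), tol = 1e-14)$root
  }
  osm_o <- bath$Na_o + bath$K_o + bath$Cl_o + bath$osm_o
  resid <- function(Em) {
    Na <- na_of_em(Em)
    Ap <- Rp / (1 + 8 / Na)^3
    K <- bath$K_o * exp(-(Em - y * Ap / gK) / RTF)
    Cl <- if (with_cl) bath$Cl_o * exp(Em / RTF) else Cl_fixed
    An <- (Na + K - Cl) / (-z)
    Na + K + Cl + An + osm_i - osm_o
  }
  Em <- stats::uniroot(resid, c(-0.12, 0.08), tol = 1e-13)$root
  Na <- na_of_em(Em)
  Ap <- Rp / (1 + 8 / Na)^3
  K <- bath$K_o * exp(-(Em - y * Ap / gK) / RTF)
  Cl <- if (with_cl) bath$Cl_o * exp(Em / RTF) else Cl_fixed
  list(Em = Em, Na = Na, K = K, Cl = Cl, Ap = Ap)
}
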