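# Benzene benchmark parameter set, built in code for use across tests.

benzene_compound <- function(...) {
  compound_parameters(henry = 0.23, mu_max = 0.68, K = 12.22, Y = 0.708,
                      Dw = 1.04e-9, ...)
}

benzene_biofilm <- function(density = 100, area = 40, thickness = 5e-5) {
  biofilm_parameters(density, area, thickness)
}

benzene_bed <- function(ebrt = 60, n = 10L, eps = 0.35, inlet = 0.13) {
  bed_operation(height = 1.5, n_segments = n, void_fraction = eps,
                ebrt = ebrt, inlet = inlet)
}

benzene_derived <- function(ebrt = 60, n = 10L, eps = 0.35, inlet = 0.13) {
  derive_parameters(benzene_compound(), benzene_biofilm(),
                    benzene_bed(ebrt, n, eps, inlet))
}

# Independent oracle: stiff ODE integration (deSolve::lsoda) of the
# tanks-in-series discretization of the gas-phase balance, built from the raw
# transport coefficients (not from gamma1/gamma2).
ode_cascade <- function(dp, cg0, times, rtol = 1e-11, atol = 1e-14) {
  a <- dp$velocity / (dp$void_fraction * dp$dh)
  b <- dp$flux_coeff / (dp$henry * dp$void_fraction)
  n <- dp$n_segments
  rhs <- function(t, y, parms) {
    upstream <- c(cg0, y[-n])
    list(a * (upstream - y) - b * y)
  }
  sol <- deSolve::lsoda(y = numeric(n), times = times, func = rhs,
                        parms = NULL, rtol = rtol, atol = atol)
  unname(sol[, -1, drop = FALSE])
}

max_rel_err <- function(got, want) {
  max(abs(got - want) / pmax(abs(want), .Machine$double.xmin))
}
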