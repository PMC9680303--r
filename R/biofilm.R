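#' Pollutant concentration inside the biofilm
#'
#' Closed-form solution of the first-order diffusion-reaction balance
#' `De * Cl'' = k1 * Cl` in a planar biofilm slab of thickness `delta`, with
#' Henry equilibrium at the gas interface (`Cl(0) = Cg / H'`) and zero flux at
#' the support (`Cl'(delta) = 0`):
#'
#' `Cl(x) = Cg / (H' * (1 + exp(-2 delta phi))) * (exp(phi (x - 2 delta)) + exp(-phi x))`
#'
#' All exponential arguments are non-positive on `0 <= x <= delta`, so the
#' expression is overflow-free even at large `phi * delta`. At `x = delta` it
#' reduces to `Cg / (H' cosh(phi delta))`; in the no-reaction limit `phi -> 0`
#' the profile is flat at `Cg / H'`.
#'
#' @param cg local gas-phase concentration (g m^-3); >= 0.
#' @param x position(s) within the biofilm (m); `0 <= x <= delta`, vectorised.
#' @param henry dimensionless Henry's constant; > 0.
#' @param phi Thiele-type parameter (m^-1); >= 0.
#' @param delta biofilm thickness (m); > 0.
#' @return Liquid-phase concentration(s) Cl (g m^-3), same length as `x`.
#' @seealso [interfacial_gradient()], [biofilm_profile()]
#' @examples
#' biofilm_concentration(cg = 0.13, x = 0, henry = 0.23, phi = 1e5, delta = 5e-5)
#' @export
biofilm_concentration <- function(cg, x, henry, phi, delta) {
  stop_unless_scalar(cg = cg, henry = henry, phi = phi, delta = delta)
  if (cg < 0) stop("'cg' must be non-negative", call. = FALSE)
  if (henry <= 0) stop("'henry' must be positive", call. = FALSE)
  if (phi < 0) stop("'phi' must be non-negative", call. = FALSE)
  if (delta <= 0) stop("'delta' must be positive", call. = FALSE)
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("'x' must be finite numeric", call. = FALSE)
  if (any(x < 0 | x > delta))
    stop("'x' must lie within the biofilm, 0 <= x <= delta", call. = FALSE)
  cg / (henry * (1 + exp(-2 * delta * phi))) *
    (exp(phi * (x - 2 * delta)) + exp(-phi * x))
}

#' Concentration gradient at the gas-biofilm interface
#'
#' Derivative of [biofilm_concentration()] at `x = 0`:
#' `dCl/dx|_{x=0} = -(phi * Cg / H') * tanh(phi * delta)`, always <= 0 — the
#' flux is directed into the biofilm. Multiplied by `De * As` this is the
#' volumetric sink term of the gas-phase balance, and it is linear in the
#' local gas concentration, which is what makes the segment balance solvable
#' in closed form.
#'
#' @inheritParams biofilm_concentration
#' @return Gradient dCl/dx at x = 0 (g m^-4), <= 0.
#' @examples
#' interfacial_gradient(cg = 0.13, henry = 0.23, phi = 1.04e5, delta = 5e-5)
#' @export
interfacial_gradient <- function(cg, henry, phi, delta) {
  stop_unless_scalar(cg = cg, henry = henry, phi = phi, delta = delta)
  if (cg < 0) stop("'cg' must be non-negative", call. = FALSE)
  if (henry <= 0) stop("'henry' must be positive", call. = FALSE)
  if (phi < 0) stop("'phi' must be non-negative", call. = FALSE)
  if (delta <= 0) stop("'delta' must be positive", call. = FALSE)
  -(phi * cg / henry) * tanh(phi * delta)
}

#' Biofilm concentration profile on a regular grid
#'
#' Evaluates [biofilm_concentration()] on `n_points` evenly spaced positions
#' across the biofilm, for reporting and plotting.
#'
#' @inheritParams biofilm_concentration
#' @param n_points number of grid points (default 101).
#' @return A data.frame with columns `x_m` and `cl_g_per_m3`, carrying the
#'   evaluation parameters (`cg`, `henry`, `phi`, `delta`) as attributes.
#' @examples
#' prof <- biofilm_profile(cg = 0.13, henry = 0.23, phi = 1.04e5, delta = 5e-5)
#' head(prof)
#' @export
biofilm_profile <- function(cg, henry, phi, delta, n_points = 101L) {
  if (length(n_points) != 1 || n_points < 2 || n_points != round(n_points))
    stop("'n_points' must be a single integer >= 2", call. = FALSE)
  x <- seq(0, delta, length.out = n_points)
  cl <- biofilm_concentration(cg, x, henry, phi, delta)
  out <- data.frame(x_m = x, cl_g_per_m3 = cl)
  attr(out, "cg") <- cg
  attr(out, "henry") <- henry
  attr(out, "phi") <- phi
  attr(out, "delta") <- delta
  out
}

#' Write a biofilm profile to CSV
#'
#' Exports a [biofilm_profile()] with a commented metadata header recording
#' the gas concentration, Henry's constant, Thiele parameter and thickness.
#' Comma-separated, '.' decimal, UTF-8.
#'
#' @param profile a data.frame from [biofilm_profile()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    sprintf("# cg_g_per_m3 = %.15g", attr(profile, "cg")),
    sprintf("# henry = %.15g", attr(profile, "henry")),
    sprintf("# phi_per_m = %.15g", attr(profile, "phi")),
    sprintf("# delta_m = %.15g", attr(profile, "delta"))
  ), con)
  utils::write.table(profile, con, sep = ",", dec = ".", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
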