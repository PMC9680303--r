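#' Compound-specific physical and kinetic constants
#'
#' Bundles the per-pollutant constants needed by the biofilter model: the
#' dimensionless Henry's constant (gas/liquid partition, `Cg/Cl`), the Monod
#' kinetic parameters (maximum specific growth rate, half-saturation constant,
#' yield coefficient), and the aqueous diffusivity of the pollutant.
#'
#' The maximum specific growth rate is most often tabulated in the literature
#' in reciprocal hours; `mu_max_units = "1/h"` (the default) converts it to the
#' package-internal unit of reciprocal seconds at construction time. Supplying
#' a pre-converted value with `mu_max_units = "1/s"` yields an identical object.
#'
#' @param henry dimensionless Henry's constant H' (gas-phase over liquid-phase
#'   concentration at equilibrium); unitless, > 0.
#' @param mu_max maximum specific growth rate, in the units given by
#'   `mu_max_units`; >= 0.
#' @param K Monod half-saturation constant (g m^-3); > 0.
#' @param Y yield coefficient, biomass formed per pollutant consumed
#'   (unitless); > 0.
#' @param Dw diffusivity of the pollutant in water (m^2 s^-1); > 0.
#' @param mu_max_units `"1/h"` (literature convention, default) or `"1/s"`.
#' @return An object of class `compound_parameters`: a list with fields
#'   `henry`, `mu_max` (s^-1), `K`, `Y`, `Dw`.
#' @seealso [biofilm_parameters()], [bed_operation()], [derive_parameters()]
#' @examples
#' benzene <- compound_parameters(henry = 0.23, mu_max = 0.68, K = 12.22,
#'                                Y = 0.708, Dw = 1.04e-9)
#' benzene
#' @export
compound_parameters <- function(henry, mu_max, K, Y, Dw,
                                mu_max_units = c("1/h", "1/s")) {
  mu_max_units <- match.arg(mu_max_units)
  stop_unless_scalar(henry = henry, mu_max = mu_max, K = K, Y = Y, Dw = Dw)
  if (!is.finite(henry) || henry <= 0)
    stop("'henry' must be a finite positive dimensionless partition constant",
         call. = FALSE)
  if (mu_max < 0) stop("'mu_max' must be non-negative", call. = FALSE)
  if (K <= 0) stop("'K' (half-saturation constant) must be positive", call. = FALSE)
  if (Y <= 0) stop("'Y' (yield coefficient) must be positive", call. = FALSE)
  if (Dw <= 0) stop("'Dw' (aqueous diffusivity) must be positive", call. = FALSE)
  if (mu_max_units == "1/h") mu_max <- mu_max / 3600
  structure(
    list(henry = henry, mu_max = mu_max, K = K, Y = Y, Dw = Dw),
    class = "compound_parameters"
  )
}

#' Biofilm geometry and density
#'
#' @param density biofilm (dry) density Xv (kg m^-3); > 0. Enters both the
#'   effective-diffusivity correlation (in kg m^-3) and the lumped first-order
#'   rate constant (converted to g m^-3 there so units cancel against the
#'   half-saturation constant).
#' @param area biofilm surface area per unit bed volume As (m^-1 = m^2 m^-3); > 0.
#' @param thickness biofilm thickness delta (m); > 0. The biofilm is modelled
#'   as a planar slab of this thickness with a zero-flux backing.
#' @return An object of class `biofilm_parameters`.
#' @examples
#' biofilm_parameters(density = 100, area = 40, thickness = 5e-5)
#' @export
biofilm_parameters <- function(density, area, thickness) {
  stop_unless_scalar(density = density, area = area, thickness = thickness)
  if (density <= 0) stop("'density' must be positive", call. = FALSE)
  if (area <= 0) stop("'area' must be positive", call. = FALSE)
  if (thickness <= 0) stop("'thickness' must be positive", call. = FALSE)
  # fail early if the density lies outside the diffusivity correlation's range
  diffusivity_ratio(density)
  structure(
    list(density = density, area = area, thickness = thickness),
    class = "biofilm_parameters"
  )
}

#' Bed geometry and operating point
#'
#' Describes the packed bed and its gas flow. Exactly one of `velocity`
#' (superficial gas velocity, m s^-1) or `ebrt` (empty bed residence time,
#' `height / velocity`, s) must be supplied; the other is derived. If both are
#' given they must agree to 1e-12 relative.
#'
#' @param height bed height H (m); > 0.
#' @param n_segments number of well-mixed segments the bed is divided into
#'   (integer >= 1, default 10). Segment length is `height / n_segments`.
#' @param void_fraction gas-accessible fraction of the bed volume (0 < eps < 1,
#'   default 0.35). Sets the transient time constant only; the steady state is
#'   independent of it.
#' @param velocity superficial gas velocity ug (m s^-1), or `NULL`.
#' @param ebrt empty bed residence time (s), or `NULL`.
#' @param inlet constant inlet concentration (g m^-3, >= 0), or `NULL` when a
#'   time-varying [inlet_schedule()] will be supplied to the simulator.
#' @return An object of class `bed_operation` with fields `height`,
#'   `n_segments`, `void_fraction`, `velocity`, `ebrt`, `dh`, `inlet`.
#' @examples
#' bed_operation(height = 1.5, ebrt = 60, inlet = 0.13)
#' @export
bed_operation <- function(height, n_segments = 10L, void_fraction = 0.35,
                          velocity = NULL, ebrt = NULL, inlet = NULL) {
  stop_unless_scalar(height = height, void_fraction = void_fraction)
  if (height <= 0) stop("'height' must be positive", call. = FALSE)
  if (length(n_segments) != 1 || !is.finite(n_segments) ||
      n_segments < 1 || n_segments != round(n_segments))
    stop("'n_segments' must be a single integer >= 1", call. = FALSE)
  n_segments <- as.integer(n_segments)
  if (void_fraction <= 0 || void_fraction >= 1)
    stop("'void_fraction' must lie strictly between 0 and 1", call. = FALSE)
  if (is.null(velocity) && is.null(ebrt))
    stop("supply one of 'velocity' or 'ebrt'", call. = FALSE)
  if (!is.null(velocity)) {
    stop_unless_scalar(velocity = velocity)
    if (velocity <= 0) stop("'velocity' must be positive", call. = FALSE)
  }
  if (!is.null(ebrt)) {
    stop_unless_scalar(ebrt = ebrt)
    if (ebrt <= 0) stop("'ebrt' must be positive", call. = FALSE)
  }
  if (!is.null(velocity) && !is.null(ebrt)) {
    if (abs(ebrt * velocity - height) > 1e-12 * height)
      stop("'ebrt' and 'velocity' are inconsistent: ebrt * velocity must equal ",
           "the bed height", call. = FALSE)
  } else if (is.null(velocity)) {
    velocity <- height / ebrt
  } else {
    ebrt <- height / velocity
  }
  if (!is.null(inlet)) {
    stop_unless_scalar(inlet = inlet)
    if (inlet < 0) stop("'inlet' must be non-negative", call. = FALSE)
  }
  structure(
    list(height = height, n_segments = n_segments,
         void_fraction = void_fraction, velocity = velocity, ebrt = ebrt,
         dh = height / n_segments, inlet = inlet),
    class = "bed_operation"
  )
}

# Bracketed ratio of the density correlation; shared by effective_diffusivity()
# and the biofilm_parameters() validity check.
diffusivity_ratio <- function(Xv) {
  r <- 1 - 0.43 * Xv^0.92 / (11.19 + 0.27 * Xv^0.99)
  if (r <= 0)
    stop("biofilm density ", Xv, " kg/m3 lies outside the validity range of ",
         "the effective-diffusivity correlation (ratio <= 0)", call. = FALSE)
  r
}

#' Effective diffusivity of the pollutant in the biofilm
#'
#' Empirical correlation relating the pollutant's diffusivity in the biofilm
#' to its diffusivity in water, as a decreasing function of biofilm density:
#' `De = Dw * (1 - 0.43 * Xv^0.92 / (11.19 + 0.27 * Xv^0.99))` with `Xv` in
#' kg m^-3. At zero density the ratio is 1 (`De = Dw`); the correlation's
#' bracket must remain positive.
#'
#' @param Dw diffusivity in water (m^2 s^-1); > 0.
#' @param Xv biofilm density (kg m^-3); >= 0.
#' @return Effective diffusivity De (m^2 s^-1), with `0 < De <= Dw`.
#' @examples
#' effective_diffusivity(Dw = 1.04e-9, Xv = 100)
#' @export
effective_diffusivity <- function(Dw, Xv) {
  stop_unless_scalar(Dw = Dw, Xv = Xv)
  if (Dw <= 0) stop("'Dw' must be positive", call. = FALSE)
  if (Xv < 0) stop("'Xv' must be non-negative", call. = FALSE)
  if (Xv == 0) return(Dw)
  Dw * diffusivity_ratio(Xv)
}

#' Lumped first-order biodegradation rate constant
#'
#' In the low-concentration limit of Monod kinetics the volumetric degradation
#' rate in the biofilm is first order in the pollutant, with rate constant
#' `k1 = mu_max * X / (Y * K)`. The biofilm density is supplied in kg m^-3 and
#' converted internally to g m^-3 (`X = 1000 * Xv`) so that units cancel
#' against the half-saturation constant `K` (g m^-3), leaving s^-1.
#'
#' @param mu_max maximum specific growth rate (s^-1); >= 0.
#' @param Xv biofilm density (kg m^-3); >= 0.
#' @param Y yield coefficient (unitless); > 0.
#' @param K Monod half-saturation constant (g m^-3); > 0.
#' @return First-order rate constant k1 (s^-1).
#' @examples
#' first_order_rate(mu_max = 0.68 / 3600, Xv = 100, Y = 0.708, K = 12.22)
#' @export
first_order_rate <- function(mu_max, Xv, Y, K) {
  stop_unless_scalar(mu_max = mu_max, Xv = Xv, Y = Y, K = K)
  if (mu_max < 0) stop("'mu_max' must be non-negative", call. = FALSE)
  if (Xv < 0) stop("'Xv' must be non-negative", call. = FALSE)
  if (Y <= 0) stop("'Y' must be positive", call. = FALSE)
  if (K <= 0) stop("'K' must be positive", call. = FALSE)
  mu_max * (1000 * Xv) / (Y * K)
}

#' Thiele-type reaction-diffusion parameter
#'
#' `phi = sqrt(k1 / De)` (m^-1). The product `phi * delta` with the biofilm
#' thickness governs how deeply the pollutant penetrates the biofilm before
#' being consumed; `tanh(phi * delta)` is the slab effectiveness factor scale.
#'
#' @param k1 first-order rate constant (s^-1); >= 0.
#' @param De effective diffusivity in the biofilm (m^2 s^-1); > 0.
#' @return phi (m^-1).
#' @examples
#' thiele_phi(k1 = 2.18, De = 2.03e-10)
#' @export
thiele_phi <- function(k1, De) {
  stop_unless_scalar(k1 = k1, De = De)
  if (k1 < 0) stop("'k1' must be non-negative", call. = FALSE)
  if (De <= 0) stop("'De' must be positive", call. = FALSE)
  sqrt(k1 / De)
}

#' Derive all model parameters for a compound / biofilm / bed combination
#'
#' Runs the full parameter chain: effective diffusivity `De`, lumped
#' first-order rate constant `k1`, Thiele-type parameter `phi = sqrt(k1/De)`,
#' the interfacial flux coefficient `De * As * phi * tanh(delta * phi)`
#' (m s^-1), and the two segment-level model constants
#' \describe{
#'   \item{gamma1}{`H' ug / (H' ug + flux_coeff * dh)` — the fraction of
#'     pollutant surviving one bed segment at steady state (0 < gamma1 < 1).}
#'   \item{gamma2}{`(H' ug + flux_coeff * dh) / (H' eps * dh)` — the
#'     per-segment first-order transient rate constant (s^-1). Algebraically
#'     `gamma2 = ug / (gamma1 * eps * dh)`.}
#' }
#' The steady-state outlet of an `n`-segment bed with inlet `Cg0` is
#' `Cg0 * gamma1^n`, independent of the void fraction (which enters only
#' `gamma2`, i.e. the transient time constant).
#'
#' @param compound a [compound_parameters()] object.
#' @param biofilm a [biofilm_parameters()] object.
#' @param bed a [bed_operation()] object.
#' @return An object of class `derived_parameters`: a list with `De`, `k1`,
#'   `phi`, `flux_coeff`, `gamma1`, `gamma2`, plus the carried quantities
#'   `henry`, `velocity`, `void_fraction`, `dh`, `n_segments`, `delta` and
#'   `inlet` needed by the simulators.
#' @examples
#' benzene <- compound_parameters(0.23, 0.68, 12.22, 0.708, 1.04e-9)
#' film <- biofilm_parameters(100, 40, 5e-5)
#' bed <- bed_operation(1.5, ebrt = 60, inlet = 0.13)
#' derive_parameters(benzene, film, bed)
#' @export
derive_parameters <- function(compound, biofilm, bed) {
  stopifnot(inherits(compound, "compound_parameters"),
            inherits(biofilm, "biofilm_parameters"),
            inherits(bed, "bed_operation"))
  De <- effective_diffusivity(compound$Dw, biofilm$density)
  k1 <- first_order_rate(compound$mu_max, biofilm$density, compound$Y, compound$K)
  phi <- thiele_phi(k1, De)
  flux_coeff <- De * biofilm$area * phi * tanh(biofilm$thickness * phi)
  ug <- bed$velocity
  Hp <- compound$henry
  dh <- bed$dh
  eps <- bed$void_fraction
  gamma1 <- Hp * ug / (Hp * ug + flux_coeff * dh)
  gamma2 <- (Hp * ug + flux_coeff * dh) / (Hp * eps * dh)
  structure(
    list(De = De, k1 = k1, phi = phi, flux_coeff = flux_coeff,
         gamma1 = gamma1, gamma2 = gamma2,
         henry = Hp, velocity = ug, void_fraction = eps, dh = dh,
         n_segments = bed$n_segments, delta = biofilm$thickness,
         inlet = bed$inlet),
    class = "derived_parameters"
  )
}

#' @export
print.compound_parameters <- function(x, ...) {
  cat("Compound parameters\n")
  cat(sprintf("  Henry's constant H'      : %g (-)\n", x$henry))
  cat(sprintf("  mu_max                   : %g 1/s (%.4g 1/h)\n",
              x$mu_max, x$mu_max * 3600))
  cat(sprintf("  half-saturation K        : %g g/m3\n", x$K))
  cat(sprintf("  yield Y                  : %g (-)\n", x$Y))
  cat(sprintf("  aqueous diffusivity Dw   : %g m2/s\n", x$Dw))
  invisible(x)
}

#' @export
print.biofilm_parameters <- function(x, ...) {
  cat("Biofilm parameters\n")
  cat(sprintf("  density Xv       : %g kg/m3\n", x$density))
  cat(sprintf("  specific area As : %g 1/m\n", x$area))
  cat(sprintf("  thickness delta  : %g m\n", x$thickness))
  invisible(x)
}

#' @export
print.bed_operation <- function(x, ...) {
  cat("Bed operation\n")
  cat(sprintf("  height H        : %g m  (%d segments, dh = %g m)\n",
              x$height, x$n_segments, x$dh))
  cat(sprintf("  void fraction   : %g (-)\n", x$void_fraction))
  cat(sprintf("  velocity ug     : %g m/s  (EBRT = %g s)\n", x$velocity, x$ebrt))
  if (!is.null(x$inlet))
    cat(sprintf("  inlet Cg0       : %g g/m3\n", x$inlet))
  invisible(x)
}

#' @export
print.derived_parameters <- function(x, ...) {
  cat("Derived biofilter model parameters\n")
  cat(sprintf("  De (biofilm diffusivity) : %.6g m2/s\n", x$De))
  cat(sprintf("  k1 (first-order rate)    : %.6g 1/s\n", x$k1))
  cat(sprintf("  phi = sqrt(k1/De)        : %.6g 1/m  (phi*delta = %.4g)\n",
              x$phi, x$phi * x$delta))
  cat(sprintf("  flux coefficient         : %.6g m/s\n", x$flux_coeff))
  cat(sprintf("  gamma1 (per-segment att.): %.6g (-)\n", x$gamma1))
  cat(sprintf("  gamma2 (per-segment rate): %.6g 1/s\n", x$gamma2))
  invisible(x)
}

# shared scalar-argument validator
stop_unless_scalar <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
  }
  invisible(TRUE)
}
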