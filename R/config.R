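#' Read a run configuration from a YAML file
#'
#' The configuration mirrors how biofilter parameters are tabulated in the
#' literature: a `compound` section (Henry's constant, Monod kinetics, aqueous
#' diffusivity), a `biofilm` section (density, specific area, thickness), and
#' a `bed` section (height, segmentation, void fraction, velocity or EBRT,
#' constant inlet). Optional top-level keys: `schedule` (either explicit
#' `breakpoints`/`levels` or a `random` block with `t_end`, `dwell`, `cmin`,
#' `cmax`), `seed` (required for random schedules), and `solver`
#' (`"cascade"`, the exponential-propagation integrator, or `"analytic"`, the
#' closed-form product solution — constant inlet only).
#'
#' Validation is strict: unknown keys anywhere are errors, so typos cannot
#' silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return An object of class `run_config`: list with `compound`, `biofilm`,
#'   `bed`, `schedule` (`NULL` or [inlet_schedule()]), `seed`, `solver`.
#' @seealso [write_run_config()], [steady_sweep()], [run_transient()]
#' @examples
#' cfg <- read_run_config(system.file("extdata", "benzene.yaml",
#'                                    package = "biofiltr"))
#' cfg$bed$ebrt
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  as_run_config(yaml::read_yaml(path))
}

#' Build a validated run configuration from a list
#'
#' @param x a nested list following the schema of [read_run_config()].
#' @return An object of class `run_config`.
#' @export
as_run_config <- function(x) {
  if (!is.list(x)) stop("config must be a list", call. = FALSE)
  check_keys(x, required = c("compound", "biofilm", "bed"),
             optional = c("schedule", "seed", "solver"), where = "top level")

  cmp <- x$compound
  check_keys(cmp, required = c("henry", "mu_max", "K", "yield", "Dw"),
             optional = "mu_max_units", where = "compound")
  compound <- compound_parameters(
    henry = cmp$henry, mu_max = cmp$mu_max, K = cmp$K, Y = cmp$yield,
    Dw = cmp$Dw,
    mu_max_units = if (is.null(cmp$mu_max_units)) "1/h" else cmp$mu_max_units)

  bf <- x$biofilm
  check_keys(bf, required = c("density", "area", "thickness"), optional = NULL,
             where = "biofilm")
  biofilm <- biofilm_parameters(bf$density, bf$area, bf$thickness)

  bd <- x$bed
  check_keys(bd, required = "height",
             optional = c("n_segments", "void_fraction", "velocity", "ebrt",
                          "inlet"), where = "bed")
  bed <- bed_operation(
    height = bd$height,
    n_segments = if (is.null(bd$n_segments)) 10L else bd$n_segments,
    void_fraction = if (is.null(bd$void_fraction)) 0.35 else bd$void_fraction,
    velocity = bd$velocity, ebrt = bd$ebrt, inlet = bd$inlet)

  seed <- x$seed
  if (!is.null(seed)) {
    if (length(seed) != 1 || !is.finite(seed) || seed != round(seed))
      stop("'seed' must be a single integer", call. = FALSE)
    seed <- as.integer(seed)
  }

  schedule <- NULL
  if (!is.null(x$schedule)) {
    sc <- x$schedule
    if (!is.null(sc$random)) {
      check_keys(sc, required = "random", optional = NULL, where = "schedule")
      check_keys(sc$random, required = c("t_end", "dwell", "cmin", "cmax"),
                 optional = NULL, where = "schedule$random")
      if (is.null(seed))
        stop("a top-level 'seed' is required for random schedules",
             call. = FALSE)
      schedule <- random_inlet_schedule(sc$random$t_end, sc$random$dwell,
                                        sc$random$cmin, sc$random$cmax,
                                        seed = seed)
    } else {
      check_keys(sc, required = c("breakpoints", "levels"), optional = NULL,
                 where = "schedule")
      schedule <- inlet_schedule(sc$breakpoints, sc$levels)
    }
  }

  solver <- if (is.null(x$solver)) "cascade" else x$solver
  if (!solver %in% c("cascade", "analytic"))
    stop("'solver' must be \"cascade\" or \"analytic\"", call. = FALSE)

  structure(list(compound = compound, biofilm = biofilm, bed = bed,
                 schedule = schedule, seed = seed, solver = solver),
            class = "run_config")
}

check_keys <- function(x, required, optional, where) {
  if (!is.list(x))
    stop("config section '", where, "' must be a mapping", call. = FALSE)
  nms <- names(x)
  missing <- setdiff(required, nms)
  if (length(missing) > 0)
    stop("config ", where, ": missing required key(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  unknown <- setdiff(nms, c(required, optional))
  if (length(unknown) > 0)
    stop("config ", where, ": unknown key(s) ",
         paste(unknown, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

# shortest decimal representation that parses back to exactly x
fmt_num <- function(x) {
  if (x == round(x) && abs(x) < 1e15 && x != 0)
    return(sprintf("%.1f", x))  # keep YAML floats typed as floats
  if (x == 0) return("0.0")
  for (d in 1:17) {
    s <- sprintf("%.*g", d, x)
    if (as.numeric(s) == x) break
  }
  # YAML 1.1 floats need a dot in the mantissa and a signed exponent
  if (grepl("e", s) && !grepl("\\.", s)) s <- sub("e", ".0e", s)
  if (!grepl("[.e]", s)) s <- paste0(s, ".0")
  s <- sub("e([0-9])", "e+\\1", s)
  s
}

#' Write a run configuration to a YAML file
#'
#' Inverse of [read_run_config()]: numbers are written with enough digits to
#' round-trip exactly, and `mu_max` is written in the internal unit (1/s), so
#' `read_run_config(write_run_config(cfg, f))` reconstructs `cfg` identically.
#'
#' @param config a `run_config` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  cmp <- config$compound
  bf <- config$biofilm
  bd <- config$bed
  lines <- c(
    "compound:",
    sprintf("  henry: %s", fmt_num(cmp$henry)),
    sprintf("  mu_max: %s", fmt_num(cmp$mu_max)),
    "  mu_max_units: 1/s",
    sprintf("  K: %s", fmt_num(cmp$K)),
    sprintf("  yield: %s", fmt_num(cmp$Y)),
    sprintf("  Dw: %s", fmt_num(cmp$Dw)),
    "biofilm:",
    sprintf("  density: %s", fmt_num(bf$density)),
    sprintf("  area: %s", fmt_num(bf$area)),
    sprintf("  thickness: %s", fmt_num(bf$thickness)),
    "bed:",
    sprintf("  height: %s", fmt_num(bd$height)),
    sprintf("  n_segments: %d", bd$n_segments),
    sprintf("  void_fraction: %s", fmt_num(bd$void_fraction)),
    sprintf("  velocity: %s", fmt_num(bd$velocity)),
    sprintf("  ebrt: %s", fmt_num(bd$ebrt))
  )
  if (!is.null(bd$inlet))
    lines <- c(lines, sprintf("  inlet: %s", fmt_num(bd$inlet)))
  if (!is.null(config$schedule)) {
    sc <- config$schedule
    lines <- c(lines, "schedule:",
               sprintf("  breakpoints: [%s]",
                       paste(vapply(sc$breakpoints, fmt_num, ""), collapse = ", ")),
               sprintf("  levels: [%s]",
                       paste(vapply(sc$levels, fmt_num, ""), collapse = ", ")))
  }
  if (!is.null(config$seed))
    lines <- c(lines, sprintf("seed: %d", config$seed))
  lines <- c(lines, sprintf("solver: %s", config$solver))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("Biofilter run configuration\n")
  print(x$compound)
  print(x$biofilm)
  print(x$bed)
  if (!is.null(x$schedule))
    cat(sprintf("Inlet schedule: %d levels on [0, %g] s\n",
                length(x$schedule$levels), max(x$schedule$breakpoints)))
  cat(sprintf("Solver: %s\n", x$solver))
  invisible(x)
}

#' Steady-state sweep over operating points
#'
#' Evaluates the closed-form steady-state outlet `Cg0 * gamma1^n` for a set of
#' (EBRT, inlet) pairs under one compound/biofilm/bed parameter set. The
#' vectors are recycled to a common length, so a sweep of EBRTs at a fixed
#' inlet, or paired (EBRT, inlet) conditions, are both one call.
#'
#' @param config a `run_config` object.
#' @param ebrt empty-bed residence times (s); defaults to the config bed's.
#' @param inlet inlet concentrations (g m^-3); defaults to the config bed's.
#' @return A data.frame with columns `ebrt_s`, `velocity_m_s`, `inlet_g_m3`,
#'   `outlet_g_m3`, `removal_efficiency`, `gamma1`. Zero-length sweeps give a
#'   zero-row frame.
#' @examples
#' cfg <- read_run_config(system.file("extdata", "benzene.yaml",
#'                                    package = "biofiltr"))
#' steady_sweep(cfg, ebrt = c(60, 120), inlet = 0.13)
#' @export
steady_sweep <- function(config, ebrt = NULL, inlet = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(ebrt)) ebrt <- config$bed$ebrt
  if (is.null(inlet)) inlet <- config$bed$inlet
  if (is.null(inlet))
    stop("no inlet concentration: supply 'inlet' or set it in the config",
         call. = FALSE)
  m <- max(length(ebrt), length(inlet))
  if (m == 0)
    return(data.frame(ebrt_s = numeric(0), velocity_m_s = numeric(0),
                      inlet_g_m3 = numeric(0), outlet_g_m3 = numeric(0),
                      removal_efficiency = numeric(0), gamma1 = numeric(0)))
  ebrt <- rep_len(ebrt, m)
  inlet <- rep_len(inlet, m)
  n <- config$bed$n_segments
  rows <- lapply(seq_len(m), function(i) {
    bed <- bed_operation(height = config$bed$height, n_segments = n,
                         void_fraction = config$bed$void_fraction,
                         ebrt = ebrt[i], inlet = inlet[i])
    dp <- derive_parameters(config$compound, config$biofilm, bed)
    out <- steady_state_outlet(inlet[i], dp$gamma1, n)
    data.frame(ebrt_s = ebrt[i], velocity_m_s = bed$velocity,
               inlet_g_m3 = inlet[i], outlet_g_m3 = out,
               removal_efficiency = removal_efficiency(inlet[i], out),
               gamma1 = dp$gamma1)
  })
  do.call(rbind, rows)
}

#' Run a transient simulation from a configuration
#'
#' Wraps [derive_parameters()] and the transient solvers. With
#' `solver = "cascade"` (default) the piecewise-exponential integrator
#' [simulate_cascade()] is used and any inlet schedule in the config is
#' honoured. With `solver = "analytic"` the closed-form product solution is
#' evaluated per segment (`Cg0 * gamma1^i * (1 - exp(-gamma2 t))^i`); this
#' requires a constant inlet and a clean initial bed.
#'
#' @param config a `run_config` object.
#' @param t_end simulation horizon (s).
#' @param dt_out output time step (s); defaults to `t_end / 500`.
#' @return A `simulation_result` (see [simulate_cascade()]).
#' @examples
#' cfg <- read_run_config(system.file("extdata", "benzene.yaml",
#'                                    package = "biofiltr"))
#' res <- run_transient(cfg, t_end = 120)
#' res$steady_outlet
#' @export
run_transient <- function(config, t_end, dt_out = t_end / 500) {
  stopifnot(inherits(config, "run_config"))
  dp <- derive_parameters(config$compound, config$biofilm, config$bed)
  inlet <- if (!is.null(config$schedule)) config$schedule else config$bed$inlet
  if (is.null(inlet))
    stop("config has neither a constant inlet nor a schedule", call. = FALSE)
  if (config$solver == "analytic") {
    if (inherits(inlet, "inlet_schedule"))
      stop("the analytic solver requires a constant inlet; use solver: cascade",
           call. = FALSE)
    times <- seq(0, t_end, by = dt_out)
    if (times[length(times)] < t_end) times <- c(times, t_end)
    n <- dp$n_segments
    seg <- vapply(seq_len(n), function(i)
      cascade_outlet(inlet, dp$gamma1, dp$gamma2, i, times), numeric(length(times)))
    dimnames(seg) <- list(NULL, sprintf("seg_%02d", seq_len(n)))
    inlet_series <- rep_len(inlet, length(times))
    outlet <- seg[, n]
    return(structure(
      list(times = times, inlet = inlet_series, segment_conc = seg,
           outlet = outlet,
           steady_outlet = steady_state_outlet(inlet, dp$gamma1, n),
           removal_efficiency = removal_efficiency(inlet_series, outlet)),
      class = "simulation_result"))
  }
  simulate_cascade(dp, inlet = inlet, t_end = t_end, dt_out = dt_out)
}

#' Log the derived parameters of a configuration
#'
#' Prints the full derived-parameter chain (De, k1, phi, flux coefficient,
#' gamma1, gamma2) for auditability before a run.
#'
#' @param config a `run_config` object.
#' @return The [derive_parameters()] object, invisibly.
#' @export
log_derived_parameters <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dp <- derive_parameters(config$compound, config$biofilm, config$bed)
  print(dp)
  invisible(dp)
}
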