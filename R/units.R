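## Physical constants (CODATA 2018) and unit conversions.
## Internal conventions: energies in cm^-1, dipoles in atomic units,
## coordinates in Angstrom. Conversions happen only at computation
## boundaries (Coulomb sums are done in atomic units internally).

#' Physical constants used throughout the package
#'
#' A named list of conversion factors and constants. All energies are
#' handled internally in cm^-1, dipoles in atomic units and coordinates
#' in Angstrom; these factors convert at the boundaries.
#'
#' @format Named list with elements:
#' \describe{
#'   \item{hartree_cm1}{cm^-1 per hartree (219474.6313632)}
#'   \item{bohr_A}{Angstrom per bohr (0.529177210903)}
#'   \item{kJmol_cm1}{cm^-1 per kJ/mol}
#'   \item{kB_cm1}{Boltzmann constant in cm^-1/K (0.6950348)}
#'   \item{R_JmolK}{molar gas constant in J mol^-1 K^-1}
#'   \item{rotatory_au_cgs}{10^-40 cgs units per atomic unit of rotatory strength}
#' }
#' @export
chirospect_constants <- list(
  hartree_cm1     = 219474.6313632,
  bohr_A          = 0.529177210903,
  kJmol_cm1       = 83.59346005,
  kB_cm1          = 0.695034800,
  R_JmolK         = 8.314462618,
  rotatory_au_cgs = 235.7220
)

#' @keywords internal
.const <- chirospect_constants

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Run configuration for a spectra-simulation pipeline
#'
#' Bundles the handful of knobs shared across the pipeline stages:
#' temperature, the scalar correction added to all transition energies
#' (e.g. the difference between a cheap and an accurate electronic-structure
#' level for the isolated chromophore), Gaussian broadening half-widths for
#' the three kinds of band (pure electronic, vibronic, combined), the
#' hydrogen-bond score threshold and F-function geometry parameters, the
#' DVR grid, and the vibronic prescreening caps.
#'
#' @param temperature temperature in K (default 300)
#' @param energy_shift scalar shift added to all transition energies, cm^-1
#' @param broadening_hwhm named numeric: half-width at half-maximum in cm^-1
#'   for `electronic`, `vibronic` and `combined` band shapes
#'   (defaults 900, 550, 450)
#' @param hb_threshold F-function value above which a hydrogen bond is
#'   counted (default 0.7, strict: bond present iff F >= threshold)
#' @param f_params numeric of length 4: optimum distance (A), optimum angle
#'   deviation (deg), distance HWHM (A), angle HWHM (deg);
#'   defaults c(1.8, 6, 0.2, 5)
#' @param dvr_params list with `n_basis` (default 251) and `step` in degrees
#'   (default 4)
#' @param prescreen list with `C1max` (default 50), `C2max` (default 30) and
#'   `NImax` (default 1e9) for class-based stick enumeration
#' @param seed integer seed for stochastic components
#' @return object of class `run_config`
#' @export
run_config <- function(temperature = 300,
                       energy_shift = 0,
                       broadening_hwhm = c(electronic = 900, vibronic = 550,
                                           combined = 450),
                       hb_threshold = 0.7,
                       f_params = c(r0 = 1.8, theta0 = 6, w_r = 0.2, w_theta = 5),
                       dvr_params = list(n_basis = 251, step = 4),
                       prescreen = list(C1max = 50, C2max = 30, NImax = 1e9),
                       seed = 1L) {
  stopifnot(is.numeric(temperature), length(temperature) == 1,
            temperature > 0)
  if (any(broadening_hwhm <= 0)) stop("all broadening HWHM must be > 0")
  if (!(hb_threshold > 0 && hb_threshold < 1))
    stop("hb_threshold must lie strictly between 0 and 1")
  stopifnot(length(f_params) == 4, all(f_params[c(1, 3, 4)] > 0))
  cfg <- list(temperature = temperature,
              energy_shift = energy_shift,
              broadening_hwhm = broadening_hwhm,
              hb_threshold = hb_threshold,
              f_params = f_params,
              dvr_params = dvr_params,
              prescreen = prescreen,
              seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat("chirospect run configuration\n")
  cat(sprintf("  temperature    : %g K\n", x$temperature))
  cat(sprintf("  energy shift   : %g cm^-1\n", x$energy_shift))
  cat(sprintf("  broadening     : %s cm^-1 (HWHM)\n",
              paste(sprintf("%s=%g", names(x$broadening_hwhm),
                            x$broadening_hwhm), collapse = ", ")))
  cat(sprintf("  HB threshold   : %g\n", x$hb_threshold))
  cat(sprintf("  F params       : r0=%g A, th0=%g deg, w_r=%g A, w_th=%g deg\n",
              x$f_params[1], x$f_params[2], x$f_params[3], x$f_params[4]))
  cat(sprintf("  DVR            : %d functions, %g deg step\n",
              x$dvr_params$n_basis, x$dvr_params$step))
  invisible(x)
}

#' Read or write a run configuration as YAML
#'
#' @param path file path
#' @return `read_config` returns a `run_config`; `write_config` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  for (fld in c("broadening_hwhm", "f_params"))
    if (!is.null(y[[fld]])) y[[fld]] <- unlist(y[[fld]])
  do.call(run_config, y)
}

#' @rdname read_config
#' @param config a `run_config`
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$broadening_hwhm <- as.list(x$broadening_hwhm)
  x$f_params <- as.list(x$f_params)
  yaml::write_yaml(x, path)
  invisible(path)
}
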