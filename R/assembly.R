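## Composition of electronic (PMM) and vibronic ingredients into final
## OPA/ECD/OPE/CPL spectra: Boltzmann weighting of conformers, Gaussian
## broadening, per-frame shift-and-scale of the reference vibronic band,
## the half-fluctuation Herzberg-Teller rule, and line-shape prefactors.

SPECTRUM_KINDS <- c("OPA", "ECD", "OPE", "CPL")

#' Boltzmann weights from relative free energies
#'
#' w_i = exp(-dG_i / RT) / sum_j exp(-dG_j / RT) with
#' R = 8.314462618 J mol^-1 K^-1.
#'
#' @param dG_kJmol relative free energies, kJ/mol
#' @param T temperature, K
#' @param percent return percentages (default FALSE)
#' @return normalized weights
#' @export
boltzmann_weights <- function(dG_kJmol, T = 300, percent = FALSE) {
  stopifnot(all(is.finite(dG_kJmol)), T > 0)
  x <- -dG_kJmol * 1000 / (.const$R_JmolK * T)
  w <- exp(x - max(x))
  w <- w / sum(w)
  if (percent) w * 100 else w
}

#' Line-shape prefactor
#'
#' Absorption-type observables (OPA, ECD) scale linearly with the
#' transition energy; emission-type observables (OPE, CPL) with its cube
#' (spontaneous-emission convention). Overall units are arbitrary.
#'
#' @param kind one of "OPA", "ECD", "OPE", "CPL"
#' @param E transition energy, cm^-1 (> 0); vectorized
#' @param enabled with FALSE, returns unit factors (shape-only mode)
#' @return multiplicative factor
#' @export
prefactor <- function(kind, E, enabled = TRUE) {
  kind <- match.arg(kind, SPECTRUM_KINDS)
  if (!enabled) return(rep(1, length(E)))
  if (kind %in% c("OPA", "ECD")) E else E^3
}

#' Construct a band spectrum container
#' @keywords internal
band_spectrum <- function(grid, intensity, kind, hwhm = NA,
                          provenance = list()) {
  stopifnot(length(grid) == length(intensity))
  if (length(grid) > 1 && any(diff(grid) <= 0))
    stop("band grid must be strictly increasing")
  structure(list(grid = grid, intensity = intensity, kind = kind,
                 hwhm = hwhm, provenance = provenance),
            class = "band_spectrum")
}

#' @export
print.band_spectrum <- function(x, ...) {
  cat(sprintf("band_spectrum [%s]: %d points on [%.0f, %.0f] cm^-1",
              x$kind, length(x$grid), min(x$grid), max(x$grid)))
  if (is.finite(x$hwhm)) cat(sprintf(", HWHM %g cm^-1", x$hwhm))
  cat("\n")
  invisible(x)
}

#' Default energy grid covering a stick set
#' @param energies stick energies, cm^-1
#' @param hwhm broadening HWHM, cm^-1
#' @param spacing grid spacing (default 10 cm^-1)
#' @param pad grid padding in units of HWHM (default 5)
#' @export
default_grid <- function(energies, hwhm, spacing = 10, pad = 5) {
  lo <- floor((min(energies) - pad * hwhm) / spacing) * spacing
  hi <- ceiling((max(energies) + pad * hwhm) / spacing) * spacing
  seq(lo, hi, by = spacing)
}

#' Gaussian broadening of a stick spectrum
#'
#' Each stick is convolved with a unit-area Gaussian of the given HWHM,
#' g(E) = sqrt(ln2/pi)/HWHM exp(-ln2 ((E - E0)/HWHM)^2), so the integral
#' of the band equals the total stick weight.
#'
#' @param energies stick positions, cm^-1
#' @param weights stick weights (signed allowed, e.g. rotatory)
#' @param hwhm half-width at half-maximum, cm^-1 (> 0)
#' @param grid energy grid; default covers sticks +- 5 HWHM at 10 cm^-1
#' @param kind observable label for the result (default "OPA")
#' @return a `band_spectrum`
#' @export
broaden <- function(energies, weights, hwhm, grid = NULL, kind = "OPA") {
  stopifnot(hwhm > 0, length(energies) == length(weights))
  if (!length(energies)) {
    if (is.null(grid)) grid <- seq(0, 1, length.out = 2)
    return(band_spectrum(grid, numeric(length(grid)), kind, hwhm))
  }
  if (is.null(grid)) grid <- default_grid(energies, hwhm)
  if (min(energies) - 4 * hwhm < min(grid) ||
      max(energies) + 4 * hwhm > max(grid))
    warning("grid does not cover sticks +- 4 HWHM; band tails are clipped")
  a <- log(2) / hwhm^2
  norm <- sqrt(log(2) / pi) / hwhm
  y <- numeric(length(grid))
  for (s in seq_along(energies))
    y <- y + weights[s] * norm * exp(-a * (grid - energies[s])^2)
  band_spectrum(grid, y, kind, hwhm)
}

#' Pure electronic band of one or more clusters
#'
#' Per-frame stick weight = prefactor(kind, E) x (|mu'|^2 for OPA/OPE, R'
#' for ECD/CPL); frames are averaged within each cluster, clusters are
#' combined with their population weights, and the result is broadened
#' (default HWHM 900 cm^-1 for pure electronic bands).
#'
#' @param cluster_sticks a single `ensemble_sticks` or a list of them
#'   (one per cluster)
#' @param kind observable kind
#' @param populations cluster weights (default: equal); normalized
#'   internally
#' @param hwhm broadening HWHM, cm^-1 (default 900)
#' @param grid optional common energy grid
#' @param use_prefactor apply the energy prefactor (default TRUE)
#' @return a `band_spectrum`
#' @export
electronic_band <- function(cluster_sticks, kind, populations = NULL,
                            hwhm = 900, grid = NULL, use_prefactor = TRUE) {
  kind <- match.arg(kind, SPECTRUM_KINDS)
  if (inherits(cluster_sticks, "ensemble_sticks"))
    cluster_sticks <- list(cluster_sticks)
  ncl <- length(cluster_sticks)
  if (is.null(populations)) populations <- rep(1 / ncl, ncl)
  populations <- populations / sum(populations)
  all_e <- unlist(lapply(cluster_sticks, function(s) s$sticks$E_cm1))
  if (is.null(grid)) grid <- default_grid(all_e, hwhm)
  total <- numeric(length(grid))
  for (c in seq_len(ncl)) {
    st <- cluster_sticks[[c]]$sticks
    base <- if (kind %in% c("OPA", "OPE")) st$mu2_au else st$R_au
    wts <- base * prefactor(kind, st$E_cm1, use_prefactor) / nrow(st)
    total <- total + populations[c] *
      broaden(st$E_cm1, wts, hwhm, grid, kind)$intensity
  }
  band_spectrum(grid, total, kind, hwhm,
                provenance = list(model = "electronic",
                                  populations = populations))
}

## scale factors f per frame relative to the reference transition
frame_scale_factors <- function(frame_records, reference, kind,
                                radiating_pair = c(1, 2)) {
  st <- frame_records$sticks
  i <- radiating_pair[1]; j <- radiating_pair[2]
  mu_ref <- reference$elec_dipole[i, j, ]
  m_ref <- reference$mag_dipole[j, ]
  if (kind %in% c("OPA", "OPE")) {
    mu2_ref <- sum(mu_ref^2)
    if (mu2_ref == 0) stop("reference |mu|^2 = 0: scaling undefined")
    st$mu2_au / mu2_ref
  } else {
    R_ref <- sum(mu_ref * m_ref)
    if (R_ref == 0)
      stop("reference rotatory strength is zero: ", kind,
           " scaling undefined")
    st$R_au / R_ref
  }
}

#' Combine a reference vibronic band with PMM frame fluctuations (FC level)
#'
#' For each frame the reference stick spectrum is translated so its 0-0
#' line follows the frame's perturbed transition energy and all stick
#' weights are scaled by f = |mu'|^2 / |mu_ref|^2 (OPA/OPE) or
#' R'/R_ref (ECD/CPL, signed); the frames are averaged and broadened at
#' the combined HWHM (default 450 cm^-1).
#'
#' @param vibronic a `stick_spectrum` for the cluster's reference
#' @param frame_records an `ensemble_sticks` for the same cluster
#' @param reference the cluster's `electronic_reference`
#' @param kind observable kind; emission kinds place vibronic sticks at
#'   E_00 - offset, absorption kinds at E_00 + offset
#' @param hwhm combined broadening HWHM (default 450)
#' @param grid optional energy grid
#' @param radiating_pair reference state pair (default c(1, 2))
#' @param use_prefactor apply the energy prefactor at the frame 0-0
#'   energy (default TRUE)
#' @return a `band_spectrum`; attribute fields `mean_f` (ensemble-mean
#'   scale) and `frame_shifts` are stored in `provenance`
#' @export
combine_fc <- function(vibronic, frame_records, reference, kind,
                       hwhm = 450, grid = NULL, radiating_pair = c(1, 2),
                       use_prefactor = TRUE) {
  kind <- match.arg(kind, SPECTRUM_KINDS)
  st <- vibronic$sticks
  vib_w <- if (kind %in% c("OPA", "OPE")) st$w_el else st$w_rot
  sgn <- if (kind %in% c("OPE", "CPL")) -1 else 1
  f <- frame_scale_factors(frame_records, reference, kind, radiating_pair)
  E00 <- frame_records$sticks$E_cm1
  nfr <- length(E00)
  all_e <- c(outer(sgn * st$energy, E00, "+"))
  if (is.null(grid)) grid <- default_grid(all_e, hwhm)
  total <- numeric(length(grid))
  ## normalize the vibronic band by its reference electric/rotatory
  ## weight so the frame scale factor carries the absolute moment
  for (k in seq_len(nfr)) {
    wts <- vib_w * f[k] * prefactor(kind, E00[k], use_prefactor)
    total <- total + broaden(E00[k] + sgn * st$energy, wts, hwhm, grid,
                             kind)$intensity / nfr
  }
  band_spectrum(grid, total, kind, hwhm,
                provenance = list(model = paste0("combined-", vibronic$model),
                                  mean_f = mean(f),
                                  frame_shifts = E00 - mean(E00),
                                  frame_energies = E00))
}

#' Standalone vibronic band of a reference configuration
#'
#' Places the stick spectrum at an absolute 0-0 energy (emission kinds at
#' E00 - offset, absorption kinds at E00 + offset), applies the energy
#' prefactor at the 0-0 position, and broadens. This is exactly the
#' single-frame, unit-scale special case of [combine_fc()].
#'
#' @param vibronic a `stick_spectrum`
#' @param E00 absolute 0-0 transition energy, cm^-1
#' @param kind observable kind
#' @param hwhm broadening HWHM (default 550 cm^-1, vibronic stage)
#' @param grid optional grid
#' @param use_prefactor apply the energy prefactor (default TRUE)
#' @return a `band_spectrum`
#' @export
vibronic_band <- function(vibronic, E00, kind, hwhm = 550, grid = NULL,
                          use_prefactor = TRUE) {
  kind <- match.arg(kind, SPECTRUM_KINDS)
  st <- vibronic$sticks
  vib_w <- if (kind %in% c("OPA", "OPE")) st$w_el else st$w_rot
  sgn <- if (kind %in% c("OPE", "CPL")) -1 else 1
  if (is.null(grid)) grid <- default_grid(E00 + sgn * st$energy, hwhm)
  wts <- vib_w * 1 * prefactor(kind, E00, use_prefactor)
  b <- broaden(E00 + sgn * st$energy, wts, hwhm, grid, kind)
  b$intensity <- b$intensity / 1
  b$provenance <- list(model = vibronic$model, E00 = E00)
  b
}

#' Add the Herzberg-Teller increment under the half-fluctuation rule
#'
#' The FC-FCHT difference is evaluated explicitly only for the reference
#' configuration; the effect of solvent fluctuations on that increment is
#' taken as half the value computed for the FC part:
#' S_FCHT = S_FC,fluct + Delta_HT,ref x (1 + (<f> - 1)/2), where
#' Delta_HT,ref = ref FCHT band - ref FC band and <f> is the
#' ensemble-mean FC scale factor. Each Delta_HT copy is energy-shifted by
#' the same per-frame shifts as the FC part before averaging.
#'
#' @param fc_combined `band_spectrum` from [combine_fc()] (carries the
#'   per-frame shifts and mean scale in its provenance)
#' @param ref_fc_band reference-configuration FC band on the same grid
#' @param ref_fcht_band reference-configuration FCHT band on the same grid
#' @param mean_fluct_factor override for <f> (default: taken from
#'   `fc_combined` provenance)
#' @return a `band_spectrum`
#' @export
combine_fcht <- function(fc_combined, ref_fc_band, ref_fcht_band,
                         mean_fluct_factor = NULL) {
  g <- fc_combined$grid
  if (!isTRUE(all.equal(g, ref_fc_band$grid)) ||
      !isTRUE(all.equal(g, ref_fcht_band$grid)))
    stop("all bands must share one energy grid")
  f_mean <- mean_fluct_factor %||%
    (fc_combined$provenance$mean_f %||% 1)
  dHT <- ref_fcht_band$intensity - ref_fc_band$intensity
  shifts <- fc_combined$provenance$frame_shifts %||% 0
  if (length(shifts) && any(shifts != 0)) {
    acc <- numeric(length(g))
    for (s in shifts)
      acc <- acc + stats::approx(g + s, dHT, xout = g, rule = 2)$y
    dHT <- acc / length(shifts)
  }
  scale <- 1 + (f_mean - 1) / 2
  band_spectrum(g, fc_combined$intensity + scale * dHT,
                fc_combined$kind, fc_combined$hwhm,
                provenance = c(fc_combined$provenance,
                               list(ht_scale = scale)))
}

#' Final Boltzmann-weighted spectra over conformers
#'
#' Combines per-conformer (already cluster-combined) bands with Boltzmann
#' weights from their relative free energies. The sign structure of
#' circular observables is preserved, so conformers with opposite-sign
#' rotatory strengths produce a bisignate band.
#'
#' @param per_conformer_bands list of `band_spectrum`, one per conformer,
#'   on a common grid and of a common kind
#' @param dG_kJmol relative free energies per conformer, kJ/mol
#' @param T temperature, K (default 300)
#' @return a `band_spectrum`
#' @export
assemble_emission <- function(per_conformer_bands, dG_kJmol, T = 300) {
  stopifnot(length(per_conformer_bands) == length(dG_kJmol))
  w <- boltzmann_weights(dG_kJmol, T)
  g <- per_conformer_bands[[1]]$grid
  kind <- per_conformer_bands[[1]]$kind
  total <- numeric(length(g))
  for (c in seq_along(per_conformer_bands)) {
    b <- per_conformer_bands[[c]]
    if (!isTRUE(all.equal(g, b$grid)))
      stop("conformer bands must share one energy grid")
    if (!identical(kind, b$kind))
      stop("conformer bands must share one observable kind")
    total <- total + w[c] * b$intensity
  }
  band_spectrum(g, total, kind, per_conformer_bands[[1]]$hwhm,
                provenance = list(weights = w, dG_kJmol = dG_kJmol, T = T))
}

#' Assembly plan for a full emission (or absorption) simulation
#'
#' Small container tying together the conformer free energies, per-
#' conformer cluster populations, the broadening widths per stage and the
#' temperature.
#'
#' @param dG_kJmol conformer relative free energies, kJ/mol
#' @param cluster_populations list (one numeric vector per conformer)
#'   of cluster weights; each must sum to 1 within 1e-9
#' @param broadening_hwhm named numeric (electronic, vibronic, combined)
#' @param temperature K
#' @return object of class `assembly_plan`
#' @export
assembly_plan <- function(dG_kJmol, cluster_populations,
                          broadening_hwhm = c(electronic = 900,
                                              vibronic = 550,
                                              combined = 450),
                          temperature = 300) {
  stopifnot(temperature > 0)
  for (p in cluster_populations)
    if (abs(sum(p) - 1) > 1e-9)
      stop("cluster populations of each conformer must sum to 1")
  structure(list(dG_kJmol = dG_kJmol,
                 cluster_populations = cluster_populations,
                 broadening_hwhm = broadening_hwhm,
                 temperature = temperature),
            class = "assembly_plan")
}
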