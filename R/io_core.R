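## I/O for every external artifact: MD frames (extended XYZ with a charge
## column, or GRO + charge table), electronic reference data, PES scans,
## normal-mode sets and spectra. All readers validate the type invariants
## they document; all writer/reader pairs round-trip.

#' Construct a single MD snapshot
#'
#' A frame holds the (rigid) solute geometry plus the environment point
#' charges: for a methanol-like solvent each residue is a charge triad
#' (hydroxyl O, hydroxyl H, united CH3). Coordinates are in Angstrom,
#' charges in elementary charge units.
#'
#' @param index integer frame index (stable over a trajectory)
#' @param solute_elem character vector of solute atom labels; the carbonyl
#'   fragment atoms must be labelled "C" (carbonyl carbon), "O" (carbonyl
#'   oxygen) and "C1", "C2" (the two carbon neighbours of C)
#' @param solute_coords numeric matrix n_atoms x 3, Angstrom
#' @param env data.frame with columns `x`, `y`, `z` (Angstrom), `q`
#'   (elementary charges), `resid` (integer residue id grouping solvent
#'   sites) and `role` (character: "O", "H", "CH3", ...)
#' @return object of class `md_frame`
#' @export
md_frame <- function(index, solute_elem, solute_coords, env) {
  solute_coords <- as.matrix(solute_coords)
  stopifnot(ncol(solute_coords) == 3,
            length(solute_elem) == nrow(solute_coords))
  if (!all(is.finite(solute_coords)))
    stop("non-finite solute coordinates in frame ", index)
  env <- as.data.frame(env)
  need <- c("x", "y", "z", "q", "resid", "role")
  if (!all(need %in% names(env)))
    stop("env must have columns ", paste(need, collapse = ", "))
  if (nrow(env) && !all(is.finite(as.matrix(env[, c("x", "y", "z", "q")]))))
    stop("non-finite environment data in frame ", index)
  structure(list(index = as.integer(index),
                 solute_elem = as.character(solute_elem),
                 solute_coords = solute_coords,
                 env = env),
            class = "md_frame")
}

#' @export
print.md_frame <- function(x, ...) {
  cat(sprintf("md_frame %d: %d solute atoms, %d env sites (%d residues)\n",
              x$index, nrow(x$solute_coords), nrow(x$env),
              length(unique(x$env$resid))))
  invisible(x)
}

env_coords <- function(frame) as.matrix(frame$env[, c("x", "y", "z")])

#' Read MD frames from file
#'
#' Two plain-text formats are supported. `"xyz"` is extended XYZ: for each
#' frame a line with the atom count, a comment line `frame=<i> nsolute=<k>`,
#' then one line per atom with columns
#' `element x y z charge resid role` (solute atoms first, with resid 0 and
#' role "solute"). `"gro"` is a GROMACS-style coordinate file (positions in
#' nm, converted to Angstrom on read) paired with a separate charge table
#' (CSV: `atom`, `q`, `resid`, `role`, `solute` flag) given as
#' `charge_table`; multi-frame GRO files concatenate blocks.
#'
#' @param path input file
#' @param format `"xyz"` or `"gro"`
#' @param charge_table path to the charge-table CSV (GRO format only)
#' @return list of `md_frame`, in file order with stable indices
#' @export
read_frames <- function(path, format = c("xyz", "gro"), charge_table = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "xyz") read_frames_xyz(path) else {
    if (is.null(charge_table))
      stop("GRO format requires a charge table (missing charge column)")
    read_frames_gro(path, charge_table)
  }
}

read_frames_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat))
      stop(sprintf("malformed atom-count record at line %d of %s", i, path))
    comment <- lines[i + 1L]
    idx <- sub(".*frame=([0-9]+).*", "\\1", comment)
    nsol <- sub(".*nsolute=([0-9]+).*", "\\1", comment)
    if (idx == comment || nsol == comment)
      stop(sprintf("malformed comment record at line %d of %s (need frame= and nsolute=)",
                   i + 1L, path))
    idx <- as.integer(idx); nsol <- as.integer(nsol)
    block <- lines[(i + 2L):(i + 1L + nat)]
    tok <- strsplit(trimws(block), "[[:space:]]+")
    nfield <- lengths(tok)
    if (any(nfield < 5))
      stop(sprintf("missing charge column at line %d of %s",
                   i + 1L + which(nfield < 5)[1], path))
    if (any(nfield != 7))
      stop(sprintf("malformed atom record at line %d of %s (expect 7 fields)",
                   i + 1L + which(nfield != 7)[1], path))
    m <- do.call(rbind, tok)
    num <- suppressWarnings(apply(m[, 2:6, drop = FALSE], 2, as.numeric))
    if (nat == 1) num <- matrix(num, nrow = 1)
    if (any(!is.finite(num)))
      stop(sprintf("non-numeric field near line %d of %s", i + 2L, path))
    sol <- seq_len(nsol)
    envr <- setdiff(seq_len(nat), sol)
    frames[[length(frames) + 1L]] <- md_frame(
      index = idx,
      solute_elem = m[sol, 1],
      solute_coords = num[sol, 1:3, drop = FALSE],
      env = data.frame(x = num[envr, 1], y = num[envr, 2], z = num[envr, 3],
                       q = num[envr, 4], resid = as.integer(num[envr, 5]),
                       role = m[envr, 7]))
    i <- i + 2L + nat
  }
  frames
}

#' Write MD frames to extended XYZ (with charge column)
#'
#' @param frames list of `md_frame`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_frames <- function(frames, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    nsol <- nrow(fr$solute_coords)
    nat <- nsol + nrow(fr$env)
    writeLines(as.character(nat), con)
    writeLines(sprintf("frame=%d nsolute=%d", fr$index, nsol), con)
    writeLines(sprintf("%s %.10f %.10f %.10f %.10f %d %s",
                       fr$solute_elem,
                       fr$solute_coords[, 1], fr$solute_coords[, 2],
                       fr$solute_coords[, 3],
                       0, 0L, "solute"), con)
    if (nrow(fr$env))
      writeLines(sprintf("%s %.10f %.10f %.10f %.10f %d %s",
                         fr$env$role, fr$env$x, fr$env$y, fr$env$z,
                         fr$env$q, fr$env$resid, fr$env$role), con)
  }
  invisible(path)
}

read_frames_gro <- function(path, charge_table) {
  qt <- utils::read.csv(charge_table)
  need <- c("atom", "q", "resid", "role", "solute")
  if (!all(need %in% names(qt)))
    stop("charge table must have columns ", paste(need, collapse = ", "))
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  k <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat))
      stop(sprintf("malformed GRO atom count at line %d of %s", i + 1L, path))
    if (nat != nrow(qt))
      stop("charge table rows do not match GRO atom count")
    block <- lines[(i + 2L):(i + 1L + nat)]
    ## fixed-width GRO fields; positions nm -> Angstrom
    x <- as.numeric(substr(block, 21, 28)) * 10
    y <- as.numeric(substr(block, 29, 36)) * 10
    z <- as.numeric(substr(block, 37, 44)) * 10
    if (any(!is.finite(c(x, y, z))))
      stop(sprintf("malformed GRO coordinate record near line %d of %s",
                   i + 2L, path))
    k <- k + 1L
    sol <- which(qt$solute != 0)
    envr <- which(qt$solute == 0)
    elem <- trimws(substr(block, 11, 15))
    frames[[k]] <- md_frame(
      index = k,
      solute_elem = elem[sol],
      solute_coords = cbind(x[sol], y[sol], z[sol]),
      env = data.frame(x = x[envr], y = y[envr], z = z[envr],
                       q = qt$q[envr], resid = as.integer(qt$resid[envr]),
                       role = qt$role[envr]))
    i <- i + 3L + nat       # title, count, atoms, box line
  }
  frames
}

## ---------------------------------------------------------------- reference

#' Construct an electronic reference for one cluster
#'
#' Holds the variational (reference-frame) electronic structure used by the
#' perturbed-matrix method: adiabatic state energies, the complete electric
#' transition-dipole matrix, magnetic transition dipoles from the radiating
#' state, per-state atomic charges and the solute site coordinates, plus the
#' environment charges present when the reference was computed.
#'
#' States are numbered 1..n_states with state 1 the electronic ground state
#' of the propagated surface.
#'
#' @param energies numeric, cm^-1 per state, strictly increasing
#' @param elec_dipole numeric array n x n x 3, atomic units; must be
#'   symmetric in its first two indices (real-wavefunction convention)
#' @param mag_dipole numeric matrix n x 3: magnetic transition dipole of
#'   the transition radiating_state -> j (imaginary part stored as real
#'   components), atomic units
#' @param atomic_charges numeric matrix n_states x n_atoms, elementary
#'   charges; every row must sum to `total_charge` within 1e-6
#' @param site_coords numeric matrix n_atoms x 3, Angstrom
#' @param site_elem character labels for the solute atoms
#' @param ref_env data.frame of environment sites (`x`,`y`,`z`,`q`, optional
#'   `resid`,`role`) used when the reference was computed; may have 0 rows
#' @param radiating_state index of the state the magnetic dipoles refer to
#'   (default 1)
#' @param total_charge total molecular charge in e (default 0)
#' @return object of class `electronic_reference`
#' @export
electronic_reference <- function(energies, elec_dipole, mag_dipole,
                                 atomic_charges, site_coords, site_elem,
                                 ref_env = NULL, radiating_state = 1L,
                                 total_charge = 0) {
  n <- length(energies)
  stopifnot(n >= 2)
  if (any(diff(energies) <= 0))
    stop("reference energies must be strictly increasing")
  elec_dipole <- as_dipole_array(elec_dipole, n)
  for (k in 1:3) {
    asym <- max(abs(elec_dipole[, , k] - t(elec_dipole[, , k])))
    if (asym > 1e-6)
      stop(sprintf("electric dipole block %d not symmetric (max asym %.3g)",
                   k, asym))
    elec_dipole[, , k] <- (elec_dipole[, , k] + t(elec_dipole[, , k])) / 2
  }
  mag_dipole <- as.matrix(mag_dipole)
  stopifnot(nrow(mag_dipole) == n, ncol(mag_dipole) == 3)
  atomic_charges <- as.matrix(atomic_charges)
  if (nrow(atomic_charges) != n)
    stop("atomic_charges must have one row per state (state count mismatch)")
  sums <- rowSums(atomic_charges)
  if (any(abs(sums - total_charge) > 1e-6))
    stop(sprintf("per-state atomic charges must sum to %g e (worst deviation %.3g)",
                 total_charge, max(abs(sums - total_charge))))
  site_coords <- as.matrix(site_coords)
  stopifnot(ncol(site_coords) == 3,
            ncol(atomic_charges) == nrow(site_coords))
  if (is.null(ref_env))
    ref_env <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                          q = numeric(0))
  structure(list(n_states = n, energies = as.numeric(energies),
                 elec_dipole = elec_dipole, mag_dipole = mag_dipole,
                 atomic_charges = atomic_charges,
                 site_coords = site_coords,
                 site_elem = as.character(site_elem),
                 ref_env = as.data.frame(ref_env),
                 radiating_state = as.integer(radiating_state),
                 total_charge = total_charge),
            class = "electronic_reference")
}

as_dipole_array <- function(x, n) {
  x <- if (is.array(x) && length(dim(x)) == 3) x else
    array(x, dim = c(n, n, 3))
  if (!all(dim(x) == c(n, n, 3)))
    stop("elec_dipole must be an n x n x 3 array (state count mismatch)")
  x
}

#' @export
print.electronic_reference <- function(x, ...) {
  cat(sprintf("electronic_reference: %d states, %d atoms, %d ref env sites\n",
              x$n_states, nrow(x$site_coords), nrow(x$ref_env)))
  cat(sprintf("  first transition: %.1f cm^-1\n",
              x$energies[2] - x$energies[1]))
  invisible(x)
}

#' Read / write an electronic reference file
#'
#' The file is a sectioned plain-text format: a header
#' (`nstates`, `natoms`, `radiating_state`, `total_charge`) followed by
#' bracketed sections `[energies]`, `[elec_dipole]` (rows `i j mx my mz`,
#' full matrix), `[mag_dipole]` (rows `j mx my mz`), `[atomic_charges]`
#' (one row per state), `[site_coords]` (rows `elem x y z`) and optional
#' `[ref_env]` (rows `x y z q`). All invariants are validated on load; a
#' dipole matrix that is not symmetric within 1e-6 a.u. is rejected.
#'
#' @param path file path
#' @return `read_reference` returns an `electronic_reference`
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  hdr <- function(key) {
    ln <- grep(paste0("^", key, "\\b"), trimws(lines), value = TRUE)
    if (!length(ln)) stop("reference file missing header field ", key)
    as.numeric(strsplit(trimws(ln[1]), "[[:space:]]+")[[1]][2])
  }
  n <- as.integer(hdr("nstates")); nat <- as.integer(hdr("natoms"))
  rad <- as.integer(hdr("radiating_state")); qt <- hdr("total_charge")
  sec <- function(name) {
    starts <- which(trimws(lines) == sprintf("[%s]", name))
    if (!length(starts)) return(NULL)
    i <- starts[1] + 1L
    out <- character(0)
    while (i <= length(lines) && !startsWith(trimws(lines[i]), "[")) {
      out <- c(out, lines[i]); i <- i + 1L
    }
    out
  }
  num_rows <- function(x) {
    if (is.null(x)) return(NULL)
    do.call(rbind, lapply(strsplit(trimws(x), "[[:space:]]+"),
                          function(v) suppressWarnings(as.numeric(v))))
  }
  energies <- as.numeric(num_rows(sec("energies")))
  if (length(energies) != n) stop("state count mismatch in [energies]")
  dip_rows <- num_rows(sec("elec_dipole"))
  if (is.null(dip_rows) || nrow(dip_rows) != n * n)
    stop("state count mismatch in [elec_dipole] (need full n x n rows)")
  dip <- array(0, c(n, n, 3))
  for (r in seq_len(nrow(dip_rows))) {
    i <- as.integer(dip_rows[r, 1]); j <- as.integer(dip_rows[r, 2])
    dip[i, j, ] <- dip_rows[r, 3:5]
  }
  mag_rows <- num_rows(sec("mag_dipole"))
  mag <- matrix(0, n, 3)
  if (!is.null(mag_rows))
    for (r in seq_len(nrow(mag_rows)))
      mag[as.integer(mag_rows[r, 1]), ] <- mag_rows[r, 2:4]
  chg <- num_rows(sec("atomic_charges"))
  coords_rows <- sec("site_coords")
  tok <- strsplit(trimws(coords_rows), "[[:space:]]+")
  elem <- vapply(tok, `[`, "", 1)
  coords <- do.call(rbind, lapply(tok, function(v) as.numeric(v[2:4])))
  if (nrow(coords) != nat) stop("atom count mismatch in [site_coords]")
  envr <- num_rows(sec("ref_env"))
  ref_env <- if (is.null(envr))
    NULL else data.frame(x = envr[, 1], y = envr[, 2], z = envr[, 3],
                         q = envr[, 4])
  electronic_reference(energies = energies, elec_dipole = dip,
                       mag_dipole = mag, atomic_charges = chg,
                       site_coords = coords, site_elem = elem,
                       ref_env = ref_env, radiating_state = rad,
                       total_charge = qt)
}

#' @rdname read_reference
#' @param ref an `electronic_reference`
#' @export
write_reference <- function(ref, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# chirospect electronic reference v1")
  w("nstates %d", ref$n_states)
  w("natoms %d", nrow(ref$site_coords))
  w("radiating_state %d", ref$radiating_state)
  w("total_charge %.10g", ref$total_charge)
  w("[energies]")
  writeLines(sprintf("%.10f", ref$energies), con)
  w("[elec_dipole]")
  for (i in seq_len(ref$n_states))
    for (j in seq_len(ref$n_states))
      w("%d %d %.12e %.12e %.12e", i, j,
        ref$elec_dipole[i, j, 1], ref$elec_dipole[i, j, 2],
        ref$elec_dipole[i, j, 3])
  w("[mag_dipole]")
  for (j in seq_len(ref$n_states))
    w("%d %.12e %.12e %.12e", j, ref$mag_dipole[j, 1],
      ref$mag_dipole[j, 2], ref$mag_dipole[j, 3])
  w("[atomic_charges]")
  for (i in seq_len(ref$n_states))
    writeLines(paste(sprintf("%.12e", ref$atomic_charges[i, ]),
                     collapse = " "), con)
  w("[site_coords]")
  for (a in seq_len(nrow(ref$site_coords)))
    w("%s %.10f %.10f %.10f", ref$site_elem[a], ref$site_coords[a, 1],
      ref$site_coords[a, 2], ref$site_coords[a, 3])
  if (nrow(ref$ref_env)) {
    w("[ref_env]")
    for (s in seq_len(nrow(ref$ref_env)))
      w("%.10f %.10f %.10f %.12e", ref$ref_env$x[s], ref$ref_env$y[s],
        ref$ref_env$z[s], ref$ref_env$q[s])
  }
  invisible(path)
}

## ------------------------------------------------------------------ spectra

#' Write a spectrum (stick or band) to a two-column text file
#'
#' Bands are written as `energy_cm1,intensity` (or `wavelength_nm,intensity`
#' with `unit = "nm"`), preceded by comment lines naming the observable kind
#' and broadening. An empty spectrum produces a header-only file.
#'
#' @param spectrum a `band_spectrum` (see [broaden()]) or a data.frame with
#'   columns `energy` and `intensity`
#' @param path output file
#' @param unit `"cm1"` (default) or `"nm"`
#' @return `path`, invisibly
#' @export
write_spectrum <- function(spectrum, path, unit = c("cm1", "nm")) {
  unit <- match.arg(unit)
  kind <- attr(spectrum, "kind")
  hwhm <- attr(spectrum, "hwhm")
  if (inherits(spectrum, "band_spectrum")) {
    energy <- spectrum$grid; intensity <- spectrum$intensity
    kind <- spectrum$kind; hwhm <- spectrum$hwhm
  } else {
    energy <- spectrum$energy; intensity <- spectrum$intensity
  }
  if (length(energy) > 1 && any(diff(energy) <= 0))
    stop("spectrum energy grid must be strictly increasing")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind: %s", if (is.null(kind)) "unknown" else kind), con)
  writeLines(sprintf("# broadening_hwhm_cm1: %s",
                     if (is.null(hwhm)) "NA" else format(hwhm)), con)
  if (unit == "nm") {
    writeLines("wavelength_nm,intensity", con)
    if (length(energy)) {
      o <- order(1e7 / energy)
      writeLines(sprintf("%.8f,%.12e", (1e7 / energy)[o], intensity[o]), con)
    }
  } else {
    writeLines("energy_cm1,intensity", con)
    if (length(energy))
      writeLines(sprintf("%.8f,%.12e", energy, intensity), con)
  }
  invisible(path)
}

#' Read a spectrum written by [write_spectrum()]
#'
#' @param path input file
#' @return data.frame with columns `energy` (cm^-1) and `intensity`, with
#'   attributes `kind` and `hwhm` when present in the header
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.csv(text = paste(body, collapse = "\n"))
  if (names(df)[1] == "wavelength_nm") {
    energy <- 1e7 / df[[1]]
    o <- order(energy)
    df <- data.frame(energy = energy[o], intensity = df[[2]][o])
  } else names(df) <- c("energy", "intensity")
  kind_ln <- grep("^# kind:", hdr, value = TRUE)
  if (length(kind_ln)) attr(df, "kind") <- trimws(sub("^# kind:", "", kind_ln[1]))
  hw_ln <- grep("^# broadening_hwhm_cm1:", hdr, value = TRUE)
  if (length(hw_ln)) {
    hw <- suppressWarnings(as.numeric(trimws(sub(".*:", "", hw_ln[1]))))
    if (is.finite(hw)) attr(df, "hwhm") <- hw
  }
  df
}

## --------------------------------------------------------------- PES, modes

#' Read a 1-D potential-energy scan from CSV
#'
#' Expects columns `angle_deg` and `energy_kJmol` (or `energy_cm1`); the
#' grid must be uniform. The effective inertia of the large-amplitude
#' coordinate (atomic units, m_e a0^2 equivalents for an angle in radians)
#' is not part of the scan and must be supplied.
#'
#' @param path CSV path
#' @param inertia effective inertia, atomic units
#' @return a `pes_curve`
#' @export
read_pes <- function(path, inertia) {
  df <- utils::read.csv(path)
  if (!"angle_deg" %in% names(df)) stop("PES CSV needs an angle_deg column")
  e_col <- intersect(c("energy_kJmol", "energy_cm1"), names(df))
  if (!length(e_col)) stop("PES CSV needs energy_kJmol or energy_cm1")
  e <- df[[e_col[1]]]
  if (e_col[1] == "energy_kJmol") e <- e * .const$kJmol_cm1
  pes_curve(df$angle_deg, e, inertia)
}

#' Construct a 1-D PES curve for the large-amplitude motion
#'
#' @param angle numeric grid of angles in degrees, uniformly spaced
#' @param energy_cm1 potential energy on the grid, cm^-1
#' @param inertia effective inertia in atomic units (scalar, or one value
#'   per grid point for a coordinate-dependent kinetic operator)
#' @return object of class `pes_curve`
#' @export
pes_curve <- function(angle, energy_cm1, inertia) {
  stopifnot(length(angle) == length(energy_cm1), length(angle) >= 3)
  d <- diff(angle)
  if (max(abs(d - d[1])) > 1e-9)
    stop("PES grid must be uniformly spaced")
  if (!all(is.finite(energy_cm1))) stop("non-finite PES energies")
  stopifnot(all(inertia > 0),
            length(inertia) %in% c(1L, length(angle)))
  structure(list(angle = as.numeric(angle),
                 energy_cm1 = as.numeric(energy_cm1),
                 step = d[1], inertia = inertia),
            class = "pes_curve")
}

#' @rdname read_pes
#' @param pes a `pes_curve`
#' @export
write_pes <- function(pes, path) {
  utils::write.csv(data.frame(angle_deg = pes$angle,
                              energy_cm1 = pes$energy_cm1),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a normal-mode set for the vertical-gradient vibronic model
#'
#' @param freq_cm1 initial-state harmonic frequencies, cm^-1, all > 0
#' @param gradient final-state energy gradient along each initial-state
#'   dimensionless normal coordinate, cm^-1 per unit Q
#' @param dmu_dQ optional n_modes x 3 matrix of electric transition-dipole
#'   derivatives per dimensionless Q (a.u.), for Herzberg-Teller terms
#' @param removed logical mask of modes to exclude from all sums (e.g. the
#'   mode parallel to the large-amplitude motion, methyl rotations)
#' @return object of class `mode_set`
#' @export
mode_set <- function(freq_cm1, gradient = NULL, dmu_dQ = NULL,
                     removed = NULL) {
  n <- length(freq_cm1)
  if (any(freq_cm1 <= 0)) stop("mode frequencies must be positive")
  if (is.null(gradient)) gradient <- numeric(n)
  stopifnot(length(gradient) == n)
  if (is.null(dmu_dQ)) dmu_dQ <- matrix(0, n, 3)
  dmu_dQ <- as.matrix(dmu_dQ)
  stopifnot(nrow(dmu_dQ) == n, ncol(dmu_dQ) == 3)
  if (is.null(removed)) removed <- rep(FALSE, n)
  structure(list(freq = as.numeric(freq_cm1),
                 gradient = as.numeric(gradient),
                 dmu_dQ = dmu_dQ, removed = as.logical(removed)),
            class = "mode_set")
}

#' Read / write a mode set as CSV
#'
#' Columns: `mode`, `freq_cm1`, `gradient`, `dmu_dQ_x`, `dmu_dQ_y`,
#' `dmu_dQ_z`, `removed`.
#'
#' @param path CSV path
#' @export
read_modes <- function(path) {
  df <- utils::read.csv(path)
  mode_set(df$freq_cm1, df$gradient,
           cbind(df$dmu_dQ_x, df$dmu_dQ_y, df$dmu_dQ_z),
           as.logical(df$removed))
}

#' @rdname read_modes
#' @param modes a `mode_set`
#' @export
write_modes <- function(modes, path) {
  utils::write.csv(
    data.frame(mode = seq_along(modes$freq), freq_cm1 = modes$freq,
               gradient = modes$gradient, dmu_dQ_x = modes$dmu_dQ[, 1],
               dmu_dQ_y = modes$dmu_dQ[, 2], dmu_dQ_z = modes$dmu_dQ[, 3],
               removed = modes$removed),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
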