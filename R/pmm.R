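## Perturbed Matrix Method: per-frame electrostatic perturbation of a
## diagonal reference electronic Hamiltonian. The diagonal of the
## perturbation uses the atom-based expansion (per-state atomic charges
## contracted with the potential difference at each solute atom); the
## off-diagonal couplings contract the reference transition-dipole matrix
## with the electric-field difference at the expansion center.

#' Electrostatic potential and field of a set of point charges
#'
#' Computes, in atomic units, the Coulomb potential of the environment
#' sites at each evaluation point and the electric field at the expansion
#' center: phi(p) = sum_s q_s / |p - r_s| and
#' E(c) = sum_s q_s (r_c - r_s) / |r_c - r_s|^3.
#'
#' @param env data.frame with `x`, `y`, `z` (Angstrom) and `q` (e)
#' @param points m x 3 matrix of evaluation points, Angstrom
#' @param center 3-vector expansion center, Angstrom (default: mean of
#'   `points`)
#' @param guard minimum allowed site-point distance in Angstrom
#'   (default 1e-3); a closer site is an error
#' @param frame_index used only in error messages
#' @return list with `phi` (hartree/e per point) and `field` (a.u.,
#'   3-vector at the center)
#' @export
env_potential_and_field <- function(env, points, center = NULL,
                                    guard = 1e-3, frame_index = NA) {
  points <- matrix(as.numeric(points), ncol = 3)
  if (is.null(center)) center <- colMeans(points)
  if (!nrow(env))
    return(list(phi = numeric(nrow(points)), field = c(0, 0, 0)))
  b <- 1 / .const$bohr_A
  sx <- env$x * b; sy <- env$y * b; sz <- env$z * b; q <- env$q
  phi <- numeric(nrow(points))
  for (p in seq_len(nrow(points))) {
    dx <- points[p, 1] * b - sx
    dy <- points[p, 2] * b - sy
    dz <- points[p, 3] * b - sz
    r <- sqrt(dx^2 + dy^2 + dz^2)
    if (any(r < guard * b)) {
      s <- which.min(r)
      stop(sprintf("environment site %d within guard radius of evaluation point %d (frame %s)",
                   s, p, frame_index))
    }
    phi[p] <- sum(q / r)
  }
  cx <- center[1] * b - sx; cy <- center[2] * b - sy; cz <- center[3] * b - sz
  rc <- sqrt(cx^2 + cy^2 + cz^2)
  if (any(rc < guard * b))
    stop(sprintf("environment site within guard radius of expansion center (frame %s)",
                 frame_index))
  field <- c(sum(q * cx / rc^3), sum(q * cy / rc^3), sum(q * cz / rc^3))
  list(phi = phi, field = field)
}

#' Build the per-frame perturbation matrix
#'
#' The perturbation is the difference of the environment electrostatics
#' between a frame and the reference configuration. Diagonal elements use
#' the atom-based expansion with the per-state atomic charges,
#' [dV]_ii = sum_a q_i(a) (phi_frame(r_a) - phi_ref(r_a)); off-diagonal
#' elements couple states through the reference transition dipoles and the
#' field difference at the expansion center, [dV]_ij = -dE . mu_ij. The
#' result is symmetrized and returned in cm^-1.
#'
#' If per-state-pair transition atomic charges are available they may be
#' supplied as `transition_charges` (array n x n x n_atoms) and are then
#' used for the off-diagonal atom-based expansion instead of the dipole
#' contraction.
#'
#' @param reference an `electronic_reference`
#' @param frame an `md_frame` (or a `collective_frame`-like list with an
#'   `env` data.frame)
#' @param transition_charges optional n x n x n_atoms array, e
#' @return list of class `perturbation_matrix`: `matrix` (cm^-1),
#'   `frame`, `center`
#' @export
build_perturbation <- function(reference, frame, transition_charges = NULL) {
  n <- reference$n_states
  pts <- reference$site_coords
  center <- colMeans(pts)
  fi <- if (!is.null(frame$index)) frame$index else NA
  new <- env_potential_and_field(frame$env, pts, center, frame_index = fi)
  old <- env_potential_and_field(reference$ref_env, pts, center,
                                 frame_index = "reference")
  dphi <- new$phi - old$phi              # hartree / e, per solute atom
  dE <- new$field - old$field            # a.u.
  if (is.null(reference$atomic_charges))
    stop("reference is missing per-state atomic charges")
  V <- matrix(0, n, n)
  diag(V) <- as.numeric(reference$atomic_charges %*% dphi)
  if (is.null(transition_charges)) {
    for (k in 1:3)
      V <- V - dE[k] * reference$elec_dipole[, , k] *
        (1 - diag(n))                    # off-diagonal only
  } else {
    stopifnot(all(dim(transition_charges) == c(n, n, nrow(pts))))
    for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
      V[i, j] <- sum(transition_charges[i, j, ] * dphi)
  }
  V <- (V + t(V)) / 2
  structure(list(matrix = V * .const$hartree_cm1,
                 frame = fi, center = center),
            class = "perturbation_matrix")
}

#' Diagonalize the perturbed Hamiltonian
#'
#' Forms H = diag(reference energies) + dV, diagonalizes it, fixes each
#' eigenvector's sign so its largest-magnitude component is positive, and
#' rotates the electric transition-dipole matrix into the perturbed basis,
#' mu' = C^T mu C (componentwise).
#'
#' @param reference an `electronic_reference`
#' @param dV a `perturbation_matrix` or a plain symmetric matrix in cm^-1
#' @return list of class `perturbed_states`: `values` (cm^-1, ascending),
#'   `vectors` (columns = perturbed states in the reference basis),
#'   `elec_dipole` (n x n x 3, perturbed), `assignment` (reference state
#'   each perturbed state maps to, by maximal overlap)
#' @export
diagonalize_pmm <- function(reference, dV) {
  V <- if (inherits(dV, "perturbation_matrix")) dV$matrix else as.matrix(dV)
  if (!all(is.finite(V))) stop("non-finite entries in perturbation matrix")
  if (max(abs(V - t(V))) > 1e-8 * max(1, max(abs(V))))
    stop("perturbation matrix must be symmetric")
  n <- reference$n_states
  H <- diag(reference$energies, n) + V
  es <- eigen(H, symmetric = TRUE)
  ord <- order(es$values)
  vals <- es$values[ord]
  C <- es$vectors[, ord, drop = FALSE]
  for (j in seq_len(n)) {
    i <- which.max(abs(C[, j]))
    if (C[i, j] < 0) C[, j] <- -C[, j]
  }
  ## state tracking: perturbed state j is assigned to the reference state
  ## it overlaps most (survives near-crossings); ties to the lower index
  assignment <- apply(abs(C), 2, which.max)
  mu <- array(0, c(n, n, 3))
  for (k in 1:3)
    mu[, , k] <- t(C) %*% reference$elec_dipole[, , k] %*% C
  structure(list(values = vals, vectors = C, elec_dipole = mu,
                 assignment = as.integer(assignment)),
            class = "perturbed_states")
}

#' Per-frame spectroscopic observables of the radiating transition
#'
#' Extracts, for the transition between the two tracked reference states
#' of `radiating_pair`, the perturbed transition energy (plus the global
#' `energy_shift`), the squared perturbed electric transition dipole, and
#' the rotatory strength R' = mu' . m_ref. Environment fluctuations are
#' taken as negligible for the magnetic transition dipole, which therefore
#' stays at its (unrotated) reference value; `rotate_magnetic = TRUE`
#' applies the eigenvector rotation to the magnetic moments instead, for
#' sensitivity studies.
#'
#' @param perturbed a `perturbed_states`
#' @param reference the matching `electronic_reference`
#' @param radiating_pair integer pair of reference state indices
#'   (default c(1, 2): ground and first excited state)
#' @param energy_shift scalar added to the transition energy, cm^-1
#' @param rotate_magnetic also rotate the magnetic moments by C
#'   (default FALSE)
#' @return list: `energy_cm1`, `mu2_au` (|mu'|^2), `R_au`,
#'   `R_cgs` (10^-40 cgs), `mu_vec`, `m_vec`, `states` (perturbed indices)
#' @export
frame_observables <- function(perturbed, reference, radiating_pair = c(1, 2),
                              energy_shift = 0, rotate_magnetic = FALSE) {
  n <- reference$n_states
  stopifnot(all(radiating_pair >= 1), all(radiating_pair <= n))
  i <- which(perturbed$assignment == radiating_pair[1])[1]
  j <- which(perturbed$assignment == radiating_pair[2])[1]
  if (is.na(i)) i <- radiating_pair[1]
  if (is.na(j)) j <- radiating_pair[2]
  e <- perturbed$values[j] - perturbed$values[i] + energy_shift
  mu <- perturbed$elec_dipole[i, j, ]
  m <- if (rotate_magnetic) {
    ## sensitivity mode: rotate the magnetic column into the perturbed basis
    as.numeric(crossprod(perturbed$vectors[, j], reference$mag_dipole))
  } else {
    reference$mag_dipole[radiating_pair[2], ]
  }
  R <- sum(mu * m)
  list(energy_cm1 = e, mu2_au = sum(mu^2), R_au = R,
       R_cgs = R * .const$rotatory_au_cgs, mu_vec = mu, m_vec = m,
       states = c(i, j))
}

#' Perturbed stick parameters for every frame of a cluster
#'
#' Runs [build_perturbation()], [diagonalize_pmm()] and
#' [frame_observables()] over a sub-trajectory and collects one record per
#' frame, plus summary statistics of the transition-energy shift.
#'
#' @param reference the cluster's `electronic_reference`
#' @param frames list of `md_frame` belonging to the cluster
#' @param radiating_pair reference state pair (default c(1, 2))
#' @param energy_shift scalar transition-energy correction, cm^-1
#' @return list of class `ensemble_sticks`: `sticks` (data.frame frame,
#'   E_cm1, mu2_au, R_au, R_cgs), `mean_shift`, `shift_var` (about the
#'   unshifted reference transition energy)
#' @export
ensemble_sticks <- function(reference, frames, radiating_pair = c(1, 2),
                            energy_shift = 0) {
  if (!length(frames)) stop("empty frame list")
  e_ref <- reference$energies[radiating_pair[2]] -
    reference$energies[radiating_pair[1]]
  rows <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    dV <- build_perturbation(reference, frames[[k]])
    ps <- diagonalize_pmm(reference, dV)
    ob <- frame_observables(ps, reference, radiating_pair, energy_shift)
    rows[[k]] <- data.frame(frame = frames[[k]]$index,
                            E_cm1 = ob$energy_cm1, mu2_au = ob$mu2_au,
                            R_au = ob$R_au, R_cgs = ob$R_cgs)
  }
  df <- do.call(rbind, rows)
  shifts <- df$E_cm1 - energy_shift - e_ref
  structure(list(sticks = df, mean_shift = mean(shifts),
                 shift_var = stats::var(shifts),
                 reference_energy = e_ref),
            class = "ensemble_sticks")
}
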