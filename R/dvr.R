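## 1-D vibrational Schroedinger solver for the large-amplitude motion
## (carbonyl out-of-plane bend): sinc-DVR on a uniform angular grid
## (Colbert-Miller), well assignment, thermal populations and
## vibrational averaging of coordinate-dependent properties.

#' Solve the 1-D vibrational problem by sinc-DVR
#'
#' Uniform-grid sinc-DVR kinetic matrix (Colbert-Miller, infinite-range
#' variant): T_ii = (hbar^2 / 2 I dx^2) pi^2/3 and
#' T_ij = (hbar^2 / 2 I dx^2) 2 (-1)^(i-j) / (i-j)^2, with the potential
#' diagonal. The coordinate is the angle in radians; the effective inertia
#' is in atomic units, so with hbar = 1 all energies come out in hartree
#' and are converted to cm^-1. A per-grid-point inertia is discretized
#' symmetrically, T -> (1/2)(G^(1/2) T0 G^(1/2) + ...) reduced here to the
#' symmetric average G_ij = (1/2)(1/I_i + 1/I_j) scaling of the constant-
#' inertia kernel.
#'
#' Eigenfunctions are returned normalized with the grid quadrature weight,
#' sum_i psi_v(x_i)^2 dx = 1.
#'
#' @param pes a `pes_curve` (angles deg, energies cm^-1, inertia a.u.)
#' @param n_states_out number of lowest eigenpairs to return (default 30)
#' @return list of class `lam_solution`: `values` (cm^-1), `functions`
#'   (n_grid x n_states_out), `grid` (deg), `step_rad`, `pes`
#' @export
solve_dvr <- function(pes, n_states_out = 30) {
  stopifnot(inherits(pes, "pes_curve"))
  ng <- length(pes$angle)
  if (n_states_out > ng)
    stop("n_states_out exceeds the number of grid points")
  dx <- deg2rad(pes$step)
  idx <- seq_len(ng)
  D <- outer(idx, idx, "-")
  Tmat <- 2 * (-1)^D / (D^2 + diag(ng))   # off-diagonal kernel
  diag(Tmat) <- pi^2 / 3
  if (length(pes$inertia) == 1) {
    Tmat <- Tmat / (2 * pes$inertia * dx^2)
  } else {
    Ginv <- outer(1 / pes$inertia, 1 / pes$inertia, function(a, b) (a + b) / 2)
    Tmat <- Tmat * Ginv / (2 * dx^2)
  }
  H <- Tmat * .const$hartree_cm1
  diag(H) <- diag(H) + pes$energy_cm1
  es <- eigen(H, symmetric = TRUE)
  ord <- order(es$values)[seq_len(n_states_out)]
  vals <- es$values[ord]
  vecs <- es$vectors[, ord, drop = FALSE]
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  structure(list(values = vals,
                 functions = vecs / sqrt(dx),
                 grid = pes$angle, step_rad = dx, pes = pes),
            class = "lam_solution")
}

#' @export
print.lam_solution <- function(x, ...) {
  cat(sprintf("lam_solution: %d states on %d-point grid [%g, %g] deg\n",
              length(x$values), length(x$grid), min(x$grid), max(x$grid)))
  cat(sprintf("  lowest levels (cm^-1): %s\n",
              paste(sprintf("%.2f", utils::head(x$values - x$values[1], 5)),
                    collapse = ", ")))
  invisible(x)
}

#' Assign vibrational states to potential wells
#'
#' A state is `well1` if at least `p_loc` of its probability lies on the
#' well-1 side of the barrier, `well2` if at most `1 - p_loc` does, and
#' `delocalized` otherwise.
#'
#' @param solution a `lam_solution`
#' @param barrier_position angle (deg) of the interior barrier maximum; if
#'   missing it is located as the interior PES maximum between the two
#'   minima
#' @param p_loc localization probability threshold (default 0.9)
#' @return character vector of labels per state
#' @export
assign_wells <- function(solution, barrier_position = NULL, p_loc = 0.9) {
  if (is.null(barrier_position))
    barrier_position <- locate_barrier(solution$pes)
  dx <- solution$step_rad
  left <- solution$grid < barrier_position
  p_left <- colSums(solution$functions[left, , drop = FALSE]^2) * dx
  ifelse(p_left >= p_loc, "well1",
         ifelse(p_left <= 1 - p_loc, "well2", "delocalized"))
}

#' Locate the interior barrier of a double-well PES
#'
#' @param pes a `pes_curve`
#' @return angle (deg) of the interior maximum between the two outermost
#'   minima; the grid edge if there is no interior maximum
#' @export
locate_barrier <- function(pes) {
  e <- pes$energy_cm1
  n <- length(e)
  mins <- which(diff(sign(diff(e))) > 0) + 1L
  if (length(mins) < 2) return(pes$angle[n])   # single well
  lo <- min(mins); hi <- max(mins)
  seg <- lo:hi
  pes$angle[seg[which.max(e[seg])]]
}

#' Boltzmann populations of the vibrational states
#'
#' Populations are computed over all supplied levels; states below the
#' retention threshold are dropped from the retained list, and both the
#' unrenormalized and the renormalized retained populations are reported.
#'
#' @param solution a `lam_solution`
#' @param T temperature, K
#' @param retain_threshold minimum population for a state to be retained
#'   (default 0.005, i.e. 0.5 percent)
#' @return list: `populations` (all states, sums to 1), `retained`
#'   (indices), `retained_populations` (unrenormalized),
#'   `retained_renormalized`
#' @export
thermal_populations <- function(solution, T = 300, retain_threshold = 0.005) {
  stopifnot(T > 0)
  e <- solution$values - min(solution$values)
  w <- exp(-e / (.const$kB_cm1 * T))
  p <- w / sum(w)
  keep <- which(p >= retain_threshold)
  list(populations = p, retained = keep,
       retained_populations = p[keep],
       retained_renormalized = p[keep] / sum(p[keep]))
}

#' Vibrationally average a coordinate-dependent property
#'
#' Grid-quadrature expectation values <psi_v | A | psi_w> of a property
#' sampled on the DVR grid. Vector properties (n_grid x k matrices) are
#' averaged componentwise.
#'
#' @param solution a `lam_solution`
#' @param property numeric vector over the grid, or a matrix with one row
#'   per grid point (componentwise averaging)
#' @param states state indices to average over (default: all)
#' @param cross also return the off-diagonal matrix elements
#'   (default FALSE)
#' @return if `property` is a vector: numeric of diagonal expectations
#'   (or the full matrix when `cross = TRUE`); if a matrix: a matrix of
#'   diagonal expectations (states x components)
#' @export
lam_average <- function(solution, property, states = NULL, cross = FALSE) {
  if (is.null(states)) states <- seq_along(solution$values)
  psi <- solution$functions[, states, drop = FALSE]
  dx <- solution$step_rad
  if (is.matrix(property)) {
    if (nrow(property) != length(solution$grid))
      stop("property grid does not match the DVR grid")
    return(t(psi^2) %*% property * dx)
  }
  if (length(property) != length(solution$grid))
    stop("property grid does not match the DVR grid")
  if (cross) {
    t(psi) %*% (psi * property) * dx
  } else {
    as.numeric(colSums(psi^2 * property) * dx)
  }
}

#' Vibrationally averaged transition-moment geometry
#'
#' Averages the electric and magnetic transition-dipole components over a
#' vibrational state and recombines them into |mu|, |m| and the cosine of
#' the angle between them (the quantities that control rotatory strength).
#'
#' @param solution a `lam_solution`
#' @param mu_curve n_grid x 3 electric transition dipole along the scan, a.u.
#' @param m_curve n_grid x 3 magnetic transition dipole along the scan, a.u.
#' @param states state indices (default: all)
#' @return data.frame: state, mu_norm, m_norm, cos_angle, R (= mu . m)
#' @export
lam_moment_geometry <- function(solution, mu_curve, m_curve, states = NULL) {
  if (is.null(states)) states <- seq_along(solution$values)
  mu_avg <- lam_average(solution, as.matrix(mu_curve), states)
  m_avg <- lam_average(solution, as.matrix(m_curve), states)
  mu_n <- sqrt(rowSums(mu_avg^2)); m_n <- sqrt(rowSums(m_avg^2))
  R <- rowSums(mu_avg * m_avg)
  data.frame(state = states, mu_norm = mu_n, m_norm = m_n,
             cos_angle = ifelse(mu_n * m_n > 0, R / (mu_n * m_n), NA),
             R = R)
}
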