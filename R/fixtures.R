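## Synthetic generators for every pipeline input: solvated-frame streams
## with tunable hydrogen-bond propensities, valid electronic references,
## double-well PES curves and displaced-oscillator mode sets. All
## generation is bit-reproducible under a fixed seed and every generated
## artifact passes its target type's invariant validation.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Specification for a synthetic solvated-trajectory fixture
#'
#' @param seed integer RNG seed
#' @param n_frames number of frames to generate
#' @param propensities length-4 numeric, target fractions for
#'   (noHB, HB-VS1, HB-VS2, twoHB); must sum to 1
#' @param n_far number of distant (non-bonding) methanol triads per frame
#' @param state electronic state for the VS placement rule
#' @return object of class `fixture_spec`
#' @export
fixture_spec <- function(seed = 1L, n_frames = 100L,
                         propensities = c(noHB = 0.58, `HB-VS1` = 0.19,
                                          `HB-VS2` = 0.215, twoHB = 0.015),
                         n_far = 2L, state = "excited") {
  stopifnot(length(propensities) == 4, all(propensities >= 0))
  if (abs(sum(propensities) - 1) > 1e-9)
    stop("propensities must sum to 1")
  structure(list(seed = as.integer(seed), n_frames = as.integer(n_frames),
                 propensities = propensities, n_far = as.integer(n_far),
                 state = state),
            class = "fixture_spec")
}

#' Rigid carbonyl fragment used by all synthetic frames
#'
#' A planar formaldehyde-like fragment: carbonyl C at the origin, O on the
#' +x axis (1.22 A), the two carbon neighbours of C at 120 degrees in the
#' xy plane.
#'
#' @return list with `elem` and `coords`
#' @export
carbonyl_fragment <- function() {
  list(elem = c("C", "O", "C1", "C2"),
       coords = rbind(c(0, 0, 0),
                      c(1.22, 0, 0),
                      1.5 * c(cos(2 * pi / 3), sin(2 * pi / 3), 0),
                      1.5 * c(cos(2 * pi / 3), -sin(2 * pi / 3), 0)))
}

## methanol-like 3-site triad charges (fixture constants: hydroxyl O,
## hydroxyl H, united CH3; net neutral)
METHANOL_Q <- c(O = -0.700, H = 0.435, CH3 = 0.265)

rand_unit3 <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-6) return(v / n)
  }
}
perp_unit <- function(d) {
  a <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unit3(cross3(d, a))
}

## place one methanol triad hydrogen-bonded to a VS: H at distance r along
## the outward lone-pair axis, methanol O making a VS...H-O angle of
## (180 - theta) degrees, united CH3 completing the triad
place_bonded_methanol <- function(vs, o_solute, r, theta, resid) {
  d <- unit3(vs - o_solute)                 # outward lone-pair direction
  H <- vs + r * d
  p <- perp_unit(d)
  az <- stats::runif(1, 0, 2 * pi)
  p <- cos(az) * p + sin(az) * cross3(d, p)
  dev <- deg2rad(theta)
  ## angle between H->VS (= -d) and H->O must be 180 - theta
  o_dir <- cos(pi - dev) * (-d) + sin(pi - dev) * p
  Om <- H + 0.96 * o_dir
  ch3 <- Om + 1.42 * unit3(o_dir + 0.4 * p)
  data.frame(x = c(Om[1], H[1], ch3[1]),
             y = c(Om[2], H[2], ch3[2]),
             z = c(Om[3], H[3], ch3[3]),
             q = as.numeric(METHANOL_Q),
             resid = resid, role = c("O", "H", "CH3"))
}

place_far_methanol <- function(center, resid, r_min = 5, r_max = 9) {
  d <- rand_unit3()
  Om <- center + stats::runif(1, r_min, r_max) * d
  h_dir <- rand_unit3()
  H <- Om + 0.96 * h_dir
  ch3 <- Om - 1.42 * h_dir
  data.frame(x = c(Om[1], H[1], ch3[1]),
             y = c(Om[2], H[2], ch3[2]),
             z = c(Om[3], H[3], ch3[3]),
             q = as.numeric(METHANOL_Q),
             resid = resid, role = c("O", "H", "CH3"))
}

## draw a bonded (r, theta) pair: Gaussians around the F-function optima
## with the F-function half-widths, rejection-truncated to F >= f_min so
## the generated label is recovered deterministically by the classifier
draw_bonded_geometry <- function(f_params = c(1.8, 6, 0.2, 5),
                                 f_min = 0.75) {
  repeat {
    r <- stats::rnorm(1, f_params[1], f_params[3])
    th <- stats::rnorm(1, f_params[2], f_params[4])
    if (r > 0 && th >= 0 && f_function(r, th, f_params) >= f_min)
      return(c(r = r, theta = th))
  }
}

#' Generate a synthetic solvated trajectory with known HB propensities
#'
#' Frames hold the rigid carbonyl fragment plus methanol-like charge
#' triads. Each frame's hydrogen-bond label is drawn from the requested
#' propensities; bonded triads are placed with (r, theta) inside the
#' F >= 0.75 region around the optimum (so classification at the 0.7
#' threshold recovers the drawn label), unbonded triads are kept far away
#' (F ~ 0). Deterministic under the spec seed.
#'
#' @param spec a `fixture_spec`
#' @return list with `frames` (list of `md_frame`) and `labels` (the drawn
#'   labels, for parameter-recovery checks)
#' @export
gen_solvent_frames <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  frag <- carbonyl_fragment()
  vs <- place_virtual_sites(frag$coords, frag$elem, state = spec$state)
  o_sol <- frag$coords[2, ]
  center <- colMeans(frag$coords)
  lv <- c("noHB", "HB-VS1", "HB-VS2", "twoHB")
  with_seed(spec$seed, {
    labels <- sample(lv, spec$n_frames, replace = TRUE,
                     prob = spec$propensities)
    frames <- vector("list", spec$n_frames)
    for (i in seq_len(spec$n_frames)) {
      parts <- list()
      resid <- 1L
      if (labels[i] %in% c("HB-VS1", "twoHB")) {
        g <- draw_bonded_geometry()
        parts[[length(parts) + 1L]] <-
          place_bonded_methanol(vs$vs1, o_sol, g["r"], g["theta"], resid)
        resid <- resid + 1L
      }
      if (labels[i] %in% c("HB-VS2", "twoHB")) {
        g <- draw_bonded_geometry()
        parts[[length(parts) + 1L]] <-
          place_bonded_methanol(vs$vs2, o_sol, g["r"], g["theta"], resid)
        resid <- resid + 1L
      }
      for (k in seq_len(spec$n_far)) {
        parts[[length(parts) + 1L]] <- place_far_methanol(center, resid)
        resid <- resid + 1L
      }
      env <- if (length(parts)) do.call(rbind, parts)
      else data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      q = numeric(0), resid = integer(0),
                      role = character(0))
      frames[[i]] <- md_frame(i, frag$elem, frag$coords, env)
    }
    list(frames = frames, labels = labels)
  })
}

#' Generate a valid synthetic electronic reference
#'
#' Energies start a camphor-like first gap (~33,000 cm^-1, the carbonyl
#' n -> pi* region) above the ground state and increase strictly; the
#' electric dipole matrix is symmetric with a controllable radiating
#' transition moment; the magnetic transition moment of the radiating
#' transition is oriented at a controllable angle to the electric one;
#' per-state atomic charges sum to zero.
#'
#' @param n_states number of electronic states (>= 2; default 11)
#' @param seed RNG seed
#' @param first_gap_cm1 energy of the first transition (default 33000)
#' @param mu01 magnitude of the radiating electric transition dipole, a.u.
#' @param m01 magnitude of the radiating magnetic transition dipole, a.u.
#' @param angle_deg angle between the radiating electric and magnetic
#'   transition dipoles, degrees (default 30; 90 gives R = 0)
#' @param ref_env optional environment data.frame present at the reference
#' @return an `electronic_reference`
#' @export
gen_reference_electronic <- function(n_states = 11, seed = 1L,
                                     first_gap_cm1 = 33000,
                                     mu01 = 0.5, m01 = 0.005,
                                     angle_deg = 30, ref_env = NULL) {
  stopifnot(n_states >= 2)
  frag <- carbonyl_fragment()
  nat <- nrow(frag$coords)
  with_seed(seed, {
    gaps <- c(first_gap_cm1,
              stats::runif(n_states - 2, 2000, 6000))
    energies <- c(0, cumsum(gaps))
    dip <- array(0, c(n_states, n_states, 3))
    for (k in 1:3) {
      m <- matrix(stats::rnorm(n_states^2, 0, 0.1), n_states)
      m <- (m + t(m)) / 2
      diag(m) <- stats::runif(n_states, -1, 1)
      dip[, , k] <- m
    }
    mu_dir <- rand_unit3()
    dip[1, 2, ] <- dip[2, 1, ] <- mu01 * mu_dir
    p <- perp_unit(mu_dir)
    mag <- matrix(stats::rnorm(3 * n_states, 0, 0.002), n_states, 3)
    mag[1, ] <- 0
    mag[2, ] <- m01 * (cos(deg2rad(angle_deg)) * mu_dir +
                       sin(deg2rad(angle_deg)) * p)
    chg <- matrix(stats::rnorm(n_states * nat, 0, 0.3), n_states, nat)
    chg <- chg - rowMeans(chg)         # each state sums to 0 exactly
    electronic_reference(energies = energies, elec_dipole = dip,
                         mag_dipole = mag, atomic_charges = chg,
                         site_coords = frag$coords,
                         site_elem = frag$elem,
                         ref_env = ref_env, radiating_state = 1L,
                         total_charge = 0)
  })
}

## stationary analysis of V(x) = a (x^2 - x0^2)^2 + c x
dw_stationary <- function(a, c, x0) {
  ## V'(x) = 4 a x^3 - 4 a x0^2 x + c
  r <- polyroot(c(c, -4 * a * x0^2, 0, 4 * a))
  r <- Re(r[abs(Im(r)) < 1e-8 * (1 + abs(Re(r)))])
  r <- sort(r)
  if (length(r) < 3) return(NULL)
  v <- a * (r^2 - x0^2)^2 + c * r
  list(x_min = r[c(1, 3)], x_max = r[2],
       v_min = v[c(1, 3)], v_max = v[2],
       barrier = v[2] - min(v[c(1, 3)]),
       asymmetry = abs(v[3] - v[1]))
}

#' Generate a double-well PES for the large-amplitude motion
#'
#' Quartic-plus-linear form V(x) = a (x^2 - x0^2)^2 + c x fitted so that
#' the interior maximum lies `barrier` above the deeper minimum and the
#' two minima differ by `asymmetry` (both in kJ/mol; the minima positions
#' shift slightly from +-`minima` under the tilt). Defaults emulate the
#' S1 carbonyl out-of-plane double well: 18 kJ/mol barrier, minima near
#' +-25 degrees, 4 degree grid step.
#'
#' @param barrier interior barrier height above the deeper minimum, kJ/mol
#' @param minima magnitude of the (untilted) minima positions, degrees
#' @param asymmetry energy difference between the two minima, kJ/mol
#'   (must be smaller than the barrier)
#' @param step grid step, degrees (default 4)
#' @param span half-width of the grid, degrees (default 60)
#' @param inertia effective inertia passed through to the `pes_curve`
#'   (atomic units; default 1e6, giving well frequencies of order
#'   100-150 cm^-1 for the default well)
#' @return a `pes_curve` with attributes `barrier_kJmol`,
#'   `asymmetry_kJmol` and `params` (fitted a, c, x0)
#' @export
gen_double_well <- function(barrier = 18, minima = 25, asymmetry = 0,
                            step = 4, span = 60, inertia = 1e6) {
  stopifnot(barrier > 0, asymmetry >= 0)
  if (asymmetry >= barrier)
    stop("asymmetry must be smaller than the barrier (no interior maximum)")
  x0 <- minima
  fit_c <- function(a) {
    if (asymmetry == 0) return(0)
    c_crit <- 8 * a * x0^3 / (3 * sqrt(3))   # tilt at which a well vanishes
    f <- function(cc) {
      st <- dw_stationary(a, cc, x0)
      if (is.null(st)) return(NA_real_)
      st$asymmetry - asymmetry
    }
    hi <- 0.999 * c_crit
    if (!is.finite(f(hi)) || f(hi) < 0)
      stop("parameters admit no interior maximum at requested asymmetry")
    stats::uniroot(f, c(1e-12, hi), tol = 1e-14)$root
  }
  g <- function(a) {
    st <- dw_stationary(a, fit_c(a), x0)
    st$barrier - barrier
  }
  gs <- function(a) tryCatch(g(a), error = function(e) NA_real_)
  a0 <- barrier / x0^4                      # exact for the symmetric case
  if (asymmetry == 0) {
    a_fit <- a0
  } else {
    ## the tilted problem is feasible only above a minimum quartic
    ## coefficient (below it the shallow well vanishes before the target
    ## asymmetry is reached); scan for a feasible sign-change bracket
    cand <- a0 * 2^seq(-8, 8, by = 0.25)
    vals <- vapply(cand, gs, 0)
    ok <- which(is.finite(vals))
    if (!length(ok) || all(vals[ok] > 0) || all(vals[ok] < 0))
      stop("parameters admit no interior maximum at requested asymmetry")
    i_hi <- ok[which(vals[ok] > 0)[1]]
    i_lo <- max(ok[ok < i_hi & vals[ok] < 0])
    a_fit <- stats::uniroot(g, c(cand[i_lo], cand[i_hi]), tol = 1e-15)$root
  }
  c_fit <- fit_c(a_fit)
  grid <- seq(-span, span, by = step)
  v <- a_fit * (grid^2 - x0^2)^2 + c_fit * grid
  st <- dw_stationary(a_fit, c_fit, x0)
  v <- v - min(st$v_min)                    # deeper minimum at zero
  pes <- pes_curve(grid, v * .const$kJmol_cm1, inertia)
  attr(pes, "barrier_kJmol") <- st$barrier
  attr(pes, "asymmetry_kJmol") <- st$asymmetry
  attr(pes, "params") <- c(a = a_fit, c = c_fit, x0 = x0)
  pes
}

#' Generate a displaced-oscillator mode set
#'
#' Frequencies are drawn in 200-1800 cm^-1; gradients are back-computed
#' from Huang-Rhys factors sampled in `S_range`, so
#' `vg_shifts(gen_mode_set(...))` recovers the requested S exactly.
#'
#' @param n_modes number of modes (>= 1)
#' @param S_range length-2 numeric range of Huang-Rhys factors
#' @param seed RNG seed
#' @param ht also draw dipole derivatives for Herzberg-Teller tests
#'   (default FALSE)
#' @return a `mode_set` with attribute `S` (the sampled factors)
#' @export
gen_mode_set <- function(n_modes = 10, S_range = c(0, 1), seed = 1L,
                         ht = FALSE) {
  stopifnot(n_modes >= 1, length(S_range) == 2)
  with_seed(seed, {
    freq <- sort(stats::runif(n_modes, 200, 1800))
    S <- stats::runif(n_modes, S_range[1], S_range[2])
    sgn <- sample(c(-1, 1), n_modes, replace = TRUE)
    delta <- sgn * sqrt(2 * S)
    gradient <- -delta * freq
    dmu <- if (ht) matrix(stats::rnorm(3 * n_modes, 0, 0.05), n_modes, 3)
    else matrix(0, n_modes, 3)
    ms <- mode_set(freq, gradient, dmu)
    attr(ms, "S") <- S
    ms
  })
}
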