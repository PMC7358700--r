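## Independent numerical oracles used by the test-suite. These deliberately
## avoid the package's own code paths: a hand-written cyclic Jacobi
## eigensolver, Rayleigh-Schroedinger perturbation theory, and quadrature
## of explicit Hermite functions.

## --- brute-force symmetric eigensolver (cyclic Jacobi rotations) --------
jacobi_eigen <- function(A, tol = 1e-14, max_sweeps = 100) {
  A <- as.matrix(A)
  n <- nrow(A)
  V <- diag(n)
  for (sweep in seq_len(max_sweeps)) {
    off <- sqrt(sum(A[upper.tri(A)]^2))
    if (off < tol * max(1, sqrt(sum(diag(A)^2)))) break
    for (p in 1:(n - 1)) for (q in (p + 1):n) {
      if (abs(A[p, q]) < 1e-300) next
      theta <- (A[q, q] - A[p, p]) / (2 * A[p, q])
      t <- sign(theta) / (abs(theta) + sqrt(theta^2 + 1))
      if (theta == 0) t <- 1
      cs <- 1 / sqrt(t^2 + 1)
      sn <- t * cs
      G <- diag(n); G[p, p] <- cs; G[q, q] <- cs
      G[p, q] <- sn; G[q, p] <- -sn
      A <- t(G) %*% A %*% G
      V <- V %*% G
    }
  }
  ord <- order(diag(A))
  list(values = diag(A)[ord], vectors = V[, ord, drop = FALSE])
}

## --- Rayleigh-Schroedinger perturbation theory to 2nd order -------------
rs_pt2 <- function(eps, V) {
  n <- length(eps)
  vapply(seq_len(n), function(i) {
    corr2 <- 0
    for (j in seq_len(n)) if (j != i)
      corr2 <- corr2 + V[i, j]^2 / (eps[i] - eps[j])
    eps[i] + V[i, i] + corr2
  }, 0)
}

## --- Hermite oscillator functions and quadrature FC overlaps ------------
hermite_poly <- function(n, x) {
  if (n == 0) return(rep(1, length(x)))
  if (n == 1) return(2 * x)
  Hm2 <- rep(1, length(x)); Hm1 <- 2 * x
  for (k in 2:n) {
    H <- 2 * x * Hm1 - 2 * (k - 1) * Hm2
    Hm2 <- Hm1; Hm1 <- H
  }
  Hm1
}
ho_wavefunction <- function(n, x) {
  hermite_poly(n, x) * exp(-x^2 / 2) /
    sqrt(2^n * factorial(n) * sqrt(pi))
}
## |<m | n, displaced by delta>|^2 by trapezoid quadrature
fc_overlap_sq_quadrature <- function(S, m, n, npts = 4001, span = 12) {
  delta <- sqrt(2 * S)
  x <- seq(-span, span + delta, length.out = npts)
  f <- ho_wavefunction(m, x) * ho_wavefunction(n, x - delta)
  dx <- x[2] - x[1]
  (sum(f) - (f[1] + f[npts]) / 2)^2 * dx^2
}
## <0 | Q | n, displaced>^2 by quadrature (dimensionless Q)
fcq_overlap_sq_quadrature <- function(S, n, npts = 4001, span = 12) {
  delta <- sqrt(2 * S)
  x <- seq(-span, span + delta, length.out = npts)
  f <- ho_wavefunction(0, x) * x * ho_wavefunction(n, x - delta)
  dx <- x[2] - x[1]
  (sum(f) - (f[1] + f[npts]) / 2)^2 * dx^2
}

## --- direct Coulomb sums (independent of the package implementation) ----
coulomb_phi_direct <- function(env, point_A) {
  b <- 1 / 0.529177210903
  tot <- 0
  for (s in seq_len(nrow(env))) {
    d <- sqrt(sum((c(env$x[s], env$y[s], env$z[s]) - point_A)^2)) * b
    tot <- tot + env$q[s] / d
  }
  tot
}

## --- misc fixtures -------------------------------------------------------
make_harmonic_pes <- function(omega_cm1 = 500, inertia = 1e6, n = 251,
                              nsigma = 6) {
  hart <- 219474.6313632
  w_au <- omega_cm1 / hart
  sigma_rad <- 1 / sqrt(inertia * w_au)
  x_deg <- seq(-nsigma * sigma_rad, nsigma * sigma_rad,
               length.out = n) * 180 / pi
  v_cm1 <- 0.5 * inertia * w_au^2 * (x_deg * pi / 180)^2 * hart
  pes_curve(x_deg, v_cm1, inertia)
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
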