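## Vertical-Gradient vibronic stick spectra in the time-independent
## sum-over-states picture: Huang-Rhys factors from final-state gradients,
## analytic displaced-oscillator Franck-Condon factors, class-based stick
## enumeration with prescreening, and optional Herzberg-Teller terms
## linear in the dipole derivatives.

#' Huang-Rhys factors and reorganization energy of a mode set
#'
#' In the vertical-gradient model the dimensionless displacement of each
#' initial-state normal mode is delta_k = -g_k / omega_k (gradient and
#' frequency in consistent reduced units), the Huang-Rhys factor is
#' S_k = delta_k^2 / 2 and the reorganization energy is
#' lambda = sum_k S_k omega_k. Removed modes are excluded from all sums.
#'
#' @param modes a `mode_set`
#' @return list: `delta`, `S`, `lambda_cm1`, `active` (indices of modes
#'   kept)
#' @export
vg_shifts <- function(modes) {
  active <- which(!modes$removed)
  w <- modes$freq[active]; g <- modes$gradient[active]
  if (any(w == 0 & g != 0))
    stop("zero-frequency mode with nonzero gradient")
  delta <- numeric(length(modes$freq))
  delta[active] <- -g / w
  S <- delta^2 / 2
  S[-active] <- 0
  list(delta = delta, S = S,
       lambda_cm1 = sum(S[active] * modes$freq[active]),
       active = active)
}

#' Generalized Laguerre polynomial (small orders, by recurrence)
#' @keywords internal
laguerre_gen <- function(n, a, x) {
  if (n == 0) return(rep(1, length(x)))
  if (n == 1) return(1 + a - x)
  Lm2 <- rep(1, length(x)); Lm1 <- 1 + a - x
  for (k in 2:n) {
    L <- ((2 * k - 1 + a - x) * Lm1 - (k - 1 + a) * Lm2) / k
    Lm2 <- Lm1; Lm1 <- L
  }
  Lm1
}

#' Squared Franck-Condon overlap of equal-frequency displaced oscillators
#'
#' Closed form via associated Laguerre polynomials: for n >= m,
#' |<m|n>|^2 = e^-S S^(n-m) (m!/n!) [L_m^(n-m)(S)]^2, symmetric in (m, n).
#' At m = 0 this is the Poisson progression e^-S S^n / n!.
#'
#' @param S Huang-Rhys factor (>= 0)
#' @param n_init initial-state quantum number (>= 0)
#' @param n_final final-state quantum number (>= 0)
#' @return squared overlap in [0, 1]
#' @export
fc_overlap_sq <- function(S, n_init, n_final) {
  stopifnot(S >= 0, n_init >= 0, n_final >= 0)
  if (S == 0) return(as.numeric(n_init == n_final))
  m <- min(n_init, n_final); n <- max(n_init, n_final)
  exp(-S + (n - m) * log(S) + lfactorial(m) - lfactorial(n)) *
    laguerre_gen(m, n - m, S)^2
}

## signed overlap amplitudes <0 | n'> and <0 | Q | n'> for a final state
## displaced by delta (dimensionless Q convention: Q = (a + a^dag)/sqrt(2)).
## With alpha = delta / sqrt(2), S = alpha^2:
##   <0|n'>   = e^(-S/2) (-alpha)^n / sqrt(n!)
##   <0|Q|n'> = <1|n'> / sqrt(2),  <1|n'> = e^(-S/2) (-alpha)^(n-1) (n - S) / sqrt(n!)
fc_amp0 <- function(delta, n) {
  alpha <- delta / sqrt(2); S <- alpha^2
  exp(-S / 2) * (-alpha)^n / sqrt(factorial(n))
}
fcq_amp0 <- function(delta, n) {
  alpha <- delta / sqrt(2); S <- alpha^2
  amp1 <- if (n == 0) alpha * exp(-S / 2)
  else exp(-S / 2) * (-alpha)^(n - 1) * (n - S) / sqrt(factorial(n))
  amp1 / sqrt(2)
}

#' Enumerate vibronic sticks by excitation class
#'
#' Builds the 0 K time-independent stick spectrum of the vertical-gradient
#' model. Sticks are organized by class (the number of simultaneously
#' excited final-state modes): class 0 is the 0-0 line, class 1 runs each
#' mode up to `C1max` quanta, class 2 pairs of modes up to `C2max` quanta
#' each; classes >= 3 (up to `max_class`) enumerate mode combinations
#' ranked by the product of their single-mode maximum FC weights, with the
#' per-mode quanta cap halved for each class beyond 2. The total number of
#' evaluated integrals never exceeds `NImax`; on truncation the recovered
#' intensity fraction is recorded.
#'
#' With `model = "FCHT"` the transition-dipole expansion
#' mu(Q) = mu0 + sum_k dmu_k Q_k adds Herzberg-Teller amplitudes through
#' the analytic <0|Q_k|n_k> matrix elements; each stick then carries its
#' FC, HT and interference contributions to the electric intensity
#' separately, plus the signed rotatory weight against the equilibrium
#' magnetic moment (which carries no HT terms).
#'
#' @param modes a `mode_set`
#' @param model `"FC"` or `"FCHT"`
#' @param prescreen list with `C1max` (50), `C2max` (30), `NImax` (1e9)
#' @param mu0 equilibrium electric transition dipole, a.u. 3-vector
#' @param m0 equilibrium magnetic transition dipole, a.u. 3-vector
#' @param max_class highest excitation class enumerated (default 4)
#' @param weight_floor sticks with vibrational weight below this are not
#'   stored (default 1e-10)
#' @return object of class `stick_spectrum`: data.frame `sticks` with
#'   columns `energy` (offset from the 0-0 line, cm^-1), `w_vib`
#'   (pure vibrational FC weight, product of squared overlaps), `w_el`
#'   (electric intensity |mu_eff|^2 incl. HT), `w_fc`, `w_ht`, `w_int`
#'   (decomposition of `w_el`), `w_rot` (signed rotatory weight),
#'   `class`, `quanta`; plus `n_integrals`, `truncated`, `model`
#' @export
enumerate_sticks <- function(modes, model = c("FC", "FCHT"),
                             prescreen = list(C1max = 50, C2max = 30,
                                              NImax = 1e9),
                             mu0 = c(1, 0, 0), m0 = c(0, 0, 0),
                             max_class = 4, weight_floor = 1e-10) {
  model <- match.arg(model)
  sh <- vg_shifts(modes)
  active <- sh$active
  nm <- length(active)
  C1 <- prescreen$C1max %||% 50
  C2 <- prescreen$C2max %||% 30
  NImax <- prescreen$NImax %||% 1e9
  ht_on <- model == "FCHT"
  dmu <- modes$dmu_dQ
  w <- modes$freq
  delta <- sh$delta
  ## per-active-mode single-excitation amplitude tables (quanta 0..C1)
  amp <- vector("list", length(w)); qamp <- vector("list", length(w))
  for (k in active) {
    ns <- 0:C1
    amp[[k]] <- vapply(ns, function(n) fc_amp0(delta[k], n), 0)
    qamp[[k]] <- vapply(ns, function(n) fcq_amp0(delta[k], n), 0)
  }
  n_int <- 0L
  truncated <- FALSE
  rows <- list()
  emit <- function(energy, qn_modes, qn_quanta, cls) {
    ## vibrational amplitude: product over excited modes of <0|n_k'>;
    ## unexcited active modes contribute their <0|0'> factor
    a_exc <- 1
    for (t in seq_along(qn_modes))
      a_exc <- a_exc * amp[[qn_modes[t]]][qn_quanta[t] + 1L]
    a00 <- prod(vapply(active, function(k) amp[[k]][1], 0))
    denom0 <- prod(vapply(qn_modes, function(k) amp[[k]][1], 0))
    a_vib <- if (length(qn_modes)) a_exc * a00 / denom0 else a00
    w_vib <- a_vib^2
    ## electric amplitude vector (FC + HT)
    A <- mu0 * a_vib
    if (ht_on) {
      for (k in active) {
        nk <- { t <- match(k, qn_modes); if (is.na(t)) 0L else qn_quanta[t] }
        ak <- amp[[k]][nk + 1L]
        rest <- if (abs(ak) > 0) a_vib / ak else {
          r <- 1
          for (kk in setdiff(active, k)) {
            nkk <- { t <- match(kk, qn_modes); if (is.na(t)) 0L else qn_quanta[t] }
            r <- r * amp[[kk]][nkk + 1L]
          }
          r
        }
        A <- A + dmu[k, ] * qamp[[k]][nk + 1L] * rest
      }
    }
    w_fc <- sum((mu0 * a_vib)^2)
    w_el <- sum(A^2)
    Hvec <- A - mu0 * a_vib
    w_ht <- sum(Hvec^2)
    w_int <- w_el - w_fc - w_ht
    w_rot <- sum(A * m0) * a_vib      # magnetic amplitude is FC-only
    if (w_vib >= weight_floor || w_el >= weight_floor)
      rows[[length(rows) + 1L]] <<- list(
        energy = energy, w_vib = w_vib, w_el = w_el, w_fc = w_fc,
        w_ht = w_ht, w_int = w_int, w_rot = w_rot, class = cls,
        quanta = if (length(qn_modes))
          paste(sprintf("%d^%d", qn_modes, qn_quanta), collapse = ",")
        else "0-0")
    n_int <<- n_int + 1L
  }
  ## class 0
  emit(0, integer(0), integer(0), 0L)
  ## class 1
  for (k in active) {
    for (n in seq_len(C1)) {
      if (n_int >= NImax) { truncated <- TRUE; break }
      emit(n * w[k], k, n, 1L)
    }
    if (truncated) break
  }
  ## classes >= 2: combinations ranked by product of single-mode maxima
  if (nm >= 2 && max_class >= 2 && !truncated) {
    score1 <- vapply(active, function(k) max(amp[[k]][-1]^2), 0)
    names(score1) <- as.character(active)
    for (cls in 2:min(max_class, nm)) {
      cap <- max(1L, as.integer(C2 %/% 2^(cls - 2L)))
      combs <- utils::combn(active, cls)
      sc <- apply(combs, 2, function(ks) prod(score1[as.character(ks)]))
      ord <- order(sc, decreasing = TRUE)
      for (ci in ord) {
        ks <- combs[, ci]
        grids <- rep(list(seq_len(cap)), cls)
        qn <- as.matrix(expand.grid(grids))
        for (r in seq_len(nrow(qn))) {
          if (n_int >= NImax) { truncated <- TRUE; break }
          emit(sum(qn[r, ] * w[ks]), ks, as.integer(qn[r, ]), cls)
        }
        if (truncated) break
      }
      if (truncated) break
    }
  }
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(r, stringsAsFactors = FALSE)))
  if (is.null(df))
    df <- data.frame(energy = numeric(0), w_vib = numeric(0),
                     w_el = numeric(0), w_fc = numeric(0),
                     w_ht = numeric(0), w_int = numeric(0),
                     w_rot = numeric(0), class = integer(0),
                     quanta = character(0))
  structure(list(sticks = df, n_integrals = n_int, truncated = truncated,
                 model = model, mu0 = mu0, m0 = m0,
                 lambda_cm1 = sh$lambda_cm1),
            class = "stick_spectrum")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.stick_spectrum <- function(x, ...) {
  cat(sprintf("stick_spectrum (%s): %d sticks, %d integrals%s\n",
              x$model, nrow(x$sticks), x$n_integrals,
              if (x$truncated) " [truncated]" else ""))
  cat(sprintf("  FC progress: %.6f; reorganization energy %.1f cm^-1\n",
              spectral_progress(x), x$lambda_cm1))
  invisible(x)
}

#' Fraction of total Franck-Condon intensity recovered
#'
#' For a normalized 0 K FC spectrum the analytic total vibrational weight
#' is 1; the ratio of the summed stick weights to that total measures the
#' convergence of the truncated sum-over-states.
#'
#' @param sticks a `stick_spectrum` (FC weights are used)
#' @return recovered fraction in [0, 1]
#' @export
spectral_progress <- function(sticks) {
  if (!nrow(sticks$sticks)) return(1.0)
  sum(sticks$sticks$w_vib)
}
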