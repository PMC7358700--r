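test_that("Boltzmann weights reproduce closed forms", {
  expect_equal(boltzmann_weights(c(0, 0)), c(0.5, 0.5))
  RT_ln2 <- chirospect_constants$R_JmolK * 300 * log(2) / 1000
  expect_equal(boltzmann_weights(c(0, RT_ln2), 300), c(2 / 3, 1 / 3),
               tolerance = 1e-12)
  ## order invariance
  w <- boltzmann_weights(c(3, 0, 7), 250)
  expect_equal(boltzmann_weights(c(7, 0, 3), 250), w[c(3, 2, 1)],
               tolerance = 1e-15)
})

test_that("Gaussian broadening has the analytic peak height and conserves weight", {
  hwhm <- 120
  b <- broaden(5000, 1, hwhm, grid = seq(3000, 7000, 1))
  expect_lt(abs(max(b$intensity) - sqrt(log(2) / pi) / hwhm), 1e-9)
  expect_lt(abs(trapz(b$grid, b$intensity) - 1), 1e-6)

  ## two equal sticks 10 HWHM apart -> two resolved equal maxima
  b2 <- broaden(c(4000, 4000 + 10 * hwhm), c(1, 1), hwhm,
                grid = seq(2000, 8000, 1))
  peaks <- which(diff(sign(diff(b2$intensity))) < 0) + 1
  expect_length(peaks, 2)
  expect_lt(abs(b2$intensity[peaks[1]] - b2$intensity[peaks[2]]), 1e-12)

  ## integral conservation on a random signed stick set
  set.seed(3)
  e <- runif(20, 10000, 20000); wts <- rnorm(20)
  b3 <- broaden(e, wts, 200)
  expect_lt(abs(trapz(b3$grid, b3$intensity) - sum(wts)), 1e-6 * sum(abs(wts)))
})

test_that("prefactors scale linearly for absorption, cubically for emission", {
  expect_equal(prefactor("OPA", 2000) / prefactor("OPA", 1000), 2)
  expect_equal(prefactor("OPE", 2000) / prefactor("OPE", 1000), 8)
  expect_equal(prefactor("ECD", 1500, enabled = FALSE), 1)
  expect_error(prefactor("XYZ", 1000))
})

make_ref_and_frames <- function(seed = 201, n_frames = 3, angle = 30,
                                jitter = 0) {
  sp <- fixture_spec(seed = seed, n_frames = n_frames,
                     propensities = c(1, 0, 0, 0), n_far = 2)
  frames <- gen_solvent_frames(sp)$frames
  ref <- gen_reference_electronic(5, seed = seed + 1, angle_deg = angle,
                                  ref_env = frames[[1]]$env)
  list(ref = ref, frames = frames)
}

test_that("electronic bands combine clusters convexly and propagate sign", {
  fx <- make_ref_and_frames()
  ens <- ensemble_sticks(fx$ref, fx$frames)
  grid <- seq(25000, 45000, 10)
  one <- electronic_band(ens, "OPA", hwhm = 900, grid = grid)
  ## equal cluster spectra with weights (0.3, 0.7) equal either alone
  both <- electronic_band(list(ens, ens), "OPA", populations = c(0.3, 0.7),
                          hwhm = 900, grid = grid)
  expect_equal(both$intensity, one$intensity, tolerance = 1e-12)

  ## single frame: band centered at its transition energy
  ens1 <- ensemble_sticks(fx$ref, fx$frames[1])
  b1 <- electronic_band(ens1, "OPA", hwhm = 900, grid = grid,
                        use_prefactor = FALSE)
  expect_lt(abs(b1$grid[which.max(b1$intensity)] - ens1$sticks$E_cm1[1]),
            20)

  ## negative rotatory strength -> strictly negative ECD band
  fx_neg <- make_ref_and_frames(seed = 301, angle = 170)
  ens_neg <- ensemble_sticks(fx_neg$ref, fx_neg$frames)
  expect_true(all(ens_neg$sticks$R_au < 0))
  ecd <- electronic_band(ens_neg, "ECD", hwhm = 900, grid = grid)
  core <- abs(ecd$grid - mean(ens_neg$sticks$E_cm1)) < 2000
  expect_true(all(ecd$intensity[core] < 0))
})

test_that("combined FC band reduces to the reference vibronic band for the identity frame", {
  fx <- make_ref_and_frames(n_frames = 1)
  ## the frame environment IS the reference environment
  ens <- ensemble_sticks(fx$ref, fx$frames[1])
  expect_lt(abs(ens$mean_shift), 1e-9)
  ms <- gen_mode_set(4, c(0.1, 0.7), seed = 8)
  st <- enumerate_sticks(ms, "FC", mu0 = fx$ref$elec_dipole[1, 2, ],
                         m0 = fx$ref$mag_dipole[2, ])
  grid <- seq(20000, 40000, 10)
  comb <- suppressWarnings(
    combine_fc(st, ens, fx$ref, "OPE", hwhm = 450, grid = grid))
  ref_band <- suppressWarnings(
    vibronic_band(st, ens$sticks$E_cm1[1], "OPE", hwhm = 450, grid = grid))
  expect_identical(comb$intensity, ref_band$intensity)
})

test_that("combined FC band averages shifted copies linearly", {
  fx <- make_ref_and_frames(n_frames = 1)
  ens <- ensemble_sticks(fx$ref, fx$frames[1])
  ## fabricate a two-frame record with +-500 cm-1 shifts, equal scale
  ens2 <- ens
  ens2$sticks <- rbind(ens$sticks, ens$sticks)
  ens2$sticks$frame <- 1:2
  ens2$sticks$E_cm1 <- ens$sticks$E_cm1[1] + c(-500, 500)
  ms <- gen_mode_set(3, c(0.2, 0.5), seed = 5)
  st <- enumerate_sticks(ms, "FC", mu0 = fx$ref$elec_dipole[1, 2, ],
                         m0 = fx$ref$mag_dipole[2, ])
  grid <- seq(18000, 42000, 10)
  comb <- suppressWarnings(
    combine_fc(st, ens2, fx$ref, "OPA", hwhm = 450, grid = grid,
               use_prefactor = FALSE))
  lo <- suppressWarnings(
    vibronic_band(st, ens2$sticks$E_cm1[1], "OPA", 450, grid,
                  use_prefactor = FALSE))
  hi <- suppressWarnings(
    vibronic_band(st, ens2$sticks$E_cm1[2], "OPA", 450, grid,
                  use_prefactor = FALSE))
  expect_equal(comb$intensity, (lo$intensity + hi$intensity) / 2,
               tolerance = 1e-12)
})

test_that("ensemble energy fluctuations add variances in the combined band", {
  ## frames with Gaussian-distributed transition-energy shifts: the
  ## combined band's second moment must equal vibronic + shift + broadening
  fx <- make_ref_and_frames(n_frames = 1)
  ens <- ensemble_sticks(fx$ref, fx$frames[1])
  sigma <- 300
  n_syn <- 2000
  set.seed(99)
  shifts <- rnorm(n_syn, 0, sigma)
  ens_syn <- ens
  ens_syn$sticks <- ens$sticks[rep(1, n_syn), ]
  ens_syn$sticks$frame <- seq_len(n_syn)
  ens_syn$sticks$E_cm1 <- ens$sticks$E_cm1[1] + shifts
  ms <- gen_mode_set(3, c(0.3, 0.8), seed = 6)
  st <- enumerate_sticks(ms, "FC", mu0 = c(0.5, 0, 0))
  hwhm <- 450
  grid <- seq(15000, 50000, 20)
  comb <- suppressWarnings(
    combine_fc(st, ens_syn, fx$ref, "OPA", hwhm = hwhm, grid = grid,
               use_prefactor = FALSE))
  m2 <- function(x, y) {
    y <- pmax(y, 0); mu <- trapz(x, x * y) / trapz(x, y)
    trapz(x, (x - mu)^2 * y) / trapz(x, y)
  }
  wv <- st$sticks$w_vib
  e_mean <- sum(st$sticks$energy * wv) / sum(wv)
  var_vib <- sum((st$sticks$energy - e_mean)^2 * wv) / sum(wv)
  var_broad <- hwhm^2 / (2 * log(2))
  var_shift <- var(shifts) * (n_syn - 1) / n_syn
  expected <- var_vib + var_shift + var_broad
  expect_lt(abs(m2(comb$grid, comb$intensity) - expected) / expected, 0.02)
})

test_that("the half-fluctuation rule composes the Herzberg-Teller increment", {
  grid <- seq(0, 4000, 2)
  mk_band <- function(w) broaden(c(1000, 2000, 3000), w, 150, grid)
  fc_ref <- mk_band(c(1, 0.5, 0.2))
  fcht_ref <- mk_band(c(1.2, 0.45, 0.3))
  ## <f> = 1, zero shifts -> FCHT band reproduced exactly
  fc_comb <- fc_ref
  fc_comb$provenance <- list(mean_f = 1, frame_shifts = 0)
  out <- combine_fcht(fc_comb, fc_ref, fcht_ref)
  expect_equal(out$intensity, fcht_ref$intensity, tolerance = 1e-12)

  ## zero HT difference -> combined FC unchanged
  out2 <- combine_fcht(fc_comb, fc_ref, fc_ref)
  expect_equal(out2$intensity, fc_comb$intensity)

  ## <f> = 1.4 -> increment scaled by 1.2 (hand-computed composition)
  fc_comb3 <- fc_ref
  fc_comb3$provenance <- list(mean_f = 1.4, frame_shifts = 0)
  out3 <- combine_fcht(fc_comb3, fc_ref, fcht_ref)
  manual <- fc_ref$intensity +
    1.2 * (fcht_ref$intensity - fc_ref$intensity)
  expect_equal(out3$intensity, manual, tolerance = 1e-12)

  ## grid mismatch is rejected
  short <- broaden(1000, 1, 150, grid = seq(0, 4000, 4))
  expect_error(combine_fcht(fc_comb, short, fcht_ref), "grid")
})

test_that("conformer assembly is a Boltzmann-weighted convex combination", {
  grid <- seq(0, 1000, 1)
  up <- broaden(500, 1, 50, grid, kind = "CPL")
  down <- broaden(500, -1, 50, grid, kind = "CPL")
  ## opposite equal-magnitude CPL at dG = (0, 0) cancels exactly
  tot <- assemble_emission(list(up, down), c(0, 0))
  expect_true(all(abs(tot$intensity) < 1e-15))
  ## single conformer is the identity
  one <- assemble_emission(list(up), 0)
  expect_equal(one$intensity, up$intensity)
  ## permuting conformers never changes the result
  a <- broaden(400, 1, 50, grid, kind = "CPL")
  b <- broaden(600, -2, 50, grid, kind = "CPL")
  t1 <- assemble_emission(list(a, b), c(0, 2))
  t2 <- assemble_emission(list(b, a), c(2, 0))
  expect_equal(t1$intensity, t2$intensity, tolerance = 1e-12)
})

test_that("opposite-sign conformers give a bisignate CPL whose crossing tracks the amplitude ratio", {
  grid <- seq(0, 2000, 1)
  crossings <- vapply(c(2, 5, 10), function(ratio) {
    b1 <- broaden(800, 1, 150, grid, kind = "CPL")
    b2 <- broaden(1200, -ratio, 150, grid, kind = "CPL")
    tot <- assemble_emission(list(b1, b2), c(0, 8.73))
    s <- sign(tot$intensity)
    idx <- which(diff(s[s != 0]) != 0)
    x <- grid[s != 0]
    x[idx[1]]
  }, 0)
  expect_length(unique(sign(diff(crossings))), 1)  # monotone shift
  ## and the band is genuinely bisignate for the middle ratio
  b1 <- broaden(800, 1, 150, grid, kind = "CPL")
  b2 <- broaden(1200, -5, 150, grid, kind = "CPL")
  tot <- assemble_emission(list(b1, b2), c(0, 8.73))
  expect_true(any(tot$intensity > 1e-6) && any(tot$intensity < -1e-6))
})

test_that("assembly plans validate their cluster populations", {
  expect_error(assembly_plan(c(0, 8), list(c(0.5, 0.4))), "sum to 1")
  pl <- assembly_plan(c(0, 8.73), list(c(0.58, 0.19, 0.215, 0.015),
                                       c(0.65, 0.174, 0.169, 0.007)))
  expect_s3_class(pl, "assembly_plan")
})
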