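frag <- carbonyl_fragment()

pracma_cross <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

test_that("virtual sites sit at the lone-pair geometry, mirrored about C=O", {
  vs <- place_virtual_sites(frag$coords, frag$elem, "ground")
  O <- frag$coords[2, ]; C <- frag$coords[1, ]
  for (v in list(vs$vs1, vs$vs2)) {
    expect_lt(abs(sqrt(sum((v - O)^2)) - 0.3067), 1e-6)
    u1 <- (C - O) / sqrt(sum((C - O)^2))
    u2 <- (v - O) / sqrt(sum((v - O)^2))
    expect_lt(abs(acos(sum(u1 * u2)) * 180 / pi - 111.3), 1e-4)
  }
  ## mirror images through the C=O axis plane (here the xz plane)
  expect_equal(vs$vs1[1], vs$vs2[1], tolerance = 1e-12)
  expect_equal(vs$vs1[2], -vs$vs2[2], tolerance = 1e-12)
  ## ground state: both VSs in the molecular (xy) plane
  expect_lt(abs(vs$vs1[3]), 1e-12)
  expect_lt(abs(vs$vs2[3]), 1e-12)
})

test_that("excited-state virtual sites lie in the orthogonal plane", {
  ## pyramidalized fragment: O lifted out of the C-C-C plane
  coords <- frag$coords
  coords[2, ] <- c(1.15, 0, 0.4)
  vs <- place_virtual_sites(coords, frag$elem, "excited")
  O <- coords[2, ]; C <- coords[1, ]
  ## explicit cross-product check of the plane constraint
  n_ccc <- c(0, 0, 1)                       # C, C1, C2 span the xy plane
  u <- O - C
  n_p1 <- pracma_cross(n_ccc, u)            # normal of span{n_ccc, u}
  n_vs <- pracma_cross(vs$vs1 - O, vs$vs2 - O)
  cosang <- sum(n_vs * n_p1) /
    sqrt(sum(n_vs^2) * sum(n_p1^2))
  ## perpendicular planes have perpendicular normals
  expect_lt(abs(cosang), 1e-6)
  ## distances and angles still hold
  expect_lt(abs(sqrt(sum((vs$vs1 - O)^2)) - 0.3067), 1e-6)
  ## degenerate geometry errors
  bad <- coords; bad[3, ] <- bad[4, ]
  expect_error(place_virtual_sites(bad, frag$elem, "ground"), "degenerate")
})

test_that("virtual-site charge fitting solves the scalar least squares", {
  vs <- place_virtual_sites(frag$coords, frag$elem, "ground")
  base <- c(0.45, -0.5, 0.02, 0.03)
  b <- 1 / chirospect_constants$bohr_A
  mu_base <- colSums(frag$coords * b * base)

  ## target equal to the base dipole -> q = 0
  fit0 <- fit_vs_charges(base, frag$coords, vs, mu_base, o_index = 2)
  expect_lt(abs(fit0$q_vs), 1e-12)

  ## target shifted along the VS bisector: closed-form single unknown
  d <- (vs$vs1 + vs$vs2 - 2 * frag$coords[2, ]) * b
  target <- mu_base + 0.17 * d
  fit <- fit_vs_charges(base, frag$coords, vs, target, o_index = 2)
  expect_lt(abs(fit$q_vs - 0.17), 1e-10)
  expect_lt(fit$residual, 1e-10)

  ## charge conservation: total charge unchanged
  total_before <- sum(base)
  total_after <- sum(base[-2]) + fit$o_charge + 2 * fit$q_vs
  expect_lt(abs(total_after - total_before), 1e-12)

  ## residual orthogonal to the displacement direction -> flagged
  perp <- c(-d[2], d[1], 0)
  fit_ill <- fit_vs_charges(base, frag$coords, vs, mu_base + perp,
                            o_index = 2)
  expect_true(fit_ill$ill_conditioned)
})

test_that("F function hits its defining values and is monotone", {
  expect_equal(f_function(1.8, 6), 1)
  expect_equal(f_function(2.0, 6), 0.5)
  expect_equal(f_function(1.6, 6), 0.5)      # penalized inside optimum too
  expect_equal(f_function(2.0, 11), 0.25)
  ## separately non-increasing in |r - r0| and |theta - theta0|
  r <- seq(1.8, 3, by = 0.05)
  expect_true(all(diff(f_function(r, 6)) <= 0))
  expect_true(all(diff(f_function(rev(seq(0.5, 1.8, by = 0.05)), 6)) <= 0))
  th <- seq(6, 40, by = 1)
  expect_true(all(diff(f_function(1.8, th)) <= 0))
})

make_frame_with_methanols <- function(geoms) {
  ## geoms: list of list(vs = 1|2, r, theta) placed deterministically
  vs <- place_virtual_sites(frag$coords, frag$elem, "ground")
  o_sol <- frag$coords[2, ]
  parts <- list()
  for (i in seq_along(geoms)) {
    g <- geoms[[i]]
    vsc <- if (g$vs == 1) vs$vs1 else vs$vs2
    d <- (vsc - o_sol) / sqrt(sum((vsc - o_sol)^2))
    H <- vsc + g$r * d
    p <- c(0, 0, 1)
    dev <- g$theta * pi / 180
    o_dir <- cos(pi - dev) * (-d) + sin(pi - dev) * p
    Om <- H + 0.96 * o_dir
    ch3 <- Om + 1.42 * o_dir
    parts[[i]] <- data.frame(
      x = c(Om[1], H[1], ch3[1]), y = c(Om[2], H[2], ch3[2]),
      z = c(Om[3], H[3], ch3[3]), q = c(-0.7, 0.435, 0.265),
      resid = i, role = c("O", "H", "CH3"))
  }
  env <- if (length(parts)) do.call(rbind, parts) else
    data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
               q = numeric(0), resid = integer(0), role = character(0))
  list(frame = md_frame(1, frag$elem, frag$coords, env), vs = vs)
}

test_that("hydrogen bonds are assigned greedily with one methanol per VS", {
  ## optimal methanol at VS1, nothing near VS2
  fx <- make_frame_with_methanols(list(list(vs = 1, r = 1.8, theta = 6)))
  rec <- assign_hbonds(fx$frame, fx$vs)
  expect_true(rec$vs1$bonded)
  expect_false(rec$vs2$bonded)
  expect_equal(rec$vs1$F, 1, tolerance = 1e-9)
  expect_identical(classify_frame(rec), "HB-VS1")

  ## two methanols, one per VS -> twoHB
  fx2 <- make_frame_with_methanols(list(list(vs = 1, r = 1.8, theta = 6),
                                        list(vs = 2, r = 1.85, theta = 8)))
  rec2 <- assign_hbonds(fx2$frame, fx2$vs)
  expect_true(rec2$vs1$bonded && rec2$vs2$bonded)
  expect_identical(classify_frame(rec2), "twoHB")

  ## empty environment -> F = 0 records
  fx0 <- make_frame_with_methanols(list())
  rec0 <- assign_hbonds(fx0$frame, fx0$vs)
  expect_equal(rec0$vs1$F, 0)
  expect_identical(classify_frame(rec0), "noHB")
})

test_that("a methanol optimal for both sites binds only the higher-F site", {
  ## single methanol exactly on the C=O axis beyond O: symmetric w.r.t.
  ## both VSs -> tie, must go to VS1, the other site stays empty
  vs <- place_virtual_sites(frag$coords, frag$elem, "ground")
  O <- frag$coords[2, ]; C <- frag$coords[1, ]
  d <- (O - C) / sqrt(sum((O - C)^2))
  H <- O + 2.1 * d
  Om <- H + 0.96 * d
  env <- data.frame(x = c(Om[1], H[1], Om[1] + 1.4),
                    y = c(Om[2], H[2], Om[2]),
                    z = c(Om[3], H[3], Om[3]),
                    q = c(-0.7, 0.435, 0.265), resid = 1L,
                    role = c("O", "H", "CH3"))
  fr <- md_frame(1, frag$elem, frag$coords, env)
  rec <- assign_hbonds(fr, vs, threshold = 1e-6)
  ## tie broken to VS1; the single residue is assigned only once
  expect_true(rec$vs1$bonded)
  expect_false(rec$vs2$bonded)
  expect_true(is.na(rec$vs2$resid) || rec$vs2$resid != rec$vs1$resid)
})

test_that("frame classification applies the strict 0.7 threshold", {
  mk <- function(F1, F2)
    structure(list(frame = 1L,
                   vs1 = list(F = F1, bonded = F1 >= 0.7),
                   vs2 = list(F = F2, bonded = F2 >= 0.7)),
              class = "hb_record")
  expect_identical(classify_frame(mk(0.9, 0.1)), "HB-VS1")
  expect_identical(classify_frame(mk(0.75, 0.8)), "twoHB")
  expect_identical(classify_frame(mk(0.69, 0.69)), "noHB")
  expect_identical(classify_frame(mk(0.7, 0.69)), "HB-VS1")
})

test_that("cluster populations count exactly and sum to 100", {
  p <- cluster_populations(c("noHB", "noHB", "HB-VS1", "twoHB"))
  expect_equal(unname(p), c(50, 25, 0, 25))
  expect_identical(sum(p), 100)
  p2 <- cluster_populations(rep("noHB", 7))
  expect_equal(unname(p2), c(100, 0, 0, 0))
  expect_error(cluster_populations(character(0)))
})

test_that("classification is invariant under residue relabeling", {
  fx <- make_frame_with_methanols(list(list(vs = 1, r = 1.82, theta = 7),
                                       list(vs = 2, r = 1.9, theta = 5)))
  fr <- fx$frame
  lab1 <- classify_frame(assign_hbonds(fr, fx$vs))
  ## permute residues (swap ids and row order)
  env <- fr$env
  env$resid <- ifelse(env$resid == 1L, 2L, 1L)
  env <- env[order(env$resid), ]
  fr2 <- md_frame(1, frag$elem, frag$coords, env)
  lab2 <- classify_frame(assign_hbonds(fr2, fx$vs))
  expect_identical(lab1, lab2)
})

test_that("collective frames average charges and respect the radius cut", {
  sp <- fixture_spec(seed = 21, n_frames = 6, propensities = c(0, 1, 0, 0),
                     n_far = 1)
  frames <- gen_solvent_frames(sp)$frames
  ## n identical frames -> collective charges equal one frame's charges
  same <- rep(frames[1], 4)
  cf <- build_collective_frame(same, n = 4, radius = 30)
  expect_equal(sort(tapply(cf$env$q, interaction(round(cf$env$x, 6),
                                                 round(cf$env$y, 6)), sum)),
               sort(frames[[1]]$env$q), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_lt(abs(cf$total_charge - cf$mean_source_charge), 1e-9)

  ## 2 frames with disjoint single charges q -> two sites of q/2
  f1 <- md_frame(1, frag$elem, frag$coords,
                 data.frame(x = 5, y = 0, z = 0, q = 0.4, resid = 1L,
                            role = "O"))
  f2 <- md_frame(2, frag$elem, frag$coords,
                 data.frame(x = -5, y = 0, z = 0, q = 0.4, resid = 1L,
                            role = "O"))
  cf2 <- build_collective_frame(list(f1, f2), n = 2)
  expect_equal(cf2$env$q, c(0.2, 0.2))

  ## a site at 31 A is excluded
  f3 <- md_frame(3, frag$elem, frag$coords,
                 data.frame(x = c(5, 31.5), y = 0, z = 0,
                            q = c(0.4, 9), resid = 1:2, role = "O"))
  cf3 <- build_collective_frame(list(f3), n = 1)
  expect_equal(nrow(cf3$env), 1L)

  ## fewer frames than requested -> warn and rescale
  expect_warning(build_collective_frame(list(f1, f2), n = 5), "using all")
})

test_that("trajectory partitioning recovers constructed propensities", {
  sp <- fixture_spec(seed = 5, n_frames = 400,
                     propensities = c(0.5, 0.2, 0.25, 0.05))
  g <- gen_solvent_frames(sp)
  part <- partition_trajectory(g$frames)
  expect_identical(unname(part$labels), unname(g$labels))
  expect_equal(sum(part$populations), 100)
  expect_named(part$populations, c("noHB", "HB-VS1", "HB-VS2", "twoHB"))
  ## partition records expose the raw per-VS F values
  expect_true(all(part$records$F_VS1 >= 0 & part$records$F_VS1 <= 1))
})
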