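## Solute-solvent hydrogen-bond analysis: carbonyl lone-pair virtual sites,
## the smooth geometric F score, per-frame bond assignment, partition of a
## trajectory into {noHB, HB-VS1, HB-VS2, twoHB} clusters, and construction
## of the per-cluster collective embedding frame.

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("degenerate (zero-length) vector in geometry")
  v / n
}
cross3 <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

carbonyl_atoms <- function(solute_elem) {
  idx <- function(lbl) {
    i <- which(solute_elem == lbl)
    if (!length(i)) stop("solute is missing required atom label '", lbl, "'")
    i[1]
  }
  list(C = idx("C"), O = idx("O"), C1 = idx("C1"), C2 = idx("C2"))
}

#' Place the two oxygen lone-pair virtual sites
#'
#' The two massless virtual sites (VS) model the sp2 lone pairs of the
#' carbonyl oxygen: each sits 0.3067 Angstrom from O with a C-O-VS angle of
#' 111.3 degrees, symmetric about the C=O axis. The plane containing the
#' sites is state dependent: in the ground state the VSs lie in the plane
#' of the carbonyl fragment (O, C and the two carbon neighbours of C); in
#' the excited (pyramidalized) state they lie in the plane orthogonal to
#' the plane spanned by the C-C-C normal and the oxygen direction.
#'
#' @param solute_coords n x 3 matrix, Angstrom; rows labelled via
#'   `solute_elem`
#' @param solute_elem atom labels containing "C", "O", "C1", "C2"
#' @param state `"ground"` or `"excited"`
#' @param d_ovs O-VS distance in Angstrom (default 0.3067)
#' @param angle C-O-VS angle in degrees (default 111.3)
#' @return list with `vs1`, `vs2` (3-vectors, Angstrom) and the axes used
#' @export
place_virtual_sites <- function(solute_coords, solute_elem,
                                state = c("ground", "excited"),
                                d_ovs = 0.3067, angle = 111.3) {
  state <- match.arg(state)
  at <- carbonyl_atoms(solute_elem)
  C <- solute_coords[at$C, ]; O <- solute_coords[at$O, ]
  C1 <- solute_coords[at$C1, ]; C2 <- solute_coords[at$C2, ]
  u <- O - C                     # C=O axis, pointing from C to O
  if (sqrt(sum(u^2)) < 1e-6) stop("degenerate carbonyl geometry: C == O")
  u <- unit3(u)
  n_ccc <- cross3(C1 - C, C2 - C)
  if (sqrt(sum(n_ccc^2)) < 1e-8)
    stop("degenerate carbonyl geometry: C, C1, C2 collinear")
  n_ccc <- unit3(n_ccc)
  if (state == "ground") {
    ## in-plane direction perpendicular to the C=O axis within the
    ## O-C(O)-C fragment plane (spanned by the C=O axis and the C1-C2
    ## direction; identical to the C-C-C plane for a planar fragment)
    w <- C1 - C2
    v <- w - u * sum(u * w)
    if (sqrt(sum(v^2)) < 1e-8)
      stop("degenerate carbonyl geometry: C1-C2 parallel to C=O axis")
    v <- unit3(v)
  } else {
    ## plane orthogonal to span{n_ccc, O-C direction}: it shares the C=O
    ## axis and its second direction is the normal of that span
    v <- unit3(cross3(n_ccc, u))
  }
  a <- deg2rad(angle)
  ## VS direction from O: angle `a` away from the O->C direction
  dir1 <- cos(a) * (-u) + sin(a) * v
  dir2 <- cos(a) * (-u) - sin(a) * v
  list(vs1 = O + d_ovs * dir1, vs2 = O + d_ovs * dir2,
       axis = u, in_plane = v, state = state)
}

#' Fit the virtual-site charge to reproduce a target dipole
#'
#' Both VSs carry the same charge q; the oxygen charge is reduced by 2q so
#' the total molecular charge is conserved. q is the single scalar that
#' minimizes, in the least-squares sense, the residual between the
#' point-charge dipole and the target (QM) dipole of the electronic state.
#'
#' Closed form: with displacement vector d = vs1 + vs2 - 2 r_O (converted
#' to bohr), q = d . (mu_target - mu_base) / (d . d).
#'
#' @param base_charges atomic charges per solute atom, e
#' @param solute_coords n x 3, Angstrom
#' @param vs_coords list with `vs1`, `vs2` (as from [place_virtual_sites()])
#' @param target_dipole 3-vector, atomic units (e bohr)
#' @param o_index row index of the carbonyl oxygen in `solute_coords`
#' @return list with `q_vs` (charge on each VS, e), `o_charge` (adjusted
#'   oxygen charge), `residual` (norm of remaining dipole error, a.u.) and
#'   `ill_conditioned` flag
#' @export
fit_vs_charges <- function(base_charges, solute_coords, vs_coords,
                           target_dipole, o_index) {
  b <- 1 / .const$bohr_A        # bohr per Angstrom
  rc <- as.matrix(solute_coords) * b
  mu_base <- colSums(rc * base_charges)
  d <- (vs_coords$vs1 + vs_coords$vs2 - 2 * solute_coords[o_index, ]) * b
  dd <- sum(d^2)
  resid0 <- target_dipole - mu_base
  ill <- FALSE
  if (dd < 1e-12) {
    ill <- TRUE
    q <- 0
  } else {
    q <- sum(d * resid0) / dd
    ## displacement orthogonal to the dipole residual: fit cannot improve
    if (sum(resid0^2) > 1e-20 &&
        abs(sum(d * resid0)) < 1e-10 * sqrt(dd * sum(resid0^2)))
      ill <- TRUE
  }
  list(q_vs = q, o_charge = base_charges[o_index] - 2 * q,
       residual = sqrt(sum((resid0 - q * d)^2)),
       ill_conditioned = ill)
}

#' Smooth hydrogen-bond score
#'
#' F(r, theta) decays as a Gaussian in the deviation of the donor-acceptor
#' distance and angle from their optimum values, parameterized by
#' half-widths at half-maximum: F = exp(-ln2 ((r-r0)/w_r)^2) *
#' exp(-ln2 ((theta-theta0)/w_theta)^2). Defaults (1.8 A, 6 deg, 0.2 A,
#' 5 deg) are the optima and HWHMs obtained from pure-methanol sampling.
#' Deviations are penalized on both sides of the optimum.
#'
#' @param r VS...H distance, Angstrom (vectorized)
#' @param theta deviation of the VS...H-O angle from linearity, degrees
#' @param params numeric length 4: (r0, theta0, w_r, w_theta)
#' @return F in [0, 1]
#' @export
f_function <- function(r, theta,
                       params = c(r0 = 1.8, theta0 = 6, w_r = 0.2,
                                  w_theta = 5)) {
  p <- unname(params)
  exp(-log(2) * ((r - p[1]) / p[3])^2) *
    exp(-log(2) * ((theta - p[2]) / p[4])^2)
}

## geometry of one VS against all methanol residues in a frame:
## r = |VS - H|, theta = 180 - angle(VS, H, O_methanol) in degrees
vs_methanol_geometry <- function(vs, env) {
  hs <- env[env$role == "H", , drop = FALSE]
  os <- env[env$role == "O", , drop = FALSE]
  os <- os[match(hs$resid, os$resid), , drop = FALSE]
  if (!nrow(hs))
    return(data.frame(resid = integer(0), r = numeric(0),
                      theta = numeric(0)))
  dh <- cbind(hs$x - vs[1], hs$y - vs[2], hs$z - vs[3])
  r <- sqrt(rowSums(dh^2))
  do_ <- cbind(os$x - hs$x, os$y - hs$y, os$z - hs$z)
  ## angle at H between H->VS and H->O
  cosang <- rowSums(-dh * do_) / (r * sqrt(rowSums(do_^2)))
  cosang <- pmin(1, pmax(-1, cosang))
  ang <- rad2deg(acos(cosang))
  data.frame(resid = hs$resid, r = r, theta = 180 - ang)
}

#' Score and assign hydrogen bonds for one frame
#'
#' For each virtual site, every methanol residue (identified by its
#' hydroxyl H and O roles) is scored with [f_function()] using the
#' VS...H distance and the deviation of the VS...H-O angle from linearity.
#' A methanol may bind at most one VS: when the same residue is the best
#' candidate for both sites it is assigned greedily to the site where its
#' F is larger (ties to VS1) and the other site takes its next-best
#' partner. A bond is present iff F >= threshold.
#'
#' @param frame an `md_frame`
#' @param vs_coords list with `vs1`, `vs2`
#' @param threshold F threshold for an effective hydrogen bond (default 0.7)
#' @param f_params passed to [f_function()]
#' @return list of class `hb_record`: `frame`, and per VS a list
#'   (`resid`, `r`, `theta`, `F`, `bonded`)
#' @export
assign_hbonds <- function(frame, vs_coords, threshold = 0.7,
                          f_params = c(1.8, 6, 0.2, 5)) {
  g1 <- vs_methanol_geometry(vs_coords$vs1, frame$env)
  g2 <- vs_methanol_geometry(vs_coords$vs2, frame$env)
  g1$F <- if (nrow(g1)) f_function(g1$r, g1$theta, f_params) else numeric(0)
  g2$F <- if (nrow(g2)) f_function(g2$r, g2$theta, f_params) else numeric(0)
  pick <- function(g, exclude = NULL) {
    if (!is.null(exclude)) g <- g[g$resid != exclude, , drop = FALSE]
    if (!nrow(g)) return(list(resid = NA_integer_, r = NA_real_,
                              theta = NA_real_, F = 0))
    i <- which.max(g$F)
    list(resid = g$resid[i], r = g$r[i], theta = g$theta[i], F = g$F[i])
  }
  b1 <- pick(g1); b2 <- pick(g2)
  if (!is.na(b1$resid) && !is.na(b2$resid) && b1$resid == b2$resid) {
    ## exclusivity: greedy by descending F, tie broken in favour of VS1
    if (b2$F > b1$F) b1 <- pick(g1, exclude = b2$resid)
    else b2 <- pick(g2, exclude = b1$resid)
  }
  b1$bonded <- b1$F >= threshold
  b2$bonded <- b2$F >= threshold
  structure(list(frame = frame$index, vs1 = b1, vs2 = b2),
            class = "hb_record")
}

#' Classify a frame by its hydrogen-bond pattern
#'
#' @param record an `hb_record` from [assign_hbonds()]
#' @return one of `"noHB"`, `"HB-VS1"`, `"HB-VS2"`, `"twoHB"`
#' @export
classify_frame <- function(record) {
  b1 <- isTRUE(record$vs1$bonded); b2 <- isTRUE(record$vs2$bonded)
  if (b1 && b2) "twoHB"
  else if (b1) "HB-VS1"
  else if (b2) "HB-VS2"
  else "noHB"
}

#' Cluster population fractions
#'
#' @param labels character vector of frame labels
#' @param percent report percentages (default TRUE)
#' @return named numeric over the four cluster labels, summing to 100 (or 1)
#' @export
cluster_populations <- function(labels, percent = TRUE) {
  if (!length(labels)) stop("no frames to count")
  lv <- c("noHB", "HB-VS1", "HB-VS2", "twoHB")
  counts <- table(factor(labels, levels = lv))
  frac <- as.numeric(counts) / length(labels)
  names(frac) <- lv
  if (percent) frac * 100 else frac
}

#' Partition a trajectory into hydrogen-bond clusters
#'
#' Runs the full chain [place_virtual_sites()] -> [assign_hbonds()] ->
#' [classify_frame()] over a list of frames and tabulates populations.
#'
#' @param frames list of `md_frame` (rigid solute assumed: VSs placed once
#'   from the first frame)
#' @param state electronic state for the VS placement rule
#' @param threshold F threshold (default 0.7)
#' @param f_params F-function parameters
#' @return list of class `cluster_partition`: `labels`, `populations`
#'   (percent), `records` (data.frame frame, F_VS1, F_VS2, label),
#'   `vs_coords`
#' @export
partition_trajectory <- function(frames, state = "excited", threshold = 0.7,
                                 f_params = c(1.8, 6, 0.2, 5)) {
  stopifnot(length(frames) >= 1)
  vs <- place_virtual_sites(frames[[1]]$solute_coords,
                            frames[[1]]$solute_elem, state = state)
  recs <- lapply(frames, assign_hbonds, vs_coords = vs,
                 threshold = threshold, f_params = f_params)
  labels <- vapply(recs, classify_frame, "")
  df <- data.frame(frame = vapply(recs, function(r) r$frame, 0L),
                   F_VS1 = vapply(recs, function(r) r$vs1$F, 0),
                   F_VS2 = vapply(recs, function(r) r$vs2$F, 0),
                   label = labels)
  structure(list(labels = labels,
                 populations = cluster_populations(labels),
                 records = df, vs_coords = vs),
            class = "cluster_partition")
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat(sprintf("cluster_partition over %d frames\n", length(x$labels)))
  for (lv in names(x$populations))
    cat(sprintf("  %-7s %6.2f %%\n", lv, x$populations[lv]))
  invisible(x)
}

#' Build the collective embedding frame of a cluster
#'
#' Superimposes the environment sites of n sequential snapshots, keeping
#' only sites within `radius` of the solute geometric center and scaling
#' every kept charge by 1/n, so the collective configuration represents
#' the cluster's average environment.
#'
#' @param frames list of `md_frame` belonging to one cluster
#' @param n number of snapshots to use (default 30); if fewer frames are
#'   available all are used (scaled by 1/actual) with a warning
#' @param radius cut radius in Angstrom (default 30)
#' @return list of class `collective_frame`: `env` (data.frame x,y,z,q),
#'   `n_used`, `radius`, `source_frames`, `total_charge`
#' @export
build_collective_frame <- function(frames, n = 30, radius = 30) {
  if (!length(frames)) stop("no frames supplied")
  if (length(frames) < n) {
    warning(sprintf("only %d frames available, using all (requested %d)",
                    length(frames), n))
    n <- length(frames)
  }
  use <- frames[seq_len(n)]
  totals <- numeric(n)
  parts <- vector("list", n)
  for (i in seq_len(n)) {
    fr <- use[[i]]
    center <- colMeans(fr$solute_coords)
    d <- sqrt((fr$env$x - center[1])^2 + (fr$env$y - center[2])^2 +
              (fr$env$z - center[3])^2)
    keep <- fr$env[d <= radius, , drop = FALSE]
    totals[i] <- sum(keep$q)
    parts[[i]] <- data.frame(x = keep$x, y = keep$y, z = keep$z,
                             q = keep$q / n, source = fr$index)
  }
  env <- do.call(rbind, parts)
  structure(list(env = env, n_used = n, radius = radius,
                 source_frames = vapply(use, function(f) f$index, 0L),
                 total_charge = sum(env$q),
                 mean_source_charge = mean(totals)),
            class = "collective_frame")
}
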