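# Superposition and geometric observables.

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' `mobile` and `ref` over the fit atoms (SVD of the covariance with the
#' usual determinant sign correction, so reflections are never returned).
#'
#' @param mobile,ref n x 3 coordinate matrices.
#' @param fit_idx atom indices used for the fit (default: all); at least 3
#'   non-collinear atoms.
#' @return `list(R=, t=, rmsd=)`: apply as `coords %*% R + t` (row-vector
#'   convention); `rmsd` is the fit RMSD in Angstrom.
#' @export
kabsch_superpose <- function(mobile, ref, fit_idx = NULL) {
  if (is.null(fit_idx)) fit_idx <- seq_len(nrow(mobile))
  if (length(fit_idx) < 3) stop("kabsch_superpose: need at least 3 fit atoms")
  P <- mobile[fit_idx, , drop = FALSE]
  Q <- ref[fit_idx, , drop = FALSE]
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  # degenerate (collinear) sets have rank < 2 covariance
  H <- crossprod(P0, Q0)
  s <- svd(H)
  if (s$d[2] < 1e-10 * max(s$d[1], 1e-30))
    stop("kabsch_superpose: degenerate (collinear) fit atom set")
  d <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  t <- as.numeric(cq - cp %*% R)
  fitted <- sweep(P %*% R, 2, t, `+`)
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(R = R, t = t, rmsd = rmsd)
}

apply_fit <- function(coords, fit) sweep(coords %*% fit$R, 2, fit$t, `+`)

rmsd_between <- function(a, b, idx = NULL) {
  if (!is.null(idx)) { a <- a[idx, , drop = FALSE]; b <- b[idx, , drop = FALSE] }
  sqrt(mean(rowSums((a - b)^2)))
}

#' Superpose every frame of a trajectory onto a reference frame
#'
#' @param traj a [trajectory()].
#' @param ref n x 3 reference coordinates.
#' @param fit_idx fit atom indices.
#' @return A new [trajectory()] with fitted coordinates.
#' @export
superpose_trajectory <- function(traj, ref, fit_idx = NULL) {
  xyz <- traj$xyz
  for (f in seq_len(nrow(xyz))) {
    m <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    xyz[f, ] <- as_xyz_vec(apply_fit(m, kabsch_superpose(m, ref, fit_idx)))
  }
  trajectory(xyz, traj$times, traj$label)
}

scalar_series <- function(values, times, label, observable, units) {
  stopifnot(length(values) == length(times))
  structure(data.frame(system = label, time_ns = times, observable = observable,
                       value = values, units = units,
                       stringsAsFactors = FALSE),
            class = c("scalar_series", "data.frame"))
}

#' Summarize a scalar series (mean, SD, histogram)
#'
#' @param s a scalar series as returned by [rmsd_series()] etc.
#' @param bin_width histogram bin width in the series units (default 0.05,
#'   fine enough to resolve distribution widths of ~0.2 A).
#' @return `list(mean=, sd=, histogram=)`.
#' @export
summarize_series <- function(s, bin_width = 0.05) {
  v <- s$value
  br <- seq(floor(min(v) / bin_width) * bin_width,
            ceiling(max(v) / bin_width) * bin_width + bin_width, by = bin_width)
  h <- graphics::hist(v, breaks = br, plot = FALSE)
  list(mean = mean(v), sd = stats::sd(v),
       histogram = data.frame(mid = h$mids, count = h$counts))
}

#' Per-frame RMSD of a measured atom set after fitting on another
#'
#' Each frame is superposed onto the reference over `fit_idx` (e.g. the
#' protein core), then the RMSD is evaluated over `measure_idx` (e.g. the
#' cofactor heavy atoms) without re-fitting, so the series measures motion
#' of the measured group relative to the fitted frame of reference.
#'
#' @param traj a [trajectory()].
#' @param ref n x 3 reference coordinates.
#' @param fit_idx,measure_idx atom index vectors; `measure_idx` must be
#'   non-empty.
#' @param observable name recorded in the series.
#' @return A `scalar_series` data.frame (system, time_ns, observable, value,
#'   units).
#' @export
rmsd_series <- function(traj, ref, fit_idx, measure_idx,
                        observable = "rmsd") {
  if (!length(measure_idx)) stop("rmsd_series: empty measure set")
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    m <- get_frame(traj, f)
    fit <- kabsch_superpose(m, ref, fit_idx)
    rmsd_between(apply_fit(m, fit), ref, measure_idx)
  }, numeric(1))
  scalar_series(vals, traj$times, traj$label, observable, "A")
}

iterative_mean_fit <- function(traj, idx = NULL, tol = 1e-6, max_iter = 100) {
  # superpose all frames onto their mean, re-derive the mean, iterate
  xyz <- traj$xyz
  n <- ncol(xyz) / 3
  if (is.null(idx)) idx <- seq_len(n)
  mref <- matrix(xyz[1, ], ncol = 3, byrow = TRUE)
  for (it in seq_len(max_iter)) {
    for (f in seq_len(nrow(xyz))) {
      m <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
      xyz[f, ] <- as_xyz_vec(apply_fit(m, kabsch_superpose(m, mref, idx)))
    }
    mnew <- matrix(colMeans(xyz), ncol = 3, byrow = TRUE)
    drift <- max(abs(mnew - mref))
    mref <- mnew
    if (drift < tol) break
  }
  list(xyz = xyz, mean = mref, iterations = it, drift = drift)
}

#' Per-residue root-mean-square fluctuation
#'
#' Frames are superposed onto their iteratively refined mean structure
#' (fit on `sel_idx`, tolerance 1e-6 A on the mean), then per-atom RMSF
#' values are aggregated to residues. With `average_monomers = TRUE`,
#' equivalent residues of the two monomers (matched by residue number)
#' are averaged to a single profile.
#'
#' @param traj a [trajectory()] with at least 2 frames.
#' @param top the matching [topology()].
#' @param sel_idx atom indices to fit and profile (default: all `CA` atoms).
#' @param average_monomers average A/B residues on a shared residue axis.
#' @return An `rmsf_profile` data.frame (system, group, resno, value, units).
#' @export
rmsf_profile <- function(traj, top, sel_idx = NULL, average_monomers = FALSE) {
  if (n_frames(traj) < 2) stop("rmsf_profile: need at least 2 frames")
  if (is.null(sel_idx))
    sel_idx <- select_atoms(top, sel_term(group = c("A", "B"), name = "CA"))
  sub <- extract_subsystem(top, sel_idx, traj)
  fit <- iterative_mean_fit(sub$trajectory)
  dev2 <- sweep(fit$xyz, 2, as_xyz_vec(fit$mean))^2
  per_coord <- colMeans(dev2)
  per_atom <- sqrt(per_coord[c(TRUE, FALSE, FALSE)] +
                   per_coord[c(FALSE, TRUE, FALSE)] +
                   per_coord[c(FALSE, FALSE, TRUE)])
  a <- sub$topology$atoms
  key <- paste(a$group, a$resno)
  agg <- tapply(per_atom, key, mean)
  ord <- order(match(names(agg), unique(key)))
  agg <- agg[ord]
  parts <- do.call(rbind, strsplit(names(agg), " "))
  out <- data.frame(system = traj$label, group = parts[, 1],
                    resno = as.integer(parts[, 2]),
                    value = as.numeric(agg), units = "A",
                    stringsAsFactors = FALSE)
  if (average_monomers) {
    m <- tapply(out$value, out$resno, mean)
    out <- data.frame(system = traj$label, group = "A+B",
                      resno = as.integer(names(m)), value = as.numeric(m),
                      units = "A", stringsAsFactors = FALSE)
    out <- out[order(out$resno), ]
    rownames(out) <- NULL
  }
  structure(out, class = c("rmsf_profile", "data.frame"),
            averaged = average_monomers)
}

#' Distance series between two atoms or group centroids
#'
#' @param traj a [trajectory()].
#' @param i,j atom indices or index vectors (vectors use the centroid).
#' @param observable name recorded in the series.
#' @return A `scalar_series` data.frame, Angstrom.
#' @export
distance_series <- function(traj, i, j, observable = "distance") {
  if (length(intersect(i, j)) && identical(sort(i), sort(j)))
    stop("distance_series: identical atom set on both sides")
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    m <- get_frame(traj, f)
    ci <- colMeans(m[i, , drop = FALSE]); cj <- colMeans(m[j, , drop = FALSE])
    sqrt(sum((ci - cj)^2))
  }, numeric(1))
  scalar_series(vals, traj$times, traj$label, observable, "A")
}

ring_plane <- function(coords) {
  if (nrow(coords) < 3) stop("ring_stacking: ring needs at least 3 atoms")
  c0 <- colMeans(coords)
  X <- sweep(coords, 2, c0)
  s <- svd(X)
  if (s$d[2] < 1e-8 * max(s$d[1], 1e-30))
    stop("ring_stacking: degenerate (collinear) ring")
  list(center = c0, normal = s$v[, 3])
}

#' Ring-stacking geometry between two rings
#'
#' Per frame, each ring gets a least-squares plane; the interplanar angle is
#' `acos(|nA . nB|)` in `[0, 90]` degrees and the separation is the distance
#' between ring centroids projected onto the mean normal (sign-aligned
#' before averaging). Used for pi-pi contacts such as the tryptophan indole
#' against the cofactor pyrimidine ring.
#'
#' @param traj a [trajectory()].
#' @param ring_a,ring_b atom index vectors (>= 3 non-collinear atoms each).
#' @return `list(separation=, angle=)` of scalar series (A and degrees).
#' @export
ring_stacking <- function(traj, ring_a, ring_b) {
  nf <- n_frames(traj)
  sep <- ang <- numeric(nf)
  for (f in seq_len(nf)) {
    m <- get_frame(traj, f)
    pa <- ring_plane(m[ring_a, , drop = FALSE])
    pb <- ring_plane(m[ring_b, , drop = FALSE])
    dp <- sum(pa$normal * pb$normal)
    ang[f] <- acos(pmin(1, abs(dp))) * 180 / pi
    nb <- pb$normal * ifelse(dp < 0, -1, 1)
    nm <- pa$normal + nb
    nm <- nm / sqrt(sum(nm^2))
    sep[f] <- abs(sum((pb$center - pa$center) * nm))
  }
  list(separation = scalar_series(sep, traj$times, traj$label,
                                  "ring_separation", "A"),
       angle = scalar_series(ang, traj$times, traj$label,
                             "ring_angle", "deg"))
}

#' Detect a loop-opening transition from paired RMSF profiles
#'
#' Compares the RMSF of a ligand/substrate-bound (closed) system against the
#' unbound one over the "door" loop: the transition is called when every
#' loop residue gains at least `threshold` Angstrom of RMSF.
#'
#' @param bound,unbound `rmsf_profile` objects on a shared residue axis.
#' @param loop_range closed residue-number interval of the loop.
#' @param threshold minimum per-residue RMSF gain, A (default 10).
#' @return `list(detected=, delta=, threshold=)`; `delta` is a per-residue
#'   data.frame over the loop.
#' @export
detect_loop_opening <- function(bound, unbound, loop_range, threshold = 10) {
  key <- function(p) paste(p$group, p$resno)
  hit <- match(key(bound), key(unbound))
  if (anyNA(hit))
    stop("detect_loop_opening: profiles do not share a residue axis")
  delta <- data.frame(group = bound$group, resno = bound$resno,
                      delta = unbound$value[hit] - bound$value,
                      stringsAsFactors = FALSE)
  inloop <- delta$resno >= loop_range[1] & delta$resno <= loop_range[2]
  if (!any(inloop))
    stop("detect_loop_opening: loop range outside the profiles")
  list(detected = min(delta$delta[inloop]) >= threshold,
       delta = delta[inloop, ], threshold = threshold)
}

#' Export scalar series or profiles to CSV
#'
#' @param x a `scalar_series`, `rmsf_profile`, or plain data.frame.
#' @param path output CSV file.
#' @export
write_series_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
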