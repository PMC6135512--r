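test_that("Kabsch superposition recovers exact transforms", {
  set.seed(1)
  ref <- matrix(rnorm(30), 10, 3)
  same <- kabsch_superpose(ref, ref)
  expect_equal(same$rmsd, 0, tolerance = 1e-12)
  expect_equal(same$R, diag(3), tolerance = 1e-8)

  R <- random_rotation(); t <- c(3, -2, 7)
  mob <- sweep(ref %*% R, 2, t, `+`)
  fit <- kabsch_superpose(mob, ref)
  expect_equal(fit$rmsd, 0, tolerance = 1e-8)
  expect_equal(fit$R, t(R), tolerance = 1e-8)
  expect_equal(det(fit$R), 1, tolerance = 1e-10)

  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch_superpose(line + 0, line), "degenerate")
})

test_that("Kabsch RMSD lower-bounds a brute-force random search", {
  set.seed(2)
  for (rep in 1:3) {
    a <- matrix(rnorm(15), 5, 3)
    b <- matrix(rnorm(15), 5, 3)
    kab <- kabsch_superpose(a, b)$rmsd
    cb <- colMeans(b)
    a0 <- sweep(a, 2, colMeans(a))
    best <- Inf
    for (i in 1:20000) {
      R <- random_rotation()
      fitted <- sweep(a0 %*% R, 2, cb, `+`)   # centroid-aligned translation
      best <- min(best, sqrt(mean(rowSums((fitted - b)^2))))
    }
    expect_lte(kab, best + 1e-12)
  }
})

test_that("RMSD is invariant under common rigid transforms and matches the fit", {
  sys <- tiny_system(n_frames = 10)
  sel <- select_atoms(sys$top, sel_term(group = c("A", "B"), name = "CA"))
  s1 <- rmsd_series(sys$traj, sys$ref, sel, sel)
  # transform every frame and the reference by the same rigid motion
  R <- random_rotation(); t <- c(10, -4, 2)
  xyz2 <- t(apply(sys$traj$xyz, 1, function(v)
    as_xyz_vec(rigid_move(matrix(v, ncol = 3, byrow = TRUE), R, t))))
  s2 <- rmsd_series(trajectory(xyz2, sys$traj$times, "WT"),
                    rigid_move(sys$ref, R, t), sel, sel)
  expect_equal(s1$value, s2$value, tolerance = 1e-8)
  # measuring the fit set reproduces the Kabsch fit RMSD frame by frame
  direct <- vapply(seq_len(10), function(f)
    kabsch_superpose(get_frame(sys$traj, f), sys$ref, sel)$rmsd, numeric(1))
  expect_equal(s1$value, direct, tolerance = 1e-10)
  expect_error(rmsd_series(sys$traj, sys$ref, sel, integer(0)),
               "empty measure set")
})

test_that("a rigidly displaced ligand reads back as a constant RMSD", {
  spec <- synthetic_spec(residues_per_monomer = 14, n_frames = 6,
                         amp_mean = c(WT = 0), amp_sd = 0,
                         ligand_amp = c(WT = 0), jitter_sd = 0, seed = 3)
  toy <- build_toy_dimer(spec)
  tr <- generate_trajectory(toy$topology, toy$reference, spec, "WT", toy$meta)
  d <- 1.7
  iL <- which(toy$topology$atoms$group == "L2")
  xyz <- tr$xyz
  cols <- 3 * (iL - 1) + 2
  xyz[, cols] <- xyz[, cols] + d
  fit_idx <- select_atoms(toy$topology, sel_term(group = c("A", "B"),
                                                 name = "CA"))
  ser <- rmsd_series(trajectory(xyz, tr$times, "WT"), toy$reference,
                     fit_idx, iL)
  expect_equal(ser$value, rep(d, 6), tolerance = 1e-8)
})

test_that("RMSF profiles: static zero, order invariance, loop contrast", {
  sys <- tiny_system(n_frames = 12, jitter_sd = 0.2, seed = 8)
  static <- trajectory(sys$traj$xyz[c(1, 1), ], c(0, 1), "WT")
  expect_true(all(rmsf_profile(static, sys$top)$value < 1e-10))
  expect_error(rmsf_profile(trajectory(sys$traj$xyz[1, , drop = FALSE],
                                       0, "WT"), sys$top), "2 frames")

  prof <- rmsf_profile(sys$traj, sys$top)
  perm <- sample(nrow(sys$traj$xyz))
  prof_p <- rmsf_profile(trajectory(sys$traj$xyz[perm, ],
                                    sys$traj$times, "WT"), sys$top)
  expect_equal(prof$value, prof_p$value, tolerance = 1e-6)

  # planted loop opening half-way raises loop RMSF >= 4x over the rest
  spec <- synthetic_spec(residues_per_monomer = 20, n_frames = 200,
                         amp_mean = c(WT = 0), amp_sd = 0,
                         ligand_amp = c(WT = 0), jitter_sd = 0.1,
                         loop_range = c(2, 3), loop_open_A = 10, seed = 9)
  toy <- build_toy_dimer(spec)
  tr <- generate_trajectory(toy$topology, toy$reference, spec, "WT", toy$meta)
  p <- rmsf_profile(tr, toy$topology, average_monomers = TRUE)
  inloop <- p$resno %in% 2:3
  expect_gte(min(p$value[inloop]), 4 * max(p$value[!inloop]))
  expect_equal(mean(p$value[inloop]), 10, tolerance = 0.1)
})

test_that("distance series handles atoms, centroids and degenerate input", {
  sys <- tiny_system(n_frames = 4, jitter_sd = 0)
  d <- sys$meta$donors
  ser <- distance_series(sys$traj, d$donor[1], d$acceptor[1])
  expect_equal(ser$value, rep(2.9, 4), tolerance = 1e-9)
  # centroid of a singleton group equals the atom variant
  ser2 <- distance_series(sys$traj, d$donor[1], d$acceptor[1])
  expect_equal(ser$value, ser2$value)
  expect_error(distance_series(sys$traj, d$donor[1], d$donor[1]),
               "identical atom")
})

test_that("ring stacking reports planted separations and angles", {
  hex <- function(offset = c(0, 0, 0), R = diag(3)) {
    ang <- (0:5) * pi / 3
    sweep(cbind(1.4 * cos(ang), 1.4 * sin(ang), 0) %*% R, 2, offset, `+`)
  }
  mk <- function(b) trajectory(matrix(as_xyz_vec(rbind(hex(), b)), 1), 0, "X")
  tr <- mk(hex(offset = c(0, 0, 3.8)))
  st <- ring_stacking(tr, 1:6, 7:12)
  expect_equal(st$separation$value, 3.8, tolerance = 1e-9)
  expect_equal(st$angle$value, 0, tolerance = 1e-6)

  Rx <- matrix(c(1, 0, 0, 0, 0, -1, 0, 1, 0), 3, 3)   # 90 degrees about x
  st90 <- ring_stacking(mk(hex(c(0, 5, 0), Rx)), 1:6, 7:12)
  expect_equal(st90$angle$value, 90, tolerance = 1e-6)

  th <- 27.5
  Rt <- matrix(c(1, 0, 0, 0, cos(th * pi / 180), -sin(th * pi / 180),
                 0, sin(th * pi / 180), cos(th * pi / 180)), 3, 3,
               byrow = TRUE)
  stt <- ring_stacking(mk(hex(c(0, 0, 4), Rt)), 1:6, 7:12)
  expect_equal(stt$angle$value, th, tolerance = 1e-6)
  # symmetry in ring order and atom order
  sw <- ring_stacking(mk(hex(c(0, 0, 4), Rt)), rev(7:12), sample(1:6))
  expect_equal(sw$angle$value, stt$angle$value, tolerance = 1e-9)
  expect_error(ring_stacking(mk(hex()), 1:2, 7:12), "at least 3")
})

test_that("loop-opening verdicts follow the RMSF-gain threshold", {
  prof <- function(vals) {
    structure(data.frame(system = "S", group = "A+B", resno = seq_along(vals),
                         value = vals, units = "A"),
              class = c("rmsf_profile", "data.frame"))
  }
  base <- prof(rep(0.5, 40))
  same <- detect_loop_opening(base, base, c(15, 32))
  expect_false(same$detected)
  expect_true(all(same$delta$delta == 0))

  open12 <- prof(replace(rep(0.5, 40), 15:32, 12.5))
  expect_true(detect_loop_opening(base, open12, c(15, 32))$detected)
  open5 <- prof(replace(rep(0.5, 40), 15:32, 5.5))
  expect_false(detect_loop_opening(base, open5, c(15, 32))$detected)
  expect_error(detect_loop_opening(base, open12, c(50, 60)), "loop range")
})
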