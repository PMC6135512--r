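make_four_systems <- function(residues = 20, n_frames = 150, jitter = 0.08,
                              amp_sd = 1, seed = 17) {
  spec <- synthetic_spec(residues_per_monomer = residues, n_frames = n_frames,
                         amp_sd = amp_sd, jitter_sd = jitter,
                         ligand_amp = c(WT = 0), seed = seed)
  toy <- build_toy_dimer(spec)
  labels <- c("WT", "E266K", "R267H", "P300L")
  trs <- lapply(labels, function(lb)
    generate_trajectory(toy$topology, toy$reference, spec, lb, toy$meta))
  names(trs) <- labels
  list(spec = spec, toy = toy, trs = trs,
       sel = toy_pca_selection(toy$topology, toy$meta))
}

test_that("the PC model satisfies its spectral invariants", {
  fx <- make_four_systems(n_frames = 60)
  mod <- fit_pc_model(fx$trs, fx$toy$topology, fx$sel,
                      window_ns = 40, stride_ns = 1)
  V <- mod$evec
  expect_lt(max(abs(crossprod(V) - diag(ncol(V)))), 1e-8)
  expect_true(all(diff(mod$evals) <= 1e-9))
  expect_true(all(mod$evals >= 0))
  expect_equal(mod$provenance$pooled_frames, 4 * 40)
  # sign convention: the largest loading of each PC is positive
  for (k in 1:5)
    expect_gt(V[which.max(abs(V[, k])), k], 0)

  # static identical frames give a null spectrum
  st <- lapply(fx$trs["WT"], function(tr)
    trajectory(tr$xyz[rep(1, 10), ], 0:9, "WT"))
  mod0 <- fit_pc_model(st, fx$toy$topology, fx$sel, window_ns = 9,
                       stride_ns = 1)
  expect_lt(max(mod0$evals), 1e-12)
})

test_that("projection is the exact inner-product displacement", {
  fx <- make_four_systems(n_frames = 40)
  mod <- fit_pc_model(fx$trs, fx$toy$topology, fx$sel, 30, 1)
  n_all <- ncol(fx$trs$WT$xyz) / 3
  embed <- function(selmat) {
    # place selection coordinates into a full-size frame (other atoms at
    # their reference positions so extraction still works)
    fr <- fx$toy$reference
    fr[mod$sel_idx, ] <- selmat
    trajectory(matrix(as_xyz_vec(fr), 1), 0, "WT")
  }
  d0 <- project_trajectory(mod, embed(mod$mean), fx$toy$topology, 1)
  expect_equal(d0$value, 0, tolerance = 1e-8)
  cval <- 2.37
  m1 <- mod$mean + matrix(cval * mod$evec[, 1], ncol = 3, byrow = TRUE)
  expect_equal(project_trajectory(mod, embed(m1), fx$toy$topology, 1)$value,
               cval, tolerance = 1e-6)
  expect_equal(project_trajectory(mod, embed(m1), fx$toy$topology, 2)$value,
               0, tolerance = 1e-6)
  expect_error(project_trajectory(mod, fx$trs$WT, fx$toy$topology,
                                  ncol(mod$evec) + 1), "component index")
})

test_that("pooled-frame projections reproduce the spectrum (Parseval)", {
  fx <- make_four_systems(n_frames = 30, jitter = 0.05)
  mod <- fit_pc_model(fx$trs["WT"], fx$toy$topology, fx$sel, 29, 1)
  sub <- extract_subsystem(fx$toy$topology, mod$sel_idx,
                           fx$trs$WT)$trajectory
  fidx <- schedule_frames(fx$trs$WT, 29, 1)
  centered <- t(vapply(fidx, function(f) {
    m <- get_frame(sub, f)
    m <- dimerdyn:::apply_fit(m, kabsch_superpose(m, mod$mean))
    as_xyz_vec(m) - as_xyz_vec(mod$mean)
  }, numeric(3 * mod$n_centers)))
  proj_var <- apply(centered %*% mod$evec, 2, stats::var)
  keep <- mod$evals > 1e-10
  expect_equal(proj_var[keep], mod$evals[keep], tolerance = 1e-6)
  expect_equal(sum(proj_var), sum(mod$evals), tolerance = 1e-6)
})

test_that("a planted interface mode is recovered in direction and scale", {
  fx <- make_four_systems(n_frames = 200, jitter = 0.05, amp_sd = 1.2)
  mod <- fit_pc_model(fx$trs, fx$toy$topology, fx$sel, 150, 1)
  pl <- attr(fx$trs$WT, "planted")
  expect_gte(abs(sum(mod$evec[, 1] * pl$mode$sel)), 0.95)
  # lambda1 tracks the planted variance seen through the selection
  fidx <- dimerdyn:::schedule_frames(fx$trs$WT, 150, 1)
  amps <- unlist(lapply(fx$trs, function(tr)
    attr(tr, "planted")$amp[fidx]))
  v_planted <- stats::var(amps) * pl$mode$eta^2
  expect_equal(mod$evals[1], v_planted, tolerance = 0.1)
})

test_that("reference zeroing recovers the planted sign pattern", {
  fx <- make_four_systems(n_frames = 250, jitter = 0.08)
  mod <- fit_pc_model(fx$trs, fx$toy$topology, fx$sel, 200, 1)
  disp <- lapply(fx$trs, function(tr)
    project_trajectory(mod, tr, fx$toy$topology, 1,
                       frames = schedule_frames(tr, 200, 1)))
  expect_error(zero_reference(disp, "NOPE"), "not present")
  z <- zero_reference(disp, "WT")
  expect_lt(abs(mean(z$WT$value)), 1e-10)
  m <- vapply(z, function(d) mean(d$value), numeric(1))
  # planted: R267H strongly positive, E266K and P300L negative
  expect_gt(m["R267H"], 0)
  expect_lt(m["E266K"], 0)
  expect_lt(m["P300L"], 0)
  eta <- attr(fx$trs$WT, "planted")$mode$eta
  se <- 3 * 1.2 / sqrt(200)     # generous per-system SE bound
  expect_lt(abs(m["R267H"] - 4 * eta), 3 * se)
  expect_lt(abs(m["E266K"] + 2 * eta), 3 * se)
  # linearity: shifting by the reference mean moves all systems equally
  off <- attr(z, "offset")
  expect_equal(mean(disp$R267H$value) - off, m[["R267H"]], tolerance = 1e-10)
})

test_that("ellipse summaries report componentwise moments", {
  e0 <- ellipse_summary(rep(2, 5), rep(-1, 5))
  expect_equal(unlist(e0), c(mean_x = 2, mean_y = -1, sd_x = 0, sd_y = 0))
  set.seed(5)
  x <- rnorm(1e4); y <- rnorm(1e4)
  e <- ellipse_summary(x, y)
  expect_lt(abs(e$mean_x), 0.05); expect_lt(abs(e$mean_y), 0.05)
  expect_equal(e$sd_x, 1, tolerance = 0.05)
  expect_equal(e$sd_y, 1, tolerance = 0.05)
  ea <- ellipse_summary(3 * x + 1, y)
  expect_equal(ea$mean_x, 3 * e$mean_x + 1, tolerance = 1e-12)
  expect_equal(ea$sd_x, 3 * e$sd_x, tolerance = 1e-12)
  expect_error(ellipse_summary(1:3, 1:4), "length mismatch")
})

test_that("models survive a serialize/restore round trip", {
  fx <- make_four_systems(n_frames = 20)
  mod <- fit_pc_model(fx$trs["WT"], fx$toy$topology, fx$sel, 15, 1)
  stem <- file.path(withr::local_tempdir(), "model")
  save_pc_model(mod, stem)
  back <- load_pc_model(stem)
  expect_equal(back$mean, mod$mean, tolerance = 1e-12)
  expect_equal(back$evals, mod$evals, tolerance = 1e-12)
  expect_equal(back$evec, mod$evec, tolerance = 1e-12)
  expect_equal(back$provenance$pooled_frames, mod$provenance$pooled_frames)
})
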