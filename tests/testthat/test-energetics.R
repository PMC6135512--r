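test_that("Coulomb and Lennard-Jones match closed forms", {
  top <- ions_topology(c(1, 1))
  fr <- rbind(c(0, 0, 0), c(3.32, 0, 0))
  cl <- coulomb_lj_energy(top, fr)
  expect_equal(cl$coulomb, 332.0637 / 3.32, tolerance = 1e-12)
  # a pair at exactly rmin sits at -eps
  rmin <- 2 * 1.6612
  cl2 <- coulomb_lj_energy(ions_topology(c(0, 0)), rbind(c(0, 0, 0),
                                                         c(rmin, 0, 0)))
  expect_equal(cl2$lj, -0.21, tolerance = 1e-12)
  expect_equal(cl2$coulomb, 0)
  # neutral epsilon-free atoms contribute nothing
  t0 <- ions_topology(c(0, 0))
  t0$atoms$lj_eps <- 0
  cl3 <- coulomb_lj_energy(t0, fr)
  expect_equal(unlist(cl3), c(coulomb = 0, lj = 0))
  expect_error(coulomb_lj_energy(top, rbind(c(0, 0, 0), c(0, 0, 1e-9))),
               "overlapping")
})

test_that("OBC2 effective radii: isolated, distant and buried limits", {
  ion <- ion_topology(gb_radius = 1.5)
  expect_equal(effective_born_radii(ion, matrix(0, 1, 3)), 1.41,
               tolerance = 1e-12)
  two <- ions_topology(c(-1, -1))
  rfar <- effective_born_radii(two, rbind(c(0, 0, 0), c(50, 0, 0)))
  expect_lt(max(abs(rfar / 1.41 - 1)), 0.01)
  # an atom tightly caged by neighbors is descreened upward
  shell <- rbind(c(0, 0, 0), 2.2 * rbind(diag(3), -diag(3)))
  caged <- ions_topology(rep(0, 7))
  rr <- effective_born_radii(caged, shell)
  expect_gt(rr[1], 1.41)
})

test_that("GB energy reduces to the Born formula and its distant-ion limit", {
  kd <- 1 - 1 / 78.5
  ion <- ion_topology(charge = -1, gb_radius = 1.5)
  e1 <- gb_polar_energy(ion, matrix(0, 1, 3))
  expect_equal(e1, -166.03185 * kd / 1.41, tolerance = 1e-4)
  # two identical ions at 50 A: two Born terms plus the screened
  # point-charge interaction (the exact f_GB -> r limit)
  two <- ions_topology(c(-1, -1))
  fr <- rbind(c(0, 0, 0), c(50, 0, 0))
  R <- effective_born_radii(two, fr)
  closed <- sum(-166.03185 * kd / R) - 332.0637 * kd / 50
  expect_lt(abs(gb_polar_energy(two, fr) / closed - 1), 1e-3)
  # zero charges, or matched dielectrics, kill the term entirely
  expect_equal(gb_polar_energy(ions_topology(c(0, 0)), fr), 0)
  expect_equal(gb_polar_energy(two, fr,
                               constants = energy_constants(eps_out = 1)), 0)
})

test_that("LCPO areas: isolated, additive and overlap-reduced", {
  ion <- ion_topology()
  iso <- sasa_lcpo(ion, matrix(0, 1, 3))
  expect_equal(iso$total, 0.77914 * 4 * pi * (1.6612 + 1.4)^2,
               tolerance = 1e-12)
  two <- ions_topology(c(0, 0))
  far <- sasa_lcpo(two, rbind(c(0, 0, 0), c(30, 0, 0)))
  expect_equal(far$total, 2 * iso$total, tolerance = 1e-12)
  near <- sasa_lcpo(two, rbind(c(0, 0, 0), c(2.5, 0, 0)))
  expect_lt(near$total, far$total)
  expect_equal(near$energy, 0.005 * near$total, tolerance = 1e-12)
})

test_that("bonded terms follow the harmonic conventions", {
  sys <- tiny_system(n_frames = 2)
  expect_equal(bonded_energy(sys$top, sys$ref), 0, tolerance = 1e-18)
  # stretch one bond by delta: energy k*delta^2
  b <- sys$top$bond_params[1, ]
  fr <- sys$ref
  dirv <- fr[b$j, ] - fr[b$i, ]; dirv <- dirv / sqrt(sum(dirv^2))
  fr[b$j, ] <- fr[b$j, ] + 0.25 * dirv
  expect_equal(bonded_energy(sys$top, fr), 300 * 0.25^2, tolerance = 1e-9)
  # rigid transforms leave it unchanged
  set.seed(3)
  expect_equal(bonded_energy(sys$top, rigid_move(fr)), 300 * 0.25^2,
               tolerance = 1e-9)
  # a bond without parameters is an error naming the atoms
  broken <- sys$top
  bad <- topology(broken$atoms, broken$bonds,
                  bond_params = broken$bond_params[-1, ])
  expect_error(bonded_energy(bad, sys$ref), "missing bond parameter")
})

test_that("system energies are rigid-invariant and scale as expected", {
  sys <- tiny_system(residues = 12, n_frames = 2, jitter_sd = 0.1, seed = 2)
  fr <- get_frame(sys$traj, 1)
  e <- system_energy(sys$top, fr)
  expect_equal(e$total,
               e$bonded + e$coulomb + e$lj + e$gb + e$nonpolar,
               tolerance = 1e-12)
  set.seed(9)
  e2 <- system_energy(sys$top, rigid_move(fr))
  expect_lt(abs(e2$total - e$total), 1e-8)
  # doubling all charges quadruples Coulomb and GB, leaves the rest alone
  t2 <- sys$top
  a2 <- t2$atoms; a2$charge <- 2 * a2$charge
  t2 <- topology(a2, t2$bonds, bond_params = t2$bond_params)
  e4 <- system_energy(t2, fr)
  expect_equal(e4$coulomb, 4 * e$coulomb, tolerance = 1e-10)
  expect_equal(e4$gb, 4 * e$gb, tolerance = 1e-10)
  expect_equal(e4$lj, e$lj, tolerance = 1e-12)
  expect_equal(e4$sasa_A2, e$sasa_A2, tolerance = 1e-12)
})

test_that("the EM/EE/EL/ET identity holds exactly per frame", {
  sys <- tiny_system(residues = 12, n_frames = 10, seed = 6)
  bd <- decompose_em_ee_el(sys$top, sys$traj, window_ns = 8, stride_ns = 1)
  pf <- bd$per_frame
  expect_equal(pf$ET, pf$EM + pf$EE + pf$EL, tolerance = 1e-14)
  expect_equal(pf$EM, pf$EM1 + pf$EM2, tolerance = 1e-14)
  expect_equal(pf$EL, pf$EL1 + pf$EL2, tolerance = 1e-14)
  expect_true(all(is.finite(unlist(pf))))
  expect_true(all(bd$summary$sd >= 0))
  expect_error(decompose_em_ee_el(sys$top, sys$traj, window_ns = 1e-9),
               "window")
})

test_that("infinitely separated neutral monomers have EE = EL = 0", {
  # two neutral two-atom monomers 500 A apart, no ligand
  top <- topology(data.frame(
    name = rep(c("CA", "CB"), 2), element = "C", resno = c(1, 1, 1, 1),
    resname = "GLY", group = c("A", "A", "B", "B"), charge = 0,
    lj_eps = 0.1094, lj_rmin_half = 1.908, gb_radius = 1.7,
    lcpo_p1 = 0.77887, lcpo_p2 = -0.28063, lcpo_p3 = -0.0012968,
    lcpo_p4 = 0.00039328, stringsAsFactors = FALSE),
    rbind(c(1, 2), c(3, 4)),
    bond_params = data.frame(i = c(1, 3), j = c(2, 4), k = 300, r0 = 1.5))
  fr <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(500, 0, 0), c(501.5, 0, 0))
  traj <- trajectory(matrix(as_xyz_vec(fr), 1), 0, "far")
  bd <- decompose_em_ee_el(top, traj, window_ns = 1, stride_ns = 1)
  expect_lt(abs(bd$per_frame$EE), 1e-6)
  expect_equal(bd$per_frame$EL, 0)
  expect_equal(bd$per_frame$ET, bd$per_frame$EM, tolerance = 1e-9)
})

test_that("per-residue decompositions are exact and reference-subtractable", {
  sys <- tiny_system(residues = 12, n_frames = 6, seed = 12)
  bd <- decompose_em_ee_el(sys$top, sys$traj, window_ns = 5, stride_ns = 1)
  ee <- pairwise_residue_decomposition(sys$top, sys$traj, "interface", 5, 1)
  el <- pairwise_residue_decomposition(sys$top, sys$traj, "ligand", 5, 1)
  expect_lt(max(abs(rowSums(attr(ee, "per_frame")) - bd$per_frame$EE)), 1e-6)
  expect_lt(max(abs(rowSums(attr(el, "per_frame")) - bd$per_frame$EL)), 1e-6)
  # subtracting a profile from itself zeroes every residue
  rel <- pairwise_residue_decomposition(sys$top, sys$traj, "interface", 5, 1,
                                        reference = ee)
  expect_true(all(abs(rel$mean) < 1e-12))
})

test_that("a single charged residue pair carries the entire Coulomb EE", {
  sys <- tiny_system(residues = 12, n_frames = 2, jitter_sd = 0, seed = 1)
  a <- sys$top$atoms
  a$charge <- 0
  qres <- 6
  a$charge[a$group == "A" & a$resno == qres & a$name == "CA"] <- 1
  a$charge[a$group == "B" & a$resno == qres & a$name == "CA"] <- -1
  a$lj_eps <- 0
  top <- topology(a, sys$top$bonds, bond_params = sys$top$bond_params)
  # vacuum electrostatics only: no solvent screening, no cavity term
  const <- energy_constants(eps_out = 1, gamma_tension = 0)
  ee <- pairwise_residue_decomposition(top, sys$traj, "interface", 1, 1,
                                       constants = const)
  on_pair <- ee$tag %in% paste0(c("A:", "B:"), qres)
  expect_true(all(abs(ee$mean[!on_pair]) < 1e-10))
  iA <- which(a$group == "A" & a$resno == qres & a$name == "CA")
  iB <- which(a$group == "B" & a$resno == qres & a$name == "CA")
  r <- sqrt(sum((sys$ref[iA, ] - sys$ref[iB, ])^2))
  expect_equal(sum(ee$mean[on_pair]), -332.0637 / r, tolerance = 1e-6)
})

test_that("the published energy table satisfies ET = EM + EE + EL", {
  tab <- published_energy_table()
  expect_equal(nrow(tab), 4)
  expect_equal(check_energy_accounting(tab), 0, tolerance = 5e-3)
})
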