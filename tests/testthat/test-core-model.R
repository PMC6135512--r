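test_that("atom selection is deterministic, idempotent and order-independent", {
  sys <- tiny_system(n_frames = 2)
  top <- sys$top
  t1 <- sel_term(group = "A", resno = c(3, 8), name = "CA")
  t2 <- sel_term(group = c("L1", "L2"), name = "C6")
  s12 <- select_atoms(top, selection_spec(t1, t2))
  s21 <- select_atoms(top, selection_spec(t2, t1))
  sdup <- select_atoms(top, selection_spec(t1, t2, t1, t2))
  expect_identical(s12, s21)
  expect_identical(s12, sdup)
  expect_identical(s12, sort(unique(s12)))
  expect_length(select_atoms(top, sel_term(resname = "NOPE")), 0)
  expect_warning(select_atoms(top, sel_term(name = "ZZ9")), "not present")
  expect_length(select_atoms(top, sel_term(group = c("A", "B", "L1", "L2"))),
                nrow(top$atoms))
})

test_that("every atom belongs to exactly one monomer or ligand site", {
  top <- tiny_system(n_frames = 2)$top
  sizes <- vapply(c("A", "B", "L1", "L2"),
                  function(g) length(which(top$atoms$group == g)), integer(1))
  expect_equal(sum(sizes), nrow(top$atoms))
  expect_equal(sizes[["A"]], sizes[["B"]])
  expect_error(topology(top$atoms, rbind(c(1, nrow(top$atoms)))),
               "crossing the monomer")
})

test_that("subsystem extraction keeps parameters and partitions the atom set", {
  sys <- tiny_system(n_frames = 3)
  iA <- which(sys$top$atoms$group == "A")
  sub <- extract_subsystem(sys$top, iA, sys$traj)
  expect_equal(nrow(sub$topology$atoms), length(iA))
  expect_true(dimerdyn:::is_parameterized(sub$topology))
  comp <- extract_subsystem(sys$top, setdiff(seq_len(nrow(sys$top$atoms)), iA))
  expect_equal(nrow(sub$topology$atoms) + nrow(comp$atoms),
               nrow(sys$top$atoms))
  expect_error(extract_subsystem(sys$top, 10^6), "out of range")
  # coordinates follow the atom subset
  expect_equal(get_frame(sub$trajectory, 2), get_frame(sys$traj, 2)[iA, ])
})

test_that("isolated-ligand energy matches a restricted double-loop oracle", {
  sys <- tiny_system(n_frames = 2)
  iL <- which(sys$top$atoms$group == "L1")
  lig <- extract_subsystem(sys$top, iL)
  fr <- sys$ref[iL, ]
  got <- coulomb_lj_energy(lig, fr)
  # brute-force pair loop with the same exclusion rules
  pcm <- dimerdyn:::pair_class_matrix(lig)
  a <- lig$atoms
  ec <- el <- 0
  for (i in seq_len(nrow(a) - 1)) for (j in (i + 1):nrow(a)) {
    if (pcm[i, j] == 1L) next
    sc <- if (pcm[i, j] == 2L) 1 / 1.2 else 1
    sl <- if (pcm[i, j] == 2L) 1 / 2.0 else 1
    r <- sqrt(sum((fr[i, ] - fr[j, ])^2))
    ec <- ec + sc * 332.0637 * a$charge[i] * a$charge[j] / r
    s6 <- ((a$lj_rmin_half[i] + a$lj_rmin_half[j]) / r)^6
    el <- el + sl * sqrt(a$lj_eps[i] * a$lj_eps[j]) * (s6^2 - 2 * s6)
  }
  expect_equal(got$coulomb, ec, tolerance = 1e-12)
  expect_equal(got$lj, el, tolerance = 1e-12)
})

test_that("PDB reading enforces the two-chain dimer contract", {
  sys <- tiny_system(n_frames = 2)
  p <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(sys$top, sys$ref, p)
  rd <- read_pdb(p)
  expect_equal(nrow(rd$topology$atoms), nrow(sys$top$atoms))
  expect_setequal(unique(rd$topology$atoms$group), c("A", "B", "L1", "L2"))
  expect_equal(rd$topology$atoms$name, sys$top$atoms$name)
  expect_lt(max(abs(rd$frame - sys$ref)), 1e-3 + 1e-9)

  # three protein chains -> error
  lines <- readLines(p)
  extra <- lines[grep("^ATOM", lines)[1]]
  substr(extra, 22, 22) <- "C"
  writeLines(append(lines, extra, after = grep("^ATOM", lines)[1]), p)
  expect_error(read_pdb(p), "2 protein chains")
})

test_that("malformed, altloc and duplicate PDB records are rejected", {
  sys <- tiny_system(n_frames = 2)
  p <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(sys$top, sys$ref, p)
  lines <- readLines(p)
  i <- grep("^ATOM", lines)[3]

  bad <- lines; substr(bad[i], 31, 38) <- "   xx.xx"
  writeLines(bad, p)
  expect_error(read_pdb(p), paste0("line ", i))

  bad <- lines; substr(bad[i], 17, 17) <- "B"     # altLoc column
  writeLines(bad, p)
  expect_error(read_pdb(p), "lternate location")

  bad <- append(lines, lines[i], after = i)       # duplicate atom
  writeLines(bad, p)
  expect_error(read_pdb(p), "uplicate atom")
})

test_that("trajectory round trips preserve identities and coordinates", {
  sys <- tiny_system(n_frames = 4)
  xp <- withr::local_tempfile(fileext = ".xyz")
  write_xyz_series(sys$top, sys$traj, xp)
  back <- read_trajectory(xp, sys$top, label = "WT")
  expect_equal(back$xyz, sys$traj$xyz, tolerance = 1e-6)
  expect_equal(back$times, sys$traj$times)

  # multi-model PDB round trip at format precision
  pp <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(sys$top, sys$traj, pp)
  mm <- read_trajectory(pp, sys$top, t0 = 0, dt = 1)
  expect_equal(dim(mm$xyz), dim(sys$traj$xyz))
  expect_lt(max(abs(mm$xyz - sys$traj$xyz)), 1e-3 + 1e-9)

  # XYZ series with supplied clock
  t2 <- trajectory(sys$traj$xyz, sys$traj$times, "WT")
  xp2 <- withr::local_tempfile(fileext = ".xyz")
  writeLines(sub("t= [0-9.]+", "t=", readLines(xp)), xp2)  # strip stamps
  back2 <- read_trajectory(xp2, sys$top, t0 = 200, dt = 1)
  expect_equal(back2$times, 200 + 0:3)

  # atom-count mismatch names the frame
  small <- extract_subsystem(sys$top, 1:10)
  expect_error(read_trajectory(xp, small), "atoms")
})

test_that("parameter sidecar fully parameterizes or fails loudly", {
  sys <- tiny_system(n_frames = 2)
  sc <- withr::local_tempfile(fileext = ".tsv")
  write_parameter_sidecar(sys$top, sc)
  skel <- topology(sys$top$atoms[, c("name", "element", "resno", "resname",
                                     "group")],
                   sys$top$bonds)
  full <- read_parameter_sidecar(sc, skel)
  expect_true(dimerdyn:::is_parameterized(full))
  expect_equal(full$atoms$charge, sys$top$atoms$charge)
  expect_equal(full$bond_params$r0, sys$top$bond_params$r0, tolerance = 1e-9)

  # drop one atom row -> error naming it
  lines <- readLines(sc)
  row <- grep("^A\t5\t", lines)[1]
  writeLines(lines[-row], sc)
  expect_error(read_parameter_sidecar(sc, skel), "unparameterized atom")

  # corrupt a declared net charge -> warning
  write_parameter_sidecar(sys$top, sc)
  lines <- readLines(sc)
  lines[grep("^#NETCHARGE A", lines)] <- "#NETCHARGE A 5.0"
  writeLines(lines, sc)
  expect_warning(read_parameter_sidecar(sc, skel), "differs from declared")
})
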