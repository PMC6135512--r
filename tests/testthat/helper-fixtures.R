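# Shared fixtures: all built in code, no files.

# a one-atom "ion" topology with full parameters
ion_topology <- function(charge = -1, gb_radius = 1.5, group = "A",
                         resno = 1) {
  topology(data.frame(
    name = "X", element = "O", resno = resno, resname = "ION",
    group = group, charge = charge, lj_eps = 0.21, lj_rmin_half = 1.6612,
    gb_radius = gb_radius, lcpo_p1 = 0.77914, lcpo_p2 = -0.25262,
    lcpo_p3 = -0.0016056, lcpo_p4 = 0.00035071,
    stringsAsFactors = FALSE))
}

# n ions in one topology (groups alternate A/B so the dimer invariant holds)
ions_topology <- function(charges, groups = NULL) {
  n <- length(charges)
  if (is.null(groups)) groups <- rep(c("A", "B"), length.out = n)
  topology(data.frame(
    name = "X", element = "O", resno = seq_len(n), resname = "ION",
    group = groups, charge = charges, lj_eps = 0.21, lj_rmin_half = 1.6612,
    gb_radius = 1.5, lcpo_p1 = 0.77914, lcpo_p2 = -0.25262,
    lcpo_p3 = -0.0016056, lcpo_p4 = 0.00035071,
    stringsAsFactors = FALSE))
}

# small toy dimer + trajectory in one call
tiny_system <- function(residues = 14, n_frames = 30, label = "WT",
                        jitter_sd = 0.05, seed = 11, ...) {
  spec <- synthetic_spec(residues_per_monomer = residues,
                         n_frames = n_frames, jitter_sd = jitter_sd,
                         seed = seed, ...)
  toy <- build_toy_dimer(spec)
  traj <- generate_trajectory(toy$topology, toy$reference, spec, label,
                              toy$meta)
  list(spec = spec, top = toy$topology, ref = toy$reference,
       meta = toy$meta, traj = traj)
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

rigid_move <- function(coords, R = random_rotation(), t = rnorm(3, 0, 5)) {
  sweep(coords %*% R, 2, t, `+`)
}
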