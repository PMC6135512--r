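# Parameterized toy homodimer and trajectory generator with planted
# statistical structure: a collective interface counter-rotation mode with
# per-system amplitude means, a door-loop opening raising loop RMSF by a
# controlled amount, two-state Markov hydrogen-bond dynamics with exact
# stationary occupancy, per-system rigid cofactor mobility, and isotropic
# Gaussian thermal jitter. Every planted quantity is recorded so downstream
# modules can be scored against ground truth.

#' Specification of a synthetic dimer system
#'
#' Defaults emulate the study conditions of the hGOT1 analysis: a
#' 413-residue-per-monomer dimer with one PLP-like ligand per interface
#' site, 1000 frames at 1 ns spacing (analysis windows use the last 800),
#' a door loop at the scaled position of residues 15-32, per-system
#' interface-mode displacement means following the wild-type-zero /
#' R267H-positive / E266K,P300L-negative pattern, and per-system cofactor
#' mobilities scaled to the published cofactor RMSD averages (0.99, 1.13,
#' 1.48 and 1.40 A).
#'
#' @param residues_per_monomer residues per protein chain (>= 12).
#' @param ligand_atoms_per_site cofactor atoms per site (6-12; the first 6
#'   form the ring, then hydroxyl, bridge, phosphate tail).
#' @param amp_mean named vector of interface-mode displacement means, A,
#'   one entry per system label.
#' @param amp_sd SD of the per-frame interface-mode amplitude, A.
#' @param ligand_amp named vector of per-system rigid cofactor displacement
#'   scales (SD of the axial slide, A); labels absent from the vector get 0.
#'   Defaults are calibrated so the mean fitted cofactor RMSD (axial slide
#'   plus default jitter) reproduces the published per-system averages.
#' @param loop_range closed residue interval of the door loop (default:
#'   positions 15-32 scaled to the chain length).
#' @param loop_open_A target RMSF raise of the loop in the open state, A
#'   (0 disables; internally a shift of twice this value is applied after
#'   the onset frame, so the two-state RMSF equals the target).
#' @param loop_onset_frac fraction of the trajectory after which the loop
#'   opens.
#' @param k_on,k_off per-frame Markov switching probabilities of the
#'   planted hydrogen bonds (defaults 1/0: always formed).
#' @param jitter_sd isotropic thermal jitter per coordinate, A.
#' @param n_frames,dt_ns frame count (>= 2) and spacing.
#' @param seed integer seed; identical spec + seed + label gives a
#'   bitwise-identical trajectory.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(residues_per_monomer = 413,
                           ligand_atoms_per_site = 12,
                           amp_mean = c(WT = 0, E266K = -2, P300L = -2,
                                        R267H = 4),
                           amp_sd = 1.0,
                           ligand_amp = c(WT = 1.05, E266K = 1.24,
                                          R267H = 1.71, P300L = 1.60),
                           loop_range = NULL,
                           loop_open_A = 0, loop_onset_frac = 0.5,
                           k_on = 1, k_off = 0,
                           jitter_sd = 0.25,
                           n_frames = 1000, dt_ns = 1, seed = 42) {
  R <- as.integer(residues_per_monomer)
  if (R < 12) stop("synthetic_spec: need at least 12 residues per monomer")
  if (ligand_atoms_per_site < 6 || ligand_atoms_per_site > 12)
    stop("synthetic_spec: ligand_atoms_per_site must be in 6..12")
  if (is.null(loop_range))
    loop_range <- c(max(1, round(15 / 413 * R)), max(2, round(32 / 413 * R)))
  if (loop_range[2] > R)
    stop("synthetic_spec: loop range exceeds residues per monomer")
  if (amp_sd < 0 || jitter_sd < 0 || loop_open_A < 0)
    stop("synthetic_spec: SDs and displacements must be >= 0")
  if (any(c(k_on, k_off) < 0) || any(c(k_on, k_off) > 1))
    stop("synthetic_spec: switch rates must be probabilities in [0, 1]")
  if (n_frames < 2) stop("synthetic_spec: need at least 2 frames")
  structure(list(residues_per_monomer = R,
                 ligand_atoms_per_site = as.integer(ligand_atoms_per_site),
                 amp_mean = amp_mean, amp_sd = amp_sd,
                 ligand_amp = ligand_amp,
                 loop_range = loop_range, loop_open_A = loop_open_A,
                 loop_onset_frac = loop_onset_frac,
                 k_on = k_on, k_off = k_off, jitter_sd = jitter_sd,
                 n_frames = as.integer(n_frames), dt_ns = dt_ns,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# element-level force-field parameter table of the toy model
TOY_ELEMENT_PARAMS <- data.frame(
  element = c("C", "N", "O", "P"),
  lj_eps = c(0.1094, 0.17, 0.21, 0.20),
  lj_rmin_half = c(1.908, 1.824, 1.6612, 2.10),
  gb_radius = c(1.70, 1.55, 1.50, 1.85),
  lcpo_p1 = c(0.77887, 0.78602, 0.77914, 0.38650),
  lcpo_p2 = c(-0.28063, -0.29198, -0.25262, -0.18249),
  lcpo_p3 = c(-0.0012968, -0.0006537, -0.0016056, -0.0036598),
  lcpo_p4 = c(0.00039328, 0.00036247, 0.00035071, 0.00042640),
  stringsAsFactors = FALSE)

TOY_LIG_NAMES <- c("C2", "N1", "C6", "C5", "C4", "C3", "O3", "C5A", "P",
                   "O1P", "O2P", "O3P")
TOY_LIG_ELEM <- c("C", "N", "C", "C", "C", "C", "O", "C", "P", "O", "O", "O")
TOY_LIG_CHARGE <- c(0.3, -0.6, 0.1, 0.0, 0.1, 0.2, -0.55, 0.0, 1.25,
                    -0.9, -0.9, -1.0)

toy_ligand_coords <- function(zc, nlig) {
  ang <- (0:5) * pi / 3
  ring <- cbind(0, 1.4 * cos(ang), zc + 1.4 * sin(ang))
  extra <- rbind(c(0, 2.8 * cos(ang[6]), zc + 2.8 * sin(ang[6])),  # O3
                 c(0, -2.8, zc),                                    # C5A
                 c(0, -4.5, zc),                                    # P
                 c(0, -4.2, zc + 1.55),                             # O1P
                 c(0, -4.2, zc - 1.55),                             # O2P
                 c(0, -6.1, zc))                                    # O3P
  rbind(ring, extra)[seq_len(nlig), , drop = FALSE]
}

toy_ligand_bonds <- function(nlig) {
  b <- rbind(cbind(1:5, 2:6), c(6, 1))      # ring cycle
  ext <- rbind(c(6, 7), c(4, 8), c(8, 9), c(9, 10), c(9, 11), c(9, 12))
  b <- rbind(b, ext[ext[, 1] <= nlig & ext[, 2] <= nlig, , drop = FALSE])
  b
}

#' Build the toy homodimer topology and reference frame
#'
#' Constructs two mirror-image protein chains (Calpha plus a sidechain
#' dummy per residue) along the z axis at x = +/-7 A, one rigid PLP-like
#' ligand per interface site (six-membered coplanar ring including atoms
#' named C6 and N1, hydroxyl, bridge carbon and a charged phosphate-like
#' tail, net -2 e when complete), three hydrogen-bond donor residues per
#' monomer whose `OG` atoms sit 2.9 A from ligand-1 acceptors, and one
#' tryptophan-like residue per monomer carrying a six-membered ring stacked
#' 3.8 A from the ligand-2 ring plane. All bond parameters are harmonic
#' with the reference geometry as equilibrium, so the reference frame has
#' zero bonded energy.
#'
#' @param spec a [synthetic_spec()].
#' @param substitutions optional named vector mapping residue numbers to
#'   replacement residue names (applied to both monomers), emulating point
#'   variants.
#' @return `list(topology=, reference=, meta=)`; `meta` records donor/
#'   acceptor atoms, the door loop, core and PCA residue ranges, the
#'   stacking rings and the site compositions.
#' @export
build_toy_dimer <- function(spec = synthetic_spec(), substitutions = NULL) {
  R <- spec$residues_per_monomer
  nlig <- spec$ligand_atoms_per_site
  loop <- spec$loop_range
  s1_res <- max(loop[2] + 3, round(R / 3))
  r_trp <- round(2 * R / 3)
  donor_res <- s1_res + (-1):1
  if (r_trp %in% donor_res || s1_res + 2 >= r_trp)
    stop("build_toy_dimer: chain too short to place sites apart")
  z1 <- 3.8 * s1_res; z2 <- 3.8 * r_trp
  lig1 <- toy_ligand_coords(z1, nlig)
  lig_names <- TOY_LIG_NAMES[seq_len(nlig)]
  # acceptors paired with the three donor residues (availability depends
  # on ligand size): N1 always, O3 needs >= 7 atoms, O1P needs >= 10
  acc_names <- c("N1", if (nlig >= 7) "O3", if (nlig >= 10) "O1P")
  donor_res <- donor_res[seq_along(acc_names)]

  atoms <- list(); coords <- list(); bonds <- list()
  add <- function(name, element, resno, resname, group, charge, xyz) {
    k <- length(atoms) + 1L
    atoms[[k]] <<- data.frame(name = name, element = element, resno = resno,
                              resname = resname, group = group,
                              charge = charge, stringsAsFactors = FALSE)
    coords[[k]] <<- xyz
    k
  }
  # monomer A
  ca_idx <- integer(R)
  for (i in seq_len(R)) {
    is_donor <- i %in% donor_res
    resname <- if (is_donor) "SER" else if (i == r_trp) "TRP" else "GLY"
    qca <- if (is_donor) -0.3 else if (i %% 2 == 1) 0.05 else -0.05
    ca_idx[i] <- add("CA", "C", i, resname, "A", qca, c(7, 0, 3.8 * i))
    if (is_donor) {
      acc <- acc_names[match(i, donor_res)]
      apos <- lig1[match(acc, lig_names), ]
      og <- add("OG", "O", i, resname, "A", 0.3, apos + c(2.9, 0, 0))
      bonds[[length(bonds) + 1L]] <- c(ca_idx[i], og)
    } else if (i == r_trp) {
      ang <- (0:5) * pi / 3
      ring_nm <- c("CG", "CD1", "CD2", "CE2", "CE3", "CZ2")
      ridx <- integer(6)
      for (k in 1:6)
        ridx[k] <- add(ring_nm[k], "C", i, resname, "A", 0,
                       c(3.8, 1.4 * cos(ang[k]), z2 + 1.4 * sin(ang[k])))
      bonds <- c(bonds, lapply(1:6, function(k) c(ridx[k], ridx[k %% 6 + 1])),
                 list(c(ca_idx[i], ridx[1])))
    } else {
      cb <- add("CB", "C", i, resname, "A", 0, c(7, 1.5, 3.8 * i))
      bonds[[length(bonds) + 1L]] <- c(ca_idx[i], cb)
    }
    if (i > 1) bonds[[length(bonds) + 1L]] <- c(ca_idx[i - 1], ca_idx[i])
  }
  nA <- length(atoms)
  # monomer B: exact mirror through the x = 0 plane
  for (k in seq_len(nA)) {
    a <- atoms[[k]]
    add(a$name, a$element, a$resno, a$resname, "B", a$charge,
        coords[[k]] * c(-1, 1, 1))
  }
  bonds <- c(bonds, lapply(bonds[seq_len(length(bonds))], function(b) b + nA))
  # ligands
  lig_idx <- list()
  for (s in 1:2) {
    lco <- toy_ligand_coords(if (s == 1) z1 else z2, nlig)
    idx <- integer(nlig)
    for (k in seq_len(nlig))
      idx[k] <- add(lig_names[k], TOY_LIG_ELEM[k], R + 1, "PLP",
                    paste0("L", s), TOY_LIG_CHARGE[k], lco[k, ])
    lb <- toy_ligand_bonds(nlig)
    bonds <- c(bonds, lapply(seq_len(nrow(lb)),
                             function(r) idx[lb[r, ]]))
    lig_idx[[s]] <- idx
  }
  atab <- do.call(rbind, atoms)
  if (!is.null(substitutions)) {
    for (rn in names(substitutions)) {
      hit <- atab$group %in% c("A", "B") & atab$resno == as.integer(rn)
      atab$resname[hit] <- substitutions[[rn]]
    }
  }
  ep <- TOY_ELEMENT_PARAMS[match(atab$element, TOY_ELEMENT_PARAMS$element), ]
  atab <- cbind(atab, ep[, -1], row.names = NULL)
  ref <- do.call(rbind, coords)
  bmat <- do.call(rbind, bonds)
  r0 <- sqrt(rowSums((ref[bmat[, 1], , drop = FALSE] -
                      ref[bmat[, 2], , drop = FALSE])^2))
  bp <- data.frame(i = pmin(bmat[, 1], bmat[, 2]),
                   j = pmax(bmat[, 1], bmat[, 2]), k = 300, r0 = r0)
  top <- topology(atab, bmat, bond_params = bp)

  find_atom <- function(grp, resno, name)
    which(atab$group == grp & atab$resno == resno & atab$name == name)
  donors <- do.call(rbind, lapply(seq_along(donor_res), function(d) {
    rn <- donor_res[d]; acc <- acc_names[d]
    acc1 <- find_atom("L1", R + 1, acc)
    rbind(data.frame(donor = find_atom("A", rn, "OG"), acceptor = acc1,
                     dir = 1),
          data.frame(donor = find_atom("B", rn, "OG"), acceptor = acc1,
                     dir = -1))
  }))
  meta <- list(donor_res = donor_res, donors = donors,
               loop_range = loop,
               core_range = c(round(80 / 413 * R), round(300 / 413 * R)),
               pca_range = c(round(40 / 413 * R), round(403 / 413 * R)),
               trp_ring = vapply(c("CG", "CD1", "CD2", "CE2", "CE3", "CZ2"),
                                 function(nm) find_atom("A", r_trp, nm),
                                 integer(1)),
               lig_rings = lapply(1:2, function(s) lig_idx[[s]][1:6]),
               sites = lig_idx, site_res = c(s1_res, r_trp),
               c6 = c(find_atom("L1", R + 1, "C6"),
                      find_atom("L2", R + 1, "C6")))
  list(topology = top, reference = ref, meta = meta)
}

#' The essential-dynamics selection of a toy dimer
#'
#' Calpha atoms of the scaled inner residue range of both monomers plus
#' the C6 ring carbon of each cofactor site (for the full-size dimer:
#' residues 40-403, giving 730 centers).
#'
#' @param top toy [topology()].
#' @param meta meta list from [build_toy_dimer()].
#' @return Sorted atom indices.
#' @export
toy_pca_selection <- function(top, meta) {
  select_atoms(top, selection_spec(
    sel_term(group = c("A", "B"), resno = meta$pca_range, name = "CA"),
    sel_term(group = c("L1", "L2"), name = "C6")))
}

# planted interface mode: tapered counter-rotation of the two core domains
# about the interface axis, monomer B scaled by 0.85; oriented so that the
# rigid-projected selection restriction obeys the package's PC sign
# convention (largest-|component| coordinate positive).
interface_mode <- function(top, ref, meta, sel_idx) {
  a <- top$atoms
  n <- nrow(a)
  v <- matrix(0, n, 3)
  for (grp in c("A", "B")) {
    idx <- which(a$group == grp & a$resno >= meta$core_range[1] &
                   a$resno <= meta$core_range[2])
    c0 <- colMeans(ref[idx, , drop = FALSE])
    z <- ref[idx, 3]
    w <- 0.7 + 0.6 * (z - min(z)) / max(max(z) - min(z), 1e-9)
    u <- cbind(0, -(ref[idx, 3] - c0[3]), ref[idx, 2] - c0[2]) * w
    if (grp == "B") u <- -0.85 * u
    v[idx, ] <- u
  }
  vv <- as_xyz_vec(v)
  vv <- vv / sqrt(sum(vv^2))
  sel3 <- as.vector(t(outer(sel_idx, 1:3, function(i, k) 3 * (i - 1) + k)))
  m <- project_out_rigid(vv[sel3], ref[sel_idx, , drop = FALSE])
  eta <- sqrt(sum(m^2))            # amplitude fraction visible to PCA
  m <- m / eta
  if (m[which.max(abs(m))] < 0) { m <- -m; vv <- -vv }
  list(full = vv, sel = m, sel_idx = sel_idx, eta = eta)
}

label_seed <- function(seed, label) {
  (seed * 1009L + sum(utf8ToInt(label)) * 31L) %% 2147483647L
}

#' Generate a synthetic trajectory with planted structure
#'
#' Frames are the reference pose plus, in order: the interface mode scaled
#' by a per-frame amplitude `a(t) ~ N(mean[label], sd)`; the door-loop
#' opening displacement after the onset frame; a per-frame rigid random
#' displacement of each cofactor; isotropic Gaussian jitter on every atom;
#' and finally the hydrogen-bond donor atoms are posed at exactly 2.9 A
#' (formed) or 5.5 A (broken) from their acceptor according to a two-state
#' Markov chain with the spec's switch rates, so the planted occupancy is
#' exactly the chain's realized state fraction.
#'
#' @param top toy [topology()] from [build_toy_dimer()].
#' @param ref reference frame from [build_toy_dimer()].
#' @param spec the [synthetic_spec()].
#' @param label system label; must have an entry in `spec$amp_mean`.
#' @param meta meta list from [build_toy_dimer()].
#' @param bond_rates optional data.frame (`bond`, `k_on`, `k_off`) giving
#'   per-bond overrides of the Markov rates (`bond` indexes rows of
#'   `meta$donors`).
#' @return A [trajectory()] with attribute `planted`: the mode vectors and
#'   `eta`, drawn amplitudes, Markov state matrix, loop onset frame.
#' @export
generate_trajectory <- function(top, ref, spec, label, meta,
                                bond_rates = NULL) {
  if (!label %in% names(spec$amp_mean))
    stop("generate_trajectory: unknown system label '", label, "'")
  n <- n_atoms(top); Tn <- spec$n_frames
  sel <- toy_pca_selection(top, meta)
  mode <- interface_mode(top, ref, meta, sel)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(label_seed(spec$seed, label))

  amp <- stats::rnorm(Tn, spec$amp_mean[[label]], spec$amp_sd)
  lamp <- if (label %in% names(spec$ligand_amp))
    spec$ligand_amp[[label]] else 0
  # cofactor mobility is planted as a rigid slide along the pocket (z)
  # axis: it is clash-free by construction for any amplitude
  lig_shift <- lapply(1:2, function(s) stats::rnorm(Tn, 0, lamp))
  jit <- matrix(stats::rnorm(Tn * 3 * n, 0, spec$jitter_sd), Tn, 3 * n)

  nb <- nrow(meta$donors)
  rates <- data.frame(k_on = rep(spec$k_on, nb), k_off = rep(spec$k_off, nb))
  if (!is.null(bond_rates))
    for (r in seq_len(nrow(bond_rates))) {
      rates$k_on[bond_rates$bond[r]] <- bond_rates$k_on[r]
      rates$k_off[bond_rates$bond[r]] <- bond_rates$k_off[r]
    }
  p_stat <- ifelse(rates$k_on + rates$k_off > 0,
                   rates$k_on / (rates$k_on + rates$k_off), 1)
  states <- matrix(FALSE, Tn, nb)
  states[1, ] <- stats::runif(nb) < p_stat
  if (Tn > 1) {
    u <- matrix(stats::runif((Tn - 1) * nb), Tn - 1, nb)
    for (t in 2:Tn)
      states[t, ] <- ifelse(states[t - 1, ],
                            u[t - 1, ] >= rates$k_off,
                            u[t - 1, ] < rates$k_on)
  }

  onset <- if (spec$loop_open_A > 0)
    floor(spec$loop_onset_frac * Tn) + 1L else Tn + 1L
  a <- top$atoms
  loop_atoms <- lapply(c(A = 1, B = -1), function(sgn) {
    grp <- if (sgn > 0) "A" else "B"
    which(a$group == grp & a$resno >= spec$loop_range[1] &
            a$resno <= spec$loop_range[2])
  })
  refv <- as_xyz_vec(ref)
  xyz <- matrix(0, Tn, 3 * n)
  xcols <- function(idx) as.vector(t(outer(idx, 1:3,
                                           function(i, k) 3 * (i - 1) + k)))
  for (t in seq_len(Tn)) {
    fv <- refv + amp[t] * mode$full
    if (t >= onset) {
      for (gn in c("A", "B")) {
        sgn <- if (gn == "A") 1 else -1
        ii <- loop_atoms[[gn]]
        fv[3 * (ii - 1) + 1] <- fv[3 * (ii - 1) + 1] +
          sgn * 2 * spec$loop_open_A
      }
    }
    for (s in 1:2) {
      ii <- meta$sites[[s]]
      fv[3 * (ii - 1) + 3] <- fv[3 * (ii - 1) + 3] + lig_shift[[s]][t]
    }
    fv <- fv + jit[t, ]
    # pose donors relative to their (displaced, jittered) acceptor
    for (b in seq_len(nb)) {
      dn <- meta$donors$donor[b]; ac <- meta$donors$acceptor[b]
      d <- if (states[t, b]) 2.9 else 5.5
      fv[xcols(dn)] <- fv[xcols(ac)] + c(meta$donors$dir[b] * d, 0, 0)
    }
    xyz[t, ] <- fv
  }
  traj <- trajectory(xyz, spec$dt_ns * (seq_len(Tn) - 1), label)
  attr(traj, "planted") <- list(mode = mode, amp = amp, states = states,
                                loop_onset = onset,
                                stationary_occupancy = p_stat)
  traj
}
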