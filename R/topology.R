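#' @keywords internal
"_PACKAGE"

# Atom groups: "A"/"B" are the two protein monomers, "L1"/"L2" the two
# cofactor binding sites. Atom indices are 1-based and contiguous.

ATOM_GROUPS <- c("A", "B", "L1", "L2")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a molecular topology
#'
#' A topology holds atom identities, the monomer/ligand partition, the bond
#' graph and (optionally) the force-field parameters needed by the energy
#' functions: partial charges, Lennard-Jones well depth and radius, intrinsic
#' generalized-Born radii and the four LCPO surface-area coefficients.
#'
#' @param atoms data.frame with columns `name`, `element`, `resno`, `resname`,
#'   `group` (one of `"A"`, `"B"`, `"L1"`, `"L2"`) and optionally `charge`,
#'   `lj_eps`, `lj_rmin_half`, `gb_radius`, `lcpo_p1`..`lcpo_p4`.
#' @param bonds two-column integer matrix of bonded atom index pairs.
#' @param bond_params optional data.frame (`i`, `j`, `k`, `r0`) of harmonic
#'   bond parameters, kcal/mol/A^2 and Angstrom.
#' @param angle_params optional data.frame (`i`, `j`, `k3`, `ktheta`,
#'   `theta0`) with `theta0` in degrees.
#' @param torsion_params optional data.frame (`i`, `j`, `k3`, `l`, `vn`,
#'   `period`, `phase`) with `phase` in degrees.
#' @return An object of class `topology`.
#' @export
topology <- function(atoms, bonds = matrix(integer(0), ncol = 2),
                     bond_params = NULL, angle_params = NULL,
                     torsion_params = NULL) {
  stopifnot(is.data.frame(atoms))
  req <- c("name", "element", "resno", "resname", "group")
  miss <- setdiff(req, names(atoms))
  if (length(miss))
    stop("topology: atoms table lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(atoms$group %in% ATOM_GROUPS))
    stop("topology: atom group must be one of ", paste(ATOM_GROUPS, collapse = "/"))
  for (col in c("charge", "lj_eps", "lj_rmin_half", "gb_radius",
                "lcpo_p1", "lcpo_p2", "lcpo_p3", "lcpo_p4"))
    if (is.null(atoms[[col]])) atoms[[col]] <- NA_real_
  if (any(is.finite(atoms$gb_radius) & atoms$gb_radius <= 0))
    stop("topology: intrinsic GB radii must be positive")
  bonds <- as_bond_matrix(bonds, nrow(atoms))
  # no bond may link the two monomers (the cofactor is non-covalently bound,
  # so neither may protein-ligand bonds exist)
  g <- as.character(atoms$group)
  if (nrow(bonds)) {
    cross <- g[bonds[, 1]] != g[bonds[, 2]]
    if (any(cross))
      stop("topology: bonds crossing the monomer/ligand partition are not allowed (",
           sum(cross), " found)")
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, bonds = bonds,
                 bond_params = bond_params, angle_params = angle_params,
                 torsion_params = torsion_params,
                 cache = new.env(parent = emptyenv())),
            class = "topology")
}

as_bond_matrix <- function(bonds, natoms) {
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds)) {
    if (any(bonds < 1L | bonds > natoms))
      stop("topology: bond index out of range")
    bonds <- t(apply(bonds, 1, sort))
    bonds <- unique(bonds)
  }
  bonds
}

#' @export
print.topology <- function(x, ...) {
  a <- x$atoms
  cat("topology:", nrow(a), "atoms,", nrow(x$bonds), "bonds\n")
  for (grp in ATOM_GROUPS) {
    idx <- which(a$group == grp)
    if (length(idx))
      cat(sprintf("  %-2s: %4d atoms, residues %d..%d\n", grp, length(idx),
                  min(a$resno[idx]), max(a$resno[idx])))
  }
  cat("  parameterized:", if (is_parameterized(x)) "yes" else "no", "\n")
  invisible(x)
}

#' @rdname topology
#' @param x object to test.
#' @export
is.topology <- function(x) inherits(x, "topology")

n_atoms <- function(top) nrow(top$atoms)

is_parameterized <- function(top) {
  a <- top$atoms
  all(is.finite(a$charge)) && all(is.finite(a$lj_eps)) &&
    all(is.finite(a$lj_rmin_half)) && all(is.finite(a$gb_radius)) &&
    all(is.finite(a$lcpo_p1))
}

group_indices <- function(top, grp) which(top$atoms$group %in% grp)

#' Atom selection specifications
#'
#' A selection is a union of terms; each term constrains any of monomer/site
#' group, residue-number range (closed interval in author numbering), residue
#' name and atom name. Evaluation on a topology is deterministic and returns
#' a sorted, duplicate-free index vector.
#'
#' @param ... terms built with [sel_term()].
#' @return An object of class `atom_selection`.
#' @examples
#' # the essential-dynamics selection for an hGOT1-numbered dimer:
#' # Calpha of residues 40-403 of both monomers plus the cofactor C6 carbon
#' sel <- selection_spec(
#'   sel_term(group = "A", resno = c(40, 403), name = "CA"),
#'   sel_term(group = "B", resno = c(40, 403), name = "CA"),
#'   sel_term(group = c("L1", "L2"), name = "C6"))
#' @export
selection_spec <- function(...) {
  terms <- list(...)
  if (!all(vapply(terms, inherits, logical(1), "sel_term")))
    stop("selection_spec: all arguments must be sel_term() objects")
  structure(list(terms = terms), class = "atom_selection")
}

#' @rdname selection_spec
#' @param group monomer/site ids to match (subset of A/B/L1/L2), or NULL.
#' @param resno length-2 closed residue-number interval, or NULL.
#' @param resname residue name(s), or NULL.
#' @param name atom name(s), or NULL.
#' @export
sel_term <- function(group = NULL, resno = NULL, resname = NULL, name = NULL) {
  if (!is.null(resno)) {
    if (!length(resno) %in% 1:2 || anyNA(resno))
      stop("sel_term: resno must be a residue number or a length-2 closed interval")
    if (length(resno) == 1) resno <- c(resno, resno)
  }
  structure(list(group = group, resno = resno, resname = resname, name = name),
            class = "sel_term")
}

#' Evaluate an atom selection on a topology
#'
#' @param top a [topology()].
#' @param spec an [selection_spec()] object, or a single [sel_term()].
#' @return Sorted unique integer atom indices (possibly empty).
#' @export
select_atoms <- function(top, spec) {
  stopifnot(is.topology(top))
  if (inherits(spec, "sel_term")) spec <- selection_spec(spec)
  if (!inherits(spec, "atom_selection"))
    stop("select_atoms: spec must be a selection_spec()")
  a <- top$atoms
  hits <- integer(0)
  for (term in spec$terms) {
    keep <- rep(TRUE, nrow(a))
    if (!is.null(term$group)) keep <- keep & a$group %in% term$group
    if (!is.null(term$resno))
      keep <- keep & a$resno >= term$resno[1] & a$resno <= term$resno[2]
    if (!is.null(term$resname)) keep <- keep & a$resname %in% term$resname
    if (!is.null(term$name)) {
      if (!any(a$name %in% term$name))
        warning("select_atoms: atom name(s) ",
                paste(setdiff(term$name, a$name), collapse = ","),
                " not present in topology; term matches nothing")
      keep <- keep & a$name %in% term$name
    }
    hits <- c(hits, which(keep))
  }
  sort(unique(hits))
}

#' Extract a parameterized subsystem
#'
#' Returns the topology restricted to `idx` (atoms renumbered contiguously,
#' parameters kept, bonds and bonded parameters remapped; bonds crossing the
#' boundary are dropped) together with the trajectory restricted to the same
#' atoms, when one is supplied.
#'
#' @param top a [topology()].
#' @param idx valid atom indices.
#' @param traj optional [trajectory()] on the same topology.
#' @return The sub-topology, or `list(topology=, trajectory=)` if `traj` given.
#' @export
extract_subsystem <- function(top, idx, traj = NULL) {
  stopifnot(is.topology(top))
  idx <- sort(unique(as.integer(idx)))
  if (length(idx) == 0) stop("extract_subsystem: empty index set")
  if (any(idx < 1L | idx > n_atoms(top)))
    stop("extract_subsystem: atom index out of range")
  map <- integer(n_atoms(top)); map[idx] <- seq_along(idx)
  atoms <- top$atoms[idx, , drop = FALSE]
  keepb <- logical(0)
  bonds <- top$bonds
  if (nrow(bonds)) {
    keepb <- bonds[, 1] %in% idx & bonds[, 2] %in% idx
    bonds <- cbind(map[bonds[keepb, 1]], map[bonds[keepb, 2]])
  }
  remap_tab <- function(tab, cols) {
    if (is.null(tab) || !nrow(tab)) return(tab)
    keep <- Reduce(`&`, lapply(cols, function(cl) tab[[cl]] %in% idx))
    tab <- tab[keep, , drop = FALSE]
    for (cl in cols) tab[[cl]] <- map[tab[[cl]]]
    rownames(tab) <- NULL
    tab
  }
  sub <- topology(atoms, bonds,
                  bond_params = remap_tab(top$bond_params, c("i", "j")),
                  angle_params = remap_tab(top$angle_params, c("i", "j", "k3")),
                  torsion_params = remap_tab(top$torsion_params,
                                             c("i", "j", "k3", "l")))
  if (is.null(traj)) return(sub)
  stopifnot(is.trajectory(traj))
  cols <- as.vector(t(outer(idx, 1:3, function(i, k) 3L * (i - 1L) + k)))
  subtraj <- trajectory(traj$xyz[, cols, drop = FALSE], traj$times, traj$label)
  list(topology = sub, trajectory = subtraj)
}

#' Trajectories of coordinate frames
#'
#' Frames are stored bio3d-style as a `T x 3n` matrix (`x1,y1,z1,x2,...`),
#' with strictly increasing time stamps in nanoseconds and a system label.
#'
#' @param xyz numeric matrix, one row per frame, `3n` columns.
#' @param times numeric vector of frame times, ns, strictly increasing.
#' @param label system label (e.g. `"WT"`, `"E266K"`).
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(xyz, times, label = "system") {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) %% 3 != 0) stop("trajectory: column count must be 3*natoms")
  if (length(times) != nrow(xyz))
    stop("trajectory: length(times) must equal the number of frames")
  if (any(!is.finite(xyz))) stop("trajectory: non-finite coordinates")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("trajectory: times must be strictly increasing")
  structure(list(xyz = xyz, times = as.numeric(times), label = label),
            class = "trajectory")
}

#' @rdname trajectory
#' @param x object to test.
#' @export
is.trajectory <- function(x) inherits(x, "trajectory")

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory '%s': %d frames x %d atoms, t = %.6g..%.6g ns\n",
              x$label, nrow(x$xyz), ncol(x$xyz) / 3,
              min(x$times), max(x$times)))
  invisible(x)
}

n_frames <- function(traj) nrow(traj$xyz)

#' Get one frame of a trajectory as an n x 3 coordinate matrix
#'
#' @param traj a [trajectory()].
#' @param i frame index.
#' @export
get_frame <- function(traj, i) {
  if (i < 1 || i > n_frames(traj)) stop("get_frame: frame index out of range")
  matrix(traj$xyz[i, ], ncol = 3, byrow = TRUE)
}

#' Flatten an n x 3 coordinate matrix to a 3n vector (x1,y1,z1,...)
#' @param m coordinate matrix.
#' @export
as_xyz_vec <- function(m) as.vector(t(m))

#' Pick the frame indices of an analysis schedule
#'
#' The published protocol samples the last part of each production run at a
#' fixed stride: by default the last 800 ns at one frame per ns.
#'
#' @param traj a [trajectory()].
#' @param window_ns length of the trailing time window, ns.
#' @param stride_ns sampling stride, ns.
#' @return Integer frame indices.
#' @export
schedule_frames <- function(traj, window_ns = 800, stride_ns = 1) {
  t <- traj$times
  t0 <- max(t) - window_ns
  idx <- which(t > t0 + 1e-9)
  if (!length(idx)) stop("schedule_frames: window lies outside the trajectory")
  keep <- abs(((t[idx] - t[idx[1]]) / stride_ns) -
                round((t[idx] - t[idx[1]]) / stride_ns)) < 1e-6
  idx[keep]
}
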