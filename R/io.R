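# Structure / trajectory / parameter file handling.
#
# PDB reading and writing is delegated to bio3d; this layer adds the
# dimer-specific validation (exactly two protein chains, PLP HETATM groups
# mapped to the two binding sites, no altLoc / insertion codes) and the
# topology-skeleton construction. XYZ coordinate series and the TSV
# parameter sidecar are simple line formats read and written directly.

#' Read a PDB file into a topology skeleton and coordinates
#'
#' The file must contain exactly two protein chains (mapped in order to
#' monomers A and B) and at most two `PLP` HETATM groups (the group on the
#' first chain becomes binding site L1, on the second chain L2). Alternate
#' locations and insertion codes are rejected. Residue numbers are taken
#' verbatim (1-based author numbering; all residue intervals in this package
#' are closed).
#'
#' @param path PDB file path.
#' @param multi read all MODELs (returns all frames) instead of the first.
#' @return `list(topology=, frame=)` where `frame` is an n x 3 matrix for
#'   `multi = FALSE`, else an n x 3 x nframes array.
#' @export
read_pdb <- function(path, multi = FALSE) {
  if (!file.exists(path)) stop("read_pdb: no such file: ", path)
  validate_pdb_lines(path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = multi, verbose = FALSE))
  at <- pdb$atom
  if (any(!is.na(at$alt) & at$alt != ""))
    stop("read_pdb: alternate location indicators are not supported")
  if (any(!is.na(at$insert) & at$insert != ""))
    stop("read_pdb: insertion codes are not supported")
  is_lig <- at$type == "HETATM"
  if (any(is_lig & at$resid != "PLP"))
    stop("read_pdb: unsupported HETATM residue(s): ",
         paste(unique(at$resid[is_lig & at$resid != "PLP"]), collapse = ","))
  prot_chains <- unique(at$chain[!is_lig])
  if (length(prot_chains) != 2)
    stop("read_pdb: expected exactly 2 protein chains, found ",
         length(prot_chains))
  lig_chains <- unique(at$chain[is_lig])
  if (length(lig_chains) > 2)
    stop("read_pdb: more than two PLP ligand groups")
  group <- character(nrow(at))
  group[!is_lig] <- ifelse(at$chain[!is_lig] == prot_chains[1], "A", "B")
  if (any(is_lig)) {
    site_of <- stats::setNames(paste0("L", seq_along(lig_chains)), lig_chains)
    group[is_lig] <- site_of[at$chain[is_lig]]
  }
  key <- paste(group, at$resno, at$elety)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("read_pdb: duplicate atom within residue (", d, ")")
  }
  atoms <- data.frame(name = at$elety,
                      element = guess_element(at$elety),
                      resno = at$resno, resname = at$resid,
                      group = group, stringsAsFactors = FALSE)
  top <- topology(atoms)
  if (multi) {
    nf <- nrow(pdb$xyz)
    fr <- array(NA_real_, c(nrow(atoms), 3, nf))
    for (i in seq_len(nf)) fr[, , i] <- matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE)
  } else {
    fr <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE)
  }
  list(topology = top, frame = fr)
}

validate_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  sel <- which(rec %in% c("ATOM  ", "HETATM"))
  for (i in sel) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("read_pdb: malformed record at line ", i, " (truncated)")
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38), substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (any(is.na(xyz)))
      stop("read_pdb: malformed record at line ", i, " (unparseable coordinates)")
  }
  invisible(TRUE)
}

guess_element <- function(name) {
  e <- sub("^[0-9]*", "", name)
  substr(e, 1, 1)
}

#' Write a topology and coordinates to a (multi-model) PDB file
#'
#' @param top a [topology()].
#' @param coords n x 3 matrix, n x 3 x T array, or a [trajectory()].
#' @param path output file.
#' @export
write_pdb <- function(top, coords, path) {
  stopifnot(is.topology(top))
  if (is.trajectory(coords)) {
    xyz <- coords$xyz
  } else if (length(dim(coords)) == 3) {
    xyz <- t(apply(coords, 3, as_xyz_vec))
  } else {
    xyz <- matrix(as_xyz_vec(coords), nrow = 1)
  }
  a <- top$atoms
  chain <- c(A = "A", B = "B", L1 = "A", L2 = "B")[as.character(a$group)]
  type <- ifelse(a$group %in% c("L1", "L2"), "HETATM", "ATOM")
  bio3d::write.pdb(file = path, xyz = xyz, type = type, resno = a$resno,
                   resid = a$resname, chain = chain, elety = a$name,
                   eleno = seq_len(nrow(a)))
  invisible(path)
}

#' Read a coordinate trajectory matching a topology
#'
#' Accepts a multi-model PDB (`MODEL`/`ENDMDL`) or an XYZ coordinate series.
#' Times are taken from XYZ comment lines of the form `t= <ns>` when present,
#' otherwise generated as `t0 + dt * (0:(T-1))`.
#'
#' @param path trajectory file (`.pdb` or `.xyz`).
#' @param top the matching [topology()].
#' @param t0,dt time origin and spacing, ns, used when the file carries no
#'   time stamps.
#' @param label system label for the returned trajectory.
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, top, t0 = 0, dt = 1, label = "system") {
  stopifnot(is.topology(top))
  if (grepl("\\.xyz$", path, ignore.case = TRUE)) {
    out <- read_xyz_series(path)
    if (any(out$natoms != n_atoms(top))) {
      bad <- which(out$natoms != n_atoms(top))[1]
      stop("read_trajectory: frame ", bad, " has ", out$natoms[bad],
           " atoms, topology has ", n_atoms(top))
    }
    times <- if (all(is.finite(out$times))) out$times
             else t0 + dt * (seq_len(nrow(out$xyz)) - 1)
    return(trajectory(out$xyz, times, label))
  }
  res <- read_pdb(path, multi = TRUE)
  nf <- dim(res$frame)[3]
  if (n_atoms(res$topology) != n_atoms(top))
    stop("read_trajectory: frame 1 atom count (", n_atoms(res$topology),
         ") does not match topology (", n_atoms(top), ")")
  xyz <- t(apply(res$frame, 3, as_xyz_vec))
  trajectory(xyz, t0 + dt * (seq_len(nf) - 1), label)
}

read_xyz_series <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list(); times <- numeric(0); natoms <- integer(0)
  i <- 1L; k <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("read_xyz_series: bad atom-count line at line ", i)
    comment <- lines[i + 1L]
    tm <- regmatches(comment, regexec("t=\\s*([-0-9.eE+]+)", comment))[[1]]
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "\\s+")
    co <- vapply(parts, function(p) as.numeric(p[2:4]), numeric(3))
    if (any(is.na(co)))
      stop("read_xyz_series: unparseable coordinates in frame ", k + 1L)
    k <- k + 1L
    frames[[k]] <- as.vector(co)          # already x1,y1,z1,x2,...
    times[k] <- if (length(tm) == 2) as.numeric(tm[2]) else NA_real_
    natoms[k] <- n
    i <- i + 2L + n
  }
  if (!k) stop("read_xyz_series: no frames found")
  list(xyz = do.call(rbind, frames), times = times, natoms = natoms)
}

#' Write a trajectory as an XYZ coordinate series
#'
#' @param top a [topology()] supplying atom names.
#' @param traj a [trajectory()].
#' @param path output file.
#' @export
write_xyz_series <- function(top, traj, path) {
  stopifnot(is.topology(top), is.trajectory(traj))
  n <- n_atoms(top)
  nm <- top$atoms$name
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    m <- get_frame(traj, f)
    writeLines(c(as.character(n),
                 sprintf("t= %.6f ns system= %s", traj$times[f], traj$label),
                 sprintf("%-4s %12.6f %12.6f %12.6f", nm, m[, 1], m[, 2], m[, 3])),
               con)
  }
  invisible(path)
}

SIDECAR_COLS <- c("monomer", "resnum", "resname", "atomname", "charge_e",
                  "lj_eps_kcal", "lj_rmin_half_A", "gb_radius_A",
                  "lcpo_p1", "lcpo_p2", "lcpo_p3", "lcpo_p4")

#' Read a force-field parameter sidecar and parameterize a topology
#'
#' The sidecar is a flat TSV keyed by (monomer/site, residue number, atom
#' name) carrying the partial charge, Lennard-Jones parameters, intrinsic GB
#' radius and LCPO coefficients of every atom. Optional `#NETCHARGE <group>
#' <q>` header lines declare per-group net charges, checked to 1e-3 e.
#' An optional `#BONDS` section supplies harmonic bond parameters
#' (`monomer_i resnum_i atom_i monomer_j resnum_j atom_j k_kcal r0_A`).
#'
#' @param path sidecar TSV path.
#' @param top the topology skeleton to parameterize.
#' @return The fully parameterized [topology()].
#' @export
read_parameter_sidecar <- function(path, top) {
  stopifnot(is.topology(top))
  lines <- readLines(path, warn = FALSE)
  netdecl <- grep("^#NETCHARGE", lines, value = TRUE)
  bsec <- which(lines == "#BONDS")
  body_end <- if (length(bsec)) bsec - 1L else length(lines)
  body <- lines[seq_len(body_end)]
  body <- body[!startsWith(body, "#") & nzchar(trimws(body))]
  tab <- utils::read.delim(text = paste(body, collapse = "\n"),
                           stringsAsFactors = FALSE)
  miss <- setdiff(SIDECAR_COLS, names(tab))
  if (length(miss))
    stop("read_parameter_sidecar: missing column(s): ",
         paste(miss, collapse = ", "))
  if (any(tab$gb_radius_A <= 0))
    stop("read_parameter_sidecar: non-positive GB radius in sidecar")
  a <- top$atoms
  key_top <- paste(a$group, a$resno, a$name)
  key_tab <- paste(tab$monomer, tab$resnum, tab$atomname)
  hit <- match(key_top, key_tab)
  if (anyNA(hit))
    stop("read_parameter_sidecar: unparameterized atom(s): ",
         paste(utils::head(key_top[is.na(hit)], 10), collapse = "; "),
         if (sum(is.na(hit)) > 10) " ..." else "")
  a$charge <- tab$charge_e[hit]
  a$lj_eps <- tab$lj_eps_kcal[hit]
  a$lj_rmin_half <- tab$lj_rmin_half_A[hit]
  a$gb_radius <- tab$gb_radius_A[hit]
  a$lcpo_p1 <- tab$lcpo_p1[hit]; a$lcpo_p2 <- tab$lcpo_p2[hit]
  a$lcpo_p3 <- tab$lcpo_p3[hit]; a$lcpo_p4 <- tab$lcpo_p4[hit]
  for (decl in netdecl) {
    p <- strsplit(trimws(decl), "\\s+")[[1]]
    grp <- p[2]; q <- as.numeric(p[3])
    qsum <- sum(a$charge[a$group == grp])
    if (is.finite(q) && abs(qsum - q) > 1e-3)
      warning(sprintf(
        "read_parameter_sidecar: group %s charge sum %.4f differs from declared %.4f",
        grp, qsum, q))
  }
  bp <- NULL
  if (length(bsec)) {
    btab <- utils::read.delim(
      text = paste(lines[(bsec + 1L):length(lines)], collapse = "\n"),
      stringsAsFactors = FALSE)
    bi <- match(paste(btab$monomer_i, btab$resnum_i, btab$atom_i), key_top)
    bj <- match(paste(btab$monomer_j, btab$resnum_j, btab$atom_j), key_top)
    if (anyNA(bi) || anyNA(bj))
      stop("read_parameter_sidecar: bond parameter references unknown atom")
    bp <- data.frame(i = pmin(bi, bj), j = pmax(bi, bj),
                     k = btab$k_kcal, r0 = btab$r0_A)
  }
  # the bond section defines the bond graph (PDB skeletons carry no bonds)
  bonds <- top$bonds
  if (!is.null(bp) && nrow(bp))
    bonds <- unique(rbind(bonds, cbind(bp$i, bp$j)))
  topology(a, bonds, bond_params = bp %||% top$bond_params,
           angle_params = top$angle_params,
           torsion_params = top$torsion_params)
}

#' Write the parameter sidecar for a parameterized topology
#'
#' @param top a parameterized [topology()].
#' @param path output TSV path.
#' @export
write_parameter_sidecar <- function(top, path) {
  stopifnot(is.topology(top))
  a <- top$atoms
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (grp in unique(as.character(a$group)))
    writeLines(sprintf("#NETCHARGE %s %.6f", grp,
                       sum(a$charge[a$group == grp])), con)
  tab <- data.frame(monomer = a$group, resnum = a$resno, resname = a$resname,
                    atomname = a$name, charge_e = a$charge,
                    lj_eps_kcal = a$lj_eps, lj_rmin_half_A = a$lj_rmin_half,
                    gb_radius_A = a$gb_radius,
                    lcpo_p1 = a$lcpo_p1, lcpo_p2 = a$lcpo_p2,
                    lcpo_p3 = a$lcpo_p3, lcpo_p4 = a$lcpo_p4)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(top$bond_params) && nrow(top$bond_params)) {
    bp <- top$bond_params
    writeLines("#BONDS", con)
    btab <- data.frame(monomer_i = a$group[bp$i], resnum_i = a$resno[bp$i],
                       atom_i = a$name[bp$i], monomer_j = a$group[bp$j],
                       resnum_j = a$resno[bp$j], atom_j = a$name[bp$j],
                       k_kcal = bp$k, r0_A = bp$r0)
    utils::write.table(btab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
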