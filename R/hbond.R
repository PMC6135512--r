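# Geometric hydrogen-bond detection and per-bond occupancy networks.

#' Hydrogen-bond geometric criteria
#'
#' Defaults follow the common MD-analysis convention: donor-acceptor
#' heavy-atom distance <= 3.5 A and donor-hydrogen-acceptor angle >= 135
#' degrees. When the topology carries no hydrogens, set
#' `require_hydrogen = FALSE` to use the distance criterion alone
#' (heavy-atom-only mode).
#'
#' @param dist_cutoff donor-acceptor heavy-atom cutoff, A (> 0).
#' @param angle_min minimum D-H-A angle, degrees, in (0, 180].
#' @param require_hydrogen demand an explicit hydrogen and apply the angle
#'   criterion.
#' @export
hbond_criteria <- function(dist_cutoff = 3.5, angle_min = 135,
                           require_hydrogen = FALSE) {
  if (dist_cutoff <= 0) stop("hbond_criteria: dist_cutoff must be > 0")
  if (angle_min <= 0 || angle_min > 180)
    stop("hbond_criteria: angle_min must lie in (0, 180]")
  structure(list(dist_cutoff = dist_cutoff, angle_min = angle_min,
                 require_hydrogen = require_hydrogen),
            class = "hbond_criteria")
}

# donor/acceptor heavy atoms: N or O; donors additionally need an attached
# hydrogen when hydrogens are modelled.
hbond_partners <- function(top, criteria) {
  a <- top$atoms
  polar <- which(a$element %in% c("N", "O"))
  has_h <- any(a$element == "H")
  if (criteria$require_hydrogen && !has_h)
    stop("find_hbonds: topology has no hydrogens; use heavy-atom-only mode ",
         "(require_hydrogen = FALSE)")
  hyd <- vector("list", n_atoms(top))
  if (has_h) {
    g <- bond_graph(top)
    for (i in polar) hyd[[i]] <- g$adj[[i]][a$element[g$adj[[i]]] == "H"]
  }
  donors <- if (criteria$require_hydrogen)
    polar[lengths(hyd[polar]) > 0] else polar
  list(donors = donors, acceptors = polar, hydrogens = hyd)
}

# candidate donor/acceptor pairs; excludes same-residue pairs and 1-2/1-3
# bonded pairs. restriction = "ligand" keeps only pairs with exactly one
# partner in a cofactor site (the cofactor-coupled network).
hbond_candidates <- function(top, criteria, restriction = c("all", "ligand")) {
  restriction <- match.arg(restriction)
  p <- hbond_partners(top, criteria)
  cand <- expand.grid(donor = p$donors, acceptor = p$acceptors)
  cand <- cand[cand$donor != cand$acceptor, , drop = FALSE]
  a <- top$atoms
  rtag <- paste(a$group, a$resno)
  cand <- cand[rtag[cand$donor] != rtag[cand$acceptor], , drop = FALSE]
  pcm <- pair_class_matrix(top)
  cand <- cand[pcm[cbind(cand$donor, cand$acceptor)] != 1L, , drop = FALSE]
  if (!criteria$require_hydrogen) {
    # without hydrogens (d, a) and (a, d) are geometrically identical:
    # keep one orientation per heavy-atom pair
    cand <- cand[cand$donor < cand$acceptor, , drop = FALSE]
  }
  if (restriction == "ligand") {
    lig <- a$group %in% c("L1", "L2")
    cand <- cand[xor(lig[cand$donor], lig[cand$acceptor]), , drop = FALSE]
  }
  cand <- cand[order(cand$donor, cand$acceptor), , drop = FALSE]
  rownames(cand) <- NULL
  list(pairs = cand, hydrogens = p$hydrogens)
}

hbond_formed <- function(frame, pairs, hydrogens, criteria) {
  d <- frame[pairs$donor, , drop = FALSE] - frame[pairs$acceptor, , drop = FALSE]
  ok <- sqrt(rowSums(d^2)) <= criteria$dist_cutoff
  if (criteria$require_hydrogen && any(ok)) {
    for (r in which(ok)) {
      hs <- hydrogens[[pairs$donor[r]]]
      if (!length(hs)) { ok[r] <- FALSE; next }
      # vectors from the hydrogen to donor and acceptor: angle at H
      dh <- frame[rep(pairs$donor[r], length(hs)), , drop = FALSE] -
        frame[hs, , drop = FALSE]
      ah <- frame[rep(pairs$acceptor[r], length(hs)), , drop = FALSE] -
        frame[hs, , drop = FALSE]
      cosang <- rowSums(dh * ah) / (sqrt(rowSums(dh^2)) * sqrt(rowSums(ah^2)))
      ang <- acos(pmax(-1, pmin(1, cosang))) * 180 / pi
      ok[r] <- any(ang >= criteria$angle_min)
    }
  }
  ok
}

atom_tag <- function(top, idx) {
  if (!length(idx)) return(character(0))
  a <- top$atoms
  paste0(a$group[idx], ":", a$resname[idx], a$resno[idx], ":", a$name[idx])
}

#' Hydrogen bonds present in a single frame
#'
#' @param top a [topology()].
#' @param frame n x 3 coordinate matrix.
#' @param criteria an [hbond_criteria()].
#' @param restriction `"all"` or `"ligand"` (one partner in a cofactor site).
#' @return data.frame of (donor, acceptor, donor_tag, acceptor_tag),
#'   deterministically ordered by atom index.
#' @export
find_hbonds <- function(top, frame, criteria = hbond_criteria(),
                        restriction = "all") {
  cd <- hbond_candidates(top, criteria, restriction)
  ok <- hbond_formed(frame, cd$pairs, cd$hydrogens, criteria)
  out <- cd$pairs[ok, , drop = FALSE]
  out$donor_tag <- atom_tag(top, out$donor)
  out$acceptor_tag <- atom_tag(top, out$acceptor)
  rownames(out) <- NULL
  out
}

#' Per-bond occupancy over a trajectory
#'
#' A bond's identity is the (donor heavy atom, acceptor heavy atom) pair;
#' occupancy is the exact rational fraction of frames in which the
#' geometric criteria hold. Only bonds observed in at least one frame are
#' reported.
#'
#' @param traj a [trajectory()] with at least one frame.
#' @param top the matching [topology()].
#' @param criteria an [hbond_criteria()].
#' @param restriction `"all"` or `"ligand"`.
#' @param frames optional frame indices (default: all frames).
#' @return An `occupancy_table` data.frame (donor, acceptor, donor_tag,
#'   acceptor_tag, formed, frames, occupancy, system).
#' @export
occupancy_table <- function(traj, top, criteria = hbond_criteria(),
                            restriction = "ligand", frames = NULL) {
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  if (!length(frames)) stop("occupancy_table: zero frames")
  cd <- hbond_candidates(top, criteria, restriction)
  formed <- integer(nrow(cd$pairs))
  for (f in frames)
    formed <- formed + hbond_formed(get_frame(traj, f), cd$pairs,
                                    cd$hydrogens, criteria)
  keep <- formed > 0
  out <- cd$pairs[keep, , drop = FALSE]
  out$donor_tag <- atom_tag(top, out$donor)
  out$acceptor_tag <- atom_tag(top, out$acceptor)
  out$formed <- formed[keep]
  out$frames <- length(frames)
  out$occupancy <- out$formed / out$frames
  out$system <- traj$label
  rownames(out) <- NULL
  structure(out, class = c("occupancy_table", "data.frame"))
}

# bond key robust to point substitutions: residue number + atom name,
# without the residue name, so a bond at a mutated residue still matches.
bond_key <- function(tab) {
  strip <- function(tag) sub(":[A-Za-z0-9]*?([0-9]+):", ":\\1:", tag)
  paste(strip(tab$donor_tag), strip(tab$acceptor_tag), sep = " -> ")
}

#' Compare hydrogen-bond networks of variants against a reference
#'
#' Aligns occupancy tables by (group, residue number, atom name) on both
#' bond partners, so bonds at substituted residues still match by residue
#' number. Bonds with occupancy 1.0 in the reference are flagged as key
#' bonds; a bond present in the reference but absent in a variant gets
#' delta `-occupancy_ref`, and a variant-only bond gets `+occupancy_var`.
#'
#' @param reference `occupancy_table` of the reference system.
#' @param variants named list of variant `occupancy_table`s.
#' @param topologies optional named list of topologies (reference first)
#'   used to report bonds whose atoms exist in no other system under
#'   `unmatched` instead of silently dropping them.
#' @return `list(comparison=, key_bonds=, unmatched=)`.
#' @export
compare_networks <- function(reference, variants, topologies = NULL) {
  stopifnot(inherits(reference, "occupancy_table"))
  if (is.null(names(variants)) || any(!nzchar(names(variants))))
    stop("compare_networks: variants must be a named list")
  keys <- unique(c(bond_key(reference),
                   unlist(lapply(variants, bond_key))))
  occ_of <- function(tab) {
    o <- stats::setNames(rep(0, length(keys)), keys)
    o[bond_key(tab)] <- tab$occupancy
    o
  }
  ref_occ <- occ_of(reference)
  cmp <- data.frame(bond = keys, occupancy_ref = as.numeric(ref_occ),
                    stringsAsFactors = FALSE)
  for (v in names(variants)) {
    vo <- occ_of(variants[[v]])
    cmp[[paste0("occupancy_", v)]] <- as.numeric(vo)
    cmp[[paste0("delta_", v)]] <- as.numeric(vo - ref_occ)
  }
  cmp$key_bond <- cmp$occupancy_ref == 1
  unmatched <- character(0)
  if (!is.null(topologies)) {
    tags <- lapply(topologies, function(tp) {
      a <- tp$atoms
      paste0(a$group, ":", a$resno, ":", a$name)
    })
    strip1 <- function(tag) sub(":[A-Za-z0-9]*?([0-9]+):", ":\\1:", tag)
    for (k in keys) {
      ends <- strsplit(k, " -> ", fixed = TRUE)[[1]]
      present <- vapply(tags, function(tg) all(ends %in% strip1(tg)), logical(1))
      if (!all(present)) unmatched <- c(unmatched, k)
    }
    cmp <- cmp[!cmp$bond %in% unmatched, , drop = FALSE]
  }
  list(comparison = cmp, key_bonds = cmp$bond[cmp$key_bond],
       unmatched = unmatched)
}
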