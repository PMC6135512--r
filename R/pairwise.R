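# Per-residue decomposition of the dimerization (EE) and cofactor-binding
# (EL) energies. The decomposition is exact: cross Coulomb/LJ and GB pair
# terms are split half-and-half between the two partners' residues, GB
# self/intra desolvation (complex-context vs separated-context radii) and
# per-atom surface-area changes are assigned to their own residue, so the
# per-residue contributions sum to the total interaction energy per frame.

prep_binding_pair <- function(top, idxI, idxJ) {
  idxI <- sort(idxI); idxJ <- sort(idxJ)
  if (length(intersect(idxI, idxJ)))
    stop("pairwise decomposition: partitions overlap")
  all_idx <- sort(c(idxI, idxJ))
  complex_top <- extract_subsystem(top, all_idx)
  li <- match(idxI, all_idx); lj <- match(idxJ, all_idx)
  list(all_idx = all_idx, complex = complex_top,
       li = li, lj = lj,
       subI = extract_subsystem(complex_top, li),
       subJ = extract_subsystem(complex_top, lj))
}

binding_atom_contrib <- function(prep, frame_all, constants) {
  ct <- prep$complex
  fr <- frame_all[prep$all_idx, , drop = FALSE]
  a <- ct$atoms
  n <- nrow(a)
  li <- prep$li; lj <- prep$lj
  kd <- 1 / constants$eps_in - 1 / constants$eps_out
  D <- dist_matrix(fr)
  DI <- D[li, li, drop = FALSE]; DJ <- D[lj, lj, drop = FALSE]
  Rc <- effective_born_radii(ct, fr, constants, D)
  RI <- effective_born_radii(prep$subI, fr[li, , drop = FALSE], constants, DI)
  RJ <- effective_born_radii(prep$subJ, fr[lj, , drop = FALSE], constants, DJ)

  # cross Coulomb + LJ (ordinary nonbonded: partitions share no bonds)
  st <- energy_static(ct, constants)
  cross <- matrix(FALSE, n, n)
  cross[li, lj] <- TRUE; cross[lj, li] <- TRUE
  Dc <- D; diag(Dc) <- Inf
  qq <- st$qq
  s6 <- (st$rmin / Dc)^6
  Ecl <- (COULOMB_K * st$wc * qq / Dc / constants$eps_in +
          st$wl * st$eps * (s6^2 - 2 * s6)) * cross
  contrib_cl <- 0.5 * rowSums(Ecl)

  # GB: complex-context pair/self terms minus the separated-state ones
  f_c <- gb_f_matrix(D, Rc)
  inv_ref <- matrix(0, n, n)
  inv_ref[li, li] <- 1 / gb_f_matrix(DI, RI)
  inv_ref[lj, lj] <- 1 / gb_f_matrix(DJ, RJ)
  P <- -GB_HALF_K * kd * qq * (1 / f_c - inv_ref)
  contrib_gb <- rowSums(P)

  # nonpolar: per-atom surface-area change
  A_c <- sasa_lcpo(ct, fr, constants, D)$per_atom
  A_sep <- numeric(n)
  A_sep[li] <- sasa_lcpo(prep$subI, fr[li, , drop = FALSE], constants,
                         DI)$per_atom
  A_sep[lj] <- sasa_lcpo(prep$subJ, fr[lj, , drop = FALSE], constants,
                         DJ)$per_atom
  contrib_np <- constants$gamma_tension * (A_c - A_sep)

  contrib_cl + contrib_gb + contrib_np
}

residue_tags_of <- function(top, idx) {
  a <- top$atoms
  ifelse(a$group[idx] %in% c("L1", "L2"), as.character(a$group[idx]),
         paste0(a$group[idx], ":", a$resno[idx]))
}

#' Per-residue decomposition of EE or EL over a trajectory
#'
#' For `partition = "interface"` each residue's contribution to the
#' monomer-monomer dimerization energy (EE) is computed; for `partition =
#' "ligand"` contributions to the total cofactor binding energy (EL, both
#' sites) are computed, with the cofactor's own share reported under tags
#' `L1`/`L2`. Contributions are exact (they sum to the corresponding total
#' per frame) and are summarized as mean and SD over the frame schedule;
#' pass a reference profile to report values relative to it.
#'
#' @param top a parameterized [topology()].
#' @param traj the matching [trajectory()].
#' @param partition `"interface"` (EE) or `"ligand"` (EL).
#' @param window_ns,stride_ns frame schedule.
#' @param constants an [energy_constants()] list.
#' @param reference optional `residue_energy_profile` to subtract
#'   (mean-level), e.g. the wild-type profile.
#' @return A `residue_energy_profile` data.frame (tag, mean, sd) with the
#'   per-frame matrix in `$per_frame` attribute-free list form.
#' @export
pairwise_residue_decomposition <- function(top, traj,
                                           partition = c("interface", "ligand"),
                                           window_ns = 800, stride_ns = 1,
                                           constants = energy_constants(),
                                           reference = NULL) {
  require_params(top)
  partition <- match.arg(partition)
  fidx <- schedule_frames(traj, window_ns, stride_ns)
  iA <- group_indices(top, "A"); iB <- group_indices(top, "B")
  if (partition == "interface") {
    preps <- list(prep_binding_pair(top, iA, iB))
  } else {
    preps <- list()
    for (s in c("L1", "L2")) {
      iL <- group_indices(top, s)
      if (length(iL)) preps <- c(preps, list(prep_binding_pair(top, c(iA, iB), iL)))
    }
    if (!length(preps))
      stop("pairwise_residue_decomposition: topology has no cofactor sites")
  }
  tag_sets <- lapply(preps, function(p) residue_tags_of(top, p$all_idx))
  tags <- unique(unlist(tag_sets))
  mat <- matrix(0, length(fidx), length(tags),
                dimnames = list(NULL, tags))
  for (k in seq_along(fidx)) {
    fr <- get_frame(traj, fidx[k])
    for (pi in seq_along(preps)) {
      contrib <- binding_atom_contrib(preps[[pi]], fr, constants)
      agg <- tapply(contrib, tag_sets[[pi]], sum)
      mat[k, names(agg)] <- mat[k, names(agg)] + as.numeric(agg)
    }
  }
  out <- data.frame(tag = tags, mean = colMeans(mat),
                    sd = apply(mat, 2, stats::sd),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(reference)) {
    hit <- match(out$tag, reference$tag)
    ref_mean <- ifelse(is.na(hit), 0, reference$mean[hit])
    out$mean <- out$mean - ref_mean
    out$relative_to <- attr(reference, "system") %||% "reference"
  }
  structure(out, class = c("residue_energy_profile", "data.frame"),
            partition = partition, system = traj$label,
            per_frame = mat,
            schedule = list(window_ns = window_ns, stride_ns = stride_ns,
                            n_frames = length(fidx)))
}
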