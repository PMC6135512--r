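# Implicit-solvent molecular-mechanics energies and the EM/EE/EL/ET
# decomposition. All energies in kcal/mol, distances in Angstrom, charges
# in elementary charge units.

COULOMB_K <- 332.0637          # kcal*A/(mol*e^2)
GB_HALF_K <- COULOMB_K / 2     # 166.03185, prefactor of the GB double sum

# HCT/OBC pairwise descreening scale factors by element (0.8 fallback)
GB_SCREEN <- c(H = 0.85, C = 0.72, N = 0.79, O = 0.85, S = 0.80, P = 0.86)

#' Energy-model constants
#'
#' Defaults reproduce the AMBER implicit-solvent post-processing setup:
#' OBC2 generalized Born (igb = 5; alpha = 1.0, beta = 0.8, gamma = 4.85,
#' dielectric offset 0.09 A), interior/exterior dielectrics 1 and 78.5,
#' LCPO surface area (gbsa = 1) with a 1.4 A probe and surface tension
#' 0.005 kcal/(mol*A^2), no nonbonded cutoff, 1-4 scaling 1/1.2 (Coulomb)
#' and 1/2.0 (Lennard-Jones).
#'
#' @param eps_in,eps_out interior and solvent dielectric constants.
#' @param gamma_tension nonpolar surface tension, kcal/(mol*A^2).
#' @param probe solvent probe radius, A.
#' @param scale14_coul,scale14_lj divisors applied to 1-4 pairs.
#' @param obc_alpha,obc_beta,obc_gamma OBC2 tanh-rescaling coefficients.
#' @param gb_offset dielectric radius offset, A.
#' @export
energy_constants <- function(eps_in = 1, eps_out = 78.5,
                             gamma_tension = 0.005, probe = 1.4,
                             scale14_coul = 1.2, scale14_lj = 2.0,
                             obc_alpha = 1.0, obc_beta = 0.8,
                             obc_gamma = 4.85, gb_offset = 0.09) {
  as.list(environment())
}

require_params <- function(top, what = "energy evaluation") {
  if (!is_parameterized(top))
    stop(what, " requires a fully parameterized topology ",
         "(see read_parameter_sidecar)")
}

dist_matrix <- function(frame, idx_i = NULL, idx_j = NULL) {
  a <- if (is.null(idx_i)) frame else frame[idx_i, , drop = FALSE]
  b <- if (is.null(idx_i)) frame else frame[idx_j, , drop = FALSE]
  sqrt(pmax(outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b), 0))
}

# geometry-independent per-topology matrices used by the energy kernels,
# cached on the topology (keyed by the 1-4 scaling constants)
energy_static <- function(top, constants) {
  key <- paste0("static_", constants$scale14_coul, "_", constants$scale14_lj)
  st <- top$cache[[key]]
  if (!is.null(st)) return(st)
  a <- top$atoms
  n <- nrow(a)
  pcm <- pair_class_matrix(top)
  wc <- matrix(1, n, n); wl <- matrix(1, n, n)
  wc[pcm == 1L] <- 0; wl[pcm == 1L] <- 0
  wc[pcm == 2L] <- 1 / constants$scale14_coul
  wl[pcm == 2L] <- 1 / constants$scale14_lj
  diag(wc) <- 0; diag(wl) <- 0
  scr <- GB_SCREEN[a$element]
  scr[is.na(scr)] <- 0.8
  rho_t <- a$gb_radius - constants$gb_offset
  Rlc <- a$lj_rmin_half + constants$probe
  st <- list(qq = outer(a$charge, a$charge),
             eps = sqrt(outer(a$lj_eps, a$lj_eps)),
             rmin = outer(a$lj_rmin_half, a$lj_rmin_half, `+`),
             wc = wc, wl = wl,
             rho_t = rho_t,
             S = matrix(rho_t * scr, n, n, byrow = TRUE),
             RT = matrix(rho_t, n, n),
             Rlc = Rlc, S1 = 4 * pi * Rlc^2,
             Rsum = outer(Rlc, Rlc, `+`))
  top$cache[[key]] <- st
  st
}

#' Harmonic bonded energy (bonds, angles, torsions)
#'
#' AMBER conventions: `E_bond = k (r - r0)^2`, `E_angle = k (theta -
#' theta0)^2`, `E_torsion = Vn (1 + cos(n phi - phase))`. Every bond in the
#' topology must carry parameters; angle/torsion terms are evaluated only
#' where parameter rows exist.
#'
#' @param top a parameterized [topology()].
#' @param frame n x 3 coordinates.
#' @return kcal/mol.
#' @export
bonded_energy <- function(top, frame) {
  e <- 0
  b <- top$bonds
  if (nrow(b)) {
    bp <- top$bond_params
    if (is.null(bp)) stop("bonded_energy: no bond parameters in topology")
    key <- function(i, j) paste(pmin(i, j), pmax(i, j))
    hit <- match(key(b[, 1], b[, 2]), key(bp$i, bp$j))
    if (anyNA(hit)) {
      m <- which(is.na(hit))[1]
      stop("bonded_energy: missing bond parameter for atoms ",
           b[m, 1], "-", b[m, 2])
    }
    r <- sqrt(rowSums((frame[b[, 1], , drop = FALSE] -
                       frame[b[, 2], , drop = FALSE])^2))
    e <- e + sum(bp$k[hit] * (r - bp$r0[hit])^2)
  }
  ap <- top$angle_params
  if (!is.null(ap) && nrow(ap)) {
    v1 <- frame[ap$i, , drop = FALSE] - frame[ap$j, , drop = FALSE]
    v2 <- frame[ap$k3, , drop = FALSE] - frame[ap$j, , drop = FALSE]
    ct <- rowSums(v1 * v2) / (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
    th <- acos(pmax(-1, pmin(1, ct)))
    e <- e + sum(ap$ktheta * (th - ap$theta0 * pi / 180)^2)
  }
  tp <- top$torsion_params
  if (!is.null(tp) && nrow(tp)) {
    phi <- vapply(seq_len(nrow(tp)), function(r) {
      dihedral_angle(frame[tp$i[r], ], frame[tp$j[r], ],
                     frame[tp$k3[r], ], frame[tp$l[r], ])
    }, numeric(1))
    e <- e + sum(tp$vn * (1 + cos(tp$period * phi - tp$phase * pi / 180)))
  }
  e
}

dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  bn <- sqrt(sum(b2^2))
  atan2(sum(m1 * n2) / bn, sum(n1 * n2))
}

#' Coulomb and Lennard-Jones energies (exact double loop, no cutoff)
#'
#' Evaluated without periodicity or cutoff. Intra-group mode (default)
#' excludes 1-2/1-3 pairs and scales 1-4 pairs; cross-group mode sums all
#' pairs between two disjoint index sets.
#'
#' @param top a parameterized [topology()].
#' @param frame n x 3 coordinates.
#' @param igroup,jgroup atom index sets. Both `NULL`: all atoms, intra mode.
#'   Only `igroup`: intra mode within it. Both given (disjoint): cross mode.
#' @param constants an [energy_constants()] list.
#' @param D_full optional precomputed full distance matrix for `frame`.
#' @return `list(coulomb=, lj=)`, kcal/mol.
#' @export
coulomb_lj_energy <- function(top, frame, igroup = NULL, jgroup = NULL,
                              constants = energy_constants(), D_full = NULL) {
  require_params(top)
  a <- top$atoms
  if (is.null(igroup) && is.null(jgroup)) igroup <- seq_len(n_atoms(top))
  cross <- !is.null(jgroup)
  if (cross && length(intersect(igroup, jgroup)))
    stop("coulomb_lj_energy: cross-group index sets must be disjoint")
  if (cross) {
    D <- if (is.null(D_full)) dist_matrix(frame, igroup, jgroup)
         else D_full[igroup, jgroup, drop = FALSE]
    if (any(D < 1e-6)) stop("coulomb_lj_energy: overlapping atoms (r < 1e-6 A)")
    st <- energy_static(top, constants)
    wc <- st$wc[igroup, jgroup, drop = FALSE]
    wl <- st$wl[igroup, jgroup, drop = FALSE]
    qq <- st$qq[igroup, jgroup, drop = FALSE]
    eps <- st$eps[igroup, jgroup, drop = FALSE]
    rmin <- st$rmin[igroup, jgroup, drop = FALSE]
    s6 <- (rmin / D)^6
    list(coulomb = COULOMB_K * sum(wc * qq / D) / constants$eps_in,
         lj = sum(wl * eps * (s6^2 - 2 * s6)))
  } else {
    idx <- igroup
    n <- length(idx)
    if (n < 2) return(list(coulomb = 0, lj = 0))
    st <- energy_static(top, constants)
    whole <- length(idx) == n_atoms(top) && all(idx == seq_len(n_atoms(top)))
    D <- if (is.null(D_full)) dist_matrix(frame[idx, , drop = FALSE])
         else if (whole) D_full else D_full[idx, idx, drop = FALSE]
    ut <- upper.tri(D)
    if (any(D[ut] < 1e-6))
      stop("coulomb_lj_energy: overlapping atoms (r < 1e-6 A)")
    sub <- function(M) if (whole) M else M[idx, idx, drop = FALSE]
    d <- D[ut]
    s6 <- (sub(st$rmin)[ut] / d)^6
    list(coulomb = COULOMB_K * sum(sub(st$wc * st$qq)[ut] / d) / constants$eps_in,
         lj = sum(sub(st$wl * st$eps)[ut] * (s6^2 - 2 * s6)))
  }
}

#' OBC2 effective Born radii
#'
#' Pairwise HCT descreening integrals are summed into Psi, then rescaled
#' with the OBC tanh recipe `1/Reff = 1/rho_t - tanh(alpha*Psi - beta*Psi^2
#' + gamma*Psi^3)/rho`, with `rho_t = rho - offset`. An isolated atom has
#' `Reff = rho - offset`.
#'
#' @param top a parameterized [topology()].
#' @param frame n x 3 coordinates.
#' @param constants an [energy_constants()] list.
#' @param D optional precomputed distance matrix for `frame`.
#' @return Per-atom effective radii, A.
#' @export
effective_born_radii <- function(top, frame, constants = energy_constants(),
                                 D = NULL) {
  require_params(top)
  a <- top$atoms
  n <- n_atoms(top)
  rho <- a$gb_radius
  st <- energy_static(top, constants)
  rho_t <- st$rho_t
  if (any(rho_t <= 0))
    stop("effective_born_radii: intrinsic radius not larger than the offset")
  if (n == 1) return(rho_t)
  if (is.null(D)) D <- dist_matrix(frame)
  S <- st$S                                      # scaled radius of j
  RT <- st$RT                                    # offset radius of i
  L <- pmax(RT, abs(D - S))
  U <- D + S
  active <- RT < U
  diag(active) <- FALSE
  term <- matrix(0, n, n)
  idx <- which(active)
  l <- 1 / L[idx]; u <- 1 / U[idx]; d <- D[idx]; s <- S[idx]
  term[idx] <- (l - u) + 0.25 * d * (u^2 - l^2) + 0.5 * log(u / l) / d +
    0.25 * (s^2 / d) * (l^2 - u^2)
  engulf <- active & (RT < S - D)
  if (any(engulf))
    term[engulf] <- term[engulf] + 2 * (1 / RT[engulf] - 1 / L[engulf])
  psi <- 0.5 * rho_t * rowSums(term)
  reff <- 1 / (1 / rho_t -
               tanh(constants$obc_alpha * psi - constants$obc_beta * psi^2 +
                    constants$obc_gamma * psi^3) / rho)
  if (any(!is.finite(reff)))
    stop("effective_born_radii: non-finite effective radius")
  reff
}

gb_f_matrix <- function(D, reff) {
  RR <- outer(reff, reff)
  sqrt(D^2 + RR * exp(-D^2 / (4 * RR)))
}

#' Generalized Born polar solvation energy
#'
#' `E = -(k/2) (1/eps_in - 1/eps_out) sum_ij q_i q_j / f_GB(r_ij, R_i,
#' R_j)` with `f_GB = sqrt(r^2 + Ri*Rj*exp(-r^2/(4*Ri*Rj)))`, including the
#' i = j Born self terms, over all pairs (no exclusions). Effective radii
#' must come from the full evaluation context.
#'
#' @param top a parameterized [topology()].
#' @param frame n x 3 coordinates.
#' @param radii effective Born radii (default: computed from `frame`).
#' @param igroup,jgroup optional disjoint index sets for the cross-pair
#'   portion only (no self terms); default is the total energy.
#' @param constants an [energy_constants()] list.
#' @param D optional precomputed distance matrix for `frame`.
#' @return kcal/mol.
#' @export
gb_polar_energy <- function(top, frame, radii = NULL, igroup = NULL,
                            jgroup = NULL, constants = energy_constants(),
                            D = NULL) {
  require_params(top)
  if (is.null(radii)) radii <- effective_born_radii(top, frame, constants, D)
  q <- top$atoms$charge
  kd <- 1 / constants$eps_in - 1 / constants$eps_out
  if (!is.null(jgroup)) {
    Dc <- if (is.null(D)) dist_matrix(frame, igroup, jgroup)
          else D[igroup, jgroup, drop = FALSE]
    RR <- outer(radii[igroup], radii[jgroup])
    f <- sqrt(Dc^2 + RR * exp(-Dc^2 / (4 * RR)))
    return(-COULOMB_K * kd * sum(outer(q[igroup], q[jgroup]) / f))
  }
  if (is.null(D)) D <- dist_matrix(frame)
  f <- gb_f_matrix(D, radii)
  -GB_HALF_K * kd * sum(energy_static(top, constants)$qq / f)
}

#' LCPO solvent-accessible surface area and nonpolar energy
#'
#' Linear combination of pairwise overlaps: per atom, `A_i = P1*S1 +
#' P2*sum_j A_ij + P3*sum_{j,k} A_jk + P4*sum_j A_ij sum_k A_jk` over
#' neighbor spheres of radius `r + probe`. The nonpolar solvation energy is
#' `gamma_tension * total`.
#'
#' @param top a parameterized [topology()].
#' @param frame n x 3 coordinates.
#' @param constants an [energy_constants()] list.
#' @param D optional precomputed distance matrix for `frame`.
#' @return `list(total=, per_atom=, energy=)`, A^2 and kcal/mol.
#' @export
sasa_lcpo <- function(top, frame, constants = energy_constants(), D = NULL) {
  require_params(top)
  a <- top$atoms
  n <- n_atoms(top)
  st <- energy_static(top, constants)
  R <- st$Rlc
  S1 <- st$S1
  if (n == 1) {
    per <- a$lcpo_p1 * S1
    return(list(total = sum(per), per_atom = per,
                energy = constants$gamma_tension * sum(per)))
  }
  if (is.null(D)) D <- dist_matrix(frame)
  Rm <- matrix(R, n, n); RmT <- t(Rm)
  ov <- D > 0 & D < st$Rsum
  diag(ov) <- FALSE
  Aij <- matrix(0, n, n)
  idx <- which(ov)
  Aij[idx] <- 2 * pi * Rm[idx] *
    (Rm[idx] - D[idx] / 2 - (Rm[idx]^2 - RmT[idx]^2) / (2 * D[idx]))
  per <- a$lcpo_p1 * S1
  for (i in which(rowSums(ov) > 0)) {
    nb <- which(ov[i, ])
    t2 <- sum(Aij[i, nb])
    sub_ov <- ov[nb, nb, drop = FALSE]
    sub_A <- Aij[nb, nb, drop = FALSE]
    t3 <- sum(sub_A[sub_ov])
    t4 <- sum(Aij[i, nb] * rowSums(sub_A * sub_ov))
    per[i] <- per[i] + a$lcpo_p2[i] * t2 + a$lcpo_p3[i] * t3 +
      a$lcpo_p4[i] * t4
  }
  list(total = sum(per), per_atom = per,
       energy = constants$gamma_tension * sum(per))
}

#' Full implicit-solvent energy of a system
#'
#' Bonded + intra Coulomb + Lennard-Jones + generalized Born polar + LCPO
#' nonpolar terms; the total is their exact sum.
#'
#' @param top a parameterized [topology()].
#' @param frame n x 3 coordinates.
#' @param constants an [energy_constants()] list.
#' @return `list(bonded=, coulomb=, lj=, gb=, sasa_A2=, nonpolar=, total=)`.
#' @export
system_energy <- function(top, frame, constants = energy_constants()) {
  D <- dist_matrix(frame)
  cl <- coulomb_lj_energy(top, frame, constants = constants, D_full = D)
  gb <- gb_polar_energy(top, frame, constants = constants, D = D)
  sa <- sasa_lcpo(top, frame, constants = constants, D = D)
  be <- bonded_energy(top, frame)
  list(bonded = be, coulomb = cl$coulomb, lj = cl$lj, gb = gb,
       sasa_A2 = sa$total, nonpolar = sa$energy,
       total = be + cl$coulomb + cl$lj + gb + sa$energy)
}

energy_contexts <- function(top) {
  idx <- list(A = group_indices(top, "A"), B = group_indices(top, "B"),
              L1 = group_indices(top, "L1"), L2 = group_indices(top, "L2"))
  ctx <- list(monA = idx$A, monB = idx$B, dimer = c(idx$A, idx$B),
              dimerL1 = c(idx$A, idx$B, idx$L1),
              dimerL2 = c(idx$A, idx$B, idx$L2),
              L1 = idx$L1, L2 = idx$L2)
  ctx <- ctx[lengths(ctx) > 0]
  list(idx = lapply(ctx, sort),
       tops = lapply(ctx, function(i) extract_subsystem(top, sort(i))))
}

#' Monomer / dimerization / cofactor-binding energy decomposition
#'
#' Single-trajectory MM-GB/SA decomposition, per frame: `EMi` is the full
#' energy of monomer i extracted alone; `EE = E(dimer) - EM1 - EM2` is the
#' dimerization energy; per site `EL_s = E(dimer + ligand_s) - E(dimer) -
#' E(ligand_s)` and `EL = EL1 + EL2`; `ET = EM + EE + EL` by definition.
#' Effective Born radii and surface areas are recomputed in every
#' evaluation context, so EE and EL include the GB desolvation cross terms.
#'
#' @param top a parameterized [topology()] with two monomers and up to two
#'   cofactor sites.
#' @param traj the matching [trajectory()].
#' @param window_ns,stride_ns frame schedule (defaults: last 800 ns at one
#'   frame per ns).
#' @param constants an [energy_constants()] list.
#' @return An `energy_breakdown`: `$per_frame` (time_ns, EM1, EM2, EM, EE,
#'   EL1, EL2, EL, ET), `$summary` (component, mean, sd, se_block over 5
#'   contiguous blocks), `$terms` (per-frame bonded/Coulomb/LJ/GB/nonpolar
#'   detail per context), `$system`.
#' @export
decompose_em_ee_el <- function(top, traj, window_ns = 800, stride_ns = 1,
                               constants = energy_constants()) {
  require_params(top)
  fidx <- schedule_frames(traj, window_ns, stride_ns)
  cx <- energy_contexts(top)
  nm <- names(cx$idx)
  terms <- lapply(nm, function(z) NULL)
  names(terms) <- nm
  rows <- vector("list", length(fidx))
  trecs <- stats::setNames(vector("list", length(nm)), nm)
  for (z in nm) trecs[[z]] <- vector("list", length(fidx))
  for (k in seq_along(fidx)) {
    fr <- get_frame(traj, fidx[k])
    e <- stats::setNames(numeric(length(nm)), nm)
    for (z in nm) {
      rec <- system_energy(cx$tops[[z]], fr[cx$idx[[z]], , drop = FALSE],
                           constants)
      e[z] <- rec$total
      trecs[[z]][[k]] <- rec
    }
    EM1 <- e["monA"]; EM2 <- e["monB"]; EM <- EM1 + EM2
    EE <- e["dimer"] - EM1 - EM2
    EL1 <- if ("L1" %in% nm) e["dimerL1"] - e["dimer"] - e["L1"] else 0
    EL2 <- if ("L2" %in% nm) e["dimerL2"] - e["dimer"] - e["L2"] else 0
    EL <- EL1 + EL2
    rows[[k]] <- data.frame(time_ns = traj$times[fidx[k]], EM1 = EM1,
                            EM2 = EM2, EM = EM, EE = EE, EL1 = EL1,
                            EL2 = EL2, EL = EL, ET = EM + EE + EL)
  }
  per_frame <- do.call(rbind, rows)
  rownames(per_frame) <- NULL
  comp <- c("EM1", "EM2", "EM", "EE", "EL1", "EL2", "EL", "ET")
  nb <- min(5, nrow(per_frame))
  blk <- if (nb >= 2) cut(seq_len(nrow(per_frame)), nb, labels = FALSE)
         else rep(1L, nrow(per_frame))
  summ <- do.call(rbind, lapply(comp, function(cc) {
    v <- per_frame[[cc]]
    data.frame(component = cc, mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else 0,
               se_block = if (nb >= 2)
                 stats::sd(tapply(v, blk, mean)) / sqrt(nb) else NA_real_)
  }))
  term_df <- lapply(trecs, function(lst)
    do.call(rbind, lapply(lst, as.data.frame)))
  structure(list(per_frame = per_frame, summary = summ, terms = term_df,
                 system = traj$label,
                 schedule = list(window_ns = window_ns, stride_ns = stride_ns,
                                 n_frames = length(fidx))),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("energy_breakdown '%s' over %d frames:\n", x$system,
              x$schedule$n_frames))
  s <- x$summary[x$summary$component %in% c("EM", "EE", "EL", "ET"), ]
  for (r in seq_len(nrow(s)))
    cat(sprintf("  %-3s %12.2f +/- %.2f kcal/mol\n", s$component[r],
                s$mean[r], s$sd[r]))
  invisible(x)
}

#' Assemble the published-style energy table from breakdowns
#'
#' One row per system: EM, EE, EL and ET = EM + EE + EL, each with its
#' frame SD.
#'
#' @param breakdowns list of `energy_breakdown` objects.
#' @return data.frame (system, em, em_sd, ee, ee_sd, el, el_sd, et, et_sd).
#' @export
energy_table <- function(breakdowns) {
  do.call(rbind, lapply(breakdowns, function(b) {
    g <- function(cc, w) b$summary[b$summary$component == cc, w]
    data.frame(system = b$system,
               em = g("EM", "mean"), em_sd = g("EM", "sd"),
               ee = g("EE", "mean"), ee_sd = g("EE", "sd"),
               el = g("EL", "mean"), el_sd = g("EL", "sd"),
               et = g("ET", "mean"), et_sd = g("ET", "sd"))
  }))
}

#' Literature MM-GB/SA energies for the hGOT1 dimer
#'
#' Reported absolute EM/EE/EL/ET energies (kcal/mol, with frame SDs) for
#' the wild-type hGOT1-PLP complex and its E266K, R267H and P300L variants,
#' shipped as a plain-text reference table. ET is defined as EM + EE + EL;
#' [check_energy_accounting()] verifies the identity at printed precision.
#'
#' @return data.frame (system, em, em_sd, ee, ee_sd, el, el_sd, et, et_sd).
#' @export
published_energy_table <- function() {
  utils::read.csv(system.file("extdata", "published_energy_table.csv",
                              package = "dimerdyn"),
                  stringsAsFactors = FALSE)
}

#' Check the ET = EM + EE + EL accounting identity of an energy table
#'
#' @param tab data.frame in [energy_table()] layout.
#' @return Maximum absolute deviation `|et - (em + ee + el)|`, kcal/mol.
#' @export
check_energy_accounting <- function(tab) {
  max(abs(tab$et - (tab$em + tab$ee + tab$el)))
}
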