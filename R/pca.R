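# Pooled essential-dynamics PCA and the reference-zeroed PC1 displacement
# statistic used to quantify dimer-interface misalignment.

# orthonormal basis of the 6 rigid-body modes of a reference geometry
rigid_mode_basis <- function(ref) {
  n <- nrow(ref)
  c0 <- colMeans(ref)
  X <- sweep(ref, 2, c0)
  modes <- matrix(0, 3 * n, 6)
  for (k in 1:3) modes[seq(k, 3 * n, by = 3), k] <- 1   # translations
  ax <- diag(3)
  for (k in 1:3) {                                       # rotations
    u <- t(vapply(seq_len(n), function(i) {
      v <- ax[k, ]; r <- X[i, ]
      c(v[2] * r[3] - v[3] * r[2], v[3] * r[1] - v[1] * r[3],
        v[1] * r[2] - v[2] * r[1])
    }, numeric(3)))
    modes[, 3 + k] <- as_xyz_vec(u)
  }
  qr.Q(qr(modes))
}

project_out_rigid <- function(vec, ref) {
  B <- rigid_mode_basis(ref)
  as.numeric(vec - B %*% crossprod(B, vec))
}

#' Fit a pooled principal-component model over labeled trajectories
#'
#' Frames from all systems inside the schedule window are pooled, restricted
#' to the selection (typically the inner Calpha atoms of both monomers plus
#' the cofactor C6 carbons), superposed onto the iteratively refined pooled
#' mean, and the 3N x 3N Cartesian covariance (1/(n-1) normalization, no
#' mass weighting) is eigendecomposed. Eigenvector signs follow the
#' convention that each component's largest-|loading| coordinate is
#' positive, so the "positive displacement" direction is reproducible.
#'
#' @param trajs named list of [trajectory()] objects sharing the topology.
#' @param top the common [topology()].
#' @param sel_idx atom indices of the coordinate centers (length N).
#' @param window_ns,stride_ns frame schedule passed to [schedule_frames()]
#'   for every system (defaults: last 800 ns, 1 frame/ns).
#' @return A `pc_model`: mean coordinates (N x 3), eigenvectors (3N x 3N),
#'   eigenvalues (A^2), selection, and pooling provenance.
#' @export
fit_pc_model <- function(trajs, top, sel_idx, window_ns = 800, stride_ns = 1) {
  stopifnot(is.list(trajs), length(trajs) >= 1)
  if (is.null(names(trajs))) names(trajs) <- vapply(trajs, `[[`, "", "label")
  nsel <- length(sel_idx)
  blocks <- list(); counts <- integer(0)
  for (nm in names(trajs)) {
    tr <- trajs[[nm]]
    if (ncol(tr$xyz) != 3 * n_atoms(top))
      stop("fit_pc_model: trajectory '", nm, "' does not match the topology")
    fidx <- schedule_frames(tr, window_ns, stride_ns)
    sub <- extract_subsystem(top, sel_idx, tr)$trajectory
    blocks[[nm]] <- sub$xyz[fidx, , drop = FALSE]
    counts[nm] <- length(fidx)
  }
  pooled <- do.call(rbind, blocks)
  if (nrow(pooled) < 2) stop("fit_pc_model: need at least 2 pooled frames")
  fit <- iterative_mean_fit(trajectory(pooled, seq_len(nrow(pooled)) - 1,
                                       "pooled"), tol = 1e-8)
  centered <- sweep(fit$xyz, 2, as_xyz_vec(fit$mean))
  covm <- crossprod(centered) / (nrow(centered) - 1)
  eg <- eigen(covm, symmetric = TRUE)
  vec <- eg$vectors
  for (k in seq_len(ncol(vec))) {            # sign convention
    m <- which.max(abs(vec[, k]))
    if (vec[m, k] < 0) vec[, k] <- -vec[, k]
  }
  structure(list(mean = fit$mean, evec = vec,
                 evals = pmax(eg$values, 0), sel_idx = sel_idx,
                 n_centers = nsel,
                 provenance = list(systems = names(trajs),
                                   frames_per_system = counts,
                                   pooled_frames = nrow(pooled),
                                   window_ns = window_ns,
                                   stride_ns = stride_ns,
                                   superposed = TRUE,
                                   mean_fit_iterations = fit$iterations,
                                   sign_convention = "largest-loading-positive")),
            class = "pc_model")
}

#' @export
print.pc_model <- function(x, ...) {
  cat(sprintf("pc_model: N = %d centers, %d pooled frames (%s)\n",
              x$n_centers, x$provenance$pooled_frames,
              paste(x$provenance$systems, collapse = ", ")))
  tot <- sum(x$evals)
  cat(sprintf("  lambda1 = %.4g A^2 (%.1f%% of total fluctuation)\n",
              x$evals[1], 100 * x$evals[1] / max(tot, .Machine$double.eps)))
  invisible(x)
}

#' Project a trajectory onto a principal component
#'
#' Each frame is superposed onto the model's pooled mean over the selection;
#' the deviation from the mean is flattened to a 3N vector and its inner
#' product with the component vector is the scalar displacement (Angstrom).
#'
#' @param model a `pc_model` from [fit_pc_model()].
#' @param traj a [trajectory()] containing the model's selection atoms.
#' @param top the matching [topology()].
#' @param component component index (1 = PC1).
#' @param frames optional frame indices.
#' @return A `displacement_series` data.frame (system, time_ns, pc, value).
#' @export
project_trajectory <- function(model, traj, top, component = 1,
                               frames = NULL) {
  if (component > ncol(model$evec))
    stop("project_trajectory: component index exceeds 3N")
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  sub <- extract_subsystem(top, model$sel_idx, traj)$trajectory
  mu <- as_xyz_vec(model$mean)
  v <- model$evec[, component]
  vals <- vapply(frames, function(f) {
    m <- get_frame(sub, f)
    m <- apply_fit(m, kabsch_superpose(m, model$mean))
    sum((as_xyz_vec(m) - mu) * v)
  }, numeric(1))
  structure(data.frame(system = traj$label, time_ns = traj$times[frames],
                       pc = component, value = vals, stringsAsFactors = FALSE),
            class = c("displacement_series", "data.frame"))
}

#' Zero displacement series on a reference system
#'
#' Subtracts the reference system's mean displacement from every series, so
#' the reference averages to zero and variants are read as displacements
#' relative to it.
#'
#' @param series named list of `displacement_series`.
#' @param reference reference label (must be present).
#' @return The shifted list, with the applied offset in attribute `offset`.
#' @export
zero_reference <- function(series, reference) {
  if (!reference %in% names(series))
    stop("zero_reference: reference label '", reference, "' not present")
  off <- mean(series[[reference]]$value)
  out <- lapply(series, function(s) { s$value <- s$value - off; s })
  attr(out, "offset") <- off
  out
}

#' Axis-aligned ellipse summary of paired series
#'
#' Componentwise mean and standard deviation of paired (x, y) values, the
#' center and semi-axes of the axis-aligned SD ellipse used in
#' displacement-versus-energy plots.
#'
#' @param x,y equal-length numeric vectors paired by frame.
#' @return `list(mean_x=, mean_y=, sd_x=, sd_y=)`.
#' @export
ellipse_summary <- function(x, y) {
  if (length(x) != length(y)) stop("ellipse_summary: length mismatch")
  list(mean_x = mean(x), mean_y = mean(y),
       sd_x = stats::sd(x), sd_y = stats::sd(y))
}

#' Serialize / restore a pc_model (JSON metadata + TSV matrix pair)
#'
#' @param model a `pc_model`.
#' @param stem output path stem; writes `<stem>.json` and `<stem>.evec.tsv`.
#' @export
save_pc_model <- function(model, stem) {
  meta <- list(mean = as_xyz_vec(model$mean), evals = model$evals,
               sel_idx = model$sel_idx, n_centers = model$n_centers,
               provenance = model$provenance)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  utils::write.table(model$evec, paste0(stem, ".evec.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(stem)
}

#' @rdname save_pc_model
#' @export
load_pc_model <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  evec <- as.matrix(utils::read.table(paste0(stem, ".evec.tsv"), sep = "\t"))
  dimnames(evec) <- NULL
  structure(list(mean = matrix(meta$mean, ncol = 3, byrow = TRUE),
                 evec = evec, evals = meta$evals, sel_idx = meta$sel_idx,
                 n_centers = meta$n_centers,
                 provenance = as.list(meta$provenance)),
            class = "pc_model")
}
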