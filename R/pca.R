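# Least-squares superposition and coordinate-covariance PCA.

# Kabsch rigid-body fit: rotation + translation mapping `mobile` onto `ref`
# (n x 3 matrices) in the least-squares sense.
.kabsch <- function(mobile, ref) {
  cm <- colMeans(mobile)
  cr <- colMeans(ref)
  H <- crossprod(sweep(mobile, 2, cm), sweep(ref, 2, cr))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, center_mobile = cm, center_ref = cr)
}

.apply_fit <- function(xyz, fit) {
  sweep(sweep(xyz, 2, fit$center_mobile) %*% t(fit$R), 2, fit$center_ref, `+`)
}

.check_fit_selection <- function(sel, coords1) {
  if (length(sel) < 3L) stop("superposition needs at least 3 atoms")
  x <- coords1[sel, , drop = FALSE]
  if (qr(sweep(x, 2, colMeans(x)))$rank < 2L)
    stop("superposition atoms are collinear")
}

#' Rigid-body superposition of trajectory frames
#'
#' Least-squares (unweighted) fit of every frame on a selection, removing
#' global rotation and translation before covariance analysis.  With
#' `reference = "iterative_mean"` the frames are refit to the running mean
#' structure until the mean moves by less than 1e-6 A RMSD.
#'
#' @param trajectory a [trajectory()] object.
#' @param selection atoms to fit on (an [select_atoms()] result or indices);
#'   needs at least 3 non-collinear atoms.
#' @param reference `"first_frame"` or `"iterative_mean"`.
#' @return A [trajectory()] with all atoms transformed by the per-frame fits.
#' @export
superpose <- function(trajectory, selection,
                      reference = c("first_frame", "iterative_mean")) {
  reference <- match.arg(reference)
  sel <- as.integer(selection)
  nf <- n_frames(trajectory)
  first <- frame_coords(trajectory, 1)
  if (nf == 1L) return(trajectory)
  .check_fit_selection(sel, first)
  coords <- trajectory$coords
  fit_all <- function(ref_sel) {
    out <- coords
    for (f in seq_len(nf)) {
      x <- coords[f, , , drop = TRUE]
      fit <- .kabsch(x[sel, , drop = FALSE], ref_sel)
      out[f, , ] <- .apply_fit(x, fit)
    }
    out
  }
  ref_sel <- first[sel, , drop = FALSE]
  coords_fit <- fit_all(ref_sel)
  if (reference == "iterative_mean") {
    repeat {
      mean_sel <- apply(coords_fit[, sel, , drop = FALSE], c(2, 3), mean)
      rmsd <- sqrt(mean(rowSums((mean_sel - ref_sel)^2)))
      if (rmsd < 1e-6) break
      ref_sel <- mean_sel
      coords_fit <- fit_all(ref_sel)
    }
  }
  out <- trajectory
  out$coords <- coords_fit
  out
}

#' Coordinate-covariance principal component analysis
#'
#' Computes the covariance matrix of the mean-centred Cartesian coordinates
#' of a (previously superposed) selection, using every `stride`-th frame,
#' diagonalises it, and keeps the leading `n_components` eigenvectors.
#' Projections are reported for all frames, not only the strided ones.
#' Eigenvector signs follow a fixed convention (largest-magnitude component
#' positive) so output is deterministic.
#'
#' @param trajectory a superposed [trajectory()] object.
#' @param selection atoms entering the covariance (selection or indices).
#' @param stride use every `stride`-th frame for the covariance (default 5).
#' @param n_components number of components to keep (default 10, capped at
#'   3 times the number of selected atoms).
#' @return A `PCAResult`: list with `mean` (n_sel x 3 mean structure,
#'   Angstrom), `eigenvalues` (all 3 n_sel of them, descending, A^2),
#'   `vectors` (3 n_sel x n_components, orthonormal), `projections`
#'   (n_frames x n_components, A) and `trace` (total variance, A^2).
#' @export
traj_pca <- function(trajectory, selection, stride = 5, n_components = 10) {
  sel <- as.integer(selection)
  stopifnot(stride >= 1, n_components >= 1)
  n_components <- min(n_components, 3L * length(sel))
  nf <- n_frames(trajectory)
  frames <- seq(1L, nf, by = stride)
  if (length(frames) < 2L)
    stop("need at least 2 strided frames for a covariance")
  flat <- function(f) as.vector(t(frame_coords(trajectory, f)[sel, ,
                                                              drop = FALSE]))
  X <- t(vapply(frames, flat, numeric(3L * length(sel))))
  mu <- colMeans(X)
  C <- stats::cov(X)
  e <- eigen(C, symmetric = TRUE)
  vec <- e$vectors[, seq_len(n_components), drop = FALSE]
  # sign convention: the largest-magnitude loading of each mode is positive
  for (k in seq_len(ncol(vec))) {
    i <- which.max(abs(vec[, k]))
    if (vec[i, k] < 0) vec[, k] <- -vec[, k]
  }
  Xall <- t(vapply(seq_len(nf), flat, numeric(3L * length(sel))))
  proj <- sweep(Xall, 2, mu) %*% vec
  structure(list(
    mean = matrix(mu, ncol = 3, byrow = TRUE),
    eigenvalues = e$values,
    vectors = vec,
    projections = proj,
    trace = sum(diag(C)),
    stride = stride, frames_used = frames, selection = sel),
    class = "PCAResult")
}

#' @export
print.PCAResult <- function(x, ...) {
  kept <- ncol(x$vectors)
  expl <- sum(x$eigenvalues[seq_len(kept)]) / max(x$trace, .Machine$double.eps)
  cat(sprintf("PCA: %d components kept, %.1f%% of variance (trace %.3g A^2)\n",
              kept, 100 * expl, x$trace))
  invisible(x)
}

#' Write a principal mode as an interpolated multi-model PDB
#'
#' Visualises one component by sweeping the selected atoms from -amplitude
#' to +amplitude standard deviations along the mode about the mean
#' structure.
#'
#' @param pca a `PCAResult` from [traj_pca()].
#' @param topology topology of the analysed selection's parent structure.
#' @param component which mode to animate.
#' @param path output PDB path.
#' @param n_steps number of interpolation frames.
#' @param amplitude sweep amplitude in standard deviations of the mode.
#' @export
write_mode_animation <- function(pca, topology, component = 1, path,
                                 n_steps = 11, amplitude = 2) {
  sel <- pca$selection
  sd_k <- sqrt(max(pca$eigenvalues[component], 0))
  v <- matrix(pca$vectors[, component], ncol = 3, byrow = TRUE)
  sub_atoms <- topology$atoms[sel, , drop = FALSE]
  sub_top <- topology(sub_atoms[, c("name", "element", "chain", "resno",
                                    "resname", "insert", "eleno")])
  steps <- seq(-amplitude, amplitude, length.out = n_steps)
  coords <- array(0, dim = c(n_steps, length(sel), 3))
  for (i in seq_along(steps))
    coords[i, , ] <- pca$mean + steps[i] * sd_k * v
  write_trajectory(trajectory(sub_top, coords, dt = 1), path)
}
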