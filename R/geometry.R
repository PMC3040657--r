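#' Centre of mass of a set of atoms
#'
#' Uniform weighting is the default: coarse beads carry no meaningful masses,
#' and COM pulling in the simulator distributes force equally per bead.
#' Mass weighting is available via `weights`.
#'
#' @param x an [AtomicModel-class], [Trajectory-class] frame matrix, or
#'   `natoms x 3` coordinate matrix.
#' @param serials atom serials to include (matched against the model's
#'   serial column when `x` carries one; row indices for bare matrices).
#' @param weights `"uniform"` or a numeric vector of per-atom weights
#'   (recycled against `serials`).
#' @return length-3 numeric vector, Angstrom.
#' @export
centerOfMass <- function(x, serials, weights = "uniform") {
  if (length(serials) == 0) stop("centerOfMass: empty atom selection")
  if (is(x, "AtomicModel")) {
    idx <- match(serials, x@atoms$serial)
    if (any(is.na(idx))) stop("centerOfMass: unknown serial(s)")
    m <- coords(x)[idx, , drop = FALSE]
  } else {
    m <- as.matrix(x)[serials, , drop = FALSE]
  }
  if (identical(weights, "uniform")) {
    colMeans(m)
  } else {
    w <- rep_len(as.numeric(weights), nrow(m))
    colSums(m * w) / sum(w)
  }
}

#' Kabsch superposition
#'
#' Least-squares rigid superposition of `mobile` onto `reference` over the
#' fit atoms, with a proper rotation enforced (determinant +1 via the sign
#' correction on the smallest singular vector).
#'
#' @param mobile,reference `n x 3` coordinate matrices.
#' @param fit integer row indices used for the fit (default: all rows);
#'   at least 3 non-collinear points.
#' @return list with `rotation` (3x3, applies to centred mobile
#'   coordinates), `translation` (3-vector), `rmsd` (over the fit atoms, A)
#'   and `transform(m)` applying the superposition to any `n x 3` matrix.
#' @export
kabschSuperpose <- function(mobile, reference, fit = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (is.null(fit)) fit <- seq_len(nrow(mobile))
  if (length(fit) < 3) stop("kabschSuperpose: need >= 3 fit atoms")
  P <- mobile[fit, , drop = FALSE]
  Q <- reference[fit, , drop = FALSE]
  if (nrow(P) != nrow(Q)) stop("kabschSuperpose: fit atom count mismatch")
  cP <- colMeans(P); cQ <- colMeans(Q)
  P0 <- sweep(P, 2, cP); Q0 <- sweep(Q, 2, cQ)
  sv <- svd(crossprod(P0, Q0))
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1))
    stop("kabschSuperpose: degenerate (collinear) fit atom set")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  fitted <- P0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Q0)^2)))
  translation <- cQ - as.numeric(R %*% cP)
  transform <- function(m) {
    m <- as.matrix(m)
    sweep(m %*% t(R), 2, translation, `+`)
  }
  list(rotation = R, translation = translation, rmsd = rmsd,
       transform = transform)
}

#' RMSD over atoms of two coordinate sets
#' @param a,b `n x 3` matrices.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("rmsd: dimension mismatch")
  sqrt(mean(rowSums((a - b)^2)))
}

#' Per-frame RMSD series relative to a reference frame
#'
#' Standard Ca-RMSD convention: each frame is first least-squares superposed
#' onto the reference over the same selection (`superpose = TRUE`, default).
#'
#' @param traj a [Trajectory-class].
#' @param reference reference coordinates (`natoms x 3` matrix over the full
#'   model, or a frame index into `traj`).
#' @param serials atom serials of the selection (default: all atoms).
#' @param superpose fit each frame onto the reference first.
#' @return data.frame `time_ns`, `rmsd_A`.
#' @export
rmsdSeries <- function(traj, reference = 1L, serials = NULL,
                       superpose = TRUE) {
  ser <- traj@model@atoms$serial
  if (is.null(serials)) serials <- ser
  idx <- match(serials, ser)
  if (any(is.na(idx))) stop("rmsdSeries: unknown serial(s)")
  ref <- if (length(reference) == 1 && is.numeric(reference))
    coords(traj, as.integer(reference)) else as.matrix(reference)
  refSel <- ref[idx, , drop = FALSE]
  out <- vapply(seq_len(nFrames(traj)), function(f) {
    m <- coords(traj, f)[idx, , drop = FALSE]
    if (superpose) {
      kb <- kabschSuperpose(m, refSel)
      kb$rmsd
    } else {
      rmsd(m, refSel)
    }
  }, numeric(1))
  data.frame(time_ns = traj@times, rmsd_A = out)
}

#' Head-tail extension series
#'
#' Per-frame distance between the pull-group COM and the constraint-group
#' COM, minus its frame-1 value, so the first frame maps to exactly 0. This
#' is the extension coordinate of pulling experiments (the increase of the
#' distance between the constraint and pulling locations).
#'
#' @param traj a [Trajectory-class].
#' @param pullSerials,constraintSerials atom serials of the two groups.
#' @return data.frame `time_ns`, `extension_A`, plus attribute
#'   `"baseline_A"` holding the frame-1 COM distance.
#' @export
extensionSeries <- function(traj, pullSerials, constraintSerials) {
  if (length(pullSerials) == 0 || length(constraintSerials) == 0)
    stop("extensionSeries: empty selection")
  ser <- traj@model@atoms$serial
  pi <- match(pullSerials, ser); ci <- match(constraintSerials, ser)
  if (any(is.na(pi)) || any(is.na(ci)))
    stop("extensionSeries: unknown serial(s)")
  d <- vapply(seq_len(nFrames(traj)), function(f) {
    m <- coords(traj, f)
    sqrt(sum((colMeans(m[pi, , drop = FALSE]) -
              colMeans(m[ci, , drop = FALSE]))^2))
  }, numeric(1))
  out <- data.frame(time_ns = traj@times, extension_A = d - d[1])
  attr(out, "baseline_A") <- d[1]
  out
}
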