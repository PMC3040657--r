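#' Define an inter-domain hinge pair
#'
#' @param name hinge label (e.g. `"thigh/calf1"`).
#' @param A,B disjoint serial vectors of the two domains, each with at
#'   least 3 non-collinear atoms.
#' @param referenceFrame index of the trajectory frame used as reference.
#' @return hinge-pair specification list.
#' @export
hingePair <- function(name, A, B, referenceFrame = 1L) {
  if (length(intersect(A, B)) > 0) stop("hingePair: selections overlap")
  if (length(A) < 3 || length(B) < 3)
    stop("hingePair: each domain needs >= 3 atoms")
  list(name = name, A = A, B = B, referenceFrame = as.integer(referenceFrame))
}

#' Hinge angle between two domains relative to a reference frame
#'
#' The relative-rotation formulation of hinge analysis: the frame is
#' superposed onto the reference using domain A (Kabsch), then the residual
#' best-fit rotation R of domain B is computed; the hinge angle is
#' `acos((tr(R) - 1) / 2)` in degrees, i.e. the rotation of B about the
#' effective hinge axis after removing A's rigid-body motion. The axis
#' (rotation eigenvector) is returned for inspection.
#'
#' @param reference,frame full-model `natoms x 3` coordinate matrices.
#' @param pair from [hingePair()].
#' @param serials serial vector giving the row order of the matrices.
#' @return list `angle` (degrees, in `[0, 180]`) and `axis` (unit 3-vector;
#'   arbitrary for zero rotation).
#' @export
hingeAngle <- function(reference, frame, pair, serials) {
  ai <- match(pair$A, serials); bi <- match(pair$B, serials)
  if (anyNA(ai) || anyNA(bi)) stop("hingeAngle: unknown serial(s)")
  fitA <- kabschSuperpose(as.matrix(frame), as.matrix(reference), fit = ai)
  moved <- fitA$transform(as.matrix(frame))
  fitB <- kabschSuperpose(moved[bi, , drop = FALSE],
                          as.matrix(reference)[bi, , drop = FALSE])
  R <- fitB$rotation
  tr <- sum(diag(R))
  cosang <- max(-1, min(1, (tr - 1) / 2))
  ## identical configurations report exactly zero rather than acos noise
  angle <- if (cosang > 1 - 1e-12) 0 else acos(cosang) * 180 / pi
  ev <- eigen(R)
  k <- which.min(abs(ev$values - 1))
  axis <- Re(ev$vectors[, k])
  axis <- axis / sqrt(sum(axis^2))
  list(angle = angle, axis = axis)
}

#' Hinge-angle time series
#'
#' Per-frame hinge angles for a list of hinge pairs, reported by default as
#' the change relative to each pair's reference frame; `offsets` adds a
#' per-pair initial angle so absolute inter-domain angles can be reported
#' when the starting geometry is known.
#'
#' @param traj a [Trajectory-class].
#' @param pairs list of [hingePair()] specifications.
#' @param offsets named numeric vector of per-pair additive offsets
#'   (degrees), or NULL.
#' @return data.frame `time_ns, pair, angle_deg`.
#' @export
hingeAngleSeries <- function(traj, pairs, offsets = NULL) {
  ser <- traj@model@atoms$serial
  out <- list()
  for (p in pairs) {
    ref <- coords(traj, p$referenceFrame)
    off <- if (!is.null(offsets) && p$name %in% names(offsets))
      offsets[[p$name]] else 0
    ang <- vapply(seq_len(nFrames(traj)), function(f)
      hingeAngle(ref, coords(traj, f), p, ser)$angle, numeric(1))
    out[[length(out) + 1L]] <-
      data.frame(time_ns = traj@times, pair = p$name,
                 angle_deg = ang + off)
  }
  do.call(rbind, out)
}

#' Linear cooperativity fit between two hinge-angle series
#'
#' Ordinary least squares of the y-hinge angle on the x-hinge angle over a
#' fit window, quantifying concurrent (cooperative) opening of two knees.
#' The default window keeps the frames before the x hinge first exceeds
#' 95 percent of its final plateau value, i.e. the regime before the
#' molecule is over-stretched and the linear relation breaks down.
#'
#' @param seriesX,seriesY data.frames with `time_ns, angle_deg` for the two
#'   hinges (same frames).
#' @param window `"pre-plateau"` (default rule) or an integer vector of
#'   frame indices.
#' @param smoothFrames optional centred moving-average window (in frames)
#'   applied to both series before fitting; 1 (default) fits the raw
#'   series. Time-averaging suppresses the thermal wobble of the hinge
#'   bodies when the underlying opening is slower than the wobble.
#' @return fit summary list: `slope`, `intercept` (degrees), `r2`,
#'   `window` (indices used), `n`.
#' @export
cooperativityFit <- function(seriesX, seriesY, window = "pre-plateau",
                             smoothFrames = 1L) {
  x <- seriesX$angle_deg; y <- seriesY$angle_deg
  if (length(x) != length(y))
    stop("cooperativityFit: series length mismatch")
  if (smoothFrames > 1L) {
    sm <- function(v) {
      h <- (smoothFrames - 1L) %/% 2L
      vapply(seq_along(v), function(i)
        mean(v[max(1, i - h):min(length(v), i + h)]), numeric(1))
    }
    x <- sm(x); y <- sm(y)
  }
  if (identical(window, "pre-plateau")) {
    ## plateau level: mean over the final tenth of the (smoothed) series
    plateau <- mean(tail(x, max(1L, length(x) %/% 10L)))
    x0 <- x[1]
    lim <- x0 + 0.95 * (plateau - x0)
    beyond <- which(x > lim)
    end <- if (length(beyond) == 0) length(x) else max(3L, beyond[1] - 1L)
    window <- seq_len(end)
  }
  if (length(window) < 3) stop("cooperativityFit: window needs >= 3 frames")
  xv <- x[window]; yv <- y[window]
  if (var(xv) == 0)
    stop("cooperativityFit: zero variance in x within window")
  fit <- lm(yv ~ xv)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r2 = summary(fit)$r.squared, window = window, n = length(window))
}
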