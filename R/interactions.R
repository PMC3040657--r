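#' Geometric hydrogen-bond criteria
#'
#' The standard geometric rule: donor-acceptor distance strictly below
#' `maxDist` and donor-hydrogen-acceptor angle strictly above `minAngle`.
#'
#' @param maxDist maximum donor-acceptor distance, A (default 3.5).
#' @param minAngle minimum D-H-A angle, degrees (default 120).
#' @return criteria list for [findHBonds()].
#' @export
hbondCriteria <- function(maxDist = 3.5, minAngle = 120) {
  if (maxDist <= 0) stop("hbondCriteria: maxDist must be positive")
  if (minAngle <= 0 || minAngle > 180)
    stop("hbondCriteria: minAngle must be in (0, 180]")
  list(maxDist = maxDist, minAngle = minAngle)
}

#' Find hydrogen bonds between two atom groups
#'
#' Detects all (donor, hydrogen, acceptor) triples satisfying the geometric
#' criteria where the donor belongs to one group and the acceptor to the
#' other (both directions are considered: the union convention, symmetric
#' in the group labels). A donor may carry several hydrogens; bifurcated
#' geometries are collapsed so each (donor, acceptor) pair counts at most
#' one bond.
#'
#' @param model an [AtomicModel-class] carrying roles and donor links.
#' @param groupA,groupB serial vectors of the two groups.
#' @param criteria from [hbondCriteria()].
#' @param xyz optional full-model coordinate matrix (trajectory frame).
#' @return data.frame `donor, hydrogen, acceptor` (serials), one row per
#'   bonded (donor, acceptor) pair.
#' @export
findHBonds <- function(model, groupA, groupB, criteria = hbondCriteria(),
                       xyz = NULL) {
  a <- model@atoms
  if (is.null(xyz)) xyz <- coords(model)
  hyd <- which(a$role == "hydrogen")
  if (length(hyd) > 0 && anyNA(a$donorLink[hyd]))
    stop("findHBonds: hydrogen without donor link")
  onePass <- function(donSide, accSide) {
    don <- intersect(donSide, a$serial[a$role == "donor"])
    acc <- intersect(accSide, a$serial[a$role == "acceptor"])
    if (length(don) == 0 || length(acc) == 0)
      return(data.frame(donor = integer(0), hydrogen = integer(0),
                        acceptor = integer(0)))
    out <- list()
    di <- match(don, a$serial); ai <- match(acc, a$serial)
    for (k in seq_along(don)) {
      dpos <- xyz[di[k], ]
      d2 <- colSums((t(xyz[ai, , drop = FALSE]) - dpos)^2)
      cand <- which(d2 < criteria$maxDist^2)
      if (length(cand) == 0) next
      hIdx <- hyd[a$donorLink[hyd] == don[k]]
      if (length(hIdx) == 0) next
      for (ci in cand) {
        apos <- xyz[ai[ci], ]
        for (h in hIdx) {
          hpos <- xyz[h, ]
          v1 <- dpos - hpos; v2 <- apos - hpos
          cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
          ang <- acos(max(-1, min(1, cosang))) * 180 / pi
          if (ang > criteria$minAngle) {
            out[[length(out) + 1L]] <-
              data.frame(donor = don[k], hydrogen = a$serial[h],
                         acceptor = acc[ci])
            break  # one bond per (donor, acceptor) pair
          }
        }
      }
    }
    if (length(out) == 0)
      data.frame(donor = integer(0), hydrogen = integer(0),
                 acceptor = integer(0))
    else do.call(rbind, out)
  }
  res <- rbind(onePass(groupA, groupB), onePass(groupB, groupA))
  res <- res[!duplicated(res[, c("donor", "acceptor")]), , drop = FALSE]
  res <- res[order(res$donor, res$acceptor), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Hydrogen-bond count time series
#'
#' @param traj a [Trajectory-class].
#' @param groupA,groupB serial vectors.
#' @param criteria from [hbondCriteria()].
#' @param stride evaluate every `stride`-th frame.
#' @return data.frame `time_ns, count`.
#' @export
hbondCountSeries <- function(traj, groupA, groupB,
                             criteria = hbondCriteria(), stride = 1L) {
  frames <- seq(1L, nFrames(traj), by = stride)
  counts <- vapply(frames, function(f)
    nrow(findHBonds(traj@model, groupA, groupB, criteria,
                    xyz = coords(traj, f))), integer(1))
  data.frame(time_ns = traj@times[frames], count = counts)
}

#' Named COM-distance metric specification
#'
#' Describes a stability metric as the distance between the centres of mass
#' of two atom groups, optionally with an event rule (threshold crossed in
#' a direction and held) for [detectContactEvent()].
#'
#' @param name metric name.
#' @param A,B selection specifications or serial vectors.
#' @param threshold optional event threshold, A.
#' @param direction `"below"` or `"above"`.
#' @param holdTime ns the series must stay across the threshold (default 1).
#' @return metric specification list.
#' @export
distanceMetricSpec <- function(name, A, B, threshold = NULL,
                               direction = c("below", "above"),
                               holdTime = 1) {
  direction <- match.arg(direction)
  if (!is.null(threshold) && threshold <= 0)
    stop("distanceMetricSpec: threshold must be positive")
  list(name = name, A = A, B = B, threshold = threshold,
       direction = direction, holdTime = holdTime)
}

#' COM-distance time series
#'
#' Per-frame distance between the centres of mass of two groups, e.g. the
#' two sidechain oxygens of a salt-bridge aspartate versus the sidechain
#' nitrogens of its arginine partner.
#'
#' @param traj a [Trajectory-class].
#' @param A,B serial vectors of the two groups.
#' @param name metric name copied into the output.
#' @return data.frame `time_ns, distance_A, metric`.
#' @export
comDistanceSeries <- function(traj, A, B, name = "metric") {
  if (length(A) == 0 || length(B) == 0)
    stop("comDistanceSeries: empty selection")
  ser <- traj@model@atoms$serial
  ai <- match(A, ser); bi <- match(B, ser)
  if (anyNA(ai) || anyNA(bi)) stop("comDistanceSeries: unknown serial(s)")
  d <- vapply(seq_len(nFrames(traj)), function(f) {
    m <- coords(traj, f)
    sqrt(sum((colMeans(m[ai, , drop = FALSE]) -
              colMeans(m[bi, , drop = FALSE]))^2))
  }, numeric(1))
  data.frame(time_ns = traj@times, distance_A = d, metric = name)
}

#' Detect a sustained threshold-crossing event in a distance series
#'
#' Returns the first time the series crosses the threshold in the stated
#' direction and stays across it for at least the hold time (to the end of
#' the series if shorter than the hold time past the crossing is available
#' only when the remaining span covers the hold time). `NA` if no such
#' crossing exists. Mirrors contact-formation calls such as a coordination
#' distance dropping below 4 A and persisting.
#'
#' @param series data.frame with `time_ns` and a value column
#'   (`distance_A` or the second column).
#' @param threshold threshold, A.
#' @param direction `"below"` or `"above"`.
#' @param holdTime required persistence, ns.
#' @return event time in ns, or `NA` if none.
#' @export
detectContactEvent <- function(series, threshold,
                               direction = c("below", "above"),
                               holdTime = 1) {
  direction <- match.arg(direction)
  t <- series$time_ns
  v <- if ("distance_A" %in% names(series)) series$distance_A
       else series[[2]]
  if (length(t) == 0) stop("detectContactEvent: empty series")
  span <- t[length(t)] - t[1]
  if (holdTime > span)
    stop("detectContactEvent: hold time exceeds series span")
  across <- if (direction == "below") v < threshold else v > threshold
  for (i in which(across)) {
    jEnd <- which(t >= t[i] + holdTime)
    if (length(jEnd) == 0) break
    idx <- i:jEnd[1]
    if (all(across[idx])) return(t[i])
  }
  NA_real_
}
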