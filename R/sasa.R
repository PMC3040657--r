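#' Deterministic golden-spiral unit sphere points
#'
#' Quadrature node set for Shrake-Rupley surface integration. The golden
#' spiral gives a near-uniform, fully deterministic covering, so all surface
#' areas computed by the package are bit-stable.
#'
#' @param n number of points (>= 1).
#' @return `n x 3` matrix of unit vectors.
#' @export
spherePoints <- function(n) {
  if (n < 1) stop("spherePoints: n must be >= 1")
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' SASA computation parameters
#'
#' @param probeRadius solvent probe radius, A (default 1.4).
#' @param nPoints sphere points per atom (default 960; >= 12).
#' @return list of parameters for [sasa()].
#' @export
sasaParams <- function(probeRadius = 1.4, nPoints = 960L) {
  if (probeRadius < 0) stop("sasaParams: probe radius must be >= 0")
  if (nPoints < 12) stop("sasaParams: need at least 12 sphere points")
  list(probeRadius = probeRadius, nPoints = as.integer(nPoints))
}

## Core Shrake-Rupley kernel on bare coordinates + radii.
## subset/context are row indices into xyz. Neighbour search uses spatial
## binning on a grid of cell size = max pairwise cutoff.
.sasaCore <- function(xyz, radii, subset, context, probe, pts) {
  n <- length(subset)
  areas <- numeric(n)
  if (n == 0) return(areas)
  cx <- xyz[context, , drop = FALSE]
  cr <- radii[context] + probe
  cutoff <- max(radii[subset]) + max(cr) + probe
  cell <- cutoff
  key <- function(m) {
    g <- floor(sweep(m, 2, c(0, 0, 0)) / cell)
    paste(g[, 1], g[, 2], g[, 3])
  }
  ckey <- key(cx)
  bins <- split(seq_along(ckey), ckey)
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (s in seq_len(n)) {
    ai <- subset[s]
    centre <- xyz[ai, ]
    rExp <- radii[ai] + probe
    g0 <- floor(centre / cell)
    neigh <- integer(0)
    for (o in seq_len(nrow(offsets))) {
      k <- paste(g0[1] + offsets[o, 1], g0[2] + offsets[o, 2],
                 g0[3] + offsets[o, 3])
      b <- bins[[k]]
      if (!is.null(b)) neigh <- c(neigh, b)
    }
    neigh <- neigh[context[neigh] != ai]
    if (length(neigh) > 0) {
      d2 <- colSums((t(cx[neigh, , drop = FALSE]) - centre)^2)
      close <- neigh[d2 < (rExp + cr[neigh])^2]
    } else close <- integer(0)
    if (length(close) == 0) {
      areas[s] <- 4 * pi * rExp^2
      next
    }
    p <- sweep(pts * rExp, 2, centre, `+`)
    nc <- cx[close, , drop = FALSE]
    rc2 <- cr[close]^2
    free <- rep(TRUE, nrow(p))
    for (j in seq_along(close)) {
      if (!any(free)) break
      d2 <- (p[free, 1] - nc[j, 1])^2 + (p[free, 2] - nc[j, 2])^2 +
        (p[free, 3] - nc[j, 3])^2
      free[free] <- d2 >= rc2[j]
    }
    areas[s] <- 4 * pi * rExp^2 * sum(free) / nrow(p)
  }
  areas
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom SASA of `subset` atoms in the presence of `context` atoms: the
#' fraction of each atom's expanded-sphere (radius + probe) quadrature
#' points lying outside every other context atom's expanded sphere, times
#' the expanded-sphere area.
#'
#' @param model an [AtomicModel-class] (source of radii), or a bare
#'   `natoms x 3` coordinate matrix if `radii` is given.
#' @param subset serials of atoms whose areas are wanted (default: all
#'   context atoms).
#' @param context serials of atoms present as occluders (default: all).
#' @param params from [sasaParams()].
#' @param xyz optional coordinate matrix overriding the model coordinates
#'   (e.g. a trajectory frame, full-model row order).
#' @param radii per-atom radii when `model` is a bare matrix.
#' @return list with `atomArea` (named by serial), `total` (A^2) and
#'   `serials`.
#' @export
sasa <- function(model, subset = NULL, context = NULL,
                 params = sasaParams(), xyz = NULL, radii = NULL) {
  if (is(model, "AtomicModel")) {
    a <- model@atoms
    serial <- a$serial
    if (is.null(xyz)) xyz <- coords(model)
    radii <- a$radius
  } else {
    xyz <- as.matrix(model)
    serial <- seq_len(nrow(xyz))
    if (is.null(radii)) stop("sasa: radii required with bare coordinates")
    if (anyNA(radii)) stop("sasa: missing radius for atom ",
                           serial[which(is.na(radii))[1]])
  }
  if (is.null(context)) context <- serial
  if (is.null(subset)) subset <- context
  si <- match(subset, serial); ci <- match(context, serial)
  if (anyNA(si) || anyNA(ci)) stop("sasa: unknown serial(s)")
  if (!all(si %in% ci)) stop("sasa: subset must be contained in context")
  pts <- spherePoints(params$nPoints)
  areas <- .sasaCore(xyz, radii, si, ci, params$probeRadius, pts)
  names(areas) <- as.character(subset)
  list(atomArea = areas, total = sum(areas), serials = subset)
}

#' Buried SASA between two portions of a structure
#'
#' The difference between the SASA of portion A computed without and with
#' portion B present. When `restrict` is given, only the contribution of
#' those atoms (within A) is summed, yielding the per-domain buried area.
#'
#' @param model an [AtomicModel-class].
#' @param A,B disjoint serial vectors of the two portions.
#' @param restrict optional serial vector naming a domain; only atoms of
#'   that domain are summed. The domain may lie in either portion: the
#'   difference is always evaluated on the portion containing it.
#' @param params from [sasaParams()].
#' @param xyz optional full-model coordinate matrix (trajectory frame).
#' @return buried area in A^2 (non-negative up to quadrature tolerance).
#' @export
buriedSasa <- function(model, A, B, restrict = NULL,
                       params = sasaParams(), xyz = NULL) {
  if (length(intersect(A, B)) > 0)
    stop("buriedSasa: portions A and B overlap")
  if (!is.null(restrict) && length(intersect(A, restrict)) == 0 &&
      length(intersect(B, restrict)) > 0) {
    tmp <- A; A <- B; B <- tmp
  }
  sub <- if (is.null(restrict)) A else intersect(A, restrict)
  if (length(sub) == 0) return(0)
  alone <- sasa(model, subset = sub, context = A, params = params, xyz = xyz)
  both <- sasa(model, subset = sub, context = sort(c(A, B)),
               params = params, xyz = xyz)
  alone$total - both$total
}

#' Buried-SASA time series per domain
#'
#' Evaluates [buriedSasa()] on trajectory frames for each requested domain
#' restriction plus the unrestricted A-vs-B composite, in long format.
#'
#' @param traj a [Trajectory-class].
#' @param A,B disjoint serial vectors (e.g. headpiece and tailpiece).
#' @param domains named list of serial vectors used as restrictions
#'   (may be empty).
#' @param params from [sasaParams()].
#' @param stride evaluate every `stride`-th frame.
#' @return data.frame `time_ns, domain, buried_area_A2` (the composite rows
#'   carry domain `"all"`).
#' @export
buriedSasaSeries <- function(traj, A, B, domains = list(),
                             params = sasaParams(), stride = 1L) {
  frames <- seq(1L, nFrames(traj), by = stride)
  out <- list()
  for (f in frames) {
    xyz <- coords(traj, f)
    rows <- data.frame(time_ns = traj@times[f], domain = "all",
                       buried_area_A2 = buriedSasa(traj@model, A, B,
                                                   params = params,
                                                   xyz = xyz))
    for (dn in names(domains)) {
      rows <- rbind(rows, data.frame(
        time_ns = traj@times[f], domain = dn,
        buried_area_A2 = buriedSasa(traj@model, A, B,
                                    restrict = domains[[dn]],
                                    params = params, xyz = xyz)))
    }
    out[[length(out) + 1L]] <- rows
  }
  do.call(rbind, out)
}
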