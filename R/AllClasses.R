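#' @useDynLib pullMD, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods new validObject is slot
#' @importFrom stats lm coef rexp runif setNames sd median var
#' @importFrom utils read.csv write.csv head tail
NULL

## Valid hydrogen-bond roles for pseudo-atoms / annotated atoms.
.HB_ROLES <- c("none", "donor", "hydrogen", "acceptor")

#' Pseudo-atomic structure with mechanics annotations
#'
#' An `AtomicModel` holds one structure: atom records with coordinates plus
#' the per-atom annotations the analysis layer needs (van der Waals radius for
#' surface-area work, hydrogen-bond role and donor linkage for geometric
#' H-bond detection, and a hydrophobic flag for nonpolar contact metrics).
#' The `atoms` slot is a data.frame with columns `serial`, `name`, `resid`,
#' `chain`, `x`, `y`, `z`, `radius`, `role`, `donorLink`, `hydrophobic`.
#' Coordinates and radii are in Angstrom.
#'
#' @slot atoms data.frame of atom records (one row per atom).
#' @export
setClass("AtomicModel", representation(atoms = "data.frame"))

.validAtomicModel <- function(object) {
  a <- object@atoms
  need <- c("serial", "name", "resid", "chain", "x", "y", "z",
            "radius", "role", "donorLink", "hydrophobic")
  miss <- setdiff(need, names(a))
  if (length(miss) > 0)
    return(paste("missing atom columns:", paste(miss, collapse = ", ")))
  if (nrow(a) == 0) return(TRUE)
  if (anyDuplicated(a$serial))
    return("atom serials must be unique")
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    return("atom positions must be finite")
  if (!all(is.finite(a$radius)) || any(a$radius <= 0))
    return("atom radii must be positive")
  if (!all(a$role %in% .HB_ROLES))
    return(paste("unknown hbond role(s):",
                 paste(unique(setdiff(a$role, .HB_ROLES)), collapse = ", ")))
  hyd <- which(a$role == "hydrogen")
  if (length(hyd) > 0) {
    link <- a$donorLink[hyd]
    if (any(is.na(link)))
      return("every hydrogen must carry a donorLink serial")
    idx <- match(link, a$serial)
    if (any(is.na(idx)))
      return("hydrogen donorLink refers to a missing atom serial")
    if (any(a$role[idx] != "donor"))
      return("hydrogen donorLink must point at a donor atom")
  }
  TRUE
}
setValidity("AtomicModel", .validAtomicModel)

#' Named residue-range domain map
#'
#' Maps `(chain, domain)` pairs to inclusive 1-based residue ranges (a domain
#' may own several disjoint ranges, like the split hybrid domain), plus named
#' composite selections (headpiece/tailpiece splits, pulling and constraint
#' groups) stored as selection specifications.
#'
#' @slot ranges data.frame with columns `chain`, `domain`, `first`, `last`.
#' @slot composites named list of selection specification lists
#'   (see [resolveSelection()]).
#' @export
setClass("DomainMap",
         representation(ranges = "data.frame", composites = "list"))

.validDomainMap <- function(object) {
  r <- object@ranges
  need <- c("chain", "domain", "first", "last")
  if (!all(need %in% names(r)))
    return(paste("ranges needs columns:", paste(need, collapse = ", ")))
  if (nrow(r) > 0) {
    if (any(r$first > r$last)) return("range first must be <= last")
    for (key in unique(paste(r$chain, r$domain))) {
      sub <- r[paste(r$chain, r$domain) == key, , drop = FALSE]
      if (nrow(sub) < 2) next
      sub <- sub[order(sub$first), ]
      if (any(sub$first[-1] <= sub$last[-nrow(sub)]))
        return(paste("overlapping ranges within domain:", key))
    }
  }
  if (length(object@composites) > 0 &&
      (is.null(names(object@composites)) ||
       any(!nzchar(names(object@composites)))))
    return("composites must be a named list")
  TRUE
}
setValidity("DomainMap", .validDomainMap)

#' Coordinate trajectory bound to a topology
#'
#' Ordered coordinate frames with strictly increasing times (ns), referencing
#' the `AtomicModel` that supplies the per-atom annotations. Coordinates are
#' stored as an `nframes x natoms x 3` array in Angstrom.
#'
#' @slot times numeric vector of frame times in ns (strictly increasing).
#' @slot coords numeric array, `c(nframes, natoms, 3)`.
#' @slot model the [AtomicModel-class] topology.
#' @export
setClass("Trajectory",
         representation(times = "numeric", coords = "array",
                        model = "AtomicModel"))

.validTrajectory <- function(object) {
  d <- dim(object@coords)
  if (length(d) != 3 || d[3] != 3)
    return("coords must be an nframes x natoms x 3 array")
  if (d[1] != length(object@times))
    return("number of frames must match length(times)")
  if (d[2] != nrow(object@model@atoms))
    return("frame atom count must match the model")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    return("frame times must be strictly increasing")
  if (!all(is.finite(object@coords)))
    return("trajectory coordinates must be finite")
  TRUE
}
setValidity("Trajectory", .validTrajectory)

#' Coarse-grained bead-spring topology
#'
#' Backbone/shell springs, truncated-harmonic hinge potentials with a bent
#' equilibrium, and breakable interface contacts (polar contacts carry the
#' donor/hydrogen/acceptor annotations on the model side). All force constants
#' are in pN/A (bonds, contacts) or pN*A/rad^2 (hinges); lengths in Angstrom.
#'
#' @slot bonds data.frame `i, j, r0, k` (atom serials).
#' @slot hinges data.frame `a, b, c, theta0, k, cutoff` (degrees for angles;
#'   torque is zero once the angle deviates more than `cutoff` from `theta0`).
#' @slot contacts data.frame `i, j, r0, k, rbreak, depth, class`
#'   (`class` is `"polar"` or `"hydrophobic"`; force acts only inside
#'   `rbreak`, re-entering the capture radius re-engages the contact).
#' @slot dihedrals data.frame `a, b, c, d, phi0, k` (harmonic torsional
#'   restraints about the b-c axis, degrees and pN*A/rad^2; deviations are
#'   wrapped to (-180, 180]).
#' @export
setClass("CgTopology",
         representation(bonds = "data.frame", hinges = "data.frame",
                        contacts = "data.frame", dihedrals = "data.frame"))

.validCgTopology <- function(object) {
  b <- object@bonds; h <- object@hinges; ct <- object@contacts
  dh <- object@dihedrals
  if (!all(c("i", "j", "r0", "k") %in% names(b)))
    return("bonds needs columns i, j, r0, k")
  if (!all(c("a", "b", "c", "theta0", "k", "cutoff") %in% names(h)))
    return("hinges needs columns a, b, c, theta0, k, cutoff")
  if (!all(c("i", "j", "r0", "k", "rbreak", "depth", "class") %in% names(ct)))
    return("contacts needs columns i, j, r0, k, rbreak, depth, class")
  if (!all(c("a", "b", "c", "d", "phi0", "k") %in% names(dh)))
    return("dihedrals needs columns a, b, c, d, phi0, k")
  if (nrow(b) > 0 && (any(b$k < 0) || any(b$r0 < 0)))
    return("bond stiffness and rest length must be non-negative")
  if (nrow(ct) > 0) {
    if (any(ct$rbreak <= ct$r0))
      return("contact break radius must exceed rest length")
    if (!all(ct$class %in% c("polar", "hydrophobic")))
      return("contact class must be polar or hydrophobic")
  }
  TRUE
}
setValidity("CgTopology", .validCgTopology)

#' Pulling protocol specification
#'
#' One of three modes: `free` (no external load), `constant-velocity`
#' (virtual spring moving at speed `v`, force `F = k (v t - x)` on the pulled
#' centre of mass), or `constant-force` (fixed magnitude `force`). The
#' constrained group's centre of mass is tethered to its initial position by
#' a harmonic spring of stiffness `kConstraint`. The pulling direction is by
#' default fixed at the start as the unit vector from the constraint COM to
#' the pull COM; `direction = "tracking"` recomputes it every step.
#'
#' @slot mode character, `"free"`, `"constant-velocity"` or `"constant-force"`.
#' @slot pull selection specification list (see [resolveSelection()]).
#' @slot constraint selection specification list.
#' @slot k spring constant, pN/A (constant-velocity mode).
#' @slot v pulling speed, A/ns (constant-velocity mode).
#' @slot force force magnitude, pN (constant-force mode).
#' @slot direction `"fixed"` or `"tracking"`.
#' @slot kConstraint constraint spring constant, pN/A.
#' @export
setClass("PullingProtocol",
         representation(mode = "character", pull = "list",
                        constraint = "list", k = "numeric", v = "numeric",
                        force = "numeric", direction = "character",
                        kConstraint = "numeric"))

.validPullingProtocol <- function(object) {
  if (!object@mode %in% c("free", "constant-velocity", "constant-force"))
    return("mode must be free, constant-velocity or constant-force")
  if (!object@direction %in% c("fixed", "tracking"))
    return("direction must be fixed or tracking")
  if (object@k < 0 || object@kConstraint < 0)
    return("spring constants must be non-negative")
  if (object@mode == "constant-velocity" && object@k <= 0)
    return("constant-velocity mode needs a positive spring constant k")
  if (object@mode == "constant-force" && length(object@force) != 1)
    return("constant-force mode needs a single force magnitude")
  TRUE
}
setValidity("PullingProtocol", .validPullingProtocol)

#' Langevin simulation parameters
#'
#' Overdamped (Brownian) dynamics constants. Temperature enters only through
#' kB*T (41.4195 pN*A at 300 K); `gamma` is the per-bead friction.
#'
#' @slot temperature K.
#' @slot gamma per-bead friction, pN*ns/A.
#' @slot dt integration timestep, ns.
#' @slot duration total simulated time, ns.
#' @slot saveStride save every this many steps.
#' @slot seed integer RNG seed.
#' @export
setClass("SimParams",
         representation(temperature = "numeric", gamma = "numeric",
                        dt = "numeric", duration = "numeric",
                        saveStride = "integer", seed = "integer"))

.validSimParams <- function(object) {
  if (object@temperature < 0) return("temperature must be >= 0")
  if (object@gamma <= 0) return("friction gamma must be positive")
  if (object@dt <= 0 || object@duration <= 0)
    return("dt and duration must be positive")
  if (object@saveStride < 1L) return("saveStride must be >= 1")
  TRUE
}
setValidity("SimParams", .validSimParams)

#' Bell-model fit result
#'
#' Parameters of the force-dependent escape-time law
#' `t = t0 * exp(-F * dx / (kB T))`, obtained by ordinary least squares of
#' `ln t` on `F`, with standard errors (delta method for `t0`).
#'
#' @slot t0 zero-force waiting time, ns.
#' @slot dx energy-well width, A.
#' @slot t0SE,dxSE standard errors.
#' @slot kBT thermal energy used, pN*A.
#' @slot residuals per-point residuals of the log-linear fit.
#' @slot r2 coefficient of determination of the log-linear fit.
#' @slot n number of points fitted.
#' @export
setClass("BellFitResult",
         representation(t0 = "numeric", dx = "numeric", t0SE = "numeric",
                        dxSE = "numeric", kBT = "numeric",
                        residuals = "numeric", r2 = "numeric", n = "integer"))

.validBellFitResult <- function(object) {
  if (object@t0 <= 0) return("t0 must be positive")
  if (object@n >= 3L && (!is.finite(object@t0SE) || !is.finite(object@dxSE)))
    return("standard errors must be finite with >= 3 points")
  TRUE
}
setValidity("BellFitResult", .validBellFitResult)
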