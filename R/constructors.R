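## Unit conversions used throughout: forces in pN, lengths in A, times in ns.
## 1 kcal mol^-1 A^-1 = 69.479 pN; kB = 0.0138065 pN nm / K.

#' Thermal energy kB*T in pN*Angstrom
#'
#' @param temperature temperature in K (default 300, giving 41.4195 pN*A).
#' @return kB*T in pN*A.
#' @export
kBT <- function(temperature = 300) 0.0138065 * 10 * temperature

#' Convert kcal/mol/A^2 spring constants to pN/A
#'
#' @param k spring constant in kcal mol^-1 A^-2.
#' @return spring constant in pN/A (1 kcal mol^-1 A^-1 = 69.479 pN).
#' @export
kcalSpringToPn <- function(k) k * 69.479

#' Construct an AtomicModel from an atom table
#'
#' Fills optional annotation columns with defaults: radius 1.8 A (the
#' pseudo-bead default), role `"none"`, no donor link, not hydrophobic.
#'
#' @param atoms data.frame with at least `serial`, `name`, `resid`, `chain`,
#'   `x`, `y`, `z`; optional `radius`, `role`, `donorLink`, `hydrophobic`.
#' @return validated [AtomicModel-class].
#' @export
atomicModel <- function(atoms) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (is.null(atoms$radius)) atoms$radius <- 1.8
  if (is.null(atoms$role)) atoms$role <- "none"
  if (is.null(atoms$donorLink)) atoms$donorLink <- NA_integer_
  if (is.null(atoms$hydrophobic)) atoms$hydrophobic <- FALSE
  atoms$serial <- as.integer(atoms$serial)
  atoms$resid <- as.integer(atoms$resid)
  atoms$donorLink <- as.integer(atoms$donorLink)
  atoms$chain <- as.character(atoms$chain)
  atoms$name <- as.character(atoms$name)
  rownames(atoms) <- NULL
  new("AtomicModel", atoms = atoms)
}

#' Construct a Trajectory
#'
#' @param times numeric frame times in ns, strictly increasing.
#' @param coords `nframes x natoms x 3` array, or a list of `natoms x 3`
#'   frame matrices.
#' @param model the [AtomicModel-class] topology.
#' @return validated [Trajectory-class].
#' @export
trajectory <- function(times, coords, model) {
  if (is.list(coords)) {
    arr <- array(0, dim = c(length(coords), nrow(coords[[1]]), 3))
    for (i in seq_along(coords)) arr[i, , ] <- coords[[i]]
    coords <- arr
  }
  new("Trajectory", times = as.numeric(times), coords = coords, model = model)
}

#' Construct a pulling protocol
#'
#' @param mode `"free"`, `"constant-velocity"` or `"constant-force"`.
#' @param pull,constraint selection specification lists
#'   (see [resolveSelection()]); may be empty lists in free mode.
#' @param k virtual-spring constant, pN/A. `kKcal` may be given instead, in
#'   kcal mol^-1 A^-2 (the unit the SMD literature quotes).
#' @param v pulling speed, A/ns (default 1, slow enough that the viscous
#'   drag of the coarse model stays small against the rupture force peak).
#' @param force constant-force magnitude, pN.
#' @param direction `"fixed"` (set once at t = 0 from the constraint COM to
#'   the pull COM) or `"tracking"`.
#' @param kConstraint constraint tether stiffness, pN/A; `kConstraintKcal`
#'   accepts kcal mol^-1 A^-2 (default 10 kcal mol^-1 A^-2 = 694.79 pN/A).
#' @param kKcal,kConstraintKcal unit-converting alternatives to `k` and
#'   `kConstraint`.
#' @return validated [PullingProtocol-class].
#' @export
pullingProtocol <- function(mode = c("free", "constant-velocity",
                                     "constant-force"),
                            pull = list(), constraint = list(),
                            k = NULL, kKcal = NULL, v = 1,
                            force = 0, direction = "fixed",
                            kConstraint = NULL, kConstraintKcal = 10) {
  mode <- match.arg(mode)
  if (is.null(k)) k <- if (is.null(kKcal)) 0 else kcalSpringToPn(kKcal)
  if (is.null(kConstraint)) kConstraint <- kcalSpringToPn(kConstraintKcal)
  new("PullingProtocol", mode = mode, pull = pull, constraint = constraint,
      k = as.numeric(k), v = as.numeric(v), force = as.numeric(force),
      direction = direction, kConstraint = as.numeric(kConstraint))
}

#' Construct simulation parameters
#'
#' @param temperature K (default 300).
#' @param gamma per-bead friction, pN*ns/A (default 0.5, chosen so that
#'   post-rupture unfolding relaxes on the nanosecond scale).
#' @param dt timestep, ns.
#' @param duration run length, ns.
#' @param saveStride save every `saveStride` steps.
#' @param seed integer RNG seed.
#' @return validated [SimParams-class].
#' @export
simParams <- function(temperature = 300, gamma = 0.5, dt = 2.5e-04,
                      duration = 10, saveStride = 400L, seed = 1L) {
  new("SimParams", temperature = as.numeric(temperature),
      gamma = as.numeric(gamma), dt = as.numeric(dt),
      duration = as.numeric(duration), saveStride = as.integer(saveStride),
      seed = as.integer(seed))
}

#' Construct a coarse-grained topology
#'
#' @param bonds data.frame `i, j, r0, k`.
#' @param hinges data.frame `a, b, c, theta0, k, cutoff` (degrees).
#' @param contacts data.frame `i, j, r0, k, rbreak, depth, class`.
#' @param dihedrals data.frame `a, b, c, d, phi0, k` (degrees,
#'   pN*A/rad^2).
#' @return validated [CgTopology-class].
#' @export
cgTopology <- function(bonds = NULL, hinges = NULL, contacts = NULL,
                       dihedrals = NULL) {
  empty <- function(cols) {
    df <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    df
  }
  if (is.null(bonds)) bonds <- empty(c("i", "j", "r0", "k"))
  if (is.null(hinges))
    hinges <- empty(c("a", "b", "c", "theta0", "k", "cutoff"))
  if (is.null(contacts)) {
    contacts <- empty(c("i", "j", "r0", "k", "rbreak", "depth"))
    contacts$class <- character(0)
  }
  if (is.null(dihedrals))
    dihedrals <- empty(c("a", "b", "c", "d", "phi0", "k"))
  new("CgTopology", bonds = as.data.frame(bonds),
      hinges = as.data.frame(hinges), contacts = as.data.frame(contacts),
      dihedrals = as.data.frame(dihedrals))
}
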