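.topologyArrays <- function(model, topology) {
  ser <- model@atoms$serial
  idx <- function(s) {
    i <- match(s, ser)
    if (anyNA(i)) stop("topology references missing atom serial(s)")
    as.integer(i - 1L)
  }
  b <- topology@bonds; h <- topology@hinges; ct <- topology@contacts
  dh <- topology@dihedrals
  list(bi = idx(b$i), bj = idx(b$j),
       br0 = as.numeric(b$r0), bk = as.numeric(b$k),
       ha = idx(h$a), hb = idx(h$b), hc = idx(h$c),
       htheta0 = as.numeric(h$theta0) * pi / 180,
       hk = as.numeric(h$k),
       hcut = as.numeric(h$cutoff) * pi / 180,
       ci = idx(ct$i), cj = idx(ct$j),
       cr0 = as.numeric(ct$r0), ck = as.numeric(ct$k),
       crbreak = as.numeric(ct$rbreak),
       da = idx(dh$a), db = idx(dh$b), dc = idx(dh$c), dd = idx(dh$d),
       dphi0 = as.numeric(dh$phi0) * pi / 180, dk = as.numeric(dh$k))
}

## Conservative timestep stability check for overdamped dynamics:
## dt must be below gamma / (largest per-bead sum of incident stiffnesses).
.checkTimestep <- function(model, topology, params) {
  n <- nAtoms(model)
  ser <- model@atoms$serial
  acc <- numeric(n)
  addPair <- function(i, j, k) {
    ii <- match(i, ser); jj <- match(j, ser)
    for (r in seq_along(ii)) {
      acc[ii[r]] <<- acc[ii[r]] + k[r]
      acc[jj[r]] <<- acc[jj[r]] + k[r]
    }
  }
  if (nrow(topology@bonds) > 0)
    addPair(topology@bonds$i, topology@bonds$j, topology@bonds$k)
  if (nrow(topology@contacts) > 0)
    addPair(topology@contacts$i, topology@contacts$j, topology@contacts$k)
  kmax <- if (length(acc) > 0) max(acc) else 0
  ## Euler stability for the stiffest per-bead mode: dt < 2 gamma / k_max
  ## (k_max = largest per-bead sum of incident stiffnesses)
  if (kmax > 0 && params@dt >= 2 * params@gamma / kmax)
    stop(sprintf(paste0("timestep dt = %g ns violates the stability bound ",
                        "dt < 2 gamma/k_max = %g ns"),
                 params@dt, 2 * params@gamma / kmax))
  invisible(TRUE)
}

#' Run overdamped Langevin dynamics under a pulling protocol
#'
#' Integrates `dx = (F/gamma) dt + sqrt(2 kB T dt / gamma) xi` per bead
#' (Euler-Maruyama) over the bead-spring topology. The pulling force acts on
#' the pull-group COM (distributed equally over the pulled beads) along the
#' protocol's direction policy; in constant-velocity mode its magnitude is
#' the virtual-spring law `F = k (v t - x)` with `x` the COM displacement
#' along the pulling direction; the constraint COM is tethered to its
#' initial position. Contacts exert force only inside their break radius
#' and re-engage whenever the pair re-enters it (no hysteresis). An
#' instability guard aborts if any bead moves more than 5 A in one step.
#' The RNG is seeded from `params@seed`, so identical inputs replay
#' bit-identically.
#'
#' @param model an [AtomicModel-class].
#' @param topology a [CgTopology-class].
#' @param protocol a [PullingProtocol-class]; its `pull`/`constraint`
#'   selection specifications are resolved against `model` and `map`.
#' @param params a [SimParams-class].
#' @param map optional [DomainMap-class] for resolving named selections.
#' @param startCoords optional `natoms x 3` matrix overriding the model
#'   coordinates (restarts).
#' @return list with `trajectory` (a [Trajectory-class] whose first frame
#'   is the initial state) and `forceRecord` (data.frame `time_ns,
#'   fx_pN, fy_pN, fz_pN, force_pN, x_A, pull_x, pull_y, pull_z, cons_x,
#'   cons_y, cons_z`).
#' @export
runDynamics <- function(model, topology, protocol, params, map = NULL,
                        startCoords = NULL) {
  validObject(model); validObject(topology)
  validObject(protocol); validObject(params)
  .checkTimestep(model, topology, params)
  arr <- .topologyArrays(model, topology)
  ser <- model@atoms$serial
  resolveIdx <- function(spec) {
    s <- if (is.numeric(spec)) as.integer(spec)
         else resolveSelection(model, map, spec)
    as.integer(match(s, ser) - 1L)
  }
  pullIdx <- resolveIdx(protocol@pull)
  consIdx <- resolveIdx(protocol@constraint)
  if (protocol@mode != "free" && length(pullIdx) == 0)
    stop("runDynamics: pulling protocol needs a non-empty pull selection")
  mode <- match(protocol@mode,
                c("free", "constant-velocity", "constant-force")) - 1L
  nsteps <- max(1L, as.integer(round(params@duration / params@dt)))
  xyz <- if (is.null(startCoords)) coords(model) else as.matrix(startCoords)
  set.seed(params@seed)
  res <- .cppRunDynamics(xyz, arr$bi, arr$bj, arr$br0, arr$bk,
                         arr$ha, arr$hb, arr$hc, arr$htheta0, arr$hk,
                         arr$hcut, arr$ci, arr$cj, arr$cr0, arr$ck,
                         arr$crbreak, arr$da, arr$db, arr$dc, arr$dd,
                         arr$dphi0, arr$dk, pullIdx, consIdx, mode,
                         protocol@k, protocol@v, protocol@force,
                         protocol@direction == "tracking",
                         protocol@kConstraint, params@gamma,
                         kBT(params@temperature), params@dt, nsteps,
                         params@saveStride)
  dimcoords <- res$coords
  traj <- trajectory(res$times, array(dimcoords, dim = dim(dimcoords)),
                     model)
  fr <- as.data.frame(res$forceRecord)
  names(fr) <- c("time_ns", "fx_pN", "fy_pN", "fz_pN", "force_pN", "x_A",
                 "pull_x", "pull_y", "pull_z", "cons_x", "cons_y", "cons_z")
  list(trajectory = traj, forceRecord = fr)
}

#' Potential energy of a configuration
#'
#' Bond, contact and hinge terms of the bead-spring Hamiltonian (external
#' pulling and tether work excluded). Contact and hinge wells are shifted so
#' the potential is continuous at their truncation radii.
#'
#' @param model an [AtomicModel-class].
#' @param topology a [CgTopology-class].
#' @param xyz optional coordinates (default: the model's).
#' @return energy in pN*A.
#' @export
potentialEnergy <- function(model, topology, xyz = NULL) {
  if (is.null(xyz)) xyz <- coords(model)
  arr <- .topologyArrays(model, topology)
  .cppPotentialEnergy(as.matrix(xyz), arr$bi, arr$bj, arr$br0, arr$bk,
                      arr$ha, arr$hb, arr$hc, arr$htheta0, arr$hk,
                      arr$hcut, arr$ci, arr$cj, arr$cr0, arr$ck,
                      arr$crbreak, arr$da, arr$db, arr$dc, arr$dd,
                      arr$dphi0, arr$dk)
}

#' Restart inputs from a trajectory snapshot
#'
#' Extracts the coordinates of a saved frame for a new run under a new
#' protocol: the way partially-extended and fully-extended structures from
#' pulling runs are handed to free dynamics to probe their stability.
#'
#' @param traj a [Trajectory-class].
#' @param frame frame index (1-based).
#' @param protocol the new [PullingProtocol-class].
#' @return list `startCoords`, `protocol`, ready for [runDynamics()].
#' @export
snapshotRestart <- function(traj, frame, protocol) {
  if (frame < 1L || frame > nFrames(traj))
    stop("snapshotRestart: frame index out of range")
  list(startCoords = coords(traj, frame), protocol = protocol)
}
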