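#' Atom table of a model
#'
#' @param x an [AtomicModel-class] or [Trajectory-class].
#' @return data.frame of atom records.
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname atoms
#' @export
setMethod("atoms", "AtomicModel", function(x) x@atoms)

#' @rdname atoms
#' @export
setMethod("atoms", "Trajectory", function(x) x@model@atoms)

#' Number of atoms
#' @param x an [AtomicModel-class] or [Trajectory-class].
#' @return integer atom count.
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "AtomicModel", function(x) nrow(x@atoms))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "Trajectory", function(x) dim(x@coords)[2])

#' Coordinates of a model or trajectory frame
#'
#' @param x an [AtomicModel-class] or [Trajectory-class].
#' @param frame frame index (trajectories only; 1-based).
#' @return `natoms x 3` numeric matrix, Angstrom.
#' @export
setGeneric("coords", function(x, frame = 1L) standardGeneric("coords"))

#' @rdname coords
#' @export
setMethod("coords", "AtomicModel", function(x, frame = 1L) {
  m <- as.matrix(x@atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
})

#' @rdname coords
#' @export
setMethod("coords", "Trajectory", function(x, frame = 1L) {
  if (frame < 1L || frame > dim(x@coords)[1])
    stop("frame index out of range: ", frame)
  matrix(x@coords[frame, , ], ncol = 3)
})

#' Frame times of a trajectory
#' @param x a [Trajectory-class].
#' @return numeric vector, ns.
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @rdname frameTimes
#' @export
setMethod("frameTimes", "Trajectory", function(x) x@times)

#' Number of frames
#' @param x a [Trajectory-class].
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname nFrames
#' @export
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[1])

setMethod("show", "AtomicModel", function(object) {
  a <- object@atoms
  cat("AtomicModel with", nrow(a), "atoms,",
      length(unique(a$chain)), "chain(s)\n")
  if (nrow(a) > 0) {
    cat("  chains:", paste(unique(a$chain), collapse = ", "), "\n")
    cat("  roles: ",
        paste(names(table(a$role)), table(a$role), sep = "=", collapse = " "),
        "\n", sep = "")
  }
  invisible(object)
})

setMethod("show", "Trajectory", function(object) {
  n <- length(object@times)
  cat("Trajectory:", n, "frames x", dim(object@coords)[2], "atoms")
  if (n > 0)
    cat(sprintf(", t = %.4g .. %.4g ns", object@times[1], object@times[n]))
  cat("\n")
  invisible(object)
})

setMethod("show", "DomainMap", function(object) {
  r <- object@ranges
  cat("DomainMap:", length(unique(paste(r$chain, r$domain))),
      "domains on chain(s)", paste(unique(r$chain), collapse = ", "), "\n")
  if (length(object@composites) > 0)
    cat("  composites:", paste(names(object@composites), collapse = ", "),
        "\n")
  invisible(object)
})

setMethod("show", "PullingProtocol", function(object) {
  cat("PullingProtocol:", object@mode)
  if (object@mode == "constant-velocity")
    cat(sprintf(" (k = %.4g pN/A, v = %.4g A/ns)", object@k, object@v))
  if (object@mode == "constant-force")
    cat(sprintf(" (F = %.4g pN)", object@force))
  cat(",", object@direction, "direction\n")
  invisible(object)
})

setMethod("show", "BellFitResult", function(object) {
  cat(sprintf("Bell fit (n = %d): t0 = %.4g +/- %.3g ns, dx = %.4g +/- %.3g A (R2 = %.4f)\n",
              object@n, object@t0, object@t0SE, object@dx, object@dxSE,
              object@r2))
  invisible(object)
})
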