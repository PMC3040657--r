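## Fixed-width PDB v3.3 I/O. Only ATOM/HETATM coordinate records are
## interpreted; the mechanics annotations (radius, H-bond role, donor link,
## hydrophobic flag) live in a sidecar CSV because PDB has no field for them.

.ELEMENT_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20,
                    P = 1.80)
.DEFAULT_BEAD_RADIUS <- 1.8

.elementFromName <- function(name) {
  el <- toupper(substr(gsub("^[0-9 ]+", "", name), 1, 1))
  ifelse(el %in% names(.ELEMENT_RADII), el, "")
}

#' Read a PDB file into an AtomicModel
#'
#' Parses ATOM/HETATM records (PDB v3.3 fixed columns). Annotations come
#' from an optional sidecar table written by [writeAnnotations()]; without
#' one, a documented heuristic is applied: radii from a fixed element table
#' (C 1.70, N 1.55, O 1.52, S 1.80 A; 1.8 A for unrecognised pseudo-beads),
#' N atoms as donors, O atoms as acceptors, and each H attached to the
#' covalently nearest donor within 1.2 A.
#'
#' @param path PDB file path.
#' @param annotations optional path to a sidecar annotation CSV
#'   (`serial, radius, role, donor_link, hydrophobic`).
#' @return an [AtomicModel-class].
#' @export
readPDB <- function(path, annotations = NULL) {
  if (!file.exists(path)) stop("readPDB: file not found: ", path)
  lines <- readLines(path)
  isAtom <- grepl("^(ATOM  |HETATM)", lines)
  ln <- which(isAtom)
  if (length(ln) == 0) stop("readPDB: no ATOM/HETATM records in ", path)
  rec <- lines[ln]
  short <- nchar(rec) < 54
  if (any(short))
    stop("readPDB: line ", ln[which(short)[1]],
         " lacks coordinate columns (need 54 characters)")
  num <- function(from, to, what) {
    v <- suppressWarnings(as.numeric(substr(rec, from, to)))
    if (anyNA(v))
      stop("readPDB: line ", ln[which(is.na(v))[1]],
           " has an unparseable ", what, " field")
    v
  }
  atoms <- data.frame(
    serial = as.integer(num(7, 11, "serial")),
    name = trimws(substr(rec, 13, 16)),
    resid = as.integer(num(23, 26, "residue number")),
    chain = substr(rec, 22, 22),
    x = num(31, 38, "x"), y = num(39, 46, "y"), z = num(47, 54, "z"),
    stringsAsFactors = FALSE)
  if (anyDuplicated(atoms$serial))
    stop("readPDB: duplicate atom serial ",
         atoms$serial[anyDuplicated(atoms$serial)])

  if (!is.null(annotations)) {
    ann <- read.csv(annotations, stringsAsFactors = FALSE)
    idx <- match(atoms$serial, ann$serial)
    if (anyNA(idx))
      stop("readPDB: annotation table misses serial(s): ",
           paste(head(atoms$serial[is.na(idx)]), collapse = ", "))
    atoms$radius <- ann$radius[idx]
    atoms$role <- ann$role[idx]
    atoms$donorLink <- as.integer(ann$donor_link[idx])
    atoms$hydrophobic <- as.logical(ann$hydrophobic[idx])
  } else {
    el <- .elementFromName(atoms$name)
    atoms$radius <- ifelse(el %in% names(.ELEMENT_RADII),
                           .ELEMENT_RADII[el], .DEFAULT_BEAD_RADIUS)
    atoms$role <- ifelse(el == "N", "donor",
                         ifelse(el == "O", "acceptor", "none"))
    atoms$donorLink <- NA_integer_
    hyd <- which(el == "H")
    don <- which(atoms$role == "donor")
    if (length(hyd) > 0 && length(don) > 0) {
      dm <- as.matrix(atoms[don, c("x", "y", "z")])
      for (h in hyd) {
        d2 <- colSums((t(dm) - c(atoms$x[h], atoms$y[h], atoms$z[h]))^2)
        j <- which.min(d2)
        if (d2[j] <= 1.2^2) {
          atoms$role[h] <- "hydrogen"
          atoms$donorLink[h] <- atoms$serial[don[j]]
        }
      }
    }
    atoms$hydrophobic <- FALSE
  }
  atomicModel(atoms)
}

#' Write an AtomicModel as PDB v3.3
#'
#' Fixed-width ATOM records with default occupancy 1.00 and B-factor 0.00,
#' a TER record between chains, and END. Values that cannot be encoded in
#' the fixed columns (serial > 99999, residue number > 9999) raise an error
#' rather than being truncated.
#'
#' @param model an [AtomicModel-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePDB <- function(model, path) {
  a <- model@atoms
  if (any(a$serial > 99999L))
    stop("writePDB: atom serial > 99999 cannot be encoded")
  if (any(a$resid > 9999L))
    stop("writePDB: residue number > 9999 cannot be encoded")
  if (any(abs(c(a$x, a$y, a$z)) >= 10000))
    stop("writePDB: coordinate out of fixed-width range")
  name4 <- ifelse(nchar(a$name) >= 4, substr(a$name, 1, 4),
                  sprintf(" %-3s", a$name))
  rec <- sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                 a$serial, name4, "BEA", a$chain, a$resid,
                 a$x, a$y, a$z, 1, 0)
  out <- character(0)
  chains <- rle(a$chain)
  pos <- cumsum(chains$lengths)
  start <- 1L
  for (ci in seq_along(pos)) {
    out <- c(out, rec[start:pos[ci]])
    if (ci < length(pos)) out <- c(out, "TER")
    start <- pos[ci] + 1L
  }
  out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}

#' Write the sidecar annotation table of a model
#'
#' @param model an [AtomicModel-class].
#' @param path output CSV path (`serial, radius, role, donor_link,
#'   hydrophobic`).
#' @return `path`, invisibly.
#' @export
writeAnnotations <- function(model, path) {
  a <- model@atoms
  write.csv(data.frame(serial = a$serial, radius = a$radius, role = a$role,
                       donor_link = a$donorLink,
                       hydrophobic = a$hydrophobic),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a trajectory as columnar CSV
#'
#' One row per frame: `time_ns` followed by the flattened coordinates
#' `x1,y1,z1,x2,...` in atom-serial order.
#'
#' @param traj a [Trajectory-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeTrajectoryCSV <- function(traj, path) {
  n <- nAtoms(traj)
  flat <- t(vapply(seq_len(nFrames(traj)),
                   function(f) as.numeric(t(coords(traj, f))),
                   numeric(3 * n)))
  df <- data.frame(time_ns = traj@times, flat)
  names(df) <- c("time_ns",
                 paste0(rep(c("x", "y", "z"), n),
                        rep(seq_len(n), each = 3)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a columnar trajectory CSV
#'
#' @param path CSV written by [writeTrajectoryCSV()].
#' @param model the [AtomicModel-class] the frames belong to.
#' @return a [Trajectory-class].
#' @export
readTrajectoryCSV <- function(path, model) {
  df <- read.csv(path)
  n <- nAtoms(model)
  if (ncol(df) != 1 + 3 * n)
    stop("readTrajectoryCSV: expected ", 1 + 3 * n, " columns for ",
         n, " atoms, found ", ncol(df))
  arr <- array(0, dim = c(nrow(df), n, 3))
  m <- as.matrix(df[, -1, drop = FALSE])
  for (f in seq_len(nrow(df)))
    arr[f, , ] <- matrix(m[f, ], ncol = 3, byrow = TRUE)
  trajectory(df$time_ns, arr, model)
}

#' Export a trajectory as a multi-MODEL PDB
#'
#' @param traj a [Trajectory-class].
#' @param path output path.
#' @param stride write every `stride`-th frame.
#' @return `path`, invisibly.
#' @export
writeMultiModelPDB <- function(traj, path, stride = 1L) {
  con <- file(path, "w")
  on.exit(close(con))
  m <- traj@model
  frames <- seq(1L, nFrames(traj), by = stride)
  for (k in seq_along(frames)) {
    f <- frames[k]
    writeLines(sprintf("MODEL %8d", k), con)
    fm <- m
    fm@atoms[, c("x", "y", "z")] <- coords(traj, f)
    tmp <- tempfile(fileext = ".pdb")
    writePDB(fm, tmp)
    body <- readLines(tmp)
    unlink(tmp)
    writeLines(body[body != "END"], con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
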