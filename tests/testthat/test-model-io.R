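test_that("PDB reading parses fixed-width records and flags bad input", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1      11.000  22.000  33.000  1.00  0.00",
    "ATOM      2  CB  ALA A   2      -1.500   0.250   4.750  1.00  0.00",
    "END"), path)
  m <- readPDB(path)
  expect_equal(nAtoms(m), 2L)
  expect_equal(coords(m), rbind(c(11, 22, 33), c(-1.5, 0.25, 4.75)))
  expect_equal(atoms(m)$name, c("CA", "CB"))
  expect_equal(atoms(m)$resid, 1:2)

  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1      11.000  22.000  33.000  1.00  0.00",
    "ATOM      2  CB  ALA A   2"), bad)
  expect_error(readPDB(bad), "line 2")

  dup <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1      11.000  22.000  33.000  1.00  0.00",
    "ATOM      1  CB  ALA A   2      12.000  22.000  33.000  1.00  0.00"),
    dup)
  expect_error(readPDB(dup), "duplicate")
})

test_that("PDB writing is fixed-width with TER between chains and refuses
           unencodable fields", {
  m <- posModel(rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)),
                chain = c("A", "A", "B"))
  path <- withr::local_tempfile(fileext = ".pdb")
  writePDB(m, path)
  lines <- readLines(path)
  expect_equal(sum(lines == "TER"), 1L)
  expect_equal(which(lines == "TER"), 3L)
  expect_true(all(grepl(" 1.00  0.00$", lines[c(1, 2, 4)])))

  big <- posModel(matrix(0, 1, 3))
  big@atoms$serial <- 100000L
  expect_error(writePDB(big, path), "99999")
})

test_that("write/read round trip is the identity on retained fields and
           byte-stable on the synthetic bent model", {
  b <- sharedBentModel()
  pdb <- withr::local_tempfile(fileext = ".pdb")
  ann <- withr::local_tempfile(fileext = ".csv")
  writePDB(b$model, pdb)
  writeAnnotations(b$model, ann)
  back <- readPDB(pdb, annotations = ann)
  expect_equal(atoms(back)$serial, atoms(b$model)$serial)
  expect_equal(atoms(back)$name, atoms(b$model)$name)
  expect_equal(atoms(back)$resid, atoms(b$model)$resid)
  expect_equal(atoms(back)$chain, atoms(b$model)$chain)
  expect_equal(coords(back), round(coords(b$model), 3))
  expect_equal(atoms(back)$role, atoms(b$model)$role)
  expect_equal(atoms(back)$hydrophobic, atoms(b$model)$hydrophobic)
  ## byte-stability of write(read(write(m)))
  pdb2 <- withr::local_tempfile(fileext = ".pdb")
  writePDB(back, pdb2)
  expect_identical(readLines(pdb), readLines(pdb2))
})

test_that("an established structure reader agrees with the writer", {
  b <- sharedBentModel()
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writePDB(b$model, pdb)
  ref <- bio3d::read.pdb(pdb)
  expect_equal(nrow(ref$atom), nAtoms(b$model))
  expect_equal(unname(cbind(ref$atom$x, ref$atom$y, ref$atom$z)),
               round(coords(b$model), 3), tolerance = 1e-9)
  expect_equal(ref$atom$resno, atoms(b$model)$resid)
})

test_that("selection resolution matches the published pulling groups", {
  m <- residueChainModel(list(A = 1:956, B = 1:690))
  map <- defaultDomainMap()
  betaA <- resolveSelection(m, map, list(composite = "pull_betaA"))
  expect_length(betaA, 35L)
  prop <- resolveSelection(m, map, list(composite = "pull_propeller"))
  expect_length(prop, 35L)
  cons <- resolveSelection(m, map, list(composite = "constraint_betaTD"))
  expect_length(cons, sum(c(11, 4, 3, 6, 4)))
})

test_that("selection resolution is deterministic, order-stable, and strict
           about unknown names", {
  m <- residueChainModel(list(A = 1:50, B = 1:50))
  map <- defaultDomainMap()
  expect_identical(resolveSelection(m, map, list()), integer(0))
  s1 <- resolveSelection(m, map, list(chain = "A", residues = c(5, 2, 9)))
  s2 <- resolveSelection(m, map, list(residues = c(9, 5, 2), chain = "A"))
  expect_identical(s1, s2)
  expect_identical(s1, sort(s1))
  expect_identical(resolveSelection(m, map, list(chain = "Z")), integer(0))
  expect_error(resolveSelection(m, map, list(domains = "nonesuch")),
               "known")
})

test_that("centre of mass matches direct summation and handles weights", {
  m <- posModel(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(centerOfMass(m, 1:2), c(1, 0, 0))
  expect_equal(centerOfMass(m, 2L), c(2, 0, 0))
  expect_error(centerOfMass(m, integer(0)), "empty")

  xyz <- randomCloud(10, seed = 101)
  m10 <- posModel(xyz)
  sel <- c(2L, 5L, 7L, 9L)
  brute <- apply(xyz[sel, ], 2, sum) / length(sel)
  expect_equal(centerOfMass(m10, sel), brute, tolerance = 1e-12)
  w <- c(1, 2, 3, 4)
  bruteW <- colSums(xyz[sel, ] * w) / sum(w)
  expect_equal(centerOfMass(m10, sel, weights = w), bruteW,
               tolerance = 1e-12)
})

test_that("Kabsch superposition recovers generating rotations and enforces
           proper rotations", {
  ref <- randomCloud(20, seed = 7)
  fit0 <- kabschSuperpose(ref, ref)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-10)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-10)

  shifted <- sweep(ref, 2, c(5, 5, 5), `+`)
  expect_equal(kabschSuperpose(shifted, ref)$rmsd, 0, tolerance = 1e-10)

  set.seed(42)
  for (i in 1:20) {
    R <- rotationMatrix(randomAxis(), runif(1, 5, 175))
    rotated <- ref %*% t(R)
    fit <- kabschSuperpose(rotated, ref)
    expect_equal(fit$rotation %*% R, diag(3), tolerance = 1e-8)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  }

  line <- cbind(1:5, 0, 0)
  expect_error(kabschSuperpose(line, line), "collinear|degenerate")
})

test_that("superposition RMSD is invariant under common rigid transforms", {
  a <- randomCloud(15, seed = 11)
  b <- a + matrix(rnorm(45, sd = 0.3), 15, 3)
  base <- kabschSuperpose(a, b)$rmsd
  set.seed(99)
  for (i in 1:10) {
    R <- rotationMatrix(randomAxis(), runif(1, 0, 360))
    t <- rnorm(3, sd = 20)
    a2 <- sweep(a %*% t(R), 2, t, `+`)
    b2 <- sweep(b %*% t(R), 2, t, `+`)
    expect_equal(kabschSuperpose(a2, b2)$rmsd, base, tolerance = 1e-8)
  }
})

test_that("RMSD series follows the superposition convention", {
  m <- posModel(randomCloud(12, seed = 3))
  traj <- staticTrajectory(m, nframes = 4)
  expect_equal(rmsdSeries(traj)$rmsd_A, rep(0, 4), tolerance = 1e-10)

  xyz <- coords(m)
  R <- rotationMatrix(c(0, 0, 1), 40)
  moved <- sweep(xyz %*% t(R), 2, c(3, -2, 7), `+`)
  traj2 <- trajectory(c(0, 1), list(xyz, moved), m)
  expect_equal(rmsdSeries(traj2)$rmsd_A[2], 0, tolerance = 1e-8)
  shifted <- sweep(xyz, 2, c(1, 0, 0), `+`)
  traj3 <- trajectory(c(0, 1), list(xyz, shifted), m)
  expect_equal(rmsdSeries(traj3, superpose = FALSE)$rmsd_A[2], 1,
               tolerance = 1e-12)
})

test_that("extension series is zero at frame one and matches direct
           distances", {
  m <- posModel(randomCloud(8, seed = 21))
  pull <- 1:3; consN <- 6:8
  traj <- staticTrajectory(m, nframes = 3)
  expect_equal(extensionSeries(traj, pull, consN)$extension_A, rep(0, 3))

  xyz <- coords(m)
  d0 <- sqrt(sum((colMeans(xyz[pull, ]) - colMeans(xyz[consN, ]))^2))
  u <- (colMeans(xyz[pull, ]) - colMeans(xyz[consN, ])) / d0
  moved <- xyz
  moved[pull, ] <- sweep(xyz[pull, ], 2, 30 * u, `+`)
  traj2 <- trajectory(c(0, 1), list(xyz, moved), m)
  expect_equal(extensionSeries(traj2, pull, consN)$extension_A[2], 30,
               tolerance = 1e-10)

  set.seed(5)
  frames <- replicate(5, xyz + matrix(rnorm(24), 8, 3), simplify = FALSE)
  traj3 <- trajectory(0:4, frames, m)
  es <- extensionSeries(traj3, pull, consN)
  brute <- vapply(frames, function(f)
    sqrt(sum((colMeans(f[pull, ]) - colMeans(f[consN, ]))^2)), numeric(1))
  expect_equal(es$extension_A, brute - brute[1], tolerance = 1e-12)
  expect_identical(es$extension_A[1], 0)
  expect_error(extensionSeries(traj3, integer(0), consN), "empty")
})

test_that("trajectory CSV round trips frames and times", {
  m <- posModel(randomCloud(6, seed = 31))
  set.seed(8)
  frames <- replicate(4, coords(m) + matrix(rnorm(18), 6, 3),
                      simplify = FALSE)
  traj <- trajectory(c(0, 0.5, 1.2, 3), frames, m)
  path <- withr::local_tempfile(fileext = ".csv")
  writeTrajectoryCSV(traj, path)
  back <- readTrajectoryCSV(path, m)
  expect_equal(frameTimes(back), frameTimes(traj))
  for (f in 1:4)
    expect_equal(coords(back, f), coords(traj, f), tolerance = 1e-12)
})
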