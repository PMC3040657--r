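## Construct a model with a donor+hydrogen in group A and an acceptor in
## group B at chosen distance/angle.
dhaModel <- function(dDA, angleDeg) {
  dpos <- c(0, 0, 0)
  apos <- c(dDA, 0, 0)
  ## place H at 1 A from D such that the D-H-A angle equals angleDeg
  ## (numeric solve on the in-plane H position)
  best <- NULL; bestErr <- Inf
  for (phi in seq(0, pi, length.out = 721)) {
    h <- c(cos(phi), sin(phi), 0)
    v1 <- dpos - h; v2 <- apos - h
    ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
    if (abs(ang - angleDeg) < bestErr) { bestErr <- abs(ang - angleDeg); best <- h }
  }
  atomicModel(data.frame(
    serial = 1:3, name = c("N", "H", "O"), resid = 1:3,
    chain = c("A", "A", "B"),
    x = c(dpos[1], best[1], apos[1]), y = c(dpos[2], best[2], apos[2]),
    z = c(dpos[3], best[3], apos[3]),
    role = c("donor", "hydrogen", "acceptor"),
    donorLink = c(NA, 1L, NA)))
}

test_that("the geometric criterion is strict at both thresholds", {
  m <- dhaModel(3.4, 150)
  hb <- findHBonds(m, groupA = 1:2, groupB = 3L)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$donor, 1L)
  expect_equal(hb$acceptor, 3L)

  expect_equal(nrow(findHBonds(dhaModel(3.6, 150), 1:2, 3L)), 0L)
  expect_equal(nrow(findHBonds(dhaModel(3.4, 110), 1:2, 3L)), 0L)
  ## strictness at the boundary values themselves
  expect_equal(nrow(findHBonds(dhaModel(3.5, 150), 1:2, 3L)), 0L)
})

test_that("detection matches an exhaustive triple loop on random polar
           configurations and is symmetric in the groups", {
  set.seed(77)
  n <- 50
  xyz <- matrix(runif(3 * n, 0, 12), n, 3)
  role <- sample(c("donor", "acceptor"), n, replace = TRUE)
  atomsDf <- data.frame(serial = seq_len(n), name = "X",
                        resid = seq_len(n),
                        chain = rep(c("A", "B"), length.out = n),
                        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                        role = role, donorLink = NA_integer_)
  ## attach one hydrogen per donor
  don <- which(role == "donor")
  hyd <- data.frame(serial = n + seq_along(don), name = "H",
                    resid = n + seq_along(don),
                    chain = atomsDf$chain[don],
                    x = xyz[don, 1] + runif(length(don), -1, 1) * 0.6,
                    y = xyz[don, 2] + runif(length(don), -1, 1) * 0.6,
                    z = xyz[don, 3] + runif(length(don), -1, 1) * 0.6,
                    role = "hydrogen", donorLink = atomsDf$serial[don])
  m <- atomicModel(rbind(atomsDf, hyd))
  A <- atoms(m)$serial[atoms(m)$chain == "A"]
  B <- atoms(m)$serial[atoms(m)$chain == "B"]
  got <- findHBonds(m, A, B)

  ## brute force over all (donor, hydrogen, acceptor) triples
  am <- atoms(m); pos <- coords(m)
  pairs <- character(0)
  for (di in which(am$role == "donor")) for (ai in which(am$role == "acceptor")) {
    if (am$chain[di] == am$chain[ai]) next
    dda <- sqrt(sum((pos[di, ] - pos[ai, ])^2))
    if (dda >= 3.5) next
    ok <- FALSE
    for (hi in which(am$role == "hydrogen" & am$donorLink == am$serial[di])) {
      v1 <- pos[di, ] - pos[hi, ]; v2 <- pos[ai, ] - pos[hi, ]
      ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
      if (ang > 120) ok <- TRUE
    }
    if (ok) pairs <- c(pairs, paste(am$serial[di], am$serial[ai]))
  }
  expect_setequal(paste(got$donor, got$acceptor), pairs)

  swapped <- findHBonds(m, B, A)
  expect_equal(nrow(swapped), nrow(got))
  expect_setequal(paste(swapped$donor, swapped$acceptor),
                  paste(got$donor, got$acceptor))
})

test_that("hydrogen-bond counts are invariant under rigid motion of the
           whole frame", {
  b <- sharedBentModel()
  m <- b$model; map <- b$map
  hyb <- resolveSelection(m, map, list(chain = "B", domains = "hybrid"))
  btd <- resolveSelection(m, map, list(chain = "B", domains = "betaTD"))
  base <- nrow(findHBonds(m, hyb, btd))
  expect_gte(base, 4L)
  set.seed(12)
  R <- rotationMatrix(randomAxis(), 73)
  moved <- sweep(coords(m) %*% t(R), 2, c(11, -4, 8), `+`)
  expect_equal(nrow(findHBonds(m, hyb, btd, xyz = moved)), base)
})

test_that("count series follows the trajectory frames", {
  b <- sharedBentModel()
  m <- b$model; map <- b$map
  hyb <- resolveSelection(m, map, list(chain = "B", domains = "hybrid"))
  btd <- resolveSelection(m, map, list(chain = "B", domains = "betaTD"))
  traj <- staticTrajectory(m, nframes = 3)
  cs <- hbondCountSeries(traj, hyb, btd)
  expect_equal(length(unique(cs$count)), 1L)
  ## a group with no polar atoms yields zero
  cb <- atoms(m)$serial[atoms(m)$name == "CB"][1:5]
  expect_equal(hbondCountSeries(traj, cb, btd)$count, rep(0L, 3))
})

test_that("COM distance series matches brute-force recomputation", {
  m <- posModel(randomCloud(9, seed = 55))
  traj <- staticTrajectory(m, nframes = 2)
  xyz <- coords(m)
  cs <- comDistanceSeries(traj, 1:3, 4:6)
  brute <- sqrt(sum((colMeans(xyz[1:3, ]) - colMeans(xyz[4:6, ]))^2))
  expect_equal(cs$distance_A, rep(brute, 2), tolerance = 1e-12)

  ## 3-4-5 triangle and coincident groups
  m2 <- posModel(rbind(c(0, 0, 0), c(3, 4, 0)))
  t2 <- staticTrajectory(m2, nframes = 1)
  expect_equal(comDistanceSeries(t2, 1L, 2L)$distance_A, 5)
  expect_equal(comDistanceSeries(t2, 1:2, 1:2)$distance_A, 0)
  expect_error(comDistanceSeries(t2, integer(0), 2L), "empty")
})

test_that("contact events require a sustained crossing and ignore later
           content", {
  tser <- seq(0, 30, by = 0.5)
  v <- ifelse(tser < 18, 14, 3.5)
  s <- data.frame(time_ns = tser, distance_A = v)
  expect_equal(detectContactEvent(s, 4, "below", holdTime = 1), 18)

  flat <- data.frame(time_ns = tser, distance_A = rep(14, length(tser)))
  expect_true(is.na(detectContactEvent(flat, 4, "below", holdTime = 1)))
  expect_error(detectContactEvent(s, 4, "below", holdTime = 100), "span")

  ## a brief dip shorter than the hold time does not count
  v2 <- v; v2[tser >= 5 & tser < 5.5] <- 3.0
  s2 <- data.frame(time_ns = tser, distance_A = v2)
  expect_equal(detectContactEvent(s2, 4, "below", holdTime = 1), 18)

  ## appending frames after the detected event leaves it unchanged
  s3 <- rbind(s, data.frame(time_ns = seq(30.5, 40, by = 0.5),
                            distance_A = 20))
  expect_equal(detectContactEvent(s3, 4, "below", holdTime = 1), 18)
})

test_that("noisy planted crossings agree with an exhaustive scan", {
  set.seed(202)
  tser <- seq(0, 50, by = 0.25)
  for (rep in 1:5) {
    tEvent <- runif(1, 10, 35)
    v <- 10 + rnorm(length(tser), sd = 0.8)
    v[tser >= tEvent] <- 2.5 + rnorm(sum(tser >= tEvent), sd = 0.3)
    s <- data.frame(time_ns = tser, distance_A = v)
    got <- detectContactEvent(s, 4, "below", holdTime = 2)
    ## brute scan: first index below threshold staying below for >= hold
    brute <- NA_real_
    below <- v < 4
    for (i in which(below)) {
      j <- which(tser >= tser[i] + 2)[1]
      if (is.na(j)) break
      if (all(below[i:j])) { brute <- tser[i]; break }
    }
    expect_identical(got, brute)
  }
})
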