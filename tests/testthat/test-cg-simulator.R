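test_that("the default bent model has the expected architecture", {
  b <- sharedBentModel()
  m <- b$model; map <- b$map
  expect_equal(nAtoms(m), 144L)  # 12 beads x 12 domains
  expect_true(validObject(m))
  expect_true(validObject(b$topology))

  pull <- resolveSelection(m, map, list(composite = "pull_head"))
  cons <- resolveSelection(m, map, list(composite = "constraint_tail"))
  expect_length(pull, 12L)
  expect_length(cons, 12L)
  d <- sqrt(sum((centerOfMass(m, pull) - centerOfMass(m, cons))^2))
  expect_equal(d, 45, tolerance = 0.5)

  ## planted polar contacts are detected as hydrogen bonds
  hyb <- resolveSelection(m, map, list(chain = "B", domains = "hybrid"))
  btd <- resolveSelection(m, map, list(chain = "B", domains = "betaTD"))
  expect_gte(nrow(findHBonds(m, hyb, btd)), 4L)

  ## headpiece/tailpiece interface dominated by the beta chain
  head <- resolveSelection(m, map, list(composite = "headpiece"))
  tail <- resolveSelection(m, map, list(composite = "tailpiece"))
  ps <- sasaParams(nPoints = 240)
  serials <- atoms(m)$serial
  bs <- buriedSasa(m, head, tail, params = ps)
  bsB <- buriedSasa(m, head, tail,
                    restrict = serials[atoms(m)$chain == "B"], params = ps)
  bsA <- buriedSasa(m, head, tail,
                    restrict = serials[atoms(m)$chain == "A"], params = ps)
  expect_gt(bs, 0)
  expect_gt(bsB, bsA)
})

test_that("builder validates its configuration", {
  cfg <- bentModelConfig()
  cfg$headTailDistance <- 10
  expect_error(buildBentModel(cfg), "headTailDistance")
  cfg2 <- bentModelConfig()
  cfg2$minDomainSeparation <- 50
  expect_error(buildBentModel(cfg2), "overlap")
})

test_that("the built structure is a mechanical equilibrium at zero
           temperature", {
  b <- sharedBentModel()
  p0 <- pullingProtocol("free", list(composite = "pull_head"),
                        list(composite = "constraint_tail"))
  sp <- simParams(temperature = 0, duration = 1, seed = 1)
  r <- runDynamics(b$model, b$topology, p0, sp, map = b$map)
  disp <- max(abs(coords(r$trajectory, nFrames(r$trajectory)) -
                  coords(b$model)))
  expect_lt(disp, 1e-6)
})

test_that("potential energy is non-increasing in noiseless relaxation", {
  b <- sharedBentModel()
  set.seed(4)
  start <- coords(b$model) + matrix(rnorm(3 * nAtoms(b$model), sd = 0.4),
                                    nAtoms(b$model), 3)
  p0 <- pullingProtocol("free")
  sp <- simParams(temperature = 0, duration = 2, saveStride = 200L,
                  seed = 2)
  r <- runDynamics(b$model, b$topology, p0, sp, map = b$map,
                   startCoords = start)
  U <- vapply(seq_len(nFrames(r$trajectory)), function(f)
    potentialEnergy(b$model, b$topology, coords(r$trajectory, f)),
    numeric(1))
  expect_true(all(diff(U) <= 1e-6))
})

test_that("the recorded pulling force obeys the virtual-spring law", {
  b <- sharedBentModel()
  pv <- pullingProtocol("constant-velocity", list(composite = "pull_head"),
                        list(composite = "constraint_tail"),
                        kKcal = 0.5, v = 1)
  sp <- simParams(duration = 3, seed = 6)
  r <- runDynamics(b$model, b$topology, pv, sp, map = b$map)
  fr <- r$forceRecord
  k <- kcalSpringToPn(0.5)
  expect_equal(fr$force_pN, k * (1 * fr$time_ns - fr$x_A),
               tolerance = 1e-9)
  ## the force vector has the recorded magnitude
  expect_equal(sqrt(fr$fx_pN^2 + fr$fy_pN^2 + fr$fz_pN^2),
               abs(fr$force_pN), tolerance = 1e-9)
})

test_that("identical seed and configuration replay bit-identically", {
  b <- sharedBentModel()
  pf <- pullingProtocol("constant-force", list(composite = "pull_head"),
                        list(composite = "constraint_tail"), force = 150)
  sp <- simParams(duration = 2, seed = 99)
  r1 <- runDynamics(b$model, b$topology, pf, sp, map = b$map)
  r2 <- runDynamics(b$model, b$topology, pf, sp, map = b$map)
  expect_identical(r1$trajectory@coords, r2$trajectory@coords)
  expect_identical(r1$forceRecord, r2$forceRecord)
  sp2 <- simParams(duration = 2, seed = 100)
  r3 <- runDynamics(b$model, b$topology, pf, sp2, map = b$map)
  expect_false(identical(r1$trajectory@coords, r3$trajectory@coords))
})

test_that("snapshot restarts reproduce fresh runs and validate indices", {
  b <- sharedBentModel()
  p0 <- pullingProtocol("free", list(composite = "pull_head"),
                        list(composite = "constraint_tail"))
  sp <- simParams(duration = 1.5, seed = 12)
  fresh <- runDynamics(b$model, b$topology, p0, sp, map = b$map)
  rs <- snapshotRestart(fresh$trajectory, 1L, p0)
  again <- runDynamics(b$model, b$topology, rs$protocol, sp, map = b$map,
                       startCoords = rs$startCoords)
  expect_identical(fresh$trajectory@coords, again$trajectory@coords)
  expect_error(snapshotRestart(fresh$trajectory, 10000L, p0), "range")
})

test_that("the integrator guards against unstable configurations", {
  m <- posModel(rbind(c(0, 0, 0), c(200, 0, 0)))
  top <- cgTopology(bonds = data.frame(i = 1, j = 2, r0 = 0.01, k = 80))
  p0 <- pullingProtocol("free")
  expect_error(
    runDynamics(m, top, p0, simParams(duration = 0.01, seed = 1)),
    "unstable")
  topStiff <- cgTopology(bonds = data.frame(i = 1, j = 2, r0 = 1, k = 5e5))
  expect_error(
    runDynamics(m, topStiff, p0, simParams(duration = 0.01, seed = 1)),
    "stability bound")
})

test_that("higher constant force gives shorter unbending waiting times", {
  b <- sharedBentModel()
  m <- b$model; map <- b$map
  pull <- resolveSelection(m, map, list(composite = "pull_head"))
  cons <- resolveSelection(m, map, list(composite = "constraint_tail"))
  rule <- waitingTimeRule(baselineWindow = 1, delta = 20, holdTime = 1)
  wait1 <- function(force, seed) {
    pf <- pullingProtocol("constant-force", list(composite = "pull_head"),
                          list(composite = "constraint_tail"),
                          force = force)
    sp <- simParams(duration = 60, seed = seed)
    r <- runDynamics(m, b$topology, pf, sp, map = map)
    detectWaitingTime(extensionSeries(r$trajectory, pull, cons), rule)
  }
  lo <- vapply(1:3, function(s) wait1(97, 2000 + s), numeric(1))
  hi <- vapply(1:3, function(s) wait1(195, 2000 + s), numeric(1))
  expect_true(all(is.finite(hi)))
  expect_lt(median(hi), median(lo, na.rm = TRUE))
})
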