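test_that("waiting-time detection uses baseline + threshold + hold", {
  tser <- seq(0, 100, by = 0.5)
  v <- ifelse(tser < 50, 45, 150)
  s <- data.frame(time_ns = tser, extension_A = v)
  rule <- waitingTimeRule(baselineWindow = 5, delta = 20, holdTime = 1)
  expect_equal(detectWaitingTime(s, rule), 50)

  flat <- data.frame(time_ns = tser, extension_A = rep(45, length(tser)))
  expect_true(is.na(detectWaitingTime(flat, rule)))
  short <- data.frame(time_ns = c(0, 1), extension_A = c(0, 0))
  expect_error(detectWaitingTime(short, rule), "short")

  ## content after the detected hold window does not matter
  v2 <- v; v2[tser > 60] <- 0
  s2 <- data.frame(time_ns = tser, extension_A = v2)
  expect_equal(detectWaitingTime(s2, rule), 50)
})

test_that("noisy two-state traces agree with an exhaustive threshold scan", {
  set.seed(333)
  tser <- seq(0, 80, by = 0.2)
  rule <- waitingTimeRule(baselineWindow = 5, delta = 20, holdTime = 1)
  for (rep in 1:5) {
    tEvent <- runif(1, 20, 60)
    v <- 45 + rnorm(length(tser), sd = 2)
    v[tser >= tEvent] <- 95 + rnorm(sum(tser >= tEvent), sd = 3)
    s <- data.frame(time_ns = tser, extension_A = v)
    got <- detectWaitingTime(s, rule)
    base <- mean(v[tser <= 5]); thr <- base + 20
    brute <- NA_real_
    above <- v > thr
    for (i in which(above)) {
      j <- which(tser >= tser[i] + 1)[1]
      if (is.na(j)) break
      if (all(above[i:j])) { brute <- tser[i]; break }
    }
    expect_identical(got, brute)
  }
})

test_that("the Bell fit inverts exact force-lifetime data", {
  f <- c(0, 20.7097, 41.4195)
  times <- 100 * exp(-f * 2 / kBT(300))
  expect_equal(times, c(100, 36.788, 13.534), tolerance = 1e-4)
  fit <- suppressWarnings(fitBell(f, times))
  expect_equal(fit@t0, 100, tolerance = 1e-6)
  expect_equal(fit@dx, 2, tolerance = 1e-6)
  expect_equal(fit@r2, 1, tolerance = 1e-12)

  two <- fitBell(c(50, 150), c(20, 4))
  expect_equal(two@residuals, c(0, 0), tolerance = 1e-12)
  expect_true(is.na(two@t0SE))

  expect_error(fitBell(100, 5), "points")
  expect_error(fitBell(c(1, 2), c(3, -1)), "positive")
  expect_error(fitBell(c(5, 5), c(3, 1)), "distinct")
})

test_that("exact Bell data is inverted for any positive parameters", {
  set.seed(17)
  for (i in 1:25) {
    t0 <- runif(1, 0.5, 5000)
    dx <- runif(1, 0.1, 5)
    temp <- runif(1, 250, 350)
    f <- sort(runif(5, 0, 300))
    times <- t0 * exp(-f * dx / kBT(temp))
    fit <- suppressWarnings(fitBell(f, times, temperature = temp))
    expect_equal(fit@t0, t0, tolerance = 1e-6 * t0)
    expect_equal(fit@dx, dx, tolerance = 1e-6)
  }
})

test_that("escape simulation reproduces the closed-form mean lifetimes", {
  s0 <- simulateEscape(100, 0, forces = c(0, 100, 200),
                       samplesPerForce = 1e4, seed = 5)
  means <- tapply(s0$time_ns, s0$force_pN, mean)
  expect_true(all(abs(means - 100) / 100 < 0.05))

  s1 <- simulateEscape(728, 1.2, forces = c(0, 195),
                       samplesPerForce = 1e4, seed = 6)
  m0 <- mean(s1$time_ns[s1$force_pN == 0])
  m195 <- mean(s1$time_ns[s1$force_pN == 195])
  expect_equal(m0, 728, tolerance = 0.05 * 728)
  tau195 <- 728 * exp(-195 * 1.2 / kBT(300))
  expect_equal(tau195, 2.561, tolerance = 1e-3)
  expect_equal(m195, tau195, tolerance = 0.05 * tau195)

  expect_error(simulateEscape(-1, 1, 10), "t0")
  expect_error(simulateEscape(1, 1, 10, samplesPerForce = 0), "sample")
})

test_that("sample means converge at the exponential-variance rate", {
  set.seed(8)
  for (n in c(100, 1000, 10000)) {
    s <- simulateEscape(50, 0, forces = 0, samplesPerForce = n,
                        seed = 1000 + n)
    relErr <- abs(mean(s$time_ns) - 50) / 50
    expect_lt(relErr, 3 / sqrt(n))
  }
})

test_that("fitting single log-lifetimes is biased low by the
           Euler-Mascheroni constant while log of the mean is not", {
  set.seed(44)
  x <- rexp(2e5, rate = 1 / 30)
  expect_equal(mean(log(x)), log(30) - 0.57722, tolerance = 0.01)
  expect_equal(log(mean(x)), log(30), tolerance = 0.01)
})

test_that("replicated recovery of the Bell parameters is centred on the
           truth", {
  fits <- bellRecoveryExperiment(100, 2, forces = c(50, 100, 150, 200),
                                 samplesPerForce = 100, replicates = 100,
                                 seed = 3)
  sem <- sd(fits$dx_A) / sqrt(nrow(fits))
  expect_lt(abs(mean(fits$dx_A) - 2), 2 * sem + 1e-3)
  expect_lt(abs(median(fits$t0_ns) - 100) / 100, 0.1)
})

test_that("force peaks are found with correct prominence ranking", {
  ext <- seq(0, 40, by = 0.25)
  tri <- pmax(0, 300 - 30 * abs(ext - 20))
  pk <- detectForcePeaks(ext, tri, smoothWindow = 0.4)
  expect_equal(pk$extension_A[1], 20, tolerance = 0.3)
  expect_equal(pk$force_pN[1], 300, tolerance = 10)

  two <- pmax(0, 200 - 40 * abs(ext - 10)) + pmax(0, 320 - 40 * abs(ext - 30))
  pk2 <- detectForcePeaks(ext, two, smoothWindow = 0.4, minProminence = 50)
  expect_equal(nrow(pk2), 2L)
  expect_equal(pk2$extension_A, c(30, 10), tolerance = 0.3)
  expect_true(all(diff(pk2$prominence_pN) <= 0))

  expect_error(detectForcePeaks(ext, tri, smoothWindow = 100), "span")
  expect_error(detectForcePeaks(ext[1:2], tri[1:2]), "points")
})

test_that("peak detection matches a brute-force prominence oracle on
           random piecewise curves", {
  bruteForcePeaks <- function(sm) {
    n <- length(sm)
    out <- NULL
    for (p in seq_len(n)) {
      left <- if (p > 1) sm[p - 1] else -Inf
      right <- if (p < n) sm[p + 1] else -Inf
      if (!(sm[p] > left && sm[p] >= right)) next
      h <- sm[p]
      higherL <- which(sm[seq_len(p - 1)] > h)
      lo <- if (p == 1) h else min(sm[(if (length(higherL)) max(higherL) else 1):p])
      idxR <- if (p == n) integer(0) else (p + 1):n
      higherR <- idxR[sm[idxR] > h]
      hi <- if (length(idxR) == 0) h else
        min(sm[p:(if (length(higherR)) min(higherR) else n)])
      out <- rbind(out, c(p, h, h - max(lo, hi)))
    }
    out
  }
  set.seed(202)
  for (rep in 1:5) {
    ext <- seq(0, 30, by = 0.5)
    force <- cumsum(rnorm(length(ext), sd = 15))
    got <- detectForcePeaks(ext, force, smoothWindow = 1e-6,
                            minProminence = 0)
    oracle <- bruteForcePeaks(force)
    expect_equal(sort(got$extension_A), sort(ext[oracle[, 1]]))
    expect_equal(sort(got$prominence_pN), sort(oracle[, 3]),
                 tolerance = 1e-10)
  }
})
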