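#' Waiting-time detection rule
#'
#' @param baselineWindow ns averaged at the start of the trace to define
#'   the bent-state baseline (default 5).
#' @param delta rise above baseline that marks unbending onset, A
#'   (default 20).
#' @param holdTime ns the trace must stay above baseline + delta
#'   (default 1).
#' @return rule list for [detectWaitingTime()].
#' @export
waitingTimeRule <- function(baselineWindow = 5, delta = 20, holdTime = 1) {
  if (baselineWindow <= 0 || delta <= 0 || holdTime <= 0)
    stop("waitingTimeRule: all fields must be positive")
  list(baselineWindow = baselineWindow, delta = delta, holdTime = holdTime)
}

#' Detect the unbending waiting time in a distance trace
#'
#' The baseline is the mean over the initial baseline window; the waiting
#' time is the first time the trace exceeds baseline + delta and remains
#' above it for at least the hold time (the moment unbending starts in a
#' constant-force run). `NA` if no sustained crossing occurs.
#'
#' @param series data.frame `time_ns` plus a value column (`extension_A`,
#'   `distance_A`, or the second column).
#' @param rule from [waitingTimeRule()].
#' @return waiting time in ns, or `NA`.
#' @export
detectWaitingTime <- function(series, rule = waitingTimeRule()) {
  t <- series$time_ns
  v <- if ("extension_A" %in% names(series)) series$extension_A
       else if ("distance_A" %in% names(series)) series$distance_A
       else series[[2]]
  if (length(t) < 2) stop("detectWaitingTime: series too short")
  span <- t[length(t)] - t[1]
  if (span < rule$baselineWindow + rule$holdTime)
    stop("detectWaitingTime: series shorter than baseline + hold windows")
  base <- mean(v[t <= t[1] + rule$baselineWindow])
  thr <- base + rule$delta
  above <- v > thr
  for (i in which(above)) {
    jEnd <- which(t >= t[i] + rule$holdTime)
    if (length(jEnd) == 0) break
    if (all(above[i:jEnd[1]])) return(t[i])
  }
  NA_real_
}

#' Fit the Bell model to force-dependent waiting times
#'
#' Ordinary least squares of `ln t` on force `F` for the two-state escape
#' law `t = t0 exp(-F dx / (kB T))`: the well width is `dx = -slope kB T`
#' and the zero-force waiting time `t0 = exp(intercept)`. Standard errors
#' come from the regression covariance, with the delta method for `t0`.
#' With exactly two points the line passes through both and the errors are
#' undefined (NA).
#'
#' @param force numeric forces, pN (distinct, >= 2 values).
#' @param time waiting times, ns (positive).
#' @param temperature K (default 300).
#' @return a [BellFitResult-class].
#' @export
fitBell <- function(force, time, temperature = 300) {
  if (length(force) != length(time) || length(force) < 2)
    stop("fitBell: need >= 2 (force, time) points")
  if (any(time <= 0)) stop("fitBell: waiting times must be positive")
  if (length(unique(force)) < 2) stop("fitBell: forces must be distinct")
  kt <- kBT(temperature)
  y <- log(time)
  fit <- lm(y ~ force)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  dx <- -slope * kt
  t0 <- exp(intercept)
  if (length(force) >= 3) {
    cv <- summary(fit)$coefficients
    interceptSE <- cv[1, 2]; slopeSE <- cv[2, 2]
    t0SE <- t0 * interceptSE       # delta method
    dxSE <- slopeSE * kt
    r2 <- summary(fit)$r.squared
  } else {
    t0SE <- NA_real_; dxSE <- NA_real_; r2 <- 1
  }
  new("BellFitResult", t0 = t0, dx = dx, t0SE = t0SE, dxSE = dxSE,
      kBT = kt, residuals = unname(fit$residuals), r2 = r2,
      n = length(force))
}

#' Simulate two-state escape waiting times under force
#'
#' Draws exponential waiting times with mean
#' `tau(F) = t0 exp(-F dx / (kB T))`: force lowers the barrier and
#' exponentiates the escape rate.
#'
#' @param t0 zero-force waiting time, ns (> 0).
#' @param dx well width, A.
#' @param forces numeric forces, pN.
#' @param temperature K.
#' @param samplesPerForce draws per force level (> 0).
#' @param seed integer RNG seed (NULL leaves the RNG state alone).
#' @return data.frame `force_pN, time_ns`.
#' @export
simulateEscape <- function(t0, dx, forces, temperature = 300,
                           samplesPerForce = 1L, seed = NULL) {
  if (t0 <= 0) stop("simulateEscape: t0 must be positive")
  if (samplesPerForce < 1) stop("simulateEscape: need >= 1 sample per force")
  if (!is.null(seed)) set.seed(seed)
  kt <- kBT(temperature)
  out <- lapply(forces, function(f) {
    tau <- t0 * exp(-f * dx / kt)
    data.frame(force_pN = f, time_ns = rexp(samplesPerForce, rate = 1 / tau))
  })
  do.call(rbind, out)
}

#' Detect force peaks on a force-extension curve
#'
#' Smooths the curve with a centred moving average in the extension domain
#' and reports local maxima whose prominence (height above the higher of
#' the two flanking minima separating it from larger peaks) exceeds the
#' floor, ranked by prominence. The rank-1 peak is the major force peak of
#' a pulling experiment.
#'
#' @param extension,force numeric vectors (sorted by extension), A and pN.
#' @param smoothWindow moving-average window in extension units, A
#'   (default 2).
#' @param minProminence prominence floor, pN.
#' @return data.frame `extension_A, force_pN, prominence_pN`, ordered by
#'   decreasing prominence.
#' @export
detectForcePeaks <- function(extension, force, smoothWindow = 2,
                             minProminence = 0) {
  if (length(extension) != length(force) || length(extension) < 3)
    stop("detectForcePeaks: need >= 3 points")
  if (is.unsorted(extension)) stop("detectForcePeaks: sort by extension")
  if (smoothWindow > (extension[length(extension)] - extension[1]))
    stop("detectForcePeaks: smoothing window larger than curve span")
  sm <- vapply(seq_along(extension), function(i) {
    keep <- abs(extension - extension[i]) <= smoothWindow / 2
    mean(force[keep])
  }, numeric(1))
  n <- length(sm)
  isMax <- vapply(seq_len(n), function(i) {
    left <- if (i > 1) sm[i - 1] else -Inf
    right <- if (i < n) sm[i + 1] else -Inf
    sm[i] > left && sm[i] >= right
  }, logical(1))
  peaks <- which(isMax)
  if (length(peaks) == 0)
    return(data.frame(extension_A = numeric(0), force_pN = numeric(0),
                      prominence_pN = numeric(0)))
  prom <- vapply(peaks, function(p) {
    h <- sm[p]
    higherL <- which(sm[seq_len(p - 1)] > h)
    lo <- if (p == 1) h else {
      from <- if (length(higherL) == 0) 1 else max(higherL)
      min(sm[from:p])
    }
    idxR <- if (p == n) integer(0) else (p + 1):n
    higherR <- idxR[sm[idxR] > h]
    hi <- if (length(idxR) == 0) h else {
      to <- if (length(higherR) == 0) n else min(higherR)
      min(sm[p:to])
    }
    h - max(lo, hi)
  }, numeric(1))
  keep <- prom >= minProminence
  res <- data.frame(extension_A = extension[peaks][keep],
                    force_pN = sm[peaks][keep],
                    prominence_pN = prom[keep])
  res <- res[order(-res$prominence_pN), , drop = FALSE]
  rownames(res) <- NULL
  res
}
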