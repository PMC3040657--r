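## Fixtures are built in code: small models, random clouds, rotations.

## Minimal model from positions (n x 3), optional extras per atom.
posModel <- function(xyz, chain = "A", name = "CA", radius = 1.8,
                     role = "none", donorLink = NA_integer_,
                     hydrophobic = FALSE, resid = NULL) {
  n <- nrow(xyz)
  atomicModel(data.frame(
    serial = seq_len(n), name = rep_len(name, n),
    resid = if (is.null(resid)) seq_len(n) else resid,
    chain = rep_len(chain, n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    radius = rep_len(radius, n), role = rep_len(role, n),
    donorLink = rep(donorLink, length.out = n),
    hydrophobic = rep_len(hydrophobic, n)))
}

randomCloud <- function(n, seed, sd = 5) {
  set.seed(seed)
  matrix(rnorm(3 * n, sd = sd), n, 3)
}

## Rotation matrix from a unit quaternion built from axis + angle (deg).
rotationMatrix <- function(axis, angleDeg) {
  axis <- axis / sqrt(sum(axis^2))
  a <- angleDeg * pi / 180
  q <- c(cos(a / 2), sin(a / 2) * axis)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

randomAxis <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

## Chain of CA atoms, one per residue over given inclusive ranges.
residueChainModel <- function(chains) {
  rows <- list()
  serial <- 0L
  for (ch in names(chains)) {
    for (resid in chains[[ch]]) {
      serial <- serial + 1L
      rows[[serial]] <- data.frame(
        serial = serial, name = "CA", resid = resid, chain = ch,
        x = serial * 0.5, y = 0, z = 0)
    }
  }
  atomicModel(do.call(rbind, rows))
}

## Analytic accessible area of two intersecting spheres of radius r1, r2
## at centre distance d with probe p: expanded spheres minus buried caps.
twoSphereSasa <- function(r1, r2, d, probe) {
  R1 <- r1 + probe; R2 <- r2 + probe
  if (d >= R1 + R2) return(4 * pi * (R1^2 + R2^2))
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  (4 * pi * R1^2 - 2 * pi * R1 * h1) + (4 * pi * R2^2 - 2 * pi * R2 * h2)
}

## A built bent model shared across tests (deterministic; cached per run).
sharedBentModel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- buildBentModel()
    cache
  }
})

## Static trajectory: identical frames of a model.
staticTrajectory <- function(model, nframes = 3, dt = 1) {
  xyz <- coords(model)
  trajectory(seq(0, by = dt, length.out = nframes),
             replicate(nframes, xyz, simplify = FALSE), model)
}
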