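#' Default configuration of the bent-model builder
#'
#' Geometry and mechanics defaults of the synthetic bent two-chain molecule.
#' Lengths in A, stiffnesses in pN/A (bonds/contacts) and pN*A/rad^2
#' (hinges), well depths in pN*A.
#'
#' @return named list of builder parameters; see [buildBentModel()].
#' @export
bentModelConfig <- function() {
  list(
    beadsPerDomain = 12L,
    headTailDistance = 45,
    beadRadius = 1.8,
    shellRadius = 2.2,
    kIntra = 60,          # all-pair springs inside a domain (rigid-ish body)
    kBackbone = 150,      # inter-domain junction springs
    kBundle = 4,          # leg-bundling springs calf2 <-> betaTD
    kLegCoupling = 30,    # inter-leg springs calf2 <-> EGF4 (knee slaving)
    kDonorH = 200,        # stiff donor-hydrogen attachment
    kneeK = 300,          # outer knee stiffness (wide, soft restoring well)
    kneeCutoffAlpha = 70, # deg; torque-free once the alpha knee opens past it
    kneeCutoffBeta = 60,  # deg; same for the beta knee
    kneeKStiff = 1500,    # inner knee stiffness (narrow well: low wobble)
    kneeCutoffStiff = 10, # deg; width of the stiff inner well
    jointK = 150,         # shape-holding hinge at non-knee junctions
    jointCutoff = 60,     # deg
    kSegment = 25,        # all-pair springs rigidifying each segment
    kTorsion = 700,       # dihedral restraint about articulation axes
    kPin = 300,           # knee axle pin-bead bonds (coincident pairs)
    pinOffset = 3,        # half-width of the knee axle, A
    nPolar = 4L,          # hybrid/betaTD hydrogen-bonded contacts
    polarR0 = 3.0, polarRBreak = 4.5, polarDepth = 90,
    nHydrophobic = 2L,    # hybrid/EGF4 nonpolar cluster contacts
    hydroR0 = 4.0, hydroRBreak = 6.0, hydroDepth = 110,
    lockR0 = 3.0, lockRBreak = 6.0, lockDepth = 100,
    lockArm = 10,         # radius of the knee-lock bead pair from the axle
    lockAngleAlpha = 95,  # deg opening at which the genu-ion lock engages
    lockAngleBeta = 100,  # deg opening at which the beta-knee lock engages
    minDomainSeparation = 3)
}

## Residue numbers for one domain: evenly spaced through its real ranges so
## the shipped DomainMap resolves the synthetic beads.
.domainResidues <- function(map, chain, domain, n) {
  r <- map@ranges
  r <- r[r$chain == chain & r$domain == domain, , drop = FALSE]
  all <- unlist(lapply(seq_len(nrow(r)),
                       function(i) seq.int(r$first[i], r$last[i])))
  all[unique(round(seq(1, length(all), length.out = n)))][seq_len(n)]
}

## Beads of a generic rod/blob domain: centre bead "CA" plus a helical
## shell of "CB" beads of lateral radius rs along the axis (length L).
.rodBeads <- function(center, axis, L, nShell, rs) {
  axis <- axis / sqrt(sum(axis^2))
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  s <- if (nShell > 1) seq(-L / 2, L / 2, length.out = nShell) else 0
  golden <- pi * (3 - sqrt(5))
  out <- matrix(0, nShell + 1, 3)
  out[1, ] <- center
  for (i in seq_len(nShell)) {
    ang <- golden * i
    out[i + 1, ] <- center + s[i] * axis +
      rs * (cos(ang) * e1 + sin(ang) * e2)
  }
  out
}

#' Build the bent two-chain coarse-grained model
#'
#' Constructs the synthetic bent ectodomain: chain A (alpha analog) with
#' beta-propeller, thigh, calf-1 and calf-2; chain B (beta analog) with PSI,
#' hybrid, betaA, EGF1-4 and betaTD; every domain a rigid-ish bead cluster
#' (default 12 beads, giving 144 atoms). The hybrid domain is an elongated
#' rod whose lower face carries four hydrogen-bond donor/hydrogen bead pairs
#' facing betaTD acceptor beads (the polar interface) and two hydrophobic
#' beads facing an EGF4 nonpolar pair (the hydrophobic interface); both
#' interface groups are breakable contacts, so their rupture produces the
#' dominant force peak under pulling. The two knees (thigh/calf-1 and
#' EGF1/EGF2) are pin-bead axles carrying truncated-harmonic hinge wells
#' with bent equilibrium: partially extended structures are pulled back
#' toward the bent state, fully opened knees are outside the restoring
#' range, and lock contacts (including the thigh-aspartate/genu-ion analog
#' pair) engage only in the open-knee geometry and stabilize the extended
#' conformation. The legs run parallel and are coupled by packing springs,
#' so the knees open cooperatively. The bent head-tail (betaA COM to
#' betaTD COM) distance is set by `headTailDistance`.
#'
#' @param config list from [bentModelConfig()]; entries may be overridden.
#' @return list with `model` ([AtomicModel-class]), `topology`
#'   ([CgTopology-class]) and `map` ([DomainMap-class], the shipped map plus
#'   synthetic pulling composites `pull_head`, `constraint_tail`,
#'   `salt_bridge_A`, `salt_bridge_B`, `hydrophobic_A`, `hydrophobic_B`,
#'   `genu_A`, `genu_B`).
#' @export
buildBentModel <- function(config = bentModelConfig()) {
  cf <- bentModelConfig()
  cf[names(config)] <- config
  bpd <- as.integer(cf$beadsPerDomain)
  if (bpd < 12L) stop("buildBentModel: beadsPerDomain must be >= 12")
  map <- defaultDomainMap()

  D <- cf$headTailDistance
  if (D < 25) stop("buildBentModel: headTailDistance must be >= 25 A")
  zA <- 21 + sqrt(D^2 - 41)        # betaA centre height for the target D

  ## domain centres of the bent conformation. The beta leg is a hairpin of
  ## two straight segments joined at the EGF1/EGF2 knee: hybrid bottom ->
  ## PSI -> EGF1 -> EGF2 (down), then EGF2 -> EGF3 -> EGF4 -> betaTD back
  ## up along the hybrid's lower face. Straightening the knee therefore
  ## yields a straight leg with every other junction at its built angle.
  hybridTop <- zA - 8
  segS <- c(3, 4, 22)         # down-segment start, below the hybrid bottom
  segE <- c(8, 4, 7)          # the beta knee (EGF2 centre)
  segT <- c(-4, -4, 24)       # return-segment end (betaTD centre)
  ## the alpha leg parallels the beta leg at a +5 A y-offset: its knee sits
  ## beside the beta knee (same x, z) and its lower arm runs along the same
  ## return direction, so the two knees bend about parallel axes and the
  ## inter-leg packing springs stay at rest length under concurrent opening
  kneeApt <- c(segE[1], segE[2] + 5, segE[3])
  u2 <- (segT - segE) / sqrt(sum((segT - segE)^2))
  spanRet <- sqrt(sum((segT - segE)^2))
  propCtr <- c(0, 9, zA)
  ctr <- list(
    betaA = c(0, 0, zA),
    hybrid = c(0, 0, (26 + hybridTop) / 2),
    PSI = segS + 0.32 * (segE - segS),
    EGF1 = segS + 0.72 * (segE - segS),
    EGF2 = segE,
    EGF3 = segE + 0.40 * (segT - segE),
    EGF4 = segE + 0.75 * (segT - segE),
    betaTD = segT,
    propeller = propCtr,
    thigh = kneeApt + 0.52 * (propCtr - c(0, 0, 6) - kneeApt),
    calf1 = kneeApt + 0.40 * spanRet * u2,
    calf2 = kneeApt + 0.75 * spanRet * u2)
  hybridLen <- hybridTop - 26
  thighLen <- 0.8 * sqrt(sum((propCtr - kneeApt)^2))
  len <- c(betaA = 8, hybrid = hybridLen, PSI = 5, EGF1 = 8, EGF2 = 8,
           EGF3 = 8, EGF4 = 8, betaTD = 8, propeller = 8, thigh = thighLen,
           calf1 = 8, calf2 = 8)
  chainOf <- c(betaA = "B", hybrid = "B", PSI = "B", EGF1 = "B",
               EGF2 = "B", EGF3 = "B", EGF4 = "B", betaTD = "B",
               propeller = "A", thigh = "A", calf1 = "A", calf2 = "A")
  chainPath <- list(
    A = c("propeller", "thigh", "calf1", "calf2"),
    B = c("betaA", "hybrid", "PSI", "EGF1", "EGF2", "EGF3", "EGF4",
          "betaTD"))

  ## pairwise centre separation guard
  cm <- do.call(rbind, ctr)
  dm <- as.matrix(dist(cm))
  diag(dm) <- Inf
  if (min(dm) < cf$minDomainSeparation)
    stop(sprintf(paste0("buildBentModel: domains '%s' and '%s' overlap ",
                        "(centre distance %.2f A)"),
                 rownames(cm)[which(dm == min(dm), arr.ind = TRUE)[1, 1]],
                 rownames(cm)[which(dm == min(dm), arr.ind = TRUE)[1, 2]],
                 min(dm)))

  axisOf <- function(dn) {
    for (ch in names(chainPath)) {
      p <- chainPath[[ch]]
      i <- match(dn, p)
      if (is.na(i)) next
      a <- if (i == 1) ctr[[p[2]]] - ctr[[p[1]]]
           else if (i == length(p)) ctr[[p[i]]] - ctr[[p[i - 1]]]
           else ctr[[p[i + 1]]] - ctr[[p[i - 1]]]
      return(a / sqrt(sum(a^2)))
    }
    c(0, 0, 1)
  }

  unitTo <- function(from, to) {
    v <- to - from
    v / sqrt(sum(v^2))
  }

  ## assemble beads domain by domain
  rows <- list()
  serial <- 0L
  addBead <- function(dn, name, pos, role = "none", donorLink = NA_integer_,
                      hydrophobic = FALSE) {
    serial <<- serial + 1L
    rows[[serial]] <<- data.frame(
      serial = serial, name = name, resid = 0L, chain = chainOf[[dn]],
      x = pos[1], y = pos[2], z = pos[3], radius = cf$beadRadius,
      role = role, donorLink = donorLink, hydrophobic = hydrophobic,
      domain = dn, stringsAsFactors = FALSE)
    serial
  }

  special <- list()  # named bead serials for contacts/metrics
  ## shell bead counts so every domain holds exactly bpd beads
  nHybridFill <- bpd - 2L - 2L * cf$nPolar - cf$nHydrophobic
  if (nHybridFill < 0)
    stop("buildBentModel: too many interface beads for beadsPerDomain")
  nBtdShell <- bpd - 1L - cf$nPolar
  nEgf4Shell <- bpd - 1L - cf$nHydrophobic
  nExtra <- bpd - 12L
  ## knee axles: two coincident pin-bead pairs per knee on the axis
  ## perpendicular to the bending plane; each domain owns one copy, the
  ## copies are tied together by zero-length bonds, leaving pure bending
  ## about the axle as the only soft articulation
  kneeJA <- kneeApt
  kneeHA <- c(0, 1, 0)        # parallel axles: both knees bend about +/-y
  kneeJB <- (ctr$EGF1 + ctr$EGF2) / 2
  kneeHB <- c(0, 1, 0)
  ## extension-stabilizing lock pairs: a bead on the proximal arm and one
  ## on the distal arm placed (by rotation about the knee axle) so that
  ## they meet only once the knee has opened by the lock angle -- the
  ## synthetic counterpart of the coordination that forms between the
  ## thigh aspartate and the alpha-genu metal ion upon extension
  rodrigues <- function(v, h, phi)
    v * cos(phi) + c(h[2] * v[3] - h[3] * v[2], h[3] * v[1] - h[1] * v[3],
                     h[1] * v[2] - h[2] * v[1]) * sin(phi) +
      h * sum(h * v) * (1 - cos(phi))
  perpUnit <- function(v, h) {
    w <- v - sum(v * h) * h
    w / sqrt(sum(w^2))
  }
  openSign <- function(J, h, prox, distFar) {
    a0 <- sum(perpUnit(prox - J, h) * perpUnit(distFar - J, h))
    ap <- sum(perpUnit(prox - J, h) *
              perpUnit(rodrigues(distFar - J, h, 0.1), h))
    if (acos(max(-1, min(1, ap))) > acos(max(-1, min(1, a0)))) 1 else -1
  }
  lockPair <- function(J, h, prox, distFar, lockAngle) {
    sgn <- openSign(J, h, prox, distFar)
    nh <- perpUnit(prox - J, h)
    r <- cf$lockArm
    p1 <- J + r * nh + 1.5 * h
    p2 <- J + rodrigues(r * nh - 1.5 * h, h, -sgn * lockAngle * pi / 180)
    list(p1 = p1, p2 = p2)
  }
  lockA <- lockPair(kneeJA, kneeHA, ctr$thigh, ctr$calf2, cf$lockAngleAlpha)
  lockB <- lockPair(kneeJB, kneeHB, ctr$EGF1, ctr$EGF3, cf$lockAngleBeta)
  for (dn in c(chainPath$A, chainPath$B)) {
    cen <- ctr[[dn]]; ax <- axisOf(dn)
    if (dn == "hybrid") {
      addBead(dn, "CA", cen)
      addBead(dn, "CB", cen + (hybridLen / 2) * c(0, 0, 1))  # top, bonds betaA
      uPolar <- unitTo(c(0, 0, 0), c(ctr$betaTD[1], ctr$betaTD[2], 0))
      uHydro <- unitTo(c(0, 0, 0), c(ctr$EGF4[1], ctr$EGF4[2], 0))
      donorZ <- seq(27.5, 32, length.out = cf$nPolar)
      for (i in seq_len(cf$nPolar)) {
        dpos <- c(0, 0, donorZ[i]) + cf$shellRadius * uPolar
        apos <- dpos + cf$polarR0 * unitTo(dpos, ctr$betaTD)
        ds <- addBead(dn, "ND", dpos, role = "donor")
        hs <- addBead(dn, "HD", dpos + 1.0 * unitTo(dpos, apos),
                      role = "hydrogen", donorLink = ds)
        special[[paste0("donor", i)]] <- ds
        special[[paste0("hydrogen", i)]] <- hs
        special[[paste0("acceptorPos", i)]] <- apos
      }
      hydZ <- c(28, 31)
      for (i in seq_len(cf$nHydrophobic)) {
        hpos <- c(0, 0, hydZ[i]) + cf$shellRadius * uHydro
        hb <- addBead(dn, "CH", hpos, hydrophobic = TRUE)
        special[[paste0("hybHyd", i)]] <- hb
        special[[paste0("egfHydPos", i)]] <-
          hpos + cf$hydroR0 * unitTo(hpos, ctr$EGF4)
      }
      if (nHybridFill > 0) {
        fill <- .rodBeads(cen, ax, hybridLen * 0.6, nHybridFill,
                          cf$shellRadius)
        for (p in seq_len(nHybridFill)) addBead(dn, "CB", fill[p + 1, ])
      }
    } else if (dn == "betaTD") {
      shell <- .rodBeads(cen, ax, len[[dn]], nBtdShell, cf$shellRadius)
      addBead(dn, "CA", shell[1, ])
      for (i in seq_len(nBtdShell)) addBead(dn, "CB", shell[i + 1, ])
      for (i in seq_len(cf$nPolar))
        special[[paste0("acceptor", i)]] <-
          addBead(dn, "OA", special[[paste0("acceptorPos", i)]],
                  role = "acceptor")
    } else if (dn == "EGF4") {
      shell <- .rodBeads(cen, ax, len[[dn]], nEgf4Shell, cf$shellRadius)
      addBead(dn, "CA", shell[1, ])
      for (i in seq_len(nEgf4Shell)) addBead(dn, "CB", shell[i + 1, ])
      for (i in seq_len(cf$nHydrophobic))
        special[[paste0("egfHyd", i)]] <-
          addBead(dn, "CH", special[[paste0("egfHydPos", i)]],
                  hydrophobic = TRUE)
    } else if (dn == "thigh") {
      shell <- .rodBeads(cen, ax, len[[dn]], 8L + nExtra, cf$shellRadius)
      addBead(dn, "CA", shell[1, ])
      for (i in seq_len(8L + nExtra)) addBead(dn, "CB", shell[i + 1, ])
      ## Asp457 analog: thigh sidechain bead of the genu-ion lock
      special$aspA <- addBead(dn, "OD", lockA$p1, role = "acceptor")
      special$pinA1thigh <- addBead(dn, "PN", kneeJA + cf$pinOffset * kneeHA)
      special$pinA2thigh <- addBead(dn, "PN", kneeJA - cf$pinOffset * kneeHA)
    } else if (dn == "calf1") {
      shell <- .rodBeads(cen, ax, len[[dn]], 8L + nExtra, cf$shellRadius)
      addBead(dn, "CA", shell[1, ])
      for (i in seq_len(8L + nExtra)) addBead(dn, "CB", shell[i + 1, ])
      ## alpha-genu metal ion analog: meets the thigh aspartate bead once
      ## the alpha knee has opened by the lock angle
      special$genuIon <- addBead(dn, "IO", lockA$p2)
      special$pinA1calf <- addBead(dn, "PN", kneeJA + cf$pinOffset * kneeHA)
      special$pinA2calf <- addBead(dn, "PN", kneeJA - cf$pinOffset * kneeHA)
    } else if (dn == "EGF1") {
      shell <- .rodBeads(cen, ax, len[[dn]], 8L + nExtra, cf$shellRadius)
      addBead(dn, "CA", shell[1, ])
      for (i in seq_len(8L + nExtra)) addBead(dn, "CB", shell[i + 1, ])
      special$pinB1egf1 <- addBead(dn, "PN", kneeJB + cf$pinOffset * kneeHB)
      special$pinB2egf1 <- addBead(dn, "PN", kneeJB - cf$pinOffset * kneeHB)
      special$lockBegf1 <- addBead(dn, "LK", lockB$p1)
    } else if (dn == "EGF2") {
      shell <- .rodBeads(cen, ax, len[[dn]], 9L + nExtra, cf$shellRadius)
      addBead(dn, "CA", shell[1, ])
      for (i in seq_len(9L + nExtra)) addBead(dn, "CB", shell[i + 1, ])
      special$pinB1egf2 <- addBead(dn, "PN", kneeJB + cf$pinOffset * kneeHB)
      special$pinB2egf2 <- addBead(dn, "PN", kneeJB - cf$pinOffset * kneeHB)
    } else if (dn == "EGF3") {
      shell <- .rodBeads(cen, ax, len[[dn]], 10L + nExtra, cf$shellRadius)
      addBead(dn, "CA", shell[1, ])
      for (i in seq_len(10L + nExtra)) addBead(dn, "CB", shell[i + 1, ])
      special$lockBegf3 <- addBead(dn, "LK", lockB$p2)
    } else {
      shell <- .rodBeads(cen, ax, len[[dn]], 11L + nExtra, cf$shellRadius)
      addBead(dn, "CA", shell[1, ])
      for (i in seq_len(11L + nExtra)) addBead(dn, "CB", shell[i + 1, ])
    }
  }
  atoms <- do.call(rbind, rows)

  ## calibrate the head-tail COM distance to the configured value by
  ## shifting the head dimer (betaA + propeller) along z
  headSel <- atoms$domain == "betaA"
  tailSel <- atoms$domain == "betaTD"
  dimer <- atoms$domain %in% c("betaA", "propeller")
  comOf <- function(sel) c(mean(atoms$x[sel]), mean(atoms$y[sel]),
                           mean(atoms$z[sel]))
  hc <- comOf(headSel); tc <- comOf(tailSel)
  lat2 <- (hc[1] - tc[1])^2 + (hc[2] - tc[2])^2
  if (lat2 >= D^2) stop("buildBentModel: headTailDistance unreachable")
  atoms$z[dimer] <- atoms$z[dimer] + (tc[3] + sqrt(D^2 - lat2) - hc[3])

  ## residue numbers per bead, inside the shipped domain ranges
  for (dn in unique(atoms$domain)) {
    sel <- which(atoms$domain == dn)
    atoms$resid[sel] <- .domainResidues(map, chainOf[[dn]], dn, length(sel))
  }
  domainOfSerial <- atoms$domain
  model <- atomicModel(atoms[, setdiff(names(atoms), "domain")])
  xyz <- coords(model)

  ## ---- topology ----
  bonds <- list()
  addBond <- function(i, j, k, r0 = NULL) {
    if (is.null(r0)) r0 <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    bonds[[length(bonds) + 1L]] <<- data.frame(i = i, j = j, r0 = r0, k = k)
  }
  ## rigid-ish bodies: all bead pairs within a domain
  for (dn in unique(domainOfSerial)) {
    sel <- which(domainOfSerial == dn)
    for (a in seq_along(sel))
      for (b in seq_len(a - 1L))
        addBond(sel[a], sel[b], cf$kIntra)
  }
  ## stiff donor-hydrogen attachments
  for (i in seq_len(cf$nPolar))
    addBond(special[[paste0("donor", i)]],
            special[[paste0("hydrogen", i)]], cf$kDonorH)
  ## backbone junctions: n closest bead pairs between consecutive domains.
  ## Knee junctions get 2 attachment bonds (a bendable hinge with torsion
  ## restrained); all other junctions get 3 (no relative rotation), so
  ## hinge-angle analysis sees bending at the knees, not free torsion.
  closestPairs <- function(d1, d2, n) {
    s1 <- which(domainOfSerial == d1); s2 <- which(domainOfSerial == d2)
    dd <- outer(seq_along(s1), seq_along(s2), Vectorize(function(a, b)
      sum((xyz[s1[a], ] - xyz[s2[b], ])^2)))
    o <- order(dd)[seq_len(min(n, length(dd)))]
    cbind(s1[(o - 1) %% length(s1) + 1], s2[(o - 1) %/% length(s1) + 1])
  }
  junctionBonds <- function(d1, d2, n, k) {
    pr <- closestPairs(d1, d2, n)
    for (r in seq_len(nrow(pr))) addBond(pr[r, 1], pr[r, 2], k)
  }
  ## knee axles: tie the coincident pin-bead pairs with zero-length bonds
  caOfDomain <- function(dn) which(domainOfSerial == dn)[1]
  addBond(special$pinA1thigh, special$pinA1calf, cf$kPin, r0 = 0)
  addBond(special$pinA2thigh, special$pinA2calf, cf$kPin, r0 = 0)
  addBond(special$pinB1egf1, special$pinB1egf2, cf$kPin, r0 = 0)
  addBond(special$pinB2egf1, special$pinB2egf2, cf$kPin, r0 = 0)
  for (ch in names(chainPath)) {
    p <- chainPath[[ch]]
    for (i in seq_len(length(p) - 1L)) {
      if (paste(p[i], p[i + 1], sep = ":") %in%
          c("thigh:calf1", "EGF1:EGF2")) next
      junctionBonds(p[i], p[i + 1], 3L, cf$kBackbone)
    }
  }
  ## head dimer interface, leg bundle, and inter-leg packing springs that
  ## couple the two knees (the legs of the real molecule pack against each
  ## other, which is what makes the two knees open cooperatively)
  junctionBonds("propeller", "betaA", 3L, cf$kBackbone)
  junctionBonds("calf2", "betaTD", 3L, cf$kBundle)
  junctionBonds("calf2", "EGF4", 3L, cf$kLegCoupling)
  junctionBonds("calf1", "EGF3", 2L, cf$kLegCoupling)
  ## rigid segments: weak all-pair springs between domains that move as one
  ## body. The head dimer and both upper legs form a single upper body (in
  ## the bent molecule the headpiece and upper legs are packed together),
  ## so the two knees are the only soft articulations and open against the
  ## same rigid frame; the lower legs are separate arms coupled by the
  ## inter-leg packing springs.
  segments <- list(c("betaA", "propeller", "thigh", "hybrid", "PSI", "EGF1"),
                   c("calf1", "calf2"),
                   c("EGF2", "EGF3", "EGF4"))
  segmentK <- c(8, cf$kSegment, cf$kSegment)
  for (si in seq_along(segments)) {
    seg <- segments[[si]]
    for (a in seq_along(seg))
      for (b in seq_len(a - 1L)) {
        s1 <- which(domainOfSerial == seg[a])
        s2 <- which(domainOfSerial == seg[b])
        for (i1 in s1) for (i2 in s2) addBond(i1, i2, segmentK[si])
      }
  }
  bonds <- do.call(rbind, bonds)

  ## hinges: angle at domain-centre triplets along each chain. The two
  ## knees get stiff truncated wells; other junctions get shape-holders.
  caOf <- function(dn) which(domainOfSerial == dn)[1]
  builtAngle <- function(a, b, c) {
    u <- xyz[a, ] - xyz[b, ]; w <- xyz[c, ] - xyz[b, ]
    acos(max(-1, min(1, sum(u * w) / sqrt(sum(u^2) * sum(w^2))))) * 180 / pi
  }
  hinges <- list()
  addHinge <- function(d1, d2, d3, k, cutoff) {
    a <- caOf(d1); b <- caOf(d2); c <- caOf(d3)
    hinges[[length(hinges) + 1L]] <<- data.frame(
      a = a, b = b, c = c, theta0 = builtAngle(a, b, c), k = k,
      cutoff = cutoff)
  }
  ## the two knees: truncated bent wells (bistability); other junctions:
  ## shape holders active at any deviation, so the leg cannot crumple and
  ## the straightened leg is strain-free at every non-knee joint
  addHinge("thigh", "calf1", "calf2", cf$kneeK, cf$kneeCutoffAlpha)
  addHinge("thigh", "calf1", "calf2", cf$kneeKStiff, cf$kneeCutoffStiff)
  ## longer arms (PSI/EGF4) keep the angle gradient well-conditioned
  addHinge("PSI", "EGF2", "EGF4", cf$kneeK, cf$kneeCutoffBeta)
  addHinge("PSI", "EGF2", "EGF4", cf$kneeKStiff, cf$kneeCutoffStiff)
  ## keep the flexibly mounted tail domain aligned with the return arm
  addHinge("EGF3", "EGF4", "betaTD", cf$jointK, cf$jointCutoff)
  hinges <- do.call(rbind, hinges)

  ## breakable interface contacts
  contacts <- list()
  addContact <- function(i, j, r0, rbreak, depth, class) {
    contacts[[length(contacts) + 1L]] <<- data.frame(
      i = i, j = j, r0 = r0, k = 2 * depth / (rbreak - r0)^2,
      rbreak = rbreak, depth = depth, class = class)
  }
  for (i in seq_len(cf$nPolar))
    addContact(special[[paste0("donor", i)]],
               special[[paste0("acceptor", i)]],
               cf$polarR0, cf$polarRBreak, cf$polarDepth, "polar")
  for (i in seq_len(cf$nHydrophobic))
    addContact(special[[paste0("hybHyd", i)]],
               special[[paste0("egfHyd", i)]],
               cf$hydroR0, cf$hydroRBreak, cf$hydroDepth, "hydrophobic")
  addContact(special$aspA, special$genuIon,
             cf$lockR0, cf$lockRBreak, cf$lockDepth, "polar")
  addContact(special$lockBegf1, special$lockBegf3,
             cf$lockR0, cf$lockRBreak, cf$lockDepth, "polar")
  contacts <- do.call(rbind, contacts)

  ## torsional restraints about the articulation axes: without them the
  ## rod-shaped bodies spin freely about their long axes and hinge-angle
  ## analysis reads torsion instead of bending
  builtDihedral <- function(a, b, c, d) {
    b1 <- xyz[b, ] - xyz[a, ]; b2 <- xyz[c, ] - xyz[b, ]
    b3 <- xyz[d, ] - xyz[c, ]
    n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
            b1[1] * b2[2] - b1[2] * b2[1])
    n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
            b2[1] * b3[2] - b2[2] * b3[1])
    m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
            n1[1] * b2[2] - n1[2] * b2[1])
    atan2(sum(m1 * n2) / sqrt(sum(b2^2)), sum(n1 * n2)) * 180 / pi
  }
  dihedrals <- list()
  addDihedral <- function(d1, d2, k) {
    ca1 <- caOfDomain(d1); ca2 <- caOfDomain(d2)
    axis <- xyz[ca2, ] - xyz[ca1, ]
    axis <- axis / sqrt(sum(axis^2))
    lateralBead <- function(dn, ca) {
      sel <- which(domainOfSerial == dn)
      rel <- sweep(xyz[sel, , drop = FALSE], 2, xyz[ca, ])
      lat2 <- rowSums(rel^2) - (rel %*% axis)^2
      sel[which.max(lat2)]
    }
    a <- lateralBead(d1, ca1); d <- lateralBead(d2, ca2)
    dihedrals[[length(dihedrals) + 1L]] <<- data.frame(
      a = a, b = ca1, c = ca2, d = d,
      phi0 = builtDihedral(a, ca1, ca2, d), k = k)
  }
  addDihedral("hybrid", "PSI", cf$kTorsion)
  dihedrals <- do.call(rbind, dihedrals)

  topology <- cgTopology(bonds, hinges, contacts, dihedrals)

  ## synthetic composites on top of the shipped map
  ser <- model@atoms$serial
  map@composites$pull_head <- list(chain = "B", domains = "betaA")
  map@composites$constraint_tail <- list(chain = "B", domains = "betaTD")
  map@composites$salt_bridge_A <-
    list(serials = ser[unlist(special[paste0("donor",
                                             seq_len(cf$nPolar))])[1]])
  map@composites$salt_bridge_B <-
    list(serials = ser[special$acceptor1])
  map@composites$hydrophobic_A <-
    list(serials = ser[unlist(special[paste0("hybHyd",
                                             seq_len(cf$nHydrophobic))])])
  map@composites$hydrophobic_B <-
    list(serials = ser[unlist(special[paste0("egfHyd",
                                             seq_len(cf$nHydrophobic))])])
  map@composites$genu_A <- list(serials = ser[special$aspA])
  map@composites$genu_B <- list(serials = ser[special$genuIon])

  list(model = model, topology = topology, map = map)
}
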