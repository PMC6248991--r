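makeStaticTrajectory <- function(ref, nFrames = 2) {
  n <- nrow(ref$xyz)
  Trajectory(array(rep(ref$xyz, each = nFrames), c(nFrames, n, 3)),
             ref$topology)
}

test_that("ideal helices are assigned H in the interior", {
  ref <- makeBundleReference(1, 20)
  tr <- makeStaticTrajectory(ref, 3)
  ss <- assignSecondaryStructure(tr)
  ## hand application of the i -> i+4 rule to ideal geometry: the 4-turn
  ## holds for donors 1..16, consecutive turns mark residues 2..19
  expect_equal(unname(ss$classes[, 1]),
               c("C", rep("H", 18), "C"))
  ## constant over frames
  expect_identical(ss$classes[, 1], ss$classes[, 2])
  expect_equal(unique(ss$helixCounts$count), 18)
})

test_that("extended chains carry no helix", {
  bb <- HelixDynamics:::buildBackbone(20, phi = 180, psi = 180)
  top <- makeBundleReference(1, 20)$topology
  tr <- Trajectory(array(bb, c(1, nrow(bb), 3)), top)
  ss <- assignSecondaryStructure(tr)
  expect_equal(sum(ss$classes == "H"), 0L)
})

test_that("assignments are invariant under rigid motion and replicas agree", {
  ref <- makeBundleReference(2, 12)
  tr <- makeStaticTrajectory(ref, 2)
  th <- 0.8
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  co2 <- tr@coords
  for (f in 1:2) co2[f, , ] <- tr@coords[f, , ] %*% t(R) +
      matrix(c(7, -3, 11), dim(co2)[2], 3, byrow = TRUE)
  tr2 <- Trajectory(co2, ref$topology)
  expect_identical(assignSecondaryStructure(tr)$classes,
                   assignSecondaryStructure(tr2)$classes)
  ## identical replicas -> zero SD of helix counts
  sm <- helixCountSummary(list(assignSecondaryStructure(tr),
                               assignSecondaryStructure(tr2)))
  expect_equal(sm$sd, rep(0, nrow(sm)))
})

test_that("missing backbone atoms are reported by residue", {
  ref <- makeBundleReference(1, 6, atoms = "calpha")
  tr <- makeStaticTrajectory(ref)
  expect_error(assignSecondaryStructure(tr), "missing backbone")
})

test_that("contact occupancies follow distances and a brute-force oracle", {
  ## two 'residues' of 2 heavy atoms each plus a far spectator
  atoms <- data.frame(
    name = c("CB", "CG", "CB", "CG", "CB"),
    element = "C",
    resno = c(1, 1, 2, 2, 3),
    resid = "ALA", chain = "A",
    segment = c("TM1", "TM1", "TM2", "TM2", "TM3"))
  top <- Topology(atoms)
  nf <- 20
  co <- array(0, c(nf, 5, 3))
  inContact <- seq_len(nf) <= 7           # contact in 7 of 20 frames
  for (f in seq_len(nf)) {
    co[f, 1, ] <- c(0, 0, 0); co[f, 2, ] <- c(1.5, 0, 0)
    gap <- if (inContact[f]) 3.0 else 8.0
    co[f, 3, ] <- c(1.5 + gap, 0, 0); co[f, 4, ] <- c(3 + gap, 0, 0)
    co[f, 5, ] <- c(0, 40, 0)
  }
  tr <- Trajectory(co, top)
  cmap <- contactMap(tr, focalSelection = 1:2, candidateSelection = 3:5,
                     cutoff = 4.5)
  occ <- cmap$occupancy
  expect_equal(occ$occupancy[occ$resno == 2], 0.35)
  expect_equal(occ$occupancy[occ$resno == 3], 0)
  ## brute-force all-pairs distance loop oracle
  manual <- mean(sapply(seq_len(nf), function(f) {
    d <- Inf
    for (a in 1:2) for (b in 3:4)
      d <- min(d, sqrt(sum((co[f, a, ] - co[f, b, ])^2)))
    d <= 4.5
  }))
  expect_equal(occ$occupancy[occ$resno == 2], manual)
  ## occupancy monotone non-decreasing in the cutoff
  occs <- vapply(c(2, 4.5, 9), function(cu)
    contactMap(tr, 1:2, 3:4, cu)$occupancy$occupancy[1], numeric(1))
  expect_true(all(diff(occs) >= 0))
  expect_error(contactMap(tr, 1:2, 3:4, cutoff = -1), "positive")
})

test_that("hydrogen bonds obey the distance and angle gates", {
  ## donor hydroxyl O-H pointing at an acceptor carbonyl O
  mkTop <- function() Topology(data.frame(
    name = c("OG", "HG", "O"), element = c("O", "H", "O"),
    resno = c(1, 1, 2), resid = c("SER", "SER", "ALA"), chain = "A",
    segment = c("TM1", "TM1", "TM2")))
  geom <- function(angleDeg, dDA) {
    ## donor at origin, H at (1,0,0); acceptor at distance dDA from donor,
    ## placed so the D-H-A angle equals angleDeg
    th <- angleDeg * pi / 180
    dirHA <- c(-cos(th), sin(th), 0)   # angle between H->D (= -x) and H->A
    f <- function(s) sqrt(sum((c(1, 0, 0) + s * dirHA)^2)) - dDA
    s <- uniroot(f, c(0.1, 10))$root
    rbind(c(0, 0, 0), c(1, 0, 0), c(1, 0, 0) + s * dirHA)
  }
  trOf <- function(xyz) Trajectory(array(xyz, c(1, 3, 3)), mkTop())
  good <- hbonds(trOf(geom(170, 2.8)), 1:2, 3)
  expect_equal(nrow(good), 1L)
  expect_equal(good$occupancy, 1)
  bad <- suppressWarnings(hbonds(trOf(geom(90, 2.8)), 1:2, 3))
  expect_equal(nrow(bad), 0L)
  far <- suppressWarnings(hbonds(trOf(geom(170, 4.2)), 1:2, 3))
  expect_equal(nrow(far), 0L)
  expect_warning(hbonds(trOf(geom(170, 2.8)), integer(0), 3), "no donor")
})

test_that("equivalent carboxylate oxygens accumulate independent occupancies", {
  top <- Topology(data.frame(
    name = c("OG", "HG", "OD1", "OD2"), element = c("O", "H", "O", "O"),
    resno = c(1, 1, 2, 2), resid = c("SER", "SER", "ASP", "ASP"),
    chain = "A", segment = c("TM1", "TM1", "TM2", "TM2")))
  nf <- 4
  co <- array(0, c(nf, 4, 3))
  for (f in seq_len(nf)) {
    co[f, 1, ] <- c(0, 0, 0); co[f, 2, ] <- c(1, 0, 0)
    ## the H-bond alternates between the two oxygens frame by frame
    near <- c(2.8, 0, 0); off <- c(2.8, 3.5, 0)
    if (f %% 2 == 1) { co[f, 3, ] <- near; co[f, 4, ] <- off }
    else { co[f, 3, ] <- off; co[f, 4, ] <- near }
  }
  hb <- hbonds(Trajectory(co, top), 1:2, 3:4)
  expect_equal(nrow(hb), 2L)
  expect_equal(sort(hb$acceptorName), c("OD1", "OD2"))
  expect_equal(hb$occupancy, c(0.5, 0.5))
})

test_that("density profiles conserve particle number and detect topology", {
  mb <- makeMembraneBox(membraneBoxSpec(nFrames = 40, seed = 31))
  g <- list(water = atomSelect(mb$topology, segment = "WATER"),
            phosphate = atomSelect(mb$topology, name = "P"),
            methyl = atomSelect(mb$topology, name = "CM"))
  prof <- densityProfile(mb$trajectory, g)
  vol <- prof@binWidth * prof@area
  for (grp in names(g))
    expect_equal(sum(prof@density[, grp]) * vol, length(g[[grp]]),
                 tolerance = 1e-9)
  expect_true(all(prof@density >= 0))
  ## no water inside the core slabs by construction
  hc <- hydrationCount(prof, c(-10, 10))
  expect_equal(hc$count, 0)
  ## full z-range recovers the total water count
  expect_equal(hydrationCount(prof, c(-60, 60))$count, 2000, tolerance = 1e-9)
  tp <- detectBilayerTopology(prof)
  expect_lt(max(abs(tp$core - c(-10, 10))), 1 + 1e-9)
  expect_lt(max(abs(tp$interfaces$upper - c(15, 25))), 1 + 1e-9)
  expect_lt(max(abs(tp$interfaces$lower - c(-25, -15))), 1 + 1e-9)
  ## doubling all counts leaves the detected intervals unchanged
  mb2 <- makeMembraneBox(membraneBoxSpec(nWater = 4000, nPhosphate = 400,
                                         nMethyl = 800, nFrames = 40,
                                         seed = 31))
  prof2 <- densityProfile(mb2$trajectory, list(
    water = atomSelect(mb2$topology, segment = "WATER"),
    phosphate = atomSelect(mb2$topology, name = "P"),
    methyl = atomSelect(mb2$topology, name = "CM")))
  tp2 <- detectBilayerTopology(prof2)
  expect_lt(max(abs(tp2$core - tp$core)), 1 + 1e-9)
  expect_error(hydrationCount(prof, c(0, 0)), "non-empty")
})

test_that("planted core waters are recovered by integration", {
  mb <- makeMembraneBox(membraneBoxSpec(
    nWater = 50, nPhosphate = 0, nMethyl = 0,
    waterSlabs = rbind(c(-10, 10)), nFrames = 1, seed = 12))
  prof <- densityProfile(mb$trajectory,
                         list(water = atomSelect(mb$topology,
                                                 segment = "WATER")))
  expect_equal(hydrationCount(prof, c(-10, 10))$count, 50, tolerance = 1e-9)
  ## half interval: exact count of atoms planted at z in [0, 10)
  z <- mb$trajectory@coords[1, , 3]
  expect_equal(hydrationCount(prof, c(0, 10))$count, sum(z >= 0 & z < 10),
               tolerance = 1e-9)
})

test_that("uniform boxes give flat profiles within sampling noise", {
  spec <- membraneBoxSpec(box = c(40, 40, 40), nWater = 8000, nPhosphate = 0,
                          nMethyl = 0, waterSlabs = rbind(c(-20, 20)),
                          nFrames = 1, seed = 6)
  mb <- makeMembraneBox(spec)
  prof <- densityProfile(mb$trajectory,
                         list(water = atomSelect(mb$topology,
                                                 segment = "WATER")))
  inner <- abs(prof@z) < 20
  counts <- prof@density[inner, "water"] * prof@binWidth * prof@area
  expected <- 8000 / sum(inner)
  expect_true(all(abs(counts - expected) < 5 * sqrt(expected)))
})

test_that("single-leaflet boxes cannot define a bilayer", {
  mb <- makeMembraneBox(membraneBoxSpec(
    nWater = 100, nPhosphate = 100, nMethyl = 100,
    phosphateSlabs = rbind(c(15, 25)),   # one leaflet only
    nFrames = 5, seed = 3))
  prof <- densityProfile(mb$trajectory, list(
    water = atomSelect(mb$topology, segment = "WATER"),
    phosphate = atomSelect(mb$topology, name = "P"),
    methyl = atomSelect(mb$topology, name = "CM")), origin = 0)
  expect_error(detectBilayerTopology(prof), "two leaflets")
})
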