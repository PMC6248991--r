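test_that("covariance matches a brute-force double loop and its algebra", {
  ref <- makeBundleReference(1, 3, atoms = "calpha")
  co <- array(0, c(5, 3, 3))
  set.seed(6)
  for (f in 1:5) co[f, , ] <- ref$xyz[atomData(ref$topology)$name == "CA", ] +
      matrix(rnorm(9, sd = 0.5), 3, 3)
  co <- array(co, c(5, 3, 3))
  tr <- Trajectory(co, ref$topology)
  m <- covarianceModel(tr, stridePs = 0)
  ## oracle: explicit element-by-element accumulation over fitted frames
  X <- flattenFrames(fitFrames(tr), 1:3)
  expect_equal(m@covariance, bruteForceCovariance(X), tolerance = 1e-10)
  ## trace identity: trace(C) = sum of per-coordinate variances
  expect_equal(sum(diag(m@covariance)),
               sum(apply(X, 2, function(v) mean((v - mean(v))^2))),
               tolerance = 1e-10)
  expect_error(covarianceModel(subsetFrames(tr, 1), stridePs = 0),
               "fewer than 2")
})

test_that("eigenpairs match a dense eigen-solve on small instances", {
  for (seed in 1:4) {
    ref <- makeBundleReference(2, 4, atoms = "calpha")   # 8 atoms
    ens <- sampleEnsemble(ensembleSpec(ref, sigma = seq(0.2, 0.9, length.out = 8),
                                       nFrames = 50, seed = seed))
    m <- covarianceModel(ens$trajectory, stridePs = 0)
    X <- flattenFrames(fitFrames(ens$trajectory), 1:8)
    Cbf <- bruteForceCovariance(X)
    ed <- eigen(Cbf, symmetric = TRUE)
    expect_equal(eigenvalues(m), ed$values, tolerance = 1e-8)
    ## eigenvectors up to sign, on modes separated from their neighbours
    ## (superposition leaves a degenerate near-zero rigid-body subspace)
    ev <- eigenvalues(m)
    gap <- pmin(c(Inf, abs(diff(ev))), c(abs(diff(ev)), Inf))
    sep <- which(gap > 1e-4 * max(ev) & ev > 1e-6 * max(ev))
    dots <- abs(colSums(eigenvectors(m)[, sep, drop = FALSE] *
                          ed$vectors[, sep, drop = FALSE]))
    expect_true(all(abs(dots - 1) < 1e-6))
    expect_equal(sum(eigenvalues(m)), sum(diag(m@covariance)),
                 tolerance = 1e-8)
  }
})

test_that("projections obey orthonormality and reconstruct the frames", {
  ref <- smallBundle()
  ens <- sampleEnsemble(ensembleSpec(ref, sigma = 0.4, nFrames = 60,
                                     seed = 3))
  m <- covarianceModel(ens$trajectory, stridePs = 0)
  n3 <- 3 * nAtoms(ref$topology)
  ## planted mode series: mean + alpha(t) eigvec_1 projects to alpha exactly
  alpha <- seq(-2, 2, length.out = 10)
  V <- matrix(m@vectors[, 1], ncol = 3, byrow = TRUE)
  co <- array(0, c(10, nAtoms(ref$topology), 3))
  for (f in 1:10) co[f, , ] <- m@mean + alpha[f] * V
  trA <- Trajectory(co, ref$topology)
  pA <- projectTrajectory(trA, m, 1, fit = FALSE)
  ## orthonormality: projection recovers alpha exactly
  expect_equal(pA$projection, alpha, tolerance = 1e-10)
  ## distinct components are uncorrelated over the accumulation frames
  p1 <- projectTrajectory(ens$trajectory, m, 1)$projection
  p2 <- projectTrajectory(ens$trajectory, m, 2)$projection
  expect_lt(abs(mean(p1 * p2) - mean(p1) * mean(p2)), 1e-6)
  ## full reconstruction
  P <- vapply(seq_len(n3), function(i)
    projectTrajectory(ens$trajectory, m, i)$projection, numeric(60))
  X <- flattenFrames(fitFrames(ens$trajectory), seq_len(nAtoms(ref$topology)))
  mu <- as.numeric(t(m@mean))
  recon <- sweep(P %*% t(m@vectors), 2, mu, `+`)
  expect_lt(max(abs(recon - X)), 1e-8)
  expect_error(projectTrajectory(ens$trajectory, m, n3 + 1), "rank")
})

test_that("projection equals brute-force dot products on a 2-atom instance", {
  top2 <- Topology(data.frame(name = "CA", element = "C", resno = c(1, 5),
                              resid = "ALA", chain = "A", segment = "TM1"))
  set.seed(8)
  co <- array(rnorm(5 * 2 * 3, sd = 0.3), c(5, 2, 3)) +
    array(rep(rbind(c(0, 0, 0), c(4, 0, 0)), each = 5), c(5, 2, 3))
  tr <- Trajectory(co, top2)
  m <- covarianceModel(tr, stridePs = 0, fit = FALSE)
  p <- projectTrajectory(tr, m, 1, fit = FALSE)$projection
  X <- flattenFrames(tr, 1:2)
  mu <- as.numeric(t(m@mean))
  manual <- as.numeric(sweep(X, 2, mu) %*% m@vectors[, 1])
  expect_equal(p, manual, tolerance = 1e-10)
})

test_that("cosine content has its analytic values and invariances", {
  t <- seq(0, 250, length.out = 2000)
  cosSeries <- data.frame(time = t, projection = cos(pi * t / 250))
  expect_equal(cosineContent(cosSeries), 1, tolerance = 1e-4)
  constSeries <- data.frame(time = t, projection = rep(3.2, 2000))
  expect_lt(cosineContent(constSeries), 1e-10)
  expect_error(cosineContent(data.frame(time = t, projection = 0 * t)),
               "all-zero")
  expect_error(cosineContent(data.frame(time = 1:5, projection = 1:5)),
               "at least 8")
  ## scale and time-affine invariance
  s <- data.frame(time = t, projection = sin(2 * pi * t / 250) + 0.3)
  cc0 <- cosineContent(s)
  expect_equal(cosineContent(transform(s, projection = -7.5 * projection)),
               cc0, tolerance = 1e-12)
  expect_equal(cosineContent(transform(s, time = 40 + 3 * time)), cc0,
               tolerance = 1e-12)
})

test_that("random-walk ensembles are flagged as random diffusion", {
  ref <- smallBundle()
  cc <- vapply(1:12, function(seed) {
    ens <- sampleEnsemble(ensembleSpec(ref, sigma = 0, drift = 0.01,
                                       nFrames = 200, dt = 1, seed = seed))
    m <- covarianceModel(ens$trajectory, stridePs = 0)
    cosineContent(projectTrajectory(ens$trajectory, m, 1))
  }, numeric(1))
  expect_gt(median(cc), 0.7)
})

test_that("motion fields localize on the moving segment and antisymmetrize", {
  ref <- makeBundleReference(7, 6, atoms = "calpha")
  seg <- atomData(ref$topology)$segment
  n <- nAtoms(ref$topology)
  ## the only motion: rigid z-lift of TM6
  lift <- seq(-1.5, 1.5, length.out = 40)
  co <- array(rep(ref$xyz, each = 40), c(40, n, 3))
  for (f in 1:40) co[f, seg == "TM6", 3] <- co[f, seg == "TM6", 3] + lift[f]
  tr <- Trajectory(co, ref$topology)
  ## fit on the static helices so the lift is not absorbed by the fit
  m <- covarianceModel(tr, fitSelection = which(seg != "TM6"), stridePs = 0)
  p <- projectTrajectory(tr, m, 1, fitSelection = which(seg != "TM6"))
  mf <- motionField(m, p)
  normOn <- function(rows) sqrt(sum(mf$field[rows, ]^2))
  expect_gt(normOn(seg == "TM6") / normOn(rep(TRUE, n)), 0.9)
  ## swapped quantiles negate the field exactly
  mf2 <- motionField(m, p, quantiles = c(0.99, 0.01))
  expect_equal(mf2$field, -mf$field, tolerance = 1e-12)
  ## zero-variance ensemble: zero field with a warning
  trz <- Trajectory(array(rep(ref$xyz, each = 5), c(5, n, 3)), ref$topology)
  mz <- covarianceModel(trz, stridePs = 0)
  pz <- projectTrajectory(trz, mz, 1)
  expect_warning(mfz <- motionField(mz, pz), "zero motion")
  expect_equal(max(abs(mfz$field)), 0)
})

test_that("regression planes recover exact and planted group structure", {
  ## exact interpolation
  d <- expand.grid(x = seq(0, 3, by = 0.5), y = seq(0, 3, by = 0.5))
  d$response <- 1 + 2 * d$x - d$y
  pf <- suppressWarnings(fitMotionPlanes(d, groups = NULL))
  expect_equal(unname(pf@coefficients), c(1, 2, -1), tolerance = 1e-8)
  expect_lt(pf@residualSD, 1e-8)
  ## planted 3 A offset between groups, noise SD 0.1
  set.seed(15)
  n <- 40
  base <- data.frame(x = runif(2 * n), y = runif(2 * n),
                     group = rep(c("wild", "mutant"), each = n))
  base$response <- 2 + 0.5 * base$x + 1.5 * base$y +
    ifelse(base$group == "mutant", 3, 0) + rnorm(2 * n, sd = 0.1)
  base$group <- factor(base$group, levels = c("wild", "mutant"))
  pf2 <- fitMotionPlanes(base)
  expect_equal(unname(pf2@coefficients["offset:mutant"]), 3,
               tolerance = 0.1)
  expect_true(pf2@tests$significant[1])
  ## single group: dummy design error
  one <- base[base$group == "wild", ]
  expect_error(fitMotionPlanes(one), "at least 2 groups")
  ## collinear design names the offending column
  coll <- base; coll$y <- coll$x
  expect_error(fitMotionPlanes(coll), "collinear.*y")
})
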