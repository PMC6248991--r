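test_that("DCCM honours its contract on analytic fixtures", {
  ## two atoms displaced identically -> c = 1; anti-phase -> c = -1
  top3 <- Topology(data.frame(name = "CA", element = "C", resno = c(1, 5, 9),
                              resid = "ALA", chain = "A", segment = "TM1"))
  nf <- 12
  co <- array(0, c(nf, 3, 3))
  s <- sin(seq_len(nf))
  base <- rbind(c(0, 0, 0), c(5, 0, 0), c(0, 5, 0))
  for (f in seq_len(nf)) {
    co[f, , ] <- base
    co[f, 1, 1] <- base[1, 1] + s[f]
    co[f, 2, 1] <- base[2, 1] + s[f]      # in phase with atom 1
    co[f, 3, 1] <- base[3, 1] - s[f]      # anti-phase
  }
  tr <- Trajectory(co, top3)
  cm <- dccm(tr, selection = 1:3, stridePs = 0, fit = FALSE)
  expect_identical(diag(cm@c), rep(1, 3))
  expect_equal(cm@c[1, 2], 1, tolerance = 1e-10)
  expect_equal(cm@c[1, 3], -1, tolerance = 1e-10)
  expect_equal(cm@c, t(cm@c))
  ## zero-variance atom is a named error
  coz <- co; coz[, 2, ] <- rep(base[2, ], each = nf)
  expect_error(dccm(Trajectory(coz, top3), selection = 1:3, stridePs = 0,
                    fit = FALSE),
               "zero-variance atom")
})

test_that("DCCM is a statistic, not sample-size dependent", {
  ref <- smallBundle()
  ens <- sampleEnsemble(ensembleSpec(ref, sigma = 0.4, nFrames = 30, seed = 2))
  tr <- ens$trajectory
  cm1 <- dccm(tr, stridePs = 0)
  dup <- Trajectory(tr@coords[rep(1:30, 2), , ], ref$topology,
                    times = seq_len(60))
  cm2 <- dccm(dup, stridePs = 0)
  expect_equal(cm1@c, cm2@c, tolerance = 1e-10)
})

test_that("DCCM contract holds across random ensembles", {
  ref <- makeBundleReference(2, 4, atoms = "calpha")
  for (seed in 1:25) {
    ens <- sampleEnsemble(ensembleSpec(
      ref, sigma = runif(8, 0.1, 1),
      blocks = data.frame(segmentA = "TM1", segmentB = "TM2",
                          rho = runif(1, 0.05, 0.85)),
      nFrames = 40, seed = seed))
    cm <- dccm(ens$trajectory, stridePs = 0)
    expect_identical(diag(cm@c), rep(1, 8))
    expect_equal(cm@c, t(cm@c))
    expect_true(all(cm@c >= -1 & cm@c <= 1))
  }
})

test_that("network construction applies cutoff and sequence separation", {
  ## hand 4x4 matrix: exactly one off-diagonal pair above 0.7
  cmat <- diag(4)
  cmat[1, 3] <- cmat[3, 1] <- 0.75
  cmat[2, 4] <- cmat[4, 2] <- 0.55
  cmat[1, 2] <- cmat[2, 1] <- 0.95   # sequence neighbours (resno 1, 2)
  cm <- new("DCCM", c = cmat, atoms = 1:4, resno = c(1L, 2L, 9L, 14L),
            segment = rep("TM1", 4))
  nw <- buildNetwork(cm, cutoff = 0.7, minSeqSeparation = 2)
  expect_equal(nrow(nw@edges), 1L)
  expect_equal(c(nw@edges$i, nw@edges$j), c(1, 3))
  ## identity DCCM -> edgeless
  idm <- new("DCCM", c = diag(4), atoms = 1:4, resno = c(1L, 5L, 9L, 14L),
             segment = rep("TM1", 4))
  expect_equal(nrow(buildNetwork(idm)@edges), 0L)
  expect_error(buildNetwork(cm, cutoff = 0), "cutoff")
  ## planted two-block DCCM: within-block density >> between
  set.seed(4)
  n <- 20
  blk <- rep(1:2, each = 10)
  cmat2 <- outer(blk, blk, function(a, b) ifelse(a == b, 0.9, 0.05)) +
    matrix(rnorm(n * n, sd = 0.01), n)
  cmat2 <- (cmat2 + t(cmat2)) / 2; diag(cmat2) <- 1
  cm2 <- new("DCCM", c = cmat2, atoms = 1:20,
             resno = as.integer(seq(1, 96, by = 5)), segment = rep("TM1", 20))
  nw2 <- buildNetwork(cm2, 0.7, 2)
  within <- sum(blk[nw2@edges$i] == blk[nw2@edges$j])
  between <- sum(blk[nw2@edges$i] != blk[nw2@edges$j])
  expect_gte(within / max(between, 1), 10)
})

test_that("edge betweenness equals exhaustive path enumeration", {
  for (seed in 1:30) {
    n <- sample(4:12, 1)
    g <- randomTestGraph(n, runif(1, 0.2, 0.7), seed = 1000 + seed)
    if (!nrow(g)) next
    nw <- edgeListNetwork(n, g)
    expect_equal(edgeBetweenness(nw), bfEdgeBetweenness(n, nw@edges),
                 tolerance = 1e-9)
  }
})

test_that("edge betweenness agrees with an independent graph library", {
  skip_if_not_installed("igraph")
  for (seed in 1:10) {
    n <- sample(6:14, 1)
    g <- randomTestGraph(n, 0.4, seed = 2000 + seed)
    if (!nrow(g)) next
    nw <- edgeListNetwork(n, g)
    ig <- igraph::graph_from_edgelist(as.matrix(nw@edges[, c("i", "j")]),
                                      directed = FALSE)
    expect_equal(edgeBetweenness(nw), igraph::edge_betweenness(ig),
                 tolerance = 1e-9)
  }
})

test_that("two cliques joined by a bridge decompose into the cliques", {
  nw <- twoCliqueBridge(5)
  bc <- edgeBetweenness(nw)
  bridge <- which(nw@edges$i == 5 & nw@edges$j == 6)
  expect_equal(bc[bridge], 25)           # 5 x 5 cross pairs, all through it
  expect_equal(max(bc), bc[bridge])
  gn <- girvanNewman(nw)
  ## bridge is removed first
  expect_equal(c(gn@trace$removed_i[2], gn@trace$removed_j[2]), c(5, 6))
  mem <- communities(gn)
  expect_equal(length(unique(mem)), 2L)
  expect_equal(length(unique(mem[1:5])), 1L)
  expect_equal(length(unique(mem[6:10])), 1L)
  ## hand-applied Newman-Girvan formula: Q = 2 (10/21 - (21/42)^2)
  expect_equal(modularityScore(gn), 2 * (10 / 21 - 0.25), tolerance = 1e-12)
})

test_that("degenerate graphs follow the stated contracts", {
  ## complete graph: all betweenness equal, best partition one community
  k6 <- edgeListNetwork(6, as.data.frame(t(combn(6, 2))) |>
                          setNames(c("i", "j")))
  bc <- edgeBetweenness(k6)
  expect_true(all(abs(bc - bc[1]) < 1e-12))
  gn <- girvanNewman(k6)
  expect_equal(length(unique(communities(gn))), 1L)
  expect_equal(modularityScore(gn), 0, tolerance = 1e-12)
  ## edgeless graph: singleton communities, Q defined as 0
  e0 <- edgeListNetwork(5, data.frame(i = integer(0), j = integer(0)))
  gn0 <- girvanNewman(e0)
  expect_equal(length(unique(communities(gn0))), 5L)
  expect_equal(modularityScore(gn0), 0)
})

test_that("returned partitions maximize Q over the trace", {
  for (seed in 1:10) {
    n <- sample(6:12, 1)
    g <- randomTestGraph(n, 0.35, seed = 3000 + seed)
    if (!nrow(g)) next
    gn <- girvanNewman(edgeListNetwork(n, g))
    expect_equal(modularityScore(gn), max(gn@trace$Q), tolerance = 1e-12)
    expect_gte(modularityScore(gn), 0)   # >= trivial one-community Q
  }
})

test_that("planted two-community graphs are recovered exactly", {
  ari <- vapply(1:20, function(seed) {
    set.seed(seed)
    sz <- sample(6:10, 2, replace = TRUE)
    truth <- rep(1:2, sz)
    n <- sum(sz)
    e <- rbind(t(combn(seq_len(sz[1]), 2)),
               t(combn(sz[1] + seq_len(sz[2]), 2)),
               c(sample(sz[1], 1), sz[1] + sample(sz[2], 1)))
    e <- data.frame(i = pmin(e[, 1], e[, 2]), j = pmax(e[, 1], e[, 2]))
    e <- unique(e)
    gn <- girvanNewman(edgeListNetwork(n, e))
    adjustedRandIndex(communities(gn), truth)
  }, numeric(1))
  expect_true(all(ari == 1))
})

test_that("community filtering is a reporting view with plurality verdicts", {
  ## communities sized 25 / 12 / 4 via three disjoint cliques
  mk <- function(off, k) {
    e <- t(combn(seq_len(k) + off, 2))
    data.frame(i = e[, 1], j = e[, 2])
  }
  edges <- rbind(mk(0, 25), mk(25, 12), mk(37, 4))
  nw <- edgeListNetwork(41, edges)
  nw@nodes$segment <- c(rep("TM2", 13), rep("TM5", 12),  # community 1 mixed
                        rep("TM3", 12), rep("TM6", 4))
  gn <- girvanNewman(nw)
  expect_equal(sort(communitySizes(gn), decreasing = TRUE),
               c(`1` = 25L, `2` = 12L, `3` = 4L), ignore_attr = TRUE)
  flt <- filterCommunities(gn, 10)
  expect_length(reportedCommunities(flt), 2L)
  expect_length(reportedCommunities(filterCommunities(gn, 1)), 3L)
  expect_warning(filterCommunities(gn, 50), "no community")
  ## partition unchanged by filtering
  expect_identical(communities(flt), communities(gn))
  ## joint membership: TM2 and TM5 tie for plurality inside community 1
  ## (13 vs 12 -> TM2 dominates; TM5 needs the edge route), TM3 hosts its own
  rep25 <- connectivityReport(flt, "TM2", "TM3")
  expect_false(rep25$connected)
  expect_true(connectivityReport(flt, "TM2", "TM2")$connected)
  expect_false(connectivityReport(flt, "TM6", "TM6")$connected)  # size 4
  expect_error(connectivityReport(flt, "TM2", "XX"), "unknown segment")
})

test_that("planted inter-segment correlation drives the connectivity verdict", {
  bundle <- makeBundleReference(7, 15, atoms = "calpha")
  run <- function(rho, seed) {
    tr <- plantedPhenotype(rho, seed, bundle)
    cm <- dccm(tr, stridePs = 100)
    gn <- girvanNewman(buildNetwork(cm, 0.7, 2))
    flt <- suppressWarnings(filterCommunities(gn, 10))
    connectivityReport(flt, "TM2", "TM5")$connected
  }
  expect_true(run(0.9, 101))
  expect_false(run(0, 102))
})
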