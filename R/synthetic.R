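## Synthetic ensembles with planted statistical structure. These are
## first-class generators: every downstream statistic (RMSF, covariance,
## DCCM, communities, density profiles) can be checked against the planted
## ground truth they return.

## ---- internal-coordinate chain building ------------------------------------

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(a) sqrt(sum(a * a))

## Natural-extension reference frame: position atom D bonded to C, with
## bond length r, angle(B,C,D) = theta and dihedral(A,B,C,D) = phi (radians).
nerfPlace <- function(A, B, C, r, theta, phi) {
  bc <- C - B; bc <- bc / vnorm(bc)
  n <- vcross(B - A, bc); n <- n / vnorm(n)
  m <- vcross(n, bc)
  d2 <- c(-r * cos(theta), r * sin(theta) * cos(phi), -r * sin(theta) * sin(phi))
  C + cbind(bc, m, n) %*% d2
}

#' Dihedral angle of four points
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinates.
#' @return signed dihedral in degrees, in (-180, 180].
#' @export
dihedralAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  m1 <- vcross(n1, b2 / vnorm(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

## ideal backbone geometry (standard bond lengths/angles, degrees)
.geom <- list(bNCA = 1.458, bCAC = 1.525, bCN = 1.329, bCO = 1.231,
              aNCAC = 111.2, aCACN = 116.2, aCNCA = 121.7, aCACO = 120.8)

## Build one polypeptide backbone (N, CA, C, O per residue) with the given
## phi/psi (degrees); omega fixed at 180.
buildBackbone <- function(nres, phi = -57, psi = -47) {
  d <- pi / 180
  g <- .geom
  xyz <- matrix(0, 4L * nres, 3L)
  rownames(xyz) <- rep(c("N", "CA", "C", "O"), nres)
  idx <- function(i, a) (i - 1L) * 4L + match(a, c("N", "CA", "C", "O"))
  xyz[idx(1, "N"), ] <- c(0, 0, 0)
  xyz[idx(1, "CA"), ] <- c(g$bNCA, 0, 0)
  ang <- (180 - g$aNCAC) * d
  xyz[idx(1, "C"), ] <- xyz[idx(1, "CA"), ] + g$bCAC * c(cos(ang), sin(ang), 0)
  for (i in seq_len(nres)) {
    N <- xyz[idx(i, "N"), ]; CA <- xyz[idx(i, "CA"), ]; C <- xyz[idx(i, "C"), ]
    ## carbonyl O: dihedral N-CA-C-O = psi + 180
    xyz[idx(i, "O"), ] <- nerfPlace(N, CA, C, g$bCO, g$aCACO * d, (psi + 180) * d)
    if (i == nres) break
    Nn <- nerfPlace(N, CA, C, g$bCN, g$aCACN * d, psi * d)
    CAn <- nerfPlace(CA, C, Nn, g$bNCA, g$aCNCA * d, pi)  # omega = 180
    Cn <- nerfPlace(C, Nn, CAn, g$bCAC, g$aNCAC * d, phi * d)
    xyz[idx(i + 1L, "N"), ] <- Nn
    xyz[idx(i + 1L, "CA"), ] <- CAn
    xyz[idx(i + 1L, "C"), ] <- Cn
  }
  xyz
}

## rotation taking unit vector a onto unit vector b (Rodrigues)
rotationBetween <- function(a, b) {
  a <- a / vnorm(a); b <- b / vnorm(b)
  v <- vcross(a, b); s <- vnorm(v); cth <- sum(a * b)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    ## opposite: rotate pi about any perpendicular axis
    p <- if (abs(a[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- vcross(a, p); v <- v / vnorm(v)
    K <- matrix(c(0, v[3L], -v[2L], -v[3L], 0, v[1L], v[2L], -v[1L], 0), 3L, 3L)
    return(diag(3) + 2 * K %*% K)
  }
  K <- matrix(c(0, v[3L], -v[2L], -v[3L], 0, v[1L], v[2L], -v[1L], 0), 3L, 3L)
  diag(3) + K + K %*% K * ((1 - cth) / s^2)
}

#' Build an idealized helix-bundle reference structure
#'
#' Generates \code{nHelices} ideal alpha-helices (backbone N, CA, C, O built
#' from standard internal coordinates with phi = -57, psi = -47; rise 1.5 A
#' and ~100 degrees twist per residue follow from that geometry), each
#' aligned to the membrane normal (z), arranged on a circle and alternating
#' up/down as in a transmembrane bundle. Helix h is labelled segment TMh;
#' residue numbering is contiguous from \code{firstResno}.
#'
#' @param nHelices number of helices (1..7).
#' @param residuesPerHelix residues per helix (>= 2).
#' @param bundleRadius circle radius for helix axes, Angstrom.
#' @param firstResno residue number of the first residue (default 358,
#'   the conventional first transmembrane-domain residue of the receptor
#'   numbering this package documents).
#' @param atoms \code{"backbone"} (N, CA, C, O) or \code{"calpha"}.
#' @return list with \code{topology} (\linkS4class{Topology}) and \code{xyz}
#'   (atoms x 3 reference coordinates, Angstrom).
#' @examples
#' ref <- makeBundleReference(7, 25)
#' nAtoms(ref$topology)
#' @export
makeBundleReference <- function(nHelices = 7, residuesPerHelix = 25,
                                bundleRadius = 11.5, firstResno = 358,
                                atoms = c("backbone", "calpha")) {
  atoms <- match.arg(atoms)
  if (nHelices < 1 || nHelices > 7) stop("nHelices must be in 1..7")
  if (residuesPerHelix < 2) stop("residuesPerHelix must be >= 2")
  atab <- NULL; xyz <- NULL
  resno0 <- firstResno
  for (h in seq_len(nHelices)) {
    bb <- buildBackbone(residuesPerHelix)
    ca <- bb[rownames(bb) == "CA", , drop = FALSE]
    ## helix axis via principal direction of the CA trace
    cen <- colMeans(ca)
    ax <- svd(sweep(ca, 2L, cen))$v[, 1L]
    if (sum(ax * (ca[nrow(ca), ] - ca[1L, ])) < 0) ax <- -ax
    R <- rotationBetween(ax, c(0, 0, 1))
    hb <- sweep(bb, 2L, cen) %*% t(R)
    if (h %% 2L == 0L)  # antiparallel bundle: flip every other helix
      hb <- hb %*% diag(c(1, -1, -1))
    th <- 2 * pi * (h - 1L) / max(nHelices, 2L)
    hb[, 1L] <- hb[, 1L] + bundleRadius * cos(th)
    hb[, 2L] <- hb[, 2L] + bundleRadius * sin(th)
    resno <- rep(resno0 + seq_len(residuesPerHelix) - 1L, each = 4L)
    tab <- data.frame(name = rep(c("N", "CA", "C", "O"), residuesPerHelix),
                      element = rep(c("N", "C", "C", "O"), residuesPerHelix),
                      resno = resno, resid = "ALA", chain = "A",
                      segment = paste0("TM", h), stringsAsFactors = FALSE)
    if (atoms == "calpha") {
      keep <- tab$name == "CA"
      tab <- tab[keep, , drop = FALSE]
      hb <- hb[keep, , drop = FALSE]
    }
    atab <- rbind(atab, tab)
    xyz <- rbind(xyz, hb)
    resno0 <- resno0 + residuesPerHelix
  }
  rownames(xyz) <- NULL
  list(topology = Topology(atab), xyz = unname(xyz))
}

#' Backbone phi/psi dihedrals of a structure
#'
#' @param topology a \linkS4class{Topology} with backbone atoms.
#' @param xyz atoms x 3 coordinate matrix.
#' @return data.frame with \code{resno}, \code{phi}, \code{psi} (degrees;
#'   NA at chain/segment termini).
#' @export
backboneDihedrals <- function(topology, xyz) {
  a <- atomData(topology)
  prot <- a$segment %in% c(paste0("TM", 1:7), "H8", paste0("IL", 1:3),
                           paste0("EL", 1:3), "NT", "CT", "OTHER")
  res <- unique(a$resno[prot])
  get <- function(rn, nm) {
    i <- which(a$resno == rn & a$name == nm)
    if (length(i) != 1L) return(NULL)
    xyz[i, ]
  }
  seg <- a$segment[match(res, a$resno)]
  out <- data.frame(resno = res, phi = NA_real_, psi = NA_real_)
  for (k in seq_along(res)) {
    rn <- res[k]
    N <- get(rn, "N"); CA <- get(rn, "CA"); C <- get(rn, "C")
    if (is.null(N) || is.null(CA) || is.null(C)) next
    if (k > 1L && seg[k - 1L] == seg[k] && res[k - 1L] == rn - 1L) {
      Cp <- get(rn - 1L, "C")
      if (!is.null(Cp)) out$phi[k] <- dihedralAngle(Cp, N, CA, C)
    }
    if (k < length(res) && seg[k + 1L] == seg[k] && res[k + 1L] == rn + 1L) {
      Nn <- get(rn + 1L, "N")
      if (!is.null(Nn)) out$psi[k] <- dihedralAngle(N, CA, C, Nn)
    }
  }
  out
}

## ---- Gaussian ensembles with planted covariance ----------------------------

#' Specification of a synthetic fluctuation ensemble
#'
#' Defines a Gaussian ensemble about a reference structure: per-atom
#' isotropic fluctuation amplitudes, equicorrelated inter-segment blocks,
#' and optional diffusive drift of the atomic mean positions. The planted
#' 3N x 3N covariance is exactly known, so sampled trajectories carry their
#' own ground truth.
#'
#' A correlation block (segmentA, segmentB, rho) makes the atom union
#' A u B an equicorrelated cluster: every pair inside the union (within and
#' across the two segments) has displacement correlation rho on each axis,
#' as produced by a single shared latent factor. This is the minimal
#' positive-semidefinite structure with the stated cross-segment
#' correlation.
#'
#' @param reference list with \code{topology} and \code{xyz}, as returned
#'   by \code{\link{makeBundleReference}}.
#' @param sigma per-atom fluctuation SD per Cartesian axis, Angstrom
#'   (scalar recycled or one value per atom). The expected RMSF of an atom
#'   is \code{sigma * sqrt(3)}.
#' @param blocks data.frame with columns \code{segmentA}, \code{segmentB},
#'   \code{rho} (|rho| <= 1), or NULL.
#' @param drift diffusion coefficient D for random-walk drift of atomic
#'   means, Angstrom^2/ps (0 = none); per-axis step SD is
#'   \code{sqrt(2 * D * dt)}.
#' @param driftMode \code{"atom"} (independent walk per atom),
#'   \code{"segment"} (one shared walk per segment) or \code{"global"}.
#' @param nFrames number of frames to sample.
#' @param dt frame spacing, ps.
#' @param seed integer RNG seed; generation is a pure function of
#'   (spec, seed).
#' @return an object of class \code{EnsembleSpec} (list).
#' @export
ensembleSpec <- function(reference, sigma = 0.5, blocks = NULL, drift = 0,
                         driftMode = c("atom", "segment", "global"),
                         nFrames = 1000, dt = 4, seed = 1) {
  driftMode <- match.arg(driftMode)
  n <- nAtoms(reference$topology)
  sigma <- rep_len(as.numeric(sigma), n)
  if (any(sigma < 0)) stop("sigma must be non-negative")
  if (!is.null(blocks)) {
    blocks <- as.data.frame(blocks, stringsAsFactors = FALSE)
    if (!all(c("segmentA", "segmentB", "rho") %in% names(blocks)))
      stop("blocks needs columns segmentA, segmentB, rho")
    if (any(abs(blocks$rho) > 1)) stop("|rho| must be <= 1")
  }
  if (drift < 0) stop("drift diffusion coefficient must be >= 0")
  if (nFrames < 1) stop("nFrames must be >= 1")
  structure(list(reference = reference, sigma = sigma, blocks = blocks,
                 drift = drift, driftMode = driftMode,
                 nFrames = as.integer(nFrames), dt = dt,
                 seed = as.integer(seed)),
            class = "EnsembleSpec")
}

## N x N planted correlation matrix of an EnsembleSpec
plantedCorrelation <- function(spec) {
  top <- spec$reference$topology
  n <- nAtoms(top)
  seg <- atomData(top)$segment
  R <- diag(n)
  if (!is.null(spec$blocks)) {
    for (k in seq_len(nrow(spec$blocks))) {
      members <- which(seg %in% c(spec$blocks$segmentA[k], spec$blocks$segmentB[k]))
      if (length(members) < 2L) next
      R[members, members] <- spec$blocks$rho[k]
      diag(R)[members] <- 1
    }
  }
  R
}

#' Planted 3N x 3N covariance of an ensemble spec
#'
#' Coordinate ordering (x1, y1, z1, x2, ...): cross-axis covariances are
#' zero; per-axis covariance of atoms i, j is \code{sigma_i sigma_j R_ij}.
#'
#' @param spec an \code{EnsembleSpec}.
#' @return 3N x 3N covariance matrix, Angstrom^2.
#' @export
plantedCovariance <- function(spec) {
  R <- plantedCorrelation(spec)
  S <- R * outer(spec$sigma, spec$sigma)
  kronecker(S, diag(3))
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(expr)
}

#' Sample a synthetic trajectory from an ensemble specification
#'
#' Draws frames from a multivariate normal about the (possibly drifting)
#' reference coordinates. The planted correlation matrix is checked for
#' positive semidefiniteness (eigenvalue floor -1e-10) before any sampling.
#'
#' @param spec an \code{EnsembleSpec} from \code{\link{ensembleSpec}}.
#' @return list with \code{trajectory} (\linkS4class{Trajectory}),
#'   \code{covariance} (exact planted 3N x 3N matrix),
#'   \code{correlation} (planted N x N per-axis correlation) and
#'   \code{sigma}.
#' @examples
#' ref <- makeBundleReference(2, 8)
#' ens <- sampleEnsemble(ensembleSpec(ref, sigma = 0.5, nFrames = 50, seed = 7))
#' nFrames(ens$trajectory)
#' @export
sampleEnsemble <- function(spec) {
  stopifnot(inherits(spec, "EnsembleSpec"))
  top <- spec$reference$topology
  ref <- spec$reference$xyz
  n <- nAtoms(top)
  R <- plantedCorrelation(spec)
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < -1e-10)
    stop(sprintf("planted covariance is not positive semidefinite (min eigenvalue %.3g)",
                 min(ev$values)))
  sqrtR <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  nf <- spec$nFrames
  seg <- atomData(top)$segment
  co <- withSeed(spec$seed, {
    out <- array(0, c(nf, n, 3L))
    for (k in 1:3) {
      Y <- matrix(stats::rnorm(nf * n), nf, n) %*% sqrtR
      out[, , k] <- sweep(Y, 2L, spec$sigma, `*`) +
        matrix(ref[, k], nf, n, byrow = TRUE)
    }
    if (spec$drift > 0) {
      stepSD <- sqrt(2 * spec$drift * spec$dt)
      nwalk <- switch(spec$driftMode,
                      atom = n,
                      segment = length(unique(seg)),
                      global = 1L)
      map <- switch(spec$driftMode,
                    atom = seq_len(n),
                    segment = match(seg, unique(seg)),
                    global = rep(1L, n))
      for (k in 1:3) {
        W <- apply(matrix(stats::rnorm(nf * nwalk, sd = stepSD), nf, nwalk),
                   2L, cumsum)
        W <- matrix(W, nf, nwalk)  # nf == 1 edge case
        out[, , k] <- out[, , k] + W[, map, drop = FALSE]
      }
    }
    out
  })
  traj <- Trajectory(co, top, times = (seq_len(nf) - 1) * spec$dt)
  S <- R * outer(spec$sigma, spec$sigma)
  list(trajectory = traj, covariance = kronecker(S, diag(3)),
       correlation = R, sigma = spec$sigma)
}

## ---- membrane pseudo-atom boxes --------------------------------------------

#' Specification of a toy membrane box
#'
#' Pseudo-atom slabs along the bilayer normal (z): water, phosphate-like
#' head groups and methyl-like chain termini, each uniformly distributed in
#' configured z-intervals. The geometry emulates a solvated bilayer whose
#' hydrophobic core is bounded by the methyl distribution and whose
#' water-lipid interfaces are bounded by the phosphate peaks.
#'
#' @param box length-3 box edges (Lx, Ly, Lz), Angstrom; z spans
#'   [-Lz/2, Lz/2].
#' @param nWater,nPhosphate,nMethyl pseudo-atom counts (>= 0).
#' @param waterSlabs,phosphateSlabs,methylSlabs k x 2 matrices of z-intervals
#'   (Angstrom) inside [-Lz/2, Lz/2]; atoms are assigned to slabs with
#'   probability proportional to slab width.
#' @param nFrames frames to generate (positions redrawn independently).
#' @param seed integer RNG seed.
#' @return an object of class \code{MembraneBoxSpec} (list).
#' @export
membraneBoxSpec <- function(box = c(60, 60, 80),
                            nWater = 2000, nPhosphate = 200, nMethyl = 400,
                            waterSlabs = rbind(c(-40, -25), c(25, 40)),
                            phosphateSlabs = rbind(c(-25, -15), c(15, 25)),
                            methylSlabs = rbind(c(-10, 10)),
                            nFrames = 1, seed = 1) {
  box <- as.numeric(box)
  if (length(box) != 3L || any(box <= 0)) stop("box must be 3 positive edges")
  chk <- function(sl, what, n) {
    if (n == 0L) return(invisible())
    sl <- rbind(sl)
    if (ncol(sl) != 2L || any(sl[, 1L] >= sl[, 2L]))
      stop(what, " slabs must be k x 2 intervals with lo < hi")
    if (any(sl[, 1L] < -box[3L] / 2 - 1e-9) || any(sl[, 2L] > box[3L] / 2 + 1e-9))
      stop(what, " slab outside box z-range [", -box[3L] / 2, ", ", box[3L] / 2, "]")
  }
  if (any(c(nWater, nPhosphate, nMethyl) < 0)) stop("counts must be >= 0")
  chk(waterSlabs, "water", nWater)
  chk(phosphateSlabs, "phosphate", nPhosphate)
  chk(methylSlabs, "methyl", nMethyl)
  structure(list(box = box, nWater = as.integer(nWater),
                 nPhosphate = as.integer(nPhosphate),
                 nMethyl = as.integer(nMethyl),
                 waterSlabs = rbind(waterSlabs),
                 phosphateSlabs = rbind(phosphateSlabs),
                 methylSlabs = rbind(methylSlabs),
                 nFrames = as.integer(nFrames), seed = as.integer(seed)),
            class = "MembraneBoxSpec")
}

sampleSlabZ <- function(n, slabs) {
  if (n == 0L) return(numeric(0))
  w <- slabs[, 2L] - slabs[, 1L]
  pick <- sample.int(nrow(slabs), n, replace = TRUE, prob = w)
  stats::runif(n, slabs[pick, 1L], slabs[pick, 2L])
}

#' Generate a toy membrane box
#'
#' @param spec a \code{MembraneBoxSpec} from \code{\link{membraneBoxSpec}}.
#' @return list with \code{topology} (water O atoms plus phosphate-like P
#'   and methyl-like C lipid pseudo-atoms) and \code{trajectory}
#'   (\linkS4class{Trajectory} with per-frame box).
#' @export
makeMembraneBox <- function(spec) {
  stopifnot(inherits(spec, "MembraneBoxSpec"))
  nw <- spec$nWater; np <- spec$nPhosphate; nm <- spec$nMethyl
  n <- nw + np + nm
  if (n == 0L) stop("membrane box with zero atoms")
  atoms <- data.frame(
    name = c(rep("OW", nw), rep("P", np), rep("CM", nm)),
    element = c(rep("O", nw), rep("P", np), rep("C", nm)),
    resno = seq_len(n),
    resid = c(rep("HOH", nw), rep("SDP", np + nm)),
    chain = "M",
    segment = c(rep("WATER", nw), rep("LIPID", np + nm)),
    stringsAsFactors = FALSE)
  top <- Topology(atoms)
  nf <- spec$nFrames
  co <- withSeed(spec$seed, {
    out <- array(0, c(nf, n, 3L))
    for (f in seq_len(nf)) {
      out[f, , 1L] <- stats::runif(n, 0, spec$box[1L])
      out[f, , 2L] <- stats::runif(n, 0, spec$box[2L])
      out[f, , 3L] <- c(sampleSlabZ(nw, spec$waterSlabs),
                        sampleSlabZ(np, spec$phosphateSlabs),
                        sampleSlabZ(nm, spec$methylSlabs))
    }
    out
  })
  traj <- Trajectory(co, top, times = seq_len(nf) - 1, box = spec$box)
  list(topology = top, trajectory = traj)
}
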