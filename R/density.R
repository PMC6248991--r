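## Number-density profiles along the bilayer normal, hydration by
## integration over the hydrophobic core, and bilayer-topology detection
## from the methyl and phosphate distributions.

#' DensityProfile: binned number density along the bilayer normal
#'
#' Per-group number density in bins of width \code{binWidth} along z,
#' origin at the bilayer midplane, normalized by the bin volume
#' dz x A_average with A_average the time-averaged lateral box area.
#' The integral of each group's density over all bins exactly equals its
#' (frame-averaged) atom count.
#'
#' @slot z bin centers, Angstrom.
#' @slot density bins x groups matrix, atoms/Angstrom^3 (frame mean, or
#'   replica mean when built from several trajectories).
#' @slot sd bins x groups matrix of replica SDs (zeros for one replica).
#' @slot binWidth numeric, Angstrom.
#' @slot area time-averaged lateral area, Angstrom^2.
#' @slot counts named per-group frame-averaged atom counts.
#' @export
setClass("DensityProfile",
         representation(z = "numeric", density = "matrix", sd = "matrix",
                        binWidth = "numeric", area = "numeric",
                        counts = "numeric"))

setValidity("DensityProfile", function(object) {
  if (any(object@density < 0)) return("densities must be non-negative")
  if (!identical(dim(object@density), dim(object@sd)))
    return("sd must match density dimensions")
  vol <- object@binWidth * object@area
  tot <- colSums(object@density) * vol
  ref <- object@counts[colnames(object@density)]
  if (any(abs(tot - ref) > 1e-6 * pmax(1, ref)))
    return("density integral must equal the group atom count")
  TRUE
})

setMethod("show", "DensityProfile", function(object) {
  cat(sprintf("DensityProfile: %d bins of %.3g A, groups %s\n",
              length(object@z), object@binWidth,
              paste(sprintf("%s(n=%.6g)", colnames(object@density),
                            object@counts[colnames(object@density)]),
                    collapse = " ")))
})

profileOneTrajectory <- function(trajectory, groups, binWidth, origin,
                                 breaks = NULL) {
  if (!nrow(boxDims(trajectory)))
    stop("density profiles need per-frame box dimensions")
  nf <- nFrames(trajectory)
  area <- mean(boxDims(trajectory)[, 1L] * boxDims(trajectory)[, 2L])
  zmat <- trajectory@coords[, , 3L, drop = FALSE]
  dim(zmat) <- dim(trajectory@coords)[1:2]
  zmat <- matrix(zmat, nrow = nf)
  ## per-frame origin (bilayer midplane)
  org <- vapply(seq_len(nf), function(f) {
    if (is.numeric(origin)) return(origin)
    ph <- groups[[origin]]
    z <- zmat[f, ph]
    ## leaflet split at the mean, refined once: robust to unequal leaflet
    ## occupancies (a median split can land inside one leaflet)
    cut <- mean(z)
    for (it in 1:2) {
      up <- z >= cut
      if (!any(up) || all(up)) break
      cut <- (mean(z[up]) + mean(z[!up])) / 2
    }
    cut
  }, numeric(1L))
  zrel <- zmat - org
  if (is.null(breaks)) {
    zmax <- max(abs(zrel[, unlist(groups)])) + binWidth
    k <- ceiling(zmax / binWidth)
    breaks <- seq(-k, k) * binWidth
  }
  centers <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  dens <- matrix(0, length(centers), length(groups),
                 dimnames = list(NULL, names(groups)))
  counts <- numeric(length(groups)); names(counts) <- names(groups)
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    acc <- numeric(length(centers))
    for (f in seq_len(nf)) {
      z <- zrel[f, idx]
      if (any(z < breaks[1L]) || any(z > breaks[length(breaks)]))
        stop("atom outside the binning range; widen zrange")
      h <- findInterval(z, breaks, rightmost.closed = TRUE)
      acc <- acc + tabulate(h, nbins = length(centers))
    }
    dens[, g] <- acc / nf / (binWidth * area)
    counts[g] <- length(idx)
  }
  list(z = centers, density = dens, counts = counts, area = area,
       breaks = breaks)
}

#' Number-density profile along the bilayer normal
#'
#' Histograms each atom group along z (origin at the bilayer midplane,
#' defined per frame as the midpoint between the mean z of the two
#' phosphate leaflets, or a fixed value), normalizes by bin volume
#' dz x A_average, and averages over frames. With several trajectories
#' (replicas) the profile is the replica mean with per-bin SD.
#'
#' @param trajectory a \linkS4class{Trajectory} or a list of replicas
#'   (common topology).
#' @param groups named list of atom-index vectors or
#'   \linkS4class{Selection}s (e.g. \code{list(water = ..., phosphate =
#'   ..., methyl = ...)}).
#' @param binWidth bin width, Angstrom (default 1).
#' @param origin \code{"phosphate"}-style group name used to locate the
#'   midplane, or a fixed numeric z. Default: the group named
#'   \code{"phosphate"} when present, else 0.
#' @return a \linkS4class{DensityProfile}.
#' @export
densityProfile <- function(trajectory, groups, binWidth = 1, origin = NULL) {
  trajs <- if (is(trajectory, "Trajectory")) list(trajectory) else trajectory
  top <- topology(trajs[[1L]])
  groups <- lapply(groups, function(g)
    if (is(g, "Selection")) atomSelect(top, g) else as.integer(g))
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be a named list")
  if (any(vapply(groups, length, 1L) == 0L)) stop("empty atom group")
  if (is.null(origin))
    origin <- if ("phosphate" %in% names(groups)) "phosphate" else 0
  if (is.character(origin) && !origin %in% names(groups))
    stop("origin group '", origin, "' not in groups")
  ## common symmetric breaks across replicas
  zspan <- max(vapply(trajs, function(tr) {
    z <- tr@coords[, unlist(groups), 3L]
    max(abs(range(z))) }, numeric(1L))) + max(50, binWidth)
  k <- ceiling(zspan / binWidth)
  breaks <- seq(-k, k) * binWidth
  profs <- lapply(trajs, profileOneTrajectory, groups = groups,
                  binWidth = binWidth, origin = origin, breaks = breaks)
  dens <- Reduce(`+`, lapply(profs, `[[`, "density")) / length(profs)
  sdm <- if (length(profs) > 1L) {
    arr <- simplify2array(lapply(profs, `[[`, "density"))
    apply(arr, c(1L, 2L), stats::sd)
  } else matrix(0, nrow(dens), ncol(dens), dimnames = dimnames(dens))
  counts <- Reduce(`+`, lapply(profs, `[[`, "counts")) / length(profs)
  area <- mean(vapply(profs, `[[`, numeric(1L), "area"))
  ## trim all-zero outer bins (keep integrals intact by construction)
  nz <- which(rowSums(dens) > 0)
  keep <- if (length(nz)) {
    w <- max(abs(profs[[1L]]$z[nz])) + binWidth
    which(abs(profs[[1L]]$z) <= w)
  } else seq_along(profs[[1L]]$z)
  new("DensityProfile", z = profs[[1L]]$z[keep],
      density = dens[keep, , drop = FALSE], sd = sdm[keep, , drop = FALSE],
      binWidth = binWidth, area = area, counts = counts)
}

#' Hydration count by density integration
#'
#' Integrates a group's number density over a z-interval (bin sum of
#' density x bin volume over bins whose centers fall inside), the
#' operational definition of the interhelical water count over the
#' hydrophobic core (-10, 10) A.
#'
#' @param profile a \linkS4class{DensityProfile}.
#' @param interval length-2 z-interval, Angstrom (default c(-10, 10));
#'   must be non-empty.
#' @param group group name (default \code{"water"}).
#' @return list with \code{count} and, when replica SDs are present,
#'   \code{lower}/\code{upper} (count from mean -/+ SD profiles).
#' @export
hydrationCount <- function(profile, interval = c(-10, 10), group = "water") {
  if (length(interval) != 2L || interval[1L] >= interval[2L])
    stop("interval must be a non-empty (lo, hi) pair")
  if (!group %in% colnames(profile@density))
    stop("group '", group, "' not in profile")
  sel <- profile@z >= interval[1L] & profile@z < interval[2L]
  if (!any(sel)) stop("interval outside the profile range")
  vol <- profile@binWidth * profile@area
  count <- sum(profile@density[sel, group]) * vol
  out <- list(count = count)
  if (any(profile@sd > 0)) {
    out$lower <- sum(pmax(profile@density[sel, group] -
                            profile@sd[sel, group], 0)) * vol
    out$upper <- sum(profile@density[sel, group] +
                       profile@sd[sel, group]) * vol
  }
  out
}

#' Detect bilayer topology from a density profile
#'
#' The hydrophobic core is the smallest symmetric interval holding the
#' central \code{coreFraction} of the methyl-like density; each water-lipid
#' interface is the interval within half-maximum of the corresponding
#' phosphate leaflet peak. A phosphate distribution without two leaflets
#' (one side empty) is an error.
#'
#' @param profile a \linkS4class{DensityProfile}.
#' @param methylGroup,phosphateGroup group names (defaults "methyl",
#'   "phosphate").
#' @param coreFraction central methyl-density fraction defining the core
#'   (default 0.9).
#' @return list with \code{core} (c(lo, hi)) and \code{interfaces}
#'   (list \code{lower}, \code{upper}, each c(lo, hi)).
#' @export
detectBilayerTopology <- function(profile, methylGroup = "methyl",
                                  phosphateGroup = "phosphate",
                                  coreFraction = 0.9) {
  for (g in c(methylGroup, phosphateGroup))
    if (!g %in% colnames(profile@density))
      stop("group '", g, "' not in profile")
  z <- profile@z; dz <- profile@binWidth
  dm <- profile@density[, methylGroup]
  if (sum(dm) <= 0) stop("no methyl-like density")
  ord <- order(abs(z))
  cum <- cumsum(dm[ord]) / sum(dm)
  need <- ord[seq_len(which(cum >= coreFraction)[1L])]
  w <- max(abs(z[need])) + dz / 2
  core <- c(-w, w)
  dp <- profile@density[, phosphateGroup]
  tot <- sum(dp)
  sides <- list(lower = which(z < 0), upper = which(z > 0))
  frac <- vapply(sides, function(s) sum(dp[s]) / tot, numeric(1L))
  if (any(frac < 0.05))
    stop("phosphate distribution is not bimodal across the midplane: ",
         "cannot define two leaflets")
  interfaces <- lapply(sides, function(s) {
    pk <- max(dp[s])
    hit <- s[dp[s] >= pk / 2]
    c(min(z[hit]) - dz / 2, max(z[hit]) + dz / 2)
  })
  list(core = core, interfaces = interfaces)
}
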