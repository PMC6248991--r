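## Least-squares rigid-body superposition (Kabsch), RMSD time series and
## RMSF profiles with replica aggregation. All fits are mass-unweighted;
## the reference is always frame 0 (the first frame) of each trajectory.

#' Optimal rigid superposition of two coordinate sets
#'
#' Finds the proper rotation and translation minimizing the unweighted
#' least-squares deviation of \code{mobile} from \code{reference} over the
#' atoms in \code{fitSelection} (Kabsch algorithm via SVD). The transform
#' maps mobile coordinates as \code{x %*% t(rotation) + translation}.
#'
#' @param mobile atoms x 3 matrix, Angstrom.
#' @param reference atoms x 3 matrix of the same atom count.
#' @param fitSelection 1-based atom indices used for the fit (default all);
#'   at least 3 non-collinear atoms.
#' @return list with \code{rotation} (3 x 3, det +1), \code{translation}
#'   (length 3) and \code{rmsd} (Angstrom, the minimized value over the fit
#'   selection).
#' @examples
#' ref <- makeBundleReference(1, 10)$xyz
#' superpose(ref, ref)$rmsd
#' @export
superpose <- function(mobile, reference, fitSelection = NULL) {
  if (!is.matrix(mobile) || !is.matrix(reference) ||
      ncol(mobile) != 3L || ncol(reference) != 3L)
    stop("mobile and reference must be atoms x 3 matrices")
  if (nrow(mobile) != nrow(reference))
    stop(sprintf("size mismatch: mobile has %d atoms, reference has %d",
                 nrow(mobile), nrow(reference)))
  if (is.null(fitSelection)) fitSelection <- seq_len(nrow(mobile))
  if (length(fitSelection) < 3L)
    stop("fit selection must contain at least 3 atoms")
  M <- mobile[fitSelection, , drop = FALSE]
  R0 <- reference[fitSelection, , drop = FALSE]
  mc <- colMeans(M); rc <- colMeans(R0)
  Mc <- sweep(M, 2L, mc); Rc <- sweep(R0, 2L, rc)
  ## degenerate (collinear) selections have rank < 2 cross-covariance
  if (svd(Mc, nu = 0, nv = 0)$d[2L] < 1e-8 * max(1, svd(Mc, nu = 0, nv = 0)$d[1L]))
    stop("fit selection is collinear or degenerate")
  H <- crossprod(Mc, Rc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  U <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)  # proper rotation
  fitted <- Mc %*% t(U)
  rmsd <- sqrt(mean(rowSums((fitted - Rc)^2)))
  list(rotation = U, translation = as.numeric(rc - U %*% mc), rmsd = rmsd)
}

applyTransform <- function(xyz, fit) {
  sweep(xyz %*% t(fit$rotation), 2L, fit$translation, `+`)
}

#' Superpose every frame onto the first frame
#'
#' Fits each frame's \code{fitSelection} atoms onto frame 1 (the
#' "conformation at time 0") and applies the transform to all atoms.
#'
#' @param trajectory a \linkS4class{Trajectory}.
#' @param fitSelection atom indices to fit on (default all atoms).
#' @param reference optional external reference coordinates (atoms x 3);
#'   default frame 1 of the trajectory.
#' @return a \linkS4class{Trajectory} with fitted coordinates.
#' @export
fitFrames <- function(trajectory, fitSelection = NULL, reference = NULL) {
  co <- trajectory@coords
  ref <- if (is.null(reference)) matrix(co[1L, , ], ncol = 3L) else reference
  out <- co
  for (f in seq_len(dim(co)[1L])) {
    fr <- matrix(co[f, , ], ncol = 3L)
    ft <- superpose(fr, ref, fitSelection)
    out[f, , ] <- applyTransform(fr, ft)
  }
  bx <- if (nrow(trajectory@box)) trajectory@box else NULL
  Trajectory(out, trajectory@topology, times = trajectory@times, box = bx)
}

#' RMSD time series against the first frame
#'
#' Each frame is superposed on frame 1 using \code{fitSelection}; the RMSD
#' is then measured over \code{measureSelection} (which may differ, e.g.
#' fit on the whole transmembrane domain, measure one helix). The value at
#' frame 1 is exactly 0.
#'
#' @param trajectory a \linkS4class{Trajectory}.
#' @param fitSelection atom indices for the superposition (default all).
#' @param measureSelection atom indices for the deviation (default =
#'   \code{fitSelection}).
#' @return data.frame with \code{time} (ps) and \code{rmsd} (Angstrom).
#' @export
rmsdSeries <- function(trajectory, fitSelection = NULL,
                       measureSelection = NULL) {
  if (is.null(fitSelection)) fitSelection <- seq_len(nAtoms(trajectory))
  if (is.null(measureSelection)) measureSelection <- fitSelection
  if (!length(measureSelection)) stop("empty measure selection")
  co <- trajectory@coords
  ref <- matrix(co[1L, , ], ncol = 3L)
  refM <- ref[measureSelection, , drop = FALSE]
  out <- numeric(dim(co)[1L])
  for (f in seq_len(dim(co)[1L])) {
    fr <- matrix(co[f, , ], ncol = 3L)
    ft <- superpose(fr, ref, fitSelection)
    moved <- applyTransform(fr[measureSelection, , drop = FALSE], ft)
    out[f] <- sqrt(mean(rowSums((moved - refM)^2)))
  }
  out[1L] <- 0
  data.frame(time = trajectory@times, rmsd = out)
}

#' Root-mean-square fluctuation profile with replica aggregation
#'
#' For each replica, every frame is superposed onto that replica's own
#' first frame over \code{fitSelection}; the RMSF of each measured atom is
#' the root-mean-square displacement about its time-mean position. Replica
#' mean and SD are unweighted across replicas (each replica contributes one
#' value per atom; unequal lengths allowed).
#'
#' @param trajectory a \linkS4class{Trajectory} (the first replica).
#' @param fitSelection atom indices for the superposition (default all).
#' @param measureSelection atom indices to profile (default: all CA atoms,
#'   or all atoms when no CA present).
#' @param replicas optional list of additional \linkS4class{Trajectory}
#'   objects (e.g. restart runs R1, R2).
#' @return data.frame with \code{atom}, \code{resno}, \code{segment},
#'   \code{rmsf} (replica mean, Angstrom), \code{sd} (replica SD; 0 with a
#'   single replica) and one \code{rmsf.R<k>} column per replica.
#' @export
rmsfProfile <- function(trajectory, fitSelection = NULL,
                        measureSelection = NULL, replicas = list()) {
  if (is.null(measureSelection)) {
    measureSelection <- atomSelect(trajectory, name = "CA")
    if (!length(measureSelection)) measureSelection <- seq_len(nAtoms(trajectory))
  }
  if (!length(measureSelection)) stop("empty measure selection")
  all <- c(list(trajectory), replicas)
  one <- function(tr) {
    if (nFrames(tr) < 2L)
      stop("RMSF is undefined for a single-frame trajectory")
    ft <- fitFrames(tr, fitSelection)
    co <- ft@coords[, measureSelection, , drop = FALSE]
    mu <- apply(co, c(2L, 3L), mean)
    dev2 <- sweep(co, c(2L, 3L), mu)^2
    sqrt(apply(dev2, 2L, mean) * 3)  # mean over frames of summed xyz dev
  }
  prof <- vapply(all, one, numeric(length(measureSelection)))
  prof <- matrix(prof, ncol = length(all))
  a <- atomData(trajectory)[measureSelection, , drop = FALSE]
  out <- data.frame(atom = measureSelection, resno = a$resno,
                    segment = a$segment,
                    rmsf = rowMeans(prof),
                    sd = if (ncol(prof) > 1L) apply(prof, 1L, stats::sd) else 0)
  for (k in seq_len(ncol(prof))) out[[paste0("rmsf.R", k - 1L)]] <- prof[, k]
  rownames(out) <- NULL
  out
}
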