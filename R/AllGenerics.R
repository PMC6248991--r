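#' @import methods
NULL

#' Number of atoms
#'
#' @param x a \linkS4class{Topology} or \linkS4class{Trajectory}.
#' @return integer atom count.
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Number of frames
#'
#' @param x a \linkS4class{Trajectory}.
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Frame times in picoseconds
#'
#' @param x a \linkS4class{Trajectory}.
#' @return numeric vector of frame times (ps).
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' Atom table
#'
#' One row per atom: \code{name}, \code{element}, \code{resno},
#' \code{resid}, \code{chain}, \code{segment}. Row order is the internal
#' (1-based) atom index used by all selections.
#'
#' @param x a \linkS4class{Topology} or \linkS4class{Trajectory}.
#' @return data.frame of per-atom records.
#' @export
setGeneric("atomData", function(x) standardGeneric("atomData"))

#' Coordinates
#'
#' @param x a \linkS4class{Trajectory}.
#' @param frame optional frame index; if given, an atoms x 3 matrix is
#'   returned instead of the full frames x atoms x 3 array.
#' @return numeric array (frames x atoms x 3, Angstrom) or matrix.
#' @export
setGeneric("coords", function(x, frame = NULL) standardGeneric("coords"))

#' Per-frame box dimensions
#'
#' @param x a \linkS4class{Trajectory}.
#' @return frames x 3 matrix of orthorhombic box edges (Angstrom), or a
#'   zero-row matrix when no box is stored.
#' @export
setGeneric("boxDims", function(x) standardGeneric("boxDims"))

#' Topology of an object
#'
#' @param x an object carrying a \linkS4class{Topology} reference.
#' @return the \linkS4class{Topology}.
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))

#' Evaluate an atom selection
#'
#' @param x a \linkS4class{Topology} or \linkS4class{Trajectory}.
#' @param sel a \linkS4class{Selection}, or criteria passed to
#'   \code{\link{selection}} via \code{...}.
#' @param ... selection criteria when \code{sel} is missing.
#' @return sorted 1-based atom indices (integer vector, possibly empty).
#' @export
setGeneric("atomSelect", function(x, sel, ...) standardGeneric("atomSelect"))

#' Eigenvalues of a covariance model
#'
#' @param x a \linkS4class{CovarianceModel}.
#' @return numeric vector, descending, in Angstrom^2.
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))

#' Eigenvectors of a covariance model
#'
#' @param x a \linkS4class{CovarianceModel}.
#' @return 3N x 3N matrix, one orthonormal column per mode.
#' @export
setGeneric("eigenvectors", function(x) standardGeneric("eigenvectors"))

#' Community membership of a dynamic network
#'
#' @param x a \linkS4class{DynamicNetwork}.
#' @return integer community id per node (NA before decomposition).
#' @export
setGeneric("communities", function(x) standardGeneric("communities"))

#' Modularity of the reported partition
#'
#' @param x a \linkS4class{DynamicNetwork}.
#' @return numeric Q in [-0.5, 1].
#' @export
setGeneric("modularityScore", function(x) standardGeneric("modularityScore"))
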