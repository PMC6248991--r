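#' Trajectory: a coordinate ensemble over time
#'
#' Frames x atoms x 3 Cartesian coordinates in Angstrom, per-frame times in
#' picoseconds, optional orthorhombic per-frame box edges, and the Topology
#' the atom axis refers to. Boxes are orthorhombic only; triclinic cells are
#' rejected at read time.
#'
#' @slot coords numeric array, frames x atoms x 3, Angstrom.
#' @slot times numeric, ps, strictly increasing.
#' @slot box frames x 3 matrix of box edges (Angstrom); zero rows = no box.
#' @slot topology the \linkS4class{Topology}.
#' @export
setClass("Trajectory",
         representation(coords = "array", times = "numeric",
                        box = "matrix", topology = "Topology"))

setValidity("Trajectory", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[3L] != 3L)
    return("coords must be a frames x atoms x 3 array")
  if (d[1L] < 1L) return("trajectory must have at least one frame")
  if (d[2L] != nAtoms(object@topology))
    return(sprintf("coordinate atom count (%d) != topology atom count (%d)",
                   d[2L], nAtoms(object@topology)))
  if (length(object@times) != d[1L])
    return("times must have one entry per frame")
  if (d[1L] > 1L && any(diff(object@times) <= 0))
    return("frame times must be strictly increasing")
  if (nrow(object@box) && (nrow(object@box) != d[1L] || ncol(object@box) != 3L))
    return("box must be a frames x 3 matrix (or have zero rows)")
  TRUE
})

#' Construct a Trajectory
#'
#' @param coords frames x atoms x 3 array (Angstrom). A single atoms x 3
#'   matrix is promoted to a one-frame trajectory.
#' @param topology the \linkS4class{Topology}.
#' @param times frame times in ps; default \code{0, dt, 2 dt, ...}.
#' @param box per-frame box edges: frames x 3 matrix, a length-3 vector
#'   (replicated), or NULL.
#' @param dt frame spacing in ps used when \code{times} is NULL.
#' @return a \linkS4class{Trajectory}.
#' @export
Trajectory <- function(coords, topology, times = NULL, box = NULL, dt = 1) {
  if (is.matrix(coords)) coords <- array(coords, c(1L, dim(coords)))
  nf <- dim(coords)[1L]
  if (is.null(times)) times <- (seq_len(nf) - 1) * dt
  if (is.null(box)) {
    box <- matrix(numeric(0), 0L, 3L)
  } else if (!is.matrix(box)) {
    box <- matrix(rep(as.numeric(box), each = nf), nf, 3L)
  }
  new("Trajectory", coords = coords, times = as.numeric(times),
      box = box, topology = topology)
}

#' @describeIn nFrames frames in a trajectory
#' @export
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[1L])

#' @describeIn nAtoms atoms in a trajectory
#' @export
setMethod("nAtoms", "Trajectory", function(x) dim(x@coords)[2L])

#' @describeIn frameTimes times of a trajectory
#' @export
setMethod("frameTimes", "Trajectory", function(x) x@times)

#' @describeIn coords coordinate array of a trajectory
#' @export
setMethod("coords", "Trajectory", function(x, frame = NULL) {
  if (is.null(frame)) return(x@coords)
  matrix(x@coords[frame, , ], ncol = 3L,
         dimnames = list(NULL, c("x", "y", "z")))
})

#' @describeIn boxDims box of a trajectory
#' @export
setMethod("boxDims", "Trajectory", function(x) x@box)

#' @describeIn topology topology of a trajectory
#' @export
setMethod("topology", "Trajectory", function(x) x@topology)

#' @describeIn atomData atom table of a trajectory's topology
#' @export
setMethod("atomData", "Trajectory", function(x) x@topology@atoms)

#' @describeIn atomSelect evaluate on a trajectory's topology
#' @export
setMethod("atomSelect", "Trajectory", function(x, sel, ...)
  atomSelect(x@topology, sel, ...))

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", nFrames(object), "frames x", nAtoms(object), "atoms\n")
  tt <- object@times
  cat(sprintf("  time %.6g..%.6g ps%s\n", tt[1L], tt[length(tt)],
              if (nrow(object@box)) sprintf(", box %.6g x %.6g x %.6g A",
                                            object@box[1L, 1L],
                                            object@box[1L, 2L],
                                            object@box[1L, 3L]) else ""))
})

## ---- plain frame-table format ---------------------------------------------
##
## Repo dialect, hand-writable:
##   # helixdyn frame table v1
##   natoms <N>
##   frame <time_ps> [<Lx> <Ly> <Lz>]
##   <x> <y> <z>          (N rows, Angstrom, full double precision)
##   frame <time_ps> [...]
##   ...
## Comments (#) and blank lines allowed between records.

#' Write a trajectory as a plain frame table
#'
#' Text format defined by this package (see source header): an atom-count
#' header then, per frame, a \code{frame <time> [box]} line followed by one
#' \code{x y z} row per atom. Values are written with 17 significant digits
#' so a write-then-read round trip is bit-exact.
#'
#' @param trajectory a \linkS4class{Trajectory}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeFrameTable <- function(trajectory, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nf <- nFrames(trajectory); na <- nAtoms(trajectory)
  hasBox <- nrow(trajectory@box) > 0L
  writeLines(c("# helixdyn frame table v1", paste("natoms", na)), con)
  for (f in seq_len(nf)) {
    hdr <- sprintf("frame %.17g", trajectory@times[f])
    if (hasBox)
      hdr <- paste(hdr, paste(sprintf("%.17g", trajectory@box[f, ]), collapse = " "))
    writeLines(hdr, con)
    xyz <- matrix(trajectory@coords[f, , ], ncol = 3L)
    writeLines(sprintf("%.17g %.17g %.17g", xyz[, 1L], xyz[, 2L], xyz[, 3L]), con)
  }
  invisible(path)
}

readFrameTable <- function(path, topology) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines) || !startsWith(lines[1L], "natoms"))
    stop("frame table '", path, "': missing 'natoms' header")
  na <- as.integer(strsplit(lines[1L], "[[:space:]]+")[[1L]][2L])
  if (is.na(na) || na < 1L)
    stop("frame table '", path, "': invalid atom count")
  if (na != nAtoms(topology))
    stop(sprintf("atom-count mismatch: file has %d atoms, topology has %d",
                 na, nAtoms(topology)))
  i <- 2L; n <- length(lines)
  times <- numeric(0); boxes <- NULL; frames <- list(); f <- 0L
  while (i <= n) {
    if (!startsWith(lines[i], "frame"))
      stop("frame table '", path, "': expected 'frame' header at record line ", i)
    tok <- as.numeric(strsplit(lines[i], "[[:space:]]+")[[1L]][-1L])
    if (!length(tok) %in% c(1L, 4L) || anyNA(tok))
      stop("frame table '", path, "': malformed frame header at record line ", i)
    f <- f + 1L
    if (i + na > n)
      stop(sprintf("frame table '%s': truncated frame %d (%d of %d atom rows present)",
                   path, f, n - i, na))
    block <- strsplit(lines[(i + 1L):(i + na)], "[[:space:]]+")
    if (any(vapply(block, length, 1L) != 3L))
      stop(sprintf("frame table '%s': malformed coordinate row in frame %d", path, f))
    xyz <- matrix(as.numeric(unlist(block)), ncol = 3L, byrow = TRUE)
    if (anyNA(xyz))
      stop(sprintf("frame table '%s': non-numeric coordinate in frame %d", path, f))
    times[f] <- tok[1L]
    frames[[f]] <- xyz
    if (length(tok) == 4L) boxes <- rbind(boxes, tok[2:4])
    i <- i + na + 1L
  }
  if (!f) stop("frame table '", path, "': no frames")
  if (!is.null(boxes) && nrow(boxes) != f)
    stop("frame table '", path, "': box given for some frames but not all")
  co <- array(0, c(f, na, 3L))
  for (k in seq_len(f)) co[k, , ] <- frames[[k]]
  Trajectory(co, topology, times = times, box = boxes)
}

#' Read a coordinate trajectory
#'
#' Supported containers: the package's plain frame table (format
#' \code{"table"}) and binary CHARMM/NAMD DCD (format \code{"dcd"}, read via
#' bio3d). For DCD, frame times are \code{first + (0:(n-1)) * dt} since the
#' container stores no time axis. The atom count must match the topology.
#'
#' @param path trajectory file.
#' @param topology the \linkS4class{Topology} describing the atom axis.
#' @param format \code{"auto"} (by extension), \code{"table"} or \code{"dcd"}.
#' @param dt frame spacing in ps (DCD only; default 1).
#' @param first time of the first frame in ps (DCD only).
#' @param box per-frame box edges for containers that store none.
#' @return a \linkS4class{Trajectory}.
#' @export
readTrajectory <- function(path, topology, format = c("auto", "table", "dcd"),
                           dt = 1, first = 0, box = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.dcd$", path, ignore.case = TRUE)) "dcd" else "table"
  if (format == "table") return(readFrameTable(path, topology))
  xyz <- bio3d::read.dcd(path, verbose = FALSE)
  na <- ncol(xyz) / 3L
  if (na != nAtoms(topology))
    stop(sprintf("atom-count mismatch: file has %d atoms, topology has %d",
                 na, nAtoms(topology)))
  nf <- nrow(xyz)
  co <- array(0, c(nf, na, 3L))
  for (f in seq_len(nf))
    co[f, , ] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
  Trajectory(co, topology, times = first + (seq_len(nf) - 1) * dt, box = box)
}

#' Extract a frame range or atom subset
#'
#' @param trajectory a \linkS4class{Trajectory}.
#' @param frames frame indices to keep (default all).
#' @return a \linkS4class{Trajectory} over the kept frames.
#' @export
subsetFrames <- function(trajectory, frames) {
  co <- trajectory@coords[frames, , , drop = FALSE]
  bx <- if (nrow(trajectory@box)) trajectory@box[frames, , drop = FALSE] else NULL
  Trajectory(co, trajectory@topology, times = trajectory@times[frames], box = bx)
}
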