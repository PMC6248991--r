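## Dynamical cross-correlation matrices and correlation-network community
## analysis: build a graph from residues whose C-alpha displacement
## correlation passes a cutoff, decompose it by Girvan-Newman edge-
## betweenness removal with a modularity convergence trace, filter small
## communities for reporting, and test inter-segment connectivity.

#' @useDynLib HelixDynamics, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' DCCM: dynamical cross-correlation matrix
#'
#' Normalized cross-correlations of C-alpha displacement vectors,
#' c_ij = <dr_i . dr_j> / sqrt(<dr_i^2><dr_j^2>), with dr the 3D
#' displacement from the atom's time-mean position after superposition.
#'
#' @slot c N x N symmetric matrix, unit diagonal, entries in [-1, 1].
#' @slot atoms topology atom indices of the nodes.
#' @slot resno residue numbers.
#' @slot segment segment labels.
#' @export
setClass("DCCM",
         representation(c = "matrix", atoms = "integer",
                        resno = "integer", segment = "character"))

setValidity("DCCM", function(object) {
  m <- object@c
  if (nrow(m) != ncol(m)) return("correlation matrix must be square")
  if (max(abs(m - t(m))) > 1e-10) return("correlation matrix must be symmetric")
  if (any(abs(diag(m) - 1) > 0)) return("diagonal must be exactly 1")
  if (any(m < -1 - 1e-10) || any(m > 1 + 1e-10))
    return("entries must lie in [-1, 1]")
  if (length(object@resno) != nrow(m)) return("one residue number per node")
  TRUE
})

setMethod("show", "DCCM", function(object) {
  m <- object@c
  off <- m[upper.tri(m)]
  cat(sprintf("DCCM: %d C-alpha nodes; off-diagonal range [%.3f, %.3f]\n",
              nrow(m), if (length(off)) min(off) else NA,
              if (length(off)) max(off) else NA))
})

#' Dynamical cross-correlation matrix of a C-alpha selection
#'
#' Frames are resampled at \code{stridePs} and superposed onto the first
#' frame; correlations are computed from the displacements about each
#' atom's time-mean position. The diagonal is exactly 1 by construction.
#'
#' @param trajectory a \linkS4class{Trajectory}.
#' @param selection atom indices to correlate (default: all CA atoms).
#' @param fitSelection atom indices for superposition (default =
#'   \code{selection}).
#' @param stridePs resampling stride in ps (default 100; 0 keeps every
#'   frame).
#' @param fit superpose frames onto the first frame (default TRUE; FALSE
#'   correlates raw displacements, e.g. for pre-fitted ensembles).
#' @return a \linkS4class{DCCM}.
#' @export
dccm <- function(trajectory, selection = NULL, fitSelection = NULL,
                 stridePs = 100, fit = TRUE) {
  if (is.null(selection)) {
    selection <- atomSelect(trajectory, name = "CA")
    if (!length(selection)) selection <- seq_len(nAtoms(trajectory))
  }
  if (is.null(fitSelection)) fitSelection <- selection
  keep <- strideFrames(trajectory@times, stridePs)
  if (length(keep) < 2L) stop("fewer than 2 frames retained after striding")
  tr <- subsetFrames(trajectory, keep)
  if (fit) tr <- fitFrames(tr, fitSelection)
  co <- tr@coords[, selection, , drop = FALSE]
  nf <- dim(co)[1L]
  mu <- apply(co, c(2L, 3L), mean)
  num <- matrix(0, dim(co)[2L], dim(co)[2L])
  for (k in 1:3) {
    Xc <- co[, , k] - matrix(mu[, k], nf, dim(co)[2L], byrow = TRUE)
    num <- num + crossprod(Xc) / nf
  }
  v <- diag(num)
  zero <- which(v <= 0)
  if (length(zero)) {
    a <- atomData(trajectory)[selection[zero[1L]], ]
    stop(sprintf("zero-variance atom %d (%s %s%d): correlation undefined",
                 selection[zero[1L]], a$name, a$resid, a$resno))
  }
  cmat <- num / sqrt(outer(v, v))
  cmat <- (cmat + t(cmat)) / 2
  cmat[cmat > 1] <- 1; cmat[cmat < -1] <- -1
  diag(cmat) <- 1
  a <- atomData(trajectory)[selection, , drop = FALSE]
  new("DCCM", c = cmat, atoms = as.integer(selection),
      resno = as.integer(a$resno), segment = a$segment)
}

#' DynamicNetwork: correlation graph and its community decomposition
#'
#' @slot nodes data.frame: \code{node}, \code{atom}, \code{resno},
#'   \code{segment}.
#' @slot edges data.frame: \code{i}, \code{j} (node indices, i < j,
#'   lexicographic order), \code{weight} (= |c_ij|).
#' @slot membership integer community id per node (NA before
#'   \code{\link{girvanNewman}} runs).
#' @slot trace data.frame of the modularity trace: \code{step},
#'   \code{removed_i}, \code{removed_j}, \code{betweenness}, \code{Q}
#'   (step 0 = partition before any removal).
#' @slot Q modularity of the reported partition.
#' @slot minSize community size threshold used for reporting views.
#' @export
setClass("DynamicNetwork",
         representation(nodes = "data.frame", edges = "data.frame",
                        membership = "integer", trace = "data.frame",
                        Q = "numeric", minSize = "integer"),
         prototype(membership = NA_integer_, Q = NA_real_, minSize = 1L))

setValidity("DynamicNetwork", function(object) {
  if (nrow(object@edges)) {
    if (any(object@edges$i >= object@edges$j))
      return("edges must have i < j")
    if (max(object@edges$j) > nrow(object@nodes))
      return("edge endpoint outside node set")
  }
  if (!anyNA(object@membership) && length(object@membership) &&
      length(object@membership) != nrow(object@nodes))
    return("membership must cover every node")
  if (!is.na(object@Q) && (object@Q < -0.5 - 1e-9 || object@Q > 1 + 1e-9))
    return("Q must lie in [-0.5, 1]")
  TRUE
})

setMethod("show", "DynamicNetwork", function(object) {
  cat(sprintf("DynamicNetwork: %d nodes, %d edges", nrow(object@nodes),
              nrow(object@edges)))
  if (!anyNA(object@membership)) {
    sz <- communitySizes(object)
    cat(sprintf("; %d communities (Q = %.4f), sizes %s",
                length(sz), object@Q,
                paste(sort(sz, decreasing = TRUE), collapse = " ")))
  }
  cat("\n")
})

#' @describeIn communities membership vector of a network
#' @export
setMethod("communities", "DynamicNetwork", function(x) x@membership)

#' @describeIn modularityScore modularity of the reported partition
#' @export
setMethod("modularityScore", "DynamicNetwork", function(x) x@Q)

#' Build a correlation network from a DCCM
#'
#' Residue pairs become edges when |c_ij| >= cutoff and the residues are at
#' least \code{minSeqSeparation} apart in sequence (suppressing trivial
#' backbone-neighbour correlations). Anti-correlated pairs connect through
#' the absolute value; edge weights store |c_ij|.
#'
#' @param dccm a \linkS4class{DCCM}.
#' @param cutoff correlation threshold in (0, 1] (default 0.7).
#' @param minSeqSeparation minimum |resno_i - resno_j| (default 2).
#' @return a \linkS4class{DynamicNetwork} (communities unset; an edgeless
#'   graph is allowed).
#' @export
buildNetwork <- function(dccm, cutoff = 0.7, minSeqSeparation = 2) {
  stopifnot(is(dccm, "DCCM"))
  if (cutoff <= 0 || cutoff > 1) stop("cutoff must be in (0, 1]")
  n <- nrow(dccm@c)
  nodes <- data.frame(node = seq_len(n), atom = dccm@atoms,
                      resno = dccm@resno, segment = dccm@segment,
                      stringsAsFactors = FALSE)
  idx <- which(upper.tri(dccm@c), arr.ind = TRUE)
  keep <- abs(dccm@c[idx]) >= cutoff &
    abs(dccm@resno[idx[, 1L]] - dccm@resno[idx[, 2L]]) >= minSeqSeparation
  idx <- idx[keep, , drop = FALSE]
  edges <- data.frame(i = pmin(idx[, 1L], idx[, 2L]),
                      j = pmax(idx[, 1L], idx[, 2L]),
                      weight = abs(dccm@c[idx]))
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  new("DynamicNetwork", nodes = nodes, edges = edges,
      membership = NA_integer_, trace = data.frame(), Q = NA_real_,
      minSize = 1L)
}

#' Girvan-Newman community decomposition
#'
#' Iteratively removes the edge with the greatest betweenness (shortest
#' paths unweighted; ties broken deterministically by lexicographic edge
#' order), recording the Newman-Girvan modularity Q of the component
#' partition after every removal. The returned partition is the one
#' maximizing Q along the trace (earliest step on ties). An edgeless graph
#' yields singleton communities with Q = 0.
#'
#' @param network a \linkS4class{DynamicNetwork} from
#'   \code{\link{buildNetwork}}.
#' @return the network with \code{membership}, \code{Q} and \code{trace}
#'   filled in; community ids are renumbered by decreasing size.
#' @export
girvanNewman <- function(network) {
  stopifnot(is(network, "DynamicNetwork"))
  n <- nrow(network@nodes)
  e <- network@edges
  res <- .girvanNewmanCpp(n, as.integer(e$i), as.integer(e$j))
  mem <- res$membership
  ## renumber communities by decreasing size (stable on ties by first node)
  sz <- table(mem)
  ord <- order(-as.integer(sz), as.integer(names(sz)))
  relab <- integer(length(sz))
  relab[as.integer(names(sz))[ord]] <- seq_along(ord)
  mem <- relab[mem]
  nrem <- length(res$removed)
  trace <- data.frame(
    step = 0:nrem,
    removed_i = c(NA_integer_, e$i[res$removed]),
    removed_j = c(NA_integer_, e$j[res$removed]),
    betweenness = c(NA_real_, res$removedBetweenness),
    Q = res$traceQ)
  initialize(network, membership = as.integer(mem), trace = trace,
             Q = res$Q)
}

#' Edge betweenness of a network
#'
#' Number of unweighted shortest paths crossing each edge (pairs with
#' multiple shortest paths contribute fractionally).
#'
#' @param network a \linkS4class{DynamicNetwork}.
#' @return numeric vector, one value per edge (in edge-table order).
#' @export
edgeBetweenness <- function(network) {
  stopifnot(is(network, "DynamicNetwork"))
  e <- network@edges
  .edgeBetweennessCpp(nrow(network@nodes), as.integer(e$i), as.integer(e$j))
}

#' Community sizes
#'
#' @param network a decomposed \linkS4class{DynamicNetwork}.
#' @return named integer vector of community sizes.
#' @export
communitySizes <- function(network) {
  if (anyNA(network@membership))
    stop("run girvanNewman() before inspecting communities")
  tab <- table(network@membership)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Filter communities for reporting
#'
#' Marks communities below \code{minSize} as unreported (the partition
#' itself is unchanged). Mirrors the reporting rule that only communities
#' of at least 10 C-alpha atoms are drawn.
#'
#' @param network a decomposed \linkS4class{DynamicNetwork}.
#' @param minSize minimum community size to report (default 10, >= 1).
#' @return the network with \code{minSize} set; a warning is raised when no
#'   community passes.
#' @export
filterCommunities <- function(network, minSize = 10) {
  if (minSize < 1) stop("minSize must be >= 1")
  sz <- communitySizes(network)
  if (!any(sz >= minSize))
    warning("no community reaches the reporting size ", minSize)
  initialize(network, minSize = as.integer(minSize))
}

#' Reported community ids
#'
#' @param network a decomposed, optionally filtered
#'   \linkS4class{DynamicNetwork}.
#' @return integer ids of communities meeting the reporting size.
#' @export
reportedCommunities <- function(network) {
  sz <- communitySizes(network)
  as.integer(names(sz)[sz >= network@minSize])
}

#' Inter-segment connectivity verdict
#'
#' Two segments are connected when a reported community dominated by
#' segment A is linked to one dominated by segment B by an edge of the
#' network, or when a single reported community is jointly dominated by
#' both. "Dominated" means the segment attains the plurality of the
#' community's members (ties allowed). With \code{segmentA == segmentB} the
#' verdict is TRUE iff the segment hosts at least one reported community.
#'
#' @param network a decomposed \linkS4class{DynamicNetwork}; apply
#'   \code{\link{filterCommunities}} first to control the reporting size.
#' @param segmentA,segmentB segment labels from
#'   \code{\link{segmentLevels}}.
#' @return list with \code{connected} (logical), \code{supporting}
#'   (data.frame of residue pairs or community members backing the
#'   verdict) and \code{communities} (per-community segment dominance
#'   table).
#' @export
connectivityReport <- function(network, segmentA, segmentB) {
  bad <- setdiff(c(segmentA, segmentB), segmentLevels())
  if (length(bad))
    stop("unknown segment label(s): ", paste(bad, collapse = ", "))
  mem <- network@membership
  if (anyNA(mem)) stop("run girvanNewman() before connectivity reporting")
  nodes <- network@nodes
  rep_ids <- reportedCommunities(network)
  ## per-community dominant segments (plurality, ties allowed)
  dominant <- lapply(rep_ids, function(cid) {
    tab <- table(nodes$segment[mem == cid])
    names(tab)[tab == max(tab)]
  })
  names(dominant) <- rep_ids
  commTab <- data.frame(
    community = rep_ids,
    size = as.integer(table(mem)[as.character(rep_ids)]),
    dominant = vapply(dominant, paste, "", collapse = "+"))
  hostsA <- rep_ids[vapply(dominant, function(d) segmentA %in% d, TRUE)]
  hostsB <- rep_ids[vapply(dominant, function(d) segmentB %in% d, TRUE)]

  if (segmentA == segmentB) {
    sup <- if (length(hostsA))
      nodes[mem %in% hostsA, c("resno", "segment")] else data.frame()
    return(list(connected = length(hostsA) > 0, supporting = sup,
                communities = commTab))
  }
  ## joint membership: one reported community dominated by both
  joint <- intersect(hostsA, hostsB)
  if (length(joint)) {
    members <- nodes[mem %in% joint & nodes$segment %in% c(segmentA, segmentB),
                     c("resno", "segment")]
    return(list(connected = TRUE, supporting = members,
                communities = commTab))
  }
  ## inter-community edges between an A-dominated and a B-dominated community
  e <- network@edges
  if (nrow(e)) {
    ci <- mem[e$i]; cj <- mem[e$j]
    hit <- (ci %in% hostsA & cj %in% hostsB) |
      (ci %in% hostsB & cj %in% hostsA)
    if (any(hit)) {
      sup <- data.frame(resnoA = nodes$resno[e$i[hit]],
                        segmentA = nodes$segment[e$i[hit]],
                        resnoB = nodes$resno[e$j[hit]],
                        segmentB = nodes$segment[e$j[hit]],
                        weight = e$weight[hit])
      return(list(connected = TRUE, supporting = sup, communities = commTab))
    }
  }
  list(connected = FALSE, supporting = data.frame(), communities = commTab)
}
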