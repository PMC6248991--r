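## Dictionary-based secondary-structure accounting (Kabsch-Sander backbone
## H-bond energies with rebuilt amide hydrogens), residue contact maps and
## geometric hydrogen-bond detection.

.proteinSegments <- c(paste0("TM", 1:7), "H8", paste0("IL", 1:3),
                      paste0("EL", 1:3), "NT", "CT", "OTHER")

## per-residue backbone atom index table for the selected protein residues
backboneTable <- function(topology, selection) {
  a <- atomData(topology)
  sel <- selection[a$segment[selection] %in% .proteinSegments]
  res <- unique(data.frame(chain = a$chain[sel], resno = a$resno[sel]))
  res <- res[order(res$chain, res$resno), , drop = FALSE]
  find <- function(ch, rn, nm) {
    i <- sel[a$chain[sel] == ch & a$resno[sel] == rn & a$name[sel] == nm]
    if (length(i)) i[1L] else NA_integer_
  }
  tab <- data.frame(chain = res$chain, resno = res$resno)
  for (nm in c("N", "CA", "C", "O"))
    tab[[nm]] <- mapply(find, res$chain, res$resno, nm)
  tab$segment <- a$segment[tab$CA]
  miss <- is.na(tab$N) | is.na(tab$CA) | is.na(tab$C) | is.na(tab$O)
  if (any(miss))
    stop("missing backbone atoms (need N, CA, C, O) for residues: ",
         paste(tab$resno[miss], collapse = ", "))
  tab
}

## Kabsch-Sander H-bond energy matrix for one frame: E[i, j] is the energy
## of the bond donated by the N-H of residue i to the C=O of residue j.
## Amide H rebuilt 1.0 A from N along the bisector of (N - C_prev) and
## (N - CA); chain-leading residues have no H and donate nothing.
ksEnergy <- function(xyz, tab) {
  n <- nrow(tab)
  N <- xyz[tab$N, , drop = FALSE]; CA <- xyz[tab$CA, , drop = FALSE]
  C <- xyz[tab$C, , drop = FALSE]; O <- xyz[tab$O, , drop = FALSE]
  prev <- c(NA_integer_, seq_len(n - 1L))
  contiguous <- c(FALSE, tab$resno[-1L] == tab$resno[-n] + 1L &
                           tab$chain[-1L] == tab$chain[-n])
  H <- matrix(NA_real_, n, 3L)
  for (i in which(contiguous)) {
    u <- N[i, ] - C[prev[i], ]; u <- u / sqrt(sum(u^2))
    v <- N[i, ] - CA[i, ]; v <- v / sqrt(sum(v^2))
    b <- u + v; b <- b / sqrt(sum(b^2))
    H[i, ] <- N[i, ] + b
  }
  E <- matrix(Inf, n, n)
  dist1 <- function(P, Q) sqrt(rowSums((P - Q)^2))
  for (i in which(contiguous)) {
    Ni <- matrix(N[i, ], n, 3L, byrow = TRUE)
    Hi <- matrix(H[i, ], n, 3L, byrow = TRUE)
    rON <- dist1(O, Ni); rCN <- dist1(C, Ni)
    rOH <- dist1(O, Hi); rCH <- dist1(C, Hi)
    E[i, ] <- 0.084 * 332 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
  }
  ## no bond with self or sequence neighbours
  for (i in seq_len(n)) {
    lo <- max(1L, i - 1L); hi <- min(n, i + 1L)
    E[i, lo:hi] <- Inf
  }
  E
}

## classes for one frame from the H-bond pattern (priority H > G > I > T)
ssFromEnergy <- function(E, tab, cutoff = -0.5) {
  n <- nrow(tab)
  bonded <- E < cutoff
  sameRun <- function(i, j)  # both ends in one contiguous chain stretch
    all(tab$chain[i:j] == tab$chain[i]) && all(diff(tab$resno[i:j]) == 1L)
  turn <- function(k) {
    t <- rep(FALSE, n)
    for (i in seq_len(n - k)) {
      if (bonded[i + k, i] && sameRun(i, i + k)) t[i] <- TRUE
    }
    t
  }
  t3 <- turn(3L); t4 <- turn(4L); t5 <- turn(5L)
  cls <- rep("C", n)
  mark <- function(tn, k, letter) {
    for (i in which(tn)) {
      if (i > 1L && tn[i - 1L]) {
        span <- i:(i + k - 1L)
        span <- span[cls[span] == "C"]
        cls[span] <<- letter
      }
    }
  }
  mark(t4, 4L, "H")
  mark(t3, 3L, "G")
  mark(t5, 5L, "I")
  ## isolated turns
  for (k in c(3L, 4L, 5L)) {
    tn <- list(`3` = t3, `4` = t4, `5` = t5)[[as.character(k)]]
    for (i in which(tn)) {
      span <- (i + 1L):(i + k - 1L)
      span <- span[span <= n & cls[span] == "C"]
      cls[span] <- "T"
    }
  }
  cls
}

#' Secondary-structure assignment from backbone H-bond patterns
#'
#' Implements the Kabsch-Sander dictionary: a backbone hydrogen bond is
#' declared when the electrostatic energy
#' E = 0.084 (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) * 332 kcal/mol falls below
#' -0.5 kcal/mol (amide H rebuilt at 1.0 A along the backbone bisector);
#' alpha-helix (H) from consecutive i -> i+4 bond patterns, 3-10 (G) and pi
#' (I) helices from i -> i+3 / i -> i+5 analogously, isolated turns T, coil
#' C. Strand (E) and bend (S) classes are part of the vocabulary but are
#' not assigned (helix-bundle scope).
#'
#' @param trajectory a \linkS4class{Trajectory} with backbone N, CA, C, O.
#' @param selection protein atom indices (default: all protein-segment
#'   atoms).
#' @return object of class \code{SSAssignment}: list with \code{classes}
#'   (residues x frames character matrix), \code{resno}, \code{segment},
#'   and \code{helixCounts} (data.frame: segment, time, count of H
#'   residues).
#' @export
assignSecondaryStructure <- function(trajectory, selection = NULL) {
  top <- topology(trajectory)
  if (is.null(selection)) {
    a <- atomData(top)
    selection <- which(a$segment %in% .proteinSegments)
  }
  tab <- backboneTable(top, selection)
  nf <- nFrames(trajectory)
  cls <- matrix("C", nrow(tab), nf,
                dimnames = list(tab$resno, NULL))
  for (f in seq_len(nf)) {
    xyz <- coords(trajectory, f)
    cls[, f] <- ssFromEnergy(ksEnergy(xyz, tab), tab)
  }
  segs <- unique(tab$segment)
  hc <- do.call(rbind, lapply(segs, function(s) {
    rows <- tab$segment == s
    data.frame(segment = s, time = trajectory@times,
               count = colSums(cls[rows, , drop = FALSE] == "H"))
  }))
  structure(list(classes = cls, resno = tab$resno, segment = tab$segment,
                 helixCounts = hc),
            class = "SSAssignment")
}

#' Replica summary of helix residue counts
#'
#' Per-segment time-averaged alpha-helix residue counts, aggregated over
#' replicas (unweighted mean and SD, one value per replica per segment).
#'
#' @param assignments list of \code{SSAssignment} objects (one per
#'   replica).
#' @return data.frame with \code{segment}, \code{mean}, \code{sd}.
#' @export
helixCountSummary <- function(assignments) {
  if (inherits(assignments, "SSAssignment")) assignments <- list(assignments)
  per <- lapply(assignments, function(a)
    tapply(a$helixCounts$count, a$helixCounts$segment, mean))
  segs <- names(per[[1L]])
  m <- vapply(per, function(p) as.numeric(p[segs]), numeric(length(segs)))
  m <- matrix(m, nrow = length(segs))
  data.frame(segment = segs, mean = rowMeans(m),
             sd = if (ncol(m) > 1L) apply(m, 1L, stats::sd) else 0,
             row.names = NULL)
}

#' Residue contact map around a focal selection
#'
#' A partner residue is in contact in a frame when the minimum heavy-atom
#' distance between the focal atoms and the partner's atoms is at most
#' \code{cutoff}. Reports per-frame events and the occupancy fraction per
#' partner residue.
#'
#' @param trajectory a \linkS4class{Trajectory}.
#' @param focalSelection atom indices of the focal residue (e.g. its
#'   side-chain atoms).
#' @param candidateSelection atom indices of candidate partners (the focal
#'   residue itself is excluded).
#' @param cutoff heavy-atom distance cutoff, Angstrom (default 4.5, > 0).
#' @return object of class \code{ContactMap}: list with \code{events}
#'   (partners x frames logical matrix), \code{occupancy} (data.frame:
#'   resno, segment, occupancy) and \code{times}.
#' @export
contactMap <- function(trajectory, focalSelection, candidateSelection,
                       cutoff = 4.5) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (!length(focalSelection) || !length(candidateSelection))
    stop("selections must be non-empty")
  a <- atomData(trajectory)
  heavy <- a$element != "H"
  focalSelection <- focalSelection[heavy[focalSelection]]
  focalRes <- unique(paste(a$chain[focalSelection], a$resno[focalSelection]))
  cand <- candidateSelection[heavy[candidateSelection]]
  cand <- cand[!(paste(a$chain[cand], a$resno[cand]) %in% focalRes)]
  if (!length(focalSelection) || !length(cand))
    stop("selections must contain heavy atoms outside the focal residue")
  key <- paste(a$chain[cand], a$resno[cand])
  partners <- unique(key)
  nf <- nFrames(trajectory)
  ev <- matrix(FALSE, length(partners), nf,
               dimnames = list(partners, NULL))
  for (f in seq_len(nf)) {
    xyz <- coords(trajectory, f)
    F0 <- xyz[focalSelection, , drop = FALSE]
    P <- xyz[cand, , drop = FALSE]
    ## min distance from each candidate atom to the focal set
    d2 <- outer(rowSums(P^2), rowSums(F0^2), `+`) - 2 * P %*% t(F0)
    dmin <- sqrt(pmax(apply(d2, 1L, min), 0))
    hit <- tapply(dmin, key, min) <= cutoff
    ev[names(hit), f] <- as.logical(hit)
  }
  occ <- data.frame(resno = a$resno[cand][match(partners, key)],
                    segment = a$segment[cand][match(partners, key)],
                    occupancy = rowMeans(ev))
  structure(list(events = ev, occupancy = occ, times = trajectory@times),
            class = "ContactMap")
}

## amide H rebuilt for a backbone N lacking an explicit hydrogen
rebuildAmideH <- function(xyz, a, donor) {
  rn <- a$resno[donor]; ch <- a$chain[donor]
  Cp <- which(a$resno == rn - 1L & a$chain == ch & a$name == "C")
  CA <- which(a$resno == rn & a$chain == ch & a$name == "CA")
  if (!length(Cp) || !length(CA)) return(NULL)
  u <- xyz[donor, ] - xyz[Cp[1L], ]; u <- u / sqrt(sum(u^2))
  v <- xyz[donor, ] - xyz[CA[1L], ]; v <- v / sqrt(sum(v^2))
  b <- u + v; b <- b / sqrt(sum(b^2))
  xyz[donor, ] + b
}

#' Geometric hydrogen-bond detection
#'
#' A bond exists in a frame when the donor-acceptor heavy-atom distance is
#' at most \code{dCut} and the donor-H-acceptor angle is at least
#' \code{angleCut}. Donors are N/O atoms of the donor selection carrying an
#' explicit hydrogen (same residue, within 1.25 A in frame 1); backbone
#' amide nitrogens without explicit H get one rebuilt from the local
#' geometry. Each (donor, H, acceptor) triplet is tracked separately, so
#' e.g. the two carboxylate oxygens of an aspartate accumulate independent
#' occupancies.
#'
#' @param trajectory a \linkS4class{Trajectory}.
#' @param donorSelection atom indices containing candidate donor heavy
#'   atoms (their hydrogens may be inside or outside the selection).
#' @param acceptorSelection atom indices containing candidate acceptor N/O
#'   atoms.
#' @param dCut donor-acceptor distance cutoff, Angstrom (default 3.5).
#' @param angleCut minimum donor-H-acceptor angle, degrees (default 120).
#' @return data.frame with one row per observed triplet: \code{donor},
#'   \code{hydrogen} (NA when rebuilt), \code{acceptor}, donor/acceptor
#'   residue info, and \code{occupancy}; attribute \code{events} holds the
#'   triplets x frames logical matrix.
#' @export
hbonds <- function(trajectory, donorSelection, acceptorSelection,
                   dCut = 3.5, angleCut = 120) {
  a <- atomData(trajectory)
  xyz1 <- coords(trajectory, 1L)
  donors <- donorSelection[a$element[donorSelection] %in% c("N", "O")]
  acceptors <- acceptorSelection[a$element[acceptorSelection] %in% c("N", "O")]
  if (!length(donors) || !length(acceptors)) {
    warning("no donor or acceptor heavy atoms in the selections")
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), occupancy = numeric(0)))
  }
  hyd <- which(a$element == "H")
  pairs <- NULL  # (donor, hydrogen) with NA hydrogen = rebuilt amide H
  for (d in donors) {
    hs <- hyd[a$resno[hyd] == a$resno[d] & a$chain[hyd] == a$chain[d]]
    if (length(hs)) {
      dd <- sqrt(rowSums((xyz1[hs, , drop = FALSE] -
                            matrix(xyz1[d, ], length(hs), 3L, byrow = TRUE))^2))
      hs <- hs[dd <= 1.25]
    }
    if (length(hs)) {
      pairs <- rbind(pairs, cbind(d, hs))
    } else if (a$name[d] == "N") {
      pairs <- rbind(pairs, cbind(d, NA_integer_))
    }
  }
  if (is.null(pairs)) {
    warning("no usable donor-hydrogen pairs")
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), occupancy = numeric(0)))
  }
  nf <- nFrames(trajectory)
  triplets <- NULL; events <- NULL
  for (p in seq_len(nrow(pairs))) {
    d <- pairs[p, 1L]; h <- pairs[p, 2L]
    acc <- acceptors[!(a$resno[acceptors] == a$resno[d] &
                         a$chain[acceptors] == a$chain[d])]
    if (!length(acc)) next
    pres <- matrix(FALSE, length(acc), nf)
    for (f in seq_len(nf)) {
      xyz <- coords(trajectory, f)
      Hpos <- if (is.na(h)) rebuildAmideH(xyz, a, d) else xyz[h, ]
      if (is.null(Hpos)) next
      D <- xyz[d, ]
      A3 <- xyz[acc, , drop = FALSE]
      dda <- sqrt(rowSums(sweep(A3, 2L, D)^2))
      v1 <- matrix(D - Hpos, length(acc), 3L, byrow = TRUE)
      v2 <- sweep(A3, 2L, Hpos)
      csang <- rowSums(v1 * v2) /
        (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
      ang <- acos(pmin(pmax(csang, -1), 1)) * 180 / pi
      pres[, f] <- dda <= dCut & ang >= angleCut
    }
    seen <- which(rowSums(pres) > 0)
    for (s in seen) {
      triplets <- rbind(triplets,
                        data.frame(donor = d, hydrogen = h, acceptor = acc[s]))
      events <- rbind(events, pres[s, ])
    }
  }
  if (is.null(triplets))
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), occupancy = numeric(0)))
  out <- data.frame(triplets,
                    donorResno = a$resno[triplets$donor],
                    donorName = a$name[triplets$donor],
                    acceptorResno = a$resno[triplets$acceptor],
                    acceptorName = a$name[triplets$acceptor],
                    occupancy = rowMeans(events))
  attr(out, "events") <- events
  out
}
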