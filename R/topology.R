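#' Segment vocabulary
#'
#' Canonical structural segment labels for a 7-helix-bundle receptor:
#' transmembrane helices TM1-TM7, the amphipathic helix 8 (H8),
#' intracellular/extracellular loops, termini, and environment classes.
#'
#' @export
segmentLevels <- function() {
  c(paste0("TM", 1:7), "H8",
    paste0("IL", 1:3), paste0("EL", 1:3),
    "NT", "CT", "LIPID", "WATER", "ION", "OTHER")
}

#' Topology: atoms, residues and segment assignments
#'
#' Holds one row per atom (name, element, residue number and name, chain,
#' structural segment) plus optional masses. Atom order defines the internal
#' 1-based atom index every selection and trajectory refers to; residue
#' numbers are author-provided biological numbering (e.g. 358-646 for a
#' receptor transmembrane domain).
#'
#' @slot atoms data.frame with columns \code{name}, \code{element},
#'   \code{resno}, \code{resid}, \code{chain}, \code{segment}.
#' @slot masses numeric vector (amu), length 0 or one per atom.
#' @export
setClass("Topology",
         representation(atoms = "data.frame", masses = "numeric"),
         prototype(masses = numeric(0)))

setValidity("Topology", function(object) {
  a <- object@atoms
  need <- c("name", "element", "resno", "resid", "chain", "segment")
  miss <- setdiff(need, names(a))
  if (length(miss))
    return(paste("atoms table lacks columns:", paste(miss, collapse = ", ")))
  if (nrow(a) < 1L) return("topology must contain at least one atom")
  bad <- setdiff(unique(a$segment), segmentLevels())
  if (length(bad))
    return(paste("unknown segment labels:", paste(bad, collapse = ", ")))
  ## every residue maps to exactly one segment
  key <- paste(a$chain, a$resno)
  nseg <- tapply(a$segment, key, function(s) length(unique(s)))
  if (any(nseg > 1L))
    return(paste("residues mapped to multiple segments:",
                 paste(names(nseg)[nseg > 1L], collapse = ", ")))
  if (length(object@masses) && length(object@masses) != nrow(a))
    return("masses must be empty or one per atom")
  TRUE
})

#' Construct a Topology
#'
#' @param atoms data.frame with columns \code{name}, \code{element},
#'   \code{resno}, \code{resid}, \code{chain}, \code{segment}. Missing
#'   \code{element} is inferred from the first letter of the atom name;
#'   missing \code{chain} defaults to \code{"A"}; missing \code{segment}
#'   defaults to \code{"OTHER"}.
#' @param masses optional numeric vector, amu, one per atom.
#' @return a \linkS4class{Topology}.
#' @export
Topology <- function(atoms, masses = numeric(0)) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (is.null(atoms$element))
    atoms$element <- substr(trimws(atoms$name), 1L, 1L)
  if (is.null(atoms$chain)) atoms$chain <- "A"
  if (is.null(atoms$segment)) atoms$segment <- "OTHER"
  if (is.null(atoms$resid)) atoms$resid <- "UNK"
  rownames(atoms) <- NULL
  new("Topology", atoms = atoms, masses = as.numeric(masses))
}

#' @describeIn nAtoms atoms in a topology
#' @export
setMethod("nAtoms", "Topology", function(x) nrow(x@atoms))

#' @describeIn atomData atom table of a topology
#' @export
setMethod("atomData", "Topology", function(x) x@atoms)

setMethod("show", "Topology", function(object) {
  a <- object@atoms
  segs <- table(a$segment)
  cat("Topology:", nrow(a), "atoms,",
      length(unique(paste(a$chain, a$resno))), "residues\n")
  cat("  segments:",
      paste(sprintf("%s(%d)", names(segs), as.integer(segs)), collapse = " "),
      "\n")
})

## ---- segment configuration -------------------------------------------------

#' Read a segment-definition config
#'
#' Maps residue ranges to segment labels. Accepts a data.frame with columns
#' \code{segment}, \code{first}, \code{last}, or a path to a plain-text file
#' with one \code{segment first last} triple per line (blank lines and lines
#' starting with \code{#} ignored). Ranges must not overlap.
#'
#' @param x data.frame or file path.
#' @return data.frame with columns \code{segment}, \code{first}, \code{last}.
#' @export
readSegmentConfig <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    lines <- readLines(x, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    parts <- strsplit(lines, "[[:space:]:,-]+")
    bad <- which(vapply(parts, length, 1L) != 3L)
    if (length(bad))
      stop("segment config: cannot parse line ", bad[1L], ": '", lines[bad[1L]], "'")
    cfg <- data.frame(segment = vapply(parts, `[`, "", 1L),
                      first = as.integer(vapply(parts, `[`, "", 2L)),
                      last = as.integer(vapply(parts, `[`, "", 3L)),
                      stringsAsFactors = FALSE)
  } else {
    cfg <- as.data.frame(x, stringsAsFactors = FALSE)
  }
  if (!all(c("segment", "first", "last") %in% names(cfg)))
    stop("segment config needs columns segment, first, last")
  bad <- setdiff(cfg$segment, segmentLevels())
  if (length(bad))
    stop("segment config: unknown segment labels: ", paste(bad, collapse = ", "))
  if (any(cfg$first > cfg$last))
    stop("segment config: range with first > last")
  ## overlapping ranges are a config error
  o <- order(cfg$first)
  f <- cfg$first[o]; l <- cfg$last[o]
  if (nrow(cfg) > 1L && any(f[-1L] <= l[-nrow(cfg)]))
    stop("segment config: overlapping residue ranges")
  cfg
}

segmentOfResno <- function(resno, cfg) {
  seg <- rep("OTHER", length(resno))
  for (k in seq_len(nrow(cfg))) {
    hit <- resno >= cfg$first[k] & resno <= cfg$last[k]
    seg[hit] <- cfg$segment[k]
  }
  seg
}

## residue names classified as solvent/lipid/ion environment
.waterResid <- c("HOH", "WAT", "TIP", "TIP3", "SPC", "SOL")
.ionResid <- c("NA", "CL", "K", "SOD", "CLA", "POT", "MG", "CA2")
.lipidResid <- c("SDP", "SDPC", "POPC", "POPE", "DPPC", "DOPC", "LIP", "CHL")

#' Read a topology from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d) and assigns structural segments
#' from a residue-range config. Protein residues outside every configured
#' range get segment OTHER; waters, lipids and ions are classified by
#' residue name.
#'
#' @param path PDB file.
#' @param segmentConfig optional segment config (see
#'   \code{\link{readSegmentConfig}}).
#' @return a \linkS4class{Topology}.
#' @export
readTopology <- function(path, segmentConfig = NULL) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("PDB parse error in '", path, "': ",
                                           conditionMessage(e)))
  at <- pdb$atom
  if (anyDuplicated(at$eleno))
    stop("PDB '", path, "': duplicate atom serial number ",
         at$eleno[duplicated(at$eleno)][1L])
  resid <- toupper(trimws(at$resid))
  seg <- rep("OTHER", nrow(at))
  seg[resid %in% .waterResid] <- "WATER"
  seg[resid %in% .ionResid] <- "ION"
  seg[resid %in% .lipidResid] <- "LIPID"
  env <- seg != "OTHER"
  if (!is.null(segmentConfig)) {
    cfg <- readSegmentConfig(segmentConfig)
    seg[!env] <- segmentOfResno(at$resno[!env], cfg)
  }
  elem <- trimws(at$elesy)
  noel <- is.na(elem) | !nzchar(elem)
  elem[noel] <- substr(gsub("[0-9]", "", trimws(at$elety[noel])), 1L, 1L)
  Topology(data.frame(name = trimws(at$elety), element = elem,
                      resno = at$resno, resid = resid,
                      chain = ifelse(is.na(at$chain) | !nzchar(at$chain),
                                     "A", at$chain),
                      segment = seg, stringsAsFactors = FALSE))
}

#' Write a structure as PDB
#'
#' Writes one coordinate set (topology + atoms x 3 matrix) as a PDB file
#' through bio3d, preserving residue numbering and atom names.
#'
#' @param topology a \linkS4class{Topology}.
#' @param xyz atoms x 3 coordinate matrix, Angstrom.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeStructurePDB <- function(topology, xyz, path) {
  a <- atomData(topology)
  if (!is.matrix(xyz) || nrow(xyz) != nrow(a) || ncol(xyz) != 3L)
    stop("xyz must be an atoms x 3 matrix matching the topology")
  bio3d::write.pdb(file = path, xyz = as.numeric(t(xyz)),
                   resno = a$resno, resid = a$resid,
                   eleno = seq_len(nrow(a)), elety = a$name,
                   chain = a$chain)
  invisible(path)
}

## ---- selections ------------------------------------------------------------

#' Selection: a reusable atom predicate
#'
#' A conjunction of per-field criteria over topology atoms. Empty criteria
#' match everything; evaluation is topology-only (frame content never
#' matters) and returns sorted 1-based atom indices.
#'
#' @slot name character, atom names to match (empty = any).
#' @slot element character, element symbols.
#' @slot resno numeric, residue numbers.
#' @slot segment character, segment labels.
#' @slot chain character, chain ids.
#' @export
setClass("Selection",
         representation(name = "character", element = "character",
                        resno = "numeric", segment = "character",
                        chain = "character"),
         prototype(name = character(0), element = character(0),
                   resno = numeric(0), segment = character(0),
                   chain = character(0)))

#' Build a Selection
#'
#' @param name atom names (e.g. \code{"CA"}).
#' @param element element symbols (e.g. \code{"O"}).
#' @param resno residue numbers (e.g. \code{358:646}).
#' @param segment segment labels (e.g. \code{c("TM2","TM5")}); must belong
#'   to \code{\link{segmentLevels}}.
#' @param chain chain identifiers.
#' @return a \linkS4class{Selection}.
#' @examples
#' selection(name = "CA", resno = 358:646)
#' @export
selection <- function(name = character(0), element = character(0),
                      resno = numeric(0), segment = character(0),
                      chain = character(0)) {
  bad <- setdiff(segment, segmentLevels())
  if (length(bad))
    stop("unknown segment label(s): ", paste(bad, collapse = ", "))
  new("Selection", name = as.character(name), element = as.character(element),
      resno = as.numeric(resno), segment = as.character(segment),
      chain = as.character(chain))
}

setMethod("show", "Selection", function(object) {
  parts <- character(0)
  if (length(object@name)) parts <- c(parts, paste0("name %in% {", paste(object@name, collapse = ","), "}"))
  if (length(object@element)) parts <- c(parts, paste0("element %in% {", paste(object@element, collapse = ","), "}"))
  if (length(object@resno)) parts <- c(parts, paste0("resno in [", min(object@resno), ",", max(object@resno), "]"))
  if (length(object@segment)) parts <- c(parts, paste0("segment %in% {", paste(object@segment, collapse = ","), "}"))
  if (length(object@chain)) parts <- c(parts, paste0("chain %in% {", paste(object@chain, collapse = ","), "}"))
  cat("Selection:", if (length(parts)) paste(parts, collapse = " & ") else "<all atoms>", "\n")
})

#' @describeIn atomSelect evaluate on a topology
#' @export
setMethod("atomSelect", "Topology", function(x, sel, ...) {
  if (missing(sel)) sel <- selection(...)
  if (!is(sel, "Selection")) stop("sel must be a Selection")
  a <- x@atoms
  keep <- rep(TRUE, nrow(a))
  if (length(sel@name)) keep <- keep & a$name %in% sel@name
  if (length(sel@element)) keep <- keep & a$element %in% sel@element
  if (length(sel@resno)) keep <- keep & a$resno %in% sel@resno
  if (length(sel@segment)) keep <- keep & a$segment %in% sel@segment
  if (length(sel@chain)) keep <- keep & a$chain %in% sel@chain
  sort(which(keep))
})
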