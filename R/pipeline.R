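## Per-phenotype orchestration: fit -> RMSD/RMSF -> secondary structure ->
## density/hydration -> PCA/cosine content -> DCCM -> network ->
## connectivity verdict, from a single config, with replica handling and a
## cross-phenotype comparison.

#' Validate a study configuration
#'
#' A config is a named list (or a YAML file) with:
#' \describe{
#'   \item{label}{phenotype label, e.g. "I1".}
#'   \item{topology}{a \linkS4class{Topology}, or list(pdb = path,
#'     segments = segment-config path).}
#'   \item{replicas}{list of \linkS4class{Trajectory} objects or frame-table
#'     paths (first entry = main run R0).}
#'   \item{caRange}{optional residue range for the C-alpha analyses.}
#'   \item{pcaStridePs, networkStridePs}{strides in ps (defaults 4, 100).}
#'   \item{cutoff, minSeqSeparation, minCommunity}{network parameters
#'     (defaults 0.7, 2, 10).}
#'   \item{report}{length-2 segment pair for the connectivity verdict
#'     (default c("TM2", "TM5")).}
#'   \item{density}{optional list(groups = named selections/indices,
#'     binWidth, interval) computed on \code{replicas} when present, or on
#'     \code{densityReplicas}.}
#'   \item{outputDir}{where tables are written (created if needed).}
#'   \item{seed}{integer recorded in the manifest (analyses are
#'     deterministic; the seed documents upstream generation).}
#' }
#'
#' @param config list or YAML file path.
#' @return the normalized config (defaults filled in).
#' @export
validateStudyConfig <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or YAML path")
  if (is.null(config$label)) stop("config needs a phenotype label")
  if (is.null(config$replicas) || !length(config$replicas))
    stop("config needs at least one replica trajectory")
  paths <- unlist(Filter(is.character, config$replicas))
  missing <- if (length(paths)) paths[!file.exists(paths)] else character(0)
  if (length(missing))
    stop("missing replica file(s): ", paste(missing, collapse = ", "))
  if (!is.null(config$topology) && is.list(config$topology) &&
      !is(config$topology, "Topology")) {
    if (!file.exists(config$topology$pdb))
      stop("missing topology PDB: ", config$topology$pdb)
  }
  defaults <- list(pcaStridePs = 4, networkStridePs = 100, cutoff = 0.7,
                   minSeqSeparation = 2, minCommunity = 10,
                   report = c("TM2", "TM5"), seed = 1L,
                   outputDir = file.path(tempdir(), config$label))
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  config
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

writeTable <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(format(df, digits = 12, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  path
}

#' Run the full per-phenotype analysis
#'
#' Executes every analysis stage on the configured replicas and writes tidy
#' CSV tables plus a JSON manifest under the output directory. All stages
#' are deterministic given the config (and any generation seed recorded in
#' it); rerunning reproduces the tables byte for byte.
#'
#' @param config see \code{\link{validateStudyConfig}}.
#' @return object of class \code{StudyReport}: list with \code{label},
#'   \code{rmsf}, \code{helix}, \code{cc}, \code{eigenvalues},
#'   \code{network}, \code{connectivity}, \code{hydration}, \code{files}.
#' @export
runStudy <- function(config) {
  config <- validateStudyConfig(config)
  dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
  top <- stage("topology", {
    if (is(config$topology, "Topology")) config$topology
    else readTopology(config$topology$pdb, config$topology$segments)
  })
  trajs <- stage("trajectories", lapply(config$replicas, function(r)
    if (is(r, "Trajectory")) r else readTrajectory(r, top)))
  caSel <- if (is.null(config$caRange)) atomSelect(top, name = "CA")
           else atomSelect(top, name = "CA", resno = config$caRange)
  if (!length(caSel)) stop("stage 'selection' failed: no C-alpha atoms")
  files <- character(0)

  rmsf <- stage("rmsf", rmsfProfile(trajs[[1L]], fitSelection = caSel,
                                    measureSelection = caSel,
                                    replicas = trajs[-1L]))
  files["rmsf"] <- writeTable(rmsf, config$outputDir, "rmsf.csv")

  helix <- NULL
  hasBackbone <- all(c("N", "C", "O") %in%
                       atomData(top)$name[atomData(top)$segment %in%
                                            .proteinSegments])
  if (hasBackbone) {
    helix <- stage("secondary_structure", {
      ass <- lapply(trajs, assignSecondaryStructure)
      helixCountSummary(ass)
    })
    files["helix"] <- writeTable(helix, config$outputDir, "helix_counts.csv")
  }

  ed <- stage("essential_dynamics", {
    model <- covarianceModel(trajs[[1L]], fitSelection = caSel,
                             pcaSelection = caSel,
                             stridePs = config$pcaStridePs)
    cc <- vapply(seq_along(trajs), function(k) {
      pr <- projectTrajectory(trajs[[k]], model, 1L)
      cosineContent(pr)
    }, numeric(1L))
    list(model = model,
         cc = data.frame(replica = paste0("R", seq_along(trajs) - 1L),
                         cc = cc),
         eig = data.frame(mode = seq_along(eigenvalues(model)),
                          eigenvalue = eigenvalues(model)))
  })
  files["cc"] <- writeTable(ed$cc, config$outputDir, "cosine_content.csv")
  files["eigenvalues"] <- writeTable(ed$eig, config$outputDir,
                                     "eigenvalues.csv")

  net <- stage("network", {
    cm <- dccm(trajs[[1L]], selection = caSel,
               stridePs = config$networkStridePs)
    nw <- buildNetwork(cm, cutoff = config$cutoff,
                       minSeqSeparation = config$minSeqSeparation)
    nw <- girvanNewman(nw)
    suppressWarnings(filterCommunities(nw, config$minCommunity))
  })
  commTab <- data.frame(net@nodes, community = net@membership,
                        reported = net@membership %in%
                          reportedCommunities(net))
  files["communities"] <- writeTable(commTab, config$outputDir,
                                     "communities.csv")
  files["edges"] <- writeTable(
    data.frame(resnoA = net@nodes$resno[net@edges$i],
               resnoB = net@nodes$resno[net@edges$j],
               weight = net@edges$weight),
    config$outputDir, "network_edges.csv")

  conn <- stage("connectivity",
                connectivityReport(net, config$report[1L], config$report[2L]))
  files["connectivity"] <- writeTable(
    data.frame(segmentA = config$report[1L], segmentB = config$report[2L],
               connected = conn$connected, Q = modularityScore(net)),
    config$outputDir, "connectivity.csv")

  hydration <- NULL
  if (!is.null(config$density)) {
    hydration <- stage("density", {
      dtr <- config$density$trajectories
      prof <- densityProfile(dtr, config$density$groups,
                             binWidth = config$density$binWidth %||% 1)
      hc <- hydrationCount(prof,
                           interval = config$density$interval %||% c(-10, 10))
      list(profile = prof, count = hc)
    })
    files["density"] <- writeTable(
      data.frame(z = hydration$profile@z, hydration$profile@density),
      config$outputDir, "density_profile.csv")
  }

  manifest <- list(label = config$label, seed = config$seed,
                   parameters = config[c("pcaStridePs", "networkStridePs",
                                         "cutoff", "minSeqSeparation",
                                         "minCommunity", "report", "caRange")],
                   nReplicas = length(trajs),
                   nFrames = vapply(trajs, nFrames, 1L),
                   outputs = as.list(files))
  mf <- file.path(config$outputDir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  files["manifest"] <- mf

  structure(list(label = config$label, rmsf = rmsf, helix = helix,
                 cc = ed$cc, eigenvalues = ed$eig, model = ed$model,
                 network = net, connectivity = conn, hydration = hydration,
                 files = files, config = config),
            class = "StudyReport")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare phenotype reports
#'
#' Side-by-side RMSF deltas, helix-count deltas, cosine-content table,
#' connectivity verdicts, and a pairwise dissimilarity matrix of the RMSF
#' profiles (mean absolute difference, Angstrom).
#'
#' @param reports list of \code{StudyReport} objects (>= 2) over matching
#'   C-alpha selections.
#' @return list with \code{rmsf}, \code{helix}, \code{cc},
#'   \code{connectivity}, \code{pairwiseRMSF}.
#' @export
comparePhenotypes <- function(reports) {
  if (length(reports) < 2L) stop("need at least 2 reports")
  labels <- vapply(reports, `[[`, "", "label")
  resno <- reports[[1L]]$rmsf$resno
  for (r in reports[-1L])
    if (!identical(r$rmsf$resno, resno))
      stop("mismatched C-alpha selections across reports")
  rmsf <- data.frame(resno = resno)
  for (k in seq_along(reports)) rmsf[[labels[k]]] <- reports[[k]]$rmsf$rmsf
  for (k in seq_along(reports)[-1L])
    rmsf[[paste0("delta.", labels[k])]] <- rmsf[[labels[k]]] - rmsf[[labels[1L]]]
  helix <- NULL
  if (!is.null(reports[[1L]]$helix)) {
    helix <- data.frame(segment = reports[[1L]]$helix$segment)
    for (k in seq_along(reports)) {
      h <- reports[[k]]$helix
      helix[[labels[k]]] <- h$mean[match(helix$segment, h$segment)]
      helix[[paste0("sd.", labels[k])]] <- h$sd[match(helix$segment, h$segment)]
    }
    for (k in seq_along(reports)[-1L])
      helix[[paste0("delta.", labels[k])]] <-
        helix[[labels[k]]] - helix[[labels[1L]]]
  }
  cc <- do.call(rbind, lapply(seq_along(reports), function(k)
    cbind(label = labels[k], reports[[k]]$cc)))
  connectivity <- data.frame(
    label = labels,
    connected = vapply(reports, function(r) r$connectivity$connected, TRUE),
    Q = vapply(reports, function(r) modularityScore(r$network), 1))
  n <- length(reports)
  pw <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) for (j in seq_len(n))
    pw[i, j] <- mean(abs(reports[[i]]$rmsf$rmsf - reports[[j]]$rmsf$rmsf))
  list(rmsf = rmsf, helix = helix, cc = cc, connectivity = connectivity,
       pairwiseRMSF = pw)
}
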