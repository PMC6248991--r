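## Essential dynamics: positional covariance of the C-alpha selection,
## eigen-decomposition, projections on principal components, the
## cosine-content convergence diagnostic, principal-motion displacement
## fields ("porcupine" vectors) and dummy-variable regression planes for
## interface C-alpha motions.

#' CovarianceModel: positional covariance and its eigen-decomposition
#'
#' @slot mean N x 3 mean structure of the analysed selection, Angstrom.
#' @slot covariance 3N x 3N covariance matrix C, Angstrom^2 (coordinate
#'   order x1, y1, z1, x2, ...).
#' @slot values eigenvalues, Angstrom^2, descending.
#' @slot vectors orthonormal eigenvectors, one column per mode.
#' @slot atoms 1-based atom indices of the selection in the topology.
#' @slot resno residue numbers of the selection.
#' @slot segment segment labels of the selection.
#' @slot times ps times of the frames used for accumulation.
#' @export
setClass("CovarianceModel",
         representation(mean = "matrix", covariance = "matrix", values = "numeric",
                        vectors = "matrix", atoms = "integer",
                        resno = "integer", segment = "character",
                        times = "numeric"))

setValidity("CovarianceModel", function(object) {
  n3 <- 3L * nrow(object@mean)
  if (!all(dim(object@covariance) == n3)) return("C must be 3N x 3N")
  if (max(abs(object@covariance - t(object@covariance))) > 1e-8 * max(1, max(abs(object@covariance))))
    return("C must be symmetric")
  if (min(object@values) < -1e-10 * max(1, max(object@values)))
    return("eigenvalues below the numerical floor")
  tr <- sum(diag(object@covariance))
  if (abs(sum(object@values) - tr) > 1e-8 * max(1, abs(tr)))
    return("sum of eigenvalues must equal trace(C)")
  G <- crossprod(object@vectors)
  if (max(abs(G - diag(ncol(object@vectors)))) > 1e-8)
    return("eigenvectors must be orthonormal")
  TRUE
})

#' @describeIn eigenvalues eigenvalues of the covariance
#' @export
setMethod("eigenvalues", "CovarianceModel", function(x) x@values)

#' @describeIn eigenvectors eigenvectors of the covariance
#' @export
setMethod("eigenvectors", "CovarianceModel", function(x) x@vectors)

setMethod("show", "CovarianceModel", function(object) {
  n <- nrow(object@mean)
  tr <- sum(diag(object@covariance))
  cat(sprintf("CovarianceModel: %d atoms (3N = %d), trace %.4g A^2\n",
              n, 3L * n, tr))
  k <- min(3L, length(object@values))
  cat(sprintf("  top eigenvalues: %s (%.1f%% on PC1)\n",
              paste(sprintf("%.4g", object@values[seq_len(k)]), collapse = ", "),
              100 * object@values[1L] / tr))
})

## frames retained by a ps stride: frame 1 plus every frame whose time
## advanced by >= stride since the last retained one
strideFrames <- function(times, stridePs) {
  if (is.null(stridePs) || stridePs <= 0) return(seq_along(times))
  keep <- integer(0); lastT <- -Inf
  for (f in seq_along(times)) {
    if (times[f] - lastT >= stridePs - 1e-9) {
      keep <- c(keep, f); lastT <- times[f]
    }
  }
  keep
}

#' Positional covariance of a C-alpha selection
#'
#' Frames are resampled at \code{stridePs}, superposed onto the first frame
#' over \code{fitSelection}, and the mass-unweighted 3N x 3N covariance of
#' the \code{pcaSelection} coordinates is accumulated (denominator:
#' number of retained frames) and eigen-decomposed.
#'
#' @param trajectory a \linkS4class{Trajectory}.
#' @param fitSelection atom indices for superposition (default =
#'   \code{pcaSelection}).
#' @param pcaSelection atom indices to analyse (default: all CA atoms).
#' @param stridePs resampling stride in ps (default 4; 0 keeps every frame).
#' @param fit superpose frames onto frame 1 before accumulation (default
#'   TRUE; FALSE analyses raw coordinates, e.g. for pre-fitted ensembles or
#'   selections too small to fit).
#' @return a \linkS4class{CovarianceModel}.
#' @export
covarianceModel <- function(trajectory, fitSelection = NULL,
                            pcaSelection = NULL, stridePs = 4, fit = TRUE) {
  if (is.null(pcaSelection)) {
    pcaSelection <- atomSelect(trajectory, name = "CA")
    if (!length(pcaSelection)) pcaSelection <- seq_len(nAtoms(trajectory))
  }
  if (is.null(fitSelection)) fitSelection <- pcaSelection
  keep <- strideFrames(trajectory@times, stridePs)
  if (length(keep) < 2L)
    stop("fewer than 2 frames retained after striding")
  tr <- subsetFrames(trajectory, keep)
  if (fit) tr <- fitFrames(tr, fitSelection)
  co <- tr@coords[, pcaSelection, , drop = FALSE]
  nf <- dim(co)[1L]; n <- dim(co)[2L]
  ## flatten to frames x 3N in (x1, y1, z1, x2, ...) order
  X <- matrix(aperm(co, c(3L, 2L, 1L)), nrow = nf, byrow = TRUE)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  C <- crossprod(Xc) / nf
  C <- (C + t(C)) / 2
  ed <- eigen(C, symmetric = TRUE)
  a <- atomData(trajectory)[pcaSelection, , drop = FALSE]
  new("CovarianceModel",
      mean = matrix(mu, ncol = 3L, byrow = TRUE),
      covariance = C, values = ed$values, vectors = ed$vectors,
      atoms = as.integer(pcaSelection), resno = as.integer(a$resno),
      segment = a$segment, times = tr@times)
}

#' Project a trajectory onto a principal component
#'
#' p_i(t) = eigvec_i . (x(t) - mean), with each frame first superposed the
#' same way the model was accumulated (fit onto the model's frame set is
#' reproduced by fitting onto frame 1 over the model atoms).
#'
#' @param trajectory a \linkS4class{Trajectory} over the same topology and
#'   selection as the model.
#' @param model a \linkS4class{CovarianceModel}.
#' @param component principal-component index i (1 = largest variance).
#' @param fitSelection atom indices for superposition (default: the model's
#'   atoms).
#' @param stridePs resampling stride in ps (default: keep every frame).
#' @param fit superpose frames before projecting (default TRUE; use the
#'   same setting as the model).
#' @return data.frame of class \code{ProjectionSeries} with \code{time}
#'   (ps) and \code{projection} (Angstrom); attribute \code{component}.
#' @export
projectTrajectory <- function(trajectory, model, component = 1L,
                              fitSelection = NULL, stridePs = 0, fit = TRUE) {
  rank <- sum(model@values > 1e-12 * max(model@values))
  if (component < 1L || component > ncol(model@vectors))
    stop("component ", component, " exceeds the model rank")
  if (is.null(fitSelection)) fitSelection <- model@atoms
  keep <- strideFrames(trajectory@times, stridePs)
  tr <- subsetFrames(trajectory, keep)
  if (fit) tr <- fitFrames(tr, fitSelection)
  co <- tr@coords[, model@atoms, , drop = FALSE]
  nf <- dim(co)[1L]
  X <- matrix(aperm(co, c(3L, 2L, 1L)), nrow = nf, byrow = TRUE)
  mu <- as.numeric(t(model@mean))
  p <- as.numeric(sweep(X, 2L, mu) %*% model@vectors[, component])
  out <- data.frame(time = tr@times, projection = p)
  attr(out, "component") <- as.integer(component)
  class(out) <- c("ProjectionSeries", class(out))
  out
}

#' Cosine content of a projection series
#'
#' CC = (2/T) (integral_0^T cos(pi t / T) p(t) dt)^2 /
#' integral_0^T p(t)^2 dt, the single half-period convergence diagnostic
#' for essential-dynamics projections; integrals by the trapezoid rule over
#' the frame times. Values near 1 indicate random-diffusion-like sampling.
#'
#' @param series a \code{ProjectionSeries} from
#'   \code{\link{projectTrajectory}}, or a data.frame with \code{time} and
#'   \code{projection}.
#' @return CC in [0, 1].
#' @examples
#' t <- seq(0, 100, length.out = 512)
#' cosineContent(data.frame(time = t, projection = cos(pi * t / 100)))
#' @export
cosineContent <- function(series) {
  t <- series$time; p <- series$projection
  if (length(t) < 8L) stop("cosine content needs at least 8 frames")
  t <- t - t[1L]
  T <- t[length(t)]
  if (T <= 0) stop("degenerate time axis")
  if (all(p == 0)) stop("cosine content undefined for an all-zero series")
  trap <- function(y) sum(diff(t) * (y[-1L] + y[-length(y)]) / 2)
  num <- trap(cos(pi * t / T) * p)^2 * (2 / T)
  den <- trap(p^2)
  if (den == 0) stop("cosine content undefined for an all-zero series")
  min(1, num / den)
}

#' Principal-motion displacement field
#'
#' Per-atom displacement vectors spanning the motion along one principal
#' component, from a low to a high quantile of the projection (robust
#' trajectory "extremes"). Also returns the two extreme conformations.
#'
#' @param model a \linkS4class{CovarianceModel}.
#' @param series the matching \code{ProjectionSeries}.
#' @param quantiles length-2 projection quantiles (default 1\%/99\%).
#' @return list with \code{field} (N x 3 matrix, Angstrom; rows follow the
#'   model atoms), \code{low}/\code{high} (extreme conformations, N x 3),
#'   \code{resno}, \code{segment} and \code{span} (p_high - p_low).
#' @export
motionField <- function(model, series, quantiles = c(0.01, 0.99)) {
  component <- attr(series, "component")
  if (is.null(component)) component <- 1L
  q <- stats::quantile(series$projection, quantiles, names = FALSE, type = 7)
  span <- q[2L] - q[1L]
  if (span == 0) warning("equal projection quantiles: zero motion field")
  v <- model@vectors[, component]
  V <- matrix(v, ncol = 3L, byrow = TRUE)
  list(field = span * V,
       low = model@mean + q[1L] * V,
       high = model@mean + q[2L] * V,
       resno = model@resno, segment = model@segment, span = span)
}

#' PlaneFit: regression plane with categorical offsets
#'
#' Ordinary least squares of a scalar response (e.g. the z-coordinate or
#' PC1 displacement of interface C-alpha atoms) on lateral position with
#' dummy-coded group offsets (phenotype, replica). Group offsets are tested
#' against the baseline by two-sided t-tests with Holm correction.
#'
#' @slot coefficients named numeric (intercept, x, y, one offset per
#'   non-baseline group).
#' @slot residualSD numeric, response units.
#' @slot tests data.frame: term, estimate, se, t, p, pHolm, significant.
#' @slot fit the underlying \code{lm} object.
#' @export
setClass("PlaneFit",
         representation(coefficients = "numeric", residualSD = "numeric",
                        tests = "data.frame", fit = "ANY"))

setMethod("show", "PlaneFit", function(object) {
  cat("PlaneFit: response = b0 + b1 x + b2 y + group offsets\n")
  print(round(object@coefficients, 6))
  cat(sprintf("  residual SD %.4g\n", object@residualSD))
  if (nrow(object@tests))
    print(object@tests, digits = 4)
})

#' Fit local regression planes with dummy-coded groups
#'
#' @param data data.frame with numeric \code{x}, \code{y}, \code{response},
#'   and a \code{group} column (factor or character; first level is the
#'   baseline) when \code{groups} is not given separately.
#' @param groups optional vector of group labels overriding
#'   \code{data$group}; NULL fits a plane without offsets.
#' @param alpha significance level for the Holm-corrected offset tests.
#' @return a \linkS4class{PlaneFit}.
#' @examples
#' d <- data.frame(x = runif(20), y = runif(20))
#' d$response <- 1 + 2 * d$x - d$y
#' fitMotionPlanes(d, groups = NULL)@coefficients
#' @export
fitMotionPlanes <- function(data, groups = data$group, alpha = 0.05) {
  data <- as.data.frame(data)
  if (!all(c("x", "y", "response") %in% names(data)))
    stop("data needs columns x, y, response")
  hasGroups <- !is.null(groups)
  if (hasGroups) {
    g <- factor(groups)
    if (nlevels(g) < 2L)
      stop("dummy-variable design needs at least 2 groups")
    if (any(table(g) < 3L))
      stop("each group needs at least 3 points")
    data$..group <- g
    fm <- stats::lm(response ~ x + y + ..group, data = data)
  } else {
    fm <- stats::lm(response ~ x + y, data = data)
  }
  ## rank deficiency: name the collinear columns instead of silently dropping
  if (fm$rank < length(stats::coef(fm))) {
    bad <- names(stats::coef(fm))[is.na(stats::coef(fm))]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fm)
  co <- stats::coef(sm)
  cf <- stats::coef(fm)
  names(cf) <- sub("^\\.\\.group", "offset:", names(cf))
  tests <- data.frame(term = character(0), estimate = numeric(0),
                      se = numeric(0), t = numeric(0), p = numeric(0),
                      pHolm = numeric(0), significant = logical(0))
  if (hasGroups) {
    rows <- grep("^\\.\\.group", rownames(co))
    if (length(rows)) {
      p <- co[rows, 4L]
      tests <- data.frame(term = sub("^\\.\\.group", "offset:", rownames(co)[rows]),
                          estimate = co[rows, 1L], se = co[rows, 2L],
                          t = co[rows, 3L], p = p,
                          pHolm = stats::p.adjust(p, "holm"))
      tests$significant <- tests$pHolm < alpha
      rownames(tests) <- NULL
    }
  }
  new("PlaneFit", coefficients = cf, residualSD = sm$sigma,
      tests = tests, fit = fm)
}
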