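## Independent oracles and shared fixture builders. Every oracle here is a
## deliberately naive implementation (enumeration, double loops, closed
## forms) kept separate from the package's computational paths.

## small C-alpha bundle shared across tests
smallBundle <- function(nHelices = 3, rph = 8, atoms = "calpha")
  makeBundleReference(nHelices, rph, atoms = atoms)

## ---- rotation-grid RMSD oracle --------------------------------------------

rodrigues <- function(axis, theta) {
  k <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

## minimum RMSD over rotations about `axes` sampled at 1-degree resolution,
## optimal translation applied in closed form (centering)
gridMinRMSD <- function(mobile, reference, axes) {
  Mc <- sweep(mobile, 2, colMeans(mobile))
  Rc <- sweep(reference, 2, colMeans(reference))
  thetas <- (0:359) * pi / 180
  best <- Inf
  for (a in seq_len(nrow(axes))) {
    k <- axes[a, ] / sqrt(sum(axes[a, ]^2))
    ## R(theta) x = cos t x + sin t (k x x) + (1 - cos t) k (k.x)
    Kx <- cbind(k[2] * Mc[, 3] - k[3] * Mc[, 2],
                k[3] * Mc[, 1] - k[1] * Mc[, 3],
                k[1] * Mc[, 2] - k[2] * Mc[, 1])
    kk <- (Mc %*% k) %*% t(k)
    for (th in thetas) {
      rot <- cos(th) * Mc + sin(th) * Kx + (1 - cos(th)) * kk
      v <- sqrt(mean(rowSums((rot - Rc)^2)))
      if (v < best) best <- v
    }
  }
  best
}

## ---- exhaustive edge-betweenness oracle -----------------------------------

## all-pairs shortest-path enumeration on a small graph: for each ordered
## pair, enumerate every shortest path recursively and credit each edge
## 1/n_paths. Undirected pairs counted once.
bfEdgeBetweenness <- function(n, edges) {
  m <- nrow(edges)
  adj <- vector("list", n)
  for (e in seq_len(m)) {
    adj[[edges$i[e]]] <- rbind(adj[[edges$i[e]]], c(edges$j[e], e))
    adj[[edges$j[e]]] <- rbind(adj[[edges$j[e]]], c(edges$i[e], e))
  }
  bc <- numeric(m)
  for (s in seq_len(n)) {
    ## BFS distances from s
    dist <- rep(NA_integer_, n); dist[s] <- 0L
    q <- s
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      for (r in seq_len(NROW(adj[[v]]))) {
        if (!NROW(adj[[v]])) break
        w <- adj[[v]][r, 1]
        if (is.na(dist[w])) { dist[w] <- dist[v] + 1L; q <- c(q, w) }
      }
    }
    for (t in seq_len(n)) {
      if (t <= s || is.na(dist[t])) next
      ## enumerate all shortest s-t paths as edge sequences
      paths <- list()
      walk <- function(v, used) {
        if (v == s) { paths[[length(paths) + 1]] <<- used; return(invisible()) }
        for (r in seq_len(NROW(adj[[v]]))) {
          w <- adj[[v]][r, 1]; e <- adj[[v]][r, 2]
          if (!is.na(dist[w]) && dist[w] == dist[v] - 1L)
            walk(w, c(used, e))
        }
      }
      walk(t, integer(0))
      np <- length(paths)
      for (p in paths) bc[p] <- bc[p] + 1 / np
    }
  }
  bc
}

randomTestGraph <- function(n, p, seed) {
  set.seed(seed)
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < p
  data.frame(i = pairs[keep, 1], j = pairs[keep, 2])
}

## wrap an edge table into a DynamicNetwork (nodes = 1..n, unit weights)
edgeListNetwork <- function(n, edges) {
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  new("DynamicNetwork",
      nodes = data.frame(node = seq_len(n), atom = seq_len(n),
                         resno = seq_len(n), segment = "TM1",
                         stringsAsFactors = FALSE),
      edges = data.frame(i = edges$i, j = edges$j,
                         weight = rep(1, nrow(edges))),
      membership = NA_integer_, trace = data.frame(), Q = NA_real_,
      minSize = 1L)
}

twoCliqueBridge <- function(k = 5) {
  e <- rbind(t(combn(seq_len(k), 2)),
             t(combn(k + seq_len(k), 2)),
             c(k, k + 1))
  edgeListNetwork(2 * k, data.frame(i = pmin(e[, 1], e[, 2]),
                                    j = pmax(e[, 1], e[, 2])))
}

adjustedRandIndex <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab))); sj <- sum(ch2(colSums(tab)))
  nt <- ch2(sum(tab))
  exp_ <- si * sj / nt
  (sij - exp_) / ((si + sj) / 2 - exp_)
}

## ---- brute-force covariance oracle ----------------------------------------

## explicit element-by-element double loop over fitted coordinates
bruteForceCovariance <- function(X) {
  nf <- nrow(X); d <- ncol(X)
  mu <- numeric(d)
  for (k in seq_len(d)) mu[k] <- sum(X[, k]) / nf
  C <- matrix(0, d, d)
  for (a in seq_len(d)) for (b in seq_len(d)) {
    s <- 0
    for (f in seq_len(nf)) s <- s + (X[f, a] - mu[a]) * (X[f, b] - mu[b])
    C[a, b] <- s / nf
  }
  C
}

flattenFrames <- function(trajectory, sel) {
  co <- trajectory@coords[, sel, , drop = FALSE]
  matrix(aperm(co, c(3, 2, 1)), nrow = dim(co)[1], byrow = TRUE)
}

## planted-block ensemble used by network and acceptance tests
plantedPhenotype <- function(rho, seed, bundle = NULL, nFrames = 300) {
  if (is.null(bundle)) bundle <- makeBundleReference(7, 15, atoms = "calpha")
  blocks <- if (rho > 0)
    data.frame(segmentA = "TM2", segmentB = "TM5", rho = rho) else NULL
  sampleEnsemble(ensembleSpec(bundle, sigma = 0.4, blocks = blocks,
                              nFrames = nFrames, dt = 100,
                              seed = seed))$trajectory
}
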