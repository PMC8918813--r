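# Fixture builders and independent oracles shared across the suite.

# Two-cell track fixture with a lineage branch: c1 divides into c2/c3.
tinyTracks <- function() {
  tt <- seq(26, 27, by = 1 / 6)
  p <- rbind(
    data.frame(embryo_id = "e1", cell_id = "c0", parent_id = NA,
               t = tt, x = 10, y = 20 + seq_along(tt),
               z = 0.5, vessel_label = "ISV_1"),
    data.frame(embryo_id = "e1", cell_id = "c1", parent_id = NA,
               t = tt[1:4], x = 12, y = 30, z = 0, vessel_label = "ISV_1"),
    data.frame(embryo_id = "e1", cell_id = "c2", parent_id = "c1",
               t = tt[5:7], x = 12, y = 29, z = 0, vessel_label = "ISV_1"),
    data.frame(embryo_id = "e1", cell_id = "c3", parent_id = "c1",
               t = tt[5:7], x = 12, y = 31, z = 0, vessel_label = "ISV_1"))
  TrackTable(p)
}

# A straight-ISV world: one ISV at x = 50, DLAV at y = 80; the supplied
# cells data.frame needs cell_id, t, y (x defaults to 50).
oneIsvTracks <- function(cells, x = 50) {
  cells$embryo_id <- cells$embryo_id %||% "e1"
  if (is.null(cells$x)) cells$x <- x
  cells$z <- cells$z %||% 0
  TrackTable(cells)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

oneIsvMap <- function() regionMap(c(ISV_1 = 50), yDlav = 80)

# Independent dense flow oracle: assembles the full (all-node) system --
# identity rows for boundary nodes, Kirchhoff rows for interior nodes --
# and solves it with base::solve. Deliberately a different assembly path
# from the package's reduced interior system.
denseFlowOracle <- function(network, params, t = NA) {
  n <- vesselNodes(network)
  e <- vesselEdges(network)
  D <- e$diameter
  if (any(is.na(D))) {
    dia <- network@diameters
    for (k in which(is.na(D))) {
      s <- dia[dia$class == e$class[k], ]
      hit <- which(abs(s$t - t) < 1e-9)
      D[k] <- if (length(hit)) s$diameter[hit[1]] else {
        nz <- s[s$diameter > 0, ]
        stats::approx(nz$t, nz$diameter, xout = t, rule = 2)$y
      }
    }
  }
  G <- pi * D^4 / (128 * params$mu * e$length)
  G[D == 0] <- params$conductanceFloor
  nn <- nrow(n)
  A <- matrix(0, nn, nn, dimnames = list(n$id, n$id))
  b <- numeric(nn)
  da_len <- sum(e$length[e$class == "DA"])
  p_bc <- n$pressure
  p_bc[n$role == "da_inlet"] <- params$pDaIn
  p_bc[n$role == "da_outlet"] <- if (is.null(params$outletPressure))
    params$pDaIn * (1 - da_len / params$lFish) else
    params$outletPressure(params, da_len)
  p_bc[n$role == "sink"] <- params$pPcv
  for (i in seq_len(nn)) {
    if (n$role[i] != "interior") {
      A[i, i] <- 1
      b[i] <- p_bc[i]
    }
  }
  for (k in seq_len(nrow(e))) {
    i <- match(e$from[k], n$id); j <- match(e$to[k], n$id)
    if (n$role[i] == "interior") {
      A[i, i] <- A[i, i] + G[k]; A[i, j] <- A[i, j] - G[k]
    }
    if (n$role[j] == "interior") {
      A[j, j] <- A[j, j] + G[k]; A[j, i] <- A[j, i] - G[k]
    }
  }
  ## row-equilibrate the interior rows (conductances are ~1e-16, the
  ## identity boundary rows are 1) before the dense solve
  for (i in which(n$role == "interior")) {
    sc <- A[i, i]
    A[i, ] <- A[i, ] / sc
    b[i] <- b[i] / sc
  }
  p <- solve(A, b)
  list(pressures = p, flow = G * (p[match(e$from, n$id)] -
                                    p[match(e$to, n$id)]),
       conductance = G, D = D)
}

# Random connected test network with <= nMax nodes: a random spanning
# tree plus extra edges, >= 2 boundary nodes with random fixed
# pressures, diameters 3-12 um. Extra (non-bridging) edges are
# occasionally unmeasured (D = 0, conductance floor); tree edges stay
# measured so every node keeps a measured path to a boundary, which is
# the regime the floor is designed for -- a region tied to the
# boundaries only through floor edges has numerically indeterminate
# pressure.
randomNetwork <- function(seed, nMax = 50) {
  set.seed(seed)
  nn <- sample(5:nMax, 1)
  ids <- sprintf("n%02d", seq_len(nn))
  edges <- data.frame(from = integer(), to = integer())
  for (i in 2:nn) edges <- rbind(edges,
                                 data.frame(from = sample(i - 1, 1), to = i))
  n_tree <- nrow(edges)
  extra <- sample(0:min(10, nn - 2), 1)
  for (k in seq_len(extra)) {
    ij <- sample(nn, 2)
    edges <- rbind(edges, data.frame(from = ij[1], to = ij[2]))
  }
  nb <- min(nn - 1, sample(c(2, 2, 3, 4, 5), 1))
  boundary <- sample(nn, nb)
  nodes <- data.frame(id = ids, x = runif(nn) * 1e-3, y = runif(nn) * 1e-3,
                      role = "interior", pressure = NA_real_)
  nodes$role[boundary] <- "fixed"
  nodes$pressure[boundary] <- runif(nb, 0, 250)
  D <- runif(nrow(edges), 3e-6, 12e-6)
  D[seq_len(nrow(edges)) > n_tree & runif(nrow(edges)) < 0.3] <- 0
  e <- data.frame(id = sprintf("e%02d", seq_len(nrow(edges))),
                  from = ids[edges$from], to = ids[edges$to],
                  class = "aISV", length = runif(nrow(edges), 5e-5, 5e-4),
                  diameter = D)
  new("VesselNetwork", nodes = nodes, edges = e,
      diameters = data.frame(class = character(), t = numeric(),
                             diameter = numeric()))
}

# Independent Watson U2 oracle: ECDF step functions evaluated over the
# pooled sample, variance of their difference under the pooled ECDF.
watsonU2Oracle <- function(a, b) {
  pooled <- sort(c(a %% (2 * pi), b %% (2 * pi)))
  Fa <- stats::ecdf(a %% (2 * pi))
  Fb <- stats::ecdf(b %% (2 * pi))
  d <- Fa(pooled) - Fb(pooled)
  n <- length(a); m <- length(b); N <- n + m
  n * m / N^2 * sum((d - mean(d))^2)
}

# Exhaustive conditional permutation oracle for the discrete KS test at
# tiny n: enumerates every split of the pooled sample.
discreteKsExactOracle <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  support <- sort(unique(pooled))
  Dof <- function(xa, xb) {
    Fa <- vapply(support, function(v) mean(xa <= v), 0)
    Fb <- vapply(support, function(v) mean(xb <= v), 0)
    max(abs(Fa - Fb))
  }
  Dobs <- Dof(a, b)
  combos <- utils::combn(length(pooled), na)
  ge <- vapply(seq_len(ncol(combos)), function(ci) {
    xa <- pooled[combos[, ci]]
    xb <- pooled[-combos[, ci]]
    Dof(xa, xb) >= Dobs - 1e-12
  }, TRUE)
  list(D = Dobs, p = mean(ge))
}

# Monte-Carlo oracle for the branching division process used by the
# embryo generator: exponential waiting times with clock starting at
# max(track start, window start), accepted inside the window with the
# generator's two-frame snapping margins.
divisionProcessOracle <- function(hazard, t0, t1, window, dtFrame,
                                  cellsPerVessel, nVessels, seed) {
  set.seed(seed)
  times <- seq(t0, t1, by = dtFrame)
  nF <- length(times)
  sim_cell <- function(startIdx) {
    clock0 <- max(times[startIdx], window[1])
    tdiv <- clock0 + stats::rexp(1, hazard)
    if (tdiv > min(times[nF], window[2])) return(0)
    i <- findInterval(tdiv, times)
    if (i < startIdx + 2 || i > nF - 2) return(0)
    1 + sim_cell(i + 1) + sim_cell(i + 1)
  }
  mean(vapply(seq_len(nVessels), function(v)
    sum(vapply(seq_len(cellsPerVessel), function(cc) sim_cell(1), 0)), 0))
}
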