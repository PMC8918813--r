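#' Physical parameters of the network flow model
#'
#' Defaults are the model's literature-derived constants: blood dynamic
#' viscosity 0.0035 kg m^-1 s^-1, aorta inlet pressure 201.3 Pa, the
#' vein treated as a zero-pressure flow sink, and the inlet pressure
#' dissipating over the 2 mm length of the fish. The aorta outlet
#' pressure applies that gradient to the fraction of the aorta inside
#' the model: P_out = P_in (1 - L_DA,model / L_fish); `outletPressure`
#' is a replaceable hook `function(params, daLength)` for other boundary
#' treatments. Edges without a diameter measurement (D = 0) keep the
#' conductance matrix invertible through `conductanceFloor`.
#'
#' @param mu dynamic viscosity, kg m^-1 s^-1.
#' @param pDaIn aorta inlet pressure, Pa.
#' @param pPcv sink pressure, Pa.
#' @param lFish fish length, m.
#' @param conductanceFloor conductance for unmeasured edges,
#'   m^3 Pa^-1 s^-1.
#' @param outletPressure NULL (default gradient rule) or a function
#'   `(params, daLength)` returning the outlet pressure in Pa.
#' @return validated list of class `flowParameters`.
#' @export
flowParameters <- function(mu = 0.0035, pDaIn = 201.3, pPcv = 0,
                           lFish = 2e-3, conductanceFloor = 1e-30,
                           outletPressure = NULL) {
  if (mu <= 0) .stopf("mu must be > 0")
  if (pDaIn <= pPcv) .stopf("pDaIn must exceed pPcv")
  if (conductanceFloor <= 0) .stopf("conductanceFloor must be > 0")
  structure(list(mu = mu, pDaIn = pDaIn, pPcv = pPcv, lFish = lFish,
                 conductanceFloor = conductanceFloor,
                 outletPressure = outletPressure),
            class = "flowParameters")
}

#' Poiseuille conductance of a vessel segment
#'
#' G = pi D^4 / (128 mu L). A zero diameter encodes a missing
#' measurement and returns `conductanceFloor` so the system stays
#' invertible. Vectorised over D and L.
#'
#' @param D diameter, m.
#' @param L length, m.
#' @param mu dynamic viscosity, kg m^-1 s^-1.
#' @param conductanceFloor value returned where D = 0.
#' @return conductance, m^3 Pa^-1 s^-1.
#' @examples
#' edgeConductance(7e-6, 100e-6, 0.0035) # ~1.68e-19
#' @export
edgeConductance <- function(D, L, mu = 0.0035, conductanceFloor = 1e-30) {
  if (any(D < 0) || any(L <= 0))
    .stopf("domain error: need D >= 0 and L > 0")
  if (mu <= 0) .stopf("domain error: mu must be > 0")
  G <- pi * D^4 / (128 * mu * L)
  G[D == 0] <- conductanceFloor
  G
}

#' Build the idealized trunk vessel network
#'
#' The aorta chain runs from the inlet through the aISV base nodes to
#' the outlet; the DLAV chain crosses all ISV apices; aISVs connect the
#' aorta to the DLAV and vISVs hang from the DLAV down to terminal sink
#' nodes (the vein is not part of the network, it is the pressure sink).
#' ISV classes alternate starting from `firstClass`; boundary nodes are
#' exactly the aorta inlet and outlet plus one terminal node per vISV.
#' ISV k sits at x = k * spacing and the outlet one spacing beyond the
#' last aISV base.
#'
#' @param isvSpacing,isvLength geometry in micrometres (converted to SI
#'   internally).
#' @param nIsv number of ISVs (default 30).
#' @param firstClass class of ISV 1.
#' @param diameters class diameter series: a [DiameterTable-class]
#'   (averaged per class) or a data.frame `class`, `t`, `diameter` in
#'   micrometres. NULL leaves the series empty (edges then need fixed
#'   diameters before solving).
#' @return a validated [VesselNetwork-class].
#' @export
buildIdealizedNetwork <- function(isvSpacing, isvLength, nIsv = 30L,
                                  firstClass = c("aISV", "vISV"),
                                  diameters = NULL) {
  firstClass <- match.arg(firstClass)
  nIsv <- as.integer(nIsv)
  if (nIsv < 1L) .stopf("nIsv must be >= 1")
  if (isvSpacing <= 0 || isvLength <= 0)
    .stopf("spacing and length must be > 0")
  sp <- isvSpacing * .um
  len <- isvLength * .um
  classes <- rep(if (firstClass == "aISV") c("aISV", "vISV")
                 else c("vISV", "aISV"), length.out = nIsv)
  xk <- sp * seq_len(nIsv)
  a_idx <- which(classes == "aISV")
  v_idx <- which(classes == "vISV")

  nodes <- data.frame(id = "DA_in", x = 0, y = 0, role = "da_inlet",
                      pressure = NA_real_)
  add_node <- function(id, x, y, role)
    nodes <<- rbind(nodes, data.frame(id = id, x = x, y = y, role = role,
                                      pressure = NA_real_))
  for (k in a_idx) add_node(sprintf("base_%d", k), xk[k], 0, "interior")
  x_out <- if (length(a_idx)) xk[max(a_idx)] + sp else sp * (nIsv + 1)
  add_node("DA_out", x_out, 0, "da_outlet")
  for (k in seq_len(nIsv)) add_node(sprintf("apex_%d", k), xk[k], len,
                                    "interior")
  for (k in v_idx) add_node(sprintf("sink_%d", k), xk[k], 0, "sink")

  edges <- list()
  add_edge <- function(id, from, to, class, length)
    edges[[length(edges) + 1L]] <<- data.frame(
      id = id, from = from, to = to, class = class, length = length,
      diameter = NA_real_)
  da_chain <- c("DA_in", sprintf("base_%d", a_idx), "DA_out")
  da_x <- c(0, xk[a_idx], x_out)
  for (i in seq_len(length(da_chain) - 1L))
    add_edge(sprintf("DA_%d", i), da_chain[i], da_chain[i + 1L], "DA",
             da_x[i + 1L] - da_x[i])
  if (nIsv > 1L)
    for (k in seq_len(nIsv - 1L))
      add_edge(sprintf("DLAV_%d", k), sprintf("apex_%d", k),
               sprintf("apex_%d", k + 1L), "DLAV", xk[k + 1L] - xk[k])
  for (k in a_idx)
    add_edge(sprintf("aISV_%d", k), sprintf("base_%d", k),
             sprintf("apex_%d", k), "aISV", len)
  for (k in v_idx)
    add_edge(sprintf("vISV_%d", k), sprintf("apex_%d", k),
             sprintf("sink_%d", k), "vISV", len)
  edges <- do.call(rbind, edges)

  dia <- data.frame(class = character(), t = numeric(),
                    diameter = numeric())
  if (!is.null(diameters)) {
    if (is(diameters, "DiameterTable")) {
      m <- diameterMeasurements(diameters)
      dia <- aggregate(diameter ~ vessel_class + t, data = m, FUN = mean)
      names(dia)[names(dia) == "vessel_class"] <- "class"
    } else {
      dia <- as.data.frame(diameters)[, c("class", "t", "diameter")]
    }
    dia$diameter <- dia$diameter * .um
    dia <- dia[order(dia$class, dia$t), ]
  }
  new("VesselNetwork", nodes = nodes, edges = edges, diameters = dia)
}

#' @describeIn buildIdealizedNetwork node table accessor.
#' @param x a VesselNetwork.
#' @export
vesselNodes <- function(x) {
  stopifnot(is(x, "VesselNetwork"))
  x@nodes
}

#' @describeIn buildIdealizedNetwork edge table accessor.
#' @export
vesselEdges <- function(x) {
  stopifnot(is(x, "VesselNetwork"))
  x@edges
}

setMethod("show", "VesselNetwork", function(object) {
  tab <- table(object@edges$class)
  cat(sprintf("VesselNetwork: %d nodes, %d edges (%s)\n",
              nrow(object@nodes), nrow(object@edges),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  cat(sprintf("  boundary: %s\n",
              paste(object@nodes$id[object@nodes$role != "interior"][
                seq_len(min(5L, sum(object@nodes$role != "interior")))],
                collapse = ", ")))
})

## per-edge diameters (m) at time t: fixed edge diameters win, else the
## class series; exact grid hits return the stored value (zero included,
## the missing-measurement sentinel), otherwise interpolation over the
## nonzero measurements
.edgeDiametersAt <- function(network, t) {
  e <- network@edges
  D <- e$diameter
  need <- which(is.na(D))
  if (!length(need)) return(D)
  dia <- network@diameters
  for (cls in unique(e$class[need])) {
    s <- dia[dia$class == cls, ]
    if (!nrow(s))
      .stopf("no diameter series for class %s and no fixed diameters", cls)
    hit <- which(abs(s$t - t) < 1e-9)
    d <- if (length(hit)) s$diameter[hit[1L]] else {
      nz <- s[s$diameter > 0, ]
      if (!nrow(nz)) 0
      else if (nrow(nz) == 1L) nz$diameter
      else approx(nz$t, nz$diameter, xout = t, rule = 2)$y
    }
    D[need][e$class[need] == cls] <- d
  }
  D
}

.boundaryPressures <- function(network, params) {
  n <- network@nodes
  p <- n$pressure
  da_len <- sum(network@edges$length[network@edges$class == "DA"])
  p[n$role == "da_inlet"] <- params$pDaIn
  p[n$role == "da_outlet"] <- if (is.null(params$outletPressure))
    params$pDaIn * (1 - da_len / params$lFish)
  else params$outletPressure(params, da_len)
  p[n$role == "sink"] <- params$pPcv
  p
}

#' Solve nodal pressures at one time point
#'
#' Assembles the conductance-weighted flow-balance system over the
#' interior nodes, with boundary nodes held at their prescribed
#' pressures (inlet pDaIn, outlet from the aorta gradient rule, vISV
#' terminals at pPcv, `fixed` nodes at their own value), and solves it
#' with a sparse symmetric solver (dense fallback). Flow and wall shear
#' stress are derived per edge: Q = G dp and tau = 32 mu |Q| / (pi D^3);
#' edges held at the conductance floor report tau = 0.
#'
#' @param network a [VesselNetwork-class].
#' @param params [flowParameters()].
#' @param t time (hpf) at which the class diameter series are evaluated.
#' @return a [FlowSolution-class] with a single time point.
#' @export
solvePressures <- function(network, params = flowParameters(), t = NA) {
  n <- network@nodes
  e <- network@edges
  D <- .edgeDiametersAt(network, t)
  G <- edgeConductance(D, e$length, params$mu, params$conductanceFloor)
  p_bc <- .boundaryPressures(network, params)
  interior <- which(n$role == "interior")
  idx <- match(c(e$from, e$to), n$id)
  from_i <- idx[seq_len(nrow(e))]
  to_i <- idx[-seq_len(nrow(e))]
  p <- p_bc
  if (length(interior)) {
    imap <- match(seq_len(nrow(n)), interior) # node -> unknown index
    nI <- length(interior)
    ii <- c(); jj <- c(); vv <- c()
    b <- numeric(nI)
    for (k in seq_len(nrow(e))) {
      a <- from_i[k]; bnd <- to_i[k]; g <- G[k]
      ia <- imap[a]; ib <- imap[bnd]
      if (!is.na(ia)) { ii <- c(ii, ia); jj <- c(jj, ia); vv <- c(vv, g) }
      if (!is.na(ib)) { ii <- c(ii, ib); jj <- c(jj, ib); vv <- c(vv, g) }
      if (!is.na(ia) && !is.na(ib)) {
        ii <- c(ii, ia, ib); jj <- c(jj, ib, ia); vv <- c(vv, -g, -g)
      } else if (!is.na(ia)) {
        b[ia] <- b[ia] + g * p_bc[bnd]
      } else if (!is.na(ib)) {
        b[ib] <- b[ib] + g * p_bc[a]
      }
    }
    A <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(nI, nI))
    sol <- tryCatch(as.numeric(Matrix::solve(A, b)),
                    error = function(err) {
      Ad <- as.matrix(A)
      tryCatch(solve(Ad, b), error = function(err2)
        .stopf(paste("numerical error: singular flow system despite",
                     "conductance floor (%d interior nodes, min G = %g)"),
               nI, min(G)))
    })
    p[interior] <- sol
  }
  dp <- p[from_i] - p[to_i]
  Q <- G * dp
  wss <- ifelse(D > 0, 32 * params$mu * abs(Q) / (pi * D^3), 0)
  one <- function(v, nm) matrix(v, ncol = 1, dimnames = list(nm, NULL))
  new("FlowSolution", network = network, times = as.numeric(t),
      pressures = one(p, n$id), conductance = one(G, e$id),
      dp = one(dp, e$id), flow = one(Q, e$id), wss = one(wss, e$id))
}

#' @describeIn solvePressures per-edge flow and wall shear stress at one
#'   solved time point.
#' @param solution a [FlowSolution-class].
#' @return `flowAndWss`: data.frame `edge`, `class`, `diameter`, `dp`,
#'   `flow`, `wss`.
#' @export
flowAndWss <- function(solution, t = NULL) {
  stopifnot(is(solution, "FlowSolution"))
  ti <- if (is.null(t)) 1L else which.min(abs(solution@times - t))
  e <- solution@network@edges
  data.frame(edge = e$id, class = e$class,
             diameter = .edgeDiametersAt(solution@network,
                                         solution@times[ti]),
             conductance = solution@conductance[, ti],
             dp = solution@dp[, ti], flow = solution@flow[, ti],
             wss = solution@wss[, ti])
}

#' Maximum relative flow-balance violation at interior nodes
#'
#' @param solution a [FlowSolution-class].
#' @return max over times and interior nodes of |sum Q| / max |Q|.
#' @export
kirchhoffResidual <- function(solution) {
  n <- solution@network@nodes
  e <- solution@network@edges
  interior <- n$id[n$role == "interior"]
  if (!length(interior)) return(0)
  worst <- 0
  for (ti in seq_along(solution@times)) {
    Q <- solution@flow[, ti]
    net <- vapply(interior, function(nd)
      sum(Q[e$to == nd]) - sum(Q[e$from == nd]), 0)
    worst <- max(worst, max(abs(net)) / max(abs(Q), .Machine$double.xmin))
  }
  worst
}

#' Solve the network over a developmental time course
#'
#' Re-solves the pressure system at every requested time point, each
#' time re-evaluating the diameter series and hence the conductance
#' matrix.
#'
#' @inheritParams solvePressures
#' @param times time points (hpf).
#' @return a [FlowSolution-class] spanning `times`.
#' @export
simulateTimecourse <- function(network, params = flowParameters(), times) {
  sols <- lapply(times, function(t) solvePressures(network, params, t))
  new("FlowSolution", network = network, times = as.numeric(times),
      pressures = do.call(cbind, lapply(sols, slot, "pressures")),
      conductance = do.call(cbind, lapply(sols, slot, "conductance")),
      dp = do.call(cbind, lapply(sols, slot, "dp")),
      flow = do.call(cbind, lapply(sols, slot, "flow")),
      wss = do.call(cbind, lapply(sols, slot, "wss")))
}

#' Per-class mean wall shear stress over time
#'
#' @param solution a [FlowSolution-class].
#' @param classes vessel classes to summarise.
#' @return data.frame: `class`, `t`, `mean_wss` (Pa), `mean_flow`
#'   (m^3 s^-1, magnitudes).
#' @export
wssSummary <- function(solution,
                       classes = c("aISV", "vISV", "DA", "DLAV")) {
  e <- solution@network@edges
  out <- list()
  for (cls in intersect(classes, unique(e$class))) {
    sel <- e$class == cls
    for (ti in seq_along(solution@times))
      out[[length(out) + 1L]] <- data.frame(
        class = cls, t = solution@times[ti],
        mean_wss = mean(solution@wss[sel, ti]),
        mean_flow = mean(abs(solution@flow[sel, ti])))
  }
  res <- do.call(rbind, out)
  res[order(res$class, res$t), ]
}

#' @describeIn solvePressures nodal pressures accessor (Pa).
#' @export
pressures <- function(solution) {
  stopifnot(is(solution, "FlowSolution"))
  solution@pressures
}

setMethod("show", "FlowSolution", function(object) {
  cat(sprintf("FlowSolution: %d nodes, %d edges, %d time point(s)\n",
              nrow(object@pressures), nrow(object@flow),
              length(object@times)))
  if (length(object@times) == 1L && !is.na(object@times))
    cat(sprintf("  t = %g; pressure range [%.3g, %.3g] Pa; max |Q| %.3g m^3/s\n",
                object@times, min(object@pressures), max(object@pressures),
                max(abs(object@flow))))
})
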