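flatDiameters <- function(d = c(DA = 22, DLAV = 6, aISV = 7, vISV = 8))
  data.frame(class = names(d), t = 26, diameter = unname(d))

zeroGradient <- flowParameters(outletPressure = function(p, len) p$pDaIn)

test_that("the default idealized build matches the printed structure", {
  net <- buildIdealizedNetwork(55, 80, diameters = flatDiameters())
  e <- vesselEdges(net)
  n <- vesselNodes(net)
  expect_equal(sum(e$class %in% c("aISV", "vISV")), 30L)
  expect_equal(sum(e$class == "aISV"), 15L)
  expect_equal(sum(e$class == "vISV"), 15L)
  ## alternating: consecutive ISVs differ in class
  isv <- e[e$class %in% c("aISV", "vISV"), ]
  ord <- order(as.integer(sub(".*_", "", isv$id)))
  expect_true(all(isv$class[ord][-1] != isv$class[ord][-30]))
  boundary <- n[n$role != "interior", ]
  expect_setequal(boundary$role,
                  c("da_inlet", "da_outlet", rep("sink", 15)))
  expect_equal(sum(boundary$role == "sink"), 15L)
})

test_that("degenerate and hand-enumerated builds have the right shape", {
  n1 <- buildIdealizedNetwork(55, 80, nIsv = 1)
  expect_equal(sum(vesselEdges(n1)$class == "aISV"), 1L)
  expect_equal(sum(vesselEdges(n1)$class == "vISV"), 0L)
  expect_equal(sum(vesselEdges(n1)$class == "DLAV"), 0L)
  expect_equal(sum(vesselNodes(n1)$role == "sink"), 0L)

  n4 <- buildIdealizedNetwork(55, 80, nIsv = 4)
  expect_equal(nrow(vesselNodes(n4)), 10L)
  expect_equal(nrow(vesselEdges(n4)), 10L)
  expect_equal(sum(vesselEdges(n4)$class == "DA"), 3L)
  expect_equal(sum(vesselEdges(n4)$class == "DLAV"), 3L)
  expect_error(buildIdealizedNetwork(55, 80, nIsv = 0), ">= 1")
})

test_that("edge conductance follows the closed form with the D = 0 floor", {
  expect_equal(edgeConductance(7e-6, 100e-6, 0.0035),
               pi * (7e-6)^4 / (128 * 0.0035 * 100e-6), tolerance = 1e-14)
  expect_equal(edgeConductance(7e-6, 100e-6, 0.0035), 1.6837e-16,
               tolerance = 1e-4)
  expect_identical(edgeConductance(0, 1e-4, 0.0035), 1e-30)
  expect_equal(edgeConductance(2e-5, 1e-4, 0.0035) /
                 edgeConductance(1e-5, 1e-4, 0.0035), 16,
               tolerance = 1e-12)
  expect_error(edgeConductance(-1e-6, 1e-4, 0.0035), "domain")
  expect_error(edgeConductance(1e-6, 0, 0.0035), "domain")
})

test_that("pressure solve handles trivial and symmetric systems", {
  ## single edge between two fixed-pressure nodes: no interior system
  net1 <- new("VesselNetwork",
    nodes = data.frame(id = c("a", "b"), x = c(0, 1e-3), y = 0,
                       role = "fixed", pressure = c(201.3, 0)),
    edges = data.frame(id = "e1", from = "a", to = "b", class = "aISV",
                       length = 1e-3, diameter = 8e-6),
    diameters = data.frame(class = character(), t = numeric(),
                           diameter = numeric()))
  s1 <- solvePressures(net1, flowParameters())
  expect_equal(unname(pressures(s1)[, 1]), c(201.3, 0))
  expect_gt(s1@flow[1, 1], 0)

  ## two identical edges in series: midpoint = mean of the boundaries
  net2 <- new("VesselNetwork",
    nodes = data.frame(id = c("a", "m", "b"), x = c(0, 1, 2) * 1e-3,
                       y = 0, role = c("fixed", "interior", "fixed"),
                       pressure = c(100, NA, 40)),
    edges = data.frame(id = c("e1", "e2"), from = c("a", "m"),
                       to = c("m", "b"), class = "aISV", length = 1e-3,
                       diameter = 8e-6),
    diameters = data.frame(class = character(), t = numeric(),
                           diameter = numeric()))
  s2 <- solvePressures(net2, flowParameters())
  expect_equal(pressures(s2)["m", 1], 70, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("solver matches the dense brute-force oracle on the 4-ISV net", {
  net <- buildIdealizedNetwork(55, 80, nIsv = 4,
                               diameters = flatDiameters())
  sol <- solvePressures(net, zeroGradient, t = 26)
  oracle <- denseFlowOracle(net, zeroGradient, t = 26)
  expect_equal(unname(pressures(sol)[, 1]), unname(oracle$pressures),
               tolerance = 1e-10)
  expect_lt(kirchhoffResidual(sol), 1e-12)
})

test_that("flow and WSS satisfy the Poiseuille identities", {
  ## worked example: D = 10 um, L = 1 mm, dp = 100 Pa -> tau = 0.25 Pa
  net <- new("VesselNetwork",
    nodes = data.frame(id = c("a", "b"), x = c(0, 1e-3), y = 0,
                       role = "fixed", pressure = c(100, 0)),
    edges = data.frame(id = "e1", from = "a", to = "b", class = "aISV",
                       length = 1e-3, diameter = 10e-6),
    diameters = data.frame(class = character(), t = numeric(),
                           diameter = numeric()))
  fw <- flowAndWss(solvePressures(net, flowParameters()))
  expect_equal(fw$wss, 0.25, tolerance = 1e-12)
  expect_equal(fw$wss, fw$diameter * fw$dp / (4 * 1e-3),
               tolerance = 1e-12)

  ## dp = 0: no flow, no shear
  net0 <- net
  net0@nodes$pressure <- c(50, 50)
  fw0 <- flowAndWss(solvePressures(net0, flowParameters()))
  expect_equal(fw0$flow, 0)
  expect_equal(fw0$wss, 0)

  ## reversing edge orientation negates Q, leaves tau unchanged
  netr <- net
  netr@edges$from <- "b"; netr@edges$to <- "a"
  fwr <- flowAndWss(solvePressures(netr, flowParameters()))
  expect_equal(fwr$flow, -fw$flow, tolerance = 1e-12)
  expect_equal(fwr$wss, fw$wss, tolerance = 1e-12)

  ## both shear formulas agree on every edge of a full network
  big <- buildIdealizedNetwork(55, 80, diameters = flatDiameters())
  fb <- flowAndWss(solvePressures(big, flowParameters(), 26))
  tau_geom <- fb$diameter * abs(fb$dp) /
    (4 * vesselEdges(big)$length)
  expect_equal(fb$wss, tau_geom, tolerance = 1e-12)
})

test_that("time stepping, viscosity invariance and vISV enlargement", {
  dgrow <- rbind(
    data.frame(class = "DA", t = c(26, 44), diameter = 22),
    data.frame(class = "DLAV", t = c(26, 44), diameter = 6),
    data.frame(class = "aISV", t = c(26, 44), diameter = 7),
    data.frame(class = "vISV", t = c(26, 44), diameter = c(8, 16)))
  net <- buildIdealizedNetwork(55, 80, diameters = dgrow)
  times <- seq(26, 44, by = 2)
  sol <- simulateTimecourse(net, flowParameters(), times)
  ws <- wssSummary(sol)
  a <- ws[ws$class == "aISV", ]
  ## aISV WSS rises while the aISV diameter stays constant: the network
  ## effect of vISV enlargement
  expect_true(all(diff(a$mean_wss) > 0))
  ## constant diameters give a constant series
  dflat <- flatDiameters()
  netf <- buildIdealizedNetwork(55, 80, diameters = dflat)
  solf <- simulateTimecourse(netf, flowParameters(), times)
  expect_equal(max(apply(solf@wss, 1, function(r) diff(range(r)))), 0,
               tolerance = 1e-15)
  ## uniform viscosity rescale leaves tau unchanged under pressure BCs
  sol3 <- simulateTimecourse(net, flowParameters(mu = 3 * 0.0035), times)
  expect_equal(sol3@wss, sol@wss, tolerance = 1e-12)
  ## DA inlet flow is positive
  expect_true(all(sol@flow["DA_1", ] > 0))
})

test_that("network symmetry and conductance monotonicity hold", {
  ## with a zero aorta gradient, same-class ISVs become identical in the
  ## equipotential-conduit limit (very wide DA and DLAV); at realistic
  ## conduit diameters only the interior ISVs are near-uniform because
  ## edge ISVs see different conduit resistance
  wide <- buildIdealizedNetwork(55, 80, diameters = flatDiameters(
    c(DA = 2000, DLAV = 2000, aISV = 7, vISV = 8)))
  fww <- flowAndWss(solvePressures(wide, zeroGradient, 26))
  for (cls in c("aISV", "vISV")) {
    q <- abs(fww$flow[fww$class == cls])
    expect_lt(diff(range(q)) / max(q), 1e-6)
    expect_true(all(q > 0))
  }
  ## growing one vISV never decreases total inlet flow
  net <- buildIdealizedNetwork(55, 80, diameters = flatDiameters())
  inlet_flow <- function(network, t = 26)
    flowAndWss(solvePressures(network, flowParameters(), t))$flow[1]
  base <- inlet_flow(net)
  for (mult in c(1.2, 2, 5)) {
    net2 <- net
    k <- which(net2@edges$id == "vISV_2")
    net2@edges$diameter[k] <- 8e-6 * mult
    expect_gte(inlet_flow(net2), base - abs(base) * 1e-12)
  }
})

test_that("unmeasured edges sit at the floor and report zero shear", {
  d0 <- flatDiameters()
  d0$diameter[d0$class == "DLAV"] <- 0
  net <- buildIdealizedNetwork(55, 80, nIsv = 6, diameters = d0)
  sol <- solvePressures(net, flowParameters(), 26)
  fw <- flowAndWss(sol)
  dlav <- fw[fw$class == "DLAV", ]
  expect_true(all(dlav$conductance == 1e-30))
  expect_true(all(dlav$wss == 0))
  expect_lt(kirchhoffResidual(sol), 1e-12)
})
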