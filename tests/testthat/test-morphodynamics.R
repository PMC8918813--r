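test_that("windowed velocity is exact on linear and stationary tracks", {
  tt <- seq(26, 44, by = 1 / 6)
  tracks <- oneIsvTracks(rbind(
    data.frame(cell_id = "lin", t = tt, y = 2.5 * (tt - 26) + 10),
    data.frame(cell_id = "flat", t = tt, y = 40)))
  fate <- data.frame(embryo_id = "e1", vessel_id = "ISV_1",
                     class = "aISV", unresolved = FALSE)
  vp <- windowedVelocity(tracks, fate, map = oneIsvMap(), bootstrap = 50L)
  lin <- vp[vp$n_cells > 0, ]
  expect_true(all(is.finite(lin$velocity)))
  ## the linear cell leaves the ISV band near the end; while both cells
  ## are in-band the class mean is (2.5 + 0)/2
  early <- lin[lin$t_mid <= 40, ]
  expect_equal(unique(round(early$velocity, 9)), 1.25)

  solo <- windowedVelocity(tracks, fate, map = oneIsvMap(),
                           bootstrap = 50L, cells = "flat")
  expect_equal(unique(round(solo$velocity[solo$n_cells > 0], 12)), 0)
})

test_that("mirroring all tracks through y -> -y negates every velocity", {
  cfg <- embryoSimConfig(n_isv = 4L, seed = 8)
  sim <- generateEmbryo(cfg)
  map <- regionMap(sim$truth$isv_x, yDlav = sim$truth$isv_length)
  fate <- assignFate(sim$tracks, 44, connectivity = sim$truth$connectivity,
                     map = map)
  asg <- assignRegions(sim$tracks, map)
  vp <- windowedVelocity(sim$tracks, fate, assignment = asg,
                         bootstrap = 50L)
  asg_m <- asg
  asg_m$y <- -asg_m$y
  vp_m <- windowedVelocity(sim$tracks, fate, assignment = asg_m,
                           bootstrap = 50L)
  expect_equal(vp_m$velocity, -vp$velocity, tolerance = 1e-12)
})

test_that("fate assignment recovers injected identities and flags gaps", {
  cfg <- embryoSimConfig(seed = 4)
  sim <- generateEmbryo(cfg)
  map <- regionMap(sim$truth$isv_x, yDlav = sim$truth$isv_length)
  fate <- assignFate(sim$tracks, 44, connectivity = sim$truth$connectivity,
                     map = map)
  truth <- sim$truth$fates
  m <- merge(fate, truth, by = c("embryo_id", "vessel_id"))
  expect_equal(m$class.x, m$class.y)
  expect_equal(sum(m$class.x == "vISV"), 5L)

  ## all ISVs still DA-connected: every fate arterial
  conn_da <- sim$truth$connectivity
  conn_da$ventral_connection <- "DA"
  fa <- assignFate(sim$tracks, 44, connectivity = conn_da, map = map)
  expect_true(all(fa$class == "aISV"))

  ## an ISV truncated before the final frame is unresolved
  p <- trackPoints(sim$tracks)
  drop_cells <- p$cell_id[!is.na(p$vessel_label) &
                            p$vessel_label == "ISV_3"]
  keep <- p[!(p$cell_id %in% drop_cells & p$t > 40), ]
  tr2 <- TrackTable(keep)
  f2 <- assignFate(tr2, 44, connectivity = sim$truth$connectivity,
                   map = map)
  expect_true(f2$unresolved[f2$vessel_id == "ISV_3"])
})

test_that("exchange detection is hysteretic and exact on injected events", {
  tt <- seq(26, 44, by = 1 / 6)
  map <- oneIsvMap()
  ## a DLAV cell translocating into the ISV over 5 frames at 33 hpf
  onset <- which(abs(tt - 33) < 1e-9)
  y_imm <- c(rep(83, onset - 1), seq(83, 60, length.out = 5),
             rep(60, length(tt) - onset - 4))
  ## a cell poking over the DLAV boundary for 2 frames then returning
  y_flick <- rep(50, length(tt)); y_flick[60:61] <- 78
  tracks <- oneIsvTracks(rbind(
    data.frame(cell_id = "imm", t = tt, y = y_imm),
    data.frame(cell_id = "flick", t = tt, y = y_flick)))
  ex <- detectExchanges(tracks, map, K = 6L)
  expect_equal(ex$imm_dlav, 1L)
  expect_equal(ex$emi_dlav, 0L)
  ev <- attr(ex, "events")
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$cell_id, "imm")

  ## adding more sub-K flicker leaves the ledger invariant
  y_flick2 <- y_flick; y_flick2[80:83] <- 2
  tracks2 <- oneIsvTracks(rbind(
    data.frame(cell_id = "imm", t = tt, y = y_imm),
    data.frame(cell_id = "flick", t = tt, y = y_flick2)))
  ex2 <- detectExchanges(tracks2, map, K = 6L)
  expect_identical(as.data.frame(ex2), as.data.frame(ex))
})

test_that("synthetic cohorts give perfect event recovery at zero noise", {
  cfg <- embryoSimConfig(noise_sd = 0, seed = 31)
  co <- generateCohort(cfg, nEmbryos = 5L)
  map <- regionMap(co$truth[[1]]$isv_x, yDlav = cfg$isv_length)
  ex <- detectExchanges(co$tracks, map, K = 6L)
  ev <- attr(ex, "events")
  led <- co$ledger[co$ledger$type != "division", ]
  expect_setequal(paste(ev$embryo_id, ev$type, ev$vessel_id, ev$cell_id),
                  paste(led$embryo_id, led$type, led$vessel_id,
                        led$cell_id))
  ## mitoses equal the ledger exactly
  mi <- countMitoses(co$tracks, map)
  div <- co$ledger[co$ledger$type == "division", ]
  truth_tab <- table(paste(div$embryo_id, div$vessel_id))
  want <- truth_tab[paste(mi$embryo_id, mi$vessel_id)]
  want <- ifelse(is.na(want), 0L, as.integer(want))
  expect_equal(mi$mitoses, unname(want))
})

test_that("mitosis counting is a pure lineage query", {
  tt26 <- seq(26, 44, by = 1 / 6)
  noDiv <- oneIsvTracks(data.frame(cell_id = "c1", t = tt26, y = 40))
  expect_equal(sum(countMitoses(noDiv, oneIsvMap())$mitoses), 0L)

  p <- rbind(
    data.frame(cell_id = "c1", parent_id = NA, t = tt26[1:30], y = 40),
    data.frame(cell_id = "c1a", parent_id = "c1", t = tt26[31:109], y = 38),
    data.frame(cell_id = "c1b", parent_id = "c1", t = tt26[31:109], y = 42))
  one <- oneIsvTracks(p)
  mi <- countMitoses(one, oneIsvMap())
  expect_equal(mi$mitoses[mi$vessel_id == "ISV_1"], 1L)
  ## >2 children is a data error
  bad <- rbind(p, data.frame(cell_id = "c1c", parent_id = "c1",
                             t = tt26[31:109], y = 44))
  expect_error(countMitoses(oneIsvTracks(bad), oneIsvMap()),
               ">2 children")
})

test_that("cell numbers partition every cell exactly once", {
  cfg <- embryoSimConfig(noise_sd = 0, seed = 12)
  sim <- generateEmbryo(cfg)
  map <- regionMap(sim$truth$isv_x, yDlav = sim$truth$isv_length)
  cn <- cellNumber(sim$tracks, map, t = 44)
  asg <- assignRegions(sim$tracks, map)
  tf <- max(asg$t)
  in_isv <- asg[abs(asg$t - tf) < 1e-9 &
                  !asg$region %in% c("ventral", "dlav"), ]
  expect_equal(sum(cn$n_cells), nrow(in_isv))
  expect_error(cellNumber(sim$tracks, map, t = 99), "outside")
  ## an emptied ISV slot counts zero
  cfg0 <- embryoSimConfig(p_exchange = c(imm_dlav_aisv = 0,
                                         emi_dlav_visv = 0,
                                         imm_pcv_visv = 0),
                          division_hazard = c(aISV = 0, vISV = 0),
                          noise_sd = 0, seed = 12)
  sim0 <- generateEmbryo(cfg0)
  p0 <- trackPoints(sim0$tracks)
  drop0 <- p0$cell_id[!is.na(p0$vessel_label) & p0$vessel_label == "ISV_2"]
  cn0 <- cellNumber(subsetTracks(sim0$tracks,
                                 cells = setdiff(unique(p0$cell_id), drop0)),
                    map, t = 44)
  expect_equal(cn0$n_cells[cn0$vessel_id == "ISV_2"], 0L)
})

test_that("ledger bookkeeping closes: dN = net immigration + mitoses", {
  cfg <- embryoSimConfig(noise_sd = 0, seed = 77)
  co <- generateCohort(cfg, nEmbryos = 5L)
  map <- regionMap(co$truth[[1]]$isv_x, yDlav = cfg$isv_length)
  led <- buildExchangeLedger(co$tracks, map, K = 6L)
  n0 <- cellNumber(co$tracks, map, t = 26)
  n1 <- cellNumber(co$tracks, map, t = 44)
  m <- merge(merge(led, setNames(n0[, c(1, 2, 4)],
                                 c("embryo_id", "vessel_id", "n0")),
                   by = c("embryo_id", "vessel_id")),
             setNames(n1[, c(1, 2, 4)],
                      c("embryo_id", "vessel_id", "n1")),
             by = c("embryo_id", "vessel_id"))
  expect_equal(m$n1 - m$n0, m$net_immigration + m$mitoses)
})

test_that("net immigration is immigration minus emigration by construction", {
  cfg <- embryoSimConfig(seed = 19)
  sim <- generateEmbryo(cfg)
  map <- regionMap(sim$truth$isv_x, yDlav = sim$truth$isv_length)
  ex <- detectExchanges(sim$tracks, map)
  expect_equal(ex$net_immigration,
               (ex$imm_dlav + ex$imm_pcv) - (ex$emi_dlav + ex$emi_pcv))
  expect_true(all(ex$imm_dlav >= 0 & ex$emi_dlav >= 0 &
                    ex$imm_pcv >= 0 & ex$emi_pcv >= 0))
  fr <- exchangeFractions(ex$imm_dlav)
  expect_equal(sum(fr$fraction), 1)
})

test_that("diameter profiles average vessels and recover injected growth", {
  m <- data.frame(embryo_id = "e1", vessel_id = c("a", "b"),
                  vessel_class = "aISV", t = 30, diameter = c(6, 8))
  dp <- diameterProfile(DiameterTable(m), bootstrap = 100L)
  expect_equal(dp$mean, 7)

  one <- diameterProfile(DiameterTable(m[1, ]), bootstrap = 100L)
  expect_equal(one$mean, 6)
  expect_equal(one$lower, one$upper)

  cfg <- embryoSimConfig(seed = 23)
  co <- generateCohort(cfg, nEmbryos = 10L)
  dp2 <- diameterProfile(co$diameters, bootstrap = 100L)
  for (cls in c("aISV", "vISV")) {
    g <- dp2[dp2$vessel_class == cls, ]
    slope <- stats::coef(stats::lm(mean ~ t, g))[2]
    expect_equal(unname(slope), cfg$diameter_slope[[cls]],
                 tolerance = 0.05)
  }
})

test_that("driver correlations hit the exact limits on constructed data", {
  led <- data.frame(embryo_id = "e1", vessel_id = sprintf("ISV_%d", 1:8),
                    class = "vISV", net_immigration = c(-2:5),
                    mitoses = c(5:-2))
  dia <- DiameterTable(data.frame(
    embryo_id = "e1", vessel_id = sprintf("ISV_%d", 1:8),
    vessel_class = "vISV", t = 44, diameter = 6 + 0.5 * (-2:5)))
  cc <- correlateDrivers(led, dia)
  expect_equal(cc$estimate[cc$driver == "net_immigration"], 1)
  expect_equal(cc$estimate[cc$driver == "mitoses"], -1)
  expect_error(correlateDrivers(led[1:2, ], dia), ">= 3 ISVs")
})

test_that("permuted driver pairings have null correlations", {
  set.seed(99)
  n <- 30
  r <- replicate(500, stats::cor(sample(0:3, n, TRUE), rnorm(n, 7, 0.5)))
  expect_lt(abs(mean(r)), 0.05)
  ## 95th percentile of |r| against the t-distribution critical value
  tcrit <- stats::qt(0.975, n - 2)
  rcrit <- tcrit / sqrt(n - 2 + tcrit^2)
  expect_equal(unname(stats::quantile(abs(r), 0.95)), rcrit,
               tolerance = 0.2)
})

test_that("wound metrics follow their defining arithmetic", {
  tt <- seq(0, 960, by = 10)
  straight <- TrackTable(data.frame(
    cell_id = "s", t = tt, x = 80 * tt / 960, y = 0),
    frameInterval = 10, timeUnit = "min", is2D = TRUE)
  wm <- woundMetrics(straight, area0 = 0.5, area16 = 0.2)
  expect_equal(wm$perTrack$effective_speed, 5)
  expect_equal(wm$perTrack$angle, pi / 2)
  expect_equal(wm$closure_pct, 60)

  loop <- TrackTable(data.frame(cell_id = "l", t = c(0, 480, 960),
                                x = c(0, 30, 0), y = c(0, 10, 0)),
                     frameInterval = 10, timeUnit = "min", is2D = TRUE)
  wl <- woundMetrics(loop)
  expect_equal(wl$perTrack$effective_speed, 0)
  expect_true(is.na(wl$perTrack$angle))

  ## chord <= path for every generated track
  m <- generateMonolayer(monolayerSimConfig(n_tracks = 100L, seed = 7,
                                            mode = "isotropic"))
  w <- woundMetrics(m$tracks)
  expect_true(all(w$perTrack$effective_speed <=
                    w$perTrack$mean_speed + 1e-9))
})
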