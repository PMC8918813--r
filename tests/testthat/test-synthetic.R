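test_that("generation is deterministic under a fixed seed and config", {
  cfg <- embryoSimConfig(seed = 42)
  s1 <- generateEmbryo(cfg, "embryo_1")
  s2 <- generateEmbryo(cfg, "embryo_1")
  expect_identical(trackPoints(s1$tracks), trackPoints(s2$tracks))
  expect_identical(s1$ledger, s2$ledger)
  expect_identical(diameterMeasurements(s1$diameters),
                   diameterMeasurements(s2$diameters))
  ## a different embryo id gives a different stream
  s3 <- generateEmbryo(cfg, "embryo_2")
  expect_false(identical(trackPoints(s1$tracks)$y,
                         trackPoints(s3$tracks)$y))
})

test_that("noise-free vISV remodelling drift integrates exactly", {
  cfg <- embryoSimConfig(noise_sd = 0,
                         division_hazard = c(aISV = 0, vISV = 0),
                         p_exchange = c(imm_dlav_aisv = 0,
                                        emi_dlav_visv = 0,
                                        imm_pcv_visv = 0), seed = 1)
  sim <- generateEmbryo(cfg)
  p <- trackPoints(sim$tracks)
  v2 <- sim$truth$fates$vessel_id[sim$truth$fates$class == "vISV"][1]
  cell <- p$cell_id[p$vessel_label == v2][1]
  y <- p$y[p$cell_id == cell]
  t <- p$t[p$cell_id == cell]
  ## any 2-h window fully inside the remodelling phase: displacement 6 um
  for (t_start in c(33, 34.5, 36, 38)) {
    i1 <- which(abs(t - t_start) < 1e-9)
    i2 <- which(abs(t - (t_start + 2)) < 1e-9)
    expect_equal(y[i2] - y[i1], 6, tolerance = 1e-12)
  }
  ## aISV remodelling drift -0.6 um/h: -1.2 um over 2 h
  a1 <- sim$truth$fates$vessel_id[sim$truth$fates$class == "aISV"][1]
  cella <- p$cell_id[p$vessel_label == a1][1]
  ya <- p$y[p$cell_id == cella]; ta <- p$t[p$cell_id == cella]
  i1 <- which(abs(ta - 34) < 1e-9); i2 <- which(abs(ta - 36) < 1e-9)
  expect_equal(ya[i2] - ya[i1], -1.2, tolerance = 1e-12)
})

test_that("division counts match an independent hazard-process oracle", {
  ## 0.12 /cell/h over the full 18 h, 3 cells per vessel, 200 vessels
  cfg <- embryoSimConfig(n_isv = 10L, noise_sd = 0,
                         division_hazard = c(aISV = 0.12, vISV = 0.12),
                         division_window = c(26, 44),
                         p_exchange = c(imm_dlav_aisv = 0,
                                        emi_dlav_visv = 0,
                                        imm_pcv_visv = 0),
                         n_da_cells = 0L, dlav_cells_per_isv = 0L,
                         seed = 9)
  co <- generateCohort(cfg, nEmbryos = 20L)
  per_vessel <- with(co$ledger[co$ledger$type == "division", ],
                     table(paste(embryo_id, vessel_id)))
  got <- sum(per_vessel) / 200
  exp_oracle <- divisionProcessOracle(0.12, 26, 44, c(26, 44), 1 / 6,
                                      3, 4000, seed = 101)
  ## SE of the generator-side mean over 200 vessels
  nv <- as.numeric(per_vessel)
  nv <- c(nv, rep(0, 200 - length(nv)))
  se <- stats::sd(nv) / sqrt(200)
  expect_lt(abs(got - exp_oracle), 3 * se)
})

test_that("config validation rejects impossible setups", {
  expect_error(embryoSimConfig(n_isv = 0), "zero ISVs")
  expect_error(embryoSimConfig(p_second_cell = 1.2), "probabilities")
  expect_error(embryoSimConfig(t0 = 44, t1 = 26), "t1 must exceed")
  expect_error(embryoSimConfig(noise_sd = -1), "noise sd")
  expect_error(monolayerSimConfig(speed = -3), "negative speed")
})

test_that("ledger events are realizable in the emitted tracks", {
  cfg <- embryoSimConfig(noise_sd = 0, seed = 21)
  sim <- generateEmbryo(cfg)
  p <- trackPoints(sim$tracks)
  ex <- sim$ledger[sim$ledger$type != "division", ]
  for (i in seq_len(nrow(ex))) {
    cell <- p[p$cell_id == ex$cell_id[i], ]
    expect_gt(nrow(cell), 0)
    ## the cell ends up where the event says: ISV band after an
    ## immigration, DLAV band after an emigration to the DLAV
    y_end <- cell$y[which.max(cell$t)]
    if (ex$type[i] == "immigration") {
      expect_lt(y_end, sim$truth$isv_length - 5)
      expect_gt(y_end, 5)
    } else if (ex$destination[i] == "DLAV") {
      expect_gt(y_end, sim$truth$isv_length - 5)
    }
  }
})

test_that("monolayer generator matches its stated symmetry and speed", {
  ## pure +x drift, zero noise: all directionality angles equal pi/2
  mc <- monolayerSimConfig(n_tracks = 50L, noise_sd = 0, seed = 3)
  m <- generateMonolayer(mc)
  wm <- woundMetrics(m$tracks)
  expect_equal(unique(round(wm$perTrack$angle, 12)), pi / 2)
  expect_equal(mean(wm$perTrack$effective_speed), 15, tolerance = 1e-9)

  ## isotropic: resultant length near zero at n = 300
  iso <- generateMonolayer(monolayerSimConfig(mode = "isotropic",
                                              speed = 6, seed = 4))
  wi <- woundMetrics(iso$tracks)
  cm <- circularMeanSd(wi$perTrack$angle)
  expect_lt(cm$R, 0.12)

  ## control-like vs knockdown-like speed ratio 0.4 recovered within 5%
  ctrl <- generateMonolayer(monolayerSimConfig(seed = 5))
  kd <- generateMonolayer(monolayerSimConfig(mode = "isotropic",
                                             speed = 15 * 0.4, seed = 6))
  ratio <- mean(woundMetrics(kd$tracks)$perTrack$effective_speed) /
    mean(woundMetrics(ctrl$tracks)$perTrack$effective_speed)
  expect_equal(ratio, 0.4, tolerance = 0.05)

  ## wound area shrinks consistently with the front advance
  expect_true(all(diff(ctrl$areas$area) <= 0))
  a0 <- ctrl$areas$area[1]
  a16 <- ctrl$areas$area[nrow(ctrl$areas)]
  expect_equal(a0, 500 * 1000)
  expect_equal((a0 - a16) / a0 * 100,
               100 * min(1, 2 * 15 * 16 / 500), tolerance = 1e-9)
})
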