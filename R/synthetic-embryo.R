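#' Configuration for the synthetic zebrafish embryo generator
#'
#' The generator emits nuclei tracks on an idealized trunk scaffold: the
#' dorsal aorta along the x-axis at y = 0, the DLAV at y = `isv_length`,
#' and vertical ISVs at multiples of `isv_spacing`. Each ISV cell's y(t)
#' integrates a class- and phase-dependent dorsoventral drift; iid
#' Gaussian positional noise is added per frame (measurement noise, not a
#' random walk). Divisions are a per-cell hazard process that branches
#' tracks; inter-vessel exchange events are continuous translocations
#' over several frames, never teleports. All injected events are recorded
#' in a ground-truth ledger.
#'
#' Defaults encode the study conditions: imaging from 26 to 44 hpf at one
#' frame per 10 min; drift 5 (vISV) and 3.9 (aISV) um/h during sprouting,
#' 2 and 1 during anastomosis, +3 and -0.6 during remodelling, and near
#' zero after 40 hpf; per-vessel probabilities of at least one exchange
#' event of 0.60 (DLAV to aISV immigration), 0.76 (vISV to DLAV
#' emigration) and 0.92 (PCV to vISV immigration); linear diameter growth
#' reaching ~7 um (aISV) and ~8 um (vISV) by 44 hpf. Phase cut points
#' (30, 33, 40 hpf) are configurable, not asserted.
#'
#' @param n_isv number of ISVs (fates alternate starting `first_class`).
#' @param isv_spacing,isv_length scaffold geometry, micrometres.
#' @param t0,t1 recording span, hpf.
#' @param frame_interval minutes between frames.
#' @param phase_breaks named increasing vector of phase onset times (hpf).
#' @param drift list with per-class drift (um/h), one value per phase.
#' @param noise_sd positional measurement noise sd, um per frame.
#' @param cells_per_isv,n_da_cells,dlav_cells_per_isv cell counts.
#' @param division_hazard per-cell division hazard (1/h) per class.
#' @param division_window hpf window in which divisions may occur.
#' @param p_exchange named probabilities of at least one event per
#'   vessel: `imm_dlav_aisv`, `emi_dlav_visv`, `imm_pcv_visv`.
#' @param p_second_cell probability a vessel with events gets a second.
#' @param exchange_window hpf window for exchange event onsets.
#' @param traversal_frames frames an exchange translocation spans (>= 3).
#' @param diameter_start,diameter_slope,diameter_noise_sd per-class
#'   linear diameter model (um, um/h) plus measurement noise.
#' @param first_class class of the first (most rostral) ISV.
#' @param random_frame emit tracks in a random rigid frame (the
#'   canonical coordinates are kept in the ground truth) to exercise
#'   alignment.
#' @param seed master seed; each embryo derives its own stream from
#'   (seed, embryo_id).
#' @return a validated list of class `embryoSimConfig`.
#' @export
embryoSimConfig <- function(n_isv = 10L, isv_spacing = 55, isv_length = 80,
    t0 = 26, t1 = 44, frame_interval = 10,
    phase_breaks = c(sprouting = 26, anastomosis = 30,
                     remodelling = 33, plateau = 40),
    drift = list(aISV = c(3.9, 1, -0.6, 0), vISV = c(5, 2, 3, 0)),
    noise_sd = 0.5, cells_per_isv = 3L, n_da_cells = 20L,
    dlav_cells_per_isv = 1L,
    division_hazard = c(aISV = 0.013, vISV = 0.033),
    division_window = c(27, 43),
    p_exchange = c(imm_dlav_aisv = 0.60, emi_dlav_visv = 0.76,
                   imm_pcv_visv = 0.92),
    p_second_cell = 0.3, exchange_window = c(33, 41.5),
    traversal_frames = 6L,
    diameter_start = c(DA = 22, DLAV = 5, aISV = 4, vISV = 4),
    diameter_slope = c(DA = 0, DLAV = 1 / 18, aISV = 3 / 18, vISV = 4 / 18),
    diameter_noise_sd = 0.3, first_class = c("aISV", "vISV"),
    random_frame = FALSE, seed = 1L) {
  first_class <- match.arg(first_class)
  cfg <- list(n_isv = as.integer(n_isv), isv_spacing = isv_spacing,
              isv_length = isv_length, t0 = t0, t1 = t1,
              frame_interval = frame_interval, phase_breaks = phase_breaks,
              drift = drift, noise_sd = noise_sd,
              cells_per_isv = as.integer(cells_per_isv),
              n_da_cells = as.integer(n_da_cells),
              dlav_cells_per_isv = as.integer(dlav_cells_per_isv),
              division_hazard = division_hazard,
              division_window = division_window, p_exchange = p_exchange,
              p_second_cell = p_second_cell,
              exchange_window = exchange_window,
              traversal_frames = as.integer(traversal_frames),
              diameter_start = diameter_start,
              diameter_slope = diameter_slope,
              diameter_noise_sd = diameter_noise_sd,
              first_class = first_class,
              random_frame = isTRUE(random_frame), seed = as.integer(seed))
  if (cfg$t1 <= cfg$t0) .stopf("config error: t1 must exceed t0")
  if (any(cfg$p_exchange < 0 | cfg$p_exchange > 1) ||
      cfg$p_second_cell < 0 || cfg$p_second_cell > 1)
    .stopf("config error: probabilities must lie in [0, 1]")
  if (cfg$n_isv == 0L && any(cfg$p_exchange > 0))
    .stopf("config error: zero ISVs with nonzero exchange probabilities")
  if (!all(vapply(cfg$drift, function(v) all(is.finite(v)), TRUE)))
    .stopf("config error: drift velocities must be finite")
  if (cfg$noise_sd < 0 || cfg$diameter_noise_sd < 0)
    .stopf("config error: noise sd must be >= 0")
  if (any(cfg$division_hazard < 0))
    .stopf("config error: division hazard must be >= 0")
  if (cfg$traversal_frames < 3L)
    .stopf("config error: traversal must span >= 3 frames")
  np <- length(cfg$phase_breaks)
  if (!all(vapply(cfg$drift, length, 1L) == np))
    .stopf("config error: drift needs one value per phase")
  structure(cfg, class = "embryoSimConfig")
}

## cumulative drift offsets on the frame grid for one class
.cumDrift <- function(times, breaks, drift_values) {
  dth <- diff(times)
  idx <- findInterval(times[-length(times)], breaks)
  c(0, cumsum(drift_values[idx] * dth))
}

#' Generate one synthetic embryo dataset
#'
#' @param config an [embryoSimConfig()].
#' @param embryo_id identifier; also keys this embryo's RNG stream.
#' @return list with elements `tracks` ([TrackTable-class]),
#'   `diameters` ([DiameterTable-class]), `ledger` (data.frame of
#'   injected division/immigration/emigration events), and `truth`
#'   (fates, final-frame ventral connectivity, scaffold geometry, true
#'   drifts and diameter model; canonical coordinates when
#'   `random_frame` is TRUE).
#' @export
generateEmbryo <- function(config, embryo_id = "embryo_1") {
  stopifnot(inherits(config, "embryoSimConfig"))
  set.seed(.childSeed(config$seed, embryo_id))
  cfg <- config
  dt <- cfg$frame_interval / 60
  times <- seq(cfg$t0, cfg$t1, by = dt)
  nF <- length(times)
  cum <- lapply(cfg$drift, .cumDrift, times = times,
                breaks = cfg$phase_breaks)

  classes <- rep(if (cfg$first_class == "aISV") c("aISV", "vISV")
                 else c("vISV", "aISV"),
                 length.out = cfg$n_isv)
  isv_ids <- if (cfg$n_isv) sprintf("ISV_%d", seq_len(cfg$n_isv)) else
    character()
  isv_x <- setNames(cfg$isv_spacing * seq_len(cfg$n_isv), isv_ids)

  rows <- list()
  ledger <- list()
  emit <- function(cell_id, parent_id, idx, x_det, y_det, z_det, label) {
    n <- length(idx)
    rows[[length(rows) + 1L]] <<- data.frame(
      embryo_id = embryo_id, cell_id = cell_id, parent_id = parent_id,
      t = times[idx],
      x = x_det + rnorm(n, 0, cfg$noise_sd),
      y = y_det + rnorm(n, 0, cfg$noise_sd),
      z = z_det + rnorm(n, 0, cfg$noise_sd),
      vessel_label = label)
  }
  log_event <- function(type, cell_id, vessel_id, source, destination, t) {
    ledger[[length(ledger) + 1L]] <<- data.frame(
      embryo_id = embryo_id, type = type, cell_id = cell_id,
      vessel_id = vessel_id, source = source, destination = destination,
      t = t)
  }

  ## --- DA cells: static cloud along the aorta -------------------------
  for (i in seq_len(cfg$n_da_cells)) {
    x0 <- runif(1, 0, cfg$isv_spacing * (cfg$n_isv + 1))
    emit(sprintf("%s_DA_c%d", embryo_id, i), NA_character_, seq_len(nF),
         rep(x0, nF), rep(rnorm(1, 0, 0.8), nF), rep(rnorm(1, 0, 1.5), nF),
         "DA")
  }

  ## --- DLAV resident cells -------------------------------------------
  for (k in seq_len(cfg$n_isv)) for (j in seq_len(cfg$dlav_cells_per_isv)) {
    x0 <- isv_x[k] + runif(1, -10, 10)
    y0 <- cfg$isv_length + 3 + rnorm(1, 0, 0.8)
    emit(sprintf("%s_DLAV_k%d_c%d", embryo_id, k, j), NA_character_,
         seq_len(nF), rep(x0, nF), rep(y0, nF), rep(rnorm(1, 0, 1.5), nF),
         "DLAV")
  }

  ## --- choose exchange events per ISV ---------------------------------
  n_events <- function(p) {
    if (runif(1) >= p) return(0L)
    1L + rbinom(1L, 1L, cfg$p_second_cell)
  }
  draw_onsets <- function(n) {
    if (n == 0L) return(integer())
    vapply(seq_len(n), function(i) draw_onset(), 1L)
  }
  ## event onset frame; leaves room for the traversal plus persistent
  ## residence after arrival
  draw_onset <- function() {
    te <- runif(1, cfg$exchange_window[1L], cfg$exchange_window[2L])
    as.integer(min(max(2L, findInterval(te, times)),
                   nF - cfg$traversal_frames - 7L))
  }

  imm_dlav <- lapply(seq_len(cfg$n_isv), function(k)
    if (classes[k] == "aISV")
      draw_onsets(n_events(cfg$p_exchange[["imm_dlav_aisv"]])) else integer())
  emi_dlav <- lapply(seq_len(cfg$n_isv), function(k)
    if (classes[k] == "vISV")
      draw_onsets(n_events(cfg$p_exchange[["emi_dlav_visv"]])) else integer())
  imm_pcv <- lapply(seq_len(cfg$n_isv), function(k)
    if (classes[k] == "vISV")
      draw_onsets(n_events(cfg$p_exchange[["imm_pcv_visv"]])) else integer())

  ## --- ISV resident cells, divisions, emigrants -----------------------
  exchange_cells <- character()
  for (k in seq_len(cfg$n_isv)) {
    cls <- classes[k]
    n_emi <- min(length(emi_dlav[[k]]), cfg$cells_per_isv)
    emi_onsets <- sort(emi_dlav[[k]])[seq_len(n_emi)]
    for (j in seq_len(cfg$cells_per_isv)) {
      cid <- sprintf("%s_%s_c%d", embryo_id, isv_ids[k], j)
      x0 <- isv_x[k] + rnorm(1, 0, 0.8)
      z0 <- rnorm(1, 0, 1.5)
      y0 <- runif(1, 8, 18)
      if (j <= n_emi) {
        ## emigrant: resident until onset, translocates into the DLAV
        ie <- emi_onsets[j]
        tf <- cfg$traversal_frames
        y_pre <- y0 + cum[[cls]][seq_len(ie - 1L)]
        y_go <- seq(y_pre[ie - 1L], cfg$isv_length + 3,
                    length.out = tf + 1L)[-1L]
        y_post <- rep(cfg$isv_length + 3, nF - ie - tf + 1L)
        lab <- c(rep(isv_ids[k], ie - 1L + floor(tf / 2)),
                 rep("DLAV", nF - ie + 1L - floor(tf / 2)))
        emit(cid, NA_character_, seq_len(nF), rep(x0, nF),
             c(y_pre, y_go, y_post), rep(z0, nF), lab)
        log_event("emigration", cid, isv_ids[k], isv_ids[k], "DLAV",
                  times[ie])
        exchange_cells <- c(exchange_cells, cid)
      } else {
        ## resident: hazard-driven branching lineage
        .simLineage(cid, NA_character_, 1L, times, nF, dt, cfg, cum, cls,
                    x0, y0, z0, isv_ids[k], emit, log_event)
      }
    }
    ## immigrants from the DLAV (aISVs)
    for (ei in seq_along(imm_dlav[[k]])) {
      ie <- imm_dlav[[k]][ei]
      tf <- cfg$traversal_frames
      cid <- sprintf("%s_%s_immD%d", embryo_id, isv_ids[k], ei)
      x0 <- isv_x[k] + rnorm(1, 0, 0.8)
      y_src <- cfg$isv_length + 3 + rnorm(1, 0, 0.8)
      y_arr <- cfg$isv_length - 20
      y_pre <- rep(y_src, ie - 1L)
      y_go <- seq(y_src, y_arr, length.out = tf + 1L)[-1L]
      post_idx <- seq(ie + tf, nF)
      y_post <- y_arr + cum[[cls]][post_idx] - cum[[cls]][ie + tf]
      lab <- c(rep("DLAV", ie - 1L + floor(tf / 2)),
               rep(isv_ids[k], nF - ie + 1L - floor(tf / 2)))
      emit(cid, NA_character_, seq_len(nF), rep(x0, nF),
           c(y_pre, y_go, y_post), rep(rnorm(1, 0, 1.5), nF), lab)
      log_event("immigration", cid, isv_ids[k], "DLAV", isv_ids[k],
                times[ie])
      exchange_cells <- c(exchange_cells, cid)
    }
    ## immigrants from the PCV (vISVs); the PCV is a source band below
    ## the aorta (y < 0), entry at the ISV's ventral end
    for (ei in seq_along(imm_pcv[[k]])) {
      ie <- imm_pcv[[k]][ei]
      tf <- cfg$traversal_frames + 3L
      cid <- sprintf("%s_%s_immP%d", embryo_id, isv_ids[k], ei)
      x0 <- isv_x[k] + rnorm(1, 0, 0.8)
      y_src <- -5 + rnorm(1, 0, 0.8)
      y_arr <- 15
      y_pre <- rep(y_src, ie - 1L)
      y_go <- seq(y_src, y_arr, length.out = tf + 1L)[-1L]
      post_idx <- seq(ie + tf, nF)
      y_post <- y_arr + cum[[cls]][post_idx] - cum[[cls]][ie + tf]
      lab <- c(rep("PCV", ie - 1L + floor(tf / 2)),
               rep(isv_ids[k], nF - ie + 1L - floor(tf / 2)))
      emit(cid, NA_character_, seq_len(nF), rep(x0, nF),
           c(y_pre, y_go, y_post), rep(rnorm(1, 0, 1.5), nF), lab)
      log_event("immigration", cid, isv_ids[k], "PCV", isv_ids[k],
                times[ie])
      exchange_cells <- c(exchange_cells, cid)
    }
  }

  points <- do.call(rbind, rows)
  ledger <- if (length(ledger)) do.call(rbind, ledger) else
    data.frame(embryo_id = character(), type = character(),
               cell_id = character(), vessel_id = character(),
               source = character(), destination = character(),
               t = numeric())

  truth <- list(
    fates = data.frame(embryo_id = embryo_id, vessel_id = isv_ids,
                       class = classes),
    connectivity = data.frame(embryo_id = embryo_id, vessel_id = isv_ids,
                              ventral_connection =
                                ifelse(classes == "vISV", "PCV", "DA")),
    isv_x = isv_x, isv_length = cfg$isv_length,
    drift = cfg$drift, phase_breaks = cfg$phase_breaks,
    diameter_start = cfg$diameter_start,
    diameter_slope = cfg$diameter_slope,
    exchange_cells = unique(exchange_cells))

  ## --- diameters (hourly grid, per-vessel noise around class line) ----
  td <- seq(cfg$t0, cfg$t1, by = 1)
  dia_rows <- lapply(seq_len(cfg$n_isv), function(k) {
    cls <- classes[k]
    d <- cfg$diameter_start[[cls]] + cfg$diameter_slope[[cls]] * (td - cfg$t0) +
      rnorm(length(td), 0, cfg$diameter_noise_sd)
    data.frame(embryo_id = embryo_id, vessel_id = isv_ids[k],
               vessel_class = cls, t = td, diameter = pmax(d, 0.2))
  })
  for (cls in c("DA", "DLAV")) {
    d <- cfg$diameter_start[[cls]] + cfg$diameter_slope[[cls]] * (td - cfg$t0) +
      rnorm(length(td), 0, cfg$diameter_noise_sd)
    dia_rows[[length(dia_rows) + 1L]] <-
      data.frame(embryo_id = embryo_id, vessel_id = paste0(cls, "_1"),
                 vessel_class = cls, t = td, diameter = pmax(d, 0.2))
  }
  diameters <- DiameterTable(do.call(rbind, dia_rows))

  ## --- optional random rigid frame ------------------------------------
  if (cfg$random_frame) {
    truth$canonical <- TrackTable(points,
                                  frameInterval = cfg$frame_interval)
    Q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    shift <- runif(3, -100, 100)
    xyz <- t(Q %*% t(as.matrix(points[, c("x", "y", "z")])) + shift)
    points$x <- xyz[, 1]; points$y <- xyz[, 2]; points$z <- xyz[, 3]
    truth$applied_rotation <- Q
    truth$applied_translation <- shift
  }

  list(tracks = TrackTable(points, frameInterval = cfg$frame_interval),
       diameters = diameters, ledger = ledger, truth = truth,
       config = cfg)
}

## recursive hazard-driven lineage simulation for one resident cell;
## divisions snap to the frame grid, each segment keeps >= 2 frames
.simLineage <- function(cid, parent, startIdx, times, nF, dt, cfg, cum,
                        cls, x0, y_at_start, z0, vessel, emit, log_event) {
  hz <- cfg$division_hazard[[cls]]
  idiv <- NA_integer_
  if (hz > 0) {
    clock0 <- max(times[startIdx], cfg$division_window[1L])
    tdiv <- clock0 + stats::rexp(1L, hz)
    if (tdiv <= min(times[nF], cfg$division_window[2L])) {
      i <- findInterval(tdiv, times)
      if (i >= startIdx + 2L && i <= nF - 2L) idiv <- i
    }
  }
  y_path <- function(idx) y_at_start + cum[[cls]][idx] - cum[[cls]][startIdx]
  if (is.na(idiv)) {
    idx <- seq(startIdx, nF)
    emit(cid, parent, idx, rep(x0, length(idx)), y_path(idx),
         rep(z0, length(idx)), vessel)
    return(invisible())
  }
  idx <- seq(startIdx, idiv)
  emit(cid, parent, idx, rep(x0, length(idx)), y_path(idx),
       rep(z0, length(idx)), vessel)
  log_event("division", cid, vessel, vessel, vessel, times[idiv])
  y_div <- y_path(idiv)
  for (d in 1:2) {
    off <- if (d == 1L) -1.5 else 1.5
    .simLineage(paste0(cid, letters[d]), cid, idiv + 1L, times, nF, dt,
                cfg, cum, cls, x0 + rnorm(1, 0, 0.8), y_div + off,
                z0, vessel, emit, log_event)
  }
  invisible()
}

#' Generate a cohort of synthetic embryos
#'
#' Each embryo uses its own RNG stream derived from (seed, embryo id), so
#' any embryo can be regenerated in isolation.
#'
#' @param config an [embryoSimConfig()].
#' @param nEmbryos number of embryos.
#' @return list with combined `tracks`, `diameters`, `ledger`, `fates`,
#'   `connectivity`, `exchange_cells` and the per-embryo `truth` list.
#' @export
generateCohort <- function(config, nEmbryos = 20L) {
  sims <- lapply(seq_len(nEmbryos), function(i)
    generateEmbryo(config, embryo_id = sprintf("embryo_%d", i)))
  tracks <- TrackTable(do.call(rbind, lapply(sims, function(s)
    trackPoints(s$tracks))), frameInterval = config$frame_interval)
  diameters <- DiameterTable(do.call(rbind, lapply(sims, function(s)
    diameterMeasurements(s$diameters))))
  list(tracks = tracks, diameters = diameters,
       ledger = do.call(rbind, lapply(sims, `[[`, "ledger")),
       fates = do.call(rbind, lapply(sims, function(s) s$truth$fates)),
       connectivity = do.call(rbind, lapply(sims, function(s)
         s$truth$connectivity)),
       exchange_cells = unlist(lapply(sims, function(s)
         s$truth$exchange_cells), use.names = FALSE),
       truth = lapply(sims, `[[`, "truth"),
       config = config)
}
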