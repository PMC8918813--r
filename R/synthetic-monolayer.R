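#' Configuration for the synthetic HUVEC monolayer generator
#'
#' Emulates nuclei tracks from a scratch-wound assay: the wound edge runs
#' along the y-axis and the cell-free space is the positive-x half plane.
#' Control-like cells move persistently toward the wound (+x); knockdown-
#' like cells keep the same step scale but take a random, per-cell
#' persistent direction, so their chord-based effective speed is set by
#' `speed` while their net advance into the wound collapses.
#'
#' Defaults: 300 tracks over 16 h at one frame per 10 min, a 500 um
#' cell-free gap, control drift 15 um/h.
#'
#' @param n_tracks number of cells.
#' @param duration assay duration, minutes.
#' @param frame_interval minutes between frames.
#' @param mode `"drift"` (control-like, toward +x) or `"isotropic"`
#'   (random persistent per-cell direction).
#' @param speed persistent migration speed, um/h (must be >= 0).
#' @param noise_sd positional noise sd, um per frame.
#' @param gap_width initial cell-free gap, um.
#' @param field_height imaged field height, um.
#' @param seed RNG seed.
#' @return a validated list of class `monolayerSimConfig`.
#' @export
monolayerSimConfig <- function(n_tracks = 300L, duration = 960,
    frame_interval = 10, mode = c("drift", "isotropic"), speed = 15,
    noise_sd = 0.5, gap_width = 500, field_height = 1000, seed = 1L) {
  mode <- match.arg(mode)
  if (speed < 0) .stopf("config error: negative speed")
  if (noise_sd < 0) .stopf("config error: negative noise sd")
  if (duration <= 0 || frame_interval <= 0)
    .stopf("config error: duration and frame interval must be positive")
  structure(list(n_tracks = as.integer(n_tracks), duration = duration,
                 frame_interval = frame_interval, mode = mode,
                 speed = speed, noise_sd = noise_sd,
                 gap_width = gap_width, field_height = field_height,
                 seed = as.integer(seed)),
            class = "monolayerSimConfig")
}

#' Generate a synthetic scratch-wound dataset
#'
#' @param config a [monolayerSimConfig()].
#' @param assay_id identifier used as the embryo/assay field.
#' @return list with `tracks` (2D [TrackTable-class], time in minutes),
#'   `areas` (data.frame `t` minutes, `area` um^2 of cell-free space)
#'   and `truth` (per-cell direction and speed, front speed).
#' @export
generateMonolayer <- function(config, assay_id = "assay_1") {
  stopifnot(inherits(config, "monolayerSimConfig"))
  set.seed(.childSeed(config$seed, assay_id))
  cfg <- config
  times <- seq(0, cfg$duration, by = cfg$frame_interval)
  nF <- length(times)
  th <- times / 60 # hours
  theta <- if (cfg$mode == "drift") rep(0, cfg$n_tracks) else
    runif(cfg$n_tracks, -pi, pi)
  x0 <- runif(cfg$n_tracks, -200, 0)
  y0 <- runif(cfg$n_tracks, 0, cfg$field_height)
  rows <- lapply(seq_len(cfg$n_tracks), function(i) {
    data.frame(embryo_id = assay_id,
               cell_id = sprintf("%s_c%03d", assay_id, i),
               parent_id = NA_character_, t = times,
               x = x0[i] + cfg$speed * th * cos(theta[i]) +
                 rnorm(nF, 0, cfg$noise_sd),
               y = y0[i] + cfg$speed * th * sin(theta[i]) +
                 rnorm(nF, 0, cfg$noise_sd),
               z = 0, vessel_label = NA_character_)
  })
  tracks <- TrackTable(do.call(rbind, rows),
                       frameInterval = cfg$frame_interval,
                       timeUnit = "min", is2D = TRUE)
  ## both wound fronts advance at the mean x-velocity of the population
  v_front <- cfg$speed * mean(cos(theta)) # um/h
  gap <- pmax(0, cfg$gap_width - 2 * pmax(0, v_front) * th)
  areas <- data.frame(t = times, area = gap * cfg$field_height)
  list(tracks = tracks, areas = areas,
       truth = list(direction = theta, speed = cfg$speed,
                    front_speed = v_front))
}
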