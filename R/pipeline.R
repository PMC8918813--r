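#' Align each embryo's tracks into its own canonical frame
#'
#' Fits the aorta axis and DLAV roll per embryo (frames are never shared
#' across embryos) and returns the recombined table plus the per-embryo
#' frames.
#'
#' @param tracks a [TrackTable-class] with DA and DLAV vessel labels.
#' @param daLabel,dlavLabel labels used for the fit.
#' @return list: `tracks` (aligned), `frames` (named list of
#'   [CanonicalFrame-class]).
#' @export
alignEmbryos <- function(tracks, daLabel = "DA", dlavLabel = "DLAV") {
  p <- trackPoints(tracks)
  frames <- list()
  parts <- lapply(unique(p$embryo_id), function(em) {
    sub <- TrackTable(p[p$embryo_id == em, , drop = FALSE],
                      frameInterval = tracks@frameInterval,
                      timeUnit = tracks@timeUnit, is2D = tracks@is2D)
    ct <- canonicalTransform(sub, daLabel = daLabel, dlavLabel = dlavLabel)
    frames[[em]] <<- ct$frame
    trackPoints(ct$tracks)
  })
  list(tracks = TrackTable(do.call(rbind, parts),
                           frameInterval = tracks@frameInterval,
                           timeUnit = tracks@timeUnit, is2D = tracks@is2D),
       frames = frames)
}

## order-insensitive content hash (FNV-1a over the serialised object)
.configHash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 2166136261
  for (b in bytes) h <- ((bitwXor(as.integer(h %% 2^31), b)) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Run the simulate - align - quantify - flow - stats pipeline
#'
#' One reproducible end-to-end run over synthetic data: every stage
#' writes tidy CSV/JSON outputs into `outDir`, a markdown report links
#' the five quantity families (cell trajectories, vessel diameters,
#' vessel cell number, cell mitosis, inter-vessel cell migration), and a
#' manifest records the configuration, its hash, all seeds and package
#' versions so any stage can be re-run in isolation. A stage failure
#' aborts with the failing stage named; outputs of completed stages are
#' retained.
#'
#' @param config list (or path to a YAML file) with elements `seed`,
#'   `out_dir`, `stages` (subset of simulate, align, quantify, flow,
#'   stats), `n_embryos`, `sim` (arguments for [embryoSimConfig()]),
#'   `quantify` (window, K, final_time), `flow` (times, parameter
#'   overrides).
#' @return invisibly, a list with the in-memory results per stage.
#' @export
runPipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  stages <- config$stages %||% c("simulate", "align", "quantify", "flow",
                                 "stats")
  out_dir <- config$out_dir %||% stop("config needs out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  t_start <- Sys.time()
  log_line <- function(stage, msg)
    message(sprintf("[vesseldyn] %-9s %6.1fs  %s", stage,
                    as.numeric(difftime(Sys.time(), t_start, units = "secs")),
                    msg))
  run_stage <- function(stage, fn) {
    log_line(stage, "start")
    out <- tryCatch(fn(), error = function(e)
      .stopf("stage '%s' failed: %s", stage, conditionMessage(e)))
    log_line(stage, "done")
    out
  }

  sim_args <- config$sim %||% list()
  sim_args$seed <- seed
  sim_cfg <- do.call(embryoSimConfig, sim_args)
  if ("simulate" %in% stages) {
    res$simulate <- run_stage("simulate", function() {
      cohort <- generateCohort(sim_cfg, nEmbryos = config$n_embryos %||% 5L)
      writeTracks(cohort$tracks, file.path(out_dir, "tracks.csv"))
      writeDiameters(cohort$diameters, file.path(out_dir, "diameters.csv"))
      write.csv(cohort$ledger, file.path(out_dir, "ledger.csv"),
                row.names = FALSE)
      write.csv(cohort$connectivity, file.path(out_dir, "connectivity.csv"),
                row.names = FALSE)
      cohort
    })
  }
  cohort <- res$simulate
  if ("align" %in% stages && !is.null(cohort)) {
    res$align <- run_stage("align", function() {
      if (sim_cfg$random_frame) alignEmbryos(cohort$tracks)
      else list(tracks = cohort$tracks, frames = list())
    })
  }
  aligned <- res$align$tracks %||% cohort$tracks
  qcfg <- config$quantify %||% list()
  map <- NULL
  if (!is.null(cohort)) {
    map <- regionMap(setNames(sim_cfg$isv_spacing * seq_len(sim_cfg$n_isv),
                              sprintf("ISV_%d", seq_len(sim_cfg$n_isv))),
                     yDlav = sim_cfg$isv_length,
                     delta = qcfg$delta %||% 5)
  }
  if ("quantify" %in% stages && !is.null(cohort)) {
    res$quantify <- run_stage("quantify", function() {
      final_time <- qcfg$final_time %||% sim_cfg$t1
      fate <- assignFate(aligned, finalTime = final_time,
                         connectivity = cohort$connectivity, map = map)
      vel <- windowedVelocity(aligned, fate, map = map,
                              window = qcfg$window %||% 2,
                              t0 = sim_cfg$t0, t1 = sim_cfg$t1,
                              bootstrap = qcfg$bootstrap %||% 1000L,
                              seed = seed)
      ledger <- buildExchangeLedger(aligned, map, K = qcfg$K %||% 6L,
                                    fate = fate)
      numbers <- cellNumber(aligned, map, t = final_time, fate = fate)
      dprof <- diameterProfile(cohort$diameters, fate = fate,
                               bootstrap = qcfg$bootstrap %||% 1000L,
                               seed = seed)
      corr <- correlateDrivers(ledger, cohort$diameters, t = final_time)
      write.csv(vel, file.path(out_dir, "velocity_profile.csv"),
                row.names = FALSE)
      write.csv(as.data.frame(ledger),
                file.path(out_dir, "exchange_ledger.csv"),
                row.names = FALSE)
      write.csv(ledger[, c("embryo_id", "vessel_id", "class", "mitoses")],
                file.path(out_dir, "mitoses.csv"), row.names = FALSE)
      write.csv(numbers, file.path(out_dir, "cell_numbers.csv"),
                row.names = FALSE)
      write.csv(dprof, file.path(out_dir, "diameter_profile.csv"),
                row.names = FALSE)
      write.csv(corr, file.path(out_dir, "correlations.csv"),
                row.names = FALSE)
      list(fate = fate, velocity = vel, ledger = ledger,
           numbers = numbers, diameter_profile = dprof,
           correlations = corr)
    })
  }
  if ("flow" %in% stages && !is.null(cohort)) {
    res$flow <- run_stage("flow", function() {
      fcfg <- config$flow %||% list()
      params <- do.call(flowParameters, fcfg$params %||% list())
      net <- buildIdealizedNetwork(
        isvSpacing = sim_cfg$isv_spacing, isvLength = sim_cfg$isv_length,
        nIsv = fcfg$n_isv %||% 30L, diameters = cohort$diameters)
      times <- fcfg$times %||% seq(sim_cfg$t0, sim_cfg$t1, by = 1)
      sol <- simulateTimecourse(net, params, times)
      ws <- wssSummary(sol)
      write.csv(ws, file.path(out_dir, "wss.csv"), row.names = FALSE)
      list(network = net, solution = sol, wss = ws)
    })
  }
  if ("stats" %in% stages && !is.null(res$quantify)) {
    res$stats <- run_stage("stats", function() {
      ledger <- res$quantify$ledger
      by_class <- split(ledger, ledger$class)
      out <- list()
      if (all(c("aISV", "vISV") %in% names(by_class))) {
        ks_mit <- discreteKs(by_class$aISV$mitoses, by_class$vISV$mitoses,
                             seed = seed)
        num <- res$quantify$numbers
        ks_num <- discreteKs(num$n_cells[num$class == "aISV"],
                             num$n_cells[num$class == "vISV"],
                             seed = seed + 1L)
        out <- list(
          mitoses_aISV_vs_vISV = list(D = unname(ks_mit$statistic),
                                      p = ks_mit$p.value),
          cell_number_aISV_vs_vISV = list(D = unname(ks_num$statistic),
                                          p = ks_num$p.value))
      }
      jsonlite::write_json(out, file.path(out_dir, "stats.json"),
                           auto_unbox = TRUE, digits = NA)
      out
    })
  }

  manifest <- list(
    config = config, config_hash = .configHash(config), seed = seed,
    stages = stages,
    versions = list(R = R.version.string,
                    vesseldyn = as.character(utils::packageVersion("vesseldyn"))),
    outputs = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report <- c(
    "# vesseldyn run report", "",
    sprintf("- embryos: %d", config$n_embryos %||% 5L),
    sprintf("- stages: %s", paste(stages, collapse = ", ")),
    sprintf("- seed: %d", seed),
    "",
    "Quantity families: cell trajectories (tracks.csv, velocity_profile.csv),",
    "vessel diameters (diameters.csv, diameter_profile.csv, wss.csv),",
    "vessel cell number (cell_numbers.csv), cell mitosis (mitoses.csv),",
    "inter-vessel cell migration (exchange_ledger.csv).")
  writeLines(report, file.path(out_dir, "report.md"))
  invisible(res)
}
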