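#' Assign arterial/venous fate to each ISV from its final connectivity
#'
#' An ISV is venous if its ventral connection at the final frame is the
#' PCV, arterial if it remains connected to the aorta. Fate is applied
#' retroactively to all earlier frames. ISVs without a resolvable
#' ventral connection are flagged unresolved and excluded from class
#' statistics.
#'
#' @param tracks an aligned [TrackTable-class] (used with the geometric
#'   fallback and to list ISVs present at the final frame).
#' @param finalTime hpf of the final identity call (44 by default).
#' @param connectivity data.frame `embryo_id`, `vessel_id`,
#'   `ventral_connection` ("DA" or "PCV") read off the final frame; when
#'   NULL a geometric fallback marks an ISV venous if any of its member
#'   cells traverses the ventral band in the last quarter of the
#'   recording.
#' @param map a [regionMap()]; required for the geometric fallback and
#'   for the presence check.
#' @return data.frame of class `isvFate`: `embryo_id`, `vessel_id`,
#'   `class` ("aISV"/"vISV", NA when unresolved), `unresolved`.
#' @export
assignFate <- function(tracks, finalTime = 44, connectivity = NULL,
                       map = NULL) {
  if (is.null(connectivity) && is.null(map))
    .stopf("assignFate needs a connectivity table or a region map")
  if (!is.null(map)) {
    asg <- assignRegions(tracks, map)
    if (finalTime < min(asg$t) - 1e-9 || finalTime > max(asg$t) + 1e-9)
      .stopf("finalTime %g outside the recording [%g, %g]",
             finalTime, min(asg$t), max(asg$t))
    tf <- asg$t[which.min(abs(asg$t - finalTime))]
    present <- unique(asg[abs(asg$t - tf) < 1e-9 &
                            !asg$region %in% c("ventral", "dlav"),
                          c("embryo_id", "region")])
    names(present) <- c("embryo_id", "vessel_id")
    universe <- expand.grid(embryo_id = unique(trackPoints(tracks)$embryo_id),
                            vessel_id = names(map$isv_x),
                            stringsAsFactors = FALSE)
  } else {
    present <- unique(connectivity[, c("embryo_id", "vessel_id")])
    universe <- present
  }
  present$at_final <- TRUE
  if (!is.null(connectivity)) {
    out <- merge(universe, connectivity, all.x = TRUE)
    out <- merge(out, present, all.x = TRUE)
    out$class <- ifelse(is.na(out$ventral_connection), NA_character_,
                        ifelse(out$ventral_connection == "PCV",
                               "vISV", "aISV"))
    ## an ISV no longer present at the final frame has no resolvable
    ## final identity
    if (!is.null(map)) out$class[is.na(out$at_final)] <- NA_character_
    out$ventral_connection <- NULL
    out$at_final <- NULL
  } else {
    ## geometric fallback: late ventral-band traffic marks a PCV
    ## connection
    t_late <- max(asg$t) - (max(asg$t) - min(asg$t)) / 4
    late <- asg[asg$t >= t_late, ]
    ventral_cells <- unique(late$cell_id[late$region == "ventral"])
    out <- universe
    pk <- paste(present$embryo_id, present$vessel_id)
    out$class <- vapply(seq_len(nrow(out)), function(i) {
      if (!paste(out$embryo_id[i], out$vessel_id[i]) %in% pk)
        return(NA_character_)
      members <- unique(late$cell_id[late$region == out$vessel_id[i] &
                                       late$embryo_id == out$embryo_id[i]])
      if (any(members %in% ventral_cells)) "vISV" else "aISV"
    }, "")
  }
  out$unresolved <- is.na(out$class)
  out <- out[order(out$embryo_id, out$vessel_id), ]
  rownames(out) <- NULL
  class(out) <- c("isvFate", "data.frame")
  out
}

.classOf <- function(fate) {
  setNames(fate$class, paste(fate$embryo_id, fate$vessel_id, sep = "\r"))
}

#' Windowed dorsoventral velocity profiles per vessel class
#'
#' For each cell and each 2-h window (stepped every 10 min across the
#' recording) the velocity is the signed y-displacement between the
#' cell's first and last sample inside the window divided by the time
#' between those samples; positive means dorsal movement (away from the
#' aorta). A cell contributes to the class of the ISV it occupies for
#' the majority of the window; cells with fewer than two samples in a
#' window, or mostly outside the ISV band, contribute nothing. Per-class
#' means carry a nonparametric bootstrap confidence interval over cells.
#'
#' @param tracks aligned [TrackTable-class].
#' @param fate an [assignFate()] result.
#' @param map a [regionMap()] (ignored if `assignment` given).
#' @param assignment precomputed [assignRegions()] output.
#' @param window window width, hours.
#' @param step grid step, hours (10 min).
#' @param t0,t1 profile span, hpf.
#' @param bootstrap resamples for the CI.
#' @param level confidence level.
#' @param seed seed for the bootstrap stream.
#' @param cells restrict to these cell ids (default all).
#' @return data.frame of class `velocityProfile`: `class`, `t_mid`,
#'   `velocity` (um/h), `lower`, `upper`, `n_cells`.
#' @export
windowedVelocity <- function(tracks, fate, map = NULL, assignment = NULL,
                             window = 2, step = 1 / 6, t0 = 26, t1 = 44,
                             bootstrap = 2000L, level = 0.95, seed = 1L,
                             cells = NULL) {
  if (is.null(assignment)) {
    if (is.null(map)) .stopf("need a region map or a precomputed assignment")
    assignment <- assignRegions(tracks, map)
  }
  a <- assignment
  if (!is.null(cells)) a <- a[a$cell_id %in% cells, , drop = FALSE]
  cls_of <- .classOf(fate)
  a$key <- paste(a$embryo_id, a$cell_id, sep = "\r")
  a <- a[order(a$key, a$t), ]
  centers <- seq(t0 + window / 2, t1 - window / 2, by = step)
  split_idx <- split(seq_len(nrow(a)), a$key)
  out <- vector("list", length(centers))
  for (w in seq_along(centers)) {
    lo <- centers[w] - window / 2
    hi <- centers[w] + window / 2
    per_cell <- vapply(split_idx, function(ii) {
      tt <- a$t[ii]
      inw <- which(tt >= lo - 1e-9 & tt <= hi + 1e-9)
      if (length(inw) < 2L) return(c(NA_real_, NA_real_))
      reg <- a$region[ii][inw]
      isv <- reg[!reg %in% c("ventral", "dlav")]
      if (length(isv) <= length(inw) / 2) return(c(NA_real_, NA_real_))
      vessel <- names(which.max(table(isv)))
      cls <- cls_of[paste(a$embryo_id[ii][1L], vessel, sep = "\r")]
      if (is.na(cls)) return(c(NA_real_, NA_real_))
      i1 <- inw[1L]; i2 <- inw[length(inw)]
      v <- (a$y[ii][i2] - a$y[ii][i1]) / (tt[i2] - tt[i1])
      c(v, if (cls == "aISV") 1 else 2)
    }, c(0, 0))
    for (ci in 1:2) {
      cls <- c("aISV", "vISV")[ci]
      v <- per_cell[1L, per_cell[2L, ] == ci & !is.na(per_cell[2L, ])]
      ci95 <- bootstrapCI(v, n = bootstrap, level = level,
                          seed = seed + w * 7L + ci)
      out[[w]] <- rbind(out[[w]],
        data.frame(class = cls, t_mid = centers[w],
                   velocity = ci95[["mean"]], lower = ci95[["lower"]],
                   upper = ci95[["upper"]], n_cells = ci95[["n"]]))
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("velocityProfile", "data.frame")
  res
}

## hysteretic held-state sequence from a per-frame region sequence:
## a state must persist >= K consecutive frames to register
.heldStates <- function(regions, K) {
  r <- rle(regions)
  keep <- r$lengths >= K
  if (!any(keep)) return(list(states = character(), starts = integer()))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  s <- r$values[keep]
  st <- starts[keep]
  dup <- c(FALSE, s[-1L] == s[-length(s)])
  list(states = s[!dup], starts = st[!dup])
}

#' Detect inter-vessel exchange events with hysteresis
#'
#' A cell's region assignment must persist for at least `K` consecutive
#' frames (default 6, i.e. 1 h at 10-min frames) to count as a new
#' residence; sub-threshold boundary flicker generates no events.
#' Transitions between held residences involving an ISV are recorded as
#' immigration into or emigration out of that ISV, from/to the DLAV or
#' the ventral (PCV) band.
#'
#' @param tracks aligned [TrackTable-class].
#' @param map a [regionMap()] (ignored if `assignment` given).
#' @param K persistence threshold, frames.
#' @param fate optional [assignFate()] result, adds a class column.
#' @param assignment precomputed [assignRegions()] output.
#' @return data.frame of class `exchangeCounts`, one row per ISV:
#'   `embryo_id`, `vessel_id`, `class`, `imm_dlav`, `emi_dlav`,
#'   `imm_pcv`, `emi_pcv`, `net_immigration`; attribute `"events"` holds
#'   the individual events.
#' @export
detectExchanges <- function(tracks, map = NULL, K = 6L, fate = NULL,
                            assignment = NULL) {
  if (is.null(assignment)) {
    if (is.null(map)) .stopf("need a region map or a precomputed assignment")
    assignment <- assignRegions(tracks, map)
  }
  a <- assignment
  a$key <- paste(a$embryo_id, a$cell_id, sep = "\r")
  a <- a[order(a$key, a$t), ]
  ev <- list()
  for (ii in split(seq_len(nrow(a)), a$key)) {
    hs <- .heldStates(a$region[ii], K)
    s <- hs$states
    if (length(s) < 2L) next
    for (j in seq_len(length(s) - 1L)) {
      from <- s[j]; to <- s[j + 1L]
      t_ev <- a$t[ii][hs$starts[j + 1L]]
      em <- a$embryo_id[ii][1L]; cid <- a$cell_id[ii][1L]
      rec <- function(type, vessel, src, dst)
        ev[[length(ev) + 1L]] <<- data.frame(
          embryo_id = em, cell_id = cid, type = type, vessel_id = vessel,
          source = src, destination = dst, t = t_ev)
      from_isv <- !from %in% c("ventral", "dlav")
      to_isv <- !to %in% c("ventral", "dlav")
      if (from_isv && to == "dlav") rec("emigration", from, from, "DLAV")
      else if (from == "dlav" && to_isv) rec("immigration", to, "DLAV", to)
      else if (from_isv && to == "ventral") rec("emigration", from, from, "PCV")
      else if (from == "ventral" && to_isv) rec("immigration", to, "PCV", to)
      ## ISV-to-ISV or ventral<->dlav residence changes carry no
      ## ISV exchange semantics
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(embryo_id = character(), cell_id = character(),
               type = character(), vessel_id = character(),
               source = character(), destination = character(),
               t = numeric())
  ## tabulate per ISV over the full slot universe
  isv_ids <- names(map$isv_x %||% NULL)
  universe <- unique(rbind(
    unique(a[!a$region %in% c("ventral", "dlav"), c("embryo_id", "region")]),
    if (!is.null(isv_ids))
      expand.grid(embryo_id = unique(a$embryo_id), region = isv_ids,
                  stringsAsFactors = FALSE)))
  names(universe) <- c("embryo_id", "vessel_id")
  universe <- unique(universe)
  cnt <- function(type, src_dst, col) {
    sel <- events[events$type == type & events[[col]] == src_dst, ]
    if (!nrow(sel)) return(integer(nrow(universe)))
    key <- paste(sel$embryo_id, sel$vessel_id)
    tab <- table(key)
    as.integer(tab[paste(universe$embryo_id, universe$vessel_id)]) |>
      (\(v) ifelse(is.na(v), 0L, v))()
  }
  out <- universe
  out$imm_dlav <- cnt("immigration", "DLAV", "source")
  out$emi_dlav <- cnt("emigration", "DLAV", "destination")
  out$imm_pcv <- cnt("immigration", "PCV", "source")
  out$emi_pcv <- cnt("emigration", "PCV", "destination")
  out$net_immigration <- (out$imm_dlav + out$imm_pcv) -
    (out$emi_dlav + out$emi_pcv)
  if (!is.null(fate)) {
    cls_of <- .classOf(fate)
    out$class <- unname(cls_of[paste(out$embryo_id, out$vessel_id,
                                     sep = "\r")])
  } else out$class <- NA_character_
  out <- out[order(out$embryo_id, out$vessel_id),
             c("embryo_id", "vessel_id", "class", "imm_dlav", "emi_dlav",
               "imm_pcv", "emi_pcv", "net_immigration")]
  rownames(out) <- NULL
  attr(out, "events") <- events
  class(out) <- c("exchangeCounts", "data.frame")
  out
}

#' Fraction-of-ISVs histogram of per-vessel event counts
#'
#' Bins per-ISV counts into 0, 1, 2 and >= 3 events, pooled over all
#' embryos, and reports the fraction of ISVs in each bin (optionally per
#' class).
#'
#' @param counts integer vector of per-ISV counts (e.g. one column of a
#'   [detectExchanges()] result, or mitosis counts).
#' @return data.frame: `events` ("0","1","2",">=3"), `fraction`, `n_isv`.
#' @export
exchangeFractions <- function(counts) {
  counts <- counts[!is.na(counts)]
  b <- cut(counts, c(-0.5, 0.5, 1.5, 2.5, Inf),
           labels = c("0", "1", "2", ">=3"))
  tab <- table(b)
  data.frame(events = names(tab),
             fraction = as.numeric(tab) / max(1L, length(counts)),
             n_isv = as.integer(tab))
}

#' Count mitoses per vessel from lineage branching
#'
#' One mitosis per branching node of the lineage forest, attributed to
#' the vessel containing the parent at its last frame.
#'
#' @inheritParams detectExchanges
#' @return data.frame: `embryo_id`, `vessel_id`, `class`, `mitoses`.
#' @export
countMitoses <- function(tracks, map = NULL, fate = NULL,
                         assignment = NULL) {
  if (is.null(assignment)) {
    if (is.null(map)) .stopf("need a region map or a precomputed assignment")
    assignment <- assignRegions(tracks, map)
  }
  div <- lineageDivisions(tracks)
  a <- assignment
  isv_ids <- names(map$isv_x %||% NULL)
  universe <- unique(rbind(
    unique(a[!a$region %in% c("ventral", "dlav"), c("embryo_id", "region")]),
    if (!is.null(isv_ids))
      expand.grid(embryo_id = unique(a$embryo_id), region = isv_ids,
                  stringsAsFactors = FALSE)))
  names(universe) <- c("embryo_id", "vessel_id")
  universe <- unique(universe)
  n <- integer(nrow(universe))
  if (nrow(div)) {
    reg <- vapply(seq_len(nrow(div)), function(i) {
      sel <- a$embryo_id == div$embryo_id[i] & a$cell_id == div$parent_id[i]
      tt <- a$t[sel]
      a$region[sel][which.max(tt)]
    }, "")
    key <- paste(div$embryo_id, reg)
    tab <- table(key)
    hit <- tab[paste(universe$embryo_id, universe$vessel_id)]
    n <- ifelse(is.na(hit), 0L, as.integer(hit))
  }
  out <- universe
  out$mitoses <- n
  if (!is.null(fate)) {
    cls_of <- .classOf(fate)
    out$class <- unname(cls_of[paste(out$embryo_id, out$vessel_id,
                                     sep = "\r")])
  } else out$class <- NA_character_
  out <- out[order(out$embryo_id, out$vessel_id),
             c("embryo_id", "vessel_id", "class", "mitoses")]
  rownames(out) <- NULL
  out
}

#' Cells per ISV at a time point
#'
#' Counts distinct cells assigned to each ISV at the frame nearest `t`.
#' Boundary points are resolved by the nearest-ISV-axis rule of the
#' region map, so each cell is counted exactly once.
#'
#' @inheritParams detectExchanges
#' @param t hpf; must lie inside the recording.
#' @return data.frame: `embryo_id`, `vessel_id`, `class`, `n_cells`.
#' @export
cellNumber <- function(tracks, map = NULL, t, fate = NULL,
                       assignment = NULL) {
  if (is.null(assignment)) {
    if (is.null(map)) .stopf("need a region map or a precomputed assignment")
    assignment <- assignRegions(tracks, map)
  }
  a <- assignment
  if (t < min(a$t) - 1e-9 || t > max(a$t) + 1e-9)
    .stopf("t = %g outside the recording [%g, %g]", t, min(a$t), max(a$t))
  tf <- a$t[which.min(abs(a$t - t))]
  frame <- a[abs(a$t - tf) < 1e-9 & !a$region %in% c("ventral", "dlav"), ]
  isv_ids <- names(map$isv_x %||% NULL)
  universe <- unique(rbind(
    unique(a[!a$region %in% c("ventral", "dlav"), c("embryo_id", "region")]),
    if (!is.null(isv_ids))
      expand.grid(embryo_id = unique(a$embryo_id), region = isv_ids,
                  stringsAsFactors = FALSE)))
  names(universe) <- c("embryo_id", "vessel_id")
  universe <- unique(universe)
  key <- paste(frame$embryo_id, frame$region)
  tab <- table(key)
  hit <- tab[paste(universe$embryo_id, universe$vessel_id)]
  out <- universe
  out$n_cells <- ifelse(is.na(hit), 0L, as.integer(hit))
  if (!is.null(fate)) {
    cls_of <- .classOf(fate)
    out$class <- unname(cls_of[paste(out$embryo_id, out$vessel_id,
                                     sep = "\r")])
  } else out$class <- NA_character_
  out <- out[order(out$embryo_id, out$vessel_id),
             c("embryo_id", "vessel_id", "class", "n_cells")]
  rownames(out) <- NULL
  out
}

#' Per-class vessel diameter profile with bootstrap CI
#'
#' @param diameters a [DiameterTable-class] (um).
#' @param fate optional [assignFate()] result overriding the table's
#'   `vessel_class` for ISVs.
#' @param bootstrap,level,seed bootstrap CI over vessels.
#' @return data.frame: `vessel_class`, `t`, `mean`, `lower`, `upper`,
#'   `n_vessels`.
#' @export
diameterProfile <- function(diameters, fate = NULL, bootstrap = 2000L,
                            level = 0.95, seed = 1L) {
  m <- diameterMeasurements(diameters)
  if (!nrow(m)) .stopf("empty diameter table")
  if (!is.null(fate)) {
    cls_of <- .classOf(fate)
    hit <- cls_of[paste(m$embryo_id, m$vessel_id, sep = "\r")]
    m$vessel_class <- ifelse(is.na(hit), m$vessel_class, hit)
  }
  groups <- split(m, list(m$vessel_class, m$t), drop = TRUE)
  out <- lapply(seq_along(groups), function(gi) {
    g <- groups[[gi]]
    ci <- bootstrapCI(g$diameter, n = bootstrap, level = level,
                      seed = seed + gi)
    data.frame(vessel_class = g$vessel_class[1L], t = g$t[1L],
               mean = ci[["mean"]], lower = ci[["lower"]],
               upper = ci[["upper"]], n_vessels = ci[["n"]])
  })
  res <- do.call(rbind, out)
  res <- res[order(res$vessel_class, res$t), ]
  rownames(res) <- NULL
  res
}

#' Correlate per-ISV cellular drivers with final vessel diameter
#'
#' Compares mitotic events and net immigration (immigration minus
#' emigration) with the final diameter of each ISV, per vessel class.
#'
#' @param ledger merged per-ISV table with `mitoses` and
#'   `net_immigration` (see [buildExchangeLedger()]).
#' @param diameters a [DiameterTable-class].
#' @param t hpf of the "final" diameter (nearest measurement used).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return data.frame: `class`, `driver`, `estimate`, `p.value`, `n`.
#' @export
correlateDrivers <- function(ledger, diameters, t = 44,
                             method = c("pearson", "spearman")) {
  method <- match.arg(method)
  m <- diameterMeasurements(diameters)
  m <- m[order(abs(m$t - t)), ]
  final <- m[!duplicated(paste(m$embryo_id, m$vessel_id)),
             c("embryo_id", "vessel_id", "diameter")]
  d <- merge(ledger, final, by = c("embryo_id", "vessel_id"))
  out <- list()
  for (cls in unique(d$class[!is.na(d$class)])) {
    g <- d[!is.na(d$class) & d$class == cls, ]
    for (driver in c("mitoses", "net_immigration")) {
      if (nrow(g) < 3L)
        .stopf("need >= 3 ISVs per group (class %s has %d)", cls, nrow(g))
      ct <- suppressWarnings(
        cor.test(g[[driver]], g$diameter, method = method))
      out[[length(out) + 1L]] <- data.frame(
        class = cls, driver = driver, estimate = unname(ct$estimate),
        p.value = ct$p.value, n = nrow(g), method = method)
    }
  }
  do.call(rbind, out)
}

#' Merge exchange counts and mitoses into one per-ISV ledger
#'
#' @inheritParams detectExchanges
#' @return data.frame with exchange counts, `mitoses` and
#'   `net_immigration` per ISV.
#' @export
buildExchangeLedger <- function(tracks, map, K = 6L, fate = NULL) {
  assignment <- assignRegions(tracks, map)
  ex <- detectExchanges(tracks, map = map, K = K, fate = fate,
                        assignment = assignment)
  mi <- countMitoses(tracks, map = map, fate = fate,
                     assignment = assignment)
  events <- attr(ex, "events")
  out <- merge(as.data.frame(ex),
               mi[, c("embryo_id", "vessel_id", "mitoses")],
               by = c("embryo_id", "vessel_id"))
  out <- out[order(out$embryo_id, out$vessel_id), ]
  rownames(out) <- NULL
  attr(out, "events") <- events
  out
}

#' Scratch-wound migration metrics
#'
#' Effective speed is the start-to-end chord length divided by the
#' tracking time; directionality is the signed angle between the
#' start-to-end vector and the +y axis (the wound edge), in (-pi, pi],
#' so movement into the wound (+x) maps to +pi/2. Wound closure is
#' (A0 - A16)/A0 x 100.
#'
#' @param tracks 2D [TrackTable-class] with time in minutes.
#' @param area0,area16 cell-free areas at assay start and end (same
#'   units).
#' @return list: `perTrack` (data.frame `cell_id`, `effective_speed`
#'   um/h, `mean_speed` um/h path-based, `angle` radians, NA for
#'   zero-displacement tracks), `closure_pct`.
#' @export
woundMetrics <- function(tracks, area0 = NULL, area16 = NULL) {
  p <- trackPoints(tracks)
  to_h <- if (tracks@timeUnit == "min") 1 / 60 else 1
  per <- lapply(split(p, paste(p$embryo_id, p$cell_id, sep = "\r")), function(g) {
    g <- g[order(g$t), ]
    dur <- (g$t[nrow(g)] - g$t[1L]) * to_h
    if (dur <= 0) return(NULL) # zero-duration track excluded
    dx <- g$x[nrow(g)] - g$x[1L]
    dy <- g$y[nrow(g)] - g$y[1L]
    chord <- sqrt(dx^2 + dy^2)
    path <- sum(sqrt(diff(g$x)^2 + diff(g$y)^2))
    data.frame(embryo_id = g$embryo_id[1L], cell_id = g$cell_id[1L],
               effective_speed = chord / dur, mean_speed = path / dur,
               angle = if (chord == 0) NA_real_ else atan2(dx, dy))
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  closure <- if (!is.null(area0) && !is.null(area16)) {
    if (area0 <= 0) .stopf("area0 must be positive")
    (area0 - area16) / area0 * 100
  } else NA_real_
  list(perTrack = per, closure_pct = closure)
}
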