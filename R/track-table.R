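#' Construct a TrackTable
#'
#' Normalises column types, fills optional columns (`parent_id`,
#' `vessel_label`, `z`), sorts by embryo, cell and time, and validates
#' the lineage invariants.
#'
#' @param points data.frame with at least `cell_id`, `t`, `x`, `y`.
#' @param frameInterval sampling interval in minutes (zebrafish: 10).
#' @param timeUnit `"hpf"` (zebrafish) or `"min"` (monolayers).
#' @param is2D set TRUE for planar data; z is stored as 0.
#' @return a validated [TrackTable-class].
#' @examples
#' tt <- TrackTable(data.frame(cell_id = "c1", t = c(26, 26 + 1 / 6),
#'                             x = 0, y = c(10, 11)))
#' nCells(tt)
#' @export
TrackTable <- function(points, frameInterval = 10, timeUnit = "hpf",
                       is2D = FALSE) {
  points <- as.data.frame(points)
  if (nrow(points)) {
    need <- c("cell_id", "t", "x", "y")
    missing_cols <- setdiff(need, names(points))
    if (length(missing_cols))
      .stopf("track format error: missing mandatory column(s): %s",
             paste(missing_cols, collapse = ", "))
    if (is.null(points$embryo_id)) points$embryo_id <- "embryo_1"
    if (is.null(points$parent_id)) points$parent_id <- NA_character_
    if (is.null(points$vessel_label)) points$vessel_label <- NA_character_
    if (is.null(points$z)) {
      points$z <- 0
      is2D <- TRUE
    }
    points$embryo_id <- as.character(points$embryo_id)
    points$cell_id <- as.character(points$cell_id)
    points$parent_id <- as.character(points$parent_id)
    points$vessel_label <- as.character(points$vessel_label)
    points$parent_id[!is.na(points$parent_id) &
                       points$parent_id == ""] <- NA_character_
    points$vessel_label[!is.na(points$vessel_label) &
                          points$vessel_label == ""] <- NA_character_
    for (cc in c("t", "x", "y", "z")) points[[cc]] <- as.numeric(points[[cc]])
    points <- points[order(points$embryo_id, points$cell_id, points$t),
                     .TRACK_COLS, drop = FALSE]
    rownames(points) <- NULL
  }
  new("TrackTable", points = points, frameInterval = as.numeric(frameInterval),
      timeUnit = timeUnit, is2D = isTRUE(is2D))
}

#' @describeIn TrackTable access the points data.frame.
#' @param x a TrackTable.
#' @export
trackPoints <- function(x) {
  stopifnot(is(x, "TrackTable"))
  x@points
}

#' @describeIn TrackTable sampling interval in minutes.
#' @export
frameInterval <- function(x) {
  stopifnot(is(x, "TrackTable"))
  x@frameInterval
}

#' @describeIn TrackTable number of distinct cells.
#' @export
nCells <- function(x) {
  p <- trackPoints(x)
  if (!nrow(p)) return(0L)
  nrow(unique(p[, c("embryo_id", "cell_id")]))
}

#' @describeIn TrackTable ids of lineage roots (cells without a parent).
#' @export
lineageRoots <- function(x) {
  p <- trackPoints(x)
  if (!nrow(p)) return(character())
  first <- p[!duplicated(paste(p$embryo_id, p$cell_id, sep = "\r")), ]
  first$cell_id[is.na(first$parent_id)]
}

#' Division events encoded in the lineage
#'
#' One row per branching node: the parent cell, the time of its last
#' point, and its daughters. Errors if any parent has more than two
#' daughters.
#'
#' @param x a [TrackTable-class].
#' @return data.frame: `embryo_id`, `parent_id`, `t`, `daughters`.
#' @export
lineageDivisions <- function(x) {
  p <- trackPoints(x)
  out <- data.frame(embryo_id = character(), parent_id = character(),
                    t = numeric(), daughters = character())
  if (!nrow(p)) return(out)
  first <- p[!duplicated(paste(p$embryo_id, p$cell_id, sep = "\r")), ]
  kids <- first[!is.na(first$parent_id), , drop = FALSE]
  if (!nrow(kids)) return(out)
  key <- paste(kids$embryo_id, kids$parent_id, sep = "\r")
  nk <- table(key)
  if (any(nk > 2L))
    .stopf("data error: division with >2 children: %s",
           paste(names(nk)[nk > 2L], collapse = ", "))
  last_t <- tapply(p$t, paste(p$embryo_id, p$cell_id, sep = "\r"), max)
  by_parent <- split(kids$cell_id, key)
  parents <- do.call(rbind, strsplit(names(by_parent), "\r", fixed = TRUE))
  data.frame(embryo_id = parents[, 1L], parent_id = parents[, 2L],
             t = unname(last_t[names(by_parent)]),
             daughters = vapply(by_parent, paste, "", collapse = ";"),
             row.names = NULL)
}

#' Restrict a TrackTable to a subset of cells or a time range
#'
#' @param x a [TrackTable-class].
#' @param cells keep only these cell ids (default all).
#' @param tmin,tmax keep points with `tmin <= t <= tmax`.
#' @param dropLineage if TRUE, parent ids pointing outside the kept set
#'   are cleared so the result remains a valid forest.
#' @return a [TrackTable-class].
#' @export
subsetTracks <- function(x, cells = NULL, tmin = -Inf, tmax = Inf,
                         dropLineage = TRUE) {
  p <- trackPoints(x)
  if (!is.null(cells)) p <- p[p$cell_id %in% cells, , drop = FALSE]
  p <- p[p$t >= tmin & p$t <= tmax, , drop = FALSE]
  if (dropLineage && nrow(p))
    p$parent_id[!paste(p$embryo_id, p$parent_id) %in%
                  paste(p$embryo_id, p$cell_id)] <- NA_character_
  TrackTable(p, frameInterval = x@frameInterval, timeUnit = x@timeUnit,
             is2D = x@is2D)
}

setMethod("show", "TrackTable", function(object) {
  p <- object@points
  cat(sprintf("TrackTable: %d points, %d cells, %d embryo(s)\n",
              nrow(p), nCells(object),
              length(unique(p$embryo_id))))
  if (nrow(p))
    cat(sprintf("  time [%g, %g] %s, frame interval %g min%s\n",
                min(p$t), max(p$t), object@timeUnit, object@frameInterval,
                if (object@is2D) ", 2D" else ""))
})

#' Construct a DiameterTable
#'
#' @param measurements data.frame with `embryo_id`, `vessel_id`,
#'   `vessel_class`, `t` (hpf), `diameter` (micrometres; 0 encodes a
#'   missing measurement).
#' @return a validated [DiameterTable-class].
#' @export
DiameterTable <- function(measurements) {
  m <- as.data.frame(measurements)
  if (nrow(m)) {
    m$embryo_id <- as.character(m$embryo_id)
    m$vessel_id <- as.character(m$vessel_id)
    m$vessel_class <- as.character(m$vessel_class)
    m$t <- as.numeric(m$t)
    m$diameter <- as.numeric(m$diameter)
    m <- m[order(m$embryo_id, m$vessel_id, m$t), , drop = FALSE]
    rownames(m) <- NULL
  }
  new("DiameterTable", measurements = m)
}

#' @describeIn DiameterTable access the measurements data.frame.
#' @param x a DiameterTable.
#' @export
diameterMeasurements <- function(x) {
  stopifnot(is(x, "DiameterTable"))
  x@measurements
}

setMethod("show", "DiameterTable", function(object) {
  m <- object@measurements
  cat(sprintf("DiameterTable: %d measurements, %d vessel(s)\n",
              nrow(m), length(unique(m$vessel_id))))
})

setMethod("show", "KeyFile", function(object) {
  e <- object@experiments
  cat(sprintf("KeyFile: %d experiment(s) [%s]\n", nrow(e),
              paste(unique(e$condition), collapse = ", ")))
})
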