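#' Region map partitioning the canonical frame
#'
#' Canonical y is split into a ventral PCV/DA band (y < yDa + delta), a
#' DLAV band (y > yDlav - delta) and the ISV band between them; within
#' the ISV band a point belongs to the ISV whose x-axis is nearest, so
#' the slots partition the plane and every point is assigned exactly
#' once.
#'
#' @param isvX named numeric: ISV axis x positions (um), names are
#'   vessel ids.
#' @param yDlav DLAV height (um, canonical frame).
#' @param yDa aorta height, 0 in the canonical frame.
#' @param delta band half-margin (um, default 5).
#' @return list of class `regionMap`.
#' @export
regionMap <- function(isvX, yDlav, yDa = 0, delta = 5) {
  if (is.null(names(isvX)) || !length(isvX))
    .stopf("isvX must be a nonempty named vector")
  if (yDlav - delta <= yDa + delta)
    .stopf("bands overlap: yDlav too close to yDa for this delta")
  structure(list(isv_x = sort(isvX), y_ventral = yDa + delta,
                 y_dorsal = yDlav - delta),
            class = "regionMap")
}

#' Build a region map from labelled tracks
#'
#' ISV x slots are the per-vessel median x of `ISV_*`-labelled points;
#' the DLAV height is the median y of DLAV-labelled points.
#'
#' @param tracks an aligned [TrackTable-class] with vessel labels.
#' @param delta band half-margin (um).
#' @export
regionMapFromLabels <- function(tracks, delta = 5) {
  p <- trackPoints(tracks)
  isv <- p[!is.na(p$vessel_label) & grepl("^ISV_", p$vessel_label), ]
  dlav <- p[!is.na(p$vessel_label) & p$vessel_label == "DLAV", ]
  if (!nrow(isv) || !nrow(dlav))
    .stopf("need ISV_* and DLAV labels to infer a region map")
  isv_x <- tapply(isv$x, isv$vessel_label, stats::median)
  regionMap(setNames(as.numeric(isv_x), names(isv_x)),
            yDlav = stats::median(dlav$y), delta = delta)
}

#' Assign every track point to a region
#'
#' @param tracks an aligned [TrackTable-class].
#' @param map a [regionMap()].
#' @return data.frame: `embryo_id`, `cell_id`, `t`, `y`, `region`
#'   ("ventral", "dlav" or an ISV id).
#' @export
assignRegions <- function(tracks, map) {
  stopifnot(inherits(map, "regionMap"))
  p <- trackPoints(tracks)
  slot_idx <- pmax(1L, findInterval(p$x, c(-Inf, map$isv_x[-1L] -
                                             diff(map$isv_x) / 2)))
  region <- names(map$isv_x)[slot_idx]
  if (length(map$isv_x) == 1L) region <- rep(names(map$isv_x), nrow(p))
  region[p$y < map$y_ventral] <- "ventral"
  region[p$y > map$y_dorsal] <- "dlav"
  data.frame(embryo_id = p$embryo_id, cell_id = p$cell_id, t = p$t,
             y = p$y, region = region)
}
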