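#' Read cell tracks from disk
#'
#' Two dialects of the community track layout are accepted. `"flat"` is a
#' single CSV with columns `embryo_id, cell_id, parent_id, t, x, y, z,
#' vessel_label` (extra columns are tolerated and dropped). The
#' `"objects_links"` dialect is the two-file layout: an objects table
#' (`object_id, embryo_id, t, x, y, z, vessel_label`) and a links table
#' (`cell_id, object_id, parent_id`) joining objects into tracks.
#'
#' @param path CSV file (flat) or length-2 character vector
#'   c(objects, links) for the two-file dialect.
#' @param dialect `"flat"` or `"objects_links"`.
#' @param frameInterval,timeUnit,is2D metadata passed to [TrackTable()];
#'   declared, never inferred from the data.
#' @return a validated [TrackTable-class].
#' @export
readTracks <- function(path, dialect = c("flat", "objects_links"),
                       frameInterval = 10, timeUnit = "hpf", is2D = FALSE) {
  dialect <- match.arg(dialect)
  if (dialect == "flat") {
    if (!file.exists(path)) .stopf("track file not found: %s", path)
    raw <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("cell_id", "t", "x", "y")
    missing_cols <- setdiff(need, names(raw))
    if (length(missing_cols))
      .stopf("track format error in %s: missing column(s): %s",
             path, paste(missing_cols, collapse = ", "))
    keep <- intersect(.TRACK_COLS, names(raw))
    raw <- raw[, keep, drop = FALSE]
  } else {
    if (length(path) != 2L)
      .stopf("objects_links dialect needs c(objects_csv, links_csv)")
    for (f in path) if (!file.exists(f)) .stopf("track file not found: %s", f)
    objects <- read.csv(path[[1L]], stringsAsFactors = FALSE)
    links <- read.csv(path[[2L]], stringsAsFactors = FALSE)
    if (!all(c("object_id", "t", "x", "y") %in% names(objects)))
      .stopf("track format error in %s: objects table needs object_id, t, x, y",
             path[[1L]])
    if (!all(c("cell_id", "object_id") %in% names(links)))
      .stopf("track format error in %s: links table needs cell_id, object_id",
             path[[2L]])
    if (is.null(links$parent_id)) links$parent_id <- NA_character_
    raw <- merge(links, objects, by = "object_id")
    raw <- raw[, intersect(.TRACK_COLS, names(raw)), drop = FALSE]
  }
  TrackTable(raw, frameInterval = frameInterval, timeUnit = timeUnit,
             is2D = is2D)
}

#' Write cell tracks to disk
#'
#' The flat dialect round-trips bit-exactly through [readTracks()]:
#' numbers are serialised with full precision.
#'
#' @param x a [TrackTable-class].
#' @param path output CSV file (flat) or c(objects, links) paths.
#' @param dialect `"flat"` or `"objects_links"`.
#' @return `path`, invisibly.
#' @export
writeTracks <- function(x, path, dialect = c("flat", "objects_links")) {
  dialect <- match.arg(dialect)
  p <- trackPoints(x)
  fmt <- function(d) {
    for (cc in c("t", "x", "y", "z"))
      d[[cc]] <- sprintf("%.17g", d[[cc]])
    d
  }
  if (dialect == "flat") {
    out <- if (nrow(p)) fmt(p) else
      setNames(as.data.frame(matrix(nrow = 0, ncol = length(.TRACK_COLS))),
               .TRACK_COLS)
    write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  } else {
    if (length(path) != 2L)
      .stopf("objects_links dialect needs c(objects_csv, links_csv)")
    p$object_id <- if (nrow(p)) sprintf("o%06d", seq_len(nrow(p))) else
      character()
    objects <- p[, c("object_id", "embryo_id", "t", "x", "y", "z",
                     "vessel_label")]
    links <- p[, c("cell_id", "object_id", "parent_id")]
    write.csv(fmt(objects), path[[1L]], row.names = FALSE, quote = FALSE,
              na = "")
    write.csv(links, path[[2L]], row.names = FALSE, quote = FALSE, na = "")
  }
  invisible(path)
}

#' Read / write a vessel-diameter table
#'
#' @param path CSV with columns `embryo_id, vessel_id, vessel_class, t,
#'   diameter` (micrometres); extra columns tolerated.
#' @return a validated [DiameterTable-class].
#' @export
readDiameters <- function(path) {
  if (!file.exists(path)) .stopf("diameter file not found: %s", path)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("embryo_id", "vessel_id", "vessel_class", "t", "diameter")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    .stopf("diameter format error in %s: missing column(s): %s",
           path, paste(missing_cols, collapse = ", "))
  DiameterTable(raw[, need, drop = FALSE])
}

#' @rdname readDiameters
#' @param x a [DiameterTable-class].
#' @export
writeDiameters <- function(x, path) {
  m <- diameterMeasurements(x)
  m$t <- sprintf("%.17g", m$t)
  m$diameter <- sprintf("%.17g", m$diameter)
  write.csv(m, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read an experiment key file
#'
#' YAML list of experiments; each entry carries `embryo_id`, `condition`
#' (closed vocabulary), `tracks_file`, optional `diameters_file` and
#' `time_unit`. Every referenced file must exist relative to the key
#' file's directory.
#'
#' @param path YAML file.
#' @return a validated [KeyFile-class].
#' @export
readKeyFile <- function(path) {
  if (!file.exists(path)) .stopf("key file not found: %s", path)
  doc <- yaml::read_yaml(path)
  entries <- doc$experiments %||% doc
  rows <- lapply(entries, function(e) {
    data.frame(embryo_id = as.character(e$embryo_id),
               condition = as.character(e$condition),
               tracks_file = as.character(e$tracks_file),
               diameters_file = as.character(e$diameters_file %||% NA),
               time_unit = as.character(e$time_unit %||% "hpf"))
  })
  experiments <- do.call(rbind, rows)
  base <- dirname(normalizePath(path))
  refs <- c(experiments$tracks_file,
            experiments$diameters_file[!is.na(experiments$diameters_file)])
  missing_files <- refs[!file.exists(file.path(base, refs))]
  if (length(missing_files))
    .stopf("key file %s references missing file(s): %s",
           path, paste(unique(missing_files), collapse = ", "))
  new("KeyFile", experiments = experiments, path = base)
}

#' @rdname readKeyFile
#' @param x a [KeyFile-class].
#' @export
writeKeyFile <- function(x, path) {
  e <- x@experiments
  entries <- lapply(seq_len(nrow(e)), function(i) {
    out <- as.list(e[i, , drop = FALSE])
    out <- lapply(out, unname)
    out[!vapply(out, function(v) all(is.na(v)), TRUE)]
  })
  yaml::write_yaml(list(experiments = entries), path)
  invisible(path)
}
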