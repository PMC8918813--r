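#' @import methods
#' @importFrom stats approx aggregate complete.cases cor.test p.adjust
#'   quantile rbinom rnorm rpois runif sd setNames t.test ks.test
#' @importFrom utils head read.csv tail write.csv
#' @useDynLib vesseldyn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.VESSEL_CLASSES <- c("DA", "DLAV", "aISV", "vISV")
.CONDITIONS <- c("control", "MO-wasb", "MO-gata1", "MO-gata1-wasb",
                 "siCTR", "siWAS", "siPECAM")

.TRACK_COLS <- c("embryo_id", "cell_id", "parent_id", "t",
                 "x", "y", "z", "vessel_label")

#' TrackTable: 3D+t nuclei tracks with lineage
#'
#' Ordered collection of track points. Each row is one nucleus position at
#' one time point. Lineage is encoded through `parent_id`: a division ends
#' the parent track and starts two daughter tracks sharing the parent's id
#' in `parent_id`, so mitosis counting is a pure lineage query.
#'
#' Invariants enforced by the validity method: at most one point per
#' (embryo, cell, time); the lineage graph is a forest with at most two
#' children per division; a daughter track starts no earlier than its
#' parent's last time point.
#'
#' @slot points data.frame with columns `embryo_id`, `cell_id`,
#'   `parent_id` (NA for lineage roots), `t` (hpf for zebrafish, minutes
#'   for monolayers), `x`, `y`, `z` (micrometres), `vessel_label`
#'   (optional, NA allowed).
#' @slot frameInterval sampling interval in minutes.
#' @slot timeUnit `"hpf"` or `"min"`; declared, never inferred.
#' @slot is2D TRUE for planar (monolayer) data where z is stored as 0.
#' @export
setClass("TrackTable",
  representation(points = "data.frame", frameInterval = "numeric",
                 timeUnit = "character", is2D = "logical"),
  prototype(points = data.frame(), frameInterval = 10,
            timeUnit = "hpf", is2D = FALSE))

setValidity("TrackTable", function(object) {
  p <- object@points
  if (nrow(p) == 0L) return(TRUE)
  missing_cols <- setdiff(.TRACK_COLS, names(p))
  if (length(missing_cols))
    return(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  if (!all(is.finite(p$t)) || !all(is.finite(p$x)) ||
      !all(is.finite(p$y)) || !all(is.finite(p$z)))
    return("non-finite t/x/y/z values")
  key <- paste(p$embryo_id, p$cell_id, p$t, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))
    return(sprintf("duplicated (cell_id, t) at rows: %s",
                   paste(head(dup, 5L), collapse = ", ")))
  }
  if (!object@timeUnit %in% c("hpf", "min"))
    return("timeUnit must be 'hpf' or 'min'")
  if (length(object@frameInterval) != 1L || object@frameInterval <= 0)
    return("frameInterval must be a single positive number")
  ## lineage forest checks, per embryo
  for (em in unique(p$embryo_id)) {
    q <- p[p$embryo_id == em, , drop = FALSE]
    first_t <- tapply(q$t, q$cell_id, min)
    last_t <- tapply(q$t, q$cell_id, max)
    par <- tapply(q$parent_id, q$cell_id, function(v) v[[1L]])
    kids <- par[!is.na(par)]
    if (length(kids)) {
      unknown <- setdiff(unique(kids), names(first_t))
      if (length(unknown))
        return(sprintf("embryo %s: parent_id not a known cell: %s",
                       em, paste(unknown, collapse = ", ")))
      nk <- table(kids)
      if (any(nk > 2L))
        return(sprintf("embryo %s: >2 children at division of: %s",
                       em, paste(names(nk)[nk > 2L], collapse = ", ")))
      bad <- names(kids)[first_t[names(kids)] <
                           last_t[as.character(kids)] - 1e-9]
      if (length(bad))
        return(sprintf("embryo %s: daughter starts before parent ends: %s",
                       em, paste(unique(bad), collapse = ", ")))
      ## cycle check: walk each lineage chain to a root
      parent_of <- setNames(as.character(kids), names(kids))
      for (cid in names(parent_of)) {
        seen <- character(); cur <- cid
        repeat {
          nxt <- unname(parent_of[cur])
          if (is.na(nxt)) break
          if (nxt %in% seen)
            return(sprintf("embryo %s: lineage cycle at %s", em, cid))
          seen <- c(seen, cur)
          cur <- nxt
        }
      }
    }
  }
  TRUE
})

#' DiameterTable: per-vessel diameter measurements over time
#'
#' @slot measurements data.frame with columns `embryo_id`, `vessel_id`,
#'   `vessel_class` (DA, DLAV, aISV or vISV), `t` (hpf) and `diameter`
#'   (micrometres). A missing measurement is encoded as diameter 0, the
#'   sentinel the flow model maps to its conductance floor.
#' @export
setClass("DiameterTable", representation(measurements = "data.frame"))

setValidity("DiameterTable", function(object) {
  m <- object@measurements
  if (nrow(m) == 0L) return(TRUE)
  need <- c("embryo_id", "vessel_id", "vessel_class", "t", "diameter")
  missing_cols <- setdiff(need, names(m))
  if (length(missing_cols))
    return(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  if (any(!m$vessel_class %in% .VESSEL_CLASSES))
    return(sprintf("unknown vessel_class: %s",
                   paste(setdiff(unique(m$vessel_class), .VESSEL_CLASSES),
                         collapse = ", ")))
  if (any(!is.finite(m$diameter)) || any(m$diameter < 0))
    return("diameters must be finite and >= 0")
  TRUE
})

#' KeyFile: per-experiment metadata
#'
#' @slot experiments data.frame with columns `embryo_id`, `condition`
#'   (closed vocabulary: control, MO-wasb, MO-gata1, MO-gata1-wasb,
#'   siCTR, siWAS, siPECAM), `tracks_file`, `diameters_file` (NA allowed),
#'   `time_unit`.
#' @slot path directory the file references are relative to.
#' @export
setClass("KeyFile",
  representation(experiments = "data.frame", path = "character"))

setValidity("KeyFile", function(object) {
  e <- object@experiments
  if (nrow(e) == 0L) return(TRUE)
  need <- c("embryo_id", "condition", "tracks_file")
  missing_cols <- setdiff(need, names(e))
  if (length(missing_cols))
    return(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  bad <- setdiff(unique(e$condition), .CONDITIONS)
  if (length(bad))
    return(sprintf("condition outside vocabulary: %s",
                   paste(bad, collapse = ", ")))
  TRUE
})

#' CanonicalFrame: rigid transform into the analysis frame
#'
#' In the canonical frame the dorsal aorta lies on the x-axis and the
#' DLAV in the positive-y half plane, so y reads out ventral-to-dorsal
#' position. The transform is `p' = R (p - centre)`; `dorsalFlip` records
#' whether a half-turn about the x-axis was needed to bring the DLAV to
#' positive y.
#'
#' @slot rotation 3x3 proper orthonormal matrix.
#' @slot translation centre subtracted before rotation (micrometres).
#' @slot dorsalFlip logical.
#' @export
setClass("CanonicalFrame",
  representation(rotation = "matrix", translation = "numeric",
                 dorsalFlip = "logical"))

setValidity("CanonicalFrame", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-8)
    return("rotation is not orthonormal")
  if (abs(det(R) - 1) > 1e-8)
    return("rotation must be proper (det +1)")
  if (length(object@translation) != 3L) return("translation must be length 3")
  TRUE
})

#' VesselNetwork: vessel graph with time-varying diameters
#'
#' Nodes carry positions (metres) and boundary roles; edges carry a
#' vessel class, a length and either a fixed diameter or a class-level
#' diameter series looked up at solve time. Strict SI units internally.
#'
#' @slot nodes data.frame: `id`, `x`, `y` (m), `role` in interior,
#'   da_inlet, da_outlet, sink, fixed; `pressure` (Pa, NA for interior,
#'   required for role "fixed").
#' @slot edges data.frame: `id`, `from`, `to`, `class`, `length` (m),
#'   `diameter` (m; NA means use the class diameter series).
#' @slot diameters data.frame: `class`, `t` (hpf), `diameter` (m);
#'   linearly interpolated at solve time. May be empty if all edges carry
#'   fixed diameters.
#' @export
setClass("VesselNetwork",
  representation(nodes = "data.frame", edges = "data.frame",
                 diameters = "data.frame"))

setValidity("VesselNetwork", function(object) {
  n <- object@nodes; e <- object@edges
  if (!all(c("id", "x", "y", "role", "pressure") %in% names(n)))
    return("nodes need columns id, x, y, role, pressure")
  if (!all(c("id", "from", "to", "class", "length", "diameter") %in% names(e)))
    return("edges need columns id, from, to, class, length, diameter")
  if (anyDuplicated(n$id)) return("duplicate node ids")
  if (anyDuplicated(e$id)) return("duplicate edge ids")
  if (!all(c(e$from, e$to) %in% n$id))
    return("edge endpoints must be node ids")
  if (any(e$length <= 0)) return("edge lengths must be > 0")
  if (any(!n$role %in% c("interior", "da_inlet", "da_outlet", "sink", "fixed")))
    return("unknown node role")
  if (any(n$role == "fixed" & !is.finite(n$pressure)))
    return("nodes with role 'fixed' need a finite pressure")
  TRUE
})

#' FlowSolution: pressures, flows and wall shear stress over time
#'
#' One column per solved time point. `flow` is signed by edge orientation
#' (positive from `from` to `to`); `wss` is nonnegative, and zero on edges
#' held at the conductance floor (no diameter measurement).
#'
#' @slot network the [VesselNetwork-class] that was solved.
#' @slot times solved time points (hpf).
#' @slot pressures nodes x times matrix (Pa).
#' @slot conductance,dp,flow,wss edges x times matrices
#'   (m^3 Pa^-1 s^-1, Pa, m^3 s^-1, Pa).
#' @export
setClass("FlowSolution",
  representation(network = "VesselNetwork", times = "numeric",
                 pressures = "matrix", conductance = "matrix",
                 dp = "matrix", flow = "matrix", wss = "matrix"))

setValidity("FlowSolution", function(object) {
  nt <- length(object@times)
  if (ncol(object@pressures) != nt) return("pressures: one column per time")
  for (s in c("conductance", "dp", "flow", "wss"))
    if (ncol(slot(object, s)) != nt)
      return(sprintf("%s: one column per time", s))
  if (any(object@wss < -1e-300, na.rm = TRUE)) return("wss must be >= 0")
  TRUE
})
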