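#' Fit the aorta axis through a 3D nuclei point cloud
#'
#' Orthogonal (total-least-squares) line fit: the line through the
#' centroid along the principal axis of the centred cloud. Unlike an
#' ordinary regression of y on x, this fit is rotation invariant, which
#' is what a geometric vessel axis requires; the ordinary-least-squares
#' variant is available behind `method = "ols"` for parity checks with
#' pipelines that regressed y (and z) on x.
#'
#' Positional data of all aorta nuclei over the whole recording are
#' pooled into one cloud.
#'
#' @param points matrix or data.frame with columns x, y, z (um).
#' @param method `"tls"` (principal axis, default) or `"ols"`.
#' @return list of class `aortaAxis`: `point` (centroid), `direction`
#'   (unit vector, positive x component), `residual_sd`.
#' @export
fitAortaAxis <- function(points, method = c("tls", "ols")) {
  method <- match.arg(method)
  P <- as.matrix(as.data.frame(points)[, c("x", "y", "z")])
  storage.mode(P) <- "double"
  if (nrow(P) < 2L) .stopf("degenerate-axis error: need >= 2 points")
  ctr <- colMeans(P)
  C <- sweep(P, 2L, ctr)
  if (max(abs(C)) < 1e-12)
    .stopf("degenerate-axis error: all points coincident")
  if (method == "tls") {
    d <- svd(C, nu = 0L, nv = 3L)$v[, 1L]
  } else {
    fy <- stats::lm.fit(cbind(1, C[, 1L]), C[, 2L])$coefficients[2L]
    fz <- stats::lm.fit(cbind(1, C[, 1L]), C[, 3L])$coefficients[2L]
    d <- c(1, fy, fz)
    d <- d / sqrt(sum(d^2))
  }
  ## orient along +x (fall back to the largest component for near-
  ## transverse axes)
  if (abs(d[1L]) > 1e-9) {
    if (d[1L] < 0) d <- -d
  } else if (d[which.max(abs(d))] < 0) d <- -d
  resid <- C - outer(drop(C %*% d), d)
  structure(list(point = ctr, direction = d,
                 residual_sd = sqrt(mean(rowSums(resid^2)))),
            class = "aortaAxis")
}

## rotation taking unit vector a onto unit vector b (Rodrigues)
.rotationBetween <- function(a, b) {
  v <- c(a[2L] * b[3L] - a[3L] * b[2L],
         a[3L] * b[1L] - a[1L] * b[3L],
         a[1L] * b[2L] - a[2L] * b[1L])
  cth <- sum(a * b)
  s2 <- sum(v^2)
  if (s2 < 1e-24) {
    if (cth > 0) return(diag(3))
    ## antiparallel: half turn about any axis perpendicular to a
    p <- if (abs(a[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    w <- p - sum(p * a) * a
    w <- w / sqrt(sum(w^2))
    return(2 * outer(w, w) - diag(3))
  }
  Vx <- matrix(c(0, v[3L], -v[2L], -v[3L], 0, v[1L], v[2L], -v[1L], 0), 3L)
  diag(3) + Vx + Vx %*% Vx * ((1 - cth) / s2)
}

#' Apply a canonical frame to coordinates
#'
#' @param frame a [CanonicalFrame-class].
#' @param x a [TrackTable-class] or a 3-column matrix (um).
#' @return object of the same kind with transformed coordinates.
#' @export
applyFrame <- function(frame, x) {
  stopifnot(is(frame, "CanonicalFrame"))
  transform3 <- function(M)
    t(frame@rotation %*% (t(M) - frame@translation))
  if (is(x, "TrackTable")) {
    p <- trackPoints(x)
    M <- transform3(as.matrix(p[, c("x", "y", "z")]))
    p$x <- M[, 1L]; p$y <- M[, 2L]; p$z <- M[, 3L]
    return(TrackTable(p, frameInterval = x@frameInterval,
                      timeUnit = x@timeUnit, is2D = x@is2D))
  }
  transform3(as.matrix(x))
}

#' Rigidly transform tracks into the canonical analysis frame
#'
#' After the transform the aorta centroid sits at the origin with the
#' aorta axis along +x, and the DLAV lies in the positive-y half plane
#' with its centroid rolled into the z = 0 plane, so the y coordinate is
#' the ventral-to-dorsal read-out. The transform is rigid (a proper
#' rotation plus translation); if the DLAV initially mapped to negative
#' y, a half turn about the x-axis (y -> -y, z -> -z) is absorbed into
#' the rotation and flagged as `dorsalFlip`.
#'
#' @param tracks a [TrackTable-class].
#' @param axis an [fitAortaAxis()] result; fitted from `daLabel` points
#'   when NULL.
#' @param dlavReference 3-column matrix of DLAV positions; taken from
#'   `dlavLabel` points when NULL.
#' @param daLabel,dlavLabel vessel labels used when fitting internally.
#' @param tol ambiguity tolerance (um): error if the DLAV centroid is
#'   closer than this to the aorta axis.
#' @return list: `tracks` (transformed [TrackTable-class]), `frame`
#'   ([CanonicalFrame-class]).
#' @export
canonicalTransform <- function(tracks, axis = NULL, dlavReference = NULL,
                               daLabel = "DA", dlavLabel = "DLAV",
                               tol = 1e-6) {
  p <- trackPoints(tracks)
  if (is.null(axis)) {
    da <- p[!is.na(p$vessel_label) & p$vessel_label == daLabel,
            c("x", "y", "z")]
    if (!nrow(da)) .stopf("no points labelled '%s' to fit the axis", daLabel)
    axis <- fitAortaAxis(da)
  }
  if (is.null(dlavReference)) {
    dlavReference <- p[!is.na(p$vessel_label) & p$vessel_label == dlavLabel,
                       c("x", "y", "z")]
  }
  dlavReference <- as.matrix(as.data.frame(dlavReference))
  if (!nrow(dlavReference)) .stopf("dlavReference must be nonempty")
  R1 <- .rotationBetween(axis$direction, c(1, 0, 0))
  ctr <- drop(R1 %*% (colMeans(dlavReference) - axis$point))
  r <- sqrt(ctr[2L]^2 + ctr[3L]^2)
  if (r < tol)
    .stopf("ambiguous-orientation error: DLAV centroid lies on the axis")
  psi <- atan2(ctr[3L], ctr[2L])
  Rx <- matrix(c(1, 0, 0,
                 0, cos(psi), -sin(psi),
                 0, sin(psi), cos(psi)), 3L, byrow = TRUE)
  ## roll by -psi brings the DLAV centroid to (y = r > 0, z = 0)
  R <- t(Rx) %*% R1
  frame <- new("CanonicalFrame", rotation = R, translation = axis$point,
               dorsalFlip = abs(psi) > pi / 2)
  list(tracks = applyFrame(frame, tracks), frame = frame)
}
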