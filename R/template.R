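# Bone templates and the canonical anatomical frame.
#
# The frame convention used throughout: x = proximo-distal axis (increasing
# distal -> proximal), y = medio-lateral, z = cranio-caudal; centroid at the
# origin; right-handed. Crop masks index into the template's point order, so
# that order is part of the object's identity and is never permuted.

ELEMENTS <- c("femur", "tibia", "humerus", "radius", "metacarpal", "metatarsal")
SIDES <- c("left", "right")
MARK_TYPES <- c("pit", "score", "cut", "percussion")
LINEAR_TYPES <- c("score", "cut")

#' Construct a bone template
#'
#' A `bone_template` is an ordered 3D point cloud of one skeletal element in
#' the canonical anatomical frame (x proximo-distal, y medio-lateral,
#' z cranio-caudal, centroid at the origin). Use [canonicalize_template()] to
#' bring raw coordinates into this frame first.
#'
#' @param points n x 3 numeric matrix of coordinates in mm, canonical frame.
#' @param element one of `"femur"`, `"tibia"`, `"humerus"`, `"radius"`,
#'   `"metacarpal"`, `"metatarsal"`.
#' @param side `"left"` or `"right"`.
#' @param size_class small integer animal size class.
#' @param template_id identifier; defaults to `"<element>_<side>"`.
#' @return An object of class `bone_template` with fields `points`, `element`,
#'   `side`, `size_class`, `length` (inter-epiphyseal x extent, mm) and
#'   `template_id`.
#' @export
bone_template <- function(points, element, side, size_class = 3L,
                          template_id = paste(element, side, sep = "_")) {
  points <- as_xyz(points)
  element <- match.arg(element, ELEMENTS)
  side <- match.arg(side, SIDES)
  if (nrow(points) < 100L)
    ot_stop("a bone template needs at least 100 points", "too_few_points")
  ctr <- colMeans(points)
  if (max(abs(ctr)) > 1e-6)
    ot_stop("template points must be centred at the origin (canonicalize first)",
            "not_canonical")
  len <- max(points[, 1]) - min(points[, 1])
  if (len <= 0) ot_stop("template has zero proximo-distal extent", "degenerate_cloud")
  structure(
    list(template_id = template_id, element = element, side = side,
         size_class = as.integer(size_class), points = points, length = len),
    class = "bone_template")
}

#' @export
print.bone_template <- function(x, ...) {
  cat(sprintf("<bone_template %s: %s %s, %d points, length %.1f mm>\n",
              x$template_id, x$side, x$element, nrow(x$points), x$length))
  invisible(x)
}

#' Principal longitudinal axis of a point cloud
#'
#' Unit eigenvector of the point covariance matrix with the largest
#' eigenvalue. Requires a dominant axis: the ratio of the first to the second
#' eigenvalue must be at least `min_ratio`, otherwise the cloud is considered
#' near-symmetric (e.g. a sphere) and an error is raised. The sign is fixed
#' deterministically by making the component of largest magnitude positive.
#'
#' @param x a `bone_template` or an n x 3 coordinate matrix.
#' @param min_ratio minimum eigenvalue ratio lambda1/lambda2 for a dominant
#'   axis (default 1.5).
#' @return unit length-3 numeric vector.
#' @export
principal_axis <- function(x, min_ratio = 1.5) {
  pts <- if (inherits(x, "bone_template")) x$points else as_xyz(x)
  ed <- cloud_eigen(pts, min_ratio)
  ed$vectors[, 1]
}

# Eigen-decomposition of the point covariance with sign fixing and the
# dominance / rank checks shared by principal_axis() and canonicalize_template().
cloud_eigen <- function(pts, min_ratio = 1.5) {
  if (nrow(pts) < 100L)
    ot_stop("need at least 100 points", "too_few_points")
  cen <- sweep(pts, 2, colMeans(pts))
  ed <- eigen(stats::cov(cen), symmetric = TRUE)
  ev <- ed$values
  if (ev[3] <= max(ev[1], 1) * 1e-12)
    ot_stop("degenerate cloud: covariance rank < 3", "degenerate_cloud")
  if (ev[1] / ev[2] < min_ratio)
    ot_stop(sprintf(
      "degenerate cloud: no dominant axis (eigenvalue ratio %.3f < %.2f)",
      ev[1] / ev[2], min_ratio), "degenerate_cloud")
  V <- ed$vectors
  # deterministic signs: largest-magnitude component of axes 1 and 2 positive,
  # third axis completes a right-handed frame
  for (j in 1:2) {
    k <- which.max(abs(V[, j]))
    if (V[k, j] < 0) V[, j] <- -V[, j]
  }
  V[, 3] <- c(V[2, 1] * V[3, 2] - V[3, 1] * V[2, 2],
              V[3, 1] * V[1, 2] - V[1, 1] * V[3, 2],
              V[1, 1] * V[2, 2] - V[2, 1] * V[1, 2])
  list(values = ev, vectors = V, centroid = colMeans(pts))
}

#' Rigidly transform a raw point cloud into the canonical anatomical frame
#'
#' Rotates and translates the cloud so that the first principal axis of the
#' point covariance becomes x (proximo-distal), the second y, the third z,
#' with the centroid at the origin and a right-handed frame. Axis signs are
#' fixed deterministically (largest-magnitude eigenvector component positive),
#' which makes the operation idempotent: a cloud already in canonical pose is
#' returned unchanged up to translation.
#'
#' @inheritParams bone_template
#' @param raw_points n x 3 matrix of raw coordinates, mm.
#' @param min_ratio dominance threshold passed to the axis test.
#' @return a `bone_template`.
#' @export
canonicalize_template <- function(raw_points, element, side, size_class = 3L,
                                  template_id = paste(element, side, sep = "_"),
                                  min_ratio = 1.5) {
  pts <- as_xyz(raw_points, "raw_points")
  ed <- cloud_eigen(pts, min_ratio)
  canon <- sweep(pts, 2, ed$centroid) %*% ed$vectors
  bone_template(canon, element, side, size_class, template_id)
}

#' Axis-aligned bounding box of a template, optionally expanded
#' @param template a `bone_template`
#' @param tol expansion in mm applied on every side
#' @return list with `min` and `max` length-3 vectors
#' @export
template_bbox <- function(template, tol = 0) {
  p <- template$points
  list(min = apply(p, 2, min) - tol, max = apply(p, 2, max) + tol)
}

in_bbox <- function(pos, bbox) {
  all(pos >= bbox$min - 1e-12) && all(pos <= bbox$max + 1e-12)
}
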