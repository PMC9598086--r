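# Survivorship: crop masks over the shared template point order,
# superimposition into per-point overlap counts (heatmaps) and the
# overlap-based MNE. Crops are index masks into the template, which makes
# overlap counting exact; externally supplied cropped clouds are matched to
# template points by nearest neighbour with a configurable tolerance.

#' Construct a crop mask
#' @param template a `bone_template`
#' @param retained logical vector over template point indices
#' @param specimen_id owning specimen id
#' @param parameters optional list describing how the crop was made
#' @return object of class `crop_mask`
#' @export
crop_mask <- function(template, retained, specimen_id = NA_character_,
                      parameters = list()) {
  stopifnot(inherits(template, "bone_template"), is.logical(retained))
  if (length(retained) != nrow(template$points))
    ot_stop("mask length must equal the template point count", "bad_mask")
  if (!any(retained)) ot_stop("empty crop: no points retained", "empty_crop")
  structure(list(specimen_id = specimen_id,
                 template_id = template$template_id,
                 retained = retained, parameters = parameters),
            class = "crop_mask")
}

#' @export
print.crop_mask <- function(x, ...) {
  cat(sprintf("<crop_mask %s on %s: %d/%d points retained>\n",
              x$specimen_id, x$template_id, sum(x$retained),
              length(x$retained)))
  invisible(x)
}

# even-odd rule point-in-polygon; boundary points count as inside
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    # boundary test: point on segment (i, j)
    cross <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
    within <- px >= pmin(xi, xj) - 1e-12 & px <= pmax(xi, xj) + 1e-12 &
              py >= pmin(yi, yj) - 1e-12 & py <= pmax(yi, yj) + 1e-12
    on_edge <- on_edge | (abs(cross) < 1e-9 & within)
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
   ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

polygon_is_simple <- function(vx, vy) {
  n <- length(vx)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      # skip adjacent edges (share a vertex)
      if (abs(i - j) <= 1 || abs(i - j) == n - 1) next
      i2 <- if (i == n) 1L else i + 1L
      j2 <- if (j == n) 1L else j + 1L
      if (segments_intersect(c(vx[i], vy[i]), c(vx[i2], vy[i2]),
                             c(vx[j], vy[j]), c(vx[j2], vy[j2])))
        return(FALSE)
    }
  }
  TRUE
}

#' Polygonal crop of a template
#'
#' Retains exactly the template points whose projection onto the named plane
#' falls inside (or outside) a simple polygon. Point-in-polygon uses the
#' even-odd rule; boundary points count as inside.
#'
#' @param template a `bone_template`
#' @param polygon_2d m x 2 matrix of polygon vertices (m >= 3), in the
#'   projection plane's coordinates, mm
#' @param projection_plane `"xy"`, `"xz"` or `"yz"`
#' @param keep `"inside"` or `"outside"`
#' @param specimen_id owning specimen id
#' @return a `crop_mask`
#' @export
crop_polygonal <- function(template, polygon_2d,
                           projection_plane = c("xy", "xz", "yz"),
                           keep = c("inside", "outside"),
                           specimen_id = NA_character_) {
  stopifnot(inherits(template, "bone_template"))
  projection_plane <- match.arg(projection_plane)
  keep <- match.arg(keep)
  poly <- as.matrix(polygon_2d)
  if (nrow(poly) < 3L || ncol(poly) != 2L)
    ot_stop("polygon needs at least 3 vertices (m x 2 matrix)", "bad_polygon")
  if (!polygon_is_simple(poly[, 1], poly[, 2]))
    ot_stop("self-intersecting polygon", "bad_polygon")
  ax <- switch(projection_plane, xy = c(1L, 2L), xz = c(1L, 3L), yz = c(2L, 3L))
  p <- template$points
  inside <- point_in_polygon(p[, ax[1]], p[, ax[2]], poly[, 1], poly[, 2])
  retained <- if (keep == "inside") inside else !inside
  if (!any(retained)) ot_stop("empty crop: no points retained", "empty_crop")
  crop_mask(template, retained, specimen_id,
            list(mode = "polygon", projection_plane = projection_plane,
                 keep = keep, polygon = unname(poly)))
}

#' Interval crop of a template along one axis
#'
#' Scriptable analogue of interactive cropping: retains the points whose
#' normalized coordinate along the chosen axis lies in `[lo_frac, hi_frac)`
#' (the upper bound is closed when `hi_frac == 1`).
#'
#' @inheritParams crop_polygonal
#' @param axis `"x"`, `"y"` or `"z"`
#' @param lo_frac,hi_frac interval bounds as fractions of the axis extent,
#'   `0 <= lo < hi <= 1`
#' @return a `crop_mask`
#' @export
crop_interval <- function(template, axis = c("x", "y", "z"), lo_frac, hi_frac,
                          specimen_id = NA_character_) {
  stopifnot(inherits(template, "bone_template"))
  axis <- match.arg(axis)
  if (!(lo_frac >= 0 && hi_frac <= 1 && lo_frac < hi_frac))
    ot_stop("interval must satisfy 0 <= lo < hi <= 1", "bad_interval")
  j <- match(axis, c("x", "y", "z"))
  v <- template$points[, j]
  tnorm <- (v - min(v)) / (max(v) - min(v))
  retained <- tnorm >= lo_frac & (tnorm < hi_frac | (hi_frac == 1 & tnorm <= 1))
  if (!any(retained)) ot_stop("empty crop: no points retained", "empty_crop")
  crop_mask(template, retained, specimen_id,
            list(mode = "interval", axis = axis, lo = lo_frac, hi = hi_frac))
}

#' Match an externally cropped cloud back onto its template
#'
#' For crops supplied as free point clouds rather than index masks: each cloud
#' point is matched to its nearest template point; points farther than `tol`
#' from any template point are rejected and reported.
#'
#' @inheritParams crop_polygonal
#' @param cloud n x 3 matrix of cropped-cloud coordinates, mm
#' @param tol matching tolerance, mm
#' @return a `crop_mask`; attribute `rejected` holds indices of unmatched
#'   cloud points
#' @export
match_cloud_crop <- function(template, cloud, tol = 0.5,
                             specimen_id = NA_character_) {
  cloud <- as_xyz(cloud, "cloud")
  tp <- template$points
  retained <- rep(FALSE, nrow(tp))
  rejected <- integer()
  for (i in seq_len(nrow(cloud))) {
    d2 <- (tp[, 1] - cloud[i, 1])^2 + (tp[, 2] - cloud[i, 2])^2 +
          (tp[, 3] - cloud[i, 3])^2
    j <- which.min(d2)
    if (d2[j] <= tol^2) retained[j] <- TRUE else rejected <- c(rejected, i)
  }
  if (length(rejected))
    warning(sprintf("%d cloud point(s) farther than %g mm from the template were rejected",
                    length(rejected), tol))
  m <- crop_mask(template, retained, specimen_id,
                 list(mode = "matched_cloud", tol = tol))
  attr(m, "rejected") <- rejected
  m
}

#' Superimpose crop masks into a survivorship heatmap
#'
#' `counts[i]` is the number of specimens retaining template point `i`; the
#' overlap-based MNE is `max(counts)`. Complete (uncropped) specimens
#' contribute 1 to every point.
#'
#' @param masks list of `crop_mask` objects on the same template
#' @return object of class `heatmap_field` with fields `counts`,
#'   `n_specimens`, `mne`, `template_id`
#' @export
superimpose <- function(masks) {
  if (!length(masks)) ot_stop("no masks supplied", "bad_mask")
  stopifnot(all(vapply(masks, inherits, TRUE, "crop_mask")))
  tid <- unique(vapply(masks, function(m) m$template_id, ""))
  if (length(tid) != 1L)
    ot_stop("masks reference different templates", "mixed_templates")
  counts <- Reduce(`+`, lapply(masks, function(m) as.integer(m$retained)))
  structure(list(counts = counts, n_specimens = length(masks),
                 mne = max(counts), template_id = tid),
            class = "heatmap_field")
}

#' @export
print.heatmap_field <- function(x, ...) {
  cat(sprintf("<heatmap_field on %s: %d specimens, MNE = %d>\n",
              x$template_id, x$n_specimens, x$mne))
  invisible(x)
}

#' MNE table per (element, side) group
#'
#' Groups crop masks by the element and side of their template and reports,
#' per group, the number of specimens and the overlap-based MNE. Empty groups
#' are omitted with a warning.
#'
#' @param masks list of `crop_mask` objects (possibly on several templates)
#' @param templates named list of the `bone_template`s the masks refer to
#' @return data.frame with columns `element`, `side`, `n_specimens`, `mne`
#' @export
mne_report <- function(masks, templates) {
  if (!length(masks)) {
    warning("no masks: empty MNE report")
    return(data.frame(element = character(), side = character(),
                      n_specimens = integer(), mne = integer()))
  }
  tids <- vapply(masks, function(m) m$template_id, "")
  rows <- list()
  for (tid in sort(unique(tids))) {
    tp <- templates[[tid]]
    if (is.null(tp)) ot_stop(sprintf("unknown template '%s'", tid),
                             "unknown_template")
    fld <- superimpose(masks[tids == tid])
    rows[[tid]] <- data.frame(element = tp$element, side = tp$side,
                              n_specimens = fld$n_specimens, mne = fld$mne,
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$element, out$side), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a heatmap as CSV (point_index, x, y, z, count) or scalar PLY
#' @param field a `heatmap_field`
#' @param template the matching `bone_template`
#' @param path output path
#' @param format `"csv"` or `"ply"`
#' @export
write_heatmap <- function(field, template, path, format = c("csv", "ply")) {
  format <- match.arg(format)
  stopifnot(inherits(field, "heatmap_field"),
            identical(field$template_id, template$template_id))
  if (format == "csv") {
    df <- data.frame(point_index = seq_along(field$counts),
                     x = fmt_num(template$points[, 1]),
                     y = fmt_num(template$points[, 2]),
                     z = fmt_num(template$points[, 3]),
                     count = field$counts)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    write_ply(template$points, path, binary = FALSE, scalar = field$counts)
  }
  invisible(path)
}

# crop (de)serialization for the store's crops.json
crop_to_list <- function(m) {
  list(specimen_id = m$specimen_id, template_id = m$template_id,
       parameters = m$parameters, retained = which(m$retained),
       n_points = length(m$retained))
}

crop_from_list <- function(l) {
  retained <- rep(FALSE, l$n_points)
  retained[unlist(l$retained)] <- TRUE
  structure(list(specimen_id = l$specimen_id, template_id = l$template_id,
                 retained = retained, parameters = l$parameters),
            class = "crop_mask")
}

#' Attach a crop mask to a store
#' @param store an `assemblage_store`
#' @param mask a `crop_mask` whose `specimen_id` exists in the store
#' @export
add_crop <- function(store, mask) {
  stopifnot(inherits(store, "assemblage_store"), inherits(mask, "crop_mask"))
  if (!mask$specimen_id %in% store$specimens$specimen_id)
    ot_stop(sprintf("unknown specimen '%s'", mask$specimen_id),
            "unknown_specimen")
  store$crops[[mask$specimen_id]] <- mask
  log_op(store, "add_crop", list(specimen_id = mask$specimen_id))
  invisible(mask$specimen_id)
}
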