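# The assemblage store: templates, specimens, marks and crop masks with
# referential integrity and a provenance log. Backed by an environment so
# mutators update in place; queries never mutate. Persistence is flat CSV
# (marks, specimens) + JSON (templates, crops), diffable and round-trippable.

FRACTURE_STATES <- c("green", "dry", "unknown")
SHAFT_TYPES <- c("1", "2", "3", "unknown")

empty_marks_df <- function() {
  df <- data.frame(mark_id = character(), specimen_id = character(),
                   template_id = character(), mark_type = character(),
                   x = double(), y = double(), z = double(),
                   x1 = double(), y1 = double(), z1 = double(),
                   x2 = double(), y2 = double(), z2 = double(),
                   stringsAsFactors = FALSE)
  df
}

#' Create an empty assemblage store
#'
#' Holds bone templates, specimen metadata, registered marks and crop masks,
#' enforcing referential integrity (every mark references an existing specimen
#' and template). Every mutating operation is appended to a provenance log.
#'
#' @param off_template_tol tolerance in mm by which the template bounding box
#'   is expanded when validating mark positions.
#' @return an object of class `assemblage_store`.
#' @export
assemblage_store <- function(off_template_tol = 2) {
  e <- new.env(parent = emptyenv())
  e$templates <- list()
  e$specimens <- data.frame(specimen_id = character(), site = character(),
                            taxon = character(), element = character(),
                            side = character(), size_class = integer(),
                            age = character(), fracture_state = character(),
                            shaft_circumference_type = character(),
                            stringsAsFactors = FALSE)
  e$marks <- empty_marks_df()
  e$crops <- list()
  e$provenance <- list()
  e$mark_counter <- 0L
  e$off_template_tol <- off_template_tol
  class(e) <- "assemblage_store"
  e
}

#' @export
print.assemblage_store <- function(x, ...) {
  cat(sprintf(
    "<assemblage_store: %d templates, %d specimens, %d marks, %d crops>\n",
    length(x$templates), nrow(x$specimens), nrow(x$marks), length(x$crops)))
  invisible(x)
}

log_op <- function(store, op, params) {
  store$provenance[[length(store$provenance) + 1L]] <-
    list(operation = op, timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         parameters = params)
  invisible(store)
}

#' Add a bone template to a store
#' @param store an `assemblage_store`
#' @param template a `bone_template`
#' @export
add_template <- function(store, template) {
  stopifnot(inherits(store, "assemblage_store"),
            inherits(template, "bone_template"))
  if (template$template_id %in% names(store$templates))
    ot_stop(sprintf("template '%s' already exists", template$template_id),
            "duplicate_id")
  store$templates[[template$template_id]] <- template
  log_op(store, "add_template", list(template_id = template$template_id))
  invisible(template$template_id)
}

#' Add a specimen record to a store
#' @inheritParams add_template
#' @param specimen_id unique specimen identifier
#' @param template_id id of the bone template this specimen is registered on
#' @param site,taxon,age free-text metadata
#' @param fracture_state `"green"`, `"dry"` or `"unknown"`
#' @param shaft_circumference_type Bunn shaft circumference type
#'   (`"1"`, `"2"`, `"3"` or `"unknown"`)
#' @export
add_specimen <- function(store, specimen_id, template_id, site = "", taxon = "",
                         age = "", fracture_state = "unknown",
                         shaft_circumference_type = "unknown") {
  stopifnot(inherits(store, "assemblage_store"))
  tp <- store$templates[[template_id]]
  if (is.null(tp))
    ot_stop(sprintf("unknown template '%s'", template_id), "unknown_template")
  if (specimen_id %in% store$specimens$specimen_id)
    ot_stop(sprintf("specimen '%s' already exists", specimen_id), "duplicate_id")
  fracture_state <- match.arg(fracture_state, FRACTURE_STATES)
  shaft_circumference_type <- match.arg(as.character(shaft_circumference_type),
                                        SHAFT_TYPES)
  store$specimens <- rbind(store$specimens, data.frame(
    specimen_id = specimen_id, site = site, taxon = taxon,
    element = tp$element, side = tp$side, size_class = tp$size_class,
    age = age, fracture_state = fracture_state,
    shaft_circumference_type = shaft_circumference_type,
    stringsAsFactors = FALSE))
  log_op(store, "add_specimen",
         list(specimen_id = specimen_id, template_id = template_id))
  invisible(specimen_id)
}

specimen_template <- function(store, specimen_id) {
  row <- store$specimens[store$specimens$specimen_id == specimen_id, ]
  if (nrow(row) == 0L)
    ot_stop(sprintf("unknown specimen '%s'", specimen_id), "unknown_specimen")
  for (tp in store$templates)
    if (tp$element == row$element && tp$side == row$side) return(tp)
  ot_stop("specimen has no matching template", "unknown_template")
}

#' Register a bone surface modification
#'
#' Punctual marks (`pit`, `percussion`) are given by a single `position`;
#' linear marks (`score`, `cut`) are given by two distinct `endpoints` and
#' their stored position is the segment midpoint. Positions must fall within
#' the template bounding box expanded by the store's tolerance.
#'
#' @inheritParams add_template
#' @param specimen_id id of an existing specimen
#' @param mark_type `"pit"`, `"score"`, `"cut"` or `"percussion"`
#' @param position length-3 coordinate (punctual marks), mm
#' @param endpoints 2 x 3 matrix or list of two length-3 coordinates (linear
#'   marks), mm
#' @return the stored mark as a one-row data.frame
#' @export
register_mark <- function(store, specimen_id, mark_type, position = NULL,
                          endpoints = NULL) {
  stopifnot(inherits(store, "assemblage_store"))
  mark_type <- match.arg(mark_type, MARK_TYPES)
  tp <- specimen_template(store, specimen_id)
  linear <- mark_type %in% LINEAR_TYPES
  if (linear) {
    if (is.null(endpoints))
      ot_stop(sprintf("endpoints required for mark type '%s'", mark_type),
              "endpoints_required")
    if (is.list(endpoints)) endpoints <- do.call(rbind, endpoints)
    endpoints <- as_xyz(endpoints, "endpoints")
    if (nrow(endpoints) != 2L)
      ot_stop("endpoints must be two 3D coordinates", "bad_coords")
    if (sqrt(sum((endpoints[1, ] - endpoints[2, ])^2)) < 1e-9)
      ot_stop("degenerate segment: endpoints are identical", "degenerate_segment")
    position <- colMeans(endpoints)
  } else {
    if (!is.null(endpoints))
      ot_stop(sprintf("endpoints not allowed for mark type '%s'", mark_type),
              "endpoints_not_allowed")
    if (is.null(position))
      ot_stop("punctual mark requires a position", "position_required")
    position <- drop(as_xyz(position, "position"))
  }
  bbox <- template_bbox(tp, store$off_template_tol)
  if (!in_bbox(position, bbox))
    ot_stop("off-template mark: position outside expanded template box",
            "off_template")
  store$mark_counter <- store$mark_counter + 1L
  mark_id <- sprintf("m%06d", store$mark_counter)
  rec <- data.frame(mark_id = mark_id, specimen_id = specimen_id,
                    template_id = tp$template_id, mark_type = mark_type,
                    x = position[1], y = position[2], z = position[3],
                    x1 = if (linear) endpoints[1, 1] else NA_real_,
                    y1 = if (linear) endpoints[1, 2] else NA_real_,
                    z1 = if (linear) endpoints[1, 3] else NA_real_,
                    x2 = if (linear) endpoints[2, 1] else NA_real_,
                    y2 = if (linear) endpoints[2, 2] else NA_real_,
                    z2 = if (linear) endpoints[2, 3] else NA_real_,
                    stringsAsFactors = FALSE)
  store$marks <- rbind(store$marks, rec)
  rownames(store$marks) <- NULL
  log_op(store, "register_mark",
         list(mark_id = mark_id, specimen_id = specimen_id,
              mark_type = mark_type))
  invisible(rec)
}

QUERY_KEYS <- c("element", "side", "mark_type", "site", "specimen", "size_class")

#' Query registered marks
#'
#' Returns exactly the marks matching the conjunction of all supplied filters,
#' ordered by `mark_id`. An empty filter returns all marks.
#'
#' @inheritParams add_template
#' @param ... named filters among `element`, `side`, `mark_type`, `site`,
#'   `specimen`, `size_class`
#' @return data.frame of matching marks (canonical mark columns)
#' @export
query_marks <- function(store, ...) {
  stopifnot(inherits(store, "assemblage_store"))
  filters <- list(...)
  bad <- setdiff(names(filters), QUERY_KEYS)
  if (length(bad))
    ot_stop(sprintf("unknown filter key(s) %s; valid keys: %s",
                    paste(sQuote(bad), collapse = ", "),
                    paste(QUERY_KEYS, collapse = ", ")), "bad_filter")
  m <- store$marks
  if (nrow(m) == 0L) return(m)
  sp <- store$specimens
  meta <- sp[match(m$specimen_id, sp$specimen_id), ]
  keep <- rep(TRUE, nrow(m))
  for (k in names(filters)) {
    v <- filters[[k]]
    keep <- keep & switch(k,
      element = meta$element %in% v,
      side = meta$side %in% v,
      mark_type = m$mark_type %in% v,
      site = meta$site %in% v,
      specimen = m$specimen_id %in% v,
      size_class = meta$size_class %in% as.integer(v))
  }
  out <- m[keep, , drop = FALSE]
  out <- out[order(out$mark_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Persist a store to a directory (CSV + JSON)
#'
#' Writes `marks.csv`, `specimens.csv`, `templates.json` and `crops.json`.
#' [read_store()] reloads a record-identical store (provenance restarts).
#'
#' @inheritParams add_template
#' @param dir output directory (created if needed)
#' @export
write_store <- function(store, dir) {
  stopifnot(inherits(store, "assemblage_store"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_marks_csv(store$marks, file.path(dir, "marks.csv"))
  write_specimens_csv(store$specimens, file.path(dir, "specimens.csv"))
  jsonlite::write_json(lapply(store$templates, template_to_list),
                       file.path(dir, "templates.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(lapply(store$crops, crop_to_list),
                       file.path(dir, "crops.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_store
#' @export
read_store <- function(dir, off_template_tol = 2) {
  store <- assemblage_store(off_template_tol)
  tpl <- jsonlite::read_json(file.path(dir, "templates.json"),
                             simplifyVector = TRUE, simplifyDataFrame = FALSE,
                             simplifyMatrix = TRUE)
  for (l in tpl) add_template(store, template_from_list(l))
  sp <- read_specimens_csv(file.path(dir, "specimens.csv"))
  store$specimens <- sp
  marks <- read_marks_csv(file.path(dir, "marks.csv"))
  store$marks <- marks
  if (nrow(marks))
    store$mark_counter <- max(as.integer(sub("^m", "", marks$mark_id)))
  cr_path <- file.path(dir, "crops.json")
  if (file.exists(cr_path)) {
    cr <- jsonlite::read_json(cr_path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
    store$crops <- lapply(cr, crop_from_list)
    names(store$crops) <- vapply(store$crops, function(x) x$specimen_id, "")
  }
  store$provenance <- list()
  store
}
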