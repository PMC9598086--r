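# Readers and writers for interchange formats: PLY (ascii + binary little
# endian), OBJ (vertices only), whitespace XYZ, marks/specimens CSV, and
# template/crop JSON. All coordinates are mm, stored double; CSV numeric
# fields are written with 9 significant digits.

MARKS_HEADER <- c("mark_id", "specimen_id", "template_id", "mark_type",
                  "x", "y", "z", "x1", "y1", "z1", "x2", "y2", "z2")
SPECIMENS_HEADER <- c("specimen_id", "site", "taxon", "element", "side",
                      "size_class", "age", "fracture_state",
                      "shaft_circumference_type")

#' Read a 3D point cloud
#'
#' Supports PLY (ascii and binary_little_endian), OBJ (vertex lines only) and
#' whitespace-separated XYZ. Format is inferred from the file extension unless
#' given explicitly.
#'
#' @param path file path
#' @param format `"ply"`, `"obj"`, `"xyz"` or `"auto"`
#' @return n x 3 numeric matrix
#' @export
read_cloud <- function(path, format = c("auto", "ply", "obj", "xyz")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, ply = "ply", obj = "obj", xyz = "xyz", txt = "xyz",
                     ot_stop(sprintf("cannot infer cloud format from '%s'", path),
                             "bad_format"))
  }
  switch(format,
         ply = read_ply(path),
         obj = read_obj(path),
         xyz = as_xyz(as.matrix(utils::read.table(path)[, 1:3])))
}

#' Write a 3D point cloud
#' @param points n x 3 matrix (or a `bone_template`, whose points are used)
#' @param path output path
#' @param format `"ply"`, `"obj"` or `"xyz"`; PLY may be ascii or binary
#' @param binary write binary_little_endian PLY (PLY only)
#' @param scalar optional per-point scalar written as a `quality` property (PLY only)
#' @export
write_cloud <- function(points, path, format = c("ply", "obj", "xyz"),
                        binary = FALSE, scalar = NULL) {
  if (inherits(points, "bone_template")) points <- points$points
  points <- as_xyz(points)
  format <- match.arg(format)
  switch(format,
         ply = write_ply(points, path, binary = binary, scalar = scalar),
         obj = writeLines(c("# OBJ point cloud",
                            sprintf("v %s %s %s", fmt_num(points[, 1]),
                                    fmt_num(points[, 2]), fmt_num(points[, 3]))),
                          path),
         xyz = utils::write.table(
           matrix(fmt_num(points), ncol = 3), path,
           quote = FALSE, row.names = FALSE, col.names = FALSE))
  invisible(path)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(magic, "ply")) ot_stop("not a PLY file", "bad_format")
  fmt <- NULL; nvert <- NULL; props <- character(); in_vertex <- FALSE
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) ot_stop("truncated PLY header", "bad_format")
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "element") {
      in_vertex <- tok[2] == "vertex"
      if (in_vertex) nvert <- as.integer(tok[3])
    } else if (tok[1] == "property" && in_vertex) props <- c(props, tok[3])
    else if (tok[1] == "end_header") break
  }
  if (is.null(nvert)) ot_stop("PLY file has no vertex element", "bad_format")
  np <- length(props)
  if (identical(fmt, "ascii")) {
    vals <- scan(con, what = double(), n = nvert * np, quiet = TRUE)
  } else if (identical(fmt, "binary_little_endian")) {
    vals <- readBin(con, what = "double", n = nvert * np, size = 8L,
                    endian = "little")
  } else ot_stop(sprintf("unsupported PLY format '%s'", fmt), "bad_format")
  m <- matrix(vals, nrow = nvert, ncol = np, byrow = TRUE)
  colnames(m) <- props
  out <- as_xyz(m[, c("x", "y", "z"), drop = FALSE])
  extra <- setdiff(props, c("x", "y", "z"))
  if (length(extra)) attr(out, "scalars") <- m[, extra, drop = FALSE]
  out
}

write_ply <- function(points, path, binary = FALSE, scalar = NULL) {
  n <- nrow(points)
  props <- c("property double x", "property double y", "property double z")
  dat <- points
  if (!is.null(scalar)) {
    stopifnot(length(scalar) == n)
    props <- c(props, "property double quality")
    dat <- cbind(points, quality = as.double(scalar))
  }
  hdr <- c("ply",
           sprintf("format %s 1.0",
                   if (binary) "binary_little_endian" else "ascii"),
           sprintf("element vertex %d", n), props, "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con, sep = "\n")
    writeBin(as.vector(t(dat)), con, size = 8L, endian = "little")
  } else {
    body <- apply(dat, 1L, function(r) paste(fmt_num(r), collapse = " "))
    writeLines(c(hdr, body), path)
  }
  invisible(path)
}

read_obj <- function(path) {
  lines <- readLines(path)
  v <- lines[startsWith(lines, "v ")]
  if (!length(v)) ot_stop("OBJ file contains no vertices", "bad_format")
  m <- do.call(rbind, lapply(strsplit(trimws(v), "\\s+"), function(t)
    as.numeric(t[2:4])))
  as_xyz(m)
}

#' Write a mark table to CSV
#'
#' Columns (exact header): `mark_id,specimen_id,template_id,mark_type,x,y,z,
#' x1,y1,z1,x2,y2,z2`; endpoint columns are empty for punctual marks.
#' @param marks data.frame of marks as returned by [query_marks()]
#' @param path output path
#' @export
write_marks_csv <- function(marks, path) {
  out <- marks[, MARKS_HEADER]
  num <- vapply(out, is.numeric, logical(1))
  for (j in which(num)) out[[j]] <- ifelse(is.na(out[[j]]), "", fmt_num(out[[j]]))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a mark table from CSV
#' @param path CSV path with the canonical mark header
#' @return data.frame with one row per mark; endpoint columns are `NA` for
#'   punctual marks
#' @export
read_marks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(mark_id = "character",
                                       specimen_id = "character",
                                       template_id = "character"))
  missing <- setdiff(MARKS_HEADER, names(df))
  if (length(missing))
    ot_stop(paste("marks CSV missing columns:", paste(missing, collapse = ", ")),
            "bad_format")
  for (cc in c("x", "y", "z", "x1", "y1", "z1", "x2", "y2", "z2"))
    df[[cc]] <- as.numeric(df[[cc]])
  df[, MARKS_HEADER]
}

#' @rdname write_marks_csv
#' @param specimens data.frame of specimen metadata
#' @export
write_specimens_csv <- function(specimens, path) {
  utils::write.csv(specimens[, SPECIMENS_HEADER], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname read_marks_csv
#' @export
read_specimens_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing <- setdiff(SPECIMENS_HEADER, names(df))
  if (length(missing))
    ot_stop(paste("specimens CSV missing columns:",
                  paste(missing, collapse = ", ")), "bad_format")
  df$size_class <- as.integer(df$size_class)
  df[, SPECIMENS_HEADER]
}

template_to_list <- function(tp) {
  list(template_id = tp$template_id, element = tp$element, side = tp$side,
       size_class = tp$size_class, length = tp$length,
       points = unname(tp$points))
}

template_from_list <- function(l) {
  pts <- l$points
  if (is.list(pts)) pts <- do.call(rbind, lapply(pts, unlist))
  bone_template(pts, l$element, l$side, l$size_class, l$template_id)
}
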