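test_that("canonicalize_template is idempotent and inverts known rotations", {
  tube <- tube_cloud()
  c0 <- canonicalize_template(tube, "tibia", "left")
  # already-canonical cloud: returned unchanged up to translation
  c1 <- canonicalize_template(c0$points, "tibia", "left")
  expect_lt(max(abs(c0$points - c1$points)), 1e-9)
  # pre-rotated 30 degrees about z: output equals unrotated canonical form
  c2 <- canonicalize_template(tube %*% t(rot_z(30)), "tibia", "left")
  expect_lt(max(abs(c0$points - c2$points)), 1e-6)
  # invariants
  expect_lt(max(abs(colMeans(c0$points))), 1e-6)
  expect_equal(c0$length, max(c0$points[, 1]) - min(c0$points[, 1]),
               tolerance = 1e-9)
})

test_that("canonicalize_template rejects degenerate clouds", {
  set.seed(7)
  u <- matrix(rnorm(300 * 3), ncol = 3)
  sphere <- u / sqrt(rowSums(u^2))
  expect_error(canonicalize_template(sphere, "femur", "left"),
               class = "degenerate_cloud")
  # rank-deficient: all points in a plane through zero z-variance
  flat <- cbind(runif(200, 0, 10), runif(200), 0)
  expect_error(canonicalize_template(flat, "femur", "left"),
               class = "degenerate_cloud")
  expect_error(canonicalize_template(tube_cloud(n = 50), "femur", "left"),
               class = "too_few_points")
})

test_that("register_mark enforces the midpoint and endpoint rules", {
  d <- demo_store()
  rec <- register_mark(d$store, "fl1", "score",
                       endpoints = rbind(c(10, 2, 0), c(20, 4, 2)))
  expect_equal(c(rec$x, rec$y, rec$z), c(15, 3, 1))
  pit <- register_mark(d$store, "fl1", "pit", position = c(0, 0, 0))
  got <- query_marks(d$store, mark_type = "pit")
  expect_equal(got$mark_id, pit$mark_id)
  expect_true(all(is.na(got[, c("x1", "y1", "z1", "x2", "y2", "z2")])))
  # error cases
  expect_error(register_mark(d$store, "fl1", "pit", position = c(0, 0, 0),
                             endpoints = rbind(c(0, 0, 0), c(1, 1, 1))),
               class = "endpoints_not_allowed")
  expect_error(register_mark(d$store, "fl1", "score", position = c(0, 0, 0)),
               class = "endpoints_required")
  expect_error(register_mark(d$store, "fl1", "score",
                             endpoints = rbind(c(1, 1, 1), c(1, 1, 1))),
               class = "degenerate_segment")
  expect_error(register_mark(d$store, "fl1", "pit", position = c(500, 0, 0)),
               class = "off_template")
  expect_error(register_mark(d$store, "nope", "pit", position = c(0, 0, 0)),
               class = "unknown_specimen")
})

test_that("mark ids are zero-padded sequential and the midpoint invariant holds", {
  d <- demo_store()
  set.seed(3)
  for (i in 1:5)
    register_mark(d$store, "fl1", "score",
                  endpoints = rbind(runif(3, -5, 5), runif(3, 6, 10)))
  m <- query_marks(d$store)
  expect_equal(m$mark_id, sprintf("m%06d", 1:5))
  expect_equal(m$x, (m$x1 + m$x2) / 2, tolerance = 1e-12)
  expect_equal(m$y, (m$y1 + m$y2) / 2, tolerance = 1e-12)
  expect_equal(m$z, (m$z1 + m$z2) / 2, tolerance = 1e-12)
})

test_that("query_marks filters match a brute-force scan", {
  d <- demo_store()
  set.seed(11)
  specs <- c("fl1", "fr1", "tl1")
  types <- c("pit", "score", "percussion")
  for (i in 1:30) {
    sp <- sample(specs, 1)
    ty <- sample(types, 1)
    if (ty == "score")
      register_mark(d$store, sp, ty,
                    endpoints = rbind(runif(3, -5, 0), runif(3, 1, 5)))
    else register_mark(d$store, sp, ty, position = runif(3, -5, 5))
  }
  all_marks <- query_marks(d$store)
  expect_equal(nrow(all_marks), 30L)
  # conjunction filter vs linear scan oracle
  got <- query_marks(d$store, element = "femur", side = "left",
                     mark_type = "pit")
  oracle <- sum(all_marks$specimen_id == "fl1" & all_marks$mark_type == "pit")
  expect_equal(nrow(got), oracle)
  # nonexistent site: empty, no error
  expect_equal(nrow(query_marks(d$store, site = "nowhere")), 0L)
  # unknown key lists valid keys
  err <- tryCatch(query_marks(d$store, colour = "red"), error = identity)
  expect_s3_class(err, "bad_filter")
  expect_match(conditionMessage(err), "mark_type")
  # deterministic order
  expect_equal(all_marks$mark_id, sort(all_marks$mark_id))
})

test_that("store round-trips through CSV/JSON record-identically", {
  d <- demo_store()
  register_mark(d$store, "fl1", "score",
                endpoints = rbind(c(-10, 2, 0), c(20, 4, 2)))
  register_mark(d$store, "fr1", "pit", position = c(1, 2, 3))
  add_crop(d$store, crop_interval(d$tpl, "x", 0, 0.5, specimen_id = "fl1"))
  dir <- withr::local_tempdir()
  write_store(d$store, dir)
  re <- read_store(dir)
  expect_equal(re$marks, d$store$marks, tolerance = 1e-12)
  expect_equal(re$specimens, d$store$specimens)
  expect_equal(names(re$templates), names(d$store$templates))
  for (id in names(re$templates))
    expect_equal(re$templates[[id]]$points, d$store$templates[[id]]$points,
                 tolerance = 1e-12)
  expect_equal(re$crops[["fl1"]]$retained, d$store$crops[["fl1"]]$retained)
})

test_that("provenance log length equals number of mutating operations", {
  d <- demo_store()  # 3 add_template + 3 add_specimen
  register_mark(d$store, "fl1", "pit", position = c(0, 0, 0))
  add_crop(d$store, crop_interval(d$tpl, "x", 0, 1, specimen_id = "fl1"))
  expect_length(d$store$provenance, 8L)
  query_marks(d$store)  # queries never mutate
  expect_length(d$store$provenance, 8L)
})

test_that("point clouds round-trip through PLY (ascii and binary), OBJ, XYZ", {
  pts <- tube_cloud(n = 120, seed = 9)
  dir <- withr::local_tempdir()
  for (spec in list(list(f = "ply", binary = FALSE), list(f = "ply", binary = TRUE),
                    list(f = "obj", binary = FALSE), list(f = "xyz", binary = FALSE))) {
    path <- file.path(dir, paste0("c", spec$binary, ".", spec$f))
    write_cloud(pts, path, format = spec$f, binary = spec$binary)
    back <- read_cloud(path)
    tol <- if (spec$f == "ply" && spec$binary) 1e-12 else 1e-6
    expect_equal(unname(back), unname(pts), tolerance = tol)
  }
})

test_that("marks CSV round-trips with the exact canonical header", {
  d <- demo_store()
  register_mark(d$store, "fl1", "score",
                endpoints = rbind(c(-10, 2, 0), c(20, 4, 2)))
  register_mark(d$store, "fl1", "pit", position = c(5, -3, 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_marks_csv(d$store$marks, path)
  hdr <- strsplit(readLines(path, n = 1), ",")[[1]]
  expect_equal(hdr, c("mark_id", "specimen_id", "template_id", "mark_type",
                      "x", "y", "z", "x1", "y1", "z1", "x2", "y2", "z2"))
  back <- read_marks_csv(path)
  expect_equal(back, d$store$marks, tolerance = 1e-9)
})
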