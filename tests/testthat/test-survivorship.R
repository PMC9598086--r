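test_that("crop_polygonal matches a brute-force point-in-polygon oracle", {
  tp <- small_template(n_points = 1500)
  p <- tp$points
  # rectangle covering the full xy extent keeps everything
  bb <- template_bbox(tp, 1)
  rect_all <- rbind(c(bb$min[1], bb$min[2]), c(bb$max[1], bb$min[2]),
                    c(bb$max[1], bb$max[2]), c(bb$min[1], bb$max[2]))
  m_all <- crop_polygonal(tp, rect_all, "xy", "inside")
  expect_true(all(m_all$retained))
  # rectangle over the x < mid half: oracle is a direct coordinate test
  mid <- (bb$min[1] + bb$max[1]) / 2
  rect_half <- rbind(c(bb$min[1], bb$min[2]), c(mid, bb$min[2]),
                     c(mid, bb$max[2]), c(bb$min[1], bb$max[2]))
  m_half <- crop_polygonal(tp, rect_half, "xy", "inside")
  oracle <- p[, 1] <= mid  # rectangle spans full y, so only x decides
  expect_equal(m_half$retained, unname(oracle))
  # keep = outside complements
  m_out <- crop_polygonal(tp, rect_half, "xy", "outside")
  expect_equal(m_out$retained, !m_half$retained)
  # irregular pentagon vs an independently coded even-odd oracle
  poly <- rbind(c(-60, -25), c(40, -30), c(80, 10), c(0, 35), c(-90, 12))
  m_poly <- crop_polygonal(tp, poly, "xz", "inside")
  eo <- function(px, py) {
    n <- nrow(poly); inside <- FALSE; j <- n
    for (i in seq_len(n)) {
      if ((poly[i, 2] > py) != (poly[j, 2] > py) &&
          px < (poly[j, 1] - poly[i, 1]) * (py - poly[i, 2]) /
            (poly[j, 2] - poly[i, 2]) + poly[i, 1]) inside <- !inside
      j <- i
    }
    inside
  }
  oracle2 <- vapply(seq_len(nrow(p)), function(i) eo(p[i, 1], p[i, 3]), TRUE)
  expect_equal(m_poly$retained, oracle2)
})

test_that("crop_polygonal rejects bad polygons and empty crops", {
  tp <- small_template(n_points = 500)
  bowtie <- rbind(c(0, 0), c(10, 10), c(10, 0), c(0, 10))
  expect_error(crop_polygonal(tp, bowtie, "xy"), class = "bad_polygon")
  expect_error(crop_polygonal(tp, rbind(c(0, 0), c(1, 1)), "xy"),
               class = "bad_polygon")
  far <- rbind(c(900, 900), c(910, 900), c(905, 910))
  expect_error(crop_polygonal(tp, far, "xy"), class = "empty_crop")
})

test_that("crop_interval retains the stated normalized slab", {
  tp <- small_template()
  full <- crop_interval(tp, "x", 0, 1)
  expect_true(all(full$retained))
  lo <- crop_interval(tp, "x", 0, 0.5)
  hi <- crop_interval(tp, "x", 0.5, 1)
  expect_true(all(xor(lo$retained, hi$retained)))  # exact partition
  # uniform tube (no epiphyseal flare): retained fraction tracks the width
  tube <- make_template("femur", "left", length = 240, shaft_radius = 12,
                        epiphysis_radii = c(12.01, 12.01), n_points = 4000,
                        seed = 6)
  mid <- crop_interval(tube, "x", 0.4, 0.6)
  expect_lt(abs(mean(mid$retained) - 0.2), 0.02)
  expect_error(crop_interval(tp, "x", 0.6, 0.4), class = "bad_interval")
})

test_that("superimpose counts overlaps and reports the MNE", {
  tp <- small_template(n_points = 800)
  two_full <- superimpose(list(crop_interval(tp, "x", 0, 1, specimen_id = "a"),
                               crop_interval(tp, "x", 0, 1, specimen_id = "b")))
  expect_true(all(two_full$counts == 2L))
  expect_equal(two_full$mne, 2L)
  halves <- superimpose(list(crop_interval(tp, "x", 0, 0.5),
                             crop_interval(tp, "x", 0.5, 1)))
  expect_equal(halves$mne, 1L)
  expect_equal(sum(halves$counts), nrow(tp$points))
  # mixed templates rejected
  other <- make_template("tibia", "right", length = 260, n_points = 500,
                         seed = 4)
  expect_error(superimpose(list(crop_interval(tp, "x", 0, 1),
                                crop_interval(other, "x", 0, 1))),
               class = "mixed_templates")
})

test_that("MNE equals the analytic stabbing number on crop fixtures", {
  tp <- small_template()
  ivs <- list(c(0, 0.7), c(0.2, 0.8), c(0.3, 1), c(0.35, 0.65), c(0.1, 0.9))
  masks <- make_crop_set(tp, ivs)
  expect_equal(superimpose(masks)$mne, attr(masks, "ground_truth_overlap"))
  # randomized fixtures: 10 crops, analytic truth from the generator
  set.seed(21)
  for (rep in 1:5) {
    lo <- runif(10, 0, 0.8)
    hi <- pmin(lo + runif(10, 0.05, 0.5), 1)
    masks <- make_crop_set(tp, Map(c, lo, hi))
    expect_equal(superimpose(masks)$mne, attr(masks, "ground_truth_overlap"))
  }
})

test_that("mne is invariant to mask order and complete specimens add one", {
  tp <- small_template(n_points = 600)
  ivs <- list(c(0, 0.6), c(0.3, 0.9), c(0.5, 1), c(0.2, 0.7))
  masks <- make_crop_set(tp, ivs)
  f1 <- superimpose(masks)
  f2 <- superimpose(rev(masks))
  expect_equal(f1$counts, f2$counts)
  expect_equal(f1$mne, f2$mne)
  # adding a complete specimen increments every count and the MNE by 1
  f3 <- superimpose(c(masks, list(crop_interval(tp, "x", 0, 1))))
  expect_equal(f3$counts, f1$counts + 1L)
  expect_equal(f3$mne, f1$mne + 1L)
  # k complete specimens give a constant-k heatmap
  fk <- superimpose(replicate(3, crop_interval(tp, "x", 0, 1),
                              simplify = FALSE))
  expect_true(all(fk$counts == 3L))
})

test_that("mne_report groups by element and side", {
  tpl <- small_template(n_points = 400)
  tpr <- make_template("femur", "right", length = 240, n_points = 400,
                       seed = 2)
  templates <- list(femur_left = tpl, femur_right = tpr)
  masks <- list(crop_interval(tpl, "x", 0, 1, specimen_id = "L1"),
                crop_interval(tpl, "x", 0, 1, specimen_id = "L2"),
                crop_interval(tpr, "x", 0, 0.5, specimen_id = "R1"),
                crop_interval(tpr, "x", 0.5, 1, specimen_id = "R2"))
  rep <- mne_report(masks, templates)
  expect_equal(rep$mne[rep$side == "left"], 2L)
  expect_equal(rep$mne[rep$side == "right"], 1L)
  expect_true(all(rep$mne <= rep$n_specimens))
  # single complete specimen
  one <- mne_report(masks[1], templates)
  expect_equal(one$mne, 1L)
  expect_warning(mne_report(list(), templates), "empty")
})

test_that("external clouds are matched back with tolerance and reporting", {
  tp <- small_template(n_points = 500)
  keep <- tp$points[1:200, ]
  jitter <- keep + matrix(runif(600, -0.1, 0.1), ncol = 3)
  m <- match_cloud_crop(tp, jitter, tol = 0.5, specimen_id = "ext")
  expect_gte(sum(m$retained), 190)  # jittered points snap to their sources
  off <- rbind(keep[1:5, ], matrix(500, 3, 3))
  expect_warning(m2 <- match_cloud_crop(tp, off, tol = 0.5), "rejected")
  expect_equal(length(attr(m2, "rejected")), 3L)
})

test_that("heatmaps export as CSV and scalar PLY", {
  tp <- small_template(n_points = 300)
  fld <- superimpose(list(crop_interval(tp, "x", 0, 0.6),
                          crop_interval(tp, "x", 0.4, 1)))
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "h.csv")
  write_heatmap(fld, tp, csv, "csv")
  back <- utils::read.csv(csv)
  expect_equal(back$count, fld$counts)
  ply <- file.path(dir, "h.ply")
  write_heatmap(fld, tp, ply, "ply")
  cloud <- read_cloud(ply)
  expect_equal(unname(attr(cloud, "scalars")[, "quality"]),
               as.double(fld$counts), tolerance = 1e-6)
})
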