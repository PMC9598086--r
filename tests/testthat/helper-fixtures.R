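# Shared fixtures, generated in code (no data files).

# noisy tube along x with distinct y/z spreads so all three principal axes
# are numerically well separated
tube_cloud <- function(n = 500, len = 100, sy = 6, sz = 4, seed = 42) {
  set.seed(seed)
  cbind(runif(n, 0, len), rnorm(n, 0, sy) * 1.3, rnorm(n, 0, sz))
}

rot_z <- function(deg) {
  th <- deg * pi / 180
  rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
}

small_template <- function(seed = 1, n_points = 2000) {
  make_template("femur", "left", length = 240, shaft_radius = 12,
                epiphysis_radii = c(28, 30), n_points = n_points, seed = seed)
}

# literal double-loop oracles for the second-order estimators
naive_k <- function(pts, w, r) {
  n <- nrow(pts)
  L <- w$max - w$min
  total <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    dx <- abs(pts[i, ] - pts[j, ])
    d <- sqrt(sum(dx^2))
    if (d <= r) total <- total + w$volume / prod(L - dx)
  }
  w$volume / (n * (n - 1)) * total
}

naive_pcf <- function(pts, w, r, h) {
  n <- nrow(pts)
  L <- w$max - w$min
  total <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    dx <- abs(pts[i, ] - pts[j, ])
    d <- sqrt(sum(dx^2))
    u <- (r - d) / h
    if (abs(u) < 1) total <- total + 0.75 * (1 - u^2) / h * w$volume / prod(L - dx)
  }
  w$volume / (n * (n - 1)) * total / (4 * pi * r^2)
}

# store with one template + specimens on both sides, a few marks
demo_store <- function() {
  store <- assemblage_store()
  tpl <- small_template()
  tpr <- make_template("femur", "right", length = 240, n_points = 1000,
                       seed = 2)
  tib <- make_template("tibia", "left", length = 260, n_points = 1000,
                       seed = 3)
  add_template(store, tpl)
  add_template(store, tpr)
  add_template(store, tib)
  add_specimen(store, "fl1", "femur_left", site = "siteA")
  add_specimen(store, "fr1", "femur_right", site = "siteA")
  add_specimen(store, "tl1", "tibia_left", site = "siteB")
  list(store = store, tpl = tpl, tpr = tpr, tib = tib)
}
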