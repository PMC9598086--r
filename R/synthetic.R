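# Synthetic fixtures: bone-like templates, point processes with known
# statistical structure, score populations with controlled axial orientation,
# and crop sets with analytic overlap ground truth. Every generator takes an
# explicit seed and is bit-reproducible; there is no hidden global RNG state.

#' Generate a synthetic long-bone template
#'
#' Samples points uniformly (by area) on the surface of a tube of given shaft
#' radius whose ends flare into ellipsoidal epiphyses, a geometric stand-in
#' for a long bone: a central diaphysis with two wider epiphyses. The cloud is
#' produced directly in canonical pose (long axis = x, centroid at origin).
#'
#' @param element,side as in [bone_template()]
#' @param length inter-epiphyseal extent, mm; must exceed twice the largest
#'   epiphysis radius
#' @param shaft_radius diaphysis radius, mm
#' @param epiphysis_radii length-2 vector (distal, proximal) epiphysis radii, mm
#' @param n_points number of surface points (>= 100)
#' @param seed integer seed (mandatory)
#' @param size_class animal size class
#' @param template_id identifier
#' @return a `bone_template` with `n_points` points whose x extent equals
#'   `length` within 1%%
#' @export
make_template <- function(element, side, length = 240, shaft_radius = 12,
                          epiphysis_radii = c(28, 30), n_points = 5000,
                          seed, size_class = 3L,
                          template_id = paste(element, side, sep = "_")) {
  stopifnot(!missing(seed))
  if (length <= 2 * max(epiphysis_radii))
    ot_stop("inconsistent geometry: length must exceed 2 * max(epiphysis_radii)",
            "bad_geometry")
  if (shaft_radius <= 0 || any(epiphysis_radii <= 0))
    ot_stop("inconsistent geometry: radii must be positive", "bad_geometry")
  if (n_points < 100L) ot_stop("n_points must be >= 100", "too_few_points")
  ep_frac <- 0.15  # axial fraction of the bone occupied by each epiphysis
  pts <- with_seed(seed, {
    # radius profile along normalized axial coordinate t in [0,1]:
    # distal flare -> shaft -> proximal flare (smooth cosine blend)
    radius_at <- function(t) {
      r <- rep(shaft_radius, base::length(t))
      lo <- t < ep_frac
      hi <- t > 1 - ep_frac
      r[lo] <- shaft_radius + (epiphysis_radii[1] - shaft_radius) *
        (0.5 + 0.5 * cos(pi * t[lo] / ep_frac))
      r[hi] <- shaft_radius + (epiphysis_radii[2] - shaft_radius) *
        (0.5 + 0.5 * cos(pi * (1 - t[hi]) / ep_frac))
      r
    }
    # area-weighted axial sampling: surface band width ~ 2*pi*r(t) dt
    tg <- seq(0, 1, length.out = 4096)
    w <- radius_at(tg)
    t <- sample(tg, n_points, replace = TRUE, prob = w)
    t <- pmin(pmax(t + stats::runif(n_points, -1, 1) / 8192, 0), 1)
    phi <- stats::runif(n_points, 0, 2 * pi)
    r <- radius_at(t)
    cbind(x = t * length, y = r * cos(phi), z = r * sin(phi))
  })
  # force the stated x extent exactly, then centre (canonical frame)
  pts[, 1] <- (pts[, 1] - min(pts[, 1])) / diff(range(pts[, 1])) * length
  pts <- sweep(pts, 2, colMeans(pts))
  tp <- bone_template(pts, element, side, size_class, template_id)
  # generator metadata: lets downstream code evaluate the ideal radius profile
  attr(tp, "geometry") <- list(length = length, shaft_radius = shaft_radius,
                               epiphysis_radii = epiphysis_radii,
                               ep_frac = ep_frac)
  tp
}

#' Ideal surface radius of a synthetic template at normalized axial position
#'
#' Only available for templates from [make_template()] (uses the stored
#' generator geometry).
#' @param template a `bone_template` carrying generator geometry
#' @param t normalized axial positions in [0, 1] (0 = distal end)
#' @return radii, mm
#' @export
template_radius <- function(template, t) {
  g <- attr(template, "geometry")
  if (is.null(g)) ot_stop("template carries no generator geometry", "no_geometry")
  r <- rep(g$shaft_radius, length(t))
  lo <- t < g$ep_frac
  hi <- t > 1 - g$ep_frac
  r[lo] <- g$shaft_radius + (g$epiphysis_radii[1] - g$shaft_radius) *
    (0.5 + 0.5 * cos(pi * t[lo] / g$ep_frac))
  r[hi] <- g$shaft_radius + (g$epiphysis_radii[2] - g$shaft_radius) *
    (0.5 + 0.5 * cos(pi * (1 - t[hi]) / g$ep_frac))
  r
}

#' Axis-aligned 3D observation window
#' @param min,max length-3 numeric vectors of box corners, mm
#' @return object of class `box3_window` with fields `min`, `max`, `volume`
#' @export
box3_window <- function(min = c(0, 0, 0), max = c(1, 1, 1)) {
  min <- as.numeric(min); max <- as.numeric(max)
  stopifnot(length(min) == 3L, length(max) == 3L)
  if (any(max <= min))
    ot_stop("window must have positive extent on all axes", "bad_window")
  structure(list(min = min, max = max, volume = prod(max - min)),
            class = "box3_window")
}

#' @export
print.box3_window <- function(x, ...) {
  cat(sprintf("<box3_window [%s] to [%s], |W| = %g>\n",
              paste(x$min, collapse = ", "), paste(x$max, collapse = ", "),
              x$volume))
  invisible(x)
}

#' Default observation window for a template: bounding box padded by 1 mm
#' @param template a `bone_template`
#' @param pad padding, mm
#' @export
template_window <- function(template, pad = 1) {
  bb <- template_bbox(template, pad)
  box3_window(bb$min, bb$max)
}

#' Sample complete spatial randomness in a box
#'
#' Binomial mode places exactly `n` i.i.d. uniform points; Poisson mode draws
#' `N ~ Poisson(lambda |W|)` and places that many uniform points.
#'
#' @param window a `box3_window`
#' @param n_or_lambda point count (binomial) or intensity per unit volume
#'   (poisson)
#' @param mode `"binomial"` or `"poisson"`
#' @param seed integer seed
#' @return n x 3 matrix of points inside the window
#' @export
sample_csr <- function(window, n_or_lambda, mode = c("binomial", "poisson"),
                       seed) {
  stopifnot(inherits(window, "box3_window"), !missing(seed))
  mode <- match.arg(mode)
  if (n_or_lambda < 0)
    ot_stop("negative count/intensity", "bad_parameter")
  with_seed(seed, {
    n <- if (mode == "binomial") as.integer(n_or_lambda)
         else stats::rpois(1L, n_or_lambda * window$volume)
    m <- matrix(stats::runif(3L * n), ncol = 3L)
    as_xyz(sweep(sweep(m, 2, window$max - window$min, "*"), 2, window$min, "+"))
  })
}

#' Sample a Matern cluster process in a box
#'
#' Parents are Poisson(`parent_intensity` |W|) in the window expanded by
#' `radius` (so clusters near the boundary are not thinned); each parent gets
#' a Poisson(`mean_offspring`) number of offspring placed uniformly in the
#' ball of given radius around it; offspring are clipped to the window. Only
#' offspring are returned.
#'
#' @inheritParams sample_csr
#' @param parent_intensity parent intensity per unit volume
#' @param mean_offspring expected offspring per parent
#' @param radius cluster ball radius, mm
#' @return n x 3 matrix of offspring points; parents attached as attribute
#'   `parents`
#' @export
sample_matern <- function(window, parent_intensity, mean_offspring, radius,
                          seed) {
  stopifnot(inherits(window, "box3_window"), !missing(seed))
  if (radius <= 0) ot_stop("radius must be positive", "bad_parameter")
  if (radius > min(window$max - window$min) / 2)
    warning("cluster radius exceeds half the shortest window side; ",
            "edge effects dominate")
  with_seed(seed, {
    ext_min <- window$min - radius
    ext_max <- window$max + radius
    vol_ext <- prod(ext_max - ext_min)
    n_par <- stats::rpois(1L, parent_intensity * vol_ext)
    parents <- matrix(stats::runif(3L * n_par), ncol = 3L)
    parents <- sweep(sweep(parents, 2, ext_max - ext_min, "*"), 2, ext_min, "+")
    n_off <- stats::rpois(n_par, mean_offspring)
    total <- sum(n_off)
    if (total == 0L) {
      out <- matrix(numeric(0), 0L, 3L)
    } else {
      # uniform in a ball: direction uniform on sphere, radius ~ R * U^(1/3)
      u <- matrix(stats::rnorm(3L * total), ncol = 3L)
      u <- u / sqrt(rowSums(u^2))
      rr <- radius * stats::runif(total)^(1 / 3)
      out <- parents[rep.int(seq_len(n_par), n_off), , drop = FALSE] + u * rr
      keep <- out[, 1] >= window$min[1] & out[, 1] <= window$max[1] &
              out[, 2] >= window$min[2] & out[, 2] <= window$max[2] &
              out[, 3] >= window$min[3] & out[, 3] <= window$max[3]
      out <- out[keep, , drop = FALSE]
    }
    out <- as_xyz(out)
    attr(out, "parents") <- parents
    out
  })
}

# von Mises sampler (Best & Fisher 1979 rejection method); kappa = 0 -> uniform
rvonmises <- function(n, mu, kappa) {
  if (kappa < 0) ot_stop("kappa must be >= 0", "bad_parameter")
  if (kappa < 1e-10) return(stats::runif(n, -pi, pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3L)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  out
}

#' Simulate tooth scores with controlled axial orientation
#'
#' Places score midpoints uniformly on the template surface (uniform over the
#' template's points, which are themselves area-uniform on the surface for
#' templates from [make_template()]). Each score's axial angle to the bone's
#' long axis follows a von Mises distribution on doubled angles: axial data
#' live on [0, 180), so the generator samples `phi ~ vM(2 mu, kappa)` and uses
#' `phi / 2`. Endpoints are placed symmetrically about the midpoint along the
#' surface geodesic through the midpoint at that angle (axial offset
#' `h cos(theta)`, circumferential arc `h sin(theta)`), so they stay on the
#' bone surface rather than on a tangent plane.
#'
#' @param template a `bone_template`
#' @param n number of scores (>= 1)
#' @param mean_orientation_deg mean axial angle to the x axis, degrees in
#'   [0, 180)
#' @param kappa von Mises concentration (0 = uniform orientation)
#' @param length_lognormal length-2 vector (meanlog, sdlog) of the lognormal
#'   score length distribution, mm (default ~8 mm median)
#' @param seed integer seed
#' @return data.frame of score marks (canonical mark columns, specimen_id
#'   `"synthetic"`)
#' @export
sample_scores <- function(template, n, mean_orientation_deg = 90, kappa = 2,
                          length_lognormal = c(log(8), 0.4), seed) {
  stopifnot(inherits(template, "bone_template"), n >= 1, !missing(seed))
  if (kappa < 0) ot_stop("kappa must be >= 0", "bad_parameter")
  with_seed(seed, {
    idx <- sample.int(nrow(template$points), n, replace = TRUE)
    mid <- template$points[idx, , drop = FALSE]
    theta <- rvonmises(n, 2 * mean_orientation_deg * pi / 180, kappa) / 2
    theta <- theta %% pi
    len <- stats::rlnorm(n, length_lognormal[1], length_lognormal[2])
    half <- len / 2
    xmin <- min(template$points[, 1])
    L <- template$length
    r0 <- sqrt(mid[, 2]^2 + mid[, 3]^2)
    r0[r0 < 1e-9] <- 1e-9
    phi0 <- atan2(mid[, 3], mid[, 2])
    has_geom <- !is.null(attr(template, "geometry"))
    ep_xyz <- function(sgn) {
      xx <- mid[, 1] + sgn * half * cos(theta)
      tt <- pmin(pmax((xx - xmin) / L, 0), 1)
      rr <- if (has_geom) template_radius(template, tt) else r0
      pp <- phi0 + sgn * half * sin(theta) / r0
      cbind(xx, rr * cos(pp), rr * sin(pp))
    }
    e1 <- ep_xyz(-1)
    e2 <- ep_xyz(+1)
    mid <- (e1 + e2) / 2
    data.frame(mark_id = sprintf("s%06d", seq_len(n)),
               specimen_id = "synthetic", template_id = template$template_id,
               mark_type = "score",
               x = mid[, 1], y = mid[, 2], z = mid[, 3],
               x1 = e1[, 1], y1 = e1[, 2], z1 = e1[, 3],
               x2 = e2[, 1], y2 = e2[, 2], z2 = e2[, 3],
               stringsAsFactors = FALSE)
  })
}

#' Generate a crop set with analytic overlap ground truth
#'
#' Each specimen retains the template points whose normalized x coordinate
#' falls in its `[lo, hi)` interval. The analytic maximum overlap (the
#' interval stabbing number) is attached, so heatmap/MNE code can be tested
#' against a known answer.
#'
#' @param template a `bone_template`
#' @param retained_intervals list of length-2 vectors `c(lo, hi)`, fractions
#'   of the x extent in [0, 1]
#' @param specimen_ids optional ids, default `"spec1"`, `"spec2"`, ...
#' @return list of `crop_mask` objects with attribute `ground_truth_overlap`
#'   (the analytic stabbing number)
#' @export
make_crop_set <- function(template, retained_intervals, specimen_ids = NULL) {
  stopifnot(inherits(template, "bone_template"))
  k <- length(retained_intervals)
  if (is.null(specimen_ids)) specimen_ids <- sprintf("spec%d", seq_len(k))
  masks <- vector("list", k)
  for (i in seq_len(k)) {
    iv <- retained_intervals[[i]]
    if (length(iv) != 2L || iv[1] < 0 || iv[2] > 1 || iv[1] >= iv[2])
      ot_stop("retained intervals must satisfy 0 <= lo < hi <= 1",
              "bad_interval")
    masks[[i]] <- crop_interval(template, "x", iv[1], iv[2],
                                specimen_id = specimen_ids[i])
  }
  # stabbing number: max number of intervals containing a common point;
  # evaluate at all interval endpoints (half-open [lo, hi))
  los <- vapply(retained_intervals, `[`, 0, 1L)
  his <- vapply(retained_intervals, `[`, 0, 2L)
  cand <- sort(unique(los))
  gt <- max(vapply(cand, function(p) sum(los <= p & p < his), 0L))
  attr(masks, "ground_truth_overlap") <- as.integer(gt)
  masks
}
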