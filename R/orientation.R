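# Circular statistics for tooth-score orientations relative to the bone's
# principal longitudinal axis. Scores are axial data (a score has no head or
# tail), so angles live on [0, 180) and all moments and tests operate on
# doubled angles; central orientations are reported as 180-degree-apart
# pairs, matching how rose diagrams of axial data are read.

#' Construct an orientation sample
#' @param angles axial angles in degrees, will be reduced modulo 180
#' @param element,side,context optional grouping metadata
#' @return object of class `orientation_sample`
#' @export
orientation_sample <- function(angles, element = NA_character_,
                               side = NA_character_,
                               context = NA_character_) {
  angles <- as.numeric(angles) %% 180
  structure(list(angles = angles, element = element, side = side,
                 context = context, n = length(angles)),
            class = "orientation_sample")
}

#' @export
print.orientation_sample <- function(x, ...) {
  cat(sprintf("<orientation_sample: n = %d%s>\n", x$n,
              if (!is.na(x$context)) paste0(", ", x$context) else ""))
  invisible(x)
}

#' Axial angle between a score and the bone's longitudinal axis
#'
#' The angle between the endpoint difference vector and the axis, treated
#' axially (theta and theta + 180 are the same score): computed as
#' `acos(|d . a| / |d|)` and mapped to [0, 180) with a signed in-plane
#' convention, so left- and right-leaning scores remain distinct (45 vs 135
#' degrees). The sign comes from the perpendicular component of the score
#' relative to `ref` (default: the canonical medio-lateral y axis); under a
#' joint rigid rotation of scores, axis and reference the angle is invariant,
#' as is swapping a score's endpoints.
#'
#' @param mark one-row mark data.frame with endpoint columns (a linear mark),
#'   a multi-row mark data.frame (vectorized), or a 2 x 3 matrix of endpoints
#' @param axis unit length-3 axis vector (e.g. [principal_axis()])
#' @param ref reference direction fixing the in-plane sign; must not be
#'   parallel to `axis`
#' @return angle in degrees in [0, 180)
#' @export
score_angle <- function(mark, axis, ref = c(0, 1, 0)) {
  if (is.data.frame(mark)) {
    if (nrow(mark) != 1L) {
      return(vapply(seq_len(nrow(mark)),
                    function(i) score_angle(mark[i, ], axis, ref), 0))
    }
    if (!mark$mark_type %in% LINEAR_TYPES || is.na(mark$x1))
      ot_stop("punctual mark has no orientation", "not_linear")
    d <- c(mark$x2 - mark$x1, mark$y2 - mark$y1, mark$z2 - mark$z1)
  } else {
    ep <- as_xyz(mark, "endpoints")
    d <- ep[2, ] - ep[1, ]
  }
  nd <- sqrt(sum(d^2))
  if (nd < 1e-12) ot_stop("degenerate segment", "degenerate_segment")
  axis <- axis / sqrt(sum(axis^2))
  cosang <- min(abs(sum(d * axis)) / nd, 1)
  ang <- acos(cosang) * 180 / pi
  # axial fold: orient d along +axis, then sign the in-plane part against the
  # reference frame (ref projected off the axis, completed right-handedly)
  if (sum(d * axis) < 0) d <- -d
  perp <- d - sum(d * axis) * axis
  if (sqrt(sum(perp^2)) > 1e-12) {
    r_perp <- ref - sum(ref * axis) * axis
    nr <- sqrt(sum(r_perp^2))
    if (nr < 1e-12)
      ot_stop("reference direction is parallel to the axis", "bad_parameter")
    r_perp <- r_perp / nr
    s <- sum(perp * r_perp)
    if (abs(s) < 1e-12) {
      t3 <- c(axis[2] * r_perp[3] - axis[3] * r_perp[2],
              axis[3] * r_perp[1] - axis[1] * r_perp[3],
              axis[1] * r_perp[2] - axis[2] * r_perp[1])
      s <- sum(perp * t3)
    }
    if (s < 0) ang <- 180 - ang
  }
  ang %% 180
}

#' Circular moments of an axial orientation sample
#'
#' All quantities are computed on doubled angles `theta = 2 phi` (axial
#' convention): mean resultant length `Rbar`, circular variance `V = 1 -
#' Rbar`, circular dispersion `delta = (1 - rho2) / (2 Rbar^2)`, standardized
#' skewness `b = rho2 sin(mu2 - 2 mu) / (1 - Rbar)^(3/2)` and standardized
#' kurtosis `k = (rho2 cos(mu2 - 2 mu) - Rbar^4) / (1 - Rbar)^2` (Fisher's
#' definitions), where `rho2, mu2` are the second trigonometric moment. The
#' central orientation is `mu / 2` on the axial scale, reported as the pair
#' `(mu/2, mu/2 - 180)` degrees.
#'
#' @param sample an `orientation_sample` (or numeric axial angles, degrees)
#' @return object of class `circular_summary`; when `Rbar == 1` the
#'   dispersion, skewness and kurtosis are undefined and reported as `NA`
#' @export
circular_summary <- function(sample) {
  if (!inherits(sample, "orientation_sample"))
    sample <- orientation_sample(sample)
  if (sample$n < 2L) ot_stop("need at least 2 angles", "too_few_points")
  th <- 2 * sample$angles * pi / 180
  C1 <- mean(cos(th)); S1 <- mean(sin(th))
  C2 <- mean(cos(2 * th)); S2 <- mean(sin(2 * th))
  Rbar <- sqrt(C1^2 + S1^2)
  mu <- atan2(S1, C1)
  rho2 <- sqrt(C2^2 + S2^2)
  mu2 <- atan2(S2, C2)
  V <- 1 - Rbar
  degenerate <- V < 1e-12
  disp <- if (degenerate) NA_real_ else (1 - rho2) / (2 * Rbar^2)
  skew <- if (degenerate) NA_real_ else
    rho2 * sin(mu2 - 2 * mu) / (1 - Rbar)^1.5
  kurt <- if (degenerate) NA_real_ else
    (rho2 * cos(mu2 - 2 * mu) - Rbar^4) / (1 - Rbar)^2
  wrap180 <- function(x) ((x + 180) %% 360) - 180
  central_deg <- (mu / 2) * 180 / pi
  central_pair <- c(central_deg, wrap180(central_deg - 180))
  structure(list(Rbar = Rbar, variance = V, dispersion = disp,
                 skewness = skew, kurtosis = kurt,
                 central_deg = central_pair,
                 central_rad = central_pair * pi / 180, n = sample$n),
            class = "circular_summary")
}

#' @export
print.circular_summary <- function(x, ...) {
  cat(sprintf(paste0("<circular_summary: n = %d, Rbar = %.4f, V = %.4f, ",
                     "central %.1f/%.1f deg>\n"),
              x$n, x$Rbar, x$variance, x$central_deg[1], x$central_deg[2]))
  invisible(x)
}

new_test_result <- function(method, statistic, p, n, n_rand = NA_integer_,
                            seed = NA_integer_, inputs = list()) {
  structure(list(method = method, statistic = statistic,
                 p = min(max(p, 0), 1), n = n, n_rand = n_rand, seed = seed,
                 inputs = inputs),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result %s: statistic = %.4g, p = %.3g, n = %s>\n",
              x$method, x$statistic, x$p, x$n))
  invisible(x)
}

#' Rayleigh uniformity test for axial orientations
#'
#' Tests uniformity of the (doubled) angles against a unimodal alternative.
#' With `Z = n Rbar^2`, the tail probability uses the series approximation
#' `p = exp(-Z) [1 + (2Z - Z^2)/(4n) - (24Z - 132Z^2 + 76Z^3 - 9Z^4)/(288
#' n^2)]` clipped to [0, 1]. The series bracket turns negative for very large
#' Z (the expansion diverges), in which case the leading term `exp(-Z)` is
#' used. The reported statistic is `Rbar`.
#'
#' @param sample an `orientation_sample`, or `NULL` when `Rbar` and `n` are
#'   given directly
#' @param Rbar mean resultant length in [0, 1] (direct mode)
#' @param n sample size (>= 4)
#' @return a `test_result` (`statistic` = Rbar)
#' @export
rayleigh_test <- function(sample = NULL, Rbar = NULL, n = NULL) {
  if (!is.null(sample)) {
    if (!inherits(sample, "orientation_sample"))
      sample <- orientation_sample(sample)
    cs <- circular_summary(sample)
    Rbar <- cs$Rbar
    n <- sample$n
  }
  if (is.null(Rbar) || is.null(n))
    ot_stop("supply a sample or both Rbar and n", "bad_parameter")
  if (Rbar < 0 || Rbar > 1) ot_stop("Rbar must be in [0, 1]", "bad_parameter")
  if (n < 4) ot_stop("need n >= 4", "too_few_points")
  Z <- n * Rbar^2
  bracket <- 1 + (2 * Z - Z^2) / (4 * n) -
    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2)
  p <- if (bracket > 0) exp(-Z) * bracket else exp(-Z)
  new_test_result("rayleigh", Rbar, p, n, inputs = list(Z = Z))
}

#' Randomized Mardia-Watson-Wheeler test for two axial samples
#'
#' Nonparametric comparison of two circular samples via uniform scores: the
#' pooled doubled angles are ranked (midranks under ties, with a warning),
#' mapped to `beta = 2 pi rank / N`, and
#' `W = 2 sum_g (C_g^2 + S_g^2) / n_g` where `C_g, S_g` are the group sums of
#' `cos(beta), sin(beta)`. The p-value is the permutation tail probability
#' over `n_rand` random relabellings, with plus-one correction.
#'
#' @param a,b `orientation_sample`s (or numeric axial angles, degrees), each
#'   with n >= 4
#' @param n_rand number of permutations (default 9999)
#' @param seed integer seed
#' @return a `test_result` (`statistic` = W)
#' @export
mww_test <- function(a, b, n_rand = 9999L, seed) {
  stopifnot(!missing(seed))
  if (!inherits(a, "orientation_sample")) a <- orientation_sample(a)
  if (!inherits(b, "orientation_sample")) b <- orientation_sample(b)
  if (a$n < 4 || b$n < 4) ot_stop("each sample needs n >= 4", "too_few_points")
  th <- c(2 * a$angles, 2 * b$angles) %% 360
  N <- length(th)
  if (anyDuplicated(round(th, 10)))
    warning("ties in pooled angles: using midranks")
  rk <- rank(th, ties.method = "average")
  beta <- 2 * pi * rk / N
  cb <- cos(beta); sb <- sin(beta)
  grp <- rep(c(TRUE, FALSE), c(a$n, b$n))
  wstat <- function(g) {
    C1 <- sum(cb[g]); S1 <- sum(sb[g])
    C2 <- sum(cb[!g]); S2 <- sum(sb[!g])
    2 * ((C1^2 + S1^2) / a$n + (C2^2 + S2^2) / b$n)
  }
  W <- wstat(grp)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_rand), function(i)
      wstat(sample(grp)) >= W, TRUE))
  })
  p <- (exceed + 1) / (n_rand + 1)
  new_test_result("mww", W, p, c(a$n, b$n), n_rand = as.integer(n_rand),
                  seed = seed)
}

#' False positive risk from a p-value
#'
#' Sellke-Bayarri-Berger minimum Bayes factor bound `BF = -e p log(p)`
#' (valid for `p < 1/e`), converted to the posterior probability that a
#' rejection is a false positive under a prior probability `prior_h1` that
#' the alternative is true:
#' `FPR = (1 - prior) BF / ((1 - prior) BF + prior)`.
#'
#' @param p p-value in (0, 1/e)
#' @param prior_h1 prior probability of the alternative (default 0.5)
#' @return a `test_result` (`statistic` = the Bayes factor bound, `p` = FPR)
#' @export
false_positive_risk <- function(p, prior_h1 = 0.5) {
  if (p <= 0 || p >= 1) ot_stop("p must be in (0, 1)", "bad_parameter")
  if (p >= exp(-1))
    ot_stop("bound not informative: p >= 1/e", "bound_not_informative")
  if (prior_h1 <= 0 || prior_h1 >= 1)
    ot_stop("prior_h1 must be in (0, 1)", "bad_parameter")
  BF <- -exp(1) * p * log(p)
  fpr <- (1 - prior_h1) * BF / ((1 - prior_h1) * BF + prior_h1)
  new_test_result("fpr", BF, fpr, NA_integer_,
                  inputs = list(p = p, prior_h1 = prior_h1))
}

#' Rose diagram sector counts for axial data
#'
#' Each axial angle contributes to the sector containing `theta` and to the
#' one containing `theta + 180`, so the counts over [0, 360) sum to `2n`.
#'
#' @param sample an `orientation_sample` (or numeric axial angles, degrees)
#' @param n_sectors number of equal sectors over [0, 360), default 36
#' @return data.frame with `sector_start`, `sector_end` (degrees) and `count`
#' @export
rose_histogram <- function(sample, n_sectors = 36L) {
  if (!inherits(sample, "orientation_sample"))
    sample <- orientation_sample(sample)
  if (sample$n < 1L) ot_stop("need at least 1 angle", "too_few_points")
  ang <- c(sample$angles, sample$angles + 180) %% 360
  width <- 360 / n_sectors
  k <- pmin(floor(ang / width), n_sectors - 1L)
  counts <- tabulate(k + 1L, nbins = n_sectors)
  data.frame(sector_start = (seq_len(n_sectors) - 1L) * width,
             sector_end = seq_len(n_sectors) * width, count = counts)
}

#' Orientation summary table for grouped scores (one row per group)
#'
#' Mirrors the classical reporting layout: skewness, kurtosis, circular
#' variance, circular dispersion, central orientation pair, mean resultant
#' length and Rayleigh p per (context, element, side) group of scores.
#'
#' @param marks data.frame of score marks with grouping columns `context`,
#'   `element`, `side` attached (or a list of `orientation_sample`s)
#' @param axis unit axis vector used for [score_angle()] (mark-table input)
#' @return data.frame, one row per group
#' @export
orientation_report <- function(marks, axis = c(1, 0, 0)) {
  groups <- if (is.data.frame(marks)) {
    key <- interaction(marks$context %||% "all", marks$element %||% "all",
                       marks$side %||% "all", drop = TRUE)
    lapply(split(marks, key), function(df)
      orientation_sample(score_angle(df, axis),
                         element = df$element[1] %||% NA_character_,
                         side = df$side[1] %||% NA_character_,
                         context = df$context[1] %||% NA_character_))
  } else marks
  rows <- lapply(groups, function(s) {
    cs <- circular_summary(s)
    rt <- rayleigh_test(s)
    data.frame(context = s$context, element = s$element, side = s$side,
               n = s$n, skewness = cs$skewness, kurtosis = cs$kurtosis,
               circular_variance = cs$variance,
               circular_dispersion = cs$dispersion,
               central_deg_1 = cs$central_deg[1],
               central_deg_2 = cs$central_deg[2],
               Rbar = cs$Rbar, rayleigh_p = rt$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
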