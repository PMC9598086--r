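# 3D second-order summary statistics for point patterns in a box window:
# Ripley K, nearest-neighbour G, empty-space F, pair correlation g, their
# square-root transforms, and Monte Carlo CSR envelopes.
#
# Estimators (stated explicitly because the classical references name the
# functions, not the estimators):
#   K:   translation edge correction, e_ij = |W| / prod_k (L_k - |dx_k|),
#        Khat(r) = |W|/(n(n-1)) * sum_{i!=j} 1{d_ij <= r} e_ij
#   G:   border correction (reduced sample) or Kaplan-Meier with the
#        boundary distance as censoring time
#   F:   empty-space distances from a regular lattice of test locations,
#        border corrected as G
#   pcf: Epanechnikov kernel, translation weights, Stoyan's bandwidth
#        h = 0.26 * lambda^(-1/3)
# lambda^2 is estimated by n(n-1)/|W|^2 (unbiased for binomial patterns).

check_points_window <- function(points, window, min_n = 2L) {
  points <- as_xyz(points)
  stopifnot(inherits(window, "box3_window"))
  n <- nrow(points)
  if (n < min_n)
    ot_stop(sprintf("needs >= %d points", min_n), "too_few_points")
  if (n > 0) {
    inside <- points[, 1] >= window$min[1] & points[, 1] <= window$max[1] &
              points[, 2] >= window$min[2] & points[, 2] <= window$max[2] &
              points[, 3] >= window$min[3] & points[, 3] <= window$max[3]
    if (!all(inside))
      ot_stop("point outside window", "point_outside_window")
  }
  points
}

#' Default r grid for a window: 128 values from 0 to shortest side / 4
#' @param window a `box3_window`
#' @param n_r number of grid values
#' @export
default_r_grid <- function(window, n_r = 128L) {
  seq(0, min(window$max - window$min) / 4, length.out = n_r)
}

new_fe <- function(fun, r, est, theo, correction, n_points, window) {
  structure(list(fun = fun, r = r, est = est, theoretical = theo,
                 correction = correction, n_points = n_points,
                 sqrt_applied = FALSE, window = window),
            class = "function_estimate")
}

#' @export
print.function_estimate <- function(x, ...) {
  cat(sprintf("<function_estimate %s%s: %d r values, n = %d, correction = %s>\n",
              x$fun, if (x$sqrt_applied) " (sqrt)" else "", length(x$r),
              x$n_points, x$correction))
  invisible(x)
}

# pairwise distances and translation-correction weights for ordered pairs
pairwise_translation <- function(points, window) {
  n <- nrow(points)
  L <- window$max - window$min
  ii <- rep(seq_len(n), each = n)
  jj <- rep(seq_len(n), times = n)
  keep <- ii != jj
  ii <- ii[keep]; jj <- jj[keep]
  dx <- abs(points[ii, 1] - points[jj, 1])
  dy <- abs(points[ii, 2] - points[jj, 2])
  dz <- abs(points[ii, 3] - points[jj, 3])
  d <- sqrt(dx^2 + dy^2 + dz^2)
  w <- window$volume / ((L[1] - dx) * (L[2] - dy) * (L[3] - dz))
  list(d = d, w = w)
}

#' 3D Ripley K function with translation edge correction
#'
#' Cumulative count of further points within distance r of a typical point,
#' scaled by intensity. Under complete spatial randomness
#' `K(r) = (4/3) pi r^3`.
#'
#' @param points n x 3 matrix of mark coordinates, mm
#' @param window a `box3_window` containing all points
#' @param r_grid increasing vector of distances (default [default_r_grid()])
#' @return a `function_estimate`
#' @export
k3est <- function(points, window, r_grid = default_r_grid(window)) {
  points <- check_points_window(points, window, 2L)
  n <- nrow(points)
  pw <- pairwise_translation(points, window)
  ord <- order(pw$d)
  dsort <- pw$d[ord]
  wcum <- cumsum(pw$w[ord])
  idx <- findInterval(r_grid, dsort)
  est <- window$volume / (n * (n - 1)) * ifelse(idx > 0, wcum[pmax(idx, 1L)], 0)
  new_fe("K", r_grid, est, 4 / 3 * pi * r_grid^3, "translation", n, window)
}

boundary_distance <- function(points, window) {
  pmin(points[, 1] - window$min[1], window$max[1] - points[, 1],
       points[, 2] - window$min[2], window$max[2] - points[, 2],
       points[, 3] - window$min[3], window$max[3] - points[, 3])
}

# shared reduced-sample / Kaplan-Meier machinery for G and F
edf_censored <- function(d, b, r_grid, correction) {
  if (correction == "border") {
    est <- vapply(r_grid, function(r) {
      denom <- sum(b > r)
      if (denom == 0L) return(NA_real_)
      sum(d <= r & b > r) / denom
    }, 0)
  } else {
    # Kaplan-Meier: observe o = min(d, b), event = (d <= b);
    # Ghat(r) = 1 - prod_{o_i <= r, event} (1 - 1 / Y(o_i))
    o <- pmin(d, b)
    event <- d <= b
    ord <- order(o)
    o <- o[ord]; event <- event[ord]
    nn <- length(o)
    atrisk <- nn - seq_len(nn) + 1L
    surv <- cumprod(ifelse(event, 1 - 1 / atrisk, 1))
    idx <- findInterval(r_grid, o)
    est <- 1 - ifelse(idx > 0, surv[pmax(idx, 1L)], 1)
  }
  est
}

#' 3D nearest-neighbour distance function G
#'
#' Distribution function of the distance from a typical point of the pattern
#' to its nearest neighbour. Under CSR
#' `G(r) = 1 - exp(-lambda (4/3) pi r^3)`.
#'
#' @inheritParams k3est
#' @param correction `"border"` (reduced sample) or `"km"` (Kaplan-Meier with
#'   boundary distances as censoring times)
#' @return a `function_estimate`; r values whose border denominator is zero
#'   are reported as `NA`
#' @export
g3est <- function(points, window, r_grid = default_r_grid(window),
                  correction = c("border", "km")) {
  correction <- match.arg(correction)
  points <- check_points_window(points, window, 2L)
  n <- nrow(points)
  d2 <- as.matrix(stats::dist(points))^2
  diag(d2) <- Inf
  d <- sqrt(apply(d2, 1L, min))
  b <- boundary_distance(points, window)
  est <- edf_censored(d, b, r_grid, correction)
  lam <- n / window$volume
  new_fe("G", r_grid, est, 1 - exp(-lam * 4 / 3 * pi * r_grid^3),
         correction, n, window)
}

#' 3D empty-space function F
#'
#' Distribution function of the distance from a typical location of the
#' window to the nearest point of the pattern, estimated from a regular
#' lattice of test locations. Under CSR
#' `F(r) = 1 - exp(-lambda (4/3) pi r^3)`. An empty pattern gives `F == 0`.
#'
#' @inheritParams g3est
#' @param grid_spacing lattice spacing, mm (default shortest window side / 32)
#' @return a `function_estimate`
#' @export
f3est <- function(points, window, r_grid = default_r_grid(window),
                  grid_spacing = min(window$max - window$min) / 32,
                  correction = c("border", "km")) {
  correction <- match.arg(correction)
  points <- check_points_window(points, window, 0L)
  gr <- lapply(1:3, function(k)
    seq(window$min[k] + grid_spacing / 2, window$max[k] - grid_spacing / 2,
        by = grid_spacing))
  test <- as.matrix(expand.grid(gr[[1]], gr[[2]], gr[[3]]))
  m <- nrow(test)
  if (nrow(points) == 0L) {
    d <- rep(Inf, m)
  } else {
    d2 <- rep(Inf, m)
    for (i in seq_len(nrow(points)))
      d2 <- pmin(d2, (test[, 1] - points[i, 1])^2 +
                     (test[, 2] - points[i, 2])^2 +
                     (test[, 3] - points[i, 3])^2)
    d <- sqrt(d2)
  }
  b <- boundary_distance(test, window)
  est <- edf_censored(d, b, r_grid, correction)
  lam <- nrow(points) / window$volume
  new_fe("F", r_grid, est, 1 - exp(-lam * 4 / 3 * pi * r_grid^3),
         correction, nrow(points), window)
}

#' 3D pair correlation function
#'
#' Kernel estimate of the ring density `g(r)` (1 under CSR, > 1 at distances
#' where points aggregate). Uses the Epanechnikov kernel with Stoyan's
#' bandwidth `h = 0.26 lambda^(-1/3)` and translation edge correction.
#'
#' @inheritParams k3est
#' @param bandwidth kernel half-width h, mm; default Stoyan's rule
#' @return a `function_estimate`
#' @export
pcf3est <- function(points, window, r_grid = default_r_grid(window)[-1],
                    bandwidth = NULL) {
  points <- check_points_window(points, window, 2L)
  if (any(r_grid <= 0))
    ot_stop("pcf r grid must exclude 0", "bad_r_grid")
  n <- nrow(points)
  lam <- n / window$volume
  h <- bandwidth %||% (0.26 * lam^(-1 / 3))
  pw <- pairwise_translation(points, window)
  est <- vapply(r_grid, function(r) {
    u <- (r - pw$d) / h
    k <- ifelse(abs(u) < 1, 0.75 * (1 - u^2) / h, 0)
    window$volume / (n * (n - 1)) * sum(k * pw$w) / (4 * pi * r^2)
  }, 0)
  fe <- new_fe("pcf", r_grid, est, rep(1, length(r_grid)), "translation", n,
               window)
  fe$bandwidth <- h
  fe
}

#' Square-root transform of a cumulative summary function
#'
#' Applies an element-wise square root to the estimate and its theoretical
#' reference, a variance-stabilising device for K, F and G. Not defined for
#' the pair correlation function, and cannot be applied twice.
#'
#' @param fe a `function_estimate` with `fun` in K, F, G
#' @return the transformed `function_estimate` (`sqrt_applied = TRUE`)
#' @export
sqrt_version <- function(fe) {
  stopifnot(inherits(fe, "function_estimate"))
  if (!fe$fun %in% c("K", "F", "G"))
    ot_stop("sqrt transform applies to K, F and G only", "bad_function")
  if (fe$sqrt_applied)
    ot_stop("sqrt transform already applied", "double_sqrt")
  fe$est <- sqrt(fe$est)
  fe$theoretical <- sqrt(fe$theoretical)
  fe$sqrt_applied <- TRUE
  fe
}

estimate_fun <- function(fun, points, window, r_grid, ...) {
  switch(fun,
         K = k3est(points, window, r_grid),
         G = g3est(points, window, r_grid, ...),
         F = f3est(points, window, r_grid, ...),
         pcf = pcf3est(points, window, r_grid, ...))
}

#' Monte Carlo CSR envelope for a summary function
#'
#' Simulates `nsim` binomial CSR patterns with the observed number of points
#' in the same window, evaluates the chosen summary function on each, and
#' returns the rank-th smallest/largest simulated values pointwise. With
#' `rank = 1` the two-sided pointwise exceedance probability at a fixed r is
#' `2 rank / (nsim + 1)`.
#'
#' @inheritParams k3est
#' @param fun `"K"`, `"F"`, `"G"` or `"pcf"`
#' @param nsim number of CSR simulations (>= 3; classical default 500)
#' @param rank envelope rank
#' @param seed integer seed
#' @param sqrt_transform apply [sqrt_version()] to observed and simulated
#'   curves (K, F, G only)
#' @param ... passed to the estimator (e.g. `correction`)
#' @return object of class `envelope_result` with the observed
#'   `function_estimate` and `lo`/`hi` curves
#' @export
csr_envelope <- function(points, window, fun = c("K", "F", "G", "pcf"),
                         nsim = 500L, rank = 1L, seed,
                         r_grid = NULL, sqrt_transform = FALSE, ...) {
  fun <- match.arg(fun)
  stopifnot(!missing(seed))
  if (nsim < 3L) ot_stop("nsim must be >= 3", "bad_parameter")
  if (rank < 1L || 2L * rank > nsim)
    ot_stop("rank must satisfy 1 <= 2*rank <= nsim", "bad_parameter")
  points <- as_xyz(points)
  if (is.null(r_grid)) {
    r_grid <- default_r_grid(window)
    if (fun == "pcf") r_grid <- r_grid[-1]
  }
  n <- nrow(points)
  obs <- estimate_fun(fun, points, window, r_grid, ...)
  if (sqrt_transform) obs <- sqrt_version(obs)
  sims <- with_seed(seed, {
    vapply(seq_len(nsim), function(i) {
      p <- matrix(stats::runif(3L * n), ncol = 3L)
      p <- sweep(sweep(p, 2, window$max - window$min, "*"), 2, window$min, "+")
      fe <- estimate_fun(fun, p, window, r_grid, ...)
      if (sqrt_transform) fe <- sqrt_version(fe)
      fe$est
    }, numeric(length(r_grid)))
  })
  if (is.null(dim(sims))) sims <- matrix(sims, nrow = length(r_grid))
  lo <- apply(sims, 1L, function(v) sort(v, na.last = TRUE)[rank])
  hi <- apply(sims, 1L, function(v) sort(v, decreasing = TRUE, na.last = TRUE)[rank])
  structure(list(observed = obs, lo = lo, hi = hi, nsim = nsim,
                 rank = rank, seed = seed),
            class = "envelope_result")
}

#' @export
print.envelope_result <- function(x, ...) {
  cat(sprintf("<envelope_result %s: nsim = %d, rank = %d>\n",
              x$observed$fun, x$nsim, x$rank))
  invisible(x)
}

#' @export
plot.envelope_result <- function(x, ...) {
  r <- x$observed$r
  yl <- range(c(x$lo, x$hi, x$observed$est, x$observed$theoretical),
              na.rm = TRUE)
  graphics::plot(r, x$observed$est, type = "n", ylim = yl, xlab = "r (mm)",
                 ylab = x$observed$fun, ...)
  graphics::polygon(c(r, rev(r)), c(x$lo, rev(x$hi)), col = "grey85",
                    border = NA)
  graphics::lines(r, x$observed$theoretical, col = "red", lty = 2)
  graphics::lines(r, x$observed$est, col = "black")
  invisible(x)
}

#' Write a function estimate or envelope to CSV (r, observed, theoretical, lo, hi)
#' @param x a `function_estimate` or `envelope_result`
#' @param path output path
#' @export
write_function_csv <- function(x, path) {
  if (inherits(x, "envelope_result")) {
    df <- data.frame(r = x$observed$r, observed = x$observed$est,
                     theoretical = x$observed$theoretical, lo = x$lo, hi = x$hi)
  } else {
    df <- data.frame(r = x$r, observed = x$est, theoretical = x$theoretical,
                     lo = NA_real_, hi = NA_real_)
  }
  num <- vapply(df, is.numeric, TRUE)
  for (j in which(num)) df[[j]] <- ifelse(is.na(df[[j]]), "", fmt_num(df[[j]]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
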