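# Bivariate wavelet coherence of two axial mark-intensity profiles.
#
# Continuous Morlet transform (omega0 = 6) on dyadic scales (s0 = 2 dt,
# dj = 1/12, scales truncated at one third of the series length), coherence
# R^2(s, t) = |S(W_ab / s)|^2 / (S(|W_a|^2 / s) S(|W_b|^2 / s)) with Gaussian
# time-smoothing of width proportional to the scale and boxcar smoothing over
# 0.6/dj adjacent scales (the Morlet decorrelation length). Significance is
# assessed against AR(1) surrogate pairs matching each series' lag-1
# autocorrelation; the phase of the smoothed cross-spectrum gives lead/lag.

morlet_omega0 <- 6

# continuous wavelet transform, Torrence & Compo normalization; dt = 1
cwt_morlet <- function(x, scales) {
  n <- length(x)
  npad <- 2^ceiling(log2(n))
  xp <- c(x - mean(x), rep(0, npad - n))
  omega <- 2 * pi * c(0:(npad / 2), -((npad / 2 - 1):1)) / npad
  fx <- stats::fft(xp)
  W <- matrix(0i, length(scales), n)
  for (si in seq_along(scales)) {
    s <- scales[si]
    psi <- sqrt(2 * pi * s) * pi^(-0.25) *
      exp(-0.5 * (s * omega - morlet_omega0)^2) * (omega > 0)
    W[si, ] <- stats::fft(fx * psi, inverse = TRUE)[1:n] / npad
  }
  W
}

# Precompute the smoothing operators for a given scale set and series
# length: per-scale Gaussian time-smoothing matrices (edge-renormalized) and
# a boxcar scale-smoothing matrix over 0.6/dj adjacent scales. Building these
# once per coherence call makes the surrogate loop cheap.
make_smoothing_plan <- function(scales, n, dj) {
  tmats <- lapply(scales, function(s) {
    d <- outer(seq_len(n), seq_len(n), `-`)
    W <- exp(-d^2 / (2 * s^2))
    t(W / rowSums(W))  # column t sums to 1: proper edge renormalization
  })
  ns <- length(scales)
  win <- max(1L, round(0.6 / dj))
  half <- floor(win / 2)
  smat <- matrix(0, ns, ns)
  for (si in seq_len(ns)) {
    lo <- max(1L, si - half)
    hi <- min(ns, si + half)
    smat[si, lo:hi] <- 1 / (hi - lo + 1L)
  }
  list(tmats = tmats, smat = smat)
}

# Gaussian time smoothing (width ~ scale) applied row-wise, then boxcar
# smoothing across scales
smooth_field <- function(M, plan) {
  out <- M
  for (si in seq_len(nrow(M)))
    out[si, ] <- M[si, ] %*% plan$tmats[[si]]
  plan$smat %*% out
}

lag1_autocor <- function(x) {
  x <- x - mean(x)
  r <- sum(x[-1] * x[-length(x)]) / sum(x^2)
  max(min(r, 0.99), -0.99)
}

ar1_surrogate <- function(n, rho) {
  innov <- stats::rnorm(n + 50L)
  x <- stats::filter(innov, rho, method = "recursive")
  as.numeric(x[(50L + 1L):(50L + n)])
}

coherence_core <- function(a, b, scales, plan) {
  Wa <- cwt_morlet(a, scales)
  Wb <- cwt_morlet(b, scales)
  inv_s <- 1 / scales
  Sa <- smooth_field(Re(Wa * Conj(Wa)) * inv_s, plan)
  Sb <- smooth_field(Re(Wb * Conj(Wb)) * inv_s, plan)
  Wab <- Wa * Conj(Wb) * inv_s
  Sab_re <- smooth_field(Re(Wab), plan)
  Sab_im <- smooth_field(Im(Wab), plan)
  coh <- (Sab_re^2 + Sab_im^2) / (Sa * Sb)
  list(coherence = pmin(coh, 1), phase = atan2(Sab_im, Sab_re))
}

#' Bivariate Morlet wavelet coherence of two series profiles
#'
#' Scale-resolved squared correlation between two mark-intensity profiles,
#' with phase (lead/lag) and a pointwise significance mask from AR(1)
#' surrogate pairs.
#'
#' @param a,b `series_profile`s (or numeric vectors) of equal length >= 16
#' @param nrands number of AR(1) surrogate pairs for the significance mask
#'   (classical default 10000; reduce for quick runs). `nrands = 0` skips the
#'   significance computation.
#' @param seed integer seed for the surrogates
#' @param dj scale resolution in octaves (default 1/12)
#' @param alpha significance level (default 0.05)
#' @return object of class `coherence_map`: `coherence` and `phase` matrices
#'   (scales x positions), `scales`, `positions`, `coi` (cone of influence,
#'   maximum trustworthy scale per position), `significant` logical matrix,
#'   `nrands`, `seed`
#' @export
wavelet_coherence <- function(a, b, nrands = 10000L, seed, dj = 1 / 12,
                              alpha = 0.05) {
  xa <- if (inherits(a, "series_profile")) as.numeric(a$counts) else as.numeric(a)
  xb <- if (inherits(b, "series_profile")) as.numeric(b$counts) else as.numeric(b)
  if (length(xa) != length(xb))
    ot_stop("series must have equal length", "bad_parameter")
  n <- length(xa)
  if (n < 16L) ot_stop("series too short (need >= 16 units)", "bad_parameter")
  if (stats::sd(xa) == 0 || stats::sd(xb) == 0)
    ot_stop("zero variance: constant series", "zero_variance")
  if (nrands > 0L && missing(seed))
    ot_stop("seed is required when nrands > 0", "bad_parameter")
  xa <- (xa - mean(xa)) / stats::sd(xa)
  xb <- (xb - mean(xb)) / stats::sd(xb)
  s0 <- 2
  smax <- n / 3
  J <- floor(log2(smax / s0) / dj)
  if (J < 1L) ot_stop("series too short for the scale range", "bad_parameter")
  scales <- s0 * 2^(dj * (0:J))
  plan <- make_smoothing_plan(scales, n, dj)
  cc <- coherence_core(xa, xb, scales, plan)
  # cone of influence: e-folding time of the Morlet wavelet is sqrt(2) s,
  # so at distance e from the nearest edge scales above e/sqrt(2) are edge-
  # affected
  edge_dist <- pmin(seq_len(n) - 1L, n - seq_len(n))
  coi <- pmax(edge_dist, 1e-9) / sqrt(2)
  significant <- NULL
  thresholds <- NULL
  if (nrands > 0L) {
    r1a <- lag1_autocor(xa)
    r1b <- lag1_autocor(xb)
    sim_max <- with_seed(seed, {
      vals <- array(NA_real_, c(length(scales), n, nrands))
      for (k in seq_len(nrands)) {
        sa <- ar1_surrogate(n, r1a)
        sb <- ar1_surrogate(n, r1b)
        if (stats::sd(sa) == 0 || stats::sd(sb) == 0) next
        vals[, , k] <- coherence_core(sa, sb, scales, plan)$coherence
      }
      vals
    })
    # per-scale null distribution pooled over positions and surrogates
    thresholds <- apply(sim_max, 1L, function(m)
      stats::quantile(as.vector(m), 1 - alpha, na.rm = TRUE))
    significant <- sweep(cc$coherence, 1L, thresholds, ">")
  }
  structure(list(coherence = cc$coherence, phase = cc$phase, scales = scales,
                 positions = seq_len(n), coi = coi,
                 significant = significant, thresholds = thresholds,
                 nrands = nrands,
                 seed = if (nrands > 0L) seed else NA_integer_,
                 dj = dj, alpha = alpha),
            class = "coherence_map")
}

#' @export
print.coherence_map <- function(x, ...) {
  cat(sprintf("<coherence_map: %d scales x %d positions, nrands = %d>\n",
              length(x$scales), length(x$positions), x$nrands))
  invisible(x)
}

#' Logical matrix of cells inside the cone of influence
#' @param map a `coherence_map`
#' @export
inside_coi <- function(map) {
  outer(map$scales, map$coi, "<=")
}

#' Down-sampled phase arrow field
#'
#' Arrows encode the lead/lag relation: angle 0 (right) = in phase, pi
#' (left) = anti-phase; intermediate angles indicate one series leading the
#' other (positive phase: the first series leads).
#'
#' @param map a `coherence_map`
#' @param stride keep every `stride`-th position and scale
#' @param min_coherence only emit arrows where coherence exceeds this value
#' @return data.frame with `position`, `scale`, `angle` (radians)
#' @export
phase_arrows <- function(map, stride = 4L, min_coherence = 0) {
  si <- seq(1L, length(map$scales), by = stride)
  ti <- seq(1L, length(map$positions), by = stride)
  grid <- expand.grid(s = si, t = ti)
  keep <- map$coherence[cbind(grid$s, grid$t)] >= min_coherence
  grid <- grid[keep, , drop = FALSE]
  data.frame(position = map$positions[grid$t], scale = map$scales[grid$s],
             angle = map$phase[cbind(grid$s, grid$t)])
}

#' Write coherence matrices to CSV
#' @param map a `coherence_map`
#' @param path_prefix files `<prefix>_coherence.csv` and `<prefix>_phase.csv`
#'   are written with scales as rows and positions as columns
#' @export
write_coherence_csv <- function(map, path_prefix) {
  wr <- function(m, suffix) {
    df <- data.frame(scale = fmt_num(map$scales),
                     matrix(fmt_num(m), nrow = nrow(m)))
    names(df)[-1] <- sprintf("u%d", map$positions)
    utils::write.csv(df, paste0(path_prefix, "_", suffix, ".csv"),
                     row.names = FALSE, quote = FALSE)
  }
  wr(map$coherence, "coherence")
  wr(map$phase, "phase")
  invisible(path_prefix)
}

#' Render a coherence map as a pseudo-colour heatmap (PNG)
#' @param map a `coherence_map`
#' @param path output PNG path
#' @export
plot_coherence_png <- function(map, path) {
  grDevices::png(path, width = 800, height = 500)
  on.exit(grDevices::dev.off())
  graphics::image(map$positions, log2(map$scales), t(map$coherence),
                  col = grDevices::hcl.colors(64, "Blue-Red"),
                  xlab = "position (units)", ylab = "log2 scale",
                  main = "wavelet coherence", zlim = c(0, 1))
  graphics::lines(map$positions, log2(map$coi), lty = 2)
  invisible(path)
}
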