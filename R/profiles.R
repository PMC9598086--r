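# Axial "time-series" profiles: marks are projected onto an anatomical axis
# (the proximo-distal x axis being the most informative), normalized by bone
# length, and binned into a fixed number of units so that samples of
# different absolute size and bone length become comparable.

#' Normalized axial positions of marks on a template
#'
#' Projects each mark (linear marks are represented by their stored central
#' point) onto the chosen anatomical axis and normalizes by the template's
#' extent along that axis, giving positions in [0, 1].
#'
#' @param marks data.frame of marks (canonical mark columns)
#' @param template the `bone_template` the marks are registered on
#' @param axis `"x"` (proximo-distal, default), `"y"` or `"z"`
#' @param tol tolerated overshoot outside [0, 1] (fraction) before a mark is
#'   considered off-template; overshoots within tolerance are clamped
#' @return numeric vector of positions in [0, 1]
#' @export
axial_positions <- function(marks, template, axis = c("x", "y", "z"),
                            tol = 0.02) {
  axis <- match.arg(axis)
  stopifnot(inherits(template, "bone_template"))
  if (!all(marks$template_id %in% template$template_id))
    ot_stop("marks belong to a different template", "mixed_templates")
  j <- match(axis, c("x", "y", "z"))
  v <- marks[[c("x", "y", "z")[j]]]
  lo <- min(template$points[, j])
  ext <- diff(range(template$points[, j]))
  pos <- (v - lo) / ext
  if (any(pos < -tol | pos > 1 + tol))
    ot_stop("mark position outside template extent beyond tolerance",
            "off_template")
  pmin(pmax(pos, 0), 1)
}

#' Bin normalized positions into a series profile
#'
#' Divides [0, 1] into `n_units` half-open bins `[k/N, (k+1)/N)`; the last
#' bin is closed so position 1 is counted. Mark counts are conserved.
#'
#' @param positions numeric vector in [0, 1]
#' @param n_units number of units (>= 2), default 50
#' @param label profile label
#' @param axis axis the positions came from (metadata)
#' @return object of class `series_profile` with `counts` (length `n_units`)
#'   and `proportions`
#' @export
bin_series <- function(positions, n_units = 50L, label = "profile",
                       axis = "x") {
  if (n_units < 2L) ot_stop("n_units must be >= 2", "bad_parameter")
  if (!length(positions)) {
    warning("no positions: all-zero profile")
    counts <- integer(n_units)
  } else {
    stopifnot(all(positions >= 0 & positions <= 1))
    k <- pmin(floor(positions * n_units), n_units - 1L)
    counts <- tabulate(k + 1L, nbins = n_units)
  }
  total <- sum(counts)
  structure(list(label = label, axis = axis, n_units = as.integer(n_units),
                 counts = counts,
                 proportions = if (total > 0) counts / total else
                   rep(0, n_units)),
            class = "series_profile")
}

#' @export
print.series_profile <- function(x, ...) {
  cat(sprintf("<series_profile '%s': %d units, %d marks along %s>\n",
              x$label, x$n_units, sum(x$counts), x$axis))
  invisible(x)
}

#' Stack profiles into a relative-distribution comparison table
#'
#' Per-sample proportions plus the across-sample mean, on a shared unit grid.
#' Profiles of different elements can be concatenated sequentially beforehand
#' (e.g. femur units followed by tibia units) to compare whole hindlimbs.
#'
#' @param profiles list of `series_profile`s with equal `n_units`
#' @return data.frame with columns `unit`, one proportion column per profile
#'   label, and `mean`
#' @export
relative_profile <- function(profiles) {
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, inherits, TRUE, "series_profile")))
  nu <- vapply(profiles, function(p) p$n_units, 0L)
  if (length(unique(nu)) != 1L)
    ot_stop("profiles have mismatched n_units", "bad_parameter")
  mat <- vapply(profiles, function(p) p$proportions, numeric(nu[1]))
  colnames(mat) <- vapply(profiles, function(p) p$label, "")
  out <- data.frame(unit = seq_len(nu[1]), mat, check.names = FALSE)
  out$mean <- rowMeans(mat)
  out
}

#' Concatenate profiles end to end (sequential elements on one axis)
#' @param profiles list of `series_profile`s
#' @param label label for the combined profile
#' @return a `series_profile` whose units are the inputs' units in sequence
#' @export
concat_profiles <- function(profiles, label = "combined") {
  stopifnot(all(vapply(profiles, inherits, TRUE, "series_profile")))
  counts <- unlist(lapply(profiles, function(p) p$counts))
  total <- sum(counts)
  structure(list(label = label, axis = profiles[[1]]$axis,
                 n_units = length(counts), counts = counts,
                 proportions = if (total > 0) counts / total else
                   rep(0, length(counts))),
            class = "series_profile")
}

#' Write a profile to CSV (bin, count, proportion)
#' @param profile a `series_profile`
#' @param path output path
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(data.frame(bin = seq_len(profile$n_units),
                              count = profile$counts,
                              proportion = fmt_num(profile$proportions)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
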