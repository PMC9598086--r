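# t-SNE embedding of normalized mark coordinates plus DBSCAN cluster
# labelling of the 2D embedding. The exact (O(n^2)) t-SNE gradient is used:
# assemblages hold at most a few thousand marks, and exactness keeps the
# embedding deterministic for a given seed.

#' Perplexity heuristic: ceiling of the square root of the sample size
#'
#' Clipped (with a warning) to stay below n/3, the usual upper bound for a
#' meaningful neighbourhood size.
#'
#' @param n sample size (>= 4)
#' @return integer perplexity
#' @export
optimal_perplexity <- function(n) {
  if (n < 4) ot_stop("need at least 4 marks", "too_few_points")
  p <- ceiling(sqrt(n))
  limit <- floor((n - 1) / 3)
  if (p > limit) {
    warning(sprintf("perplexity %d clipped to %d (< n/3)", p, limit))
    p <- max(limit, 1L)
  }
  as.integer(p)
}

# conditional Gaussian affinities with per-point precision found by binary
# search on the perplexity (Shannon entropy target)
tsne_affinities <- function(X, perplexity) {
  n <- nrow(X)
  D2 <- as.matrix(stats::dist(X))^2
  logU <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1
    lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp < .Machine$double.xmin) sp <- .Machine$double.xmin
      H <- log(sp) + beta * sum(di * p) / sp
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p / sp
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, .Machine$double.xmin)
}

#' Normalized mark feature matrix for embedding
#'
#' Features are the marks' coordinates normalized by the template geometry:
#' x by the bone length, y and z by their template extents. Mark type and
#' sample of origin are labels for colouring, not features.
#'
#' @param marks data.frame of marks
#' @param template the `bone_template` the marks live on
#' @return n x 3 numeric matrix
#' @export
mark_features <- function(marks, template) {
  stopifnot(inherits(template, "bone_template"))
  p <- template$points
  cbind(x = (marks$x - min(p[, 1])) / template$length,
        y = (marks$y - min(p[, 2])) / diff(range(p[, 2])),
        z = (marks$z - min(p[, 3])) / diff(range(p[, 3])))
}

#' t-SNE embedding of marks
#'
#' Exact t-distributed stochastic neighbour embedding into 2D, trained with
#' early exaggeration and momentum gradient descent for a fixed number of
#' iterations. Deterministic given the seed. `restarts > 1` reruns the
#' optimisation from different derived seeds (t-SNE is stochastic, so
#' inspecting several runs is good practice) and returns all runs.
#'
#' @param features n x d numeric feature matrix (e.g. [mark_features()]), or
#'   a data.frame of marks together with `template`
#' @param template optional `bone_template`; when supplied and `features` is
#'   a mark data.frame, features are computed with [mark_features()]
#' @param iterations gradient-descent iterations (default 1000)
#' @param perplexity neighbourhood size; `NULL` means [optimal_perplexity()]
#' @param seed integer seed
#' @param restarts number of independent runs
#' @return an `embedding_result`: `coords` (n x 2) of the first run, `runs`
#'   (list of n x 2 matrices), `perplexity`, `iterations`, `seed`,
#'   `run_seeds`; cluster fields are filled by [dbscan_cluster()]
#' @export
tsne_embed <- function(features, template = NULL, iterations = 1000L,
                       perplexity = NULL, seed, restarts = 1L) {
  stopifnot(!missing(seed))
  if (is.data.frame(features)) {
    if (is.null(template))
      ot_stop("supply a template to derive features from a mark table",
              "bad_parameter")
    features <- mark_features(features, template)
  }
  X <- as.matrix(features)
  n <- nrow(X)
  if (n < 8L) ot_stop("need at least 8 marks to embed", "too_few_points")
  if (is.null(perplexity)) perplexity <- optimal_perplexity(n)
  if (n < 3 * perplexity + 1)
    ot_stop(sprintf(
      "fewer marks (%d) than 3*perplexity + 1 (%d); lower the perplexity to <= %d",
      n, 3 * perplexity + 1, floor((n - 1) / 3)), "too_few_points")
  P <- tsne_affinities(X, perplexity)
  run_seeds <- vapply(seq_len(restarts),
                      function(k) derive_seed(seed, paste0("tsne", k)), 0L)
  runs <- lapply(run_seeds, function(s)
    with_seed(s, tsne_run(P, n, iterations)))
  structure(list(coords = runs[[1]], runs = runs, perplexity = perplexity,
                 iterations = as.integer(iterations), seed = seed,
                 run_seeds = run_seeds, labels = NULL, eps = NA_real_,
                 min_pts = NA_integer_),
            class = "embedding_result")
}

tsne_run <- function(P, n, iterations) {
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  gains <- matrix(1, n, 2)
  inc <- matrix(0, n, 2)
  momentum <- 0.5
  eta <- 100
  exag_until <- min(100L, iterations)
  P4 <- P * 4  # early exaggeration
  for (it in seq_len(iterations)) {
    Pcur <- if (it <= exag_until) P4 else P
    D2 <- as.matrix(stats::dist(Y))^2
    num <- 1 / (1 + D2)
    diag(num) <- 0
    Q <- num / sum(num)
    Q <- pmax(Q, .Machine$double.xmin)
    L <- (Pcur - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    inc <- momentum * inc - eta * gains * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
    if (it == 250L) momentum <- 0.8
  }
  colnames(Y) <- c("dim1", "dim2")
  Y
}

#' @export
print.embedding_result <- function(x, ...) {
  cat(sprintf("<embedding_result: %d marks, perplexity %d, %d iterations%s>\n",
              nrow(x$coords), x$perplexity, x$iterations,
              if (!is.null(x$labels))
                sprintf(", %d clusters",
                        length(setdiff(unique(x$labels), -1L))) else ""))
  invisible(x)
}

#' DBSCAN clustering of a 2D embedding
#'
#' Classic density-based clustering: a point with at least `min_pts`
#' neighbours within `eps` (itself included) is a core point; clusters are the
#' connected components of core points plus their border points; everything
#' else is noise (label -1).
#'
#' @param embedding an `embedding_result` or an n x 2 coordinate matrix
#' @param eps neighbourhood radius in embedding units (default 3)
#' @param min_pts minimum neighbourhood size for a core point (default 4)
#' @return if given an `embedding_result`, the same object with `labels`,
#'   `eps`, `min_pts` filled; otherwise an integer label vector (clusters
#'   numbered from 1, noise = -1)
#' @export
dbscan_cluster <- function(embedding, eps = 3, min_pts = 4L) {
  coords <- if (inherits(embedding, "embedding_result")) embedding$coords
            else as.matrix(embedding)
  n <- nrow(coords)
  D <- as.matrix(stats::dist(coords))
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(nb, length, 0L) >= min_pts
  labels <- rep(NA_integer_, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!is.na(labels[i]) || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      j <- queue[[1]]
      queue <- queue[-1]
      for (k in nb[[j]]) {
        if (is.na(labels[k]) || labels[k] == -1L) {
          newly <- is.na(labels[k])
          labels[k] <- cl
          if (newly && core[k]) queue <- c(queue, k)
        }
      }
    }
  }
  labels[is.na(labels)] <- -1L
  if (inherits(embedding, "embedding_result")) {
    embedding$labels <- labels
    embedding$eps <- eps
    embedding$min_pts <- as.integer(min_pts)
    embedding
  } else labels
}

#' Write an embedding (with cluster labels) to CSV
#' @param embedding an `embedding_result`
#' @param path output path
#' @param mark_ids optional mark ids (default row numbers)
#' @export
write_embedding_csv <- function(embedding, path, mark_ids = NULL) {
  n <- nrow(embedding$coords)
  df <- data.frame(mark_id = mark_ids %||% sprintf("m%06d", seq_len(n)),
                   dim1 = fmt_num(embedding$coords[, 1]),
                   dim2 = fmt_num(embedding$coords[, 2]),
                   cluster = embedding$labels %||% rep(NA_integer_, n))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
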