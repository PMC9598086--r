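# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a structured error class
#' @noRd
ot_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "osteotrace_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Coerce to an n x 3 numeric coordinate matrix
#' @noRd
as_xyz <- function(x, arg = "points") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.numeric(x) && is.null(dim(x)) && length(x) == 3L) x <- matrix(x, 1L, 3L)
  if (!is.matrix(x) || ncol(x) != 3L || !is.numeric(x))
    ot_stop(sprintf("'%s' must be an n x 3 numeric matrix", arg), "bad_coords")
  storage.mode(x) <- "double"
  colnames(x) <- c("x", "y", "z")
  x
}

#' Derive a child RNG seed (< 2^31) from a master seed and a stage label
#'
#' Deterministic and label-sensitive so that every stochastic stage of a
#' pipeline receives its own reproducible stream.
#' @param seed master integer seed
#' @param label character stage label
#' @return integer seed in [1, 2^31 - 1]
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (ch in utf8ToInt(as.character(label))) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(seed) * 7919 + h) %% 2147483646 + 1)
}

#' Evaluate an expression under a local, restored RNG state
#' @noRd
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' File hash for run manifests (sha256 when available, else md5)
#' @noRd
ot_hash <- function(path) {
  sha <- Sys.which("sha256sum")
  if (nzchar(sha)) {
    out <- system2(sha, shQuote(path), stdout = TRUE)
    list(algo = "sha256", value = substr(out[1], 1L, 64L))
  } else {
    list(algo = "md5", value = unname(tools::md5sum(path)))
  }
}

fmt_num <- function(x) formatC(x, digits = 9, format = "g")
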