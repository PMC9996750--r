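#' @keywords internal
"_PACKAGE"

# Run code under a local RNG state so package functions never disturb the
# caller's .Random.seed. All exported stochastic functions take an explicit
# seed and route through this.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministically derive a stage seed from a master seed. Keeps results
# < 2^31 - 1 and well-separated across stage indices.
spawn_seed <- function(master, stage) {
  master <- as.double(master)
  stage <- as.double(stage)
  as.integer((master * 48271 + stage * 16807 + 12345) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (x < lower || x > upper)
    stopf("'%s' must be in [%s, %s]", name, format(lower), format(upper))
  invisible(x)
}

#' Orthogonal Procrustes alignment of two point configurations
#'
#' Finds the rotation/reflection (and optionally isotropic scaling) plus
#' translation of \code{x} that best matches \code{target} in the
#' least-squares sense. Embeddings produced by multidimensional scaling or
#' ordinal embedding are defined only up to rigid transforms, so all
#' configuration comparisons in this package are made after Procrustes
#' alignment.
#'
#' @param x numeric matrix (k points by d dims) to be transformed.
#' @param target numeric matrix of the same dimension to align to.
#' @param scale logical; allow isotropic scaling (default \code{TRUE}).
#' @return list with components \code{aligned} (transformed \code{x}),
#'   \code{rotation}, \code{scale}, \code{translation} and \code{rms}, the
#'   root-mean-square residual per point after alignment.
#' @examples
#' pts <- matrix(rnorm(20), 10, 2)
#' th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
#' moved <- pts %*% R + 5
#' procrustes_align(moved, pts)$rms  # ~ 0
#' @export
procrustes_align <- function(x, target, scale = TRUE) {
  x <- as.matrix(x); target <- as.matrix(target)
  if (!all(dim(x) == dim(target)))
    stopf("configurations must have identical dimensions")
  cx <- colMeans(x); ct <- colMeans(target)
  xc <- sweep(x, 2, cx); tc <- sweep(target, 2, ct)
  s <- svd(crossprod(tc, xc))
  rot <- s$v %*% t(s$u)
  sc <- if (scale) sum(s$d) / sum(xc^2) else 1
  aligned <- sc * xc %*% rot
  aligned <- sweep(aligned, 2, ct, `+`)
  rms <- sqrt(mean(rowSums((aligned - target)^2)))
  list(aligned = aligned, rotation = rot, scale = sc,
       translation = ct - sc * as.vector(cx %*% rot), rms = rms)
}

#' Area under the ROC curve by the rank (Mann-Whitney) formulation
#'
#' Computes AUC as the probability that a randomly chosen positive case
#' receives a higher score than a randomly chosen negative case, with ties
#' counted one half. Equivalent to the normalized Mann-Whitney U statistic.
#'
#' @param scores numeric vector of predicted scores.
#' @param labels binary vector (logical, 0/1, or two-level factor); the
#'   second factor level / larger value is the positive class.
#' @return AUC in [0, 1].
#' @examples
#' auc_rank(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
#' @export
auc_rank <- function(scores, labels) {
  if (length(scores) != length(labels))
    stopf("scores and labels must have equal length")
  y <- as_binary(labels)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L)
    stopf("AUC requires both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Coerce a binary outcome to integer 0/1.
as_binary <- function(x) {
  if (is.logical(x)) return(as.integer(x))
  if (is.factor(x)) {
    if (nlevels(x) != 2L) stopf("binary outcome must have exactly 2 levels")
    return(as.integer(x) - 1L)
  }
  u <- sort(unique(x[!is.na(x)]))
  if (length(u) > 2L) stopf("outcome is not binary")
  as.integer(x == max(u))
}

# Significance stars at the conventional thresholds (configurable).
significance_stars <- function(p, thresholds = c(0.05, 0.01, 0.001)) {
  vapply(p, function(pi) {
    if (is.na(pi)) return("")
    paste(rep("*", sum(pi < thresholds)), collapse = "")
  }, character(1))
}

# Euclidean distance matrix from a coordinate matrix (dense, zero diagonal).
coord_dist <- function(x) as.matrix(stats::dist(as.matrix(x)))
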