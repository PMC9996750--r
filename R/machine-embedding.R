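# Machine-derived latent feature vectors: a pluggable feature-extractor
# contract, pairwise cosine similarity, and classical multidimensional
# scaling down to d coordinates per drawing.
#
# The default extractor is deterministic and self-contained: concatenated
# multi-resolution ink-occupancy grids plus global shape statistics. Any
# function satisfying the same contract (declared input side and output
# length) can stand in for it, including an adapter around a pretrained
# convolutional network's penultimate layer; none is required for the
# pipeline to run.

#' Reference feature extractor: multi-resolution ink occupancy
#'
#' Builds an extractor that maps a binary bitmap to the concatenation of
#' ink-fraction grids at the requested resolutions (default 4x4, 8x8,
#' 16x16 cells) plus six global statistics: overall ink fraction, bounding
#' box height and width as fractions of the image, and the ink centroid
#' (row, column) as fractions, and the ink perimeter fraction.
#'
#' @param grids integer vector of grid resolutions.
#' @param input_side declared input side length in pixels.
#' @return object of class \code{sketch_extractor} with elements
#'   \code{input_side}, \code{length}, \code{fun}.
#' @export
reference_extractor <- function(grids = c(4L, 8L, 16L), input_side = 224L) {
  grids <- as.integer(grids)
  len <- sum(grids^2) + 6L
  fun <- function(b) {
    m <- b * 1
    v <- unlist(lapply(grids, function(g) {
      ri <- ceiling(seq_len(nrow(m)) * g / nrow(m))
      ci <- ceiling(seq_len(ncol(m)) * g / ncol(m))
      cell <- rowsum(t(rowsum(m, ri)), ci)        # g x g sums (transposed)
      counts <- rowsum(t(rowsum(matrix(1, nrow(m), ncol(m)), ri)), ci)
      as.vector(t(cell / counts))
    }), use.names = FALSE)
    ink <- which(b, arr.ind = TRUE)
    bb_h <- diff(range(ink[, 1])) + 1L
    bb_w <- diff(range(ink[, 2])) + 1L
    # crude perimeter: ink pixels with at least one background 4-neighbor
    pad <- rbind(FALSE, cbind(FALSE, b, FALSE), FALSE)
    core <- pad[2:(nrow(b) + 1), 2:(ncol(b) + 1)]
    nb <- pad[1:nrow(b), 2:(ncol(b) + 1)] & pad[3:(nrow(b) + 2), 2:(ncol(b) + 1)] &
      pad[2:(nrow(b) + 1), 1:ncol(b)] & pad[2:(nrow(b) + 1), 3:(ncol(b) + 2)]
    perim <- sum(core & !nb)
    c(v, mean(m), bb_h / nrow(b), bb_w / ncol(b),
      mean(ink[, 1]) / nrow(b), mean(ink[, 2]) / ncol(b),
      perim / length(b))
  }
  structure(list(input_side = as.integer(input_side), length = len,
                 fun = fun, label = "reference"),
            class = "sketch_extractor")
}

#' Random-projection feature extractor
#'
#' Projects the flattened bitmap through a fixed Gaussian random matrix.
#' Deterministic given its seed; used to exercise the extractor-swap
#' contract of the embedding pipeline.
#'
#' @param n_features output vector length.
#' @param input_side declared input side length.
#' @param seed seed fixing the projection matrix.
#' @return \code{sketch_extractor} object.
#' @export
random_projection_extractor <- function(n_features = 64L, input_side = 224L,
                                        seed = 1L) {
  input_side <- as.integer(input_side)
  proj <- with_seed(seed, matrix(stats::rnorm(n_features * input_side^2),
                                 n_features, input_side^2))
  fun <- function(b) as.vector(proj %*% as.vector(b * 1))
  structure(list(input_side = input_side, length = as.integer(n_features),
                 fun = fun, label = "random_projection"),
            class = "sketch_extractor")
}

#' @export
print.sketch_extractor <- function(x, ...) {
  cat(sprintf("<sketch_extractor '%s': input %dx%d -> %d features>\n",
              x$label, x$input_side, x$input_side, x$length))
  invisible(x)
}

#' Extract feature vectors from prepared bitmaps
#'
#' @param bitmaps a single logical bitmap or a named list of bitmaps (ids as
#'   names), each of the extractor's declared input side.
#' @param extractor a \code{sketch_extractor} (default
#'   \code{\link{reference_extractor}}).
#' @return numeric matrix, one row per drawing (rownames = ids), columns =
#'   extractor features.
#' @export
extract_features <- function(bitmaps, extractor = reference_extractor()) {
  if (!inherits(extractor, "sketch_extractor"))
    stopf("'extractor' must be a sketch_extractor")
  if (is.matrix(bitmaps)) bitmaps <- list(drawing = bitmaps)
  out <- t(vapply(bitmaps, function(b) {
    if (nrow(b) != extractor$input_side || ncol(b) != extractor$input_side)
      stopf("bitmap is %dx%d but extractor expects %dx%d",
            nrow(b), ncol(b), extractor$input_side, extractor$input_side)
    if (!any(b)) stopf("all-background bitmap cannot be embedded")
    v <- extractor$fun(b)
    if (length(v) != extractor$length || any(!is.finite(v)))
      stopf("extractor returned an invalid feature vector")
    v
  }, numeric(extractor$length)))
  rownames(out) <- names(bitmaps)
  out
}

#' Pairwise cosine similarity matrix
#'
#' @param vectors numeric matrix of feature vectors (rows = drawings).
#' @return symmetric k x k similarity matrix with unit diagonal, entries in
#'   [-1, 1], dimnames = drawing ids.
#' @export
cosine_matrix <- function(vectors) {
  v <- as.matrix(vectors)
  if (nrow(v) < 2L) stopf("need at least 2 vectors")
  nrm <- sqrt(rowSums(v^2))
  if (any(nrm == 0)) stopf("zero-norm feature vector")
  s <- tcrossprod(v / nrm)
  s <- pmin(pmax(s, -1), 1)
  s <- (s + t(s)) / 2
  diag(s) <- 1
  dimnames(s) <- list(rownames(v), rownames(v))
  s
}

#' Classical multidimensional scaling of a similarity or distance matrix
#'
#' Embeds k items in d dimensions so that pairwise Euclidean distances
#' approximate the input dissimilarities. A similarity matrix is first
#' converted by the chord distance delta = sqrt(2 (1 - s)) (exact for
#' unit-normalized vectors under cosine similarity); a distance matrix is
#' used as-is. The squared dissimilarities are double-centered and the
#' coordinates are the top-d eigenvectors scaled by the square roots of
#' their (non-negative) eigenvalues; axes with non-positive eigenvalues are
#' zero-filled. Each axis's sign is canonicalized so its largest-magnitude
#' coordinate is positive.
#'
#' @param s square symmetric matrix: cosine similarities (\code{input =
#'   "similarity"}) or dissimilarities (\code{input = "distance"}).
#' @param d embedding dimension, 1 <= d <= k - 1.
#' @param input how to interpret \code{s}.
#' @return object of class \code{sketch_embedding}: list with \code{coords}
#'   (k x d matrix, rownames = ids), \code{eig} (all eigenvalues),
#'   \code{negative_mass} (sum of |negative eigenvalues| over sum |all|),
#'   \code{source}.
#' @export
classical_mds <- function(s, d = 2L, input = c("similarity", "distance")) {
  input <- match.arg(input)
  s <- as.matrix(s)
  k <- nrow(s)
  if (k != ncol(s) || max(abs(s - t(s))) > 1e-8)
    stopf("input must be a symmetric square matrix")
  d <- as.integer(d)
  if (d < 1L || d > k - 1L) stopf("d must be in 1..k-1")
  delta <- if (input == "similarity") sqrt(pmax(2 * (1 - s), 0)) else s
  d2 <- delta^2
  # double centering: B = -1/2 J d2 J
  rm <- rowMeans(d2); gm <- mean(d2)
  b <- -0.5 * (d2 - outer(rm, rm, `+`) + gm)
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  lam <- e$values[seq_len(d)]
  coords <- e$vectors[, seq_len(d), drop = FALSE] %*%
    diag(sqrt(pmax(lam, 0)), d)
  coords <- canonicalize_axes(coords)
  rownames(coords) <- rownames(s)
  colnames(coords) <- paste0("x", seq_len(d))
  neg <- sum(abs(pmin(e$values, 0)))
  structure(list(coords = coords, eig = e$values,
                 negative_mass = neg / max(sum(abs(e$values)), 1e-300),
                 source = "machine", dims = d),
            class = "sketch_embedding")
}

# Flip each axis so that the coordinate with the largest absolute value is
# positive (ties broken by the first such index).
canonicalize_axes <- function(coords) {
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, j]))
    if (length(i) && coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  coords
}

#' @export
print.sketch_embedding <- function(x, ...) {
  cat(sprintf("<sketch_embedding: %d drawings in %d dims (source: %s)>\n",
              nrow(x$coords), x$dims, x$source))
  if (!is.null(x$negative_mass))
    cat(sprintf("  negative eigenvalue mass: %.3g\n", x$negative_mass))
  if (!is.null(x$holdout_accuracy))
    cat(sprintf("  holdout accuracy: %.3f\n", x$holdout_accuracy))
  invisible(x)
}

#' @export
plot.sketch_embedding <- function(x, dims = c(1, 2), ...) {
  co <- x$coords[, dims, drop = FALSE]
  graphics::plot(co, xlab = paste0("dim ", dims[1]),
                 ylab = paste0("dim ", dims[2]),
                 main = sprintf("%s embedding", x$source), ...)
  invisible(x)
}

#' Machine-derived embedding of a set of drawings
#'
#' Convenience pipeline: feature extraction, cosine similarity, classical
#' MDS.
#'
#' @param bitmaps named list of prepared bitmaps.
#' @param dims embedding dimension.
#' @param extractor feature extractor.
#' @return \code{sketch_embedding} (source = "machine").
#' @export
machine_embedding <- function(bitmaps, dims = 2L,
                              extractor = reference_extractor()) {
  fv <- extract_features(bitmaps, extractor)
  classical_mds(cosine_matrix(fv), d = dims)
}
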