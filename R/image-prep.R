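# Normalization of heterogeneous drawing images into uniform binary bitmaps:
# binarize -> crop to content -> center/pad to a square working size ->
# resample to the feature extractor's input dimensions.

as_gray <- function(img) {
  if (is.logical(img)) return(1 - img * 1)     # ink TRUE -> dark
  if (length(dim(img)) == 3L) {
    # average the color channels (ignore alpha if present)
    nc <- min(dim(img)[3], 3L)
    img <- apply(img[, , seq_len(nc), drop = FALSE], c(1, 2), mean)
  }
  img
}

#' Binarize a raster image
#'
#' Contrast-normalizes a grayscale or color raster so that every pixel is
#' either ink (dark) or background (light): a pixel becomes ink iff its
#' luminance falls below the threshold. With \code{threshold = NULL} the
#' threshold is chosen by Otsu's method on the luminance histogram.
#'
#' @param img numeric matrix or array with values in [0, 1] (as returned by
#'   \code{png::readPNG}), or a logical ink matrix.
#' @param threshold luminance cutoff in [0, 1], or NULL for Otsu.
#' @return logical matrix; TRUE = ink.
#' @export
binarize <- function(img, threshold = NULL) {
  if (length(img) == 0L) stopf("empty image")
  g <- as_gray(img)
  if (!is.null(threshold)) {
    assert_scalar_number(threshold, "threshold", 0, 1)
  } else {
    threshold <- otsu_threshold(g)
  }
  g < threshold
}

# Otsu's threshold on a [0,1] grayscale matrix (256-bin histogram,
# maximizing between-class variance). Falls back to 0.5 on constant images.
otsu_threshold <- function(g, bins = 256L) {
  v <- as.vector(g)
  if (max(v) - min(v) < 1e-12) return(0.5)
  h <- tabulate(pmin(pmax(floor(v * bins) + 1L, 1L), bins), bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(bins) - 0.5) / bins)
  mu_t <- mu[bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  which.max(sigma_b) / bins
}

#' Crop a bitmap to its ink bounding box
#'
#' @param b logical ink bitmap.
#' @param margin background pixels to retain around the ink bounding box
#'   (clipped at the image border).
#' @return cropped logical bitmap.
#' @export
crop_to_content <- function(b, margin = 0L) {
  if (!any(b)) stopf("blank bitmap: no ink to crop to")
  margin <- as.integer(margin)
  rows <- range(which(rowSums(b) > 0))
  cols <- range(which(colSums(b) > 0))
  r0 <- max(1L, rows[1] - margin); r1 <- min(nrow(b), rows[2] + margin)
  c0 <- max(1L, cols[1] - margin); c1 <- min(ncol(b), cols[2] + margin)
  b[r0:r1, c0:c1, drop = FALSE]
}

#' Center a bitmap on a square white canvas
#'
#' Places the bitmap, unscaled, on a side x side background canvas with the
#' content's bounding-box center at the canvas center (up to the 1-pixel
#' rounding inherent to integer placement).
#'
#' @param b logical ink bitmap.
#' @param side output side length; must be >= both bitmap dimensions.
#' @return side x side logical bitmap with identical ink-pixel count.
#' @export
center_pad <- function(b, side = 224L) {
  side <- as.integer(side)
  if (side < max(dim(b))) stopf("side %d smaller than content", side)
  out <- matrix(FALSE, side, side)
  r0 <- floor((side - nrow(b)) / 2)
  c0 <- floor((side - ncol(b)) / 2)
  out[r0 + seq_len(nrow(b)), c0 + seq_len(ncol(b))] <- b
  out
}

#' Resample a bitmap to an extractor's input dimensions
#'
#' Area (block-mean) resampling when both dimensions are integer multiples
#' of the target, nearest-neighbor index mapping otherwise. Returns a
#' numeric raster with values in [0, 1] (ink coverage per output pixel).
#'
#' @param b logical or numeric bitmap.
#' @param target output side length (positive).
#' @return target x target numeric matrix in [0, 1].
#' @export
resize_for_extractor <- function(b, target = 224L) {
  target <- as.integer(target)
  if (target < 1L) stopf("target must be positive")
  m <- b * 1
  if (nrow(m) == target && ncol(m) == target) return(m)
  if (nrow(m) %% target == 0L && ncol(m) %% target == 0L) {
    fr <- nrow(m) %/% target; fc <- ncol(m) %/% target
    ri <- (seq_len(nrow(m)) - 1L) %/% fr + 1L
    ci <- (seq_len(ncol(m)) - 1L) %/% fc + 1L
    out <- rowsum(t(rowsum(m, ri)), ci) / (fr * fc)
    return(t(out)[seq_len(target), seq_len(target)])
  }
  ri <- pmin(pmax(ceiling(seq_len(target) * nrow(m) / target), 1L), nrow(m))
  ci <- pmin(pmax(ceiling(seq_len(target) * ncol(m) / target), 1L), ncol(m))
  m[ri, ci]
}

#' Full image-preparation pipeline
#'
#' binarize -> crop to ink content -> center and pad to a uniform square.
#' Idempotent: applying it to its own output returns the same bitmap.
#'
#' @param img raster or logical bitmap.
#' @param side uniform output side length.
#' @param threshold binarization threshold (NULL = Otsu).
#' @param margin crop margin in pixels.
#' @return side x side logical bitmap.
#' @export
prep_image <- function(img, side = 224L, threshold = NULL, margin = 2L) {
  b <- binarize(img, threshold)
  if (!any(b)) stopf("blank drawing: no ink after binarization")
  b <- crop_to_content(b, margin)
  if (max(dim(b)) > side) b <- shrink_to_fit(b, side)
  center_pad(b, side)
}

# Downscale a bitmap so it fits in side x side, preserving aspect ratio
# (nearest-neighbor on the ink mask; a resampled pixel is ink if its source
# block contains >= 25% ink, keeping thin strokes visible).
shrink_to_fit <- function(b, side) {
  f <- side / max(dim(b))
  nr <- max(1L, floor(nrow(b) * f)); nc <- max(1L, floor(ncol(b) * f))
  ri <- pmin(pmax(ceiling(seq_len(nr) / f), 1L), nrow(b))
  ci <- pmin(pmax(ceiling(seq_len(nc) / f), 1L), ncol(b))
  # block coverage via a padded 2D cumulative sum for an area-style decision
  cs <- apply(b * 1, 2, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, nrow = 1L)
  cs <- t(apply(cs, 1, cumsum))
  if (is.null(dim(cs)) || nrow(cs) != nrow(b)) cs <- matrix(cs, nrow = nrow(b))
  cs <- rbind(0, cbind(0, cs))
  r0 <- c(0L, ri[-nr]); c0 <- c(0L, ci[-nc])
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) {
    rows <- (r0[i] + 1L):ri[i]
    for (jj in seq_len(nc)) {
      cols <- (c0[jj] + 1L):ci[jj]
      tot <- cs[ri[i] + 1L, ci[jj] + 1L] - cs[r0[i] + 1L, ci[jj] + 1L] -
        cs[ri[i] + 1L, c0[jj] + 1L] + cs[r0[i] + 1L, c0[jj] + 1L]
      out[i, jj] <- tot / (length(rows) * length(cols)) >= 0.25
    }
  }
  out
}

#' Read a drawing image from a PNG file
#'
#' @param path PNG file path.
#' @return numeric raster (matrix or array) with values in [0, 1].
#' @export
read_drawing <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  png::readPNG(path)
}

#' Write a binary bitmap as a PNG file
#'
#' @param b logical ink bitmap (TRUE = black).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_drawing <- function(b, path) {
  png::writePNG(1 - b * 1, path)
  invisible(path)
}
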