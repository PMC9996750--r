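# Structure comparison between metric spaces: nearest neighbors, cross-space
# top-K overlap, cross-space coordinate regressions, checklist-prediction
# regressions, and correlations between inter-drawing distance matrices.

embedding_coords <- function(e) {
  if (inherits(e, "sketch_embedding")) return(e$coords)
  if (is.data.frame(e)) {
    idc <- intersect("drawing_id", names(e))
    m <- as.matrix(e[, setdiff(names(e), idc), drop = FALSE])
    if (length(idc)) rownames(m) <- e$drawing_id
    return(m)
  }
  as.matrix(e)
}

#' Distance matrix of an embedding or scalar metric
#'
#' Euclidean distances between all drawing pairs of an embedding, or the
#' absolute score differences for a scalar metric such as the checklist
#' score (a valid 1D metric satisfying the triangle inequality).
#'
#' @param x \code{sketch_embedding}, coordinate matrix, or a named numeric
#'   vector of scalar scores.
#' @param label metric label stored as the "metric_label" attribute.
#' @return symmetric k x k distance matrix with zero diagonal.
#' @export
metric_distances <- function(x, label = NULL) {
  m <- if (is.numeric(x) && is.null(dim(x)) && !is.null(names(x))) {
    out <- abs(outer(x, x, `-`))
    dimnames(out) <- list(names(x), names(x))
    out
  } else {
    coord_dist(embedding_coords(x))
  }
  attr(m, "metric_label") <- label
  m
}

#' Nearest neighbors of every drawing
#'
#' @param e embedding (or coordinate matrix), or a precomputed symmetric
#'   distance matrix.
#' @param K neighbors per drawing (K < number of drawings).
#' @return named list: for each drawing, the ids of its K nearest other
#'   drawings ordered by non-decreasing distance (ties broken by id order).
#' @export
nearest_neighbors <- function(e, K = 5L) {
  dm <- if (is.matrix(e) && nrow(e) == ncol(e) &&
              !is.null(rownames(e)) && identical(rownames(e), colnames(e)) &&
              all(abs(diag(e)) < 1e-12))
    e else coord_dist(embedding_coords(e))
  k <- nrow(dm)
  K <- as.integer(K)
  if (K >= k) stopf("K must be smaller than the number of drawings (%d)", k)
  ids <- rownames(dm) %||% as.character(seq_len(k))
  out <- lapply(seq_len(k), function(i) {
    d <- dm[i, -i]
    nb <- ids[-i]
    nb[order(d, nb)][seq_len(K)]
  })
  names(out) <- ids
  out
}

#' Cross-space nearest-neighbor overlap
#'
#' For each drawing, checks whether its single nearest neighbor in one
#' embedding space appears among the top K closest drawings for the same
#' referent in the other space, and reports the fraction for which it does,
#' in both directions.
#'
#' @param eA,eB embeddings (or distance matrices) over the same drawing ids.
#' @param K top-K window in the other space (default 10).
#' @return named numeric vector c(a_in_b, b_in_a), each in [0, 1].
#' @export
nn_overlap <- function(eA, eB, K = 10L) {
  nnA1 <- nearest_neighbors(eA, 1L)
  nnB1 <- nearest_neighbors(eB, 1L)
  idsA <- names(nnA1); idsB <- names(nnB1)
  if (!setequal(idsA, idsB)) stopf("embeddings cover different drawing ids")
  nnAK <- nearest_neighbors(eA, K)
  nnBK <- nearest_neighbors(eB, K)
  a_in_b <- mean(vapply(idsA, function(id)
    nnA1[[id]][1] %in% nnBK[[id]], logical(1)))
  b_in_a <- mean(vapply(idsA, function(id)
    nnB1[[id]][1] %in% nnAK[[id]], logical(1)))
  c(a_in_b = a_in_b, b_in_a = b_in_a)
}

#' Cross-space coordinate regressions
#'
#' Fits the four ordinary least-squares models predicting each coordinate of
#' one 2D embedding from both coordinates of the other plus their
#' interaction (X_A ~ X_B * Y_B and so on), reporting R-squared and the
#' overall-F p-value per model.
#'
#' @param eA,eB 2D embeddings over the same drawing ids.
#' @return data.frame with four rows: model label, dependent space and
#'   coordinate, r_squared, adj_r_squared, p_value.
#' @export
cross_space_regression <- function(eA, eB) {
  a <- embedding_coords(eA); b <- embedding_coords(eB)
  if (ncol(a) != 2L || ncol(b) != 2L) stopf("both embeddings must be 2D")
  if (is.null(rownames(a)) || is.null(rownames(b)))
    stopf("embeddings must carry drawing ids as rownames")
  common <- intersect(rownames(a), rownames(b))
  if (!setequal(rownames(a), rownames(b)))
    stopf("embeddings cover different drawing ids")
  b <- b[rownames(a), , drop = FALSE]
  one <- function(y, pred, label) {
    df <- data.frame(y = y, x1 = pred[, 1], x2 = pred[, 2])
    fit <- stats::lm(y ~ x1 * x2, data = df)
    sm <- summary(fit)
    p <- stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                   lower.tail = FALSE)
    data.frame(model = label, r_squared = sm$r.squared,
               adj_r_squared = sm$adj.r.squared, p_value = unname(p),
               stringsAsFactors = FALSE)
  }
  out <- rbind(one(a[, 1], b, "X_A ~ X_B * Y_B"),
               one(a[, 2], b, "Y_A ~ X_B * Y_B"),
               one(b[, 1], a, "X_B ~ X_A * Y_A"),
               one(b[, 2], a, "Y_B ~ X_A * Y_A"))
  rownames(out) <- NULL
  out
}

#' Checklist-prediction model ladder
#'
#' Fits the six regression models predicting the mean-of-raters checklist
#' score from the new metrics: quality-rank only, human embedding only,
#' machine embedding only, quality x human, quality x machine, and the full
#' model (quality x human + quality x machine, with full interactions
#' within each pairing), reporting adjusted R-squared and the nested
#' comparison p-value for each model against its reference.
#'
#' @param checklist data.frame with drawing_id and final (checklist score).
#' @param quality data.frame with drawing_id and score (quality-rank).
#' @param eH,eM 2D human- and machine-derived embeddings.
#' @return data.frame: model, reference, adj_r_squared, r_squared, p_value
#'   (nested F-test against the reference model; NA for the null reference
#'   rows reports the overall-F p-value instead).
#' @export
checklist_prediction_ladder <- function(checklist, quality, eH, eM) {
  h <- embedding_coords(eH); m <- embedding_coords(eM)
  ids <- Reduce(intersect, list(checklist$drawing_id, quality$drawing_id,
                                rownames(h), rownames(m)))
  if (length(ids) < nrow(checklist))
    stopf("incomplete metric coverage: %d of %d drawings have all metrics",
          length(ids), nrow(checklist))
  df <- data.frame(
    y = checklist$final[match(ids, checklist$drawing_id)],
    qr = quality$score[match(ids, quality$drawing_id)],
    hx = h[ids, 1], hy = h[ids, 2],
    mx = m[ids, 1], my = m[ids, 2])
  forms <- list(
    "QR only" = y ~ qr,
    "HE only" = y ~ hx * hy,
    "ME only" = y ~ mx * my,
    "QR x HE" = y ~ qr * hx * hy,
    "QR x ME" = y ~ qr * mx * my,
    "QR x HE x ME" = y ~ qr * hx * hy + qr * mx * my)
  refs <- c("QR only" = "null", "HE only" = "null", "ME only" = "null",
            "QR x HE" = "HE only", "QR x ME" = "QR only",
            "QR x HE x ME" = "QR x HE")
  fits <- lapply(forms, function(f) stats::lm(f, data = df))
  out <- do.call(rbind, lapply(names(forms), function(nm) {
    sm <- summary(fits[[nm]])
    ref <- refs[[nm]]
    p <- if (ref == "null") {
      stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                lower.tail = FALSE)
    } else {
      stats::anova(fits[[ref]], fits[[nm]])[2, "Pr(>F)"]
    }
    data.frame(model = nm, reference = ref,
               adj_r_squared = sm$adj.r.squared,
               r_squared = sm$r.squared, p_value = unname(p),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Correlations between inter-drawing distance matrices
#'
#' Pearson correlations over the strictly-upper-triangle entries for every
#' pair of metrics (distances in an embedding space, or absolute checklist
#' score differences). Optionally adds a Mantel-style permutation p-value
#' (drawing pairs are not independent, so the plain correlation's nominal
#' p-value is not valid; the permutation test permutes drawing labels).
#'
#' @param matrices named list of distance matrices over the same ids (see
#'   \code{\link{metric_distances}}).
#' @param mantel_permutations 0 for none, otherwise number of label
#'   permutations.
#' @param seed seed for the permutations.
#' @return data.frame: metric_a, metric_b, correlation, n_pairs, and
#'   mantel_p when requested.
#' @export
distance_metric_correlations <- function(matrices, mantel_permutations = 0L,
                                         seed = 1L) {
  nm <- names(matrices) %||% paste0("m", seq_along(matrices))
  ids <- rownames(matrices[[1]])
  for (m in matrices) {
    if (!is.null(ids) && !is.null(rownames(m)) &&
        !identical(rownames(m), ids))
      stopf("distance matrices cover different (or differently ordered) ids")
    if (nrow(m) != nrow(matrices[[1]]))
      stopf("distance matrices have different sizes")
  }
  ut <- upper.tri(matrices[[1]])
  combos <- utils::combn(seq_along(matrices), 2)
  out <- do.call(rbind, lapply(seq_len(ncol(combos)), function(ci) {
    i <- combos[1, ci]; j <- combos[2, ci]
    a <- matrices[[i]][ut]; b <- matrices[[j]][ut]
    if (stats::sd(a) == 0 || stats::sd(b) == 0)
      stopf("constant distance vector for metric '%s' or '%s'", nm[i], nm[j])
    r <- stats::cor(a, b)
    row <- data.frame(metric_a = nm[i], metric_b = nm[j], correlation = r,
                      n_pairs = sum(ut), stringsAsFactors = FALSE)
    if (mantel_permutations > 0) {
      k <- nrow(matrices[[i]])
      perm_r <- with_seed(spawn_seed(seed, ci), {
        vapply(seq_len(mantel_permutations), function(s) {
          pp <- sample.int(k)
          stats::cor(matrices[[i]][pp, pp][ut], b)
        }, numeric(1))
      })
      row$mantel_p <- (1 + sum(abs(perm_r) >= abs(r))) /
        (1 + mantel_permutations)
    }
    row
  }))
  rownames(out) <- NULL
  out
}
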