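# Human-derived latent feature vectors: crowd-kernel ordinal embedding from
# triplet judgments, with random holdout evaluation and dimension selection.
#
# The likelihood is the crowd-kernel ratio model with a single scalar
# regularizer mu: given anchor a and options b, c,
#   P(b chosen) = (mu + |x_a - x_c|^2) / (2 mu + |x_a - x_b|^2 + |x_a - x_c|^2).
# Coordinates are estimated by full-batch gradient descent on the total
# negative log likelihood with backtracking step-halving, best of several
# random restarts.

# Accept triplets either as (anchor_id, chosen_id, rejected_id) or as the
# raw judgment schema (anchor_id, left_id, right_id, chosen_id).
normalize_triplets <- function(triplets) {
  if (all(c("anchor_id", "chosen_id", "rejected_id") %in% names(triplets)))
    return(triplets[, c("anchor_id", "chosen_id", "rejected_id")])
  need <- c("anchor_id", "left_id", "right_id", "chosen_id")
  if (!all(need %in% names(triplets)))
    stopf("triplets must have columns %s", paste(need, collapse = ", "))
  bad <- !(triplets$chosen_id == triplets$left_id |
             triplets$chosen_id == triplets$right_id)
  if (any(bad)) stopf("%d triplet(s) with chosen_id not among the options",
                      sum(bad))
  data.frame(anchor_id = triplets$anchor_id,
             chosen_id = triplets$chosen_id,
             rejected_id = ifelse(triplets$chosen_id == triplets$left_id,
                                  triplets$right_id, triplets$left_id),
             stringsAsFactors = FALSE)
}

#' Crowd-kernel triplet choice probability
#'
#' Probability that option b is judged more similar to anchor a than option
#' c under the crowd-kernel ratio model with regularizer mu.
#'
#' @param x_a,x_b,x_c numeric coordinate vectors (or matrices with one row
#'   per triplet).
#' @param mu positive regularizer; large mu pushes all probabilities to 1/2.
#' @return probability in (0, 1) (vectorized over rows).
#' @examples
#' triplet_probability(c(0, 0), c(0, 0), c(1, 0), mu = 0.1)  # 1.1 / 1.2
#' @export
triplet_probability <- function(x_a, x_b, x_c, mu = 0.1) {
  assert_scalar_number(mu, "mu", lower = 0)
  if (mu <= 0) stopf("'mu' must be positive")
  to_m <- function(x) if (is.matrix(x)) x else matrix(x, nrow = 1)
  a <- to_m(x_a); b <- to_m(x_b); cc <- to_m(x_c)
  d2b <- rowSums((a - b)^2)
  d2c <- rowSums((a - cc)^2)
  (mu + d2c) / (2 * mu + d2b + d2c)
}

#' Split triplet judgments into train and holdout sets
#'
#' @param triplets triplet data.frame.
#' @param fraction holdout fraction in (0, 1); the holdout gets
#'   \code{round(fraction * n)} trials.
#' @param seed integer seed.
#' @return list(train, test) -- a disjoint, exhaustive partition.
#' @export
split_holdout <- function(triplets, fraction = 0.10, seed = 1L) {
  n <- nrow(triplets)
  if (n < 10L) stopf("need at least 10 triplets to split")
  assert_scalar_number(fraction, "fraction", 0, 1)
  n_test <- round(fraction * n)
  if (n_test < 1L || n_test >= n)
    stopf("fraction %.3f leaves an empty partition", fraction)
  idx <- with_seed(seed, sample.int(n, n_test))
  list(train = triplets[-idx, , drop = FALSE],
       test = triplets[idx, , drop = FALSE])
}

# Holdout scoring: a triplet is correct when the chosen option is strictly
# nearer the anchor in the fitted space; exact distance ties score 0.5.
# Triplets referencing ids absent from the embedding are skipped.
score_triplets <- function(coords, triplets) {
  tr <- normalize_triplets(triplets)
  ids <- rownames(coords)
  ia <- match(tr$anchor_id, ids)
  ic <- match(tr$chosen_id, ids)
  ir <- match(tr$rejected_id, ids)
  ok <- !(is.na(ia) | is.na(ic) | is.na(ir))
  skipped <- sum(!ok)
  ia <- ia[ok]; ic <- ic[ok]; ir <- ir[ok]
  if (!length(ia)) return(list(accuracy = NA_real_, n = 0L,
                               skipped = skipped))
  dc <- rowSums((coords[ia, , drop = FALSE] - coords[ic, , drop = FALSE])^2)
  dr <- rowSums((coords[ia, , drop = FALSE] - coords[ir, , drop = FALSE])^2)
  acc <- mean(ifelse(dc < dr, 1, ifelse(dc > dr, 0, 0.5)))
  list(accuracy = acc, n = length(ia), skipped = skipped)
}

ck_loss <- function(coords, ia, ic, ir, mu) {
  dc <- rowSums((coords[ia, , drop = FALSE] - coords[ic, , drop = FALSE])^2)
  dr <- rowSums((coords[ia, , drop = FALSE] - coords[ir, , drop = FALSE])^2)
  -sum(log(mu + dr) - log(2 * mu + dc + dr))
}

ck_gradient <- function(coords, ia, ic, ir, mu) {
  k <- nrow(coords)
  va <- coords[ia, , drop = FALSE]
  vc <- va - coords[ic, , drop = FALSE]
  vr <- va - coords[ir, , drop = FALSE]
  dc <- rowSums(vc^2)
  dr <- rowSums(vr^2)
  a_term <- mu + dr
  b_term <- 2 * mu + dc + dr
  g_dc <- 1 / b_term               # dNLL / d dc
  g_dr <- 1 / b_term - 1 / a_term  # dNLL / d dr
  gc_ <- 2 * g_dc * vc
  gr_ <- 2 * g_dr * vr
  acc <- function(idx, m) {
    rs <- rowsum(m, idx)
    out <- matrix(0, k, ncol(coords))
    out[as.integer(rownames(rs)), ] <- rs
    out
  }
  acc(ia, gc_ + gr_) - acc(ic, gc_) - acc(ir, gr_)
}

#' Fit a crowd-kernel ordinal embedding from triplet judgments
#'
#' Estimates k x d coordinates by maximizing the crowd-kernel likelihood of
#' the training triplets (full-batch gradient descent with backtracking
#' step-halving, best of \code{restarts} random initializations), then
#' evaluates the embedding on a random holdout set never used in fitting:
#' the holdout accuracy is the fraction of held-out triplets whose chosen
#' option is strictly nearer the anchor (distance ties count one half).
#'
#' @param triplets triplet judgments (raw left/right/chosen schema or
#'   anchor/chosen/rejected).
#' @param dims embedding dimension (1-5 typical).
#' @param mu positive crowd-kernel regularizer.
#' @param holdout_fraction fraction of trials withheld for evaluation; set
#'   to 0 to train on everything (holdout accuracy then NA).
#' @param max_iters maximum gradient iterations per restart.
#' @param restarts number of random restarts; best train loss wins.
#' @param learning_rate initial step size.
#' @param tol relative loss-improvement convergence tolerance.
#' @param seed integer seed controlling the holdout split and
#'   initializations.
#' @param holdout optional pre-made list(train, test) from
#'   \code{\link{split_holdout}}; overrides \code{holdout_fraction}.
#' @return object of classes \code{crowd_kernel} and
#'   \code{sketch_embedding}: coords, loss trace of the winning restart,
#'   holdout accuracy and counts, convergence flag, and the fit settings.
#' @export
crowd_kernel <- function(triplets, dims = 2L, mu = 0.1,
                         holdout_fraction = 0.10, max_iters = 400L,
                         restarts = 3L, learning_rate = 0.05,
                         tol = 1e-8, seed = 1L, holdout = NULL) {
  if (mu <= 0) stopf("'mu' must be positive")
  dims <- as.integer(dims)
  if (dims < 1L) stopf("'dims' must be >= 1")
  if (is.null(holdout)) {
    holdout <- if (holdout_fraction > 0)
      split_holdout(triplets, holdout_fraction, seed = spawn_seed(seed, 91L))
    else list(train = triplets, test = NULL)
  }
  train <- normalize_triplets(holdout$train)
  ids <- sort(unique(c(train$anchor_id, train$chosen_id, train$rejected_id)))
  k <- length(ids)
  ia <- match(train$anchor_id, ids)
  ic <- match(train$chosen_id, ids)
  ir <- match(train$rejected_id, ids)

  best <- NULL
  for (r in seq_len(restarts)) {
    x <- with_seed(spawn_seed(seed, 100L + r),
                   matrix(stats::rnorm(k * dims, sd = 0.1), k, dims))
    lr <- learning_rate
    loss <- ck_loss(x, ia, ic, ir, mu)
    trace <- loss
    converged <- FALSE
    for (it in seq_len(max_iters)) {
      g <- ck_gradient(x, ia, ic, ir, mu)
      accepted <- FALSE
      for (h in 1:30) {
        x_new <- x - lr * g
        loss_new <- ck_loss(x_new, ia, ic, ir, mu)
        if (is.finite(loss_new) && loss_new <= loss) { accepted <- TRUE; break }
        lr <- lr / 2
      }
      if (!accepted) { converged <- TRUE; break }
      improve <- (loss - loss_new) / max(abs(loss), 1)
      x <- x_new
      loss <- loss_new
      trace <- c(trace, loss)
      lr <- lr * 1.1
      if (improve < tol) { converged <- TRUE; break }
    }
    if (is.null(best) || loss < best$loss)
      best <- list(x = x, loss = loss, trace = trace, converged = converged)
  }

  coords <- sweep(best$x, 2, colMeans(best$x))  # center (loss-invariant)
  coords <- canonicalize_axes(coords)
  rownames(coords) <- ids
  colnames(coords) <- paste0("x", seq_len(dims))
  sc <- if (!is.null(holdout$test) && nrow(holdout$test) > 0)
    score_triplets(coords, holdout$test)
  else list(accuracy = NA_real_, n = 0L, skipped = 0L)
  structure(list(coords = coords, dims = dims, mu = mu, seed = seed,
                 source = "human",
                 train_loss = best$loss, loss_trace = best$trace,
                 converged = best$converged,
                 holdout_accuracy = sc$accuracy,
                 holdout_n = sc$n, holdout_skipped = sc$skipped,
                 n_train = nrow(train), restarts = restarts),
            class = c("crowd_kernel", "sketch_embedding"))
}

#' @export
print.crowd_kernel <- function(x, ...) {
  cat(sprintf("Crowd-kernel ordinal embedding (%d items, %d dims, mu = %g)\n",
              nrow(x$coords), x$dims, x$mu))
  cat(sprintf("  train: %d triplets, final loss %.2f%s\n", x$n_train,
              x$train_loss, if (x$converged) "" else " (max iters reached)"))
  if (!is.na(x$holdout_accuracy))
    cat(sprintf("  holdout accuracy: %.3f on %d triplets (%d skipped)\n",
                x$holdout_accuracy, x$holdout_n, x$holdout_skipped))
  invisible(x)
}

#' @export
summary.crowd_kernel <- function(object, ...) {
  print(object)
  cat(sprintf("  loss trace: %d accepted steps, start %.2f -> end %.2f\n",
              length(object$loss_trace) - 1L, object$loss_trace[1],
              object$train_loss))
  invisible(object)
}

#' Predict choice probabilities for triplets from a fitted embedding
#'
#' @param object fitted \code{crowd_kernel}.
#' @param triplets triplet data.frame.
#' @param ... unused.
#' @return numeric vector: P(chosen option preferred) per triplet under the
#'   fitted coordinates and mu (NA for triplets with unknown ids).
#' @export
predict.crowd_kernel <- function(object, triplets, ...) {
  tr <- normalize_triplets(triplets)
  ids <- rownames(object$coords)
  ia <- match(tr$anchor_id, ids)
  ic <- match(tr$chosen_id, ids)
  ir <- match(tr$rejected_id, ids)
  out <- rep(NA_real_, nrow(tr))
  ok <- !(is.na(ia) | is.na(ic) | is.na(ir))
  out[ok] <- triplet_probability(object$coords[ia[ok], , drop = FALSE],
                                 object$coords[ic[ok], , drop = FALSE],
                                 object$coords[ir[ok], , drop = FALSE],
                                 mu = object$mu)
  out
}

#' Select the embedding dimension by holdout accuracy
#'
#' Fits crowd-kernel embeddings at each candidate dimension on a single
#' shared train/holdout split and returns the fit with the highest holdout
#' accuracy; ties are broken toward the smaller dimension. All candidate
#' accuracies are retained in the result.
#'
#' @param triplets triplet judgments.
#' @param dims_grid candidate dimensions (subset of 1..5 typical).
#' @param ... further arguments passed to \code{\link{crowd_kernel}}.
#' @param holdout_fraction shared holdout fraction.
#' @param seed integer seed (controls the shared split and all restarts).
#' @return the winning \code{crowd_kernel} fit, with an extra element
#'   \code{dimension_sweep}: data.frame(dims, holdout_accuracy, train_loss).
#' @export
select_dimension <- function(triplets, dims_grid = 1:5,
                             holdout_fraction = 0.10, seed = 1L, ...) {
  dims_grid <- as.integer(dims_grid)
  if (!length(dims_grid)) stopf("empty dimension grid")
  ho <- split_holdout(triplets, holdout_fraction,
                      seed = spawn_seed(seed, 91L))
  fits <- lapply(dims_grid, function(d)
    crowd_kernel(triplets, dims = d, holdout = ho, seed = seed, ...))
  accs <- vapply(fits, `[[`, numeric(1), "holdout_accuracy")
  ord <- order(-accs, dims_grid)    # max accuracy, ties toward smaller dims
  best <- fits[[ord[1]]]
  best$dimension_sweep <- data.frame(dims = dims_grid,
                                     holdout_accuracy = accs,
                                     train_loss = vapply(fits, `[[`,
                                                         numeric(1),
                                                         "train_loss"))
  best
}
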