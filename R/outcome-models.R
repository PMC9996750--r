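# Stepwise predictive harness: baseline checklist models, quality-rank
# substitution, embedding augmentation, nested ANOVA comparisons, adjusted
# R-squared for continuous outcomes, and repeated-holdout AUC for binary
# outcomes.
#
# Drawings are the analysis unit; a participant contributes one row per
# drawing. Model ladder (per outcome):
#   baseline:  outcome ~ checklist            + covariates
#   quality:   outcome ~ quality              + covariates
#              (increment tested by ANOVA of checklist*quality vs baseline)
#   human:     outcome ~ metric * (hx + hy)   + covariates
#   machine:   outcome ~ metric * (mx + my)   + covariates
#   both:      outcome ~ metric * (hx + hy) + metric * (mx + my) + covariates
# where "metric" is the better of checklist/quality at step 1 and each
# embedding step is compared to its reference by nested F-test (linear) or
# likelihood-ratio chi-square (logistic).

#' Prepare the merged per-drawing analysis table
#'
#' Joins per-drawing metrics to per-participant covariates/outcomes and
#' applies the configured transforms (log age for the demographic analyses).
#'
#' @param participants participant table (participant_id plus covariates and
#'   outcomes).
#' @param metrics per-drawing table with drawing_id, participant_id,
#'   checklist, quality, hx, hy, mx, my.
#' @param log_age add a log_age column (error on non-positive ages).
#' @return merged data.frame, one row per drawing.
#' @export
prepare_outcomes <- function(participants, metrics, log_age = TRUE) {
  need <- c("drawing_id", "participant_id")
  if (!all(need %in% names(metrics)))
    stopf("metrics must have drawing_id and participant_id")
  idx <- match(metrics$participant_id, participants$participant_id)
  if (anyNA(idx))
    stopf("missing join keys: %d drawing(s) reference unknown participants",
          sum(is.na(idx)))
  out <- cbind(metrics,
               participants[idx, setdiff(names(participants),
                                         "participant_id"), drop = FALSE])
  if (log_age) {
    if (any(out$age_months <= 0))
      stopf("non-positive age under log transform")
    out$log_age <- log(out$age_months)
  }
  rownames(out) <- NULL
  out
}

#' Adjusted R-squared
#'
#' @param r2 multiple R-squared.
#' @param n observations.
#' @param p non-intercept parameters.
#' @return 1 - (1 - r2) (n - 1) / (n - p - 1).
#' @export
adjusted_r2 <- function(r2, n, p) 1 - (1 - r2) * (n - 1) / (n - p - 1)

ladder_formulas <- function(outcome, covariates) {
  cov_term <- if (length(covariates))
    paste("+", paste(covariates, collapse = " + ")) else ""
  f <- function(rhs) stats::as.formula(paste(outcome, "~", rhs, cov_term))
  list(f = f)
}

# Shared ladder-construction logic: returns the ordered list of formulas,
# each step's reference step, and the selected step-1 metric.
build_ladder <- function(outcome, covariates, include_both, step1_by,
                         data) {
  fb <- ladder_formulas(outcome, covariates)$f
  fits_step1 <- list(baseline = stats::lm(fb("checklist"), data = data),
                     quality = stats::lm(fb("quality"), data = data))
  a1 <- summary(fits_step1$baseline)$adj.r.squared
  a2 <- summary(fits_step1$quality)$adj.r.squared
  metric <- if (step1_by == "quality" || a2 >= a1) "quality" else "checklist"
  emb <- function(cs) sprintf("%s * (%s)", metric, paste(cs, collapse = " + "))
  steps <- list(
    baseline = list(rhs = "checklist", ref = NA_character_),
    quality = list(rhs = "quality", ref = "baseline",
                   # the increment is tested with both metrics in the model
                   test_rhs = "checklist * quality"),
    human = list(rhs = emb(c("hx", "hy")), ref = "step1"),
    machine = list(rhs = emb(c("mx", "my")), ref = "step1"))
  if (include_both)
    steps$both <- list(rhs = paste(emb(c("hx", "hy")), "+",
                                   emb(c("mx", "my"))),
                       ref = "best_embedding")
  list(steps = steps, metric = metric, f = fb)
}

#' Fit the stepwise linear model ladder for a continuous outcome
#'
#' Ordinary least-squares fits in the step order baseline (checklist),
#' quality-rank, +human embedding, +machine embedding, and (optionally)
#' both embeddings, on the complete rows for the outcome. Each step is
#' compared to its reference by a nested F-test; the quality step's
#' increment over the checklist is tested by comparing the model containing
#' both metrics and their interaction against the baseline.
#'
#' @param data merged analysis table from \code{\link{prepare_outcomes}}.
#' @param outcome name of the continuous outcome column.
#' @param covariates character vector of covariate terms of no interest
#'   (e.g. \code{"gender"} for age, \code{"age_months * gender"} for the
#'   motor/ASQ analyses).
#' @param include_both "auto" fits the joint-embedding step only when the
#'   parameter count stays below \code{max_param_fraction} of n; TRUE/FALSE
#'   force it.
#' @param subset optional logical vector choosing analysis rows (e.g. an
#'   availability flag).
#' @param max_param_fraction guard for "auto".
#' @return object of class \code{model_ladder}: per-step fits, a tidy
#'   summary table (n, multiple and adjusted R-squared, comparison p-value
#'   and reference), and the selected step-1 metric.
#' @export
fit_linear_ladder <- function(data, outcome, covariates = character(0),
                              include_both = "auto", subset = NULL,
                              max_param_fraction = 0.1) {
  if (!is.null(subset)) data <- data[subset, , drop = FALSE]
  vars <- unique(c(outcome, "checklist", "quality", "hx", "hy", "mx", "my",
                   all.vars(stats::as.formula(
                     paste("~", paste(c("1", covariates), collapse = "+"))))))
  data <- data[stats::complete.cases(data[, intersect(vars, names(data))]), ,
               drop = FALSE]
  n <- nrow(data)
  lad <- build_ladder(outcome, covariates, TRUE, "best", data)
  # parameter guard for the joint-embedding step
  p_both <- length(attr(stats::terms(lad$f(lad$steps$both$rhs)),
                        "term.labels")) + 1L
  keep_both <- isTRUE(include_both) ||
    (identical(include_both, "auto") && p_both <= max_param_fraction * n)
  if (!keep_both) lad$steps$both <- NULL

  fits <- list(); tests <- list()
  summary_rows <- list()
  adj <- function(fit) summary(fit)$adj.r.squared
  for (nm in names(lad$steps)) {
    st <- lad$steps[[nm]]
    fit <- stats::lm(lad$f(st$rhs), data = data)
    if (any(is.na(stats::coef(fit))))
      stopf("collinear design at step '%s': %s", nm,
            paste(names(which(is.na(stats::coef(fit)))), collapse = ", "))
    fits[[nm]] <- fit
    ref_nm <- st$ref
    if (identical(ref_nm, "step1"))
      ref_nm <- if (lad$metric == "quality") "quality" else "baseline"
    if (identical(ref_nm, "best_embedding"))
      ref_nm <- if (adj(fits$human) >= adj(fits$machine)) "human" else "machine"
    p <- NA_real_
    if (!is.na(ref_nm)) {
      test_fit <- if (!is.null(st$test_rhs))
        stats::lm(lad$f(st$test_rhs), data = data) else fit
      p <- stats::anova(fits[[ref_nm]], test_fit)[2, "Pr(>F)"]
    }
    sm <- summary(fit)
    summary_rows[[nm]] <- data.frame(
      step = nm, n = n,
      n_params = length(stats::coef(fit)) - 1L,
      multiple_r2 = sm$r.squared,
      adjusted_r2 = sm$adj.r.squared,
      reference = ref_nm %||% NA_character_,
      p_value = p,
      stars = significance_stars(p),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, summary_rows)
  rownames(tab) <- NULL
  structure(list(outcome = outcome, family = "linear",
                 covariates = covariates, metric = lad$metric,
                 fits = fits, table = tab, n = n),
            class = "model_ladder")
}

#' Fit the stepwise logistic ladder for a binary outcome with repeated
#' holdout AUC
#'
#' Same step structure as \code{\link{fit_linear_ladder}}, with logistic
#' regression fits. Each step's predictive performance is the mean AUC over
#' \code{folds} random 90/10 splits (fit on the training part, AUC by the
#' rank formulation on the held-out part; folds whose training part lacks a
#' class or whose test part is single-class are redrawn and counted).
#' Step significance is the likelihood-ratio chi-square test between
#' full-data fits.
#'
#' @param data merged analysis table.
#' @param outcome name of the binary outcome column.
#' @param covariates covariate terms of no interest.
#' @param folds number of random holdout repetitions (default 100).
#' @param test_fraction held-out fraction per fold (default 0.10).
#' @param include_both,subset,max_param_fraction see
#'   \code{\link{fit_linear_ladder}}.
#' @param seed integer seed for the fold draws.
#' @return \code{model_ladder} object (family = "logistic") whose table has
#'   mean_auc per step; per-fold AUC vectors are kept in \code{auc_folds}.
#' @export
fit_logistic_auc <- function(data, outcome, covariates = character(0),
                             folds = 100L, test_fraction = 0.10,
                             include_both = "auto", subset = NULL,
                             max_param_fraction = 0.1, seed = 1L) {
  if (!is.null(subset)) data <- data[subset, , drop = FALSE]
  vars <- unique(c(outcome, "checklist", "quality", "hx", "hy", "mx", "my",
                   all.vars(stats::as.formula(
                     paste("~", paste(c("1", covariates), collapse = "+"))))))
  data <- data[stats::complete.cases(data[, intersect(vars, names(data))]), ,
               drop = FALSE]
  n <- nrow(data)
  y <- as_binary(data[[outcome]])
  if (length(unique(y)) < 2L) stopf("single-class outcome")
  data$.y <- y
  lad <- build_ladder(".y", covariates, TRUE, "best", data)
  # step-1 metric for logistic: higher full-data deviance reduction
  dev <- function(rhs) stats::glm(lad$f(rhs), data = data,
                                  family = stats::binomial())$deviance
  lad$metric <- if (dev("quality") <= dev("checklist")) "quality"
                else "checklist"
  emb <- function(cs) sprintf("%s * (%s)", lad$metric,
                              paste(cs, collapse = " + "))
  lad$steps$human$rhs <- emb(c("hx", "hy"))
  lad$steps$machine$rhs <- emb(c("mx", "my"))
  p_both <- length(attr(stats::terms(lad$f(paste(emb(c("hx", "hy")), "+",
                                                 emb(c("mx", "my"))))),
                        "term.labels")) + 1L
  keep_both <- isTRUE(include_both) ||
    (identical(include_both, "auto") && p_both <= max_param_fraction * n)
  if (keep_both) {
    lad$steps$both$rhs <- paste(emb(c("hx", "hy")), "+", emb(c("mx", "my")))
  } else lad$steps$both <- NULL

  n_test <- max(1L, round(test_fraction * n))
  if (n_test >= n) stopf("test fraction leaves no training data")
  # pre-draw the fold test sets once so every step sees identical folds
  fold_sets <- with_seed(spawn_seed(seed, 7L), {
    lapply(seq_len(folds), function(f) {
      for (try in 1:100) {
        te <- sample.int(n, n_test)
        if (length(unique(y[-te])) == 2L && length(unique(y[te])) == 2L)
          return(te)
      }
      stopf("could not draw a fold with both classes present")
    })
  })

  fits <- list(); auc_folds <- list(); summary_rows <- list()
  for (nm in names(lad$steps)) {
    st <- lad$steps[[nm]]
    form <- lad$f(st$rhs)
    fit <- suppressWarnings(stats::glm(form, data = data,
                                       family = stats::binomial()))
    fits[[nm]] <- fit
    aucs <- vapply(fold_sets, function(te) {
      m <- suppressWarnings(stats::glm(form, data = data[-te, , drop = FALSE],
                                       family = stats::binomial()))
      sc <- suppressWarnings(stats::predict(m, newdata = data[te, , drop = FALSE],
                                            type = "link"))
      auc_rank(sc, y[te])
    }, numeric(1))
    ref_nm <- st$ref
    if (identical(ref_nm, "step1"))
      ref_nm <- if (lad$metric == "quality") "quality" else "baseline"
    if (identical(ref_nm, "best_embedding"))
      ref_nm <- if (mean(auc_folds$human) >= mean(auc_folds$machine))
        "human" else "machine"
    p <- NA_real_
    if (!is.na(ref_nm)) {
      test_fit <- if (!is.null(st$test_rhs))
        suppressWarnings(stats::glm(lad$f(st$test_rhs), data = data,
                                    family = stats::binomial())) else fit
      lrt <- stats::anova(fits[[ref_nm]], test_fit, test = "Chisq")
      p <- lrt[2, "Pr(>Chi)"]
    }
    auc_folds[[nm]] <- aucs
    summary_rows[[nm]] <- data.frame(
      step = nm, n = n,
      n_params = length(stats::coef(fit)) - 1L,
      mean_auc = mean(aucs),
      reference = ref_nm %||% NA_character_,
      p_value = p,
      stars = significance_stars(p),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, summary_rows)
  rownames(tab) <- NULL
  structure(list(outcome = outcome, family = "logistic",
                 covariates = covariates, metric = lad$metric,
                 fits = fits, table = tab, auc_folds = auc_folds,
                 n = n, folds = folds, test_fraction = test_fraction,
                 seed = seed),
            class = "model_ladder")
}

#' @export
print.model_ladder <- function(x, ...) {
  cat(sprintf("Stepwise %s model ladder for '%s' (n = %d drawings)\n",
              x$family, x$outcome, x$n))
  if (length(x$covariates))
    cat("  covariates of no interest:", paste(x$covariates, collapse = ", "),
        "\n")
  cat("  step-1 metric retained:", x$metric, "\n")
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(v) round(v, 3))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.model_ladder <- function(object, ...) {
  print(object)
  for (nm in names(object$fits)) {
    cat("\n--- step:", nm, "---\n")
    print(stats::formula(object$fits[[nm]]))
  }
  invisible(object)
}

#' @export
plot.model_ladder <- function(x, ...) {
  tab <- x$table
  stat <- if (x$family == "linear") tab$adjusted_r2 else tab$mean_auc
  graphics::barplot(stat, names.arg = tab$step,
                    ylab = if (x$family == "linear") "adjusted R^2"
                           else "mean holdout AUC",
                    main = x$outcome, las = 2, ...)
  invisible(x)
}

#' Assemble results tables across outcome ladders
#'
#' Collects the per-step statistics of a set of fitted ladders into one
#' machine-readable table (one row per outcome, one column group per ladder
#' step) with significance stars at the 0.05/0.01/0.001 thresholds.
#'
#' @param ladders named list of \code{model_ladder} objects (names =
#'   outcome labels).
#' @return data.frame with columns outcome, n, metric, and per step the fit
#'   statistic (adjusted R-squared or mean AUC) with stars, plus the
#'   comparison reference.
#' @export
results_tables <- function(ladders) {
  rows <- lapply(names(ladders), function(nm) {
    l <- ladders[[nm]]
    tab <- l$table
    stat <- if (l$family == "linear") tab$adjusted_r2 else tab$mean_auc
    vals <- sprintf("%.2f%s", stat, tab$stars)
    names(vals) <- tab$step
    base <- data.frame(outcome = nm, family = l$family, n = l$n,
                       metric = l$metric, stringsAsFactors = FALSE)
    for (s in c("baseline", "quality", "human", "machine", "both"))
      base[[s]] <- if (s %in% names(vals)) vals[[s]] else NA_character_
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
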