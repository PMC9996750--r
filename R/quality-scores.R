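# Scalar drawing-quality metrics: the crowd-sourced quality-rank score from
# pairwise forced-choice judgments, the 12-item Draw-A-Child checklist score
# from two raters, and inter-rater reliability.

#' Quality-rank scores from pairwise judgments
#'
#' For each drawing, the proportion of pairwise "better drawing" trials it
#' won among all trials in which it appeared. Drawings listed in
#' \code{drawing_ids} that never appeared in any trial are reported with an
#' NA score (never shown is not the same as always rejected).
#'
#' @param pairs data.frame with left_id, right_id, chosen_id.
#' @param drawing_ids optional full roster of drawing ids to report on.
#' @return data.frame: drawing_id, wins, appearances, score (wins /
#'   appearances in [0, 1], NA when appearances = 0).
#' @export
quality_rank <- function(pairs, drawing_ids = NULL) {
  need <- c("left_id", "right_id", "chosen_id")
  if (!all(need %in% names(pairs)))
    stopf("pairs must have columns %s", paste(need, collapse = ", "))
  if (nrow(pairs) < 1L) stopf("need at least one trial")
  bad <- !(pairs$chosen_id == pairs$left_id |
             pairs$chosen_id == pairs$right_id)
  if (any(bad))
    stopf("%d malformed record(s): chosen_id not among the two shown",
          sum(bad))
  if (any(pairs$left_id == pairs$right_id))
    stopf("malformed record(s): left_id equals right_id")
  ids <- drawing_ids %||%
    sort(unique(c(pairs$left_id, pairs$right_id)))
  app <- table(factor(c(pairs$left_id, pairs$right_id), levels = ids))
  wins <- table(factor(pairs$chosen_id, levels = ids))
  out <- data.frame(drawing_id = ids,
                    wins = as.integer(wins),
                    appearances = as.integer(app),
                    stringsAsFactors = FALSE)
  out$score <- ifelse(out$appearances > 0, out$wins / out$appearances,
                      NA_real_)
  out
}

#' Checklist scores from two raters
#'
#' Per-rater score is the count of detected items (0-12); the final score is
#' the mean of the two raters, in [0, 12].
#'
#' @param raters long data.frame from \code{\link{simulate_checklist_raters}}
#'   (drawing_id, rater in 1:2, item_* indicators) or any table with
#'   drawing_id, rater and score columns.
#' @return data.frame: drawing_id, rater1, rater2, final, plus per-item
#'   agreement columns item_* (mean of the two raters' indicators) when item
#'   columns are present.
#' @export
checklist_scores <- function(raters) {
  if (!all(c("drawing_id", "rater") %in% names(raters)))
    stopf("raters table needs drawing_id and rater columns")
  item_cols <- grep("^item_", names(raters), value = TRUE)
  if (!"score" %in% names(raters)) {
    if (!length(item_cols)) stopf("raters table needs item_* or score")
    raters$score <- rowSums(raters[, item_cols, drop = FALSE])
  }
  r1 <- raters[raters$rater == 1L, ]
  r2 <- raters[raters$rater == 2L, ]
  only_one <- union(setdiff(r1$drawing_id, r2$drawing_id),
                    setdiff(r2$drawing_id, r1$drawing_id))
  if (length(only_one))
    stopf("drawing(s) scored by only one rater: %s",
          paste(utils::head(only_one, 5), collapse = ", "))
  m <- match(r1$drawing_id, r2$drawing_id)
  out <- data.frame(drawing_id = r1$drawing_id,
                    rater1 = as.numeric(r1$score),
                    rater2 = as.numeric(r2$score[m]),
                    stringsAsFactors = FALSE)
  out$final <- (out$rater1 + out$rater2) / 2
  if (length(item_cols)) {
    items <- (as.matrix(r1[, item_cols]) +
                as.matrix(r2[m, item_cols])) / 2
    out <- cbind(out, as.data.frame(items))
  }
  out
}

#' Inter-rater reliability of the checklist
#'
#' Pearson product-moment correlation between the two raters, either of the
#' per-drawing total scores (\code{by = "drawing"}) or averaged over the 12
#' per-item indicator correlations (\code{by = "item"}).
#'
#' @param raters long rater table (see \code{\link{checklist_scores}}).
#' @param by "drawing" or "item".
#' @return correlation coefficient (NA with a warning if a score vector is
#'   constant, where the correlation is undefined).
#' @export
interrater_reliability <- function(raters, by = c("drawing", "item")) {
  by <- match.arg(by)
  chk <- checklist_scores(raters)
  if (nrow(chk) < 3L) stopf("need at least 3 drawings")
  if (by == "drawing") {
    if (stats::sd(chk$rater1) == 0 || stats::sd(chk$rater2) == 0) {
      warning("constant rater scores: correlation undefined")
      return(NA_real_)
    }
    return(stats::cor(chk$rater1, chk$rater2))
  }
  item_cols <- grep("^item_", names(raters), value = TRUE)
  if (!length(item_cols)) stopf("per-item reliability needs item_* columns")
  r1 <- raters[raters$rater == 1L, ]
  r2 <- raters[raters$rater == 2L, ]
  m <- match(r1$drawing_id, r2$drawing_id)
  rs <- vapply(item_cols, function(cl) {
    a <- r1[[cl]]; b <- r2[[cl]][m]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_
    else stats::cor(a, b)
  }, numeric(1))
  mean(rs, na.rm = TRUE)
}

#' Bradley-Terry strengths from pairwise judgments (diagnostic)
#'
#' Maximum-likelihood Bradley-Terry abilities via the standard
#' minorization-maximization iteration. This is a diagnostic alternative to
#' the raw win-proportion quality-rank score, not part of the primary
#' metric set.
#'
#' @param pairs pairwise judgment table.
#' @param max_iters,tol iteration controls.
#' @return data.frame: drawing_id, strength (normalized to mean 1 on the
#'   strength scale).
#' @export
bradley_terry <- function(pairs, max_iters = 500L, tol = 1e-10) {
  ids <- sort(unique(c(pairs$left_id, pairs$right_id)))
  k <- length(ids)
  i <- match(pairs$left_id, ids); j <- match(pairs$right_id, ids)
  wi <- match(pairs$chosen_id, ids)
  wins <- tabulate(wi, k)
  p <- rep(1, k)
  for (it in seq_len(max_iters)) {
    denom <- 1 / (p[i] + p[j])
    tot <- numeric(k)
    agg <- rowsum(c(denom, denom), c(i, j))
    tot[as.integer(rownames(agg))] <- agg
    p_new <- wins / pmax(tot, 1e-12)
    p_new <- pmax(p_new, 1e-12)
    p_new <- p_new / mean(p_new)
    if (max(abs(p_new - p)) < tol) { p <- p_new; break }
    p <- p_new
  }
  data.frame(drawing_id = ids, strength = p, stringsAsFactors = FALSE)
}
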