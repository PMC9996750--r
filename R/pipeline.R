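# End-to-end orchestration: generate (or ingest) a dataset, run every
# metric computation and analysis, and write a reproducible run directory
# of CSV tables and JSON reports. One master seed deterministically spawns
# per-stage seeds.

#' Run configuration
#'
#' @param profile "desk" (60 drawings, 3,000 triplets, 1,500 pairs; the
#'   default working scale) or "study" (the full published-cohort scale: ~154
#'   participants / ~305 drawings, 31,832 triplets, 10,107 pairs).
#' @param ... overrides for any field: seed, study (a
#'   \code{\link{study_config}} list), n_triplets, n_pairs, decision_noise,
#'   discrimination, miss_rate, false_alarm_rate, canvas, dims,
#'   dims_grid (NULL to skip the dimension sweep), write_png.
#' @return list of class \code{sketch_run_config}.
#' @export
run_config <- function(profile = c("desk", "study"), ...) {
  profile <- match.arg(profile)
  cfg <- if (profile == "desk") {
    list(profile = "desk", seed = 1L,
         study = study_config(n_participants = 30L, n_adults = 5L,
                              media_weights = c(1, 1, 1)),
         n_triplets = 3000L, n_pairs = 1500L,
         decision_noise = 0.1, discrimination = 10,
         miss_rate = 0.05, false_alarm_rate = 0.02,
         canvas = 224L, dims = 2L, dims_grid = NULL,
         ck_max_iters = 300L, ck_restarts = 2L,
         auc_folds = 100L, write_png = FALSE)
  } else {
    list(profile = "study", seed = 1L,
         study = study_config(),
         n_triplets = 31832L, n_pairs = 10107L,
         decision_noise = 0.1, discrimination = 10,
         miss_rate = 0.05, false_alarm_rate = 0.02,
         canvas = 224L, dims = 2L, dims_grid = 1:5,
         ck_max_iters = 400L, ck_restarts = 3L,
         auc_folds = 100L, write_png = TRUE)
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stopf("unknown run_config field(s): %s", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "sketch_run_config"
  cfg
}

write_csv_out <- function(df, dir, name) {
  utils::write.csv(df, file.path(dir, name), row.names = FALSE)
}

embedding_table <- function(e) {
  co <- embedding_coords(e)
  data.frame(drawing_id = rownames(co), as.data.frame(co),
             stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes synthetic-data generation, image preparation, machine
#' embedding, crowd-kernel ordinal embedding, quality scoring, structure
#' comparison, and the outcome-model harness, writing every intermediate
#' table plus a summary report into \code{out_dir}. Identical
#' configurations produce byte-identical CSV outputs.
#'
#' @param config \code{\link{run_config}} list.
#' @param out_dir output directory (created if absent).
#' @param inputs optional pre-built study list (participants, drawings,
#'   triplets, pairs, raters), e.g. from \code{\link{ingest_real}}; when
#'   supplied the synthetic-data stage is bypassed.
#' @return (invisibly) list with all stage outputs; files are written under
#'   \code{out_dir}.
#' @export
run_all <- function(config = run_config(), out_dir, inputs = NULL) {
  stage <- "setup"
  on.exit(if (!is.null(stage))
    message(sprintf("pipeline aborted during stage '%s'", stage)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  stage <- "synthetic_data"
  study <- inputs %||% simulate_study(
    config = config$study, n_triplets = config$n_triplets,
    n_pairs = config$n_pairs, decision_noise = config$decision_noise,
    discrimination = config$discrimination, miss_rate = config$miss_rate,
    false_alarm_rate = config$false_alarm_rate, seed = spawn_seed(seed, 1L))
  write_csv_out(study$participants, out_dir, "participants.csv")
  write_csv_out(study$drawings, out_dir, "ground_truth.csv")
  write_csv_out(study$triplets, out_dir, "triplets.csv")
  write_csv_out(study$pairs, out_dir, "pairs.csv")
  write_csv_out(study$raters, out_dir, "raters.csv")

  stage <- "image_prep"
  bitmaps <- if (!is.null(study$bitmaps)) study$bitmaps
    else render_all(study$drawings, config$canvas)
  bitmaps <- lapply(bitmaps, prep_image, side = config$canvas)
  if (isTRUE(config$write_png)) {
    png_dir <- file.path(out_dir, "drawings")
    dir.create(png_dir, showWarnings = FALSE)
    for (id in names(bitmaps))
      write_drawing(bitmaps[[id]], file.path(png_dir, paste0(id, ".png")))
  }

  stage <- "machine_embedding"
  extractor <- reference_extractor(input_side = config$canvas)
  features <- extract_features(bitmaps, extractor)
  sim <- cosine_matrix(features)
  e_machine <- classical_mds(sim, d = config$dims)
  write_csv_out(embedding_table(e_machine), out_dir, "embedding_machine.csv")

  stage <- "ordinal_embedding"
  e_human <- if (!is.null(config$dims_grid)) {
    select_dimension(study$triplets, dims_grid = config$dims_grid,
                     max_iters = config$ck_max_iters,
                     restarts = config$ck_restarts,
                     seed = spawn_seed(seed, 2L))
  } else {
    crowd_kernel(study$triplets, dims = config$dims,
                 max_iters = config$ck_max_iters,
                 restarts = config$ck_restarts,
                 seed = spawn_seed(seed, 2L))
  }
  write_csv_out(embedding_table(e_human), out_dir, "embedding_human.csv")
  fit_report <- list(dims = e_human$dims, mu = e_human$mu,
                     train_loss = e_human$train_loss,
                     holdout_accuracy = e_human$holdout_accuracy,
                     holdout_n = e_human$holdout_n,
                     seed = e_human$seed)
  if (!is.null(e_human$dimension_sweep))
    fit_report$dimension_sweep <- e_human$dimension_sweep
  jsonlite::write_json(fit_report, file.path(out_dir, "fit_report.json"),
                       auto_unbox = TRUE, digits = NA)

  stage <- "quality_scores"
  quality <- quality_rank(study$pairs,
                          drawing_ids = study$drawings$drawing_id)
  checklist <- checklist_scores(study$raters)
  reliability <- interrater_reliability(study$raters)
  write_csv_out(quality, out_dir, "quality.csv")
  write_csv_out(checklist[, c("drawing_id", "rater1", "rater2", "final")],
                out_dir, "checklist.csv")

  stage <- "embedding_compare"
  scored <- !is.na(quality$score)
  common <- intersect(rownames(e_machine$coords)[
    rownames(e_machine$coords) %in% quality$drawing_id[scored]],
    rownames(e_human$coords))
  hm <- e_human$coords[common, , drop = FALSE]
  mm <- e_machine$coords[common, , drop = FALSE]
  chk_vec <- stats::setNames(checklist$final, checklist$drawing_id)[common]
  overlap <- nn_overlap(hm, mm, K = min(10L, length(common) - 1L))
  tab1 <- cross_space_regression(hm[, 1:2], mm[, 1:2])
  qual_df <- quality[match(common, quality$drawing_id), ]
  chk_df <- checklist[match(common, checklist$drawing_id), ]
  tab2 <- checklist_prediction_ladder(chk_df, qual_df,
                                      hm[, 1:2], mm[, 1:2])
  dmats <- list(human = metric_distances(hm),
                machine = metric_distances(mm),
                checklist = metric_distances(chk_vec))
  dist_cor <- distance_metric_correlations(dmats)
  write_csv_out(tab1, out_dir, "table1_cross_space.csv")
  write_csv_out(tab2, out_dir, "table2_checklist_prediction.csv")
  write_csv_out(dist_cor, out_dir, "distance_correlations.csv")

  stage <- "outcome_models"
  metrics <- data.frame(
    drawing_id = common,
    participant_id = study$drawings$participant_id[
      match(common, study$drawings$drawing_id)],
    checklist = chk_vec,
    quality = qual_df$score,
    hx = hm[, 1], hy = hm[, 2], mx = mm[, 1], my = mm[, 2],
    stringsAsFactors = FALSE)
  analysis <- prepare_outcomes(study$participants, metrics, log_age = TRUE)
  ladders <- list(
    age = fit_linear_ladder(analysis, "log_age", covariates = "gender"),
    gender = fit_logistic_auc(analysis, "gender", covariates = "log_age",
                              folds = config$auc_folds,
                              seed = spawn_seed(seed, 3L)))
  motor_cov <- "age_months * gender"
  for (oc in c("asq_total", "asq_communication", "asq_gross_motor",
               "asq_fine_motor", "asq_problem_solving",
               "asq_personal_social")) {
    sub <- analysis$asq_available
    if (sum(sub, na.rm = TRUE) >= 30)
      ladders[[oc]] <- fit_linear_ladder(analysis, oc,
                                         covariates = motor_cov,
                                         subset = sub)
  }
  for (oc in c("grip", "pinch")) {
    sub <- analysis$motor_available
    if (sum(sub, na.rm = TRUE) >= 30)
      ladders[[oc]] <- fit_linear_ladder(analysis, oc,
                                         covariates = motor_cov,
                                         subset = sub)
  }
  tables34 <- results_tables(ladders)
  write_csv_out(tables34, out_dir, "tables3_4.csv")

  stage <- "report"
  report <- list(
    profile = config$profile, seed = seed,
    n_participants = nrow(study$participants),
    n_drawings = nrow(study$drawings),
    n_triplets = nrow(study$triplets),
    n_pairs = nrow(study$pairs),
    human_dims = e_human$dims,
    human_holdout_accuracy = e_human$holdout_accuracy,
    interrater_reliability = reliability,
    checklist_quality_correlation = stats::cor(chk_df$final, qual_df$score),
    nn_overlap = as.list(overlap))
  jsonlite::write_json(report, file.path(out_dir, "summary_report.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(c("stages completed: synthetic_data image_prep",
               "machine_embedding ordinal_embedding quality_scores",
               "embedding_compare outcome_models report"),
             file.path(out_dir, "run_log.txt"))
  stage <- NULL
  invisible(list(study = study, bitmaps = bitmaps, features = features,
                 machine = e_machine, human = e_human, quality = quality,
                 checklist = checklist, table1 = tab1, table2 = tab2,
                 distance_correlations = dist_cor, ladders = ladders,
                 tables3_4 = tables34, report = report))
}

#' Ingest an externally collected drawing study
#'
#' Reads a real study from the module CSV schemas (and a PNG manifest) into
#' the same structure \code{\link{run_all}} consumes via its \code{inputs}
#' argument, validating referential integrity.
#'
#' @param manifest data.frame with drawing_id, path (PNG files), or NULL to
#'   skip images (machine-embedding stage then requires bitmaps supplied
#'   separately).
#' @param participants,triplets,pairs,raters data.frames or CSV paths
#'   following the schemas written by \code{run_all}.
#' @return list(participants, drawings, triplets, pairs, raters, bitmaps)
#'   suitable for \code{run_all(..., inputs = )}.
#' @export
ingest_real <- function(manifest, participants, triplets, pairs, raters) {
  load_tab <- function(x) if (is.character(x)) utils::read.csv(x) else x
  participants <- load_tab(participants)
  triplets <- load_tab(triplets); pairs <- load_tab(pairs)
  raters <- load_tab(raters); manifest <- load_tab(manifest)
  if (!all(c("drawing_id", "path") %in% names(manifest)))
    stopf("manifest must have drawing_id and path columns")
  ids <- manifest$drawing_id
  check_ids <- function(v, what) {
    missing <- setdiff(unique(v), ids)
    if (length(missing))
      stopf("%s references drawing id(s) absent from manifest: %s", what,
            paste(utils::head(missing, 5), collapse = ", "))
  }
  check_ids(c(triplets$anchor_id, triplets$left_id, triplets$right_id),
            "triplets")
  check_ids(c(pairs$left_id, pairs$right_id), "pairs")
  check_ids(raters$drawing_id, "raters")
  bitmaps <- lapply(manifest$path, read_drawing)
  names(bitmaps) <- ids
  if (!"participant_id" %in% names(manifest))
    stopf("manifest must map drawings to participant_id")
  drawings <- data.frame(drawing_id = ids,
                         participant_id = manifest$participant_id,
                         stringsAsFactors = FALSE)
  list(participants = participants, drawings = drawings,
       triplets = triplets, pairs = pairs, raters = raters,
       bitmaps = bitmaps)
}
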