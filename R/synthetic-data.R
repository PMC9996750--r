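#' The 12 Draw-A-Child checklist items, in scoring order
#'
#' @return character vector of the 12 item names (head through clothes).
#' @export
checklist_items <- function() {
  c("head", "eyes", "nose", "mouth", "ears", "hair",
    "body", "arms", "legs", "hands", "feet", "clothes")
}

drawing_stages <- function() {
  c("scribble", "circle_face", "tadpole", "differentiated")
}

#' Configuration for the synthetic drawing study
#'
#' Returns the full parameter list of the generator with defaults emulating a
#' cohort of 129 children (22-106 months) plus 25 young adults, 1-3 drawings
#' per participant, a latent drawing ability driven by log-age and gender, a
#' four-stage developmental progression (scribble, circle-face, tadpole,
#' differentiated figure), parent-report ASQ subscales (0-60), and grip/pinch
#' strength linearly coupled to ability with additive noise.
#'
#' @param ... named overrides of any default listed below.
#' @return list of generator parameters.
#' @details Key parameters: \code{n_participants} (154), \code{n_adults} (25),
#'   \code{child_age_range} (22-106 months), \code{adult_age_range} (229-264),
#'   \code{p_female} (0.53), \code{age_coef}/\code{gender_effect}/
#'   \code{ability_sd} defining latent ability, \code{stage_thresholds}
#'   partitioning the ability axis into the four stages,
#'   \code{stage_noise_sd} (per-drawing noise), \code{part_difficulties} and
#'   \code{part_slope} (item detectability by ability),
#'   \code{gender_style_effect} (displacement of the second perceptual
#'   coordinate by gender), \code{manifold_scatter_sd}, ASQ/grip/pinch
#'   intercepts, slopes and noise SDs, and availability fractions
#'   \code{asq_fraction}, \code{motor_fraction}.
#' @export
study_config <- function(...) {
  cfg <- list(
    n_participants = 154L,
    n_adults = 25L,
    child_age_range = c(22, 106),
    adult_age_range = c(229, 264),
    p_female = 0.53,
    # latent ability: age_coef * standardized log(age) + gender + noise
    age_coef = 1.0,
    log_age_center = 3.9,
    log_age_scale = 0.45,
    gender_effect = 0.3,
    ability_sd = 0.4,
    # drawings per child sampled with these weights for 1/2/3 media
    media_weights = c(57, 15, 57),
    adult_media_count = 2L,
    # developmental stages
    stage_thresholds = c(-1.0, -0.2, 0.7),
    stage_noise_sd = 0.3,
    part_slope = 1.8,
    part_difficulties = c(head = -1.5, eyes = -1.0, nose = -0.3,
                          mouth = -0.8, ears = 0.6, hair = 0.2,
                          body = -0.5, arms = -0.6, legs = -0.7,
                          hands = 0.8, feet = 0.5, clothes = 1.0),
    # true perceptual space: arc of radius manifold_scale traced by quality
    manifold_scale = 1.5,
    manifold_scatter_sd = 0.1,
    gender_style_effect = 0.15,
    # rendering
    figure_scale_range = c(0.55, 0.9),
    stroke_width_range = c(2L, 4L),
    scribble_strokes = c(3L, 8L),
    # outcomes (ASQ subscales clipped to [0, 60])
    asq_base = c(communication = 42, gross_motor = 44, fine_motor = 40,
                 problem_solving = 45, personal_social = 43),
    asq_slope = c(communication = 5, gross_motor = 4, fine_motor = 6,
                  problem_solving = 3, personal_social = 5),
    asq_sd = c(communication = 6, gross_motor = 6, fine_motor = 6,
               problem_solving = 6, personal_social = 6),
    grip_base = 12, grip_slope = 6, grip_sd = 3,
    pinch_base = 4, pinch_slope = 1.5, pinch_sd = 1,
    asq_fraction = 0.42,
    motor_fraction = 0.78
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stopf("unknown study_config parameter(s): %s",
          paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg
}

#' Sample a synthetic participant cohort
#'
#' Draws ages, genders, a latent drawing ability, and outcome measures (five
#' ASQ subscales plus total, grip and pinch strength) for \code{n}
#' participants. Ability is \code{age_coef * z(log age) + gender_effect *
#' (female - 0.5) + N(0, ability_sd)}; every outcome is a linear function of
#' ability plus Gaussian noise, clipped to its legal range (ASQ subscales to
#' [0, 60], strength to non-negative values).
#'
#' @param n number of participants (>= 1).
#' @param config list from \code{\link{study_config}}.
#' @param seed integer seed; the cohort is a pure function of (n, config, seed).
#' @return data.frame with one row per participant: identifiers, age_months,
#'   gender, latent_ability, asq_* columns, grip, pinch, and logical
#'   availability flags asq_available / motor_available (children only).
#' @export
sample_participants <- function(n, config = study_config(), seed = 1L) {
  if (!is.numeric(n) || n < 1) stopf("'n' must be a positive count")
  n <- as.integer(n)
  if (diff(config$child_age_range) <= 0)
    stopf("degenerate age range: min >= max")
  with_seed(seed, {
    n_adults <- min(config$n_adults, n - 1L)
    if (n <= 2L) n_adults <- 0L
    adult <- c(rep(FALSE, n - n_adults), rep(TRUE, n_adults))
    age <- ifelse(adult,
                  stats::runif(n, config$adult_age_range[1],
                               config$adult_age_range[2]),
                  stats::runif(n, config$child_age_range[1],
                               config$child_age_range[2]))
    female <- stats::rbinom(n, 1L, config$p_female)
    z_age <- (log(age) - config$log_age_center) / config$log_age_scale
    ability <- config$age_coef * z_age +
      config$gender_effect * (female - 0.5) +
      stats::rnorm(n, 0, config$ability_sd)
    clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
    asq <- sapply(names(config$asq_base), function(s) {
      clip(config$asq_base[[s]] + config$asq_slope[[s]] * ability +
             stats::rnorm(n, 0, config$asq_sd[[s]]), 0, 60)
    })
    grip <- pmax(config$grip_base + config$grip_slope * ability +
                   stats::rnorm(n, 0, config$grip_sd), 0)
    pinch <- pmax(config$pinch_base + config$pinch_slope * ability +
                    stats::rnorm(n, 0, config$pinch_sd), 0)
    out <- data.frame(
      participant_id = sprintf("p%03d", seq_len(n)),
      age_months = age,
      gender = factor(ifelse(female == 1L, "female", "male"),
                      levels = c("male", "female")),
      female = female,
      adult = adult,
      latent_ability = ability,
      stringsAsFactors = FALSE
    )
    colnames(asq) <- paste0("asq_", names(config$asq_base))
    out <- cbind(out, as.data.frame(asq))
    out$asq_total <- rowSums(asq)
    out$grip <- grip
    out$pinch <- pinch
    out$asq_available <- !adult & stats::runif(n) < config$asq_fraction
    out$motor_available <- !adult & stats::runif(n) < config$motor_fraction
    rownames(out) <- NULL
    out
  })
}

# Stage gates: which checklist items a drawing at each stage can contain,
# and which are guaranteed. Scribbles contain no identifiable parts;
# tadpoles have limbs attached directly to the head (no trunk);
# differentiated figures must have head, body, arms and legs.
stage_gate <- function(stage) {
  switch(stage,
    scribble = list(allowed = character(0), forced = character(0)),
    circle_face = list(
      allowed = c("head", "eyes", "nose", "mouth", "ears", "hair"),
      forced = "head"),
    tadpole = list(
      allowed = c("head", "eyes", "nose", "mouth", "ears", "hair",
                  "arms", "legs", "hands", "feet"),
      forced = c("head", "legs")),
    differentiated = list(
      allowed = checklist_items(),
      forced = c("head", "body", "arms", "legs")),
    stopf("unknown stage '%s'", stage))
}

# Quality in [0, 1]: dominated by stage (increments of 0.25), refined by the
# checklist count and a smooth term in the drawing-level ability so that
# quality is continuous and strictly monotone in stage for fixed noise.
true_quality_from <- function(stage_idx, checklist, stage_score) {
  q <- (stage_idx - 1) / 4 + 0.2 * checklist / 12 +
    0.05 * stats::plogis(stage_score)
  pmin(pmax(q, 0), 1)
}

#' Derive drawing specifications (with ground truth) for a cohort
#'
#' For each participant, samples 1-3 drawings whose developmental stage is
#' chosen by thresholding the participant's latent ability plus independent
#' per-drawing noise, samples the 12 checklist part indicators with
#' probabilities increasing in ability (masked/forced by stage), and attaches
#' ground truth: the true checklist count, a true quality in [0, 1]
#' monotone in stage, and coordinates in a curved 2D perceptual manifold
#' (scribbles at one end, differentiated figures at the other) with a gender
#' displacement on the second axis.
#'
#' @param participants data.frame from \code{\link{sample_participants}}.
#' @param media_count "auto" (sample 1-3 per child from
#'   \code{config$media_weights}; adults get \code{config$adult_media_count}),
#'   or a fixed integer 1-3.
#' @param config list from \code{\link{study_config}}.
#' @param seed integer seed.
#' @return data.frame with one row per drawing: drawing_id, participant_id,
#'   medium, stage (ordered factor), stage_score, figure_scale, stroke_width,
#'   stroke_count, jitter_seed, part_* logical columns, true_checklist,
#'   true_quality, perc_x, perc_y.
#' @export
derive_specs <- function(participants, media_count = "auto",
                         config = study_config(), seed = 1L) {
  if (!identical(media_count, "auto")) {
    if (!is.numeric(media_count) || media_count < 1 || media_count > 3)
      stopf("media_count must be 1, 2, or 3 (or \"auto\")")
  }
  items <- checklist_items()
  media <- c("marker", "finger", "stylus")
  with_seed(seed, {
    np <- nrow(participants)
    counts <- if (identical(media_count, "auto")) {
      ifelse(participants$adult, config$adult_media_count,
             sample.int(3L, np, replace = TRUE,
                        prob = config$media_weights))
    } else rep(as.integer(media_count), np)
    idx <- rep(seq_len(np), counts)
    k <- length(idx)
    medium <- unlist(lapply(counts, function(m) media[seq_len(m)]),
                     use.names = FALSE)
    stage_score <- participants$latent_ability[idx] +
      stats::rnorm(k, 0, config$stage_noise_sd)
    stage_idx <- findInterval(stage_score, config$stage_thresholds) + 1L
    stage <- drawing_stages()[stage_idx]
    # part indicators: logistic in the drawing-level ability, then gated
    pmat <- sapply(items, function(it) {
      p <- stats::plogis(config$part_slope *
                           (stage_score - config$part_difficulties[[it]]))
      stats::runif(k) < p
    })
    for (i in seq_len(k)) {
      g <- stage_gate(stage[i])
      pmat[i, !(items %in% g$allowed)] <- FALSE
      pmat[i, items %in% g$forced] <- TRUE
    }
    checklist <- rowSums(pmat)
    quality <- true_quality_from(stage_idx, checklist, stage_score)
    # perceptual manifold: arc from theta = pi (scribbles) to 0
    theta <- pi * (1 - quality)
    female <- participants$female[idx]
    perc_x <- config$manifold_scale * cos(theta) +
      stats::rnorm(k, 0, config$manifold_scatter_sd)
    perc_y <- config$manifold_scale * sin(theta) +
      config$gender_style_effect * (female - 0.5) +
      stats::rnorm(k, 0, config$manifold_scatter_sd)
    scribbles <- pmax(stats::rpois(k, 2) + config$scribble_strokes[1],
                      config$scribble_strokes[1])
    out <- data.frame(
      drawing_id = sprintf("d%04d", seq_len(k)),
      participant_id = participants$participant_id[idx],
      medium = medium,
      stage = factor(stage, levels = drawing_stages(), ordered = TRUE),
      stage_score = stage_score,
      figure_scale = stats::runif(k, config$figure_scale_range[1],
                                  config$figure_scale_range[2]),
      stroke_width = sample(seq(config$stroke_width_range[1],
                                config$stroke_width_range[2]),
                            k, replace = TRUE),
      stroke_count = pmin(scribbles, config$scribble_strokes[2]),
      jitter_seed = sample.int(2147480000L, k),
      stringsAsFactors = FALSE
    )
    colnames(pmat) <- paste0("part_", items)
    out <- cbind(out, as.data.frame(pmat))
    out$true_checklist <- as.integer(checklist)
    out$true_quality <- quality
    out$perc_x <- perc_x
    out$perc_y <- perc_y
    rownames(out) <- NULL
    out
  })
}

# Extract the true 2D perceptual coordinates from a drawings/ground-truth
# table (or pass through a plain coordinate matrix with id rownames).
gt_coords <- function(gt) {
  if (is.matrix(gt)) {
    if (is.null(rownames(gt))) stopf("coordinate matrix needs id rownames")
    return(gt)
  }
  if (!all(c("drawing_id", "perc_x", "perc_y") %in% names(gt)))
    stopf("ground truth must have drawing_id, perc_x, perc_y")
  m <- as.matrix(gt[, c("perc_x", "perc_y")])
  rownames(m) <- gt$drawing_id
  m
}

gt_quality <- function(gt) {
  if (!all(c("drawing_id", "true_quality") %in% names(gt)))
    stopf("ground truth must have drawing_id and true_quality")
  stats::setNames(gt$true_quality, gt$drawing_id)
}

#' Simulate triadic similarity judgments
#'
#' Draws \code{n_trials} triplets (anchor plus two distinct options) uniformly
#' at random and simulates the forced choice "which option is more similar to
#' the anchor". With \code{decision_noise > 0} the choice follows the same
#' crowd-kernel likelihood used by the embedder (see
#' \code{\link{triplet_probability}}) evaluated on the true perceptual
#' coordinates with mu = \code{decision_noise}; with \code{decision_noise = 0}
#' the strictly closer option is always chosen (ties resolved by a fair coin).
#'
#' @param gt drawings/ground-truth table from \code{\link{derive_specs}}, or a
#'   coordinate matrix with drawing ids as rownames.
#' @param n_trials number of judgments to simulate.
#' @param decision_noise non-negative crowd-kernel mu of the simulated judges.
#' @param seed integer seed.
#' @return data.frame: trial_id, anchor_id, left_id, right_id, chosen_id.
#' @export
simulate_triplet_judgments <- function(gt, n_trials, decision_noise = 0.1,
                                       seed = 1L) {
  assert_scalar_number(decision_noise, "decision_noise", lower = 0)
  x <- gt_coords(gt)
  k <- nrow(x)
  if (k < 3) stopf("need at least 3 drawings to form triplets")
  n_trials <- as.integer(n_trials)
  with_seed(seed, {
    a <- sample.int(k, n_trials, replace = TRUE)
    b <- sample.int(k - 1L, n_trials, replace = TRUE)
    b <- b + (b >= a)                       # option 1 != anchor
    cc <- sample.int(k - 2L, n_trials, replace = TRUE)
    lo <- pmin(a, b); hi <- pmax(a, b)
    cc <- cc + (cc >= lo)
    cc <- cc + (cc >= hi)                   # option 2 != anchor, option 1
    d2b <- rowSums((x[a, , drop = FALSE] - x[b, , drop = FALSE])^2)
    d2c <- rowSums((x[a, , drop = FALSE] - x[cc, , drop = FALSE])^2)
    if (decision_noise > 0) {
      pb <- (decision_noise + d2c) / (2 * decision_noise + d2b + d2c)
    } else {
      pb <- ifelse(d2b < d2c, 1, ifelse(d2b > d2c, 0, 0.5))
    }
    pick_b <- stats::runif(n_trials) < pb
    ids <- rownames(x)
    data.frame(trial_id = seq_len(n_trials),
               anchor_id = ids[a],
               left_id = ids[b],
               right_id = ids[cc],
               chosen_id = ifelse(pick_b, ids[b], ids[cc]),
               stringsAsFactors = FALSE)
  })
}

#' Simulate pairwise drawing-quality judgments
#'
#' Draws random pairs of distinct drawings and simulates the forced choice
#' "which is the better drawing of a person" under a Bradley-Terry-style
#' model: P(left wins) = logistic(discrimination * (q_left - q_right)) on the
#' true qualities. \code{discrimination = Inf} gives the deterministic limit
#' (ties at probability one half).
#'
#' @param gt drawings/ground-truth table with true_quality, or a named
#'   quality vector.
#' @param n_trials number of judgments.
#' @param discrimination non-negative judge sensitivity.
#' @param seed integer seed.
#' @return data.frame: trial_id, left_id, right_id, chosen_id.
#' @export
simulate_pair_judgments <- function(gt, n_trials, discrimination = 10,
                                    seed = 1L) {
  q <- if (is.numeric(gt) && !is.null(names(gt))) gt else gt_quality(gt)
  k <- length(q)
  if (k < 2) stopf("need at least 2 drawings to form pairs")
  if (!is.numeric(discrimination) || length(discrimination) != 1L ||
      is.na(discrimination) || discrimination < 0)
    stopf("'discrimination' must be a single non-negative number")
  n_trials <- as.integer(n_trials)
  with_seed(seed, {
    l <- sample.int(k, n_trials, replace = TRUE)
    r <- sample.int(k - 1L, n_trials, replace = TRUE)
    r <- r + (r >= l)
    gap <- q[l] - q[r]
    pl <- if (is.finite(discrimination)) stats::plogis(discrimination * gap)
          else ifelse(gap > 0, 1, ifelse(gap < 0, 0, 0.5))
    win_l <- stats::runif(n_trials) < pl
    ids <- names(q)
    data.frame(trial_id = seq_len(n_trials),
               left_id = ids[l],
               right_id = ids[r],
               chosen_id = ifelse(win_l, ids[l], ids[r]),
               stringsAsFactors = FALSE)
  })
}

#' Simulate two noisy checklist raters
#'
#' Each rater independently observes each drawing's true part indicators,
#' missing a present part with probability \code{miss_rate} and falsely
#' detecting an absent part with probability \code{false_alarm_rate}.
#'
#' @param gt drawings table from \code{\link{derive_specs}} (needs the
#'   part_* columns).
#' @param miss_rate probability in [0, 1] of missing a present part.
#' @param false_alarm_rate probability in [0, 1] of marking an absent part.
#' @param seed integer seed.
#' @return data.frame in long rater format: drawing_id, rater (1 or 2), the
#'   12 item_* indicator columns, and score (0-12).
#' @export
simulate_checklist_raters <- function(gt, miss_rate = 0.05,
                                      false_alarm_rate = 0.02, seed = 1L) {
  assert_scalar_number(miss_rate, "miss_rate", 0, 1)
  assert_scalar_number(false_alarm_rate, "false_alarm_rate", 0, 1)
  items <- checklist_items()
  cols <- paste0("part_", items)
  if (!all(cols %in% names(gt))) stopf("gt lacks part_* indicator columns")
  truth <- as.matrix(gt[, cols]) > 0
  k <- nrow(truth)
  with_seed(seed, {
    one_rater <- function(rater) {
      u <- matrix(stats::runif(k * 12L), k, 12L)
      obs <- ifelse(truth, u >= miss_rate, u < false_alarm_rate)
      df <- data.frame(drawing_id = gt$drawing_id, rater = rater,
                       stringsAsFactors = FALSE)
      obs <- obs * 1L
      colnames(obs) <- paste0("item_", items)
      df <- cbind(df, as.data.frame(obs))
      df$score <- as.integer(rowSums(obs))
      df
    }
    rbind(one_rater(1L), one_rater(2L))
  })
}

#' Generate a complete synthetic drawing study
#'
#' Convenience wrapper running \code{\link{sample_participants}},
#' \code{\link{derive_specs}}, and the three judgment simulators under
#' deterministically derived per-stage seeds.
#'
#' @param config list from \code{\link{study_config}}.
#' @param n_triplets,n_pairs trial counts for the judgment simulators.
#' @param decision_noise,discrimination judge parameters (see the simulators).
#' @param miss_rate,false_alarm_rate checklist rater error rates.
#' @param seed master integer seed.
#' @return list with components participants, drawings, triplets, pairs,
#'   raters.
#' @export
simulate_study <- function(config = study_config(), n_triplets = 3000,
                           n_pairs = 1500, decision_noise = 0.1,
                           discrimination = 10, miss_rate = 0.05,
                           false_alarm_rate = 0.02, seed = 1L) {
  participants <- sample_participants(config$n_participants, config,
                                      seed = spawn_seed(seed, 1L))
  drawings <- derive_specs(participants, config = config,
                           seed = spawn_seed(seed, 2L))
  triplets <- simulate_triplet_judgments(drawings, n_triplets,
                                         decision_noise,
                                         seed = spawn_seed(seed, 3L))
  pairs <- simulate_pair_judgments(drawings, n_pairs, discrimination,
                                   seed = spawn_seed(seed, 4L))
  raters <- simulate_checklist_raters(drawings, miss_rate, false_alarm_rate,
                                      seed = spawn_seed(seed, 5L))
  list(participants = participants, drawings = drawings,
       triplets = triplets, pairs = pairs, raters = raters)
}

#' Simulate a merged per-drawing analysis table
#'
#' Generates the per-drawing table the outcome-model harness consumes
#' (observed checklist, quality-rank, human and machine embedding
#' coordinates, joined with participant covariates and outcomes) directly
#' from the latent model, bypassing rendering and embedding estimation.
#' Observed metrics are the ground-truth quantities plus independent
#' Gaussian measurement noise; the machine embedding is a rotated, noisier
#' view of the same perceptual manifold. Used for the power and type-I-error
#' calibration simulations of the harness.
#'
#' @param n_participants cohort size.
#' @param config list from \code{\link{study_config}}.
#' @param quality_noise_sd,embedding_noise_sd,machine_noise_sd measurement
#'   noise SDs for the observed metrics.
#' @param checklist_miss,checklist_fa rater error rates for the observed
#'   checklist score.
#' @param seed integer seed.
#' @return data.frame, one row per drawing, with columns checklist, quality,
#'   hx, hy, mx, my plus all participant columns and log_age.
#' @export
simulate_analysis_table <- function(n_participants = 154,
                                    config = study_config(),
                                    quality_noise_sd = 0.03,
                                    embedding_noise_sd = 0.1,
                                    machine_noise_sd = 0.25,
                                    checklist_miss = 0.05,
                                    checklist_fa = 0.02,
                                    seed = 1L) {
  participants <- sample_participants(n_participants, config,
                                      seed = spawn_seed(seed, 11L))
  drawings <- derive_specs(participants, config = config,
                           seed = spawn_seed(seed, 12L))
  raters <- simulate_checklist_raters(drawings, checklist_miss, checklist_fa,
                                      seed = spawn_seed(seed, 13L))
  chk <- checklist_scores(raters)
  k <- nrow(drawings)
  with_seed(spawn_seed(seed, 14L), {
    tab <- data.frame(
      drawing_id = drawings$drawing_id,
      participant_id = drawings$participant_id,
      checklist = chk$final[match(drawings$drawing_id, chk$drawing_id)],
      quality = pmin(pmax(drawings$true_quality +
                            stats::rnorm(k, 0, quality_noise_sd), 0), 1),
      hx = drawings$perc_x + stats::rnorm(k, 0, embedding_noise_sd),
      hy = drawings$perc_y + stats::rnorm(k, 0, embedding_noise_sd),
      stringsAsFactors = FALSE
    )
    # machine view: 90-degree rotation of the manifold plus heavier noise
    tab$mx <- -drawings$perc_y + stats::rnorm(k, 0, machine_noise_sd)
    tab$my <- drawings$perc_x + stats::rnorm(k, 0, machine_noise_sd)
    idx <- match(drawings$participant_id, participants$participant_id)
    tab <- cbind(tab, participants[idx, setdiff(names(participants),
                                                "participant_id")])
    tab$log_age <- log(tab$age_months)
    rownames(tab) <- NULL
    tab
  })
}
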