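test_that("cohort sampling respects ranges, determinism, and degenerate noise", {
  cfg <- study_config(n_participants = 154L)
  p <- sample_participants(154, cfg, seed = 7)
  kids <- p[!p$adult, ]
  expect_true(all(kids$age_months >= 22 & kids$age_months <= 106))
  expect_true(all(p[p$adult, "age_months"] >= 229))
  asq <- as.matrix(p[, paste0("asq_", names(cfg$asq_base))])
  expect_true(all(asq >= 0 & asq <= 60))
  expect_equal(p$asq_total, unname(rowSums(asq)))
  expect_identical(p, sample_participants(154, cfg, seed = 7))
  expect_error(sample_participants(0, cfg), "positive")
  expect_error(sample_participants(10, study_config(child_age_range = c(50, 50))),
               "degenerate")

  # zero noise and zero slope: identical ASQ scores for everyone
  cfg0 <- study_config(asq_slope = sapply(cfg$asq_slope, function(x) 0),
                       asq_sd = sapply(cfg$asq_sd, function(x) 0))
  p0 <- sample_participants(20, cfg0, seed = 1)
  expect_equal(length(unique(p0$asq_fine_motor)), 1L)
})

test_that("ability-outcome correlation matches the variance-component value", {
  # closed form: r = slope * sd(ability) / sqrt(slope^2 var(ability) + sd_noise^2)
  cfg <- study_config(n_adults = 0L, asq_base = c(communication = 30,
                        gross_motor = 30, fine_motor = 30,
                        problem_solving = 30, personal_social = 30),
                      asq_slope = c(communication = 5, gross_motor = 5,
                                    fine_motor = 5, problem_solving = 5,
                                    personal_social = 5),
                      asq_sd = c(communication = 5, gross_motor = 5,
                                 fine_motor = 5, problem_solving = 5,
                                 personal_social = 5))
  p <- sample_participants(2000, cfg, seed = 11)
  expect_true(all(p$asq_fine_motor > 0 & p$asq_fine_motor < 60)) # no clipping
  va <- stats::var(p$latent_ability)
  r_expected <- 5 * sqrt(va) / sqrt(25 * va + 25)
  r_observed <- stats::cor(p$latent_ability, p$asq_fine_motor)
  expect_gt(r_observed, 0)
  expect_lt(abs(r_observed - r_expected), 0.05)
})

test_that("drawing specs obey stage gates and ability monotonicity", {
  fx <- make_drawings(seed = 3, n_participants = 120)
  d <- fx$drawings
  items <- paste0("part_", checklist_items())
  scr <- d$stage == "scribble"
  expect_true(all(rowSums(d[scr, items]) == 0))
  diff_ <- d$stage == "differentiated"
  expect_true(all(d[diff_, "part_head"] & d[diff_, "part_body"] &
                    d[diff_, "part_arms"] & d[diff_, "part_legs"]))
  expect_equal(d$true_checklist, unname(rowSums(d[, items])))
  expect_true(all(d$true_quality >= 0 & d$true_quality <= 1))
  expect_error(derive_specs(fx$participants, media_count = 4), "media_count")

  # stage/quality coupling over a large cohort
  rho <- stats::cor(as.integer(d$stage), d$true_quality, method = "spearman")
  expect_gte(rho, 0.8)

  # checklist count increases with ability in expectation
  ab <- fx$participants$latent_ability[
    match(d$participant_id, fx$participants$participant_id)]
  expect_gt(stats::cor(ab, d$true_checklist), 0.5)
})

test_that("stage frequencies match the threshold-and-noise model", {
  # 10,000 draws at fixed mid ability: empirical stage frequencies vs the
  # normal-CDF probabilities implied by thresholds + stage noise
  cfg <- desk_config(ability_sd = 0, gender_effect = 0, age_coef = 0)
  p <- sample_participants(10000, cfg, seed = 5)
  expect_true(all(abs(p$latent_ability) < 1e-12))   # ability pinned at 0
  d <- derive_specs(p, media_count = 1, config = cfg, seed = 6)
  thr <- cfg$stage_thresholds
  probs <- diff(c(0, stats::pnorm(thr, 0, cfg$stage_noise_sd), 1))
  emp <- as.numeric(table(d$stage)) / nrow(d)
  for (j in 1:4) {
    se <- sqrt(probs[j] * (1 - probs[j]) / nrow(d))
    expect_lt(abs(emp[j] - probs[j]), 4 * se + 1e-9)
  }
})

test_that("triplet simulator follows the crowd-kernel choice law", {
  x <- rbind(a = c(0, 0), b = c(0, 0), c = c(1, 0))
  tr <- simulate_triplet_judgments(x, 30000, decision_noise = 0.1, seed = 2)
  # anchored at a: chance the coincident point b is chosen = 1.1/1.2
  ta <- tr[tr$anchor_id == "a", ]
  picked_b <- mean(ta$chosen_id == "b")
  p_true <- 1.1 / 1.2
  se <- sqrt(p_true * (1 - p_true) / nrow(ta))
  expect_lt(abs(picked_b - p_true), 3 * se)

  # noiseless limit: strictly closer option always chosen
  x2 <- rbind(a = c(0, 0), b = c(0.5, 0), c = c(2, 0), d = c(3, 0))
  tr0 <- simulate_triplet_judgments(x2, 2000, decision_noise = 0, seed = 3)
  d2 <- function(i, j) sum((x2[i, ] - x2[j, ])^2)
  opts <- cbind(tr0$left_id, tr0$right_id)
  closer <- ifelse(mapply(d2, tr0$anchor_id, tr0$left_id) <
                     mapply(d2, tr0$anchor_id, tr0$right_id),
                   tr0$left_id, tr0$right_id)
  expect_true(all(tr0$chosen_id == closer))

  # equidistant options are a fair coin
  xe <- rbind(a = c(0, 0), b = c(1, 0), c = c(-1, 0))
  tre <- simulate_triplet_judgments(xe, 10000, decision_noise = 0.1, seed = 4)
  tea <- tre[tre$anchor_id == "a", ]
  expect_lt(abs(mean(tea$chosen_id == "b") - 0.5),
            3 * sqrt(0.25 / nrow(tea)))
  expect_error(simulate_triplet_judgments(x[1:2, ], 10), "at least 3")
})

test_that("pair simulator is a logistic choice model in true quality", {
  q <- c(a = 0.8, b = 0.3, c = 0.3)
  pr <- simulate_pair_judgments(q, 40000, discrimination = 2, seed = 9)
  ab <- pr[(pr$left_id == "a" & pr$right_id == "b") |
             (pr$left_id == "b" & pr$right_id == "a"), ]
  p_emp <- mean(ab$chosen_id == "a")
  p_true <- stats::plogis(2 * 0.5)          # ~0.731
  expect_lt(abs(p_emp - p_true), 3 * sqrt(p_true * (1 - p_true) / nrow(ab)))
  bc <- pr[(pr$left_id == "b" & pr$right_id == "c") |
             (pr$left_id == "c" & pr$right_id == "b"), ]
  expect_lt(abs(mean(bc$chosen_id == "b") - 0.5), 3 * sqrt(0.25 / nrow(bc)))

  # deterministic limit
  prI <- simulate_pair_judgments(q, 500, discrimination = Inf, seed = 10)
  abI <- prI[(prI$left_id == "a" & prI$right_id == "b") |
               (prI$left_id == "b" & prI$right_id == "a"), ]
  expect_true(all(abI$chosen_id == "a"))
  expect_error(simulate_pair_judgments(q[1], 10), "at least 2")
})

test_that("checklist raters flip items at the stated rates", {
  fx <- make_drawings(seed = 12, n_participants = 200)
  d <- fx$drawings
  # noiseless raters reproduce the truth exactly
  r0 <- simulate_checklist_raters(d, 0, 0, seed = 1)
  chk0 <- checklist_scores(r0)
  expect_equal(chk0$final[match(d$drawing_id, chk0$drawing_id)],
               as.numeric(d$true_checklist))
  expect_equal(interrater_reliability(r0), 1.0)
  # miss = 1, false alarm = 0: all scores zero
  r1 <- simulate_checklist_raters(d, 1, 0, seed = 1)
  expect_true(all(r1$score == 0))
  expect_error(simulate_checklist_raters(d, -0.1, 0), "miss_rate")

  # analytic reliability from the binomial error model
  m <- 0.05; f <- 0.05
  rr <- simulate_checklist_raters(d[1:300, ], m, f, seed = 13)
  C <- d$true_checklist[1:300]
  vb <- (1 - m - f)^2 * stats::var(C)                    # between-truth
  vw <- mean(C) * (1 - m) * m + mean(12 - C) * f * (1 - f)  # within
  r_analytic <- vb / (vb + vw)
  r_emp <- interrater_reliability(rr)
  expect_lt(abs(r_emp - r_analytic), 0.05)
})

test_that("outcomes decouple from drawing ground truth at zero slopes", {
  zero <- function(v) sapply(v, function(x) 0)
  cfg <- desk_config(asq_slope = zero(study_config()$asq_slope),
                     grip_slope = 0, pinch_slope = 0)
  fx <- make_drawings(seed = 21, n_participants = 300, config = cfg)
  kids <- fx$participants[!fx$participants$adult, ]
  d <- fx$drawings[fx$drawings$participant_id %in% kids$participant_id, ]
  ab <- kids$asq_fine_motor[match(d$participant_id, kids$participant_id)]
  r <- stats::cor.test(ab, d$true_quality)
  expect_gt(r$p.value, 0.001)
  expect_lt(abs(r$estimate), 0.15)
})
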