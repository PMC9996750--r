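test_that("outcome preparation applies transforms and validates joins", {
  fx <- make_drawings(seed = 3, n_participants = 20)
  tab <- simulate_analysis_table(20, desk_config(), seed = 3)
  expect_equal(tab$log_age, log(tab$age_months))
  idx <- which.min(abs(tab$age_months - 100))
  expect_equal(tab$log_age[idx], log(tab$age_months[idx]))

  metrics <- tab[, c("drawing_id", "participant_id", "checklist", "quality",
                     "hx", "hy", "mx", "my")]
  joined <- prepare_outcomes(fx$participants, metrics, log_age = FALSE)
  expect_false("log_age" %in% names(joined))
  bad <- metrics; bad$participant_id[1] <- "nope"
  expect_error(prepare_outcomes(fx$participants, bad), "join keys")
  neg <- fx$participants; neg$age_months[1] <- -5
  expect_error(prepare_outcomes(neg, metrics, log_age = TRUE),
               "non-positive age")
})

test_that("adjusted R-squared follows its definition", {
  expect_equal(adjusted_r2(0.5, 12, 1), 1 - 0.5 * 11 / 10)
  expect_equal(adjusted_r2(0.5, 12, 1), 0.45)
  # agrees with lm's own computation on a random design
  set.seed(5)
  df <- data.frame(y = rnorm(40), x1 = rnorm(40), x2 = rnorm(40))
  sm <- summary(lm(y ~ x1 + x2, data = df))
  expect_equal(adjusted_r2(sm$r.squared, 40, 2), sm$adj.r.squared)
})

test_that("linear ladder steps, nesting, and F-tests are correct", {
  tab <- simulate_analysis_table(154, seed = 11)
  lad <- fit_linear_ladder(tab, "log_age", covariates = "gender")
  expect_s3_class(lad, "model_ladder")
  steps <- lad$table$step
  expect_true(all(c("baseline", "quality", "human", "machine") %in% steps))
  expect_true(all(lad$table$multiple_r2 >= lad$table$adjusted_r2 - 1e-12))

  # nested F statistic equals the textbook residual-sum form (oracle)
  ref <- lad$fits[[lad$table$reference[steps == "human"]]]
  full <- lad$fits[["human"]]
  rss0 <- sum(residuals(ref)^2); rss1 <- sum(residuals(full)^2)
  ddf <- df.residual(ref) - df.residual(full)
  f_oracle <- ((rss0 - rss1) / ddf) / (rss1 / df.residual(full))
  p_oracle <- pf(f_oracle, ddf, df.residual(full), lower.tail = FALSE)
  expect_equal(lad$table$p_value[steps == "human"], p_oracle,
               tolerance = 1e-10)

  # same oracle check on random small designs
  set.seed(12)
  for (r in 1:5) {
    n <- sample(20:40, 1)
    df <- data.frame(y = rnorm(n), a = rnorm(n), b = rnorm(n), c = rnorm(n))
    m0 <- lm(y ~ a, data = df); m1 <- lm(y ~ a + b + c, data = df)
    rss0 <- sum(residuals(m0)^2); rss1 <- sum(residuals(m1)^2)
    f_o <- ((rss0 - rss1) / 2) / (rss1 / df.residual(m1))
    expect_equal(anova(m0, m1)[2, "F"], f_o, tolerance = 1e-10)
  }
})

test_that("a planted pure-quality outcome saturates the quality step", {
  tab <- simulate_analysis_table(100, seed = 21)
  tab$planted <- 3 + 5 * tab$quality
  lad <- suppressWarnings(fit_linear_ladder(tab, "planted"))  # exact fit
  qrow <- lad$table[lad$table$step == "quality", ]
  expect_equal(qrow$multiple_r2, 1, tolerance = 1e-9)
  expect_equal(lad$metric, "quality")
  # embeddings cannot add variance beyond a perfect fit
  expect_lt(lad$table$multiple_r2[lad$table$step == "human"] -
              qrow$multiple_r2, 1e-9)
})

test_that("parameter guard drops the joint-embedding step on small samples", {
  tab <- simulate_analysis_table(154, seed = 31)
  lad_auto <- fit_linear_ladder(tab, "asq_fine_motor",
                                covariates = "age_months * gender",
                                subset = tab$asq_available)
  expect_false("both" %in% lad_auto$table$step)
  lad_force <- fit_linear_ladder(tab, "log_age", covariates = "gender",
                                 include_both = TRUE)
  expect_true("both" %in% lad_force$table$step)
  # rows lacking ASQ are excluded from ASQ ladders only
  lad_age <- fit_linear_ladder(tab, "log_age", covariates = "gender")
  expect_gt(lad_age$n, lad_auto$n)
})

test_that("rank AUC equals exhaustive pair enumeration, including ties", {
  expect_equal(auc_rank(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auc_rank(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1.0)
  enum_auc <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    gr <- outer(pos, neg, `>`); eq <- outer(pos, neg, `==`)
    (sum(gr) + 0.5 * sum(eq)) / (length(pos) * length(neg))
  }
  set.seed(41)
  for (r in 1:50) {
    n <- sample(6:30, 1)
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE)   # many ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(auc_rank(s, y), enum_auc(s, y))
  }
  expect_error(auc_rank(c(1, 2), c(1, 1)), "both classes")
})

test_that("logistic ladder reports per-step holdout AUC reproducibly", {
  tab <- simulate_analysis_table(154, seed = 51)
  lad <- fit_logistic_auc(tab, "gender", covariates = "log_age",
                          folds = 25, seed = 7)
  expect_true(all(unlist(lad$auc_folds) >= 0 & unlist(lad$auc_folds) <= 1))
  expect_equal(length(lad$auc_folds$baseline), 25L)
  lad2 <- fit_logistic_auc(tab, "gender", covariates = "log_age",
                           folds = 25, seed = 7)
  expect_identical(lad$auc_folds, lad2$auc_folds)
  # the planted gender structure is detectable: embeddings beat chance
  expect_gt(lad$table$mean_auc[lad$table$step == "human"], 0.55)
  expect_error(fit_logistic_auc(within(tab, gender <- "female"), "gender"),
               "single-class")
})

test_that("results tables assemble outcomes with significance stars", {
  expect_equal(sketchlatent:::significance_stars(0.004), "**")
  expect_equal(sketchlatent:::significance_stars(c(0.2, 0.04, 0.0004)),
               c("", "*", "***"))
  tab <- simulate_analysis_table(120, seed = 61)
  ladders <- list(
    age = fit_linear_ladder(tab, "log_age", covariates = "gender"),
    gender = fit_logistic_auc(tab, "gender", covariates = "log_age",
                              folds = 10, seed = 2))
  rt <- results_tables(ladders)
  expect_equal(rt$outcome, c("age", "gender"))
  expect_true(all(c("baseline", "quality", "human", "machine", "both") %in%
                    names(rt)))
  expect_match(rt$baseline[1], "^[0-9.\\-]+\\**$")
})
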