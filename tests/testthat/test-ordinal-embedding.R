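test_that("triplet probability follows the crowd-kernel ratio form", {
  expect_equal(triplet_probability(c(0, 0), c(0, 0), c(1, 0), mu = 0.1),
               1.1 / 1.2)
  # symmetric options
  expect_equal(triplet_probability(c(0, 0), c(1, 0), c(-1, 0), mu = 0.3), 0.5)
  # large mu saturates to 1/2 regardless of geometry
  expect_equal(triplet_probability(c(0, 0), c(5, 0), c(0.1, 0), mu = 1e9),
               0.5, tolerance = 1e-6)
  # complementarity
  p_b <- triplet_probability(c(0, 0), c(0.3, 1), c(2, -1), mu = 0.2)
  p_c <- triplet_probability(c(0, 0), c(2, -1), c(0.3, 1), mu = 0.2)
  expect_equal(p_b + p_c, 1)
  expect_true(p_b > 0 && p_b < 1)
  expect_error(triplet_probability(c(0, 0), c(1, 0), c(0, 1), mu = 0),
               "positive")
})

test_that("holdout splitting is exact, exhaustive, and reproducible", {
  x <- planted_manifold(20, seed = 2)
  tr <- simulate_triplet_judgments(x, 100, seed = 3)
  sp <- split_holdout(tr, 0.10, seed = 4)
  expect_equal(nrow(sp$train), 90L)
  expect_equal(nrow(sp$test), 10L)
  expect_setequal(c(sp$train$trial_id, sp$test$trial_id), tr$trial_id)
  expect_identical(split_holdout(tr, 0.10, seed = 4), sp)
  expect_error(split_holdout(tr[1:5, ], 0.10), "at least 10")
  expect_error(split_holdout(tr, 0.0001), "empty partition")
})

test_that("crowd kernel recovers a planted 2D configuration", {
  x <- planted_manifold(60, seed = 11)
  tr <- simulate_triplet_judgments(x, 30 * nrow(x), decision_noise = 0,
                                   seed = 12)
  fit <- crowd_kernel(tr, dims = 2, seed = 13)
  expect_s3_class(fit, "crowd_kernel")
  expect_gte(fit$holdout_accuracy, 0.90)
  rho <- cor(as.vector(dist(fit$coords)),
             as.vector(dist(x[rownames(fit$coords), ])),
             method = "spearman")
  expect_gte(rho, 0.90)
  # loss trace of accepted steps never increases
  expect_true(all(diff(fit$loss_trace) <= 1e-9))
  # reproducibility
  fit2 <- crowd_kernel(tr, dims = 2, seed = 13)
  expect_identical(fit$coords, fit2$coords)
  expect_identical(fit$holdout_accuracy, fit2$holdout_accuracy)
})

test_that("a single triplet is fit perfectly and null labels score ~ 0.5", {
  one <- data.frame(anchor_id = "a", chosen_id = "b", rejected_id = "c")
  fit <- crowd_kernel(one, dims = 1, holdout_fraction = 0, max_iters = 200,
                      seed = 1)
  sc <- sketchlatent:::score_triplets(fit$coords, one)
  expect_equal(sc$accuracy, 1.0)

  # random labels: holdout accuracy within 3 binomial SDs of 0.5
  x <- planted_manifold(30, seed = 21)
  tr <- simulate_triplet_judgments(x, 1500, decision_noise = 0.1, seed = 22)
  set.seed(23)
  swap <- runif(nrow(tr)) < 0.5
  chosen <- ifelse(swap, tr$right_id, tr$left_id)   # independent of geometry
  tr$chosen_id <- chosen
  fit0 <- crowd_kernel(tr, dims = 2, seed = 24, max_iters = 200)
  n_ho <- fit0$holdout_n
  expect_lt(abs(fit0$holdout_accuracy - 0.5), 3 * sqrt(0.25 / n_ho))
})

test_that("triplet probabilities are invariant to rigid transforms", {
  x <- planted_manifold(25, seed = 31)
  tr <- simulate_triplet_judgments(x, 400, seed = 32)
  fit <- crowd_kernel(tr, dims = 2, seed = 33, max_iters = 150)
  p0 <- predict(fit, tr)
  th <- 1.1
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  fit_r <- fit
  fit_r$coords <- sweep(fit$coords %*% rot, 2, c(3, -7), `+`)
  expect_equal(predict(fit_r, tr), p0, tolerance = 1e-10)
  # reflection too
  fit_m <- fit; fit_m$coords <- fit$coords %*% diag(c(-1, 1))
  expect_equal(predict(fit_m, tr), p0, tolerance = 1e-10)
})

test_that("holdout accuracy grows with triplets per item", {
  x <- planted_manifold(40, seed = 41)
  accs <- sapply(c(5, 30), function(tpi) {
    tr <- simulate_triplet_judgments(x, tpi * nrow(x), decision_noise = 0,
                                     seed = 42)
    crowd_kernel(tr, dims = 2, seed = 43, max_iters = 250,
                 restarts = 2)$holdout_accuracy
  })
  expect_gt(accs[2], accs[1])
})

test_that("dimension selection prefers the planted dimensionality", {
  x <- planted_manifold(50, seed = 51)
  tr <- simulate_triplet_judgments(x, 25 * nrow(x), decision_noise = 0,
                                   seed = 52)
  best <- select_dimension(tr, dims_grid = c(1, 2, 3), seed = 53,
                           max_iters = 250, restarts = 2)
  expect_true(best$dims %in% c(2L, 3L))
  sweep_tab <- best$dimension_sweep
  expect_equal(sweep_tab$dims, c(1L, 2L, 3L))
  expect_true(all(sweep_tab$holdout_accuracy >= 0 &
                    sweep_tab$holdout_accuracy <= 1))
  # singleton grid returns that fit unchanged
  only2 <- select_dimension(tr, dims_grid = 2, seed = 53,
                            max_iters = 250, restarts = 2)
  expect_equal(only2$dims, 2L)
  expect_error(select_dimension(tr, dims_grid = integer(0)), "empty")
})

test_that("unseen holdout ids are skipped with a count", {
  tr <- data.frame(
    anchor_id = rep(c("a", "b", "c", "d"), 10),
    chosen_id = rep(c("b", "c", "d", "a"), 10),
    rejected_id = rep(c("c", "d", "a", "b"), 10))
  ho <- list(train = tr,
             test = data.frame(anchor_id = c("a", "zz"),
                               chosen_id = c("b", "a"),
                               rejected_id = c("c", "b")))
  fit <- crowd_kernel(tr, dims = 1, seed = 3, max_iters = 100, holdout = ho)
  expect_equal(fit$holdout_skipped, 1L)
  expect_equal(fit$holdout_n, 1L)
})
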