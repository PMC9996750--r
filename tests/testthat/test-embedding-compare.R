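test_that("nearest neighbors order by distance with stable tie-breaks", {
  x <- matrix(c(0, 1, 3), ncol = 1)
  rownames(x) <- c("p0", "p1", "p3")
  nn <- nearest_neighbors(x, 2)
  expect_equal(nn[["p1"]], c("p0", "p3"))
  # K = 1 on two points: each other's neighbor
  y <- matrix(c(0, 1), ncol = 1); rownames(y) <- c("a", "b")
  nn2 <- nearest_neighbors(y, 1)
  expect_equal(nn2[["a"]], "b")
  expect_equal(nn2[["b"]], "a")
  # no self neighbors, exact length K
  z <- planted_manifold(15, seed = 3)
  nn3 <- nearest_neighbors(z, 4)
  for (id in names(nn3)) {
    expect_false(id %in% nn3[[id]])
    expect_length(nn3[[id]], 4L)
  }
  # ties broken by id order
  tie <- matrix(c(0, 1, -1), ncol = 1); rownames(tie) <- c("m", "zz", "aa")
  expect_equal(nearest_neighbors(tie, 2)[["m"]], c("aa", "zz"))
  expect_error(nearest_neighbors(y, 2), "smaller")
})

test_that("nn_overlap is 1 against itself and ~K/(k-1) under the null", {
  e <- planted_manifold(40, seed = 7)
  self <- nn_overlap(e, e, K = 10)
  expect_equal(unname(self), c(1, 1))
  # monotone non-decreasing in K
  eB <- planted_manifold(40, seed = 8)
  rownames(eB) <- rownames(e)
  ov <- sapply(c(1, 5, 10, 20), function(K) nn_overlap(e, eB, K)[["a_in_b"]])
  expect_true(all(diff(ov) >= 0))

  # null combinatorics at k = 100, K = 10, averaged over seeds
  p0 <- 10 / 99
  reps <- 8
  ovs <- sapply(seq_len(reps), function(s) {
    set.seed(1000 + s)
    a <- matrix(rnorm(200), 100, 2); b <- matrix(rnorm(200), 100, 2)
    rownames(a) <- rownames(b) <- sprintf("d%03d", 1:100)
    mean(nn_overlap(a, b, K = 10))
  })
  se <- sqrt(p0 * (1 - p0) / (100 * reps))
  expect_lt(abs(mean(ovs) - p0), 3 * se * sqrt(2))  # directions correlated
  expect_error(nn_overlap(e, planted_manifold(30, seed = 9)), "different")
})

test_that("cross-space regressions detect affine relations and nulls", {
  e <- planted_manifold(120, seed = 11)
  th <- 0.6
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  eB <- e %*% rot + 2
  rownames(eB) <- rownames(e)
  tab <- suppressWarnings(cross_space_regression(e, eB))  # exact fit
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$r_squared, rep(1, 4), tolerance = 1e-9)

  set.seed(12)
  eN <- matrix(rnorm(240), 120, 2); rownames(eN) <- rownames(e)
  tabN <- cross_space_regression(e, eN)
  expect_true(all(tabN$r_squared < 0.15))
  expect_true(all(tabN$p_value > 1e-4))
})

test_that("checklist prediction ladder has the six models and sane nesting", {
  fx <- make_drawings(seed = 21, n_participants = 80)
  d <- fx$drawings
  ids <- d$drawing_id
  qual <- data.frame(drawing_id = ids, score = d$true_quality)
  h <- cbind(d$perc_x, d$perc_y); rownames(h) <- ids
  set.seed(22)
  m <- h %*% matrix(c(0, -1, 1, 0), 2) + matrix(rnorm(2 * nrow(h), 0, 0.3),
                                                ncol = 2)
  rownames(m) <- ids
  # planted identity: checklist an exact linear function of quality-rank
  chk_lin <- data.frame(drawing_id = ids, final = 2 + 7 * d$true_quality)
  tab <- suppressWarnings(checklist_prediction_ladder(chk_lin, qual, h, m))
  expect_equal(tab$model,
               c("QR only", "HE only", "ME only", "QR x HE", "QR x ME",
                 "QR x HE x ME"))
  expect_equal(tab$adj_r_squared[tab$model == "QR only"], 1, tolerance = 1e-9)

  # realistic checklist: unadjusted R^2 never drops along nested chains
  rr <- simulate_checklist_raters(d, 0.05, 0.02, seed = 23)
  chk <- checklist_scores(rr)
  tab2 <- checklist_prediction_ladder(chk, qual, h, m)
  r2 <- stats::setNames(tab2$r_squared, tab2$model)
  expect_gte(r2[["QR x HE"]], r2[["HE only"]])
  expect_gte(r2[["QR x ME"]], r2[["QR only"]])
  expect_gte(r2[["QR x HE x ME"]], r2[["QR x HE"]])
  # full model adjusted R^2 at least each single-metric model's
  adj <- stats::setNames(tab2$adj_r_squared, tab2$model)
  expect_gte(adj[["QR x HE x ME"]],
             max(adj[["QR only"]], adj[["HE only"]], adj[["ME only"]]) - 1e-9)
})

test_that("distance correlations use the upper triangle and respect isometry", {
  e <- planted_manifold(30, seed = 31)
  rot <- matrix(c(0, 1, -1, 0), 2, 2)
  e2 <- e %*% rot - 4
  rownames(e2) <- rownames(e)
  dm <- list(a = metric_distances(e), b = metric_distances(e2))
  tab <- distance_metric_correlations(dm)
  expect_equal(tab$correlation, 1, tolerance = 1e-10)
  expect_equal(tab$n_pairs, 30 * 29 / 2)

  # checklist distances: 1D metric satisfies the triangle inequality
  sc <- stats::setNames(sample(0:12, 30, replace = TRUE), rownames(e))
  dc <- metric_distances(sc)
  k <- nrow(dc)
  ijk <- expand.grid(i = 1:6, j = 1:6, l = 1:6)
  ok <- apply(ijk, 1, function(v)
    dc[v[1], v[3]] <= dc[v[1], v[2]] + dc[v[2], v[3]] + 1e-12)
  expect_true(all(ok))

  # combinatorial pair count at k = 305
  big <- matrix(rnorm(305 * 2), 305, 2)
  rownames(big) <- sprintf("d%03d", 1:305)
  tabk <- distance_metric_correlations(list(x = metric_distances(big),
                                            y = metric_distances(big + 1e-9)))
  expect_equal(tabk$n_pairs, 46360L)

  # Mantel permutation p-value is small for strongly related matrices
  fx <- make_drawings(seed = 33, n_participants = 40)
  d <- fx$drawings
  co <- cbind(d$perc_x, d$perc_y); rownames(co) <- d$drawing_id
  qd <- stats::setNames(d$true_quality, d$drawing_id)
  tabm <- distance_metric_correlations(
    list(emb = metric_distances(co), qual = metric_distances(qd)),
    mantel_permutations = 99, seed = 34)
  expect_lt(tabm$mantel_p, 0.05)
})

test_that("comparison statistics are invariant to rigid transforms", {
  e <- planted_manifold(35, seed = 41)
  eB <- planted_manifold(35, seed = 42); rownames(eB) <- rownames(e)
  th <- -0.9
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  eT <- e %*% rot + c(10, -3)[col(e %*% rot)]
  rownames(eT) <- rownames(e)
  expect_equal(nn_overlap(e, eB, 5), nn_overlap(eT, eB, 5))
  expect_identical(nearest_neighbors(e, 3), nearest_neighbors(eT, 3))
  d1 <- distance_metric_correlations(list(a = metric_distances(e),
                                          b = metric_distances(eB)))
  d2 <- distance_metric_correlations(list(a = metric_distances(eT),
                                          b = metric_distances(eB)))
  expect_equal(d1$correlation, d2$correlation, tolerance = 1e-9)
})
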