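# Metrics, stratification, pairwise RMSD summaries, ablation machinery.

test_that("metrics match closed forms and an independent recomputation", {
  y <- c(4.1, 5.2, 6.3)
  m <- compute_metrics(y, y)
  expect_equal(m$rmse, 0); expect_equal(m$mae, 0)
  expect_equal(m$r2, 1); expect_equal(m$pearson_r, 1)
  expect_equal(m$spearman_rho, 1)

  m2 <- compute_metrics(c(0, 0), c(3, 4))
  expect_equal(m2$rmse, sqrt(12.5))
  expect_equal(m2$mae, 3.5)

  # independent textbook recomputation on random vectors
  set.seed(30)
  for (i in 1:5) {
    yh <- rnorm(100); yy <- rnorm(100)
    m <- compute_metrics(yh, yy)
    expect_equal(m$rmse, sqrt(sum((yh - yy)^2) / 100), tolerance = 1e-10)
    expect_equal(m$mae, sum(abs(yh - yy)) / 100, tolerance = 1e-10)
    expect_equal(m$r2, 1 - sum((yh - yy)^2) / sum((yy - mean(yy))^2),
                 tolerance = 1e-10)
    pr <- sum((yh - mean(yh)) * (yy - mean(yy))) /
      sqrt(sum((yh - mean(yh))^2) * sum((yy - mean(yy))^2))
    expect_equal(m$pearson_r, pr, tolerance = 1e-10)
    rh <- rank(yh); ry <- rank(yy)
    rho <- sum((rh - mean(rh)) * (ry - mean(ry))) /
      sqrt(sum((rh - mean(rh))^2) * sum((ry - mean(ry))^2))
    expect_equal(m$spearman_rho, rho, tolerance = 1e-10)
  }

  expect_error(compute_metrics(1:3, 1:4), "shape error")
  flat <- compute_metrics(c(1, 2, 3), c(5, 5, 5))
  expect_true(flat$undefined)
  expect_true(is.na(flat$pearson_r))
  # metrics invariant to evaluation-set ordering
  set.seed(31)
  yh <- rnorm(50); yy <- rnorm(50)
  perm <- sample(50)
  expect_equal(unlist(compute_metrics(yh, yy)[1:5]),
               unlist(compute_metrics(yh[perm], yy[perm])[1:5]),
               tolerance = 1e-12)
})

test_that("good-pose counting uses the strict 2.5 A threshold and 3-way groups", {
  g <- count_good_poses(c(1.0, 3.0, 2.4))
  expect_equal(g$n_good, 2L); expect_equal(g$group, "1-4")
  g <- count_good_poses(c(2.5, 2.5))              # boundary is NOT good
  expect_equal(g$n_good, 0L); expect_equal(g$group, "none")
  g <- count_good_poses(rep(0.5, 10))
  expect_equal(g$n_good, 10L); expect_equal(g$group, ">4")
  expect_equal(count_good_poses(rep(3, 4))$group, "none")
  expect_equal(count_good_poses(c(rep(1, 4), 3))$group, "1-4")
  expect_equal(count_good_poses(rep(1, 5))$group, ">4")
})

test_that("pairwise RMSD statistics cover all pose pairs with unit-area density", {
  ds <- tiny_dataset(3, seed = 32, poses_per_entity = 5)
  bag <- ds$bags[[1]]
  pw <- pairwise_rmsd_stats(bag)
  expect_length(pw$rmsds, choose(5, 2))
  area <- sum(pw$density * diff(pw$breaks))
  expect_equal(area, 1, tolerance = 1e-9)

  # identical poses give all-zero pairwise RMSD
  same <- bag
  same$instances <- rep(bag$instances[1], 3)
  pw0 <- pairwise_rmsd_stats(same)
  expect_equal(pw0$rmsds, rep(0, 3))

  single <- bag
  single$instances <- bag$instances[1]
  expect_warning(pw1 <- pairwise_rmsd_stats(single), "fewer than 2")
  expect_length(pw1$rmsds, 0L)
})

test_that("bag-size ablation samples deterministically and degenerates at full K", {
  set.seed(33)
  st <- embedding_store()
  nbag <- 12L; D <- 6L; K <- 5L
  labels <- stats::setNames(runif(nbag, 3, 8), sprintf("e%02d", 1:nbag))
  for (b in names(labels)) {
    for (k in 1:K) embedding_store_write(st, b, k, rnorm(D))
  }
  head <- attention_head(D, fc_widths = c(4L, 3L))
  ab <- bag_size_ablation(head, st, labels, k_values = c(1, 3, 5),
                          trials = 4L, seed = 1L)
  expect_equal(sort(unique(ab$results$k)), c(1, 3, 5))
  # k = K: every trial draws the full bag, so results are identical
  at_full <- ab$results[ab$results$k == 5, "rmse"]
  expect_equal(max(at_full) - min(at_full), 0)
  ab2 <- bag_size_ablation(head, st, labels, k_values = c(1, 3, 5),
                           trials = 4L, seed = 1L)
  expect_identical(ab$results, ab2$results)
  expect_error(bag_size_ablation(head, st, labels, k_values = 9L),
               "data error")
})

test_that("method comparison table has 3 methods x 5 metrics and handles constants", {
  set.seed(34)
  labels <- stats::setNames(runif(6, 3, 8), sprintf("m%d", 1:6))
  pose_preds <- do.call(rbind, lapply(names(labels), function(e) {
    data.frame(entity_id = e, pose_rank = 1:4, is_crystal = FALSE,
               y = rnorm(4, labels[e], 0.3))
  }))
  st <- embedding_store()
  for (e in names(labels)) for (k in 1:4) embedding_store_write(st, e, k, rnorm(3))
  head <- attention_head(3L, fc_widths = c(3L, 2L))
  mil <- mil_predict(head, st, names(labels))
  cmp <- compare_methods(pose_preds, mil, labels)
  expect_equal(dim(cmp$table), c(3L, 6L))
  expect_equal(cmp$table$method, c("Top", "Avg", "MIL"))
  expect_false(anyNA(cmp$table$rmse))

  # degenerate constant backbone: Top equals Avg entity-wise
  const_preds <- pose_preds
  const_preds$y <- 5
  cmp2 <- compare_methods(const_preds, mil, labels)
  expect_equal(cmp2$table$rmse[1], cmp2$table$rmse[2], tolerance = 1e-12)
})

test_that("stratified metrics partition entities by good-pose group", {
  set.seed(35)
  y <- rnorm(30, 6); yh <- y + rnorm(30, 0, 0.3)
  ngood <- rep(c(0L, 2L, 6L), each = 10L)
  tab <- stratified_metrics(yh, y, ngood)
  expect_setequal(tab$group, c("none", "1-4", ">4"))
  expect_equal(sum(tab$n), 30L)
})
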