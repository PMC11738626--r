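# Evaluation: the five regression metrics, method comparison against the
# Top/Avg pose baselines, good-pose stratification, pairwise-RMSD
# consistency, and the bag-size ablation.

#' Regression metrics for affinity prediction
#'
#' RMSE, MAE, coefficient of determination (r2 = 1 - SS_res/SS_tot), Pearson
#' correlation and Spearman rank correlation (average ranks on ties). When
#' the observed labels have zero variance the correlation-type metrics are
#' undefined and reported as NA with `undefined = TRUE`.
#'
#' @param y_hat predicted affinities (pK units).
#' @param y observed affinities.
#' @return a `metrics_report` list: `rmse`, `mae`, `r2`, `pearson_r`,
#'   `spearman_rho`, `n`, `undefined`.
#' @export
compute_metrics <- function(y_hat, y) {
  if (length(y_hat) != length(y)) {
    stop("shape error: y_hat has length ", length(y_hat), " but y has ",
         length(y))
  }
  stopifnot(length(y) >= 2L, all(is.finite(y_hat)), all(is.finite(y)))
  res <- y_hat - y
  rmse <- sqrt(mean(res^2))
  mae <- mean(abs(res))
  sst <- sum((y - mean(y))^2)
  if (sst == 0 || stats::sd(y_hat) == 0) {
    return(structure(list(rmse = rmse, mae = mae, r2 = NA_real_,
                          pearson_r = NA_real_, spearman_rho = NA_real_,
                          n = length(y), undefined = TRUE),
                     class = "metrics_report"))
  }
  structure(list(
    rmse = rmse, mae = mae,
    r2 = 1 - sum(res^2) / sst,
    pearson_r = stats::cor(y_hat, y),
    spearman_rho = stats::cor(y_hat, y, method = "spearman"),
    n = length(y), undefined = FALSE
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("RMSE %.3f  MAE %.3f  r2 %.3f  Pearson %.3f  Spearman %.3f (n=%d)\n",
              x$rmse, x$mae, x$r2, x$pearson_r, x$spearman_rho, x$n))
  invisible(x)
}

#' Count good poses and assign the stratification group
#'
#' A pose is "good" when its RMSD to the reference is strictly below
#' `threshold`. Entities are grouped as `"none"` (0 good poses), `"1-4"`,
#' or `">4"`.
#'
#' @param rmsds per-pose RMSD values (Angstrom).
#' @param threshold good-pose cutoff (strict).
#' @return list with `n_good` and `group`.
#' @export
count_good_poses <- function(rmsds, threshold = 2.5) {
  stopifnot(all(rmsds >= 0))
  n_good <- sum(rmsds < threshold)
  group <- if (n_good == 0L) "none" else if (n_good <= 4L) "1-4" else ">4"
  list(n_good = n_good, group = group)
}

#' Pairwise RMSD consistency of a bag
#'
#' RMSD between every unordered pair of poses in the bag, plus a probability
#' density histogram (area 1). With fewer than two poses an empty result is
#' returned with a warning.
#'
#' @param bag a `pose_bag`.
#' @param breaks histogram bin edges (Angstrom); extended if any pairwise
#'   RMSD exceeds them.
#' @return list with `rmsds` (length K(K-1)/2), `breaks`, `density`.
#' @export
pairwise_rmsd_stats <- function(bag, breaks = seq(0, 15, by = 0.5)) {
  K <- length(bag$instances)
  if (K < 2L) {
    warning("bag has fewer than 2 poses; no pairwise RMSDs")
    return(list(rmsds = numeric(0), breaks = breaks,
                density = rep(0, length(breaks) - 1L)))
  }
  pairs <- utils::combn(K, 2L)
  rmsds <- apply(pairs, 2L, function(p) {
    pose_rmsd(bag$instances[[p[1L]]], bag$instances[[p[2L]]])
  })
  if (max(rmsds) > max(breaks)) {
    breaks <- c(breaks, seq(max(breaks) + 0.5, max(rmsds) + 0.5, by = 0.5))
  }
  h <- graphics::hist(rmsds, breaks = breaks, plot = FALSE)
  list(rmsds = rmsds, breaks = h$breaks, density = h$density)
}

#' Compare MIL against the Top and Avg baselines
#'
#' One row per method over the same evaluation entities: `Top` scores the
#' rank-1 docking pose's stage-1 prediction, `Avg` the unweighted mean of
#' per-pose stage-1 predictions (crystal instances included when present),
#' and `MIL` the attention-pooled bag prediction. Entities without a rank-1
#' pose are excluded from Top with a warning.
#'
#' @param pose_preds data.frame from [backbone_pose_predictions()].
#' @param mil_preds list of `bag_prediction` (e.g. [mil_predict()]).
#' @param labels named numeric vector of entity labels.
#' @return list with `table` (3 x 5 metric data.frame) and `per_method`
#'   (the underlying `metrics_report`s).
#' @export
compare_methods <- function(pose_preds, mil_preds, labels) {
  entities <- names(labels)
  split_preds <- split(pose_preds, pose_preds$entity_id)
  top <- vapply(entities, function(e) {
    pp <- split_preds[[e]]
    if (is.null(pp) || !any(pp$pose_rank == 1L)) NA_real_ else baseline_top(pp)
  }, 1.0)
  if (anyNA(top)) {
    warning(sum(is.na(top)), " entities lack a rank-1 pose; excluded from Top")
  }
  avg <- vapply(entities, function(e) baseline_avg(split_preds[[e]]), 1.0)
  mil_ids <- vapply(mil_preds, `[[`, "", "entity_id")
  mil <- vapply(entities, function(e) {
    mil_preds[[match(e, mil_ids)]]$y_hat
  }, 1.0)
  reports <- list(
    Top = compute_metrics(top[!is.na(top)], labels[!is.na(top)]),
    Avg = compute_metrics(avg, labels),
    MIL = compute_metrics(mil, labels)
  )
  tab <- do.call(rbind, lapply(names(reports), function(m) {
    r <- reports[[m]]
    data.frame(method = m, rmse = r$rmse, mae = r$mae, r2 = r$r2,
               pearson_r = r$pearson_r, spearman_rho = r$spearman_rho)
  }))
  list(table = tab, per_method = reports)
}

#' Per-group metrics stratified by good-pose count
#'
#' @param y_hat,y named-aligned prediction and label vectors.
#' @param n_good per-entity good-pose counts (same order).
#' @return data.frame with one row per group (`none`, `1-4`, `>4`) present in
#'   the data, with entity count and metrics.
#' @export
stratified_metrics <- function(y_hat, y, n_good) {
  group <- ifelse(n_good == 0L, "none", ifelse(n_good <= 4L, "1-4", ">4"))
  do.call(rbind, lapply(c("none", "1-4", ">4"), function(gr) {
    sel <- group == gr
    if (sum(sel) < 2L) return(NULL)
    r <- compute_metrics(y_hat[sel], y[sel])
    data.frame(group = gr, n = sum(sel), rmse = r$rmse, mae = r$mae,
               r2 = r$r2)
  }))
}

#' Bag-size ablation
#'
#' For each bag size k, randomly subsample k instances per bag (without
#' replacement), predict with the MIL head, and compute metrics; repeated
#' over `trials` subsampling draws. Bags with fewer than `max(k_values)`
#' instances are excluded (with a message).
#'
#' @param head a trained `attention_head`.
#' @param store an `embedding_store` for the evaluation entities.
#' @param labels named numeric vector of entity labels.
#' @param k_values bag sizes to probe.
#' @param trials subsampling repetitions per k.
#' @param seed RNG seed for the subsampling.
#' @return list with `results` (per k and trial: rmse, r2) and `summary`
#'   (per k: mean/min/max of rmse and r2 across trials).
#' @export
bag_size_ablation <- function(head, store, labels, k_values = c(1, 3, 5, 7, 9),
                              trials = 10L, seed = 0L) {
  entities <- names(labels)
  recs <- lapply(entities, function(e) embedding_store_read(store, e))
  K <- vapply(recs, function(r) length(r$pose_rank), 1L)
  ok <- K >= max(k_values)
  if (!any(ok)) stop("data error: no bag has >= ", max(k_values), " poses")
  if (any(!ok)) {
    message(sum(!ok), " bags with fewer than ", max(k_values),
            " poses excluded from ablation")
  }
  recs <- recs[ok]; labs <- labels[ok]
  set.seed(seed)
  results <- do.call(rbind, lapply(seq_len(trials), function(tr) {
    do.call(rbind, lapply(k_values, function(k) {
      y_hat <- vapply(recs, function(r) {
        sel <- sample(nrow(r$embeddings), k)
        predict_bag(r$embeddings[sel, , drop = FALSE], head)$y_hat
      }, 1.0)
      m <- compute_metrics(y_hat, labs)
      data.frame(k = k, trial = tr, rmse = m$rmse, r2 = m$r2)
    }))
  }))
  summary <- do.call(rbind, lapply(sort(unique(results$k)), function(k) {
    r <- results[results$k == k, ]
    data.frame(k = k, rmse_mean = mean(r$rmse), rmse_min = min(r$rmse),
               rmse_max = max(r$rmse), r2_mean = mean(r$r2),
               r2_min = min(r$r2), r2_max = max(r$r2))
  }))
  list(results = results, summary = summary)
}
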