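# End-to-end synthetic benchmark: generate bags, run two-stage training,
# evaluate MIL against the Top/Avg baselines, and summarize attention
# behavior on the known-informative poses.

#' Run the full two-stage MIL experiment on a synthetic dataset
#'
#' Generates a dataset from `spec`, trains the backbone on training-split
#' pose instances (stage 1), extracts frozen embeddings for all entities,
#' trains the MIL attention head on training bags (stage 2), and evaluates
#' Top / Avg / MIL on the held-out test split. Because the generator knows
#' which poses are good (true RMSD < 2.5 Angstrom), the result also reports
#' the mean attention weight mass per informative instance relative to the
#' uniform level 1/K.
#'
#' @param spec a [synthetic_spec()]; its seed drives data generation.
#' @param architecture backbone architecture.
#' @param hyper backbone hyperparameter overrides ([backbone_model()]).
#' @param stage1_epochs,stage2_epochs epoch counts for the two stages.
#' @param train_seed seed for both training stages (initialization and
#'   shuffling); data and training randomness are controlled separately.
#' @param fc_widths MIL head hidden widths.
#' @param ablation_k if non-NULL, also run [bag_size_ablation()] on the test
#'   split with these k values.
#' @return list with `methods` (3 x 5 metric table), `reports`, `attention`
#'   (per-entity mean weight on good poses and the uniform level),
#'   `stratified` (per good-pose-group MIL metrics), `ablation` (if
#'   requested), `model`, `head`, `store`, `dataset`, and the test-split
#'   predictions.
#' @export
run_mil_experiment <- function(spec, architecture = c("sgcnn", "egnn"),
                               hyper = list(), stage1_epochs = 6L,
                               stage2_epochs = 40L, train_seed = spec$seed,
                               fc_widths = c(64L, 32L),
                               ablation_k = NULL) {
  architecture <- match.arg(architecture)
  ds <- generate_dataset(spec)
  train_bags <- ds$bags[ds$split$train]
  test_bags <- ds$bags[ds$split$test]

  inst_train <- prepare_instances(train_bags, architecture)
  inst_test <- prepare_instances(test_bags, architecture)

  cfg1 <- train_config(epochs = stage1_epochs, seed = train_seed)
  model <- train_backbone(train_bags, cfg1, architecture, hyper = hyper,
                          instances = inst_train)

  store <- embedding_store()
  extract_embeddings(model, train_bags, store, instances = inst_train)
  extract_embeddings(model, test_bags, store, instances = inst_test)

  train_labels <- vapply(train_bags, `[[`, 1.0, "label")
  names(train_labels) <- names(train_bags)
  cfg2 <- train_config(epochs = stage2_epochs, seed = train_seed)
  head <- train_mil(store, train_labels, cfg2, fc_widths = fc_widths)

  test_labels <- vapply(test_bags, `[[`, 1.0, "label")
  names(test_labels) <- names(test_bags)
  pose_preds <- backbone_pose_predictions(model, test_bags,
                                          instances = inst_test)
  mil_preds <- mil_predict(head, store, names(test_labels))
  cmp <- compare_methods(pose_preds, mil_preds, test_labels)

  # attention mass on known-good poses, relative to uniform 1/K
  truth <- ds$truth
  att <- do.call(rbind, lapply(mil_preds, function(p) {
    rec <- embedding_store_read(store, p$entity_id)
    tr <- truth[truth$entity_id == p$entity_id, ]
    good <- tr$good[match(rec$pose_rank, tr$pose_rank)]
    good[is.na(good)] <- FALSE  # crystal instances are not docking poses
    if (!any(good) || all(good)) return(NULL)
    data.frame(entity_id = p$entity_id,
               mean_weight_good = mean(p$attention_weights[good]),
               uniform = 1 / length(p$attention_weights),
               n_good = sum(good))
  }))

  ent <- ds$entities
  sel <- match(names(test_labels), ent$entity_id)
  mil_y <- vapply(mil_preds, `[[`, 1.0, "y_hat")
  strat <- stratified_metrics(mil_y, unname(test_labels), ent$n_good[sel])

  out <- list(methods = cmp$table, reports = cmp$per_method,
              attention = att, stratified = strat,
              model = model, head = head, store = store, dataset = ds,
              test_labels = test_labels,
              predictions = data.frame(entity_id = names(test_labels),
                                       y = unname(test_labels), mil = mil_y))
  if (!is.null(ablation_k)) {
    out$ablation <- bag_size_ablation(head, store, test_labels,
                                      k_values = ablation_k,
                                      seed = train_seed)
  }
  out
}

#' Summarize an experiment across seeds
#'
#' Repeats [run_mil_experiment()] over a vector of seeds (used for both data
#' generation and training) and collects the per-seed method metrics and
#' attention summaries.
#'
#' @param base_spec a [synthetic_spec()]; its seed field is replaced per run.
#' @param seeds integer vector of seeds.
#' @param ... passed to [run_mil_experiment()].
#' @return list with `per_seed` (list of experiment results), `methods`
#'   (long data.frame of per-seed metric rows) and `attention` (per-seed mean
#'   good-pose weight vs uniform).
#' @export
run_mil_benchmark <- function(base_spec, seeds = 0:9, ...) {
  per_seed <- lapply(seeds, function(s) {
    spec <- base_spec
    spec$seed <- as.integer(s)
    run_mil_experiment(spec, train_seed = as.integer(s), ...)
  })
  methods <- do.call(rbind, lapply(seq_along(seeds), function(i) {
    cbind(seed = seeds[i], per_seed[[i]]$methods)
  }))
  attention <- do.call(rbind, lapply(seq_along(seeds), function(i) {
    a <- per_seed[[i]]$attention
    data.frame(seed = seeds[i],
               mean_weight_good = mean(a$mean_weight_good),
               mean_uniform = mean(a$uniform))
  }))
  list(per_seed = per_seed, methods = methods, attention = attention)
}
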