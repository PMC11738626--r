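# Two-stage ("separate") training: stage 1 fits a backbone on individual
# pose instances, each labeled with its entity's affinity; stage 2 freezes
# the backbone, extracts per-pose embeddings, and fits the MIL attention
# head on bags of embeddings. Both stages use RMSprop with a multi-step
# learning-rate schedule and keep the last-epoch checkpoint (no
# validation-based selection).

#' Training configuration
#'
#' Defaults: RMSprop, initial learning rate
#' 0.001 decayed by 0.9 at epochs 5, 10, 20, 30, 50, 70 and 90, mini-batch
#' size 20 (instances in stage 1, bags in stage 2), last-epoch
#' checkpointing. RMSprop smoothing/epsilon are the framework-standard
#' alpha = 0.99, eps = 1e-8.
#'
#' @param lr0 initial learning rate.
#' @param lr_milestones epochs (0-based) at which the rate decays.
#' @param lr_gamma multiplicative decay factor.
#' @param batch_size mini-batch size.
#' @param epochs number of epochs.
#' @param seed RNG seed controlling initialization and batch shuffling.
#' @return a `train_config`.
#' @export
train_config <- function(lr0 = 0.001, lr_milestones = c(5, 10, 20, 30, 50, 70, 90),
                         lr_gamma = 0.9, batch_size = 20L, epochs = 150L,
                         seed = 0L) {
  stopifnot(all(diff(lr_milestones) > 0), lr_gamma > 0, lr_gamma < 1)
  structure(list(optimizer = "rmsprop", lr0 = lr0,
                 lr_milestones = lr_milestones, lr_gamma = lr_gamma,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 checkpoint_policy = "last-epoch"),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' Closed form of the multi-step schedule: `lr0 * gamma^m` where `m` is the
#' number of milestones at or below `epoch` (0-based).
#'
#' @param cfg a [train_config()].
#' @param epoch 0-based epoch index.
#' @return the learning rate.
#' @export
lr_at_epoch <- function(cfg, epoch) {
  stopifnot(epoch >= 0)
  cfg$lr0 * cfg$lr_gamma^sum(cfg$lr_milestones <= epoch)
}

#' Featurize and graph every pose instance of a bag list
#'
#' @param bags list of `pose_bag`.
#' @param architecture backbone architecture (decides the graph flavor).
#' @param pocket_radius passed to [featurize_complex()].
#' @return list with per-instance `graphs`, `entity_id`, `pose_rank`,
#'   `label` (the entity label inherited by every pose) and `is_crystal`.
#' @export
prepare_instances <- function(bags, architecture = c("sgcnn", "egnn"),
                              pocket_radius = 8.0) {
  architecture <- match.arg(architecture)
  build <- function(fi) lean_build(fi, architecture)
  graphs <- list(); entity <- character(); rank <- integer()
  label <- numeric(); crystal <- logical()
  for (bag in bags) {
    # feature matrices depend only on topology: compute once per bag and
    # reuse across poses that share elements, bonds and charges
    prot <- .ensure_charges(bag$protein, "gasteiger")
    pf <- .atom_features(prot)
    lig_cache <- NULL
    for (inst in bag$instances) {
      st <- .ensure_charges(inst$structure, "gasteiger")
      inst$structure <- st
      lf <- NULL
      if (!is.null(lig_cache) &&
          identical(st$atoms$element, lig_cache$element) &&
          identical(st$bonds, lig_cache$bonds) &&
          isTRUE(all.equal(st$atoms$charge, lig_cache$charge))) {
        lf <- lig_cache$features
      } else {
        lf <- .atom_features(st)
        lig_cache <- list(element = st$atoms$element, bonds = st$bonds,
                          charge = st$atoms$charge, features = lf)
      }
      fi <- featurize_complex(prot, inst, pocket_radius = pocket_radius,
                              .protein_features = pf, .ligand_features = lf)
      graphs[[length(graphs) + 1L]] <- build(fi)
      entity <- c(entity, bag$entity_id)
      rank <- c(rank, inst$pose_rank)
      label <- c(label, bag$label)
      crystal <- c(crystal, isTRUE(inst$is_crystal))
    }
  }
  list(graphs = graphs, entity_id = entity, pose_rank = rank, label = label,
       is_crystal = crystal)
}

#' Stage-1 backbone training on individual pose instances
#'
#' Every pose inherits its bag's entity-level label (the only label
#' available); the backbone's scalar head is fit by mini-batch RMSprop on
#' mean squared error. Deterministic given `cfg$seed`; the last-epoch model
#' is returned with per-epoch loss and learning-rate traces attached.
#'
#' @param train_bags list of `pose_bag`.
#' @param cfg a [train_config()].
#' @param architecture `"sgcnn"` or `"egnn"`.
#' @param hyper named list of [backbone_model()] hyperparameter overrides.
#' @param instances optional precomputed [prepare_instances()] result.
#' @param pose_sources which instances train: `"docking"`, `"crystal"`, or
#'   `"both"`.
#' @return a trained `backbone_model` with `loss_trace` and `lr_trace`.
#' @export
train_backbone <- function(train_bags, cfg, architecture = c("sgcnn", "egnn"),
                           hyper = list(), instances = NULL,
                           pose_sources = c("both", "docking", "crystal")) {
  architecture <- match.arg(architecture)
  pose_sources <- match.arg(pose_sources)
  if (length(train_bags) == 0L && is.null(instances)) {
    stop("data error: empty training set")
  }
  if (is.null(instances)) {
    instances <- prepare_instances(train_bags, architecture)
  }
  keep <- switch(pose_sources, both = rep(TRUE, length(instances$graphs)),
                 docking = !instances$is_crystal,
                 crystal = instances$is_crystal)
  graphs <- instances$graphs[keep]
  labels <- instances$label[keep]
  if (length(graphs) == 0L) stop("data error: no training instances")
  set.seed(cfg$seed)
  model <- do.call(backbone_model, c(list(architecture = architecture), hyper))
  params <- model$params
  opt <- rmsprop_new(params)
  loss_trace <- numeric(0)
  lr_trace <- numeric(0)
  n <- length(graphs)
  for (epoch in seq_len(cfg$epochs)) {
    lr <- lr_at_epoch(cfg, epoch - 1L)
    lr_trace <- c(lr_trace, lr)
    ord <- sample(n)
    starts <- seq(1L, n, by = cfg$batch_size)
    ep_loss <- 0
    for (s in starts) {
      idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
      batch <- graph_batch(graphs[idx])
      if (architecture == "sgcnn") {
        out <- sgcnn_fast(model, batch, labels[idx])
        for (nm in names(out$grads)) params[[nm]]$grad <- out$grads[[nm]]
        lval <- out$loss
      } else {
        out <- backbone_batch_forward(model, batch)
        loss <- ad_mse(out$pred, matrix(labels[idx], ncol = 1L))
        ad_backward(loss)
        lval <- as.numeric(loss$val)
      }
      opt <- rmsprop_step(opt, lr)
      ad_zero_grads(params)
      ep_loss <- ep_loss + lval * length(idx)
    }
    loss_trace <- c(loss_trace, ep_loss / n)
  }
  model$loss_trace <- loss_trace
  model$lr_trace <- lr_trace
  model$train_config <- cfg
  model
}

#' Extract frozen-backbone embeddings into a store
#'
#' No parameter updates occur; embeddings are value snapshots, so mutating
#' the model afterwards leaves the store unchanged.
#'
#' @param model a `backbone_model`.
#' @param bags list of `pose_bag`.
#' @param store an [embedding_store()] to fill (a fresh one by default).
#' @param instances optional precomputed [prepare_instances()] result.
#' @return the filled `embedding_store`.
#' @export
extract_embeddings <- function(model, bags, store = embedding_store(),
                               instances = NULL) {
  if (is.null(instances)) {
    instances <- prepare_instances(bags, model$architecture)
  }
  n <- length(instances$graphs)
  chunk <- 200L
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    batch <- graph_batch(instances$graphs[idx])
    emb <- backbone_batch_values(model, batch)$embedding
    .embedding_store_bulk(store, instances$entity_id[idx],
                          instances$pose_rank[idx], emb)
  }
  store
}

#' Per-pose scalar predictions from the stage-1 head
#'
#' @inheritParams extract_embeddings
#' @return data.frame with `entity_id`, `pose_rank`, `is_crystal`, `y`.
#' @export
backbone_pose_predictions <- function(model, bags, instances = NULL) {
  if (is.null(instances)) {
    instances <- prepare_instances(bags, model$architecture)
  }
  n <- length(instances$graphs)
  y <- numeric(n)
  chunk <- 200L
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    batch <- graph_batch(instances$graphs[idx])
    y[idx] <- as.numeric(backbone_batch_values(model, batch)$pred)
  }
  data.frame(entity_id = instances$entity_id, pose_rank = instances$pose_rank,
             is_crystal = instances$is_crystal, y = y)
}

# padded bag layout for vectorized MIL training
.pad_bags <- function(store, entities) {
  recs <- lapply(entities, function(e) embedding_store_read(store, e))
  K <- vapply(recs, function(r) length(r$pose_rank), 1L)
  kmax <- max(K)
  D <- store$dim
  E <- matrix(0, length(entities) * kmax, D)
  mask <- rep(FALSE, length(entities) * kmax)
  for (b in seq_along(entities)) {
    rows <- (b - 1L) * kmax + seq_len(K[b])
    E[rows, ] <- recs[[b]]$embeddings
    mask[rows] <- TRUE
  }
  list(E = E, mask = mask, K = K, kmax = kmax, D = D)
}

# ad-graph MIL forward over a batch of padded bags; returns list(pred, a)
.mil_batch_forward <- function(head, E, mask, nbags, kmax) {
  groups <- rep(seq_len(nbags), each = kmax)
  p <- head$params
  if (head$mode == "single") {
    logits <- ad_tanh(ad_matmul(ad_const(E), p$W_att_1))
    a <- ad_group_softmax(logits, groups, mask)
    z <- ad_rowsum(ad_mul_colvec(ad_const(E), a), groups, nbags)
  } else {
    zs <- vector("list", head$n_heads)
    for (hh in seq_len(head$n_heads)) {
      cols <- ((hh - 1L) * head$slice + 1L):(hh * head$slice)
      Es <- E[, cols, drop = FALSE]
      logits <- ad_tanh(ad_matmul(ad_const(Es), p[[paste0("W_att_", hh)]]))
      ah <- ad_group_softmax(logits, groups, mask)
      zs[[hh]] <- ad_rowsum(ad_mul_colvec(ad_const(Es), ah), groups, nbags)
      if (hh == 1L) a <- ah
    }
    z <- do.call(ad_cbind, zs)
  }
  h1 <- ad_relu(ad_add(ad_matmul(z, p$W1), p$b1))
  h2 <- ad_relu(ad_add(ad_matmul(h1, p$W2), p$b2))
  pred <- ad_add(ad_matmul(h2, p$W3), p$b3)
  list(pred = pred, a = a)
}

#' Stage-2 MIL head training on extracted embeddings
#'
#' Minimizes bag-level mean squared error with RMSprop under the milestone
#' schedule; deterministic given `cfg$seed`; returns the last-epoch head.
#'
#' @param store an `embedding_store` of frozen-backbone embeddings.
#' @param labels named numeric vector of entity labels (pK units); every
#'   entity must have embeddings in the store.
#' @param cfg a [train_config()].
#' @param mode,n_heads,fc_widths passed to [attention_head()].
#' @return a trained `attention_head` with `loss_trace` and `lr_trace`.
#' @export
train_mil <- function(store, labels, cfg, mode = "single", n_heads = 1L,
                      fc_widths = c(128L, 64L)) {
  entities <- names(labels)
  if (is.null(entities)) stop("labels must be a named vector of entity ids")
  missing_ent <- setdiff(entities, embedding_store_entities(store))
  if (length(missing_ent)) {
    stop("alignment error: no embeddings for ",
         paste(utils::head(missing_ent, 5L), collapse = ", "))
  }
  pad <- .pad_bags(store, entities)
  set.seed(cfg$seed)
  head <- attention_head(pad$D, mode = mode, n_heads = n_heads,
                         fc_widths = fc_widths)
  # freeze training-set embedding statistics into the head so attention
  # logits stay in tanh's responsive range regardless of embedding scale
  head$center <- colMeans(pad$E[pad$mask, , drop = FALSE])
  head$scale <- pmax(apply(pad$E[pad$mask, , drop = FALSE], 2L, stats::sd),
                     1e-8)
  pad$E <- sweep(sweep(pad$E, 2L, head$center), 2L, head$scale, "/")
  pad$E[!pad$mask, ] <- 0
  params <- head$params
  opt <- rmsprop_new(params)
  nb <- length(entities)
  loss_trace <- numeric(0); lr_trace <- numeric(0)
  for (epoch in seq_len(cfg$epochs)) {
    lr <- lr_at_epoch(cfg, epoch - 1L)
    lr_trace <- c(lr_trace, lr)
    ord <- sample(nb)
    ep_loss <- 0
    for (s in seq(1L, nb, by = cfg$batch_size)) {
      bsel <- ord[s:min(s + cfg$batch_size - 1L, nb)]
      rows <- as.vector(t(outer(bsel - 1L, seq_len(pad$kmax),
                                function(b, k) b * pad$kmax + k)))
      out <- .mil_batch_forward(head, pad$E[rows, , drop = FALSE],
                                pad$mask[rows], length(bsel), pad$kmax)
      loss <- ad_mse(out$pred, matrix(labels[bsel], ncol = 1L))
      ad_backward(loss)
      opt <- rmsprop_step(opt, lr)
      ad_zero_grads(params)
      ep_loss <- ep_loss + as.numeric(loss$val) * length(bsel)
    }
    loss_trace <- c(loss_trace, ep_loss / nb)
  }
  head$loss_trace <- loss_trace
  head$lr_trace <- lr_trace
  head$train_config <- cfg
  head
}

#' MIL predictions for a set of entities
#'
#' @param head a trained `attention_head`.
#' @param store an `embedding_store`.
#' @param entities character vector of entity ids.
#' @return list of `bag_prediction`, in input order.
#' @export
mil_predict <- function(head, store, entities) {
  lapply(entities, function(e) {
    rec <- embedding_store_read(store, e)
    predict_bag(rec$embeddings, head, entity_id = e)
  })
}

#' Simultaneous (end-to-end) training of backbone and MIL head
#'
#' The alternative to separate training: gradients flow from the bag-level
#' loss through the attention head into the backbone. Mini-batch size is
#' forced to one bag. Provided for completeness; the separate two-stage path
#' is the recommended and better-exercised route.
#'
#' @inheritParams train_backbone
#' @param fc_widths MIL head widths.
#' @return list with `model` (backbone) and `head` (attention head), each
#'   with a shared `loss_trace`.
#' @export
train_simultaneous <- function(train_bags, cfg, architecture = c("sgcnn", "egnn"),
                               hyper = list(), fc_widths = c(128L, 64L)) {
  architecture <- match.arg(architecture)
  instances <- prepare_instances(train_bags, architecture)
  set.seed(cfg$seed)
  model <- do.call(backbone_model, c(list(architecture = architecture), hyper))
  head <- attention_head(model$D, fc_widths = fc_widths)
  params <- c(model$params, head$params)
  opt <- rmsprop_new(params)
  labels <- vapply(train_bags, `[[`, 1.0, "label")
  by_bag <- split(seq_along(instances$graphs), instances$entity_id)
  ids <- vapply(train_bags, `[[`, "", "entity_id")
  loss_trace <- numeric(0)
  for (epoch in seq_len(cfg$epochs)) {
    lr <- lr_at_epoch(cfg, epoch - 1L)
    ord <- sample(length(train_bags))
    ep_loss <- 0
    for (b in ord) {
      idx <- by_bag[[ids[b]]]
      batch <- graph_batch(instances$graphs[idx])
      emb <- backbone_batch_forward(model, batch)$embedding
      K <- length(idx)
      logits <- ad_tanh(ad_matmul(emb, head$params$W_att_1))
      a <- ad_group_softmax(logits, rep(1L, K))
      z <- ad_rowsum(ad_mul_colvec(emb, a), rep(1L, K), 1L)
      h1 <- ad_relu(ad_add(ad_matmul(z, head$params$W1), head$params$b1))
      h2 <- ad_relu(ad_add(ad_matmul(h1, head$params$W2), head$params$b2))
      pred <- ad_add(ad_matmul(h2, head$params$W3), head$params$b3)
      loss <- ad_mse(pred, matrix(labels[b]))
      ad_backward(loss)
      opt <- rmsprop_step(opt, lr)
      ad_zero_grads(params)
      ep_loss <- ep_loss + as.numeric(loss$val)
    }
    loss_trace <- c(loss_trace, ep_loss / length(train_bags))
  }
  model$loss_trace <- loss_trace
  head$loss_trace <- loss_trace
  list(model = model, head = head)
}

#' Write / read a flat key-value config file and run manifest
#'
#' @param cfg a [train_config()].
#' @param path file path.
#' @export
train_config_write <- function(cfg, path) {
  lines <- vapply(names(cfg), function(k) {
    paste0(k, " = ", paste(cfg[[k]], collapse = ","))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname train_config_write
#' @export
train_config_read <- function(path) {
  kv <- strsplit(readLines(path), " = ", fixed = TRUE)
  vals <- stats::setNames(lapply(kv, `[`, 2L), vapply(kv, `[`, "", 1L))
  num <- function(x) as.numeric(strsplit(x, ",", fixed = TRUE)[[1L]])
  train_config(lr0 = num(vals$lr0), lr_milestones = num(vals$lr_milestones),
               lr_gamma = num(vals$lr_gamma), batch_size = num(vals$batch_size),
               epochs = num(vals$epochs), seed = num(vals$seed))
}
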