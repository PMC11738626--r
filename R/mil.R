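# Attention-based MIL pooling: a bag of pose embeddings -> one affinity.
#
# The pooling layer computes one logit per instance, logit_k = tanh(W h_k),
# softmax-normalizes the logits across the bag into weights a_k (nonnegative,
# summing to 1), and pools z = sum_k a_k h_k. Because tanh is bounded, the
# weight ratio between any two instances is at most e^2; the softmax is taken
# directly over the tanh outputs. A three-layer fully-connected stack maps
# the pooled z to the predicted affinity. Everything is invariant to the
# order of instances in the bag.

#' Construct a MIL attention head
#'
#' @param D embedding dimension of the backbone.
#' @param mode `"single"` (one global attention projection) or `"multihead"`
#'   (each head attends over its own D/n_heads slice; head outputs are
#'   concatenated back to length D).
#' @param n_heads number of heads (multihead mode).
#' @param fc_widths hidden widths of the three-layer fully-connected stack
#'   (D -> fc_widths[1] -> fc_widths[2] -> 1, ReLU activations).
#' @return an `attention_head`; parameters are drawn from the current RNG
#'   state (Glorot-uniform weights, zero biases).
#' @export
attention_head <- function(D, mode = c("single", "multihead"), n_heads = 1L,
                           fc_widths = c(128L, 64L)) {
  mode <- match.arg(mode)
  if (mode == "multihead" && D %% n_heads != 0L) {
    stop("configuration error: D = ", D, " not divisible by n_heads = ", n_heads)
  }
  nh <- if (mode == "single") 1L else as.integer(n_heads)
  ds <- D %/% nh
  p <- list()
  for (hh in seq_len(nh)) p[[paste0("W_att_", hh)]] <- ad_glorot(ds, 1L)
  p$W1 <- ad_glorot(D, fc_widths[1L]); p$b1 <- ad_zeros(1L, fc_widths[1L])
  p$W2 <- ad_glorot(fc_widths[1L], fc_widths[2L]); p$b2 <- ad_zeros(1L, fc_widths[2L])
  p$W3 <- ad_glorot(fc_widths[2L], 1L); p$b3 <- ad_zeros(1L, 1L)
  structure(list(D = as.integer(D), mode = mode, n_heads = nh,
                 slice = ds, fc_widths = as.integer(fc_widths), params = p,
                 center = NULL, scale = NULL),
            class = "attention_head")
}

# standardize embeddings with the head's frozen training statistics (set by
# train_mil); identity for an untrained head
.head_scale <- function(H, head) {
  if (is.null(head$center)) return(H)
  sweep(sweep(H, 2L, head$center), 2L, head$scale, "/")
}

.softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' Attention pooling of a bag of embeddings
#'
#' @param H K x D matrix of instance embeddings (rows are poses).
#' @param head an [attention_head()].
#' @return list with `z` (length-D pooled embedding) and `a` (length-K
#'   attention weights, nonnegative, summing to 1). Reordering the rows of
#'   `H` permutes `a` identically and leaves `z` unchanged.
#' @export
attention_pool <- function(H, head) {
  H <- .check_bag_matrix(H, head$D)
  if (head$mode != "single") {
    mh <- multihead_pool(H, head)
    return(list(z = mh$z, a = colMeans(mh$head_weights)))
  }
  logits <- tanh(.head_scale(H, head) %*% head$params$W_att_1$val)
  a <- .softmax(as.numeric(logits))
  list(z = as.numeric(crossprod(H, a)), a = a)
}

#' Multi-head attention pooling
#'
#' Each head computes tanh-softmax attention over its own slice of the
#' embedding and pools that slice; the pooled slices are concatenated.
#'
#' @inheritParams attention_pool
#' @return list with `z` (length-D) and `head_weights` (n_heads x K matrix;
#'   each row sums to 1).
#' @export
multihead_pool <- function(H, head) {
  H <- .check_bag_matrix(H, head$D)
  K <- nrow(H)
  z <- numeric(0)
  wts <- matrix(0, head$n_heads, K)
  for (hh in seq_len(head$n_heads)) {
    cols <- ((hh - 1L) * head$slice + 1L):(hh * head$slice)
    Hs <- H[, cols, drop = FALSE]
    Hsc <- .head_scale(H, head)[, cols, drop = FALSE]
    a <- .softmax(as.numeric(tanh(Hsc %*% head$params[[paste0("W_att_", hh)]]$val)))
    z <- c(z, as.numeric(crossprod(Hs, a)))
    wts[hh, ] <- a
  }
  list(z = z, head_weights = wts)
}

.check_bag_matrix <- function(H, D) {
  H <- as.matrix(H)
  if (nrow(H) == 0L) stop("empty bag: no instance embeddings")
  if (!all(is.finite(H))) stop("numeric error: non-finite embedding")
  if (ncol(H) != D) stop("embedding dimension ", ncol(H), " != head D ", D)
  H
}

.fc_stack <- function(z, p, head = NULL) {
  if (!is.null(head) && !is.null(head$center)) {
    z <- .head_scale(z, head)
  }
  h1 <- pmax(z %*% p$W1$val + matrix(p$b1$val, nrow(z), ncol(p$b1$val),
                                     byrow = TRUE), 0)
  h2 <- pmax(h1 %*% p$W2$val + matrix(p$b2$val, nrow(h1), ncol(p$b2$val),
                                      byrow = TRUE), 0)
  h2 %*% p$W3$val + as.numeric(p$b3$val)
}

#' Predict a bag's affinity from its instance embeddings
#'
#' @inheritParams attention_pool
#' @param entity_id optional identifier carried into the result.
#' @return a `bag_prediction`: `entity_id`, `y_hat` (pK units) and
#'   `attention_weights` (length K, summing to 1).
#' @export
predict_bag <- function(H, head, entity_id = NA_character_) {
  pooled <- attention_pool(H, head)
  y <- as.numeric(.fc_stack(matrix(pooled$z, 1L), head$params, head))
  structure(list(entity_id = entity_id, y_hat = y,
                 attention_weights = pooled$a),
            class = "bag_prediction")
}

#' Top and Avg pose baselines
#'
#' `baseline_top` returns the prediction of the rank-1 pose (the top docking
#' pose by score); `baseline_avg` the unweighted mean across poses of the
#' entity. Crystal instances (rank 0) never define Top.
#'
#' @param per_pose data.frame with columns `pose_rank` and `y` (per-pose
#'   scalar predictions from the backbone's stage-1 head).
#' @return scalar prediction.
#' @export
baseline_top <- function(per_pose) {
  stopifnot(nrow(per_pose) >= 1L)
  hit <- per_pose$pose_rank == 1L
  if (!any(hit)) stop("Top undefined: no rank-1 pose present")
  per_pose$y[hit][1L]
}

#' @rdname baseline_top
#' @export
baseline_avg <- function(per_pose) {
  stopifnot(nrow(per_pose) >= 1L)
  mean(per_pose$y)
}

#' Serialize / restore an attention head
#'
#' @param head an `attention_head`.
#' @param path file path.
#' @export
attention_head_save <- function(head, path) {
  saveRDS(list(D = head$D, mode = head$mode, n_heads = head$n_heads,
               fc_widths = head$fc_widths,
               center = head$center, scale = head$scale,
               values = lapply(head$params, function(p) p$val)), path)
  invisible(path)
}

#' @rdname attention_head_save
#' @export
attention_head_load <- function(path) {
  x <- readRDS(path)
  head <- attention_head(x$D, mode = x$mode, n_heads = x$n_heads,
                         fc_widths = x$fc_widths)
  head$center <- x$center
  head$scale <- x$scale
  for (nm in names(x$values)) head$params[[nm]]$val <- x$values[[nm]]
  head
}

#' Tabulate bag predictions
#'
#' @param preds list of `bag_prediction`.
#' @return data.frame with `entity_id`, `y_hat`, `K` and attention weight
#'   columns `a1..aKmax` (NA beyond a bag's K), the package's standard
#'   prediction output table.
#' @export
bag_prediction_table <- function(preds) {
  kmax <- max(vapply(preds, function(p) length(p$attention_weights), 1L))
  rows <- lapply(preds, function(p) {
    a <- c(p$attention_weights, rep(NA_real_, kmax - length(p$attention_weights)))
    cbind(data.frame(entity_id = p$entity_id, y_hat = p$y_hat,
                     K = length(p$attention_weights)),
          stats::setNames(as.data.frame(t(a)), paste0("a", seq_len(kmax))))
  })
  do.call(rbind, rows)
}
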