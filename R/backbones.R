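# Per-instance graph-network backbones: map a complex graph to a fixed-length
# embedding plus a scalar affinity prediction (the stage-1 head).
#
# Two architectures:
#  * "sgcnn" -- a spatial graph convolutional network in the PotentialNet
#    lineage: a gated (GRU-updated) message-passing stage over covalent edges
#    followed by one over noncovalent edges (2 propagation steps each), each
#    closed by a gated attention-sum "gather" readout. The default gather
#    widths (16 covalent, 12 noncovalent) fix the concatenated embedding at
#    28. Internals the lineage leaves open (input embedding, GRU gating,
#    readout form) are reconstructions in its style.
#  * "egnn" -- an E(n)-invariant message-passing network over the radius
#    graph: 6 layers with residual connections and per-edge sigmoid attention
#    gates; the squared inter-atomic distance is the single edge feature and
#    coordinates are never updated, so the embedding is exactly invariant to
#    rotations, translations and reflections.

#' Construct a backbone model
#'
#' Parameters are initialized from the current RNG state (Glorot-uniform
#' weights, zero biases); call `set.seed()` first for reproducibility.
#'
#' @param architecture `"sgcnn"` or `"egnn"`.
#' @param hidden_dim node-state width (SGCNN GRU width; EGNN layer width and
#'   embedding dimension).
#' @param gather_cov,gather_noncov SGCNN readout ("gather") widths for the
#'   covalent and noncovalent stages; the embedding is their concatenation.
#' @param n_layers number of EGNN layers.
#' @param n_steps GRU propagation steps per SGCNN stage.
#' @param head_hidden width of the scalar head's hidden layer.
#' @return a `backbone_model` with fields `architecture`, `hyper`, `params`
#'   (named list of trainable matrices) and `D` (embedding length).
#' @export
backbone_model <- function(architecture = c("sgcnn", "egnn"),
                           hidden_dim = if (architecture[1] == "sgcnn") 16L else 128L,
                           gather_cov = 16L, gather_noncov = 12L,
                           n_layers = 6L, n_steps = 2L, head_hidden = 16L) {
  architecture <- match.arg(architecture)
  nfeat <- 19L
  h <- as.integer(hidden_dim)
  p <- list()
  if (architecture == "sgcnn") {
    p$W_in <- ad_glorot(nfeat, h); p$b_in <- ad_zeros(1L, h)
    for (s in c("cov", "noncov")) {
      p[[paste0("We_", s)]] <- ad_glorot(h + 1L, h)
      p[[paste0("be_", s)]] <- ad_zeros(1L, h)
      for (g in c("r", "z", "n")) {
        p[[paste0("Wm", g, "_", s)]] <- ad_glorot(h, h)
        p[[paste0("Wh", g, "_", s)]] <- ad_glorot(h, h)
        p[[paste0("b", g, "_", s)]] <- ad_zeros(1L, h)
      }
    }
    p$Wg_cov <- ad_glorot(h + nfeat, gather_cov)
    p$bg_cov <- ad_zeros(1L, gather_cov)
    p$Wv_cov <- ad_glorot(h + nfeat, gather_cov)
    p$bv_cov <- ad_zeros(1L, gather_cov)
    p$Wg_noncov <- ad_glorot(h + nfeat, gather_noncov)
    p$bg_noncov <- ad_zeros(1L, gather_noncov)
    p$Wv_noncov <- ad_glorot(h + nfeat, gather_noncov)
    p$bv_noncov <- ad_zeros(1L, gather_noncov)
    D <- as.integer(gather_cov + gather_noncov)
  } else {
    p$W_in <- ad_glorot(nfeat, h); p$b_in <- ad_zeros(1L, h)
    for (l in seq_len(n_layers)) {
      p[[paste0("We1_", l)]] <- ad_glorot(2L * h + 1L, h)
      p[[paste0("be1_", l)]] <- ad_zeros(1L, h)
      p[[paste0("We2_", l)]] <- ad_glorot(h, h)
      p[[paste0("be2_", l)]] <- ad_zeros(1L, h)
      p[[paste0("Wa_", l)]] <- ad_glorot(h, 1L)
      p[[paste0("ba_", l)]] <- ad_zeros(1L, 1L)
      p[[paste0("Wh1_", l)]] <- ad_glorot(2L * h, h)
      p[[paste0("bh1_", l)]] <- ad_zeros(1L, h)
      p[[paste0("Wh2_", l)]] <- ad_glorot(h, h)
      p[[paste0("bh2_", l)]] <- ad_zeros(1L, h)
    }
    p$Wo1 <- ad_glorot(h, h); p$bo1 <- ad_zeros(1L, h)
    p$Wo2 <- ad_glorot(h, h); p$bo2 <- ad_zeros(1L, h)
    D <- h
  }
  p$Wp1 <- ad_glorot(D, head_hidden); p$bp1 <- ad_zeros(1L, head_hidden)
  p$Wp2 <- ad_glorot(head_hidden, 1L); p$bp2 <- ad_zeros(1L, 1L)
  structure(list(architecture = architecture,
                 hyper = list(hidden_dim = h, gather_cov = gather_cov,
                              gather_noncov = gather_noncov,
                              n_layers = n_layers, n_steps = n_steps,
                              head_hidden = head_hidden),
                 params = p, D = D), class = "backbone_model")
}

backbone_params <- function(model) model$params

# ---- batched graph container ------------------------------------------

# lean per-graph arrays (plain vectors instead of edge data.frames) so that
# minibatch assembly in the training loop is cheap
lean_graph <- function(g) {
  lean <- function(e) list(i = as.integer(e$i), j = as.integer(e$j),
                           d = as.numeric(e$d))
  structure(list(X = g$node_features, n = nrow(g$node_features),
                 covalent = lean(g$covalent), noncovalent = lean(g$noncovalent),
                 radius = lean(g$radius)), class = "lean_graph")
}

# direct lean-graph construction from a featurized instance (skips the edge
# data.frames of the public builders; equivalence is asserted in the tests)
lean_build <- function(inst, flavor = c("sgcnn", "egnn"),
                       covalent_cutoff = 1.5, noncovalent_cutoff = 4.5,
                       radius_cutoff = 5.0) {
  flavor <- match.arg(flavor)
  n <- nrow(inst$coords)
  if (n < 2L) stop("degenerate graph: instance has fewer than 2 atoms")
  dm <- as.matrix(stats::dist(inst$coords))
  idx <- which(upper.tri(dm), arr.ind = TRUE)
  d <- dm[idx]
  mk <- function(sel) list(i = c(idx[sel, 1L], idx[sel, 2L]),
                           j = c(idx[sel, 2L], idx[sel, 1L]),
                           d = c(d[sel], d[sel]))
  none <- list(i = integer(), j = integer(), d = numeric())
  if (flavor == "sgcnn") {
    structure(list(X = inst$features, n = n,
                   covalent = mk(d > 0 & d <= covalent_cutoff),
                   noncovalent = mk(d > covalent_cutoff & d <= noncovalent_cutoff),
                   radius = none), class = "lean_graph")
  } else {
    structure(list(X = inst$features, n = n, covalent = none,
                   noncovalent = none,
                   radius = mk(d > 0 & d <= radius_cutoff)),
              class = "lean_graph")
  }
}

# concatenate complex graphs into one node/edge arena for vectorized passes
graph_batch <- function(graphs) {
  if (!inherits(graphs[[1L]], "lean_graph")) graphs <- lapply(graphs, lean_graph)
  ns <- vapply(graphs, `[[`, 1L, "n")
  offs <- c(0L, cumsum(ns))[seq_along(graphs)]
  edge_cat <- function(field) {
    list(i = unlist(lapply(seq_along(graphs),
                           function(k) graphs[[k]][[field]]$i + offs[k])),
         j = unlist(lapply(seq_along(graphs),
                           function(k) graphs[[k]][[field]]$j + offs[k])),
         d = unlist(lapply(graphs, function(g) g[[field]]$d)))
  }
  list(X = do.call(rbind, lapply(graphs, `[[`, "X")),
       covalent = edge_cat("covalent"),
       noncovalent = edge_cat("noncovalent"),
       radius = edge_cat("radius"),
       graph_id = rep(seq_along(graphs), ns),
       n_nodes = ns, ngraph = length(graphs))
}

# linear edge message + scatter-add; returns an N x h node matrix
.edge_message <- function(h_nodes, edges, We, be, n_total) {
  if (length(edges$i) == 0L) {
    return(ad_const(matrix(0, n_total, ncol(ad_val(We)))))
  }
  hj <- ad_rows(h_nodes, edges$j)
  ein <- ad_cbind(hj, matrix(edges$d / 4.5, ncol = 1L))
  msg <- ad_add(ad_matmul(ein, We), be)
  ad_rowsum(msg, edges$i, n_total)
}

.gru_update <- function(h, m, p, s) {
  r <- ad_sigmoid(ad_add(ad_add(ad_matmul(m, p[[paste0("Wmr_", s)]]),
                                ad_matmul(h, p[[paste0("Whr_", s)]])),
                         p[[paste0("br_", s)]]))
  z <- ad_sigmoid(ad_add(ad_add(ad_matmul(m, p[[paste0("Wmz_", s)]]),
                                ad_matmul(h, p[[paste0("Whz_", s)]])),
                         p[[paste0("bz_", s)]]))
  n <- ad_tanh(ad_add(ad_add(ad_matmul(m, p[[paste0("Wmn_", s)]]),
                             ad_matmul(ad_mul(r, h), p[[paste0("Whn_", s)]])),
                      p[[paste0("bn_", s)]]))
  ad_add(ad_mul(ad_sub(ad_const(matrix(1, nrow(ad_val(z)), ncol(ad_val(z)))), z), n),
         ad_mul(z, h))
}

.gather_readout <- function(h, X, p, s, graph_id, ngraph) {
  u <- ad_cbind(h, X)
  gate <- ad_sigmoid(ad_add(ad_matmul(u, p[[paste0("Wg_", s)]]),
                            p[[paste0("bg_", s)]]))
  val <- ad_add(ad_matmul(u, p[[paste0("Wv_", s)]]), p[[paste0("bv_", s)]])
  ad_rowsum(ad_mul(gate, val), graph_id, ngraph)
}

# batched forward pass; returns ad nodes (embedding ngraph x D, pred ngraph x 1)
sgcnn_batch_forward <- function(model, batch) {
  p <- model$params
  n <- nrow(batch$X)
  X <- batch$X
  h <- ad_tanh(ad_add(ad_matmul(ad_const(X), p$W_in), p$b_in))
  for (step in seq_len(model$hyper$n_steps)) {
    m <- .edge_message(h, batch$covalent, p$We_cov, p$be_cov, n)
    h <- .gru_update(h, m, p, "cov")
  }
  r_cov <- .gather_readout(h, X, p, "cov", batch$graph_id, batch$ngraph)
  for (step in seq_len(model$hyper$n_steps)) {
    m <- .edge_message(h, batch$noncovalent, p$We_noncov, p$be_noncov, n)
    h <- .gru_update(h, m, p, "noncov")
  }
  r_non <- .gather_readout(h, X, p, "noncov", batch$graph_id, batch$ngraph)
  emb <- ad_cbind(r_cov, r_non)
  pred <- ad_add(ad_matmul(ad_relu(ad_add(ad_matmul(emb, p$Wp1), p$bp1)),
                           p$Wp2), p$bp2)
  list(embedding = emb, pred = pred)
}

egnn_batch_forward <- function(model, batch) {
  p <- model$params
  n <- nrow(batch$X)
  edges <- batch$radius
  h <- ad_matmul(ad_const(batch$X), p$W_in)
  h <- ad_add(h, p$b_in)
  d2 <- matrix((edges$d / 5.0)^2, ncol = 1L)
  for (l in seq_len(model$hyper$n_layers)) {
    if (length(edges$i)) {
      hi <- ad_rows(h, edges$i)
      hj <- ad_rows(h, edges$j)
      m1 <- ad_silu(ad_add(ad_matmul(ad_cbind(hi, hj, d2),
                                     p[[paste0("We1_", l)]]),
                           p[[paste0("be1_", l)]]))
      m2 <- ad_silu(ad_add(ad_matmul(m1, p[[paste0("We2_", l)]]),
                           p[[paste0("be2_", l)]]))
      att <- ad_sigmoid(ad_add(ad_matmul(m2, p[[paste0("Wa_", l)]]),
                               p[[paste0("ba_", l)]]))
      magg <- ad_rowsum(ad_mul_colvec(m2, att), edges$i, n)
    } else {
      magg <- ad_const(matrix(0, n, model$hyper$hidden_dim))
    }
    upd <- ad_matmul(ad_silu(ad_add(ad_matmul(ad_cbind(h, magg),
                                              p[[paste0("Wh1_", l)]]),
                                    p[[paste0("bh1_", l)]])),
                     p[[paste0("Wh2_", l)]])
    h <- ad_add(h, ad_add(upd, p[[paste0("bh2_", l)]]))
  }
  hout <- ad_add(ad_matmul(ad_silu(ad_add(ad_matmul(h, p$Wo1), p$bo1)),
                           p$Wo2), p$bo2)
  pooled <- ad_rowsum(hout, batch$graph_id, batch$ngraph)
  emb <- ad_mul_colvec(pooled, matrix(1 / batch$n_nodes, ncol = 1L))
  pred <- ad_add(ad_matmul(ad_silu(ad_add(ad_matmul(emb, p$Wp1), p$bp1)),
                           p$Wp2), p$bp2)
  list(embedding = emb, pred = pred)
}

#' Backbone forward pass on a single graph
#'
#' Deterministic given fixed parameters; the embedding is the activation
#' immediately before the scalar head.
#'
#' @param graph a `complex_graph` built by [build_sgcnn_graph()] (for
#'   `sgcnn_forward`) or [build_radius_graph()] (for `egnn_forward`).
#' @param model a matching `backbone_model`.
#' @return list with `embedding` (length-D numeric) and `prediction`
#'   (scalar affinity, pK units).
#' @export
sgcnn_forward <- function(graph, model) {
  stopifnot(inherits(model, "backbone_model"))
  if (model$architecture != "sgcnn") stop("model is not an sgcnn backbone")
  if (nrow(graph$radius)) {
    stop("graph-type error: radius edges populated; expected covalent/",
         "noncovalent graph")
  }
  out <- sgcnn_batch_forward(model, graph_batch(list(graph)))
  list(embedding = as.numeric(ad_val(out$embedding)),
       prediction = as.numeric(ad_val(out$pred)))
}

#' @rdname sgcnn_forward
#' @export
egnn_forward <- function(graph, model) {
  stopifnot(inherits(model, "backbone_model"))
  if (model$architecture != "egnn") stop("model is not an egnn backbone")
  if (nrow(graph$covalent) || nrow(graph$noncovalent)) {
    stop("graph-type error: covalent/noncovalent edges populated; expected ",
         "radius graph")
  }
  out <- egnn_batch_forward(model, graph_batch(list(graph)))
  list(embedding = as.numeric(ad_val(out$embedding)),
       prediction = as.numeric(ad_val(out$pred)))
}

backbone_batch_forward <- function(model, batch) {
  if (model$architecture == "sgcnn") sgcnn_batch_forward(model, batch)
  else egnn_batch_forward(model, batch)
}

# compiled fast path for the sgcnn batched pass (training / extraction);
# numerically mirrors sgcnn_batch_forward and is cross-checked against it
sgcnn_fast <- function(model, batch, labels = NULL) {
  ec <- function(e) {
    m <- cbind(e$i, e$j) - 1L
    storage.mode(m) <- "integer"
    m
  }
  .sgcnn_batch_cpp(batch$X, ec(batch$covalent), batch$covalent$d,
                   ec(batch$noncovalent), batch$noncovalent$d,
                   batch$graph_id - 1L, batch$ngraph,
                   lapply(model$params, function(p) p$val),
                   model$hyper$n_steps, labels)
}

# plain-value batched forward for either architecture (no gradients)
backbone_batch_values <- function(model, batch) {
  if (model$architecture == "sgcnn") {
    out <- sgcnn_fast(model, batch)
    list(embedding = out$embedding, pred = out$pred)
  } else {
    out <- egnn_batch_forward(model, batch)
    list(embedding = ad_val(out$embedding), pred = ad_val(out$pred))
  }
}

#' Build the graph flavor a backbone expects
#'
#' @param model a `backbone_model`.
#' @param instance a `featurized_instance`.
#' @return a `complex_graph`.
#' @export
backbone_graph <- function(model, instance) {
  if (model$architecture == "sgcnn") build_sgcnn_graph(instance)
  else build_radius_graph(instance)
}

#' Serialize / restore a backbone checkpoint
#'
#' The checkpoint embeds architecture and hyperparameters so it is
#' self-describing.
#'
#' @param model a `backbone_model`.
#' @param path file path.
#' @export
backbone_save <- function(model, path) {
  saveRDS(list(architecture = model$architecture, hyper = model$hyper,
               D = model$D,
               values = lapply(model$params, function(p) p$val)), path)
  invisible(path)
}

#' @rdname backbone_save
#' @export
backbone_load <- function(path) {
  x <- readRDS(path)
  model <- do.call(backbone_model, c(list(architecture = x$architecture),
                                     x$hyper[c("hidden_dim", "gather_cov",
                                               "gather_noncov", "n_layers",
                                               "n_steps", "head_hidden")]))
  for (nm in names(x$values)) model$params[[nm]]$val <- x$values[[nm]]
  model
}
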