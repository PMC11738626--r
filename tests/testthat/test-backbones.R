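# Backbone forward passes: determinism, invariances, gradient flow, and the
# compiled fast path against the autodiff reference.

test_that("forward passes are deterministic and reject the wrong graph flavor", {
  set.seed(12)
  inst <- random_instance(15)
  gs <- build_sgcnn_graph(inst)
  gr <- build_radius_graph(inst)
  set.seed(1); ms <- backbone_model("sgcnn")
  set.seed(1); me <- backbone_model("egnn", hidden_dim = 16L)
  o1 <- sgcnn_forward(gs, ms)
  o2 <- sgcnn_forward(gs, ms)
  expect_identical(o1$embedding, o2$embedding)
  expect_length(o1$embedding, ms$D)
  e1 <- egnn_forward(gr, me)
  e2 <- egnn_forward(gr, me)
  expect_identical(e1$embedding, e2$embedding)
  expect_length(e1$embedding, 16L)
  expect_error(sgcnn_forward(gr, ms), "graph-type")
  expect_error(egnn_forward(gs, me), "graph-type")
  expect_error(sgcnn_forward(gs, me), "not an sgcnn")
})

test_that("both backbones are invariant to node permutation", {
  set.seed(13)
  ms <- backbone_model("sgcnn")
  me <- backbone_model("egnn", hidden_dim = 16L)
  for (i in 1:10) {
    inst <- random_instance(sample(8:20, 1))
    perm <- sample(nrow(inst$coords))
    pinst <- inst
    pinst$coords <- inst$coords[perm, ]
    pinst$features <- inst$features[perm, ]
    pinst$role <- inst$role[perm]
    es <- sgcnn_forward(build_sgcnn_graph(inst), ms)$embedding
    es_p <- sgcnn_forward(build_sgcnn_graph(pinst), ms)$embedding
    expect_equal(es_p, es, tolerance = 1e-5 * max(1, max(abs(es))))
    ee <- egnn_forward(build_radius_graph(inst), me)$embedding
    ee_p <- egnn_forward(build_radius_graph(pinst), me)$embedding
    expect_equal(ee_p, ee, tolerance = 1e-5 * max(1, max(abs(ee))))
  }
})

test_that("EGNN embedding is invariant to rigid transforms (rotation, translation, reflection)", {
  set.seed(14)
  me <- backbone_model("egnn", hidden_dim = 16L)
  inst <- random_instance(15)
  base <- egnn_forward(build_radius_graph(inst), me)$embedding
  for (i in 1:20) {
    R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    if (i %% 3 == 0) R <- -R                      # include improper rotations
    t <- rnorm(3, sd = 10)
    tinst <- inst
    tinst$coords <- sweep(inst$coords %*% R, 2, -t)
    emb <- egnn_forward(build_radius_graph(tinst), me)$embedding
    expect_equal(emb, base, tolerance = 1e-4 * max(1, max(abs(base))))
  }
})

test_that("zero features with zero biases and no distance coupling give zero output", {
  set.seed(15)
  ms <- backbone_model("sgcnn")
  for (nm in names(ms$params)) {
    if (grepl("^b", nm)) ms$params[[nm]]$val[] <- 0
  }
  # silence the distance column of both message nets so messages vanish
  h <- ms$hyper$hidden_dim
  ms$params$We_cov$val[h + 1, ] <- 0
  ms$params$We_noncov$val[h + 1, ] <- 0
  inst <- random_instance(10)
  inst$features[] <- 0
  out <- sgcnn_forward(build_sgcnn_graph(inst), ms)
  expect_equal(out$embedding, rep(0, ms$D))
  expect_equal(out$prediction, 0)
})

test_that("compiled sgcnn pass matches the autodiff reference, values and gradients", {
  set.seed(16)
  insts <- lapply(1:5, function(i) random_instance(sample(8:15, 1)))
  graphs <- lapply(insts, build_sgcnn_graph)
  batch <- poseMIL:::graph_batch(graphs)
  set.seed(2); model <- backbone_model("sgcnn")
  y <- rnorm(5, 5)
  fast <- poseMIL:::sgcnn_fast(model, batch, y)
  ref <- poseMIL:::sgcnn_batch_forward(model, batch)
  expect_equal(fast$pred, poseMIL:::ad_val(ref$pred), tolerance = 1e-12)
  expect_equal(fast$embedding, poseMIL:::ad_val(ref$embedding),
               tolerance = 1e-12)
  loss <- poseMIL:::ad_mse(ref$pred, matrix(y, ncol = 1))
  poseMIL:::ad_backward(loss)
  expect_equal(fast$loss, as.numeric(loss$val), tolerance = 1e-12)
  for (nm in names(fast$grads)) {
    expect_equal(unname(fast$grads[[nm]]), unname(model$params[[nm]]$grad),
                 tolerance = 1e-9, label = paste("grad", nm))
  }
})

test_that("each backbone overfits a 10-instance set (gradient flow sanity)", {
  set.seed(17)
  ds <- generate_dataset(synthetic_spec(n_entities = 10, poses_per_entity = 1,
                                        n_informative = 1L, seed = 17,
                                        pocket_size_range = c(20, 30),
                                        ligand_size_range = c(6, 10)))
  bags <- ds$bags
  # center labels so the scalar head needs no large bias excursion
  labs <- vapply(bags, `[[`, 1.0, "label")
  for (i in seq_along(bags)) bags[[i]]$label <- labs[i] - mean(labs)

  # 100 epochs x 5 minibatches of 2 = 500 optimizer steps
  cfg <- train_config(epochs = 100L, seed = 17, batch_size = 2L,
                      lr_milestones = c(60, 80, 90), lr_gamma = 0.5,
                      lr0 = 0.002)
  m <- train_backbone(bags, cfg, "sgcnn")
  expect_lt(tail(m$loss_trace, 1), 0.01)

  cfg_e <- train_config(epochs = 100L, seed = 17, batch_size = 2L,
                        lr_milestones = c(70, 85, 95), lr_gamma = 0.5,
                        lr0 = 0.002)
  me <- train_backbone(bags, cfg_e, "egnn", hyper = list(hidden_dim = 16L))
  expect_lt(tail(me$loss_trace, 1), 0.01)
})

test_that("checkpoints round-trip with architecture and weights intact", {
  set.seed(18)
  m <- backbone_model("sgcnn")
  path <- tempfile(fileext = ".rds")
  backbone_save(m, path)
  m2 <- backbone_load(path)
  inst <- random_instance(12)
  g <- build_sgcnn_graph(inst)
  expect_identical(sgcnn_forward(g, m)$embedding,
                   sgcnn_forward(g, m2)$embedding)
  expect_equal(m2$hyper, m$hyper)
})
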