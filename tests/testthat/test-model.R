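# Model assembly and training loop: variant construction, the end-to-end
# shape contract, determinism and small-scale optimisation behaviour.

test_that("all named variants are constructible with logged parameter counts", {
  vt <- model_variants()
  expect_equal(nrow(vt), 9L)
  for (v in vt$variant) {
    m <- tiny_model(v, seed = 1)
    expect_s3_class(m, "mwcaps_model")
    expect_gt(m$n_params, 0L)
    expect_equal(m$config$variant, v)
  }
  mw <- tiny_model("MWCapsuleNets")
  expect_equal(mw$config$frontend, "mlp_block")
  expect_equal(mw$config$capsule, "weight")
  caps <- tiny_model("CapsuleNets")
  expect_equal(caps$config$frontend, "conv")
  expect_equal(caps$config$caps$squash, "standard")
  expect_equal(caps$config$caps$f_form, "one")
  expect_false(caps$config$caps$learn_k)
  expect_error(build_variant("NoSuchNet"))
})

test_that("every variant's forward pass produces valid per-beat predictions", {
  set.seed(40)
  X <- matrix(runif(280 * 6), 280, 6)
  for (v in model_variants()$variant) {
    m <- tiny_model(v, seq_len = 3L, seed = 2)
    tp <- wcapseq:::ad_tape()
    nodes <- wcapseq:::model_nodes(tp, m$theta, wrap = wcapseq:::ad_const)
    fw <- wcapseq:::model_forward_node(tp, nodes, m$config, X, B = 2L)
    expect_equal(dim(fw$pred), c(3L, 2L))
    expect_true(all(fw$pred %in% 1:5))
  }
})

test_that("the full shape contract holds through the default architecture", {
  m <- build_variant("MWCapsuleNets", seed = 3)
  set.seed(41)
  X <- matrix(runif(280 * 10), 280, 10)   # one sequence of 10 beats
  tp <- wcapseq:::ad_tape()
  nodes <- wcapseq:::model_nodes(tp, m$theta, wrap = wcapseq:::ad_const)
  map <- wcapseq:::frontend_node(wcapseq:::ad_const(tp, X), nodes, m$config)
  expect_equal(dim(map$value), c(20L, 28L, 10L))
  u <- wcapseq:::ad_relu(wcapseq:::conv1d_node(map, nodes$Wc, nodes$bc, k = 3L))
  expect_equal(dim(u$value), c(28L, 18L, 10L))   # 18 primary capsules of dim 28
  E <- wcapseq:::embedding_node(map, nodes, m$config)
  expect_equal(dim(E$value), c(128L, 10L))       # 128-d beat embeddings
  tgt <- matrix(sample(1:5, 10, TRUE), 10, 1)
  fw <- wcapseq:::model_forward_node(tp, nodes, m$config, X, B = 1L, targets = tgt)
  expect_length(fw$logits, 10L)
  expect_equal(dim(fw$logits[[1]]$value), c(5L, 1L))  # T x C logits
})

test_that("training is deterministic under a fixed seed", {
  d <- suppressWarnings(synth_beats(n_train_patients = 2, n_test_patients = 0,
                                    beats_per_patient = 12, seed = 5))
  m1 <- tiny_model(seq_len = 4L, seed = 9)
  m2 <- tiny_model(seq_len = 4L, seed = 9)
  f1 <- mwcaps_train(d, model = m1, epochs = 3, batch_size = 2, seed = 9)
  f2 <- mwcaps_train(d, model = m2, epochs = 3, batch_size = 2, seed = 9)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$theta, f2$model$theta)
})

test_that("a small model overfits one batch of synthetic sequences", {
  d <- suppressWarnings(
    synth_beats(n_train_patients = 1, n_test_patients = 0,
                beats_per_patient = 32,
                class_probs = c(N = 0.5, S = 0.15, V = 0.2, F = 0.1, Q = 0.05),
                seed = 6))
  fit <- mwcaps_train(d, variant = "MWCapsuleNets", seq_len = 4L,
                      epochs = 200, batch_size = 8, seed = 4,
                      stop_loss = 0.009)
  final <- utils::tail(fit$history$loss, 1)
  expect_lt(final, 0.01)
  expect_lt(nrow(fit$history), 201L)
  expect_lt(final, fit$history$loss[1])  # loss decreased from its start
})

test_that("prediction returns one labelled row per non-PAD beat", {
  d <- suppressWarnings(synth_beats(n_train_patients = 1, n_test_patients = 1,
                                    beats_per_patient = 11, seed = 8))
  m <- tiny_model(seq_len = 4L, seed = 7)
  fit <- mwcaps_train(d, model = m, epochs = 1, seed = 7)
  te <- d[d$split == "test", ]
  pr <- predict(fit, te)
  expect_equal(nrow(pr), nrow(te))
  expect_true(all(pr$.pred_class %in% aami_classes()))
  expect_named(pr, c("record_id", "sequence", "position", "label", ".pred_class"))
  expect_identical(predict(fit, te), pr)
})

test_that("weight capsules do not catastrophically hurt accuracy vs the MLP variant", {
  # ablation sanity at reduced scale: averaged over 3 seeds, MWCapsuleNets
  # test accuracy stays within 2 points of the plain MLP-frontend variant
  accs <- sapply(1:3, function(sd_) {
    d <- suppressWarnings(
      synth_beats(n_train_patients = 5, n_test_patients = 2,
                  beats_per_patient = 60, seed = 20 + sd_))
    te <- dplyr::filter(d, split == "test")
    sapply(c("MWCapsuleNets", "MLP"), function(v) {
      fit <- mwcaps_train(d, variant = v, epochs = 12, batch_size = 8,
                          seed = 20 + sd_)
      eval_report(data = predict(fit, te))$acc
    })
  })
  expect_gte(mean(accs["MWCapsuleNets", ]), mean(accs["MLP", ]) - 0.02)
})

test_that("non-finite losses abort with a diagnostic", {
  d <- suppressWarnings(synth_beats(n_train_patients = 1, n_test_patients = 0,
                                    beats_per_patient = 8, seed = 10))
  m <- tiny_model(seq_len = 4L, seed = 1)
  m$theta$Wy[] <- Inf
  expect_error(mwcaps_train(d, model = m, epochs = 1, seed = 1),
               "non-finite")
})
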