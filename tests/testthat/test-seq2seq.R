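# Sequence-to-sequence head: encoder symmetries, decoding contracts,
# softmax properties and gradient flow.

test_that("encoding handles a single step and zero input correctly", {
  set.seed(20)
  p <- init_seq2seq_params(input_dim = 6L, hidden = 4L, n_classes = 3L)
  enc1 <- birnn_encode(matrix(rnorm(6), 1, 6), p)
  expect_equal(dim(enc1$outputs), c(1L, 6L))
  expect_length(enc1$final$h_fwd, 4L)
  # zero input and zero biases: every tanh/sigmoid gate sees 0, cells stay 0
  p0 <- lapply(p, function(x) x * 0)
  enc0 <- birnn_encode(matrix(0, 3, 6), p0)
  expect_equal(enc0$final$h_fwd, rep(0, 4))
  expect_equal(enc0$final$h_bwd, rep(0, 4))
  expect_true(all(enc0$outputs == 0))
  expect_error(birnn_encode(matrix(numeric(0), 0, 6), p), "empty")
})

test_that("reversing the sequence swaps forward and backward roles under tied cells", {
  set.seed(21)
  p <- init_seq2seq_params(input_dim = 5L, hidden = 3L, n_classes = 2L)
  p$Wb <- p$Wf; p$bb <- p$bf                      # tie the two directions
  xs <- matrix(rnorm(20), 4, 5)
  a <- birnn_encode(xs, p)
  b <- birnn_encode(xs[4:1, ], p)
  expect_equal(a$final$h_fwd, b$final$h_bwd, tolerance = 1e-12)
  expect_equal(a$final$h_bwd, b$final$h_fwd, tolerance = 1e-12)
})

test_that("softmax probabilities are normalised and shift-invariant", {
  p <- softmax_probs(c(2, 2, 2))
  expect_equal(p, rep(1 / 3, 3))
  z <- c(1, 2, 3)
  expect_equal(softmax_probs(z), exp(z) / sum(exp(z)))
  expect_equal(softmax_probs(z), softmax_probs(z + 57.3), tolerance = 1e-12)
  expect_equal(sum(softmax_probs(rnorm(10))), 1, tolerance = 1e-12)
})

test_that("teacher-forced decoding emits T x C logits and greedy decoding T labels", {
  set.seed(22)
  p <- init_seq2seq_params(input_dim = 6L, hidden = 4L, n_classes = 5L)
  enc <- birnn_encode(matrix(rnorm(18), 3, 6), p)
  lg <- decode_train(p, enc, targets = c(1L, 3L, NA))
  expect_equal(dim(lg), c(3L, 5L))
  lg1 <- decode_train(p, enc, targets = 2L)       # T = 1: only <GO> is consumed
  expect_equal(dim(lg1), c(1L, 5L))
  pred <- decode_infer(p, enc, n_steps = 3L)
  expect_length(pred, 3L)
  expect_true(all(pred %in% 1:5))
  expect_identical(decode_infer(p, enc, 3L), pred) # deterministic
  expect_error(decode_train(p, enc, targets = integer(0)))
})

test_that("PAD positions are masked: the loss is the mean CE over real beats only", {
  m <- tiny_model(seq_len = 4L, seed = 3)
  set.seed(23)
  X <- matrix(runif(280 * 4), 280, 4)
  tgt <- matrix(c(1L, 3L, NA, NA), 4, 1)
  tp <- wcapseq:::ad_tape()
  nodes <- wcapseq:::model_nodes(tp, m$theta, wrap = wcapseq:::ad_const)
  fw <- wcapseq:::model_forward_node(tp, nodes, m$config, X, B = 1L,
                                     targets = tgt)
  # recompute by hand from the emitted logits: only the two labelled steps count
  ce <- vapply(1:2, function(t) {
    -log(softmax_probs(as.vector(fw$logits[[t]]$value))[tgt[t, 1]])
  }, numeric(1))
  expect_equal(fw$loss$value, mean(ce), tolerance = 1e-10)
  # and the padded steps change nothing: replacing the PAD tail's logits is
  # irrelevant because their loss weight is exactly zero
  grad_free <- wcapseq:::ad_backward(fw$loss)
  expect_true(is.finite(fw$loss$value))
})

test_that("the inference interface accepts no targets", {
  expect_named(formals(decode_infer), c("params", "enc", "n_steps"))
})

test_that("gradients flow through the bidirectional encoder (toy sequence)", {
  set.seed(24)
  p <- init_seq2seq_params(input_dim = 3L, hidden = 2L, n_classes = 2L)
  theta <- c(p[c("Wf", "bf", "Wb", "bb", "Uo", "bo")],
             list(x1 = rnorm(3), x2 = rnorm(3)))
  fn <- function(q) {
    xs <- list(wcapseq:::ad_reshape(q$x1, c(3L, 1L)),
               wcapseq:::ad_reshape(q$x2, c(3L, 1L)))
    enc <- wcapseq:::encoder_node(q[c("Wf", "bf", "Wb", "bb", "Uo", "bo")], xs)
    total <- wcapseq:::ad_sum(wcapseq:::ad_square(enc$outputs[[1L]]))
    wcapseq:::ad_add(total, wcapseq:::ad_sum(wcapseq:::ad_square(enc$outputs[[2L]])))
  }
  expect_lt(wcapseq:::ad_grad_check(fn, theta, n_sample = 20L, seed = 5), 1e-4)
})
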