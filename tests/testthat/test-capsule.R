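# Capsule layer: squash functions, primary capsules, prediction vectors,
# weighted routing and its reduction to textbook routing-by-agreement.

test_that("S-S squash satisfies its closed form and boundary behaviour", {
  expect_equal(ss_squash(c(0, 0, 0)), c(0, 0, 0))
  # rho(1) evaluated independently: (2*plogis(1) - 1 + 0.1) / (1.1 + 2*plogis(1) - 1)
  s <- c(1, 0)
  v <- ss_squash(s, alpha = 0.1)
  rho1 <- (2 * plogis(1) - 1 + 0.1) / (1.1 + 2 * plogis(1) - 1)
  expect_equal(sqrt(sum(v^2)), rho1, tolerance = 1e-12)
  # direction preserved, norm < 1, across magnitudes
  set.seed(8)
  for (r in c(1e-3, 1, 1e3)) {
    s <- rnorm(4); s <- r * s / sqrt(sum(s^2))
    v <- ss_squash(s)
    expect_lt(sqrt(sum(v^2)), 1)
    cosang <- sum(v * s) / sqrt(sum(v^2) * sum(s^2))
    expect_equal(cosang, 1, tolerance = 1e-9)
  }
})

test_that("the standard squash matches its closed form", {
  v <- standard_squash(c(0, 1))
  expect_equal(sqrt(sum(v^2)), 0.5)
  expect_equal(standard_squash(c(0, 0)), c(0, 0))
  r <- c(0.1, 1, 10, 100, 1e4)
  p <- squash_profile(r, "standard")
  expect_true(all(diff(p) > 0))
  expect_lt(max(p), 1)
  set.seed(9)
  s <- rnorm(5)
  v <- standard_squash(s)
  expect_equal(v / sqrt(sum(v^2)), s / sqrt(sum(s^2)))
})

test_that("rho is strictly increasing, bounded and relieves saturation", {
  r <- seq(1e-4, 50, length.out = 10000)
  rho <- squash_profile(r, "ss")
  expect_true(all(rho > 0 & rho < 1))
  expect_true(all(diff(rho) > 0))          # strict monotonicity on the grid
  expect_equal(squash_profile(0, "ss"), 0) # rho(0) = 0
  # saturation relief: at large norms the S-S profile keeps a larger slope
  # than the standard squash
  rr <- seq(5, 50, length.out = 500)
  h <- 1e-4
  d_ss <- (squash_profile(rr + h, "ss") - squash_profile(rr - h, "ss")) / (2 * h)
  d_std <- (squash_profile(rr + h, "standard") - squash_profile(rr - h, "standard")) / (2 * h)
  expect_true(all(d_ss > d_std))
})

test_that("primary capsules are a valid ReLU convolution over the map", {
  set.seed(10)
  W <- matrix(rnorm(28 * 84, 0, 0.1), 28, 84)
  fm <- matrix(runif(20 * 28), 20, 28)
  u <- primary_caps(fm, W)
  expect_equal(dim(u), c(18L, 28L))        # 20 - 3 + 1 valid positions
  expect_true(all(u >= 0))                 # ReLU
  expect_equal(primary_caps(matrix(0, 20, 28), W), matrix(0, 18, 28))
  # hand-computed first capsule: window rows 1:3 ordered position-fastest
  win <- as.vector(fm[1:3, ])
  expect_equal(u[1, ], pmax(0, as.vector(W %*% win)))
  expect_error(primary_caps(fm[1:2, ], W))
})

test_that("prediction vectors are per-pair matrix products", {
  set.seed(11)
  u <- matrix(rnorm(6), 2, 3)
  W <- array(rnorm(2 * 2 * 2 * 3), c(2, 2, 2, 3))
  uh <- predict_uhat(u, W)
  for (i in 1:2) for (j in 1:2) {
    expect_equal(uh[i, j, ], as.vector(matrix(W[i, j, , ], 2, 3) %*% u[i, ]))
  }
  Wid <- array(0, c(2, 2, 3, 3))
  for (i in 1:2) for (j in 1:2) Wid[i, j, , ] <- diag(3)
  uh_id <- predict_uhat(u, Wid)
  for (i in 1:2) for (j in 1:2) expect_equal(uh_id[i, j, ], u[i, ])
  expect_equal(predict_uhat(u, W * 0), array(0, c(2, 2, 2)))
})

test_that("f weights are positive, bounded and neutral when disabled", {
  uh <- array(0, c(3, 4, 2))
  expect_equal(compute_f(uh), matrix(1, 3, 4))   # 1/(1+0)
  set.seed(12)
  uh2 <- array(rnorm(24), c(3, 4, 2))
  f <- compute_f(uh2)
  expect_true(all(f > 0 & f <= 1))
  expect_equal(compute_f(uh2, "one"), matrix(1, 3, 4))
})

test_that("couplings stay normalised and are uniform for one output capsule", {
  set.seed(13)
  uh1 <- array(rnorm(4 * 1 * 3), c(4, 1, 3))
  r1 <- dynamic_route(uh1, n_iter = 3)
  for (cc in r1$couplings) expect_equal(cc, matrix(1, 4, 1))
  for (rep_i in 1:10) {
    uh <- array(rnorm(5 * 4 * 2, sd = 2), c(5, 4, 2))
    r <- dynamic_route(uh, n_iter = 3)
    for (cc in r$couplings) {
      expect_equal(rowSums(cc), rep(1, 5), tolerance = 1e-6)
    }
  }
})

test_that("weighted routing with f=1, k=1, standard squash equals textbook routing", {
  set.seed(14)
  for (rep_i in 1:50) {
    uh <- array(rnorm(4 * 3 * 2, sd = 1.5), c(4, 3, 2))
    ours <- dynamic_route(uh, n_iter = 3, squash = "standard", f_form = "one",
                          k = rep(1, 3))
    ref <- oracle_routing(uh, n_iter = 3)
    expect_equal(ours$v, ref$v, tolerance = 1e-6)
    expect_equal(ours$couplings[[3]], ref$c, tolerance = 1e-6)
  }
})

test_that("routing is permutation-equivariant in the input capsules", {
  set.seed(15)
  uh <- array(rnorm(6 * 4 * 3), c(6, 4, 3))
  perm <- sample(6)
  a <- dynamic_route(uh, n_iter = 3)
  b <- dynamic_route(uh[perm, , , drop = FALSE], n_iter = 3)
  expect_equal(a$v, b$v, tolerance = 1e-10)
})

test_that("the full capsule pass gives a deterministic 128-d embedding", {
  set.seed(16)
  spec <- wcaps_spec()
  params <- init_caps_params(spec = spec)
  fm <- matrix(runif(20 * 28), 20, 28)
  e <- wcaps_forward(fm, params, spec)
  expect_length(e, 128L)
  expect_identical(wcaps_forward(fm, params, spec), e)
})

test_that("gradients flow through the capsule stack (toy spec)", {
  set.seed(17)
  spec <- wcaps_spec(n_out = 3L, d_out = 2L, learn_k = TRUE)
  theta <- list(
    Wc = matrix(rnorm(4 * 12, 0, 0.4), 4, 12),  # 4 channels, kernel 3
    bc = rnorm(4, 0, 0.1),
    W1 = matrix(rnorm(6 * 4, 0, 0.5), 6, 4),
    W2 = matrix(rnorm(6 * 4, 0, 0.5), 6, 4),
    W3 = matrix(rnorm(6 * 4, 0, 0.5), 6, 4),
    W4 = matrix(rnorm(6 * 4, 0, 0.5), 6, 4),
    k_raw = rnorm(3, 0.5, 0.1),
    x = array(runif(6 * 4 * 2), c(6, 4, 2))     # (L=6, C=4, N=2) map
  )
  fn <- function(p) {
    u <- wcapseq:::ad_relu(wcapseq:::conv1d_node(p$x, p$Wc, p$bc, k = 3L))
    uh <- wcapseq:::uhat_node(u, list(p$W1, p$W2, p$W3, p$W4),
                              d_out = 2L, n_out = 3L)
    v <- wcapseq:::routing_node(uh, n_iter = 3L, squash = "ss",
                                f_form = "inv_norm", k_raw = p$k_raw)
    e <- wcapseq:::embed_node(v, "max")
    wcapseq:::ad_sum(wcapseq:::ad_square(e))
  }
  expect_lt(wcapseq:::ad_grad_check(fn, theta, n_sample = 20L, seed = 2), 1e-4)
})

test_that("batched routing agrees with the single-beat surface functions", {
  set.seed(18)
  spec <- wcaps_spec(n_out = 5L, d_out = 3L)
  params <- init_caps_params(d_in = 28L, n_in = 18L, spec = spec)
  fm <- matrix(runif(20 * 28), 20, 28)
  # surface pipeline
  u <- primary_caps(fm, params$Wc, params$bc)
  W4 <- array(0, c(18, 5, 3, 28))
  for (i in 1:18) W4[i, , , ] <- aperm(array(params$Wcaps[[i]], c(3, 5, 28)), c(2, 1, 3))
  uh <- predict_uhat(u, W4)
  route <- dynamic_route(uh, n_iter = spec$routing_iters, squash = "ss",
                         f_form = "inv_norm", k = softplus_k(params$k_raw))
  expect_equal(wcaps_forward(fm, params, spec),
               apply(route$v, 1, max), tolerance = 1e-10)
})
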