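# Weight-capsule layer: primary convolutional capsules, the Sigmoid-squash
# (S-S) compression function, and weighted dynamic routing-by-agreement.
#
# A capsule is a vector-valued unit: its norm encodes the probability that
# an entity is present, its orientation the entity's properties.  The S-S
# function compresses a capsule's norm into [0, 1) like the classic squash
# r^2/(1+r^2), but its sigmoid-based profile keeps a larger slope at large
# norms, relieving saturation.  The weighted routing adds per-connection
# weights f_ij inside the coupling softmax and per-output-capsule weights
# k_j in the weighted sum; with f = 1, k = 1 and the classic squash it
# reduces exactly to textbook routing-by-agreement.

.squash_g <- function(x, g_form) {
  switch(g_form,
    sigmoid = 2 * stats::plogis(x) - 1,
    tanh = tanh(x),
    stop("unknown g_form: ", g_form)
  )
}

#' Sigmoid-squash (S-S) capsule compression
#'
#' Compresses a capsule vector \code{s} while preserving its direction:
#' \deqn{v = \frac{g(\|s\|^2) + \alpha\|s\|}{1 + \alpha\|s\| + g(\|s\|^2)}
#'       \cdot \frac{s}{\|s\|}}
#' with a saturating gate \code{g} (default \code{g(x) = 2*sigmoid(x) - 1},
#' which satisfies \code{g(0) = 0} so a zero input maps to a zero output)
#' and hyperparameter \code{alpha} (default 0.1).  The output norm is
#' strictly below 1 for every input, and the compression profile saturates
#' more slowly at large norms than the classic squash.
#'
#' @param s Numeric vector (a single capsule).
#' @param alpha Non-negative scalar hyperparameter.
#' @param g_form \code{"sigmoid"} (default) or \code{"tanh"}.
#' @return Compressed vector, same length and direction as \code{s}.
#' @export
#' @examples
#' sqrt(sum(ss_squash(c(3, 4))^2)) # norm < 1
ss_squash <- function(s, alpha = 0.1, g_form = "sigmoid") {
  stopifnot(alpha >= 0)
  r <- sqrt(sum(s^2))
  if (r == 0) return(s * 0)
  gh <- .squash_g(r^2, g_form)
  rho <- (gh + alpha * r) / (1 + alpha * r + gh)
  (rho / r) * s
}

#' Classic capsule squash
#'
#' The standard compression \code{v = (r^2 / (1 + r^2)) * s / r} with
#' \code{r = ||s||}; used by the plain-capsule ablation variants.
#'
#' @param s Numeric vector.
#' @return Compressed vector.
#' @export
standard_squash <- function(s) {
  r2 <- sum(s^2)
  if (r2 == 0) return(s * 0)
  (r2 / (1 + r2)) / sqrt(r2) * s
}

#' Norm compression profile of a squash function
#'
#' Returns the output norm as a function of the input norm \code{r}:
#' \code{rho(r)} for the S-S function, \code{r^2/(1+r^2)} for the classic
#' squash.  Useful for inspecting monotonicity and saturation behaviour.
#'
#' @param r Numeric vector of input norms (>= 0).
#' @inheritParams ss_squash
#' @param type \code{"ss"} or \code{"standard"}.
#' @return Numeric vector of output norms.
#' @export
squash_profile <- function(r, type = c("ss", "standard"), alpha = 0.1,
                           g_form = "sigmoid") {
  type <- match.arg(type)
  if (type == "standard") return(r^2 / (1 + r^2))
  gh <- .squash_g(r^2, g_form)
  (gh + alpha * r) / (1 + alpha * r + gh)
}

# ---- node-level pieces -----------------------------------------------------

# squash an array node over dim 1 (the capsule-component axis)
squash_node <- function(s, type = "ss", alpha = 0.1, g_form = "sigmoid",
                        eps = 1e-12) {
  d <- dim(s$value)
  sq <- ad_add(ad_sum_dims(ad_square(s), 1L), eps)
  r <- ad_sqrt(sq)
  factor <- if (type == "standard") {
    ad_div(r, ad_add(sq, 1))
  } else {
    gh <- switch(g_form,
      sigmoid = ad_sub(ad_mul(ad_sigmoid(sq), 2), 1),
      tanh = ad_tanh(sq)
    )
    num <- ad_add(gh, ad_mul(r, alpha))
    den <- ad_mul(ad_add(ad_add(ad_mul(r, alpha), gh), 1), r)
    ad_div(num, den)
  }
  ad_mul(ad_expand(factor, d), s)
}

# valid 1-D convolution along the first axis of an (L, C, N) array node.
# W: (C_out x k*C) with window ordering "position within window fastest,
# then channel"; returns (C_out, P, N) with P = L - k + 1.
conv1d_node <- function(x, W, b, k = 3L) {
  d <- dim(x$value)
  L <- d[1L]; C <- d[2L]; N <- d[3L]
  P <- L - k + 1L
  if (P < 1L) stop("input length ", L, " shorter than kernel ", k)
  idx <- conv_index(L, C, N, k)
  col <- ad_gather(x, idx)                              # (kC, P*N)
  y <- ad_add(ad_matmul(W, ad_reshape(col, c(k * C, P * N))), b)
  ad_reshape(y, c(nrow(W$value), P, N))
}

conv_index <- function(L, C, N, k) {
  p <- seq_len(L - k + 1L)
  win <- as.vector(outer(seq_len(k), (seq_len(C) - 1L) * L, `+`))  # kC offsets
  base <- rep(p - 1L, times = N) + rep((seq_len(N) - 1L) * L * C, each = length(p))
  matrix(rep(win, times = length(base)) + rep(base, each = length(win)),
         nrow = k * C)
}

# prediction vectors for all (input capsule i, output capsule j) pairs.
# u: (d_in, I, N) array node; W_list: I matrices, each (J*d_out x d_in),
# rows ordered with the output-capsule component fastest.
# returns u_hat laid out as (d_out, J, N, I): the component axis leads (so
# squash reductions are colSums) and the input-capsule axis trails (so the
# routing sum over i is rowSums) -- no transposition of the big tensor.
uhat_node <- function(u, W_list, d_out, n_out) {
  d <- dim(u$value)
  d_in <- d[1L]; I <- d[2L]; N <- d[3L]
  um <- ad_reshape(u, c(d_in, I * N))
  per_i <- lapply(seq_len(I), function(i) {
    cols <- i + (seq_len(N) - 1L) * I
    ad_matmul(W_list[[i]], ad_cols(um, cols))            # (J*d_out, N)
  })
  st <- ad_stack3(per_i)                                 # (J*d_out, N, I)
  ad_reshape(st, c(d_out, n_out, N, I))
}

# f_ij: per-connection coupling weights from the prediction-vector norms
f_node <- function(u_hat, f_form, eps = 1e-12) {
  if (f_form == "one") return(NULL)
  nrm <- ad_sqrt(ad_add(ad_sum_dims(ad_square(u_hat), 1L), eps))
  ad_recip(ad_add(nrm, 1))                               # 1 / (1 + ||u_hat||)
}

# weighted dynamic routing-by-agreement.
# u_hat: (d_out, J, N, I) node; k_raw: length-J parameter node (softplus
# reparameterised) or NULL for k = 1; returns v: (d_out, J, N).
routing_node <- function(u_hat, n_iter = 3L, squash = "ss", alpha = 0.1,
                         g_form = "sigmoid", f_form = "inv_norm",
                         k_raw = NULL, trace = NULL) {
  stopifnot(n_iter >= 1L)
  d <- dim(u_hat$value)
  d_out <- d[1L]; J <- d[2L]; N <- d[3L]; I <- d[4L]
  tp <- u_hat$tape
  f <- f_node(u_hat, f_form)
  kx <- if (!is.null(k_raw)) {
    ad_expand(ad_reshape(ad_softplus(k_raw), c(1L, J, 1L, 1L)), c(d_out, J, N, 1L))
  }
  b <- ad_const(tp, array(0, c(1L, J, N, I)))
  v <- NULL
  for (it in seq_len(n_iter)) {
    logits <- if (is.null(f)) b else ad_mul(b, f)
    cc <- ad_softmax_dim(logits, 2L)                     # couplings: sum_j c_ij = 1
    cu <- ad_mul(ad_expand(cc, d), u_hat)
    s <- ad_sum_dims(cu, 4L)                             # (d_out, J, N, 1)
    if (!is.null(kx)) s <- ad_mul(kx, s)
    v <- squash_node(s, type = squash, alpha = alpha, g_form = g_form)
    if (it < n_iter) {
      agree <- ad_sum_dims(ad_mul(u_hat, ad_expand(v, d)), 1L)
      b <- ad_add(b, agree)
    }
    if (!is.finite(sum(v$value))) {
      stop("non-finite capsule output at routing iteration ", it)
    }
    if (!is.null(trace)) {
      trace$c[[it]] <- cc$value
      trace$b <- b$value
    }
  }
  ad_reshape(v, c(d_out, J, N))
}

# reduce routed capsules to the per-beat embedding
embed_node <- function(v, reduction = "max") {
  d <- dim(v$value)
  e <- switch(reduction,
    max = ad_max_dim(v, 1L),
    norm = ad_sqrt(ad_add(ad_sum_dims(ad_square(v), 1L), 1e-12)),
    stop("unknown reduction: ", reduction)
  )
  ad_reshape(e, d[-1L])
}

# ---- exported module surface ----------------------------------------------

#' Capsule layer hyperparameters
#'
#' @param n_out Number of output (ECG weight) capsules, default 128; the
#'   beat embedding has this length.
#' @param d_out Output capsule dimension (default 4).
#' @param kernel Primary convolution kernel length (default 3, stride 1,
#'   no padding).
#' @param routing_iters Dynamic-routing iterations (default 3).
#' @param squash \code{"ss"} (Sigmoid-squash) or \code{"standard"}.
#' @param alpha S-S hyperparameter (default 0.1).
#' @param g_form Gate of the S-S function, \code{"sigmoid"} or \code{"tanh"}.
#' @param f_form Per-connection routing weight: \code{"inv_norm"} for
#'   \code{f_ij = 1 / (1 + ||u_hat_(j|i)||)} or \code{"one"} to disable.
#' @param learn_k Learn positive per-output-capsule weights \code{k_j}
#'   (softplus-reparameterised, initialised at 1)?
#' @param reduction Capsule-to-embedding reduction, \code{"max"} (maximum
#'   over capsule components) or \code{"norm"}.
#' @return A list of class \code{wcaps_spec}.
#' @export
wcaps_spec <- function(n_out = 128L, d_out = 4L, kernel = 3L,
                       routing_iters = 3L, squash = c("ss", "standard"),
                       alpha = 0.1, g_form = "sigmoid",
                       f_form = c("inv_norm", "one"), learn_k = TRUE,
                       reduction = c("max", "norm")) {
  structure(list(
    n_out = as.integer(n_out), d_out = as.integer(d_out),
    kernel = as.integer(kernel), routing_iters = as.integer(routing_iters),
    squash = match.arg(squash), alpha = alpha, g_form = g_form,
    f_form = match.arg(f_form), learn_k = isTRUE(learn_k),
    reduction = match.arg(reduction)
  ), class = "wcaps_spec")
}

#' Primary convolutional capsules
#'
#' Runs the single 1-D convolution of the primary capsule layer (28 output
#' channels, kernel 3, stride 1, no padding) along the position axis of a
#' feature map, followed by ReLU.  Each output position is one primary
#' capsule whose 28 channels form the capsule vector.
#'
#' @param feature_map A positions-by-channels matrix (20 x 28 in the full
#'   model).
#' @param W Convolution weights, \code{(C_out x kernel*C_in)}.
#' @param b Bias, length \code{C_out}.
#' @param kernel Kernel length.
#' @return An \code{n_caps x C_out} matrix of capsule vectors (rows), with
#'   \code{n_caps = nrow(feature_map) - kernel + 1}.
#' @export
primary_caps <- function(feature_map, W, b = rep(0, nrow(W)), kernel = 3L) {
  stopifnot(is.matrix(feature_map), ncol(W) == kernel * ncol(feature_map))
  tp <- ad_tape()
  x <- ad_const(tp, array(feature_map, c(dim(feature_map), 1L)))
  y <- ad_relu(conv1d_node(x, ad_const(tp, W), ad_const(tp, b), k = kernel))
  t(matrix(y$value, nrow = nrow(W)))                     # (n_caps, C_out)
}

#' Prediction vectors from input capsules
#'
#' Computes \code{u_hat_(j|i) = W_ij \%*\% u_i} for every pair of input
#' capsule \code{i} and output capsule \code{j}.
#'
#' @param u Input capsules, \code{(I x d_in)} matrix (one capsule per row).
#' @param W Transformation tensor, \code{(I, J, d_out, d_in)} array.
#' @return Array \code{(I, J, d_out)} of prediction vectors.
#' @export
predict_uhat <- function(u, W) {
  d <- dim(W)
  stopifnot(length(d) == 4L, nrow(u) == d[1L], ncol(u) == d[4L])
  out <- array(0, d[1:3])
  for (i in seq_len(d[1L])) for (j in seq_len(d[2L])) {
    out[i, j, ] <- matrix(W[i, j, , ], d[3L], d[4L]) %*% u[i, ]
  }
  out
}

#' Per-connection routing weights f_ij
#'
#' The default form \code{f_ij = 1 / (1 + ||u_hat_(j|i)||)} damps the
#' influence of large-norm prediction vectors inside the coupling softmax,
#' decorrelating the couplings from the prediction norms; \code{form =
#' "one"} recovers the standard routing softmax.
#'
#' @param u_hat \code{(I, J, d_out)} prediction array from [predict_uhat()].
#' @param form \code{"inv_norm"} (default) or \code{"one"}.
#' @return \code{(I x J)} matrix of positive bounded weights.
#' @export
compute_f <- function(u_hat, form = c("inv_norm", "one")) {
  form <- match.arg(form)
  d <- dim(u_hat)
  if (form == "one") return(matrix(1, d[1L], d[2L]))
  nrm <- sqrt(apply(u_hat^2, c(1L, 2L), sum))
  1 / (1 + nrm)
}

#' Weighted dynamic routing-by-agreement
#'
#' Iteratively routes prediction vectors into output capsules.  Routing
#' logits start at zero, so every input capsule is initially coupled to all
#' output capsules with equal probability.  Each iteration computes
#' couplings \code{c_ij = softmax_j(b_ij * f_ij)}, the weighted sum
#' \code{s_j = k_j * sum_i c_ij u_hat_(j|i)}, compresses it with the
#' configured squash, and (between iterations) reinforces logits by the
#' agreement \code{b_ij <- b_ij + u_hat_(j|i) . v_j}.  With \code{f_form =
#' "one"}, \code{k = 1} and \code{squash = "standard"} this is exactly the
#' textbook capsule routing.
#'
#' @param u_hat \code{(I, J, d_out)} prediction array.
#' @param n_iter Routing iterations (>= 1).
#' @param squash,alpha,g_form,f_form See [wcaps_spec()].
#' @param k Per-output-capsule weights: length-\code{J} positive vector
#'   (default all 1).
#' @return A list: \code{v} (\code{(J x d_out)} output capsules),
#'   \code{couplings} (per-iteration list of \code{(I x J)} coupling
#'   matrices) and \code{b} (final logits, \code{(I x J)}).
#' @export
dynamic_route <- function(u_hat, n_iter = 3L, squash = "ss", alpha = 0.1,
                          g_form = "sigmoid", f_form = "inv_norm",
                          k = NULL) {
  d <- dim(u_hat)
  stopifnot(length(d) == 3L, n_iter >= 1L)
  I <- d[1L]; J <- d[2L]; D <- d[3L]
  tp <- ad_tape()
  uh <- ad_const(tp, aperm(u_hat, c(3L, 2L, 1L)))        # (D, J, I)
  uh <- ad_reshape(uh, c(D, J, 1L, I))
  k_raw <- if (!is.null(k)) {
    stopifnot(length(k) == J, all(k > 0))
    ad_const(tp, log(expm1(k)))                          # softplus inverse
  }
  trace <- new.env(parent = emptyenv())
  trace$c <- vector("list", n_iter)
  v <- routing_node(uh, n_iter = n_iter, squash = squash, alpha = alpha,
                    g_form = g_form, f_form = f_form, k_raw = k_raw,
                    trace = trace)
  list(
    v = t(matrix(v$value, D, J)),
    couplings = lapply(trace$c, function(a) t(matrix(a, J, I))),
    b = t(matrix(trace$b, J, I))
  )
}

#' Full weight-capsule forward pass for one beat
#'
#' Chains primary capsules, prediction vectors, weighted dynamic routing
#' and the embedding reduction: a 20 x 28 feature map becomes a length-
#' \code{n_out} beat embedding.
#'
#' @param feature_map Positions-by-channels matrix (20 x 28).
#' @param params Capsule parameters from [init_caps_params()].
#' @param spec A [wcaps_spec()].
#' @return Numeric beat embedding of length \code{spec$n_out}.
#' @export
wcaps_forward <- function(feature_map, params, spec = wcaps_spec()) {
  tp <- ad_tape()
  x <- ad_const(tp, array(feature_map, c(dim(feature_map), 1L)))
  nodes <- lapply(params, function(p) {
    if (is.list(p)) lapply(p, ad_const, tape = tp) else ad_const(tp, p)
  })
  e <- caps_embed_node(x, nodes, spec)
  as.vector(e$value)
}

# shared capsule pipeline: (L, C, N) map node -> (n_out, N) embedding node
caps_embed_node <- function(x, nodes, spec) {
  u <- ad_relu(conv1d_node(x, nodes$Wc, nodes$bc, k = spec$kernel))  # (C, P, N)
  uh <- uhat_node(u, nodes$Wcaps, d_out = spec$d_out, n_out = spec$n_out)
  v <- routing_node(uh, n_iter = spec$routing_iters, squash = spec$squash,
                    alpha = spec$alpha, g_form = spec$g_form,
                    f_form = spec$f_form, k_raw = nodes$k_raw)
  embed_node(v, spec$reduction)
}

#' Initialise capsule-layer parameters
#'
#' @param d_in Input channel count of the feature map (28).
#' @param n_in Number of primary capsules produced by the valid convolution
#'   (18 for a length-20 map with kernel 3).
#' @param spec A [wcaps_spec()].
#' @return Named list: \code{Wc}, \code{bc} (primary convolution),
#'   \code{Wcaps} (list of \code{n_in} transformation matrices,
#'   \code{(n_out*d_out) x d_in} each) and \code{k_raw} (softplus
#'   pre-activation of the k_j weights) when \code{spec$learn_k}.
#' @export
init_caps_params <- function(d_in = 28L, n_in = 18L, spec = wcaps_spec()) {
  conv_fan <- spec$kernel * d_in
  params <- list(
    Wc = matrix(stats::rnorm(d_in * conv_fan, 0, sqrt(2 / conv_fan)),
                d_in, conv_fan),
    bc = rep(0, d_in),
    Wcaps = lapply(seq_len(n_in), function(i) {
      matrix(stats::rnorm(spec$n_out * spec$d_out * d_in, 0, sqrt(1 / d_in)),
             spec$n_out * spec$d_out, d_in)
    })
  )
  # k_j start at n_out / sqrt(n_in): with uniform couplings 1/n_out the
  # agreement sum over n_in incoherent prediction vectors has norm about
  # sqrt(n_in)/n_out times a prediction norm, so this calibration puts the
  # initial pre-squash norms at O(1) instead of deep in the squash's
  # near-zero regime
  if (spec$learn_k) {
    k0 <- spec$n_out / sqrt(n_in)
    params$k_raw <- rep(if (k0 > 20) k0 else log(expm1(k0)), spec$n_out)
  }
  params
}
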