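# Model assembly: the named architecture variants (combinations of MLP
# block / convolutional frontends with no / standard / weight capsules,
# all sharing the seq2seq head), parameter initialisation, and the batched
# forward pass used for both training and prediction.

.variant_table <- list(
  "Baseline"      = list(frontend = "conv",           capsule = "none"),
  "MLP"           = list(frontend = "mlp_block",      capsule = "none"),
  "McNets"        = list(frontend = "mlp_conv",       capsule = "none"),
  "M-Baseline"    = list(frontend = "mlp_conv_block", capsule = "none"),
  "CapsuleNets"   = list(frontend = "conv",           capsule = "standard"),
  "MCapsuleNets"  = list(frontend = "mlp_block",      capsule = "standard"),
  "WCapsuleNets"  = list(frontend = "conv",           capsule = "weight"),
  "CWCapsuleNets" = list(frontend = "conv_block",     capsule = "weight"),
  "MWCapsuleNets" = list(frontend = "mlp_block",      capsule = "weight")
)

#' Named model variants
#'
#' @return A tibble listing every constructible variant with its frontend
#'   and capsule type.  \code{"MWCapsuleNets"} (MLP block + weight
#'   capsules) is the package default.
#' @export
model_variants <- function() {
  tibble::tibble(
    variant = names(.variant_table),
    frontend = vapply(.variant_table, `[[`, character(1), "frontend"),
    capsule = vapply(.variant_table, `[[`, character(1), "capsule")
  )
}

#' Build a heartbeat-classifier model
#'
#' Assembles one of the named variants: a frontend that turns each
#' length-280 beat into a 20 x 28 feature map, a beat-embedding stage
#' (none / standard capsules / weight capsules) producing a 128-dimensional
#' vector per beat, and the shared BiLSTM-encoder / LSTM-decoder head.
#'
#' @param variant One of [model_variants()]'s names.
#' @param seq_len Beats per input sequence (default 10).
#' @param hidden Recurrent hidden size and embedding width (default 128).
#' @param dropout_rate MLP-block dropout rate (default 0.8).
#' @param caps A [wcaps_spec()]; its squash/routing fields are overridden
#'   to match the variant's capsule type.
#' @param encoder_cell \code{"lstm"} (default) or \code{"rnn"}.
#' @param decoder_context Feed the per-step encoder outputs to the decoder
#'   (default \code{TRUE}; see [init_seq2seq_params()]).
#' @param seed Seed for parameter initialisation.
#' @return An object of class \code{mwcaps_model} holding the
#'   configuration, the initial parameters and the parameter count.
#' @export
#' @examples
#' m <- build_variant("MWCapsuleNets", seed = 1)
#' m$n_params
build_variant <- function(variant = "MWCapsuleNets", seq_len = 10L,
                          hidden = 128L, dropout_rate = 0.8,
                          caps = wcaps_spec(), encoder_cell = "lstm",
                          decoder_context = TRUE, seed = 1L) {
  variant <- match.arg(variant, names(.variant_table))
  vt <- .variant_table[[variant]]
  if (vt$capsule == "standard") {
    caps$squash <- "standard"; caps$f_form <- "one"; caps$learn_k <- FALSE
  } else if (vt$capsule == "weight") {
    caps$squash <- "ss"; caps$f_form <- "inv_norm"; caps$learn_k <- TRUE
  }
  config <- list(
    variant = variant, frontend = vt$frontend, capsule = vt$capsule,
    seq_len = as.integer(seq_len), hidden = as.integer(hidden),
    n_classes = 5L, n_patches = 10L, n_channels = 28L,
    beat_len = 280L, dropout_rate = dropout_rate, caps = caps,
    encoder_cell = encoder_cell, decoder_context = isTRUE(decoder_context)
  )
  theta <- withr::with_seed(as.integer(seed), init_model_params(config))
  structure(
    list(config = config, theta = theta,
         n_params = sum(vapply(theta, length, integer(1)))),
    class = "mwcaps_model"
  )
}

#' @export
print.mwcaps_model <- function(x, ...) {
  cat("<mwcaps_model> ", x$config$variant,
      " (frontend: ", x$config$frontend,
      ", capsule: ", x$config$capsule, ")\n",
      "  seq_len ", x$config$seq_len, ", hidden ", x$config$hidden,
      ", parameters ", format(x$n_params, big.mark = ","), "\n", sep = "")
  invisible(x)
}

# flat parameter list (every element a plain numeric array) for Adam
init_model_params <- function(cfg) {
  S <- cfg$n_patches; C <- cfg$n_channels
  conv_w <- function() matrix(stats::rnorm(C * 3L * C, 0, sqrt(2 / (3 * C))), C, 3L * C)
  theta <- list()
  if (cfg$frontend %in% c("mlp_block", "mlp_conv", "mlp_conv_block")) {
    mb <- mlp_block_params(S, cfg$dropout_rate)
    theta$Wm <- mb$W; theta$bm <- mb$b
  }
  n_conv <- switch(cfg$frontend, conv = 1L, mlp_conv = 1L, conv_block = 2L,
                   mlp_conv_block = 2L, 0L)
  for (k in seq_len(n_conv)) {
    theta[[paste0("Wcf", k)]] <- conv_w()
    theta[[paste0("bcf", k)]] <- rep(0, C)
  }
  if (cfg$capsule == "none") {
    n_flat <- 2L * S * C
    e_dim <- cfg$caps$n_out # embedding width shared across variants
    theta$We <- matrix(stats::rnorm(e_dim * n_flat, 0, sqrt(2 / n_flat)),
                       e_dim, n_flat)
    theta$be <- rep(0, e_dim)
  } else {
    n_in <- 2L * S - cfg$caps$kernel + 1L
    cp <- init_caps_params(d_in = C, n_in = n_in, spec = cfg$caps)
    theta$Wc <- cp$Wc; theta$bc <- cp$bc
    for (i in seq_len(n_in)) theta[[sprintf("Wcaps%02d", i)]] <- cp$Wcaps[[i]]
    if (!is.null(cp$k_raw)) theta$k_raw <- cp$k_raw
  }
  c(theta, init_seq2seq_params(input_dim = cfg$caps$n_out, hidden = cfg$hidden,
                               n_classes = cfg$n_classes, cell = cfg$encoder_cell,
                               decoder_context = cfg$decoder_context))
}

# structured node views over the flat parameter list
model_nodes <- function(tp, theta, wrap = ad_const) {
  nodes <- lapply(theta, wrap, tape = tp)
  caps_i <- grep("^Wcaps\\d+$", names(theta))
  if (length(caps_i)) {
    nodes$Wcaps <- nodes[caps_i]
    nodes[caps_i] <- NULL
  }
  nodes
}

# frontend: (280 x N) beat matrix node -> (20, 28, N) feature-map node
frontend_node <- function(x, nodes, cfg, training = FALSE) {
  S <- cfg$n_patches; C <- cfg$n_channels
  N <- ncol(x$value)
  grid_m <- ad_reshape(ad_aperm(ad_reshape(x, c(C, S, N)), c(2L, 1L, 3L)),
                       c(S, C * N)) # (10, 28N): patches x channel-beat
  same_conv <- function(m, W, b) { # same-padded conv along the patch axis
    L <- nrow(m$value)
    zr <- ad_const(m$tape, matrix(0, 1L, ncol(m$value)))
    padded <- ad_reshape(ad_rbind(zr, ad_rbind(m, zr)), c(L + 2L, C, N))
    y <- ad_relu(conv1d_node(padded, W, b, k = 3L))      # (C, L, N)
    ad_reshape(ad_aperm(y, c(2L, 1L, 3L)), c(L, C * N))
  }
  mixed <- switch(cfg$frontend,
    mlp_block = ,
    mlp_conv = ,
    mlp_conv_block = {
      mask <- if (training && cfg$dropout_rate > 0) {
        ad_const(x$tape, dropout_mask(c(S, C * N), cfg$dropout_rate))
      }
      mlp_mix_node(nodes$Wm, nodes$bm, grid_m, mask)
    },
    conv = ,
    conv_block = same_conv(grid_m, nodes$Wcf1, nodes$bcf1)
  )
  if (cfg$frontend == "mlp_conv") {
    mixed <- same_conv(mixed, nodes$Wcf1, nodes$bcf1)
  } else if (cfg$frontend %in% c("conv_block", "mlp_conv_block")) {
    k <- if (cfg$frontend == "conv_block") c("Wcf2", "bcf2") else c("Wcf1", "bcf1")
    mixed <- same_conv(mixed, nodes[[k[1L]]], nodes[[k[2L]]])
    if (cfg$frontend == "mlp_conv_block") {
      mixed <- same_conv(mixed, nodes$Wcf2, nodes$bcf2)
    }
  }
  ad_reshape(ad_rbind(mixed, grid_m), c(2L * S, C, N))
}

# beat embedding: feature-map node -> (n_out x N) embedding node
embedding_node <- function(map, nodes, cfg) {
  if (cfg$capsule == "none") {
    d <- dim(map$value)
    flat <- ad_reshape(map, c(d[1L] * d[2L], d[3L]))
    ad_relu(ad_add(ad_matmul(nodes$We, flat), nodes$be))
  } else {
    caps_embed_node(map, nodes, cfg$caps)
  }
}

# full forward over a batch of sequences.
# X: (280 x B*L) beat matrix, beats ordered position-fastest within each
# sequence; targets: (L x B) integer matrix (1..C, NA = PAD) or NULL.
# Returns embedding/logit nodes and, when targets are given, the
# mask-normalised cross-entropy loss node.
model_forward_node <- function(tp, nodes, cfg, X, B, targets = NULL,
                               training = FALSE) {
  L <- ncol(X) %/% B
  C <- cfg$n_classes
  x <- ad_const(tp, X)
  map <- frontend_node(x, nodes, cfg, training = training)
  E <- embedding_node(map, nodes, cfg)                   # (n_out, B*L)
  xs <- lapply(seq_len(L), function(t) ad_cols(E, t + (seq_len(B) - 1L) * L))
  enc <- encoder_node(nodes, xs, cell = cfg$encoder_cell,
                      with_outputs = cfg$decoder_context)
  init <- decoder_init_node(nodes, enc)
  ctx <- if (cfg$decoder_context) enc$outputs
  out <- list(embedding = E)
  if (is.null(targets)) {
    out$pred <- decoder_infer_node(nodes, init, L, C, go_idx = C + 1L,
                                   context = ctx)
  } else {
    shifted <- rbind(rep(C + 1L, B),
                     ifelse(is.na(targets[-L, , drop = FALSE]), C + 2L,
                            targets[-L, , drop = FALSE]))
    if (L == 1L) shifted <- matrix(C + 1L, 1L, B)
    logits <- decoder_node(nodes, init, shifted, context = ctx)
    n_valid <- sum(!is.na(targets))
    loss <- NULL
    for (t in seq_len(L)) {
      oh <- matrix(0, C, B)
      valid <- which(!is.na(targets[t, ]))
      oh[cbind(targets[t, valid], valid)] <- 1 / max(1L, n_valid)
      lsm <- ad_logsoftmax_cols(logits[[t]])
      term <- ad_sum(ad_mul(lsm, ad_const(tp, oh)))
      loss <- if (is.null(loss)) term else ad_add(loss, term)
    }
    out$logits <- logits
    out$loss <- ad_neg(loss)
  }
  out
}
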