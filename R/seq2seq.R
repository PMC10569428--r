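# Sequence-to-sequence head: a bidirectional recurrent encoder summarises
# the sequence of per-beat embeddings ("many-to-one"), and an LSTM decoder
# emits one class per beat ("many-to-many").  During training the decoder
# is teacher-forced: it reads the target sequence shifted right by one,
# prefixed with a learned <GO> vector; at inference it feeds back its own
# greedy predictions and never sees targets.

# gate row ranges: input, forget, output, candidate
lstm_step_node <- function(W, b, x, h, c) {
  H <- nrow(h$value)
  z <- ad_add(ad_matmul(W, ad_rbind(x, h)), b)
  i <- ad_sigmoid(ad_rows(z, seq_len(H)))
  f <- ad_sigmoid(ad_rows(z, H + seq_len(H)))
  o <- ad_sigmoid(ad_rows(z, 2L * H + seq_len(H)))
  g <- ad_tanh(ad_rows(z, 3L * H + seq_len(H)))
  c2 <- ad_add(ad_mul(f, c), ad_mul(i, g))
  list(h = ad_mul(o, ad_tanh(c2)), c = c2)
}

rnn_step_node <- function(W, b, x, h) {
  ad_tanh(ad_add(ad_matmul(W, ad_rbind(x, h)), b))
}

# run one direction over a list of (E x B) input nodes; returns all hidden
# states (list) plus the final (h, c)
run_direction <- function(W, b, xs, H, B, cell, tp) {
  h <- ad_const(tp, matrix(0, H, B))
  c <- ad_const(tp, matrix(0, H, B))
  hs <- vector("list", length(xs))
  for (t in seq_along(xs)) {
    if (cell == "lstm") {
      st <- lstm_step_node(W, b, xs[[t]], h, c)
      h <- st$h; c <- st$c
    } else {
      h <- rnn_step_node(W, b, xs[[t]], h)
    }
    hs[[t]] <- h
  }
  list(states = hs, h = h, c = c)
}

# bidirectional encoder over a list of input nodes.
# returns per-step outputs y_t (combiner applied) and the final states of
# both directions.
encoder_node <- function(nodes, xs, cell = "lstm", with_outputs = TRUE) {
  tp <- xs[[1L]]$tape
  H <- length(nodes$bf$value) %/% (if (cell == "lstm") 4L else 1L)
  B <- ncol(xs[[1L]]$value)
  Tn <- length(xs)
  fwd <- run_direction(nodes$Wf, nodes$bf, xs, H, B, cell, tp)
  bwd <- run_direction(nodes$Wb, nodes$bb, rev(xs), H, B, cell, tp)
  outputs <- NULL
  if (with_outputs) {
    outputs <- lapply(seq_len(Tn), function(t) {
      both <- ad_rbind(fwd$states[[t]], bwd$states[[Tn - t + 1L]])
      ad_add(ad_matmul(nodes$Uo, both), nodes$bo)
    })
  }
  list(outputs = outputs, h_fwd = fwd$h, h_bwd = bwd$h,
       c_fwd = fwd$c, c_bwd = bwd$c)
}

# decoder initial hidden state from the encoder summary
decoder_init_node <- function(nodes, enc) {
  both <- ad_rbind(enc$h_fwd, enc$h_bwd)
  h0 <- ad_tanh(ad_add(ad_matmul(nodes$Wh0, both), nodes$bh0))
  c0 <- ad_const(h0$tape, matrix(0, nrow(h0$value), ncol(h0$value)))
  list(h = h0, c = c0)
}

# teacher-forced decoder: input_idx is a (T x B) integer matrix of embedding
# columns (classes 1..C, GO = C+1, PAD = C+2).  When `context` is supplied
# (the per-step encoder outputs y_t), it is concatenated to the label
# embedding, giving each decoder step direct attention-free access to its
# beat's features.  Returns a list of (C x B) logit nodes.
decoder_node <- function(nodes, init, input_idx, context = NULL) {
  h <- init$h; c <- init$c
  lapply(seq_len(nrow(input_idx)), function(t) {
    x <- ad_cols(nodes$Emb, input_idx[t, ])
    if (!is.null(context)) x <- ad_rbind(x, context[[t]])
    st <- lstm_step_node(nodes$Wd, nodes$bd, x, h, c)
    h <<- st$h; c <<- st$c
    ad_add(ad_matmul(nodes$Wy, h), nodes$by)
  })
}

# greedy decoder: feeds back its own argmax prediction; never reads targets
decoder_infer_node <- function(nodes, init, Tn, n_classes, go_idx,
                               context = NULL) {
  B <- ncol(init$h$value)
  h <- init$h; c <- init$c
  idx <- rep(go_idx, B)
  preds <- matrix(0L, Tn, B)
  for (t in seq_len(Tn)) {
    x <- ad_cols(nodes$Emb, idx)
    if (!is.null(context)) x <- ad_rbind(x, context[[t]])
    st <- lstm_step_node(nodes$Wd, nodes$bd, x, h, c)
    h <- st$h; c <- st$c
    logits <- ad_add(ad_matmul(nodes$Wy, h), nodes$by)
    idx <- max.col(t(logits$value), ties.method = "first")
    preds[t, ] <- idx
  }
  preds
}

#' Initialise sequence-to-sequence parameters
#'
#' @param input_dim Beat-embedding width fed to the encoder (default 128).
#' @param hidden Hidden-state size of every recurrent cell (default 128,
#'   matching the embedding width).
#' @param n_classes Number of beat classes (default 5).
#' @param cell Encoder cell, \code{"lstm"} (default; the decoder is always
#'   an LSTM) or \code{"rnn"} for a vanilla tanh recurrence.
#' @param decoder_context Concatenate the per-step encoder output y_t to
#'   the decoder input (default \code{TRUE})?  Without it the decoder sees
#'   the sequence only through the final encoder state.
#' @return Named parameter list.  The decoder embedding table has
#'   \code{n_classes + 2} columns: one per class, one for the <GO> token
#'   and one for PAD.
#' @export
init_seq2seq_params <- function(input_dim = 128L, hidden = 128L,
                                n_classes = 5L, cell = "lstm",
                                decoder_context = TRUE) {
  H <- hidden
  ctx <- if (decoder_context) input_dim else 0L
  gates <- if (cell == "lstm") 4L else 1L
  glorot <- function(r, co) matrix(stats::rnorm(r * co, 0, sqrt(2 / (r + co))), r, co)
  lstm_bias <- function() {
    b <- rep(0, gates * H)
    if (gates == 4L) b[H + seq_len(H)] <- 1 # forget-gate bias
    b
  }
  list(
    Wf = glorot(gates * H, input_dim + H), bf = lstm_bias(),
    Wb = glorot(gates * H, input_dim + H), bb = lstm_bias(),
    Uo = glorot(input_dim, 2L * H), bo = rep(0, input_dim),
    Wh0 = glorot(H, 2L * H), bh0 = rep(0, H),
    Emb = glorot(H, n_classes + 2L),
    Wd = glorot(4L * H, 2L * H + ctx),
    bd = { b <- rep(0, 4L * H); b[H + seq_len(H)] <- 1; b },
    Wy = glorot(n_classes, H), by = rep(0, n_classes)
  )
}

seq2seq_nodes <- function(tp, params, wrap = ad_const) {
  lapply(params, wrap, tape = tp)
}

#' Bidirectional recurrent encoding of a beat-embedding sequence
#'
#' Runs the forward pass \code{t = 1..T} and the backward pass
#' \code{t = T..1} over the sequence and combines the two hidden states of
#' each step through a learned linear map (the weighted-sum combiner).  The
#' final states of both directions summarise the whole sequence and
#' initialise the decoder.
#'
#' @param xs Numeric matrix with one time step per row (\code{T x input_dim}).
#' @param params Parameters from [init_seq2seq_params()].
#' @param cell \code{"lstm"} or \code{"rnn"}.
#' @return A list: \code{outputs} (\code{T x input_dim} matrix of combined
#'   per-step outputs) and \code{final} (list with \code{h_fwd},
#'   \code{h_bwd}).
#' @export
birnn_encode <- function(xs, params, cell = "lstm") {
  if (!is.matrix(xs)) xs <- matrix(xs, nrow = 1L)
  if (nrow(xs) < 1L) stop("empty input sequence")
  tp <- ad_tape()
  nodes <- seq2seq_nodes(tp, params)
  xnodes <- lapply(seq_len(nrow(xs)), function(t) ad_const(tp, cbind(xs[t, ])))
  enc <- encoder_node(nodes, xnodes, cell = cell)
  list(
    outputs = do.call(rbind, lapply(enc$outputs, function(y) as.vector(y$value))),
    final = list(h_fwd = as.vector(enc$h_fwd$value),
                 h_bwd = as.vector(enc$h_bwd$value))
  )
}

#' Teacher-forced decoding (training mode)
#'
#' Produces per-step class logits given the ground-truth target sequence:
#' the decoder input at step 1 is the <GO> vector and at step \code{t > 1}
#' the embedding of target \code{t - 1}.  PAD targets (\code{NA}) embed to
#' the PAD vector and are expected to be masked out of the loss.
#'
#' @param params Parameters from [init_seq2seq_params()].
#' @param enc An encoding from [birnn_encode()] (its \code{final} element is
#'   used).
#' @param targets Integer vector of target classes (1-based; \code{NA} =
#'   PAD).
#' @return A \code{T x n_classes} logits matrix.
#' @export
decode_train <- function(params, enc, targets) {
  C <- nrow(params$Wy)
  Tn <- length(targets)
  stopifnot(Tn >= 1L)
  tp <- ad_tape()
  nodes <- seq2seq_nodes(tp, params)
  init <- list(
    h = ad_tanh(ad_add(ad_matmul(nodes$Wh0,
          ad_const(tp, rbind(cbind(enc$final$h_fwd), cbind(enc$final$h_bwd)))),
          nodes$bh0)),
    c = ad_const(tp, matrix(0, length(params$bh0), 1L))
  )
  shifted <- c(C + 1L, ifelse(is.na(targets[-Tn]), C + 2L, targets[-Tn]))
  ctx <- decoder_context_nodes(tp, params, enc, Tn)
  logits <- decoder_node(nodes, init, matrix(shifted, ncol = 1L), context = ctx)
  t(vapply(logits, function(l) as.vector(l$value), numeric(C)))
}

# per-step context columns for the surface decoders; NULL when the decoder
# was initialised without context
decoder_context_nodes <- function(tp, params, enc, Tn) {
  H <- length(params$bh0)
  ctx_dim <- ncol(params$Wd) - 2L * H
  if (ctx_dim == 0L) return(NULL)
  if (is.null(enc$outputs)) stop("this decoder needs the encoder outputs")
  lapply(seq_len(Tn), function(t) ad_const(tp, cbind(enc$outputs[t, ])))
}

#' Greedy decoding (inference mode)
#'
#' Generates a label sequence of length \code{n_steps} by feeding back the
#' embedding of the previously predicted class (<GO> at step 1).  The
#' interface takes no targets: inference cannot read them.
#'
#' @inheritParams decode_train
#' @param n_steps Number of beats to label.
#' @return Integer vector of predicted classes (1-based).
#' @export
decode_infer <- function(params, enc, n_steps) {
  C <- nrow(params$Wy)
  tp <- ad_tape()
  nodes <- seq2seq_nodes(tp, params)
  init <- list(
    h = ad_tanh(ad_add(ad_matmul(nodes$Wh0,
          ad_const(tp, rbind(cbind(enc$final$h_fwd), cbind(enc$final$h_bwd)))),
          nodes$bh0)),
    c = ad_const(tp, matrix(0, length(params$bh0), 1L))
  )
  ctx <- decoder_context_nodes(tp, params, enc, n_steps)
  as.vector(decoder_infer_node(nodes, init, n_steps, C, go_idx = C + 1L,
                               context = ctx))
}

#' Softmax probabilities from logits
#'
#' Numerically stable softmax: positive entries summing to one, invariant
#' to adding a constant to all logits.
#'
#' @param logits Finite numeric vector.
#' @return Probability vector of the same length.
#' @export
#' @examples
#' softmax_probs(c(1, 2, 3))
softmax_probs <- function(logits) {
  stopifnot(all(is.finite(logits)))
  e <- exp(logits - max(logits))
  e / sum(e)
}
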