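# Training (Adam on the masked sequence cross-entropy) and prediction.

adam_init <- function(theta) {
  list(m = lapply(theta, function(x) x * 0),
       v = lapply(theta, function(x) x * 0),
       t = 0L)
}

adam_step <- function(theta, grads, state, lr = 0.001, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(theta)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    theta[[nm]] <- theta[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(theta = theta, state = state)
}

# long sequence tibble -> dense arrays for the batched forward pass
sequence_arrays <- function(seqs, classes = aami_classes()) {
  L <- max(seqs$position)
  ord <- dplyr::arrange(seqs, .data$record_id, .data$sequence, .data$position)
  meta <- dplyr::distinct(ord, .data$record_id, .data$sequence)
  X <- do.call(cbind, ord$samples)                       # (280, B*L), position fastest
  targets <- matrix(match(ord$label, classes), nrow = L) # (L, B); NA = PAD
  list(X = X, targets = targets, meta = meta, order = ord, L = L,
       B = nrow(meta))
}

#' Train a heartbeat sequence classifier
#'
#' Fits one of the model variants on a tibble of labeled beats: beats are
#' grouped per record into fixed-length sequences, and the model is trained
#' with the Adam optimiser on the PAD-masked sequence cross-entropy
#' (learning rate 0.001 by default).  Training is deterministic for a fixed
#' seed under single-threaded execution.
#'
#' @param beats A beats tibble ([extract_beats()] / [synth_beats()]); rows
#'   with \code{split == "test"} are ignored if a \code{split} column is
#'   present.
#' @param variant Model variant name (see [model_variants()]).
#' @param seq_len Beats per sequence (default 10).
#' @param epochs Maximum training epochs (the reference protocol allows up
#'   to 500; the default here is sized for desk-scale data).
#' @param batch_size Sequences per gradient step (default 16).
#' @param lr Adam learning rate (default 0.001).
#' @param seed Seed controlling initialisation, shuffling and dropout.
#' @param stop_loss Optional early-exit threshold: stop when the epoch mean
#'   loss falls below it.
#' @param patience Optional early-stopping patience in epochs (stops when
#'   the loss has not improved for that many epochs); \code{NULL} (default)
#'   trains to \code{epochs}.
#' @param model Optional pre-built [build_variant()] model (overrides
#'   \code{variant}/\code{seq_len}).
#' @param verbose Print per-epoch losses?
#' @return An object of class \code{mwcaps_fit}: the trained model, the
#'   per-epoch loss history, and the class levels.
#' @export
mwcaps_train <- function(beats, variant = "MWCapsuleNets", seq_len = 10L,
                         epochs = 30L, batch_size = 16L, lr = 0.001,
                         seed = 1L, stop_loss = NULL, patience = NULL,
                         model = NULL, verbose = FALSE) {
  if ("split" %in% names(beats)) beats <- dplyr::filter(beats, .data$split != "test")
  stopifnot(nrow(beats) > 0L)
  model <- model %||% build_variant(variant, seq_len = seq_len, seed = seed)
  cfg <- model$config
  seqs <- beats_to_sequences(beats, cfg$seq_len)
  arr <- sequence_arrays(seqs)
  theta <- model$theta
  state <- adam_init(theta)
  history <- numeric(0)
  withr::with_seed(as.integer(seed) + 1L, {
    best <- Inf; stale <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample.int(arr$B)
      losses <- numeric(0)
      for (start in seq(1L, arr$B, by = batch_size)) {
        bi <- ord[start:min(start + batch_size - 1L, arr$B)]
        cols <- as.vector(outer(seq_len(arr$L), (bi - 1L) * arr$L, `+`))
        tp <- ad_tape()
        nodes <- model_nodes(tp, theta, wrap = ad_param)
        fw <- model_forward_node(tp, nodes, cfg, arr$X[, cols, drop = FALSE],
                                 B = length(bi),
                                 targets = arr$targets[, bi, drop = FALSE],
                                 training = TRUE)
        if (!is.finite(fw$loss$value)) {
          stop("non-finite training loss at epoch ", ep,
               " (batch starting at sequence ", start, ")")
        }
        ad_backward(fw$loss)
        grads <- grads_of(nodes, names(theta))
        up <- adam_step(theta, grads, state, lr = lr)
        theta <- up$theta; state <- up$state
        losses <- c(losses, fw$loss$value)
      }
      history <- c(history, mean(losses))
      if (verbose) message(sprintf("epoch %3d  loss %.5f", ep, mean(losses)))
      if (!is.null(stop_loss) && mean(losses) < stop_loss) break
      if (!is.null(patience)) {
        if (mean(losses) < best - 1e-5) { best <- mean(losses); stale <- 0L }
        else if ((stale <- stale + 1L) >= patience) break
      }
    }
  })
  model$theta <- theta
  structure(
    list(model = model, classes = aami_classes(),
         history = tibble::tibble(epoch = seq_along(history), loss = history),
         n_train_beats = nrow(beats), seed = as.integer(seed)),
    class = "mwcaps_fit"
  )
}

# collect gradients from parameter nodes back into a flat list
grads_of <- function(nodes, nms) {
  out <- stats::setNames(vector("list", length(nms)), nms)
  caps <- grep("^Wcaps\\d+$", nms, value = TRUE)
  for (nm in setdiff(nms, caps)) out[[nm]] <- nodes[[nm]]$grad
  if (length(caps)) {
    for (i in seq_along(caps)) out[[caps[i]]] <- nodes$Wcaps[[i]]$grad
  }
  out
}

#' @export
print.mwcaps_fit <- function(x, ...) {
  cat("<mwcaps_fit> ", x$model$config$variant, ", ",
      nrow(x$history), " epochs, final loss ",
      signif(utils::tail(x$history$loss, 1), 4), ", ",
      x$n_train_beats, " training beats\n", sep = "")
  invisible(x)
}

#' Predict beat classes for new beats
#'
#' Groups the new beats into sequences of the fitted sequence length, runs
#' the frontend/capsule/encoder stack and greedy decoding, and returns one
#' row per (non-PAD) beat with the predicted AAMI class.
#'
#' @param object A [mwcaps_train()] fit.
#' @param beats A beats tibble; a \code{split} column, if present, is kept
#'   in the output.
#' @param batch_size Sequences per forward batch.
#' @param ... Unused.
#' @return A tibble with \code{record_id}, \code{sequence}, \code{position},
#'   the true \code{label} and \code{.pred_class}.
#' @export
predict.mwcaps_fit <- function(object, beats, batch_size = 32L, ...) {
  cfg <- object$model$config
  seqs <- beats_to_sequences(beats, cfg$seq_len)
  arr <- sequence_arrays(seqs)
  preds <- matrix(NA_integer_, arr$L, arr$B)
  for (start in seq(1L, arr$B, by = batch_size)) {
    bi <- start:min(start + batch_size - 1L, arr$B)
    cols <- as.vector(outer(seq_len(arr$L), (bi - 1L) * arr$L, `+`))
    tp <- ad_tape()
    nodes <- model_nodes(tp, object$model$theta, wrap = ad_const)
    fw <- model_forward_node(tp, nodes, cfg, arr$X[, cols, drop = FALSE],
                             B = length(bi), targets = NULL, training = FALSE)
    preds[, bi] <- fw$pred
  }
  arr$order |>
    dplyr::mutate(.pred_class = object$classes[as.vector(preds)]) |>
    dplyr::filter(!.data$pad) |>
    dplyr::select(-"samples", -"pad")
}
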