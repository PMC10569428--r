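# The MLP patch-mixing block: a length-280 beat is folded into a 10 x 28
# patches-by-channels grid, a 10-unit fully connected layer mixes the patch
# axis independently per channel (token mixing), dropout regularises the
# mixed features, and the block output is the concatenation of the mixed
# grid with its input, giving a 20 x 28 feature map.

#' Fold a beat into the patches-by-channels grid
#'
#' Row-major fold of a length-280 beat into a 10 x 28 matrix: patch (row)
#' \code{i} holds samples \code{28*(i-1)+1 .. 28*i}.  [unfold_patches()] is
#' its exact inverse.
#'
#' @param beat Numeric vector of length 280 (or \code{n_patches * n_channels}).
#' @param n_patches,n_channels Grid dimensions (default 10 x 28).
#' @return A \code{n_patches} x \code{n_channels} matrix.
#' @export
#' @examples
#' reshape_patches(seq_len(280))[1, 1:5]
reshape_patches <- function(beat, n_patches = 10L, n_channels = 28L) {
  if (length(beat) != n_patches * n_channels) {
    stop("beat must have length ", n_patches * n_channels)
  }
  matrix(beat, n_patches, n_channels, byrow = TRUE)
}

#' @rdname reshape_patches
#' @param grid A patches-by-channels matrix.
#' @export
unfold_patches <- function(grid) as.vector(t(grid))

#' Initialise MLP-block parameters
#'
#' The mixing layer has as many units as there are patches (10), so the
#' block preserves the grid shape.  The layer is linear (no activation) and
#' is followed by inverted dropout, active only during training.
#'
#' @param n_patches Patch count (and fully connected units).
#' @param dropout_rate Probability of dropping a mixed feature during
#'   training (default 0.8).
#' @param init_sd Standard deviation of the random weight initialisation.
#' @return A list with \code{W} (\code{n_patches} square matrix), \code{b}
#'   and \code{dropout_rate}.
#' @export
mlp_block_params <- function(n_patches = 10L, dropout_rate = 0.8,
                             init_sd = NULL) {
  stopifnot(dropout_rate >= 0, dropout_rate < 1)
  sd <- init_sd %||% sqrt(2 / (2 * n_patches))
  list(W = matrix(stats::rnorm(n_patches^2, 0, sd), n_patches, n_patches),
       b = rep(0, n_patches), dropout_rate = dropout_rate)
}

# node-level forward shared by the exported wrapper and the full model.
# X: (n_patches x n_channels*batch) matrix node; mask: NULL or a constant
# inverted-dropout mask of the same shape.
mlp_mix_node <- function(W, b, X, mask = NULL) {
  U <- ad_add(ad_matmul(W, X), b)
  if (!is.null(mask)) U <- ad_mul(U, mask)
  U
}

dropout_mask <- function(shape, rate) {
  if (rate <= 0) return(NULL)
  keep <- stats::rbinom(prod(shape), 1L, 1 - rate)
  array(keep / (1 - rate), dim = shape)
}

#' MLP-block mixing layer forward pass
#'
#' Applies the 10-unit fully connected mixing layer along the patch axis,
#' independently for every channel, followed by dropout.  At evaluation
#' time (\code{training = FALSE}) dropout is the identity; during training
#' an inverted-dropout mask is sampled (so evaluation needs no rescaling).
#'
#' @param x Patches-by-channels matrix from [reshape_patches()].
#' @param params Parameters from [mlp_block_params()].
#' @param training Sample a dropout mask?
#' @return Matrix of the same shape as \code{x}.
#' @export
mlp_forward <- function(x, params, training = FALSE) {
  stopifnot(is.matrix(x))
  if (nrow(x) != nrow(params$W)) stop("grid/parameter shape mismatch")
  tp <- ad_tape()
  mask <- if (training) {
    m <- dropout_mask(dim(x), params$dropout_rate)
    if (!is.null(m)) ad_const(tp, m)
  }
  mlp_mix_node(ad_const(tp, params$W), ad_const(tp, params$b),
               ad_const(tp, x), mask)$value
}

#' Concatenate the mixed grid with the block input (skip connection)
#'
#' @param u,x Two equally shaped patches-by-channels matrices (mixed
#'   features and original input).
#' @return Matrix with \code{2 * nrow(u)} rows: \code{u} on top of \code{x}.
#' @export
concat_skip <- function(u, x) {
  if (!identical(dim(u), dim(x))) stop("shape mismatch between u and x")
  rbind(u, x)
}
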