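# Minimal reverse-mode automatic differentiation over dense numeric arrays.
#
# Every forward computation appends nodes to a tape (eager build order is a
# valid topological order); ad_backward() sweeps the tape in reverse and
# accumulates vector-Jacobian products into the leaves.  Values are plain R
# numerics: scalars, matrices, or n-d arrays.  Only the operations the
# networks in this package need are implemented.

ad_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 512L)
  e$n <- 0L
  class(e) <- "ad_tape"
  e
}

ad_shape <- function(x) dim(x) %||% length(x)

new_node <- function(tape, value, parents = list(), vjps = list(), requires = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$parents <- parents
  nd$vjps <- vjps
  nd$requires <- requires %||% any(vapply(parents, function(p) p$requires, logical(1)))
  nd$grad <- NULL
  n <- tape$n + 1L
  if (n > length(tape$nodes)) tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd$id <- n
  nd$tape <- tape
  class(nd) <- "ad_node"
  nd
}

ad_const <- function(tape, value) new_node(tape, value, requires = FALSE)
ad_param <- function(tape, value) new_node(tape, value, requires = TRUE)

is_node <- function(x) inherits(x, "ad_node")

# wrap a bare numeric as a constant on the same tape as `like`
as_node <- function(x, like) if (is_node(x)) x else ad_const(like$tape, x)

#' @noRd
ad_backward <- function(root, seed = 1) {
  stopifnot(is_node(root))
  root$grad <- if (length(root$value) == 1L) seed else array(seed, dim = ad_shape(root$value))
  tape <- root$tape
  for (k in seq.int(root$id, 1L)) {
    nd <- tape$nodes[[k]]
    if (is.null(nd) || is.null(nd$grad) || !length(nd$parents)) next
    g <- nd$grad
    for (j in seq_along(nd$parents)) {
      p <- nd$parents[[j]]
      if (!p$requires) next
      pg <- nd$vjps[[j]](g)
      p$grad <- if (is.null(p$grad)) pg else p$grad + pg
    }
    if (nd$requires == FALSE) nd$grad <- NULL
  }
  invisible(root)
}

# ---- plain-array broadcast helpers (shared by forwards and vjps) -----------

# expand singleton dims of x up to `shape`, one dim at a time via C-level
# row/column replication (cheaper than aperm-based tiling on large arrays)
arr_expand <- function(x, shape) {
  dy <- dim(x)
  stopifnot(length(dy) == length(shape))
  shape <- as.integer(shape)
  if (identical(as.integer(dy), shape)) return(x)
  y <- x
  for (k in which(dy == 1L & shape > 1L)) {
    lead <- prod(dy[seq_len(k - 1L)])
    rest <- prod(dy[-seq_len(k)])
    m <- matrix(y, lead, rest)
    y <- if (lead == 1L) {
      m[rep(1L, shape[k]), , drop = FALSE]
    } else {
      m[, rep(seq_len(rest), each = shape[k]), drop = FALSE]
    }
    dy[k] <- shape[k]
  }
  dim(y) <- dy
  y
}

# sum x over dims `over`, keeping them as singletons
arr_sum_dims <- function(x, over) {
  d <- dim(x)
  nd <- length(d)
  over <- sort(as.integer(over))
  keep <- setdiff(seq_len(nd), over)
  out_dim <- d
  out_dim[over] <- 1L
  if (!length(keep)) return(array(sum(x), dim = out_dim))
  if (identical(over, seq_along(over))) {               # leading dims
    return(array(colSums(x, dims = length(over)), dim = out_dim))
  }
  if (identical(over, seq.int(nd - length(over) + 1L, nd))) { # trailing dims
    return(array(rowSums(x, dims = nd - length(over)), dim = out_dim))
  }
  if (length(over) == 1L) {                             # single middle dim
    k <- over
    lead <- prod(d[seq_len(k - 1L)])
    m <- matrix(x, lead * d[k], prod(d[seq.int(k + 1L, nd)]))
    r <- rowsum(m, group = rep(seq_len(lead), times = d[k]), reorder = TRUE)
    return(array(r, dim = out_dim))
  }
  xp <- aperm(x, c(keep, over))                         # general fallback
  m <- matrix(xp, prod(d[keep]), prod(d[over]))
  array(rowSums(m), dim = out_dim)
}

# reduce g (full shape) back down to `target` by summing expanded dims
arr_reduce_to <- function(g, target) {
  if (identical(as.integer(dim(g)), as.integer(target))) return(g)
  arr_sum_dims(g, which(target == 1L & dim(g) > 1L))
}

# ---- arithmetic ------------------------------------------------------------

# shapes: identical; or b a scalar; or a a matrix and b a length-nrow(a) bias
ad_add <- function(a, b) {
  b <- as_node(b, a)
  av <- a$value; bv <- b$value
  if (identical(ad_shape(av), ad_shape(bv))) {
    new_node(a$tape, av + bv, list(a, b), list(function(g) g, function(g) g))
  } else if (length(bv) == 1L) {
    new_node(a$tape, av + bv, list(a, b), list(function(g) g, function(g) sum(g)))
  } else if (is.matrix(av) && length(bv) == nrow(av)) {
    new_node(a$tape, av + bv, list(a, b), list(function(g) g, function(g) rowSums(g)))
  } else stop("ad_add: incompatible shapes")
}

ad_neg <- function(a) new_node(a$tape, -a$value, list(a), list(function(g) -g))

ad_sub <- function(a, b) {
  b <- as_node(b, a)
  stopifnot(identical(ad_shape(a$value), ad_shape(b$value)) || length(b$value) == 1L)
  vb <- if (length(b$value) == 1L) function(g) -sum(g) else function(g) -g
  new_node(a$tape, a$value - b$value, list(a, b), list(function(g) g, vb))
}

ad_mul <- function(a, b) {
  b <- as_node(b, a)
  av <- a$value; bv <- b$value
  if (identical(ad_shape(av), ad_shape(bv))) {
    new_node(a$tape, av * bv, list(a, b),
             list(function(g) g * bv, function(g) g * av))
  } else if (length(bv) == 1L) {
    new_node(a$tape, av * bv, list(a, b),
             list(function(g) g * bv, function(g) sum(g * av)))
  } else if (length(av) == 1L) {
    new_node(a$tape, av * bv, list(a, b),
             list(function(g) sum(g * bv), function(g) g * av))
  } else stop("ad_mul: incompatible shapes")
}

ad_div <- function(a, b) {
  b <- as_node(b, a)
  av <- a$value; bv <- b$value
  stopifnot(identical(ad_shape(av), ad_shape(bv)) || length(bv) == 1L)
  y <- av / bv
  vb <- if (length(bv) == 1L) function(g) -sum(g * av / bv^2) else function(g) -g * av / bv^2
  new_node(a$tape, y, list(a, b), list(function(g) g / bv, vb))
}

ad_matmul <- function(a, b) {
  av <- a$value; bv <- b$value
  new_node(a$tape, av %*% bv, list(a, b),
           list(function(g) g %*% t(bv), function(g) t(av) %*% g))
}

# ---- elementwise nonlinearities -------------------------------------------

ad_tanh <- function(a) {
  y <- tanh(a$value)
  new_node(a$tape, y, list(a), list(function(g) g * (1 - y * y)))
}

ad_sigmoid <- function(a) {
  y <- stats::plogis(a$value)
  new_node(a$tape, y, list(a), list(function(g) g * y * (1 - y)))
}

ad_relu <- function(a) {
  v <- a$value
  y <- v * (v > 0)
  new_node(a$tape, y, list(a), list(function(g) g * (v > 0)))
}

ad_exp <- function(a) {
  y <- exp(a$value)
  new_node(a$tape, y, list(a), list(function(g) g * y))
}

ad_log <- function(a) {
  v <- a$value
  new_node(a$tape, log(v), list(a), list(function(g) g / v))
}

ad_sqrt <- function(a) {
  y <- sqrt(a$value)
  new_node(a$tape, y, list(a), list(function(g) g / (2 * y)))
}

ad_recip <- function(a) {
  v <- a$value
  y <- 1 / v
  new_node(a$tape, y, list(a), list(function(g) -g * y * y))
}

ad_square <- function(a) {
  v <- a$value
  new_node(a$tape, v * v, list(a), list(function(g) 2 * g * v))
}

# numerically stable log(1 + exp(x)); derivative is the logistic function
ad_softplus <- function(a) {
  v <- a$value
  y <- ifelse(v > 30, v, log1p(exp(pmin(v, 30))))
  if (!is.null(dim(v))) dim(y) <- dim(v)
  new_node(a$tape, y, list(a), list(function(g) g * stats::plogis(v)))
}

# ---- reductions, reshapes, broadcasting -----------------------------------

ad_sum <- function(a) {
  shp <- ad_shape(a$value)
  new_node(a$tape, sum(a$value), list(a),
           list(function(g) if (length(shp) > 1L || is.array(a$value)) array(g, dim = dim(a$value)) else rep(g, length(a$value))))
}

ad_sum_dims <- function(a, over) {
  d <- dim(a$value)
  new_node(a$tape, arr_sum_dims(a$value, over), list(a),
           list(function(g) arr_expand(g, d)))
}

ad_expand <- function(a, shape) {
  d <- dim(a$value)
  new_node(a$tape, arr_expand(a$value, shape), list(a),
           list(function(g) arr_reduce_to(g, d)))
}

ad_reshape <- function(a, shape) {
  v <- a$value
  old <- dim(v)
  y <- v
  dim(y) <- shape
  new_node(a$tape, y, list(a), list(function(g) { dim(g) <- old; g }))
}

ad_aperm <- function(a, perm) {
  new_node(a$tape, aperm(a$value, perm), list(a),
           list(function(g) aperm(g, order(perm))))
}

# stack K equal-shape matrices into a (r, c, K) array
ad_stack3 <- function(xs) {
  stopifnot(length(xs) >= 1L)
  r <- nrow(xs[[1L]]$value); cc <- ncol(xs[[1L]]$value)
  v <- array(unlist(lapply(xs, function(x) x$value), use.names = FALSE), dim = c(r, cc, length(xs)))
  vjps <- lapply(seq_along(xs), function(k) {
    force(k)
    function(g) array(g[, , k], dim = c(r, cc))
  })
  new_node(xs[[1L]]$tape, v, xs, vjps)
}

ad_rbind <- function(a, b) {
  ra <- nrow(a$value); rb <- nrow(b$value)
  new_node(a$tape, rbind(a$value, b$value), list(a, b),
           list(function(g) g[seq_len(ra), , drop = FALSE],
                function(g) g[ra + seq_len(rb), , drop = FALSE]))
}

ad_rows <- function(a, idx) {
  v <- a$value
  new_node(a$tape, v[idx, , drop = FALSE], list(a),
           list(function(g) {
             gx <- matrix(0, nrow(v), ncol(v))
             if (anyDuplicated(idx)) {
               s <- rowsum(g, group = idx)
               gx[as.integer(rownames(s)), ] <- s
             } else gx[idx, ] <- g
             gx
           }))
}

# column gather; duplicated indices accumulate in the backward pass, which
# makes this double as an embedding lookup
ad_cols <- function(a, idx) {
  v <- a$value
  new_node(a$tape, v[, idx, drop = FALSE], list(a),
           list(function(g) {
             gx <- matrix(0, nrow(v), ncol(v))
             if (anyDuplicated(idx)) {
               s <- rowsum(t(g), group = idx)
               gx[, as.integer(rownames(s))] <- t(s)
             } else gx[, idx] <- g
             gx
           }))
}

# gather arbitrary elements by a (possibly repeating) linear index array
ad_gather <- function(a, idx) {
  v <- a$value
  y <- array(v[as.vector(idx)], dim = dim(idx))
  new_node(a$tape, y, list(a),
           list(function(g) {
             gx <- numeric(length(v))
             s <- rowsum(as.vector(g), group = as.vector(idx))
             gx[as.integer(rownames(s))] <- s
             if (!is.null(dim(v))) dim(gx) <- dim(v)
             gx
           }))
}

# max over one dim of an array, kept as a singleton dim; ties to the first
ad_max_dim <- function(a, dm) {
  v <- a$value
  d <- dim(v)
  keep <- setdiff(seq_along(d), dm)
  vp <- aperm(v, c(keep, dm))
  m <- matrix(vp, prod(d[keep]), d[dm])
  j <- max.col(m, ties.method = "first")
  lin <- cbind(seq_len(nrow(m)), j)
  out_dim <- d; out_dim[dm] <- 1L
  y <- array(m[lin], dim = out_dim)
  new_node(a$tape, y, list(a),
           list(function(g) {
             gm <- matrix(0, nrow(m), ncol(m))
             gm[lin] <- as.vector(g)
             gp <- array(gm, dim = c(d[keep], d[dm]))
             aperm(gp, order(c(keep, dm)))
           }))
}

# softmax over one dim of an array (stable)
ad_softmax_dim <- function(a, dm) {
  v <- a$value
  d <- dim(v)
  keep <- setdiff(seq_along(d), dm)
  vp <- aperm(v, c(keep, dm))
  m <- matrix(vp, prod(d[keep]), d[dm])
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  sm <- e / rowSums(e)
  y <- aperm(array(sm, dim = c(d[keep], d[dm])), order(c(keep, dm)))
  new_node(a$tape, y, list(a),
           list(function(g) {
             gy <- y * g
             y * (g - arr_expand(arr_sum_dims(gy, dm), d))
           }))
}

# log-softmax over the rows of each column (classes in rows, batch in cols)
ad_logsoftmax_cols <- function(a) {
  v <- a$value
  mx <- apply(v, 2L, max)
  z <- sweep(v, 2L, mx)
  lse <- log(colSums(exp(z)))
  y <- sweep(z, 2L, lse)
  sm <- exp(y)
  new_node(a$tape, y, list(a),
           list(function(g) g - sweep(sm, 2L, colSums(g), `*`)))
}

# ---- gradient checking -----------------------------------------------------

# central finite differences of a scalar-valued function of a flat parameter
# list, against the analytic gradient computed by `fn` itself via the tape.
# fn(theta) must return an ad_node scalar built from ad_param-wrapped theta.
ad_grad_check <- function(fn, theta, eps = 1e-5, n_sample = 25L, seed = 1L) {
  tp <- ad_tape()
  nodes <- lapply(theta, function(v) ad_param(tp, v))
  out <- fn(nodes)
  ad_backward(out)
  analytic <- lapply(nodes, function(nd) nd$grad %||% array(0, dim = ad_shape(nd$value)))
  set.seed(seed)
  worst <- 0
  for (nm in names(theta)) {
    n_el <- length(theta[[nm]])
    pick <- if (n_el <= n_sample) seq_len(n_el) else sample.int(n_el, n_sample)
    for (i in pick) {
      th <- theta
      th[[nm]][i] <- th[[nm]][i] + eps
      fp <- value_of(fn, th)
      th[[nm]][i] <- th[[nm]][i] - 2 * eps
      fm <- value_of(fn, th)
      num <- (fp - fm) / (2 * eps)
      ana <- as.vector(analytic[[nm]])[i]
      rel <- abs(num - ana) / max(1e-8, abs(num), abs(ana))
      if (abs(num - ana) < 1e-7) rel <- 0 # below central-difference noise floor
      worst <- max(worst, rel)
    }
  }
  worst
}

value_of <- function(fn, theta) {
  tp <- ad_tape()
  nodes <- lapply(theta, function(v) ad_param(tp, v))
  as.numeric(fn(nodes)$value)
}
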