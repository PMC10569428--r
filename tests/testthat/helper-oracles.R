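# Independent reference implementations used as oracles.  These are written
# as naive loops, deliberately sharing no code with the package internals.

# textbook routing-by-agreement (Sabour et al. style): logits b start at 0,
# couplings are softmax over output capsules, s_j = sum_i c_ij u_hat_(j|i),
# v_j = squash(s_j), b_ij += <u_hat_(j|i), v_j>.
oracle_routing <- function(u_hat, n_iter = 3L) {
  I <- dim(u_hat)[1]; J <- dim(u_hat)[2]; D <- dim(u_hat)[3]
  squash <- function(s) {
    r2 <- sum(s^2)
    if (r2 == 0) return(s * 0)
    (r2 / (1 + r2)) * s / sqrt(r2)
  }
  b <- matrix(0, I, J)
  v <- matrix(0, J, D)
  for (it in seq_len(n_iter)) {
    cc <- matrix(0, I, J)
    for (i in seq_len(I)) {
      e <- exp(b[i, ] - max(b[i, ]))
      cc[i, ] <- e / sum(e)
    }
    for (j in seq_len(J)) {
      s <- rep(0, D)
      for (i in seq_len(I)) s <- s + cc[i, j] * u_hat[i, j, ]
      v[j, ] <- squash(s)
    }
    if (it < n_iter) {
      for (i in seq_len(I)) for (j in seq_len(J)) {
        b[i, j] <- b[i, j] + sum(u_hat[i, j, ] * v[j, ])
      }
    }
  }
  list(v = v, c = cc)
}

# brute-force one-vs-rest metrics from raw label pairs
oracle_class_metrics <- function(truth, estimate, cls) {
  tp <- sum(truth == cls & estimate == cls)
  fn <- sum(truth == cls & estimate != cls)
  fp <- sum(truth != cls & estimate == cls)
  tn <- sum(truth != cls & estimate != cls)
  list(tp = tp, fn = fn, fp = fp, tn = tn,
       sen = if (tp + fn > 0) tp / (tp + fn) else NaN,
       spec = if (tn + fp > 0) tn / (tn + fp) else NaN,
       ppv = if (tp + fp > 0) tp / (tp + fp) else NaN)
}

# a small synthetic WFDB "database": a few records with known annotation
# layouts, written to dir; returns the tibble of beats expected per record
make_wfdb_db <- function(dir, n_records = 3L, beats_per_record = 12L,
                         fs = 360, seed = 99L) {
  withr::with_seed(seed, {
    purrr::map_chr(seq_len(n_records), function(r) {
      id <- sprintf("%03d", 100L + r)
      rr <- round(stats::runif(beats_per_record + 1L, 250, 400))
      peaks <- cumsum(rr)
      n <- max(peaks) + 300L
      t <- seq_len(n)
      sig <- 0.8 * sin(2 * pi * t / 300) + 0.1 * stats::rnorm(n)
      other <- 0.4 * cos(2 * pi * t / 250)
      symbols <- sample(c("N", "V", "A", "L"), beats_per_record + 1L,
                        replace = TRUE)
      ann <- tibble::tibble(sample = peaks, symbol = symbols)
      write_wfdb_record(dir, id, signals = list(V5 = other, MLII = sig),
                        fs = fs, annotations = ann)
      id
    })
  })
}

softplus_k <- function(x) log1p(exp(x))

# a toy model configuration: full architecture, scaled-down widths, so that
# forward/backward tests run in milliseconds
tiny_model <- function(variant = "MWCapsuleNets", seq_len = 3L, seed = 1L) {
  caps <- wcaps_spec(n_out = 6L, d_out = 2L)
  build_variant(variant, seq_len = seq_len, hidden = 8L,
                dropout_rate = 0.5, caps = caps, seed = seed)
}
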