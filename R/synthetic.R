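# Synthetic labeled heartbeats with class-dependent morphology and
# patient-level structure.  The generator exists so that the whole pipeline
# (preprocessing contracts, capsule network, seq2seq head, metrics) can be
# exercised end-to-end without downloading any ECG database: beats are sums
# of Gaussian bumps imitating the P-QRS-T complex, not physiological
# simulations.

# bump tables: center (fraction of beat), width, amplitude
.synth_bumps <- list(
  # normal: clear P, narrow QRS, modest T
  N = rbind(c(0.15, 0.025, 0.15), c(0.37, 0.008, -0.10), c(0.40, 0.012, 1.00),
            c(0.43, 0.008, -0.15), c(0.65, 0.040, 0.30)),
  # supraventricular ectopic: early narrow QRS, P shifted toward the onset
  S = rbind(c(0.08, 0.020, 0.22), c(0.29, 0.007, -0.08), c(0.32, 0.010, 0.90),
            c(0.35, 0.007, -0.12), c(0.58, 0.035, 0.28)),
  # ventricular ectopic: wide tall QRS, deep S wave, no P
  V = rbind(c(0.40, 0.050, 1.10), c(0.50, 0.035, -0.40), c(0.70, 0.060, 0.45)),
  # fusion: intermediate QRS width, attenuated P
  F = rbind(c(0.15, 0.020, 0.08), c(0.40, 0.030, 0.80), c(0.46, 0.020, -0.25),
            c(0.66, 0.050, 0.35)),
  # unknown/paced: low-amplitude, broad, irregular
  Q = rbind(c(0.15, 0.050, 0.15), c(0.35, 0.080, 0.40), c(0.60, 0.100, 0.25))
)

gauss_bumps <- function(bumps, n = 280L) {
  t <- seq(0, 1, length.out = n)
  y <- rep(0, n)
  for (k in seq_len(nrow(bumps))) {
    y <- y + bumps[k, 3] * exp(-0.5 * ((t - bumps[k, 1]) / bumps[k, 2])^2)
  }
  y
}

#' Deterministic synthetic beat template for an AAMI class
#'
#' Each class has a fixed sum-of-Gaussian-bumps waveform: V has a wide,
#' tall QRS with no P wave; S an early, narrow QRS with a shifted P; F an
#' intermediate QRS width; Q a low-amplitude irregular shape.  Templates are
#' min-max normalized to [0, 1] and are separable by construction.
#'
#' @param cls One of the five AAMI classes (see [aami_classes()]).
#' @param n Beat length in samples (default 280).
#' @return Numeric vector of length \code{n} in [0, 1].
#' @export
#' @examples
#' plot(beat_template("V"), type = "l")
beat_template <- function(cls, n = 280L) {
  cls <- match.arg(cls, aami_classes())
  normalize_signal(gauss_bumps(.synth_bumps[[cls]], n))
}

# per-patient morphology perturbation: a shared shift/stretch of bump
# centers, widths and amplitudes, making patients systematically different
# so the inter-patient split is genuinely harder than a random split
patient_morphology <- function(jitter) {
  list(
    center_shift = stats::rnorm(1, 0, 0.03 * jitter),
    width_scale = exp(stats::rnorm(1, 0, 0.20 * jitter)),
    amp_scale = exp(stats::rnorm(1, 0, 0.15 * jitter))
  )
}

patient_template <- function(cls, morph, n = 280L) {
  b <- .synth_bumps[[cls]]
  b[, 1] <- pmin(0.95, pmax(0.02, b[, 1] + morph$center_shift))
  b[, 2] <- b[, 2] * morph$width_scale
  b[, 3] <- b[, 3] * morph$amp_scale
  normalize_signal(gauss_bumps(b, n))
}

#' Generate a synthetic inter-patient heartbeat dataset
#'
#' Simulates the structure of an annotated arrhythmia database at the beat
#' level: each patient receives a fixed random morphology perturbation
#' applied to all of its beats, beat labels are drawn independently from a
#' (by default strongly N-dominant) class distribution, and i.i.d. Gaussian
#' amplitude noise is added per beat before clipping to [0, 1].  Train and
#' test patients are disjoint, emulating the inter-patient evaluation
#' paradigm.  The default class distribution mirrors the heavy imbalance of
#' real Holter data so that minority-class metrics are exercised.
#'
#' @param n_train_patients,n_test_patients Number of patients per side.
#' @param beats_per_patient Beats generated for each patient.
#' @param class_probs Probability of each AAMI class, in
#'   [aami_classes()] order; must sum to 1.
#' @param noise_sd Standard deviation of the additive amplitude noise.
#' @param morph_jitter Scale of the per-patient morphology perturbation
#'   (0 = all patients identical).
#' @param seed Integer seed; the dataset is fully reproducible from it.
#' @param n Beat length in samples.
#' @return A beats tibble with columns \code{record_id}, \code{split}
#'   (\code{"train"} or \code{"test"}), \code{r_peak}, \code{label} and the
#'   \code{samples} list-column.
#' @export
#' @examples
#' d <- synth_beats(n_train_patients = 2, n_test_patients = 1,
#'                  beats_per_patient = 20, seed = 1)
#' dplyr::count(d, split, label)
synth_beats <- function(n_train_patients = 10L, n_test_patients = 5L,
                        beats_per_patient = 100L,
                        class_probs = c(N = 0.90, S = 0.03, V = 0.05,
                                        F = 0.015, Q = 0.005),
                        noise_sd = 0.03, morph_jitter = 1, seed = 1L,
                        n = 280L) {
  stopifnot(n_train_patients >= 1L, n_test_patients >= 0L,
            beats_per_patient >= 1L, noise_sd >= 0, morph_jitter >= 0)
  stopifnot(length(class_probs) == 5L, abs(sum(class_probs) - 1) < 1e-9)
  n_pat <- n_train_patients + n_test_patients
  out <- withr::with_seed(as.integer(seed), {
    purrr::map_dfr(seq_len(n_pat), function(p) {
      morph <- patient_morphology(morph_jitter)
      templates <- lapply(stats::setNames(aami_classes(), aami_classes()),
                          patient_template, morph = morph, n = n)
      labels <- sample(aami_classes(), beats_per_patient, replace = TRUE,
                       prob = class_probs)
      beats <- lapply(labels, function(cl) {
        pmin(1, pmax(0, templates[[cl]] + stats::rnorm(n, 0, noise_sd)))
      })
      tibble::tibble(
        record_id = sprintf("SYN%03d", p),
        split = if (p <= n_train_patients) "train" else "test",
        r_peak = (seq_len(beats_per_patient) - 1L) * n,
        label = labels,
        samples = beats
      )
    })
  })
  train_classes <- unique(out$label[out$split == "train"])
  missing <- setdiff(aami_classes()[class_probs > 0], train_classes)
  if (length(missing)) {
    warning("classes with positive probability but no training beats: ",
            paste(missing, collapse = ", "))
  }
  out
}
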