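#' Min-max normalize an ECG signal to [0, 1]
#'
#' Rescales a signal affinely so its minimum maps to 0 and maximum to 1.
#' A constant signal has no scale; it is returned as all zeros with a
#' warning rather than an error so that degenerate synthetic inputs do not
#' abort a pipeline.
#'
#' @param signal Non-empty numeric vector.
#' @return Numeric vector of the same length, in [0, 1].
#' @export
#' @examples
#' normalize_signal(c(-1, 0, 1))
normalize_signal <- function(signal) {
  stopifnot(length(signal) > 0, is.numeric(signal))
  rng <- range(signal)
  if (rng[1] == rng[2]) {
    warning("constant signal: returning all zeros")
    return(rep(0, length(signal)))
  }
  (signal - rng[1]) / (rng[2] - rng[1])
}

#' Resample a heartbeat segment to a fixed length
#'
#' Resamples a segment onto \code{target_len} equally spaced points spanning
#' the whole segment.  The default is linear interpolation (deterministic,
#' endpoint-preserving); \code{method = "fourier"} uses spectral
#' zero-padding/truncation instead.
#'
#' @param segment Numeric vector of length >= 2.
#' @param target_len Output length (default 280 samples).
#' @param method \code{"linear"} or \code{"fourier"}.
#' @return Numeric vector of length \code{target_len}.
#' @export
#' @examples
#' resize_beat(seq(0, 1, length.out = 140)) |> length()
resize_beat <- function(segment, target_len = 280L, method = c("linear", "fourier")) {
  method <- match.arg(method)
  n <- length(segment)
  if (n < 2L) stop("segment must have at least 2 samples")
  if (n == target_len && method == "linear") return(segment)
  if (method == "linear") {
    stats::approx(seq(0, 1, length.out = n), segment,
                  xout = seq(0, 1, length.out = target_len))$y
  } else {
    sp <- stats::fft(segment)
    half <- n %/% 2L
    out <- complex(target_len)
    keep <- min(half, target_len %/% 2L)
    out[seq_len(keep + 1L)] <- sp[seq_len(keep + 1L)]
    if (keep > 0L) out[target_len - seq_len(keep) + 1L] <- sp[n - seq_len(keep) + 1L]
    Re(stats::fft(out, inverse = TRUE)) / n
  }
}

#' Extract fixed-length labeled heartbeats from an ECG record
#'
#' Implements the standard inter-patient preprocessing: (1) the whole-record
#' signal is min-max normalized to [0, 1]; (2) R-peak locations are taken
#' from the annotation file (no detection is run); (3) the signal is
#' segmented into beats; (4) each beat is resampled to a fixed length of 280
#' samples.  Beat labels come from [aami_class()]; non-beat annotations are
#' skipped.  No filtering or denoising is applied.
#'
#' With the default \code{segmentation = "rr"} each beat spans from its
#' R-peak annotation to the next R-peak, so the record's final annotated
#' beat (which has no following R-peak) is dropped.  With
#' \code{segmentation = "window"} a fixed window of \code{pre} samples
#' before and \code{post} samples after the R-peak is cut instead, and
#' beats whose window exceeds the record boundary are dropped.
#'
#' @param record An \code{ecg_record} from [read_wfdb_record()].
#' @param target_len Fixed beat length (default 280).
#' @param segmentation \code{"rr"} (R-to-next-R, default) or \code{"window"}.
#' @param pre,post Window half-widths in samples, used when
#'   \code{segmentation = "window"}.
#' @param resize_method Passed to [resize_beat()].
#' @return A tibble with one row per extracted beat: \code{record_id},
#'   \code{r_peak} (0-based sample index), \code{label} (AAMI class) and a
#'   list-column \code{samples} of length-\code{target_len} vectors in [0,1].
#' @export
extract_beats <- function(record, target_len = 280L,
                          segmentation = c("rr", "window"),
                          pre = 90L, post = 110L,
                          resize_method = "linear") {
  stopifnot(inherits(record, "ecg_record"))
  segmentation <- match.arg(segmentation)
  ann <- record$annotations
  cls <- aami_class(ann$symbol)
  beat_ann <- ann[!is.na(cls), , drop = FALSE]
  beat_cls <- cls[!is.na(cls)]
  if (nrow(beat_ann) < 2L) {
    warning("record ", record$record_id, ": fewer than 2 beat annotations")
    return(empty_beats(target_len))
  }
  x <- normalize_signal(record$signal)
  n <- length(x)
  r <- beat_ann$sample # 0-based
  if (segmentation == "rr") {
    starts <- r[-length(r)]
    ends <- r[-1L] - 1L
    labels <- beat_cls[-length(r)]
    peaks <- starts
  } else {
    starts <- r - pre
    ends <- r + post - 1L
    labels <- beat_cls
    peaks <- r
  }
  ok <- starts >= 0L & ends < n & (ends - starts + 1L) >= 2L
  segs <- purrr::map2(starts[ok], ends[ok], function(s, e) {
    resize_beat(x[(s:e) + 1L], target_len, method = resize_method)
  })
  tibble::tibble(
    record_id = record$record_id,
    r_peak = as.integer(peaks[ok]),
    label = labels[ok],
    samples = segs
  )
}

empty_beats <- function(target_len = 280L) {
  tibble::tibble(record_id = character(), r_peak = integer(),
                 label = character(), samples = list())
}

#' Stack a beats tibble into an n x 280 matrix
#'
#' @param beats A beats tibble (rows with a \code{samples} list-column).
#' @return Numeric matrix, one beat per row.
#' @export
beat_matrix <- function(beats) {
  if (nrow(beats) == 0L) return(matrix(numeric(0), 0, 0))
  do.call(rbind, beats$samples)
}

#' Group consecutive beats into fixed-length sequences
#'
#' Beats of each record are taken in temporal (R-peak) order and cut into
#' consecutive non-overlapping windows of \code{seq_len} beats — the input
#' unit of the sequence-to-sequence classifier.  A final short window is
#' padded to full length with PAD positions (\code{label = NA}, zero
#' samples); PAD positions are masked out of the training loss and excluded
#' from evaluation.
#'
#' @param beats A beats tibble from [extract_beats()] or [synth_beats()].
#' @param seq_len Beats per sequence (default 10).
#' @return A tibble in long form with one row per sequence position:
#'   \code{record_id}, \code{sequence}, \code{position}, \code{label}
#'   (\code{NA} for PAD) and \code{samples}.
#' @export
beats_to_sequences <- function(beats, seq_len = 10L) {
  stopifnot(seq_len >= 1L)
  if (nrow(beats) == 0L) {
    return(tibble::tibble(record_id = character(), sequence = integer(),
                          position = integer(), label = character(),
                          pad = logical(), samples = list()))
  }
  target_len <- length(beats$samples[[1L]])
  pad_samples <- rep(0, target_len)
  beats |>
    dplyr::arrange(.data$record_id, .data$r_peak) |>
    dplyr::group_by(.data$record_id) |>
    dplyr::group_modify(function(df, key) {
      n <- nrow(df)
      n_seq <- ceiling(n / seq_len)
      n_pad <- n_seq * seq_len - n
      tibble::tibble(
        sequence = rep(seq_len(n_seq), each = seq_len),
        position = rep(seq_len(seq_len), times = n_seq),
        label = c(df$label, rep(NA_character_, n_pad)),
        pad = rep(c(FALSE, TRUE), c(n, n_pad)),
        samples = c(df$samples, rep(list(pad_samples), n_pad))
      )
    }) |>
    dplyr::ungroup()
}

#' Count extracted beats per AAMI class
#'
#' @param beats A beats tibble.
#' @return A tibble with one row per AAMI class (all five classes always
#'   present) and the beat count \code{n}.
#' @export
count_beats_by_class <- function(beats) {
  cls <- factor(beats$label, levels = aami_classes())
  tibble::tibble(class = aami_classes(), n = as.integer(table(cls)))
}

#' Extract beats for every record of an inter-patient split
#'
#' Reads each WFDB record of the named split from a database directory and
#' extracts its beats.  Records are processed in the split's order but the
#' result is order-invariant at the class-count level.
#'
#' @param db_dir Directory holding the WFDB files.
#' @param split Split name (see [aami_split()]) or a character vector of
#'   record ids.
#' @param ... Passed to [extract_beats()].
#' @inheritParams read_wfdb_record
#' @return A beats tibble covering all records of the split.
#' @export
extract_split_beats <- function(db_dir, split, lead = "MLII",
                                fallback_lead = NULL, ...) {
  ids <- if (length(split) == 1L && split %in% names(.split_records)) {
    aami_split(split)$record_id
  } else as.character(split)
  purrr::map_dfr(ids, function(id) {
    rec <- tryCatch(
      read_wfdb_record(file.path(db_dir, id), lead = lead,
                       fallback_lead = fallback_lead),
      error = function(e) stop("record ", id, ": ", conditionMessage(e), call. = FALSE)
    )
    extract_beats(rec, ...)
  })
}

#' Check class-S beat counts of a local MIT-BIH copy
#'
#' Extracts beats for the DS1_3 and DS2 splits from a local copy of the
#' MIT-BIH arrhythmia database and compares the class-S (supraventricular
#' ectopic) beat counts with the published reference counts for this
#' preprocessing (941 for DS1_3, 1836 for DS2).  This requires the database
#' on disk; it is an optional integration check, not part of the unit tests.
#'
#' @param db_dir Directory with the MIT-BIH WFDB files.
#' @return A tibble with columns \code{split}, \code{class}, \code{n} and
#'   \code{reference}.
#' @export
validate_mitbih_counts <- function(db_dir) {
  ref <- tibble::tibble(split = c("DS1_3", "DS2"), reference = c(941L, 1836L))
  counts <- purrr::map_dfr(ref$split, function(s) {
    b <- extract_split_beats(db_dir, s)
    dplyr::mutate(dplyr::filter(count_beats_by_class(b), .data$class == "S"),
                  split = s, .before = 1L)
  })
  dplyr::left_join(counts, ref, by = "split")
}

#' Write / read a beat cache
#'
#' Persists a beats tibble as a plain CSV (one row per beat, sample columns
#' \code{s001}..\code{s280}) plus a JSON sidecar recording the preprocessing
#' configuration, and reads it back.
#'
#' @param beats A beats tibble.
#' @param path Output CSV path; the sidecar is \code{<path>.json}.
#' @param config Optional named list stored in the sidecar.
#' @return \code{write_beat_cache()} returns \code{path} invisibly;
#'   \code{read_beat_cache()} returns the beats tibble.
#' @export
write_beat_cache <- function(beats, path, config = list()) {
  m <- beat_matrix(beats)
  colnames(m) <- sprintf("s%03d", seq_len(ncol(m)))
  wide <- dplyr::bind_cols(
    beats[setdiff(names(beats), "samples")],
    tibble::as_tibble(m)
  )
  readr::write_csv(wide, path)
  sidecar <- c(list(n_beats = nrow(beats), target_len = ncol(m),
                    classes = aami_classes()), config)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_beat_cache
#' @export
read_beat_cache <- function(path) {
  wide <- readr::read_csv(path, show_col_types = FALSE)
  scols <- grep("^s\\d+$", names(wide), value = TRUE)
  m <- as.matrix(wide[scols])
  meta <- wide[setdiff(names(wide), scols)]
  dplyr::mutate(tibble::as_tibble(meta),
                samples = lapply(seq_len(nrow(m)), function(i) unname(m[i, ])))
}
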