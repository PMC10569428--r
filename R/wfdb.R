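# Minimal WFDB support: enough of the PhysioNet format family to read
# MIT-BIH arrhythmia records (header + format 212/16 signals + MIT-format
# annotations) and to write small records for round-trip testing.  Only the
# features those records use are implemented.

# annotation code <-> mnemonic (WFDB ecgcodes)
.wfdb_ann_codes <- c(
  "N", "L", "R", "a", "V", "F", "J", "A", "S", "E", "j", "/", "Q", "~",
  NA, "|", NA, "s", "T", "*", "D", "\"", "=", "p", "B", "^", "t", "+",
  "u", "?", "!", "[", "]", "e", "n", "@", "x", "f", "(", ")", "r"
)

.ann_code_of <- function(symbol) {
  code <- match(symbol, .wfdb_ann_codes)
  if (anyNA(code)) stop("unknown annotation symbol: ",
                        paste(symbol[is.na(code)], collapse = ", "))
  code
}

parse_hea <- function(hea_path) {
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  rec <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  n_sig <- as.integer(rec[2L])
  fs <- if (length(rec) >= 3L) as.numeric(sub("/.*", "", rec[3L])) else 250
  n_samp <- if (length(rec) >= 4L) as.integer(rec[4L]) else NA_integer_
  sig <- lapply(seq_len(n_sig), function(i) {
    f <- strsplit(trimws(lines[1L + i]), "\\s+")[[1L]]
    gain_field <- f[3L]
    baseline <- if (grepl("\\(", gain_field)) {
      as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gain_field))
    } else NA_real_
    gain <- as.numeric(sub("\\(.*", "", sub("/.*", "", gain_field)))
    if (is.na(gain) || gain == 0) gain <- 200
    adc_zero <- if (length(f) >= 5L) as.numeric(f[5L]) else 0
    list(
      file = f[1L],
      format = as.integer(sub("x.*|:.*|\\+.*", "", f[2L])),
      gain = gain,
      baseline = if (is.na(baseline)) adc_zero else baseline,
      description = if (length(f) >= 9L) paste(f[-(1:8)], collapse = " ") else paste0("sig", i)
    )
  })
  list(record = rec[1L], n_sig = n_sig, fs = fs, n_samp = n_samp, signals = sig)
}

# decode `212`-packed bytes: 3 bytes -> two signed 12-bit samples
decode_fmt212 <- function(raw_bytes, n_values) {
  b <- as.integer(raw_bytes)
  n_tri <- length(b) %/% 3L
  b1 <- b[seq(1L, by = 3L, length.out = n_tri)]
  b2 <- b[seq(2L, by = 3L, length.out = n_tri)]
  b3 <- b[seq(3L, by = 3L, length.out = n_tri)]
  s1 <- bitwAnd(b2, 0x0FL) * 256L + b1
  s2 <- bitwAnd(b2, 0xF0L) * 16L + b3
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
  s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
  out <- numeric(2L * n_tri)
  out[c(TRUE, FALSE)] <- s1
  out[c(FALSE, TRUE)] <- s2
  out[seq_len(n_values)]
}

encode_fmt212 <- function(adc) {
  if (length(adc) %% 2L == 1L) adc <- c(adc, 0L)
  adc <- as.integer(adc)
  adc <- ifelse(adc < 0L, adc + 4096L, adc)
  s1 <- adc[c(TRUE, FALSE)]
  s2 <- adc[c(FALSE, TRUE)]
  tri <- rbind(
    bitwAnd(s1, 0xFFL),
    bitwAnd(s1 %/% 256L, 0x0FL) + bitwAnd(s2 %/% 256L, 0x0FL) * 16L,
    bitwAnd(s2, 0xFFL)
  )
  as.raw(as.vector(tri))
}

read_signal_file <- function(path, fmt, n_sig, n_samp) {
  nbytes <- file.size(path)
  raw_bytes <- readBin(path, "raw", n = nbytes)
  if (fmt == 212L) {
    vals <- decode_fmt212(raw_bytes, n_values = 2L * (length(raw_bytes) %/% 3L))
  } else if (fmt == 16L) {
    vals <- readBin(raw_bytes, "integer", n = length(raw_bytes) %/% 2L,
                    size = 2L, signed = TRUE, endian = "little")
  } else stop("unsupported WFDB signal format: ", fmt)
  n_frames <- length(vals) %/% n_sig
  if (!is.na(n_samp)) n_frames <- min(n_frames, n_samp)
  m <- matrix(vals[seq_len(n_frames * n_sig)], nrow = n_sig)
  t(m)
}

#' Read a WFDB record
#'
#' Reads a PhysioNet WFDB record (header \code{.hea}, signal \code{.dat} in
#' format 212 or 16, and an optional MIT-format annotation file, by default
#' \code{.atr}).  One lead is selected by its signal description; MIT-BIH
#' arrhythmia records carry the modified limb lead II as \code{"MLII"}.
#' Annotation sample indices are 0-based positions into the signal vector.
#'
#' @param path Path to the record, with or without the \code{.hea} extension.
#' @param lead Signal description of the lead to extract (default
#'   \code{"MLII"}).
#' @param fallback_lead Optional description to fall back to when `lead` is
#'   absent; set to \code{NA} to accept the first signal.
#' @param annotator Annotation file extension (default \code{"atr"}); set to
#'   \code{NULL} to skip annotations.
#' @return An object of class \code{ecg_record}: a list with
#'   \code{record_id}, \code{signal} (numeric, physical units),
#'   \code{sampling_rate}, \code{lead}, and \code{annotations} (a tibble with
#'   0-based \code{sample} and \code{symbol}).
#' @export
read_wfdb_record <- function(path, lead = "MLII", fallback_lead = NULL,
                             annotator = "atr") {
  hea_path <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea_path)) stop("WFDB header not found: ", hea_path)
  hd <- parse_hea(hea_path)
  descs <- vapply(hd$signals, `[[`, character(1), "description")
  idx <- match(lead, descs)
  if (is.na(idx) && !is.null(fallback_lead)) {
    idx <- if (isTRUE(is.na(fallback_lead))) 1L else match(fallback_lead, descs)
  }
  if (is.na(idx)) {
    stop("record ", hd$record, " has no lead '", lead, "' (available: ",
         paste(descs, collapse = ", "), ") and no usable fallback")
  }
  dat_path <- file.path(dirname(hea_path), hd$signals[[idx]]$file)
  if (!file.exists(dat_path)) stop("WFDB signal file not found: ", dat_path)
  adc <- read_signal_file(dat_path, hd$signals[[idx]]$format, hd$n_sig, hd$n_samp)[, idx]
  sig <- (adc - hd$signals[[idx]]$baseline) / hd$signals[[idx]]$gain
  ann <- NULL
  if (!is.null(annotator)) {
    ann_path <- file.path(dirname(hea_path), paste0(hd$record, ".", annotator))
    if (file.exists(ann_path)) ann <- read_wfdb_annotations(ann_path)
  }
  if (is.null(ann)) {
    ann <- tibble::tibble(sample = integer(), symbol = character())
  }
  structure(
    list(record_id = hd$record, signal = sig, sampling_rate = hd$fs,
         lead = descs[idx], annotations = ann),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat("<ecg_record ", x$record_id, ">  lead ", x$lead, ", ",
      length(x$signal), " samples @ ", x$sampling_rate, " Hz, ",
      nrow(x$annotations), " annotations\n", sep = "")
  invisible(x)
}

#' Read a MIT-format WFDB annotation file
#'
#' @param path Path to the annotation file (e.g. \code{100.atr}).
#' @return A tibble with 0-based \code{sample} indices and annotation
#'   \code{symbol}s, in increasing sample order.
#' @export
read_wfdb_annotations <- function(path) {
  b <- as.integer(readBin(path, "raw", n = file.size(path)))
  i <- 1L
  t_cur <- 0
  samples <- integer(0)
  symbols <- character(0)
  while (i + 1L <= length(b)) {
    low <- b[i]; high <- b[i + 1L]
    code <- high %/% 4L
    interval <- bitwAnd(high, 3L) * 256L + low
    i <- i + 2L
    if (code == 0L && interval == 0L) break                    # EOF
    if (code == 59L) {                                         # SKIP: 4-byte interval, PDP-11 order
      w1 <- b[i] + b[i + 1L] * 256L
      w2 <- b[i + 2L] + b[i + 3L] * 256L
      t_cur <- t_cur + w1 * 65536 + w2
      i <- i + 4L
    } else if (code %in% c(60L, 61L, 62L)) {                   # NUM / SUB / CHN
      next
    } else if (code == 63L) {                                  # AUX: skip payload
      i <- i + interval + interval %% 2L
    } else {
      t_cur <- t_cur + interval
      samples <- c(samples, t_cur)
      symbols <- c(symbols, .wfdb_ann_codes[code])
    }
  }
  tibble::tibble(sample = as.integer(samples), symbol = symbols)
}

#' Write a WFDB record
#'
#' Writes a record in WFDB format 212 with an MIT-format annotation file.
#' Intended for building small test records and synthetic databases; the
#' amplitude resolution is the MIT-BIH convention (gain 200 adu/mV, baseline
#' 1024, 11-bit ADC).
#'
#' @param dir Output directory.
#' @param record_id Record name.
#' @param signals Named list of equal-length numeric vectors (physical
#'   units); names become the lead descriptions.
#' @param fs Sampling rate in Hz.
#' @param annotations Optional tibble/data.frame with 0-based \code{sample}
#'   and \code{symbol}, in increasing sample order.
#' @return The record path (without extension), invisibly.
#' @export
write_wfdb_record <- function(dir, record_id, signals, fs = 360,
                              annotations = NULL) {
  stopifnot(is.list(signals), length(signals) >= 1L)
  n <- unique(lengths(signals))
  stopifnot(length(n) == 1L)
  gain <- 200; baseline <- 1024
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dat_name <- paste0(record_id, ".dat")
  adc <- vapply(signals, function(s) {
    pmin(2047L, pmax(-2048L, as.integer(round(s * gain + baseline))))
  }, integer(n))
  frames <- as.vector(t(adc)) # interleave: one sample per signal per frame
  writeBin(encode_fmt212(frames), file.path(dir, dat_name))
  hea <- c(
    paste(record_id, length(signals), fs, n),
    vapply(seq_along(signals), function(i) {
      paste(dat_name, 212, paste0(gain, "(", baseline, ")/mV"), 11, baseline,
            0, 0, 0, names(signals)[i])
    }, character(1))
  )
  writeLines(hea, file.path(dir, paste0(record_id, ".hea")))
  if (!is.null(annotations) && nrow(annotations) > 0L) {
    stopifnot(!is.unsorted(annotations$sample))
    codes <- .ann_code_of(annotations$symbol)
    intervals <- diff(c(0L, as.integer(annotations$sample)))
    bytes <- integer(0)
    for (k in seq_along(codes)) {
      iv <- intervals[k]
      if (iv > 1023L) { # emit a SKIP word + 4-byte PDP-11 interval
        bytes <- c(bytes, 0L, 59L * 4L,
                   iv %/% 65536L %% 256L, iv %/% 16777216L,
                   iv %% 256L, iv %/% 256L %% 256L)
        iv <- 0L
      }
      bytes <- c(bytes, bitwAnd(iv, 255L), codes[k] * 4L + iv %/% 256L)
    }
    bytes <- c(bytes, 0L, 0L)
    writeBin(as.raw(bytes), file.path(dir, paste0(record_id, ".atr")))
  }
  invisible(file.path(dir, record_id))
}
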