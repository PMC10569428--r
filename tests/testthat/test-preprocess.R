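# Heartbeat extraction pipeline: normalization, AAMI mapping, segmentation,
# resampling, sequence construction and the inter-patient splits.

test_that("normalize_signal rescales affinely onto [0, 1]", {
  expect_equal(normalize_signal(c(-1, 0, 1)), c(0, 0.5, 1))
  expect_warning(z <- normalize_signal(c(5, 5, 5)), "constant")
  expect_equal(z, c(0, 0, 0))
  set.seed(1)
  for (i in 1:10) {
    y <- normalize_signal(rnorm(50))
    expect_equal(range(y), c(0, 1))
  }
})

test_that("AAMI symbol mapping follows EC57 and skips non-beat codes", {
  expect_equal(aami_class(c("A", "a", "J", "S")), rep("S", 4))
  expect_equal(aami_class(c("V", "E")), rep("V", 2))
  expect_equal(aami_class(c("N", "L", "R", "e", "j")), rep("N", 5))
  expect_equal(aami_class("F"), "F")
  expect_equal(aami_class(c("/", "f", "Q")), rep("Q", 3))
  expect_true(all(is.na(aami_class(c("+", "~", "|", "[", "]", "x")))))
})

test_that("resize_beat is identity at native length and exact on ramps", {
  x <- rnorm(280)
  expect_identical(resize_beat(x), x)
  ramp <- seq(2, 5, length.out = 140)
  out <- resize_beat(ramp, 280L)
  expect_equal(out, seq(2, 5, length.out = 280))
  expect_equal(out[c(1, 280)], c(2, 5)) # endpoints preserved
  expect_error(resize_beat(3), "at least 2")
})

test_that("linear resampling matches an independently evaluated interpolant", {
  # independent oracle: evaluate the piecewise-linear interpolant by hand
  n <- 300L
  seg <- sin(seq(0, 3 * pi, length.out = n))
  target <- 280L
  xout <- seq(0, 1, length.out = target)
  xin <- seq(0, 1, length.out = n)
  manual <- vapply(xout, function(x) {
    i <- min(max(findInterval(x, xin), 1L), n - 1L)
    w <- (x - xin[i]) / (xin[i + 1] - xin[i])
    (1 - w) * seg[i] + w * seg[i + 1]
  }, numeric(1))
  expect_equal(resize_beat(seg, target), manual, tolerance = 1e-12)
})

test_that("inter-patient splits match the published record lists", {
  ds1 <- aami_split("DS1")$record_id
  ds2 <- aami_split("DS2")$record_id
  ds1_2 <- aami_split("DS1_2")$record_id
  ds1_3 <- aami_split("DS1_3")$record_id
  expect_length(ds1, 22L)
  expect_length(ds2, 22L)
  expect_equal(ds1_3, c("124", "201", "203", "205", "207", "208", "209",
                        "215", "220", "223", "230"))
  expect_equal(ds2[1:3], c("100", "103", "105"))
  expect_setequal(c(ds1_2, ds1_3), ds1)           # DS1_2 u DS1_3 = DS1
  expect_length(intersect(ds1_2, ds1_3), 0L)
  expect_length(intersect(ds1, ds2), 0L)          # patient-disjoint
  expect_error(aami_split("DS9"))
})

test_that("extract_beats segments R-to-next-R, labels and bounds each beat", {
  dir <- withr::local_tempdir()
  peaks <- c(100L, 420L, 700L, 1050L, 1400L)
  ann <- tibble::tibble(sample = peaks, symbol = c("N", "V", "A", "N", "F"))
  sig <- sin(seq(0, 30, length.out = 1800))
  write_wfdb_record(dir, "seg", signals = list(MLII = sig), fs = 360,
                    annotations = ann)
  rec <- read_wfdb_record(file.path(dir, "seg"))
  beats <- extract_beats(rec)
  # last annotated beat has no following R-peak and is dropped
  expect_equal(nrow(beats), 4L)
  expect_equal(beats$label, c("N", "V", "S", "N"))
  expect_equal(beats$r_peak, peaks[1:4])
  expect_true(all(lengths(beats$samples) == 280L))
  rng <- range(unlist(beats$samples))
  expect_gte(rng[1], 0); expect_lte(rng[2], 1)
  # determinism
  expect_identical(extract_beats(rec), beats)
  # fewer than 2 beat annotations -> empty with a warning
  rec2 <- rec; rec2$annotations <- rec$annotations[1, ]
  expect_warning(e <- extract_beats(rec2), "fewer than 2")
  expect_equal(nrow(e), 0L)
})

test_that("non-beat annotations are skipped, not segmented", {
  dir <- withr::local_tempdir()
  ann <- tibble::tibble(sample = c(100L, 300L, 500L, 800L),
                        symbol = c("N", "+", "N", "N"))
  write_wfdb_record(dir, "rhy", signals = list(MLII = cos(1:1200 / 40)),
                    fs = 360, annotations = ann)
  beats <- extract_beats(read_wfdb_record(file.path(dir, "rhy")))
  # the rhythm change at 300 is ignored: segments are 100->500 and 500->800
  expect_equal(beats$r_peak, c(100L, 500L))
})

test_that("fixed-window segmentation drops beats crossing record edges", {
  dir <- withr::local_tempdir()
  ann <- tibble::tibble(sample = c(50L, 400L, 930L), symbol = c("N", "N", "N"))
  write_wfdb_record(dir, "win", signals = list(MLII = sin(1:1000 / 30)),
                    fs = 360, annotations = ann)
  rec <- read_wfdb_record(file.path(dir, "win"))
  beats <- extract_beats(rec, segmentation = "window", pre = 90L, post = 110L)
  # first peak (50 < pre) and last (930 + 110 > 1000) fall outside
  expect_equal(beats$r_peak, 400L)
})

test_that("sequence construction pads the final window and conserves beats", {
  d <- suppressWarnings(synth_beats(n_train_patients = 1, n_test_patients = 0,
                                    beats_per_patient = 10, seed = 3))
  s3 <- beats_to_sequences(d, 3L)
  expect_equal(max(s3$sequence), 4L)
  expect_equal(nrow(s3), 12L)
  expect_equal(sum(!s3$pad), 10L)                # conservation
  expect_equal(sum(is.na(s3$label)), 2L)
  expect_true(all(unlist(s3$samples[s3$pad]) == 0))
  s1 <- beats_to_sequences(d, 1L)
  expect_equal(max(s1$sequence), 10L)            # one sequence per beat
  expect_equal(sum(s1$pad), 0L)
})

test_that("class counts partition the beats and ignore record order", {
  dir <- withr::local_tempdir()
  ids <- make_wfdb_db(dir, n_records = 3L, beats_per_record = 15L)
  fwd <- extract_split_beats(dir, ids)
  rev_ <- extract_split_beats(dir, rev(ids))
  expect_equal(count_beats_by_class(fwd), count_beats_by_class(rev_))
  counts <- count_beats_by_class(fwd)
  expect_equal(sum(counts$n), nrow(fwd))
  expect_equal(counts$class, aami_classes())
  empty <- count_beats_by_class(wcapseq:::empty_beats())
  expect_equal(empty$n, rep(0L, 5L))
  expect_error(extract_split_beats(dir, "999"), "999")
})

test_that("the beat cache round-trips through CSV", {
  d <- suppressWarnings(synth_beats(n_train_patients = 1, n_test_patients = 0,
                                    beats_per_patient = 5, seed = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_beat_cache(d, path, config = list(seq_len = 10))
  back <- read_beat_cache(path)
  expect_equal(back$label, d$label)
  expect_equal(back$record_id, d$record_id)
  expect_equal(do.call(rbind, back$samples), do.call(rbind, d$samples),
               tolerance = 1e-12)
  sidecar <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(sidecar$n_beats, 5L)
  expect_equal(sidecar$seq_len, 10L)
})
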