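# Recording containers, CSV/EDF round trips and epoch selection.

test_that("Recording validity rejects malformed inputs", {
  expect_error(Recording(matrix(1:10, 2), fsHz = -1,
                         channelLabels = c("MCx", "STN")), "positive")
  expect_error(Recording(matrix(1:10, 2), 256, c("MCx", "MCx")), "unique")
  m <- matrix(rnorm(512), 2, dimnames = list(c("MCx", "STN"), NULL))
  rec <- Recording(m, 256)
  expect_equal(channelLabels(rec), c("MCx", "STN"))
  expect_equal(durationS(rec), 1)
  expect_error(samples(rec, "GPi"), "unknown channel")
})

test_that("CSV round trip preserves samples and metadata exactly", {
  set.seed(1)
  rec <- Recording(matrix(rnorm(2 * 2560), 2,
                          dimnames = list(c("MCx", "STN"), NULL)),
                   256, subjectId = "S01", groupLabel = "EV", week = 4L)
  f <- withr::local_tempfile(fileext = ".csv")
  writeRecording(rec, f)
  r2 <- readRecording(f)
  expect_equal(samples(r2), samples(rec), tolerance = 0)
  expect_identical(subjectId(r2), "S01")
  expect_identical(groupLabel(r2), "EV")
  expect_identical(week(r2), 4L)
  expect_equal(fsHz(r2), 256)
})

test_that("EDF round trip is exact to the 16-bit quantization step", {
  set.seed(2)
  rec <- Recording(matrix(rnorm(2 * 256 * 5), 2,
                          dimnames = list(c("MCx", "STN"), NULL)),
                   256, subjectId = "S02", groupLabel = "A53T-high", week = 8L)
  f <- withr::local_tempfile(fileext = ".edf")
  writeRecording(rec, f)
  r2 <- readRecording(f)
  step <- max(apply(samples(rec), 1, function(v) diff(range(v)))) / 65535
  expect_lt(max(abs(samples(r2) - samples(rec))), step)
  expect_identical(subjectId(r2), "S02")
  expect_identical(week(r2), 8L)
})

test_that("inconsistent channel lengths and unknown formats are rejected", {
  expect_error(Recording(matrix(1:10, 2), 256, c("MCx", "STN", "X")),
               "one row per channel")
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines("x", f)
  expect_error(readRecording(f), "format")
  # CSV with ragged columns fails at parse time
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,MCx,STN", "0,1,2", "0.1,3"), f2)
  expect_error(suppressWarnings(readRecording(f2)))
})

test_that("epoch selection follows the earliest-window rule on clean data", {
  set.seed(3)
  rec <- Recording(matrix(rnorm(2 * 256 * 120), 2,
                          dimnames = list(c("MCx", "STN"), NULL)), 256)
  es <- selectEpochs(rec, n = 3)
  expect_equal(unname(epochs(es)), cbind(c(0, 30, 60), c(30, 60, 90)))
  # epoching never alters samples; lengths are exact
  eps <- epochSamples(rec, "MCx", es)
  expect_equal(unlist(eps), samples(rec, "MCx")[1:(3 * 30 * 256)])
  expect_equal(sum(lengths(eps)), 3 * 30 * 256)
})

test_that("epochs avoid an injected high-amplitude transient", {
  set.seed(4)
  m <- matrix(rnorm(2 * 256 * 150), 2, dimnames = list(c("MCx", "STN"), NULL))
  idx <- (40 * 256 + 1):(41 * 256)
  m["MCx", idx] <- m["MCx", idx] + 20 * sd(m["MCx", ])
  rec <- Recording(m, 256)
  es <- selectEpochs(rec, n = 3, artifactK = 6)
  expect_equal(nEpochs(es), 3)
  for (i in seq_len(3)) {
    ep <- epochs(es)[i, ]
    expect_true(ep[2] <= 40 || ep[1] >= 41)
  }
})

test_that("epoch selection rejects recordings with too little clean data", {
  set.seed(5)
  rec <- Recording(matrix(rnorm(2 * 256 * 60), 2,
                          dimnames = list(c("MCx", "STN"), NULL)), 256)
  expect_error(selectEpochs(rec, n = 3), "90 s")
  # long enough but saturated with artifacts
  m <- matrix(rnorm(2 * 256 * 120), 2, dimnames = list(c("MCx", "STN"), NULL))
  spikes <- seq(1, ncol(m), by = 256 * 10)
  m[1, spikes] <- 50 * sd(m[1, ])
  expect_error(selectEpochs(Recording(m, 256), n = 3), "clean")
})
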