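test_that("polar_frame validates its invariants", {
  expect_error(polar_frame(matrix(-1, 2, 2), 0.005), class = "octhrombus_validation_error")
  expect_error(polar_frame(matrix(c(1, NA, 1, 1), 2, 2), 0.005),
               class = "octhrombus_validation_error")
  expect_error(polar_frame(matrix(1, 2, 2), 0), class = "octhrombus_validation_error")
  expect_error(polar_frame(matrix(1, 2, 4), 0.005, catheter_offset = 4),
               class = "octhrombus_validation_error")
  fr <- polar_frame(matrix(1, 2, 4), 0.005, catheter_offset = 3)
  expect_identical(dim(fr), c(2L, 4L))
})

test_that("pullback read/write round-trips frames and metadata", {
  tmp <- withr::local_tempdir()
  stack <- file.path(tmp, "pb.tif"); sidecar <- file.path(tmp, "pb.json")
  set.seed(1)
  frames <- lapply(1:3, function(i)
    polar_frame(matrix(sample(0:65535, 6 * 5, replace = TRUE), 6, 5),
                axial_pitch_mm = 0.005, catheter_offset = 2L,
                frame_id = paste0("f", i), patient_id = "P007"))
  write_pullback(frames, stack, sidecar)
  back <- read_pullback(stack, sidecar)
  expect_length(back, 3L)
  for (i in 1:3) {
    expect_identical(back[[i]]$intensity, frames[[i]]$intensity)  # exact ints
    expect_identical(back[[i]]$frame_id, paste0("f", i))          # order kept
    expect_equal(back[[i]]$axial_pitch_mm, 0.005)
    expect_identical(back[[i]]$catheter_offset, 2L)
    expect_identical(back[[i]]$patient_id, "P007")
  }
})

test_that("pullback error contracts: empty stack, missing sidecar keys", {
  tmp <- withr::local_tempdir()
  stack <- file.path(tmp, "empty.tif")
  write_tiff_stack(list(), stack)
  jsonlite::write_json(list(axial_pitch_mm = 0.005, catheter_offset = 0),
                       file.path(tmp, "ok.json"), auto_unbox = TRUE)
  expect_warning(out <- read_pullback(stack, file.path(tmp, "ok.json")), "empty")
  expect_length(out, 0L)

  jsonlite::write_json(list(catheter_offset = 0), file.path(tmp, "bad.json"),
                       auto_unbox = TRUE)
  write_tiff_stack(matrix(1:6, 2, 3), file.path(tmp, "one.tif"))
  expect_error(read_pullback(file.path(tmp, "one.tif"), file.path(tmp, "bad.json")),
               "axial_pitch_mm", class = "octhrombus_config_error")
  jsonlite::write_json(list(axial_pitch_mm = 0.005, catheter_offset = 0,
                            frame_ids = c("a", "b")),
                       file.path(tmp, "ids.json"), auto_unbox = TRUE)
  expect_error(read_pullback(file.path(tmp, "one.tif"), file.path(tmp, "ids.json")),
               class = "octhrombus_format_error")
})

test_that("TIFF codec agrees with an independent reader (tifffile)", {
  tmp <- withr::local_tempdir()
  set.seed(42)
  pages <- list(matrix(sample(0:65535, 7 * 9, replace = TRUE), 7, 9),
                matrix(sample(0:65535, 7 * 9, replace = TRUE), 7, 9))
  path <- file.path(tmp, "x.tif")
  write_tiff_stack(pages, path, bits = 16L)
  py <- c(
    "import sys, tifffile",
    "a = tifffile.imread(sys.argv[1])",
    "print(a.shape[0], a.shape[1], a.shape[2], int(a.sum()), int(a[1, 3, 4]))")
  script <- file.path(tmp, "probe.py")
  writeLines(py, script)
  out <- system2("python", c(script, path), stdout = TRUE)
  vals <- as.numeric(strsplit(out, " ")[[1]])
  expect_equal(vals[1:3], c(2, 7, 9))
  expect_equal(vals[4], sum(pages[[1]]) + sum(pages[[2]]))
  expect_equal(vals[5], pages[[2]][4, 5])

  # and the reverse direction: a tifffile-written stack read by the package
  py2 <- c(
    "import sys, numpy as np, tifffile",
    "a = np.arange(24, dtype=np.uint16).reshape(2, 3, 4) * 7",
    "tifffile.imwrite(sys.argv[1], a, photometric='minisblack', metadata=None)")
  writeLines(py2, script)
  system2("python", c(script, file.path(tmp, "py.tif")))
  back <- read_tiff_stack(file.path(tmp, "py.tif"))
  expect_equal(back[[1]], matrix(0:11 * 7, 3, 4, byrow = TRUE))
  expect_equal(back[[2]], matrix(12:23 * 7, 3, 4, byrow = TRUE))
})

test_that("float TIFF pages round-trip at single precision", {
  tmp <- withr::local_tempdir()
  m <- matrix(runif(40), 5, 8)
  path <- file.path(tmp, "f.tif")
  write_tiff_stack(m, path, bits = 32L)
  back <- read_tiff_stack(path)[[1]]
  expect_equal(back, m, tolerance = 1e-6)
})

test_that("masks: RLE JSON, TIFF, fragments, and dimension contract", {
  fr <- polar_frame(matrix(1, 20, 20), 0.005, frame_id = "fX")
  tmp <- withr::local_tempdir()

  jsonlite::write_json(list(shape = c(20, 20), runs = list()),
                       file.path(tmp, "zero.json"), auto_unbox = TRUE)
  m0 <- read_mask(file.path(tmp, "zero.json"), fr)
  expect_identical(sum(m0$member), 0L)
  expect_identical(m0$n_fragments, 0L)

  # two disjoint blobs of 120 and 80 pixels, via TIFF mask image
  member <- matrix(FALSE, 20, 20)
  member[1:10, 1:12] <- TRUE     # 10 x 12 = 120 px
  member[15:18, 1:20] <- TRUE    #  4 x 20 =  80 px
  write_tiff_stack(matrix(as.integer(member) * 255L, 20, 20),
                   file.path(tmp, "blobs.tif"), bits = 8L)
  m2 <- read_mask(file.path(tmp, "blobs.tif"), fr)
  expect_identical(m2$n_fragments, 2L)
  counts <- tabulate(m2$fragment_labels[m2$fragment_labels > 0], nbins = 2L)
  expect_setequal(counts, c(120L, 80L))
  expect_identical(m2$frame_id, "fX")

  # full-frame mask: member count equals n_alines * n_depth
  mfull <- region_mask(matrix(TRUE, 20, 20))
  expect_identical(sum(mfull$member), 400L)
  expect_identical(mfull$n_fragments, 1L)

  # RLE round-trip through write_mask
  write_mask(m2, file.path(tmp, "blobs.json"))
  m3 <- read_mask(file.path(tmp, "blobs.json"), fr)
  expect_identical(m3$member, m2$member)

  small <- polar_frame(matrix(1, 4, 4), 0.005)
  expect_error(read_mask(file.path(tmp, "blobs.tif"), small),
               class = "octhrombus_format_error")
})

test_that("fragment labelling equals a brute-force flood fill", {
  set.seed(99)
  for (rep in 1:25) {
    nr <- sample(3:64, 1); nc <- sample(3:64, 1)
    member <- matrix(runif(nr * nc) < runif(1, 0.2, 0.7), nr, nc)
    got <- label_fragments(member)
    want <- flood_fill_labels(member)
    # same partition: label matrices must be equal up to renaming; both number
    # fragments by first appearance in row-major-ish order, so compare counts
    # and co-membership.
    expect_identical(got > 0, want > 0)
    expect_identical(max(got), max(want))
    if (max(want) > 0) {
      key_got <- got[member]; key_want <- want[member]
      expect_true(all(tapply(key_got, key_want, function(v) length(unique(v))) == 1L))
      expect_true(all(tapply(key_want, key_got, function(v) length(unique(v))) == 1L))
    }
  }
})

test_that("statistics tables round-trip losslessly", {
  tmp <- withr::local_tempdir()
  path <- file.path(tmp, "t.csv")
  set.seed(3)
  rec <- data.frame(patient_id = sprintf("P%02d", 1:10), channel = "attenuation",
                    statistic = "median", value = rnorm(10) * exp(rnorm(10, 0, 6)),
                    included_pixels = sample.int(1e5, 10),
                    stringsAsFactors = FALSE)
  write_statistics_table(rec, path)
  back <- read_statistics_table(path)
  expect_identical(back$value, rec$value)            # bit-identical doubles
  expect_identical(back$patient_id, rec$patient_id)

  write_statistics_table(rec[1, ], path)
  expect_identical(length(readLines(path)), 2L)      # header + 1 row

  write_statistics_table(rec[0, ], path)
  expect_identical(length(readLines(path)), 1L)      # header only
  expect_identical(nrow(read_statistics_table(path)), 0L)
})

test_that("observer readings table is validated", {
  df <- data.frame(patient_id = "P1", observer_id = "obs1", session = 1L, tas = 4L)
  expect_s3_class(observer_readings(df), "observer_readings")
  expect_error(observer_readings(transform(df, tas = 7L)),
               class = "octhrombus_validation_error")
  expect_error(observer_readings(df[, -4]), class = "octhrombus_validation_error")
})
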