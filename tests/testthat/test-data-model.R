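test_that("valence/arousal scores partition into the four quadrant classes", {
  # quadrant corners
  expect_identical(assign_class(3, 3), 1L)     # LALV
  expect_identical(assign_class(2, 7), 2L)     # HALV
  expect_identical(assign_class(7, 2), 3L)     # LAHV
  expect_identical(assign_class(7, 7), 4L)     # HAHV
  # the 4.5 boundary is "high" on both axes
  expect_identical(assign_class(4.5, 4.5), 4L)
  expect_identical(assign_class(4.5, 1), 3L)
  expect_identical(assign_class(1, 4.5), 2L)
  expect_identical(assign_class(4.4999, 4.4999), 1L)
  # total on the square: every grid point gets exactly one class
  g <- expand.grid(v = seq(1, 9, by = 0.5), a = seq(1, 9, by = 0.5))
  cls <- assign_class(g$v, g$a)
  expect_true(all(cls %in% 1:4))
  expect_identical(cls, as.integer(1 + (g$a >= 4.5) + 2 * (g$v >= 4.5)))
})

test_that("out-of-range scores are rejected naming the axis", {
  expect_error(assign_class(0.5, 5), "valence")
  expect_error(assign_class(5, 9.5), "arousal")
  expect_error(assign_class(NA, 5), "valence")
})

test_that("trial construction enforces the shape and finiteness invariants", {
  expect_error(eeg_trial(matrix(1, 3, 16), 128, c("a", "b")), "3 rows")
  expect_error(eeg_trial(matrix(c(1, NA), 1, 8), 128, "a"), "non-finite")
  expect_error(eeg_trial(matrix(1, 1, 8), -1, "a"), "fs")
  tr <- eeg_trial(matrix(rnorm(64), 4), 128, letters[1:4])
  expect_identical(rownames(tr$data), letters[1:4])
})

test_that("a recording set round-trips through the canonical layout", {
  dir <- withr::local_tempdir()
  rs <- generate_dataset(2, 3, seed = 5, n_samples = 256, balanced = FALSE)
  expect_length(rs$trials, 6)
  expect_identical(nrow(rs$labels), 6L)
  write_recording_set(rs, dir)
  rs2 <- read_recording_set(dir)
  expect_identical(length(rs2$trials), length(rs$trials))
  expect_identical(rs2$labels$class_id, rs$labels$class_id)
  expect_identical(rs2$channel_names, deap_channels())
  for (i in seq_along(rs$trials)) {
    expect_equal(rs2$trials[[i]]$data, rs$trials[[i]]$data,
                 tolerance = 1e-9)
  }
  # write -> read -> write is byte-stable (idempotent on storage)
  dir2 <- withr::local_tempdir()
  write_recording_set(rs2, dir2)
  f1 <- file.path(dir, "trials", list.files(file.path(dir, "trials")))
  f2 <- file.path(dir2, "trials", list.files(file.path(dir2, "trials")))
  expect_identical(lapply(f1, readLines), lapply(f2, readLines))
})

test_that("loading validates channels, files and label scores", {
  dir <- withr::local_tempdir()
  rs <- generate_dataset(1, 4, seed = 2, n_samples = 256)
  write_recording_set(rs, dir)

  # a trial missing channel Oz fails naming Oz
  f <- file.path(dir, "trials", "s01_t01.csv")
  df <- read.csv(f, check.names = FALSE)
  write.csv(df[df$channel != "Oz", ], f, row.names = FALSE, quote = FALSE)
  expect_error(read_recording_set(dir), "Oz")
  write.csv(df, f, row.names = FALSE, quote = FALSE)

  # a missing trial file names the trial
  file.remove(file.path(dir, "trials", "s01_t03.csv"))
  expect_error(read_recording_set(dir), "s01/t03")

  # invalid label scores are dropped with a message stating the count
  labs <- read.csv(file.path(dir, "labels.csv"))
  labs$valence[2] <- 12
  labs <- labs[labs$trial_id != "t03", ]
  write.csv(labs, file.path(dir, "labels.csv"), row.names = FALSE)
  expect_message(rs2 <- read_recording_set(dir), "1 label row")
  expect_length(rs2$trials, 2)
})

test_that("input channel order is permuted to the reference montage order", {
  dir <- withr::local_tempdir()
  rs <- generate_dataset(1, 4, seed = 3, n_samples = 256)
  write_recording_set(rs, dir)
  f <- file.path(dir, "trials", "s01_t01.csv")
  df <- read.csv(f, check.names = FALSE)
  perm <- sample(nrow(df))
  write.csv(df[perm, ], f, row.names = FALSE, quote = FALSE)
  rs2 <- read_recording_set(dir)
  expect_identical(rs2$trials[[1]]$channel_names, deap_channels())
  expect_equal(rs2$trials[[1]]$data, rs$trials[[1]]$data, tolerance = 1e-9)
})

test_that("the DEAP-shaped array adapter drops peripheral channel rows", {
  arr <- array(rnorm(2 * 2 * 40 * 64), c(2, 2, 40, 64))
  lab <- array(runif(2 * 2 * 4, 1, 9), c(2, 2, 4))
  expect_warning(rs <- deap_array_to_recording_set(arr, lab), "peripheral")
  expect_length(rs$trials, 4)
  expect_identical(nrow(rs$trials[[1]]$data), 32L)
  expect_equal(rs$trials[[1]]$data[5, ], arr[1, 1, 5, ])
  expect_error(deap_array_to_recording_set(array(0, c(2, 2, 31, 64)), lab),
               "channel axis")
})
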