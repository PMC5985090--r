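test_that("trial generation is deterministic in (master seed, trial seed)", {
  cfg <- synth_config(seed = 10)
  a <- generate_trial("index", cfg, trial_seed = 3)
  b <- generate_trial("index", cfg, trial_seed = 3)
  expect_identical(a$data, b$data)
  c_ <- generate_trial("index", cfg, trial_seed = 4)
  expect_false(identical(a$data, c_$data))
  d <- generate_trial("index", synth_config(seed = 11), trial_seed = 3)
  expect_false(identical(a$data, d$data))
})

test_that("trial generation does not disturb the global RNG stream", {
  set.seed(99)
  before <- rnorm(3)
  set.seed(99)
  invisible(generate_trial("thumb", synth_config(), 1))
  expect_identical(rnorm(3), before)
})

test_that("band power scales as the squared class gain on noise-free rhythms", {
  cfg <- synth_config(noise_sigma = 0, rhythm_freqs = 10, blink_rate = 0)
  thumb <- generate_trial("thumb", cfg, trial_seed = 2)
  index <- generate_trial("index", cfg, trial_seed = 2)  # same phases
  f_thumb <- extract_features(stream_chunks(thumb)[[5]])
  f_index <- extract_features(stream_chunks(index)[[5]])
  # F3 gains: thumb 1.7 vs index 1.0 -> power ratio 1.7^2
  expect_equal(unname(f_thumb["F3"] / f_index["F3"]), 1.7^2, tolerance = 1e-9)
  # FC5 mirrors it the other way
  expect_equal(unname(f_index["FC5"] / f_thumb["FC5"]), 1.7^2, tolerance = 1e-9)
})

test_that("generated trials satisfy the trial invariants and round-trip", {
  cfg <- synth_preset("category_I", seed = 21)
  tr <- generate_trial("fist", cfg, trial_seed = 1)
  expect_s3_class(tr, "eeg_trial")
  expect_identical(dim(tr$data), c(14L, 1280L))
  expect_true(all(is.finite(tr$data)))
  expect_identical(tr$subject_category, "I")
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial(tr, path)
  back <- read_trial(path)
  expect_equal(back$data, matrix(signif(tr$data, 6), 14,
                                 dimnames = dimnames(tr$data)))
  expect_identical(back$label, "fist")
})

test_that("blink lobes land coherently on the frontal channels only", {
  clean <- synth_preset("category_II", seed = 33)
  blink <- synth_preset("category_I", seed = 33)
  a <- generate_trial("thumb", clean, trial_seed = 9)
  b <- generate_trial("thumb", blink, trial_seed = 9)  # same rhythms/noise
  delta <- b$data - a$data
  expect_gt(max(abs(delta["AF3", ])), 100)         # large frontal lobes
  expect_identical(max(abs(delta["FC5", ])), 0)    # non-blink channel untouched
  expect_equal(delta["AF3", ], delta["F4", ], tolerance = 1e-9)  # coherent lobes
  expect_true(all(delta["AF3", ] >= 0))            # positive half-sine lobes
})

test_that("presets encode the two acquisition regimes", {
  catI <- synth_preset("category_I")
  catII <- synth_preset("category_II")
  expect_gte(catI$blink_rate * catI$trial_seconds, 1)  # >= 1 expected blink/trial
  expect_identical(catII$blink_rate, 0)
  # matched otherwise
  expect_identical(catI$class_gains, catII$class_gains)
  expect_identical(catI$noise_sigma, catII$noise_sigma)
})

test_that("datasets are balanced, labelled, and reproducible", {
  cfg <- synth_config(n_trials_per_class = 2, trial_seconds = 1, seed = 8)
  ds <- generate_dataset(cfg)
  expect_length(ds$trials, 6L)
  expect_identical(ds$labels, rep(movement_classes, each = 2))
  ds2 <- generate_dataset(cfg)
  expect_identical(lapply(ds$trials, `[[`, "data"),
                   lapply(ds2$trials, `[[`, "data"))
  # disjoint seed stream under an offset
  ds3 <- generate_dataset(cfg, trial_seed_offset = 6L)
  expect_false(identical(ds$trials[[1]]$data, ds3$trials[[1]]$data))

  dir <- withr::local_tempdir()
  mf <- write_dataset(ds, dir)
  listed <- read_manifest(mf)
  expect_identical(nrow(listed), 6L)
  expect_identical(listed$label, ds$labels)
  back <- read_trial(listed$path[4])
  expect_identical(back$label, "index")
})

test_that("trial counts scale with the acquisition protocol", {
  cfg <- synth_config(n_trials_per_class = 47, trial_seconds = 0.25, seed = 2)
  ds <- generate_dataset(cfg)
  expect_length(ds$trials, 141L)  # 47 x 3
  expect_identical(unname(table(ds$labels))[1], 47L)
})

test_that("one-over-f noise has the requested scale and a red spectrum", {
  cfg <- synth_config(noise_spectrum = "one_over_f", rhythm_amp = 0,
                      blink_rate = 0, seed = 13)
  tr <- generate_trial("thumb", cfg, 1)
  x <- tr$data["O1", ]
  expect_equal(sd(x), cfg$noise_sigma, tolerance = 0.05)
  spec <- Mod(fft(x))^2
  freqs <- (seq_along(x) - 1) * cfg$fs / length(x)
  low <- mean(spec[freqs > 0.5 & freqs < 5])
  high <- mean(spec[freqs > 40 & freqs < 60])
  expect_gt(low, 5 * high)
})

test_that("default gains separate thumb and fist at F3 with a large effect", {
  cfg <- synth_config(seed = 17)
  trial_f3 <- function(cls, s) {
    tr <- generate_trial(cls, cfg, trial_seed = s)
    mean(vapply(stream_chunks(tr), function(ch) {
      channel_band_power(bandpass_8_30(ch$data["F3", ]))
    }, 0))
  }
  thumb <- vapply(1:100, function(s) trial_f3("thumb", s), 0)
  fist <- vapply(101:200, function(s) trial_f3("fist", s), 0)
  d <- (mean(fist) - mean(thumb)) /
    sqrt((stats::var(fist) + stats::var(thumb)) / 2)
  expect_gt(abs(d), 1)
})

test_that("configurations round-trip through YAML and match shipped presets", {
  cfg <- synth_config(noise_sigma = 9.5, blink_rate = 0.25, seed = 77,
                      class_gains = class_gain_map(2.2, 3.1))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_synth_config(cfg, path)
  back <- read_synth_config(path)
  expect_equal(back$class_gains, cfg$class_gains)
  expect_identical(back$noise_sigma, 9.5)
  expect_identical(back$seed, 77L)
  expect_identical(back$blink_channels, cfg$blink_channels)

  for (name in c("category_I", "category_II")) {
    shipped <- system.file("extdata", paste0(name, ".yaml"),
                           package = "eegdecode")
    expect_true(nzchar(shipped))
    file_cfg <- read_synth_config(shipped)
    code_cfg <- synth_preset(name)
    expect_equal(file_cfg[setdiff(names(file_cfg), "class_gains")],
                 code_cfg[setdiff(names(code_cfg), "class_gains")])
    expect_equal(file_cfg$class_gains, code_cfg$class_gains)
  }
})
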