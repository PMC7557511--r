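test_that("action profiles encode laterality and spectral contrast", {
  left <- make_action_profile("left_smirking", asymmetry = 2.0)
  right <- make_action_profile("right_smirking", asymmetry = 2.0)
  expect_equal(unname(left$gains["F7"] / left$gains["F8"]), 2.0)
  expect_equal(unname(left$gains["FC5"] / left$gains["FC6"]), 2.0)
  # right smirk is the mirror of the left under F7<->F8, FC5<->FC6
  expect_equal(unname(right$gains[c("F8", "F7", "FC6", "FC5")]),
               unname(left$gains[c("F7", "F8", "FC5", "FC6")]))
  expect_equal(right$band_fractions, left$band_fractions)

  # documented contrast rule: brow classes sit 2*(0.15 + contrast) apart (L1)
  for (bc in c(0, 0.15, 0.3)) {
    up <- make_action_profile("raising_brow", band_contrast = bc)
    down <- make_action_profile("furrowing_brow", band_contrast = bc)
    expect_equal(sum(abs(up$band_fractions - down$band_fractions)),
                 2 * (0.15 + bc))
    expect_equal(sum(up$band_fractions), 1)
    expect_equal(sum(down$band_fractions), 1)
  }

  # distinct actions never share a profile at default separation
  profs <- lapply(action_classes(), make_action_profile)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_false(identical(profs[[i]][c("gains", "band_fractions")],
                           profs[[j]][c("gains", "band_fractions")]))
  }
  expect_error(make_action_profile("frowning"), "unknown facial action")
})

test_that("a synthesized trial has the protocol timeline and is seeded", {
  prof <- make_action_profile("left_smirking")
  tr <- synthesize_trial(prof, seed = 11)
  expect_equal(ncol(tr$signal), 3500)  # 3.5 s at 1000 Hz
  expect_equal(nrow(tr$signal), 4)
  expect_equal(nrow(tr$events), 1)
  expect_equal(tr$events$onset_sample, 1001L)   # after 1 s preparation
  expect_equal(tr$events$duration_samples, 1500L)
  expect_identical(tr$signal, synthesize_trial(prof, seed = 11)$signal)
  expect_false(identical(tr$signal, synthesize_trial(prof, seed = 12)$signal))

  silent <- prof
  silent$baseline_rms <- 0
  silent$gains[] <- 0
  expect_true(all(synthesize_trial(silent, seed = 1)$signal == 0))
  expect_error(synthesize_trial(prof, seed = 1.5), "integer")
})

test_that("trial band powers follow the profile's band fractions", {
  prof <- make_action_profile("furrowing_brow", baseline_rms = 0)
  set.seed(21)
  fracs <- replicate(100, {
    ep <- extract_epochs(synthesize_trial(prof, seed = NULL))[[1]]
    # periodogram oracle: band power from spec.pgram, not from the features path
    pg <- spec.pgram(ep$signal["F7", ], taper = 0, plot = FALSE,
                     detrend = FALSE, fast = FALSE)
    f <- pg$freq * 1000
    p <- vapply(list(c(64, 128), c(128, 256), c(256, 500)),
                function(b) sum(pg$spec[f >= b[1] & f < b[2]]), 0)
    p / sum(p)
  })
  expect_equal(rowMeans(fracs), prof$band_fractions, tolerance = 0.05)
})

test_that("the default dataset reproduces the offline protocol counts", {
  fx <- default_features()
  ds <- fx$dataset
  expect_equal(nrow(ds$labels), 240)
  expect_equal(as.integer(table(ds$labels$label)), rep(60L, 4))
  expect_equal(nrow(ds$recording$events), nrow(ds$labels))
  # every event window lies inside the recording
  expect_true(all(ds$labels$onset_sample + ds$labels$duration_samples - 1 <=
                    ncol(ds$recording$signal)))
  # minimal plan
  mini <- synthesize_dataset(session_plan(1, 1), seed = 3)
  expect_equal(nrow(mini$labels), 4)
  expect_error(session_plan(0, 6), ">= 1")
})

test_that("dataset generation is byte-identical under a fixed seed", {
  a <- synthesize_dataset(session_plan(1, 2), seed = 33)
  b <- synthesize_dataset(session_plan(1, 2), seed = 33)
  expect_identical(a$recording$signal, b$recording$signal)
  expect_identical(a$labels, b$labels)
})

test_that("mains interference injection adds exactly one tone", {
  prof <- make_action_profile("raising_brow")
  tr <- synthesize_trial(prof, seed = 5)
  expect_identical(inject_interference(tr, 50, amplitude = 0), tr)
  expect_error(inject_interference(tr, 500, amplitude = 1), "Nyquist")

  # closed-form sinusoid power: on-bin tone of amplitude A over n samples
  # contributes |X_k|^2 = (A n / 2)^2 to the DFT bin at its frequency
  silent <- prof; silent$baseline_rms <- 0; silent$gains[] <- 0
  z <- synthesize_trial(silent, seed = 1)
  amp <- 2.5
  zi <- inject_interference(z, 50, amplitude = amp, seed = 9)
  n <- ncol(zi$signal)
  spec2 <- Mod(fft(zi$signal["F7", ]))^2
  k50 <- 50 * n / 1000 + 1  # 1-based bin index of 50 Hz
  expect_equal(spec2[k50], (amp * n / 2)^2, tolerance = 1e-9)
  # notch filtering knocks the tone down by at least 20 dB
  zn <- apply_notch(zi, 50, q = 30)
  spec2n <- Mod(fft(zn$signal["F7", ]))^2
  expect_gt(10 * log10(spec2[k50] / spec2n[k50]), 20)
})

test_that("downstream accuracy does not decrease with spatial asymmetry", {
  accs <- vapply(c(1.0, 2.0), function(asym) {
    ds <- synthesize_dataset(session_plan(2, 3), seed = 77, asymmetry = asym)
    ft <- build_feature_table(extract_epochs(preprocess_recording(ds$recording)))
    cv <- repeated_kfold(ft$features, ft$labels, k = 4, repeats = 1,
                         seed = 78, config = training_config(max_epochs = 60))
    cv$mean
  }, 0)
  expect_gte(accs[2], accs[1])
})
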