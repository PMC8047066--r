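test_that("rectified EMG area follows its closed forms", {
  expect_equal(emg_area(rep(2.5, 100)), 2.5)
  expect_equal(emg_area(rep(c(2.5, -2.5), 50)), 2.5)
  expect_equal(emg_area(c(3, -4, 0, 5)), 3)
  expect_error(emg_area(numeric(0)), "empty")
})

test_that("rectified EMG area is absolutely homogeneous", {
  set.seed(7)
  for (i in 1:20) {
    x <- rnorm(200)
    c0 <- runif(1, -10, 10)
    expect_equal(emg_area(c0 * x), abs(c0) * emg_area(x), tolerance = 1e-12)
  }
})

test_that("heart-rate features are mean and sample SD", {
  expect_equal(hr_stats(rep(70, 50)), c(hr_average = 70, hr_std = 0))
  expect_equal(hr_stats(c(60, 80))[["hr_average"]], 70)
  expect_equal(hr_stats(c(60, 70, 80))[["hr_std"]], 10)
  expect_error(hr_stats(numeric(0)), "empty")
})

test_that("clean 120-s EEG yields four epochs and no rejections", {
  eeg <- make_eeg(gen = function(ch) rnorm(60000, 0, 10))
  ep <- eeg_preprocess(eeg)
  expect_false(ep$rejected)
  expect_length(ep$epochs, 4)
  expect_length(ep$rejected_channels, 0)
  expect_length(ep$rejected_epochs, 0)
  expect_equal(dim(ep$epochs[[1]]), c(64, 30 * 500))
})

test_that("a trial with over 20% bad channels is rejected, not errored", {
  # 13/64 = 20.3% of channels carry a sustained in-band 400-uV artifact
  # (which survives both the average reference and the 0.1-40 Hz filter)
  bad_gen <- function(nbad) function(ch) {
    x <- rnorm(60000, 0, 10)
    if (ch <= nbad) x <- x + tone(3, 500, 120, 400)
    x - mean(x)
  }
  ep <- eeg_preprocess(make_eeg(gen = bad_gen(13)))
  expect_true(ep$rejected)
  expect_match(ep$reason, "rejected")
  expect_length(ep$epochs, 0)
  # 12/64 = 18.75% is tolerated
  expect_false(eeg_preprocess(make_eeg(gen = bad_gen(12)))$rejected)
})

test_that("a single noisy channel is rejected and interpolated from neighbours", {
  eeg <- make_eeg(gen = function(ch) {
    x <- rnorm(60000, 0, 10)
    if (ch == 5) x <- x + tone(3, 500, 120, 500)   # sustained 500-uV artifact
    x - mean(x)                      # zero offset: baseline correction inert
  })
  ep <- eeg_preprocess(eeg)
  expect_false(ep$rejected)
  expect_equal(ep$rejected_channels, eeg$labels[5])
  # oracle: inverse-distance weights of the 4 nearest good layout neighbours,
  # recomputed here from the shipped layout table
  layout <- read.csv(system.file("extdata", "eeg_layout_64.csv",
                                 package = "mssignal"))
  pos <- as.matrix(layout[match(eeg$labels, layout$label), c("x", "y")])
  d <- sqrt(rowSums((pos - matrix(pos[5, ], 64, 2, byrow = TRUE))^2))
  d[5] <- Inf
  nb <- order(d)[1:4]
  w <- (1 / d[nb]) / sum(1 / d[nb])
  x1 <- ep$epochs[[1]]
  oracle <- as.numeric(t(x1[nb, ]) %*% w)
  expect_equal(as.numeric(x1[5, ]), oracle, tolerance = 1e-9)
})

test_that("preprocessing rejection decisions are idempotent", {
  eeg <- make_eeg(gen = function(ch) rnorm(60000, 0, 12), seed = 8)
  ep <- eeg_preprocess(eeg)
  expect_false(ep$rejected)
  again <- eeg_preprocess(recording(do.call(cbind, ep$epochs), 500,
                                    ep$kept_channels, "EEG"))
  expect_false(again$rejected)
  expect_length(again$rejected_channels, 0)
  expect_length(again$rejected_epochs, 0)
})

test_that("EEG preprocessing validates its inputs", {
  small <- recording(matrix(rnorm(10 * 500), 10), 500, paste0("c", 1:10), "EEG")
  expect_error(eeg_preprocess(small), "64 channels")
  eeg <- make_eeg(dur = 60)
  base <- recording(eeg$samples[, 1:1000], 1000, eeg$labels, "EEG")
  expect_error(eeg_preprocess(eeg, base), "rate")
})

test_that("EEG band shares: alpha tone, white-noise flatness, unit sum", {
  rate <- 500
  mk_epochset <- function(chmat) {
    structure(list(epochs = list(chmat), rate = rate,
                   kept_channels = rownames(chmat),
                   rejected_channels = character(0),
                   rejected_epochs = integer(0), rejected = FALSE,
                   reason = NULL), class = "epoch_set")
  }
  alpha <- t(vapply(1:8, function(ch) tone(10, rate, 30, 20), numeric(15000)))
  sh <- eeg_band_relpower(mk_epochset(alpha))
  expect_gte(sh[["eeg_alpha"]], 0.95)
  expect_equal(sum(sh), 1, tolerance = 1e-9)

  # white noise: shares proportional to bandwidths over a 120-s trial
  set.seed(21)
  eeg <- make_eeg(gen = function(ch) rnorm(60000, 0, 10), seed = 31)
  ep <- structure(list(epochs = lapply(0:3, function(i)
    eeg$samples[, (i * 15000 + 1):((i + 1) * 15000)]),
    rate = rate, kept_channels = eeg$labels,
    rejected_channels = character(0), rejected_epochs = integer(0),
    rejected = FALSE, reason = NULL), class = "epoch_set")
  sh2 <- eeg_band_relpower(ep)
  expect_equal(unname(sh2), c(3.5, 4, 5, 22, 5) / 39.5, tolerance = 0.03)
  rej <- structure(list(epochs = list(), rejected = TRUE,
                        reason = "x"), class = "epoch_set")
  expect_error(eeg_band_relpower(rej), "missing")
})

test_that("extract_features returns 19 named finite values in table order", {
  cc <- coupling_preset("weak", seed = 5)
  m <- generate_measurement(3, protocol_spec("P1"), generate_latent(3, cc), cc)
  fv <- extract_features(m)
  expect_named(fv, feature_names())
  expect_true(all(is.finite(fv)))
  expect_true(all(fv[c("emg_L_area", "emg_R_area", "hr_std")] >= 0))
  expect_equal(sum(fv[1:5]), 1, tolerance = 1e-9)
  expect_equal(sum(fv[8:12]), 1, tolerance = 1e-9)
  expect_equal(sum(fv[13:17]), 1, tolerance = 1e-9)
})

test_that("swapping EMG legs swaps L/R features exactly; scaling doubles areas", {
  cc <- coupling_preset("weak", seed = 6)
  m <- generate_measurement(1, protocol_spec("P3"), generate_latent(1, cc), cc)
  fv <- extract_features(m)
  m2 <- m
  m2$emg <- recording(m$emg$samples[2:1, ], m$emg$rate,
                      m$emg$labels, "EMG")
  fv2 <- extract_features(m2)
  Lf <- grep("^emg_L", feature_names(), value = TRUE)
  Rf <- sub("^emg_L", "emg_R", Lf)
  expect_equal(unname(fv2[Lf]), unname(fv[Rf]))
  expect_equal(unname(fv2[Rf]), unname(fv[Lf]))
  m3 <- m
  m3$emg <- recording(2 * m$emg$samples, m$emg$rate, m$emg$labels, "EMG")
  fv3 <- extract_features(m3)
  expect_equal(fv3[["emg_L_area"]], 2 * fv[["emg_L_area"]], tolerance = 1e-12)
  shares <- grep("^emg_[LR]_[0-9]", feature_names(), value = TRUE)
  expect_equal(fv3[shares], fv[shares], tolerance = 1e-9)
})

test_that("a rejected EEG trial yields missing EEG features, not an error", {
  cc <- coupling_preset("weak", seed = 9)
  m <- generate_measurement(1, protocol_spec("P1"), generate_latent(1, cc), cc)
  bad <- m$eeg$samples
  bad[1:20, 100] <- 5000                     # 20/64 channels over threshold
  m$eeg <- recording(bad, m$eeg$rate, m$eeg$labels, "EEG")
  fv <- extract_features(m)
  expect_true(all(is.na(fv[1:5])))
  expect_true(all(is.finite(fv[6:19])))
})
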