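test_that("peak_centers does the index arithmetic and tie-breaking", {
  # bump peaking at frame 250 of a 700-frame epoch, onset at frame 100, 1 kHz
  w <- matrix(0, 700, 1)
  w[, 1] <- exp(-(seq_len(700) - 250)^2 / (2 * 30^2))
  expect_equal(peak_centers(w, sampling_rate = 1000, t0_index = 100), 150)

  # flat-topped bump: earliest maximal frame wins
  wf <- matrix(0, 20, 1); wf[8:11, 1] <- 1
  expect_equal(peak_centers(wf, sampling_rate = 1000, t0_index = 1), 7)

  expect_error(peak_centers(matrix(0, 10, 1), 1000, 1), "all-zero")
  expect_error(peak_centers(matrix(1, 10, 1)), "required")
})

test_that("planted peaks are recovered within one frame step", {
  gt <- make_ground_truth(seed = 5)              # desk preset, 150/250/450 ms
  x <- generate_trials(gt)
  fit <- scnm3f(x, 3, 2, control = scnm3f_control(n_restarts = 2), seed = 5)
  pk <- sort(peak_centers(fit))
  expect_equal(pk, c(150, 250, 450), tolerance = 10)
})

test_that("window_spec clips to the epoch and rejects empty windows", {
  ws <- window_spec(100, 60, sampling_rate = 250, t0_index = 10, n_time = 80)
  tms <- (ws$indices - 10) / 250 * 1000
  expect_true(all(tms >= 70 & tms <= 130))
  # clipped at the epoch end but non-empty
  edge <- window_spec(275, 60, sampling_rate = 250, t0_index = 10, n_time = 80)
  expect_true(length(edge$indices) >= 1)
  expect_error(window_spec(4000, 60, 250, 10, 80), "intersect")
  expect_error(window_spec(100, -5, 250, 10, 80), "duration")
})

test_that("window_features averages sensors over the window", {
  x <- tiny_tensor(n = 3, tt = 10, s = 4, seed = 91, sampling_rate = 1000,
                   t0_index = 1)
  # 3-frame window: direct averaging oracle
  spec <- window_spec(4, 2, 1000, 1, 10)
  expect_identical(spec$indices, 4:6)
  f <- window_features(x, spec)
  oracle <- t(sapply(1:3, function(n) colMeans(x$data[n, 4:6, ])))
  expect_equal(f, oracle)

  # constant-in-time trials: features equal the constant
  xc <- x
  for (n in 1:3) for (s in 1:4) xc$data[n, , s] <- n + s
  expect_equal(window_features(xc, spec),
               outer(1:3, 1:4, "+"), tolerance = 1e-12)

  # one-frame window returns that frame
  spec1 <- window_spec(7, 0.5, 1000, 1, 10)
  expect_identical(spec1$indices, 8L)
  expect_equal(window_features(x, spec1), x$data[, 8, ])
})

test_that("a planted window/cluster effect is found where it was planted", {
  set.seed(95)
  n <- 80; tt <- 80; s <- 12
  a <- array(rnorm(n * tt * s, sd = 0.5), c(n, tt, s))
  cls <- rep(c("a", "b"), each = 40)
  # class difference only in frames 30:36 (= 80..104 ms) on sensors 1:3
  for (i in which(cls == "b")) a[i, 30:36, 1:3] <- a[i, 30:36, 1:3] + 1.2
  x <- trial_tensor(a, labels = data.frame(trial_id = 1:n, condition = cls),
                    sampling_rate = 250, t0_index = 10)
  res <- sliding_lda(x, contrast = c("a", "b"), centers = c(92, 250),
                     duration = 28)
  expect_gt(res[[1]]$az, 0.9)
  expect_gt(res[[2]]$az, 0.35); expect_lt(res[[2]]$az, 0.65)

  # shuffled labels: both windows near chance
  set.seed(96)
  xs <- x; xs$labels$condition <- sample(cls)
  res0 <- sliding_lda(xs, contrast = c("a", "b"), centers = c(92, 250),
                      duration = 28)
  for (r in res0) { expect_gt(r$az, 0.3); expect_lt(r$az, 0.7) }
})

test_that("a single window is the decoding module applied to window features", {
  gt <- quick_gt(seed = 97)
  x <- generate_trials(gt)
  spec <- window_spec(50, 60, x$sampling_rate, x$t0_index, dim(x)[2])
  cs <- spacebytime:::contrast_split(x, "condition", c("face", "car"))
  direct_az <- roc_auc(loocv_scores(window_features(cs$tensor, spec), cs$y),
                       cs$y)
  via_baseline <- sliding_lda(x, contrast = c("face", "car"), centers = 50,
                              duration = 60)
  expect_equal(via_baseline[[1]]$az, direct_az)
})

test_that("baseline decoding varies more across subjects than coefficient decoding", {
  # six simulated subjects differing in broadband observation noise: windowed
  # sensor features inherit that noise directly, while the tri-factor
  # coefficients pool it over components, so the baseline's Az should spread
  # more from subject to subject (directional check)
  snrs <- c(3, 4, 5, 6, 3.5, 4.5)
  az_coef <- az_base <- numeric(6)
  for (s in 1:6) {
    gt <- make_ground_truth(snr = snrs[s], trials_per_condition = 50,
                            seed = 200 + s)
    x <- generate_trials(gt)
    fit <- scnm3f(x, 3, 2, control = scnm3f_control(n_restarts = 2), seed = s)
    y <- factor(x$labels$condition, levels = c("car", "face"))
    az_coef[s] <- roc_auc(loocv_scores(coef(fit), y), y)
    bl <- sliding_lda(x, contrast = c("car", "face"),
                      centers = peak_centers(fit), duration = 60)
    az_base[s] <- max(vapply(bl, `[[`, numeric(1), "az"))
  }
  expect_gt(var(az_base), var(az_coef))
  expect_gt(mean(az_coef), mean(az_base))
})
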