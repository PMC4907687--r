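make_gauss_features <- function(n_per, mu0, mu1, sigma, seed) {
  set.seed(seed)
  d <- length(mu0)
  x <- rbind(matrix(rnorm(n_per * d, sd = sigma), n_per, d, byrow = TRUE) +
               matrix(mu0, n_per, d, byrow = TRUE),
             matrix(rnorm(n_per * d, sd = sigma), n_per, d, byrow = TRUE) +
               matrix(mu1, n_per, d, byrow = TRUE))
  list(x = x, y = factor(rep(c("neg", "pos"), each = n_per),
                         levels = c("neg", "pos")))
}

test_that("select_coefficients orders columns temporal-major", {
  gt <- quick_gt(seed = 60, p = 3, l = 2)
  x <- generate_trials(gt)
  fit <- scnm3f(x, 3, 2, control = scnm3f_control(n_restarts = 1,
                                                  max_iter = 40), seed = 1)
  f <- select_coefficients(fit, temporal_ids = 3, spatial_ids = c(1, 2))
  expect_identical(colnames(f), c("h[3,1]", "h[3,2]"))
  expect_equal(ncol(f), 2L)
  expect_equal(f[, 1], fit$h[3, 1, ])

  full <- select_coefficients(fit)
  expect_equal(ncol(full), 6L)
  expect_identical(colnames(full)[1:3], c("h[1,1]", "h[1,2]", "h[2,1]"))
  expect_equal(unname(full), unname(coef(fit)), ignore_attr = TRUE)

  single <- select_coefficients(fit, 2, 1)
  expect_equal(ncol(single), 1L)
  expect_error(select_coefficients(fit, integer(0), 1), "empty")
  expect_error(select_coefficients(fit, 9, 1), "1\\.\\.3")
})

test_that("lda_train recovers the closed-form Fisher direction", {
  # d = 1, symmetric classes: positive weight, zero bias
  x1 <- matrix(c(-1.2, -0.8, -1, 0.8, 1.2, 1), ncol = 1)
  y1 <- factor(rep(c("a", "b"), each = 3), levels = c("a", "b"))
  m1 <- lda_train(x1, y1)
  expect_gt(m1$weights, 0)
  expect_equal(m1$bias, 0, tolerance = 1e-10)

  # identical class means (and a singular 2-point-per-class scatter, which
  # must trigger the ridge warning): zero projected separation
  x0 <- rbind(diag(2), diag(2))
  y0 <- factor(rep(c("a", "b"), each = 2))
  expect_warning(m0 <- lda_train(x0, y0), "ridge")
  expect_equal(sum(m0$weights * (colMeans(x0[3:4, ]) - colMeans(x0[1:2, ]))),
               0, tolerance = 1e-10)

  # 2-d Gaussians: weights parallel to solve(Sigma, mu1 - mu0)
  gf <- make_gauss_features(400, c(0, 0), c(1, 0.5), 1, seed = 2)
  m2 <- lda_train(gf$x, gf$y, lambda = 0)
  sw <- spacebytime:::pooled_scatter(gf$x, gf$y)
  ref <- solve(sw$scatter / (nrow(gf$x) - 2), sw$mu2 - sw$mu1)
  expect_equal(m2$weights / sqrt(sum(m2$weights^2)),
               as.numeric(ref / sqrt(sum(ref^2))), tolerance = 1e-6)
})

test_that("fast leave-one-out scores equal the literal per-fold refit", {
  for (seed in 1:5) {
    gf <- make_gauss_features(12, rep(0, 3), rep(0.7, 3), 1, seed = seed)
    fast <- loocv_scores(gf$x, gf$y)
    naive <- spacebytime:::loocv_scores_naive(gf$x, gf$y)
    expect_equal(fast, naive, tolerance = 1e-9)
  }
  # unbalanced classes too
  set.seed(99)
  x <- matrix(rnorm(26 * 2), 26, 2)
  y <- factor(c(rep("a", 9), rep("b", 17)))
  expect_equal(loocv_scores(x, y), spacebytime:::loocv_scores_naive(x, y),
               tolerance = 1e-9)
})

test_that("loocv handles boundary and degenerate cases", {
  # perfectly separated 1-d classes: signs consistent with labels
  x <- matrix(c(-3, -2.5, -2, 2, 2.5, 3), ncol = 1)
  y <- factor(rep(c("a", "b"), each = 3))
  sc <- loocv_scores(x, y)
  expect_true(all(sc[1:3] < 0) && all(sc[4:6] > 0))

  # N = 4 minimal case returns finite scores
  x4 <- matrix(c(0, 1, 2, 3), ncol = 1)
  y4 <- factor(c("a", "a", "b", "b"))
  expect_true(all(is.finite(loocv_scores(x4, y4))))

  expect_error(loocv_scores(x4[1:3, , drop = FALSE], factor(c("a", "a", "b"))),
               ">= 2")
  expect_identical(loocv_scores(x, y), loocv_scores(x, y))  # deterministic
})

test_that("roc_auc matches the worked example and its invariants", {
  sc <- c(0.1, 0.4, 0.35, 0.8)
  y <- factor(c("neg", "neg", "pos", "pos"), levels = c("neg", "pos"))
  expect_equal(roc_auc(sc, y), 0.75)
  expect_equal(roc_auc(rep(1, 4), y), 0.5)               # all ties
  expect_equal(roc_auc(c(1, 2, 3, 4), y), 1.0)           # perfectly ordered

  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(6:30, 1)
    y <- factor(sample(c("neg", "pos"), n, TRUE))
    while (nlevels(droplevels(y)) < 2) y <- factor(sample(c("neg", "pos"), n, TRUE))
    sc <- sample(round(rnorm(n), 1))                     # ties likely
    expect_equal(roc_auc(sc, y), auc_bruteforce(sc, y))
    # complement under score negation (with ties this still holds for midranks)
    expect_equal(roc_auc(sc, y) + roc_auc(-sc, y), 1)
    # invariance under strictly increasing transforms
    expect_equal(roc_auc(exp(2 * sc) + 1, y), roc_auc(sc, y))
  }
  expect_error(roc_auc(1:3, factor(c("a", "a", "a"))), "both classes")
})

test_that("permutation test attains the add-one floor on separable data", {
  gf <- make_gauss_features(20, rep(-3, 2), rep(3, 2), 0.5, seed = 5)
  res <- permutation_test(gf$x, gf$y, n_perm = 200, seed = 1)
  expect_s3_class(res, "decoding_result")
  expect_equal(res$az, 1.0)
  expect_equal(res$p_value, 1 / 201)
  expect_length(res$null_az, 200)
  expect_gte(res$p_value, 1 / (res$n_perm + 1))
})

test_that("null features give chance-level decoding and calm nulls", {
  set.seed(77)
  x <- matrix(rnorm(100 * 4), 100, 4)
  y <- factor(rep(c("a", "b"), 50))
  az <- roc_auc(loocv_scores(x, y), y)
  expect_gt(az, 0.35); expect_lt(az, 0.65)
  res <- permutation_test(x, y, n_perm = 99, seed = 2)
  expect_gt(res$p_value, 0.01)
})

test_that("decode wires contrast, filter and subsets together", {
  gt <- quick_gt(seed = 70)
  x <- generate_trials(gt)
  fit <- scnm3f(x, 2, 2, control = scnm3f_control(n_restarts = 1,
                                                  max_iter = 80), seed = 7)
  dr <- decode(fit, contrast = c("car", "face"), n_perm = 99, seed = 11)
  expect_gt(dr$az, 0.8)
  expect_lte(dr$p_value, 0.05)
  dr0 <- decode(fit, contrast = c("car", "face"), n_perm = 0)
  expect_equal(dr0$az, dr$az)
  expect_true(is.na(dr0$p_value))
  dr1 <- decode(fit, contrast = c("car", "face"), temporal_ids = 1,
                spatial_ids = 2, n_perm = 0)
  expect_identical(dr1$subset_spec$temporal, 1L)
  expect_error(decode(fit, on = "nope", contrast = c("a", "b")), "not found")
})
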