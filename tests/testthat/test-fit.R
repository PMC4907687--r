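test_that("noiseless planted data is recovered at the true dimensions", {
  gt <- quick_gt(seed = 31, sigma_h = 0.4, sigma_m = 0)
  x <- generate_trials(gt)
  fit <- scnm3f(x, 2, 2, control = scnm3f_control(n_restarts = 3), seed = 31)
  expect_lt(fit$rel_error, 0.01)
  mt <- match_components(fit$w_tem, gt$w_tem)
  ms <- match_components(t(fit$w_spa), t(gt$w_spa))
  expect_true(all(mt$r > 0.95))
  expect_true(all(ms$r > 0.95))
})

test_that("full-dimensional factorization reproduces any data nearly exactly", {
  x <- tiny_tensor(n = 3, tt = 5, s = 4, seed = 33)
  fit <- scnm3f(x, 5, 4, control = scnm3f_control(n_restarts = 1,
                                                  max_iter = 300), seed = 1)
  expect_lt(fit$rel_error, 1e-6)
})

test_that("fit invariants hold across seeds", {
  gt <- quick_gt(seed = 40)
  x <- generate_trials(gt)
  for (seed in 1:5) {
    fit <- scnm3f(x, 2, 2, control = scnm3f_control(n_restarts = 1,
                                                    max_iter = 60), seed = seed)
    expect_true(all(fit$w_tem >= 0))
    expect_true(all(fit$w_spa >= 0))
    expect_true(all(colSums(fit$w_tem) > 0))
    expect_true(all(rowSums(fit$w_spa) > 0))
    expect_true(all(is.finite(fit$error_trace)))
    trace <- fit$error_trace
    expect_lte(trace[length(trace)], trace[1])
    # the returned solution is the best iterate seen
    expect_lte(fit$e2, min(trace) + 1e-9)
  }
})

test_that("near-orthogonality emerges from fitting planted data", {
  gt <- quick_gt(seed = 44)
  x <- generate_trials(gt)
  off_diag_mass <- function(w) {
    wn <- sweep(w, 2, sqrt(colSums(w^2)), "/")
    g <- crossprod(wn)
    sum(abs(g[upper.tri(g)]))
  }
  set.seed(44)
  w0 <- matrix(1 - runif(dim(x)[2] * 2), dim(x)[2], 2)
  fit <- scnm3f(x, 2, 2, control = scnm3f_control(n_restarts = 1), seed = 44)
  expect_lt(off_diag_mass(fit$w_tem), off_diag_mass(w0))
  expect_lt(off_diag_mass(fit$w_tem), 0.2)
})

test_that("the error trace equals the literal reconstruction error", {
  gt <- quick_gt(seed = 46)
  x <- generate_trials(gt)
  fit <- scnm3f(x, 2, 2, control = scnm3f_control(n_restarts = 1,
                                                  max_iter = 40), seed = 3)
  lit <- reconstruction_error(x, fit$w_tem, fit$h, fit$w_spa)
  expect_equal(fit$e2, lit$total, tolerance = 1e-10)
})

test_that("restarts are seeded and reproducible", {
  gt <- quick_gt(seed = 47)
  x <- generate_trials(gt)
  f1 <- scnm3f(x, 2, 2, control = scnm3f_control(n_restarts = 2,
                                                 max_iter = 30), seed = 9)
  f2 <- scnm3f(x, 2, 2, control = scnm3f_control(n_restarts = 2,
                                                 max_iter = 30), seed = 9)
  expect_identical(f1$w_tem, f2$w_tem)
  expect_identical(f1$h, f2$h)
  expect_identical(f1$error_trace, f2$error_trace)
})

test_that("normalization option yields unit-norm components without changing the fit", {
  gt <- quick_gt(seed = 48)
  x <- generate_trials(gt)
  fit <- scnm3f(x, 2, 2, seed = 5,
                control = scnm3f_control(n_restarts = 1, max_iter = 50,
                                         normalize = TRUE))
  expect_equal(colSums(fit$w_tem^2), rep(1, 2), tolerance = 1e-12)
  expect_equal(rowSums(fit$w_spa^2), rep(1, 2), tolerance = 1e-12)
  # reconstruction is unchanged by the compensated rescaling
  lit <- reconstruction_error(x, fit$w_tem, fit$h, fit$w_spa)
  expect_equal(lit$total, fit$e2, tolerance = 1e-8)
})

test_that("decoding-based restart selection picks the most discriminative restart", {
  gt <- quick_gt(seed = 49)
  x <- generate_trials(gt)
  fit <- scnm3f(x, 2, 2, seed = 7,
                control = scnm3f_control(n_restarts = 3, max_iter = 40,
                                         restart_selection = "decoding"),
                on = "condition", contrast = c("car", "face"))
  expect_s3_class(fit, "scnm3f")
  expect_error(
    scnm3f(x, 2, 2, seed = 7,
           control = scnm3f_control(restart_selection = "decoding")),
    "needs 'on'")
})

test_that("fit rejects invalid dimensions", {
  x <- tiny_tensor(n = 3, tt = 5, s = 4)
  expect_error(scnm3f(x, 0, 2), "'p'")
  expect_error(scnm3f(x, 2, 9), "'l'")
})

test_that("S3 methods are coherent with the stored factors", {
  gt <- quick_gt(seed = 50)
  x <- generate_trials(gt)
  fit <- scnm3f(x, 2, 2, control = scnm3f_control(n_restarts = 1,
                                                  max_iter = 40), seed = 2)
  expect_output(print(fit), "space-by-time")
  expect_output(print(summary(fit)), "peaks")
  cm <- coef(fit)
  expect_identical(dim(cm), c(dim(x)[1], 4L))
  expect_identical(colnames(cm), c("h[1,1]", "h[1,2]", "h[2,1]", "h[2,2]"))
  expect_equal(unname(cm[7, "h[2,1]"]), fit$h[2, 1, 7])
  res <- residuals(fit)
  expect_equal(res + fitted(fit), x$data, tolerance = 1e-12)
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "trial_tensor")
  expect_identical(dim(sims[[1]]), dim(x))
})
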