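#' Build a feature matrix from selected coefficients
#'
#' Selects the signed per-trial coefficients combining the given temporal and
#' spatial components as decoding features: one column per (temporal,
#' spatial) pair in the Cartesian product of the ids, ordered temporal-major
#' (i outer, j inner).
#'
#' @param decomp an `scnm3f` fit.
#' @param temporal_ids,spatial_ids integer vectors of component ids (defaults:
#'   all components of that type).
#' @return an `N x d` matrix with columns named `h[i,j]` and an attribute
#'   `subset_spec`, a data.frame of the (i, j) pairs.
#' @export
select_coefficients <- function(decomp, temporal_ids = NULL, spatial_ids = NULL) {
  stopifnot(inherits(decomp, "scnm3f"))
  if (is.null(temporal_ids)) temporal_ids <- seq_len(decomp$p)
  if (is.null(spatial_ids)) spatial_ids <- seq_len(decomp$l)
  temporal_ids <- as.integer(temporal_ids); spatial_ids <- as.integer(spatial_ids)
  if (!length(temporal_ids) || !length(spatial_ids))
    stop("empty component selection")
  if (any(temporal_ids < 1L | temporal_ids > decomp$p))
    stop(sprintf("temporal ids must be in 1..%d", decomp$p))
  if (any(spatial_ids < 1L | spatial_ids > decomp$l))
    stop(sprintf("spatial ids must be in 1..%d", decomp$l))
  spec <- expand.grid(spatial = spatial_ids, temporal = temporal_ids,
                      KEEP.OUT.ATTRS = FALSE)[, c("temporal", "spatial")]
  n <- dim(decomp$h)[3L]
  vals <- matrix(NA_real_, n, nrow(spec))
  for (k in seq_len(nrow(spec)))
    vals[, k] <- decomp$h[spec$temporal[k], spec$spatial[k], ]
  colnames(vals) <- paste0("h[", spec$temporal, ",", spec$spatial, "]")
  attr(vals, "subset_spec") <- spec
  vals
}

check_binary <- function(y) {
  y <- as.factor(y)
  y <- droplevels(y)
  if (nlevels(y) != 2L) stop("labels must have exactly two classes")
  if (any(table(y) < 2L)) stop("each class needs >= 2 trials")
  y
}

# pooled within-class ridge, computed once per feature matrix:
# 1e-6 * trace(pooled covariance)/d
default_lambda <- function(x, y) {
  sw <- pooled_scatter(x, y)
  1e-6 * sum(diag(sw$scatter / (nrow(x) - 2))) / ncol(x)
}

pooled_scatter <- function(x, y) {
  idx1 <- which(y == levels(y)[1L]); idx2 <- which(y == levels(y)[2L])
  mu1 <- colMeans(x[idx1, , drop = FALSE])
  mu2 <- colMeans(x[idx2, , drop = FALSE])
  c1 <- sweep(x[idx1, , drop = FALSE], 2L, mu1)
  c2 <- sweep(x[idx2, , drop = FALSE], 2L, mu2)
  list(scatter = crossprod(c1) + crossprod(c2), mu1 = mu1, mu2 = mu2,
       n1 = length(idx1), n2 = length(idx2))
}

#' Train a Fisher linear discriminant
#'
#' Two-class Fisher LDA on a feature matrix: the weight vector is the inverse
#' pooled within-class covariance applied to the difference of class means
#' (second factor level minus first; the second level is the positive class),
#' and the bias places the decision boundary midway between the projected
#' class means. A small ridge (`1e-6 * trace/d` of the pooled covariance by
#' default) keeps the covariance invertible when trial counts are low; if the
#' unregularized covariance is singular, the ridge is applied with a warning.
#'
#' @param x `N x d` numeric feature matrix.
#' @param y two-class factor (or coercible) of length `N`.
#' @param lambda ridge added to the covariance diagonal; `NULL` for the
#'   default.
#' @return list with `weights` (length `d`), `bias`, `lambda` and the class
#'   `levels`; `score(x) = x %*% weights + bias` is positive towards the
#'   second level.
#' @export
lda_train <- function(x, y, lambda = NULL) {
  x <- as.matrix(x)
  y <- check_binary(y)
  sw <- pooled_scatter(x, y)
  cov <- sw$scatter / (nrow(x) - 2)
  if (is.null(lambda)) {
    lambda <- 1e-6 * sum(diag(cov)) / ncol(x)
    if (rcond_safe(cov) < 1e-12)
      warning("singular within-class covariance; ridge regularization applied")
  }
  delta <- sw$mu2 - sw$mu1
  w <- solve(cov + diag(lambda, ncol(x)), delta)
  b <- -sum(w * (sw$mu1 + sw$mu2) / 2)
  list(weights = as.numeric(w), bias = b, lambda = lambda, levels = levels(y))
}

rcond_safe <- function(m) {
  if (nrow(m) == 1L) return(if (m[1L] == 0) 0 else 1)
  tryCatch(rcond(m), error = function(e) 0)
}

#' Score trials with a trained discriminant
#'
#' @param model output of [lda_train()].
#' @param x `N x d` feature matrix.
#' @return numeric scores, positive towards the model's second class level.
#' @export
lda_score <- function(model, x) {
  as.numeric(as.matrix(x) %*% model$weights + model$bias)
}

#' Leave-one-out cross-validated discriminant scores
#'
#' Scores each trial with a Fisher LDA trained on all other trials. The
#' scores are exact leave-one-out values computed by rank-one downdates of
#' the pooled within-class scatter (Sherman-Morrison), which is
#' algebraically identical to refitting per fold but runs in `O(N d^2)`.
#' The ridge `lambda` is computed once from the full matrix and reused in
#' every fold so that all folds share one score scale; left-out scores are
#' pooled into a single set for ROC analysis downstream.
#'
#' @inheritParams lda_train
#' @return numeric vector of length `N` of left-out scores.
#' @export
loocv_scores <- function(x, y, lambda = NULL) {
  x <- as.matrix(x)
  y <- check_binary(y)
  n <- nrow(x); d <- ncol(x)
  if (n < 4L) stop("leave-one-out needs N >= 4")
  if (is.null(lambda)) lambda <- default_lambda(x, y)
  sw <- pooled_scatter(x, y)
  if (min(sw$n1, sw$n2) < 2L) stop("a training fold would miss a class")
  # K = S + (N-3) lambda I so that K/(N-3) is each fold's ridged covariance
  k_mat <- sw$scatter + diag((n - 3) * lambda, d)
  r <- solve(k_mat)
  is2 <- y == levels(y)[2L]
  mu_of <- matrix(rep(sw$mu1, n), n, d, byrow = TRUE)
  mu_of[is2, ] <- matrix(rep(sw$mu2, sum(is2)), sum(is2), d, byrow = TRUE)
  dmat <- x - mu_of                          # d_n = x_n - mu_{class(n)}
  nc <- ifelse(is2, sw$n2, sw$n1)
  kfac <- nc / (nc - 1)                      # scatter downdate factor
  e_n <- ifelse(is2, -1, 1) / (nc - 1)       # delta_(n) = delta + e_n d_n
  f_n <- 1 / (2 * (nc - 1))                  # midpoint shift factor
  delta <- sw$mu2 - sw$mu1
  v <- as.numeric(r %*% delta)
  u <- dmat %*% r                            # u_n rows
  q <- rowSums(u * dmat)                     # d_n' R d_n
  a <- 1 - kfac * q
  if (any(a <= 0)) stop("downdated scatter lost positive definiteness")
  pvec <- as.numeric(dmat %*% v)             # d_n' R delta
  beta <- e_n + kfac * (pvec + e_n * q) / a
  mid <- (sw$mu1 + sw$mu2) / 2
  xm <- sweep(x, 2L, mid)
  g_dot_v <- as.numeric(xm %*% v) + f_n * pvec
  g_dot_u <- rowSums(u * xm) + f_n * q
  # (n - 3) restores the per-fold covariance scale of the literal refit
  (n - 3) * (g_dot_v + beta * g_dot_u)
}

# reference implementation: literal per-fold refit (used in tests)
loocv_scores_naive <- function(x, y, lambda = NULL) {
  x <- as.matrix(x)
  y <- check_binary(y)
  if (is.null(lambda)) lambda <- default_lambda(x, y)
  vapply(seq_len(nrow(x)), function(n) {
    fit <- lda_train(x[-n, , drop = FALSE], y[-n], lambda = lambda)
    lda_score(fit, x[n, , drop = FALSE])
  }, numeric(1))
}

#' Area under the ROC curve
#'
#' Probability that a randomly chosen trial of the positive class (second
#' factor level) receives a higher score than a randomly chosen negative
#' trial, with ties counted half — the Mann-Whitney statistic divided by
#' `n_pos * n_neg`, computed from midranks.
#'
#' @param scores numeric scores.
#' @param labels two-class factor (or coercible); second level is positive.
#' @return a value in `[0, 1]`.
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), factor(c("neg", "neg", "pos", "pos")))
#' @export
roc_auc <- function(scores, labels) {
  y <- as.factor(labels)
  y <- droplevels(y)
  if (nlevels(y) != 2L) stop("both classes must be present")
  if (length(scores) != length(y)) stop("scores and labels differ in length")
  pos <- y == levels(y)[2L]
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores)                           # midranks: ties get 1/2 credit
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Permutation test of decoding performance
#'
#' Computes the observed leave-one-out decoding performance (Az) and its
#' label-shuffling null distribution: trial labels are randomly permuted
#' `n_perm` times, abolishing any label-feature association while leaving
#' the pooled feature distribution untouched, and the full LOOCV/Az pipeline
#' is rerun on each shuffle. The p-value uses the add-one estimator
#' `(1 + #null >= observed) / (n_perm + 1)`; performance is called
#' significant when the observed Az lies above the 95th percentile of the
#' null (`p <= 0.05`).
#'
#' @param x `N x d` feature matrix (e.g. from [select_coefficients()]).
#' @param y two-class factor of length `N`.
#' @param n_perm number of label shuffles (default 500).
#' @param seed integer seed for the shuffles.
#' @return an object of class `decoding_result`: list with `az`, `null_az`
#'   (length `n_perm`), `p_value`, `n_perm` and `subset_spec` (taken from
#'   `attr(x, "subset_spec")` when present).
#' @export
permutation_test <- function(x, y, n_perm = 500L, seed = 1L) {
  x <- as.matrix(x)
  y <- check_binary(y)
  n_perm <- as.integer(n_perm)
  stopifnot(n_perm >= 1L)
  lambda <- default_lambda(x, y)
  az <- roc_auc(loocv_scores(x, y, lambda = lambda), y)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))
  null_az <- vapply(seq_len(n_perm), function(k) {
    yk <- sample(y)
    roc_auc(loocv_scores(x, yk, lambda = default_lambda(x, yk)), yk)
  }, numeric(1))
  structure(
    list(az = az, null_az = null_az,
         p_value = (1 + sum(null_az >= az)) / (n_perm + 1),
         n_perm = n_perm, subset_spec = attr(x, "subset_spec")),
    class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("decoding Az = %.3f", x$az))
  if (!is.null(x$null_az) && length(x$null_az)) {
    cat(sprintf(" (null 95th pct %.3f, p = %.4g, %d permutations)",
                stats::quantile(x$null_az, 0.95, names = FALSE),
                x$p_value, x$n_perm))
  }
  cat("\n")
  if (!is.null(x$subset_spec))
    cat("  coefficients:",
        paste0("h[", x$subset_spec$temporal, ",", x$subset_spec$spatial, "]",
               collapse = " "), "\n")
  invisible(x)
}

#' Decode a binary condition contrast from fitted coefficients
#'
#' High-level wrapper: selects trials matching `filter` and the two
#' `contrast` levels of label column `on`, extracts the requested
#' coefficients, and runs leave-one-out LDA with ROC-area scoring, plus a
#' label-permutation significance test when `n_perm > 0`.
#'
#' @param decomp an `scnm3f` fit (with labels).
#' @param on label column holding the contrast variable (default
#'   `"condition"`).
#' @param contrast the two level values; the second is the positive class.
#' @param filter optional named list restricting trials (e.g.
#'   `list(level = 45)`).
#' @param temporal_ids,spatial_ids component subsets as in
#'   [select_coefficients()].
#' @param n_perm permutations for the significance test; `0` skips it.
#' @param seed seed for the permutation shuffles.
#' @return a `decoding_result`; when `n_perm = 0` its `null_az` is empty and
#'   `p_value` is `NA`.
#' @export
decode <- function(decomp, on = "condition", contrast, filter = NULL,
                   temporal_ids = NULL, spatial_ids = NULL,
                   n_perm = 500L, seed = 1L) {
  stopifnot(inherits(decomp, "scnm3f"))
  labs <- decomp$labels
  if (!on %in% names(labs)) stop(sprintf("label column '%s' not found", on))
  keep <- rep(TRUE, nrow(labs))
  for (col in names(filter)) {
    if (!col %in% names(labs)) stop(sprintf("filter column '%s' not found", col))
    keep <- keep & labs[[col]] %in% filter[[col]]
  }
  keep <- keep & labs[[on]] %in% contrast
  y <- factor(as.character(labs[[on]][keep]), levels = as.character(contrast))
  feats <- select_coefficients(decomp, temporal_ids, spatial_ids)
  spec <- attr(feats, "subset_spec")
  feats <- feats[keep, , drop = FALSE]
  attr(feats, "subset_spec") <- spec
  if (n_perm > 0L) return(permutation_test(feats, y, n_perm = n_perm, seed = seed))
  az <- roc_auc(loocv_scores(feats, y), y)
  structure(list(az = az, null_az = numeric(0), p_value = NA_real_,
                 n_perm = 0L, subset_spec = spec),
            class = "decoding_result")
}
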