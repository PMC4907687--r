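#' @export
print.scnm3f <- function(x, ...) {
  cat(sprintf("scNM3F space-by-time decomposition: %d temporal x %d spatial components\n",
              x$p, x$l))
  cat(sprintf("  %d trials, %d time frames, %d sensors\n",
              x$dims[1L], x$dims[2L], x$dims[3L]))
  cat(sprintf("  total squared error %.4g (relative %.3f%%), %d iterations%s\n",
              x$e2, 100 * x$rel_error, x$n_iter,
              if (x$converged) "" else " (iteration cap reached)"))
  invisible(x)
}

#' @export
summary.scnm3f <- function(object, ...) {
  pk <- peak_centers(object)
  structure(
    list(p = object$p, l = object$l, dims = object$dims,
         e2 = object$e2, rel_error = object$rel_error,
         n_iter = object$n_iter, converged = object$converged,
         restart_errors = object$restart_errors,
         peak_times_ms = pk,
         coef_means = apply(object$h, c(1L, 2L), mean),
         coef_sds = apply(object$h, c(1L, 2L), stats::sd)),
    class = "summary.scnm3f")
}

#' @export
print.summary.scnm3f <- function(x, ...) {
  cat(sprintf("scNM3F decomposition with P = %d temporal, L = %d spatial components\n",
              x$p, x$l))
  cat(sprintf("  data: %d trials x %d frames x %d sensors\n",
              x$dims[1L], x$dims[2L], x$dims[3L]))
  cat(sprintf("  relative reconstruction error: %.3f%% after %d iterations\n",
              100 * x$rel_error, x$n_iter))
  cat(sprintf("  restart final errors: %s\n",
              paste(signif(x$restart_errors, 4), collapse = ", ")))
  cat("  temporal component peaks (ms post-onset):",
      paste(round(x$peak_times_ms, 1), collapse = ", "), "\n")
  cat("  trial-averaged coefficients (rows = temporal, cols = spatial):\n")
  print(round(x$coef_means, 3))
  invisible(x)
}

#' Extract single-trial coefficients from a fit
#'
#' The per-trial signed coefficients are the carriers of all single-trial and
#' condition information in the decomposition. `layout = "matrix"` (default)
#' returns an `N x (P*L)` matrix whose columns are ordered temporal-major —
#' pairs (1,1), (1,2), ..., (2,1), ... — with names `h[i,j]`; this is the
#' feature layout the decoding functions use. `layout = "array"` returns the
#' raw `P x L x N` array.
#'
#' @param object an `scnm3f` fit.
#' @param layout `"matrix"` or `"array"`.
#' @param ... ignored.
#' @export
coef.scnm3f <- function(object, layout = c("matrix", "array"), ...) {
  layout <- match.arg(layout)
  if (layout == "array") return(object$h)
  h_features(object$h)
}

# P x L x N coefficient array -> N x (P*L) matrix, columns (i,j) with i outer
h_features <- function(h) {
  p <- dim(h)[1L]; l <- dim(h)[2L]; n <- dim(h)[3L]
  m <- aperm(h, c(2L, 1L, 3L))   # (L, P, N): j fastest within column stack
  dim(m) <- c(l * p, n)
  m <- t(m)
  colnames(m) <- paste0("h[", rep(seq_len(p), each = l), ",",
                        rep(seq_len(l), times = p), "]")
  m
}

#' @export
fitted.scnm3f <- function(object, ...) {
  rec <- reconstruct_spatial(object$w_tem, object$h, object$w_spa,
                             object$dims[1L])
  refold_spatial(rec, object$dims[1L])
}

#' @export
residuals.scnm3f <- function(object, ...) {
  if (is.null(object$data))
    stop("fit was run with keep_data = FALSE; residuals unavailable")
  object$data$data - fitted(object)
}

#' Plot the components of a space-by-time decomposition
#'
#' Draws the temporal components as time courses (ms relative to stimulus
#' onset) and the spatial components as per-sensor loading profiles.
#'
#' @param x an `scnm3f` fit.
#' @param which `"both"`, `"temporal"` or `"spatial"`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.scnm3f <- function(x, which = c("both", "temporal", "spatial"), ...) {
  which <- match.arg(which)
  tms <- (seq_len(x$dims[2L]) - x$t0_index) / x$sampling_rate * 1000
  if (which == "both") {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
  }
  if (which %in% c("both", "temporal"))
    graphics::matplot(tms, x$w_tem, type = "l", lty = 1,
                      xlab = "time (ms)", ylab = "temporal component", ...)
  if (which %in% c("both", "spatial"))
    graphics::matplot(seq_len(x$dims[3L]), t(x$w_spa), type = "h", lty = 1,
                      xlab = "sensor", ylab = "spatial loading", ...)
  invisible(x)
}

#' Simulate trials from a fitted decomposition
#'
#' Draws new trials from the fitted forward model: per condition, coefficient
#' matrices are sampled from a Gaussian with the condition's empirical
#' coefficient mean and standard deviation, combined with the fitted
#' components, and observation noise matching the residual scale is added.
#' Useful for parametric-bootstrap style checks.
#'
#' @param object an `scnm3f` fit carrying labels and data.
#' @param nsim number of replicate tensors.
#' @param seed integer seed.
#' @param condition_on label column defining conditions (default
#'   `"condition"` if present, otherwise all trials pooled).
#' @param ... ignored.
#' @return a list of `nsim` [trial_tensor()] objects.
#' @export
simulate.scnm3f <- function(object, nsim = 1, seed = NULL,
                            condition_on = NULL, ...) {
  if (is.null(object$data)) stop("needs a fit with keep_data = TRUE")
  if (!is.null(seed)) set.seed(seed)
  labs <- object$labels
  if (is.null(condition_on))
    condition_on <- if ("condition" %in% names(labs)) "condition" else NULL
  grp <- if (is.null(condition_on)) rep("all", nrow(labs))
         else as.character(labs[[condition_on]])
  sigma_m <- stats::sd(residuals(object))
  n <- object$dims[1L]
  out <- vector("list", nsim)
  for (k in seq_len(nsim)) {
    h_new <- object$h
    for (g in unique(grp)) {
      idx <- which(grp == g)
      mu <- apply(object$h[, , idx, drop = FALSE], c(1L, 2L), mean)
      sg <- apply(object$h[, , idx, drop = FALSE], c(1L, 2L), stats::sd)
      for (i in idx)
        h_new[, , i] <- mu + sg * matrix(stats::rnorm(object$p * object$l),
                                         object$p, object$l)
    }
    rec <- refold_spatial(
      reconstruct_spatial(object$w_tem, h_new, object$w_spa, n), n)
    rec <- rec + stats::rnorm(length(rec), sd = sigma_m)
    out[[k]] <- trial_tensor(rec, labels = labs,
                             sampling_rate = object$sampling_rate,
                             t0_index = object$t0_index)
  }
  out
}
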