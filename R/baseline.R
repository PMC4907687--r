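#' Peak latencies of the temporal components
#'
#' Time (ms relative to stimulus onset) of the maximum entry of each
#' temporal component; ties are broken towards the earliest frame. These
#' latencies anchor the windows of the sliding-window comparison analysis.
#'
#' @param w_tem an `scnm3f` fit, or a `T x P` non-negative component matrix.
#' @param sampling_rate,t0_index timing metadata; taken from the fit when
#'   `w_tem` is an `scnm3f` object.
#' @return numeric vector of peak times in ms post-onset, one per component.
#' @export
peak_centers <- function(w_tem, sampling_rate = NULL, t0_index = NULL) {
  if (inherits(w_tem, "scnm3f")) {
    sampling_rate <- w_tem$sampling_rate
    t0_index <- w_tem$t0_index
    w_tem <- w_tem$w_tem
  }
  if (is.null(sampling_rate) || is.null(t0_index))
    stop("sampling_rate and t0_index required with a bare component matrix")
  w_tem <- as.matrix(w_tem)
  if (any(colSums(abs(w_tem)) == 0)) stop("all-zero temporal component")
  idx <- apply(w_tem, 2L, which.max)     # which.max returns the first maximum
  (idx - t0_index) / sampling_rate * 1000
}

#' Fixed time window for the sliding-window baseline
#'
#' Converts a window center (ms post-onset) and duration into the range of
#' epoch frame indices it covers; frames outside the epoch are clipped.
#'
#' @param center_time window center in ms relative to stimulus onset.
#' @param duration window length in ms (default 60).
#' @param sampling_rate Hz.
#' @param t0_index 1-based onset frame index.
#' @param n_time number of frames in the epoch.
#' @return an object of class `window_spec` with the frame `indices`.
#' @export
window_spec <- function(center_time, duration = 60, sampling_rate, t0_index,
                        n_time) {
  stopifnot(duration > 0)
  frames <- seq_len(n_time)
  tms <- (frames - t0_index) / sampling_rate * 1000
  inside <- tms >= center_time - duration / 2 & tms <= center_time + duration / 2
  idx <- frames[inside]
  if (!length(idx))
    stop(sprintf("window centered at %g ms does not intersect the epoch",
                 center_time))
  structure(list(center_time = center_time, duration = duration,
                 indices = idx),
            class = "window_spec")
}

#' Per-trial sensor averages over a time window
#'
#' Averages each sensor's activity over the window's frames, separately per
#' trial, producing one spatial feature vector per trial.
#'
#' @param x a [trial_tensor()].
#' @param spec a [window_spec()] (or a center time in ms, converted with the
#'   default 60 ms duration).
#' @return `N x S` matrix of windowed sensor means.
#' @export
window_features <- function(x, spec) {
  stopifnot(inherits(x, "trial_tensor"))
  if (is.numeric(spec))
    spec <- window_spec(spec, sampling_rate = x$sampling_rate,
                        t0_index = x$t0_index, n_time = n_times(x))
  stopifnot(inherits(spec, "window_spec"))
  sub <- x$data[, spec$indices, , drop = FALSE]
  f <- apply(sub, c(1L, 3L), mean)
  dimnames(f) <- NULL
  f
}

#' Sliding-window LDA baseline decoder
#'
#' The conventional comparison analysis: for each window (typically 60 ms
#' wide and centered on the peaks of the fitted temporal components), sensor
#' activity is averaged within the window per trial, and a Fisher LDA with
#' leave-one-out cross-validation decodes the contrast from the resulting
#' sensor vectors, scored by ROC area, with an optional label-permutation
#' significance test — the same conventions as the coefficient decoder.
#'
#' @param x a [trial_tensor()] with labels.
#' @param on,contrast,filter contrast definition as in [decode()].
#' @param centers window centers in ms post-onset (e.g. from
#'   [peak_centers()]).
#' @param duration window length in ms (default 60).
#' @param n_perm permutations per window (`0` skips the significance test).
#' @param seed seed for the shuffles.
#' @return list of `decoding_result` objects, one per window, named by
#'   center time.
#' @export
sliding_lda <- function(x, on = "condition", contrast, filter = NULL,
                        centers, duration = 60, n_perm = 0L, seed = 1L) {
  cs <- contrast_split(x, on, contrast, filter)
  out <- lapply(seq_along(centers), function(k) {
    spec <- window_spec(centers[k], duration, cs$tensor$sampling_rate,
                        cs$tensor$t0_index, n_times(cs$tensor))
    feats <- window_features(cs$tensor, spec)
    if (n_perm > 0L)
      return(permutation_test(feats, cs$y, n_perm = n_perm,
                              seed = as.integer(seed) + k))
    az <- roc_auc(loocv_scores(feats, cs$y), cs$y)
    structure(list(az = az, null_az = numeric(0), p_value = NA_real_,
                   n_perm = 0L, subset_spec = NULL,
                   center_time = centers[k]),
              class = "decoding_result")
  })
  names(out) <- paste0(centers, "ms")
  out
}
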