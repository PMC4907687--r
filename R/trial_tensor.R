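#' Single-trial tensor of multichannel time series
#'
#' Bundles an `N x T x S` numeric array of signed activity (trials x time
#' frames x sensors) with per-trial labels and timing metadata. This is the
#' input container for [scnm3f()] and the sliding-window baseline.
#'
#' @param data numeric array with dimensions `c(N, T, S)`: trial, time frame,
#'   sensor. All values must be finite and every dimension at least 2.
#' @param labels `data.frame` with one row per trial. If `NULL` a minimal
#'   frame containing only `trial_id` is created. Conventional columns are
#'   `trial_id`, `condition` (categorical contrast variable, e.g. stimulus
#'   class) and `level` (ordinal difficulty such as a phase-coherence level).
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param t0_index 1-based index of the time frame of stimulus onset within
#'   the epoch (in `1..T`); times reported by [peak_centers()] are measured
#'   in ms relative to this frame.
#'
#' @return An object of class `trial_tensor`: a list with elements `data`,
#'   `labels`, `sampling_rate`, `t0_index`.
#' @examples
#' x <- trial_tensor(array(rnorm(4 * 10 * 3), c(4, 10, 3)),
#'                   sampling_rate = 100, t0_index = 2)
#' dim(x)
#' @export
trial_tensor <- function(data, labels = NULL, sampling_rate = 1000, t0_index = 1L) {
  if (!is.array(data) || length(dim(data)) != 3L || !is.numeric(data))
    stop("'data' must be a numeric 3-d array (trial x time x sensor)")
  d <- dim(data)
  if (any(d < 2L))
    stop(sprintf("all tensor dimensions must be >= 2 (got %d x %d x %d)",
                 d[1L], d[2L], d[3L]))
  bad <- which(!is.finite(data))
  if (length(bad)) {
    idx <- arrayInd(bad[1L], d)
    stop(sprintf("non-finite value at [trial %d, time %d, sensor %d]",
                 idx[1L], idx[2L], idx[3L]))
  }
  if (is.null(labels)) labels <- data.frame(trial_id = seq_len(d[1L]))
  if (!is.data.frame(labels))
    stop("'labels' must be a data.frame")
  if (nrow(labels) != d[1L])
    stop(sprintf("labels have %d rows but the tensor has %d trials",
                 nrow(labels), d[1L]))
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L || sampling_rate <= 0)
    stop("'sampling_rate' must be a positive scalar (Hz)")
  t0_index <- as.integer(t0_index)
  if (is.na(t0_index) || t0_index < 1L || t0_index > d[2L])
    stop(sprintf("'t0_index' must be in 1..%d", d[2L]))
  structure(
    list(data = data, labels = labels,
         sampling_rate = as.numeric(sampling_rate), t0_index = t0_index),
    class = "trial_tensor")
}

#' @export
dim.trial_tensor <- function(x) dim(x$data)

n_trials  <- function(x) dim(x$data)[1L]
n_times   <- function(x) dim(x$data)[2L]
n_sensors <- function(x) dim(x$data)[3L]

#' @export
print.trial_tensor <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("trial_tensor: %d trials x %d time frames x %d sensors\n",
              d[1L], d[2L], d[3L]))
  cat(sprintf("  sampling rate %g Hz, onset at frame %d (epoch %g..%g ms)\n",
              x$sampling_rate, x$t0_index,
              time_of_index(1L, x), time_of_index(d[2L], x)))
  lab <- setdiff(names(x$labels), "trial_id")
  if (length(lab)) cat("  labels:", paste(lab, collapse = ", "), "\n")
  invisible(x)
}

# ms relative to stimulus onset for a 1-based frame index
time_of_index <- function(idx, x) (idx - x$t0_index) / x$sampling_rate * 1000

# 1-based frame index closest to a time in ms (not clipped)
index_of_time <- function(ms, x) x$t0_index + ms / 1000 * x$sampling_rate

#' Subset the trials of a trial tensor
#'
#' @param x a [trial_tensor()].
#' @param trials integer or logical index over trials.
#' @return a `trial_tensor` holding the selected trials (labels subset too).
#' @export
subset_trials <- function(x, trials) {
  stopifnot(inherits(x, "trial_tensor"))
  trial_tensor(x$data[trials, , , drop = FALSE],
               labels = x$labels[trials, , drop = FALSE],
               sampling_rate = x$sampling_rate, t0_index = x$t0_index)
}

# Restrict a tensor to the trials of a binary contrast and return the
# tensor plus a two-level factor. `on` names a label column; `contrast`
# gives the two level values (positive class second). `filter` is an
# optional named list of label-column values that trials must match.
contrast_split <- function(x, on, contrast, filter = NULL) {
  stopifnot(inherits(x, "trial_tensor"))
  if (!on %in% names(x$labels))
    stop(sprintf("label column '%s' not found", on))
  if (length(contrast) != 2L)
    stop("'contrast' must name exactly two levels")
  keep <- rep(TRUE, n_trials(x))
  for (col in names(filter)) {
    if (!col %in% names(x$labels))
      stop(sprintf("filter column '%s' not found", col))
    keep <- keep & x$labels[[col]] %in% filter[[col]]
  }
  keep <- keep & x$labels[[on]] %in% contrast
  if (!any(keep)) stop("no trials match the contrast/filter")
  xs <- subset_trials(x, keep)
  y <- factor(as.character(xs$labels[[on]]), levels = as.character(contrast))
  counts <- table(y)
  if (any(counts < 2L))
    stop(sprintf("each contrast class needs >= 2 trials (got %s)",
                 paste(counts, collapse = "/")))
  list(tensor = xs, y = y)
}
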