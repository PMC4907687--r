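#' Read and write trial tensors as plain-text containers
#'
#' The on-disk dialect is self-describing plain text: the data file starts
#' with one comment line `# {json}` holding the dimensions, axis order and
#' timing metadata, followed by a tab-separated body of `N * T` rows and `S`
#' columns laid out trial-major (the `T` rows of trial 1, then trial 2, ...).
#' Labels travel in a separate comma-separated file with a header and one
#' row per trial (conventional columns `trial_id`, `condition`, `level`).
#'
#' @param x a [trial_tensor()].
#' @param data_file path of the tensor file (written/read).
#' @param labels_file path of the label CSV.
#' @return `write_trial_tensor()` returns `data_file` invisibly;
#'   `read_trial_tensor()` returns a validated [trial_tensor()].
#' @export
write_trial_tensor <- function(x, data_file, labels_file = NULL) {
  stopifnot(inherits(x, "trial_tensor"))
  d <- dim(x$data)
  meta <- list(format = "spacebytime-tensor-v1",
               n_trial = d[1L], n_time = d[2L], n_sensor = d[3L],
               axis_order = "trial,time,sensor",
               sampling_rate = x$sampling_rate, t0_index = x$t0_index)
  writeLines(paste("#", jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA)),
             data_file)
  body <- unfold_spatial(x)
  data.table::fwrite(data.table::as.data.table(body), data_file, sep = "\t",
                     append = TRUE, col.names = FALSE)
  if (!is.null(labels_file))
    data.table::fwrite(x$labels, labels_file)
  invisible(data_file)
}

#' @rdname write_trial_tensor
#' @export
read_trial_tensor <- function(data_file, labels_file = NULL) {
  if (!file.exists(data_file)) stop(sprintf("data file '%s' not found", data_file))
  header <- readLines(data_file, n = 1L)
  if (!startsWith(header, "# "))
    stop("missing metadata header line; not a spacebytime tensor file")
  meta <- jsonlite::fromJSON(sub("^# ", "", header))
  if (!identical(meta$format, "spacebytime-tensor-v1"))
    stop("unrecognized tensor file format")
  body <- as.matrix(data.table::fread(data_file, skip = 1L, sep = "\t",
                                      header = FALSE))
  dimnames(body) <- NULL
  if (nrow(body) != meta$n_trial * meta$n_time || ncol(body) != meta$n_sensor)
    stop(sprintf("body is %d x %d but metadata promise %d x %d",
                 nrow(body), ncol(body),
                 meta$n_trial * meta$n_time, meta$n_sensor))
  labels <- NULL
  if (!is.null(labels_file)) {
    if (!file.exists(labels_file))
      stop(sprintf("labels file '%s' not found", labels_file))
    labels <- as.data.frame(data.table::fread(labels_file, header = TRUE))
    if (nrow(labels) != meta$n_trial)
      stop(sprintf("labels have %d rows but the tensor has %d trials",
                   nrow(labels), meta$n_trial))
  }
  trial_tensor(refold_spatial(body, meta$n_trial), labels = labels,
               sampling_rate = meta$sampling_rate, t0_index = meta$t0_index)
}

#' Write or read a fitted decomposition
#'
#' Serializes a fit into a directory of plain-text matrices (`w_tem.tsv`,
#' `w_spa.tsv`, `h.tsv` with the `P x L` trial blocks stacked,
#' `error_trace.tsv`) plus a `config.json` sidecar with dimensions, control
#' parameters and the seed. The round trip is lossless to the 15 significant
#' digits of the text representation. Reading restores an `scnm3f` object
#' without the original data (so data-dependent methods like `residuals()`
#' are unavailable on a reloaded fit).
#'
#' @param fit an `scnm3f` object.
#' @param dir directory to create/read.
#' @return `write_decomposition()` returns `dir` invisibly;
#'   `read_decomposition()` an `scnm3f` object.
#' @export
write_decomposition <- function(fit, dir) {
  stopifnot(inherits(fit, "scnm3f"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wm <- function(m, f) data.table::fwrite(data.table::as.data.table(m),
                                          file.path(dir, f), sep = "\t",
                                          col.names = FALSE)
  wm(fit$w_tem, "w_tem.tsv")
  wm(fit$w_spa, "w_spa.tsv")
  n <- dim(fit$h)[3L]
  hm <- matrix(aperm(fit$h, c(1L, 3L, 2L)), fit$p * n, fit$l)
  wm(hm, "h.tsv")
  wm(matrix(fit$error_trace, ncol = 1L), "error_trace.tsv")
  cfg <- list(format = "spacebytime-decomp-v1",
              p = fit$p, l = fit$l, n_trial = n,
              n_time = fit$dims[2L], n_sensor = fit$dims[3L],
              e2 = fit$e2, rel_error = fit$rel_error,
              n_iter = fit$n_iter, converged = fit$converged,
              restart_errors = fit$restart_errors,
              seed = fit$seed,
              sampling_rate = fit$sampling_rate, t0_index = fit$t0_index,
              control = unclass(fit$control))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA),
             file.path(dir, "config.json"))
  if (!is.null(fit$labels))
    data.table::fwrite(fit$labels, file.path(dir, "labels.csv"))
  invisible(dir)
}

#' @rdname write_decomposition
#' @export
read_decomposition <- function(dir) {
  cfg_file <- file.path(dir, "config.json")
  if (!file.exists(cfg_file)) stop("config.json missing; not a decomposition directory")
  cfg <- jsonlite::fromJSON(cfg_file)
  if (!identical(cfg$format, "spacebytime-decomp-v1"))
    stop("unrecognized decomposition format")
  rm_ <- function(f) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stop(sprintf("dataset '%s' missing from '%s'", f, dir))
    m <- as.matrix(data.table::fread(path, sep = "\t", header = FALSE))
    dimnames(m) <- NULL
    m
  }
  w_tem <- rm_("w_tem.tsv"); w_spa <- rm_("w_spa.tsv")
  hm <- rm_("h.tsv")
  h <- aperm(array(hm, c(cfg$p, cfg$n_trial, cfg$l)), c(1L, 3L, 2L))
  labels <- NULL
  if (file.exists(file.path(dir, "labels.csv")))
    labels <- as.data.frame(data.table::fread(file.path(dir, "labels.csv")))
  ctl <- cfg$control
  control <- scnm3f_control(tol = ctl$tol, max_iter = ctl$max_iter,
                            n_restarts = ctl$n_restarts,
                            update_exponent = ctl$update_exponent,
                            eps = ctl$eps, use_pinv = ctl$use_pinv,
                            normalize = ctl$normalize,
                            restart_selection = ctl$restart_selection)
  structure(
    list(w_tem = w_tem, w_spa = w_spa, h = h,
         e2 = cfg$e2, rel_error = cfg$rel_error,
         error_trace = as.numeric(rm_("error_trace.tsv")),
         restart_errors = cfg$restart_errors,
         n_iter = cfg$n_iter, converged = cfg$converged,
         p = cfg$p, l = cfg$l, control = control, seed = cfg$seed,
         labels = labels, sampling_rate = cfg$sampling_rate,
         t0_index = cfg$t0_index,
         dims = c(cfg$n_trial, cfg$n_time, cfg$n_sensor),
         data = NULL, call = NULL),
    class = "scnm3f")
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes the workflow end to end: load (or simulate) a trial tensor,
#' optionally select the numbers of components by decoding gain, fit the
#' decomposition, decode the contrast from the coefficients, optionally run
#' the sliding-window baseline at the component peaks, write the outputs and
#' a JSON report. Every stochastic stage derives its seed from the single
#' top-level `seed`, so identical configurations reproduce byte-identical
#' reports.
#'
#' @param config a nested list (or path to a YAML file with the same
#'   structure) with blocks:
#'   \describe{
#'     \item{seed}{integer, governs everything.}
#'     \item{data / labels}{paths of an existing tensor + label file; omit to
#'       simulate.}
#'     \item{simulate}{arguments for [make_ground_truth()] (used when no
#'       data path is given).}
#'     \item{select}{optional: `max_p`, `max_l`, `alpha`, `n_perm`; presence
#'       turns on dimensionality selection.}
#'     \item{fit}{`p`, `l` (ignored when selection is on) and optional
#'       control overrides (`tol`, `max_iter`, `n_restarts`, ...).}
#'     \item{decode}{`on`, `contrast`, optional `filter`, `temporal_ids`,
#'       `spatial_ids`, `n_perm`.}
#'     \item{baseline}{optional: `duration` (ms); windows are centered on
#'       the fitted temporal peaks.}
#'     \item{output}{directory for the decomposition, report and copies of
#'       simulated data.}
#'   }
#' @return the report list, invisibly; written as `report.json` in the
#'   output directory.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config error: 'seed' is required")
  seed <- as.integer(config$seed)
  out_dir <- config$output %||% stop("config error: 'output' directory required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # --- data stage -----------------------------------------------------------
  if (!is.null(config$data)) {
    if (!file.exists(config$data))
      stop(sprintf("config error: data file '%s' not found", config$data))
    if (!is.null(config$labels) && !file.exists(config$labels))
      stop(sprintf("config error: labels file '%s' not found", config$labels))
    x <- read_trial_tensor(config$data, config$labels)
    data_path <- config$data
  } else {
    gt <- do.call(make_ground_truth,
                  c(config$simulate %||% list(), list(seed = seed)))
    x <- generate_trials(gt)
    data_path <- file.path(out_dir, "data.tsv")
    write_trial_tensor(x, data_path, file.path(out_dir, "labels.csv"))
  }

  dec <- config$decode %||% stop("config error: 'decode' block required")
  if (is.null(dec$on) || is.null(dec$contrast))
    stop("config error: decode block needs 'on' and 'contrast'")

  ctl_args <- config$fit[intersect(names(config$fit),
                                   names(formals(scnm3f_control)))]
  control <- do.call(scnm3f_control, ctl_args %||% list())

  # --- selection / fit ------------------------------------------------------
  selection <- NULL
  if (!is.null(config$select)) {
    sel <- config$select
    selection <- select_dimensions(
      x, on = dec$on, contrast = dec$contrast, filter = dec$filter,
      max_p = sel$max_p %||% 6L, max_l = sel$max_l %||% 4L,
      alpha = sel$alpha %||% 0.05, n_perm = sel$n_perm %||% 500L,
      seed = seed + 1L, control = control)
    p <- selection$chosen[["p"]]; l <- selection$chosen[["l"]]
  } else {
    p <- config$fit$p %||% stop("config error: fit block needs 'p' (or a select block)")
    l <- config$fit$l %||% stop("config error: fit block needs 'l' (or a select block)")
  }
  fit <- scnm3f(x, p, l, control = control, seed = seed + 2L)
  decomp_dir <- file.path(out_dir, "decomposition")
  write_decomposition(fit, decomp_dir)

  # --- decoding -------------------------------------------------------------
  dr <- decode(fit, on = dec$on, contrast = dec$contrast, filter = dec$filter,
               temporal_ids = dec$temporal_ids, spatial_ids = dec$spatial_ids,
               n_perm = dec$n_perm %||% 500L, seed = seed + 3L)

  # --- baseline -------------------------------------------------------------
  baseline <- NULL
  if (!is.null(config$baseline)) {
    centers <- peak_centers(fit)
    bl <- sliding_lda(x, on = dec$on, contrast = dec$contrast,
                      filter = dec$filter, centers = centers,
                      duration = config$baseline$duration %||% 60,
                      n_perm = config$baseline$n_perm %||% 0L,
                      seed = seed + 4L)
    baseline <- list(centers_ms = centers,
                     az = vapply(bl, `[[`, numeric(1), "az"))
  }

  report <- list(
    seed = seed,
    data = data_path,
    chosen = list(p = unname(p), l = unname(l),
                  by_selection = !is.null(selection)),
    selection = if (!is.null(selection))
      list(visited = selection$visited, alpha = selection$alpha),
    fit = list(rel_error = fit$rel_error, e2 = fit$e2, n_iter = fit$n_iter,
               converged = fit$converged,
               peak_centers_ms = peak_centers(fit)),
    decoding = list(az = dr$az, p_value = dr$p_value, n_perm = dr$n_perm,
                    null_az_q95 = if (length(dr$null_az))
                      stats::quantile(dr$null_az, 0.95, names = FALSE)),
    baseline = baseline,
    files = list(decomposition = decomp_dir))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
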