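#' Select the numbers of temporal and spatial components by decoding gain
#'
#' Starting from one temporal and one spatial component, the procedure
#' alternately considers adding a temporal or a spatial component. Each
#' candidate dimensionality is refit from scratch, the binary contrast is
#' decoded from all its coefficients (leave-one-out LDA, ROC area), and the
#' decoding gain of the added component is tested by permutation: only the
#' coefficients belonging to the added component are shuffled across trials
#' (jointly, as a block), all other coefficients are untouched, and the
#' decoding pipeline is rerun on each shuffle. A candidate is accepted when
#' its observed Az exceeds the 95th percentile of this null — equivalently
#' when the add-one permutation p-value is at most `alpha` — and must also
#' improve on the current model's observed Az (a redundant extra component
#' can beat the permutation null without improving decoding). At
#' `alpha = 1` the threshold is degenerate: every tried increment is
#' accepted and the search runs to its bounds. When both
#' candidate increments are significant in a round, the one with the larger
#' gain is taken (ties go to the temporal increment). The search stops when
#' neither increment is significant or the bounds are reached (with a
#' warning if an increment was still significant at the bound).
#'
#' @param x a [trial_tensor()] with labels.
#' @param on label column holding the contrast variable.
#' @param contrast two level values defining the binary contrast.
#' @param filter optional named list restricting trials before the contrast.
#' @param max_p,max_l upper bounds on the numbers of components.
#' @param alpha significance level for the gain test (default 0.05).
#' @param n_perm permutations per gain test (default 500).
#' @param seed integer seed governing refits and shuffles.
#' @param control a [scnm3f_control()] used for every refit. The default
#'   uses 2 restarts: candidate ranking by decoding is robust to restart
#'   count, and selection refits dominate the runtime.
#'
#' @return an object of class `selection_trace`: list with `chosen` (named
#'   vector `p`, `l`), `visited` (data.frame of every evaluated
#'   dimensionality with its Az and gain p-value), `alpha`, `az` (Az at the
#'   chosen dimensionality) and `fit` (the accepted `scnm3f` fit).
#' @export
select_dimensions <- function(x, on = "condition", contrast, filter = NULL,
                              max_p = 6L, max_l = 4L, alpha = 0.05,
                              n_perm = 500L, seed = 1L,
                              control = scnm3f_control(n_restarts = 2L)) {
  cs <- contrast_split(x, on, contrast, filter)
  xs <- cs$tensor; y <- cs$y
  seed <- as.integer(seed)
  fit_seed <- function(k) (seed + 104729L * k) %% 2147483647L

  fit_cur <- scnm3f(xs, 1L, 1L, control = control, seed = fit_seed(0L),
                    keep_data = FALSE)
  az_cur <- az_of(fit_cur, y)
  visited <- data.frame(p = 1L, l = 1L, az = az_cur, gain_p = NA_real_,
                        move = "start", accepted = TRUE)
  p <- 1L; l <- 1L
  counter <- 0L
  repeat {
    cands <- list()
    if (p < max_p) cands$temporal <- c(p + 1L, l)
    if (l < max_l) cands$spatial <- c(p, l + 1L)
    if (!length(cands)) break
    res <- lapply(names(cands), function(mv) {
      counter <<- counter + 1L
      dims <- cands[[mv]]
      fit_k <- scnm3f(xs, dims[1L], dims[2L], control = control,
                      seed = fit_seed(counter), keep_data = FALSE)
      gain_test(fit_k, y, mv, n_perm = n_perm,
                seed = fit_seed(counter) + 1L, az_base = az_cur)
    })
    names(res) <- names(cands)
    for (mv in names(res))
      visited <- rbind(visited, data.frame(
        p = cands[[mv]][1L], l = cands[[mv]][2L], az = res[[mv]]$az,
        gain_p = res[[mv]]$p_value, move = mv, accepted = FALSE))
    # accepted increments must beat the block-permutation null AND actually
    # improve decoding: a redundant component can be individually informative
    # (so permuting it hurts) while adding nothing over the current model.
    # At alpha >= 1 the threshold is degenerate and every increment passes.
    sig <- vapply(res, function(r)
      alpha >= 1 || (r$p_value <= alpha && r$az > az_cur), logical(1))
    if (!any(sig)) break
    gains <- vapply(res, function(r) r$az - az_cur, numeric(1))
    gains[!sig] <- -Inf
    pick <- if (sum(sig) > 1L && gains["temporal"] >= gains["spatial"])
      "temporal" else names(which.max(gains))
    p <- cands[[pick]][1L]; l <- cands[[pick]][2L]
    fit_cur <- res[[pick]]$fit
    az_cur <- res[[pick]]$az
    visited$accepted[nrow(visited) - (length(res) - match(pick, names(res)))] <- TRUE
    if (p == max_p && l == max_l) {
      warning("component bounds reached with increments still significant")
      break
    }
  }
  structure(list(chosen = c(p = p, l = l), visited = visited, alpha = alpha,
                 az = az_cur, fit = fit_cur, seed = seed,
                 on = on, contrast = contrast),
            class = "selection_trace")
}

az_of <- function(fit, y) {
  feats <- h_features(fit$h)
  roc_auc(loocv_scores(feats, y), y)
}

# permutation test of the decoding gain of the component added by `move`:
# shuffle only the coefficient block of the added (last) component across
# trials, keep everything else fixed, and redecode.
gain_test <- function(fit, y, move, n_perm, seed, az_base) {
  feats <- h_features(fit$h)
  p <- fit$p; l <- fit$l
  block <- if (move == "temporal") {
    seq.int((p - 1L) * l + 1L, p * l)       # all pairs of the new temporal comp
  } else {
    seq.int(l, p * l, by = l)               # pair j = l within every temporal comp
  }
  az <- roc_auc(loocv_scores(feats, y), y)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))
  n <- nrow(feats)
  null_az <- vapply(seq_len(n_perm), function(k) {
    fk <- feats
    fk[, block] <- fk[sample.int(n), block, drop = FALSE]
    roc_auc(loocv_scores(fk, y), y)
  }, numeric(1))
  list(az = az, p_value = (1 + sum(null_az >= az)) / (n_perm + 1),
       null_az = null_az, fit = fit, gain = az - az_base)
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("component selection by decoding gain (alpha = %g)\n", x$alpha))
  cat(sprintf("  chosen: P = %d temporal, L = %d spatial components (Az = %.3f)\n",
              x$chosen["p"], x$chosen["l"], x$az))
  cat("  search trace:\n")
  v <- x$visited
  for (i in seq_len(nrow(v)))
    cat(sprintf("    (%d, %d) %-8s Az = %.3f%s%s\n", v$p[i], v$l[i], v$move[i],
                v$az[i],
                if (is.na(v$gain_p[i])) "" else sprintf(", gain p = %.4g", v$gain_p[i]),
                if (v$accepted[i]) "  [accepted]" else ""))
  invisible(x)
}
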