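#' Control parameters for the scNM3F fit
#'
#' @param tol relative decrease of the total squared reconstruction error
#'   between consecutive iterations below which the loop stops. Dimensionless,
#'   default `1e-6`.
#' @param max_iter iteration cap per restart (default 500).
#' @param n_restarts number of random initializations; the restart with the
#'   lowest final error (or highest decoding performance, see
#'   `restart_selection`) is returned. Default 5.
#' @param update_exponent power applied to the multiplicative update ratio.
#'   The cluster-NMF derivation uses a square root (`0.5`, the default); `1`
#'   applies the raw ratio.
#' @param eps small positive stabilizer added to update denominators to avoid
#'   0/0 (default `1e-12`).
#' @param use_pinv if `TRUE` (default) per-trial coefficients are the
#'   Moore-Penrose least-squares solution; if `FALSE` the component
#'   transposes are used instead, which is a good approximation once the
#'   components become near-orthogonal and is considerably faster.
#' @param normalize if `TRUE`, rescale temporal columns and spatial rows to
#'   unit Euclidean norm at the end of the fit, with compensating rescaling
#'   of the coefficients (the factorization has a scale ambiguity; off by
#'   default).
#' @param restart_selection `"error"` (default) keeps the restart with lowest
#'   final reconstruction error; `"decoding"` keeps the restart whose
#'   coefficients best decode a binary contrast (requires `on`/`contrast`
#'   arguments to [scnm3f()]).
#' @return a list of class `scnm3f_control`.
#' @export
scnm3f_control <- function(tol = 1e-6, max_iter = 500L, n_restarts = 5L,
                           update_exponent = 0.5, eps = 1e-12,
                           use_pinv = TRUE, normalize = FALSE,
                           restart_selection = c("error", "decoding")) {
  stopifnot(tol > 0, max_iter >= 1L, n_restarts >= 1L, eps > 0,
            update_exponent > 0)
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 n_restarts = as.integer(n_restarts),
                 update_exponent = update_exponent, eps = eps,
                 use_pinv = isTRUE(use_pinv), normalize = isTRUE(normalize),
                 restart_selection = match.arg(restart_selection)),
            class = "scnm3f_control")
}

#' Multiplicative update of the temporal components
#'
#' One cluster-NMF update of the non-negative temporal component matrix
#' against the temporal unfolding. With `A = M %*% t(M)` split into positive
#' and negative parts, the update multiplies `W` elementwise by
#' `((A+ W + W W' A- W) / (A- W + W W' A+ W))^gamma`, which decreases the
#' self-reconstruction objective `||M - W W' M||^2` while keeping `W`
#' non-negative.
#'
#' @param w `T x P` non-negative matrix of temporal components (columns).
#' @param m_tem `T x (S*N)` temporal unfolding (signed).
#' @param control a [scnm3f_control()] supplying `update_exponent` and `eps`.
#' @return the updated non-negative `T x P` matrix.
#' @export
update_temporal <- function(w, m_tem, control = scnm3f_control()) {
  if (nrow(w) != nrow(m_tem)) stop("w and m_tem disagree on T")
  gram <- split_signs(tcrossprod(m_tem))
  mult_update(w, gram$pos, gram$neg, control$update_exponent, control$eps)
}

#' Multiplicative update of the spatial components
#'
#' Mirror of [update_temporal()] for the spatial factor: the update is
#' applied to `G = t(w_spa)` with Gram matrix `B = t(M) %*% M` of the
#' spatial unfolding and decreases `||M - M G t(G)... ||`, i.e.
#' `||M_spa - M_spa t(W_spa) W_spa||^2`.
#'
#' @param w_spa `L x S` non-negative matrix of spatial components (rows).
#' @param m_spa `(T*N) x S` spatial unfolding (signed).
#' @inheritParams update_temporal
#' @return the updated non-negative `L x S` matrix.
#' @export
update_spatial <- function(w_spa, m_spa, control = scnm3f_control()) {
  if (ncol(w_spa) != ncol(m_spa)) stop("w_spa and m_spa disagree on S")
  gram <- split_signs(crossprod(m_spa))
  g <- mult_update(t(w_spa), gram$pos, gram$neg,
                   control$update_exponent, control$eps)
  t(g)
}

# shared elementwise update: w <- w * ((Ap w + w w' An w)/(An w + w w' Ap w))^g
mult_update <- function(w, a_pos, a_neg, exponent, eps) {
  pw <- a_pos %*% w
  nw <- a_neg %*% w
  wtw_p <- w %*% crossprod(w, nw)   # w w' A- w
  wtw_n <- w %*% crossprod(w, pw)   # w w' A+ w
  ratio <- (pw + wtw_p) / (nw + wtw_n + eps)
  if (any(!is.finite(ratio))) stop("non-finite values in multiplicative update")
  if (exponent != 1) ratio <- ratio^exponent
  w * ratio
}

# self-reconstruction objectives minimized by the two updates
e2_temporal <- function(w, m_tem) sum((m_tem - w %*% crossprod(w, m_tem))^2)
e2_spatial  <- function(w_spa, m_spa) {
  g <- t(w_spa)
  sum((m_spa - m_spa %*% g %*% w_spa)^2)
}

#' Least-squares update of the per-trial coefficients
#'
#' For fixed components, the signed coefficient matrix of each trial is the
#' minimizer of the squared Frobenius reconstruction error, obtained through
#' the Moore-Penrose pseudoinverses: `H_n = pinv(W_tem) M_n pinv(W_spa)`.
#' With near-orthogonal components the pseudoinverses are close to the
#' transposes; `use_pinv = FALSE` in the control selects that faster variant.
#'
#' @param w_tem `T x P` temporal components, full column rank.
#' @param w_spa `L x S` spatial components, full row rank.
#' @param m a single signed `T x S` trial matrix, a [trial_tensor()], or an
#'   `N x T x S` array.
#' @inheritParams update_temporal
#' @return a `P x L` matrix for a single trial, otherwise a `P x L x N`
#'   array.
#' @export
update_coefficients <- function(w_tem, w_spa, m, control = scnm3f_control()) {
  p <- ncol(w_tem); l <- nrow(w_spa)
  if (control$use_pinv) {
    if (qr(w_tem)$rank < p)
      stop("degenerate components: temporal factor is column rank deficient")
    if (qr(t(w_spa))$rank < l)
      stop("degenerate components: spatial factor is row rank deficient")
    left  <- MASS::ginv(w_tem)          # P x T
    right <- MASS::ginv(w_spa)          # S x L
  } else {
    left  <- t(w_tem)
    right <- t(w_spa)
  }
  if (is.matrix(m)) return(left %*% m %*% right)
  a <- tensor_data(m)
  d <- dim(a)                            # N, T, S
  x <- left %*% unfold_temporal(a)       # P x (S*N)
  dim(x) <- c(p, d[3L], d[1L])           # (P, S, N)
  x <- aperm(x, c(1L, 3L, 2L))           # (P, N, S)
  dim(x) <- c(p * d[1L], d[3L])
  h <- x %*% right                       # (P*N) x L
  dim(h) <- c(p, d[1L], l)               # (P, N, L)
  aperm(h, c(1L, 3L, 2L))                # (P, L, N)
}

#' Total and per-trial reconstruction error
#'
#' Squared Frobenius norm of `M_n - W_tem H_n W_spa` per trial, and the sum
#' over trials, which is the quantity the fitting loop monitors.
#'
#' @param x a [trial_tensor()] or `N x T x S` array.
#' @param w_tem `T x P` temporal components.
#' @param h `P x L x N` coefficient array.
#' @param w_spa `L x S` spatial components.
#' @return list with `total` (scalar) and `per_trial` (length-`N` vector).
#' @export
reconstruction_error <- function(x, w_tem, h, w_spa) {
  a <- tensor_data(x)
  d <- dim(a)
  res <- unfold_spatial(a) - reconstruct_spatial(w_tem, h, w_spa, d[1L])
  rs <- rowSums(res^2)
  dim(rs) <- c(d[2L], d[1L])
  per_trial <- colSums(rs)
  list(total = sum(per_trial), per_trial = per_trial)
}

# W_tem H_n W_spa for all trials, laid out as the spatial unfolding (T*N) x S
reconstruct_spatial <- function(w_tem, h, w_spa, n_trial) {
  p <- dim(h)[1L]; l <- dim(h)[2L]
  hm <- h
  dim(hm) <- c(p, l * n_trial)
  th <- w_tem %*% hm                     # T x (L*N)
  dim(th) <- c(nrow(w_tem), l, n_trial)
  th <- aperm(th, c(1L, 3L, 2L))         # (T, N, L)
  dim(th) <- c(nrow(w_tem) * n_trial, l)
  th %*% w_spa
}

#' Fit the space-by-time decomposition (scNM3F)
#'
#' Factorizes every trial slice of a signed trial tensor as
#' `M_n ~ W_tem %*% H_n %*% W_spa`, with trial-invariant non-negative
#' temporal components (columns of `W_tem`) and spatial components (rows of
#' `W_spa`) and signed per-trial coefficients `H_n`. Components are fit with
#' cluster-NMF multiplicative updates on the two unfoldings of the tensor,
#' which handle the signed data through its positive and negative parts and
#' push the components towards sparse, near-orthogonal cluster indicators;
#' coefficients are refreshed each iteration by the pseudoinverse
#' least-squares rule. Each iteration performs, in order: spatial update,
#' temporal update, coefficient update, error evaluation. The loop stops when
#' the relative decrease of the total squared reconstruction error falls
#' below `control$tol` or `control$max_iter` is reached. Because the loop
#' alternates two objectives it is not provably monotone, so the best
#' (lowest-error) iterate seen is tracked and returned. Multiple random
#' restarts are run and the best kept.
#'
#' @param x a [trial_tensor()].
#' @param p number of temporal components (`1 <= p <= T`).
#' @param l number of spatial components (`1 <= l <= S`).
#' @param control a [scnm3f_control()].
#' @param seed integer seed governing all random initializations.
#' @param on,contrast only used when `control$restart_selection = "decoding"`:
#'   label column and pair of level values defining the binary contrast whose
#'   leave-one-out decoding performance ranks the restarts.
#' @param keep_data if `TRUE` (default) the input tensor is stored in the
#'   returned object so that [fitted()], [residuals()] and the baseline
#'   analyses can use it.
#'
#' @return An object of class `scnm3f` with elements `w_tem` (`T x P`),
#'   `w_spa` (`L x S`), `h` (`P x L x N`), `e2` (best total squared error),
#'   `rel_error` (`e2` divided by the total sum of squares of the data),
#'   `error_trace` (per-iteration totals of the returned restart),
#'   `restart_errors`, `control`, `seed`, `labels`, `sampling_rate`,
#'   `t0_index` and (optionally) `data`.
#' @examples
#' gt <- make_ground_truth(n_time = 40, n_sensor = 8, p = 2, l = 2,
#'                         peak_times_ms = c(50, 120), trials_per_condition = 10,
#'                         sampling_rate = 200, t0_index = 5, seed = 1)
#' x <- generate_trials(gt)
#' fit <- scnm3f(x, p = 2, l = 2, seed = 1,
#'               control = scnm3f_control(n_restarts = 2, max_iter = 100))
#' fit
#' @export
scnm3f <- function(x, p, l, control = scnm3f_control(), seed = 1L,
                   on = NULL, contrast = NULL, keep_data = TRUE) {
  stopifnot(inherits(x, "trial_tensor"))
  d <- dim(x$data)
  p <- as.integer(p); l <- as.integer(l)
  if (p < 1L || p > d[2L]) stop(sprintf("'p' must be in 1..%d", d[2L]))
  if (l < 1L || l > d[3L]) stop(sprintf("'l' must be in 1..%d", d[3L]))
  if (control$restart_selection == "decoding" &&
      (is.null(on) || is.null(contrast)))
    stop("restart_selection = \"decoding\" needs 'on' and 'contrast'")

  m_tem <- unfold_temporal(x)
  m_spa <- unfold_spatial(x)
  gram_tem <- split_signs(tcrossprod(m_tem))
  gram_spa <- split_signs(crossprod(m_spa))
  total_ss <- sum(m_tem^2)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))

  runs <- vector("list", control$n_restarts)
  for (r in seq_len(control$n_restarts)) {
    runs[[r]] <- tryCatch(
      scnm3f_once(d, p, l, m_tem, gram_tem, gram_spa, control, total_ss),
      error = function(e) e)
  }
  failed <- vapply(runs, inherits, logical(1), "error")
  if (all(failed))
    stop("scNM3F fit failed in every restart; last error: ",
         conditionMessage(runs[[length(runs)]]))
  runs <- runs[!failed]

  if (control$restart_selection == "decoding") {
    sc <- vapply(runs, function(run) {
      y <- factor(as.character(x$labels[[on]]), levels = as.character(contrast))
      keep <- !is.na(y)
      feats <- h_features(run$h)[keep, , drop = FALSE]
      roc_auc(loocv_scores(feats, droplevels(y[keep])), droplevels(y[keep]))
    }, numeric(1))
    best <- which.max(sc)
  } else {
    best <- which.min(vapply(runs, `[[`, numeric(1), "e2"))
  }
  run <- runs[[best]]

  if (control$normalize) {
    nt <- sqrt(colSums(run$w_tem^2))
    ns <- sqrt(rowSums(run$w_spa^2))
    run$w_tem <- sweep(run$w_tem, 2L, nt, "/")
    run$w_spa <- sweep(run$w_spa, 1L, ns, "/")
    for (n in seq_len(dim(run$h)[3L]))
      run$h[, , n] <- diag(nt, p) %*% run$h[, , n] %*% diag(ns, l)
  }

  structure(
    list(w_tem = run$w_tem, w_spa = run$w_spa, h = run$h,
         e2 = run$e2, rel_error = run$e2 / total_ss,
         error_trace = run$trace,
         restart_errors = vapply(runs, `[[`, numeric(1), "e2"),
         n_iter = run$n_iter, converged = run$converged,
         p = p, l = l, control = control, seed = as.integer(seed),
         labels = x$labels, sampling_rate = x$sampling_rate,
         t0_index = x$t0_index, dims = d,
         data = if (keep_data) x else NULL,
         call = match.call()),
    class = "scnm3f")
}

# single restart on cached unfoldings; RNG state advanced by the caller
scnm3f_once <- function(d, p, l, m_tem, gram_tem, gram_spa, control, total_ss) {
  w_tem <- matrix(1 - stats::runif(d[2L] * p), d[2L], p)
  w_spa <- matrix(1 - stats::runif(l * d[3L]), l, d[3L])
  ce <- coef_and_error(w_tem, w_spa, m_tem, d, control$use_pinv, total_ss)
  trace <- ce$e2
  best <- list(w_tem = w_tem, w_spa = w_spa, h = ce$h, e2 = ce$e2)
  reinit_tem <- rep(FALSE, p); reinit_spa <- rep(FALSE, l)
  converged <- FALSE
  iter <- 0L
  while (iter < control$max_iter) {
    iter <- iter + 1L
    g <- mult_update(t(w_spa), gram_spa$pos, gram_spa$neg,
                     control$update_exponent, control$eps)
    w_spa <- t(g)
    w_tem <- mult_update(w_tem, gram_tem$pos, gram_tem$neg,
                         control$update_exponent, control$eps)
    rt <- revive_zero(w_tem, reinit_tem, "temporal")
    w_tem <- rt$w; reinit_tem <- rt$flags
    rs <- revive_zero(t(w_spa), reinit_spa, "spatial")
    w_spa <- t(rs$w); reinit_spa <- rs$flags
    ce <- coef_and_error(w_tem, w_spa, m_tem, d, control$use_pinv, total_ss)
    prev <- trace[length(trace)]
    if (!is.finite(ce$e2)) stop("reconstruction error became non-finite")
    trace <- c(trace, ce$e2)
    if (ce$e2 < best$e2)
      best <- list(w_tem = w_tem, w_spa = w_spa, h = ce$h, e2 = ce$e2)
    if (prev > 0 && abs(prev - ce$e2) / prev < control$tol) {
      converged <- TRUE
      break
    }
  }
  if (any(colSums(abs(best$w_tem)) == 0) || any(rowSums(abs(best$w_spa)) == 0))
    stop("degenerate all-zero component at termination")
  list(w_tem = best$w_tem, w_spa = best$w_spa, h = best$h, e2 = best$e2,
       trace = trace, n_iter = iter, converged = converged)
}

# inner-loop coefficient update and error, touching the data only through
# G_n = W' M_n Ws'. Uses pinv(W) = (W'W)^+ W' (valid also for deficient
# rank), so H_n = (W'W)^+ G_n (Ws Ws')^+ and
# E^2 = ||M||^2 - 2 sum <H_n, G_n> + sum tr((W'W) H_n (Ws Ws') H_n').
coef_and_error <- function(w_tem, w_spa, m_tem, d, use_pinv, total_ss) {
  p <- ncol(w_tem); l <- nrow(w_spa)
  n <- d[1L]
  x <- crossprod(w_tem, m_tem)           # P x (S*N)
  dim(x) <- c(p, d[3L], n)
  x <- aperm(x, c(1L, 3L, 2L))
  dim(x) <- c(p * n, d[3L])
  g <- x %*% t(w_spa)                    # (P*N) x L, trial blocks of G_n
  cw <- crossprod(w_tem)                 # W'W  (P x P)
  cs <- tcrossprod(w_spa)                # Ws Ws'  (L x L)
  if (use_pinv) {
    cwi <- tryCatch(solve(cw), error = function(e) MASS::ginv(cw))
    csi <- tryCatch(solve(cs), error = function(e) MASS::ginv(cs))
    dim(g) <- c(p, n * l)
    hg <- cwi %*% g                      # (W'W)^+ G_n blocks
    dim(hg) <- c(p * n, l)
    h <- hg %*% csi
    dim(g) <- c(p * n, l)
  } else {
    h <- g
  }
  cross <- sum(h * g)                    # sum tr(H_n' G_n)
  hc <- h %*% cs                         # H_n (Ws Ws') blocks
  dim(h) <- c(p, n * l)
  dim(hc) <- c(p, n * l)
  quad <- sum((cw %*% h) * hc)           # sum tr((W'W) H_n (WsWs') H_n')
  e2 <- max(total_ss - 2 * cross + quad, 0)
  dim(h) <- c(p, n, l)
  list(h = aperm(h, c(1L, 3L, 2L)), e2 = e2)
}

# re-initialize an all-zero column once; failing twice aborts the restart.
# `w` is oriented with components along columns.
revive_zero <- function(w, flags, what) {
  zero <- colSums(abs(w)) == 0
  if (any(zero)) {
    again <- zero & flags
    if (any(again))
      stop(sprintf("%s component %d collapsed to zero twice",
                   what, which(again)[1L]))
    for (j in which(zero)) w[, j] <- 1 - stats::runif(nrow(w))
    flags <- flags | zero
  }
  list(w = w, flags = flags)
}
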