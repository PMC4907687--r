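#' Tensor unfoldings and sign splitting
#'
#' The tri-factorization works on two matricized views of the trial tensor:
#' the temporal unfolding concatenates the `T x S` trial slices side by side
#' into a `T x (S*N)` matrix, the spatial unfolding stacks them into a
#' `(T*N) x S` matrix. Both use trial-major block order: block `n` is trial
#' `n`'s slice, with sensors (columns) respectively time frames (rows) in
#' their original order.
#'
#' @param x a [trial_tensor()] or an `N x T x S` array.
#' @return `unfold_temporal()`: a `T x (S*N)` matrix whose column block `n`
#'   (width `S`) is trial `n`'s `T x S` slice. `unfold_spatial()`: a
#'   `(T*N) x S` matrix whose row block `n` (height `T`) is the same slice.
#' @seealso [refold_temporal()], [refold_spatial()] for the inverses.
#' @examples
#' x <- array(1:8, c(2, 2, 2))           # 2 trials, T = 2, S = 2
#' unfold_temporal(x)
#' unfold_spatial(x)
#' @export
unfold_temporal <- function(x) {
  a <- tensor_data(x)
  d <- dim(a)
  m <- aperm(a, c(2L, 3L, 1L))          # (T, S, N)
  dim(m) <- c(d[2L], d[3L] * d[1L])
  m
}

#' @rdname unfold_temporal
#' @export
unfold_spatial <- function(x) {
  a <- tensor_data(x)
  d <- dim(a)
  m <- aperm(a, c(2L, 1L, 3L))          # (T, N, S)
  dim(m) <- c(d[2L] * d[1L], d[3L])
  m
}

tensor_data <- function(x) {
  if (inherits(x, "trial_tensor")) x$data
  else if (is.array(x) && length(dim(x)) == 3L) x
  else stop("expected a trial_tensor or a 3-d array")
}

#' Refold an unfolded matrix back into a trial array
#'
#' Inverses of [unfold_temporal()] and [unfold_spatial()] for the fixed
#' trial-major block order.
#'
#' @param m matrix produced by the corresponding unfolding.
#' @param n_trial number of trials encoded in the block structure.
#' @return an `N x T x S` array.
#' @export
refold_temporal <- function(m, n_trial) {
  stopifnot(is.matrix(m), ncol(m) %% n_trial == 0L)
  s <- ncol(m) %/% n_trial
  a <- m
  dim(a) <- c(nrow(m), s, n_trial)      # (T, S, N)
  aperm(a, c(3L, 1L, 2L))
}

#' @rdname refold_temporal
#' @export
refold_spatial <- function(m, n_trial) {
  stopifnot(is.matrix(m), nrow(m) %% n_trial == 0L)
  tt <- nrow(m) %/% n_trial
  a <- m
  dim(a) <- c(tt, n_trial, ncol(m))     # (T, N, S)
  aperm(a, c(2L, 1L, 3L))
}

#' Split a signed matrix into its positive and negative parts
#'
#' Returns the elementwise decomposition `A = pos - neg` with
#' `pos = (|A| + A)/2` and `neg = (|A| - A)/2`; both parts are non-negative
#' and have disjoint support. This is the sign-handling primitive of the
#' cluster-NMF multiplicative updates, which use the positive and negative
#' entries of the data separately instead of rectifying them away.
#'
#' @param a numeric matrix or array with finite entries.
#' @return list with non-negative components `pos` and `neg`.
#' @examples
#' split_signs(matrix(c(3, 0, -1, -2), 2))
#' @export
split_signs <- function(a) {
  if (!is.numeric(a) || any(!is.finite(a))) stop("entries must be finite numbers")
  list(pos = (abs(a) + a) / 2, neg = (abs(a) - a) / 2)
}
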