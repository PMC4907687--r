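# small seeded fixtures used across test files

# tiny random tensor (values signed, finite)
tiny_tensor <- function(n = 4, tt = 6, s = 3, seed = 1,
                        sampling_rate = 100, t0_index = 2) {
  set.seed(seed)
  trial_tensor(array(rnorm(n * tt * s), c(n, tt, s)),
               sampling_rate = sampling_rate, t0_index = t0_index)
}

# quick planted ground truth at very small scale for unit tests
quick_gt <- function(seed = 1, n_time = 80, n_sensor = 12, p = 2, l = 2,
                     trials_per_condition = 30, sigma_h = 0.5, snr = 5,
                     ...) {
  make_ground_truth(n_time = n_time, n_sensor = n_sensor, p = p, l = l,
                    peak_times_ms = c(50, 180, 260)[seq_len(p)],
                    bump_sd_ms = 20, sampling_rate = 250, t0_index = 10,
                    trials_per_condition = trials_per_condition,
                    sigma_h = sigma_h, snr = snr, seed = seed, ...)
}

# brute-force AUC oracle: count concordant positive/negative pairs, ties = 1/2
auc_bruteforce <- function(scores, labels) {
  y <- droplevels(as.factor(labels))
  pos <- which(y == levels(y)[2L]); neg <- which(y == levels(y)[1L])
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  tot / (length(pos) * length(neg))
}

# Kronecker least-squares oracle for the per-trial coefficient update:
# vec(M) ~ (t(W_spa) %x% W_tem) vec(H)
coef_kronecker_oracle <- function(w_tem, w_spa, m) {
  design <- kronecker(t(w_spa), w_tem)
  matrix(qr.solve(design, as.numeric(m)), ncol(w_tem), nrow(w_spa))
}

# exhaustive average-linkage (UPGMA) oracle on a small distance matrix:
# returns merge heights and the leaf partition after each merge
upgma_oracle <- function(d) {
  d <- as.matrix(d)
  m <- nrow(d)
  groups <- as.list(seq_len(m))
  heights <- numeric(0)
  partitions <- list()
  while (length(groups) > 1L) {
    k <- length(groups)
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
      dd <- mean(d[groups[[i]], groups[[j]]])
      if (dd < best_d) { best_d <- dd; best <- c(i, j) }
    }
    groups[[best[1L]]] <- c(groups[[best[1L]]], groups[[best[2L]]])
    groups[[best[2L]]] <- NULL
    heights <- c(heights, best_d)
    part <- integer(m)
    for (g in seq_along(groups)) part[groups[[g]]] <- g
    partitions[[length(partitions) + 1L]] <- part
  }
  list(heights = heights, partitions = partitions)
}

# canonical form of a partition for label-free comparison
canon_partition <- function(p) as.integer(factor(p, levels = unique(p)))
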