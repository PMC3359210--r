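# Independent brute-force oracles used to cross-check the vectorized
# implementations.

# per-pixel window vote count, the slow literal reading of the majority rule
mode_filter_oracle <- function(mask, r) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(255L, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    win <- mask[max(1, i - r):min(h, i + r), max(1, j - r):min(w, j + r)]
    n0 <- sum(win == 0L)
    out[i, j] <- if (n0 >= length(win) - n0) 0L else 255L
  }
  out
}

# exhaustive criterion scan: argmax over every candidate cutoff, smallest
# index on ties, evaluated through the scalar entropy_criterion (a separate
# code path from the cumulative-sum scan inside max_entropy_threshold)
brute_force_jstar <- function(p, criterion = "kapur") {
  H <- vapply(seq_along(p) - 1L, function(j)
    entropy_criterion(p, j, criterion), 0)
  which.max(H) - 1L
}

# random normalized histogram with a controlled number of occupied bins
random_histogram <- function(n_bins, n_occupied) {
  p <- numeric(n_bins)
  occ <- sample.int(n_bins, n_occupied)
  p[occ] <- stats::rexp(n_occupied)
  p / sum(p)
}

random_groups <- function(k = 3, n = 5, mean_spread = 2) {
  g <- lapply(seq_len(k), function(i) rnorm(n, mean = i * mean_spread))
  names(g) <- paste0("g", seq_len(k))
  g
}
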