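#' Intensity histogram of a stain channel
#'
#' @param channel numeric matrix of integral intensities in
#'   `[0, 2^bit_depth - 1]`.
#' @param bit_depth bit depth (8 or 16); the histogram has `2^bit_depth` bins.
#' @return object of class `intensity_histogram`: list with `counts`
#'   (length `2^bit_depth`), `p` (normalized to sum 1), `bit_depth`, `n`.
#' @export
intensity_histogram <- function(channel, bit_depth = 8L) {
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  v <- as.vector(channel)
  if (length(v) == 0L) stop("empty image", call. = FALSE)
  mx <- max_intensity(bit_depth)
  if (min(v) < 0 || max(v) > mx || any(v != floor(v)))
    stop(sprintf("channel values must be integers in [0, %d]", mx))
  counts <- tabulate(as.integer(v) + 1L, nbins = mx + 1L)
  structure(list(counts = counts, p = counts / sum(counts),
                 bit_depth = bit_depth, n = length(v)),
            class = "intensity_histogram")
}

# -Inf-safe x*log(x) with 0 log 0 = 0
xlogx <- function(x) ifelse(x > 0, x * log(x), 0)

#' Entropy criterion for a candidate threshold
#'
#' Scores the split of a normalized histogram `P` into the low class
#' `A = {0..j}` and its complement `B`. The default (`"kapur"`) is the
#' classical maximum-entropy criterion: the sum of the Shannon entropies of
#' the two normalized within-class distributions,
#' \deqn{\psi(j) = \hat H(A) + \hat H(B), \quad
#'   \hat H(A) = -\sum_{i \le j} \frac{p_i}{P(A)} \log\frac{p_i}{P(A)},}
#' maximized when each class is internally as uniform as possible.
#' `"printed"` is the alternative algebra
#' \eqn{-\log P(A) - \log P(B) - H(A) P(A) - H(B) P(B)} with
#' \eqn{H(A) = -\sum_{i \le j} p_i \log p_i} over the raw bin
#' probabilities. Splits with an empty class return `-Inf` and are never
#' selected. Natural logarithms throughout (the argmax is base-invariant).
#'
#' This scalar form recomputes the class sums directly and is deliberately
#' independent of the vectorized scan in [max_entropy_threshold()], so the
#' two can check each other.
#'
#' @param hist an `intensity_histogram`, or a bare probability vector.
#' @param j candidate cutoff, 0-based bin index.
#' @param criterion `"kapur"` (default) or `"printed"`.
#' @return scalar criterion value (`-Inf` for degenerate splits).
#' @export
entropy_criterion <- function(hist, j, criterion = c("kapur", "printed")) {
  criterion <- match.arg(criterion)
  p <- if (inherits(hist, "intensity_histogram")) hist$p else as.numeric(hist)
  nb <- length(p)
  if (j < 0 || j > nb - 1L) stop("j out of range")
  a <- p[seq_len(j + 1L)]
  b <- p[setdiff(seq_len(nb), seq_len(j + 1L))]
  PA <- sum(a); PB <- sum(b)
  if (PA <= 0 || PB <= 0) return(-Inf)
  if (criterion == "kapur") {
    qa <- a[a > 0] / PA
    qb <- b[b > 0] / PB
    -sum(qa * log(qa)) - sum(qb * log(qb))
  } else {
    HrA <- -sum(xlogx(a)); HrB <- -sum(xlogx(b))
    -log(PA) - log(PB) - HrA * PA - HrB * PB
  }
}

# Vectorized criterion curve over bins lo..hi (0-based) of the
# renormalized sub-histogram. Returns vector of length hi-lo+1.
criterion_curve <- function(p, lo, hi, criterion = "kapur") {
  q <- p[(lo:hi) + 1L]
  s <- sum(q)
  if (s <= 0) return(rep(-Inf, hi - lo + 1L))
  q <- q / s
  PA <- cumsum(q)
  PB <- 1 - PA
  cpl <- cumsum(xlogx(q))
  tot <- cpl[length(cpl)]
  H <- rep(-Inf, length(q))
  ok <- PA > 0 & PB > 0
  if (criterion == "kapur") {
    # hat H(A) = log PA - cpl/PA ; hat H(B) = log PB - (tot-cpl)/PB
    H[ok] <- (log(PA[ok]) - cpl[ok] / PA[ok]) +
             (log(PB[ok]) - (tot - cpl[ok]) / PB[ok])
  } else {
    HrA <- -cpl; HrB <- -(tot - cpl)
    H[ok] <- -log(PA[ok]) - log(PB[ok]) -
      HrA[ok] * PA[ok] - HrB[ok] * PB[ok]
  }
  H
}

#' Maximum-entropy threshold of a histogram
#'
#' Finds the cutoff `j*` maximizing the entropy criterion over
#' `j` in `[lo, hi]`; the histogram is restricted to `[lo, hi]` and
#' renormalized first (supporting the multistage sub-histogram searches).
#' Exact ties return the smallest `j`. If all mass sits in a single bin
#' the result is flagged degenerate and `j*` is that bin.
#'
#' @param hist an `intensity_histogram` or probability vector.
#' @param lo,hi inclusive 0-based search range (defaults: full range).
#' @param criterion `"kapur"` or `"printed"`; see [entropy_criterion()].
#' @return object of class `threshold_result`: `cutoff` (0-based `j*`),
#'   `criterion_curve` (values over `lo..hi`), `max_entropy`, `lo`, `hi`,
#'   `degenerate`, `criterion`.
#' @export
max_entropy_threshold <- function(hist, lo = NULL, hi = NULL,
                                  criterion = c("kapur", "printed")) {
  criterion <- match.arg(criterion)
  p <- if (inherits(hist, "intensity_histogram")) hist$p else as.numeric(hist)
  nb <- length(p)
  if (is.null(lo)) lo <- 0L
  if (is.null(hi)) hi <- nb - 1L
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (lo > hi || lo < 0L || hi > nb - 1L) stop("invalid [lo, hi] range")
  sub <- p[(lo:hi) + 1L]
  occ <- which(sub > 0)
  if (length(occ) == 0L)
    stop("no histogram mass in [lo, hi]", call. = FALSE)
  if (length(occ) == 1L) {
    return(structure(list(cutoff = lo + occ - 1L,
                          criterion_curve = rep(-Inf, hi - lo + 1L),
                          max_entropy = -Inf, lo = lo, hi = hi,
                          degenerate = TRUE, criterion = criterion),
                     class = "threshold_result"))
  }
  H <- criterion_curve(p, lo, hi, criterion)
  jstar <- lo + which.max(H) - 1L   # which.max takes the first maximum
  structure(list(cutoff = jstar, criterion_curve = H,
                 max_entropy = max(H), lo = lo, hi = hi,
                 degenerate = FALSE, criterion = criterion),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat("Maximum-entropy threshold: j* =", x$cutoff,
      if (x$degenerate) "(degenerate)", "\n")
  cat("  criterion:", x$criterion, " search range: [", x$lo, ",", x$hi,
      "]  max criterion:", format(x$max_entropy), "\n")
  invisible(x)
}

#' Binarize a channel at a cutoff
#'
#' Pixels with value `<= j` become foreground (coded 0); the rest become
#' background (coded `2^bit_depth - 1`). Stained pixels are dark in the
#' deconvolved channel, so foreground is the stained class.
#'
#' @param channel numeric matrix of intensities.
#' @param j cutoff (0-based intensity), or a `threshold_result`.
#' @param bit_depth bit depth.
#' @return integer matrix mask with values `{0, 2^bit_depth - 1}`.
#' @export
binarize <- function(channel, j, bit_depth = 8L) {
  if (inherits(j, "threshold_result")) j <- j$cutoff
  mx <- max_intensity(bit_depth)
  if (j < 0 || j > mx) stop("invalid cutoff")
  m <- ifelse(channel <= j, 0L, mx)
  matrix(as.integer(m), nrow(channel), ncol(channel))
}

validate_mask <- function(mask, bit_depth = 8L) {
  mx <- max_intensity(bit_depth)
  u <- unique(as.vector(mask))
  if (!all(u %in% c(0L, mx)))
    stop(sprintf("mask must be binary with values {0, %d}", mx), call. = FALSE)
  invisible(mask)
}

#' Multistage (eight-layer) entropy segmentation
#'
#' The IHC nuclear-segmentation extension of the single-stage threshold.
#' The intensity range is first split into four equal-width quarters
#' (fixed boundaries `j1 = 63`, `j3 = 127`, `j5 = 191` for 8-bit input);
#' within each quarter a maximum-entropy point (`j0, j2, j4, j6`) is
#' computed on the renormalized sub-histogram. The seven ordered
#' boundaries define up to eight intensity layers. A second-stage
#' maximum-entropy threshold on the histogram of layer labels selects the
#' cut layer; layers at or below it (high stain, low intensity) become
#' nuclei foreground. Quarters with no histogram mass, or with mass in a
#' single bin, contribute no boundary (the boundary collapses).
#'
#' @param channel numeric matrix of 8-bit intensities (stain channel;
#'   nuclei dark).
#' @param criterion `"kapur"` or `"printed"`.
#' @param low_is_foreground if `TRUE` (default) layers at or below the cut
#'   are foreground; set `FALSE` to invert the polarity.
#' @return object of class `multistage_result`: `mask` (values `{0, 255}`,
#'   foreground 0), `layers` (H x W integer layer indices, 0-based),
#'   `boundaries` (ordered intensity cutoffs), `layer_cut`,
#'   `stage_results` (the per-quarter `threshold_result`s), `degenerate`.
#' @export
multistage_segment <- function(channel, criterion = c("kapur", "printed"),
                               low_is_foreground = TRUE) {
  criterion <- match.arg(criterion)
  hist <- intensity_histogram(channel, 8L)
  quarters <- list(c(0L, 63L), c(64L, 127L), c(128L, 191L), c(192L, 255L))
  stage <- list()
  entropy_points <- integer(0)
  for (q in quarters) {
    if (sum(hist$p[(q[1]:q[2]) + 1L]) <= 0) next   # empty quarter: skip
    tr <- max_entropy_threshold(hist, q[1], q[2], criterion)
    stage[[length(stage) + 1L]] <- tr
    if (!tr$degenerate) entropy_points <- c(entropy_points, tr$cutoff)
  }
  boundaries <- sort(unique(c(entropy_points, 63L, 127L, 191L)))
  layers <- matrix(findInterval(channel, boundaries + 0.5),
                   nrow(channel), ncol(channel))
  n_layers <- length(boundaries) + 1L
  pl <- tabulate(as.vector(layers) + 1L, nbins = n_layers)
  pl <- pl / sum(pl)
  occupied <- sum(pl > 0)
  if (occupied < 2L) {
    mask <- matrix(255L, nrow(channel), ncol(channel))
    return(structure(list(mask = mask, layers = layers,
                          boundaries = boundaries, layer_cut = NA_integer_,
                          stage_results = stage, degenerate = TRUE),
                     class = "multistage_result"))
  }
  tr2 <- max_entropy_threshold(pl, 0L, n_layers - 1L, criterion)
  lcut <- tr2$cutoff
  fg <- if (low_is_foreground) layers <= lcut else layers > lcut
  mask <- matrix(ifelse(fg, 0L, 255L), nrow(channel), ncol(channel))
  structure(list(mask = mask, layers = layers, boundaries = boundaries,
                 layer_cut = lcut, stage_results = stage,
                 degenerate = FALSE),
            class = "multistage_result")
}

#' @export
print.multistage_result <- function(x, ...) {
  cat("Multistage entropy segmentation\n")
  cat("  boundaries:", paste(x$boundaries, collapse = ", "), "\n")
  cat("  layer cut:", x$layer_cut,
      if (x$degenerate) "(degenerate: empty foreground)", "\n")
  cat("  foreground pixels:", sum(x$mask == 0L), "/", length(x$mask), "\n")
  invisible(x)
}

#' Majority (mode) filter of a binary mask
#'
#' Replaces every pixel by the most frequent value in its
#' `(2r+1) x (2r+1)` neighbourhood; windows are clipped at the image
#' borders (no padding). Exact ties are broken toward foreground (0),
#' which favours recovering weak, low-contrast foreground pixels. Used to
#' remove spurious isolated detections after segmentation.
#'
#' @param mask binary matrix with values `{0, 2^bit_depth - 1}`,
#'   foreground 0.
#' @param r neighbourhood radius in pixels (default 3).
#' @param bit_depth bit depth (sets the background code).
#' @return filtered mask, same coding.
#' @export
mode_filter <- function(mask, r = 3L, bit_depth = 8L) {
  validate_mask(mask, bit_depth)
  if (r < 1L) stop("r must be >= 1")
  mx <- max_intensity(bit_depth)
  h <- nrow(mask); w <- ncol(mask)
  fg <- mask == 0L
  # summed-area table with a zero top row / left column
  cs <- matrix(apply(fg * 1, 2L, cumsum), h, w)       # cumsum down rows
  cs <- matrix(t(apply(cs, 1L, cumsum)), h, w)        # then across columns
  S <- matrix(0, h + 1L, w + 1L)
  S[-1L, -1L] <- cs
  r1 <- pmax(seq_len(h) - r, 1L); r2 <- pmin(seq_len(h) + r, h)
  c1 <- pmax(seq_len(w) - r, 1L); c2 <- pmin(seq_len(w) + r, w)
  cnt <- S[r2 + 1L, c2 + 1L, drop = FALSE] - S[r1, c2 + 1L, drop = FALSE] -
         S[r2 + 1L, c1, drop = FALSE] + S[r1, c1, drop = FALSE]
  win <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  out <- ifelse(2 * cnt >= win, 0L, mx)   # ties -> foreground
  matrix(as.integer(out), h, w)
}
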