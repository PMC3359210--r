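stain_magnitude <- function(channel, polarity, bit_depth = 8L) {
  if (polarity == "magnitude") max_intensity(bit_depth) - channel else channel
}

#' Cell-replication quantification score (pixel mean)
#'
#' The score `s` is the mean stain measure over segmented foreground
#' pixels (mask value 0). Because it is a mean, it is invariant to the
#' number of cells captured in the field of view, unlike summed-intensity
#' or cell-count measures. The stain channel is intensity-like (dark =
#' stained), so the default measure per pixel is the stain magnitude
#' `2^c - 1 - I_B`; higher staining then gives a higher score. Use
#' `polarity = "raw"` to average the channel values themselves.
#'
#' @param channel numeric matrix (deconvolved stain channel).
#' @param mask binary matrix, foreground 0.
#' @param polarity `"magnitude"` (default) or `"raw"`.
#' @param bit_depth bit depth.
#' @return object of class `quant_result`: `score`, `foreground_pixels`,
#'   `n_cells` (`NA` in pixel mode), `mode`, `empty`.
#' @export
quant_score <- function(channel, mask, polarity = c("magnitude", "raw"),
                        bit_depth = 8L) {
  polarity <- match.arg(polarity)
  if (!all(dim(channel) == dim(mask)))
    stop("channel and mask shapes differ", call. = FALSE)
  validate_mask(mask, bit_depth)
  fg <- mask == 0L
  npix <- sum(fg)
  if (npix == 0L)
    return(structure(list(score = NA_real_, foreground_pixels = 0L,
                          n_cells = NA_integer_, mode = "pixel-mean",
                          empty = TRUE), class = "quant_result"))
  vals <- stain_magnitude(channel[fg], polarity, bit_depth)
  structure(list(score = mean(vals), foreground_pixels = npix,
                 n_cells = NA_integer_, mode = "pixel-mean", empty = FALSE),
            class = "quant_result")
}

# 8-connectivity labeling of a logical matrix via the pixel adjacency graph
label_components_8 <- function(fg) {
  h <- nrow(fg); w <- ncol(fg)
  lab <- matrix(0L, h, w)
  idx <- which(fg)
  if (length(idx) == 0L) return(lab)
  ri <- ((idx - 1L) %% h) + 1L
  ci <- ((idx - 1L) %/% h) + 1L
  lin <- function(r, c) (c - 1L) * h + r
  edges <- list()
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    r2 <- ri + d[1]; c2 <- ci + d[2]
    ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w
    ok[ok] <- fg[lin(r2[ok], c2[ok])]
    edges[[length(edges) + 1L]] <- cbind(idx[ok], lin(r2[ok], c2[ok]))
  }
  em <- do.call(rbind, edges)
  map <- integer(h * w)
  map[idx] <- seq_along(idx)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(em) > 0L)
    g <- igraph::add_edges(g, as.vector(t(cbind(map[em[, 1]], map[em[, 2]]))))
  comp <- igraph::components(g)
  lab[idx] <- comp$membership
  # renumber consecutively in first-pixel order
  u <- unique(lab[idx])
  lab[idx] <- match(lab[idx], u)
  lab
}

#' Cell-mean quantification score
#'
#' Per-cell variant: connected foreground components (8-connectivity) are
#' treated as cells, and the score is the unweighted mean over cells of
#' each cell's mean stain measure, `D = (1/n) sum_cells mean(measure)`.
#' With a single cell this reduces to the pixel-mean score.
#'
#' @inheritParams quant_score
#' @return a `quant_result` with `mode = "cell-mean"` and `n_cells` set.
#' @export
cell_mean_score <- function(channel, mask, polarity = c("magnitude", "raw"),
                            bit_depth = 8L) {
  polarity <- match.arg(polarity)
  if (!all(dim(channel) == dim(mask)))
    stop("channel and mask shapes differ", call. = FALSE)
  validate_mask(mask, bit_depth)
  fg <- mask == 0L
  if (!any(fg))
    return(structure(list(score = NA_real_, foreground_pixels = 0L,
                          n_cells = 0L, mode = "cell-mean", empty = TRUE),
                     class = "quant_result"))
  lab <- label_components_8(fg)
  vals <- stain_magnitude(channel[fg], polarity, bit_depth)
  cell_means <- tapply(vals, lab[fg], mean)
  structure(list(score = mean(cell_means), foreground_pixels = sum(fg),
                 n_cells = length(cell_means), mode = "cell-mean",
                 empty = FALSE),
            class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  if (x$empty) {
    cat("Quantification score: empty foreground (score undefined)\n")
  } else {
    cat(sprintf("Quantification score (%s): %.4f over %d foreground pixels",
                x$mode, x$score, x$foreground_pixels))
    if (!is.na(x$n_cells)) cat(sprintf(" in %d cells", x$n_cells))
    cat("\n")
  }
  invisible(x)
}
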