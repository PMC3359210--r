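#' Read an RGB image from TIFF, PNG or JPEG
#'
#' Returns an H x W x 3 array of 8-bit values. Grayscale images are
#' replicated to 3 channels; an alpha channel is dropped. 16-bit TIFFs
#' are accepted and rescaled to 8-bit with a warning.
#'
#' @param path file path; format dispatched on the extension.
#' @return numeric H x W x 3 array with values in `[0, 255]`.
#' @export
read_rgb_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = {
      info <- tiff::readTIFF(path, info = TRUE)
      bps <- attr(info, "bits.per.sample")
      if (!is.null(bps) && bps > 8)
        warning("16-bit TIFF rescaled to 8-bit: ", path, call. = FALSE)
      info
    },
    jpg = , jpeg = jpeg::readJPEG(path),
    stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(x)) == 2L) x <- array(rep(x, 3L), c(dim(x), 3L))
  if (dim(x)[3] > 3L) x <- x[, , 1:3, drop = FALSE]
  if (dim(x)[3] == 2L) x <- array(rep(x[, , 1], 3L), c(dim(x)[1:2], 3L))
  array(pmin(pmax(round(x * 255), 0), 255), c(dim(x)[1:2], 3L))
}

#' Write / read a segmentation mask as single-channel PNG
#'
#' Masks persist with foreground coded 0 and background 255.
#'
#' @param mask binary matrix with values `{0, 255}`.
#' @param path output path (`.png`).
#' @return `write_mask` returns `path` invisibly; `read_mask` returns the
#'   integer mask matrix.
#' @export
write_mask <- function(mask, path) {
  validate_mask(mask, 8L)
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  m <- matrix(as.integer(round(x * 255)), nrow(x), ncol(x))
  validate_mask(m, 8L)
  m
}

#' Pixel-based precision / recall of a predicted mask
#'
#' Foreground (mask value 0) is the positive class. Precision is
#' `TP / (TP + FP)`, recall `TP / (TP + FN)`; each is `NA` (flagged) when
#' its denominator is zero.
#'
#' @param predicted,truth binary masks of identical shape, foreground 0.
#' @return list with `true_positives`, `false_positives`,
#'   `false_negatives`, `precision`, `recall`.
#' @export
evaluate_mask <- function(predicted, truth) {
  if (!all(dim(predicted) == dim(truth)))
    stop("mask shapes differ", call. = FALSE)
  validate_mask(predicted); validate_mask(truth)
  pf <- predicted == 0L; tf <- truth == 0L
  tp <- sum(pf & tf); fp <- sum(pf & !tf); fn <- sum(!pf & tf)
  list(true_positives = tp, false_positives = fp, false_negatives = fn,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

#' Pipeline configuration
#'
#' Bundles every tunable of the segmentation/quantification pipeline so a
#' run can be reproduced from its resolved config.
#'
#' @param mode `"live-cell"` (single-stage threshold on the blue-stain
#'   channel) or `"ihc"` (multistage segmentation of the Haematoxylin
#'   channel followed by the mode filter).
#' @param stain a `stain_system` or a built-in name; default follows
#'   `mode`.
#' @param stain_channel which deconvolved channel to segment; defaults to
#'   the first stain (`"blue"` for live-cell, `"haematoxylin"` for IHC).
#' @param criterion entropy criterion variant, `"kapur"` or `"printed"`.
#' @param mode_filter_radius radius of the majority filter applied in IHC
#'   mode (`0` disables it).
#' @param quant_mode `"pixel"` (default) or `"cell"`.
#' @param polarity stain measure for the score, `"magnitude"` or `"raw"`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("live-cell", "ihc"), stain = NULL,
                            stain_channel = NULL,
                            criterion = c("kapur", "printed"),
                            mode_filter_radius = 3L,
                            quant_mode = c("pixel", "cell"),
                            polarity = c("magnitude", "raw")) {
  mode <- match.arg(mode)
  criterion <- match.arg(criterion)
  quant_mode <- match.arg(quant_mode)
  polarity <- match.arg(polarity)
  if (is.null(stain))
    stain <- if (mode == "live-cell") "fluor-blue" else "ihc-hed"
  if (is.character(stain)) stain <- stain_system(stain)
  if (is.null(stain_channel)) stain_channel <- stain$stain_names[1]
  structure(list(mode = mode, stain = stain, stain_channel = stain_channel,
                 criterion = criterion,
                 mode_filter_radius = as.integer(mode_filter_radius),
                 quant_mode = quant_mode, polarity = polarity),
            class = "pipeline_config")
}

#' Segment one image with the configured pipeline
#'
#' Deconvolve, then threshold: single-stage maximum entropy for
#' live-cell mode; multistage eight-layer segmentation plus mode filter
#' for IHC mode.
#'
#' @param image H x W x 3 array (8-bit values).
#' @param config a [pipeline_config()].
#' @return list with `mask`, `channel` (the deconvolved stain channel),
#'   `cutoff` (j* for live-cell, the layer cut for IHC), `degenerate`.
#' @export
segment_image <- function(image, config = pipeline_config()) {
  chans <- deconvolve(image, config$stain)
  channel <- chans[[config$stain_channel]]
  if (is.null(channel))
    stop("stain channel '", config$stain_channel, "' not in system")
  if (config$mode == "live-cell") {
    tr <- max_entropy_threshold(intensity_histogram(channel),
                                criterion = config$criterion)
    mask <- if (tr$degenerate)
      matrix(255L, nrow(channel), ncol(channel))
    else binarize(channel, tr)
    list(mask = mask, channel = channel, cutoff = tr$cutoff,
         degenerate = tr$degenerate)
  } else {
    ms <- multistage_segment(channel, config$criterion)
    mask <- ms$mask
    if (!ms$degenerate && config$mode_filter_radius >= 1L)
      mask <- mode_filter(mask, config$mode_filter_radius)
    list(mask = mask, channel = channel, cutoff = ms$layer_cut,
         degenerate = ms$degenerate)
  }
}

#' Run the full quantification pipeline over a batch of images
#'
#' Per image: colour deconvolution, entropy-based segmentation
#' (single-stage for live-cell fields, multistage + mode filter for IHC),
#' then the quantification score over the segmented foreground. A failure
#' on one image is recorded and does not abort the batch.
#'
#' @param images character vector of file paths, or a list of H x W x 3
#'   arrays (named; names become image ids).
#' @param config a [pipeline_config()].
#' @param groups optional vector of condition labels, recycled against
#'   `images`, carried into the score table.
#' @return list with `scores` (data frame: `image_id`, `group`, `mode`,
#'   `score`, `foreground_pixels`, `n_cells`, `cutoff`, `degenerate`),
#'   `masks` (named list), `errors` (named list of condition messages),
#'   `config`.
#' @export
run_pipeline <- function(images, config = pipeline_config(), groups = NULL) {
  if (is.character(images)) {
    ids <- basename(images)
    get <- function(i) read_rgb_image(images[[i]])
    n <- length(images)
  } else {
    n <- length(images)
    ids <- names(images)
    if (is.null(ids)) ids <- sprintf("image%03d", seq_len(n))
    get <- function(i) images[[i]]
  }
  if (!is.null(groups)) groups <- rep_len(as.character(groups), n)
  rows <- list(); masks <- list(); errors <- list()
  for (i in seq_len(n)) {
    res <- tryCatch({
      img <- get(i)
      seg <- segment_image(img, config)
      qr <- if (config$quant_mode == "pixel")
        quant_score(seg$channel, seg$mask, config$polarity)
      else cell_mean_score(seg$channel, seg$mask, config$polarity)
      list(seg = seg, qr = qr)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[ids[i]]] <- conditionMessage(res)
      next
    }
    masks[[ids[i]]] <- res$seg$mask
    rows[[length(rows) + 1L]] <- data.frame(
      image_id = ids[i],
      group = if (is.null(groups)) NA_character_ else groups[i],
      mode = res$qr$mode,
      score = res$qr$score,
      foreground_pixels = res$qr$foreground_pixels,
      n_cells = res$qr$n_cells,
      cutoff = res$seg$cutoff,
      degenerate = res$seg$degenerate || res$qr$empty,
      stringsAsFactors = FALSE)
  }
  scores <- if (length(rows)) do.call(rbind, rows) else
    data.frame(image_id = character(), group = character(),
               mode = character(), score = numeric(),
               foreground_pixels = integer(), n_cells = integer(),
               cutoff = integer(), degenerate = logical(),
               stringsAsFactors = FALSE)
  list(scores = scores, masks = masks, errors = errors, config = config)
}
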