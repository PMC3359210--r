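#' Specification for a synthetic fluorescent live-cell field
#'
#' Describes a gray-background fluorescence field containing
#' non-overlapping elliptical cells whose blue-stain level is drawn per
#' cell from a normal distribution. The defaults model the study
#' conditions the package targets: a mid-gray background (empty regions
#' render gray in fluorescence capture), moderate cell density, and three
#' condition groups distinguished only by their mean stain magnitude (the
#' conventional low/mid/high settings are 30, 60 and 90; see
#' [make_fluor_field()]).
#'
#' @param image_size `c(H, W)` in pixels.
#' @param n_cells number of cells to place.
#' @param cell_radius_range `c(min, max)` semi-axis length in pixels.
#' @param stain_mean,stain_sd per-cell stain magnitude distribution
#'   (intensity units on the 8-bit scale).
#' @param background_gray background intensity (0-255, exclusive).
#' @param noise_sd additive Gaussian pixel noise, intensity units.
#' @param seed RNG seed; generation is bit-reproducible given the spec.
#' @return object of class `fluor_field_spec`.
#' @export
fluor_field_spec <- function(image_size = c(256L, 256L), n_cells = 30L,
                             cell_radius_range = c(6, 12),
                             stain_mean = 60, stain_sd = 8,
                             background_gray = 200, noise_sd = 3,
                             seed = 1L) {
  stopifnot(length(image_size) == 2L, all(image_size >= 8),
            n_cells >= 0L, all(cell_radius_range > 0),
            diff(cell_radius_range) >= 0, stain_mean > 0, stain_sd >= 0,
            background_gray > 0, background_gray < 255, noise_sd >= 0)
  structure(list(image_size = as.integer(image_size),
                 n_cells = as.integer(n_cells),
                 cell_radius_range = cell_radius_range,
                 stain_mean = stain_mean, stain_sd = stain_sd,
                 background_gray = background_gray, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "fluor_field_spec")
}

# place non-overlapping ellipses by rejection sampling; returns mask and a
# per-pixel payload matrix filled with each cell's value
place_ellipses <- function(h, w, n, radius_range, values) {
  mask <- matrix(FALSE, h, w)
  payload <- matrix(0, h, w)
  centers <- matrix(0, 0, 3)   # cx, cy, max extent
  placed <- 0L; tries <- 0L
  max_tries <- 400L * max(n, 1L)
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("infeasible packing: could not place all cells without overlap",
           call. = FALSE)
    ry <- stats::runif(1, radius_range[1], radius_range[2])
    rx <- ry * stats::runif(1, 0.7, 1.3)          # mild eccentricity jitter
    ext <- max(rx, ry)
    cx <- stats::runif(1, ext + 2, h - ext - 2)
    cy <- stats::runif(1, ext + 2, w - ext - 2)
    if (nrow(centers) > 0 &&
        any(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2) <
            centers[, 3] + ext + 1))
      next
    placed <- placed + 1L
    centers <- rbind(centers, c(cx, cy, ext))
    xs <- max(1L, floor(cx - rx)):min(h, ceiling(cx + rx))
    ys <- max(1L, floor(cy - ry)):min(w, ceiling(cy + ry))
    inside <- outer(((xs - cx) / rx)^2, ((ys - cy) / ry)^2, `+`) <= 1
    mask[xs, ys][inside] <- TRUE
    payload[xs, ys][inside] <- values[placed]
  }
  list(mask = mask, payload = payload, n_placed = placed)
}

#' Generate a synthetic fluorescent live-cell field
#'
#' Renders elliptical cells over a uniform gray background. Each cell
#' draws a stain magnitude `v ~ N(stain_mean, stain_sd)` (truncated to
#' `[1, 250]`) and absorbs multiplicatively along the blue-stain OD
#' vector of the `"fluor-blue"` system: the cell's RGB is
#' `bg * exp(-a * v_blue)` with `a = -ln(1 - v/255)`, so the
#' deconvolution stage genuinely has to unmix the stain, and stained
#' pixels are always darker than background in the blue channel.
#' Additive Gaussian noise is applied after quantization and clipped to
#' range. The returned `true_score` is the pixel-mean quantification
#' score computed on the noiseless deconvolved channel with the
#' ground-truth mask (so fixture and scorer are self-consistent by
#' construction).
#'
#' @param spec a [fluor_field_spec()].
#' @return list with `image` (H x W x 3, 8-bit values), `mask`
#'   (ground-truth mask, foreground 0), `true_score` (`NA` when
#'   `n_cells = 0`), `clean_image` (noiseless), `spec`.
#' @export
make_fluor_field <- function(spec = fluor_field_spec()) {
  stopifnot(inherits(spec, "fluor_field_spec"))
  set.seed(spec$seed)
  h <- spec$image_size[1]; w <- spec$image_size[2]
  sys <- stain_system("fluor-blue")
  v_blue <- sys$od_vectors[1, ]
  vals <- pmin(pmax(stats::rnorm(spec$n_cells, spec$stain_mean,
                                 spec$stain_sd), 1), 250)
  pl <- place_ellipses(h, w, spec$n_cells, spec$cell_radius_range, vals)
  conc <- -log(1 - pl$payload / 255)
  od_bg <- log(255 / spec$background_gray)
  clean <- array(0, c(h, w, 3))
  for (ch in 1:3)
    clean[, , ch] <- 255 * exp(-(od_bg + conc * v_blue[ch]))
  clean <- array(pmin(pmax(round(clean), 0), 255), c(h, w, 3))
  noisy <- clean + array(stats::rnorm(h * w * 3, 0, spec$noise_sd),
                         c(h, w, 3))
  noisy <- array(pmin(pmax(round(noisy), 0), 255), c(h, w, 3))
  mask <- matrix(ifelse(pl$mask, 0L, 255L), h, w)
  true_score <- NA_real_
  if (spec$n_cells > 0L) {
    chan <- deconvolve(clean, sys)[["blue"]]
    true_score <- quant_score(chan, mask)$score
  }
  list(image = noisy, mask = mask, true_score = true_score,
       clean_image = clean, spec = spec)
}

#' Specification for a synthetic IHC composite
#'
#' Describes a two-stain immunohistochemistry tile built with the
#' Lambert-Beer forward model and the Haematoxylin/Eosin/DAB OD vectors:
#' nuclei receive a Haematoxylin concentration (plus optionally DAB
#' chromogen), and the whole field carries a weak diffuse counterstain.
#'
#' @param image_size `c(H, W)`.
#' @param n_nuclei number of nuclei.
#' @param nucleus_radius_range `c(min, max)` semi-axis in pixels.
#' @param haematoxylin_conc_range per-nucleus concentration, drawn
#'   uniformly.
#' @param dab_conc_range per-nucleus DAB concentration, drawn uniformly
#'   (set `c(0, 0)` for a pure-Haematoxylin tile).
#' @param counterstain_background_conc diffuse Haematoxylin concentration
#'   outside nuclei.
#' @param noise_sd additive Gaussian RGB noise, intensity units.
#' @param seed RNG seed.
#' @return object of class `ihc_composite_spec`.
#' @export
ihc_composite_spec <- function(image_size = c(256L, 256L), n_nuclei = 40L,
                               nucleus_radius_range = c(5, 10),
                               haematoxylin_conc_range = c(0.5, 0.9),
                               dab_conc_range = c(0, 0.3),
                               counterstain_background_conc = 0.05,
                               noise_sd = 2, seed = 1L) {
  stopifnot(length(image_size) == 2L, all(image_size >= 8), n_nuclei >= 0L,
            all(nucleus_radius_range > 0),
            all(haematoxylin_conc_range >= 0), all(dab_conc_range >= 0),
            counterstain_background_conc >= 0, noise_sd >= 0)
  structure(list(image_size = as.integer(image_size),
                 n_nuclei = as.integer(n_nuclei),
                 nucleus_radius_range = nucleus_radius_range,
                 haematoxylin_conc_range = haematoxylin_conc_range,
                 dab_conc_range = dab_conc_range,
                 counterstain_background_conc = counterstain_background_conc,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "ihc_composite_spec")
}

#' Generate a synthetic IHC composite with a known nuclear mask
#'
#' RGB values follow the Lambert-Beer forward model
#' `I = 255 exp(-(c_H v_H + c_D v_D))` with the normalized Haematoxylin
#' and DAB OD vectors of the `"ihc-hed"` system; nuclei are
#' non-overlapping ellipses, the background carries the diffuse
#' counterstain concentration. Noise is added after quantization.
#'
#' @param spec an [ihc_composite_spec()].
#' @return list with `image`, `mask` (foreground 0), `conc_h`, `conc_d`
#'   (ground-truth per-pixel concentration maps, noiseless), `spec`.
#' @export
make_ihc_composite <- function(spec = ihc_composite_spec()) {
  stopifnot(inherits(spec, "ihc_composite_spec"))
  set.seed(spec$seed)
  h <- spec$image_size[1]; w <- spec$image_size[2]
  sys <- stain_system("ihc-hed")
  v_h <- sys$od_vectors[1, ]; v_d <- sys$od_vectors[3, ]
  ch_vals <- stats::runif(spec$n_nuclei, spec$haematoxylin_conc_range[1],
                          spec$haematoxylin_conc_range[2])
  cd_vals <- stats::runif(spec$n_nuclei, spec$dab_conc_range[1],
                          spec$dab_conc_range[2])
  pl_h <- place_ellipses(h, w, spec$n_nuclei, spec$nucleus_radius_range,
                         seq_len(max(spec$n_nuclei, 1L)))
  idx <- pl_h$payload          # cell index per pixel (0 = background)
  conc_h <- matrix(spec$counterstain_background_conc, h, w)
  conc_d <- matrix(0, h, w)
  fg <- idx > 0
  conc_h[fg] <- ch_vals[idx[fg]]
  conc_d[fg] <- cd_vals[idx[fg]]
  img <- array(0, c(h, w, 3))
  for (ch in 1:3)
    img[, , ch] <- 255 * exp(-(conc_h * v_h[ch] + conc_d * v_d[ch]))
  img <- array(pmin(pmax(round(img), 0), 255), c(h, w, 3))
  img <- img + array(stats::rnorm(h * w * 3, 0, spec$noise_sd), c(h, w, 3))
  img <- array(pmin(pmax(round(img), 0), 255), c(h, w, 3))
  mask <- matrix(ifelse(pl_h$mask, 0L, 255L), h, w)
  list(image = img, mask = mask, conc_h = conc_h, conc_d = conc_d,
       spec = spec)
}
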