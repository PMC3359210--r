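max_intensity <- function(bit_depth) 2L^bit_depth - 1L

validate_rgb <- function(image, bit_depth = 8L) {
  if (!bit_depth %in% c(8L, 16L))
    stop("bit_depth must be 8 or 16", call. = FALSE)
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("image must be an H x W x 3 array", call. = FALSE)
  if (dim(image)[1] < 1L || dim(image)[2] < 1L)
    stop("image must have at least one pixel", call. = FALSE)
  mx <- max_intensity(bit_depth)
  if (min(image) < 0 || max(image) > mx)
    stop(sprintf("pixel values must lie in [0, %d]", mx), call. = FALSE)
  invisible(image)
}

#' Convert an RGB image to optical density
#'
#' Applies the Lambert-Beer relation channel-wise. With incident intensity
#' \eqn{I_0} and transmitted intensity \eqn{I_1}, the optical density is
#' \eqn{OD = \ln(I_0 / I_1)}, which is non-negative and linear in the amount
#' of stain. Zero intensities are clamped to 1 before the logarithm so the
#' OD stays bounded.
#'
#' @param image numeric array, H x W x 3, intensities in `[0, 2^bit_depth - 1]`.
#' @param bit_depth channel bit depth, 8 (default) or 16.
#' @param i0 incident (background) intensity per channel; scalar or length-3.
#'   Defaults to `2^bit_depth - 1` (clean white/transmitted background).
#' @return numeric array H x W x 3 of optical densities (dimensionless, >= 0
#'   wherever `i0` is the channel maximum).
#' @export
rgb_to_od <- function(image, bit_depth = 8L, i0 = NULL) {
  validate_rgb(image, bit_depth)
  if (is.null(i0)) i0 <- rep(max_intensity(bit_depth), 3L)
  if (length(i0) == 1L) i0 <- rep(i0, 3L)
  stopifnot(length(i0) == 3L, all(i0 > 0))
  od <- image
  for (ch in 1:3) od[, , ch] <- log(i0[ch] / pmax(image[, , ch], 1))
  od
}

#' Build a stain system for colour deconvolution
#'
#' Each stain is characterised by a 3-vector of optical densities (its
#' response in the R, G, B channels). Rows are normalized to unit Euclidean
#' length; a 2-stain system is completed to a 3 x 3 basis with the unit
#' cross product of the two rows (the completion channel carries residual,
#' unmodelled absorption). The deconvolution matrix `K` is the inverse of
#' the completed, normalized matrix, so that per-pixel stain amounts are
#' `C = D K` for a row vector `D` of ODs.
#'
#' @param od_vectors matrix with 2 or 3 rows and 3 columns (one OD vector
#'   per stain), or a list of 3-vectors.
#' @param names character vector of stain labels, one per row.
#' @return an object of class `stain_system` with elements `stain_names`,
#'   `od_vectors` (normalized, completed), `K`, `n_stains`, `completed`.
#' @export
build_stain_system <- function(od_vectors, names = NULL) {
  if (is.list(od_vectors)) od_vectors <- do.call(rbind, od_vectors)
  od_vectors <- as.matrix(od_vectors)
  if (ncol(od_vectors) != 3L || !nrow(od_vectors) %in% c(2L, 3L))
    stop("od_vectors must have 2 or 3 rows of 3 values", call. = FALSE)
  if (is.null(names)) names <- paste0("stain", seq_len(nrow(od_vectors)))
  stopifnot(length(names) == nrow(od_vectors))
  lens <- sqrt(rowSums(od_vectors^2))
  if (any(lens < 1e-12))
    stop("stain OD vectors must be nonzero", call. = FALSE)
  A <- od_vectors / lens
  n_stains <- nrow(A)
  completed <- FALSE
  if (n_stains == 2L) {
    cr <- c(A[1, 2] * A[2, 3] - A[1, 3] * A[2, 2],
            A[1, 3] * A[2, 1] - A[1, 1] * A[2, 3],
            A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1])
    ncr <- sqrt(sum(cr^2))
    if (ncr < 1e-8)
      stop("stain vectors are collinear: unseparable stain system", call. = FALSE)
    A <- rbind(A, cr / ncr)
    completed <- TRUE
  }
  if (abs(det(A)) < 1e-8)
    stop("stain vectors are linearly dependent: unseparable stain system",
         call. = FALSE)
  K <- solve(A)
  structure(list(stain_names = names, od_vectors = A, K = K,
                 n_stains = n_stains, completed = completed),
            class = "stain_system")
}

#' @export
print.stain_system <- function(x, ...) {
  cat("Stain system (", x$n_stains, " stain",
      if (x$n_stains > 1) "s", if (x$completed) ", completed to 3x3",
      ")\n", sep = "")
  rn <- x$stain_names
  if (x$completed) rn <- c(rn, "(completion)")
  A <- x$od_vectors
  dimnames(A) <- list(rn, c("R", "G", "B"))
  print(round(A, 4))
  invisible(x)
}

#' Built-in stain systems
#'
#' `"fluor-blue"` is the two-row system for fluorescent live-cell images:
#' the first row is the blue-stain OD vector (0.6443, 0.7167, 0.2669) and
#' the second the background-colour vector (0.1754, 0.9723, 0.1546).
#' `"ihc-hed"` is the Haematoxylin / Eosin / DAB system used for IHC
#' nuclear segmentation (rows 0.65/0.704/0.286, 0.072/0.99/0.105,
#' 0.268/0.57/0.776).
#'
#' @param name `"fluor-blue"` or `"ihc-hed"`.
#' @return a `stain_system`.
#' @export
stain_system <- function(name = c("fluor-blue", "ihc-hed")) {
  name <- match.arg(name)
  switch(name,
    "fluor-blue" = build_stain_system(
      rbind(c(0.6443, 0.7167, 0.2669),
            c(0.1754, 0.9723, 0.1546)),
      c("blue", "background")),
    "ihc-hed" = build_stain_system(
      rbind(c(0.650, 0.704, 0.286),
            c(0.072, 0.990, 0.105),
            c(0.268, 0.570, 0.776)),
      c("haematoxylin", "eosin", "dab")))
}

#' Read a stain system from a plain-text config
#'
#' One stain per line: `name r g b` (whitespace-separated). Lines starting
#' with `#` are ignored.
#'
#' @param path file path.
#' @return a `stain_system`.
#' @export
read_stain_system <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) < 2L) stop("stain config needs at least 2 stains")
  parts <- strsplit(lines, "[[:space:]]+")
  nm <- vapply(parts, `[`, "", 1L)
  vecs <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  if (anyNA(vecs)) stop("malformed stain config: expected 'name r g b' rows")
  build_stain_system(vecs, nm)
}

#' Separate stain contributions by colour deconvolution
#'
#' Converts the image to optical density and applies the deconvolution
#' matrix per pixel, `C = D K`, yielding the amount of each stain. By
#' default each stain amount is re-expressed on the intensity scale,
#' `v = (2^c - 1) exp(-C_i)`, so that `2^c - 1` means "no stain" and
#' stained pixels are dark, matching the foreground-is-low coding used by
#' the segmentation stage. Raw concentrations are available with
#' `output = "concentration"`.
#'
#' @param image numeric H x W x 3 array.
#' @param system a `stain_system`.
#' @param bit_depth channel bit depth (8 or 16).
#' @param i0 incident intensity per channel (default channel maximum).
#' @param output `"intensity"` (default) or `"concentration"`.
#' @return named list with one H x W matrix per named stain (the synthetic
#'   completion channel of a 2-stain system is discarded).
#' @export
deconvolve <- function(image, system, bit_depth = 8L, i0 = NULL,
                       output = c("intensity", "concentration")) {
  output <- match.arg(output)
  if (!inherits(system, "stain_system"))
    stop("system must be a stain_system", call. = FALSE)
  od <- rgb_to_od(image, bit_depth, i0)
  h <- dim(image)[1]; w <- dim(image)[2]
  D <- matrix(od, ncol = 3L)           # rows = pixels, cols = channels
  C <- D %*% system$K                  # rows = pixels, cols = stains
  mx <- max_intensity(bit_depth)
  out <- vector("list", system$n_stains)
  names(out) <- system$stain_names
  for (i in seq_len(system$n_stains)) {
    ci <- matrix(C[, i], h, w)
    out[[i]] <- if (output == "concentration") ci else
      matrix(pmin(pmax(round(mx * exp(-ci)), 0), mx), h, w)
  }
  out
}
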