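#' Sample random point locations in an image
#'
#' Draws `n` distinct pixel locations uniformly at random, the sampling
#' scheme behind random point annotation of photoquadrats.
#'
#' @param image_width,image_height image dimensions in pixels.
#' @param n number of points.
#' @param rng_seed integer seed.
#' @return data frame with 0-based integer columns `row`, `col`.
#' @export
sample_points <- function(image_width, image_height, n, rng_seed = 1L) {
  stopifnot(image_width >= 1L, image_height >= 1L, n >= 1L)
  npx <- as.double(image_width) * as.double(image_height)
  if (n > npx) {
    abort_reefpoint("n exceeds the number of pixels", "validation_error")
  }
  idx <- with_private_seed(rng_seed, sample.int(npx, n)) - 1L
  data.frame(row = as.integer(idx %/% image_width),
             col = as.integer(idx %% image_width))
}

#' Default patch encoder configuration
#'
#' The encoder summarizes the color and texture of a square patch centered
#' on an annotation point: per-channel mean, variance and an intensity
#' histogram capture color; histograms of oriented gradient energy at two
#' smoothing scales capture texture. Alternative encoders can be supplied
#' anywhere an `encoder` argument is taken, as long as they carry
#' `encoder_id`, `dim`, and an `encode(patch)` function.
#'
#' @param patch_size side length of the square patch in pixels (default 224;
#'   reduce for small imagery).
#' @param color_bins histogram bins per color channel.
#' @param orient_bins orientation bins for the gradient-energy histogram.
#' @param scales number of dyadic smoothing scales for the texture part.
#' @return an object of class `patch_encoder` with fields `encoder_id`,
#'   `dim`, `patch_size` and `encode`.
#' @export
default_encoder <- function(patch_size = 224L, color_bins = 8L,
                            orient_bins = 6L, scales = 2L) {
  stopifnot(patch_size >= 3L, color_bins >= 1L, orient_bins >= 1L,
            scales >= 1L)
  dim <- 3L * (2L + color_bins) + orient_bins * scales
  enc <- list(
    encoder_id = sprintf("colorstat-gradhist/p%d-c%d-o%d-s%d",
                         patch_size, color_bins, orient_bins, scales),
    dim = dim,
    patch_size = as.integer(patch_size),
    color_bins = as.integer(color_bins),
    orient_bins = as.integer(orient_bins),
    scales = as.integer(scales)
  )
  enc$encode <- function(patch) encode_patch(patch, enc)
  structure(enc, class = "patch_encoder")
}

# Mirror-reflect an index vector into [1, n] (half-sample symmetric).
reflect_index <- function(idx, n) {
  if (n == 1L) return(rep(1L, length(idx)))
  period <- 2L * n
  m <- ((idx - 1L) %% period + period) %% period
  as.integer(ifelse(m < n, m + 1L, period - m))
}

#' Extract a square patch around a point
#'
#' Out-of-bounds pixels are filled by mirror reflection at the image edges.
#'
#' @param image an `height x width x 3` array with values in `[0, 1]`.
#' @param row,col 0-based center coordinates.
#' @param patch_size patch side length.
#' @return a `patch_size x patch_size x 3` array.
#' @export
extract_patch <- function(image, row, col, patch_size) {
  check_rgb(image)
  h <- dim(image)[1L]; w <- dim(image)[2L]
  if (row < 0L || row >= h || col < 0L || col >= w) {
    abort_reefpoint("point out of image bounds", "validation_error")
  }
  half <- patch_size %/% 2L
  rows <- reflect_index((row + 1L) + seq.int(-half, length.out = patch_size), h)
  cols <- reflect_index((col + 1L) + seq.int(-half, length.out = patch_size), w)
  image[rows, cols, , drop = FALSE]
}

check_rgb <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3L] != 3L ||
      dim(image)[1L] < 1L || dim(image)[2L] < 1L) {
    abort_reefpoint("image must be a non-empty height x width x 3 RGB array",
                    "validation_error")
  }
}

box_blur2 <- function(m) {
  # 2x2 mean filter used for dyadic scale generation; keeps dimensions even.
  h <- dim(m)[1L]; w <- dim(m)[2L]
  h2 <- h %/% 2L; w2 <- w %/% 2L
  if (h2 < 2L || w2 < 2L) return(NULL)
  m <- m[seq_len(2L * h2), seq_len(2L * w2), drop = FALSE]
  0.25 * (m[seq(1L, 2L * h2, 2L), seq(1L, 2L * w2, 2L), drop = FALSE] +
          m[seq(2L, 2L * h2, 2L), seq(1L, 2L * w2, 2L), drop = FALSE] +
          m[seq(1L, 2L * h2, 2L), seq(2L, 2L * w2, 2L), drop = FALSE] +
          m[seq(2L, 2L * h2, 2L), seq(2L, 2L * w2, 2L), drop = FALSE])
}

grad_orientation_energy <- function(gray, orient_bins) {
  h <- dim(gray)[1L]; w <- dim(gray)[2L]
  gx <- gray[, c(2:w, w), drop = FALSE] - gray[, c(1L, 1:(w - 1L)), drop = FALSE]
  gy <- gray[c(2:h, h), , drop = FALSE] - gray[c(1L, 1:(h - 1L)), , drop = FALSE]
  energy <- gx^2 + gy^2
  theta <- atan2(gy, gx) %% pi
  bin <- pmin(orient_bins, floor(theta / pi * orient_bins) + 1L)
  out <- numeric(orient_bins)
  nz <- energy > 0
  if (any(nz)) {
    agg <- tapply(energy[nz], bin[nz], sum)
    out[as.integer(names(agg))] <- agg
  }
  out / length(energy)
}

encode_patch <- function(patch, enc) {
  vals <- numeric(0)
  breaks <- seq(0, 1, length.out = enc$color_bins + 1L)
  for (ch in 1:3) {
    x <- as.vector(patch[, , ch])
    hst <- hist(pmin(pmax(x, 0), 1), breaks = breaks, plot = FALSE)$counts
    vals <- c(vals, mean(x), stats::var(x), hst / length(x))
  }
  gray <- 0.299 * patch[, , 1L] + 0.587 * patch[, , 2L] + 0.114 * patch[, , 3L]
  level <- gray
  for (s in seq_len(enc$scales)) {
    vals <- c(vals, grad_orientation_energy(level, enc$orient_bins))
    nxt <- box_blur2(level)
    level <- if (is.null(nxt)) level else nxt
  }
  stopifnot(length(vals) == enc$dim)
  vals
}

#' Encode the patch around one annotation point as a feature vector
#'
#' @param image RGB array (`height x width x 3`, values in `[0, 1]`).
#' @param point length-2 vector or list `(row, col)`, 0-based.
#' @param encoder a `patch_encoder` (see [default_encoder()]).
#' @return numeric feature vector of length `encoder$dim`, with attributes
#'   `encoder_id` and `dim`.
#' @export
extract_features <- function(image, point, encoder = default_encoder()) {
  stopifnot(inherits(encoder, "patch_encoder"))
  point <- as.integer(unlist(point)[1:2])
  patch <- extract_patch(image, point[1L], point[2L], encoder$patch_size)
  v <- encoder$encode(patch)
  if (!all(is.finite(v))) {
    abort_reefpoint("non-finite feature values", "validation_error")
  }
  structure(v, encoder_id = encoder$encoder_id, dim_declared = encoder$dim)
}

#' Encode patches for every point of an annotation table
#'
#' Convenience wrapper producing the keyed feature matrix consumed by
#' [train_classifier()] and [score_points()].
#'
#' @param images named list of RGB arrays, names matching `image_id`.
#' @param points data frame with columns `image_id`, `point_index`, `row`,
#'   `col` (an [annotation_set] works).
#' @param encoder a `patch_encoder`.
#' @return list with `keys` (data frame `image_id`, `point_index`),
#'   `features` (numeric matrix, one row per key) and `encoder_id`.
#' @export
extract_feature_table <- function(images, points,
                                  encoder = default_encoder()) {
  stopifnot(is.list(images), !is.null(names(images)))
  miss <- setdiff(unique(points$image_id), names(images))
  if (length(miss)) {
    abort_reefpoint(sprintf("images not supplied: %s",
                            paste(miss, collapse = ", ")),
                    "validation_error")
  }
  feats <- matrix(NA_real_, nrow(points), encoder$dim)
  for (i in seq_len(nrow(points))) {
    feats[i, ] <- extract_features(images[[points$image_id[i]]],
                                   c(points$row[i], points$col[i]), encoder)
  }
  list(keys = data.frame(image_id = as.character(points$image_id),
                         point_index = as.integer(points$point_index)),
       features = feats,
       encoder_id = encoder$encoder_id)
}

#' Read an 8-bit RGB PNG image
#'
#' Grayscale images are expanded to RGB; an alpha channel, if present, is
#' dropped.
#'
#' @param path path to a PNG file.
#' @return `height x width x 3` array with values in `[0, 1]`.
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) {
    img <- array(rep(img, 3L), c(dim(img), 3L))
  } else if (dim(img)[3L] >= 3L) {
    img <- img[, , 1:3, drop = FALSE]
  } else {
    abort_reefpoint("unsupported channel count", "format_error")
  }
  img
}

#' Write an RGB array as a PNG image
#'
#' @param image `height x width x 3` array in `[0, 1]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  check_rgb(image)
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}
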