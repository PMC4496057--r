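#' Default class palette for synthetic mosaics
#'
#' Each class has a base RGB color and an oriented sinusoidal texture
#' (spatial frequency in cycles/pixel, orientation in radians, amplitude).
#' The default four classes are well separated in color and texture so the
#' patch encoder's task is feasible but not trivial; `separation` in
#' `[0, 1]` scales how far the base colors sit apart (1 = default spread).
#'
#' @param n_classes number of classes (2 to 6).
#' @param separation color-separation multiplier.
#' @return data frame with columns `label`, `r`, `g`, `b`, `freq`,
#'   `orientation`, `amplitude`.
#' @export
default_palette <- function(n_classes = 4L, separation = 1) {
  stopifnot(n_classes >= 2L, n_classes <= 6L, separation >= 0)
  base <- matrix(c(
    0.75, 0.45, 0.35,   # coral-like pink/brown
    0.35, 0.60, 0.30,   # algal green
    0.80, 0.75, 0.55,   # sand beige
    0.45, 0.40, 0.65,   # encrusting purple
    0.25, 0.35, 0.55,   # deep blue
    0.60, 0.60, 0.60    # grey rubble
  ), ncol = 3L, byrow = TRUE)[seq_len(n_classes), , drop = FALSE]
  center <- colMeans(base)
  cols <- sweep(sweep(base, 2L, center), 1:2, separation, "*")
  cols <- sweep(cols, 2L, center, "+")
  data.frame(
    label = paste0("class", seq_len(n_classes)),
    r = cols[, 1L], g = cols[, 2L], b = cols[, 3L],
    freq = seq(0.08, 0.3, length.out = n_classes),
    orientation = seq(0, pi * (n_classes - 1) / n_classes,
                      length.out = n_classes),
    amplitude = rep(0.08, n_classes)
  )
}

#' Specification of a synthetic textured mosaic
#'
#' A mosaic stands in for a photoquadrat: the canvas is partitioned into
#' contiguous regions (nearest-seed / Voronoi cells), each region is
#' assigned a substratum class and rendered with that class's base color
#' plus an oriented sinusoidal texture and additive Gaussian noise. The
#' exact class of every pixel is retained as a ground-truth label map.
#'
#' @param width,height canvas size in pixels.
#' @param n_regions number of Voronoi regions (at least the number of
#'   classes; each class is guaranteed at least one region).
#' @param palette class palette, see [default_palette()].
#' @param noise_sd standard deviation of the additive pixel noise.
#' @param rng_seed integer seed.
#' @return an object of class `mosaic_spec`.
#' @export
mosaic_spec <- function(width = 128L, height = 128L, n_regions = 12L,
                        palette = default_palette(), noise_sd = 0.02,
                        rng_seed = 1L) {
  stopifnot(width >= 1L, height >= 1L)
  if (n_regions < 1L) {
    abort_reefpoint("need at least one region", "validation_error")
  }
  if (n_regions < nrow(palette)) {
    abort_reefpoint("n_regions must be at least the number of classes",
                    "validation_error")
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_regions = as.integer(n_regions), palette = palette,
                 noise_sd = noise_sd, rng_seed = rng_seed),
            class = "mosaic_spec")
}

#' Generate a synthetic mosaic image with ground-truth label map
#'
#' @param spec a [mosaic_spec].
#' @return list with `image` (`height x width x 3` array in `[0, 1]`),
#'   `label_map` (`height x width` character matrix of class labels) and
#'   `seeds` (data frame of region seeds with their class).
#' @export
generate_mosaic <- function(spec) {
  stopifnot(inherits(spec, "mosaic_spec"))
  pal <- spec$palette
  k <- nrow(pal)
  with_private_seed(spec$rng_seed, {
    seeds <- data.frame(
      row = sample.int(spec$height, spec$n_regions, replace = TRUE) - 1L,
      col = sample.int(spec$width, spec$n_regions, replace = TRUE) - 1L,
      class = c(seq_len(k),
                sample.int(k, max(0L, spec$n_regions - k), replace = TRUE))
    )
    rows <- matrix(rep(seq_len(spec$height) - 1L, spec$width), spec$height)
    cols <- matrix(rep(seq_len(spec$width) - 1L, each = spec$height),
                   spec$height)
    best_d <- matrix(Inf, spec$height, spec$width)
    best_i <- matrix(1L, spec$height, spec$width)
    for (s in seq_len(spec$n_regions)) {
      d <- (rows - seeds$row[s])^2 + (cols - seeds$col[s])^2
      upd <- d < best_d   # strict: ties go to the lowest seed index
      best_d[upd] <- d[upd]
      best_i[upd] <- s
    }
    cls <- matrix(seeds$class[best_i], spec$height, spec$width)
    img <- array(0, c(spec$height, spec$width, 3L))
    for (ci in seq_len(k)) {
      mask <- cls == ci
      tex <- pal$amplitude[ci] *
        sin(2 * pi * pal$freq[ci] *
              (cols * cos(pal$orientation[ci]) +
               rows * sin(pal$orientation[ci])))
      for (ch in 1:3) {
        base <- c(pal$r[ci], pal$g[ci], pal$b[ci])[ch]
        plane <- img[, , ch]
        plane[mask] <- base + tex[mask]
        img[, , ch] <- plane
      }
    }
    img <- img + array(stats::rnorm(length(img), 0, spec$noise_sd), dim(img))
    img <- pmin(pmax(img, 0), 1)
    label_map <- matrix(pal$label[cls], spec$height, spec$width)
    list(image = img, label_map = label_map, seeds = seeds)
  })
}

#' Read ground-truth labels off a label map
#'
#' Looks up the true class of each sampled point in a mosaic's label map,
#' producing the reference ("Archived") annotations for synthetic
#' experiments.
#'
#' @param label_map `height x width` character matrix (from
#'   [generate_mosaic()]).
#' @param points data frame with 0-based `row`, `col` columns (from
#'   [sample_points()]).
#' @param label_set [labelset] of the palette classes (default: built from
#'   the map's distinct labels... pass one for stable order).
#' @param image_id image identifier for the annotation keys.
#' @return an [annotation_set] with annotator id "truth".
#' @export
annotate_truth <- function(label_map, points, label_set = NULL,
                           image_id = "img1") {
  h <- nrow(label_map); w <- ncol(label_map)
  if (any(points$row < 0L) || any(points$row >= h) ||
      any(points$col < 0L) || any(points$col >= w)) {
    abort_reefpoint("points out of label-map bounds", "validation_error")
  }
  if (is.null(label_set)) label_set <- labelset(sort(unique(as.vector(label_map))))
  labs <- label_map[cbind(points$row + 1L, points$col + 1L)]
  annotation_set(
    data.frame(image_id = image_id,
               point_index = seq_len(nrow(points)) - 1L,
               row = points$row, col = points$col, label = labs),
    label_set, "truth"
  )
}

#' Simulate a human annotator from a confusion matrix
#'
#' Each point's assigned label is drawn independently from the confusion
#' row of its true label, emulating inter- and intra-annotator
#' variability.
#'
#' @param truth an [annotation_set] of true labels.
#' @param confusion a `confusion_matrix` (rates used; row = true label)
#'   covering every truth label.
#' @param rng_seed integer seed.
#' @param annotator_id id for the simulated annotator.
#' @return an [annotation_set].
#' @export
simulate_annotator <- function(truth, confusion, rng_seed = 1L,
                               annotator_id = "simulated") {
  stopifnot(inherits(truth, "annotation_set"),
            inherits(confusion, "confusion_matrix"))
  miss <- setdiff(unique(truth$label), confusion$labels)
  if (length(miss)) {
    abort_reefpoint(sprintf("no confusion row for labels: %s",
                            paste(miss, collapse = ", ")),
                    "validation_error")
  }
  R <- confusion$rates
  df <- as.data.frame(truth)
  df$label <- with_private_seed(rng_seed, {
    vapply(df$label, function(l) {
      sample(confusion$labels, 1L, prob = R[l, ])
    }, character(1), USE.NAMES = FALSE)
  })
  annotation_set(df, attr(truth, "label_set"), annotator_id)
}

#' Specification of simulated classifier scores
#'
#' Emulates the behavior that makes score-thresholded deferral work: the
#' predicted (argmax) label is drawn through a confusion matrix, and the
#' maximum score is drawn from one of two normal distributions depending
#' on whether the prediction is correct — high (`mu_correct`) when right,
#' low (`mu_error`) when wrong. All other labels receive scores strictly
#' below the maximum with random gaps.
#'
#' @param confusion `confusion_matrix` for the argmax label (row = true).
#' @param mu_correct,mu_error means of the max-score distribution given a
#'   correct / incorrect prediction; `mu_correct > mu_error` required.
#' @param sigma common standard deviation of the max score.
#' @param rng_seed integer seed.
#' @return an object of class `score_sim_spec`.
#' @export
score_sim_spec <- function(confusion, mu_correct = 1, mu_error = -1,
                           sigma = 0.5, rng_seed = 1L) {
  stopifnot(inherits(confusion, "confusion_matrix"))
  if (!(mu_correct > mu_error)) {
    abort_reefpoint("mu_correct must exceed mu_error", "validation_error")
  }
  if (sigma <= 0) {
    abort_reefpoint("sigma must be positive", "validation_error")
  }
  structure(list(confusion = confusion, mu_correct = mu_correct,
                 mu_error = mu_error, sigma = sigma, rng_seed = rng_seed),
            class = "score_sim_spec")
}

#' Simulate a score matrix for an annotation set
#'
#' @param truth an [annotation_set] of true labels.
#' @param spec a [score_sim_spec].
#' @return a [score_matrix] whose argmax labels follow the spec's
#'   confusion matrix and whose max scores are informative of correctness.
#' @export
simulate_scores <- function(truth, spec) {
  stopifnot(inherits(truth, "annotation_set"),
            inherits(spec, "score_sim_spec"))
  L <- spec$confusion$labels
  miss <- setdiff(unique(truth$label), L)
  if (length(miss)) {
    abort_reefpoint(sprintf("no confusion row for labels: %s",
                            paste(miss, collapse = ", ")),
                    "validation_error")
  }
  R <- spec$confusion$rates
  n <- nrow(truth)
  with_private_seed(spec$rng_seed, {
    scores <- matrix(NA_real_, n, length(L), dimnames = list(NULL, L))
    for (i in seq_len(n)) {
      true_l <- truth$label[i]
      pred <- sample(L, 1L, prob = R[true_l, ])
      mu <- if (pred == true_l) spec$mu_correct else spec$mu_error
      mx <- stats::rnorm(1L, mu, spec$sigma)
      gaps <- 0.05 + stats::rexp(length(L) - 1L, rate = 2)
      s <- numeric(length(L))
      j <- match(pred, L)
      s[j] <- mx
      s[-j] <- mx - gaps
      scores[i, ] <- s
    }
    score_matrix(as.data.frame(truth)[c("image_id", "point_index", "row",
                                        "col")],
                 scores, L)
  })
}
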