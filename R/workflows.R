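#' Configuration for the synthetic end-to-end workflows
#'
#' Collects every knob of the synthetic study in one validated list so
#' runs are reproducible from the config alone: canvas and sampling sizes,
#' encoder settings, simulated-annotator confusion, alleviation grid,
#' cross-validation folds and the Bonferroni comparison count. All
#' randomness derives from `seed`.
#'
#' @param seed master integer seed; stage seeds are derived from it.
#' @param n_classes number of substratum classes in the mosaics.
#' @param image_size mosaic side length in pixels.
#' @param n_train_images,n_eval_images mosaics in the reference (training)
#'   and evaluation sets.
#' @param points_per_image annotated points per image.
#' @param patch_size encoder patch side length.
#' @param host_diag diagonal mass of the simulated human annotator's
#'   confusion matrix (off-diagonal spread uniformly).
#' @param separation color separation of the class palette.
#' @param folds cross-validation folds for the classifier confusion
#'   matrix (capped at the number of training images).
#' @param alleviation_grid target levels for the trade-off curve.
#' @param comparisons Bonferroni comparison count.
#' @param reg_strength SVM cost (NULL = small validation grid).
#' @return an object of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_classes = 4L, image_size = 96L,
                       n_train_images = 6L, n_eval_images = 3L,
                       points_per_image = 60L, patch_size = 16L,
                       host_diag = 0.9, separation = 1,
                       folds = 6L, alleviation_grid = seq(0, 1, 0.25),
                       comparisons = 8L, reg_strength = 1) {
  stopifnot(host_diag > 0, host_diag <= 1, n_train_images >= 2L,
            n_eval_images >= 1L, points_per_image >= 1L)
  structure(list(seed = as.integer(seed), n_classes = as.integer(n_classes),
                 image_size = as.integer(image_size),
                 n_train_images = as.integer(n_train_images),
                 n_eval_images = as.integer(n_eval_images),
                 points_per_image = as.integer(points_per_image),
                 patch_size = as.integer(patch_size),
                 host_diag = host_diag, separation = separation,
                 folds = as.integer(folds),
                 alleviation_grid = alleviation_grid,
                 comparisons = as.integer(comparisons),
                 reg_strength = reg_strength),
            class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Diagonally dominant confusion matrix
#'
#' Helper building the row-stochastic confusion of a simulated annotator:
#' `diag` on the diagonal, the remainder spread uniformly.
#'
#' @param labels label names.
#' @param diag diagonal (correct-assignment) rate.
#' @return a `confusion_matrix`.
#' @export
uniform_confusion <- function(labels, diag = 0.9) {
  k <- length(labels)
  stopifnot(k >= 2L, diag >= 0, diag <= 1)
  off <- (1 - diag) / (k - 1)
  R <- matrix(off, k, k, dimnames = list(labels, labels))
  diag(R) <- diag
  confusion_from_rates(R, labels)
}

synth_dataset <- function(config, n_images, seed_offset, prefix) {
  pal <- default_palette(config$n_classes, config$separation)
  label_set <- labelset(pal$label)
  images <- list()
  truths <- list()
  for (i in seq_len(n_images)) {
    sd_i <- config$seed * 1000L + seed_offset + i
    mos <- generate_mosaic(mosaic_spec(config$image_size, config$image_size,
                                       n_regions = 3L * config$n_classes,
                                       palette = pal, rng_seed = sd_i))
    id <- sprintf("%s%03d", prefix, i)
    pts <- sample_points(config$image_size, config$image_size,
                         config$points_per_image, rng_seed = sd_i + 500L)
    images[[id]] <- mos$image
    truths[[id]] <- annotate_truth(mos$label_map, pts, label_set, id)
  }
  truth <- annotation_set(do.call(rbind, lapply(truths, as.data.frame)),
                          label_set, "Archived")
  list(images = images, truth = truth, label_set = label_set)
}

#' Run the full synthetic pipeline end to end
#'
#' Generates reference and evaluation mosaics, trains the patch classifier
#' on the reference truth, scores the evaluation points, applies all three
#' operational modes (deferral at level 0.5, confusion-corrected covers,
#' top-k suggestions), and evaluates agreement and cover errors of the
#' automated, deferral and simulated-human annotations against the ground
#' truth.
#'
#' @param config a [run_config].
#' @param out path to write the JSON report to (optional).
#' @return the report as a named list (invisibly `jsonlite`-serializable);
#'   includes the config and its hash.
#' @export
run_end_to_end <- function(config = run_config(), out = NULL) {
  stopifnot(inherits(config, "run_config"))
  train <- synth_dataset(config, config$n_train_images, 0L, "ref")
  eval_ <- synth_dataset(config, config$n_eval_images, 10000L, "eval")
  label_set <- train$label_set
  enc <- default_encoder(patch_size = config$patch_size)

  feat_train <- extract_feature_table(train$images, train$truth, enc)
  feat_eval <- extract_feature_table(eval_$images, eval_$truth, enc)
  clf <- train_classifier(feat_train, train$truth$label,
                          label_order = label_set$labels,
                          reg_strength = config$reg_strength,
                          rng_seed = config$seed)
  scores <- score_points(clf, feat_eval)
  automated <- automated_annotations(scores, label_set)

  host <- simulate_annotator(eval_$truth,
                             uniform_confusion(label_set$labels,
                                               config$host_diag),
                             rng_seed = config$seed + 77L,
                             annotator_id = "Host")
  eps <- epsilon_for_level(scores, 0.5)
  allev <- alleviate(scores, host, eps)

  folds <- min(config$folds, config$n_train_images)
  qprime <- suppressWarnings(
    estimate_confusion_cv(feat_train, train$truth, folds = folds,
                          rng_seed = config$seed + 3L,
                          reg_strength = config$reg_strength %||% 1)
  )
  abund <- abundance_mode(qprime, automated)

  curve <- alleviation_curve(scores, host, eval_$truth, group = NULL,
                             grid = config$alleviation_grid)

  covers <- bind_covers(cover(eval_$truth), cover(host), cover(automated),
                        cover(allev$annotations))
  covers <- bind_covers(covers, abund)
  diffs <- suppressWarnings(cover_diffs(covers, "Archived"))

  report <- list(
    config = unclass(config),
    config_hash = config_hash(config),
    n_train_points = nrow(train$truth),
    n_eval_points = nrow(eval_$truth),
    classifier = list(cost = clf$cost, encoder = enc$encoder_id),
    kappa = list(
      automated = cohens_kappa(eval_$truth, automated),
      host = cohens_kappa(eval_$truth, host),
      alleviate = cohens_kappa(eval_$truth, allev$annotations)
    ),
    alleviate = list(epsilon = eps, level = allev$level),
    alleviation_curve = curve,
    qprime_rates = as.data.frame(qprime$rates),
    cover_bias = diffs$e,
    mae = stats::setNames(
      lapply(unique(diffs$e$annotator), function(a) cover_mae(diffs, annotators = a)),
      unique(diffs$e$annotator)
    )
  )
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = 12,
                         dataframe = "columns")
  }
  invisible(report)
}

#' Alleviation trade-off as a function of training-set size
#'
#' Retrains the classifier on nested fractions of the reference pool and
#' reports, for each size, the largest achievable level of alleviation at
#' which the agreement with ground truth stays within a relative drop of
#' the curve's maximum. With more training data the classifier is more
#' accurate, so the sustainable level of automation grows.
#'
#' @param config a [run_config].
#' @param sizes fractions of the training images to use (>= 1 value).
#' @param drop relative kappa drop tolerated (default 0.05, i.e. 5%).
#' @param group label group for the kappa (default `NULL`: full label
#'   set).
#' @return data frame with columns `size_fraction`, `n_train_points`,
#'   `kappa_max`, `lambda_at_drop` plus the per-size curves in the
#'   `curves` attribute.
#' @export
run_training_size_sweep <- function(config = run_config(),
                                    sizes = c(1 / 3, 2 / 3, 1),
                                    drop = 0.05, group = NULL) {
  stopifnot(inherits(config, "run_config"), all(sizes > 0), all(sizes <= 1))
  train <- synth_dataset(config, config$n_train_images, 0L, "ref")
  eval_ <- synth_dataset(config, config$n_eval_images, 10000L, "eval")
  label_set <- train$label_set
  enc <- default_encoder(patch_size = config$patch_size)
  feat_train <- extract_feature_table(train$images, train$truth, enc)
  feat_eval <- extract_feature_table(eval_$images, eval_$truth, enc)
  host <- simulate_annotator(eval_$truth,
                             uniform_confusion(label_set$labels,
                                               config$host_diag),
                             rng_seed = config$seed + 77L,
                             annotator_id = "Host")
  all_imgs <- names(train$images)
  rows <- list()
  curves <- list()
  for (s in sizes) {
    n_img <- max(2L, round(s * length(all_imgs)))
    keep_imgs <- all_imgs[seq_len(n_img)]   # nested subsets
    keep <- feat_train$keys$image_id %in% keep_imgs
    clf <- train_classifier(feat_train$features[keep, , drop = FALSE],
                            train$truth$label[keep],
                            label_order = label_set$labels,
                            reg_strength = config$reg_strength %||% 1)
    scores <- score_points(clf, feat_eval)
    curve <- alleviation_curve(scores, host, eval_$truth, group = group,
                               grid = config$alleviation_grid)
    kmax <- max(curve$kappa)
    ok <- curve$kappa >= kmax * (1 - drop)
    lambda_at <- max(curve$achieved_level[ok])
    rows[[length(rows) + 1L]] <- data.frame(
      size_fraction = s, n_train_points = sum(keep), kappa_max = kmax,
      lambda_at_drop = lambda_at
    )
    curves[[sprintf("size_%.3f", s)]] <- curve
  }
  out <- do.call(rbind, rows)
  attr(out, "curves") <- curves
  out
}
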