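#' The deferral (semi-automated) annotation mode
#'
#' A point keeps its automated label when the classifier is confident —
#' strictly, when the maximum of its score vector exceeds the threshold
#' `epsilon` — and is deferred to the human annotator otherwise. The
#' fraction of points labelled automatically is the level of alleviation.
#'
#' @param scores a [score_matrix].
#' @param human an [annotation_set] covering the same
#'   `(image_id, point_index)` keys (the fallback labels).
#' @param epsilon score threshold; automated labels are used where
#'   `max(scores) > epsilon` (strict inequality).
#' @return an object of class `alleviate_result`: `annotations` (the merged
#'   [annotation_set]), `epsilon`, `level` (automated fraction) and
#'   `deferred_keys` (data frame of keys sent to the human).
#' @export
alleviate <- function(scores, human, epsilon) {
  stopifnot(inherits(scores, "score_matrix"),
            inherits(human, "annotation_set"))
  skeys <- sm_keys(scores)
  hkeys <- ann_keys(human)
  missing <- setdiff(skeys, hkeys)
  extra <- setdiff(hkeys, skeys)
  if (length(missing) || length(extra)) {
    abort_reefpoint(
      sprintf("score/human key mismatch; missing from human: %s; missing from scores: %s",
              paste(utils::head(gsub("\r", ":", missing), 5L), collapse = ", "),
              paste(utils::head(gsub("\r", ":", extra), 5L), collapse = ", ")),
      "validation_error"
    )
  }
  ord <- match(skeys, hkeys)
  df <- as.data.frame(human)[ord, , drop = FALSE]
  n <- nrow(df)
  if (n == 0L) {
    res <- annotation_set(df, attr(human, "label_set"), "Alleviate")
    return(structure(list(annotations = res, epsilon = epsilon, level = NA_real_,
                          deferred_keys = df[c("image_id", "point_index")]),
                     class = "alleviate_result"))
  }
  ms <- max_scores(scores)
  auto <- ms > epsilon
  lab_auto <- scores$labels[apply(scores$scores, 1L, which.max)]
  df$label[auto] <- lab_auto[auto]
  res <- annotation_set(df, attr(human, "label_set"), "Alleviate")
  structure(list(
    annotations = res,
    epsilon = epsilon,
    level = mean(auto),
    deferred_keys = df[!auto, c("image_id", "point_index"), drop = FALSE]
  ), class = "alleviate_result")
}

#' @export
print.alleviate_result <- function(x, ...) {
  cat(sprintf("<alleviate_result> epsilon %.4g, level %.3f (%d deferred)\n",
              x$epsilon, x$level, nrow(x$deferred_keys)))
  invisible(x)
}

#' Threshold achieving a requested level of alleviation
#'
#' The level of alleviation is a step function of the threshold (it only
#' changes at observed maximum scores), so the achievable levels form a
#' finite set. Returns the threshold whose achieved level is closest to
#' the target; when two achievable levels are equally near, the lower one
#' is preferred (less automation).
#'
#' @param scores a [score_matrix].
#' @param level_target requested automated fraction in `[0, 1]`.
#' @return the threshold `epsilon` (a value of the max-score distribution,
#'   or just below its minimum for full automation).
#' @export
epsilon_for_level <- function(scores, level_target) {
  stopifnot(level_target >= 0, level_target <= 1)
  ms <- max_scores(scores)
  if (!length(ms)) {
    abort_reefpoint("empty score matrix", "validation_error")
  }
  u <- sort(unique(ms))
  cand <- c(u, u[1L] - 1)
  lam <- vapply(cand, function(e) mean(ms > e), numeric(1))
  err <- abs(lam - level_target)
  best <- which(err == min(err))
  best <- best[which.min(lam[best])]
  cand[best]
}

#' Agreement along the automation trade-off curve
#'
#' Sweeps the level of alleviation over a grid and reports, at every level,
#' the group (or full label-set) Cohen's kappa of the merged annotations
#' against a reference annotator. The endpoints reproduce the human-only
#' (level 0) and automated-only (level 1) agreement exactly.
#'
#' @param scores a [score_matrix].
#' @param human the human [annotation_set] used for deferred points.
#' @param reference the baseline [annotation_set] agreement is measured
#'   against.
#' @param group label group for the binary kappa, or `NULL` for the full
#'   label-set kappa.
#' @param grid numeric vector of target levels in `[0, 1]`.
#' @return data frame with columns `level` (target), `achieved_level`,
#'   `epsilon`, `kappa`.
#' @export
alleviation_curve <- function(scores, human, reference, group = NULL,
                              grid = seq(0, 1, by = 0.1)) {
  rows <- lapply(grid, function(lv) {
    eps <- epsilon_for_level(scores, lv)
    res <- alleviate(scores, human, eps)
    k <- if (is.null(group)) {
      cohens_kappa(reference, res$annotations)
    } else {
      kappa_group(reference, res$annotations, group)
    }
    data.frame(level = lv, achieved_level = res$level, epsilon = eps,
               kappa = k)
  })
  do.call(rbind, rows)
}

#' Cross-validated confusion matrix of the automated annotator
#'
#' Estimates the classifier's confusion matrix by k-fold cross-validation
#' on a reference (training) pool. Folds are stratified by image — all
#' points of an image share a fold — so spatially co-located patches never
#' straddle the train/test boundary. Counts accumulate out-of-fold
#' predictions; rates are row-normalized.
#'
#' @param features keyed feature list from [extract_feature_table()].
#' @param labels an [annotation_set] with the reference labels for the
#'   same keys.
#' @param folds number of folds (default 20).
#' @param rng_seed seed for the fold assignment.
#' @param reg_strength passed to [train_classifier()].
#' @return a `confusion_matrix` over the label set of `labels`.
#' @export
estimate_confusion_cv <- function(features, labels, folds = 20L,
                                  rng_seed = 1L, reg_strength = 1) {
  stopifnot(inherits(labels, "annotation_set"), folds >= 2L)
  label_set <- attr(labels, "label_set")
  fkeys <- paste(features$keys$image_id, features$keys$point_index,
                 sep = "\r")
  ord <- match(fkeys, ann_keys(labels))
  if (anyNA(ord)) {
    abort_reefpoint("features and labels have mismatched keys",
                    "validation_error")
  }
  y <- labels$label[ord]
  imgs <- unique(features$keys$image_id)
  if (length(imgs) < folds) {
    abort_reefpoint("fewer images than folds", "validation_error")
  }
  for (m in unique(y)) {
    n_img <- length(unique(features$keys$image_id[y == m]))
    if (n_img < folds) {
      warning(sprintf(
        "label '%s' occurs in %d image(s), fewer than %d folds; its confusion row may be unstable",
        m, n_img, folds))
    }
  }
  fold_of_img <- with_private_seed(
    rng_seed,
    stats::setNames(rep_len(seq_len(folds), length(imgs))[sample.int(length(imgs))],
                    imgs)
  )
  fold <- fold_of_img[features$keys$image_id]
  L <- label_set$labels
  counts <- matrix(0L, length(L), length(L), dimnames = list(L, L))
  X <- as.matrix(features$features)
  for (f in seq_len(folds)) {
    te <- fold == f
    if (!any(te)) next
    clf <- train_classifier(X[!te, , drop = FALSE], y[!te], label_order = L,
                            reg_strength = reg_strength)
    pred <- predict_labels(clf, X[te, , drop = FALSE])
    tab <- table(factor(y[te], levels = L), factor(pred, levels = L))
    counts <- counts + as.matrix(unclass(tab))
  }
  confusion_matrix(counts, L)
}

#' Correct an automated cover vector by confusion-matrix inversion
#'
#' The expected automated cover is the true cover mixed through the
#' transpose of the classifier's row-stochastic confusion matrix;
#' inverting that linear map de-biases the estimate. Covers for one image
#' (or an aggregate) are corrected as `solve(t(rates), cover)`. Because
#' each rate row sums to 1, the corrected vector still sums to 1, but
#' individual entries may be negative — that is by design, as truncation
#' would re-introduce bias in aggregate; set `clip = TRUE` to clip and
#' renormalize for display.
#'
#' @param Q_prime a `confusion_matrix` (typically from
#'   [estimate_confusion_cv()]). Zero-count rows are replaced by identity
#'   rows before inversion.
#' @param cover_auto numeric cover vector summing to 1, in the matrix's
#'   label order (names, if present, are matched).
#' @param clip clip negatives and renormalize (default `FALSE`).
#' @return corrected cover vector, named by label.
#' @export
abundance_correct <- function(Q_prime, cover_auto, clip = FALSE) {
  stopifnot(inherits(Q_prime, "confusion_matrix"))
  L <- Q_prime$labels
  if (!is.null(names(cover_auto))) {
    if (!setequal(names(cover_auto), L)) {
      abort_reefpoint("cover names do not match confusion labels",
                      "validation_error")
    }
    cover_auto <- cover_auto[L]
  }
  if (length(cover_auto) != length(L)) {
    abort_reefpoint("cover vector length must match label count",
                    "validation_error")
  }
  if (abs(sum(cover_auto) - 1) > 1e-9) {
    abort_reefpoint("cover vector must sum to 1", "validation_error")
  }
  R <- Q_prime$rates
  for (z in Q_prime$zero_rows) {
    R[z, ] <- 0
    R[z, z] <- 1
  }
  A <- t(R)
  out <- if (rcond(A) > 1e-10) {
    # mild ridge on the diagonal for numerical robustness; invisible for
    # well-conditioned matrices
    drop(solve(A + diag(1e-8, nrow(A)), cover_auto))
  } else {
    warning("confusion rate matrix is singular; using pseudo-inverse")
    drop(MASS::ginv(A) %*% cover_auto)
  }
  names(out) <- L
  if (clip) {
    out <- pmax(out, 0)
    s <- sum(out)
    if (s > 0) out <- out / s
  }
  out
}

#' The fully automated annotation mode
#'
#' Computes per-image cover vectors from automated annotations and corrects
#' each by [abundance_correct()], yielding cover estimates that are
#' unbiased in expectation (at the cost of extra variance).
#'
#' @param Q_prime the cross-validated `confusion_matrix` of the annotator.
#' @param automated an [annotation_set] of automated labels.
#' @param clip passed to [abundance_correct()].
#' @param per_image correct each image's cover separately (`TRUE`, the
#'   default) or correct the aggregate cover across images (`FALSE`).
#' @return a cover table (long data frame, annotator "Abundance"); see
#'   [cover()].
#' @export
abundance_mode <- function(Q_prime, automated, clip = FALSE,
                           per_image = TRUE) {
  stopifnot(inherits(automated, "annotation_set"))
  L <- Q_prime$labels
  ls_labels <- attr(automated, "label_set")$labels
  if (!all(ls_labels %in% L)) {
    abort_reefpoint("confusion matrix does not cover the label set",
                    "validation_error")
  }
  cov_auto <- cover(automated)
  if (per_image) {
    imgs <- unique(cov_auto$image_id)
    rows <- lapply(imgs, function(im) {
      v <- stats::setNames(rep(0, length(L)), L)
      sub <- cov_auto[cov_auto$image_id == im, ]
      v[sub$label] <- sub$cover
      cv <- abundance_correct(Q_prime, v, clip = clip)
      data.frame(image_id = im, annotator = "Abundance", label = L,
                 cover = unname(cv))
    })
    out <- do.call(rbind, rows)
  } else {
    agg <- tapply(cov_auto$cover, cov_auto$label, mean)
    v <- stats::setNames(rep(0, length(L)), L)
    v[names(agg)] <- agg / sum(agg)
    cv <- abundance_correct(Q_prime, v, clip = clip)
    out <- data.frame(image_id = "(aggregate)", annotator = "Abundance",
                      label = L, cover = unname(cv))
  }
  class(out) <- c("cover_table", "data.frame")
  out
}

#' Top-k label suggestions per point
#'
#' The suggestion mode ranks all labels by score at every point and keeps
#' the `k` best (default 5), ties broken by label order.
#'
#' @param scores a [score_matrix].
#' @param k number of suggestions per point.
#' @return long data frame with columns `image_id`, `point_index`, `rank`,
#'   `label`, `score`.
#' @export
refine_suggestions <- function(scores, k = 5L) {
  stopifnot(inherits(scores, "score_matrix"))
  if (k > length(scores$labels)) {
    abort_reefpoint("k exceeds the number of labels", "validation_error")
  }
  n <- nrow(scores$scores)
  rows <- lapply(seq_len(n), function(i) {
    s <- scores$scores[i, ]
    ord <- order(-s, seq_along(s))[seq_len(k)]
    data.frame(image_id = scores$keys$image_id[i],
               point_index = scores$keys$point_index[i],
               rank = seq_len(k),
               label = scores$labels[ord],
               score = unname(s[ord]))
  })
  if (!n) {
    return(data.frame(image_id = character(0), point_index = integer(0),
                      rank = integer(0), label = character(0),
                      score = numeric(0)))
  }
  do.call(rbind, rows)
}
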