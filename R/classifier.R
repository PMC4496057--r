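#' Construct a score matrix
#'
#' Per-point score vectors from a one-versus-rest classifier: one row per
#' `(image_id, point_index)` key, one column per label in label-set order.
#' The argmax of each row defines the automated annotation; the row maximum
#' drives the deferral rule of [alleviate()].
#'
#' @param keys data frame with columns `image_id`, `point_index` (optional
#'   `row`, `col` pixel coordinates are carried through to
#'   [automated_annotations()]).
#' @param scores numeric matrix, `nrow(keys)` rows, one column per label.
#' @param labels character vector of labels naming the columns, in the
#'   label-set order used for argmax tie-breaking.
#' @return an object of class `score_matrix`.
#' @export
score_matrix <- function(keys, scores, labels) {
  scores <- as.matrix(scores)
  if (nrow(scores) != nrow(keys)) {
    abort_reefpoint("keys and scores disagree in length", "validation_error")
  }
  if (ncol(scores) != length(labels)) {
    abort_reefpoint("score vector length must equal number of labels",
                    "validation_error")
  }
  if (nrow(scores) && any(is.na(scores))) {
    abort_reefpoint("scores must not contain NA", "validation_error")
  }
  keys <- as.data.frame(keys)
  keys$image_id <- as.character(keys$image_id)
  keys$point_index <- as.integer(keys$point_index)
  if (anyDuplicated(paste(keys$image_id, keys$point_index, sep = "\r"))) {
    abort_reefpoint("duplicate (image_id, point_index) keys",
                    "validation_error")
  }
  colnames(scores) <- labels
  structure(list(keys = keys, scores = scores, labels = as.character(labels)),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("<score_matrix> %d points x %d labels\n",
              nrow(x$scores), length(x$labels)))
  invisible(x)
}

sm_keys <- function(x) paste(x$keys$image_id, x$keys$point_index, sep = "\r")

#' Row maxima of a score matrix
#'
#' @param scores a [score_matrix].
#' @return numeric vector of per-point maximum scores.
#' @export
max_scores <- function(scores) {
  stopifnot(inherits(scores, "score_matrix"))
  if (nrow(scores$scores) == 0L) return(numeric(0))
  apply(scores$scores, 1L, max)
}

#' Write / read score matrices as CSV
#'
#' Columns are `image_id,point_index[,row,col],score_<label>...`.
#'
#' @param scores a [score_matrix].
#' @param path file path.
#' @return `write_scores` returns `path` invisibly; `read_scores` a
#'   [score_matrix].
#' @export
write_scores <- function(scores, path) {
  stopifnot(inherits(scores, "score_matrix"))
  df <- cbind(scores$keys,
              stats::setNames(as.data.frame(scores$scores),
                              paste0("score_", scores$labels)))
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        fileEncoding = "UTF-8")
  sc_cols <- grep("^score_", names(df))
  if (!length(sc_cols)) {
    abort_reefpoint("no score_<label> columns found", "format_error")
  }
  score_matrix(df[setdiff(names(df), names(df)[sc_cols])],
               as.matrix(df[sc_cols]),
               sub("^score_", "", names(df)[sc_cols]))
}

#' Train a one-versus-rest linear maximum-margin classifier
#'
#' For each label present in the training data a binary linear support
#' vector machine (label vs rest) is fitted on standardized features and
#' collapsed to an affine scoring rule `w'x + b`. Labels in `label_order`
#' that never occur in training receive a `-Inf` offset sentinel, so they
#' can never win the argmax. When `reg_strength` is `NULL` the cost
#' parameter is chosen on a small grid by accuracy on a held-out fifth of
#' the training data.
#'
#' @param features numeric matrix (one row per example) or the list
#'   returned by [extract_feature_table()].
#' @param labels character vector of training labels, one per row.
#' @param label_order full ordered label vocabulary to score (default: the
#'   distinct training labels in order of first appearance). Pass the
#'   label-set's `labels` so score columns line up with the vocabulary.
#' @param reg_strength SVM cost parameter; `NULL` selects from
#'   `c(0.1, 1, 10)` on a validation split.
#' @param rng_seed seed for the validation split.
#' @return object of class `trained_classifier` with weight matrix `W`
#'   (feature dim x labels), offsets `b`, standardization `center`/`scale`,
#'   `labels` and `encoder_id`.
#' @export
train_classifier <- function(features, labels, label_order = NULL,
                             reg_strength = NULL, rng_seed = 1L) {
  encoder_id <- NA_character_
  if (is.list(features) && !is.null(features$features)) {
    encoder_id <- features$encoder_id %||% NA_character_
    features <- features$features
  }
  X <- as.matrix(features)
  labels <- as.character(labels)
  if (nrow(X) != length(labels)) {
    abort_reefpoint("one label per feature row required", "validation_error")
  }
  present <- unique(labels)
  if (length(present) < 2L) {
    abort_reefpoint(
      "training data contains a single class; use a trivial constant predictor instead",
      "validation_error"
    )
  }
  if (is.null(label_order)) label_order <- present
  if (!all(present %in% label_order)) {
    abort_reefpoint("training labels outside label_order", "validation_error")
  }

  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")

  if (is.null(reg_strength)) {
    reg_strength <- pick_cost(Xs, labels, rng_seed)
  }

  W <- matrix(0, ncol(X), length(label_order),
              dimnames = list(NULL, label_order))
  b <- stats::setNames(rep(-Inf, length(label_order)), label_order)
  for (m in present) {
    yf <- factor(ifelse(labels == m, "pos", "neg"), levels = c("pos", "neg"))
    fit <- e1071::svm(Xs, yf, kernel = "linear", cost = reg_strength,
                      scale = FALSE)
    w <- drop(t(fit$coefs) %*% fit$SV)
    off <- -fit$rho
    dec <- drop(Xs %*% w) + off
    # libsvm orients the decision value toward the class seen first in the
    # data; flip so that positive always means "this label".
    if (mean(dec[labels == m]) < mean(dec[labels != m])) {
      w <- -w; off <- -off
    }
    W[, m] <- w
    b[m] <- off
  }
  structure(list(W = W, b = b, center = ctr, scale = scl,
                 labels = label_order, cost = reg_strength,
                 encoder_id = encoder_id),
            class = "trained_classifier")
}

pick_cost <- function(Xs, labels, rng_seed, grid = c(0.1, 1, 10)) {
  n <- nrow(Xs)
  if (n < 10L) return(1)
  idx_val <- with_private_seed(rng_seed, sample.int(n, max(2L, n %/% 5L)))
  tr <- setdiff(seq_len(n), idx_val)
  if (length(unique(labels[tr])) < 2L) return(1)
  acc <- vapply(grid, function(cost) {
    clf <- train_classifier(Xs[tr, , drop = FALSE], labels[tr],
                            reg_strength = cost)
    pred <- predict_labels(clf, Xs[idx_val, , drop = FALSE])
    mean(pred == labels[idx_val])
  }, numeric(1))
  grid[which.max(acc)]
}

score_features_matrix <- function(clf, X) {
  if (ncol(X) != nrow(clf$W)) {
    abort_reefpoint("feature dimension mismatch with classifier",
                    "validation_error")
  }
  Xs <- sweep(sweep(X, 2L, clf$center), 2L, clf$scale, "/")
  sweep(Xs %*% clf$W, 2L, clf$b, "+")
}

predict_labels <- function(clf, X) {
  sc <- score_features_matrix(clf, as.matrix(X))
  clf$labels[apply(sc, 1L, which.max)]
}

#' @export
print.trained_classifier <- function(x, ...) {
  cat(sprintf("<trained_classifier> %d labels (%d trained), dim %d, cost %g\n",
              length(x$labels), sum(is.finite(x$b)), nrow(x$W), x$cost))
  invisible(x)
}

#' Score annotation points with a trained classifier
#'
#' @param clf a `trained_classifier`.
#' @param features list from [extract_feature_table()] (keyed features).
#' @return a [score_matrix] with one row per key.
#' @export
score_points <- function(clf, features) {
  stopifnot(inherits(clf, "trained_classifier"))
  if (!is.na(clf$encoder_id) && !is.null(features$encoder_id) &&
      !identical(clf$encoder_id, features$encoder_id)) {
    abort_reefpoint(
      sprintf("encoder mismatch: classifier trained on '%s', features from '%s'",
              clf$encoder_id, features$encoder_id),
      "validation_error"
    )
  }
  X <- as.matrix(features$features)
  if (nrow(X) == 0L) {
    return(score_matrix(features$keys,
                        matrix(numeric(0), 0L, length(clf$labels)),
                        clf$labels))
  }
  score_matrix(features$keys, score_features_matrix(clf, X), clf$labels)
}

#' Automated annotations from a score matrix
#'
#' The label at every point is the argmax of its score vector, ties broken
#' by label order (first label wins).
#'
#' @param scores a [score_matrix].
#' @param label_set optional [labelset] for the result (defaults to a bare
#'   label set over the score columns).
#' @return an [annotation_set] with annotator id "Automated". If the score
#'   keys lack pixel coordinates, `row`/`col` are set to 0.
#' @export
automated_annotations <- function(scores, label_set = NULL) {
  stopifnot(inherits(scores, "score_matrix"))
  if (is.null(label_set)) label_set <- labelset(scores$labels)
  n <- nrow(scores$scores)
  lab <- if (n) {
    scores$labels[apply(scores$scores, 1L, which.max)]
  } else {
    character(0)
  }
  df <- data.frame(
    image_id = scores$keys$image_id,
    point_index = scores$keys$point_index,
    row = scores$keys$row %||% rep(0L, n),
    col = scores$keys$col %||% rep(0L, n),
    label = lab
  )
  annotation_set(df, label_set, "Automated")
}
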