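test_that("deferral keeps human labels below threshold and automated above", {
  ls <- labelset(c("A", "B", "C"))
  sc <- scores_from_matrix(rbind(c(0.2, 0.1, 0.0),
                                 c(0.1, 0.6, 0.0),
                                 c(0.0, 0.1, 0.9)), ls$labels)
  human <- ann_from_labels(c("C", "C", "C"), ls, "Host")

  hi <- alleviate(sc, human, epsilon = 2)
  expect_identical(hi$annotations$label, human$label)
  expect_identical(hi$level, 0)

  lo <- alleviate(sc, human, epsilon = -1)
  expect_identical(lo$annotations$label, c("A", "B", "C"))
  expect_identical(lo$level, 1)

  mid <- alleviate(sc, human, epsilon = 0.5)
  expect_identical(mid$annotations$label, c("C", "B", "C"))
  expect_equal(mid$level, 2 / 3)
  expect_identical(nrow(mid$deferred_keys), 1L)

  other <- ann_from_labels("A", ls, image_id = "elsewhere")
  expect_error(alleviate(sc, other, 0.5), "mismatch",
               class = "validation_error")
})

test_that("the strict inequality holds exactly at the threshold", {
  ls <- labelset(c("A", "B"))
  sc <- scores_from_matrix(rbind(c(0.5, 0), c(0.7, 0)), ls$labels)
  human <- ann_from_labels(c("B", "B"), ls, "Host")
  res <- alleviate(sc, human, epsilon = 0.5)
  # max == epsilon defers; only the 0.7 point is automated
  expect_identical(res$annotations$label, c("B", "A"))
})

test_that("deferral is monotone in the threshold", {
  set.seed(10)
  ls <- labelset(paste0("L", 1:4))
  sc <- scores_from_matrix(matrix(rnorm(80), 20), ls$labels)
  human <- ann_from_labels(sample(ls$labels, 20, replace = TRUE), ls)
  eps_grid <- sort(rnorm(6))
  prev <- NULL
  for (e in rev(eps_grid)) {   # decreasing epsilon: automated set grows
    auto_keys <- setdiff(paste(sc$keys$image_id, sc$keys$point_index),
                         paste(alleviate(sc, human, e)$deferred_keys$image_id,
                               alleviate(sc, human, e)$deferred_keys$point_index))
    if (!is.null(prev)) expect_true(all(prev %in% auto_keys))
    prev <- auto_keys
  }
})

test_that("threshold selection matches the achievable step function", {
  ls <- labelset(c("A", "B"))
  sc <- scores_from_matrix(cbind(c(1, 2, 3, 4), 0), ls$labels)
  expect_identical(epsilon_for_level(sc, 0), 4)
  expect_identical(epsilon_for_level(sc, 0.5), 2)
  expect_identical(epsilon_for_level(sc, 1), 0)  # just below the minimum

  tied <- scores_from_matrix(cbind(c(1, 1, 1), 0), ls$labels)
  # achievable levels are only {0, 1}; tie resolved toward the lower level
  eps <- epsilon_for_level(tied, 0.5)
  expect_identical(eps, 1)
  expect_identical(alleviate(tied, ann_from_labels(c("B", "B", "B"), ls),
                             eps)$level, 0)

  expect_error(epsilon_for_level(scores_from_matrix(matrix(0, 0, 2),
                                                    ls$labels), 0.5),
               "empty", class = "validation_error")

  # property: achieved level is the closest achievable one, by scan
  set.seed(11)
  m <- matrix(rnorm(60), 30)
  scr <- scores_from_matrix(m, c("A", "B"))
  ms <- max_scores(scr)
  for (target in c(0.1, 0.33, 0.5, 0.77)) {
    eps <- epsilon_for_level(scr, target)
    achieved <- mean(ms > eps)
    all_levels <- vapply(c(sort(unique(ms)), min(ms) - 1),
                         function(e) mean(ms > e), numeric(1))
    expect_equal(abs(achieved - target), min(abs(all_levels - target)))
  }
})

test_that("the alleviation curve endpoints equal human-only and automated-only kappa", {
  ls <- labelset(paste0("c", 1:3))
  set.seed(12)
  truth <- ann_multi_image(sample(ls$labels, 300, replace = TRUE), ls, 10L,
                           "Archived")
  spec <- score_sim_spec(uniform_confusion(ls$labels, 0.75),
                         mu_correct = 2, mu_error = -2, sigma = 0.5,
                         rng_seed = 13L)
  sc <- simulate_scores(truth, spec)
  host <- simulate_annotator(truth, uniform_confusion(ls$labels, 0.92),
                             rng_seed = 14L, annotator_id = "Host")
  curve <- alleviation_curve(sc, host, truth, group = NULL, grid = c(0, 1))
  expect_identical(curve$kappa[1], cohens_kappa(truth, host))
  auto <- automated_annotations(sc, ls)
  expect_identical(curve$kappa[2], cohens_kappa(truth, auto))
})

test_that("confident-score separation sustains agreement at half automation", {
  ls <- labelset(paste0("c", 1:4))
  set.seed(15)
  truth <- ann_multi_image(sample(ls$labels, 800, replace = TRUE), ls, 10L,
                           "Archived")
  spec <- score_sim_spec(uniform_confusion(ls$labels, 0.8),
                         mu_correct = 3, mu_error = -3, sigma = 0.5,
                         rng_seed = 16L)
  sc <- simulate_scores(truth, spec)
  host <- simulate_annotator(truth, uniform_confusion(ls$labels, 0.95),
                             rng_seed = 17L, annotator_id = "Host")
  curve <- alleviation_curve(sc, host, truth, group = "c1",
                             grid = c(0, 0.5))
  expect_gt(curve$kappa[2], curve$kappa[1] * 0.95)
})

test_that("cross-validated confusion is identity for separable data and matches LOO", {
  cl <- separable_clusters(n_per = 24L)
  ls <- ls_ab()
  # spread over 12 images, 4 points each
  keys <- data.frame(image_id = sprintf("im%02d", rep(1:12, each = 4)),
                     point_index = rep(0:3, 12))
  feat <- list(keys = keys, features = cl$X, encoder_id = NA)
  labs <- annotation_set(cbind(keys, row = 0L, col = 0L, label = cl$y),
                         ls, "Archived")
  cm <- estimate_confusion_cv(feat, labs, folds = 4L, rng_seed = 2L)
  expect_equal(unname(diag(cm$rates)), c(1, 1))

  # folds = number of images is leave-one-image-out; compare to explicit loop
  # (sparse-label warning expected: each label spans only half the images)
  cm_loo <- suppressWarnings(
    estimate_confusion_cv(feat, labs, folds = 12L, rng_seed = 7L)
  )
  counts <- matrix(0L, 2, 2, dimnames = list(ls$labels, ls$labels))
  for (im in unique(keys$image_id)) {
    te <- keys$image_id == im
    clf <- train_classifier(cl$X[!te, , drop = FALSE], cl$y[!te],
                            label_order = ls$labels, reg_strength = 1)
    pred <- reefpoint:::predict_labels(clf, cl$X[te, , drop = FALSE])
    tab <- table(factor(cl$y[te], levels = ls$labels),
                 factor(pred, levels = ls$labels))
    counts <- counts + as.matrix(unclass(tab))
  }
  expect_identical(unname(cm_loo$counts), unname(counts))
})

test_that("a label confined to held-out images is never predicted for its own row", {
  cl <- separable_clusters(n_per = 24L)
  ls3 <- labelset(c("A", "B", "Rare"))
  keys <- data.frame(image_id = sprintf("im%02d", rep(1:12, each = 4)),
                     point_index = rep(0:3, 12))
  y <- cl$y
  y[keys$image_id == "im01"] <- "Rare"  # only ever in image 1
  labs <- annotation_set(cbind(keys, row = 0L, col = 0L, label = y), ls3,
                         "Archived")
  feat <- list(keys = keys, features = cl$X, encoder_id = NA)
  cm <- suppressWarnings(
    estimate_confusion_cv(feat, labs, folds = 12L, rng_seed = 3L)
  )
  expect_identical(unname(cm$counts["Rare", "Rare"]), 0L)
  expect_identical(unname(sum(cm$counts["Rare", ])), 4L)
})

test_that("cover correction inverts the confusion mixing", {
  ident <- confusion_from_rates(diag(2), c("A", "B"))
  expect_equal(abundance_correct(ident, c(A = 0.3, B = 0.7)),
               c(A = 0.3, B = 0.7), tolerance = 1e-7)

  Q <- confusion_from_rates(matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE),
                            c("A", "B"))
  expect_equal(abundance_correct(Q, c(A = 0.55, B = 0.45)),
               c(A = 0.5, B = 0.5), tolerance = 1e-6)

  sing <- confusion_from_rates(matrix(c(0.5, 0.5, 0.5, 0.5), 2, byrow = TRUE),
                               c("A", "B"))
  expect_warning(abundance_correct(sing, c(A = 0.5, B = 0.5)),
                 "pseudo-inverse")
  expect_error(abundance_correct(Q, c(A = 0.9, B = 0.2)), "sum to 1",
               class = "validation_error")
})

test_that("correction is the exact inverse of mixing on random stochastic matrices", {
  set.seed(18)
  for (r in 1:20) {
    k <- sample(2:6, 1)
    R <- matrix(runif(k * k), k)
    diag(R) <- diag(R) + 2  # diagonally dominant
    R <- R / rowSums(R)
    labs <- paste0("L", 1:k)
    Q <- confusion_from_rates(R, labs)
    truth <- rgamma(k, 1); truth <- truth / sum(truth)
    mixed <- drop(t(R) %*% truth)   # expected automated cover
    rec <- abundance_correct(Q, stats::setNames(mixed, labs))
    expect_equal(unname(rec), truth, tolerance = 1e-5)
    expect_equal(sum(rec), 1, tolerance = 1e-6)  # mass conservation
  }
})

test_that("zero-count confusion rows fall back to identity before inversion", {
  counts <- matrix(c(8L, 2L, 0L, 0L), 2, byrow = TRUE,
                   dimnames = list(c("A", "B"), c("A", "B")))
  cm <- confusion_matrix(counts, c("A", "B"))
  expect_identical(cm$zero_rows, "B")
  out <- abundance_correct(cm, c(A = 0.8, B = 0.2))
  R <- rbind(c(0.8, 0.2), c(0, 1))
  expect_equal(unname(out), drop(solve(t(R), c(0.8, 0.2))), tolerance = 1e-6)
})

test_that("top-k suggestions rank labels by score with label-order ties", {
  sc <- scores_from_matrix(rbind(c(0.1, 0.9, 0.5)), c("A", "B", "C"))
  sugg <- refine_suggestions(sc, k = 2L)
  expect_identical(sugg$label, c("B", "C"))

  full <- refine_suggestions(sc, k = 3L)
  expect_identical(full$label, c("B", "C", "A"))
  expect_error(refine_suggestions(sc, k = 4L), "exceeds")

  tie <- scores_from_matrix(rbind(c(0.5, 0.5, 0.1)), c("A", "B", "C"))
  expect_identical(refine_suggestions(tie, 2L)$label, c("A", "B"))

  # top-k hit rate dominates top-1 on simulated scores
  ls <- labelset(paste0("c", 1:5))
  set.seed(19)
  truth <- ann_multi_image(sample(ls$labels, 400, replace = TRUE), ls, 10L)
  sc2 <- simulate_scores(truth, score_sim_spec(
    uniform_confusion(ls$labels, 0.6), rng_seed = 20L))
  s3 <- refine_suggestions(sc2, k = 3L)
  key <- paste(s3$image_id, s3$point_index)
  truth_key <- paste(truth$image_id, truth$point_index)
  hit1 <- mean(s3$label[s3$rank == 1] ==
                 truth$label[match(key[s3$rank == 1], truth_key)])
  hit3 <- mean(tapply(seq_len(nrow(s3)), key, function(ix) {
    any(s3$label[ix] == truth$label[match(key[ix[1]], truth_key)])
  }))
  expect_gte(hit3, hit1)
})
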