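#' Per-image cover fractions
#'
#' The cover of a label in an image is the fraction of that image's
#' annotated points carrying the label — the estimator behind random point
#' annotation. Only labels observed in an image get a row; absent labels
#' have cover 0 implicitly.
#'
#' @param annset an [annotation_set].
#' @return a `cover_table`: long data frame with columns `image_id`,
#'   `annotator`, `label`, `cover`; covers sum to 1 within each image.
#' @export
cover <- function(annset) {
  stopifnot(inherits(annset, "annotation_set"))
  if (nrow(annset) == 0L) {
    abort_reefpoint("cannot compute cover of an empty annotation set",
                    "validation_error")
  }
  tab <- as.data.frame(table(image_id = annset$image_id,
                             label = annset$label),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, ]
  npt <- table(annset$image_id)
  out <- data.frame(image_id = tab$image_id,
                    annotator = attr(annset, "annotator_id"),
                    label = tab$label,
                    cover = tab$Freq / as.vector(npt[tab$image_id]))
  out <- out[order(out$image_id, out$label), ]
  rownames(out) <- NULL
  class(out) <- c("cover_table", "data.frame")
  out
}

#' Combine cover tables from several annotators
#'
#' @param ... `cover_table` objects (or a single list of them).
#' @return one `cover_table`.
#' @export
bind_covers <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1L]]) &&
      !inherits(args[[1L]], "data.frame")) {
    args <- args[[1L]]
  }
  out <- do.call(rbind, lapply(args, as.data.frame))
  class(out) <- c("cover_table", "data.frame")
  out
}

#' Aggregate proportion of a label group in an annotation set
#'
#' @param annset an [annotation_set].
#' @param group group name or label vector.
#' @return fraction of all points whose label belongs to the group.
#' @export
group_proportion <- function(annset, group) {
  stopifnot(inherits(annset, "annotation_set"))
  members <- label_group(attr(annset, "label_set"), group)
  mean(annset$label %in% members)
}

shared_labels <- function(reference, test) {
  rk <- ann_keys(reference)
  tk <- ann_keys(test)
  common <- intersect(rk, tk)
  if (!length(common)) {
    abort_reefpoint("no shared (image_id, point_index) keys",
                    "validation_error")
  }
  list(ref = reference$label[match(common, rk)],
       test = test$label[match(common, tk)])
}

#' Confusion matrix between two annotators
#'
#' Counts, over the shared keys, how often a point labelled `r` by the
#' reference annotator was labelled `c` by the test annotator. Points
#' present in only one set are dropped pairwise.
#'
#' @param reference,test [annotation_set] objects.
#' @param label_set a [labelset] fixing the row/column order (default: the
#'   reference's label set).
#' @return a `confusion_matrix`.
#' @export
confusion <- function(reference, test, label_set = NULL) {
  if (is.null(label_set)) label_set <- attr(reference, "label_set")
  p <- shared_labels(reference, test)
  L <- label_set$labels
  tab <- table(factor(p$ref, levels = L), factor(p$test, levels = L))
  confusion_matrix(as.matrix(unclass(tab)), L)
}

kappa_from_pairs <- function(ref, test) {
  n <- length(ref)
  p_o <- mean(ref == test)
  labs <- union(ref, test)
  p_ref <- table(factor(ref, levels = labs)) / n
  p_test <- table(factor(test, levels = labs)) / n
  p_e <- sum(as.vector(p_ref) * as.vector(p_test))
  if (p_e >= 1 - 1e-12) {
    if (p_o >= 1 - 1e-12) return(1)
    abort_reefpoint("degenerate kappa: both annotators constant but unequal",
                    "degenerate_error")
  }
  (p_o - p_e) / (1 - p_e)
}

#' Cohen's kappa between two annotators
#'
#' Chance-corrected agreement `(p_o - p_e)/(1 - p_e)` over the shared
#' keys, with chance agreement computed from the two annotators' marginal
#' label distributions. When both annotators are constant and identical
#' the statistic is defined as 1.
#'
#' @param reference,test [annotation_set] objects sharing at least one key.
#' @return kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(reference, test) {
  p <- shared_labels(reference, test)
  kappa_from_pairs(p$ref, p$test)
}

#' Group (binary) Cohen's kappa
#'
#' Collapses the label set to "in the group" versus "not in the group" and
#' computes Cohen's kappa of the resulting binary task — the agreement
#' measure used for functional groups such as coral or turf algae.
#'
#' @param reference,test [annotation_set] objects.
#' @param group group name or label vector.
#' @return kappa of the binary task.
#' @export
kappa_group <- function(reference, test, group) {
  members <- label_group(attr(reference, "label_set"), group)
  p <- shared_labels(reference, test)
  kappa_from_pairs(ifelse(p$ref %in% members, "in", "out"),
                   ifelse(p$test %in% members, "in", "out"))
}

#' Closed-form expected kappa of a simulated annotator
#'
#' For an annotator drawn from a row-stochastic confusion matrix over a
#' known true-label prevalence, the expected observed agreement is
#' `sum(prev * diag(rates))` and the chance agreement follows from the
#' implied marginals. Serves as the analytic oracle against which
#' empirical kappas of simulated annotators are checked.
#'
#' @param rates row-stochastic confusion rates (row = true label).
#' @param prevalence true-label distribution (sums to 1), in row order.
#' @return the expected Cohen's kappa.
#' @export
expected_kappa <- function(rates, prevalence) {
  rates <- as.matrix(rates)
  stopifnot(length(prevalence) == nrow(rates),
            abs(sum(prevalence) - 1) < 1e-8)
  p_o <- sum(prevalence * diag(rates))
  marg_test <- drop(prevalence %*% rates)
  p_e <- sum(prevalence * marg_test)
  (p_o - p_e) / (1 - p_e)
}

#' Per-image cover differences against a reference annotator
#'
#' For every annotator, image and label, the difference
#' `d = cover - cover_reference`; per annotator and label the mean
#' difference `e` (the bias over images). Labels never observed by either
#' annotator in an image count as cover 0. Images missing for an
#' annotator are excluded from that annotator's differences with a
#' warning.
#'
#' @param covers a `cover_table` holding the reference annotator and at
#'   least one other.
#' @param reference_annotator annotator id of the baseline.
#' @return an object of class `cover_diff_summary` with data frames `d`
#'   (`annotator`, `image_id`, `label`, `d`) and `e` (`annotator`,
#'   `label`, `e`, `n_images`).
#' @export
cover_diffs <- function(covers, reference_annotator = "Archived") {
  covers <- as.data.frame(covers)
  if (!reference_annotator %in% covers$annotator) {
    abort_reefpoint("reference annotator absent from cover table",
                    "validation_error")
  }
  ref <- covers[covers$annotator == reference_annotator, ]
  ref_imgs <- unique(ref$image_id)
  labels <- sort(unique(covers$label))
  others <- setdiff(unique(covers$annotator), reference_annotator)
  if (!length(others)) {
    empty_d <- data.frame(annotator = character(0), image_id = character(0),
                          label = character(0), d = numeric(0))
    empty_e <- data.frame(annotator = character(0), label = character(0),
                          e = numeric(0), n_images = integer(0))
    return(structure(list(d = empty_d, e = empty_e,
                          reference = reference_annotator),
                     class = "cover_diff_summary"))
  }
  full_ref <- expand_cover(ref, ref_imgs, labels)

  d_rows <- lapply(others, function(a) {
    sub <- covers[covers$annotator == a, ]
    imgs <- intersect(unique(sub$image_id), ref_imgs)
    missing <- setdiff(ref_imgs, unique(sub$image_id))
    if (length(missing)) {
      warning(sprintf("annotator '%s' missing %d reference image(s); excluded",
                      a, length(missing)))
    }
    fa <- expand_cover(sub, imgs, labels)
    fr <- full_ref[full_ref$image_id %in% imgs, ]
    data.frame(annotator = a, image_id = fa$image_id, label = fa$label,
               d = fa$cover - fr$cover)
  })
  d <- do.call(rbind, d_rows)
  agg <- stats::aggregate(d$d, by = list(annotator = d$annotator,
                                         label = d$label),
                          FUN = mean)
  nimg <- stats::aggregate(d$image_id,
                           by = list(annotator = d$annotator,
                                     label = d$label),
                           FUN = function(x) length(unique(x)))
  e <- data.frame(annotator = agg$annotator, label = agg$label, e = agg$x,
                  n_images = nimg$x)
  structure(list(d = d, e = e, reference = reference_annotator),
            class = "cover_diff_summary")
}

expand_cover <- function(sub, imgs, labels) {
  full <- expand.grid(image_id = imgs, label = labels,
                      stringsAsFactors = FALSE)
  full <- full[order(full$image_id, full$label), ]
  m <- match(paste(full$image_id, full$label, sep = "\r"),
             paste(sub$image_id, sub$label, sep = "\r"))
  full$cover <- ifelse(is.na(m), 0, sub$cover[m])
  rownames(full) <- NULL
  full
}

#' @export
print.cover_diff_summary <- function(x, ...) {
  cat(sprintf("<cover_diff_summary> vs '%s': %d annotators, %d labels\n",
              x$reference, length(unique(x$e$annotator)),
              length(unique(x$e$label))))
  invisible(x)
}

#' Mean absolute error of cover biases
#'
#' The mean of `|e|` (absolute per-annotator, per-label bias) over a
#' grouping of the bias table — e.g. all locations for one substratum and
#' one annotator group.
#'
#' @param diffs a `cover_diff_summary`.
#' @param labels restrict to these labels (default all).
#' @param annotators restrict to these annotators (default all).
#' @return mean absolute bias (same units as cover, i.e. a fraction).
#' @export
cover_mae <- function(diffs, labels = NULL, annotators = NULL) {
  stopifnot(inherits(diffs, "cover_diff_summary"))
  e <- diffs$e
  if (!is.null(labels)) e <- e[e$label %in% labels, ]
  if (!is.null(annotators)) e <- e[e$annotator %in% annotators, ]
  if (!nrow(e)) {
    abort_reefpoint("empty grouping for MAE", "validation_error")
  }
  mean(abs(e$e))
}

perm_t_stats <- function(signs, d) {
  n <- length(d)
  means <- drop(signs %*% d) / n
  ssq <- sum(d^2)
  v <- (ssq - n * means^2) / (n - 1)
  v[v < 0] <- 0
  t <- ifelse(v > 0, means / sqrt(v / n),
              ifelse(means == 0, 0, sign(means) * Inf))
  t
}

#' One-sample permutation t-test of zero mean
#'
#' Tests whether the mean of paired differences is zero by randomly
#' flipping the signs of the differences and recomputing the t statistic;
#' under the null of a symmetric zero-centered distribution all sign
#' patterns are equally likely. For `n <= 12` all `2^n` patterns are
#' enumerated exactly; otherwise `n_perm` random patterns are drawn and
#' the observed pattern is included in both numerator and denominator.
#' The two-sided p-value is the fraction of patterns with `|t*| >= |t|`.
#'
#' @param d numeric vector of differences.
#' @param n_perm Monte Carlo patterns when enumeration is not used.
#' @param rng_seed seed for the Monte Carlo draw.
#' @param comparisons number of simultaneous comparisons for the
#'   Bonferroni-adjusted threshold (default 8, giving 0.05/8 = 0.00625).
#' @param alpha family significance level (default 0.05).
#' @return list with `p_value`, `alpha_corrected`, `t_obs`, `exact`
#'   (whether full enumeration was used) and `n_patterns`.
#' @export
permutation_mean_test <- function(d, n_perm = 9999L, rng_seed = 1L,
                                  comparisons = 8L, alpha = 0.05) {
  d <- as.numeric(d)
  if (!length(d)) {
    abort_reefpoint("empty difference vector", "validation_error")
  }
  alpha_corrected <- alpha / comparisons
  if (all(d == 0)) {
    return(list(p_value = 1, alpha_corrected = alpha_corrected,
                t_obs = 0, exact = TRUE, n_patterns = 1L))
  }
  n <- length(d)
  t_obs <- perm_t_stats(matrix(1, 1L, n), d)
  if (n <= 12L) {
    m <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    t_all <- perm_t_stats(m, d)
    p <- mean(abs(t_all) >= abs(t_obs) - 1e-12)
    exact <- TRUE
    n_pat <- nrow(m)
  } else {
    signs <- with_private_seed(
      rng_seed,
      matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    )
    t_all <- perm_t_stats(signs, d)
    p <- (1 + sum(abs(t_all) >= abs(t_obs) - 1e-12)) / (n_perm + 1)
    exact <- FALSE
    n_pat <- n_perm + 1L
  }
  list(p_value = p, alpha_corrected = alpha_corrected, t_obs = t_obs,
       exact = exact, n_patterns = n_pat)
}

#' Percentile-t bootstrap confidence interval for a mean
#'
#' Studentized bootstrap: resamples the data, computes
#' `t* = (mean* - mean)/se*` for each resample, and returns
#' `(mean - q_{1-alpha/2} * se, mean - q_{alpha/2} * se)` where the `q`
#' are quantiles of the bootstrap t distribution and `se` the sample
#' standard error. The original sample is included as one replicate. A
#' constant input yields a zero-width interval at that value.
#'
#' @param d numeric vector.
#' @param alpha two-sided miscoverage (default 0.05 for a 95% interval).
#' @param n_boot number of bootstrap resamples.
#' @param rng_seed seed.
#' @return named numeric vector `c(low, high)`.
#' @export
bootstrap_percentile_t_ci <- function(d, alpha = 0.05, n_boot = 999L,
                                      rng_seed = 1L) {
  d <- as.numeric(d)
  n <- length(d)
  if (n < 2L || length(unique(d)) == 1L) {
    v <- if (n) d[1L] else NA_real_
    return(c(low = v, high = v))
  }
  m <- mean(d)
  se <- stats::sd(d) / sqrt(n)
  boot <- with_private_seed(rng_seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n, n_boot)
    bm <- colMeans(matrix(d[idx], n, n_boot))
    bs <- apply(matrix(d[idx], n, n_boot), 2L, stats::sd) / sqrt(n)
    tstar <- ifelse(bs > 0, (bm - m) / bs,
                    ifelse(bm == m, 0, sign(bm - m) * Inf))
    c(tstar, 0)  # the original sample contributes t* = 0
  })
  q <- stats::quantile(boot, c(alpha / 2, 1 - alpha / 2), names = FALSE,
                       type = 7)
  c(low = m - q[2L] * se, high = m - q[1L] * se)
}

#' Standard nonparametric tests and correlation
#'
#' Thin delegation to the established routines: Mann-Whitney U
#' ([stats::wilcox.test()]), Kruskal-Wallis ([stats::kruskal.test()]),
#' one-sample Kolmogorov-Smirnov ([stats::ks.test()]) and Pearson
#' correlation ([stats::cor.test()]). Statistics and p-values are passed
#' through unchanged.
#'
#' @param x numeric vector, or list of numeric vectors for Kruskal-Wallis.
#' @param y second sample (Mann-Whitney), paired vector (Pearson), or a
#'   cumulative distribution function name such as "pnorm"
#'   (Kolmogorov-Smirnov).
#' @param test one of "mann_whitney", "kruskal_wallis", "ks", "pearson".
#' @param ... further arguments to the underlying test.
#' @return list with `statistic`, `p_value`, `method`.
#' @export
standard_tests <- function(x, y = NULL,
                           test = c("mann_whitney", "kruskal_wallis", "ks",
                                    "pearson"),
                           ...) {
  test <- match.arg(test)
  res <- switch(
    test,
    mann_whitney = {
      if (is.null(y)) abort_reefpoint("mann_whitney needs two samples",
                                      "validation_error")
      stats::wilcox.test(x, y, ...)
    },
    kruskal_wallis = {
      if (!is.list(x)) abort_reefpoint("kruskal_wallis needs a list of samples",
                                       "validation_error")
      stats::kruskal.test(x, ...)
    },
    ks = {
      if (is.null(y)) abort_reefpoint("ks needs a reference distribution",
                                      "validation_error")
      stats::ks.test(x, y, ...)
    },
    pearson = {
      if (is.null(y)) abort_reefpoint("pearson needs two samples",
                                      "validation_error")
      stats::cor.test(x, y, method = "pearson", ...)
    }
  )
  list(statistic = unname(res$statistic), p_value = res$p.value,
       method = res$method, estimate = unname(res$estimate),
       parameter = unname(res$parameter))
}
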