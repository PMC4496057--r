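# Shared builders for the test suite. Everything is generated in code;
# no stored fixtures.

ls_ab <- function() labelset(c("A", "B"))

ls4 <- function() labelset(paste0("class", 1:4),
                           groups = list(g1 = "class1"))

# annotation set from a label vector, one image, points 0..n-1
ann_from_labels <- function(labels, label_set, annotator = "x",
                            image_id = "img1") {
  annotation_set(
    data.frame(image_id = image_id,
               point_index = seq_along(labels) - 1L,
               row = 0L, col = seq_along(labels) - 1L,
               label = labels),
    label_set, annotator
  )
}

# annotation set spread over images: n_points per image
ann_multi_image <- function(labels, label_set, n_per_image,
                            annotator = "x") {
  n <- length(labels)
  stopifnot(n %% n_per_image == 0)
  annotation_set(
    data.frame(
      image_id = sprintf("im%04d", rep(seq_len(n / n_per_image),
                                       each = n_per_image)),
      point_index = rep(seq_len(n_per_image) - 1L, n / n_per_image),
      row = 0L, col = 0L, label = labels
    ),
    label_set, annotator
  )
}

# score matrix over labels with given score rows
scores_from_matrix <- function(m, labels, image_id = "img1") {
  n <- nrow(m)
  score_matrix(
    data.frame(image_id = rep(image_id, n),
               point_index = seq_len(n) - 1L,
               row = rep(0L, n), col = rep(0L, n)),
    m, labels
  )
}

# two well-separated Gaussian clusters in 5 dims
separable_clusters <- function(n_per = 20L, gap = 10, seed = 1L) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * 5), n_per),
             matrix(rnorm(n_per * 5, mean = gap), n_per))
  list(X = X, y = rep(c("A", "B"), each = n_per))
}

# random truth annotation set over k labels
random_truth <- function(n, label_set, n_per_image = 10L, seed = 1L,
                         prob = NULL) {
  set.seed(seed)
  labs <- sample(label_set$labels, n, replace = TRUE, prob = prob)
  ann_multi_image(labs, label_set, n_per_image, annotator = "Archived")
}
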