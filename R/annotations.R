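#' Construct an annotation set
#'
#' An annotation set is one annotator's point labels: one row per annotated
#' point, keyed by `(image_id, point_index)`, with 0-based pixel coordinates
#' (`row` 0 is the image top) and a label drawn from a [labelset].
#'
#' @param df data frame with columns `image_id`, `point_index`, `row`, `col`,
#'   `label`.
#' @param label_set the [labelset] the labels belong to.
#' @param annotator_id identifier of the annotator (e.g. "Archived", "Host",
#'   "Automated").
#' @return an object of class `annotation_set` (a data frame).
#' @export
annotation_set <- function(df, label_set, annotator_id = "unknown") {
  stopifnot(inherits(label_set, "labelset"))
  required <- c("image_id", "point_index", "row", "col", "label")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    abort_reefpoint(
      sprintf("missing columns: %s", paste(missing_cols, collapse = ", ")),
      "format_error"
    )
  }
  df <- as.data.frame(df)[required]
  df$image_id <- as.character(df$image_id)
  df$point_index <- as.integer(df$point_index)
  df$row <- as.integer(df$row)
  df$col <- as.integer(df$col)
  df$label <- as.character(df$label)
  if (nrow(df)) {
    if (any(df$point_index < 0L) || any(df$row < 0L) || any(df$col < 0L)) {
      abort_reefpoint("point_index, row and col must be non-negative",
                      "validation_error")
    }
    key <- paste(df$image_id, df$point_index, sep = "\r")
    if (anyDuplicated(key)) {
      abort_reefpoint("at most one label per (image_id, point_index)",
                      "validation_error")
    }
    unknown <- !(df$label %in% label_set$labels)
    if (any(unknown)) {
      offenders <- which(unknown)
      abort_reefpoint(
        sprintf(
          "labels not in label set (rows %s): %s",
          paste(utils::head(offenders, 10L), collapse = ", "),
          paste(unique(df$label[unknown]), collapse = ", ")
        ),
        "validation_error"
      )
    }
  }
  rownames(df) <- NULL
  structure(df,
            label_set = label_set,
            annotator_id = annotator_id,
            class = c("annotation_set", "data.frame"))
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> annotator '%s': %d points, %d images\n",
              attr(x, "annotator_id"), nrow(x),
              length(unique(x$image_id))))
  if (nrow(x)) print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

ann_keys <- function(x) paste(x$image_id, x$point_index, sep = "\r")

#' Read point annotations from a delimited table
#'
#' The file must be a CSV (comma- or tab-separated) with header columns
#' `image_id,point_index,row,col,label`. Labels are validated against the
#' label set; a remap preset (or explicit `c(source = target)` vector) may
#' be applied first so legacy vocabularies are translated on the way in.
#'
#' @param path path to the table.
#' @param label_set a [labelset].
#' @param annotator_id annotator identifier to attach.
#' @param remap `NULL`, the name of a remap preset declared in the label
#'   set, or a named character vector `c(source = target)`.
#' @return an [annotation_set].
#' @export
read_annotations <- function(path, label_set, annotator_id = "unknown",
                             remap = NULL) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", fileEncoding = "UTF-8")
  required <- c("image_id", "point_index", "row", "col", "label")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    abort_reefpoint(
      sprintf("annotation table %s lacks columns: %s", path,
              paste(missing_cols, collapse = ", ")),
      "format_error"
    )
  }
  if (!is.null(remap)) {
    df$label <- apply_remap_chr(df$label, resolve_remap(label_set, remap))
  }
  unknown <- !(df$label %in% label_set$labels)
  if (any(unknown)) {
    rows <- which(unknown)
    abort_reefpoint(
      sprintf("unknown labels at file rows %s: %s",
              paste(utils::head(rows, 10L), collapse = ", "),
              paste(unique(df$label[unknown]), collapse = ", ")),
      "validation_error"
    )
  }
  annotation_set(df, label_set, annotator_id)
}

#' Write point annotations to CSV
#'
#' Inverse of [read_annotations()]: writes the five-column UTF-8 CSV; an
#' empty set yields a header-only file.
#'
#' @param annset an [annotation_set].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annset, path) {
  stopifnot(inherits(annset, "annotation_set"))
  utils::write.csv(as.data.frame(annset), path, row.names = FALSE,
                   quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

resolve_remap <- function(label_set, remap) {
  if (is.character(remap) && length(remap) == 1L && is.null(names(remap))) {
    if (!remap %in% names(label_set$remaps)) {
      abort_reefpoint(sprintf("unknown remap preset '%s'", remap),
                      "labelset_error")
    }
    remap <- label_set$remaps[[remap]]
  }
  if (is.null(names(remap)) && length(remap) > 0L) {
    abort_reefpoint("remap must be a named character vector c(source = target)",
                    "labelset_error")
  }
  bad <- setdiff(unname(remap), label_set$labels)
  if (length(bad)) {
    abort_reefpoint(
      sprintf("remap targets not in label set: %s", paste(bad, collapse = ", ")),
      "labelset_error"
    )
  }
  remap
}

apply_remap_chr <- function(labels, remap) {
  hit <- labels %in% names(remap)
  labels[hit] <- unname(remap[labels[hit]])
  labels
}

#' Remap labels in an annotation set
#'
#' Applies a many-to-one label mapping (e.g. collapsing coral genera to a
#' generic hard-coral label, or translating a legacy vocabulary). The number
#' of points never changes.
#'
#' @param annset an [annotation_set].
#' @param remap a remap preset name declared in the label set, or a named
#'   character vector `c(source = target)`.
#' @return the remapped [annotation_set].
#' @export
remap_labels <- function(annset, remap) {
  stopifnot(inherits(annset, "annotation_set"))
  label_set <- attr(annset, "label_set")
  remap <- resolve_remap(label_set, remap)
  df <- as.data.frame(annset)
  df$label <- apply_remap_chr(df$label, remap)
  annotation_set(df, label_set, attr(annset, "annotator_id"))
}

#' Harmonize transect-hardware annotations across annotators
#'
#' Some annotators label points that fall on sampling apparatus as
#' 'Transect hardware' while others label the substratum inferred beneath
#' it. Whenever at least `threshold` of the sets label a point as hardware,
#' the point is set to the hardware label in every set; other points are
#' untouched. The operation is idempotent.
#'
#' @param sets list of [annotation_set] objects sharing identical
#'   `(image_id, point_index)` keys and label set.
#' @param threshold minimum number of annotators calling a point hardware
#'   for the majority rule to fire (default 2).
#' @param hardware_label name of the hardware label.
#' @return list of harmonized [annotation_set] objects.
#' @export
harmonize_transect_hardware <- function(sets, threshold = 2L,
                                        hardware_label = "Transect hardware") {
  stopifnot(length(sets) >= 1L, all(vapply(sets, inherits, TRUE,
                                           "annotation_set")))
  keys <- lapply(sets, ann_keys)
  ref <- sort(keys[[1L]])
  for (i in seq_along(keys)) {
    if (!identical(sort(keys[[i]]), ref)) {
      abort_reefpoint("annotation sets have mismatched (image_id, point_index) keys",
                      "validation_error")
    }
  }
  hw_count <- Reduce(`+`, lapply(sets, function(s) {
    stats::setNames(as.integer(s$label == hardware_label), ann_keys(s))[ref]
  }))
  flip <- names(hw_count)[hw_count >= threshold]
  lapply(sets, function(s) {
    df <- as.data.frame(s)
    df$label[ann_keys(s) %in% flip] <- hardware_label
    annotation_set(df, attr(s, "label_set"), attr(s, "annotator_id"))
  })
}

#' Rebalance a reference set by discarding out-of-group annotations
#'
#' Training pools assembled from archived surveys carry the class proportions
#' of the survey itself. To avoid evaluating a classifier under the
#' assumption that training and test proportions match, a uniformly random
#' subset of the annotations outside a focal group (e.g. non-coral points)
#' is discarded so that the group's proportion increases by a stated relative
#' fraction. All group members are retained; the discard count is the one
#' that brings the achieved proportion closest to the target, ties broken
#' toward fewer discards.
#'
#' @param annset an [annotation_set].
#' @param group group name or label vector (the set whose proportion grows).
#' @param increase relative increase of the group proportion (default 0.10,
#'   i.e. a 10 percent relative increase).
#' @param rng_seed integer seed controlling which points are discarded.
#' @return the thinned [annotation_set].
#' @export
rebalance_reference <- function(annset, group, increase = 0.10,
                                rng_seed = 1L) {
  stopifnot(inherits(annset, "annotation_set"))
  label_set <- attr(annset, "label_set")
  members <- label_group(label_set, group)
  in_group <- annset$label %in% members
  n_in <- sum(in_group)
  n_out <- sum(!in_group)
  if (n_out == 0L) {
    abort_reefpoint("no out-of-group annotations to discard", "infeasible_error")
  }
  p <- n_in / (n_in + n_out)
  target <- p * (1 + increase)
  if (target > 1) {
    abort_reefpoint(
      sprintf("target proportion %.4f exceeds 1; infeasible", target),
      "infeasible_error"
    )
  }
  if (increase == 0) return(annset)
  keep_out <- optimal_keep_count(n_in, n_out, target)
  idx_out <- which(!in_group)
  kept <- with_private_seed(rng_seed, sort(sample(idx_out, keep_out)))
  df <- as.data.frame(annset)[sort(c(which(in_group), kept)), , drop = FALSE]
  annotation_set(df, label_set, attr(annset, "annotator_id"))
}

# Number of out-of-group annotations to keep so that C/(C+N') is closest to
# the target proportion; ties go to the larger keep count (fewer discards).
optimal_keep_count <- function(n_in, n_out, target) {
  ideal <- n_in * (1 - target) / target
  cand <- unique(pmax(0L, pmin(n_out, c(floor(ideal), ceiling(ideal)))))
  err <- abs(n_in / (n_in + cand) - target)
  best <- cand[err == min(err)]
  as.integer(max(best))
}
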