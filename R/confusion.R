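#' Construct a confusion matrix
#'
#' Rows index the reference (true) label, columns the assigned label. The
#' `rates` slot is the row-normalized matrix; rows with zero total count
#' are flagged in `zero_rows` and carry `NA` rates.
#'
#' @param counts non-negative integer matrix with identical row and column
#'   label order.
#' @param labels character vector naming rows and columns.
#' @return an object of class `confusion_matrix` with fields `labels`,
#'   `counts`, `rates`, `zero_rows`.
#' @export
confusion_matrix <- function(counts, labels = rownames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(labels)) {
    abort_reefpoint("labels required", "validation_error")
  }
  if (nrow(counts) != length(labels) || ncol(counts) != length(labels)) {
    abort_reefpoint("counts must be square over the labels",
                    "validation_error")
  }
  if (any(counts < 0)) {
    abort_reefpoint("counts must be non-negative", "validation_error")
  }
  dimnames(counts) <- list(labels, labels)
  tot <- rowSums(counts)
  rates <- counts / ifelse(tot > 0, tot, NA_real_)
  structure(list(labels = as.character(labels),
                 counts = counts,
                 rates = rates,
                 zero_rows = labels[tot == 0]),
            class = "confusion_matrix")
}

#' Build a confusion matrix directly from row-stochastic rates
#'
#' Used to specify simulated annotators and classifiers: counts are left at
#' zero and only the rate matrix is meaningful.
#'
#' @param rates row-stochastic matrix (each row sums to 1).
#' @param labels label names.
#' @return a `confusion_matrix`.
#' @export
confusion_from_rates <- function(rates, labels = rownames(rates)) {
  rates <- as.matrix(rates)
  if (is.null(labels)) labels <- paste0("class", seq_len(nrow(rates)))
  if (nrow(rates) != ncol(rates)) {
    abort_reefpoint("rates must be square", "validation_error")
  }
  if (any(rates < 0) || any(abs(rowSums(rates) - 1) > 1e-8)) {
    abort_reefpoint("rates must be row-stochastic", "validation_error")
  }
  cm <- confusion_matrix(matrix(0L, nrow(rates), ncol(rates),
                                dimnames = list(labels, labels)), labels)
  cm$rates <- rates
  dimnames(cm$rates) <- list(labels, labels)
  cm$zero_rows <- character(0)
  cm
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> %d labels, %d annotations\n",
              length(x$labels), sum(x$counts)))
  if (length(x$zero_rows)) {
    cat("  zero-count rows:", paste(x$zero_rows, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write / read a confusion matrix as CSV
#'
#' First column holds the reference label, the header the assigned labels,
#' cells the counts; rates are re-derived on load.
#'
#' @param cm a `confusion_matrix`.
#' @param path file path.
#' @return `write_confusion` returns `path` invisibly; `read_confusion` a
#'   `confusion_matrix`.
#' @export
write_confusion <- function(cm, path) {
  stopifnot(inherits(cm, "confusion_matrix"))
  df <- data.frame(reference = cm$labels, cm$counts, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_confusion
#' @export
read_confusion <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        fileEncoding = "UTF-8")
  labels <- as.character(df[[1L]])
  confusion_matrix(as.matrix(df[-1L]), labels)
}
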