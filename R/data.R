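#' Construct an expression dataset
#'
#' The container consumed by training and the holdout experiment: a
#' genes-by-samples matrix of continuous expression values with a -1/+1
#' class label per sample (-1 normal mucosa, +1 tumor).
#'
#' @param values Numeric matrix, genes in rows, samples in columns.
#' @param genes Character vector of gene names (defaults to rownames).
#' @param labels Numeric vector of -1/+1 labels, one per column.
#' @param samples Optional sample identifiers (defaults to colnames or
#'   `s1..sn`).
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(values, genes = rownames(values), labels,
                               samples = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(genes)) stop("gene names are required", call. = FALSE)
  if (anyDuplicated(genes))
    stop("duplicate gene names; disambiguate with suffixes first",
         call. = FALSE)
  if (length(genes) != nrow(values))
    stop("length(genes) != nrow(values)", call. = FALSE)
  if (length(labels) != ncol(values))
    stop("one label per sample column is required", call. = FALSE)
  .check_labels(labels)
  if (!all(is.finite(values))) stop("non-finite expression values",
                                    call. = FALSE)
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  structure(list(genes = genes, samples = samples, values = values,
                 labels = as.numeric(labels)),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %d genes x %d samples (%d normal, %d tumor)\n",
              nrow(x$values), ncol(x$values),
              sum(x$labels == -1), sum(x$labels == 1)))
  invisible(x)
}

#' Subset the samples of an expression dataset
#'
#' @param dataset An `expression_dataset`.
#' @param idx Column (sample) indices to keep.
#' @return An `expression_dataset` with the selected samples.
#' @export
subset_samples <- function(dataset, idx) {
  expression_dataset(dataset$values[, idx, drop = FALSE],
                     genes = dataset$genes,
                     labels = dataset$labels[idx],
                     samples = dataset$samples[idx])
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.expression_dataset <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "gene") %>%
    tidyr::pivot_longer(-"gene", names_to = "sample", values_to = "expression") %>%
    dplyr::left_join(tibble::tibble(sample = x$samples, label = x$labels),
                     by = "sample")
}
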