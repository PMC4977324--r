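#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a trained network into a long table of CPT entries
#'
#' @param x A `trained_network`.
#' @param ... Unused.
#' @return A tibble: `node`, `parents` (comma-joined), `config` (column
#'   index, first-listed parent varying fastest), `state` (`off`/`on`),
#'   `probability`.
#' @export
tidy.trained_network <- function(x, ...) {
  purrr::map_dfr(x$tables, function(tb) {
    ncfg <- ncol(tb$prob)
    tibble::tibble(
      node = tb$node,
      parents = paste(tb$parents, collapse = ","),
      config = rep(seq_len(ncfg), each = 2),
      state = rep(c("off", "on"), ncfg),
      probability = as.vector(tb$prob)
    )
  })
}

#' One-row summary of a trained network
#'
#' @param x A `trained_network`.
#' @param ... Unused.
#' @return A tibble with `variant`, `n_nodes`, `n_edges`, `n_gene_nodes`,
#'   `etgn`, `smoothing_on`.
#' @export
glance.trained_network <- function(x, ...) {
  cats <- vapply(x$topology$nodes, `[[`, "", "category")
  tibble::tibble(
    variant = x$topology$variant,
    n_nodes = x$topology$n,
    n_edges = nrow(x$topology$edges),
    n_gene_nodes = sum(cats == "gene"),
    etgn = x$config$etgn,
    smoothing_on = x$config$smoothing_on
  )
}

#' Tidy an ROC curve
#'
#' @param x A `roc_curve` from [compute_roc()].
#' @param ... Unused.
#' @return A tibble with `fpr` and `tpr`.
#' @export
tidy.roc_curve <- function(x, ...) {
  tibble::tibble(fpr = x$fpr, tpr = x$tpr)
}

#' One-row summary of a holdout evaluation
#'
#' @param x A `holdout_evaluation` from [evaluate_holdout()].
#' @param ... Unused.
#' @return A tibble with `n`, `auc_trcmplx`, `auc_sample`, `ks_statistic`,
#'   `ks_p_value`, `ks_h01`.
#' @export
glance.holdout_evaluation <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    auc_trcmplx = x$roc_trcmplx$auc,
    auc_sample = if (is.null(x$roc_sample)) NA_real_ else x$roc_sample$auc,
    ks_statistic = if (is.null(x$ks)) NA_real_ else x$ks$statistic,
    ks_p_value = if (is.null(x$ks)) NA_real_ else x$ks$p_value,
    ks_h01 = if (is.null(x$ks)) NA_integer_ else x$ks$h01
  )
}

#' Plot an ROC curve
#'
#' @param object A `roc_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot the posterior distributions of a holdout run
#'
#' Density of the transcription-complex (and, when present, sample)
#' posteriors split by the true class.
#'
#' @param object A `holdout_result` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.holdout_result <- function(object, ...) {
  dat <- object %>%
    dplyr::mutate(class = ifelse(.data$true_label > 0, "tumor", "normal")) %>%
    tidyr::pivot_longer(dplyr::any_of(c("pr_trcmplx", "pr_sample")),
                        names_to = "query", values_to = "posterior") %>%
    dplyr::filter(!is.na(.data$posterior))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$posterior,
                                    fill = .data$class)) +
    ggplot2::geom_histogram(bins = 30, alpha = 0.6,
                            position = "identity") +
    ggplot2::facet_wrap(~query, scales = "free_y") +
    ggplot2::labs(x = "Posterior probability", y = "Test samples") +
    ggplot2::theme_minimal()
}
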