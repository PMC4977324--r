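#' ROC curve and AUC for holdout scores
#'
#' Threshold-sweep ROC with trapezoidal area under the curve. Tied scores
#' are grouped at a single threshold and the curve carries the (0,0) and
#' (1,1) sentinels. The direction is fixed (higher score means tumor), so a
#' perfectly inverted scorer yields an AUC of 0, not 0.5.
#'
#' @param scores Finite numeric prediction scores (e.g. posterior
#'   probabilities of an active transcription complex).
#' @param labels -1/+1 truth labels, both classes present.
#' @return A list of class `roc_curve`: `fpr`, `tpr` (nondecreasing from 0
#'   to 1) and `auc`.
#' @examples
#' compute_roc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, -1, -1))$auc  # 1
#' @export
compute_roc <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels differ in length", call. = FALSE)
  .check_labels(labels)
  if (!all(is.finite(scores))) stop("non-finite scores", call. = FALSE)
  if (length(unique(labels)) < 2)
    stop("both classes must be present", call. = FALSE)
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(-1, 1), direction = "<", quiet = TRUE)
  # pROC reports specificity/sensitivity from the (1,1) end; reorient
  fpr <- rev(1 - r$specificities)
  tpr <- rev(r$sensitivities)
  structure(list(fpr = fpr, tpr = tpr, auc = as.numeric(r$auc)),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d points, AUC = %.4f\n", length(x$fpr), x$auc))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Compares the empirical distributions of two prediction vectors (e.g. the
#' transcription-complex and sample posteriors of a holdout run). The
#' statistic is the supremum of the absolute ECDF difference; the p-value is
#' the asymptotic one with the usual effective-sample-size correction.
#'
#' @param x,y Nonempty numeric vectors.
#' @param alpha Significance level in (0, 1), default 0.05.
#' @return A list of class `ks_result`: `statistic`, `p_value`, `h01`
#'   (1 if the null of a common distribution is rejected at `alpha`, else 0)
#'   and `alpha`.
#' @examples
#' ks_two_sample(1:4, 5:8)$statistic   # 1
#' @export
ks_two_sample <- function(x, y, alpha = 0.05) {
  if (length(x) == 0 || length(y) == 0)
    stop("empty input vector", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  structure(list(statistic = as.numeric(kt$statistic),
                 p_value = kt$p.value,
                 h01 = as.integer(kt$p.value < alpha),
                 alpha = alpha),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("<ks_result> D = %.4f, p = %.4g, h01 = %d (alpha = %g)\n",
              x$statistic, x$p_value, x$h01, x$alpha))
  invisible(x)
}

#' Per-gene conditional summaries of the transcription-complex belief
#'
#' For every gene and true class, groups the holdout test samples by the
#' gene's evidence state (repressed/active), averages the posterior that the
#' transcription complex is active, determines the majority evidence state
#' per class (ties break toward repressed), and reports the majority-state
#' mean as the inferred belief.
#'
#' @param results A `holdout_result` tibble from
#'   [run_ge_experiment()] run with `keep_evidence = TRUE`.
#' @return A tibble: `gene`, `class`, `n_repressed`, `n_active`,
#'   `mean_repressed`, `mean_active` (NA when a group is empty),
#'   `majority_state`, `inferred_belief`, `relation`.
#' @export
summarize_gene_trcmplx <- function(results) {
  if (!"evidence" %in% names(results))
    stop("results lack the evidence column; rerun with keep_evidence = TRUE",
         call. = FALSE)
  long <- results %>%
    dplyr::mutate(class = ifelse(.data$true_label > 0, "tumor", "normal")) %>%
    dplyr::mutate(ev = purrr::map(.data$evidence, function(e)
      tibble::tibble(gene = names(e), state = as.integer(e)))) %>%
    dplyr::select("class", "pr_trcmplx", "ev") %>%
    tidyr::unnest("ev")

  grp_mean <- function(p, keep) if (any(keep)) mean(p[keep]) else NA_real_

  long %>%
    dplyr::group_by(.data$gene, .data$class) %>%
    dplyr::summarise(
      n_repressed = sum(.data$state == 1L),
      n_active = sum(.data$state == 2L),
      mean_repressed = grp_mean(.data$pr_trcmplx, .data$state == 1L),
      mean_active = grp_mean(.data$pr_trcmplx, .data$state == 2L),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      majority_state = ifelse(.data$n_active > .data$n_repressed,
                              "active", "repressed"),
      inferred_belief = ifelse(.data$majority_state == "active",
                               .data$mean_active, .data$mean_repressed),
      relation = dplyr::case_when(
        is.na(.data$inferred_belief) ~ "no evidence",
        TRUE ~ sprintf("%s mostly %s in %s; mean Pr(TRCMPLX active) = %.3f",
                       .data$gene, .data$majority_state, .data$class,
                       .data$inferred_belief)
      )
    )
}

#' Evaluate a holdout run
#'
#' Convenience wrapper producing the ROC/AUC of both prediction vectors and
#' the KS comparison between them.
#'
#' @param results A `holdout_result` tibble.
#' @param alpha KS significance level.
#' @return A list of class `holdout_evaluation`: `roc_trcmplx`,
#'   `roc_sample` (NULL for the naive-Bayes variant), `ks` (NULL likewise)
#'   and `n`.
#' @export
evaluate_holdout <- function(results, alpha = 0.05) {
  roc_t <- compute_roc(results$pr_trcmplx, results$true_label)
  has_sample <- !all(is.na(results$pr_sample))
  roc_s <- if (has_sample) compute_roc(results$pr_sample, results$true_label)
  ks <- if (has_sample) ks_two_sample(results$pr_trcmplx, results$pr_sample,
                                      alpha = alpha)
  structure(list(roc_trcmplx = roc_t, roc_sample = roc_s, ks = ks,
                 n = nrow(results)),
            class = "holdout_evaluation")
}

#' @export
print.holdout_evaluation <- function(x, ...) {
  cat(sprintf("<holdout_evaluation> n = %d, AUC(TRCMPLX) = %.4f", x$n,
              x$roc_trcmplx$auc))
  if (!is.null(x$roc_sample))
    cat(sprintf(", AUC(Sample) = %.4f, KS h01 = %d", x$roc_sample$auc,
                x$ks$h01))
  cat("\n")
  invisible(x)
}
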