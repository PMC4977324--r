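#' Enumerate all leave-pair-out splits
#'
#' Pairs every normal sample with every tumor sample as a two-sample test
#' set; the training fold is everything else. Iterations are ordered with
#' the normal index outer and the tumor index inner, so the plan is
#' deterministic.
#'
#' @param labels Numeric -1/+1 label vector.
#' @return A tibble with one row per iteration: `iteration`, `normal_idx`,
#'   `tumor_idx`, and `train_idx` (list-column of training sample indices).
#' @examples
#' plan <- generate_pairs(rep(c(-1, 1), each = 24))
#' nrow(plan)                    # 576
#' length(plan$train_idx[[1]])   # 46
#' @export
generate_pairs <- function(labels) {
  .check_labels(labels)
  normal <- which(labels == -1)
  tumor <- which(labels == +1)
  if (length(normal) == 0 || length(tumor) == 0)
    stop("both classes must be present", call. = FALSE)
  grid <- tidyr::expand_grid(normal_idx = normal, tumor_idx = tumor)
  all_idx <- seq_along(labels)
  dplyr::mutate(
    grid,
    iteration = dplyr::row_number(),
    train_idx = purrr::map2(.data$normal_idx, .data$tumor_idx,
                            function(i, j) setdiff(all_idx, c(i, j))),
    .before = 1
  )
}

#' Build gene-expression evidence for a test sample
#'
#' Discretizes each gene's test value against its training-fold threshold
#' (the training median): below the threshold means inactive (state 1),
#' at or above means active (state 2). The evidence covers every gene node
#' of the topology and nothing else.
#'
#' @param test_values Named numeric vector, gene name -> expression value.
#' @param thresholds Named numeric vector of per-gene training medians.
#' @param topology A `model_topology`.
#' @return Named integer vector of state indices over the gene nodes.
#' @export
build_ge_evidence <- function(test_values, thresholds, topology) {
  genes <- names(topology$nodes)[
    vapply(topology$nodes, `[[`, "", "category") == "gene"]
  missing <- setdiff(genes, names(test_values))
  if (length(missing) > 0)
    stop("missing gene measurement(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  missing_thr <- setdiff(genes, names(thresholds))
  if (length(missing_thr) > 0 || any(!is.finite(thresholds[genes])))
    stop("missing discretization threshold(s)", call. = FALSE)
  stats::setNames(
    vapply(genes, function(g)
      discretize(test_values[[g]], thresholds[[g]]), 1L),
    genes)
}

#' Run the exhaustive 2-holdout experiment with gene evidence
#'
#' For every (normal, tumor) test pair: trains the network on the remaining
#' samples, discretizes both test samples against the fold's thresholds,
#' and queries the posterior that the transcription complex is active — and,
#' for the variants that carry a `Sample` node, that the sample is tumorous —
#' with a fresh inference engine per test sample. Results are recorded per
#' test sample (two rows per iteration) with the true -1/+1 label.
#'
#' @param dataset An [expression_dataset()] with both classes.
#' @param variant Model variant, `"t1"`, `"t2"` or `"p1"`.
#' @param config A [training_config()].
#' @param keep_evidence If `TRUE`, the per-sample gene evidence is kept in a
#'   list-column (needed by [summarize_gene_trcmplx()]).
#' @return A tibble of class `holdout_result` with columns `iteration`,
#'   `test_idx`, `sample`, `true_label`, `pr_trcmplx`, `pr_sample` (`NA` for
#'   `"p1"`), and optionally `evidence`.
#' @export
run_ge_experiment <- function(dataset, variant = c("t1", "t2", "p1"),
                              config = training_config(),
                              keep_evidence = FALSE) {
  variant <- match.arg(variant)
  stopifnot(inherits(dataset, "expression_dataset"))
  plan <- generate_pairs(dataset$labels)
  has_sample <- variant != "p1"
  topology <- build_topology(variant)

  res <- purrr::pmap(plan, function(iteration, normal_idx, tumor_idx,
                                    train_idx) {
    train <- subset_samples(dataset, train_idx)
    net <- tryCatch(
      train_network(train, variant, config, topology = topology),
      error = function(e) stop("iteration ", iteration, ": ",
                               conditionMessage(e), call. = FALSE))
    purrr::map(c(normal_idx, tumor_idx), function(k) {
      ev <- build_ge_evidence(dataset$values[, k], net$thresholds, topology)
      tibble::tibble(
        iteration = iteration,
        test_idx = k,
        sample = dataset$samples[k],
        true_label = dataset$labels[k],
        pr_trcmplx = posterior_marginal(net, ev, "TRCMPLX")[2],
        pr_sample = if (has_sample)
          posterior_marginal(net, ev, "Sample")[2] else NA_real_,
        evidence = list(ev)
      )
    })
  })
  out <- dplyr::bind_rows(unlist(res, recursive = FALSE))
  if (!keep_evidence) out$evidence <- NULL
  class(out) <- c("holdout_result", class(out))
  out
}

#' Enumerate binary methylation configurations
#'
#' @param topology A `model_topology` with methylation nodes.
#' @param subsample Optional number of configurations to draw (without
#'   replacement, seeded) instead of the exhaustive 2^M set.
#' @param seed Seed used when `subsample` is given.
#' @return A list of named integer state vectors over the methylation nodes.
#' @export
methylation_configurations <- function(topology, subsample = NULL,
                                       seed = 1L) {
  me <- names(topology$nodes)[
    vapply(topology$nodes, `[[`, "", "category") == "methylation"]
  if (length(me) == 0)
    stop("variant has no methylation nodes", call. = FALSE)
  m <- length(me)
  total <- 2^m
  pick <- seq_len(total)
  if (!is.null(subsample) && subsample < total) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    pick <- sort(sample(pick, subsample))
  }
  lapply(pick, function(i) {
    bits <- as.integer(intToBits(i - 1L))[seq_len(m)]
    stats::setNames(bits + 1L, me)
  })
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Run the methylation-perturbation experiment
#'
#' For each leave-pair-out iteration the network is trained on the fold;
#' evidence then consists of methylation states only, swept over all 2^M
#' binary configurations of the M methylation nodes (or a seeded subsample),
#' and both posteriors are recorded per configuration.
#'
#' @inheritParams run_ge_experiment
#' @param subsample,seed Optional configuration subsample (see
#'   [methylation_configurations()]).
#' @param max_iterations Optionally restrict to the first iterations of the
#'   split plan (exhaustive by default).
#' @return A tibble: `iteration`, `config_id`, `config` (list-column of
#'   methylation evidence), `pr_trcmplx`, `pr_sample`, plus the iteration's
#'   true label pair.
#' @export
run_me_experiment <- function(dataset, variant = "t1",
                              config = training_config(),
                              subsample = NULL, seed = 1L,
                              max_iterations = NULL) {
  if (variant != "t1")
    stop("methylation evidence requires the epigenetic variant", call. = FALSE)
  stopifnot(inherits(dataset, "expression_dataset"))
  topology <- build_topology(variant)
  configs <- methylation_configurations(topology, subsample, seed)
  plan <- generate_pairs(dataset$labels)
  if (!is.null(max_iterations)) plan <- plan[seq_len(max_iterations), ]

  res <- purrr::pmap(plan, function(iteration, normal_idx, tumor_idx,
                                    train_idx) {
    train <- subset_samples(dataset, train_idx)
    net <- train_network(train, variant, config, topology = topology)
    purrr::imap(configs, function(ev, cfg_id) {
      tibble::tibble(
        iteration = iteration,
        config_id = cfg_id,
        config = list(ev),
        normal_idx = normal_idx,
        tumor_idx = tumor_idx,
        pr_trcmplx = posterior_marginal(net, ev, "TRCMPLX")[2],
        pr_sample = posterior_marginal(net, ev, "Sample")[2]
      )
    })
  })
  dplyr::bind_rows(unlist(res, recursive = FALSE))
}
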