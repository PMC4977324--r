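#' Configuration for the synthetic cohort generator
#'
#' The generator ancestrally samples the full epigenetic network under the
#' packaged parameters (fixed priors plus the printed gene tables), then
#' maps each gene's binary state to a continuous expression value through a
#' two-component Gaussian emitter. Defaults emulate the study cohort: 24
#' normal and 24 tumor samples over the 18 gene probes.
#'
#' @param n_normal,n_tumor Samples per class (>= 1).
#' @param mu_low,mu_high Emission means for the inactive/active state
#'   (`mu_low < mu_high`).
#' @param sigma Emission standard deviation (>= 0).
#' @param seed Integer seed; the generator is fully deterministic given the
#'   config.
#' @param network Generating `trained_network` (default
#'   [reference_network()]).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_normal = 24, n_tumor = 24,
                             mu_low = 0, mu_high = 1, sigma = 0.25,
                             seed = 1L, network = reference_network()) {
  if (n_normal < 1 || n_tumor < 1) stop("counts must be >= 1", call. = FALSE)
  if (mu_low >= mu_high) stop("mu_low must be < mu_high", call. = FALSE)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  structure(list(n_normal = n_normal, n_tumor = n_tumor, mu_low = mu_low,
                 mu_high = mu_high, sigma = sigma, seed = as.integer(seed),
                 network = network),
            class = "generator_config")
}

#' Generate a labeled synthetic expression cohort
#'
#' Sample (tissue status) is clamped to the requested class composition —
#' conditioning by intervention, guaranteeing exact class counts — and all
#' other nodes are ancestrally sampled in topological order from the
#' generating tables. Gene expression is emitted as
#' `Normal(mu_low, sigma)` for state 1 and `Normal(mu_high, sigma)` for
#' state 2.
#'
#' @param config A [generator_config()].
#' @return A list with `dataset` (an [expression_dataset()], genes x
#'   samples) and `truth` (a tibble of the latent binary states of every
#'   node per sample).
#' @examples
#' cohort <- generate_cohort(generator_config(seed = 7))
#' dim(cohort$dataset$values)    # 18 x 48
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  net <- config$network
  top <- net$topology
  order <- topological_order(top)
  n <- config$n_normal + config$n_tumor
  labels <- rep(c(-1, 1), c(config$n_normal, config$n_tumor))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  states <- matrix(NA_integer_, nrow = length(order), ncol = n,
                   dimnames = list(order, NULL))
  for (nd in order) {
    tb <- net$tables[[nd]]
    if (is.null(tb)) stop("generating table missing for node ", nd,
                          call. = FALSE)
    if (nd == "Sample") {
      states[nd, ] <- ifelse(labels > 0, 2L, 1L)  # clamped, not sampled
      next
    }
    cfg <- rep(1L, n)
    if (length(tb$parents) > 0) {
      mult <- 1L
      for (p in tb$parents) {
        cfg <- cfg + (states[p, ] - 1L) * mult
        mult <- mult * 2L
      }
    }
    p_on <- tb$prob[2, cfg]
    states[nd, ] <- 1L + (stats::runif(n) < p_on)
  }

  genes <- names(top$nodes)[
    vapply(top$nodes, `[[`, "", "category") == "gene"]
  mu <- c(config$mu_low, config$mu_high)
  expr <- matrix(stats::rnorm(length(genes) * n,
                              mean = mu[states[genes, ]],
                              sd = config$sigma),
                 nrow = length(genes),
                 dimnames = list(genes, paste0("s", seq_len(n))))

  truth <- tibble::as_tibble(t(states)) %>%
    dplyr::mutate(sample = paste0("s", seq_len(n)), label = labels,
                  .before = 1)
  list(
    dataset = expression_dataset(expr, genes = genes, labels = labels),
    truth = truth
  )
}

#' Six-sample worked fixture with hand-computed expectations
#'
#' A deliberately tiny dataset — expression values 1..6 for every gene, the
#' first three samples normal, the last three tumor — whose discretization
#' at the median threshold 3.5 yields the bin counts a = 0, b = 3, c = 3,
#' d = 0. The accompanying expectations are the hand-derived smoothed
#' probabilities for the estimation rules.
#'
#' @return A list with `dataset` (an [expression_dataset()] over the 18
#'   genes), `threshold`, `counts`, and `expected` (named list of smoothed
#'   CPT fragments: `sample_only_on` = Pr(on | normal), Pr(on | tumor);
#'   `trcmplx_only_on` likewise; `sample_me_col_n_m` = the (normal,
#'   methylated) column of the two-parent methylation rule, off then on).
#' @export
make_worked_fixture <- function() {
  genes <- gene_nodes()
  vals <- matrix(rep(1:6, each = length(genes)), nrow = length(genes),
                 dimnames = list(genes, paste0("s", 1:6)))
  labels <- c(-1, -1, -1, 1, 1, 1)
  list(
    dataset = expression_dataset(vals, genes = genes, labels = labels),
    threshold = 3.5,
    counts = list(a = 0L, b = 3L, c = 3L, d = 0L),
    expected = list(
      sample_only_on = c(normal = 1 / 3, tumor = 2 / 3),
      trcmplx_only_on = c(off = 1 / 3, on = 2 / 3),
      sample_me_col_n_m = c(off = 2 / 3, on = 1 / 3)
    )
  )
}
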