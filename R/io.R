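#' Read an expression matrix and labels from text files
#'
#' The matrix file is TSV/CSV: a header row of sample identifiers, first
#' column gene names, numeric cells. The labels file has one label per
#' sample, either -1/+1 or the tokens `n`/`t` (optionally with a sample-id
#' column). Duplicated gene symbols are disambiguated with `-1`, `-2`, ...
#' suffixes, mirroring the two DKK3 probe recordings.
#'
#' @param matrix_path Path to the genes-by-samples table.
#' @param labels_path Path to the label file.
#' @return An [expression_dataset()].
#' @export
read_expression <- function(matrix_path, labels_path) {
  delim <- if (grepl("\\.csv$", matrix_path, ignore.case = TRUE)) "," else "\t"
  tab <- tryCatch(
    readr::read_delim(matrix_path, delim = delim, col_types = readr::cols(),
                      progress = FALSE, show_col_types = FALSE),
    error = function(e) stop("cannot parse expression matrix: ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(tab) == 0 || ncol(tab) < 2)
    stop("expression matrix is empty or lacks sample columns", call. = FALSE)
  genes <- as.character(tab[[1]])
  vals <- as.matrix(tab[, -1])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(tab[, -1], is.numeric, TRUE))
    stop("non-numeric expression column(s): ",
         paste(names(tab[, -1])[bad], collapse = ", "), call. = FALSE)
  }
  # suffix duplicated symbols in order of appearance: DKK3 -> DKK3-1, DKK3-2
  dup <- genes[duplicated(genes)]
  for (g in unique(dup)) {
    at <- which(genes == g)
    genes[at] <- paste0(g, "-", seq_along(at))
  }

  ldelim <- if (grepl("\\.csv$", labels_path, ignore.case = TRUE)) "," else "\t"
  ltab <- tryCatch(
    readr::read_delim(labels_path, delim = ldelim, col_types = readr::cols(),
                      progress = FALSE, show_col_types = FALSE),
    error = function(e) stop("cannot parse labels: ", conditionMessage(e),
                             call. = FALSE))
  raw <- as.character(ltab[[ncol(ltab)]])
  labels <- dplyr::case_when(
    raw %in% c("-1", "n", "N", "normal") ~ -1,
    raw %in% c("1", "+1", "t", "T", "tumor", "tumorous") ~ 1,
    TRUE ~ NA_real_
  )
  if (anyNA(labels))
    stop("unknown label token(s): ",
         paste(unique(raw[is.na(labels)]), collapse = ", "), call. = FALSE)
  if (length(labels) != ncol(vals))
    stop(sprintf("label count (%d) != sample count (%d)", length(labels),
                 ncol(vals)), call. = FALSE)
  expression_dataset(vals, genes = genes, labels = labels,
                     samples = colnames(vals))
}

#' Write an expression dataset to text files
#'
#' Inverse of [read_expression()]: the matrix as TSV (header row of sample
#' ids, first column `gene`), the labels as a two-column CSV
#' (`sample,label`).
#'
#' @param dataset An [expression_dataset()].
#' @param matrix_path,labels_path Output paths.
#' @return `matrix_path`, invisibly.
#' @export
write_expression <- function(dataset, matrix_path, labels_path) {
  tab <- tibble::as_tibble(dataset$values, rownames = "gene")
  readr::write_tsv(tab, matrix_path, progress = FALSE)
  readr::write_csv(tibble::tibble(sample = dataset$samples,
                                  label = dataset$labels),
                   labels_path, progress = FALSE)
  invisible(matrix_path)
}

#' Pipeline run configuration
#'
#' Validates the configuration for [run_pipeline()]; unknown keys are
#' rejected to guard against silent typos.
#'
#' @param variant Model variant, `"t1"`, `"t2"` or `"p1"`.
#' @param evidence `"ge"` (gene expression) or `"me"` (methylation
#'   perturbation; `"t1"` only).
#' @param etgn,smoothing,smoothing_on Passed to [training_config()].
#' @param seed Integer seed (synthetic cohort and any subsampling).
#' @param matrix_path,labels_path Optional input files; when `NULL` a
#'   synthetic cohort is generated instead.
#' @param out_dir Output directory for result files.
#' @param alpha KS significance level.
#' @param me_subsample Optional number of methylation configurations.
#' @param n_normal,n_tumor,sigma Synthetic cohort settings (used only when
#'   no input files are given).
#' @return A list of class `run_config`.
#' @export
run_config <- function(variant = "t1", evidence = "ge", etgn = 0.9,
                       smoothing = 1, smoothing_on = "fractions", seed = 1L,
                       matrix_path = NULL, labels_path = NULL,
                       out_dir = tempfile("wntbn-run-"), alpha = 0.05,
                       me_subsample = NULL, n_normal = 24, n_tumor = 24,
                       sigma = 0.25) {
  cfg <- list(variant = match.arg(variant, c("t1", "t2", "p1")),
              evidence = match.arg(evidence, c("ge", "me")),
              etgn = etgn, smoothing = smoothing,
              smoothing_on = match.arg(smoothing_on,
                                       c("fractions", "counts")),
              seed = as.integer(seed), matrix_path = matrix_path,
              labels_path = labels_path, out_dir = out_dir, alpha = alpha,
              me_subsample = me_subsample, n_normal = n_normal,
              n_tumor = n_tumor, sigma = sigma)
  if (cfg$evidence == "me" && cfg$variant != "t1")
    stop("methylation evidence requires variant 't1'", call. = FALSE)
  if (xor(is.null(cfg$matrix_path), is.null(cfg$labels_path)))
    stop("matrix_path and labels_path must be given together", call. = FALSE)
  cfg$etgn <- training_config(etgn = etgn)$etgn  # range validation
  structure(cfg, class = "run_config")
}

#' Validate a configuration list against the run-config schema
#'
#' Accepts a plain list (e.g. parsed from JSON or YAML), rejects unknown
#' keys, and fills defaults through [run_config()].
#'
#' @param x Named list of configuration values.
#' @return A validated `run_config`.
#' @export
as_run_config <- function(x) {
  if (inherits(x, "run_config")) return(x)
  known <- names(formals(run_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(run_config, x)
}

#' Run the full analysis pipeline
#'
#' Simulate-or-load, holdout, evaluate: generates (or reads) the cohort,
#' runs the leave-pair-out experiment with the configured evidence mode,
#' scores it, and writes the per-test-sample results CSV and a JSON summary
#' (AUCs, KS, seed, configuration) into `out_dir`.
#'
#' @param config A [run_config()] or a plain list convertible by
#'   [as_run_config()].
#' @return Invisibly, a list with `results` (tibble), `evaluation`
#'   (for gene evidence), `files` (paths written) and `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  config <- as_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (is.null(config$matrix_path)) {
    cohort <- generate_cohort(generator_config(
      n_normal = config$n_normal, n_tumor = config$n_tumor,
      sigma = config$sigma, seed = config$seed))
    dataset <- cohort$dataset
    write_expression(dataset,
                     file.path(config$out_dir, "expression.tsv"),
                     file.path(config$out_dir, "labels.csv"))
  } else {
    dataset <- read_expression(config$matrix_path, config$labels_path)
  }

  tcfg <- training_config(etgn = config$etgn, smoothing = config$smoothing,
                          smoothing_on = config$smoothing_on)
  files <- character(0)
  if (config$evidence == "ge") {
    results <- run_ge_experiment(dataset, config$variant, tcfg)
    evaluation <- evaluate_holdout(results, alpha = config$alpha)
    summary <- list(
      variant = config$variant, evidence = config$evidence,
      etgn = config$etgn, smoothing_on = config$smoothing_on,
      seed = config$seed, iterations = max(results$iteration),
      auc_trcmplx = evaluation$roc_trcmplx$auc,
      auc_sample = if (!is.null(evaluation$roc_sample))
        evaluation$roc_sample$auc,
      ks_statistic = if (!is.null(evaluation$ks)) evaluation$ks$statistic,
      ks_h01 = if (!is.null(evaluation$ks)) evaluation$ks$h01
    )
  } else {
    results <- run_me_experiment(dataset, config$variant, tcfg,
                                 subsample = config$me_subsample,
                                 seed = config$seed)
    evaluation <- NULL
    summary <- list(
      variant = config$variant, evidence = config$evidence,
      etgn = config$etgn, smoothing_on = config$smoothing_on,
      seed = config$seed, iterations = max(results$iteration),
      configurations = length(unique(results$config_id))
    )
  }

  res_path <- file.path(config$out_dir, "results.csv")
  out_tab <- results
  for (lc in c("evidence", "config")) out_tab[[lc]] <- NULL
  readr::write_csv(out_tab, res_path, progress = FALSE)
  sum_path <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(summary, sum_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, res_path, sum_path)
  invisible(list(results = results, evaluation = evaluation, files = files,
                 config = config))
}
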