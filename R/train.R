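.wntbn_state <- new.env(parent = emptyenv())

#' Packaged network parameters
#'
#' Loads the fixed node priors (tissue status, TCF4, the literature-derived
#' methylation and histone-mark priors) and the printed reference gene tables
#' from the parameter file shipped with the package. Columns are renormalized
#' to sum exactly to one (a few printed columns are off by rounding).
#'
#' @return A list with `priors` (named list of length-2 probability vectors,
#'   order off/on) and `tables` (named list of `conditional_table`).
#' @export
wnt_parameters <- function() {
  if (!is.null(.wntbn_state$params)) return(.wntbn_state$params)
  path <- system.file("extdata", "network_parameters.json", package = "wntbn")
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  priors <- lapply(doc$priors, function(p) as.numeric(p) / sum(p))
  tables <- lapply(names(doc$tables), function(nm) {
    tb <- doc$tables[[nm]]
    prob <- rbind(off = as.numeric(tb$off), on = as.numeric(tb$on))
    prob <- sweep(prob, 2, colSums(prob), "/")
    .new_cpt(nm, as.character(tb$parents), prob)
  })
  names(tables) <- names(doc$tables)
  .wntbn_state$params <- list(priors = priors, tables = tables)
  .wntbn_state$params
}

#' Training configuration
#'
#' @param etgn Effect of the transcription complex on its target genes, i.e.
#'   the weight `1 - p` applied when TRCMPLX is on; the sweep studied is
#'   0.5 to 0.9 in steps of 0.1, with 0.9 the headline setting. The
#'   complementary weight `p = 1 - etgn` multiplies the TRCMPLX-off block.
#' @param smoothing Positive pseudo-count constant (default 1).
#' @param smoothing_on `"fractions"` (the constant is added to the
#'   fraction-valued table, as the estimation rules are stated) or
#'   `"counts"` (the constant acts on raw counts; consistent at large n).
#' @param priors Named list overriding entries of the packaged fixed priors.
#' @return A list of class `training_config`.
#' @export
training_config <- function(etgn = 0.9, smoothing = 1,
                            smoothing_on = c("fractions", "counts"),
                            priors = NULL) {
  if (etgn <= 0 || etgn >= 1) stop("etgn must be in (0, 1)", call. = FALSE)
  smoothing_on <- match.arg(smoothing_on)
  params <- wnt_parameters()
  pr <- params$priors
  if (!is.null(priors)) pr[names(priors)] <- priors
  structure(list(etgn = etgn, p = 1 - etgn, smoothing = smoothing,
                 smoothing_on = smoothing_on, priors = pr,
                 fixed_tables = params$tables),
            class = "training_config")
}

# fixed CPT for TRCMPLX in the naive-Bayes variant: active only when both
# beta-catenin and TCF4 are in their high states (analogue of the printed
# three-parent table)
.p1_trcmplx_table <- function() {
  .new_cpt("TRCMPLX", c("BETACAT", "TCF4"),
           rbind(off = c(0.99, 0.99, 0.99, 0.01),
                 on  = c(0.01, 0.01, 0.01, 0.99)))
}

.fixed_table_for <- function(node, spec, config, variant) {
  k <- length(spec$parents)
  if (k == 0) {
    pr <- config$priors[[node]]
    if (is.null(pr)) stop("no prior available for root node ", node,
                          call. = FALSE)
    return(.new_cpt(node, character(0), matrix(pr, ncol = 1,
                                               dimnames = list(c("off", "on")))))
  }
  if (variant == "p1" && node == "TRCMPLX") return(.p1_trcmplx_table())
  tb <- config$fixed_tables[[node]]
  if (is.null(tb) || !identical(tb$parents, spec$parents))
    stop("no fixed table matching the parent set of ", node, call. = FALSE)
  tb
}

.estimate_gene_table <- function(node, parents, values, labels, config) {
  me <- parents[startsWith(parents, "Me")]
  has_tr <- "TRCMPLX" %in% parents
  has_sample <- "Sample" %in% parents
  if (identical(parents, c("H3K27me3", "H3K4me3", "Sample"))) {
    estimate_cpt_dact3(values, labels, node = node,
                       smoothing = config$smoothing,
                       smoothing_on = config$smoothing_on)
  } else if (has_sample && length(me) == 1 && has_tr) {
    estimate_cpt_sample_me_trcmplx(values, labels, p = config$p, node = node,
                                   me_parent = me,
                                   smoothing = config$smoothing,
                                   smoothing_on = config$smoothing_on)
  } else if (has_sample && length(me) == 1) {
    estimate_cpt_sample_me(values, labels, node = node, me_parent = me,
                           smoothing = config$smoothing,
                           smoothing_on = config$smoothing_on)
  } else if (has_sample && has_tr) {
    estimate_cpt_sample_trcmplx(values, labels, p = config$p, node = node,
                                smoothing = config$smoothing,
                                smoothing_on = config$smoothing_on)
  } else if (identical(parents, "Sample")) {
    estimate_cpt_sample_only(values, labels, node = node,
                             smoothing = config$smoothing,
                             smoothing_on = config$smoothing_on)
  } else if (identical(parents, "TRCMPLX")) {
    estimate_cpt_trcmplx_only(values, labels, node = node,
                              smoothing = config$smoothing,
                              smoothing_on = config$smoothing_on)
  } else {
    stop("no estimation rule for parent set of ", node, call. = FALSE)
  }
}

#' Train a network on an expression dataset
#'
#' Assigns the fixed priors and fixed conditional tables to the non-gene
#' nodes and estimates every gene node's table from the training data with
#' the rule matching its parent signature (median discretization,
#' class/methylation cross-tabulation, transcription-complex weighting,
#' pseudo-count smoothing). Per-gene discretization thresholds (the training
#' medians) are recorded for later evidence building.
#'
#' @param dataset An [expression_dataset()] covering the variant's gene
#'   nodes, with both classes present.
#' @param variant Model variant, `"t1"`, `"t2"` or `"p1"`.
#' @param config A [training_config()].
#' @param topology Optional pre-built `model_topology` (e.g. with the
#'   MeDKK4 arc enabled); defaults to `build_topology(variant)`.
#' @return An object of class `trained_network`: `topology`, `tables`
#'   (one `conditional_table` per node), `thresholds`, `config`.
#' @export
train_network <- function(dataset, variant = c("t1", "t2", "p1"),
                          config = training_config(), topology = NULL) {
  variant <- match.arg(variant)
  if (is.null(topology)) topology <- build_topology(variant)
  stopifnot(inherits(dataset, "expression_dataset"))
  .check_labels(dataset$labels)
  if (length(unique(dataset$labels)) < 2)
    stop("training data must contain both classes", call. = FALSE)
  gene_nd <- names(topology$nodes)[
    vapply(topology$nodes, `[[`, "", "category") == "gene"]
  missing <- setdiff(gene_nd, dataset$genes)
  if (length(missing) > 0)
    stop("dataset lacks gene row(s): ", paste(missing, collapse = ", "),
         call. = FALSE)

  tables <- vector("list", topology$n)
  names(tables) <- names(topology$nodes)
  thresholds <- stats::setNames(rep(NA_real_, length(gene_nd)), gene_nd)
  for (nd in names(topology$nodes)) {
    spec <- topology$nodes[[nd]]
    if (spec$category == "gene") {
      vals <- dataset$values[match(nd, dataset$genes), ]
      thresholds[nd] <- compute_threshold(vals)
      tables[[nd]] <- .estimate_gene_table(nd, spec$parents, vals,
                                           dataset$labels, config)
    } else {
      tables[[nd]] <- .fixed_table_for(nd, spec, config, variant)
    }
  }
  structure(list(topology = topology, tables = tables,
                 thresholds = thresholds, config = config),
            class = "trained_network")
}

#' Reference network with the printed parameters
#'
#' Parameterizes the full epigenetic topology with the fixed priors and the
#' printed gene tables from one training iteration, as shipped in the
#' package parameter file. This is the generating model of the synthetic
#' cohort module and the parameter set behind the worked inference examples.
#'
#' @param dkk4_methylation Passed to [build_topology()]; when `TRUE`, DKK4's
#'   table is unavailable in the printed set and training is required
#'   instead.
#' @return A `trained_network` (thresholds unset).
#' @export
reference_network <- function(dkk4_methylation = FALSE) {
  if (dkk4_methylation)
    stop("no printed table for DKK4 with a methylation parent", call. = FALSE)
  topology <- build_topology("t1")
  config <- training_config()
  tables <- lapply(names(topology$nodes), function(nd)
    .fixed_table_for(nd, topology$nodes[[nd]], config, "t1"))
  names(tables) <- names(topology$nodes)
  thresholds <- stats::setNames(rep(NA_real_, length(gene_nodes())),
                                gene_nodes())
  structure(list(topology = topology, tables = tables,
                 thresholds = thresholds, config = config),
            class = "trained_network")
}

#' @export
print.trained_network <- function(x, ...) {
  cat(sprintf("<trained_network '%s'> %d nodes, etgn = %.2f\n",
              x$topology$variant, x$topology$n, x$config$etgn))
  invisible(x)
}

#' Serialize / restore a trained network as JSON
#'
#' The document carries the topology (node specs), every conditional table
#' and the discretization thresholds, and round-trips through
#' `read_network_json()`.
#'
#' @param network A `trained_network`.
#' @param path File path.
#' @return `write_network_json()` returns `path` invisibly;
#'   `read_network_json()` a `trained_network`.
#' @export
write_network_json <- function(network, path) {
  doc <- list(
    variant = network$topology$variant,
    nodes = lapply(unname(network$topology$nodes), function(nd)
      list(name = nd$name, category = nd$category, states = I(nd$states),
           parents = I(nd$parents))),
    tables = lapply(network$tables, function(tb)
      list(parents = I(tb$parents), off = I(tb$prob[1, ]),
           on = I(tb$prob[2, ]))),
    thresholds = as.list(network$thresholds),
    etgn = network$config$etgn
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  nodes <- lapply(doc$nodes, function(nd)
    list(name = nd$name, category = nd$category,
         states = as.character(nd$states),
         parents = as.character(nd$parents)))
  names(nodes) <- vapply(nodes, `[[`, "", "name")
  edges <- do.call(rbind, lapply(nodes, function(nd) {
    if (length(nd$parents) == 0) return(NULL)
    cbind(parent = nd$parents, child = nd$name)
  }))
  rownames(edges) <- NULL
  topology <- structure(
    list(variant = doc$variant, nodes = nodes, edges = edges,
         n = length(nodes)), class = "model_topology")
  tables <- lapply(names(doc$tables), function(nm) {
    tb <- doc$tables[[nm]]
    .new_cpt(nm, as.character(tb$parents),
             rbind(off = as.numeric(tb$off), on = as.numeric(tb$on)))
  })
  names(tables) <- names(doc$tables)
  structure(list(topology = topology, tables = tables,
                 thresholds = unlist(doc$thresholds),
                 config = training_config(etgn = doc$etgn)),
            class = "trained_network")
}
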