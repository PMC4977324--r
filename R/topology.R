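#' Gene nodes shared by all model variants
#'
#' The 18 expression nodes measured on the cohort, including the two separate
#' DKK3 probes (`DKK3-1`, `DKK3-2`).
#'
#' @return Character vector of gene node names.
#' @export
gene_nodes <- function() {
  c("DKK1", "DKK2", "DKK3-1", "DKK3-2", "DKK4",
    "DACT1", "DACT2", "DACT3",
    "SFRP1", "SFRP2", "SFRP3", "SFRP4", "SFRP5",
    "WIF1", "MYC", "CD44", "CCND1", "LEF1")
}

#' Methylation nodes of the epigenetic model
#' @return Character vector of methylation node names.
#' @export
methylation_nodes <- function() {
  c("MeDACT1", "MeDACT2", "MeSFRP1", "MeSFRP2", "MeSFRP4", "MeSFRP5",
    "MeDKK1", "MeDKK4", "MeWIF1")
}

# state labels per node category; index 1 is always the low/off pole
.state_labels <- list(
  gene          = c("ia", "a"),
  methylation   = c("nm", "m"),
  histone       = c("ia", "a"),
  complex       = c("ia", "a"),
  concentration = c("lc", "hc"),
  sample        = c("n", "t")
)

.node_spec <- function(name, category, parents = character()) {
  list(name = name, category = category,
       states = .state_labels[[category]], parents = parents)
}

#' Construct one of the three Wnt network model topologies
#'
#' Builds the directed acyclic graph of a model variant from its declarative
#' node/parent specification:
#' \describe{
#'   \item{`"t1"`}{the full model with prior biological knowledge and
#'     epigenetic information: 18 gene nodes, 9 promoter-methylation nodes,
#'     the two DACT3 histone-mark nodes, plus `TRCMPLX`, `Sample`, `BETACAT`,
#'     `TCF4` and `DVL2` (34 nodes).}
#'   \item{`"t2"`}{the knowledge-only model: `"t1"` with all methylation and
#'     histone nodes and their arcs removed (23 nodes).}
#'   \item{`"p1"`}{a naive-Bayes star: every gene's sole parent is `TRCMPLX`,
#'     whose parents are `BETACAT` and `TCF4`; there is no `Sample` node
#'     (21 nodes).}
#' }
#'
#' @param variant One of `"t1"`, `"t2"`, `"p1"`.
#' @param dkk4_methylation Logical; if `TRUE` the optional MeDKK4 -> DKK4 arc
#'   is added in `"t1"` (by default DKK4's parents are `Sample` and `TRCMPLX`,
#'   matching the printed four-column table, and MeDKK4 is an isolated root).
#' @return An object of class `model_topology`: a list with elements
#'   `variant`, `nodes` (named list of node specs with `name`, `category`,
#'   `states`, `parents`), `edges` (two-column matrix parent/child), and `n`.
#' @examples
#' top <- build_topology("t1")
#' top$n
#' @export
build_topology <- function(variant = c("t1", "t2", "p1"),
                           dkk4_methylation = FALSE) {
  variant <- match.arg(variant)
  genes <- gene_nodes()

  if (variant == "p1") {
    nodes <- c(
      list(.node_spec("BETACAT", "concentration"),
           .node_spec("TCF4", "complex"),
           .node_spec("TRCMPLX", "complex", c("BETACAT", "TCF4"))),
      lapply(genes, .node_spec, category = "gene", parents = "TRCMPLX")
    )
  } else {
    gene_parents <- list(
      "DKK1"   = c("Sample", "MeDKK1", "TRCMPLX"),
      "DKK2"   = "Sample",
      "DKK3-1" = "Sample",
      "DKK3-2" = "Sample",
      "DKK4"   = if (dkk4_methylation) c("Sample", "MeDKK4", "TRCMPLX")
                 else c("Sample", "TRCMPLX"),
      "DACT1"  = c("Sample", "MeDACT1"),
      "DACT2"  = c("Sample", "MeDACT2"),
      "DACT3"  = c("H3K27me3", "H3K4me3", "Sample"),
      "SFRP1"  = c("Sample", "MeSFRP1", "TRCMPLX"),
      "SFRP2"  = c("Sample", "MeSFRP2"),
      "SFRP3"  = "Sample",
      "SFRP4"  = c("Sample", "MeSFRP4"),
      "SFRP5"  = c("Sample", "MeSFRP5"),
      "WIF1"   = c("Sample", "MeWIF1", "TRCMPLX"),
      "MYC"    = c("Sample", "TRCMPLX"),
      "CD44"   = c("Sample", "TRCMPLX"),
      "CCND1"  = c("Sample", "TRCMPLX"),
      "LEF1"   = "Sample"
    )
    if (variant == "t2") {
      epi <- c(methylation_nodes(), "H3K27me3", "H3K4me3")
      gene_parents <- lapply(gene_parents, setdiff, y = epi)
      epi_specs <- list()
    } else {
      epi_specs <- c(
        lapply(methylation_nodes(), .node_spec, category = "methylation"),
        list(.node_spec("H3K27me3", "histone"),
             .node_spec("H3K4me3", "histone"))
      )
    }
    nodes <- c(
      list(.node_spec("Sample", "sample"),
           .node_spec("TCF4", "complex"),
           .node_spec("DVL2", "concentration", "DACT3"),
           .node_spec("BETACAT", "concentration", c("DACT1", "DVL2")),
           .node_spec("TRCMPLX", "complex", c("TCF4", "LEF1", "BETACAT"))),
      epi_specs,
      lapply(genes, function(g) .node_spec(g, "gene", gene_parents[[g]]))
    )
  }

  names(nodes) <- vapply(nodes, `[[`, "", "name")
  edges <- do.call(rbind, lapply(nodes, function(nd) {
    if (length(nd$parents) == 0) return(NULL)
    cbind(parent = nd$parents, child = nd$name)
  }))
  rownames(edges) <- NULL
  top <- structure(
    list(variant = variant, nodes = nodes, edges = edges, n = length(nodes)),
    class = "model_topology"
  )
  stopifnot(!is.null(topological_order(top)))  # DAG by construction
  top
}

#' @export
print.model_topology <- function(x, ...) {
  cats <- table(vapply(x$nodes, `[[`, "", "category"))
  cat(sprintf("<model_topology '%s'> %d nodes, %d edges\n",
              x$variant, x$n, nrow(x$edges)))
  cat("  ", paste(names(cats), unname(cats), sep = ":", collapse = "  "), "\n")
  invisible(x)
}

.check_nodes <- function(topology, nodes) {
  bad <- setdiff(nodes, names(topology$nodes))
  if (length(bad) > 0)
    stop("unknown node name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Topological ordering of a model topology
#'
#' @param topology A `model_topology`.
#' @return Character vector of node names, parents before children, or `NULL`
#'   if the graph is cyclic.
#' @export
topological_order <- function(topology) {
  nodes <- names(topology$nodes)
  parents <- lapply(topology$nodes, `[[`, "parents")
  order <- character(0)
  placed <- character(0)
  remaining <- nodes
  while (length(remaining) > 0) {
    ready <- remaining[vapply(remaining, function(nd)
      all(parents[[nd]] %in% placed), TRUE)]
    if (length(ready) == 0) return(NULL)
    order <- c(order, ready)
    placed <- c(placed, ready)
    remaining <- setdiff(remaining, ready)
  }
  order
}

.topology_igraph <- function(topology, directed = TRUE) {
  igraph::graph_from_data_frame(
    as.data.frame(topology$edges), directed = directed,
    vertices = names(topology$nodes)
  )
}

#' Enumerate all simple paths between two nodes
#'
#' Paths are found on the undirected skeleton of the DAG (edge directions are
#' ignored), so a path may mix arc orientations; each path visits no node
#' twice. Ordering of the returned list is lexicographic on the node
#' sequences, hence deterministic.
#'
#' @param topology A `model_topology`.
#' @param from,to Distinct node names.
#' @return A list of character vectors, each a node sequence from `from`
#'   to `to`.
#' @examples
#' paths <- enumerate_simple_paths(build_topology("t1"), "SFRP3", "TRCMPLX")
#' length(paths)  # 10
#' @export
enumerate_simple_paths <- function(topology, from, to) {
  .check_nodes(topology, c(from, to))
  if (from == to) stop("'from' and 'to' must differ", call. = FALSE)
  g <- .topology_igraph(topology, directed = FALSE)
  ps <- igraph::all_simple_paths(g, from = from, to = to)
  ps <- lapply(ps, function(p) names(p))
  keys <- vapply(ps, paste, "", collapse = "\r")
  ps[order(keys)]
}

#' Test d-separation between two nodes
#'
#' Implements the directed path-blocking criterion: a path is blocked if it
#' contains an unobserved collider with no observed descendant, or an
#' observed chain/fork node; `x` and `y` are d-separated given `observed`
#' when every path between them is blocked. Computed with the Bayes-ball
#' reachability algorithm.
#'
#' @param topology A `model_topology`.
#' @param x,y Distinct node names, neither in `observed`.
#' @param observed Character vector of observed node names (may be empty).
#' @return `TRUE` if `x` and `y` are d-separated given `observed`.
#' @examples
#' top <- build_topology("t1")
#' is_d_separated(top, "SFRP3", "TRCMPLX", "Sample")       # TRUE
#' is_d_separated(top, "Sample", "TRCMPLX", "SFRP1")       # FALSE
#' @export
is_d_separated <- function(topology, x, y, observed = character()) {
  .check_nodes(topology, c(x, y, observed))
  if (x == y) stop("'x' and 'y' must differ", call. = FALSE)
  if (x %in% observed || y %in% observed)
    stop("'observed' must exclude 'x' and 'y'", call. = FALSE)

  parents <- lapply(topology$nodes, `[[`, "parents")
  children <- lapply(names(topology$nodes), function(nd)
    topology$edges[topology$edges[, "parent"] == nd, "child"])
  names(children) <- names(topology$nodes)

  # ancestors of the observed set (inclusive)
  anc <- character(0)
  frontier <- observed
  while (length(frontier) > 0) {
    anc <- union(anc, frontier)
    frontier <- setdiff(unique(unlist(parents[frontier])), anc)
  }

  # Bayes-ball: states are (node, direction of arrival)
  visited <- character(0)
  queue <- list(c(x, "up"))
  while (length(queue) > 0) {
    cur <- queue[[1]]; queue <- queue[-1]
    key <- paste(cur, collapse = "|")
    if (key %in% visited) next
    visited <- c(visited, key)
    nd <- cur[1]; dir <- cur[2]
    if (!(nd %in% observed) && nd == y) return(FALSE)
    if (dir == "up" && !(nd %in% observed)) {
      for (p in parents[[nd]]) queue <- c(queue, list(c(p, "up")))
      for (ch in children[[nd]]) queue <- c(queue, list(c(ch, "down")))
    } else if (dir == "down") {
      if (!(nd %in% observed)) {
        for (ch in children[[nd]]) queue <- c(queue, list(c(ch, "down")))
      }
      if (nd %in% anc) {          # collider on an active trail
        for (p in parents[[nd]]) queue <- c(queue, list(c(p, "up")))
      }
    }
  }
  TRUE
}

#' Export a topology as a parent/child edge list
#'
#' One `parent<TAB>child` pair per line. Isolated nodes are preserved through
#' the JSON format (see [write_topology_json()]), not through the edge list.
#'
#' @param topology A `model_topology`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_topology_edges <- function(topology, path) {
  writeLines(paste(topology$edges[, "parent"], topology$edges[, "child"],
                   sep = "\t"), path)
  invisible(path)
}

#' Export / import a topology as a JSON document
#'
#' The JSON mirrors the node specification: name, category, state labels and
#' ordered parent list per node, plus the variant tag.
#'
#' @param topology A `model_topology`.
#' @param path File path.
#' @return `write_topology_json()` returns `path` invisibly;
#'   `read_topology_json()` returns a `model_topology`.
#' @export
write_topology_json <- function(topology, path) {
  doc <- list(
    variant = topology$variant,
    nodes = lapply(unname(topology$nodes), function(nd)
      list(name = nd$name, category = nd$category,
           states = nd$states, parents = I(nd$parents)))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_topology_json
#' @export
read_topology_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  nodes <- lapply(doc$nodes, function(nd) {
    list(name = nd$name, category = nd$category,
         states = as.character(nd$states),
         parents = as.character(nd$parents))
  })
  names(nodes) <- vapply(nodes, `[[`, "", "name")
  edges <- do.call(rbind, lapply(nodes, function(nd) {
    if (length(nd$parents) == 0) return(NULL)
    cbind(parent = nd$parents, child = nd$name)
  }))
  rownames(edges) <- NULL
  top <- structure(
    list(variant = doc$variant, nodes = nodes, edges = edges,
         n = length(nodes)),
    class = "model_topology"
  )
  if (is.null(topological_order(top))) stop("imported topology is cyclic")
  top
}
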