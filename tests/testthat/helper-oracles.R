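# Independent oracles and generators used across the suite. These share no
# code with the package internals they check.

# ---- exhaustive DFS path enumeration on the undirected skeleton ------------

oracle_simple_paths <- function(topology, from, to) {
  adj <- list()
  for (i in seq_len(nrow(topology$edges))) {
    p <- topology$edges[i, "parent"]; ch <- topology$edges[i, "child"]
    adj[[p]] <- union(adj[[p]], ch)
    adj[[ch]] <- union(adj[[ch]], p)
  }
  out <- list()
  dfs <- function(path) {
    nd <- path[length(path)]
    if (nd == to) { out[[length(out) + 1]] <<- path; return(invisible()) }
    for (nb in adj[[nd]]) if (!(nb %in% path)) dfs(c(path, nb))
  }
  dfs(from)
  out
}

# ---- moralized-ancestral-graph d-separation oracle -------------------------

oracle_d_separated <- function(topology, x, y, observed) {
  parents <- lapply(topology$nodes, `[[`, "parents")
  keep <- c(x, y, observed)
  repeat {
    more <- unique(unlist(parents[keep]))
    if (all(more %in% keep)) break
    keep <- union(keep, more)
  }
  # moralize: skeleton edges + marry parents of each kept child
  ep <- character(0)
  for (nd in keep) {
    pa <- intersect(parents[[nd]], keep)
    for (p in pa) ep <- c(ep, p, nd)
    if (length(pa) > 1) {
      cmb <- utils::combn(pa, 2)
      for (j in seq_len(ncol(cmb))) ep <- c(ep, cmb[1, j], cmb[2, j])
    }
  }
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(keep)
  if (length(ep) > 0) g <- g + igraph::edges(ep)
  g <- igraph::delete_vertices(g, observed)
  d <- igraph::distances(g, v = x, to = y)
  !is.finite(d[1, 1])
}

# ---- random DAGs with random CPTs ------------------------------------------

random_topology <- function(n_nodes, p_edge = 0.35, seed = 1) {
  set.seed(seed)
  nms <- paste0("N", seq_len(n_nodes))
  nodes <- lapply(seq_len(n_nodes), function(i) {
    pa <- if (i == 1) character(0) else
      nms[which(stats::runif(i - 1) < p_edge)]
    list(name = nms[i], category = "gene", states = c("ia", "a"),
         parents = pa)
  })
  names(nodes) <- nms
  edges <- do.call(rbind, lapply(nodes, function(nd) {
    if (length(nd$parents) == 0) return(NULL)
    cbind(parent = nd$parents, child = nd$name)
  }))
  rownames(edges) <- NULL
  structure(list(variant = "random", nodes = nodes, edges = edges,
                 n = n_nodes),
            class = "model_topology")
}

random_network <- function(n_nodes, p_edge = 0.35, seed = 1) {
  top <- random_topology(n_nodes, p_edge, seed)
  tables <- lapply(top$nodes, function(nd) {
    k <- length(nd$parents)
    on <- stats::runif(2^k, 0.05, 0.95)
    structure(list(node = nd$name, parents = nd$parents,
                   prob = rbind(off = 1 - on, on = on)),
              class = "conditional_table")
  })
  structure(list(topology = top, tables = tables,
                 thresholds = numeric(0),
                 config = wntbn::training_config()),
            class = "trained_network")
}

random_evidence <- function(network, n_obs) {
  nodes <- names(network$tables)
  picked <- sample(nodes, n_obs)
  stats::setNames(sample(1:2, n_obs, replace = TRUE), picked)
}

# ---- literal transcriptions of the estimation prose ------------------------
# Each oracle recomputes the pre-smoothing table exactly as the estimation
# rules are worded (overlapping <=/>= bins collapsed to the package's strict
# partition), applies fraction+1 smoothing, and returns the probability
# matrix. Written without reference to the package implementations.

oracle_bins <- function(values, labels, med) {
  act <- values >= med
  list(a = sum(labels < 0 & act), b = sum(labels > 0 & act),
       c = sum(labels < 0 & !act), d = sum(labels > 0 & !act),
       A0 = sum(labels < 0), B0 = sum(labels > 0))
}

oracle_smooth <- function(t) apply(t + 1, 2, function(cl) cl / sum(cl))

oracle_sample_only <- function(values, labels) {
  bb <- oracle_bins(values, labels, stats::median(values))
  on_n <- if (bb$A0 > 0) bb$a / bb$A0 else 0
  on_t <- if (bb$B0 > 0) bb$b / bb$B0 else 0
  oracle_smooth(rbind(c(1 - on_n, 1 - on_t), c(on_n, on_t)))
}

oracle_sample_trcmplx <- function(values, labels, p) {
  bb <- oracle_bins(values, labels, stats::median(values))
  on_n_off <- bb$a * p / bb$A0
  on_t_off <- bb$b * p / bb$B0
  off_n_on <- (bb$A0 - bb$a) * (1 - p) / bb$A0
  off_t_on <- (bb$B0 - bb$b) * (1 - p) / bb$B0
  oracle_smooth(rbind(
    c(1 - on_n_off, 1 - on_t_off, off_n_on, off_t_on),
    c(on_n_off, on_t_off, 1 - off_n_on, 1 - off_t_on)))
}

oracle_sample_me_trcmplx <- function(values, labels, p) {
  bb <- oracle_bins(values, labels, stats::median(values))
  A <- bb$A0 + bb$b; B <- bb$B0 + bb$a
  C <- bb$A0 + bb$d; D <- bb$B0 + bb$c
  blk <- function(w) {
    on1 <- bb$a * w / A; on2 <- bb$b * w / B
    off3 <- bb$c * w / C; off4 <- bb$d * w / D
    rbind(c(1 - on1, 1 - on2, off3, off4),
          c(on1, on2, 1 - off3, 1 - off4))
  }
  oracle_smooth(cbind(blk(p), blk(1 - p)))
}

oracle_sample_me <- function(values, labels) {
  bb <- oracle_bins(values, labels, stats::median(values))
  A <- bb$A0 + bb$b; B <- bb$B0 + bb$a
  C <- bb$A0 + bb$d; D <- bb$B0 + bb$c
  on1 <- bb$a / A; on2 <- bb$b / B
  off3 <- bb$c / C; off4 <- bb$d / D
  oracle_smooth(rbind(c(1 - on1, 1 - on2, off3, off4),
                      c(on1, on2, 1 - off3, 1 - off4)))
}

oracle_dact3 <- function(values, labels) {
  bb <- oracle_bins(values, labels, stats::median(values))
  on_n <- bb$a / bb$A0; on_t <- bb$b / bb$B0
  cols <- function(on) {
    # K27 fastest then K4: (1,1) (2,1) (1,2) (2,2); only (low, high) keeps on
    sapply(list(1 - on, 1 - on, on, 1 - on), function(o) c(1 - o, o))
  }
  oracle_smooth(cbind(cols(on_n), cols(on_t)))
}

oracle_trcmplx_only <- function(values, labels) {
  bb <- oracle_bins(values, labels, stats::median(values))
  on_off <- if (bb$A0 > 0) bb$a / bb$A0 else 0
  on_on <- if (bb$B0 > 0) bb$b / bb$B0 else 0
  oracle_smooth(rbind(c(1 - on_off, 1 - on_on), c(on_off, on_on)))
}

random_training_vector <- function(n, seed) {
  set.seed(seed)
  values <- round(stats::rnorm(n), 2)   # rounding provokes ties at the median
  labels <- sample(c(-1, 1), n, replace = TRUE)
  if (length(unique(labels)) == 1) labels[1] <- -labels[1]
  list(values = values, labels = labels)
}
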