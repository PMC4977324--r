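# ---- factor algebra over binary variables ----------------------------------

.factor_from_cpt <- function(tb) {
  vars <- c(tb$node, tb$parents)
  list(vars = vars, val = array(as.vector(tb$prob), dim = rep(2L, length(vars))))
}

.factor_expand <- function(f, vars) {
  extra <- setdiff(vars, f$vars)
  cur <- c(f$vars, extra)
  arr <- array(f$val, dim = rep(2L, length(cur)))  # recycles over extras
  arr <- aperm(arr, match(vars, cur))
  list(vars = vars, val = arr)
}

.factor_product <- function(f1, f2) {
  vars <- union(f1$vars, f2$vars)
  a1 <- .factor_expand(f1, vars)
  a2 <- .factor_expand(f2, vars)
  list(vars = vars, val = a1$val * a2$val)
}

.factor_sum_out <- function(f, var) {
  i <- match(var, f$vars)
  keep <- seq_along(f$vars)[-i]
  if (length(keep) == 0)
    return(list(vars = character(0), val = sum(f$val)))
  val <- apply(f$val, keep, sum)
  list(vars = f$vars[keep], val = array(val, dim = rep(2L, length(keep))))
}

.factor_reduce <- function(f, var, state) {
  i <- match(var, f$vars)
  if (is.na(i)) return(f)
  k <- length(f$vars)
  args <- rep(list(quote(expr = )), k)
  args[[i]] <- state
  val <- do.call(`[`, c(list(f$val), args, list(drop = FALSE)))
  if (k == 1) return(list(vars = character(0), val = sum(val)))
  list(vars = f$vars[-i], val = array(val, dim = rep(2L, k - 1)))
}

.check_evidence <- function(network, evidence) {
  if (length(evidence) == 0) return(invisible(TRUE))
  if (is.null(names(evidence)) || any(names(evidence) == ""))
    stop("evidence must be a named vector of state indices", call. = FALSE)
  if (anyDuplicated(names(evidence)))
    stop("duplicate evidence assignment", call. = FALSE)
  .check_nodes(network$topology, names(evidence))
  if (!all(evidence %in% c(1L, 2L)))
    stop("evidence states must be 1 or 2", call. = FALSE)
  invisible(TRUE)
}

#' Exact posterior marginal by variable elimination
#'
#' Computes the conditional marginal of a node given partial evidence under
#' the network's joint factorization. Every call constructs a fresh set of
#' factors from the network parameters — inference state is never reused
#' across evidence sets, so stale-evidence artifacts cannot occur. Hidden
#' variables are eliminated greedily (smallest intermediate factor first);
#' with binary nodes and the sparse pathway topologies this is exact and
#' fast.
#'
#' @param network A `trained_network`.
#' @param evidence Named integer vector, node name -> state index (1 or 2);
#'   may be empty.
#' @param node Query node name.
#' @return Numeric probability pair (state 1, state 2) summing to one.
#' @examples
#' net <- reference_network()
#' posterior_marginal(net, c(DACT3 = 1), "DVL2")   # Pr(hc) = 0.99
#' @export
posterior_marginal <- function(network, evidence = integer(), node) {
  stopifnot(inherits(network, "trained_network"))
  .check_nodes(network$topology, node)
  .check_evidence(network, evidence)
  .wntbn_state$engine_builds <- (.wntbn_state$engine_builds %||% 0L) + 1L

  factors <- lapply(network$tables, .factor_from_cpt)
  for (nd in names(evidence))
    factors <- lapply(factors, .factor_reduce, var = nd,
                      state = as.integer(evidence[[nd]]))

  hidden <- setdiff(names(network$tables), c(node, names(evidence)))
  scalar <- vapply(factors, function(f) length(f$vars) == 0, TRUE)
  consts <- prod(vapply(factors[scalar], function(f) f$val, 0))
  factors <- factors[!scalar]

  for (step in seq_along(hidden)) {
    # pick the hidden var whose elimination touches the fewest variables
    widths <- vapply(hidden, function(v) {
      involved <- vapply(factors, function(f) v %in% f$vars, TRUE)
      length(unique(unlist(lapply(factors[involved], `[[`, "vars"))))
    }, 0L)
    v <- hidden[which.min(widths)]
    hidden <- setdiff(hidden, v)
    involved <- vapply(factors, function(f) v %in% f$vars, TRUE)
    if (!any(involved)) next
    prod_f <- Reduce(.factor_product, factors[involved])
    new_f <- .factor_sum_out(prod_f, v)
    factors <- factors[!involved]
    if (length(new_f$vars) == 0) consts <- consts * new_f$val
    else factors <- c(factors, list(new_f))
  }

  if (node %in% names(evidence)) {
    z <- consts * prod(vapply(factors, function(f) sum(f$val), 0))
    if (!is.finite(z) || z <= 0)
      stop("impossible evidence: zero joint probability", call. = FALSE)
    out <- c(0, 0); out[evidence[[node]]] <- 1
    return(out)
  }

  res <- Reduce(.factor_product,
                c(factors, list(list(vars = node, val = rep(consts, 2)))))
  stopifnot(identical(res$vars, node))
  z <- sum(res$val)
  if (!is.finite(z) || z <= 0)
    stop("impossible evidence: zero joint probability", call. = FALSE)
  as.numeric(res$val / z)
}

#' Number of inference-engine constructions so far
#'
#' Each [posterior_marginal()] call builds its factor set from scratch; this
#' counter exposes that for instrumentation (e.g. asserting that every test
#' case of a holdout run used a fresh engine).
#'
#' @return Integer count.
#' @export
engine_build_count <- function() .wntbn_state$engine_builds %||% 0L

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- brute-force enumeration oracle ----------------------------------------

#' Posterior marginal by full joint enumeration
#'
#' Independent oracle for [posterior_marginal()]: materializes the full
#' 2^N joint as a vector indexed by the binary state pattern of all nodes,
#' applies evidence as indicator masks, and sums. Shares no code with the
#' variable-elimination path. Refuses networks above 24 nodes.
#'
#' @inheritParams posterior_marginal
#' @return Numeric probability pair (state 1, state 2).
#' @export
brute_force_marginal <- function(network, evidence = integer(), node) {
  stopifnot(inherits(network, "trained_network"))
  .check_nodes(network$topology, node)
  .check_evidence(network, evidence)
  nodes <- names(network$tables)
  n <- length(nodes)
  if (n > 24) stop("brute-force enumeration limited to 24 nodes",
                   call. = FALSE)
  m <- 2^n
  idx <- seq_len(m) - 1L
  state_of <- function(nd) {
    bit <- match(nd, nodes) - 1L
    bitwAnd(bitwShiftR(idx, bit), 1L) + 1L
  }
  joint <- rep(1, m)
  for (nd in nodes) {
    tb <- network$tables[[nd]]
    cfg <- rep(1L, m)
    if (length(tb$parents) > 0) {
      mult <- 1L
      for (p in tb$parents) {
        cfg <- cfg + (state_of(p) - 1L) * mult
        mult <- mult * 2L
      }
    }
    joint <- joint * as.vector(tb$prob)[(cfg - 1L) * 2L + state_of(nd)]
  }
  for (nd in names(evidence))
    joint <- joint * (state_of(nd) == as.integer(evidence[[nd]]))
  s <- state_of(node)
  out <- c(sum(joint[s == 1L]), sum(joint[s == 2L]))
  z <- sum(out)
  if (!is.finite(z) || z <= 0)
    stop("impossible evidence: zero joint probability", call. = FALSE)
  out / z
}
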