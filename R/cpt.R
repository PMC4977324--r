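#' Median discretization threshold
#'
#' The per-gene threshold is the sample median of the training expression
#' values (for an even number of values, the mean of the two central order
#' statistics).
#'
#' @param values Nonempty numeric vector of expression values.
#' @return The median, a single finite number.
#' @export
compute_threshold <- function(values) {
  if (length(values) == 0) stop("empty expression vector", call. = FALSE)
  if (!all(is.finite(values))) stop("non-finite expression values", call. = FALSE)
  stats::median(values)
}

#' Discretize an expression value against a threshold
#'
#' State 1 (inactive/repressed) if `value < threshold`, state 2
#' (active/expressed) otherwise. The same tie rule (`>=` goes to state 2) is
#' used for training counts and for test evidence, so every value occupies
#' exactly one state.
#'
#' @param value,threshold Finite numerics (vectorized over `value`).
#' @return Integer state index, 1 or 2.
#' @export
discretize <- function(value, threshold) {
  ifelse(value < threshold, 1L, 2L)
}

.check_labels <- function(labels) {
  if (!all(labels %in% c(-1, 1)))
    stop("labels must be -1 (normal) or +1 (tumor)", call. = FALSE)
  invisible(TRUE)
}

#' Cross-tabulate discretized states by class
#'
#' Counts the four bins the estimation rules work from: `a` actives in
#' normal, `b` actives in tumor, `c` inactives in normal, `d` inactives in
#' tumor (the active state meaning value at or above the threshold).
#' Denominators are rule-specific and left to the estimators.
#'
#' @param values Numeric expression vector.
#' @param labels Class labels, -1 normal / +1 tumor, same length.
#' @param threshold Discretization threshold.
#' @return A list with integers `a`, `b`, `c`, `d`, `n_normal`, `n_tumor`.
#' @export
tabulate_class_states <- function(values, labels, threshold) {
  if (length(values) != length(labels))
    stop("values and labels differ in length", call. = FALSE)
  .check_labels(labels)
  st <- discretize(values, threshold)
  list(
    a = sum(st == 2L & labels == -1),
    b = sum(st == 2L & labels == +1),
    c = sum(st == 1L & labels == -1),
    d = sum(st == 1L & labels == +1),
    n_normal = sum(labels == -1),
    n_tumor  = sum(labels == +1)
  )
}

.new_cpt <- function(node, parents, prob) {
  structure(list(node = node, parents = parents, prob = prob),
            class = "conditional_table")
}

#' @export
print.conditional_table <- function(x, ...) {
  cat(sprintf("<conditional_table> %s | %s\n", x$node,
              if (length(x$parents)) paste(x$parents, collapse = ", ")
              else "(no parents)"))
  print(round(x$prob, 4))
  invisible(x)
}

#' Pseudo-count smoothing and per-column normalization
#'
#' Adds a positive constant (default 1) to every entry of the raw table and
#' renormalizes each parent-configuration column to sum to one. This removes
#' deterministic 0/1 probabilities, which would make the inference engine
#' collapse on contradicting evidence, and represents unobserved
#' configurations at small sample size.
#'
#' @param t Matrix, 2 rows (off/on) by parent configurations, nonnegative.
#' @param constant Positive smoothing constant.
#' @return Matrix of the same shape with columns summing to 1 and all entries
#'   strictly inside (0, 1).
#' @export
smooth_and_normalize <- function(t, constant = 1) {
  if (constant <= 0) stop("smoothing constant must be > 0", call. = FALSE)
  if (any(t < 0)) stop("negative entries in count table", call. = FALSE)
  t <- t + constant
  sweep(t, 2, colSums(t), "/")
}

# shared helper: assemble, smooth (in the configured mode) and wrap.
# 'fractions' adds the constant to the fraction-valued table (as the
# estimation prose states); 'counts' rescales each column's fractions by its
# effective count first, so the constant acts as a Dirichlet pseudo-count on
# raw counts and the estimator is consistent.
.finish_cpt <- function(node, parents, frac, counts_scale,
                        smoothing = 1, smoothing_on = "fractions") {
  smoothing_on <- match.arg(smoothing_on, c("fractions", "counts"))
  if (smoothing_on == "counts") {
    raw <- sweep(frac, 2, counts_scale, "*")
    prob <- smooth_and_normalize(raw, smoothing)
  } else {
    prob <- smooth_and_normalize(frac, smoothing)
  }
  .new_cpt(node, parents, prob)
}

.frac <- function(num, den) if (den > 0) num / den else 0

#' Estimate a gene CPT with parent \{Sample\}
#'
#' Pre-smoothing, Pr(on | normal) is the fraction of active values among the
#' normal samples and Pr(on | tumor) the fraction among the tumor samples;
#' off rows are the complements. Smoothing then removes 0/1 entries (a class
#' with no samples yields a uniform column). Applies to DKK2, DKK3-1,
#' DKK3-2, SFRP3 and LEF1 in the full model, and additionally to the
#' demethylated genes in the knowledge-only model.
#'
#' @param values,labels Training expression vector and -1/+1 labels.
#' @param node Gene name recorded on the table.
#' @param smoothing Positive smoothing constant.
#' @param smoothing_on `"fractions"` (add the constant to the fraction table,
#'   as the estimation rules are stated) or `"counts"` (act on raw counts).
#' @return A `conditional_table` with columns (normal, tumor).
#' @export
estimate_cpt_sample_only <- function(values, labels, node = "gene",
                                     smoothing = 1,
                                     smoothing_on = "fractions") {
  cs <- tabulate_class_states(values, labels, compute_threshold(values))
  frac <- rbind(
    off = c(.frac(cs$c, cs$n_normal), .frac(cs$d, cs$n_tumor)),
    on  = c(.frac(cs$a, cs$n_normal), .frac(cs$b, cs$n_tumor))
  )
  .finish_cpt(node, "Sample", frac, c(cs$n_normal, cs$n_tumor),
              smoothing, smoothing_on)
}

#' Estimate a gene CPT with parents \{Sample, TRCMPLX\}
#'
#' The class fractions are weighted by the transcription-complex effect:
#' entries are multiplied by `p` when TRCMPLX is off and by `1 - p` when it
#' is on (`p = 1 - etgn`). Pre-smoothing, with `A` normals and `B` tumors:
#' Pr(on | normal, off) = a p / A, Pr(on | tumor, off) = b p / B,
#' Pr(off | normal, on) = (A - a)(1 - p) / A,
#' Pr(off | tumor, on) = (B - b)(1 - p) / B; complements fill each column.
#' Columns are ordered Sample-fastest: (n, off), (t, off), (n, on), (t, on).
#'
#' @inheritParams estimate_cpt_sample_only
#' @param p TRCMPLX-off weight in (0, 1); the headline setting is
#'   `p = 0.1` (complex-on effect of 90 percent).
#' @return A `conditional_table` with 4 columns.
#' @export
estimate_cpt_sample_trcmplx <- function(values, labels, p = 0.1,
                                        node = "gene", smoothing = 1,
                                        smoothing_on = "fractions") {
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)", call. = FALSE)
  cs <- tabulate_class_states(values, labels, compute_threshold(values))
  A <- cs$n_normal; B <- cs$n_tumor
  on_n_off  <- .frac(cs$a * p, A)
  on_t_off  <- .frac(cs$b * p, B)
  off_n_on  <- .frac((A - cs$a) * (1 - p), A)
  off_t_on  <- .frac((B - cs$b) * (1 - p), B)
  frac <- rbind(
    off = c(1 - on_n_off, 1 - on_t_off, off_n_on, off_t_on),
    on  = c(on_n_off, on_t_off, 1 - off_n_on, 1 - off_t_on)
  )
  .finish_cpt(node, c("Sample", "TRCMPLX"), frac, rep(c(A, B), 2),
              smoothing, smoothing_on)
}

#' Estimate a gene CPT with parents \{Sample, Me, TRCMPLX\}
#'
#' The 2x2 methylation-by-class cross table drives the fractions, with the
#' rule's own denominators: `A = n_normal + b`, `B = n_tumor + a`,
#' `C = n_normal + d`, `D = n_tumor + c` (the opposite class's active or
#' inactive count is added to the class total). With TRCMPLX off:
#' Pr(on | n, nm, off) = a p / A, Pr(on | t, nm, off) = b p / B,
#' Pr(off | n, m, off) = c p / C, Pr(off | t, m, off) = d p / D; the
#' TRCMPLX-on block uses `1 - p`; complements fill each column. The 8 columns
#' are ordered Sample fastest, then methylation, then TRCMPLX. Applies to
#' DKK1, SFRP1 and WIF1 in the full model.
#'
#' @inheritParams estimate_cpt_sample_trcmplx
#' @param me_parent Name of the methylation parent node.
#' @return A `conditional_table` with 8 columns.
#' @export
estimate_cpt_sample_me_trcmplx <- function(values, labels, p = 0.1,
                                           node = "gene",
                                           me_parent = paste0("Me", node),
                                           smoothing = 1,
                                           smoothing_on = "fractions") {
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)", call. = FALSE)
  cs <- tabulate_class_states(values, labels, compute_threshold(values))
  A <- cs$n_normal + cs$b
  B <- cs$n_tumor + cs$a
  C <- cs$n_normal + cs$d
  D <- cs$n_tumor + cs$c
  block <- function(w) {
    on_n_um <- .frac(cs$a * w, A)
    on_t_um <- .frac(cs$b * w, B)
    off_n_m <- .frac(cs$c * w, C)
    off_t_m <- .frac(cs$d * w, D)
    rbind(off = c(1 - on_n_um, 1 - on_t_um, off_n_m, off_t_m),
          on  = c(on_n_um, on_t_um, 1 - off_n_m, 1 - off_t_m))
  }
  frac <- cbind(block(p), block(1 - p))
  .finish_cpt(node, c("Sample", me_parent, "TRCMPLX"), frac,
              rep(c(A, B, C, D), 2), smoothing, smoothing_on)
}

#' Estimate a gene CPT with parents \{Sample, Me\}
#'
#' The two-parent analogue of the methylation cross-table rule, without the
#' TRCMPLX weight: Pr(on | n, nm) = a / A, Pr(on | t, nm) = b / B,
#' Pr(off | n, m) = c / C, Pr(off | t, m) = d / D with the same cross
#' denominators, complements filling each column. Columns ordered Sample
#' fastest: (n, nm), (t, nm), (n, m), (t, m). Applies to DACT1, DACT2,
#' SFRP2, SFRP4 and SFRP5 in the full model.
#'
#' @inheritParams estimate_cpt_sample_me_trcmplx
#' @return A `conditional_table` with 4 columns.
#' @export
estimate_cpt_sample_me <- function(values, labels, node = "gene",
                                   me_parent = paste0("Me", node),
                                   smoothing = 1,
                                   smoothing_on = "fractions") {
  cs <- tabulate_class_states(values, labels, compute_threshold(values))
  A <- cs$n_normal + cs$b
  B <- cs$n_tumor + cs$a
  C <- cs$n_normal + cs$d
  D <- cs$n_tumor + cs$c
  on_n_um <- .frac(cs$a, A)
  on_t_um <- .frac(cs$b, B)
  off_n_m <- .frac(cs$c, C)
  off_t_m <- .frac(cs$d, D)
  frac <- rbind(off = c(1 - on_n_um, 1 - on_t_um, off_n_m, off_t_m),
                on  = c(on_n_um, on_t_um, 1 - off_n_m, 1 - off_t_m))
  .finish_cpt(node, c("Sample", me_parent), frac, c(A, B, C, D),
              smoothing, smoothing_on)
}

#' Estimate the DACT3 CPT with parents \{H3K27me3, H3K4me3, Sample\}
#'
#' DACT3 expression is high when the repressive mark H3K27me3 is low and the
#' activating mark H3K4me3 is high. Pre-smoothing,
#' Pr(on | K27 = low, K4 = high, normal) = a / A with `A` the number of
#' normal samples; every other histone configuration takes the flipped
#' complement (A - a) / A. The tumor block is analogous with b / B. The 8
#' columns are ordered H3K27me3 fastest, then H3K4me3, then Sample.
#'
#' @inheritParams estimate_cpt_sample_only
#' @return A `conditional_table` with 8 columns.
#' @export
estimate_cpt_dact3 <- function(values, labels, node = "DACT3",
                               smoothing = 1, smoothing_on = "fractions") {
  cs <- tabulate_class_states(values, labels, compute_threshold(values))
  on_n <- .frac(cs$a, cs$n_normal)
  on_t <- .frac(cs$b, cs$n_tumor)
  col <- function(on) c(off = 1 - on, on = on)
  # configs, K27 fastest then K4: (1,1) (2,1) (1,2) (2,2); (1,2) = low/high
  class_block <- function(on) cbind(col(1 - on), col(1 - on), col(on), col(1 - on))
  frac <- cbind(class_block(on_n), class_block(on_t))
  rownames(frac) <- c("off", "on")
  .finish_cpt(node, c("H3K27me3", "H3K4me3", "Sample"), frac,
              rep(c(cs$n_normal, cs$n_tumor), each = 4),
              smoothing, smoothing_on)
}

#' Estimate a gene CPT with parent \{TRCMPLX\} (naive-Bayes model)
#'
#' The class label proxies the transcription-complex state (normal = off,
#' tumor = on): Pr(on | off) = a / A, Pr(on | on) = b / B pre-smoothing.
#' No TRCMPLX weight is applied.
#'
#' @inheritParams estimate_cpt_sample_only
#' @return A `conditional_table` with columns (off, on).
#' @export
estimate_cpt_trcmplx_only <- function(values, labels, node = "gene",
                                      smoothing = 1,
                                      smoothing_on = "fractions") {
  cs <- tabulate_class_states(values, labels, compute_threshold(values))
  frac <- rbind(
    off = c(.frac(cs$c, cs$n_normal), .frac(cs$d, cs$n_tumor)),
    on  = c(.frac(cs$a, cs$n_normal), .frac(cs$b, cs$n_tumor))
  )
  .finish_cpt(node, "TRCMPLX", frac, c(cs$n_normal, cs$n_tumor),
              smoothing, smoothing_on)
}
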