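test_that("ROC endpoints, separability and tie conventions", {
  perfect <- compute_roc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, -1, -1))
  expect_equal(perfect$auc, 1)
  inverted <- compute_roc(c(0.9, 0.8, 0.2, 0.1), c(-1, -1, 1, 1))
  expect_equal(inverted$auc, 0)
  ties <- compute_roc(rep(0.4, 6), c(-1, -1, -1, 1, 1, 1))
  expect_equal(ties$auc, 0.5)

  r <- compute_roc(runif(20), rep(c(-1, 1), 10))
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
  expect_equal(range(r$fpr), c(0, 1))
  expect_equal(range(r$tpr), c(0, 1))
  expect_error(compute_roc(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(5)
  scores <- rnorm(40)
  labels <- rep(c(-1, 1), 20)
  base <- compute_roc(scores, labels)$auc
  expect_equal(compute_roc(exp(scores), labels)$auc, base)
  expect_equal(compute_roc(2 * scores - 7, labels)$auc, base)
  expect_equal(compute_roc(atan(scores), labels)$auc, base)
})

test_that("the KS comparison follows the ECDF supremum and alpha rule", {
  same <- ks_two_sample(c(1, 2, 3, 2), c(1, 2, 3, 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$h01, 0L)
  disjoint <- ks_two_sample(c(1, 2, 3, 4), c(5, 6, 7, 8))
  expect_equal(disjoint$statistic, 1)
  hand <- ks_two_sample(c(1, 2), c(1.5, 2.5))
  expect_equal(hand$statistic, 0.5)
  # symmetry and range
  set.seed(8)
  x <- runif(30); y <- rbeta(25, 2, 5)
  expect_equal(ks_two_sample(x, y)$statistic, ks_two_sample(y, x)$statistic)
  expect_true(ks_two_sample(x, y)$statistic >= 0 &&
                ks_two_sample(x, y)$statistic <= 1)
  expect_error(ks_two_sample(numeric(0), 1:3), "empty")
  expect_error(ks_two_sample(1:3, 1:3, alpha = 1), "alpha")
})

make_results <- function(rows) {
  out <- tibble::as_tibble(rows)
  class(out) <- c("holdout_result", class(out))
  out
}

test_that("gene summaries group by evidence state with majority inference", {
  ev <- function(g1, g2) list(c(DKK1 = g1, LEF1 = g2))
  res <- make_results(tibble::tibble(
    iteration = 1:4,
    test_idx = 1:4,
    sample = paste0("s", 1:4),
    true_label = c(1, 1, 1, 1),
    pr_trcmplx = c(0.8, 0.8, 0.8, 0.6),
    pr_sample = NA_real_,
    evidence = c(ev(2L, 1L), ev(2L, 1L), ev(2L, 2L), ev(2L, 1L))
  ))
  sm <- summarize_gene_trcmplx(res)
  dk <- sm[sm$gene == "DKK1" & sm$class == "tumor", ]
  expect_equal(dk$majority_state, "active")
  expect_equal(dk$inferred_belief, mean(c(0.8, 0.8, 0.8, 0.6)))
  lf <- sm[sm$gene == "LEF1" & sm$class == "tumor", ]
  expect_equal(lf$majority_state, "repressed")   # 3 repressed vs 1 active
  expect_equal(lf$inferred_belief, mean(c(0.8, 0.8, 0.6)))
  expect_equal(lf$mean_active, 0.8)
  # majority ties break toward repressed
  tie <- make_results(tibble::tibble(
    iteration = 1:2, test_idx = 1:2, sample = c("a", "b"),
    true_label = c(-1, -1), pr_trcmplx = c(0.2, 0.4), pr_sample = NA_real_,
    evidence = c(ev(1L, 2L), ev(2L, 1L))))
  st <- summarize_gene_trcmplx(tie)
  expect_true(all(st$majority_state == "repressed"))
  expect_error(summarize_gene_trcmplx(res[, -7]), "keep_evidence")
})

test_that("summaries recover the generating direction of label-tied genes", {
  co <- generate_cohort(generator_config(n_normal = 6, n_tumor = 6,
                                         sigma = 0.05, seed = 71))
  # naive-Bayes model: every gene is tied to TRCMPLX directly, so pooled
  # over classes the belief must move in the direction of the generating
  # table — up for LEF1 (tumor-high), down for SFRP3 (normal-high)
  res <- run_ge_experiment(co$dataset, "p1", keep_evidence = TRUE)
  ev_state <- function(g) vapply(res$evidence, function(e) e[[g]], 1L)
  pooled <- function(g, s) mean(res$pr_trcmplx[ev_state(g) == s])
  expect_gt(pooled("LEF1", 2L), pooled("LEF1", 1L))
  expect_lt(pooled("SFRP3", 2L), pooled("SFRP3", 1L))
  # and the per-class summary table reports the same means
  sm <- summarize_gene_trcmplx(res)
  lef_t <- sm[sm$gene == "LEF1" & sm$class == "tumor", ]
  man <- res[res$true_label == 1 & ev_state("LEF1") == 2L, ]
  if (nrow(man) > 0 && lef_t$n_active > 0)
    expect_equal(lef_t$mean_active, mean(man$pr_trcmplx))
})

test_that("evaluate_holdout wires ROC and KS together", {
  res <- make_results(tibble::tibble(
    iteration = rep(1:8, each = 2),
    test_idx = rep(1:16),
    sample = paste0("s", 1:16),
    true_label = rep(c(-1, 1), 8),
    pr_trcmplx = c(rbind(runif(8, 0, 0.45), runif(8, 0.55, 1))),
    pr_sample = c(rbind(runif(8, 0, 0.45), runif(8, 0.55, 1)))
  ))
  ev <- evaluate_holdout(res)
  expect_equal(ev$roc_trcmplx$auc, 1)
  expect_equal(ev$roc_sample$auc, 1)
  expect_true(ev$ks$h01 %in% c(0L, 1L))
  g <- glance(ev)
  expect_equal(g$n, 16L)
  expect_equal(g$auc_trcmplx, 1)
  # p1-style results: no Sample posterior, no KS
  res$pr_sample <- NA_real_
  evp <- evaluate_holdout(res)
  expect_null(evp$roc_sample)
  expect_null(evp$ks)
  expect_true(is.na(glance(evp)$ks_h01))
})

test_that("tidiers and autoplot produce well-formed objects", {
  co <- generate_cohort(generator_config(n_normal = 3, n_tumor = 3,
                                         seed = 81))
  net <- train_network(co$dataset, "t2")
  td <- tidy(net)
  expect_true(all(c("node", "config", "state", "probability") %in% names(td)))
  expect_equal(nrow(td), sum(vapply(net$tables,
                                    function(tb) 2 * ncol(tb$prob), 0)))
  g <- glance(net)
  expect_equal(g$variant, "t2")
  expect_equal(g$n_gene_nodes, 18L)

  r <- compute_roc(runif(10), rep(c(-1, 1), 5))
  expect_s3_class(autoplot(r), "ggplot")
  res <- run_ge_experiment(co$dataset, "t2")
  expect_s3_class(autoplot(res), "ggplot")
})
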