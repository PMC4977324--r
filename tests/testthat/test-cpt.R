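toy_values <- 1:6
toy_labels <- c(-1, -1, -1, 1, 1, 1)

test_that("threshold and discretization follow the median rule", {
  expect_equal(compute_threshold(c(1, 2, 3)), 2)
  expect_equal(compute_threshold(c(1, 2, 3, 4)), 2.5)
  expect_equal(compute_threshold(rep(5, 4)), 5)
  expect_error(compute_threshold(numeric(0)), "empty")

  expect_equal(discretize(0.9, 1), 1L)
  expect_equal(discretize(1.1, 1), 2L)
  expect_equal(discretize(1.0, 1), 2L)   # ties go to the active state
})

test_that("class-state tabulation partitions the samples", {
  cs <- tabulate_class_states(toy_values, toy_labels, 3.5)
  expect_equal(cs[c("a", "b", "c", "d")], list(a = 0L, b = 3L, c = 3L, d = 0L))
  expect_equal(cs$a + cs$c, cs$n_normal)
  expect_equal(cs$b + cs$d, cs$n_tumor)

  all_low <- tabulate_class_states(c(1, 1, 1, 1), c(-1, -1, 1, 1), 5)
  expect_equal(all_low$a + all_low$b, 0L)
  one_class <- tabulate_class_states(1:4, rep(1, 4), 2.5)
  expect_equal(one_class$a + one_class$c, 0L)
  expect_equal(one_class$b + one_class$d, 4L)
  expect_error(tabulate_class_states(1:3, c(-1, 1), 2), "length")
})

test_that("pseudo-count smoothing removes 0/1 and normalizes columns", {
  expect_equal(smooth_and_normalize(cbind(c(0, 0)))[, 1], c(0.5, 0.5))
  expect_equal(smooth_and_normalize(cbind(c(1, 0)))[, 1], c(2 / 3, 1 / 3))
  set.seed(1)
  m <- matrix(runif(16), nrow = 2)
  sm <- smooth_and_normalize(m)
  expect_equal(colSums(sm), rep(1, 8), tolerance = 1e-12)
  expect_true(all(sm > 0 & sm < 1))
  expect_error(smooth_and_normalize(cbind(c(-1, 1))), "negative")
  expect_error(smooth_and_normalize(cbind(c(1, 1)), constant = 0), "> 0")
})

test_that("the sample-only rule reproduces the hand oracle values", {
  tb <- estimate_cpt_sample_only(toy_values, toy_labels, node = "DKK2")
  expect_identical(tb$parents, "Sample")
  expect_equal(tb$prob["on", ], c(1 / 3, 2 / 3))
  expect_equal(colSums(tb$prob), c(1, 1))
  # single-class data: the missing class column is uniform after smoothing
  one <- estimate_cpt_sample_only(1:4, rep(1, 4))
  expect_equal(one$prob[, 1], c(off = 0.5, on = 0.5))
})

test_that("the Sample+TRCMPLX rule follows the printed weighting", {
  tb <- estimate_cpt_sample_trcmplx(toy_values, toy_labels, p = 0.5)
  expect_identical(tb$parents, c("Sample", "TRCMPLX"))
  expect_equal(ncol(tb$prob), 4)
  expect_equal(tb$prob[, 2], c(off = 0.5, on = 0.5))      # (tumor, off)
  expect_equal(tb$prob[, 1], c(off = 2 / 3, on = 1 / 3))  # (normal, off)
  expect_equal(colSums(tb$prob), rep(1, 4), ignore_attr = TRUE)
  # p = 0.5 with symmetric data: the TRCMPLX-on block mirrors the off block
  # with the off/on rows swapped
  sym <- estimate_cpt_sample_trcmplx(c(1, 4, 1, 4), c(-1, -1, 1, 1), p = 0.5)
  expect_equal(unname(sym$prob[, 1:2]), unname(sym$prob[2:1, 3:4]))
  expect_error(estimate_cpt_sample_trcmplx(toy_values, toy_labels, p = 1))
})

test_that("the three-parent methylation rule uses the cross denominators", {
  tb <- estimate_cpt_sample_me_trcmplx(toy_values, toy_labels, p = 0.5,
                                       node = "DKK1", me_parent = "MeDKK1")
  expect_identical(tb$parents, c("Sample", "MeDKK1", "TRCMPLX"))
  expect_equal(ncol(tb$prob), 8)
  # hand oracle with A=6, B=3, C=3, D=6 (pre-smoothing, then (x+1)/3)
  expect_equal(unname(tb$prob["on", 2]), (3 * 0.5 / 3 + 1) / 3)  # (t, um, off)
  expect_equal(unname(tb$prob["off", 3]), (3 * 0.5 / 3 + 1) / 3) # (n, m, off)
  expect_equal(unname(tb$prob["on", 1]), (0 + 1) / 3)            # (n, um, off)
  expect_true(all(tb$prob > 0 & tb$prob < 1))
  expect_equal(colSums(tb$prob), rep(1, 8), ignore_attr = TRUE)
})

test_that("the two-parent methylation rule drops the TRCMPLX factor", {
  tb <- estimate_cpt_sample_me(toy_values, toy_labels, node = "DACT1",
                               me_parent = "MeDACT1")
  expect_identical(tb$parents, c("Sample", "MeDACT1"))
  expect_equal(tb$prob[, 3], c(off = 2 / 3, on = 1 / 3))   # (n, m)
  expect_equal(colSums(tb$prob), rep(1, 4), ignore_attr = TRUE)
  # balanced symmetric data: the methylated column mirrors the
  # unmethylated one with off/on swapped
  sym <- estimate_cpt_sample_me(c(1, 4, 1, 4), c(-1, -1, 1, 1))
  expect_equal(unname(sym$prob[, 1]), unname(rev(sym$prob[, 3])))
  expect_equal(unname(sym$prob[, 1]), unname(sym$prob[, 2]))
})

test_that("the DACT3 histone rule flips outside (low, high)", {
  tb <- estimate_cpt_dact3(toy_values, toy_labels)
  expect_identical(tb$parents, c("H3K27me3", "H3K4me3", "Sample"))
  # a = 0 of 3 normals: Pr(on | low, high, normal) smooths to 1/3,
  # all other normal histone configurations flip to 2/3
  expect_equal(unname(tb$prob["on", 3]), 1 / 3)
  expect_equal(tb$prob["on", c(1, 2, 4)], rep(2 / 3, 3), ignore_attr = TRUE)
  # columns 3 and 7 are the (low, high) columns
  expect_equal(unname(tb$prob["on", 7]), (3 / 3 + 1) / 3)
  expect_equal(colSums(tb$prob), rep(1, 8), ignore_attr = TRUE)
})

test_that("the naive-Bayes rule proxies TRCMPLX by the class label", {
  tb <- estimate_cpt_trcmplx_only(toy_values, toy_labels)
  expect_identical(tb$parents, "TRCMPLX")
  expect_equal(tb$prob["on", ], c(1 / 3, 2 / 3))
  same <- estimate_cpt_trcmplx_only(c(1, 4, 1, 4), c(-1, -1, 1, 1))
  expect_equal(same$prob[, 1], same$prob[, 2], ignore_attr = TRUE)
})

test_that("every estimator matches its literal-transcription oracle", {
  for (seed in 1:100) {
    tv <- random_training_vector(n = sample(6:20, 1), seed = seed)
    v <- tv$values; l <- tv$labels
    p <- runif(1, 0.05, 0.95)
    expect_equal(estimate_cpt_sample_only(v, l)$prob,
                 oracle_sample_only(v, l), ignore_attr = TRUE,
                 tolerance = 1e-12, info = paste("seed", seed))
    expect_equal(estimate_cpt_sample_trcmplx(v, l, p = p)$prob,
                 oracle_sample_trcmplx(v, l, p), ignore_attr = TRUE,
                 tolerance = 1e-12, info = paste("seed", seed))
    expect_equal(estimate_cpt_sample_me_trcmplx(v, l, p = p)$prob,
                 oracle_sample_me_trcmplx(v, l, p), ignore_attr = TRUE,
                 tolerance = 1e-12, info = paste("seed", seed))
    expect_equal(estimate_cpt_sample_me(v, l)$prob,
                 oracle_sample_me(v, l), ignore_attr = TRUE,
                 tolerance = 1e-12, info = paste("seed", seed))
    expect_equal(estimate_cpt_dact3(v, l)$prob,
                 oracle_dact3(v, l), ignore_attr = TRUE,
                 tolerance = 1e-12, info = paste("seed", seed))
    expect_equal(estimate_cpt_trcmplx_only(v, l)$prob,
                 oracle_trcmplx_only(v, l), ignore_attr = TRUE,
                 tolerance = 1e-12, info = paste("seed", seed))
  }
})

test_that("increasing the active-in-normal count raises Pr(on | normal, .)", {
  # same sample size, growing number of active normals
  base <- c(-1, -1, -1, -1, 1, 1, 1, 1)
  prev <- -Inf
  for (k in 0:4) {
    v <- c(rep(0, 4 - k), rep(10, k), c(0, 0, 10, 10)) +
      seq(0.001, 0.008, by = 0.001)
    tb <- estimate_cpt_sample_only(v, base)
    cur <- tb$prob["on", 1]
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("column entries stay strictly inside (0, 1) for all rules", {
  for (seed in 1:10) {
    tv <- random_training_vector(12, seed = seed + 500)
    for (tb in list(estimate_cpt_sample_only(tv$values, tv$labels),
                    estimate_cpt_sample_trcmplx(tv$values, tv$labels),
                    estimate_cpt_sample_me_trcmplx(tv$values, tv$labels),
                    estimate_cpt_dact3(tv$values, tv$labels))) {
      expect_true(all(tb$prob > 0 & tb$prob < 1))
      expect_equal(colSums(tb$prob), rep(1, ncol(tb$prob)),
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
})

test_that("train_network assigns fixed priors and estimates every gene", {
  co <- generate_cohort(generator_config(n_normal = 6, n_tumor = 6, seed = 2))
  for (variant in c("t1", "t2", "p1")) {
    net <- train_network(co$dataset, variant)
    expect_length(net$tables, net$topology$n)
    for (nd in names(net$tables)) {
      tb <- net$tables[[nd]]
      expect_equal(ncol(tb$prob), 2^length(net$topology$nodes[[nd]]$parents))
      expect_equal(colSums(tb$prob), rep(1, ncol(tb$prob)),
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
    if (variant != "p1")
      expect_equal(net$tables$Sample$prob[, 1], c(off = 0.5, on = 0.5))
    expect_equal(unname(net$thresholds[net$topology$nodes[["DKK1"]]$name]),
                 compute_threshold(co$dataset$values["DKK1", ]))
  }
  # diagnostics
  ds_bad <- co$dataset
  one_class <- subset_samples(co$dataset, 1:6)
  expect_error(train_network(one_class, "t1"), "both classes")
  shrunk <- expression_dataset(co$dataset$values[-1, , drop = FALSE],
                               genes = co$dataset$genes[-1],
                               labels = co$dataset$labels)
  expect_error(train_network(shrunk, "t1"), "lacks gene row")
})

test_that("trained networks round-trip through JSON", {
  co <- generate_cohort(generator_config(n_normal = 5, n_tumor = 5, seed = 4))
  net <- train_network(co$dataset, "t2")
  jf <- withr::local_tempfile(fileext = ".json")
  write_network_json(net, jf)
  back <- read_network_json(jf)
  expect_equal(back$thresholds, net$thresholds)
  for (nd in names(net$tables))
    expect_equal(back$tables[[nd]]$prob, net$tables[[nd]]$prob,
                 ignore_attr = TRUE)
  ev <- c(DKK2 = 2L, LEF1 = 1L)
  expect_equal(posterior_marginal(back, ev, "TRCMPLX"),
               posterior_marginal(net, ev, "TRCMPLX"), tolerance = 1e-12)
})
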