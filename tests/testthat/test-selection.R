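# F1 gate, trending index, two-dataset selection, knowledge-graph
# representatives, SVM ROC

test_that("f1_score follows the printed definition", {
  expect_equal(f1_score(10, 0, 0), 1)
  expect_equal(f1_score(5, 5, 0), 2 * 0.5 / 1.5)   # precision .5, recall 1
  expect_equal(f1_score(0, 3, 2), 0)
  expect_true(is.na(f1_score(0, 0, 0)))
})

test_that("per-feature logistic F1: separation, null level, determinism", {
  set.seed(20)
  lab <- rep(c("HSC", "diff"), each = 1000)
  x_sep <- c(rnorm(1000, 10), rnorm(1000, -10))
  expect_equal(evaluate_feature(x_sep, lab, seed = 2)$f1, 1)

  x_null <- rnorm(2000)
  f1_null <- evaluate_feature(x_null, lab, seed = 2)$f1
  expect_lt(abs(f1_null - 0.5), 0.12)

  expect_identical(evaluate_feature(x_null, lab, seed = 7),
                   evaluate_feature(x_null, lab, seed = 7))
  expect_true(evaluate_feature(rep(1, 2000), lab, seed = 1)$degenerate)
})

test_that("trending index reproduces the printed examples exactly", {
  expect_identical(trending_index(c(0, 1, 2, 3)), 1)
  expect_identical(trending_index(c(3, 2, 1, 0)), -1)
  expect_equal(trending_index(c(0, 1, 0, 1)), 1 / 3)
  expect_true(is.na(trending_index(c(2, 2, 2))))
})

test_that("TI is bounded, extremal exactly for monotone means, sign-flips under negation", {
  set.seed(21)
  for (i in 1:200) {
    m <- rnorm(sample(2:6, 1))
    ti <- trending_index(m)
    if (is.na(ti)) next
    expect_lte(abs(ti), 1)
    strict_mono <- all(diff(m) > 0) || all(diff(m) < 0)
    expect_identical(abs(ti) == 1, strict_mono)
    expect_equal(trending_index(-m), -ti)
  }
})

test_that("selection recovers ground-truth informative features across datasets", {
  signs <- c(1, -1, 1, 1, -1, 1, -1, 1, 1, -1)  # trend direction per feature
  ta <- simulate_population_features(population_benchmark_spec(21, signs))
  tb <- simulate_population_features(population_benchmark_spec(22, signs))
  sel <- select_features(ta, tb, seed = 31)
  truth <- c(rep(TRUE, 10), rep(FALSE, 10))
  precision <- sum(sel$selected & truth) / max(sum(sel$selected), 1)
  recall <- sum(sel$selected & truth) / 10
  expect_gte(precision, 0.95)
  expect_gte(recall, 0.95)

  # conjunction rule: monotone in A but flat in B is rejected
  tb_flat <- tb; tb_flat$feat_01 <- rnorm(nrow(tb))
  sel2 <- select_features(ta, tb_flat, seed = 31)
  expect_false(sel2$selected[sel2$feature_id == "feat_01"])

  # vacuous gate empties the selection
  sel3 <- select_features(ta, tb, f1_cut = 1.01, seed = 31)
  expect_equal(sum(sel3$selected), 0)
})

test_that("selection is invariant to positive affine maps, TI flips under negation", {
  signs <- rep(1, 10)
  ta <- simulate_population_features(population_benchmark_spec(23, signs))
  tb <- simulate_population_features(population_benchmark_spec(24, signs))
  ta2 <- ta; ta2$feat_01 <- 3 * ta$feat_01 + 10
  tb2 <- tb; tb2$feat_01 <- 0.5 * tb$feat_01 - 2
  s1 <- select_features(ta, tb, features = "feat_01", seed = 5)
  s2 <- select_features(ta2, tb2, features = "feat_01", seed = 5)
  expect_equal(s1$selected, s2$selected)
  expect_equal(s1$F1_a, s2$F1_a)
  expect_equal(s1$TI_a, s2$TI_a)
  ta3 <- ta; ta3$feat_01 <- -ta$feat_01
  s3 <- select_features(ta3, tb, features = "feat_01", seed = 5)
  expect_equal(s3$TI_a, -s1$TI_a)
})

test_that("knowledge-graph reduction keeps enriched nodes and emits canonical members", {
  reg <- mob_registry()
  graph <- knowledge_graph(reg)
  # every registry feature belongs to exactly one node
  members <- unlist(lapply(graph, `[[`, "members"))
  expect_setequal(members, reg$feature_id)
  expect_false(anyDuplicated(members) > 0)

  node <- graph[["mitochondria.NADPH_intensity.signal"]]
  sel <- data.frame(feature_id = reg$feature_id,
                    selected = reg$feature_id %in% node$members)
  reps <- representatives(sel, graph)
  expect_equal(nrow(reps), 1)
  expect_equal(reps$representative, "mito_NADPH_intensity_average")

  # 1-of-n selected in a node: dropped at the 0.5 fraction cut
  one <- data.frame(feature_id = reg$feature_id,
                    selected = reg$feature_id == node$members[4])
  expect_equal(nrow(representatives(one, graph)), 0)

  none <- data.frame(feature_id = reg$feature_id, selected = FALSE)
  expect_equal(nrow(representatives(none, graph)), 0)

  stray <- data.frame(feature_id = "not_a_feature", selected = TRUE)
  expect_error(representatives(stray, graph), "not covered")
})

test_that("SVM ROC: separable, permuted-null, and nested-information behavior", {
  set.seed(30)
  lab <- rep(c("HSC", "diff"), each = 250)
  x_sep <- cbind(f = c(rnorm(250, 5), rnorm(250, -5)))
  expect_equal(classifier_roc(x_sep, lab, seed = 3)$auc, 1)

  x_null <- cbind(f = rnorm(2000))
  lab_null <- sample(rep(c("HSC", "diff"), each = 1000))
  expect_lt(abs(classifier_roc(x_null, lab_null, seed = 3)$auc - 0.5), 0.06)

  x_info <- cbind(good = c(rnorm(250, 2), rnorm(250, 0)),
                  noise = rnorm(500))
  auc_all <- classifier_roc(x_info, lab, seed = 3)$auc
  auc_noise <- classifier_roc(x_info[, "noise", drop = FALSE], lab,
                              seed = 3)$auc
  expect_gte(auc_all, auc_noise)
})

test_that("the trapezoid AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  lab <- rep(c(1, 0), each = 150)
  x <- cbind(f = c(rnorm(150, 1), rnorm(150)))
  got <- classifier_roc(x, lab, positive = "1", seed = 4)
  # recompute with pROC on the same held-out decision values
  y <- factor(as.integer(lab == 1), levels = c(0, 1))
  train <- mobflim:::.stratified_split(as.integer(lab == 1), 0.7, 4L)
  fit <- e1071::svm(x[train, , drop = FALSE], y[train], kernel = "radial")
  dv <- attr(predict(fit, x[!train, , drop = FALSE], decision.values = TRUE),
             "decision.values")[, 1]
  ref <- suppressMessages(pROC::auc(pROC::roc(as.integer(lab[!train] == 1), dv,
                                              direction = "auto")))
  expect_equal(got$auc, as.numeric(ref), tolerance = 1e-9)
})
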