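fast_cfg <- function(seed = 1L, repeats = 2L) {
  classifier_config("logistic", cv_repeats = repeats, seed = seed)
}

test_that("subset enumeration matches the combinatorial identities", {
  p7 <- letters[1:7]
  expect_length(enumerate_subsets(p7), 120)      # 2^7 - 7 - 1
  expect_length(enumerate_subsets(letters[1:4]), 11)  # 6 + 4 + 1
  s <- enumerate_subsets(letters[1:3], 2, 3)
  expect_equal(s, list(c("a", "b"), c("a", "c"), c("b", "c"), c("a", "b", "c")))
  expect_error(enumerate_subsets(character(0)))
  expect_error(enumerate_subsets(p7, min_size = 5, max_size = 3))
})

test_that("train_cv is seeded, bounded, and rejects bad input", {
  recs <- planted_records(50, "ais", delta = 2, seed = 1)
  cfg <- classifier_config("nnet", hidden_units = 4L, decay = 0.01,
                           cv_repeats = 2L, seed = 3L)
  a <- train_cv(recs, c("ais", "area"), cfg)
  b <- train_cv(recs, c("area", "ais"), cfg)   # order-invariant
  expect_identical(a$per_fold_accuracies, b$per_fold_accuracies)
  expect_gte(a$mean_accuracy, 0); expect_lte(a$mean_accuracy, 1)
  # null features: accuracy stays near the majority-class fraction (held-out
  # accuracy on label-independent features fluctuates just below it)
  null_recs <- planted_records(200, "ais", delta = 0, seed = 2)
  rn <- train_cv(null_recs, descriptor_names("colony"), fast_cfg(4L, 5L))
  maj <- max(table(null_recs$phenotype)) / nrow(null_recs)
  expect_lt(abs(rn$mean_accuracy - maj), max(3 * rn$sem_accuracy, 0.07))
  # near-separable planted feature
  sep <- planted_records(100, "shape_factor", delta = 8, seed = 3)
  rs <- train_cv(sep, "shape_factor", fast_cfg(5L))
  expect_gt(rs$mean_accuracy, 0.95)
  one_class <- planted_records(20, "ais", 1, seed = 4)
  one_class$phenotype <- "good"
  expect_error(train_cv(one_class, "ais", fast_cfg()),
               class = "colonymorph_single_class")
  expect_error(train_cv(recs, "not_a_param", fast_cfg()), "unknown parameter")
})

test_that("importance averages subset accuracies and counts models", {
  recs <- planted_records(60, "ais", delta = 1.5, seed = 5)
  imp <- importance_table(recs, c("ais", "area", "perimeter", "shape_factor"),
                          fast_cfg(6L))
  expect_equal(imp$parameter[1], "ais")
  expect_true(all(imp$n_models == 2^3 - 1))     # subsets of size >= 2 containing p
  sres <- attr(imp, "subset_results")
  expect_length(sres, 11)
  # importance of a parameter equals the mean over subsets containing it
  accs <- vapply(sres, function(r) r$mean_accuracy, numeric(1))
  has_ais <- vapply(sres, function(r) "ais" %in% r$subset, logical(1))
  expect_equal(imp$importance[imp$parameter == "ais"], mean(accs[has_ais]))
})

test_that("importance of exchangeable noise parameters stays flat", {
  recs <- planted_records(80, "ais", delta = 0, seed = 7)
  imp <- importance_table(recs, c("ais", "area", "perimeter", "shape_factor"),
                          fast_cfg(8L, 4L))
  expect_lt(diff(range(imp$importance)), 0.08)
})

test_that("top-k curve ends at the full model and feeds minimal-model selection", {
  recs <- planted_records(60, "ais", delta = 1.5, seed = 9)
  cfg <- fast_cfg(10L)
  imp <- importance_table(recs, c("ais", "area", "perimeter", "shape_factor"), cfg)
  curve <- topk_curve(recs, imp, cfg)
  expect_equal(curve$k, 2:4)
  full <- train_cv(recs, c("ais", "area", "perimeter", "shape_factor"), cfg)
  expect_equal(curve$mean_accuracy[curve$k == 4], full$mean_accuracy)
})

test_that("the one-SEM minimal-model rule reproduces its worked example", {
  curve <- tibble::tibble(
    k = 1:7,
    mean_accuracy = c(0.66, 0.70, 0.73, 0.74, 0.74, 0.735, 0.74),
    sem_accuracy = c(0.01, 0.01, 0.01, 0.006, 0.006, 0.006, 0.006)
  )
  expect_equal(select_minimal_model(curve)$k, 4)
  flat <- tibble::tibble(k = 2:7, mean_accuracy = 0.7, sem_accuracy = 0.01)
  expect_equal(select_minimal_model(flat)$k, 2)
  rising <- tibble::tibble(k = 2:5, mean_accuracy = c(0.6, 0.7, 0.8, 0.8),
                           sem_accuracy = 0.001)
  expect_equal(select_minimal_model(rising)$k, 4)
})

test_that("confusion metrics reproduce printed-table arithmetic", {
  t2 <- confusion_metrics(confusion_from_counts(55, 21, 12, 58))
  expect_equal(t2$accuracy_pct, 77)
  expect_equal(unname(t2$per_class_pct), c(72, 83))
  t3 <- confusion_metrics(confusion_from_counts(720, 379, 513, 1248))
  expect_equal(t3$accuracy_pct, 69)
  expect_equal(unname(t3$per_class_pct), c(66, 71))
  # perfect predictions
  obs <- rep(c("bad", "good"), each = 10)
  ev <- evaluate_predictions(obs, obs)
  expect_equal(ev$metrics$accuracy, 1)
  expect_equal(sum(ev$confusion) - sum(diag(ev$confusion)), 0)
  # row sums are observed class totals
  cm <- confusion_from_counts(5, 3, 2, 9)
  expect_equal(unname(rowSums(cm)), c(8, 11))
  expect_error(confusion_matrix(obs, obs[-1]))
})

test_that("per-line misclassification counts accompany the confusion matrix", {
  obs <- c("bad", "bad", "good", "good", "bad", "good")
  prd <- c("bad", "good", "good", "bad", "bad", "good")
  line <- c("A", "A", "A", "B", "B", "B")
  ev <- evaluate_predictions(obs, prd, line = line)
  expect_equal(ev$per_line$misclassified, c(1L, 1L))
  expect_equal(ev$per_line$misclassified_pct, c(33, 33))
})

test_that("per-line models mirror the pooled protocol", {
  recs <- planted_records(40, "ais", delta = 1.5, seed = 11)
  recs$line <- rep(c("A", "B", "C"), length.out = nrow(recs))
  res <- per_line_models(recs, c("ais", "area"), fast_cfg(12L))
  expect_length(res, 3)
  # a single-line input equals the pooled model
  one <- recs[recs$line == "A", ]
  pooled <- train_cv(one, c("ais", "area"), fast_cfg(13L))
  per <- per_line_models(one, c("ais", "area"), fast_cfg(13L))
  expect_equal(per$A$mean_accuracy, pooled$mean_accuracy)
  # single-class lines are skipped with a warning
  recs2 <- recs
  recs2$phenotype[recs2$line == "C"] <- "good"
  expect_warning(res2 <- per_line_models(recs2, c("ais", "area"), fast_cfg(14L)),
                 "single phenotype")
  expect_length(res2, 2)
})

test_that("the collinearity pre-filter drops near-duplicate descriptors", {
  set.seed(15)
  recs <- tibble::tibble(
    minor_axis = rnorm(100),
    area = rnorm(100),
    shape_factor = rnorm(100)
  )
  recs$feret_d <- recs$minor_axis + rnorm(100, 0, 0.01)     # r ~ 1
  recs$min_feret_d <- recs$minor_axis + rnorm(100, 0, 0.01)
  kept <- drop_correlated(recs, c("minor_axis", "feret_d", "min_feret_d",
                                  "area", "shape_factor"))
  expect_equal(as.character(kept), c("minor_axis", "area", "shape_factor"))
  expect_equal(attr(kept, "dropped"), c("feret_d", "min_feret_d"))
})
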