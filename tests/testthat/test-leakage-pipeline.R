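toy_cm <- function(counts, classes, types = "tumor") {
  rownames(counts) <- sprintf("s%02d", seq_len(nrow(counts)))
  colnames(counts) <- sprintf("g%02d", seq_len(ncol(counts)))
  count_matrix(counts, data.frame(
    sample_id = rownames(counts), class_label = rep_len(classes, nrow(counts)),
    sample_type = rep_len(types, nrow(counts)),
    library_size = rowSums(counts) + 1e6))
}

test_that("empty-submatrix extraction follows the prevalence-then-sample filter", {
  counts <- matrix(0L, 6, 3)
  counts[1:5, 1] <- 7L   # genus present in 5 samples
  counts[1, 2] <- 2L     # rare genus, present in 1 sample
  cm <- toy_cm(counts, c("A", "B"))
  out <- extract_empty_submatrix(cm, prevalence_cutoff = 5)
  expect_equal(colnames(out$counts), c("g02", "g03"))  # g01 dropped by prevalence
  expect_equal(rownames(out$counts), sprintf("s%02d", 2:6))  # s01 had g02 reads
  expect_true(all(out$counts == 0L))

  # all-zero input is unchanged
  cm0 <- toy_cm(matrix(0L, 4, 2), "A")
  out0 <- extract_empty_submatrix(cm0, 5)
  expect_identical(out0$counts, cm0$counts)

  # cutoff 0 retains no features
  expect_warning(out_e <- extract_empty_submatrix(cm, 0), "empty")
  expect_equal(ncol(out_e$counts), 0L)
})

test_that("population copies values by id and is row-order invariant", {
  cm <- toy_cm(matrix(0L, 5, 3), c("A", "B"))
  vals <- matrix(rnorm(15), 5, 3, dimnames = dimnames(cm$counts))
  nm <- normalized_matrix(vals, list(transform = "t"), rep(TRUE, 3),
                          stats::setNames(rep(1e6, 5), rownames(vals)))
  pop <- populate_from_normalized(cm, nm)
  expect_equal(pop$values, vals)
  # shuffling the normalized row order changes nothing (keyed join)
  perm <- c(3, 5, 1, 2, 4)
  nm2 <- normalized_matrix(vals[perm, ], list(transform = "t"), rep(TRUE, 3),
                           stats::setNames(rep(1e6, 5), rownames(vals)[perm]))
  expect_equal(populate_from_normalized(cm, nm2)$values, vals)
  # constant normalized matrix populates a constant
  nmc <- normalized_matrix(matrix(2.5, 5, 3, dimnames = dimnames(vals)),
                           list(transform = "t"), rep(TRUE, 3),
                           stats::setNames(rep(1e6, 5), rownames(vals)))
  expect_true(all(populate_from_normalized(cm, nmc)$values == 2.5))
  # absent features are dropped with a message; absent samples are an error
  nmd <- normalized_matrix(vals[, 1:2], list(transform = "t"), rep(TRUE, 2),
                           stats::setNames(rep(1e6, 5), rownames(vals)))
  expect_message(popd <- populate_from_normalized(cm, nmd), "dropping 1")
  expect_equal(ncol(popd$values), 2L)
  nms <- normalized_matrix(vals[1:3, ], list(transform = "t"), rep(TRUE, 3),
                           stats::setNames(rep(1e6, 3), rownames(vals)[1:3]))
  expect_error(populate_from_normalized(cm, nms), "absent")
})

test_that("a deterministic class indicator is classified perfectly", {
  n <- 60
  cls <- rep(c("A", "B"), each = n / 2)
  x <- cbind(ind = as.numeric(cls == "A"))
  ev <- one_vs_all_evaluate(x, cls, n_folds = 5, n_estimators = 30, seed = 1)
  a <- ev$per_class[ev$per_class$class == "A", ]
  expect_equal(a$auc, 1)
  expect_equal(a$sensitivity, 1)
  expect_equal(a$specificity, 1)
})

test_that("pure-noise features score near chance", {
  set.seed(2)
  x <- matrix(rnorm(200 * 5), 200, 5)
  cls <- rep(c("A", "B", "C", "D"), each = 50)
  ev <- one_vs_all_evaluate(x, cls, n_folds = 5, n_estimators = 30, seed = 3)
  expect_lt(abs(ev$medians[["auc"]] - 0.5), 0.1)
  expect_error(one_vs_all_evaluate(x, rep("A", 200)), "2 classes")
})

test_that("evaluation metrics are well-formed and medians skip undefined values", {
  set.seed(4)
  x <- matrix(rnorm(80 * 3), 80, 3)
  cls <- rep(c("A", "B"), each = 40)
  ev <- one_vs_all_evaluate(x, cls, n_folds = 4, n_estimators = 20, seed = 5)
  m <- ev$per_class[, c("auc", "sensitivity", "specificity", "ppv", "npv")]
  expect_true(all(is.na(as.matrix(m)) | (as.matrix(m) >= 0 & as.matrix(m) <= 1)))
  expect_false(anyNA(ev$medians[c("auc", "sensitivity", "specificity", "npv")]))
})

test_that("trapezoid AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(6)
  y <- sample(c(TRUE, FALSE), 100, replace = TRUE)
  s <- rnorm(100) + y
  ours <- leakforensics:::trapezoid_auc(s, y)
  ref <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = s,
                                        quiet = TRUE, direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
  # ties: a constant score is exactly chance
  expect_equal(leakforensics:::trapezoid_auc(rep(1, 100), y), 0.5)
})

test_that("the information-free experiment is null without leakage and hot with it", {
  cm <- simulate_count_matrix(sprintf("C%d", 1:4), 30, n_common_features = 0,
                              n_rare_features = 0, n_zero_features = 8, seed = 7)
  blind <- supervised_normalize(voom_logcpm(cm), rep("x", 120), leak_mode = "none")
  res0 <- run_fig6_experiment(cm, blind, n_folds = 5, n_estimators = 20, seed = 8)
  expect_true(res0$provenance$raw_all_zero)
  expect_equal(res0$evaluation$medians[["auc"]], 0.5, tolerance = 0.1)

  leaky <- supervised_normalize(voom_logcpm(cm), cm$metadata$class_label,
                                leak_mode = "class_offsets", seed = 9)
  res1 <- run_fig6_experiment(cm, leaky, n_folds = 5, n_estimators = 20, seed = 8)
  expect_gt(res1$evaluation$medians[["sensitivity"]], 0.9)
  expect_gt(res1$evaluation$medians[["specificity"]], 0.9)
  expect_equal(res1$provenance$n_samples, 120L)
  expect_equal(res1$provenance$n_features, 8L)
})

test_that("only primary tumor samples enter the classifier stage", {
  cm <- simulate_count_matrix(c("A", "B"), 30, n_common_features = 0,
                              n_rare_features = 0, n_zero_features = 6,
                              sample_type = c("tumor", "normal"), seed = 10)
  leaky <- supervised_normalize(voom_logcpm(cm), cm$metadata$class_label,
                                leak_mode = "class_offsets", seed = 11)
  res <- run_fig6_experiment(cm, leaky, n_folds = 5, n_estimators = 20, seed = 12)
  expect_equal(res$provenance$n_samples, sum(cm$metadata$sample_type == "tumor"))
})
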