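mat1 <- function(x, ids = sprintf("s%d", seq_along(x))) {
  matrix(as.integer(x), ncol = 1, dimnames = list(ids, "g1"))
}

test_that("inflation report implements the stated pair, tenfold and within-50 rules", {
  A <- mat1(c(100, 20, 5)); B <- mat1(c(5, 15, 0))
  r <- inflation_report(A, B, thresholds = 10)
  expect_equal(r$n_pairs, 2L)       # entries with A >= 10
  expect_equal(r$n_tenfold, 1L)     # 100 vs 5
  expect_equal(r$n_within50, 1L)    # 20 vs 15

  # identity: tenfold fraction 0, within-50 fraction 1
  C <- mat1(c(12, 40, 100))
  ri <- inflation_report(C, C, thresholds = c(10, 100))
  expect_equal(ri$frac_tenfold, c(0, 0))
  expect_equal(ri$frac_within50[1L], 1)
  expect_true(is.na(ri$n_within50[2L]))

  # a zero in B counts as tenfold whenever the pair is considered
  rz <- inflation_report(mat1(1000), mat1(0), thresholds = 10)
  expect_equal(rz$n_tenfold, 1L)

  expect_error(inflation_report(A, mat1(c(1, 2, 3), ids = c("x", "y", "z"))),
               "ids disagree")
})

test_that("inflation is antisymmetric in the matrix roles", {
  set.seed(8)
  B <- matrix(10L + rpois(50, 20), 10, 5,
              dimnames = list(sprintf("s%d", 1:10), sprintf("g%d", 1:5)))
  A <- B * 100L
  expect_equal(inflation_report(A, B, 10)$frac_tenfold, 1)
  expect_equal(inflation_report(B, A, 10)$frac_tenfold, 0)
})

test_that("duplicate-value clusters recover tag groups and ignore singletons", {
  expect_equal(duplicate_value_clusters(c(1.5, 2.5, 3.7))$size, integer(0))
  expect_equal(duplicate_value_clusters(rep(3.14159, 7))$size, 7L)
  x <- c(rep(1.00000001, 3), rep(1.00000002, 2), 5)
  d <- duplicate_value_clusters(x, sig_digits = 9)
  expect_equal(d$size, c(3L, 2L))
  # at coarser tolerance the two tags merge
  expect_equal(duplicate_value_clusters(x, sig_digits = 6)$size, 5L)
  expect_error(duplicate_value_clusters(x, group = logical(6)), "empty")
})

test_that("normal-tissue tag clusters in the reconstructed case study are 38/18/5", {
  fx <- mulikevirus_fixture()
  d <- duplicate_value_clusters(fx$normalized$values[, "Mulikevirus"],
                                fx$labels == "normal")
  expect_equal(d$size, c(38L, 18L, 5L))
  # every normal value sits below every tumor value
  expect_lt(max(fx$normalized$values[fx$labels == "normal", 1]),
            min(fx$normalized$values[fx$labels == "tumor", 1]))
  expect_true(all(fx$raw$counts == 0L))
})

test_that("threshold rules agree with brute-force confusion matrices", {
  set.seed(9)
  for (rep in 1:5) {
    v <- round(rnorm(20), 1)
    lab <- sample(c(TRUE, FALSE), 20, replace = TRUE)
    if (all(lab) || !any(lab)) next
    thr <- sample(v, 1)
    for (d in c("ge", "gt", "le", "lt"))
      expect_equal(threshold_rule_eval(v, lab, thr, d)[1:4],
                   brute_rule(v, lab, thr, d))
  }
  expect_error(threshold_rule_eval(1:4, rep(TRUE, 4), 2), "both classes")
})

test_that("the single-virus rule reproduces the published sensitivity and error count", {
  fx <- hepandensovirus_fixture()
  ev <- threshold_rule_eval(fx$normalized$values[, "Hepandensovirus"],
                            fx$labels == "ACC", fx$tag_value, "le")
  expect_equal(ev$sensitivity, 71 / 79)
  expect_equal(ev$n_errors, 77L)
  expect_equal(ev$error_rate, 77 / 17625)
  # the raw column is informationless: one sample with 2 reads, rest zero
  expect_equal(sum(fx$raw$counts != 0), 1L)
  expect_equal(max(fx$raw$counts), 2L)
})

test_that("perfect separation yields sensitivity 1 and error rate 0", {
  ev <- threshold_rule_eval(c(1, 2, 8, 9), c(FALSE, FALSE, TRUE, TRUE), 5, "ge")
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$specificity, 1)
  expect_equal(ev$error_rate, 0)
})

test_that("best threshold rule maximizes balanced accuracy with sane defaults", {
  r <- best_threshold_rule(c(0, 0, 1, 1), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(r$balanced_accuracy, 1)
  expect_equal(r$direction, "ge")
  # never below 0.5, whatever the labels
  set.seed(10)
  for (rep in 1:20) {
    v <- rnorm(30)
    lab <- sample(c(TRUE, FALSE), 30, replace = TRUE, prob = c(0.3, 0.7))
    if (all(lab) || !any(lab)) next
    expect_gte(best_threshold_rule(v, lab)$balanced_accuracy, 0.5)
  }
  # labels independent of values stay near chance
  set.seed(11)
  bas <- replicate(10, {
    v <- rnorm(100)
    best_threshold_rule(v, sample(rep(c(TRUE, FALSE), 50)))$balanced_accuracy
  })
  expect_true(all(abs(bas - 0.5) < 0.15))
})

test_that("rule metrics are invariant under monotone transforms of the values", {
  set.seed(12)
  v <- rnorm(50)
  lab <- v + rnorm(50) > 0
  ev1 <- threshold_rule_eval(v, lab, 0.3, "ge")
  ev2 <- threshold_rule_eval(exp(v), lab, exp(0.3), "ge")
  expect_equal(ev1, ev2)
})

test_that("disjoint tumor/normal values in the kidney case study separate almost perfectly", {
  fx <- thiorhodospira_fixture()
  r <- best_threshold_rule(fx$normalized$values[, 1], fx$labels == "tumor")
  expect_gt(r$balanced_accuracy, 0.95)
  # raw counts: 85 zeros, 7 ones
  expect_equal(sum(fx$raw$counts == 1L), 7L)
  expect_equal(sum(fx$raw$counts == 0L), 85L)
})

test_that("discordance scan flags leak-tagged zero features and only those", {
  cm <- simulate_count_matrix(c("A", "B"), 25, n_common_features = 3,
                              n_rare_features = 0, n_zero_features = 3,
                              seed = 13)
  cm$metadata$library_size <- rep(1e6, 50)
  cm <- count_matrix(cm$counts, cm$metadata)
  leaky <- supervised_normalize(voom_logcpm(cm), cm$metadata$class_label,
                                leak_mode = "class_offsets", offset_sd = 2,
                                noise_sd = 0.05, seed = 14)
  scan <- discordance_scan(cm, leaky, cm$metadata$class_label)
  expect_true(all(scan$discordant[grepl("zero", scan$feature)]))
  blind <- supervised_normalize(voom_logcpm(cm), rep("all", 50),
                                leak_mode = "none")
  scan0 <- discordance_scan(cm, blind, cm$metadata$class_label)
  expect_false(any(scan0$discordant))
})

test_that("the reconstructed head-and-neck case study is flagged as discordant", {
  fx <- mulikevirus_fixture()
  scan <- discordance_scan(fx$raw, fx$normalized, fx$labels)
  expect_true(scan$discordant[1L])
  # the normal samples sit below the rule threshold, tumors above
  ev <- threshold_rule_eval(fx$normalized$values[, 1], fx$labels == "normal",
                            scan$threshold[1L], scan$direction[1L])
  expect_gte(ev$sensitivity + ev$specificity, 1.9)
})
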