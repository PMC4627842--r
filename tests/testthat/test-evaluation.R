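test_that("confusion counts partition the residue set", {
  truth <- rep(c("D", "O"), each = 5)
  expect_equal(unclass(confusion(truth, truth))[c("TP", "TN", "FP", "FN")],
               list(TP = 5L, TN = 5L, FP = 0L, FN = 0L))
  inv <- ifelse(truth == "D", "O", "D")
  cc <- confusion(truth, inv)
  expect_equal(cc$FP + cc$FN, 10)
  expect_equal(cc$TP + cc$TN + cc$FP + cc$FN, 10)
  expect_error(confusion(c("D", "U"), c("D", "D")), "excluded")
})

test_that("binary_metrics handles the perfect and degenerate cases", {
  m <- binary_metrics(list(TP = 1, TN = 1, FP = 0, FN = 0))
  expect_equal(c(m$SENS, m$SPEC, m$ACC, m$PPV, m$Sw, m$MCC),
               c(1, 1, 1, 1, 1, 1))
  # zero denominators give NA markers, never silent zeros
  m0 <- binary_metrics(list(TP = 0, TN = 5, FP = 0, FN = 0))
  expect_true(is.na(m0$SENS))
  expect_true(is.na(m0$Sw))
  expect_true(is.na(m0$PPV))
  expect_error(binary_metrics(list(TP = -1, TN = 0, FP = 0, FN = 0)),
               "negative")
})

test_that("MCC is antisymmetric under swapping predicted classes", {
  set.seed(21)
  for (i in 1:20) {
    cc <- random_confusion()
    m <- binary_metrics(cc)
    swapped <- binary_metrics(list(TP = cc$FN, TN = cc$FP,
                                   FP = cc$TN, FN = cc$TP))
    expect_equal(m$MCC, -swapped$MCC, tolerance = 1e-12)
    expect_true(m$MCC >= -1 && m$MCC <= 1)
  }
})

test_that("content MAE is a mean absolute difference, order-invariant", {
  expect_equal(content_mae(c(0.2, 0.4), c(0.2, 0.4)), 0)
  expect_equal(content_mae(c(0.2, 0.4), c(0.4, 0.2)), 0.2)
  expect_equal(content_mae(rev(c(0.2, 0.4)), rev(c(0.4, 0.2))), 0.2)
  expect_error(content_mae(numeric(0), numeric(0)), "empty")
})

test_that("rank AUC matches the exhaustive pairwise oracle", {
  set.seed(41)
  for (i in 1:25) {
    n <- sample(10:50, 1)
    truth <- sample(c("D", "O"), n, replace = TRUE)
    if (length(unique(truth)) < 2) truth[1:2] <- c("D", "O")
    # discretized probabilities force ties
    prob <- round(runif(n), sample(c(1, 2, 6), 1))
    r <- roc_auc(truth, prob, n_boot = 0)
    expect_equal(r$auc, auc_oracle(truth, prob), tolerance = 1e-12)
  }
})

test_that("AUC hits 1 for perfect ranking and ~0.5 for noise", {
  truth <- rep(c("D", "O"), each = 50)
  expect_equal(roc_auc(truth, ifelse(truth == "D", 1, 0), n_boot = 0)$auc, 1)
  set.seed(8)
  noisy <- roc_auc(rep(c("D", "O"), each = 2000), runif(4000), n_boot = 0)
  expect_lt(abs(noisy$auc - 0.5), 0.05)
  expect_error(roc_auc(rep("D", 5), runif(5), n_boot = 0), "both classes")
})

test_that("AUC agrees with pROC and the bootstrap CI brackets it", {
  skip_if_not_installed("pROC")
  set.seed(13)
  truth <- rep(c("D", "O"), c(40, 110))
  prob <- ifelse(truth == "D", rnorm(150, 0.7, 0.2), rnorm(150, 0.35, 0.2))
  r <- roc_auc(truth, prob, n_boot = 500, seed = 2)
  ref <- suppressMessages(
    as.numeric(pROC::auc(pROC::roc(truth, prob, levels = c("O", "D"),
                                   direction = "<"))))
  expect_equal(r$auc, ref, tolerance = 1e-12)
  expect_lte(r$ci[1], r$auc)
  expect_gte(r$ci[2], r$auc)
  # seeded bootstrap is reproducible
  expect_identical(r$ci, roc_auc(truth, prob, n_boot = 500, seed = 2)$ci)
  # curve points: ROC starts at (0,0) and ends at (1,1)
  expect_equal(unlist(r$roc[1, c("fpr", "tpr")]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(r$roc[nrow(r$roc), c("fpr", "tpr")]),
               c(fpr = 1, tpr = 1))
})

test_that("fold construction follows modular assignment", {
  ids <- rep(c("a", "b", "c"), times = c(4, 3, 5))
  f <- make_folds(ids, "residue", 10)
  expect_equal(f[1:10], 1:10)  # one residue per fold across the first ten
  expect_equal(f[11:12], 1:2)
  fs <- make_folds(ids, "sequence", 2)
  # a chain is never split across folds
  expect_true(all(vapply(split(fs, ids), function(x) length(unique(x)), 1L)
                  == 1L))
  expect_equal(unique(fs[ids == "a"]), 1L)
  expect_equal(unique(fs[ids == "b"]), 2L)
  expect_identical(f, make_folds(ids, "residue", 10))
  expect_error(make_folds(ids, "sequence", 5), "fewer")
})

test_that("overlap probability follows the analytic formula", {
  expect_equal(overlap_probability(477, 400, 21),
               (100 / 9) * 20 / (477^2 * 400))
  expect_equal(overlap_probability(100, 300, 1), 0)
  expect_equal(overlap_probability(100, 300, 21),
               4 * overlap_probability(200, 300, 21))
})

test_that("cross-validation isolates folds and reports both views", {
  feat <- tiny_features()
  cv <- cross_validate(feat$x, feat$meta, hyper_params(window = 5L),
                       k = 4, split = "sequence", seed = 55, n_boot = 100)
  expect_length(cv$folds, 4)
  expect_identical(nrow(cv$summary), 6L)
  # partition property: every evaluated residue predicted exactly once
  known <- feat$meta$label != "U"
  expect_identical(nrow(cv$pred), sum(known))
  # fold counts sum to the pooled counts
  expect_equal(sum(vapply(cv$folds, function(f) f$TP + f$TN + f$FP + f$FN,
                          0)),
               cv$pooled$TP + cv$pooled$TN + cv$pooled$FP + cv$pooled$FN)
  # sequence folds keep chains intact
  expect_true(all(vapply(split(cv$pred$fold, cv$pred$id),
                         function(x) length(unique(x)), 1L) == 1L))
  expect_true(cv$pooled$AUC >= 0 && cv$pooled$AUC <= 1)
  expect_false(is.na(cv$pooled$MAE))
})

test_that("report files carry the Sw = 2 ACC - 1 identity", {
  m <- binary_metrics(list(TP = 40, TN = 80, FP = 20, FN = 10))
  base <- withr::local_tempfile()
  write_report(m, base)
  kv <- read.table(paste0(base, ".tsv"), sep = "\t",
                   stringsAsFactors = FALSE)
  vals <- setNames(kv$V2, kv$V1)
  expect_equal(as.numeric(vals["Sw"]), 2 * as.numeric(vals["ACC"]) - 1,
               tolerance = 1e-9)
  expect_true(file.exists(paste0(base, ".txt")))
})
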