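test_that("portion splits are stratified 80/20 and disjoint", {
  meta <- data.frame(record = sprintf("r%02d", 1:10),
                     patient = sprintf("p%02d", 1:10),
                     label = rep(c("NSR", "AFib"), each = 5),
                     stringsAsFactors = FALSE)
  # several beats per portion
  meta <- meta[rep(1:10, each = 7), ]
  sp <- make_split(meta, "portion", seed = 3)
  expect_length(sp$train_units, 8)
  expect_length(sp$test_units, 2)
  expect_length(intersect(sp$train_units, sp$test_units), 0)
  expect_setequal(c(sp$train, sp$test), seq_len(nrow(meta)))
  # stratified: one test portion per class
  lab_of <- setNames(rep(c("NSR", "AFib"), each = 5), sprintf("r%02d", 1:10))
  expect_setequal(unique(lab_of[sp$test_units]), c("NSR", "AFib"))
})

test_that("a 23-patient pool splits 18 train / 5 test with no overlap", {
  meta <- data.frame(record = sprintf("r%03d", 1:46),
                     patient = rep(sprintf("p%02d", 1:23), 2),
                     label = rep(c("NSR", "AFib"), each = 23),
                     stringsAsFactors = FALSE)
  sp <- make_split(meta, "patient", seed = 9)
  expect_length(sp$train_units, 18)
  expect_length(sp$test_units, 5)
  expect_length(intersect(unique(meta$patient[sp$train]),
                          unique(meta$patient[sp$test])), 0)
  expect_error(make_split(data.frame(record = "a", patient = "p",
                                     label = "NSR"), "patient"),
               "2 patients")
})

test_that("undersampling balances the training classes deterministically", {
  labels <- c(rep("NSR", 1000), rep("AFib", 300))
  idx <- balance_classes(labels, seed = 4)
  expect_equal(unname(table(labels[idx])), c(300L, 300L),
               ignore_attr = TRUE)
  # minority class untouched
  expect_true(all(which(labels == "AFib") %in% idx))
  expect_identical(idx, balance_classes(labels, seed = 4))
  expect_false(identical(idx, balance_classes(labels, seed = 5)))
  # already balanced: identity
  lab2 <- rep(c("NSR", "AFib"), 10)
  expect_identical(balance_classes(lab2, seed = 1), 1:20)
  expect_error(balance_classes(rep("NSR", 5)), "both classes")
})

test_that("threshold selection maximises Youden's J", {
  # perfectly separated scores: threshold in the gap, J = 1
  prob <- c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9)
  y <- c(0, 0, 0, 1, 1, 1)
  thr <- select_threshold(prob, y)
  expect_gt(thr, 0.3); expect_lte(thr, 0.7)
  r <- evaluate(prob, y, thr)
  expect_equal(r$recall + r$counts["TN"] / 3 - 1, 1, ignore_attr = TRUE)

  # brute-force J over a dense grid is never beaten
  set.seed(6)
  for (i in 1:20) {
    p <- runif(40); yy <- rbinom(40, 1, 0.5)
    if (length(unique(yy)) < 2) next
    t0 <- select_threshold(p, yy)
    jfun <- function(t) {
      pr <- p >= t
      sum(pr & yy == 1) / sum(yy == 1) - sum(pr & yy == 0) / sum(yy == 0)
    }
    grid <- seq(0.001, 0.999, by = 0.001)
    expect_gte(jfun(t0) + 1e-12, max(vapply(grid, jfun, numeric(1))))
    # swapping labels: the optimal J for flipped labels is attainable too
    t1 <- select_threshold(p, 1 - yy)
    jflip <- function(t) {
      pr <- p >= t
      sum(pr & yy == 0) / sum(yy == 0) - sum(pr & yy == 1) / sum(yy == 1)
    }
    expect_gte(jflip(t1) + 1e-12, max(vapply(grid, jflip, numeric(1))))
  }

  expect_warning(t2 <- select_threshold(runif(5), rep(1, 5)), "degenerate")
  expect_equal(t2, 0.5)
})

test_that("evaluation metrics match closed forms and stay self-consistent", {
  # TP 8, FP 2, FN 2, TN 8
  prob <- c(rep(0.9, 8), rep(0.1, 2), rep(0.9, 2), rep(0.1, 8))
  y <- c(rep(1, 10), rep(0, 10))
  r <- evaluate(prob, y, 0.5)
  expect_equal(unname(r$counts), c(8L, 2L, 8L, 2L))
  expect_equal(r$accuracy, 0.8)
  expect_equal(r$precision, 0.8)
  expect_equal(r$recall, 0.8)
  expect_equal(r$f1, 0.8)

  perfect <- evaluate(c(0.9, 0.9, 0.1), c(1, 1, 0), 0.5)
  expect_equal(perfect$accuracy, 1); expect_equal(perfect$f1, 1)
  expect_equal(perfect$auc, 1)

  allpos <- evaluate(rep(0.9, 10), rep(c(0, 1), 5), 0.5)
  expect_equal(allpos$recall, 1)
  expect_equal(allpos$accuracy, 0.5)

  # metrics recomputable from the confusion counts
  set.seed(12)
  p <- runif(100); yy <- rbinom(100, 1, 0.4)
  rr <- evaluate(p, yy, 0.6)
  with(as.list(rr$counts), {
    expect_equal(rr$accuracy, (TP + TN) / 100)
    expect_equal(rr$precision, if (TP + FP) TP / (TP + FP) else 0)
    expect_equal(rr$recall, TP / (TP + FN))
    expect_equal(rr$f1,
                 2 * rr$precision * rr$recall / (rr$precision + rr$recall))
  })
})

test_that("trapezoidal AUC equals pairwise concordance, including ties", {
  set.seed(13)
  for (i in 1:25) {
    n <- sample(10:200, 1)
    p <- sample(round(runif(n), 2))  # rounding forces ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(evaluate(p, y, 0.5)$auc, auc_bruteforce(p, y),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  p <- runif(150); y <- rbinom(150, 1, 0.5)
  ours <- evaluate(p, y, 0.5)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("Mann-Whitney U matches exhaustive pair counting and wilcox.test", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  m <- mannwhitney_u(a, b)
  expect_equal(m$U, 0)  # U counts pairs where a > b

  same <- mannwhitney_u(1:10, 1:10)
  expect_gt(same$p, 0.9)

  set.seed(15)
  # small instances (n1 + n2 <= 12), heavy ties
  for (i in 1:300) {
    n1 <- sample(1:6, 1); n2 <- sample(1:6, 1)
    x <- sample(1:4, n1, replace = TRUE)
    y <- sample(1:4, n2, replace = TRUE)
    got <- mannwhitney_u(x, y)
    expect_equal(got$U, mwu_bruteforce(x, y))
    expect_true(got$U >= 0 && got$U <= n1 * n2)
    expect_true(got$p > 0 && got$p <= 1)
  }
  # larger random instances
  for (i in 1:1000) {
    n1 <- sample(5:30, 1); n2 <- sample(5:30, 1)
    x <- round(rnorm(n1), 1); y <- round(rnorm(n2, 0.3), 1)
    expect_equal(mannwhitney_u(x, y)$U, mwu_bruteforce(x, y))
  }
  # p agrees with the tie-corrected normal approximation in wilcox.test
  set.seed(16)
  x <- rnorm(40); y <- rnorm(35, 0.4)
  ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  got <- mannwhitney_u(x, y)
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  expect_equal(got$U, unname(ref$statistic))
  expect_error(mannwhitney_u(numeric(0), 1), "non-empty")
})

test_that("the LCSD-only logistic baseline behaves at the extremes", {
  cfg <- train_config(max_epochs = 300, patience = 100,
                      learning_rate = 0.05, seed = 1)
  # perfectly separated LCSD
  tr_l <- c(runif(40, 0, 0.05), runif(40, 0.4, 0.8))
  tr_y <- rep(0:1, each = 40)
  te_l <- c(runif(10, 0, 0.05), runif(10, 0.4, 0.8))
  te_y <- rep(0:1, each = 10)
  rep1 <- lcsd_baseline(tr_l, tr_y, te_l, te_y, config = cfg)
  expect_equal(rep1$f1, 1)

  # constant LCSD raises the degenerate flag
  rep2 <- suppressMessages(suppressWarnings(
    lcsd_baseline(rep(0.2, 80), tr_y, te_l, te_y, config = cfg)))
  expect_true("constant_lcsd" %in% rep2$degenerate)
})

test_that("cross-validation partitions folds and returns the best instance", {
  bb <- beat_benchmark()
  idx <- seq_len(min(120, nrow(bb$x)))
  cv <- suppressMessages(crossval_train(
    bb$x[idx, ], bb$y[idx], lcsd = bb$lcsd[idx], family = "sup_ae",
    folds = 3, config = scaled_config(max_epochs = 40, patience = 15),
    seed = 2))
  expect_equal(sort(unique(cv$assignment)), 1:3)
  expect_length(cv$assignment, length(idx))
  expect_equal(min(cv$folds$val_loss), cv$folds$val_loss[cv$best_fold])
  expect_s3_class(cv$model, "beat_classifier")
  p <- predict(cv$model, bb$x[idx, ], lcsd = bb$lcsd[idx])
  expect_true(all(p > 0 & p < 1))
  expect_error(crossval_train(bb$x[1:5, ], bb$y[1:5], folds = 10,
                              config = scaled_config()),
               "fewer samples")
})

test_that("a pipeline manifest re-executes to bit-identical reports", {
  cfg <- pipeline_config(seed = 17, n_per_class = 4, duration = 20,
                         folds = 2,
                         train = list(max_epochs = 40, patience = 15))
  r1 <- suppressMessages(run_pipeline(cfg))
  r2 <- suppressMessages(run_pipeline(r1$manifest))
  expect_identical(r1$eval, r2$eval)
  expect_identical(r1$cv, r2$cv)
  expect_identical(r1$mwu[c("U", "z", "p")], r2$mwu[c("U", "z", "p")])
  expect_identical(r1$data_summary, r2$data_summary)
})

test_that("a model/feature grid shares one test set across cells", {
  cfg <- pipeline_config(seed = 18, n_per_class = 4, duration = 20,
                         folds = 2,
                         train = list(max_epochs = 30, patience = 10))
  grid <- suppressMessages(run_grid(cfg))
  expect_named(grid, c("ae", "ae+lcsd", "sup_ae", "sup_ae+lcsd"))
  tests <- lapply(grid, function(g) g$data_summary$test_units)
  expect_identical(tests[[1]], tests[[2]])
  expect_identical(tests[[1]], tests[[3]])
  expect_identical(tests[[1]], tests[[4]])
  expect_equal(unname(vapply(grid, function(g) sum(g$eval$counts),
                             numeric(1))),
               rep(sum(grid[[1]]$eval$counts), 4))
})

test_that("patient-mode runs report the patient partition", {
  cfg <- pipeline_config(seed = 19, n_per_class = 4, duration = 20,
                         folds = 2, patients = 4, patient_morph_sd = 0.2,
                         split_mode = "patient",
                         train = list(max_epochs = 30, patience = 10))
  r <- suppressMessages(run_pipeline(cfg))
  expect_equal(r$data_summary$split_mode, "patient")
  expect_length(intersect(r$data_summary$train_units,
                          r$data_summary$test_units), 0)
  expect_setequal(c(r$data_summary$train_units, r$data_summary$test_units),
                  sprintf("pat-%03d", 1:4))
})
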