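# Evaluation protocol: splits, class balancing, cross-validated training of
# the two model pipelines (encoder+MLP and supervised AE), ROC threshold
# selection, classification metrics, the Mann-Whitney U validation of the
# LCSD statistic, and the orchestrating run_pipeline().

#' Split a beat dataset into train and test sets
#'
#' `"portion"` mode splits on signal portions (maximal same-label intervals;
#' for synthetic and CinC-like data one record = one portion), stratified by
#' class; `"patient"` mode splits on patient ids so no patient appears on
#' both sides. The training side receives `round(train_frac * n_units)`
#' units.
#'
#' @param meta Per-beat metadata data frame with columns `record`,
#'   `patient`, `label`.
#' @param mode `"portion"` or `"patient"`.
#' @param train_frac Fraction of units assigned to training (default 0.8).
#' @param seed RNG seed.
#' @return List with `train` and `test` beat-row indices and the unit
#'   partitions (`train_units`, `test_units`).
#' @export
make_split <- function(meta, mode = c("portion", "patient"),
                       train_frac = 0.8, seed = 1L) {
  mode <- match.arg(mode)
  set.seed(as.integer(seed))
  if (mode == "patient") {
    units <- unique(meta$patient)
    if (length(units) < 2L) stop("patient mode needs >= 2 patients")
    n_train <- as.integer(rhalf(train_frac * length(units)))
    n_train <- min(max(n_train, 1L), length(units) - 1L)
    train_units <- sample(units, n_train)
    unit_of <- meta$patient
  } else {
    # stratify portions by their class so both sides see both rhythms
    ulab <- unique(meta[, c("record", "label")])
    units <- ulab$record
    if (anyDuplicated(units))
      stop("portion mode expects one label per record portion")
    train_units <- character(0)
    for (cl in unique(ulab$label)) {
      u <- ulab$record[ulab$label == cl]
      n_train <- as.integer(rhalf(train_frac * length(u)))
      n_train <- min(max(n_train, 1L), max(length(u) - 1L, 1L))
      train_units <- c(train_units, sample(u, n_train))
    }
    unit_of <- meta$record
  }
  test_units <- setdiff(units, train_units)
  list(train = which(unit_of %in% train_units),
       test = which(unit_of %in% test_units),
       train_units = sort(train_units), test_units = sort(test_units),
       mode = mode)
}

#' Undersample the majority class
#'
#' Training-set balancing: the majority class is randomly undersampled
#' (seeded, without replacement) down to the minority-class count; the
#' minority class is untouched. Test data are never balanced.
#'
#' @param labels Character or factor vector of beat labels.
#' @param seed RNG seed.
#' @return Sorted integer indices of the balanced subset.
#' @export
balance_classes <- function(labels, seed = 1L) {
  tab <- table(labels)
  if (length(tab) < 2L) stop("both classes must be present to balance")
  n_min <- min(tab)
  set.seed(as.integer(seed))
  idx <- unlist(lapply(names(tab), function(cl) {
    rows <- which(labels == cl)
    if (length(rows) > n_min) sort(sample(rows, n_min)) else rows
  }))
  sort(idx)
}

#' Select the ROC operating threshold by Youden's J
#'
#' Scans the ROC of the validation scores and returns the threshold
#' maximising `J = sensitivity + specificity - 1`; ties are broken toward
#' 0.5. Degenerate label sets return 0.5 with a warning.
#'
#' @param prob Predicted probabilities for the positive (AFib) class.
#' @param labels Binary labels (1 = positive).
#' @return The selected threshold in (0, 1).
#' @export
select_threshold <- function(prob, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    warning("degenerate labels; returning threshold 0.5")
    return(0.5)
  }
  s <- sort(unique(prob))
  cand <- unique(pmin(pmax(c((c(s[1] - 1e-6, s) + c(s, s[length(s)] + 1e-6)) / 2,
                             0.5), 1e-9), 1 - 1e-9))
  j <- vapply(cand, function(t) {
    pred <- prob >= t
    tpr <- sum(pred & labels == 1L) / sum(labels == 1L)
    fpr <- sum(pred & labels == 0L) / sum(labels == 0L)
    tpr - fpr
  }, numeric(1))
  best <- which(j >= max(j) - 1e-12)
  cand[best][which.min(abs(cand[best] - 0.5))]
}

roc_points <- function(prob, labels) {
  labels <- as.integer(labels)
  o <- order(prob, decreasing = TRUE)
  p <- prob[o]; y <- labels[o]
  # collapse ties so tied scores move diagonally (concordance ties = 1/2)
  grp <- cumsum(c(TRUE, diff(p) != 0))
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- which(!duplicated(grp, fromLast = TRUE))
  P <- sum(y); N <- sum(1 - y)
  data.frame(threshold = c(Inf, p[last]),
             tpr = c(0, tp[last] / max(P, 1)),
             fpr = c(0, fp[last] / max(N, 1)))
}

trapezoid_auc <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

#' Evaluate binary predictions
#'
#' Thresholds the probabilities, computes the confusion counts and the
#' derived metrics (accuracy, precision, recall, F1), and the AUC by the
#' trapezoidal rule over the full ROC (equal to the pairwise concordance
#' probability with ties counted 1/2). Division-by-zero metrics are reported
#' as 0 and flagged.
#'
#' @param prob Predicted probabilities for the positive class.
#' @param labels Binary labels (1 = AFib).
#' @param threshold Decision threshold.
#' @return An object of class `eval_report`.
#' @export
evaluate <- function(prob, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  if (length(prob) != length(labels)) stop("prob and labels length mismatch")
  pred <- as.integer(prob >= threshold)
  tp <- sum(pred == 1L & labels == 1L); fp <- sum(pred == 1L & labels == 0L)
  tn <- sum(pred == 0L & labels == 0L); fn <- sum(pred == 0L & labels == 1L)
  n <- tp + fp + tn + fn
  degenerate <- character(0)
  div <- function(num, den, what) {
    if (den == 0) { degenerate <<- c(degenerate, what); return(0) }
    num / den
  }
  precision <- div(tp, tp + fp, "precision")
  recall <- div(tp, tp + fn, "recall")
  f1 <- div(2 * precision * recall, precision + recall, "f1")
  roc <- roc_points(prob, labels)
  auc <- if (length(unique(labels)) < 2L) {
    degenerate <- c(degenerate, "auc"); 0
  } else trapezoid_auc(roc)
  structure(list(counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
                 accuracy = div(tp + tn, n, "accuracy"),
                 precision = precision, recall = recall, f1 = f1,
                 auc = auc, roc = roc, threshold = threshold,
                 degenerate = degenerate),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> n=%d  acc %.3f  P %.3f  R %.3f  F1 %.3f  AUC %.3f (thr %.3g)\n",
    sum(x$counts), x$accuracy, x$precision, x$recall, x$f1, x$auc,
    x$threshold))
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", x$counts["TP"],
              x$counts["FP"], x$counts["TN"], x$counts["FN"]))
  if (length(x$degenerate))
    cat("  degenerate:", paste(x$degenerate, collapse = ", "), "\n")
  invisible(x)
}

#' Mann-Whitney U test (normal approximation with tie correction)
#'
#' Rank-based two-sample test. `U` counts the pairs where a value of group A
#' exceeds one of group B, ties counted 1/2 (so `U` lies in `[0, n1*n2]`).
#' The z value uses the normal approximation with the midrank tie correction
#' and a 0.5 continuity correction; the p value is two-sided.
#'
#' @param a,b Numeric samples.
#' @return An object of class `mwu_test`: `U`, `z`, `p`, `n1`, `n2`.
#' @export
mannwhitney_u <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(c(a, b))
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) {
    z <- 0; p <- 1
  } else {
    cc <- sign(u - mu) * 0.5
    z <- (u - mu - cc) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  structure(list(U = u, z = z, p = p, n1 = n1, n2 = n2),
            class = "mwu_test")
}

#' @export
print.mwu_test <- function(x, ...) {
  cat(sprintf("<mwu_test> U = %g (n1 %d, n2 %d), z = %.3f, p = %.3g\n",
              x$U, x$n1, x$n2, x$z, x$p))
  invisible(x)
}

# ---------------------------------------------------------------------------
# classifier wrapper: standardizer + (encoder stage) + classifier stage

new_beat_classifier <- function(family, scaler, encoder = NULL, clf,
                                use_lcsd, threshold = 0.5) {
  structure(list(family = family, scaler = scaler, encoder = encoder,
                 clf = clf, use_lcsd = use_lcsd, threshold = threshold),
            class = "beat_classifier")
}

#' Predict AFib probabilities from a fitted pipeline classifier
#'
#' Applies the stored training standardization, encodes the templates when
#' the model has an encoder stage, and returns classifier-head
#' probabilities.
#'
#' @param object A `beat_classifier` from [crossval_train()].
#' @param x Raw (unstandardized) beat-template matrix.
#' @param lcsd LCSD values (required when the model uses the LCSD feature).
#' @param type `"prob"` or `"class"`.
#' @param ... Unused.
#' @export
predict.beat_classifier <- function(object, x, lcsd = NULL,
                                    type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- as.matrix(x)
  feats <- if (object$use_lcsd) {
    if (is.null(lcsd)) stop("this model uses the LCSD feature; supply `lcsd`")
    cbind(x, lcsd)
  } else x
  z <- apply_standardizer(object$scaler, feats)
  xs <- z[, seq_len(ncol(x)), drop = FALSE]
  extra <- if (object$use_lcsd) z[, ncol(x) + 1L, drop = FALSE]
  if (object$family == "sup_ae") {
    p <- predict(object$clf, xs, extra = extra, type = "prob")
  } else {
    code <- encode(object$encoder, xs)
    p <- predict(object$clf, code, extra = extra, type = "prob")
  }
  if (type == "class") as.integer(p >= object$threshold) else p
}

#' @export
print.beat_classifier <- function(x, ...) {
  cat(sprintf("<beat_classifier> %s%s, threshold %.3g\n", x$family,
              if (x$use_lcsd) " + LCSD" else "", x$threshold))
  invisible(x)
}

#' Cross-validated training with model-instance selection
#'
#' Assigns the (balanced) training beats to `folds` seeded folds; each fold
#' in turn serves as the validation set for early stopping while the rest
#' train the model. The returned instance is the fold run with the lowest
#' validation loss. Standardization (templates and LCSD jointly) is fitted
#' on each fold's training rows only. For `family = "ae"` the pipeline is
#' two-stage (sparse autoencoder then MLP on the code, selection by the
#' classifier's validation loss); `"sup_ae"` trains jointly.
#'
#' @param x Raw beat templates (balanced training set).
#' @param y Binary labels (1 = AFib).
#' @param lcsd LCSD values or NULL (model without the rhythm feature).
#' @param family `"ae"` or `"sup_ae"`.
#' @param folds Number of cross-validation folds (default 10).
#' @param config A [train_config()].
#' @param seed Seed for fold assignment and weight initialisation.
#' @return List: `model` (a `beat_classifier`, threshold set by Youden's J
#'   on its validation fold), `folds` (per-fold validation losses), `best_fold`,
#'   `assignment`.
#' @export
crossval_train <- function(x, y, lcsd = NULL, family = c("sup_ae", "ae"),
                           folds = 10, config = train_config(), seed = 1L) {
  family <- match.arg(family)
  x <- as.matrix(x); y <- as.integer(y)
  n <- nrow(x)
  if (n < folds) stop("fewer samples than folds")
  use_lcsd <- !is.null(lcsd)
  set.seed(as.integer(seed))
  assignment <- sample(rep(seq_len(folds), length.out = n))

  fold_tab <- data.frame(fold = seq_len(folds), val_loss = NA_real_,
                         epochs = NA_integer_)
  best <- NULL
  for (k in seq_len(folds)) {
    tr <- which(assignment != k); va <- which(assignment == k)
    feats <- if (use_lcsd) cbind(x, lcsd) else x
    scaler <- fit_standardizer(feats[tr, , drop = FALSE])
    z_tr <- apply_standardizer(scaler, feats[tr, , drop = FALSE])
    z_va <- apply_standardizer(scaler, feats[va, , drop = FALSE])
    xs_tr <- z_tr[, seq_len(ncol(x)), drop = FALSE]
    xs_va <- z_va[, seq_len(ncol(x)), drop = FALSE]
    ex_tr <- if (use_lcsd) z_tr[, ncol(x) + 1L, drop = FALSE]
    ex_va <- if (use_lcsd) z_va[, ncol(x) + 1L, drop = FALSE]
    fold_seed <- seed + k

    if (family == "sup_ae") {
      fit <- fit_beatnet(xs_tr, y[tr], family = "sup_ae", extra = ex_tr,
                         validation = list(x = xs_va, y = y[va],
                                           extra = ex_va),
                         config = config, seed = fold_seed)
      val_loss <- fit$result$best_val
      model <- new_beat_classifier("sup_ae", scaler, clf = fit,
                                   use_lcsd = use_lcsd)
      val_prob <- predict(fit, xs_va, extra = ex_va, type = "prob")
      epochs <- fit$result$epochs_run
    } else {
      ae <- fit_beatnet(xs_tr, family = "sae",
                        validation = list(x = xs_va),
                        config = config, seed = fold_seed)
      code_tr <- encode(ae, xs_tr); code_va <- encode(ae, xs_va)
      mlp <- fit_beatnet(code_tr, y[tr], family = "mlp", extra = ex_tr,
                         validation = list(x = code_va, y = y[va],
                                           extra = ex_va),
                         config = config, seed = fold_seed + 1000L)
      val_loss <- mlp$result$best_val
      model <- new_beat_classifier("ae", scaler, encoder = ae, clf = mlp,
                                   use_lcsd = use_lcsd)
      val_prob <- predict(mlp, code_va, extra = ex_va, type = "prob")
      epochs <- mlp$result$epochs_run
    }
    fold_tab$val_loss[k] <- val_loss
    fold_tab$epochs[k] <- epochs
    if (is.null(best) || val_loss < best$val_loss)
      best <- list(fold = k, val_loss = val_loss, model = model,
                   val_prob = val_prob, val_y = y[va])
  }
  best$model$threshold <- select_threshold(best$val_prob, best$val_y)
  list(model = best$model, folds = fold_tab, best_fold = best$fold,
       assignment = assignment,
       val_prob = best$val_prob, val_y = best$val_y)
}

#' LCSD-only logistic baseline
#'
#' Trains a single-input logistic model (a bare sigmoid unit from the
#' network core) on the LCSD value alone and evaluates it like any other
#' model; quantifies how much of the class separation rhythm irregularity
#' alone achieves.
#'
#' @param train_lcsd,train_y Training LCSD values and labels.
#' @param test_lcsd,test_y Test LCSD values and labels.
#' @param config A [train_config()].
#' @param seed RNG seed.
#' @return An `eval_report` (with a `degenerate` flag when the training LCSD
#'   is constant).
#' @export
lcsd_baseline <- function(train_lcsd, train_y, test_lcsd, test_y,
                          config = train_config(), seed = 1L) {
  xtr <- matrix(as.numeric(train_lcsd), ncol = 1L)
  scaler <- fit_standardizer(xtr)
  spec <- network_spec(1L, "mlp", head_hidden = 0L)
  fit <- fit_beatnet(apply_standardizer(scaler, xtr), as.integer(train_y),
                     family = "mlp", spec = spec, validation = 0.2,
                     config = config, seed = seed)
  set.seed(as.integer(seed))
  n_val <- max(1L, as.integer(rhalf(0.2 * nrow(xtr))))
  val_idx <- sample.int(nrow(xtr), n_val)
  zs <- apply_standardizer(scaler, xtr)
  thr <- select_threshold(predict(fit, zs[val_idx, , drop = FALSE]),
                          as.integer(train_y)[val_idx])
  p_test <- predict(fit, apply_standardizer(
    scaler, matrix(as.numeric(test_lcsd), ncol = 1L)))
  rep_ <- evaluate(p_test, as.integer(test_y), thr)
  if (stats::sd(train_lcsd) == 0)
    rep_$degenerate <- unique(c(rep_$degenerate, "constant_lcsd"))
  rep_
}

# ---------------------------------------------------------------------------
# pipeline orchestration

#' Default pipeline configuration
#'
#' Fully-resolved configuration for [run_pipeline()]; the returned list is
#' also the reproducibility manifest (re-running [run_pipeline()] on it
#' recreates bit-identical results).
#'
#' @param seed Master seed; every stage seed is derived from it.
#' @param n_per_class,duration,fs,patients,patient_morph_sd Synthetic data
#'   settings (see [generate_dataset()]).
#' @param noise_sd White-noise standard deviation of the generated signals,
#'   mV (baseline wander keeps its default).
#' @param family `"sup_ae"` or `"ae"`.
#' @param use_lcsd Include the LCSD feature in the classifier.
#' @param split_mode `"portion"` or `"patient"`.
#' @param folds Cross-validation folds.
#' @param dmean_threshold Cosine-distance outlier threshold.
#' @param train List of [train_config()] overrides
#'   (e.g. `list(max_epochs = 200)`).
#' @export
pipeline_config <- function(seed = 1L, n_per_class = 8, duration = 30,
                            fs = 250, patients = NULL,
                            patient_morph_sd = 0, noise_sd = 0.02,
                            family = "sup_ae",
                            use_lcsd = TRUE, split_mode = "portion",
                            folds = 10, dmean_threshold = 0.2,
                            train = list()) {
  tc <- do.call(train_config, train)
  list(seed = as.integer(seed), n_per_class = n_per_class,
       duration = duration, fs = fs, patients = patients,
       patient_morph_sd = patient_morph_sd, noise_sd = noise_sd,
       family = family,
       use_lcsd = use_lcsd, split_mode = split_mode, folds = folds,
       dmean_threshold = dmean_threshold, train = unclass(tc))
}

pipeline_seeds <- function(seed) {
  set.seed(as.integer(seed))
  s <- sample.int(2^30, 4L)
  list(data = s[1], split = s[2], balance = s[3], train = s[4])
}

#' Run the full evaluation pipeline on synthetic data
#'
#' Generates a labelled dataset, preprocesses it into beat templates with
#' LCSD values, splits portion- or patient-wise, undersamples the majority
#' class in the training set, trains the requested model family under
#' cross-validation, selects the operating threshold by Youden's J on the
#' validation fold, and evaluates on the untouched test set. Also runs the
#' Mann-Whitney U validation of the LCSD statistic on the training beats.
#'
#' @param config A [pipeline_config()] list (the manifest).
#' @param data Optional pre-built list `list(bm, split)` to share one
#'   dataset/split across several configurations (see [run_grid()]).
#' @return An object of class `af_pipeline`: `eval` (test `eval_report`),
#'   `model`, `cv` (fold table), `mwu` (LCSD Mann-Whitney result on training
#'   beats), `manifest`, and `data_summary`.
#' @export
run_pipeline <- function(config = pipeline_config(), data = NULL) {
  seeds <- pipeline_seeds(config$seed)
  if (is.null(data)) data <- pipeline_data(config)
  bm <- data$bm; split <- data$split
  y <- as.integer(bm$meta$label == "AFib")

  tr_idx <- split$train
  bal <- balance_classes(bm$meta$label[tr_idx], seed = seeds$balance)
  tr_idx <- tr_idx[bal]

  mwu <- mannwhitney_u(bm$meta$lcsd[tr_idx][y[tr_idx] == 1L],
                       bm$meta$lcsd[tr_idx][y[tr_idx] == 0L])

  tc <- do.call(train_config, config$train)
  cv <- crossval_train(bm$x[tr_idx, , drop = FALSE], y[tr_idx],
                       lcsd = if (config$use_lcsd) bm$meta$lcsd[tr_idx],
                       family = config$family, folds = config$folds,
                       config = tc, seed = seeds$train)
  te_idx <- split$test
  p_test <- predict(cv$model, bm$x[te_idx, , drop = FALSE],
                    lcsd = if (config$use_lcsd) bm$meta$lcsd[te_idx])
  eval_rep <- evaluate(p_test, y[te_idx], cv$model$threshold)

  structure(list(
    eval = eval_rep, model = cv$model, cv = cv$folds,
    best_fold = cv$best_fold, mwu = mwu, manifest = config,
    data_summary = list(
      n_beats = nrow(bm$x), n_train = length(tr_idx),
      n_test = length(te_idx),
      train_units = split$train_units, test_units = split$test_units,
      split_mode = split$mode)),
    class = "af_pipeline")
}

# generate + preprocess + split; factored out so a model/feature grid can
# share one dataset and one test set
pipeline_data <- function(config) {
  seeds <- pipeline_seeds(config$seed)
  ds <- generate_dataset(config$n_per_class, duration = config$duration,
                         fs = config$fs, patients = config$patients,
                         patient_morph_sd = config$patient_morph_sd,
                         noise = noise_params(white_sd = config$noise_sd %||% 0.02),
                         seed = seeds$data)
  bm <- preprocess_dataset(ds, dmean_threshold = config$dmean_threshold)
  bm <- drop_undefined_lcsd(bm)
  split <- make_split(bm$meta, mode = config$split_mode, seed = seeds$split)
  list(bm = bm, split = split)
}

#' Run a model/feature grid on one shared dataset and split
#'
#' Evaluates every combination of model family and LCSD usage on the same
#' preprocessed beats and the same test set, mirroring a
#' controlled-comparison results table.
#'
#' @param config Base [pipeline_config()]; `family`/`use_lcsd` are
#'   overridden per cell.
#' @param families Model families to run.
#' @param lcsd_options Logical vector of LCSD-usage settings.
#' @return Named list of `af_pipeline` results
#'   (`"<family>"` / `"<family>+lcsd"`).
#' @export
run_grid <- function(config = pipeline_config(),
                     families = c("ae", "sup_ae"),
                     lcsd_options = c(FALSE, TRUE)) {
  data <- pipeline_data(config)
  out <- list()
  for (fam in families) {
    for (ul in lcsd_options) {
      cfg <- config; cfg$family <- fam; cfg$use_lcsd <- ul
      out[[paste0(fam, if (ul) "+lcsd")]] <- run_pipeline(cfg, data = data)
    }
  }
  out
}

#' @export
print.af_pipeline <- function(x, ...) {
  cat(sprintf("<af_pipeline> %s%s, %s split\n", x$manifest$family,
              if (x$manifest$use_lcsd) " + LCSD" else "",
              x$data_summary$split_mode))
  cat(sprintf("  beats: %d total, %d train (balanced), %d test\n",
              x$data_summary$n_beats, x$data_summary$n_train,
              x$data_summary$n_test))
  cat(sprintf("  LCSD Mann-Whitney: U = %g, p = %.3g\n", x$mwu$U, x$mwu$p))
  print(x$eval)
  invisible(x)
}
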