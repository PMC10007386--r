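# User-facing fitted-model interface around the network core, in the classic
# R modelling idiom: one fitting function returning a classed object with
# print / summary / coef / predict / plot / residuals methods.

#' Fit a beat-classification network
#'
#' Fits one of the four model archetypes to a matrix of (standardized) beat
#' templates. For autoencoder families the model learns a compressed
#' morphological code; the supervised autoencoder additionally trains a
#' classifier head jointly (MSE + binary cross-entropy); the MLP is a plain
#' feed-forward classifier. A validation split for early stopping is carved
#' from the training rows unless an explicit validation set is supplied.
#'
#' @param x Numeric matrix of beat templates (rows = beats).
#' @param y Binary labels (1 = AFib, 0 = NSR); required for supervised
#'   families.
#' @param family `"ae"`, `"sae"`, `"sup_ae"` or `"mlp"`.
#' @param extra Optional side-feature matrix (e.g. the LCSD column) fed to
#'   the classifier head.
#' @param validation Either a fraction in (0, 1) to carve from the training
#'   rows (seeded), or a list `list(x, y, extra)`.
#' @param spec A [network_spec()]; built from `x` and `family` when NULL.
#' @param config A [train_config()].
#' @param seed Seed for weight initialisation and the validation carve-out.
#' @return An object of class `beatnet` with elements `network`, `result`
#'   (loss curves, best epoch, stop reason), `spec`, `family`, `threshold`
#'   (decision threshold, default 0.5 until set by threshold selection).
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200 * 20), 200)
#' fit <- fit_beatnet(x, family = "ae",
#'                    config = train_config(max_epochs = 30, patience = 10,
#'                                          learning_rate = 1e-2))
#' fit
#' @export
fit_beatnet <- function(x, y = NULL, family = c("ae", "sae", "sup_ae", "mlp"),
                        extra = NULL, validation = 0.2, spec = NULL,
                        config = train_config(), seed = 1L) {
  family <- match.arg(family)
  x <- as.matrix(x)
  supervised <- family %in% c("sup_ae", "mlp")
  if (supervised && is.null(y))
    stop("labels `y` are required for family '", family, "'")
  if (!is.null(y) && length(y) != nrow(x))
    stop("length(y) must equal nrow(x)")
  if (is.null(spec))
    spec <- network_spec(ncol(x), family,
                         extra_inputs = if (is.null(extra)) 0L else ncol(as.matrix(extra)))
  if (!is.null(extra)) extra <- as.matrix(extra)

  if (is.list(validation)) {
    tr_idx <- seq_len(nrow(x))
    vx <- as.matrix(validation$x); vy <- validation$y
    vextra <- if (!is.null(validation$extra)) as.matrix(validation$extra)
  } else {
    stopifnot(validation > 0, validation < 1)
    set.seed(as.integer(seed))
    n_val <- max(1L, as.integer(rhalf(validation * nrow(x))))
    val_idx <- sample.int(nrow(x), n_val)
    tr_idx <- setdiff(seq_len(nrow(x)), val_idx)
    vx <- x[val_idx, , drop = FALSE]
    vy <- if (!is.null(y)) y[val_idx]
    vextra <- if (!is.null(extra)) extra[val_idx, , drop = FALSE]
  }

  net <- build_network(spec, seed = seed)
  res <- train_network(net,
                       x[tr_idx, , drop = FALSE],
                       if (!is.null(y)) y[tr_idx],
                       if (!is.null(extra)) extra[tr_idx, , drop = FALSE],
                       vx, vy, vextra, config = config)
  structure(list(network = res$network, result = res, spec = spec,
                 family = family, threshold = 0.5,
                 n_train = length(tr_idx), n_val = nrow(vx),
                 call = match.call()),
            class = "beatnet")
}

#' @export
print.beatnet <- function(x, ...) {
  cat(sprintf("Beat network (%s), %d trainable parameters\n",
              x$family, x$network$n_params))
  cat(sprintf("  trained %d epochs (%s); best validation loss %.6g at epoch %d\n",
              x$result$epochs_run, x$result$stop_reason,
              x$result$best_val, x$result$best_epoch))
  if (!is.null(x$network$head))
    cat(sprintf("  decision threshold: %.4g\n", x$threshold))
  invisible(x)
}

#' @export
summary.beatnet <- function(object, ...) {
  s <- object$spec
  cat(sprintf("Family: %s\n", object$family))
  if (!is.null(object$network$enc))
    cat(sprintf("Architecture: %d -> %d -> %d (code at 25%% of input width)\n",
                s$input_width, s$code_width, s$input_width))
  if (!is.null(object$network$head))
    cat(sprintf("Classifier head: %d (+%d side features) -> %d -> 1 sigmoid\n",
                if (object$family == "mlp") s$input_width else s$code_width,
                s$extra_inputs, s$head_hidden))
  cat(sprintf("Loss weights: w_rec %g, w_cls %g, lambda_sparse %g\n",
              s$w_rec, s$w_cls, s$lambda_sparse))
  cat(sprintf("Trainable parameters: %d\n", object$network$n_params))
  cat(sprintf("Training: %d epochs (%s), best epoch %d, validation loss %.6g\n",
              object$result$epochs_run, object$result$stop_reason,
              object$result$best_epoch, object$result$best_val))
  invisible(object)
}

#' @export
coef.beatnet <- function(object, ...) {
  net <- object$network
  out <- list()
  for (part in c("enc", "dec", "head")) {
    st <- net[[part]]
    if (is.null(st)) next
    for (i in seq_along(st))
      out[[sprintf("%s%d", part, i)]] <- list(W = st[[i]]$W, b = st[[i]]$b)
  }
  out
}

#' Predict from a fitted beat network
#'
#' @param object A `beatnet`.
#' @param newdata Matrix of beat templates.
#' @param extra Side features, if the model uses them.
#' @param type `"prob"` (class probability), `"class"` (0/1 at the model's
#'   threshold), `"code"` (encoded features) or `"reconstruction"`.
#' @param threshold Decision threshold overriding the stored one.
#' @param ... Unused.
#' @export
predict.beatnet <- function(object, newdata, extra = NULL,
                            type = c("prob", "class", "code", "reconstruction"),
                            threshold = NULL, ...) {
  type <- match.arg(type)
  net <- object$network
  if (type %in% c("code", "reconstruction")) {
    # encoder/decoder outputs never need the head's side features
    if (is.null(net$enc)) stop("family '", object$family, "' has no encoder")
    code <- encode(net, newdata)
    if (type == "code") return(code)
    return(forward_stack(net$dec, code)$out)
  }
  fw <- nn_forward(net, newdata, extra)
  if (is.null(fw$prob)) stop("family '", object$family,
                             "' has no classifier head")
  if (type == "prob") return(as.numeric(fw$prob))
  thr <- threshold %||% object$threshold
  as.integer(as.numeric(fw$prob) >= thr)
}

#' @export
residuals.beatnet <- function(object, newdata = NULL, ...) {
  if (is.null(object$network$dec))
    stop("residuals are reconstruction errors; family '", object$family,
         "' has no decoder")
  if (is.null(newdata))
    stop("supply `newdata`: the templates to reconstruct")
  newdata <- as.matrix(newdata)
  newdata - predict(object, newdata, type = "reconstruction")
}

#' Plot training and validation loss curves
#' @param x A `beatnet`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.beatnet <- function(x, ...) {
  cv <- x$result$curves
  graphics::matplot(cv$epoch, cbind(cv$train, cv$val), type = "l", lty = 1,
                    col = c("black", "firebrick"), xlab = "epoch",
                    ylab = "loss", ...)
  graphics::abline(v = x$result$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("black", "firebrick"), bty = "n")
  invisible(x)
}
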