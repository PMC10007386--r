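# Dense feed-forward network core covering four archetypes:
#   "ae"     undercomplete autoencoder            (MSE loss)
#   "sae"    sparse autoencoder                   (MSE + L1 code penalty)
#   "sup_ae" supervised autoencoder               (MSE + BCE joint loss)
#   "mlp"    feed-forward classifier              (BCE loss)
# Implemented directly on base matrix algebra: parameters are a list of
# (W, b) layers, gradients come from hand-derived backpropagation, and
# optimisation is Adam with mini-batches and early stopping on validation
# loss. Everything is seeded and double precision.

ACTIVATIONS <- list(
  linear = list(f = function(z) z, df = function(z, a) 1),
  tanh = list(f = tanh, df = function(z, a) 1 - a^2),
  relu = list(f = function(z) pmax(z, 0), df = function(z, a) (z > 0) * 1),
  sigmoid = list(f = function(z) 1 / (1 + exp(-z)),
                 df = function(z, a) a * (1 - a))
)

init_stack <- function(widths, acts) {
  stopifnot(length(acts) == length(widths) - 1L)
  lapply(seq_along(acts), function(i) {
    fan_in <- widths[i]; fan_out <- widths[i + 1L]
    list(W = matrix(stats::runif(fan_in * fan_out, -1, 1) / sqrt(fan_in),
                    fan_out, fan_in),
         b = numeric(fan_out), act = acts[i])
  })
}

stack_params <- function(stack)
  sum(vapply(stack, function(l) length(l$W) + length(l$b), numeric(1)))

forward_stack <- function(stack, x) {
  cache <- vector("list", length(stack))
  a <- x
  for (i in seq_along(stack)) {
    l <- stack[[i]]
    z <- a %*% t(l$W)
    z <- sweep(z, 2L, l$b, "+")
    a_new <- ACTIVATIONS[[l$act]]$f(z)
    cache[[i]] <- list(input = a, z = z, a = a_new)
    a <- a_new
  }
  list(out = a, cache = cache)
}

# d_out is dL/da of the final layer, unless `d_is_dz` (then dL/dz, used to
# fuse sigmoid + binary cross-entropy stably)
backprop_stack <- function(stack, cache, d_out, d_is_dz = FALSE) {
  grads <- vector("list", length(stack))
  d <- d_out
  for (i in rev(seq_along(stack))) {
    l <- stack[[i]]; c <- cache[[i]]
    dz <- if (i == length(stack) && d_is_dz) d
          else d * ACTIVATIONS[[l$act]]$df(c$z, c$a)
    grads[[i]] <- list(W = t(dz) %*% c$input, b = colSums(dz))
    d <- dz %*% l$W
  }
  list(grads = grads, d_input = d)
}

#' Specify a network architecture
#'
#' Builds the layer plan for one of the four model archetypes. Autoencoder
#' presets use a single code layer at 25% of the input width (75%
#' compression) with a symmetric decoder: layers `input -> code -> input`,
#' tanh code activation and linear output (inputs are standardized, so a
#' linear reconstruction output is natural). The classifier head is
#' `code (+ extra features) -> head_hidden tanh units -> 1 sigmoid unit`;
#' `head_hidden = 0` gives a bare logistic unit.
#'
#' @param input_width Number of input features (template length).
#' @param family `"ae"`, `"sae"`, `"sup_ae"` or `"mlp"`.
#' @param code_width Code layer width; default `round(0.25 * input_width)`
#'   (half away from zero).
#' @param lambda_sparse L1 code penalty weight (>= 0); default 1e-4 for
#'   `"sae"`/`"sup_ae"`, 0 for `"ae"`.
#' @param w_rec,w_cls Reconstruction and classification loss weights.
#' @param extra_inputs Number of side features (e.g. LCSD) appended to the
#'   code before the classifier head.
#' @param head_hidden Hidden units in the classifier head.
#' @param hidden_act Activation of code/hidden layers.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(input_width,
                         family = c("ae", "sae", "sup_ae", "mlp"),
                         code_width = NULL, lambda_sparse = NULL,
                         w_rec = 1, w_cls = 1, extra_inputs = 0,
                         head_hidden = 3, hidden_act = "tanh") {
  family <- match.arg(family)
  stopifnot_scalar(input_width, "input_width", positive = TRUE)
  input_width <- as.integer(input_width)
  if (is.null(code_width)) code_width <- as.integer(rhalf(0.25 * input_width))
  code_width <- as.integer(code_width)
  if (family != "mlp" && code_width < 1) stop("code_width must be >= 1")
  if (is.null(lambda_sparse))
    lambda_sparse <- if (family %in% c("sae", "sup_ae")) 1e-4 else 0
  if (lambda_sparse < 0) stop("lambda_sparse must be >= 0")
  if (!hidden_act %in% names(ACTIVATIONS)) stop("unknown activation")
  structure(list(input_width = input_width, family = family,
                 code_width = code_width, lambda_sparse = lambda_sparse,
                 w_rec = w_rec, w_cls = w_cls,
                 extra_inputs = as.integer(extra_inputs),
                 head_hidden = as.integer(head_hidden),
                 hidden_act = hidden_act),
            class = "network_spec")
}

#' Build a network from a specification
#'
#' Weights are initialised from a seeded uniform distribution scaled by
#' `1/sqrt(fan_in)`; biases start at zero. The trainable-parameter count
#' (`sum(fan_in * fan_out + fan_out)` over layers) is stored on the object.
#'
#' @param spec A [network_spec()].
#' @param seed Integer RNG seed.
#' @return An object of class `beat_network` with elements `enc`, `dec`,
#'   `head` (layer stacks or NULL) and `n_params`.
#' @export
build_network <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  set.seed(as.integer(seed))
  enc <- dec <- head <- NULL
  if (spec$family %in% c("ae", "sae", "sup_ae")) {
    enc <- init_stack(c(spec$input_width, spec$code_width), spec$hidden_act)
    dec <- init_stack(c(spec$code_width, spec$input_width), "linear")
  }
  if (spec$family %in% c("sup_ae", "mlp")) {
    head_in <- if (spec$family == "mlp") spec$input_width + spec$extra_inputs
               else spec$code_width + spec$extra_inputs
    head <- if (spec$head_hidden > 0)
      init_stack(c(head_in, spec$head_hidden, 1L),
                 c(spec$hidden_act, "sigmoid"))
    else init_stack(c(head_in, 1L), "sigmoid")
  }
  n_params <- sum(vapply(Filter(Negate(is.null), list(enc, dec, head)),
                         stack_params, numeric(1)))
  structure(list(spec = spec, enc = enc, dec = dec, head = head,
                 n_params = n_params),
            class = "beat_network")
}

#' @export
print.beat_network <- function(x, ...) {
  cat(sprintf("<beat_network %s> input %d, code %s, %d trainable parameters\n",
              x$spec$family, x$spec$input_width,
              if (is.null(x$enc)) "-" else x$spec$code_width, x$n_params))
  invisible(x)
}

as_input_matrix <- function(x, width) {
  x <- as.matrix(x)
  if (ncol(x) != width)
    stop(sprintf("input has %d columns; network expects %d", ncol(x), width))
  storage.mode(x) <- "double"
  x
}

#' Forward pass
#'
#' @param net A `beat_network`.
#' @param x Input matrix (rows = samples).
#' @param extra Optional matrix of side features fed to the classifier head.
#' @return List with `code`, `recon` and `prob` (NULL where the archetype
#'   has no such output); probabilities lie strictly in (0, 1).
#' @export
nn_forward <- function(net, x, extra = NULL) {
  x <- as_input_matrix(x, net$spec$input_width)
  if (net$spec$extra_inputs > 0) {
    if (is.null(extra)) stop("this network expects `extra` features")
    extra <- as.matrix(extra)
    if (ncol(extra) != net$spec$extra_inputs || nrow(extra) != nrow(x))
      stop("`extra` has the wrong shape")
  }
  code <- recon <- prob <- NULL
  if (!is.null(net$enc)) {
    code <- forward_stack(net$enc, x)$out
    recon <- forward_stack(net$dec, code)$out
  }
  if (!is.null(net$head)) {
    hin <- if (net$spec$family == "mlp") x else code
    if (net$spec$extra_inputs > 0) hin <- cbind(hin, extra)
    prob <- forward_stack(net$head, hin)$out
  }
  list(code = code, recon = recon, prob = prob)
}

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Loss of a network on a batch
#'
#' Total loss `w_rec * MSE + w_cls * BCE + lambda_sparse * mean(|code|)`,
#' with only the terms the archetype owns. MSE averages over all matrix
#' entries, BCE over samples, and the L1 penalty over all code entries.
#'
#' @param net A `beat_network`.
#' @param x Input batch.
#' @param y Binary labels (0/1), required iff a classifier head is present.
#' @param extra Side features for the head.
#' @param target Optional reconstruction target; defaults to `x` (the
#'   autoencoding objective). Supplying a different target turns the
#'   decoder into a plain least-squares regressor, used as a training
#'   oracle.
#' @return List `total`, `mse`, `bce`, `l1` (absent terms are 0).
#' @export
nn_loss <- function(net, x, y = NULL, extra = NULL, target = NULL) {
  fw <- nn_forward(net, x, extra)
  x <- as_input_matrix(x, net$spec$input_width)
  tgt <- if (is.null(target)) x else as.matrix(target)
  mse <- bce <- l1 <- 0
  if (!is.null(fw$recon)) mse <- mean((fw$recon - tgt)^2)
  if (!is.null(net$head)) {
    if (is.null(y)) stop("labels are required for a supervised loss")
    bce <- bce_loss(as.numeric(fw$prob), as.numeric(y))
  }
  if (!is.null(fw$code) && net$spec$lambda_sparse > 0)
    l1 <- mean(abs(fw$code))
  total <- net$spec$w_rec * mse * (!is.null(fw$recon)) +
    net$spec$w_cls * bce * (!is.null(net$head)) +
    net$spec$lambda_sparse * l1
  list(total = total, mse = mse, bce = bce, l1 = l1)
}

#' Analytic gradients by backpropagation
#'
#' @inheritParams nn_loss
#' @return List with per-stack gradient lists (`enc`, `dec`, `head`, each a
#'   list of `W`/`b` gradients) and the loss components.
#' @export
nn_gradients <- function(net, x, y = NULL, extra = NULL, target = NULL) {
  spec <- net$spec
  x <- as_input_matrix(x, spec$input_width)
  tgt <- if (is.null(target)) x else as.matrix(target)
  n <- nrow(x)
  code_cache <- recon_cache <- head_cache <- NULL
  code <- recon <- prob <- NULL
  if (!is.null(net$enc)) {
    ec <- forward_stack(net$enc, x); code <- ec$out; code_cache <- ec$cache
    dc <- forward_stack(net$dec, code); recon <- dc$out; recon_cache <- dc$cache
  }
  if (!is.null(net$head)) {
    if (is.null(y)) stop("labels are required for a supervised loss")
    y <- matrix(as.numeric(y), ncol = 1L)
    hin <- if (spec$family == "mlp") x else code
    if (spec$extra_inputs > 0) hin <- cbind(hin, as.matrix(extra))
    hc <- forward_stack(net$head, hin); prob <- hc$out; head_cache <- hc$cache
  }

  g_enc <- g_dec <- g_head <- NULL
  d_code <- if (!is.null(code)) matrix(0, n, spec$code_width) else NULL
  if (!is.null(recon)) {
    d_recon <- spec$w_rec * 2 * (recon - tgt) / (n * ncol(tgt))
    bp <- backprop_stack(net$dec, recon_cache, d_recon)
    g_dec <- bp$grads
    d_code <- d_code + bp$d_input
  }
  if (!is.null(prob)) {
    dz <- spec$w_cls * (prob - y) / n  # fused sigmoid + BCE gradient
    bp <- backprop_stack(net$head, head_cache, dz, d_is_dz = TRUE)
    g_head <- bp$grads
    if (spec$family != "mlp")
      d_code <- d_code + bp$d_input[, seq_len(spec$code_width), drop = FALSE]
  }
  if (!is.null(code)) {
    if (spec$lambda_sparse > 0)
      d_code <- d_code + spec$lambda_sparse * sign(code) / (n * spec$code_width)
    g_enc <- backprop_stack(net$enc, code_cache, d_code)$grads
  }
  list(enc = g_enc, dec = g_dec, head = g_head)
}

# -- flat parameter access (used by the optimiser and gradient checks) ------

#' Get all trainable parameters as one numeric vector
#' @param net A `beat_network`.
#' @export
nn_get_params <- function(net) {
  unlist(lapply(c(net$enc, net$dec, net$head),
                function(l) c(as.numeric(l$W), l$b)), use.names = FALSE)
}

#' Set all trainable parameters from one numeric vector
#' @param net A `beat_network`.
#' @param v Vector as produced by [nn_get_params()].
#' @export
nn_set_params <- function(net, v) {
  pos <- 0L
  set_stack <- function(stack) {
    for (i in seq_along(stack)) {
      nw <- length(stack[[i]]$W)
      stack[[i]]$W[] <- v[(pos + 1L):(pos + nw)]; pos <<- pos + nw
      nb <- length(stack[[i]]$b)
      stack[[i]]$b <- v[(pos + 1L):(pos + nb)]; pos <<- pos + nb
    }
    stack
  }
  if (!is.null(net$enc)) net$enc <- set_stack(net$enc)
  if (!is.null(net$dec)) net$dec <- set_stack(net$dec)
  if (!is.null(net$head)) net$head <- set_stack(net$head)
  if (pos != length(v)) stop("parameter vector length mismatch")
  net
}

flatten_grads <- function(g) {
  unlist(lapply(c(g$enc, g$dec, g$head),
                function(l) c(as.numeric(l$W), l$b)), use.names = FALSE)
}

#' Training configuration
#'
#' Defaults follow the reference protocol: mini-batches of 32 samples, Adam
#' with initial learning rate 1e-4 (beta1 0.9, beta2 0.999, eps 1e-8), at
#' most 2000 epochs, and early stopping with a 50-epoch patience after no
#' decrease in validation loss.
#'
#' @param batch_size,learning_rate,max_epochs,patience,seed Scalars.
#' @param beta1,beta2,eps Adam moment parameters.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 32, learning_rate = 1e-4,
                         max_epochs = 2000, patience = 50, seed = 1L,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  stopifnot(batch_size >= 1, learning_rate > 0, max_epochs >= 1,
            patience >= 1, patience < max_epochs)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed),
                 beta1 = beta1, beta2 = beta2, eps = eps),
            class = "train_config")
}

#' Train a network with Adam and early stopping
#'
#' Seeded shuffled mini-batches; after each epoch the full training and
#' validation losses are recorded, and the parameters achieving the lowest
#' validation loss are retained. Training stops when the validation loss has
#' not decreased for `patience` epochs, or at the epoch cap.
#'
#' @param net A `beat_network` (freshly built or warm).
#' @param x,y,extra Training inputs, labels (if supervised) and side
#'   features.
#' @param val_x,val_y,val_extra Validation set (disjoint from training).
#' @param config A [train_config()].
#' @return An object of class `train_result`: the best-epoch `network`,
#'   per-epoch `curves` (total and classification losses), `best_epoch`,
#'   `best_val`, `epochs_run`, `stop_reason`.
#' @export
train_network <- function(net, x, y = NULL, extra = NULL,
                          val_x, val_y = NULL, val_extra = NULL,
                          config = train_config(), target = NULL,
                          val_target = NULL) {
  if (!is.null(target)) target <- as.matrix(target)
  if (!is.null(val_target)) val_target <- as.matrix(val_target)
  x <- as_input_matrix(x, net$spec$input_width)
  val_x <- as_input_matrix(val_x, net$spec$input_width)
  n <- nrow(x)
  if (n == 0L || nrow(val_x) == 0L)
    stop("training and validation sets must be non-empty")

  theta <- nn_get_params(net)
  m <- v <- numeric(length(theta))
  tstep <- 0L
  best_val <- Inf; best_theta <- theta; best_epoch <- 0L
  since_best <- 0L
  curves <- vector("list", config$max_epochs)
  set.seed(config$seed)
  epoch <- 0L; stop_reason <- "max_epochs"

  while (epoch < config$max_epochs) {
    epoch <- epoch + 1L
    perm <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    for (s in starts) {
      idx <- perm[s:min(s + config$batch_size - 1L, n)]
      g <- nn_gradients(net,
                        x[idx, , drop = FALSE],
                        if (!is.null(y)) y[idx],
                        if (!is.null(extra)) extra[idx, , drop = FALSE],
                        if (!is.null(target)) target[idx, , drop = FALSE])
      gv <- flatten_grads(g)
      tstep <- tstep + 1L
      m <- config$beta1 * m + (1 - config$beta1) * gv
      v <- config$beta2 * v + (1 - config$beta2) * gv^2
      mhat <- m / (1 - config$beta1^tstep)
      vhat <- v / (1 - config$beta2^tstep)
      theta <- theta - config$learning_rate * mhat / (sqrt(vhat) + config$eps)
      net <- nn_set_params(net, theta)
    }
    tr <- nn_loss(net, x, y, extra, target)
    vl <- nn_loss(net, val_x, val_y, val_extra, val_target)
    curves[[epoch]] <- data.frame(epoch = epoch, train = tr$total,
                                  val = vl$total, train_bce = tr$bce,
                                  val_bce = vl$bce)
    if (vl$total < best_val) {
      best_val <- vl$total; best_theta <- theta; best_epoch <- epoch
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= config$patience) { stop_reason <- "early_stopping"; break }
    }
  }
  structure(list(network = nn_set_params(net, best_theta),
                 curves = do.call(rbind, curves[seq_len(epoch)]),
                 best_epoch = best_epoch, best_val = best_val,
                 epochs_run = epoch, stop_reason = stop_reason,
                 config = config),
            class = "train_result")
}

#' @export
print.train_result <- function(x, ...) {
  cat(sprintf(
    "<train_result> %d epochs (%s); best validation loss %.6g at epoch %d\n",
    x$epochs_run, x$stop_reason, x$best_val, x$best_epoch))
  invisible(x)
}

#' Encode inputs into code vectors
#' @param object A `beat_network` or `beatnet` with an encoder.
#' @param x Input matrix.
#' @param ... Unused.
#' @return Matrix of code vectors (columns = code width).
#' @export
encode <- function(object, x, ...) UseMethod("encode")

#' @export
encode.beat_network <- function(object, x, ...) {
  if (is.null(object$enc)) stop("this network has no encoder")
  forward_stack(object$enc, as_input_matrix(x, object$spec$input_width))$out
}

#' @export
encode.beatnet <- function(object, x, ...) encode(object$network, x, ...)
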