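# Shared fixtures and oracles, all built in code at test time.

# noiseless, wander-free generator settings for exact-arithmetic tests
quiet_noise <- function() noise_params(white_sd = 0, wander_amplitude = 0,
                                       wander_freq = 0.25)

# small standardized synthetic beat benchmark for network tests
beat_benchmark <- function(n_records = 4, duration = 20, fs = 250, seed = 42) {
  ds <- generate_dataset(n_records, duration = duration, fs = fs, seed = seed)
  bm <- suppressMessages(preprocess_dataset(ds))
  bm <- suppressMessages(drop_undefined_lcsd(bm))
  sc <- fit_standardizer(bm$x)
  list(x = apply_standardizer(sc, bm$x),
       y = as.integer(bm$meta$label == "AFib"),
       lcsd = bm$meta$lcsd, meta = bm$meta)
}

# central-difference numeric gradient of the total loss
numeric_gradient <- function(net, x, y = NULL, extra = NULL, target = NULL,
                             h = 1e-5) {
  theta <- nn_get_params(net)
  vapply(seq_along(theta), function(i) {
    tp <- theta; tp[i] <- tp[i] + h
    lp <- nn_loss(nn_set_params(net, tp), x, y, extra, target)$total
    tm <- theta; tm[i] <- tm[i] - h
    lm <- nn_loss(nn_set_params(net, tm), x, y, extra, target)$total
    (lp - lm) / (2 * h)
  }, numeric(1))
}

max_rel_grad_err <- function(net, x, y = NULL, extra = NULL, target = NULL) {
  g <- beatae:::flatten_grads(nn_gradients(net, x, y, extra, target))
  num <- numeric_gradient(net, x, y, extra, target)
  max(abs(g - num) / pmax(abs(num), 1e-6))
}

# literal transcription of the LCSD definition, kept independent of
# compute_lcsd(): numerator loops over beats, denominator is the plain mean
# RR-interval of the series
lcsd_bruteforce <- function(r) {
  n <- length(r)
  out <- rep(NA_real_, n)
  if (n < 3) return(out)
  denom <- 0
  for (j in 1:(n - 1)) denom <- denom + (r[j + 1] - r[j])
  denom <- denom / (n - 1)
  for (i in 2:(n - 1)) {
    out[i] <- abs((r[i + 1] - r[i]) - (r[i] - r[i - 1])) / denom
  }
  out
}

# pairwise-counting Mann-Whitney U (ties counted 1/2)
mwu_bruteforce <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

# concordance-probability AUC (ties counted 1/2)
auc_bruteforce <- function(prob, labels) {
  pos <- prob[labels == 1]; neg <- prob[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# cosine distance of each row to the column mean, independent of the package
cosdist_bruteforce <- function(m) {
  mu <- colMeans(m)
  apply(m, 1, function(v) 1 - sum(v * mu) / (sqrt(sum(v^2)) * sqrt(sum(mu^2))))
}

scaled_config <- function(seed = 1L, max_epochs = 150, patience = 25,
                          learning_rate = 1e-4)
  train_config(max_epochs = max_epochs, patience = patience,
               learning_rate = learning_rate, seed = seed)
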