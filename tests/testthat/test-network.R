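test_that("autoencoder presets compress to 25% and count parameters exactly", {
  expect_equal(network_spec(150, "ae")$code_width, 38L)  # round(0.25 * 150)
  expect_equal(network_spec(180, "ae")$code_width, 45L)

  # 4 -> 2 -> 4 linear AE: (4*2+2) + (2*4+4) = 22
  net <- build_network(network_spec(4, "ae", code_width = 2,
                                    hidden_act = "linear"), seed = 1)
  expect_equal(net$n_params, 22)

  # MLP head: (in*h + h) + (h*1 + 1)
  m <- build_network(network_spec(38, "mlp", extra_inputs = 1,
                                  head_hidden = 3), seed = 1)
  expect_equal(m$n_params, (39 * 3 + 3) + (3 + 1))
})

test_that("forward pass honours identity, zero weights and determinism", {
  # identity-configured linear 2->2->2 AE reproduces its input
  net <- build_network(network_spec(2, "ae", code_width = 2,
                                    hidden_act = "linear"), seed = 1)
  net <- nn_set_params(net, c(1, 0, 0, 1, 0, 0, 1, 0, 0, 1, 0, 0))
  x <- matrix(rnorm(10), 5)
  expect_equal(nn_forward(net, x)$recon, x)

  # zero-weight sigmoid head answers 0.5
  m <- build_network(network_spec(4, "mlp", head_hidden = 0), seed = 1)
  m <- nn_set_params(m, numeric(length(nn_get_params(m))))
  expect_equal(as.numeric(nn_forward(m, matrix(rnorm(12), 3))$prob),
               rep(0.5, 3))

  # seeded reproducibility of the forward map
  a <- build_network(network_spec(10, "sup_ae"), seed = 7)
  b <- build_network(network_spec(10, "sup_ae"), seed = 7)
  xb <- matrix(rnorm(30), 3)
  expect_identical(nn_forward(a, xb)$recon, nn_forward(b, xb)$recon)

  expect_error(nn_forward(a, matrix(0, 2, 4)), "expects")
})

test_that("loss components match closed forms and a brute-force MSE oracle", {
  # balanced labels at probability 0.5: BCE = ln 2
  m <- build_network(network_spec(4, "mlp", head_hidden = 0), seed = 1)
  m <- nn_set_params(m, numeric(length(nn_get_params(m))))
  l <- nn_loss(m, matrix(rnorm(40), 10), y = rep(c(0, 1), 5))
  expect_equal(l$bce, log(2), tolerance = 1e-12)

  # perfect reconstruction: total loss reduces to the L1 code penalty
  net <- build_network(network_spec(2, "sae", code_width = 2,
                                    hidden_act = "linear",
                                    lambda_sparse = 0.1), seed = 1)
  net <- nn_set_params(net, c(1, 0, 0, 1, 0, 0, 1, 0, 0, 1, 0, 0))
  x <- matrix(rnorm(10), 5)
  l2 <- nn_loss(net, x)
  expect_equal(l2$mse, 0, tolerance = 1e-25)
  expect_equal(l2$total, 0.1 * mean(abs(x)), tolerance = 1e-12)

  # plain AE loss equals the brute-force mean of squared residuals
  ae <- build_network(network_spec(6, "ae"), seed = 3)
  xa <- matrix(rnorm(42), 7)
  recon <- nn_forward(ae, xa)$recon
  expect_equal(nn_loss(ae, xa)$total, mean((recon - xa)^2),
               tolerance = 1e-14)
})

test_that("analytic gradients match central differences for all presets", {
  set.seed(20)
  x <- matrix(rnorm(48), 8)
  y <- rep(c(0, 1), 4)
  ex <- matrix(rnorm(8), 8)
  nets <- list(
    ae = list(net = build_network(network_spec(6, "ae", code_width = 3),
                                  seed = 2), y = NULL, ex = NULL),
    sae = list(net = build_network(network_spec(6, "sae", code_width = 3,
                                                lambda_sparse = 0.05),
                                   seed = 3), y = NULL, ex = NULL),
    sup_ae = list(net = build_network(network_spec(6, "sup_ae",
                                                   code_width = 3,
                                                   lambda_sparse = 0.05,
                                                   extra_inputs = 1),
                                      seed = 4), y = y, ex = ex),
    mlp = list(net = build_network(network_spec(6, "mlp", extra_inputs = 1),
                                   seed = 5), y = y, ex = ex))
  for (nm in names(nets)) {
    cfg <- nets[[nm]]
    err <- max_rel_grad_err(cfg$net, x, cfg$y, cfg$ex)
    expect_lt(err, 1e-4)
  }
  # zero input, zero targets, zero penalty: first-layer weight gradient is 0
  z <- build_network(network_spec(4, "ae", code_width = 2,
                                  lambda_sparse = 0), seed = 6)
  g <- nn_gradients(z, matrix(0, 3, 4))
  expect_equal(g$enc[[1]]$W, matrix(0, 2, 4), ignore_attr = TRUE)
})

test_that("a degenerate linear net trained on noiseless data recovers slope and intercept", {
  set.seed(30)
  x <- matrix(runif(80, -1, 1), ncol = 1)
  slope <- 1.7; intercept <- -0.4
  ytgt <- slope * x + intercept
  net <- build_network(network_spec(1, "ae", code_width = 1,
                                    hidden_act = "linear"), seed = 8)
  res <- train_network(net, x, target = ytgt,
                       val_x = x[1:20, , drop = FALSE],
                       val_target = ytgt[1:20, , drop = FALSE],
                       config = train_config(max_epochs = 2000, patience = 200,
                                             learning_rate = 0.02, seed = 1))
  fit <- nn_forward(res$network, matrix(c(0, 1), 2))$recon
  expect_equal(fit[1], intercept, tolerance = 1e-3)
  expect_equal(fit[2] - fit[1], slope, tolerance = 1e-3)
})

test_that("early stopping halts patience epochs after the last improvement", {
  bb <- beat_benchmark()
  net <- build_network(network_spec(ncol(bb$x), "ae"), seed = 1)
  res <- train_network(net, bb$x[1:100, ], val_x = bb$x[101:140, ],
                       config = train_config(max_epochs = 500, patience = 10,
                                             learning_rate = 1e-3, seed = 2))
  if (res$stop_reason == "early_stopping") {
    expect_equal(res$epochs_run, res$best_epoch + 10L)
  }
  expect_equal(res$best_val, min(res$curves$val))
  expect_equal(res$curves$val[res$best_epoch], res$best_val)

  # identical seeds give identical loss curves
  net2 <- build_network(network_spec(ncol(bb$x), "ae"), seed = 1)
  res2 <- train_network(net2, bb$x[1:100, ], val_x = bb$x[101:140, ],
                        config = train_config(max_epochs = 500, patience = 10,
                                              learning_rate = 1e-3, seed = 2))
  expect_identical(res$curves, res2$curves)
  expect_error(train_network(net, bb$x[0, , drop = FALSE], val_x = bb$x),
               "non-empty")
})

test_that("supervised AE with zero classification weight reduces to the plain AE loss", {
  x <- matrix(rnorm(60), 10)
  ae <- build_network(network_spec(6, "ae", code_width = 3), seed = 11)
  sup <- build_network(network_spec(6, "sup_ae", code_width = 3,
                                    lambda_sparse = 0, w_cls = 0), seed = 11)
  # encoder/decoder draws precede the head draw, so weights coincide
  expect_identical(sup$enc, ae$enc)
  expect_identical(sup$dec, ae$dec)
  expect_equal(nn_loss(sup, x, y = rep(0:1, 5))$total, nn_loss(ae, x)$total,
               tolerance = 1e-15)
})

test_that("the L1 penalty drives code activations toward zero", {
  bb <- beat_benchmark()
  idx <- seq_len(min(150, nrow(bb$x)))
  x <- bb$x[idx, ]
  cfg <- train_config(max_epochs = 120, patience = 120 - 1,
                      learning_rate = 1e-2, seed = 3)
  frac_small <- function(lambda) {
    net <- build_network(network_spec(ncol(x), "sae", lambda_sparse = lambda),
                         seed = 4)
    res <- train_network(net, x[1:100, ], val_x = x[101:150, ], config = cfg)
    code <- encode(res$network, x)
    mean(abs(code) < 1e-3)
  }
  expect_gt(frac_small(0.05), frac_small(0))
})

test_that("an undercomplete AE reconstructs far better than the mean template", {
  bb <- beat_benchmark()
  idx <- seq_len(min(200, nrow(bb$x)))
  x <- bb$x[idx, ]
  fit <- fit_beatnet(x, family = "ae",
                     config = train_config(max_epochs = 200, patience = 50,
                                           learning_rate = 1e-2, seed = 5),
                     seed = 5)
  mse_ae <- mean(residuals(fit, x)^2)
  mu <- colMeans(x)
  mse_mean <- mean(sweep(x, 2, mu)^2)
  expect_lt(mse_ae, 0.5 * mse_mean)
})

test_that("the fitted-model interface exposes the usual methods", {
  bb <- beat_benchmark()
  idx <- seq_len(min(160, nrow(bb$x)))
  fit <- fit_beatnet(bb$x[idx, ], bb$y[idx], family = "sup_ae",
                     extra = matrix(bb$lcsd[idx], ncol = 1),
                     config = scaled_config(max_epochs = 60, patience = 20,
                                            learning_rate = 1e-3),
                     seed = 6)
  expect_s3_class(fit, "beatnet")
  expect_output(print(fit), "sup_ae")
  expect_output(summary(fit), "Trainable parameters")
  cf <- coef(fit)
  expect_true(all(c("enc1", "dec1", "head1") %in% names(cf)))
  p <- predict(fit, bb$x[idx, ], extra = matrix(bb$lcsd[idx], ncol = 1))
  expect_true(all(p > 0 & p < 1))
  cl <- predict(fit, bb$x[idx, ], extra = matrix(bb$lcsd[idx], ncol = 1),
                type = "class")
  expect_true(all(cl %in% 0:1))
  code <- predict(fit, bb$x[idx, ], extra = matrix(bb$lcsd[idx], ncol = 1),
                  type = "code")
  expect_equal(ncol(code), fit$spec$code_width)
  r <- residuals(fit, bb$x[idx, ])
  expect_equal(dim(r), dim(bb$x[idx, ]))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
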