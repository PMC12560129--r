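# Loss algebra (EMA normalization, weighted cross-entropy, class weights)
# and the jointly trained autoencoder-classifier.

test_that("EMA update reproduces the recurrence and its fixed point", {
  st <- ema_state(alpha = 0.9)
  st <- ema_update(st, 1.0, 1.0)          # first update initializes
  expect_equal(st$ema_recon, 1.0)
  st2 <- ema_update(st, 2.0, 3.0)
  expect_equal(st2$ema_recon, 0.9 * 1.0 + 0.1 * 2.0)   # = 1.1
  expect_equal(st2$ema_classifier, 0.9 * 1.0 + 0.1 * 3.0)

  # constant loss stream: the average converges to the constant
  st <- ema_state(0.9); st <- ema_update(st, 5, 5)
  for (i in 1:200) st <- ema_update(st, 2, 2)
  expect_equal(st$ema_recon, 2, tolerance = 1e-8)

  # 50-step trajectory equals a brute-force loop oracle
  set.seed(31)
  lr <- runif(50, 0.1, 2); lc <- runif(50, 0.1, 2)
  st <- ema_state(0.9)
  oracle_r <- oracle_c <- NA
  for (t in 1:50) {
    st <- ema_update(st, lr[t], lc[t])
    if (t == 1) { oracle_r <- lr[1]; oracle_c <- lc[1] }
    else {
      oracle_r <- 0.9 * oracle_r + 0.1 * lr[t]
      oracle_c <- 0.9 * oracle_c + 0.1 * lc[t]
    }
  }
  expect_equal(st$ema_recon, oracle_r, tolerance = 1e-12)
  expect_equal(st$ema_classifier, oracle_c, tolerance = 1e-12)
  expect_error(ema_update(st, -1, 1), "losses")
})

test_that("combined loss normalizes each term by its moving average", {
  st <- ema_update(ema_state(0.9), 0.4, 1.7)
  # at the normalization fixed point both terms contribute beta each
  expect_equal(combined_loss(0.4, 1.7, st), 1.0)
  # degenerate weight: reduces to the single normalized term
  expect_equal(combined_loss(0.8, 99, st, loss_weights(0.5, 0)), 0.5 * 0.8 / 0.4)
  # arbitrary positive inputs: direct arithmetic oracle
  expect_equal(combined_loss(0.66, 2.5, st, loss_weights(0.3, 0.7)),
               0.3 * 0.66 / 0.4 + 0.7 * 2.5 / 1.7, tolerance = 1e-12)
  expect_error(combined_loss(1, 1, ema_state(0.9)), "initialized")
})

test_that("reconstruction loss is the elementwise mean squared error", {
  x <- array(0, c(4, 4, 3, 2)); xh <- array(1, c(4, 4, 3, 2))
  expect_equal(reconstruction_loss(x, x), 0)
  expect_equal(reconstruction_loss(x, xh), 1.0)
  set.seed(32)
  a <- array(runif(96), c(4, 4, 3, 2)); b <- array(runif(96), c(4, 4, 3, 2))
  brute <- 0
  for (i in seq_along(a)) brute <- brute + (a[i] - b[i])^2
  expect_equal(reconstruction_loss(a, b), brute / length(a), tolerance = 1e-12)
  expect_error(reconstruction_loss(a, array(0, c(4, 4, 3, 3))), "mismatch")
})

test_that("weighted cross-entropy matches its closed forms and loop oracle", {
  # probability ~1 on the true class
  logits <- matrix(c(100, 0, 0), 1, 3)
  expect_equal(classification_loss(logits, 1L), 0, tolerance = 1e-10)
  # uniform logits over k classes: ln(k)
  for (k in c(2, 6, 12))
    expect_equal(classification_loss(matrix(0, 5, k), rep(1L, 5)), log(k))
  # weighted value equals a naive per-sample loop
  set.seed(33)
  lg <- matrix(rnorm(8 * 4), 8, 4)
  y <- sample.int(4, 8, replace = TRUE)
  w <- c(0.5, 1.5, 0.8, 1.2)
  brute <- 0
  for (i in 1:8) {
    p <- exp(lg[i, ]) / sum(exp(lg[i, ]))
    brute <- brute + w[y[i]] * (-log(p[y[i]]))
  }
  expect_equal(classification_loss(lg, y, w), brute / 8, tolerance = 1e-12)
  expect_error(classification_loss(lg, c(y[-1], 9L), w), "label")
})

test_that("class weights are inverse-frequency, normalized to mean one", {
  expect_equal(unname(compute_class_weights(rep(c("a", "b"), c(100, 100)))),
               c(1, 1))
  w <- compute_class_weights(rep(c("a", "b"), c(100, 50)))
  expect_equal(unname(w), c(2 / 3, 4 / 3), tolerance = 1e-12)  # prop. to 1:2
  expect_equal(mean(w), 1)
  # permuting class order permutes weights identically
  w2 <- compute_class_weights(factor(rep(c("b", "a"), c(50, 100)),
                                     levels = c("b", "a")))
  expect_equal(unname(w2[c("a", "b")]), unname(w[c("a", "b")]))
})

test_that("joint training is reproducible and learns to reconstruct", {
  crops <- generate_crops(30, binary_conditions(3), crop_size = 24, seed = 61)
  labels <- label_scheme("binary_pfas")$map(crops$info)
  cfg <- training_config(epochs = 5, batch_size = 30, seed = 77)
  m1 <- train_joint(crops, labels, small_espec(), config = cfg)
  m2 <- train_joint(crops, labels, small_espec(), config = cfg)
  expect_identical(m1$history, m2$history)          # determinism
  expect_true(all(is.finite(as.matrix(m1$history[1:3]))))
  expect_lt(m1$history$L_recon[5], m1$history$L_recon[1])  # curve decreases

  # shapes and evaluation-mode determinism of the three heads
  z <- encode(m1, crops)
  expect_equal(dim(z), c(60, 32))
  expect_identical(z, encode(m1, crops))
  expect_true(all(is.finite(z)) && all(rowSums(abs(z)) > 0))
  xh <- decode(m1, z)
  expect_equal(dim(xh), dim(crops$images))
  expect_error(decode(m1, z[, 1:10]), "latent width")

  expect_error(train_joint(crops, factor(rep("one", 60)),
                           small_espec(), config = cfg), "2 classes")
})

test_that("checkpoints restore bit-identical evaluation forwards", {
  m <- tiny_model()
  crops <- generate_crops(4, binary_conditions(3), crop_size = 24, seed = 43)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(encode(m, crops), encode(m2, crops))
  expect_identical(predict_classes(m, crops), predict_classes(m2, crops))
  unlink(path)
})

test_that("EMA state scales each branch gradient without redirecting it", {
  set.seed(34)
  es <- small_espec(latent = 32, input = 16)
  enc <- lcdrops:::build_encoder_layers(es)
  dec <- lcdrops:::build_decoder_layers(es)
  X <- array(runif(16 * 16 * 3 * 3), c(16, 16, 3, 3))
  branch_grad <- function(er) {
    fe <- lcdrops:::net_forward(enc, X, train = TRUE)
    fd <- lcdrops:::net_forward(dec, fe$out, train = TRUE)
    bd <- lcdrops:::net_backward(dec, fd$caches,
                                 (0.5 / er) * 2 * (fd$out - X) / length(X))
    be <- lcdrops:::net_backward(enc, fe$caches, bd$dX)
    as.vector(be$grads[[1]]$W)
  }
  g1 <- branch_grad(0.2); g2 <- branch_grad(0.8)
  expect_equal(g2 * 4, g1, tolerance = 1e-10)   # pure rescaling by ema ratio
  cosine <- sum(g1 * g2) / sqrt(sum(g1^2) * sum(g2^2))
  expect_equal(cosine, 1, tolerance = 1e-12)
})

test_that("both normalized loss terms hover near one in a stationary run", {
  # a stationary loss stream realizes the EMA fixed point: unstructured
  # noise inputs (reconstruction plateaus at the noise floor) with
  # arbitrary labels and a small head (cross-entropy plateaus near ln 2)
  set.seed(62)
  n <- 500
  crops <- crop_set(array(runif(16 * 16 * 3 * n), c(16, 16, 3, n)),
                    data.frame(droplet_id = sprintf("n%04d", 1:n)))
  labels <- factor(rep(c("a", "b"), n / 2))
  m <- train_joint(crops, labels, small_espec(latent = 32, input = 16),
                   cspec = classifier_spec(2, hidden_sizes = c(32, 16)),
                   config = training_config(epochs = 25, batch_size = 250,
                                            seed = 3))
  h <- m$history
  # reconstruct the EMA trajectory the run used (per-epoch updates)
  st <- ema_state(0.9)
  ratios_r <- ratios_c <- numeric(nrow(h))
  for (t in seq_len(nrow(h))) {
    if (t == 1) st <- ema_update(st, h$L_recon[1], h$L_classifier[1])
    ratios_r[t] <- h$L_recon[t] / st$ema_recon
    ratios_c[t] <- h$L_classifier[t] / st$ema_classifier
    st <- ema_update(st, h$L_recon[t], h$L_classifier[t])
  }
  last <- (nrow(h) - 9):nrow(h)
  expect_lt(abs(mean(ratios_r[last]) - 1), 0.2)
  expect_lt(abs(mean(ratios_c[last]) - 1), 0.2)
})

test_that("reconstruction error is non-increasing over the latent grid", {
  # trend over 3 seeded runs per latent width (32, 64, 128)
  crops <- generate_crops(25, binary_conditions(3), crop_size = 24, seed = 63)
  labels <- label_scheme("binary_pfas")$map(crops$info)
  err <- vapply(c(32, 64, 128), function(ld) {
    mean(vapply(1:3, function(sd) {
      m <- train_joint(crops, labels,
                       encoder_spec(ld, c(6, 8, 12), input_size = 24),
                       config = training_config(epochs = 8, batch_size = 50,
                                                seed = sd))
      reconstruction_loss(crops$images, decode(m, encode(m, crops)))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(err) <= 0))
})

test_that("reconstructions preserve the droplets' radial ring structure", {
  crops <- generate_crops(40, binary_conditions(0)[1, , drop = FALSE],
                          crop_size = 24, seed = 64)
  labels <- factor(rep(c("a", "b"), 20))   # arbitrary labels; recon matters
  m <- train_joint(crops, labels, encoder_spec(128, c(8, 12, 16), input_size = 24),
                   config = training_config(epochs = 150, batch_size = 40, seed = 5))
  xh <- decode(m, encode(m, crops))
  radial_profile <- function(img) {
    g <- rowMeans(img, dims = 2)
    n <- nrow(g); ctr <- (n + 1) / 2
    r <- sqrt((row(g) - ctr)^2 + (col(g) - ctr)^2)
    vapply(0:10, function(k) mean(g[r >= k & r < k + 1]), numeric(1))
  }
  cors <- vapply(seq_len(10), function(i)
    cor(radial_profile(crops$images[, , , i]), radial_profile(xh[, , , i])),
    numeric(1))
  expect_gt(mean(cors), 0.8)
})
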