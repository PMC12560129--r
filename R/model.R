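#' Encoder architecture specification
#'
#' Three convolutional stages, each 3x3 convolution -> 2x2 average pooling
#' -> batch normalization -> ReLU, followed by a linear map from the final
#' feature map to the latent vector.
#'
#' @param latent_dim latent width; the documented grid is 32, 64 or 128.
#' @param channel_widths integer vector of three per-stage channel counts.
#' @param input_size input crop side in pixels (multiple of 8).
#' @return A list of class `encoder_spec`.
#' @export
encoder_spec <- function(latent_dim = 128, channel_widths = c(16, 32, 64),
                         input_size = 64) {
  if (!latent_dim %in% c(32, 64, 128))
    stopf("latent_dim must be one of 32, 64, 128 (the documented grid)")
  if (length(channel_widths) != 3) stopf("exactly 3 conv stages")
  if (input_size %% 8 != 0) stopf("input_size must be a multiple of 8")
  structure(list(latent_dim = latent_dim, channel_widths = channel_widths,
                 input_size = input_size), class = "encoder_spec")
}

#' Classifier-head architecture specification
#'
#' Fully connected head on the latent vector: two hidden ReLU layers with a
#' dropout layer before the output logits.
#'
#' @param n_classes number of output classes (>= 2).
#' @param hidden_sizes two hidden-layer widths.
#' @param dropout_rate dropout probability in `[0, 1)`.
#' @return A list of class `classifier_spec`.
#' @export
classifier_spec <- function(n_classes, hidden_sizes = c(256, 128),
                            dropout_rate = 0.2) {
  if (n_classes < 2) stopf("n_classes must be >= 2")
  if (dropout_rate < 0 || dropout_rate >= 1) stopf("dropout_rate must be in [0, 1)")
  structure(list(n_classes = n_classes, hidden_sizes = hidden_sizes,
                 dropout_rate = dropout_rate), class = "classifier_spec")
}

#' Joint-training configuration
#'
#' @param learning_rate Adam learning rate.
#' @param epochs training epochs per fit.
#' @param batch_size minibatch size.
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout.
#' @param class_weighting apply inverse-frequency class weights to the
#'   classification loss.
#' @return A list of class `training_config`.
#' @export
training_config <- function(learning_rate = 0.001, epochs = 50,
                            batch_size = 200, seed = 1L,
                            class_weighting = TRUE) {
  if (epochs < 1) stopf("epochs must be >= 1")
  if (batch_size < 1) stopf("batch_size must be >= 1")
  structure(list(learning_rate = learning_rate, epochs = epochs,
                 batch_size = batch_size, seed = as.integer(seed),
                 class_weighting = class_weighting), class = "training_config")
}

#' Mixing weights of the combined loss
#' @param beta_recon,beta_classifier non-negative weights of the normalized
#'   reconstruction and classification terms (both 0.5 by default).
#' @return A list of class `loss_weights`.
#' @export
loss_weights <- function(beta_recon = 0.5, beta_classifier = 0.5) {
  if (beta_recon < 0 || beta_classifier < 0) stopf("weights must be >= 0")
  structure(list(beta_recon = beta_recon, beta_classifier = beta_classifier),
            class = "loss_weights")
}

#' Running loss-normalization state
#'
#' Holds the exponential moving averages of the reconstruction and
#' classification losses used to normalize the combined loss, with
#' smoothing parameter `alpha` (0.9: most weight on the previous average).
#'
#' @param alpha smoothing parameter in `(0, 1)`.
#' @return A list of class `ema_state`.
#' @export
ema_state <- function(alpha = 0.9) {
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  structure(list(ema_recon = NA_real_, ema_classifier = NA_real_,
                 alpha = alpha, initialized = FALSE), class = "ema_state")
}

#' Update the loss moving averages
#'
#' Applies the per-epoch recurrences
#' `Lbar(t) = alpha * Lbar(t-1) + (1 - alpha) * L(t)` to both loss
#' averages. The first update initializes the averages to the observed
#' losses.
#'
#' @param state an [ema_state()].
#' @param l_recon,l_classifier observed (non-negative) epoch losses.
#' @return The updated `ema_state`.
#' @export
ema_update <- function(state, l_recon, l_classifier) {
  stopifnot(inherits(state, "ema_state"))
  if (l_recon < 0 || l_classifier < 0) stopf("losses must be >= 0")
  if (!state$initialized) {
    state$ema_recon <- l_recon
    state$ema_classifier <- l_classifier
    state$initialized <- TRUE
  } else {
    a <- state$alpha
    state$ema_recon <- a * state$ema_recon + (1 - a) * l_recon
    state$ema_classifier <- a * state$ema_classifier + (1 - a) * l_classifier
  }
  state
}

#' Dynamically normalized combined loss
#'
#' `L_total = beta_recon * L_recon / Lbar_recon +
#'  beta_classifier * L_classifier / Lbar_classifier`, where the averages
#' are treated as constants (no gradient flows through them). Averages are
#' floored at 1e-8 to guard near-zero reconstruction losses.
#'
#' @param l_recon,l_classifier current raw losses.
#' @param state an initialized [ema_state()].
#' @param weights a [loss_weights()].
#' @return Scalar `L_total`.
#' @export
combined_loss <- function(l_recon, l_classifier, state,
                          weights = loss_weights()) {
  if (!inherits(state, "ema_state") || !state$initialized)
    stopf("EMA state must be initialized before computing the combined loss")
  weights$beta_recon * l_recon / max(state$ema_recon, 1e-8) +
    weights$beta_classifier * l_classifier / max(state$ema_classifier, 1e-8)
}

#' Mean-squared reconstruction loss
#' @param x,x_hat arrays of identical shape.
#' @return Mean of squared differences over all pixels and channels.
#' @export
reconstruction_loss <- function(x, x_hat) {
  if (!identical(dim(x), dim(x_hat))) stopf("shape mismatch")
  mean((x - x_hat)^2)
}

#' Inverse-frequency class weights
#'
#' `w_c` proportional to `1 / n_c`, normalized so the mean weight is 1.
#'
#' @param labels factor (or coercible) of class labels; every level must
#'   occur at least once.
#' @return Named numeric weight vector over levels.
#' @export
compute_class_weights <- function(labels) {
  labels <- as.factor(labels)
  n <- table(labels)
  if (any(n == 0)) stopf("class '%s' has no observations",
                         names(n)[which(n == 0)[1]])
  w <- 1 / as.numeric(n)
  w <- w / mean(w)
  names(w) <- names(n)
  w
}

#' Weighted cross-entropy classification loss
#'
#' Batch mean of `w_y * (-log p_y)` under a softmax over the logits, with
#' per-class weights `w` (unit weights if omitted).
#'
#' @param logits `n x k` matrix, one row per sample.
#' @param labels integer class indices in `1..k` (or a factor).
#' @param class_weights optional length-`k` weight vector.
#' @return Scalar loss, >= 0.
#' @export
classification_loss <- function(logits, labels, class_weights = NULL) {
  if (is.factor(labels)) labels <- as.integer(labels)
  k <- ncol(logits)
  if (any(labels < 1 | labels > k)) stopf("label outside [1, %d]", k)
  if (is.null(class_weights)) class_weights <- rep(1, k)
  if (length(class_weights) != k) stopf("need one weight per class")
  z <- logits - apply(logits, 1, max)
  logp <- z - log(rowSums(exp(z)))
  nll <- -logp[cbind(seq_len(nrow(logits)), labels)]
  mean(class_weights[labels] * nll)
}

# softmax over columns of a k x n logit matrix
softmax_cols <- function(Z) {
  Z <- Z - rep(apply(Z, 2, max), each = nrow(Z))
  E <- exp(Z)
  E / rep(colSums(E), each = nrow(Z))
}

build_encoder_layers <- function(es) {
  cw <- es$channel_widths
  s8 <- es$input_size / 8
  list(conv_init(3, 3, cw[1]), list(type = "pool"), bn_init(cw[1]),
       list(type = "relu"),
       conv_init(3, cw[1], cw[2]), list(type = "pool"), bn_init(cw[2]),
       list(type = "relu"),
       conv_init(3, cw[2], cw[3]), list(type = "pool"), bn_init(cw[3]),
       list(type = "relu"),
       list(type = "flatten"),
       linear_init(s8 * s8 * cw[3], es$latent_dim))
}

build_decoder_layers <- function(es) {
  cw <- es$channel_widths
  s8 <- es$input_size / 8
  list(linear_init(es$latent_dim, s8 * s8 * cw[3]),
       list(type = "unflatten", h = s8, w = s8, c = cw[3]),
       list(type = "upsample"), conv_init(3, cw[3], cw[2]), bn_init(cw[2]),
       list(type = "relu"),
       list(type = "upsample"), conv_init(3, cw[2], cw[1]), bn_init(cw[1]),
       list(type = "relu"),
       list(type = "upsample"), conv_init(3, cw[1], 3),
       list(type = "sigmoid"))
}

build_classifier_layers <- function(cs, latent_dim) {
  h <- cs$hidden_sizes
  list(linear_init(latent_dim, h[1]), list(type = "relu"),
       linear_init(h[1], h[2]), list(type = "relu"),
       list(type = "dropout", p = cs$dropout_rate),
       linear_init(h[2], cs$n_classes))
}

# crops -> (H, W, N, 3) network input
crops_to_input <- function(crops) {
  X <- if (inherits(crops, "crop_set")) crops$images else crops
  aperm(X, c(1, 2, 4, 3))
}

#' Jointly train the autoencoder and classifier
#'
#' Trains encoder, decoder and classifier with Adam on the EMA-normalized
#' combined loss. Within an epoch every minibatch is normalized by the
#' averages from the end of the previous epoch (epoch 1 initializes them
#' from the first batch's losses); the averages are updated once per epoch
#' from that epoch's mean losses and are excluded from gradients.
#' Reproducible given `config$seed`.
#'
#' @param crops a [crop_set()] (values in `[0, 1]`).
#' @param labels factor of class labels, one per crop.
#' @param espec an [encoder_spec()]; its `input_size` must match the crops.
#' @param cspec a [classifier_spec()] (defaults to the label count).
#' @param config a [training_config()].
#' @param weights a [loss_weights()].
#' @param ema_alpha EMA smoothing parameter.
#' @return A `trained_model`: layer parameter sets, specs, config, final
#'   [ema_state()], per-epoch loss history (`L_recon`, `L_classifier`,
#'   `L_total`), class levels and the training droplet ids.
#' @export
train_joint <- function(crops, labels, espec = NULL, cspec = NULL,
                        config = training_config(), weights = loss_weights(),
                        ema_alpha = 0.9) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2) stopf("training requires >= 2 classes")
  X_all <- crops_to_input(crops)
  d <- dim(X_all)
  if (is.null(espec)) espec <- encoder_spec(input_size = d[1])
  if (d[1] != espec$input_size || d[2] != espec$input_size)
    stopf("crop size %dx%d does not match encoder input_size %d",
          d[1], d[2], espec$input_size)
  if (is.null(cspec)) cspec <- classifier_spec(nlevels(labels))
  if (cspec$n_classes != nlevels(labels))
    stopf("classifier n_classes (%d) != label levels (%d)",
          cspec$n_classes, nlevels(labels))
  y <- as.integer(labels)
  n <- d[3]
  cw <- if (config$class_weighting) as.numeric(compute_class_weights(labels))
        else rep(1, cspec$n_classes)
  with_seed(config$seed, {
    nets <- list(encoder = build_encoder_layers(espec),
                 decoder = build_decoder_layers(espec),
                 classifier = build_classifier_layers(cspec, espec$latent_dim))
    adam <- adam_init(nets)
    ema <- ema_state(ema_alpha)
    hist <- vector("list", config$epochs)
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(n)
      starts <- seq(1, n, by = config$batch_size)
      er_sum <- ec_sum <- et_sum <- 0
      for (s in starts) {
        idx <- perm[s:min(s + config$batch_size - 1, n)]
        nb <- length(idx)
        Xb <- X_all[, , idx, , drop = FALSE]
        fe <- net_forward(nets$encoder, Xb, train = TRUE)
        nets$encoder <- fe$layers
        z <- fe$out
        fd <- net_forward(nets$decoder, z, train = TRUE)
        nets$decoder <- fd$layers
        fc <- net_forward(nets$classifier, z, train = TRUE)
        nets$classifier <- fc$layers
        l_recon <- mean((fd$out - Xb)^2)
        P <- softmax_cols(fc$out)
        yb <- y[idx]
        l_cls <- mean(cw[yb] * (-log(pmax(P[cbind(yb, seq_len(nb))], 1e-12))))
        if (!ema$initialized) ema <- ema_update(ema, l_recon, l_cls)
        er <- max(ema$ema_recon, 1e-8)
        ec <- max(ema$ema_classifier, 1e-8)
        l_total <- weights$beta_recon * l_recon / er +
          weights$beta_classifier * l_cls / ec
        # backward: EMA denominators are constants
        d_xhat <- (2 / length(Xb)) * (fd$out - Xb) * (weights$beta_recon / er)
        bd <- net_backward(nets$decoder, fd$caches, d_xhat)
        G <- P
        G[cbind(yb, seq_len(nb))] <- G[cbind(yb, seq_len(nb))] - 1
        G <- G * rep(cw[yb] / nb, each = cspec$n_classes) *
          (weights$beta_classifier / ec)
        bc <- net_backward(nets$classifier, fc$caches, G)
        be <- net_backward(nets$encoder, fe$caches, bd$dX + bc$dX)
        st <- adam_step(nets,
                        list(encoder = be$grads, decoder = bd$grads,
                             classifier = bc$grads),
                        adam, config$learning_rate)
        nets <- st$nets; adam <- st$state
        er_sum <- er_sum + l_recon * nb
        ec_sum <- ec_sum + l_cls * nb
        et_sum <- et_sum + l_total * nb
      }
      ema <- ema_update(ema, er_sum / n, ec_sum / n)
      hist[[epoch]] <- c(L_recon = er_sum / n, L_classifier = ec_sum / n,
                         L_total = et_sum / n)
    }
    # recalibrate BN running statistics on the training data so that
    # evaluation-mode forwards use representative activation moments
    nets$encoder <- calibrate_bn(nets$encoder, X_all, config$batch_size)
    z_all <- forward_chunked(nets$encoder, X_all, config$batch_size)
    nets$decoder <- calibrate_bn(nets$decoder, z_all, config$batch_size)
  })
  history <- as.data.frame(do.call(rbind, hist))
  history$epoch <- seq_len(nrow(history))
  structure(list(
    encoder = nets$encoder, decoder = nets$decoder,
    classifier = nets$classifier,
    encoder_spec = espec, classifier_spec = cspec, config = config,
    weights = weights, ema = ema, history = history,
    class_levels = levels(labels),
    train_droplet_ids = if (inherits(crops, "crop_set"))
      unique(crops$info$droplet_id) else NULL
  ), class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> latent %d, %d classes, %d epochs (final L_total %.3f)\n",
              x$encoder_spec$latent_dim, x$classifier_spec$n_classes,
              nrow(x$history), x$history$L_total[nrow(x$history)]))
  invisible(x)
}

#' Encode crops into latent space
#'
#' Deterministic evaluation-mode forward pass through the encoder (dropout
#' off, batch-normalization statistics frozen).
#'
#' @param model a `trained_model`.
#' @param crops a [crop_set()] or `H x W x 3 x n` array.
#' @return `n x latent_dim` matrix.
#' @export
encode <- function(model, crops) {
  X <- crops_to_input(crops)
  if (dim(X)[1] != model$encoder_spec$input_size)
    stopf("crop size does not match encoder input")
  t(forward_chunked(model$encoder, X, model$config$batch_size %||% 200))
}

#' Decode latent vectors into reconstructed crops
#' @param model a `trained_model`.
#' @param latent `n x latent_dim` matrix.
#' @return `H x W x 3 x n` array of reconstructions in `[0, 1]`.
#' @export
decode <- function(model, latent) {
  if (ncol(latent) != model$encoder_spec$latent_dim)
    stopf("latent width %d does not match latent_dim %d",
          ncol(latent), model$encoder_spec$latent_dim)
  out <- forward_chunked(model$decoder, t(latent), model$config$batch_size %||% 200)
  aperm(out, c(1, 2, 4, 3))
}

#' Classify crops
#' @param model a `trained_model`.
#' @param crops a [crop_set()] or array.
#' @return Factor of predicted classes (argmax logits; ties break to the
#'   lowest class index).
#' @export
predict_classes <- function(model, crops) {
  z <- encode(model, crops)
  logits <- net_forward(model$classifier, t(z), train = FALSE)$out
  factor(model$class_levels[apply(logits, 2, which.max)],
         levels = model$class_levels)
}

#' Save / load a model checkpoint
#'
#' The checkpoint holds all parameter sets, architecture specs, training
#' config and EMA state; reloading restores bit-identical evaluation-mode
#' forward passes.
#'
#' @param model a `trained_model`.
#' @param path checkpoint file path.
#' @return `load_checkpoint` returns the `trained_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "trained_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "trained_model"))
  model
}
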