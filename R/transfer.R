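#' Extract frozen-encoder latent features
#'
#' Feeds crops through a pretrained encoder in evaluation mode. The
#' encoder parameters are frozen: extraction performs no updates and the
#' model (or checkpoint file) is left untouched.
#'
#' @param model a `trained_model` or a checkpoint path.
#' @param crops a [crop_set()].
#' @return A `latent_features` object: `features` (`n x latent_dim`
#'   matrix), `info` (per-crop metadata), `provenance` (encoder
#'   identifier).
#' @export
extract_latent_features <- function(model, crops) {
  if (is.character(model)) model <- load_checkpoint(model)
  stopifnot(inherits(model, "trained_model"))
  feats <- encode(model, crops)
  structure(list(
    features = feats,
    info = if (inherits(crops, "crop_set")) crops$info else
      data.frame(droplet_id = sprintf("crop%05d", seq_len(nrow(feats)))),
    provenance = sprintf("encoder[latent=%d,seed=%d]",
                         model$encoder_spec$latent_dim, model$config$seed)
  ), class = "latent_features")
}

# Train a classifier head (fresh initialization) on latent features.
fit_head <- function(feats, y, cspec, config, class_weights) {
  k <- cspec$n_classes
  n <- nrow(feats)
  Xt <- t(feats)  # latent_dim x n
  with_seed(config$seed, {
    layers <- build_classifier_layers(cspec, ncol(feats))
    adam <- adam_init(list(head = layers))
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(n)
      for (s in seq(1, n, by = config$batch_size)) {
        idx <- perm[s:min(s + config$batch_size - 1, n)]
        nb <- length(idx)
        fw <- net_forward(layers, Xt[, idx, drop = FALSE], train = TRUE)
        layers <- fw$layers
        P <- softmax_cols(fw$out)
        yb <- y[idx]
        G <- P
        G[cbind(yb, seq_len(nb))] <- G[cbind(yb, seq_len(nb))] - 1
        G <- G * rep(class_weights[yb] / nb, each = k)
        bw <- net_backward(layers, fw$caches, G)
        st <- adam_step(list(head = layers), list(head = bw$grads), adam,
                        config$learning_rate)
        layers <- st$nets$head; adam <- st$state
      }
    }
  })
  layers
}

head_predict <- function(layers, feats, levels) {
  logits <- net_forward(layers, t(feats), train = FALSE)$out
  factor(levels[apply(logits, 2, which.max)], levels = levels)
}

#' Transfer learning: train a new classifier on frozen latent features
#'
#' Trains only a fresh classifier head (same architecture as the joint
#' model's head) on latent features from a frozen pretrained encoder, with
#' inverse-frequency class weighting and stratified k-fold CV at droplet
#' level. No reconstruction term is involved and the encoder is never
#' updated.
#'
#' @param features a `latent_features` from [extract_latent_features()].
#' @param scheme a [label_scheme()] (or name), or `NULL` with explicit
#'   `labels`.
#' @param labels optional explicit per-row label factor.
#' @param cspec a [classifier_spec()] (defaults to the label count).
#' @param config a [training_config()].
#' @param k folds.
#' @param seed master seed.
#' @return A `cv_report` with the fitted full-data head in `$head`.
#' @export
train_transfer_classifier <- function(features, scheme = NULL, labels = NULL,
                                      cspec = NULL,
                                      config = training_config(), k = 5,
                                      seed = 1L) {
  stopifnot(inherits(features, "latent_features"))
  if (is.null(labels)) {
    if (is.character(scheme)) scheme <- label_scheme(scheme)
    labels <- scheme$map(features$info)
  }
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2) stopf("transfer task requires >= 2 classes")
  if (is.null(cspec)) cspec <- classifier_spec(nlevels(labels))
  y <- as.integer(labels)
  cw <- if (config$class_weighting) as.numeric(compute_class_weights(labels))
        else rep(1, cspec$n_classes)
  ids <- features$info$droplet_id
  did <- !duplicated(ids)
  folds <- assign_folds(ids[did], labels[did], k = k, seed = seed)
  fold_of <- folds$fold[match(ids, folds$droplet_id)]
  lev <- levels(labels)
  cm <- matrix(0L, length(lev), length(lev), dimnames = list(lev, lev))
  per_fold_f1 <- numeric(k)
  seeds <- derive_seeds(seed, k + 1)
  for (f in seq_len(k)) {
    tr <- which(fold_of != f); va <- which(fold_of == f)
    cfg <- config; cfg$seed <- seeds[f]
    head <- fit_head(features$features[tr, , drop = FALSE], y[tr], cspec,
                     cfg, cw)
    pred <- head_predict(head, features$features[va, , drop = FALSE], lev)
    fold_cm <- table(factor(labels[va], levels = lev),
                     factor(pred, levels = lev))
    cm <- cm + as.matrix(fold_cm)
    per_fold_f1[f] <- macro_f1(fold_cm)
  }
  rep <- new_cv_report(per_fold_f1, cm,
                       if (!is.null(scheme)) scheme$name else "custom")
  cfg <- config; cfg$seed <- seeds[k + 1]
  rep$head <- fit_head(features$features, y, cspec, cfg, cw)
  rep$provenance <- features$provenance
  rep
}
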