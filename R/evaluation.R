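#' Label schemes for the classification tasks
#'
#' Maps condition labels to the class structures of the study's
#' classification tasks:
#' \describe{
#'   \item{twelve_class}{water matrix x (control, 1 ppm, 1 ppb, 1 ppt PFOA)
#'     over all three matrices (12 classes).}
#'   \item{six_class_rw}{river water only: control, the three PFOA
#'     concentrations, PFOS, and the PFOA + PFOS mixture.}
#'   \item{four_class_rw}{river water only: control, PFOA (all
#'     concentrations pooled), PFOS, mixture.}
#'   \item{binary_pfas}{control vs any PFAS-containing condition.}
#'   \item{random_binary}{two arbitrary groups assigned externally (see
#'     [random_label_control()]).}
#' }
#'
#' @param name scheme name.
#' @return A `label_scheme` with a `$map(info)` function returning a factor
#'   (errors if a row is outside the scheme's domain).
#' @export
label_scheme <- function(name = c("twelve_class", "six_class_rw",
                                  "four_class_rw", "binary_pfas",
                                  "random_binary")) {
  name <- match.arg(name)
  map <- switch(name,
    twelve_class = function(info) {
      bad <- info$analyte %in% c("PFOS", "Mixture")
      if (any(bad)) stopf("twelve_class covers only Control/PFOA conditions")
      lev <- as.vector(t(outer(c("MilliQ", "Tap", "RiverWater"),
                               c("Control", "1ppm", "1ppb", "1ppt"), paste,
                               sep = "/")))
      cls <- paste(info$matrix,
                   ifelse(info$analyte == "Control", "Control",
                          info$concentration_class), sep = "/")
      factor(cls, levels = lev)
    },
    six_class_rw = function(info) {
      if (any(info$matrix != "RiverWater"))
        stopf("six_class_rw covers only RiverWater conditions")
      cls <- ifelse(info$analyte == "Control", "Control",
             ifelse(info$analyte == "PFOA",
                    paste0("PFOA-", info$concentration_class),
                    info$analyte))
      factor(cls, levels = c("Control", "PFOA-1ppm", "PFOA-1ppb",
                             "PFOA-1ppt", "PFOS", "Mixture"))
    },
    four_class_rw = function(info) {
      if (any(info$matrix != "RiverWater"))
        stopf("four_class_rw covers only RiverWater conditions")
      cls <- ifelse(info$analyte == "Control", "Control", info$analyte)
      factor(cls, levels = c("Control", "PFOA", "PFOS", "Mixture"))
    },
    binary_pfas = function(info)
      factor(ifelse(info$analyte == "Control", "Control", "PFAS"),
             levels = c("Control", "PFAS")),
    random_binary = function(info) {
      if (is.null(info$random_group))
        stopf("random_binary requires a 'random_group' column (see random_label_control)")
      factor(info$random_group, levels = c("Control", "PFAS"))
    })
  structure(list(name = name, map = map), class = "label_scheme")
}

#' Stratified droplet-level fold assignment
#'
#' Partitions droplets (not crops: all augmented variants of one droplet
#' share its fold) into `k` folds, stratified by class so every fold's
#' class counts match the global proportions to within one droplet per
#' class. Deterministic given `seed`.
#'
#' @param droplet_ids character vector, one per droplet (unique).
#' @param classes factor of the same length.
#' @param k number of folds.
#' @param seed integer seed.
#' @return Data frame `droplet_id`, `class`, `fold` (1..k).
#' @export
assign_folds <- function(droplet_ids, classes, k = 5, seed = 1L) {
  stopifnot(!anyDuplicated(droplet_ids))
  classes <- droplevels(as.factor(classes))
  cnt <- table(classes)
  if (any(cnt < k))
    stopf("class '%s' has %d droplets, fewer than k = %d",
          names(cnt)[which.min(cnt)], min(cnt), k)
  fold <- integer(length(droplet_ids))
  with_seed(seed, {
    for (cl in levels(classes)) {
      idx <- which(classes == cl)
      fold[idx] <- rep_len(seq_len(k), length(idx))[sample.int(length(idx))]
    }
  })
  data.frame(droplet_id = droplet_ids, class = classes, fold = fold,
             stringsAsFactors = FALSE)
}

#' Macro-averaged F1 score of a confusion matrix
#'
#' Unweighted mean over classes of the per-class harmonic mean of
#' precision and recall (rows = truth, columns = prediction). A class with
#' zero precision + recall contributes F1 = 0.
#'
#' @param cm square numeric confusion matrix.
#' @return Scalar in `[0, 1]`.
#' @export
macro_f1 <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stopf("confusion matrix must be square")
  if (sum(cm) == 0) stopf("macro F1 undefined for an all-zero matrix")
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  mean(f1)
}

#' Chance accuracy level
#'
#' Analytic chance level `100 / n_classes` for uniform random prediction
#' (8.33% for 12 classes, 16.7% for 6, 25% for 4, 50% for binary), with an
#' optional Monte-Carlo estimate (uniform random predictions against a
#' balanced truth).
#'
#' @param n_classes number of classes (>= 2).
#' @param method `"analytic"` or `"monte_carlo"`.
#' @param n_sim Monte-Carlo sample size.
#' @param seed Monte-Carlo seed.
#' @return Percentage in `(0, 50]`.
#' @export
chance_level <- function(n_classes, method = c("analytic", "monte_carlo"),
                         n_sim = 1e5, seed = 1L) {
  if (n_classes < 2) stopf("n_classes must be >= 2")
  method <- match.arg(method)
  if (method == "analytic") return(100 / n_classes)
  with_seed(seed, {
    truth <- rep_len(seq_len(n_classes), n_sim)
    pred <- sample.int(n_classes, n_sim, replace = TRUE)
    100 * mean(pred == truth)
  })
}

new_cv_report <- function(per_fold_f1, cm, scheme_name) {
  ra <- rowSums(cm)
  structure(list(
    per_fold_macro_f1 = per_fold_f1,
    macro_f1_mean = mean(per_fold_f1),
    macro_f1_sd = sd(per_fold_f1),
    pooled_confusion = cm,
    per_class_accuracy = ifelse(ra > 0, diag(cm) / ra, NA_real_),
    pooled_accuracy = sum(diag(cm)) / sum(cm),
    scheme = scheme_name
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> scheme %s: pooled accuracy %.1f%%, macro F1 %.3f +/- %.3f\n",
              x$scheme, 100 * x$pooled_accuracy, x$macro_f1_mean,
              x$macro_f1_sd))
  cat("pooled confusion matrix (rows = truth):\n")
  print(x$pooled_confusion)
  invisible(x)
}

#' Stratified k-fold cross-validated training and evaluation
#'
#' For each fold: trains the joint autoencoder-classifier on the other
#' k-1 folds (augmentation, if requested, is applied after fold assignment
#' so variants of one droplet never straddle train/validation), predicts
#' the held-out fold's raw crops, and accumulates a pooled confusion
#' matrix and per-fold macro F1. Per-fold training uses identical
#' hyperparameters with a fold-indexed derived seed.
#'
#' @param crops a [crop_set()] of raw (pre-augmentation) droplet crops.
#' @param scheme a [label_scheme()] (or its name), or `NULL` if `labels`
#'   given.
#' @param labels optional explicit factor of per-crop labels (overrides
#'   `scheme`).
#' @param espec,cspec,config,weights model and training settings (see
#'   [train_joint()]).
#' @param k folds.
#' @param seed master seed (fold assignment + per-fold training seeds).
#' @param augment optional [augmentation_spec()] applied to each fold's
#'   training crops.
#' @return A `cv_report`: per-fold macro F1, mean +/- SD, pooled confusion
#'   matrix, per-class accuracies (row-normalized diagonal) and pooled
#'   accuracy.
#' @export
run_cv <- function(crops, scheme = NULL, labels = NULL, espec = NULL,
                   cspec = NULL, config = training_config(),
                   weights = loss_weights(), k = 5, seed = 1L,
                   augment = NULL) {
  if (is.null(labels)) {
    if (is.character(scheme)) scheme <- label_scheme(scheme)
    labels <- scheme$map(crops$info)
  }
  scheme_name <- if (!is.null(scheme)) scheme$name else "custom"
  labels <- droplevels(as.factor(labels))
  if (anyNA(labels)) stopf("labels contain NA; filter the crops to the scheme's domain")
  ids <- crops$info$droplet_id
  did <- !duplicated(ids)
  folds <- assign_folds(ids[did], labels[did], k = k, seed = seed)
  fold_of <- folds$fold[match(ids, folds$droplet_id)]
  lev <- levels(labels)
  cm <- matrix(0L, length(lev), length(lev), dimnames = list(lev, lev))
  per_fold_f1 <- numeric(k)
  train_seeds <- derive_seeds(seed, k)
  for (f in seq_len(k)) {
    tr <- which(fold_of != f)
    va <- which(fold_of == f)
    tr_crops <- crops[tr]
    tr_labels <- labels[tr]
    if (!is.null(augment)) {
      tr_crops <- augment_dataset(tr_crops, augment, seed = train_seeds[f])
      tr_labels <- rep(tr_labels, each = augment$factor)
    }
    cfg <- config
    cfg$seed <- train_seeds[f]
    model <- train_joint(tr_crops, tr_labels, espec, cspec, cfg, weights)
    pred <- predict_classes(model, crops[va])
    fold_cm <- table(factor(labels[va], levels = lev),
                     factor(pred, levels = lev))
    cm <- cm + as.matrix(fold_cm)
    per_fold_f1[f] <- macro_f1(fold_cm)
  }
  new_cv_report(per_fold_f1, cm, scheme_name)
}

#' Random-label negative control
#'
#' Splits droplets of a single homogeneous condition 50/50 (droplet level;
#' group sizes differ by at most one) into arbitrary "PFAS" / "Control"
#' groups and runs the full cross-validated pipeline. Since the groups
#' differ only in their arbitrary labels, pooled accuracy is expected to
#' be statistically indistinguishable from 50%.
#'
#' @param crops a [crop_set()] whose crops all share one true condition.
#' @param espec,cspec,config,weights,k,augment as in [run_cv()].
#' @param seed seed for the random split and CV.
#' @return A `cv_report` (with the realized group sizes in
#'   `$group_sizes`).
#' @export
random_label_control <- function(crops, espec = NULL, cspec = NULL,
                                 config = training_config(), weights = loss_weights(),
                                 k = 5, seed = 1L, augment = NULL) {
  cond <- condition_string(crops$info)
  if (!is.null(cond) && length(unique(cond)) != 1)
    stopf("random_label_control requires crops from a single condition")
  ids <- unique(crops$info$droplet_id)
  n <- length(ids)
  grp_ids <- with_seed(seed, sample(ids, floor(n / 2)))
  grp <- ifelse(crops$info$droplet_id %in% grp_ids, "PFAS", "Control")
  labels <- factor(grp, levels = c("Control", "PFAS"))
  rep <- run_cv(crops, scheme = NULL, labels = labels, espec = espec,
                cspec = cspec, config = config, weights = weights, k = k,
                seed = seed, augment = augment)
  rep$scheme <- "random_binary"
  rep$group_sizes <- table(labels[!duplicated(crops$info$droplet_id)])
  rep
}

#' Blind test on held-out droplets
#'
#' Applies a trained model to droplets never seen in training or
#' validation, asserting droplet-id disjointness (a leakage guard), and
#' reports accuracy and the confusion matrix.
#'
#' @param model a `trained_model`.
#' @param crops held-out [crop_set()].
#' @param labels factor of true classes (levels matching the model's), or
#'   a [label_scheme()] to derive them.
#' @return List with `accuracy`, `confusion`, `n`.
#' @export
blind_test <- function(model, crops, labels = NULL) {
  if (length(crops) == 0) stopf("empty test set")
  if (inherits(labels, "label_scheme")) labels <- labels$map(crops$info)
  if (is.null(labels)) stopf("'labels' required")
  if (!is.null(model$train_droplet_ids) &&
      length(intersect(crops$info$droplet_id, model$train_droplet_ids)) > 0)
    stopf("leakage: test droplets overlap the model's training droplets")
  pred <- predict_classes(model, crops)
  lev <- model$class_levels
  cmt <- table(factor(labels, levels = lev), factor(pred, levels = lev))
  list(accuracy = mean(as.character(pred) == as.character(labels)),
       confusion = as.matrix(cmt), n = length(crops))
}
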