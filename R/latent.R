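#' Principal component analysis projection
#'
#' Standard PCA on mean-centered (unscaled) data. The explained-variance
#' ratio of each component is its variance divided by the total variance
#' of the data, so the ratios are non-increasing and sum to at most 1.
#' Component signs are fixed by making each component's largest-magnitude
#' loading positive, so projections are fully reproducible.
#'
#' @param x numeric matrix (rows = observations); both dimensions must be
#'   at least `n_components`.
#' @param n_components number of components to return.
#' @param source optional tag (`"raw_images"` or `"latent_features"`)
#'   recorded on the result.
#' @return A `pca_result`: `components` (loadings, `p x n_components`),
#'   `explained_variance_ratio`, `projections` (`n x n_components`),
#'   `source`.
#' @export
pca_project <- function(x, n_components = 3, source = NA_character_) {
  x <- as.matrix(x)
  if (nrow(x) < n_components || ncol(x) < n_components)
    stopf("need at least %d rows and columns for %d components",
          n_components, n_components)
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  xc <- sweep(x, 2, colMeans(x))
  total_var <- sum(xc^2) / (nrow(x) - 1)
  nc <- min(n_components, length(pc$sdev))
  ratio <- numeric(n_components)
  ratio[seq_len(nc)] <- pc$sdev[seq_len(nc)]^2 / total_var
  rot <- matrix(0, ncol(x), n_components)
  proj <- matrix(0, nrow(x), n_components)
  rot[, seq_len(nc)] <- pc$rotation[, seq_len(nc)]
  proj[, seq_len(nc)] <- pc$x[, seq_len(nc)]
  for (j in seq_len(nc)) {  # sign convention
    if (rot[which.max(abs(rot[, j])), j] < 0) {
      rot[, j] <- -rot[, j]
      proj[, j] <- -proj[, j]
    }
  }
  structure(list(components = rot, explained_variance_ratio = ratio,
                 projections = proj, source = source), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %s: %s%% variance explained\n",
              x$source %||% "data",
              paste(sprintf("%.1f", 100 * x$explained_variance_ratio),
                    collapse = " / ")))
  invisible(x)
}

#' Flatten crops into a raw-pixel matrix
#'
#' One row per crop, `height x width x channels` columns (R's column-major
#' flattening, so `array(row, dim(crop))` recovers the crop exactly).
#'
#' @param crops a [crop_set()] or 4-D array of uniformly sized crops.
#' @return `n x (H*W*3)` numeric matrix.
#' @export
flatten_images <- function(crops) {
  X <- if (inherits(crops, "crop_set")) crops$images else crops
  if (length(dim(X)) != 4) stopf("crops must share a uniform H x W x C shape")
  d <- dim(X)
  t(matrix(X, d[1] * d[2] * d[3], d[4]))
}

#' Permutation test on between-class centroid separation
#'
#' Tests whether class centroids in a low-dimensional projection are more
#' separated than expected under label exchange: the statistic is the mean
#' pairwise between-class centroid distance, compared against its
#' permutation distribution.
#'
#' @param proj `n x d` projection matrix.
#' @param labels factor of class labels.
#' @param n_perm number of label permutations.
#' @param seed integer seed.
#' @return List with `statistic` and `p_value`.
#' @export
centroid_separation_test <- function(proj, labels, n_perm = 1000, seed = 1L) {
  labels <- droplevels(as.factor(labels))
  stat <- function(lab) {
    cen <- apply(proj, 2, tapply, lab, mean)
    mean(dist(cen))
  }
  obs <- stat(labels)
  with_seed(seed, {
    perm <- replicate(n_perm, stat(sample(labels)))
  })
  list(statistic = obs, p_value = (1 + sum(perm >= obs)) / (1 + n_perm))
}
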