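#' Augmentation specification
#'
#' Controls the 20-fold expansion of each droplet crop by composite affine
#' transforms: random shearing, rotation and horizontal/vertical flips.
#' Out-of-frame pixels are filled with a constant background intensity
#' (the dark field between crossed polarizers).
#'
#' @param factor variants per crop (>= 1; the study design uses 20).
#' @param rotation_range max absolute rotation, degrees.
#' @param shear_range max absolute shear, degrees.
#' @param hflip_prob,vflip_prob flip probabilities.
#' @param fill background fill intensity for out-of-frame pixels.
#' @return A list of class `augmentation_spec`.
#' @export
augmentation_spec <- function(factor = 20, rotation_range = 180,
                              shear_range = 10, hflip_prob = 0.5,
                              vflip_prob = 0.5, fill = 0.03) {
  if (factor < 1) stopf("factor must be >= 1")
  if (rotation_range < 0 || shear_range < 0) stopf("ranges must be >= 0")
  assert_prob(c(hflip_prob, vflip_prob), "flip probabilities")
  structure(list(factor = factor, rotation_range = rotation_range,
                 shear_range = shear_range, hflip_prob = hflip_prob,
                 vflip_prob = vflip_prob, fill = fill),
            class = "augmentation_spec")
}

# Apply one sampled (shear, rotation, flips) composite affine transform to
# an H x W x 3 crop. Rotations that are exact multiples of 90 degrees with
# no shear/flip-interpolation needs are performed losslessly on the pixel
# lattice.
apply_affine <- function(img, rot_deg, shear_deg, hflip, vflip, fill) {
  n <- dim(img)[1]
  if (shear_deg == 0 && rot_deg %% 90 == 0) {
    out <- img
    k <- (as.integer(round(rot_deg / 90)) %% 4L)
    for (i in seq_len(k)) # 90-degree lattice rotation: transpose + reverse rows
      out <- aperm(out, c(2, 1, 3))[dim(out)[2]:1, , , drop = FALSE]
    if (hflip) out <- out[, dim(out)[2]:1, , drop = FALSE]
    if (vflip) out <- out[dim(out)[1]:1, , , drop = FALSE]
    return(out)
  }
  th <- rot_deg * pi / 180
  sh <- tan(shear_deg * pi / 180)
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  shm <- matrix(c(1, 0, sh, 1), 2, 2)
  flp <- diag(c(if (hflip) -1 else 1, if (vflip) -1 else 1))
  A <- flp %*% rot %*% shm
  ctr <- (n + 1) / 2
  off <- c(ctr, ctr) - A %*% c(ctr, ctr)
  m <- rbind(t(A), as.numeric(off))  # EBImage: out = cbind(in, 1) %*% m
  y <- EBImage::affine(EBImage::Image(img, colormode = EBImage::Color), m,
                       filter = "bilinear", bg.col = fill)
  out <- imageData(y)
  dim(out) <- dim(img)
  out
}

#' Augment one droplet crop
#'
#' Produces exactly `spec$factor` variants of a crop, each by an
#' independently sampled composite affine transform (shear, rotation,
#' flips). All variants share the input's `droplet_id` and condition label.
#'
#' @param crop a length-1 [crop_set()].
#' @param spec an [augmentation_spec()].
#' @param seed integer seed.
#' @return A `crop_set` of `spec$factor` crops.
#' @export
augment_crop <- function(crop, spec = augmentation_spec(), seed = 1L) {
  stopifnot(inherits(crop, "crop_set"), length(crop) == 1)
  augment_dataset(crop, spec, seed)
}

#' Augmented-manifest bookkeeping
#'
#' Expands a per-crop metadata table by the augmentation factor, exactly as
#' [augment_dataset()] does for the images: each input row yields `factor`
#' output rows sharing its `droplet_id`, label and provenance, with a
#' `variant` counter added. Useful for reasoning about dataset sizes
#' without rendering pixels.
#'
#' @param info data frame of per-crop metadata.
#' @param factor variants per crop.
#' @return The expanded data frame with `factor * nrow(info)` rows.
#' @export
augmentation_manifest <- function(info, factor = 20) {
  if (factor < 1) stopf("factor must be >= 1")
  out <- info[rep(seq_len(nrow(info)), each = factor), , drop = FALSE]
  out$variant <- rep(seq_len(factor), times = nrow(info))
  rownames(out) <- NULL
  out
}

#' Augment a crop collection
#'
#' Expands every crop into `spec$factor` variants; the output has exactly
#' `factor * n` crops and preserves each variant's parent `droplet_id`,
#' label and provenance row-wise. Deterministic given the seed.
#'
#' @param crops a [crop_set()].
#' @param spec an [augmentation_spec()].
#' @param seed integer seed.
#' @return The augmented `crop_set` with a `variant` column added.
#' @export
augment_dataset <- function(crops, spec = augmentation_spec(), seed = 1L) {
  n <- length(crops)
  if (n == 0) stopf("'crops' must be non-empty")
  f <- spec$factor
  d <- dim(crops$images)
  out <- array(0, c(d[1], d[2], 3, n * f))
  with_seed(seed, {
    rot <- runif(n * f, -spec$rotation_range, spec$rotation_range)
    shr <- runif(n * f, -spec$shear_range, spec$shear_range)
    hfl <- runif(n * f) < spec$hflip_prob
    vfl <- runif(n * f) < spec$vflip_prob
  })
  if (spec$rotation_range == 0) rot[] <- 0
  if (spec$shear_range == 0) shr[] <- 0
  k <- 0L
  for (i in seq_len(n)) {
    img <- crops$images[, , , i]
    for (j in seq_len(f)) {
      k <- k + 1L
      out[, , , k] <- if (rot[k] == 0 && shr[k] == 0 && !hfl[k] && !vfl[k]) img
      else apply_affine(img, rot[k], shr[k], hfl[k], vfl[k], spec$fill)
    }
  }
  info <- crops$info[rep(seq_len(n), each = f), , drop = FALSE]
  info$variant <- rep(seq_len(f), times = n)
  rownames(info) <- NULL
  crop_set(out, info)
}
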