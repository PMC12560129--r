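#' Droplet detection and cropping configuration
#'
#' Parameters of the Canny/Gaussian droplet detector and of the
#' distribution-determined size and quality filters. The size cutoffs are
#' quantiles of the detected box-area distribution of the batch itself,
#' not fixed pixel constants.
#'
#' @param gaussian_sigma Gaussian pre-smoothing SD in pixels.
#' @param canny_low,canny_high hysteresis thresholds on Sobel gradient
#'   magnitude (image intensities in `[0, 1]`).
#' @param size_cutoff_low_q,size_cutoff_high_q area quantiles retained by
#'   [size_filter()].
#' @param min_circularity minimum `4*pi*A/P^2` shape circularity.
#' @param min_contrast minimum interior intensity spread (P95 - P5) below
#'   which a crop is rejected as faint.
#' @param min_sharpness minimum variance-of-Laplacian below which a crop is
#'   rejected as out of focus.
#' @param close_brush diameter (px) of the disc brush used to close edge
#'   contours before hole filling; must exceed the widest gap the
#'   extinction cross leaves in a droplet's rim edge, and stay below the
#'   gap between neighbouring droplets.
#' @param crop_size output crop side in pixels.
#' @return A list of class `extraction_config`.
#' @export
extraction_config <- function(gaussian_sigma = 2, canny_low = 0.008,
                              canny_high = 0.022, size_cutoff_low_q = 0.01,
                              size_cutoff_high_q = 0.99, min_circularity = 0.4,
                              min_contrast = 0.2, min_sharpness = 1e-4,
                              close_brush = 21, crop_size = 64) {
  if (size_cutoff_low_q >= size_cutoff_high_q)
    stopf("size_cutoff_low_q must be < size_cutoff_high_q")
  if (crop_size <= 0) stopf("crop_size must be > 0")
  if (canny_low > canny_high) stopf("canny_low must be <= canny_high")
  structure(list(gaussian_sigma = gaussian_sigma, canny_low = canny_low,
                 canny_high = canny_high, size_cutoff_low_q = size_cutoff_low_q,
                 size_cutoff_high_q = size_cutoff_high_q,
                 min_circularity = min_circularity, min_contrast = min_contrast,
                 min_sharpness = min_sharpness, close_brush = close_brush,
                 crop_size = crop_size),
            class = "extraction_config")
}

# Sobel gradients of a 2-D matrix (replicated border).
sobel_gradients <- function(g) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- imageData(EBImage::filter2(EBImage::Image(g), kx))
  gy <- imageData(EBImage::filter2(EBImage::Image(g), t(kx)))
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

# Canny edge map: Sobel gradients, 4-direction non-maximum suppression,
# double threshold, hysteresis by iterative dilation of strong edges.
canny_edges <- function(g, low, high) {
  sg <- sobel_gradients(g)
  mag <- sg$mag
  H <- nrow(mag); W <- ncol(mag)
  ang <- atan2(sg$gy, sg$gx)
  dir4 <- (round(ang / (pi / 4)) %% 4)  # 0:horiz grad, 1:diag, 2:vert, 3:anti-diag
  shift <- function(m, dr, dc) {
    out <- matrix(0, H, W)
    rs <- max(1, 1 + dr):min(H, H + dr); cs <- max(1, 1 + dc):min(W, W + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  keep <- matrix(FALSE, H, W)
  offs <- list(`0` = c(0, 1), `1` = c(1, 1), `2` = c(1, 0), `3` = c(1, -1))
  for (d in 0:3) {
    o <- offs[[as.character(d)]]
    sel <- dir4 == d
    keep[sel] <- (mag >= shift(mag, o[1], o[2]) &
                  mag >= shift(mag, -o[1], -o[2]))[sel]
  }
  nms <- mag * keep
  strong <- nms >= high
  weak <- nms >= low
  # hysteresis: grow strong set through weak-connected pixels
  brush <- matrix(1, 3, 3)
  repeat {
    grown <- (imageData(EBImage::dilate(EBImage::Image(strong * 1), brush)) > 0) & weak
    if (sum(grown) == sum(strong)) break
    strong <- grown
  }
  strong
}

#' Detect droplet candidates in a field micrograph
#'
#' Converts to grayscale, Gaussian-smooths, runs Canny edge detection,
#' morphologically closes and fills edge contours, labels connected
#' regions, and returns one bounding box per region with a circularity
#' score. Boxes touching the image border are discarded (partial droplets).
#' Deterministic.
#'
#' @param image `H x W x 3` numeric array in `[0, 1]` (or an EBImage
#'   `Image`).
#' @param config an [extraction_config()].
#' @param source_image optional path recorded on each box.
#' @return Data frame of boxes: `x0, y0, x1, y1` (0-based, half-open),
#'   `score` (circularity), `source_image`.
#' @export
detect_candidates <- function(image, config = extraction_config(),
                              source_image = NA_character_) {
  if (EBImage::is.Image(image)) image <- imageData(image)
  if (is.null(dim(image)) || length(dim(image)) < 2)
    stopf("'image' must be a 2-D raster")
  g <- if (length(dim(image)) == 3) rowMeans(image, dims = 2) else image
  if (config$gaussian_sigma > 0)
    g <- imageData(EBImage::gblur(EBImage::Image(g), sigma = config$gaussian_sigma))
  edges <- canny_edges(g, config$canny_low, config$canny_high)
  # close the rim gaps the extinction cross leaves, then fill the interior
  brush <- EBImage::makeBrush(config$close_brush, "disc")
  closed <- EBImage::erode(EBImage::fillHull(
    EBImage::dilate(EBImage::Image(edges * 1), brush)), brush)
  lab <- EBImage::bwlabel(closed)
  nobj <- max(lab)
  if (nobj == 0)
    return(data.frame(x0 = integer(0), y0 = integer(0), x1 = integer(0),
                      y1 = integer(0), score = numeric(0),
                      source_image = character(0)))
  shp <- EBImage::computeFeatures.shape(lab)
  labm <- imageData(lab)
  H <- nrow(labm); W <- ncol(labm)
  idx <- which(labm > 0)
  obj <- labm[idx]
  rr <- ((idx - 1) %% H) + 1
  cc <- ((idx - 1) %/% H) + 1
  r0 <- tapply(rr, obj, min); r1 <- tapply(rr, obj, max)
  c0 <- tapply(cc, obj, min); c1 <- tapply(cc, obj, max)
  area <- shp[, "s.area"]
  perim <- pmax(shp[, "s.perimeter"], 1)
  circ <- pmin(4 * pi * area / perim^2, 1)
  out <- data.frame(
    x0 = as.integer(c0 - 1), y0 = as.integer(r0 - 1),
    x1 = as.integer(c1), y1 = as.integer(r1),
    score = as.numeric(circ), source_image = source_image,
    stringsAsFactors = FALSE)
  border <- out$x0 <= 0 | out$y0 <= 0 | out$x1 >= W | out$y1 >= H
  tiny <- area < 9  # single-pixel noise specks, below any droplet scale
  out[!border & !tiny, , drop = FALSE]
}

#' Distribution-determined size filtering of detected boxes
#'
#' Computes the empirical distribution of box areas over the whole batch
#' and keeps boxes whose area lies between the configured low and high
#' quantiles (inclusive) and whose circularity score meets
#' `min_circularity`. The cutoffs are derived from the batch itself.
#'
#' @param boxes data frame from [detect_candidates()] (possibly several
#'   fields concatenated).
#' @param config an [extraction_config()].
#' @return The retained subset of `boxes`.
#' @export
size_filter <- function(boxes, config = extraction_config()) {
  if (nrow(boxes) == 0) return(boxes)
  area <- (boxes$x1 - boxes$x0) * (boxes$y1 - boxes$y0)
  qs <- quantile(area, c(config$size_cutoff_low_q, config$size_cutoff_high_q),
                 names = FALSE)
  keep <- area >= qs[1] & area <= qs[2]
  if (!is.null(boxes$score)) keep <- keep & boxes$score >= config$min_circularity
  boxes[keep, , drop = FALSE]
}

#' Crop one droplet from a field and resize
#'
#' Extracts the bounding box with a fixed relative margin (clamped at the
#' image border) and bilinearly resizes to a square crop, preserving color
#' channels.
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param box one-row data frame with `x0, y0, x1, y1` (0-based half-open).
#' @param crop_size output side in pixels.
#' @param margin_frac margin added around the box, as a fraction of its
#'   side.
#' @return `crop_size x crop_size x 3` array.
#' @export
crop_and_resize <- function(image, box, crop_size = 64, margin_frac = 0.1) {
  H <- dim(image)[1]; W <- dim(image)[2]
  if (box$x0 < 0 || box$y0 < 0 || box$x1 > W || box$y1 > H ||
      box$x1 <= box$x0 || box$y1 <= box$y0)
    stopf("bounding box outside image")
  mw <- round(margin_frac * (box$x1 - box$x0))
  mh <- round(margin_frac * (box$y1 - box$y0))
  c0 <- max(box$x0 - mw, 0) + 1; c1 <- min(box$x1 + mw, W)
  r0 <- max(box$y0 - mh, 0) + 1; r1 <- min(box$y1 + mh, H)
  sub <- image[r0:r1, c0:c1, , drop = FALSE]
  if (dim(sub)[1] == crop_size && dim(sub)[2] == crop_size) return(sub)
  out <- imageData(EBImage::resize(EBImage::Image(sub, colormode = EBImage::Color),
                                   w = crop_size, h = crop_size))
  dim(out) <- c(crop_size, crop_size, 3)
  out
}

# Interior contrast (P95 - P5 of grayscale over the central disc) and
# variance-of-Laplacian sharpness of a crop.
crop_quality_stats <- function(img) {
  g <- rowMeans(img, dims = 2)
  n <- nrow(g)
  ax <- seq_len(n) - (n + 1) / 2
  inside <- outer(ax, ax, function(y, x) sqrt(x^2 + y^2)) <= 0.45 * n
  v <- g[inside]
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  lg <- imageData(EBImage::filter2(EBImage::Image(g), lap))
  c(contrast = as.numeric(diff(quantile(v, c(0.05, 0.95), names = FALSE))),
    sharpness = var(as.numeric(lg[inside])))
}

#' Reject faint and out-of-focus droplet crops
#'
#' Algorithmic counterpart of judging droplets "faint or substantially out
#' of focus": removes crops whose interior contrast (P95 - P5 of grayscale
#' over the central disc) falls below `min_contrast`, or whose
#' variance-of-Laplacian sharpness falls below `min_sharpness`.
#' Deterministic.
#'
#' @param crops a [crop_set()].
#' @param config an [extraction_config()].
#' @return The retained `crop_set`.
#' @export
quality_filter <- function(crops, config = extraction_config()) {
  n <- length(crops)
  if (n == 0) return(crops)
  stats <- vapply(seq_len(n),
                  function(i) crop_quality_stats(crops$images[, , , i]),
                  numeric(2))
  keep <- stats["contrast", ] >= config$min_contrast &
    stats["sharpness", ] >= config$min_sharpness
  crops[keep]
}

#' Extract droplet crops from a generated dataset
#'
#' Full extraction pipeline over a dataset directory written by
#' [generate_dataset()]: per-field Canny detection, batch-level
#' distribution-determined size filtering, cropping/resizing, and
#' faint/defocus quality rejection. Droplet ids encode source field and
#' box index.
#'
#' @param dir dataset directory containing images and `manifest.csv`.
#' @param config an [extraction_config()].
#' @return A [crop_set()] with provenance columns (`source_image`,
#'   `x0, y0, x1, y1`).
#' @export
extract_droplets <- function(dir, config = extraction_config()) {
  man <- read_manifest(dir)
  imgs <- lapply(file.path(dir, man$image_path), read_field_image)
  all_boxes <- do.call(rbind, lapply(seq_len(nrow(man)), function(i)
    detect_candidates(imgs[[i]], config, source_image = man$image_path[i])))
  kept <- size_filter(all_boxes, config)
  if (nrow(kept) == 0) stopf("no droplets detected")
  images <- array(0, c(config$crop_size, config$crop_size, 3, nrow(kept)))
  info <- vector("list", nrow(kept))
  for (i in seq_len(nrow(kept))) {
    b <- kept[i, ]
    m <- man[man$image_path == b$source_image, ][1, ]
    images[, , , i] <- crop_and_resize(imgs[[which(man$image_path == b$source_image)[1]]],
                                       b, config$crop_size)
    info[[i]] <- data.frame(
      droplet_id = sprintf("%s_box%04d", sub("\\.[a-z]+$", "", b$source_image), i),
      matrix = m$matrix, analyte = m$analyte,
      concentration_class = m$concentration_class,
      source_image = b$source_image, x0 = b$x0, y0 = b$y0, x1 = b$x1, y1 = b$y1,
      stringsAsFactors = FALSE)
  }
  quality_filter(crop_set(images, do.call(rbind, info)), config)
}

read_field_image <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
  } else {
    img <- tiff::readTIFF(path)
  }
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}

#' Match detections against ground-truth boxes
#'
#' Greedy one-to-one matching by center containment: a detection matches a
#' ground-truth box if the truth-box center lies inside the detection (and
#' vice versa at most once). Used to score detection recall/precision on
#' synthetic fields.
#'
#' @param detected,truth box data frames (`x0, y0, x1, y1`).
#' @return List with `n_matched`, `recall`, `precision`.
#' @export
match_detections <- function(detected, truth) {
  if (nrow(truth) == 0)
    return(list(n_matched = 0L, recall = NA_real_,
                precision = if (nrow(detected)) 0 else NA_real_))
  cx <- (truth$x0 + truth$x1) / 2; cy <- (truth$y0 + truth$y1) / 2
  used <- rep(FALSE, nrow(detected))
  matched <- 0L
  for (i in seq_len(nrow(truth))) {
    hit <- which(!used & detected$x0 <= cx[i] & detected$x1 >= cx[i] &
                   detected$y0 <= cy[i] & detected$y1 >= cy[i])
    if (length(hit)) { used[hit[1]] <- TRUE; matched <- matched + 1L }
  }
  list(n_matched = matched, recall = matched / nrow(truth),
       precision = if (nrow(detected)) matched / nrow(detected) else NA_real_)
}
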