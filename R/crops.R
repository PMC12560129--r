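#' Droplet crop collections
#'
#' A `crop_set` bundles a stack of fixed-size RGB droplet crops with their
#' per-crop metadata: the condition label (water matrix, analyte,
#' concentration class), a stable `droplet_id` shared by all augmented
#' variants of one physical droplet, and provenance (source image, bounding
#' box) where available.
#'
#' @param images numeric array `crop_size x crop_size x 3 x n` with values in
#'   `[0, 1]`.
#' @param info data frame with one row per crop; must contain a `droplet_id`
#'   column. Label columns are `matrix`, `analyte`, `concentration_class`.
#' @return An object of class `crop_set`.
#' @export
crop_set <- function(images, info) {
  if (length(dim(images)) == 3L) dim(images) <- c(dim(images), 1L)
  if (length(dim(images)) != 4L || dim(images)[3] != 3L)
    stopf("'images' must be an H x W x 3 x n array")
  if (!is.data.frame(info) || nrow(info) != dim(images)[4])
    stopf("'info' must be a data frame with one row per crop")
  if (is.null(info$droplet_id)) stopf("'info' must have a droplet_id column")
  structure(list(images = images, info = info), class = "crop_set")
}

#' @export
print.crop_set <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<crop_set> %d crops of %dx%d px, %d distinct droplets\n",
              d[4], d[1], d[2], length(unique(x$info$droplet_id))))
  lab <- condition_string(x$info)
  if (!is.null(lab)) print(table(lab))
  invisible(x)
}

#' @export
length.crop_set <- function(x) dim(x$images)[4]

#' Subset a crop set
#' @param x a `crop_set`.
#' @param i integer or logical index over crops.
#' @param ... unused.
#' @export
`[.crop_set` <- function(x, i, ...) {
  crop_set(x$images[, , , i, drop = FALSE], x$info[i, , drop = FALSE])
}

#' Concatenate crop sets
#' @param ... `crop_set` objects with identical crop dimensions.
#' @return A single combined `crop_set`.
#' @export
bind_crops <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1]]) && !inherits(xs[[1]], "crop_set"))
    xs <- xs[[1]]
  dims <- vapply(xs, function(x) dim(x$images)[1:3], numeric(3))
  if (any(dims != dims[, 1])) stopf("crop dimensions differ")
  images <- array(0, c(dims[, 1], sum(vapply(xs, length, 1L))))
  at <- 0L
  for (x in xs) {
    n <- length(x)
    if (n > 0) images[, , , at + seq_len(n)] <- x$images
    at <- at + n
  }
  info <- do.call(rbind, lapply(xs, `[[`, "info"))
  rownames(info) <- NULL
  crop_set(images, info)
}

# Compact condition string for display/stratification, or NULL if no labels.
condition_string <- function(info) {
  if (is.null(info$matrix) || is.null(info$analyte)) return(NULL)
  conc <- info$concentration_class %||% rep("none", nrow(info))
  paste(info$matrix, info$analyte, conc, sep = "/")
}
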