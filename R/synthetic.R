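#' Condition label for a droplet-array sample
#'
#' Encodes the experimental condition a field micrograph belongs to: the
#' water matrix, the analyte spiked into it, and its concentration class.
#' Controls carry concentration class `"none"`; the PFOA + PFOS mixture
#' condition exists only in simulated river water.
#'
#' @param matrix one of `"MilliQ"`, `"Tap"`, `"RiverWater"`.
#' @param analyte one of `"Control"`, `"PFOA"`, `"PFOS"`, `"Mixture"`.
#' @param concentration_class one of `"1ppm"`, `"1ppb"`, `"1ppt"`,
#'   `"3.5ppt"`, `"none"`.
#' @return A one-row data frame with the three label columns.
#' @export
condition_label <- function(matrix = "MilliQ", analyte = "Control",
                            concentration_class = "none") {
  matrix <- match.arg(matrix, c("MilliQ", "Tap", "RiverWater"))
  analyte <- match.arg(analyte, c("Control", "PFOA", "PFOS", "Mixture"))
  concentration_class <- match.arg(concentration_class,
                                   c("1ppm", "1ppb", "1ppt", "3.5ppt", "none"))
  if (analyte == "Control" && concentration_class != "none")
    stopf("Control samples must have concentration_class = 'none'")
  if (analyte != "Control" && concentration_class == "none")
    stopf("analyte '%s' requires a concentration class", analyte)
  if (analyte == "Mixture" && matrix != "RiverWater")
    stopf("the PFOA + PFOS mixture condition exists only in RiverWater")
  data.frame(matrix = matrix, analyte = analyte,
             concentration_class = concentration_class,
             stringsAsFactors = FALSE)
}

#' Optical parameters of one bipolar LC droplet
#'
#' Parameters of the crossed-polarizer transmission model used to render a
#' single bipolar droplet: the droplet footprint, the (undirected) bipolar
#' axis orientation, the interference ring pattern, the two dark surface
#' defects at the poles, and image-quality factors (focus blur, brightness).
#'
#' @param radius droplet radius in pixels (> 0).
#' @param center numeric length-2, droplet center `(x, y)` in pixels.
#' @param director_angle bipolar-axis orientation in radians; wrapped to
#'   `[0, pi)` since the axis is undirected.
#' @param ring_phase offset of the interference ring pattern, radians in
#'   `[0, 2*pi)`.
#' @param retardance_scale dimensionless > 0; sets the ring count/spacing
#'   (scaled per color channel by the channel retardance factors).
#' @param defect_contrast darkness of the two polar defect points, in
#'   `[0, 1]`.
#' @param blur_sigma Gaussian focus blur in pixels, >= 0.
#' @param brightness overall droplet brightness in `(0, 1]`.
#' @return A list of class `droplet_params`.
#' @export
droplet_params <- function(radius = 25, center = c(0, 0),
                           director_angle = 0, ring_phase = 0,
                           retardance_scale = 12, defect_contrast = 0.6,
                           blur_sigma = 0.6, brightness = 0.9) {
  if (radius <= 0) stopf("radius must be > 0")
  if (retardance_scale < 0) stopf("retardance_scale must be >= 0")
  if (blur_sigma < 0) stopf("blur_sigma must be >= 0")
  if (brightness <= 0 || brightness > 1) stopf("brightness must be in (0, 1]")
  assert_prob(defect_contrast, "defect_contrast")
  structure(list(
    radius = radius, center = center,
    director_angle = director_angle %% pi,
    ring_phase = ring_phase %% (2 * pi),
    retardance_scale = retardance_scale,
    defect_contrast = defect_contrast,
    blur_sigma = blur_sigma, brightness = brightness
  ), class = "droplet_params")
}

# Per-channel retardance factors: optical path difference in waves scales as
# 1/lambda, so blue shows more rings than red (R ~ 610 nm, G ~ 530, B ~ 470).
.channel_factors <- c(0.90, 1.04, 1.17)

#' Render a single bipolar droplet under crossed polarizers
#'
#' Renders the characteristic crossed-polarizer texture of a bipolar nematic
#' droplet: a four-fold extinction cross `sin^2(2*phi)` about the bipolar
#' axis, per-channel concentric interference rings
#' `sin^2(s_c * t(r) + ring_phase)` with normalized thickness
#' `t(r) = sqrt(1 - (r/R)^2)`, two darkened surface defects where the axis
#' meets the rim, and optional Gaussian focus blur. Deterministic given the
#' parameters.
#'
#' @param params a [droplet_params()] object.
#' @param out_size output image side in pixels (>= 2 * radius).
#' @return `out_size x out_size x 3` array in `[0, 1]`.
#' @export
render_droplet <- function(params, out_size) {
  if (!inherits(params, "droplet_params")) stopf("'params' must be droplet_params")
  if (out_size <= 0) stopf("out_size must be > 0")
  if (out_size < 2 * params$radius)
    stopf("out_size (%d) must be >= 2 * radius (%.1f)", out_size, 2 * params$radius)
  R <- params$radius
  # symmetric pixel grid centered on the crop -> exact under 90-degree rotation
  ax <- seq_len(out_size) - (out_size + 1) / 2
  xx <- matrix(ax, out_size, out_size, byrow = TRUE)   # column coordinate
  yy <- matrix(ax, out_size, out_size)                 # row coordinate
  r <- sqrt(xx^2 + yy^2) / R
  inside <- r <= 1
  t_r <- sqrt(pmax(0, 1 - r^2))
  phi <- atan2(yy, xx) - params$director_angle
  cross <- sin(2 * phi)^2
  # polar defects: dark spots where the bipolar axis meets the rim
  px <- R * cos(params$director_angle); py <- R * sin(params$director_angle)
  sig_d <- 0.18 * R
  d1 <- ((xx - px)^2 + (yy - py)^2) / (2 * sig_d^2)
  d2 <- ((xx + px)^2 + (yy + py)^2) / (2 * sig_d^2)
  defect <- 1 - params$defect_contrast * (exp(-d1) + exp(-d2))
  img <- array(0, c(out_size, out_size, 3))
  for (ch in 1:3) {
    s_c <- params$retardance_scale * .channel_factors[ch]
    rings <- sin(s_c * t_r + params$ring_phase)^2
    plane <- params$brightness * cross * rings * defect
    plane[!inside] <- 0
    img[, , ch] <- plane
  }
  if (params$blur_sigma > 0.05) {
    img <- imageData(EBImage::gblur(EBImage::Image(img, colormode = EBImage::Color),
                                    sigma = params$blur_sigma))
  }
  clamp(img, 0, 1)
}

#' @importFrom EBImage imageData
NULL

#' Class-dependent optical perturbation
#'
#' Describes how a condition label perturbs droplet optics relative to a
#' control droplet: additive shifts of retardance (ring count), defect
#' contrast, ring phase and brightness. All shifts are multiplied by a
#' single `effect_size`; at `effect_size = 0` every label generates
#' statistically identical droplets.
#'
#' @param delta_retardance additive retardance shift (dimensionless).
#' @param delta_defect additive defect-contrast shift.
#' @param delta_ring_phase additive ring-phase shift (radians).
#' @param texture_noise_shift additive brightness shift.
#' @param effect_size global non-negative multiplier applied to all deltas.
#' @return A list of class `class_effect`.
#' @export
class_effect <- function(delta_retardance = 0, delta_defect = 0,
                         delta_ring_phase = 0, texture_noise_shift = 0,
                         effect_size = 1) {
  if (effect_size < 0) stopf("effect_size must be >= 0")
  structure(list(delta_retardance = delta_retardance,
                 delta_defect = delta_defect,
                 delta_ring_phase = delta_ring_phase,
                 texture_noise_shift = texture_noise_shift,
                 effect_size = effect_size), class = "class_effect")
}

#' Apply a class effect to droplet parameters
#'
#' Adds each perturbation of `effect`, scaled by its `effect_size`, to the
#' corresponding droplet parameter, plus small label-independent per-droplet
#' jitter. With `effect_size = 0` the output distribution is identical for
#' every label (exchangeability).
#'
#' @param params a [droplet_params()] object (the control draw).
#' @param effect a [class_effect()].
#' @param jitter_sd standard deviation of the label-independent jitter added
#'   to the retardance scale (the other parameters carry their jitter in the
#'   field-level base draws).
#' @return Perturbed `droplet_params`.
#' @export
plant_effect <- function(params, effect, jitter_sd = 0.15) {
  es <- effect$effect_size
  droplet_params(
    radius = params$radius, center = params$center,
    director_angle = params$director_angle,
    ring_phase = params$ring_phase + es * effect$delta_ring_phase,
    retardance_scale = max(0.01, params$retardance_scale +
                             es * effect$delta_retardance + rnorm(1, 0, jitter_sd)),
    defect_contrast = clamp(params$defect_contrast + es * effect$delta_defect, 0, 1),
    blur_sigma = params$blur_sigma,
    brightness = clamp(params$brightness + es * effect$texture_noise_shift,
                       0.01, 1)
  )
}

#' Field-micrograph geometry and noise specification
#'
#' Geometry of a synthetic field micrograph of a stamped droplet array:
#' image size, droplet count range, droplet size dispersion, array pitch
#' (center-to-center grid spacing), background noise level, and the
#' fractions of faint and out-of-focus droplets.
#'
#' @param image_width,image_height field size in pixels.
#' @param droplets_per_field_min,droplets_per_field_max inclusive range of
#'   droplet counts per field.
#' @param radius_mean,radius_sd droplet radius distribution in pixels.
#' @param background_noise_sd Gaussian background noise SD (intensity units,
#'   image range `[0, 1]`).
#' @param pitch grid spacing in pixels; must be `>= 2 * radius_mean`.
#' @param faint_fraction,defocus_fraction probabilities that a droplet is
#'   rendered faint (low brightness) or strongly defocused.
#' @return A list of class `field_spec`.
#' @export
field_spec <- function(image_width = 800, image_height = 600,
                       droplets_per_field_min = 24, droplets_per_field_max = 30,
                       radius_mean = 25, radius_sd = 2,
                       background_noise_sd = 0.015, pitch = 100,
                       faint_fraction = 0.05, defocus_fraction = 0.05) {
  if (droplets_per_field_min < 0 || droplets_per_field_max < droplets_per_field_min)
    stopf("need 0 <= droplets_per_field_min <= droplets_per_field_max")
  if (pitch < 2 * radius_mean)
    stopf("pitch (%.1f) must be >= 2 * radius_mean (%.1f)", pitch, 2 * radius_mean)
  assert_prob(faint_fraction, "faint_fraction")
  assert_prob(defocus_fraction, "defocus_fraction")
  structure(list(image_width = image_width, image_height = image_height,
                 droplets_per_field_min = droplets_per_field_min,
                 droplets_per_field_max = droplets_per_field_max,
                 radius_mean = radius_mean, radius_sd = radius_sd,
                 background_noise_sd = background_noise_sd, pitch = pitch,
                 faint_fraction = faint_fraction,
                 defocus_fraction = defocus_fraction), class = "field_spec")
}

# Label-independent base draw of one droplet's optical parameters.
draw_base_params <- function(spec, faint = FALSE, defocus = FALSE) {
  droplet_params(
    radius = max(4, rnorm(1, spec$radius_mean, spec$radius_sd)),
    center = c(0, 0),
    director_angle = runif(1, 0, pi),
    # droplets of one batch share a typical residual phase (set by material
    # and droplet geometry) with moderate spread; a concentrated base
    # distribution is what makes additive phase effects observable at all
    ring_phase = rnorm(1, 1.5, 0.4),
    retardance_scale = max(0.5, rnorm(1, 12, 0.8)),
    defect_contrast = clamp(rnorm(1, 0.6, 0.05), 0, 1),
    blur_sigma = if (defocus) runif(1, 5, 8) else abs(rnorm(1, 0.6, 0.3)),
    brightness = if (faint) runif(1, 0.08, 0.2) else clamp(rnorm(1, 0.85, 0.05), 0.3, 1)
  )
}

#' Render a synthetic field micrograph
#'
#' Draws a droplet count uniformly within the spec's range, places droplets
#' on a jittered square grid with the given pitch (mirroring the stamped
#' array geometry, which guarantees non-overlap), perturbs each droplet's
#' optics by the label's class effect, renders it, marks random subsets as
#' faint or defocused, and adds Gaussian background noise.
#'
#' @param spec a [field_spec()].
#' @param label a [condition_label()] row (used only for bookkeeping).
#' @param effect a [class_effect()] for the label.
#' @param seed integer seed; the field is a pure function of
#'   `(spec, label, effect, seed)`.
#' @return A list with `image` (`height x width x 3` array in `[0, 1]`),
#'   `boxes` (data frame `x0, y0, x1, y1`, 0-based half-open pixel
#'   coordinates), `label`, and `seed`.
#' @export
render_field <- function(spec, label, effect = class_effect(effect_size = 0),
                         seed = 1L) {
  stopifnot(inherits(spec, "field_spec"))
  with_seed(seed, {
    W <- spec$image_width; H <- spec$image_height; p <- spec$pitch
    margin <- p / 2
    gx <- floor((W - 2 * margin) / p) + 1
    gy <- floor((H - 2 * margin) / p) + 1
    counts <- spec$droplets_per_field_min:spec$droplets_per_field_max
    n <- counts[sample.int(length(counts), 1)]
    if (n > gx * gy)
      stopf("field grid (%d cells) cannot host %d droplets", gx * gy, n)
    img <- array(0.03, c(H, W, 3))
    boxes <- data.frame(x0 = integer(0), y0 = integer(0),
                        x1 = integer(0), y1 = integer(0),
                        faint = logical(0), defocus = logical(0))
    if (n > 0) {
      cells <- sample.int(gx * gy, n)
      jit <- 0.12 * p
      faint <- runif(n) < spec$faint_fraction
      defoc <- runif(n) < spec$defocus_fraction
      for (i in seq_len(n)) {
        cx <- margin + ((cells[i] - 1) %% gx) * p + runif(1, -jit, jit)
        cy <- margin + ((cells[i] - 1) %/% gx) * p + runif(1, -jit, jit)
        base <- draw_base_params(spec, faint[i], defoc[i])
        pars <- plant_effect(base, effect)
        R <- pars$radius
        half <- ceiling(R + max(2, 2 * pars$blur_sigma))
        tile <- render_droplet(droplet_params(
          radius = R, center = c(0, 0), director_angle = pars$director_angle,
          ring_phase = pars$ring_phase, retardance_scale = pars$retardance_scale,
          defect_contrast = pars$defect_contrast, blur_sigma = pars$blur_sigma,
          brightness = pars$brightness), out_size = 2 * half + 1)
        rows <- round(cy) + (-half:half); cols <- round(cx) + (-half:half)
        ok_r <- rows >= 1 & rows <= H; ok_c <- cols >= 1 & cols <= W
        img[rows[ok_r], cols[ok_c], ] <-
          pmax(img[rows[ok_r], cols[ok_c], , drop = FALSE],
               tile[ok_r, ok_c, , drop = FALSE])
        boxes <- rbind(boxes, data.frame(
          x0 = floor(round(cx) - R) - 1L, y0 = floor(round(cy) - R) - 1L,
          x1 = ceiling(round(cx) + R), y1 = ceiling(round(cy) + R),
          faint = faint[i], defocus = defoc[i]))
      }
    }
    if (spec$background_noise_sd > 0)
      img <- img + array(rnorm(length(img), 0, spec$background_noise_sd), dim(img))
    list(image = clamp(img, 0, 1), boxes = boxes, label = label, seed = seed)
  })
}

#' Per-label class-effect table for the PFOA / PFOS study design
#'
#' Builds the table of [class_effect()]s for the study's conditions: 12
#' PFOA classes (4 concentrations including control, in 3 water matrices)
#' plus the river-water PFOS (3.5 ppt) and PFOA + PFOS mixture conditions.
#' PFOA concentration acts chiefly on retardance (ring count) with magnitude
#' increasing with concentration; the water matrix shifts ring phase,
#' defect contrast and brightness; PFOS acts on defect contrast with an
#' opposite ring-phase shift; the mixture effect is the exact superposition
#' of the PFOA (1 ppt) and PFOS effects.
#'
#' @param effect_size global effect-size multiplier applied to every label.
#' @param include_pfos also include the PFOS and mixture river-water rows.
#' @return A data frame with label columns and a list-column `effect`.
#' @export
study_effect_table <- function(effect_size = 1, include_pfos = TRUE) {
  conc_delta <- c("1ppt" = 0.8, "1ppb" = 1.6, "1ppm" = 2.4)
  mat_phase <- c(MilliQ = 0, Tap = 0.5, RiverWater = 1.0)
  mat_defect <- c(MilliQ = 0, Tap = 0.02, RiverWater = 0.04)
  mat_bright <- c(MilliQ = 0, Tap = 0.015, RiverWater = -0.03)
  pfos <- c(defect = 0.12, phase = -0.6, bright = 0.05)
  rows <- list(); effs <- list()
  add <- function(lab, dr, dd, dp, tn) {
    rows[[length(rows) + 1]] <<- lab
    effs[[length(effs) + 1]] <<- class_effect(dr, dd, dp, tn, effect_size)
  }
  for (m in c("MilliQ", "Tap", "RiverWater")) {
    add(condition_label(m, "Control", "none"),
        0, mat_defect[[m]], mat_phase[[m]], mat_bright[[m]])
    for (cc in names(conc_delta))
      add(condition_label(m, "PFOA", cc),
          conc_delta[[cc]], mat_defect[[m]] + 0.02,
          mat_phase[[m]], mat_bright[[m]])
  }
  if (include_pfos) {
    add(condition_label("RiverWater", "PFOS", "3.5ppt"),
        0, mat_defect[["RiverWater"]] + pfos[["defect"]],
        mat_phase[["RiverWater"]] + pfos[["phase"]],
        mat_bright[["RiverWater"]] + pfos[["bright"]])
    add(condition_label("RiverWater", "Mixture", "3.5ppt"),
        conc_delta[["1ppt"]],
        mat_defect[["RiverWater"]] + 0.02 + pfos[["defect"]],
        mat_phase[["RiverWater"]] + pfos[["phase"]],
        mat_bright[["RiverWater"]] + pfos[["bright"]])
  }
  out <- do.call(rbind, rows)
  out$effect <- effs
  out
}

#' Generate a synthetic field-micrograph dataset on disk
#'
#' Renders `fields_per_label` fields for every row of the effect table,
#' writes each as an 8-bit PNG (or TIFF), and returns (and writes) a
#' manifest CSV recording per-field condition labels, seeds, ground-truth
#' droplet counts and bounding boxes. Fully reproducible: identical
#' `(spec, effects, fields_per_label, seed)` give byte-identical manifests
#' and images.
#'
#' @param spec a [field_spec()].
#' @param effects effect table from [study_effect_table()] (label columns +
#'   `effect` list-column).
#' @param fields_per_label number of fields per condition (>= 1).
#' @param out_dir output directory (created if missing).
#' @param seed integer master seed.
#' @param format `"png"` or `"tiff"`.
#' @return The manifest data frame, invisibly also written to
#'   `file.path(out_dir, "manifest.csv")` with bounding boxes serialized as
#'   `x0;y0;x1;y1` groups separated by `|`.
#' @export
generate_dataset <- function(spec, effects, fields_per_label, out_dir,
                             seed = 1L, format = c("png", "tiff")) {
  format <- match.arg(format)
  if (fields_per_label < 1) stopf("fields_per_label must be >= 1")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stopf("cannot create output directory '%s'", out_dir)
  n_lab <- nrow(effects)
  seeds <- matrix(derive_seeds(seed, n_lab * fields_per_label),
                  n_lab, fields_per_label)
  recs <- vector("list", n_lab * fields_per_label)
  k <- 0L
  for (i in seq_len(n_lab)) {
    lab <- effects[i, c("matrix", "analyte", "concentration_class")]
    for (j in seq_len(fields_per_label)) {
      fld <- render_field(spec, lab, effects$effect[[i]], seed = seeds[i, j])
      fname <- sprintf("field_%s_%s_%s_%03d.%s", lab$matrix, lab$analyte,
                       lab$concentration_class, j, format)
      path <- file.path(out_dir, fname)
      write_field_image(fld$image, path, format)
      k <- k + 1L
      recs[[k]] <- data.frame(
        image_path = fname, matrix = lab$matrix, analyte = lab$analyte,
        concentration_class = lab$concentration_class,
        field_seed = seeds[i, j], n_droplets = nrow(fld$boxes),
        boxes = paste(sprintf("%d;%d;%d;%d", fld$boxes$x0, fld$boxes$y0,
                              fld$boxes$x1, fld$boxes$y1), collapse = "|"),
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, recs)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}

write_field_image <- function(img, path, format = "png") {
  img8 <- round(clamp(img, 0, 1) * 255) / 255   # 8-bit quantization
  if (format == "png") png::writePNG(img8, path)
  else tiff::writeTIFF(img8, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a manifest written by [generate_dataset()]
#' @param dir dataset directory containing `manifest.csv`.
#' @return The manifest data frame with a `boxes_df` list-column of parsed
#'   bounding-box data frames.
#' @export
read_manifest <- function(dir) {
  man <- read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  man$boxes_df <- lapply(man$boxes, parse_boxes)
  man
}

parse_boxes <- function(s) {
  if (is.na(s) || !nzchar(s))
    return(data.frame(x0 = integer(0), y0 = integer(0),
                      x1 = integer(0), y1 = integer(0)))
  parts <- do.call(rbind, lapply(strsplit(strsplit(s, "|", fixed = TRUE)[[1]],
                                          ";", fixed = TRUE), as.integer))
  data.frame(x0 = parts[, 1], y0 = parts[, 2], x1 = parts[, 3], y1 = parts[, 4])
}

#' Generate single-droplet crops directly (no field stage)
#'
#' Convenience generator used for model-level experiments: draws droplet
#' parameters from the same base distribution as [render_field()], applies
#' each label's class effect, and renders centered crops. Equivalent to a
#' perfect extraction from synthetic fields, without the detection step.
#'
#' @param n_per_label crops per effect-table row.
#' @param effects effect table ([study_effect_table()] or a subset).
#' @param crop_size output crop side in pixels.
#' @param seed integer seed.
#' @param radius_frac droplet radius as a fraction of `crop_size / 2`.
#' @return A [crop_set()].
#' @export
generate_crops <- function(n_per_label, effects, crop_size = 64, seed = 1L,
                           radius_frac = 0.8) {
  spec <- field_spec(radius_mean = radius_frac * crop_size / 2,
                     radius_sd = 0.04 * crop_size,
                     pitch = 2 * radius_frac * crop_size / 2 + 4)
  n_lab <- nrow(effects)
  images <- array(0, c(crop_size, crop_size, 3, n_per_label * n_lab))
  info <- vector("list", n_lab)
  with_seed(seed, {
    k <- 0L
    for (i in seq_len(n_lab)) {
      for (j in seq_len(n_per_label)) {
        base <- draw_base_params(spec)
        base$radius <- min(base$radius, crop_size / 2 - 1)
        pars <- plant_effect(base, effects$effect[[i]])
        k <- k + 1L
        images[, , , k] <- render_droplet(pars, crop_size)
      }
      info[[i]] <- data.frame(
        droplet_id = sprintf("s%d_L%02d_D%05d", seed, i, seq_len(n_per_label)),
        matrix = effects$matrix[i], analyte = effects$analyte[i],
        concentration_class = effects$concentration_class[i],
        stringsAsFactors = FALSE)
    }
  })
  crop_set(images, do.call(rbind, info))
}
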