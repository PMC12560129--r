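# Synthetic micrograph generator: renderer physics, effect planting,
# field composition and dataset reproducibility.

rot90_img <- function(x) aperm(x, c(2, 1, 3))[dim(x)[2]:1, , , drop = FALSE]

test_that("droplet renderer obeys the crossed-polarizer transmission model", {
  # four-fold symmetry: without polar defects the texture is invariant
  # under 90-degree rotation about the droplet center
  p <- droplet_params(radius = 20, defect_contrast = 0, blur_sigma = 0,
                      director_angle = 0.7, ring_phase = 1.1)
  img <- render_droplet(p, 51)
  expect_lt(max(abs(rot90_img(img) - img)), 1e-12)

  # zero retardance: the sin^2 ring term vanishes, interior uniformly dark
  dark <- render_droplet(droplet_params(radius = 20, retardance_scale = 0,
                                        ring_phase = 0, defect_contrast = 0,
                                        blur_sigma = 0), 48)
  expect_equal(max(dark), 0)

  # the two polar defects darken the rim where the director axis meets it
  ang <- 0.3
  base <- render_droplet(droplet_params(radius = 20, director_angle = ang,
                                        defect_contrast = 0, blur_sigma = 0,
                                        ring_phase = 1.5), 51)
  spotted <- render_droplet(droplet_params(radius = 20, director_angle = ang,
                                           defect_contrast = 0.9, blur_sigma = 0,
                                           ring_phase = 1.5), 51)
  expect_true(all(spotted <= base + 1e-12))
  expect_gt(sum(base - spotted), 0)

  expect_error(render_droplet(p, 10), "out_size")
  expect_error(droplet_params(radius = -1), "radius")
})

test_that("radial bright-ring count matches a 1-D scan oracle", {
  # shared peak counter: strict local maxima with 5%-of-max prominence
  count_peaks <- function(prof) {
    n <- length(prof); cnt <- 0; prom <- 0.05 * max(prof)
    for (i in 2:(n - 1))
      if (prof[i] > prof[i - 1] && prof[i] >= prof[i + 1] &&
          prof[i] - max(min(prof[1:i]), min(prof[i:n])) > prom)
        cnt <- cnt + 1
    cnt
  }
  # oracle: brute-force 1-D scan of sin^2(s * t(r)); the scan stops at
  # r = 22 of R = 30 because rings crowd sub-pixel tight near the rim and
  # are not resolvable on the pixel grid
  ring_count_oracle <- function(s, R = 30)
    count_peaks(sin(s * sqrt(1 - (seq(2, 22, by = 0.001) / R)^2))^2)
  bilin <- function(g, y, x) {
    i0 <- floor(y); j0 <- floor(x); di <- y - i0; dj <- x - j0
    g[i0, j0] * (1 - di) * (1 - dj) + g[i0 + 1, j0] * di * (1 - dj) +
      g[i0, j0 + 1] * (1 - di) * dj + g[i0 + 1, j0 + 1] * di * dj
  }
  ray_count <- function(g) {
    ctr <- (nrow(g) + 1) / 2
    th <- seq(0, 2 * pi, length.out = 129)[-1]
    rs <- seq(2, 22, by = 0.5)
    count_peaks(vapply(rs, function(rr)
      mean(vapply(th, function(a)
        bilin(g, ctr + rr * sin(a), ctr + rr * cos(a)), numeric(1))),
      numeric(1)))
  }
  chan_factors <- c(0.90, 1.04, 1.17)
  for (s in c(5, 9, 12, 16.5)) {
    img <- render_droplet(droplet_params(radius = 30, retardance_scale = s,
                                         ring_phase = 0, defect_contrast = 0,
                                         blur_sigma = 0), 101)
    for (ch in 1:3)
      expect_equal(ray_count(img[, , ch]),
                   ring_count_oracle(s * chan_factors[ch]),
                   label = sprintf("s=%g ch=%d", s, ch))
  }
})

test_that("plant_effect shifts parameters linearly and is label-blind at zero effect", {
  base_draw <- function() droplet_params(radius = 20, retardance_scale = 12,
                                         defect_contrast = 0.6, brightness = 0.8)
  # zero effect size: draws are exchangeable across different labels
  set.seed(1)
  a <- replicate(1000, plant_effect(base_draw(),
                                    class_effect(2, 0.3, 1, 0.1, effect_size = 0))$retardance_scale)
  b <- replicate(1000, plant_effect(base_draw(),
                                    class_effect(0, 0, 0, 0, effect_size = 0))$retardance_scale)
  expect_gt(suppressWarnings(ks.test(a, b)$p.value), 0.01)

  # Monte-Carlo mean shift equals delta_retardance at effect_size 1
  set.seed(2)
  shift1 <- mean(replicate(10000, plant_effect(base_draw(),
                                               class_effect(delta_retardance = 0.2))$retardance_scale)) - 12
  expect_equal(shift1, 0.2, tolerance = 0.02)

  # doubling the effect size doubles the mean shift
  set.seed(3)
  shift2 <- mean(replicate(10000, plant_effect(base_draw(),
                                               class_effect(delta_retardance = 0.2, effect_size = 2))$retardance_scale)) - 12
  expect_equal(shift2, 2 * shift1, tolerance = 0.05)
})

test_that("field rendering places 24-30 droplets with exact bounding boxes", {
  sp <- field_spec()
  counts <- vapply(1:8, function(s)
    nrow(render_field(sp, condition_label(), seed = s)$boxes), numeric(1))
  expect_true(all(counts >= 24 & counts <= 30))

  # empty field: pure background, no boxes
  sp0 <- field_spec(droplets_per_field_min = 0, droplets_per_field_max = 0)
  fld0 <- render_field(sp0, condition_label(), seed = 1)
  expect_equal(nrow(fld0$boxes), 0)
  expect_lt(diff(range(fld0$image)), 0.2)

  # connected-component oracle on the noiseless image: rendered droplet
  # count equals the generator's bookkeeping (a morphological closing merges
  # the lobes the dark extinction cross cuts a single droplet into; droplets
  # sit at least ~40 px apart so closing cannot merge neighbours)
  spn <- field_spec(background_noise_sd = 0, faint_fraction = 0,
                    defocus_fraction = 0)
  for (s in 1:10) {
    fld <- render_field(spn, condition_label(), seed = 100 + s)
    mask <- rowMeans(fld$image, dims = 2) > 0.06
    closed <- EBImage::closing(EBImage::Image(mask * 1),
                               EBImage::makeBrush(15, "disc"))
    ncomp <- max(EBImage::bwlabel(closed))
    expect_equal(ncomp, nrow(fld$boxes), label = sprintf("seed %d", 100 + s))
  }
})

test_that("ground-truth boxes never overlap at the default array pitch", {
  sp <- field_spec()   # pitch 100 >= 2 * (25 + 3 * 2)
  for (s in 1:6) {
    b <- render_field(sp, condition_label(), seed = 200 + s)$boxes
    if (nrow(b) < 2) next
    for (i in seq_len(nrow(b) - 1)) {
      ov <- b$x0[-(1:i)] < b$x1[i] & b$x1[-(1:i)] > b$x0[i] &
        b$y0[-(1:i)] < b$y1[i] & b$y1[-(1:i)] > b$y0[i]
      expect_false(any(ov))
    }
  }
})

test_that("per-label pixel statistics are exchangeable at zero effect size", {
  eff <- study_effect_table(effect_size = 0, include_pfos = FALSE)
  two <- eff[c(1, 8), ]   # different matrix and concentration labels
  crops <- generate_crops(250, two, crop_size = 24, seed = 5)
  g <- apply(crops$images, 4, mean)
  v <- apply(crops$images, 4, var)
  first <- crops$info$matrix == two$matrix[1] &
    crops$info$concentration_class == two$concentration_class[1]
  expect_gt(suppressWarnings(ks.test(g[first], g[!first])$p.value), 0.01)
  expect_gt(suppressWarnings(ks.test(v[first], v[!first])$p.value), 0.01)
})

test_that("dataset generation is byte-reproducible and seed-sensitive", {
  eff <- study_effect_table(effect_size = 1, include_pfos = FALSE)
  sp <- field_spec(image_width = 320, image_height = 240,
                   droplets_per_field_min = 4, droplets_per_field_max = 6,
                   pitch = 64, radius_mean = 18, radius_sd = 1.5)
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  d3 <- file.path(tempdir(), "ds3")
  m1 <- generate_dataset(sp, eff, fields_per_label = 1, out_dir = d1, seed = 9)
  m2 <- generate_dataset(sp, eff, fields_per_label = 1, out_dir = d2, seed = 9)
  m3 <- generate_dataset(sp, eff, fields_per_label = 1, out_dir = d3, seed = 10)

  expect_equal(nrow(m1), 12)             # 12 labels x 1 field
  expect_true(all(m1$n_droplets >= 4))
  expect_identical(m1$boxes, m2$boxes)   # same seed: identical manifests
  expect_identical(unname(tools::md5sum(file.path(d1, m1$image_path[1]))),
                   unname(tools::md5sum(file.path(d2, m2$image_path[1]))))
  expect_false(identical(m1$boxes, m3$boxes))  # disjoint seeds differ

  rt <- read_manifest(d1)
  expect_equal(nrow(rt$boxes_df[[1]]), rt$n_droplets[1])
  unlink(c(d1, d2, d3), recursive = TRUE)
})
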