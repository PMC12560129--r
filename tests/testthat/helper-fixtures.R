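# Shared fixtures. Heavy objects are built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# Small encoder for fast tests (24 px input keeps three 2x poolings valid).
small_espec <- function(latent = 32, input = 24)
  encoder_spec(latent_dim = latent, channel_widths = c(6, 8, 12),
               input_size = input)

# The model-scale encoder used for the cross-validated experiments.
cv_espec <- function() encoder_spec(latent_dim = 128, input_size = 32)

# Two well-separated conditions (MilliQ control vs 1 ppm PFOA).
binary_conditions <- function(effect_size) {
  eff <- study_effect_table(effect_size = effect_size, include_pfos = FALSE)
  eff[eff$matrix == "MilliQ" &
        (eff$analyte == "Control" | eff$concentration_class == "1ppm"), ]
}

# River-water conditions for the 4-class species task (single PFOA level).
rw4_conditions <- function(effect_size) {
  eff <- study_effect_table(effect_size = effect_size)
  eff[eff$matrix == "RiverWater" &
        (eff$analyte %in% c("Control", "PFOS", "Mixture") |
           (eff$analyte == "PFOA" & eff$concentration_class == "1ppb")), ]
}

# River-water conditions for the 6-class transfer task.
rw6_conditions <- function(effect_size) {
  eff <- study_effect_table(effect_size = effect_size)
  eff[eff$matrix == "RiverWater", ]
}

# A small untrained-ish trained model fitted on a trivial 2-class task;
# reused wherever tests only need a valid model object.
tiny_model <- function() memo("tiny_model", {
  crops <- generate_crops(12, binary_conditions(3), crop_size = 24, seed = 42)
  train_joint(crops, label_scheme("binary_pfas")$map(crops$info),
              espec = small_espec(),
              config = training_config(epochs = 2, batch_size = 12, seed = 7))
})

expect_partition <- function(folds, ids) {
  expect_setequal(folds$droplet_id, ids)
  expect_false(anyDuplicated(folds$droplet_id) > 0)
}
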