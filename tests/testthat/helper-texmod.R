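# Shared fixtures: small designs and scenarios built in code.

study_freqs <- c(1, 2, 4, 8)
study_kinds <- c("SN", "SQ", "CS")

small_design <- function(...) {
  study_design(texture_types = c("OM", "CVM"), n_participants = 2,
               thresholds_per_condition = 3, ...)
}

noise_free_scenario <- function(seed = 1) {
  generator_scenario(noise_cv = 0, seed = seed)
}

# A small texture spec that renders quickly.
small_spec <- function(type = "OM", n_gabors = 40) {
  texture_spec(type, field_diameter = 3, n_gabors = n_gabors)
}

regime_params <- function() {
  list(detection = dog_params(100, 0.6, 12, 1.8),
       discrimination = dog_params(100, 1, 2, 4),
       cvm = dog_params(100, 1, 2.5, 4))
}
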