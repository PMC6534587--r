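# Shared fixture builders: everything is generated in code at test time.

# Degenerate (noise-free) stage parameters with a given mean.
flat_params <- function(mean_g = 100, stage = "Control", n_points = 200) {
  stage_params(stage, mean_g = mean_g, between_sd = 0, within_sd = 0,
               axial_slope = 0, n_animals = 1)
}

# A gvalue_image holding the 8-bit quantized version of a generated field,
# i.e. what load_gvalue_image() returns after a lossless round trip.
quantized_image <- function(gen) {
  q <- quantize_gvalues(gen$image)
  gvalue_image(matrix(as.numeric(q), nrow(q)))
}

# Profile with positions 0:(n-1).
make_profile <- function(values, stage = NA_character_, id = NA_character_) {
  measurement_profile(values, seq_along(values) - 1, stage, id)
}

# One animal's measurement-line profile (after render->load quantization).
simulated_profile <- function(params, seed, n_points = 200) {
  gen <- generate_animal_field(params, 1, seed, width = n_points, height = 3)
  img <- quantized_image(gen)
  extract_line_profile(img, line_spec(c(0, 1), c(n_points - 1, 1), n_points),
                       stage_label = params$stage_label)
}

# Pooled quantized pixels of n independently seeded animals (1-row fields).
pooled_stage_pixels <- function(params, n_animals, seeds, n_points = 200) {
  unlist(lapply(seeds[seq_len(n_animals)], function(s) {
    gen <- generate_animal_field(params, 1, s, width = n_points, height = 1)
    as.numeric(quantize_gvalues(gen$image))
  }))
}

# Small two-stage config for fast end-to-end runs.
tiny_config <- function() {
  list(
    model = "tiny", n_points = 40L, height = 8L,
    stages = list(
      Control = stage_params("Control", 32.5, 1.5, 1.2, 0.01, n_animals = 3),
      LGD = stage_params("LGD", 54.6, 3, 2, -0.01, n_animals = 3)
    )
  )
}

# Mann-Whitney AUC oracle: tie-corrected U / (n1 n2) via rank sums.
mann_whitney_auc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  n1 <- length(pos); n2 <- length(neg)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}
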