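# Shared fixtures, built in code at test time.

# A deterministic geometry-only phantom spec: vanishing speckle, flat
# surface and DEJ, no hyperkeratosis or shadows.
flat_spec <- function(height = 64, width = 48, thickness = 20, seed = 1L, ...) {
  phantom_spec(height = height, width = width,
               surface_depth_mean = 12, surface_roughness_amplitude = 0,
               epidermis_thickness_mean = thickness,
               epidermis_thickness_amplitude = 0,
               speckle_contrast = 0.01, attenuation_rate = 0.01,
               hyperkeratosis_probability = 0,
               hyperkeratosis_extra_thickness = 1,
               shadow_count_mean = 0, seed = seed, ...)
}

# A small low-noise phantom spec sized for fast model tests.
tiny_spec <- function(seed = 1L, height = 32L, width = 32L,
                      speckle = 0.05) {
  phantom_spec(height = height, width = width,
               surface_depth_mean = 8, surface_roughness_amplitude = 2,
               epidermis_thickness_mean = 8, epidermis_thickness_amplitude = 2,
               speckle_contrast = speckle, attenuation_rate = 0.02,
               hyperkeratosis_probability = 0,
               hyperkeratosis_extra_thickness = 1,
               shadow_count_mean = 0, seed = seed)
}

tiny_dataset <- function(n, seed0 = 500L, height = 32L, width = 32L,
                         speckle = 0.05) {
  ds <- lapply(seq_len(n), function(i) {
    p <- generate_phantom(tiny_spec(seed = seed0 + i, height = height,
                                    width = width, speckle = speckle))
    list(image = p$image, mask = p$mask)
  })
  names(ds) <- sprintf("item%02d", seq_len(n))
  ds
}
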