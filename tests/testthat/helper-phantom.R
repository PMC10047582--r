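# small, fast phantom used throughout the suite
small_spec <- function(effect_size = 2, seed = 42, ...) {
  phantom_spec(grid_shape = c(36, 36, 36), cavity_radius_mm = 5,
               shell_thickness_mm = 7, recurrence_depth_mm = 6,
               effect_size = effect_size, seed = seed, ...)
}

rand_grid <- function(dm = c(8, 8, 8), seed = 1, spacing = c(1, 1, 1)) {
  set.seed(seed)
  voxel_grid(array(rnorm(prod(dm)), dm), spacing)
}
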