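# Small, fast phantoms for unit tests: 500 um lateral field (the smallest
# that still holds the 450 um quasi-point window) and a shallow epithelium so
# the axial field can be short.

tiny_spec <- function(...) {
  args <- list(...)
  defaults <- list(
    epithelial_thickness_um = 40,
    bowman_thickness_um = 15,
    lateral_extent_um = 500,
    axial_depth_um_optical = 160,
    tear_depth_um_optical = 25,
    n_frames = 2,
    speckle_contrast = 0,
    jitter_sd_px = 0,
    seed = 42L
  )
  do.call(phantom_spec, utils::modifyList(defaults, args))
}

# Ground-truth interface rows of a stack in the 1-based internal convention.
truth_rows <- function(stack) {
  lapply(stack$ground_truth, function(d) d / stack$axial_px_um_optical + 1)
}

# Tiny three-group cohort parameters for fast pipeline tests.
tiny_group_params <- function(n = 3) {
  list(
    HC = group_params("HC", n, 15.41, 1.0, 40, 1.0, 539.72, 20, 43.7, 1.7,
                      40, 10, 0.5),
    KC = group_params("KC", n, 14.27, 1.0, 38, 1.0, 507.58, 20, 51.7, 8.4,
                      32, 9, 0.2),
    CD = group_params("CD", n, 15.65, 1.0, 40, 1.0, 564.44, 20, 45.9, 2.3,
                      69, 14, 0.5)
  )
}

tiny_config <- function(seed = 1L, ...) {
  pipeline_config(
    seed = seed,
    group_params = tiny_group_params(),
    n_captures = 1L,
    spec_overrides = list(lateral_extent_um = 500,
                          axial_depth_um_optical = 160,
                          tear_depth_um_optical = 25,
                          n_frames = 2,
                          speckle_contrast = 0.1,
                          jitter_sd_px = 1),
    ...
  )
}
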