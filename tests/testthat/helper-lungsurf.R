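# shared fixtures, built once per test run and memoised

default_params <- acquisition_params()

# scaled-down thorax for fast unit/property tests: same physical extent as
# the default phantom, coarser voxels
small_phantom_spec <- function(...) {
  phantom_spec(shape = c(96, 96, 76), spacing = c(1.2, 1.2, 1.5), ...)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

small_noiseless <- function() cached("small_noiseless", function()
  build_phantom(small_phantom_spec(noise_sd = 0, seed = 11), default_params))

small_snr50 <- function() cached("small_snr50", function()
  build_phantom(small_phantom_spec(seed = 12), default_params))

# full-size datasets at the default study conditions
full_noiseless <- function() cached("full_noiseless", function()
  build_phantom(phantom_spec(noise_sd = 0, seed = 21), default_params))

full_snr50 <- function() cached("full_snr50", function()
  build_phantom(phantom_spec(seed = 22), default_params))

# minimal concentration result wrapping a raw concentration array, for
# metric tests that construct fields directly
synth_conc <- function(cmap, spacing, clamp_negative = TRUE) {
  structure(
    list(concentration = volume3d(cmap, spacing),
         r1_post = NULL, R1_pre = NA_real_, r1 = NA_real_,
         clamp_negative = clamp_negative,
         invalid_voxel_count = 0L, negative_clamped_count = 0L,
         mask = array(TRUE, dim(cmap))),
    class = "concentration_result"
  )
}
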