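# Shared fixtures, computed lazily and cached across test files so the
# expensive 128^3 pipelines run once per test_dir invocation.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Axial angular error in degrees, folded into [0, 90].
ha_error <- function(a, b) abs(((a - b + 90) %% 180) - 90)

# The headline helical ramp phantom: 128^3, 5.8 um voxels, HA +60 -> -60,
# IA 0, noise-free, analysed with the 123.5 um window.
ramp_fixture <- function() {
  cached_fixture("ramp", {
    spec <- fiber_phantom_spec(
      dims = c(128L, 128L, 128L), voxel_size_um = 5.8,
      ha_epi_deg = 60, ha_endo_deg = -60, ia_deg = 0,
      dispersion_deg = 0, noise_sigma = 0, seed = 1L
    )
    ph <- generate_fiber_phantom(spec)
    map <- compute_myomap(ph$volume, tissue_mask = "all",
                          window_size_um = 123.5)
    list(spec = spec, phantom = ph, map = map)
  })
}

# Region-mean FA of a volume over its margin-excluded valid voxels at the
# standard 123.5 um window.
valid_mean_fa <- function(vol) {
  map <- compute_myomap(vol, tissue_mask = "all", window_size_um = 123.5)
  as.numeric(mean_fa(map$FA, valid = map$valid))
}

# Small asymmetric integer test volume: every axis has a different extent
# and a ramp with a different slope, so any axis swap or flip is detected.
asymmetric_volume <- function() {
  d <- c(4L, 5L, 6L)
  arr <- array(0, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    arr[i, j, k] <- i + 10 * j + 100 * k
  }
  volume3d(arr, voxel_size_um = c(1, 2, 3))
}

python_bin <- function() Sys.which("python")
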