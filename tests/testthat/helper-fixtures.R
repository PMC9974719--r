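# shared fixtures: a coarse (3 mm) phantom keeps unit tests fast while
# preserving the default anatomy; the full-resolution default is exercised in
# the acceptance suite.

small_phantom_config <- function(...) {
  phantom_config(grid_shape = c(86, 86, 64), voxel_spacing = c(3, 3, 3), ...)
}

# memoized phantoms (generated once per test run)
.fixture_env <- new.env()
small_phantom <- function(noise = FALSE) {
  key <- if (noise) "noisy" else "noiseless"
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_phantom(
      small_phantom_config(noise_sd = if (noise) 0.5 else 0, seed = 7L))
  .fixture_env[[key]]
}

uniform_dose <- function(value, dims = c(10, 10, 10), spacing = c(2, 2, 2)) {
  volume_grid(array(value, dim = dims), spacing)
}

full_mask <- function(dims = c(10, 10, 10), spacing = c(2, 2, 2),
                      name = "struct") {
  structure_mask(name, array(TRUE, dim = dims), spacing)
}

# brute-force all-pairs margin expansion (oracle for expand_margin)
brute_force_expand <- function(mask, margin_mm) {
  d <- dim(mask$data)
  co <- as.matrix(expand.grid(
    x = (seq_len(d[1]) - 1) * mask$spacing[1],
    y = (seq_len(d[2]) - 1) * mask$spacing[2],
    z = (seq_len(d[3]) - 1) * mask$spacing[3]))
  src <- co[as.vector(mask$data), , drop = FALSE]
  hit <- vapply(seq_len(nrow(co)), function(i) {
    min(sqrt(colSums((t(src) - co[i, ])^2))) <= margin_mm + 1e-9
  }, logical(1))
  structure_mask(mask$name, array(hit, dim = d), mask$spacing, mask$origin)
}

# sorting oracle for Dx%: minimum dose of the hottest `frac` of the voxels
sort_oracle_dx <- function(doses, frac) {
  sort(doses, decreasing = TRUE)[ceiling(frac * length(doses))]
}
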