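# Shared fixtures: desk-scale phantoms (64^3 at 3.75 mm keeps the whole
# thorax on the grid) and smooth random dose fields.

small_dims <- c(64L, 64L, 64L)
small_spacing <- 3.75

noiseless_spec <- function(seed = 1L, ...) {
  phantom_spec(dim = small_dims, spacing = small_spacing,
               noise_sd = c(air = 0, fat = 0, lung = 0, soft_tissue = 0,
                            bone = 0),
               dixon_noise_sd = 0, seed = seed, ...)
}

noisy_spec <- function(seed = 1L, ...) {
  phantom_spec(dim = small_dims, spacing = small_spacing, seed = seed, ...)
}

# bone labels collapse to soft tissue in the 4-class Dixon view
four_class <- function(labels) {
  v <- labels$values
  v[v == TISSUE_CODES[["bone"]]] <- TISSUE_CODES[["soft_tissue"]]
  v
}

# smooth positive random field in [offset, offset + 1] on an n^3 grid
smooth_field <- function(n = 16L, spacing = 2, seed = 1L, offset = 0.01) {
  set.seed(seed)
  a <- array(rnorm(n^3), rep(n, 3L))
  a <- synctdose:::gauss_smooth_cpp(as.numeric(a), rep(n, 3L), rep(2, 3))
  a <- (a - min(a)) / (max(a) - min(a))
  volume_grid(array(a + offset, rep(n, 3L)), spacing)
}

# a realistic evaluated/reference dose pair: mostly shared structure with a
# small independent perturbation
smooth_dose_pair <- function(seed, n = 16L, mix = 0.03) {
  r <- smooth_field(n, seed = seed)
  p <- smooth_field(n, seed = seed + 5000L)
  e <- r
  e$values <- (1 - mix) * r$values + mix * p$values + mix / 3
  list(reference = r, evaluated = e)
}

uniform_density <- function(value = 1, n = 41L, spacing = 2) {
  volume_grid(array(value, rep(n, 3L)), spacing)
}
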