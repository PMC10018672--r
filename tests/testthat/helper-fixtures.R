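# Fixture builders shared across the suite. Everything is generated in code;
# nothing is read from disk except files the tests themselves write.

# constant-valued volume on a small grid
const_volume <- function(value, dim = c(8, 8, 8), spacing = c(1, 1, 1)) {
  volume_grid(array(value, dim = dim), spacing = spacing)
}

full_mask <- function(dim = c(8, 8, 8), spacing = c(1, 1, 1), label = "all") {
  binary_mask(array(TRUE, dim = dim), spacing = spacing, label = label)
}

# axis-aligned block mask: TRUE on the given index ranges
block_mask <- function(dim, i, j, k, spacing = c(1, 1, 1), label = "block") {
  a <- array(FALSE, dim = dim)
  a[i, j, k] <- TRUE
  binary_mask(a, spacing = spacing, label = label)
}

# smooth positive dose blob with a controllable fraction of low-dose voxels
blob_dose <- function(dim = c(16, 16, 16), spacing = c(2, 2, 2),
                      peak = 50, width = 0.35) {
  co <- .coords_list(dim)
  c0 <- (dim + 1) / 2
  r2 <- ((co$i - c0[1]) / (width * dim[1]))^2 +
        ((co$j - c0[2]) / (width * dim[2]))^2 +
        ((co$k - c0[3]) / (width * dim[3]))^2
  volume_grid(array(peak * exp(-r2), dim = dim), spacing = spacing)
}

.coords_list <- function(dim) {
  list(
    i = array(rep(seq_len(dim[1]), times = dim[2] * dim[3]), dim = dim),
    j = array(rep(rep(seq_len(dim[2]), each = dim[1]), times = dim[3]), dim = dim),
    k = array(rep(seq_len(dim[3]), each = dim[1] * dim[2]), dim = dim)
  )
}

# random smooth-ish dose pair for gamma testing: reference blob plus a
# perturbed evaluated copy (multiplicative drift + localized bump)
random_dose_pair <- function(seed, dim = c(16, 16, 16), spacing = c(2, 2, 2)) {
  set.seed(seed)
  ref <- blob_dose(dim = dim, spacing = spacing,
                   peak = runif(1, 30, 70), width = runif(1, 0.25, 0.4))
  co <- .coords_list(dim)
  bump_c <- runif(3, 4, dim - 3)
  bump <- exp(-(((co$i - bump_c[1]))^2 + ((co$j - bump_c[2]))^2 +
                  ((co$k - bump_c[3]))^2) / runif(1, 8, 20))
  drift <- 1 + runif(1, -0.03, 0.03)
  ev <- volume_grid(ref$values * drift +
                      runif(1, -0.05, 0.05) * max(ref$values) * bump,
                    spacing = spacing)
  ev$values[ev$values < 0] <- 0
  list(ref = ref, ev = ev)
}

# a phantom spec with every error knob off: sCT identical to dCT; any knob
# can be switched back on through ...
null_error_spec <- function(seed = 1, ...) {
  args <- list(bias_amplitude_hu = 0, noise_sd_hu = 0, bone_dropout_prob = 0,
               edge_blur = FALSE, n_air_dct_only = 0, n_air_sct_only = 0,
               n_air_shared = 0, sct_dose_scale = 1, dose_perturb_frac = 0,
               seed = seed)
  do.call(phantom_spec, utils::modifyList(args, list(...)))
}
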