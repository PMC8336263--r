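# Fixture builders shared across test files. Everything is generated in code;
# no binary fixtures are stored.

# noiseless default-geometry spec: the calibration fixtures
fixture_spec <- function(...) panel_spec(noise_sd = 0, ...)

fixture_plant <- function(seed = 3L, spec = fixture_spec(), ...) {
  generate_plant(spec, seed = seed, sample_id = sprintf("fix%02d", seed), ...)
}

# a bundle whose five rasters are all the given constant matrix
constant_bundle <- function(value = 50, nr = 24L, nc = 24L, id = "const") {
  m <- matrix(value, nr, nc)
  scan_bundle(stats::setNames(rep(list(m), 5L), BUNDLE_ELEMENTS), id)
}

# bundle from one shared metal raster (all four metals identical) + compton
bundle_from_rasters <- function(metal, compton = metal, id = "fix") {
  scan_bundle(list(Zn = metal, K = metal, Ca = metal, Ni = metal,
                   Compton = compton), id)
}

# tiny labelled map: 10 plant pixels in a 6x6 image, 2 px of each class
# plus 2 extra tissue px
tiny_labels <- function() {
  m <- matrix(0L, 6L, 6L)
  m[1, 1:2] <- 1L  # petiole
  m[2, 1:2] <- 2L  # margin
  m[3, 1:2] <- 3L  # vein
  m[4, 1:2] <- 4L  # tissue
  m[5, 1:2] <- 4L
  seg_labels(m)
}

# simulate trait values (no images) for a balanced accession panel
simulate_trait <- function(n_acc, k, sd_g, sd_e, seed) {
  withr::with_seed(seed, {
    g <- rnorm(n_acc, 0, sd_g)
    data.frame(accession_id = rep(sprintf("a%03d", seq_len(n_acc)), each = k),
               value = rep(g, each = k) + rnorm(n_acc * k, 0, sd_e))
  })
}

expect_same_mask <- function(a, b) expect_identical(unname(a), unname(b))
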