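# Shared in-code fixtures: tiny images and enrichment sets built fresh per
# run, never stored on disk.

tiny_image <- function() {
  spectral_image(
    coords = cbind(x = c(0L, 1L, 0L), y = c(0L, 0L, 1L)),
    mz = c(400.2, 520.6, 766.5),
    intensities = rbind(c(2, 3, 5), c(1, 1, 2), c(4, 0, 6))
  )
}

identity_ratios <- c(gls_ogdh = 1, ogdh_sdhf = 1, sdhf_mdh = 1)

# small noiseless rendered dataset shared by segmentation/enrichment tests
noiseless_dataset <- function(n_types = 3, seed = 11L, width = 16, height = 16) {
  simulate_msi_dataset(width = width, height = height, n_types = n_types,
                       noise_sd = 0, tic_cv = 0, seed = seed)
}

random_fractions <- function(n) {
  x <- stats::runif(n + 1)
  x / sum(x)
}
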