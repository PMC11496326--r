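# Shared small fixtures for the study-condition network used across tests.

mtl_region_spec <- function() region_spec(AMG = 2, HPC = 2, TP = 2, PHP = 2)

mtl_edges <- function(strength = 0.4, lag = 1L) {
  dplyr::bind_rows(
    coupling_edge("AMG", "HPC", strength, lag = lag),
    coupling_edge("TP", "HPC", strength, lag = lag),
    coupling_edge("TP", "PHP", strength, lag = lag)
  )
}

# A short clean recording for preprocessing tests: sinusoids + noise.
toy_recording <- function(n_sec = 30, fs = 250, n_ch = 4, seed = 1) {
  set.seed(seed)
  t <- seq_len(n_sec * fs) / fs
  X <- sapply(seq_len(n_ch), function(j) {
    sin(2 * pi * (4 + 3 * j) * t) + rnorm(length(t), sd = 0.5)
  })
  labs <- paste0(rep(c("HPC", "AMG"), each = ceiling(n_ch / 2)),
                 rep(1:2, 2))[seq_len(n_ch)]
  regions <- sub("[0-9]+$", "", labs)
  names(regions) <- labs
  recording(X, sampling_rate = fs, labels = labs, regions = regions)
}
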