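# Shared fixture builders. Everything is generated in code; nothing is
# stored on disk except transient WAVs in tempdir().

# a quantized sinusoidal epoch set (n x 2400) with labels
toy_epochs <- function(n = 4L, W = 2400L, f0 = 500, label = 0L, seed = 1L) {
  set.seed(seed)
  m <- t(vapply(seq_len(n), function(i)
    quantize16(0.8 * sin(2 * pi * f0 * (seq_len(W) + i * 7) / 8000)), numeric(W)))
  wb_epochs(m, label = label, source_id = sprintf("toy%03d", seq_len(n)),
            recorded_at = seq_len(n))
}

# a small standardized noise pool
toy_pool <- function(n = 3L, tag = "train", seed = 2L, duration = 1) {
  set.seed(seed)
  make_noise_pool(n_per_kind = n, duration = duration, partition_tag = tag,
                  kinds = c("harmonic", "broadband"))
}

# write a 16-bit mono WAV from raw integer PCM values; returns the path
write_pcm16 <- function(pcm, sample_rate, path = tempfile(fileext = ".wav")) {
  write_wav(pcm / 32768, path, sample_rate)
  path
}

# labeled random-ish dataset: one epoch per recording so chronological
# fold parts can be balanced exactly
flat_epoch_set <- function(n_per_class, num_class, seed = 3L) {
  set.seed(seed)
  n <- n_per_class * num_class
  wb_epochs(matrix(rnorm(n * 32), n, 32),
            label = rep(seq_len(num_class) - 1L, each = n_per_class),
            source_id = sprintf("r%04d", seq_len(n)),
            recorded_at = rep(seq_len(n_per_class), num_class))
}
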